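STOP_CODONS <- c("TAA", "TAG", "TGA")
SUBST_TYPES <- c("G>A", "C>T", "T>C", "A>G", "G>C", "C>G",
                 "A>C", "A>T", "C>A", "G>T", "T>A", "T>G")

#' Generate a random transcript model
#'
#' The CDS is a valid open reading frame (ATG start, single terminal stop, no
#' internal stop codons); every exon junction gets random intron flanks with
#' the canonical GT (donor) and AG (acceptor) dinucleotides planted. Fully
#' deterministic under `seed`.
#'
#' @param n_exons number of exons (used when `exon_lengths` is `NULL`).
#' @param exon_lengths optional integer vector of coding bp per exon; the
#'   total is forced to a multiple of 3 when drawn randomly, and must be one
#'   when supplied.
#' @param seed integer master seed.
#' @param flank_len intron flank length stored per junction side (>= 26 so
#'   junction-proximal scans have full protospacer+PAM context).
#' @param name transcript name.
#' @return `transcript_model`.
#' @export
make_transcript <- function(n_exons = 12, exon_lengths = NULL, seed = 1,
                            flank_len = 30, name = "SYNTX1") {
  if (flank_len < 26) stop("flank_len must be >= 26")
  with_seed(sub_seed(seed, "transcript"), {
    if (is.null(exon_lengths)) {
      exon_lengths <- sample(60:400, n_exons, replace = TRUE)
      rem <- sum(exon_lengths) %% 3
      if (rem != 0) exon_lengths[n_exons] <- exon_lengths[n_exons] + (3 - rem)
    }
    exon_lengths <- as.integer(exon_lengths)
    total <- sum(exon_lengths)
    if (total %% 3 != 0)
      stop("total coding length (", total, ") must be divisible by 3")
    if (total < 6) stop("CDS too short for start + stop")
    sense <- setdiff(names(genetic_code()), STOP_CODONS)
    n_codons <- total / 3
    codons <- c("ATG", sample(sense, n_codons - 2, replace = TRUE), "TAA")
    cds <- paste(codons, collapse = "")
    flanks <- lapply(seq_len(length(exon_lengths) - 1), function(j) {
      list(donor = paste0("GT", paste(sample(DNA_BASES, flank_len - 2,
                                             replace = TRUE), collapse = "")),
           acceptor = paste0(paste(sample(DNA_BASES, flank_len - 2,
                                          replace = TRUE), collapse = ""), "AG"))
    })
    transcript_model(name, exon_lengths, cds, flanks)
  })
}

set_codon <- function(model, codon_number, codon) {
  stopifnot(nchar(codon) == 3)
  s <- (codon_number - 1) * 3 + 1
  substr(model$cds_seq, s, s + 2) <- codon
  model
}

#' Synthetic stand-in for the CRB1-A reference transcript
#'
#' The real reference transcript (RefSeq NM_201253) cannot be redistributed
#' or fetched offline, so worked examples run against this synthetic
#' stand-in. It is a random ORF with the documented structural facts of the
#' CRB1-A coding sequence planted deterministically: 12 exons, CDS 4221 bp
#' with exons 6+7+9 spanning 2448 bp and c.2843 as the first nucleotide of
#' exon 9; codon 948 = TGC so c.2843G>A is a Cys>Tyr missense ABE target;
#' Asn codons at c.93 and c.1647 so the C>T changes there are synonymous; and
#' a Ser1025 (AGC) neighbourhood around c.3074 carrying an NNNRRT PAM such
#' that SaCas9-KKH places the mutant adenine of c.3074G>A at editing-window
#' position 10 with bystander adenines at window positions 6, 8 and 9 only.
#' Everything outside these planted features is synthetic filler and carries
#' no relation to the real gene.
#'
#' @return `transcript_model` named `"CRB1A_synthetic"`.
#' @export
crb1a_synthetic_model <- function() {
  lengths <- c(90, 213, 186, 144, 279, 1022, 726, 182, 700, 300, 250, 129)
  model <- make_transcript(exon_lengths = lengths, seed = 1908,
                           name = "CRB1A_synthetic")
  model <- set_codon(model, 31, "AAC")    # c.93C>T  -> synonymous
  model <- set_codon(model, 549, "AAC")   # c.1647C>T -> synonymous
  model <- set_codon(model, 745, "ACA")   # c.2234C>T -> missense (ABE, antisense)
  model <- set_codon(model, 764, "CGT")   # c.2290C>T -> missense
  model <- set_codon(model, 948, "TGC")   # c.2843G>A -> Cys948Tyr
  # c.3058..3096: Ser1025 block with planted NNNRRT PAM at c.3085-3090
  block <- c("CTG", "GAG", "TCC", "TGC", "ACA", "AGC", "TGC",
             "CTG", "GTC", "CAG", "GAT", "GGC", "CTT")
  for (i in seq_along(block))
    model <- set_codon(model, 1019 + i, block[i])
  model
}

#' Specification of a synthetic two-source variant cohort
#'
#' Defaults restate the published cohort structure: 1115 variants of which
#' 211 appear in both pseudo-sources; 49% of records carry at least one
#' pathogenic-level label (41% pathogenic/likely pathogenic, 8% conflicting
#' with a pathogenic label); the analyzed consequence mix is 46/30/16/6/1.5/0.5
#' percent missense / indel / nonsense / splice / intronic / synonymous; and
#' the substitution-type mix yields 53% transitions with an ABE/CBE/GBE/none
#' editor split of 34/19/9/38 percent.
#'
#' @param n_variants cohort size.
#' @param overlap_fraction fraction of variants present in both sources.
#' @param label_model named fractions over
#'   `pathogenic`, `conflicting_pathogenic`, `conflicting_other`, `vus`,
#'   `benign`, `unclassified` (must sum to 1).
#' @param consequence_mix named fractions over the analyzed consequence
#'   classes `missense`, `nonsense`, `synonymous`, `ins/del/dup`, `splice`,
#'   `intronic`.
#' @param substitution_mix named fractions over the 12 ordered substitution
#'   types (`"G>A"`, ...), applied to analyzed SNVs.
#' @param report_count_model list with `prob`: per-source report counts are
#'   `1 + rgeom(prob)`.
#' @param exact plant compositions by exact counts (largest remainder) rather
#'   than sampling; keeps recovery tests sharp.
#' @param gene gene symbol written to the exports.
#' @param seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_variants = 1115,
                        overlap_fraction = 211 / 1115,
                        label_model = c(pathogenic = 0.41,
                                        conflicting_pathogenic = 0.08,
                                        conflicting_other = 0.03,
                                        vus = 0.24, benign = 0.20,
                                        unclassified = 0.04),
                        consequence_mix = c(missense = 0.46, nonsense = 0.16,
                                            synonymous = 0.005,
                                            `ins/del/dup` = 0.30,
                                            splice = 0.06, intronic = 0.015),
                        substitution_mix = c(`G>A` = 0.23, `C>T` = 0.11,
                                             `T>C` = 0.14, `A>G` = 0.05,
                                             `G>C` = 0.045, `C>G` = 0.045,
                                             `A>C` = 0.38 / 6, `A>T` = 0.38 / 6,
                                             `C>A` = 0.38 / 6, `G>T` = 0.38 / 6,
                                             `T>A` = 0.38 / 6, `T>G` = 0.38 / 6),
                        report_count_model = list(prob = 0.6),
                        exact = TRUE, gene = "GENE1", seed = 1) {
  stopifnot(n_variants >= 1, overlap_fraction >= 0, overlap_fraction <= 1,
            abs(sum(label_model) - 1) < 1e-8,
            abs(sum(consequence_mix) - 1) < 1e-8,
            abs(sum(substitution_mix) - 1) < 1e-8,
            setequal(names(substitution_mix), SUBST_TYPES))
  structure(list(n_variants = as.integer(n_variants),
                 overlap_fraction = overlap_fraction,
                 label_model = label_model,
                 consequence_mix = consequence_mix,
                 substitution_mix = substitution_mix,
                 report_count_model = report_count_model,
                 exact = exact, gene = gene, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Bucket every (CDS position, substitution type) pair by the consequence a
# direct codon translation gives it. This is the brute-force oracle route:
# the generator's ground truth never goes through call_consequence().
exonic_buckets <- function(model) {
  cds <- strsplit(model$cds_seq, "", fixed = TRUE)[[1]]
  total <- length(cds)
  gc <- genetic_code()
  codon_idx <- (seq_len(total) - 1) %/% 3 + 1
  within <- (seq_len(total) - 1) %% 3 + 1
  codons <- vapply(seq_len(total / 3), function(i)
    paste(cds[(3 * i - 2):(3 * i)], collapse = ""), character(1))
  ref_aa <- unname(gc[codons])
  out <- list()
  for (ty in SUBST_TYPES) {
    ref <- substr(ty, 1, 1); alt <- substr(ty, 3, 3)
    pos <- which(cds == ref)
    if (!length(pos)) next
    alt_codons <- codons[codon_idx[pos]]
    for (k in 1:3) {
      sel <- within[pos] == k
      if (any(sel)) {
        tmp <- alt_codons[sel]
        substr(tmp, k, k) <- alt
        alt_codons[sel] <- tmp
      }
    }
    alt_aa <- unname(gc[alt_codons])
    raa <- ref_aa[codon_idx[pos]]
    cons <- ifelse(alt_aa == "*" & raa != "*", "nonsense",
                   ifelse(alt_aa == raa, "synonymous", "missense"))
    out[[ty]] <- split(pos, cons)
  }
  out
}

# Junction slots for splice (+/-1,+/-2) and intronic (+/-3) substitutions:
# one row per (junction, signed offset) with its anchored coding position and
# the reference base read from the stored flank.
junction_slots <- function(model) {
  cs <- cumsum(model$exon_cds_lengths)
  rows <- list()
  for (j in seq_len(length(model$exon_cds_lengths) - 1)) {
    fl <- model$intron_flanks[[j]]
    if (is.null(fl)) next
    for (o in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        junction = j, position = cs[j], offset = o,
        ref = substr(fl$donor, o, o),
        category = if (o <= 2) "splice" else "intronic",
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        junction = j, position = cs[j] + 1L, offset = -o,
        ref = substr(fl$acceptor, nchar(fl$acceptor) - o + 1,
                     nchar(fl$acceptor) - o + 1),
        category = if (o <= 2) "splice" else "intronic",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Fill an (type x category) allocation matrix with row quotas sc, column
# quotas cc, capped by bucket availability. Categories are filled in order of
# increasing flexibility; missense absorbs row remainders.
allocate_joint <- function(sc, cc, avail, exact) {
  cats <- c("nonsense", "synonymous", "splice", "intronic", "missense")
  M <- matrix(0L, nrow = length(SUBST_TYPES), ncol = length(cats),
              dimnames = list(SUBST_TYPES, cats))
  sc_rem <- sc
  for (cat in setdiff(cats, "missense")) {
    q <- cc[[cat]] %||% 0L
    while (q > 0) {
      cap <- pmin(sc_rem, vapply(SUBST_TYPES, function(t)
        avail[[t]][[cat]] %||% 0L, numeric(1)) - M[, cat])
      cap[cap < 0] <- 0
      if (sum(cap) == 0) {
        msg <- paste0("cannot place ", q, " remaining '", cat,
                      "' variants: no feasible (type, position) pairs left")
        if (exact) stop(msg) else { warning(msg, call. = FALSE); break }
      }
      take <- apportion(cap / sum(cap), min(q, sum(cap)))
      take <- pmin(take, cap)
      M[, cat] <- M[, cat] + as.integer(take)
      sc_rem <- sc_rem - as.integer(take)
      q <- q - sum(take)
    }
  }
  M[, "missense"] <- as.integer(sc_rem)
  short <- sc_rem - vapply(SUBST_TYPES, function(t)
    avail[[t]][["missense"]] %||% 0L, numeric(1))
  if (any(short > 0))
    stop("transcript too small: not enough distinct missense positions for ",
         paste(SUBST_TYPES[short > 0], collapse = ","))
  M
}

#' Generate a synthetic two-source variant cohort
#'
#' Emits two database-export-style entry tables (an LOVD-like and a
#' ClinVar-like pseudo-source) plus a ground-truth table of every planted
#' attribute, so pipeline recovery can be asserted exactly. With
#' `spec$exact = TRUE` (default) all compositions are planted by exact
#' counts. Ground-truth consequences come from direct codon translation of
#' the transcript, independent of the pipeline's consequence caller.
#'
#' @param spec [cohort_spec()].
#' @param model `transcript_model` with `cds_seq` and intron flanks.
#' @return list with `source_a` (LOVD-like entries), `source_b`
#'   (ClinVar-like), and `truth` (one row per variant: `key`, `hgvs_c`,
#'   `class`, `consequence`, `subst_type`, `titv`, `editor`, `in_both`,
#'   `conflict`, `conflicting_pathogenic`, `reports_a`, `reports_b`).
#' @export
make_cohort <- function(spec, model) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "transcript_model"))
  n <- spec$n_variants

  class_counts <- apportion(spec$label_model, n)
  analyzed_classes <- c("pathogenic", "conflicting_pathogenic")
  n_a <- sum(class_counts[analyzed_classes])

  cc <- apportion(spec$consequence_mix, n_a)
  n_indel <- cc[["ins/del/dup"]]
  snv_cc <- cc[setdiff(names(cc), "ins/del/dup")]
  n_snv <- sum(snv_cc)
  sc <- apportion(spec$substitution_mix, n_snv)

  ex_b <- exonic_buckets(model)
  slots <- junction_slots(model)
  avail <- lapply(stats::setNames(SUBST_TYPES, SUBST_TYPES), function(ty) {
    ref <- substr(ty, 1, 1)
    ex <- ex_b[[ty]] %||% list()
    list(missense = length(ex$missense %||% integer(0)),
         nonsense = length(ex$nonsense %||% integer(0)),
         synonymous = length(ex$synonymous %||% integer(0)),
         splice = sum(slots$ref == ref & slots$category == "splice"),
         intronic = sum(slots$ref == ref & slots$category == "intronic"))
  })
  M <- allocate_joint(sc, as.list(snv_cc), avail, spec$exact)

  # ---- instantiate analyzed variants --------------------------------------
  hgvs <- character(0); consequence <- character(0); stype <- character(0)
  with_seed(sub_seed(spec$seed, "positions"), {
    for (ty in SUBST_TYPES) {
      ref <- substr(ty, 1, 1); alt <- substr(ty, 3, 3)
      for (cat in c("missense", "nonsense", "synonymous")) {
        k <- M[ty, cat]
        if (k == 0) next
        pool <- ex_b[[ty]][[cat]]
        pos <- if (length(pool) == 1) pool else sample(pool, k)
        hgvs <- c(hgvs, paste0("c.", pos, ref, ">", alt))
        consequence <- c(consequence, rep(cat, k))
        stype <- c(stype, rep(ty, k))
      }
      for (cat in c("splice", "intronic")) {
        k <- M[ty, cat]
        if (k == 0) next
        pool <- which(slots$ref == ref & slots$category == cat)
        sel <- if (length(pool) == 1) pool else sample(pool, k)
        off <- slots$offset[sel]
        hgvs <- c(hgvs, paste0("c.", slots$position[sel],
                               ifelse(off > 0, "+", ""), off, ref, ">", alt))
        consequence <- c(consequence, rep(cat, k))
        stype <- c(stype, rep(ty, k))
      }
    }
    # indels: small deletions/duplications/insertions at distinct positions
    if (n_indel > 0) {
      total <- sum(model$exon_cds_lengths)
      pos <- sample(seq_len(total - 6), n_indel)
      kind3 <- rep_len(c("del", "dup", "ins"), n_indel)
      ihgvs <- ifelse(kind3 == "del", paste0("c.", pos, "_", pos + 2, "del"),
               ifelse(kind3 == "dup", paste0("c.", pos, "dup"),
                      paste0("c.", pos, "_", pos + 1, "ins",
                             sample(DNA_BASES, n_indel, replace = TRUE))))
      hgvs <- c(hgvs, ihgvs)
      consequence <- c(consequence, rep("ins/del/dup", n_indel))
      stype <- c(stype, rep(NA_character_, n_indel))
    }
  })
  stopifnot(length(hgvs) == n_a, !anyDuplicated(hgvs))

  # ---- non-analyzed variants ----------------------------------------------
  n_rest <- n - n_a
  with_seed(sub_seed(spec$seed, "background"), {
    used <- new.env(parent = emptyenv())
    for (h in hgvs) assign(h, TRUE, envir = used)
    rest <- character(0)
    cdsv <- strsplit(model$cds_seq, "", fixed = TRUE)[[1]]
    guard <- 0L
    while (length(rest) < n_rest) {
      guard <- guard + 1L
      if (guard > 200L) stop("could not generate enough distinct background variants")
      need <- n_rest - length(rest)
      p <- sample(length(cdsv), need * 2L, replace = TRUE)
      a <- vapply(cdsv[p], function(b) sample(setdiff(DNA_BASES, b), 1),
                  character(1))
      cand <- paste0("c.", p, cdsv[p], ">", a)
      cand <- cand[!duplicated(cand)]
      cand <- cand[!vapply(cand, exists, logical(1), envir = used)]
      take <- utils::head(cand, need)
      for (h in take) assign(h, TRUE, envir = used)
      rest <- c(rest, take)
    }
  })
  rest_stype <- sub("^c\\.\\d+([ACGT])>([ACGT])$", "\\1>\\2", rest)

  all_hgvs <- c(hgvs, rest)
  all_cons <- c(consequence, rep(NA_character_, n_rest))
  all_type <- c(stype, rest_stype)
  all_class <- c(rep(analyzed_classes, class_counts[analyzed_classes]),
                 rep(setdiff(names(class_counts), analyzed_classes),
                     class_counts[setdiff(names(class_counts), analyzed_classes)]))

  # ---- source membership ---------------------------------------------------
  n_shared <- if (spec$exact) as.integer(round(spec$overlap_fraction * n))
              else stats::rbinom(1, n, spec$overlap_fraction)
  conflicting <- grepl("^conflicting", all_class)
  if (sum(conflicting) > n_shared)
    stop("overlap_fraction too small to host all conflicting variants (",
         sum(conflicting), " conflicts, ", n_shared, " shared slots)")
  in_both <- conflicting
  with_seed(sub_seed(spec$seed, "overlap"), {
    extra <- sample(which(!conflicting), n_shared - sum(conflicting))
    in_both[extra] <- TRUE
    only_a <- rep(FALSE, n)
    solo <- which(!in_both)
    only_a[solo[sample(length(solo), ceiling(length(solo) / 2))]] <- TRUE
  })

  # ---- significance labels -------------------------------------------------
  path_strings <- c("Pathogenic", "Likely pathogenic", "Pathogenic/Likely pathogenic")
  ben_strings <- c("Benign", "Likely benign", "Benign/Likely benign")
  lab_a <- rep(NA_character_, n); lab_b <- rep(NA_character_, n)
  with_seed(sub_seed(spec$seed, "labels"), {
    for (i in seq_len(n)) {
      cl <- all_class[i]
      pick <- function(x) x[sample.int(length(x), 1)]
      if (cl == "pathogenic") {
        la <- pick(path_strings); lb <- pick(path_strings)
      } else if (cl == "conflicting_pathogenic") {
        la <- pick(path_strings); lb <- pick(c("Uncertain significance", ben_strings))
        if (stats::runif(1) < 0.5) { tmp <- la; la <- lb; lb <- tmp }
      } else if (cl == "conflicting_other") {
        la <- pick(ben_strings); lb <- "Uncertain significance"
        if (stats::runif(1) < 0.5) { tmp <- la; la <- lb; lb <- tmp }
      } else if (cl == "vus") {
        la <- lb <- "Uncertain significance"
      } else if (cl == "benign") {
        la <- pick(ben_strings); lb <- pick(ben_strings)
      } else {
        la <- lb <- ""
      }
      lab_a[i] <- la; lab_b[i] <- lb
    }
    # exercise the "classified in one, unclassified in the other" merge rule
    sp <- which(in_both & all_class == "pathogenic")
    if (length(sp) >= 10) lab_b[sp[seq(1, length(sp), by = 10)]] <- ""
  })

  # ---- report counts -------------------------------------------------------
  prob <- spec$report_count_model$prob %||% 0.6
  with_seed(sub_seed(spec$seed, "reports"), {
    rep_a <- 1L + stats::rgeom(n, prob)
    rep_b <- 1L + stats::rgeom(n, prob)
  })
  rep_a[!(in_both | only_a)] <- 0L
  rep_b[!(in_both | !only_a)] <- 0L

  tt <- rep(NA_character_, n); edd <- rep(NA_character_, n)
  has_t <- !is.na(all_type)
  if (any(has_t)) {
    r <- substr(all_type[has_t], 1, 1); a <- substr(all_type[has_t], 3, 3)
    re <- required_editor(r, a)
    tt[has_t] <- re$titv; edd[has_t] <- re$editor
  }

  truth <- data.frame(
    key = paste0(spec$gene, ":", all_hgvs),
    hgvs_c = all_hgvs, class = all_class, consequence = all_cons,
    subst_type = all_type, titv = tt, editor = edd,
    in_both = in_both,
    conflict = grepl("^conflicting", all_class),
    conflicting_pathogenic = all_class == "conflicting_pathogenic",
    reports_a = ifelse(in_both | only_a, rep_a, 0L),
    reports_b = ifelse(in_both | !only_a, rep_b, 0L),
    stringsAsFactors = FALSE)

  mk_entries <- function(present, labels, reports) {
    data.frame(gene = spec$gene, hgvs_c = all_hgvs[present],
               significance = labels[present],
               times_reported = reports[present],
               flagged = "false", stringsAsFactors = FALSE)
  }
  pres_a <- in_both | only_a
  pres_b <- in_both | !only_a
  list(source_a = mk_entries(pres_a, lab_a, rep_a),
       source_b = mk_entries(pres_b, lab_b, rep_b),
       truth = truth)
}

#' Construct a context guaranteed to contain a planted placement
#'
#' Builds a mutant-allele sequence context that the scanner is guaranteed to
#' resolve to at least one placement for `spec` with the requested target
#' window position and exactly `n_bystanders` bystander substrate bases, and
#' (optionally) no placement at all for a second Cas. The construction is
#' verified by running the scanner before returning; unsatisfiable requests
#' fail after bounded retries.
#'
#' @param substrate_base `"A"` or `"C"`.
#' @param spec [cas_spec()] to plant for.
#' @param target_window_pos requested window position of the target base.
#' @param n_bystanders requested bystander count (at most window size - 1).
#' @param seed integer seed.
#' @param avoid_spec optional [cas_spec()] that must yield zero placements.
#' @param max_tries retry bound for the `avoid_spec` rejection loop.
#' @return list with `context` ([sequence_context()]), `call` (editability
#'   call usable with [find_placements()]), and `cas` (the planted Cas name).
#' @export
plant_pam_context <- function(substrate_base, spec, target_window_pos,
                              n_bystanders, seed = 1, avoid_spec = NULL,
                              max_tries = 100L) {
  stopifnot(inherits(spec, "cas_spec"), substrate_base %in% c("A", "C"))
  w <- as.integer(target_window_pos)
  win <- seq.int(spec$window[1], spec$window[2])
  if (!w %in% win)
    stop("target_window_pos ", w, " outside the ", spec$name, " window ",
         spec$window[1], "-", spec$window[2])
  if (n_bystanders > length(win) - 1)
    stop("n_bystanders ", n_bystanders, " exceeds window size - 1")
  editor <- if (substrate_base == "A") "ABE" else
    intersect(c("CBE", "GBE"), spec$compatible_editors)[1]
  if (is.na(editor) || !editor %in% spec$compatible_editors)
    stop(spec$name, " has no compatible editor for substrate ", substrate_base)
  call <- list(editor = editor, substrate_base = substrate_base,
               substrate_strand = "sense")
  L <- spec$protospacer_len
  non_sub <- setdiff(DNA_BASES, substrate_base)
  with_seed(sub_seed(seed, paste0("plant_", spec$name)), {
    for (try in seq_len(max_tries)) {
      proto <- sample(non_sub, L, replace = TRUE)
      proto[w] <- substrate_base
      if (n_bystanders > 0)
        proto[sample(setdiff(win, w), n_bystanders)] <- substrate_base
      pam <- vapply(strsplit(spec$pam_patterns[1], "")[[1]],
                    function(ch) sample(IUPAC_SETS[[ch]], 1)[1], character(1))
      left <- sample(DNA_BASES, 26, replace = TRUE)
      right <- sample(DNA_BASES, 26, replace = TRUE)
      seq <- if (spec$pam_side == "downstream")
        paste(c(left, proto, pam, right), collapse = "") else
        paste(c(left, pam, proto, right), collapse = "")
      t0 <- if (spec$pam_side == "downstream") 26 + w - 1 else
        26 + length(pam) + w - 1
      ctx <- sequence_context(seq, t0, "mutant")
      pl <- find_placements(ctx, call, spec)
      hit <- pl[pl$target_window_pos == w & pl$n_bystanders == n_bystanders, ]
      if (!nrow(hit)) next
      if (!is.null(avoid_spec)) {
        if (call$editor %in% avoid_spec$compatible_editors &&
            nrow(find_placements(ctx, call, avoid_spec)) > 0) next
      }
      return(list(context = ctx, call = call, cas = spec$name))
    }
  })
  stop("could not satisfy planted-context request for ", spec$name,
       " after ", max_tries, " tries")
}
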