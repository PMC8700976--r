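#' Construct a transcript model in coding coordinates
#'
#' Holds the exon structure of a transcript as per-exon coding lengths, the
#' CDS sequence, and optional intron flank sequences at each exon junction.
#' All variant arithmetic in the package is done in HGVS c. coordinates over
#' this model; genomic liftover is out of scope.
#'
#' @param name transcript name.
#' @param exon_cds_lengths integer vector of coding bp per exon, in transcript
#'   order (exons numbered 1-based).
#' @param cds_seq CDS sequence (`character` or `DNAString`), length equal to
#'   `sum(exon_cds_lengths)`; may be `NULL` for coordinate-only models.
#' @param intron_flanks optional list, one element per junction `i` (between
#'   exon `i` and exon `i+1`), each a list with `donor` (first bases of the
#'   intron) and `acceptor` (last bases of the intron), each at least 26 nt
#'   for full protospacer+PAM context at junctions.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(name, exon_cds_lengths, cds_seq = NULL,
                             intron_flanks = NULL) {
  exon_cds_lengths <- as.integer(exon_cds_lengths)
  stopifnot(length(exon_cds_lengths) >= 1, all(exon_cds_lengths > 0))
  total <- sum(exon_cds_lengths)
  if (!is.null(cds_seq)) {
    cds_seq <- toupper(as.character(cds_seq))
    if (nchar(cds_seq) != total)
      stop("cds_seq length (", nchar(cds_seq), ") != sum(exon_cds_lengths) (",
           total, ")")
    if (!is_dna(cds_seq)) stop("cds_seq contains non-ACGTN characters")
    if (total %% 3 == 0) {
      if (substr(cds_seq, 1, 3) != "ATG")
        warning("CDS does not start with ATG", call. = FALSE)
      last <- substr(cds_seq, total - 2, total)
      if (!last %in% c("TAA", "TAG", "TGA"))
        warning("CDS does not end with a stop codon", call. = FALSE)
    }
  }
  if (!is.null(intron_flanks)) {
    stopifnot(is.list(intron_flanks))
    for (fl in intron_flanks)
      if (!is.null(fl) && (!is_dna(fl$donor %||% "") || !is_dna(fl$acceptor %||% "")))
        stop("intron flank sequences must be ACGTN")
  }
  structure(list(name = name, exon_cds_lengths = exon_cds_lengths,
                 cds_seq = cds_seq, intron_flanks = intron_flanks),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$name, ": ", length(x$exon_cds_lengths),
      " exons, CDS ", sum(x$exon_cds_lengths), " bp",
      if (is.null(x$cds_seq)) " (coordinates only)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Locate the exon containing a coding position
#'
#' @param model `transcript_model`.
#' @param position coding coordinate, `1 <= position <= CDS length`.
#' @return list with `exon` (1-based index) and `offset` (1-based position
#'   within that exon), satisfying `cumsum(lengths)[exon-1] + offset == position`.
#' @export
locate_exon <- function(model, position) {
  stopifnot(inherits(model, "transcript_model"))
  total <- sum(model$exon_cds_lengths)
  if (!is.numeric(position) || position < 1 || position > total)
    stop("position ", position, " outside CDS (1..", total, ")")
  cs <- cumsum(model$exon_cds_lengths)
  exon <- findInterval(position - 1, c(0, cs), rightmost.closed = FALSE)
  prev <- if (exon > 1) cs[exon - 1] else 0L
  list(exon = as.integer(exon), offset = as.integer(position - prev))
}

#' Coding-length summary of a set of exons
#'
#' @param model `transcript_model`.
#' @param exon_indices integer vector of exon numbers (1-based).
#' @return list with `bp` (integer sum of coding lengths) and `fraction`
#'   (share of the CDS).
#' @export
exon_length_summary <- function(model, exon_indices) {
  stopifnot(inherits(model, "transcript_model"))
  n <- length(model$exon_cds_lengths)
  if (any(exon_indices < 1 | exon_indices > n | exon_indices != floor(exon_indices)))
    stop("exon indices out of range 1..", n)
  bp <- sum(model$exon_cds_lengths[unique(exon_indices)])
  list(bp = as.integer(bp), fraction = bp / sum(model$exon_cds_lengths))
}

.pkg_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  # standard code via Biostrings; cached as a plain named vector
  if (is.null(.pkg_cache$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$gc <- stats::setNames(as.character(gc), names(gc))
  }
  .pkg_cache$gc
}

translate_codon <- function(codon) {
  unname(genetic_code()[codon])
}

#' Translate a CDS string
#' @param cds character CDS (length divisible by 3).
#' @return amino-acid string, `*` for stops.
#' @export
translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  # plain codon lookup: no initiator-codon special-casing, so consequence
  # comparisons at codon 1 are positionwise
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Call the mutational consequence of a parsed cDNA change
#'
#' Exonic substitutions are classified by translating the reference and
#' alternate codons: a stop in the alternate codon is `nonsense`, an unchanged
#' amino acid `synonymous`, otherwise `missense`. Substitutions at intron
#' offsets +/-1 and +/-2 disrupt the canonical splice donor/acceptor
#' (`splice`); offset +/-3 is `intronic`; deeper offsets are kept as
#' `intronic-deep` and excluded from the standard breakdown. Deletions,
#' insertions, duplications and delins map to `ins/del/dup`; copy-number
#' syntax passes through as `cnv`; UTR and unrecognised descriptions are
#' `other`.
#'
#' @param change a `cdna_change` (or one row of [parse_hgvs_table()] as list).
#' @param model `transcript_model` with `cds_seq` (required for exonic
#'   substitutions).
#' @return list with `category`, `exon` (or `NA`), `codon_number`,
#'   `aa_ref`, `aa_alt`.
#' @export
call_consequence <- function(change, model) {
  stopifnot(inherits(model, "transcript_model"))
  empty <- list(category = NA_character_, exon = NA_integer_,
                codon_number = NA_integer_, aa_ref = NA_character_,
                aa_alt = NA_character_)
  kind <- change$kind
  if (kind == "cnv") { empty$category <- "cnv"; return(empty) }
  if (kind %in% c("deletion", "insertion", "duplication", "delins")) {
    empty$category <- "ins/del/dup"
    if (!is.na(change$position) && change$intron_offset == 0 &&
        change$position <= sum(model$exon_cds_lengths))
      empty$exon <- locate_exon(model, change$position)$exon
    return(empty)
  }
  if (kind == "other" || isTRUE(change$utr)) { empty$category <- "other"; return(empty) }

  # substitution
  off <- change$intron_offset
  if (off != 0) {
    loc <- locate_exon(model, change$position)
    empty$exon <- loc$exon
    empty$category <- if (abs(off) <= 2) "splice"
                      else if (abs(off) == 3) "intronic" else "intronic-deep"
    return(empty)
  }
  if (is.null(model$cds_seq))
    stop("consequence calling for exonic substitutions needs cds_seq")
  p <- change$position
  total <- sum(model$exon_cds_lengths)
  if (p < 1 || p > total) stop("position ", p, " outside CDS (1..", total, ")")
  obs <- substr(model$cds_seq, p, p)
  if (obs != change$ref)
    stop("reference mismatch at c.", p, ": transcript has ", obs,
         ", HGVS says ", change$ref)
  codon_number <- (p - 1) %/% 3 + 1
  cstart <- (codon_number - 1) * 3 + 1
  ref_codon <- substr(model$cds_seq, cstart, cstart + 2)
  within <- p - cstart + 1
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- change$alt
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  category <- if (aa_alt == "*" && aa_ref != "*") "nonsense"
              else if (aa_alt == aa_ref) "synonymous" else "missense"
  list(category = category, exon = locate_exon(model, p)$exon,
       codon_number = as.integer(codon_number), aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Read/write a transcript model as JSON + FASTA
#'
#' The JSON file carries `name`, `exon_cds_lengths` and the junction inventory;
#' the FASTA carries the CDS (`<name>|cds`) and one record per stored flank
#' (`<name>|junction<i>|donor` / `...|acceptor`).
#'
#' @param model `transcript_model`.
#' @param json_path,fasta_path file paths.
#' @return `write_transcript` returns the paths invisibly; `read_transcript`
#'   returns a `transcript_model`.
#' @export
write_transcript <- function(model, json_path, fasta_path) {
  stopifnot(inherits(model, "transcript_model"))
  junctions <- which(!vapply(model$intron_flanks %||% list(), is.null, logical(1)))
  jsonlite::write_json(list(name = model$name,
                            exon_cds_lengths = model$exon_cds_lengths,
                            junctions_with_flanks = as.integer(junctions)),
                       json_path, auto_unbox = TRUE, digits = NA)
  seqs <- c(stats::setNames(model$cds_seq %||% character(0),
                            if (is.null(model$cds_seq)) NULL
                            else paste0(model$name, "|cds")))
  for (i in junctions) {
    fl <- model$intron_flanks[[i]]
    seqs[paste0(model$name, "|junction", i, "|donor")] <- fl$donor
    seqs[paste0(model$name, "|junction", i, "|acceptor")] <- fl$acceptor
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  invisible(c(json_path, fasta_path))
}

#' @rdname write_transcript
#' @export
read_transcript <- function(json_path, fasta_path) {
  if (!file.exists(json_path)) stop("transcript JSON not found: ", json_path)
  if (!file.exists(fasta_path)) stop("transcript FASTA not found: ", fasta_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- names(seqs)
  cds <- seqs[nm == paste0(meta$name, "|cds")]
  flanks <- NULL
  junc <- meta$junctions_with_flanks
  if (length(junc)) {
    flanks <- vector("list", length(meta$exon_cds_lengths) - 1)
    for (i in junc) {
      flanks[[i]] <- list(
        donor = as.character(seqs[[paste0(meta$name, "|junction", i, "|donor")]]),
        acceptor = as.character(seqs[[paste0(meta$name, "|junction", i, "|acceptor")]]))
    }
  }
  transcript_model(meta$name, meta$exon_cds_lengths,
                   if (length(cds)) as.character(cds[[1]]) else NULL, flanks)
}
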