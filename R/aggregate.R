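CONSEQ_LEVELS <- c("missense", "nonsense", "synonymous", "ins/del/dup",
                   "splice", "intronic")

#' Annotate analyzed records with mutational consequence
#'
#' @param records `variant_records`.
#' @param model `transcript_model`.
#' @return records with `consequence`, `exon`, `codon_number` columns.
#' @export
annotate_consequence <- function(records, model) {
  n <- nrow(records)
  cons <- rep(NA_character_, n)
  exon <- rep(NA_integer_, n)
  codn <- rep(NA_integer_, n)
  cs <- cumsum(model$exon_cds_lengths)
  total <- cs[length(cs)]
  exon_of <- function(p) as.integer(findInterval(p - 1, c(0, cs)))

  kind <- records$kind
  utr <- records$utr %in% TRUE
  cons[kind == "cnv"] <- "cnv"
  idl <- kind %in% c("deletion", "insertion", "duplication", "delins")
  cons[idl] <- "ins/del/dup"
  okp <- idl & !is.na(records$position) & records$intron_offset == 0 &
    records$position >= 1 & records$position <= total
  exon[okp] <- exon_of(records$position[okp])
  cons[kind == "other" | (kind == "substitution" & utr)] <- "other"

  sub <- which(kind == "substitution" & !utr)
  if (length(sub)) {
    off <- records$intron_offset[sub]
    p <- records$position[sub]
    bad <- p < 1 | p > total
    if (any(bad))
      stop("position ", p[which(bad)[1]], " outside CDS (1..", total, ")")
    exon[sub] <- exon_of(p)
    spl <- off != 0
    cons[sub[spl]] <- ifelse(abs(off[spl]) <= 2, "splice",
                             ifelse(abs(off[spl]) == 3, "intronic",
                                    "intronic-deep"))
    ex <- sub[!spl]
    if (length(ex)) {
      if (is.null(model$cds_seq))
        stop("consequence calling for exonic substitutions needs cds_seq")
      pe <- records$position[ex]
      obs <- substring(model$cds_seq, pe, pe)
      mm <- obs != records$ref[ex]
      if (any(mm))
        stop("reference mismatch at c.", pe[which(mm)[1]],
             ": transcript has ", obs[which(mm)[1]],
             ", HGVS says ", records$ref[ex][which(mm)[1]])
      cod <- (pe - 1) %/% 3 + 1
      within <- pe - (cod - 1) * 3
      codon_ref <- substring(model$cds_seq, (cod - 1) * 3 + 1, cod * 3)
      codon_alt <- codon_ref
      for (k in 1:3) {
        selk <- within == k
        if (any(selk)) {
          tmp <- codon_alt[selk]
          substr(tmp, k, k) <- records$alt[ex][selk]
          codon_alt[selk] <- tmp
        }
      }
      gc <- genetic_code()
      aref <- unname(gc[codon_ref])
      aalt <- unname(gc[codon_alt])
      cons[ex] <- ifelse(aalt == "*" & aref != "*", "nonsense",
                         ifelse(aalt == aref, "synonymous", "missense"))
      codn[ex] <- as.integer(cod)
    }
  }
  records$consequence <- cons
  records$exon <- exon
  records$codon_number <- codn
  records
}

#' Rank variants by total report count
#'
#' Descending by `total_reports`; ties broken by variant key lexicographically
#' (stable across runs).
#'
#' @param records `variant_records`.
#' @param n how many to return.
#' @return data.frame with `key`, per-source report columns, `total_reports`.
#' @export
top_reported <- function(records, n) {
  stopifnot(n >= 1)
  ord <- order(-records$total_reports, records$key, method = "radix")
  cols <- c("key", "hgvs_c", grep("^reports_", names(records), value = TRUE),
            "total_reports")
  out <- as.data.frame(records[ord[seq_len(min(n, nrow(records)))], cols,
                               drop = FALSE])
  rownames(out) <- NULL
  out
}

fraction_table <- function(x, levels) {
  n <- length(x)
  tab <- table(factor(x, levels = levels))
  data.frame(class = levels, count = as.integer(tab),
             fraction = if (n) as.numeric(tab) / n else rep(0, length(levels)),
             stringsAsFactors = FALSE)
}

#' Summarize a cohort into the standard report breakdowns
#'
#' Produces the per-cohort breakdowns: clinical significance over all merged
#' records; consequence, transition/transversion and editor class over the
#' analyzed (pathogenic-level-containing) records; per-exon counts with
#' exon-length fractions over exonic analyzed SNVs; most-reported variants;
#' and, when a scan is supplied, the per-Cas assignment breakdown whose
#' denominator is the editable SNVs (the "no PAM" class completes it to 1).
#' Percent display uses round-half-up; raw fractions are retained.
#'
#' @param records all merged `variant_records` (before selection), annotated
#'   with consequence and editability columns for the analyzed subset.
#' @param model `transcript_model`.
#' @param assignments optional assignments data.frame from [scan_cohort()].
#' @param top_n how many most-reported variants to tabulate.
#' @return object of class `summary_report` (a list of data.frames).
#' @export
summarize_cohort <- function(records, model, assignments = NULL, top_n = 10L) {
  analyzed <- select_for_analysis(records)

  sig_class <- ifelse(records$conflict, "conflicting",
                      records$collapsed)
  significance <- fraction_table(
    sig_class, c("pathogenic-level", "VUS", "benign-level", "conflicting",
                 "unclassified"))
  significance$n_conflicting_pathogenic <- c(
    rep(NA_integer_, 3), sum(records$conflicting_pathogenic), NA_integer_)

  keep <- !is.na(analyzed$consequence) &
    analyzed$consequence %in% CONSEQ_LEVELS
  consequence <- fraction_table(analyzed$consequence[keep], CONSEQ_LEVELS)

  snv <- analyzed[analyzed$kind == "substitution" & !is.na(analyzed$editor), ,
                  drop = FALSE]
  titv <- fraction_table(snv$titv, c("transition", "transversion"))
  editor <- fraction_table(snv$editor, c("ABE", "CBE", "GBE", "none"))

  exonic <- analyzed[analyzed$kind == "substitution" &
                       !is.na(analyzed$exon) & analyzed$intron_offset == 0, ,
                     drop = FALSE]
  n_ex <- length(model$exon_cds_lengths)
  exon_table <- data.frame(
    exon = seq_len(n_ex),
    cds_bp = model$exon_cds_lengths,
    cds_fraction = model$exon_cds_lengths / sum(model$exon_cds_lengths),
    n_snv = as.integer(table(factor(exonic$exon, levels = seq_len(n_ex)))),
    n_editable = as.integer(table(factor(
      exonic$exon[exonic$editor != "none"], levels = seq_len(n_ex))))
  )

  cas <- NULL
  if (!is.null(assignments) && nrow(assignments)) {
    lv <- unique(c(default_cas_precedence(), "none", "context unavailable",
                   assignments$assigned))
    cas <- fraction_table(assignments$assigned, lv)
    names(cas)[1] <- "cas"
  }

  structure(list(
    n_records = nrow(records),
    n_analyzed = nrow(analyzed),
    n_analyzed_snv = nrow(snv),
    significance_breakdown = significance,
    consequence_breakdown = consequence,
    titv_breakdown = titv,
    editor_breakdown = editor,
    exon_table = exon_table,
    cas_assignment_breakdown = cas,
    top_reported = top_reported(records, top_n)
  ), class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  pct <- function(f) paste0(round_half_up(100 * f), "%")
  cat("<summary_report> ", x$n_records, " records, ", x$n_analyzed,
      " analyzed (", pct(x$n_analyzed / max(1, x$n_records)), "), ",
      x$n_analyzed_snv, " SNVs\n", sep = "")
  cat("  editor classes: ",
      paste(x$editor_breakdown$class, pct(x$editor_breakdown$fraction),
            collapse = ", "), "\n", sep = "")
  editable <- sum(x$editor_breakdown$fraction[x$editor_breakdown$class != "none"])
  cat("  editable: ", pct(editable), " of analyzed SNVs\n", sep = "")
  if (!is.null(x$cas_assignment_breakdown)) {
    cb <- x$cas_assignment_breakdown
    cat("  Cas assignment (editable SNVs): ",
        paste(cb$cas, pct(cb$fraction), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a summary report to disk
#'
#' One TSV per breakdown plus a combined JSON with full-precision fractions.
#'
#' @param report `summary_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  tabs <- c("significance_breakdown", "consequence_breakdown", "titv_breakdown",
            "editor_breakdown", "exon_table", "cas_assignment_breakdown",
            "top_reported")
  for (nm in tabs) {
    df <- report[[nm]]
    if (is.null(df)) next
    p <- file.path(dir, paste0(gsub("_breakdown$", "", nm), ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(paths, jp))
}
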