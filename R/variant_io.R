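SIG_LEVELS <- c("benign-level", "VUS", "pathogenic-level", "unclassified")

#' Collapse a clinical-significance string to one of three pathogenicity levels
#'
#' Implements the ACMG-style three-level collapse used when deciding whether
#' labels disagree: benign / likely benign / benign-likely-benign map to one
#' level, uncertain significance to a second, pathogenic / likely pathogenic /
#' pathogenic-likely-pathogenic to a third. A variant labelled both
#' "pathogenic" and "likely pathogenic" is therefore not in conflict, whereas
#' "benign" vs "likely pathogenic" is. Matching is case-insensitive and
#' tolerant of `_` and surrounding whitespace; anything unrecognised maps to
#' `"unclassified"` with a warning (real exports contain free text).
#'
#' @param significance_raw character vector of significance strings.
#' @return character vector over `benign-level`, `VUS`, `pathogenic-level`,
#'   `unclassified`.
#' @export
collapse_significance <- function(significance_raw) {
  x <- tolower(trimws(gsub("_", " ", as.character(significance_raw))))
  x <- gsub("[[:space:]]+", " ", x)
  out <- rep("unclassified", length(x))
  out[x %in% c("benign", "likely benign", "benign/likely benign")] <- "benign-level"
  out[x %in% c("uncertain significance", "vus")] <- "VUS"
  out[x %in% c("pathogenic", "likely pathogenic", "pathogenic/likely pathogenic")] <-
    "pathogenic-level"
  unknown <- unique(x[out == "unclassified" & nzchar(x) &
                        !x %in% c("unclassified", "not provided", "not classified", "-")])
  if (length(unknown))
    warning("unrecognised significance label(s) mapped to 'unclassified': ",
            paste(utils::head(unknown, 5), collapse = "; "), call. = FALSE)
  out
}

#' Read a variant table in an LOVD-like or ClinVar-like TSV dialect
#'
#' Tab-delimited with a header row. Required columns (remappable through
#' `col_map`): `gene`, `hgvs_c`, `significance`; optional `times_reported`
#' (defaults to one report per row) and logical `flagged` (rows flagged by the
#' source database as incorrect; dropped before merging).
#'
#' @param path TSV file path.
#' @param source_id label for the source, e.g. `"lovd"` or `"clinvar"`.
#' @param col_map named character vector mapping the canonical column names to
#'   the file's column names.
#' @return data.frame of source entries.
#' @export
read_variant_table <- function(path, source_id,
                               col_map = c(gene = "gene", hgvs_c = "hgvs_c",
                                           significance = "significance",
                                           times_reported = "times_reported",
                                           flagged = "flagged")) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", fileEncoding = "UTF-8")
  need <- c("gene", "hgvs_c", "significance")
  for (nm in need) {
    col <- col_map[[nm]] %||% nm
    if (!col %in% names(df))
      stop("column '", col, "' (", nm, ") missing from ", path)
  }
  out <- data.frame(
    source_id = source_id,
    gene = df[[col_map[["gene"]] %||% "gene"]],
    hgvs_c = df[[col_map[["hgvs_c"]] %||% "hgvs_c"]],
    significance_raw = df[[col_map[["significance"]] %||% "significance"]],
    stringsAsFactors = FALSE
  )
  trc <- col_map[["times_reported"]] %||% "times_reported"
  out$times_reported <- if (trc %in% names(df)) {
    n <- suppressWarnings(as.integer(df[[trc]]))
    ifelse(is.na(n) | n < 1L, 1L, n)
  } else 1L
  flc <- col_map[["flagged"]] %||% "flagged"
  out$flagged <- if (flc %in% names(df))
    tolower(df[[flc]]) %in% c("true", "t", "1", "yes") else FALSE
  if (any(!nzchar(out$hgvs_c)))
    stop("empty hgvs_c value(s) in ", path)
  out
}

#' Merge source entries into harmonized variant records
#'
#' Entries are keyed by gene symbol plus the normalized HGVS c. string.
#' Flagged rows are dropped, within-source duplicates are combined first
#' (report counts summed, labels unioned), then sources are merged: per-source
#' report counts are kept and summed into `total_reports`; the collapsed level
#' set across sources drives the conflict flags. A record classified in one
#' source and unclassified in the other keeps the existing classification. A
#' record is `conflict` when its labels span two or more of the three
#' pathogenicity levels, and `conflicting_pathogenic` when in addition at
#' least one label is pathogenic-level.
#'
#' @param entries data.frame as returned by [read_variant_table()] (rows from
#'   any number of sources bound together).
#' @return data.frame of class `variant_records`, one row per distinct
#'   variant, carrying the parsed change columns from [parse_hgvs_table()].
#' @export
merge_sources <- function(entries) {
  stopifnot(is.data.frame(entries))
  entries <- entries[!entries$flagged %||% FALSE, , drop = FALSE]
  if (!nrow(entries)) return(empty_records())
  entries$norm <- normalize_hgvs(entries$hgvs_c)
  entries$key <- paste0(entries$gene, ":", entries$norm)
  entries$level <- collapse_significance(entries$significance_raw)

  sources <- unique(entries$source_id)
  keys <- sort(unique(entries$key))
  kf <- factor(entries$key, levels = keys)
  ki <- as.integer(kf)
  first <- which(!duplicated(ki))
  first <- first[order(ki[first])]

  parsed <- parse_hgvs_table(entries$norm[first])

  # guard: one key must not carry two different parsed ref bases
  fast <- grepl(SUBST_FAST_RE, entries$norm)
  eref <- ifelse(fast, sub(SUBST_FAST_RE, "\\3", entries$norm), "")
  if (any(!fast)) {
    un <- unique(entries$norm[!fast])
    uref <- vapply(un, function(h) parse_hgvs_c(h)$ref, character(1))
    eref[!fast] <- uref[match(entries$norm[!fast], un)]
  }
  pair <- !duplicated(paste0(ki, "\r", eref)) & nzchar(eref)
  nref <- tabulate(ki[pair], nbins = length(keys))
  if (any(nref > 1))
    stop("inconsistent source data: key '", keys[which(nref > 1)[1]],
         "' parsed with different reference bases")

  has <- function(lv) {
    sel <- entries$level == lv
    tabulate(ki[sel], nbins = length(keys)) > 0
  }
  has_path <- has("pathogenic-level")
  has_vus <- has("VUS")
  has_ben <- has("benign-level")
  n_levels <- has_path + has_vus + has_ben
  collapsed <- ifelse(has_path, "pathogenic-level",
                      ifelse(has_vus, "VUS",
                             ifelse(has_ben, "benign-level", "unclassified")))
  conflict <- n_levels >= 2
  conflicting_pathogenic <- conflict & has_path

  rec <- data.frame(
    key = keys,
    gene = entries$gene[first],
    hgvs_c = parsed$hgvs,
    stringsAsFactors = FALSE, row.names = NULL
  )
  rec <- cbind(rec, parsed[, c("position", "intron_offset", "ref", "alt",
                               "kind", "end_position", "utr")])
  rec$collapsed <- collapsed
  rec$conflict <- conflict
  rec$conflicting_pathogenic <- conflicting_pathogenic
  for (s in sources) {
    cnt <- entries$times_reported * (entries$source_id == s)
    rec[[paste0("reports_", s)]] <- as.integer(rowsum(cnt, ki, reorder = TRUE)[, 1])
  }
  src_pair <- !duplicated(paste0(ki, "\r", entries$source_id))
  rec$n_sources <- tabulate(ki[src_pair], nbins = length(keys))
  rec$total_reports <- as.integer(rowSums(
    as.matrix(rec[, paste0("reports_", sources), drop = FALSE])))
  lab <- split(stats::setNames(entries$significance_raw, entries$source_id), kf)
  lev <- lapply(split(entries$level, kf), unique)
  rec$labels <- I(lab)
  rec$levels <- I(lev)
  class(rec) <- c("variant_records", "data.frame")
  rec
}

empty_records <- function() {
  rec <- data.frame(key = character(), gene = character(), hgvs_c = character(),
                    position = integer(), intron_offset = integer(),
                    ref = character(), alt = character(), kind = character(),
                    end_position = integer(), utr = logical(),
                    collapsed = character(), conflict = logical(),
                    conflicting_pathogenic = logical(),
                    n_sources = integer(), total_reports = integer(),
                    stringsAsFactors = FALSE)
  rec$labels <- I(list()); rec$levels <- I(list())
  class(rec) <- c("variant_records", "data.frame")
  rec
}

#' Select the records entering the amenability analysis
#'
#' Keeps pathogenic/likely-pathogenic records plus conflicting records whose
#' label set includes at least one pathogenic-level classification (which keep
#' their conflict flag). Everything else — benign, VUS, unclassified, and
#' conflicts without a pathogenic label — is excluded.
#'
#' @param records a `variant_records` data.frame.
#' @return the included subset, same class.
#' @export
select_for_analysis <- function(records) {
  keep <- vapply(records$levels, function(l) "pathogenic-level" %in% l, logical(1))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write harmonized variant records as TSV and JSON-lines
#'
#' @param records `variant_records`.
#' @param tsv_path,jsonl_path output paths; either may be `NULL` to skip.
#' @return invisibly, the record count.
#' @export
write_variant_records <- function(records, tsv_path = NULL, jsonl_path = NULL) {
  flat <- records
  flat$labels <- vapply(records$labels, function(l)
    paste(paste0(names(l), "=", l), collapse = ";"), character(1))
  flat$levels <- vapply(records$levels, paste, character(1), collapse = ";")
  if (!is.null(tsv_path))
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(jsonl_path)) {
    con <- file(jsonl_path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(flat)))
      writeLines(jsonlite::toJSON(as.list(flat[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA), con)
  }
  invisible(nrow(records))
}
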