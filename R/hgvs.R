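#' Parse an HGVS coding-DNA (c.) variant description
#'
#' Structural parser for the HGVS dialects found in locus-specific database
#' exports. Substitutions (including intronic offsets such as `c.100+1G>T`),
#' deletions, insertions, duplications and delins are typed; UTR positions
#' (`c.-12`, `c.*45`) and copy-number/uncertain syntax (parentheses, `?`) are
#' recognised and flagged rather than rejected. Position validation beyond
#' syntax is deferred to the transcript model.
#'
#' @param raw a single HGVS string beginning with `"c."`.
#' @return an object of class `cdna_change`: a list with `position`,
#'   `intron_offset`, `ref`, `alt`, `kind` (one of `substitution`, `deletion`,
#'   `insertion`, `duplication`, `delins`, `cnv`, `other`), `end_position`,
#'   `end_intron_offset`, `utr` and the normalized string `hgvs`.
#' @examples
#' parse_hgvs_c("c.2843G>A")
#' parse_hgvs_c("c.100+1G>T")$intron_offset
#' @export
parse_hgvs_c <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("hgvs: expected a single character string")
  s <- gsub("[[:space:]]", "", raw)
  if (!startsWith(tolower(s), "c."))
    stop("hgvs parse error: missing 'c.' prefix in '", raw, "'")
  body <- substr(s, 3, nchar(s))
  if (nchar(body) == 0)
    stop("hgvs parse error: empty description after 'c.' in '", raw, "'")

  out <- list(position = NA_integer_, intron_offset = 0L,
              ref = "", alt = "", kind = "other",
              end_position = NA_integer_, end_intron_offset = 0L,
              utr = FALSE, hgvs = paste0("c.", toupper(body)))
  out$hgvs <- normalize_hgvs_body(body)

  # CNV / uncertain breakpoint syntax: flagged, not failed.
  if (grepl("[(?]", body)) {
    out$kind <- "cnv"
    return(structure(out, class = "cdna_change"))
  }

  pos_re <- "([*-]?\\d+)([+-]\\d+)?"

  # substitution
  m <- regexec(paste0("^", pos_re, "([ACGTacgt])>([ACGTacgt])$"), body)
  g <- regmatches(body, m)[[1]]
  if (length(g)) {
    p <- parse_pos(g[2], g[3])
    out$position <- p$position; out$intron_offset <- p$offset; out$utr <- p$utr
    out$ref <- toupper(g[4]); out$alt <- toupper(g[5])
    if (out$ref == out$alt)
      stop("hgvs parse error: ref equals alt in '", raw, "'")
    out$kind <- if (p$utr) "other" else "substitution"
    return(structure(out, class = "cdna_change"))
  }

  # del / dup / delins / ins over a position or range
  m <- regexec(paste0("^", pos_re, "(?:_", pos_re, ")?",
                      "(delins|del|dup|ins)([ACGTNacgtn]*)$"), body)
  g <- regmatches(body, m)[[1]]
  if (length(g)) {
    p1 <- parse_pos(g[2], g[3])
    out$position <- p1$position; out$intron_offset <- p1$offset; out$utr <- p1$utr
    if (nzchar(g[4])) {
      p2 <- parse_pos(g[4], g[5])
      out$end_position <- p2$position; out$end_intron_offset <- p2$offset
      out$utr <- out$utr || p2$utr
    }
    op <- tolower(g[6]); seq <- toupper(g[7])
    if (op == "ins" && !nzchar(seq))
      stop("hgvs parse error: insertion without inserted sequence in '", raw, "'")
    if (op == "ins" && !nzchar(g[4]))
      stop("hgvs parse error: insertion requires a two-position interval in '", raw, "'")
    out$alt <- if (op %in% c("ins", "delins")) seq else ""
    out$ref <- if (op %in% c("del")) seq else ""
    out$kind <- switch(op, del = "deletion", ins = "insertion",
                       dup = "duplication", delins = "delins")
    return(structure(out, class = "cdna_change"))
  }

  # bare position or interval with no operator, repeats, inversions: "other"
  if (grepl(paste0("^", pos_re, "(_", pos_re, ")?(inv|\\[\\d+\\])?$"), body)) {
    p <- regmatches(body, regexec(paste0("^", pos_re), body))[[1]]
    pp <- parse_pos(p[2], p[3])
    out$position <- pp$position; out$intron_offset <- pp$offset; out$utr <- pp$utr
    out$kind <- "other"
    return(structure(out, class = "cdna_change"))
  }

  stop("hgvs parse error: unrecognised token '", body, "' in '", raw, "'")
}

# position core: "*45" (3' UTR), "-12" (5' UTR), "2843"; offset "+1"/"-2"
parse_pos <- function(pos, off) {
  utr <- grepl("^[*-]", pos)
  position <- if (utr) NA_integer_ else as.integer(pos)
  offset <- if (is.na(off) || !nzchar(off)) 0L else as.integer(off)
  list(position = position, offset = offset, utr = utr)
}

normalize_hgvs_body <- function(body) {
  b <- gsub("[[:space:]]", "", body)
  # uppercase bases, keep operators lowercase
  b <- toupper(b)
  b <- gsub("DELINS", "delins", b, fixed = TRUE)
  b <- gsub("DEL", "del", b, fixed = TRUE)
  b <- gsub("DUP", "dup", b, fixed = TRUE)
  b <- gsub("INS", "ins", b, fixed = TRUE)
  b <- gsub("INV", "inv", b, fixed = TRUE)
  paste0("c.", b)
}

#' Normalize an HGVS c. string for use as a merge key
#'
#' Whitespace is stripped and case is canonicalised (uppercase bases,
#' lowercase operators). Used, together with the gene symbol, as the record
#' key when merging database exports.
#'
#' @param raw character vector of HGVS c. strings.
#' @return character vector of normalized strings.
#' @export
normalize_hgvs <- function(raw) {
  vapply(raw, function(s) {
    s <- gsub("[[:space:]]", "", s)
    if (!startsWith(tolower(s), "c."))
      stop("hgvs parse error: missing 'c.' prefix in '", s, "'")
    normalize_hgvs_body(substr(s, 3, nchar(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.cdna_change <- function(x, ...) {
  cat("<cdna_change> ", x$hgvs, " [", x$kind, "]\n", sep = "")
  invisible(x)
}

SUBST_FAST_RE <- "^c\\.(\\d+)([+-]\\d+)?([ACGT])>([ACGT])$"

#' Parse a vector of HGVS c. strings into a data frame
#'
#' Plain substitutions take a vectorized fast path; everything else goes
#' through [parse_hgvs_c()].
#'
#' @param raw character vector.
#' @return data.frame with one row per input: `hgvs`, `position`,
#'   `intron_offset`, `ref`, `alt`, `kind`, `end_position`, `utr`.
#' @export
parse_hgvs_table <- function(raw) {
  norm <- gsub("[[:space:]]", "", raw)
  fast <- grepl(SUBST_FAST_RE, norm) &
    sub(SUBST_FAST_RE, "\\3", norm) != sub(SUBST_FAST_RE, "\\4", norm)
  if (all(fast)) {
    off <- sub(SUBST_FAST_RE, "\\2", norm)
    return(data.frame(
      hgvs = norm,
      position = as.integer(sub(SUBST_FAST_RE, "\\1", norm)),
      intron_offset = ifelse(off == "", 0L, as.integer(off)),
      ref = sub(SUBST_FAST_RE, "\\3", norm),
      alt = sub(SUBST_FAST_RE, "\\4", norm),
      kind = "substitution", end_position = NA_integer_, utr = FALSE,
      stringsAsFactors = FALSE))
  }
  if (any(fast)) {
    out <- vector("list", 2)
    out[[1]] <- parse_hgvs_table(norm[fast])
    out[[2]] <- parse_hgvs_table_slow(norm[!fast])
    res <- rbind(out[[1]], out[[2]])
    res <- res[order(c(which(fast), which(!fast))), , drop = FALSE]
    rownames(res) <- NULL
    return(res)
  }
  parse_hgvs_table_slow(norm)
}

parse_hgvs_table_slow <- function(raw) {
  rows <- lapply(raw, parse_hgvs_c)
  data.frame(
    hgvs = vapply(rows, `[[`, character(1), "hgvs"),
    position = vapply(rows, `[[`, integer(1), "position"),
    intron_offset = vapply(rows, `[[`, integer(1), "intron_offset"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    kind = vapply(rows, `[[`, character(1), "kind"),
    end_position = vapply(rows, `[[`, integer(1), "end_position"),
    utr = vapply(rows, `[[`, logical(1), "utr"),
    stringsAsFactors = FALSE
  )
}
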