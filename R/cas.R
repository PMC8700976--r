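IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_regex <- function(pattern) {
  key <- paste0("rx_", pattern)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad))
    stop("unknown IUPAC code(s) in pattern '", pattern, "': ",
         paste(bad, collapse = ","))
  rx <- paste0("^", paste(vapply(chars, function(ch) {
    if (ch == "N") "[ACGTN]"
    else if (nchar(paste(IUPAC_SETS[[ch]], collapse = "")) == 1) IUPAC_SETS[[ch]]
    else paste0("[", paste(IUPAC_SETS[[ch]], collapse = ""), "]")
  }, character(1)), collapse = ""), "$")
  .pkg_cache[[key]] <- rx
  rx
}

#' Match a DNA k-mer against an IUPAC degenerate pattern
#'
#' Positionwise set membership: `R` = G/A, `Y` = C/T, `V` = A/C/G, `N` = any,
#' and the rest of the IUPAC alphabet. Pattern and sequence must have equal
#' length.
#'
#' @param pattern IUPAC pattern string (e.g. `"NNGRRT"`).
#' @param seq DNA string of the same length.
#' @return logical.
#' @examples
#' iupac_match("NNGRRT", "AAGGAT")  # TRUE
#' iupac_match("TTTV", "TTTT")      # FALSE: V excludes T
#' @export
iupac_match <- function(pattern, seq) {
  if (nchar(pattern) != nchar(seq))
    stop("pattern and sequence lengths differ (", nchar(pattern), " vs ",
         nchar(seq), ")")
  grepl(iupac_regex(pattern), toupper(seq))
}

#' Construct a Cas protein specification
#'
#' @param name Cas protein name.
#' @param pam_patterns character vector of IUPAC PAM patterns (alternatives).
#' @param pam_side `"downstream"` (3' of the protospacer; Cas9 family) or
#'   `"upstream"` (5'; Cas12 family).
#' @param window inclusive editing-window bounds in protospacer coordinates
#'   (positions numbered 1..`protospacer_len`, 5' to 3' on the protospacer
#'   strand).
#' @param compatible_editors subset of `c("ABE","CBE","GBE")` this Cas has
#'   been functionally coupled with.
#' @param protospacer_len protospacer length (20).
#' @param size_aa protein size in amino acids (`NA` if not tracked).
#' @return object of class `cas_spec`.
#' @export
cas_spec <- function(name, pam_patterns, pam_side, window, compatible_editors,
                     protospacer_len = 20L, size_aa = NA_integer_) {
  pam_side <- match.arg(pam_side, c("downstream", "upstream"))
  window <- as.integer(window)
  stopifnot(length(pam_patterns) >= 1, length(window) == 2,
            1 <= window[1], window[1] <= window[2],
            window[2] <= protospacer_len,
            all(compatible_editors %in% c("ABE", "CBE", "GBE")))
  for (p in pam_patterns) iupac_regex(p)  # validates codes
  structure(list(name = name, pam_patterns = toupper(pam_patterns),
                 pam_side = pam_side, window = window,
                 compatible_editors = compatible_editors,
                 protospacer_len = as.integer(protospacer_len),
                 size_aa = as.integer(size_aa)),
            class = "cas_spec")
}

#' @export
print.cas_spec <- function(x, ...) {
  cat("<cas_spec> ", x$name, ": PAM ", paste(x$pam_patterns, collapse = "/"),
      " (", x$pam_side, "), window ", x$window[1], "-", x$window[2],
      ", editors ", paste(x$compatible_editors, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Default Cas library
#'
#' The Cas proteins evaluated by the pipeline, restricted to those with
#' demonstrated mammalian-cell activity when coupled to the corresponding
#' editor class: SpCas9 and xCas/SpCas9-NG (full ABE/CBE/GBE support — GBEs
#' have only been coupled to these two), SaCas9 and SaCas9-KKH (ABE/CBE),
#' LbCas12a and enAsCas12a-RR/RVR (ABE/CBE, upstream T-rich PAMs), and the
#' compact CasMINI (ABE only, 2-bp window).
#'
#' @return object of class `cas_library`: a named list of [cas_spec()]s.
#' @export
default_cas_library <- function() {
  specs <- list(
    cas_spec("SpCas9", "NGG", "downstream", c(4, 8),
             c("ABE", "CBE", "GBE"), size_aa = 1368),
    cas_spec("xCas/SpCas9-NG", "NG", "downstream", c(4, 8),
             c("ABE", "CBE", "GBE")),
    cas_spec("SaCas9", "NNGRRT", "downstream", c(4, 12),
             c("ABE", "CBE"), size_aa = 1053),
    cas_spec("SaCas9-KKH", "NNNRRT", "downstream", c(2, 15),
             c("ABE", "CBE")),
    cas_spec("LbCas12a", "TTTV", "upstream", c(8, 13),
             c("ABE", "CBE"), size_aa = 1228),
    cas_spec("enAsCas12a", c("TATV", "TYCV"), "upstream", c(8, 13),
             c("ABE", "CBE")),
    cas_spec("CasMINI", "TTTV", "upstream", c(3, 4),
             "ABE", size_aa = 529)
  )
  structure(stats::setNames(specs, vapply(specs, `[[`, character(1), "name")),
            class = "cas_library")
}

#' Default precedence order for single-Cas assignment
#' @return character vector of Cas names, most preferred first.
#' @export
default_cas_precedence <- function() {
  c("SpCas9", "xCas/SpCas9-NG", "SaCas9", "SaCas9-KKH",
    "LbCas12a", "enAsCas12a", "CasMINI")
}

#' Read/write a Cas library as JSON
#'
#' One object per Cas with fields `name`, `pam_patterns`, `pam_side`,
#' `window`, `compatible_editors`, `protospacer_len`, `size_aa`. The default
#' library ships as `system.file("extdata", "cas_library.json", package =
#' "bescan")`.
#'
#' @param lib `cas_library`.
#' @param path JSON file path.
#' @export
write_cas_library <- function(lib, path) {
  jsonlite::write_json(lapply(unclass(lib), unclass), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_cas_library
#' @export
read_cas_library <- function(path) {
  if (!file.exists(path)) stop("Cas library config not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(raw, function(x)
    cas_spec(x$name, x$pam_patterns, x$pam_side, x$window,
             x$compatible_editors, x$protospacer_len %||% 20L,
             x$size_aa %||% NA_integer_))
  structure(stats::setNames(specs, vapply(specs, `[[`, character(1), "name")),
            class = "cas_library")
}

#' Sequence context around a variant base
#'
#' @param seq DNA string (sense strand of the transcript/pre-mRNA region).
#' @param target_offset 0-based index of the variant base within `seq`.
#' @param allele_state `"mutant"` (scans are performed on the patient allele)
#'   or `"reference"`.
#' @return object of class `sequence_context`.
#' @export
sequence_context <- function(seq, target_offset, allele_state = "mutant") {
  seq <- toupper(as.character(seq))
  stopifnot(is_dna(seq), target_offset >= 0, target_offset < nchar(seq))
  structure(list(seq = seq, target_offset = as.integer(target_offset),
                 allele_state = match.arg(allele_state, c("mutant", "reference"))),
            class = "sequence_context")
}

#' Enumerate valid protospacer placements for one variant and one Cas
#'
#' For every editing-window position `w`, a protospacer is placed on the
#' substrate strand (the strand carrying the base the deaminase acts on, which
#' is the PAM-bearing/gRNA-matching strand) such that the substrate base sits
#' at protospacer position `w`. The placement is kept iff the PAM-side k-mer
#' adjacent to the protospacer matches one of the Cas's IUPAC PAM patterns and
#' the protospacer plus PAM lie fully inside the context. Bystanders are the
#' other in-window protospacer positions carrying the same substrate base.
#'
#' @param ctx [sequence_context()] built on the mutant allele.
#' @param call one-row editability call (list or data.frame row) with
#'   `editor`, `substrate_base`, `substrate_strand`.
#' @param spec [cas_spec()].
#' @return data.frame with zero or more rows: `cas`, `strand`,
#'   `protospacer_start` (0-based, in coordinates of the scanned strand —
#'   i.e. of the reverse-complemented context for antisense placements),
#'   `protospacer`, `pam_observed`, `target_window_pos`,
#'   `bystander_positions` (comma-joined), `n_bystanders`. Rows are sorted by
#'   `(strand, protospacer_start)`.
#' @export
find_placements <- function(ctx, call, spec) {
  stopifnot(inherits(ctx, "sequence_context"), inherits(spec, "cas_spec"))
  editor <- call$editor
  if (is.null(editor) || is.na(editor) || editor == "none")
    stop("find_placements requires an editable variant (editor != none)")
  if (!editor %in% spec$compatible_editors)
    stop(spec$name, " is not compatible with editor class ", editor)
  strand <- call$substrate_strand
  sub <- toupper(call$substrate_base)

  if (strand == "sense") {
    sseq <- ctx$seq
    t1 <- ctx$target_offset + 1L
  } else {
    sseq <- revcomp(ctx$seq)
    t1 <- nchar(ctx$seq) - ctx$target_offset
  }
  if (substr(sseq, t1, t1) != sub)
    stop("context/substrate mismatch: expected ", sub, " at target on the ",
         strand, " strand, found ", substr(sseq, t1, t1),
         " (was the context built on the mutant allele?)")

  L <- spec$protospacer_len
  n <- nchar(sseq)
  ws <- seq.int(spec$window[1], spec$window[2])
  truncated <- FALSE
  out <- list()
  chars <- strsplit(sseq, "", fixed = TRUE)[[1]]
  for (w in ws) {
    s <- t1 - w + 1L
    for (pam in spec$pam_patterns) {
      k <- nchar(pam)
      if (spec$pam_side == "downstream") {
        lo <- s; hi <- s + L - 1L + k
        pam_at <- s + L
      } else {
        lo <- s - k; hi <- s + L - 1L
        pam_at <- s - k
      }
      if (lo < 1L || hi > n) { truncated <- TRUE; next }
      pam_seq <- substr(sseq, pam_at, pam_at + k - 1L)
      if (!iupac_match(pam, pam_seq)) next
      proto_chars <- chars[s:(s + L - 1L)]
      bys <- ws[proto_chars[ws] == sub & ws != w]
      out[[length(out) + 1L]] <- data.frame(
        cas = spec$name, strand = strand, protospacer_start = s - 1L,
        protospacer = paste(proto_chars, collapse = ""),
        pam_observed = pam_seq, target_window_pos = w,
        bystander_positions = paste(bys, collapse = ","),
        n_bystanders = length(bys), stringsAsFactors = FALSE)
      break  # one placement per window position even if both patterns match
    }
  }
  if (truncated)
    warning("insufficient flank around target for ", spec$name,
            ": some window positions could not be evaluated", call. = FALSE)
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    cas = character(), strand = character(), protospacer_start = integer(),
    protospacer = character(), pam_observed = character(),
    target_window_pos = integer(), bystander_positions = character(),
    n_bystanders = integer(), stringsAsFactors = FALSE)
  res[order(res$strand, res$protospacer_start), , drop = FALSE]
}

#' Scan one variant against a Cas library
#'
#' Runs [find_placements()] for every library entry compatible with the
#' variant's required editor class; incompatible Cas proteins are omitted from
#' the result (not returned as empty). A variant with `editor == "none"`
#' yields an empty result.
#'
#' @param ctx [sequence_context()].
#' @param call editability call (see [find_placements()]).
#' @param library `cas_library`.
#' @return named list of placement data.frames, one per compatible Cas.
#' @export
scan_variant <- function(ctx, call, library = default_cas_library()) {
  if (is.null(call$editor) || is.na(call$editor) || call$editor == "none")
    return(stats::setNames(list(), character(0)))
  compat <- Filter(function(s) call$editor %in% s$compatible_editors, library)
  lapply(compat, function(spec) find_placements(ctx, call, spec))
}

#' Assign one Cas per variant by precedence
#'
#' Mirrors a mutually-exclusive per-variant Cas accounting: the first Cas in
#' `precedence` with at least one valid placement wins; `"none"` means no PAM
#' anywhere in the library.
#'
#' @param scan_result named list from [scan_variant()].
#' @param precedence ordered character vector of Cas names.
#' @param known character vector of valid Cas names for validation (defaults
#'   to the default library plus whatever the scan returned).
#' @return single Cas name, or `"none"`.
#' @export
assign_primary_cas <- function(scan_result,
                               precedence = default_cas_precedence(),
                               known = NULL) {
  known <- unique(c(known %||% default_cas_precedence(), names(scan_result)))
  bad <- setdiff(precedence, known)
  if (length(bad))
    stop("unknown Cas name(s) in precedence: ", paste(bad, collapse = ", "))
  for (nm in precedence) {
    pl <- scan_result[[nm]]
    if (!is.null(pl) && nrow(pl) > 0) return(nm)
  }
  "none"
}
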