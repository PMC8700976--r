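# Correction map: for a pathogenic ref>alt substitution, which editor class
# reverts the mutant allele to reference, which base it deaminates, and on
# which strand. ABE does A->G, CBE C->T, GBE C->G, always on the strand that
# carries the substrate base of the *mutant* allele.
EDITOR_MAP <- data.frame(
  ref = c("G", "C", "T", "A", "G", "C"),
  alt = c("A", "T", "C", "G", "C", "G"),
  editor = c("ABE", "ABE", "CBE", "CBE", "GBE", "GBE"),
  substrate_base = c("A", "A", "C", "C", "C", "C"),
  substrate_strand = c("sense", "antisense", "sense", "antisense",
                       "sense", "antisense"),
  stringsAsFactors = FALSE
)

PURINES <- c("A", "G")

check_bases <- function(ref, alt) {
  if (any(!toupper(ref) %in% DNA_BASES) || any(!toupper(alt) %in% DNA_BASES))
    stop("ref/alt must be single bases in ACGT")
  if (any(toupper(ref) == toupper(alt)))
    stop("ref and alt must differ")
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are the four purine-to-purine or pyrimidine-to-pyrimidine
#' changes (A>G, G>A, C>T, T>C); the remaining eight ordered changes are
#' transversions.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @return character vector over `transition` / `transversion`.
#' @export
classify_titv <- function(ref, alt) {
  check_bases(ref, alt)
  ifelse((toupper(ref) %in% PURINES) == (toupper(alt) %in% PURINES),
         "transition", "transversion")
}

#' Determine the base-editor class that corrects a substitution
#'
#' Editability means therapeutic correction: the editor must convert the
#' mutant (alt) base back to the reference. G>A and C>T mutations are
#' ABE-correctable (the mutant A, on the sense or antisense strand
#' respectively, is deaminated back to G); T>C and A>G are CBE-correctable;
#' the G:C<->C:G transversions are GBE-correctable; the remaining six
#' transversions have no current editor.
#'
#' @param ref,alt single bases (vectorized).
#' @return data.frame with `titv`, `editor` (`ABE`/`CBE`/`GBE`/`none`),
#'   `substrate_base` (`A`/`C`/`NA`), `substrate_strand`
#'   (`sense`/`antisense`/`NA`).
#' @export
required_editor <- function(ref, alt) {
  check_bases(ref, alt)
  ref <- toupper(ref); alt <- toupper(alt)
  i <- match(paste(ref, alt), paste(EDITOR_MAP$ref, EDITOR_MAP$alt))
  data.frame(
    titv = classify_titv(ref, alt),
    editor = ifelse(is.na(i), "none", EDITOR_MAP$editor[i]),
    substrate_base = ifelse(is.na(i), NA_character_, EDITOR_MAP$substrate_base[i]),
    substrate_strand = ifelse(is.na(i), NA_character_, EDITOR_MAP$substrate_strand[i]),
    stringsAsFactors = FALSE
  )
}

#' Annotate variant records with transition/transversion and editor class
#'
#' Adds `titv`, `editor`, `substrate_base`, `substrate_strand` columns for
#' substitution rows (`NA` elsewhere).
#'
#' @param records `variant_records` data.frame.
#' @return the records with editability columns appended.
#' @export
annotate_editability <- function(records) {
  n <- nrow(records)
  records$titv <- rep(NA_character_, n)
  records$editor <- rep(NA_character_, n)
  records$substrate_base <- rep(NA_character_, n)
  records$substrate_strand <- rep(NA_character_, n)
  snv <- which(records$kind == "substitution")
  if (length(snv)) {
    ed <- required_editor(records$ref[snv], records$alt[snv])
    records$titv[snv] <- ed$titv
    records$editor[snv] <- ed$editor
    records$substrate_base[snv] <- ed$substrate_base
    records$substrate_strand[snv] <- ed$substrate_strand
  }
  records
}

#' Breakdown of SNVs by required editor class
#'
#' @param editor character vector of editor calls over
#'   `ABE`/`CBE`/`GBE`/`none` (SNVs only).
#' @return named numeric vector of fractions over the four classes, summing
#'   to 1; all zero (with `n = 0` attribute) for empty input.
#' @export
editor_breakdown <- function(editor) {
  classes <- c("ABE", "CBE", "GBE", "none")
  if (!length(editor))
    return(structure(stats::setNames(rep(0, 4), classes), n = 0L))
  stopifnot(all(editor %in% classes))
  tab <- table(factor(editor, levels = classes))
  structure(stats::setNames(as.numeric(tab) / length(editor), classes),
            n = length(editor))
}
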