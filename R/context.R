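#' Build the mutant-allele sequence context for a variant
#'
#' Assembles the pre-mRNA neighbourhood of a substitution from the transcript
#' model: exonic positions draw from the CDS and, near exon junctions, from
#' the stored intron flank sequences (the biological neighbour of an exon
#' edge is the intron, not the next exon); splice (+/-1, +/-2) and intronic
#' (+/-3 and deeper) positions sit inside the donor/acceptor flanks. The
#' variant base itself is set to the alternate allele — scanning happens on
#' the molecule present in patients, and the mutant base participates in PAM
#' matching.
#'
#' @param model `transcript_model` with `cds_seq`.
#' @param change parsed `cdna_change` (substitution).
#' @param flank context width on each side of the target (26 covers a 20-nt
#'   protospacer plus the longest PAM in the default library).
#' @return a [sequence_context()], or `NULL` when the needed intron flank is
#'   not stored ("context unavailable").
#' @export
build_context <- function(model, change, flank = 26L) {
  stopifnot(inherits(model, "transcript_model"))
  if (change$kind != "substitution")
    stop("contexts are built for substitutions only")
  if (is.null(model$cds_seq)) stop("transcript model has no cds_seq")
  cds <- model$cds_seq
  cs <- cumsum(model$exon_cds_lengths)
  p <- change$position
  off <- change$intron_offset
  loc <- locate_exon(model, p)
  e <- loc$exon
  ex_start <- if (e > 1) cs[e - 1] + 1L else 1L
  ex_end <- cs[e]

  flank_of <- function(j) {
    fl <- model$intron_flanks
    if (is.null(fl) || j < 1 || j > length(fl)) NULL else fl[[j]]
  }

  if (off == 0) {
    obs <- substr(cds, p, p)
    if (obs != change$ref)
      stop("reference mismatch at c.", p, ": transcript has ", obs,
           ", HGVS says ", change$ref)
    left_lo <- max(ex_start, p - flank)
    left <- substr(cds, left_lo, p - 1)
    if (p - flank < ex_start && e > 1) {
      need <- ex_start - (p - flank)
      fl <- flank_of(e - 1)
      if (is.null(fl)) {
        warning("no acceptor flank stored for junction ", e - 1,
                "; context truncated", call. = FALSE)
      } else {
        acc <- fl$acceptor
        left <- paste0(substr(acc, max(1, nchar(acc) - need + 1), nchar(acc)), left)
      }
    }
    right <- substr(cds, p + 1, min(ex_end, p + flank))
    if (p + flank > ex_end && e < length(cs)) {
      need <- p + flank - ex_end
      fl <- flank_of(e)
      if (is.null(fl)) {
        warning("no donor flank stored for junction ", e,
                "; context truncated", call. = FALSE)
      } else {
        right <- paste0(right, substr(fl$donor, 1, need))
      }
    }
    seq <- paste0(left, change$alt, right)
    return(sequence_context(seq, nchar(left), "mutant"))
  }

  if (off > 0) {
    # donor side: c.p+off, p is the last coding base of its exon
    fl <- flank_of(e)
    if (is.null(fl) || nchar(fl$donor) < off) return(NULL)
    don <- fl$donor
    obs <- substr(don, off, off)
    if (obs != change$ref)
      stop("reference mismatch at c.", p, "+", off,
           ": intron flank has ", obs, ", HGVS says ", change$ref)
    keep_left <- flank - (off - 1)
    ex_tail <- if (keep_left > 0)
      substr(cds, max(ex_start, p - keep_left + 1), p) else ""
    seq <- paste0(ex_tail, substr(don, 1, off - 1), change$alt,
                  substr(don, off + 1, min(nchar(don), off + flank)))
    return(sequence_context(seq, nchar(ex_tail) + off - 1, "mutant"))
  }

  # acceptor side: c.p-|off|, p is the first coding base of its exon
  fl <- flank_of(e - 1)
  if (is.null(fl)) return(NULL)
  acc <- fl$acceptor
  j <- nchar(acc) + off + 1L   # off is negative; -1 = last intron base
  if (j < 1) return(NULL)
  obs <- substr(acc, j, j)
  if (obs != change$ref)
    stop("reference mismatch at c.", p, off,
         ": intron flank has ", obs, ", HGVS says ", change$ref)
  left <- substr(acc, max(1, j - flank), j - 1)
  intr_right <- substr(acc, j + 1, nchar(acc))
  need_ex <- flank - nchar(intr_right)
  ex_head <- if (need_ex > 0)
    substr(cds, p, min(ex_end, p + need_ex - 1)) else ""
  seq <- paste0(left, change$alt, intr_right, ex_head)
  sequence_context(seq, nchar(left), "mutant")
}

#' Scan an annotated cohort against a Cas library
#'
#' Builds the mutant context for every editable SNV, enumerates placements
#' for all compatible Cas proteins, and assigns one Cas per variant by
#' precedence.
#'
#' @param records annotated `variant_records` (after [annotate_editability()]).
#' @param model `transcript_model`.
#' @param library `cas_library`.
#' @param precedence see [assign_primary_cas()].
#' @param flank context width per side.
#' @return list with `assignments` (data.frame `key`, `editor`, `assigned`:
#'   a Cas name, `"none"` for no PAM, or `"context unavailable"`) over
#'   editable SNVs, and `placements` (row-bound placement table with a
#'   leading `key` column).
#' @export
scan_cohort <- function(records, model, library = default_cas_library(),
                        precedence = default_cas_precedence(), flank = 26L) {
  stopifnot("editor" %in% names(records))
  idx <- which(records$kind == "substitution" &
                 !is.na(records$editor) & records$editor != "none")
  assigned_v <- character(length(idx))
  placements <- list()
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    change <- list(kind = "substitution", position = records$position[i],
                   intron_offset = records$intron_offset[i],
                   ref = records$ref[i], alt = records$alt[i], utr = records$utr[i])
    call <- list(editor = records$editor[i],
                 substrate_base = records$substrate_base[i],
                 substrate_strand = records$substrate_strand[i])
    ctx <- build_context(model, change, flank = flank)
    if (is.null(ctx)) {
      assigned <- "context unavailable"
    } else {
      sc <- scan_variant(ctx, call, library)
      assigned <- assign_primary_cas(sc, precedence,
                                     known = names(library))
      for (nm in names(sc)) {
        pl <- sc[[nm]]
        if (nrow(pl)) {
          pl <- cbind(key = records$key[i], pl, stringsAsFactors = FALSE)
          placements[[length(placements) + 1L]] <- pl
        }
      }
    }
    assigned_v[ii] <- assigned
  }
  assignments <- data.frame(key = records$key[idx], editor = records$editor[idx],
                            assigned = assigned_v, stringsAsFactors = FALSE)
  placements <- if (length(placements)) do.call(rbind, placements) else
    data.frame(key = character(), cas = character(), strand = character(),
               protospacer_start = integer(), protospacer = character(),
               pam_observed = character(), target_window_pos = integer(),
               bystander_positions = character(), n_bystanders = integer(),
               stringsAsFactors = FALSE)
  rownames(placements) <- NULL
  list(assignments = assignments, placements = placements)
}
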