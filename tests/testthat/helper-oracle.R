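# Independent brute-force scanner oracle: enumerates every protospacer offset
# on the substrate strand, checks window membership, PAM match and bounds by
# naive positionwise set lookup. Shares no code path with find_placements
# (reverse complement via Biostrings, PAM check via explicit set membership).

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_pam_ok <- function(pattern, s) {
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  if (length(pc) != length(sc)) return(FALSE)
  for (i in seq_along(pc)) {
    if (pc[i] == "N") next
    if (!sc[i] %in% oracle_iupac[[pc[i]]]) return(FALSE)
  }
  TRUE
}

oracle_rc <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

oracle_placements <- function(ctx, call, spec) {
  strand <- call$substrate_strand
  sseq <- if (strand == "sense") ctx$seq else oracle_rc(ctx$seq)
  t1 <- if (strand == "sense") ctx$target_offset + 1 else
    nchar(ctx$seq) - ctx$target_offset
  L <- spec$protospacer_len
  n <- nchar(sseq)
  rows <- list()
  for (s in seq_len(max(0, n - L + 1))) {
    w <- t1 - s + 1
    if (w < spec$window[1] || w > spec$window[2]) next
    for (pat in spec$pam_patterns) {
      k <- nchar(pat)
      lo <- if (spec$pam_side == "downstream") s + L else s - k
      if (lo < 1 || lo + k - 1 > n) next
      pam <- substr(sseq, lo, lo + k - 1)
      if (!oracle_pam_ok(pat, pam)) next
      proto <- substr(sseq, s, s + L - 1)
      win <- spec$window[1]:spec$window[2]
      bys <- win[vapply(win, function(p)
        substr(proto, p, p) == call$substrate_base, logical(1)) & win != w]
      rows[[length(rows) + 1]] <- data.frame(
        cas = spec$name, strand = strand, protospacer_start = s - 1,
        protospacer = proto, pam_observed = pam, target_window_pos = w,
        bystander_positions = paste(bys, collapse = ","),
        n_bystanders = length(bys), stringsAsFactors = FALSE)
      break
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cas = character(), strand = character(),
               protospacer_start = integer(), protospacer = character(),
               pam_observed = character(), target_window_pos = integer(),
               bystander_positions = character(), n_bystanders = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Random editable context: picks one of the six correctable substitution
# types, plants the mutant base at target_offset of a random sequence.
random_editable_context <- function(len = 60) {
  types <- data.frame(ref = c("G", "C", "T", "A", "G", "C"),
                      alt = c("A", "T", "C", "G", "C", "G"))
  i <- sample(6, 1)
  call <- as.list(required_editor(types$ref[i], types$alt[i]))
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  t0 <- sample(seq_len(len), 1) - 1
  mutant <- if (call$substrate_strand == "sense") call$substrate_base else
    chartr("ACGT", "TGCA", call$substrate_base)
  substr(seq, t0 + 1, t0 + 1) <- mutant
  list(ctx = sequence_context(seq, t0, "mutant"), call = call)
}

# Entries table from a generated cohort, as the pipeline's reader would
# produce it.
entries_from_cohort <- function(cohort) {
  mk <- function(df, sid) data.frame(
    source_id = sid, gene = df$gene, hgvs_c = df$hgvs_c,
    significance_raw = df$significance,
    times_reported = df$times_reported, flagged = FALSE,
    stringsAsFactors = FALSE)
  rbind(mk(cohort$source_a, "lovd"), mk(cohort$source_b, "clinvar"))
}

# Tiny deterministic ORF model for unit tests: 2 exons, 60 bp.
toy_model <- function() {
  cds <- paste0("ATG", "AAC", "GGC", "TGC", "CAA", "TCC", "GAT", "CTG",
                "GTC", "AGC", "TTT", "CCC", "GGG", "AAA", "CAT", "TAC",
                "TGG", "CTT", "GAA", "TAA")
  transcript_model("TOY", c(30, 30), cds,
                   list(list(donor = paste0("GT", strrep("C", 28)),
                             acceptor = paste0(strrep("G", 28), "AG"))))
}
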