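test_that("exonic context places the mutant base with symmetric flanks", {
  m <- make_transcript(n_exons = 2, exon_lengths = c(120, 120), seed = 1)
  p <- 60L
  ref <- substr(m$cds_seq, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  ctx <- build_context(m, list(kind = "substitution", position = p,
                               intron_offset = 0L, ref = ref, alt = alt))
  expect_equal(nchar(ctx$seq), 53)
  expect_equal(ctx$target_offset, 26L)
  expect_equal(substr(ctx$seq, 27, 27), alt)
  # neighbours are untouched CDS
  expect_equal(substr(ctx$seq, 1, 26), substr(m$cds_seq, p - 26, p - 1))
  expect_equal(substr(ctx$seq, 28, 53), substr(m$cds_seq, p + 1, p + 26))
  # reference mismatch is an error
  expect_error(build_context(m, list(kind = "substitution", position = p,
                                     intron_offset = 0L, ref = alt, alt = ref)),
               "mismatch")
})

test_that("junction-proximal exonic context splices in intron flanks", {
  m <- make_transcript(n_exons = 2, exon_lengths = c(120, 120), seed = 2)
  p <- 118L  # 2 bp from the donor junction
  ref <- substr(m$cds_seq, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  ctx <- build_context(m, list(kind = "substitution", position = p,
                               intron_offset = 0L, ref = ref, alt = alt))
  expect_equal(ctx$target_offset, 26L)
  # right context: 2 exonic bases then the donor flank (starting GT)
  right <- substr(ctx$seq, 28, 53)
  expect_equal(substr(right, 1, 2), substr(m$cds_seq, 119, 120))
  expect_equal(substr(right, 3, 4), "GT")
  expect_equal(substr(right, 3, 26), substr(m$intron_flanks[[1]]$donor, 1, 24))
})

test_that("splice and intronic contexts come from the stored flanks", {
  m <- make_transcript(n_exons = 2, exon_lengths = c(120, 120), seed = 3)
  don <- m$intron_flanks[[1]]$donor
  acc <- m$intron_flanks[[1]]$acceptor
  # donor +1 (the planted G of GT)
  ctx <- build_context(m, list(kind = "substitution", position = 120L,
                               intron_offset = 1L, ref = "G", alt = "T"))
  expect_equal(substr(ctx$seq, ctx$target_offset + 1, ctx$target_offset + 1), "T")
  expect_equal(substr(ctx$seq, 1, 26), substr(m$cds_seq, 95, 120))
  # acceptor -1 (the planted G of AG)
  ctx2 <- build_context(m, list(kind = "substitution", position = 121L,
                               intron_offset = -1L, ref = "G", alt = "C"))
  expect_equal(substr(ctx2$seq, ctx2$target_offset + 1, ctx2$target_offset + 1), "C")
  # bases after the target are the exon head
  expect_equal(substr(ctx2$seq, ctx2$target_offset + 2,
                      ctx2$target_offset + 27),
               substr(m$cds_seq, 121, 146))
  # intronic +3 with wrong stated ref errors
  real3 <- substr(don, 3, 3)
  wrong <- setdiff(c("A", "C", "G", "T"), real3)[1]
  expect_error(build_context(m, list(kind = "substitution", position = 120L,
                                     intron_offset = 3L, ref = wrong,
                                     alt = real3)), "mismatch")
  # a model without flanks: context unavailable
  m2 <- transcript_model("NF", c(120, 120), m$cds_seq)
  expect_null(build_context(m2, list(kind = "substitution", position = 120L,
                                     intron_offset = 1L, ref = "G", alt = "T")))
})

test_that("scan_cohort assigns by precedence and tabulates placements", {
  m <- make_transcript(n_exons = 6, seed = 8)
  sp <- cohort_spec(n_variants = 200, seed = 8)
  co <- make_cohort(sp, m)
  rec <- merge_sources(entries_from_cohort(co))
  an <- annotate_editability(annotate_consequence(select_for_analysis(rec), m))
  sc <- suppressWarnings(scan_cohort(an, m))
  editable <- an[an$kind == "substitution" & !is.na(an$editor) &
                   an$editor != "none", ]
  expect_equal(nrow(sc$assignments), nrow(editable))
  expect_true(all(sc$assignments$assigned %in%
                    c(default_cas_precedence(), "none", "context unavailable")))
  # every placement's variant is an editable SNV and re-validates
  expect_true(all(sc$placements$key %in% editable$key))
  lib <- default_cas_library()
  for (j in seq_len(min(25, nrow(sc$placements)))) {
    row <- sc$placements[j, ]
    spec <- lib[[row$cas]]
    expect_true(row$target_window_pos >= spec$window[1] &&
                  row$target_window_pos <= spec$window[2])
    expect_true(any(vapply(spec$pam_patterns, function(p)
      nchar(p) == nchar(row$pam_observed) && iupac_match(p, row$pam_observed),
      logical(1))))
  }
  # GBE variants never assigned to ABE/CBE-only Cas
  gbe <- sc$assignments[sc$assignments$editor == "GBE", ]
  expect_true(all(gbe$assigned %in% c("SpCas9", "xCas/SpCas9-NG", "none",
                                      "context unavailable")))
})
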