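test_that("generated transcripts are valid ORFs, deterministic under seed", {
  m1 <- make_transcript(n_exons = 3, exon_lengths = c(30, 60, 30), seed = 1)
  m2 <- make_transcript(n_exons = 3, exon_lengths = c(30, 60, 30), seed = 1)
  expect_identical(m1$cds_seq, m2$cds_seq)
  expect_identical(m1$intron_flanks, m2$intron_flanks)
  expect_equal(nchar(m1$cds_seq), 120)
  aa <- translate_cds(m1$cds_seq)
  expect_equal(substr(aa, 1, 1), "M")
  expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))  # no internal stop
  # canonical junction dinucleotides planted
  for (fl in m1$intron_flanks) {
    expect_equal(substr(fl$donor, 1, 2), "GT")
    expect_equal(substr(fl$acceptor, nchar(fl$acceptor) - 1,
                        nchar(fl$acceptor)), "AG")
  }
  m3 <- make_transcript(n_exons = 3, exon_lengths = c(30, 60, 30), seed = 2)
  expect_false(identical(m1$cds_seq, m3$cds_seq))
  expect_error(make_transcript(exon_lengths = c(10, 10), seed = 1), "divisible")
})

test_that("cohorts are deterministic and plant compositions exactly", {
  m <- make_transcript(n_exons = 8, seed = 4)
  sp <- cohort_spec(n_variants = 500, seed = 4)
  co <- make_cohort(sp, m)
  co2 <- make_cohort(sp, m)
  expect_identical(co, co2)
  tr <- co$truth
  expect_equal(nrow(tr), 500)
  expect_false(any(duplicated(tr$key)))
  # planted class counts
  expect_equal(as.integer(table(factor(tr$class, names(sp$label_model)))),
               as.integer(bescan:::apportion(sp$label_model, 500)))
  # overlap planted exactly
  expect_equal(sum(tr$in_both), round(sp$overlap_fraction * 500))
  # conflicting variants are always shared
  expect_true(all(tr$in_both[tr$conflict]))
  # substitution mix over analyzed SNVs planted exactly
  an <- tr[tr$class %in% c("pathogenic", "conflicting_pathogenic"), ]
  snv <- an[!is.na(an$subst_type), ]
  n_snv <- nrow(snv)
  expect_equal(as.integer(table(factor(snv$subst_type,
                                       names(sp$substitution_mix)))),
               as.integer(bescan:::apportion(sp$substitution_mix, n_snv)))
  # consequence mix planted exactly
  cc <- bescan:::apportion(sp$consequence_mix, nrow(an))
  expect_equal(as.integer(table(factor(an$consequence, names(cc)))),
               as.integer(cc))
})

test_that("degenerate cohort specs behave as stated", {
  m <- make_transcript(n_exons = 5, seed = 6)
  # all-G>A cohort: every SNV has ground-truth editor ABE
  sp <- cohort_spec(
    n_variants = 60, seed = 6,
    substitution_mix = stats::setNames(
      c(1, rep(0, 11)),
      c("G>A", "C>T", "T>C", "A>G", "G>C", "C>G",
        "A>C", "A>T", "C>A", "G>T", "T>A", "T>G")),
    consequence_mix = c(missense = 0.9, nonsense = 0.1, synonymous = 0,
                        `ins/del/dup` = 0, splice = 0, intronic = 0))
  co <- make_cohort(sp, m)
  an <- co$truth[co$truth$class %in% c("pathogenic", "conflicting_pathogenic"), ]
  expect_true(all(an$editor == "ABE"))
  expect_true(all(an$subst_type == "G>A"))
  # zero-discordance cohort: no conflicts anywhere
  sp0 <- cohort_spec(n_variants = 60, seed = 6,
                     label_model = c(pathogenic = 0.5,
                                     conflicting_pathogenic = 0,
                                     conflicting_other = 0,
                                     vus = 0.25, benign = 0.2,
                                     unclassified = 0.05))
  co0 <- make_cohort(sp0, m)
  rec <- merge_sources(entries_from_cohort(co0))
  expect_equal(sum(rec$conflict), 0)
})

test_that("infeasible exact composition errors instead of drifting", {
  m <- make_transcript(n_exons = 2, exon_lengths = c(30, 30), seed = 2)
  # demand far more nonsense G>C SNVs than a 60-bp CDS can host: alt C can
  # never create a stop codon, so this must fail in exact mode
  sp <- cohort_spec(
    n_variants = 40, seed = 2,
    label_model = c(pathogenic = 1, conflicting_pathogenic = 0,
                    conflicting_other = 0, vus = 0, benign = 0,
                    unclassified = 0),
    overlap_fraction = 0,
    substitution_mix = stats::setNames(
      c(0, 0, 0, 0, 1, 0, rep(0, 6)),
      c("G>A", "C>T", "T>C", "A>G", "G>C", "C>G",
        "A>C", "A>T", "C>A", "G>T", "T>A", "T>G")),
    consequence_mix = c(missense = 0, nonsense = 1, synonymous = 0,
                        `ins/del/dup` = 0, splice = 0, intronic = 0))
  expect_error(make_cohort(sp, m), "nonsense")
})

test_that("planted PAM contexts are verified by the scanner", {
  lib <- default_cas_library()
  pk <- plant_pam_context("A", lib[["SaCas9-KKH"]], 10, 3, seed = 7)
  pl <- find_placements(pk$context, pk$call, lib[["SaCas9-KKH"]])
  hit <- pl[pl$target_window_pos == 10, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$n_bystanders, 3L)
  # CasMINI zero-bystander scenario
  pk2 <- plant_pam_context("A", lib$CasMINI, 3, 0, seed = 1)
  pl2 <- find_placements(pk2$context, pk2$call, lib$CasMINI)
  expect_true(any(pl2$target_window_pos == 3 & pl2$n_bystanders == 0))
  # avoidance constraint: no SpCas9 placement when requested
  pk3 <- plant_pam_context("A", lib[["SaCas9-KKH"]], 8, 1, seed = 9,
                           avoid_spec = lib$SpCas9)
  expect_equal(nrow(find_placements(pk3$context, pk3$call, lib$SpCas9)), 0)
  expect_true(nrow(find_placements(pk3$context, pk3$call,
                                   lib[["SaCas9-KKH"]])) >= 1)
  # precondition violations
  expect_error(plant_pam_context("A", lib[["SaCas9-KKH"]], 16, 0),
               "outside")
  expect_error(plant_pam_context("A", lib$CasMINI, 3, 2), "exceeds")
})

test_that("deterministic generator substreams do not interfere", {
  m <- make_transcript(n_exons = 5, seed = 10)
  sp <- cohort_spec(n_variants = 100, seed = 10)
  co_a <- make_cohort(sp, m)
  # drawing unrelated random numbers between calls must not change output
  set.seed(999); runif(10)
  co_b <- make_cohort(sp, m)
  expect_identical(co_a, co_b)
})
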