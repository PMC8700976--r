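mk_entries <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(source_id = r[[1]], gene = "G1", hgvs_c = r[[2]],
               significance_raw = r[[3]],
               times_reported = if (length(r) > 3) r[[4]] else 1L,
               flagged = FALSE, stringsAsFactors = FALSE)))
}

test_that("significance collapses to the three ACMG levels", {
  expect_equal(collapse_significance(c("Pathogenic", "likely pathogenic",
                                       "Pathogenic/Likely pathogenic")),
               rep("pathogenic-level", 3))
  expect_equal(collapse_significance(c("Benign", "LIKELY BENIGN",
                                       "benign/likely benign")),
               rep("benign-level", 3))
  expect_equal(collapse_significance("Uncertain significance"), "VUS")
  expect_equal(collapse_significance(""), "unclassified")
  expect_warning(out <- collapse_significance("drug response"), "unrecognised")
  expect_equal(out, "unclassified")
})

test_that("merge combines sources, sums reports, and flags conflicts", {
  e <- mk_entries(
    list("lovd", "c.10G>A", "Pathogenic", 202L),
    list("clinvar", "c.10G>A", "Likely pathogenic", 24L),
    list("lovd", "c.20C>T", "Pathogenic"),
    list("clinvar", "c.20C>T", "Uncertain significance"),
    list("lovd", "c.30A>G", "Benign"),
    list("clinvar", "c.30A>G", "Likely pathogenic"),
    list("clinvar", "c.40T>C", "Benign"),
    list("clinvar", "c.50G>T", "Uncertain significance"),
    list("lovd", "c.50G>T", ""))
  rec <- merge_sources(e)
  expect_equal(nrow(rec), 5)
  r10 <- rec[rec$hgvs_c == "c.10G>A", ]
  expect_false(r10$conflict)  # pathogenic + likely pathogenic: same level
  expect_equal(r10$total_reports, 226L)
  expect_equal(r10$reports_lovd, 202L)
  r20 <- rec[rec$hgvs_c == "c.20C>T", ]
  expect_true(r20$conflict)
  expect_true(r20$conflicting_pathogenic)
  r30 <- rec[rec$hgvs_c == "c.30A>G", ]
  expect_true(r30$conflict && r30$conflicting_pathogenic)
  r50 <- rec[rec$hgvs_c == "c.50G>T", ]
  expect_false(r50$conflict)  # classified in one, unclassified in the other
  expect_equal(r50$collapsed, "VUS")
})

test_that("merging a dataset with an exact copy doubles counts only", {
  e <- mk_entries(list("lovd", "c.10G>A", "Pathogenic", 3L),
                  list("lovd", "c.20C>T", "Benign"))
  both <- rbind(e, transform(e, source_id = "clinvar"))
  r1 <- merge_sources(e)
  r2 <- merge_sources(both)
  expect_equal(r2$key, r1$key)
  expect_equal(r2$collapsed, r1$collapsed)
  expect_equal(r2$conflict, r1$conflict)
  expect_equal(r2$total_reports, 2L * r1$total_reports)
})

test_that("whitespace/case variants of one description merge to one key", {
  e <- mk_entries(list("lovd", "c.10G>A", "Pathogenic"),
                  list("clinvar", " c.10 G>A", "Pathogenic"))
  expect_equal(nrow(merge_sources(e)), 1)
  # different ref bases give different normalized keys, kept apart
  e2 <- mk_entries(list("lovd", "c.10G>A", "Pathogenic"),
                   list("clinvar", "c.10C>A", "Pathogenic"))
  expect_equal(nrow(merge_sources(e2)), 2)
})

test_that("selection keeps exactly the records with a pathogenic-level label", {
  e <- mk_entries(
    list("lovd", "c.10G>A", "Pathogenic"),
    list("lovd", "c.20C>T", "Benign"),
    list("clinvar", "c.20C>T", "Likely pathogenic"),
    list("lovd", "c.30A>G", "Benign"),
    list("clinvar", "c.30A>G", "Uncertain significance"),
    list("lovd", "c.40T>C", "Uncertain significance"))
  rec <- merge_sources(e)
  sel <- select_for_analysis(rec)
  expect_setequal(sel$hgvs_c, c("c.10G>A", "c.20C>T"))
  expect_true(sel$conflict[sel$hgvs_c == "c.20C>T"])  # conflict retained
  expect_true(all(sel$key %in% rec$key))
  expect_false(any(sel$collapsed == "benign-level" & !sel$conflict))
})

test_that("collapse is order-independent and merge associative up to counts", {
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  e <- mk_entries(list("lovd", "c.10G>A", "Benign"),
                  list("clinvar", "c.10G>A", "Likely pathogenic"),
                  list("clinvar", "c.10G>A", "Uncertain significance"))
  base <- merge_sources(e)
  for (p in perms) {
    r <- merge_sources(e[p, ])
    expect_equal(r$collapsed, base$collapsed)
    expect_equal(r$conflict, base$conflict)
    expect_equal(r$total_reports, base$total_reports)
  }
})

test_that("round-trip through TSV reader preserves entries", {
  dir <- withr::local_tempdir()
  df <- data.frame(gene = "G1", hgvs_c = c("c.10G>A", "c.20C>T"),
                   significance = c("Pathogenic", "Benign"),
                   times_reported = c(5L, 1L), flagged = c("false", "true"))
  path <- file.path(dir, "a.tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_variant_table(path, "lovd")
  expect_equal(got$times_reported, c(5L, 1L))
  expect_equal(got$flagged, c(FALSE, TRUE))
  rec <- merge_sources(got)
  expect_equal(nrow(rec), 1)  # flagged row dropped before merging
  expect_error(read_variant_table(file.path(dir, "nope.tsv"), "x"),
               "not found")
})
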