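test_that("iupac_match implements positionwise set membership", {
  expect_true(iupac_match("NNGRRT", "AAGGAT"))
  expect_false(iupac_match("TTTV", "TTTT"))
  expect_true(iupac_match("TTTV", "TTTC"))
  # NG over all 16 2-mers: exactly 4 matches, by enumeration
  two <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"))
  hits <- mapply(function(a, b) iupac_match("NG", paste0(a, b)), two$a, two$b)
  expect_equal(sum(hits), 4)
  expect_true(all(two$b[hits] == "G"))
  expect_error(iupac_match("NXG", "AAG"), "unknown IUPAC")
  expect_error(iupac_match("NG", "AAG"), "lengths differ")
})

test_that("default library encodes the Cas inventory and its restrictions", {
  lib <- default_cas_library()
  expect_equal(names(lib),
               c("SpCas9", "xCas/SpCas9-NG", "SaCas9", "SaCas9-KKH",
                 "LbCas12a", "enAsCas12a", "CasMINI"))
  expect_equal(lib$CasMINI$compatible_editors, "ABE")
  gbe <- names(Filter(function(s) "GBE" %in% s$compatible_editors, lib))
  expect_setequal(gbe, c("SpCas9", "xCas/SpCas9-NG"))
  expect_equal(lib[["SaCas9-KKH"]]$window, c(2L, 15L))
  expect_equal(lib[["SaCas9-KKH"]]$pam_patterns, "NNNRRT")
  expect_equal(lib$SaCas9$pam_patterns, "NNGRRT")
  expect_equal(lib$LbCas12a$pam_side, "upstream")
  expect_equal(lib$enAsCas12a$pam_patterns, c("TATV", "TYCV"))
  expect_equal(lib$SpCas9$size_aa, 1368L)
  expect_equal(lib$CasMINI$size_aa, 529L)
  # packaged JSON config equals the in-code default
  cfg <- system.file("extdata", "cas_library.json", package = "bescan")
  expect_true(nzchar(cfg))
  expect_equal(read_cas_library(cfg), lib)
})

test_that("a planted SpCas9 fixture yields exactly one placement", {
  # substrate A at protospacer position 5, AGG PAM at 21-23
  proto <- rep("C", 20); proto[5] <- "A"
  seq <- paste0(strrep("T", 6), paste(proto, collapse = ""), "AGG",
                strrep("T", 6))
  ctx <- sequence_context(seq, 6 + 5 - 1, "mutant")
  call <- as.list(required_editor("G", "A"))
  pl <- find_placements(ctx, call, default_cas_library()$SpCas9)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$target_window_pos, 5L)
  expect_equal(pl$pam_observed, "AGG")
  expect_equal(pl$bystander_positions, "")
  expect_equal(pl$n_bystanders, 0L)
  # PAM mutated to ACC: no placement
  seq2 <- sub("AGG", "ACC", seq, fixed = TRUE)
  ctx2 <- sequence_context(seq2, 6 + 5 - 1, "mutant")
  expect_equal(nrow(find_placements(ctx2, call, default_cas_library()$SpCas9)), 0)
})

test_that("incompatible editor/Cas pairs error; scan omits them", {
  lib <- default_cas_library()
  call <- as.list(required_editor("G", "C"))  # GBE
  ctx <- sequence_context(strrep("C", 25), 12, "mutant")
  expect_error(find_placements(ctx, call, lib$SaCas9), "not compatible")
  sc <- suppressWarnings(scan_variant(ctx, call, lib))  # 25-nt context truncates
  expect_true(all(names(sc) %in% c("SpCas9", "xCas/SpCas9-NG")))
  none <- scan_variant(ctx, list(editor = "none"), lib)
  expect_length(none, 0)
})

test_that("scan_variant equals the brute-force oracle on random contexts", {
  set.seed(101)
  lib <- default_cas_library()
  for (i in 1:300) {
    rc <- random_editable_context(60)
    sc <- suppressWarnings(scan_variant(rc$ctx, rc$call, lib))
    for (nm in names(sc)) {
      got <- sc[[nm]]
      want <- suppressWarnings(oracle_placements(rc$ctx, rc$call, lib[[nm]]))
      rownames(got) <- NULL
      expect_equal(got, want, info = paste("cas", nm, "iter", i))
    }
  }
})

test_that("every returned placement satisfies its own invariants", {
  set.seed(77)
  lib <- default_cas_library()
  for (i in 1:50) {
    rc <- random_editable_context(60)
    sc <- suppressWarnings(scan_variant(rc$ctx, rc$call, lib))
    for (nm in names(sc))

      if (nrow(sc[[nm]])) {
        spec <- lib[[nm]]
        pl <- sc[[nm]]
        expect_true(all(pl$target_window_pos >= spec$window[1] &
                          pl$target_window_pos <= spec$window[2]))
        for (j in seq_len(nrow(pl))) {
          expect_true(any(vapply(spec$pam_patterns, function(p)
            nchar(p) == nchar(pl$pam_observed[j]) &&
              iupac_match(p, pl$pam_observed[j]), logical(1))))
          # target base on the protospacer is the substrate base
          expect_equal(substr(pl$protospacer[j], pl$target_window_pos[j],
                              pl$target_window_pos[j]), rc$call$substrate_base)
          if (nzchar(pl$bystander_positions[j])) {
            bys <- as.integer(strsplit(pl$bystander_positions[j], ",")[[1]])
            expect_true(all(bys >= spec$window[1] & bys <= spec$window[2] &
                              bys != pl$target_window_pos[j]))
          }
        }
      }
  }
})

test_that("PAM relaxation and window widening never lose placements", {
  set.seed(202)
  sa <- default_cas_library()$SaCas9
  kkh <- default_cas_library()[["SaCas9-KKH"]]
  sa_wide <- cas_spec("SaCas9-wide", "NNGRRT", "downstream", c(2, 15),
                      c("ABE", "CBE"))
  for (i in 1:100) {
    rc <- random_editable_context(70)
    if (!rc$call$editor %in% sa$compatible_editors) next  # GBE: SpCas9-only
    n_sa <- nrow(suppressWarnings(find_placements(rc$ctx, rc$call, sa)))
    # NNGRRT -> NNNRRT with the wider window dominates both relaxations
    n_kkh <- nrow(suppressWarnings(find_placements(rc$ctx, rc$call, kkh)))
    n_wide <- nrow(suppressWarnings(find_placements(rc$ctx, rc$call, sa_wide)))
    expect_gte(n_wide, n_sa)   # window widening
    expect_gte(n_kkh, n_wide)  # PAM relaxation at equal window
  }
})

test_that("reverse-complement invariance: strands swap, windows persist", {
  set.seed(303)
  lib <- default_cas_library()
  for (i in 1:50) {
    rc <- random_editable_context(60)
    flip <- rc$call
    flip$substrate_strand <- if (flip$substrate_strand == "sense")
      "antisense" else "sense"
    ctx_rc <- sequence_context(oracle_rc(rc$ctx$seq),
                               nchar(rc$ctx$seq) - rc$ctx$target_offset - 1,
                               "mutant")
    a <- suppressWarnings(scan_variant(rc$ctx, rc$call, lib))
    b <- suppressWarnings(scan_variant(ctx_rc, flip, lib))
    expect_equal(names(a), names(b))
    for (nm in names(a)) {
      expect_equal(a[[nm]]$target_window_pos, b[[nm]]$target_window_pos)
      expect_equal(a[[nm]]$protospacer, b[[nm]]$protospacer)
      expect_equal(a[[nm]]$pam_observed, b[[nm]]$pam_observed)
      expect_equal(a[[nm]]$protospacer_start, b[[nm]]$protospacer_start)
      expect_equal(a[[nm]]$bystander_positions, b[[nm]]$bystander_positions)
      if (nrow(a[[nm]]))
        expect_true(all(a[[nm]]$strand != b[[nm]]$strand))
    }
  }
})

test_that("primary Cas assignment follows precedence", {
  pl1 <- data.frame(cas = "x", target_window_pos = 5)
  empty <- data.frame()
  sc <- list(SpCas9 = pl1, CasMINI = pl1)
  expect_equal(assign_primary_cas(sc), "SpCas9")
  expect_equal(assign_primary_cas(list()), "none")
  expect_equal(assign_primary_cas(list(SaCas9 = pl1)), "SaCas9")
  expect_equal(assign_primary_cas(list(SpCas9 = empty, CasMINI = pl1)),
               "CasMINI")
  expect_error(assign_primary_cas(sc, precedence = c("NopeCas", "SpCas9")),
               "unknown Cas")
  # custom precedence is honoured
  expect_equal(assign_primary_cas(sc, precedence = c("CasMINI", "SpCas9")),
               "CasMINI")
})
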