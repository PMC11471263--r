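score_csv <- function(tbl) {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(tbl, f)
  f
}

two_pos_tbl <- function() {
  tibble::tibble(
    position_label = rep(c("10", "11"), each = 20),
    wt_aa = rep(c("A", "C"), each = 20),
    mut_aa = rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 2),
    score = seq(-2, 1.9, by = 0.1))
}

test_that("long-form score CSVs pivot to position x 20 matrices", {
  sm <- parse_scores(score_csv(two_pos_tbl()), "antiberty_pll")
  expect_equal(dim(sm$scores), c(2L, 20L))
  expect_false(anyNA(sm$scores))
  expect_equal(sm$positions$wt_aa, c("A", "C"))

  dup <- dplyr::bind_rows(two_pos_tbl(), two_pos_tbl()[1, ])
  expect_error(parse_scores(score_csv(dup), "x"), "duplicate")

  missing_col <- dplyr::select(two_pos_tbl(), -"wt_aa")
  expect_error(parse_scores(score_csv(missing_col), "x"), "wt_aa")
})

test_that("score matrices round-trip through write and parse", {
  sm <- parse_scores(score_csv(two_pos_tbl()), "antiberty_pll")
  f <- tempfile(fileext = ".csv")
  write_scores(sm, f)
  sm2 <- parse_scores(f, "antiberty_pll")
  expect_equal(sm$scores, sm2$scores)
  expect_equal(sm$positions, sm2$positions)
})

test_that("WT scaling subtracts the wild-type score and zeroes WT cells", {
  tbl <- two_pos_tbl()
  tbl$score[tbl$position_label == "10" & tbl$mut_aa == "A"] <- -1.3
  tbl$score[tbl$position_label == "10" & tbl$mut_aa == "D"] <- -0.5
  sm <- scale_to_wt(parse_scores(score_csv(tbl), "antiberty_pll"))
  expect_equal(unname(sm$scores["10", "A"]), 0)
  expect_equal(unname(sm$scores["11", "C"]), 0)
  expect_equal(unname(sm$scores["10", "D"]), 0.8)

  # constant row scales to all zeros
  flat <- two_pos_tbl(); flat$score <- 2.5
  smf <- scale_to_wt(parse_scores(score_csv(flat), "x"))
  expect_true(all(smf$scores == 0))

  expect_error(scale_to_wt(sm), "already")

  no_wt <- dplyr::filter(two_pos_tbl(),
                         !(position_label == "10" & mut_aa == "A"))
  expect_error(scale_to_wt(parse_scores(score_csv(no_wt), "x")), "position")
})

test_that("multi-mutant scores sum scaled cells and respect the contracts", {
  tbl <- two_pos_tbl()
  tbl <- dplyr::bind_rows(tbl, dplyr::mutate(tbl[1:20, ], position_label = "12",
                                             wt_aa = "G"))
  sm <- scale_to_wt(parse_scores(score_csv(tbl), "antiberty_pll"))
  sm$scores["10", "F"] <- 1.2
  sm$scores["11", "W"] <- -0.3
  sm$scores["12", "M"] <- 0.5
  muts <- tibble::tibble(position_label = c("10", "11", "12"),
                         mut_aa = c("F", "W", "M"))
  expect_equal(multi_mutant_score(sm, muts)$score, 1.4)

  # permutation invariance
  expect_equal(multi_mutant_score(sm, muts[c(3, 1, 2), ])$score, 1.4)

  # empty list is the WT baseline
  expect_equal(multi_mutant_score(sm, muts[0, ])$score, 0)

  # single mutation equals the scaled cell exactly
  expect_equal(multi_mutant_score(sm, muts[1, ])$score,
               unname(sm$scores["10", "F"]))

  expect_error(multi_mutant_score(sm, muts[c(1, 1), ]), "duplicate")
  expect_error(multi_mutant_score(sm, tibble::tibble(position_label = "99",
                                                     mut_aa = "F")), "unknown")
  expect_error(multi_mutant_score(sm, tibble::tibble(position_label = "10",
                                                     mut_aa = "A")), "WT")
})

test_that("non-additive point-scan scores are refused unless forced", {
  tbl <- two_pos_tbl()
  sm <- scale_to_wt(parse_scores(score_csv(tbl), "rosetta_pmut"))
  muts <- tibble::tibble(position_label = "10", mut_aa = "F")
  expect_error(multi_mutant_score(sm, muts), "non-additive")
  forced <- multi_mutant_score(sm, muts, force = TRUE)
  expect_true(is.numeric(forced$score))
})

test_that("a quintuple mutant with three favourable singles can still sum positive", {
  tbl <- two_pos_tbl()
  for (p in c("12", "13", "14")) {
    tbl <- dplyr::bind_rows(tbl, dplyr::mutate(two_pos_tbl()[1:20, ],
                                               position_label = p, wt_aa = "G"))
  }
  sm <- scale_to_wt(parse_scores(score_csv(tbl), "antiberty_pll"))
  sm$scores["10", "T"] <- 1.1;  sm$scores["11", "D"] <- 0.7
  sm$scores["12", "Y"] <- 0.9;  sm$scores["13", "T"] <- -0.6
  sm$scores["14", "A"] <- -0.4
  muts <- tibble::tibble(position_label = c("10", "11", "12", "13", "14"),
                         mut_aa = c("T", "D", "Y", "T", "A"))
  res <- multi_mutant_score(sm, muts)
  expect_equal(sum(res$per_mutation$score > 0), 3L)
  expect_gt(res$score, 0)
})

test_that("identical inputs give a null isotype-sensitivity result", {
  spec <- fixture_spec(61)
  sf <- make_score_fixture(spec, n_positions = 20, n_planted = 0)
  b <- parse_scores(sf$paths$iso_b, "rosetta_pmut")
  res <- isotype_sensitivity(b, b, b)
  expect_true(all(res$effect == 0))
  expect_true(all(res$p_value == 1))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("a planted shifted position dominates the sensitivity ranking", {
  spec <- fixture_spec(61)
  sf <- make_score_fixture(spec, n_positions = 50, n_planted = 1,
                           shift = 2, noise_sd = 0.5)
  a <- parse_scores(sf$paths$iso_a, "rosetta_pmut")
  b <- parse_scores(sf$paths$iso_b, "rosetta_pmut")
  ctrl <- parse_scores(sf$paths$ctrl, "rosetta_pmut")
  res <- isotype_sensitivity(a, b, ctrl)
  planted <- sf$truth$planted_positions
  expect_equal(res$position_label[which.max(abs(res$effect))], planted)
  expect_equal(res$position_label[which.min(res$q_value)], planted)
})

test_that("swapping the isotypes negates the per-position mean difference", {
  spec <- fixture_spec(62)
  sf <- make_score_fixture(spec, n_positions = 30, n_planted = 2)
  a <- parse_scores(sf$paths$iso_a, "x")
  b <- parse_scores(sf$paths$iso_b, "x")
  ctrl <- parse_scores(sf$paths$ctrl, "x")
  r1 <- isotype_sensitivity(a, b, ctrl)
  r2 <- isotype_sensitivity(b, a, ctrl)
  expect_equal(r2$mean_d_iso, -r1$mean_d_iso, tolerance = 1e-12)
  # the isotype-preference direction flips wherever it is non-zero
  expect_true(all(sign(r2$mean_d_iso) == -sign(r1$mean_d_iso)))
})

test_that("mismatched WT residues and scaling states are rejected", {
  sm1 <- parse_scores(score_csv(two_pos_tbl()), "x")
  tbl2 <- two_pos_tbl(); tbl2$wt_aa[tbl2$position_label == "10"] <- "W"
  sm2 <- parse_scores(score_csv(tbl2), "x")
  expect_error(isotype_sensitivity(sm1, sm2, sm1), "WT residues disagree")
  expect_error(isotype_sensitivity(scale_to_wt(sm1), sm1, sm1), "scale")
})
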