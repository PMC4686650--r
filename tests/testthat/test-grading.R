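# The full evaluation grids, as published: every cell hard-coded.
c1_oracle <- data.frame(
  roundness  = rep(c("flat", "round", "oval"), each = 3),
  verticality = rep(c("horizontal", "oblique", "vertical"), 3),
  grade = c(0, 0.5, NA, 0.5, 1, 2, 1, 1.5, 2)
)
c2_oracle <- data.frame(
  depth_relation = rep(c("CS_less_H", "CS_equal_H", "CS_greater_H"), each = 3),
  verticality = rep(c("horizontal", "oblique", "vertical"), 3),
  grade = c(0, 0.5, 0.5, 1, 1, 1.5, 1, 1.5, 2)
)
c3_oracle <- data.frame(
  exposure = rep(c("much_less", "less", "equal", "greater", "much_greater"), 2),
  th = rep(c("emptied", "filled"), each = 5),
  grade = c(2, 1, 0.5, 0, 0, 2, 1.5, 1, 0.5, 0)
)

test_that("C1 grading reproduces the roundness x verticality grid", {
  for (i in seq_len(nrow(c1_oracle))) {
    row <- c1_oracle[i, ]
    if (is.na(row$grade)) {
      expect_error(grade_c1(row$roundness, row$verticality),
                   "not applicable")
    } else {
      expect_identical(grade_c1(row$roundness, row$verticality), row$grade)
    }
  }
  expect_error(grade_c1("spherical", "horizontal"), "invalid roundness")
})

test_that("C2 grading reproduces the collateral-sulcus grid", {
  for (i in seq_len(nrow(c2_oracle))) {
    row <- c2_oracle[i, ]
    expect_identical(grade_c2(row$depth_relation, row$verticality), row$grade)
  }
})

test_that("C3 grading reproduces the medial-positioning grid, extremes ignoring the temporal horn", {
  for (i in seq_len(nrow(c3_oracle))) {
    row <- c3_oracle[i, ]
    expect_identical(grade_c3(row$exposure, row$th), row$grade)
  }
  # the extreme relations are insensitive to the temporal horn
  expect_identical(grade_c3("much_less", "emptied"),
                   grade_c3("much_less", "filled"))
  expect_identical(grade_c3("much_greater", "emptied"),
                   grade_c3("much_greater", "filled"))
})

test_that("C4 and C5 grading follow their binary and three-level rules", {
  expect_identical(grade_c4(c(TRUE, FALSE)), c(2, 0))
  expect_true(all(grade_c4(c(TRUE, FALSE)) %in% criterion_levels("c4")))
  expect_identical(
    grade_c5(c("none", "oblique_crossing", "vertical_crossing")),
    c(0, 1, 2)
  )
  expect_error(grade_c5("diagonal"), "invalid crossing")
})

test_that("roundness classification honours the relative tolerance", {
  expect_identical(classify_roundness(10, 5), "flat")
  expect_identical(classify_roundness(7, 7), "round")
  expect_identical(classify_roundness(5, 8), "oval")
  # |10 - 9.2| = 0.8 <= 0.1 * 10: visually indistinguishable
  expect_identical(classify_roundness(10, 9.2, rel_tolerance = 0.1), "round")
  expect_identical(classify_roundness(10, 8.9, rel_tolerance = 0.1), "flat")
  expect_error(classify_roundness(-1, 5), "invalid geometry")
  expect_error(classify_roundness(5, 0), "invalid geometry")
})

test_that("verticality bins are horizontal / oblique / vertical with angular tolerance", {
  expect_identical(classify_verticality(c(0, 10, 45, 80, 85, 90)),
                   c("horizontal", "horizontal", "oblique",
                     "vertical", "vertical", "vertical"))
  expect_error(classify_verticality(95), "invalid geometry")
  expect_error(classify_verticality(-3), "invalid geometry")
})

test_that("exposure ratio binning maps zero to much_less and respects the cut points", {
  expect_identical(exposure_relation(0, 5), "much_less")
  expect_identical(exposure_relation(5, 5), "equal")
  # ratio 10 exceeds the top default cut point 4
  expect_identical(exposure_relation(20, 2), "much_greater")
  expect_identical(
    exposure_relation(c(0.8, 3, 4, 6, 20), rep(4, 5)),
    c("much_less", "less", "equal", "greater", "much_greater")
  )
  expect_error(exposure_relation(1, 1, bin_edges = c(1, 0.5, 2, 3)),
               "strictly increasing")
  expect_error(exposure_relation(1, 0), "invalid geometry")
})

test_that("the composite score sums the five grades on the half-point grid", {
  expect_identical(ihi_score(0, 0, 0, 0, 0), 0)
  expect_identical(ihi_score(2, 2, 2, 2, 2), 10)
  expect_identical(ihi_score(1, 1.5, 0.5, 0, 1), 4)
  expect_error(ihi_score(1, NA, 0, 0, 0), "incomplete assessment")
  expect_error(ihi_score(0.3, 0, 0, 0, 0), "invalid C1")
  expect_error(ihi_score(0, 0, 0, 1, 0), "invalid C4")

  # every attainable score lies in [0, 10] on the 0.5 grid, and raising any
  # single grade never lowers the score
  grid <- expand.grid(c1 = criterion_levels("c1"), c2 = criterion_levels("c2"),
                      c3 = criterion_levels("c3"), c4 = criterion_levels("c4"),
                      c5 = criterion_levels("c5"))
  s <- ihi_score(grid$c1, grid$c2, grid$c3, grid$c4, grid$c5)
  expect_true(all(s >= 0 & s <= 10))
  expect_true(all(s * 2 == round(s * 2)))
  expect_true(all(ihi_score(pmin(grid$c1 + 0.5, 2), grid$c2, grid$c3,
                            grid$c4, grid$c5) >= s))
})

test_that("binary classification is strict-exceedance and monotone in the score", {
  expect_false(classify_ihi(3.5, 3.75))
  expect_true(classify_ihi(4, 3.75))
  expect_false(classify_ihi(0, 3.75))
  s <- seq(0, 10, by = 0.5)
  cl <- classify_ihi(s, 3.75)
  expect_true(all(diff(cl) >= 0)) # once IHI, always IHI as score grows
  expect_error(classify_ihi(11), "lie in")
})

test_that("the accuracy-maximising threshold is found on midpoint candidates", {
  fit <- optimal_threshold(c(2, 3, 3.5, 4, 5), c(0, 0, 0, 2, 2))
  expect_identical(fit$threshold, 3.75)
  expect_identical(fit$accuracy, 1)
  # midpoints between consecutive distinct scores only
  expect_identical(fit$candidates$threshold, c(2.5, 3.25, 3.75, 4.5))
})

test_that("threshold fitting ignores partial cases and is invariant to duplication and order", {
  score <- c(1, 2, 3, 3.5, 4, 4.5, 6, 2.5)
  c0 <- c(0, 0, 0, 0, 2, 2, 2, 1) # the C0 = 1 record must not matter
  fit <- optimal_threshold(score, c0)
  expect_identical(fit$threshold, 3.75)
  fit_dup <- optimal_threshold(rep(score, 2), rep(c0, 2))
  expect_identical(fit_dup$threshold, fit$threshold)
  expect_identical(fit_dup$accuracy, fit$accuracy)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  expect_identical(optimal_threshold(score[perm], c0[perm])$threshold,
                   fit$threshold)
})

test_that("degenerate threshold inputs are rejected", {
  expect_error(optimal_threshold(c(1, 2), c(0, 0)), "degenerate")
  expect_error(optimal_threshold(c(1, 1), c(0, 2)), "degenerate")
  expect_error(optimal_threshold(c(1, 2, 3), c(1, 1, 1)), "degenerate")
})
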