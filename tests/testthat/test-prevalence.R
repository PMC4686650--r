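test_that("Wald proportion intervals match hand computation and clip at the boundaries", {
  est <- proportion_ci(50, 100)
  expect_equal(est$p_hat, 0.5)
  # 0.5 +/- qnorm(0.975) * sqrt(0.25 / 100), by hand
  expect_equal(est$ci_low, 0.4020018, tolerance = 1e-6)
  expect_equal(est$ci_high, 0.5979982, tolerance = 1e-6)

  zero <- proportion_ci(0, 100)
  expect_identical(c(zero$ci_low, zero$ci_high), c(0, 0))
  all_ <- proportion_ci(100, 100)
  expect_identical(c(all_$ci_low, all_$ci_high), c(1, 1))

  left_total <- proportion_ci(343, 2008)
  expect_equal(left_total$p_hat, 0.1708, tolerance = 1e-3)
  expect_equal(left_total$ci_low, 0.1544, tolerance = 1e-3)
  expect_equal(left_total$ci_high, 0.1872, tolerance = 1e-3)

  expect_error(proportion_ci(5, 0), "degenerate")
  expect_error(proportion_ci(11, 10), "lie in")
})

test_that("the Wilson interval is ordered and never leaves [0, 1]", {
  for (count in c(0, 1, 50, 99, 100)) {
    w <- proportion_ci(count, 100, method = "wilson")
    expect_lte(w$ci_low, w$p_hat)
    expect_gte(w$ci_high, w$p_hat)
    expect_gte(w$ci_low, 0)
    expect_lte(w$ci_high, 1)
  }
  # Wilson is strictly inside (0, 1) at the degenerate counts, unlike Wald
  expect_gt(proportion_ci(0, 100, method = "wilson")$ci_high, 0)
})

test_that("C0 frequency tables normalise and report exclusions", {
  toy <- make_assessments(rep(paste0("s", 1:4), each = 2),
                          rep(c("left", "right"), 4),
                          c0 = c(0, 0, 0, 0, 1, 0, 2, 0))
  tab <- c0_frequency_table(toy, "left")
  expect_equal(tab$p_hat, c(0.5, 0.25, 0.25))
  expect_equal(sum(tab$p_hat), 1)
  expect_identical(attr(tab, "excluded"), 0L)

  all0 <- make_assessments(paste0("s", 1:5), "left", c0 = 0)
  expect_equal(c0_frequency_table(all0, "left")$p_hat, c(1, 0, 0))

  with_na <- make_assessments(paste0("s", 1:4), "left", c0 = c(0, NA, 2, 2))
  tab_na <- c0_frequency_table(with_na, "left")
  expect_identical(attr(tab_na, "excluded"), 1L)
  expect_equal(sum(tab_na$p_hat), 1)
})

test_that("co-occurrence cells sum to one and marginals conserve the per-side counts", {
  set.seed(5)
  n <- 120L
  ids <- paste0("s", 1:n)
  toy <- rbind(
    make_assessments(ids, "left", c0 = sample(0:2, n, TRUE, c(0.7, 0.1, 0.2))),
    make_assessments(ids, "right", c0 = sample(0:2, n, TRUE, c(0.85, 0.09, 0.06)))
  )
  co <- cooccurrence_table(toy)
  counts <- attr(co, "counts")
  expect_equal(sum(co$p_hat), 1)
  expect_identical(sum(counts), n)
  left_counts <- table(factor(toy$c0[toy$side == "left"], levels = 0:2))
  right_counts <- table(factor(toy$c0[toy$side == "right"], levels = 0:2))
  expect_identical(unname(rowSums(counts)), as.numeric(left_counts))
  expect_identical(unname(colSums(counts)), as.numeric(right_counts))

  alike <- rbind(make_assessments(ids, "left", c0 = 0),
                 make_assessments(ids, "right", c0 = 0))
  co0 <- cooccurrence_table(alike)
  expect_equal(co0$p_hat[co0$left == "no_ihi" & co0$right == "no_ihi"], 1)
})

test_that("the chi-squared test equals the brute-force sum over cells", {
  expect_equal(chi2_independence(matrix(c(5, 5, 7, 7), 2))$chi2, 0)
  expect_equal(chi2_independence(matrix(c(5, 5, 7, 7), 2))$p, 1)
  perfect <- chi2_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(perfect$chi2, 20)
  expect_identical(perfect$df, 1L)
  set.seed(13)
  for (rep in 1:8) {
    tab <- matrix(rpois(6, 12) + 1, 2)
    res <- chi2_independence(tab)
    expect_equal(res$chi2, bf_chi2(tab), tolerance = 1e-10)
    expect_identical(res$df, 2L)
  }
  expect_error(chi2_independence(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero marginal")
})

test_that("side counts reconstructed from published frequencies give the reported lateralisation", {
  # left 70.9 / 11.9 / 17.1 %, right 84.6 / 9.0 / 6.5 % of n = 2008 per side;
  # the printed statistic (129.2) is not exactly recoverable from rounded
  # percentages, the reconstruction lands near 127
  counts <- rbind(
    left = round(2008 * c(0.709, 0.119, 0.171)),
    right = round(2008 * c(0.846, 0.090, 0.065))
  )
  res <- chi2_independence(counts)
  expect_identical(res$df, 2L)
  expect_gt(res$chi2, 120)
  expect_lt(res$chi2, 132)
  expect_lt(res$p, 1e-26)
})

test_that("side and covariate comparisons build the right tables and track exclusions", {
  n <- 60
  ids <- paste0("s", 1:n)
  c0s <- rep(c(0, 0, 0, 1, 2), length.out = n)
  toy <- rbind(make_assessments(ids, "left", c0 = c0s),
               make_assessments(ids, "right", c0 = c0s))
  # identical distributions on both sides
  expect_equal(side_comparison(toy)$chi2, 0)
  sm <- side_comparison(toy, method = "stuart_maxwell")
  expect_equal(sm$chi2, 0)

  cov <- data.frame(subject_id = ids,
                    sex = rep(c("F", "M"), length.out = n),
                    handedness = c(rep("right", n - 10), rep(NA, 10)),
                    stringsAsFactors = FALSE)
  # sex alternates against a repeating C0 pattern: build succeeds, df matches
  res <- covariate_comparison(toy, cov, "sex", "left")
  expect_identical(res$df, 2L)
  expect_identical(attr(res, "excluded"), 0L)
  # single observed level after NA exclusion
  expect_error(covariate_comparison(toy, cov, "handedness", "left"),
               "fewer than two")
})

test_that("criterion grade distributions normalise and identical sides give null tests", {
  n <- 50
  ids <- paste0("s", 1:n)
  g <- rep(criterion_levels("c1"), length.out = n)
  toy <- rbind(
    data.frame(subject_id = ids, side = "left", c1 = g, c2 = g, c3 = g,
               c4 = rep(c(0, 2), length.out = n),
               c5 = rep(0:2, length.out = n)),
    data.frame(subject_id = ids, side = "right", c1 = g, c2 = g, c3 = g,
               c4 = rep(c(0, 2), length.out = n),
               c5 = rep(0:2, length.out = n))
  )
  dist <- criterion_distribution(toy)
  sums <- aggregate(proportion ~ criterion + side, dist$frequencies, sum)
  expect_true(all(abs(sums$proportion - 1) < 1e-12))
  expect_true(all(dist$tests$chi2 == 0))
  expect_identical(nrow(dist$tests), 5L)
})

test_that("threshold frequencies distinguish the two denominators via partial cases only", {
  ids <- paste0("s", 1:10)
  scores <- c(0, 1, 2, 3, 3.5, 4, 5, 6, 2, 1)
  c0s <- c(0, 0, 0, 0, 1, 2, 2, 2, 1, 0)
  toy <- rbind(make_assessments(ids, "left", c0 = c0s, score = scores),
               make_assessments(ids, "right", c0 = c0s, score = scores))
  all_mode <- threshold_frequency_table(toy, 3.75, mode = "classify_all")
  fix_mode <- threshold_frequency_table(toy, 3.75, mode = "exclude_partial")
  left_all <- all_mode[all_mode$side == "left", ]
  expect_equal(left_all$p_hat[left_all$group == "ihi"], 0.3)
  expect_equal(sum(left_all$p_hat), 1)
  left_fix <- fix_mode[fix_mode$side == "left", ]
  # partial cases (both below threshold here) leave the no-IHI count only
  expect_equal(left_fix$p_hat[left_fix$group == "ihi"], 0.3)
  expect_equal(left_fix$p_hat[left_fix$group == "no_ihi"], 0.5)
  expect_equal(sum(left_fix$p_hat) + 0.2, 1) # the 2 partials are the gap

  zero <- make_assessments(ids, "left", c0 = 0, score = 0)
  ztab <- threshold_frequency_table(zero, 3.75)
  expect_equal(ztab$p_hat[ztab$group == "ihi" & ztab$side == "left"], 0)
})
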