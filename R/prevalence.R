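# Prevalence and lateralisation analysis of IHI ratings.
#
# Frequencies of the global criterion C0 per side with binomial confidence
# intervals, left x right co-occurrence, chi-squared comparisons across
# side, sex and handedness, per-criterion grade distributions, and
# threshold-based IHI frequencies.

.c0_labels <- c(`0` = "no_ihi", `1` = "partial_ihi", `2` = "total_ihi")

#' Binomial proportion with confidence interval
#'
#' Wald normal-approximation interval (the default), clipped to `[0, 1]`,
#' or the Wilson score interval. `count` may be non-integral, which allows
#' reconstructing intervals from published percentages at a known sample
#' size.
#'
#' @param count Number of successes (`0 <= count <= n`); vectorised.
#' @param n Sample size (`>= 1`).
#' @param conf_level Confidence level, default 0.95.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return Data frame with columns `count`, `n`, `p_hat`, `ci_low`,
#'   `ci_high`.
#' @export
#' @examples
#' proportion_ci(343, 2008)
proportion_ci <- function(count, n, conf_level = 0.95,
                          method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (any(n < 1)) stop("degenerate input: n must be >= 1", call. = FALSE)
  if (any(count < 0) || any(count > n)) {
    stop("count must lie in [0, n]", call. = FALSE)
  }
  p <- count / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- pmax(0, p - half)
    hi <- pmin(1, p + half)
  } else {
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- pmax(0, ctr - half)
    hi <- pmin(1, ctr + half)
  }
  data.frame(count = count, n = n, p_hat = p, ci_low = lo, ci_high = hi)
}

#' @keywords internal
check_assessments <- function(assessments,
                              need = c("subject_id", "side", "c0")) {
  miss <- setdiff(need, names(assessments))
  if (length(miss)) {
    stop(sprintf("assessments is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  check_category(assessments$side, c("left", "right"), "side")
  if ("c0" %in% need) check_grade(assessments$c0, "c0")
  assessments
}

#' Frequency of the global criterion C0 for one side
#'
#' Proportion of hippocampi rated no / partial / total IHI on the given
#' side, each with its confidence interval. Hippocampi with a missing C0
#' are excluded and counted in the `excluded` attribute.
#'
#' @param assessments Data frame with columns `subject_id`, `side`, `c0`.
#' @param side `"left"` or `"right"`.
#' @param conf_level Confidence level, default 0.95.
#' @param method CI method, see [proportion_ci()].
#' @return Data frame with rows `no_ihi`, `partial_ihi`, `total_ihi` and
#'   the [proportion_ci()] columns; attribute `excluded` holds the number
#'   of hippocampi dropped for missing C0.
#' @export
c0_frequency_table <- function(assessments, side = c("left", "right"),
                               conf_level = 0.95, method = "wald") {
  side <- match.arg(side)
  check_assessments(assessments)
  c0 <- assessments$c0[assessments$side == side]
  excluded <- sum(is.na(c0))
  c0 <- c0[!is.na(c0)]
  if (!length(c0)) stop("degenerate input: no rated hippocampi", call. = FALSE)
  counts <- table(factor(c0, levels = c(0, 1, 2)))
  out <- proportion_ci(as.integer(counts), length(c0),
                       conf_level = conf_level, method = method)
  out <- cbind(category = unname(.c0_labels), out)
  attr(out, "excluded") <- excluded
  out
}

#' Left x right co-occurrence of the global criterion C0
#'
#' Joint distribution of the left and right C0 grade over subjects with both
#' sides rated, as proportions of the population with confidence intervals.
#' Row and column sums reproduce the per-side marginal frequencies exactly
#' at the count level.
#'
#' @inheritParams c0_frequency_table
#' @return Data frame with one row per (left C0, right C0) cell: `left`,
#'   `right`, and the [proportion_ci()] columns. Attributes: `counts` (the
#'   3 x 3 count matrix, left in rows) and `excluded` (subjects missing a
#'   side).
#' @export
cooccurrence_table <- function(assessments, conf_level = 0.95,
                               method = "wald") {
  check_assessments(assessments)
  wide <- merge(
    assessments[assessments$side == "left", c("subject_id", "c0")],
    assessments[assessments$side == "right", c("subject_id", "c0")],
    by = "subject_id", suffixes = c("_left", "_right")
  )
  complete <- !is.na(wide$c0_left) & !is.na(wide$c0_right)
  excluded <- length(unique(assessments$subject_id)) - sum(complete)
  wide <- wide[complete, ]
  if (!nrow(wide)) stop("degenerate input: no bilaterally rated subjects",
                        call. = FALSE)
  counts <- table(factor(wide$c0_left, levels = c(0, 1, 2)),
                  factor(wide$c0_right, levels = c(0, 1, 2)))
  counts <- matrix(as.integer(counts), 3,
                   dimnames = list(left = .c0_labels, right = .c0_labels))
  grid <- expand.grid(left = unname(.c0_labels), right = unname(.c0_labels),
                      stringsAsFactors = FALSE)
  out <- cbind(grid, proportion_ci(as.vector(counts), nrow(wide),
                                   conf_level = conf_level, method = method))
  attr(out, "counts") <- counts
  attr(out, "excluded") <- excluded
  out
}

#' Pearson chi-squared test of independence
#'
#' Plain Pearson chi-squared on a contingency table, without continuity
#' correction, with the p-value from the asymptotic chi-squared
#' distribution.
#'
#' @param tab Count matrix (at least 2 x 2 after dropping empty margins is
#'   required; a zero marginal raises an error).
#' @return An `ihi_chi2` object: list with `table`, `expected`, `chi2`,
#'   `df`, `p`.
#' @export
#' @examples
#' chi2_independence(matrix(c(10, 0, 0, 10), 2))
chi2_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate input: zero marginal in the contingency table",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(
    list(
      table = tab, expected = ht$expected,
      chi2 = unname(ht$statistic), df = unname(ht$parameter),
      p = unname(ht$p.value)
    ),
    class = "ihi_chi2"
  )
}

#' @export
print.ihi_chi2 <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: X2 = %.4g, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Compare C0 frequencies between the two sides
#'
#' Builds the 2 x 3 (side x C0 category) count table and tests independence.
#' Following the original analysis, the two hippocampi of a subject are
#' treated as independent observations; `method = "stuart_maxwell"` instead
#' runs the Stuart--Maxwell marginal-homogeneity test, which respects the
#' pairing.
#'
#' @param assessments Data frame with `subject_id`, `side`, `c0`.
#' @param method `"independence"` (default) or `"stuart_maxwell"`.
#' @return An `ihi_chi2` object.
#' @export
side_comparison <- function(assessments,
                            method = c("independence", "stuart_maxwell")) {
  method <- match.arg(method)
  check_assessments(assessments)
  if (method == "independence") {
    ok <- !is.na(assessments$c0)
    tab <- table(factor(assessments$side[ok], levels = c("left", "right")),
                 factor(assessments$c0[ok], levels = c(0, 1, 2)))
    return(chi2_independence(as.matrix(tab)))
  }
  co <- cooccurrence_table(assessments)
  counts <- attr(co, "counts")
  d <- rowSums(counts) - colSums(counts)
  d <- d[-3]
  v <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) {
      v[i, j] <- if (i == j) {
        rowSums(counts)[i] + colSums(counts)[i] - 2 * counts[i, i]
      } else {
        -(counts[i, j] + counts[j, i])
      }
    }
  }
  chi2 <- if (all(d == 0)) 0 else as.numeric(t(d) %*% MASS::ginv(v) %*% d)
  structure(
    list(table = counts, expected = NULL, chi2 = chi2, df = 2,
         p = stats::pchisq(chi2, 2, lower.tail = FALSE)),
    class = "ihi_chi2"
  )
}

#' Compare C0 frequencies across a subject covariate
#'
#' Cross-tabulates a categorical covariate (sex, handedness, ...) against
#' the C0 grade for one side and tests independence. Subjects with a
#' missing covariate or C0 are excluded listwise; their number is recorded
#' in the `excluded` attribute of the returned object.
#'
#' @param assessments Data frame with `subject_id`, `side`, `c0`.
#' @param covariates Data frame with `subject_id` and the covariate column.
#' @param covariate Name of the covariate column.
#' @param side `"left"` or `"right"`.
#' @return An `ihi_chi2` object with an `excluded` attribute.
#' @export
covariate_comparison <- function(assessments, covariates, covariate,
                                 side = c("left", "right")) {
  side <- match.arg(side)
  check_assessments(assessments)
  if (!covariate %in% names(covariates)) {
    stop(sprintf("covariates has no column '%s'", covariate), call. = FALSE)
  }
  sub <- assessments[assessments$side == side, c("subject_id", "c0")]
  sub <- merge(sub, covariates[, c("subject_id", covariate)], by = "subject_id")
  ok <- !is.na(sub$c0) & !is.na(sub[[covariate]])
  excluded <- nrow(sub) - sum(ok)
  sub <- sub[ok, ]
  groups <- unique(sub[[covariate]])
  if (length(groups) < 2) {
    stop("degenerate input: covariate has fewer than two observed levels",
         call. = FALSE)
  }
  tab <- table(sub[[covariate]], factor(sub$c0, levels = c(0, 1, 2)))
  tab <- as.matrix(tab)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  res <- chi2_independence(tab)
  attr(res, "excluded") <- excluded
  res
}

#' Grade distribution of each individual criterion, by side
#'
#' Per-criterion, per-side relative frequencies of every permitted grade,
#' plus a left-vs-right chi-squared test per criterion (sides treated as
#' independent samples, matching the original analysis; grades never
#' observed on either side are dropped from the test table).
#'
#' @param assessments Data frame with `subject_id`, `side` and grade
#'   columns `c1` ... `c5`.
#' @return List with `frequencies` (data frame: `criterion`, `side`,
#'   `grade`, `count`, `proportion`) and `tests` (data frame: `criterion`,
#'   `chi2`, `df`, `p`).
#' @export
criterion_distribution <- function(assessments) {
  check_assessments(assessments, need = c("subject_id", "side"))
  freq <- list()
  tests <- list()
  for (cr in c("c1", "c2", "c3", "c4", "c5")) {
    if (!cr %in% names(assessments)) next
    lv <- criterion_levels(cr)
    check_grade(assessments[[cr]], cr)
    counts <- matrix(0L, 2, length(lv),
                     dimnames = list(c("left", "right"), lv))
    for (sd in c("left", "right")) {
      g <- assessments[[cr]][assessments$side == sd]
      g <- g[!is.na(g)]
      counts[sd, ] <- as.integer(table(factor(g, levels = lv)))
      freq[[length(freq) + 1]] <- data.frame(
        criterion = cr, side = sd, grade = lv,
        count = counts[sd, ],
        proportion = counts[sd, ] / max(1, sum(counts[sd, ]))
      )
    }
    test_tab <- counts[, colSums(counts) > 0, drop = FALSE]
    ht <- chi2_independence(test_tab)
    tests[[length(tests) + 1]] <- data.frame(
      criterion = cr, chi2 = ht$chi2, df = ht$df, p = ht$p
    )
  }
  list(
    frequencies = do.call(rbind, freq),
    tests = do.call(rbind, tests)
  )
}

#' IHI frequency under the score threshold
#'
#' Classifies each hippocampus by `score > threshold` and reports the IHI /
#' no-IHI frequencies per side. Two denominators are available:
#' `"exclude_partial"` drops hippocampi with C0 = 1 (partial IHI) before the
#' split, reporting proportions of the full side population, while
#' `"classify_all"` classifies every hippocampus with a score.
#'
#' @param assessments Data frame with `subject_id`, `side`, `c0`, `score`.
#' @param threshold Classification threshold, default 3.75.
#' @param mode `"classify_all"` (default) or `"exclude_partial"`.
#' @param conf_level Confidence level, default 0.95.
#' @return Data frame with rows (side x {ihi, no_ihi}) and the
#'   [proportion_ci()] columns; `excluded` attribute counts hippocampi
#'   without a score (plus, under `"exclude_partial"`, the partial cases).
#' @export
threshold_frequency_table <- function(assessments, threshold = 3.75,
                                      mode = c("classify_all", "exclude_partial"),
                                      conf_level = 0.95) {
  mode <- match.arg(mode)
  check_assessments(assessments, need = c("subject_id", "side", "c0", "score"))
  out <- list()
  excluded <- 0L
  for (sd in c("left", "right")) {
    sub <- assessments[assessments$side == sd, ]
    if (!nrow(sub)) next
    n_side <- sum(!is.na(sub$score))
    excluded <- excluded + nrow(sub) - n_side
    sub <- sub[!is.na(sub$score), ]
    if (mode == "exclude_partial") {
      drop <- !is.na(sub$c0) & sub$c0 == 1
      excluded <- excluded + sum(drop)
      sub <- sub[!drop, ]
    }
    ihi <- classify_ihi(sub$score, threshold)
    est <- proportion_ci(c(sum(ihi), sum(!ihi)), n_side,
                         conf_level = conf_level)
    out[[sd]] <- cbind(side = sd, group = c("ihi", "no_ihi"), est)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}
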