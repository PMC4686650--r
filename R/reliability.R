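# Inter- and intra-rater reliability for ordinal visual ratings.
#
# Agreement between two raters (or two sessions of the same rater) is
# summarised by Cohen's kappa for nominal-style criteria (C0, C4, C5) and by
# linearly weighted kappa for the half-point ordinal criteria (C1-C3).
# Standard errors use the Fleiss-Cohen-Everitt large-sample form; both
# statistics are computed from the same weighted machinery (identity weights
# recover plain kappa).

#' Cross-tabulate two rating series
#'
#' Builds the square confusion matrix of two grade series over a fixed
#' category set. Categories that were never used are retained so that the
#' chance-agreement term of kappa is computed over the full set.
#'
#' @param rater_a,rater_b Grade vectors of equal length (>= 1).
#' @param levels Ordered vector of permitted categories. Defaults to the
#'   union of observed values, sorted.
#' @return Integer matrix with `rater_a` in rows, `rater_b` in columns.
#' @export
#' @examples
#' confusion_table(c(0, 0, 2), c(0, 2, 2), levels = c(0, 2))
confusion_table <- function(rater_a, rater_b, levels = NULL) {
  if (length(rater_a) == 0 || length(rater_a) != length(rater_b)) {
    stop("rating series must be non-empty and of equal length", call. = FALSE)
  }
  if (is.null(levels)) levels <- sort(unique(c(rater_a, rater_b)))
  bad <- c(setdiff(rater_a, levels), setdiff(rater_b, levels))
  if (length(bad)) {
    stop(sprintf("grade(s) outside the category set: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  tab <- table(factor(rater_a, levels = levels),
               factor(rater_b, levels = levels))
  m <- matrix(as.integer(tab), nrow = length(levels),
              dimnames = list(levels, levels))
  m
}

#' @keywords internal
kappa_stat <- function(tab, weighting = c("none", "linear", "quadratic"),
                       conf_level = 0.95) {
  weighting <- match.arg(weighting)
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("confusion table must be square", call. = FALSE)
  n <- sum(tab)
  if (n < 2) stop("at least two rated items are required", call. = FALSE)
  k <- nrow(tab)
  p <- tab / n
  w <- switch(weighting,
    none = diag(k),
    linear = 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1),
    quadratic = 1 - (outer(seq_len(k), seq_len(k), "-") / (k - 1))^2
  )
  r <- rowSums(p)
  cl <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, cl))
  if (1 - pe < 1e-12) {
    stop(paste(
      "undefined kappa: chance agreement is 1",
      "(both raters constant on the same category)"
    ), call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance of weighted kappa
  wi <- as.vector(w %*% cl)     # row-wise expected weights
  wj <- as.vector(t(w) %*% r)   # column-wise expected weights
  term <- sum(p * (w - outer(wi, wj, "+") * (1 - kappa))^2)
  v <- (term - (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      kappa = kappa, se = se,
      ci_low = max(-1, kappa - z * se), ci_high = min(1, kappa + z * se),
      weighting = weighting, conf_level = conf_level,
      n = n, p_observed = po, p_expected = pe
    ),
    class = "ihi_kappa"
  )
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` for a square
#' confusion table, with the asymptotic (Fleiss--Cohen--Everitt) standard
#' error and a normal confidence interval.
#'
#' @param tab Square count matrix from [confusion_table()].
#' @param conf_level Confidence level, default 0.95.
#' @return An `ihi_kappa` object: list with `kappa`, `se`, `ci_low`,
#'   `ci_high`, `weighting`, `n`.
#' @export
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2))$kappa  # 0.4
cohen_kappa <- function(tab, conf_level = 0.95) {
  kappa_stat(tab, weighting = "none", conf_level = conf_level)
}

#' Weighted kappa for ordinal ratings
#'
#' Penalises disagreements by their distance on the ordinal scale:
#' `kappa_w = 1 - sum(d * o) / sum(d * e)` with disagreement weights
#' `d_ij = |i - j| / (k - 1)` (linear, the default) or its square
#' (quadratic). With two categories it coincides with plain Cohen's kappa.
#'
#' @param tab Square count matrix over the ordered category set.
#' @param weighting `"linear"` (default) or `"quadratic"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An `ihi_kappa` object.
#' @export
weighted_kappa <- function(tab, weighting = c("linear", "quadratic"),
                           conf_level = 0.95) {
  kappa_stat(tab, weighting = match.arg(weighting), conf_level = conf_level)
}

#' @export
print.ihi_kappa <- function(x, ...) {
  lbl <- switch(x$weighting, none = "Cohen's kappa",
                sprintf("weighted kappa (%s)", x$weighting))
  cat(sprintf("%s: %.3f (SE %.3f, %d%% CI [%.3f, %.3f], n = %d)\n",
              lbl, x$kappa, x$se, round(100 * x$conf_level),
              x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Reproducibility report over criteria and rater comparisons
#'
#' Reproduces the two-rater, two-session reliability design: each rater
#' grades the same series twice, yielding two intra-rater comparisons
#' (session 1 vs. 2 within rater) and two inter-rater comparisons (rater vs.
#' rater within session). Criteria C1--C3 use linearly weighted kappa over
#' their half-point grids; C0, C4 and C5 use plain Cohen's kappa. A
#' criterion on which both series are constant and identical (as happens
#' for C4 when no rated subject shows a thickened subiculum) has no defined
#' kappa and is flagged not evaluable instead.
#'
#' @param ratings Long-format data frame with columns `item_id`,
#'   `criterion` (`"c0"` ... `"c5"`), `rater`, `session` (1 or 2) and
#'   `grade`.
#' @param conf_level Confidence level for the intervals, default 0.95.
#' @return Data frame with one row per criterion x comparison: `criterion`,
#'   `comparison`, `weighting`, `kappa`, `se`, `ci_low`, `ci_high`, `n`,
#'   `evaluable`.
#' @export
reproducibility_report <- function(ratings, conf_level = 0.95) {
  need <- c("item_id", "criterion", "rater", "session", "grade")
  miss <- setdiff(need, names(ratings))
  if (length(miss)) {
    stop(sprintf("ratings is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  raters <- sort(unique(ratings$rater))
  if (length(raters) != 2) {
    stop("exactly two raters are required", call. = FALSE)
  }
  sessions <- sort(unique(ratings$session))
  if (length(sessions) != 2) {
    stop("exactly two sessions are required", call. = FALSE)
  }
  comparisons <- list(
    list(a = c(raters[1], sessions[1]), b = c(raters[1], sessions[2])),
    list(a = c(raters[2], sessions[1]), b = c(raters[2], sessions[2])),
    list(a = c(raters[1], sessions[1]), b = c(raters[2], sessions[1])),
    list(a = c(raters[1], sessions[2]), b = c(raters[2], sessions[2]))
  )
  criteria <- intersect(c("c0", "c1", "c2", "c3", "c4", "c5"),
                        unique(tolower(ratings$criterion)))
  out <- list()
  for (cr in criteria) {
    lv <- criterion_levels(cr)
    weighting <- if (cr %in% c("c1", "c2", "c3")) "linear" else "none"
    sub <- ratings[tolower(ratings$criterion) == cr, ]
    for (cmp in comparisons) {
      sa <- sub[sub$rater == cmp$a[1] & sub$session == cmp$a[2], ]
      sb <- sub[sub$rater == cmp$b[1] & sub$session == cmp$b[2], ]
      common <- intersect(sa$item_id, sb$item_id)
      ga <- sa$grade[match(common, sa$item_id)]
      gb <- sb$grade[match(common, sb$item_id)]
      label <- sprintf("%s%s vs %s%s", cmp$a[1], cmp$a[2], cmp$b[1], cmp$b[2])
      row <- data.frame(
        criterion = cr, comparison = label, weighting = weighting,
        kappa = NA_real_, se = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_,
        n = length(common), evaluable = FALSE,
        stringsAsFactors = FALSE
      )
      kp <- tryCatch(
        kappa_stat(confusion_table(ga, gb, levels = lv),
                   weighting = weighting, conf_level = conf_level),
        error = function(e) NULL
      )
      if (!is.null(kp)) {
        row$kappa <- kp$kappa
        row$se <- kp$se
        row$ci_low <- kp$ci_low
        row$ci_high <- kp$ci_high
        row$evaluable <- TRUE
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}
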