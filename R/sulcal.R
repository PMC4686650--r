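# Association between IHI and sulcal morphometry.
#
# Subjects are split, per side, into an IHI group (score above threshold on
# that side) and a common non-IHI group (no IHI on either side). Each
# (sulcus, measure) cell is compared between groups with a pooled-variance
# Student t-test and Cohen's d, in four directions: left IHI vs. left or
# right hemisphere sulci, right IHI vs. right or left hemisphere sulci.
# Raw p-values are Bonferroni-corrected over the fixed design family of
# 45 sulci x 5 measures x 4 directions = 900 tests.

.directions <- data.frame(
  direction = c("leftIHI-leftHem", "leftIHI-rightHem",
                "rightIHI-rightHem", "rightIHI-leftHem"),
  ihi_side = c("left", "left", "right", "right"),
  hemisphere = c("left", "right", "right", "left"),
  stringsAsFactors = FALSE
)

#' Default sulcus nomenclature
#'
#' The 45 sulcus labels per hemisphere used by the default analysis and the
#' synthetic generator, in BrainVisa-style abbreviated form. Shipped as an
#' editable CSV under `extdata`.
#'
#' @return Character vector of 45 sulcus labels.
#' @export
#' @examples
#' head(sulcus_nomenclature())
sulcus_nomenclature <- function() {
  path <- system.file("extdata", "sulci_nomenclature.csv",
                      package = "ihiscore", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)$label
}

#' Morphometric measures recognised per sulcus
#'
#' Five measures enter the correction family (surface of the sulcal medial
#' sheet, maximal and mean depth, opening i.e. sulcal width, and gray
#' matter thickness); sulcus length is carried in the data model as a sixth
#' measure but does not enlarge the default Bonferroni denominator.
#'
#' @return Character vector of measure names.
#' @export
sulcal_measures <- function() {
  c("surface", "max_depth", "mean_depth", "opening", "gm_thickness", "length")
}

#' Split subjects into IHI and non-IHI groups
#'
#' @param assessments Data frame with `subject_id`, `side`, `score` (both
#'   sides rated per subject).
#' @param threshold Classification threshold on the composite score,
#'   default 3.75.
#' @return List with character vectors `ihi_left`, `ihi_right` (subjects
#'   classified IHI on that side) and `non_ihi` (subjects with IHI on
#'   neither side). A subject IHI only on the opposite side belongs to
#'   neither set for a given side's comparison.
#' @export
build_groups <- function(assessments, threshold = 3.75) {
  check_assessments(assessments, need = c("subject_id", "side", "score"))
  wide <- merge(
    assessments[assessments$side == "left", c("subject_id", "score")],
    assessments[assessments$side == "right", c("subject_id", "score")],
    by = "subject_id", suffixes = c("_left", "_right")
  )
  wide <- wide[!is.na(wide$score_left) & !is.na(wide$score_right), ]
  ihi_l <- classify_ihi(wide$score_left, threshold)
  ihi_r <- classify_ihi(wide$score_right, threshold)
  list(
    ihi_left = wide$subject_id[ihi_l],
    ihi_right = wide$subject_id[ihi_r],
    non_ihi = wide$subject_id[!ihi_l & !ihi_r]
  )
}

#' Pooled-variance two-sample Student t-test
#'
#' Classic equal-variance t with `df = n_a + n_b - 2` and a two-sided
#' p-value. Missing values are dropped. When the pooled variance is zero
#' the statistic is 0 (equal means) or signed infinity (unequal means,
#' flagged by `infinite = TRUE`).
#'
#' @param values_a,values_b Numeric vectors, each with at least two
#'   non-missing values.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `pooled_sd`, `infinite`.
#' @export
group_ttest <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least two non-missing values", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (delta == 0) {
      return(list(t = 0, df = df, p = 1, mean_a = mean(a), mean_b = mean(b),
                  n_a = na, n_b = nb, pooled_sd = 0, infinite = FALSE))
    }
    return(list(t = sign(delta) * Inf, df = df, p = 0, mean_a = mean(a),
                mean_b = mean(b), n_a = na, n_b = nb, pooled_sd = 0,
                infinite = TRUE))
  }
  t <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  list(
    t = t, df = df, p = 2 * stats::pt(-abs(t), df),
    mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb,
    pooled_sd = sqrt(sp2), infinite = FALSE
  )
}

#' Cohen's d standardised mean difference
#'
#' `(mean_a - mean_b) / pooled SD`; by the sign convention used throughout,
#' the first group is the IHI group, so a positive d means larger values
#' with IHI.
#'
#' @inheritParams group_ttest
#' @return Numeric effect size (`NaN` when the pooled SD is zero).
#' @export
cohens_d <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least two non-missing values", call. = FALSE)
  }
  df <- length(a) + length(b) - 2
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
              (length(b) - 1) * stats::var(b)) / df)
  (mean(a) - mean(b)) / sp
}

#' Bonferroni correction
#'
#' @param p_raw Raw p-value(s) in `[0, 1]`.
#' @param m Family size; the default 900 is the fixed design denominator
#'   (45 sulci x 5 measures x 4 directions), kept even when some cells are
#'   missing.
#' @return `min(1, m * p_raw)`, vectorised.
#' @export
#' @examples
#' bonferroni(1e-8)       # 9e-6
#' bonferroni(0.5)        # 1
bonferroni <- function(p_raw, m = 900) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop("p_raw must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, m * p_raw)
}

#' Run the full IHI x sulcal morphometry association
#'
#' For every (direction, sulcus, measure) cell with data, compares the IHI
#' group of the direction's side against the common non-IHI group on the
#' direction's hemisphere: group means, pooled t, Cohen's d, raw and
#' Bonferroni-corrected p. Analysis is complete-case per cell, so the
#' effective group sizes can vary across cells. Cells where either group
#' has fewer than two values are skipped and counted in the `skipped`
#' attribute.
#'
#' @param measures Long-format data frame with columns `subject_id`,
#'   `hemisphere`, `sulcus`, `measure`, `value`.
#' @param groups Group membership from [build_groups()].
#' @param alpha Significance level on the corrected p-values, default 0.05.
#' @param m Bonferroni family size, default 900.
#' @return Data frame of class `ihi_assoc`, sorted by direction, sulcus and
#'   measure, with columns `direction`, `sulcus`, `measure`, `n_ihi`,
#'   `n_non_ihi`, `mean_ihi`, `mean_non_ihi`, `t`, `df`, `cohens_d`,
#'   `p_raw`, `p_bonf`, `significant`. Attributes: `alpha`, `m`, `skipped`.
#' @export
run_association <- function(measures, groups, alpha = 0.05, m = 900) {
  need <- c("subject_id", "hemisphere", "sulcus", "measure", "value")
  miss <- setdiff(need, names(measures))
  if (length(miss)) {
    stop(sprintf("measures is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  check_category(measures$hemisphere, c("left", "right"), "hemisphere")
  out <- vector("list", 0)
  skipped <- 0L
  for (d in seq_len(nrow(.directions))) {
    dir <- .directions$direction[d]
    ihi_ids <- groups[[paste0("ihi_", .directions$ihi_side[d])]]
    non_ids <- groups$non_ihi
    hem <- measures[measures$hemisphere == .directions$hemisphere[d], ]
    if (!length(ihi_ids) || !length(non_ids) || !nrow(hem)) {
      next
    }
    cells <- unique(hem[, c("sulcus", "measure")])
    cells <- cells[order(cells$sulcus, cells$measure), ]
    for (i in seq_len(nrow(cells))) {
      cell <- hem[hem$sulcus == cells$sulcus[i] &
                  hem$measure == cells$measure[i], ]
      va <- cell$value[cell$subject_id %in% ihi_ids]
      vb <- cell$value[cell$subject_id %in% non_ids]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (length(va) < 2 || length(vb) < 2) {
        skipped <- skipped + 1L
        next
      }
      tt <- group_ttest(va, vb)
      d_hat <- if (tt$pooled_sd > 0) {
        (tt$mean_a - tt$mean_b) / tt$pooled_sd
      } else NaN
      out[[length(out) + 1]] <- data.frame(
        direction = dir, sulcus = cells$sulcus[i], measure = cells$measure[i],
        n_ihi = tt$n_a, n_non_ihi = tt$n_b,
        mean_ihi = tt$mean_a, mean_non_ihi = tt$mean_b,
        t = tt$t, df = tt$df, cohens_d = d_hat,
        p_raw = tt$p, p_bonf = bonferroni(tt$p, m),
        stringsAsFactors = FALSE
      )
    }
  }
  if (skipped > 0) {
    warning(sprintf("%d cell(s) skipped for insufficient group data", skipped),
            call. = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(
      direction = character(), sulcus = character(), measure = character(),
      n_ihi = integer(), n_non_ihi = integer(), mean_ihi = numeric(),
      mean_non_ihi = numeric(), t = numeric(), df = integer(),
      cohens_d = numeric(), p_raw = numeric(), p_bonf = numeric()
    )
  }
  res <- res[order(res$direction, res$sulcus, res$measure), ]
  rownames(res) <- NULL
  res$significant <- res$p_bonf < alpha
  attr(res, "alpha") <- alpha
  attr(res, "m") <- m
  attr(res, "skipped") <- skipped
  class(res) <- c("ihi_assoc", "data.frame")
  res
}
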