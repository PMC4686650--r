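# Synthetic cohort generator.
#
# Emulates the statistical structure of a large community sample of rated
# hippocampi: per-side ordinal grade marginals, a latent severity shared
# across criteria and (with attenuation) across hemispheres, a global
# criterion C0 coupled to the composite score with overlap confined to the
# partial band, a second-rater perturbation process, subject covariates,
# and sulcal morphometry with group-conditional mean shifts.
#
# Grades are drawn by a Gaussian copula: each criterion's latent value is a
# mixture of the side's severity and independent noise, and its normal
# quantile is cut at the marginal distribution's cumulative probabilities.

# Per-side grade marginals (percent). The right C1 row of the source
# distribution does not total 100; the residual mass is assigned to grade 0,
# the modal typical-anatomy grade.
.default_marginals <- list(
  left = list(
    c1 = c(`0` = 23, `0.5` = 44, `1` = 23, `1.5` = 8, `2` = 1),
    c2 = c(`0` = 18, `0.5` = 42, `1` = 28, `1.5` = 11, `2` = 1),
    c3 = c(`0` = 27, `0.5` = 40, `1` = 21, `1.5` = 10, `2` = 2),
    c4 = c(`0` = 97, `2` = 3),
    c5 = c(`0` = 59, `1` = 20, `2` = 20)
  ),
  right = list(
    c1 = c(`0` = 51, `0.5` = 28, `1` = 18, `1.5` = 3, `2` = 0),
    c2 = c(`0` = 9, `0.5` = 57, `1` = 29, `1.5` = 4, `2` = 0),
    c3 = c(`0` = 38, `0.5` = 39, `1` = 17, `1.5` = 5, `2` = 1),
    c4 = c(`0` = 98, `2` = 2),
    c5 = c(`0` = 85, `1` = 6, `2` = 9)
  )
)

# C0 given score: overlap between the reference classes is confined to the
# 3.5 band, so the accuracy-maximising threshold sits between 3.5 and 4.
.default_c0_rule <- list(
  low = c(0.97, 0.03, 0),    # score <= 3
  mid = c(0.35, 0.50, 0.15), # score == 3.5
  high = c(0, 0.26, 0.74)    # score >= 4
)

# Group-conditional sulcal effects: ipsilateral and contralateral mean
# shifts with pooled SDs back-computed from the means and standardised
# effect sizes they reproduce.
.default_sulcal_effects <- data.frame(
  direction = c(rep("leftIHI-leftHem", 12),
                rep("rightIHI-rightHem", 2), "rightIHI-leftHem"),
  sulcus = c("F.Cal.", "F.Cal.", "F.Cal.", "F.Coll.", "F.Coll.",
             "S.Call.", "S.Call.", "S.Call.", "S.Call.", "S.Call.",
             "S.Li.", "S.O.T.lat.ant.",
             "F.Coll.", "S.C.", "F.Cal."),
  measure = c("gm_thickness", "opening", "surface", "max_depth", "opening",
              "max_depth", "mean_depth", "length", "opening", "surface",
              "mean_depth", "opening",
              "max_depth", "gm_thickness", "opening"),
  mean_ihi = c(3.7875, 1.8468, 2127.1, 26.560, 1.6391,
               11.263, 6.7289, 100.59, 4.1009, 932.01,
               10.014, 3.1394,
               26.205, 3.6417, 1.8009),
  mean_non_ihi = c(3.8853, 1.5848, 2362.0, 21.384, 1.5341,
                   12.520, 7.2136, 111.48, 3.5540, 1113.0,
                   9.5270, 2.8511,
                   21.436, 3.7501, 1.5848),
  d = c(-0.33, 0.5, -0.36, 0.36, 0.29,
        -0.38, -0.45, -0.31, 0.38, -0.42,
        0.24, 0.22,
        0.35, -0.32, 0.46),
  stringsAsFactors = FALSE
)
.default_sulcal_effects$sd <-
  (.default_sulcal_effects$mean_ihi - .default_sulcal_effects$mean_non_ihi) /
  .default_sulcal_effects$d

# Baseline (no-effect) distribution per measure, on plausible scales.
.default_sulcal_baseline <- data.frame(
  measure = c("surface", "max_depth", "mean_depth", "opening",
              "gm_thickness", "length"),
  mean = c(1500, 18, 9, 2.5, 3.6, 80),
  sd = c(500, 5, 2, 0.8, 0.3, 25),
  stringsAsFactors = FALSE
)

#' Configuration of the synthetic cohort generator
#'
#' Bundles every tunable of the generator with defaults calibrated to the
#' published summary tables of a large community study: per-side grade
#' marginals, the cross-side latent correlation, the within-side
#' criterion-severity loading, the score-to-C0 rule, the second-rater
#' perturbation rate, covariate splits and group-conditional sulcal
#' effects.
#'
#' @param n_subjects Number of subjects, default 2008.
#' @param seed Base random seed, default 1.
#' @param grade_marginals Named list `left`/`right` of per-criterion
#'   probability (or percentage) vectors named by grade value.
#' @param side_coupling Correlation of the latent severity across
#'   hemispheres, in `[0, 1)`; default 0.9.
#' @param criterion_loading Loading of each criterion's latent value on the
#'   side severity, in `[0, 1]`; default 0.5.
#' @param c0_rule List with probability vectors `low` (score <= 3), `mid`
#'   (score 3.5) and `high` (score >= 4) over C0 = 0, 1, 2.
#' @param rater_error Adjacent-grade perturbation probability for the
#'   simulated second rating, default 0.1.
#' @param sex_split Named probabilities for `F`/`M`.
#' @param handedness_split Named probabilities for `right`/`left`/`both`.
#' @param handedness_missing Probability that handedness is unrecorded.
#' @param sulcal_effects Data frame of group-conditional effects
#'   (`direction`, `sulcus`, `measure`, `mean_ihi`, `mean_non_ihi`, `sd`).
#' @param sulcal_baseline Data frame of per-measure baseline `mean` and
#'   `sd` for cells without a configured effect.
#' @param threshold Score threshold used when classifying subjects for the
#'   sulcal simulation, default 3.75.
#' @return List of class `ihi_generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 100, seed = 7)
generator_config <- function(n_subjects = 2008,
                             seed = 1,
                             grade_marginals = .default_marginals,
                             side_coupling = 0.9,
                             criterion_loading = 0.5,
                             c0_rule = .default_c0_rule,
                             rater_error = 0.1,
                             sex_split = c(F = 1029, M = 978) / 2007,
                             handedness_split = c(right = 1740, left = 218,
                                                  both = 14) / 1972,
                             handedness_missing = 36 / 2008,
                             sulcal_effects = .default_sulcal_effects,
                             sulcal_baseline = .default_sulcal_baseline,
                             threshold = 3.75) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (side_coupling < 0 || side_coupling >= 1) {
    stop("side_coupling must lie in [0, 1)", call. = FALSE)
  }
  if (criterion_loading < 0 || criterion_loading > 1) {
    stop("criterion_loading must lie in [0, 1]", call. = FALSE)
  }
  if (rater_error < 0 || rater_error >= 1) {
    stop("rater_error must lie in [0, 1)", call. = FALSE)
  }
  for (sd_ in c("left", "right")) {
    for (cr in c("c1", "c2", "c3", "c4", "c5")) {
      p <- grade_marginals[[sd_]][[cr]]
      if (is.null(p) || any(p < 0) || sum(p) <= 0) {
        stop(sprintf("configuration error: invalid %s marginal for %s side",
                     cr, sd_), call. = FALSE)
      }
      g <- as.numeric(names(p))
      if (anyNA(g) || !all(g %in% criterion_levels(cr))) {
        stop(sprintf("configuration error: %s marginal names must be grades on %s's grid",
                     cr, toupper(cr)), call. = FALSE)
      }
      grade_marginals[[sd_]][[cr]] <- p / sum(p)
    }
  }
  for (band in c("low", "mid", "high")) {
    q <- c0_rule[[band]]
    if (is.null(q) || length(q) != 3 || any(q < 0) || sum(q) <= 0) {
      stop("configuration error: c0_rule bands must be probability vectors over C0 = 0, 1, 2",
           call. = FALSE)
    }
    c0_rule[[band]] <- q / sum(q)
  }
  if (any(sulcal_effects$sd <= 0) || any(sulcal_baseline$sd <= 0)) {
    stop("configuration error: sulcal SDs must be strictly positive",
         call. = FALSE)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), seed = as.integer(seed),
      grade_marginals = grade_marginals, side_coupling = side_coupling,
      criterion_loading = criterion_loading, c0_rule = c0_rule,
      rater_error = rater_error, sex_split = sex_split / sum(sex_split),
      handedness_split = handedness_split / sum(handedness_split),
      handedness_missing = handedness_missing,
      sulcal_effects = sulcal_effects, sulcal_baseline = sulcal_baseline,
      threshold = threshold
    ),
    class = "ihi_generator_config"
  )
}

#' @keywords internal
sample_c0 <- function(score, rule) {
  band <- ifelse(score <= 3, "low", ifelse(score >= 4, "high", "mid"))
  u <- stats::runif(length(score))
  vapply(seq_along(score), function(i) {
    q <- cumsum(rule[[band[i]]])
    c(0, 1, 2)[findInterval(u[i], q) + 1L][1]
  }, numeric(1))
}

#' Generate a synthetic rated cohort
#'
#' Draws, per subject, a bivariate-normal latent severity (one per
#' hemisphere, correlated by `side_coupling`), then per criterion a latent
#' value loading on that severity, cut at the configured grade marginals
#' (Gaussian copula). The composite score is the sum of grades and the
#' global criterion C0 is drawn from the score band rule. Covariates (sex,
#' age, handedness) are drawn independently.
#'
#' @param config A [generator_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#' @return List of class `ihi_cohort` with elements `ratings` (data frame:
#'   `subject_id`, `side`, `c0`, `c1` ... `c5`, `score`) and `covariates`
#'   (data frame: `subject_id`, `sex`, `age_years`, `handedness`).
#' @export
#' @examples
#' cohort <- generate_assessments(generator_config(n_subjects = 50))
#' head(cohort$ratings)
generate_assessments <- function(config = generator_config(), seed = NULL) {
  if (!inherits(config, "ihi_generator_config")) {
    stop("config must come from generator_config()", call. = FALSE)
  }
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- config$n_subjects
  ids <- sprintf("S%05d", seq_len(n))
  rho <- config$side_coupling
  z_left <- stats::rnorm(n)
  z_right <- rho * z_left + sqrt(1 - rho^2) * stats::rnorm(n)
  lat <- list(left = z_left, right = z_right)
  a <- config$criterion_loading
  ratings <- list()
  for (sd_ in c("left", "right")) {
    grades <- list()
    for (cr in c("c1", "c2", "c3", "c4", "c5")) {
      p <- config$grade_marginals[[sd_]][[cr]]
      cuts <- stats::qnorm(cumsum(p))
      x <- a * lat[[sd_]] + sqrt(1 - a^2) * stats::rnorm(n)
      idx <- findInterval(x, cuts[-length(cuts)]) + 1L
      grades[[cr]] <- as.numeric(names(p))[idx]
    }
    score <- grades$c1 + grades$c2 + grades$c3 + grades$c4 + grades$c5
    ratings[[sd_]] <- data.frame(
      subject_id = ids, side = sd_,
      c0 = sample_c0(score, config$c0_rule),
      c1 = grades$c1, c2 = grades$c2, c3 = grades$c3,
      c4 = grades$c4, c5 = grades$c5,
      score = score, stringsAsFactors = FALSE
    )
  }
  ratings <- rbind(ratings$left, ratings$right)
  ratings <- ratings[order(ratings$subject_id, ratings$side), ]
  rownames(ratings) <- NULL
  sex <- sample(names(config$sex_split), n, replace = TRUE,
                prob = config$sex_split)
  age <- round(pmin(17.2, pmax(12.9, stats::rnorm(n, 14.5, 0.4))), 1)
  hand <- sample(names(config$handedness_split), n, replace = TRUE,
                 prob = config$handedness_split)
  hand[stats::runif(n) < config$handedness_missing] <- NA
  covariates <- data.frame(
    subject_id = ids, sex = sex, age_years = age, handedness = hand,
    stringsAsFactors = FALSE
  )
  structure(list(ratings = ratings, covariates = covariates,
                 config = config),
            class = "ihi_cohort")
}

#' @export
print.ihi_cohort <- function(x, ...) {
  cat(sprintf("Synthetic IHI cohort: %d subjects (%d rated hippocampi)\n",
              nrow(x$covariates), nrow(x$ratings)))
  invisible(x)
}

#' Simulate a second rating of the same series
#'
#' Perturbs each grade (C0--C5) independently with probability `epsilon` to
#' an adjacent value on the criterion's grid (moving inward at the ends),
#' emulating a second rater or session. With `epsilon = 0` the copy is
#' identical and every kappa equals 1; as `epsilon` grows agreement decays
#' towards the chance level.
#'
#' @param ratings Ratings data frame (from an `ihi_cohort` or read from
#'   file) with grade columns `c0` ... `c5`.
#' @param epsilon Perturbation probability per grade, in `[0, 1)`.
#' @param seed Random seed, default 1.
#' @return Ratings data frame of the same shape with perturbed grades and
#'   recomputed scores.
#' @export
generate_rater_pair <- function(ratings, epsilon = 0.1, seed = 1) {
  if (epsilon < 0 || epsilon >= 1) {
    stop("epsilon must lie in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  out <- ratings
  for (cr in c("c0", "c1", "c2", "c3", "c4", "c5")) {
    if (!cr %in% names(out)) next
    lv <- criterion_levels(cr)
    g <- out[[cr]]
    idx <- match(g, lv)
    hit <- stats::runif(length(g)) < epsilon & !is.na(idx)
    step <- sample(c(-1L, 1L), length(g), replace = TRUE)
    new_idx <- idx + step
    new_idx[new_idx < 1L] <- 2L
    new_idx[new_idx > length(lv)] <- length(lv) - 1L
    idx[hit] <- new_idx[hit]
    out[[cr]] <- lv[idx]
  }
  if (all(c("c1", "c2", "c3", "c4", "c5", "score") %in% names(out))) {
    out$score <- out$c1 + out$c2 + out$c3 + out$c4 + out$c5
  }
  out
}

#' Generate synthetic sulcal morphometry
#'
#' Draws one value per (subject, hemisphere, sulcus, measure) from normal
#' distributions. Cells with a configured effect use the group-conditional
#' means: subjects in the direction's IHI group get `mean_ihi`, all others
#' `mean_non_ihi` (the ipsilateral effect takes precedence for bilateral
#' IHI when both an ipsi- and a contralateral effect target the same cell).
#' All other cells share a per-measure baseline with no group difference.
#'
#' @param cohort An `ihi_cohort` from [generate_assessments()].
#' @param config Generator configuration; defaults to the cohort's own.
#' @param seed Random seed, default `config$seed + 1`.
#' @param sulci Sulcus labels to simulate; default the full 45-label
#'   nomenclature.
#' @param measures Measures to simulate; default all six.
#' @return Long-format data frame: `subject_id`, `hemisphere`, `sulcus`,
#'   `measure`, `value`.
#' @export
generate_sulcal_measures <- function(cohort, config = NULL, seed = NULL,
                                     sulci = sulcus_nomenclature(),
                                     measures = sulcal_measures()) {
  if (!inherits(cohort, "ihi_cohort")) {
    stop("cohort must come from generate_assessments()", call. = FALSE)
  }
  if (is.null(config)) config <- cohort$config
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  groups <- build_groups(cohort$ratings, config$threshold)
  ids <- cohort$covariates$subject_id
  n <- length(ids)
  in_ihi <- list(left = ids %in% groups$ihi_left,
                 right = ids %in% groups$ihi_right)
  eff <- merge(config$sulcal_effects, .directions, by = "direction")
  base <- config$sulcal_baseline
  out <- vector("list", 2 * length(sulci) * length(measures))
  k <- 0L
  for (hem in c("left", "right")) {
    for (su in sulci) {
      for (me in measures) {
        b <- base[base$measure == me, ]
        if (!nrow(b)) {
          stop(sprintf("configuration error: no baseline for measure '%s'", me),
               call. = FALSE)
        }
        mu <- rep(b$mean, n)
        sigma <- b$sd
        e <- eff[eff$hemisphere == hem & eff$sulcus == su & eff$measure == me, ]
        if (nrow(e)) {
          # ipsilateral effect first so it wins for bilateral IHI
          e <- e[order(e$ihi_side != hem), ]
          mu <- rep(e$mean_non_ihi[1], n)
          sigma <- e$sd[1]
          for (j in rev(seq_len(nrow(e)))) {
            mu[in_ihi[[e$ihi_side[j]]]] <- e$mean_ihi[j]
          }
        }
        k <- k + 1L
        out[[k]] <- data.frame(
          subject_id = ids, hemisphere = hem, sulcus = su, measure = me,
          value = stats::rnorm(n, mu, sigma), stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}
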