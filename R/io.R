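# CSV schemas and the end-to-end pipeline.
#
# Three plain-CSV schemas (UTF-8, comma separators, "." decimals, header
# row): per-hippocampus ratings, subject covariates, and long-format sulcal
# measures. Grades are written as decimal strings on the 0.5 grid so that a
# write/read round trip is lossless.

.rating_grade_cols <- c("c0", "c1", "c2", "c3", "c4", "c5")

#' @keywords internal
check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: schema mismatch, missing column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a per-hippocampus ratings table
#'
#' One row per subject x side with the global criterion `c0` and either the
#' five criterion grades `c1` ... `c5` or raw observation columns from
#' which they are computed (`c1a_mm`, `c1b_mm`, `c1_angle_deg`,
#' `c2_depth_relation`, `c2_verticality`, `c3a_mm`, `c3b_mm`, `th_state`,
#' `c4_bulging`, `c5_crossing`). Grades must lie on each criterion's grid;
#' offending rows are reported with their line numbers. The composite
#' score is (re)computed from the grades.
#'
#' @param path Path to a CSV file.
#' @return Validated ratings data frame with a `score` column.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "side", "c0"), "ratings")
  check_category(df$side, c("left", "right"), "side")
  dup <- duplicated(df[, c("subject_id", "side")])
  if (any(dup)) {
    stop(sprintf("ratings: duplicated (subject_id, side) at row(s) %s",
                 paste(which(dup) + 1L, collapse = ", ")), call. = FALSE)
  }
  for (cr in setdiff(.rating_grade_cols, names(df))) df[[cr]] <- NA_real_
  # derive grades from raw observations where the grade is absent
  if (all(c("c1a_mm", "c1b_mm", "c1_angle_deg") %in% names(df))) {
    need <- is.na(df$c1) & !is.na(df$c1a_mm)
    if (any(need)) {
      df$c1[need] <- grade_c1(
        classify_roundness(df$c1a_mm[need], df$c1b_mm[need]),
        classify_verticality(df$c1_angle_deg[need])
      )
    }
  }
  if (all(c("c2_depth_relation", "c2_verticality") %in% names(df))) {
    need <- is.na(df$c2) & !is.na(df$c2_depth_relation)
    if (any(need)) {
      df$c2[need] <- grade_c2(df$c2_depth_relation[need],
                              df$c2_verticality[need])
    }
  }
  if (all(c("c3a_mm", "c3b_mm", "th_state") %in% names(df))) {
    need <- is.na(df$c3) & !is.na(df$c3a_mm)
    if (any(need)) {
      df$c3[need] <- grade_c3(exposure_relation(df$c3a_mm[need], df$c3b_mm[need]),
                              df$th_state[need])
    }
  }
  if ("c4_bulging" %in% names(df)) {
    need <- is.na(df$c4) & !is.na(df$c4_bulging)
    if (any(need)) df$c4[need] <- grade_c4(as.logical(df$c4_bulging[need]))
  }
  if ("c5_crossing" %in% names(df)) {
    need <- is.na(df$c5) & !is.na(df$c5_crossing)
    if (any(need)) df$c5[need] <- grade_c5(df$c5_crossing[need])
  }
  errs <- character()
  for (cr in .rating_grade_cols) {
    lv <- criterion_levels(cr)
    bad <- which(!is.na(df[[cr]]) & !(df[[cr]] %in% lv))
    if (length(bad)) {
      errs <- c(errs, sprintf("row %d: %s = %s is off the %s grid {%s}",
                              bad + 1L, cr, df[[cr]][bad], toupper(cr),
                              paste(lv, collapse = ", ")))
    }
  }
  if (length(errs)) {
    stop(paste(c("ratings: invalid grade value(s):", errs), collapse = "\n  "),
         call. = FALSE)
  }
  complete <- !is.na(df$c1) & !is.na(df$c2) & !is.na(df$c3) &
    !is.na(df$c4) & !is.na(df$c5)
  df$score <- NA_real_
  if (any(complete)) {
    df$score[complete] <- ihi_score(df$c1[complete], df$c2[complete],
                                    df$c3[complete], df$c4[complete],
                                    df$c5[complete])
  }
  df
}

#' Read a subject covariates table
#'
#' Columns `subject_id`, `sex` (`F`/`M`), `age_years`, `handedness`
#' (`right`/`left`/`both`; may be empty).
#'
#' @param path Path to a CSV file.
#' @return Validated covariates data frame.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  check_columns(df, c("subject_id", "sex", "age_years", "handedness"),
                "covariates")
  check_category(df$sex, c("F", "M"), "sex")
  check_category(df$handedness, c("right", "left", "both"), "handedness")
  if (any(duplicated(df$subject_id))) {
    stop("covariates: duplicated subject_id", call. = FALSE)
  }
  df
}

#' Read a long-format sulcal measures table
#'
#' Columns `subject_id`, `hemisphere` (`left`/`right`), `sulcus`,
#' `measure`, `value`; one row per measurement, unique per key.
#'
#' @param path Path to a CSV file.
#' @return Validated measures data frame.
#' @export
read_sulcal <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "hemisphere", "sulcus", "measure", "value"),
                "sulcal measures")
  check_category(df$hemisphere, c("left", "right"), "hemisphere")
  check_category(df$measure, sulcal_measures(), "measure")
  key <- df[, c("subject_id", "hemisphere", "sulcus", "measure")]
  if (any(duplicated(key))) {
    stop("sulcal measures: duplicated (subject, hemisphere, sulcus, measure)",
         call. = FALSE)
  }
  if (any(!is.finite(df$value))) {
    stop("sulcal measures: non-finite value(s)", call. = FALSE)
  }
  df
}

#' @keywords internal
format_grade <- function(x) {
  ifelse(is.na(x), "", ifelse(x == floor(x), sprintf("%d", as.integer(x)),
                              sprintf("%.1f", x)))
}

#' Write a ratings table
#'
#' Grades and scores are serialised as decimal strings on the 0.5 grid so
#' the round trip through [read_ratings()] is exact.
#'
#' @param ratings Ratings data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  out <- ratings
  for (cr in intersect(c(.rating_grade_cols, "score"), names(out))) {
    out[[cr]] <- format_grade(out[[cr]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a covariates table
#' @param covariates Covariates data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sulcal measures table
#' @param measures Long-format measures data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_sulcal <- function(measures, path) {
  utils::write.csv(measures, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' @param ratings,covariates,sulcal Optional input CSV paths. When
#'   `ratings` is `NULL` a synthetic cohort is generated instead.
#' @param output_dir Directory for the report bundle.
#' @param threshold `"fit"` (default) to fit the score threshold against
#'   C0, or a fixed numeric override.
#' @param alpha Significance level, default 0.05.
#' @param bonferroni_m Correction family size, default 900.
#' @param seed Random seed, default 1.
#' @param generator [generator_config()] used when simulating.
#' @param simulate_sulcal Whether to simulate sulcal measures when no
#'   `sulcal` path is given, default `FALSE`.
#' @return List of class `ihi_pipeline_config`.
#' @export
pipeline_config <- function(ratings = NULL, covariates = NULL, sulcal = NULL,
                            output_dir = "ihi_report", threshold = "fit",
                            alpha = 0.05, bonferroni_m = 900, seed = 1,
                            generator = generator_config(seed = seed),
                            simulate_sulcal = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (bonferroni_m < 1) stop("bonferroni_m must be >= 1", call. = FALSE)
  if (!identical(threshold, "fit") && !is.numeric(threshold)) {
    stop("threshold must be \"fit\" or a number", call. = FALSE)
  }
  structure(
    list(ratings = ratings, covariates = covariates, sulcal = sulcal,
         output_dir = output_dir, threshold = threshold, alpha = alpha,
         bonferroni_m = bonferroni_m, seed = seed, generator = generator,
         simulate_sulcal = simulate_sulcal),
    class = "ihi_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; generator
#' sub-keys mirror [generator_config()].
#'
#' @param path Path to a YAML file.
#' @return An `ihi_pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator
  if (is.null(gen_args)) gen_args <- list()
  if (is.null(gen_args$seed) && !is.null(y$seed)) gen_args$seed <- y$seed
  y$generator <- do.call(generator_config, gen_args)
  do.call(pipeline_config, y)
}

#' @keywords internal
write_table_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the inputs, fits or applies the score threshold,
#' and writes the report bundle: C0 frequency tables per side, the left x
#' right co-occurrence table, side/sex/handedness comparisons, per-criterion
#' grade distributions, threshold-based frequencies under both denominators,
#' the sulcal association table when measures are available, and a
#' provenance JSON (seed, package version, row counts). Outputs are
#' deterministic given inputs and configuration.
#'
#' @param config An [pipeline_config()] object (or YAML path).
#' @return Invisibly, a list with the in-memory results and the output
#'   file paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "ihi_pipeline_config")) {
    stop("config must come from pipeline_config()", call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- NULL
  if (is.null(config$ratings)) {
    cohort <- stage("simulate", generate_assessments(config$generator,
                                                     seed = config$seed))
    ratings <- cohort$ratings
    covariates <- cohort$covariates
  } else {
    ratings <- stage("read_ratings", read_ratings(config$ratings))
    covariates <- if (!is.null(config$covariates)) {
      stage("read_covariates", read_covariates(config$covariates))
    } else NULL
  }

  measures <- NULL
  if (!is.null(config$sulcal)) {
    measures <- stage("read_sulcal", read_sulcal(config$sulcal))
  } else if (config$simulate_sulcal) {
    if (is.null(cohort)) {
      stop("pipeline stage 'simulate_sulcal' failed: sulcal simulation requires a simulated cohort",
           call. = FALSE)
    }
    measures <- stage("simulate_sulcal",
                      generate_sulcal_measures(cohort, config$generator,
                                               seed = config$seed + 1L))
  }

  thr <- stage("threshold", {
    if (identical(config$threshold, "fit")) {
      optimal_threshold(ratings$score, ratings$c0)
    } else {
      list(threshold = config$threshold, accuracy = NA_real_,
           n = sum(!is.na(ratings$score)))
    }
  })

  results <- list(threshold = thr)
  paths <- character()

  results$c0_left <- stage("prevalence", c0_frequency_table(ratings, "left"))
  results$c0_right <- c0_frequency_table(ratings, "right")
  freq <- rbind(cbind(side = "left", results$c0_left),
                cbind(side = "right", results$c0_right))
  paths["c0_frequency"] <- write_table_csv(freq, config$output_dir,
                                           "c0_frequency")

  results$cooccurrence <- stage("cooccurrence", cooccurrence_table(ratings))
  paths["cooccurrence"] <- write_table_csv(results$cooccurrence,
                                           config$output_dir, "cooccurrence")

  results$side_test <- stage("side_comparison", side_comparison(ratings))
  comparisons <- data.frame(
    comparison = "left_vs_right", side = "both",
    chi2 = results$side_test$chi2, df = results$side_test$df,
    p = results$side_test$p, excluded = 0L, stringsAsFactors = FALSE
  )
  if (!is.null(covariates)) {
    for (cov in intersect(c("sex", "handedness"), names(covariates))) {
      for (sd_ in c("left", "right")) {
        ct <- stage(paste0(cov, "_comparison"),
                    covariate_comparison(ratings, covariates, cov, sd_))
        comparisons <- rbind(comparisons, data.frame(
          comparison = cov, side = sd_, chi2 = ct$chi2, df = ct$df, p = ct$p,
          excluded = attr(ct, "excluded"), stringsAsFactors = FALSE
        ))
      }
    }
  }
  results$comparisons <- comparisons
  paths["comparisons"] <- write_table_csv(comparisons, config$output_dir,
                                          "c0_comparisons")

  results$criterion_distribution <- stage("criterion_distribution",
                                          criterion_distribution(ratings))
  paths["criterion_frequencies"] <- write_table_csv(
    results$criterion_distribution$frequencies, config$output_dir,
    "criterion_frequencies")
  paths["criterion_tests"] <- write_table_csv(
    results$criterion_distribution$tests, config$output_dir,
    "criterion_side_tests")

  results$threshold_frequencies <- stage("threshold_frequencies", {
    rbind(
      cbind(mode = "exclude_partial",
            threshold_frequency_table(ratings, thr$threshold,
                                      mode = "exclude_partial")),
      cbind(mode = "classify_all",
            threshold_frequency_table(ratings, thr$threshold,
                                      mode = "classify_all"))
    )
  })
  paths["threshold_frequencies"] <- write_table_csv(
    results$threshold_frequencies, config$output_dir, "threshold_frequencies")

  if (!is.null(measures)) {
    groups <- stage("build_groups", build_groups(ratings, thr$threshold))
    results$association <- stage("association",
                                 suppressWarnings(run_association(
                                   measures, groups,
                                   alpha = config$alpha,
                                   m = config$bonferroni_m)))
    paths["association"] <- write_table_csv(
      as.data.frame(results$association), config$output_dir, "association")
  }

  provenance <- list(
    package = "ihiscore",
    version = as.character(utils::packageVersion("ihiscore")),
    seed = config$seed,
    threshold = thr$threshold,
    simulated = is.null(config$ratings),
    n_subjects = length(unique(ratings$subject_id)),
    n_hippocampi = nrow(ratings),
    n_sulcal_rows = if (is.null(measures)) 0L else nrow(measures),
    alpha = config$alpha,
    bonferroni_m = config$bonferroni_m
  )
  prov_path <- file.path(config$output_dir, "provenance.json")
  jsonlite::write_json(provenance, prov_path, auto_unbox = TRUE, pretty = TRUE)
  paths["provenance"] <- prov_path

  invisible(list(results = results, paths = paths, config = config))
}
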