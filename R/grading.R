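# Visual grading scale for incomplete hippocampal inversion (IHI).
#
# Five individual criteria (C1-C5) are rated per hippocampus on coronal
# T1-weighted slices; their sum is the composite IHI score (0-10 on a 0.5
# grid). A global criterion C0 (0 = no, 1 = partial, 2 = total IHI) serves
# as the reference when fitting a score threshold for binary classification.

#' Permitted grade values per criterion
#'
#' The ordinal codomain of each rating criterion. C1--C3 are graded on a
#' half-point grid from 0 to 2, C4 is binary (normal vs. thickened
#' subiculum, coded 0/2), C5 takes 0, 1 or 2, and the global criterion C0
#' takes 0 (no IHI), 1 (partial) or 2 (total).
#'
#' @param criterion One of `"c0"` ... `"c5"`.
#' @return Numeric vector of permitted grade values, in increasing order.
#' @export
#' @examples
#' criterion_levels("c1")
#' criterion_levels("c4")
criterion_levels <- function(criterion) {
  criterion <- match.arg(tolower(criterion), c("c0", "c1", "c2", "c3", "c4", "c5"))
  switch(criterion,
    c0 = c(0, 1, 2),
    c1 = ,
    c2 = ,
    c3 = seq(0, 2, by = 0.5),
    c4 = c(0, 2),
    c5 = c(0, 1, 2)
  )
}

#' @keywords internal
check_grade <- function(x, criterion) {
  lv <- criterion_levels(criterion)
  bad <- !is.na(x) & !(x %in% lv)
  if (any(bad)) {
    stop(sprintf(
      "invalid %s grade(s): %s (permitted: %s)",
      toupper(criterion), paste(unique(x[bad]), collapse = ", "),
      paste(lv, collapse = ", ")
    ), call. = FALSE)
  }
  x
}

#' Classify hippocampal body roundness from segment lengths
#'
#' The hippocampal body in coronal view is compared along two orthogonal
#' segments: its width (parallel to the ventral cornu Ammonis/subiculum) and
#' its height. A body wider than tall is *flat*, one of equal extent *round*,
#' and one taller than wide *oval*. Visual rating treats near-equal segments
#' as equal; `rel_tolerance` quantifies that as a fraction of the larger
#' segment.
#'
#' @param width_mm,height_mm Segment lengths in mm (strictly positive).
#' @param rel_tolerance Relative tolerance for calling the two segments
#'   equal, as a fraction of the larger one. Default 0.1.
#' @return Character vector in `{"flat", "round", "oval"}`.
#' @export
#' @examples
#' classify_roundness(10, 5)  # flat
#' classify_roundness(7, 7)   # round
classify_roundness <- function(width_mm, height_mm, rel_tolerance = 0.1) {
  if (any(!is.finite(width_mm)) || any(!is.finite(height_mm)) ||
      any(width_mm <= 0) || any(height_mm <= 0)) {
    stop("invalid geometry: segment lengths must be finite and strictly positive",
         call. = FALSE)
  }
  if (rel_tolerance < 0 || rel_tolerance >= 1) {
    stop("rel_tolerance must lie in [0, 1)", call. = FALSE)
  }
  tol <- rel_tolerance * pmax(width_mm, height_mm)
  ifelse(abs(width_mm - height_mm) <= tol, "round",
    ifelse(width_mm > height_mm, "flat", "oval")
  )
}

#' Classify segment verticality from its angle to the horizontal
#'
#' @param angle_deg Angle of the width segment from the horizontal, in
#'   degrees, within `[0, 90]`.
#' @param tol Angular tolerance in degrees; the segment is *horizontal* up to
#'   `tol` and *vertical* from `90 - tol`. Default 10.
#' @return Character vector in `{"horizontal", "oblique", "vertical"}`.
#' @export
#' @examples
#' classify_verticality(c(0, 45, 85))
classify_verticality <- function(angle_deg, tol = 10) {
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0) || any(angle_deg > 90)) {
    stop("invalid geometry: angle must lie in [0, 90] degrees", call. = FALSE)
  }
  if (tol <= 0 || tol >= 45) stop("tol must lie in (0, 45)", call. = FALSE)
  ifelse(angle_deg <= tol, "horizontal",
    ifelse(angle_deg >= 90 - tol, "vertical", "oblique")
  )
}

#' Bin the subiculum exposure ratio into an ordinal relation
#'
#' Criterion C3 compares the length of subiculum not covered by the dentate
#' gyrus (`c3a_mm`) with the covered ventral part (`c3b_mm`). The rating
#' scale uses five qualitative relations; this helper quantifies them by
#' binning the ratio `c3a/c3b` at four cut points. A ratio of zero (the
#' uncovered part is not visible) always maps to `much_less`.
#'
#' @param c3a_mm Uncovered subiculum length, mm (`>= 0`).
#' @param c3b_mm Covered length, mm (`> 0`).
#' @param bin_edges Four strictly increasing ratio cut points. The defaults
#'   (0.25, 0.8, 1.25, 4) are symmetric on the log scale around 1.
#' @return Character vector in
#'   `{"much_less", "less", "equal", "greater", "much_greater"}`.
#' @export
#' @examples
#' exposure_relation(0, 5)   # much_less
#' exposure_relation(5, 5)   # equal
exposure_relation <- function(c3a_mm, c3b_mm,
                              bin_edges = c(0.25, 0.8, 1.25, 4)) {
  if (length(bin_edges) != 4 || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be four strictly increasing cut points", call. = FALSE)
  }
  if (any(!is.finite(c3a_mm)) || any(c3a_mm < 0) ||
      any(!is.finite(c3b_mm)) || any(c3b_mm <= 0)) {
    stop("invalid geometry: c3a must be >= 0 and c3b > 0", call. = FALSE)
  }
  r <- c3a_mm / c3b_mm
  lv <- c("much_less", "less", "equal", "greater", "much_greater")
  lv[findInterval(r, bin_edges) + 1L]
}

# Grading tables. Rows/columns follow the published evaluation grids; the
# flat/vertical cell of C1 is anatomically contradictory and not applicable.
.c1_table <- matrix(
  c(0, 0.5, NA,
    0.5, 1, 2,
    1, 1.5, 2),
  nrow = 3, byrow = TRUE,
  dimnames = list(
    c("flat", "round", "oval"),
    c("horizontal", "oblique", "vertical")
  )
)

.c2_table <- matrix(
  c(0, 0.5, 0.5,
    1, 1, 1.5,
    1, 1.5, 2),
  nrow = 3, byrow = TRUE,
  dimnames = list(
    c("CS_less_H", "CS_equal_H", "CS_greater_H"),
    c("horizontal", "oblique", "vertical")
  )
)

.c3_table <- matrix(
  c(2, 1, 0.5, 0, 0,
    2, 1.5, 1, 0.5, 0),
  nrow = 2, byrow = TRUE,
  dimnames = list(
    c("emptied", "filled"),
    c("much_less", "less", "equal", "greater", "much_greater")
  )
)

#' @keywords internal
check_category <- function(x, levels, what) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf(
      "invalid %s: %s (expected one of: %s)",
      what, paste(unique(x[bad]), collapse = ", "),
      paste(levels, collapse = ", ")
    ), call. = FALSE)
  }
  x
}

#' Grade criterion C1: roundness and verticality of the hippocampal body
#'
#' A flat horizontal body is typical (grade 0); rounder and more vertical
#' bodies grade higher, up to 2 for a vertical round or oval body. A flat
#' vertical body is anatomically contradictory and raises an error.
#'
#' @param roundness `"flat"`, `"round"` or `"oval"`.
#' @param verticality `"horizontal"`, `"oblique"` or `"vertical"`.
#' @return Numeric grade in `{0, 0.5, 1, 1.5, 2}`.
#' @export
#' @examples
#' grade_c1("flat", "horizontal")  # 0
#' grade_c1("oval", "vertical")    # 2
grade_c1 <- function(roundness, verticality) {
  check_category(roundness, rownames(.c1_table), "roundness")
  check_category(verticality, colnames(.c1_table), "verticality")
  g <- .c1_table[cbind(roundness, verticality)]
  if (any(is.na(g) & !is.na(roundness) & !is.na(verticality))) {
    stop("not applicable: a flat vertical hippocampal body has no C1 grade",
         call. = FALSE)
  }
  unname(g)
}

#' Grade criterion C2: depth and verticality of the collateral sulcus
#'
#' The collateral sulcus (CS) is compared with the lateral limit of the
#' hippocampus (H): a sulcus that does not reach it grades 0--1, one that
#' crosses it grades 1--2, with more vertical sulci grading higher.
#'
#' @param depth_relation `"CS_less_H"`, `"CS_equal_H"` or `"CS_greater_H"`.
#' @param verticality `"horizontal"`, `"oblique"` or `"vertical"`.
#' @return Numeric grade in `{0, 0.5, 1, 1.5, 2}`.
#' @export
#' @examples
#' grade_c2("CS_greater_H", "vertical")  # 2
grade_c2 <- function(depth_relation, verticality) {
  check_category(depth_relation, rownames(.c2_table), "depth_relation")
  check_category(verticality, colnames(.c2_table), "verticality")
  unname(.c2_table[cbind(depth_relation, verticality)])
}

#' Grade criterion C3: medial positioning of the hippocampus
#'
#' Based on the exposure of the subiculum relative to the part covered by
#' the dentate gyrus, modulated by whether the temporal horn (TH) of the
#' lateral ventricle is emptied or filled by CSF. The two extreme relations
#' grade 2 and 0 regardless of the TH.
#'
#' @param exposure_relation One of `"much_less"`, `"less"`, `"equal"`,
#'   `"greater"`, `"much_greater"` (uncovered vs. covered length).
#' @param temporal_horn `"emptied"` or `"filled"`.
#' @return Numeric grade in `{0, 0.5, 1, 1.5, 2}`.
#' @export
#' @examples
#' grade_c3("much_less", "filled")  # 2
#' grade_c3("equal", "emptied")     # 0.5
grade_c3 <- function(exposure_relation, temporal_horn) {
  check_category(exposure_relation, colnames(.c3_table), "exposure_relation")
  check_category(temporal_horn, rownames(.c3_table), "temporal_horn")
  unname(.c3_table[cbind(temporal_horn, exposure_relation)])
}

#' Grade criterion C4: thickness of the subiculum
#'
#' @param bulging Logical; `TRUE` if the subiculum bulges upward (looks
#'   thickened).
#' @return Numeric grade: 2 if bulging, otherwise 0.
#' @export
grade_c4 <- function(bulging) {
  if (any(!is.na(bulging) & !is.logical(bulging))) {
    stop("bulging must be logical", call. = FALSE)
  }
  ifelse(bulging, 2, 0)
}

#' Grade criterion C5: sulci of the fusiform gyrus
#'
#' Whether the collateral or occipito-temporal sulcus is deep enough to
#' cross the level of the subiculum, and with what orientation.
#'
#' @param crossing `"none"`, `"oblique_crossing"` or `"vertical_crossing"`.
#' @return Numeric grade in `{0, 1, 2}`.
#' @export
grade_c5 <- function(crossing) {
  check_category(crossing, c("none", "oblique_crossing", "vertical_crossing"),
                 "crossing")
  unname(c(none = 0, oblique_crossing = 1, vertical_crossing = 2)[crossing])
}

#' Composite IHI score
#'
#' The sum of the five individual criterion grades, ranging from 0 (typical
#' hippocampus) to 10 (pronounced incomplete inversion) on a 0.5 grid.
#'
#' @param c1,c2,c3,c4,c5 Numeric grade vectors on each criterion's grid
#'   (recycled to a common length).
#' @return Numeric score vector in `[0, 10]`.
#' @export
#' @examples
#' ihi_score(1, 1.5, 0.5, 0, 1)  # 4
ihi_score <- function(c1, c2, c3, c4, c5) {
  check_grade(c1, "c1"); check_grade(c2, "c2"); check_grade(c3, "c3")
  check_grade(c4, "c4"); check_grade(c5, "c5")
  s <- c1 + c2 + c3 + c4 + c5
  if (any(is.na(s))) {
    stop("incomplete assessment: all five criterion grades are required",
         call. = FALSE)
  }
  s
}

#' Binary IHI classification of a hippocampus
#'
#' A hippocampus is classified as showing IHI when its composite score
#' strictly exceeds the threshold. Thresholds fitted by
#' [optimal_threshold()] are midpoints between attainable grid values, so
#' with the reference threshold 3.75 this reproduces the rule "IHI iff
#' score >= 4".
#'
#' @param score Numeric score vector in `[0, 10]`.
#' @param threshold Classification threshold; default 3.75.
#' @return Logical vector: `TRUE` for IHI.
#' @export
#' @examples
#' classify_ihi(c(3.5, 4))  # FALSE TRUE
classify_ihi <- function(score, threshold = 3.75) {
  if (any(!is.na(score) & (score < 0 | score > 10))) {
    stop("score must lie in [0, 10]", call. = FALSE)
  }
  score > threshold
}

#' Accuracy-maximising score threshold against the global criterion
#'
#' Fits the binary classification threshold on the composite IHI score using
#' the global criterion C0 as reference. Only hippocampi judged unambiguous
#' (C0 = 0, no IHI, or C0 = 2, total IHI) enter the fit; partial cases
#' (C0 = 1) are excluded. Candidate thresholds are the midpoints between
#' consecutive distinct observed scores; the one maximising classification
#' accuracy of the rule `score > threshold` is returned, ties broken towards
#' the smallest candidate.
#'
#' @param score Numeric composite scores.
#' @param c0 Global criterion grades in `{0, 1, 2}`, same length as `score`.
#' @return An object of class `ihi_threshold`: a list with elements
#'   `threshold`, `accuracy`, `n` (hippocampi used) and `candidates` (a
#'   data frame of all candidate thresholds with their accuracies).
#' @export
#' @examples
#' fit <- optimal_threshold(c(2, 3, 3.5, 4, 5), c(0, 0, 0, 2, 2))
#' fit$threshold  # 3.75
optimal_threshold <- function(score, c0) {
  if (length(score) != length(c0)) {
    stop("score and c0 must have the same length", call. = FALSE)
  }
  check_grade(c0, "c0")
  keep <- !is.na(score) & !is.na(c0) & c0 %in% c(0, 2)
  score <- score[keep]
  truth <- c0[keep] == 2
  if (!any(truth) || all(truth)) {
    stop(paste(
      "degenerate input: threshold fitting needs both C0 = 0 and C0 = 2",
      "hippocampi"
    ), call. = FALSE)
  }
  s <- sort(unique(score))
  if (length(s) < 2) {
    stop("degenerate input: all scores identical, no candidate thresholds",
         call. = FALSE)
  }
  cand <- (s[-length(s)] + s[-1]) / 2
  acc <- vapply(cand, function(t) mean((score > t) == truth), numeric(1))
  best <- cand[which.max(acc)] # which.max takes the first, i.e. smallest
  structure(
    list(
      threshold = best,
      accuracy = max(acc),
      n = length(score),
      candidates = data.frame(threshold = cand, accuracy = acc)
    ),
    class = "ihi_threshold"
  )
}

#' @export
print.ihi_threshold <- function(x, ...) {
  cat(sprintf(
    "IHI score threshold: %.4g (accuracy %.3f on %d hippocampi with C0 in {0, 2})\n",
    x$threshold, x$accuracy, x$n
  ))
  invisible(x)
}
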