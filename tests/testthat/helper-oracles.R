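# Independent brute-force oracles, written against the defining formulas
# and kept free of the package's own computational paths.

# Pearson chi-squared by explicit double loop over cells.
bf_chi2 <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Kappa from two rating vectors via the disagreement-weight definition
# kappa = 1 - sum(d * o) / sum(d * e), d_ij = (|i - j| / (k - 1))^power
# (power 0 treated as identity disagreement, i.e. plain kappa).
bf_kappa <- function(a, b, levels, weighting = "none") {
  k <- length(levels)
  o <- matrix(0, k, k)
  for (m in seq_along(a)) {
    i <- match(a[m], levels)
    j <- match(b[m], levels)
    o[i, j] <- o[i, j] + 1
  }
  o <- o / length(a)
  e <- outer(rowSums(o), colSums(o))
  d <- switch(weighting,
    none = 1 - diag(k),
    linear = abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1),
    quadratic = (outer(seq_len(k), seq_len(k), "-") / (k - 1))^2
  )
  1 - sum(d * o) / sum(d * e)
}

# Pooled two-sample t by direct formula evaluation.
bf_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Toy assessments table builder: one row per subject x side.
make_assessments <- function(subject_id, side, c0 = NA, score = NA, ...) {
  data.frame(subject_id = subject_id, side = side, c0 = c0, score = score,
             ..., stringsAsFactors = FALSE)
}

# Long reliability ratings for two raters x two sessions from a base grade
# vector and a perturbation function.
make_reliability <- function(base, criterion, perturb = identity) {
  out <- list()
  for (rater in c("CC", "FC")) {
    for (session in 1:2) {
      out[[length(out) + 1]] <- data.frame(
        item_id = seq_along(base), criterion = criterion,
        rater = rater, session = session,
        grade = perturb(base), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
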