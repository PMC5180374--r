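#' Bootstrap standard errors of transition probabilities
#'
#' Resamples spines (paired t0/t1 units) with replacement `R` times,
#' re-estimates the transition matrix for each resample in the original
#' cluster space, and reports per-cell standard errors: the square root
#' of the mean squared deviation of the resampled probabilities from the
#' original estimate, so the error is on the probability scale.
#'
#' @param W0,W1 Membership matrices of the original population in the
#'   fitted cluster space.
#' @param method `"crisp"` or `"qp"` estimator.
#' @param R Number of bootstrap resamples (default 1000).
#' @param seed Master seed; replicate `r` uses the r-th seed of a
#'   deterministic stream, so results are reproducible and extending `R`
#'   does not perturb earlier replicates.
#' @return k x k matrix of standard errors (entries in `[0, 1]`).
#' @export
bootstrap_se <- function(W0, W1, method = c("crisp", "qp"), R = 1000,
                         seed = 1) {
  method <- match.arg(method)
  if (R < 1) stop("R must be >= 1", call. = FALSE)
  W0 <- as.matrix(W0); W1 <- as.matrix(W1)
  est <- function(w0, w1) {
    if (method == "crisp") estimate_crisp(w0, w1) else estimate_qp(w0, w1)
  }
  T0 <- est(W0, W1)$T
  n <- nrow(W0)
  seeds <- replicate_seeds(seed, R)
  acc <- matrix(0, nrow(T0), ncol(T0))
  for (r in seq_len(R)) {
    idx <- with_seed(seeds[r], sample.int(n, n, replace = TRUE))
    Tr <- est(W0[idx, , drop = FALSE], W1[idx, , drop = FALSE])$T
    acc <- acc + (T0 - Tr)^2
  }
  sqrt(acc / R)
}

#' Relative change of cluster total weights between time points
#'
#' For each cluster, the relative change of its total membership weight
#' from t0 to t1: `(sum_s w1[s, n] - sum_s w0[s, n]) / sum_s w0[s, n]`.
#' Clusters with zero total t0 weight get the value 0 and are flagged in
#' the `"undefined"` attribute (the ratio is undefined there).
#'
#' @param W0,W1 Membership matrices of one population.
#' @return Length-k numeric vector with attribute `undefined` (logical).
#' @export
relative_change <- function(W0, W1) {
  t0 <- colSums(as.matrix(W0))
  t1 <- colSums(as.matrix(W1))
  undef <- t0 == 0
  out <- numeric(length(t0))
  out[!undef] <- (t1[!undef] - t0[!undef]) / t0[!undef]
  attr(out, "undefined") <- undef
  out
}

#' RDC: squared difference of relative distribution changes
#'
#' The statistic comparing how the shape-cluster distributions of two
#' populations change between t0 and t1: the sum over clusters of the
#' squared difference of the per-cluster relative changes.
#'
#' @param g1,g2 Each a list with membership matrices `W0` and `W1` for
#'   one population (in a shared cluster space with the same `k`).
#' @return Non-negative scalar; 0 on identical inputs; symmetric.
#' @export
rdc <- function(g1, g2) {
  c1 <- relative_change(g1$W0, g1$W1)
  c2 <- relative_change(g2$W0, g2$W1)
  if (length(c1) != length(c2)) {
    stop("populations must share one taxonomy (equal k)", call. = FALSE)
  }
  sum((c1 - c2)^2)
}

#' SMD: squared difference of transition matrices
#'
#' The statistic comparing the transition behaviour of two populations:
#' the sum of squared differences of corresponding transition-matrix
#' cells. Rows whose source cluster is empty in either model are excluded
#' by default because their (policy-filled) probabilities carry no
#' information.
#'
#' @param T1,T2 `transition_model` objects (or bare k x k matrices) in a
#'   shared cluster space.
#' @param exclude_empty Drop rows flagged as empty-source in either
#'   model (default `TRUE`; ignored for bare matrices).
#' @return Non-negative scalar; 0 on identical inputs; symmetric.
#' @export
smd <- function(T1, T2, exclude_empty = TRUE) {
  M1 <- if (inherits(T1, "transition_model")) T1$T else as.matrix(T1)
  M2 <- if (inherits(T2, "transition_model")) T2$T else as.matrix(T2)
  if (!all(dim(M1) == dim(M2))) {
    stop("transition matrices must have equal dimensions", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(M1))
  if (exclude_empty) {
    if (inherits(T1, "transition_model")) keep <- keep & !T1$empty_rows
    if (inherits(T2, "transition_model")) keep <- keep & !T2$empty_rows
  }
  sum((M1[keep, , drop = FALSE] - M2[keep, , drop = FALSE])^2)
}

# Fit the taxonomy on the pooled rows of two groups and estimate one
# transition model per group. X0/X1: per-spine feature rows; idx1/idx2:
# spine indices (with multiplicity) forming the two groups.
fit_two_group_models <- function(X0, X1, idx1, idx2, method, k, m,
                                 seed) {
  n1 <- length(idx1); n2 <- length(idx2)
  sel <- c(idx1, idx2)
  Xtrain <- rbind(X0[sel, , drop = FALSE], X1[sel, , drop = FALSE])
  fit <- if (method == "hier") fit_hierarchical(Xtrain, k)
         else fit_cmeans(Xtrain, k, m = m, seed = seed)
  ntot <- n1 + n2
  W0 <- fit$W[seq_len(ntot), , drop = FALSE]
  W1 <- fit$W[ntot + seq_len(ntot), , drop = FALSE]
  est <- function(w0, w1) {
    if (method == "hier") estimate_crisp(w0, w1) else estimate_qp(w0, w1)
  }
  g1 <- list(W0 = W0[seq_len(n1), , drop = FALSE],
             W1 = W1[seq_len(n1), , drop = FALSE])
  g2 <- list(W0 = W0[n1 + seq_len(n2), , drop = FALSE],
             W1 = W1[n1 + seq_len(n2), , drop = FALSE])
  list(model = fit$model, g1 = g1, g2 = g2,
       T1 = est(g1$W0, g1$W1), T2 = est(g2$W0, g2$W1))
}

two_group_stats <- function(fit2, statistic) {
  vapply(statistic, function(st) {
    switch(st,
           rdc = rdc(fit2$g1, fit2$g2),
           smd = smd(fit2$T1, fit2$T2),
           stop("unknown statistic: ", st, call. = FALSE))
  }, numeric(1))
}

#' Bootstrap hypothesis test comparing two spine populations
#'
#' Tests the null hypothesis that two populations share a common
#' distribution of shape changes. The groups are pooled; each of `R`
#' replicates draws two groups of the original sizes with replacement
#' from the pool, refits the shape taxonomy on the union of the drawn
#' groups (both time points), estimates one transition model per group,
#' and computes the test statistic(s). The p-value is
#' `(1 + #\{replicate >= observed\}) / (R + 1)`, with the observed value
#' computed the same way on the original groups.
#'
#' Feature reduction (split PCA) is fitted once on the pooled original
#' groups; replicates resample spines, so their reduced coordinates are
#' reused.
#'
#' @param A,B Spine tables for the two populations (shared schema).
#' @param statistic Character vector from `c("rdc", "smd")`; both may be
#'   requested in one call to share the replicate work.
#' @param method Clustering method: `"hier"` (crisp transition estimator)
#'   or `"cmeans"` (QP estimator).
#' @param k,m Clustering parameters.
#' @param R Number of bootstrap replicates (default 1000).
#' @param seed Master seed (deterministic replicate stream).
#' @param truncation Loading truncation for the feature reduction.
#' @return For a single statistic, an object of class `boot_test` (list
#'   with `statistic`, `observed`, `null` distribution, `p_value`, `R`,
#'   `seed`); for several, a named list of such objects.
#' @export
bootstrap_test <- function(A, B, statistic = c("rdc", "smd"),
                           method = c("hier", "cmeans"), k, m = 2,
                           R = 1000, seed = 1, truncation = 0.10) {
  method <- match.arg(method)
  statistic <- match.arg(statistic, several.ok = TRUE)
  fitp <- fit_split_pca(list(A, B), truncation = truncation)
  reduced <- reduce_features(list(A, B), fitp)
  r0 <- reduced[reduced$time == "t0", ]
  r1 <- reduced[reduced$time == "t1", ]
  key0 <- paste(r0$population, r0$spine_id)
  key1 <- paste(r1$population, r1$spine_id)
  r1 <- r1[match(key0, key1), ]
  X0 <- as.matrix(r0[, c("comp1", "comp2")])
  X1 <- as.matrix(r1[, c("comp1", "comp2")])
  nA <- nrow(A); nB <- nrow(B); n <- nA + nB
  # rows 1..nA belong to A, the rest to B (reduce_features keeps order)
  seeds <- replicate_seeds(seed, R + 1)
  observed <- two_group_stats(
    fit_two_group_models(X0, X1, seq_len(nA), nA + seq_len(nB),
                         method, k, m, seeds[1]), statistic)
  null <- matrix(NA_real_, R, length(statistic),
                 dimnames = list(NULL, statistic))
  for (r in seq_len(R)) {
    idx <- with_seed(seeds[r + 1], list(
      a = sample.int(n, nA, replace = TRUE),
      b = sample.int(n, nB, replace = TRUE)))
    fit2 <- fit_two_group_models(X0, X1, idx$a, idx$b, method, k, m,
                                 seeds[r + 1])
    null[r, ] <- two_group_stats(fit2, statistic)
  }
  results <- lapply(statistic, function(st) {
    obs <- observed[[st]]
    structure(list(
      statistic = st, observed = obs, null = null[, st],
      p_value = (1 + sum(null[, st] >= obs)) / (R + 1),
      R = R, seed = seed), class = "boot_test")
  })
  names(results) <- statistic
  if (length(results) == 1) results[[1]] else results
}

#' @export
print.boot_test <- function(x, ...) {
  cat("Bootstrap test (", toupper(x$statistic), "): observed = ",
      format(x$observed, digits = 4), ", p = ",
      format(x$p_value, digits = 4), " (R = ", x$R, ")\n", sep = "")
  invisible(x)
}
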