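default_loading_map <- function() {
  nm <- descriptor_schema()$names
  base <- c(length = 1.25, hw = 0.74, mwl = 0.59, mw = 0.84, nw = 0.49,
            foot = 0.85, circumference = 4.6, area = 0.73, wlr = 0.70,
            lwr = 1.90, lar = 1.85)
  size <- c(length = 0.20, hw = 0, mwl = 0, mw = 0, nw = 0, foot = 0,
            circumference = 1.00, area = 0.15, wlr = 0, lwr = 0, lar = 0)
  contour <- c(length = 0, hw = -0.04, mwl = 0.02, mw = -0.05,
               nw = -0.03, foot = -0.04, circumference = 0, area = 0,
               wlr = -0.10, lwr = 0.60, lar = 0.30)
  list(base = base[nm], size = size[nm], contour = contour[nm],
       noise_sd = 0.05 * base[nm])
}

#' Specification of a synthetic spine population
#'
#' Describes the generative process used to validate the estimators: a
#' 2-D latent shape space (generalized size and contour coordinates)
#' with `k` Gaussian clusters, Markov-on-clusters dynamics with a known
#' transition matrix, and a linear map from latent coordinates to the 11
#' positive morphometric descriptors.
#'
#' @param k Number of latent shape clusters.
#' @param n Number of spines.
#' @param centroids k x 2 matrix of latent cluster centres; default is
#'   `k` well-separated points on a diagonal layout.
#' @param spread Within-cluster latent standard deviation (scalar or
#'   per-cluster vector). The default 0.6 makes neighbouring clusters
#'   touch, emulating the continuum of spine shapes seen in real
#'   morphometric data rather than an idealized well-separated mixture;
#'   pass a smaller value (e.g. 0.25) for well-separated validation
#'   scenarios.
#' @param T_true k x k row-stochastic transition matrix governing the
#'   t0 -> t1 cluster moves; default has strong diagonal inertia.
#' @param initial Initial cluster distribution (default uniform).
#' @param loading_map List with `base`, `size`, `contour` and `noise_sd`
#'   vectors over the 11 descriptors mapping latent `(u, v)` to
#'   descriptors as `base + size*u + contour*v + noise`; default keeps
#'   descriptor means in realistic micrometre-scale ranges.
#' @param mean_shift Optional named numeric vector of additive descriptor
#'   mean shifts (applied to `base`), used to create systematically
#'   different populations for balancing studies.
#' @param population Population label written into generated tables.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(k = 3, n = 300, centroids = NULL,
                           spread = 0.6, T_true = NULL, initial = NULL,
                           loading_map = default_loading_map(),
                           mean_shift = NULL, population = "POP") {
  if (is.null(centroids)) {
    u <- seq(-1.5, 1.5, length.out = k)
    v <- seq(1.2, -1.2, length.out = k)
    centroids <- cbind(u, v * rep_len(c(1, -1), k))
  }
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != k || ncol(centroids) != 2) {
    stop("centroids must be a k x 2 matrix", call. = FALSE)
  }
  if (is.null(T_true)) {
    T_true <- matrix(0.2 / max(1, k - 1), k, k)
    diag(T_true) <- if (k > 1) 0.8 else 1
  }
  T_true <- as.matrix(T_true)
  if (nrow(T_true) != k || ncol(T_true) != k || any(T_true < 0) ||
      any(abs(rowSums(T_true) - 1) > 1e-8)) {
    stop("T_true must be a k x k row-stochastic matrix", call. = FALSE)
  }
  if (is.null(initial)) initial <- rep(1 / k, k)
  if (length(initial) != k || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-8) {
    stop("initial must be a length-k probability vector", call. = FALSE)
  }
  spread <- rep_len(spread, k)
  structure(list(k = k, n = n, centroids = centroids, spread = spread,
                 T_true = T_true, initial = initial,
                 loading_map = loading_map, mean_shift = mean_shift,
                 population = population),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("Synthetic population spec: n = ", x$n, ", k = ", x$k,
      " latent clusters, population '", x$population, "'\n", sep = "")
  invisible(x)
}

latent_to_descriptors <- function(U, lm_, mean_shift = NULL,
                                  floor_val = 1e-3) {
  n <- nrow(U)
  base <- lm_$base
  if (!is.null(mean_shift)) {
    base[names(mean_shift)] <- base[names(mean_shift)] + mean_shift
  }
  X <- matrix(rep(base, each = n), n, length(base),
              dimnames = list(NULL, names(base)))
  X <- X + outer(U[, 1], lm_$size) + outer(U[, 2], lm_$contour)
  X <- X + matrix(stats::rnorm(n * length(base),
                               sd = rep(lm_$noise_sd, each = n)),
                  n, length(base))
  clipped <- sum(X < floor_val)
  X[X < floor_val] <- floor_val
  attr(X, "n_clipped") <- clipped
  X
}

#' Generate a synthetic spine population with known ground truth
#'
#' Samples the process the transition model assumes: each spine draws a
#' t0 cluster from the initial distribution and a latent t0 point from
#' an isotropic Gaussian at that cluster's centre; its t1 cluster is
#' drawn from the t0 cluster's row of the true transition matrix and the
#' t1 latent point from the destination centroid (pure Markov-on-clusters
#' dynamics). Latent points are mapped to the 11 positive descriptors
#' through the linear loading map plus Gaussian noise (values are floored
#' at a small positive constant; the number of floored cells is recorded
#' in attribute `n_clipped` of the table).
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return List with `table` (a [spine_table()]), `truth` (data frame
#'   `spine_id`, `cluster_t0`, `cluster_t1`, latent coordinates `u0`,
#'   `v0`, `u1`, `v1`).
#' @export
generate_population <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(seed, {
    n <- spec$n; k <- spec$k
    c0 <- sample.int(k, n, replace = TRUE, prob = spec$initial)
    c1 <- vapply(c0, function(cl) {
      sample.int(k, 1, prob = spec$T_true[cl, ])
    }, integer(1))
    L0 <- spec$centroids[c0, , drop = FALSE] +
      matrix(stats::rnorm(2 * n, sd = rep(spec$spread[c0], 2)), n, 2)
    L1 <- spec$centroids[c1, , drop = FALSE] +
      matrix(stats::rnorm(2 * n, sd = rep(spec$spread[c1], 2)), n, 2)
    X0 <- latent_to_descriptors(L0, spec$loading_map, spec$mean_shift)
    X1 <- latent_to_descriptors(L1, spec$loading_map, spec$mean_shift)
    ids <- sprintf("%s_s%04d", spec$population, seq_len(n))
    df <- data.frame(spine_id = ids, population = spec$population,
                     stringsAsFactors = FALSE)
    for (nm in colnames(X0)) {
      df[[paste0(nm, "_t0")]] <- X0[, nm]
      df[[paste0(nm, "_t1")]] <- X1[, nm]
    }
    tab <- spine_table(df)
    attr(tab, "n_clipped") <- attr(X0, "n_clipped") +
      attr(X1, "n_clipped")
    truth <- data.frame(spine_id = ids, cluster_t0 = c0, cluster_t1 = c1,
                        u0 = L0[, 1], v0 = L0[, 2],
                        u1 = L1[, 1], v1 = L1[, 2],
                        stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  })
}

#' Generate a pair of synthetic populations
#'
#' Convenience wrapper producing two groups: under the null both are
#' independent draws from the same specification (for calibration
#' studies); under an alternative the second specification may differ in
#' its transition matrix, centroids or descriptor mean shifts (for power
#' and balancing studies).
#'
#' @param spec_a Specification for the first group.
#' @param spec_b Specification for the second group; defaults to
#'   `spec_a` with the population label changed (null mode).
#' @param seed Master seed (each group gets its own derived seed).
#' @return List with elements `a` and `b`, each a
#'   [generate_population()] result.
#' @export
generate_group_pair <- function(spec_a, spec_b = NULL, seed = 1) {
  if (is.null(spec_b)) {
    spec_b <- spec_a
    spec_b$population <- paste0(spec_a$population, "B")
  }
  seeds <- replicate_seeds(seed, 2)
  list(a = generate_population(spec_a, seed = seeds[1]),
       b = generate_population(spec_b, seed = seeds[2]))
}
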