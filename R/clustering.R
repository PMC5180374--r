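new_cluster_model <- function(kind, k, centroids, m = NULL,
                              training = NULL) {
  structure(list(kind = kind, k = as.integer(k), m = m,
                 centroids = centroids, training = training),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Shape cluster model: ", x$kind, ", k = ", x$k, sep = "")
  if (x$kind == "fuzzy") cat(", m = ", x$m, sep = "")
  cat("\n")
  invisible(x)
}

membership_from_labels <- function(labels, k) {
  W <- matrix(0, length(labels), k)
  W[cbind(seq_along(labels), labels)] <- 1
  W
}

crisp_centroids <- function(X, labels, k) {
  C <- matrix(NA_real_, k, ncol(X))
  for (n in seq_len(k)) {
    members <- X[labels == n, , drop = FALSE]
    if (nrow(members) > 0) C[n, ] <- colMeans(members)
  }
  C
}

#' Crisp shape clustering by average-linkage hierarchical clustering
#'
#' Agglomerative clustering with average linkage on Euclidean distances;
#' the tree is cut at `k` clusters and every point receives a one-hot
#' membership vector. Training coordinates are retained in the model so
#' new spines can be assigned by first-nearest-neighbour lookup (see
#' [assign_new_spine()]).
#'
#' @param X Numeric feature matrix (rows = observations; typically the
#'   two-column reduced representation with each spine contributing its
#'   t0 and t1 rows).
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @return List with `model` (a `cluster_model`, kind `"crisp"`) and `W`
#'   (n x k one-hot membership matrix, rows in input order).
#' @export
fit_hierarchical <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be in 1..nrow(X)", call. = FALSE)
  labels <- if (k == n) seq_len(n) else if (k == 1) rep(1L, n) else {
    tree <- stats::hclust(stats::dist(X), method = "average")
    stats::cutree(tree, k = k)
  }
  W <- membership_from_labels(labels, k)
  model <- new_cluster_model("crisp", k,
                             centroids = crisp_centroids(X, labels, k),
                             training = list(x = X, w = W))
  list(model = model, W = W)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1, prob = prob)
    centers[j + 1, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j + 1, ])^2))
  }
  centers
}

#' Fuzzy shape clustering by fuzzy c-means
#'
#' Standard fuzzy c-means (alternating optimization of memberships and
#' centroids with fuzzifier `m`) with k-means++-style centroid seeding,
#' multiple restarts, and the best objective kept. Deterministic under a
#' fixed `seed`.
#'
#' @param X Numeric feature matrix.
#' @param k Number of clusters (`k <= nrow(X)`).
#' @param m Fuzzifier, `> 1`; larger values give softer memberships.
#' @param seed Integer seed for the restart initializations.
#' @param tol Convergence tolerance on the relative objective improvement.
#' @param max_iter Iteration cap per restart; non-convergence yields a
#'   warning with the last iterate, not a failure.
#' @param restarts Number of seeded restarts (default 5).
#' @return List with `model` (a `cluster_model`, kind `"fuzzy"`, centroids
#'   from the best fit), `W` (n x k membership matrix, rows summing to 1)
#'   and `objective` (the fuzzy c-means objective of the kept fit).
#' @export
fit_cmeans <- function(X, k, m = 2, seed = 1, tol = 1e-6,
                       max_iter = 300, restarts = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be in 1..nrow(X)", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  if (k == 1) {
    ctr <- matrix(colMeans(X), 1)
    model <- new_cluster_model("fuzzy", 1, centroids = ctr, m = m)
    return(list(model = model, W = matrix(1, n, 1), objective = 0))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(X, k)
      fit <- tryCatch(
        e1071::cmeans(X, centers = init, iter.max = max_iter, m = m,
                      method = "cmeans", control = list(reltol = tol)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (fit$iter >= max_iter) {
        warning("fuzzy c-means did not converge within ", max_iter,
                " iterations (restart ", r, "); using last iterate",
                call. = FALSE)
      }
      if (is.null(best) || fit$withinerror < best$withinerror) best <- fit
    }
  })
  if (is.null(best)) stop("fuzzy c-means failed for all restarts",
                          call. = FALSE)
  model <- new_cluster_model("fuzzy", k, centroids = unname(best$centers),
                             m = m)
  # e1071 reports the objective per point; rescale to J_m = sum w^m d^2
  list(model = model, W = unname(best$membership),
       objective = best$withinerror * n)
}

#' Membership weights of a point under a fuzzy cluster model
#'
#' Evaluates the fuzzy c-means membership formula: the weight of cluster
#' `n` is inversely proportional to the distance to its centroid raised
#' to `2/(m-1)`, normalized across clusters. A point coinciding with a
#' centroid gets full weight on that cluster (split equally if several
#' centroids coincide with it).
#'
#' @param s A feature point (vector) or matrix of points (rows).
#' @param model A fuzzy `cluster_model`.
#' @return A weight vector summing to 1 (or a matrix of such rows).
#' @export
membership <- function(s, model) {
  if (model$kind != "fuzzy") {
    stop("membership() needs a fuzzy cluster model; crisp models assign ",
         "via assign_new_spine()", call. = FALSE)
  }
  S <- if (is.matrix(s)) s else matrix(s, 1)
  C <- model$centroids
  if (model$k == 1) {
    W <- matrix(1, nrow(S), 1)
    return(if (!is.matrix(s)) as.vector(W) else W)
  }
  expo <- 2 / (model$m - 1)
  W <- t(apply(S, 1, function(p) {
    d <- sqrt(colSums((t(C) - p)^2))
    if (any(d == 0)) {
      w <- as.numeric(d == 0)
      return(w / sum(w))
    }
    v <- d^(-expo)
    v / sum(v)
  }))
  if (!is.matrix(s)) as.vector(W) else W
}

#' Within-cluster sum of squares
#'
#' Membership-weighted sum of squared Euclidean distances of every point
#' to every centroid: `sum_n sum_s w[s, n] * ||x_s - c_n||^2`. Applies to
#' crisp (one-hot) and fuzzy membership matrices alike.
#'
#' @param X n x d feature matrix.
#' @param W n x k membership matrix.
#' @param centroids k x d centroid matrix; rows of unoccupied clusters
#'   may be `NA` and contribute nothing.
#' @return Non-negative scalar.
#' @export
compute_wss <- function(X, W, centroids) {
  X <- as.matrix(X); W <- as.matrix(W)
  centroids <- as.matrix(centroids)
  if (nrow(X) != nrow(W) || ncol(W) != nrow(centroids) ||
      ncol(X) != ncol(centroids)) {
    stop("shape mismatch between X, W and centroids", call. = FALSE)
  }
  total <- 0
  for (n in seq_len(nrow(centroids))) {
    if (anyNA(centroids[n, ])) next
    d2 <- rowSums(sweep(X, 2, centroids[n, ])^2)
    total <- total + sum(W[, n] * d2)
  }
  total
}

# Plain-membership-weighted cluster centroids: c_n = sum_s w_n(s) s /
# sum_s w_n(s). These minimize the membership-weighted sum of squares
# for given weights, and are the centroids the WSS curve is defined
# with (for crisp memberships they are the ordinary member means).
membership_centroids <- function(X, W) {
  C <- t(as.matrix(W)) %*% X
  tot <- colSums(W)
  C[tot > 0, ] <- C[tot > 0, , drop = FALSE] / tot[tot > 0]
  C[tot == 0, ] <- NA_real_
  C
}

# Minimal fuzzy c-means iterator used for warm-start candidates in the
# WSS scan (e1071 refuses coincident initial centers; a previous-k
# solution with a duplicated centroid is a legitimate start here).
fcm_iterate <- function(X, centers, m, tol = 1e-9, max_iter = 500) {
  expo <- 2 / (m - 1)
  for (it in seq_len(max_iter)) {
    D2 <- outer(rowSums(X^2), rowSums(centers^2), "+") -
      2 * tcrossprod(X, centers)
    D2[D2 < 1e-300] <- 1e-300
    V <- D2^(-expo / 2)
    W <- V / rowSums(V)
    Wm <- W^m
    new_centers <- t(Wm) %*% X / colSums(Wm)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  list(centers = centers, W = W)
}

#' Scan within-cluster sum of squares over a parameter grid
#'
#' Computes the WSS curve used for knee-point model selection: over a
#' grid of cluster counts `k` (crisp hierarchical) or a grid of `(k, m)`
#' pairs (fuzzy c-means). WSS is always evaluated with the final
#' memberships and their plain-membership-weighted centroids.
#'
#' For the fuzzy scan, each `(k, m)` cell takes the best (lowest-WSS)
#' of several seeded k-means++ restarts plus a warm-start candidate
#' derived from the previous `k`'s solution with one centroid duplicated
#' (and slightly jittered). At large fuzzifiers the effective number of
#' distinct clusters saturates, and the warm start keeps the flat tail
#' of the curve stable instead of jumping between local optima.
#'
#' @param X Feature matrix.
#' @param method `"hier"` or `"cmeans"`.
#' @param k_grid Cluster counts (consecutive integers recommended).
#' @param m_grid Fuzzifier grid for `"cmeans"` (default
#'   `c(1.5, 2, 3, 4, 5)`); ignored for `"hier"`.
#' @param seed Master seed for the restart stream.
#' @param restarts Seeded restarts per `(k, m)` cell (default 8).
#' @return Object of class `wss_curve`: data frame with columns `k`, `m`
#'   (`NA` for crisp) and `wss`.
#' @export
wss_scan <- function(X, method = c("hier", "cmeans"), k_grid = 1:10,
                     m_grid = c(1.5, 2, 3, 4, 5), seed = 1,
                     restarts = 8) {
  method <- match.arg(method)
  X <- as.matrix(X)
  rows <- list()
  if (method == "hier") {
    tree <- if (max(k_grid) > 1)
      stats::hclust(stats::dist(X), method = "average") else NULL
    for (k in k_grid) {
      labels <- if (k == 1) rep(1L, nrow(X)) else stats::cutree(tree, k)
      W <- membership_from_labels(labels, k)
      wss <- compute_wss(X, W, membership_centroids(X, W))
      rows[[length(rows) + 1]] <- data.frame(k = k, m = NA_real_,
                                             wss = wss)
    }
  } else {
    data_scale <- sqrt(mean(apply(X, 2, stats::var)))
    for (m in sort(m_grid)) {
      prev_centers <- NULL
      for (k in sort(k_grid)) {
        cand_W <- list()
        seeds <- replicate_seeds(seed + 7919L * match(m, sort(m_grid)),
                                 restarts * max(k_grid))
        for (r in seq_len(restarts)) {
          f <- tryCatch(
            fit_cmeans(X, k, m = m, seed = seeds[(k - 1) * restarts + r],
                       restarts = 1),
            error = function(e) NULL)
          if (!is.null(f)) cand_W[[length(cand_W) + 1]] <- f$W
        }
        if (!is.null(prev_centers) && k == nrow(prev_centers) + 1) {
          dup <- which.max(vapply(seq_len(nrow(prev_centers)),
            function(n) {
              d2 <- rowSums(sweep(X, 2, prev_centers[n, ])^2)
              sum(d2)
            }, numeric(1)))
          jitter <- with_seed(seeds[restarts * max(k_grid)],
                              stats::rnorm(ncol(X),
                                           sd = 1e-6 * data_scale))
          init <- rbind(prev_centers, prev_centers[dup, ] + jitter)
          f <- tryCatch(fcm_iterate(X, init, m), error = function(e) NULL)
          if (!is.null(f)) cand_W[[length(cand_W) + 1]] <- f$W
        }
        if (length(cand_W) == 0) stop("all fuzzy c-means fits failed",
                                      call. = FALSE)
        wssv <- vapply(cand_W, function(W)
          compute_wss(X, W, membership_centroids(X, W)), numeric(1))
        best <- which.min(wssv)
        prev_centers <- membership_centroids(X, cand_W[[best]])
        rows[[length(rows) + 1]] <- data.frame(k = k, m = m,
                                               wss = wssv[best])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wss_curve", "data.frame")
  out
}

#' @export
plot.wss_curve <- function(x, ...) {
  ms <- unique(x$m)
  graphics::plot(NULL, xlim = range(x$k), ylim = range(x$wss),
                 xlab = "k (number of clusters)",
                 ylab = "within-cluster sum of squares", ...)
  for (i in seq_along(ms)) {
    sl <- if (is.na(ms[i])) x[is.na(x$m), ] else x[!is.na(x$m) &
                                                   x$m == ms[i], ]
    graphics::lines(sl$k, sl$wss, col = i)
    graphics::points(sl$k, sl$wss, col = i, pch = 19)
  }
  if (any(!is.na(ms))) {
    graphics::legend("topright", legend = paste("m =", ms), col =
                     seq_along(ms), lty = 1, bty = "n")
  }
  invisible(x)
}

knee_of_slice <- function(k, wss) {
  ord <- order(k)
  k <- k[ord]; wss <- wss[ord]
  if (length(k) < 3) stop("knee detection needs >= 3 k values",
                          call. = FALSE)
  if (all(diff(wss) > 0)) {
    stop("invalid WSS curve: monotonically increasing in k",
         call. = FALSE)
  }
  # Bend detection on the log curve: the discrete second difference of
  # log(WSS) is scale-free, so the knee is where the relative decay
  # slows the most -- the visual elbow. (On the raw curve the second
  # difference is dominated by the first large drop regardless of where
  # the curve actually flattens.) A floor keeps exact zeros finite.
  lw <- log(pmax(wss, 1e-12 * max(wss, 1)))
  interior <- 2:(length(k) - 1)
  d2 <- lw[interior - 1] - 2 * lw[interior] + lw[interior + 1]
  # ties -> smallest k (tolerance relative to curve magnitude)
  tol <- 1e-9 * max(1, abs(max(d2)))
  k[interior][which(d2 >= max(d2) - tol)[1]]
}

#' Knee-point selection of clustering parameters from a WSS curve
#'
#' Picks the number of clusters at the point where the WSS curve bends
#' the most: the `k` maximizing the discrete second difference of
#' `log WSS` within each fuzzifier slice (the scale-free bend, i.e. the
#' visual elbow of the plot). For
#' fuzzy scans the smallest `m` whose knee agrees with the knee of the
#' next larger `m` on the grid is chosen (a stable knee); if no adjacent
#' pair agrees the smallest `m` is returned with a warning. Ties break
#' toward the smallest `k`, then the smallest `m`.
#'
#' @param curve A [wss_scan()] result covering at least 3 consecutive
#'   `k` values per slice.
#' @return List with `k` and (for fuzzy scans) `m`.
#' @export
knee_select <- function(curve) {
  if (all(is.na(curve$m))) {
    return(list(k = knee_of_slice(curve$k, curve$wss)))
  }
  ms <- sort(unique(curve$m))
  knees <- vapply(ms, function(m) {
    sl <- curve[curve$m == m, ]
    knee_of_slice(sl$k, sl$wss)
  }, numeric(1))
  if (length(ms) == 1) return(list(k = knees[1], m = ms[1]))
  stable <- which(knees[-length(knees)] == knees[-1])
  if (length(stable) == 0) {
    warning("no stable knee across the m grid; returning the smallest m",
            call. = FALSE)
    return(list(k = knees[1], m = ms[1]))
  }
  i <- stable[1]
  list(k = knees[i], m = ms[i])
}
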