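# O(n^3) reference implementation of average-linkage agglomeration:
# recompute all inter-cluster average distances at every step.
average_linkage_oracle <- function(X, k_stop) {
  clusters <- as.list(seq_len(nrow(X)))
  D <- as.matrix(dist(X))
  while (length(clusters) > k_stop) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < best[1]) best <- c(d, a, b)
      }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  labels <- integer(nrow(X))
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

same_partition <- function(a, b) {
  identical(as.integer(unclass(factor(a, levels = unique(a)))),
            as.integer(unclass(factor(b, levels = unique(b)))))
}

test_that("average-linkage clustering matches a brute-force oracle", {
  set.seed(71)
  X <- matrix(rnorm(16), 8, 2)
  for (k in c(2, 3, 4)) {
    fit <- fit_hierarchical(X, k)
    expect_true(same_partition(max.col(fit$W),
                               average_linkage_oracle(X, k)))
  }
})

test_that("singleton clustering has zero WSS; separation forces the cut", {
  set.seed(72)
  X <- matrix(rnorm(20), 10, 2)
  fit <- fit_hierarchical(X, 10)
  expect_equal(compute_wss(X, fit$W, fit$model$centroids), 0)
  blobs <- make_blobs(25)
  fit2 <- fit_hierarchical(blobs$X, 2)
  expect_true(same_partition(max.col(fit2$W), blobs$labels))
  expect_error(fit_hierarchical(X, 11), "k must be")
})

test_that("fuzzy c-means matches a reference alternating-optimization loop", {
  blobs <- make_blobs(30, gap = 6)
  X <- blobs$X
  fit <- fit_cmeans(X, 2, m = 2, seed = 9, restarts = 1)
  # reference loop from the same k-means++ initialization
  init <- spinetax:::with_seed(9, spinetax:::kmeanspp_init(X, 2))
  centers <- init
  for (it in 1:500) {
    D2 <- outer(rowSums(X^2), rowSums(centers^2), "+") -
      2 * tcrossprod(X, centers)
    D2[D2 < 1e-12] <- 1e-12         # a centre can sit on a data point
    V <- D2^(-1 / (2 - 1))          # exponent 2/(m-1) applied to d^2
    W <- V / rowSums(V)
    Wm <- W^2
    newc <- t(Wm) %*% X / colSums(Wm)
    if (max(abs(newc - centers)) < 1e-10) break
    centers <- newc
  }
  obj <- sum(Wm * D2)
  expect_equal(fit$objective, obj, tolerance = 1e-4)
  # centroids agree up to cluster relabeling
  d <- min(max(abs(fit$model$centroids - centers)),
           max(abs(fit$model$centroids - centers[2:1, ])))
  expect_lt(d, 1e-3)
})

test_that("k = 1 fuzzy clustering is the data mean with unit weights", {
  set.seed(73)
  X <- matrix(rnorm(30), 15, 2)
  fit <- fit_cmeans(X, 1, m = 3, seed = 1)
  expect_equal(fit$W, matrix(1, 15, 1))
  expect_equal(as.vector(fit$model$centroids), colMeans(X))
  expect_error(fit_cmeans(X, 2, m = 1), "m must be")
})

test_that("the membership formula gives hand-computed weights", {
  model <- spinetax:::new_cluster_model(
    "fuzzy", 2, centroids = rbind(c(0, 0), c(3, 0)), m = 2)
  # distances (1, 2) with exponent 2/(m-1) = 2: weights (0.8, 0.2)
  expect_equal(membership(c(1, 0), model), c(0.8, 0.2))
  # coincidence with a centroid gives the one-hot limit
  expect_equal(membership(c(3, 0), model), c(0, 1))
  # weights positive and summing to 1 for arbitrary points
  set.seed(74)
  W <- membership(matrix(rnorm(40), 20, 2), model)
  expect_true(all(W > 0))
  expect_equal(rowSums(W), rep(1, 20))
  # a point equidistant from both centroids splits evenly
  expect_equal(membership(c(1.5, 2), model), c(0.5, 0.5))
})

test_that("WSS equals a double-loop oracle for crisp and fuzzy weights", {
  set.seed(75)
  X <- matrix(rnorm(24), 12, 2)
  # single crisp cluster: total sum of squared deviations from the mean
  W1 <- matrix(1, 12, 1)
  expect_equal(compute_wss(X, W1, matrix(colMeans(X), 1)),
               sum(sweep(X, 2, colMeans(X))^2))
  W <- random_fuzzy_W(12, 3)
  C <- matrix(rnorm(6), 3, 2)
  oracle <- 0
  for (n in 1:3) {
    for (s in 1:12) {
      oracle <- oracle + W[s, n] * sum((X[s, ] - C[n, ])^2)
    }
  }
  expect_equal(compute_wss(X, W, C), oracle)
  expect_error(compute_wss(X, W, C[1:2, ]), "shape mismatch")
})

test_that("knee selection maximizes the discrete second difference", {
  curve <- data.frame(k = 1:4, m = NA_real_, wss = c(100, 40, 35, 33))
  class(curve) <- c("wss_curve", "data.frame")
  expect_equal(knee_select(curve)$k, 2)
  # exactly linear curve: tie rule gives the smallest interior k
  lin <- data.frame(k = 1:5, m = NA_real_, wss = seq(50, 10, by = -10))
  class(lin) <- c("wss_curve", "data.frame")
  expect_equal(knee_select(lin)$k, 2)
  # increasing curve violates the WSS property
  bad <- data.frame(k = 1:4, m = NA_real_, wss = c(1, 2, 3, 4))
  class(bad) <- c("wss_curve", "data.frame")
  expect_error(knee_select(bad), "invalid WSS curve")
  # fuzzy grid: smallest m with a knee stable across adjacent m values
  fz <- rbind(
    data.frame(k = 1:5, m = 2, wss = c(100, 60, 30, 28, 27)),  # knee 3
    data.frame(k = 1:5, m = 3, wss = c(120, 80, 45, 43, 42)),  # knee 3
    data.frame(k = 1:5, m = 4, wss = c(150, 90, 80, 50, 48)))  # knee 4
  class(fz) <- c("wss_curve", "data.frame")
  sel <- knee_select(fz)
  expect_equal(sel$k, 3)
  expect_equal(sel$m, 2)
})

test_that("cluster relabeling permutes centroids and memberships together", {
  blobs <- make_blobs(20, gap = 8, seed = 76)
  fit <- fit_cmeans(blobs$X, 2, m = 2, seed = 3)
  W2 <- fit$W[, 2:1]
  C2 <- fit$model$centroids[2:1, ]
  model2 <- spinetax:::new_cluster_model("fuzzy", 2, centroids = C2, m = 2)
  expect_equal(membership(blobs$X, model2), W2, tolerance = 1e-6)
  expect_equal(compute_wss(blobs$X, W2, C2),
               compute_wss(blobs$X, fit$W, fit$model$centroids))
})

test_that("taxonomy fitting uses two rows per spine and splits back", {
  pair <- generate_group_pair(generator_spec(n = 40, population = "A"),
                              seed = 6)
  tabs <- list(pair$a$table, pair$b$table)
  red <- reduce_features(tabs, fit_split_pca(tabs))
  tax <- fit_taxonomy(red, "hier", k = 3)
  expect_named(tax$groups, c("A", "AB"))
  gr <- tax$groups$A
  expect_equal(nrow(gr$W0), 40)
  expect_equal(rowSums(gr$W0), rep(1, 40))
  expect_equal(rowSums(gr$W1), rep(1, 40))
})
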