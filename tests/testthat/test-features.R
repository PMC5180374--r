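test_that("PCA recovers rank-1 structure and matches an eigen oracle", {
  set.seed(11)
  # collinear points in d = 3: first component carries all variance
  t_ <- rnorm(20)
  X1 <- cbind(1 + 2 * t_, 3 - t_, 0.5 * t_)
  p1 <- fit_pca(X1)
  expect_equal(p1$explained[1], 1)
  # random matrix: loadings equal covariance eigendecomposition up to sign
  X <- matrix(rnorm(20 * 11), 20, 11)
  p <- fit_pca(X)
  eig <- eigen(cov(X), symmetric = TRUE)
  for (i in 1:5) {
    v <- eig$vectors[, i]
    expect_equal(abs(sum(v * p$loadings[i, ])), 1, tolerance = 1e-8)
  }
  expect_equal(p$explained, eig$values / sum(eig$values))
  expect_true(all(diff(p$explained) <= 1e-12))
  # deterministic sign convention: repeated fits identical, largest
  # loading positive
  expect_identical(fit_pca(X)$loadings, p$loadings)
  for (i in seq_len(nrow(p$loadings))) {
    expect_gt(p$loadings[i, which.max(abs(p$loadings[i, ]))], 0)
  }
  expect_error(fit_pca(matrix(1, 5, 3)), "degenerate")
})

test_that("isotropic 2-D data splits variance evenly", {
  set.seed(12)
  X <- matrix(rnorm(4000), ncol = 2)
  expect_equal(fit_pca(X)$explained, c(0.5, 0.5), tolerance = 0.05)
})

test_that("split PCA equals independent PCA on each descriptor block", {
  tab <- make_table(30, seed = 21)
  sch <- descriptor_schema()
  fit <- fit_split_pca(tab)
  Xs <- rbind(descriptor_matrix(tab, "t0", sch$size_set),
              descriptor_matrix(tab, "t1", sch$size_set))
  Xc <- rbind(descriptor_matrix(tab, "t0", sch$contour_set),
              descriptor_matrix(tab, "t1", sch$contour_set))
  expect_equal(fit$size$loadings, fit_pca(Xs)$loadings)
  expect_equal(fit$contour$loadings, fit_pca(Xc)$loadings)
})

test_that("a dominant-variance descriptor dominates the size component", {
  # circumference varies much more than length/area, as in real spine
  # tables: its loading must dominate Comp.1
  spec <- generator_spec(n = 300)
  tab <- generate_population(spec, seed = 5)$table
  fit <- fit_split_pca(tab)
  l <- fit$size$loadings[1, ]
  expect_identical(names(which.max(abs(l))), "circumference")
})

test_that("loading truncation matches a mask-then-renormalize oracle", {
  v <- c(0.99, 0.05, 0.05)
  expect_equal(truncate_loadings(v, 0.10), c(1, 0, 0))
  u <- c(0.6, 0.5, 0.45, 0.43)  # all above threshold, already unit norm
  u <- u / sqrt(sum(u^2))
  expect_equal(truncate_loadings(u, 0.10), u)
  set.seed(31)
  for (i in 1:20) {
    w <- rnorm(8); w <- w / sqrt(sum(w^2))
    masked <- ifelse(abs(w) < 0.10, 0, w)
    expect_equal(truncate_loadings(w, 0.10),
                 masked / sqrt(sum(masked^2)))
  }
  expect_error(truncate_loadings(c(0.05, -0.03), 0.10), "threshold")
  expect_error(truncate_loadings(v, 1), "threshold")
})

test_that("projection centers, truncates and is affine", {
  tab <- make_table(40, seed = 41)
  fit <- fit_split_pca(tab)
  red <- reduce_features(tab, fit)
  expect_equal(nrow(red), 80)  # two rows per spine
  # explicit dot-product oracle per spine
  sch <- descriptor_schema()
  l1 <- truncate_loadings(fit$size$loadings[1, ], 0.10)
  l2 <- truncate_loadings(fit$contour$loadings[1, ], 0.10)
  X0s <- descriptor_matrix(tab, "t0", sch$size_set)
  X0c <- descriptor_matrix(tab, "t0", sch$contour_set)
  r0 <- red[red$time == "t0", ]
  for (i in c(1, 17, 40)) {
    expect_equal(r0$comp1[i], sum((X0s[i, ] - fit$size$center) * l1))
    expect_equal(r0$comp2[i], sum((X0c[i, ] - fit$contour$center) * l2))
  }
  # a spine sitting at the pooled mean maps to the origin
  mean_spine <- make_wide_df(1)
  for (nm in sch$size_set) {
    mean_spine[[paste0(nm, "_t0")]] <- fit$size$center[nm]
  }
  for (nm in sch$contour_set) {
    mean_spine[[paste0(nm, "_t0")]] <- fit$contour$center[nm]
  }
  red_mean <- reduce_features(spine_table(mean_spine), fit)
  expect_equal(red_mean$comp1[red_mean$time == "t0"], 0)
  expect_equal(red_mean$comp2[red_mean$time == "t0"], 0)
  # two spines differing only in a truncated-out descriptor coincide
  dropped <- names(which(l2 == 0))
  if (length(dropped) > 0) {
    df <- make_wide_df(2, seed = 43)
    df[2, ] <- df[1, ]
    df$spine_id <- c("p1", "p2")
    df[[paste0(dropped[1], "_t0")]][2] <-
      df[[paste0(dropped[1], "_t0")]][1] + 1
    rp <- reduce_features(spine_table(df), fit)
    expect_equal(rp$comp1[rp$spine_id == "p1"],
                 rp$comp1[rp$spine_id == "p2"])
    expect_equal(rp$comp2[rp$spine_id == "p1"],
                 rp$comp2[rp$spine_id == "p2"])
  }
  # affinity: transform(alpha x + (1-alpha) y) interpolates
  dfa <- make_wide_df(2, seed = 44)
  alpha <- 0.3
  mix <- dfa[1, ]
  mix$spine_id <- "mix"
  for (cl in setdiff(names(dfa), c("spine_id", "population"))) {
    mix[[cl]] <- alpha * dfa[[cl]][1] + (1 - alpha) * dfa[[cl]][2]
  }
  rall <- reduce_features(spine_table(rbind(dfa, mix)), fit)
  r0 <- rall[rall$time == "t0", ]
  expect_equal(r0$comp1[3], alpha * r0$comp1[1] + (1 - alpha) * r0$comp1[2])
  expect_equal(r0$comp2[3], alpha * r0$comp2[1] + (1 - alpha) * r0$comp2[2])
})

test_that("full PCA top-2 variance bounds the split-PCA coverage", {
  # the two split first components are orthonormal directions in the
  # 11-D space, so the full PCA top-2 subspace must capture at least as
  # much variance
  for (seed in c(3, 8)) {
    tab <- generate_population(generator_spec(n = 200), seed = seed)$table
    sch <- descriptor_schema()
    Xall <- rbind(descriptor_matrix(tab, "t0"), descriptor_matrix(tab, "t1"))
    full <- fit_pca(Xall)
    fit <- fit_split_pca(tab)
    tot <- sum(apply(Xall, 2, var))
    tot_s <- sum(apply(Xall[, sch$size_set], 2, var))
    tot_c <- sum(apply(Xall[, sch$contour_set], 2, var))
    split_cover <- (fit$size$explained[1] * tot_s +
                    fit$contour$explained[1] * tot_c) / tot
    full_cover <- sum(full$explained[1:2])
    expect_gte(full_cover, split_cover)
  }
})
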