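test_that("crisp estimation counts cluster moves", {
  # 4 spines start in cluster 1; 3 stay, 1 moves to cluster 2
  W0 <- membership_from_labels_test(c(1, 1, 1, 1, 2, 2), 2)
  W1 <- membership_from_labels_test(c(1, 1, 1, 2, 2, 2), 2)
  tm <- estimate_crisp(W0, W1)
  expect_equal(tm$T, rbind(c(0.75, 0.25), c(0, 1)))
  expect_equal(tm$initial_weights, c(4, 2))
  # nobody moves: identity on occupied clusters
  tm2 <- estimate_crisp(W0, W0)
  expect_equal(tm2$T, diag(2))
  expect_equal(tm2$E, 0)
  # an empty source cluster gets a flagged uniform row
  W0e <- membership_from_labels_test(c(1, 1, 1), 3)
  W1e <- membership_from_labels_test(c(1, 2, 3), 3)
  tme <- estimate_crisp(W0e, W1e)
  expect_true(all(tme$empty_rows == c(FALSE, TRUE, TRUE)))
  expect_equal(tme$T[2, ], rep(1 / 3, 3))
  # fuzzy input is routed away
  expect_error(estimate_crisp(random_fuzzy_W(5, 2), W0[1:5, ]),
               "one-hot")
})

test_that("the QP estimator recovers a planted transition matrix", {
  set.seed(81)
  k <- 4
  Tstar <- random_stochastic(k)
  W0 <- rbind(diag(k), random_fuzzy_W(196, k))  # spans the simplex
  W1 <- W0 %*% Tstar                             # exact linear dynamics
  tm <- estimate_qp(W0, W1)
  expect_lt(max(abs(tm$T - Tstar)), 1e-4)
  expect_lt(tm$E, 1e-8)
})

test_that("k = 1 transition model is the trivial one", {
  tm <- estimate_qp(matrix(1, 10, 1), matrix(1, 10, 1))
  expect_equal(tm$T, matrix(1, 1, 1))
  expect_equal(tm$E, 0)
})

test_that("prediction follows the law of total probability", {
  set.seed(82)
  k <- 5
  T <- random_stochastic(k)
  tm <- spinetax:::new_transition_model(T, "qp")
  w0 <- as.vector(random_fuzzy_W(1, k))
  w1 <- predict_t1(tm, w0)
  oracle <- numeric(k)
  for (m in 1:k) for (n in 1:k) oracle[m] <- oracle[m] + T[n, m] * w0[n]
  expect_equal(w1, oracle)
  expect_equal(sum(w1), 1)
  # identity keeps weights; one-hot input selects a row
  expect_equal(predict_t1(baseline_model(k, "identity"), w0), w0)
  e3 <- as.numeric(1:k == 3)
  expect_equal(predict_t1(tm, e3), T[3, ])
})

test_that("prediction error matches its closed forms and a loop oracle", {
  tm <- spinetax:::new_transition_model(rbind(c(0, 1), c(1, 0)), "crisp")
  # one spine predicted (1, 0) but observed (0, 1): error 2
  pe <- prediction_error(tm, matrix(c(0, 1), 1), matrix(c(0, 1), 1))
  expect_equal(pe$E, 2)
  set.seed(83)
  W0 <- random_fuzzy_W(15, 3); W1 <- random_fuzzy_W(15, 3)
  T <- random_stochastic(3)
  tmr <- spinetax:::new_transition_model(T, "qp")
  oracle <- 0
  for (s in 1:15) {
    pred <- as.vector(crossprod(T, W0[s, ]))
    oracle <- oracle + sum((pred - W1[s, ])^2)
  }
  expect_equal(prediction_error(tmr, W0, W1)$E, oracle)
})

test_that("new-spine assignment equals a linear-scan nearest neighbour", {
  set.seed(84)
  X <- matrix(rnorm(40), 20, 2)
  fit <- fit_hierarchical(X, 4)
  # querying a training point returns its own weights
  expect_equal(assign_new_spine(fit$model, X[7, ]), fit$W[7, ])
  for (i in 1:10) {
    q <- rnorm(2)
    d2 <- rowSums(sweep(X, 2, q)^2)
    expect_equal(assign_new_spine(fit$model, q), fit$W[which.min(d2), ])
  }
  # equidistant query breaks the tie toward the smaller training index
  Xt <- rbind(c(0, 0), c(2, 0))
  fit2 <- fit_hierarchical(Xt, 2)
  expect_equal(assign_new_spine(fit2$model, c(1, 0)), fit2$W[1, ])
})

test_that("baseline models are argmax, identity and seeded Dirichlet", {
  tm <- spinetax:::new_transition_model(
    rbind(c(0.6, 0.4), c(0.3, 0.7)), "qp")
  expect_equal(baseline_model(tm, "majority")$T, diag(2))
  expect_equal(baseline_model(3, "identity")$T, diag(3))
  r1 <- baseline_model(4, "random", seed = 11)
  r2 <- baseline_model(4, "random", seed = 11)
  expect_identical(r1$T, r2$T)
  expect_equal(rowSums(r1$T), rep(1, 4))
  expect_true(all(r1$T >= 0))
  # identity baseline error reduces to the raw weight change
  set.seed(85)
  W0 <- random_fuzzy_W(12, 3); W1 <- random_fuzzy_W(12, 3)
  expect_equal(prediction_error(baseline_model(3, "identity"), W0, W1)$E,
               sum((W0 - W1)^2))
})

test_that("cross-validation partitions spines and scores all models", {
  blob_tab <- generate_population(generator_spec(n = 60), seed = 9)$table
  red <- reduce_features(blob_tab, fit_split_pca(blob_tab))
  cv <- cross_validate(red, "hier", k = 3, folds = 5, seed = 2)
  expect_setequal(cv$model, c("stm", "majority", "identity", "random"))
  expect_true(all(cv$mean_E >= 0))
  E <- attr(cv, "fold_errors")
  expect_equal(dim(E), c(5, 4))
  expect_error(cross_validate(red, "hier", k = 3, folds = 61), "folds")
})

test_that("static data yields zero cross-validated error for STM and identity", {
  # t1 identical to t0: nothing moves, so the transition model and the
  # no-transition baseline are both perfect in every fold
  df <- make_wide_df(30, seed = 91)
  for (nm in desc_names) df[[paste0(nm, "_t1")]] <- df[[paste0(nm, "_t0")]]
  tab <- spine_table(df)
  red <- reduce_features(tab, fit_split_pca(tab))
  cv <- cross_validate(red, "hier", k = 3, folds = 5, seed = 3)
  expect_equal(cv$mean_E[cv$model == "stm"], 0)
  expect_equal(cv$mean_E[cv$model == "identity"], 0)
})

test_that("the transition model beats the no-transition baseline on moving data", {
  spec <- generator_spec(k = 3, n = 400, spread = 0.25,
                         T_true = rbind(c(0.5, 0.5, 0), c(0, 0.6, 0.4),
                                        c(0.3, 0, 0.7)))
  tab <- generate_population(spec, seed = 10)$table
  red <- reduce_features(tab, fit_split_pca(tab))
  cv <- cross_validate(red, "hier", k = 3, folds = 10, seed = 4)
  expect_lt(cv$mean_E[cv$model == "stm"],
            cv$mean_E[cv$model == "identity"])
})
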