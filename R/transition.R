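new_transition_model <- function(T, method, initial_weights = NULL,
                                 empty_rows = NULL, E = NULL, se = NULL) {
  k <- nrow(T)
  if (is.null(empty_rows)) empty_rows <- rep(FALSE, k)
  structure(list(T = T, method = method,
                 initial_weights = initial_weights,
                 empty_rows = empty_rows, E = E, se = se),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, digits = 3, ...) {
  cat("Shape transition model (", x$method, "), k = ", nrow(x$T), "\n",
      sep = "")
  print(round(x$T, digits))
  if (any(x$empty_rows)) {
    cat("  rows with empty source cluster (uniform by policy): ",
        paste(which(x$empty_rows), collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$E)) cat("  training prediction error E =",
                         format(x$E, digits = 4), "\n")
  invisible(x)
}

check_transition_matrix <- function(T, tol = 1e-8) {
  if (any(T < -tol)) stop("transition matrix has negative entries",
                          call. = FALSE)
  if (any(abs(rowSums(T) - 1) > tol)) {
    stop("transition matrix rows must sum to 1", call. = FALSE)
  }
  invisible(T)
}

#' Crisp transition-matrix estimator
#'
#' For one-hot membership matrices, the transition probability from
#' cluster `n` to cluster `m` is the fraction of spines assigned to `n`
#' at t0 that are assigned to `m` at t1:
#' `T[n, m] = sum_s w0[s, n] w1[s, m] / sum_s w0[s, n]`.
#' Clusters with no spines at t0 receive a uniform row and are flagged in
#' `empty_rows`.
#'
#' @param W0,W1 One-hot membership matrices (same spines in the same row
#'   order, same number of clusters).
#' @return A `transition_model` (`method = "crisp"`) with row-stochastic
#'   `T`, `initial_weights` (t0 cluster occupancies) and the achieved
#'   training prediction error `E`.
#' @export
estimate_crisp <- function(W0, W1) {
  W0 <- check_membership(W0, arg = "W0")
  W1 <- check_membership(W1, arg = "W1")
  if (!is_one_hot(W0) || !is_one_hot(W1)) {
    stop("estimate_crisp() needs one-hot memberships; use estimate_qp() ",
         "for fuzzy membership matrices", call. = FALSE)
  }
  k <- ncol(W0)
  counts <- crossprod(W0, W1)           # k x k co-occurrence
  occ <- colSums(W0)
  T <- matrix(1 / k, k, k)
  empty <- occ == 0
  T[!empty, ] <- counts[!empty, , drop = FALSE] / occ[!empty]
  model <- new_transition_model(T, "crisp", initial_weights = occ,
                                empty_rows = empty)
  model$E <- prediction_error(model, W0, W1)$E
  model
}

#' Transition-matrix estimation by constrained quadratic programming
#'
#' Estimates the row-stochastic transition matrix minimizing the squared
#' prediction error of the t1 memberships under the law of total
#' probability: predicted `w1[m] = sum_n T[n, m] w0[n]`, objective
#' `E = sum_s sum_m (predicted - observed)^2`, subject to `T >= 0` and
#' unit row sums. Works for fuzzy and crisp memberships alike; on one-hot
#' input it reproduces [estimate_crisp()].
#'
#' @param W0,W1 Membership matrices (rows sum to 1; same spines, same k).
#' @param tol Solver feasibility/optimality tolerance (default 1e-8).
#' @return A `transition_model` (`method = "qp"`) with the achieved `E`.
#'   Source clusters with (numerically) zero total t0 weight do not enter
#'   the objective; their rows are set uniform and flagged.
#' @details The quadratic program is solved over the rows with positive
#'   t0 occupancy: with `G = W0'W0` restricted to those clusters and
#'   `M = W0'W1`, the objective is `tr(T'GT) - 2 tr(T'M)` + const, a
#'   convex QP in the stacked columns of `T` solved with an active-set
#'   method. A tiny ridge (1e-10 of the mean diagonal) is added if `G` is
#'   numerically singular.
#' @export
estimate_qp <- function(W0, W1, tol = 1e-8) {
  W0 <- check_membership(W0, arg = "W0")
  W1 <- check_membership(W1, arg = "W1")
  if (ncol(W0) != ncol(W1) || nrow(W0) != nrow(W1)) {
    stop("W0 and W1 must have identical dimensions", call. = FALSE)
  }
  k <- ncol(W0)
  occ <- colSums(W0)
  if (k == 1) {
    model <- new_transition_model(matrix(1, 1, 1), "qp",
                                  initial_weights = occ)
    model$E <- prediction_error(model, W0, W1)$E
    return(model)
  }
  active <- occ > k * nrow(W0) * 1e-12
  T <- matrix(1 / k, k, k)
  if (any(active)) {
    W0a <- W0[, active, drop = FALSE]
    G <- crossprod(W0a)
    M <- crossprod(W0a, W1)
    ka <- sum(active)
    ridge <- 0
    if (rcond(G) < 1e-12) ridge <- 1e-10 * mean(diag(G))
    C <- kronecker(diag(k), G + diag(ridge, ka))
    d <- -as.vector(M)
    Aeq <- kronecker(matrix(1, 1, k), diag(ka))   # row sums of T_active
    sol <- pracma::quadprog(C, d, Aeq = Aeq, beq = rep(1, ka),
                            lb = rep(0, ka * k))
    Ta <- matrix(sol$xmin, ka, k)
    # clean tiny constraint violations from the active-set solve
    Ta[Ta < 0] <- 0
    Ta <- Ta / rowSums(Ta)
    T[active, ] <- Ta
  }
  check_transition_matrix(T, tol = 1e-6)
  model <- new_transition_model(T, "qp", initial_weights = occ,
                                empty_rows = !active)
  model$E <- prediction_error(model, W0, W1)$E
  model
}

#' Predict t1 membership weights from t0 weights
#'
#' Applies the law of total probability: the predicted weight of cluster
#' `m` at t1 is `sum_n T[n, m] * w0[n]` (multiplication by the transpose
#' of the row-stochastic transition matrix).
#'
#' @param model A `transition_model`.
#' @param w0 A valid weight vector (or a matrix of weight rows).
#' @return A weight vector (or matrix of rows) summing to 1.
#' @export
predict_t1 <- function(model, w0) {
  T <- model$T
  if (is.matrix(w0)) {
    if (ncol(w0) != nrow(T)) stop("dimension mismatch", call. = FALSE)
    return(w0 %*% T)
  }
  if (length(w0) != nrow(T)) stop("dimension mismatch", call. = FALSE)
  as.vector(crossprod(T, w0))
}

#' Assign taxonomy weights to a new spine at t0
#'
#' For a crisp model, copies the membership vector of the nearest
#' training point (Euclidean distance; ties broken toward the smallest
#' training index). For a fuzzy model, evaluates the explicit membership
#' formula (see [membership()]).
#'
#' @param model A fitted `cluster_model` (crisp models must retain
#'   training coordinates).
#' @param s Feature point (vector) or matrix of points.
#' @return Membership weight vector (or matrix of rows).
#' @export
assign_new_spine <- function(model, s) {
  if (model$kind == "fuzzy") return(membership(s, model))
  if (is.null(model$training) || nrow(model$training$x) == 0) {
    stop("crisp model has no retained training coordinates", call. = FALSE)
  }
  S <- if (is.matrix(s)) s else matrix(s, 1)
  X <- model$training$x
  W <- do.call(rbind, lapply(seq_len(nrow(S)), function(i) {
    d2 <- rowSums(sweep(X, 2, S[i, ])^2)
    model$training$w[which.min(d2), ]   # which.min: first = smallest index
  }))
  if (!is.matrix(s)) as.vector(W) else W
}

#' Prediction error of a transition model
#'
#' The summed squared difference between predicted and derived t1
#' memberships: `E = sum_s sum_m (predict(w0(s))[m] - w1(s)[m])^2`.
#'
#' @param model A `transition_model`.
#' @param W0,W1 Membership matrices.
#' @return List of class `prediction_error` with `E`, `n_spines`, `k`.
#' @export
prediction_error <- function(model, W0, W1) {
  W0 <- as.matrix(W0); W1 <- as.matrix(W1)
  E <- sum((W0 %*% model$T - W1)^2)
  structure(list(E = E, n_spines = nrow(W0), k = ncol(W0)),
            class = "prediction_error")
}

#' @export
print.prediction_error <- function(x, ...) {
  cat("Prediction error E =", format(x$E, digits = 6), "over",
      x$n_spines, "spines,", x$k, "clusters\n")
  invisible(x)
}

#' Baseline transition models
#'
#' The three reference models the Shape Transition Model is compared
#' against: `"majority"` hardens an estimated matrix so each source
#' cluster moves entirely to its most probable destination (ties toward
#' the smallest index); `"identity"` keeps every spine in its initial
#' cluster; `"random"` draws each row from the flat Dirichlet
#' distribution under a fixed seed.
#'
#' @param x For `"majority"`, an estimated `transition_model`; for the
#'   other kinds, the number of clusters `k` (an estimated model is also
#'   accepted and supplies `k`).
#' @param kind `"majority"`, `"identity"` or `"random"`.
#' @param seed Seed for the random baseline.
#' @return A `transition_model` with `method` set to the baseline kind.
#' @export
baseline_model <- function(x, kind = c("majority", "identity", "random"),
                           seed = 1) {
  kind <- match.arg(kind)
  if (kind == "majority") {
    if (!inherits(x, "transition_model")) {
      stop("the majority baseline hardens an estimated transition model",
           call. = FALSE)
    }
    k <- nrow(x$T)
    T <- matrix(0, k, k)
    T[cbind(seq_len(k), apply(x$T, 1, which.max))] <- 1
    return(new_transition_model(T, "majority",
                                initial_weights = x$initial_weights,
                                empty_rows = x$empty_rows))
  }
  k <- if (inherits(x, "transition_model")) nrow(x$T) else as.integer(x)
  if (kind == "identity") {
    return(new_transition_model(diag(k), "identity"))
  }
  T <- with_seed(seed, {
    G <- matrix(stats::rgamma(k * k, shape = 1), k, k)
    G / rowSums(G)
  })
  new_transition_model(T, "random")
}

#' Cross-validated prediction error of transition models
#'
#' Ten-fold (by default) cross-validation of the Shape Transition Model
#' against the majority, identity and random baselines. Spines are split
#' into folds as paired (t0, t1) units; per fold, the shape taxonomy is
#' refit on the training spines (both time points), training memberships
#' yield the transition estimates, and held-out spines are assigned into
#' the taxonomy via the model's assignment rule (crisp: first nearest
#' neighbour; fuzzy: membership formula) at t0 and at t1, the latter
#' serving as the derived memberships the prediction is scored against.
#'
#' @param reduced A [reduce_features()] result (both time points per
#'   spine).
#' @param method Clustering method, `"hier"` (crisp estimator) or
#'   `"cmeans"` (QP estimator).
#' @param k,m Clustering parameters (`m` for `"cmeans"` only).
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold split, clustering restarts and the
#'   random baseline.
#' @return Data frame of class `cv_result`: one row per model
#'   (`stm`, `majority`, `identity`, `random`) with `mean_E` and `sd_E`
#'   across folds.
#' @export
cross_validate <- function(reduced, method = c("hier", "cmeans"), k,
                           m = 2, folds = 10, seed = 1) {
  method <- match.arg(method)
  ids <- unique(reduced$spine_id)
  n <- length(ids)
  if (folds > n) stop("more folds than spines", call. = FALSE)
  fold_of <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  seeds <- replicate_seeds(seed, folds)
  r0 <- reduced[reduced$time == "t0", ]
  r1 <- reduced[reduced$time == "t1", ]
  r0 <- r0[match(ids, r0$spine_id), ]
  r1 <- r1[match(ids, r1$spine_id), ]
  X0 <- as.matrix(r0[, c("comp1", "comp2")])
  X1 <- as.matrix(r1[, c("comp1", "comp2")])

  models <- c("stm", "majority", "identity", "random")
  E <- matrix(NA_real_, folds, length(models),
              dimnames = list(NULL, models))
  for (f in seq_len(folds)) {
    train <- fold_of != f
    Xtrain <- rbind(X0[train, , drop = FALSE], X1[train, , drop = FALSE])
    fit <- if (method == "hier") fit_hierarchical(Xtrain, k)
           else fit_cmeans(Xtrain, k, m = m, seed = seeds[f])
    ntr <- sum(train)
    W0tr <- fit$W[seq_len(ntr), , drop = FALSE]
    W1tr <- fit$W[ntr + seq_len(ntr), , drop = FALSE]
    stm <- if (method == "hier") estimate_crisp(W0tr, W1tr)
           else estimate_qp(W0tr, W1tr)
    W0te <- assign_new_spine(fit$model, X0[!train, , drop = FALSE])
    W1te <- assign_new_spine(fit$model, X1[!train, , drop = FALSE])
    E[f, "stm"] <- prediction_error(stm, W0te, W1te)$E
    E[f, "majority"] <- prediction_error(
      baseline_model(stm, "majority"), W0te, W1te)$E
    E[f, "identity"] <- prediction_error(
      baseline_model(k, "identity"), W0te, W1te)$E
    E[f, "random"] <- prediction_error(
      baseline_model(k, "random", seed = seeds[f]), W0te, W1te)$E
  }
  out <- data.frame(model = models, mean_E = colMeans(E),
                    sd_E = apply(E, 2, stats::sd),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fold_errors") <- E
  class(out) <- c("cv_result", "data.frame")
  out
}
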