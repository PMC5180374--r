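#' Principal component analysis of a descriptor block
#'
#' Covariance PCA (centered, no per-column rescaling) with a
#' deterministic sign convention: each component is oriented so that its
#' largest-magnitude loading is positive. Used on the size and contour
#' descriptor blocks to build interpretable reduced features.
#'
#' @param X Numeric matrix, observations in rows (`n >= 2`), descriptors
#'   in columns; all entries finite.
#' @param correlation If `TRUE`, PCA of the correlation matrix (columns
#'   standardized) instead of the covariance default.
#' @return Object of class `spine_pca`: list with `loadings` (components
#'   x descriptors, each row unit Euclidean norm), `center` (column means
#'   removed), `explained` (non-increasing variance fractions summing to
#'   1), `descriptors` (column names), and `scale` when `correlation`.
#' @export
fit_pca <- function(X, correlation = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 observations", call. = FALSE)
  if (any(!is.finite(X))) stop("PCA input must be finite", call. = FALSE)
  total_var <- sum(apply(X, 2, stats::var))
  if (total_var <= 0) {
    stop("degenerate data: all observations identical", call. = FALSE)
  }
  p <- stats::prcomp(X, center = TRUE, scale. = correlation)
  L <- t(p$rotation)               # components x descriptors
  rownames(L) <- NULL
  # sign convention: largest-|loading| entry of each component positive
  for (i in seq_len(nrow(L))) {
    j <- which.max(abs(L[i, ]))
    if (L[i, j] < 0) L[i, ] <- -L[i, ]
  }
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    loadings = L, center = p$center,
    scale = if (correlation) p$scale else NULL,
    explained = expl,
    descriptors = colnames(X)
  ), class = "spine_pca")
}

#' @export
print.spine_pca <- function(x, ...) {
  cat("PCA fit on ", length(x$descriptors), " descriptors; component 1 ",
      "explains ", sprintf("%.1f%%", 100 * x$explained[1]),
      " of variance\n", sep = "")
  invisible(x)
}

stack_descriptor_rows <- function(tables, descriptors) {
  if (inherits(tables, "spine_table")) tables <- list(tables)
  do.call(rbind, unlist(lapply(tables, function(tb) {
    list(descriptor_matrix(tb, "t0", descriptors),
         descriptor_matrix(tb, "t1", descriptors))
  }), recursive = FALSE))
}

#' Split PCA on size and contour descriptor blocks
#'
#' Fits two independent PCAs — one on the size descriptors
#' (length, circumference, area) and one on the contour descriptors —
#' using the rows of all supplied populations at both time points pooled
#' together (each spine contributes two rows). The first component of the
#' size block is a generalized size descriptor (Comp.1) and the first
#' component of the contour block a generalized slenderness descriptor
#' (Comp.2); small loadings are dropped at projection time (see
#' [reduce_features()]).
#'
#' @param tables A spine table or list of spine tables (e.g., both
#'   populations) pooled for the fit.
#' @param truncation Loading-magnitude threshold stored with the fit
#'   (default 0.10); applied by [reduce_features()].
#' @param correlation Passed to [fit_pca()].
#' @return Object of class `split_pca`: list with `size` and `contour`
#'   `spine_pca` fits and the `truncation` threshold.
#' @export
fit_split_pca <- function(tables, truncation = 0.10, correlation = FALSE) {
  schema <- if (inherits(tables, "spine_table")) attr(tables, "schema")
            else attr(tables[[1]], "schema")
  Xs <- stack_descriptor_rows(tables, schema$size_set)
  Xc <- stack_descriptor_rows(tables, schema$contour_set)
  structure(list(
    size = fit_pca(Xs, correlation = correlation),
    contour = fit_pca(Xc, correlation = correlation),
    truncation = truncation
  ), class = "split_pca")
}

#' @export
print.split_pca <- function(x, ...) {
  fmt <- function(pca) {
    v <- truncate_loadings(pca$loadings[1, ], 0)  # as fitted
    paste(sprintf("%+.2f*%s", v, pca$descriptors), collapse = " ")
  }
  cat("Split PCA (truncation ", x$truncation, ")\n", sep = "")
  cat("  Comp.1 (size):    ", fmt(x$size), "\n", sep = "")
  cat("  Comp.2 (contour): ", fmt(x$contour), "\n", sep = "")
  invisible(x)
}

#' Drop small loadings from a component
#'
#' Sets loading entries with magnitude below `threshold` to zero and
#' renormalizes the remainder to unit Euclidean norm, so projections stay
#' scale-comparable after truncation.
#'
#' @param v Numeric loading vector (nonzero).
#' @param threshold Magnitude threshold in `[0, 1)`; default 0.10.
#' @return Truncated, renormalized loading vector (names preserved).
#' @export
truncate_loadings <- function(v, threshold = 0.10) {
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must be in [0, 1)", call. = FALSE)
  }
  w <- ifelse(abs(v) < threshold, 0, v)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) {
    stop("all loadings below threshold; nothing left to project on",
         call. = FALSE)
  }
  w / nrm
}

#' Project spines onto the reduced (Comp.1, Comp.2) representation
#'
#' Projects every spine at both time points onto the truncated first
#' components of the split PCA: `comp1` is the generalized size
#' coordinate (size descriptors only), `comp2` the generalized
#' slenderness coordinate (contour descriptors only). Descriptors are
#' centered with the means stored in the fit before projection.
#'
#' @param tables A spine table or list of spine tables.
#' @param fit A [fit_split_pca()] result.
#' @param truncation Loading threshold; defaults to the one stored in
#'   `fit`.
#' @return Object of class `reduced_features`: a data frame with columns
#'   `spine_id`, `population`, `time` (`"t0"`/`"t1"`), `comp1`, `comp2`
#'   (two rows per spine), with the truncated loading vectors attached as
#'   attribute `"loadings"`.
#' @export
reduce_features <- function(tables, fit, truncation = fit$truncation) {
  if (inherits(tables, "spine_table")) tables <- list(tables)
  schema <- attr(tables[[1]], "schema")
  l1 <- truncate_loadings(fit$size$loadings[1, ], truncation)
  l2 <- truncate_loadings(fit$contour$loadings[1, ], truncation)
  project <- function(tb, time) {
    Xs <- sweep(descriptor_matrix(tb, time, schema$size_set), 2,
                fit$size$center)
    Xc <- sweep(descriptor_matrix(tb, time, schema$contour_set), 2,
                fit$contour$center)
    if (!is.null(fit$size$scale)) {
      Xs <- sweep(Xs, 2, fit$size$scale, "/")
      Xc <- sweep(Xc, 2, fit$contour$scale, "/")
    }
    data.frame(
      spine_id = tb$spine_id, population = tb$population, time = time,
      comp1 = as.vector(Xs %*% l1),
      comp2 = as.vector(Xc %*% l2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unlist(lapply(tables, function(tb) {
    list(project(tb, "t0"), project(tb, "t1"))
  }), recursive = FALSE))
  rownames(out) <- NULL
  structure(out, loadings = list(comp1 = l1, comp2 = l2),
            class = c("reduced_features", "data.frame"))
}

#' Feature-space matrix of a reduced representation
#'
#' @param reduced A [reduce_features()] result.
#' @param time `"t0"`, `"t1"`, or `"both"` (default; stacked, t0 rows
#'   first).
#' @return Numeric matrix with columns `comp1`, `comp2`.
#' @export
feature_matrix <- function(reduced, time = c("both", "t0", "t1")) {
  time <- match.arg(time)
  r <- if (time == "both") reduced[order(reduced$time), , drop = FALSE]
       else reduced[reduced$time == time, , drop = FALSE]
  X <- as.matrix(r[, c("comp1", "comp2")])
  rownames(X) <- paste(r$spine_id, r$time, sep = "@")
  X
}
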