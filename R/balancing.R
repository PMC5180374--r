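#' Normalized Euclidean distance between descriptor vectors
#'
#' Distance used by the balanced-pair selection: each descriptor
#' difference is divided by a per-descriptor scale (by default the pooled
#' standard deviation, see [select_balanced_pairs()]) before the Euclidean
#' norm is taken: `sqrt(sum(((x - y) / scale)^2))`.
#'
#' @param x,y Numeric descriptor vectors of equal length.
#' @param scale Strictly positive per-descriptor scale constants.
#' @return Non-negative scalar; zero iff `x == y`.
#' @export
normalized_distance <- function(x, y, scale = rep(1, length(x))) {
  if (length(x) != length(y) || length(scale) != length(x)) {
    stop("x, y and scale must have the same length", call. = FALSE)
  }
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    stop("scale entries must be strictly positive; drop constant ",
         "descriptors or set their scale to 1", call. = FALSE)
  }
  sqrt(sum(((x - y) / scale)^2))
}

pooled_scale <- function(XA, XB) {
  s <- apply(rbind(XA, XB), 2, stats::sd)
  if (any(s == 0)) {
    warning("constant descriptor(s) in pooled data: ",
            paste(colnames(XA)[s == 0], collapse = ", "),
            "; using scale 1 for them", call. = FALSE)
    s[s == 0] <- 1
  }
  s
}

#' Select balanced subpopulations by greedy closest-pair matching
#'
#' Builds balanced subsets of two populations by repeatedly drawing the
#' globally closest unmatched cross-population pair of spines, where
#' closeness is the normalized Euclidean distance between t0 descriptor
#' vectors. Matching is without replacement: each spine is used at most
#' once. This is the procedure that turns two unequal source populations
#' into matched cohorts whose per-descriptor means no longer differ
#' significantly (see [balance_report()]).
#'
#' @param A,B Spine tables for the two populations.
#' @param n_pairs Number of pairs to draw; at most `min(nrow(A), nrow(B))`.
#' @param scale Per-descriptor normalization constants for the distance;
#'   default (`NULL`) uses the standard deviation of the pooled t0 values
#'   of `A` and `B`. Recorded in the result for reproducibility.
#' @return An object of class `balanced_selection`: list with `pairs`
#'   (data frame `id_a`, `id_b`, `distance`, in draw order, distances
#'   non-decreasing), `n_pairs`, `scale`, and the induced subtables
#'   `subset_a`, `subset_b` (row order = draw order).
#' @details Ties in distance are broken by `(id_a, id_b)` lexicographic
#'   order so the selection is deterministic.
#' @export
select_balanced_pairs <- function(A, B, n_pairs, scale = NULL) {
  XA <- descriptor_matrix(A, "t0")
  XB <- descriptor_matrix(B, "t0")
  if (n_pairs < 1 || n_pairs > min(nrow(XA), nrow(XB))) {
    stop("n_pairs must be between 1 and min(|A|, |B|) = ",
         min(nrow(XA), nrow(XB)), call. = FALSE)
  }
  if (is.null(scale)) scale <- pooled_scale(XA, XB)
  if (any(scale <= 0)) stop("scale must be strictly positive", call. = FALSE)

  ZA <- sweep(XA, 2, scale, "/")
  ZB <- sweep(XB, 2, scale, "/")
  # full cross-distance matrix, accumulated per descriptor: exact zeros
  # for identical spines (the Gram-matrix shortcut is not)
  d2 <- matrix(0, nrow(ZA), nrow(ZB))
  for (d in seq_len(ncol(ZA))) {
    d2 <- d2 + outer(ZA[, d], ZB[, d], "-")^2
  }
  D <- sqrt(d2)

  ia <- rep(seq_len(nrow(D)), times = ncol(D))
  ib <- rep(seq_len(ncol(D)), each = nrow(D))
  ord <- order(as.vector(D), A$spine_id[ia], B$spine_id[ib])
  used_a <- logical(nrow(D)); used_b <- logical(ncol(D))
  sel_a <- integer(n_pairs); sel_b <- integer(n_pairs)
  sel_d <- numeric(n_pairs)
  got <- 0L
  for (idx in ord) {
    i <- ia[idx]; j <- ib[idx]
    if (used_a[i] || used_b[j]) next
    got <- got + 1L
    used_a[i] <- TRUE; used_b[j] <- TRUE
    sel_a[got] <- i; sel_b[got] <- j; sel_d[got] <- D[i, j]
    if (got == n_pairs) break
  }
  pairs <- data.frame(id_a = A$spine_id[sel_a], id_b = B$spine_id[sel_b],
                      distance = sel_d, stringsAsFactors = FALSE)
  structure(list(
    pairs = pairs, n_pairs = n_pairs, scale = scale,
    subset_a = spine_table(as.data.frame(A)[sel_a, , drop = FALSE],
                           schema = attr(A, "schema")),
    subset_b = spine_table(as.data.frame(B)[sel_b, , drop = FALSE],
                           schema = attr(B, "schema"))
  ), class = "balanced_selection")
}

#' @export
print.balanced_selection <- function(x, ...) {
  cat("Balanced selection: ", x$n_pairs, " closest cross-population ",
      "pairs\n", sep = "")
  cat("  distance range: [", format(min(x$pairs$distance), digits = 4),
      ", ", format(max(x$pairs$distance), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Per-descriptor balance report between two populations
#'
#' For each of the 11 descriptors, reports group means and standard
#' deviations plus the p-value of a Welch two-sample two-tailed t-test of
#' the difference in means — the layout used to assess whether two
#' populations (or their balanced subsets) are comparable at a time point.
#'
#' @param A,B Spine tables (each with at least 2 spines).
#' @param time `"t0"` (default) or `"t1"`.
#' @return A data frame of class `balance_report` with columns
#'   `descriptor`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `p_value`.
#' @export
balance_report <- function(A, B, time = c("t0", "t1")) {
  time <- match.arg(time)
  XA <- descriptor_matrix(A, time)
  XB <- descriptor_matrix(B, time)
  if (nrow(XA) < 2 || nrow(XB) < 2) {
    stop("each group needs at least 2 spines for a t-test", call. = FALSE)
  }
  res <- lapply(colnames(XA), function(nm) {
    a <- XA[, nm]; b <- XB[, nm]
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      1  # identical constant samples: no evidence of difference
    } else {
      stats::t.test(a, b, var.equal = FALSE)$p.value
    }
    data.frame(descriptor = nm, mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("balance_report", "data.frame")
  out
}
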