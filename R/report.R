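#' Build a filtered transition graph
#'
#' Turns a transition model into a graph whose nodes are shape clusters
#' (labelled with their initial total weights — the number of spines per
#' cluster in the crisp case) and whose edges are the transitions
#' surviving the probability filter, by default those with probability
#' above 20%. With `filter_mode = "mass"` the filter is applied to the
#' transported initial weight (`probability * initial weight of the
#' source cluster`) relative to the source weight times the threshold —
#' an alternative reading of "20% of the initial weight".
#'
#' @param model A `transition_model` (optionally carrying an `se`
#'   matrix, which is attached to the surviving edges).
#' @param threshold Filter threshold in `[0, 1)` (default 0.20).
#' @param filter_mode `"prob"` (default) keeps edges with
#'   `T[n, m] > threshold`; `"mass"` keeps edges moving more than
#'   `threshold` of the source cluster's initial weight (equivalent for
#'   occupied clusters, but drops all edges out of empty ones).
#' @return Object of class `transition_graph`: list with `nodes` (data
#'   frame `cluster`, `weight`) and `edges` (data frame `from`, `to`,
#'   `probability`, optional `se`), deterministically ordered.
#' @export
build_graph <- function(model, threshold = 0.20,
                        filter_mode = c("prob", "mass")) {
  filter_mode <- match.arg(filter_mode)
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must be in [0, 1)", call. = FALSE)
  }
  T <- model$T
  k <- nrow(T)
  w0 <- model$initial_weights
  if (is.null(w0)) w0 <- rep(NA_real_, k)
  keep <- if (filter_mode == "prob") T > threshold else
    sweep(T, 1, w0, "*") > threshold * pmax(w0, 0)
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  edges <- data.frame(from = idx[, 1], to = idx[, 2],
                      probability = T[idx])
  if (!is.null(model$se)) edges$se <- model$se[idx]
  structure(list(
    nodes = data.frame(cluster = seq_len(k), weight = w0),
    edges = edges, threshold = threshold, filter_mode = filter_mode
  ), class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("Transition graph: ", nrow(x$nodes), " clusters, ",
      nrow(x$edges), " edges (filter: ", x$filter_mode, " > ",
      x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Export a transition graph in DOT format
#'
#' Writes a standard DOT digraph: one node per shape cluster labelled
#' with its initial weight, one edge per surviving transition labelled
#' with the probability in integer percent (with "p +/- se" when
#' standard errors are available). Full-precision values live in the
#' model JSON; the DOT file is a rendering artifact.
#'
#' @param graph A [build_graph()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_dot <- function(graph, path) {
  lines <- c("digraph transitions {", "  rankdir=LR;")
  for (i in seq_len(nrow(graph$nodes))) {
    w <- graph$nodes$weight[i]
    lbl <- if (is.na(w)) sprintf("C%d", graph$nodes$cluster[i]) else
      sprintf("C%d\\n(%s)", graph$nodes$cluster[i],
              format(round(w, 1)))
    lines <- c(lines, sprintf("  n%d [label=\"%s\"];",
                              graph$nodes$cluster[i], lbl))
  }
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    lbl <- sprintf("%d%%", round(100 * e$probability))
    if (!is.null(graph$edges$se) && !is.na(e$se)) {
      lbl <- sprintf("%d%% ± %d%%", round(100 * e$probability),
                     round(100 * e$se))
    }
    lines <- c(lines, sprintf("  n%d -> n%d [label=\"%s\"];",
                              e$from, e$to, lbl))
  }
  lines <- c(lines, "}")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write DOT file '",
                                           path, "': ",
                                           conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
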