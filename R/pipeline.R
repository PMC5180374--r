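#' Fit the shape taxonomy on reduced features
#'
#' Fits the chosen clustering on the union of all populations at both
#' time points (each spine contributes its t0 and t1 rows, so the
#' taxonomy describes both time points equally well) and splits the
#' memberships back into per-population t0/t1 matrices.
#'
#' @param reduced A [reduce_features()] result.
#' @param method `"hier"` or `"cmeans"`.
#' @param k,m Clustering parameters.
#' @param seed,restarts Passed to [fit_cmeans()].
#' @return List with `model` (`cluster_model`) and `groups`: a named
#'   list per population, each with `ids`, `W0` and `W1` (rows aligned
#'   with `ids`).
#' @export
fit_taxonomy <- function(reduced, method = c("hier", "cmeans"), k,
                         m = 2, seed = 1, restarts = 5) {
  method <- match.arg(method)
  r0 <- reduced[reduced$time == "t0", ]
  r1 <- reduced[reduced$time == "t1", ]
  key0 <- paste(r0$population, r0$spine_id)
  r1 <- r1[match(key0, paste(r1$population, r1$spine_id)), ]
  X <- rbind(as.matrix(r0[, c("comp1", "comp2")]),
             as.matrix(r1[, c("comp1", "comp2")]))
  stopifnot(nrow(X) == 2 * nrow(r0))  # two rows per spine
  fit <- if (method == "hier") fit_hierarchical(X, k)
         else fit_cmeans(X, k, m = m, seed = seed, restarts = restarts)
  n <- nrow(r0)
  W0 <- fit$W[seq_len(n), , drop = FALSE]
  W1 <- fit$W[n + seq_len(n), , drop = FALSE]
  groups <- lapply(split(seq_len(n), r0$population), function(ix) {
    list(ids = r0$spine_id[ix], W0 = W0[ix, , drop = FALSE],
         W1 = W1[ix, , drop = FALSE])
  })
  list(model = fit$model, groups = groups)
}

write_membership_csv <- function(groups, path) {
  rows <- do.call(rbind, lapply(names(groups), function(g) {
    gr <- groups[[g]]
    k <- ncol(gr$W0)
    out <- rbind(
      data.frame(spine_id = gr$ids, population = g, time = "t0",
                 gr$W0, stringsAsFactors = FALSE),
      data.frame(spine_id = gr$ids, population = g, time = "t1",
                 gr$W1, stringsAsFactors = FALSE))
    names(out)[-(1:3)] <- paste0("w_", seq_len(k))
    out
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full shape-taxonomy and transition-analysis pipeline
#'
#' Deterministic end-to-end driver: optional balanced subset selection,
#' split-PCA feature reduction on the pooled populations, shape
#' clustering on the union of both populations at both time points,
#' per-population transition models with bootstrap standard errors,
#' RDC/SMD bootstrap comparison tests, and filtered transition graphs.
#' With `out_dir` set, all artifacts are written to disk (CSV/JSON/DOT)
#' together with a run log recording every seed used.
#'
#' @param A,B Spine tables for the two populations.
#' @param n_pairs Number of balanced pairs to select before analysis;
#'   `NULL` (default) skips balancing.
#' @param method Clustering method (`"hier"` or `"cmeans"`).
#' @param k,m Clustering parameters.
#' @param truncation PCA loading truncation threshold.
#' @param R_se Bootstrap replicates for transition-probability standard
#'   errors (0 skips them).
#' @param R_test Bootstrap replicates for the RDC/SMD tests (0 skips).
#' @param edge_threshold Transition-graph filter threshold.
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return List of class `spinetax_run` with elements `balance`
#'   (selection + before/after reports, when balancing), `pca`,
#'   `reduced`, `taxonomy`, `transitions` (per population, with `se`),
#'   `tests` (per statistic), `graphs`, and `log` (character vector).
#' @export
run_pipeline <- function(A, B, n_pairs = NULL,
                         method = c("hier", "cmeans"), k = 5, m = 2,
                         truncation = 0.10, R_se = 200, R_test = 200,
                         edge_threshold = 0.20, seed = 1,
                         out_dir = NULL) {
  method <- match.arg(method)
  log <- c(sprintf("spinetax pipeline; master seed = %d", seed),
           sprintf("populations: %s (n=%d), %s (n=%d)",
                   A$population[1], nrow(A), B$population[1], nrow(B)))
  seeds <- replicate_seeds(seed, 5)
  balance <- NULL
  if (!is.null(n_pairs)) {
    before <- balance_report(A, B, "t0")
    sel <- select_balanced_pairs(A, B, n_pairs)
    A <- sel$subset_a; B <- sel$subset_b
    after <- balance_report(A, B, "t0")
    balance <- list(selection = sel, before = before, after = after)
    log <- c(log, sprintf("balancing: selected %d closest pairs", n_pairs))
  }
  pca <- fit_split_pca(list(A, B), truncation = truncation)
  reduced <- reduce_features(list(A, B), pca)
  log <- c(log, sprintf(
    "reduction: size Comp.1 %.1f%%, contour Comp.2 %.1f%% of block variance",
    100 * pca$size$explained[1], 100 * pca$contour$explained[1]))
  tax <- fit_taxonomy(reduced, method = method, k = k, m = m,
                      seed = seeds[1])
  log <- c(log, sprintf("taxonomy: %s, k = %d%s (clustering seed %d)",
                        method, k,
                        if (method == "cmeans") sprintf(", m = %g", m)
                        else "", seeds[1]))
  estimator <- if (method == "hier") "crisp" else "qp"
  transitions <- lapply(tax$groups, function(gr) {
    mod <- if (estimator == "crisp") estimate_crisp(gr$W0, gr$W1)
           else estimate_qp(gr$W0, gr$W1)
    if (R_se > 0) {
      mod$se <- bootstrap_se(gr$W0, gr$W1, method = estimator, R = R_se,
                             seed = seeds[2])
    }
    mod
  })
  log <- c(log, sprintf("transitions: %s estimator, SE bootstrap R = %d (seed %d)",
                        estimator, R_se, seeds[2]))
  tests <- NULL
  if (R_test > 0) {
    tests <- bootstrap_test(A, B, statistic = c("rdc", "smd"),
                            method = method, k = k, m = m, R = R_test,
                            seed = seeds[3], truncation = truncation)
    log <- c(log, sprintf("tests: RDC p = %.4f, SMD p = %.4f (R = %d, seed %d)",
                          tests$rdc$p_value, tests$smd$p_value, R_test,
                          seeds[3]))
  }
  graphs <- lapply(transitions, build_graph, threshold = edge_threshold)
  out <- structure(list(balance = balance, pca = pca, reduced = reduced,
                        taxonomy = tax, transitions = transitions,
                        tests = tests, graphs = graphs, log = log),
                   class = "spinetax_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_artifacts(out, out_dir)
  }
  out
}

write_run_artifacts <- function(run, out_dir) {
  fp <- function(...) file.path(out_dir, ...)
  if (!is.null(run$balance)) {
    write_spine_table(run$balance$selection$subset_a, fp("subset_a.csv"))
    write_spine_table(run$balance$selection$subset_b, fp("subset_b.csv"))
    utils::write.csv(run$balance$before, fp("balance_before.csv"),
                     row.names = FALSE)
    utils::write.csv(run$balance$after, fp("balance_after.csv"),
                     row.names = FALSE)
  }
  write_model(run$pca, fp("split_pca.json"))
  utils::write.csv(as.data.frame(run$reduced), fp("reduced.csv"),
                   row.names = FALSE)
  write_membership_csv(run$taxonomy$groups, fp("memberships.csv"))
  for (g in names(run$transitions)) {
    write_model(run$transitions[[g]],
                fp(sprintf("transition_%s.json", g)))
    export_dot(run$graphs[[g]], fp(sprintf("transitions_%s.dot", g)))
  }
  if (!is.null(run$tests)) {
    for (st in names(run$tests)) {
      t <- run$tests[[st]]
      jsonlite::write_json(
        list(statistic = t$statistic, observed = t$observed,
             p_value = t$p_value, R = t$R, seed = t$seed),
        fp(sprintf("test_%s.json", st)), auto_unbox = TRUE, digits = NA)
      utils::write.csv(data.frame(replicate = seq_along(t$null),
                                  statistic = t$null),
                       fp(sprintf("null_%s.csv", st)), row.names = FALSE)
    }
  }
  writeLines(run$log, fp("run_log.txt"))
  invisible(out_dir)
}

#' @export
print.spinetax_run <- function(x, ...) {
  cat("spinetax pipeline run\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
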