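# Shared fixtures: all synthetic, built in code.

desc_names <- descriptor_schema()$names

# A minimal valid wide-format data frame with n spines; descriptor values
# are positive and rounded so CSV round trips are exact.
make_wide_df <- function(n, population = "POP", seed = 1,
                         prefix = "s") {
  set.seed(seed)
  df <- data.frame(spine_id = paste0(prefix, seq_len(n)),
                   population = population, stringsAsFactors = FALSE)
  for (nm in desc_names) {
    df[[paste0(nm, "_t0")]] <- round(runif(n, 0.2, 3), 6)
    df[[paste0(nm, "_t1")]] <- round(runif(n, 0.2, 3), 6)
  }
  df
}

make_table <- function(n, population = "POP", seed = 1, prefix = "s") {
  spine_table(make_wide_df(n, population, seed, prefix))
}

membership_from_labels_test <- function(labels, k) {
  W <- matrix(0, length(labels), k)
  W[cbind(seq_along(labels), labels)] <- 1
  W
}

# Random one-hot membership matrix with every cluster occupied.
random_crisp_W <- function(n, k) {
  labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  W <- matrix(0, n, k)
  W[cbind(seq_len(n), labels)] <- 1
  W
}

# Random fuzzy membership matrix (rows on the simplex interior).
random_fuzzy_W <- function(n, k) {
  W <- matrix(rexp(n * k), n, k)
  W / rowSums(W)
}

# Random row-stochastic matrix.
random_stochastic <- function(k) {
  T <- matrix(rexp(k * k), k, k)
  T / rowSums(T)
}

# Two well-separated Gaussian blobs in 2-D.
make_blobs <- function(n_per = 30, gap = 10, sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- rbind(
    cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
    cbind(rnorm(n_per, gap, sd), rnorm(n_per, 0, sd)))
  list(X = X, labels = rep(1:2, each = n_per))
}
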