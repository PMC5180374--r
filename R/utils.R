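# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-replicate seed stream: the first n seeds are a stable
# prefix, so increasing R never perturbs earlier replicates.
replicate_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max, n))
}

check_membership <- function(W, tol = 1e-9, arg = "W") {
  W <- as.matrix(W)
  if (any(W < -tol)) stop(arg, " has negative membership weights",
                          call. = FALSE)
  if (any(abs(rowSums(W) - 1) > tol)) {
    stop(arg, " rows must sum to 1 (tolerance ", tol, ")", call. = FALSE)
  }
  W
}

is_one_hot <- function(W, tol = 1e-9) {
  all(abs(W - round(W)) <= tol) && all(round(W) %in% c(0, 1)) &&
    all(abs(rowSums(W) - 1) <= tol)
}
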