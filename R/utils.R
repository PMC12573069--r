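# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic child seeds spawned from a master seed (kept < 2^31).
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

upper_tri_values <- function(M) M[upper.tri(M)]

# Names "a--b" for the upper-triangle edges of a p x p matrix.
edge_names <- function(ids) {
  idx <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
  paste0(ids[idx[, 1]], "--", ids[idx[, 2]])
}

is_square_sym <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
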