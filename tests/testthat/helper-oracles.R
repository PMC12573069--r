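# Shared fixtures and independent oracles used across the suite.

# Enumerate all set partitions of n elements (restricted growth strings).
all_partitions <- function(n) {
  out <- vector("list", 0)
  rec <- function(pref, maxl) {
    if (length(pref) == n) {
      out[[length(out) + 1]] <<- pref
      return(invisible())
    }
    for (l in seq_len(maxl + 1)) rec(c(pref, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  out
}

# Signed Spinglass energy computed directly from the definition,
# independent of the package's implementation.
brute_hamiltonian <- function(W, memb) {
  p <- ncol(W)
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  diag(Wp) <- 0; diag(Wn) <- 0
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  mp <- sum(sp); mn <- sum(sn)
  H <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (memb[i] != memb[j]) next
      pos <- Wp[i, j] - (if (mp > 0) sp[i] * sp[j] / mp else 0)
      neg <- Wn[i, j] - (if (mn > 0) sn[i] * sn[j] / mn else 0)
      H <- H - (pos - neg)
    }
  }
  unname(H)
}

# Exhaustive-enumeration minimum energy over all partitions.
brute_min_hamiltonian <- function(W) {
  parts <- all_partitions(ncol(W))
  min(vapply(parts, function(m) brute_hamiltonian(W, m), numeric(1)))
}

# Random signed weighted graph with at least one nonzero edge.
random_signed_graph <- function(p, density = 0.5, wmin = -0.5,
                                wmax = 0.5) {
  repeat {
    W <- matrix(0, p, p)
    ut <- which(upper.tri(W))
    on <- runif(length(ut)) < density
    W[ut[on]] <- runif(sum(on), wmin, wmax)
    W <- W + t(W)
    colnames(W) <- rownames(W) <- paste0("n", seq_len(p))
    if (any(W != 0)) return(W)
  }
}

# Dense penalized-likelihood solver: general-purpose optimizer over the
# free parameters of a symmetric Theta with a smoothed L1 penalty.
oracle_glasso <- function(S, lambda, eps = 1e-12) {
  p <- ncol(S)
  unpack <- function(par) {
    Th <- matrix(0, p, p)
    Th[upper.tri(Th, diag = TRUE)] <- par
    Th + t(Th) - diag(diag(Th))
  }
  obj <- function(par) {
    Th <- unpack(par)
    ch <- tryCatch(chol(Th), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ld <- 2 * sum(log(diag(ch)))
    pen <- 2 * lambda * sum(sqrt(Th[upper.tri(Th)]^2 + eps))
    -(ld - sum(S * Th)) + pen
  }
  par <- diag(p)[upper.tri(diag(p), diag = TRUE)]
  for (m in c("BFGS", "Nelder-Mead", "BFGS")) {
    fit <- stats::optim(par, obj, method = m,
                        control = list(maxit = 50000, reltol = 1e-15))
    par <- fit$par
  }
  unpack(par)
}

# Random sparse positive-definite precision matrix (unit-ish diagonal).
random_precision <- function(p, density = 0.3, wmin = 0.1, wmax = 0.3) {
  W <- matrix(0, p, p)
  ut <- which(upper.tri(W))
  on <- runif(length(ut)) < density
  W[ut[on]] <- runif(sum(on), wmin, wmax)
  W <- W + t(W)
  Th <- diag(p) - W
  ev <- min(eigen(Th, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 0.05) diag(Th) <- diag(Th) + (0.05 - ev)
  colnames(Th) <- rownames(Th) <- paste0("v", seq_len(p))
  Th
}

# Gaussian sample with the correlation implied by a precision matrix.
sample_gaussian <- function(theta, n) {
  Sigma <- solve(theta)
  d <- sqrt(diag(Sigma))
  Sigma <- Sigma / outer(d, d)
  Z <- matrix(rnorm(n * ncol(theta)), n) %*% chol(Sigma)
  colnames(Z) <- colnames(theta)
  Z
}

# Small ordinal fixture: 4 items, no missingness.
toy_items <- function(n = 40, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    m <- matrix(sample(0:3, n * 4, replace = TRUE), n, 4,
                dimnames = list(NULL, paste0("it", 1:4)))
    item_response_matrix(m)
  })
}

# Recovery metrics of an estimated weight matrix against a truth pattern.
edge_recovery <- function(W_est, W_true) {
  ut <- upper.tri(W_true)
  truth <- W_true[ut] != 0
  est <- W_est[ut] != 0
  c(sensitivity = sum(est & truth) / sum(truth),
    specificity = sum(!est & !truth) / sum(!truth))
}
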