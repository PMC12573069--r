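# Gaussian graphical model estimation: graphical lasso over a log-spaced
# penalty path, extended-BIC model selection, and conversion of the
# selected precision matrix to partial-correlation edge weights.

#' Penalty path for the graphical lasso
#'
#' `n_lambda` values log-spaced from the largest absolute off-diagonal
#' correlation (the saturation point above which the graph is empty) down
#' to `lambda_min_ratio` times it.
#'
#' @param S Correlation matrix or `cor_matrix`.
#' @param n_lambda Number of values (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest value (default
#'   0.01).
#' @return Numeric vector of penalties, descending.
#' @export
lambda_path <- function(S, n_lambda = 100, lambda_min_ratio = 0.01) {
  if (inherits(S, "cor_matrix")) S <- S$S
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax == 0) {
    warnf("all off-diagonal correlations are zero; degenerate path")
    return(0)
  }
  if (lambda_min_ratio >= 1) return(rep(lmax, n_lambda))
  exp(seq(log(lmax), log(lambda_min_ratio * lmax),
          length.out = n_lambda))
}

#' Graphical lasso fit at a single penalty
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lambda * sum |Theta_ij|`
#' (off-diagonal penalty) by block coordinate descent. Convergence when
#' the largest parameter change in a sweep falls below `tol`, or after
#' `max_sweeps` sweeps.
#'
#' @param S Correlation matrix (must be positive semidefinite) or
#'   `cor_matrix`.
#' @param lambda Penalty, `>= 0`.
#' @param tol Convergence tolerance (default 1e-6).
#' @param max_sweeps Sweep cap (default 10000).
#' @param warm Optional warm start: list with elements `w` and `beta`
#'   from a previous fit.
#' @param zero_tol Entries of Theta below this magnitude are treated as
#'   exact zeros (default 1e-8).
#' @param check Validate symmetry and positive semidefiniteness of `S`
#'   (default TRUE; [estimate_network()] validates once for a whole
#'   path).
#' @param keep_warm Attach the warm-start state (attributes `"w"` and
#'   `"beta"`) for reuse along a penalty path (default FALSE).
#' @return The estimated precision matrix.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-6, max_sweeps = 10000,
                       warm = NULL, zero_tol = 1e-8, check = TRUE,
                       keep_warm = FALSE) {
  if (inherits(S, "cor_matrix")) S <- S$S
  if (lambda < 0) stopf("lambda must be >= 0")
  if (check) {
    if (!is_square_sym(S)) stopf("S must be a symmetric matrix")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stopf("S is not positive semidefinite (min eigenvalue %.3g); repair it first",
            min(ev))
  }
  fit <- glasso_cd(S, lambda,
                   W0 = if (is.null(warm)) NULL else warm$w,
                   B0 = if (is.null(warm)) NULL else warm$beta,
                   tol = tol, max_sweeps = as.integer(max_sweeps))
  theta <- fit$theta
  off <- abs(theta) < zero_tol
  diag(off) <- FALSE
  theta[off] <- 0
  dimnames(theta) <- dimnames(S)
  if (keep_warm) {
    attr(theta, "w") <- fit$w
    attr(theta, "beta") <- fit$beta
  }
  theta
}

#' Extended Bayesian information criterion
#'
#' `EBIC = -2 L + E log(n) + 4 E gamma log(p)` with Gaussian
#' log-likelihood `L = (n/2)(log det Theta - tr(S Theta))` and `E` the
#' number of nonzero upper-triangle entries of `Theta`. `gamma = 0`
#' reduces to the BIC; `gamma = 0.5` is the conservative default.
#'
#' @param theta Precision matrix (positive definite).
#' @param S Correlation matrix used in the fit.
#' @param n Effective sample size.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @return The EBIC score (lower is better), with attributes `"loglik"`
#'   and `"n_edges"`.
#' @export
ebic <- function(theta, S, n, gamma = 0.5) {
  if (inherits(S, "cor_matrix")) S <- S$S
  p <- ncol(theta)
  ch <- tryCatch(chol(theta), error = function(e) NULL)
  if (is.null(ch)) stopf("theta is not positive definite")
  logdet <- 2 * sum(log(diag(ch)))
  L <- (n / 2) * (logdet - sum(S * theta))
  E <- sum(theta[upper.tri(theta)] != 0)
  score <- -2 * L + E * log(n) + 4 * E * gamma * log(p)
  attr(score, "loglik") <- L
  attr(score, "n_edges") <- E
  score
}

#' Precision matrix to partial-correlation weights
#'
#' `W_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)`, diagonal zeroed. Entries
#' below `zero_tol` in magnitude are set to exact zero so sparsity counts
#' are stable.
#'
#' @param theta Precision matrix.
#' @param zero_tol Magnitude below which weights are exact zeros
#'   (default 1e-8).
#' @return Symmetric weight matrix with zero diagonal.
#' @export
precision_to_partial <- function(theta, zero_tol = 1e-8) {
  d <- diag(theta)
  if (any(d <= 0)) stopf("theta has non-positive diagonal")
  W <- -theta / sqrt(outer(d, d))
  diag(W) <- 0
  W <- (W + t(W)) / 2
  W[abs(W) < zero_tol] <- 0
  W
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso along the full penalty path (with warm
#' starts), scores every fit with the EBIC at `gamma`, selects the
#' minimizer — ties broken toward the larger penalty, i.e. the sparser
#' model — and converts the selected precision matrix to
#' partial-correlation edge weights.
#'
#' @param S `cor_matrix` from [spearman_matrix()], or a plain correlation
#'   matrix.
#' @param n Effective sample size; defaults to the median pairwise
#'   complete-case count when `S` is a `cor_matrix`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio Path settings (defaults 100, 0.01).
#' @param tol,max_sweeps Passed to [glasso_fit()].
#' @return A list of class `network_model`: `node_ids`, `theta`,
#'   `weights`, `lambda`, `ebic_gamma`, `n`, and `path` (a data.frame
#'   with per-penalty edge counts, log-likelihoods and EBIC scores).
#' @export
estimate_network <- function(S, n = NULL, gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01, tol = 1e-6,
                             max_sweeps = 10000) {
  if (inherits(S, "cor_matrix")) {
    if (is.null(n)) n <- median(S$pairwise_n[upper.tri(S$pairwise_n)])
    Sm <- S$S
  } else {
    Sm <- S
    if (is.null(n)) stopf("n is required when S is a plain matrix")
  }
  ids <- colnames(Sm)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(Sm)))
  if (!is_square_sym(Sm)) stopf("S must be a symmetric matrix")
  ev <- eigen(Sm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stopf("S is not positive semidefinite; repair it first (see spearman_matrix)")
  lambdas <- suppressWarnings(lambda_path(Sm, n_lambda, lambda_min_ratio))
  fits <- vector("list", length(lambdas))
  scores <- numeric(length(lambdas))
  edges <- integer(length(lambdas))
  logliks <- numeric(length(lambdas))
  warm <- NULL
  for (k in seq_along(lambdas)) {
    th <- glasso_fit(Sm, lambdas[k], tol = tol, max_sweeps = max_sweeps,
                     warm = warm, check = FALSE, keep_warm = TRUE)
    warm <- list(w = attr(th, "w"), beta = attr(th, "beta"))
    sc <- ebic(th, Sm, n, gamma)
    fits[[k]] <- th
    scores[k] <- as.numeric(sc)
    edges[k] <- attr(sc, "n_edges")
    logliks[k] <- attr(sc, "loglik")
  }
  # lambdas descend, so the first minimizer is the largest-lambda tie
  sel <- which.min(scores)
  theta <- fits[[sel]]
  attr(theta, "w") <- NULL
  attr(theta, "beta") <- NULL
  attr(theta, "converged") <- NULL
  dimnames(theta) <- list(ids, ids)
  W <- precision_to_partial(theta)
  dimnames(W) <- list(ids, ids)
  structure(list(node_ids = ids, theta = theta, weights = W,
                 lambda = lambdas[sel], lambda_index = sel,
                 ebic_gamma = gamma, n = n,
                 path = data.frame(lambda = lambdas, n_edges = edges,
                                   loglik = logliks, ebic = scores)),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  p <- length(x$node_ids)
  cand <- p * (p - 1) / 2
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf(
    "Regularized partial-correlation network: %d nodes\n", p))
  cat(sprintf("  %d of %d candidate edges nonzero (%.1f%%)\n", nz, cand,
              100 * nz / cand))
  cat(sprintf("  lambda = %.4g selected by EBIC (gamma = %.2f), n = %g\n",
              x$lambda, x$ebic_gamma, x$n))
  invisible(x)
}
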