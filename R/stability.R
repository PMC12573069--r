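# Bootstrap accuracy and stability: nonparametric bootstrap of edge
# weights and expected influence (quantile CIs and difference tests) and
# the case-dropping bootstrap with the correlation-stability coefficient.

# Default resample estimator: pairwise Spearman + EBIC glasso on the
# fixed node set, returning the upper-triangle weights and EI vector.
default_estimator <- function(gamma = 0.5, n_lambda = 100,
                              lambda_min_ratio = 0.01) {
  function(X, covariates) {
    S <- spearman_matrix(X, covariates)
    model <- estimate_network(S, gamma = gamma, n_lambda = n_lambda,
                              lambda_min_ratio = lambda_min_ratio)
    list(edges = upper_tri_values(model$weights),
         ei = rowSums(model$weights),
         node_ids = model$node_ids)
  }
}

resample_ok <- function(X, covariates) {
  M <- unclass(X)
  storage.mode(M) <- "double"
  if (!is.null(covariates)) M <- cbind(M, data.matrix(covariates))
  sds <- apply(M, 2, sd, na.rm = TRUE)
  all(!is.na(sds) & sds > 0)
}

# Significance matrix from bootstrap draws: CI of pairwise differences
# excluding 0 at level alpha. draws: B x K matrix.
diff_sig_matrix <- function(draws, names_k, alpha = 0.05) {
  K <- ncol(draws)
  sig <- matrix(FALSE, K, K, dimnames = list(names_k, names_k))
  lo_p <- alpha / 2
  hi_p <- 1 - alpha / 2
  for (i in seq_len(K - 1)) {
    d <- draws[, (i + 1):K, drop = FALSE] - draws[, i]
    qs <- apply(d, 2, quantile, probs = c(lo_p, hi_p), names = FALSE)
    s <- qs[1, ] > 0 | qs[2, ] < 0
    sig[i, (i + 1):K] <- s
    sig[(i + 1):K, i] <- s
  }
  sig
}

#' Nonparametric bootstrap of the network
#'
#' Draws `B` row-resamples with replacement (rows kept intact with their
#' missingness), re-runs the full estimator on the fixed node set, and
#' summarizes the bootstrap distribution of every edge weight and of
#' every node's expected influence: means, 2.5%/97.5% quantile CIs, and
#' pairwise difference tests (a difference is significant when its
#' bootstrap CI excludes zero). Resamples with a constant column are
#' redrawn (up to 10 retries).
#'
#' @param X Item-response matrix.
#' @param covariates Optional covariate data.frame (same rows as `X`).
#' @param B Bootstrap iterations (default 1000).
#' @param seed Master seed; resample seeds are spawned from it.
#' @param gamma,n_lambda,lambda_min_ratio Estimator settings.
#' @param edge_diff,ei_diff Compute the pairwise difference-test matrices
#'   (edge matrices are quadratic in the edge count; disable for large
#'   networks).
#' @param alpha Level of the difference tests (default 0.05).
#' @param estimator Optional replacement estimator
#'   `function(X, covariates)` returning `list(edges, ei, node_ids)`;
#'   used for testing.
#' @return A list of class `edge_bootstrap`: `edge_summary`,
#'   `ei_summary`, `edge_draws`, `ei_draws`, `edge_sig`, `ei_sig`,
#'   `sample_edges`, `sample_ei`, `B`, `seed`.
#' @export
nonparametric_bootstrap <- function(X, covariates = NULL, B = 1000,
                                    seed = 1L, gamma = 0.5,
                                    n_lambda = 100,
                                    lambda_min_ratio = 0.01,
                                    edge_diff = TRUE, ei_diff = TRUE,
                                    alpha = 0.05, estimator = NULL) {
  if (is.null(estimator))
    estimator <- default_estimator(gamma, n_lambda, lambda_min_ratio)
  full <- estimator(X, covariates)
  ids <- full$node_ids
  enames <- edge_names(ids)
  n <- nrow(X)
  seeds <- spawn_seeds(seed, B)
  edge_draws <- matrix(NA_real_, B, length(full$edges),
                       dimnames = list(NULL, enames))
  ei_draws <- matrix(NA_real_, B, length(ids),
                     dimnames = list(NULL, ids))
  for (b in seq_len(B)) {
    res <- with_seed(seeds[b], {
      for (try in 1:10) {
        rows <- sample.int(n, n, replace = TRUE)
        Xb <- X[rows, , drop = FALSE]
        cb <- if (is.null(covariates)) NULL else
          covariates[rows, , drop = FALSE]
        if (resample_ok(Xb, cb)) break
        if (try == 10)
          stopf("could not draw a non-degenerate resample in 10 tries")
        warnf("degenerate resample (constant column); redrawing")
      }
      estimator(Xb, cb)
    })
    edge_draws[b, ] <- res$edges
    ei_draws[b, ] <- res$ei
  }
  summarize <- function(draws, truth, what) {
    qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975),
                names = FALSE)
    data.frame(id = colnames(draws), sample = unname(truth),
               mean = unname(colMeans(draws)), lower = qs[1, ],
               upper = qs[2, ], row.names = NULL,
               stringsAsFactors = FALSE)
  }
  structure(list(
    edge_summary = summarize(edge_draws, full$edges),
    ei_summary = summarize(ei_draws, full$ei),
    edge_draws = edge_draws, ei_draws = ei_draws,
    edge_sig = if (edge_diff) diff_sig_matrix(edge_draws, enames, alpha)
    else NULL,
    ei_sig = if (ei_diff) diff_sig_matrix(ei_draws, ids, alpha)
    else NULL,
    sample_edges = setNames(full$edges, enames),
    sample_ei = setNames(full$ei, ids),
    node_ids = ids, B = B, seed = seed, alpha = alpha),
    class = "edge_bootstrap")
}

#' Case-dropping bootstrap
#'
#' For each drop proportion `q`, draws `B` subsets of `ceiling((1-q) n)`
#' rows without replacement, re-runs the estimator, and records the
#' Pearson correlation between the full-sample statistic vector (edge
#' weights; expected influence) and the subset version. Proportions whose
#' subsets are smaller than the node count are skipped with a warning.
#'
#' @inheritParams nonparametric_bootstrap
#' @param proportions Drop proportions (default `seq(0.1, 0.7, 0.1)`).
#' @return A list of class `casedrop_profile`: `proportions`, `cors`
#'   (list of B x length(proportions) correlation matrices per
#'   statistic), `B`, `seed`.
#' @export
case_dropping_bootstrap <- function(X, covariates = NULL,
                                    proportions = seq(0.1, 0.7, by = 0.1),
                                    B = 1000, seed = 1L, gamma = 0.5,
                                    n_lambda = 100,
                                    lambda_min_ratio = 0.01,
                                    estimator = NULL) {
  if (any(proportions <= 0 | proportions >= 1))
    stopf("proportions must lie in (0, 1)")
  if (is.null(estimator))
    estimator <- default_estimator(gamma, n_lambda, lambda_min_ratio)
  full <- estimator(X, covariates)
  n <- nrow(X)
  p <- length(full$node_ids)
  keep_q <- vapply(proportions,
                   function(q) ceiling((1 - q) * n) >= p, TRUE)
  if (!all(keep_q))
    warnf("drop proportion(s) %s skipped: subset smaller than node count",
          paste(proportions[!keep_q], collapse = ", "))
  proportions <- proportions[keep_q]
  seeds <- spawn_seeds(seed, max(1, length(proportions) * B))
  cors <- list(
    edges = matrix(NA_real_, B, length(proportions),
                   dimnames = list(NULL, proportions)),
    ei = matrix(NA_real_, B, length(proportions),
                dimnames = list(NULL, proportions)))
  k <- 0
  for (qi in seq_along(proportions)) {
    m <- ceiling((1 - proportions[qi]) * n)
    for (b in seq_len(B)) {
      k <- k + 1
      res <- with_seed(seeds[k], {
        out <- NULL
        for (try in 1:10) {
          rows <- sample.int(n, m, replace = FALSE)
          Xs <- X[rows, , drop = FALSE]
          cs <- if (is.null(covariates)) NULL else
            covariates[rows, , drop = FALSE]
          if (!resample_ok(Xs, cs)) next
          out <- tryCatch(estimator(Xs, cs), error = function(e) NULL)
          if (!is.null(out)) break
        }
        out
      })
      if (is.null(res)) next
      cors$edges[b, qi] <- suppressWarnings(cor(full$edges, res$edges))
      cors$ei[b, qi] <- suppressWarnings(cor(full$ei, res$ei))
    }
  }
  structure(list(proportions = proportions, cors = cors,
                 sample_edges = full$edges, sample_ei = full$ei,
                 B = B, seed = seed),
            class = "casedrop_profile")
}

#' Correlation-stability (CS) coefficient
#'
#' The largest tested drop proportion at which at least `prob` of the
#' subsets still correlate at least `cor_threshold` with the full-sample
#' statistic; 0 when no proportion qualifies. CS above 0.5 indicates
#' strong stability.
#'
#' @param profile A `casedrop_profile`.
#' @param cor_threshold Correlation criterion (default 0.7).
#' @param prob Required fraction of qualifying subsets (default 0.95).
#' @return Named numeric vector of CS values (one per statistic).
#' @export
cs_coefficient <- function(profile, cor_threshold = 0.7, prob = 0.95) {
  if (length(profile$proportions) == 0)
    stopf("profile is empty")
  vapply(profile$cors, function(m) {
    frac <- colMeans(!is.na(m) & m >= cor_threshold)
    ok <- frac >= prob
    if (any(ok)) max(profile$proportions[ok]) else 0
  }, numeric(1))
}
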