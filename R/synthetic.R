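# Synthetic ordinal item data with planted network structure: a sparse
# partial-correlation target over subscale-style communities, converted
# to a positive-definite precision matrix, sampled through a Gaussian
# copula and discretized to the 0-3 rating scale.

#' Default synthetic network layout
#'
#' Emulates the layout of a pooled anxiety/autism item set after item
#' screening: four anxiety communities (panic/agoraphobia 7, separation
#' 6, social 6, generalized 3 items), one autism community (9 items),
#' and two covariate nodes (age, functioning). Two autism nodes (a
#' sameness/routine item and a sensory item) carry planted bridge edges
#' into the generalized-anxiety block; both covariates carry mild
#' positive links into the social block.
#'
#' @param communities Named integer vector of community sizes.
#' @param within_density Probability that a within-community pair is
#'   connected (default 0.5, which keeps the positive-definiteness
#'   repair mild so realized weights stay near `within_range`).
#' @param within_range Range of within-community partial correlations
#'   (default `c(0.15, 0.35)`, positive).
#' @param bridge_nodes Names of the planted bridge nodes.
#' @param bridge_to Community receiving the bridge edges.
#' @param n_bridge_edges Bridge edges per bridge node (default 1; chosen so the planted partition is the Spinglass optimum of the noiseless ground-truth weights).
#' @param bridge_range Bridge edge-weight range (default `c(0.1, 0.2)`).
#' @param covariate_to Community the covariates link into.
#' @param n_covariate_edges Item links per covariate (default 3).
#' @param covariate_range Covariate edge-weight range (default
#'   `c(0.1, 0.2)`).
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(communities = c(panic = 7L, separation = 6L,
                                         social = 6L, generalized = 3L,
                                         autism = 9L),
                         within_density = 0.5,
                         within_range = c(0.15, 0.35),
                         bridge_nodes = c("aut7", "aut9"),
                         bridge_to = "generalized",
                         n_bridge_edges = 1L,
                         bridge_range = c(0.1, 0.2),
                         covariate_to = "social",
                         n_covariate_edges = 3L,
                         covariate_range = c(0.1, 0.2)) {
  if (within_density < 0 || within_density > 1)
    stopf("within_density must lie in [0, 1]")
  stopifnot(length(within_range) == 2, length(bridge_range) == 2)
  structure(list(communities = communities,
                 within_density = within_density,
                 within_range = within_range,
                 bridge_nodes = bridge_nodes, bridge_to = bridge_to,
                 n_bridge_edges = as.integer(n_bridge_edges),
                 bridge_range = bridge_range,
                 covariate_to = covariate_to,
                 n_covariate_edges = as.integer(n_covariate_edges),
                 covariate_range = covariate_range),
            class = "network_spec")
}

spec_node_ids <- function(spec) {
  comm <- spec$communities
  prefix <- c(panic = "pan", separation = "sep", social = "soc",
              generalized = "gen", autism = "aut")
  ids <- unlist(lapply(names(comm), function(nm) {
    pre <- if (nm %in% names(prefix)) prefix[[nm]] else
      substr(nm, 1, 3)
    paste0(pre, seq_len(comm[[nm]]))
  }))
  c(ids, "age", "functioning")
}

#' Build a ground-truth network
#'
#' Constructs a sparse symmetric partial-correlation target per the
#' layout spec, converts it to a precision matrix (unit diagonal,
#' off-diagonal `-w`), inflates the diagonal until the minimum eigenvalue
#' reaches 0.05, and recomputes the implied partial correlations. The
#' returned object carries everything downstream stages can be checked
#' against: the precision and weight matrices, the planted partition
#' (covariates belong to the community they are wired into), the planted
#' bridge nodes, and the discretization thresholds.
#'
#' @param spec A [network_spec()].
#' @param seed RNG seed for edge placement and weights.
#' @param thresholds Latent cut points for the 0-3 item scale (default
#'   `c(0.2, 1.0, 1.8)`, right-skewed marginals).
#' @return A list of class `ground_truth`.
#' @export
build_ground_truth <- function(spec = network_spec(), seed = 1L,
                               thresholds = c(0.2, 1.0, 1.8)) {
  comm <- spec$communities
  ids <- spec_node_ids(spec)
  p <- length(ids)
  blocks <- rep(names(comm), comm)
  names(blocks) <- ids[seq_along(blocks)]
  with_seed(seed, {
    Wt <- matrix(0, p, p, dimnames = list(ids, ids))
    for (nm in names(comm)) {
      members <- which(blocks == nm)
      if (length(members) < 2) next
      # a community must be internally connected to be a community:
      # include a random spanning tree (unless the block is switched
      # off entirely with zero density), then add further pairs at the
      # configured density
      if (spec$within_density > 0) {
        ord <- sample(members)
        for (k in 2:length(ord)) {
          i <- ord[k]
          j <- ord[sample.int(k - 1, 1)]
          Wt[i, j] <- Wt[j, i] <- runif(1, spec$within_range[1],
                                        spec$within_range[2])
        }
      }
      pairs <- which(upper.tri(diag(length(members))), arr.ind = TRUE)
      on <- runif(nrow(pairs)) < spec$within_density
      for (k in which(on)) {
        i <- members[pairs[k, 1]]
        j <- members[pairs[k, 2]]
        if (Wt[i, j] != 0) next
        Wt[i, j] <- Wt[j, i] <- runif(1, spec$within_range[1],
                                      spec$within_range[2])
      }
    }
    pick <- function(pool, k) {
      k <- min(k, length(pool))
      if (k <= 0) return(integer(0))
      pool[sample.int(length(pool), k)]
    }
    target <- which(blocks == spec$bridge_to)
    for (bn in spec$bridge_nodes) {
      i <- match(bn, ids)
      if (is.na(i)) stopf("bridge node '%s' not in layout", bn)
      js <- pick(target, spec$n_bridge_edges)
      for (j in js)
        Wt[i, j] <- Wt[j, i] <- runif(1, spec$bridge_range[1],
                                      spec$bridge_range[2])
    }
    cov_ids <- c("age", "functioning")
    cov_target <- which(blocks == spec$covariate_to)
    for (cn in cov_ids) {
      i <- match(cn, ids)
      js <- pick(cov_target, spec$n_covariate_edges)
      for (j in js)
        Wt[i, j] <- Wt[j, i] <- runif(1, spec$covariate_range[1],
                                      spec$covariate_range[2])
    }
    theta <- diag(p) - Wt
    dimnames(theta) <- list(ids, ids)
    ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 0.05)
      diag(theta) <- diag(theta) + (0.05 - ev)
    W_true <- precision_to_partial(theta)
    dimnames(W_true) <- list(ids, ids)
    partition <- c(match(blocks, names(comm)),
                   rep(match(spec$covariate_to, names(comm)), 2))
    names(partition) <- ids
    structure(list(theta_true = theta, w_true = W_true,
                   partition_true = partition,
                   bridge_nodes_true = spec$bridge_nodes,
                   thresholds = thresholds,
                   covariate_ids = cov_ids,
                   item_ids = ids[seq_along(blocks)],
                   blocks = blocks, spec = spec, seed = seed),
              class = "ground_truth")
  })
}

#' Sample ordinal item data from a ground truth
#'
#' Draws a latent multivariate normal with the correlation structure
#' implied by the planted precision matrix, discretizes item columns at
#' the thresholds into 0-3 scores, emits the covariate columns as an
#' age-like continuous variable and an ordinal 1-8 functioning level,
#' and masks item cells missing-completely-at-random.
#'
#' @param gt A [build_ground_truth()] object.
#' @param n Sample size (default 600; must be at least 10).
#' @param thresholds Item cut points (default: those stored in `gt`).
#' @param missing_rate MCAR missingness rate on item cells (default
#'   0.02).
#' @param seed RNG seed.
#' @return list with `items` (an [item_response_matrix()]),
#'   `covariates` (data.frame with `age`, `functioning`, `sex`), and
#'   `ground_truth`.
#' @export
sample_ordinal_data <- function(gt, n = 600, thresholds = NULL,
                                missing_rate = 0.02, seed = 1L) {
  if (n < 10) stopf("n must be at least 10")
  if (is.null(thresholds)) thresholds <- gt$thresholds
  if (any(diff(thresholds) <= 0))
    stopf("thresholds must be strictly increasing")
  ids <- colnames(gt$theta_true)
  p <- length(ids)
  Sigma <- solve(gt$theta_true)
  d <- sqrt(diag(Sigma))
  Sigma <- Sigma / outer(d, d)
  with_seed(seed, {
    Z <- matrix(rnorm(n * p), n, p) %*% chol(Sigma)
    colnames(Z) <- ids
    items <- Z[, gt$item_ids, drop = FALSE]
    scored <- matrix(0L, n, length(gt$item_ids),
                     dimnames = list(NULL, gt$item_ids))
    for (t in thresholds) scored <- scored + (items > t)
    if (missing_rate > 0) {
      mask <- matrix(runif(length(scored)) < missing_rate,
                     nrow(scored), ncol(scored))
      scored[mask] <- NA_integer_
    }
    age <- round(10.5 + 2.3 * Z[, "age"], 1)
    fcuts <- qnorm(seq_len(7) / 8)
    functioning <- 1L + rowSums(outer(Z[, "functioning"], fcuts, ">"))
    sex <- ifelse(rbinom(n, 1, 0.17) == 1, "female", "male")
    list(items = item_response_matrix(scored),
         covariates = data.frame(age = age, functioning = functioning,
                                 sex = sex, stringsAsFactors = FALSE),
         ground_truth = gt)
  })
}
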