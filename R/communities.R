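# Signed Spinglass community detection with ensemble aggregation, and
# bridge expected influence with a percentile cutoff.

# Signed null-adjusted coupling matrix: split W into positive and
# negative layers, subtract each layer's configuration-model expectation
# p+-_ij = s_i s_j / (2m), and combine: M = (W+ - g+ P+) - (W- - g- P-).
signed_null_matrix <- function(W, gamma_pos = 1, gamma_neg = 1) {
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  diag(Wp) <- 0
  diag(Wn) <- 0
  layer <- function(A, g) {
    s <- rowSums(A)
    m2 <- sum(s)
    if (m2 == 0) return(matrix(0, nrow(A), ncol(A)))
    A - g * outer(s, s) / m2
  }
  M <- layer(Wp, gamma_pos) - layer(Wn, gamma_neg)
  diag(M) <- 0
  M
}

#' Spinglass Hamiltonian of a partition
#'
#' Energy of a community assignment under the signed Reichardt-Bornholdt
#' model: within-community positive weight in excess of its
#' configuration-model expectation lowers the energy, within-community
#' negative weight raises it.
#'
#' @param W Symmetric signed edge-weight matrix.
#' @param membership Integer community labels, one per node.
#' @param gamma_pos,gamma_neg Resolution parameters of the positive and
#'   negative layers (defaults 1).
#' @return The energy (scalar; lower is better).
#' @export
spin_hamiltonian <- function(W, membership, gamma_pos = 1,
                             gamma_neg = 1) {
  if (!is_square_sym(W)) stopf("W must be a symmetric matrix")
  if (length(membership) != ncol(W))
    stopf("membership must assign every node")
  M <- signed_null_matrix(W, gamma_pos, gamma_neg)
  same <- outer(membership, membership, "==")
  diag(same) <- FALSE
  -sum(M[same]) / 2
}

# Relabel communities 1..K in order of first node occurrence.
canonicalize_membership <- function(m) {
  u <- unique(m)
  out <- match(m, u)
  names(out) <- names(m)
  out
}

#' Single Spinglass run
#'
#' Simulated annealing over single-node label moves with Metropolis
#' acceptance and geometric cooling; returns the lowest-energy assignment
#' visited, canonicalized by first node occurrence.
#'
#' @param W Symmetric signed edge-weight matrix with at least one nonzero
#'   edge.
#' @param seed RNG seed of the run.
#' @param max_spins Number of available spin states (default
#'   `min(25, p)`).
#' @param start_temp,stop_temp,cooling Annealing schedule (defaults 1.0,
#'   0.01, 0.99).
#' @param sweeps_per_temp Node sweeps per temperature level (default 5).
#' @param gamma_pos,gamma_neg Resolution parameters (defaults 1).
#' @return A list of class `partition`: `membership` (named), `k`,
#'   `hamiltonian`, `seed`.
#' @export
spinglass_once <- function(W, seed = 1L, max_spins = NULL,
                           start_temp = 1.0, stop_temp = 0.01,
                           cooling = 0.99, sweeps_per_temp = 5L,
                           gamma_pos = 1, gamma_neg = 1) {
  if (!is_square_sym(W)) stopf("W must be a symmetric matrix")
  p <- ncol(W)
  ids <- colnames(W)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  offd <- W
  diag(offd) <- 0
  if (all(offd == 0)) {
    warnf("empty network: every node assigned its own community")
    memb <- setNames(seq_len(p), ids)
    return(structure(list(membership = memb, k = p, hamiltonian = 0,
                          seed = seed), class = "partition"))
  }
  if (is.null(max_spins)) max_spins <- min(25L, p)
  M <- signed_null_matrix(W, gamma_pos, gamma_neg)
  res <- spinglass_anneal(M, as.integer(max_spins), as.integer(seed),
                          start_temp, stop_temp, cooling,
                          as.integer(sweeps_per_temp))
  memb <- canonicalize_membership(setNames(res$membership, ids))
  structure(list(membership = memb, k = length(unique(memb)),
                 hamiltonian = res$hamiltonian, seed = seed),
            class = "partition")
}

#' Ensemble Spinglass community detection
#'
#' Runs the Spinglass annealer `n_runs` times with independently spawned
#' seeds, canonicalizes and tabulates the distinct partitions, and
#' reports the modal solution with its frequency plus the pairwise
#' co-classification matrix. Nodes without any nonzero edge are assigned
#' singleton communities before running.
#'
#' @param W Symmetric signed edge-weight matrix.
#' @param n_runs Number of runs (default 1000).
#' @param seed Master seed from which run seeds are spawned.
#' @param ... Passed to [spinglass_once()].
#' @return A list of class `partition_ensemble`: `solutions` (data.frame
#'   of distinct partitions with frequencies and energies),
#'   `modal_partition`, `modal_frequency`, `co_classification`,
#'   `memberships` (runs x nodes matrix), `isolated`.
#' @export
ensemble_detect <- function(W, n_runs = 1000, seed = 1L, ...) {
  if (!is_square_sym(W)) stopf("W must be a symmetric matrix")
  p <- ncol(W)
  ids <- colnames(W)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  colnames(W) <- rownames(W) <- ids
  offd <- W
  diag(offd) <- 0
  isolated <- rowSums(offd != 0) == 0
  active <- which(!isolated)
  seeds <- spawn_seeds(seed, n_runs)
  membs <- matrix(NA_integer_, n_runs, p, dimnames = list(NULL, ids))
  energies <- numeric(n_runs)
  Wa <- W[active, active, drop = FALSE]
  for (r in seq_len(n_runs)) {
    full <- integer(p)
    if (length(active) > 0) {
      part <- spinglass_once(Wa, seed = seeds[r], ...)
      full[active] <- part$membership
    }
    if (any(isolated))
      full[isolated] <- max(full) + seq_len(sum(isolated))
    full <- canonicalize_membership(setNames(full, ids))
    membs[r, ] <- full
    energies[r] <- spin_hamiltonian(W, full)
  }
  keys <- apply(membs, 1, paste, collapse = ",")
  tab <- table(keys)
  sol_keys <- names(tab)
  sol <- data.frame(partition = sol_keys,
                    frequency = as.numeric(tab) / n_runs,
                    hamiltonian = energies[match(sol_keys, keys)],
                    k = vapply(sol_keys, function(k)
                      length(unique(strsplit(k, ",")[[1]])), 1L),
                    stringsAsFactors = FALSE, row.names = NULL)
  sol <- sol[order(-sol$frequency, sol$hamiltonian), , drop = FALSE]
  rownames(sol) <- NULL
  modal_key <- sol$partition[1]
  modal <- setNames(as.integer(strsplit(modal_key, ",")[[1]]), ids)
  co <- matrix(0, p, p, dimnames = list(ids, ids))
  for (r in seq_len(n_runs))
    co <- co + outer(membs[r, ], membs[r, ], "==")
  co <- co / n_runs
  structure(list(solutions = sol,
                 modal_partition = modal,
                 modal_frequency = sol$frequency[1],
                 modal_hamiltonian = sol$hamiltonian[1],
                 co_classification = co,
                 memberships = membs,
                 isolated = ids[isolated],
                 n_runs = n_runs, seed = seed),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf(
    "Spinglass ensemble: %d runs, %d distinct solutions\n", x$n_runs,
    nrow(x$solutions)))
  cat(sprintf("  modal solution: %d communities, frequency %.1f%%, H = %.4g\n",
              length(unique(x$modal_partition)),
              100 * x$modal_frequency, x$modal_hamiltonian))
  invisible(x)
}

#' Bridge expected influence
#'
#' One-step bridge expected influence: for each node, the signed sum of
#' its edge weights to nodes in other communities.
#'
#' @param W Symmetric signed edge-weight matrix.
#' @param membership Community labels covering all nodes.
#' @return Named numeric vector of BEI scores.
#' @export
bridge_expected_influence <- function(W, membership) {
  if (inherits(membership, "partition")) membership <- membership$membership
  if (!is_square_sym(W)) stopf("W must be a symmetric matrix")
  if (length(membership) != ncol(W))
    stopf("membership must cover all nodes")
  ids <- colnames(W)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(W)))
  cross <- outer(membership, membership, "!=")
  bei <- rowSums(W * cross)
  setNames(unname(bei), ids)
}

#' Flag bridge nodes by percentile cutoff
#'
#' The cutoff is the linear-interpolation percentile of the BEI scores
#' (inclusive: nodes at the cutoff are flagged, ties all flagged).
#'
#' @param bei Named BEI vector from [bridge_expected_influence()].
#' @param percentile Percentile in (0, 100), default 80.
#' @return A list of class `bridge_report`: `bei`, `cutoff`,
#'   `percentile`, `bridges` (flagged node names), `flagged` (logical).
#' @export
flag_bridges <- function(bei, percentile = 80) {
  if (length(bei) < 2) stopf("need at least 2 nodes")
  if (percentile <= 0 || percentile >= 100)
    stopf("percentile must lie in (0, 100)")
  cutoff <- unname(quantile(bei, percentile / 100, type = 7))
  flagged <- bei >= cutoff
  if (all(flagged))
    warnf("all bridge expected influence values are equal; all flagged")
  structure(list(bei = bei, cutoff = cutoff, percentile = percentile,
                 bridges = names(bei)[flagged], flagged = flagged),
            class = "bridge_report")
}
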