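# Node-level inference: expected-influence centrality and predictability.

#' Expected influence
#'
#' One-step expected influence: the signed sum of a node's edge weights
#' (negative edges count against it). A z-standardized copy (within the
#' network) is returned for plotting.
#'
#' @param W Edge-weight matrix or a `network_model`.
#' @return data.frame with `node`, `ei`, `ei_z`.
#' @export
expected_influence <- function(W) {
  if (inherits(W, "network_model")) W <- W$weights
  if (!is_square_sym(W)) stopf("W must be a symmetric matrix")
  ids <- colnames(W)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(W)))
  ei <- rowSums(W) - diag(W)
  s <- sd(ei)
  ei_z <- if (is.na(s) || s == 0) rep(0, length(ei)) else
    (ei - mean(ei)) / s
  data.frame(node = ids, ei = unname(ei), ei_z = unname(ei_z),
             stringsAsFactors = FALSE)
}

#' Node predictability
#'
#' Proportion of a node's variance explained by all remaining nodes. With
#' the input standardized to unit diagonal, the residual variance of node
#' i given the rest is `1 / Theta_ii`, so `R2_i = 1 - 1 / Theta_ii`
#' (clipped to `[0, 1]`; equivalent to nodewise regression R-squared at
#' zero penalty).
#'
#' @param model A `network_model` (or a precision matrix).
#' @return data.frame with `node`, `r2`; the network mean is attached as
#'   attribute `"mean_r2"`.
#' @export
predictability <- function(model) {
  theta <- if (inherits(model, "network_model")) model$theta else model
  d <- diag(theta)
  if (any(d <= 0)) stopf("theta has non-positive diagonal")
  r2 <- 1 - 1 / d
  if (any(r2 < 0)) {
    warnf("Theta_ii < 1 after regularization for %d node(s); clipped to 0",
          sum(r2 < 0))
    r2 <- pmax(r2, 0)
  }
  r2 <- pmin(r2, 1)
  ids <- colnames(theta)
  if (is.null(ids)) ids <- paste0("V", seq_along(r2))
  out <- data.frame(node = ids, r2 = unname(r2), stringsAsFactors = FALSE)
  attr(out, "mean_r2") <- mean(r2)
  out
}
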