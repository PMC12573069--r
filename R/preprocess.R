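# Item screening and correlation-matrix construction: informativeness
# (per-item SD), near-zero-variance exclusion, redundancy (topological
# overlap) screening, covariate screening, and the pairwise-complete
# Spearman matrix with positive-semidefinite repair.

#' Item informativeness
#'
#' Computes each item's standard deviation over non-missing responses and
#' its maximum single-category proportion. An item is flagged as
#' uninformative when its SD falls more than `sd_k` item-SD standard
#' deviations below the mean item SD, or when a single response category
#' holds more than `max_prop` of the responses.
#'
#' @param X Item-response matrix.
#' @param sd_k Multiplier of the between-item SD spread (default 2.5).
#' @param max_prop Maximum allowed single-category proportion (default
#'   0.95).
#' @return data.frame with `item`, `sd`, `max_category_prop`, `flagged`
#'   and a `reason` string for flagged items.
#' @export
informativeness <- function(X, sd_k = 2.5, max_prop = 0.95) {
  X <- unclass(X)
  n_ok <- colSums(!is.na(X))
  if (any(n_ok < 2))
    stopf("item(s) with fewer than 2 non-missing values: %s",
          paste(colnames(X)[n_ok < 2], collapse = ", "))
  sds <- apply(X, 2, sd, na.rm = TRUE)
  maxp <- apply(X, 2, function(v) {
    v <- v[!is.na(v)]
    max(tabulate(v + 1L, nbins = 4L)) / length(v)
  })
  low_cut <- mean(sds) - sd_k * sd(sds)
  low_sd <- if (is.finite(low_cut)) sds < low_cut else
    rep(FALSE, length(sds))
  dominant <- maxp > max_prop
  reason <- ifelse(low_sd & dominant, "low SD; dominant category",
                   ifelse(low_sd, "low SD",
                          ifelse(dominant, "dominant category", "")))
  data.frame(item = colnames(X), sd = unname(sds),
             max_category_prop = unname(maxp),
             flagged = unname(low_sd | dominant),
             reason = reason, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Drop uninformative items
#'
#' Removes the items flagged by [informativeness()], preserving the order
#' of survivors. Exclusions and reasons are attached as attribute
#' `"excluded"`.
#'
#' @param X Item-response matrix.
#' @param report Output of [informativeness()] computed on `X`.
#' @return The reduced item matrix.
#' @export
variance_filter <- function(X, report) {
  if (!all(report$item == colnames(X)))
    stopf("report does not match the columns of X")
  keep <- !report$flagged
  if (!any(keep))
    stopf("all items flagged as uninformative; nothing to analyze")
  out <- X[, keep, drop = FALSE]
  class(out) <- class(X)
  attr(out, "excluded") <- report[report$flagged,
                                  c("item", "sd", "reason")]
  out
}

#' Pairwise-complete Spearman correlation matrix
#'
#' Rank correlations per pair over that pair's complete cases (average
#' ranks for ties). Pairwise deletion can yield an indefinite matrix;
#' when the minimum eigenvalue falls below `eig_floor`, eigenvalues are
#' clipped at the floor and the matrix rescaled to unit diagonal
#' (`psd_adjusted` set).
#'
#' @param X Item-response matrix.
#' @param covariates Optional covariate data.frame appended as additional
#'   columns.
#' @param eig_floor Minimum eigenvalue enforced (default 1e-4).
#' @return A list of class `cor_matrix`: `S` (correlations),
#'   `pairwise_n` (complete-pair counts), `psd_adjusted`.
#' @export
spearman_matrix <- function(X, covariates = NULL, eig_floor = 1e-4) {
  M <- unclass(X)
  storage.mode(M) <- "double"
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cv <- data.matrix(cv)
    if (nrow(cv) != nrow(M))
      stopf("covariates have %d rows; expected %d", nrow(cv), nrow(M))
    M <- cbind(M, cv)
  }
  sp <- spearman_pairwise(M)
  pn <- sp$n
  dimnames(pn) <- list(colnames(M), colnames(M))
  if (any(pn[upper.tri(pn)] < 3)) {
    idx <- which(upper.tri(pn) & pn < 3, arr.ind = TRUE)[1, ]
    stopf("pair (%s, %s) has fewer than 3 complete observations",
          colnames(M)[idx[1]], colnames(M)[idx[2]])
  }
  S <- sp$rho
  dimnames(S) <- list(colnames(M), colnames(M))
  if (anyNA(S)) {
    idx <- which(is.na(S) & upper.tri(S), arr.ind = TRUE)[1, ]
    stopf("correlation undefined for pair (%s, %s) (constant values?)",
          colnames(M)[idx[1]], colnames(M)[idx[2]])
  }
  S <- (S + t(S)) / 2
  diag(S) <- 1
  psd_adjusted <- FALSE
  for (i in 1:10) {
    ev <- eigen(S, symmetric = TRUE)
    if (min(ev$values) >= eig_floor) break
    psd_adjusted <- TRUE
    vals <- pmax(ev$values, eig_floor)
    S <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(S))
    S <- S / outer(d, d)
    S <- (S + t(S)) / 2
    diag(S) <- 1
  }
  dimnames(S) <- list(colnames(M), colnames(M))
  structure(list(S = S, pairwise_n = pn, psd_adjusted = psd_adjusted),
            class = "cor_matrix")
}

# Hittner-style test for two dependent overlapping correlations
# r13 = cor(x1, z), r23 = cor(x2, z), sharing z; r12 = cor(x1, x2).
# Dunn & Clark's z with the back-transformed average correlation in the
# covariance term. Returns the two-sided p-value.
dependent_cor_test <- function(r13, r23, r12, n) {
  clamp <- function(r) pmin(pmax(r, -0.9999999), 0.9999999)
  z13 <- atanh(clamp(r13))
  z23 <- atanh(clamp(r23))
  rbar <- tanh((z13 + z23) / 2)
  cnum <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
  cc <- cnum / (1 - rbar^2)^2
  cc <- pmin(pmax(cc, -1), 0.999999)
  z <- (z13 - z23) * sqrt((n - 3) / (2 - 2 * cc))
  2 * pnorm(-abs(z))
}

#' Redundancy (topological overlap) screen
#'
#' For each item pair correlating at least `min_cor`, tests for every
#' third node whether the two items' correlations with it differ
#' (dependent-correlations z test with back-transformed averaged Fisher
#' z). A pair whose proportion of significantly differing third-party
#' correlations is below `prop_threshold` has statistically
#' indistinguishable correlation profiles and is reported redundant.
#'
#' @param X Item-response matrix.
#' @param min_cor Minimum Spearman correlation to consider a pair
#'   (default 0.5).
#' @param prop_threshold Proportion threshold (default 0.25).
#' @param alpha Test level (default 0.05).
#' @param covariates Optional covariates included as third-party nodes.
#' @return data.frame of tested pairs: `item_a`, `item_b`, `cor`,
#'   `prop_significant`, `redundant`.
#' @export
redundancy_screen <- function(X, min_cor = 0.5, prop_threshold = 0.25,
                              alpha = 0.05, covariates = NULL) {
  cm <- spearman_matrix(X, covariates)
  S <- cm$S
  pn <- cm$pairwise_n
  p <- ncol(S)
  if (p < 3) stopf("redundancy screen needs at least 3 nodes")
  ids <- colnames(S)
  out <- list()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (S[i, j] < min_cor) next
      zs <- setdiff(seq_len(p), c(i, j))
      nz <- pmin(pn[i, j], pn[i, zs], pn[j, zs])
      pv <- dependent_cor_test(S[i, zs], S[j, zs], S[i, j], nz)
      prop <- mean(pv < alpha)
      out[[length(out) + 1]] <- data.frame(
        item_a = ids[i], item_b = ids[j], cor = S[i, j],
        prop_significant = prop,
        redundant = prop < prop_threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(item_a = character(), item_b = character(),
                      cor = numeric(), prop_significant = numeric(),
                      redundant = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Covariate screening
#'
#' Spearman correlation (and p-value) of each covariate with every item.
#' A covariate is retained as a network node iff it shows at least one
#' item correlation with p below `alpha`. Constant covariates are
#' excluded with a warning.
#'
#' @param X Item-response matrix.
#' @param covariates data.frame of candidate covariates.
#' @param alpha Inclusion level (default 0.05).
#' @param adjust Multiplicity adjustment over items per covariate:
#'   `"none"` (default, mirroring per-item screening) or `"BH"`.
#' @return list with `correlations` (covariate, item, rho, p) and
#'   `included` (character vector of retained covariates).
#' @export
covariate_screen <- function(X, covariates, alpha = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  M <- unclass(X)
  cv <- as.data.frame(covariates)
  rows <- list()
  included <- character()
  for (nm in names(cv)) {
    v <- cv[[nm]]
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v))
    if (sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      warnf("covariate '%s' is constant; excluded", nm)
      next
    }
    res <- lapply(colnames(M), function(it) {
      ct <- suppressWarnings(
        cor.test(v, M[, it], method = "spearman", exact = FALSE))
      data.frame(covariate = nm, item = it,
                 rho = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (adjust == "BH") res$p <- p.adjust(res$p, method = "BH")
    if (any(res$p < alpha)) included <- c(included, nm)
    rows[[nm]] <- res
  }
  correlations <- if (length(rows)) do.call(rbind, c(rows,
                                                     make.row.names = FALSE))
  else data.frame(covariate = character(), item = character(),
                  rho = numeric(), p = numeric())
  list(correlations = correlations, included = included)
}
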