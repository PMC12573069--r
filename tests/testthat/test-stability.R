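# A fast deterministic stub estimator and a noisy variant used to probe
# the bootstrap plumbing without the cost of full re-estimation.
fixed_estimator <- function(edges, ei, ids) {
  function(X, covariates) list(edges = edges, ei = ei, node_ids = ids)
}

mean_estimator <- function() {
  # statistics that depend smoothly on which rows are present
  function(X, covariates) {
    M <- unclass(X)
    cm <- colMeans(M, na.rm = TRUE)
    p <- length(cm)
    edges <- outer(cm, cm, "+")[upper.tri(diag(p))] / 6
    list(edges = edges, ei = cm, node_ids = colnames(M))
  }
}

test_that("a fixed estimator yields degenerate CIs and no differences", {
  X <- toy_items(n = 30, seed = 71)
  est <- fixed_estimator(rep(0.25, 6), rep(0.3, 4), paste0("it", 1:4))
  bb <- nonparametric_bootstrap(X, B = 25, seed = 1, estimator = est)
  expect_true(all(bb$edge_summary$lower == bb$edge_summary$upper))
  expect_equal(bb$edge_summary$mean, bb$edge_summary$sample)
  expect_true(all(bb$edge_summary$sample == 0.25))
  expect_false(any(bb$edge_sig))
  expect_false(any(bb$ei_sig))
  # an edge compared with itself is never significant
  est2 <- fixed_estimator(c(0.3, 0, -0.2, 0.1, 0, 0.05),
                          c(0.1, 0.2, 0.3, 0.4), paste0("it", 1:4))
  bb2 <- nonparametric_bootstrap(X, B = 10, seed = 2, estimator = est2)
  expect_false(any(diag(bb2$edge_sig)))
  expect_false(any(diag(bb2$ei_sig)))
})

test_that("difference matrices agree with recomputation from draws", {
  X <- toy_items(n = 60, seed = 72)
  bb <- nonparametric_bootstrap(X, B = 40, seed = 2,
                                estimator = mean_estimator())
  K <- ncol(bb$edge_draws)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      d <- bb$edge_draws[, i] - bb$edge_draws[, j]
      ci <- quantile(d, c(0.025, 0.975), names = FALSE)
      expect_equal(bb$edge_sig[i, j], ci[1] > 0 || ci[2] < 0)
      expect_equal(bb$edge_sig[j, i], bb$edge_sig[i, j])
    }
  }
  expect_true(isSymmetric(bb$ei_sig))
})

test_that("bootstraps are exactly reproducible from the master seed", {
  X <- toy_items(n = 40, seed = 73)
  b1 <- nonparametric_bootstrap(X, B = 15, seed = 9,
                                estimator = mean_estimator())
  b2 <- nonparametric_bootstrap(X, B = 15, seed = 9,
                                estimator = mean_estimator())
  expect_identical(b1$edge_draws, b2$edge_draws)
  expect_identical(b1$ei_draws, b2$ei_draws)

  c1 <- case_dropping_bootstrap(X, proportions = c(0.2, 0.5), B = 10,
                                seed = 4, estimator = mean_estimator())
  c2 <- case_dropping_bootstrap(X, proportions = c(0.2, 0.5), B = 10,
                                seed = 4, estimator = mean_estimator())
  expect_identical(c1$cors, c2$cors)
  expect_identical(cs_coefficient(c1), cs_coefficient(c2))
})

test_that("CS coefficient tabulates the qualifying proportions", {
  mk_profile <- function(props, fracs, B = 100) {
    cors <- sapply(seq_along(props), function(i) {
      c(rep(0.9, round(fracs[i] * B)), rep(0.1, B - round(fracs[i] * B)))
    })
    colnames(cors) <- props
    structure(list(proportions = props,
                   cors = list(edges = cors, ei = cors),
                   B = B, seed = 1), class = "casedrop_profile")
  }
  # 0.3 passes (97% >= 0.7), 0.4 fails (90%)
  pr <- mk_profile(c(0.1, 0.2, 0.3, 0.4), c(1, 0.99, 0.97, 0.90))
  expect_equal(unname(cs_coefficient(pr)["edges"]), 0.3)
  # every proportion qualifies up the grid
  pr2 <- mk_profile(seq(0.1, 0.7, 0.1), rep(1, 7))
  expect_equal(unname(cs_coefficient(pr2)["ei"]), 0.7)
  # none qualifies
  pr3 <- mk_profile(c(0.1, 0.2), c(0.5, 0.4))
  expect_equal(unname(cs_coefficient(pr3)["edges"]), 0)
})

test_that("case-dropping skips subsets smaller than the node count", {
  X <- toy_items(n = 12, seed = 74)
  expect_warning(
    pr <- case_dropping_bootstrap(X, proportions = c(0.2, 0.8), B = 5,
                                  seed = 3, estimator = mean_estimator()),
    "skipped")
  expect_equal(pr$proportions, 0.2)
})

test_that("degenerate resamples are redrawn", {
  # one item almost constant: resampling will occasionally draw an
  # all-constant column and must retry rather than fail
  set.seed(75)
  m <- cbind(a = c(1L, rep(0L, 19)), b = sample(0:3, 20, TRUE),
             c = sample(0:3, 20, TRUE))
  X <- item_response_matrix(m)
  counter <- new.env()
  counter$n <- 0
  est <- function(Xb, cb) {
    counter$n <- counter$n + 1
    sds <- apply(unclass(Xb), 2, sd)
    stopifnot(all(sds > 0))  # estimator only ever sees valid resamples
    list(edges = c(0, 0, 0), ei = colMeans(unclass(Xb)),
         node_ids = colnames(Xb))
  }
  bb <- suppressWarnings(
    nonparametric_bootstrap(X, B = 30, seed = 5, estimator = est))
  expect_equal(nrow(bb$edge_draws), 30)
  expect_gte(counter$n, 30)
})
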