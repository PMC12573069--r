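test_that("informativeness flags degenerate and dominant items", {
  m <- matrix(c(0, 1, 2, 3,
                0, 0, 0, 0,
                1, 0, 2, 3,
                0, 2, 1, 3), 4, 4,
              dimnames = list(NULL, c("a", "const", "c", "d")))
  X <- item_response_matrix(m)
  rep <- informativeness(X)
  # sample SD of 0,1,2,3 is sqrt(5/3)
  expect_equal(rep$sd[rep$item == "a"], sqrt(5 / 3))
  expect_equal(rep$sd[rep$item == "const"], 0)
  expect_true(rep$flagged[rep$item == "const"])
  expect_match(rep$reason[rep$item == "const"], "dominant")

  # 96% single category trips the max-category rule even with some spread
  v <- c(rep(0L, 96), 1L, 2L, 3L, 1L)
  m2 <- cbind(x = v, y = sample(0:3, 100, replace = TRUE),
              z = sample(0:3, 100, replace = TRUE))
  rep2 <- informativeness(item_response_matrix(m2))
  expect_true(rep2$flagged[rep2$item == "x"])
  expect_gt(rep2$max_category_prop[rep2$item == "x"], 0.95)

  # filter drops flagged items, keeps order, logs exclusions
  Xr <- variance_filter(X, rep)
  expect_equal(colnames(Xr), c("a", "c", "d"))
  expect_equal(nrow(Xr), 4)
  expect_equal(attr(Xr, "excluded")$item, "const")

  rep$flagged[] <- FALSE
  expect_equal(colnames(variance_filter(X, rep)), colnames(X))
  rep$flagged[] <- TRUE
  expect_error(variance_filter(X, rep), "all items")
})

test_that("spearman matrix matches hand values", {
  # rho = 1 - 6*sum(d^2)/(n(n^2-1)) with one swapped pair
  m <- cbind(a = c(0L, 1L, 2L, 3L), b = c(0L, 1L, 3L, 2L))
  cm <- spearman_matrix(item_response_matrix(m))
  expect_equal(cm$S["a", "b"], 0.8)
  expect_true(all(cm$pairwise_n == 4))
  expect_false(cm$psd_adjusted)

  # duplicate and reversed columns hit the rank-correlation bounds;
  # the exact-singular matrix is then nudged to the eigenvalue floor
  m2 <- cbind(a = c(0L, 1L, 2L, 3L), dup = c(0L, 1L, 2L, 3L),
              rev = c(3L, 2L, 1L, 0L))
  cm2 <- spearman_matrix(item_response_matrix(m2))
  expect_true(cm2$psd_adjusted)
  expect_equal(cm2$S["a", "dup"], 1, tolerance = 1e-3)
  expect_equal(cm2$S["a", "rev"], -1, tolerance = 1e-3)

  # pairwise missing bookkeeping
  m3 <- cbind(a = c(0L, 1L, 2L, 3L), b = c(0L, 1L, 3L, 2L),
              c = c(1L, 0L, 2L, 3L))
  m3[1, "b"] <- NA
  cm3 <- spearman_matrix(item_response_matrix(m3))
  expect_equal(cm3$pairwise_n["a", "b"], 3)
  expect_equal(cm3$pairwise_n["a", "c"], 4)

  # agreement with stats::cor on data with ties and missingness
  set.seed(11)
  m4 <- matrix(sample(0:3, 400, TRUE), 80, 5,
               dimnames = list(NULL, paste0("i", 1:5)))
  m4[sample(length(m4), 30)] <- NA
  ref <- suppressWarnings(cor(m4, method = "spearman",
                              use = "pairwise.complete.obs"))
  expect_equal(spearman_matrix(item_response_matrix(m4))$S, ref,
               tolerance = 1e-12)

  expect_error(spearman_matrix(item_response_matrix(
    cbind(a = c(0L, 1L, 2L, 3L), b = c(2L, 2L, 2L, 2L)))),
    "undefined")
})

test_that("indefinite pairwise matrices are repaired to the floor", {
  # patterned missingness yields an inconsistent correlation triangle:
  # r(a,b) = 1 and r(b,c) = -1, but r(a,c) mixes opposite-sign halves
  set.seed(42)
  n <- 40
  x <- sample(0:3, n, TRUE)
  b <- x; c_ <- integer(n)
  c_[10:25] <- 3L - x[10:25]
  c_[26:40] <- x[26:40]
  m <- cbind(a = x, b = b, c = c_,
             d = sample(0:3, n, TRUE))
  m[26:40, "b"] <- NA
  m[1:9, "c"] <- NA
  X <- item_response_matrix(m)
  raw <- netbridge:::spearman_pairwise(
    `storage.mode<-`(unclass(X), "double"))$rho
  expect_lt(min(eigen(raw, symmetric = TRUE, only.values = TRUE)$values),
            1e-4)
  cm <- spearman_matrix(X)
  expect_true(cm$psd_adjusted)
  ev <- eigen(cm$S, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-4 - 1e-10)
  expect_equal(diag(cm$S), rep(1, 4), ignore_attr = TRUE)

  # repair is a no-op on an already-PSD matrix
  m_ok <- matrix(sample(0:3, 200, TRUE), 50, 4,
                 dimnames = list(NULL, paste0("i", 1:4)))
  expect_false(spearman_matrix(item_response_matrix(m_ok))$psd_adjusted)
})

test_that("spearman matrix is invariant to monotone transforms", {
  set.seed(5)
  m <- matrix(sample(0:3, 200, TRUE), 50, 4,
              dimnames = list(NULL, paste0("i", 1:4)))
  X <- item_response_matrix(m)
  base <- spearman_matrix(X)$S
  # strictly monotone transform of a column leaves ranks unchanged;
  # feed transformed data through the covariate path (continuous scale)
  tr <- data.frame(t1 = exp(m[, 1]))
  with_t <- spearman_matrix(item_response_matrix(m[, 2:4]), tr)$S
  expect_equal(unname(with_t["t1", paste0("i", 2:4)]),
               unname(base["i1", paste0("i", 2:4)]), tolerance = 1e-12)
})

test_that("redundancy screen finds duplicates and respects gates", {
  set.seed(7)
  n <- 200
  x <- sample(0:3, n, TRUE)
  other <- sample(0:3, n, TRUE)
  X <- item_response_matrix(cbind(a = x, b = x, c = other))
  red <- redundancy_screen(X)
  row_ab <- red[red$item_a == "a" & red$item_b == "b", ]
  expect_equal(nrow(row_ab), 1)
  expect_true(row_ab$redundant)
  expect_equal(row_ab$prop_significant, 0)

  # low-correlation pairs are never tested
  set.seed(8)
  Xw <- item_response_matrix(matrix(sample(0:3, 300, TRUE), 100, 3,
                                    dimnames = list(NULL, c("a", "b", "c"))))
  redw <- redundancy_screen(Xw)
  expect_equal(nrow(redw), 0)

  # correlated pair with opposite-sign third-party profiles is kept
  set.seed(9)
  n <- 400
  f <- rnorm(n)
  a <- as.integer(cut(f + rnorm(n), breaks = c(-Inf, -0.5, 0.5, 1.5, Inf))) - 1L
  b <- as.integer(cut(f + rnorm(n), breaks = c(-Inf, -0.5, 0.5, 1.5, Inf))) - 1L
  # third parties correlated with a but anti-correlated with b
  zs <- sapply(1:6, function(k) {
    as.integer(cut((a - b) + rnorm(n, sd = 0.8),
                   breaks = c(-Inf, -1, 0, 1, Inf))) - 1L
  })
  colnames(zs) <- paste0("z", 1:6)
  Xp <- item_response_matrix(cbind(a = a, b = b, zs))
  redp <- redundancy_screen(Xp)
  row_ab <- redp[redp$item_a == "a" & redp$item_b == "b", ]
  if (nrow(row_ab) == 1) {
    expect_gt(row_ab$prop_significant, 0.25)
    expect_false(row_ab$redundant)
  } else {
    # pair fell below the 0.5 correlation gate; nothing tested
    expect_equal(nrow(row_ab), 0)
  }

  expect_error(redundancy_screen(item_response_matrix(
    cbind(a = x, b = x))), "at least 3")
})

test_that("covariate screening includes informative covariates only", {
  set.seed(13)
  n <- 150
  m <- matrix(sample(0:3, n * 4, TRUE), n, 4,
              dimnames = list(NULL, paste0("i", 1:4)))
  X <- item_response_matrix(m)
  cov <- data.frame(same = m[, 1],              # identical to an item
                    noise = rnorm(n),           # independent
                    flat = rep(2, n))           # constant
  expect_warning(sc <- covariate_screen(X, cov), "constant")
  expect_true("same" %in% sc$included)
  rho_same <- sc$correlations$rho[sc$correlations$covariate == "same" &
                                    sc$correlations$item == "i1"]
  expect_equal(rho_same, 1)
  expect_false("flat" %in% sc$included)

  # a null covariate should usually be excluded (per-family control);
  # check the exclusion rate over repeated nulls
  set.seed(14)
  excl <- replicate(60, {
    cv <- data.frame(z = rnorm(n))
    !("z" %in% covariate_screen(X, cv)$included)
  })
  expect_gt(mean(excl), 0.6)  # 1 - (1 - 0.05)^4 ~ 0.19 inclusion by chance
})
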