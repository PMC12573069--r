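test_that("hamiltonian matches hand-evaluated energies", {
  # two nodes, one positive unit edge: null p12 = 0.5
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(spin_hamiltonian(W, c(1, 1)), -0.5)
  expect_equal(spin_hamiltonian(W, c(1, 2)), 0)

  # all-singleton partition has zero energy for any graph
  set.seed(51)
  Wr <- random_signed_graph(6)
  expect_equal(spin_hamiltonian(Wr, 1:6), 0)

  # flipping an edge sign flips its within-community contribution
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 0.5
  W3[2, 3] <- W3[3, 2] <- 0.4
  h_pos <- spin_hamiltonian(W3, c(1, 1, 2))
  W3n <- W3
  W3n[1, 2] <- W3n[2, 1] <- -0.5
  h_neg <- spin_hamiltonian(W3n, c(1, 1, 2))
  # with a single-layer edge moved between layers the null terms change
  # layer-wise, but the sign of the within contribution reverses
  expect_lt(h_pos, 0)
  expect_gt(h_neg, 0)

  # agreement with the independent brute-force energy on random graphs
  set.seed(52)
  for (i in 1:10) {
    W <- random_signed_graph(7)
    memb <- sample.int(3, 7, replace = TRUE)
    expect_equal(spin_hamiltonian(W, memb), brute_hamiltonian(W, memb),
                 tolerance = 1e-12)
  }
})

test_that("spinglass recovers separable structure deterministically", {
  # two disconnected positive 4-cliques
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  colnames(W) <- rownames(W) <- paste0("n", 1:8)
  for (s in c(1, 7, 23, 99, 1234)) {
    part <- spinglass_once(W, seed = s)
    expect_equal(unname(part$membership), rep(1:2, each = 4))
  }

  # complete positive graph: a single community beats any split
  # (w - p = 1/n > 0 for every within pair)
  Wc <- matrix(1, 5, 5)
  diag(Wc) <- 0
  partc <- spinglass_once(Wc, seed = 3)
  expect_equal(unname(partc$membership), rep(1, 5))

  # empty network: singletons with a warning
  expect_warning(pe <- spinglass_once(matrix(0, 3, 3)), "empty")
  expect_equal(unname(pe$membership), 1:3)
  expect_equal(pe$hamiltonian, 0)
})

test_that("annealer attains the exhaustive minimum on small graphs", {
  set.seed(53)
  hits <- replicate(20, {
    W <- random_signed_graph(6, density = 0.6)
    best <- brute_min_hamiltonian(W)
    ens <- ensemble_detect(W, n_runs = 30, seed = sample.int(1e6, 1))
    abs(ens$modal_hamiltonian - best) < 1e-9
  })
  expect_gte(mean(hits), 0.95)
})

test_that("canonicalization makes relabeled partitions identical", {
  m1 <- c(2, 2, 1, 3, 1)
  m2 <- c(1, 1, 3, 2, 3)  # same grouping, different labels
  expect_equal(unname(netbridge:::canonicalize_membership(m1)),
               unname(netbridge:::canonicalize_membership(m2)))
})

test_that("ensemble tabulates solutions and co-classification", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  ens <- ensemble_detect(W, n_runs = 25, seed = 4)
  expect_equal(ens$modal_frequency, 1.0)
  expect_equal(nrow(ens$solutions), 1)
  expect_equal(sum(ens$solutions$frequency), 1)
  expect_equal(unname(ens$modal_partition), rep(1:2, each = 4))
  co <- ens$co_classification
  expect_true(all(co[1:4, 1:4] == 1))
  expect_true(all(co[1:4, 5:8] == 0))
  expect_equal(diag(co), rep(1, 8), ignore_attr = TRUE)
  expect_true(isSymmetric(co))

  # isolated node gets a singleton community
  W2 <- rbind(cbind(W, 0), 0)
  colnames(W2) <- rownames(W2) <- paste0("n", 1:9)
  ens2 <- ensemble_detect(W2, n_runs = 10, seed = 5)
  expect_equal(ens2$isolated, "n9")
  expect_equal(unname(ens2$modal_partition["n9"]), 3)
})

test_that("bridge expected influence sums cross-community edges", {
  W <- matrix(c(0, .3, -.1,
                .3, 0, .2,
                -.1, .2, 0), 3, 3, byrow = TRUE)
  bei <- bridge_expected_influence(W, c(1, 2, 2))
  expect_equal(unname(bei), c(0.2, 0.3, -0.1))
  # no cross-community edges
  expect_equal(unname(bridge_expected_influence(W, c(1, 1, 1))),
               c(0, 0, 0))
  # a node with edges only inside its community scores zero
  W4 <- matrix(0, 4, 4)
  W4[1, 2] <- W4[2, 1] <- 0.5
  W4[3, 4] <- W4[4, 3] <- 0.5
  expect_equal(unname(bridge_expected_influence(W4, c(1, 1, 2, 2))),
               rep(0, 4))
})

test_that("bridge flags use the interpolated percentile, inclusive", {
  bei <- setNames(seq(0, 0.9, by = 0.1), paste0("n", 1:10))
  fb <- flag_bridges(bei, 80)
  expect_equal(fb$cutoff, 0.72)
  expect_equal(fb$bridges, c("n9", "n10"))

  bei2 <- setNames(c(0, 0, 0, 0, 0.5), paste0("m", 1:5))
  expect_equal(flag_bridges(bei2, 80)$bridges, "m5")

  expect_warning(fb3 <- flag_bridges(setNames(rep(1, 4), letters[1:4])),
                 "equal")
  expect_equal(length(fb3$bridges), 4)
  expect_error(flag_bridges(bei[1]), "at least 2")
  expect_error(flag_bridges(bei, 100), "percentile")
})

test_that("modal solution energy never exceeds the planted partition's", {
  gt <- build_ground_truth(seed = 6)
  d <- sample_ordinal_data(gt, n = 400, seed = 6)
  m <- estimate_network(spearman_matrix(d$items,
                                        d$covariates[c("age", "functioning")]))
  ens <- ensemble_detect(m$weights, n_runs = 40, seed = 2)
  planted <- gt$partition_true[m$node_ids]
  expect_lte(ens$modal_hamiltonian,
             spin_hamiltonian(m$weights, planted) + 1e-9)
})
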