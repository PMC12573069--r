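test_that("item tables read, validate and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "0,0", "0,0", "0,0"), tmp)
  X <- load_item_table(tmp)
  expect_equal(dim(X), c(3, 2))
  expect_true(all(X == 0))
  expect_false(anyNA(X))

  # out-of-range cell names row and column
  writeLines(c("a,b", "0,4", "0,0", "1,2"), tmp)
  expect_error(load_item_table(tmp), "out-of-range.*'b'")

  # empty cells become missing markers
  writeLines(c("a,b", "0,", "1,2", "3,1"), tmp)
  X <- load_item_table(tmp)
  expect_true(is.na(X[1, "b"]))
  expect_equal(sum(is.na(X)), 1)

  # unknown item vs metadata
  md <- item_metadata(c("b", "a"), "anxiety", "social")
  writeLines(c("a,z", "0,1", "1,2", "3,1"), tmp)
  expect_error(load_item_table(tmp, md), "unknown item_id")

  # metadata fixes column order
  writeLines(c("a,b", "0,1", "1,2", "3,1"), tmp)
  X <- load_item_table(tmp, md)
  expect_equal(colnames(X), c("b", "a"))

  # write/read round-trip preserves values and missingness
  gt <- build_ground_truth(network_spec(communities = c(panic = 3L,
                                                        autism = 3L),
                                        bridge_nodes = "aut1",
                                        bridge_to = "panic",
                                        covariate_to = "panic"),
                           seed = 2)
  d <- sample_ordinal_data(gt, n = 30, missing_rate = 0.1, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_item_table(d$items, f)
  back <- load_item_table(f)
  expect_equal(unclass(back), unclass(d$items),
               ignore_attr = "dimnames")
})

test_that("config defaults, validation and YAML loading", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", tmp)
  cfg <- load_config(tmp)
  expect_equal(cfg$ebic_gamma, 0.5)
  expect_equal(cfg$n_boot, 1000L)
  expect_equal(cfg$bridge_percentile, 80)
  expect_equal(cfg$spinglass$n_runs, 1000L)
  expect_equal(cfg$drop_proportions, seq(0.1, 0.7, by = 0.1))

  writeLines("bridge_percentile: 150", tmp)
  expect_error(load_config(tmp), "bridge_percentile")
  writeLines("nonsense_key: 1", tmp)
  expect_error(load_config(tmp), "unknown config key")
  writeLines(c("ebic_gamma: 0.25", "n_boot: 50"), tmp)
  cfg <- load_config(tmp)
  expect_equal(cfg$ebic_gamma, 0.25)
  expect_equal(cfg$n_boot, 50L)
})

test_that("network export formats honor sparsity and round-trip", {
  th <- diag(3)
  th[1, 2] <- th[2, 1] <- -0.4
  colnames(th) <- rownames(th) <- c("a", "b", "c")
  model <- structure(list(node_ids = c("a", "b", "c"), theta = th,
                          weights = precision_to_partial(th),
                          lambda = 0.1, ebic_gamma = 0.5, n = 100),
                     class = "network_model")
  f <- withr::local_tempfile(fileext = ".csv")
  export_network(model, f, "edgelist")
  el <- read.csv(f)
  expect_equal(nrow(el), 1)
  expect_equal(el$node_a, "a")
  expect_equal(el$node_b, "b")

  j <- withr::local_tempfile(fileext = ".json")
  export_network(model, j, "json")
  back <- read_network_json(j)
  expect_equal(back$weights, model$weights, tolerance = 0)
  expect_equal(back$theta, model$theta, tolerance = 0)
  expect_equal(back$lambda, model$lambda)

  # empty network: empty edge list, GraphML with nodes only
  empty <- model
  empty$theta <- diag(3)
  dimnames(empty$theta) <- dimnames(th)
  empty$weights <- precision_to_partial(empty$theta)
  export_network(empty, f, "edgelist")
  expect_equal(nrow(read.csv(f)), 0)
  g <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, g, "graphml")
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(gr), 3)
  expect_equal(igraph::ecount(gr), 0)
})

test_that("item matrix constructor enforces its invariants", {
  m <- matrix(0:3, 2, 2, dimnames = list(NULL, c("a", "a")))
  expect_error(item_response_matrix(m), "duplicated")
  m <- matrix(c(0, 1, 2, 5), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(item_response_matrix(m), "out-of-range")
  expect_error(item_response_matrix(matrix(0, 1, 2,
                                           dimnames = list(NULL, c("a", "b")))),
               "at least 2")
  expect_error(covariate_table(data.frame(functioning = c(0, 2))),
               "1..8")
})
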