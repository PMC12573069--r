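# Full-pipeline orchestration: screening -> correlation -> estimation ->
# centrality/predictability -> ensemble communities -> bridges ->
# bootstraps, with machine-readable reports, layout and rendering.

#' Run the full network analysis
#'
#' Executes, for each configured node set: item screening
#' (informativeness + near-zero-variance exclusion, redundancy report),
#' covariate screening, the pairwise-complete Spearman matrix, EBIC
#' graphical lasso estimation, expected influence and predictability,
#' the Spinglass ensemble, bridge identification, and (when
#' `config$n_boot > 0`) the nonparametric and case-dropping bootstraps.
#' Identical seeds produce identical reports.
#'
#' @param items An [item_response_matrix()].
#' @param covariates Optional covariate data.frame aligned with `items`.
#' @param metadata Optional [item_metadata()] carried into exports.
#' @param config An [analysis_config()].
#' @return A list of class `analysis_report`: config echo, per-network
#'   results, package version and master seed.
#' @export
run_pipeline <- function(items, covariates = NULL, metadata = NULL,
                         config = analysis_config()) {
  validate_config(config)
  node_sets <- config$node_sets
  if (is.null(node_sets)) {
    all_nodes <- c(colnames(items),
                   if (!is.null(covariates))
                     setdiff(names(covariates), "sex"))
    node_sets <- list(network = all_nodes)
  }
  networks <- lapply(seq_along(node_sets), function(si) {
    set_name <- names(node_sets)[si]
    wanted <- node_sets[[si]]
    item_cols <- intersect(wanted, colnames(items))
    cov_cols <- intersect(wanted,
                          if (is.null(covariates)) character()
                          else names(covariates))
    if (length(item_cols) < 2)
      stopf("[screening] node set '%s' selects fewer than 2 items",
            set_name)
    X <- items[, item_cols, drop = FALSE]
    class(X) <- class(items)
    analyze_node_set(set_name, X,
                     if (length(cov_cols))
                       covariates[, cov_cols, drop = FALSE] else NULL,
                     metadata, config)
  })
  names(networks) <- names(node_sets)
  structure(list(config = config[setdiff(names(config), "node_sets")],
                 node_sets = lapply(node_sets, identity),
                 networks = networks,
                 version = as.character(utils::packageVersion("netbridge")),
                 seed = config$seed),
            class = "analysis_report")
}

analyze_node_set <- function(set_name, X, covariates, metadata, config) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", what, conditionMessage(e)))
  }
  screen <- stage("screening", informativeness(
    X, sd_k = config$informativeness_sd_k,
    max_prop = config$informativeness_max_prop))
  Xk <- stage("screening", variance_filter(X, screen))
  redundant <- stage("screening", {
    if (ncol(Xk) >= 3) redundancy_screen(Xk) else
      data.frame(item_a = character(), item_b = character(),
                 cor = numeric(), prop_significant = numeric(),
                 redundant = logical())
  })
  cov_screen <- NULL
  cov_kept <- NULL
  if (!is.null(covariates) && ncol(covariates) > 0) {
    cov_screen <- stage("screening", covariate_screen(Xk, covariates))
    if (length(cov_screen$included) > 0)
      cov_kept <- covariates[, cov_screen$included, drop = FALSE]
  }
  S <- stage("correlation", spearman_matrix(Xk, cov_kept))
  model <- stage("estimation", estimate_network(
    S, gamma = config$ebic_gamma, n_lambda = config$n_lambda,
    lambda_min_ratio = config$lambda_min_ratio))
  ei <- stage("inference", expected_influence(model))
  pred <- stage("inference", predictability(model))
  sg <- config$spinglass
  ens <- stage("communities", ensemble_detect(
    model$weights, n_runs = sg$n_runs, seed = config$seed,
    max_spins = sg$max_spins, start_temp = sg$start_temp,
    stop_temp = sg$stop_temp, cooling = sg$cooling,
    sweeps_per_temp = sg$sweeps_per_temp))
  bei <- stage("bridges", bridge_expected_influence(
    model$weights, ens$modal_partition))
  bridges <- stage("bridges", flag_bridges(bei,
                                           config$bridge_percentile))
  boot <- NULL
  casedrop <- NULL
  cs <- NULL
  if (config$n_boot > 0) {
    boot <- stage("bootstrap", nonparametric_bootstrap(
      Xk, cov_kept, B = config$n_boot, seed = config$seed,
      gamma = config$ebic_gamma, n_lambda = config$n_lambda,
      lambda_min_ratio = config$lambda_min_ratio, edge_diff = FALSE))
    casedrop <- stage("bootstrap", case_dropping_bootstrap(
      Xk, cov_kept, proportions = config$drop_proportions,
      B = config$n_boot, seed = config$seed,
      gamma = config$ebic_gamma, n_lambda = config$n_lambda,
      lambda_min_ratio = config$lambda_min_ratio))
    cs <- cs_coefficient(casedrop)
  }
  p <- length(model$node_ids)
  candidate_edges <- p * (p - 1) / 2
  nonzero_edges <- sum(model$weights[upper.tri(model$weights)] != 0)
  list(name = set_name,
       screening = list(informativeness = screen,
                        excluded = attr(Xk, "excluded"),
                        redundant_pairs = redundant,
                        covariates = cov_screen),
       node_ids = model$node_ids,
       n_nodes = p,
       candidate_edges = candidate_edges,
       nonzero_edges = nonzero_edges,
       nonzero_proportion = nonzero_edges / candidate_edges,
       lambda = model$lambda,
       model = model,
       expected_influence = ei,
       predictability = pred,
       mean_predictability = attr(pred, "mean_r2"),
       ensemble = ens,
       bridge = bridges,
       bootstrap = boot,
       case_dropping = casedrop,
       cs = cs)
}

#' Write an analysis report as JSON
#'
#' Serializes the report (screening tables, per-network summaries,
#' centrality, community ensemble summary, bridges, stability) with full
#' numeric precision. Two runs with the same seed produce byte-identical
#' files.
#'
#' @param report An `analysis_report`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_report_json <- function(report, file) {
  nets <- lapply(report$networks, function(net) {
    list(name = net$name,
         node_ids = net$node_ids,
         n_nodes = net$n_nodes,
         candidate_edges = net$candidate_edges,
         nonzero_edges = net$nonzero_edges,
         nonzero_proportion = net$nonzero_proportion,
         lambda = net$lambda,
         weights = net$model$weights,
         theta = net$model$theta,
         expected_influence = net$expected_influence,
         predictability = net$predictability,
         mean_predictability = net$mean_predictability,
         communities = list(
           modal_partition = as.list(net$ensemble$modal_partition),
           modal_frequency = net$ensemble$modal_frequency,
           n_solutions = nrow(net$ensemble$solutions),
           solutions = net$ensemble$solutions),
         bridge = list(bei = as.list(net$bridge$bei),
                       cutoff = net$bridge$cutoff,
                       percentile = net$bridge$percentile,
                       bridges = net$bridge$bridges),
         cs = if (!is.null(net$cs)) as.list(net$cs) else NULL,
         screening = list(
           excluded = net$screening$excluded,
           redundant_pairs = net$screening$redundant_pairs,
           included_covariates =
             if (!is.null(net$screening$covariates))
               net$screening$covariates$included else character()))
  })
  obj <- list(version = report$version, seed = report$seed,
              config = report$config, networks = nets)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(file)
}

#' Fruchterman-Reingold layout
#'
#' Force-directed 2-D coordinates computed on the absolute edge weights,
#' centered at the origin and scaled to the unit bounding box.
#' Deterministic for a given seed.
#'
#' @param W Edge-weight matrix or `network_model`.
#' @param seed RNG seed (default 1).
#' @param iterations Iterations of the layout algorithm (default 500).
#' @return n x 2 matrix of coordinates (rows named by node).
#' @export
fr_layout <- function(W, seed = 1L, iterations = 500) {
  if (inherits(W, "network_model")) W <- W$weights
  ids <- colnames(W)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(W)))
  if (ncol(W) == 1)
    return(matrix(0, 1, 2, dimnames = list(ids, c("x", "y"))))
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  xy <- with_seed(seed, igraph::layout_with_fr(
    g, niter = iterations,
    weights = if (igraph::ecount(g) > 0) igraph::E(g)$weight else NULL))
  xy <- sweep(xy, 2, colMeans(xy))
  mx <- max(abs(xy))
  if (mx > 0) xy <- xy / mx
  dimnames(xy) <- list(ids, c("x", "y"))
  xy
}

draw_ring <- function(x, y, r, frac, col) {
  th <- seq(0, 2 * pi, length.out = 120)
  graphics::polygon(x + 1.18 * r * cos(th), y + 1.18 * r * sin(th),
                    border = "grey70", col = NA, lwd = 1.4)
  if (frac > 0) {
    th2 <- seq(pi / 2, pi / 2 - 2 * pi * frac, length.out = 120)
    graphics::lines(x + 1.18 * r * cos(th2), y + 1.18 * r * sin(th2),
                    col = col, lwd = 3)
  }
}

plot_network_figure <- function(net, layout, file) {
  W <- net$model$weights
  p <- ncol(W)
  comm <- net$ensemble$modal_partition
  pal <- grDevices::hcl.colors(max(comm), palette = "Dark 3")
  pred <- setNames(net$predictability$r2, net$predictability$node)
  grDevices::png(file, width = 900, height = 900, res = 120)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = net$name)
  wmax <- max(abs(W))
  if (wmax > 0) {
    idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      w <- W[i, j]
      graphics::segments(layout[i, 1], layout[i, 2],
                         layout[j, 1], layout[j, 2],
                         lwd = 0.5 + 4 * abs(w) / wmax,
                         lty = if (w > 0) 1 else 2,
                         col = if (w > 0) "#3366AAAA" else "#BB3333AA")
    }
  }
  r <- 0.045
  for (i in seq_len(p)) {
    draw_ring(layout[i, 1], layout[i, 2], r, pred[i], "grey30")
    graphics::symbols(layout[i, 1], layout[i, 2], circles = r,
                      inches = FALSE, add = TRUE,
                      bg = pal[comm[i]], fg = "grey20")
    lab <- rownames(layout)[i]
    if (lab %in% net$bridge$bridges) lab <- paste0(lab, "*")
    graphics::text(layout[i, 1], layout[i, 2], lab, cex = 0.45)
  }
  invisible(file)
}

plot_ei_figure <- function(net, file) {
  ei <- net$expected_influence
  ei <- ei[order(ei$ei_z), ]
  grDevices::png(file, width = 700, height = 900, res = 120)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(4, 7, 2, 1))
  graphics::barplot(ei$ei_z, names.arg = ei$node, horiz = TRUE,
                    las = 1, cex.names = 0.6,
                    xlab = "Expected influence (z)",
                    main = net$name, col = "#3366AA")
  invisible(file)
}

#' Render an analysis report to files
#'
#' Writes, per network: the network figure (edge thickness proportional
#' to weight, solid positive / dashed negative edges, predictability
#' rings, community colors, asterisks on bridge nodes), the ranked
#' expected-influence chart, edge-list CSV, GraphML with node
#' attributes, ensemble solution and co-classification CSVs — plus the
#' overall JSON report.
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if absent).
#' @param layout_seed Seed of the shared layout (default: report seed).
#' @return Character vector of written files, invisibly.
#' @export
render_report <- function(report, out_dir, layout_seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", out_dir)
  }
  if (is.null(layout_seed)) layout_seed <- report$seed
  files <- character()
  emit <- function(f) files <<- c(files, f)
  # one layout on the largest network, reused where nodes are shared
  sizes <- vapply(report$networks, function(n) n$n_nodes, 1)
  ref_layout <- fr_layout(report$networks[[which.max(sizes)]]$model,
                          seed = layout_seed)
  for (net in report$networks) {
    base <- file.path(out_dir, net$name)
    lay <- if (all(net$node_ids %in% rownames(ref_layout)))
      ref_layout[net$node_ids, , drop = FALSE]
    else fr_layout(net$model, seed = layout_seed)
    attrs <- data.frame(
      community = unname(net$ensemble$modal_partition),
      ei = net$expected_influence$ei,
      predictability = net$predictability$r2,
      bridge = net$node_ids %in% net$bridge$bridges)
    emit(export_network(net$model, paste0(base, "_edges.csv"),
                        "edgelist"))
    emit(export_network(net$model, paste0(base, ".graphml"), "graphml",
                        node_attrs = attrs))
    write.csv(net$ensemble$solutions,
              paste0(base, "_solutions.csv"), row.names = FALSE)
    emit(paste0(base, "_solutions.csv"))
    write.csv(net$ensemble$co_classification,
              paste0(base, "_coclassification.csv"))
    emit(paste0(base, "_coclassification.csv"))
    emit(plot_network_figure(net, lay, paste0(base, "_network.png")))
    emit(plot_ei_figure(net, paste0(base, "_ei.png")))
  }
  emit(write_report_json(report, file.path(out_dir, "report.json")))
  invisible(files)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("netbridge analysis report (seed %d)\n", x$seed))
  for (net in x$networks) {
    cat(sprintf(
      " - %s: %d nodes, %d/%d edges nonzero (%.1f%%), modal solution %.1f%% (%d communities), %d bridge node(s)\n",
      net$name, net$n_nodes, net$nonzero_edges, net$candidate_edges,
      100 * net$nonzero_proportion, 100 * net$ensemble$modal_frequency,
      length(unique(net$ensemble$modal_partition)),
      length(net$bridge$bridges)))
  }
  invisible(x)
}
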