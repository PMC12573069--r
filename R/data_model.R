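# Core data types and file I/O: ordinal item matrices, item metadata,
# covariate tables, analysis configuration, and network export formats.

#' Construct an ordinal item-response matrix
#'
#' Wraps and validates a person x item matrix of ordinal questionnaire
#' scores. Non-missing entries must be integers in 0--3 (the caregiver
#' rating scale from "never" to "always"); missing responses are `NA`.
#'
#' @param values Numeric matrix, persons in rows, items in columns.
#' @param row_ids Optional person identifiers (default: existing rownames
#'   or `person_1..person_n`).
#' @param item_ids Optional item identifiers (default: column names).
#' @return An integer matrix of class `item_matrix` with row and column
#'   names set.
#' @export
item_response_matrix <- function(values, row_ids = NULL, item_ids = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  n <- nrow(values)
  p <- ncol(values)
  if (n < 2L || p < 2L)
    stopf("item matrix needs at least 2 rows and 2 columns (got %d x %d)",
          n, p)
  if (is.null(item_ids)) item_ids <- colnames(values)
  if (is.null(item_ids))
    stopf("item_ids are required (no column names present)")
  if (anyDuplicated(item_ids))
    stopf("duplicated item_ids: %s",
          paste(unique(item_ids[duplicated(item_ids)]), collapse = ", "))
  if (is.null(row_ids)) row_ids <- rownames(values)
  if (is.null(row_ids)) row_ids <- paste0("person_", seq_len(n))
  bad <- which(!is.na(values) & !(values %in% 0:3))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% n) + 1
    j <- ((bad[1] - 1) %/% n) + 1
    stopf("out-of-range score %s at row '%s', item '%s' (allowed: 0-3)",
          format(values[bad[1]]), row_ids[i], item_ids[j])
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(row_ids, item_ids)
  class(values) <- c("item_matrix", class(values))
  values
}

#' Item metadata table
#'
#' One record per item: its instrument (`anxiety` or `autism`) and
#' subscale label. Every item in an [item_response_matrix()] must have
#' exactly one metadata record.
#'
#' @param item_id Character vector of item identifiers.
#' @param instrument `"anxiety"` or `"autism"`, recycled if length 1.
#' @param subscale Subscale labels (e.g. panic/agoraphobia, separation,
#'   social, generalized; autism: social-communication,
#'   focused/repetitive, sensory).
#' @param text Optional item text.
#' @return A data.frame with columns `item_id`, `instrument`, `subscale`,
#'   `text`.
#' @export
item_metadata <- function(item_id, instrument, subscale, text = "") {
  if (anyDuplicated(item_id))
    stopf("duplicated item_id in metadata")
  instrument <- rep_len(as.character(instrument), length(item_id))
  ok <- instrument %in% c("anxiety", "autism", "covariate")
  if (!all(ok))
    stopf("unknown instrument: %s",
          paste(unique(instrument[!ok]), collapse = ", "))
  data.frame(item_id = as.character(item_id),
             instrument = instrument,
             subscale = rep_len(as.character(subscale), length(item_id)),
             text = rep_len(as.character(text), length(item_id)),
             stringsAsFactors = FALSE)
}

#' Read an item-response CSV
#'
#' The CSV header must contain item identifiers; cells are integer scores
#' 0--3 or empty (missing). Columns are reordered to follow the metadata
#' order; unknown columns are an error.
#'
#' @param path CSV file path.
#' @param metadata Optional [item_metadata()] table used to check and
#'   order the columns.
#' @return An [item_response_matrix()].
#' @export
load_item_table <- function(path, metadata = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- colnames(df)
  if (!is.null(metadata)) {
    unknown <- setdiff(ids, metadata$item_id)
    if (length(unknown) > 0)
      stopf("unknown item_id(s) in '%s': %s", path,
            paste(unknown, collapse = ", "))
    ids <- metadata$item_id[metadata$item_id %in% ids]
    df <- df[, ids, drop = FALSE]
  }
  m <- as.matrix(df)
  if (is.character(m)) {
    m[m == ""] <- NA
    num <- suppressWarnings(as.numeric(m))
    if (any(is.na(num) & !is.na(m)))
      stopf("non-numeric cell(s) in '%s'", path)
    m <- matrix(num, nrow(df), ncol(df), dimnames = dimnames(m))
  }
  item_response_matrix(m, item_ids = ids)
}

#' Read a covariate CSV
#'
#' Expects columns among `age` (years, continuous), `functioning`
#' (ordinal approximate level of functioning, 1--8) and `sex`.
#'
#' @param path CSV file path.
#' @param row_ids Optional person identifiers the rows must align with.
#' @return A validated data.frame.
#' @export
load_covariates <- function(path, row_ids = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  covariate_table(df, row_ids = row_ids)
}

#' Validate a covariate table
#'
#' @param df data.frame of covariates, rows aligned with the item matrix.
#' @param row_ids Optional person identifiers to check length against.
#' @return The validated data.frame.
#' @export
covariate_table <- function(df, row_ids = NULL) {
  df <- as.data.frame(df)
  if (!is.null(row_ids) && nrow(df) != length(row_ids))
    stopf("covariate table has %d rows; expected %d", nrow(df),
          length(row_ids))
  if ("functioning" %in% names(df)) {
    f <- df$functioning
    if (any(!is.na(f) & !(f %in% 1:8)))
      stopf("functioning must be an ordinal level in 1..8")
  }
  df
}

default_spinglass_opts <- function() {
  list(n_runs = 1000L, max_spins = NULL, start_temp = 1.0,
       stop_temp = 0.01, cooling = 0.99, sweeps_per_temp = 5L)
}

#' Analysis configuration
#'
#' Bundles all tunable settings of the pipeline with the study defaults:
#' EBIC hyperparameter `gamma = 0.5` (the conservative default), a
#' 100-value penalty path down to 1% of the maximum, 1000 bootstrap
#' iterations, the 80th-percentile bridge cutoff, a 1000-run Spinglass
#' ensemble, and case-dropping proportions 0.1--0.7.
#'
#' @param node_sets Named list of character vectors: the node sets
#'   (item ids plus covariate names) to analyze as separate networks.
#'   `NULL` means one network over all available nodes.
#' @param ebic_gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda Number of penalty values on the path (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest
#'   (default 0.01).
#' @param n_boot Bootstrap iterations (default 1000; 0 skips bootstraps).
#' @param bridge_percentile Percentile cutoff for bridge flags (default
#'   80, must lie in (0, 100)).
#' @param informativeness_sd_k Relative informativeness rule: flag items
#'   whose SD falls this many between-item SDs below the mean item SD
#'   (default 2.5; `Inf` disables the relative rule, leaving only the
#'   dominant-category rule).
#' @param informativeness_max_prop Flag items whose most frequent
#'   category exceeds this proportion (default 0.95).
#' @param spinglass List of Spinglass ensemble settings: `n_runs`,
#'   `max_spins`, `start_temp`, `stop_temp`, `cooling`,
#'   `sweeps_per_temp`.
#' @param drop_proportions Case-dropping proportions (default 0.1--0.7 by
#'   0.1).
#' @param seed Master seed for all randomness.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(node_sets = NULL,
                            ebic_gamma = 0.5,
                            n_lambda = 100L,
                            lambda_min_ratio = 0.01,
                            n_boot = 1000L,
                            bridge_percentile = 80,
                            informativeness_sd_k = 2.5,
                            informativeness_max_prop = 0.95,
                            spinglass = list(),
                            drop_proportions = seq(0.1, 0.7, by = 0.1),
                            seed = 1L) {
  sg <- utils::modifyList(default_spinglass_opts(), spinglass)
  cfg <- list(node_sets = node_sets, ebic_gamma = ebic_gamma,
              n_lambda = as.integer(n_lambda),
              lambda_min_ratio = lambda_min_ratio,
              n_boot = as.integer(n_boot),
              bridge_percentile = bridge_percentile,
              informativeness_sd_k = informativeness_sd_k,
              informativeness_max_prop = informativeness_max_prop,
              spinglass = sg,
              drop_proportions = drop_proportions,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  chk_pos <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || any(is.na(v)) || any(v <= 0))
      stopf("config '%s' must be positive numeric", key)
  }
  for (key in c("ebic_gamma", "n_lambda", "lambda_min_ratio",
                "bridge_percentile", "informativeness_sd_k",
                "informativeness_max_prop", "seed"))
    chk_pos(key)
  if (!is.numeric(cfg$n_boot) || cfg$n_boot < 0)
    stopf("config 'n_boot' must be >= 0")
  if (cfg$bridge_percentile <= 0 || cfg$bridge_percentile >= 100)
    stopf("config 'bridge_percentile' must lie in (0, 100), got %s",
          format(cfg$bridge_percentile))
  if (any(cfg$drop_proportions <= 0 | cfg$drop_proportions >= 1))
    stopf("config 'drop_proportions' must lie in (0, 1)")
  sg <- cfg$spinglass
  for (key in c("n_runs", "start_temp", "stop_temp", "cooling",
                "sweeps_per_temp")) {
    if (!is.numeric(sg[[key]]) || sg[[key]] <= 0)
      stopf("config 'spinglass.%s' must be positive numeric", key)
  }
  if (sg$cooling >= 1)
    stopf("config 'spinglass.cooling' must be < 1")
  invisible(cfg)
}

#' Load an analysis configuration from YAML
#'
#' Defaults are applied for absent keys; an empty file yields the full
#' default configuration. Invalid values raise an error naming the key.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stopf("malformed YAML in '%s': %s",
                                            path, conditionMessage(e)))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stopf("config '%s' must be a YAML mapping", path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(analysis_config, raw)
}

#' Export a network model
#'
#' Writes the selected network as an upper-triangle edge list CSV (only
#' nonzero edges, weights rounded to 6 decimals), as GraphML with node
#' attributes, or as a full-precision JSON report that round-trips via
#' [read_network_json()].
#'
#' @param model A `network_model` from [estimate_network()].
#' @param file Output file path.
#' @param format `"edgelist"`, `"graphml"` or `"json"`.
#' @param node_attrs Optional data.frame of per-node attributes (e.g.
#'   subscale, community, expected influence, predictability, bridge
#'   flag) carried into GraphML; must have one row per node.
#' @return `file`, invisibly.
#' @export
export_network <- function(model, file,
                           format = c("edgelist", "graphml", "json"),
                           node_attrs = NULL) {
  format <- match.arg(format)
  W <- model$weights
  ids <- model$node_ids
  if (format == "edgelist") {
    idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    df <- data.frame(node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
                     weight = round(W[idx], 6))
    write.csv(df, file, row.names = FALSE)
  } else if (format == "graphml") {
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::V(g)$name <- ids
    if (!is.null(node_attrs)) {
      if (nrow(node_attrs) != length(ids))
        stopf("node_attrs must have one row per node")
      for (nm in setdiff(names(node_attrs), "node"))
        g <- igraph::set_vertex_attr(g, nm, value = node_attrs[[nm]])
    }
    igraph::write_graph(g, file, format = "graphml")
  } else {
    obj <- list(node_ids = ids,
                theta = model$theta,
                weights = W,
                lambda = model$lambda,
                ebic_gamma = model$ebic_gamma,
                n = model$n)
    jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  }
  invisible(file)
}

#' Read a JSON network export back into a `network_model`
#'
#' @param file Path written by [export_network()] with `format = "json"`.
#' @return A `network_model`.
#' @export
read_network_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  ids <- obj$node_ids
  as_mat <- function(x) {
    if (!is.matrix(x))
      x <- matrix(unlist(x), length(ids), length(ids), byrow = TRUE)
    dimnames(x) <- list(ids, ids)
    x
  }
  theta <- as_mat(obj$theta)
  W <- as_mat(obj$weights)
  structure(list(node_ids = ids, theta = theta, weights = W,
                 lambda = obj$lambda, ebic_gamma = obj$ebic_gamma,
                 n = obj$n, path = NULL),
            class = "network_model")
}

#' Write an item matrix to CSV (empty cells for missing)
#'
#' @param X An [item_response_matrix()].
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_item_table <- function(X, file) {
  df <- as.data.frame(unclass(X))
  write.csv(df, file, row.names = FALSE, na = "")
  invisible(file)
}
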