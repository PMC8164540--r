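# End-to-end pipeline: expression -> correlation graph -> mixture-ERGM
# clusters -> MRF hub calls -> (optional) gene-set enrichment. One global
# seed fans out deterministically to per-stage child seeds, so any stage
# can be re-run in isolation and reproduce the full run.

#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults matching the module-level
#' defaults, serializable to/from JSON for run manifests.
#'
#' @param threshold Correlation threshold for [build_cell_graph()].
#' @param transform Expression transform for [pearson_matrix()].
#' @param terms,decay ERGM term set and decay for [stat_config()].
#' @param G Fixed number of clusters, or `NULL` to select by ICL.
#' @param G_range Candidate cluster numbers when `G` is `NULL`.
#' @param max_iter,tol,n_restarts,online,step_size_exponent EM options.
#' @param hp [mrf_hyperparams()] for the hub stage.
#' @param n_burnin,n_samples Gibbs sweeps for the hub stage.
#' @param invert_hv Apply the hub z-transform to `1 - hv`.
#' @param enrich_mode Enrichment tail/point mode.
#' @param enrich_adjust Enrichment multiplicity adjustment.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(threshold = 0.27, transform = "log1p",
                       terms = c("edges", "two_stars", "gwesp", "gw_degree"),
                       decay = 0.5, G = NULL, G_range = 2:6,
                       max_iter = 50L, tol = 1e-6, n_restarts = 1L,
                       online = FALSE, step_size_exponent = 0.7,
                       hp = mrf_hyperparams(), n_burnin = 1000L,
                       n_samples = 5000L, invert_hv = FALSE,
                       enrich_mode = "tail", enrich_adjust = "none",
                       seed = 1L) {
  structure(list(
    threshold = threshold, transform = transform, terms = terms,
    decay = decay, G = G, G_range = G_range, max_iter = max_iter, tol = tol,
    n_restarts = n_restarts, online = online,
    step_size_exponent = step_size_exponent, hp = unclass(hp),
    n_burnin = n_burnin, n_samples = n_samples, invert_hv = invert_hv,
    enrich_mode = enrich_mode, enrich_adjust = enrich_adjust,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param config A [run_config()] object.
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- run_config()
  raw <- raw[intersect(names(raw), names(base))]
  if (!is.null(raw$hp)) raw$hp <- do.call(mrf_hyperparams, as.list(raw$hp))
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes graph construction, mixture-ERGM clustering (with ICL selection
#' of the number of clusters unless `config$G` is fixed), MRF hub
#' detection, and optionally gene-set enrichment of a prioritized gene
#' list. All stage outputs, a JSON manifest sufficient to replay the run,
#' and a log are written to `out_dir`. Runs with identical inputs, config
#' and seed produce identical outputs.
#'
#' @param expr Genes-by-cells matrix, or a path readable by
#'   [read_expression()].
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config()].
#' @param gene_sets Optional named list of gene sets (or a GMT path) for
#'   the enrichment stage.
#' @param prioritized Optional character vector of prioritized gene ids;
#'   required for the enrichment stage.
#' @return A `pipeline_result` list: `graph`, `model`, `icl_table` (when G
#'   was selected), `clusters`, `hubs`, `enrichment` (or `NULL`),
#'   `manifest`, `out_dir`.
#' @export
run_pipeline <- function(expr, out_dir, config = run_config(),
                         gene_sets = NULL, prioritized = NULL) {
  if (is.character(expr)) {
    if (!file.exists(expr)) abort(sprintf("Missing input file: %s", expr))
    expr <- read_expression(expr)
  }
  expr <- expression_matrix(expr)
  if (is.character(gene_sets)) {
    if (!file.exists(gene_sets)) {
      abort(sprintf("Missing gene-set file: %s", gene_sets))
    }
    gene_sets <- read_gmt(gene_sets)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  say("[graph] %d genes x %d cells; transform=%s threshold=%g",
      nrow(expr), ncol(expr), config$transform, config$threshold)
  corr <- pearson_matrix(expr, transform = config$transform)
  graph <- build_cell_graph(corr, threshold = config$threshold)
  write_edge_list(graph, file.path(out_dir, "edges.tsv"))
  say("[graph] %d edges among %d cells", igraph::ecount(graph),
      igraph::vcount(graph))

  sc <- stat_config(config$terms, config$decay)
  cl_seed <- derive_seed(config$seed, "cluster")
  icl_tab <- NULL
  if (is.null(config$G)) {
    sel <- select_G(graph, G_range = config$G_range, config = sc,
                    max_iter = config$max_iter, tol = config$tol,
                    n_restarts = config$n_restarts, seed = cl_seed,
                    online = config$online,
                    step_size_exponent = config$step_size_exponent)
    model <- sel$best_model
    icl_tab <- sel$table
    say("[cluster] ICL selected G = %d over {%s}", sel$best_G,
        paste(config$G_range, collapse = ","))
  } else {
    model <- fit_mixture_ergm(graph, G = config$G, config = sc,
                              max_iter = config$max_iter, tol = config$tol,
                              n_restarts = config$n_restarts, seed = cl_seed,
                              online = config$online,
                              step_size_exponent = config$step_size_exponent)
    icl_tab <- icl(model)
    say("[cluster] fitted fixed G = %d", config$G)
  }
  clusters <- cluster_assignments(model)
  readr::write_tsv(clusters, file.path(out_dir, "clusters.tsv"),
                   progress = FALSE)
  readr::write_tsv(icl_tab, file.path(out_dir, "icl.tsv"), progress = FALSE)
  say("[cluster] L_C = %.4f, sizes: %s", model$L_C,
      paste(tabulate(model$labels, model$G), collapse = "/"))

  hv <- hub_values(graph, model$labels)
  omega <- z_transform(hv, invert = config$invert_hv)
  hp <- do.call(mrf_hyperparams, as.list(config$hp))
  post <- gibbs_posterior(omega, graph, hp = hp,
                          n_burnin = config$n_burnin,
                          n_samples = config$n_samples,
                          seed = derive_seed(config$seed, "hubs"))
  deg <- igraph::degree(graph)
  hubs <- tibble::tibble(
    node_id = igraph::V(graph)$name,
    degree = as.integer(deg),
    n_distinct_neighbor_clusters = as.integer(round(hv * pmax(deg, 1))),
    hv = unname(hv),
    omega = unname(omega),
    posterior_marginal = unname(post$marginal),
    hub_call = unname(post$hub_call)
  )
  readr::write_tsv(hubs, file.path(out_dir, "hubs.tsv"), progress = FALSE)
  say("[hubs] %d hub call(s) at marginal > 0.5", sum(hubs$hub_call))

  enr <- NULL
  if (!is.null(gene_sets) && !is.null(prioritized)) {
    enr <- enrich_collection(prioritized, rownames(expr), gene_sets,
                             mode = config$enrich_mode,
                             adjust = config$enrich_adjust)
    readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
    say("[enrich] %d gene set(s); smallest P = %.3g", nrow(enr),
        min(enr$p_value))
  }

  manifest <- list(
    package = "cellmixnet",
    version = as.character(utils::packageVersion("cellmixnet")),
    config = unclass(config),
    seed = config$seed,
    stage_seeds = list(cluster = cl_seed,
                       hubs = derive_seed(config$seed, "hubs")),
    dims = list(genes = nrow(expr), cells = ncol(expr),
                edges = igraph::ecount(graph)),
    icl_table = as.data.frame(icl_tab),
    selected_G = model$G,
    logpl_trace = model$logpl_trace
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(log_lines, log_path)

  structure(list(graph = graph, model = model, icl_table = icl_tab,
                 clusters = clusters, hubs = hubs, enrichment = enr,
                 manifest = manifest, out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> G = %d clusters, %d hub call(s), outputs in %s\n",
              x$model$G, sum(x$hubs$hub_call), x$out_dir))
  invisible(x)
}
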