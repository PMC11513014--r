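#' Default pipeline configuration
#'
#' Nested list mirroring the YAML schema accepted by [run_pipeline()]:
#' `data` (either `synthetic: true` plus [synthetic_spec()] fields, or file
#' paths under `paths`), `preprocess`, `graph`, `model` ([mml_config()]
#' fields), `clustering`, `svg`, and a global `seed`.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 0,
    output_dir = "spotfuse_output",
    data = list(synthetic = TRUE),
    preprocess = list(n_hvg = 3000, normalize = TRUE, log1p = TRUE),
    graph = list(k = 6),
    model = list(epochs = 600),
    clustering = list(K = NULL, method = "gmm", refine = FALSE),
    svg = list(run = TRUE, fc_threshold = 1.5, alpha_fdr = 0.05,
               portion = 1.0, target_mean_neighbors = 10)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

load_pipeline_config <- function(config) {
  user <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else if (is.null(config)) {
    list()
  } else {
    stop("config must be a YAML path or a list")
  }
  merge_config(default_pipeline_config(), user)
}

pipeline_dataset <- function(cfg, verbose = TRUE) {
  dc <- cfg$data
  if (isTRUE(dc$synthetic)) {
    spec_args <- dc[setdiff(names(dc), c("synthetic", "paths"))]
    if (is.null(spec_args$seed)) spec_args$seed <- cfg$seed
    spec <- do.call(synthetic_spec, spec_args)
    log_msg("generating synthetic dataset (%d x %d grid, K = %d, seed %d)",
            spec$n_rows, spec$n_cols, spec$K, spec$seed, verbose = verbose)
    sim <- generate_synthetic(spec)
    list(ds = sim$dataset, truth_svgs = sim$truth_svgs)
  } else {
    p <- dc$paths
    if (is.null(p$expr)) stop("config error: data.paths.expr is required when data.synthetic is false")
    if (is.null(p$image) && !isTRUE(dc$allow_missing_image)) {
      stop("config error: no image features given; provide data.paths.image ",
           "or set data.allow_missing_image to run without the image modality")
    }
    log_msg("reading dataset from %s", p$expr, verbose = verbose)
    ds <- read_dataset(p$expr, coords_path = p$coords,
                       image_path = p$image, labels_path = p$labels,
                       format = dc$format %||% "tabular")
    list(ds = ds, truth_svgs = NULL)
  }
}

#' Run the full two-stage pipeline
#'
#' Executes load/simulate, preprocessing, spatial-graph construction,
#' multi-modal training, domain clustering and (optionally) SVG detection,
#' writing all artifacts to the output directory: `domains.csv`,
#' `loss_trace.csv`, `svg_report.csv` + per-domain gene lists,
#' `metrics.json` (ARI/NMI when reference labels exist; median Moran's I of
#' the detected SVGs), and `config_used.yaml` recording every resolved
#' default and seed.
#'
#' @param config YAML file path or nested list (see
#'   [default_pipeline_config()]); `NULL` runs the synthetic default.
#' @param output_dir overrides `config$output_dir`.
#' @param seed overrides `config$seed`.
#' @param verbose log progress to the console.
#' @return Invisibly, a list with the dataset, graph, fit, assignment,
#'   SVG report, metrics and artifact paths.
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL, seed = NULL,
                         verbose = TRUE) {
  cfg <- load_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  inp <- pipeline_dataset(cfg, verbose)
  ds <- inp$ds

  log_msg("preprocessing (n_hvg = %d)", cfg$preprocess$n_hvg,
          verbose = verbose)
  ds <- preprocess(ds, n_hvg = cfg$preprocess$n_hvg,
                   normalize = cfg$preprocess$normalize,
                   log1p = cfg$preprocess$log1p)

  log_msg("building spatial kNN graph (k = %d)", cfg$graph$k,
          verbose = verbose)
  graph <- build_knn_graph(ds$coords, k = cfg$graph$k)

  model_args <- cfg$model
  if (is.null(model_args$seed)) model_args$seed <- cfg$seed
  mcfg <- do.call(mml_config, model_args)
  log_msg("training multi-modal model (%d epochs, seed %d)",
          mcfg$epochs, mcfg$seed, verbose = verbose)
  fit <- train_mml(ds, graph, mcfg)
  write_loss_trace(fit, file.path(out, "loss_trace.csv"))

  K <- cfg$clustering$K
  if (is.null(K)) {
    if (is.null(ds$labels)) {
      stop("config error: clustering.K is required when the dataset has no ",
           "reference labels")
    }
    K <- length(unique(ds$labels))
  }
  log_msg("clustering embedding into K = %d domains (%s)", K,
          cfg$clustering$method, verbose = verbose)
  assignment <- cluster_embedding(fit$Zfusion, K,
                                  method = cfg$clustering$method,
                                  seed = cfg$seed)
  if (isTRUE(cfg$clustering$refine)) {
    assignment <- refine_domains(assignment, graph)
  }
  write_domains(assignment, ds$spot_ids, file.path(out, "domains.csv"))

  metrics <- list(seed = cfg$seed, K = K, n_spots = nrow(ds$expr),
                  n_genes = ncol(ds$expr))
  if (!is.null(ds$labels)) {
    agr <- score_agreement(assignment$labels, ds$labels)
    metrics$ari <- agr$ari
    metrics$nmi <- agr$nmi
    log_msg("domain agreement: ARI %.3f, NMI %.3f", agr$ari, agr$nmi,
            verbose = verbose)
  }

  report <- NULL
  if (isTRUE(cfg$svg$run)) {
    log_msg("detecting spatially variable genes", verbose = verbose)
    report <- detect_svgs(ds, assignment,
                          fc_threshold = cfg$svg$fc_threshold,
                          alpha_fdr = cfg$svg$alpha_fdr,
                          portion = cfg$svg$portion,
                          target_mean_neighbors = cfg$svg$target_mean_neighbors)
    write_svg_report(report, out)
    final_union <- unique(unlist(lapply(report$domains, `[[`, "final_set")))
    if (length(final_union)) {
      mi <- vapply(final_union, function(g) {
        morans_i(ds$expr[, g], graph)
      }, numeric(1))
      metrics$n_svgs <- length(final_union)
      metrics$median_morans_i <- median(mi)
      log_msg("%d SVGs detected, median Moran's I %.3f",
              length(final_union), median(mi), verbose = verbose)
    } else {
      metrics$n_svgs <- 0L
    }
  }

  jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(cfg, file.path(out, "config_used.yaml"))

  invisible(list(dataset = ds, graph = graph, fit = fit,
                 assignment = assignment, svg_report = report,
                 truth_svgs = inp$truth_svgs, metrics = metrics,
                 config = cfg, output_dir = out))
}
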