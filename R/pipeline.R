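#' Pipeline configuration
#'
#' Bundles a simulation config (or paths to existing inputs), the methods to
#' run, and the benchmark settings. Methods are given as a named list of
#' parameter records; recognized names are "oracle", "cc", "bimax",
#' "xmotif", "kmeans", "hierarchical", and "import" (with a `path` to an
#' exchange-format file).
#'
#' @param simulation A [sim_config()], or a list with `matrix`, `labels`,
#'   `tissue_gmt`, `go_gmt` file paths for pre-existing inputs.
#' @param methods Named list: method name -> parameter list.
#' @param alpha Significance threshold for both gene-based benchmarks.
#' @param n_resamples Resamples for TiGER-Sig and GO-Sig (default 1000).
#' @param min_genes,min_samples,top_n Result-filter settings (defaults 10,
#'   10, 40).
#' @param min_var Variance-filter threshold (default 1).
#' @param seed Integer master seed.
#' @param output_dir Directory for intermediate artifacts and the report.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            methods = list(kmeans = list(k = 5L),
                                           hierarchical = list(k = 5L)),
                            alpha = 0.05, n_resamples = 1000L,
                            min_genes = 10L, min_samples = 10L, top_n = 40L,
                            min_var = 1, seed = 1L,
                            output_dir = tempfile("biclustbench_")) {
  if (length(methods) == 0L) stop("at least one method or import is required")
  structure(list(simulation = simulation, methods = methods, alpha = alpha,
                 n_resamples = as.integer(n_resamples),
                 min_genes = as.integer(min_genes),
                 min_samples = as.integer(min_samples),
                 top_n = as.integer(top_n), min_var = min_var,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Paths in the file are resolved relative to the file's directory. The
#' `simulation` block maps onto [sim_config()] fields.
#'
#' @param path Path to a YAML config.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  sim <- doc$simulation
  if (!is.null(sim$matrix)) {
    sim <- lapply(sim, function(p) file.path(base, p))
  } else {
    if (!is.null(sim$type_sizes)) sim$type_sizes <- unlist(sim$type_sizes)
    sim <- do.call(sim_config, sim)
  }
  methods <- doc$methods
  if (is.null(methods)) methods <- list()
  for (nm in names(methods)) {
    if (identical(nm, "import") && !is.null(methods[[nm]]$path)) {
      methods[[nm]]$path <- file.path(base, methods[[nm]]$path)
    }
    if (is.null(methods[[nm]])) methods[[nm]] <- list()
  }
  args <- doc[setdiff(names(doc), c("simulation", "methods"))]
  if (!is.null(args$output_dir)) {
    args$output_dir <- file.path(base, args$output_dir)
  }
  do.call(pipeline_config,
          c(list(simulation = sim, methods = methods), args))
}

run_one_method <- function(name, params, m, cfg) {
  p <- function(key, default) {
    if (!is.null(params[[key]])) params[[key]] else default
  }
  # the entry name doubles as the algorithm unless overridden, so the same
  # algorithm can appear twice (e.g. sample-axis and gene-axis clustering)
  algorithm <- p("algorithm", name)
  switch(algorithm,
    cc = cc_biclusters(m, delta = p("delta", 50),
                       alpha_rate = p("alpha_rate", 1.5),
                       n_biclusters = p("n_biclusters", 40L),
                       seed = p("seed", cfg$seed)),
    bimax = {
      b <- binarize_matrix(m, z_threshold = p("z_threshold", 1))
      bimax_enumerate(b, min_genes = p("min_genes", 2L),
                      min_samples = p("min_samples", 2L),
                      max_results = p("max_results", 100L))
    },
    xmotif = constant_interval_biclusters(
      m, interval_width = p("interval_width", 0.5),
      n_seeds = p("n_seeds", 100L), min_genes = p("min_genes", 2L),
      min_samples = p("min_samples", 2L), seed = p("seed", cfg$seed)),
    kmeans = one_way_cluster_adapter(
      m, axis = p("axis", "samples"), k = p("k", 5L), method = "kmeans",
      seed = p("seed", cfg$seed)),
    hierarchical = one_way_cluster_adapter(
      m, axis = p("axis", "samples"), k = p("k", 5L),
      method = "hierarchical", seed = p("seed", cfg$seed)),
    import = load_bicluster_set(params$path),
    stop("unknown method: ", name)
  )
}

#' Run the full benchmarking pipeline
#'
#' Stages: simulate (or load) -> drop genes with missing values -> variance
#' filter -> run or import each method -> size/top-n filter -> SampleDif,
#' TiGER-Sig, GO-Sig and the mean pairwise gene-overlap diagnostic. Every
#' intermediate artifact is persisted under `cfg$output_dir`; the whole run
#' is reproducible from (config, seed). Wall-clock seconds per method are
#' recorded as metadata, never benchmarked against.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Emit progress messages.
#' @return A `benchmark_report`: data.frame of per-method rows plus
#'   provenance attributes.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)

  if (inherits(cfg$simulation, "sim_config")) {
    say("simulating dataset (seed ", cfg$simulation$seed, ")")
    sim <- generate_multitissue_dataset(cfg$simulation)
    m <- sim$matrix
    labels <- sim$labels
    ann <- generate_annotation_sets(sim$truth, rownames(m),
                                    seed = cfg$simulation$seed)
    tissue <- ann$tissue
    go <- ann$go
    truth <- sim$truth
    write_expression_matrix(m, file.path(cfg$output_dir, "matrix.tsv"))
    write_sample_labels(labels, file.path(cfg$output_dir, "labels.tsv"))
    write_gmt(tissue, file.path(cfg$output_dir, "tissue.gmt"))
    write_gmt(go, file.path(cfg$output_dir, "go.gmt"))
    save_bicluster_set(oracle_bicluster_set(truth),
                       file.path(cfg$output_dir, "oracle.json"))
  } else {
    say("loading inputs")
    m <- read_expression_matrix(cfg$simulation$matrix)
    labels <- read_sample_labels(cfg$simulation$labels)
    tissue <- read_gmt(cfg$simulation$tissue_gmt)
    go <- read_gmt(cfg$simulation$go_gmt)
    truth <- NULL
  }

  say("preprocessing: ", nrow(m), " genes")
  m <- drop_missing_genes(m, verbose = verbose)
  m <- variance_filter(m, min_var = cfg$min_var, verbose = verbose)
  say("after filters: ", nrow(m), " genes")
  universe <- rownames(m)

  rows <- list()
  for (nm in names(cfg$methods)) {
    say("method: ", nm)
    t0 <- proc.time()[["elapsed"]]
    bs <- tryCatch({
      if (identical(nm, "oracle")) {
        if (is.null(truth)) stop("oracle method requires simulated input")
        oracle_bicluster_set(truth)
      } else {
        run_one_method(nm, cfg$methods[[nm]], m, cfg)
      }
    }, error = function(e) {
      stop("stage 'method:", nm, "' failed (artifacts so far in ",
           cfg$output_dir, "): ", conditionMessage(e), call. = FALSE)
    })
    runtime <- proc.time()[["elapsed"]] - t0
    save_bicluster_set(bs, file.path(cfg$output_dir,
                                     paste0(nm, "_raw.json")))
    bs <- restrict_bicluster_set(bs, rownames(m), colnames(m))
    bs <- filter_bicluster_set(bs, min_genes = cfg$min_genes,
                               min_samples = cfg$min_samples,
                               top_n = cfg$top_n)
    save_bicluster_set(bs, file.path(cfg$output_dir,
                                     paste0(nm, "_filtered.json")))
    k <- n_biclusters(bs)
    sdif <- if (k > 0L) sample_dif(bs, labels) else
      suppressWarnings(sample_dif(bs, labels))
    ts <- tiger_sig(bs, tissue, universe, alpha = cfg$alpha,
                    n_resamples = cfg$n_resamples, seed = cfg$seed)
    gs <- go_sig(bs, go, universe, alpha = cfg$alpha,
                 n_resamples = cfg$n_resamples, seed = cfg$seed)
    overlap <- if (k >= 2L) mean_pairwise_gene_overlap(bs) else NA_real_
    per_bc <- data.frame(
      bicluster = seq_len(k),
      n_genes = vapply(bs$biclusters, function(b) length(b$genes),
                       integer(1L)),
      n_samples = vapply(bs$biclusters, function(b) length(b$samples),
                         integer(1L)),
      tiger_p = if (k) ts$per_bicluster_p else numeric(0L),
      go_adj_p = if (k) gs$per_bicluster_p else numeric(0L))
    utils::write.table(per_bc,
                       file.path(cfg$output_dir,
                                 paste0(nm, "_per_bicluster.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rows[[nm]] <- data.frame(
      method = nm, k = k, sample_dif = sdif,
      go_sig = gs$significant_fraction,
      tiger_sig = ts$significant_fraction,
      mean_gene_overlap = overlap,
      runtime_sec = runtime,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "config") <- cfg
  attr(report, "seed") <- cfg$seed
  attr(report, "version") <- as.character(utils::packageVersion("biclustbench"))
  class(report) <- c("benchmark_report", class(report))
  write_benchmark_report(report, cfg$output_dir)
  report
}

#' Write a benchmark report to disk
#'
#' Emits `report.tsv` (one row per method) and `report.json` mirroring the
#' three-benchmark layout, with runtime kept as metadata.
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory.
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- as.data.frame(report)
  utils::write.table(tab, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  doc <- list(
    seed = attr(report, "seed"),
    version = attr(report, "version"),
    benchmarks = lapply(seq_len(nrow(tab)), function(i) {
      list(method = tab$method[i], k = tab$k[i],
           sample_dif = tab$sample_dif[i],
           go_sig = tab$go_sig[i], tiger_sig = tab$tiger_sig[i],
           mean_gene_overlap = tab$mean_gene_overlap[i],
           runtime_sec = tab$runtime_sec[i])
    }))
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark report (seed ", attr(x, "seed"), "):\n", sep = "")
  tab <- as.data.frame(x)
  tab$sample_dif <- round(tab$sample_dif, 3)
  tab$go_sig <- round(tab$go_sig, 3)
  tab$tiger_sig <- round(tab$tiger_sig, 3)
  tab$mean_gene_overlap <- round(tab$mean_gene_overlap, 3)
  tab$runtime_sec <- round(tab$runtime_sec, 2)
  print(tab)
  invisible(x)
}
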