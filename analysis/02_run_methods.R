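#!/usr/bin/env Rscript
# Stage 2: run the reference (bi)clustering methods on the simulated study
# data.
#
# Reads the stage-1 artifacts, applies the standard preprocessing (drop
# genes with missing values, discard genes with across-sample variance < 1),
# then runs: k-means and hierarchical clustering on both axes (sample
# clusters k = 5 to match the five tissues, gene clusters k = 10), the
# Cheng-Church residue algorithm, Bimax on the z-score-binarized matrix, and
# the constant-interval search. Each raw result is saved in the exchange
# format under results/methods/ together with its wall-clock runtime.

suppressPackageStartupMessages(library(biclustbench))

seed <- 20260921L
data_dir <- "results/data"
out <- "results/methods"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

m <- read_expression_matrix(file.path(data_dir, "matrix.tsv"))
m <- drop_missing_genes(m, verbose = TRUE)
m <- variance_filter(m, min_var = 1, verbose = TRUE)
message("preprocessed matrix: ", nrow(m), " genes x ", ncol(m), " samples")

runs <- list(
  kmeans_samples = function() one_way_cluster_adapter(
    m, axis = "samples", k = 5L, method = "kmeans", seed = seed),
  kmeans_genes = function() one_way_cluster_adapter(
    m, axis = "genes", k = 10L, method = "kmeans", seed = seed),
  hier_samples = function() one_way_cluster_adapter(
    m, axis = "samples", k = 5L, method = "hierarchical"),
  hier_genes = function() one_way_cluster_adapter(
    m, axis = "genes", k = 10L, method = "hierarchical"),
  # delta chosen at the scale of this data (unit background variance); the
  # published 50.0 applies to raw microarray intensity scales
  cc = function() cc_biclusters(m, delta = 1, alpha_rate = 1.5,
                                n_biclusters = 10L, seed = seed),
  bimax = function() bimax_enumerate(binarize_matrix(m, z_threshold = 1.5),
                                     min_genes = 2L, min_samples = 2L,
                                     max_results = 200L),
  xmotif = function() constant_interval_biclusters(
    m, interval_width = 0.75, n_seeds = 100L, min_genes = 2L,
    min_samples = 2L, seed = seed)
)

timings <- data.frame(method = character(0), k = integer(0),
                      runtime_sec = numeric(0))
for (nm in names(runs)) {
  t0 <- proc.time()[["elapsed"]]
  bs <- suppressWarnings(runs[[nm]]())
  dt <- proc.time()[["elapsed"]] - t0
  save_bicluster_set(bs, file.path(out, paste0(nm, ".json")))
  timings <- rbind(timings, data.frame(method = nm, k = n_biclusters(bs),
                                       runtime_sec = round(dt, 2)))
  message(sprintf("%-15s %4d biclusters  %7.2fs", nm, n_biclusters(bs), dt))
}
write.table(timings, file.path(out, "runtimes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("raw results written under ", out)
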