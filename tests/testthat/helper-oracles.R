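# Independent oracles and fixture builders shared across test files.
# These deliberately re-derive every quantity from first principles rather
# than reusing package internals.

# step-by-step simulation of the greedy matching procedure: take the global
# maximum, record it, delete its row and column, repeat
oracle_greedy <- function(d) {
  v <- numeric(0L)
  while (nrow(d) > 0L && ncol(d) > 0L) {
    best <- which(d == max(d), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    v <- c(v, d[best[1L, 1L], best[1L, 2L]])
    d <- d[-best[1L, 1L], -best[1L, 2L], drop = FALSE]
  }
  v
}

# exhaustive hypergeometric tail: probability that a uniform random subset of
# size k intersects the category in at least x elements
oracle_fisher_exhaustive <- function(universe, category, k, x) {
  subsets <- utils::combn(universe, k, simplify = FALSE)
  hits <- vapply(subsets, function(s) length(intersect(s, category)) >= x,
                 logical(1L))
  mean(hits)
}

# brute-force enumeration of inclusion-maximal all-ones submatrices via all
# column subsets (feasible for <= ~12 columns)
oracle_maximal_blocks <- function(b) {
  nc <- ncol(b)
  keys <- character(0L)
  out <- list()
  for (mask in seq_len(2^nc - 1L)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(nc) - 1L)) > 0L)
    rows <- which(rowSums(b[, cols, drop = FALSE] == 1L) == length(cols))
    if (length(rows) == 0L) next
    ccols <- which(colSums(b[rows, , drop = FALSE]) == length(rows))
    key <- paste(paste(rows, collapse = ","), paste(ccols, collapse = ","),
                 sep = "|")
    if (!(key %in% keys)) {
      keys <- c(keys, key)
      out[[length(out) + 1L]] <- list(rows = rows, cols = ccols)
    }
  }
  out
}

block_keys <- function(blocks) {
  sort(vapply(blocks, function(bl) {
    paste(paste(bl$rows, collapse = ","), paste(bl$cols, collapse = ","),
          sep = "|")
  }, character(1L)))
}

bicluster_set_keys <- function(bs, row_ids, col_ids) {
  sort(vapply(bs$biclusters, function(b) {
    paste(paste(sort(match(b$genes, row_ids)), collapse = ","),
          paste(sort(match(b$samples, col_ids)), collapse = ","),
          sep = "|")
  }, character(1L)))
}

# direct mean-squared-residue recomputation (no shared code with the package)
oracle_msr <- function(a) {
  res <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  mean(res^2)
}

random_expression_matrix <- function(n_genes, n_samples, seed = 1L, sd = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

random_bicluster_set <- function(universe, samples, k, gene_size, sample_size,
                                 seed = 1L) {
  set.seed(seed)
  bicluster_set(lapply(seq_len(k), function(i) {
    bicluster(sample(universe, gene_size), sample(samples, sample_size))
  }), method_name = "random")
}

# small labelled design mirroring a five-tissue study at reduced scale
desk_sim_config <- function(...) {
  sim_config(n_genes = 400L,
             type_sizes = c(blood_tcell = 12L, cerebral_cortex = 19L,
                            liver = 5L, striated_muscle = 8L, testis = 4L),
             signature_size = 20L, effect_size = 4, noise_sd = 1,
             correlated_fraction = 0.5, seed = 11L, ...)
}
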