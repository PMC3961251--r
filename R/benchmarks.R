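#' Dice / Sorensen overlap between two id sets
#'
#' `2 |a intersect b| / (|a| + |b|)`, in [0, 1], symmetric, and equal to 1
#' exactly when the two sets are equal. Applied to sample sets for the
#' sample-differentiation benchmark and, in its symmetric gene-set form, to
#' gene sets for the tissue-specific enrichment benchmark.
#'
#' @param a,b Character vectors treated as sets; at least one non-empty.
#' @return Overlap score in [0, 1].
#' @export
dice_overlap <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    stop("dice_overlap undefined for two empty sets")
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Bicluster-by-type overlap matrix
#'
#' Entry (j, i) is the Dice overlap between the sample set of bicluster j and
#' the set of samples carrying type label i.
#'
#' @param bs A `bicluster_set`.
#' @param labels A `sample_labels` covering every sample id in `bs`.
#' @return k x t numeric matrix; rows are bicluster indices, columns type
#'   labels.
#' @export
overlap_matrix <- function(bs, labels) {
  stopifnot(inherits(bs, "bicluster_set"), inherits(labels, "sample_labels"))
  types <- sort(unique(unclass(labels)))
  type_cols <- lapply(types, function(ty) names(labels)[unclass(labels) == ty])
  names(type_cols) <- types
  k <- n_biclusters(bs)
  d <- matrix(0, nrow = k, ncol = length(types),
              dimnames = list(NULL, types))
  if (k == 0L) return(d)
  for (j in seq_len(k)) {
    s <- bs$biclusters[[j]]$samples
    unknown <- setdiff(s, names(labels))
    if (length(unknown) > 0L) {
      stop("bicluster ", j, " contains unlabeled sample id: ", unknown[1L])
    }
    d[j, ] <- vapply(type_cols, function(cols) dice_overlap(s, cols),
                     numeric(1L))
  }
  d
}

#' Greedy matching of biclusters to sample types
#'
#' Repeatedly extracts the global maximum of the overlap matrix, records its
#' value, and deletes the corresponding row and column, until either
#' dimension is exhausted. Ties are broken toward the lowest row index, then
#' the lowest column index. The recorded values form the score vector `v`
#' (length `min(k, t)`, non-increasing).
#'
#' @param d Overlap matrix from [overlap_matrix()].
#' @return List with `v` (matched scores in extraction order) and `pairing`
#'   (data.frame of bicluster index and type label per extraction).
#' @export
greedy_match <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 1L, ncol(d) >= 1L)
  rows <- seq_len(nrow(d))
  cols <- seq_len(ncol(d))
  v <- numeric(0L)
  pr <- integer(0L)
  pc <- integer(0L)
  while (length(rows) > 0L && length(cols) > 0L) {
    sub <- d[rows, cols, drop = FALSE]
    best <- max(sub)
    hits <- which(sub == best, arr.ind = TRUE)
    # lowest original row index first, then lowest column index
    hits <- hits[order(rows[hits[, 1L]], cols[hits[, 2L]]), , drop = FALSE]
    ri <- hits[1L, 1L]
    ci <- hits[1L, 2L]
    v <- c(v, best)
    pr <- c(pr, rows[ri])
    pc <- c(pc, cols[ci])
    rows <- rows[-ri]
    cols <- cols[-ci]
  }
  type_labels <- colnames(d)
  pairing <- data.frame(
    bicluster = pr,
    type = if (is.null(type_labels)) as.character(pc) else type_labels[pc],
    score = v,
    stringsAsFactors = FALSE)
  list(v = v, pairing = pairing)
}

#' Sample-differentiation benchmark (SampleDif)
#'
#' Mean of the greedily matched Dice overlaps between bicluster sample sets
#' and sample-type column sets. 1 means each type is recovered exactly by a
#' distinct bicluster; an empty bicluster set scores 0 with a warning.
#'
#' @param bs A `bicluster_set`.
#' @param labels A `sample_labels`.
#' @return Scalar in [0, 1].
#' @export
sample_dif <- function(bs, labels) {
  if (n_biclusters(bs) == 0L) {
    warning("empty bicluster set: SampleDif is 0 (nothing distinguishes ",
            "nothing)")
    return(0)
  }
  mean(greedy_match(overlap_matrix(bs, labels))$v)
}

#' Resampling p-value for gene-set overlap
#'
#' Observed statistic is the Dice overlap between the bicluster's genes and
#' the special (e.g. tissue-specific) genes. The null redraws gene sets of
#' the same size uniformly without replacement from the universe;
#' `p = (1 + #{resamples with overlap >= observed}) / (n_resamples + 1)`.
#' The add-one correction keeps p in [1/(B+1), 1]; `strict = TRUE` counts
#' only strictly larger overlaps (the literal "higher overlaps" reading)
#' without the correction.
#'
#' @param bicluster_genes Character vector, subset of `universe`.
#' @param special_genes Character vector, subset of `universe`.
#' @param universe Character vector of all candidate gene ids.
#' @param n_resamples Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param strict Use the strict ">" counting without add-one correction.
#' @return Empirical p-value.
#' @export
resampling_overlap_pvalue <- function(bicluster_genes, special_genes,
                                      universe, n_resamples = 1000L,
                                      seed = 1L, strict = FALSE) {
  universe <- unique(universe)
  bicluster_genes <- unique(bicluster_genes)
  special_genes <- unique(special_genes)
  k <- length(bicluster_genes)
  if (k > length(universe)) {
    stop("bicluster has more genes than the universe")
  }
  if (length(setdiff(bicluster_genes, universe)) > 0L ||
      length(setdiff(special_genes, universe)) > 0L) {
    stop("gene ids outside the universe")
  }
  observed <- dice_overlap(bicluster_genes, special_genes)
  set.seed(seed)
  special_flag <- universe %in% special_genes
  n_special <- length(special_genes)
  idx <- matrix(0L, n_resamples, k)
  for (b in seq_len(n_resamples)) {
    idx[b, ] <- sample.int(length(universe), k)
  }
  inter <- rowSums(matrix(special_flag[idx], n_resamples, k))
  null_dice <- 2 * inter / (k + n_special)
  if (strict) {
    sum(null_dice > observed) / n_resamples
  } else {
    (1 + sum(null_dice >= observed)) / (n_resamples + 1)
  }
}

#' Tissue-specific gene-set significance (TiGER-Sig)
#'
#' For each bicluster, an empirical resampling p-value against the union of
#' all selected types' tissue-specific gene sets; the benchmark value is the
#' fraction of biclusters with p below `alpha`. Annotation genes absent from
#' the universe are ignored.
#'
#' @param bs A `bicluster_set`.
#' @param special A `gene_set_collection` of tissue-specific sets (restricted
#'   to the studied types).
#' @param universe All candidate gene ids (the expression matrix's genes).
#' @param alpha Significance threshold (default 0.05).
#' @param n_resamples Resamples per bicluster (default 1000).
#' @param seed Integer seed.
#' @return List: `per_bicluster_p`, `significant_fraction`, `alpha`,
#'   `n_resamples`, `seed`.
#' @export
tiger_sig <- function(bs, special, universe, alpha = 0.05,
                      n_resamples = 1000L, seed = 1L) {
  stopifnot(inherits(bs, "bicluster_set"),
            inherits(special, "gene_set_collection"),
            alpha > 0, alpha < 1, n_resamples >= 1L)
  # annotation genes absent from the universe (e.g. removed by the variance
  # filter) cannot be discovered and are ignored, as in standard enrichment
  # practice
  target <- intersect(unique(unlist(special, use.names = FALSE)), universe)
  if (length(target) == 0L) {
    stop("union of tissue-specific sets is empty within the universe")
  }
  k <- n_biclusters(bs)
  if (k == 0L) {
    return(list(per_bicluster_p = numeric(0L), significant_fraction = 0,
                alpha = alpha, n_resamples = n_resamples, seed = seed))
  }
  p <- vapply(seq_len(k), function(j) {
    resampling_overlap_pvalue(bs$biclusters[[j]]$genes, target, universe,
                              n_resamples = n_resamples, seed = seed + j)
  }, numeric(1L))
  list(per_bicluster_p = p,
       significant_fraction = mean(p < alpha),
       alpha = alpha, n_resamples = n_resamples, seed = seed)
}

#' Fisher's exact over-representation p-value
#'
#' One-sided upper-tail hypergeometric probability of seeing at least the
#' observed intersection between a bicluster's genes and a category when the
#' same number of genes is drawn at random from the universe.
#'
#' @param bicluster_genes,category_genes Character vectors, subsets of
#'   `universe`.
#' @param universe All candidate gene ids (non-empty).
#' @return p-value in (0, 1].
#' @export
fisher_enrichment_pvalue <- function(bicluster_genes, category_genes,
                                     universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  bicluster_genes <- unique(bicluster_genes)
  category_genes <- unique(category_genes)
  x <- length(intersect(bicluster_genes, category_genes))
  stats::phyper(x - 1L, m = length(category_genes),
                n = length(universe) - length(category_genes),
                k = length(bicluster_genes), lower.tail = FALSE)
}

# hypergeometric upper-tail p for a whole matrix of intersection counts
# (rows = draws, cols = categories), vectorized
phyper_matrix <- function(counts, cat_sizes, n_universe, n_draw) {
  p <- stats::phyper(as.vector(counts) - 1L,
                     m = rep(cat_sizes, each = nrow(counts)),
                     n = n_universe - rep(cat_sizes, each = nrow(counts)),
                     k = n_draw, lower.tail = FALSE)
  matrix(p, nrow(counts), ncol(counts))
}

#' Westfall-Young minP adjusted p-values for category enrichment
#'
#' Raw Fisher's exact p-values for every category are adjusted by the minP
#' resampling procedure: for each resample a random gene set of the
#' bicluster's size is drawn from the universe and the minimum Fisher p over
#' all categories recorded; the adjusted p of a category is
#' `(1 + #{resamples with min-p <= raw p}) / (n_resamples + 1)`, with
#' step-down monotonicity enforced in raw-p order. Controls the family-wise
#' error rate across categories. Category members absent from the universe
#' are ignored on both the observed and the null side.
#'
#' @param bicluster_genes Character vector, subset of `universe`.
#' @param categories A `gene_set_collection`.
#' @param universe All candidate gene ids.
#' @param n_resamples Resamples (default 1000).
#' @param seed Integer seed.
#' @return Named numeric vector of adjusted p-values (one per category), plus
#'   attribute `raw` with the raw Fisher p-values.
#' @export
westfall_young_adjust <- function(bicluster_genes, categories, universe,
                                  n_resamples = 1000L, seed = 1L) {
  stopifnot(inherits(categories, "gene_set_collection"))
  universe <- unique(universe)
  bicluster_genes <- unique(bicluster_genes)
  k <- length(bicluster_genes)
  if (k > length(universe)) stop("bicluster larger than universe")
  # categories are restricted to the universe so the raw Fisher p and the
  # resampling null count the same genes
  cats_u <- lapply(categories, intersect, universe)
  cat_sizes <- lengths(cats_u)
  raw <- vapply(cats_u, function(cat) {
    fisher_enrichment_pvalue(bicluster_genes, cat, universe)
  }, numeric(1L))

  set.seed(seed)
  # membership indicator: universe genes x categories
  memb <- vapply(categories, function(cat) universe %in% cat,
                 logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe))
  idx <- replicate(n_resamples, sample.int(length(universe), k))
  # counts[b, c] = |resample_b intersect category_c|
  grp <- rep(seq_len(n_resamples), each = k)
  counts <- rowsum(memb[as.vector(idx), , drop = FALSE] * 1L, grp)
  null_p <- phyper_matrix(counts, cat_sizes, length(universe), k)
  min_p <- apply(null_p, 1L, min)

  ord <- order(raw)
  adj <- numeric(length(raw))
  adj[ord] <- vapply(raw[ord], function(p) {
    (1 + sum(min_p <= p)) / (n_resamples + 1)
  }, numeric(1L))
  adj[ord] <- cummax(adj[ord])  # step-down monotonicity
  names(adj) <- names(categories)
  attr(adj, "raw") <- raw
  adj
}

#' GO-category enrichment significance (GO-Sig)
#'
#' A bicluster is significant when its minimum Westfall-Young-adjusted
#' Fisher p over all categories is below `alpha`; the benchmark value is the
#' fraction of significant biclusters.
#'
#' @param bs A `bicluster_set`.
#' @param categories A `gene_set_collection` playing the GO-category role.
#' @param universe All candidate gene ids.
#' @param alpha Significance threshold (default 0.05).
#' @param n_resamples Resamples per bicluster (default 1000).
#' @param seed Integer seed.
#' @return List: `per_bicluster_p` (minimum adjusted p per bicluster),
#'   `significant_fraction`, `alpha`, `n_resamples`, `seed`.
#' @export
go_sig <- function(bs, categories, universe, alpha = 0.05,
                   n_resamples = 1000L, seed = 1L) {
  stopifnot(inherits(bs, "bicluster_set"), alpha > 0, alpha < 1)
  k <- n_biclusters(bs)
  if (k == 0L) {
    return(list(per_bicluster_p = numeric(0L), significant_fraction = 0,
                alpha = alpha, n_resamples = n_resamples, seed = seed))
  }
  p <- vapply(seq_len(k), function(j) {
    adj <- westfall_young_adjust(bs$biclusters[[j]]$genes, categories,
                                 universe, n_resamples = n_resamples,
                                 seed = seed + j)
    min(adj)
  }, numeric(1L))
  list(per_bicluster_p = p,
       significant_fraction = mean(p < alpha),
       alpha = alpha, n_resamples = n_resamples, seed = seed)
}

#' Mean pairwise gene overlap of a bicluster set
#'
#' Mean Dice overlap between the gene sets of all unordered bicluster pairs.
#' High values flag gene-redundant result sets whose enrichment fractions are
#' driven by the same genes counted repeatedly — a bias diagnostic to report
#' alongside GO-Sig.
#'
#' @param bs A `bicluster_set` with at least 2 biclusters.
#' @return Scalar in [0, 1].
#' @export
mean_pairwise_gene_overlap <- function(bs) {
  stopifnot(inherits(bs, "bicluster_set"))
  k <- n_biclusters(bs)
  if (k < 2L) stop("need at least 2 biclusters for pairwise gene overlap")
  tot <- 0
  n <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      tot <- tot + dice_overlap(bs$biclusters[[i]]$genes,
                                bs$biclusters[[j]]$genes)
      n <- n + 1L
    }
  }
  tot / n
}
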