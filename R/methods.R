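#' Binarize an expression matrix by per-gene z-score
#'
#' Entry is 1 iff the gene-wise z-score (across-sample mean and SD of that
#' gene) exceeds `z_threshold`. Genes with zero SD cannot be standardized and
#' yield an all-zero row with a warning.
#'
#' @param m Expression matrix without missing entries.
#' @param z_threshold z-score cutoff (default 1).
#' @return Integer 0/1 matrix with the same dimnames.
#' @export
binarize_matrix <- function(m, z_threshold = 1) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("binarize_matrix requires a matrix without missing values")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  zero <- sd == 0
  if (any(zero)) {
    warning(sum(zero), " zero-SD gene(s) binarized to all-zero rows")
    sd[zero] <- 1
  }
  z <- (m - mu) / sd
  b <- (z > z_threshold) * 1L
  b[zero, ] <- 0L
  storage.mode(b) <- "integer"
  b
}

#' Enumerate inclusion-maximal all-ones biclusters (Bimax)
#'
#' Finds every submatrix of a binary matrix that consists entirely of ones
#' and is inclusion-maximal (no further row or column can be added), meeting
#' both minimum sizes. Maximal all-ones submatrices are enumerated by a
#' close-by-one recursion over columns with a configurable cap on the number
#' of results to bound worst-case output size.
#'
#' @param b Binary (0/1) matrix with dimnames.
#' @param min_genes Minimum rows per bicluster (default 2).
#' @param min_samples Minimum columns per bicluster (default 2).
#' @param max_results Cap on returned biclusters (default 100).
#' @return A `bicluster_set` named "bimax".
#' @export
bimax_enumerate <- function(b, min_genes = 2L, min_samples = 2L,
                            max_results = 100L) {
  stopifnot(is.matrix(b), all(b %in% c(0L, 1L)))
  nr <- nrow(b)
  nc <- ncol(b)
  storage.mode(b) <- "integer"
  out <- list()
  capped <- FALSE

  col_support <- function(rows, j) rows[b[rows, j] == 1L]
  closure_cols <- function(rows) {
    if (length(rows) == 0L) return(integer(0L))
    which(colSums(b[rows, , drop = FALSE]) == length(rows))
  }

  emit <- function(rows, cols) {
    if (length(rows) >= min_genes && length(cols) >= min_samples) {
      out[[length(out) + 1L]] <<- bicluster(rownames(b)[rows],
                                            colnames(b)[cols])
    }
  }

  # close-by-one over columns: (rows, cols) is always a concept
  recurse <- function(rows, cols, next_col) {
    if (length(out) >= max_results) {
      capped <<- TRUE
      return()
    }
    emit(rows, cols)
    for (j in setdiff(seq(next_col, length.out = max(0L, nc - next_col + 1L)),
                      cols)) {
      rows2 <- col_support(rows, j)
      if (length(rows2) == 0L || length(rows2) < min_genes) next
      cols2 <- closure_cols(rows2)
      # canonical test: no column before j may be newly closed
      if (any(cols2 < j & !(cols2 %in% cols))) next
      recurse(rows2, cols2, j + 1L)
      if (length(out) >= max_results) return()
    }
  }

  # root concept: all rows, columns that are all-ones over all rows
  root_rows <- seq_len(nr)
  root_cols <- closure_cols(root_rows)
  recurse(root_rows, root_cols, 1L)
  if (capped) {
    warning("bimax_enumerate: result cap of ", max_results, " reached")
  }
  bicluster_set(out, method_name = "bimax",
                parameters = list(min_genes = min_genes,
                                  min_samples = min_samples,
                                  max_results = max_results))
}

#' Mean squared residue of a submatrix
#'
#' The Cheng-Church homogeneity score: mean of squared entries after removing
#' row means, column means and the overall mean.
#'
#' @param a Numeric matrix (the submatrix).
#' @export
mean_squared_residue <- function(a) {
  stopifnot(is.matrix(a), !anyNA(a))
  r <- rowMeans(a)
  c <- colMeans(a)
  mu <- mean(a)
  mean((a - outer(r, rep(1, ncol(a))) -
          outer(rep(1, nrow(a)), c) + mu)^2)
}

row_residues <- function(a) {
  res <- a - rowMeans(a) - rep(colMeans(a), each = nrow(a)) + mean(a)
  rowMeans(res^2)
}
col_residues <- function(a) {
  res <- a - rowMeans(a) - rep(colMeans(a), each = nrow(a)) + mean(a)
  colMeans(res^2)
}

cc_find_one <- function(a, delta, alpha_rate) {
  rows <- seq_len(nrow(a))
  cols <- seq_len(ncol(a))
  sub <- function() a[rows, cols, drop = FALSE]

  # multiple node deletion: remove every row/column whose mean residue
  # exceeds alpha_rate * H while H > delta
  repeat {
    h <- mean_squared_residue(sub())
    if (h <= delta || length(rows) <= 2L || length(cols) <= 2L) break
    removed <- FALSE
    rr <- row_residues(sub())
    drop_r <- rr > alpha_rate * h
    if (any(drop_r) && sum(!drop_r) >= 2L) {
      rows <- rows[!drop_r]
      removed <- TRUE
    }
    if (length(cols) > 2L) {
      h <- mean_squared_residue(sub())
      cr <- col_residues(sub())
      drop_c <- cr > alpha_rate * h
      if (any(drop_c) && sum(!drop_c) >= 2L) {
        cols <- cols[!drop_c]
        removed <- TRUE
      }
    }
    if (!removed) break
  }

  # single node deletion: drop the worst row or column one at a time
  repeat {
    h <- mean_squared_residue(sub())
    if (h <= delta || (length(rows) <= 2L && length(cols) <= 2L)) break
    rr <- row_residues(sub())
    cr <- col_residues(sub())
    worst_r <- which.max(rr)
    worst_c <- which.max(cr)
    if ((rr[worst_r] >= cr[worst_c] && length(rows) > 2L) ||
        length(cols) <= 2L) {
      rows <- rows[-worst_r]
    } else {
      cols <- cols[-worst_c]
    }
  }

  # node addition: re-admit rows/columns whose mean residue does not raise H
  repeat {
    added <- FALSE
    h <- mean_squared_residue(sub())
    out_cols <- setdiff(seq_len(ncol(a)), cols)
    if (length(out_cols) > 0L) {
      block <- a[rows, , drop = FALSE]
      res <- block - rowMeans(a[rows, cols, drop = FALSE]) -
        rep(colMeans(block), each = length(rows)) +
        mean(a[rows, cols, drop = FALSE])
      cand_res <- colMeans(res^2)[out_cols]
      add_c <- out_cols[cand_res <= h]
      if (length(add_c) > 0L) {
        cols2 <- sort(c(cols, add_c))
        if (mean_squared_residue(a[rows, cols2, drop = FALSE]) <= delta) {
          cols <- cols2
          added <- TRUE
          h <- mean_squared_residue(sub())
        }
      }
    }
    out_rows <- setdiff(seq_len(nrow(a)), rows)
    if (length(out_rows) > 0L) {
      block <- a[, cols, drop = FALSE]
      res <- block - rowMeans(block) -
        rep(colMeans(a[rows, cols, drop = FALSE]), each = nrow(a)) +
        mean(a[rows, cols, drop = FALSE])
      cand_res <- rowMeans(res^2)[out_rows]
      add_r <- out_rows[cand_res <= h]
      if (length(add_r) > 0L) {
        rows2 <- sort(c(rows, add_r))
        if (mean_squared_residue(a[rows2, cols, drop = FALSE]) <= delta) {
          rows <- rows2
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  list(rows = rows, cols = cols)
}

#' Cheng-Church delta-biclustering
#'
#' Iteratively extracts up to `n_biclusters` submatrices whose mean squared
#' residue (MSR) is at most `delta`, via multiple node deletion at rate
#' `alpha_rate`, single node deletion, then node addition. After each
#' discovery the covered cells are masked with uniform random values over the
#' observed data range so later rounds find different structure.
#'
#' @param m Expression matrix without missing entries, at least 2x2.
#' @param delta MSR ceiling (the published benchmark setting is 50.0 for
#'   microarray-scale data).
#' @param alpha_rate Multiple-deletion aggressiveness, > 1 (typical 1.5).
#' @param n_biclusters Number of biclusters to extract (typical 40).
#' @param seed Integer seed for the masking noise.
#' @return A `bicluster_set` named "cc".
#' @export
cc_biclusters <- function(m, delta = 50, alpha_rate = 1.5,
                          n_biclusters = 40L, seed = 1L) {
  stopifnot(is.matrix(m), delta >= 0, alpha_rate > 1)
  if (anyNA(m)) stop("cc_biclusters requires a matrix without missing values")
  if (nrow(m) < 2L || ncol(m) < 2L) stop("matrix must be at least 2x2")
  set.seed(seed)
  rng <- range(m)
  work <- m
  out <- list()
  for (i in seq_len(n_biclusters)) {
    bc <- cc_find_one(work, delta, alpha_rate)
    if (mean_squared_residue(work[bc$rows, bc$cols, drop = FALSE]) > delta) {
      break  # residue target unreachable on the remaining (masked) data
    }
    # report only submatrices that satisfy the ceiling on the ORIGINAL data;
    # candidates built over masked cells are skipped but still masked so the
    # search moves on
    if (mean_squared_residue(m[bc$rows, bc$cols, drop = FALSE]) <= delta) {
      out[[length(out) + 1L]] <- bicluster(rownames(m)[bc$rows],
                                           colnames(m)[bc$cols])
    }
    work[bc$rows, bc$cols] <-
      matrix(stats::runif(length(bc$rows) * length(bc$cols),
                          rng[1L], rng[2L]),
             length(bc$rows), length(bc$cols))
  }
  bicluster_set(out, method_name = "cc",
                parameters = list(delta = delta, alpha_rate = alpha_rate,
                                  n_biclusters = n_biclusters, seed = seed))
}

#' Constant-interval (xMOTIF-style) biclustering
#'
#' Seeds the search with random small sample sets; for each seed set it
#' collects the genes whose values across those samples span at most
#' `interval_width`, then greedily extends the sample set with any sample
#' that keeps every collected gene inside its window. Every returned
#' bicluster verifiably satisfies the window condition; duplicates are
#' dropped and minimum sizes enforced.
#'
#' @param m Expression matrix without missing entries.
#' @param interval_width Maximum per-gene value range inside a bicluster.
#' @param n_seeds Number of random seed draws.
#' @param min_genes,min_samples Minimum bicluster dimensions.
#' @param seed Integer seed.
#' @return A `bicluster_set` named "xmotif".
#' @export
constant_interval_biclusters <- function(m, interval_width = 0.5,
                                         n_seeds = 100L, min_genes = 2L,
                                         min_samples = 2L, seed = 1L) {
  stopifnot(is.matrix(m), interval_width >= 0)
  if (anyNA(m)) stop("constant_interval_biclusters requires no missing values")
  set.seed(seed)
  nc <- ncol(m)
  seed_size <- min(max(2L, min_samples), nc)
  out <- list()
  seen <- character(0L)
  for (i in seq_len(n_seeds)) {
    s0 <- sort(sample.int(nc, seed_size))
    block <- m[, s0, drop = FALSE]
    lo <- apply(block, 1L, min)
    hi <- apply(block, 1L, max)
    genes <- which(hi - lo <= interval_width)
    if (length(genes) < min_genes) next
    samples <- s0
    glo <- lo[genes]
    ghi <- hi[genes]
    for (s in setdiff(seq_len(nc), s0)) {
      v <- m[genes, s]
      nlo <- pmin(glo, v)
      nhi <- pmax(ghi, v)
      if (all(nhi - nlo <= interval_width)) {
        samples <- c(samples, s)
        glo <- nlo
        ghi <- nhi
      }
    }
    if (length(samples) < min_samples) next
    samples <- sort(samples)
    key <- paste(paste(genes, collapse = ","),
                 paste(samples, collapse = ","), sep = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- bicluster(rownames(m)[genes],
                                         colnames(m)[samples])
  }
  bicluster_set(out, method_name = "xmotif",
                parameters = list(interval_width = interval_width,
                                  n_seeds = n_seeds, min_genes = min_genes,
                                  min_samples = min_samples, seed = seed))
}

#' One-way clustering adapter
#'
#' Partitions one axis into k disjoint clusters and wraps each cluster as a
#' bicluster spanning the full other axis, so conventional clustering can be
#' scored with the biclustering benchmarks. k-means uses Euclidean distance
#' with multiple seeded restarts; hierarchical uses Pearson correlation
#' distance (1 - r) between the clustered items' profile vectors with
#' complete linkage, cut at k.
#'
#' @param m Expression matrix without missing entries.
#' @param axis "samples" or "genes": which axis to cluster.
#' @param k Number of clusters (>= 2).
#' @param method "kmeans" or "hierarchical".
#' @param seed Integer seed (k-means initialization).
#' @param nstart k-means restarts (default 10).
#' @return A `bicluster_set` named after the method and axis.
#' @export
one_way_cluster_adapter <- function(m, axis = c("samples", "genes"), k,
                                    method = c("kmeans", "hierarchical"),
                                    seed = 1L, nstart = 10L) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("clustering requires a matrix without missing values")
  if (k < 2L) stop("k must be at least 2")
  x <- if (axis == "samples") t(m) else m
  if (k > nrow(x)) stop("k exceeds the number of items on the ", axis, " axis")
  if (method == "kmeans") {
    set.seed(seed)
    cl <- stats::kmeans(x, centers = k, nstart = nstart)$cluster
  } else {
    d <- stats::as.dist(1 - stats::cor(t(x)))
    cl <- stats::cutree(stats::hclust(d, method = "complete"), k = k)
  }
  ids <- rownames(x)
  other <- if (axis == "samples") rownames(m) else colnames(m)
  bcs <- lapply(sort(unique(cl)), function(g) {
    members <- ids[cl == g]
    if (axis == "samples") bicluster(other, members)
    else bicluster(members, other)
  })
  bicluster_set(bcs,
                method_name = paste(method, axis, sep = "_"),
                parameters = list(axis = axis, k = k, method = method,
                                  seed = seed))
}

#' Filter and rank a bicluster set
#'
#' Drops biclusters with fewer than `min_genes` genes or `min_samples`
#' samples, sorts survivors by sample count in decreasing order (stable for
#' ties), and keeps the top `top_n`. The published benchmark setting is
#' minima of 10 and top 40.
#'
#' @param bs A `bicluster_set`.
#' @param min_genes,min_samples Minimum dimensions (default 10).
#' @param top_n Maximum number kept (default 40).
#' @export
filter_bicluster_set <- function(bs, min_genes = 10L, min_samples = 10L,
                                 top_n = 40L) {
  stopifnot(inherits(bs, "bicluster_set"))
  keep <- Filter(function(b) {
    length(b$genes) >= min_genes && length(b$samples) >= min_samples
  }, bs$biclusters)
  if (length(keep) > 0L) {
    sizes <- vapply(keep, function(b) length(b$samples), integer(1L))
    ord <- order(-sizes)  # order() is stable: ties keep original rank
    keep <- keep[ord]
  }
  keep <- utils::head(keep, top_n)
  bicluster_set(keep, method_name = bs$method_name,
                parameters = c(bs$parameters,
                               list(filter_min_genes = min_genes,
                                    filter_min_samples = min_samples,
                                    filter_top_n = top_n)))
}
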