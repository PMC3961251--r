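#' Read a gene expression matrix from TSV
#'
#' Expression matrices are stored genes-in-rows with a header row of sample
#' identifiers and the gene identifier in the first column. Values are parsed
#' as numeric; entries equal to `missing_token` are flagged as missing (`NA`)
#' and are never imputed.
#'
#' @param path Path to a tab-separated file.
#' @param missing_token Token marking a missing entry (default `"NA"`).
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames; missing entries are `NA`.
#' @export
read_expression_matrix <- function(path, missing_token = "NA") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         sample_ids[duplicated(sample_ids)][1L])
  }
  ncol_expected <- length(header)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != ncol_expected)) {
    bad <- which(widths != ncol_expected)[1L]
    stop("ragged row at line ", bad + 1L, ": expected ", ncol_expected,
         " fields, found ", widths[bad])
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  cells <- vapply(body, function(f) f[-1L], character(length(sample_ids)))
  cells <- if (is.null(dim(cells))) matrix(cells, nrow = 1L) else t(cells)
  cells[cells == missing_token] <- NA_character_
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad_cell <- which(is.na(values) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad_cell) > 0L) {
    stop("non-numeric value '", cells[bad_cell[1L, , drop = FALSE]],
         "' at gene ", gene_ids[bad_cell[1L, 1L]],
         ", sample ", sample_ids[bad_cell[1L, 2L]])
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Write a gene expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; `NA` entries are written as
#' `missing_token`.
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param missing_token Token for missing entries.
#' @export
write_expression_matrix <- function(m, path, missing_token = "NA") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  body <- format(m, trim = TRUE, digits = 17)
  body[is.na(m)] <- missing_token
  lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample-type labels from a two-column TSV
#'
#' @param path Path to a tab-separated file: sample id, type label.
#' @param header Logical; skip one header line (default `FALSE`).
#' @return Named character vector mapping sample id to type label, with class
#'   `sample_labels`.
#' @export
read_sample_labels <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (header) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("label file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("label line ", which(lengths(fields) < 2L)[1L],
         " has fewer than 2 fields")
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in labels: ", ids[duplicated(ids)][1L])
  }
  labels <- vapply(fields, `[[`, character(1L), 2L)
  sample_labels(stats::setNames(labels, ids))
}

#' Construct a sample-labels object
#'
#' @param x Named character vector: names are sample ids, values type labels.
#' @export
sample_labels <- function(x) {
  stopifnot(is.character(x), !is.null(names(x)))
  if (anyDuplicated(names(x))) stop("duplicate sample id in labels")
  if (length(x) == 0L) stop("labels must contain at least one sample")
  structure(x, class = "sample_labels")
}

#' Number of distinct sample types
#' @param labels A `sample_labels` object.
#' @export
n_types <- function(labels) length(unique(unclass(labels)))

#' Write sample labels as two-column TSV
#' @param labels A `sample_labels` object.
#' @param path Output path.
#' @export
write_sample_labels <- function(labels, path) {
  writeLines(paste(names(labels), unclass(labels), sep = "\t"), path)
  invisible(path)
}

#' @export
print.sample_labels <- function(x, ...) {
  cat("sample labels:", length(x), "samples,", n_types(x), "types\n")
  print(table(unclass(x)))
  invisible(x)
}

#' Read a gene set collection from a GMT file
#'
#' Broad GMT dialect: one set per line, fields are name, description, then
#' member gene ids, all tab-separated. Duplicate members within a line are
#' collapsed.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: named list of character vectors of gene
#'   ids, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name: ", nm[duplicated(nm)][1L])
  }
  desc <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, descriptions = stats::setNames(desc, nm))
}

#' Construct a gene set collection
#' @param sets Named list of character vectors (gene ids).
#' @param descriptions Optional named character vector of descriptions.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicate gene set name")
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set: ", names(sets)[lengths(sets) == 0L][1L])
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' Write a gene set collection as GMT
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(gsc, path) {
  desc <- attr(gsc, "descriptions")
  lines <- vapply(names(gsc), function(nm) {
    paste(c(nm, desc[[nm]], gsc[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene set collection:", length(x), "sets, sizes",
      paste(range(lengths(x)), collapse = "-"), "\n")
  invisible(x)
}

#' Construct a bicluster
#'
#' A bicluster is a pair (gene-id subset, sample-id subset) selecting a
#' submatrix of an expression matrix.
#'
#' @param genes Character vector of gene ids (non-empty).
#' @param samples Character vector of sample ids (non-empty).
#' @export
bicluster <- function(genes, samples) {
  genes <- unique(as.character(genes))
  samples <- unique(as.character(samples))
  if (length(genes) == 0L) stop("bicluster gene set must be non-empty")
  if (length(samples) == 0L) stop("bicluster sample set must be non-empty")
  structure(list(genes = genes, samples = samples), class = "bicluster")
}

#' Construct an ordered set of biclusters
#'
#' Order is meaningful: it is the method's ranking and drives top-n filtering.
#'
#' @param biclusters List of [bicluster()] objects (possibly empty).
#' @param method_name Name of the generating method.
#' @param parameters Named list recording the parameters used.
#' @export
bicluster_set <- function(biclusters = list(), method_name = "unknown",
                          parameters = list()) {
  stopifnot(is.list(biclusters))
  ok <- vapply(biclusters, inherits, logical(1L), "bicluster")
  if (length(ok) && !all(ok)) stop("all elements must be bicluster objects")
  structure(list(method_name = method_name,
                 parameters = parameters,
                 biclusters = biclusters),
            class = "bicluster_set")
}

#' Number of biclusters in a set
#' @param bs A `bicluster_set`.
#' @export
n_biclusters <- function(bs) length(bs$biclusters)

#' @export
print.bicluster_set <- function(x, ...) {
  cat("bicluster set [", x$method_name, "]: ", n_biclusters(x),
      " biclusters\n", sep = "")
  if (n_biclusters(x) > 0L) {
    sz <- vapply(x$biclusters,
                 function(b) c(length(b$genes), length(b$samples)),
                 integer(2L))
    cat("  gene sizes ", paste(range(sz[1L, ]), collapse = "-"),
        ", sample sizes ", paste(range(sz[2L, ]), collapse = "-"), "\n",
        sep = "")
  }
  invisible(x)
}

BICLUSTER_SCHEMA_VERSION <- "1.0"

#' Save a bicluster set to the JSON exchange format
#'
#' Versioned schema: `{schema_version, method_name, parameters,
#' biclusters: [{genes: [...], samples: [...]}]}`; arrays preserve order.
#' This is also the import path for results produced by external tools.
#'
#' @param bs A `bicluster_set`.
#' @param path Output path.
#' @export
save_bicluster_set <- function(bs, path) {
  stopifnot(inherits(bs, "bicluster_set"))
  doc <- list(
    schema_version = BICLUSTER_SCHEMA_VERSION,
    method_name = bs$method_name,
    parameters = bs$parameters,
    biclusters = lapply(bs$biclusters, function(b) {
      list(genes = as.list(b$genes), samples = as.list(b$samples))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a bicluster set from the JSON exchange format
#' @param path Path written by [save_bicluster_set()] or an external tool
#'   following the documented schema.
#' @export
load_bicluster_set <- function(path) {
  if (!file.exists(path)) stop("bicluster file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- doc$schema_version
  if (is.null(ver) || !identical(as.character(ver), BICLUSTER_SCHEMA_VERSION)) {
    stop("unknown bicluster schema version: ",
         if (is.null(ver)) "<missing>" else ver)
  }
  bcs <- lapply(doc$biclusters, function(b) {
    bicluster(unlist(b$genes, use.names = FALSE),
              unlist(b$samples, use.names = FALSE))
  })
  params <- doc$parameters
  if (is.null(params)) params <- list()
  bicluster_set(bcs, method_name = as.character(doc$method_name),
                parameters = params)
}

#' Restrict a bicluster set to the axes of a processed matrix
#'
#' Intersects every bicluster with the given gene and sample universes and
#' drops biclusters that become empty on either axis. Needed when results
#' (imports from external tools, or planted truth) reference genes that were
#' removed by preprocessing.
#'
#' @param bs A `bicluster_set`.
#' @param genes,samples Character vectors of retained ids.
#' @export
restrict_bicluster_set <- function(bs, genes, samples) {
  stopifnot(inherits(bs, "bicluster_set"))
  kept <- list()
  for (b in bs$biclusters) {
    g <- intersect(b$genes, genes)
    s <- intersect(b$samples, samples)
    if (length(g) > 0L && length(s) > 0L) {
      kept[[length(kept) + 1L]] <- bicluster(g, s)
    }
  }
  bicluster_set(kept, method_name = bs$method_name,
                parameters = bs$parameters)
}

#' Drop genes with missing values
#'
#' Genes (rows) containing any missing entry are excluded; nothing is ever
#' imputed.
#'
#' @param m Expression matrix (`NA` marks missing).
#' @param verbose Report how many genes were removed.
#' @return Matrix with no missing entries.
#' @export
drop_missing_genes <- function(m, verbose = FALSE) {
  stopifnot(is.matrix(m))
  keep <- rowSums(is.na(m)) == 0L
  if (!any(keep)) stop("all genes contain missing values; nothing remains")
  if (verbose && any(!keep)) {
    message("drop_missing_genes: removed ", sum(!keep), " of ", nrow(m),
            " genes")
  }
  m[keep, , drop = FALSE]
}

#' Filter genes by across-sample variance
#'
#' Keeps genes whose sample variance (n-1 denominator) is at least `min_var`;
#' genes with variance strictly below the threshold are discarded. Row order
#' is preserved.
#'
#' @param m Expression matrix without missing entries.
#' @param min_var Variance threshold (default 1, the usual cutoff for
#'   normalized expression units).
#' @param verbose Report how many genes were removed.
#' @export
variance_filter <- function(m, min_var = 1, verbose = FALSE) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("variance_filter requires a matrix without missing values")
  v <- apply(m, 1L, stats::var)
  keep <- v >= min_var
  if (!any(keep)) stop("no genes pass the variance filter")
  if (verbose && any(!keep)) {
    message("variance_filter: removed ", sum(!keep), " of ", nrow(m),
            " genes with variance < ", min_var)
  }
  m[keep, , drop = FALSE]
}
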