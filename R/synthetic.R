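#' Simulation configuration for the multi-tissue generator
#'
#' Defaults emulate the structure of a multi-tissue expression compendium:
#' five transcriptionally distinct tissues with sample counts 59 (blood
#' t-cell), 95 (cerebral cortex), 13 (liver), 41 (striated muscle) and
#' 20 (testis), each owning a module of signature genes that is either
#' shifted (low-variance, constant-expression archetype) or driven by a
#' shared latent profile (correlated-expression archetype) over exactly that
#' tissue's samples, on a Gaussian background.
#'
#' @param n_genes Total number of genes.
#' @param type_sizes Named integer vector: samples per tissue type.
#' @param signature_size Signature genes per type.
#' @param effect_size Shift magnitude / latent amplitude, expression units.
#' @param n_extra_biclusters Additional planted biclusters not tied to one
#'   type.
#' @param overlap_fraction Fraction of a previous bicluster's genes and
#'   samples reused by each extra bicluster (0 = disjoint regime).
#' @param noise_sd Background and additive noise standard deviation.
#' @param missing_rate Fraction of entries flagged missing after planting.
#' @param correlated_fraction Probability that a planted module uses the
#'   correlated archetype rather than the constant shift.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       type_sizes = c(blood_tcell = 59L, cerebral_cortex = 95L,
                                      liver = 13L, striated_muscle = 41L,
                                      testis = 20L),
                       signature_size = 40L,
                       effect_size = 3,
                       n_extra_biclusters = 0L,
                       overlap_fraction = 0,
                       noise_sd = 1,
                       missing_rate = 0,
                       correlated_fraction = 0.5,
                       seed = 1L) {
  stopifnot(n_genes >= 1L, all(type_sizes >= 1L), !is.null(names(type_sizes)),
            signature_size >= 1L, effect_size > 0,
            overlap_fraction >= 0, overlap_fraction < 1,
            noise_sd > 0, missing_rate >= 0, missing_rate < 1,
            correlated_fraction >= 0, correlated_fraction <= 1)
  t <- length(type_sizes)
  if (signature_size * t > n_genes) {
    stop("infeasible config: ", t, " signatures of ", signature_size,
         " genes exceed the pool of ", n_genes, " genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 type_sizes = type_sizes,
                 signature_size = as.integer(signature_size),
                 effect_size = effect_size,
                 n_extra_biclusters = as.integer(n_extra_biclusters),
                 overlap_fraction = overlap_fraction,
                 noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 correlated_fraction = correlated_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

plant_pattern <- function(values, genes, samples, kind, effect_size,
                          noise_sd) {
  if (kind == "constant_shift") {
    values[genes, samples] <- values[genes, samples] + effect_size
  } else {
    # shared latent profile across samples; gene-specific positive loading
    # and offset, plus fresh noise on top of the replaced cells
    p <- stats::rnorm(length(samples))
    a <- stats::runif(length(genes), 0.5, 2) * effect_size / 1.25
    b <- stats::rnorm(length(genes))
    values[genes, samples] <-
      outer(a, p) + b +
      matrix(stats::rnorm(length(genes) * length(samples), sd = noise_sd),
             length(genes), length(samples))
  }
  values
}

#' Generate a multi-tissue expression dataset with planted ground truth
#'
#' Background entries are Normal(0, noise_sd^2). Each tissue type's signature
#' genes receive their pattern over exactly that type's samples: the constant
#' shift adds `effect_size`; the correlated archetype replaces cells with
#' `a_g * p_s + b_g + noise`, `p_s` a per-sample latent profile drawn once per
#' module and `a_g > 0`. Extra biclusters are planted afterwards, reusing a
#' fraction of an earlier bicluster's genes and samples when
#' `overlap_fraction > 0`. Missing entries are injected last, after the
#' ground truth is fixed. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `matrix` (genes x samples, `NA` = missing),
#'   `labels` (a `sample_labels`), and `truth` (planted biclusters, type
#'   signatures, pattern kinds, noise sd, seed).
#' @export
generate_multitissue_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  types <- names(cfg$type_sizes)
  n_samples <- sum(cfg$type_sizes)
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  sample_ids <- sprintf("s%04d", seq_len(n_samples))
  labels <- sample_labels(stats::setNames(
    rep(types, times = cfg$type_sizes), sample_ids))

  values <- matrix(stats::rnorm(cfg$n_genes * n_samples, sd = cfg$noise_sd),
                   cfg$n_genes, n_samples,
                   dimnames = list(gene_ids, sample_ids))

  # disjoint signature gene blocks, one per type
  sig_idx <- split(seq_len(cfg$signature_size * length(types)),
                   rep(seq_along(types), each = cfg$signature_size))
  type_signatures <- list()
  planted <- list()
  for (i in seq_along(types)) {
    genes <- gene_ids[sig_idx[[i]]]
    samples <- names(labels)[unclass(labels) == types[i]]
    kind <- if (stats::runif(1L) < cfg$correlated_fraction) {
      "correlated"
    } else {
      "constant_shift"
    }
    values <- plant_pattern(values, genes, samples, kind, cfg$effect_size,
                            cfg$noise_sd)
    type_signatures[[types[i]]] <- genes
    planted[[length(planted) + 1L]] <- list(
      genes = genes, samples = samples, pattern_kind = kind,
      effect_size = cfg$effect_size, type = types[i])
  }

  free_genes <- setdiff(gene_ids, unlist(type_signatures))
  if (cfg$n_extra_biclusters > 0L) {
    extra_sample_size <- max(10L, round(0.1 * n_samples))
    for (e in seq_len(cfg$n_extra_biclusters)) {
      n_reuse_g <- round(cfg$overlap_fraction * cfg$signature_size)
      n_reuse_s <- round(cfg$overlap_fraction * extra_sample_size)
      prev <- planted[[sample.int(length(planted), 1L)]]
      genes <- c(sample(prev$genes, min(n_reuse_g, length(prev$genes))),
                 sample(free_genes,
                        min(cfg$signature_size - n_reuse_g,
                            length(free_genes))))
      if (length(genes) == 0L) stop("gene pool exhausted for extra biclusters")
      samples <- unique(c(
        sample(prev$samples, min(n_reuse_s, length(prev$samples))),
        sample(sample_ids, extra_sample_size - n_reuse_s)))
      kind <- if (stats::runif(1L) < cfg$correlated_fraction) {
        "correlated"
      } else {
        "constant_shift"
      }
      values <- plant_pattern(values, genes, samples, kind, cfg$effect_size,
                              cfg$noise_sd)
      planted[[length(planted) + 1L]] <- list(
        genes = genes, samples = samples, pattern_kind = kind,
        effect_size = cfg$effect_size, type = NA_character_)
      free_genes <- setdiff(free_genes, genes)
    }
  }

  if (cfg$missing_rate > 0) {
    n_miss <- round(cfg$missing_rate * length(values))
    miss <- sample.int(length(values), n_miss)
    values[miss] <- NA_real_
  }

  truth <- structure(list(planted = planted,
                          type_signatures = type_signatures,
                          noise_sd = cfg$noise_sd,
                          seed = cfg$seed),
                     class = "ground_truth")
  list(matrix = values, labels = labels, truth = truth)
}

#' Build annotation gene-set collections from planted ground truth
#'
#' Emits (a) one tissue-specific set per type, equal to its signature genes,
#' optionally corrupted by removing a fraction of true members (dropout) and
#' adding spurious genes, mimicking database incompleteness; and (b) a
#' GO-like collection in which each planted gene module is a category, padded
#' with random background categories drawn from the gene universe.
#'
#' @param truth Ground truth from [generate_multitissue_dataset()].
#' @param universe Character vector of all gene ids in the matrix.
#' @param dropout_rate Fraction of true members removed from each
#'   tissue-specific set.
#' @param spurious_rate Spurious members added, as a fraction of set size.
#' @param n_background Number of random GO-like background categories.
#' @param background_size Genes per background category.
#' @param seed Integer seed.
#' @return List with `tissue` and `go` gene set collections.
#' @export
generate_annotation_sets <- function(truth, universe, dropout_rate = 0,
                                     spurious_rate = 0, n_background = 20L,
                                     background_size = 40L, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(seed)
  corrupt <- function(genes) {
    keep_n <- ceiling((1 - dropout_rate) * length(genes))
    kept <- if (keep_n < length(genes)) sample(genes, keep_n) else genes
    n_spur <- round(spurious_rate * length(genes))
    if (n_spur > 0L) {
      pool <- setdiff(universe, genes)
      kept <- c(kept, sample(pool, min(n_spur, length(pool))))
    }
    kept
  }
  tissue <- lapply(truth$type_signatures, corrupt)
  tissue_gsc <- gene_set_collection(
    tissue,
    descriptions = stats::setNames(
      paste0("tissue-specific genes: ", names(tissue)), names(tissue)))

  go <- lapply(truth$planted, `[[`, "genes")
  names(go) <- sprintf("module_%02d", seq_along(go))
  bg <- lapply(seq_len(n_background), function(i) {
    sample(universe, min(background_size, length(universe)))
  })
  names(bg) <- sprintf("background_%02d", seq_len(n_background))
  go_gsc <- gene_set_collection(c(go, bg))
  list(tissue = tissue_gsc, go = go_gsc)
}

#' Oracle bicluster set from planted ground truth
#'
#' Returns the perfect-recovery answer: one bicluster per planted module
#' (each type's signature genes paired with that type's samples, plus any
#' extra planted biclusters). Used as a calibration control: its SampleDif is
#' 1 by construction on disjoint plantings.
#'
#' @param truth Ground truth from [generate_multitissue_dataset()].
#' @return A `bicluster_set` named "oracle".
#' @export
oracle_bicluster_set <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  bcs <- lapply(truth$planted, function(p) bicluster(p$genes, p$samples))
  bicluster_set(bcs, method_name = "oracle",
                parameters = list(seed = truth$seed))
}
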