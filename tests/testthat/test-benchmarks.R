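test_that("Dice overlap matches direct arithmetic and its set properties", {
  s <- paste0("x", 1:7)
  expect_equal(dice_overlap(s, s), 1.0)
  expect_equal(dice_overlap(paste0("a", 1:3), paste0("b", 1:4)), 0.0)
  # a 13-sample type fully inside a 20-sample bicluster
  expect_equal(dice_overlap(paste0("s", 1:13), paste0("s", 1:20)), 26 / 33,
               tolerance = 1e-15)
  expect_error(dice_overlap(character(0L), character(0L)), "empty")

  set.seed(10L)
  universe <- sprintf("u%03d", 1:60)
  for (i in 1:200) {
    a <- sample(universe, sample(1:30, 1L))
    b <- sample(universe, sample(1:30, 1L))
    d <- dice_overlap(a, b)
    expect_identical(d, dice_overlap(b, a))
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_identical(d == 1, setequal(a, b))
  }
})

test_that("the overlap matrix scores bicluster samples against each type", {
  lab <- sample_labels(setNames(rep(c("A", "B"), each = 8L),
                                sprintf("s%02d", 1:16)))
  # single bicluster holding all samples of both equal-sized types
  bs <- bicluster_set(list(bicluster("g1", sprintf("s%02d", 1:16))))
  d <- overlap_matrix(bs, lab)
  expect_equal(dim(d), c(1L, 2L))
  expect_equal(unname(d[1L, ]), c(2 * 8 / 24, 2 * 8 / 24))

  # exact per-type biclusters give an identity-like matrix
  bs2 <- bicluster_set(list(bicluster("g1", sprintf("s%02d", 1:8)),
                            bicluster("g2", sprintf("s%02d", 9:16))))
  d2 <- overlap_matrix(bs2, lab)
  expect_equal(unname(diag(d2)), c(1, 1))
  expect_equal(dim(overlap_matrix(bicluster_set(), lab)), c(0L, 2L))

  bad <- bicluster_set(list(bicluster("g1", "nope")))
  expect_error(overlap_matrix(bad, lab), "nope")
})

test_that("greedy matching follows the extract-delete trace", {
  expect_equal(greedy_match(diag(2))$v, c(1, 1))
  d <- matrix(c(0.9, 0.8, 0.2, 0.7), 2L, 2L)
  expect_equal(greedy_match(d)$v, c(0.9, 0.7))

  # v is the greedy trace, not the optimal assignment
  d2 <- matrix(c(0.9, 0.85, 0.8, 0.1), 2L, 2L)
  expect_equal(greedy_match(d2)$v, c(0.9, 0.1))

  for (trial in 1:100) {
    set.seed(trial + 500L)
    d <- matrix(runif(24L), 6L, 4L)
    v <- greedy_match(d)$v
    expect_identical(v, oracle_greedy(d))
    expect_length(v, 4L)
    expect_true(all(diff(v) <= 0))
  }
})

test_that("SampleDif averages the matched scores", {
  n <- 6L
  lab <- sample_labels(setNames(rep(paste0("t", 1:5), each = n),
                                sprintf("s%02d", seq_len(5L * n))))
  all_in_one <- bicluster_set(list(bicluster("g1", names(lab))))
  expect_equal(sample_dif(all_in_one, lab), 2 * n / (5 * n + n))
  expect_warning(z <- sample_dif(bicluster_set(), lab), "empty")
  expect_equal(z, 0)

  # random sample sets score far below a perfect match
  set.seed(77L)
  rand <- bicluster_set(lapply(1:5, function(i) {
    bicluster("g1", sample(names(lab), n))
  }))
  expect_lt(sample_dif(rand, lab), 0.75)
})

test_that("resampling overlap p-values converge to exhaustive enumeration", {
  universe <- paste0("g", 1:4)
  bc <- c("g1", "g2")
  # all C(4,2) = 6 equally likely draws; only {g1,g2} ties the observed
  # overlap of 1, so P(null >= obs) = 1/6
  p <- mean(vapply(1:6, function(s) {
    resampling_overlap_pvalue(bc, bc, universe, n_resamples = 2000L,
                              seed = s)
  }, numeric(1L)))
  expect_lt(abs(p - 1 / 6), 0.015)

  # degenerate: special set = universe means every draw ties the observed
  expect_equal(resampling_overlap_pvalue(bc, universe, universe,
                                         n_resamples = 200L, seed = 1L), 1)

  expect_error(resampling_overlap_pvalue(paste0("g", 1:9), bc, universe),
               "more genes than the universe")

  # bounds and determinism
  set.seed(3L)
  u <- sprintf("u%03d", 1:200)
  p1 <- resampling_overlap_pvalue(sample(u, 20L), sample(u, 30L), u,
                                  n_resamples = 500L, seed = 9L)
  p2 <- resampling_overlap_pvalue(sample(u, 20L), sample(u, 30L), u,
                                  n_resamples = 500L, seed = 9L)
  expect_gte(p1, 1 / 501)
  expect_lte(p1, 1)
})

test_that("p-values are monotone in the observed overlap at a shared seed", {
  u <- sprintf("u%03d", 1:100)
  special <- u[1:30]
  # nested bicluster gene sets with increasing overlap
  ps <- vapply(c(2L, 6L, 12L, 20L), function(n_in) {
    genes <- c(u[seq_len(n_in)], u[51:60])
    resampling_overlap_pvalue(genes, special, u, n_resamples = 400L,
                              seed = 5L)
  }, numeric(1L))
  expect_true(all(diff(ps) <= 0))
})

test_that("TiGER-Sig calibrates to 1 on planted truth and ~alpha on null", {
  cfg <- desk_sim_config()
  sim <- generate_multitissue_dataset(cfg)
  universe <- rownames(sim$matrix)
  ann <- generate_annotation_sets(sim$truth, universe, seed = 1L)
  bs <- oracle_bicluster_set(sim$truth)
  res <- tiger_sig(bs, ann$tissue, universe, alpha = 0.05,
                   n_resamples = 500L, seed = 3L)
  expect_equal(res$significant_fraction, 1.0)
  expect_true(all(res$per_bicluster_p <= 1 / 100))

  empty <- tiger_sig(bicluster_set(), ann$tissue, universe)
  expect_equal(empty$significant_fraction, 0)

  # annotation genes missing from the universe (e.g. variance-filtered) are
  # ignored rather than breaking the null draw
  special_plus <- gene_set_collection(list(
    t1 = c(ann$tissue[[1L]], "not_in_matrix_1", "not_in_matrix_2")))
  res_plus <- tiger_sig(bs, special_plus, universe, alpha = 0.05,
                        n_resamples = 200L, seed = 3L)
  special_only <- gene_set_collection(list(t1 = ann$tissue[[1L]]))
  res_only <- tiger_sig(bs, special_only, universe, alpha = 0.05,
                        n_resamples = 200L, seed = 3L)
  expect_identical(res_plus$per_bicluster_p, res_only$per_bicluster_p)

  # null biclusters reject at about alpha
  null_bs <- random_bicluster_set(universe, names(sim$labels), k = 150L,
                                  gene_size = 20L, sample_size = 10L,
                                  seed = 21L)
  null_res <- tiger_sig(null_bs, ann$tissue, universe, alpha = 0.05,
                        n_resamples = 400L, seed = 13L)
  ci <- qbinom(c(0.005, 0.995), 150L, 0.05) / 150L
  expect_gte(null_res$significant_fraction, ci[1L])
  expect_lte(null_res$significant_fraction, ci[2L])
})

test_that("Fisher enrichment equals the hypergeometric tail exactly", {
  u10 <- paste0("g", 1:10)
  # drawing 5 of 10 and hitting all 5 category members: 1 / C(10,5)
  expect_equal(fisher_enrichment_pvalue(u10[1:5], u10[1:5], u10), 1 / 252,
               tolerance = 1e-12)
  # empty intersection with positive expectation: tail from zero is 1
  expect_equal(fisher_enrichment_pvalue(u10[1:3], u10[4:8], u10), 1)
  expect_error(fisher_enrichment_pvalue("g1", "g1", character(0L)),
               "empty universe")

  # exhaustive-subset oracle on small universes
  set.seed(8L)
  for (trial in 1:12) {
    n_u <- sample(6:12, 1L)
    u <- paste0("g", seq_len(n_u))
    cat_genes <- sample(u, sample(2:(n_u - 1L), 1L))
    k <- sample(2:(n_u - 1L), 1L)
    draw <- sample(u, k)
    x <- length(intersect(draw, cat_genes))
    expect_equal(fisher_enrichment_pvalue(draw, cat_genes, u),
                 oracle_fisher_exhaustive(u, cat_genes, k, x),
                 tolerance = 1e-12)
  }
})

test_that("Westfall-Young adjustment is monotone and tracks a single
           category's resampling estimate", {
  u <- sprintf("u%03d", 1:120)
  cats <- gene_set_collection(list(only = u[1:25]))
  genes <- c(u[1:10], u[100:104])
  adj <- westfall_young_adjust(genes, cats, u, n_resamples = 1500L, seed = 4L)
  raw <- attr(adj, "raw")
  # with one category, minP resampling estimates the raw p itself
  expect_equal(unname(adj["only"]), unname(raw["only"]), tolerance = 0.05)

  set.seed(15L)
  many <- gene_set_collection(setNames(
    lapply(1:8, function(i) sample(u, 20L)), paste0("c", 1:8)))
  adj_m <- westfall_young_adjust(sample(u, 15L), many, u,
                                 n_resamples = 300L, seed = 6L)
  raw_m <- attr(adj_m, "raw")
  expect_true(all(diff(adj_m[order(raw_m)]) >= 0))
  expect_true(all(adj_m >= raw_m - 1e-12))
  expect_true(all(adj_m >= 1 / 301 & adj_m <= 1))
})

test_that("GO-Sig is 1 on category-identical biclusters and ~0 on noise", {
  cfg <- desk_sim_config()
  sim <- generate_multitissue_dataset(cfg)
  universe <- rownames(sim$matrix)
  ann <- generate_annotation_sets(sim$truth, universe, seed = 1L)
  bs <- oracle_bicluster_set(sim$truth)
  res <- go_sig(bs, ann$go, universe, alpha = 0.05, n_resamples = 400L,
                seed = 5L)
  expect_equal(res$significant_fraction, 1.0)

  expect_equal(go_sig(bicluster_set(), ann$go, universe)$significant_fraction,
               0)

  # random biclusters against random categories: family-wise error near or
  # below alpha
  set.seed(19L)
  null_cats <- gene_set_collection(setNames(
    lapply(1:15, function(i) sample(universe, 25L)), paste0("n", 1:15)))
  null_bs <- random_bicluster_set(universe, names(sim$labels), k = 60L,
                                  gene_size = 20L, sample_size = 10L,
                                  seed = 23L)
  null_res <- go_sig(null_bs, null_cats, universe, alpha = 0.05,
                     n_resamples = 300L, seed = 7L)
  ci_hi <- qbinom(0.995, 60L, 0.05) / 60L
  expect_lte(null_res$significant_fraction, ci_hi)
})

test_that("mean pairwise gene overlap matches direct arithmetic", {
  g <- sprintf("g%02d", 1:30)
  shared <- bicluster_set(list(bicluster(g[1:10], "s1"),
                               bicluster(g[1:10], "s2"),
                               bicluster(g[1:10], "s3")))
  expect_equal(mean_pairwise_gene_overlap(shared), 1.0)

  disjoint <- bicluster_set(list(bicluster(g[1:10], "s1"),
                                 bicluster(g[11:20], "s2"),
                                 bicluster(g[21:30], "s3")))
  expect_equal(mean_pairwise_gene_overlap(disjoint), 0.0)

  half <- bicluster_set(list(bicluster(g[1:10], "s1"),
                             bicluster(g[6:15], "s2")))
  expect_equal(mean_pairwise_gene_overlap(half), 0.5)

  expect_error(mean_pairwise_gene_overlap(bicluster_set(list(
    bicluster("g1", "s1")))), "at least 2")
})
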