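test_that("array-mean normalization scales each replicate to mean 1", {
  t <- tibble::tibble(probe_id = c("p1", "p2", "p3"), gene_id = "g1",
                      chromosome = "chr1", replicate = 1,
                      intensity = c(1, 2, 3))
  n <- normalize_to_array_mean(t)
  expect_equal(n$intensity, c(0.5, 1, 1.5))
  expect_equal(normalize_to_array_mean(n)$intensity, n$intensity)  # idempotent

  two <- dplyr::bind_rows(t, dplyr::mutate(t, replicate = 2,
                                           intensity = intensity * 50))
  n2 <- normalize_to_array_mean(two)
  means <- tapply(n2$intensity, n2$replicate, mean)
  expect_equal(as.numeric(means), c(1, 1))
})

test_that("probe aggregation averages replicates then probes", {
  t <- tiny_expression()  # g1: probes (2, 4) in both replicates; g2: 1
  g <- aggregate_probes(t, allow_unnormalized = TRUE)
  expect_equal(g$activity[g$gene_id == "g1"], 3)
  expect_equal(g$activity[g$gene_id == "g2"], 1)

  one_probe <- tibble::tibble(
    probe_id = "p1", gene_id = "g", chromosome = "chr1",
    replicate = c(1, 2), intensity = c(1, 3))
  expect_equal(aggregate_probes(one_probe,
                                allow_unnormalized = TRUE)$activity, 2)

  expect_error(aggregate_probes(tiny_expression()), "normalized")
  expect_message(aggregate_probes(tiny_expression(),
                                  allow_unnormalized = TRUE),
                 "explicitly allowed")
})

test_that("probe aggregation equals the group-by oracle on random tables", {
  cfg <- sim_config(n_chromosomes = 5, genes_per_chromosome = 20,
                    noise_sd = 0.4, seed = 17)
  e <- simulate_expression(cfg)
  t <- normalize_to_array_mean(e$table)
  g <- aggregate_probes(t)
  oracle <- oracle_gene_activity(t)
  expect_equal(setNames(g$activity, g$gene_id)[names(oracle)],
               oracle, tolerance = 1e-12)
})

test_that("chromosome activity divides by the annotated gene count", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chromosome = "chr1",
                          activity = c(2, 4))
  ann <- tibble::tibble(chromosome = "chr1", gene_count = 4)
  a <- chromosome_activity(genes, ann)
  expect_equal(a$activity, 1.5)
  expect_equal(a$log_activity, log(1.5))

  # dropping an unobserved annotated gene changes nothing; adding an
  # observed gene with activity eps changes A by eps / N
  eps <- 1e-3
  genes2 <- dplyr::bind_rows(genes, tibble::tibble(
    gene_id = "c", chromosome = "chr1", activity = eps))
  a2 <- chromosome_activity(genes2, ann)
  expect_equal(a2$activity - a$activity, eps / 4, tolerance = 1e-9)

  # chromosome with zero observed genes is flagged and excluded downstream
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(chromosome = "chr2",
                                               gene_count = 10))
  a3 <- suppressMessages(chromosome_activity(genes, ann2))
  expect_true(a3$excluded[a3$chromosome == "chr2"])
  iad <- compute_iad(a3)
  expect_identical(dm_labels(iad), "chr1")
})

test_that("IAD is an exact 1-D embedding metric, invariant to rescaling", {
  act <- tibble::tibble(chromosome = c("chrA", "chrB"),
                        log_activity = c(1, 2))
  expect_equal(as.matrix(compute_iad(act))["chrA", "chrB"], 1)

  same <- tibble::tibble(chromosome = paste0("chr", 1:5), log_activity = 3)
  expect_true(all(as.matrix(compute_iad(same)) == 0))

  set.seed(12)
  la <- rnorm(8)
  act8 <- tibble::tibble(chromosome = paste0("chr", 1:8), log_activity = la)
  M <- as.matrix(compute_iad(act8))
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(M[i, k], M[i, j] + M[j, k] + 1e-12)
  }

  # global intensity rescaling cancels in log differences, exactly
  genes <- tibble::tibble(gene_id = paste0("g", 1:12),
                          chromosome = rep(paste0("chr", 1:4), each = 3),
                          activity = exp(rnorm(12)))
  ann <- tibble::tibble(chromosome = paste0("chr", 1:4), gene_count = 3)
  m1 <- as.matrix(compute_iad(chromosome_activity(genes, ann)))
  genes$activity <- genes$activity * 37.5
  m2 <- as.matrix(compute_iad(chromosome_activity(genes, ann)))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("high-expresser selection applies the per-chromosome threshold", {
  flat <- tibble::tibble(gene_id = paste0("g", 1:4), chromosome = "chr1",
                         activity = 1)
  expect_equal(nrow(select_high_expressers(flat)), 4)

  two <- tibble::tibble(gene_id = c("hi", "lo"), chromosome = "chr1",
                        activity = c(10, 1))
  kept <- select_high_expressers(two)  # mean 5.5, cutoff 2.2
  expect_identical(kept$gene_id, "hi")

  cfg <- sim_config(n_chromosomes = 4, seed = 31)
  e <- simulate_expression(cfg)
  g <- aggregate_probes(normalize_to_array_mean(e$table))
  sel <- select_high_expressers(g, 0.4)
  brute <- do.call(rbind, lapply(split(g, g$chromosome), function(d) {
    d[d$activity > 0.4 * mean(d$activity), ]
  }))
  expect_setequal(sel$gene_id, brute$gene_id)
})

test_that("FWHM of a triangular difference histogram is analytic", {
  # difference of two U(0,1) variables is triangular on (-1, 1) peaked at
  # 0; the density falls to half its modal height at +/- 1/2, so the FWHM
  # is 1.  A handful of outliers beyond one FWHM must be the selection.
  set.seed(7)
  d <- c(runif(40000) - runif(40000), rep(c(-3, 3), each = 50))
  a <- tibble::tibble(gene_id = paste0("g", seq_along(d)),
                      chromosome = "chr1", activity = d)
  b <- dplyr::mutate(a, activity = 0)
  sel <- differential_selection(a, b, bins = 120)
  binw <- diff(sel$breaks[1:2])
  expect_lt(abs(sel$fwhm - 1), 2 * binw)
  expect_lt(abs(sel$mode), binw)
  # selected genes are exactly those beyond one FWHM of the mode
  expect_setequal(
    sel$genes$gene_id[sel$genes$selected],
    a$gene_id[abs(d - sel$mode) > sel$fwhm])
  expect_true(all(paste0("g", 40001:40100) %in%
                    sel$genes$gene_id[sel$genes$selected]))

  # identical tables have an empty selection
  expect_error(differential_selection(a, a), "empty")
})

test_that("differential selection recovers shifted genes", {
  hits <- false <- numeric(10)
  for (k in 1:10) {
    cfg <- sim_config(n_chromosomes = 6, genes_per_chromosome = 80,
                      seed = 400 + k)
    pair <- simulate_expression_pair(cfg, shift_fraction = 0.2,
                                     log_shift = 2)
    ga <- aggregate_probes(normalize_to_array_mean(pair$cell_a))
    gb <- aggregate_probes(normalize_to_array_mean(pair$cell_b))
    sel <- differential_selection(ga, gb, log_scale = TRUE)
    picked <- sel$genes$gene_id[sel$genes$selected]
    hits[k] <- mean(pair$shifted_genes %in% picked)
    unshifted <- setdiff(sel$genes$gene_id, pair$shifted_genes)
    false[k] <- mean(unshifted %in% picked)
  }
  # recovery assessed over the seed ensemble
  expect_gte(mean(hits), 0.95)
  expect_lte(mean(false), 0.05)
})

test_that("paired IADs share the selection and localise differences", {
  cfg <- sim_config(n_chromosomes = 6, genes_per_chromosome = 60,
                    seed = 77)
  pair <- simulate_expression_pair(cfg, shift_fraction = 0.2, log_shift = 2)
  ga <- aggregate_probes(normalize_to_array_mean(pair$cell_a))
  gb <- aggregate_probes(normalize_to_array_mean(pair$cell_b))
  sel <- differential_selection(ga, gb, log_scale = TRUE)
  out <- build_pairwise_iads(sel, pair$annotation)
  expect_identical(dm_labels(out$iad_ab), dm_labels(out$iad_ba))

  # the per-chromosome selected counts are the same for both matrices by
  # construction, and the difference matrix matches a direct recomputation
  sel_genes <- sel$genes[sel$genes$selected, ]
  ann <- pair$annotation
  mk <- function(col) {
    as.matrix(compute_iad(chromosome_activity(
      dplyr::select(sel_genes, gene_id, chromosome,
                    activity = dplyr::all_of(col)), ann)))
  }
  expect_equal(as.matrix(out$iad_ab) - as.matrix(out$iad_ba),
               mk("activity_a") - mk("activity_b"), tolerance = 1e-12)

  # identical cell types with the full gene set give identical matrices
  sel_all <- sel
  sel_all$genes$selected <- TRUE
  sel_all$genes$activity_b <- sel_all$genes$activity_a
  same <- build_pairwise_iads(sel_all, ann)
  expect_equal(as.matrix(same$iad_ab), as.matrix(same$iad_ba))
})
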