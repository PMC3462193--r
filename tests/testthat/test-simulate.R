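test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_chromosomes = 1), "at least 2")
  expect_error(sim_config(coupling_beta = 1.2), "0, 1")
  expect_error(sim_config(coupling_length = 0), "coupling_length")
  expect_error(sim_config(occupancy_target = 0), "occupancy_target")
  expect_error(sim_config(replicate_count = 0), ">= 1")
  expect_error(sim_config(network_size_range = c(10, 5)), "increasing")
})

test_that("nucleus generator is deterministic and geometrically valid", {
  cfg <- sim_config(n_nuclei = 8, n_chromosomes = 6, seed = 11)
  a <- simulate_nuclei(cfg)
  b <- simulate_nuclei(cfg)
  expect_identical(a, b)

  nrm <- sqrt(a$coords$x^2 + a$coords$y^2 + a$coords$z^2)
  expect_true(all(nrm <= 1 + 1e-9))
  counts <- dplyr::count(a$coords, nucleus, chromosome)
  expect_true(all(counts$n == 2))
  expect_equal(nrow(a$coords), 8 * 6 * 2)
})

test_that("decoupled placement carries no activity information", {
  # beta = 0: base positions are uniform draws, so the correlation between
  # |delta log activity| and base inter-centre distance vanishes on average
  rs <- vapply(1:20, function(sd) {
    s <- simulate_nuclei(sim_config(coupling_beta = 0, seed = sd))
    base <- as.matrix(s$base[, c("x", "y", "z")])
    d <- as.matrix(dist(base))
    la <- s$activity$log_activity
    ad <- abs(outer(la, la, "-"))
    cor(d[upper.tri(d)], ad[upper.tri(ad)])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("fully coupled two-chromosome placement has exact spacing", {
  cfg <- sim_config(n_nuclei = 1, n_chromosomes = 2, coupling_beta = 1,
                    coupling_length = 0.1, position_jitter = 0, seed = 5)
  s <- simulate_nuclei(cfg)
  base <- as.matrix(s$base[, c("x", "y", "z")])
  expect_equal(sqrt(sum((base[1, ] - base[2, ])^2)), 0.1,
               tolerance = 1e-12)
  # with zero jitter every homologue sits on the base position
  d12 <- compute_ipd(s$coords)
  expect_equal(as.matrix(d12)["chr1", "chr2"], 0.1, tolerance = 1e-12)
})

test_that("coupled placement induces IPD-IAD correlation verified by oracle", {
  cfg <- sim_config(coupling_beta = 1, seed = 1)
  s <- simulate_nuclei(cfg)
  ipd <- compute_ipd(s$coords)
  iad <- compute_iad(s$activity)
  pcc <- correlate_matrices(ipd, iad)$pcc
  # same quantity recomputed from raw coordinates with the literal oracle
  sub <- s$coords[s$coords$nucleus <= 8, ]
  expect_equal(as.matrix(compute_ipd(sub)),
               oracle_ipd(sub, "mean"), tolerance = 1e-12)
  expect_equal(pcc, oracle_matrix_pcc(as.matrix(ipd), as.matrix(iad)),
               tolerance = 1e-12)
  expect_gt(pcc, 0.2)  # clearly positive under full coupling
})

test_that("coupling strength separates the null and coupled regimes", {
  meds <- vapply(c(0, 1), function(beta) {
    median(vapply(1:10, function(sd) {
      s <- simulate_nuclei(sim_config(coupling_beta = beta, seed = sd))
      correlate_matrices(compute_ipd(s$coords),
                         compute_iad(s$activity))$pcc
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(meds[1]), 0.1)
  expect_gt(meds[2], meds[1] + 0.1)
})

test_that("zero-noise expression recovers the input activity exactly", {
  cfg <- sim_config(n_chromosomes = 3, genes_per_chromosome = 4,
                    probes_per_gene = 1, replicate_count = 1,
                    noise_sd = 0, intensity_scale = 1, seed = 3)
  act <- tibble::tibble(chromosome = paste0("chr", 1:3),
                        log_activity = c(-0.5, 0, 1))
  e <- simulate_expression(cfg, act)
  genes <- aggregate_probes(e$table, allow_unnormalized = TRUE)
  a <- chromosome_activity(genes, e$annotation)
  expect_equal(a$log_activity, act$log_activity, tolerance = 1e-12)
})

test_that("expression tables are reproducible and strictly positive", {
  cfg <- sim_config(n_chromosomes = 4, noise_sd = 0.5, seed = 9)
  e1 <- simulate_expression(cfg)
  e2 <- simulate_expression(cfg)
  expect_identical(e1$table, e2$table)
  expect_true(all(e1$table$intensity > 0))
  expect_setequal(names(e1$table),
                  c("probe_id", "gene_id", "chromosome", "replicate",
                    "intensity"))
})

test_that("log-activity recovery is unbiased under multiplicative noise", {
  truth <- c(-0.8, 0.2, 1.1)
  recov <- matrix(0, 50, 3)
  for (k in 1:50) {
    cfg <- sim_config(n_chromosomes = 3, genes_per_chromosome = 10,
                      probes_per_gene = 1, replicate_count = 1,
                      noise_sd = 0.3, intensity_scale = 1, seed = 1000 + k)
    act <- tibble::tibble(chromosome = paste0("chr", 1:3),
                          log_activity = truth)
    e <- simulate_expression(cfg, act)
    genes <- aggregate_probes(e$table, allow_unnormalized = TRUE)
    recov[k, ] <- chromosome_activity(genes, e$annotation)$log_activity
  }
  se <- apply(recov, 2, sd) / sqrt(50)
  expect_true(all(abs(colMeans(recov) - truth) < 3 * se))
})

test_that("network catalogs honour size and occupancy structure", {
  cfg <- sim_config(seed = 7)
  e <- simulate_expression(cfg)
  catalog <- dplyr::distinct(e$table, gene_id, chromosome)

  nets <- simulate_networks(cfg, catalog)
  expect_length(nets, 87)
  expect_true(all(lengths(nets) >= 1))
  rng <- cfg$network_size_range
  expect_true(all(lengths(nets) >= rng[1] & lengths(nets) <= rng[2]))

  occ <- network_occupancy(nets, catalog, n_chromosomes = 22)
  expect_gt(cor(occ$occupancy, occ$n_genes, method = "spearman"), 0.5)

  # degenerate cases
  one <- list(solo = catalog$gene_id[1])
  expect_equal(unname(network_occupancy(one, catalog, 22)$occupancy),
               1 / 22)
  everywhere <- list(all = catalog$gene_id)
  expect_equal(unname(network_occupancy(everywhere, catalog, 22)$occupancy),
               1)
})

test_that("paint phantoms carry analytic ground truth", {
  # two cuboids, 1 um face gap along x
  blobs <- tibble::tibble(
    channel = c(1, 1, 2, 2), shape = "cuboid",
    cx = c(1.0, 1.0, 3.0, 3.0), cy = c(2.0, 8.0, 2.0, 8.0),
    cz = c(8, 8, 8, 8),
    rx = 0.5, ry = 0.5, rz = 1.0
  )
  ps <- simulate_paint_stack(blobs, dim = c(64, 64, 32),
                             spacing = c(0.2, 0.2, 0.5))
  gt <- ps$ground_truth
  same_row <- gt[gt$blob_a == 1 & gt$blob_b == 3, ]
  expect_equal(same_row$gap_um, 1.0)

  # touching blobs have zero analytic gap
  touch <- tibble::tibble(
    channel = c(1, 2), shape = "cuboid",
    cx = c(2, 4), cy = 5, cz = 8, rx = 1, ry = 1, rz = 1)
  pt <- simulate_paint_stack(touch, dim = c(64, 64, 32),
                             spacing = c(0.2, 0.2, 0.5))
  expect_equal(pt$ground_truth$gap_um, 0)

  expect_error(
    simulate_paint_stack(
      tibble::tibble(channel = 1, shape = "sphere", cx = 0.1, cy = 5,
                     cz = 5, rx = 1, ry = 1, rz = 1),
      dim = c(64, 64, 32), spacing = c(0.2, 0.2, 0.5)),
    "outside the stack bounds")
})

test_that("two-cell-type mode shifts the configured gene fraction", {
  cfg <- sim_config(n_chromosomes = 5, seed = 21)
  pair <- simulate_expression_pair(cfg, shift_fraction = 0.25, log_shift = 2)
  n_genes <- dplyr::n_distinct(pair$cell_a$gene_id)
  expect_equal(length(pair$shifted_genes), round(0.25 * n_genes))
  expect_identical(sort(unique(pair$cell_a$gene_id)),
                   sort(unique(pair$cell_b$gene_id)))
  # shifted genes really are higher in cell B on the raw scale
  ga <- oracle_gene_activity(pair$cell_a)
  gb <- oracle_gene_activity(pair$cell_b)
  ratio <- log(gb[pair$shifted_genes] / ga[pair$shifted_genes])
  expect_gt(median(ratio), 1.5)
})
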