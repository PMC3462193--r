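test_that("adjacency kernel matches its closed form", {
  v <- matrix(c(0, 0.07, 0.07, 0), 2)
  ipd <- dist_matrix(v, labels = c("a", "b"), role = "IPD_mean",
                     units = "nuclear_radius", diag_excluded = TRUE)
  adj <- build_adjacency(ipd, 0.07)
  expect_equal(as.matrix(adj)["a", "b"], exp(-1), tolerance = 1e-12)
  expect_equal(diag(as.matrix(adj)), c(a = 1, b = 1))
  expect_error(build_adjacency(ipd, 0), "positive")

  # elementwise monotone decreasing in distance
  m <- make_metric_matrix(8, seed = 1)
  A <- as.matrix(build_adjacency(m, 0.2))
  ut <- upper.tri(A)
  expect_equal(order(A[ut]), order(-m$values[ut]))
})

test_that("network matrix integrates activities per chromosome", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    chromosome = c("chr1", "chr2", "chr2"),
    activity = c(exp(2), exp(1), exp(1)))
  catalog <- list(f1 = "g1", f2 = c("g2", "g3"))
  nm <- build_network_matrix(genes, catalog,
                             chromosomes = c("chr1", "chr2", "chr3"))
  expect_equal(nm$phi["chr1", "f1"], 2)
  expect_equal(nm$phi["chr2", "f1"], 0)  # exact zero where no genes
  expect_equal(nm$phi["chr2", "f2"], 1 + log(2), tolerance = 1e-12)
  expect_equal(nm$phi["chr3", "f2"], 0)

  expect_warning(
    build_network_matrix(genes, list(ghost = "nope"),
                         chromosomes = c("chr1", "chr2")),
    "no genes")
})

test_that("network matrix equals the group-and-sum oracle", {
  sc <- coupled_scene(seed = 13)
  phi <- sc$phi$phi
  for (f in sample(seq_along(sc$nets), 10)) {
    ids <- intersect(sc$nets[[f]], sc$genes$gene_id)
    for (ch in dm_labels(sc$ipd)) {
      sub <- sc$genes[sc$genes$gene_id %in% ids &
                        sc$genes$chromosome == ch, ]
      expected <- if (nrow(sub)) log(sum(sub$activity)) else 0
      expect_equal(phi[ch, f], expected, tolerance = 1e-12)
    }
  }
})

test_that("H obeys its algebraic identities", {
  set.seed(2)
  A <- as.matrix(make_metric_matrix(6, seed = 3))
  A <- exp(-A)
  adj <- dist_matrix(A, labels = paste0("chr", 1:6), role = "adjacency")

  # constant columns: H = 0
  expect_equal(compute_H(adj, matrix(5, 6, 3)), 0)

  # forced 2x1 case
  a2 <- dist_matrix(matrix(c(1, 0.5, 0.5, 1), 2), labels = c("a", "b"),
                    role = "adjacency")
  expect_equal(compute_H(a2, matrix(c(1, 3), 2, 1)), 2)

  phi <- matrix(rnorm(6 * 4), 6, 4)
  h <- compute_H(adj, phi)
  expect_gte(h, 0)
  expect_equal(h, oracle_h(A, phi), tolerance = 1e-10)

  # per-column additive shifts cancel exactly
  shifted <- sweep(phi, 2, c(10, -3, 0.5, 100), "+")
  expect_equal(compute_H(adj, shifted), h, tolerance = 1e-9)

  # simultaneous permutation invariance; adjacency-only permutation moves H
  for (k in 1:25) {
    p <- sample(6)
    both <- dist_matrix(A[p, p], labels = paste0("chr", 1:6),
                        role = "adjacency")
    expect_equal(compute_H(both, phi[p, , drop = FALSE]), h,
                 tolerance = 1e-10)
  }
  p <- c(2, 1, 3, 4, 6, 5)
  only_adj <- dist_matrix(A[p, p], labels = paste0("chr", 1:6),
                          role = "adjacency")
  expect_gt(abs(compute_H(only_adj, phi) - h), 1e-8)

  # increasing one informative weight strictly increases H
  A2 <- A
  A2[1, 2] <- A2[2, 1] <- min(1, A[1, 2] + 0.05)
  adj2 <- dist_matrix(A2, labels = paste0("chr", 1:6), role = "adjacency")
  expect_gt(compute_H(adj2, phi), h)
})

test_that("H randomization summarises the trajectory correctly", {
  sc <- coupled_scene(seed = 4)
  cfgE <- energy_config(n_iterations = 400, seed = 8)
  rz <- randomize_H(sc$adjacency, sc$phi, cfgE)
  expect_length(rz$trajectory, 400)
  expect_equal(rz$h_av, mean(rz$trajectory))
  expect_equal(rz$sigma, sd(rz$trajectory))
  expect_equal(rz$delta_h, (rz$h_av - rz$h0) / rz$sigma)
  expect_equal(rz$p_empirical, mean(rz$trajectory <= rz$h0))
  expect_true(all(rz$trajectory >= 0))

  # reproducible under a fixed seed, in both modes
  rz2 <- randomize_H(sc$adjacency, sc$phi, cfgE)
  expect_identical(rz$trajectory, rz2$trajectory)
  ind <- randomize_H(sc$adjacency, sc$phi,
                     energy_config(n_iterations = 50,
                                   mode = "independent", seed = 5))
  expect_length(ind$trajectory, 50)

  # degenerate constant Phi exercises the sigma = 0 path
  flat <- matrix(1, nrow(sc$phi$phi), 2)
  dz <- randomize_H(sc$adjacency, flat,
                    energy_config(n_iterations = 20, seed = 1))
  expect_equal(dz$sigma, 0)
  expect_true(is.na(dz$delta_h))

  # homologue exclusion only zeroes the diagonal bookkeeping
  excl <- randomize_H(sc$adjacency, sc$phi,
                      energy_config(n_iterations = 400, seed = 8,
                                    exclude_homologues = TRUE))
  expect_equal(excl$trajectory, rz$trajectory, tolerance = 1e-12)
})

test_that("H rises early along cumulative randomization of coupled data", {
  # the climb away from H0 happens within the first couple of hundred
  # swaps; afterwards the chain fluctuates around its stationary mean
  early_below <- logical(5)
  for (sd in 1:5) {
    sc <- coupled_scene(seed = sd)
    rz <- randomize_H(sc$adjacency, sc$phi,
                      energy_config(n_iterations = 4000, seed = 10 + sd))
    expect_gt(rz$delta_h, 1)
    expect_lt(mean(rz$trajectory[1:20]), rz$h_av)  # initial climb
    early_below[sd] <- mean(rz$trajectory[1:200]) <
      mean(rz$trajectory[2000:4000])
  }
  expect_gte(mean(early_below), 0.8)
})

test_that("the Gaussian-tail mapping matches an independent erfc oracle", {
  expect_equal(deviation_to_p(0), 1)
  grid <- c(-1, 0.3, 0.71, 1.02, 1.97, 3.5)
  oracle <- pmin(1, pracma::erfc(grid / sqrt(2)))
  expect_equal(deviation_to_p(grid), oracle, tolerance = 1e-12)
  expect_error(deviation_to_p(NA), "finite")
})

test_that("lambda scan returns a well-formed curve and argmax", {
  sc <- coupled_scene(seed = 5)
  single <- scan_lambda(sc$ipd, sc$phi, lambda_grid = 0.1,
                        n_iterations = 60, seed = 2)
  expect_equal(attr(single, "lambda_opt"), 0.1)

  grid <- seq(0.02, 0.8, by = 0.05)
  sc2 <- scan_lambda(sc$ipd, sc$phi, lambda_grid = grid,
                     n_iterations = 60, seed = 3)
  expect_true(all(is.finite(sc2$delta_h)))
  expect_equal(nrow(sc2), length(grid))
  expect_error(scan_lambda(sc$ipd, sc$phi, lambda_grid = c(-0.1, 0.2)),
               "positive")
})

test_that("lambda scan favours the coupling scale when coupling is local", {
  # one informative distance scale: chromosome pairs with similar network
  # activity sit at d0 = 0.1, all other distances are unstructured - the
  # deviate is larger near d0 than at long range
  set.seed(9)
  L <- 14
  d0 <- 0.1
  v <- matrix(runif(L * L, 0.5, 1.5), L, L)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  phi <- matrix(rnorm(L * 6), L, 6)
  for (k in seq(1, L, by = 2)) {
    v[k, k + 1] <- v[k + 1, k] <- d0
    phi[k + 1, ] <- phi[k, ] + rnorm(6, 0, 0.05)
  }
  ipd <- dist_matrix(v, labels = paste0("chr", 1:L), role = "IPD_mean",
                     units = "nuclear_radius", diag_excluded = TRUE)
  grid <- c(0.04, 0.06, 0.08, 0.1, 0.6, 0.7, 0.8)
  sc <- scan_lambda(ipd, phi, lambda_grid = grid,
                    n_iterations = 2000, seed = 77)
  expect_gt(mean(sc$delta_h[sc$lambda <= 0.1]),
            mean(sc$delta_h[sc$lambda >= 0.6]))
  expect_gt(attr(sc, "delta_h_max"), 1)
})

test_that("per-network sensitivity is deterministic and flags H0 = 0", {
  sc <- coupled_scene(seed = 12)
  s1 <- per_network_sensitivity(sc$adjacency, sc$phi, n_steps = 50,
                                reps = 2, seed = 5)
  s2 <- per_network_sensitivity(sc$adjacency, sc$phi, n_steps = 50,
                                reps = 2, seed = 5)
  expect_equal(s1$delta_h_rel, s2$delta_h_rel)
  expect_equal(nrow(s1), length(sc$nets))

  # a network whose genes all sit on one chromosome has H0 > 0 (zero/value
  # contrast), but a constant-Phi catalog gives H0 = 0 and is flagged
  flatphi <- sc$phi
  flatphi$phi[, 1] <- 2
  s3 <- per_network_sensitivity(sc$adjacency, flatphi, n_steps = 10,
                                reps = 1, seed = 1)
  expect_true(is.na(s3$delta_h_rel[1]))
})

test_that("occupancy and per-chromosome network counts match brute force", {
  sc <- coupled_scene(seed = 14)
  occ <- network_occupancy(sc$phi)
  brute <- vapply(seq_along(sc$nets), function(f) {
    ids <- intersect(sc$nets[[f]], sc$genes$gene_id)
    length(unique(sc$genes$chromosome[sc$genes$gene_id %in% ids])) / 22
  }, numeric(1))
  expect_equal(unname(occ$occupancy), unname(brute), tolerance = 1e-12)
  expect_equal(unname(occ$occupancy),
               unname(network_occupancy(sc$nets, sc$genes, 22)$occupancy))

  ann <- tibble::tibble(chromosome = dm_labels(sc$ipd),
                        basepairs = seq(2.4e8, 5e7, length.out = 22),
                        gene_count = tabulate(factor(
                          sc$genes$chromosome, levels = dm_labels(sc$ipd))))
  npc <- networks_per_chromosome(sc$nets, sc$genes, ann)
  brute_counts <- vapply(ann$chromosome, function(ch) {
    sum(vapply(sc$nets, function(ids) {
      any(sc$genes$chromosome[sc$genes$gene_id %in% ids] == ch)
    }, logical(1)))
  }, numeric(1))
  expect_equal(unname(npc$n_networks), unname(brute_counts))

  # constructed degenerate and proportional cases
  single <- list(all = sc$genes$gene_id)
  one <- networks_per_chromosome(single, sc$genes, ann)
  expect_true(all(one$n_networks == 1))
  expect_true(is.na(attr(one, "pcc_gene_count")))
})
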