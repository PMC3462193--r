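# Independent brute-force oracles and small fixture builders.  Each oracle
# deliberately takes the most literal route (explicit loops, stats::dist,
# igraph flood fill) so it shares no code path with the implementation it
# checks.

# IPD by explicit iteration over nuclei and homologue pairings
oracle_ipd <- function(coords, mode = "mean") {
  labels <- unique(coords$chromosome)
  L <- length(labels)
  out <- matrix(NA_real_, L, L, dimnames = list(labels, labels))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      vals <- c()
      for (nuc in unique(coords$nucleus)) {
        a <- coords[coords$nucleus == nuc & coords$chromosome == labels[i], ]
        b <- coords[coords$nucleus == nuc & coords$chromosome == labels[j], ]
        if (i == j) {
          if (nrow(a) == 2) {
            vals <- c(vals, sqrt(sum((a[1, c("x", "y", "z")] -
                                        a[2, c("x", "y", "z")])^2)))
          }
          next
        }
        if (nrow(a) == 0 || nrow(b) == 0) next
        d4 <- c()
        for (p in seq_len(nrow(a))) {
          for (q in seq_len(nrow(b))) {
            d4 <- c(d4, sqrt(sum((a[p, c("x", "y", "z")] -
                                    b[q, c("x", "y", "z")])^2)))
          }
        }
        vals <- c(vals, if (mode == "mean") mean(d4) else min(d4))
      }
      out[i, j] <- if (length(vals)) mean(vals) else NA_real_
    }
  }
  out
}

# H by the literal triple loop over networks and unordered pairs
oracle_h <- function(A, phi) {
  L <- nrow(phi)
  h <- 0
  for (f in seq_len(ncol(phi))) {
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        h <- h + A[i, j] * (phi[i, f] - phi[j, f])^2
      }
    }
  }
  h
}

# PCC between two dist matrices via direct vector extraction and cor()
oracle_matrix_pcc <- function(M1, M2) {
  cor(M1[upper.tri(M1)], M2[upper.tri(M2)])
}

# minimum cross-set distance via stats::dist on the pooled coordinates
oracle_min_distance <- function(a, b) {
  D <- as.matrix(dist(rbind(a, b)))
  min(D[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b))])
}

# 26-connected components via igraph on the voxel adjacency graph
oracle_components <- function(mask) {
  idx <- which(mask)
  co <- arrayInd(idx, dim(mask))
  n <- length(idx)
  edges <- c()
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      if (all(abs(co[u, ] - co[v, ]) <= 1)) edges <- c(edges, u, v)
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  split(idx, comp)
}

# per-gene aggregation by base-R tapply (replicate mean, then probe mean)
oracle_gene_activity <- function(t) {
  probe_mean <- tapply(t$intensity, t$probe_id, mean)
  gene_of <- tapply(t$gene_id, t$probe_id, function(x) x[1])
  out <- tapply(as.numeric(probe_mean), as.character(gene_of), mean)
  setNames(as.numeric(out), names(out))[sort(names(out))]
}

# labelled symmetric metric matrix from random points in 3-space
make_metric_matrix <- function(L, seed, role = "other") {
  set.seed(seed)
  pts <- matrix(rnorm(3 * L), L, 3)
  m <- as.matrix(dist(pts))
  dist_matrix(m, labels = paste0("chr", seq_len(L)),
              role = role, diag_excluded = FALSE)
}

# small expression table built by hand
tiny_expression <- function() {
  tibble::tibble(
    probe_id = c("g1_p1", "g1_p2", "g2_p1", "g1_p1", "g1_p2", "g2_p1"),
    gene_id = c("g1", "g1", "g2", "g1", "g1", "g2"),
    chromosome = c("chr1", "chr1", "chr2", "chr1", "chr1", "chr2"),
    replicate = c(1, 1, 1, 2, 2, 2),
    intensity = c(2, 4, 1, 2, 4, 1)
  )
}

# fully-built coupled synthetic scene shared by the energy tests
coupled_scene <- function(seed, beta = 1, lambda = 0.07) {
  cfg <- sim_config(coupling_beta = beta, seed = seed)
  s <- simulate_nuclei(cfg)
  ipd <- compute_ipd(s$coords)
  e <- simulate_expression(cfg, s$activity)
  genes <- aggregate_probes(normalize_to_array_mean(e$table))
  nets <- simulate_networks(
    cfg, dplyr::distinct(e$table, gene_id, chromosome),
    activity = s$activity)
  phi <- suppressMessages(
    build_network_matrix(genes, nets, chromosomes = dm_labels(ipd)))
  list(cfg = cfg, sim = s, ipd = ipd, genes = genes, nets = nets,
       phi = phi, adjacency = build_adjacency(ipd, lambda))
}
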