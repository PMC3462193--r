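#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators.  The defaults
#' reproduce the study conditions the downstream analysis assumes: 54 nuclei,
#' 22 autosomes with two homologues each, positions in units of the nuclear
#' radius, probe-level expression with multiple probes per gene and duplicate
#' arrays, and a catalog of 87 transcription-factor networks whose sizes span
#' roughly 5 to 300 genes.
#'
#' @param n_nuclei number of nuclei to simulate (default 54).
#' @param n_chromosomes number of chromosomes (default 22 autosomes); must be
#'   at least 2.
#' @param coupling_beta position-activity coupling strength in `[0, 1]`:
#'   0 places chromosomes independently of activity, 1 uses the fully
#'   activity-coupled neighbourhood placement.
#' @param coupling_length length scale, as a fraction of the nuclear radius,
#'   separating chromosomes of adjacent activity rank within a co-regulation
#'   neighbourhood (default 0.07, the adjacency length scale the energy
#'   analysis targets).
#' @param cluster_size number of activity-adjacent chromosomes per
#'   co-regulation neighbourhood (default 4); coupling is confined to this
#'   range, so positional information about activity is short-ranged.
#' @param position_jitter standard deviation (fraction of nuclear radius) of
#'   the isotropic per-nucleus, per-homologue displacement around each
#'   chromosome's base position (default 0.10).
#' @param activity_sd standard deviation of the per-chromosome ground-truth
#'   log activities (default 0.4: chromosome-level mean expression varies
#'   only a few fold, less than per-chromosome gene density does).
#' @param genes_per_chromosome genes simulated per chromosome: a scalar
#'   (constant count), a vector of length `n_chromosomes`, or `NULL`
#'   (default) for a heterogeneous log-normal profile around 120 genes —
#'   gene density varies several-fold between real chromosomes, and that
#'   variation is what decouples large-network activity sums from
#'   chromosome positions.
#' @param intensity_scale native intensity units of the simulated array
#'   (default 500): probe intensities are `intensity_scale * exp(log
#'   activity + noise)`, matching the magnitude of summarised microarray
#'   output.  Array-mean normalization removes it; the network activity
#'   matrix, built on integrated raw intensities, retains it.
#' @param probes_per_gene probes per gene on the array (default 3).
#' @param replicate_count replicate arrays (default 2).
#' @param noise_sd log-scale multiplicative noise SD applied independently at
#'   the gene and at the probe level (default 0.3).
#' @param n_networks number of transcription-factor networks (default 87).
#' @param network_size_range inclusive range of network sizes in genes
#'   (default `c(5, 300)`).
#' @param occupancy_target mean fraction of chromosomes carrying at least one
#'   gene of a network, in `(0, 1]` (default 0.6).
#' @param seed integer seed; a fixed seed makes every generator
#'   byte-reproducible.  Generators use fixed offsets from this seed so the
#'   stages are mutually independent but jointly deterministic.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_nuclei = 54,
                       n_chromosomes = 22,
                       coupling_beta = 0.5,
                       coupling_length = 0.07,
                       cluster_size = 4,
                       position_jitter = 0.10,
                       activity_sd = 0.4,
                       genes_per_chromosome = NULL,
                       intensity_scale = 500,
                       probes_per_gene = 3,
                       replicate_count = 2,
                       noise_sd = 0.3,
                       n_networks = 87,
                       network_size_range = c(5, 300),
                       occupancy_target = 0.6,
                       seed = 1L) {
  cfg <- list(
    n_nuclei = as.integer(n_nuclei),
    n_chromosomes = as.integer(n_chromosomes),
    coupling_beta = coupling_beta,
    coupling_length = coupling_length,
    cluster_size = as.integer(cluster_size),
    position_jitter = position_jitter,
    activity_sd = activity_sd,
    genes_per_chromosome = if (is.null(genes_per_chromosome)) NULL else
      as.integer(genes_per_chromosome),
    intensity_scale = intensity_scale,
    probes_per_gene = as.integer(probes_per_gene),
    replicate_count = as.integer(replicate_count),
    noise_sd = noise_sd,
    n_networks = as.integer(n_networks),
    network_size_range = as.integer(network_size_range),
    occupancy_target = occupancy_target,
    seed = as.integer(seed)
  )
  counts <- c(cfg$n_nuclei, cfg$n_chromosomes, cfg$probes_per_gene,
              cfg$replicate_count, cfg$n_networks, cfg$cluster_size,
              cfg$genes_per_chromosome %||% 1L)
  if (any(is.na(counts)) || any(counts < 1)) {
    abort("all counts in a sim_config must be >= 1.")
  }
  if (cfg$n_chromosomes < 2) {
    abort("`n_chromosomes` must be at least 2.")
  }
  if (!is.numeric(cfg$coupling_beta) || cfg$coupling_beta < 0 ||
      cfg$coupling_beta > 1) {
    abort("`coupling_beta` must lie in [0, 1].")
  }
  if (cfg$coupling_length <= 0 || cfg$position_jitter < 0 ||
      cfg$noise_sd < 0 || cfg$activity_sd < 0 || cfg$intensity_scale <= 0) {
    abort("scale parameters must be non-negative (coupling_length > 0).")
  }
  if (length(cfg$network_size_range) != 2 ||
      cfg$network_size_range[1] > cfg$network_size_range[2] ||
      cfg$network_size_range[1] < 1) {
    abort("`network_size_range` must be an increasing pair of counts >= 1.")
  }
  if (cfg$occupancy_target <= 0 || cfg$occupancy_target > 1) {
    abort("`occupancy_target` must lie in (0, 1].")
  }
  if (!is.null(cfg$genes_per_chromosome) &&
      !(length(cfg$genes_per_chromosome) %in% c(1L, cfg$n_chromosomes))) {
    abort("`genes_per_chromosome` must be NULL, scalar or length n_chromosomes.")
  }
  structure(cfg, class = "sim_config")
}

chromosome_labels <- function(n) paste0("chr", seq_len(n))

# uniform points in the unit ball (direction x cube-root radius)
random_ball <- function(n) {
  dir <- matrix(rnorm(3 * n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  dir * runif(n)^(1 / 3)
}

# Coupled placement with a finite correlation length.  Chromosomes sorted by
# log activity are grouped into consecutive runs of `cluster_size`
# (co-regulation neighbourhoods).  Each neighbourhood sits at a random
# location in the nucleus; inside it, members are laid out along a straight
# segment with steps proportional to their log-activity gaps, normalised so
# the mean consecutive step across the genome equals `coupling_length`.
# Within a neighbourhood, inter-centre distance therefore grows with
# |delta log activity| at scale coupling_length; between neighbourhoods,
# distances are unrelated to activity — coupling is short-ranged.
place_coupled <- function(log_activity, coupling_length, cluster_size) {
  L <- length(log_activity)
  ord <- order(log_activity)
  la <- log_activity[ord]
  gaps <- diff(la)
  steps <- if (L == 1 || mean(gaps) == 0) {
    rep(0, max(L - 1, 0))
  } else {
    coupling_length * gaps / mean(gaps)
  }
  ncl <- ceiling(L / cluster_size)
  centers <- random_ball(ncl) * 0.8
  dirs <- matrix(rnorm(3 * ncl), ncl, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pos <- matrix(0, L, 3)
  for (c in seq_len(ncl)) {
    ranks <- ((c - 1) * cluster_size + 1):min(c * cluster_size, L)
    if (length(ranks) > 1) {
      within <- steps[ranks[-length(ranks)]]
      # renormalise within the neighbourhood so its mean step is exactly
      # coupling_length while relative activity gaps set the layout
      if (mean(within) > 0) within <- within * coupling_length / mean(within)
      cum <- c(0, cumsum(within))
    } else {
      cum <- 0
    }
    cum <- cum - mean(cum)
    pos[ranks, ] <- centers[rep(c, length(ranks)), , drop = FALSE] +
      outer(cum, dirs[c, ])
  }
  out <- matrix(0, L, 3)
  out[ord, ] <- pos
  out
}

#' Simulate chromosome territory centroids
#'
#' Generates per-nucleus 3D centroid coordinates for two homologues of each
#' chromosome, in units of the nuclear radius, with a tunable coupling
#' between chromosome position and a ground-truth transcriptional activity.
#'
#' Each chromosome receives a ground-truth log activity drawn from
#' `N(0, activity_sd^2)`.  Chromosomes sorted by log activity form
#' consecutive co-regulation neighbourhoods of `cluster_size`; each
#' neighbourhood is dropped at a random location in the nucleus and its
#' members are spaced along a segment in proportion to their log-activity
#' gaps (mean consecutive spacing `coupling_length`), so positions carry
#' activity information only over the neighbourhood range.  These coupled
#' positions are blended with uniform random positions in the unit ball
#' with weight `coupling_beta` (1 = fully activity-coupled, 0 = independent
#' of activity).  Every nucleus then
#' displaces each homologue independently by isotropic Gaussian jitter of SD
#' `position_jitter`, and positions are clipped to the unit ball.
#'
#' @param config a [sim_config()].
#' @return An object of class `nucleus_sim`: a list with
#'   * `coords` — tibble `(nucleus, chromosome, homologue, x, y, z)`,
#'   * `activity` — tibble `(chromosome, log_activity)` (ground truth),
#'   * `base` — tibble of noise-free base positions per chromosome,
#'   * `config` — the configuration used.
#' @export
#' @examples
#' sim <- simulate_nuclei(sim_config(n_nuclei = 4, n_chromosomes = 5))
#' head(sim$coords)
simulate_nuclei <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$n_chromosomes
  labels <- chromosome_labels(L)
  set.seed(config$seed)
  log_activity <- rnorm(L, 0, config$activity_sd)
  coupled <- place_coupled(log_activity, config$coupling_length,
                           config$cluster_size)
  unif <- random_ball(L)
  base <- config$coupling_beta * coupled + (1 - config$coupling_beta) * unif

  n_pos <- config$n_nuclei * L * 2L
  jit <- matrix(rnorm(3 * n_pos, 0, config$position_jitter), n_pos, 3)
  idx_chr <- rep(rep(seq_len(L), each = 2L), times = config$n_nuclei)
  pos <- base[idx_chr, , drop = FALSE] + jit
  nrm <- sqrt(rowSums(pos^2))
  over <- nrm > 1
  if (any(over)) pos[over, ] <- pos[over, ] / nrm[over]

  coords <- tibble(
    nucleus = rep(seq_len(config$n_nuclei), each = 2L * L),
    chromosome = labels[idx_chr],
    homologue = rep(rep(1:2, times = L), times = config$n_nuclei),
    x = pos[, 1], y = pos[, 2], z = pos[, 3]
  )
  structure(
    list(
      coords = coords,
      activity = tibble(chromosome = labels, log_activity = log_activity),
      base = tibble(chromosome = labels,
                    x = base[, 1], y = base[, 2], z = base[, 3]),
      config = config
    ),
    class = "nucleus_sim"
  )
}

#' @export
print.nucleus_sim <- function(x, ...) {
  cat(sprintf(
    "<nucleus_sim> %d nuclei, %d chromosomes x 2 homologues (beta = %.2f)\n",
    x$config$n_nuclei, x$config$n_chromosomes, x$config$coupling_beta))
  invisible(x)
}

# per-chromosome gene counts: explicit profile, or a heterogeneous
# log-normal draw (consumes RNG — call under the stage seed, first)
resolve_gpc <- function(config) {
  if (is.null(config$genes_per_chromosome)) {
    pmax(20L, as.integer(round(exp(rnorm(config$n_chromosomes,
                                         log(120), 0.5)))))
  } else {
    rep(config$genes_per_chromosome, length.out = config$n_chromosomes)
  }
}

# gene-level log means around the chromosome log activity; each log-normal
# layer is mean-corrected by -sd^2/2 so linear-scale expectations equal the
# target activity and log-activity recovery is unbiased
sim_gene_means <- function(config, activity_tbl, gpc) {
  chrom <- rep(activity_tbl$chromosome, times = gpc)
  la <- rep(activity_tbl$log_activity, times = gpc)
  gene_id <- paste0(chrom, "_g", unlist(lapply(gpc, seq_len)))
  eps <- rnorm(length(la), 0, config$noise_sd)
  tibble(gene_id = gene_id, chromosome = chrom,
         log_mean = la + eps - config$noise_sd^2 / 2)
}

sim_probe_table <- function(config, gene_means) {
  P <- config$probes_per_gene
  Rp <- config$replicate_count
  G <- nrow(gene_means)
  tab <- tibble(
    probe_id = rep(paste0(rep(gene_means$gene_id, each = P), "_p",
                          rep(seq_len(P), times = G)), times = Rp),
    gene_id = rep(rep(gene_means$gene_id, each = P), times = Rp),
    chromosome = rep(rep(gene_means$chromosome, each = P), times = Rp),
    replicate = rep(seq_len(Rp), each = P * G),
    log_mean = rep(rep(gene_means$log_mean, each = P), times = Rp)
  )
  noise <- rnorm(nrow(tab), 0, config$noise_sd)
  tab$intensity <- config$intensity_scale *
    exp(tab$log_mean + noise - config$noise_sd^2 / 2)
  tab$log_mean <- NULL
  tab
}

# human-like decreasing basepair lengths for the synthetic annotation
sim_annotation <- function(config, gpc) {
  L <- config$n_chromosomes
  tibble(
    chromosome = chromosome_labels(L),
    basepairs = round(seq(2.45e8, 4.7e7, length.out = L)),
    gene_count = as.integer(gpc)
  )
}

#' Simulate a probe-level expression table
#'
#' Generates log-normal probe intensities around per-chromosome activity
#' levels, with multiple probes per gene and replicate arrays, emulating
#' MAS5-style summarised microarray output.
#'
#' @param config a [sim_config()].
#' @param activity ground-truth per-chromosome log activities: a tibble with
#'   columns `chromosome`, `log_activity` (as returned in
#'   [simulate_nuclei()]`$activity`), or `NULL` to draw a fresh vector.
#' @return An object of class `expression_sim`: a list with
#'   * `table` — tibble `(probe_id, gene_id, chromosome, replicate,
#'      intensity)`, intensities strictly positive,
#'   * `annotation` — tibble `(chromosome, basepairs, gene_count)` with the
#'      annotated gene counts,
#'   * `activity` — the ground-truth activity used,
#'   * `config`.
#' @export
simulate_expression <- function(config, activity = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  L <- config$n_chromosomes
  if (is.null(activity)) {
    activity <- tibble(chromosome = chromosome_labels(L),
                       log_activity = rnorm(L, 0, config$activity_sd))
  }
  activity <- as_tibble(activity)
  if (nrow(activity) != L) {
    abort("`activity` must have one row per chromosome.")
  }
  gpc <- resolve_gpc(config)
  gm <- sim_gene_means(config, activity, gpc)
  tab <- sim_probe_table(config, gm)
  structure(
    list(table = tab, annotation = sim_annotation(config, gpc),
         activity = activity, config = config),
    class = "expression_sim"
  )
}

#' Simulate a matched two-cell-type expression pair
#'
#' Derives a second expression table from the first by shifting a fraction of
#' genes by a fixed log offset, mimicking cell-type specific differential
#' expression, to exercise the FWHM differential-selection stage.  Gene-level
#' means are shared between the two tables; probe noise is independent.
#'
#' @inheritParams simulate_expression
#' @param shift_fraction fraction of genes whose cell-B mean is shifted
#'   (default 0.2).
#' @param log_shift log offset added to the shifted genes in cell B
#'   (default 2).
#' @return A list of class `expression_pair_sim` with elements `cell_a`,
#'   `cell_b` (probe tibbles), `shifted_genes` (character), `annotation`,
#'   `activity`, `config`.
#' @export
simulate_expression_pair <- function(config, activity = NULL,
                                     shift_fraction = 0.2, log_shift = 2) {
  stopifnot(inherits(config, "sim_config"))
  if (shift_fraction < 0 || shift_fraction > 1) {
    abort("`shift_fraction` must lie in [0, 1].")
  }
  set.seed(config$seed + 2000L)
  L <- config$n_chromosomes
  if (is.null(activity)) {
    activity <- tibble(chromosome = chromosome_labels(L),
                       log_activity = rnorm(L, 0, config$activity_sd))
  }
  gpc <- resolve_gpc(config)
  gm <- sim_gene_means(config, activity, gpc)
  shifted <- sample(gm$gene_id, size = round(shift_fraction * nrow(gm)))
  gm_b <- gm
  gm_b$log_mean <- gm_b$log_mean + log_shift * (gm_b$gene_id %in% shifted)
  cell_a <- sim_probe_table(config, gm)
  cell_b <- sim_probe_table(config, gm_b)
  structure(
    list(cell_a = cell_a, cell_b = cell_b, shifted_genes = shifted,
         annotation = sim_annotation(config, gpc),
         activity = as_tibble(activity),
         config = config),
    class = "expression_pair_sim"
  )
}

#' Simulate a transcription-factor network catalog
#'
#' Draws networks with log-uniform sizes in `network_size_range` and assigns
#' their genes to chromosomes so that small networks concentrate on few
#' chromosomes: each network's target chromosome occupancy follows a
#' saturating curve `1 - exp(-size / s0)` with `s0` calibrated so the mean
#' realized occupancy approximates `occupancy_target`.  This reproduces the
#' empirical size-occupancy law of annotated TF-network catalogs (large
#' networks span essentially all chromosomes, networks under ~50 genes fewer
#' than half).
#'
#' Each network's chromosomes are chosen as a contiguous window in
#' activity rank when a ground-truth `activity` is supplied (co-regulated
#' targets tend to share expression levels, so a network's chromosomes are
#' activity-similar — the property that couples network topology to spatial
#' organization); without `activity` the chromosomes are sampled uniformly.
#'
#' @param config a [sim_config()].
#' @param gene_catalog tibble with columns `gene_id`, `chromosome`: the gene
#'   universe to draw from (e.g. `distinct(sim$table, gene_id, chromosome)`).
#' @param activity optional tibble `(chromosome, log_activity)`; when given,
#'   network chromosome sets are contiguous in activity rank.
#' @return A named list of gene-id vectors of class `network_catalog`.
#' @export
simulate_networks <- function(config, gene_catalog, activity = NULL) {
  stopifnot(inherits(config, "sim_config"))
  gene_catalog <- distinct(as_tibble(gene_catalog), .data$gene_id,
                           .data$chromosome)
  if (nrow(gene_catalog) == 0) abort("`gene_catalog` is empty.")
  set.seed(config$seed + 3000L)
  chroms <- unique(gene_catalog$chromosome)
  L <- length(chroms)
  pool <- split(gene_catalog$gene_id, gene_catalog$chromosome)[chroms]
  rank_order <- if (!is.null(activity)) {
    activity <- as_tibble(activity)
    ord <- intersect(activity$chromosome[order(activity$log_activity)],
                     chroms)
    if (length(ord) != L) {
      abort("`activity` must cover every chromosome of the gene catalog.")
    }
    ord
  } else NULL

  rng <- config$network_size_range
  sizes <- round(exp(runif(config$n_networks, log(rng[1]), log(rng[2]))))
  sizes <- pmin(pmax(sizes, rng[1]), min(rng[2], nrow(gene_catalog)))

  occ_of <- function(s0) 1 - exp(-sizes / s0)
  target <- config$occupancy_target
  if (target >= 1) {
    occ <- rep(1, length(sizes))
  } else {
    f <- function(s0) mean(occ_of(s0)) - target
    s0 <- tryCatch(uniroot(f, c(1e-3, 1e6))$root, error = function(e) NULL)
    occ <- if (is.null(s0)) rep(target, length(sizes)) else occ_of(s0)
  }

  nets <- vector("list", config$n_networks)
  for (k in seq_len(config$n_networks)) {
    m <- max(1L, min(L, sizes[k], round(occ[k] * L)))
    sel_chroms <- if (is.null(rank_order)) {
      sample(chroms, m)
    } else {
      # networks occupy whole co-regulation neighbourhoods (windows snapped
      # to neighbourhood boundaries), so a small network's chromosomes are
      # spatially coherent and its zero-activity neighbours are distant
      cs <- config$cluster_size
      if (sizes[k] >= cs) {
        m <- min(L, sizes[k], max(cs, cs * round(m / cs)))
      }
      starts <- seq(1L, L, by = cs)
      starts <- starts[starts <= L - m + 1L]
      if (!length(starts)) starts <- max(1L, L - m + 1L)
      start <- if (length(starts) == 1L) starts else sample(starts, 1)
      rank_order[start:(start + m - 1L)]
    }
    avail <- lengths(pool[sel_chroms])
    # one gene per selected chromosome, remainder spread uniformly,
    # capped by per-chromosome availability
    alloc <- rep(1L, m)
    rem <- sizes[k] - m
    while (rem > 0) {
      open <- which(alloc < avail)
      if (!length(open)) break
      take <- open[(seq_len(min(rem, length(open))) - 1L) %%
                     length(open) + 1L]
      add <- tabulate(take, nbins = m)
      alloc <- alloc + add
      rem <- rem - sum(add)
    }
    nets[[k]] <- unlist(lapply(seq_len(m), function(i) {
      sample(pool[[sel_chroms[i]]], min(alloc[i], avail[i]))
    }), use.names = FALSE)
  }
  names(nets) <- sprintf("TFN%03d", seq_len(config$n_networks))
  structure(nets, class = "network_catalog", sizes = lengths(nets))
}

#' @export
print.network_catalog <- function(x, ...) {
  sz <- lengths(x)
  cat(sprintf("<network_catalog> %d networks, sizes %d-%d (median %d)\n",
              length(x), min(sz), max(sz), as.integer(stats::median(sz))))
  invisible(x)
}

# ---- phantom paint stacks ---------------------------------------------------

blob_extent_ok <- function(b, bounds) {
  if (b$shape == "sphere") {
    all(c(b$cx - b$rx, b$cy - b$rx, b$cz - b$rx) >= 0) &&
      b$cx + b$rx <= bounds[1] && b$cy + b$rx <= bounds[2] &&
      b$cz + b$rx <= bounds[3]
  } else {
    all(c(b$cx - b$rx, b$cy - b$ry, b$cz - b$rz) >= 0) &&
      b$cx + b$rx <= bounds[1] && b$cy + b$ry <= bounds[2] &&
      b$cz + b$rz <= bounds[3]
  }
}

# analytic minimum surface gap between two blobs (micrometres)
blob_gap <- function(a, b) {
  dc <- abs(c(a$cx - b$cx, a$cy - b$cy, a$cz - b$cz))
  if (a$shape == "sphere" && b$shape == "sphere") {
    max(0, sqrt(sum(dc^2)) - a$rx - b$rx)
  } else if (a$shape == "cuboid" && b$shape == "cuboid") {
    g <- pmax(0, dc - (c(a$rx, a$ry, a$rz) + c(b$rx, b$ry, b$rz)))
    sqrt(sum(g^2))
  } else {
    s <- if (a$shape == "sphere") a else b
    q <- if (a$shape == "sphere") b else a
    g <- pmax(0, dc - c(q$rx, q$ry, q$rz))
    max(0, sqrt(sum(g^2)) - s$rx)
  }
}

#' Simulate a two-channel chromosome-paint phantom stack
#'
#' Builds a voxelised two-channel z-stack containing the given territory
#' blobs (spheres or axis-aligned cuboids, specified in micrometres) over a
#' uniform background, together with the analytic ground-truth minimum
#' surface gap for every cross-channel blob pairing.  Voxel centres sit at
#' `(i - 0.5) * spacing`.
#'
#' @param blobs tibble with columns `channel` (1 or 2), `shape`
#'   (`"sphere"`/`"cuboid"`), centre `cx, cy, cz` and extent `rx, ry, rz`
#'   (sphere radius in `rx`; cuboid half-widths) — all in micrometres.
#' @param dim stack dimensions in voxels, `c(nx, ny, nz)`.
#' @param spacing voxel spacing `c(dx, dy, dz)` in micrometres.
#' @param fg,bg foreground / background intensity levels.
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param seed optional seed for the noise.
#' @return A list of class `paint_sim`: `stacks` (list of two 3D arrays
#'   indexed `[x, y, z]`), `spacing`, `blobs`, and `ground_truth` — a tibble
#'   `(blob_a, blob_b, gap_um)` of analytic surface gaps for the four
#'   cross-channel pairings.
#' @export
simulate_paint_stack <- function(blobs, dim = c(64, 64, 32),
                                 spacing = c(0.2, 0.2, 0.5),
                                 fg = 100, bg = 10, noise_sd = 0,
                                 seed = NULL) {
  blobs <- as_tibble(blobs)
  need <- c("channel", "shape", "cx", "cy", "cz", "rx", "ry", "rz")
  miss <- setdiff(need, names(blobs))
  if (length(miss)) {
    abort(paste0("`blobs` missing columns: ", paste(miss, collapse = ", ")))
  }
  bounds <- dim * spacing
  for (i in seq_len(nrow(blobs))) {
    if (!blob_extent_ok(as.list(blobs[i, ]), bounds)) {
      abort(sprintf("blob %d extends outside the stack bounds.", i))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  xs <- (seq_len(dim[1]) - 0.5) * spacing[1]
  ys <- (seq_len(dim[2]) - 0.5) * spacing[2]
  zs <- (seq_len(dim[3]) - 0.5) * spacing[3]
  X <- array(rep(xs, times = dim[2] * dim[3]), dim = dim)
  Y <- array(rep(rep(ys, each = dim[1]), times = dim[3]), dim = dim)
  Z <- array(rep(zs, each = dim[1] * dim[2]), dim = dim)

  stacks <- lapply(1:2, function(ch) {
    mask <- array(FALSE, dim = dim)
    for (i in which(blobs$channel == ch)) {
      b <- as.list(blobs[i, ])
      inside <- if (b$shape == "sphere") {
        (X - b$cx)^2 + (Y - b$cy)^2 + (Z - b$cz)^2 <= b$rx^2
      } else {
        abs(X - b$cx) <= b$rx & abs(Y - b$cy) <= b$ry & abs(Z - b$cz) <= b$rz
      }
      mask <- mask | inside
    }
    img <- array(bg, dim = dim) + (fg - bg) * mask
    if (noise_sd > 0) img <- img + array(rnorm(prod(dim), 0, noise_sd), dim)
    img
  })

  ia <- which(blobs$channel == 1)
  ib <- which(blobs$channel == 2)
  gt <- tidyr::expand_grid(blob_a = ia, blob_b = ib)
  gt$gap_um <- purrr::map2_dbl(gt$blob_a, gt$blob_b, function(a, b) {
    blob_gap(as.list(blobs[a, ]), as.list(blobs[b, ]))
  })
  structure(
    list(stacks = stacks, spacing = spacing, blobs = blobs,
         ground_truth = gt),
    class = "paint_sim"
  )
}

#' Random spherical-territory phantom
#'
#' Convenience generator: two non-overlapping spheres per channel at random
#' positions inside the stack, for oracle tests of the interface-distance
#' pipeline.
#'
#' @inheritParams simulate_paint_stack
#' @param radius_range_um sphere radius range in micrometres.
#' @param seed integer seed.
#' @return A `paint_sim`, see [simulate_paint_stack()].
#' @export
random_paint_phantom <- function(dim = c(64, 64, 32),
                                 spacing = c(0.2, 0.2, 0.5),
                                 radius_range_um = c(0.8, 1.6),
                                 fg = 100, bg = 10, noise_sd = 0,
                                 seed = 1L) {
  set.seed(seed)
  bounds <- dim * spacing
  draw_channel <- function(ch) {
    repeat {
      r <- runif(2, radius_range_um[1], radius_range_um[2])
      ctr <- cbind(runif(2, r + spacing[1], bounds[1] - r - spacing[1]),
                   runif(2, r + spacing[2], bounds[2] - r - spacing[2]),
                   runif(2, r + spacing[3], bounds[3] - r - spacing[3]))
      gap <- sqrt(sum((ctr[1, ] - ctr[2, ])^2)) - sum(r)
      if (gap > 2 * max(spacing)) break  # same-channel homologues separable
    }
    tibble(channel = ch, shape = "sphere",
           cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
           rx = r, ry = r, rz = r)
  }
  blobs <- bind_rows(draw_channel(1L), draw_channel(2L))
  simulate_paint_stack(blobs, dim = dim, spacing = spacing, fg = fg, bg = bg,
                       noise_sd = noise_sd, seed = seed + 1L)
}
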