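#' Inter-chromosome physical distance (IPD) matrix
#'
#' Builds the IPD matrix from per-nucleus chromosome centroid coordinates.
#' For each nucleus and each chromosome pair, the distances between all
#' available homologue pairings (four when both homologues of both
#' chromosomes are present) are aggregated — their mean in `"mean"` mode, or
#' their minimum in `"min"` mode — and the per-nucleus values are then
#' averaged over every nucleus contributing both chromosomes.  Diagonal
#' entries hold the mean distance between the two homologues of each
#' chromosome; they are stored but flagged as excluded from correlation
#' analysis.
#'
#' @param coords data frame with columns `nucleus`, `chromosome`,
#'   `homologue` (1 or 2), `x`, `y`, `z` (coordinates in units of the
#'   nuclear radius).
#' @param mode `"mean"` (default) or `"min"` homologue-pairing aggregation.
#' @return A [dist_matrix()] with role `IPD_mean` or `IPD_min`, units
#'   `nuclear_radius`, `diag_excluded = TRUE`.  Attribute `n_nuclei` carries
#'   the per-pair count of contributing nuclei.
#' @export
#' @examples
#' sim <- simulate_nuclei(sim_config(n_nuclei = 6, n_chromosomes = 4))
#' compute_ipd(sim$coords)
compute_ipd <- function(coords, mode = c("mean", "min")) {
  mode <- match.arg(mode)
  coords <- as_tibble(coords)
  need <- c("nucleus", "chromosome", "homologue", "x", "y", "z")
  miss <- setdiff(need, names(coords))
  if (length(miss)) {
    abort(paste0("`coords` missing columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(coords) == 0) abort("`coords` is empty.")
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) abort("`coords` contains NaN/Inf coordinates.")
  key <- paste(coords$nucleus, coords$chromosome, coords$homologue)
  if (anyDuplicated(key)) {
    abort("duplicate (nucleus, chromosome, homologue) entries.")
  }
  nrm <- sqrt(rowSums(xyz^2))
  if (any(nrm > 1 + 1e-9)) {
    warn(sprintf("%d coordinates lie outside the unit nuclear radius.",
                 sum(nrm > 1 + 1e-9)))
  }

  labels <- unique(coords$chromosome)
  L <- length(labels)
  sums <- matrix(0, L, L)
  cnts <- matrix(0L, L, L)
  dsum <- numeric(L)
  dcnt <- integer(L)

  for (nuc in split(seq_len(nrow(coords)), coords$nucleus)) {
    ci <- match(coords$chromosome[nuc], labels)
    rows <- split(seq_along(nuc), ci)
    present <- as.integer(names(rows))
    D <- as.matrix(dist(xyz[nuc, , drop = FALSE]))
    np <- length(present)
    for (a in seq_len(np)) {
      ra <- rows[[a]]
      if (length(ra) == 2) {
        i <- present[a]
        dsum[i] <- dsum[i] + D[ra[1], ra[2]]
        dcnt[i] <- dcnt[i] + 1L
      }
      if (a < np) {
        for (b in (a + 1):np) {
          blk <- D[ra, rows[[b]], drop = FALSE]
          v <- if (mode == "mean") mean(blk) else min(blk)
          i <- present[a]; j <- present[b]
          sums[i, j] <- sums[i, j] + v
          cnts[i, j] <- cnts[i, j] + 1L
        }
      }
    }
  }

  ut <- upper.tri(sums)
  if (any(cnts[ut] == 0L)) {
    bad <- which(cnts == 0L & ut, arr.ind = TRUE)[1, ]
    abort(sprintf("no nucleus contributes both %s and %s.",
                  labels[bad[1]], labels[bad[2]]))
  }
  m <- matrix(0, L, L)
  m[ut] <- sums[ut] / cnts[ut]
  m <- m + t(m)
  diag(m) <- ifelse(dcnt > 0, dsum / pmax(dcnt, 1L), 0)
  out <- dist_matrix(m, labels = labels, units = "nuclear_radius",
                     role = if (mode == "mean") "IPD_mean" else "IPD_min",
                     diag_excluded = TRUE)
  attr(out, "n_nuclei") <- cnts + t(cnts)
  out
}

#' Inter-chromosome basepair-length difference (IBD) matrix
#'
#' `IBD[i, j] = |Chrbp(i) - Chrbp(j)|`, the absolute difference of the two
#' chromosomes' basepair lengths; a size control for the physical distance
#' matrices.
#'
#' @param annotation data frame with columns `chromosome` and `basepairs`.
#' @param labels optional label ordering; defaults to annotation order.
#' @return A [dist_matrix()] with role `IBD`, units `basepairs`.
#' @export
compute_ibd <- function(annotation, labels = NULL) {
  annotation <- as_tibble(annotation)
  if (!all(c("chromosome", "basepairs") %in% names(annotation))) {
    abort("`annotation` needs columns `chromosome`, `basepairs`.")
  }
  labels <- labels %||% annotation$chromosome
  idx <- match(labels, annotation$chromosome)
  if (anyNA(idx)) {
    abort(paste0("chromosomes missing from annotation: ",
                 paste(labels[is.na(idx)], collapse = ", ")))
  }
  bp <- annotation$basepairs[idx]
  if (any(bp <= 0)) abort("basepair lengths must be positive.")
  m <- abs(outer(bp, bp, "-"))
  dist_matrix(m, labels = labels, units = "basepairs", role = "IBD")
}

#' Cumulative row/column swap randomization of a matrix
#'
#' Randomizes a labelled symmetric matrix by repeatedly picking a uniform
#' random unordered label pair and exchanging the corresponding rows and
#' columns simultaneously, each swap acting on the previously swapped matrix.
#' The output is the input conjugated by a permutation, so the multiset of
#' entries — and the triangle inequality, when the input is metric — is
#' preserved; only chromosome identities are scrambled.
#'
#' @param m a [dist_matrix()].
#' @param n_swaps number of swaps (200 is ample for complete randomization
#'   of a 22-chromosome matrix).
#' @param seed optional integer seed.
#' @param cumulative kept for interface clarity: a single call always chains
#'   its swaps cumulatively; pass `cumulative = FALSE` to assert (it has no
#'   effect within one call, a fresh call restarts from `m`).
#' @return A list with `matrix` (the permuted [dist_matrix()]),
#'   `permutation` (integer vector `p` such that
#'   `out[k, l] == m[p[k], p[l]]`), and `swaps` (two-column matrix of the
#'   swapped label indices, in order).
#' @export
permute_matrix <- function(m, n_swaps, seed = NULL, cumulative = TRUE) {
  stopifnot(inherits(m, "dist_matrix"))
  if (n_swaps < 0) abort("`n_swaps` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  L <- length(m$labels)
  p <- seq_len(L)
  swaps <- matrix(0L, nrow = n_swaps, ncol = 2)
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(L, 2)
    p[ij] <- p[rev(ij)]
    swaps[s, ] <- ij
  }
  v <- m$values[p, p, drop = FALSE]
  out <- dist_matrix(v, labels = m$labels, units = m$units, role = m$role,
                     diag_excluded = m$diag_excluded)
  list(matrix = out, permutation = p, swaps = swaps)
}

#' Uniform random permutation conjugation
#'
#' Draws a single uniformly random relabelling of the matrix (the limiting
#' distribution of a long cumulative swap chain): rows and columns are
#' conjugated by one permutation drawn uniformly from the symmetric group.
#' Used for null ensembles and the permutation FDR.
#'
#' @param m a [dist_matrix()].
#' @param seed optional integer seed.
#' @return Same structure as [permute_matrix()], without `swaps`.
#' @export
random_conjugation <- function(m, seed = NULL) {
  stopifnot(inherits(m, "dist_matrix"))
  if (!is.null(seed)) set.seed(seed)
  p <- sample.int(length(m$labels))
  v <- m$values[p, p, drop = FALSE]
  list(
    matrix = dist_matrix(v, labels = m$labels, units = m$units,
                         role = m$role, diag_excluded = m$diag_excluded),
    permutation = p
  )
}
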