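#' Exponential adjacency matrix from an IPD matrix
#'
#' `A[i, j] = exp(-IPD[i, j] / lambda)`: a proximity weight in `(0, 1]` with
#' length scale `lambda` (a fraction of the nuclear radius).  The steep
#' exponential sharply distinguishes nearby chromosomes from distant ones.
#'
#' @param ipd a [dist_matrix()] of non-negative distances.
#' @param lambda distance parameter, `> 0`; 0.07 (7% of the nuclear radius)
#'   is the scale at which the coupling analysis is most sensitive.
#' @return A [dist_matrix()] with role `adjacency`.
#' @export
build_adjacency <- function(ipd, lambda = 0.07) {
  stopifnot(inherits(ipd, "dist_matrix"))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    abort("`lambda` must be a single positive number.")
  }
  if (any(ipd$values < 0)) abort("IPD values must be non-negative.")
  dist_matrix(exp(-ipd$values / lambda), labels = ipd$labels,
              units = "dimensionless", role = "adjacency",
              diag_excluded = ipd$diag_excluded)
}

#' Chromosome-by-network activity matrix
#'
#' For each transcription-factor network `f` and chromosome `i`,
#' `Phi[i, f]` is the natural logarithm of the integrated (summed) activity
#' of the network's genes found on that chromosome in the expression data;
#' chromosomes carrying no gene of the network get exactly zero.  Catalog
#' genes absent from the expression table are dropped (their count is
#' reported).
#'
#' @param genes per-gene activity table (columns `gene_id`, `chromosome`,
#'   `activity`, activities positive).
#' @param catalog a [simulate_networks()] catalog or any named list of
#'   gene-id vectors.
#' @param chromosomes label order for the rows; defaults to the unique
#'   chromosomes of `genes` in order of appearance.
#' @return An object of class `network_matrix`: list with `phi` (chromosomes
#'   x networks numeric matrix), `counts` (genes per cell), `n_dropped`
#'   (catalog genes absent from the table), `labels`, `networks`.
#' @export
build_network_matrix <- function(genes, catalog, chromosomes = NULL) {
  genes <- as_tibble(genes)
  if (!all(c("gene_id", "chromosome", "activity") %in% names(genes))) {
    abort("`genes` needs columns `gene_id`, `chromosome`, `activity`.")
  }
  if (any(genes$activity <= 0)) abort("activities must be positive.")
  if (!is.list(catalog) || is.null(names(catalog)) ||
      anyDuplicated(names(catalog))) {
    abort("`catalog` must be a uniquely named list of gene sets.")
  }
  chromosomes <- chromosomes %||% unique(genes$chromosome)
  L <- length(chromosomes)
  f_names <- names(catalog)
  phi <- matrix(0, L, length(catalog),
                dimnames = list(chromosomes, f_names))
  counts <- matrix(0L, L, length(catalog),
                   dimnames = list(chromosomes, f_names))
  chr_of <- setNames(match(genes$chromosome, chromosomes), genes$gene_id)
  act_of <- setNames(genes$activity, genes$gene_id)
  n_dropped <- 0L
  for (f in seq_along(catalog)) {
    ids <- intersect(catalog[[f]], genes$gene_id)
    n_dropped <- n_dropped + length(catalog[[f]]) - length(ids)
    if (!length(ids)) {
      warn(sprintf("network '%s' has no genes in the expression table.",
                   f_names[f]))
      next
    }
    tot <- tapply(act_of[ids], chr_of[ids], sum)
    rows <- as.integer(names(tot))
    phi[rows, f] <- log(as.numeric(tot))
    counts[rows, f] <- as.integer(table(chr_of[ids]))
  }
  if (n_dropped > 0) {
    inform(sprintf("%d catalog genes absent from the expression table.",
                   n_dropped))
  }
  structure(
    list(phi = phi, counts = counts, n_dropped = n_dropped,
         labels = chromosomes, networks = f_names),
    class = "network_matrix"
  )
}

#' @export
print.network_matrix <- function(x, ...) {
  cat(sprintf("<network_matrix> %d chromosomes x %d networks (%d genes dropped)\n",
              nrow(x$phi), ncol(x$phi), x$n_dropped))
  invisible(x)
}

as_phi <- function(phi) {
  if (inherits(phi, "network_matrix")) phi$phi else as.matrix(phi)
}

# S[i, j] = sum_f (phi[i, f] - phi[j, f])^2, with an exactly zero diagonal
phi_pair_sq <- function(phi) {
  phi <- as_phi(phi)
  G <- tcrossprod(phi)
  d <- diag(G)
  S <- outer(d, rep(1, length(d))) + outer(rep(1, length(d)), d) - 2 * G
  S[S < 0] <- 0
  diag(S) <- 0
  S
}

h_from_perm <- function(A, S, p) 0.5 * sum(A[p, p] * S)

#' Network-coupling energy H
#'
#' `H = sum_f sum_{i<j} A[i, j] * (Phi[i, f] - Phi[j, f])^2`: for every
#' unordered chromosome pair and every network, the squared difference in
#' network activity weighted by the pair's spatial adjacency.  `H` is low
#' when chromosomes that are close together carry similar network
#' activities, and zero exactly when every network's activity column is
#' constant across chromosomes.  Diagonal adjacency terms multiply a zero
#' squared difference and never contribute.
#'
#' @param adjacency an adjacency [dist_matrix()] (see [build_adjacency()]).
#' @param phi a [build_network_matrix()] result, or a plain chromosomes x
#'   networks matrix with matching row order.
#' @return A single non-negative number.
#' @export
compute_H <- function(adjacency, phi) {
  stopifnot(inherits(adjacency, "dist_matrix"))
  P <- as_phi(phi)
  if (nrow(P) != nrow(adjacency$values)) {
    abort("`phi` rows must match the adjacency dimension.")
  }
  if (inherits(phi, "network_matrix") &&
      !identical(phi$labels, adjacency$labels)) {
    abort("chromosome labels of `phi` and `adjacency` differ.")
  }
  S <- phi_pair_sq(P)
  h_from_perm(adjacency$values, S, seq_len(nrow(P)))
}

#' Energy randomization configuration
#'
#' @param lambda adjacency length scale used when a configuration also
#'   drives matrix construction (default 0.07).
#' @param n_iterations randomization iterations (default `1e4`).
#' @param mode `"cumulative"` — one long swap chain with H recorded after
#'   every swap — or `"independent"` — each iteration is a fresh matrix
#'   produced by 100 swaps from the original.
#' @param exclude_homologues zero the diagonal adjacency before
#'   randomization (bookkeeping only: diagonal terms never contribute to H).
#' @param seed optional integer seed.
#' @return A list of class `energy_config`.
#' @export
energy_config <- function(lambda = 0.07, n_iterations = 1e4,
                          mode = c("cumulative", "independent"),
                          exclude_homologues = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  if (lambda <= 0) abort("`lambda` must be positive.")
  if (n_iterations < 1) abort("`n_iterations` must be >= 1.")
  structure(list(lambda = lambda, n_iterations = as.integer(n_iterations),
                 mode = mode, exclude_homologues = exclude_homologues,
                 seed = seed),
            class = "energy_config")
}

#' Randomize the adjacency matrix and summarise the H distribution
#'
#' Randomizes chromosome positions by swapping rows and columns of the
#' adjacency matrix and records H at each of `n_iterations` steps — either
#' along one cumulative swap chain, or as independent matrices each produced
#' by 100 swaps from the original.  Summarises the recorded values as
#' `H_av`, `sigma`, the optimality deviate
#' `delta_H = (H_av - H_0) / sigma`, its two-sided Gaussian-tail p-value,
#' and the empirical fraction of randomized H values at or below `H_0`.
#' A large positive `delta_H` means random rearrangements almost always
#' increase H: the observed arrangement is near-optimal for the given
#' network activities.
#'
#' @inheritParams compute_H
#' @param config an [energy_config()].
#' @return An object of class `h_randomization`: list with `h0`,
#'   `trajectory` (numeric, length `n_iterations`), `h_av`, `sigma`,
#'   `delta_h`, `p_gaussian`, `p_empirical`, `mode`, `n_iterations`.
#'   With a degenerate constant `Phi` (`sigma = 0`), `delta_h` and the
#'   p-values are `NA`.
#' @export
randomize_H <- function(adjacency, phi, config = energy_config()) {
  stopifnot(inherits(adjacency, "dist_matrix"),
            inherits(config, "energy_config"))
  P <- as_phi(phi)
  S <- phi_pair_sq(P)
  A <- adjacency$values
  if (config$exclude_homologues) diag(A) <- 0
  L <- nrow(A)
  if (!is.null(config$seed)) set.seed(config$seed)
  h0 <- h_from_perm(A, S, seq_len(L))
  n <- config$n_iterations
  traj <- numeric(n)
  if (config$mode == "cumulative") {
    p <- seq_len(L)
    for (t in seq_len(n)) {
      ij <- sample.int(L, 2)
      p[ij] <- p[rev(ij)]
      traj[t] <- h_from_perm(A, S, p)
    }
  } else {
    for (t in seq_len(n)) {
      p <- seq_len(L)
      for (s in 1:100) {
        ij <- sample.int(L, 2)
        p[ij] <- p[rev(ij)]
      }
      traj[t] <- h_from_perm(A, S, p)
    }
  }
  h_av <- mean(traj)
  sigma <- sd(traj)
  delta_h <- if (sigma > 0) (h_av - h0) / sigma else NA_real_
  structure(
    list(h0 = h0, trajectory = traj, h_av = h_av, sigma = sigma,
         delta_h = delta_h,
         p_gaussian = if (is.na(delta_h)) NA_real_ else
           deviation_to_p(delta_h),
         p_empirical = if (sigma > 0) mean(traj <= h0) else NA_real_,
         mode = config$mode, n_iterations = n,
         exclude_homologues = config$exclude_homologues),
    class = "h_randomization"
  )
}

#' @export
print.h_randomization <- function(x, ...) {
  cat(sprintf(
    "<h_randomization> H0 = %.4g, H_av = %.4g, sigma = %.4g, delta_H = %.3f (p = %.3f)\n",
    x$h0, x$h_av, x$sigma, x$delta_h, x$p_gaussian))
  invisible(x)
}

#' @rdname randomize_H
#' @param x an `h_randomization`.
#' @param ... unused.
#' @method glance h_randomization
#' @export
glance.h_randomization <- function(x, ...) {
  tibble(h0 = x$h0, h_av = x$h_av, sigma = x$sigma, delta_h = x$delta_h,
         p_gaussian = x$p_gaussian, p_empirical = x$p_empirical,
         mode = x$mode, n_iterations = x$n_iterations)
}

#' @rdname randomize_H
#' @method tidy h_randomization
#' @export
tidy.h_randomization <- function(x, ...) {
  tibble(iteration = seq_along(x$trajectory), h = x$trajectory)
}

#' @rdname randomize_H
#' @param object an `h_randomization`.
#' @method autoplot h_randomization
#' @export
autoplot.h_randomization <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$iteration, .data$h)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$h0, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "randomization step", y = "H",
                  title = sprintf("delta_H = %.2f (p = %.3f)",
                                  object$delta_h, object$p_gaussian)) +
    ggplot2::theme_minimal()
}

#' Gaussian-tail p-value of an optimality deviate
#'
#' Maps `delta_H` — the number of standard deviations by which the observed
#' H lies below the randomized mean — to a two-sided normal tail
#' probability, `2 * (1 - pnorm(delta_H))`, clipped to `[0, 1]`.  A deviate
#' of 1.97 maps to 0.049, i.e. the 5% significance edge.
#'
#' @param delta_h numeric vector of deviates.
#' @return p-values in `[0, 1]`.
#' @export
#' @examples
#' round(deviation_to_p(c(1.97, 1.02, 0.71)), 2)
deviation_to_p <- function(delta_h) {
  if (any(!is.finite(delta_h))) abort("`delta_h` must be finite.")
  pmin(pmax(2 * (1 - pnorm(delta_h)), 0), 1)
}

#' Scan the adjacency length scale
#'
#' For each candidate `lambda`, builds the adjacency matrix, runs
#' [randomize_H()] (typically with reduced iterations) and records the
#' optimality deviate `delta_H = (H_av - H_0) / sigma`.  The returned argmax
#' is the length scale at which randomization degrades the observed
#' arrangement the most — the scale where positional/transcriptional
#' coupling is sharpest.
#'
#' @inheritParams build_adjacency
#' @param phi network activity matrix (see [build_network_matrix()]).
#' @param lambda_grid candidate length scales (default 2% to 80% of the
#'   nuclear radius in 1% steps).
#' @param n_iterations randomization iterations per grid point (default
#'   200; the deviate stabilises quickly).
#' @param mode,seed passed to [energy_config()].
#' @return An object of class `lambda_scan`: tibble `(lambda, delta_h, h0,
#'   h_av, sigma)` with attributes `lambda_opt` and `delta_h_max`.
#' @export
scan_lambda <- function(ipd, phi, lambda_grid = seq(0.02, 0.80, by = 0.01),
                        n_iterations = 200, mode = "cumulative",
                        seed = NULL) {
  if (any(lambda_grid <= 0)) abort("grid values must be positive.")
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map(lambda_grid, function(lam) {
    adj <- build_adjacency(ipd, lam)
    rz <- randomize_H(adj, phi,
                      energy_config(lambda = lam,
                                    n_iterations = n_iterations,
                                    mode = mode))
    tibble(lambda = lam, delta_h = rz$delta_h, h0 = rz$h0,
           h_av = rz$h_av, sigma = rz$sigma)
  })
  out <- bind_rows(rows)
  finite <- which(is.finite(out$delta_h))
  if (!length(finite)) abort("delta_H degenerate over the whole grid.")
  best <- finite[which.max(out$delta_h[finite])]
  attr(out, "lambda_opt") <- out$lambda[best]
  attr(out, "delta_h_max") <- out$delta_h[best]
  class(out) <- c("lambda_scan", class(out))
  out
}

#' @rdname scan_lambda
#' @param x a `lambda_scan`.
#' @param ... unused.
#' @method glance lambda_scan
#' @export
glance.lambda_scan <- function(x, ...) {
  tibble(lambda_opt = attr(x, "lambda_opt"),
         delta_h_max = attr(x, "delta_h_max"),
         n_lambda = nrow(x))
}

#' @rdname scan_lambda
#' @param object a `lambda_scan`.
#' @method autoplot lambda_scan
#' @export
autoplot.lambda_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lambda, .data$delta_h)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "lambda_opt"),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "lambda (fraction of nuclear radius)",
                  y = "(H_av - H0) / sigma") +
    ggplot2::theme_minimal()
}

#' Per-network sensitivity to positional randomization
#'
#' Runs the H randomization for each network separately (using only that
#' network's activity column) for `n_steps` swaps, averaged over `reps`
#' chains, and reports the relative change
#' `delta_h_rel = (mean H after n_steps - H_0) / H_0` together with its
#' correlation against network size.  Small, chromosomally clustered
#' networks respond most strongly to positional randomization.
#'
#' @inheritParams compute_H
#' @param n_steps swaps per chain (default 200, where most of the H rise
#'   happens).
#' @param reps chains per network (default 20).
#' @param seed optional integer seed.
#' @return An object of class `network_sensitivity`: tibble `(network, h0,
#'   delta_h_rel, n_genes)` with attributes `pcc_size` (Pearson),
#'   `rank_cor_size` (Spearman) and `frac_positive` (fraction of networks
#'   with a positive relative change).  Networks with `H_0 = 0` get `NA`.
#' @export
per_network_sensitivity <- function(adjacency, phi, n_steps = 200,
                                    reps = 20, seed = NULL) {
  stopifnot(inherits(phi, "network_matrix"))
  A <- adjacency$values
  L <- nrow(A)
  if (!is.null(seed)) set.seed(seed)
  n_genes <- colSums(phi$counts)
  res <- purrr::map(seq_along(phi$networks), function(f) {
    S <- phi_pair_sq(phi$phi[, f, drop = FALSE])
    h0 <- h_from_perm(A, S, seq_len(L))
    if (h0 == 0) {
      return(tibble(network = phi$networks[f], h0 = 0,
                    delta_h_rel = NA_real_, n_genes = n_genes[f]))
    }
    h_end <- vapply(seq_len(reps), function(r) {
      p <- seq_len(L)
      for (s in seq_len(n_steps)) {
        ij <- sample.int(L, 2)
        p[ij] <- p[rev(ij)]
      }
      h_from_perm(A, S, p)
    }, numeric(1))
    tibble(network = phi$networks[f], h0 = h0,
           delta_h_rel = (mean(h_end) - h0) / h0, n_genes = n_genes[f])
  })
  out <- bind_rows(res)
  ok <- is.finite(out$delta_h_rel)
  attr(out, "pcc_size") <- if (sum(ok) > 2)
    cor(out$delta_h_rel[ok], out$n_genes[ok]) else NA_real_
  attr(out, "rank_cor_size") <- if (sum(ok) > 2)
    cor(out$delta_h_rel[ok], out$n_genes[ok], method = "spearman") else
      NA_real_
  attr(out, "frac_positive") <- mean(out$delta_h_rel[ok] > 0)
  class(out) <- c("network_sensitivity", class(out))
  out
}

#' @rdname per_network_sensitivity
#' @param x a `network_sensitivity`.
#' @param ... unused.
#' @method glance network_sensitivity
#' @export
glance.network_sensitivity <- function(x, ...) {
  tibble(pcc_size = attr(x, "pcc_size"),
         rank_cor_size = attr(x, "rank_cor_size"),
         frac_positive = attr(x, "frac_positive"),
         n_networks = nrow(x))
}

#' Chromosome occupancy of each network
#'
#' The fraction of chromosomes carrying at least one gene of the network.
#'
#' @param catalog a named list of gene sets (see [simulate_networks()]), or
#'   a [build_network_matrix()] result (in which case `genes` and
#'   `n_chromosomes` are taken from it).
#' @param genes per-gene table with `gene_id`, `chromosome`; ignored when
#'   `catalog` is a `network_matrix`.
#' @param n_chromosomes total chromosome count; defaults to the number of
#'   distinct chromosomes in `genes`.
#' @return A tibble `(network, occupancy, n_genes)`.
#' @export
network_occupancy <- function(catalog, genes = NULL, n_chromosomes = NULL) {
  if (inherits(catalog, "network_matrix")) {
    hit <- colSums(catalog$counts > 0)
    return(tibble(network = catalog$networks,
                  occupancy = hit / nrow(catalog$counts),
                  n_genes = colSums(catalog$counts)))
  }
  genes <- as_tibble(genes)
  n_chromosomes <- n_chromosomes %||% length(unique(genes$chromosome))
  chr_of <- setNames(genes$chromosome, genes$gene_id)
  tibble(
    network = names(catalog),
    occupancy = vapply(catalog, function(ids) {
      length(unique(chr_of[intersect(ids, names(chr_of))])) / n_chromosomes
    }, numeric(1)),
    n_genes = vapply(catalog, function(ids) {
      length(intersect(ids, names(chr_of)))
    }, numeric(1))
  )
}

#' Networks associated with each chromosome
#'
#' Counts, per chromosome, the networks with at least one gene there, and
#' correlates the counts with chromosome basepair length and annotated gene
#' count.
#'
#' @inheritParams network_occupancy
#' @param annotation table with `chromosome`, `basepairs`, `gene_count`.
#' @return A tibble `(chromosome, n_networks)` with attributes
#'   `pcc_basepairs` and `pcc_gene_count` (`NA` with zero variance).
#' @export
networks_per_chromosome <- function(catalog, genes, annotation) {
  genes <- as_tibble(genes)
  annotation <- as_tibble(annotation)
  chr_of <- setNames(genes$chromosome, genes$gene_id)
  hits <- lapply(catalog, function(ids) {
    unique(chr_of[intersect(ids, names(chr_of))])
  })
  counts <- vapply(annotation$chromosome, function(ch) {
    sum(vapply(hits, function(h) ch %in% h, logical(1)))
  }, numeric(1))
  out <- tibble(chromosome = annotation$chromosome, n_networks = counts)
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  }
  attr(out, "pcc_basepairs") <-
    if ("basepairs" %in% names(annotation))
      safe_cor(counts, annotation$basepairs) else NA_real_
  attr(out, "pcc_gene_count") <-
    if ("gene_count" %in% names(annotation))
      safe_cor(counts, annotation$gene_count) else NA_real_
  out
}
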