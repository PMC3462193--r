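#' Off-diagonal vector of a symmetric matrix
#'
#' Extracts the upper-triangle (i < j) values in fixed label order.  Diagonal
#' entries — homologue distances in IPD matrices — are never included, as
#' they carry no inter-chromosome information.
#'
#' @param m a [dist_matrix()].
#' @return Numeric vector of length `L * (L - 1) / 2`.
#' @export
offdiag_vector <- function(m) {
  stopifnot(inherits(m, "dist_matrix"))
  m$values[upper.tri(m$values)]
}

#' Correlate two labelled matrices
#'
#' Pearson correlation and least-squares regression (m2 on m1) over the
#' aligned off-diagonal upper triangles of two matrices.
#'
#' @param m1,m2 [dist_matrix()] objects with equal label sets (or pass
#'   `intersect = TRUE` to subset to the shared labels).
#' @param intersect subset both matrices to their common labels.
#' @return An object of class `matrix_cor`: list with `pcc`, `slope`,
#'   `intercept`, `n_pairs`, `labels`, and the paired off-diagonal vectors
#'   `x` (m1) and `y` (m2).
#' @export
#' @examples
#' a <- dist_matrix(abs(outer(1:4, 1:4, "-")))
#' b <- dist_matrix(2 * abs(outer(1:4, 1:4, "-")) + 1 -
#'                  diag(1, 4))
#' glance(correlate_matrices(a, b))
correlate_matrices <- function(m1, m2, intersect = FALSE) {
  al <- align_matrices(m1, m2, intersect = intersect)
  x <- offdiag_vector(al$m1)
  y <- offdiag_vector(al$m2)
  if (length(x) < 3) abort("need at least 3 chromosome pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in one of the off-diagonal vectors.")
  }
  slope <- cov(x, y) / var(x)
  structure(
    list(pcc = cor(x, y), slope = slope,
         intercept = mean(y) - slope * mean(x),
         n_pairs = length(x), labels = al$m1$labels, x = x, y = y),
    class = "matrix_cor"
  )
}

#' @export
print.matrix_cor <- function(x, ...) {
  cat(sprintf("<matrix_cor> PCC = %.3f, slope = %.3f, n_pairs = %d\n",
              x$pcc, x$slope, x$n_pairs))
  invisible(x)
}

#' @rdname correlate_matrices
#' @param x a `matrix_cor`.
#' @param ... unused.
#' @method glance matrix_cor
#' @export
glance.matrix_cor <- function(x, ...) {
  tibble(pcc = x$pcc, slope = x$slope, intercept = x$intercept,
         n_pairs = x$n_pairs)
}

#' @rdname correlate_matrices
#' @method tidy matrix_cor
#' @export
tidy.matrix_cor <- function(x, ...) {
  tibble(term = c("pcc", "slope", "intercept"),
         estimate = c(x$pcc, x$slope, x$intercept))
}

#' @rdname correlate_matrices
#' @param object a `matrix_cor`.
#' @method autoplot matrix_cor
#' @export
autoplot.matrix_cor <- function(object, ...) {
  df <- tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept, colour = "red") +
    ggplot2::labs(
      x = "matrix 1 (off-diagonal)", y = "matrix 2 (off-diagonal)",
      title = sprintf("PCC = %.3f, slope = %.3f", object$pcc, object$slope)) +
    ggplot2::theme_minimal()
}

# all L! permutations of 1..L as a matrix (rows); L <= 8 intended
all_permutations <- function(L) {
  if (L == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(L - 1L)
  out <- matrix(0L, nrow(sub) * L, L)
  r <- 1L
  for (pos in seq_len(L)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], L,
                   sub[, seq(pos, L - 1L)[seq_len(L - pos)], drop = FALSE])
    out[r:(r + nrow(sub) - 1L), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# PCCs between conjugations of M and a fixed matrix O, over off-diagonals.
# The off-diagonal multiset of a conjugated matrix is invariant, so its mean
# and SD are computed once; each permutation costs one elementwise product.
null_pcc_engine <- function(M, O, perms) {
  n <- nrow(M)
  xo <- M[upper.tri(M)]
  yo <- O[upper.tri(O)]
  np <- length(xo)
  mx <- mean(xo); sx <- sd(xo)
  my <- mean(yo); sy <- sd(yo)
  O0 <- O
  diag(O0) <- 0
  vapply(seq_len(nrow(perms)), function(k) {
    p <- perms[k, ]
    cross <- 0.5 * sum(M[p, p] * O0)
    (cross - np * mx * my) / ((np - 1) * sx * sy)
  }, numeric(1))
}

#' Permutation false discovery rate for a matrix correlation
#'
#' Estimates the significance of an observed matrix correlation `PCC_0`
#' against the null of random chromosome identities: one of the matrices is
#' conjugated by random label permutations (rows and columns permuted
#' together), each permuted matrix is correlated with the other, and the FDR
#' is the fraction of permutations with `PCC > PCC_0` (strict inequality;
#' ties count as non-discoveries).
#'
#' @inheritParams correlate_matrices
#' @param n_perm number of random permutations (default `1e5`).
#' @param seed optional integer seed.
#' @param randomize which matrix to permute: `"first"` (default) or
#'   `"second"`.
#' @param exhaustive enumerate all `L!` permutations instead of sampling
#'   (feasible for up to ~8 labels); `n_perm` is ignored.
#' @return An object of class `matrix_fdr`: list with `pcc0`, `fdr`,
#'   `n_perm`, `null_mean`, `null_sd`, `null_pcc` (the null sample),
#'   `exhaustive`, plus the underlying `matrix_cor` as `$observed`.
#' @export
permutation_fdr <- function(m1, m2, n_perm = 1e5, seed = NULL,
                            randomize = c("first", "second"),
                            exhaustive = FALSE, intersect = FALSE) {
  randomize <- match.arg(randomize)
  obs <- correlate_matrices(m1, m2, intersect = intersect)
  al <- align_matrices(m1, m2, intersect = intersect)
  M <- if (randomize == "first") al$m1$values else al$m2$values
  O <- if (randomize == "first") al$m2$values else al$m1$values
  L <- nrow(M)
  if (exhaustive) {
    if (L > 8) abort("exhaustive enumeration limited to 8 labels.")
    perms <- all_permutations(L)
  } else {
    if (n_perm < 1) abort("`n_perm` must be >= 1.")
    if (!is.null(seed)) set.seed(seed)
    perms <- t(vapply(seq_len(n_perm), function(k) sample.int(L),
                      integer(L)))
  }
  null_pcc <- null_pcc_engine(M, O, perms)
  structure(
    list(pcc0 = obs$pcc, fdr = mean(null_pcc > obs$pcc),
         n_perm = nrow(perms), null_mean = mean(null_pcc),
         null_sd = sd(null_pcc), null_pcc = null_pcc,
         exhaustive = exhaustive, randomize = randomize, observed = obs),
    class = "matrix_fdr"
  )
}

#' @export
print.matrix_fdr <- function(x, ...) {
  cat(sprintf(
    "<matrix_fdr> PCC0 = %.3f, FDR = %.4g (%d permutations%s), null %.3f +/- %.3f\n",
    x$pcc0, x$fdr, x$n_perm, if (x$exhaustive) ", exhaustive" else "",
    x$null_mean, x$null_sd))
  invisible(x)
}

#' @rdname permutation_fdr
#' @param x a `matrix_fdr`.
#' @param ... unused.
#' @method glance matrix_fdr
#' @export
glance.matrix_fdr <- function(x, ...) {
  tibble(pcc0 = x$pcc0, fdr = x$fdr, n_perm = x$n_perm,
         null_mean = x$null_mean, null_sd = x$null_sd,
         exhaustive = x$exhaustive)
}

#' @rdname permutation_fdr
#' @method tidy matrix_fdr
#' @export
tidy.matrix_fdr <- function(x, ...) {
  tibble(pcc_null = x$null_pcc)
}

#' @rdname permutation_fdr
#' @param object a `matrix_fdr`.
#' @method autoplot matrix_fdr
#' @export
autoplot.matrix_fdr <- function(object, ...) {
  ggplot2::ggplot(tibble(pcc = object$null_pcc),
                  ggplot2::aes(.data$pcc)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$pcc0, colour = "red") +
    ggplot2::labs(x = "null PCC", y = "count",
                  title = sprintf("FDR = %.4g (PCC0 = %.3f)",
                                  object$fdr, object$pcc0)) +
    ggplot2::theme_minimal()
}

#' Correlation decay under cumulative swap randomization
#'
#' Tracks the Pearson correlation between a reference matrix and a
#' progressively swap-randomized copy of `m`: for each rep a fresh cumulative
#' swap chain is run and the PCC to `reference` recorded after every swap.
#' On structured matrices the curve decays from `PCC(reference, m)` at zero
#' swaps to the uniform-permutation null level within a few tens of swaps.
#'
#' @param m [dist_matrix()] to randomize.
#' @param reference [dist_matrix()] held fixed.
#' @param max_swaps chain length (default 200).
#' @param reps independent chains averaged (default 20).
#' @param seed optional integer seed.
#' @return An object of class `decay_curve`: tibble `(swaps, pcc_mean,
#'   pcc_se)` for swap counts `0..max_swaps`.
#' @export
randomization_decay <- function(m, reference, max_swaps = 200, reps = 20,
                                seed = NULL) {
  al <- align_matrices(m, reference)
  M <- al$m1$values
  O <- al$m2$values
  L <- nrow(M)
  if (!is.null(seed)) set.seed(seed)
  xo <- M[upper.tri(M)]
  yo <- O[upper.tri(O)]
  np <- length(xo)
  denom <- (np - 1) * sd(xo) * sd(yo)
  base <- np * mean(xo) * mean(yo)
  O0 <- O
  diag(O0) <- 0
  traj <- matrix(0, nrow = reps, ncol = max_swaps + 1)
  for (r in seq_len(reps)) {
    p <- seq_len(L)
    traj[r, 1] <- (0.5 * sum(M[p, p] * O0) - base) / denom
    for (s in seq_len(max_swaps)) {
      ij <- sample.int(L, 2)
      p[ij] <- p[rev(ij)]
      traj[r, s + 1] <- (0.5 * sum(M[p, p] * O0) - base) / denom
    }
  }
  out <- tibble(
    swaps = 0:max_swaps,
    pcc_mean = colMeans(traj),
    pcc_se = apply(traj, 2, sd) / sqrt(reps)
  )
  class(out) <- c("decay_curve", class(out))
  out
}

#' @rdname randomization_decay
#' @param object a `decay_curve`.
#' @param ... unused.
#' @method autoplot decay_curve
#' @export
autoplot.decay_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$swaps, .data$pcc_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$pcc_mean - 2 * .data$pcc_se,
      ymax = .data$pcc_mean + 2 * .data$pcc_se), fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cumulative swaps", y = "PCC to reference") +
    ggplot2::theme_minimal()
}
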