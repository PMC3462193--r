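#' Labelled symmetric distance matrix
#'
#' Shared container for the square, symmetric, chromosome-labelled matrices
#' the pipeline manipulates: inter-chromosome physical distances (IPD, in
#' units of the nuclear radius), activity distances (IAD, absolute
#' differences of log mean chromosomal expression), basepair-length
#' differences (IBD) and exponential adjacency weights.
#'
#' The diagonal of an IPD matrix holds the mean distance between the two
#' homologues of each chromosome.  Diagonal values are retained for
#' inspection but flagged with `diag_excluded = TRUE`, and every correlation
#' routine in the package honours that flag by working on the off-diagonal
#' upper triangle only.
#'
#' @param values square numeric matrix, exactly symmetric, all finite.
#' @param labels character vector of row/column labels (chromosome names).
#'   Defaults to the matrix dimnames.
#' @param units one of `"nuclear_radius"`, `"log_activity"`, `"basepairs"`,
#'   `"micrometre"`, `"dimensionless"`.
#' @param role one of `"IPD_mean"`, `"IPD_min"`, `"IAD"`, `"IBD"`,
#'   `"adjacency"`, `"other"`.
#' @param diag_excluded logical; `TRUE` marks the diagonal as not to be used
#'   in correlation analyses.
#'
#' @return An object of class `dist_matrix`.
#' @export
#' @examples
#' m <- dist_matrix(matrix(c(0, 1, 1, 0), 2), labels = c("chr1", "chr2"))
#' tidy(m)
dist_matrix <- function(values,
                        labels = rownames(values),
                        units = c("dimensionless", "nuclear_radius",
                                  "log_activity", "basepairs", "micrometre"),
                        role = c("other", "IPD_mean", "IPD_min", "IAD",
                                 "IBD", "adjacency"),
                        diag_excluded = FALSE) {
  units <- match.arg(units)
  role <- match.arg(role)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    abort("`values` must be a square matrix.")
  }
  if (any(!is.finite(values))) {
    abort("`values` must be entirely finite.")
  }
  if (max(abs(values - t(values))) != 0) {
    abort("`values` must be exactly symmetric.")
  }
  if (is.null(labels)) {
    labels <- paste0("item", seq_len(nrow(values)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(values) || anyDuplicated(labels)) {
    abort("`labels` must be unique and match the matrix dimension.")
  }
  off <- values[upper.tri(values)]
  if (role %in% c("IPD_mean", "IPD_min", "IAD", "IBD") && any(off < 0)) {
    abort("distance-role matrices must have non-negative off-diagonal values.")
  }
  if (role == "adjacency" && (any(values <= 0) || any(values > 1))) {
    abort("adjacency values must lie in (0, 1].")
  }
  dimnames(values) <- list(labels, labels)
  structure(
    list(values = values, labels = labels, units = units, role = role,
         diag_excluded = diag_excluded),
    class = "dist_matrix"
  )
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$values

#' @export
dim.dist_matrix <- function(x) dim(x$values)

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d x %d  role=%s  units=%s%s\n",
              nrow(x$values), ncol(x$values), x$role, x$units,
              if (x$diag_excluded) "  (diagonal excluded)" else ""))
  print(round(x$values, 4))
  invisible(x)
}

#' Labels of a distance matrix
#' @param m a [dist_matrix()].
#' @return Character vector of chromosome labels.
#' @export
dm_labels <- function(m) {
  stopifnot(inherits(m, "dist_matrix"))
  m$labels
}

#' Subset a distance matrix by label
#'
#' @param m a [dist_matrix()].
#' @param labels labels to keep, in the order given.
#' @return A `dist_matrix` restricted to `labels`.
#' @export
dm_subset <- function(m, labels) {
  stopifnot(inherits(m, "dist_matrix"))
  missing <- setdiff(labels, m$labels)
  if (length(missing)) {
    abort(paste0("labels not present in matrix: ",
                 paste(missing, collapse = ", ")))
  }
  dist_matrix(m$values[labels, labels, drop = FALSE], labels = labels,
              units = m$units, role = m$role, diag_excluded = m$diag_excluded)
}

#' Tidy a distance matrix into a pair table
#'
#' @param x a [dist_matrix()].
#' @param include_diagonal return the diagonal (homologue) entries too.
#' @param ... unused.
#' @return A tibble with columns `chrom_a`, `chrom_b`, `value`; one row per
#'   unordered pair (upper triangle, in label order).
#' @method tidy dist_matrix
#' @export
tidy.dist_matrix <- function(x, include_diagonal = FALSE, ...) {
  v <- x$values
  ut <- upper.tri(v, diag = include_diagonal && !x$diag_excluded)
  if (include_diagonal && x$diag_excluded) {
    ut <- upper.tri(v, diag = TRUE)
  }
  idx <- which(ut, arr.ind = TRUE)
  tibble(
    chrom_a = x$labels[idx[, 1]],
    chrom_b = x$labels[idx[, 2]],
    value = v[ut]
  )
}

#' Heatmap of a distance matrix
#'
#' @param object a [dist_matrix()].
#' @param ... unused.
#' @return A ggplot heatmap with warmer colours for larger values.
#' @method autoplot dist_matrix
#' @export
autoplot.dist_matrix <- function(object, ...) {
  df <- as_tibble(as.data.frame(as.table(object$values)))
  names(df) <- c("chrom_a", "chrom_b", "value")
  df$chrom_a <- factor(df$chrom_a, levels = object$labels)
  df$chrom_b <- factor(df$chrom_b, levels = rev(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$chrom_a, .data$chrom_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "plasma", name = object$units) +
    ggplot2::labs(x = NULL, y = NULL, title = object$role) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

# align two matrices on a common label set; error unless intersect = TRUE
align_matrices <- function(m1, m2, intersect = FALSE) {
  stopifnot(inherits(m1, "dist_matrix"), inherits(m2, "dist_matrix"))
  if (identical(m1$labels, m2$labels)) {
    return(list(m1 = m1, m2 = m2))
  }
  common <- intersect(m1$labels, m2$labels)
  if (!intersect &&
      !(setequal(m1$labels, m2$labels))) {
    abort(paste0(
      "matrix labels differ; pass `intersect = TRUE` to use the ",
      length(common), " shared labels."))
  }
  if (length(common) < 3) {
    abort("fewer than 3 shared labels after alignment.")
  }
  list(m1 = dm_subset(m1, common), m2 = dm_subset(m2, common))
}
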