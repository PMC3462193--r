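#' Read / write pipeline file formats
#'
#' Plain-text interchange formats used throughout the pipeline:
#' * coordinates TSV — columns `nucleus`, `chromosome`, `homologue`,
#'   `x`, `y`, `z`;
#' * expression TSV — columns `probe_id`, `gene_id`, `chromosome`,
#'   `replicate`, `intensity`;
#' * annotation TSV — columns `chromosome`, `basepairs`, `gene_count`;
#' * labelled matrix TSV — full square matrix, first row and first column
#'   carry the chromosome labels;
#' * GMT — one gene set per line: name, description, then member genes,
#'   tab-separated.
#'
#' @param path file path.
#' @param x object to write.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_coordinates_tsv <- function(path) {
  t <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("nucleus", "chromosome", "homologue", "x", "y", "z")
  miss <- setdiff(need, names(t))
  if (length(miss)) {
    abort(paste0(path, ": missing columns ", paste(miss, collapse = ", ")))
  }
  t
}

#' @rdname pipeline_io
#' @export
write_coordinates_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_expression_tsv <- function(path) {
  check_expression_table(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname pipeline_io
#' @export
write_expression_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_annotation_tsv <- function(path) {
  t <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("chromosome", "basepairs", "gene_count"), names(t))
  if (length(miss)) {
    abort(paste0(path, ": missing columns ", paste(miss, collapse = ", ")))
  }
  t
}

#' @rdname pipeline_io
#' @param units,role,diag_excluded metadata for the reconstructed
#'   [dist_matrix()].
#' @export
read_matrix_tsv <- function(path, units = "dimensionless", role = "other",
                            diag_excluded = FALSE) {
  raw <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(raw)
  if (!identical(rownames(m), colnames(m))) {
    abort(paste0(path, ": row and column labels differ."))
  }
  asym <- max(abs(m - t(m)))
  if (asym > 0) {
    idx <- which(abs(m - t(m)) == asym, arr.ind = TRUE)[1, ]
    abort(sprintf("%s: asymmetric matrix (max |M - t(M)| = %g at %s/%s).",
                  path, asym, rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  dist_matrix(m, labels = rownames(m), units = units, role = role,
              diag_excluded = diag_excluded)
}

#' @rdname pipeline_io
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "dist_matrix"))
  df <- as.data.frame(x$values)
  df <- cbind(chromosome = x$labels, df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(sprintf("%s: line %d has fewer than 3 fields.", path, bad[1]))
  }
  nms <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nms)) {
    abort(sprintf("%s: duplicate network name '%s'.", path,
                  nms[duplicated(nms)][1]))
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nms
  structure(sets, class = "network_catalog", sizes = lengths(sets))
}

#' @rdname pipeline_io
#' @param descriptions optional per-set description column.
#' @export
write_gmt <- function(x, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(x))
  lines <- vapply(seq_along(x), function(i) {
    paste(c(names(x)[i], descriptions[i], x[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @details TIFF stacks are written one z-section per page, intensities
#'   rescaled to `[0, 1]` by the stack maximum and stored as 16-bit; the
#'   absolute intensity scale is not preserved (the mean + SD threshold is
#'   invariant to it).
#' @export
write_stack_tiff <- function(x, path) {
  stopifnot(is.array(x), length(dim(x)) == 3)
  mx <- max(x)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  out <- array(0, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) out[, , k] <- pages[[k]]
  out
}
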