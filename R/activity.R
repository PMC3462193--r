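#' Normalize probe intensities to the array mean
#'
#' Divides every probe intensity by the arithmetic mean of all probe
#' intensities in its array (replicate), so each array has post-normalization
#' mean exactly 1.  This removes global intensity differences between arrays
#' from different cell types before activities are compared.
#'
#' @param t probe-level table with columns `probe_id`, `gene_id`,
#'   `chromosome`, `replicate`, `intensity` (strictly positive).
#' @return The same tibble with `intensity` rescaled per replicate.
#' @export
#' @examples
#' t <- tibble::tibble(probe_id = c("p1", "p2", "p3"), gene_id = "g",
#'                     chromosome = "chr1", replicate = 1,
#'                     intensity = c(1, 2, 3))
#' normalize_to_array_mean(t)$intensity  # 0.5 1.0 1.5
normalize_to_array_mean <- function(t) {
  t <- check_expression_table(t)
  t %>%
    group_by(.data$replicate) %>%
    mutate(intensity = .data$intensity / mean(.data$intensity)) %>%
    ungroup()
}

check_expression_table <- function(t) {
  t <- as_tibble(t)
  need <- c("probe_id", "gene_id", "chromosome", "replicate", "intensity")
  miss <- setdiff(need, names(t))
  if (length(miss)) {
    abort(paste0("expression table missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(t$intensity)) || any(t$intensity <= 0)) {
    abort("intensities must be strictly positive and finite.")
  }
  chr_per_gene <- tapply(t$chromosome, t$gene_id,
                         function(ch) length(unique(ch)))
  if (any(chr_per_gene > 1)) {
    abort("each gene must map to exactly one chromosome.")
  }
  t
}

is_array_normalized <- function(t, tol = 1e-8) {
  means <- tapply(t$intensity, t$replicate, mean)
  all(abs(means - 1) < tol)
}

#' Aggregate probes to per-gene activities
#'
#' Collapses the probe-level table to one activity per gene: first the mean
#' over replicates for each probe, then the mean over a gene's probes.  The
#' table is expected to be array-mean normalized first (see
#' [normalize_to_array_mean()]); pass `allow_unnormalized = TRUE` to
#' aggregate raw intensities deliberately.
#'
#' @inheritParams normalize_to_array_mean
#' @param allow_unnormalized skip the normalization check (logged).
#' @return A tibble `(gene_id, chromosome, activity, n_probes)`.
#' @export
aggregate_probes <- function(t, allow_unnormalized = FALSE) {
  t <- check_expression_table(t)
  if (!is_array_normalized(t)) {
    if (allow_unnormalized) {
      inform("aggregating un-normalized intensities (explicitly allowed).")
    } else {
      abort(paste0(
        "table is not array-mean normalized; call normalize_to_array_mean() ",
        "first or pass allow_unnormalized = TRUE."))
    }
  }
  t %>%
    group_by(.data$gene_id, .data$chromosome, .data$probe_id) %>%
    summarise(probe_activity = mean(.data$intensity), .groups = "drop") %>%
    group_by(.data$gene_id, .data$chromosome) %>%
    summarise(activity = mean(.data$probe_activity),
              n_probes = dplyr::n(), .groups = "drop") %>%
    arrange(.data$chromosome, .data$gene_id)
}

#' Mean chromosome activity
#'
#' Computes each chromosome's mean activity as the total activity of its
#' observed genes divided by the *annotated* gene count `N` of the
#' chromosome — not by the number of genes observed, and not by the
#' chromosome's basepair length — together with its natural logarithm.
#' Chromosomes with annotated genes but no observed genes are flagged
#' `excluded` and dropped from downstream activity-distance matrices.
#'
#' @param genes per-gene activity table from [aggregate_probes()] (columns
#'   `gene_id`, `chromosome`, `activity`).
#' @param annotation data frame with columns `chromosome`, `gene_count`
#'   (annotated gene numbers).
#' @return A tibble `(chromosome, activity, log_activity, n_genes_used,
#'   n_annotated, excluded)` in annotation order.
#' @export
chromosome_activity <- function(genes, annotation) {
  genes <- as_tibble(genes)
  annotation <- as_tibble(annotation)
  if (!all(c("chromosome", "gene_count") %in% names(annotation))) {
    abort("`annotation` needs columns `chromosome`, `gene_count`.")
  }
  if (any(annotation$gene_count < 1)) {
    abort("annotated gene counts must be >= 1.")
  }
  missing <- setdiff(unique(genes$chromosome), annotation$chromosome)
  if (length(missing)) {
    abort(paste0("genes on chromosomes absent from annotation: ",
                 paste(missing, collapse = ", ")))
  }
  obs <- genes %>%
    group_by(.data$chromosome) %>%
    summarise(total = sum(.data$activity), n_genes_used = dplyr::n(),
              .groups = "drop")
  out <- annotation %>%
    select("chromosome", n_annotated = "gene_count") %>%
    left_join(obs, by = "chromosome") %>%
    mutate(
      n_genes_used = ifelse(is.na(.data$n_genes_used), 0L,
                            .data$n_genes_used),
      activity = .data$total / .data$n_annotated,
      log_activity = log(.data$activity),
      excluded = .data$n_genes_used == 0L
    ) %>%
    select("chromosome", "activity", "log_activity", "n_genes_used",
           "n_annotated", "excluded")
  if (any(out$excluded)) {
    inform(paste0("chromosomes with no observed genes excluded: ",
                  paste(out$chromosome[out$excluded], collapse = ", ")))
  }
  out
}

#' Inter-chromosome activity distance (IAD) matrix
#'
#' `IAD[i, j] = |ln A_i - ln A_j|`, the absolute difference of log mean
#' chromosomal activities — a one-dimensional embedding metric (symmetric,
#' zero diagonal, triangle inequality).  The natural log makes the matrix
#' invariant to global rescaling of all intensities.
#'
#' @param activity a tibble from [chromosome_activity()], or any data frame
#'   with columns `chromosome` and `log_activity`.  Excluded chromosomes
#'   (zero observed genes) are dropped.
#' @return A [dist_matrix()] with role `IAD`, units `log_activity`.
#' @export
compute_iad <- function(activity) {
  activity <- as_tibble(activity)
  if (!all(c("chromosome", "log_activity") %in% names(activity))) {
    abort("`activity` needs columns `chromosome`, `log_activity`.")
  }
  if ("excluded" %in% names(activity)) {
    activity <- filter(activity, !.data$excluded)
  }
  if (any(!is.finite(activity$log_activity))) {
    abort("log activities must be finite (positive activities).")
  }
  la <- activity$log_activity
  m <- abs(outer(la, la, "-"))
  dist_matrix(m, labels = activity$chromosome, units = "log_activity",
              role = "IAD")
}

#' Select highly expressing genes per chromosome
#'
#' Keeps, on each chromosome, the genes whose activity exceeds a fraction
#' (default 40%) of that chromosome's mean observed-gene activity.  Used to
#' build an `IAD` restricted to the actively transcribed subset of the
#' genome (roughly the top quarter of genes at the default threshold on
#' log-normal expression).
#'
#' @param genes per-gene activity table (columns `gene_id`, `chromosome`,
#'   `activity`).
#' @param fraction_of_chr_mean threshold as a fraction of the per-chromosome
#'   mean activity (default 0.4).
#' @return The filtered gene tibble.  Chromosomes where nothing passes are
#'   recorded in attribute `flagged_chromosomes`.
#' @export
select_high_expressers <- function(genes, fraction_of_chr_mean = 0.4) {
  genes <- as_tibble(genes)
  out <- genes %>%
    group_by(.data$chromosome) %>%
    filter(.data$activity > fraction_of_chr_mean * mean(.data$activity)) %>%
    ungroup()
  flagged <- setdiff(unique(genes$chromosome), unique(out$chromosome))
  if (length(flagged)) {
    warn(paste0("no genes pass the threshold on: ",
                paste(flagged, collapse = ", ")))
  }
  attr(out, "flagged_chromosomes") <- flagged
  out
}

#' Differential gene selection by FWHM of the difference histogram
#'
#' Selects the genes whose expression difference between two cell types
#' deviates from the bulk by more than one full width at half maximum (FWHM)
#' of the per-gene difference histogram.  The histogram is built with
#' Freedman-Diaconis bins by default; the FWHM is the width of the
#' contiguous run of bins, containing the modal bin, whose counts are at
#' least half the modal count; differences are centred at the modal bin
#' midpoint (or at zero with `center = "zero"`).  The same selected gene set
#' serves both cell types, so the per-chromosome selected counts are
#' identical in the derived matrix pair.
#'
#' @param a,b per-gene activity tables for the two cell types (columns
#'   `gene_id`, `chromosome`, `activity`); the gene universes are
#'   inner-joined on `gene_id`.
#' @param bins histogram bin specification passed to [graphics::hist()]
#'   `breaks` (default `"FD"`).
#' @param log_scale compute differences of log activities instead of linear
#'   activities.
#' @param center `"mode"` (default) or `"zero"`: the reference the
#'   difference must deviate from by more than one FWHM.
#' @return An object of class `differential_selection`: list with `genes`
#'   (tibble `gene_id, chromosome, activity_a, activity_b, diff, selected`),
#'   `fwhm`, `mode` (modal bin midpoint), `n_selected`, `center`,
#'   `log_scale`.
#' @export
differential_selection <- function(a, b, bins = "FD", log_scale = FALSE,
                                   center = c("mode", "zero")) {
  center <- match.arg(center)
  a <- as_tibble(a)
  b <- as_tibble(b)
  joined <- inner_join(
    select(a, "gene_id", "chromosome", activity_a = "activity"),
    select(b, "gene_id", activity_b = "activity"),
    by = "gene_id"
  )
  if (nrow(joined) == 0) abort("no shared genes between the two tables.")
  d <- if (log_scale) {
    log(joined$activity_a) - log(joined$activity_b)
  } else {
    joined$activity_a - joined$activity_b
  }
  h <- graphics::hist(d, breaks = bins, plot = FALSE)
  peak <- which.max(h$counts)
  half <- h$counts[peak] / 2
  lo <- peak
  while (lo > 1 && h$counts[lo - 1] >= half) lo <- lo - 1
  hi <- peak
  while (hi < length(h$counts) && h$counts[hi + 1] >= half) hi <- hi + 1
  fwhm <- h$breaks[hi + 1] - h$breaks[lo]
  ctr <- if (center == "mode") h$mids[peak] else 0
  selected <- abs(d - ctr) > fwhm
  if (!any(selected)) {
    abort(paste0(
      "FWHM selection is empty (no gene deviates by more than one FWHM); ",
      "the two tables may be identical, or try coarser `bins`."))
  }
  joined$diff <- d
  joined$selected <- selected
  structure(
    list(genes = joined, fwhm = fwhm, mode = ctr,
         n_selected = sum(selected), center = center,
         log_scale = log_scale, breaks = h$breaks),
    class = "differential_selection"
  )
}

#' @export
print.differential_selection <- function(x, ...) {
  cat(sprintf(
    "<differential_selection> %d / %d genes beyond 1 FWHM (%.4g, centre %.4g)\n",
    x$n_selected, nrow(x$genes), x$fwhm, x$mode))
  invisible(x)
}

#' Paired cell-type IAD matrices from a differential selection
#'
#' Applies [chromosome_activity()] and [compute_iad()] to the selected genes'
#' activities in each cell type, yielding the matrix pair
#' `IAD^{A-B}` (activities read from cell A) and `IAD^{B-A}` (from cell B).
#' The identical gene selection guarantees identical per-chromosome gene
#' counts in both matrices.
#'
#' @param selection a [differential_selection()].
#' @param annotation annotation table with `chromosome`, `gene_count`.
#' @return A list with `iad_ab`, `iad_ba` ([dist_matrix()] objects) and
#'   `selected_counts` (per-chromosome selected gene counts).
#' @export
build_pairwise_iads <- function(selection, annotation) {
  stopifnot(inherits(selection, "differential_selection"))
  sel <- filter(selection$genes, .data$selected)
  if (nrow(sel) == 0) abort("empty selection.")
  act_a <- chromosome_activity(
    select(sel, "gene_id", "chromosome", activity = "activity_a"),
    annotation)
  act_b <- chromosome_activity(
    select(sel, "gene_id", "chromosome", activity = "activity_b"),
    annotation)
  list(
    iad_ab = compute_iad(act_a),
    iad_ba = compute_iad(act_b),
    selected_counts = sel %>%
      group_by(.data$chromosome) %>%
      summarise(n_selected = dplyr::n(), .groups = "drop")
  )
}
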