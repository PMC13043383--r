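#' Remove cells whose total counts are MAD outliers
#'
#' Cells whose total feature counts fall beyond `n_mads` absolute deviations
#' of the median (unscaled median absolute deviation on raw totals,
#' two-sided) are removed as outliers. If the MAD is zero while totals
#' differ, the mean absolute deviation is used instead with a warning; if
#' all totals are identical no cell is removed.
#'
#' @param counts cells x genes count matrix (dense or sparse).
#' @param n_mads number of absolute deviations defining the bounds
#'   (default 5).
#' @return list with `counts` (retained cells) and `report`, a `data.frame`
#'   of every cell's total, the bounds, and whether it was removed.
#' @export
filter_cells_mad <- function(counts, n_mads = 5) {
  stopifnot(n_mads > 0, nrow(counts) >= 3)
  totals <- Matrix::rowSums(counts)
  med <- stats::median(totals)
  dev <- abs(totals - med)
  mad_raw <- stats::median(dev)
  if (mad_raw == 0 && any(dev > 0)) {
    warning("MAD of totals is zero; falling back to mean absolute deviation")
    mad_raw <- mean(dev)
  }
  lower <- med - n_mads * mad_raw
  upper <- med + n_mads * mad_raw
  removed <- totals < lower | totals > upper
  report <- data.frame(cell = if (is.null(rownames(counts))) {
    as.character(seq_along(totals))
  } else {
    rownames(counts)
  },
  total = totals, lower = lower, upper = upper,
  removed = removed, row.names = NULL)
  list(counts = counts[!removed, , drop = FALSE], report = report)
}

#' Remove genes detected in too few cells
#'
#' A gene is detected in a cell when its count is positive; genes detected
#' in fewer than `min_cells` cells are dropped. Surviving gene order is
#' preserved.
#'
#' @param counts cells x genes count matrix.
#' @param min_cells minimum number of cells (default 50).
#' @return the filtered matrix.
#' @export
filter_genes_min_cells <- function(counts, min_cells = 50) {
  stopifnot(min_cells >= 0)
  detected <- Matrix::colSums(counts > 0)
  keep <- detected >= min_cells
  if (!any(keep)) {
    stop("no gene is detected in at least ", min_cells,
         " cells; lower the threshold")
  }
  counts[, keep, drop = FALSE]
}

#' Depth-normalize counts to the median cell total, then log-transform
#'
#' Each cell's counts are scaled so its total equals the median
#' pre-normalization total, then transformed with `log(1 + x)`. The raw
#' counts are retained alongside for count-level analyses downstream.
#'
#' @param counts cells x genes count matrix with positive cell totals.
#' @return list with `normalized` (log-scale matrix), `counts` (the input),
#'   and `target` (the median total used as scaling target).
#' @export
normalize_log <- function(counts) {
  totals <- Matrix::rowSums(counts)
  if (any(totals <= 0)) {
    stop("cells with zero total counts present; run cell QC first")
  }
  target <- stats::median(totals)
  scaled <- Matrix::Diagonal(x = target / totals) %*% counts
  normalized <- log1p(scaled)
  dimnames(normalized) <- dimnames(counts)
  list(normalized = normalized, counts = counts, target = target)
}
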