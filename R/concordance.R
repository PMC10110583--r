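#' Assemble a feature-by-comparison effect matrix from comparison tables
#'
#' Inner-joins per-comparison differential-expression (or gene-set NES) tables
#' on their feature ids; only features present in every comparison are scored.
#'
#' @param tables named list (length >= 2) of data.frames with columns
#'   \code{feature_id} and \code{log2fc} (or \code{nes}).
#' @param value_col column holding the effect (default \code{"log2fc"}).
#'
#' @return numeric matrix, features in rows (rownames = feature ids), one
#'   column per comparison; attribute \code{"n_dropped"} counts features absent
#'   from at least one comparison.
#' @export
build_comparison_matrix <- function(tables, value_col = "log2fc") {
  if (length(tables) < 2) stop("need at least 2 comparisons")
  ids <- lapply(tables, function(t) {
    if (anyDuplicated(t$feature_id))
      stop("duplicate feature ids within a comparison")
    t$feature_id
  })
  common <- Reduce(intersect, ids)
  all_ids <- unique(unlist(ids))
  mat <- vapply(tables, function(t) {
    t[[value_col]][match(common, t$feature_id)]
  }, numeric(length(common)))
  mat <- matrix(mat, nrow = length(common),
                dimnames = list(common, names(tables)))
  if (any(!is.finite(mat))) stop("non-finite effect values in input tables")
  attr(mat, "n_dropped") <- length(all_ids) - length(common)
  mat
}

#' Signal-to-noise concordance of effects across comparisons
#'
#' Scores each feature for a conserved effect across k independent
#' comparisons with the signal-to-noise ratio: squared mean divided by sample
#' variance (denominator k - 1) of the per-comparison effects. Features whose
#' effect is reproducibly large relative to its between-comparison spread
#' score high regardless of direction; direction is reported separately as the
#' sign of the mean.
#'
#' @param mat numeric matrix of effects, features x comparisons (k >= 2
#'   columns), finite entries.
#' @param variance_floor lower bound applied to the sample variance so
#'   zero-variance features score finitely and ordering stays total
#'   (default 1e-8).
#'
#' @return data.frame with \code{feature_id}, \code{snr}, \code{mean_log2fc}
#'   and \code{direction} (\code{up}/\code{down}/\code{flat}), in input row
#'   order.
#' @export
snr_concordance <- function(mat, variance_floor = 1e-8) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 comparisons")
  if (any(!is.finite(mat))) stop("effect matrix has non-finite entries")
  m <- rowMeans(mat)
  v <- apply(mat, 1, stats::var)
  snr <- m^2 / pmax(v, variance_floor)
  data.frame(
    feature_id = if (is.null(rownames(mat))) as.character(seq_len(nrow(mat)))
                 else rownames(mat),
    snr = snr,
    mean_log2fc = m,
    direction = factor(ifelse(m > 0, "up", ifelse(m < 0, "down", "flat")),
                       levels = c("up", "down", "flat")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the top-k most concordant features
#'
#' Orders a concordance ranking by descending SNR, breaking ties by descending
#' |mean effect| and then lexicographically on the feature id, and returns the
#' first \code{k} rows. The tie rule makes the selection reproducible.
#'
#' @param rankings data.frame from [snr_concordance()].
#' @param k number of features to keep (<= number of scored features).
#'
#' @return data.frame of the k selected rows with a \code{rank} column.
#' @export
select_top_concordant <- function(rankings, k) {
  if (k > nrow(rankings))
    stop("k (", k, ") exceeds the number of scored features (",
         nrow(rankings), ")")
  ord <- order(-rankings$snr, -abs(rankings$mean_log2fc),
               rankings$feature_id)
  out <- rankings[ord[seq_len(k)], , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}

#' Z-score scale the columns of a matrix
#'
#' Centers and scales each column to mean 0 and sample standard deviation 1,
#' the display scaling used for cross-comparison effect heatmaps. Columns with
#' zero variance become all-zero with a warning.
#'
#' @param mat numeric matrix with at least 2 rows.
#' @return matrix of the same shape.
#' @export
zscale_columns <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 rows per column")
  mu <- colMeans(mat)
  sd <- apply(mat, 2, stats::sd)
  zero <- sd == 0
  if (any(zero)) {
    warning(sum(zero), " constant column(s) scaled to all-zero")
    sd[zero] <- 1
  }
  out <- sweep(sweep(mat, 2, mu, "-"), 2, sd, "/")
  out[, zero] <- 0
  out
}

#' Row ordering from Ward's minimum-variance clustering
#'
#' Leaf order of an agglomerative dendrogram built with Ward's minimum
#' variance criterion on Euclidean distances between rows — the ordering used
#' to display conserved-signature heatmaps.
#'
#' @param mat numeric matrix (typically column z-scaled) with >= 2 rows.
#' @return integer permutation of row indices.
#' @export
ward_leaf_order <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 rows")
  stats::hclust(stats::dist(mat), method = "ward.D2")$order
}

#' Signed log10-p rank metric for pre-ranked gene-set enrichment
#'
#' Builds the per-gene ranking metric for pre-ranked GSEA: the sign of the
#' log2 fold change times -log10 of the p-value. Where no p-value could be
#' computed the log2 fold change itself is used; p = 1 maps to 0.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param p_value p-values in (0, 1]; NA means no p-value available.
#' @return numeric vector of rank metrics.
#' @export
gsea_rank_metric <- function(log2fc, p_value) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  if (any(p_value <= 0, na.rm = TRUE) || any(p_value > 1, na.rm = TRUE))
    stop("p_value must be in (0, 1]")
  n <- max(length(log2fc), length(p_value))
  log2fc <- rep_len(log2fc, n); p_value <- rep_len(p_value, n)
  ifelse(is.na(p_value), log2fc, sign(log2fc) * -log10(p_value))
}

#' Quality-control filter for single cells
#'
#' Keeps cells with total counts above \code{min_counts}, expressed genes
#' above \code{min_genes} and mitochondrial read percentage below
#' \code{max_pct_mito}; all inequalities strict.
#'
#' @param cells data.frame with columns \code{total_counts}, \code{n_genes},
#'   \code{pct_mito}.
#' @param min_counts minimum total counts (default 2000).
#' @param min_genes minimum expressed genes (default 1000).
#' @param max_pct_mito maximum mitochondrial percentage (default 20).
#'
#' @return data.frame of kept cells.
#' @export
cell_qc_filter <- function(cells, min_counts = 2000, min_genes = 1000,
                           max_pct_mito = 20) {
  cells <- as.data.frame(cells)
  need <- c("total_counts", "n_genes", "pct_mito")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in need)
    if (any(!is.finite(cells[[col]]))) stop("non-finite values in ", col)
  keep <- cells$total_counts > min_counts & cells$n_genes > min_genes &
    cells$pct_mito < max_pct_mito
  cells[keep, , drop = FALSE]
}
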