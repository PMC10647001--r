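#' Variance-stabilizing style normalization (log2 + median calibration)
#'
#' Transforms raw intensities with `log2(x + 1)` (skipped when the matrix
#' is already on the log2 scale) and then applies a per-sample affine
#' calibration so every sample's median matches the grand median. Rank
#' order within each sample is preserved, per-sample medians agree to
#' numerical precision afterwards, and the operation is idempotent.
#'
#' This is a deliberately transparent stand-in for a full
#' variance-stabilizing transform: at CSF-proteomics intensity scales the
#' dominant between-sample artifact is a multiplicative loading/depletion
#' factor, which is an additive offset after log transform and is exactly
#' what the median calibration removes.
#'
#' @param matrix An [abundance_matrix()] on the `raw`, `log2` or
#'   `normalized` scale.
#' @return The matrix on the `normalized` scale.
#' @export
vst_normalize <- function(matrix) {
  matrix <- as_abundance(matrix)
  vals <- matrix$values
  if (matrix$scale == "raw") {
    if (any(vals < 0, na.rm = TRUE)) {
      stop("raw intensities must be nonnegative", call. = FALSE)
    }
    vals <- log2(vals + 1)
  }
  col_ok <- colSums(!is.na(vals)) > 0
  if (!all(col_ok)) {
    stop("sample(s) with all values missing: ",
      paste(colnames(vals)[!col_ok], collapse = ", "),
      call. = FALSE
    )
  }
  med <- apply(vals, 2, stats::median, na.rm = TRUE)
  target <- stats::median(vals, na.rm = TRUE)
  vals <- sweep(vals, 2, med - target)
  abundance_matrix(vals, scale = "normalized")
}

#' Remove additive batch effects
#'
#' For each protein, subtracts the per-batch mean and restores the
#' protein's grand mean, so post-adjustment batch means agree across
#' batches to numerical precision while each protein's overall mean is
#' unchanged. Batches with a single sample cannot be distinguished from
#' biology and are passed through with a warning.
#'
#' @param matrix An [abundance_matrix()].
#' @param metadata Sample metadata with a `batch` column aligned by
#'   `sample_id`.
#' @return Adjusted matrix on the same scale.
#' @export
batch_adjust <- function(matrix, metadata) {
  matrix <- as_abundance(matrix)
  vals <- matrix$values
  batch <- metadata$batch[match(colnames(vals), metadata$sample_id)]
  if (anyNA(batch)) stop("every sample needs a batch label", call. = FALSE)
  tab <- table(batch)
  singletons <- names(tab)[tab < 2]
  if (length(singletons)) {
    warning("singleton batch(es) passed through unadjusted: ",
      paste(singletons, collapse = ", "),
      call. = FALSE
    )
  }
  adjustable <- !(batch %in% singletons)
  grand <- rowMeans(vals, na.rm = TRUE)
  out <- vals
  for (b in setdiff(names(tab), singletons)) {
    cols <- which(batch == b)
    bm <- rowMeans(vals[, cols, drop = FALSE], na.rm = TRUE)
    out[, cols] <- vals[, cols, drop = FALSE] - bm + grand
  }
  # keep the protein grand mean exact when some batches were skipped
  if (any(!adjustable) && any(adjustable)) {
    resid <- grand - rowMeans(out, na.rm = TRUE)
    out[, adjustable] <- out[, adjustable, drop = FALSE] +
      resid * ncol(out) / sum(adjustable)
  }
  abundance_matrix(out, scale = matrix$scale)
}

#' Filter proteins by missingness
#'
#' Retains proteins whose fraction of missing entries does not exceed
#' `max_missing_frac`; row order is preserved.
#'
#' @param matrix An [abundance_matrix()].
#' @param max_missing_frac Threshold in `[0, 1]`.
#' @return Filtered matrix.
#' @export
filter_proteins <- function(matrix, max_missing_frac) {
  matrix <- as_abundance(matrix)
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stop("max_missing_frac must lie in [0, 1]", call. = FALSE)
  }
  frac <- rowMeans(is.na(matrix$values))
  keep <- frac <= max_missing_frac + 1e-12
  abundance_matrix(matrix$values[keep, , drop = FALSE], scale = matrix$scale)
}
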