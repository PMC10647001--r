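#' Protein-by-sample abundance matrix
#'
#' Light container for a label-free quantitation (LFQ) style protein
#' abundance matrix: proteins as rows, samples as columns, missing entries
#' allowed (`NA`). The `scale` field records where the values sit in the
#' processing chain and may only move forward: `"raw"` intensities,
#' `"log2"` intensities, or `"normalized"` (log2 + per-sample calibration).
#'
#' @param values Numeric matrix with unique rownames (protein IDs) and
#'   unique colnames (sample IDs).
#' @param scale One of `"raw"`, `"log2"`, `"normalized"`.
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values` and `scale`.
#' @export
abundance_matrix <- function(values, scale = c("log2", "raw", "normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have protein rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate protein IDs", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs", call. = FALSE)
  }
  structure(list(values = values, scale = scale), class = "abundance_matrix")
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' @method print abundance_matrix
#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf(
    "abundance_matrix: %d proteins x %d samples [%s scale, %.1f%% missing]\n",
    nrow(x$values), ncol(x$values), x$scale,
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @rdname abundance_matrix
#' @param x An `abundance_matrix`.
#' @export
protein_ids <- function(x) rownames(x$values)

#' @rdname abundance_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

as_abundance <- function(x) {
  if (inherits(x, "abundance_matrix")) return(x)
  abundance_matrix(x)
}

#' Validate a sample-metadata table
#'
#' Checks the per-sample annotation table that accompanies an
#' [abundance_matrix()]: one row per sample with patient identity, visit
#' structure and clinical covariates. Within each patient,
#' `months_from_baseline` must increase strictly with `visit_index` and a
#' baseline visit (`visit_index == 0`) must exist.
#'
#' @param metadata Data frame with columns `sample_id`, `patient_id`,
#'   `visit_index` (0-based), `months_from_baseline`, `batch`, and
#'   (optionally) `sex`, `age_at_onset`, `onset_site`, `alsfrsr_slope`.
#' @return The validated data frame, invisibly.
#' @export
validate_metadata <- function(metadata) {
  required <- c(
    "sample_id", "patient_id", "visit_index", "months_from_baseline", "batch"
  )
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  for (pid in unique(metadata$patient_id)) {
    rows <- metadata[metadata$patient_id == pid, ]
    rows <- rows[order(rows$visit_index), ]
    if (rows$visit_index[1] != 0) {
      stop("patient ", pid, " has no baseline visit (visit_index 0)", call. = FALSE)
    }
    if (is.unsorted(rows$months_from_baseline, strictly = TRUE)) {
      stop("months_from_baseline not strictly increasing for patient ", pid,
        call. = FALSE
      )
    }
  }
  invisible(metadata)
}
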