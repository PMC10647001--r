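#' Logistic panel score
#'
#' Maximum-likelihood logistic regression of the class label on a set of
#' marker abundances; the per-sample score is the fitted probability of
#' the positive (fast-progressing) class. With a single marker the score
#' is a monotone transform of the marker, so ROC analysis of the score
#' equals ROC analysis of the marker itself. Under complete separation
#' the ML estimate diverges; the fit is then flagged and the score is
#' rebuilt from the linear predictor with coefficients capped at a large
#' finite magnitude, which preserves the ranking.
#'
#' @param markers Matrix of marker abundances: markers as rows and
#'   samples as columns (an [abundance_matrix()] subset is accepted), or
#'   samples x markers with `samples_as_rows = TRUE`. No missing values.
#' @param labels Vector of two classes, one per sample.
#' @param positive Level treated as the positive class (default `"FP"`
#'   when present, otherwise the second sorted level).
#' @param samples_as_rows Set TRUE when `markers` is samples x markers.
#' @return List with `score` (named per-sample probability of the
#'   positive class), `coefficients`, `separation` flag, and the `glm`
#'   fit (NULL when the capped fallback was used).
#' @export
fit_logistic_panel <- function(markers, labels, positive = NULL,
                               samples_as_rows = FALSE) {
  if (inherits(markers, "abundance_matrix")) markers <- markers$values
  markers <- as.matrix(markers)
  if (!samples_as_rows) markers <- t(markers)
  if (anyNA(markers)) stop("marker submatrix must be complete", call. = FALSE)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("two classes required", call. = FALSE)
  if (is.null(positive)) positive <- if ("FP" %in% lev) "FP" else lev[2]
  y <- as.integer(labels == positive)
  df <- as.data.frame(markers)
  colnames(df) <- paste0("m", seq_len(ncol(df)))
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  prob <- stats::fitted(fit)
  separated <- any(abs(stats::coef(fit)[-1]) > 1e3, na.rm = TRUE) ||
    all(prob[y == 1] > 1 - 1e-8) && all(prob[y == 0] < 1e-8)
  if (separated) {
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0
    sds <- apply(markers, 2, stats::sd)
    sds[sds == 0] <- 1
    cap <- 10 / sds
    cf[-1] <- pmax(pmin(cf[-1], cap), -cap)
    eta <- cf[1] + as.matrix(df) %*% cf[-1]
    prob <- stats::plogis(drop(eta))
    out <- list(
      score = stats::setNames(prob, rownames(markers)),
      coefficients = cf, separation = TRUE, fit = NULL,
      positive = positive
    )
    return(out)
  }
  list(
    score = stats::setNames(prob, rownames(markers)),
    coefficients = stats::coef(fit), separation = FALSE, fit = fit,
    positive = positive
  )
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a random positive-class score
#' exceeds a random negative-class score, with ties counted one half --
#' identically the Mann-Whitney U statistic divided by `n1 * n0`.
#'
#' @param scores Numeric scores.
#' @param labels Two-class labels aligned with `scores`.
#' @param positive Positive class (default `"FP"` when present, else the
#'   second sorted level).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("both classes must be present", call. = FALSE)
  if (length(lev) > 2) stop("two classes required", call. = FALSE)
  if (is.null(positive)) positive <- if ("FP" %in% lev) "FP" else lev[2]
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Stratified bootstrap: samples are resampled with replacement within
#' each class (so every resample retains both classes), the AUC is
#' recomputed on each resample, and the percentile interval at the
#' requested level is returned.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap resamples (>= 100; default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000, level = 0.95,
                             seed = NULL, positive = NULL) {
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (is.null(positive)) positive <- if ("FP" %in% lev) "FP" else lev[2]
  idx_pos <- which(labels == positive)
  idx_neg <- which(labels != positive)
  aucs <- vapply(seq_len(n_boot), function(i) {
    take <- c(
      sample(idx_pos, length(idx_pos), replace = TRUE),
      sample(idx_neg, length(idx_neg), replace = TRUE)
    )
    roc_auc(scores[take], labels[take], positive = positive)
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' Optimal classification criterion (Youden index)
#'
#' Scans cutoffs (midpoints between adjacent distinct scores, plus
#' sentinels below and above the score range; a sample is called positive
#' when its score is at least the cutoff) and returns the criterion
#' maximizing the Youden index J = sensitivity + specificity - 1. Ties
#' are broken toward higher specificity, i.e. the largest such cutoff.
#'
#' @inheritParams roc_auc
#' @return List with `criterion`, `sensitivity`, `specificity`, `youden`.
#' @export
optimal_criterion <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("both classes must be present", call. = FALSE)
  if (is.null(positive)) positive <- if ("FP" %in% lev) "FP" else lev[2]
  pos <- labels == positive
  s <- sort(unique(scores))
  cuts <- c(
    s[1] - 1,
    if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
    s[length(s)] + 1
  )
  sens <- vapply(cuts, function(cut) sum(scores >= cut & pos) / sum(pos), 0)
  spec <- vapply(cuts, function(cut) sum(scores < cut & !pos) / sum(!pos), 0)
  j <- sens + spec - 1
  cand <- which(j >= max(j) - 1e-12)
  cand <- cand[spec[cand] >= max(spec[cand]) - 1e-12]
  pick <- cand[length(cand)] # largest tying cutoff
  list(
    criterion = cuts[pick], sensitivity = sens[pick],
    specificity = spec[pick], youden = j[pick]
  )
}
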