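#' Mutual information between a continuous variable and a binary label
#'
#' Nearest-neighbour estimator of the mutual information (in nats)
#' between a continuous marker and a discrete class label. For each
#' sample the distance to its k-th nearest neighbour within the same
#' class defines a radius; counting how many samples of any class fall
#' strictly inside that radius yields the digamma-based estimate
#' `psi(N) + psi(k) - mean(psi(n_class)) - mean(psi(m))`, where `n_class`
#' is the size of each sample's class and `m` the within-radius count
#' (self included). The estimate is clipped at zero and is bounded above
#' by the label entropy. Being rank/neighbour based, it is insensitive to
#' monotone rescaling of the marker.
#'
#' @param x Continuous values (no missing).
#' @param labels Binary class labels aligned with `x`.
#' @param k Neighbour count (default 3); reduced per class when a class
#'   has at most `k` members.
#' @return Mutual information estimate in nats (>= 0).
#' @export
mutual_information_cd <- function(x, labels, k = 3) {
  if (anyNA(x)) stop("x must be complete; drop missing pairwise upstream",
    call. = FALSE
  )
  labels <- as.character(labels)
  n <- length(x)
  if (n != length(labels)) stop("length mismatch", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(0)
  }
  counts <- table(labels)
  if (any(counts < 2)) stop("each class needs at least 2 samples", call. = FALSE)
  psi_m <- numeric(n)
  psi_k <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    same <- same[same != i]
    d_same <- sort(abs(x[same] - x[i]))
    ki <- min(k, length(d_same))
    radius <- d_same[ki]
    if (radius > 0) {
      m <- sum(abs(x - x[i]) < radius) # includes self
    } else {
      # tied values: count the tie group itself
      m <- sum(abs(x - x[i]) <= 0)
    }
    psi_m[i] <- digamma(max(1, m))
    psi_k[i] <- digamma(ki)
  }
  psi_nc <- digamma(as.numeric(counts[labels]))
  mi <- digamma(n) + mean(psi_k) - mean(psi_nc) - mean(psi_m)
  max(0, mi)
}

#' Rank proteins by mutual information with progression class
#'
#' Computes [mutual_information_cd()] for every protein against the
#' fast/slow class label (missing values dropped pairwise per protein)
#' and returns the top `k` proteins. Ties are broken by protein ID so
#' the ranking is deterministic.
#'
#' @param matrix An [abundance_matrix()] or proteins x samples matrix.
#' @param labels Class label per sample.
#' @param k Number of top proteins to report (default 20).
#' @param knn_k Neighbour count for the estimator (default 3).
#' @return Data frame `protein_id`, `mi` (nats), sorted nonincreasing;
#'   attribute `label_entropy` carries the upper bound `H(label)`.
#' @export
rank_by_mi <- function(matrix, labels, k = 20, knn_k = 3) {
  if (inherits(matrix, "abundance_matrix")) matrix <- matrix$values
  if (k > nrow(matrix)) stop("k exceeds number of proteins", call. = FALSE)
  labels <- as.character(labels)
  mi <- vapply(seq_len(nrow(matrix)), function(i) {
    xi <- matrix[i, ]
    ok <- !is.na(xi)
    if (sum(ok) < 6 || length(unique(labels[ok])) < 2) {
      return(0)
    }
    mutual_information_cd(xi[ok], labels[ok], k = knn_k)
  }, numeric(1))
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(matrix)))
  ord <- order(-mi, ids)
  out <- data.frame(
    protein_id = ids[ord][seq_len(k)],
    mi = mi[ord][seq_len(k)],
    stringsAsFactors = FALSE
  )
  p <- table(labels) / length(labels)
  attr(out, "label_entropy") <- -sum(p * log(p))
  out
}
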