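# Small-sample exact tests used across the cohort-demographics and
# differential-abundance stages. Cohorts here are ~5-6 patients per arm, so
# the exact (enumeration) regime is the common case, not the fallback.

# cache of combination index matrices keyed by "n.k"
.combn_cache <- new.env(parent = emptyenv())

combn_cached <- function(n, k) {
  key <- paste(n, k, sep = ".")
  m <- .combn_cache[[key]]
  if (is.null(m)) {
    m <- utils::combn(n, k)
    .combn_cache[[key]] <- m
  }
  m
}

# mid-rank Mann-Whitney U of a versus b (ties count 1/2)
mw_u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact two-sided p by full enumeration of group-A index sets over the
# mid-rank vector; valid with ties
mw_p_enumerate <- function(a, b) {
  na <- length(a)
  n <- na + length(b)
  r <- rank(c(a, b))
  idx <- combn_cached(n, na)
  sums <- colSums(matrix(r[idx], nrow = na))
  obs <- sum(r[seq_len(na)])
  tol <- 1e-9
  lower <- mean(sums <= obs + tol)
  upper <- mean(sums >= obs - tol)
  min(1, 2 * min(lower, upper))
}

# normal approximation with tie correction and continuity correction
mw_p_normal <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  u <- mw_u_statistic(a, b)
  ties <- table(c(a, b))
  n <- na + nb
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(1)
  }
  z <- u - na * nb / 2
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Exact two-sided Mann-Whitney test for small samples
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) p-value computed by full
#' combinatorial enumeration of all group assignments, with mid-ranks for
#' ties. The two-sided p is twice the smaller tail probability (including
#' the observed point mass), capped at 1. Beyond the exact regime the
#' tie-corrected normal approximation is used instead.
#'
#' At the scale of the cohorts this package targets (5-6 patients per
#' progression group) the full enumeration is exact and instant, e.g.
#' C(11, 5) = 462 assignments for a 6-vs-5 comparison.
#'
#' @param values_a,values_b Numeric vectors, one per group.
#' @param exact_max_n Largest total sample size for which the full
#'   enumeration is used (default 15); larger inputs delegate to the
#'   tie-corrected normal approximation.
#' @return Two-sided p-value in `[0, 1]`.
#' @seealso [fisher_exact_2x2()] for the categorical counterpart.
#' @export
exact_mann_whitney <- function(values_a, values_b, exact_max_n = 15) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (!length(a) || !length(b)) stop("both groups must be nonempty", call. = FALSE)
  if (length(a) + length(b) <= exact_max_n) {
    mw_p_enumerate(a, b)
  } else {
    mw_p_normal(a, b)
  }
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test of independence in a 2x2 contingency table: with
#' the margins fixed, the first cell follows a hypergeometric
#' distribution, and the two-sided p-value is the sum of the probabilities
#' of all tables no more probable than the observed one (the standard
#' two-sided convention).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("table entries must be nonnegative integers", call. = FALSE)
  }
  m <- sum(table[1, ]) # row 1 margin
  n <- sum(table[2, ])
  k <- sum(table[, 1]) # column 1 margin
  if (m + n == 0) {
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(table[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
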