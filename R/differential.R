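#' Classify ALS progression rate from the ALSFRS-R slope
#'
#' Applies the standard progression-rate thresholds to the monthly
#' ALSFRS-R decline: `fast` for a slope of at least 1 unit/month
#' (boundary inclusive), `slow` for a slope below 0.5, and
#' `intermediate` otherwise (intermediate patients are excluded from all
#' group analyses).
#'
#' @param alsfrsr_slope Numeric vector of nonnegative monthly declines.
#' @return Character vector of `"fast"`, `"slow"`, `"intermediate"`.
#' @export
progression_label <- function(alsfrsr_slope) {
  if (anyNA(alsfrsr_slope)) {
    stop("missing ALSFRS-R slope; cannot assign progression label",
      call. = FALSE
    )
  }
  if (any(alsfrsr_slope < 0)) {
    stop("ALSFRS-R slope must be nonnegative (decline per month)",
      call. = FALSE
    )
  }
  ifelse(alsfrsr_slope >= 1.0, "fast",
    ifelse(alsfrsr_slope < 0.5, "slow", "intermediate")
  )
}

#' Per-protein Mann-Whitney differential abundance with BH correction
#'
#' For each protein, compares the two sample groups with a two-sided
#' Mann-Whitney test (mid-ranks; exact enumeration when the total
#' per-protein sample count is at most `exact_max_n`, tie-corrected normal
#' approximation otherwise) and reports the log2 fold change as the
#' difference of group means on the log2 scale. Raw p-values are adjusted
#' by the Benjamini-Hochberg step-up rule over all testable proteins, and
#' a protein is flagged significant when `|log2_fc| >= log2(fc_threshold)`
#' and `p_adj <= alpha`. Proteins with fewer than two observed values in
#' either group are marked untestable and excluded from the BH family.
#'
#' @param matrix An [abundance_matrix()] (log2 or normalized scale).
#' @param groups Character/factor vector, one entry per sample, with
#'   exactly two non-missing levels; samples with `NA` group are dropped.
#' @param group_a Which level plays the "A" role (fold change is A minus
#'   B); defaults to `"FP"` when present, otherwise the first level.
#' @param fc_threshold Fold-change cutoff on the natural scale
#'   (default 1.5).
#' @param alpha Adjusted-p cutoff (default 0.0125).
#' @param exact_max_n Passed to the test; see [exact_mann_whitney()].
#' @return Data frame with one row per protein: `protein_id`, `log2_fc`,
#'   `p_raw`, `p_adj`, `significant`, `direction` (`up_in_<A>` /
#'   `up_in_<B>`), `testable`.
#' @export
mann_whitney_bh <- function(matrix, groups, group_a = NULL,
                            fc_threshold = 1.5, alpha = 0.0125,
                            exact_max_n = 12) {
  matrix <- as_abundance(matrix)
  vals <- matrix$values
  groups <- as.character(groups)
  keep <- !is.na(groups)
  vals <- vals[, keep, drop = FALSE]
  groups <- groups[keep]
  lev <- unique(groups)
  if (length(lev) != 2) stop("`groups` must have exactly two levels", call. = FALSE)
  if (is.null(group_a)) group_a <- if ("FP" %in% lev) "FP" else lev[1]
  if (!group_a %in% lev) stop("group_a not found in groups", call. = FALSE)
  group_b <- setdiff(lev, group_a)
  a_cols <- groups == group_a

  n <- nrow(vals)
  log2_fc <- p_raw <- rep(NA_real_, n)
  testable <- logical(n)
  for (i in seq_len(n)) {
    a <- vals[i, a_cols]
    b <- vals[i, !a_cols]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) next
    testable[i] <- TRUE
    log2_fc[i] <- mean(a) - mean(b)
    p_raw[i] <- if (length(a) + length(b) <= exact_max_n) {
      mw_p_enumerate(a, b)
    } else {
      mw_p_normal(a, b)
    }
  }
  p_adj <- rep(NA_real_, n)
  p_adj[testable] <- stats::p.adjust(p_raw[testable], method = "BH")
  significant <- testable &
    !is.na(p_adj) & p_adj <= alpha &
    abs(log2_fc) >= log2(fc_threshold) - 1e-12
  direction <- ifelse(is.na(log2_fc), NA_character_,
    ifelse(log2_fc > 0, paste0("up_in_", group_a), paste0("up_in_", group_b))
  )
  data.frame(
    protein_id = rownames(vals),
    log2_fc = log2_fc,
    p_raw = p_raw,
    p_adj = p_adj,
    significant = significant,
    direction = direction,
    testable = testable,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# per-patient first / last visit sample IDs for labelled patients
first_last_samples <- function(metadata) {
  labels <- progression_label(metadata$alsfrsr_slope)
  out <- do.call(rbind, lapply(split(
    data.frame(metadata, label = labels, stringsAsFactors = FALSE),
    metadata$patient_id
  ), function(rows) {
    rows <- rows[order(rows$visit_index), ]
    data.frame(
      patient_id = rows$patient_id[1],
      label = rows$label[1],
      first = rows$sample_id[1],
      last = rows$sample_id[nrow(rows)],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[out$label != "intermediate", ]
}

#' Four-way cross-sectional candidate panel
#'
#' Runs the four cross-sectional fast-vs-slow comparisons -- FP first
#' visit vs SP first visit, FP last vs SP last, FP first vs SP last, and
#' FP last vs SP first -- each via [mann_whitney_bh()], and intersects the
#' significant protein sets. By default a protein must also show the same
#' fold-change direction in all four comparisons to enter the panel (the
#' observed panels form coherent up/down blocks); set
#' `require_direction = FALSE` to intersect on significance alone.
#'
#' "First" and "last" are the baseline visit (`visit_index == 0`) and the
#' highest visit index per patient; intermediate progressors are excluded.
#'
#' @param matrix An [abundance_matrix()].
#' @param metadata Sample metadata including `alsfrsr_slope`.
#' @param fc_threshold,alpha,exact_max_n Passed to [mann_whitney_bh()].
#' @param require_direction Require consistent direction (default TRUE).
#' @return List with `panel` (character vector of protein IDs) and
#'   `comparisons` (named list of the four per-comparison result frames).
#' @export
four_way_panel <- function(matrix, metadata, fc_threshold = 1.5,
                           alpha = 0.0125, exact_max_n = 12,
                           require_direction = TRUE) {
  matrix <- as_abundance(matrix)
  fl <- first_last_samples(metadata)
  pick <- function(lbl, when) fl[fl$label == lbl, when]
  specs <- list(
    FPfirst_vs_SPfirst = list(a = pick("fast", "first"), b = pick("slow", "first")),
    FPlast_vs_SPlast   = list(a = pick("fast", "last"),  b = pick("slow", "last")),
    FPfirst_vs_SPlast  = list(a = pick("fast", "first"), b = pick("slow", "last")),
    FPlast_vs_SPfirst  = list(a = pick("fast", "last"),  b = pick("slow", "first"))
  )
  comparisons <- lapply(specs, function(s) {
    cols <- c(s$a, s$b)
    sub <- abundance_matrix(
      matrix$values[, cols, drop = FALSE],
      scale = matrix$scale
    )
    grp <- rep(c("FP", "SP"), c(length(s$a), length(s$b)))
    mann_whitney_bh(sub, grp,
      group_a = "FP", fc_threshold = fc_threshold,
      alpha = alpha, exact_max_n = exact_max_n
    )
  })
  sig_sets <- lapply(comparisons, function(res) res$protein_id[res$significant])
  panel <- Reduce(intersect, sig_sets)
  if (require_direction && length(panel)) {
    dirs <- sapply(comparisons, function(res) {
      res$direction[match(panel, res$protein_id)]
    })
    dirs <- matrix(dirs, nrow = length(panel))
    consistent <- apply(dirs, 1, function(d) length(unique(d)) == 1)
    panel <- panel[consistent]
  }
  list(panel = panel, comparisons = comparisons)
}
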