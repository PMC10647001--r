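#' Configuration for repeated double cross-validated RF selection
#'
#' Tuning parameters of the repeated double cross-validation (rdCV)
#' random-forest variable selection: outer folds estimate prediction
#' error on held-out samples, inner folds drive recursive variable
#' elimination by permutation importance, and the whole procedure is
#' repeated to average over fold assignments. Defaults mirror common
#' rdCV practice for cohorts of tens of samples.
#'
#' @param n_repetitions Number of repetitions of the double CV.
#' @param n_outer,n_inner Outer / inner fold counts (both >= 2).
#' @param drop_fraction Fraction of variables dropped per elimination
#'   step (in (0, 1)).
#' @param model_choice `"min"` (fewest variables at minimal inner error,
#'   the parsimonious choice) -- the only choice currently implemented.
#' @param n_trees Trees per random forest.
#' @param seed Integer seed controlling fold assignment and forests.
#' @param stratify_by_patient Keep all visits of a patient in the same
#'   fold (avoids longitudinal leakage); requires `patient_ids` in
#'   [rdcv_select()].
#' @return List of class `rdcv_config`.
#' @export
rdcv_config <- function(n_repetitions = 30, n_outer = 6, n_inner = 5,
                        drop_fraction = 0.2, model_choice = "min",
                        n_trees = 300, seed = 1,
                        stratify_by_patient = TRUE) {
  if (n_outer < 2 || n_inner < 2) stop("fold counts must be >= 2", call. = FALSE)
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    stop("drop_fraction must lie in (0, 1)", call. = FALSE)
  }
  model_choice <- match.arg(model_choice, "min")
  structure(
    list(
      n_repetitions = n_repetitions, n_outer = n_outer, n_inner = n_inner,
      drop_fraction = drop_fraction, model_choice = model_choice,
      n_trees = n_trees, seed = seed,
      stratify_by_patient = stratify_by_patient
    ),
    class = "rdcv_config"
  )
}

# deal units round-robin to folds within each class after shuffling
assign_folds <- function(unit_class, n_folds) {
  fold <- integer(length(unit_class))
  for (cls in unique(unit_class)) {
    idx <- which(unit_class == cls)
    if (length(idx) < n_folds) {
      warning("class '", cls, "' has fewer units (", length(idx),
        ") than folds (", n_folds, "); folds will be unbalanced",
        call. = FALSE
      )
    }
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

rf_fit <- function(x, y, vars, n_trees, seed, importance = "none") {
  ranger::ranger(
    x = x[, vars, drop = FALSE], y = y,
    num.trees = n_trees, probability = TRUE,
    importance = importance,
    seed = seed, num.threads = 1,
    min.node.size = 1
  )
}

rf_class_prob <- function(fit, x, vars) {
  p <- stats::predict(fit, data = x[, vars, drop = FALSE],
    num.threads = 1
  )$predictions
  p
}

#' Repeated double cross-validated random-forest variable selection
#'
#' Identifies a minimal protein panel separating two classes. In each
#' repetition samples (or whole patients) are split into outer folds;
#' within every outer training set an inner cross-validation drives
#' recursive variable elimination: forests are fit on the inner training
#' folds, variables are ranked by out-of-bag permutation importance
#' averaged over inner folds, the lowest-ranked `drop_fraction` is
#' removed, and the inner misclassification count is recorded per panel
#' size. The panel size with minimal inner error (smallest size on ties)
#' is refit on the full outer training set and applied to the held-out
#' outer fold, yielding unbiased per-sample class probabilities.
#' A repetition selects a protein when any of its outer-fold minimum
#' models contains it; the consensus panel consists of the proteins
#' selected by at least half of the repetitions, so complementary or
#' redundant markers that alternate across folds all enter the panel.
#'
#' @param matrix Markers x samples matrix or [abundance_matrix()]
#'   (complete; impute or filter upstream).
#' @param labels Two-class vector, one per sample.
#' @param config An [rdcv_config()].
#' @param patient_ids Optional per-sample patient IDs for
#'   patient-stratified folds.
#' @return List of class `rdcv_selection`: `selected_proteins` (ordered
#'   by selection frequency), `n_selected`, `selection_frequency`
#'   (per-repetition), `fold_frequency` (per outer-fold run),
#'   `per_sample_probability` (mean probability of the sample's own class
#'   over repetitions), `misclassified` (samples with probability < 0.5),
#'   `n_misclassified`, `labels`, and the per-run chosen panel sizes.
#' @export
rdcv_select <- function(matrix, labels, config = rdcv_config(),
                        patient_ids = NULL) {
  if (inherits(matrix, "abundance_matrix")) matrix <- matrix$values
  x <- t(as.matrix(matrix)) # samples x proteins
  if (anyNA(x)) stop("input submatrix must be complete (no NA)", call. = FALSE)
  y <- factor(as.character(labels))
  if (nlevels(y) != 2 || min(table(y)) < 2) {
    stop("two classes with >= 2 samples each required", call. = FALSE)
  }
  n_samp <- nrow(x)
  proteins <- colnames(x)
  if (is.null(proteins)) {
    proteins <- paste0("V", seq_len(ncol(x)))
    colnames(x) <- proteins
  }

  by_patient <- config$stratify_by_patient && !is.null(patient_ids)
  if (by_patient) {
    units <- unique(patient_ids)
    unit_of <- match(patient_ids, units)
    unit_class <- as.character(y[match(units, patient_ids)])
  } else {
    units <- seq_len(n_samp)
    unit_of <- seq_len(n_samp)
    unit_class <- as.character(y)
  }

  prob_sum <- stats::setNames(numeric(n_samp), rownames(x))
  prob_n <- numeric(n_samp)
  sel_count <- stats::setNames(numeric(length(proteins)), proteins)
  rep_count <- stats::setNames(numeric(length(proteins)), proteins)
  n_runs <- 0L
  n_reps_done <- 0L
  chosen_sizes <- integer(0)
  rf_seed <- config$seed * 1000L

  for (rep_i in seq_len(config$n_repetitions)) {
    set.seed(config$seed + 7919L * rep_i)
    rep_union <- character(0)
    outer_fold_unit <- assign_folds(unit_class, config$n_outer)
    outer_fold <- outer_fold_unit[unit_of]
    for (k in seq_len(config$n_outer)) {
      test_idx <- which(outer_fold == k)
      train_idx <- which(outer_fold != k)
      if (!length(test_idx) ||
        length(unique(y[train_idx])) < 2) {
        next
      }
      inner_units <- which(outer_fold_unit != k)
      inner_fold_unit <- rep(NA_integer_, length(units))
      inner_fold_unit[inner_units] <- assign_folds(
        unit_class[inner_units], config$n_inner
      )
      inner_fold <- inner_fold_unit[unit_of]

      vars <- proteins
      history <- list()
      while (length(vars) >= 1) {
        errs <- numeric(0)
        imp_sum <- stats::setNames(numeric(length(vars)), vars)
        imp_n <- 0L
        for (j in seq_len(config$n_inner)) {
          itr <- train_idx[inner_fold[train_idx] != j &
            !is.na(inner_fold[train_idx])]
          iva <- train_idx[inner_fold[train_idx] == j]
          if (!length(iva) || length(unique(y[itr])) < 2) next
          rf_seed <- rf_seed + 1L
          fit <- rf_fit(x[itr, , drop = FALSE], y[itr], vars,
            config$n_trees, rf_seed,
            importance = "permutation"
          )
          p <- rf_class_prob(fit, x[iva, , drop = FALSE], vars)
          pred <- colnames(p)[max.col(p, ties.method = "first")]
          errs <- c(errs, sum(pred != as.character(y[iva])))
          imp <- fit$variable.importance
          # tiny out-of-bag sets can yield NaN importance; treat as zero
          imp[!is.finite(imp)] <- 0
          imp_sum[names(imp)] <- imp_sum[names(imp)] + imp
          imp_n <- imp_n + 1L
        }
        if (!imp_n) break
        history[[length(history) + 1L]] <- list(
          vars = vars, error = sum(errs) / imp_n
        )
        if (length(vars) == 1) break
        n_drop <- max(1L, floor(config$drop_fraction * length(vars)))
        keep_n <- max(1L, length(vars) - n_drop)
        ord <- order(imp_sum / imp_n, decreasing = TRUE)
        vars <- vars[ord[seq_len(keep_n)]]
      }
      if (!length(history)) next
      errors <- vapply(history, `[[`, 0, "error")
      sizes <- vapply(history, function(h) length(h$vars), 0L)
      # minimal error; among ties the smallest panel (min model)
      cand <- which(errors <= min(errors) + 1e-12)
      pick <- cand[which.min(sizes[cand])]
      chosen <- history[[pick]]$vars
      chosen_sizes <- c(chosen_sizes, length(chosen))
      sel_count[chosen] <- sel_count[chosen] + 1
      rep_union <- union(rep_union, chosen)
      n_runs <- n_runs + 1L

      rf_seed <- rf_seed + 1L
      fit <- rf_fit(x[train_idx, , drop = FALSE], y[train_idx], chosen,
        config$n_trees, rf_seed
      )
      p <- rf_class_prob(fit, x[test_idx, , drop = FALSE], chosen)
      own <- p[cbind(seq_along(test_idx), match(
        as.character(y[test_idx]), colnames(p)
      ))]
      prob_sum[test_idx] <- prob_sum[test_idx] + own
      prob_n[test_idx] <- prob_n[test_idx] + 1
    }
    if (length(rep_union)) {
      rep_count[rep_union] <- rep_count[rep_union] + 1
      n_reps_done <- n_reps_done + 1L
    }
  }
  if (!n_runs) stop("no successful cross-validation runs", call. = FALSE)

  # a repetition "selects" a protein when any of its outer minimum models
  # contains it; the consensus panel holds proteins selected by most
  # repetitions (redundant markers that alternate across folds all enter)
  freq <- sel_count / n_runs
  rep_freq <- rep_count / n_reps_done
  ord <- order(-rep_freq, -freq, names(freq))
  selected <- names(rep_freq)[ord][rep_freq[ord] >= 0.5]
  if (!length(selected)) selected <- names(rep_freq)[ord][1]
  prob <- ifelse(prob_n > 0, prob_sum / prob_n, NA_real_)
  names(prob) <- rownames(x)
  miscls <- names(prob)[!is.na(prob) & prob < 0.5]
  structure(
    list(
      selected_proteins = selected,
      n_selected = length(selected),
      selection_frequency = rep_freq[ord],
      fold_frequency = freq[ord],
      per_sample_probability = prob,
      misclassified = miscls,
      n_misclassified = length(miscls),
      chosen_sizes = chosen_sizes,
      labels = stats::setNames(as.character(y), rownames(x)),
      n_runs = n_runs
    ),
    class = "rdcv_selection"
  )
}

#' Swim-lane prediction summary
#'
#' Per-patient, per-visit table of cross-validated class-probability
#' predictions: each row is one sample with its mean probability of the
#' patient's own class, the implied per-visit call, a high-confidence
#' flag (probability > 0.9), and the patient-level call taken as the
#' majority of visit calls (ties broken toward the class with the higher
#' mean probability).
#'
#' @param result An [rdcv_select()] result.
#' @param metadata Sample metadata (`sample_id`, `patient_id`,
#'   `visit_index`).
#' @return Data frame with one row per sample.
#' @export
swim_lane_table <- function(result, metadata) {
  prob <- result$per_sample_probability
  labels <- result$labels
  ids <- names(prob)
  m <- metadata[match(ids, metadata$sample_id), ]
  own <- labels[ids]
  other <- vapply(own, function(l) setdiff(unique(labels), l)[1], "")
  visit_call <- ifelse(!is.na(prob) & prob >= 0.5, own, other)
  out <- data.frame(
    patient_id = m$patient_id,
    visit_index = m$visit_index,
    sample_id = ids,
    true_class = own,
    prob_own_class = unname(prob),
    visit_call = visit_call,
    misclassified = !is.na(prob) & prob < 0.5,
    high_confidence = !is.na(prob) & prob > 0.9,
    stringsAsFactors = FALSE, row.names = NULL
  )
  calls <- vapply(split(out, out$patient_id), function(rows) {
    tab <- table(rows$visit_call)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) {
      return(top)
    }
    means <- vapply(top, function(cl) {
      mean(ifelse(rows$visit_call == cl,
        rows$prob_own_class, 1 - rows$prob_own_class
      ), na.rm = TRUE)
    }, 0)
    top[which.max(means)]
  }, "")
  out$patient_call <- calls[out$patient_id]
  out[order(out$patient_id, out$visit_index), ]
}
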