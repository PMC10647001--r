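#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates the stages -- synthetic cohort, preprocessing, four-way
#' differential panel, rdCV selection, logistic/ROC panel evaluation,
#' marker trajectories, mutual-information ranking, and the OU
#' state-transition fit -- from a single configuration, writing per-stage
#' outputs and a run manifest (seeds, file hashes) to `out_dir`. Each
#' stage gets a deterministic sub-seed derived from the global seed, so a
#' rerun with the same configuration reproduces all outputs
#' bit-identically. A stage failure is recorded in the manifest and
#' downstream stages are skipped.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure: optional `seed` (default 1), `stages` (character vector
#'   of stages to run; default all), `cohort` (arguments for
#'   [cohort_spec()]), `preprocess` (`max_missing_frac`), `differential`
#'   (`fc_threshold`, `alpha`), `select` (arguments for [rdcv_config()]),
#'   `mi` (`k`), `state` (`t_back_months`, `n_paths`).
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("proteostate_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  all_stages <- c(
    "synth", "preprocess", "differential", "select",
    "evaluate", "trajectories", "mi", "state"
  )
  stages <- if (is.null(config$stages)) all_stages else config$stages
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sub_seed <- function(i) (seed + 1000003L * i) %% 2147483647L

  manifest <- list(
    package_version = as.character(utils::packageVersion("proteostate")),
    seed = seed, stages = stages, outputs = list(), status = list()
  )
  state <- new.env()
  record <- function(stage, files) {
    manifest$outputs[[stage]] <<- lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
    manifest$status[[stage]] <<- "ok"
  }

  run_stage <- function(stage, fun) {
    if (!stage %in% stages) return(TRUE)
    ok <- tryCatch(
      {
        fun()
        TRUE
      },
      error = function(e) {
        manifest$status[[stage]] <<- paste("failed:", conditionMessage(e))
        FALSE
      }
    )
    ok
  }

  ok <- run_stage("synth", function() {
    args <- if (is.null(config$cohort)) list() else config$cohort
    args$seed <- sub_seed(1)
    cohort <- generate_cohort(do.call(cohort_spec, args))
    state$cohort <- cohort
    dir <- file.path(out_dir, "cohort")
    write_cohort(cohort$matrix, cohort$metadata, dir)
    record("synth", file.path(dir, c("abundance.tsv", "metadata.tsv")))
  })
  if (!ok) {
    return(finish_manifest(manifest, out_dir))
  }
  if (!"synth" %in% stages) {
    if (is.null(config$input_dir)) {
      stop("either enable the synth stage or provide config$input_dir",
        call. = FALSE
      )
    }
    cohort <- read_cohort(config$input_dir)
    if (!"group" %in% names(cohort$metadata)) {
      lab <- progression_label(cohort$metadata$alsfrsr_slope)
      cohort$metadata$group <- ifelse(lab == "fast", "FP",
        ifelse(lab == "slow", "SP", NA_character_)
      )
    }
    state$cohort <- cohort
  }

  ok <- run_stage("preprocess", function() {
    max_miss <- config$preprocess$max_missing_frac
    if (is.null(max_miss)) max_miss <- 0.5
    m <- vst_normalize(state$cohort$matrix)
    m <- batch_adjust(m, state$cohort$metadata)
    m <- filter_proteins(m, max_miss)
    state$matrix <- m
    dir <- file.path(out_dir, "preprocessed")
    write_cohort(m, state$cohort$metadata, dir)
    record("preprocess", file.path(dir, "abundance.tsv"))
  })
  if (!ok) {
    return(finish_manifest(manifest, out_dir))
  }
  if (is.null(state$matrix)) state$matrix <- state$cohort$matrix
  meta <- state$cohort$metadata

  ok <- run_stage("differential", function() {
    fc <- config$differential$fc_threshold
    alpha <- config$differential$alpha
    res <- four_way_panel(state$matrix, meta,
      fc_threshold = if (is.null(fc)) 1.5 else fc,
      alpha = if (is.null(alpha)) 0.0125 else alpha
    )
    state$panel <- res$panel
    path <- file.path(out_dir, "differential_panel.tsv")
    utils::write.table(
      data.frame(protein_id = res$panel), path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    record("differential", path)
  })

  complete_submatrix <- function(ids) {
    vals <- state$matrix$values[ids, , drop = FALSE]
    keep <- rowSums(is.na(vals)) == 0
    vals[keep, , drop = FALSE]
  }

  if (ok && "select" %in% stages) {
    ok <- run_stage("select", function() {
      ids <- if (length(state$panel)) state$panel else protein_ids(state$matrix)
      vals <- complete_submatrix(ids)
      cfg_args <- if (is.null(config$select)) list() else config$select
      cfg_args$seed <- sub_seed(4)
      sel <- rdcv_select(vals, meta$group,
        config = do.call(rdcv_config, cfg_args),
        patient_ids = meta$patient_id
      )
      state$selection <- sel
      path <- file.path(out_dir, "selection.json")
      jsonlite::write_json(
        list(
          selected_proteins = sel$selected_proteins,
          n_misclassified = sel$n_misclassified,
          per_sample_probability = as.list(sel$per_sample_probability)
        ),
        path,
        auto_unbox = TRUE, digits = NA
      )
      record("select", path)
    })
  }

  if (ok && "evaluate" %in% stages && !is.null(state$selection)) {
    run_stage("evaluate", function() {
      markers <- state$selection$selected_proteins
      vals <- complete_submatrix(markers)
      panel_fit <- fit_logistic_panel(vals, meta$group)
      auc <- roc_auc(panel_fit$score, meta$group)
      ci <- bootstrap_auc_ci(panel_fit$score, meta$group,
        seed = sub_seed(5)
      )
      crit <- optimal_criterion(panel_fit$score, meta$group)
      path <- file.path(out_dir, "roc.json")
      jsonlite::write_json(
        list(
          markers = markers, auc = auc,
          ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
          criterion = crit$criterion,
          sensitivity = crit$sensitivity, specificity = crit$specificity
        ),
        path,
        auto_unbox = TRUE, digits = NA
      )
      record("evaluate", path)
    })
  }

  if ("trajectories" %in% stages && !is.null(state$selection)) {
    run_stage("trajectories", function() {
      markers <- state$selection$selected_proteins
      fits <- lapply(markers, function(pid) {
        v <- state$matrix$values[pid, ]
        okv <- !is.na(v)
        fit <- fit_random_slope_model(
          v[okv], meta$months_from_baseline[okv],
          meta$patient_id[okv], meta$group[okv],
          meta$age_at_onset[okv]
        )
        base <- meta$visit_index == 0 & okv
        list(
          protein_id = pid,
          slope = as.list(fit$fixed_slope),
          slope_p = as.list(fit$slope_p_value),
          converged = fit$converged,
          baseline_p = baseline_compare(v[base], meta$group[base])
        )
      })
      path <- file.path(out_dir, "trajectories.json")
      jsonlite::write_json(fits, path, auto_unbox = TRUE, digits = NA)
      record("trajectories", path)
    })
  }

  if ("mi" %in% stages) {
    run_stage("mi", function() {
      k <- if (is.null(config$mi$k)) 20 else config$mi$k
      k <- min(k, nrow(state$matrix$values))
      ranking <- rank_by_mi(state$matrix, meta$group, k = k)
      path <- file.path(out_dir, "mi_ranking.tsv")
      utils::write.table(ranking, path,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      record("mi", path)
    })
  }

  if ("state" %in% stages) {
    run_stage("state", function() {
      traj <- pc1_trajectories(state$matrix, meta)
      fits <- fit_ou(traj)
      vb <- variance_biomarker(traj)
      t_back <- config$state$t_back_months
      if (is.null(t_back)) t_back <- 30
      n_paths <- config$state$n_paths
      if (is.null(n_paths)) n_paths <- 200
      back <- lapply(names(fits), function(g) {
        x0 <- mean(traj$state[traj$group == g &
          traj$time == 0])
        b <- backcast(fits[[g]]$params, x0, t_back, n_paths,
          seed = sub_seed(8)
        )
        list(group = g, path_variance = mean(apply(b$states, 2, stats::var)))
      })
      path <- file.path(out_dir, "state_transition.json")
      jsonlite::write_json(
        list(
          fits = lapply(fits, function(f) {
            list(
              theta = f$params$theta, mu = f$params$mu,
              beta_inv = f$params$beta_inv, converged = f$converged
            )
          }),
          variance_biomarker = list(
            ratio = vb$ratio,
            group_stats = as.list(vb$group_stats)
          ),
          backcast = back
        ),
        path,
        auto_unbox = TRUE, digits = NA
      )
      record("state", path)
    })
  }

  finish_manifest(manifest, out_dir)
}

finish_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
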