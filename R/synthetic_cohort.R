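#' Specification of a synthetic longitudinal CSF cohort
#'
#' Parameters of the synthetic-cohort generator. Defaults emulate the
#' discovery-cohort design this package targets: 6 fast-progressing (FP)
#' and 5 slow-progressing (SP) ALS patients, 3-5 clinic visits each over
#' roughly 6-35 months, ~1,150 quantified proteins of which a subset
#' carries a stable FP-vs-SP group shift with near-zero slope over time,
#' larger visit-to-visit proteome fluctuation in FP than SP, additive
#' batch structure, and intensity-dependent (MNAR-weighted) missingness.
#'
#' @param n_fast,n_slow Number of fast / slow progressing patients.
#' @param visits_per_patient Integer range `c(min, max)` of visits.
#' @param visit_spacing_months Mean gap between consecutive visits
#'   (months); individual gaps are drawn uniformly within +/-40% of it.
#' @param n_proteins Total proteins quantified.
#' @param n_signal_proteins Proteins carrying a true group effect.
#' @param group_effect_log2 Magnitude of the FP-minus-SP mean shift on the
#'   log2 scale for signal proteins (direction alternates across signal
#'   proteins so both up- and down-in-FP markers exist).
#' @param within_patient_sd_fast,within_patient_sd_slow Visit-to-visit
#'   noise SD (log2 units) per group; the FP value exceeds the SP value
#'   when emulating the elevated proteome variance of fast progressors.
#' @param patient_random_effect_sd SD of the per-patient, per-protein
#'   random offset (biological between-patient variation).
#' @param batch_count Number of processing batches.
#' @param batch_effect_sd SD of additive per-protein batch offsets.
#' @param missing_rate Overall expected fraction of missing entries.
#' @param missing_mnar_weight In `[0, 1]`: 0 = missing completely at
#'   random, 1 = fully intensity-dependent (low-abundance entries more
#'   likely missing), blended linearly in between.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   cohorts.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_fast = 6, n_slow = 5,
                        visits_per_patient = c(3, 5),
                        visit_spacing_months = 6,
                        n_proteins = 1150,
                        n_signal_proteins = 50,
                        group_effect_log2 = 1.5,
                        within_patient_sd_fast = 0.9,
                        within_patient_sd_slow = 0.3,
                        patient_random_effect_sd = 0.4,
                        batch_count = 3,
                        batch_effect_sd = 0.3,
                        missing_rate = 0,
                        missing_mnar_weight = 0.5,
                        seed = 1) {
  spec <- list(
    n_fast = n_fast, n_slow = n_slow,
    visits_per_patient = visits_per_patient,
    visit_spacing_months = visit_spacing_months,
    n_proteins = n_proteins,
    n_signal_proteins = n_signal_proteins,
    group_effect_log2 = group_effect_log2,
    within_patient_sd_fast = within_patient_sd_fast,
    within_patient_sd_slow = within_patient_sd_slow,
    patient_random_effect_sd = patient_random_effect_sd,
    batch_count = batch_count,
    batch_effect_sd = batch_effect_sd,
    missing_rate = missing_rate,
    missing_mnar_weight = missing_mnar_weight,
    seed = seed
  )
  counts <- c(
    "n_fast", "n_slow", "n_proteins", "n_signal_proteins", "batch_count"
  )
  for (f in counts) {
    v <- spec[[f]]
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      stop("`", f, "` must be a single nonnegative integer", call. = FALSE)
    }
  }
  if (spec$n_signal_proteins > spec$n_proteins) {
    stop("n_signal_proteins must not exceed n_proteins", call. = FALSE)
  }
  if (spec$missing_rate < 0 || spec$missing_rate > 1) {
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  }
  if (spec$missing_mnar_weight < 0 || spec$missing_mnar_weight > 1) {
    stop("missing_mnar_weight must lie in [0, 1]", call. = FALSE)
  }
  if (length(spec$visits_per_patient) != 2 ||
    spec$visits_per_patient[1] < 2 ||
    spec$visits_per_patient[1] > spec$visits_per_patient[2]) {
    stop("visits_per_patient must be a range c(min, max) with min >= 2",
      call. = FALSE
    )
  }
  positive <- c("visit_spacing_months", "within_patient_sd_fast",
                "within_patient_sd_slow")
  for (f in positive) {
    if (spec[[f]] <= 0) stop("`", f, "` must be positive", call. = FALSE)
  }
  if (spec$batch_effect_sd < 0 || spec$patient_random_effect_sd < 0) {
    stop("effect SDs must be nonnegative", call. = FALSE)
  }
  class(spec) <- "cohort_spec"
  spec
}

#' Draw ALSFRS-R progression slopes for a synthetic cohort
#'
#' Monthly ALSFRS-R decline rates: fast progressors are drawn uniformly
#' from `[1.0, 2.7]` units/month and slow progressors from `[0.0, 0.48]`,
#' ranges that bracket the observed discovery- and validation-cohort
#' slopes. Every fast slope is `>= 1` and every slow slope `< 0.5` by
#' construction, so [progression_label()] reproduces the requested group
#' sizes exactly.
#'
#' @param n_fast,n_slow Number of fast / slow progressors.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_fast + n_slow` (fast first).
#' @export
generate_alsfrsr_slopes <- function(n_fast, n_slow, seed = NULL) {
  if (n_fast < 0 || n_slow < 0) stop("counts must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  c(
    stats::runif(n_fast, 1.0, 2.7),
    stats::runif(n_slow, 0.0, 0.48)
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates a protein-by-sample log2 abundance matrix plus sample
#' metadata with the structure the downstream analyses assume. Each entry
#' is built additively from a protein baseline, a constant group shift for
#' signal proteins (no slope over time, matching markers that separate
#' groups yet remain flat within patients), a per-patient random offset,
#' an additive per-protein batch offset, and visit-to-visit noise whose SD
#' differs by progression group. Entries are then removed with probability
#' blending uniform and intensity-ranked (low-abundance-biased)
#' missingness. FP/SP labels derive from generated ALSFRS-R slopes via
#' [progression_label()].
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `matrix` (an [abundance_matrix()],
#'   `log2` scale), `metadata` (data frame, see [validate_metadata()]),
#'   and `truth` (signal protein IDs and their effect directions, for
#'   recovery studies).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  set.seed(spec$seed)

  n_pat <- spec$n_fast + spec$n_slow
  patient_id <- c(
    sprintf("F%02d", seq_len(spec$n_fast)),
    sprintf("S%02d", seq_len(spec$n_slow))
  )
  group <- rep(c("FP", "SP"), c(spec$n_fast, spec$n_slow))
  slopes <- generate_alsfrsr_slopes(spec$n_fast, spec$n_slow)
  sex <- sample(c("M", "F"), n_pat, replace = TRUE)
  age_at_onset <- round(pmin(80, pmax(25, stats::rnorm(n_pat, 54, 11))))
  onset_site <- sample(c("Limb", "Bulbar"), n_pat,
    replace = TRUE, prob = c(0.85, 0.15)
  )

  visit_choices <- seq(spec$visits_per_patient[1], spec$visits_per_patient[2])
  n_visits <- visit_choices[sample.int(length(visit_choices), n_pat,
    replace = TRUE
  )]

  meta <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
    nv <- n_visits[i]
    gaps <- stats::runif(nv - 1, 0.6, 1.4) * spec$visit_spacing_months
    data.frame(
      sample_id = sprintf("%s_V%d", patient_id[i], seq_len(nv)),
      patient_id = patient_id[i],
      visit_index = seq_len(nv) - 1L,
      months_from_baseline = c(0, cumsum(gaps)),
      batch = NA_character_,
      sex = sex[i],
      age_at_onset = age_at_onset[i],
      onset_site = onset_site[i],
      alsfrsr_slope = slopes[i],
      group = group[i],
      stringsAsFactors = FALSE
    )
  }))
  rownames(meta) <- NULL
  n_samp <- nrow(meta)
  meta$batch <- sprintf("B%d", sample(rep_len(
    seq_len(spec$batch_count), n_samp
  )))

  prot <- sprintf("P%04d", seq_len(spec$n_proteins))
  n_sig <- spec$n_signal_proteins
  signal <- prot[seq_len(n_sig)]
  direction <- if (n_sig > 0) rep_len(c(1, -1), n_sig) else numeric(0)

  baseline <- stats::rnorm(spec$n_proteins, 20, 2)
  values <- matrix(baseline,
    nrow = spec$n_proteins, ncol = n_samp,
    dimnames = list(prot, meta$sample_id)
  )

  # constant group shift: +/- effect/2 so FP - SP equals the stated effect
  if (n_sig > 0) {
    shift <- direction * spec$group_effect_log2 / 2
    is_fp <- meta$group == "FP"
    values[seq_len(n_sig), is_fp] <- values[seq_len(n_sig), is_fp] + shift
    values[seq_len(n_sig), !is_fp] <- values[seq_len(n_sig), !is_fp] - shift
  }

  pat_effect <- matrix(
    stats::rnorm(spec$n_proteins * n_pat, 0, spec$patient_random_effect_sd),
    nrow = spec$n_proteins, dimnames = list(prot, patient_id)
  )
  values <- values + pat_effect[, meta$patient_id]

  batches <- sort(unique(meta$batch))
  batch_effect <- matrix(
    stats::rnorm(spec$n_proteins * length(batches), 0, spec$batch_effect_sd),
    nrow = spec$n_proteins, dimnames = list(prot, batches)
  )
  values <- values + batch_effect[, meta$batch]

  noise_sd <- ifelse(meta$group == "FP",
    spec$within_patient_sd_fast, spec$within_patient_sd_slow
  )
  values <- values + matrix(
    stats::rnorm(spec$n_proteins * n_samp),
    nrow = spec$n_proteins
  ) * rep(noise_sd, each = spec$n_proteins)

  if (spec$missing_rate > 0) {
    w <- spec$missing_mnar_weight
    r <- spec$missing_rate
    # rank weight in (0, 1), mean 1/2, largest for the lowest intensities
    u <- (length(values) + 1 - rank(values, ties.method = "first")) /
      (length(values) + 1)
    p_miss <- pmin(1, (1 - w) * r + w * r * 2 * u)
    drop <- stats::runif(length(values)) < p_miss
    values[drop] <- NA_real_
  }

  list(
    matrix = abundance_matrix(values, scale = "log2"),
    metadata = meta,
    truth = list(signal_proteins = signal, direction = direction)
  )
}

#' Write / read a cohort as TSV files
#'
#' `write_cohort()` serializes an abundance matrix and its metadata to
#' `abundance.tsv` (proteins as rows, first column `protein_id`) and
#' `metadata.tsv` (one row per sample) in `dir`. Missing entries are
#' written as `NA`. Values are written with 17 significant digits so the
#' round trip is lossless for doubles. `read_cohort()` restores both and
#' validates IDs.
#'
#' @param matrix An [abundance_matrix()] (or plain matrix).
#' @param metadata Sample metadata data frame.
#' @param dir Directory path (created if absent).
#' @return `write_cohort()` the directory invisibly; `read_cohort()` a
#'   list with `matrix` and `metadata`.
#' @export
write_cohort <- function(matrix, metadata, dir) {
  matrix <- as_abundance(matrix)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vals <- matrix$values
  chr <- formatC(vals, format = "g", digits = 17)
  chr[is.na(vals)] <- "NA"
  ab <- data.frame(protein_id = rownames(vals), chr,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(ab, file.path(dir, "abundance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(paste0("# scale: ", matrix$scale), file.path(dir, "scale.txt"))
  utils::write.table(metadata, file.path(dir, "metadata.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ab_path <- file.path(dir, "abundance.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(ab_path) || !file.exists(meta_path)) {
    stop("missing abundance.tsv or metadata.tsv in ", dir, call. = FALSE)
  }
  ab <- utils::read.delim(ab_path, check.names = FALSE,
    colClasses = "character"
  )
  if (names(ab)[1] != "protein_id") {
    stop("malformed abundance.tsv header (expected first column protein_id)",
      call. = FALSE
    )
  }
  vals <- as.matrix(ab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ab$protein_id
  scale <- "log2"
  scale_path <- file.path(dir, "scale.txt")
  if (file.exists(scale_path)) {
    scale <- sub("^# scale: ", "", readLines(scale_path)[1])
  }
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  validate_metadata(meta)
  if (!identical(colnames(vals), meta$sample_id)) {
    if (!setequal(colnames(vals), meta$sample_id)) {
      stop("abundance and metadata sample IDs disagree", call. = FALSE)
    }
    meta <- meta[match(colnames(vals), meta$sample_id), ]
    rownames(meta) <- NULL
  }
  list(matrix = abundance_matrix(vals, scale = scale), metadata = meta)
}
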