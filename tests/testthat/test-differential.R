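test_that("progression labels apply the unit/month thresholds", {
  expect_equal(progression_label(1.69), "fast")
  expect_equal(progression_label(0.32), "slow")
  expect_equal(progression_label(1.00), "fast") # boundary inclusive
  expect_equal(progression_label(0.75), "intermediate")
  expect_equal(
    progression_label(c(0.49999, 0.5, 2.7)),
    c("slow", "intermediate", "fast")
  )
  expect_error(progression_label(NA_real_), "missing")
  expect_error(progression_label(-0.1), "nonnegative")
})

mat_of <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("P", seq_along(rows))
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  abundance_matrix(m)
}

test_that("per-protein Mann-Whitney matches hand enumeration", {
  m <- mat_of(list(
    c(1, 2, 3, 4, 5, 6), # A = {1,2,3}, B = {4,5,6}
    c(5, 5, 5, 5, 5, 5) # identical groups
  ))
  res <- mann_whitney_bh(m, rep(c("A", "B"), each = 3), group_a = "A")
  expect_equal(res$p_raw[1], 0.1) # 2 * (1 / C(6,3))
  expect_equal(res$log2_fc[1], -3)
  expect_equal(res$p_raw[2], 1)
  expect_equal(res$log2_fc[2], 0)
  expect_equal(res$direction[1], "up_in_B")
})

test_that("BH adjustment follows the step-up rule and is monotone", {
  # four proteins engineered to give distinct raw p-values, then compare
  # the adjusted values against p.adjust on the same raw vector
  set.seed(41)
  rows <- lapply(1:30, function(i) rnorm(14, 20))
  m <- mat_of(rows)
  res <- mann_whitney_bh(m, rep(c("A", "B"), each = 7), group_a = "A")
  expect_equal(res$p_adj, p.adjust(res$p_raw, "BH"))
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
  # frozen step-up example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("proteins untestable in a group are excluded from the BH family", {
  m <- mat_of(list(
    c(1, 2, 3, 10, 11, 12),
    c(1, NA, NA, 10, 11, 12) # one observed value in group A
  ))
  res <- mann_whitney_bh(m, rep(c("A", "B"), each = 3), group_a = "A")
  expect_false(res$testable[2])
  expect_true(is.na(res$p_adj[2]))
  expect_equal(res$p_adj[1], res$p_raw[1]) # BH family of size 1
})

test_that("four-way panel recovers planted signal and respects direction", {
  co <- generate_cohort(cohort_spec(
    n_fast = 12, n_slow = 12, visits_per_patient = c(3, 4),
    n_proteins = 400, n_signal_proteins = 20, group_effect_log2 = 2,
    within_patient_sd_fast = 0.35, within_patient_sd_slow = 0.25,
    patient_random_effect_sd = 0.25, batch_effect_sd = 0, seed = 42
  ))
  res <- four_way_panel(co$matrix, co$metadata)
  truth <- co$truth$signal_proteins
  expect_gte(length(intersect(res$panel, truth)) / length(truth), 0.9)
  expect_equal(length(setdiff(res$panel, truth)), 0)
  # intersection panel contained in each single-comparison set
  for (cmp in res$comparisons) {
    expect_true(all(res$panel %in% cmp$protein_id[cmp$significant]))
  }
})

test_that("null cohorts give an empty panel", {
  co <- generate_cohort(cohort_spec(
    n_fast = 12, n_slow = 12, n_proteins = 300, n_signal_proteins = 0,
    within_patient_sd_fast = 0.3, within_patient_sd_slow = 0.3,
    seed = 43
  ))
  res <- four_way_panel(co$matrix, co$metadata)
  expect_length(res$panel, 0)
})

test_that("a protein significant in only three comparisons is excluded", {
  # planted shift present at both visits for FP except the last visit,
  # killing the FP-last comparisons
  co <- generate_cohort(cohort_spec(
    n_fast = 12, n_slow = 12, visits_per_patient = c(3, 3),
    n_proteins = 60, n_signal_proteins = 1, group_effect_log2 = 3,
    within_patient_sd_fast = 0.2, within_patient_sd_slow = 0.2,
    patient_random_effect_sd = 0.1, batch_effect_sd = 0, seed = 44
  ))
  vals <- co$matrix$values
  meta <- co$metadata
  last_fp <- unlist(lapply(split(meta, meta$patient_id), function(rows) {
    if (rows$group[1] != "FP") {
      return(NULL)
    }
    rows$sample_id[which.max(rows$visit_index)]
  }))
  vals["P0001", last_fp] <- vals["P0001", last_fp] - 3 # cancel the shift
  res <- four_way_panel(abundance_matrix(vals), meta)
  sig1 <- vapply(res$comparisons, function(cmp) {
    cmp$significant[cmp$protein_id == "P0001"]
  }, TRUE)
  expect_equal(sum(sig1), 2) # the two FP-first comparisons only
  expect_false("P0001" %in% res$panel)
})

test_that("label permutation keeps the significant fraction near nominal", {
  co <- generate_cohort(cohort_spec(
    n_fast = 6, n_slow = 5, visits_per_patient = c(3, 3),
    n_proteins = 150, n_signal_proteins = 30, group_effect_log2 = 2,
    seed = 45
  ))
  meta <- co$metadata
  base <- meta[meta$visit_index == 0, ]
  vals <- co$matrix$values[, base$sample_id]
  set.seed(46)
  frac_sig <- replicate(60, {
    perm <- sample(base$group)
    grp <- perm[match(base$patient_id, base$patient_id)]
    res <- mann_whitney_bh(abundance_matrix(vals), perm, group_a = "FP",
      alpha = 0.05, fc_threshold = 1
    )
    mean(res$significant)
  })
  expect_lte(mean(frac_sig), 0.05)
})
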