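# compact cohorts reused across tests
tiny_cohort <- function(seed = 1, n_proteins = 120, n_signal = 10,
                        effect = 2, sd_fast = 0.3, sd_slow = 0.2,
                        missing_rate = 0, ...) {
  generate_cohort(cohort_spec(
    n_proteins = n_proteins, n_signal_proteins = n_signal,
    group_effect_log2 = effect,
    within_patient_sd_fast = sd_fast, within_patient_sd_slow = sd_slow,
    patient_random_effect_sd = 0.2, batch_effect_sd = 0.2,
    missing_rate = missing_rate, seed = seed, ...
  ))
}

# brute-force two-sided Mann-Whitney by enumerating assignments and
# counting pairwise wins (independent of the rank-sum implementation)
bf_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  obs <- u_of(a, b)
  sets <- utils::combn(n, na)
  us <- apply(sets, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  tol <- 1e-9
  min(1, 2 * min(mean(us <= obs + tol), mean(us >= obs - tol)))
}

# brute-force Fisher 2x2 by enumerating tables with fixed margins
bf_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }, 0)
  obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
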