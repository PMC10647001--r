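test_that("ROC AUC equals the normalized Mann-Whitney U", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c("a", "a", "b", "b")), 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c("a", "b", "a", "b")), 0.75)
  expect_equal(roc_auc(rep(1, 6), rep(c("a", "b"), 3)), 0.5)
  # complement under score negation
  set.seed(51)
  s <- rnorm(30)
  l <- rep(c("a", "b"), 15)
  expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
  expect_error(roc_auc(1:3, c("a", "a", "a")), "both classes")
})

test_that("rank AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(52)
  for (i in 1:5) {
    s <- rnorm(40)
    l <- sample(rep(c("a", "b"), 20))
    ref <- as.numeric(pROC::auc(pROC::roc(l, s,
      levels = c("a", "b"), direction = "<", quiet = TRUE
    )))
    expect_equal(roc_auc(s, l, positive = "b"), ref)
  }
})

test_that("logistic panel scores behave under separation and rescaling", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), nrow = 1,
    dimnames = list("m1", paste0("S", 1:6))
  )
  l <- rep(c("SP", "FP"), each = 3)
  fit <- fit_logistic_panel(x, l)
  expect_true(fit$separation)
  expect_equal(roc_auc(fit$score, l), 1.0)

  set.seed(53)
  x2 <- matrix(rnorm(40), nrow = 1, dimnames = list("m1", paste0("S", 1:40)))
  l2 <- sample(rep(c("SP", "FP"), 20))
  f_a <- fit_logistic_panel(x2, l2)
  f_b <- fit_logistic_panel(x2 * 7 - 100, l2)
  expect_equal(roc_auc(f_a$score, l2), roc_auc(f_b$score, l2))
})

test_that("null-marker AUC concentrates around one half", {
  set.seed(54)
  aucs <- replicate(100, {
    x <- rnorm(40)
    l <- sample(rep(c("SP", "FP"), 20))
    roc_auc(x, l)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("bootstrap CI is seeded, ordered and degenerate when perfect", {
  set.seed(55)
  s <- c(rnorm(30, 0), rnorm(30, 10))
  l <- rep(c("SP", "FP"), each = 30)
  ci <- bootstrap_auc_ci(s, l, n_boot = 200, seed = 9)
  expect_equal(unname(ci), c(1, 1))
  s2 <- rnorm(60)
  ci_a <- bootstrap_auc_ci(s2, l, n_boot = 200, seed = 10)
  ci_b <- bootstrap_auc_ci(s2, l, n_boot = 200, seed = 10)
  expect_identical(ci_a, ci_b)
  expect_lte(ci_a[["ci_low"]], roc_auc(s2, l))
  expect_gte(ci_a[["ci_high"]], roc_auc(s2, l))
  expect_error(bootstrap_auc_ci(s2, l, n_boot = 50), "at least 100")
})

test_that("bootstrap interval covers the null AUC at near-nominal rate", {
  set.seed(56)
  l <- rep(c("SP", "FP"), 20)
  cover <- replicate(120, {
    s <- rnorm(40)
    ci <- bootstrap_auc_ci(s, l, n_boot = 200)
    ci[["ci_low"]] <= 0.5 && 0.5 <= ci[["ci_high"]]
  })
  expect_gte(mean(cover), 0.85) # percentile CI, modest n
})

test_that("Youden criterion matches an exhaustive threshold search", {
  expect_youden_optimal <- function(scores, labels) {
    got <- optimal_criterion(scores, labels, positive = "FP")
    pos <- labels == "FP"
    best_j <- max(vapply(c(scores, -Inf, Inf), function(cut) {
      sum(scores >= cut & pos) / sum(pos) +
        sum(scores < cut & !pos) / sum(!pos) - 1
    }, 0))
    expect_equal(got$youden, best_j, tolerance = 1e-12)
    expect_equal(
      got$sensitivity + got$specificity - 1, got$youden,
      tolerance = 1e-12
    )
  }
  expect_youden_optimal(
    c(0.1, 0.2, 0.8, 0.9), c("SP", "SP", "FP", "FP")
  )
  got <- optimal_criterion(
    c(0.1, 0.2, 0.8, 0.9), c("SP", "SP", "FP", "FP"),
    positive = "FP"
  )
  expect_equal(got$sensitivity, 1)
  expect_equal(got$specificity, 1)
  expect_gt(got$criterion, 0.2)
  expect_lte(got$criterion, 0.8)
  # all-tied scores carry no information
  tied <- optimal_criterion(rep(0.4, 6), rep(c("SP", "FP"), 3))
  expect_equal(tied$youden, 0)
  set.seed(57)
  for (i in 1:20) {
    s <- round(runif(6), 2)
    l <- sample(rep(c("SP", "FP"), 3))
    expect_youden_optimal(s, l)
  }
})

test_that("Fisher exact matches enumeration and published demographics", {
  expect_equal(fisher_exact_2x2(matrix(c(4, 2, 2, 3), 2, 2,
    byrow = TRUE
  )), 0.5670996, tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  # invariances: transpose and simultaneous row+column swap
  set.seed(58)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2, 2)
    p <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(t(tab)), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), p, tolerance = 1e-12)
    expect_equal(p, bf_fisher(tab), tolerance = 1e-12)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("exact Mann-Whitney reproduces enumeration oracles", {
  # published discovery-cohort ages: tie at 56 across groups
  sp_age <- c(43, 53, 31, 56, 34)
  fp_age <- c(56, 65, 54, 59, 52, 40)
  expect_equal(exact_mann_whitney(sp_age, fp_age), 64 / 462,
    tolerance = 1e-12
  )
  expect_equal(exact_mann_whitney(c(1, 2), c(1, 2)), 1.0)
  expect_equal(exact_mann_whitney(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # agreement with wilcox.test exact p when there are no ties
  set.seed(59)
  for (i in 1:10) {
    a <- rnorm(5)
    b <- rnorm(6)
    expect_equal(
      exact_mann_whitney(a, b),
      wilcox.test(a, b, exact = TRUE)$p.value,
      tolerance = 1e-12
    )
  }
})

test_that("exact tests agree with brute force on random small instances", {
  set.seed(60)
  for (i in 1:100) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    vals <- sample(1:6, na + nb, replace = TRUE) # heavy ties
    a <- vals[seq_len(na)]
    b <- vals[-seq_len(na)]
    expect_equal(exact_mann_whitney(a, b), bf_mann_whitney(a, b),
      tolerance = 1e-12
    )
  }
})
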