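test_that("AUC handles separation and full ties, and matches pair counting", {
  expect_equal(roc_and_auc(c(1, 2, 3, 10, 11), c(-1, -1, -1, 1, 1))$auc, 1)
  expect_equal(roc_and_auc(rep(2, 6), c(1, 1, 1, -1, -1, -1))$auc, 0.5)
  expect_error(roc_and_auc(1:4, rep(1, 4)), "both classes")
  set.seed(1)
  for (case in 1:100) {
    n <- sample(5:30, 1)
    labels <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(-1, 1)
    scores <- sample(1:10, n, replace = TRUE) + rnorm(n, 0, 0.01 * (case %% 2))
    expect_equal(roc_and_auc(scores, labels)$auc, auc_pairs(scores, labels),
                 info = sprintf("case %d", case))
  }
})

test_that("the AUC standard error follows the Hanley-McNeil formula", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.9, 0.7)
  labels <- c(-1, -1, -1, 1, 1, 1)
  ra <- roc_and_auc(scores, labels)
  a <- ra$auc
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 2 * (q1 - a^2) + 2 * (q2 - a^2)) / 9)
  expect_equal(ra$auc_se, se)
})

test_that("operating point maximizes Youden with specificity tie-break", {
  ra <- roc_and_auc(c(1, 2, 3, 10, 11), c(-1, -1, -1, 1, 1))
  op <- pick_operating_point(ra$roc)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  # monotone transform invariance
  sc <- c(0.2, 0.5, 0.9, 0.4, 0.6, 0.8)
  lb <- c(-1, -1, 1, -1, 1, 1)
  op1 <- pick_operating_point(roc_and_auc(sc, lb)$roc)
  op2 <- pick_operating_point(roc_and_auc(exp(5 * sc), lb)$roc)
  expect_equal(op1$sensitivity, op2$sensitivity)
  expect_equal(op1$specificity, op2$specificity)
})

test_that("symmetric overlapping score distributions put the cut near zero", {
  set.seed(2)
  scores <- c(rnorm(2000, 1), rnorm(2000, -1))
  labels <- c(rep(1, 2000), rep(-1, 2000))
  op <- pick_operating_point(roc_and_auc(scores, labels)$roc)
  expect_lt(abs(op$threshold), 0.2)
})

test_that("balanced error rate equals confusion-matrix arithmetic", {
  sc <- c(5, 4, 3, 2, 1)
  lb <- c(1, 1, -1, -1, -1)
  expect_equal(balanced_error_rate(sc, lb, 3.5), 0)
  expect_equal(balanced_error_rate(sc, lb, -10), 0.5)  # everything positive
  # one FN (sens 1/2), one FP (spec 2/3) at threshold 4.5
  expect_equal(balanced_error_rate(sc, lb, 4.5), (1 / 2 + 0) / 2)
  expect_equal(balanced_error_rate(sc, lb, 2.5), (0 + 1 / 3) / 2)
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (case in 1:20) {
    n <- 40
    labels <- c(rep(1, 15), rep(-1, 25))
    scores <- rnorm(n) + 0.8 * (labels > 0)
    ref <- as.numeric(suppressMessages(pROC::auc(labels > 0, scores)))
    expect_equal(roc_and_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

make_loo_fixture <- function(seed, n_pos = 5, n_neg = 10, p = 6,
                             effect = 3) {
  set.seed(seed)
  n <- n_pos + n_neg
  labels <- setNames(c(rep(1, n_pos), rep(-1, n_neg)),
                     sprintf("S%02d", seq_len(n)))
  X <- matrix(rlnorm(n * p, 0, 0.3), n, dimnames = list(names(labels), NULL))
  X[labels > 0, 1] <- X[labels > 0, 1] * exp(effect)
  list(pm = as_peak_matrix(X), labels = labels)
}

test_that("LOO is deterministic and conserves occurrence counts", {
  fx <- make_loo_fixture(4)
  g <- 10^c(-1, 0, 1)
  a <- loo_pipeline(fx$pm, fx$labels, k_max = 3, gamma_grid = g)
  b <- loo_pipeline(fx$pm, fx$labels, k_max = 3, gamma_grid = g)
  expect_identical(a$records, b$records)
  occ <- summarize_occurrences(a)
  expect_equal(sum(occ$occurrence), sum(a$records$k))
  expect_true(all(occ$occurrence <= nrow(a$records)))
  expect_equal(nrow(a$records), 15)
})

test_that("a strong planted marker dominates LOO selection", {
  fx <- make_loo_fixture(5)
  loo <- loo_pipeline(fx$pm, fx$labels, k_max = 3,
                      gamma_grid = 10^c(-1, 0, 1))
  expect_equal(loo$median_k, 1)
  occ <- summarize_occurrences(loo)
  expect_equal(occ$column[1], colnames(fx$pm$intensity)[1])
  expect_gte(occ$occurrence[1], 0.9 * nrow(loo$records))
  expect_gt(loo$auc, 0.9)
})

test_that("with no selection freedom, paper and nested modes coincide", {
  fx <- make_loo_fixture(6)
  a <- loo_pipeline(fx$pm, fx$labels, k_max = 1, gamma_grid = 1,
                    selection_mode = "paper")
  b <- loo_pipeline(fx$pm, fx$labels, k_max = 1, gamma_grid = 1,
                    selection_mode = "nested")
  expect_equal(a$records$score, b$records$score, tolerance = 1e-10)
  expect_equal(a$auc, b$auc)
})

test_that("on pure noise, nested LOO is calibrated and paper mode is optimistic", {
  g <- 10^c(-1, 0, 1)
  nested <- numeric(80)
  paper <- numeric(80)
  for (s in 1:80) {
    fx <- make_loo_fixture(1000 + s, n_pos = 6, n_neg = 12, p = 8,
                           effect = 0)
    suppressWarnings({
      nested[s] <- loo_pipeline(fx$pm, fx$labels, k_max = 3, gamma_grid = g,
                                selection_mode = "nested")$auc
      paper[s] <- loo_pipeline(fx$pm, fx$labels, k_max = 3, gamma_grid = g,
                               selection_mode = "paper")$auc
    })
  }
  expect_lt(abs(mean(nested) - 0.5), 0.07)
  expect_gt(mean(paper), mean(nested))
})

test_that("a fold without significant peaks falls back to the best single peak", {
  fx <- make_loo_fixture(7, n_pos = 3, n_neg = 5, p = 3, effect = 0)
  expect_warning(
    loo <- loo_pipeline(fx$pm, fx$labels, k_max = 2, gamma_grid = 1),
    "lowest-p")
  expect_true(all(loo$records$k >= 1))
})
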