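test_that("metrics hit their closed-form values on degenerate classifiers", {
  y <- c(rep(1L, 3), rep(0L, 7))
  perfect <- c(rep(0.9, 3), rep(0.1, 7))
  m <- compute_metrics(y, perfect)
  expect_equal(m$auc, 100)
  expect_equal(m$accuracy, 100)
  expect_equal(m$balanced_accuracy, 100)
  expect_equal(m$f1, 100)

  # constant scores: chance AUC via tie handling; all-majority labels give
  # 50% balanced accuracy on imbalanced data
  mc <- compute_metrics(y, rep(0.2, 10))
  expect_equal(mc$auc, 50)
  expect_equal(mc$balanced_accuracy, 50)
  expect_equal(mc$f1, 0)
  expect_equal(mc$accuracy, 70)

  expect_error(compute_metrics(rep(1L, 5), runif(5)), "single class")
})

test_that("AUC equals the Mann-Whitney pair count and is monotone-invariant", {
  brute_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(pairs)
  }
  withr::with_seed(12, {
    for (i in 1:100) {
      n <- sample(4:10, 1)
      y <- c(1L, 0L, rbinom(n - 2, 1, 0.5))
      s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
      expect_equal(compute_metrics(y, s)$auc, 100 * brute_auc(y, s),
                   tolerance = 1e-12)
      # strictly monotone transforms leave AUC unchanged
      expect_equal(compute_metrics(y, plogis(5 * s - 2))$auc,
                   compute_metrics(y, s)$auc)
    }
    # independent library cross-check on a larger vector
    y <- rbinom(300, 1, 0.3)
    s <- runif(300) + 0.5 * y
    expect_equal(compute_metrics(y, s)$auc,
                 100 * as.numeric(pROC::auc(y, s, quiet = TRUE)),
                 tolerance = 1e-10)
  })
})

test_that("balanced accuracy of label-permuted classifiers concentrates at 50%", {
  withr::with_seed(22, {
    y <- c(rep(1L, 30), rep(0L, 270))
    s <- runif(300)
    bas <- replicate(1000, compute_metrics(sample(y), s)$balanced_accuracy)
    expect_lt(abs(mean(bas) - 50), 1)
  })
})

test_that("the corrected resampled t-test matches its formula and limits", {
  expect_equal(corrected_resampled_ttest(rep(0, 5), 80, 20),
               list(t = 0, p = 1, df = 4, zero_variance = FALSE))

  d <- c(1.2, 0.8, 1.5, 0.9, 1.1)
  res <- corrected_resampled_ttest(d, n_train = 80, n_test = 20)
  t_manual <- mean(d) / sqrt((1 / 5 + 20 / 80) * var(d))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 4), tolerance = 1e-12)

  # vanishing test fraction recovers the standard paired t statistic
  res0 <- corrected_resampled_ttest(d, n_train = 1e9, n_test = 1)
  expect_equal(res0$t, unname(t.test(d)$statistic), tolerance = 1e-6)

  resz <- corrected_resampled_ttest(c(2, 2, 2), 80, 20)
  expect_true(resz$zero_variance)
  expect_equal(resz$p, 0)
})

test_that("Holm-Bonferroni is a step-down adjustment with monotonicity", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  # hand evaluation: sorted (.01,.03,.04) x multipliers (3,2,1) = (.03,.06,.04),
  # running-max gives (.03,.06,.06)
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(rep(0.02, 4)), rep(0.08, 4))
  expect_equal(holm_bonferroni(c(0.5, 0.9)), c(1, 1))

  withr::with_seed(2, {
    p <- runif(10)
    adj <- holm_bonferroni(p)
    expect_true(all(adj >= p))
    expect_false(is.unsorted(adj[order(p)]))   # ordering preserved
    expect_true(all(adj <= 1))
  })
})

test_that("the Friedman test matches the rank-sum formula and is block-order invariant", {
  withr::with_seed(33, {
    m <- matrix(runif(12), 3, 4)   # 3 models x 4 datasets, untied
    res <- friedman_test(m)
    # direct evaluation of the classical statistic
    R <- rowSums(apply(m, 2, function(col) rank(-col)))
    k <- 3; N <- 4
    chi2_manual <- 12 / (N * k * (k + 1)) * sum(R^2) - 3 * N * (k + 1)
    expect_equal(res$chi2, chi2_manual, tolerance = 1e-10)
    expect_equal(res$df, 2)
    expect_equal(res$p, pchisq(chi2_manual, 2, lower.tail = FALSE),
                 tolerance = 1e-10)

    perm <- sample(4)
    expect_equal(friedman_test(m[, perm])$chi2, res$chi2)
  })

  tied <- matrix(5, 4, 3)
  res_tied <- friedman_test(tied)
  expect_equal(res_tied$chi2, 0)
  expect_equal(res_tied$p, 1)
})

test_that("Nemenyi critical differences follow the studentized-range table", {
  expect_equal(round(nemenyi_critical_difference(4, 7, 0.10), 2), 1.58)
  expect_equal(round(nemenyi_critical_difference(4, 7, 0.05), 2), 1.77)
  # CD shrinks to zero as the number of datasets grows
  cds <- vapply(c(5, 10, 50, 200, 5000), function(N) {
    nemenyi_critical_difference(4, N, 0.05)
  }, numeric(1))
  expect_true(all(diff(cds) < 0))
  expect_lt(cds[5], 0.1)
  expect_error(nemenyi_critical_difference(4, 7, 0.2), "not tabulated")
})
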