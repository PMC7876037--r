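test_that("a feature identical to the label is ranked first by all five methods", {
  withr::with_seed(19, {
    n <- 500
    X <- matrix(rnorm(n * 9), n, 9)
    x <- rbinom(n, 1, 0.4)
    X <- cbind(X, x)
    colnames(X) <- sprintf("f%02d", 1:10)
    y <- x
    for (m in RANK_METHODS) {
      expect_equal(unname(rank_features(X, y, m)$rank[["f10"]]), 1L,
                   info = m)
    }
  })
})

test_that("ANOVA ranking reproduces the closed-form F statistic", {
  withr::with_seed(3, {
    n <- 80
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(n, 1, 0.5)
    # independent oracle: F from lm/anova per column
    f_oracle <- vapply(1:3, function(j) {
      stats::anova(stats::lm(X[, j] ~ factor(y)))[["F value"]][1]
    }, numeric(1))
    f_pkg <- trialterm:::anova_f_scores(X, y)
    expect_equal(unname(f_pkg), f_oracle, tolerance = 1e-10)
    rl <- rank_features(X, y, "anova")
    expect_equal(unname(rl$rank[order(-f_oracle)]), 1:3)
  })
})

test_that("estimated MI of an independent feature sits in the permutation null band", {
  withr::with_seed(11, {
    n <- 2000
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.3)
    xd <- discretize_ef(x, 10)
    obs <- trialterm:::mi_disc(xd, y)
    null <- replicate(400, trialterm:::mi_disc(xd, sample(y)))
    expect_lte(obs, quantile(null, 0.975))
    expect_gte(obs, quantile(null, 0.025))
  })
})

test_that("rank lists are permutations and errors are raised on degenerate input", {
  withr::with_seed(4, {
    X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
    X[, 2] <- 1   # constant feature still gets a defined rank
    y <- rbinom(50, 1, 0.5)
    for (m in RANK_METHODS) {
      r <- rank_features(X, y, m)$rank
      expect_setequal(unname(r), 1:4)
    }
    expect_error(rank_features(X, rep(1, 50), "anova"), "both classes")
    X[1, 1] <- NA
    expect_error(rank_features(X, y, "anova"), "missing")
  })
})

test_that("Dowdall aggregation matches the reciprocal-rank arithmetic", {
  mk <- function(method, ranks) {
    structure(list(method = method,
                   rank = stats::setNames(as.integer(ranks), names(ranks))),
              class = "rank_list")
  }
  # single voter: output order equals input order
  single <- mk("anova", c(f1 = 2L, f2 = 1L, f3 = 3L))
  agg1 <- dowdall_aggregate(list(single))
  expect_equal(agg1$order, c("f2", "f1", "f3"))

  # hand-computed reciprocal sums
  l1 <- mk("anova", c(f1 = 1, f2 = 2, f3 = 3))
  l2 <- mk("relieff", c(f1 = 3, f2 = 1, f3 = 2))
  agg <- dowdall_aggregate(list(l1, l2))
  expect_equal(unname(agg$score[c("f1", "f2", "f3")]),
               c(1 + 1 / 3, 1 / 2 + 1, 1 / 3 + 1 / 2), tolerance = 1e-12)
  expect_equal(agg$order, c("f2", "f1", "f3"))

  # many first preferences beat uniformly middling ranks
  ranks_f <- c(1, 100, 100)
  ranks_g <- c(3, 3, 3)
  expect_gt(sum(1 / ranks_f), sum(1 / ranks_g))
  expect_equal(sum(1 / ranks_f), 1.02)
  expect_equal(sum(1 / ranks_g), 1, tolerance = 1e-12)

  # mismatched feature sets are rejected with the difference named
  l3 <- mk("mi", c(f1 = 1, f9 = 2, f3 = 3))
  expect_error(dowdall_aggregate(list(l1, l3)), "f2.*f9|f9.*f2")
})

test_that("aggregation is voter-order invariant and bounded by the method count", {
  withr::with_seed(6, {
    p <- 20
    nm <- sprintf("f%02d", 1:p)
    lists <- lapply(1:4, function(i) {
      structure(list(method = paste0("m", i),
                     rank = stats::setNames(sample(p), nm)),
                class = "rank_list")
    })
    a1 <- dowdall_aggregate(lists)
    a2 <- dowdall_aggregate(rev(lists))
    expect_equal(a1$score, a2$score)
    expect_equal(a1$order, a2$order)
    expect_true(all(a1$score > 0 & a1$score <= 4))
    # unanimous first place attains exactly M
    unanimous <- lapply(lists, function(l) {
      l$rank["f01"] <- 0L; l$rank <- stats::setNames(rank(l$rank), nm); l
    })
    expect_equal(unname(dowdall_aggregate(unanimous)$score["f01"]), 4)
  })
})

test_that("ranking_report mirrors the per-method ranks and aggregate order", {
  withr::with_seed(15, {
    n <- 150
    X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, sprintf("v%d", 1:6)))
    y <- as.integer(X[, 4] > 0)
    rep <- ranking_report(X, y)
    expect_equal(nrow(rep), 6)
    expect_equal(rep$feature[1], "v4")
    expect_equal(rep$aggregate_rank, 1:6)
    expect_true(all(sprintf("rank_%s", RANK_METHODS) %in% names(rep)))
    # dowdall_score column matches the reciprocal sum of the rank columns
    recomputed <- rowSums(1 / as.matrix(rep[sprintf("rank_%s", RANK_METHODS)]))
    expect_equal(rep$dowdall_score, unname(recomputed), tolerance = 1e-12)
  })
})
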