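balanced_cohort <- function() {
  sites <- lapply(c("A", "B"), function(id) {
    site_cohort(id, data.frame(x = rnorm(10)), rep(c(0, 1), each = 5))
  })
  federated_cohort(sites)
}

test_that("fold plans stratify exactly and partition every row", {
  set.seed(1)
  co <- balanced_cohort()
  plan <- build_fold_plan(co, k = 5, seed = 3)
  for (id in c("A", "B")) {
    f <- plan$assignments[[id]]
    lab <- co$sites[[id]]$labels
    expect_identical(sort(unique(f)), 1:5)
    for (i in 1:5) {
      expect_identical(sum(f == i & lab == 1), 1L)
      expect_identical(sum(f == i & lab == 0), 1L)
    }
  }
  # same seed, same plan; union over folds recovers each row exactly once
  expect_identical(plan, build_fold_plan(co, k = 5, seed = 3))
  counts <- rowSums(sapply(1:5, function(i) plan$assignments$A == i))
  expect_true(all(counts == 1))
})

test_that("fold plans stay within one sample of exact class proportions", {
  co <- make_small_cohort(n_sites = 3, n = 157, seed = 17,
                          incidence = c(0.2, 0.35, 0.5))
  plan <- build_fold_plan(co, k = 5, seed = 2)
  for (id in site_ids(co)) {
    lab <- co$sites[[id]]$labels
    f <- plan$assignments[[id]]
    for (cl in 0:1) {
      per_fold <- tabulate(f[lab == cl], nbins = 5)
      expect_lte(max(per_fold) - min(per_fold), 1L)
    }
  }
})

test_that("tiny single-class-starved sites fall back with a warning", {
  sites <- list(
    site_cohort("tiny", data.frame(x = rnorm(6)), c(1, 0, 0, 0, 0, 0)),
    site_cohort("ok", data.frame(x = rnorm(20)), rep(c(0, 1), 10))
  )
  expect_warning(plan <- build_fold_plan(federated_cohort(sites), k = 5,
                                         seed = 1),
                 "non-stratified")
  expect_identical(sort(unique(plan$assignments$tiny)), 1:5)
  expect_error(build_fold_plan(federated_cohort(sites), k = 1), "at least 2")
})

test_that("auroc matches closed forms and the all-pairs oracle", {
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auroc(c(10, 11, 1, 2), c(0, 0, 1, 1)), 0)
  # 8-point toy set with ties
  s <- c(0.1, 0.4, 0.4, 0.4, 0.5, 0.5, 0.7, 0.9)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  expect_equal(auroc(s, y), oracle_auroc(s, y), tolerance = 1e-12)
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auroc(s, y), oracle_auroc(s, y), tolerance = 1e-12)
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("auroc approaches 1/2 under independent scores", {
  set.seed(5)
  s <- runif(20000)
  y <- rbinom(20000, 1, 0.4)
  expect_lt(abs(auroc(s, y) - 0.5), 0.02)
})

test_that("auroc is invariant under strictly monotone score transforms", {
  set.seed(7)
  for (rep in 1:10) {
    s <- rnorm(60)
    y <- c(0, 1, rbinom(58, 1, 0.5))
    a <- auroc(s, y)
    expect_equal(auroc(exp(s), y), a, tolerance = 1e-12)
    expect_equal(auroc(2 * s - 7, y), a, tolerance = 1e-12)
    expect_equal(auroc(rank(s, ties.method = "average"), y), a,
                 tolerance = 1e-12)
  }
})

test_that("auroc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (rep in 1:5) {
    s <- round(runif(50), 2)
    y <- c(0, 1, rbinom(48, 1, 0.3))
    ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
    expect_equal(auroc(s, y), ref, tolerance = 1e-10)
  }
})

test_that("the Youden point matches an exhaustive sweep", {
  # perfect separation: sensitivity and specificity both 1
  op <- youden_operating_point(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  # documented tie-break: lowest qualifying threshold
  op_tie <- youden_operating_point(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(op_tie$threshold, 2)
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    op <- youden_operating_point(s, y)
    ref <- oracle_youden(s, y)
    expect_equal(op$threshold, ref$threshold)
    expect_equal(op$sensitivity, ref$sensitivity)
    expect_equal(op$specificity, ref$specificity)
  }
  expect_error(youden_operating_point(c(0.1, 0.2), c(0, 0)), "both classes")
})

test_that("fold summaries use the normal-approximation interval", {
  sm <- summarize_folds(c(0.7, 0.8, 0.9))
  expect_equal(sm$mean, 0.8)
  expect_equal(sm$ci_hi - sm$mean, 1.96 * 0.1 / sqrt(3))
  expect_equal(sm$mean - sm$ci_lo, 1.96 * 0.1 / sqrt(3))
  # identical folds give a zero-width interval
  sm0 <- summarize_folds(rep(0.75, 5))
  expect_equal(sm0$ci_lo, 0.75)
  expect_equal(sm0$ci_hi, 0.75)
  # clipping near the boundary
  sm1 <- summarize_folds(c(0.97, 0.99, 1.0))
  expect_lte(sm1$ci_hi, 1)
  expect_error(summarize_folds(0.8), "two folds")
})
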