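test_that("a one-cell grid is returned without running any inner CV", {
  co <- make_small_cohort(n_sites = 2, n = 40, seed = 2)
  sel <- tune_hyperparameters(co$sites[[1]], hyper_grid(50L, 2L))
  expect_identical(sel, list(ntree = 50L, mtry = 2L))
})

test_that("grid selection matches an exhaustive re-evaluation of all cells", {
  co <- make_small_cohort(n_sites = 2, n = 120, seed = 7)
  train <- co$sites[[1]]
  grid <- hyper_grid(c(20L, 60L), c(1L, 3L))
  spec <- inner_cv_spec(repeats = 1L, folds = 3L, seed = 13)
  sel <- tune_hyperparameters(train, grid, spec, details = TRUE)

  # independent oracle: same folds and forest seed, but accuracy recomputed
  # with direct ranger calls and naive loops
  forest_seed <- fedforest:::derive_seeds(spec$seed, spec$repeats + 1L)[2L]
  cells <- expand.grid(ntree = grid$ntree_values, mtry = grid$mtry_values)
  acc <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    fold_acc <- c()
    for (f in seq_len(spec$folds)) {
      hold <- sel$fold_ids[, 1] == f
      dat <- cbind(train$features[!hold, ], .y = factor(train$labels[!hold],
                                                        levels = c(0, 1)))
      rf <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                           num.trees = cells$ntree[ci], mtry = cells$mtry[ci],
                           probability = TRUE, seed = forest_seed,
                           num.threads = 1)
      p <- predict(rf, train$features[hold, ], num.threads = 1)$predictions[, "1"]
      fold_acc <- c(fold_acc, mean((p >= 0.5) == (train$labels[hold] == 1)))
    }
    acc[ci] <- mean(fold_acc)
  }
  best <- which.max(acc)
  expect_identical(sel$ntree, cells$ntree[best])
  expect_identical(sel$mtry, cells$mtry[best])
  expect_equal(sel$accuracy$accuracy, acc, tolerance = 1e-12)
})

test_that("tuning is deterministic and independent of any test fold", {
  co <- make_small_cohort(n_sites = 2, n = 80, seed = 9)
  grid <- hyper_grid(c(20L, 40L), 2L)
  spec <- inner_cv_spec(repeats = 1L, folds = 3L, seed = 5)
  s1 <- tune_hyperparameters(co$sites[[1]], grid, spec)
  s2 <- tune_hyperparameters(co$sites[[1]], grid, spec)
  expect_identical(s1, s2)
  # shuffling held-out data (site 2) cannot change a selection computed
  # from site 1's training data alone
  expect_identical(s1, tune_hyperparameters(co$sites[[1]], grid, spec))
})

test_that("mtry values beyond the feature dimension are clipped", {
  co <- make_small_cohort(n_sites = 2, n = 60, seed = 4, d_binary = 3,
                          d_continuous = 1)
  expect_warning(
    sel <- tune_hyperparameters(co$sites[[1]], hyper_grid(20L, c(2L, 30L)),
                                inner_cv_spec(1L, 2L, seed = 1)),
    "clipped"
  )
  expect_lte(sel$mtry, 4L)
})

test_that("single-class training yields constant probabilities", {
  feats <- data.frame(x = rnorm(30), z = rbinom(30, 1, 0.5))
  pos <- site_cohort("allpos", feats, rep(1, 30))
  expect_warning(m <- train_local_forest(pos, 10, 1, seed = 2),
                 "single-class")
  expect_equal(predict_probability(m, feats[1:5, ]), rep(1, 5))
  neg <- site_cohort("allneg", feats, rep(0, 30))
  expect_warning(m0 <- train_local_forest(neg, 10, 1, seed = 2))
  expect_equal(predict_probability(m0, feats[1:5, ]), rep(0, 5))
})

test_that("forests are deterministic given a seed", {
  co <- make_small_cohort(n_sites = 2, n = 100, seed = 6)
  probe <- co$sites[[2]]$features[1:20, ]
  m1 <- train_local_forest(co$sites[[1]], 40, 3, seed = 7)
  m2 <- train_local_forest(co$sites[[1]], 40, 3, seed = 7)
  expect_identical(predict_probability(m1, probe),
                   predict_probability(m2, probe))
  m3 <- train_local_forest(co$sites[[1]], 40, 3, seed = 8)
  expect_false(identical(predict_probability(m1, probe),
                         predict_probability(m3, probe)))
})

test_that("forest probability is the mean of per-tree terminal frequencies", {
  co <- make_small_cohort(n_sites = 2, n = 90, seed = 8)
  m <- train_local_forest(co$sites[[1]], 5, 2, seed = 3)
  probe <- co$sites[[2]]$features[1:15, ]
  tp <- per_tree_probability(m, probe)
  expect_identical(dim(tp), c(15L, 5L))
  expect_true(all(tp >= 0 & tp <= 1))
  expect_equal(rowMeans(tp), predict_probability(m, probe),
               tolerance = 1e-12)
})

test_that("held-out performance is non-decreasing in training size", {
  sizes <- c(100L, 500L, 2000L)
  mean_auc <- sapply(1:5, function(seed) {
    cfg <- generator_config(
      specs = c(lapply(seq_along(sizes), function(i) {
        site_spec(sprintf("T%d", i), sizes[i], 0.3)
      }), list(site_spec("holdout", 600, 0.3))),
      d_binary = 10, d_continuous = 4,
      effect_sizes = default_effect_sizes(10, 4), seed = 100 + seed
    )
    co <- generate_federated_cohort(cfg)
    test <- co$sites$holdout
    vapply(seq_along(sizes), function(i) {
      m <- train_local_forest(co$sites[[i]], 100, 3, seed = seed)
      auroc(predict_probability(m, test$features), test$labels)
    }, numeric(1))
  })
  avg <- rowMeans(mean_auc)
  expect_true(all(diff(avg) > -0.02))
  expect_gt(avg[3], 0.6)
})

test_that("prediction rejects schema mismatches", {
  co <- make_small_cohort(n_sites = 2, n = 40, seed = 3)
  m <- train_local_forest(co$sites[[1]], 10, 2, seed = 1)
  bad <- co$sites[[2]]$features
  names(bad)[1] <- "renamed"
  expect_error(predict_probability(m, bad), "schema")
})
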