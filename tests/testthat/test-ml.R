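# Classifier harness: splits, standardization, the seven models, metric
# oracles, population comparison, tree importances, MLP training.

synth_dataset <- function(n_models = 30, seed = 5) {
  suppressWarnings(
    synthetic_risk_experiment(n_patients = n_models, seed = seed))
}

test_that("splits have the right sizes and standardization semantics", {
  ex <- synth_dataset(30)
  ds <- ex$baseline
  expect_identical(nrow(ds), 510L)
  cfg <- experiment_config()
  sp <- split_and_standardize(ds, cfg, seed = 4)
  expect_identical(nrow(sp$train$x), 357L) # floor(0.7 * 510)
  expect_identical(nrow(sp$test$x), 153L)
  # per-split mode: each split has mean 0, SD 1 per column
  expect_equal(unname(colMeans(sp$train$x)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(sp$train$x, 2, sd)), rep(1, 4))
  expect_equal(unname(colMeans(sp$test$x)), rep(0, 4), tolerance = 1e-12)
  # determinism
  sp2 <- split_and_standardize(ds, cfg, seed = 4)
  expect_identical(sp$idx, sp2$idx)
  # train-fit mode: test columns standardized by train statistics
  cfg2 <- experiment_config(standardize = "train-fit")
  sp3 <- split_and_standardize(ds, cfg2, seed = 4)
  expect_false(isTRUE(all.equal(unname(colMeans(sp3$test$x)),
                                rep(0, 4), tolerance = 1e-9)))
})

test_that("every model separates a linearly separable fixture", {
  fx <- make_fixtures(1)
  x <- cbind(fx$ml_separable$x, f3 = 0.1, f4 = -0.1)
  y <- fx$ml_separable$y
  tr <- list(x = x, y = y)
  for (m in c("knn", "svm", "logistic", "tree", "xgboost", "nn3",
              "nn4")) {
    pr <- suppressWarnings(train_and_predict(m, tr, tr, seed = 2))
    acc <- mean(pr$labels == y)
    expect_gte(acc, 0.97)
  }
  expect_error(train_and_predict("logistic",
                                 list(x = x, y = rep(1, nrow(x))), tr),
               "single-class")
})

test_that("intercept-only logistic regression predicts the class prior", {
  set.seed(9)
  n <- 200
  x <- matrix(0, n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(n, 1, 0.3)
  pr <- suppressWarnings(
    train_and_predict("logistic", list(x = x, y = y), list(x = x, y = y)))
  expect_equal(unique(round(pr$scores, 10)), round(mean(y), 10))
})

test_that("metrics agree with brute-force and pair-counting oracles", {
  # printed-formula arithmetic: TP 9, FP 1, FN 3, TN 7
  scores <- c(rep(0.9, 9), 0.8, rep(0.1, 3), rep(0.2, 7))
  labels <- c(rep(1, 9), 0, rep(1, 3), rep(0, 7))
  m <- compute_metrics(scores, labels)
  expect_identical(unname(m$confusion), c(9L, 1L, 3L, 7L))
  expect_equal(unname(m$metrics["precision"]), 0.90)
  expect_equal(unname(m$metrics["sensitivity"]), 0.75)
  expect_equal(unname(m$metrics["accuracy"]), 0.80)

  # perfect scores
  p <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(p$metrics["auc"]), 1)
  expect_equal(unname(p$metrics["ap"]), 1)

  # exhaustive small fixtures: every 2-class labelling of 4 samples,
  # with ties and distinct scores
  score_sets <- list(c(0.1, 0.4, 0.6, 0.9), c(0.5, 0.5, 0.2, 0.8))
  for (bits in 1:14) {
    labs <- as.integer(intToBits(bits))[1:4]
    for (sc in score_sets) {
      got <- compute_metrics(sc, labs)
      expect_equal(got$metrics[c("accuracy", "precision", "sensitivity")],
                   brute_metrics(sc, labs))
      expect_equal(unname(got$metrics["auc"]), pair_count_auc(sc, labs))
    }
  }

  # random scores on balanced labels: AUC near 1/2
  set.seed(11)
  sc <- runif(10000); lb <- rep(0:1, 5000)
  a <- compute_metrics(sc, lb)$metrics["auc"]
  expect_lt(abs(a - 0.5), 0.02)

  # one-class labels: AUC/AP undefined
  one <- compute_metrics(c(0.2, 0.8), c(1, 1))
  expect_true(is.na(one$metrics["auc"]))
  expect_true(is.na(one$metrics["ap"]))
})

test_that("experiment aggregation is coherent", {
  ex <- synth_dataset(12)
  cfg <- experiment_config(models = c("logistic", "tree"), n_runs = 3,
                           seed = 2)
  mt <- run_experiment(ex$baseline, cfg)
  expect_identical(mt$failed, 0L)
  acc <- mt$summary[mt$summary$metric == "accuracy", ]
  expect_true(all(acc$mean >= acc$min & acc$mean <= acc$max))
  single <- run_experiment(ex$baseline,
                           experiment_config(models = "logistic",
                                             n_runs = 1, seed = 2))
  expect_true(all(single$summary$sd == 0 | is.na(single$summary$sd)))
})

test_that("population comparison tests point the right way", {
  set.seed(3)
  a <- rnorm(100, 0.85, 0.01)
  runs_of <- function(v) {
    mt <- list(runs = data.frame(run = seq_along(v), model = "m",
                                 accuracy = v))
    mt
  }
  same <- compare_populations(runs_of(a), runs_of(a))
  expect_equal(same$p_t_one_sided, 0.5, tolerance = 1e-6)
  b <- a + 0.05
  up <- compare_populations(runs_of(a), runs_of(b))
  expect_lt(up$p_t_one_sided, 1e-10)
  down <- compare_populations(runs_of(b), runs_of(a))
  expect_gt(down$p_t_one_sided, 0.5)
  # variance shrink detected by the one-sided F-test
  shrunk <- compare_populations(runs_of(a),
                                runs_of(rnorm(100, 0.9, 0.003)))
  expect_lt(shrunk$p_f_one_sided, 1e-10)
})

test_that("tree importances are normalized and rank the driving feature", {
  set.seed(21)
  n <- 400
  x <- matrix(rnorm(4 * n), n, 4,
              dimnames = list(NULL, c("seg_vol", "seg_isch_pct",
                                      "total_vol", "total_isch_vol")))
  # labels driven purely by total ischemic volume
  y <- as.integer(x[, "total_isch_vol"] > 0.2)
  pr <- train_and_predict("tree", list(x = x, y = y), list(x = x, y = y))
  imp <- tree_importance(pr$fit)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_identical(names(imp)[1], "total_isch_vol")
  expect_gt(imp[1], 0.9)
  expect_error(tree_importance(lm(y ~ x)), "rpart")
})

test_that("the native MLP learns and is architecture-faithful", {
  fx <- make_fixtures(3)
  x <- fx$ml_separable$x
  y <- fx$ml_separable$y
  fit <- fit_mlp(x, y, hidden = c(32, 17, 8), seed = 1)
  expect_identical(vapply(fit$W, nrow, integer(1)), c(2L, 32L, 17L, 8L))
  expect_identical(vapply(fit$W, ncol, integer(1)), c(32L, 17L, 8L, 2L))
  p <- predict(fit, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(mean((p >= 0.5) == y), 0.95)
  # deterministic given the seed
  fit2 <- fit_mlp(x, y, hidden = c(32, 17, 8), seed = 1)
  expect_identical(fit$W, fit2$W)
})
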