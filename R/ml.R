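# Classifier harness: the seven risk models with their stated
# hyperparameters, the 70/30 split x n-runs scheme, aggregation into
# metrics tables, and the baseline-vs-augmented statistical comparison.

.feature_cols <- c("seg_vol", "seg_isch_pct", "total_vol", "total_isch_vol")

#' Experiment configuration
#'
#' The seven models and their fixed hyperparameters: k-nearest neighbours
#' (k = 5), RBF support vector machine (C = 2), logistic regression,
#' depth-3 decision tree, gradient-boosted trees (library defaults pinned:
#' 100 rounds, eta 0.3, max depth 6), and 3- and 4-hidden-layer
#' perceptrons (32-17-8 and 32-17-8-8 nodes).
#'
#' @param models character vector of model names.
#' @param train_frac training fraction of rows.
#' @param n_runs number of random-split repetitions.
#' @param standardize `"per-split"` standardizes train and test each with
#'   its own mean/SD (the harness default); `"train-fit"` applies the
#'   training statistics to both (the conventional leakage-free scheme).
#' @param stratified preserve class ratio in the split.
#' @param seed root seed; run `r` uses `seed + r`.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(models = c("knn", "svm", "logistic", "tree",
                                         "xgboost", "nn3", "nn4"),
                              train_frac = 0.7, n_runs = 100,
                              standardize = c("per-split", "train-fit"),
                              stratified = FALSE, seed = 1L) {
  standardize <- match.arg(standardize)
  stopifnot(train_frac > 0, train_frac < 1, n_runs >= 1)
  known <- c("knn", "svm", "logistic", "tree", "xgboost", "nn3", "nn4")
  bad <- setdiff(models, known)
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  structure(list(models = models, train_frac = train_frac, n_runs = n_runs,
                 standardize = standardize, stratified = stratified,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

.standardize <- function(x, center, scale) {
  bad <- scale == 0 | !is.finite(scale)
  if (any(bad)) {
    warning("zero-variance feature(s) left centred only: ",
            paste(colnames(x)[bad], collapse = ", "))
    scale[bad] <- 1
  }
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Random split and standardization
#'
#' Rows are shuffled and split `train_frac` / `1 - train_frac`. In
#' `"per-split"` mode each split is standardized with its own column mean
#' and SD; `"train-fit"` mode uses the training statistics for both.
#'
#' @param dataset a `risk_dataset` (needs >= 10 rows).
#' @param cfg an [experiment_config()].
#' @param seed split seed.
#' @return List `train`, `test` (each `x` matrix, `y` labels), `idx`.
#' @export
split_and_standardize <- function(dataset, cfg = experiment_config(),
                                  seed = cfg$seed) {
  stopifnot(nrow(dataset) >= 10)
  set.seed(seed)
  n <- nrow(dataset)
  n_train <- floor(cfg$train_frac * n)
  if (cfg$stratified) {
    pos <- which(dataset$label == 1); neg <- which(dataset$label == 0)
    np <- round(length(pos) * cfg$train_frac)
    tr <- c(sample(pos, np), sample(neg, n_train - np))
  } else {
    tr <- sample.int(n, n_train)
  }
  x <- as.matrix(dataset[.feature_cols])
  y <- dataset$label
  xtr <- x[tr, , drop = FALSE]; xte <- x[-tr, , drop = FALSE]
  if (cfg$standardize == "per-split") {
    xtr <- .standardize(xtr, colMeans(xtr), apply(xtr, 2, sd))
    xte <- .standardize(xte, colMeans(xte), apply(xte, 2, sd))
  } else {
    ctr <- colMeans(xtr); scl <- apply(xtr, 2, sd)
    xtr <- .standardize(xtr, ctr, scl)
    xte <- .standardize(xte, ctr, scl)
  }
  list(train = list(x = xtr, y = y[tr]),
       test = list(x = xte, y = y[-tr]), idx = tr)
}

#' Train one classifier and score the test set
#'
#' @param model one of `"knn"`, `"svm"`, `"logistic"`, `"tree"`,
#'   `"xgboost"`, `"nn3"`, `"nn4"`.
#' @param train,test lists with `x` (matrix) and `y` (0/1), as produced by
#'   [split_and_standardize()].
#' @param seed seed for stochastic learners.
#' @return List `scores` (positive-class score in \[0,1\]), `labels`
#'   (hard labels at 0.5), and `fit` (the fitted model object, where the
#'   backend exposes one).
#' @export
train_and_predict <- function(model, train, test, seed = 1L) {
  if (length(unique(train$y)) < 2)
    stop("single-class training set; cannot train ", model)
  scores <- switch(
    model,
    knn = {
      pr <- class::knn(train$x, test$x, factor(train$y), k = 5,
                       prob = TRUE)
      p <- attr(pr, "prob") # proportion of votes for the winning class
      ifelse(pr == "1", p, 1 - p)
    },
    svm = {
      fit <- e1071::svm(train$x, factor(train$y), kernel = "radial",
                        cost = 2, probability = TRUE)
      at <- attr(predict(fit, test$x, probability = TRUE), "probabilities")
      at[, "1"]
    },
    logistic = {
      df <- data.frame(train$x, y = train$y)
      fit <- glm(y ~ ., data = df, family = binomial())
      predict(fit, data.frame(test$x), type = "response")
    },
    tree = {
      df <- data.frame(train$x, y = factor(train$y))
      fit <- rpart::rpart(y ~ ., data = df,
                          method = "class",
                          control = rpart::rpart.control(maxdepth = 3,
                                                         cp = 0,
                                                         minsplit = 2))
      attr(df, "fit") <- fit
      p <- predict(fit, data.frame(test$x))[, "1"]
      attr(p, "fit") <- fit
      p
    },
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(train$x, label = train$y, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.3,
                      max_depth = 6, nthread = 1),
        data = dtr, nrounds = 100, verbose = 0)
      predict(fit, xgboost::xgb.DMatrix(test$x, nthread = 1))
    },
    nn3 = {
      fit <- fit_mlp(train$x, train$y, hidden = c(32, 17, 8), seed = seed)
      predict(fit, test$x)
    },
    nn4 = {
      fit <- fit_mlp(train$x, train$y, hidden = c(32, 17, 8, 8),
                     seed = seed)
      predict(fit, test$x)
    },
    stop("unknown model: ", model))
  fit <- attr(scores, "fit")
  scores <- as.numeric(scores)
  list(scores = scores, labels = as.integer(scores >= 0.5), fit = fit)
}

#' Run the repeated-split experiment
#'
#' `n_runs` independent 70/30 splits; each model is trained and scored on
#' every split and all metrics collected, then aggregated per model
#' (mean, SD, max, min over runs).
#'
#' @param dataset a `risk_dataset`.
#' @param cfg an [experiment_config()].
#' @return A `metrics_table`: `runs` (long data frame: run, model,
#'   metrics), `summary` (per model x metric: mean/sd/max/min),
#'   `failed` (count of failed runs).
#' @export
run_experiment <- function(dataset, cfg = experiment_config()) {
  runs <- list()
  failed <- 0L
  for (r in seq_len(cfg$n_runs)) {
    sp <- split_and_standardize(dataset, cfg, seed = cfg$seed + r)
    for (m in cfg$models) {
      res <- try({
        pr <- train_and_predict(m, sp$train, sp$test, seed = cfg$seed + r)
        compute_metrics(pr$scores, sp$test$y)$metrics
      }, silent = TRUE)
      if (inherits(res, "try-error")) { failed <- failed + 1L; next }
      runs[[length(runs) + 1L]] <-
        data.frame(run = r, model = m, t(res))
    }
  }
  runs <- do.call(rbind, runs)
  metric_names <- c("accuracy", "precision", "sensitivity", "ap", "auc")
  summ <- do.call(rbind, lapply(split(runs, runs$model), function(d) {
    do.call(rbind, lapply(metric_names, function(mn) {
      v <- d[[mn]]
      data.frame(model = d$model[1], metric = mn,
                 mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE),
                 max = suppressWarnings(max(v, na.rm = TRUE)),
                 min = suppressWarnings(min(v, na.rm = TRUE)))
    }))
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ, failed = failed,
                 config = cfg), class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  acc <- x$summary[x$summary$metric == "accuracy", ]
  cat(sprintf("metrics_table: %d runs x %d models (%d failed)\n",
              max(x$runs$run), length(unique(x$runs$model)), x$failed))
  print(acc[order(-acc$mean), ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare baseline against augmented experiment results
#'
#' Per model: a one-sided Welch t-test of whether mean test accuracy is
#' greater on the augmented arm, and a one-sided F-test of whether the
#' accuracy variance is smaller; two-sided p-values are reported alongside.
#'
#' @param baseline,augmented `metrics_table`s from [run_experiment()].
#' @param metric metric to compare.
#' @return Data frame per model: means, SDs, one- and two-sided p-values.
#' @export
compare_populations <- function(baseline, augmented, metric = "accuracy") {
  mb <- baseline$runs; ma <- augmented$runs
  models <- intersect(unique(mb$model), unique(ma$model))
  do.call(rbind, lapply(models, function(m) {
    vb <- mb[[metric]][mb$model == m]
    va <- ma[[metric]][ma$model == m]
    tt1 <- t.test(va, vb, alternative = "greater")
    tt2 <- t.test(va, vb)
    ft1 <- if (var(va) > 0 && var(vb) > 0)
      var.test(va, vb, alternative = "less") else NULL
    ft2 <- if (!is.null(ft1)) var.test(va, vb) else NULL
    data.frame(model = m,
               mean_baseline = mean(vb), mean_augmented = mean(va),
               sd_baseline = sd(vb), sd_augmented = sd(va),
               p_t_one_sided = tt1$p.value, p_t_two_sided = tt2$p.value,
               p_f_one_sided = if (is.null(ft1)) NA_real_ else ft1$p.value,
               p_f_two_sided = if (is.null(ft2)) NA_real_ else ft2$p.value)
  }))
}

#' Decision-tree feature importances
#'
#' Impurity-decrease importances of a fitted depth-limited tree,
#' normalized to sum to 1 and ranked.
#'
#' @param fit an `rpart` fit (e.g. the `fit` element returned by
#'   [train_and_predict()] for the tree model).
#' @return Named numeric vector, decreasing.
#' @export
tree_importance <- function(fit) {
  if (!inherits(fit, "rpart")) stop("fit must be a fitted rpart tree")
  if (is.null(fit$splits) || nrow(fit$splits) == 0)
    stop("tree is unfitted or has no splits")
  vi <- fit$variable.importance
  if (is.null(vi)) stop("tree carries no importance information")
  out <- vi / sum(vi)
  miss <- setdiff(.feature_cols, names(out))
  if (length(miss)) out[miss] <- 0
  sort(out, decreasing = TRUE)
}
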