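# End-to-end pipeline orchestration: YAML config in, staged outputs and a
# run manifest out, with hash-based stage skipping on rerun. Also the
# deterministic fixture bundle used by the test suite.

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(config), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

#' Default pipeline configuration
#'
#' @param n_patients,nx,ny,spacing population generator settings.
#' @param seed root seed funnelling all randomness.
#' @param peel_set augmentation peel levels.
#' @param n_runs,models ML experiment settings.
#' @return Nested list understood by [run_pipeline()]; serializable as
#'   YAML.
#' @export
pipeline_config <- function(n_patients = 8, nx = 40, ny = 40,
                            spacing = 0.25, seed = 1L,
                            peel_set = c(1, 2, 5, 10), n_runs = 10,
                            models = c("knn", "svm", "logistic", "tree",
                                       "xgboost", "nn3", "nn4")) {
  list(population = list(n_patients = n_patients, nx = nx, ny = ny,
                         spacing = spacing),
       seed = as.integer(seed),
       peel_set = peel_set,
       outcome = list(kind = "surrogate"),
       ml = list(models = models, n_runs = n_runs, train_frac = 0.7))
}

#' Run the full pipeline
#'
#' Stages: population generation -> peel augmentation -> vulnerability
#' outcomes (surrogate inducibility) -> feature extraction -> datasets ->
#' classifier experiment and baseline-vs-augmented comparison. Outputs and
#' a manifest JSON land under `out_dir`; rerunning with an unchanged
#' config skips completed stages (matching config hash and existing
#' outputs).
#'
#' @param config config list ([pipeline_config()]) or path to a YAML file.
#' @param out_dir run directory.
#' @return The run manifest (list), invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  man_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = TRUE) else
      list(config_hash = "", stages = list())
  fresh <- !identical(manifest$config_hash, hash)
  manifest$config_hash <- hash
  manifest$seed <- config$seed
  manifest$version <- as.character(utils::packageVersion("reentryforge"))
  done <- function(stage, outputs) {
    st <- manifest$stages[[stage]]
    if (fresh || !isTRUE(st$status == "done")) return(FALSE)
    paths <- file.path(out_dir, outputs)
    if (!all(file.exists(paths))) return(FALSE)
    sums <- unname(tools::md5sum(paths))
    if (!identical(sums, unname(unlist(st$checksums))))
      stop(sprintf("checksum mismatch for stage '%s' outputs; %s",
                   stage, "intermediate file corrupted or edited"))
    TRUE
  }
  mark <- function(stage, outputs) {
    manifest$stages[[stage]] <<- list(
      status = "done", outputs = outputs,
      checksums = unname(tools::md5sum(file.path(out_dir, outputs))))
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  pc <- config$population
  # stage 1+2: population + augmentation
  pop_out <- "population_manifest.csv"
  exp <- NULL
  if (done("population", pop_out)) {
    message("skipping completed stage: population")
  }
  # outcomes through datasets are produced together by the experiment
  ds_out <- c("dataset_baseline.csv", "dataset_augmented.csv",
              "outcomes.csv", "vulnerability_summary.csv", pop_out)
  if (done("datasets", ds_out)) {
    message("skipping completed stage: datasets")
    ds_base <- read_dataset(file.path(out_dir, "dataset_baseline.csv"))
    ds_aug <- read_dataset(file.path(out_dir, "dataset_augmented.csv"))
  } else {
    exp <- synthetic_risk_experiment(
      n_patients = pc$n_patients, seed = config$seed,
      peel_set = config$peel_set, nx = pc$nx, ny = pc$ny,
      spacing = pc$spacing)
    write.csv(exp$population$manifest, file.path(out_dir, pop_out),
              row.names = FALSE)
    mark("population", pop_out)
    write.csv(exp$evaluation$outcomes, file.path(out_dir, "outcomes.csv"),
              row.names = FALSE)
    write.csv(exp$evaluation$summary$by_peel,
              file.path(out_dir, "vulnerability_summary.csv"),
              row.names = FALSE)
    write_dataset(exp$baseline, file.path(out_dir, "dataset_baseline.csv"))
    write_dataset(exp$augmented,
                  file.path(out_dir, "dataset_augmented.csv"))
    mark("datasets", ds_out)
    ds_base <- exp$baseline
    ds_aug <- exp$augmented
  }
  # stage: ML experiment
  ml_out <- c("metrics_baseline.csv", "metrics_augmented.csv",
              "comparison.csv")
  if (done("ml", ml_out)) {
    message("skipping completed stage: ml")
  } else {
    cfg <- experiment_config(models = config$ml$models,
                             train_frac = config$ml$train_frac,
                             n_runs = config$ml$n_runs,
                             seed = config$seed)
    mt_b <- run_experiment(ds_base, cfg)
    mt_a <- run_experiment(ds_aug, cfg)
    write.csv(mt_b$summary, file.path(out_dir, "metrics_baseline.csv"),
              row.names = FALSE)
    write.csv(mt_a$summary, file.path(out_dir, "metrics_augmented.csv"),
              row.names = FALSE)
    write.csv(compare_populations(mt_b, mt_a),
              file.path(out_dir, "comparison.csv"), row.names = FALSE)
    mark("ml", ml_out)
  }
  invisible(manifest)
}

#' Deterministic fixture bundle for tests and examples
#'
#' A small geometry with segments, fibers and a layered ischemic disc;
#' constructed activation-event tables exhibiting an unsustained (UR) and
#' a sustained (R) reexcitation pattern; and a linearly separable
#' two-feature classification fixture.
#'
#' @param seed integer seed.
#' @return Named list `geometry`, `layers`, `events_ur`, `events_r`,
#'   `ml_separable` (list `x`, `y`); attribute `hash` carries a stable
#'   digest of the bundle's canonical text form.
#' @export
make_fixtures <- function(seed = 1L) {
  g <- generate_slab(20, 20, 0.25, ischemia_spec(radius = 1.2,
                                                 n_layers = 3),
                     seed = seed)
  g <- assign_fibers(assign_aha_segments(g), 60, -60)
  al <- assign_layers(g, 3)
  # stimulated beat at t = 0 on elements 1..5, then reexcitation episodes
  ur <- data.frame(element = c(1:5, 2, 3, 2, 3),
                   time = c(rep(5, 5), 300, 320, 600, 620))
  r <- data.frame(element = c(1:5, rep(2:4, times = 12)),
                  time = c(rep(5, 5), 100 + sort(rep(1:12, 3)) * 160))
  set.seed(seed)
  n <- 60
  x <- cbind(f1 = c(rnorm(n / 2, -2), rnorm(n / 2, 2)),
             f2 = rnorm(n))
  y <- rep(0:1, each = n / 2)
  bundle <- list(geometry = al$geometry, layers = al$layers,
                 events_ur = ur, events_r = r,
                 ml_separable = list(x = x, y = y))
  tf <- tempfile()
  writeLines(paste(deparse(bundle), collapse = "\n"), tf)
  attr(bundle, "hash") <- unname(tools::md5sum(tf))
  unlink(tf)
  bundle
}
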