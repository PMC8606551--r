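# Programmed-stimulation protocol: state machine against scripted
# simulators, capture checking, outcome classification, pacing sites, and
# population bookkeeping.

# scripted backend: `script` maps "<stage>@<interval>" to a result; any
# unscripted attempt captures without reentry
stub_backend <- function(script, cfg = protocol_config()) {
  log <- new.env(parent = emptyenv())
  log$attempts <- list()
  fn <- function(fixed, test_time, stage) {
    interval <- test_time - max(fixed)
    log$attempts[[length(log$attempts) + 1L]] <-
      list(stage = stage, interval = interval, fixed = fixed)
    key <- sprintf("%s@%g", stage, interval)
    res <- script[[key]]
    if (is.null(res)) res <- list(captured = TRUE, outcome = "NR")
    res$episode_duration <- res$episode_duration %||% 0
    res
  }
  attr(fn, "log") <- log
  fn
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("S2 reentry stops the protocol with the right bookkeeping", {
  # reentry at S2 coupling 160 after captures at 200..170
  sc <- list("S2@160" = list(captured = TRUE, outcome = "R",
                             episode_duration = 1500))
  res <- run_protocol_statemachine(stub_backend(sc), site = 7)
  expect_identical(res$outcome, "R")
  expect_identical(res$inducing_stage, "S2")
  expect_equal(unname(res$intervals["S2"]), 160)
  expect_identical(res$n_attempts, 5L) # 200, 190, 180, 170, 160
})

test_that("capture failure escalates to S3 with S2 fixed at the last
           captured interval", {
  sc <- list("S2@140" = list(captured = FALSE, outcome = "NR"),
             "S3@250" = list(captured = TRUE, outcome = "UR",
                             episode_duration = 600))
  be <- stub_backend(sc)
  res <- run_protocol_statemachine(be, site = 3)
  expect_identical(res$outcome, "UR")
  expect_identical(res$inducing_stage, "S3")
  expect_equal(unname(res$intervals["S2"]), 150) # fixed at last captured
  expect_equal(unname(res$intervals["S3"]), 250)
  # the S3 attempt rode on the fixed S1 train plus the captured S2
  log <- attr(be, "log")$attempts
  last <- log[[length(log)]]
  s1_last <- 10 + 4 * 350
  expect_equal(max(last$fixed), s1_last + 150)
  expect_identical(last$stage, "S3")
})

test_that("a fully exhausted protocol is NR and respects the floor", {
  # everything captures, nothing induces: S2, S3, S4 all walk to the floor
  be <- stub_backend(list())
  res <- run_protocol_statemachine(be, site = 1)
  expect_identical(res$outcome, "NR")
  expect_identical(res$inducing_stage, "none")
  log <- attr(be, "log")$attempts
  ints <- vapply(log, function(a) a$interval, numeric(1))
  expect_true(all(ints >= protocol_config()$coupling_floor))
  # stages in order, each starting at its configured offset
  stages <- vapply(log, function(a) a$stage, character(1))
  expect_identical(unique(stages), c("S2", "S3", "S4"))

  # nothing captured at S2 at all: protocol cannot escalate, ends NR
  sc2 <- setNames(
    lapply(seq(200, 100, -10), function(i)
      list(captured = FALSE, outcome = "NR")),
    sprintf("S2@%d", seq(200, 100, -10)))
  res2 <- run_protocol_statemachine(stub_backend(sc2), site = 2)
  expect_identical(res2$outcome, "NR")
  expect_identical(res2$n_attempts, 1L)
})

test_that("capture requires propagation away from the electrode", {
  g <- generate_slab(40, 40, 0.25)
  site <- electrode_patch(g, 20 + 19 * 40)
  ctr <- colMeans(g$centers[site, ])
  # local-only excitation: all events within 5 mm
  near <- which(sqrt(rowSums((g$centers - matrix(ctr, 1600, 2,
                                                 byrow = TRUE))^2)) < 4)
  ev_local <- data.frame(element = near[1:10], time = 20)
  expect_false(check_capture(ev_local, g, site, stim_onset = 10))
  # a propagating beat reaches distant elements quickly
  far <- which(sqrt(rowSums((g$centers - matrix(ctr, 1600, 2,
                                                byrow = TRUE))^2)) > 6)
  ev_prop <- rbind(ev_local, data.frame(element = far[1:5], time = 40))
  expect_true(check_capture(ev_prop, g, site, stim_onset = 10))
  # refractory tissue: no events at all
  expect_false(check_capture(ev_prop[0, ], g, site, stim_onset = 10))
  # propagation after the capture window does not count
  ev_late <- data.frame(element = far[1], time = 150)
  expect_false(check_capture(ev_late, g, site, stim_onset = 10))
})

test_that("outcome classification separates NR, UR and R", {
  cfg <- protocol_config()
  fx <- make_fixtures(1)
  none <- data.frame(element = integer(0), time = numeric(0))
  expect_identical(as.character(classify_outcome(none, 0, cfg)), "NR")
  # stimulated beat only (one activation per element) is NR
  beat <- data.frame(element = 1:20, time = 60)
  expect_identical(as.character(classify_outcome(beat, 0, cfg)), "NR")
  # fixture with 600 ms of reexcitation then silence: UR
  expect_identical(as.character(classify_outcome(fx$events_ur, 0, cfg)),
                   "UR")
  # fixture spanning the window into its final 200 ms: R
  expect_identical(as.character(classify_outcome(fx$events_r, 0, cfg)),
                   "R")
  # episode duration accounting
  expect_gt(attr(classify_outcome(fx$events_r, 0, cfg),
                 "episode_duration"), 1000)
})

test_that("17 pacing sites land inside their own segments", {
  g <- assign_aha_segments(generate_slab(60, 60, 0.25))
  sites <- select_pacing_sites(g)
  expect_identical(names(sites), as.character(1:17))
  for (sgid in 1:17) {
    el <- sites[[as.character(sgid)]]$site
    expect_true(all(g$segment_id[el] == sgid))
  }
  # degenerate geometry without an apex-cap segment errors
  g2 <- g
  g2$segment_id[g2$segment_id == 17L] <- 16L
  expect_error(select_pacing_sites(g2), "segment 17")
})

test_that("population bookkeeping reproduces the arithmetic identities", {
  # outcome table shaped like a 30-patient baseline: 111 of 510 positive
  mk_outcomes <- function(n_pat, pos_per_pat, peel = 0) {
    do.call(rbind, lapply(seq_len(n_pat), function(p) {
      k <- pos_per_pat[p]
      data.frame(model_id = sprintf("P%02d_peel%d", p, peel),
                 patient = sprintf("P%02d", p), peel = peel,
                 segment = 1:17,
                 outcome = c(rep("R", k), rep("NR", 17 - k)))
    }))
  }
  # 111 positives spread over 14 inducible patients, 16 without reentry
  pos <- c(rep(8, 13), 7, rep(0, 16))
  stopifnot(sum(pos) == 111, length(pos) == 30)
  out <- mk_outcomes(30, pos)
  s <- vulnerability_summary(out)
  expect_identical(s$tested, 510L)
  expect_identical(s$arrhythmic, 111L)
  expect_equal(round(s$ratio, 3), 0.218)
  expect_equal(s$by_peel$mean_reentries_per_model, mean(pos))
  expect_equal(round(s$by_peel$mean_reentries_per_model, 2), 3.70)
  expect_identical(s$by_peel$n_patients_reentry, 14L)

  # all-NR population
  s0 <- vulnerability_summary(mk_outcomes(5, rep(0, 5)))
  expect_identical(s0$arrhythmic, 0L)
  expect_identical(s0$by_peel$n_patients_reentry, 0L)

  # duplicate keys are rejected
  expect_error(vulnerability_summary(rbind(out, out[1, ])), "duplicate")
})

test_that("the full protocol on a healthy slab is NR", {
  # shortened drive train and coarse decrements keep this integration run
  # desk-sized; the substrate-free expectation is unchanged
  g <- assign_fibers(assign_aha_segments(generate_slab(24, 24, 0.25)),
                     0, 0)
  cmap <- cell_param_map(NULL, preset = "baseline")
  cond <- conductivity_field(g)
  cfg <- protocol_config(s1_count = 2, s1_cl = 300, s2_offset = 200,
                         decrement = 40, observation = 300,
                         coupling_floor = 150)
  site <- electrode_patch(g, 2 + 1 * 24) # corner electrode
  res <- run_vulnerability_protocol(g, cond, cmap, site, cfg, dt = 0.05)
  expect_identical(res$outcome, "NR")
  expect_identical(res$inducing_stage, "none")
  expect_gte(res$n_attempts, 3L) # multiple S2 decrements plus escalation
})
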