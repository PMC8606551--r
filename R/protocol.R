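# Adaptive programmed-stimulation vulnerability protocol: S1x5 drive train,
# premature S2/S3/S4 extrastimuli with 10 ms decrements, capture checking,
# NR/UR/R outcome classification, and population-level summaries.

#' Programmed-stimulation protocol configuration
#'
#' Defaults follow the clinical-style protocol: five S1 drive stimuli at a
#' 350 ms cycle length, an S2 coupled at 200 ms and shortened in 10 ms
#' steps until reentry or capture failure, then S3 and S4 each starting
#' 250 ms after the last captured stimulus, with a 2000 ms observation
#' window after every delivered premature stimulus.
#'
#' @param s1_count,s1_cl drive-train beat count and cycle length (ms).
#' @param s2_offset initial S2 coupling interval (ms).
#' @param decrement coupling-interval decrement (ms).
#' @param s3_offset,s4_offset initial S3/S4 coupling intervals (ms).
#' @param observation post-stimulus observation window (ms).
#' @param coupling_floor hard lower bound on coupling intervals (ms),
#'   bounding protocol runtime.
#' @param latency post-stimulus latency before activations count as
#'   reexcitation (ms).
#' @param sustained_window activity within this final span of the
#'   observation window classifies the episode as sustained (ms).
#' @param stim_duration,stim_amplitude stimulus pulse shape (ms, uA/cm^2).
#' @param s1_onset absolute onset of the first S1 (ms).
#' @return A `protocol_config`.
#' @export
protocol_config <- function(s1_count = 5, s1_cl = 350, s2_offset = 200,
                            decrement = 10, s3_offset = 250,
                            s4_offset = 250, observation = 2000,
                            coupling_floor = 100, latency = 50,
                            sustained_window = 200, stim_duration = 10,
                            stim_amplitude = 100, s1_onset = 10) {
  stopifnot(s1_count >= 1, s1_cl > 0, s2_offset > 0, decrement > 0,
            decrement < s2_offset, s3_offset > 0, s4_offset > 0,
            observation > 0, coupling_floor >= 10)
  structure(list(s1_count = s1_count, s1_cl = s1_cl, s2_offset = s2_offset,
                 decrement = decrement, s3_offset = s3_offset,
                 s4_offset = s4_offset, observation = observation,
                 coupling_floor = coupling_floor, latency = latency,
                 sustained_window = sustained_window,
                 stim_duration = stim_duration,
                 stim_amplitude = stim_amplitude, s1_onset = s1_onset),
            class = "protocol_config")
}

#' Capture check
#'
#' A delivered stimulus captured when at least one activation occurs at
#' least `min_dist` from the electrode centroid within `window` of onset
#' (local-only excitation under the electrode does not count).
#'
#' @param events data frame `element`, `time` (absolute ms).
#' @param geom the geometry (for element positions).
#' @param site_elements electrode footprint element indices.
#' @param stim_onset stimulus onset (ms).
#' @param min_dist minimal propagation distance, mm.
#' @param window capture window after onset, ms.
#' @return Logical.
#' @export
check_capture <- function(events, geom, site_elements, stim_onset,
                          min_dist = 5, window = 100) {
  if (nrow(events) == 0) return(FALSE)
  ctr <- colMeans(geom$centers[site_elements, , drop = FALSE])
  ev <- events[events$time >= stim_onset &
                 events$time <= stim_onset + window, , drop = FALSE]
  if (nrow(ev) == 0) return(FALSE)
  d <- sqrt(rowSums((geom$centers[ev$element, , drop = FALSE] -
                       matrix(ctr, nrow(ev), length(ctr),
                              byrow = TRUE))^2))
  any(d >= min_dist)
}

#' Classify a post-stimulus observation window
#'
#' Reexcitation means some element activates at least twice after the last
#' stimulus onset plus a latency (excluding the stimulated beat's own
#' upstroke). `"R"` (sustained reentry) requires activity persisting into
#' the final `sustained_window` ms of the observation window; `"UR"` marks
#' reexcitation that extinguished earlier; `"NR"` means no reexcitation.
#'
#' @param events data frame `element`, `time` (absolute ms).
#' @param last_onset onset of the last delivered stimulus (ms).
#' @param cfg a [protocol_config()].
#' @return One of `"NR"`, `"UR"`, `"R"` with attribute `episode_duration`
#'   (ms from first reexcitation to last event; 0 for NR).
#' @export
classify_outcome <- function(events, last_onset, cfg = protocol_config()) {
  t_lat <- last_onset + cfg$latency
  win_end <- last_onset + cfg$observation
  ev <- events[events$time > t_lat & events$time <= win_end, , drop = FALSE]
  reex <- FALSE
  if (nrow(ev) > 0) {
    cnt <- table(ev$element)
    reex <- any(cnt >= 2)
  }
  if (!reex) return(structure("NR", episode_duration = 0))
  dup <- names(which(table(ev$element) >= 2))
  ev2 <- ev[ev$element %in% as.integer(dup), , drop = FALSE]
  first_re <- min(tapply(ev2$time, ev2$element, function(t) sort(t)[2]))
  last_ev <- max(ev$time)
  dur <- last_ev - first_re
  out <- if (last_ev >= win_end - cfg$sustained_window) "R" else "UR"
  structure(out, episode_duration = dur)
}

#' Protocol state machine over an abstract attempt backend
#'
#' Drives the adaptive S2/S3/S4 logic against any `attempt` function, so
#' the state machine can be exercised with scripted stand-in simulators as
#' well as the monodomain backend. `attempt(fixed_times, test_time, stage)`
#' must return `list(captured = logical, outcome = "NR"|"UR"|"R",
#' episode_duration = numeric)` describing the observation window after a
#' premature stimulus at `test_time` on top of the fixed schedule.
#'
#' @param attempt backend function (see above).
#' @param cfg a [protocol_config()].
#' @param site site label carried into the result.
#' @return A `site_result`: `site`, `outcome`, `inducing_stage` (`"S2"`,
#'   `"S3"`, `"S4"` or `"none"`), `intervals` (named fixed/final coupling
#'   intervals, ms), `episode_duration`, `n_attempts`.
#' @export
run_protocol_statemachine <- function(attempt, cfg = protocol_config(),
                                      site = NA) {
  s1_times <- cfg$s1_onset + (seq_len(cfg$s1_count) - 1) * cfg$s1_cl
  fixed <- s1_times
  last_fixed <- s1_times[length(s1_times)]
  stages <- c(S2 = cfg$s2_offset, S3 = cfg$s3_offset, S4 = cfg$s4_offset)
  intervals <- c()
  n_attempts <- 0L
  for (sg in names(stages)) {
    interval <- stages[[sg]]
    last_captured <- NA_real_
    repeat {
      test_time <- last_fixed + interval
      n_attempts <- n_attempts + 1L
      res <- attempt(fixed, test_time, sg)
      if (res$outcome %in% c("UR", "R")) {
        intervals[sg] <- interval
        return(structure(list(site = site, outcome = res$outcome,
                              inducing_stage = sg, intervals = intervals,
                              episode_duration = res$episode_duration,
                              n_attempts = n_attempts),
                         class = "site_result"))
      }
      if (!res$captured) break
      last_captured <- interval
      interval <- interval - cfg$decrement
      if (interval < cfg$coupling_floor) break
    }
    if (is.na(last_captured)) break # nothing captured at this stage
    intervals[sg] <- last_captured
    last_fixed <- last_fixed + last_captured
    fixed <- c(fixed, last_fixed)
  }
  structure(list(site = site, outcome = "NR", inducing_stage = "none",
                 intervals = intervals, episode_duration = 0,
                 n_attempts = n_attempts),
            class = "site_result")
}

#' @export
print.site_result <- function(x, ...) {
  cat(sprintf("site %s: %s (stage %s, %d attempts)\n",
              as.character(x$site), x$outcome, x$inducing_stage,
              x$n_attempts))
  if (length(x$intervals))
    cat("  coupling intervals:",
        paste(sprintf("%s=%g", names(x$intervals), x$intervals),
              collapse = ", "), "ms\n")
  invisible(x)
}

# monodomain attempt backend with per-prefix state caching
.monodomain_backend <- function(geom, cond, cell_map, site_elements, cfg,
                                dt = 0.02) {
  cache <- new.env(parent = emptyenv())
  cache$key <- ""
  cache$state <- NULL
  cache$t <- 0
  cache$events <- data.frame(element = integer(0), time = numeric(0))
  mk_stim <- function(t) stimulus(site_elements, onset = t,
                                  duration = cfg$stim_duration,
                                  amplitude = cfg$stim_amplitude)
  function(fixed, test_time, stage) {
    key <- paste(round(fixed, 6), collapse = ",")
    if (!identical(cache$key, key)) {
      # simulate the fixed schedule once, ending just after its last pulse
      t_stop <- max(fixed) + cfg$stim_duration + 1
      r <- run_monodomain(geom, cond, cell_map, lapply(fixed, mk_stim),
                          t_end = t_stop, dt = dt)
      cache$key <- key
      cache$state <- r$final_state
      cache$t <- t_stop
      cache$events <- r$events
    }
    r2 <- run_monodomain(geom, cond, cell_map, list(mk_stim(test_time)),
                         t_end = test_time + cfg$observation + 1 - cache$t,
                         dt = dt, init_state = cache$state, t0 = cache$t)
    ev <- rbind(cache$events, r2$events)
    cap <- check_capture(ev, geom, site_elements, test_time)
    out <- classify_outcome(ev, test_time, cfg)
    list(captured = cap, outcome = as.character(out),
         episode_duration = attr(out, "episode_duration"), events = ev)
  }
}

#' Run the vulnerability protocol at one pacing site
#'
#' Full monodomain realisation of the adaptive protocol: the drive-train
#' state is cached and reused across premature-stimulus attempts.
#'
#' @param geom slab `ventricle_geometry`.
#' @param cond a [conductivity_field()].
#' @param cell_map region parameter matrix ([cell_param_map()]).
#' @param site a [stimulus()]-style electrode footprint (element indices)
#'   or a `stimulus` object (its site is used).
#' @param cfg a [protocol_config()].
#' @param dt solver time step, ms.
#' @return A `site_result` (see [run_protocol_statemachine()]).
#' @export
run_vulnerability_protocol <- function(geom, cond, cell_map, site,
                                       cfg = protocol_config(), dt = 0.02) {
  elems <- if (inherits(site, "stimulus")) site$site else as.integer(site)
  seg <- unique(geom$segment_id[elems])
  backend <- .monodomain_backend(geom, cond, cell_map, elems, cfg, dt)
  run_protocol_statemachine(backend, cfg,
                            site = if (length(seg) == 1) seg else NA)
}

#' Select the 17 AHA pacing sites
#'
#' One electrode per AHA segment, centred on the element nearest the
#' segment's geometric centroid (midwall), with a 2x2-element footprint.
#'
#' @param geom geometry with assigned segments.
#' @param cfg a [protocol_config()] (for the stimulus template).
#' @return Named list of 17 [stimulus()] objects (names `"1"`..`"17"`).
#' @export
select_pacing_sites <- function(geom, cfg = protocol_config()) {
  if (all(is.na(geom$segment_id))) stop("segments not assigned")
  sites <- list()
  for (sgid in 1:17) {
    idx <- which(geom$mask & !is.na(geom$segment_id) &
                   geom$segment_id == sgid)
    if (length(idx) == 0)
      stop(sprintf("AHA segment %d is empty; cannot place electrode", sgid))
    ctr <- colMeans(geom$centers[idx, , drop = FALSE])
    d2 <- rowSums((geom$centers[idx, , drop = FALSE] -
                     matrix(ctr, length(idx), length(ctr), byrow = TRUE))^2)
    e0 <- idx[which.min(d2)]
    patch <- if (geom$kind == "slab") electrode_patch(geom, e0) else e0
    patch <- patch[geom$segment_id[patch] == sgid & !is.na(
      geom$segment_id[patch])]
    if (length(patch) == 0) patch <- e0
    sites[[as.character(sgid)]] <- stimulus(patch, onset = 0,
                                            duration = cfg$stim_duration,
                                            amplitude = cfg$stim_amplitude)
  }
  sites
}

#' Population vulnerability summary
#'
#' Aggregates per-site protocol outcomes into the population bookkeeping:
#' totals, arrhythmic ratio, and a per-peel-level summary table (patients,
#' ischemia burden, patients with reentry, percent of segments with
#' reentry, reentries per model). UR and R both count as arrhythmic.
#'
#' @param outcomes data frame with columns `model_id`, `patient`, `peel`,
#'   `segment`, `outcome` (`"NR"`, `"UR"`, `"R"`).
#' @param manifest optional population manifest carrying `model_id` and
#'   `ischemic_pct` (adds ischemia statistics to the summary).
#' @return A `vulnerability_summary`: `tested`, `arrhythmic`, `ratio`
#'   (3 d.p. in the printout; full precision stored), `by_peel` data frame.
#' @export
vulnerability_summary <- function(outcomes, manifest = NULL) {
  stopifnot(all(c("model_id", "patient", "peel", "segment", "outcome")
                %in% names(outcomes)))
  if (anyDuplicated(outcomes[c("model_id", "segment")]))
    stop("duplicate (model, segment) outcome rows")
  pos <- outcomes$outcome %in% c("UR", "R")
  tested <- nrow(outcomes)
  arr <- sum(pos)
  per_model <- aggregate(pos, by = list(model_id = outcomes$model_id,
                                        peel = outcomes$peel), FUN = sum)
  names(per_model)[3] <- "n_reentry"
  if (!is.null(manifest))
    per_model <- merge(per_model,
                       manifest[c("model_id", "ischemic_pct")],
                       by = "model_id", all.x = TRUE)
  lev <- sort(unique(outcomes$peel))
  by_peel <- do.call(rbind, lapply(lev, function(pl) {
    pm <- per_model[per_model$peel == pl, ]
    segs <- sum(outcomes$peel == pl)
    data.frame(
      peel = pl,
      n_patients = nrow(pm),
      mean_ischemia_pct = if ("ischemic_pct" %in% names(pm))
        mean(pm$ischemic_pct) else NA_real_,
      sd_ischemia_pct = if ("ischemic_pct" %in% names(pm))
        sd(pm$ischemic_pct) else NA_real_,
      n_patients_reentry = sum(pm$n_reentry > 0),
      pct_patients_reentry = 100 * mean(pm$n_reentry > 0),
      pct_segments_reentry = 100 * sum(pm$n_reentry) / segs,
      mean_reentries_per_model = mean(pm$n_reentry),
      sd_reentries_per_model = sd(pm$n_reentry))
  }))
  structure(list(tested = tested, arrhythmic = arr,
                 ratio = arr / tested, by_peel = by_peel,
                 per_model = per_model),
            class = "vulnerability_summary")
}

#' @export
print.vulnerability_summary <- function(x, ...) {
  cat(sprintf("vulnerability: %d of %d segments arrhythmic (ratio %.3f)\n",
              x$arrhythmic, x$tested, x$ratio))
  print(x$by_peel, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate a model population
#'
#' Runs a per-(model, segment) outcome function over a population and
#' aggregates the result. The default outcome function is the full
#' monodomain protocol (desk-scale populations only); the surrogate
#' inducibility model ([surrogate_outcome_fn()]) makes population-scale
#' experiments tractable.
#'
#' @param pop a `model_population` from [build_augmented_population()].
#' @param outcome_fn `function(model, segment_id)` returning `"NR"`,
#'   `"UR"` or `"R"`. Models failing to evaluate are logged and excluded.
#' @param cfg a [protocol_config()].
#' @return List `outcomes` (data frame), `summary`
#'   ([vulnerability_summary()]), `failed` (model ids).
#' @export
evaluate_population <- function(pop, outcome_fn, cfg = protocol_config()) {
  stopifnot(inherits(pop, "model_population"))
  rows <- list()
  failed <- character(0)
  for (mid in names(pop$models)) {
    m <- pop$models[[mid]]
    segs <- sort(unique(stats::na.omit(m$geometry$segment_id)))
    res <- try({
      do.call(rbind, lapply(segs, function(sg) {
        data.frame(model_id = mid, patient = as.character(m$patient),
                   peel = m$peel, segment = sg,
                   outcome = outcome_fn(m, sg))
      }))
    }, silent = TRUE)
    if (inherits(res, "try-error")) { failed <- c(failed, mid); next }
    rows[[mid]] <- res
  }
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL
  list(outcomes = outcomes,
       summary = vulnerability_summary(outcomes, pop$manifest),
       failed = failed)
}
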