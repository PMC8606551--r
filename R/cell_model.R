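# ten Tusscher-Panfilov (2006) cell model: parameter sets, paced runs,
# action-potential measurement, S1S2 restitution.

# internal parameter-vector layout shared with the C++ kernel
.par_names <- c("K_o", "ina_scale", "ical_scale", "f_atp", "g_katp",
                "G_Kr", "G_Ks", "G_pCa", "G_pK", "tau_f_mult")

#' Ionic model parameter set
#'
#' Builds a parameter set for the ten Tusscher-Panfilov (2006) epicardial
#' ventricular myocyte model, optionally with ischemic modifications.
#'
#' The `"steep"` preset selects the published slope-1.8 restitution variant
#' of the model (`G_pCa` = 0.8666 nS/pF, `G_pK` = 0.00219 nS/pF, doubled
#' voltage-dependent inactivation time constant of the L-type calcium
#' current), which promotes alternans and wavebreak. Ischemic remodeling is
#' expressed through `K_o` (elevated extracellular potassium), `ina_scale` /
#' `ical_scale` (fractional sodium and L-type calcium current conductance),
#' and `f_atp` (fraction of open ATP-sensitive potassium channels; the
#' current is `g_katp * f_atp * (K_o/5.4)^0.24 * (V - E_K)`).
#'
#' `g_katp` defaults to 3.9 nS/pF, calibrated once so that
#' `f_atp = 0.0049` shortens the healthy APD90 by 10-25 percent.
#'
#' @param preset `"baseline"` for the published default conductances or
#'   `"steep"` for the steep-restitution (slope 1.8) variant.
#' @param K_o extracellular potassium, mM (healthy 5.4).
#' @param ina_scale,ical_scale multiplicative scales on I_Na and I_CaL
#'   maximal conductance, in (0, 1].
#' @param f_atp fraction of open ATP-sensitive K+ channels in \[0, 1\].
#' @param g_katp maximal ATP-sensitive K+ conductance, nS/pF.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(preset = c("baseline", "steep"), K_o = 5.4,
                        ina_scale = 1, ical_scale = 1, f_atp = 0,
                        g_katp = 3.9) {
  preset <- match.arg(preset)
  stopifnot(K_o >= 4, K_o <= 12, ina_scale > 0, ina_scale <= 1,
            ical_scale > 0, ical_scale <= 1, f_atp >= 0, f_atp <= 1)
  p <- c(K_o, ina_scale, ical_scale, f_atp, g_katp,
         0.153, 0.392, 0.1238, 0.0146, 1)
  names(p) <- .par_names
  if (preset == "steep") {
    p["G_pCa"] <- 0.8666
    p["G_pK"] <- 0.00219
    p["tau_f_mult"] <- 2
  }
  structure(list(par = p, preset = preset), class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("TP06 cell parameters (preset:", x$preset, ")\n")
  print(round(x$par, 5))
  invisible(x)
}

.par_vec <- function(params) {
  if (inherits(params, "cell_params")) params$par
  else if (is.numeric(params) && length(params) == length(.par_names)) {
    names(params) <- .par_names; params
  } else stop("'params' must be a cell_params object")
}

#' Resting (paced steady-state) initial state vector
#'
#' @return Named numeric state vector (membrane voltage in mV, gating
#'   variables, intracellular/SR concentrations in mM).
#' @export
cell_initial_state <- function() {
  s <- cpp_tp06_initial_state()
  names(s) <- c("V", "K_i", "Na_i", "Ca_i", "Ca_ss", "Ca_sr", "m", "h", "j",
                "xr1", "xr2", "xs", "r", "s", "d", "f", "f2", "fcass", "Rq")
  s
}

#' Membrane currents at a given state
#'
#' Evaluates all transmembrane currents of the (possibly ischemically
#' modified) model at a fixed state; mainly for verification against
#' independent implementations.
#'
#' @param state named state vector as from [cell_initial_state()].
#' @param params a [cell_params()] object.
#' @return Named vector of currents (pA/pF) and reversal potentials (mV).
#' @export
cell_currents <- function(state, params) {
  stopifnot(all(is.finite(state)))
  cpp_tp06_currents(unname(state), unname(.par_vec(params)))
}

#' Full state time-derivative
#'
#' @param state state vector.
#' @param params a [cell_params()] object.
#' @param i_stim stimulus current in pA/pF (negative = depolarizing).
#' @return Named derivative vector (gating derivatives as `(x_inf - x)/tau`).
#' @export
cell_derivatives <- function(state, params, i_stim = 0) {
  if (!all(is.finite(state))) stop("non-finite state")
  d <- cpp_tp06_derivatives(unname(state), unname(.par_vec(params)), i_stim)
  names(d) <- names(cell_initial_state())
  d
}

#' Paced single-cell simulation
#'
#' Runs the ionic model under a regular pacing train and returns the
#' voltage trace.
#'
#' @param params a [cell_params()] object.
#' @param cl_ms pacing cycle length, ms.
#' @param n_beats number of stimuli.
#' @param dt time step, ms (Rush-Larsen gating; must be <= 0.05).
#' @param stim_offset time of the first stimulus, ms.
#' @param stim_amp,stim_dur stimulus amplitude (pA/pF) and duration (ms).
#' @param t_pad extra simulated time after the last cycle, ms.
#' @param record_every recording interval in steps.
#' @param init_state optional initial state (defaults to the paced resting
#'   state).
#' @return An `ap_trace` object: data frame columns `time` (ms), `V` (mV),
#'   plus attributes `stim_times` and `final_state`. The `steady_state`
#'   attribute is TRUE when the last two beats' APD90 differ by < 1 ms.
#' @export
simulate_cell <- function(params, cl_ms = 1000, n_beats = 5, dt = 0.02,
                          stim_offset = 50, stim_amp = 52, stim_dur = 1,
                          t_pad = 500, record_every = 5, init_state = NULL) {
  stopifnot(dt > 0, dt <= 0.05, n_beats >= 0, cl_ms > 0)
  if (is.null(init_state)) init_state <- cell_initial_state()
  stim_times <- if (n_beats > 0) stim_offset + (seq_len(n_beats) - 1) * cl_ms
                else numeric(0)
  t_end <- if (n_beats > 0) stim_offset + (n_beats - 1) * cl_ms + t_pad
           else t_pad
  res <- cpp_simulate_cell(unname(.par_vec(params)), unname(init_state),
                           stim_times, stim_dur, stim_amp, t_end, dt,
                           as.integer(record_every))
  tr <- data.frame(time = res$time, V = res$V)
  fs <- res$final_state
  names(fs) <- names(cell_initial_state())
  ss <- NA
  if (n_beats >= 2) {
    a <- try(apd(structure(tr, stim_times = stim_times, class =
                             c("ap_trace", "data.frame"))), silent = TRUE)
    if (!inherits(a, "try-error") && length(a) >= 2) {
      last2 <- tail(a, 2)
      ss <- abs(diff(last2)) < 1
    }
  }
  structure(tr, stim_times = stim_times, final_state = fs,
            steady_state = ss, class = c("ap_trace", "data.frame"))
}

#' Action potential duration(s) from a voltage trace
#'
#' Detects action potentials as upward crossings of a detection threshold,
#' anchors each at its maximum-upstroke-velocity time, and measures the time
#' to a given percent repolarization toward the pre-stimulus diastolic
#' voltage.
#'
#' @param trace an `ap_trace` (or data frame with `time`, `V` columns).
#' @param level percent repolarization (90 gives APD90).
#' @param threshold AP detection threshold, mV.
#' @return Numeric vector of APDs (ms), one per detected and fully
#'   repolarized AP; attribute `upstroke_times` carries the anchors.
#' @export
apd <- function(trace, level = 90, threshold = -40) {
  tm <- trace$time
  V <- trace$V
  if (any(diff(tm) <= 0)) stop("trace time must be strictly increasing")
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold)
  if (length(up) == 0) stop("no action potential detected in trace")
  apds <- numeric(0)
  anchors <- numeric(0)
  for (k in seq_along(up)) {
    i0 <- up[k]
    i_end <- if (k < length(up)) up[k + 1] - 1 else length(V)
    # diastolic reference: voltage just before the upstroke
    pre <- max(1, i0 - 5)
    v_dia <- V[pre]
    # anchor at max dV/dt within 10 ms around the crossing
    w <- which(tm >= tm[i0] - 2 & tm <= tm[i0] + 10)
    dv <- diff(V[w]) / diff(tm[w])
    i_up <- w[which.max(dv)]
    seg <- i_up:i_end
    v_peak <- max(V[seg])
    v_target <- v_peak - (level / 100) * (v_peak - v_dia)
    ip <- seg[which.max(V[seg])]
    after <- ip:i_end
    hit <- which(V[after] <= v_target)
    if (length(hit) == 0) next # AP did not repolarize within the trace
    apds <- c(apds, tm[after[hit[1]]] - tm[i_up])
    anchors <- c(anchors, tm[i_up])
  }
  if (length(apds) == 0) stop("no fully repolarized action potential found")
  structure(apds, upstroke_times = anchors)
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("ap_trace: %d samples over %.1f ms, %d stimuli\n",
              nrow(x), max(x$time), length(attr(x, "stim_times"))))
  invisible(x)
}

#' S1S2 action-potential-duration restitution
#'
#' Paces the cell to approximate steady state at `s1_cl`, then for each
#' diastolic interval delivers a premature S2 after the last S1's APD90 and
#' measures the S2 APD90. The maximum finite-difference slope d(APD)/d(DI)
#' over adjacent grid points is reported; a slope above 1 is the classical
#' alternans/wavebreak criterion.
#'
#' @param params a [cell_params()] object (e.g. `cell_params("steep")`).
#' @param s1_cl S1 cycle length, ms.
#' @param di_grid diastolic intervals to probe, ms (order irrelevant).
#' @param n_s1 number of conditioning S1 beats.
#' @param dt time step, ms.
#' @return List with `max_slope`, `curve` (data frame `di`, `apd`), and
#'   `s1_apd`.
#' @export
restitution_slope <- function(params, s1_cl = 600,
                              di_grid = c(500, 400, 300, 250, 200, 150, 120,
                                          100, 80, 60, 50, 40, 30, 25, 20,
                                          15, 10, 5),
                              n_s1 = 30, dt = 0.02) {
  di_grid <- sort(unique(di_grid), decreasing = TRUE)
  pv <- unname(.par_vec(params))
  s0 <- unname(cell_initial_state())
  # conditioning train up to the onset of the final S1
  if (n_s1 > 1) {
    pre <- cpp_simulate_cell(pv, s0, (seq_len(n_s1 - 1) - 1) * s1_cl,
                             1, 52, (n_s1 - 1) * s1_cl, dt, 25L)
    s0 <- pre$final_state
  }
  # final S1 alone: measure its APD90 from this exact state
  last <- cpp_simulate_cell(pv, s0, 0, 1, 52, min(s1_cl, 600), dt, 1L)
  tr <- data.frame(time = last$time, V = last$V)
  a1 <- apd(tr)
  s1_apd <- a1[1]
  t_up <- attr(a1, "upstroke_times")[1]
  curve <- data.frame(di = numeric(0), apd = numeric(0))
  for (di in di_grid) {
    t_s2 <- t_up + s1_apd + di
    run <- try(cpp_simulate_cell(pv, s0, c(0, t_s2), 1, 52,
                                 t_s2 + 600, dt, 1L), silent = TRUE)
    if (inherits(run, "try-error")) next
    tr2 <- data.frame(time = run$time, V = run$V)
    # capture criterion: the S2 response must be a full AP with overshoot
    if (max(tr2$V[tr2$time > t_s2]) <= 0) next
    a <- try(apd(tr2), silent = TRUE)
    if (inherits(a, "try-error")) next
    ups <- attr(a, "upstroke_times")
    k <- which(ups > t_s2 - 5)
    if (length(k) == 0) next # S2 failed to elicit an AP
    curve <- rbind(curve, data.frame(di = di, apd = a[k[1]]))
  }
  if (nrow(curve) < 2)
    stop("S2 failed to elicit an action potential over the DI grid")
  curve <- curve[order(curve$di), ]
  slopes <- diff(curve$apd) / diff(curve$di)
  list(max_slope = max(slopes), curve = curve, s1_apd = unname(s1_apd))
}
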