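# Ionic model: current oracle agreement, Nernst potentials, paced
# behaviour, APD measurement, ischemic modifications, restitution.

test_that("currents match an independent implementation at fixed states", {
  s0 <- cell_initial_state()
  set.seed(42)
  states <- list(s0)
  for (k in 1:4) {
    s <- s0
    s["V"] <- runif(1, -85, 30)
    s[c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2",
        "fcass")] <- runif(12)
    s["Ca_i"] <- runif(1, 5e-5, 5e-4)
    s["Ca_ss"] <- runif(1, 1e-4, 1e-3)
    states[[k + 1]] <- s
  }
  for (pp in list(cell_params(),
                  cell_params(K_o = 10, ina_scale = 0.7,
                              ical_scale = 0.7, f_atp = 0.0049,
                              g_katp = 1.5))) {
    for (s in states) {
      got <- cell_currents(s, pp)
      want <- oracle_currents(s, pp$par)
      for (nm in names(want))
        expect_equal(got[[nm]], want[[nm]], tolerance = 1e-6,
                     label = nm)
    }
  }
})

test_that("potassium reversal follows the Nernst equation", {
  s <- cell_initial_state()
  s["K_i"] <- 138
  got <- cell_currents(s, cell_params(K_o = 10))
  expect_equal(got[["E_K"]],
               8314.472 * 310 / 96485.3415 * log(10 / 138),
               tolerance = 1e-9)
  expect_lt(abs(got[["E_K"]] - (-70)), 1.5) # about -70 mV at 37 C

  # f_ATP = 0 switches the KATP current off exactly
  expect_identical(cell_currents(s, cell_params(f_atp = 0))[["I_Katp"]], 0)
  # healthy-limit: scales at 1 reproduce the unmodified derivative
  d1 <- cell_derivatives(s, cell_params())
  d2 <- cell_derivatives(s, cell_params(ina_scale = 1, ical_scale = 1,
                                        K_o = 5.4, f_atp = 0))
  expect_identical(d1, d2)
  expect_error(cell_derivatives(replace(s, 1, NaN), cell_params()),
               "non-finite")
})

test_that("paced cell rests, fires and stays quiescent without stimulus", {
  tr <- simulate_cell(cell_params(), cl_ms = 1000, n_beats = 2)
  pre <- tr$V[tr$time < 45]
  expect_true(all(pre > -88 & pre < -84))
  expect_gt(max(tr$V), 0) # overshooting APs

  # elevated K_o depolarizes the resting membrane
  tr_isch <- simulate_cell(cell_params(K_o = 10), cl_ms = 1000,
                           n_beats = 1)
  expect_gt(tr_isch$V[tr_isch$time < 45][100], pre[100])

  # zero stimulus: within 1 mV of rest for 1 s
  q <- simulate_cell(cell_params(), n_beats = 0, t_pad = 1000)
  expect_lt(diff(range(q$V)), 1)
})

test_that("APD measurement behaves on constructed and simulated traces", {
  # square pulse: -85 mV baseline, +20 mV for 200 ms
  t <- seq(0, 400, by = 0.5)
  v <- ifelse(t >= 50 & t < 250, 20, -85)
  a <- apd(data.frame(time = t, V = v)) # 90% repol target is -74.5 mV
  expect_lt(abs(a[1] - 200), 2 * 0.5) # within one sample step of 200 ms

  # two identical APs give identical APDs; APD90 >= APD50
  tr <- simulate_cell(cell_params(), cl_ms = 800, n_beats = 3)
  a90 <- apd(tr, 90)
  a50 <- apd(tr, 50)
  expect_lt(abs(a90[2] - a90[3]), 1)
  expect_true(all(a90 >= a50[seq_along(a90)]))

  expect_error(apd(data.frame(time = t, V = rep(-85, length(t)))),
               "no action potential")
})

test_that("KATP activation shortens the action potential monotonically", {
  apd_at <- function(f) {
    tr <- simulate_cell(cell_params(f_atp = f, g_katp = 1.5),
                        cl_ms = 1000, n_beats = 2)
    tail(apd(tr), 1)
  }
  a <- vapply(c(0, 0.0049, 0.02), apd_at, numeric(1))
  expect_true(all(diff(a) < 0))
  # the calibrated default shortens healthy APD90 by 10-25%
  red <- 100 * (1 - a[2] / a[1])
  expect_gt(red, 10)
  expect_lt(red, 25)
})

test_that("gating variables stay in [0,1] under long stochastic pacing", {
  set.seed(7)
  s <- unname(cell_initial_state())
  p <- cell_params("steep", K_o = 9, ina_scale = 0.7, ical_scale = 0.7,
                   f_atp = 0.0049, g_katp = 1.5)
  # irregular strong pacing to sweep the state space
  stim <- cumsum(runif(20, 150, 400))
  res <- reentryforge:::cpp_simulate_cell(unname(p$par), s, stim, 1, 52,
                                          max(stim) + 400, 0.02, 50L)
  fs <- res$final_state
  expect_true(all(fs[7:19] >= 0 & fs[7:19] <= 1))
  expect_true(all(is.finite(fs)))
})

test_that("restitution protocol is grid-order independent and steepens
           with the steep preset", {
  r1 <- restitution_slope(cell_params("steep"), n_s1 = 15,
                          di_grid = c(500, 400, 200, 120, 80, 60, 50, 40))
  r2 <- restitution_slope(cell_params("steep"), n_s1 = 15,
                          di_grid = c(40, 80, 500, 50, 120, 60, 200, 400))
  expect_equal(r1$curve, r2$curve)
  # the curve flattens at long diastolic intervals
  long <- r1$curve[r1$curve$di >= 400, ]
  expect_lt(max(diff(long$apd) / diff(long$di)), 0.2)

  rb <- restitution_slope(cell_params(), n_s1 = 15,
                          di_grid = c(500, 400, 200, 120, 80, 60, 50, 40))
  expect_gt(r1$max_slope, 1)
  expect_gt(r1$max_slope, rb$max_slope)
})
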