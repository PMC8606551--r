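# Monodomain solver: quiescence, wavefront propagation, determinism,
# conduction velocity physics, activation detection, conservation,
# refinement convergence and reentry capability.

strand <- function(nx = 80, ny = 10, dx = 0.25, endo = 0, epi = 0) {
  g <- assign_fibers(generate_slab(nx, ny, dx), endo, epi)
  list(geom = g, cond = conductivity_field(g),
       cmap = cell_param_map(NULL, preset = "baseline"))
}

test_that("resting tissue stays quiescent and stimulated tissue fires once", {
  s <- strand(40, 10)
  q <- run_monodomain(s$geom, s$cond, s$cmap, list(), t_end = 100,
                      dt = 0.05)
  expect_identical(nrow(q$events), 0L)
  expect_true(all(abs(q$final_state[, 1] - q$final_state[1, 1]) < 1))

  stim <- stimulus(electrode_patch(s$geom, 20 + 4 * 40, 2), onset = 2)
  r <- run_monodomain(s$geom, s$cond, s$cmap, list(stim), t_end = 40,
                      dt = 0.05)
  # every element activates exactly once
  expect_identical(sort(unique(r$events$element)), seq_len(400))
  expect_identical(nrow(r$events), 400L)
  # activation time increases with distance from the electrode
  ctr <- colMeans(s$geom$centers[stim$site, ])
  d <- sqrt(rowSums((s$geom$centers[r$events$element, ] -
                       matrix(ctr, 400, 2, byrow = TRUE))^2))
  # elliptical wavefront under anisotropy: time grows with distance but
  # the Euclidean fit is only approximately linear
  fit <- stats::lm(r$events$time ~ d)
  expect_gt(coef(fit)[["d"]], 0)
  expect_gt(summary(fit)$r.squared, 0.85)

  # determinism
  r2 <- run_monodomain(s$geom, s$cond, s$cmap, list(stim), t_end = 40,
                       dt = 0.05)
  expect_identical(r$events, r2$events)
})

test_that("conduction velocity follows cable theory", {
  s <- strand()
  stim <- stimulus(electrode_patch(s$geom, 3 + 4 * 80, 2), onset = 2)
  ray <- (20:75) + 4 * 80
  r <- run_monodomain(s$geom, s$cond, s$cmap, list(stim), t_end = 45,
                      dt = 0.02)
  cv <- conduction_velocity(r, s$geom, ray)
  expect_gt(cv, 0.3)
  expect_lt(cv, 0.8)

  # 40% conductivity reduction: CV ratio ~ sqrt(0.6) within 10%
  c2 <- s$cond
  for (nm in c("Dxx", "Dyy", "Dxy")) c2[[nm]] <- s$cond[[nm]] * 0.6
  r2 <- run_monodomain(s$geom, c2, s$cmap, list(stim), t_end = 55,
                       dt = 0.02)
  cv2 <- conduction_velocity(r2, s$geom, ray)
  expect_lt(abs(cv2 / cv - sqrt(0.6)) / sqrt(0.6), 0.10)

  # transverse propagation is slower when sigma_t < sigma_l
  st <- strand(endo = 90, epi = 90)
  rt <- run_monodomain(st$geom, st$cond, st$cmap, list(stim), t_end = 70,
                       dt = 0.02)
  expect_lt(conduction_velocity(rt, st$geom, ray), cv)

  expect_error(conduction_velocity(
    structure(list(events = data.frame(element = 1L, time = 1)),
              class = "sim_result"), s$geom, ray), "fewer than 3")
})

test_that("activation detection handles chatter and double beats", {
  t <- seq(0, 1000, by = 1)
  # monotone subthreshold trace: no events
  expect_identical(
    nrow(detect_activations(seq(-85, -60, length.out = length(t)), t)), 0L)
  # two crossings 300 ms apart: two events
  v <- rep(-85, length(t))
  v[t >= 100 & t < 150] <- 0
  v[t >= 400 & t < 450] <- 0
  ev <- detect_activations(v, t)
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$time, c(100, 400))
  # threshold chatter suppressed by the lockout
  vc <- rep(-85, length(t))
  vc[t >= 100 & t < 140] <- rep(c(-39, -41), 20)
  ev2 <- detect_activations(vc, t, lockout = 50)
  expect_identical(nrow(ev2), 1L)
})

test_that("no-flux diffusion conserves the spatial mean", {
  # axis-aligned fibers over a heterogeneous (ischemia-scaled) field: the
  # face-flux main terms are exactly conservative. (The mixed-derivative
  # cross term for rotated fibers uses a non-conservative central scheme.)
  g <- assign_fibers(generate_slab(30, 30, 0.25,
                                   ischemia_spec(radius = 1.5,
                                                 n_layers = 2)), 0, 0)
  cond <- conductivity_field(g)
  cmap <- cell_param_map(grade_layers(2))
  init <- matrix(rep(cell_initial_state(), each = 900), nrow = 900)
  init[, 1] <- runif(900, -90, 20) # arbitrary voltage field
  r <- run_monodomain(g, cond, cmap, list(), t_end = 20, dt = 0.05,
                      init_state = init, reaction = FALSE)
  expect_equal(mean(r$final_state[, 1]), mean(init[, 1]),
               tolerance = 1e-10)
  # and the field actually diffused
  expect_lt(sd(r$final_state[, 1]), sd(init[, 1]))
})

test_that("conduction velocity converges under mesh refinement", {
  # same 15 x 1.5 mm strand at dx = 0.2 and 0.1 mm
  cmap <- cell_param_map(NULL, preset = "baseline")
  cvs <- vapply(c(0.2, 0.1), function(dx) {
    nx <- round(15 / dx); ny <- max(10, round(1.5 / dx))
    g <- assign_fibers(generate_slab(nx, ny, dx), 0, 0)
    stim <- stimulus(electrode_patch(g, 3 + (ny %/% 2) * nx,
                                     max(2, round(0.5 / dx))), onset = 2)
    r <- run_monodomain(g, conductivity_field(g), cmap, list(stim),
                        t_end = 35, dt = 0.02)
    ray <- (round(nx / 4):round(nx * 0.9)) + (ny %/% 2) * nx
    conduction_velocity(r, g, ray)
  }, numeric(1))
  expect_lt(abs(cvs[2] - cvs[1]) / cvs[2], 0.05)
})

test_that("a cross-field S2 on a graded ischemic sheet can reexcite", {
  nx <- 60; ny <- 60
  g <- generate_slab(nx, ny, 0.25,
                     ischemia_spec(center = c(7.5, 7.5), radius = 4,
                                   n_layers = 5))
  g <- assign_fibers(assign_aha_segments(g), 0, 0)
  al <- assign_layers(g, 5)
  cmap <- cell_param_map(grade_layers(al$layers), preset = "steep",
                         g_katp = 1.5)
  cond <- conductivity_field(al$geometry)
  left <- which(seq_len(nx * ny) %% nx %in% 1:2)
  quad <- which((seq_len(nx * ny) - 1) %% nx < nx / 2 &
                  (seq_len(nx * ny) - 1) %/% nx < ny / 2)
  r1 <- run_monodomain(al$geometry, cond, cmap,
                       list(stimulus(left, onset = 10, duration = 2,
                                     amplitude = 150)),
                       t_end = 330, dt = 0.05)
  r2 <- run_monodomain(al$geometry, cond, cmap,
                       list(stimulus(quad, onset = 345, duration = 2,
                                     amplitude = 150)),
                       t_end = 815, dt = 0.05,
                       init_state = r1$final_state, t0 = 330)
  ev <- r2$events[r2$events$time > 345 + 50, ]
  expect_gt(sum(table(ev$element) >= 2), 0) # at least one reexcitation
})
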