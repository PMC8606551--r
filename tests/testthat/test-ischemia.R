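# Layer assignment, grading law, peeling, and population augmentation.

test_that("layer indices follow boundary distance", {
  # single-element region, L = 1
  g1 <- generate_slab(12, 12, 0.25)
  ctr <- as.integer(6 + 5 * 12)
  g1$region_label[ctr] <- 1L
  a1 <- assign_layers(g1, 1)
  expect_identical(a1$layers$layer_index, 1L)
  expect_identical(a1$layers$element, ctr)

  # concentric disc: layer index nondecreasing along rays from rim to centre
  al <- small_ischemic_slab(60, 60, radius = 4, n_layers = 5)
  g <- al$geometry
  nx <- 60
  ctr_xy <- g$meta$isch_center
  for (ang in c(0, pi / 3, 2.1)) {
    rr <- seq(4, 0, by = -0.25)
    idx <- vapply(rr, function(r) {
      p <- ctr_xy + r * c(cos(ang), sin(ang))
      i <- pmin(nx, pmax(1, round(p[1] / 0.25 + 0.5)))
      j <- pmin(nx, pmax(1, round(p[2] / 0.25 + 0.5)))
      as.integer(i + (j - 1) * nx)
    }, integer(1))
    lab <- g$region_label[idx]
    lab <- lab[lab > 0]
    expect_true(all(diff(lab) >= 0))
  }

  # L = 1 puts every ischemic element in layer 1
  aL1 <- assign_layers(al$geometry, 1)
  expect_true(all(aL1$layers$layer_index == 1L))

  # too many layers collapses with a warning
  g2 <- generate_slab(12, 12, 0.25)
  g2$region_label[c(72, 73)] <- 1L
  expect_warning(a2 <- assign_layers(g2, 10), "distinct distance levels")
  expect_lte(a2$layers$L, 2L)
})

test_that("grading law matches the hand-derived layout", {
  tab5 <- grade_layers(5)
  expect_equal(tab5$K_o, c(7.5, 8.125, 8.75, 9.375, 10.0))
  expect_equal(tab5$ina_scale, c(0.8, 0.8, 0.7, 0.7, 0.7))
  expect_equal(tab5$ical_scale, c(0.8, 0.8, 0.7, 0.7, 0.7))
  expect_true(all(tab5$f_atp == 0.0049))
  expect_true(all(tab5$cond_scale == 0.6))

  tab1 <- grade_layers(1)
  expect_equal(tab1$K_o, 10.0)
  expect_equal(tab1$ina_scale, 0.7)

  # K_o monotone nondecreasing with exact endpoints for any L
  for (L in c(2, 3, 10, 27)) {
    tab <- grade_layers(L)
    expect_true(all(diff(tab$K_o) >= 0))
    expect_equal(tab$K_o[1], 7.5)
    expect_equal(tab$K_o[L], 10.0)
  }
})

test_that("peeling removes outer layers and regenerates the gradient", {
  al <- small_ischemic_slab(60, 60, radius = 4, n_layers = 12)
  L <- al$layers$L
  expect_gte(L, 11)

  # k = 0 is the identity
  p0 <- peel_layers(al$geometry, al$layers, 0)
  expect_identical(p0$geometry$region_label, al$geometry$region_label)

  # peel 10 of 12 leaves 2 layers, strictly fewer ischemic elements
  p10 <- peel_layers(al$geometry, al$layers, 10)
  expect_true(p10$valid)
  expect_identical(p10$layers$L, L - 10L)
  expect_lt(sum(p10$geometry$region_label > 0),
            sum(al$geometry$region_label > 0))
  # the regenerated outermost layer is graded back to the mild end
  expect_equal(grade_layers(p10$layers)$K_o[1], 7.5)

  # composition: peel(a) then peel(b) equals peel(a+b)
  pa <- peel_layers(al$geometry, al$layers, 3)
  pab <- peel_layers(pa$geometry, pa$layers, 4)
  p7 <- peel_layers(al$geometry, al$layers, 7)
  expect_identical(pab$geometry$region_label, p7$geometry$region_label)

  # peeling everything marks the model invalid
  pall <- peel_layers(al$geometry, al$layers, L)
  expect_false(pall$valid)
  expect_true(all(pall$geometry$region_label == 0))

  expect_error(peel_layers(al$geometry, al$layers, -1), ">= 0")

  # ischemic volume strictly decreasing in peel level until invalid
  vols <- vapply(c(0, 1, 2, 5, 10), function(k) {
    p <- peel_layers(al$geometry, al$layers, k)
    unname(geometry_volumes(p$geometry)["ischemic"])
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("augmented population bookkeeping matches the peel arithmetic", {
  base <- lapply(1:3, function(i) {
    al <- small_ischemic_slab(60, 60, radius = 4, n_layers = 12, seed = i)
    list(geometry = al$geometry, layers = al$layers, id = paste0("P", i))
  })
  pop <- build_augmented_population(base, peel_set = c(1, 2, 5, 10))
  expect_equal(nrow(pop$manifest), 15) # 3 baseline + 3 x 4 peels
  expect_identical(attr(pop$manifest, "excluded"), 0L)
  expect_true(all(table(pop$manifest$peel) == 3))

  # a model with fewer layers drops its deepest peel
  base8 <- list(list(
    geometry = small_ischemic_slab(40, 40, radius = 2, n_layers = 8)$geometry,
    layers = small_ischemic_slab(40, 40, radius = 2, n_layers = 8)$layers,
    id = "S"))
  pop8 <- build_augmented_population(base8, peel_set = c(1, 2, 5, 10))
  expect_identical(sort(pop8$manifest$peel), c(0, 1, 2, 5))
  expect_identical(attr(pop8$manifest, "excluded"), 1L)
})
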