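test_that("zero base dose gives a uniform prescription inside the optimization interval", {
  seg <- adult_segmentation(180)
  ph <- adult_phantom(180)
  grid <- tbiplan:::default_dose_grid(ph$ct)
  ## interior VMAT sub-target: junction ramps at both ends
  d <- vmat_surrogate_dose(seg$set, rx = 1.65, grid = grid, index = 2)
  st <- seg$set$subtargets[2, ]
  cc <- vol_axis_coords(d)
  core <- cc$z > st$opt_inf + 55 & cc$z < st$opt_sup - 55
  expect_true(all(abs(d$values[, , core] - 1.65) < 1e-12))
  outside <- cc$z < st$opt_inf - 5 | cc$z > st$opt_sup + 5
  expect_true(all(d$values[, , outside] == 0))
})

test_that("a base dose above the prescription is rejected", {
  seg <- adult_segmentation(180)
  ph <- adult_phantom(180)
  grid <- tbiplan:::default_dose_grid(ph$ct)
  base <- tbiplan:::as_dose(grid, array(2, dim = dim(grid$values)))
  expect_error(vmat_surrogate_dose(seg$set, base_dose = base, rx = 1.65,
                                   grid = grid, index = 2),
               "exceeds the prescription")
  expect_error(vmat_surrogate_dose(seg$set, rx = 1.65, grid = grid,
                                   index = which(seg$set$subtargets$kind == "APPA")[1]),
               "VMAT")
})

test_that("the surrogate descends as the complement of an ascending wedge base", {
  w <- water_phantom(c(150, 150, 300))
  params <- segmentation_params()
  ## wedge at a junction placed at z = 0 in the water block
  jz <- 0
  beams <- make_step_wedge(c(0, 0, jz))
  wedge <- sum_dose(lapply(beams, compute_beam_dose, ct = w,
                           constants = physics_constants(), grid = w))
  base <- normalize_wedge_base(wedge, c(0, 0, jz), rx = 1.65, params)
  ## a sub-target sitting above the junction inside the water block
  loc <- list(kind = "VMAT", index = 2L,
              z_inf = jz, z_sup = jz + 230,
              opt_inf = jz - 25, opt_sup = jz + 230,
              interior_sup = FALSE, interior_inf = TRUE,
              is_last = FALSE, ofz = 25, iso = c(0, 0, jz + 115))
  d <- vmat_surrogate_dose(loc, base_dose = base, rx = 1.65, grid = w)
  cc <- vol_axis_coords(w)
  i0 <- which.min(abs(cc$x)); j0 <- which.min(abs(cc$y))
  ks <- which(cc$z >= jz - 25 & cc$z <= jz + 25)
  prof <- d$values[i0, j0, ks]
  baseprof <- base$values[i0, j0, ks]
  ## complement: surrogate + base = rx across the junction, and descending
  expect_equal(prof + baseprof, rep(1.65, length(ks)), tolerance = 1e-9)
  expect_true(all(diff(prof) >= -1e-9))
})

test_that("adjacent sub-target composites close the junction at the prescription", {
  pd <- adult_surrogate_dose(180)
  set <- adult_segmentation(180)$set
  je <- junction_error(pd$composite, pd$composite, set$junctions, rx = 1.65)
  expect_true(all(abs(je$deviation_pct) <= 2))
})

test_that("optimization intervals respect the split-arc field length", {
  set <- adult_segmentation(180)$set
  st <- set$subtargets
  lim <- compute_vmat_limit(set$params$mlc_travel_limit,
                            set$params$field_margin_per_side,
                            2 * set$params$ofz_halfwidth)
  vmat <- st[st$kind == "VMAT", ]
  expect_true(all(vmat$opt_sup - vmat$opt_inf <= lim$field_length * 10 + 1e-9))

  ## a division that would violate the limit is rejected outright
  expect_error(segmentation_params(vmat_max_length = 30) |>
                 (\(p) {
                   ph <- adult_phantom(180)
                   divide_ptv(adult_segmentation(180)$ptv, ph$structures, p)
                 })(),
               "split-arc")
})

test_that("composite plan dose equals the sum of per-isocentre grids", {
  pd <- adult_surrogate_dose(180)
  expect_identical(pd$composite$values,
                   Reduce(`+`, lapply(pd$per_iso, `[[`, "values")))
})

test_that("lung dose rate scales inversely with MU rate and stays below the open-beam rate", {
  ph <- adult_phantom(180)
  plan <- adult_plan(180)
  pd <- adult_surrogate_dose(180)
  lung <- mask_on_grid(tbiplan:::structure_volume(ph$structures, "lungs"),
                       pd$composite)
  r200 <- lung_dose_rate(plan, pd$per_iso, lung, mu_rate = 200)
  r100 <- lung_dose_rate(plan, pd$per_iso, lung, mu_rate = 100)
  expect_gt(r200$rate_cgy_per_min, 0)
  expect_equal(r100$rate_cgy_per_min, r200$rate_cgy_per_min / 2,
               tolerance = 1e-12)
  ## open-beam comparator: the machine's dmax output delivered continuously
  open_rate <- physics_constants()$dose_per_mu * 100 * 200
  expect_lt(r200$rate_cgy_per_min, open_rate)

  broken <- plan
  for (i in seq_along(broken$beams)) broken$beams[[i]]$mu <- 0
  expect_error(lung_dose_rate(broken, pd$per_iso, lung), "zero beam-on")
})
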