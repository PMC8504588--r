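test_that("a zero scenario reproduces the nominal composite bit-identically", {
  plan <- adult_plan(180)
  pd <- adult_surrogate_dose(180)
  n <- nrow(plan$subtargets$subtargets)
  pert <- apply_scenario(plan, shift_scenario(matrix(0, n, 3)), pd$per_iso)
  expect_identical(pert$values, pd$composite$values)

  expect_error(apply_scenario(plan, shift_scenario(matrix(0, n - 1, 3)),
                              pd$per_iso),
               "displacements")
})

test_that("lateral and vertical errors are fully corrected under the default policy", {
  plan <- adult_plan(180)
  pd <- adult_surrogate_dose(180)
  n <- nrow(plan$subtargets$subtargets)
  sh <- matrix(0, n, 3)
  sh[, 1] <- 8; sh[, 2] <- -15
  pert <- apply_scenario(plan, shift_scenario(sh), pd$per_iso)
  expect_identical(pert$values, pd$composite$values)

  ## DVH metrics invariant under arbitrarily large corrected errors
  ptv <- mask_on_grid(adult_segmentation(180)$ptv, pd$composite)
  sh2 <- matrix(0, n, 3); sh2[, 1] <- 40; sh2[, 2] <- 40
  pert2 <- apply_scenario(plan, shift_scenario(sh2), pd$per_iso)
  expect_identical(compute_dvh(pert2, ptv, plan$rx_fx),
                   compute_dvh(pd$composite, ptv, plan$rx_fx))
})

test_that("longitudinal errors follow the linear-ramp closed form", {
  plan <- adult_plan(180)
  pd <- adult_surrogate_dose(180)
  set <- plan$subtargets
  n <- nrow(set$subtargets)
  rx <- plan$rx_fx
  for (dz in c(1, 2, 5, 10, 15, 20, 25)) {
    sh <- matrix(0, n, 3); sh[3, 3] <- dz
    pert <- apply_scenario(plan, shift_scenario(sh), pd$per_iso)
    je <- junction_error(pd$composite, pert, set$junctions, rx = rx)
    ## the shifted sub-target's two junctions deviate by dz/50 of rx
    expect_equal(max(abs(je$deviation_pct)), dz / 50 * 100,
                 tolerance = 2e-2,
                 info = sprintf("dz = %d mm", dz))
    ## hot where the sub-target moved toward, cold where it moved away
    expect_gt(je$deviation_pct[2], 0)
    expect_lt(je$deviation_pct[3], 0)
  }
})

test_that("junction errors report hot and cold deviations correctly", {
  plan <- adult_plan(180)
  pd <- adult_surrogate_dose(180)
  je0 <- junction_error(pd$composite, pd$composite, plan$subtargets$junctions,
                        rx = plan$rx_fx)
  expect_true(all(abs(je0$deviation_pct) < 1e-9))

  hot <- pd$composite
  hot$values <- hot$values * 1.1
  jeh <- junction_error(pd$composite, hot, plan$subtargets$junctions,
                        rx = plan$rx_fx)
  expect_true(all(abs(jeh$deviation_pct - 10) < 1e-6))
})

test_that("feathered junctions dominate abrupt matches for every tested shift", {
  ## engine comparison on a water block: two adjacent AP/PA sub-targets,
  ## feathered 3-segment beams versus single abrupt-edged fields
  w <- water_phantom(c(150, 150, 300))
  constants <- physics_constants()
  set <- two_appa_set(len = 250)
  mk_abrupt <- function(i) {
    st <- set$subtargets[i, ]
    lapply(c(0, 180), function(g)
      tbi_beam(c(0, 0, st$iso_z), g, 90, 6, mu = 100,
               segments = list(beam_segment(st$z_inf - st$iso_z,
                                            st$z_sup - st$iso_z,
                                            -200, 200)),
               technique = "feathered_appa"))
  }
  mk_feathered <- function(i) {
    pair <- make_feathered_appa(set, index = i, mu = 100)
    list(pair$ap, pair$pa)
  }
  dose_of <- function(beams)
    sum_dose(lapply(beams, compute_beam_dose, ct = w, constants = constants,
                    grid = w))
  per_iso_f <- list(dose_of(mk_feathered(1)), dose_of(mk_feathered(2)))
  per_iso_a <- list(dose_of(mk_abrupt(1)), dose_of(mk_abrupt(2)))
  junctions <- set$junctions

  for (dz in c(5, 10, 15, 25)) {
    dev <- function(per_iso) {
      nominal <- sum_dose(per_iso)
      pert <- sum_dose(list(per_iso[[1]],
                            shift_volume(per_iso[[2]], c(0, 0, -dz))))
      max(abs(junction_error(nominal, pert, junctions)$deviation_pct))
    }
    expect_lt(dev(per_iso_f), dev(per_iso_a))
  }
})

test_that("an abrupt junction gap goes cold by about the full prescription", {
  ## two abutting uniform slabs; shift the inferior one away by 5 mm
  w <- water_phantom(c(50, 50, 150))
  mk <- function(lo, hi) {
    cc <- vol_axis_coords(w)
    prof <- as.numeric(cc$z >= lo & cc$z < hi)
    d <- dim(w$values)
    tbiplan:::as_dose(w, array(rep(prof, each = d[1] * d[2]), dim = d))
  }
  sup <- mk(0, 140); inf <- mk(-140, 0)
  nominal <- sum_dose(list(sup, inf))
  pert <- sum_dose(list(sup, shift_volume(inf, c(0, 0, -5))))
  je <- junction_error(nominal, pert, data.frame(x = 0, y = 0, z = 0), rx = 1)
  expect_lt(je$deviation_pct, -99)
})

test_that("scenario sampling is reproducible and calibrated", {
  set <- adult_segmentation(180)$set
  model <- make_shift_model(set)
  expect_setequal(unique(model$region),
                  intersect(c("head", "lung", "abdomen", "pelvis"),
                            model$region))
  expect_true("lung" %in% model$region)

  a <- sample_scenarios(5, model, seed = 42)
  b <- sample_scenarios(5, model, seed = 42)
  expect_identical(lapply(a, `[[`, "shifts"), lapply(b, `[[`, "shifts"))

  zero <- model; zero$sigma <- rep(0, length(model$sigma))
  z <- sample_scenarios(3, zero, seed = 1)
  expect_true(all(vapply(z, function(s) all(s$shifts == 0), logical(1))))

  bad <- model; bad$sigma[1] <- -1
  expect_error(sample_scenarios(3, bad, seed = 1), "sigma")

  ## Monte-Carlo check of the generator against its own calibration
  n <- 4000
  sc <- sample_scenarios(n, model, seed = 7)
  exceed <- vapply(seq_along(model$sigma), function(i)
    mean(vapply(sc, function(s) any(abs(s$shifts[i, ]) > 5), logical(1))),
    numeric(1))
  targets <- model$exceedance[model$region]
  expect_true(all(abs(exceed - targets) < 0.03))
})

test_that("the robustness report summarizes junction errors per scenario", {
  plan <- adult_plan(180)
  pd <- adult_surrogate_dose(180)
  model <- make_shift_model(plan$subtargets)
  sc <- sample_scenarios(4, model, seed = 3)
  rep <- run_robustness(plan, pd$per_iso, sc)
  expect_equal(dim(rep$junction_errors),
               c(4, nrow(plan$subtargets$junctions)))
  expect_true(all(rep$summary$max_abs >= rep$summary$mean_abs - 1e-12))
})
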