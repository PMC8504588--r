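test_that("beam inversion follows the mirror-and-rotate formulas", {
  b <- tbi_beam(c(10, 20, 300), gantry = 0, collimator = 90, mu = 50,
                segments = list(beam_segment(-50, 50, -50, 50)))
  inv <- invert_beam_to_sff(b, origin_point = c(0, 0, 0))
  expect_equal(inv$gantry, 0)
  expect_equal(inv$collimator, 270)
  expect_equal(inv$isocenter, c(-10, 20, -300))

  b90 <- tbi_beam(c(0, 0, 100), gantry = 90, collimator = 90)
  expect_equal(invert_beam_to_sff(b90, c(0, 0, 0))$gantry, 270)
})

test_that("beam inversion is an involution on random beams", {
  set.seed(99)
  op <- c(1, 0, 0)
  for (i in 1:500) {
    b <- tbi_beam(isocenter = runif(3, -400, 400),
                  gantry = runif(1, 0, 359.99),
                  collimator = runif(1, 0, 359.99),
                  energy = sample(c(6, 10), 1),
                  mu = runif(1, 1, 500),
                  segments = list(beam_segment(-60, 40, -50, 50,
                                               weight = runif(1, 0.1, 1))),
                  aux = list(z_inf = -100, z_sup = 120))
    back <- invert_beam_to_sff(invert_beam_to_sff(b, op), op)
    expect_equal(back$gantry, b$gantry, tolerance = 1e-9)
    expect_equal(back$collimator, b$collimator, tolerance = 1e-9)
    expect_equal(back$isocenter, b$isocenter, tolerance = 1e-9)
    expect_equal(back$aux$z_inf, b$aux$z_inf, tolerance = 1e-9)
    expect_equal(back$aux$z_sup, b$aux$z_sup, tolerance = 1e-9)
    expect_identical(back$mu, b$mu)
    expect_identical(back$segments, b$segments)
  }
})

test_that("an AP beam still enters anteriorly after the frame change", {
  ph <- adult_phantom(170, seed = 3)
  ct <- ph$ct
  constants <- physics_constants()
  iso <- c(0, 0, -600)
  b <- tbi_beam(iso, gantry = 0, collimator = 90, mu = 100,
                segments = list(beam_segment(-100, 100, -150, 150)))
  entry_side <- function(dose, ct_frame, iso_z) {
    cc <- vol_axis_coords(dose)
    i0 <- which.min(abs(cc$x - 60))
    k0 <- which.min(abs(cc$z - iso_z))
    prof <- dose$values[i0, , k0]
    body <- which(prof > 0)
    ## compare points ~2 cm inside each surface (clear of the build-up
    ## ramp): the anterior (larger y) entry side sees more dose
    prof[max(body) - 4] > prof[min(body) + 4]
  }
  d <- compute_beam_dose(b, ct, constants)
  expect_true(entry_side(d, ct, -600))

  op <- c(0, 0, 0)
  inv <- invert_beam_to_sff(b, op)
  ct_sff <- tbiplan:::rotate_about_vertical(ct, op)
  d_sff <- compute_beam_dose(inv, ct_sff, constants)
  expect_true(entry_side(d_sff, ct_sff, -iso[3]))
})

test_that("plan splitting partitions beams about the origin point", {
  plan <- adult_plan(180)
  set <- plan$subtargets
  sp <- split_plan(plan)
  expect_equal(length(sp$shf$beams) + length(sp$sff$beams),
               length(plan$beams))
  ## SHF holds the superior (VMAT) isocentres, SFF the inferior (AP/PA)
  shf_idx <- unique(vapply(sp$shf$beams, function(b) b$aux$subtarget_index,
                           numeric(1)))
  sff_idx <- unique(vapply(sp$sff$beams, function(b) b$aux$subtarget_index,
                           numeric(1)))
  expect_length(intersect(shf_idx, sff_idx), 0)
  st <- set$subtargets
  expect_true(all(st$kind[sff_idx] == "APPA"))
  expect_true(all(st$iso_z[shf_idx] > 0))
  expect_true(all(st$iso_z[sff_idx] < 0))

  ## MU is conserved across the split
  expect_equal(total_mu(sp$shf) + total_mu(sp$sff), total_mu(plan),
               tolerance = 1e-12)

  ## table shifts equal the planned isocentre spacings
  shf_z <- sort(unique(st$iso_z[shf_idx]), decreasing = TRUE)
  expect_equal(sp$shf$table_shifts, diff(shf_z))

  ## degenerate cases
  expect_warning(split_plan(plan, origin_point = c(0, 0, -2000)), "SFF")
  expect_error(split_plan(plan, origin_point = c(0, 0, st$iso_z[2])),
               "tie-break")
})

test_that("delivery plans reproduce the whole-body dose to tight tolerance", {
  ph <- adult_phantom(170, seed = 3)
  seg <- cached("seg_170", {
    ptv <- build_ptv(ph$structures)
    list(ptv = ptv, set = divide_ptv(ptv, ph$structures))
  })
  plan <- make_tbi_plan(ph$ct, ph$structures, seg$set, rx_fx = 1.65)
  pd <- compute_plan_dose(plan, ph$ct, appa = "engine")
  sp <- split_plan(plan)
  ver <- verify_equivalence(pd$composite, sp$shf, sp$sff, ph$ct,
                            tol = 1e-6, appa = "engine")
  expect_true(ver$pass)
  expect_lt(ver$max_abs_diff, 1e-6)

  ## fault injection: corrupting one gantry breaks the equivalence
  bad <- sp
  appa_beam <- which(vapply(bad$sff$beams, function(b)
    b$technique == "feathered_appa", logical(1)))[1]
  bad$sff$beams[[appa_beam]]$gantry <-
    (bad$sff$beams[[appa_beam]]$gantry + 5) %% 360
  ver_bad <- verify_equivalence(pd$composite, bad$shf, bad$sff, ph$ct,
                                tol = 1e-6, appa = "engine")
  expect_false(ver_bad$pass)

  ## an empty SFF plan compares over the SHF beams alone
  suppressWarnings(sp_all <- split_plan(plan, origin_point = c(0, 0, -2000)))
  pd_all <- compute_plan_dose(plan, ph$ct, appa = "engine")
  ver_all <- verify_equivalence(pd_all$composite, sp_all$shf, sp_all$sff,
                                ph$ct, tol = 1e-6, appa = "engine")
  expect_true(ver_all$pass)
})

test_that("plans survive a JSON round trip", {
  plan <- adult_plan(180)
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_length(back$beams, length(plan$beams))
  expect_equal(total_mu(back), total_mu(plan))
  expect_equal(vapply(back$beams, `[[`, numeric(1), "gantry"),
               vapply(plan$beams, `[[`, numeric(1), "gantry"))
  expect_equal(back$beams[[1]]$segments, plan$beams[[1]]$segments)

  sp <- split_plan(plan)
  write_plan(sp$sff, path)
  back_sff <- read_plan(path)
  expect_equal(back_sff$orientation, "SFF")
  expect_equal(back_sff$table_shifts, sp$sff$table_shifts)
})
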