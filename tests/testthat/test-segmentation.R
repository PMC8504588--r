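test_that("the machine-constraint derivation yields the field, optimization and sub-target limits", {
  lim <- compute_vmat_limit(14.5, 0.5, 5)
  expect_equal(lim$field_length, 29)
  expect_equal(lim$opt_limit, 28)
  expect_equal(lim$subtarget_limit, 23)

  expect_equal(unlist(compute_vmat_limit(10, 0, 0)),
               c(field_length = 20, opt_limit = 20, subtarget_limit = 20))
  expect_error(compute_vmat_limit(14.5, 0.5, 28), "not positive")
})

test_that("AP/PA length lookup agrees with exhaustive search", {
  params <- segmentation_params()
  oracle <- function(rem, lengths = c(25, 30, 35), margin = 5) {
    for (count in 1:20)
      for (L in lengths)
        if (count * L >= rem + margin - 1e-9)
          return(list(length = L, count = count))
  }
  expect_equal(appa_length_lookup(45, params), list(length = 25, count = 2L))
  expect_equal(appa_length_lookup(65, params), list(length = 35, count = 2L))
  expect_equal(appa_length_lookup(20, params), list(length = 25, count = 1L))
  for (rem in 1:200) {
    got <- appa_length_lookup(rem, params)
    want <- oracle(rem)
    expect_equal(got$length, want$length, info = sprintf("remaining %d", rem))
    expect_equal(got$count, as.integer(want$count))
  }
  expect_error(appa_length_lookup(0, params), "positive")
})

test_that("PTV construction contracts the skin and excludes lungs and kidneys", {
  ph <- adult_phantom(180)
  s <- ph$structures

  broken <- s
  broken$masks$kidneys <- NULL
  expect_error(build_ptv(broken), "kidneys")

  p0 <- build_ptv(s, segmentation_params(skin_contraction = 0))
  expect_identical(p0$values,
                   s$masks$body & !s$masks$lungs & !s$masks$kidneys)

  ptv <- build_ptv(s, segmentation_params(skin_contraction = 5))
  expect_false(any(ptv$values & s$masks$lungs))
  expect_false(any(ptv$values & s$masks$kidneys))
  ## independent distance check on a mid-trunk slab: every PTV voxel is at
  ## least the contraction away from the nearest non-body voxel in-plane
  cc <- vol_axis_coords(ptv)
  k <- which.min(abs(cc$z - 100))
  ptv_sl <- ptv$values[, , k]
  out_sl <- !s$masks$body[, , k]
  pw <- which(ptv_sl, arr.ind = TRUE)
  ow <- which(out_sl, arr.ind = TRUE)
  dmin <- min(sqrt(outer(pw[, 1] * ptv$spacing[1], ow[, 1] * ptv$spacing[1], "-")^2 +
                   outer(pw[, 2] * ptv$spacing[2], ow[, 2] * ptv$spacing[2], "-")^2))
  expect_gte(dmin, 5)
})

test_that("an adult phantom divides into 7-8 sub-targets with an inferior AP/PA run", {
  set <- adult_segmentation(180)$set
  st <- set$subtargets
  expect_true(nrow(st) %in% 7:8)
  n_appa <- sum(st$kind == "APPA")
  expect_true(n_appa %in% 2:3)
  ## AP/PA sub-targets form the most inferior run
  expect_true(all(st$kind[st$index > nrow(st) - n_appa] == "APPA"))
  expect_null(check_partition(set))
})

test_that("a trunk-only target divides into VMAT sub-targets alone", {
  ## synthetic trunk: a box PTV wholly above the top of the legs
  ext <- list(x = c(-150, 150), y = c(-100, 100), z = c(-10, 600))
  g <- make_grid(ext, c(10, 10, 10), fill = FALSE)
  box <- g
  box$values <- array(TRUE, dim = dim(g$values))
  structures <- tbi_structures(
    masks = list(body = box$values, lungs = array(FALSE, dim(box$values)),
                 kidneys = array(FALSE, dim(box$values))),
    landmarks = list(head_top = 600, neck_bottom = 420, legs_top = -100,
                     feet_bottom = -150),
    geometry = g)
  set <- divide_ptv(box, structures)
  expect_true(all(set$subtargets$kind == "VMAT"))
  expect_null(check_partition(set))
})

test_that("partition invariants hold across random phantoms", {
  for (seed in 1:10) {
    spec <- random_phantom_spec(seed)
    ph <- generate_phantom(spec)
    ptv <- build_ptv(ph$structures)
    set <- divide_ptv(ptv, ph$structures)
    expect_null(check_partition(set), info = sprintf("seed %d", seed))
  }
})

test_that("an overlong head sub-target is rejected with advice", {
  spec <- phantom_spec(height = 180, neck_bottom_z = 0.48 * 180 - 27,
                      voxel_spacing = c(10, 10, 10))
  ph <- generate_phantom(spec)
  ptv <- build_ptv(ph$structures)
  expect_error(divide_ptv(ptv, ph$structures), "review")
})

test_that("pediatric adjustment places a junction in the lung-kidney gap", {
  ph <- generate_phantom(phantom_spec(height = 132,
                                      voxel_spacing = c(5, 5, 5), seed = 11))
  expect_true(ph$structures$spec$is_pediatric)
  ptv <- build_ptv(ph$structures)
  set <- divide_ptv(ptv, ph$structures)
  adj <- pediatric_adjust(set, ph$structures)
  expect_null(check_partition(adj))

  lung_bottom <- mask_z_extent(ph$structures$masks$lungs, ph$ct)[1]
  kid_top <- mask_z_extent(ph$structures$masks$kidneys, ph$ct)[2]
  ofz <- adj$params$ofz_halfwidth * 10
  contained <- vapply(adj$junctions$z, function(b)
    b - ofz >= kid_top - 1e-6 && b + ofz <= lung_bottom + 1e-6, logical(1))
  expect_true(any(contained))

  ## VMAT lengths are only ever reduced (the AP/PA remainder re-runs its
  ## own lookup)
  vmat_new <- adj$subtargets[adj$subtargets$kind == "VMAT", ]
  expect_true(all(vmat_new$z_sup - vmat_new$z_inf <=
                    adj$params$vmat_max_length * 10 + 1e-6))

  ## a gap narrower than the junction region is an error stating the gap
  ph2 <- generate_phantom(phantom_spec(height = 132, lung_center_z = 0.20 * 132,
                                       kidney_center_z = 0.095 * 132,
                                       voxel_spacing = c(5, 5, 5)))
  set2 <- divide_ptv(build_ptv(ph2$structures), ph2$structures)
  expect_error(pediatric_adjust(set2, ph2$structures), "gap")

  ## adult sets pass through unchanged
  adult <- adult_segmentation(180)$set
  expect_identical(pediatric_adjust(adult, adult_phantom(180)$structures),
                   adult)
})

test_that("large-patient adjustment shortens VMAT sub-targets and re-tiles", {
  set <- adult_segmentation(180)$set
  expect_identical(large_patient_adjust(set, 38), set)

  adj1 <- large_patient_adjust(set, 42)
  v1 <- adj1$subtargets[adj1$subtargets$kind == "VMAT" & adj1$subtargets$index > 1, ]
  expect_true(all(abs((v1$z_sup - v1$z_inf) - 220) < 1e-6))
  expect_null(check_partition(adj1))

  adj2 <- large_patient_adjust(set, 47)
  v2 <- adj2$subtargets[adj2$subtargets$kind == "VMAT" & adj2$subtargets$index > 1, ]
  expect_true(all(abs((v2$z_sup - v2$z_inf) - 210) < 1e-6))
  expect_null(check_partition(adj2))
})

test_that("sub-target sets survive a JSON round trip", {
  set <- adult_segmentation(180)$set
  path <- withr::local_tempfile(fileext = ".json")
  write_subtargets(set, path)
  back <- read_subtargets(path)
  expect_equal(back$subtargets, set$subtargets)
  expect_equal(back$junctions, set$junctions)
  expect_equal(back$origin_point, set$origin_point)
  expect_null(check_partition(back))
})
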