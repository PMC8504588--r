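## shared fixtures, built once per test run; coarse grids keep the suite fast
.fixtures <- new.env()

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

adult_phantom <- function(height = 180, spacing = c(5, 5, 5), seed = 1) {
  cached(sprintf("ph_%s_%s_%s", height, paste(spacing, collapse = "x"), seed),
         generate_phantom(phantom_spec(height = height,
                                       voxel_spacing = spacing, seed = seed)))
}

adult_segmentation <- function(height = 180) {
  cached(sprintf("seg_%s", height), {
    ph <- adult_phantom(height)
    ptv <- build_ptv(ph$structures)
    list(ptv = ptv, set = divide_ptv(ptv, ph$structures))
  })
}

adult_plan <- function(height = 180) {
  cached(sprintf("plan_%s", height), {
    ph <- adult_phantom(height)
    seg <- adult_segmentation(height)
    make_tbi_plan(ph$ct, ph$structures, seg$set, rx_fx = 1.65)
  })
}

adult_surrogate_dose <- function(height = 180) {
  cached(sprintf("sdose_%s", height), {
    ph <- adult_phantom(height)
    compute_plan_dose(adult_plan(height), ph$ct, appa = "surrogate")
  })
}

## homogeneous water block (0 HU) centred on the origin
water_phantom <- function(half_mm = c(150, 150, 300), spacing = 5) {
  cached(sprintf("water_%s_%s", paste(half_mm, collapse = "x"), spacing), {
    ext <- list(x = c(-half_mm[1], half_mm[1]),
                y = c(-half_mm[2], half_mm[2]),
                z = c(-half_mm[3], half_mm[3]))
    g <- make_grid(ext, spacing, fill = 0)
    g
  })
}

## nearest-neighbour resampling of a mask volume onto a dose grid
mask_on_grid <- function(maskvol, grid) {
  d <- dim(grid$values)
  cc <- vol_axis_coords(grid)
  px <- rep(cc$x, times = d[2] * d[3])
  py <- rep(rep(cc$y, each = d[1]), times = d[3])
  pz <- rep(cc$z, each = d[1] * d[2])
  vals <- tbiplan:::vol_nearest(as_head_first(maskvol), px, py, pz, fill = 0)
  array(vals > 0.5, dim = d)
}

## z-extent (mm, outer faces) of a mask inside a volume
mask_z_extent <- function(mask, vol) {
  d <- dim(mask)
  cc <- vol_axis_coords(vol)
  sl <- colSums(matrix(mask, d[1] * d[2], d[3])) > 0
  range(cc$z[sl]) + c(-1, 1) * vol$spacing[3] / 2
}

## partition invariants of a sub-target set; returns NULL or a message
check_partition <- function(set, tol = 1e-6) {
  st <- set$subtargets
  n <- nrow(st)
  if (any(diff(st$z_sup) >= 0)) return("sub-targets not ordered head to feet")
  if (abs(st$z_sup[1] - set$meta$ptv_top) > tol)
    return("first sub-target does not reach the PTV top")
  for (i in seq_len(n - 1)) {
    if (abs(st$z_inf[i] - st$z_sup[i + 1]) > tol)
      return(sprintf("gap or overlap at boundary %d", i))
    overlap <- st$opt_sup[i + 1] - st$opt_inf[i]
    if (abs(overlap - 2 * set$params$ofz_halfwidth * 10) > tol)
      return(sprintf("opt-interval overlap at boundary %d is %.2f mm", i, overlap))
  }
  appa <- st[st$kind == "APPA", ]
  if (nrow(appa)) {
    lens <- appa$z_sup - appa$z_inf
    if (diff(range(lens)) > tol) return("AP/PA sub-targets have unequal lengths")
    if (any(st$kind[seq_len(n - nrow(appa))] != "VMAT"))
      return("AP/PA sub-targets are not the most inferior run")
    margin <- set$meta$ptv_bottom - st$z_inf[n]
    if (margin < set$params$feet_margin_min * 10 - tol)
      return(sprintf("feet margin %.1f mm below minimum", margin))
  } else {
    if (st$z_inf[n] - set$meta$ptv_bottom > tol)
      return("VMAT-only set does not reach the PTV bottom")
  }
  if (length(unique(st$iso_x)) != 1 || length(unique(st$iso_y)) != 1)
    return("isocentres are not collinear")
  if (nrow(set$junctions) != n - 1) return("wrong junction count")
  if (any(set$junctions$x != st$iso_x[1]) || any(set$junctions$y != st$iso_y[1]))
    return("junction points are not collinear with isocentres")
  NULL
}

## random valid phantom spec for property-style tests
random_phantom_spec <- function(seed, spacing = c(10, 10, 10)) {
  set.seed(seed)
  h <- runif(1, 139, 193)
  phantom_spec(height = h,
               shoulder_width = runif(1, 0.20, 0.24) * h,
               umbilicus_separation = runif(1, 0.10, 0.14) * h,
               leg_width = min(runif(1, 0.14, 0.18) * h, 34),
               lung_center_z = runif(1, 0.20, 0.24) * h,
               lung_length = runif(1, 0.11, 0.14) * h,
               kidney_center_z = runif(1, 0.06, 0.09) * h,
               kidney_length = 0.07 * h,
               voxel_spacing = spacing, seed = seed)
}

## minimal two-sub-target AP/PA set on a water phantom, for junction
## dosimetry studies (lengths in mm, boundary at z = 0)
two_appa_set <- function(len = 300) {
  params <- segmentation_params()
  st <- data.frame(index = 1:2, kind = "APPA",
                   z_inf = c(0, -len), z_sup = c(len, 0),
                   opt_inf = c(-25, -len), opt_sup = c(len, 25),
                   iso_x = 0, iso_y = 0, iso_z = c(len / 2, -len / 2))
  structure(list(subtargets = st,
                 junctions = data.frame(x = 0, y = 0, z = 0),
                 origin_point = c(0, 0, 0), params = params,
                 meta = list(ptv_top = len, ptv_bottom = -len,
                             landmarks = list(), iso_xy = c(0, 0),
                             feet_margin = NA)),
            class = "tbi_subtargets")
}
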