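## 2-D in-plane erosion of a logical (x, z) mask by radius mm
erode_mask2d <- function(m, spacing_xz, radius_mm) {
  if (radius_mm <= 0) return(m)
  d <- dim(m)
  nmax <- floor(radius_mm / spacing_xz)
  out <- m
  for (di in -nmax[1]:nmax[1])
    for (dk in -nmax[2]:nmax[2]) {
      if (di == 0 && dk == 0) next
      if (sum((c(di, dk) * spacing_xz)^2) > radius_mm^2 + 1e-9) next
      sh <- array(FALSE, dim = d)
      si <- seq_len(d[1]) - di; sk <- seq_len(d[2]) - dk
      ki <- si >= 1 & si <= d[1]; kk <- sk >= 1 & sk <= d[2]
      sh[which(ki), which(kk)] <- m[si[ki], sk[kk]]
      out <- out & sh
    }
  out
}

#' Recreate the classic whole-body AP/PA comparator plan
#'
#' Single-isocentre opposed 10 MV beams at a 400 cm source-axis distance
#' with a 40 x 40 cm field collimated at 45 degrees; a 1 cm Lucite spoiler
#' modelled as added water-equivalent build-up; a cerrobend lung block
#' (lung outline contracted 5 mm in the beam's eye view, thickness solved
#' so the blocked mid-lung dose equals 10 Gy for adults or 8 Gy for
#' pediatric patients) and a 4 cm thick kidney block.  Monitor units are
#' set from the maximum body thickness so the open beams deliver the
#' prescription at mid-separation.
#'
#' @param ct whole-body CT.
#' @param structures matching [tbi_structures] with lungs and kidneys.
#' @param rx total prescription over the course, Gy (12 or 13.2 by
#'   protocol).
#' @param constants a [physics_constants].
#' @param pediatric use the 8 Gy mid-lung target instead of 10 Gy.
#' @param grid dose-grid template; default 5 mm isotropic.
#' @return list with `plan` (the two blocked beams plus block metadata),
#'   `dose` (blocked course dose, `tbi_dose`), `open_dose`, and `details`
#'   (MU, block thickness, reference points).
#' @export
recreate_classic_appa <- function(ct, structures, rx = 13.2,
                                  constants = physics_constants(),
                                  pediatric = NULL, grid = NULL) {
  ct <- as_head_first(ct)
  if (is.null(grid)) grid <- default_dose_grid(ct)
  for (nm in c("body", "lungs", "kidneys"))
    if (is.null(structures$masks[[nm]]))
      stop(sprintf("structure set is missing required mask '%s'", nm))
  if (is.null(pediatric)) pediatric <- isTRUE(structures$spec$is_pediatric)

  body <- structures$masks$body
  cc_ct <- vol_axis_coords(ct)
  ## maximum body thickness along the beam axis (y) and its mid-separation
  thick <- apply(body, c(1, 3), sum) * ct$spacing[2]
  idx <- which(thick == max(thick), arr.ind = TRUE)[1, ]
  x_star <- cc_ct$x[idx[1]]; z_star <- cc_ct$z[idx[2]]
  y_mid <- mean(cc_ct$y[body[idx[1], , idx[2]]])

  iso <- c(x_star, y_mid, z_star)
  spoiler <- constants$spoiler_thickness_cm * constants$lucite_density
  ## the 40 x 40 cm collimator setting is defined at the standard 100 cm
  ## distance; at the 400 cm source-axis distance it projects to 160 cm at
  ## the isocentre plane, and the 45 degree collimator turns the square
  ## into a diamond whose long diagonal covers the patient longitudinally
  jaw_half <- 200 * 4000 / 1000
  mk <- function(gantry)
    tbi_beam(iso, gantry = gantry, collimator = 45, energy = 10, sad = 4000,
             mu = 1, mu_rate = 200,
             segments = list(beam_segment(-jaw_half, jaw_half,
                                          -jaw_half, jaw_half)),
             technique = "classic_appa",
             aux = list(spoiler_wed_cm = spoiler))
  ap <- mk(0); pa <- mk(180)
  d_ap <- compute_beam_dose(ap, ct, constants, grid)
  d_pa <- compute_beam_dose(pa, ct, constants, grid)
  unit <- sum_dose(list(d_ap, d_pa))
  per_mu_mid <- vol_interp(unit, x_star, y_mid, z_star)
  if (!is.finite(per_mu_mid) || per_mu_mid <= 0)
    stop("mid-separation reference point receives no dose")
  mu_each <- rx / per_mu_mid
  open_dose <- as_dose(grid, unit$values * mu_each)

  ## lung block: BEV lung outline contracted 5 mm, thickness solved for the
  ## mid-lung target dose
  lung_target <- if (pediatric) 8 else 10
  lungs <- structures$masks$lungs
  lung_shadow_ct <- apply(lungs, c(1, 3), any)
  lung_shadow_ct <- erode_mask2d(lung_shadow_ct, ct$spacing[c(1, 3)], 5)
  if (!any(lung_shadow_ct)) stop("lung block shape is empty after contraction")
  lung_shadow <- bev_shadow_from_proj(lung_shadow_ct, ct, grid)
  ## mid-lung reference: centroid of one lung (the paired-lung centroid
  ## would fall in the mediastinum, outside the block)
  cc_mid <- vol_axis_coords(ct)
  one_lung <- lungs
  one_lung[cc_mid$x < 0, , ] <- FALSE
  if (!any(one_lung)) one_lung <- lungs
  mid_lung <- mask_centroid(one_lung, ct)
  d_open_midlung <- vol_interp(open_dose, mid_lung[1], mid_lung[2], mid_lung[3])
  t_lung <- max(log(d_open_midlung / lung_target) / constants$mu_cerrobend, 0)
  trans_lung <- exp(-constants$mu_cerrobend * t_lung)

  kidneys <- structures$masks$kidneys
  kid_shadow_ct <- apply(kidneys, c(1, 3), any)
  if (!any(kid_shadow_ct)) stop("kidney block shape is empty")
  kid_shadow <- bev_shadow_from_proj(kid_shadow_ct, ct, grid)
  trans_kid <- exp(-constants$mu_cerrobend * 4)

  blocks <- list(list(name = "lung", mask = lung_shadow,
                      thickness_cm = t_lung, transmission = trans_lung),
                 list(name = "kidney", mask = kid_shadow, thickness_cm = 4,
                      transmission = trans_kid))
  blocked <- open_dose
  d <- dim(blocked$values)
  ii <- rep(seq_len(d[1]), times = d[2] * d[3])
  kk <- rep(seq_len(d[3]), each = d[1] * d[2])
  for (blk in blocks) {
    shadow <- blk$mask[cbind(ii, kk)]
    blocked$values[shadow] <- blocked$values[shadow] * blk$transmission
  }

  ap$mu <- pa$mu <- mu_each
  ap$blocks <- pa$blocks <- blocks
  list(plan = list(beams = list(ap = ap, pa = pa), blocks = blocks,
                   rx = rx, pediatric = pediatric),
       dose = blocked, open_dose = open_dose,
       details = list(mu_per_beam = mu_each,
                      max_thickness_cm = max(thick) / 10,
                      mid_separation_point = iso,
                      mid_lung_point = mid_lung,
                      open_mid_lung_dose = d_open_midlung,
                      lung_block_thickness_cm = t_lung,
                      lung_target = lung_target))
}

## resample a precomputed CT-grid (x, z) projection onto the dose grid
bev_shadow_from_proj <- function(proj, ct, grid) {
  d <- dim(proj)
  cc_ct <- vol_axis_coords(as_head_first(ct))
  cc <- vol_axis_coords(grid)
  ii <- pmin(pmax(round((cc$x - cc_ct$x[1]) / ct$spacing[1]) + 1, 1), d[1])
  kk <- pmin(pmax(round((cc$z - cc_ct$z[1]) / ct$spacing[3]) + 1, 1), d[2])
  proj[ii, kk, drop = FALSE]
}

## centroid (mm) of a CT-grid mask
mask_centroid <- function(mask, ct) {
  cc <- vol_axis_coords(as_head_first(ct))
  d <- dim(mask)
  w <- which(mask)
  i <- (w - 1) %% d[1] + 1
  j <- ((w - 1) %/% d[1]) %% d[2] + 1
  k <- (w - 1) %/% (d[1] * d[2]) + 1
  c(mean(cc$x[i]), mean(cc$y[j]), mean(cc$z[k]))
}
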