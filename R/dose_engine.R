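#' Rectangular beam segment
#'
#' Aperture edges are in the isocentre-plane collimator frame, mm:
#' `x1 <= xb <= x2`, `y1 <= yb <= y2`.  With the collimator at 90 degrees
#' the collimator-frame X axis maps to the patient longitudinal axis
#' (superior positive), which is how the AP/PA feathering and step-wedge
#' segments express their stepped longitudinal edges.
#'
#' @param x1,x2,y1,y2 aperture edges, mm.
#' @param weight nonnegative relative weight.
#' @return An object of class `beam_segment`.
#' @export
beam_segment <- function(x1, x2, y1, y2, weight = 1) {
  if (!(x2 > x1 && y2 > y1)) stop("degenerate segment aperture")
  if (weight < 0) stop("segment weight must be nonnegative")
  structure(list(x1 = x1, x2 = x2, y1 = y1, y2 = y2, weight = weight),
            class = "beam_segment")
}

#' Deliverable beam geometry
#'
#' @param isocenter mm triple in the plan frame.
#' @param gantry,collimator angles, degrees in `[0, 360)`; gantry 0 is an
#'   anterior (AP) beam for a supine patient.
#' @param energy nominal energy, 6 or 10 (MV).
#' @param sad source-axis distance, mm (default 1000; the classic
#'   whole-body comparator uses 4000).
#' @param mu monitor units for this beam.
#' @param mu_rate delivery rate, MU/min (200 at the lung isocentre, 600
#'   elsewhere by convention).
#' @param segments list of [beam_segment]s; weights are normalized to sum
#'   to one.
#' @param technique one of `"feathered_appa"`, `"step_wedge"`,
#'   `"vmat_arc_surrogate"`, `"classic_appa"`.
#' @param blocks optional list of shadow blocks (see
#'   [recreate_classic_appa()]).
#' @param aux optional list of technique-specific fields (e.g. the
#'   optimization interval of a VMAT arc surrogate, mm).
#' @return An object of class `tbi_beam`.
#' @export
tbi_beam <- function(isocenter, gantry, collimator, energy = 6, sad = 1000,
                     mu = 0, mu_rate = 600, segments = list(),
                     technique = "feathered_appa", blocks = NULL,
                     aux = list()) {
  if (gantry < 0 || gantry >= 360 || collimator < 0 || collimator >= 360)
    stop("gantry and collimator must be in [0, 360)")
  if (!energy %in% c(6, 10)) stop("energy must be 6 or 10 MV")
  techniques <- c("feathered_appa", "step_wedge", "vmat_arc_surrogate",
                  "classic_appa")
  technique <- match.arg(technique, techniques)
  if (length(segments)) {
    tot <- sum(vapply(segments, `[[`, numeric(1), "weight"))
    if (tot <= 0) stop("segment weights must not all be zero")
    segments <- lapply(segments, function(s) { s$weight <- s$weight / tot; s })
  }
  structure(list(isocenter = as.numeric(isocenter), gantry = gantry,
                 collimator = collimator, energy = energy, sad = sad,
                 mu = mu, mu_rate = mu_rate, segments = segments,
                 technique = technique, blocks = blocks, aux = aux),
            class = "tbi_beam")
}

#' @export
print.tbi_beam <- function(x, ...) {
  cat(sprintf("<tbi_beam> %s g=%g c=%g %gMV SAD=%gmm MU=%.1f@%g/min, %d segment(s)\n",
              x$technique, x$gantry, x$collimator, x$energy, x$sad, x$mu,
              x$mu_rate, length(x$segments)))
  invisible(x)
}

## collimator-frame coordinates (xb, yb, mm at the isocentre plane), the
## distance dw along the beam axis from the source, and the true
## source-voxel distance, for point vectors in the plan frame
beam_coords <- function(beam, px, py, pz) {
  g <- beam$gantry * pi / 180
  cang <- beam$collimator * pi / 180
  dx <- px - beam$isocenter[1]
  dy <- py - beam$isocenter[2]
  dz <- pz - beam$isocenter[3]
  dw <- beam$sad - dx * sin(g) - dy * cos(g)
  pu <- (dx * cos(g) - dy * sin(g)) * beam$sad / dw
  pv <- dz * beam$sad / dw
  xb <- cos(cang) * pu + sin(cang) * pv
  yb <- -sin(cang) * pu + cos(cang) * pv
  src <- beam$isocenter + beam$sad * c(sin(g), cos(g), 0)
  dist <- sqrt((px - src[1])^2 + (py - src[2])^2 + (pz - src[3])^2)
  list(xb = xb, yb = yb, dw = dw, dist = dist)
}

## per-segment fluence (normalized weights times aperture indicators)
segment_fluence <- function(beam, xb, yb) {
  flu <- numeric(length(xb))
  for (s in beam$segments)
    flu <- flu + s$weight * (xb >= s$x1 & xb <= s$x2 &
                             yb >= s$y1 & yb <= s$y2)
  flu
}

#' Fluence profile of a beam along the longitudinal axis
#'
#' Evaluates the summed segment fluence at the isocentre plane along the
#' line through the isocentre parallel to the patient z axis (the axis the
#' collimator-90 segments feather).
#'
#' @param beam a [tbi_beam] (or list of beams, summed).
#' @param z_mm offsets from the beam isocentre along z, mm.
#' @return numeric fluence values (weights sum to 1 inside the largest
#'   aperture).
#' @export
fluence_profile <- function(beam, z_mm) {
  beams <- if (inherits(beam, "tbi_beam")) list(beam) else beam
  prof <- numeric(length(z_mm))
  for (b in beams) {
    bc <- beam_coords(b, b$isocenter[1], b$isocenter[2], b$isocenter[3] + z_mm)
    prof <- prof + segment_fluence(b, bc$xb, bc$yb)
  }
  prof / length(beams)
}

## water-equivalent depth (cm) along the beam direction for every voxel of
## the density array `dens` on grid `grid`; parallel-ray model along the
## central-axis direction (documented approximation)
compute_wed <- function(beam, dens, grid) {
  d <- dim(dens)
  sp <- grid$spacing
  g <- beam$gantry %% 360
  wed <- array(0, dim = d)
  if (isTRUE(all.equal(g, 0)) || isTRUE(all.equal(g, 180))) {
    dy <- sp[2] / 10
    acc <- matrix(0, d[1], d[3])
    js <- if (abs(g) < 90) d[2]:1 else 1:d[2]
    for (j in js) {
      sl <- dens[, j, ] * dy
      wed[, j, ] <- acc + 0.5 * sl
      acc <- acc + sl
    }
  } else if (isTRUE(all.equal(g, 90)) || isTRUE(all.equal(g, 270))) {
    dxl <- sp[1] / 10
    acc <- matrix(0, d[2], d[3])
    is <- if (g < 180) d[1]:1 else 1:d[1]
    for (i in is) {
      sl <- dens[i, , ] * dxl
      wed[i, , ] <- acc + 0.5 * sl
      acc <- acc + sl
    }
  } else {
    ## oblique: fixed-step sampling toward the source with nearest lookup
    gr <- g * pi / 180
    dir <- c(sin(gr), cos(gr), 0)          # toward the source
    cc <- vol_axis_coords(grid)
    px <- rep(cc$x, times = d[2] * d[3])
    py <- rep(rep(cc$y, each = d[1]), times = d[3])
    pz <- rep(cc$z, each = d[1] * d[2])
    ds <- 2                                 # mm
    ext <- vol_extent(grid)
    maxpath <- sqrt(diff(ext$x)^2 + diff(ext$y)^2)
    nstep <- ceiling(maxpath / ds)
    dvol <- grid; dvol$values <- dens
    acc <- numeric(length(px))
    for (k in seq_len(nstep)) {
      s <- (k - 0.5) * ds
      acc <- acc + vol_nearest(dvol, px + dir[1] * s, py + dir[2] * s,
                               pz + dir[3] * s, fill = 0)
    }
    wed <- array(acc * ds / 10, dim = d)
    ## half-voxel centre correction to match the axis-aligned paths
    wed <- wed - dens * min(sp[1:2]) / 10 / 2
    wed[wed < 0] <- 0
  }
  wed
}

#' Compute the dose of a single beam with the primary-only engine
#'
#' For each voxel inside the projected aperture the dose is
#' `MU x segment weight x inverse-square x build-up x exp(-mu_eff x WED)`,
#' with lung density scaling the water-equivalent depth (WED) and optional
#' shadow blocks multiplying in their transmission.  Voxels outside all
#' apertures receive exactly zero (no penumbra model).
#'
#' @param beam a [tbi_beam].
#' @param ct a [tbi_volume] of HU values.
#' @param constants a [physics_constants].
#' @param grid optional dose-grid template ([tbi_volume]); default is a
#'   5 mm isotropic grid covering the CT.
#' @return A dose grid: a [tbi_volume] with class `tbi_dose`, values in Gy.
#' @export
compute_beam_dose <- function(beam, ct, constants = physics_constants(),
                              grid = NULL) {
  ct <- as_head_first(ct)
  if (is.null(grid)) grid <- default_dose_grid(ct)

  ## beams only irradiate a longitudinal window around their aperture;
  ## restrict the computation to those slices and embed the result
  cc_full <- vol_axis_coords(grid)
  xb_range <- range(unlist(lapply(beam$segments, function(s) c(s$x1, s$x2))))
  yb_range <- range(unlist(lapply(beam$segments, function(s) c(s$y1, s$y2))))
  cang <- beam$collimator * pi / 180
  ## |pv| bound from the collimator-frame box, inflated for divergence
  pv_max <- (max(abs(xb_range)) * abs(sin(cang)) +
             max(abs(yb_range)) * abs(cos(cang))) * 1.6 + 30
  ks <- which(abs(cc_full$z - beam$isocenter[3]) <= pv_max)
  if (!length(ks)) {
    warning("beam misses the dose grid; returning a zero dose grid")
    return(as_dose(grid, array(0, dim = dim(grid$values))))
  }
  if (length(ks) < dim(grid$values)[3]) {
    sub <- tbi_volume(grid$values[, , ks, drop = FALSE],
                      c(grid$origin[1:2], cc_full$z[min(ks)]),
                      grid$spacing, grid$orientation)
    sub_dose <- compute_beam_dose(beam, ct, constants, sub)
    full <- array(0, dim = dim(grid$values))
    full[, , ks] <- sub_dose$values
    return(as_dose(grid, full))
  }

  d <- dim(grid$values)
  cc <- vol_axis_coords(grid)
  px <- rep(cc$x, times = d[2] * d[3])
  py <- rep(rep(cc$y, each = d[1]), times = d[3])
  pz <- rep(cc$z, each = d[1] * d[2])

  bc <- beam_coords(beam, px, py, pz)
  flu <- segment_fluence(beam, bc$xb, bc$yb)
  if (!any(flu > 0 & bc$dw > 0)) {
    warning("beam misses the dose grid; returning a zero dose grid")
    return(as_dose(grid, array(0, dim = d)))
  }

  dens <- array(hu_to_density(vol_nearest(ct, px, py, pz, fill = -1000),
                              constants), dim = d)
  wed <- compute_wed(beam, dens, grid)
  if (!is.null(beam$aux$spoiler_wed_cm)) wed <- wed + beam$aux$spoiler_wed_cm

  en <- as.character(beam$energy)
  mu_eff <- constants$mu_eff[[en]]
  dmax <- constants$dmax_cm[[en]]
  wedv <- as.vector(wed)
  depth_factor <- pmin(wedv / dmax, 1) * exp(-mu_eff * pmax(wedv - dmax, 0))
  invsq <- (beam$sad / bc$dist)^2

  dose <- constants$dose_per_mu * beam$mu * flu * invsq * depth_factor
  dose[bc$dw <= 0] <- 0

  if (length(beam$blocks)) {
    ii <- rep(seq_len(d[1]), times = d[2] * d[3])
    kk <- rep(seq_len(d[3]), each = d[1] * d[2])
    for (blk in beam$blocks) {
      shadow <- blk$mask[cbind(ii, kk)]
      dose[shadow] <- dose[shadow] * blk$transmission
    }
  }
  as_dose(grid, array(dose, dim = d))
}

## default 5 mm isotropic dose grid covering a CT volume
default_dose_grid <- function(ct, spacing = 5) {
  make_grid(vol_extent(as_head_first(ct)), spacing)
}

as_dose <- function(grid, values) {
  out <- grid
  out$values <- values
  class(out) <- c("tbi_dose", class(grid)[!class(grid) %in% "tbi_dose"])
  out
}

#' Sum dose grids
#'
#' @param doses list of aligned `tbi_dose` grids.
#' @return their voxelwise sum.
#' @export
sum_dose <- function(doses) {
  stopifnot(length(doses) >= 1)
  out <- doses[[1]]
  if (length(doses) > 1)
    for (i in 2:length(doses)) {
      if (!same_grid(out, doses[[i]])) stop("dose grids are not aligned")
      out$values <- out$values + doses[[i]]$values
    }
  out
}
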