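#' Rigid transform between scan frames
#'
#' A fine correction (translation plus optional small rotations) mapping
#' the feet-first scan into the head-first frame.  Rotations are
#' small-angle corrections about the patient axes through the pelvis
#' origin; magnitudes above 10 degrees are rejected because registration
#' here is a fine correction, not a pose solve.
#'
#' @param translation mm triple.
#' @param rotation degrees triple about (x, y, z); default zero.
#' @param metric final similarity metric value, if any.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation, rotation = c(0, 0, 0),
                            metric = NA_real_) {
  if (any(abs(rotation) > 10))
    stop("rotation magnitudes above 10 degrees are not supported")
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation), metric = metric),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.2f, %.2f, %.2f) mm, r = (%.2f, %.2f, %.2f) deg\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3]))
  invisible(x)
}

## rotation matrix for small angles (degrees) about patient x, y, z
rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(r[1]), -sin(r[1]), 0, sin(r[1]), cos(r[1])),
               3, byrow = TRUE)
  ry <- matrix(c(cos(r[2]), 0, sin(r[2]), 0, 1, 0, -sin(r[2]), 0, cos(r[2])),
               3, byrow = TRUE)
  rz <- matrix(c(cos(r[3]), -sin(r[3]), 0, sin(r[3]), cos(r[3]), 0, 0, 0, 1),
               3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Register the feet-first scan to the head-first scan in the pelvis
#'
#' Mono-modal intensity registration restricted to the pelvis overlap:
#' minimizes the mean squared intensity difference between the head-first
#' scan and the rigidly transformed feet-first scan over the region, with
#' a coarse translation grid search followed by Nelder-Mead refinement.
#' Translation-only by default; small rotations can be enabled.
#'
#' @param shf head-first scan ([tbi_volume]).
#' @param sff feet-first scan (stored feet-first; reoriented internally).
#' @param region z-interval (mm pair) of the registration region in the
#'   head-first frame; default is the scans' z-overlap shrunk by 15 mm on
#'   each side.
#' @param allow_rotation also optimize small rotations about the patient
#'   axes.
#' @param max_points cap on the number of voxels used in the metric.
#' @return A [rigid_transform] mapping the feet-first scan into the
#'   head-first frame.
#' @export
register_pelvis <- function(shf, sff, region = NULL, allow_rotation = FALSE,
                            max_points = 150000) {
  shf <- as_head_first(shf)
  sff_p <- as_head_first(sff)
  ext_s <- vol_extent(shf); ext_f <- vol_extent(sff_p)
  if (is.null(region)) {
    region <- c(max(ext_s$z[1], ext_f$z[1]) + 15,
                min(ext_s$z[2], ext_f$z[2]) - 15)
  }
  if (region[1] >= region[2] ||
      region[2] <= ext_s$z[1] || region[1] >= ext_s$z[2] ||
      region[2] <= ext_f$z[1] || region[1] >= ext_f$z[2])
    stop("registration region has no overlap with both scans")

  cc <- vol_axis_coords(shf)
  ks <- which(cc$z >= region[1] & cc$z <= region[2])
  d <- dim(shf$values)
  px <- rep(cc$x, times = d[2] * length(ks))
  py <- rep(rep(cc$y, each = d[1]), times = length(ks))
  pz <- rep(cc$z[ks], each = d[1] * d[2])
  ref <- as.vector(shf$values[, , ks])
  ## prefer interior tissue voxels well away from the body surface: the
  ## smooth tissue intensities localize the optimum without the sampling-
  ## phase bias a reconstructed hard edge carries; fall back to all voxels
  ## when the region holds little tissue
  tissue <- shf$values[, , ks, drop = FALSE] > -500
  interior <- erode_mask(tissue, shf$spacing, 12)
  if (mean(interior) > 0.1) {
    keep <- as.vector(interior)
    px <- px[keep]; py <- py[keep]; pz <- pz[keep]; ref <- ref[keep]
  }
  if (length(ref) > max_points) {
    stride <- ceiling(length(ref) / max_points)
    keep <- seq(1, length(ref), by = stride)
    px <- px[keep]; py <- py[keep]; pz <- pz[keep]; ref <- ref[keep]
  }

  ## symmetric formulation: both scans are interpolated by half the
  ## candidate shift, so the trilinear smoothing they experience is
  ## identical for every candidate and the optimum is not biased toward
  ## grid-aligned shifts
  metric <- function(par) {
    t <- par[1:3]
    fixed <- vol_interp(shf, px + t[1] / 2, py + t[2] / 2, pz + t[3] / 2,
                        fill = -1000)
    if (allow_rotation && length(par) == 6) {
      R <- rotation_matrix(par[4:6])
      q <- t(solve(R) %*% rbind(px - t[1] / 2, py - t[2] / 2, pz - t[3] / 2))
      mov <- vol_interp(sff_p, q[, 1], q[, 2], q[, 3], fill = -1000)
    } else {
      mov <- vol_interp(sff_p, px - t[1] / 2, py - t[2] / 2, pz - t[3] / 2,
                        fill = -1000)
    }
    mean((fixed - mov)^2)
  }

  ## coarse translation grid, then simplex refinement
  grid1 <- seq(-10, 10, by = 5)
  coarse <- expand.grid(x = grid1, y = grid1, z = grid1)
  vals <- apply(coarse, 1, function(g) metric(as.numeric(g)))
  start <- as.numeric(coarse[which.min(vals), ])
  par0 <- if (allow_rotation) c(start, 0, 0, 0) else start
  opt <- stats::optim(par0, metric, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
  if (opt$convergence != 0)
    stop(sprintf("registration did not converge (final metric %.4g)",
                 opt$value))
  rigid_transform(opt$par[1:3],
                  if (allow_rotation) opt$par[4:6] else c(0, 0, 0),
                  metric = opt$value)
}

#' Stitch the two scans into a whole-body volume
#'
#' Assembles a single head-first volume spanning head to feet on the
#' head-first scan's grid: above the mid-overlap plane the head-first
#' voxels are copied unchanged (hard transition with SHF precedence);
#' below it the feet-first scan is resampled through the registration
#' transform.  A longitudinal gap between the transformed scans is an
#' error reporting the gap extent.
#'
#' @param shf head-first scan.
#' @param sff feet-first scan.
#' @param t a [rigid_transform] from [register_pelvis()].
#' @return the stitched whole-body [tbi_volume].
#' @export
stitch <- function(shf, sff, t) {
  shf <- as_head_first(shf)
  sff_p <- as_head_first(sff)
  tr <- t$translation
  ext_s <- vol_extent(shf); ext_f <- vol_extent(sff_p)
  top_f <- ext_f$z[2] + tr[3]
  if (top_f < ext_s$z[1])
    stop(sprintf("longitudinal gap of %.1f mm between transformed scans",
                 ext_s$z[1] - top_f))
  mid <- (ext_s$z[1] + top_f) / 2

  dz <- shf$spacing[3]
  zbot <- ext_f$z[1] + tr[3]
  n_extra <- max(0L, ceiling((shf$origin[3] - dz / 2 - zbot) / dz))
  cc_s <- vol_axis_coords(shf)
  zcoords <- c(shf$origin[3] - dz * (n_extra:1), cc_s$z)
  d <- dim(shf$values)
  out_vals <- array(-1000, dim = c(d[1], d[2], length(zcoords)))
  out <- tbi_volume(out_vals, c(shf$origin[1:2], zcoords[1]),
                    shf$spacing, "SHF")

  use_rot <- any(t$rotation != 0)
  Rinv <- if (use_rot) solve(rotation_matrix(t$rotation)) else NULL
  for (k in seq_along(zcoords)) {
    z <- zcoords[k]
    k_shf <- k - n_extra
    if (z >= mid && k_shf >= 1 && k_shf <= d[3]) {
      out$values[, , k] <- shf$values[, , k_shf]
    } else {
      px <- rep(cc_s$x, times = d[2])
      py <- rep(cc_s$y, each = d[1])
      if (use_rot) {
        q <- t(Rinv %*% rbind(px - tr[1], py - tr[2], rep(z - tr[3], length(px))))
        vals <- vol_interp(sff_p, q[, 1], q[, 2], q[, 3], fill = -1000)
      } else {
        vals <- vol_interp(sff_p, px - tr[1], py - tr[2],
                           rep(z - tr[3], length(px)), fill = -1000)
      }
      out$values[, , k] <- matrix(vals, d[1], d[2])
    }
  }
  out
}
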