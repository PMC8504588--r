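#' Regular 3-D image volume
#'
#' Lightweight container for CT-like intensities, binary masks and dose
#' rasters.  Values live on a regular grid in the patient coordinate frame:
#' x is lateral (patient left positive), y is anterior positive, z is
#' longitudinal (superior positive), with the origin (0,0,0) at the pelvis
#' reference mark.  `origin` is the patient-frame coordinate (mm) of the
#' centre of stored voxel `[1,1,1]`.
#'
#' For a head-first (`"SHF"`) volume the third storage index increases
#' superiorly; for a feet-first (`"SFF"`) volume the stored slice order is
#' flipped along z relative to patient coordinates, so the third index
#' increases inferiorly.  This makes the head-first/feet-first "rotate
#' series" step of plan conversion a real array transform.
#'
#' @param values numeric or logical 3-D array, storage order `[x, y, z]`.
#' @param origin length-3 numeric, mm.
#' @param spacing length-3 numeric, mm, strictly positive.
#' @param orientation `"SHF"` or `"SFF"`.
#' @return An object of class `tbi_volume`.
#' @export
tbi_volume <- function(values, origin, spacing, orientation = "SHF") {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("origin and spacing must have length 3")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (!orientation %in% c("SHF", "SFF")) stop("orientation must be SHF or SFF")
  structure(list(values = values, origin = origin, spacing = spacing,
                 orientation = orientation),
            class = "tbi_volume")
}

#' @export
print.tbi_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tbi_volume> %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = " x "),
              x$orientation))
  ext <- vol_extent(x)
  cat(sprintf("  x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              ext$x[1], ext$x[2], ext$y[1], ext$y[2], ext$z[1], ext$z[2]))
  invisible(x)
}

#' Patient-frame coordinates of voxel centres along each axis
#'
#' @param vol a [tbi_volume].
#' @return list with numeric vectors `x`, `y`, `z` (mm); `z` is decreasing
#'   for feet-first volumes.
#' @export
vol_axis_coords <- function(vol) {
  d <- dim(vol$values)
  zdir <- if (vol$orientation == "SFF") -1 else 1
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
       z = vol$origin[3] + zdir * (seq_len(d[3]) - 1) * vol$spacing[3])
}

#' Spatial extent of a volume (outer voxel faces)
#'
#' @param vol a [tbi_volume].
#' @return list of length-2 ranges `x`, `y`, `z` in mm.
#' @export
vol_extent <- function(vol) {
  cc <- vol_axis_coords(vol)
  h <- vol$spacing / 2
  list(x = range(cc$x) + c(-h[1], h[1]),
       y = range(cc$y) + c(-h[2], h[2]),
       z = range(cc$z) + c(-h[3], h[3]))
}

#' Reorder a volume into head-first storage
#'
#' @param vol a [tbi_volume].
#' @return the same volume with storage slice order increasing superiorly.
#' @export
as_head_first <- function(vol) {
  if (vol$orientation == "SHF") return(vol)
  d <- dim(vol$values)
  vals <- vol$values[, , rev(seq_len(d[3])), drop = FALSE]
  origin <- vol$origin
  origin[3] <- vol$origin[3] - (d[3] - 1) * vol$spacing[3]
  tbi_volume(vals, origin, vol$spacing, "SHF")
}

#' Reorder a volume into feet-first storage
#'
#' @param vol a [tbi_volume].
#' @return the same volume with storage slice order increasing inferiorly.
#' @export
as_feet_first <- function(vol) {
  if (vol$orientation == "SFF") return(vol)
  d <- dim(vol$values)
  vals <- vol$values[, , rev(seq_len(d[3])), drop = FALSE]
  origin <- vol$origin
  origin[3] <- vol$origin[3] + (d[3] - 1) * vol$spacing[3]
  tbi_volume(vals, origin, vol$spacing, "SFF")
}

## trilinear interpolation at arbitrary patient-frame points; vol must be
## head-first ordered (callers convert with as_head_first first)
vol_interp <- function(vol, x, y, z, fill = NA_real_) {
  stopifnot(vol$orientation == "SHF")
  d <- dim(vol$values)
  fx <- (x - vol$origin[1]) / vol$spacing[1] + 1
  fy <- (y - vol$origin[2]) / vol$spacing[2] + 1
  fz <- (z - vol$origin[3]) / vol$spacing[3] + 1
  out <- rep(fill, length(fx))
  ok <- fx >= 1 & fx <= d[1] & fy >= 1 & fy <= d[2] & fz >= 1 & fz <= d[3]
  if (!any(ok)) return(out)
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  i0 <- pmin(floor(fx), d[1] - 1L); j0 <- pmin(floor(fy), d[2] - 1L)
  k0 <- pmin(floor(fz), d[3] - 1L)
  i0 <- pmax(i0, 1L); j0 <- pmax(j0, 1L); k0 <- pmax(k0, 1L)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  v <- vol$values
  idx <- function(i, j, k) v[cbind(i, j, k)]
  val <-
    idx(i0,     j0,     k0)     * (1 - wx) * (1 - wy) * (1 - wz) +
    idx(i0 + 1, j0,     k0)     * wx       * (1 - wy) * (1 - wz) +
    idx(i0,     j0 + 1, k0)     * (1 - wx) * wy       * (1 - wz) +
    idx(i0 + 1, j0 + 1, k0)     * wx       * wy       * (1 - wz) +
    idx(i0,     j0,     k0 + 1) * (1 - wx) * (1 - wy) * wz +
    idx(i0 + 1, j0,     k0 + 1) * wx       * (1 - wy) * wz +
    idx(i0,     j0 + 1, k0 + 1) * (1 - wx) * wy       * wz +
    idx(i0 + 1, j0 + 1, k0 + 1) * wx       * wy       * wz
  out[ok] <- val
  out
}

## nearest-neighbour lookup, same conventions as vol_interp
vol_nearest <- function(vol, x, y, z, fill = NA_real_) {
  stopifnot(vol$orientation == "SHF")
  d <- dim(vol$values)
  i <- round((x - vol$origin[1]) / vol$spacing[1]) + 1
  j <- round((y - vol$origin[2]) / vol$spacing[2]) + 1
  k <- round((z - vol$origin[3]) / vol$spacing[3]) + 1
  out <- rep(fill, length(i))
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out[ok] <- vol$values[cbind(i[ok], j[ok], k[ok])]
  out
}

## empty head-first volume covering `extent` (list of x/y/z ranges, mm) at
## `spacing`; grid is anchored at the lower corner of the extent
make_grid <- function(extent, spacing, fill = 0) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  n <- vapply(seq_len(3), function(a) {
    rng <- extent[[a]]
    max(1L, as.integer(ceiling((rng[2] - rng[1]) / spacing[a] - 1e-9)))
  }, integer(1))
  origin <- c(extent$x[1], extent$y[1], extent$z[1]) + spacing / 2
  tbi_volume(array(fill, dim = n), origin, spacing, "SHF")
}

## TRUE when two volumes share grid geometry exactly
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    a$orientation == b$orientation
}

#' Translate a volume's contents by a rigid offset
#'
#' Resamples the values on the unchanged grid after displacing the contents
#' by `delta` (mm, patient frame): the output at point `p` equals the input
#' at `p - delta`.  Linear interpolation; points sampled outside the input
#' get `fill`.  A zero offset returns the input untouched.
#'
#' @param vol a head-first [tbi_volume].
#' @param delta length-3 numeric displacement, mm.
#' @param fill value for points displaced in from outside the grid.
#' @return a [tbi_volume] on the same grid.
#' @export
shift_volume <- function(vol, delta, fill = 0) {
  delta <- as.numeric(delta)
  if (all(delta == 0)) return(vol)
  vol <- as_head_first(vol)
  cc <- vol_axis_coords(vol)
  d <- dim(vol$values)
  pts <- list(x = rep(cc$x, times = d[2] * d[3]),
              y = rep(rep(cc$y, each = d[1]), times = d[3]),
              z = rep(cc$z, each = d[1] * d[2]))
  vals <- vol_interp(vol, pts$x - delta[1], pts$y - delta[2],
                     pts$z - delta[3], fill = fill)
  out <- vol
  out$values <- array(vals, dim = d)
  out
}

## 180 degree rotation about the vertical axis through `origin_pt`:
## x -> 2*ox - x, z -> 2*oz - z, y unchanged.  Pure array flips, exact.
rotate_about_vertical <- function(vol, origin_pt) {
  d <- dim(vol$values)
  vals <- vol$values[rev(seq_len(d[1])), , rev(seq_len(d[3])), drop = FALSE]
  cc <- vol_axis_coords(vol)
  ## flipping both axes preserves the storage direction convention, so the
  ## orientation flag carries over unchanged
  origin <- c(2 * origin_pt[1] - max(cc$x), vol$origin[2],
              2 * origin_pt[3] - cc$z[d[3]])
  tbi_volume(vals, origin, vol$spacing, vol$orientation)
}

#' Write a volume to NIfTI with a JSON sidecar
#'
#' The dialect is NIfTI-1 via RNifti with voxel dimensions in mm; the
#' patient-frame origin, spacing and head/feet-first orientation flag are
#' stored in `<path>.json` because NIfTI sform conventions are not needed
#' for this toolkit's single fixed frame.
#'
#' @param vol a [tbi_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values * 1, pixdim = vol$spacing)
  RNifti::writeNifti(img, path)
  meta <- list(origin = vol$origin, spacing = vol$spacing,
               orientation = vol$orientation)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume]
#'
#' @param path path previously given to [write_volume].
#' @return a [tbi_volume].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tbi_volume(array(as.numeric(img), dim = dim(img)),
             meta$origin, meta$spacing, meta$orientation)
}
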