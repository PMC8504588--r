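#' Synthetic whole-body phantom specification
#'
#' Parameterizes a simplified anthropomorphic phantom built from stacked
#' analytic solids: an ellipsoidal head on a neck cylinder, an
#' elliptic-cylinder trunk and paired leg cylinders, with embedded lung and
#' kidney ellipsoids.  All longitudinal positions are in the patient frame
#' with z = 0 at the pelvis reference mark and z increasing superiorly.
#' Defaults scale with height using simple anthropometric fractions; any
#' field can be overridden.
#'
#' @param height body height, cm (accepted range 100-220; the generator is
#'   routinely exercised over 139-193).
#' @param shoulder_width lateral trunk width including adducted arms, cm.
#' @param umbilicus_separation anterior-posterior trunk thickness at the
#'   umbilicus, cm.
#' @param leg_width total lateral width of the paired legs, cm; must not
#'   exceed 35 cm (AP/PA field-width eligibility).
#' @param lung_center_z,lung_length lung ellipsoid centre and full length
#'   along z, cm.
#' @param kidney_center_z,kidney_length kidney ellipsoid centre and full
#'   length along z, cm.
#' @param neck_bottom_z bottom of the neck (head sub-target boundary), cm.
#' @param legs_top_z top of the legs (VMAT/AP-PA boundary region), cm.
#' @param is_pediatric logical flag carried through to planning rules.
#' @param voxel_spacing grid spacing, mm, length 3 (default 2.5 x 2.5 x 5,
#'   i.e. 5 mm slices).
#' @param seed integer seed controlling the deterministic soft-tissue
#'   texture phase.
#' @return A validated object of class `phantom_spec` (all lengths stored
#'   in cm, spacing in mm).
#' @export
phantom_spec <- function(height = 180,
                         shoulder_width = 0.22 * height,
                         umbilicus_separation = 0.12 * height,
                         leg_width = min(0.16 * height, 34),
                         lung_center_z = 0.22 * height,
                         lung_length = 0.13 * height,
                         kidney_center_z = 0.08 * height,
                         kidney_length = 0.07 * height,
                         neck_bottom_z = 0.48 * height - min(24, 0.14 * height),
                         legs_top_z = -0.05 * height,
                         is_pediatric = height < 140,
                         voxel_spacing = c(2.5, 2.5, 5),
                         seed = 1L) {
  spec <- list(height = height, shoulder_width = shoulder_width,
               umbilicus_separation = umbilicus_separation,
               leg_width = leg_width,
               lung_center_z = lung_center_z, lung_length = lung_length,
               kidney_center_z = kidney_center_z,
               kidney_length = kidney_length,
               neck_bottom_z = neck_bottom_z, legs_top_z = legs_top_z,
               is_pediatric = is_pediatric,
               voxel_spacing = rep(as.numeric(voxel_spacing), length.out = 3),
               seed = as.integer(seed),
               head_top_z = 0.48 * height, feet_bottom_z = -0.52 * height)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks the geometric invariants a phantom must satisfy before
#' generation; errors name the violated field.
#'
#' @param spec a [phantom_spec].
#' @return `spec`, invisibly, if valid.
#' @export
validate_phantom_spec <- function(spec) {
  fail <- function(field, msg) stop(sprintf("invalid phantom spec: %s %s", field, msg),
                                    call. = FALSE)
  if (!is.finite(spec$height) || spec$height < 100 || spec$height > 220)
    fail("height", "must be in [100, 220] cm")
  if (spec$leg_width > 35)
    fail("leg_width", "must be <= 35 cm for AP/PA eligibility")
  for (f in c("shoulder_width", "umbilicus_separation", "leg_width",
              "lung_length", "kidney_length"))
    if (spec[[f]] <= 0) fail(f, "must be positive")
  lung_bottom <- spec$lung_center_z - spec$lung_length / 2
  kidney_top <- spec$kidney_center_z + spec$kidney_length / 2
  if (lung_bottom <= kidney_top)
    fail("lung_center_z", "lungs must lie strictly superior to kidneys")
  if (spec$neck_bottom_z <= spec$lung_center_z)
    fail("neck_bottom_z", "must be superior to lung_center_z")
  if (spec$neck_bottom_z >= spec$head_top_z)
    fail("neck_bottom_z", "must be inferior to the head top")
  if (spec$legs_top_z <= spec$feet_bottom_z)
    fail("legs_top_z", "must be superior to feet_bottom_z")
  if (any(spec$voxel_spacing <= 0))
    fail("voxel_spacing", "must be strictly positive")
  invisible(spec)
}

#' Structure set: masks plus landmarks on a shared grid
#'
#' @param masks named list of logical arrays (`body`, `lungs`, `kidneys`)
#'   sharing the grid of `geometry`.
#' @param landmarks named list of z coordinates in mm (`head_top`,
#'   `neck_bottom`, `legs_top`, `feet_bottom`).
#' @param geometry a [tbi_volume] defining the common grid.
#' @param spec the generating [phantom_spec], if any.
#' @return An object of class `tbi_structures`.
#' @export
tbi_structures <- function(masks, landmarks, geometry, spec = NULL) {
  for (m in masks) stopifnot(identical(dim(m), dim(geometry$values)))
  structure(list(masks = masks, landmarks = landmarks,
                 geometry = geometry[c("origin", "spacing", "orientation")],
                 spec = spec),
            class = "tbi_structures")
}

#' @export
print.tbi_structures <- function(x, ...) {
  cat("<tbi_structures>", paste(names(x$masks), collapse = ", "), "\n")
  cat("  landmarks (mm):",
      paste(sprintf("%s=%.0f", names(x$landmarks), unlist(x$landmarks)),
            collapse = ", "), "\n")
  invisible(x)
}

## mask as a tbi_volume sharing the structure-set grid
structure_volume <- function(structures, name) {
  g <- structures$geometry
  tbi_volume(structures$masks[[name]], g$origin, g$spacing, g$orientation)
}

## analytic phantom fields at arbitrary patient-frame points (mm):
## HU plus body/lung/kidney membership.  Used both to voxelize the phantom
## and to emulate re-acquisition of a displaced patient, so scans are
## sampled from the continuous model rather than interpolated.
phantom_fields <- function(spec, X, Y, Z) {
  cm <- 10
  ht <- spec$head_top_z * cm; nb <- spec$neck_bottom_z * cm
  lt <- spec$legs_top_z * cm; fb <- spec$feet_bottom_z * cm
  sw <- spec$shoulder_width * cm; us <- spec$umbilicus_separation * cm
  lw <- spec$leg_width * cm

  trunk <- (X / (sw / 2))^2 + (Y / (us / 2))^2 <= 1 & Z >= lt & Z < nb
  r_leg <- lw / 4
  legs <- ((sqrt((X - lw / 4)^2 + Y^2) <= r_leg) |
           (sqrt((X + lw / 4)^2 + Y^2) <= r_leg)) & Z >= fb & Z < lt
  hc <- (nb + ht) / 2; c_head <- (ht - nb) / 2
  a_head <- min(85, sw / 4); b_head <- min(105, a_head * 1.25)
  head <- (X / a_head)^2 + (Y / b_head)^2 + ((Z - hc) / c_head)^2 <= 1
  neck <- sqrt(X^2 + Y^2) <= min(50, a_head * 0.7) &
    Z >= nb & Z <= nb + 0.5 * c_head
  body <- trunk | legs | head | neck

  lz <- spec$lung_center_z * cm; laz <- spec$lung_length / 2 * cm
  lax <- 0.16 * sw; lay <- 0.30 * us; lcx <- 0.24 * sw
  lungs <- ((((X - lcx) / lax)^2 + (Y / lay)^2 + ((Z - lz) / laz)^2 <= 1) |
            (((X + lcx) / lax)^2 + (Y / lay)^2 + ((Z - lz) / laz)^2 <= 1)) &
    body
  kz <- spec$kidney_center_z * cm; kaz <- spec$kidney_length / 2 * cm
  kax <- 0.08 * sw; kay <- 0.14 * us; kcx <- 0.16 * sw; kcy <- -0.22 * us
  kidneys <- ((((X - kcx) / kax)^2 + ((Y - kcy) / kay)^2 +
                 ((Z - kz) / kaz)^2 <= 1) |
              (((X + kcx) / kax)^2 + ((Y - kcy) / kay)^2 +
                 ((Z - kz) / kaz)^2 <= 1)) & body

  set.seed(spec$seed)
  phase <- stats::runif(6, 0, 2 * pi)
  hu <- rep(-1000, length(X))
  ## smooth multi-scale soft-tissue modulation (stands in for the internal
  ## anatomy a real pelvis CT offers the registration metric); periods are
  ## several voxels long so trilinear interpolation represents it faithfully
  texture <- 60 * sin(2 * pi * X / 61 + phase[1]) *
    sin(2 * pi * Y / 47 + phase[2]) * sin(2 * pi * Z / 83 + phase[3]) +
    40 * sin(2 * pi * X / 103 + phase[4]) *
    sin(2 * pi * Y / 71 + phase[5]) * sin(2 * pi * Z / 131 + phase[6])
  hu[body] <- 0 + texture[body]
  hu[lungs] <- -700
  list(hu = hu, body = body, lungs = lungs, kidneys = kidneys)
}

#' Generate a synthetic whole-body CT phantom and structure set
#'
#' Builds the body from stacked analytic solids and embeds lungs and
#' kidneys at the specified longitudinal positions.  HU values are
#' deliberately simple -- soft tissue 0 HU (plus a deterministic
#' low-frequency texture that gives intensity gradients for registration),
#' lungs -700 HU, air -1000 HU; bone is omitted because the dose engine
#' uses water-equivalent depth with a lung density override only.
#' Deterministic for a fixed spec and seed.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `ct` (a [tbi_volume]) and `structures`
#'   (a [tbi_structures]).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  sp <- spec$voxel_spacing
  cm <- 10  # cm -> mm
  half_w <- max(spec$shoulder_width, spec$leg_width, 20) / 2 * cm + 40
  half_d <- spec$umbilicus_separation / 2 * cm + 40
  ext <- list(x = c(-half_w, half_w), y = c(-half_d, half_d),
              z = c(spec$feet_bottom_z * cm - 20, spec$head_top_z * cm + 20))
  grid <- make_grid(ext, sp, fill = -1000)
  cc <- vol_axis_coords(grid)
  nx <- length(cc$x); ny <- length(cc$y); nz <- length(cc$z)

  X <- array(rep(cc$x, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(cc$y, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(cc$z, each = nx * ny), dim = c(nx, ny, nz))

  ht <- spec$head_top_z * cm; nb <- spec$neck_bottom_z * cm
  lt <- spec$legs_top_z * cm; fb <- spec$feet_bottom_z * cm

  fields <- phantom_fields(spec, X, Y, Z)
  dims <- c(nx, ny, nz)
  body <- array(fields$body, dim = dims)
  lungs <- array(fields$lungs, dim = dims)
  kidneys <- array(fields$kidneys, dim = dims)

  ct <- grid; ct$values <- array(fields$hu, dim = dims)
  structures <- tbi_structures(
    masks = list(body = body, lungs = lungs, kidneys = kidneys),
    landmarks = list(head_top = ht, neck_bottom = nb,
                     legs_top = lt, feet_bottom = fb),
    geometry = ct, spec = spec)
  list(ct = ct, structures = structures)
}

#' Split a whole-body phantom into paired head-first and feet-first scans
#'
#' Emulates the two-scan acquisition: a supine head-first (SHF) scan from
#' above the head to below the pelvis and a supine feet-first (SFF) scan
#' from below the feet to above the pelvis, overlapping in the pelvis.  The
#' SFF scan is resampled with a known rigid offset applied, simulating the
#' patient setup change between scans, and stored in feet-first slice
#' order.  The applied offset is echoed back as the registration ground
#' truth.
#'
#' @param whole whole-body CT, a head-first [tbi_volume].
#' @param structures matching [tbi_structures] (supplies the pelvis mark).
#' @param overlap_cm longitudinal scan overlap centred on the pelvis mark,
#'   cm (default 10; the acquisition protocol does not pin this down).
#' @param applied_offset length-3 rigid offset of the second scan, mm; each
#'   component must not exceed 20 mm in magnitude.
#' @return list with `shf`, `sff` ([tbi_volume]s) and `truth` (mm triple).
#' @export
split_scans <- function(whole, structures, overlap_cm = 10,
                        applied_offset = c(0, 0, 0)) {
  applied_offset <- as.numeric(applied_offset)
  if (length(applied_offset) != 3 || any(abs(applied_offset) > 20))
    stop("applied_offset must be a mm triple with |offset| <= 20 mm per axis")
  whole <- as_head_first(whole)
  half <- overlap_cm / 2 * 10
  cc <- vol_axis_coords(whole)
  shf_idx <- which(cc$z >= -half)
  sff_idx <- which(cc$z <= half)
  if (overlap_cm <= 0 || length(intersect(shf_idx, sff_idx)) == 0)
    stop("scan overlap region is empty")
  shf <- tbi_volume(whole$values[, , shf_idx, drop = FALSE],
                    c(whole$origin[1:2], cc$z[min(shf_idx)]),
                    whole$spacing, "SHF")
  sff_vals <- whole$values[, , sff_idx, drop = FALSE]
  sff <- tbi_volume(sff_vals,
                    c(whole$origin[1:2], cc$z[min(sff_idx)]),
                    whole$spacing, "SHF")
  if (any(applied_offset != 0)) {
    ## scan content at point p images the patient shifted by the offset:
    ## sff(p) = patient(p + offset).  When the analytic spec is available
    ## the displaced patient is re-sampled exactly (a genuine second
    ## acquisition); otherwise the whole volume is interpolated.
    d <- dim(sff$values)
    scc <- vol_axis_coords(sff)
    px <- rep(scc$x, times = d[2] * d[3])
    py <- rep(rep(scc$y, each = d[1]), times = d[3])
    pz <- rep(scc$z, each = d[1] * d[2])
    vals <- if (!is.null(structures$spec))
      phantom_fields(structures$spec, px + applied_offset[1],
                     py + applied_offset[2], pz + applied_offset[3])$hu
    else
      vol_interp(whole, px + applied_offset[1], py + applied_offset[2],
                 pz + applied_offset[3], fill = -1000)
    sff$values <- array(vals, dim = d)
  }
  list(shf = shf, sff = as_feet_first(sff), truth = applied_offset)
}
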