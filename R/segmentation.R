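#' Parameters of the rule-based PTV division
#'
#' Houses the machine- and protocol-derived symbols of the sub-target
#' division rules: the MLC travel limit and split-arc doubling that cap the
#' VMAT sub-target length at 23 cm, the 2.5 cm optimization feathering zone
#' (OFZ) half-width that creates 5 cm junctions, the allowed AP/PA
#' sub-target lengths 25/30/35 cm, and the minimum 5 cm field margin beyond
#' the feet.
#'
#' @param skin_contraction isotropic skin contraction building the PTV, mm.
#' @param mlc_travel_limit MLC travel limit, cm.
#' @param field_margin_per_side field margin per side, cm.
#' @param ofz_halfwidth OFZ extension per interior end, cm.
#' @param vmat_max_length VMAT sub-target length limit, cm; by default
#'   derived from the machine constraint via [compute_vmat_limit()].
#' @param appa_allowed_lengths allowed AP/PA sub-target lengths, cm,
#'   ascending.
#' @param feet_margin_min minimum field margin beyond the feet, cm.
#' @param appa_width_limit maximum body width planned with AP/PA beams, cm.
#' @param vmat_width_threshold lateral field width above which VMAT
#'   sub-target lengths are shortened for large patients, cm.
#' @return An object of class `segmentation_params` (lengths in cm except
#'   `skin_contraction` in mm).
#' @export
segmentation_params <- function(skin_contraction = 3,
                                mlc_travel_limit = 14.5,
                                field_margin_per_side = 0.5,
                                ofz_halfwidth = 2.5,
                                vmat_max_length = NULL,
                                appa_allowed_lengths = c(25, 30, 35),
                                feet_margin_min = 5,
                                appa_width_limit = 35,
                                vmat_width_threshold = 40) {
  lim <- compute_vmat_limit(mlc_travel_limit, field_margin_per_side,
                            2 * ofz_halfwidth)
  if (is.null(vmat_max_length)) vmat_max_length <- lim$subtarget_limit
  if (is.unsorted(appa_allowed_lengths, strictly = TRUE))
    stop("appa_allowed_lengths must be sorted ascending")
  p <- list(skin_contraction = skin_contraction,
            mlc_travel_limit = mlc_travel_limit,
            field_margin_per_side = field_margin_per_side,
            ofz_halfwidth = ofz_halfwidth,
            vmat_max_length = vmat_max_length,
            appa_allowed_lengths = appa_allowed_lengths,
            feet_margin_min = feet_margin_min,
            appa_width_limit = appa_width_limit,
            vmat_width_threshold = vmat_width_threshold,
            field_length = lim$field_length, opt_limit = lim$opt_limit)
  class(p) <- "segmentation_params"
  p
}

#' Derive the VMAT sub-target length limit from machine constraints
#'
#' The superior-inferior field length is twice the MLC travel limit (split
#' arcs); the optimization-target limit subtracts the per-side field
#' margins; the sub-target limit further subtracts the feathering-zone
#' width.  With the 14.5 cm travel limit, 5 mm margins and a 5 cm OFZ this
#' yields a 29 cm field, a 28 cm optimization limit and a 23 cm sub-target
#' limit.
#'
#' @param mlc_travel_limit MLC travel limit, cm.
#' @param field_margin_per_side field margin per side, cm.
#' @param ofz_width total feathering-zone width per sub-target, cm.
#' @return list with `field_length`, `opt_limit`, `subtarget_limit` (cm).
#' @export
compute_vmat_limit <- function(mlc_travel_limit, field_margin_per_side,
                               ofz_width) {
  if (mlc_travel_limit <= 0 || field_margin_per_side < 0 || ofz_width < 0)
    stop("limit inputs must be positive")
  field_length <- 2 * mlc_travel_limit
  opt_limit <- field_length - 2 * field_margin_per_side
  subtarget_limit <- opt_limit - ofz_width
  if (subtarget_limit <= 0)
    stop("derived sub-target limit is not positive; check machine constants")
  list(field_length = field_length, opt_limit = opt_limit,
       subtarget_limit = subtarget_limit)
}

#' Look up the AP/PA sub-target length for a remaining PTV length
#'
#' Chooses among the allowed lengths the combination that covers the
#' remaining PTV plus the required feet margin with the fewest isocenters,
#' and among equal counts the shortest length (smallest isocenter
#' distances).
#'
#' @param remaining_length PTV length left below the last VMAT sub-target,
#'   cm; must be positive.
#' @param params a [segmentation_params].
#' @return list with `length` (cm) and `count`.
#' @export
appa_length_lookup <- function(remaining_length, params = segmentation_params()) {
  if (remaining_length <= 0) stop("remaining_length must be positive")
  need <- remaining_length + params$feet_margin_min
  lengths <- params$appa_allowed_lengths
  count <- 1L
  repeat {
    feasible <- lengths[count * lengths >= need - 1e-9]
    if (length(feasible))
      return(list(length = min(feasible), count = count))
    count <- count + 1L
  }
}

## shift a logical array by an integer voxel offset, padding with FALSE
shift_mask <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    src[[a]] <- seq_len(d[a]) - o
    keep <- src[[a]] >= 1 & src[[a]] <= d[a]
    src[[a]] <- src[[a]][keep]
    dst[[a]] <- seq_len(d[a])[keep]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

## isotropic morphological erosion by radius mm (ball structuring element
## expressed in voxel offsets)
erode_mask <- function(mask, spacing, radius_mm) {
  if (radius_mm <= 0) return(mask)
  nmax <- floor(radius_mm / spacing)
  out <- mask
  for (di in -nmax[1]:nmax[1])
    for (dj in -nmax[2]:nmax[2])
      for (dk in -nmax[3]:nmax[3]) {
        if (di == 0 && dj == 0 && dk == 0) next
        if (sum((c(di, dj, dk) * spacing)^2) > radius_mm^2 + 1e-9) next
        out <- out & shift_mask(mask, c(di, dj, dk))
      }
  out
}

#' Build the planning target volume
#'
#' PTV = body contracted in from the skin by `skin_contraction` (isotropic
#' morphological erosion), minus the lungs and kidneys.
#'
#' @param structures a [tbi_structures] with `body`, `lungs`, `kidneys`.
#' @param params a [segmentation_params].
#' @return The PTV mask as a logical-valued [tbi_volume].
#' @export
build_ptv <- function(structures, params = segmentation_params()) {
  for (nm in c("body", "lungs", "kidneys"))
    if (is.null(structures$masks[[nm]]))
      stop(sprintf("structure set is missing required mask '%s'", nm))
  g <- structures$geometry
  body <- structures$masks$body
  eroded <- erode_mask(body, g$spacing, params$skin_contraction)
  ptv <- eroded & !structures$masks$lungs & !structures$masks$kidneys
  if (!any(ptv)) stop("PTV is empty after contraction and organ exclusion")
  tbi_volume(ptv, g$origin, g$spacing, g$orientation)
}

## core longitudinal division; all inputs in mm
divide_core <- function(ptv_top, ptv_bottom, landmarks, params, iso_xy,
                        forced_boundary = NULL,
                        allow_vmat_below_legs = FALSE) {
  vlen <- params$vmat_max_length * 10
  ofz <- params$ofz_halfwidth * 10
  opt_limit <- params$opt_limit * 10
  nb <- landmarks$neck_bottom
  lt <- landmarks$legs_top
  if (nb >= ptv_top || nb <= ptv_bottom)
    stop("landmarks inconsistent with the PTV extent")
  if ((ptv_top - nb) + ofz > opt_limit + 1e-9)
    stop("head sub-target exceeds the optimization length limit; review the phantom spec")

  kinds <- "VMAT"; sup <- ptv_top; inf <- nb
  cur <- nb
  if (!is.null(forced_boundary)) {
    if (forced_boundary >= cur || forced_boundary <= ptv_bottom)
      stop("forced junction boundary outside the PTV")
    n_above <- ceiling((cur - forced_boundary) / vlen - 1e-9)
    len_above <- (cur - forced_boundary) / n_above
    for (i in seq_len(n_above)) {
      kinds <- c(kinds, "VMAT")
      sup <- c(sup, cur); inf <- c(inf, cur - len_above)
      cur <- cur - len_above
    }
  }
  trunk_only <- ptv_bottom > lt
  stack_floor <- if (trunk_only) ptv_bottom else lt
  while (if (allow_vmat_below_legs && !trunk_only) cur - 1e-6 > lt
         else cur - vlen >= stack_floor - 1e-6) {
    kinds <- c(kinds, "VMAT")
    sup <- c(sup, cur); inf <- c(inf, cur - vlen)
    cur <- cur - vlen
  }
  feet_margin <- NA_real_
  if (trunk_only) {
    if (cur > ptv_bottom + 1e-6) {
      kinds <- c(kinds, "VMAT")
      sup <- c(sup, cur); inf <- c(inf, ptv_bottom)
      cur <- ptv_bottom
    }
  } else {
    remaining <- (cur - ptv_bottom) / 10
    if (remaining > 1e-6) {
      lk <- appa_length_lookup(remaining, params)
      for (i in seq_len(lk$count)) {
        kinds <- c(kinds, "APPA")
        sup <- c(sup, cur); inf <- c(inf, cur - lk$length * 10)
        cur <- cur - lk$length * 10
      }
      feet_margin <- (ptv_bottom - cur) / 10
    }
  }

  n <- length(kinds)
  interior_sup <- seq_len(n) > 1
  interior_inf <- seq_len(n) < n
  st <- data.frame(index = seq_len(n), kind = kinds,
                   z_inf = inf, z_sup = sup,
                   opt_inf = inf - ifelse(interior_inf, ofz, 0),
                   opt_sup = sup + ifelse(interior_sup, ofz, 0),
                   iso_x = iso_xy[1], iso_y = iso_xy[2],
                   iso_z = (inf + sup) / 2)
  for (i in which(st$kind == "VMAT"))
    if (st$opt_sup[i] - st$opt_inf[i] > opt_limit + 1e-6)
      stop("VMAT optimization interval exceeds the split-arc field length")
  junctions <- data.frame(x = iso_xy[1], y = iso_xy[2],
                          z = st$z_inf[-n])
  structure(list(subtargets = st, junctions = junctions,
                 origin_point = c(iso_xy[1], iso_xy[2], 0),
                 params = params,
                 meta = list(ptv_top = ptv_top, ptv_bottom = ptv_bottom,
                             landmarks = landmarks, iso_xy = iso_xy,
                             allow_vmat_below_legs = allow_vmat_below_legs,
                             feet_margin = feet_margin)),
            class = "tbi_subtargets")
}

#' @export
print.tbi_subtargets <- function(x, ...) {
  st <- x$subtargets
  cat(sprintf("<tbi_subtargets> %d sub-targets (%d VMAT, %d AP/PA)\n",
              nrow(st), sum(st$kind == "VMAT"), sum(st$kind == "APPA")))
  print(transform(st, length_cm = (z_sup - z_inf) / 10), row.names = FALSE)
  invisible(x)
}

#' Divide the PTV into VMAT and AP/PA sub-targets
#'
#' Executes the longitudinal division rules: the first VMAT sub-target
#' spans from the top of the head to the bottom of the neck; subsequent
#' VMAT sub-targets of the limit length (23 cm by default) stack
#' inferiorly until the next full sub-target would extend below the top of
#' the legs; equal-length AP/PA sub-targets chosen by
#' [appa_length_lookup()] cover the remainder with at least the required
#' margin beyond the feet.  Each sub-target gets an isocentre at its
#' centre, each junction region a junction point at its centre, and all
#' points share the lateral/vertical coordinates of the pelvis-level PTV
#' centroid (rounded to 1 mm).
#'
#' @param ptv PTV mask as a logical-valued [tbi_volume] (see
#'   [build_ptv()]).
#' @param structures a [tbi_structures] supplying the landmarks.
#' @param params a [segmentation_params].
#' @param allow_vmat_below_legs if `TRUE` the last full VMAT sub-target may
#'   cross the top of the legs; by default it must end at or above it.
#' @return An object of class `tbi_subtargets`.
#' @export
divide_ptv <- function(ptv, structures, params = segmentation_params(),
                       allow_vmat_below_legs = FALSE) {
  vals <- ptv$values
  d <- dim(vals)
  cc <- vol_axis_coords(ptv)
  slice_any <- colSums(matrix(vals, d[1] * d[2], d[3])) > 0
  if (!any(slice_any)) stop("PTV is empty")
  zin <- range(cc$z[slice_any])
  ptv_top <- max(zin) + ptv$spacing[3] / 2
  ptv_bottom <- min(zin) - ptv$spacing[3] / 2

  ## shared lateral/vertical coordinates: pelvis-level PTV centroid
  pelvis <- abs(cc$z) <= 25
  if (!any(pelvis & slice_any)) pelvis <- slice_any
  sel <- vals & rep(pelvis, each = d[1] * d[2])
  xs <- rep(cc$x, times = d[2] * d[3])[sel]
  ys <- rep(rep(cc$y, each = d[1]), times = d[3])[sel]
  iso_xy <- round(c(mean(xs), mean(ys)))

  set <- divide_core(ptv_top, ptv_bottom, structures$landmarks, params,
                     iso_xy, allow_vmat_below_legs = allow_vmat_below_legs)
  set$meta$is_pediatric <- isTRUE(structures$spec$is_pediatric)
  set
}

#' Shift a junction into the lung-kidney gap for pediatric patients
#'
#' For pediatric cases the thoracic/abdominal VMAT sub-targets are
#' shortened (never lengthened) so that one junction region's 5 cm
#' optimization overlap lies entirely between the inferior lung extent and
#' the superior kidney extent.  Adult sets are returned unchanged.
#'
#' @param set a `tbi_subtargets` from [divide_ptv()].
#' @param structures the matching [tbi_structures] (lungs and kidneys
#'   required).
#' @return An adjusted `tbi_subtargets`.
#' @export
pediatric_adjust <- function(set, structures) {
  if (!isTRUE(set$meta$is_pediatric) &&
      !isTRUE(structures$spec$is_pediatric)) return(set)
  for (nm in c("lungs", "kidneys"))
    if (is.null(structures$masks[[nm]]))
      stop(sprintf("structure set is missing required mask '%s'", nm))
  g <- structures$geometry
  zext <- function(mask) {
    d <- dim(mask)
    zz <- vol_axis_coords(structure_volume(structures, "body"))$z
    sl <- colSums(matrix(mask, d[1] * d[2], d[3])) > 0
    range(zz[sl]) + c(-1, 1) * g$spacing[3] / 2
  }
  lung_bottom <- zext(structures$masks$lungs)[1]
  kid_top <- zext(structures$masks$kidneys)[2]
  gap <- lung_bottom - kid_top
  ofz_w <- 2 * set$params$ofz_halfwidth * 10
  if (gap < ofz_w - 1e-9)
    stop(sprintf("lung-kidney z-gap is %.1f cm, smaller than the %.0f cm junction region",
                 gap / 10, ofz_w / 10))
  b <- (lung_bottom + kid_top) / 2
  out <- divide_core(set$meta$ptv_top, set$meta$ptv_bottom,
                     set$meta$landmarks, set$params, set$meta$iso_xy,
                     forced_boundary = b,
                     allow_vmat_below_legs = set$meta$allow_vmat_below_legs)
  out$meta$is_pediatric <- TRUE
  out
}

#' Shorten VMAT sub-targets for large patients
#'
#' When the lateral field width required to cover the arms exceeds a
#' threshold, VMAT sub-target lengths are reduced by 1 cm (or 2 cm when the
#' excess is more than 5 cm) and the division is re-tiled.
#'
#' @param set a `tbi_subtargets`.
#' @param arm_extent required lateral extent including the arms, cm.
#' @return An adjusted `tbi_subtargets` (unchanged when under threshold).
#' @export
large_patient_adjust <- function(set, arm_extent) {
  thr <- set$params$vmat_width_threshold
  if (arm_extent <= thr) return(set)
  reduction <- if (arm_extent <= thr + 5) 1 else 2
  params <- set$params
  params$vmat_max_length <- params$vmat_max_length - reduction
  out <- divide_core(set$meta$ptv_top, set$meta$ptv_bottom,
                     set$meta$landmarks, params, set$meta$iso_xy,
                     allow_vmat_below_legs = set$meta$allow_vmat_below_legs)
  out$meta$is_pediatric <- set$meta$is_pediatric
  out
}

#' Serialize a sub-target set to JSON
#'
#' Intervals and points are written in mm; the schema has `subtargets`
#' (index, kind, z intervals, optimization intervals, isocentres),
#' `junction_points`, `origin_point` and the generating parameters.
#'
#' @param set a `tbi_subtargets`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subtargets <- function(set, path) {
  payload <- list(subtargets = set$subtargets,
                  junction_points = set$junctions,
                  origin_point = set$origin_point,
                  params = unclass(set$params),
                  meta = set$meta)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a sub-target set written by [write_subtargets]
#'
#' @param path path to the JSON file.
#' @return A `tbi_subtargets`.
#' @export
read_subtargets <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- p$params
  class(params) <- "segmentation_params"
  meta <- p$meta
  meta$landmarks <- as.list(meta$landmarks)
  structure(list(subtargets = as.data.frame(p$subtargets),
                 junctions = as.data.frame(p$junction_points),
                 origin_point = as.numeric(p$origin_point),
                 params = params, meta = meta),
            class = "tbi_subtargets")
}
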