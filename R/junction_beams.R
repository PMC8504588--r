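## extract one sub-target with its context flags
get_subtarget <- function(set, index) {
  st <- set$subtargets
  if (index < 1 || index > nrow(st)) stop("no such sub-target")
  row <- as.list(st[index, ])
  row$is_last <- index == nrow(st)
  row$interior_sup <- index > 1
  row$interior_inf <- index < nrow(st)
  row$iso <- c(row$iso_x, row$iso_y, row$iso_z)
  row$ofz <- set$params$ofz_halfwidth * 10
  row
}

#' Build the feathered AP/PA beam pair for a leg/feet sub-target
#'
#' Two opposed 6 MV beams (gantry 0 and 180 degrees) with the collimator
#' at 90 degrees so the collimator-frame X axis runs longitudinally.  Each
#' beam has three rectangular segments with the lateral jaws at maximum
#' and longitudinal edges stepped in OFZ-halfwidth (2.5 cm) decrements at
#' each junction-facing end, producing a 3-level dose ramp across the 5 cm
#' junction.  The most inferior pair has its inferior edge at the maximum
#' 20 cm from the isocentre to guarantee field margin beyond the feet.
#'
#' @param subtarget a sub-target extracted from a `tbi_subtargets` (index
#'   into the set), or the set itself plus `index`.
#' @param params the [segmentation_params] of the set.
#' @param index sub-target index when `subtarget` is a `tbi_subtargets`.
#' @param mu monitor units per beam.
#' @return list with beams `ap` and `pa`.
#' @export
make_feathered_appa <- function(subtarget, params = segmentation_params(),
                                index = NULL, mu = 100) {
  if (inherits(subtarget, "tbi_subtargets")) {
    params <- subtarget$params
    subtarget <- get_subtarget(subtarget, index)
  }
  if (!identical(subtarget$kind, "APPA"))
    stop("feathered AP/PA beams require an APPA sub-target")
  ofz <- params$ofz_halfwidth * 10
  jaw <- 200  # mm, maximum half field
  up <- subtarget$z_sup - subtarget$iso_z
  lo <- subtarget$z_inf - subtarget$iso_z
  sup_edges <- if (subtarget$interior_sup) c(up + ofz, up, up - ofz)
               else rep(up, 3)
  inf_edges <- if (subtarget$is_last) rep(-jaw, 3)
               else c(lo - ofz, lo, lo + ofz)
  segs <- lapply(1:3, function(i)
    beam_segment(inf_edges[i], sup_edges[i], -jaw, jaw, weight = 1 / 3))
  mk <- function(gantry)
    tbi_beam(subtarget$iso, gantry = gantry, collimator = 90, energy = 6,
             mu = mu, mu_rate = 600, segments = segs,
             technique = "feathered_appa",
             aux = list(subtarget_index = subtarget$index,
                        z_inf = subtarget$z_inf, z_sup = subtarget$z_sup))
  list(ap = mk(0), pa = mk(180))
}

#' Build the step-wedge junction beams
#'
#' Nine equally weighted step-and-shoot beams with gantry angles 40
#' degrees apart (starting at 0), each carrying five equally weighted
#' nested rectangular segments whose longitudinal edges advance in 1 cm
#' steps across the 5 cm junction.  The summed fluence is a monotone
#' 5-level staircase spanning the junction, ascending toward the inferior
#' side; the resulting wedge-shaped dose is used as an optimization base
#' dose only, never delivered.
#'
#' @param junction_point mm triple (a junction point of the sub-target
#'   set).
#' @param params a [segmentation_params] (supplies the junction width).
#' @param mu monitor units per beam.
#' @return list of 9 [tbi_beam]s.
#' @export
make_step_wedge <- function(junction_point, params = segmentation_params(),
                            mu = 10) {
  width <- 2 * params$ofz_halfwidth * 10
  nseg <- 5L
  step <- width / nseg
  jaw <- 200
  half <- width / 2
  segs <- lapply(seq_len(nseg), function(j)
    beam_segment(-half, -half + j * step, -jaw, jaw, weight = 1 / nseg))
  lapply(seq(0, 320, by = 40), function(g)
    tbi_beam(junction_point, gantry = g, collimator = 90, energy = 6,
             mu = mu, mu_rate = 600, segments = segs,
             technique = "step_wedge",
             aux = list(junction_z = junction_point[3])))
}

#' Optimize beam segment weights for uniform target dose
#'
#' Nonnegative least squares over all segments of the given beams,
#' minimizing the squared deviation from the prescription over the target
#' voxels.  The optimal objective never exceeds the best uniformly-scaled
#' equal-weights objective.
#'
#' @param beams list of [tbi_beam]s.
#' @param target logical mask (array or logical-valued [tbi_volume]) of
#'   target voxels on `grid`.
#' @param ct CT volume.
#' @param constants a [physics_constants].
#' @param rx prescription dose over the target, Gy.
#' @param grid dose-grid template; defaults to 5 mm isotropic over the CT.
#' @return list with `weights` (normalized, summing to 1 across all
#'   segments), `scale` (total weight returned by the solver), `objective`
#'   and `equal_objective` (sum of squared Gy deviations), and `beams`
#'   with the optimized weights and scaled MU applied.
#' @export
optimize_segment_weights <- function(beams, target, ct,
                                     constants = physics_constants(),
                                     rx = 1, grid = NULL) {
  if (inherits(target, "tbi_volume")) target <- target$values
  nseg_per_beam <- vapply(beams, function(b) length(b$segments), integer(1))
  if (sum(nseg_per_beam) < 1) stop("need at least one segment")
  if (is.null(grid)) grid <- default_dose_grid(ct)

  cols <- list()
  for (b in beams)
    for (s in seq_along(b$segments)) {
      one <- b
      one$segments <- b$segments[s]
      one$segments[[1]]$weight <- 1
      one$mu <- 1
      d <- suppressWarnings(compute_beam_dose(one, ct, constants, grid))
      cols[[length(cols) + 1]] <- d$values[target]
    }
  A <- do.call(cbind, cols)
  bvec <- rep(rx, nrow(A))
  w <- pracma::lsqnonneg(A, bvec)$x
  if (sum(w) <= 0) stop("segment weight optimization collapsed to zero")
  objective <- sum((A %*% w - bvec)^2)
  w_eq <- rep(1, ncol(A))
  s_eq <- sum((A %*% w_eq) * bvec) / sum((A %*% w_eq)^2)
  equal_objective <- sum((A %*% (s_eq * w_eq) - bvec)^2)

  out_beams <- beams
  pos <- 0
  for (bi in seq_along(beams)) {
    wb <- w[pos + seq_len(nseg_per_beam[bi])]
    pos <- pos + nseg_per_beam[bi]
    share <- sum(wb)
    if (share > 0) {
      for (s in seq_along(out_beams[[bi]]$segments))
        out_beams[[bi]]$segments[[s]]$weight <- wb[s] / share
      out_beams[[bi]]$mu <- share  # unit-MU columns: MU carries the scale
    } else out_beams[[bi]]$mu <- 0
  }
  list(weights = w / sum(w), scale = sum(w), objective = objective,
       equal_objective = equal_objective, beams = out_beams)
}
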