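## evaluate a surrogate achieved-dose profile (Gy) at longitudinal
## positions z (mm): rx inside the optimization interval, complementary
## linear ramps across each interior junction, half-voxel rolloff at
## exterior ends
surrogate_profile <- function(z, opt_inf, opt_sup, ramps, rx, ofz, dz) {
  f <- rep(rx, length(z))
  f[z < opt_inf | z > opt_sup] <- 0
  for (r in ramps) {
    width <- 2 * ofz
    if (r$end == "inferior") {
      ## junction [b-ofz, b+ofz]; dose descends to 0 at the inferior
      ## opt-interval end
      base <- rx * pmin(pmax((r$b + ofz - z) / width, 0), 1)
    } else {
      base <- rx * pmin(pmax((z - (r$b - ofz)) / width, 0), 1)
    }
    f <- f - base * (z >= opt_inf & z <= opt_sup)
  }
  ## half-voxel rolloff at non-junction exterior ends
  hr <- dz / 2
  ramp_ends <- vapply(ramps, function(r) r$end, character(1))
  if (!"superior" %in% ramp_ends)
    f <- f * pmin(pmax((opt_sup + hr - z) / hr, 0), 1)
  if (!"inferior" %in% ramp_ends)
    f <- f * pmin(pmax((z - (opt_inf - hr)) / hr, 0), 1)
  pmax(f, 0)
}

#' Idealized achieved dose of a VMAT sub-target (optimizer surrogate)
#'
#' Models the plan the step-wedge base dose forces the optimizer toward,
#' not the optimizer itself: the prescription minus the base dose inside
#' the optimization interval, clipped at zero, and zero outside with a
#' half-voxel linear rolloff.  With the default linear-ramp junction base
#' the surrogate exactly complements its neighbour so their sum is the
#' prescription across the junction.
#'
#' @param subtarget a sub-target from a `tbi_subtargets` (pass the set and
#'   `index`), kind VMAT.
#' @param base_dose optional base `tbi_dose` on `grid` (e.g. a computed
#'   step-wedge dose); `NULL` uses the ideal linear junction ramps at the
#'   sub-target's interior ends.
#' @param rx prescription dose, Gy.
#' @param grid dose-grid template.
#' @param index sub-target index when `subtarget` is a `tbi_subtargets`.
#' @return A `tbi_dose` grid.
#' @export
vmat_surrogate_dose <- function(subtarget, base_dose = NULL, rx, grid,
                                index = NULL) {
  if (inherits(subtarget, "tbi_subtargets"))
    subtarget <- get_subtarget(subtarget, index)
  if (!identical(subtarget$kind, "VMAT"))
    stop("surrogate dose is defined for VMAT sub-targets")
  d <- dim(grid$values)
  cc <- vol_axis_coords(grid)
  ofz <- subtarget$ofz
  if (!is.null(base_dose)) {
    if (!same_grid(base_dose, grid)) stop("base dose grid mismatch")
    inside <- cc$z >= subtarget$opt_inf & cc$z <= subtarget$opt_sup
    base <- base_dose$values
    sel <- rep(inside, each = d[1] * d[2])
    if (any(base[sel] > rx + 1e-9))
      stop("base dose exceeds the prescription inside the optimization interval")
    prof <- surrogate_profile(cc$z, subtarget$opt_inf, subtarget$opt_sup,
                              ramps = list(), rx, ofz, grid$spacing[3])
    vals <- array(rep(prof, each = d[1] * d[2]), dim = d)
    vals[sel] <- pmax(vals[sel] - base[sel], 0)
    return(as_dose(grid, vals))
  }
  ramps <- list()
  if (subtarget$interior_inf)
    ramps <- c(ramps, list(list(end = "inferior", b = subtarget$z_inf)))
  if (subtarget$interior_sup)
    ramps <- c(ramps, list(list(end = "superior", b = subtarget$z_sup)))
  prof <- surrogate_profile(cc$z, subtarget$opt_inf, subtarget$opt_sup,
                            ramps, rx, ofz, grid$spacing[3])
  as_dose(grid, array(rep(prof, each = d[1] * d[2]), dim = d))
}

#' Convert a computed step-wedge dose into a normalized junction base
#'
#' Extracts the wedge's longitudinal profile along the junction point
#' line, normalizes it monotonically to `[0, rx]` across the junction and
#' broadcasts it as a base-dose grid.  This ties the staircase wedge the
#' planning beams actually deliver to the linear base the surrogate
#' complements.
#'
#' @param wedge_dose summed `tbi_dose` of the [make_step_wedge()] beams.
#' @param junction_point mm triple.
#' @param rx prescription, Gy.
#' @param params a [segmentation_params].
#' @return A `tbi_dose` base grid.
#' @export
normalize_wedge_base <- function(wedge_dose, junction_point, rx,
                                 params = segmentation_params()) {
  half <- params$ofz_halfwidth * 10
  cc <- vol_axis_coords(wedge_dose)
  zsel <- cc$z >= junction_point[3] - half & cc$z <= junction_point[3] + half
  line <- vol_interp(as_head_first(wedge_dose),
                     rep(junction_point[1], sum(zsel)),
                     rep(junction_point[2], sum(zsel)), cc$z[zsel], fill = 0)
  if (max(line) <= 0) stop("wedge dose is zero along the junction line")
  prof <- rep(0, length(cc$z))
  prof[zsel] <- line / max(line) * rx
  prof[cc$z < junction_point[3] - half] <- rx  # wedge saturates inferiorly
  prof <- rev(cummax(rev(prof)))               # enforce monotone descent with z
  d <- dim(wedge_dose$values)
  as_dose(wedge_dose, array(rep(prof, each = d[1] * d[2]), dim = d))
}

#' Assemble a whole-body VMAT-TBI plan
#'
#' Creates the beam objects for every sub-target: surrogate split arcs for
#' VMAT sub-targets (one full arc for the head, two pairs for the lung
#' sub-target, one pair elsewhere; 200 MU/min at the lung isocentre,
#' 600 MU/min elsewhere) and feathered AP/PA pairs for the leg/feet
#' sub-targets.  Monitor units per sub-target are set from the
#' water-equivalent mid-depth at its isocentre, with a modulation factor
#' for the intensity-modulated arcs.
#'
#' @param ct whole-body CT ([tbi_volume]).
#' @param structures matching [tbi_structures].
#' @param set `tbi_subtargets` from [divide_ptv()].
#' @param rx_fx prescription per fraction, Gy (1.65 or 1.50 by protocol).
#' @param n_fractions number of fractions (8 by protocol).
#' @param constants a [physics_constants].
#' @param modulation MU inflation factor of modulated arcs relative to
#'   open fields.
#' @param lung_sparing fraction of the prescription the optimizer is
#'   assumed to leave in lung (used when compositing with a lung mask).
#' @return An object of class `tbi_plan`.
#' @export
make_tbi_plan <- function(ct, structures, set, rx_fx = 1.65, n_fractions = 8,
                          constants = physics_constants(), modulation = 3,
                          lung_sparing = 0.7) {
  ct <- as_head_first(ct)
  st <- set$subtargets
  lungs_z <- structures$spec$lung_center_z * 10
  if (is.null(lungs_z)) {
    lungs <- structure_volume(structures, "lungs")
    cc <- vol_axis_coords(lungs)
    sl <- colSums(matrix(lungs$values, prod(dim(lungs$values)[1:2]),
                         dim(lungs$values)[3])) > 0
    lungs_z <- mean(range(cc$z[sl]))
  }
  lung_index <- which(st$z_inf <= lungs_z & lungs_z < st$z_sup)

  mid_wed_cm <- function(iso) {
    cc <- vol_axis_coords(ct)
    i <- which.min(abs(cc$x - iso[1]))
    k <- which.min(abs(cc$z - iso[3]))
    dens <- hu_to_density(ct$values[i, , k], constants)
    sum(dens) * ct$spacing[2] / 10 / 2
  }
  depth_factor <- function(iso, energy) {
    en <- as.character(energy)
    wed <- mid_wed_cm(iso)
    exp(-constants$mu_eff[[en]] *
          max(wed - constants$dmax_cm[[en]], 0))
  }

  beams <- list()
  for (i in seq_len(nrow(st))) {
    sub <- get_subtarget(set, i)
    is_lung <- i %in% lung_index
    if (sub$kind == "VMAT") {
      n_arcs <- if (i == 1) 1L else if (is_lung) 4L else 2L
      mu_st <- modulation * rx_fx /
        (constants$dose_per_mu * depth_factor(sub$iso, 6))
      ramps <- list()
      if (sub$interior_inf)
        ramps <- c(ramps, list(list(end = "inferior", b = sub$z_inf)))
      if (sub$interior_sup)
        ramps <- c(ramps, list(list(end = "superior", b = sub$z_sup)))
      for (a in seq_len(n_arcs)) {
        beams[[length(beams) + 1]] <- tbi_beam(
          sub$iso, gantry = 0, collimator = 90, energy = 6,
          mu = mu_st / n_arcs, mu_rate = if (is_lung) 200 else 600,
          segments = list(beam_segment(sub$opt_inf - sub$iso[3],
                                       sub$opt_sup - sub$iso[3],
                                       -200, 200)),
          technique = "vmat_arc_surrogate",
          aux = list(subtarget_index = i, share = 1 / n_arcs,
                     surrogate = list(opt_inf = sub$opt_inf,
                                      opt_sup = sub$opt_sup,
                                      ramps = ramps, rx = rx_fx,
                                      ofz = sub$ofz)))
      }
    } else {
      mu_each <- rx_fx / (2 * constants$dose_per_mu * depth_factor(sub$iso, 6))
      pair <- make_feathered_appa(set, index = i, mu = mu_each)
      for (b in pair) {
        b$aux$subtarget_index <- i
        b$aux$share <- 1 / 2
        ramps <- list()
        if (sub$interior_inf)
          ramps <- c(ramps, list(list(end = "inferior", b = sub$z_inf)))
        if (sub$interior_sup)
          ramps <- c(ramps, list(list(end = "superior", b = sub$z_sup)))
        b$aux$surrogate <- list(opt_inf = sub$opt_inf, opt_sup = sub$opt_sup,
                                ramps = ramps, rx = rx_fx, ofz = sub$ofz)
        beams[[length(beams) + 1]] <- b
      }
    }
  }
  structure(list(subtargets = set, beams = beams, rx_fx = rx_fx,
                 n_fractions = n_fractions, origin_point = set$origin_point,
                 lung_index = lung_index, modulation = modulation,
                 lung_sparing = lung_sparing,
                 id = sprintf("tbiplan-%d-subtargets", nrow(st))),
            class = "tbi_plan")
}

#' @export
print.tbi_plan <- function(x, ...) {
  cat(sprintf("<tbi_plan> %s: %d beams, rx %.2f Gy x %d fx\n", x$id,
              length(x$beams), x$rx_fx, x$n_fractions))
  invisible(x)
}

## dose of any single beam: engine for deliverable apertures, surrogate
## profile for VMAT arc surrogates
beam_any_dose <- function(beam, ct, constants, grid,
                          appa = c("surrogate", "engine")) {
  appa <- match.arg(appa)
  use_profile <- beam$technique == "vmat_arc_surrogate" ||
    (beam$technique == "feathered_appa" && appa == "surrogate" &&
       !is.null(beam$aux$surrogate))
  if (use_profile) {
    s <- beam$aux$surrogate
    d <- dim(grid$values)
    cc <- vol_axis_coords(grid)
    prof <- surrogate_profile(cc$z, s$opt_inf, s$opt_sup, s$ramps, s$rx,
                              s$ofz, grid$spacing[3])
    share <- beam$aux$share %||% 1
    as_dose(grid, array(rep(prof * share, each = d[1] * d[2]), dim = d))
  } else {
    compute_beam_dose(beam, ct, constants, grid)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Composite plan dose per fraction
#'
#' Sums the per-isocentre contributions: idealized surrogate profiles for
#' the VMAT sub-targets (and, by default, for the AP/PA sub-targets too,
#' giving the analytically checkable composite with complementary linear
#' junction ramps), or the primary-beam engine for the AP/PA pairs when
#' `appa = "engine"`.  When a lung mask is given the lung voxels of every
#' contribution are scaled by the plan's assumed lung sparing.
#'
#' @param plan a `tbi_plan`.
#' @param ct whole-body CT.
#' @param constants a [physics_constants].
#' @param grid dose-grid template; default 5 mm isotropic over the CT.
#' @param appa `"surrogate"` (default) or `"engine"` for the AP/PA
#'   sub-target contributions.
#' @param lung_mask optional logical array on `grid` for lung-sparing
#'   scaling.
#' @return list with `composite` (`tbi_dose`, Gy per fraction) and
#'   `per_iso` (list of `tbi_dose` keyed by sub-target index).
#' @export
compute_plan_dose <- function(plan, ct, constants = physics_constants(),
                              grid = NULL, appa = c("surrogate", "engine"),
                              lung_mask = NULL) {
  appa <- match.arg(appa)
  ct <- as_head_first(ct)
  if (is.null(grid)) grid <- default_dose_grid(ct)
  n_st <- nrow(plan$subtargets$subtargets)
  per_iso <- vector("list", n_st)
  for (b in plan$beams) {
    i <- b$aux$subtarget_index
    d <- beam_any_dose(b, ct, constants, grid, appa = appa)
    per_iso[[i]] <- if (is.null(per_iso[[i]])) d else sum_dose(list(per_iso[[i]], d))
  }
  empty <- as_dose(grid, array(0, dim = dim(grid$values)))
  per_iso <- lapply(per_iso, function(d) if (is.null(d)) empty else d)
  if (!is.null(lung_mask)) {
    if (inherits(lung_mask, "tbi_volume")) lung_mask <- lung_mask$values
    per_iso <- lapply(per_iso, function(d) {
      d$values[lung_mask] <- d$values[lung_mask] * plan$lung_sparing
      d
    })
  }
  list(composite = sum_dose(per_iso), per_iso = per_iso)
}

#' Mean lung dose rate of the lung-isocentre beams
#'
#' Mean lung dose per fraction delivered by the beams at the lung
#' isocentre, divided by their beam-on time (total MU over MU rate), in
#' cGy/min.  Scales inversely with the MU rate, which is why 200 MU/min is
#' used at the lung isocentre.
#'
#' @param plan a `tbi_plan`.
#' @param per_iso per-isocentre dose list from [compute_plan_dose()].
#' @param lung_mask logical lung mask on the dose grid.
#' @param mu_rate optional MU-rate override for the lung beams, MU/min.
#' @return list with `rate_cgy_per_min`, `beam_on_min` and
#'   `lung_dose_cgy`.
#' @export
lung_dose_rate <- function(plan, per_iso, lung_mask, mu_rate = NULL) {
  if (inherits(lung_mask, "tbi_volume")) lung_mask <- lung_mask$values
  if (!length(plan$lung_index)) stop("plan has no lung-isocentre sub-target")
  lung_beams <- Filter(function(b) b$aux$subtarget_index %in% plan$lung_index,
                       plan$beams)
  mus <- vapply(lung_beams, `[[`, numeric(1), "mu")
  rates <- vapply(lung_beams, `[[`, numeric(1), "mu_rate")
  if (!is.null(mu_rate)) rates <- rep(mu_rate, length(rates))
  if (sum(mus) <= 0) stop("lung-isocentre beams have zero MU (zero beam-on time)")
  beam_on <- sum(mus / rates)
  dose_cgy <- 100 * mean(Reduce(`+`, lapply(plan$lung_index, function(i)
    per_iso[[i]]$values))[lung_mask])
  list(rate_cgy_per_min = dose_cgy / beam_on, beam_on_min = beam_on,
       lung_dose_cgy = dose_cgy)
}
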