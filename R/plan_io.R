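#' Invert a beam from the whole-body (head-first) frame to feet-first
#'
#' The feet-first frame is the 180 degree rotation of the patient about
#' the vertical axis through the origin point: x and z are negated about
#' it, y is unchanged.  Delivering the same physical beam to the rotated
#' patient requires the collimator rotated by 180 degrees and the gantry
#' angle mirrored left-right (g -> 360 - g); the isocentre is re-expressed
#' in the feet-first frame.  MU, energy and the segments' dosimetric
#' content are unchanged.  The transform is an involution.
#'
#' @param b a [tbi_beam].
#' @param origin_point mm triple (the pelvis origin point of the plan).
#' @return the inverted [tbi_beam].
#' @export
invert_beam_to_sff <- function(b, origin_point) {
  out <- b
  out$gantry <- (360 - b$gantry) %% 360
  out$collimator <- (b$collimator + 180) %% 360
  out$isocenter <- c(2 * origin_point[1] - b$isocenter[1],
                     b$isocenter[2],
                     2 * origin_point[3] - b$isocenter[3])
  oz <- origin_point[3]
  flipz <- function(z) 2 * oz - z
  aux <- b$aux
  for (pair in list(c("z_inf", "z_sup"), c("opt_inf", "opt_sup"))) {
    if (!is.null(aux[[pair[1]]])) {
      lo <- aux[[pair[1]]]; hi <- aux[[pair[2]]]
      aux[[pair[1]]] <- flipz(hi); aux[[pair[2]]] <- flipz(lo)
    }
  }
  if (!is.null(aux$surrogate)) {
    s <- aux$surrogate
    tmp <- flipz(s$opt_sup); s$opt_sup <- flipz(s$opt_inf); s$opt_inf <- tmp
    s$ramps <- lapply(s$ramps, function(r) {
      r$b <- flipz(r$b)
      r$end <- if (r$end == "inferior") "superior" else "inferior"
      r
    })
    aux$surrogate <- s
  }
  aux$frame <- if (identical(b$aux$frame, "SFF")) "SHF" else "SFF"
  out$aux <- aux
  out
}

#' Split a whole-body plan into head-first and feet-first delivery plans
#'
#' Beams with isocentres superior to the origin point form the head-first
#' (SHF) delivery plan; beams with isocentres inferior to it are inverted
#' with [invert_beam_to_sff()] and form the feet-first (SFF) plan.  An
#' isocentre exactly at the origin z is an error demanding an explicit
#' tie-break, since a silent choice risks double delivery.
#'
#' @param plan a `tbi_plan`.
#' @param origin_point mm triple; defaults to the plan's origin point.
#' @return list with `shf` and `sff` delivery plans (class
#'   `tbi_delivery_plan`), each carrying the planned longitudinal table
#'   shifts between its consecutive isocentres.
#' @export
split_plan <- function(plan, origin_point = plan$origin_point) {
  oz <- origin_point[3]
  iso_z <- vapply(plan$beams, function(b) b$isocenter[3], numeric(1))
  if (any(abs(iso_z - oz) < 1e-6))
    stop("a beam isocentre lies exactly at the origin z; choose a tie-break by moving the origin point")
  sup <- iso_z > oz
  mk <- function(beams, orientation) {
    zs <- unique(vapply(beams, function(b) b$isocenter[3], numeric(1)))
    zs <- sort(zs, decreasing = (orientation == "SHF"))
    structure(list(orientation = orientation, beams = beams,
                   origin_point = origin_point,
                   table_shifts = diff(zs),
                   provenance = plan$id),
              class = "tbi_delivery_plan")
  }
  if (!any(sup)) warning("SHF delivery plan is empty")
  if (all(sup)) warning("SFF delivery plan is empty")
  shf <- mk(plan$beams[sup], "SHF")
  sff <- mk(lapply(plan$beams[!sup], invert_beam_to_sff,
                   origin_point = origin_point), "SFF")
  list(shf = shf, sff = sff)
}

#' @export
print.tbi_delivery_plan <- function(x, ...) {
  cat(sprintf("<tbi_delivery_plan> %s, %d beams, table shifts (mm): %s\n",
              x$orientation, length(x$beams),
              paste(round(x$table_shifts, 1), collapse = ", ")))
  invisible(x)
}

#' Total monitor units of a plan or beam list
#'
#' @param x a `tbi_plan`, `tbi_delivery_plan` or list of beams.
#' @return total MU.
#' @export
total_mu <- function(x) {
  beams <- if (!is.null(x$beams)) x$beams else x
  sum(vapply(beams, `[[`, numeric(1), "mu"))
}

#' Verify delivery-plan dose equivalence with the whole-body plan
#'
#' Recomputes the dose of the head-first beams in the whole-body frame and
#' of the feet-first beams in the feet-first frame (the CT rotated 180
#' degrees about the vertical axis through the origin point), maps the
#' latter back into the whole-body frame, sums both, and compares
#' voxelwise against the whole-body composite.
#'
#' @param whole_dose whole-body composite `tbi_dose` per fraction.
#' @param shf,sff delivery plans from [split_plan()].
#' @param ct whole-body CT.
#' @param constants a [physics_constants].
#' @param tol pass tolerance on the maximum voxel difference, Gy.
#' @param appa dose mode for AP/PA beams (see [compute_plan_dose()]).
#' @return list with `max_abs_diff` (Gy), `tol` and `pass`.
#' @export
verify_equivalence <- function(whole_dose, shf, sff, ct,
                               constants = physics_constants(),
                               tol = 1e-6, appa = "engine") {
  ct <- as_head_first(ct)
  grid <- as_dose(whole_dose, array(0, dim = dim(whole_dose$values)))
  zero <- grid
  acc <- zero
  for (b in shf$beams)
    acc <- sum_dose(list(acc, beam_any_dose(b, ct, constants, grid,
                                            appa = appa)))
  if (length(sff$beams)) {
    op <- sff$origin_point
    ct_sff <- rotate_about_vertical(ct, op)
    grid_sff <- rotate_about_vertical(zero, op)
    acc_sff <- grid_sff
    for (b in sff$beams)
      acc_sff <- sum_dose(list(acc_sff, beam_any_dose(b, ct_sff, constants,
                                                      grid_sff, appa = appa)))
    mapped <- rotate_about_vertical(acc_sff, op)
    if (!identical(dim(mapped$values), dim(acc$values)))
      stop("frame mapping failed: rotated dose grid does not align")
    acc$values <- acc$values + mapped$values
  }
  max_abs_diff <- max(abs(acc$values - whole_dose$values))
  list(max_abs_diff = max_abs_diff, tol = tol, pass = max_abs_diff <= tol)
}

## serialize beams (without block masks) for plan JSON
beam_to_list <- function(b) {
  list(isocenter = b$isocenter, gantry = b$gantry, collimator = b$collimator,
       energy = b$energy, sad = b$sad, mu = b$mu, mu_rate = b$mu_rate,
       technique = b$technique,
       segments = lapply(b$segments, function(s)
         list(x1 = s$x1, x2 = s$x2, y1 = s$y1, y2 = s$y2,
              weight = s$weight)),
       aux = b$aux)
}

beam_from_list <- function(l) {
  segs <- lapply(l$segments, function(s)
    beam_segment(s$x1, s$x2, s$y1, s$y2, s$weight))
  aux <- l$aux
  if (!is.null(aux$surrogate)) {
    aux$surrogate <- lapply(aux$surrogate, identity)
    aux$surrogate$ramps <- lapply(aux$surrogate$ramps, as.list)
  }
  tbi_beam(unlist(l$isocenter), l$gantry, l$collimator, l$energy, l$sad,
           l$mu, l$mu_rate, segs, l$technique, aux = aux)
}

#' Write a plan to the documented JSON schema
#'
#' Beams with their segments, MU, isocentres and technique tags; block
#' shadow masks are not serialized (they are re-derived from the
#' structures when needed).
#'
#' @param plan a `tbi_plan` or `tbi_delivery_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  payload <- list(class = class(plan)[1],
                  orientation = plan$orientation,
                  rx_fx = plan$rx_fx, n_fractions = plan$n_fractions,
                  origin_point = plan$origin_point,
                  table_shifts = plan$table_shifts,
                  id = plan$id %||% plan$provenance,
                  beams = lapply(plan$beams, beam_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a plan written by [write_plan]
#'
#' @param path JSON path.
#' @return a list with the plan fields and reconstructed beams.
#' @export
read_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  beams <- lapply(p$beams, beam_from_list)
  out <- list(orientation = p$orientation, rx_fx = p$rx_fx,
              n_fractions = p$n_fractions,
              origin_point = unlist(p$origin_point),
              table_shifts = unlist(p$table_shifts),
              id = p$id, beams = beams)
  class(out) <- p$class
  out
}
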