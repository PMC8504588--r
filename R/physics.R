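#' Machine and physics constants for the primary-beam dose engine
#'
#' The engine is a transparent primary-only model: dose follows
#' inverse-square from the source times exponential attenuation in
#' water-equivalent depth, with a linear build-up ramp to `dmax`.  The
#' defaults below are engineering values chosen for plausibility at
#' megavoltage energies; they are configurable because the toolkit's
#' contributions are geometric and compositional, not dosimetric.
#'
#' @param mu_eff named water-equivalent effective attenuation per energy,
#'   1/cm (names `"6"` and `"10"` MV).
#' @param dmax_cm named build-up depth per energy, cm.
#' @param lung_density relative electron density used for lung voxels.
#' @param cerrobend_density block alloy density, g/cm^3.
#' @param mu_cerrobend effective block attenuation, 1/cm.
#' @param lucite_density spoiler density, g/cm^3.
#' @param spoiler_thickness_cm physical spoiler thickness, cm.
#' @param dose_per_mu calibration, Gy per MU at `dmax` on axis at the
#'   source-axis distance.
#' @param hu_soft,hu_air HU thresholds separating soft tissue / lung / air.
#' @return An object of class `physics_constants`.
#' @export
physics_constants <- function(mu_eff = c("6" = 0.049, "10" = 0.044),
                              dmax_cm = c("6" = 1.5, "10" = 2.5),
                              lung_density = 0.3,
                              cerrobend_density = 9.4,
                              mu_cerrobend = 0.5,
                              lucite_density = 1.18,
                              spoiler_thickness_cm = 1,
                              dose_per_mu = 0.01,
                              hu_soft = -350, hu_air = -900) {
  pc <- list(mu_eff = mu_eff, dmax_cm = dmax_cm, lung_density = lung_density,
             cerrobend_density = cerrobend_density,
             mu_cerrobend = mu_cerrobend, lucite_density = lucite_density,
             spoiler_thickness_cm = spoiler_thickness_cm,
             dose_per_mu = dose_per_mu, hu_soft = hu_soft, hu_air = hu_air)
  num <- unlist(pc[c("mu_eff", "dmax_cm", "lung_density", "cerrobend_density",
                     "mu_cerrobend", "lucite_density", "spoiler_thickness_cm",
                     "dose_per_mu")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("physics constants must be positive and finite")
  class(pc) <- "physics_constants"
  pc
}

#' Read physics constants from a YAML or JSON config file
#'
#' Fields present in the file override the defaults of
#' [physics_constants()].
#'
#' @param path config path ending in `.yaml`, `.yml` or `.json`.
#' @return An object of class `physics_constants`.
#' @export
read_physics_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- physics_constants()
  for (nm in intersect(names(cfg), names(unclass(defaults)))) {
    v <- cfg[[nm]]
    if (!is.null(names(defaults[[nm]])) && is.list(v)) v <- unlist(v)
    if (!is.null(names(defaults[[nm]])) && is.null(names(v)))
      names(v) <- names(defaults[[nm]])
    defaults[[nm]] <- v
  }
  do.call(physics_constants, unclass(defaults))
}

## HU -> relative electron density with a lung override
hu_to_density <- function(hu, constants) {
  dens <- ifelse(hu >= constants$hu_soft, 1,
                 ifelse(hu > constants$hu_air, constants$lung_density, 0))
  dens
}
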