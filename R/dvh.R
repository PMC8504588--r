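#' Dose-volume histogram metrics for a structure
#'
#' `Vx` is the percentage of the structure's voxels receiving at least
#' `x`% of the prescription dose; `Dmean` is the mean structure dose in
#' Gy.  `Vx` is nonincreasing in `x`; `V110` is a hotspot metric.
#'
#' @param dose a `tbi_dose` grid, Gy.
#' @param mask logical array (or logical-valued [tbi_volume]) on the same
#'   grid.
#' @param rx prescription dose, Gy.
#' @param levels percentages at which to evaluate `Vx`.
#' @return An object of class `dvh_metrics`: named `V<level>` percentages
#'   plus `Dmean` (Gy).
#' @export
compute_dvh <- function(dose, mask, rx, levels = c(90, 95, 100, 110)) {
  if (inherits(mask, "tbi_volume")) {
    if (!same_grid(dose, mask)) stop("dose and mask grids are misaligned")
    mask <- mask$values
  }
  if (!identical(dim(mask), dim(dose$values)))
    stop("dose and mask grids are misaligned")
  vals <- dose$values[mask]
  if (!length(vals)) stop("structure mask is empty")
  out <- vapply(levels, function(x) 100 * mean(vals >= x / 100 * rx),
                numeric(1))
  names(out) <- paste0("V", levels)
  res <- as.list(out)
  res$Dmean <- mean(vals)
  res$rx <- rx
  res$n_voxels <- length(vals)
  class(res) <- "dvh_metrics"
  res
}

#' @export
print.dvh_metrics <- function(x, ...) {
  vx <- unlist(x[grep("^V", names(x))])
  cat("<dvh_metrics>",
      paste(sprintf("%s=%.1f%%", names(vx), vx), collapse = " "),
      sprintf(" Dmean=%.2f Gy (rx %.2f Gy, %d voxels)\n",
              x$Dmean, x$rx, x$n_voxels))
  invisible(x)
}
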