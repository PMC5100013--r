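# Zonation: division-zone delineation from brightness, cell production rate
# from velocity and cell lengths, and the flux-conservation diagnostic.

#' Delineate the division zone end from a brightness profile
#'
#' The division zone ends where the longitudinal near-infrared brightness
#' drops below a fraction (default 70%) of its maximum. The profile is first
#' smoothed with a moving average of width `smooth_window` (mm) so that
#' single-sample dips cannot trigger the rule; the crossing is located by
#' linear interpolation between the bracketing samples.
#'
#' @param brightness A [brightness_profile()].
#' @param threshold_fraction Fraction of the maximum, in (0, 1); default 0.70.
#' @param smooth_window Moving-average width (mm); default 0.2. Use 0 to skip
#'   smoothing.
#' @return An object of class `zone_boundaries`: list with `dz_length` (mm),
#'   `dz_end_crossing_value` (the threshold fraction), and `brightness_max`.
#' @export
detect_dz_end <- function(brightness, threshold_fraction = 0.70,
                          smooth_window = 0.2) {
  stopifnot(inherits(brightness, "brightness_profile"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("`threshold_fraction` must be in (0, 1)", call. = FALSE)
  }
  x <- brightness$position_mm
  b <- brightness$brightness
  if (length(x) < 5L) stop("brightness profile too short", call. = FALSE)
  if (smooth_window > 0) {
    k <- round(smooth_window / stats::median(diff(x)))
    b <- running_mean(b, k)
  }
  imax <- which.max(b)
  if (imax == length(b)) {
    warning("brightness maximum at the last position: profile rises ",
            "monotonically, boundary is suspicious", call. = FALSE)
  }
  thr <- threshold_fraction * b[imax]
  j <- which(b < thr & seq_along(b) > imax)
  if (!length(j)) {
    stop("no boundary: brightness never falls below the threshold", call. = FALSE)
  }
  j <- j[1]
  dz <- x[j - 1L] + (b[j - 1L] - thr) / (b[j - 1L] - b[j]) * (x[j] - x[j - 1L])
  structure(list(dz_length = dz,
                 dz_end_crossing_value = threshold_fraction,
                 brightness_max = b[imax]),
            class = "zone_boundaries")
}

#' @export
print.zone_boundaries <- function(x, ...) {
  cat(sprintf("Division zone end at %.4g mm (brightness %.0f%% crossing)\n",
              x$dz_length, 100 * x$dz_end_crossing_value))
  invisible(x)
}

#' Mean cell length in the apical meristem
#'
#' Arithmetic mean of the measured cell lengths at positions within the
#' division zone (`position <= dz_length`), the denominator of the cell
#' production rate. Requires at least 5 cells in range.
#'
#' @param cells A [cell_length_profile()].
#' @param dz_length Division zone length (mm).
#' @param range Optional sub-range `c(lo, hi)` (mm) to average over instead
#'   of `[0, dz_length]`.
#' @return Mean cell length (micrometres).
#' @export
mean_meristem_cell_length <- function(cells, dz_length, range = NULL) {
  stopifnot(inherits(cells, "cell_length_profile"))
  stopifnot_scalar(dz_length, "dz_length", positive = TRUE)
  if (is.null(range)) range <- c(0, dz_length)
  sel <- cells$position_mm >= range[1] & cells$position_mm <= range[2]
  if (sum(sel) < 5L) {
    stop(sprintf("insufficient data: only %d cells measured within [%.3g, %.3g] mm (need >= 5)",
                 sum(sel), range[1], range[2]), call. = FALSE)
  }
  mean(cells$cell_length_um[sel])
}

#' Cell production rate of the meristem
#'
#' The number of cells leaving the meristem per unit time: the velocity at
#' the division zone end (linear interpolation on the smoothed profile,
#' converted to um h^-1) divided by the mean meristem cell length.
#'
#' @param velocity A (smoothed) [velocity_profile()].
#' @param dz_length Division zone length (mm), within the profile's support.
#' @param mean_cell_length Mean meristem cell length (um), > 0.
#' @return Cell production rate (cells h^-1).
#' @export
cell_production_rate <- function(velocity, dz_length, mean_cell_length) {
  stopifnot(inherits(velocity, "velocity_profile"))
  stopifnot_scalar(mean_cell_length, "mean_cell_length", positive = TRUE)
  x <- velocity$position_mm
  if (dz_length < min(x) || dz_length > max(x)) {
    stop(sprintf("dz_length (%.3g mm) outside the velocity profile support [%.3g, %.3g]",
                 dz_length, min(x), max(x)), call. = FALSE)
  }
  v_dz <- stats::approx(x, velocity$velocity_mm_per_h, xout = dz_length)$y
  v_dz * 1000 / mean_cell_length
}

#' Cell flux profile and steadiness diagnostic
#'
#' Under steady growth with no division beyond the division zone, the cell
#' flux `v(x) / l(x)` is constant for `x > dz_length` and equals the cell
#' production rate. This function computes the flux over the overlapping
#' support of the two profiles (velocity interpolated at the cell-profile
#' positions) and reports the coefficient of variation of the flux beyond the
#' DZ as a steadiness diagnostic.
#'
#' @param velocity A [velocity_profile()].
#' @param cells A [cell_length_profile()].
#' @param dz_length Division zone length (mm).
#' @param cv_bound Steadiness bound on the flux CV beyond the DZ; default 0.05.
#' @return List of class `cell_flux_profile`: `position_mm`, `flux_cells_per_h`,
#'   `cv_beyond_dz`, `steady` (logical).
#' @export
cell_flux_profile <- function(velocity, cells, dz_length, cv_bound = 0.05) {
  stopifnot(inherits(velocity, "velocity_profile"),
            inherits(cells, "cell_length_profile"))
  lo <- max(min(velocity$position_mm), min(cells$position_mm))
  hi <- min(max(velocity$position_mm), max(cells$position_mm))
  if (lo >= hi) stop("velocity and cell-length profiles do not overlap", call. = FALSE)
  sel <- cells$position_mm >= lo & cells$position_mm <= hi
  x <- cells$position_mm[sel]
  v <- stats::approx(velocity$position_mm, velocity$velocity_mm_per_h, xout = x)$y
  flux <- v * 1000 / cells$cell_length_um[sel]
  beyond <- x > dz_length
  cv <- if (sum(beyond) >= 2L) {
    stats::sd(flux[beyond]) / mean(flux[beyond])
  } else NA_real_
  structure(list(position_mm = x, flux_cells_per_h = flux,
                 cv_beyond_dz = cv,
                 steady = isTRUE(cv < cv_bound)),
            class = "cell_flux_profile")
}

#' @export
print.cell_flux_profile <- function(x, ...) {
  cat(sprintf("Cell flux profile over [%.3g, %.3g] mm; CV beyond DZ = %.3g (%s)\n",
              min(x$position_mm), max(x$position_mm), x$cv_beyond_dz,
              if (isTRUE(x$steady)) "steady" else "not steady"))
  invisible(x)
}
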