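# Position-indexed profile containers. All profiles are data frames indexed
# by distance from the quiescent center (mm, ascending), with a class tag and
# a few attributes; they print and subset like data frames.

new_profile <- function(position, value, value_name, class_name,
                        root_id = NA_character_, time_label = NA_character_) {
  if (length(position) != length(value)) {
    stop("position and value lengths differ", call. = FALSE)
  }
  if (any(!is.finite(position))) stop("positions must be finite", call. = FALSE)
  if (is.unsorted(position, strictly = TRUE)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  df <- data.frame(position_mm = position, value = value)
  names(df)[2] <- value_name
  structure(df, class = c(class_name, "data.frame"),
            root_id = root_id, time_label = time_label)
}

#' Velocity profile container
#'
#' Material velocity away from the quiescent center (mm h^-1) as a function of
#' position (mm from the QC, strictly increasing, >= 0).
#'
#' @param position Positions (mm from QC), strictly increasing, >= 0.
#' @param velocity Velocities (mm h^-1).
#' @param n_obs Optional observation count per position (from PIV binning).
#' @param root_id,time_label Optional identifiers carried as attributes.
#' @return A data frame of class `velocity_profile` with columns
#'   `position_mm`, `velocity_mm_per_h` (and `n_obs` if given).
#' @export
velocity_profile <- function(position, velocity, n_obs = NULL,
                             root_id = NA_character_, time_label = NA_character_) {
  if (any(position < 0)) stop("positions must be >= 0", call. = FALSE)
  p <- new_profile(position, velocity, "velocity_mm_per_h", "velocity_profile",
                   root_id, time_label)
  if (!is.null(n_obs)) p$n_obs <- n_obs
  p
}

#' EER profile container
#'
#' Elemental elongation rate (strain rate, h^-1) along the root axis.
#'
#' @param position Positions (mm from QC), strictly increasing.
#' @param strain_rate Strain rates (h^-1), finite.
#' @return A data frame of class `eer_profile` with columns `position_mm`,
#'   `eer_per_h`.
#' @export
eer_profile <- function(position, strain_rate) {
  if (any(!is.finite(strain_rate))) stop("strain rates must be finite", call. = FALSE)
  new_profile(position, strain_rate, "eer_per_h", "eer_profile")
}

#' Brightness profile container
#'
#' Longitudinal near-infrared brightness (arbitrary units >= 0) used to
#' delineate the division zone.
#'
#' @param position Positions (mm from QC), strictly increasing.
#' @param brightness Brightness values (a.u.), max > 0.
#' @return A data frame of class `brightness_profile`.
#' @export
brightness_profile <- function(position, brightness) {
  if (max(brightness) <= 0) stop("max brightness must be > 0", call. = FALSE)
  new_profile(position, brightness, "brightness", "brightness_profile")
}

#' Cell length profile container
#'
#' Cortical cell length (micrometres, > 0) along the root axis.
#'
#' @param position Positions (mm from QC), strictly increasing.
#' @param cell_length Cell lengths (um), > 0.
#' @return A data frame of class `cell_length_profile`.
#' @export
cell_length_profile <- function(position, cell_length) {
  if (any(cell_length <= 0)) stop("cell lengths must be > 0", call. = FALSE)
  new_profile(position, cell_length, "cell_length_um", "cell_length_profile")
}

#' Simulate a noisy velocity profile from a growth field
#'
#' Evaluates the analytic velocity (the cumulative integral of the EER field,
#' see [field_velocity()]) at the requested positions and adds i.i.d.
#' Gaussian measurement noise. In the QC frame the noiseless velocity at
#' position 0 is exactly 0.
#'
#' @inheritParams eval_eer_field
#' @param noise_sd Gaussian noise standard deviation (mm h^-1), >= 0.
#' @param seed RNG seed (explicit; the caller's random state is untouched).
#' @return A [velocity_profile()].
#' @export
simulate_velocity_profile <- function(spec, x, t = 0, noise_sd = 0, seed = NULL) {
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (is.unsorted(x, strictly = TRUE)) {
    stop("`x` must be sorted strictly ascending", call. = FALSE)
  }
  v <- field_velocity(spec, x, t)
  if (noise_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(x), 0, noise_sd))
  }
  velocity_profile(x, v)
}

# Longitudinal brightness envelope: full brightness over the division zone,
# logistic decay beyond it crossing exactly `threshold` (default 70% of the
# plateau) at x = dz_length, and a floor so mature tissue keeps some texture
# contrast. Shared between the profile simulator and the image renderer so
# both agree on the ground-truth crossing.
brightness_envelope <- function(x, dz_length, threshold = 0.7, floor = 0.25,
                                slope_mm = 0.15) {
  frac <- (threshold - floor) / (1 - floor)
  centre <- dz_length + slope_mm * log(frac / (1 - frac))
  floor + (1 - floor) / (1 + exp((x - centre) / slope_mm))
}

#' Simulate a brightness profile from a growth field
#'
#' A plateau over the division zone followed by a logistic decay whose 70%
#' crossing sits exactly at the spec's `dz_length` (the functional form is a
#' modelling choice; only the threshold rule comes from the delineation
#' method). Additive Gaussian noise, in units of the plateau value.
#'
#' @inheritParams simulate_velocity_profile
#' @param scale Plateau brightness (arbitrary units).
#' @param noise_sd Additive Gaussian noise sd, as a fraction of `scale`.
#' @return A [brightness_profile()] with attribute `true_dz_length`.
#' @export
simulate_brightness_profile <- function(spec, x, noise_sd = 0, scale = 100,
                                        seed = NULL) {
  stopifnot(inherits(spec, "growth_field_spec"))
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  b <- scale * brightness_envelope(x, spec$dz_length)
  if (noise_sd > 0) {
    b <- b + with_seed(seed, stats::rnorm(length(x), 0, noise_sd * scale))
  }
  out <- brightness_profile(x, pmax(b, 0))
  attr(out, "true_dz_length") <- spec$dz_length
  out
}

#' Simulate a steady-state cell length profile
#'
#' Under steady growth with no division beyond the division zone, the cell
#' flux `F = v(x) / l(x)` (cells h^-1) is conserved along the axis, so the
#' cell length profile follows from the velocity field: cells keep the
#' meristem length up to the DZ end and then stretch as `l(x) = v(x) / F`
#' with `F = v(dz_length) / meristem_cell_length`. Multiplicative log-normal
#' noise with coefficient of variation `noise_cv` emulates measurement
#' scatter in sectioned material.
#'
#' @inheritParams simulate_velocity_profile
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @return A [cell_length_profile()] with attribute `true_flux` (cells h^-1).
#' @export
simulate_cell_length_profile <- function(spec, x, noise_cv = 0, seed = NULL) {
  stopifnot(inherits(spec, "growth_field_spec"))
  stopifnot_scalar(noise_cv, "noise_cv", nonneg = TRUE)
  v_dz <- field_velocity(spec, spec$dz_length)
  if (v_dz <= .Machine$double.eps) {
    stop("degenerate growth field: velocity at the DZ end is 0", call. = FALSE)
  }
  flux <- v_dz * 1000 / spec$meristem_cell_length  # cells h^-1
  l <- ifelse(x <= spec$dz_length,
              spec$meristem_cell_length,
              field_velocity(spec, x) * 1000 / flux)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    l <- l * with_seed(seed, stats::rlnorm(length(x), -sdlog^2 / 2, sdlog))
  }
  out <- cell_length_profile(x, l)
  attr(out, "true_flux") <- flux
  out
}
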