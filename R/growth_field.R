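#' Ground-truth growth field specification
#'
#' Defines a parametric elemental elongation rate (EER) field along the root
#' axis, in the quiescent-center (QC) frame: position `x` is the distance from
#' the QC in mm, strain rates are in h^-1. The field is unimodal, non-negative,
#' and identically zero beyond the growth zone (`x >= gz_length`). It is the
#' single source of truth for all kinematic phantoms: velocity profiles, image
#' sequences, brightness and cell-length profiles are all derived from it, so
#' every downstream estimate can be checked against known values.
#'
#' Three shapes are available. `"triangular"` rises linearly from 0 at the QC
#' to `eer_max` at `x_peak` and falls linearly to 0 at `gz_length`; its
#' velocity integral is piecewise quadratic and closed-form, which anchors
#' exact tests. `"beta-kernel"` is a C^1 unimodal kernel proportional to a
#' beta density on `[0, gz_length]` with its mode at `x_peak` (concentration
#' controlled by `beta_concentration`); it is the default because it exercises
#' the smoothing spline with a realistic smooth profile. `"gaussian-windowed"`
#' is a Gaussian bump centred at `x_peak`, shifted and clipped so that it
#' reaches exactly zero at `gz_length`.
#'
#' An optional step-stress scenario rescales the whole field over time: growth
#' collapses at stress onset, recovers through a damped oscillation passing
#' through a maximum (default near 45 min), and settles on a new steady state
#' (a fixed scaled copy of the control field, default 50% of it) from
#' `t_steady` onwards. See [step_stress_scenario()].
#'
#' @param eer_max Peak strain rate (h^-1), >= 0 (0 yields a static root,
#'   useful as a no-growth phantom).
#' @param x_peak Abscissa of the EER peak (mm from the QC), in (0, gz_length).
#' @param gz_length Growth zone length (mm): EER is 0 at and beyond it.
#' @param dz_length Division zone length (mm), in (0, gz_length).
#' @param shape One of `"beta-kernel"`, `"triangular"`, `"gaussian-windowed"`.
#' @param meristem_cell_length Mean cell length in the meristem (micrometres).
#' @param stress_scenario `NULL` for a steady control field, or the result of
#'   [step_stress_scenario()].
#' @param beta_concentration Concentration of the beta kernel (larger =
#'   narrower peak); only used by `shape = "beta-kernel"`.
#' @return An object of class `growth_field_spec`.
#' @examples
#' spec <- growth_field_spec(eer_max = 0.3, x_peak = 3, gz_length = 6,
#'                           dz_length = 1.5, shape = "triangular")
#' eval_eer_field(spec, x = c(0, 3, 7))
#' field_velocity(spec, x = 10)  # total growth rate 0.9 mm/h
#' @export
growth_field_spec <- function(eer_max = 0.3, x_peak = 2.5, gz_length = 6,
                              dz_length = 1.5,
                              shape = c("beta-kernel", "triangular",
                                        "gaussian-windowed"),
                              meristem_cell_length = 10,
                              stress_scenario = NULL,
                              beta_concentration = 4) {
  shape <- match.arg(shape)
  stopifnot_scalar(eer_max, "eer_max", nonneg = TRUE)
  stopifnot_scalar(x_peak, "x_peak", positive = TRUE)
  stopifnot_scalar(gz_length, "gz_length", positive = TRUE)
  stopifnot_scalar(dz_length, "dz_length", positive = TRUE)
  stopifnot_scalar(meristem_cell_length, "meristem_cell_length", positive = TRUE)
  if (x_peak >= gz_length) stop("`x_peak` must lie inside (0, gz_length)", call. = FALSE)
  if (dz_length >= gz_length) stop("`dz_length` must be < `gz_length`", call. = FALSE)
  if (!is.null(stress_scenario) && !inherits(stress_scenario, "stress_scenario")) {
    stop("`stress_scenario` must be NULL or a step_stress_scenario()", call. = FALSE)
  }
  structure(list(eer_max = eer_max, x_peak = x_peak, gz_length = gz_length,
                 dz_length = dz_length, shape = shape,
                 meristem_cell_length = meristem_cell_length,
                 stress_scenario = stress_scenario,
                 beta_concentration = beta_concentration),
            class = "growth_field_spec")
}

#' @export
print.growth_field_spec <- function(x, ...) {
  cat("Growth field spec (", x$shape, ")\n", sep = "")
  cat(sprintf("  EER_max %.3g h^-1 at %.3g mm; GZ %.3g mm; DZ %.3g mm\n",
              x$eer_max, x$x_peak, x$gz_length, x$dz_length))
  cat(sprintf("  meristem cell length %.3g um; growth rate %.4g mm/h\n",
              x$meristem_cell_length, field_velocity(x, x$gz_length)))
  if (!is.null(x$stress_scenario)) {
    s <- x$stress_scenario
    cat(sprintf("  step stress: new steady state %.0f%% of control from t = %.2g h\n",
                100 * s$scale, s$t_onset + s$t_steady))
  }
  invisible(x)
}

#' Draw a random growth field specification
#'
#' Samples a [growth_field_spec()] from ranges representative of vigorously
#' growing root apices: peak strain rate 0.2-0.4 h^-1, growth zone 4.5-6 mm
#' with the peak at 35-65% of it, division zone 1.2-1.9 mm, meristem cell
#' length 8-14 um, and a shape drawn uniformly from the three kernels. The
#' implied whole-root growth rates span roughly 0.4-1.2 mm h^-1.
#'
#' @param seed RNG seed.
#' @return A [growth_field_spec()].
#' @export
random_growth_field_spec <- function(seed) {
  with_seed(seed, {
    gz <- stats::runif(1, 4.5, 6)
    growth_field_spec(
      eer_max = stats::runif(1, 0.2, 0.4),
      x_peak = stats::runif(1, 0.35, 0.65) * gz,
      gz_length = gz,
      dz_length = stats::runif(1, 1.2, 1.9),
      shape = sample(c("beta-kernel", "triangular", "gaussian-windowed"), 1),
      meristem_cell_length = stats::runif(1, 8, 14))
  })
}

#' Step-stress scenario for a growth field
#'
#' Describes a two-phase response of the growth field to an osmotic step: an
#' abrupt collapse at stress onset, a transient recovery with a damped
#' oscillation passing through a maximum near `t_peak`, and a new steady state
#' equal to `scale` times the control field for all `t >= t_onset + t_steady`
#' (exactly: the transient term is tapered to zero at `t_steady`). The default
#' `scale = 0.5` emulates the halving of the peak elongation rate under
#' moderate osmotic stress; the transient's magnitude and form are
#' illustrative, not calibrated.
#'
#' @param scale Steady-state multiplier of the control field, in (0, 1].
#' @param t_onset Stress onset time (h).
#' @param t_peak Time after onset of the transient maximum (h); default 0.75.
#' @param t_steady Time after onset at which the new steady state is reached
#'   (h); default 2.
#' @param dip Field multiplier immediately after onset (fraction of control).
#' @param damping Exponential time constant of the transient (h).
#' @return An object of class `stress_scenario`.
#' @export
step_stress_scenario <- function(scale = 0.5, t_onset = 0, t_peak = 0.75,
                                 t_steady = 2, dip = 0.15, damping = 0.6) {
  stopifnot_scalar(scale, "scale", positive = TRUE)
  stopifnot_scalar(t_peak, "t_peak", positive = TRUE)
  stopifnot_scalar(t_steady, "t_steady", positive = TRUE)
  stopifnot_scalar(dip, "dip", nonneg = TRUE)
  if (scale > 1) stop("`scale` must be <= 1", call. = FALSE)
  if (t_peak >= t_steady) stop("`t_peak` must be < `t_steady`", call. = FALSE)
  structure(list(scale = scale, t_onset = t_onset, t_peak = t_peak,
                 t_steady = t_steady, dip = dip, damping = damping),
            class = "stress_scenario")
}

#' Time course multiplier of a stressed growth field
#'
#' Returns the scalar factor by which the control EER field is multiplied at
#' time `t`: 1 before onset, the transient during `[t_onset, t_onset +
#' t_steady)`, and exactly `scale` afterwards.
#'
#' @param scenario A [step_stress_scenario()], or `NULL` (always 1).
#' @param t Times (h); vectorised.
#' @return Numeric vector of multipliers, same length as `t`.
#' @export
stress_multiplier <- function(scenario, t) {
  if (is.null(scenario)) return(rep(1, length(t)))
  stopifnot(inherits(scenario, "stress_scenario"))
  u <- t - scenario$t_onset
  out <- rep(1, length(t))
  post <- u >= 0
  out[post] <- scenario$scale
  trans <- post & u < scenario$t_steady
  if (any(trans)) {
    ut <- u[trans]
    taper <- 1 - ut / scenario$t_steady
    osc <- cos(pi * ut / scenario$t_peak) * exp(-ut / scenario$damping)
    out[trans] <- scenario$scale +
      (scenario$dip - scenario$scale) * osc * taper
  }
  pmax(out, 0)
}

beta_kernel_params <- function(spec) {
  m <- spec$x_peak / spec$gz_length
  k <- spec$beta_concentration
  list(a = 1 + m * k, b = 1 + (1 - m) * k, m = m)
}

#' Evaluate the elemental elongation rate field
#'
#' Deterministic, closed-form evaluation of EER(x, t) for a
#' [growth_field_spec()]. Positions at or beyond the growth zone return 0;
#' the stress scenario (if any) rescales the whole field in time.
#'
#' @param spec A [growth_field_spec()].
#' @param x Positions (mm from the QC), >= 0; vectorised.
#' @param t Time (h); a scalar or a vector the same length as `x`.
#' @return Strain rates (h^-1), same length as `x`.
#' @export
eval_eer_field <- function(spec, x, t = 0) {
  stopifnot(inherits(spec, "growth_field_spec"))
  if (any(!is.finite(x)) || any(x < 0)) stop("`x` must be finite and >= 0", call. = FALSE)
  if (!(length(t) == 1L || length(t) == length(x))) {
    stop("`t` must be scalar or match `x` in length", call. = FALSE)
  }
  gz <- spec$gz_length; mu <- spec$x_peak; emax <- spec$eer_max
  e <- switch(spec$shape,
    "triangular" = {
      up <- x <= mu
      v <- numeric(length(x))
      v[up] <- emax * x[up] / mu
      v[!up] <- emax * pmax(0, (gz - x[!up]) / (gz - mu))
      v
    },
    "gaussian-windowed" = {
      sigma <- (gz - mu) / 2.5
      cc <- exp(-2.5^2 / 2)
      raw <- (exp(-(x - mu)^2 / (2 * sigma^2)) - cc) / (1 - cc)
      emax * pmax(0, raw) * as.numeric(x < gz)
    },
    "beta-kernel" = {
      p <- beta_kernel_params(spec)
      z <- x / gz
      v <- numeric(length(x))
      inside <- z > 0 & z < 1
      v[inside] <- emax * stats::dbeta(z[inside], p$a, p$b) /
        stats::dbeta(p$m, p$a, p$b)
      v
    },
    stop(sprintf("unknown EER field shape '%s'", spec$shape), call. = FALSE)
  )
  e * stress_multiplier(spec$stress_scenario, t)
}

#' Analytic velocity profile of a growth field
#'
#' The material velocity away from the QC is the cumulative spatial integral
#' of the EER field, `v(x) = integral of EER(s, t) ds from 0 to x`; this is
#' the exact inverse of differentiating a velocity profile to obtain EER.
#' Computed in closed form for all three field shapes (piecewise quadratic,
#' Gaussian error function, and regularized incomplete beta respectively).
#' `v(gz_length)` (equivalently `v(Inf)`) is the whole-root growth rate.
#'
#' @inheritParams eval_eer_field
#' @return Velocities (mm h^-1), same length as `x`.
#' @export
field_velocity <- function(spec, x, t = 0) {
  stopifnot(inherits(spec, "growth_field_spec"))
  if (!(length(t) == 1L || length(t) == length(x))) {
    stop("`t` must be scalar or match `x` in length", call. = FALSE)
  }
  gz <- spec$gz_length; mu <- spec$x_peak; emax <- spec$eer_max
  xc <- pmin(pmax(x, 0), gz)
  v <- switch(spec$shape,
    "triangular" = {
      vtot <- emax * gz / 2
      ifelse(xc <= mu,
             emax * xc^2 / (2 * mu),
             vtot - emax * (gz - xc)^2 / (2 * (gz - mu)))
    },
    "gaussian-windowed" = {
      sigma <- (gz - mu) / 2.5
      cc <- exp(-2.5^2 / 2)
      x0 <- max(0, 2 * mu - gz)  # left end of the positive support
      xs <- pmax(xc, x0)
      gauss_part <- sigma * sqrt(2 * pi) *
        (stats::pnorm((xs - mu) / sigma) - stats::pnorm((x0 - mu) / sigma))
      emax / (1 - cc) * (gauss_part - cc * (xs - x0))
    },
    "beta-kernel" = {
      p <- beta_kernel_params(spec)
      emax * gz * stats::pbeta(xc / gz, p$a, p$b) / stats::dbeta(p$m, p$a, p$b)
    },
    stop(sprintf("unknown EER field shape '%s'", spec$shape), call. = FALSE)
  )
  v * stress_multiplier(spec$stress_scenario, t)
}
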