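# Kinematics: spline smoothing of velocity profiles, differentiation to the
# elemental elongation rate, and growth trait extraction.

#' Smooth a velocity profile with a cubic smoothing spline
#'
#' Fits `stats::smooth.spline` to the raw profile (default `spar = 0.5`) and
#' evaluates it on a uniform position grid. The fitted spline is carried as
#' an attribute so that [compute_eer()] can take its analytic derivative
#' rather than finite-differencing the samples.
#'
#' Knots are budgeted by physical extent — one knot per 0.2 mm of profile
#' span, bounded by the number of observations and capped at 45 — so that
#' the spline derivative (the EER) stays estimable from noisy profiles while
#' still resolving the approach of the EER to zero at the growth zone end.
#'
#' Smoothing is idempotent by construction: a profile that already carries a
#' spline fit from the same configuration is returned unchanged, because a
#' penalized re-fit on the (denser) resampling grid would apply additional
#' shrinkage rather than reproduce the curve.
#'
#' @param profile A [velocity_profile()] with at least 10 points.
#' @param smoothing Smoothing level, passed to `smooth.spline` as `spar`
#'   (roughness penalty parameter, in (0, 1] for typical use; values near 0
#'   interpolate, larger values smooth harder). Default 0.5.
#' @param grid_step Resampling grid step (mm), > 0. Default 0.01.
#' @return A [velocity_profile()] on the uniform grid, with attributes
#'   `spline` (the `smooth.spline` fit) and `smoothed = TRUE`.
#' @export
smooth_velocity <- function(profile, smoothing = 0.5, grid_step = 0.01) {
  stopifnot(inherits(profile, "velocity_profile"))
  stopifnot_scalar(grid_step, "grid_step", positive = TRUE)
  stopifnot_scalar(smoothing, "smoothing")
  if (smoothing <= 0 || smoothing > 1.5) {
    stop("`smoothing` must lie in (0, 1.5]", call. = FALSE)
  }
  if (isTRUE(attr(profile, "smoothed")) &&
      identical(attr(profile, "smoothing"), smoothing) &&
      identical(attr(profile, "grid_step"), grid_step)) {
    return(profile)
  }
  x <- profile$position_mm
  y <- profile$velocity_mm_per_h
  if (length(x) < 10L) {
    stop("insufficient data: need >= 10 points to smooth", call. = FALSE)
  }
  nk <- max(10L, min(45L, round(diff(range(x)) / 0.2), length(x)))
  fit <- stats::smooth.spline(x, y, spar = smoothing, nknots = nk,
                              keep.data = FALSE)
  grid <- seq(min(x), max(x), by = grid_step)
  out <- velocity_profile(grid, stats::predict(fit, grid)$y,
                          root_id = attr(profile, "root_id"),
                          time_label = attr(profile, "time_label"))
  attr(out, "spline") <- fit
  attr(out, "smoothed") <- TRUE
  attr(out, "smoothing") <- smoothing
  attr(out, "grid_step") <- grid_step
  out
}

#' Differentiate a smoothed velocity profile to the EER profile
#'
#' The elemental elongation rate is the spatial derivative of the velocity
#' profile. For a spline-smoothed profile (from [smooth_velocity()]) the
#' analytic first derivative of the fitted spline is evaluated on the same
#' grid. Passing a raw, unsmoothed profile triggers a warning (the derivative
#' of noise is meaningless) and the profile is smoothed with defaults first.
#'
#' @param smoothed A smoothed [velocity_profile()].
#' @return An [eer_profile()] on the same grid.
#' @export
compute_eer <- function(smoothed) {
  stopifnot(inherits(smoothed, "velocity_profile"))
  fit <- attr(smoothed, "spline")
  if (is.null(fit) || !isTRUE(attr(smoothed, "smoothed"))) {
    warning("profile is not spline-smoothed; smoothing with defaults before ",
            "differentiating (the derivative of raw noise is meaningless)",
            call. = FALSE)
    smoothed <- smooth_velocity(smoothed)
    fit <- attr(smoothed, "spline")
  }
  d <- stats::predict(fit, smoothed$position_mm, deriv = 1)$y
  eer_profile(smoothed$position_mm, d)
}

#' Growth traits of a root at one time point
#'
#' Container for the six kinematic traits: whole-root growth rate (mm h^-1),
#' maximal EER (h^-1) and its abscissa (mm), growth zone length (mm),
#' division zone length (mm), elongation zone length (mm, = GZ - DZ), and
#' cell production rate (cells h^-1).
#'
#' @param growth_rate,eer_max,eer_max_abscissa,gz_length,dz_length,ez_length,cell_production_rate
#'   Trait values; `NA` where not yet determined.
#' @return An object of class `growth_traits`.
#' @export
growth_traits <- function(growth_rate = NA_real_, eer_max = NA_real_,
                          eer_max_abscissa = NA_real_, gz_length = NA_real_,
                          dz_length = NA_real_, ez_length = NA_real_,
                          cell_production_rate = NA_real_) {
  structure(list(growth_rate = growth_rate, eer_max = eer_max,
                 eer_max_abscissa = eer_max_abscissa, gz_length = gz_length,
                 dz_length = dz_length, ez_length = ez_length,
                 cell_production_rate = cell_production_rate),
            class = "growth_traits")
}

#' @export
print.growth_traits <- function(x, ...) {
  cat("Growth traits:\n")
  cat(sprintf("  growth rate          %8.4g mm/h\n", x$growth_rate))
  cat(sprintf("  EER_max              %8.4g /h at %.4g mm\n",
              x$eer_max, x$eer_max_abscissa))
  cat(sprintf("  growth zone length   %8.4g mm\n", x$gz_length))
  cat(sprintf("  division zone length %8.4g mm\n", x$dz_length))
  cat(sprintf("  elongation zone      %8.4g mm\n", x$ez_length))
  cat(sprintf("  cell production rate %8.4g cells/h\n", x$cell_production_rate))
  invisible(x)
}

#' @export
as.data.frame.growth_traits <- function(x, ...) {
  data.frame(growth_rate_mm_h = x$growth_rate, eer_max_h = x$eer_max,
             eer_max_abscissa_mm = x$eer_max_abscissa,
             gz_length_mm = x$gz_length, dz_length_mm = x$dz_length,
             ez_length_mm = x$ez_length,
             cell_production_rate_h = x$cell_production_rate)
}

#' Ground-truth growth traits of a synthetic field
#'
#' Evaluates the analytic velocity and EER profiles of a
#' [growth_field_spec()] on a dense (1 um) grid, extracts the growth traits
#' with the same rules as the estimation pipeline, and adds the exact cell
#' production rate implied by flux conservation
#' (`v(dz_length) / meristem_cell_length`). This is the reference against
#' which phantom-recovery accuracy is measured.
#'
#' @param spec A [growth_field_spec()].
#' @param gz_rule,gz_threshold Growth-zone end rule (see
#'   [extract_growth_traits()]).
#' @param grid_step Evaluation grid step (mm); default 0.001.
#' @return A [growth_traits()].
#' @export
field_growth_traits <- function(spec, gz_rule = "relative",
                                gz_threshold = 0.03, grid_step = 0.001) {
  stopifnot(inherits(spec, "growth_field_spec"))
  x <- seq(0, spec$gz_length * 1.3, by = grid_step)
  tr <- extract_growth_traits(
    velocity_profile(x, field_velocity(spec, x)),
    eer_profile(x, eval_eer_field(spec, x)),
    dz_length = spec$dz_length, gz_rule = gz_rule, gz_threshold = gz_threshold)
  tr$cell_production_rate <-
    field_velocity(spec, spec$dz_length) * 1000 / spec$meristem_cell_length
  tr
}

#' Extract growth traits from velocity and EER profiles
#'
#' Implements the standard kinematic trait definitions: the root growth rate
#' is the maximum of the velocity profile; `EER_max` is the maximum of the
#' EER profile (with sub-grid parabolic refinement of both the value and its
#' abscissa); the growth zone ends at the first position beyond the EER peak
#' where the EER falls below a threshold and stays below it for at least
#' `min_below` mm (linear interpolation between grid points); the elongation
#' zone is the growth zone minus the division zone. The threshold is either
#' relative (`gz_threshold` x `EER_max`, default 3%) or an absolute rate in
#' h^-1.
#'
#' @param velocity A (smoothed) [velocity_profile()].
#' @param eer The matching [eer_profile()].
#' @param dz_length Division zone length (mm), e.g. from [detect_dz_end()];
#'   `NA` allowed (then `ez_length` is `NA` too).
#' @param gz_rule `"relative"` (fraction of EER_max) or `"absolute"` (h^-1).
#' @param gz_threshold Threshold value under the chosen rule; default 0.03.
#' @param min_below Persistence window (mm) the EER must stay below the
#'   threshold for a crossing to count; suppresses noisy-tail recrossings.
#' @return A [growth_traits()] (with `cell_production_rate = NA`; see
#'   [cell_production_rate()]).
#' @export
extract_growth_traits <- function(velocity, eer, dz_length = NA_real_,
                                  gz_rule = c("relative", "absolute"),
                                  gz_threshold = 0.03, min_below = 0.2) {
  gz_rule <- match.arg(gz_rule)
  stopifnot(inherits(velocity, "velocity_profile"), inherits(eer, "eer_profile"))
  stopifnot_scalar(gz_threshold, "gz_threshold", positive = TRUE)
  if (!is.na(dz_length)) stopifnot_scalar(dz_length, "dz_length", nonneg = TRUE)
  x <- eer$position_mm; e <- eer$eer_per_h
  if (max(e) <= 0) stop("EER profile has no positive maximum", call. = FALSE)

  growth_rate <- max(velocity$velocity_mm_per_h)

  i <- which.max(e)
  if (i > 1L && i < length(e)) {
    v <- parabolic_vertex(x[(i - 1):(i + 1)], e[(i - 1):(i + 1)])
    eer_max <- v$y; eer_abs <- v$x
  } else {
    eer_max <- e[i]; eer_abs <- x[i]
  }

  thr <- if (gz_rule == "relative") gz_threshold * eer_max else gz_threshold
  below <- e < thr
  gz <- NA_real_
  first_cross <- NA_real_
  j <- i
  while (j < length(e)) {
    j <- j + 1L
    if (below[j] && !below[j - 1L]) {
      cross <- x[j - 1L] + (e[j - 1L] - thr) / (e[j - 1L] - e[j]) *
        (x[j] - x[j - 1L])
      if (is.na(first_cross)) first_cross <- cross
      # require persistence below threshold for >= min_below mm
      horizon <- x <= x[j] + min_below & x >= x[j]
      if (all(below[horizon])) {
        gz <- cross
        break
      }
    }
  }
  # noisy tails can recross the threshold repeatedly; if no crossing is
  # followed by a clean min_below window, fall back to the first down-crossing
  if (is.na(gz)) gz <- first_cross
  if (is.na(gz)) {
    stop("open-ended growth zone: EER never falls below the threshold within ",
         "the profile", call. = FALSE)
  }
  if (!is.na(dz_length) && dz_length > gz) {
    stop(sprintf("inconsistent zones: dz_length (%.3g mm) exceeds gz_length (%.3g mm)",
                 dz_length, gz), call. = FALSE)
  }
  growth_traits(growth_rate = growth_rate, eer_max = eer_max,
                eer_max_abscissa = eer_abs, gz_length = gz,
                dz_length = dz_length,
                ez_length = if (is.na(dz_length)) NA_real_ else gz - dz_length)
}
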