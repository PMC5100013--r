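#' Fit the growth-kinematics model to a root's profiles
#'
#' The central estimator of the package. Given a raw velocity profile in the
#' quiescent-center frame (typically from [piv_velocity_profile()]), and
#' optionally a brightness profile and a cell-length profile, it
#' (1) fits a cubic smoothing spline to the velocity profile
#' ([smooth_velocity()]), (2) differentiates the spline analytically to the
#' elemental elongation rate profile ([compute_eer()]), (3) delineates the
#' division zone from the brightness drop ([detect_dz_end()]) unless
#' `dz_length` is supplied, (4) extracts the growth traits
#' ([extract_growth_traits()]), and (5) if cell lengths are available,
#' computes the cell production rate ([cell_production_rate()]) and the
#' flux-conservation diagnostic ([cell_flux_profile()]).
#'
#' @param velocity A raw [velocity_profile()].
#' @param brightness Optional [brightness_profile()] for DZ delineation.
#' @param cells Optional [cell_length_profile()] for the production rate.
#' @param dz_length Division zone length (mm); overrides `brightness`.
#' @param smoothing,grid_step Passed to [smooth_velocity()].
#' @param gz_rule,gz_threshold,min_below Passed to [extract_growth_traits()].
#' @param brightness_threshold,smooth_window Passed to [detect_dz_end()].
#' @return An object of class `root_kinematics`: list with `raw`, `smoothed`,
#'   `eer` (profiles), `traits` (a [growth_traits()]), `zones`, `flux`,
#'   `config`, `call`. Supported methods: `print`, `summary`, `coef`
#'   (the traits as a named vector), `predict` (velocity or EER at new
#'   positions), `fitted`, `residuals`, `plot`.
#' @examples
#' spec <- growth_field_spec(shape = "triangular", eer_max = 0.3, x_peak = 3,
#'                           gz_length = 6, dz_length = 1.5)
#' x <- seq(0, 7, by = 0.05)
#' vp <- simulate_velocity_profile(spec, x, noise_sd = 0.01, seed = 1)
#' fit <- root_kinematics(vp, dz_length = 1.5)
#' coef(fit)
#' @export
root_kinematics <- function(velocity, brightness = NULL, cells = NULL,
                            dz_length = NULL, smoothing = 0.5,
                            grid_step = 0.01,
                            gz_rule = c("relative", "absolute"),
                            gz_threshold = 0.03, min_below = 0.2,
                            brightness_threshold = 0.70, smooth_window = 0.2) {
  gz_rule <- match.arg(gz_rule)
  stopifnot(inherits(velocity, "velocity_profile"))
  smoothed <- smooth_velocity(velocity, smoothing = smoothing,
                              grid_step = grid_step)
  eer <- compute_eer(smoothed)

  zones <- NULL
  if (is.null(dz_length) && !is.null(brightness)) {
    zones <- detect_dz_end(brightness, threshold_fraction = brightness_threshold,
                           smooth_window = smooth_window)
    dz_length <- zones$dz_length
  }
  traits <- extract_growth_traits(smoothed, eer,
                                  dz_length = dz_length %||% NA_real_,
                                  gz_rule = gz_rule,
                                  gz_threshold = gz_threshold,
                                  min_below = min_below)
  flux <- NULL
  if (!is.null(cells) && !is.na(traits$dz_length)) {
    mcl <- mean_meristem_cell_length(cells, traits$dz_length)
    traits$cell_production_rate <- cell_production_rate(smoothed,
                                                        traits$dz_length, mcl)
    flux <- cell_flux_profile(smoothed, cells, traits$dz_length)
  }
  structure(list(raw = velocity, smoothed = smoothed, eer = eer,
                 traits = traits, zones = zones, flux = flux,
                 config = list(smoothing = smoothing, grid_step = grid_step,
                               gz_rule = gz_rule, gz_threshold = gz_threshold,
                               min_below = min_below,
                               brightness_threshold = brightness_threshold,
                               smooth_window = smooth_window),
                 call = match.call()),
            class = "root_kinematics")
}

#' @export
print.root_kinematics <- function(x, ...) {
  cat("Root growth kinematics fit\n")
  cat(sprintf("  %d raw points over [%.3g, %.3g] mm; spline smoothing %.2g, grid %.3g mm\n",
              nrow(x$raw), min(x$raw$position_mm), max(x$raw$position_mm),
              x$config$smoothing, x$config$grid_step))
  print(x$traits)
  invisible(x)
}

#' @export
summary.root_kinematics <- function(object, ...) {
  res <- residuals(object)
  out <- list(traits = object$traits,
              n_raw = nrow(object$raw),
              rmse = sqrt(mean(res^2)),
              gz_rule = object$config$gz_rule,
              gz_threshold = object$config$gz_threshold,
              flux = object$flux)
  class(out) <- "summary.root_kinematics"
  out
}

#' @export
print.summary.root_kinematics <- function(x, ...) {
  print(x$traits)
  cat(sprintf("  growth zone rule: %s %.3g; raw-vs-spline RMSE %.4g mm/h (n = %d)\n",
              x$gz_rule, x$gz_threshold, x$rmse, x$n_raw))
  if (!is.null(x$flux)) {
    cat(sprintf("  cell flux CV beyond DZ: %.3g (%s)\n", x$flux$cv_beyond_dz,
                if (isTRUE(x$flux$steady)) "steady" else "not steady"))
  }
  invisible(x)
}

#' @export
coef.root_kinematics <- function(object, ...) {
  unlist(as.data.frame(object$traits))
}

#' @export
predict.root_kinematics <- function(object, positions = NULL,
                                    what = c("velocity", "eer"), ...) {
  what <- match.arg(what)
  fit <- attr(object$smoothed, "spline")
  if (is.null(positions)) positions <- object$smoothed$position_mm
  stats::predict(fit, positions, deriv = if (what == "eer") 1L else 0L)$y
}

#' @export
fitted.root_kinematics <- function(object, ...) {
  predict(object, positions = object$raw$position_mm)
}

#' @export
residuals.root_kinematics <- function(object, ...) {
  object$raw$velocity_mm_per_h - fitted(object)
}

#' @export
plot.root_kinematics <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$raw$position_mm, x$raw$velocity_mm_per_h, pch = 16,
                 cex = 0.5, col = "grey50",
                 xlab = "position from QC (mm)", ylab = "velocity (mm/h)", ...)
  graphics::lines(x$smoothed$position_mm, x$smoothed$velocity_mm_per_h,
                  col = "firebrick", lwd = 2)
  graphics::abline(v = c(x$traits$dz_length, x$traits$gz_length),
                   lty = c(3, 2), col = "grey30")
  graphics::plot(x$eer$position_mm, x$eer$eer_per_h, type = "l", lwd = 2,
                 col = "forestgreen", xlab = "position from QC (mm)",
                 ylab = "EER (1/h)")
  graphics::abline(v = c(x$traits$dz_length, x$traits$gz_length),
                   lty = c(3, 2), col = "grey30")
  invisible(x)
}

#' End-to-end kinematic analysis of an image sequence
#'
#' Convenience pipeline: PIV velocimetry over the sequence
#' ([piv_velocity_profile()]), then the kinematics fit
#' ([root_kinematics()]). Brightness can be extracted from the images
#' ([image_brightness_profile()]) or supplied.
#'
#' @param images An `image_sequence`.
#' @param brightness Optional [brightness_profile()]; when `NULL` it is
#'   extracted from the middle frame.
#' @param cells Optional [cell_length_profile()].
#' @param qc_offset Tip-to-QC distance (mm).
#' @param ... Passed to [root_kinematics()].
#' @return A `root_kinematics` fit.
#' @export
analyze_image_sequence <- function(images, brightness = NULL, cells = NULL,
                                   qc_offset = 0.5, ...) {
  vp <- piv_velocity_profile(images, qc_offset = qc_offset)
  if (is.null(brightness)) {
    brightness <- image_brightness_profile(images, qc_offset = qc_offset)
  }
  root_kinematics(vp, brightness = brightness, cells = cells, ...)
}

#' Longitudinal brightness profile of an image sequence
#'
#' Column intensity of one or more frames, expressed against distance from
#' the QC (the tracked tip minus `qc_offset`), for use with
#' [detect_dz_end()]. Within each column the intensity is summarized by a
#' row quantile (default the median) rather than the mean: the sparse
#' particle texture thins out as tissue stretches through the elongation
#' zone, which would bias a mean-based profile apically, while the median
#' tracks the smooth tissue envelope and is unbiased under symmetric sensor
#' noise.
#'
#' @param images An `image_sequence`.
#' @param frames Frame indices to average; default all frames.
#' @param qc_offset Tip-to-QC distance (mm).
#' @param rows Optional row range.
#' @param probs Row quantile summarizing each column; default 0.5.
#' @param max_position Truncate the profile at this distance from the QC (mm).
#' @return A [brightness_profile()].
#' @export
image_brightness_profile <- function(images, frames = NULL, qc_offset = 0.5,
                                     rows = NULL, probs = 0.5,
                                     max_position = NULL) {
  stopifnot(inherits(images, "image_sequence"))
  tip <- track_tip(images, rows = rows)
  if (is.null(frames)) frames <- seq_along(images$frames)
  if (is.null(rows)) {
    # restrict to the rows the root actually occupies, so background does
    # not contaminate the column quantiles
    rm_ <- rowMeans(images$frames[[frames[1]]])
    occ <- which(rm_ > 0.5 * max(rm_))
    rows <- c(min(occ), max(occ))
  }
  px_mm <- images$pixel_size / 1000
  acc <- NULL
  for (k in frames) {
    prof <- apply(images$frames[[k]][rows[1]:rows[2], , drop = FALSE], 2L,
                  stats::quantile, probs = probs, names = FALSE)
    qc_px <- tip$tip_px[k] - qc_offset / px_mm
    x <- (qc_px - seq_along(prof)) * px_mm
    keep <- x >= 0
    d <- data.frame(x = x[keep], b = prof[keep])
    acc <- if (is.null(acc)) d else rbind(acc, d)
  }
  acc <- acc[order(acc$x), ]
  # collapse positions pooled across frames onto a single grid
  bin <- round(acc$x / (px_mm / 2))
  b <- tapply(acc$b, bin, mean)
  x <- as.numeric(names(b)) * px_mm / 2
  if (!is.null(max_position)) {
    keep <- x <= max_position
    x <- x[keep]; b <- b[keep]
  }
  brightness_profile(x, as.numeric(b))
}
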