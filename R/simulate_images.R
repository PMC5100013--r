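#' Render a time-lapse phantom of a growing root tip
#'
#' Produces a synthetic near-infrared image sequence of a root apex whose
#' particle texture is advected by the material velocity field implied by a
#' [growth_field_spec()]. Each texture point seeded at material distance `x`
#' from the QC follows the trajectory `dx/dt = v(x, t)` (integrated with
#' `deSolve`), so its image position is `qc(t) - x(t)`; the root cap
#' (between the QC and the visible tip, `qc_offset` mm long) moves rigidly
#' with the QC. Two camera conventions are supported. With
#' `camera = "tracking"` (default) the stage follows the apex, the quiescent
#' center stays at a fixed image position, and texture streams away from the
#' tip by exactly the material displacement `integral of v dt` — mature
#' tissue moves at the whole-root growth rate. With `camera = "fixed"`
#' mature tissue is stationary and the tip advances through the frame
#' instead.
#'
#' A longitudinal brightness envelope at full level over the division zone
#' decays beyond it and crosses 70% of its plateau exactly at the spec's
#' `dz_length` (recorded as ground truth); additive Gaussian sensor noise is
#' applied last. Per-pair ground-truth displacements of every texture point
#' are returned for velocimetry validation.
#'
#' @param spec A [growth_field_spec()].
#' @param n_frames Number of frames (>= 2).
#' @param dt Inter-frame interval (h); default 0.1 (one frame every 6 min).
#' @param pixel_size Pixel size (micrometres per pixel).
#' @param width,height Frame size in pixels; the root axis runs along columns
#'   (tip pointing right).
#' @param texture_density Particles per mm^2 of root area (> 0).
#' @param noise_sd Additive Gaussian sensor noise sd (intensity units; the
#'   texture dynamic range is about 1).
#' @param seed RNG seed for texture placement and sensor noise.
#' @param qc_offset Distance from the visible tip to the QC (mm); the root
#'   cap. Default 0.5.
#' @param camera `"tracking"` (apex held at a fixed image position) or
#'   `"fixed"` (stationary camera, tip advances).
#' @param t_start Time of the first frame (h), relative to the spec's stress
#'   scenario clock.
#' @return An object of class `image_sequence`: a list with `frames` (list of
#'   height x width matrices, intensities >= 0), `timestamps` (h),
#'   `pixel_size` (um/px), `axis` (`"tip-right"`), and a `truth` list holding
#'   the spec, per-frame QC and tip positions (px, 1-based column
#'   coordinates), particle trajectories (lab px), per-pair particle
#'   displacements (px), and the ground-truth `dz_length`.
#' @export
render_image_sequence <- function(spec, n_frames = 20, dt = 0.1,
                                  pixel_size = 20, width = 512, height = 256,
                                  texture_density = 40, noise_sd = 0.02,
                                  seed = NULL, qc_offset = 0.5,
                                  camera = c("tracking", "fixed"),
                                  t_start = 0) {
  camera <- match.arg(camera)
  stopifnot(inherits(spec, "growth_field_spec"))
  if (n_frames < 2) stop("`n_frames` must be >= 2", call. = FALSE)
  stopifnot_scalar(texture_density, "texture_density", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)

  times <- t_start + dt * (seq_len(n_frames) - 1L)
  width_mm <- width * pixel_size / 1000
  px_mm <- 1000 / pixel_size  # px per mm

  # QC trajectory in the lab frame: advances at the (possibly time-varying)
  # whole-root growth rate, computed on a fine grid.
  v0 <- field_velocity(growth_field_spec(spec$eer_max, spec$x_peak,
                                         spec$gz_length, spec$dz_length,
                                         spec$shape, spec$meristem_cell_length,
                                         NULL, spec$beta_concentration),
                       spec$gz_length)
  tg <- seq(times[1], times[n_frames], length.out = 50 * n_frames)
  vg <- v0 * stress_multiplier(spec$stress_scenario, tg)
  adv <- c(0, cumsum((vg[-1] + vg[-length(vg)]) / 2 * diff(tg)))
  advance_total <- adv[length(adv)]
  qc_of_t <- stats::approxfun(tg, adv)

  qc0_mm <- width_mm - 0.3 - qc_offset -
    if (camera == "fixed") advance_total else 0
  if (qc0_mm < spec$gz_length + 0.4) {
    stop("frame too small to contain the growth zone at the final frame; ",
         "enlarge `width` or `pixel_size`", call. = FALSE)
  }
  qc_mm <- qc0_mm + if (camera == "fixed") qc_of_t(times) else rep(0, n_frames)
  tip_mm <- qc_mm + qc_offset              # visible tip per frame (mm)

  # Transverse band occupied by the root.
  band <- round(c(0.2, 0.8) * height)
  band_rows <- band[1]:band[2]
  band_mm <- length(band_rows) * pixel_size / 1000

  x_extent <- qc_mm[1] + qc_offset         # material span visible at t = 0
  n_part <- max(50L, round(texture_density * x_extent * band_mm))
  parts <- with_seed(seed, {
    list(x0 = stats::runif(n_part, -qc_offset, x_extent - qc_offset),
         row = stats::runif(n_part, band[1] + 1, band[2] - 1),
         amp = stats::runif(n_part, 0.5, 1),
         noise = if (noise_sd > 0) {
           stats::rnorm(n_frames * height * width, 0, noise_sd)
         } else numeric(0))
  })

  # Material trajectories x_i(t): cap points (x <= 0) ride with the QC.
  deriv <- function(t, x, parms) {
    v <- numeric(length(x))
    pos <- x > 0
    if (any(pos)) v[pos] <- field_velocity(spec, x[pos], t)
    list(v)
  }
  sol <- deSolve::ode(y = parts$x0, times = times, func = deriv, parms = NULL,
                      method = "rk4", hini = dt / 5)
  xmat <- sol[, -1, drop = FALSE]          # n_frames x n_part material coords

  lab_mm <- outer(qc_mm, rep(1, n_part)) - xmat   # lab positions (mm)
  lab_px <- lab_mm * px_mm + 0.5                  # 1-based pixel coordinates

  sigma_blob <- 1.3
  offs <- expand.grid(dy = -3:3, dx = -3:3)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    img <- matrix(0, height, width)
    # Base root body intensity, modulated by the brightness envelope.
    col_mm <- (seq_len(width) - 0.5) / px_mm
    xcol <- qc_mm[k] - col_mm                      # material distance from QC
    base <- 0.35 * brightness_envelope(pmax(xcol, 0), spec$dz_length)
    base[col_mm > tip_mm[k]] <- 0
    img[band_rows, ] <- matrix(base, length(band_rows), width, byrow = TRUE)

    # Particle texture (Gaussian blobs), envelope-modulated, tip-clipped.
    env_k <- parts$amp * brightness_envelope(pmax(xmat[k, ], 0), spec$dz_length)
    cx <- lab_px[k, ]; cy <- parts$row
    keep <- cx >= -3 & cx <= width + 3
    if (any(keep)) {
      cxk <- cx[keep]; cyk <- cy[keep]; ak <- env_k[keep]
      r0 <- round(cyk); c0 <- round(cxk)
      idx_all <- integer(0); val_all <- numeric(0)
      for (o in seq_len(nrow(offs))) {
        r <- r0 + offs$dy[o]; cc <- c0 + offs$dx[o]
        ok <- r >= 1 & r <= height & cc >= 1 & cc <= width
        if (!any(ok)) next
        d2 <- (r[ok] - cyk[ok])^2 + (cc[ok] - cxk[ok])^2
        idx_all <- c(idx_all, (cc[ok] - 1L) * height + r[ok])
        val_all <- c(val_all, ak[ok] * exp(-d2 / (2 * sigma_blob^2)))
      }
      if (length(idx_all)) {
        agg <- rowsum(val_all, idx_all)
        img[as.integer(rownames(agg))] <- img[as.integer(rownames(agg))] + agg[, 1]
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(parts$noise[((k - 1) * height * width + 1):(k * height * width)],
                          height, width)
    }
    frames[[k]] <- pmax(img, 0)
  }

  displacement_px <- (lab_px[-1, , drop = FALSE] -
                        lab_px[-n_frames, , drop = FALSE])
  structure(list(
    frames = frames, timestamps = times, pixel_size = pixel_size,
    axis = "tip-right",
    truth = list(spec = spec, qc_px = qc_mm * px_mm + 0.5,
                 tip_px = tip_mm * px_mm + 0.5,
                 qc_offset = qc_offset,
                 particle_x0 = parts$x0, particle_row = parts$row,
                 trajectories_px = lab_px,
                 material_x = xmat,
                 displacement_px = displacement_px,
                 dz_length = spec$dz_length,
                 growth_rate = v0 * stress_multiplier(spec$stress_scenario, times))
  ), class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Image sequence: %d frames of %d x %d px, %.3g um/px, dt %.3g h\n",
              length(x$frames), d[1], d[2], x$pixel_size,
              if (length(x$timestamps) > 1) diff(x$timestamps)[1] else NA))
  invisible(x)
}
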