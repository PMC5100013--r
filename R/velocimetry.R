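# Velocimetry: recover axial displacement and velocity profiles from image
# sequences by windowed normalized cross-correlation.

#' Track the root tip across an image sequence
#'
#' Locates the tip in every frame as the distal intensity edge along the root
#' axis: the transverse-averaged column profile is lightly smoothed and the
#' last axial position where it exceeds a fraction of its maximum is refined
#' to subpixel precision by linear interpolation on the falling edge. Tip
#' velocity is a robust (Theil-Sen) straight-line fit of tip position against
#' time.
#'
#' @param images An `image_sequence` (see [render_image_sequence()] and
#'   [read_image_sequence()]).
#' @param threshold_frac Edge threshold as a fraction of the maximum column
#'   intensity (default 0.3).
#' @param rows Optional row range (length-2 integer) to average over; default
#'   all rows.
#' @return List with `tip_px` (per-frame tip column, subpixel),
#'   `velocity_mm_per_h` (signed tip velocity), and the fitted `intercept_px`.
#' @export
track_tip <- function(images, threshold_frac = 0.3, rows = NULL) {
  stopifnot(inherits(images, "image_sequence"))
  frames <- images$frames
  if (length(frames) < 2L) stop("need >= 2 frames", call. = FALSE)
  if (is.null(rows)) rows <- c(1L, nrow(frames[[1]]))
  tip <- vapply(seq_along(frames), function(k) {
    prof <- colMeans(frames[[k]][rows[1]:rows[2], , drop = FALSE])
    prof <- running_mean(prof, 3L)
    thr <- threshold_frac * max(prof)
    above <- which(prof >= thr)
    if (!length(above)) stop("tip not found: no column above threshold", call. = FALSE)
    j <- max(above)
    if (j >= length(prof)) {
      stop(sprintf("tip leaves the field of view at frame %d", k), call. = FALSE)
    }
    # linear interpolation of the crossing between columns j and j+1
    j + (prof[j] - thr) / (prof[j] - prof[j + 1])
  }, numeric(1))
  fit <- theil_sen(images$timestamps, tip)
  list(tip_px = tip,
       velocity_mm_per_h = fit$slope * images$pixel_size / 1000,
       intercept_px = fit$intercept)
}

#' Axial displacements between two frames by windowed cross-correlation
#'
#' For interrogation windows spaced along the root axis, finds the axial
#' (column) shift that maximizes the normalized cross-correlation between the
#' window in `frame_a` and the shifted window in `frame_b`, searched over
#' integer lags within `search_radius` and refined to subpixel precision by a
#' parabolic fit through the correlation peak and its two axial neighbours.
#' Windows that would extend outside the image, have (near-)zero variance, or
#' whose correlation peak falls below `min_peak` are flagged, never silently
#' dropped.
#'
#' @param frame_a,frame_b Intensity matrices of identical dimensions (rows =
#'   transverse, columns = axial).
#' @param window_size Axial window extent (px), >= 8.
#' @param window_step Spacing of window centers (px).
#' @param search_radius Maximum absolute lag searched (px).
#' @param rows Optional row range used for correlation (default all rows).
#' @param min_peak Acceptance threshold on the correlation peak.
#' @return A data frame of class `displacement_field` with columns
#'   `center_px`, `displacement_px` (positive towards larger column index,
#'   i.e. towards the tip), `peak` (normalized correlation in [-1, 1]), and
#'   `flag` (`"ok"`, `"low_peak"`, `"flat"`, or `"edge_peak"` when the best
#'   lag sits on the search boundary and cannot be refined).
#' @export
piv_displacements <- function(frame_a, frame_b, window_size = 32,
                              window_step = 8, search_radius = 12,
                              rows = NULL, min_peak = 0.5) {
  stopifnot(is.matrix(frame_a), is.matrix(frame_b))
  if (!all(dim(frame_a) == dim(frame_b))) {
    stop("frames must have identical dimensions", call. = FALSE)
  }
  if (window_size < 8) stop("`window_size` must be >= 8 px", call. = FALSE)
  w <- ncol(frame_a)
  if (is.null(rows)) rows <- c(1L, nrow(frame_a))
  ridx <- rows[1]:rows[2]
  half <- window_size %/% 2L
  lags <- -search_radius:search_radius

  centers_all <- seq(half + 1L, w - half + 1L, by = window_step)
  # a window at center c spans columns [c - half, c + half - 1]
  usable <- centers_all - half + min(lags) >= 1L &
    centers_all + half - 1L + max(lags) <= w
  out <- data.frame(center_px = centers_all,
                    displacement_px = NA_real_,
                    peak = NA_real_,
                    flag = ifelse(usable, "ok", "outside"),
                    stringsAsFactors = FALSE)
  centers <- centers_all[usable]
  if (!length(centers)) {
    return(structure(out, class = c("displacement_field", "data.frame")))
  }

  grab <- function(frame, shift) {
    vapply(centers, function(cc) {
      as.vector(frame[ridx, (cc - half + shift):(cc + half - 1L + shift)])
    }, numeric(length(ridx) * window_size))
  }
  A <- grab(frame_a, 0L)
  npx <- nrow(A)
  a_mean <- colMeans(A)
  Ac <- sweep(A, 2L, a_mean)
  a_ss <- colSums(Ac^2)
  eps <- 1e-12 * npx

  ncc <- matrix(NA_real_, length(lags), length(centers))
  for (li in seq_along(lags)) {
    B <- grab(frame_b, lags[li])
    Bc <- sweep(B, 2L, colMeans(B))
    b_ss <- colSums(Bc^2)
    denom <- sqrt(a_ss * b_ss)
    ncc[li, ] <- ifelse(denom > eps, colSums(Ac * Bc) / denom, NA_real_)
  }

  ui <- which(usable)
  for (j in seq_along(centers)) {
    y <- ncc[, j]
    if (all(is.na(y)) || a_ss[j] <= eps) {
      out$flag[ui[j]] <- "flat"
      next
    }
    k <- which.max(y)
    out$peak[ui[j]] <- y[k]
    if (k == 1L || k == length(y) || is.na(y[k - 1]) || is.na(y[k + 1])) {
      out$displacement_px[ui[j]] <- lags[k]
      out$flag[ui[j]] <- "edge_peak"
    } else {
      v <- parabolic_vertex(lags[(k - 1):(k + 1)], y[(k - 1):(k + 1)])
      out$displacement_px[ui[j]] <- v$x
      out$flag[ui[j]] <- if (y[k] >= min_peak) "ok" else "low_peak"
    }
  }
  structure(out, class = c("displacement_field", "data.frame"),
            window_size = window_size, search_radius = search_radius)
}

#' Convert displacement fields to a velocity profile in the QC frame
#'
#' Window centers are mapped to distance behind the quiescent center (the QC
#' is taken at a fixed offset, default 0.5 mm, behind the tracked tip);
#' displacements become velocities via the pixel size and frame interval; and
#' the tip's own motion is subtracted so that the result is the material
#' velocity away from the QC (0 at the QC, the root growth rate in mature
#' tissue). Estimates from all frame pairs are pooled and aggregated by the
#' median within position bins.
#'
#' @param fields List of [piv_displacements()] results, one per consecutive
#'   frame pair (pair `k` compares frames `k` and `k + 1`).
#' @param tip_track Result of [track_tip()] on the same sequence.
#' @param pixel_size Pixel size (um per px), > 0.
#' @param dt Frame interval (h), > 0.
#' @param qc_offset Distance from visible tip to QC (mm), >= 0; default 0.5.
#' @param bin_width Position bin width (mm) for aggregation; default 0.1.
#' @param min_peak Windows with flags other than `"ok"` or peak below this are
#'   excluded from aggregation.
#' @param max_position Optional cap on position (mm from QC).
#' @return A [velocity_profile()] with an `n_obs` column.
#' @export
displacements_to_velocity <- function(fields, tip_track, pixel_size, dt,
                                      qc_offset = 0.5, bin_width = 0.1,
                                      min_peak = 0.5, max_position = NULL) {
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(qc_offset, "qc_offset", nonneg = TRUE)
  if (inherits(fields, "displacement_field")) fields <- list(fields)
  vtip <- tip_track$velocity_mm_per_h
  px_mm <- pixel_size / 1000

  pos <- numeric(0); vel <- numeric(0)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    qc_px <- tip_track$tip_px[k] - qc_offset / px_mm
    ok <- f$flag == "ok" & !is.na(f$peak) & f$peak >= min_peak
    x <- (qc_px - f$center_px[ok]) * px_mm
    v <- vtip - f$displacement_px[ok] * px_mm / dt
    keep <- x >= 0
    pos <- c(pos, x[keep]); vel <- c(vel, v[keep])
  }
  if (!is.null(max_position)) {
    keep <- pos <= max_position
    pos <- pos[keep]; vel <- vel[keep]
  }
  if (!length(pos)) stop("no accepted PIV windows in the QC frame", call. = FALSE)
  bin <- floor(pos / bin_width)
  med <- tapply(vel, bin, stats::median)
  n <- tapply(vel, bin, length)
  centers <- (as.numeric(names(med)) + 0.5) * bin_width
  ord <- order(centers)
  velocity_profile(centers[ord], as.numeric(med)[ord], n_obs = as.integer(n)[ord])
}

# Row range actually occupied by the root (transverse band), from the row
# means of one frame; correlating background rows only adds noise and cost.
root_band_rows <- function(frame, frac = 0.5) {
  rm_ <- rowMeans(frame)
  occ <- which(rm_ > frac * max(rm_))
  c(min(occ), max(occ))
}

# Remove the slowly varying longitudinal intensity envelope (brightness
# drop beyond the division zone, vignetting) before correlation: a window
# with a strong internal amplitude gradient otherwise weights its match
# towards the brighter side, biasing displacements there. Columns are
# divided by a running-mean column profile, floored to avoid amplifying
# background noise beyond the tip.
flatfield_frame <- function(frame, rows, width_px = 16L) {
  prof <- running_mean(colMeans(frame[rows[1]:rows[2], , drop = FALSE]),
                       width_px)
  frame / rep(pmax(prof, 0.1 * max(prof)), each = nrow(frame))
}

#' Run PIV over a whole image sequence
#'
#' Convenience wrapper: tracks the tip, flat-fields each frame (dividing out
#' the smoothed longitudinal intensity envelope, which would otherwise bias
#' window matches towards their brighter side), computes
#' [piv_displacements()] for every consecutive frame pair, and aggregates
#' them with [displacements_to_velocity()] into a raw velocity profile in
#' the QC frame.
#'
#' @inheritParams piv_displacements
#' @inheritParams displacements_to_velocity
#' @param images An `image_sequence`.
#' @param flatfield Divide out the longitudinal envelope first (default TRUE).
#' @return A [velocity_profile()].
#' @export
piv_velocity_profile <- function(images, window_size = 32, window_step = 8,
                                 search_radius = 12, qc_offset = 0.5,
                                 bin_width = 0.1, min_peak = 0.5,
                                 rows = NULL, flatfield = TRUE) {
  stopifnot(inherits(images, "image_sequence"))
  tip <- track_tip(images, rows = rows)
  n <- length(images$frames)
  frames <- images$frames
  if (is.null(rows)) rows <- root_band_rows(frames[[1L]])
  if (flatfield) {
    frames <- lapply(frames, flatfield_frame, rows = rows)
  }
  fields <- lapply(seq_len(n - 1L), function(k) {
    piv_displacements(frames[[k]], frames[[k + 1L]],
                      window_size = window_size, window_step = window_step,
                      search_radius = search_radius, rows = rows,
                      min_peak = min_peak)
  })
  dt <- diff(images$timestamps)[1]
  displacements_to_velocity(fields, tip, pixel_size = images$pixel_size,
                            dt = dt, qc_offset = qc_offset,
                            bin_width = bin_width, min_peak = min_peak)
}
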