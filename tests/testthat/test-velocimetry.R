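test_that("identical frames give zero displacement with unit correlation", {
  img <- make_texture(seed = 1)
  f <- piv_displacements(img, img, window_size = 32, window_step = 8,
                         search_radius = 6)
  ok <- f$flag == "ok"
  expect_true(any(ok))
  expect_true(all(abs(f$displacement_px[ok]) < 0.05))
  expect_true(all(f$peak[ok] > 0.999))
  expect_true(all(f$flag[!ok] %in% c("outside", "flat", "low_peak", "edge_peak")))
})

test_that("an exact integer roll is recovered to 0.05 px", {
  img <- make_texture(seed = 2)
  rolled <- img[, c(rep(1, 3), 1:(ncol(img) - 3))]  # content moved +3 columns
  f <- piv_displacements(img, rolled, search_radius = 6)
  ok <- f$flag == "ok"
  expect_true(all(abs(f$displacement_px[ok] - 3) < 0.05))
})

test_that("Fourier-interpolated subpixel shifts are recovered within 0.2 px", {
  shifts <- seq(0.1, 0.9, by = 0.2)
  for (seed in 1:5) {
    img <- make_texture(seed = seed)
    for (s in c(shifts, 3.25)) {
      shifted <- fourier_shift_cols(img, s)
      f <- piv_displacements(img, shifted, search_radius = 6)
      ok <- f$flag == "ok"
      err <- abs(stats::median(f$displacement_px[ok]) - s)
      expect_lt(err, if (s == 3.25) 0.15 else 0.2)
    }
  }
})

test_that("flat windows are flagged rather than dropped", {
  flat <- matrix(0.5, 64, 128)
  f <- piv_displacements(flat, flat, search_radius = 6)
  expect_true(all(f$flag %in% c("flat", "outside")))
  expect_equal(nrow(f), length(seq(17, 113, by = 8)))
  expect_error(piv_displacements(flat, flat[, 1:64]), "identical dimensions")
  expect_error(piv_displacements(flat, flat, window_size = 4), "window_size")
})

test_that("tip tracking recovers static, growing, and time-reversed motion", {
  static <- growth_field_spec(eer_max = 0, x_peak = 3, gz_length = 6,
                              dz_length = 1.5, shape = "triangular")
  s0 <- render_image_sequence(static, n_frames = 8, seed = 14)
  expect_lt(abs(track_tip(s0)$velocity_mm_per_h), 0.01)

  spec <- compact_spec()  # growth rate 0.9 mm/h
  s1 <- render_image_sequence(spec, n_frames = 8, pixel_size = 10, seed = 14,
                              camera = "fixed")
  tip <- track_tip(s1)
  expect_equal(tip$velocity_mm_per_h, 0.9, tolerance = 0.05)

  rev_seq <- s1
  rev_seq$frames <- rev(s1$frames)
  tip_rev <- track_tip(rev_seq)
  expect_equal(tip_rev$velocity_mm_per_h, -tip$velocity_mm_per_h,
               tolerance = 0.01)
})

test_that("displacement-to-velocity conversion uses the right units and frame", {
  # a displacement of 5 px away from the QC at 10 um/px over 0.1 h is
  # 0.5 mm/h; with the tip static, axial (columnwise) displacement is -5 px
  field <- structure(data.frame(center_px = c(40, 60, 80),
                                displacement_px = -5, peak = 0.9, flag = "ok"),
                     class = c("displacement_field", "data.frame"))
  tip <- list(tip_px = c(150, 150), velocity_mm_per_h = 0)
  vp <- displacements_to_velocity(list(field), tip, pixel_size = 10, dt = 0.1,
                                  qc_offset = 0)
  expect_true(all(abs(vp$velocity_mm_per_h - 0.5) < 1e-12))
  # window ordering along the axis is preserved in the profile
  expect_false(is.unsorted(vp$position_mm, strictly = TRUE))

  # windows moving exactly with the tip have zero material velocity
  tip2 <- list(tip_px = c(150, 154.5), velocity_mm_per_h = 0.45)
  field2 <- field
  field2$displacement_px <- 4.5
  vp2 <- displacements_to_velocity(list(field2), tip2, pixel_size = 10, dt = 0.1)
  expect_true(all(abs(vp2$velocity_mm_per_h) < 1e-12))
  expect_error(displacements_to_velocity(list(field), tip, 10, dt = -1), "dt")
  expect_error(displacements_to_velocity(list(field), tip, -10, dt = 0.1),
               "pixel_size")
})

test_that("full-phantom PIV recovers the analytic velocity profile", {
  spec <- growth_field_spec(eer_max = 0.3, x_peak = 2.5, gz_length = 6,
                            dz_length = 1.5)
  s <- render_image_sequence(spec, n_frames = 12, seed = 8, noise_sd = 0.02,
                             camera = "fixed")
  vp <- piv_velocity_profile(s)
  vtrue <- field_velocity(spec, vp$position_mm)
  rmse <- sqrt(mean((vp$velocity_mm_per_h - vtrue)^2))
  expect_lt(rmse, 0.05 * max(vtrue))
  # mature-region velocity equals tip velocity within 3% (the kinematic
  # definition of the root growth rate)
  tipv <- track_tip(s)$velocity_mm_per_h
  mature <- vp$position_mm > spec$gz_length + 0.5
  expect_equal(stats::median(vp$velocity_mm_per_h[mature]), tipv,
               tolerance = 0.03)
})
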