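test_that("the smoothing spline reproduces low-degree and constant profiles", {
  x <- seq(0, 5, by = 0.05)
  lin <- velocity_profile(x, 0.1 * x)
  sm <- smooth_velocity(lin, smoothing = 0.01)
  expect_lt(max(abs(sm$velocity_mm_per_h - 0.1 * sm$position_mm)), 1e-6)
  cst <- velocity_profile(x, rep(0.4, length(x)))
  for (lev in c(0.1, 0.5, 1.0)) {
    smc <- smooth_velocity(cst, smoothing = lev)
    expect_lt(max(abs(smc$velocity_mm_per_h - 0.4)), 1e-8)
  }
  expect_error(smooth_velocity(velocity_profile(1:5 / 10, 1:5 / 10)),
               "insufficient data")
})

test_that("smoothing reduces the error of a noisy profile", {
  spec <- growth_field_spec(eer_max = 0.3, x_peak = 2.5, gz_length = 6,
                            dz_length = 1.5)
  x <- seq(0, 7, by = 0.05)
  vp <- simulate_velocity_profile(spec, x, noise_sd = 0.05 * 0.95, seed = 31)
  sm <- smooth_velocity(vp)
  raw_rmse <- sqrt(mean((vp$velocity_mm_per_h - field_velocity(spec, x))^2))
  sm_rmse <- sqrt(mean((sm$velocity_mm_per_h -
                          field_velocity(spec, sm$position_mm))^2))
  expect_lt(sm_rmse, raw_rmse)
})

test_that("smoothing is idempotent", {
  spec <- growth_field_spec(eer_max = 0.3, x_peak = 2.5, gz_length = 6,
                            dz_length = 1.5)
  x <- seq(0, 7, by = 0.05)
  vp <- simulate_velocity_profile(spec, x, noise_sd = 0.02, seed = 5)
  s1 <- smooth_velocity(vp)
  s2 <- smooth_velocity(s1)
  rel <- max(abs(s2$velocity_mm_per_h - s1$velocity_mm_per_h)) /
    max(abs(s1$velocity_mm_per_h))
  expect_lt(rel, 1e-3)
  # a re-fit under a different configuration still tracks the curve closely
  s3 <- smooth_velocity(s1, grid_step = 0.02)
  common <- s3$position_mm
  rel3 <- max(abs(s3$velocity_mm_per_h -
                    predict(attr(s1, "spline"), common)$y)) /
    max(abs(s1$velocity_mm_per_h))
  expect_lt(rel3, 0.02)
})

test_that("the EER is the analytic spline derivative", {
  x <- seq(0, 5, by = 0.05)
  sm <- smooth_velocity(velocity_profile(x, 0.1 * x), smoothing = 0.01)
  e <- compute_eer(sm)
  expect_lt(max(abs(e$eer_per_h - 0.1)), 1e-6)
  smc <- smooth_velocity(velocity_profile(x, rep(1, length(x))), smoothing = 0.5)
  expect_lt(max(abs(compute_eer(smc)$eer_per_h)), 1e-8)
  expect_warning(compute_eer(velocity_profile(x, 0.1 * x)), "not spline-smoothed")
})

test_that("spline-derivative EER matches the analytic field on a noiseless phantom", {
  spec <- tri_spec()
  x <- seq(0, 7, by = 0.02)
  sm <- smooth_velocity(simulate_velocity_profile(spec, x), smoothing = 0.03,
                        grid_step = 0.01)
  e <- compute_eer(sm)
  away <- abs(e$position_mm - 3) > 0.25  # away from the triangle apex
  err <- abs(e$eer_per_h - eval_eer_field(spec, e$position_mm))
  expect_lt(max(err[away]), 0.02 * 0.3)
})

test_that("the triangular field yields its closed-form traits to 4 significant figures", {
  spec <- tri_spec()
  x <- seq(0, 7, by = 0.001)
  vp <- velocity_profile(x, field_velocity(spec, x))
  ep <- eer_profile(x, eval_eer_field(spec, x))
  tr <- extract_growth_traits(vp, ep, dz_length = 1.5)
  expect_equal(tr$growth_rate, 0.9, tolerance = 1e-4)
  expect_equal(tr$eer_max, 0.3, tolerance = 1e-4)
  expect_equal(tr$eer_max_abscissa, 3, tolerance = 1e-3)
  expect_equal(tr$gz_length, 5.91, tolerance = 1e-4)
  expect_equal(tr$ez_length, 4.41, tolerance = 1e-4)
  tr_abs <- extract_growth_traits(vp, ep, dz_length = 1.5, gz_rule = "absolute")
  expect_equal(tr_abs$gz_length, 5.70, tolerance = 1e-4)
})

test_that("trait extraction rejects inconsistent or open-ended inputs", {
  spec <- tri_spec()
  x <- seq(0, 7, by = 0.01)
  vp <- velocity_profile(x, field_velocity(spec, x))
  ep <- eer_profile(x, eval_eer_field(spec, x))
  expect_error(extract_growth_traits(vp, ep, dz_length = 6.5), "inconsistent")
  xs <- seq(0, 4, by = 0.01)  # truncated before the EER tail
  expect_error(extract_growth_traits(
    velocity_profile(xs, field_velocity(spec, xs)),
    eer_profile(xs, eval_eer_field(spec, xs))), "open-ended")
  expect_error(extract_growth_traits(vp, eer_profile(x, rep(0, length(x)))),
               "no positive maximum")
})

test_that("traits scale correctly under velocity rescaling", {
  spec <- growth_field_spec(eer_max = 0.3, x_peak = 2.5, gz_length = 6,
                            dz_length = 1.5)
  x <- seq(0, 7.5, by = 0.002)
  v <- field_velocity(spec, x)
  for (k in c(0.5, 2)) {
    tr1 <- extract_growth_traits(velocity_profile(x, v),
                                 eer_profile(x, eval_eer_field(spec, x)))
    trk <- extract_growth_traits(velocity_profile(x, k * v),
                                 eer_profile(x, k * eval_eer_field(spec, x)))
    expect_equal(trk$growth_rate, k * tr1$growth_rate, tolerance = 1e-10)
    expect_equal(trk$eer_max, k * tr1$eer_max, tolerance = 1e-10)
    expect_equal(trk$eer_max_abscissa, tr1$eer_max_abscissa, tolerance = 1e-8)
    # relative rule: growth zone length is scale-free
    expect_equal(trk$gz_length, tr1$gz_length, tolerance = 1e-8)
  }
})

test_that("the EER integral over the growth zone matches the growth rate", {
  for (seed in c(3, 4)) {
    spec <- random_growth_field_spec(seed)
    x <- seq(0, spec$gz_length * 1.3, by = 0.002)
    ep <- eer_profile(x, eval_eer_field(spec, x))
    vp <- velocity_profile(x, field_velocity(spec, x))
    tr <- extract_growth_traits(vp, ep)
    inside <- x <= tr$gz_length
    integral <- sum(diff(x[inside]) *
                      (ep$eer_per_h[inside][-1] + head(ep$eer_per_h[inside], -1)) / 2)
    expect_lt(abs(integral - tr$growth_rate), 3 * 0.03 * tr$eer_max * tr$gz_length)
  }
})

test_that("traits are recovered from noisy profiles within field tolerances", {
  errs <- list(gr = c(), eer = c(), gz = c())
  for (seed in 1:20) {
    spec <- random_growth_field_spec(seed)
    truth <- field_truth_traits(spec)
    x <- seq(0, spec$gz_length * 1.3, by = 0.05)
    for (rep in 1:10) {
      vmax <- field_velocity(spec, spec$gz_length)
      vp <- simulate_velocity_profile(spec, x, noise_sd = 0.05 * vmax,
                                      seed = 1000 * seed + rep)
      sm <- smooth_velocity(vp)
      tr <- try(extract_growth_traits(sm, compute_eer(sm)), silent = TRUE)
      if (inherits(tr, "try-error")) {  # counted as a miss, not skipped
        errs$gr <- c(errs$gr, Inf); errs$eer <- c(errs$eer, Inf)
        errs$gz <- c(errs$gz, Inf)
        next
      }
      errs$gr <- c(errs$gr, abs(tr$growth_rate - truth$growth_rate) / truth$growth_rate)
      errs$eer <- c(errs$eer, abs(tr$eer_max - truth$eer_max) / truth$eer_max)
      errs$gz <- c(errs$gz, abs(tr$gz_length - truth$gz_length))
    }
  }
  expect_lt(stats::median(errs$gr), 0.05)
  expect_lt(stats::median(errs$eer), 0.10)
  expect_lt(stats::median(errs$gz), 0.3)
})
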