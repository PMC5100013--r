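test_that("triangular field has its closed-form values", {
  spec <- tri_spec()
  expect_equal(eval_eer_field(spec, 3), 0.3)              # peak by construction
  expect_equal(eval_eer_field(spec, 7), 0)                # beyond growth zone
  expect_equal(eval_eer_field(spec, 0), 0)
  expect_equal(field_velocity(spec, 10), 0.9)             # triangle area
  expect_equal(field_velocity(spec, 0), 0)
  expect_equal(field_velocity(spec, 1.5), 0.1125)         # quadratic branch
})

test_that("gaussian-windowed field matches an independent closed-form evaluation", {
  spec <- growth_field_spec(eer_max = 0.35, x_peak = 2.2, gz_length = 5.5,
                            dz_length = 1.4, shape = "gaussian-windowed")
  x <- seq(0, 7, length.out = 200)
  # independent re-evaluation: Gaussian bump shifted to zero at gz
  sigma <- (5.5 - 2.2) / 2.5
  cc <- exp(-2.5^2 / 2)
  expected <- 0.35 * pmax(0, (exp(-(x - 2.2)^2 / (2 * sigma^2)) - cc) / (1 - cc))
  expected[x >= 5.5] <- 0
  expect_equal(eval_eer_field(spec, x), expected, tolerance = 1e-12)
})

test_that("field is non-negative, unimodal-peaked, and zero beyond the growth zone", {
  for (sh in c("beta-kernel", "triangular", "gaussian-windowed")) {
    spec <- growth_field_spec(eer_max = 0.3, x_peak = 2.5, gz_length = 6,
                              dz_length = 1.5, shape = sh)
    x <- seq(0, 8, by = 0.01)
    e <- eval_eer_field(spec, x)
    expect_true(all(e >= 0), info = sh)
    expect_true(all(e[x >= 6] == 0), info = sh)
    expect_equal(max(e), 0.3, tolerance = 1e-6, info = sh)
    expect_equal(x[which.max(e)], 2.5, tolerance = 0.01, info = sh)
  }
})

test_that("closed-form velocity matches adaptive quadrature of the field", {
  for (sh in c("beta-kernel", "triangular", "gaussian-windowed")) {
    spec <- growth_field_spec(eer_max = 0.3, x_peak = 2.5, gz_length = 6,
                              dz_length = 1.5, shape = sh)
    xs <- c(0.4, 1.3, 2.5, 3.7, 5.2, 6.5)
    vq <- vapply(xs, function(xx) {
      stats::integrate(function(s) eval_eer_field(spec, s), 0, xx,
                       rel.tol = 1e-10)$value
    }, numeric(1))
    expect_equal(field_velocity(spec, xs), vq, tolerance = 1e-6, info = sh)
  }
})

test_that("velocity and EER are exact duals on a fine grid", {
  x <- seq(0, 7, by = 0.01)  # 10 um grid
  for (sh in c("beta-kernel", "triangular", "gaussian-windowed")) {
    spec <- growth_field_spec(eer_max = 0.3, x_peak = 2.5, gz_length = 6,
                              dz_length = 1.5, shape = sh)
    v <- field_velocity(spec, x)
    d_central <- (v[-(1:2)] - v[1:(length(v) - 2)]) / (2 * 0.01)
    e <- eval_eer_field(spec, x[-c(1, length(x))])
    expect_lt(max(abs(d_central - e)), 1e-4 + 0.02 * (sh == "triangular"))
  }
})

test_that("step-stress scenario gives the two-phase response", {
  sc <- step_stress_scenario(scale = 0.5)
  expect_equal(stress_multiplier(sc, c(-1, -0.01)), c(1, 1))
  # new steady state is exactly the scaled copy from t_steady onwards
  expect_equal(stress_multiplier(sc, c(2, 2.5, 5)), c(0.5, 0.5, 0.5))
  tt <- seq(0, 2, by = 0.01)
  s <- stress_multiplier(sc, tt)
  expect_true(all(s >= 0))
  expect_lt(s[1], 0.2)                       # abrupt collapse at onset
  expect_gt(max(s), 0.5)                     # transient overshoots the plateau
  expect_lt(tt[which.max(s)], 1)             # maximum within the first hour
  spec <- growth_field_spec(eer_max = 0.3, x_peak = 2.5, gz_length = 6,
                            dz_length = 1.5, stress_scenario = sc)
  x <- seq(0, 6, by = 0.05)
  expect_equal(eval_eer_field(spec, x, t = 3),
               0.5 * eval_eer_field(spec, x, t = -1))
})

test_that("spec validation rejects inconsistent geometry and unknown shapes", {
  expect_error(growth_field_spec(x_peak = 7, gz_length = 6), "x_peak")
  expect_error(growth_field_spec(dz_length = 6, gz_length = 6), "dz_length")
  expect_error(growth_field_spec(eer_max = -1), "eer_max")
  expect_error(growth_field_spec(shape = "boxcar"))
  bad <- tri_spec()
  bad$shape <- "boxcar"
  expect_error(eval_eer_field(bad, 1), "unknown EER field shape")
  expect_error(eval_eer_field(tri_spec(), -1), "x")
})

test_that("random spec generator is deterministic and in range", {
  s1 <- random_growth_field_spec(7)
  s2 <- random_growth_field_spec(7)
  expect_identical(s1, s2)
  for (seed in 1:10) {
    s <- random_growth_field_spec(seed)
    expect_true(s$eer_max >= 0.2 && s$eer_max <= 0.4)
    expect_true(s$x_peak > 0 && s$x_peak < s$gz_length)
    expect_true(s$dz_length < s$gz_length)
    gr <- field_velocity(s, s$gz_length)
    expect_true(gr > 0.3 && gr < 1.6)  # realistic tip velocities
  }
})
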