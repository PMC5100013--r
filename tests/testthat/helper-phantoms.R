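# Shared fixtures and independent oracles, built in code.

# The triangular field with closed-form traits used throughout:
# growth rate 0.9 mm/h, gz 5.91 mm (relative 3% rule), ez 4.41 mm.
tri_spec <- function() {
  growth_field_spec(eer_max = 0.3, x_peak = 3, gz_length = 6, dz_length = 1.5,
                    shape = "triangular")
}

# A compact phantom whose mature region fits a 512 px frame at 10 um/px:
# growth rate 0.9 mm/h with a 3 mm growth zone.
compact_spec <- function() {
  growth_field_spec(eer_max = 0.6, x_peak = 1.2, gz_length = 3,
                    dz_length = 0.8, shape = "triangular")
}

# Blob texture image (band-limited, so subpixel interpolation is meaningful).
make_texture <- function(nrow = 64, ncol = 128, n_blobs = 120, seed = 1) {
  set.seed(seed)
  img <- matrix(0.1, nrow, ncol)
  cx <- runif(n_blobs, 4, ncol - 3)
  cy <- runif(n_blobs, 4, nrow - 3)
  amp <- runif(n_blobs, 0.4, 1)
  for (i in seq_len(n_blobs)) {
    r <- (round(cy[i]) - 3):(round(cy[i]) + 3)
    cc <- (round(cx[i]) - 3):(round(cx[i]) + 3)
    d2 <- outer((r - cy[i])^2, (cc - cx[i])^2, `+`)
    img[r, cc] <- img[r, cc] + amp[i] * exp(-d2 / (2 * 1.3^2))
  }
  img
}

# Exact subpixel shift along columns by Fourier interpolation (the
# independent shift oracle for the PIV tests).
fourier_shift_cols <- function(img, s) {
  n <- ncol(img)
  k <- c(0:floor(n / 2), seq.int(-(n - floor(n / 2) - 1), -1))
  stopifnot(length(k) == n)
  ph <- exp(-2i * pi * k * s / n)
  F <- stats::mvfft(t(img))
  Re(t(stats::mvfft(F * ph, inverse = TRUE)) / n)
}

# Fixed-step RK4 integration of dx/dt = v(x, t): the trajectory oracle,
# independent of the deSolve-backed renderer.
rk4_trajectory <- function(spec, x0, times, n_sub = 50) {
  out <- matrix(NA_real_, length(times), length(x0))
  out[1, ] <- x0
  x <- x0
  for (i in seq_len(length(times) - 1)) {
    h <- (times[i + 1] - times[i]) / n_sub
    t <- times[i]
    v_of <- function(x, t) ifelse(x > 0, field_velocity(spec, pmax(x, 0), t), 0)
    for (j in seq_len(n_sub)) {
      k1 <- v_of(x, t)
      k2 <- v_of(x + h / 2 * k1, t + h / 2)
      k3 <- v_of(x + h / 2 * k2, t + h / 2)
      k4 <- v_of(x + h * k3, t + h)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i + 1, ] <- x
  }
  out
}

# Brute-force Benjamini-Hochberg step-up (independent of stats::p.adjust).
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Repeated-measures one-way ANOVA by explicit sums of squares.
rm_anova_bruteforce <- function(mat) {  # roots x times
  n <- nrow(mat); t <- ncol(mat)
  grand <- mean(mat)
  ss_time <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- t * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  df1 <- t - 1; df2 <- (t - 1) * (n - 1)
  F <- (ss_time / df1) / (ss_err / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# Textbook paired t statistic.
paired_t_bruteforce <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}

# The 32 sample column names of the full 2x2x2 design with 4 replicates.
design_units_fixture <- function() {
  g <- expand.grid(rep = 1:4, time = c("0.5h", "3h"),
                   treatment = c("CTL", "PEG"), zone = c("DZ", "EZ"),
                   stringsAsFactors = FALSE)
  paste0(g$zone, "_", g$treatment, "_", g$time, "_R", g$rep)
}

# Ground-truth growth traits of a field, from dense analytic profiles.
field_truth_traits <- function(spec, gz_rule = "relative", gz_threshold = 0.03) {
  field_growth_traits(spec, gz_rule = gz_rule, gz_threshold = gz_threshold)
}
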