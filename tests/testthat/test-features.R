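mk_time <- function(horizon = 31) seq(-2, horizon, by = 1)

test_that("maximum amplitude subtracts the pre-stimulus mean over a 24-h window", {
  time <- mk_time()
  tr <- rep(10, length(time))
  tr[time == 5] <- 50
  expect_equal(max_amplitude(tr, time), 40)

  expect_equal(max_amplitude(rep(7, length(time)), time), 0)

  # a later peak is outside the window
  tr2 <- rep(10, length(time))
  tr2[time == 27] <- 99
  tr2[time == 5] <- 30
  expect_equal(max_amplitude(tr2, time), 20)

  expect_error(max_amplitude(1:5, c(0, 1, 2, 3, 4)), "pre-onset")
})

test_that("lag time is the first crossing of 1.5x the three-frame baseline", {
  time <- mk_time()
  tr <- rep(10, length(time))
  tr[time >= 6] <- 15.2
  expect_equal(lag_time(tr, time), 6)

  expect_true(is.na(lag_time(rep(10, length(time)) +
                               c(0, 0, 0, rep(4, length(time) - 3)), time)))

  # exact equality counts as reached (inclusive convention)
  tr3 <- rep(10, length(time))
  tr3[time >= 3] <- 15
  expect_equal(lag_time(tr3, time), 3)

  expect_error(lag_time(rep(0, length(time)), time), "baseline")
})

test_that("half-max width matches geometry and a Gaussian FWHM oracle", {
  # symmetric triangle: baseline 0, peak 10 at 5 h, zeros at 0 and 10 h
  time <- mk_time(20)
  tri <- pmax(0, 10 - 2 * abs(time - 5))
  expect_equal(as.numeric(half_max_width(tri, time)), 5)

  # sampled Gaussian pulse: width ~ 2.355 sigma within one grid step
  sigma <- 2.5
  gau <- 30 * exp(-(time - 8)^2 / (2 * sigma^2))
  w <- half_max_width(gau, time)
  expect_lt(abs(as.numeric(w) - 2 * sqrt(2 * log(2)) * sigma), 1)
  expect_false(attr(w, "censored"))

  # plateau that never descends is right-censored
  plat <- c(0, 0, seq(0, 20, length.out = length(time) - 2))
  wp <- half_max_width(plat, time)
  expect_true(attr(wp, "censored"))

  expect_error(half_max_width(rep(1, length(time)), time), "peak")
})

test_that("tanh induction fit recovers slope a*c and pulse amplitude 2*c", {
  time <- mk_time()
  truth <- list(a = 0.5, b = -2, c = 20, d = 5)
  y <- tanh(truth$a * time + truth$b) * truth$c + truth$d
  f <- tanh_fit(y, time)
  expect_true(f$converged)
  expect_equal(f$slope, 10, tolerance = 1e-6)
  expect_equal(f$pulse_amplitude, 40, tolerance = 1e-6)

  flat <- tanh_fit(rep(3, length(time)), time)
  expect_lt(abs(flat$slope), 1e-4)

  # 5% noise: slope recovered within 5% on average over seeded repeats
  set.seed(808)
  slopes <- replicate(100, {
    yn <- y + rnorm(length(y), 0, 0.05 * truth$c)
    tanh_fit(yn, time)$slope
  })
  expect_lt(abs(mean(slopes) - 10) / 10, 0.05)
})

test_that("CV is scale-invariant and matches hand arithmetic", {
  time <- mk_time(3)
  m <- matrix(rep(c(1, 3), each = length(time)), nrow = 2, byrow = TRUE)
  tm <- trace_matrix(m, time)
  expect_equal(cv_over_time(tm)$cv, rep(sqrt(2) / 2, length(time)))

  ident <- trace_matrix(matrix(5, 4, length(time)), time)
  expect_equal(cv_over_time(ident)$cv, rep(0, length(time)))

  expect_equal(cv_over_time(trace_matrix(7 * m, time))$cv,
               cv_over_time(tm)$cv)

  expect_equal(feature_cv(c(1, 3)), sqrt(2) / 2)
})

test_that("pulse amplitudes are measured independently per pulse window", {
  time <- mk_time()
  tr <- rep(12, length(time))
  tr[time == 5] <- 30
  expect_equal(as.numeric(pulse_amplitude_window(tr, time, 0)), 18)

  dec <- 50 - time
  expect_equal(as.numeric(pulse_amplitude_window(dec, time, 0)), 0)

  # two-pulse construction with known per-pulse increments
  tr2 <- rep(5, length(time))
  tr2[time >= 2 & time <= 8] <- 25          # +20 in pulse-1 window
  tr2[time >= 16 & time <= 22] <- 40        # +35 over onset value 5
  a1 <- pulse_amplitude_window(tr2, time, 0, 4, mode = "simulation")
  a2 <- pulse_amplitude_window(tr2, time, 14, 18, mode = "simulation")
  expect_equal(as.numeric(a1), 20)
  expect_equal(as.numeric(a2), 35)
})

test_that("responder classes and conditional probabilities follow the threshold", {
  amp <- rbind(c(10, 1), c(1, 10), c(10, 10), c(1, 1), c(8, 9))
  cls <- classify_responders(amp, threshold = 5)
  expect_equal(as.character(cls$classes),
               c("+/-", "-/+", "+/+", "-/-", "+/+"))
  expect_equal(cls$p_resp2_given_resp1, 2 / 3)
  expect_equal(cls$p_resp2_given_nonresp1, 1 / 2)
  expect_error(classify_responders(amp, threshold = 0), "threshold")
})

test_that("feature correlation handles identity, orthogonal, and sampled cases", {
  expect_equal(feature_correlation(1:10, 1:10)$r, 1)
  alt <- rep(c(1, -1), 50)
  expect_lt(abs(feature_correlation(alt, rep(c(1, 1, -1, -1), 25))$r), 0.15)
  expect_true(is.na(feature_correlation(rep(1, 5), 1:5)$r))

  set.seed(99)
  x <- rnorm(500)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(500)
  est <- feature_correlation(x, y)
  expect_equal(est$n, 500)
  expect_lt(abs(est$r - 0.5), 0.1)
})

test_that("features ignore extra leading pre-stimulus frames and track gain", {
  time <- mk_time()
  tr <- 10 + pmax(0, 30 * sin(pmin(pmax(time, 0), 12) * pi / 12))
  time_ext <- c(-4, -3, time)
  tr_ext <- c(10, 10, tr)
  expect_equal(max_amplitude(tr, time), max_amplitude(tr_ext, time_ext))
  expect_equal(lag_time(tr, time), lag_time(tr_ext, time_ext))

  # amplitude is equivariant under gain; lag invariant under gain
  g <- 3.7
  expect_equal(max_amplitude(g * tr, time), g * max_amplitude(tr, time))
  expect_equal(lag_time(g * tr, time), lag_time(tr, time))
  expect_equal(as.numeric(pulse_amplitude_window(g * tr, time, 0)),
               g * as.numeric(pulse_amplitude_window(tr, time, 0)))
})

test_that("the feature table covers every cell with the expected columns", {
  kin <- preset_kinetics("IRF1")
  tm <- gen_population(kin, preset_adaptation(), "constant:10", n_cells = 30,
                       seed = 4)
  ft <- extract_features(tm, width = TRUE, tanh_features = TRUE)
  expect_equal(nrow(ft), 30)
  expect_true(all(c("baseline", "max_amplitude", "lag_time", "width",
                    "slope", "pulse_amplitude") %in% names(ft)))
  expect_true(all(ft$max_amplitude > 0))
})
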