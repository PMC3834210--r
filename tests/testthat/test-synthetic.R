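test_that("discrete source is a unit-peak bump with controlled width", {
  d <- make_discrete_source(350, center = 0.5, width = 0.1)
  expect_equal(which.max(d), 176, tolerance = 1)      # sample 175, 0-based
  expect_equal(max(d), 1)
  expect_lt(max(d[1], d[350]), 1e-3)                  # zero at boundaries
  narrow <- make_discrete_source(350, 0.5, 0.02)
  wide <- make_discrete_source(350, 0.5, 0.2)
  expect_lt(sum(narrow > 0.01), sum(wide > 0.01))
  # integral against an independent trapezoid-rule oracle on a fine grid
  f <- function(u) exp(-0.5 * ((u - 0.5) / 0.1)^2)
  u_fine <- seq(0, 1, length.out = 20001)
  trap <- sum((f(u_fine)[-1] + f(u_fine)[-20001]) / 2) * (1 / 20000)
  expect_equal(mean(d), trap, tolerance = 1e-4)
  expect_error(make_discrete_source(100, center = 1.2, width = 0.1), "center")
})

test_that("rhythmic source has exactly two peaks, periodic wrap and phase control", {
  r <- make_rhythmic_source(350, phase = 0.1, peak_ratio = 0.8)
  d1 <- diff(c(r[350], r, r[1]))
  expect_equal(sum(d1[-length(d1)] > 0 & d1[-1] <= 0), 2)  # circular maxima
  expect_equal(max(r), 1)
  # periodic at the wrap-around: the jump and curvature across the boundary
  # are no larger than anywhere in the interior
  expect_lte(abs(r[1] - r[350]), 1.05 * max(abs(diff(r))))
  dd <- diff(c(r[349:350], r[1:2]))
  expect_lte(abs(diff(dd))[2], 1.5 * max(abs(diff(r, differences = 2))))

  # phase moves the waveform by a quarter period (circular cross-correlation)
  r0 <- make_rhythmic_source(352, 0)
  r25 <- make_rhythmic_source(352, 0.25)
  cc <- vapply(0:351, function(s)
    sum(r0 * r25[((0:351 + s) %% 352) + 1]), numeric(1))
  expect_equal(which.max(cc) - 1, 88, tolerance = 1)

  # equal peak heights at ratio 1
  req <- make_rhythmic_source(350, 0.1, peak_ratio = 1)
  pk <- sort(req, decreasing = TRUE)[1:2]
  expect_equal(pk[1], pk[2], tolerance = 1e-9)
})

test_that("mixtures follow the anechoic generative model exactly", {
  base <- list(sources = list(list(kind = "discrete", center = 0.5, width = 0.1)),
               weights = matrix(1, 1, 1), delay_mean = matrix(0, 1, 1),
               delay_sd = matrix(0, 1, 1), noise_sigma = 0,
               n_trials = 1, n_samples = 64, sample_rate = 64, seed = 5)
  # identity mixture: one channel equals the source
  d0 <- make_mixture_dataset(do.call(scenario_config, base))
  expect_equal(d0$trajectories$data[1, ], d0$truth$sources[1, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # half-period delay = circular shift by T/2 samples
  base$delay_mean <- matrix(0.5, 1, 1)   # 32 samples at 64 Hz
  d1 <- make_mixture_dataset(do.call(scenario_config, base))
  expect_equal(d1$trajectories$data[1, ], d0$truth$sources[1, c(33:64, 1:32)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noiseless channel variance matches a brute-force time-domain oracle", {
  # integer delays so the oracle is plain index shifting
  cfg <- scenario_config(
    n_trials = 2, n_samples = 100, sample_rate = 100,
    sources = list(list(kind = "discrete", center = 0.4, width = 0.08),
                   list(kind = "rhythmic", phase = 0.2, peak_ratio = 0.7)),
    weights = cbind(c(1, 0.3, 0.6), c(0.2, 1, 0.8)),
    delay_mean = cbind(c(0.05, 0.10, 0), c(0.12, 0, 0.30)),
    delay_sd = matrix(0, 3, 2), noise_sigma = 0, seed = 9)
  dat <- make_mixture_dataset(cfg)
  shift_int <- function(y, d) y[((seq_along(y) - 1 - d) %% length(y)) + 1]
  grp <- rep(1:3, times = 2)
  for (i in seq_len(nrow(dat$trajectories$data))) {
    g <- grp[i]
    oracle <- cfg$weights[g, 1] * shift_int(dat$truth$sources[1, ],
                                            round(cfg$delay_mean[g, 1] * 100)) +
      cfg$weights[g, 2] * shift_int(dat$truth$sources[2, ],
                                    round(cfg$delay_mean[g, 2] * 100))
    expect_equal(var(dat$trajectories$data[i, ]), var(oracle), tolerance = 1e-9)
    expect_equal(dat$trajectories$data[i, ], oracle, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("generation is seed-deterministic and noise scales correctly", {
  cfg <- gait_reach_config(n_trials = 8, noise_sigma = 0.05, seed = 21)
  a <- make_mixture_dataset(cfg)
  b <- make_mixture_dataset(cfg)
  expect_identical(a$trajectories$data, b$trajectories$data)
  expect_identical(a$truth$delays, b$truth$delays)

  # residual SD of (data - noiseless part) matches noise_sigma within 15%
  cfg2 <- gait_reach_config(n_trials = 40, noise_sigma = 0.05, seed = 22)
  dat <- make_mixture_dataset(cfg2)   # 240 x 350 > 1e4 values
  resid <- dat$trajectories$data - truth_reconstruct(dat$truth)
  expect_equal(sd(resid), 0.05, tolerance = 0.15)
})

test_that("default sources are band-limited to the first ten harmonics", {
  for (src in list(make_discrete_source(350, 0.45, 0.1),
                   make_rhythmic_source(350, 0.1, 0.8))) {
    p <- Mod(fft(src - mean(src)))^2
    in_band <- sum(p[2:11]) + sum(p[341:350])
    expect_gte(in_band / sum(p[-1]), 0.999)
  }
})

test_that("gait fixture carries consistent ground-truth events", {
  fx <- make_gait_marker_fixture(n_strides = 2, cadence = 1.25,
                                 noise_sigma = 0, seed = 1)
  expect_equal(sum(fx$events$type == "RTL"), 2)
  expect_equal(sum(fx$events$type == "LTL"), 2)
  # exactly one global maximum on the hand channel
  h <- fx$trajectories$data["hand_dist", ]
  expect_equal(sum(h == max(h)), 1)

  # noiseless detection agrees with the truth to within one sample
  fx4 <- make_gait_marker_fixture(n_strides = 4, cadence = 1.25,
                                  noise_sigma = 0, seed = 1)
  rate <- fx4$trajectories$sample_rate
  tl <- detect_foot_events(fx4$trajectories$data["R_toe_z", ], rate,
                           marker = "toe", foot = "R")
  truth <- sort(fx4$events$time[fx4$events$type == "RTL"])
  expect_lt(max(abs(sort(tl$time) - truth)), 1 / rate)

  expect_error(make_gait_marker_fixture(n_strides = 1), "at least 2")
  expect_error(make_gait_marker_fixture(4, cadence = -1), "positive")
})
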