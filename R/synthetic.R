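# Ground-truth generators: anechoic mixtures of a discrete (bell-shaped) and
# a rhythmic (two-peaked) source, and gait-like marker fixtures with known
# event times. Everything is seeded and deterministic.

#' Bell-shaped discrete source waveform
#'
#' A unit-peak Gaussian bump over one record, wrapped periodically so the
#' waveform is smooth across the circular boundary. Emulates the discrete
#' (reach-like) primitive: a single bump.
#'
#' @param n_samples Record length (>= 16).
#' @param center Peak position as a fraction of the record, in `[0, 1]`.
#' @param width Gaussian standard deviation as a fraction of the record,
#'   in `(0, 1)`.
#' @return Numeric vector of length `n_samples`, maximum 1.
#' @export
make_discrete_source <- function(n_samples = 350L, center = 0.5, width = 0.1) {
  if (center < 0 || center > 1) abort("`center` must lie in [0, 1].")
  if (width <= 0 || width >= 1) abort("`width` must lie in (0, 1).")
  u <- (0:(n_samples - 1L)) / n_samples
  y <- rep(0, n_samples)
  for (wrap in -1:1) y <- y + exp(-0.5 * ((u - center + wrap) / width)^2)
  y / max(y)
}

#' Rhythmic two-peaked source waveform
#'
#' A periodic waveform with exactly two local maxima per record (counted
#' circularly), emulating the rhythmic (gait-like) primitive over a window
#' spanning two gait cycles: one flexion peak per cycle, so two per window.
#' Each peak is a wrapped Gaussian bump, which gives the spread harmonic
#' content of real joint-angle cycles rather than a pure tone;
#' `peak_ratio` sets the height of the second peak relative to the first.
#'
#' @param n_samples Record length (>= 16).
#' @param phase Circular phase offset as a fraction of the record.
#' @param peak_ratio Second/first peak height ratio, in `(0, 1]`.
#' @param width Gaussian width of each peak as a fraction of the record
#'   (default 0.09).
#' @return Numeric vector of length `n_samples`, maximum 1, periodic in
#'   value and first difference.
#' @export
make_rhythmic_source <- function(n_samples = 350L, phase = 0, peak_ratio = 1,
                                 width = 0.09) {
  if (n_samples < 16L) abort("`n_samples` must be at least 16.")
  if (peak_ratio <= 0 || peak_ratio > 1) abort("`peak_ratio` must be in (0, 1].")
  if (width <= 0 || width >= 0.25) abort("`width` must lie in (0, 0.25).")
  u <- (0:(n_samples - 1L)) / n_samples
  bump <- function(center) {
    y <- rep(0, n_samples)
    for (wrap in -1:1) y <- y + exp(-0.5 * ((u - center + wrap) / width)^2)
    y
  }
  y <- bump(phase %% 1) + peak_ratio * bump((phase + 0.5) %% 1)
  y / max(y)
}

#' Scenario configuration for synthetic anechoic mixtures
#'
#' Bundles every hidden parameter of the generative model
#' `x_i = sum_j a[g(i), j] s_j(t - tau_ij) + noise`: the source shapes, the
#' per-channel-group mixing weights, the per-(group, source) Gaussian delay
#' distributions, the noise level and the seed. Channels are generated as
#' `n_trials` repetitions of the group layout, with fresh delay and noise
#' draws per trial.
#'
#' @param n_trials Number of trials (each contributes one channel per group).
#' @param n_samples Samples per channel (>= 16, default 350).
#' @param sample_rate Sampling rate in Hz (default 120).
#' @param sources List of source specs: each a list with `kind`
#'   (`"discrete"` or `"rhythmic"`) plus the shape arguments of
#'   [make_discrete_source()] / [make_rhythmic_source()].
#' @param weights Numeric matrix, groups x sources, non-negative by default.
#' @param delay_mean,delay_sd Numeric matrices (groups x sources) of the
#'   per-trial Gaussian delay distributions, in seconds; `delay_sd >= 0`.
#' @param noise_sigma Additive Gaussian noise SD (>= 0), signal units.
#' @param group_labels Character vector of group names (length = rows of
#'   `weights`).
#' @param seed Integer seed.
#' @return A `scenario_config` list.
#' @seealso [gait_reach_config()], [make_mixture_dataset()]
#' @export
scenario_config <- function(n_trials, n_samples = 350L, sample_rate = 120,
                            sources, weights, delay_mean, delay_sd,
                            noise_sigma = 0.05, group_labels = NULL,
                            seed = 1L) {
  weights <- as.matrix(weights)
  delay_mean <- as.matrix(delay_mean); delay_sd <- as.matrix(delay_sd)
  if (n_samples < 16L) abort("`n_samples` must be at least 16.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (any(delay_sd < 0)) abort("`delay_sd` entries must be >= 0.")
  if (length(sources) != ncol(weights))
    abort("`weights` must have one column per source.")
  if (!all(dim(delay_mean) == dim(weights)) ||
      !all(dim(delay_sd) == dim(weights)))
    abort("`delay_mean`/`delay_sd` must match the shape of `weights`.")
  if (is.null(group_labels)) group_labels <- paste0("g", seq_len(nrow(weights)))
  structure(list(n_trials = as.integer(n_trials), n_samples = as.integer(n_samples),
                 sample_rate = sample_rate, sources = sources, weights = weights,
                 delay_mean = delay_mean, delay_sd = delay_sd,
                 noise_sigma = noise_sigma, group_labels = group_labels,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Default gait-reach scenario
#'
#' Two ground-truth sources over a window spanning two gait cycles: a
#' discrete bell-shaped source loaded mainly on the right-shoulder channels
#' (the reach) and a rhythmic two-peaked source whose weights grow toward
#' the lower-body channels (the gait), with left-side rhythmic delays offset
#' by half a gait cycle and per-trial Gaussian delay jitter. Six channel
#' groups emulate right/left shoulder, hip and knee flexion angles.
#'
#' @param n_trials Number of trials (default 40).
#' @param noise_sigma Noise SD (default 0.05; sources are unit-peak).
#' @param delay_sd Per-trial delay jitter SD in seconds (default 0.08).
#' @param seed Integer seed.
#' @param n_samples,sample_rate Record geometry (350 samples at 120 Hz,
#'   i.e. ~2.9 s covering two ~1.46 s gait cycles).
#' @return A [scenario_config()].
#' @export
gait_reach_config <- function(n_trials = 40L, noise_sigma = 0.05,
                              delay_sd = 0.08, seed = 1L,
                              n_samples = 350L, sample_rate = 120) {
  groups <- c("RShoulder", "LShoulder", "RHip", "LHip", "RKnee", "LKnee")
  half_cycle <- (n_samples / 2) / sample_rate / 2   # half of one gait cycle, s
  scenario_config(
    n_trials = n_trials, n_samples = n_samples, sample_rate = sample_rate,
    sources = list(
      list(kind = "discrete", center = 0.45, width = 0.1),
      list(kind = "rhythmic", phase = 0.1, peak_ratio = 0.8)
    ),
    weights = cbind(discrete = c(1.0, 0.25, 0.15, 0.12, 0.10, 0.08),
                    rhythmic = c(0.25, 0.30, 0.70, 0.75, 1.00, 0.95)),
    delay_mean = cbind(c(0, 0, 0, 0, 0, 0),
                       c(0, 0, 0, half_cycle, 0, half_cycle)),
    delay_sd = matrix(delay_sd, 6, 2),
    noise_sigma = noise_sigma, group_labels = groups, seed = seed
  )
}

# exact fractional circular shifts of one series: rows = one shifted copy per
# entry of tau (samples); frequency-domain phase ramp on signed frequencies
shift_rows <- function(s, tau) {
  Tn <- length(s)
  kk <- c(0:floor(Tn / 2), -(ceiling(Tn / 2) - 1):-1)
  if (Tn %% 2 == 0) kk <- c(0:(Tn / 2), -(Tn / 2 - 1):-1)
  s_hat <- fft(s)
  E <- exp(-2i * pi * outer(tau, kk) / Tn)
  B <- E * matrix(s_hat, length(tau), Tn, byrow = TRUE)
  t(Re(stats::mvfft(t(B), inverse = TRUE))) / Tn
}

build_source <- function(spec, n_samples) {
  switch(spec$kind,
    discrete = make_discrete_source(n_samples,
                                    center = spec$center %||% 0.5,
                                    width = spec$width %||% 0.1),
    rhythmic = make_rhythmic_source(n_samples,
                                    phase = spec$phase %||% 0,
                                    peak_ratio = spec$peak_ratio %||% 1),
    abort(paste("Unknown source kind:", spec$kind))
  )
}

#' Generate a ground-truth anechoic mixture dataset
#'
#' Draws per-(channel, source) delays from the configured Gaussian
#' distributions, synthesizes every channel as the weighted sum of
#' circularly delayed sources plus Gaussian noise, and returns the hidden
#' parameters alongside the data. Identical seeds give bit-identical output.
#'
#' @param cfg A [scenario_config()].
#' @return List with `trajectories` (a [trajectory_set()]; channels are
#'   trial x group, labelled `t<trial>_<group>`) and `truth` (class
#'   `ground_truth`: `sources` matrix N x T, `weights` and `delays`
#'   (channels x N, delays in seconds), `noise_sigma`, `group_labels`).
#' @export
make_mixture_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  Tn <- cfg$n_samples
  G <- nrow(cfg$weights); N <- ncol(cfg$weights)
  M <- cfg$n_trials * G
  src <- t(vapply(cfg$sources, build_source, numeric(Tn), n_samples = Tn))
  grp <- rep(seq_len(G), times = cfg$n_trials)
  with_local_seed(cfg$seed, {
    delays <- matrix(0, M, N)
    for (j in seq_len(N))
      delays[, j] <- rnorm(M, cfg$delay_mean[grp, j], cfg$delay_sd[grp, j])
    X <- matrix(0, M, Tn)
    W <- cfg$weights[grp, , drop = FALSE]
    for (j in seq_len(N))
      X <- X + W[, j] * shift_rows(src[j, ], delays[, j] * cfg$sample_rate)
    noise <- matrix(rnorm(M * Tn, 0, cfg$noise_sigma), M, Tn)
    labels <- paste0("t", sprintf("%02d", rep(seq_len(cfg$n_trials), each = G)),
                     "_", cfg$group_labels[grp])
    ts <- trajectory_set(X + noise, cfg$sample_rate, channel_labels = labels,
                         trial_ids = rep(seq_len(cfg$n_trials), each = G),
                         conditions = NULL)
    truth <- structure(list(sources = src, weights = W, delays = delays,
                            noise_sigma = cfg$noise_sigma,
                            group_labels = cfg$group_labels[grp],
                            config = cfg),
                       class = "ground_truth")
    list(trajectories = ts, truth = truth)
  })
}

#' Noiseless reconstruction from a ground truth
#'
#' @param truth A `ground_truth` from [make_mixture_dataset()].
#' @return Channels x samples matrix of the noiseless mixture.
#' @export
truth_reconstruct <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  Tn <- ncol(truth$sources)
  rate <- truth$config$sample_rate
  X <- matrix(0, nrow(truth$weights), Tn)
  for (j in seq_len(ncol(truth$weights)))
    X <- X + truth$weights[, j] *
      shift_rows(truth$sources[j, ], truth$delays[, j] * rate)
  X
}

#' Synthetic gait marker fixture with known event times
#'
#' Builds vertical toe and heel position channels for both feet plus a
#' hand-to-origin distance channel, with analytically known toe-lift, heel
#' -strike and reach-peak times, so the event-detection pipeline can be
#' validated end to end. Toe channels have one minimum per gait cycle at the
#' lift time; heel channels one maximum at the strike time; the hand channel
#' oscillates with the gait and carries one dominant reach bump.
#'
#' @param n_strides Number of gait cycles (>= 2).
#' @param cadence Gait-cycle duration in seconds (> 0; default 1.25).
#' @param noise_sigma Additive position noise SD in metres (default 0).
#' @param seed Integer seed for the noise.
#' @param sample_rate Sampling rate in Hz (default 120).
#' @param stance_fraction Stance phase as a fraction of the cycle
#'   (default 0.6).
#' @return List with `trajectories` (channels `R_toe_z`, `R_heel_z`,
#'   `L_toe_z`, `L_heel_z`, `hand_dist`), `events` (tibble `time`, `type`
#'   with types RTL/RHS/LTL/LHS) and `reach_time` (seconds).
#' @export
make_gait_marker_fixture <- function(n_strides = 4L, cadence = 1.25,
                                     noise_sigma = 0, seed = 1L,
                                     sample_rate = 120, stance_fraction = 0.6) {
  if (n_strides < 2L) abort("`n_strides` must be at least 2.")
  if (cadence <= 0) abort("`cadence` must be positive.")
  cyc <- cadence
  total <- n_strides * cyc
  tt <- seq(0, total, by = 1 / sample_rate)
  swing <- 1 - stance_fraction
  t0_R <- 0.4 * cyc              # first right toe lift
  t0_L <- t0_R + 0.5 * cyc       # left foot in anti-phase
  toe_wave <- function(t_lift0) 0.05 * (1 - cos(2 * pi * (tt - t_lift0) / cyc))
  heel_wave <- function(t_strike0) 0.04 * (1 + cos(2 * pi * (tt - t_strike0) / cyc))
  lifts <- function(t0) { x <- t0 + (-1:(n_strides + 1)) * cyc; x[x >= 0 & x <= total] }
  strikes <- function(t0) lifts(t0 + swing * cyc)
  t_reach <- 0.5 * total
  hand <- 0.9 + 0.02 * sin(2 * pi * tt / cyc) +
    0.3 * exp(-0.5 * ((tt - t_reach) / (0.12 * cyc))^2)
  reach_time <- tt[which.max(hand)]
  X <- rbind(R_toe_z = toe_wave(t0_R), R_heel_z = heel_wave(t0_R + swing * cyc),
             L_toe_z = toe_wave(t0_L), L_heel_z = heel_wave(t0_L + swing * cyc),
             hand_dist = hand)
  if (noise_sigma > 0) {
    X <- with_local_seed(seed,
      X + matrix(rnorm(length(X), 0, noise_sigma), nrow(X)))
  }
  events <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(time = lifts(t0_R), type = "RTL"),
    tibble::tibble(time = strikes(t0_R), type = "RHS"),
    tibble::tibble(time = lifts(t0_L), type = "LTL"),
    tibble::tibble(time = strikes(t0_L), type = "LHS")
  ), .data$time)
  list(trajectories = trajectory_set(X, sample_rate,
                                     channel_labels = rownames(X)),
       events = events, reach_time = reach_time)
}
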