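#' Multichannel trajectory container
#'
#' A `trajectory_set` holds a numeric matrix of kinematic signals with one
#' channel per row (a channel is typically one joint angle of one trial) and
#' one time sample per column, together with the sampling rate and per-channel
#' labels. Sample `k` (0-based) occurs at time `k / sample_rate` seconds.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#'   At least 1 row and 4 columns; no missing values.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of channel names, one per row.
#'   Defaults to `"ch1"`, `"ch2"`, ...
#' @param trial_ids Optional per-channel trial tags (any atomic vector,
#'   length = number of rows). Used by [cross_validate()] to split by trial.
#' @param conditions Optional per-channel condition labels (length = rows).
#'
#' @return An object of class `trajectory_set`: a list with elements `data`,
#'   `sample_rate`, `channel_labels`, `trial_ids`, `conditions`.
#' @seealso [load_trajectories()], [resample_and_smooth()], [tidy.trajectory_set()]
#' @export
#' @examples
#' ts <- trajectory_set(matrix(rnorm(40), 4, 10), sample_rate = 120)
#' ts
trajectory_set <- function(data, sample_rate, channel_labels = NULL,
                           trial_ids = NULL, conditions = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L) abort("`data` must have at least one channel (row).")
  if (ncol(data) < 4L) abort("`data` must have at least 4 time samples (columns).")
  if (anyNA(data)) abort("`data` contains missing values; interpolate or drop them first.")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    abort("`sample_rate` must be a single positive number (Hz).")
  m <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(m))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != m)
    abort(sprintf("%d channel labels for %d channels.", length(channel_labels), m))
  if (!is.null(trial_ids) && length(trial_ids) != m)
    abort("`trial_ids` must have one entry per channel.")
  if (!is.null(conditions) && length(conditions) != m)
    abort("`conditions` must have one entry per channel.")
  rownames(data) <- channel_labels
  structure(
    list(data = data, sample_rate = sample_rate,
         channel_labels = channel_labels,
         trial_ids = trial_ids, conditions = conditions),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d channel%s x %d samples @ %g Hz (%.3g s)\n",
              nrow(x$data), if (nrow(x$data) == 1L) "" else "s",
              ncol(x$data), x$sample_rate, ncol(x$data) / x$sample_rate))
  if (!is.null(x$trial_ids))
    cat(sprintf("  trials: %d unique\n", length(unique(x$trial_ids))))
  if (!is.null(x$conditions))
    cat(sprintf("  conditions: %s\n",
                paste(unique(x$conditions), collapse = ", ")))
  invisible(x)
}

#' @export
dim.trajectory_set <- function(x) dim(x$data)

#' Time stamps of a trajectory set
#'
#' @param ts A [trajectory_set()].
#' @return Numeric vector of sample times in seconds (`0, 1/rate, ...`).
#' @export
time_points <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  (seq_len(ncol(ts$data)) - 1) / ts$sample_rate
}

#' Tidy a trajectory set into a long tibble
#'
#' @param x A [trajectory_set()].
#' @param ... Unused.
#' @return A tibble with columns `channel`, `trial`, `condition`, `time`
#'   (seconds) and `value`.
#' @method tidy trajectory_set
#' @export
tidy.trajectory_set <- function(x, ...) {
  m <- nrow(x$data); tt <- time_points(x)
  tibble::tibble(
    channel = rep(x$channel_labels, each = length(tt)),
    trial = rep(x$trial_ids %||% rep(NA, m), each = length(tt)),
    condition = rep(x$conditions %||% rep(NA_character_, m), each = length(tt)),
    time = rep(tt, times = m),
    value = as.vector(t(x$data))
  )
}

#' Build a trajectory set from a long data frame
#'
#' Inverse of [tidy.trajectory_set()]: takes one row per (channel, time)
#' observation and pivots into the channels-by-samples matrix.
#'
#' @param df Data frame with columns `channel`, `time`, `value` and optionally
#'   `trial` and `condition`.
#' @param sample_rate Sampling rate in Hz; if `NULL`, inferred from the median
#'   spacing of `time` within a channel.
#' @return A [trajectory_set()].
#' @export
as_trajectory_set <- function(df, sample_rate = NULL) {
  stopifnot(all(c("channel", "time", "value") %in% names(df)))
  wide <- df |>
    dplyr::arrange(.data$time) |>
    tidyr::pivot_wider(id_cols = "channel", names_from = "time",
                       values_from = "value")
  labs <- wide$channel
  mat <- as.matrix(wide[, -1])
  if (is.null(sample_rate)) {
    dt <- diff(sort(unique(df$time)))
    sample_rate <- 1 / median(dt)
  }
  meta <- df[!duplicated(df$channel), , drop = FALSE]
  meta <- meta[match(labs, meta$channel), , drop = FALSE]
  trajectory_set(mat, sample_rate, channel_labels = as.character(labs),
                 trial_ids = if ("trial" %in% names(df) && !all(is.na(meta$trial))) meta$trial,
                 conditions = if ("condition" %in% names(df) && !all(is.na(meta$condition))) as.character(meta$condition))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear interpolation of interior NA runs no longer than max_gap samples
interpolate_gaps <- function(y, max_gap = 5L) {
  if (!anyNA(y)) return(y)
  na <- is.na(y)
  if (na[1L] || na[length(y)])
    abort("Missing values at a channel boundary cannot be interpolated.")
  runs <- rle(na)
  if (max(runs$lengths[runs$values]) > max_gap)
    abort(sprintf("Missing-value gap longer than %d samples.", max_gap))
  approx(which(!na), y[!na], xout = seq_along(y))$y
}

#' Read a trajectory set from a delimited matrix and JSON sidecar
#'
#' The matrix file is plain delimited numeric text (comma, tab or whitespace
#' separated) with no header, one channel per row unless the sidecar's
#' `orientation` field says `"channels_in_columns"`. The sidecar is JSON with
#' at least `sample_rate` and optionally `channel_labels`, `trial_ids`,
#' `conditions` and `orientation`.
#'
#' @param path_matrix Path to the delimited matrix file.
#' @param path_meta Path to the JSON metadata sidecar.
#' @param interpolate_missing If `TRUE` (default), interior runs of missing
#'   values up to `max_gap` samples are filled by linear interpolation;
#'   longer gaps, boundary gaps, or any missing value when `FALSE`, error.
#' @param max_gap Longest missing run (samples) eligible for interpolation.
#' @return A [trajectory_set()].
#' @export
load_trajectories <- function(path_matrix, path_meta,
                              interpolate_missing = TRUE, max_gap = 5L) {
  if (!file.exists(path_matrix)) abort(paste("No such file:", path_matrix))
  if (!file.exists(path_meta)) abort(paste("No such file:", path_meta))
  first <- readLines(path_matrix, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  mat <- as.matrix(read.table(path_matrix, sep = sep, header = FALSE,
                              na.strings = c("NA", "NaN", "nan", "")))
  dimnames(mat) <- NULL
  meta <- jsonlite::read_json(path_meta, simplifyVector = TRUE)
  if (is.null(meta$sample_rate)) abort("Metadata must contain `sample_rate`.")
  if (identical(meta$orientation, "channels_in_columns")) mat <- t(mat)
  if (anyNA(mat)) {
    if (!interpolate_missing)
      abort("Matrix contains missing values and interpolation is disabled.")
    mat <- t(apply(mat, 1L, interpolate_gaps, max_gap = max_gap))
  }
  trajectory_set(mat, meta$sample_rate,
                 channel_labels = meta$channel_labels,
                 trial_ids = meta$trial_ids,
                 conditions = meta$conditions)
}

#' Write a trajectory set to a delimited matrix and JSON sidecar
#'
#' Inverse of [load_trajectories()]: values are written at full double
#' precision so a load/save round trip reproduces the data.
#'
#' @param ts A [trajectory_set()].
#' @param path_matrix Output path for the CSV matrix (no header, one channel
#'   per row).
#' @param path_meta Output path for the JSON sidecar.
#' @return `ts`, invisibly.
#' @export
save_trajectories <- function(ts, path_matrix, path_meta) {
  stopifnot(inherits(ts, "trajectory_set"))
  out <- format(ts$data, digits = 17, trim = TRUE, scientific = TRUE)
  write.table(out, path_matrix, sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  meta <- list(sample_rate = ts$sample_rate,
               channel_labels = ts$channel_labels,
               orientation = "channels_in_rows")
  if (!is.null(ts$trial_ids)) meta$trial_ids <- ts$trial_ids
  if (!is.null(ts$conditions)) meta$conditions <- ts$conditions
  jsonlite::write_json(meta, path_meta, auto_unbox = TRUE, digits = NA)
  invisible(ts)
}

#' Resample every channel to a fixed length with spline smoothing
#'
#' Each channel is smoothed by a cubic smoothing spline whose penalty is
#' chosen by generalized cross-validation (so noiseless channels are left
#' essentially untouched), then interpolated by a cubic spline onto
#' `n_points` equally spaced samples spanning the original time window.
#' 350 points is the conventional normalized length for gait-cycle windows.
#'
#' @param ts A [trajectory_set()] with at least 4 samples per channel.
#' @param n_points Output samples per channel (default 350, minimum 4).
#' @param spar Optional fixed smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` (default) selects it by GCV.
#' @param smooth If `FALSE`, skip the smoothing stage and purely interpolate.
#' @return A new [trajectory_set()] with `n_points` columns and the sampling
#'   rate rescaled so the spanned duration is preserved.
#' @export
resample_and_smooth <- function(ts, n_points = 350L, spar = NULL, smooth = TRUE) {
  stopifnot(inherits(ts, "trajectory_set"))
  n_points <- as.integer(n_points)
  if (n_points < 4L) abort("`n_points` must be at least 4.")
  t_old <- time_points(ts)
  duration <- t_old[length(t_old)]
  t_new <- seq(0, duration, length.out = n_points)
  res <- t(apply(ts$data, 1L, function(y) {
    ys <- y
    if (smooth) {
      fit <- if (is.null(spar)) {
        tryCatch(smooth.spline(t_old, y, cv = FALSE),
                 error = function(e) NULL)
      } else smooth.spline(t_old, y, spar = spar)
      if (!is.null(fit)) {
        fitted_vals <- predict(fit, t_old)$y
        # GCV may undersmooth pathologically flat channels; keep raw data
        # when the spline cannot improve on it
        if (all(is.finite(fitted_vals))) ys <- fitted_vals
      }
    }
    spline(t_old, ys, xout = t_new, method = "fmm")$y
  }))
  trajectory_set(res, sample_rate = (n_points - 1) / duration,
                 channel_labels = ts$channel_labels,
                 trial_ids = ts$trial_ids, conditions = ts$conditions)
}

#' @method autoplot trajectory_set
#' @export
autoplot.trajectory_set <- function(object, max_channels = 12L, ...) {
  df <- tidy(object)
  keep <- utils::head(unique(df$channel), max_channels)
  ggplot2::ggplot(dplyr::filter(df, .data$channel %in% keep),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "signal")
}
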