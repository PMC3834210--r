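# VAF, the regression scree criterion, by-trial cross-validation and source
# alignment.

#' Percentage of variance accounted for
#'
#' `100 * (1 - ||X - X_rec||_F^2 / ||X - Xbar||_F^2)`, where `Xbar` repeats
#' each row's mean: the fraction of the channels' temporal variance captured
#' by a reconstruction, on the original signal scale.
#'
#' @param X Observed matrix (channels x samples) or [trajectory_set()].
#' @param X_rec Reconstruction of the same shape.
#' @return A percentage (`<= 100`; negative if the reconstruction is worse
#'   than the channel means).
#' @export
vaf <- function(X, X_rec) {
  if (inherits(X, "trajectory_set")) X <- X$data
  if (inherits(X_rec, "trajectory_set")) X_rec <- X_rec$data
  X <- as.matrix(X); X_rec <- as.matrix(X_rec)
  if (!all(dim(X) == dim(X_rec))) abort("`X` and `X_rec` shapes differ.")
  denom <- sum((X - rowMeans(X))^2)
  if (denom == 0) abort("All rows of `X` are constant; VAF is undefined.")
  100 * (1 - sum((X - X_rec)^2) / denom)
}

new_vaf_curve <- function(df) {
  structure(df, class = c("vaf_curve", class(tibble::tibble())))
}

#' VAF as a function of the number of anechoic sources
#'
#' Fits the anechoic model for each candidate source count (best of the
#' configured restarts) and records the resulting VAF.
#'
#' @param data A [trajectory_set()].
#' @param n_range Candidate source counts (default `1:5`).
#' @param fit_config Named list of arguments passed on to [fit_fada()]
#'   (e.g. `n_restarts`, `order`, `seed`, `tol`).
#' @return A `vaf_curve` tibble with columns `n`, `vaf`, `fit_error` and a
#'   `fit` list-column holding each model.
#' @seealso [scree_select()], [pca_vaf_sweep()]
#' @export
vaf_sweep <- function(data, n_range = 1:5, fit_config = list()) {
  fits <- vector("list", length(n_range))
  prev <- NULL
  for (i in seq_along(n_range)) {
    fits[[i]] <- do.call(fit_fada, c(list(data = data, n_sources = n_range[i],
                                          warm_start = prev), fit_config))
    prev <- fits[[i]]
  }
  new_vaf_curve(tibble::tibble(
    n = as.integer(n_range),
    vaf = vapply(fits, `[[`, numeric(1), "vaf"),
    fit_error = vapply(fits, `[[`, numeric(1), "fit_error"),
    fit = fits
  ))
}

#' Select the number of sources by the regression scree criterion
#'
#' Fits ordinary least-squares lines to trailing segments of the VAF curve,
#' starting from the whole curve and successively dropping the leftmost
#' point. The chosen order is the smallest `N` whose trailing segment is
#' both well fitted by a line (mean square residual below `mse_threshold`,
#' computed with VAF on the 0-1 scale) and saturated (slope below
#' `slope_threshold` per additional source) -- i.e. the elbow after which
#' extra sources no longer pay. Segments keep at least 3 points. Returns
#' `NA` when no segment qualifies (as happens for curves that keep rising,
#' e.g. the PCA baseline on delay-rich data).
#'
#' @param curve A `vaf_curve` (from [vaf_sweep()] or [pca_vaf_sweep()]), or
#'   a numeric vector of VAF values (percent or 0-1) for counts `1, 2, ...`.
#' @param mse_threshold Mean-square-residual threshold on the 0-1 VAF scale
#'   (default 0.001).
#' @param slope_threshold Saturation bound on the fitted slope, 0-1 VAF per
#'   source (default 0.01).
#' @return Integer source count, or `NA_integer_` if no segment passes.
#' @export
scree_select <- function(curve, mse_threshold = 0.001, slope_threshold = 0.01) {
  if (is.data.frame(curve)) {
    n_values <- curve$n; v <- curve$vaf
  } else {
    v <- as.numeric(curve); n_values <- seq_along(v)
  }
  if (length(v) < 3L) abort("Need at least 3 points on the VAF curve.")
  if (max(abs(v), na.rm = TRUE) > 1.5) v <- v / 100  # percent -> 0-1 scale
  for (start in seq_len(length(v) - 2L)) {
    idx <- start:length(v)
    fit <- lm(v[idx] ~ n_values[idx])
    mse <- mean(fit$residuals^2)
    slope <- abs(coef(fit)[2L])
    if (mse < mse_threshold && slope < slope_threshold)
      return(as.integer(n_values[start]))
  }
  NA_integer_
}

# subset a trajectory_set by channel index
subset_channels <- function(ts, idx) {
  trajectory_set(ts$data[idx, , drop = FALSE], ts$sample_rate,
                 channel_labels = ts$channel_labels[idx],
                 trial_ids = ts$trial_ids[idx],
                 conditions = ts$conditions[idx])
}

#' Cross-validate anechoic fits by trial
#'
#' Splits the trials (all channels of a trial stay together; stratified by
#' condition label when present), fits the model on the training split for
#' each candidate source count, then freezes the trained sources and
#' re-estimates only weights and delays on the held-out trials. The test VAF
#' measures how well the trained primitives generalize.
#'
#' @param data A [trajectory_set()] with `trial_ids` and at least 5 trials.
#' @param train_fraction Fraction of trials used for training, in (0, 1);
#'   default 0.8.
#' @param n_range Candidate source counts.
#' @param fit_config Named list of arguments for [fit_fada()].
#' @param seed Integer seed for the split.
#' @return A `vaf_curve` tibble with columns `n`, `vaf` (test VAF),
#'   `vaf_train` and a `fit` list-column with the trained models; the split
#'   is recorded in attributes `train_trials` / `test_trials`.
#' @export
cross_validate <- function(data, train_fraction = 0.8, n_range = 1:5,
                           fit_config = list(), seed = 1L) {
  stopifnot(inherits(data, "trajectory_set"))
  if (is.null(data$trial_ids)) abort("`data` must carry trial_ids.")
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("`train_fraction` must lie strictly between 0 and 1.")
  trials <- unique(data$trial_ids)
  if (length(trials) < 5L) abort("Need at least 5 trials to cross-validate.")
  trial_cond <- if (!is.null(data$conditions)) {
    vapply(trials, function(tr) {
      cs <- unique(data$conditions[data$trial_ids == tr])
      if (length(cs) == 1L) as.character(cs) else NA_character_
    }, character(1))
  } else rep(NA_character_, length(trials))
  train_trials <- with_local_seed(seed, {
    if (!anyNA(trial_cond) && length(unique(trial_cond)) > 1L) {
      unlist(lapply(split(trials, trial_cond), function(tr) {
        k <- max(1L, round(train_fraction * length(tr)))
        sample(tr, k)
      }), use.names = FALSE)
    } else {
      sample(trials, max(1L, round(train_fraction * length(trials))))
    }
  })
  test_trials <- setdiff(trials, train_trials)
  if (length(test_trials) == 0L) abort("Empty test split; lower `train_fraction`.")
  train <- subset_channels(data, data$trial_ids %in% train_trials)
  test <- subset_channels(data, data$trial_ids %in% test_trials)
  rows <- purrr::map(n_range, function(n) {
    fit <- do.call(fit_fada, c(list(data = train, n_sources = n), fit_config))
    ewd <- estimate_weights_delays(test, fit$sources)
    test_model <- fit
    test_model$weights <- ewd$weights
    test_model$delays <- ewd$delays / data$sample_rate
    test_model$channel_means <- rowMeans(test$data)
    test_model$channel_labels <- test$channel_labels
    test_model$trial_ids <- test$trial_ids
    list(n = n, fit = fit, vaf_train = fit$vaf,
         vaf = vaf(test$data, reconstruct(test_model)))
  })
  out <- new_vaf_curve(tibble::tibble(
    n = as.integer(n_range),
    vaf = vapply(rows, `[[`, numeric(1), "vaf"),
    vaf_train = vapply(rows, `[[`, numeric(1), "vaf_train"),
    fit = purrr::map(rows, "fit")
  ))
  attr(out, "train_trials") <- train_trials
  attr(out, "test_trials") <- test_trials
  out
}

as_source_matrix <- function(x, n_samples = NULL) {
  if (is.list(x) && length(x) && inherits(x[[1]], "fourier_series")) {
    n <- n_samples %||% x[[1]]$period
    t(vapply(x, fourier_eval, numeric(n), n_samples = n))
  } else if (inherits(x, "anechoic_model")) {
    as_source_matrix(x$sources, n_samples)
  } else as.matrix(x)
}

circ_corr <- function(a, b) {
  # correlation of a with every circular shift of b (shift s: b delayed by s)
  n <- length(a)
  ac <- a - mean(a); bc <- b - mean(b)
  num <- Re(fft(fft(ac) * Conj(fft(bc)), inverse = TRUE)) / n
  num / (sqrt(sum(ac^2)) * sqrt(sum(bc^2)))
}

#' Align two source sets by permutation and circular shift
#'
#' Pairs the sources of `set_b` with those of `set_a` (exhaustively for up
#' to 4 sources, greedily above) so that the summed post-alignment absolute
#' correlation is maximal. With `method = "peak"` (the conventional
#' re-alignment) each pair is circularly shifted so the maximum peaks
#' coincide before the correlation is computed; `method = "max_corr"` takes
#' the shift maximizing the absolute circular correlation.
#'
#' @param set_a,set_b Source sets of equal count: lists of
#'   [fourier_series()], `anechoic_model`s, or numeric matrices (sources x
#'   samples).
#' @param method Shift rule, `"peak"` or `"max_corr"`.
#' @return Tibble with one row per pair: `source_a`, `source_b`, `shift`
#'   (samples `set_b` must be delayed to match `set_a`), `sign` (+/-1 flip
#'   applied to `set_b`), `correlation` (after shift and flip).
#' @export
align_sources <- function(set_a, set_b, method = c("peak", "max_corr")) {
  method <- match.arg(method)
  A <- as_source_matrix(set_a)
  B <- as_source_matrix(set_b, n_samples = ncol(A))
  if (nrow(A) != nrow(B)) abort("Source sets must have equal counts.")
  N <- nrow(A); n <- ncol(A)
  score <- matrix(0, N, N); shift <- matrix(0L, N, N); sgn <- matrix(1, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (method == "peak") {
      s <- (which.max(A[i, ]) - which.max(B[j, ])) %% n
      r <- circ_corr(A[i, ], B[j, ])[s + 1L]
    } else {
      cc <- circ_corr(A[i, ], B[j, ])
      s <- which.max(abs(cc)) - 1L
      r <- cc[s + 1L]
    }
    score[i, j] <- abs(r); shift[i, j] <- s; sgn[i, j] <- ifelse(r < 0, -1, 1)
  }
  perm <- if (N <= 4L) {
    perms <- all_permutations(N)
    tot <- vapply(perms, function(p) sum(score[cbind(seq_len(N), p)]), numeric(1))
    perms[[which.max(tot)]]
  } else {
    p <- integer(N); used <- logical(N)
    for (i in order(apply(score, 1, max), decreasing = TRUE)) {
      j <- order(score[i, ], decreasing = TRUE)
      j <- j[!used[j]][1L]
      p[i] <- j; used[j] <- TRUE
    }
    p
  }
  tibble::tibble(
    source_a = seq_len(N), source_b = perm,
    shift = shift[cbind(seq_len(N), perm)],
    sign = sgn[cbind(seq_len(N), perm)],
    correlation = score[cbind(seq_len(N), perm)] *
      1  # |r| reported positive after the optional sign flip
  )
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' @method autoplot vaf_curve
#' @export
autoplot.vaf_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), dplyr::any_of(c("n", "vaf", "vaf_train"))),
    -"n", names_to = "set", values_to = "vaf")
  df$set <- dplyr::recode(df$set, vaf = "VAF", vaf_train = "VAF (train)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$vaf,
                                   colour = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of sources N", y = "VAF (%)", colour = NULL)
}
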