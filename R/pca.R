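# Correlation-matrix PCA baseline: the instantaneous mixing model the
# anechoic fit is compared against. Channels are z-scored first because
# joint-angle magnitudes differ widely between upper and lower body.

#' Principal component analysis on the channel correlation matrix
#'
#' Standardizes every channel (row) to zero mean and unit variance, performs
#' PCA on the resulting correlation structure, and returns the top temporal
#' components with their channel weights. Reconstructions de-standardize
#' back to the original signal scale so VAF is comparable with the anechoic
#' model's.
#'
#' @param data A [trajectory_set()].
#' @param n_components Number of components to keep (`<=` channels).
#' @return Object of class `pca_model`: `components` (samples x N temporal
#'   PCs), `weights` (channels x N loadings, each column's largest-magnitude
#'   weight positive), `explained` (all variance fractions, non-increasing),
#'   `center`/`scale` (per-channel standardization), plus labels.
#' @export
fit_pca <- function(data, n_components) {
  stopifnot(inherits(data, "trajectory_set"))
  X <- data$data
  M <- nrow(X)
  N <- as.integer(n_components)
  if (N < 1L || N > M) abort("`n_components` must lie in 1..channels.")
  sds <- apply(X, 1L, sd)
  if (any(sds == 0))
    abort(paste("Zero-variance channel(s):",
                paste(data$channel_labels[sds == 0], collapse = ", ")))
  pc <- stats::prcomp(t(X), center = TRUE, scale. = TRUE)
  W <- pc$rotation[, seq_len(N), drop = FALSE]
  P <- pc$x[, seq_len(N), drop = FALSE] # samples x N scores
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(N)) {
    top <- which.max(abs(W[, j]))
    if (W[top, j] < 0) { W[, j] <- -W[, j]; P[, j] <- -P[, j] }
  }
  structure(list(components = unname(P), weights = unname(W),
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 center = rowMeans(X), scale = sds,
                 n_components = N,
                 channel_labels = data$channel_labels,
                 sample_rate = data$sample_rate),
            class = "pca_model")
}

#' Reconstruct trajectories from a PCA model
#'
#' @param model A `pca_model`.
#' @param n_components Number of leading components to use (default: all
#'   kept in the model).
#' @return Channels x samples matrix on the original (de-standardized)
#'   scale.
#' @export
pca_reconstruct <- function(model, n_components = model$n_components) {
  stopifnot(inherits(model, "pca_model"))
  k <- seq_len(n_components)
  Z <- model$weights[, k, drop = FALSE] %*% t(model$components[, k, drop = FALSE])
  Z * model$scale + model$center
}

#' PCA VAF as a function of the number of components
#'
#' Companion of [vaf_sweep()] for the instantaneous-mixing baseline: VAF is
#' computed by [vaf()] on de-standardized reconstructions, so the two curves
#' are directly comparable.
#'
#' @param data A [trajectory_set()].
#' @param n_range Candidate component counts (default `1:5`).
#' @return A `vaf_curve` tibble with columns `n`, `vaf` and a `fit`
#'   list-column (the full `pca_model`, shared across rows).
#' @export
pca_vaf_sweep <- function(data, n_range = 1:5) {
  model <- fit_pca(data, max(n_range))
  new_vaf_curve(tibble::tibble(
    n = as.integer(n_range),
    vaf = vapply(n_range, function(n)
      vaf(data$data, pca_reconstruct(model, n)), numeric(1)),
    fit = rep(list(model), length(n_range))
  ))
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d component%s of %d channels; explained: %s\n",
              x$n_components, if (x$n_components == 1L) "" else "s",
              length(x$channel_labels),
              paste(sprintf("%.1f%%", 100 * x$explained[seq_len(x$n_components)]),
                    collapse = ", ")))
  invisible(x)
}

#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, ...) {
  M <- length(x$channel_labels); N <- x$n_components
  tibble::tibble(channel = rep(x$channel_labels, times = N),
                 component = rep(seq_len(N), each = M),
                 weight = as.vector(x$weights))
}

#' @method glance pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 explained = sum(x$explained[seq_len(x$n_components)]))
}

#' @method autoplot pca_model
#' @export
autoplot.pca_model <- function(object, ...) {
  n <- nrow(object$components)
  tt <- (0:(n - 1L)) / object$sample_rate
  df <- tibble::tibble(
    component = rep(seq_len(object$n_components), each = n),
    time = rep(tt, times = object$n_components),
    value = as.vector(object$components))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "temporal PC")
}
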