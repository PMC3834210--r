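# Fourier-based anechoic demixing: each channel x_i(t) is modelled as
#   x_i(t) = mean_i + sum_j a_ij * s_j(t - tau_ij)   (delays circular over the
# trial window), fitted entirely on the truncated Fourier coefficients of the
# mean-centred channels (harmonics 1..F).

# run code with a temporary RNG state so fits are reproducible and do not
# disturb the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Non-negative factorization of a Fourier magnitude matrix
#'
#' Solves the magnitude demixing step of the anechoic model: the matrix of
#' absolute Fourier coefficients of the data is factorized as
#' `abs_coeffs ~ weights %*% source_mags` with all entries non-negative,
#' by seeded multiplicative updates minimizing the Frobenius reconstruction
#' error. This supplies the source spectral magnitudes and initial weights
#' that the phase and delay steps refine.
#'
#' @param abs_coeffs Non-negative numeric matrix, channels by harmonics.
#' @param n_sources Number of sources `N`, `1 <= N <= min(dim(abs_coeffs))`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter,tol Update count cap and relative-change stopping rule.
#' @return List with `weights` (channels x N), `source_mags`
#'   (N x harmonics) and `error` (Frobenius residual).
#' @export
magnitude_demix <- function(abs_coeffs, n_sources, seed = 1L,
                            max_iter = 1000L, tol = 1e-10) {
  V <- as.matrix(abs_coeffs)
  if (any(V < 0)) abort("`abs_coeffs` must be non-negative.")
  n <- as.integer(n_sources)
  if (n < 1L || n > min(dim(V)))
    abort("`n_sources` must lie in 1..min(dim(abs_coeffs)).")
  if (all(V == 0)) {
    return(list(weights = matrix(0, nrow(V), n),
                source_mags = matrix(0, n, ncol(V)), error = 0))
  }
  eps <- 1e-12
  one_run <- function() {
    sc <- sqrt(mean(V) / n)
    W <- matrix(runif(nrow(V) * n, 0.1, 1), nrow(V), n) * sc
    H <- matrix(runif(n * ncol(V), 0.1, 1), n, ncol(V)) * sc
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
      W <- W * ((V %*% t(H)) / (W %*% tcrossprod(H) + eps))
      if (it %% 10L == 0L) {
        err <- sqrt(sum((V - W %*% H)^2))
        if (is.finite(err_prev) && (err_prev - err) < tol * max(err_prev, eps)) break
        err_prev <- err
      }
    }
    list(weights = W, source_mags = H, error = sqrt(sum((V - W %*% H)^2)))
  }
  with_local_seed(seed, {
    # multiplicative updates are sensitive to the starting point; keep the
    # best of a few seeded starts
    best <- one_run()
    for (r in 1:2) {
      cand <- one_run()
      if (cand$error < best$error) best <- cand
    }
    best
  })
}

# ---- internal coefficient-domain workhorses ------------------------------

# model coefficients: M x F complex matrix sum_j (a_j * phasor(tau_j)) * S[j,]
model_coeffs <- function(A, tau, S, Tn) {
  Fh <- ncol(S)
  out <- matrix(0i, nrow(A), Fh)
  for (j in seq_len(ncol(A))) {
    out <- out + (A[, j] * delay_phasors(tau[, j], Fh, Tn)) *
      matrix(S[j, ], nrow(A), Fh, byrow = TRUE)
  }
  out
}

fada_objective <- function(D, A, tau, S, Tn) {
  sum(Mod(D - model_coeffs(A, tau, S, Tn))^2)
}

# coordinate-descent minimization of the coefficient residual over the source
# phases, magnitudes/weights/delays held fixed; exact per-coordinate minimum,
# hence monotone
phase_step <- function(D, A, tau, S, Tn, sweeps = 3L) {
  Fh <- ncol(S); N <- ncol(A)
  for (k in seq_len(Fh)) {
    mag <- Mod(S[, k]); ph <- Arg(S[, k])
    if (all(mag == 0)) next
    Ek <- exp(-2i * pi * k * tau / Tn)          # M x N
    G <- A * Ek                                  # M x N, times mag_j below
    m <- G %*% (mag * exp(1i * ph))
    for (sw in seq_len(sweeps)) {
      for (j in seq_len(N)) {
        if (mag[j] == 0) next
        gj <- G[, j] * mag[j]
        r <- D[, k] - (m - gj * exp(1i * ph[j]))
        z <- sum(Conj(gj) * r)
        if (Mod(z) > 0) {
          new_ph <- Arg(z)
          m <- m + gj * (exp(1i * new_ph) - exp(1i * ph[j]))
          ph[j] <- new_ph
        }
      }
    }
    S[, k] <- mag * exp(1i * ph)
  }
  S
}

# exact complex least-squares refit of the source coefficients given weights
# and delays (one small N x N solve per harmonic); monotone
source_step <- function(D, A, tau, S, Tn) {
  Fh <- ncol(S); N <- ncol(A)
  for (k in seq_len(Fh)) {
    G <- A * exp(-2i * pi * k * tau / Tn)       # M x N
    H <- Conj(t(G)) %*% G
    diag(H) <- diag(H) + 1e-12 * max(Mod(diag(H)), 1e-300)
    S[, k] <- solve(H, Conj(t(G)) %*% D[, k])
  }
  S
}

# Delay/weight estimation given the sources: exact per-channel conditional
# coordinate descent. For each source in turn, every channel scans the full
# 1-sample circular lag grid; each candidate lag is scored by the explained
# variance of the channel under *jointly* least-squares-fitted weights for
# all sources (closed form via precomputed Gram lookups), so spectral overlap
# between sources cannot mislead the search. The winning lag is refined on a
# 0.1-sample local grid with a parabolic vertex step. Weights are then
# refitted per channel by least squares.
ewd_step <- function(D, S, A, tau, Tn, n_iter = 2L, nonneg = FALSE) {
  M <- nrow(D); Fh <- ncol(D); N <- nrow(S)
  # the circular correlation against an order-F series is smooth over
  # ~ Tn / (2F) samples, so a 2-sample coarse grid loses nothing when that
  # bandwidth is wide; the local grid below recovers 0.1-sample resolution
  step <- if (Tn >= 16L * Fh) 2L else 1L
  tgrid <- seq.int(0L, Tn - 1L, by = step)
  Ecoarse <- exp(2i * pi * outer(tgrid, seq_len(Fh)) / Tn)          # G x F
  delta <- seq(-step, step, by = 0.1)
  Efine <- t(exp(2i * pi * outer(delta, seq_len(Fh)) / Tn))         # F x nd
  nd <- length(delta)
  rows <- seq_len(M)
  kvec <- seq_len(Fh)
  Ecross <- exp(2i * pi * outer(0:(Tn - 1L), seq_len(Fh)) / Tn)     # Tn x F
  # correlation tables B[[j]][i, g] = <delayed s_j at lag tgrid[g], d_i>
  B <- lapply(seq_len(N), function(j)
    2 * Re((D * matrix(Conj(S[j, ]), M, Fh, byrow = TRUE)) %*% t(Ecoarse)))
  gdiag <- 2 * rowSums(Mod(S)^2)
  # cross[[j]][[l]][d+1] = <s_j at lag t_j, s_l at lag t_l>, d = t_j - t_l
  cross <- lapply(seq_len(N), function(j) lapply(seq_len(N), function(l)
    as.vector(2 * Re((Conj(S[j, ]) * S[l, ]) %*% t(Ecross)))))
  eps <- 1e-12

  for (it in seq_len(n_iter)) {
    for (j in seq_len(N)) {
      if (gdiag[j] <= eps) { tau[, j] <- 0; next }
      others <- setdiff(seq_len(N), j)
      if (length(others) == 0L) {
        no <- 0L
        ratio <- B[[j]]^2 / gdiag[j]
        Qi_flat <- NULL
      } else {
        t_o <- round(tau[, others, drop = FALSE]) %% Tn          # M x (N-1)
        # per-channel inverse Gram of the other sources and their fitted
        # contribution Q^{-1} b_o (B sampled at the nearest grid point)
        no <- length(others)
        g_o <- (round(t_o / step) %% length(tgrid)) + 1L
        bo <- vapply(seq_len(no), function(a)
          B[[others[a]]][cbind(rows, g_o[, a])], numeric(M))
        bo <- matrix(bo, M, no)
        if (no == 1L) {
          Qi_flat <- matrix(1 / max(gdiag[others], eps), M, 1L)
          wvec <- bo * Qi_flat[, 1L]
        } else {
          Qi_flat <- matrix(0, M, no * no)
          wvec <- matrix(0, M, no)
          # pairwise cross-Gram entries for all channels at once
          pair_q <- vector("list", no * no)
          for (a in 1:(no - 1L)) for (b in (a + 1L):no) {
            pair_q[[(a - 1L) * no + b]] <-
              cross[[others[a]]][[others[b]]][((t_o[, a] - t_o[, b]) %% Tn) + 1L]
          }
          ridge <- 1e-9 * max(gdiag)
          Qbase <- diag(gdiag[others] + ridge, no)
          for (i in rows) {
            Q <- Qbase
            for (a in 1:(no - 1L)) for (b in (a + 1L):no) {
              Q[a, b] <- Q[b, a] <- pair_q[[(a - 1L) * no + b]][i]
            }
            Qi <- solve(Q)
            Qi_flat[i, ] <- Qi
            wvec[i, ] <- Qi %*% bo[i, ]
          }
        }
        # v_a[i, t+1] = <s_j at lag t, s_a at lag t_o[i, a]>, via a doubled
        # lookup vector so no modulo is needed
        V <- lapply(seq_len(no), function(a) {
          cv2 <- cross[[j]][[others[a]]]
          cv2 <- c(cv2, cv2)
          v <- cv2[outer(Tn + 1L - t_o[, a], tgrid, "+")]
          dim(v) <- c(M, length(tgrid))
          v
        })
        num <- B[[j]]
        for (a in seq_len(no)) num <- num - V[[a]] * wvec[, a]
        den <- matrix(gdiag[j], M, length(tgrid))
        for (a in seq_len(no)) for (b in a:no) {
          fac <- if (a == b) 1 else 2
          den <- den - (V[[a]] * V[[b]]) * (fac * Qi_flat[, (a - 1L) * no + b])
        }
        ratio <- num^2 / pmax(den, eps * gdiag[j])
      }
      ti <- max.col(ratio, ties.method = "first")                 # 1-based
      base_val <- ratio[cbind(rows, ti)]
      t_int <- tgrid[ti]
      # 0.1-sample local refinement of the same conditional objective
      ph <- exp(2i * pi * outer(t_int, kvec) / Tn)
      Bf <- 2 * Re((D * matrix(Conj(S[j, ]), M, Fh, byrow = TRUE) * ph) %*% Efine)
      if (no == 0L) {
        fr <- Bf^2 / gdiag[j]
      } else {
        numf <- Bf; denf <- matrix(gdiag[j], M, nd)
        Vf <- lapply(seq_len(no), function(a) {
          pha <- exp(2i * pi * outer(t_int - t_o[, a], kvec) / Tn)
          2 * Re((matrix(Conj(S[j, ]) * S[others[a], ], M, Fh, byrow = TRUE) * pha) %*% Efine)
        })
        for (a in seq_len(no)) numf <- numf - Vf[[a]] * wvec[, a]
        for (a in seq_len(no)) for (b in seq_len(no)) {
          denf <- denf - (Vf[[a]] * Vf[[b]]) * Qi_flat[, (a - 1L) * no + b]
        }
        fr <- numf^2 / pmax(denf, eps * gdiag[j])
      }
      fi <- max.col(fr, ties.method = "first")
      fl <- pmax(fi - 1L, 1L); fhi <- pmin(fi + 1L, nd)
      c0 <- fr[cbind(rows, fi)]
      cl <- fr[cbind(rows, fl)]; cr <- fr[cbind(rows, fhi)]
      dpar <- cl - 2 * c0 + cr
      adj <- ifelse(fl < fi & fhi > fi & dpar < 0, 0.5 * (cl - cr) / dpar, 0)
      tau_new <- t_int + delta[fi] + 0.1 * adj
      improved <- c0 >= base_val - eps
      tau[, j] <- ifelse(improved, tau_new, t_int)
      tau[B[[j]][cbind(rows, ti)]^2 <= 1e-300, j] <- 0  # silent channel
    }
    # joint least-squares weights per channel given the delayed sources:
    # exact Gram and cross-correlation terms at the fractional delays
    bmat <- vapply(seq_len(N), function(j)
      2 * rowSums(Re(D * (matrix(Conj(S[j, ]), M, Fh, byrow = TRUE) *
                            exp(2i * pi * outer(tau[, j], kvec) / Tn)))),
      numeric(M))
    bmat <- matrix(bmat, M, N)
    if (N == 1L) {
      A <- matrix(bmat[, 1L] / max(gdiag[1L], eps), M, 1L)
      if (nonneg) A[A < 0] <- 0
    } else {
      Gpair <- array(0, c(M, N, N))
      for (j in seq_len(N)) Gpair[, j, j] <- gdiag[j]
      for (j in 1:(N - 1L)) for (l in (j + 1L):N) {
        glj <- 2 * rowSums(Re(matrix(Conj(S[j, ]) * S[l, ], M, Fh, byrow = TRUE) *
                                exp(2i * pi * outer(tau[, j] - tau[, l], kvec) / Tn)))
        Gpair[, j, l] <- Gpair[, l, j] <- glj
      }
      if (N == 2L) {
        det2 <- pmax(Gpair[, 1, 1] * Gpair[, 2, 2] - Gpair[, 1, 2]^2,
                     eps * max(gdiag)^2)
        A <- cbind((Gpair[, 2, 2] * bmat[, 1] - Gpair[, 1, 2] * bmat[, 2]) / det2,
                   (Gpair[, 1, 1] * bmat[, 2] - Gpair[, 1, 2] * bmat[, 1]) / det2)
        if (nonneg) {
          # active-set by cases: compare the two single-source solutions
          # wherever the unconstrained solution leaves the feasible cone
          bad <- A[, 1] < 0 | A[, 2] < 0
          if (any(bad)) {
            a1 <- pmax(bmat[, 1] / max(gdiag[1], eps), 0)
            a2 <- pmax(bmat[, 2] / max(gdiag[2], eps), 0)
            e1 <- a1^2 * gdiag[1]; e2 <- a2^2 * gdiag[2]  # explained variance
            use1 <- e1 >= e2
            A[bad & use1, 1] <- a1[bad & use1]; A[bad & use1, 2] <- 0
            A[bad & !use1, 2] <- a2[bad & !use1]; A[bad & !use1, 1] <- 0
          }
        }
      } else {
        ridge <- diag(1e-9 * max(gdiag), N)
        for (i in rows) {
          Gi <- Gpair[i, , ] + ridge
          a <- solve(Gi, bmat[i, ])
          if (nonneg) {
            for (rep_i in 1:3) {
              neg <- a < 0
              if (!any(neg)) break
              a[neg] <- 0
              keep <- which(!neg)
              if (length(keep) == 0L) break
              a[keep] <- solve(Gi[keep, keep, drop = FALSE], bmat[i, keep])
            }
            a[a < 0] <- 0
          }
          A[i, ] <- a
        }
      }
    }
  }
  list(A = A, tau = tau)
}

# exact per-channel integer-lag scan over all (t1, t2) pairs for two
# sources: scores every pair by the explained variance under jointly fitted
# weights (closed form), so no coordinate-descent trap can survive
exhaustive_pair_scan <- function(D, S, Tn) {
  M <- nrow(D); Fh <- ncol(D)
  Ec <- exp(2i * pi * outer(0:(Tn - 1L), seq_len(Fh)) / Tn)
  g11 <- 2 * sum(Mod(S[1, ])^2); g22 <- 2 * sum(Mod(S[2, ])^2)
  cr <- as.vector(2 * Re((Conj(S[1, ]) * S[2, ]) %*% t(Ec)))
  B1 <- 2 * Re((D * matrix(Conj(S[1, ]), M, Fh, byrow = TRUE)) %*% t(Ec))
  B2 <- 2 * Re((D * matrix(Conj(S[2, ]), M, Fh, byrow = TRUE)) %*% t(Ec))
  idx <- (outer(0:(Tn - 1L), 0:(Tn - 1L), "-") %% Tn) + 1L
  G12 <- matrix(cr[idx], Tn, Tn)
  det0 <- pmax(g11 * g22 - G12^2, 1e-9 * max(g11 * g22, 1e-300))
  tau <- matrix(0, M, 2L)
  for (i in seq_len(M)) {
    obj <- (g22 * B1[i, ]^2 - 2 * G12 * (B1[i, ] * rep(B2[i, ], each = Tn)) +
              g11 * rep(B2[i, ]^2, each = Tn)) / det0
    w <- arrayInd(which.max(obj), c(Tn, Tn))
    tau[i, ] <- c(w[1L] - 1L, w[2L] - 1L)
  }
  tau
}

#' Estimate per-channel weights and delays for fixed sources
#'
#' For each channel, each source's circular delay is located by
#' frequency-domain cross-correlation on a dense lag grid (1-sample coarse
#' scan, 0.1-sample local grid, parabolic refinement), then the weights are
#' re-fitted by least squares given the delayed sources; the two steps are
#' alternated to a fixed point.
#'
#' @param data A [trajectory_set()] (channels are mean-centred internally) or
#'   a complex coefficient matrix (channels x harmonics `1..F`).
#' @param sources List of [fourier_series()] (zero-mean) or a complex matrix
#'   (sources x harmonics `1..F`).
#' @param period Record length in samples; required when `data` is a matrix.
#' @param n_iter Number of delay/weight alternations.
#' @param nonneg_weights Constrain weights to be non-negative.
#' @param exhaustive For exactly two sources, precede the alternation with
#'   an exhaustive scan over all integer lag pairs (exact up to grid
#'   resolution, then refined below the sample). `NULL` (default) enables
#'   it automatically when the problem is small enough.
#' @return List with `weights` (channels x N) and `delays` (channels x N,
#'   samples, wrapped to `[-T/2, T/2)`).
#' @export
estimate_weights_delays <- function(data, sources, period = NULL,
                                    n_iter = 4L, nonneg_weights = FALSE,
                                    exhaustive = NULL) {
  if (inherits(data, "trajectory_set")) {
    X <- data$data
    Xc <- X - rowMeans(X)
    Fh <- if (is.list(sources) && inherits(sources[[1]], "fourier_series"))
      sources[[1]]$order else ncol(sources)
    D <- coeff_matrix(Xc, Fh)
    Tn <- ncol(X)
  } else {
    D <- as.matrix(data)
    if (is.null(period)) abort("`period` is required for matrix input.")
    Tn <- period
  }
  S <- if (is.list(sources)) {
    t(vapply(sources, function(s) s$coeffs[-1L], complex(ncol(D))))
  } else as.matrix(sources)
  if (nrow(S) > min(nrow(D), ncol(D)))
    abort("More sources than channels or harmonics.")
  if (ncol(S) != ncol(D)) abort("Source and data harmonic counts differ.")
  M <- nrow(D); N <- nrow(S)
  if (is.null(exhaustive))
    exhaustive <- N == 2L && M * Tn^2 <= 1e7
  tau0 <- if (exhaustive && N == 2L) exhaustive_pair_scan(D, S, Tn)
          else matrix(0, M, N)
  res <- ewd_step(D, S, A = matrix(0, M, N), tau = tau0,
                  Tn = Tn, n_iter = n_iter, nonneg = nonneg_weights)
  list(weights = res$A, delays = wrap_delay(res$tau, Tn))
}

wrap_delay <- function(tau, Tn) ((tau + Tn / 2) %% Tn) - Tn / 2

#' Refit source phases against data coefficients
#'
#' Replaces the phases of the model's source Fourier coefficients by a local
#' minimizer of the Frobenius residual between the data coefficients and the
#' model coefficients (coordinate descent, magnitudes, weights and delays
#' fixed). The objective never increases.
#'
#' @param data_coeffs Complex matrix of channel coefficients, channels by
#'   harmonics (`1..F`, or `0..F` in which case harmonic 0 is dropped).
#' @param model An [fit_fada()] model.
#' @param sweeps Coordinate-descent sweeps per harmonic.
#' @return The model with updated source phases and `fit_error` diagnostics
#'   recomputed in the coefficient domain.
#' @export
update_phases <- function(data_coeffs, model, sweeps = 5L) {
  stopifnot(inherits(model, "anechoic_model"))
  D <- as.matrix(data_coeffs)
  S <- source_coeff_matrix(model)
  if (ncol(D) == ncol(S) + 1L) D <- D[, -1L, drop = FALSE]
  if (ncol(D) != ncol(S)) abort("Coefficient harmonic counts differ.")
  Tn <- model$period
  tau <- model$delays * model$sample_rate
  S2 <- phase_step(D, model$weights, tau, S, Tn, sweeps = sweeps)
  model$sources <- lapply(seq_len(nrow(S2)), function(j)
    fourier_series(c(0, S2[j, ]), period = Tn, sample_rate = model$sample_rate))
  model$fit_error <- sqrt(2 * Tn * fada_objective(D, model$weights, tau, S2, Tn))
  model
}

source_coeff_matrix <- function(model) {
  t(vapply(model$sources, function(s) s$coeffs[-1L],
           complex(model$order)))
}

#' Pick a truncation order from the spectral energy of the data
#'
#' Returns the smallest harmonic band containing `energy` of the average
#' spectral energy of the mean-centred channels, capped at `cap` and at
#' `(T - 1) / 2`.
#'
#' @param data A [trajectory_set()].
#' @param energy Fraction of spectral energy to capture (default 0.999).
#' @param cap Upper bound for the order (default 10).
#' @return Integer order.
#' @export
choose_fourier_order <- function(data, energy = 0.999, cap = 10L) {
  X <- data$data - rowMeans(data$data)
  Tn <- ncol(X)
  kmax <- floor((Tn - 1) / 2)
  pw <- rep(0, kmax)
  for (i in seq_len(nrow(X))) {
    c_all <- fft(X[i, ]) / Tn
    pw <- pw + 2 * Mod(c_all[2:(kmax + 1L)])^2
  }
  cum <- cumsum(pw) / sum(pw)
  as.integer(min(max(which(cum >= energy)[1L], 1L), cap, kmax))
}

#' Fit the anechoic mixing model by Fourier-domain alternating optimization
#'
#' Fits `x_i(t) = mean_i + sum_j a_ij s_j(t - tau_ij)` with `N` shared
#' band-limited sources, per-channel weights and circular delays. Each
#' restart (i) factorizes the magnitudes of the channel Fourier coefficients
#' non-negatively ([magnitude_demix()]) to obtain source spectral magnitudes
#' and initial weights, (ii) randomizes phases and delays, then (iii)
#' alternates phase refitting, delay/weight estimation and a per-harmonic
#' least-squares source refinement until the coefficient residual stalls.
#' The best restart is returned under canonical conventions: unit-L2-norm
#' sources ordered by explained variance, delays wrapped to `[-T/2, T/2)`
#' with zero weighted mean per source, and each source's dominant extremum
#' positive.
#'
#' @param data A [trajectory_set()].
#' @param n_sources Number of sources `N >= 1`.
#' @param order Truncation order `F` (harmonics above `F` are ignored);
#'   default 10, see [choose_fourier_order()].
#' @param n_restarts Random restarts; the lowest-residual solution is kept
#'   (ties broken by restart index). Default 25.
#' @param max_outer_iter,tol Outer-loop cap and relative-improvement
#'   stopping rule.
#' @param seed Integer seed; the same seed always reproduces the same fit.
#' @param warm_start Optional `anechoic_model` with fewer sources used to
#'   seed one extra optimization run: its sources are kept and the missing
#'   sources are seeded from the residual (nested initialization, which
#'   keeps the VAF monotone across a model-order sweep).
#' @param nonneg_weights Constrain the reported mixing weights to be
#'   non-negative (default `FALSE`: signed weights). The alternating
#'   optimization itself always runs unconstrained; the constraint is
#'   applied in a final delay/weight re-estimation with the sources fixed.
#' @return An object of class `anechoic_model` with elements `sources`
#'   (list of [fourier_series()]), `weights`, `delays` (seconds), `vaf`,
#'   `fit_error`, `restart_errors` and bookkeeping fields.
#' @seealso [reconstruct()], [vaf()], [vaf_sweep()], [tidy.anechoic_model()]
#' @export
fit_fada <- function(data, n_sources, order = 10L, n_restarts = 25L,
                     max_outer_iter = 200L, tol = 1e-6, seed = 1L,
                     nonneg_weights = FALSE, warm_start = NULL) {
  stopifnot(inherits(data, "trajectory_set"))
  X <- data$data
  M <- nrow(X); Tn <- ncol(X)
  N <- as.integer(n_sources)
  Fh <- as.integer(order)
  if (N < 1L) abort("`n_sources` must be >= 1.")
  if (N > min(M, Fh))
    abort(sprintf("N = %d sources exceed min(channels = %d, order = %d).", N, M, Fh))
  mu <- rowMeans(X)
  D <- coeff_matrix(X - mu, Fh)
  absD <- Mod(D)
  denom <- sum(Mod(D)^2)

  n_lock <- 8L       # magnitude-locked warm-up iterations (phases/delays only)
  screen_iters <- 8L   # short-run length used to rank restarts
  n_finalists <- max(3L, min(5L, n_restarts))

  # short run: stage 1 with source magnitudes locked at the non-negative
  # factorization (robust delay crystallization), then a few full
  # alternations; cheap enough to do for every restart
  short_run <- function(r) {
    with_local_seed(seed + 7919L * r, {
      nmf <- magnitude_demix(absD, N, seed = seed + 7919L * r + 1L,
                             max_iter = 400L)
      A <- nmf$weights
      if (r == 1L) {
        # warm start: zero delays, source phases from the weight-averaged
        # data coefficients; subsequent restarts are fully random
        ph <- vapply(seq_len(Fh), function(k) Arg(crossprod(A, D[, k]))[, 1L],
                     numeric(N))
        S <- nmf$source_mags * exp(1i * matrix(ph, N, Fh))
        tau <- matrix(0, M, N)
      } else {
        S <- nmf$source_mags * exp(1i * matrix(runif(N * Fh, -pi, pi), N, Fh))
        tau <- matrix(runif(M * N, -Tn / 4, Tn / 4), M, N)
      }
      # screening always runs unconstrained: sign freedom helps the
      # alternation cross poor basins; the constraint is enforced in the
      # finalist runs below
      for (it in seq_len(n_lock)) {
        S <- phase_step(D, A, tau, S, Tn, sweeps = 3L)
        st <- ewd_step(D, S, A, tau, Tn, n_iter = 1L)
        A <- st$A; tau <- st$tau
      }
      for (it in seq_len(screen_iters)) {
        S <- source_step(D, A, tau, S, Tn)
        st <- ewd_step(D, S, A, tau, Tn, n_iter = 1L)
        A <- st$A; tau <- st$tau
      }
      list(J = fada_objective(D, A, tau, S, Tn),
           A = A, tau = tau, S = S)
    })
  }

  # full alternation with per-harmonic source refinement, from a short-run
  # state to convergence
  long_run <- function(state) {
    A <- state$A; tau <- state$tau; S <- state$S
    J_best <- state$J; best <- state
    J_prev <- state$J
    converged <- FALSE; iters <- max_outer_iter
    for (it in seq_len(max_outer_iter)) {
      S <- source_step(D, A, tau, S, Tn)
      st <- ewd_step(D, S, A, tau, Tn, n_iter = 1L)
      A <- st$A; tau <- st$tau
      J <- fada_objective(D, A, tau, S, Tn)
      if (J < J_best) { J_best <- J; best <- list(J = J, A = A, tau = tau, S = S) }
      if (J_prev - J < tol * max(J_prev, 1e-300) || J < 1e-14 * denom) {
        converged <- TRUE; iters <- it; break
      }
      J_prev <- J
    }
    list(J = J_best, par = best, iters = iters, converged = converged)
  }

  shorts <- lapply(seq_len(n_restarts), short_run)
  errs <- vapply(shorts, `[[`, numeric(1), "J")
  finalists <- order(errs)[seq_len(n_finalists)]
  longs <- lapply(shorts[finalists], long_run)
  errs[finalists] <- vapply(longs, `[[`, numeric(1), "J")
  if (!is.null(warm_start) && inherits(warm_start, "anechoic_model") &&
      warm_start$n_sources < N && warm_start$order == Fh) {
    # nested initialization: keep the smaller model's sources and seed each
    # missing source from the dominant channel of the current residual
    Aw <- warm_start$weights
    tw <- warm_start$delays * data$sample_rate
    Sw <- source_coeff_matrix(warm_start)
    while (nrow(Sw) < N) {
      Rw <- D - model_coeffs(Aw, tw, Sw, Tn)
      i_star <- which.max(rowSums(Mod(Rw)^2))
      Sw <- rbind(Sw, Rw[i_star, ])
      Aw <- cbind(Aw, 0); tw <- cbind(tw, 0)
      st <- ewd_step(D, Sw, Aw, tw, Tn, n_iter = 2L)
      Aw <- st$A; tw <- st$tau
      Sw <- source_step(D, Aw, tw, Sw, Tn)
    }
    warm <- long_run(list(J = fada_objective(D, Aw, tw, Sw, Tn),
                          A = Aw, tau = tw, S = Sw))
    longs <- c(longs, list(warm))
    finalists <- c(finalists, NA_integer_)
  }
  best_pos <- which.min(vapply(longs, `[[`, numeric(1), "J"))
  best_idx <- finalists[best_pos]
  best <- longs[[best_pos]]
  A <- best$par$A; tau <- best$par$tau; S <- best$par$S

  # canonical form: unit-norm sources with a positive dominant extremum,
  # delays wrapped with zero weighted mean per source, sources ordered by
  # explained variance
  canonicalize <- function(A, tau, S, flip_signs = TRUE) {
    for (j in seq_len(N)) {
      lam <- sqrt(2 * Tn * sum(Mod(S[j, ])^2))
      if (lam > 0) { S[j, ] <- S[j, ] / lam; A[, j] <- A[, j] * lam }
      w <- abs(A[, j])
      if (sum(w) > 0) {
        # alternate wrapping and re-centring: wrapping can move the weighted
        # mean, so iterate until both conventions are met (or nearly so for
        # delay distributions that straddle the circular boundary)
        for (pass in 1:3) {
          tau[, j] <- wrap_delay(tau[, j], Tn)
          dshift <- sum(w * tau[, j]) / sum(w)
          tau[, j] <- tau[, j] - dshift
          S[j, ] <- S[j, ] * exp(-2i * pi * seq_len(Fh) * dshift / Tn)
        }
        tau[, j] <- wrap_delay(tau[, j], Tn)
      }
      if (flip_signs) {
        sj <- 2 * Re(S[j, , drop = FALSE] %*%
                       exp(2i * pi * outer(seq_len(Fh), 0:(Tn - 1L)) / Tn))
        if (abs(min(sj)) > max(sj)) { S[j, ] <- -S[j, ]; A[, j] <- -A[, j] }
      }
    }
    tau <- wrap_delay(tau, Tn)
    ord <- order(colSums(A^2), decreasing = TRUE)
    list(A = A[, ord, drop = FALSE], tau = tau[, ord, drop = FALSE],
         S = S[ord, , drop = FALSE])
  }
  cf <- canonicalize(A, tau, S)
  A <- cf$A; tau <- cf$tau; S <- cf$S
  if (nonneg_weights) {
    # optimization runs unconstrained (sign freedom helps it escape poor
    # basins); the constraint is enforced by a final delay/weight
    # re-estimation against the canonical sources
    st <- ewd_step(D, S, A, tau, Tn, n_iter = 3L, nonneg = TRUE)
    cf <- canonicalize(st$A, st$tau, S, flip_signs = FALSE)
    A <- cf$A; tau <- cf$tau; S <- cf$S
  }

  model <- structure(list(
    sources = lapply(seq_len(N), function(j)
      fourier_series(c(0, S[j, ]), period = Tn,
                     sample_rate = data$sample_rate)),
    weights = A,
    delays = tau / data$sample_rate,
    n_sources = N, order = Fh,
    channel_means = mu,
    channel_labels = data$channel_labels,
    trial_ids = data$trial_ids,
    period = Tn, sample_rate = data$sample_rate,
    restart_errors = sqrt(2 * Tn * errs),
    best_restart = best_idx,
    finalists = finalists,
    converged = vapply(longs, `[[`, logical(1), "converged"),
    outer_iters = vapply(longs, `[[`, integer(1), "iters"),
    seed = seed
  ), class = "anechoic_model")
  if (!any(model$converged))
    warn("No restart reached the convergence tolerance; best iterate kept.")
  Xrec <- reconstruct(model)
  model$fit_error <- sqrt(sum((X - Xrec)^2))
  model$vaf <- vaf(X, Xrec)
  model
}

#' Synthesize channel trajectories from a fitted anechoic model
#'
#' Evaluates `mean_i + sum_j a_ij s_j(t - tau_ij)` from the Fourier
#' representation on `n_samples` equally spaced points over the record.
#'
#' @param model An `anechoic_model` from [fit_fada()].
#' @param n_samples Number of evaluation points (default: native length).
#' @return Numeric matrix, channels by `n_samples`.
#' @export
reconstruct <- function(model, n_samples = model$period) {
  stopifnot(inherits(model, "anechoic_model"))
  n <- as.integer(n_samples)
  S <- source_coeff_matrix(model)
  Fh <- ncol(S); M <- nrow(model$weights)
  tau_frac <- (model$delays * model$sample_rate) / model$period  # of period
  C <- matrix(0i, M, Fh)
  for (j in seq_len(ncol(model$weights))) {
    C <- C + (model$weights[, j] *
                exp(-2i * pi * outer(tau_frac[, j], seq_len(Fh)))) *
      matrix(S[j, ], M, Fh, byrow = TRUE)
  }
  coeff_eval(C, n) + model$channel_means
}

#' @export
print.anechoic_model <- function(x, ...) {
  cat(sprintf("<anechoic_model> %d source%s, order %d, %d channels\n",
              x$n_sources, if (x$n_sources == 1L) "" else "s",
              x$order, nrow(x$weights)))
  cat(sprintf("  VAF %.2f%%, residual %.4g, best of %d restarts (#%d)\n",
              x$vaf, x$fit_error, length(x$restart_errors), x$best_restart))
  invisible(x)
}

#' Tidy the mixing parameters of an anechoic model
#'
#' @param x An `anechoic_model`.
#' @param ... Unused.
#' @return Tibble with one row per (channel, source): columns `channel`,
#'   `trial`, `source`, `weight`, `delay` (seconds).
#' @method tidy anechoic_model
#' @export
tidy.anechoic_model <- function(x, ...) {
  M <- nrow(x$weights); N <- x$n_sources
  tibble::tibble(
    channel = rep(x$channel_labels, times = N),
    trial = rep(x$trial_ids %||% rep(NA, M), times = N),
    source = rep(seq_len(N), each = M),
    weight = as.vector(x$weights),
    delay = as.vector(x$delays)
  )
}

#' One-row summary of an anechoic model fit
#'
#' @param x An `anechoic_model`.
#' @param ... Unused.
#' @return Tibble with `n_sources`, `order`, `vaf`, `fit_error`,
#'   `n_restarts`, `n_converged`, `best_restart`.
#' @method glance anechoic_model
#' @export
glance.anechoic_model <- function(x, ...) {
  tibble::tibble(n_sources = x$n_sources, order = x$order, vaf = x$vaf,
                 fit_error = x$fit_error,
                 n_restarts = length(x$restart_errors),
                 n_converged = sum(x$converged),
                 best_restart = x$best_restart)
}

#' Extract fitted source waveforms as a tibble
#'
#' @param model An `anechoic_model`.
#' @param n_samples Evaluation points per source.
#' @return Tibble with `source`, `time` (seconds) and `value`.
#' @export
source_waveforms <- function(model, n_samples = model$period) {
  tt <- (0:(n_samples - 1L)) / n_samples * model$period / model$sample_rate
  purrr::map_dfr(seq_along(model$sources), function(j)
    tibble::tibble(source = j, time = tt,
                   value = fourier_eval(model$sources[[j]], n_samples)))
}

#' @method autoplot anechoic_model
#' @export
autoplot.anechoic_model <- function(object, ...) {
  df <- source_waveforms(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~source, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "source amplitude",
                  title = sprintf("Anechoic sources (VAF %.1f%%)", object$vaf))
}
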