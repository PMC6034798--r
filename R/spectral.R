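#' Split a record into consecutive analysis windows
#'
#' Records are processed in non-overlapping consecutive windows (the
#' device splits its 30 s records into 10 s intervals, giving three
#' windows per record). A trailing partial window is discarded.
#'
#' @param record an `acg_record`.
#' @param window_s window length in seconds (default 10); must not exceed
#'   the record duration.
#' @return a list of `acg_window` objects, each carrying its samples, the
#'   sampling rate, and the global sample offset of its first sample so
#'   that phases are referenced to a common time origin.
#' @export
window_signal <- function(record, window_s = 10) {
  stopifnot(inherits(record, "acg_record"))
  if (window_s > record$duration_s + 1e-12) {
    stop("`window_s` exceeds the record duration", call. = FALSE)
  }
  n_win <- as.integer(round(window_s * record$sampling_rate_hz))
  n_total <- length(record$samples)
  n_windows <- n_total %/% n_win
  purrr::map(seq_len(n_windows), function(i) {
    i0 <- (i - 1L) * n_win
    structure(
      list(samples = record$samples[(i0 + 1L):(i0 + n_win)],
           sampling_rate_hz = record$sampling_rate_hz,
           start_index = i0,
           window_index = i,
           duration_s = window_s),
      class = "acg_window"
    )
  })
}

as_acg_window <- function(x) {
  if (inherits(x, "acg_window")) return(x)
  if (inherits(x, "acg_record")) {
    return(structure(
      list(samples = x$samples, sampling_rate_hz = x$sampling_rate_hz,
           start_index = 0L, window_index = 1L, duration_s = x$duration_s),
      class = "acg_window"
    ))
  }
  stop("expected an `acg_window` or `acg_record`", call. = FALSE)
}

#' Least-squares decomposition of a window into known-frequency sinusoids
#'
#' Fits `y(t) ~ sum_k a_k cos(2 pi f_k t) + b_k sin(2 pi f_k t)` by
#' ordinary least squares. Frequencies are known exactly, so the problem
#' is linear; the normal equations are accumulated in streaming chunks so
#' long windows never need a full design matrix in memory. Amplitude is
#' `A_k = sqrt(a_k^2 + b_k^2)` and phase `phi_k = atan2(a_k, b_k)`, the
#' convention under which a pure `sin(2 pi f t + phi)` yields phase `phi`.
#' Time is referenced to the record origin (the window's global sample
#' offset), so phases are comparable across windows.
#'
#' @param window an `acg_window` (or a whole `acg_record`).
#' @param frequencies_hz component frequencies; must be distinct and below
#'   the Nyquist frequency.
#' @param chunk_size samples per accumulation chunk.
#' @return a tibble of class `acg_spectral_estimate` with columns
#'   `component`, `frequency_hz`, `amplitude`, `phase_rad`, and attributes
#'   `residual_rms`, `window_index`, `window_duration_s`, `n_samples`.
#' @export
lsm_decompose <- function(window, frequencies_hz, chunk_size = 2e6L) {
  w <- as_acg_window(window)
  fs <- w$sampling_rate_hz
  n <- length(w$samples)
  k <- length(frequencies_hz)
  if (anyDuplicated(frequencies_hz) > 0) {
    stop("validation error: duplicate frequencies give a rank-deficient ",
         "design", call. = FALSE)
  }
  if (any(frequencies_hz >= fs / 2)) {
    stop("frequencies must lie below the Nyquist frequency", call. = FALSE)
  }
  if (n < 2 * 2 * k) {
    stop("window too short for ", k, " components (need >= ", 4 * k,
         " samples)", call. = FALSE)
  }
  p <- 2L * k
  xtx <- matrix(0, p, p)
  xty <- numeric(p)
  start <- 1L
  while (start <= n) {
    end <- min(n, start + as.integer(chunk_size) - 1L)
    idx <- seq.int(w$start_index + start - 1L, w$start_index + end - 1L)
    t <- idx / fs
    m <- end - start + 1L
    X <- matrix(0, m, p)
    for (j in seq_len(k)) {
      cycles <- (frequencies_hz[j] * t) %% 1
      arg <- 2 * pi * cycles
      X[, 2L * j - 1L] <- cos(arg)
      X[, 2L * j] <- sin(arg)
    }
    y <- w$samples[start:end]
    xtx <- xtx + crossprod(X)
    xty <- xty + crossprod(X, y)[, 1L]
    start <- end + 1L
  }
  coef <- tryCatch(
    drop(chol2inv(chol(xtx)) %*% xty),
    error = function(e) {
      stop("validation error: rank-deficient sinusoid design (",
           conditionMessage(e), ")", call. = FALSE)
    }
  )
  a <- coef[seq(1L, p, by = 2L)]
  b <- coef[seq(2L, p, by = 2L)]
  # second streaming pass: residuals computed directly, not via the
  # normal-equation identity, which cancels catastrophically on
  # near-noiseless input
  rss <- 0
  start <- 1L
  while (start <= n) {
    end <- min(n, start + as.integer(chunk_size) - 1L)
    idx <- seq.int(w$start_index + start - 1L, w$start_index + end - 1L)
    t <- idx / fs
    pred <- numeric(end - start + 1L)
    for (j in seq_len(k)) {
      arg <- 2 * pi * ((frequencies_hz[j] * t) %% 1)
      pred <- pred + coef[2L * j - 1L] * cos(arg) + coef[2L * j] * sin(arg)
    }
    rss <- rss + sum((w$samples[start:end] - pred)^2)
    start <- end + 1L
  }
  out <- tibble::tibble(
    component = seq_len(k),
    frequency_hz = as.numeric(frequencies_hz),
    amplitude = sqrt(a^2 + b^2),
    phase_rad = atan2(a, b)
  )
  attr(out, "residual_rms") <- sqrt(rss / n)
  attr(out, "window_index") <- w$window_index
  attr(out, "window_duration_s") <- w$duration_s
  attr(out, "n_samples") <- n
  class(out) <- c("acg_spectral_estimate", class(out))
  out
}

#' Residual RMS of a spectral estimate
#' @param estimate an `acg_spectral_estimate`.
#' @return the root-mean-square fit residual in signal units.
#' @export
residual_rms <- function(estimate) attr(estimate, "residual_rms")

# analytic signal via FFT (positive-frequency doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Coarse delay between received and transmitted records
#'
#' Estimates the absolute transit delay, used only to pick the integer
#' cycle counts in [time_of_flight()]; the final sub-sample precision
#' comes from the phases.
#'
#' A continuous uniform-grid multitone is a difficult ranging waveform:
#' its envelope repeats every `1 / spacing` (~6.9 us for the standard
#' grid), the whole waveform every 90 us, and head-scale dispersion
#' decoheres the full-band carrier correlation. Two strategies are
#' implemented:
#'
#' * When `frequencies_hz` is supplied (>= 3 components), the component
#'   phases of both records are recovered by least squares and candidate
#'   delays across `search_window_s` are scored by how well their
#'   cycle-resolved per-component delays fit a line in frequency (the
#'   linear-dispersion signature). A wrong cycle branch produces a
#'   jagged, 1/f-shaped delay profile with tens of nanoseconds of
#'   lack-of-fit versus sub-nanosecond for the true branch, so the true
#'   branch is selected with a wide margin. This is the pipeline path.
#' * Otherwise the band-limited carrier cross-correlation peak inside
#'   the search window is returned with one-sample resolution
#'   (adequate for a dispersionless or narrowband delay).
#'
#' `search_window_s` should bracket the physically admissible delays;
#' the transcranial default of 60--140 microseconds covers head-scale
#' paths at soft-tissue sound speeds. Pass a window containing zero to
#' measure near-zero lags.
#'
#' @param received,transmitted `acg_record`s at the same sampling rate.
#' @param search_window_s numeric length-2, admissible delay range (s).
#' @param frequencies_hz optional component grid enabling the
#'   phase-profile search.
#' @param band_hz passband retained before cross-correlation (Hz); the
#'   default brackets the standard pulse band.
#' @return the estimated delay in seconds.
#' @export
estimate_coarse_delay <- function(received, transmitted,
                                  search_window_s = c(60e-6, 140e-6),
                                  frequencies_hz = NULL,
                                  band_hz = c(0.5e6, 2.2e6)) {
  stopifnot(received$sampling_rate_hz == transmitted$sampling_rate_hz)
  if (search_window_s[2] <= search_window_s[1]) {
    stop("`search_window_s` must be an increasing range", call. = FALSE)
  }
  if (!is.null(frequencies_hz) && length(frequencies_hz) >= 3) {
    return(phase_profile_delay(received, transmitted, search_window_s,
                               frequencies_hz))
  }
  fs <- received$sampling_rate_hz
  x <- transmitted$samples
  y <- received$samples
  n <- max(length(x), length(y))
  nfft <- 2^ceiling(log2(2 * n))
  pad <- function(v) c(v, numeric(nfft - length(v)))
  X <- stats::fft(pad(x))
  Y <- stats::fft(pad(y))
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  fold <- pmin(freqs, fs - freqs)
  mask <- fold >= band_hz[1] & fold <= band_hz[2]
  C <- Y * Conj(X) * mask
  corr <- Re(stats::fft(C, inverse = TRUE) / nfft)
  lag_lo <- ceiling(search_window_s[1] * fs)
  lag_hi <- floor(search_window_s[2] * fs)
  lags <- seq.int(lag_lo, lag_hi)
  # lag l >= 0 sits at index l + 1; negative lags wrap to the tail
  idx <- ifelse(lags >= 0, lags + 1, nfft + lags + 1)
  best <- lags[which.max(corr[idx])]
  best / fs
}

# Cycle-branch search over the admissible delay window: seeds spaced
# closely enough that every integer branch of the lowest component is
# visited; each seed is ladder-resolved (lowest component first, then
# each component against the previous one) and scored by the RMS
# lack-of-fit of its delays to a line in frequency.
phase_profile_delay <- function(received, transmitted, search_window_s,
                                frequencies_hz) {
  f <- as.numeric(frequencies_hz)
  tx_est <- lsm_decompose(transmitted, f)
  rx_est <- lsm_decompose(received, f)
  frac <- wrap_phase(tx_est$phase_rad - rx_est$phase_rad) / (2 * pi)
  ladder <- function(seed) {
    t_k <- numeric(length(f))
    t_ref <- seed
    for (k in seq_along(f)) {
      m <- round(f[k] * t_ref - frac[k])
      t_k[k] <- (frac[k] + m) / f[k]
      t_ref <- t_k[k]
    }
    t_k
  }
  design <- cbind(1, f)
  seeds <- seq(search_window_s[1], search_window_s[2], by = 0.4 / f[1])
  best_t1 <- NA_real_
  best_score <- Inf
  for (s in seeds) {
    t_k <- ladder(s)
    if (t_k[1] < search_window_s[1] - 0.5 / f[1] ||
        t_k[1] > search_window_s[2] + 0.5 / f[1]) next
    score <- sqrt(mean(stats::lm.fit(design, t_k)$residuals^2))
    if (score < best_score) {
      best_score <- score
      best_t1 <- t_k[1]
    }
  }
  if (!is.finite(best_t1)) {
    stop("no admissible delay found in the search window", call. = FALSE)
  }
  best_t1
}

#' Noise level that yields a target per-component phase standard error
#'
#' For a least-squares sinusoid fit on `n_samples` points of white noise
#' with standard deviation `sigma`, the phase standard error of a
#' component of amplitude `A` is `sigma * sqrt(2 / n) / A`. Inverting
#' gives the noise level to inject for a target phase precision, used to
#' calibrate precision simulations.
#'
#' @param amplitude component amplitude (received scale).
#' @param n_samples samples in the analysis window.
#' @param phase_se_rad target phase standard error (radians).
#' @return the white-noise standard deviation.
#' @export
noise_sigma_for_phase_se <- function(amplitude, n_samples, phase_se_rad) {
  amplitude * phase_se_rad * sqrt(n_samples / 2)
}
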