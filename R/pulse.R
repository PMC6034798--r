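#' Define the transmitted compound multitone pulse
#'
#' Acoustocerebrography transmits a compound pulse made of `n_components`
#' discrete sinusoids spanning a band of roughly 0.7--2 MHz. The component
#' frequencies are uniformly spaced from `f_low_hz` to `f_high_hz`
#' inclusive; each component has an integer transmit amplitude on the
#' device's 1--255 scale.
#'
#' @param f_low_hz lowest component frequency (Hz).
#' @param f_high_hz highest component frequency (Hz).
#' @param n_components number of components (>= 2).
#' @param sampling_rate_hz sampling rate F_s (Hz). Must be at least five
#'   times `f_high_hz`; the default 25 MHz is 12.5x the top component.
#' @param amplitudes per-component transmit amplitude in `[1, 255]`;
#'   recycled if scalar.
#' @param record_duration_s default record length in seconds (one exam
#'   records 30 s).
#'
#' @return an object of class `acg_pulse_spec`.
#' @export
#' @examples
#' spec <- pulse_spec()
#' diff(spec$frequencies_hz)[1] # ~144.4 kHz spacing
pulse_spec <- function(f_low_hz = 0.7e6,
                       f_high_hz = 2.0e6,
                       n_components = 10,
                       sampling_rate_hz = 25e6,
                       amplitudes = 128,
                       record_duration_s = 30) {
  if (!is.numeric(f_low_hz) || !is.numeric(f_high_hz) || f_low_hz <= 0 ||
      f_low_hz >= f_high_hz) {
    stop("`f_low_hz` must be positive and strictly below `f_high_hz`",
         call. = FALSE)
  }
  if (n_components < 2) stop("`n_components` must be >= 2", call. = FALSE)
  if (sampling_rate_hz < 5 * f_high_hz) {
    stop("configuration error: sampling rate must be at least 5x the top ",
         "component frequency (got ", sampling_rate_hz, " Hz for f_high ",
         f_high_hz, " Hz)", call. = FALSE)
  }
  amplitudes <- rep_len(as.numeric(amplitudes), n_components)
  if (any(!is.finite(amplitudes)) || any(amplitudes < 1) ||
      any(amplitudes > 255)) {
    stop("validation error: amplitudes must lie in [1, 255]", call. = FALSE)
  }
  if (record_duration_s <= 0) {
    stop("`record_duration_s` must be positive", call. = FALSE)
  }
  structure(
    list(
      frequencies_hz = seq(f_low_hz, f_high_hz, length.out = n_components),
      amplitudes = amplitudes,
      sampling_rate_hz = sampling_rate_hz,
      record_duration_s = record_duration_s
    ),
    class = "acg_pulse_spec"
  )
}

#' @export
print.acg_pulse_spec <- function(x, ...) {
  cat(sprintf(
    "<acg_pulse_spec> %d components, %.3f-%.3f MHz, Fs = %.1f MHz, %g s\n",
    length(x$frequencies_hz), min(x$frequencies_hz) / 1e6,
    max(x$frequencies_hz) / 1e6, x$sampling_rate_hz / 1e6,
    x$record_duration_s
  ))
  invisible(x)
}

#' Describe the acoustic propagation path through the head
#'
#' The path is modelled as a single dispersive, attenuating segment of
#' length `path_length_m`. Phase velocity is linear in frequency,
#' `c(f) = c0 + slope * (f - f_ref)`, and attenuation follows the
#' soft-tissue power law `alpha(f) = alpha0 * (f / 1 MHz)^gamma` (Np/m).
#' Additive white Gaussian receiver noise is specified as an SNR in dB
#' relative to the received signal power; leave `snr_db = NULL` for a
#' noiseless path.
#'
#' @param path_length_m acoustic path length L (m).
#' @param c0_mps phase velocity at the reference frequency (m/s).
#' @param dispersion_slope_mps_per_mhz velocity slope (m/s per MHz).
#' @param alpha0_np_per_m attenuation coefficient at 1 MHz (Np/m).
#' @param attenuation_exponent power-law exponent gamma (>= 0).
#' @param snr_db receiver SNR in dB, or `NULL` for noiseless.
#' @param f_ref_hz reference frequency for `c0_mps` (default mid-band,
#'   1.35 MHz).
#'
#' @return an object of class `acg_medium`.
#' @export
medium_model <- function(path_length_m,
                         c0_mps,
                         dispersion_slope_mps_per_mhz = 0,
                         alpha0_np_per_m = 0,
                         attenuation_exponent = 1,
                         snr_db = NULL,
                         f_ref_hz = 1.35e6) {
  if (path_length_m <= 0) {
    stop("validation error: `path_length_m` must be positive", call. = FALSE)
  }
  if (c0_mps <= 0) stop("`c0_mps` must be positive", call. = FALSE)
  if (alpha0_np_per_m < 0) {
    stop("`alpha0_np_per_m` must be >= 0", call. = FALSE)
  }
  if (attenuation_exponent < 0) {
    stop("`attenuation_exponent` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      path_length_m = path_length_m,
      c0_mps = c0_mps,
      dispersion_slope_mps_per_mhz = dispersion_slope_mps_per_mhz,
      alpha0_np_per_m = alpha0_np_per_m,
      attenuation_exponent = attenuation_exponent,
      snr_db = snr_db,
      f_ref_hz = f_ref_hz
    ),
    class = "acg_medium"
  )
}

#' @export
print.acg_medium <- function(x, ...) {
  cat(sprintf(
    paste0("<acg_medium> L = %.4f m, c(f_ref) = %.1f m/s, slope = %.2f ",
           "m/s/MHz,\n  alpha0 = %.3f Np/m, gamma = %.3f, snr = %s dB\n"),
    x$path_length_m, x$c0_mps, x$dispersion_slope_mps_per_mhz,
    x$alpha0_np_per_m, x$attenuation_exponent,
    if (is.null(x$snr_db)) "none" else format(x$snr_db)
  ))
  invisible(x)
}

#' Phase velocity of a medium at given frequencies
#' @param medium an `acg_medium`.
#' @param f_hz frequencies (Hz).
#' @return velocities (m/s).
#' @export
phase_velocity <- function(medium, f_hz) {
  v <- medium$c0_mps +
    medium$dispersion_slope_mps_per_mhz * (f_hz - medium$f_ref_hz) / 1e6
  if (any(v <= 0)) {
    stop("phase velocity non-positive within the requested band", call. = FALSE)
  }
  v
}

#' Attenuation coefficient of a medium at given frequencies
#' @inheritParams phase_velocity
#' @return attenuation (Np/m).
#' @export
attenuation_coef <- function(medium, f_hz) {
  medium$alpha0_np_per_m * (f_hz / 1e6)^medium$attenuation_exponent
}

# per-component delays (s) and amplitude gains exp(-alpha L)
component_delays <- function(medium, f_hz) {
  medium$path_length_m / phase_velocity(medium, f_hz)
}

component_gains <- function(medium, f_hz) {
  exp(-attenuation_coef(medium, f_hz) * medium$path_length_m)
}

new_record <- function(samples, sampling_rate_hz, duration_s, quality = NA_real_) {
  structure(
    list(samples = samples, sampling_rate_hz = sampling_rate_hz,
         duration_s = duration_s, quality = quality),
    class = "acg_record"
  )
}

#' @export
print.acg_record <- function(x, ...) {
  cat(sprintf("<acg_record> %d samples, Fs = %.1f MHz, %g s, quality = %s\n",
              length(x$samples), x$sampling_rate_hz / 1e6, x$duration_s,
              if (is.na(x$quality)) "unset" else sprintf("%.3f", x$quality)))
  invisible(x)
}

# Sum of delayed, scaled sinusoids, evaluated in chunks so long records do
# not require more than one chunk of scratch per component. The sine
# argument is reduced modulo one cycle before multiplication by 2*pi to
# preserve phase precision at large t.
multitone_samples <- function(freqs, amps, n, fs, delays = NULL, gains = NULL,
                              chunk = 4e6L) {
  if (is.null(delays)) delays <- rep(0, length(freqs))
  if (is.null(gains)) gains <- rep(1, length(freqs))
  out <- numeric(n)
  start <- 1L
  while (start <= n) {
    end <- min(n, start + as.integer(chunk) - 1L)
    t <- (seq.int(start - 1L, end - 1L)) / fs
    acc <- numeric(end - start + 1L)
    for (k in seq_along(freqs)) {
      cycles <- (freqs[k] * (t - delays[k])) %% 1
      acc <- acc + amps[k] * gains[k] * sin(2 * pi * cycles)
    }
    out[start:end] <- acc
    start <- end + 1L
  }
  out
}

#' Synthesize the transmitted pulse waveform
#'
#' Produces the deterministic transmit waveform
#' `y(t) = sum_k A_k sin(2 pi f_k t)` (zero initial phases) sampled at the
#' spec's rate over `duration_s`.
#'
#' @param spec an [pulse_spec()] object.
#' @param duration_s record length; defaults to the spec's record duration.
#' @return an `acg_record`.
#' @export
synthesize_pulse <- function(spec, duration_s = spec$record_duration_s) {
  stopifnot(inherits(spec, "acg_pulse_spec"))
  if (all(spec$amplitudes == 0)) {
    stop("validation error: all-zero amplitudes", call. = FALSE)
  }
  n <- round(duration_s * spec$sampling_rate_hz)
  samples <- multitone_samples(spec$frequencies_hz, spec$amplitudes, n,
                               spec$sampling_rate_hz)
  new_record(samples, spec$sampling_rate_hz, duration_s)
}

#' Propagate a transmitted pulse through a medium
#'
#' Each component k is delayed by `t_k = L / c(f_k)` and scaled by
#' `exp(-alpha(f_k) L)`. The delay is applied as an exact per-component
#' phase shift (2 pi f_k t_k), so ground-truth delays are not limited by
#' the sample grid. White Gaussian noise is added at the medium's
#' `snr_db` relative to the received signal power (omitted when
#' `snr_db` is `NULL`). Noise draws come from the R session RNG; seed with
#' [set.seed()] or [withr::with_seed()] for reproducibility.
#'
#' @param signal the transmitted `acg_record` (from [synthesize_pulse()]).
#' @param spec the [pulse_spec()] the signal was synthesized from.
#' @param medium an [medium_model()].
#' @return an `acg_record` of the received waveform.
#' @export
propagate <- function(signal, spec, medium) {
  stopifnot(inherits(signal, "acg_record"), inherits(spec, "acg_pulse_spec"),
            inherits(medium, "acg_medium"))
  n <- length(signal$samples)
  delays <- component_delays(medium, spec$frequencies_hz)
  gains <- component_gains(medium, spec$frequencies_hz)
  samples <- multitone_samples(spec$frequencies_hz, spec$amplitudes, n,
                               signal$sampling_rate_hz,
                               delays = delays, gains = gains)
  if (!is.null(medium$snr_db)) {
    p_signal <- mean(samples^2)
    sigma <- sqrt(p_signal / 10^(medium$snr_db / 10))
    samples <- samples + stats::rnorm(n, sd = sigma)
  }
  new_record(samples, signal$sampling_rate_hz, signal$duration_s)
}

# one-sided band energy (mean-square units) around f_center +/- halfwidth
band_energy <- function(samples, fs, f_center, halfwidth) {
  n <- length(samples)
  spec <- Mod(stats::fft(samples))^2
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= (f_center - halfwidth) & freqs <= (f_center + halfwidth) &
    freqs <= fs / 2
  2 * sum(spec[keep]) / n^2
}

#' Record quality score from the two extreme components
#'
#' ACG hardware flags a record as usable when the integrated received
#' energy of the two extreme pulse components exceeds 70% of the expected
#' reference energy. The reference for each extreme component is the
#' transmitted band energy scaled by `reference_gains^2`, the expected
#' amplitude gain established during the device's transmit-amplitude
#' selection; with the default gains of 1 the score is simply the
#' received/transmitted band-energy ratio. The score is the minimum over
#' the two extreme components, clipped to `[0, 1]`.
#'
#' @param received,transmitted `acg_record`s at the same sampling rate.
#' @param spec the [pulse_spec()].
#' @param reference_gains expected amplitude gains for the lowest and
#'   highest component (length 2, defaults to `c(1, 1)`).
#' @return a quality fraction in `[0, 1]`; records pass when > 0.70.
#' @export
quality_score <- function(received, spec, transmitted,
                          reference_gains = c(1, 1)) {
  stopifnot(received$sampling_rate_hz == transmitted$sampling_rate_hz)
  f <- spec$frequencies_hz
  extremes <- c(f[1], f[length(f)])
  hw <- if (length(f) > 1) min(diff(f)) / 2 else f[1] / 4
  ratios <- vapply(seq_along(extremes), function(i) {
    e_rx <- band_energy(received$samples, received$sampling_rate_hz,
                        extremes[i], hw)
    e_tx <- band_energy(transmitted$samples, transmitted$sampling_rate_hz,
                        extremes[i], hw)
    e_rx / (e_tx * reference_gains[i]^2)
  }, numeric(1))
  min(pmax(0, pmin(1, ratios)))
}

#' Choose transmit amplitudes that equalize expected received energy
#'
#' Emulates the device's initial per-component transmit amplitude
#' selection on the 1--255 integer scale: amplitudes are set inversely
#' proportional to the medium's expected amplitude gain so all components
#' arrive with roughly equal energy, with the largest set to 255. One
#' deterministic iteration; no hardware feedback loop.
#'
#' @param spec a [pulse_spec()].
#' @param medium an [medium_model()] (typically a calibration estimate).
#' @return integer amplitudes of length `n_components` in `[1, 255]`.
#' @export
select_transmit_amplitudes <- function(spec, medium) {
  gains <- component_gains(medium, spec$frequencies_hz)
  raw <- 1 / gains
  amps <- round(raw / max(raw) * 255)
  as.integer(pmin(255, pmax(1, amps)))
}
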