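#' Parametric description of a frequency-modulated echolocation call
#'
#' An FM call is modelled as a sum of linearly swept harmonics, each of the
#' form \eqn{\cos(2\pi(f_0 t + \frac{1}{2} m t^2))} shaped by a common Kaiser
#' envelope. Each harmonic sweeps downward from its start frequency to its
#' terminal frequency over the call duration; the synthesized waveform is
#' normalized to unit total energy so that signal designs can be compared at
#' equal total power.
#'
#' @param f_start Sweep start frequency in Hz (the highest instantaneous
#'   frequency of the fundamental component).
#' @param f_terminal Sweep terminal (lowest, ending) frequency in Hz.
#' @param duration Call duration in seconds. Default 3 ms, typical of the
#'   vespertilionid search/approach calls modelled here.
#' @param window_beta Kaiser window shape parameter \eqn{\beta} (dimensionless,
#'   default 4). \eqn{\beta = 0} gives a rectangular envelope.
#' @param sample_rate Sampling rate in Hz. Default 500 kHz, comfortably above
#'   twice the highest frequency used by any preset.
#' @param harmonics Optional data frame describing a multiharmonic call, with
#'   columns `f_start`, `f_terminal` (Hz) and `weight` (relative power weight,
#'   positive). When `NULL`, a single component sweeping
#'   `f_start` to `f_terminal` is used.
#'
#' @return An object of class `signal_spec`.
#' @seealso [synthesize_call()], [multiharmonic_spec()]
#' @export
#' @examples
#' spec <- signal_spec(130e3, 40e3)
#' call <- synthesize_call(spec)
#' sum(call$samples^2)  # unit energy
signal_spec <- function(f_start, f_terminal, duration = 3e-3, window_beta = 4,
                        sample_rate = 5e5, harmonics = NULL) {
  if (is.null(harmonics)) {
    harmonics <- data.frame(f_start = f_start, f_terminal = f_terminal,
                            weight = 1)
  }
  stopifnot(is.data.frame(harmonics),
            all(c("f_start", "f_terminal", "weight") %in% names(harmonics)),
            nrow(harmonics) >= 1)
  if (any(harmonics$f_terminal <= 0) ||
      any(harmonics$f_start <= harmonics$f_terminal)) {
    stop("each harmonic must sweep downward: f_start > f_terminal > 0")
  }
  if (any(harmonics$weight <= 0)) stop("harmonic weights must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (window_beta < 0) stop("window_beta must be >= 0")
  f_max <- max(harmonics$f_start)
  if (sample_rate <= 2 * f_max) {
    stop(sprintf(
      "sample_rate (%g Hz) must exceed twice the highest instantaneous frequency (%g Hz)",
      sample_rate, f_max))
  }
  structure(
    list(f_start = f_start, f_terminal = f_terminal, duration = duration,
         window_beta = window_beta, sample_rate = sample_rate,
         harmonics = harmonics),
    class = "signal_spec")
}

#' @export
print.signal_spec <- function(x, ...) {
  cat(sprintf("<signal_spec> %d harmonic(s), %.3g ms, Kaiser beta=%g, fs=%g kHz\n",
              nrow(x$harmonics), x$duration * 1e3, x$window_beta,
              x$sample_rate / 1e3))
  for (p in seq_len(nrow(x$harmonics))) {
    h <- x$harmonics[p, ]
    cat(sprintf("  [%d] %.1f -> %.1f kHz (weight %.3g)\n",
                p, h$f_start / 1e3, h$f_terminal / 1e3, h$weight))
  }
  invisible(x)
}

#' Multiharmonic call specification
#'
#' Builds a multiharmonic FM call from a fundamental sweep: component `p`
#' sweeps `p * f1_start` down to `p * f1_terminal`. The default emulates a
#' five-harmonic approach call of *Rhinopoma microphyllum*: harmonics 2--6 of
#' an (almost silent, hence omitted) 16 -> 12 kHz fundamental, so the emitted
#' components jointly cover 24--96 kHz.
#'
#' @param f1_start,f1_terminal Fundamental sweep start/terminal frequency (Hz).
#' @param harmonic_indices Integer vector of harmonic numbers to include.
#' @param weights Relative power weight per component; equal by default.
#' @inheritParams signal_spec
#' @return A `signal_spec`.
#' @export
multiharmonic_spec <- function(f1_start = 16e3, f1_terminal = 12e3,
                               harmonic_indices = 2:6, weights = NULL,
                               duration = 3e-3, window_beta = 4,
                               sample_rate = 5e5) {
  stopifnot(length(harmonic_indices) >= 1, all(harmonic_indices >= 1))
  if (is.null(weights)) weights <- rep(1, length(harmonic_indices))
  harm <- data.frame(f_start = harmonic_indices * f1_start,
                     f_terminal = harmonic_indices * f1_terminal,
                     weight = weights)
  signal_spec(max(harm$f_start), min(harm$f_terminal), duration = duration,
              window_beta = window_beta, sample_rate = sample_rate,
              harmonics = harm)
}

#' Kaiser envelope window
#'
#' Symmetric Kaiser window with unit peak, used as the call's amplitude
#' envelope.
#'
#' @param n_samples Window length (>= 2).
#' @param beta Shape parameter (>= 0); 0 gives a rectangular window.
#' @return Numeric vector of length `n_samples`.
#' @export
kaiser_envelope <- function(n_samples, beta) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (beta < 0) stop("beta must be >= 0")
  as.numeric(signal::kaiser(n_samples, beta))
}

#' A sampled pressure waveform
#'
#' @param samples Numeric vector of pressure amplitudes (arbitrary units).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `time_series`.
#' @export
time_series <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples @ %g kHz (%.3g ms), energy %.4g\n",
              length(x$samples), x$sample_rate / 1e3,
              length(x$samples) / x$sample_rate * 1e3, sum(x$samples^2)))
  invisible(x)
}

# Instantaneous frequency of harmonic p at times t (internal).
instantaneous_frequency <- function(spec, p, t) {
  h <- spec$harmonics[p, ]
  m <- (h$f_terminal - h$f_start) / spec$duration
  h$f_start + m * t
}

#' Synthesize a time-domain echolocation call
#'
#' Sums the linearly swept harmonics of the specification, each
#' \eqn{x_p(t) = \cos(2\pi(f_{0,p} t + \frac{1}{2} m_p t^2))} with the sweep
#' rate \eqn{m_p} set so the instantaneous frequency reaches the harmonic's
#' terminal frequency at the end of the call, applies the Kaiser envelope, and
#' normalizes the result to unit total energy. Harmonic power weights are
#' applied as amplitude factors `sqrt(weight)` before the final normalization.
#'
#' @param spec A [signal_spec()].
#' @return A [time_series()] of length `round(duration * sample_rate)` with
#'   unit total energy.
#' @export
synthesize_call <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  env <- kaiser_envelope(n, spec$window_beta)
  x <- numeric(n)
  for (p in seq_len(nrow(spec$harmonics))) {
    h <- spec$harmonics[p, ]
    m <- (h$f_terminal - h$f_start) / spec$duration
    x <- x + sqrt(h$weight) * cos(2 * pi * (h$f_start * t + 0.5 * m * t^2))
  }
  x <- x * env
  e <- sum(x^2)
  if (e == 0) stop("synthesized signal has zero energy")
  time_series(x / sqrt(e), spec$sample_rate)
}

#' Normalize a set of signals to equal (unit) total energy
#'
#' Signal designs are compared at equal total power: every waveform is rescaled
#' so that the sum of its squared samples is exactly 1.
#'
#' @param signals A list of [time_series()] objects (or a single one).
#' @return A list of [time_series()] with unit energy each.
#' @export
normalize_power <- function(signals) {
  if (inherits(signals, "time_series")) signals <- list(signals)
  stopifnot(is.list(signals), length(signals) >= 1)
  lapply(signals, function(ts) {
    stopifnot(inherits(ts, "time_series"))
    e <- sum(ts$samples^2)
    if (e == 0) stop("cannot normalize an all-zero signal")
    time_series(ts$samples / sqrt(e), ts$sample_rate)
  })
}

#' Frequency-band grid
#'
#' The spectral support on which observation vectors and beam templates live:
#' a set of strictly increasing band centre frequencies with a logical
#' selection mask. By default the bands are the positive-frequency bins of a
#' zero-padded FFT.
#'
#' @param centre_frequencies Ascending positive frequencies in Hz.
#' @param selection_mask Logical vector, one entry per band; `TRUE` marks the
#'   bands retained for analysis.
#' @return An object of class `band_grid`.
#' @export
band_grid <- function(centre_frequencies, selection_mask = NULL) {
  stopifnot(is.numeric(centre_frequencies), length(centre_frequencies) >= 1)
  if (any(diff(centre_frequencies) <= 0)) {
    stop("centre frequencies must be strictly increasing")
  }
  if (any(centre_frequencies < 0)) stop("centre frequencies must be >= 0")
  if (is.null(selection_mask)) {
    selection_mask <- rep(TRUE, length(centre_frequencies))
  }
  stopifnot(is.logical(selection_mask),
            length(selection_mask) == length(centre_frequencies))
  structure(list(centre_frequencies = centre_frequencies,
                 selection_mask = selection_mask),
            class = "band_grid")
}

#' @export
print.band_grid <- function(x, ...) {
  sel <- x$centre_frequencies[x$selection_mask]
  cat(sprintf("<band_grid> %d bands (%d selected), %.1f - %.1f kHz selected\n",
              length(x$centre_frequencies), sum(x$selection_mask),
              if (length(sel)) min(sel) / 1e3 else NA,
              if (length(sel)) max(sel) / 1e3 else NA))
  invisible(x)
}

#' FFT band grid for a sampling rate
#'
#' Positive-frequency bins (0 to Nyquist) of a length-`nfft` discrete Fourier
#' transform. The default 8192-point transform at 500 kHz resolves the
#' ultrasonic range at ~61 Hz spacing.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param nfft FFT length (default 8192).
#' @return A [band_grid()] with all bands selected.
#' @export
fft_band_grid <- function(sample_rate, nfft = 8192) {
  band_grid((0:(nfft %/% 2)) * sample_rate / nfft)
}

# Selected centre frequencies of a band grid (internal).
active_bands <- function(bands) bands$centre_frequencies[bands$selection_mask]

#' Amplitude spectrum of a waveform on a band grid
#'
#' Magnitude of the discrete Fourier transform of the waveform, zero-padded to
#' a fixed FFT length, evaluated at the band centre frequencies. Band centres
#' must coincide with FFT bin frequencies (the default grids do); only the
#' bands marked selected are returned.
#'
#' @param ts A [time_series()].
#' @param bands A [band_grid()]; defaults to the full FFT grid for the
#'   signal's sample rate.
#' @param nfft FFT length used for zero padding (default 8192).
#' @return Named numeric vector of nonnegative band amplitudes, one per
#'   selected band.
#' @export
amplitude_spectrum <- function(ts, bands = NULL, nfft = 8192) {
  stopifnot(inherits(ts, "time_series"))
  if (is.null(bands)) bands <- fft_band_grid(ts$sample_rate, nfft)
  stopifnot(inherits(bands, "band_grid"))
  nyq <- ts$sample_rate / 2
  if (any(bands$centre_frequencies > nyq + 1e-9)) {
    stop("band centre frequencies must lie within [0, sample_rate/2]")
  }
  if (length(ts$samples) > nfft) stop("signal longer than FFT length")
  X <- stats::fft(c(ts$samples, numeric(nfft - length(ts$samples))))
  mag <- Mod(X[1:(nfft %/% 2 + 1)])
  bin <- round(bands$centre_frequencies / (ts$sample_rate / nfft)) + 1
  if (max(abs((bin - 1) * ts$sample_rate / nfft - bands$centre_frequencies)) >
      1e-6 * ts$sample_rate / nfft) {
    stop("band centres must coincide with FFT bin frequencies")
  }
  out <- mag[bin][bands$selection_mask]
  names(out) <- format(bands$centre_frequencies[bands$selection_mask])
  out
}

#' Select analysis bands by spectral drop relative to the peak
#'
#' Restricts a band grid to the bands whose on-axis amplitude lies within
#' `drop_db` decibels of the spectral peak. This is the support convention used
#' to define a call's bandwidth (a 25 dB drop by default) and hence the K
#' frequency bands carried by all downstream observation vectors.
#'
#' @param on_axis_spectrum Nonnegative amplitude per band of `bands` (all
#'   bands, in grid order).
#' @param bands A [band_grid()] whose length matches `on_axis_spectrum`.
#' @param drop_db Inclusion threshold below the peak, in dB (default 25).
#' @return A [band_grid()] with an updated selection mask.
#' @export
select_bands <- function(on_axis_spectrum, bands, drop_db = 25) {
  stopifnot(inherits(bands, "band_grid"),
            length(on_axis_spectrum) == length(bands$centre_frequencies))
  if (any(on_axis_spectrum < 0) || all(on_axis_spectrum == 0)) {
    stop("spectrum must be nonnegative and not all zero")
  }
  keep <- on_axis_spectrum >= max(on_axis_spectrum) * 10^(-drop_db / 20)
  if (!any(keep)) stop("band selection is empty; check drop_db")
  band_grid(bands$centre_frequencies, keep)
}
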