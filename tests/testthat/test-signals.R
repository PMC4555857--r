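test_that("synthesized sweep has the specified endpoint frequencies", {
  ts <- synthesize_call(emarg_spec())
  fi <- instantaneous_frequency_oracle(ts)
  n <- length(fi)
  # phase differentiation is noisy at the tapered ends; probe just inside
  i_head <- seq(round(0.02 * n), round(0.06 * n))
  i_tail <- seq(round(0.94 * n), round(0.98 * n))
  t_head <- mean(i_head) / ts$sample_rate
  t_tail <- mean(i_tail) / ts$sample_rate
  slope <- (40e3 - 130e3) / 3e-3
  expect_equal(mean(fi[i_head]), 130e3 + slope * t_head, tolerance = 0.01)
  expect_equal(mean(fi[i_tail]), 130e3 + slope * t_tail, tolerance = 0.01)
  # down-sweep contract: instantaneous frequency monotone decreasing
  mid <- seq(round(0.05 * n), round(0.95 * n))
  smoothed <- stats::filter(fi[mid], rep(1 / 25, 25), sides = 2)
  expect_true(all(diff(stats::na.omit(as.numeric(smoothed))) < 0))
})

test_that("multiharmonic call spans 24-96 kHz with five components", {
  spec <- multiharmonic_spec()
  expect_equal(nrow(spec$harmonics), 5)
  expect_equal(min(spec$harmonics$f_terminal), 24e3)
  expect_equal(max(spec$harmonics$f_start), 96e3)
  # each component is a scaled copy of the 16 -> 12 kHz fundamental
  expect_equal(spec$harmonics$f_start / spec$harmonics$f_terminal,
               rep(16 / 12, 5))
})

test_that("every synthesized call has unit total energy", {
  specs <- list(emarg_spec(), multiharmonic_spec(),
                signal_spec(60e3, 20e3, duration = 1e-3, window_beta = 0))
  for (spec in specs) {
    expect_equal(sum(synthesize_call(spec)$samples^2), 1, tolerance = 1e-9)
  }
})

test_that("signal_spec rejects invalid parameter combinations", {
  expect_error(signal_spec(40e3, 130e3), "downward")
  expect_error(signal_spec(130e3, 40e3, duration = -1), "duration")
  expect_error(signal_spec(300e3, 40e3, sample_rate = 5e5), "Nyquist|twice")
  expect_error(multiharmonic_spec(f1_start = 60e3, harmonic_indices = 2:6),
               "twice")
})

test_that("kaiser envelope is symmetric with unit peak, matching the Bessel form", {
  for (n in c(7, 65, 501)) {
    for (beta in c(0, 2, 4, 9)) {
      w <- kaiser_envelope(n, beta)
      expect_equal(w, rev(w))
      expect_equal(max(w), 1)   # odd length: the centre sample sits at the peak
      if (beta == 0) expect_equal(w, rep(1, n))
    }
  }
  # even lengths straddle the peak symmetrically
  w <- kaiser_envelope(64, 4)
  expect_equal(w, rev(w))
  expect_true(max(w) <= 1 && max(w) > 0.999)
  # endpoint of the beta = 4 window is 1 / I0(4), by an independent series
  w <- kaiser_envelope(1500, 4)
  expect_equal(w[1], 1 / bessel_i0_series(4), tolerance = 1e-6)
  expect_equal(w[1], 0.0885, tolerance = 1e-3)
  expect_error(kaiser_envelope(1, 4), "n_samples")
})

test_that("normalize_power equalizes energies and is idempotent", {
  fs <- 5e5
  a <- time_series(2 * sin(2 * pi * 50e3 * (0:999) / fs), fs)  # energy ~4x
  b <- time_series(3 * cos(2 * pi * 80e3 * (0:999) / fs), fs)
  out <- normalize_power(list(a, b))
  expect_equal(sum(out[[1]]$samples^2), 1, tolerance = 1e-12)
  expect_equal(sum(out[[2]]$samples^2), 1, tolerance = 1e-12)
  again <- normalize_power(out)
  expect_equal(again[[1]]$samples, out[[1]]$samples, tolerance = 1e-12)
  solo <- normalize_power(a)
  expect_equal(sum(solo[[1]]$samples^2), 1, tolerance = 1e-12)
  expect_error(normalize_power(time_series(numeric(10), fs)), "zero")
})

test_that("amplitude spectrum peaks at the tone frequency and satisfies Parseval", {
  fs <- 5e5
  nfft <- 8192
  f_tone <- 64 * fs / nfft  # exactly on a bin
  ts <- synthesize_call(signal_spec(f_tone + 1e-9, f_tone - 1e-9,
                                    duration = nfft / fs))
  spec <- amplitude_spectrum(ts)
  grid <- fft_band_grid(fs)
  expect_equal(grid$centre_frequencies[which.max(spec)], f_tone)

  # Parseval: full-FFT power equals energy x FFT length
  x <- synthesize_call(signal_spec(130e3, 40e3))
  full <- Mod(stats::fft(c(x$samples, numeric(nfft - length(x$samples)))))
  expect_equal(sum(full^2), sum(x$samples^2) * nfft, tolerance = 1e-9)
  expect_true(all(amplitude_spectrum(x) >= 0))
})

test_that("chirp spectrum is single-lobed with its peak inside the sweep band", {
  x <- synthesize_call(emarg_spec())
  spec <- amplitude_spectrum(x)
  f <- fft_band_grid(5e5)$centre_frequencies
  fpk <- f[which.max(spec)]
  expect_gt(fpk, 40e3)
  expect_lt(fpk, 130e3)
  # single-lobed down to a 25 dB drop: the retained support is contiguous
  keep <- spec >= max(spec) * 10^(-25 / 20)
  expect_equal(sum(abs(diff(keep))), 2)
})

test_that("band selection keeps exactly the bands within the dB drop", {
  grid <- band_grid(c(1, 2, 3, 4) * 1e4)
  flat <- select_bands(rep(0.5, 4), grid)
  expect_true(all(flat$selection_mask))
  spiky <- select_bands(c(1, 10^(-30 / 20), 10^(-30 / 20), 10^(-30 / 20)),
                        grid, drop_db = 25)
  expect_equal(spiky$selection_mask, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(select_bands(rep(0, 4), grid), "zero")

  # selected support of the 130->40 kHz call is contiguous within the sweep
  x <- synthesize_call(emarg_spec())
  full <- fft_band_grid(5e5)
  sel <- select_bands(amplitude_spectrum(x), full)
  f <- active_bands_of(list(bands = sel))
  expect_true(min(f) >= 35e3 && max(f) <= 135e3)
  expect_equal(diff(range(which(sel$selection_mask))) + 1,
               sum(sel$selection_mask))
})

test_that("amplitude_spectrum rejects bands beyond Nyquist", {
  fs <- 1e5
  ts <- time_series(sin(2 * pi * 10e3 * (0:499) / fs), fs)
  expect_error(amplitude_spectrum(ts, band_grid(c(1e4, 6e4))), "Nyquist|sample_rate")
})
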