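test_that("piston gain is 1 on axis and vanishes at the first Bessel null", {
  em <- emarg_emitter()
  expect_equal(piston_gain(0, 65e3, em), 1)
  expect_equal(piston_gain(0, 125e3, em), 1)

  # first null: x = first positive root of J1, located by bisection on an
  # independent power series
  x1 <- j1_first_root()
  expect_equal(x1, 3.8317, tolerance = 1e-4)
  f <- 125e3
  theta_null <- asin(x1 * em$sound_speed / (2 * pi * f * em$radius)) * 180 / pi
  expect_equal(theta_null, 15.41, tolerance = 1e-3)
  expect_lt(piston_gain(theta_null, f, em), 1e-6)
})

test_that("off-axis gain matches the series-evaluated Bessel form", {
  em <- emarg_emitter()
  x <- 2 * pi * 65e3 / em$sound_speed * em$radius * sin(12 * pi / 180)
  oracle <- abs(2 * bessel_j1_series(x) / x)
  expect_equal(piston_gain(12, 65e3, em), oracle, tolerance = 1e-9)
  expect_equal(oracle, 0.725, tolerance = 2e-3)
})

test_that("gain obeys aperture-frequency duality and stays within [0, 1]", {
  em <- emitter(7e-3)
  thetas <- seq(0.5, 89.5, by = 7)
  freqs <- c(25e3, 60e3, 110e3)
  for (gamma in c(0.5, 2, 3)) {
    em_g <- emitter(7e-3 / gamma)
    for (f in freqs) {
      expect_equal(piston_gain(thetas, f, em),
                   piston_gain(thetas, gamma * f, em_g), tolerance = 1e-12)
    }
  }
  g <- piston_gain(rep(thetas, times = length(freqs)),
                   rep(freqs, each = length(thetas)), em)
  expect_true(all(g >= 0 & g <= 1 + 1e-12))
  # dependence on theta only through sin(theta)
  th <- c(10, 35, 70)
  x <- 2 * pi * 50e3 / em$sound_speed * em$radius * sin(th * pi / 180)
  expect_equal(piston_gain(th, 50e3, em),
               abs(2 * besselJ(x, 1) / x), tolerance = 1e-12)
})

test_that("piston gain rejects out-of-range inputs", {
  em <- emarg_emitter()
  expect_error(piston_gain(-1, 50e3, em), "theta")
  expect_error(piston_gain(95, 50e3, em), "theta")
  expect_error(piston_gain(10, -5, em), "frequency|positive")
  expect_error(emitter(0), "radius|> 0|TRUE")
})

test_that("beam table row at 0 degrees equals the on-axis spectrum", {
  for (tab in list(emarg_table_tv(), emarg_table_pb())) {
    on_axis <- amplitude_spectrum(synthesize_call(emarg_spec()),
                                  tab$bands)
    i0 <- which.min(abs(tab$grid$angles))
    expect_equal(unname(tab$values[i0, ]), unname(on_axis), tolerance = 1e-9)
  }
})

test_that("per-band amplitudes fall monotonically with angle up to the band's first null", {
  tab <- emarg_table_tv()
  em <- emarg_emitter()
  f <- active_bands_of(tab)
  x1 <- j1_first_root()
  for (fi in c(45e3, 70e3, 100e3, 125e3)) {
    j <- which.min(abs(f - fi))
    null_angle <- asin(min(1, x1 * em$sound_speed /
                             (2 * pi * f[j] * em$radius))) * 180 / pi
    keep <- tab$grid$angles <= null_angle - 2
    prof <- tab$values[keep, j]
    expect_true(all(diff(prof) < 1e-4 * prof[1]))
    # oracle: profile proportional to the piston gain itself (on-axis value
    # times gain), within a small synthesis-smearing tolerance
    gain <- piston_gain(tab$grid$angles[keep], f[j], em)
    expect_equal(prof / prof[1], gain, tolerance = 0.02)
  }
})

test_that("high frequencies decay with angle faster than low frequencies", {
  tab <- emarg_table_tv()
  f <- active_bands_of(tab)
  j_hi <- which.min(abs(f - 120e3))
  j_lo <- which.min(abs(f - 50e3))
  ratio <- function(th) {
    i <- which.min(abs(tab$grid$angles - th))
    tab$values[i, j_hi] / tab$values[i, j_lo]
  }
  expect_lt(ratio(50), ratio(10))
  # the contrast grows monotonically up to the high band's second null;
  # beyond it the ratio oscillates with the side-lobe structure
  r <- vapply(c(10, 20, 30), ratio, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("per-band fast mode agrees with time-varying synthesis away from nulls", {
  tv <- emarg_table_tv()
  pb <- emarg_table_pb()
  for (th in c(2, 5, 10, 15)) {
    i <- which.min(abs(tv$grid$angles - th))
    a <- tv$values[i, ]
    b <- pb$values[i, ]
    keep <- b >= max(b) * 10^(-20 / 20)  # bands within 20 dB of the row peak
    expect_lt(max(abs(20 * log10(a[keep] / b[keep]))), 0.5)
  }
  # across all angles the bulk of the bands agree closely
  for (th in c(25, 60, 80)) {
    i <- which.min(abs(tv$grid$angles - th))
    a <- tv$values[i, ]
    b <- pb$values[i, ]
    keep <- b >= max(b) * 10^(-20 / 20)
    expect_lt(stats::median(abs(20 * log10(a[keep] / b[keep]))), 0.2)
  }
})

test_that("angle_spectrum_table validates its inputs", {
  expect_error(angle_grid(10, 5), "TRUE|to > from")
  expect_error(angle_spectrum_table(emarg_spec(), emarg_emitter(),
                                    grid = angle_grid(0, 90, 5),
                                    bands = band_grid(1e3,
                                                      selection_mask = FALSE)),
               "selected|bands")
})
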