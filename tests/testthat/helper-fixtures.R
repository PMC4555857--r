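# Shared, lazily built fixtures. Beam tables are expensive; each is built at
# most once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

emarg_spec <- function() signal_spec(130e3, 40e3)
emarg_emitter <- function() emitter(6.3e-3)

# Fine-grid time-varying table (the default synthesis path).
emarg_table_tv <- function() memo("emarg_tv", function() {
  angle_spectrum_table(emarg_spec(), emarg_emitter())
})

# Fine-grid per-band table (fast path; exact for continuous refinement).
emarg_table_pb <- function() memo("emarg_pb", function() {
  angle_spectrum_table(emarg_spec(), emarg_emitter(), mode = "per_band")
})

# Gamma-tone re-expression of the per-band table.
emarg_table_gt <- function() memo("emarg_gt", function() {
  gammatone_table(emarg_table_pb())
})

emarg_metrics <- function() memo("emarg_metrics", function() {
  metrics_profile(emarg_table_tv())
})

gape_table <- function() memo("gape_all", function() {
  gape_experiment_all()
})

# Small synthetic table with a handful of bands; cheap observations and a
# fully controlled geometry for noise/estimator edge cases.
toy_table <- function(n_bands = 8, step = 1) {
  grid <- angle_grid(0, 30, step)
  f <- seq(40e3, 96e3, length.out = n_bands)
  em <- emitter(6e-3)
  vals <- t(vapply(grid$angles,
                   function(th) piston_gain(th, f, em) * seq(1, 2,
                                                             length.out = n_bands),
                   numeric(n_bands)))
  structure(list(grid = grid,
                 bands = band_grid(f),
                 values = vals,
                 spec = NULL, emitter = em, mode = "per_band", nfft = NA),
            class = "angle_spectrum_table")
}

# Subsample the bands of a table (keeps every `stride`-th band); used to make
# Monte Carlo oracles affordable.
subset_bands <- function(table, stride) {
  sel <- seq(1, ncol(table$values), by = stride)
  f <- active_bands_of(table)[sel]
  out <- table
  out$values <- table$values[, sel, drop = FALSE]
  out$bands <- band_grid(f)
  out
}

active_bands_of <- function(table) {
  table$bands$centre_frequencies[table$bands$selection_mask]
}

# --- independent numeric oracles -------------------------------------------

# Modified Bessel function of the first kind, order 0, by power series.
bessel_i0_series <- function(x, terms = 60) {
  k <- 0:terms
  sum((x / 2)^(2 * k) / factorial(k)^2)
}

# Bessel J1 by power series (accurate for |x| < ~20 at these term counts).
bessel_j1_series <- function(x, terms = 40) {
  k <- 0:terms
  sum((-1)^k / (factorial(k) * gamma(k + 2)) * (x / 2)^(2 * k + 1))
}

# First positive root of J1 located by bisection on the series.
j1_first_root <- function(lo = 3, hi = 4.5, tol = 1e-12) {
  flo <- bessel_j1_series(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- bessel_j1_series(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else hi <- mid
  }
  (lo + hi) / 2
}

# Instantaneous frequency by differentiating the phase of the FFT-based
# analytic signal; independent of the synthesis path.
instantaneous_frequency_oracle <- function(ts) {
  x <- ts$samples
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi  # unwrap increments
  dph * ts$sample_rate / (2 * pi)
}
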