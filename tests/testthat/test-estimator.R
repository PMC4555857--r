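test_that("self-match gives a perfect, scale-invariant correlation peak", {
  tab <- emarg_table_pb()
  i0 <- which.min(abs(tab$grid$angles - 25))
  cv <- correlation_curve(tab$values[i0, ], tab)
  expect_equal(max(cv$values), 1, tolerance = 1e-12)
  expect_equal(cv$peak_angle, 25)
  expect_true(all(cv$values >= 0 & cv$values <= 1 + 1e-9))
  # only the self-match attains 1
  expect_lt(max(cv$values[-i0]), 1)
  cv_scaled <- correlation_curve(7.3 * tab$values[i0, ], tab)
  expect_equal(cv_scaled$values, cv$values, tolerance = 1e-12)
  expect_error(correlation_curve(numeric(ncol(tab$values)), tab), "zero")
})

test_that("noiseless 25-degree echo peaks at 25 with a side lobe near 50", {
  tab <- emarg_table_tv()
  y <- make_observation(tab, 25, noise_spec(Inf, 0))
  cv <- correlation_curve(y, tab)
  expect_equal(cv$peak_angle, 25)
  p <- pslr(cv)
  expect_equal(attr(p, "flag"), "ok")
  expect_equal(attr(p, "side_angle"), 50, tolerance = 0.1)  # ca 50 degrees
  expect_gt(as.numeric(p), 0)
})

test_that("noiseless targets at 5, 25 and 65 degrees are recovered on the grid", {
  tab <- emarg_table_tv()
  step <- tab$grid$step
  for (th in c(5, 25, 65)) {
    y <- make_observation(tab, th, noise_spec(Inf, 0))
    est <- ml_estimate(correlation_curve(y, tab))
    expect_lte(abs(est - th), step)
  }
})

test_that("noiseless estimates equal truth at every interior grid angle", {
  tab <- emarg_table_pb()
  G <- tab$values
  rn2 <- rowSums(G^2)
  C <- (G %*% t(G))^2 / outer(rn2, rn2)
  peaks <- max.col(C, ties.method = "first")
  interior <- 2:(nrow(G) - 1)
  expect_true(all(peaks[interior] == interior))
})

test_that("a flat curve returns the smallest grid angle with a flag", {
  tab <- toy_table()
  tab$values <- matrix(1, nrow(tab$values), ncol(tab$values))
  cv <- correlation_curve(rep(1, ncol(tab$values)), tab)
  expect_true(cv$flat_peak)
  est <- ml_estimate(cv)
  expect_equal(as.numeric(est), min(tab$grid$angles))
  expect_true(attr(est, "flat_peak"))
})

test_that("grid argmax matches a naive exhaustive recomputation of the statistic", {
  set.seed(42)
  for (rep in 1:20) {
    n_ang <- sample(10:30, 1)
    n_band <- sample(4:12, 1)
    tab <- toy_table(n_band, step = 1)
    tab$values <- matrix(stats::runif(31 * n_band, 0.1, 1), 31, n_band)
    y <- stats::runif(n_band, 0.1, 1)
    cv <- correlation_curve(y, tab)
    # brute force: explicit loop over angles
    best <- -Inf; best_i <- NA
    for (i in seq_len(nrow(tab$values))) {
      g <- tab$values[i, ]
      stat <- sum(g * y)^2 / (sum(g * g) * sum(y * y))
      if (stat > best) { best <- stat; best_i <- i }
    }
    expect_equal(cv$peak_index, best_i)
    expect_equal(ml_estimate(cv), tab$grid$angles[best_i])
  }
})

test_that("curvature width recovers the closed form of a parabolic peak", {
  w <- 7.3
  theta0 <- 20
  grid <- seq(0, 40, by = 0.05)
  L <- 1 - ((grid - theta0) / w)^2
  res <- sonarbeam:::curvature_width(L, 0.05, which(grid == theta0))
  expect_equal(res$width, w / sqrt(2), tolerance = 1e-6)
  expect_equal(res$flag, "ok")
})

test_that("peak width is flagged flat at broadside and finite off axis", {
  tab <- emarg_table_tv()
  pw0 <- peak_width(tab, 0)
  expect_true(is.infinite(pw0))
  expect_equal(attr(pw0, "flag"), "flat_peak")
  pw25 <- peak_width(tab, 25)
  expect_true(is.finite(pw25) && pw25 > 0)
  expect_equal(attr(pw25, "flag"), "ok")
})

test_that("pslr computes the dB ratio to the largest secondary maximum", {
  grid <- angle_grid(0, 90, 1)
  mk_curve <- function(vals) {
    structure(list(grid = grid, values = vals,
                   peak_angle = grid$angles[which.max(vals)],
                   peak_index = which.max(vals), flat_peak = FALSE),
              class = "correlation_curve")
  }
  vals <- pmax(1 - (grid$angles - 30)^2 / 400, 0) +
    0.1 * exp(-(grid$angles - 70)^2 / 20)
  p <- pslr(mk_curve(vals))
  expect_equal(as.numeric(p), 10, tolerance = 0.05)
  expect_equal(attr(p, "side_angle"), 70, tolerance = 1)

  mono <- mk_curve(exp(-grid$angles / 20))
  pm <- pslr(mono)
  expect_true(is.infinite(pm))
  expect_equal(attr(pm, "flag"), "no_side_lobe")
})

test_that("metrics profiles are invariant to a global rescaling of the table", {
  tab <- toy_table(10, step = 1)
  prof1 <- metrics_profile(tab, report_angles = 5:25)
  tab$values <- tab$values * 3.7
  prof2 <- metrics_profile(tab, report_angles = 5:25)
  expect_equal(prof1$peak_width_deg, prof2$peak_width_deg, tolerance = 1e-12)
  expect_equal(prof1$pslr_db, prof2$pslr_db, tolerance = 1e-12)
})

test_that("continuous refinement stays within a grid step and improves the statistic", {
  tab <- emarg_table_pb()
  sigma <- sigma_from_snr(40, tab)
  y <- make_observation(tab, 25, noise_spec(40, sigma, seed = 5))
  cv <- correlation_curve(y, tab)
  est <- ml_estimate(cv, tab, y, refine = TRUE)
  expect_lte(abs(est - cv$peak_angle), tab$grid$step)
  # noiseless refinement reproduces the true angle almost exactly
  y0 <- make_observation(tab, 25, noise_spec(Inf, 0))
  cv0 <- correlation_curve(y0, tab)
  expect_equal(ml_estimate(cv0, tab, y0, refine = TRUE), 25,
               tolerance = 1e-4)
})
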