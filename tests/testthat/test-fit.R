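test_that("log-quadratic initial estimate is exact on noiseless signals", {
  b <- default_scheme()
  s <- dki_signal(b, 1000, 1.44e-3, 0.69)
  est <- initial_estimate(s, b)
  expect_equal(est[["s0"]], 1000, tolerance = 1e-9)
  expect_equal(est[["d_app"]], 1.44e-3, tolerance = 1e-9)
  expect_equal(est[["k_app"]], 0.69, tolerance = 1e-9)
  # mono-exponential signal starts at the k lower bound
  est0 <- initial_estimate(adc_signal(b, 1000, 1.0e-3), b)
  expect_equal(est0[["k_app"]], 0, tolerance = 1e-9)
  # a heavily concave log-signal clips k at the lower bound
  s_neg <- exp(log(1000) - 1e-3 * as.numeric(b) - 1e-7 * as.numeric(b)^2)
  expect_identical(initial_estimate(s_neg, b)[["k_app"]], 0)
  expect_error(initial_estimate(c(10, 0, 5, 2, 1), b), "positive")
})

test_that("fitter round-trips noiseless signals across the parameter box", {
  b <- default_scheme()
  for (s0 in c(500, 2000)) {
    for (d in c(0.8e-3, 1.44e-3, 2.5e-3)) {
      for (k in c(0, 0.3, 0.69, 1.5)) {
        fit <- fit_dki_voxel(dki_signal(b, s0, d, k), b)
        expect_true(fit$converged)
        expect_equal(fit$s0, s0, tolerance = 1e-6)
        expect_equal(fit$d_app, d, tolerance = 1e-6)
        if (k == 0) {
          expect_lt(fit$k_app, 1e-6)
        } else {
          expect_equal(fit$k_app, k, tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("fitter recovers the two group-mean parameter sets exactly", {
  b <- default_scheme()
  fit_r <- fit_dki_voxel(dki_signal(b, 1000, 1.44e-3, 0.69), b)
  expect_equal(fit_r$k_app, 0.69, tolerance = 1e-6)
  expect_equal(fit_r$d_app, 1.44e-3, tolerance = 1e-6)
  fit_n <- fit_dki_voxel(dki_signal(b, 1000, 1.51e-3, 0.51), b)
  expect_equal(fit_n$k_app, 0.51, tolerance = 1e-6)
  expect_equal(fit_n$d_app, 1.51e-3, tolerance = 1e-6)
})

test_that("ADC fit is the exact log-linear slope on its subset", {
  b <- default_scheme()
  s <- adc_signal(b, 1000, 1.22e-3)
  expect_equal(fit_adc_voxel(s, b), 1.22e-3, tolerance = 1e-12)
  expect_equal(fit_adc_voxel(s, b, subset = c(100, 1700)), 1.22e-3, tolerance = 1e-12)
  # on a kurtosis signal the ADC is defined as the subset's OLS slope
  sk <- dki_signal(b, 1000, 1.44e-3, 0.69)
  sub <- c(100, 500, 900)
  idx <- match(sub, as.numeric(b))
  slope <- -coef(lm(log(sk[idx]) ~ sub))[[2]]
  expect_equal(fit_adc_voxel(sk, b), slope, tolerance = 1e-12)
  expect_error(fit_adc_voxel(s, b, subset = c(100, 800)), "subset")
  expect_error(fit_adc_voxel(c(1, -1, 1, 1, 1), b, subset = c(100, 500)), "positive")
})

test_that("kurtosis fit constrained to k = 0 matches the mono-exponential fit", {
  b <- default_scheme()
  s <- adc_signal(b, 1000, 1.3e-3)
  opt <- fit_options(k_bounds = c(0, 0))
  fit <- fit_dki_voxel(s, b, opt)
  adc_full <- fit_adc_voxel(s, b, subset = as.numeric(b))
  expect_equal(fit$d_app, adc_full, tolerance = 1e-8)
})

test_that("solver never loses to the exhaustive grid oracle", {
  b <- default_scheme()
  set.seed(42)
  grid <- list(
    s0 = seq(600, 1400, length.out = 9),
    d_app = seq(0.5e-3, 3e-3, length.out = 11),
    k_app = seq(0, 2, length.out = 9)
  )
  for (i in 1:20) {
    s0 <- runif(1, 800, 1200)
    d <- runif(1, 0.8e-3, 2.2e-3)
    k <- runif(1, 0.2, 1.2)
    noisy <- abs(dki_signal(b, s0, d, k) + rnorm(5, 0, s0 / 40))
    fit <- fit_dki_voxel(noisy, b)
    oracle <- grid_oracle_fit(noisy, b, grid)
    expect_true(fit$converged)
    expect_lte(fit$rss, oracle$rss + 1e-9)
  }
})

test_that("grid oracle returns on-grid optima and degenerate grids verbatim", {
  b <- default_scheme()
  s <- dki_signal(b, 1000, 1.5e-3, 0.5)
  grid <- list(s0 = c(900, 1000, 1100), d_app = c(1e-3, 1.5e-3, 2e-3),
               k_app = c(0.25, 0.5, 0.75))
  hit <- grid_oracle_fit(s, b, grid)
  expect_equal(c(hit$s0, hit$d_app, hit$k_app), c(1000, 1.5e-3, 0.5))
  expect_equal(hit$rss, 0, tolerance = 1e-20)
  one <- grid_oracle_fit(s, b, list(s0 = 800, d_app = 1e-3, k_app = 1))
  expect_equal(c(one$s0, one$d_app, one$k_app), c(800, 1e-3, 1))
  expect_error(grid_oracle_fit(s, b, list(s0 = 1, d_app = numeric(0), k_app = 1)),
               "non-empty")
})

test_that("noisy-voxel estimates reach the Cramer-Rao precision floor", {
  # the fit should be statistically efficient: its median absolute error may
  # not exceed ~1.25x the CRLB-implied median for an unbiased estimator
  # (0.6745 * CRLB sd). Scaled-down regression; a larger run lives in the
  # acceptance suite.
  b <- default_scheme()
  s0 <- 1000
  d <- 1.3e-3
  k <- 0.6
  sigma <- s0 / 50
  clean <- dki_signal(b, s0, d, k)
  bb <- as.numeric(b)
  grad <- cbind(
    clean / s0,
    clean * (-bb + 2 * bb^2 * d * k / 6),
    clean * (bb^2 * d^2 / 6)
  )
  crlb_sd <- sqrt(diag(solve(crossprod(grad) / sigma^2)))
  set.seed(99)
  errs <- vapply(seq_len(400), function(i) {
    noisy <- sqrt((clean + rnorm(5, 0, sigma))^2 + rnorm(5, 0, sigma)^2)
    fit <- fit_dki_voxel(noisy, b)
    c(abs(fit$k_app - k), abs(fit$d_app - d))
  }, numeric(2))
  expect_lt(median(errs[1, ]), 1.25 * 0.6745 * crlb_sd[3])
  expect_lt(median(errs[2, ]), 1.25 * 0.6745 * crlb_sd[2])
})

test_that("volume fitting maps truth exactly for a noiseless uniform phantom", {
  ph <- small_phantom(seed = 1, d = 1.44e-3, k = 0.69)
  maps <- fit_volume(ph$series, ph$mask)
  inside <- ph$mask$labels > 0L
  expect_true(all(maps$qc[inside] == 0L))
  expect_true(all(abs(maps$k_app[inside] - 0.69) < 1e-6))
  expect_true(all(abs(maps$d_app[inside] / 1.44e-3 - 1) < 1e-6))
  expect_true(all(is.nan(maps$k_app[!inside])))
  expect_true(all(maps$qc[!inside] == 1L))
  # deterministic: a second run is identical
  maps2 <- fit_volume(ph$series, ph$mask)
  expect_identical(maps[c("s0", "d_app", "k_app", "adc", "qc")],
                   maps2[c("s0", "d_app", "k_app", "adc", "qc")])
})

test_that("voxels with non-positive samples are flagged, not fitted", {
  ph <- small_phantom(seed = 1)
  series <- ph$series
  idx <- which(ph$mask$labels == 1L)[1]
  co <- arrayInd(idx, dim(ph$mask$labels))
  sig <- series$signal
  sig[co[1], co[2], co[3], 3] <- 0
  series2 <- dwi_series(sig, series$scheme, series$voxel_size)
  maps <- fit_volume(series2, ph$mask)
  expect_equal(maps$qc[idx], 2L)
  expect_true(is.nan(maps$k_app[idx]))
})

test_that("empty masks warn and return all-NaN maps", {
  ph <- small_phantom(seed = 1)
  empty <- roi_mask(array(0L, dim(ph$mask$labels)))
  expect_warning(maps <- fit_volume(ph$series, empty), "Empty mask")
  expect_true(all(is.nan(maps$k_app)))
  expect_true(all(maps$qc == 1L))
})

test_that("single-voxel fit rejects malformed input", {
  b <- default_scheme()
  expect_error(fit_dki_voxel(rep(0, 5), b), "All-zero")
  expect_error(fit_dki_voxel(c(100, 200), b), "mismatch")
  expect_error(fit_dki_voxel(c(100, 5, 0, 0, 0), b), "3 positive")
})

test_that("tidy() and glance() expose fitted maps as tables", {
  ph <- small_phantom(seed = 1, d = 1.44e-3, k = 0.69)
  maps <- fit_volume(ph$series, ph$mask)
  tb <- tidy(maps)
  expect_equal(nrow(tb), sum(maps$qc == 0L))
  expect_true(all(abs(tb$k_app - 0.69) < 1e-6))
  gl <- glance(maps)
  expect_equal(gl$n_fitted, nrow(tb))
  expect_equal(gl$convergence_rate, 1)
})
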