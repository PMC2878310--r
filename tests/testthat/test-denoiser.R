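test_that("noise sigma estimator follows the MAD/0.6745 definition", {
  expect_equal(estimate_sigma(c(0.6745, -0.6745, 0.6745, 0.6745)), 1.0)
  expect_equal(estimate_sigma(rep(0, 4)), 0)
  expect_error(estimate_sigma(numeric(0)), "insufficient data")
})

test_that("sigma estimate is unbiased on white noise at the finest scale", {
  # scaled-down Monte Carlo (the acceptance suite runs the full 100 seeds)
  est <- vapply(1:25, function(s) {
    set.seed(s)
    estimate_sigma(dwt(rnorm(8192), "db4", 1)$details[[1L]])
  }, 0)
  expect_gte(mean(est), 0.95)
  expect_lte(mean(est), 1.05)
})

test_that("universal threshold has the Donoho-Johnstone closed form", {
  expect_equal(universal_threshold(1, 4096), sqrt(2 * log(4096)))
  expect_equal(universal_threshold(0, 100), 0)
  expect_equal(
    universal_threshold(2, 4096),
    2 * universal_threshold(1, 4096)
  )
  expect_error(universal_threshold(1, 1), "invalid length")
})

test_that("hybrid shrinkage reproduces hard and soft rules at the lambda endpoints", {
  set.seed(5)
  w <- runif(1000, -5, 5)
  T <- runif(1000, 0, 3)
  for (i in seq_along(w)) {
    hard <- if (abs(w[i]) <= T[i]) 0 else w[i]
    soft <- if (abs(w[i]) <= T[i]) 0 else sign(w[i]) * (abs(w[i]) - T[i])
    expect_identical(shrink_hybrid(w[i], T[i], lambda = 0), hard)
    expect_identical(shrink_hybrid(w[i], T[i], lambda = 1), soft)
  }
})

test_that("hybrid shrinkage interpolates, contracts and preserves sign", {
  expect_equal(shrink_hybrid(0.5, 1, 0.7), 0)
  expect_equal(shrink_hybrid(2, 1, 0), 2)
  expect_equal(shrink_hybrid(2, 1, 1), 1)
  expect_equal(shrink_hybrid(-2, 1, 0.4), -1.6)
  set.seed(6)
  w <- runif(500, -5, 5)
  out <- shrink_hybrid(w, 1.2, 0.3)
  expect_true(all(abs(out) <= abs(w)))
  expect_true(all(out == 0 | sign(out) == sign(w)))
  expect_error(shrink_hybrid(1, 1, lambda = 1.5), "invalid parameter")
})

test_that("cross-scale correlation is the product of adjacent-scale coefficients", {
  details <- list(rep(2, 8), rep(3, 4), rep(1, 2))
  fld <- scale_correlation(details)
  expect_length(fld$corr, 2L)
  expect_equal(fld$corr[[1L]], rep(6, 8))
  expect_equal(fld$corr[[2L]], rep(3, 4))
  # zero coarser scale kills the correlation
  details2 <- list(rnorm(8), rep(0, 4))
  expect_equal(scale_correlation(details2)$corr[[1L]], rep(0, 8))
  expect_error(scale_correlation(list(rnorm(8))), "insufficient scales")
})

test_that("correlation is maximal at an isolated spike", {
  x <- rep(0, 128)
  x[64] <- 10
  w <- dwt(x, "haar", 3)
  fld <- scale_correlation(w)
  peak_pos <- which.max(abs(fld$corr[[1L]]))
  expect_equal(peak_pos, 32L) # haar coefficient covering samples 63-64
})

test_that("normalized correlation matches the detail energy per scale", {
  set.seed(7)
  w <- dwt(gauss_peak() + rnorm(256, sd = 5), "db4", 4)
  fld <- normalize_correlation(scale_correlation(w), w)
  for (j in seq_along(fld$new_corr)) {
    expect_equal(sum(fld$new_corr[[j]]^2), sum(w$details[[j]]^2),
      tolerance = 1e-8
    )
  }
  # scale-factor cancellation: corr = 2 * Wf gives new_corr = Wf
  details <- list(c(1, -2, 3, 0.5), c(9, 9))
  fld2 <- structure(
    list(corr = list(2 * details[[1L]]), levels = 2L),
    class = "correlation_field"
  )
  out <- normalize_correlation(fld2, details)
  expect_equal(out$new_corr[[1L]], details[[1L]], tolerance = 1e-12)
  # zero correlation energy is flagged, not an error
  fld3 <- structure(
    list(corr = list(rep(0, 4)), levels = 2L),
    class = "correlation_field"
  )
  out3 <- normalize_correlation(fld3, details)
  expect_true(out3$zero_energy[1L])
  expect_equal(out3$new_corr[[1L]], rep(0, 4))
})

test_that("spatial-adaptive mask is empty on degenerate input", {
  w <- dwt(rep(0, 64), "haar", 3)
  m <- spatial_adaptive_mask(w)
  expect_false(any(unlist(m$mask)))
  expect_error(
    spatial_adaptive_mask(dwt(rnorm(64), "haar", 1)),
    "insufficient scales"
  )
})

test_that("spatial-adaptive mask localizes a noiseless step edge", {
  x <- c(rep(0, 99), rep(10, 157))
  w <- dwt(x, "haar", 2)
  m <- spatial_adaptive_mask(w)
  hits <- which(m$mask[[1L]])
  expect_gt(length(hits), 0L)
  # scale-1 haar coefficient n covers samples 2n-1..2n; the edge sits
  # between samples 99 and 100, i.e. coefficient 50
  samples <- 2L * hits
  expect_true(all(abs(samples - 100L) <= 2L))
})

test_that("edges are recovered from noisy steps by the masked reconstruction", {
  # scaled-down Monte Carlo of the SNR-5 localization experiment
  step <- c(rep(0, 99), rep(10, 157))
  hit <- vapply(1:20, function(s) {
    set.seed(s)
    e <- detect_edges(step + rnorm(256, sd = 2))
    nrow(e) > 0 && abs(e$position[1L] - 99.5) <= 2
  }, TRUE)
  expect_gte(mean(hit), 0.85)
  # no signal evidence on pure zeros
  expect_equal(nrow(detect_edges(rep(0, 256))), 0L)
})

test_that("denoising preserves clean signals and maps zero to zero", {
  expect_equal(denoise_signal(rep(0, 256)), rep(0, 256))
  clean <- gauss_peak()
  den <- denoise_signal(clean)
  expect_length(den, 256L)
  expect_lt(sqrt(mean((den - clean)^2)), 0.05 * 100)
})

test_that("denoising reduces the error of noisy peaks", {
  clean <- gauss_peak()
  ratios <- vapply(1:15, function(s) {
    set.seed(s)
    noisy <- clean + rnorm(256, sd = 20)
    den <- denoise_signal(noisy)
    sqrt(mean((den - clean)^2)) / sqrt(mean((noisy - clean)^2))
  }, 0)
  expect_lt(median(ratios), 0.7)
})

test_that("expected denoising error is monotone in the noise level", {
  clean <- gauss_peak()
  rmse_at <- function(sd_noise) {
    median(vapply(1:15, function(s) {
      set.seed(s)
      den <- denoise_signal(clean + rnorm(256, sd = sd_noise))
      sqrt(mean((den - clean)^2))
    }, 0))
  }
  r <- vapply(c(20, 10, 5), rmse_at, 0)
  # one-sided tolerance: 5% slack for Monte-Carlo wobble
  expect_lte(r[2L], r[1L] * 1.05)
  expect_lte(r[3L], r[2L] * 1.05)
})

test_that("denoising is close to idempotent on the standard fixture", {
  set.seed(9)
  x <- gauss_peak() + rnorm(256, sd = 5)
  d1 <- denoise_signal(x)
  d2 <- denoise_signal(d1)
  expect_lt(
    sqrt(mean((d2 - d1)^2)),
    0.1 * sqrt(mean(d1^2))
  )
})

test_that("denoise configuration validates its parameters", {
  expect_error(denoise_config(lambda = 1.2), "lambda")
  cfg <- denoise_config(wavelet = "haar", levels = 3, threshold_scope = "per-scale")
  expect_s3_class(cfg, "denoise_config")
  # config is honoured end to end
  set.seed(10)
  x <- gauss_peak() + rnorm(256, sd = 5)
  expect_length(denoise_signal(x, cfg), 256L)
  # short signals reduce depth instead of failing
  expect_length(denoise_signal(c(1, 2, 4, 2, 1, 0.5, 0.2, 0.1)), 8L)
})
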