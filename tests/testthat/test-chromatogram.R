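make_spectra <- function(mz_list, int_list, rt = NULL) {
  n <- length(mz_list)
  tibble::tibble(
    scan = seq_len(n),
    rt = if (is.null(rt)) as.numeric(seq_len(n) - 1L) else rt,
    mz = mz_list,
    intensity = int_list
  )
}

test_that("chromatogram constructor enforces its invariants", {
  expect_s3_class(chromatogram(1:3, 0:2, c(1, 2, 1)), "chromatogram")
  expect_error(chromatogram(c(1, 1, 2), 0:2, c(1, 2, 1)), "strictly increasing")
  expect_error(chromatogram(1:3, 0:2, c(1, -2, 1)), "non-negative")
  expect_error(chromatogram(1:3, 0:1, c(1, 2, 1)), "equal length")
})

test_that("XIC extraction sums matching peaks per scan and zeroes the rest", {
  sp <- make_spectra(
    list(500.0, 500.0, 500.0),
    list(10, 20, 10)
  )
  xic <- extract_xic(sp, 500.0, 0.5)
  expect_equal(xic$intensity, c(10, 20, 10))
  # centre offset by twice the tolerance: nothing matches
  xic0 <- extract_xic(sp, 501.0, 0.5)
  expect_equal(xic0$intensity, c(0, 0, 0))
  # two peaks inside tolerance are summed; hand-computed fixture
  sp2 <- make_spectra(
    list(c(499.8, 500.1, 502.0), c(499.9, 500.4)),
    list(c(5, 7, 100), c(3, 11))
  )
  expect_equal(extract_xic(sp2, 500.0, 0.5)$intensity, c(12, 14))
  expect_error(extract_xic(sp[0, ], 500.0), "empty input")
})

test_that("peak region spans the expected width of a clean Gaussian", {
  n <- 128
  clean <- gauss_peak(n, apex = 50, amplitude = 100, sigma = 5)
  chrom <- chromatogram(1:n, 0:(n - 1), clean)
  reg <- find_peak_region(chrom, 50, clean)
  expect_equal(reg$apex_scan, 50L)
  # 5% boundary factor cuts a Gaussian at sqrt(2 log 20) = 2.45 sigma
  half_width <- (reg$end_scan - reg$start_scan) / 2
  expect_gt(half_width, 2 * 5)
  expect_lt(half_width, 4 * 5)
})

test_that("flat traces give no-peak errors and plateaus break ties early", {
  flat <- chromatogram(1:64, 0:63, rep(0, 64))
  expect_error(find_peak_region(flat, 30, rep(0, 64)), "no peak")
  # plateau: two equal maxima at scans 30 and 31
  y <- gauss_peak(64, apex = 30, sigma = 4)
  y <- pmin(y, y[28])
  chrom <- chromatogram(1:64, 0:63, y)
  reg <- find_peak_region(chrom, 30, y)
  expect_equal(reg$apex_scan, 28L) # first scan reaching the plateau value
})

test_that("overlapping peaks are split and the expected peak quantified", {
  n <- 256
  s <- 1:n
  clean <- 300 * exp(-(s - 120)^2 / 50) + 100 * exp(-(s - 140)^2 / 50)
  chrom <- chromatogram(s, s - 1, clean)
  den <- denoise_signal(clean)
  reg <- find_peak_region(chrom, 120, den)
  sp <- split_overlap(chrom, reg, den, expected_rt = chrom$rt[120])
  expect_true(sp$split_from_overlap)
  # never extends beyond the parent region
  expect_gte(sp$start_scan, reg$start_scan)
  expect_lte(sp$end_scan, reg$end_scan)
  bg <- estimate_background(chrom, sp, den)
  area <- peak_area(chrom, sp, den, bg)
  truth <- 300 * 5 * sqrt(2 * pi)
  expect_lt(abs(area - truth) / truth, 0.1)

  # picking the minor peak when the expected RT sits there
  sp_minor <- split_overlap(chrom, reg, den, expected_rt = chrom$rt[140])
  expect_true(sp_minor$split_from_overlap)
  expect_gt(sp_minor$apex_scan, 130L)
})

test_that("single and fully merged peaks are not split", {
  n <- 256
  s <- 1:n
  single <- 300 * exp(-(s - 120)^2 / 50)
  ch1 <- chromatogram(s, s - 1, single)
  den1 <- denoise_signal(single)
  r1 <- find_peak_region(ch1, 120, den1)
  expect_false(split_overlap(ch1, r1, den1, expected_rt = 119)$split_from_overlap)

  merged <- 300 * exp(-(s - 120)^2 / 50) + 100 * exp(-(s - 122)^2 / 50)
  ch2 <- chromatogram(s, s - 1, merged)
  den2 <- denoise_signal(merged)
  r2 <- find_peak_region(ch2, 120, den2)
  expect_false(split_overlap(ch2, r2, den2, expected_rt = 119)$split_from_overlap)
})

test_that("background comes from the flanking median with an in-region fallback", {
  n <- 100
  y <- c(rep(5, 40), gauss_peak(20, apex = 10, sigma = 3) + 5, rep(5, 40))
  chrom <- chromatogram(1:n, 0:(n - 1), y)
  reg <- tibble::tibble(
    start_scan = 41L, end_scan = 60L, apex_scan = 50L,
    background = NA_real_, area = NA_real_,
    split_from_overlap = FALSE, valley_scan = NA_integer_
  )
  expect_equal(estimate_background(chrom, reg, y), 5.0)
  # zero-baseline synthetic peak
  z <- gauss_peak(100, apex = 50, sigma = 4)
  chz <- chromatogram(1:100, 0:99, z)
  regz <- find_peak_region(chz, 50, z)
  expect_lt(estimate_background(chz, regz, z), 0.5)
  # no flanks at all: lower-decile fallback
  reg_all <- tibble::tibble(
    start_scan = 1L, end_scan = 100L, apex_scan = 50L,
    background = NA_real_, area = NA_real_,
    split_from_overlap = FALSE, valley_scan = NA_integer_
  )
  expect_gte(estimate_background(chrom, reg_all, y), 0)
})

test_that("noisy baselines are recovered within the Monte-Carlo band", {
  est <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 200
    y <- pmax(50 + gauss_peak(n, apex = 100, sigma = 5) + rnorm(n, sd = 2), 0)
    chrom <- chromatogram(1:n, 0:(n - 1), y)
    den <- denoise_signal(y)
    reg <- find_peak_region(chrom, 100, den)
    estimate_background(chrom, reg, den)
  }, 0)
  expect_true(all(est >= 46 & est <= 54))
})

test_that("peak areas follow the trapezoid over retention time", {
  # constant trace at background: zero area
  chrom <- chromatogram(1:10, 0:9, rep(7, 10))
  reg <- tibble::tibble(
    start_scan = 2L, end_scan = 9L, apex_scan = 5L, background = 7,
    area = NA_real_, split_from_overlap = FALSE, valley_scan = NA_integer_
  )
  expect_equal(peak_area(chrom, reg, chrom$intensity), 0)
  # rectangle of height background + 10 over 5 scans at 1 s spacing
  y <- rep(3, 9)
  y[3:7] <- 13
  ch2 <- chromatogram(1:9, 0:8, y)
  reg2 <- tibble::tibble(
    start_scan = 3L, end_scan = 7L, apex_scan = 5L, background = 3,
    area = NA_real_, split_from_overlap = FALSE, valley_scan = NA_integer_
  )
  expect_equal(peak_area(ch2, reg2, y), 40)
  # unit Gaussian, sigma 5 s: closed form sqrt(2 pi) * 5
  n <- 200
  g <- gauss_peak(n, apex = 100, amplitude = 1, sigma = 5)
  chg <- chromatogram(1:n, 0:(n - 1), g)
  regg <- tibble::tibble(
    start_scan = 75L, end_scan = 125L, apex_scan = 100L, background = 0,
    area = NA_real_, split_from_overlap = FALSE, valley_scan = NA_integer_
  )
  expect_equal(peak_area(chg, regg, g), sqrt(2 * pi) * 5, tolerance = 0.01)
})

test_that("area scales linearly with intensity at zero background", {
  n <- 200
  g <- gauss_peak(n, apex = 100, sigma = 5)
  chg <- chromatogram(1:n, 0:(n - 1), g)
  reg <- find_peak_region(chg, 100, g)
  a1 <- peak_area(chg, reg, g, background = 0)
  a3 <- peak_area(chg, reg, 3 * g, background = 0)
  expect_equal(a3 / a1, 3, tolerance = 1e-6)
})

test_that("de-noised integration is no worse than raw integration on noisy peaks", {
  # standard fixture noise: 5% of apex, baseline at 3x the noise sigma
  truth <- 100 * 5 * sqrt(2 * pi)
  errs <- vapply(1:25, function(s) {
    set.seed(s)
    n <- 256
    y <- pmax(15 + gauss_peak(n) + rnorm(n, sd = 5), 0)
    chrom <- chromatogram(1:n, 0:(n - 1), y)
    den <- denoise_signal(y)
    reg_d <- find_peak_region(chrom, 128, den)
    bg_d <- estimate_background(chrom, reg_d, den)
    err_d <- abs(peak_area(chrom, reg_d, den, bg_d) - truth) / truth
    reg_r <- find_peak_region(chrom, 128, y)
    bg_r <- estimate_background(chrom, reg_r, y)
    err_r <- abs(peak_area(chrom, reg_r, y, bg_r) - truth) / truth
    c(err_d, err_r)
  }, c(0, 0))
  expect_lte(median(errs[1L, ]), median(errs[2L, ]))
})
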