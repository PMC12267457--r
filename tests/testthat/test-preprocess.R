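test_that("constant spectra are reduced to zero by baseline correction", {
  s <- zooms_spectrum(seq(1000, 1500, 0.1), rep(7.5, 5001))
  for (off in c(0, 25)) {
    out <- correct_baseline(s, preprocess_config(baseline_relative_offset = off))
    expect_equal(max(abs(out$intensity)), 0)
  }
})

test_that("planted peak apexes survive baseline correction within 5%", {
  set.seed(42)
  centers <- c(1100, 1300, 1650, 1900)
  amps <- c(50, 80, 35, 60)
  ramp <- function(mz) 5 + 0.01 * (mz - 1000)   # linear chemical background
  s <- planted_spectrum(centers, amps, mz_min = 1000, mz_max = 2000,
                        baseline = ramp, noise_sd = 0)
  out <- correct_baseline(s)
  for (i in seq_along(centers)) {
    apex <- max(out$intensity[abs(out$mz - centers[i]) < 0.5])
    expect_lt(abs(apex - amps[i]) / amps[i], 0.05)
  }
})

test_that("baseline correction is near-idempotent", {
  s <- planted_spectrum(c(1200, 1700), c(40, 60), mz_min = 1000,
                        mz_max = 2000,
                        baseline = function(mz) 10 + 0.005 * (mz - 1000))
  once <- correct_baseline(s)
  twice <- correct_baseline(once)
  expect_lt(abs(sum(twice$intensity) - sum(once$intensity)) /
              sum(once$intensity), 0.01)
})

test_that("order-2 Savitzky-Golay smoothing preserves quadratic signals", {
  mz <- seq(1000, 1010, 0.02)
  y <- 100 + 3 * (mz - 1005) + 0.8 * (mz - 1005)^2
  s <- zooms_spectrum(mz, y)
  for (cycles in c(1L, 2L)) {
    out <- smooth_spectrum(s, preprocess_config(smooth_cycles = cycles))
    expect_equal(out$intensity, y, tolerance = 1e-8)
  }
})

test_that("smoothing reduces white-noise variance and composes over cycles", {
  set.seed(44)
  mz <- seq(1000, 1100, 0.02)
  s <- zooms_spectrum(mz, rnorm(length(mz), 50, 1))
  sm <- smooth_spectrum(s, preprocess_config(smooth_cycles = 1L))
  expect_lt(var(sm$intensity), var(s$intensity))
  twice <- smooth_spectrum(sm, preprocess_config(smooth_cycles = 1L))
  direct <- smooth_spectrum(s, preprocess_config(smooth_cycles = 2L))
  expect_equal(direct$intensity, twice$intensity, tolerance = 1e-12)
})

test_that("noise estimate recovers the planted sigma and resists sparse peaks", {
  set.seed(45)
  mz <- seq(1000, 1200, 0.02)          # 10001 points
  noise <- rnorm(length(mz), 20, 1)
  s <- zooms_spectrum(mz, noise)
  est <- estimate_noise(s)
  expect_true(all(est >= 0.8 & est <= 1.2))

  spiked <- s
  spiked$intensity <- spiked$intensity +
    500 * exp(-(mz - 1100)^2 / (2 * 0.08^2))
  est2 <- estimate_noise(spiked)
  expect_lt(max(abs(est2 - est) / est), 0.10)

  zero <- zooms_spectrum(mz, rep(0, length(mz)))
  expect_true(all(estimate_noise(zero) > 0))
  expect_lt(max(estimate_noise(zero)), 1e-6)
})

test_that("peak picking centroids planted peaks and respects the S/N threshold", {
  set.seed(46)
  pedestal <- function(mz) 20   # residual background, keeps noise unclipped
  s <- planted_spectrum(2000, 10, sigma = 0.08, mz_min = 1950, mz_max = 2050,
                        noise_sd = 1, baseline = pedestal)
  pl <- pick_peaks(smooth_spectrum(mark_processed(s)),
                   noise = estimate_noise(s))
  hit <- pl$peaks[abs(pl$peaks$mz - 2000) < 1, ]
  expect_identical(nrow(hit), 1L)
  expect_lt(abs(hit$mz - 2000), 0.1)
  expect_gte(hit$snr, 3)

  weak <- planted_spectrum(2000, 2, sigma = 0.08, mz_min = 1950,
                           mz_max = 2050, noise_sd = 1, baseline = pedestal)
  plw <- pick_peaks(smooth_spectrum(mark_processed(weak)),
                    noise = estimate_noise(weak))
  expect_identical(nrow(plw$peaks[abs(plw$peaks$mz - 2000) < 0.3 &
                                    plw$peaks$snr >= 3, ]), 0L)
})

test_that("two planted peaks 5 Da apart are resolved to separate centroids", {
  set.seed(47)
  s <- planted_spectrum(c(2000, 2005), c(12, 9), sigma = 0.08,
                        mz_min = 1950, mz_max = 2050, noise_sd = 1,
                        baseline = function(mz) 20)
  pl <- pick_peaks(smooth_spectrum(mark_processed(s)),
                   noise = estimate_noise(s))
  for (ctr in c(2000, 2005)) {
    hit <- pl$peaks[abs(pl$peaks$mz - ctr) < 1, ]
    expect_identical(nrow(hit), 1L)
    expect_lt(abs(hit$mz - ctr), 0.1)
  }
})

test_that("centroid error vanishes as noise vanishes", {
  errs <- vapply(c(0, 0.2), function(sd) {
    set.seed(48)
    s <- planted_spectrum(1500.37, 20, sigma = 0.08, mz_min = 1450,
                          mz_max = 1550, noise_sd = sd)
    pl <- pick_peaks(smooth_spectrum(mark_processed(s)),
                     noise = pmax(estimate_noise(s), 1e-3))
    hit <- pl$peaks[abs(pl$peaks$mz - 1500.37) < 1, ]
    abs(hit$mz[which.max(hit$intensity)] - 1500.37)
  }, numeric(1))
  expect_lt(errs[1], 0.011)   # sub-grid-step accuracy at zero noise
  expect_lte(errs[1], errs[2] + 1e-9)
})

test_that("peak count is nonincreasing in the S/N threshold", {
  set.seed(49)
  s <- planted_spectrum(seq(1210, 1390, 20), runif(10, 3, 40),
                        mz_min = 1150, mz_max = 1450, noise_sd = 1)
  noise <- estimate_noise(s)
  sm <- smooth_spectrum(mark_processed(s))
  counts <- vapply(c(1, 2, 3, 5, 10, 20), function(th)
    nrow(pick_peaks(sm, preprocess_config(snr_threshold = th),
                    noise = noise)$peaks), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pipeline order violations are warned about", {
  s <- planted_spectrum(1200, 30, mz_min = 1150, mz_max = 1250, noise_sd = 1)
  expect_warning(pick_peaks(s), "baseline")
  expect_silent(preprocess_spectrum(s))
  short <- zooms_spectrum(c(1000, 1001, 1002), c(1, 5, 1))
  expect_warning(correct_baseline(short), "single segment")
})
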