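test_that("stationary-segment selection finds flat stretches and rejects drift", {
  b <- simulate_strip(clean_params(noise_sd_mN = 0.05, period_cv = 0.2),
                      1800, 10, seed = 4)
  seg <- select_stationary_segment(b$trace, b$events, min_len_s = 300)
  # drift-free trace: the full eligible extent (past KCl washout) qualifies
  expect_lte(seg$t_start, 310)
  expect_gte(seg$t_end, 1780)

  b_dr <- simulate_strip(clean_params(noise_sd_mN = 0.05, period_cv = 0.2,
                                      drift_mN_per_min = 0.5),
                         1800, 10, seed = 4)
  expect_error(select_stationary_segment(b_dr$trace, b_dr$events,
                                         min_len_s = 300),
               "non-stationary")

  # drifting prologue, flat afterwards: the segment must sit in the flat half
  b_half <- simulate_strip(clean_params(noise_sd_mN = 0.05, period_cv = 0.2,
                                        drift_mN_per_min = 0.8,
                                        drift_stop_s = 900),
                           1800, 10, seed = 4)
  seg2 <- select_stationary_segment(b_half$trace, b_half$events,
                                    min_len_s = 300)
  expect_gte(seg2$t_start, 880)
  # brute-force oracle: scan all contiguous windows of the lower envelope;
  # no window of the chosen segment may drift faster than the tolerance
  env <- myotrace:::lower_envelope(
    b_half$trace$samples[(seg2$t_start * 10):(seg2$t_end * 10)], 10,
    window_s = 60, step_s = 10)
  slopes <- diff(env$env) / diff(env$t) * 60
  expect_true(all(abs(slopes) < 0.01 * 20 * 1.5))
})

test_that("amplitude histograms count every sample and reject constants", {
  expect_error(amplitude_histogram(rep(1, 1000)), "degenerate")
  expect_error(amplitude_histogram(rnorm(50)), "too short")
  x <- rep(c(0, 1), 500)
  h <- amplitude_histogram(x, n_bins = 10)
  expect_equal(sum(h$counts), 1000)
  expect_equal(sum(h$counts > 0), 2)
  set.seed(1)
  x2 <- rnorm(5000)
  h2 <- amplitude_histogram(x2)
  expect_equal(sum(h2$counts), 5000)   # counting oracle
  expect_true(length(h2$centers) >= 30 && length(h2$centers) <= 200)
})

test_that("two-Gaussian fit recovers a labelled mixture and flags unimodality", {
  set.seed(10)
  comp <- sample(c(0, 1), 1e5, replace = TRUE)
  x <- rnorm(1e5, mean = comp, sd = 0.1)
  h <- amplitude_histogram(x)
  gf <- fit_two_gaussians(h)
  # oracle: labelled component means
  sep_true <- mean(x[comp == 1]) - mean(x[comp == 0])
  expect_false(gf$unimodal)
  expect_equal(gf$mu2 - gf$mu1, sep_true, tolerance = 0.02)
  expect_equal(gf$w1, 0.5, tolerance = 0.05)

  # (center, count) pairs are order-free
  h_rev <- h
  h_rev$centers <- rev(h$centers); h_rev$counts <- rev(h$counts)
  gf_rev <- fit_two_gaussians(h_rev)
  expect_equal(gf_rev$mu1, gf$mu1, tolerance = 1e-8)
  expect_equal(gf_rev$mu2, gf$mu2, tolerance = 1e-8)

  set.seed(11)
  h1 <- amplitude_histogram(rnorm(5e4))
  expect_true(fit_two_gaussians(h1)$unimodal)
})

test_that("A_SC is the normalized Gaussian-mean distance", {
  gf <- list(mu1 = 5, mu2 = 5 + 0.046 * 20, sd1 = 0.05, sd2 = 0.05,
             unimodal = FALSE)
  expect_equal(estimate_asc(gf, 20), 4.6)
  expect_equal(estimate_asc(gf, 10), 2 * 4.6)   # definition, not luck
  expect_error(estimate_asc(gf, 0), "normalization")
  gf$unimodal <- TRUE
  expect_warning(a0 <- estimate_asc(gf, 20), "unimodal")
  expect_equal(a0, 0)
})

test_that("the power spectrum satisfies Parseval and resolves pure tones", {
  fs <- 10
  tt <- (0:9999) / fs   # exactly one spectral segment at the default band
  x <- sin(2 * pi * 0.05 * tt)
  sp <- power_spectrum(x, fs, band_low = 0.005, taper = 0, detrend = FALSE)
  expect_equal(sp$freq[which.max(sp$power)], 0.05, tolerance = sp$df)
  # Parseval, exact for an untapered, mean-removed single segment
  expect_equal(sum(sp$power) * sp$df, mean((x - mean(x))^2), tolerance = 1e-9)
  set.seed(3)
  xr <- rnorm(10000)
  spr <- power_spectrum(xr, fs, band_low = 0.005, taper = 0.1)
  expect_equal(sum(spr$power) * spr$df, var(xr), tolerance = 0.01)
  expect_error(power_spectrum(rnorm(100), fs, band_low = 0.005), "resolution")
})

test_that("f_SC estimation picks the strongest harmonic, not the highest", {
  fs <- 10
  tt <- (0:19999) / fs
  x <- sin(2 * pi * 0.03 * tt) + 0.5 * sin(2 * pi * 0.10 * tt)  # power 1 vs 0.25
  sp <- power_spectrum(x, fs, taper = 0)
  pk <- estimate_fsc(sp)
  # brute-force argmax over the periodogram is the oracle
  sel <- sp$freq >= 0.005 & sp$freq <= 0.5
  expect_equal(pk$f_SC, sp$freq[sel][which.max(sp$power[sel])],
               tolerance = sp$df)
  expect_equal(pk$f_SC, 0.03, tolerance = sp$df)

  x2 <- sin(2 * pi * 0.047 * tt)
  pk2 <- estimate_fsc(power_spectrum(x2, fs, taper = 0))
  expect_equal(pk2$f_SC, 0.047, tolerance = sp$df)

  flat <- list(freq = seq(0.001, 0.5, by = 0.001),
               power = rep(1, 500), df = 0.001, n_segments = 1)
  expect_error(estimate_fsc(flat), "no dominant rhythm")
})

test_that("white noise rarely produces a spurious dominant rhythm", {
  set.seed(20)
  hits <- sum(replicate(50, {
    sp <- power_spectrum(rnorm(10000), 10)
    !inherits(tryCatch(estimate_fsc(sp), error = function(e) e), "error")
  }))
  expect_lte(hits, 4)   # calibrated ~1% false-alarm rate
})

test_that("noiseless jitter-free strips are recovered at oracle accuracy", {
  p <- clean_params()
  b <- simulate_strip(p, 1800, 10, seed = 6)
  st <- quantify_spontaneous(b)
  expect_equal(st$A_SC, p$asc_true, tolerance = 0.01)        # <1% relative
  expect_equal(st$f_SC, p$fsc_true,
               tolerance = st$spectrum_peak$band[1] / 5 / p$fsc_true)
  expect_equal(st$T_SC * st$f_SC, 1)
})

test_that("estimates are invariant to gain rescaling and time shifts", {
  b <- simulate_strip(default_params("control", "intact"), 1800, 10, seed = 9)
  st <- quiet_quantify(b)
  st_g <- quiet_quantify(rescale_bundle(b, 3.7))
  # exact up to one auto-binning flip of the histogram under rescaling
  expect_equal(st_g$A_SC, st$A_SC, tolerance = 2e-3)
  expect_equal(st_g$f_SC, st$f_SC, tolerance = 1e-9)
  st_s <- quiet_quantify(shift_bundle(b, 500))
  expect_equal(st_s$A_SC, st$A_SC, tolerance = 1e-6)
  expect_equal(st_s$f_SC, st$f_SC, tolerance = 1e-9)
})

test_that("quantification demands a KCl window for normalization", {
  b <- simulate_strip(clean_params(), 1800, 10, seed = 1)
  b$events$kcl <- NULL
  expect_error(quantify_spontaneous(b), "KCl")
})

test_that("ensemble A_SC and f_SC biases stay below 5% at default noise", {
  p <- default_params("control", "intact")
  co <- simulate_cohort(200, p, master_seed = 31)
  st <- suppressWarnings(lapply(co, quantify_spontaneous))
  est_a <- sapply(st, `[[`, "A_SC")
  est_f <- sapply(st, `[[`, "f_SC")
  tru_a <- sapply(co, function(b) b$ground_truth$params$asc_true)
  tru_f <- sapply(co, function(b) b$ground_truth$params$fsc_true)
  expect_lt(abs(mean(est_a) / mean(tru_a) - 1), 0.05)
  expect_lt(abs(mean(est_f, na.rm = TRUE) / mean(tru_f) - 1), 0.05)
})
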