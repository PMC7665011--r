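test_that("KCl reference amplitude is exact on clean pulses, robust on noisy", {
  b <- flat_bundle(kcl_amp = 20)
  expect_equal(kcl_reference_amplitude(b), 20, tolerance = 1e-12)
  set.seed(5)
  bn <- b
  sigma <- 0.2   # 1% of the pulse
  bn$trace$samples <- bn$trace$samples + rnorm(length(bn$trace$samples), 0, sigma)
  expect_lt(abs(kcl_reference_amplitude(bn) - 20), 3 * sigma)
  b$events$kcl <- NULL
  expect_error(kcl_reference_amplitude(b), "normalization")
})

test_that("EFS amplitudes are exact on noiseless data and monotone in duration", {
  p <- clean_params(asc_true = 0)
  durs <- c(0.4, 1.6, 3.2, 4, 6, 8, 9, 10)
  b <- simulate_strip(p, 2000, 10,
                      protocol_efs_series(durations = durs, start = 300,
                                          atropine = FALSE), seed = 2)
  r <- efs_responses(b)
  expected <- 100 * b$ground_truth$trains$A_total / p$kcl_amp_mN
  expect_equal(r$A_EFS, expected, tolerance = 1e-9)
  expect_true(all(diff(r$A_EFS[order(r$duration)]) >= 0))
})

test_that("a full neurogenic block yields zero EFS response", {
  p <- clean_params(asc_true = 0)
  prot <- protocol_drug("lidocaine", concentration = 2e-3, t_on = 500,
                        t_off = 800, efs_every = 180, duration_s = 800)
  b <- simulate_strip(p, 800, 10, prot, seed = 2)
  r <- efs_responses(b)
  expect_true(all(r$A_EFS[r$onset >= 500] == 0))
  expect_true(all(r$A_EFS[r$onset + 32 < 500] > 0))
  expect_gte(sum(r$onset + 32 < 500), 1)
})

test_that("overlapping response windows are refused", {
  p <- clean_params(asc_true = 0)
  tr <- data.frame(onset = c(300, 320), train_duration = 2,
                   pulse_width_ms = 0.5, frequency_Hz = 10, amplitude_V = 100)
  prot <- event_log(kcl = list(t_on = 60, t_off = 120), efs_trains = tr)
  b <- simulate_strip(p, 600, 10, prot, seed = 1)
  expect_error(efs_amplitude(b, 1), "ambiguity")
})

test_that("normalized EFS amplitudes are gain-invariant", {
  p <- default_params("control", "intact")
  b <- simulate_strip(p, 2000, 10,
                      protocol_efs_series(durations = c(2, 6), start = 300,
                                          atropine = FALSE), seed = 8)
  r1 <- efs_responses(b)
  r2 <- efs_responses(rescale_bundle(b, 0.42))
  expect_equal(r2$A_EFS, r1$A_EFS, tolerance = 1e-9)
})

test_that("duration-response curves aggregate correctly", {
  p <- clean_params(asc_true = 0)
  b <- simulate_strip(p, 3600, 10, protocol_efs_series(), seed = 3)
  r <- efs_responses(b)
  cur_pre <- duration_response(r[!r$atr, ], condition = "pre-ATR")
  cur_atr <- duration_response(r[r$atr, ], condition = "post-ATR")
  expect_equal(cur_pre$duration, sort(cur_pre$duration))
  expect_true(all(is.na(cur_pre$sd_A_EFS)))   # single strip: SD undefined
  expect_true(all(cur_pre$n == 1))
  # ATR can only remove a component: post-ATR curve is pointwise <= pre
  expect_true(all(cur_atr$mean_A_EFS <= cur_pre$mean_A_EFS + 1e-12))
  # saturation: amplitudes level off above 4 s
  sat <- cur_pre$mean_A_EFS[cur_pre$duration >= 4]
  expect_lt(max(sat) - min(sat), 0.05 * max(sat))
})

test_that("cholinergic dissection recovers the configured plateau fraction", {
  # identical curves: no cholinergic component anywhere
  cur <- data.frame(duration = c(1, 2, 4, 6, 8), mean_A_EFS = c(3, 6, 9, 10, 10))
  d0 <- cholinergic_dissection(cur, cur)
  expect_true(all(d0$by_duration$fraction == 0))
  expect_equal(d0$plateau_fraction, 0)

  # parameter recovery at a non-default plateau fraction, noiseless
  p <- clean_params(asc_true = 0, chol_fraction_plateau = 0.3)
  b <- simulate_strip(p, 3600, 10, protocol_efs_series(), seed = 4)
  r <- efs_responses(b)
  d <- cholinergic_dissection(r[!r$atr, ], r[r$atr, ])
  # generator oracle: plateau = cpf * mean share saturation above 4 s
  expect_equal(d$plateau_fraction,
               mean(myotrace:::chol_share(c(4, 6, 8, 9, 10), p)) / 1,
               tolerance = 1e-6)
  expect_equal(d$plateau_fraction, 0.3, tolerance = 0.02)

  # dissection consistency: components sum to the pre-ATR amplitude
  m <- merge(r[!r$atr, c("duration", "A_EFS")], r[r$atr, c("duration", "A_EFS")],
             by = "duration")
  chol <- m$A_EFS.x - m$A_EFS.y
  expect_equal(chol + m$A_EFS.y, m$A_EFS.x, tolerance = 1e-12)
  gt <- b$ground_truth$trains
  expect_equal(chol[order(m$duration)],
               100 * gt$A_chol[1:8][order(gt$train_duration[1:8])] /
                 p$kcl_amp_mN,
               tolerance = 1e-9)
})

test_that("cancer cohorts reproduce the component-wise fold reductions", {
  # noiseless control and cancer strips; folds are measured from recovered
  # plateau components, the generator anchors them at 3.54 and 1.38
  run <- function(group) {
    p <- default_params(group, "intact")
    p$noise_sd_mN <- 0; p$asc_true <- 0; p$period_cv <- 0
    b <- simulate_strip(p, 3600, 10, protocol_efs_series(), seed = 6)
    r <- efs_responses(b)
    m <- merge(r[!r$atr, c("duration", "A_EFS")],
               r[r$atr, c("duration", "A_EFS")], by = "duration")
    list(chol = mean((m$A_EFS.x - m$A_EFS.y)[m$duration >= 4]),
         non = mean(m$A_EFS.y[m$duration >= 4]))
  }
  ctrl <- run("control"); cncr <- run("cancer")
  expect_equal(ctrl$chol / cncr$chol, 3.54, tolerance = 0.01)
  expect_equal(ctrl$non / cncr$non, 1.38, tolerance = 0.01)
})

test_that("fold/percent conversion matches its closed form", {
  # 100 * (1 - 1/3.54) = 71.75; consistent with the reported 71.7% at the
  # precision both numbers were printed with
  expect_lt(abs(fold_to_percent(3.54) - 71.7), 0.1)
  expect_equal(fold_to_percent(1), 0)
  expect_equal(fold_to_percent(2), 50)
  expect_error(fold_to_percent(0.9), "domain")
})
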