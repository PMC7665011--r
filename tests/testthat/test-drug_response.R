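gsk_protocol <- function() protocol_drug("GSK1016790A", t_on = 1500, t_off = 4200)

test_that("drug-evoked tension changes are read off the lower envelope", {
  p <- clean_params()
  b <- simulate_strip(p, 4200, 10, gsk_protocol(), seed = 1)
  d <- baseline_tension_change(b, "GSK1016790A")
  expect_equal(d$delta_tension, 7, tolerance = 0.02)   # configured 7% of KCl

  # a null drug produces no measurable shift
  p0 <- clean_params(noise_sd_mN = 0.05)
  p0$drug_effects$GSK1016790A <- list(tension_amp = 0, tension_tau = 180,
                                      asc_fold = 1, fsc_fold = 1, efs_fold = 1)
  b0 <- simulate_strip(p0, 4200, 10, gsk_protocol(), seed = 2)
  expect_lt(abs(baseline_tension_change(b0, "GSK1016790A")$delta_tension), 0.5)

  # a relaxant of configured size gives the mirrored negative delta
  pr <- clean_params()
  pr$drug_effects$GSK1016790A <- list(tension_amp = -6, tension_tau = 180,
                                      asc_fold = 1, fsc_fold = 1, efs_fold = 1)
  br <- simulate_strip(pr, 4200, 10, gsk_protocol(), seed = 3)
  expect_equal(baseline_tension_change(br, "GSK1016790A")$delta_tension, -6,
               tolerance = 0.05)

  b_short <- b
  b_short$events$drugs$t_off <- b_short$events$drugs$t_on + 10
  expect_error(baseline_tension_change(b_short, "GSK1016790A"), "resolution")
})

test_that("pre/post spontaneous folds recover the configured drug effects", {
  # noiseless: the GSK A_SC fold comes back at oracle precision
  b <- simulate_strip(clean_params(), 4200, 10, gsk_protocol(), seed = 4)
  f <- pre_post_spontaneous(b, "GSK1016790A")
  expect_equal(f$asc_fold, 2.2, tolerance = 0.05)   # within 5%, noiseless
  expect_equal(f$fsc_fold, 1, tolerance = 0.06)

  # a drug with no effect on spontaneous activity: both folds are one
  p0 <- clean_params()
  p0$drug_effects$GSK1016790A <- list(tension_amp = 0, tension_tau = 180,
                                      asc_fold = 1, fsc_fold = 1, efs_fold = 1)
  b0 <- simulate_strip(p0, 4200, 10, gsk_protocol(), seed = 5)
  f0 <- pre_post_spontaneous(b0, "GSK1016790A")
  expect_equal(f0$asc_fold, 1, tolerance = 0.02)
  expect_equal(f0$fsc_fold, 1, tolerance = 0.06)

  # cancer + TEA: frequency stays put while amplitude doubles
  pc <- default_params("cancer", "intact")
  pc$noise_sd_mN <- 0; pc$period_cv <- 0
  bc <- simulate_strip(pc, 4200, 10,
                       protocol_drug("TEA", concentration = 3e-3,
                                     t_on = 1500, t_off = 4200), seed = 6)
  fc <- pre_post_spontaneous(bc, "TEA")
  expect_equal(fc$fsc_fold, 1, tolerance = 0.06)
  expect_equal(fc$asc_fold, pc$drug_effects$TEA$asc_fold, tolerance = 0.05)
})

test_that("pre/post EFS folds recover the configured multipliers", {
  base_prot <- function(drug) {
    pr <- protocol_drug(drug, t_on = 1500, t_off = 4200, efs_every = 180,
                        duration_s = 4200)
    pr$drugs <- rbind(pr$drugs,
                      data.frame(name = "ATR", concentration = 1e-6,
                                 t_on = 0, t_off = 4200))
    pr
  }
  p <- clean_params(asc_true = 0)
  # CAP on an atropine background multiplies A_EFS by 1.3
  b <- simulate_strip(p, 4200, 10, base_prot("CAP"), seed = 7)
  f <- pre_post_efs(b, "CAP")
  expect_equal(f$efs_fold, 1.3, tolerance = 0.05)

  # a neutral drug leaves A_EFS unchanged
  p1 <- clean_params(asc_true = 0)
  p1$drug_effects$CAP$efs_fold <- 1
  b1 <- simulate_strip(p1, 4200, 10, base_prot("CAP"), seed = 8)
  # the CAP tension transient still shifts baselines slightly; 0.1% slack
  expect_equal(pre_post_efs(b1, "CAP")$efs_fold, 1, tolerance = 1e-3)

  # complete block is flagged
  b2 <- simulate_strip(p, 4200, 10, base_prot("lidocaine"), seed = 9)
  f2 <- pre_post_efs(b2, "lidocaine")
  expect_equal(f2$efs_fold, 0)
  expect_match(f2$flags, "zero-response")
})

test_that("folds are gain-invariant and stable to the settling margin", {
  b <- simulate_strip(default_params("control", "intact"), 4200, 10,
                      gsk_protocol(), seed = 10)
  f <- suppressWarnings(pre_post_spontaneous(b, "GSK1016790A"))
  fg <- suppressWarnings(pre_post_spontaneous(rescale_bundle(b, 2.5),
                                              "GSK1016790A"))
  # histogram auto-binning can flip by one bin under rescaling; folds are
  # gain-invariant up to that discreteness
  expect_equal(fg$asc_fold, f$asc_fold, tolerance = 0.01)
  expect_equal(fg$fsc_fold, f$fsc_fold, tolerance = 1e-9)
  for (m in c(60, 120)) {
    fm <- suppressWarnings(pre_post_spontaneous(b, "GSK1016790A",
                                                settling_s = m))
    expect_equal(fm$asc_fold, f$asc_fold, tolerance = 0.02)
    expect_equal(fm$fsc_fold, f$fsc_fold, tolerance = 0.02)
  }
})

test_that("drug_effect assembles the measures each protocol supports", {
  # spontaneous-activity protocol (no EFS): tension + A_SC/f_SC folds
  p <- clean_params()
  b <- simulate_strip(p, 4200, 10, gsk_protocol(), seed = 11)
  de <- drug_effect(b, "GSK1016790A")
  expect_s3_class(de, "drug_effect")
  expect_equal(de$delta_tension, 7, tolerance = 0.1)
  expect_equal(de$asc_fold, 2.2, tolerance = 0.1)
  expect_true(is.na(de$efs_fold))

  # EFS protocol (trains every 3 min leave no segment long enough for the
  # spectral analysis): EFS fold is measured, spontaneous folds are flagged
  pc <- clean_params(asc_true = 0)
  prot <- protocol_drug("CAP", t_on = 1500, t_off = 4200,
                        efs_every = 180, duration_s = 4200)
  bc <- simulate_strip(pc, 4200, 10, prot, seed = 12)
  dc <- drug_effect(bc, "CAP")
  expect_equal(dc$efs_fold, pc$drug_effects$CAP$efs_fold, tolerance = 0.05)
  expect_true(is.na(dc$asc_fold))
  expect_gt(length(dc$flags), 0)
})
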