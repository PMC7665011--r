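#' Generator parameters for one DSM strip
#'
#' All contraction amplitudes are expressed as percent of the strip's 60 mM
#' KCl reference contraction, the normalization that removes strip-size
#' dependence. Frequencies are in Hz, times in seconds, tensions in mN.
#'
#' @param baseline_mN Resting (preload) tension, mN.
#' @param kcl_amp_mN Amplitude of the 60 mM KCl reference contraction, mN.
#' @param asc_true True spontaneous-contraction amplitude, % of KCl.
#' @param fsc_true True spontaneous-contraction frequency, Hz.
#' @param period_cv Coefficient of variation of inter-event intervals
#'   (renewal-process jitter).
#' @param event_duty Fraction of the mean period occupied by one contraction
#'   event (raised-cosine bump width = `event_duty / fsc_true`).
#' @param efs_Amax EFS contraction amplitude at the duration plateau, % of KCl.
#' @param efs_tauD Duration-saturation constant of
#'   `A(D) = Amax * (1 - exp(-D / tauD))`, s.
#' @param chol_fraction_plateau Cholinergic (atropine-blockable) fraction of
#'   the EFS amplitude at plateau durations, in `[0, 1]`.
#' @param chol_delay,chol_tau Onset delay and saturation constant (s) of the
#'   cholinergic share as a function of train duration: the share is
#'   negligible below ~2 s trains and saturates above 4 s.
#' @param purinergic_share Fraction of the non-cholinergic amplitude carried
#'   by the purinergic component (0.8-0.9; summary bookkeeping only).
#' @param drug_effects Named list, one entry per drug, each a list with
#'   `tension_amp` (% of KCl; sign gives direction), `tension_tau` (s, alpha
#'   transient time constant), `asc_fold`, `fsc_fold`, `efs_fold`
#'   (multipliers applied inside the drug window).
#' @param noise_sd_mN SD of white measurement noise, mN.
#' @param drift_mN_per_min Linear baseline drift rate, mN/min.
#' @param drift_stop_s Time at which drift stops (allows a drifting prologue
#'   followed by a stationary plateau); `Inf` keeps drifting.
#' @param re_cv Named list of strip-level random-effect CVs used by
#'   [simulate_cohort()]: `asc`, `fsc`, `kcl`.
#' @param group,urothelium,strip_id,animal_id Strip labels.
#' @param seed Integer seed making [simulate_strip()] deterministic.
#' @return An object of class `strip_params`.
#' @export
strip_params <- function(baseline_mN = 5, kcl_amp_mN = 20,
                         asc_true = 4.6, fsc_true = 0.047,
                         period_cv = 0.2, event_duty = 0.4,
                         efs_Amax = 60, efs_tauD = 1.3,
                         chol_fraction_plateau = 0.52,
                         chol_delay = 1.6, chol_tau = 0.8,
                         purinergic_share = 0.85,
                         drug_effects = list(),
                         noise_sd_mN = 0.05,
                         drift_mN_per_min = 0, drift_stop_s = Inf,
                         re_cv = list(asc = 2.9 / 4.6, fsc = 0.018 / 0.047,
                                      kcl = 0.25),
                         group = "control", urothelium = "intact",
                         strip_id = "strip_01", animal_id = "animal_1",
                         seed = 1L) {
  p <- structure(as.list(environment()), class = "strip_params")
  validate_strip_params(p)
  p
}

validate_strip_params <- function(p) {
  stopifnot(p$asc_true >= 0, p$fsc_true > 0, p$period_cv >= 0,
            p$event_duty > 0, p$event_duty < 1,
            p$chol_fraction_plateau >= 0, p$chol_fraction_plateau <= 1,
            p$kcl_amp_mN > 0, p$efs_tauD > 0)
  invisible(p)
}

#' @export
print.strip_params <- function(x, ...) {
  cat(sprintf(paste0("<strip_params> %s/%s: A_SC %.3g%% KCl, f_SC %.3g Hz, ",
                     "EFS Amax %.3g%% (chol. plateau %.2f), KCl %.3g mN\n"),
              x$group, x$urothelium, x$asc_true, x$fsc_true, x$efs_Amax,
              x$chol_fraction_plateau, x$kcl_amp_mN))
  invisible(x)
}

# Library of drug-effect defaults. Printed study values where available
# (GSK1016790A tension and A_SC folds); the remaining transients are set to
# magnitudes consistent with the qualitative descriptions (modest CAP/CBD/TEA
# tension transients, TEA frequency doubling in control but not cancer,
# complete neurogenic block by lidocaine).
default_drug_effects <- function(group, urothelium) {
  control <- group == "control"
  intact <- urothelium == "intact"
  list(
    GSK1016790A = list(
      tension_amp = if (!control) 7 else if (intact) 7 else 4.5,
      tension_tau = 180,
      asc_fold = if (!control) 1.3 else if (intact) 2.2 else 1.3,
      fsc_fold = 1, efs_fold = 1),
    TEA = list(tension_amp = 5, tension_tau = 60,
               asc_fold = 2, fsc_fold = if (control) 2.5 else 1, efs_fold = 1),
    CAP = list(tension_amp = if (control) 3 else 5, tension_tau = 60,
               asc_fold = 1, fsc_fold = 1,
               efs_fold = if (control) 1.3 else 1.6),
    CBD = list(tension_amp = if (control) 4 else 3.5, tension_tau = 120,
               asc_fold = if (control) 1.5 else 1.4, fsc_fold = 1, efs_fold = 1),
    ATR = list(tension_amp = 0, tension_tau = 60,
               asc_fold = 1, fsc_fold = 1, efs_fold = 1),
    lidocaine = list(tension_amp = 0, tension_tau = 60,
                     asc_fold = 1, fsc_fold = 1, efs_fold = 0)
  )
}

#' Study-anchored default generator parameters
#'
#' Returns the generator parameter set for a control or bladder-cancer DSM
#' strip. Spontaneous-contraction defaults are the study means (control:
#' A_SC 4.6% of KCl at 0.047 Hz; cancer: 2.8% at 0.027 Hz), strip-level
#' random-effect CVs are the printed SD/mean ratios, and the cancer EFS
#' amplitude is derived from the control one by shrinking the cholinergic
#' component 3.54-fold and the non-cholinergic component 1.38-fold.
#'
#' @param group `"control"` or `"cancer"`.
#' @param urothelium `"intact"` or `"denuded"`.
#' @return A [strip_params()] object.
#' @export
default_params <- function(group = c("control", "cancer"),
                           urothelium = c("intact", "denuded")) {
  group <- match.arg(group)
  urothelium <- match.arg(urothelium)
  de <- default_drug_effects(group, urothelium)
  if (group == "control") {
    strip_params(group = group, urothelium = urothelium, drug_effects = de)
  } else {
    ctrl <- strip_params()
    chol <- ctrl$efs_Amax * ctrl$chol_fraction_plateau / 3.54
    nonchol <- ctrl$efs_Amax * (1 - ctrl$chol_fraction_plateau) / 1.38
    strip_params(group = group, urothelium = urothelium,
                 asc_true = 2.8, fsc_true = 0.027,
                 efs_Amax = chol + nonchol,
                 chol_fraction_plateau = chol / (chol + nonchol),
                 re_cv = list(asc = 1.6 / 2.8, fsc = 0.007 / 0.027, kcl = 0.25),
                 drug_effects = de)
  }
}
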