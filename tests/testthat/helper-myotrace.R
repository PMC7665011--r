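# Fixture builders shared across the suite. Everything is generated in code;
# "clean" params switch off noise and timing jitter so constructed amplitudes
# are exact.

clean_params <- function(group = "control", urothelium = "intact", ...) {
  p <- default_params(group, urothelium)
  p$noise_sd_mN <- 0
  p$period_cv <- 0
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

# minimal hand-built bundle: flat baseline with a rectangular KCl pulse
flat_bundle <- function(duration_s = 600, fs = 10, baseline = 5, kcl_amp = 20,
                        kcl_on = 60, kcl_off = 120) {
  tt <- (seq_len(duration_s * fs) - 1) / fs
  y <- rep(baseline, length(tt))
  y[tt >= kcl_on + 5 & tt < kcl_off - 5] <- baseline + kcl_amp
  trace_bundle(
    tension_trace(y, fs, strip_meta = list(strip_id = "hand_01")),
    event_log(kcl = list(t_on = kcl_on, t_off = kcl_off)))
}

# rescale a bundle's gain (units change); all normalized estimates must be
# invariant under this
rescale_bundle <- function(bundle, g) {
  bundle$trace$samples <- bundle$trace$samples * g
  bundle
}

# shift a bundle's clock; all estimates must be invariant under this
shift_bundle <- function(bundle, dt) {
  bundle$trace$start_time <- bundle$trace$start_time + dt
  ev <- bundle$events
  if (!is.null(ev$kcl)) {
    ev$kcl$t_on <- ev$kcl$t_on + dt
    ev$kcl$t_off <- ev$kcl$t_off + dt
  }
  if (nrow(ev$efs_trains)) ev$efs_trains$onset <- ev$efs_trains$onset + dt
  if (nrow(ev$drugs)) {
    ev$drugs$t_on <- ev$drugs$t_on + dt
    ev$drugs$t_off <- ev$drugs$t_off + dt
  }
  bundle$events <- ev
  bundle
}

quiet_quantify <- function(bundle, ...) {
  suppressWarnings(quantify_spontaneous(bundle, ...))
}
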