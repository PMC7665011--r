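#' Experimental protocols for the synthetic generator
#'
#' A protocol is an [event_log()] describing when the KCl reference
#' contraction, EFS trains, and drug windows occur. These builders reproduce
#' the study's designs: a KCl contracture early in the recording, EFS trains
#' applied every 3 min, and long drug windows that leave room for stationary
#' pre/post analysis segments.
#'
#' @param kcl_on,kcl_off KCl window, s.
#' @return An [event_log()].
#' @export
#' @rdname protocols
protocol_spontaneous <- function(kcl_on = 60, kcl_off = 120) {
  event_log(kcl = list(t_on = kcl_on, t_off = kcl_off, concentration_mM = 60))
}

#' @param durations EFS train durations, s. Default is the study's duration
#'   series 0.4-10 s.
#' @param start Onset of the first pre-atropine train, s.
#' @param interval Inter-train interval, s (trains every 3 min).
#' @param atropine If `TRUE`, append an atropine window and repeat the whole
#'   duration series inside it.
#' @param atr_gap_s Gap between the end of the last pre-ATR response and the
#'   first post-ATR train, s.
#' @export
#' @rdname protocols
protocol_efs_series <- function(durations = c(0.4, 1.6, 3.2, 4, 6, 8, 9, 10),
                                start = 400, interval = 180,
                                atropine = TRUE, atr_gap_s = 200,
                                kcl_on = 60, kcl_off = 120) {
  pre <- data.frame(onset = start + (seq_along(durations) - 1) * interval,
                    train_duration = durations,
                    pulse_width_ms = 0.5, frequency_Hz = 10, amplitude_V = 100)
  trains <- pre
  drugs <- empty_drugs()
  if (atropine) {
    atr_on <- max(pre$onset + pre$train_duration) + atr_gap_s
    post <- pre
    post$onset <- post$onset - start + atr_on + 100
    trains <- rbind(pre, post)
    drugs <- data.frame(name = "ATR", concentration = 1e-6,
                        t_on = atr_on,
                        t_off = max(post$onset + post$train_duration) + 60)
  }
  event_log(kcl = list(t_on = kcl_on, t_off = kcl_off, concentration_mM = 60),
            efs_trains = trains, drugs = drugs)
}

#' @param drug Drug name (must have an entry in the params' `drug_effects`).
#' @param concentration Molar concentration recorded in the annotation.
#' @param t_on,t_off Drug window, s. The defaults leave >1000 s of eligible
#'   trace on each side of the application for spectral analysis.
#' @param efs_every If not `NULL`, also schedule 2 s EFS trains at this
#'   interval (s) throughout the recording (the standard stimulation
#'   protocol), for pre/post EFS fold estimation.
#' @param duration_s Recording length the protocol is designed for; EFS
#'   trains are scheduled up to this time.
#' @export
#' @rdname protocols
protocol_drug <- function(drug, concentration = 1e-6,
                          t_on = 1500, t_off = 4200,
                          efs_every = NULL, duration_s = t_off,
                          kcl_on = 60, kcl_off = 120) {
  trains <- empty_trains()
  if (!is.null(efs_every)) {
    onsets <- seq(400, duration_s - 60, by = efs_every)
    trains <- data.frame(onset = onsets, train_duration = 2,
                         pulse_width_ms = 0.5, frequency_Hz = 10,
                         amplitude_V = 100)
  }
  event_log(kcl = list(t_on = kcl_on, t_off = kcl_off, concentration_mM = 60),
            efs_trains = trains,
            drugs = data.frame(name = drug, concentration = concentration,
                               t_on = t_on, t_off = t_off))
}

# raised-cosine bump of unit height on [t0, t0 + w)
raised_cosine <- function(t, t0, w) {
  s <- (t - t0) / w
  ifelse(s >= 0 & s < 1, 0.5 * (1 - cos(2 * pi * s)), 0)
}

# attack-hold-release envelope reaching exactly 1 on [t0+rise, t_hold_end]
ahr_envelope <- function(t, t0, rise, t_hold_end, release) {
  up <- (t - t0) / rise
  down <- (t - t_hold_end) / release
  out <- numeric(length(t))
  i <- t >= t0 & t < t0 + rise
  out[i] <- 0.5 * (1 - cos(pi * up[i]))
  i <- t >= t0 + rise & t <= t_hold_end
  out[i] <- 1
  i <- t > t_hold_end & t < t_hold_end + release
  out[i] <- 0.5 * (1 + cos(pi * down[i]))
  out
}

# piecewise-constant drug multiplier over time
drug_multiplier_fun <- function(drugs, effects, field) {
  function(tt) {
    m <- rep(1, length(tt))
    if (nrow(drugs) == 0) return(m)
    for (i in seq_len(nrow(drugs))) {
      eff <- effects[[drugs$name[i]]]
      if (is.null(eff)) next
      inside <- tt >= drugs$t_on[i] & tt < drugs$t_off[i]
      m[inside] <- m[inside] * (eff[[field]] %||% 1)
    }
    m
  }
}

# cholinergic share of the total EFS amplitude as a function of train
# duration: zero below the onset delay, saturating above ~4 s
chol_share <- function(D, p) {
  g <- pmax(0, 1 - exp(-(D - p$chol_delay) / p$chol_tau))
  p$chol_fraction_plateau * g
}

# renewal event times on [0, t_max) with time-varying rate r(t) = fsc * fold(t),
# gamma-distributed unit intervals with the given CV, simulated in phase time
renewal_events <- function(t_max, fsc, cv, fold_fun, dt = 1) {
  grid <- seq(0, t_max, by = dt)
  rate <- fsc * fold_fun(grid)
  phase <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * diff(grid)))
  total_phase <- phase[length(phase)]
  draw <- function() {
    if (cv <= 0) return(1)
    shape <- 1 / cv^2
    stats::rgamma(1, shape = shape, rate = shape)
  }
  ph <- stats::runif(1) * draw()     # random initial phase
  out <- numeric(0)
  while (ph < total_phase) {
    out <- c(out, ph)
    ph <- ph + draw()
  }
  if (length(out) == 0) return(numeric(0))
  stats::approx(phase, grid, xout = out, rule = 2)$y
}

#' Simulate one synthetic DSM strip recording
#'
#' Forward model: tension(t) = preload + drift + KCl contracture + sum of
#' spontaneous events + sum of EFS responses + sum of drug transients +
#' white Gaussian noise. Spontaneous events are a renewal process (gamma
#' intervals, mean period `1/fsc_true`, CV `period_cv`) of raised-cosine
#' bumps of height `asc_true * kcl_amp_mN / 100`. Each EFS train of duration
#' D contributes `A(D) = efs_Amax * (1 - exp(-D/efs_tauD))` (% of KCl) split
#' into a fast-rising non-cholinergic and a slow-rising cholinergic kernel;
#' an active atropine window zeroes the cholinergic part, and any other
#' active drug multiplies the response by its `efs_fold`. Drug transients are
#' alpha functions `(t/tau) * exp(1 - t/tau)` scaled by `tension_amp`;
#' inside a drug window the spontaneous amplitude, rate, and EFS responses
#' are multiplied by the drug's `asc_fold` / `fsc_fold` / `efs_fold`.
#' Spontaneous events that would collide with the KCl contracture or an EFS
#' response are dropped (evoked contractions reset ongoing spontaneous
#' activity). The same seed always produces a bit-identical bundle.
#'
#' @param params A [strip_params()] object.
#' @param duration_s Recording length, s. Must cover all protocol events.
#' @param sampling_rate Sampling rate, Hz; must be at least `10 * fsc_true`.
#' @param protocol An [event_log()]; default [protocol_spontaneous()].
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A [trace_bundle()] with ground truth attached.
#' @export
simulate_strip <- function(params, duration_s = 1800, sampling_rate = 10,
                           protocol = NULL, seed = params$seed) {
  validate_strip_params(params)
  if (sampling_rate < 10 * params$fsc_true) {
    stop("domain error: sampling_rate below 10 * fsc_true (Nyquist margin)",
         call. = FALSE)
  }
  protocol <- protocol %||% protocol_spontaneous()
  ev <- protocol
  if (!is.null(ev$kcl) && ev$kcl$t_off > duration_s) {
    stop("duration_s does not cover the KCl window", call. = FALSE)
  }
  if (nrow(ev$efs_trains) &&
      max(ev$efs_trains$onset + ev$efs_trains$train_duration) > duration_s) {
    stop("duration_s does not cover all EFS trains", call. = FALSE)
  }
  if (nrow(ev$drugs) && max(ev$drugs$t_off) > duration_s) {
    stop("duration_s does not cover all drug windows", call. = FALSE)
  }

  n <- round(duration_s * sampling_rate)
  tt <- (seq_len(n) - 1) / sampling_rate
  p <- params
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    y <- rep(p$baseline_mN, n)

    # slow drift (optionally stopping after a prologue)
    if (p$drift_mN_per_min != 0) {
      y <- y + p$drift_mN_per_min / 60 * pmin(tt, p$drift_stop_s)
    }

    # KCl contracture: 5 s attack, hold, 30 s release starting 15 s before t_off
    if (!is.null(ev$kcl)) {
      y <- y + p$kcl_amp_mN *
        ahr_envelope(tt, ev$kcl$t_on, rise = 5,
                     t_hold_end = ev$kcl$t_off - 15, release = 30)
    }

    asc_fold <- drug_multiplier_fun(ev$drugs, p$drug_effects, "asc_fold")
    fsc_fold <- drug_multiplier_fun(ev$drugs, p$drug_effects, "fsc_fold")
    efs_fold <- drug_multiplier_fun(ev$drugs, p$drug_effects, "efs_fold")

    # exclusion zones where evoked contractions suppress spontaneous events
    excl <- NULL
    if (!is.null(ev$kcl)) excl <- rbind(excl, c(ev$kcl$t_on, ev$kcl$t_off + 30))
    if (nrow(ev$efs_trains)) {
      excl <- rbind(excl, cbind(ev$efs_trains$onset - 12,
                                ev$efs_trains$onset +
                                  ev$efs_trains$train_duration + 14))
    }

    # spontaneous events
    ev_times <- numeric(0); ev_heights <- numeric(0); ev_widths <- numeric(0)
    if (p$asc_true > 0) {
      ev_times <- renewal_events(duration_s, p$fsc_true, p$period_cv, fsc_fold)
      # snap onsets to the sampling grid and widths to an even sample count
      # so each raised-cosine peak is realized exactly on a sample
      ev_times <- round(ev_times * sampling_rate) / sampling_rate
      ev_widths <- p$event_duty / (p$fsc_true * fsc_fold(ev_times))
      ev_widths <- pmax(2, 2 * round(ev_widths * sampling_rate / 2)) /
        sampling_rate
      keep <- rep(TRUE, length(ev_times))
      if (!is.null(excl)) {
        for (i in seq_len(nrow(excl))) {
          keep <- keep & !intervals_overlap(ev_times, ev_times + ev_widths,
                                            excl[i, 1], excl[i, 2])
        }
      }
      keep <- keep & (ev_times + ev_widths <= duration_s)
      ev_times <- ev_times[keep]; ev_widths <- ev_widths[keep]
      ev_heights <- p$asc_true / 100 * p$kcl_amp_mN * asc_fold(ev_times)
      for (i in seq_along(ev_times)) {
        j1 <- max(1L, floor(ev_times[i] * sampling_rate) + 1L)
        j2 <- min(n, ceiling((ev_times[i] + ev_widths[i]) * sampling_rate) + 1L)
        idx <- j1:j2
        y[idx] <- y[idx] + ev_heights[i] *
          raised_cosine(tt[idx], ev_times[i], ev_widths[i])
      }
    }

    # EFS responses
    trains <- ev$efs_trains
    train_truth <- NULL
    if (nrow(trains)) {
      atr_active <- function(t0) {
        any(ev$drugs$name == "ATR" & ev$drugs$t_on <= t0 & t0 < ev$drugs$t_off)
      }
      A_tot <- A_chol <- A_non <- numeric(nrow(trains))
      for (i in seq_len(nrow(trains))) {
        o <- trains$onset[i]; D <- trains$train_duration[i]
        A <- p$kcl_amp_mN * p$efs_Amax / 100 * (1 - exp(-D / p$efs_tauD)) *
          efs_fold(o)
        C <- A * chol_share(D, p); N <- A - C
        if (atr_active(o)) C <- 0   # muscarinic block removes the slow part
        A_tot[i] <- C + N; A_chol[i] <- C; A_non[i] <- N
        hold_end <- o + D + 2
        j1 <- max(1L, floor(o * sampling_rate) + 1L)
        j2 <- min(n, ceiling((hold_end + 10) * sampling_rate) + 1L)
        idx <- j1:j2
        y[idx] <- y[idx] +
          N * ahr_envelope(tt[idx], o, rise = 0.5, t_hold_end = hold_end,
                           release = 4) +
          C * ahr_envelope(tt[idx], o, rise = 2, t_hold_end = hold_end,
                           release = 8)
      }
      train_truth <- cbind(trains[, c("onset", "train_duration")],
                           A_total = A_tot, A_chol = A_chol,
                           A_nonchol = A_non)
    }

    # drug tension transients
    if (nrow(ev$drugs)) {
      for (i in seq_len(nrow(ev$drugs))) {
        eff <- p$drug_effects[[ev$drugs$name[i]]]
        if (is.null(eff) || (eff$tension_amp %||% 0) == 0) next
        s <- (tt - ev$drugs$t_on[i]) / eff$tension_tau
        a <- ifelse(s > 0, s * exp(1 - s), 0)
        y <- y + p$kcl_amp_mN * eff$tension_amp / 100 * a
      }
    }

    if (p$noise_sd_mN > 0) y <- y + stats::rnorm(n, 0, p$noise_sd_mN)

    gt <- list(params = unclass(p)[setdiff(names(p), "drug_effects")],
               drug_effects = p$drug_effects,
               event_times = ev_times, event_heights = ev_heights,
               event_widths = ev_widths, trains = train_truth,
               seed = as.integer(seed))
    trace <- tension_trace(y, sampling_rate,
                           strip_meta = list(group = p$group,
                                             urothelium = p$urothelium,
                                             preload = p$baseline_mN,
                                             strip_id = p$strip_id,
                                             animal_id = p$animal_id))
    trace_bundle(trace, ev, ground_truth = gt)
  })
}

#' Simulate a cohort of synthetic DSM strips
#'
#' Generates `n` strips with strip-level random effects: the true A_SC, f_SC
#' and KCl amplitude of each strip are the cohort values multiplied by
#' mean-one lognormal effects with the CVs in `params$re_cv`. Effects are
#' drawn by stratified (one-per-quantile-stratum, randomly permuted)
#' lognormal sampling so that a cohort of modest size represents the
#' between-strip distribution without the luck of raw i.i.d. draws; marginal
#' spread still matches the configured CVs. Child seeds are derived
#' deterministically from `master_seed`, so the whole cohort is reproducible.
#'
#' @param n Number of strips (>= 1).
#' @param params Cohort-level [strip_params()].
#' @param master_seed Integer master seed.
#' @param duration_s,sampling_rate,protocol Passed to [simulate_strip()].
#' @return List of [trace_bundle()]s, one per strip.
#' @export
simulate_cohort <- function(n, params, master_seed = 1L,
                            duration_s = 1800, sampling_rate = 10,
                            protocol = NULL) {
  if (n < 1) stop("domain error: n must be >= 1", call. = FALSE)
  validate_strip_params(params)
  eff <- withr::with_seed(as.integer(master_seed) %% 2147483647L, {
    strat_lnorm <- function(n, cv) {
      if (cv <= 0) return(rep(1, n))
      sdl <- sqrt(log(1 + cv^2))
      u <- (sample.int(n) - stats::runif(n)) / n
      x <- stats::qlnorm(u, meanlog = -sdl^2 / 2, sdlog = sdl)
      x / mean(x)   # recentre: the cohort represents the population mean
    }
    list(asc = strat_lnorm(n, params$re_cv$asc %||% 0),
         fsc = strat_lnorm(n, params$re_cv$fsc %||% 0),
         kcl = strat_lnorm(n, params$re_cv$kcl %||% 0))
  })
  lapply(seq_len(n), function(i) {
    p <- params
    p$asc_true <- p$asc_true * eff$asc[i]
    p$fsc_true <- p$fsc_true * eff$fsc[i]
    p$kcl_amp_mN <- p$kcl_amp_mN * eff$kcl[i]
    p$strip_id <- sprintf("%s_%02d", p$group, i)
    p$animal_id <- sprintf("%s_animal_%d", p$group, ((i - 1) %% 3) + 1)
    simulate_strip(p, duration_s = duration_s, sampling_rate = sampling_rate,
                   protocol = protocol, seed = child_seed(master_seed, i))
  })
}
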