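#' Select a stationary analysis segment
#'
#' Finds the longest contiguous stretch of the recording over which basal
#' tension does not change, mirroring manual selection of "flat" chart
#' regions. The trace is scanned with sliding windows (default 60 s, step
#' 10 s); each window's baseline is a lower-envelope statistic (10th
#' percentile), so spontaneous bumps do not masquerade as drift, and the
#' local slope of that baseline must stay below `slope_tol`. Windows inside
#' KCl/EFS/drug events (plus washout margins) are ineligible.
#'
#' @param trace A [tension_trace()].
#' @param events An [event_log()] or `NULL`.
#' @param min_len_s Minimum acceptable segment length, s.
#' @param slope_tol Maximum |baseline slope| in mN/min. Default is 1% of
#'   `ref_amp_mN` per minute.
#' @param ref_amp_mN Reference (KCl) amplitude used to scale the default
#'   slope tolerance; default 20 mN.
#' @param t_range Optional `[t0, t1]` restricting the search (used for
#'   pre/post drug analysis). When the range lies inside a drug window, that
#'   window is not excluded.
#' @param window_s,step_s Sliding-window geometry, s.
#' @param kcl_washout_s Washout margin appended to the KCl window, s.
#' @param drift_band Maximum total excursion of the window baselines across
#'   the accepted segment, mN (default 2% of `ref_amp_mN`). A slow monotone
#'   drift can keep every local slope below `slope_tol` yet accumulate; the
#'   band bounds the cumulative change in basal tension.
#' @return List with `t_start`, `t_end` (s) of the selected segment.
#' @export
select_stationary_segment <- function(trace, events = NULL, min_len_s = 300,
                                      slope_tol = NULL, ref_amp_mN = 20,
                                      t_range = NULL,
                                      window_s = 60, step_s = 10,
                                      kcl_washout_s = 180, drift_band = NULL) {
  fs <- trace$sampling_rate
  slope_tol <- slope_tol %||% (0.01 * ref_amp_mN)
  drift_band <- drift_band %||% (0.02 * ref_amp_mN)
  lo <- trace$start_time
  hi <- trace_end(trace)
  if (!is.null(t_range)) {
    lo <- max(lo, t_range[1]); hi <- min(hi, t_range[2])
  }
  if (hi - lo < min_len_s) {
    stop("non-stationary recording: eligible extent shorter than min_len_s",
         call. = FALSE)
  }
  excl <- NULL
  if (!is.null(events)) {
    if (!is.null(events$kcl)) {
      excl <- rbind(excl, c(events$kcl$t_on, events$kcl$t_off + kcl_washout_s))
    }
    if (nrow(events$efs_trains)) {
      excl <- rbind(excl, cbind(events$efs_trains$onset - 12,
                                events$efs_trains$onset +
                                  events$efs_trains$train_duration + 14))
    }
    if (nrow(events$drugs)) {
      for (i in seq_len(nrow(events$drugs))) {
        w <- c(events$drugs$t_on[i], events$drugs$t_off[i])
        inside <- !is.null(t_range) && t_range[1] >= w[1] && t_range[2] <= w[2]
        if (!inside) excl <- rbind(excl, w)
      }
    }
  }
  pieces <- interval_complement(lo, hi, excl)
  best <- NULL
  for (k in seq_len(nrow(pieces))) {
    a <- pieces[k, 1]; b <- pieces[k, 2]
    if (b - a < min_len_s) next
    starts <- seq(a, b - window_s, by = step_s)
    if (length(starts) < 3) next
    i0 <- round((starts - trace$start_time) * fs) + 1
    w <- round(window_s * fs)
    env <- vapply(i0, function(j) {
      stats::quantile(trace$samples[j:min(j + w - 1, length(trace$samples))],
                      0.1, names = FALSE)
    }, numeric(1))
    centers <- starts + window_s / 2
    m <- length(env)
    # central-difference slope of the lower envelope, mN/min
    slope <- numeric(m)
    slope[2:(m - 1)] <- (env[3:m] - env[1:(m - 2)]) /
      (centers[3:m] - centers[1:(m - 2)]) * 60
    slope[1] <- slope[2]; slope[m] <- slope[m - 1]
    ok <- abs(slope) < slope_tol
    # longest run of consecutive stationary windows ...
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1
    for (ci in which(r$values)) {
      # ... further restricted to the longest stretch whose baselines stay
      # inside a band of width drift_band (two-pointer scan)
      idx <- begs[ci]:ends[ci]
      lo_ptr <- 1L
      for (hi_ptr in seq_along(idx)) {
        while (diff(range(env[idx[lo_ptr:hi_ptr]])) > drift_band) {
          lo_ptr <- lo_ptr + 1L
        }
        s0 <- starts[idx[lo_ptr]]
        s1 <- starts[idx[hi_ptr]] + window_s
        if (s1 - s0 >= min_len_s &&
            (is.null(best) || s1 - s0 > best$t_end - best$t_start)) {
          best <- list(t_start = s0, t_end = s1)
        }
      }
    }
  }
  if (is.null(best)) {
    stop("non-stationary recording: no stationary segment of length >= ",
         min_len_s, " s", call. = FALSE)
  }
  best
}

#' Amplitude histogram of a trace segment
#'
#' Equal-width histogram over the segment's tension range. The default bin
#' count follows the Freedman-Diaconis rule with a resolution floor of one
#' bin per 75 samples, clamped to 30-200 bins. The floor matters because a
#' dwell-dominated tension distribution is far spikier than the unimodal
#' densities FD was derived for; without it the baseline and peak dwell
#' modes are quantized to coarse bin centers.
#'
#' @param x Numeric vector of tension samples (at least 100).
#' @param n_bins Number of bins; `NULL` for Freedman-Diaconis.
#' @return List with `centers`, `counts`, `breaks`, `bin_width`, `n`.
#' @export
amplitude_histogram <- function(x, n_bins = NULL) {
  if (length(x) < 100) stop("segment too short for an amplitude histogram",
                            call. = FALSE)
  rng <- range(x)
  if (diff(rng) == 0) {
    stop("degenerate histogram: constant segment (zero amplitude range)",
         call. = FALSE)
  }
  if (is.null(n_bins)) {
    bw_fd <- 2 * stats::IQR(x) / length(x)^(1 / 3)
    fd_bins <- if (bw_fd <= 0) 200L else ceiling(diff(rng) / bw_fd)
    n_bins <- clamp(max(fd_bins, length(x) %/% 75L), 30L, 200L)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  list(centers = h$mids, counts = h$counts, breaks = breaks,
       bin_width = diff(breaks[1:2]), n = length(x))
}

two_gauss_model <- function(x, a1, m1, s1, a2, m2, s2) {
  a1 * exp(-0.5 * ((x - m1) / s1)^2) + a2 * exp(-0.5 * ((x - m2) / s2)^2)
}

fit_two_gauss_once <- function(cx, cn, start, lower, upper) {
  df <- data.frame(x = cx, y = cn)
  suppressWarnings(minpack.lm::nlsLM(
    y ~ a1 * exp(-0.5 * ((x - m1) / s1)^2) + a2 * exp(-0.5 * ((x - m2) / s2)^2),
    data = df, start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)))
}

# Locate the two dwell modes of the (lightly smoothed) histogram: the main
# mode, and the farthest local maximum that is tall enough and separated
# from the main mode by a genuine valley (so neither count fluctuations on
# a flank nor a smeared baseline shoulder qualify). Returns centers
# c(lower, upper); upper is NA if no second mode exists.
find_histogram_modes <- function(hist, min_sep_bins = 5) {
  cn <- boxcar_smooth(as.numeric(hist$counts), 3)
  n <- length(cn)
  locmax <- which(cn >= c(-Inf, cn[-n]) & cn >= c(cn[-1], -Inf) & cn > 0)
  if (length(locmax) == 0) return(c(NA_real_, NA_real_))
  i1 <- locmax[which.max(cn[locmax])]
  cand <- locmax[abs(locmax - i1) >= min_sep_bins &
                   cn[locmax] >= max(5, 0.02 * cn[i1])]
  has_valley <- vapply(cand, function(i) {
    min(cn[min(i, i1):max(i, i1)]) < 0.75 * min(cn[i], cn[i1])
  }, logical(1))
  cand <- cand[has_valley]
  if (length(cand) == 0) return(c(hist$centers[i1], NA_real_))
  i2 <- cand[which.max(abs(cand - i1))]
  sort(hist$centers[c(i1, i2)])
}

# Gaussian + linear background fit restricted to the neighbourhood of one
# histogram mode; the background absorbs the inter-modal dwell-time shoulder
# so the peak position is read without it. `ilo`/`ihi` bound the
# neighbourhood (e.g. at the inter-modal valley) so the window never leaks
# into the other peak.
local_peak_fit <- function(hist, m0, ilo = 1L, ihi = length(hist$centers)) {
  cx <- hist$centers; cn <- as.numeric(hist$counts)
  sm <- boxcar_smooth(cn, 3)
  i0 <- which.min(abs(cx - m0))
  pk <- sm[i0]
  lo <- i0; while (lo > ilo && sm[lo - 1] >= pk / 2) lo <- lo - 1
  hi <- i0; while (hi < ihi && sm[hi + 1] >= pk / 2) hi <- hi + 1
  whalf <- max(cx[hi] - cx[lo], 2 * hist$bin_width) / 2
  sel <- which(abs(cx - cx[i0]) <= 2.5 * whalf)
  sel <- sel[sel >= ilo & sel <= ihi]
  if (length(sel) < 6) sel <- max(ilo, i0 - 3):min(ihi, i0 + 3)
  df <- data.frame(x = cx[sel], y = cn[sel])
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ a * exp(-0.5 * ((x - m) / s)^2) + b0 + b1 * (x - m),
      data = df,
      start = list(a = max(df$y), m = cx[i0], s = whalf / 1.18,
                   b0 = min(df$y), b1 = 0),
      lower = c(0, min(df$x), hist$bin_width / 4, -Inf, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  stats::coef(fit)[c("a", "m", "s")]
}

#' Fit two Gaussians to an amplitude histogram
#'
#' Least-squares fit of the sum of two Gaussian peaks to the bin counts, the
#' scheme used to read the near-baseline and near-maximal-amplitude regions
#' of a spontaneous-contraction amplitude histogram. A first pass fits the
#' 6-parameter sum over all bins (means initialized at the 10th/90th
#' amplitude percentiles). Because the dwell-time density between the two
#' modes is not Gaussian, a plain global fit drags the means inward; when
#' the first pass is bimodal, each mean is therefore refined by a local
#' Gaussian-plus-linear-background fit anchored at the corresponding
#' histogram mode, which is exactly a fit of the near-baseline and
#' near-maximal regions. Means are returned with `mu1 < mu2`; a unimodality
#' flag is set when `|mu2 - mu1| < (sd1 + sd2) / 2` or no second mode
#' exists.
#'
#' @param hist A histogram from [amplitude_histogram()].
#' @param n_restarts Number of jittered restarts on failure.
#' @param refine Run the local mode-anchored refinement (default `TRUE`).
#' @return List with `mu1`, `mu2`, `sd1`, `sd2`, `w1`, `w2` (mixture
#'   weights), `fit_residual` (RMS count residual of the global pass),
#'   `unimodal` flag.
#' @export
fit_two_gaussians <- function(hist, n_restarts = 5, refine = TRUE) {
  ord <- order(hist$centers)   # (center, count) pairs are order-free
  hist$centers <- hist$centers[ord]
  hist$counts <- hist$counts[ord]
  cx <- hist$centers; cn <- as.numeric(hist$counts)
  # weighted sample quantiles from the histogram itself
  cw <- cumsum(cn) / sum(cn)
  qx <- function(p) cx[which(cw >= p)[1]]
  rng <- diff(range(cx))
  near <- function(m) max(cn[abs(cx - m) <= rng / 8], 1)
  start0 <- list(a1 = near(qx(0.10)), m1 = qx(0.10), s1 = rng / 12,
                 a2 = near(qx(0.90)), m2 = qx(0.90), s2 = rng / 12)
  lower <- c(a1 = 0, m1 = min(cx) - rng, s1 = hist$bin_width / 2,
             a2 = 0, m2 = min(cx) - rng, s2 = hist$bin_width / 2)
  upper <- c(a1 = Inf, m1 = max(cx) + rng, s1 = rng,
             a2 = Inf, m2 = max(cx) + rng, s2 = rng)
  fit <- NULL
  last_err <- NULL
  for (k in 0:n_restarts) {
    start <- start0
    if (k > 0) {
      start$m1 <- start0$m1 + rng * (k %% 3 - 1) * 0.05
      start$m2 <- start0$m2 - rng * (k %% 3 - 1) * 0.05
      start$s1 <- start0$s1 * 2^((k %/% 3) - 0.5)
      start$s2 <- start$s1
    }
    fit <- tryCatch(fit_two_gauss_once(cx, cn, start, lower, upper),
                    error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("two-Gaussian fit failed to converge after restarts: ",
         conditionMessage(last_err), call. = FALSE)
  }
  cf <- stats::coef(fit)
  if (cf["m1"] > cf["m2"]) {
    cf <- cf[c("a2", "m2", "s2", "a1", "m1", "s1")]
    names(cf) <- c("a1", "m1", "s1", "a2", "m2", "s2")
  }
  res <- cn - two_gauss_model(cx, cf["a1"], cf["m1"], cf["s1"],
                              cf["a2"], cf["m2"], cf["s2"])
  unimodal <- unname(abs(cf["m2"] - cf["m1"]) < (cf["s1"] + cf["s2"]) / 2)
  if (refine) {
    modes <- find_histogram_modes(hist)
    bimodal <- !anyNA(modes)
    if (bimodal) {
      sm <- boxcar_smooth(cn, 3)
      i1 <- which.min(abs(cx - modes[1]))
      i2 <- which.min(abs(cx - modes[2]))
      iv <- i1 - 1L + which.min(sm[i1:i2])   # valley bin
      f1 <- local_peak_fit(hist, modes[1], ihi = iv)
      f2 <- local_peak_fit(hist, modes[2], ilo = iv)
      if (!is.null(f1) && !is.null(f2) && f1["m"] < f2["m"]) {
        cf["a1"] <- f1["a"]; cf["m1"] <- f1["m"]; cf["s1"] <- f1["s"]
        cf["a2"] <- f2["a"]; cf["m2"] <- f2["m"]; cf["s2"] <- f2["s"]
        unimodal <- unname(abs(cf["m2"] - cf["m1"]) < (cf["s1"] + cf["s2"]) / 2)
      }
    } else {
      unimodal <- TRUE
    }
  }
  area1 <- cf["a1"] * cf["s1"]; area2 <- cf["a2"] * cf["s2"]
  list(mu1 = unname(cf["m1"]), mu2 = unname(cf["m2"]),
       sd1 = unname(cf["s1"]), sd2 = unname(cf["s2"]),
       w1 = unname(area1 / (area1 + area2)),
       w2 = unname(area2 / (area1 + area2)),
       fit_residual = sqrt(mean(res^2)),
       unimodal = unimodal)
}

#' Spontaneous contraction amplitude from a two-Gaussian fit
#'
#' The distance between the two Gaussian means is the spontaneous
#' contraction amplitude; it is normalized to the strip's KCl reference
#' contraction. A fit flagged unimodal reports `A_SC = 0` with a warning: a
#' strip without detectable spontaneous activity is a valid observation,
#' not an analysis failure.
#'
#' @param gauss_fit Result of [fit_two_gaussians()].
#' @param kcl_amp KCl reference amplitude, mN (> 0).
#' @return A_SC in % of the KCl contraction.
#' @export
estimate_asc <- function(gauss_fit, kcl_amp) {
  if (!is.numeric(kcl_amp) || kcl_amp <= 0) {
    stop("normalization error: KCl reference amplitude must be > 0",
         call. = FALSE)
  }
  if (isTRUE(gauss_fit$unimodal)) {
    warning("amplitude histogram is unimodal; reporting A_SC = 0 ",
            "(no detectable spontaneous activity)", call. = FALSE)
    return(0)
  }
  100 * (gauss_fit$mu2 - gauss_fit$mu1) / kcl_amp
}

#' Power spectrum of a trace segment
#'
#' Linearly detrended, split-cosine-tapered averaged (Welch) periodogram.
#' The sub-segment length is chosen so that the frequency resolution is at
#' least `band_low / 5`; sub-segments overlap by 50% and their one-sided
#' power spectral densities are averaged. The PSD is scaled so that its
#' band integral equals the signal variance (Parseval), exactly so for an
#' untapered single segment.
#'
#' @param x Numeric tension samples of a stationary segment.
#' @param sampling_rate Hz.
#' @param band_low Lower edge of the frequency band of interest, Hz; sets
#'   the required resolution.
#' @param taper Proportion of each sub-segment tapered (split cosine bell;
#'   0 = rectangular).
#' @param detrend Remove a per-segment linear trend (default `TRUE`); with
#'   `detrend = FALSE` only the mean is removed, and for an untapered single
#'   segment the Parseval identity is then exact.
#' @return List with `freq` (Hz), `power` (PSD, mN^2/Hz), `df`, `n_segments`,
#'   `segment_s`.
#' @export
power_spectrum <- function(x, sampling_rate, band_low = 0.005, taper = 0.1,
                           detrend = TRUE) {
  n <- length(x)
  need <- round(5 / band_low * sampling_rate)   # samples for df = band_low/5
  if (n < need) {
    stop("resolution error: segment of ", round(n / sampling_rate),
         " s cannot resolve ", band_low / 5, " Hz (needs >= ",
         round(need / sampling_rate), " s)", call. = FALSE)
  }
  seg_len <- need
  hop <- seg_len %/% 2
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  # drop a trailing sliver window only if it would exceed the signal
  w <- stats::spec.taper(rep(1, seg_len), p = taper)
  U <- mean(w^2)
  nf <- seg_len %/% 2
  acc <- numeric(nf)
  idx_t <- seq_len(seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- if (detrend) {
      stats::residuals(stats::lm.fit(cbind(1, idx_t), seg))
    } else {
      seg - mean(seg)
    }
    seg <- seg * w
    X <- stats::fft(seg)
    P <- (Mod(X[2:(nf + 1)])^2) * 2 / (seg_len^2 * U) * seg_len / sampling_rate
    if (seg_len %% 2 == 0) P[nf] <- P[nf] / 2   # Nyquist bin is not doubled
    acc <- acc + P
  }
  df <- sampling_rate / seg_len
  list(freq = (1:nf) * df, power = acc / length(starts), df = df,
       n_segments = length(starts), segment_s = seg_len / sampling_rate)
}

#' Main-harmonic frequency of spontaneous contractions
#'
#' Locates the maximal power within the search band (DC excluded) and
#' refines it by parabolic interpolation across the three bins around the
#' maximum. A peak must be prominent to count as a dominant rhythm: it has
#' to exceed 4x the band median power and the 99th percentile of the
#' within-band maximum expected under a flat (white-noise) spectrum given
#' the number of averaged segments - otherwise every noise spectrum would
#' hand back its tallest fluctuation.
#'
#' @param spectrum Result of [power_spectrum()].
#' @param band Search band `[low, high]`, Hz. The default 0.005-0.5 Hz
#'   brackets reported detrusor rhythms (0.027-0.047 Hz) with wide margin.
#' @param prominence Multiple of the band median power the peak must exceed.
#' @return List with `f_SC` (Hz), `peak_power`, `band`, `prominence_ratio`.
#' @export
estimate_fsc <- function(spectrum, band = c(0.005, 0.5), prominence = 4) {
  sel <- which(spectrum$freq >= band[1] & spectrum$freq <= band[2])
  if (length(sel) < 5) stop("spectrum does not cover the search band",
                            call. = FALSE)
  P <- spectrum$power[sel]
  f <- spectrum$freq[sel]
  med <- stats::median(P)
  K <- spectrum$n_segments
  # null 99th percentile of max/median for K-segment-averaged white noise
  null_max <- stats::qgamma(0.99^(1 / length(sel)), shape = K, rate = K) /
    stats::qgamma(0.5, shape = K, rate = K)
  thr <- med * max(prominence, null_max)
  i <- which.max(P)
  if (P[i] <= thr) {
    stop("no dominant rhythm: maximal band power does not exceed the ",
         "prominence threshold", call. = FALSE)
  }
  f_hat <- f[i]
  if (i > 1 && i < length(sel)) {
    y1 <- P[i - 1]; y2 <- P[i]; y3 <- P[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) f_hat <- f[i] + 0.5 * (y1 - y3) / denom * spectrum$df
  }
  list(f_SC = f_hat, peak_power = P[i], band = band,
       prominence_ratio = P[i] / med)
}

#' Quantify spontaneous contractions of one strip
#'
#' End-to-end spontaneous-contraction analysis: selects a stationary
#' segment, reads A_SC (% of KCl) off a two-Gaussian fit to the amplitude
#' histogram, and reads f_SC off the main harmonic of the power spectrum.
#'
#' @param bundle A [trace_bundle()] whose events include a KCl window (for
#'   normalization).
#' @param band f_SC search band, Hz.
#' @param t_range Optional `[t0, t1]` restricting the analysis (pre/post
#'   drug comparisons).
#' @param min_len_s Minimum stationary-segment length, s; raised internally
#'   to whatever the spectral resolution requires for `band[1]`.
#' @param n_bins Histogram bin count; `NULL` for Freedman-Diaconis.
#' @param slope_tol Stationarity slope tolerance, mN/min; default 1% of the
#'   KCl amplitude per minute.
#' @param smooth_s Boxcar pre-smoothing applied to the segment before the
#'   amplitude histogram, s. Contraction events dwell near baseline and
#'   near their peak for seconds, so this suppresses measurement noise
#'   (which otherwise smears the one-sided dwell densities and biases the
#'   Gaussian means inward) without distorting event amplitudes. The
#'   spectrum is computed on the unsmoothed segment.
#' @return An object of class `spontaneous_stats`: `A_SC` (% of KCl), `f_SC`
#'   (Hz), `T_SC` (s), `segment`, `gauss_fit`, `spectrum_peak`, `kcl_amp_mN`,
#'   `flags`.
#' @export
quantify_spontaneous <- function(bundle, band = c(0.005, 0.5), t_range = NULL,
                                 min_len_s = 300, n_bins = NULL,
                                 slope_tol = NULL, smooth_s = 0.5) {
  stopifnot(inherits(bundle, "trace_bundle"))
  if (is.null(bundle$events$kcl)) {
    stop("normalization error: bundle has no KCl window", call. = FALSE)
  }
  kcl_amp <- kcl_reference_amplitude(bundle)
  min_len_eff <- max(min_len_s, 5 / band[1])
  segment <- select_stationary_segment(
    bundle$trace, bundle$events, min_len_s = min_len_eff,
    slope_tol = slope_tol, ref_amp_mN = kcl_amp, t_range = t_range)
  fs <- bundle$trace$sampling_rate
  i0 <- round((segment$t_start - bundle$trace$start_time) * fs) + 1
  i1 <- round((segment$t_end - bundle$trace$start_time) * fs)
  x <- bundle$trace$samples[i0:min(i1, length(bundle$trace$samples))]

  flags <- character(0)
  xs <- if (smooth_s > 0) boxcar_smooth(x, max(1L, round(smooth_s * fs))) else x
  hist <- amplitude_histogram(xs, n_bins = n_bins)
  gf <- fit_two_gaussians(hist)
  A_SC <- withCallingHandlers(
    estimate_asc(gf, kcl_amp),
    warning = function(w) {
      flags <<- c(flags, "unimodal_histogram")
      invokeRestart("muffleWarning")
    })

  spec <- power_spectrum(x, fs, band_low = band[1])
  pk <- tryCatch(estimate_fsc(spec, band = band), error = function(e) e)
  if (inherits(pk, "error")) {
    flags <- c(flags, "no_dominant_rhythm")
    f_SC <- NA_real_
    pk <- NULL
  } else {
    f_SC <- pk$f_SC
  }
  structure(list(A_SC = A_SC, f_SC = f_SC,
                 T_SC = if (is.na(f_SC)) NA_real_ else 1 / f_SC,
                 segment = segment, gauss_fit = gf, spectrum_peak = pk,
                 kcl_amp_mN = kcl_amp, flags = flags),
            class = "spontaneous_stats")
}

#' @export
print.spontaneous_stats <- function(x, ...) {
  cat(sprintf(paste0("<spontaneous_stats> A_SC %.3g%% of KCl, f_SC %.4g Hz ",
                     "(T_SC %.3g s), segment [%g, %g] s%s\n"),
              x$A_SC, x$f_SC, x$T_SC, x$segment$t_start, x$segment$t_end,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}
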