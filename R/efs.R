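window_samples <- function(trace, t0, t1) {
  fs <- trace$sampling_rate
  i0 <- max(1L, round((t0 - trace$start_time) * fs) + 1L)
  i1 <- min(length(trace$samples), round((t1 - trace$start_time) * fs) + 1L)
  if (i1 < i0) stop("empty sample window [", t0, ", ", t1, "]", call. = FALSE)
  trace$samples[i0:i1]
}

#' KCl reference contraction amplitude
#'
#' Peak tension inside the annotated 60 mM KCl window minus the median
#' tension over the 30 s preceding it. The peak is read from a lightly
#' smoothed (0.5 s boxcar) signal to avoid the upward bias of a raw max
#' under measurement noise. All other amplitudes of the same strip are
#' normalized to this value.
#'
#' @param bundle A [trace_bundle()] with a KCl window annotated.
#' @return Reference amplitude in mN (> 0).
#' @export
kcl_reference_amplitude <- function(bundle) {
  kcl <- bundle$events$kcl
  if (is.null(kcl)) {
    stop("normalization error: no KCl window annotated", call. = FALSE)
  }
  tr <- bundle$trace
  base <- stats::median(window_samples(tr, kcl$t_on - 30, kcl$t_on))
  pk <- smoothed_peak(window_samples(tr, kcl$t_on, kcl$t_off),
                      tr$sampling_rate)
  amp <- pk - base
  if (amp <= 0) {
    stop("quality error: non-positive KCl contraction amplitude", call. = FALSE)
  }
  amp
}

#' EFS contraction amplitude for one train
#'
#' A_EFS = 100 * (response-window peak - pre-stimulus baseline) / KCl
#' amplitude. The response window runs from train onset to
#' `onset + train_duration + post_s` (default 30 s, long enough for the slow
#' cholinergic peak); the baseline is the median of the 10 s before onset,
#' robust to a spontaneous bump landing there. Negative differences clamp
#' to 0.
#'
#' @param bundle A [trace_bundle()].
#' @param train Row index into `bundle$events$efs_trains`, or a list with
#'   `onset` and `train_duration`.
#' @param post_s Response window extension past train end, s.
#' @param kcl_amp Optional precomputed KCl amplitude, mN.
#' @return List of class `efs_response`: `train_onset`, `train_duration`,
#'   `raw_peak` (mN), `pre_stim_baseline` (mN), `A_EFS` (% of KCl),
#'   `drug_context` (character vector of drugs active at onset).
#' @export
efs_amplitude <- function(bundle, train, post_s = 30, kcl_amp = NULL) {
  tr <- bundle$trace
  trains <- bundle$events$efs_trains
  if (is.numeric(train) && length(train) == 1) {
    stopifnot(train >= 1, train <= nrow(trains))
    train <- as.list(trains[train, ])
  }
  o <- train$onset; D <- train$train_duration
  w_end <- o + D + post_s
  if (nrow(trains)) {
    others <- trains$onset != o
    if (any(others & intervals_overlap(trains$onset,
                                       trains$onset + trains$train_duration,
                                       o, w_end))) {
      stop("ambiguity error: another EFS train falls inside the response ",
           "window", call. = FALSE)
    }
  }
  kcl_amp <- kcl_amp %||% kcl_reference_amplitude(bundle)
  base <- stats::median(window_samples(tr, o - 10, o))
  pk <- smoothed_peak(window_samples(tr, o, w_end), tr$sampling_rate)
  drugs <- bundle$events$drugs
  ctx <- character(0)
  if (nrow(drugs)) {
    ctx <- drugs$name[drugs$t_on <= o & o < drugs$t_off]
  }
  structure(list(train_onset = o, train_duration = D, raw_peak = pk,
                 pre_stim_baseline = base,
                 A_EFS = max(0, 100 * (pk - base) / kcl_amp),
                 drug_context = ctx),
            class = "efs_response")
}

#' All EFS responses of a bundle as a data frame
#'
#' Convenience wrapper running [efs_amplitude()] on every annotated train.
#'
#' @param bundle A [trace_bundle()].
#' @param ... Passed to [efs_amplitude()].
#' @return Data frame with columns `strip_id`, `onset`, `duration`, `A_EFS`,
#'   `atr` (logical: atropine active), `drug_context`.
#' @export
efs_responses <- function(bundle, ...) {
  trains <- bundle$events$efs_trains
  if (nrow(trains) == 0) return(data.frame())
  kcl_amp <- kcl_reference_amplitude(bundle)
  rows <- lapply(seq_len(nrow(trains)), function(i) {
    r <- efs_amplitude(bundle, i, kcl_amp = kcl_amp, ...)
    data.frame(strip_id = bundle$trace$strip_meta$strip_id,
               onset = r$train_onset, duration = r$train_duration,
               A_EFS = r$A_EFS, atr = "ATR" %in% r$drug_context,
               drug_context = paste(r$drug_context, collapse = "+"))
  })
  do.call(rbind, rows)
}

#' Duration-response curve of EFS contractions
#'
#' Groups normalized EFS amplitudes by train duration and returns mean, SD
#' and n per duration for one condition (e.g. pre- vs post-atropine).
#'
#' @param responses Data frame as returned by [efs_responses()] (possibly
#'   row-bound across strips), with columns `duration` and `A_EFS`.
#' @param condition Label stored on the curve.
#' @return Object of class `duration_response`: a data frame with
#'   `duration`, `mean_A_EFS`, `sd_A_EFS`, `n`, plus a `condition`
#'   attribute. Single-observation durations carry `NA` SD.
#' @export
duration_response <- function(responses, condition = "pre-ATR") {
  stopifnot(nrow(responses) >= 1)
  sp <- split(responses$A_EFS, responses$duration)
  out <- data.frame(
    duration = as.numeric(names(sp)),
    mean_A_EFS = vapply(sp, mean, numeric(1)),
    sd_A_EFS = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                      numeric(1)),
    n = vapply(sp, length, integer(1)))
  out <- out[order(out$duration), ]
  rownames(out) <- NULL
  attr(out, "condition") <- condition
  class(out) <- c("duration_response", "data.frame")
  out
}

#' Cholinergic / non-cholinergic dissection of EFS contractions
#'
#' The atropine-blockable (cholinergic) fraction at each train duration is
#' `(A_pre - A_ATR) / A_pre`, clamped to [0, 1]; the plateau fraction is its
#' mean over durations >= `plateau_min_s`. When the inputs carry per-strip
#' responses (`strip_id` column), fractions are computed per strip and then
#' averaged, the within-strip paired design of the experiment; curve-level
#' inputs fall back to group means.
#'
#' @param pre Either an [efs_responses()]-style data frame or a
#'   [duration_response()] curve, without atropine.
#' @param atr Same, with atropine.
#' @param plateau_min_s Durations at or above this count as plateau
#'   (default 4 s); at least two are required.
#' @return Object of class `cholinergic_dissection`: `by_duration` data
#'   frame (`duration`, `fraction`, `sd`, `n`), `plateau_fraction`,
#'   `plateau_sd`, `n_strips`.
#' @export
cholinergic_dissection <- function(pre, atr, plateau_min_s = 4) {
  per_strip <- is.data.frame(pre) && all(c("strip_id", "A_EFS") %in% names(pre))
  if (per_strip) {
    stopifnot(all(c("strip_id", "A_EFS") %in% names(atr)))
    m <- merge(pre[, c("strip_id", "duration", "A_EFS")],
               atr[, c("strip_id", "duration", "A_EFS")],
               by = c("strip_id", "duration"), suffixes = c("_pre", "_atr"))
    m <- m[m$A_EFS_pre > 0, , drop = FALSE]   # fraction undefined at A_pre = 0
    m$fraction <- clamp((m$A_EFS_pre - m$A_EFS_atr) / m$A_EFS_pre, 0, 1)
    sp <- split(m$fraction, m$duration)
    by_dur <- data.frame(
      duration = as.numeric(names(sp)),
      fraction = vapply(sp, mean, numeric(1)),
      sd = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                  numeric(1)),
      n = vapply(sp, length, integer(1)))
    pl <- m[m$duration >= plateau_min_s, , drop = FALSE]
    if (length(unique(pl$duration)) < 2) {
      stop("plateau undefined: fewer than 2 durations >= ", plateau_min_s,
           " s", call. = FALSE)
    }
    per_strip_plateau <- vapply(split(pl$fraction, pl$strip_id), mean,
                                numeric(1))
    plateau <- mean(per_strip_plateau)
    plateau_sd <- if (length(per_strip_plateau) > 1) stats::sd(per_strip_plateau) else NA_real_
    n_strips <- length(per_strip_plateau)
  } else {
    m <- merge(as.data.frame(pre)[, c("duration", "mean_A_EFS")],
               as.data.frame(atr)[, c("duration", "mean_A_EFS")],
               by = "duration", suffixes = c("_pre", "_atr"))
    m <- m[m$mean_A_EFS_pre > 0, , drop = FALSE]
    frac <- clamp((m$mean_A_EFS_pre - m$mean_A_EFS_atr) / m$mean_A_EFS_pre,
                  0, 1)
    by_dur <- data.frame(duration = m$duration, fraction = frac,
                         sd = NA_real_, n = 1L)
    pl <- frac[m$duration >= plateau_min_s]
    if (length(pl) < 2) {
      stop("plateau undefined: fewer than 2 durations >= ", plateau_min_s,
           " s", call. = FALSE)
    }
    plateau <- mean(pl); plateau_sd <- NA_real_; n_strips <- NA_integer_
  }
  rownames(by_dur) <- NULL
  structure(list(by_duration = by_dur, plateau_fraction = plateau,
                 plateau_sd = plateau_sd, n_strips = n_strips,
                 plateau_min_s = plateau_min_s),
            class = "cholinergic_dissection")
}

#' @export
print.cholinergic_dissection <- function(x, ...) {
  cat(sprintf(paste0("<cholinergic_dissection> plateau (>= %g s) fraction ",
                     "%.3f%s\n"),
              x$plateau_min_s, x$plateau_fraction,
              if (is.na(x$plateau_sd)) "" else sprintf(" +/- %.3f (n = %d strips)",
                                                       x$plateau_sd, x$n_strips)))
  invisible(x)
}

#' Convert a fold decrease to a percent decrease
#'
#' A k-fold decrease corresponds to a `100 * (1 - 1/k)` percent decrease
#' (e.g. a 3.54-fold decrease is one by about 71.7%). Returned at full
#' precision; rounding is left to presentation.
#'
#' @param fold Fold decrease, >= 1.
#' @return Percent decrease.
#' @export
fold_to_percent <- function(fold) {
  if (any(fold < 1)) {
    stop("domain error: fold must be >= 1 (use the percent-increase pathway ",
         "for enhancements)", call. = FALSE)
  }
  100 * (1 - 1 / fold)
}
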