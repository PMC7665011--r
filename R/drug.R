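find_drug_window <- function(bundle, drug) {
  d <- bundle$events$drugs
  if (is.list(drug) && !is.null(drug$t_on)) return(drug)
  i <- which(d$name == drug)
  if (length(i) == 0) stop("no window annotated for drug '", drug, "'",
                           call. = FALSE)
  as.list(d[i[1], ])
}

mask_efs_windows <- function(trace, events, post_s = 30) {
  x <- trace$samples
  tr <- events$efs_trains
  if (nrow(tr) == 0) return(x)
  fs <- trace$sampling_rate
  for (i in seq_len(nrow(tr))) {
    i0 <- max(1L, round((tr$onset[i] - trace$start_time) * fs) + 1L)
    i1 <- min(length(x), round((tr$onset[i] + tr$train_duration[i] + post_s -
                                  trace$start_time) * fs) + 1L)
    x[i0:i1] <- NA_real_
  }
  x
}

#' Drug-evoked change of basal tension
#'
#' The drug "tension" effect is the shift of basal tension under the
#' superimposed contraction spikes, so it is read off a lower-envelope
#' baseline: a sliding 10th-percentile filter (30 s windows) with EFS
#' response windows masked out. The reported delta is the peak of the
#' envelope inside the drug window minus the pre-drug envelope median,
#' normalized to the KCl amplitude; transient drugs therefore report their
#' peak effect. Relaxing drugs give negative values.
#'
#' @param bundle A [trace_bundle()].
#' @param drug Drug name, or a list with `t_on`, `t_off`.
#' @param pre_s Length of pre-drug reference stretch, s (>= 60 required).
#' @param envelope_s Envelope window, s.
#' @return List: `delta_tension` (% of KCl), `pre_baseline_mN`,
#'   `peak_baseline_mN`, `window`.
#' @export
baseline_tension_change <- function(bundle, drug, pre_s = 300,
                                    envelope_s = 30) {
  w <- find_drug_window(bundle, drug)
  tr <- bundle$trace
  fs <- tr$sampling_rate
  if (w$t_off - w$t_on < envelope_s) {
    stop("resolution error: drug window shorter than the envelope window",
         call. = FALSE)
  }
  pre_s <- max(pre_s, 60)
  if (w$t_on - pre_s < tr$start_time) {
    stop("fewer than ", pre_s, " s of pre-drug trace", call. = FALSE)
  }
  masked <- mask_efs_windows(tr, bundle$events)
  grab <- function(t0, t1) {
    i0 <- max(1L, round((t0 - tr$start_time) * fs) + 1L)
    i1 <- min(length(masked), round((t1 - tr$start_time) * fs) + 1L)
    v <- masked[i0:i1]
    v[!is.na(v)]
  }
  env_q <- function(v) {
    e <- lower_envelope(v, fs, window_s = envelope_s, step_s = 5)
    e$env
  }
  pre <- stats::median(env_q(grab(w$t_on - pre_s, w$t_on)))
  inside <- env_q(grab(w$t_on, w$t_off))
  # peak shift in either direction (relaxants move the envelope down)
  shifts <- inside - pre
  delta_mN <- shifts[which.max(abs(shifts))]
  kcl_amp <- kcl_reference_amplitude(bundle)
  list(delta_tension = 100 * delta_mN / kcl_amp,
       pre_baseline_mN = pre, peak_baseline_mN = pre + delta_mN,
       window = c(w$t_on, w$t_off))
}

#' Pre/post drug fold change of spontaneous contraction parameters
#'
#' Runs [quantify_spontaneous()] independently on the recording before the
#' drug window and inside it (after a settling margin past drug onset, so
#' the initial tension transient is avoided; stationary-segment selection
#' inside the window does the rest) and returns post/pre ratios of A_SC and
#' f_SC.
#'
#' @param bundle A [trace_bundle()].
#' @param drug Drug name, or a list with `t_on`, `t_off`.
#' @param settling_s Margin after drug onset before the post window starts, s.
#' @param band f_SC search band, Hz.
#' @param ... Passed to [quantify_spontaneous()].
#' @return List: `asc_fold`, `fsc_fold` (post/pre; `NA` with a flag when a
#'   side is not estimable), `pre`, `post` (the two `spontaneous_stats`),
#'   `flags`.
#' @export
pre_post_spontaneous <- function(bundle, drug, settling_s = 90,
                                 band = c(0.005, 0.5), ...) {
  w <- find_drug_window(bundle, drug)
  run <- function(t_range) {
    tryCatch(quantify_spontaneous(bundle, band = band, t_range = t_range, ...),
             error = function(e) e)
  }
  pre <- run(c(bundle$trace$start_time, w$t_on))
  post <- run(c(w$t_on + settling_s, w$t_off))
  flags <- character(0)
  if (inherits(pre, "error")) flags <- c(flags, paste0("pre: ", conditionMessage(pre)))
  if (inherits(post, "error")) flags <- c(flags, paste0("post: ", conditionMessage(post)))
  ok <- !inherits(pre, "error") && !inherits(post, "error")
  asc_fold <- fsc_fold <- NA_real_
  if (ok) {
    if (pre$A_SC > 0) asc_fold <- post$A_SC / pre$A_SC
    else flags <- c(flags, "pre A_SC = 0: asc_fold undefined")
    if (!is.na(pre$f_SC) && !is.na(post$f_SC)) fsc_fold <- post$f_SC / pre$f_SC
    else flags <- c(flags, "f_SC not estimable on one side")
  }
  list(asc_fold = asc_fold, fsc_fold = fsc_fold,
       pre = if (ok || !inherits(pre, "error")) pre else NULL,
       post = if (ok || !inherits(post, "error")) post else NULL,
       flags = flags)
}

#' Pre/post drug fold change of EFS contraction amplitude
#'
#' Ratio of the mean normalized EFS amplitude of trains inside the drug
#' window (after a settling margin) to the mean over trains before drug
#' onset. Train settings must be identical on both sides.
#'
#' @param bundle A [trace_bundle()] with EFS trains on both sides of the
#'   drug onset.
#' @param drug Drug name, or a list with `t_on`, `t_off`.
#' @param settling_s Post-onset margin before trains count as "post", s.
#' @return List: `efs_fold`, `pre_mean`, `post_mean` (% of KCl), `n_pre`,
#'   `n_post`, `flags`.
#' @export
pre_post_efs <- function(bundle, drug, settling_s = 90) {
  w <- find_drug_window(bundle, drug)
  resp <- efs_responses(bundle)
  if (nrow(resp) == 0) stop("no EFS trains annotated", call. = FALSE)
  pre <- resp$A_EFS[resp$onset + 2 < w$t_on]  # response complete before onset
  post <- resp$A_EFS[resp$onset >= w$t_on + settling_s & resp$onset < w$t_off]
  if (length(pre) < 1 || length(post) < 1) {
    stop("need at least one EFS train on each side of drug onset",
         call. = FALSE)
  }
  flags <- character(0)
  fold <- NA_real_
  if (mean(pre) == 0) {
    flags <- c(flags, "pre-drug mean A_EFS = 0: fold undefined")
  } else {
    fold <- mean(post) / mean(pre)
    if (fold == 0) flags <- c(flags, "zero-response: complete block")
  }
  list(efs_fold = fold, pre_mean = mean(pre), post_mean = mean(post),
       n_pre = length(pre), n_post = length(post), flags = flags)
}

#' Full drug-effect quantification for one strip
#'
#' Combines [baseline_tension_change()], [pre_post_spontaneous()] and (when
#' EFS trains are present) [pre_post_efs()] into one record.
#'
#' @param bundle A [trace_bundle()].
#' @param drug Drug name.
#' @param ... Passed to [pre_post_spontaneous()].
#' @return Object of class `drug_effect` with fields `drug`,
#'   `concentration`, `delta_tension`, `asc_fold`, `fsc_fold`, `efs_fold`,
#'   `flags`.
#' @export
drug_effect <- function(bundle, drug, ...) {
  w <- find_drug_window(bundle, drug)
  dt <- baseline_tension_change(bundle, drug)
  sp <- pre_post_spontaneous(bundle, drug, ...)
  ef <- if (nrow(bundle$events$efs_trains) > 0) {
    tryCatch(pre_post_efs(bundle, drug), error = function(e) {
      list(efs_fold = NA_real_, flags = conditionMessage(e))
    })
  } else list(efs_fold = NA_real_, flags = character(0))
  structure(list(drug = if (is.character(drug)) drug else "window",
                 concentration = w$concentration %||% NA_real_,
                 delta_tension = dt$delta_tension,
                 asc_fold = sp$asc_fold, fsc_fold = sp$fsc_fold,
                 efs_fold = ef$efs_fold,
                 flags = c(sp$flags, ef$flags)),
            class = "drug_effect")
}

#' @export
print.drug_effect <- function(x, ...) {
  cat(sprintf(paste0("<drug_effect> %s: tension %+.2f%% KCl; folds A_SC ",
                     "%.3g, f_SC %.3g, A_EFS %.3g%s\n"),
              x$drug, x$delta_tension, x$asc_fold, x$fsc_fold, x$efs_fold,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "),
                                          "]") else ""))
  invisible(x)
}
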