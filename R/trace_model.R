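#' Isometric tension trace
#'
#' Container for a uniformly sampled organ-bath tension recording. Time is in
#' seconds, zero-based at the start of the recording; tension is in mN.
#'
#' @param samples Numeric vector of tension values (mN); all finite, length
#'   at least 2.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param start_time Recording start time in s (default 0).
#' @param strip_meta Named list of strip metadata: `group`
#'   (`"control"`/`"cancer"`), `urothelium` (`"intact"`/`"denuded"`),
#'   `preload` (mN, the initial stretch load), `strip_id`, `animal_id`.
#' @return An object of class `tension_trace`.
#' @export
tension_trace <- function(samples, sampling_rate, start_time = 0,
                          strip_meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("a tension trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples))) stop("non-finite tension samples", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0", call. = FALSE)
  }
  meta <- utils::modifyList(
    list(group = NA_character_, urothelium = NA_character_,
         preload = 5, strip_id = NA_character_, animal_id = NA_character_),
    strip_meta)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 start_time = start_time, strip_meta = meta),
            class = "tension_trace")
}

#' Time axis of a trace, in seconds.
#' @param trace A [tension_trace()].
#' @export
trace_time <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1) / trace$sampling_rate
}

trace_end <- function(trace) {
  trace$start_time + (length(trace$samples) - 1) / trace$sampling_rate
}

#' @export
print.tension_trace <- function(x, ...) {
  cat(sprintf("<tension_trace> %d samples @ %g Hz (%.1f s), strip %s [%s/%s]\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              x$strip_meta$strip_id, x$strip_meta$group, x$strip_meta$urothelium))
  invisible(x)
}

empty_trains <- function() {
  data.frame(onset = numeric(0), train_duration = numeric(0),
             pulse_width_ms = numeric(0), frequency_Hz = numeric(0),
             amplitude_V = numeric(0))
}

empty_drugs <- function() {
  data.frame(name = character(0), concentration = numeric(0),
             t_on = numeric(0), t_off = numeric(0))
}

#' Event annotations for a tension trace
#'
#' Timed annotations of the experimental protocol: the 60 mM KCl reference
#' contraction window, EFS pulse trains, and drug application windows. All
#' windows are half-open `[t_on, t_off)` in seconds on the trace clock.
#'
#' @param kcl `NULL`, or a list with `t_on`, `t_off` (s) and
#'   `concentration_mM` (default 60).
#' @param efs_trains Data frame with columns `onset` (s), `train_duration`
#'   (s), `pulse_width_ms`, `frequency_Hz`, `amplitude_V`.
#' @param drugs Data frame with columns `name`, `concentration`, `t_on`,
#'   `t_off`.
#' @return An object of class `event_log`.
#' @export
event_log <- function(kcl = NULL, efs_trains = empty_trains(),
                      drugs = empty_drugs()) {
  if (!is.null(kcl)) {
    kcl <- utils::modifyList(list(concentration_mM = 60), kcl)
    stopifnot(is.numeric(kcl$t_on), is.numeric(kcl$t_off), kcl$t_on < kcl$t_off)
  }
  efs_trains <- as.data.frame(efs_trains)
  drugs <- as.data.frame(drugs)
  if (nrow(efs_trains)) efs_trains <- efs_trains[order(efs_trains$onset), , drop = FALSE]
  rownames(efs_trains) <- NULL
  rownames(drugs) <- NULL
  structure(list(kcl = kcl, efs_trains = efs_trains, drugs = drugs),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> KCl: %s; %d EFS train(s); %d drug window(s)\n",
              if (is.null(x$kcl)) "none" else
                sprintf("[%g, %g) s, %g mM", x$kcl$t_on, x$kcl$t_off,
                        x$kcl$concentration_mM),
              nrow(x$efs_trains), nrow(x$drugs)))
  invisible(x)
}

#' Trace + events (+ optional ground truth) bundle
#'
#' @param trace A [tension_trace()].
#' @param events An [event_log()].
#' @param ground_truth Optional list of generator parameters and realized
#'   event times; present only for synthetic data.
#' @return An object of class `trace_bundle`.
#' @export
trace_bundle <- function(trace, events, ground_truth = NULL) {
  stopifnot(inherits(trace, "tension_trace"), inherits(events, "event_log"))
  structure(list(trace = trace, events = events, ground_truth = ground_truth),
            class = "trace_bundle")
}

#' @export
print.trace_bundle <- function(x, ...) {
  print(x$trace); print(x$events)
  if (!is.null(x$ground_truth)) cat("  (synthetic: ground truth attached)\n")
  invisible(x)
}

#' Validate a trace bundle
#'
#' Checks every type invariant and returns findings instead of raising, so a
#' batch of files can be screened. An empty character vector means the bundle
#' conforms.
#'
#' @param bundle A [trace_bundle()].
#' @return Character vector of findings, one per violated invariant.
#' @export
validate_bundle <- function(bundle) {
  f <- character(0)
  tr <- bundle$trace; ev <- bundle$events
  if (!all(is.finite(tr$samples))) f <- c(f, "trace: non-finite samples")
  if (length(tr$samples) < 2) f <- c(f, "trace: fewer than 2 samples")
  if (!is.numeric(tr$sampling_rate) || tr$sampling_rate <= 0) {
    f <- c(f, "trace: sampling_rate not positive")
  }
  if (is.null(tr$strip_meta$preload) || !is.finite(tr$strip_meta$preload)) {
    f <- c(f, "trace: preload not recorded")
  }
  t0 <- tr$start_time; t1 <- trace_end(tr)
  in_span <- function(a, b) a >= t0 & b <= t1 + 1 / tr$sampling_rate
  if (!is.null(ev$kcl) && !in_span(ev$kcl$t_on, ev$kcl$t_off)) {
    f <- c(f, "events: KCl window outside trace span")
  }
  if (nrow(ev$efs_trains)) {
    tr_on <- ev$efs_trains$onset
    tr_off <- tr_on + ev$efs_trains$train_duration
    bad <- !in_span(tr_on, tr_off)
    if (any(bad)) f <- c(f, sprintf("events: EFS train %d outside trace span",
                                    which(bad)))
    if (nrow(ev$efs_trains) > 1) {
      for (i in seq_len(nrow(ev$efs_trains) - 1)) {
        for (j in (i + 1):nrow(ev$efs_trains)) {
          if (intervals_overlap(tr_on[i], tr_off[i], tr_on[j], tr_off[j])) {
            f <- c(f, sprintf("events: EFS trains %d and %d overlap", i, j))
          }
        }
      }
    }
  }
  if (nrow(ev$drugs)) {
    bad <- !in_span(ev$drugs$t_on, ev$drugs$t_off)
    if (any(bad)) f <- c(f, sprintf("events: drug window '%s' outside trace span",
                                    ev$drugs$name[bad]))
    if (any(ev$drugs$t_on >= ev$drugs$t_off)) {
      f <- c(f, "events: drug window with t_on >= t_off")
    }
    # same drug applied twice concurrently contradicts itself
    for (nm in unique(ev$drugs$name)) {
      d <- ev$drugs[ev$drugs$name == nm, , drop = FALSE]
      if (nrow(d) > 1) {
        for (i in seq_len(nrow(d) - 1)) {
          for (j in (i + 1):nrow(d)) {
            if (intervals_overlap(d$t_on[i], d$t_off[i], d$t_on[j], d$t_off[j])) {
              f <- c(f, sprintf("events: drug '%s' applied twice concurrently", nm))
            }
          }
        }
      }
    }
  }
  f
}

sidecar_path <- function(path) sub("\\.csv$", "", path) |> paste0(".events.yaml")

#' Write a trace bundle to disk
#'
#' The trace goes to a two-column CSV (`time_s,tension_mN`, full double
#' precision so that reading inverts writing bit-exactly) and the annotations
#' to a YAML sidecar next to it (`<stem>.events.yaml`).
#'
#' @param bundle A valid [trace_bundle()].
#' @param path Path of the trace CSV file.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "trace_bundle"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  tt <- trace_time(bundle$trace)
  lines <- c("time_s,tension_mN",
             sprintf("%.17g,%.17g", tt, bundle$trace$samples))
  writeLines(lines, path)
  ev <- bundle$events
  side <- list(
    strip_meta = bundle$trace$strip_meta,
    kcl = ev$kcl,
    efs_trains = if (nrow(ev$efs_trains)) unname(split(ev$efs_trains, seq_len(nrow(ev$efs_trains)))) |>
      lapply(as.list) else list(),
    drugs = if (nrow(ev$drugs)) unname(split(ev$drugs, seq_len(nrow(ev$drugs)))) |>
      lapply(as.list) else list(),
    ground_truth = bundle$ground_truth
  )
  yaml::write_yaml(side, sidecar_path(path), precision = 17)
  invisible(path)
}

#' Read a trace bundle from disk
#'
#' Reads a two-column delimited trace (`time_s,tension_mN`) plus its YAML
#' annotation sidecar. The sampling rate is inferred from the median time
#' step; step jitter beyond 1% of the median step is rejected because
#' digitized chart recordings are expected to be uniformly sampled.
#'
#' @param path Path of the trace CSV file (sidecar `<stem>.events.yaml` must
#'   be adjacent).
#' @param jitter_tol Maximum tolerated relative deviation of any time step
#'   from the median step (default 0.01).
#' @return A validated [trace_bundle()].
#' @export
read_bundle <- function(path, jitter_tol = 0.01) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop("annotation error: missing sidecar ", sp, call. = FALSE)
  }
  d <- utils::read.csv(path)
  if (!all(c("time_s", "tension_mN") %in% names(d))) {
    stop("format error: expected columns time_s,tension_mN", call. = FALSE)
  }
  if (anyNA(d$tension_mN) || !all(is.finite(d$tension_mN))) {
    stop("format error: NaN or non-finite tension values", call. = FALSE)
  }
  dt <- diff(d$time_s)
  if (any(dt <= 0)) stop("format error: time not strictly increasing", call. = FALSE)
  med <- stats::median(dt)
  if (max(abs(dt - med)) / med > jitter_tol) {
    stop("format error: non-uniform sampling beyond ",
         sprintf("%g%%", 100 * jitter_tol), " step jitter", call. = FALSE)
  }
  side <- yaml::read_yaml(sp)
  to_df <- function(lst, empty) {
    if (length(lst) == 0) return(empty)
    do.call(rbind, lapply(lst, function(r) as.data.frame(r)))
  }
  trace <- tension_trace(d$tension_mN, sampling_rate = 1 / med,
                         start_time = d$time_s[1],
                         strip_meta = side$strip_meta %||% list())
  events <- event_log(kcl = side$kcl,
                      efs_trains = to_df(side$efs_trains, empty_trains()),
                      drugs = to_df(side$drugs, empty_drugs()))
  trace_bundle(trace, events, ground_truth = side$ground_truth)
}
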