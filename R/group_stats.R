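#' Mean, sample SD and n of a metric
#'
#' Cohort results are reported as mean +/- SD with n the number of strips.
#' Sample SD uses the n - 1 denominator; a single value reports `NA` SD with
#' a flag.
#'
#' @param values Numeric vector (NAs dropped).
#' @return List: `mean`, `sd`, `n`, `flags`.
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("domain error: no values to summarize",
                                call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_,
       n = length(values),
       flags = if (length(values) == 1) "single value: SD undefined" else character(0))
}

#' Unpaired two-sample t-test between cohorts
#'
#' Classical pooled-variance (Student) unpaired t-test, two-sided, with
#' significance at P < 0.05; the Welch unequal-variance variant is
#' available via `var_equal = FALSE`. Degenerate zero-variance inputs are
#' handled explicitly: equal means give t = 0, p = 1; unequal means are
#' flagged degenerate.
#'
#' @param groupA,groupB Numeric vectors, each with n >= 2 (NAs dropped).
#' @param metric Metric name carried into the result.
#' @param var_equal Pool variances (classical Student test) if `TRUE`.
#' @param alpha Significance level.
#' @return Object of class `group_comparison`: `metric`, `groupA`/`groupB`
#'   summaries, `t_statistic`, `degrees_of_freedom`, `p_value`,
#'   `significant`, `flags`.
#' @export
unpaired_t <- function(groupA, groupB, metric = "metric", var_equal = TRUE,
                       alpha = 0.05) {
  groupA <- groupA[!is.na(groupA)]; groupB <- groupB[!is.na(groupB)]
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("both groups need n >= 2 for a t-test", call. = FALSE)
  }
  sA <- summarize_values(groupA); sB <- summarize_values(groupB)
  flags <- character(0)
  if (sA$sd == 0 && sB$sd == 0) {
    if (sA$mean == sB$mean) {
      t_stat <- 0; df <- sA$n + sB$n - 2; p <- 1
    } else {
      t_stat <- NA_real_; df <- sA$n + sB$n - 2; p <- NA_real_
      flags <- "degenerate: zero pooled variance with unequal means"
    }
  } else {
    tt <- stats::t.test(groupA, groupB, var.equal = var_equal)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(metric = metric, groupA = sA, groupB = sB,
                 t_statistic = t_stat, degrees_of_freedom = df,
                 p_value = p,
                 significant = !is.na(p) && p < alpha, alpha = alpha,
                 flags = flags),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0("<group_comparison> %s: %.4g +/- %.3g (n=%d) vs ",
                     "%.4g +/- %.3g (n=%d); t = %.3g, df = %.3g, P = %.3g%s\n"),
              x$metric, x$groupA$mean, x$groupA$sd, x$groupA$n,
              x$groupB$mean, x$groupB$sd, x$groupB$n,
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Compare control and cancer cohorts metric by metric
#'
#' Strips are the statistical unit (pooled across animals), matching the
#' original design; this is a pseudo-replication caveat, not something the
#' package corrects. Strips with a missing (flagged) value of a metric are
#' excluded from that metric's test with n adjusted. No multiple-testing
#' correction is applied.
#'
#' @param control,cancer Data frames of per-strip metrics (one row per
#'   strip).
#' @param metrics Character vector of column names to compare.
#' @param ... Passed to [unpaired_t()].
#' @return Data frame of class `cohort_comparison`, one row per metric:
#'   group means/SDs/ns, t, df, p, significance. Metrics absent from either
#'   table are reported with `NA`s and a note.
#' @export
compare_cohorts <- function(control, cancer, metrics, ...) {
  rows <- lapply(metrics, function(m) {
    if (!m %in% names(control) || !m %in% names(cancer)) {
      return(data.frame(metric = m, control_mean = NA, control_sd = NA,
                        control_n = NA, cancer_mean = NA, cancer_sd = NA,
                        cancer_n = NA, t = NA, df = NA, p = NA,
                        significant = NA, note = "metric absent"))
    }
    cmp <- unpaired_t(control[[m]], cancer[[m]], metric = m, ...)
    data.frame(metric = m,
               control_mean = cmp$groupA$mean, control_sd = cmp$groupA$sd,
               control_n = cmp$groupA$n,
               cancer_mean = cmp$groupB$mean, cancer_sd = cmp$groupB$sd,
               cancer_n = cmp$groupB$n,
               t = cmp$t_statistic, df = cmp$degrees_of_freedom,
               p = cmp$p_value, significant = cmp$significant, note = "")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_comparison", "data.frame")
  out
}

#' Write a comparison report: summary table plus bar figures
#'
#' Writes `comparisons.csv` and, per metric, a bar chart of group mean +/-
#' SD with a significance mark, the standard presentation of cohort
#' contrasts in this field.
#'
#' @param comparisons A [compare_cohorts()] result (>= 1 row).
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
report <- function(comparisons, out_dir) {
  if (nrow(comparisons) < 1) stop("no comparisons to report", call. = FALSE)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  tab <- file.path(out_dir, "comparisons.csv")
  utils::write.csv(as.data.frame(comparisons), tab, row.names = FALSE)
  files <- tab
  for (i in seq_len(nrow(comparisons))) {
    r <- comparisons[i, ]
    if (is.na(r$control_mean)) next
    d <- data.frame(group = factor(c("control", "cancer"),
                                   levels = c("control", "cancer")),
                    mean = c(r$control_mean, r$cancer_mean),
                    sd = c(r$control_sd, r$cancer_sd))
    g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
      ggplot2::geom_col(fill = c("grey80", "grey40"), width = 0.6) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             width = 0.15) +
      ggplot2::labs(title = r$metric,
                    subtitle = sprintf("P = %.3g%s", r$p,
                                       if (isTRUE(r$significant)) " *" else ""),
                    x = NULL, y = r$metric) +
      ggplot2::theme_classic()
    f <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", r$metric),
                                   ".pdf"))
    ggplot2::ggsave(f, g, width = 3, height = 4)
    files <- c(files, f)
  }
  invisible(files)
}
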