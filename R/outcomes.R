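#' Packaged clinical-outcome fixtures
#'
#' `arat_fixture()` returns the 19-item Action Research Arm Test score
#' table (items x conditions `no_brace`, `emg_myopro`, `bci_myopro`),
#' and `release_times_fixture()` the object release times in seconds
#' under BCI and myoelectric (EMG) orthosis control, as recorded during
#' the trial's grasp-move-release task.
#'
#' @return a data.frame
#' @export
arat_fixture <- function() {
  utils::read.csv(system.file("extdata", "arat_items.csv", package = "bcisim"),
                  check.names = FALSE)
}

#' @rdname arat_fixture
#' @export
release_times_fixture <- function() {
  utils::read.csv(system.file("extdata", "release_times.csv", package = "bcisim"))
}

#' ARAT total for one condition
#'
#' The Action Research Arm Test scores 19 upper-limb items from 0 to 3;
#' the condition total is their sum (range 0-57).
#'
#' @param table item-score data.frame with an `item` column and one
#'   column per condition (see [arat_fixture()])
#' @param condition condition column name
#' @return integer total
#' @export
arat_total <- function(table, condition) {
  if (!condition %in% names(table)) stop("unknown condition: ", condition)
  scores <- table[[condition]]
  if (length(scores) != 19L) stop("ARAT requires 19 items, got ", length(scores))
  bad <- which(!(scores %in% 0:3))
  if (length(bad))
    stop("score outside 0-3 for item: ", table$item[bad[1]])
  as.integer(sum(scores))
}

#' Two-sample t test on release times
#'
#' Pooled-variance (Student) two-sample two-tailed t test, the variant
#' under which the packaged release-time data reproduce the reported
#' group difference; the unequal-variance (Welch) alternative is
#' available via `var_equal = FALSE`.  Implemented in closed form:
#' `t = (mean(a) - mean(b)) / (s_p * sqrt(1/n1 + 1/n2))` with the pooled
#' SD `s_p`, `df = n1 + n2 - 2`, and the two-tailed p from the t
#' distribution.
#'
#' @param a,b numeric samples (each n >= 2)
#' @param var_equal pooled variance? (default TRUE)
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `pooled_sd`
#' @export
pooled_t_test <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    sp2 <- NA_real_
  }
  tstat <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  p <- if (se == 0) 1 else 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p, mean_a = mean(a), mean_b = mean(b),
       pooled_sd = if (var_equal) sqrt(sp2) else NA_real_)
}

#' Extract release times from a session log
#'
#' Pairs each `over_bin` event with the following `release` event in the
#' same trial; trials lacking a release (timeouts) are excluded and
#' counted.  A release logged before its over-bin event is an event
#' ordering error.
#'
#' @param log a [session_log][run_closed_loop]
#' @param condition condition label to attach (default the log's mode)
#' @return list with `condition`, `times` (seconds, one per completed
#'   cycle) and `n_excluded`
#' @export
release_times_from_log <- function(log, condition = NULL) {
  if (is.null(condition))
    condition <- if (nrow(log)) log$mode[1] else "unknown"
  times <- numeric(0)
  n_excluded <- 0L
  if (nrow(log)) {
    for (tr in unique(log$trial)) {
      ev <- log[log$trial == tr & !is.na(log$event), c("time", "event")]
      t_ob <- ev$time[ev$event == "over_bin"]
      t_rel <- ev$time[ev$event == "release"]
      if (length(t_rel) && (!length(t_ob) || t_rel[1] < t_ob[1]))
        stop("event order: release before over_bin in trial ", tr)
      if (length(t_ob) && length(t_rel)) {
        times <- c(times, t_rel[1] - t_ob[1])
      } else if (length(t_ob)) {
        n_excluded <- n_excluded + 1L
      }
    }
  }
  list(condition = condition, times = times, n_excluded = n_excluded)
}

# reference clinical scales carried as data (single-participant
# measurements; not recomputable from items)
reference_scales <- function() {
  list(
    fugl_meyer_ue = c(pre_implant_1mo = 30, post_implant_1mo = 36,
                      post_implant_7wk = 38),
    motricity_index = c(pre_implant_1mo = 48, post_implant_2mo = 61.5,
                        post_implant_3mo = 75.5),
    stroke_impact_scale = c(pre_implant_1mo = 232, post_explant_3mo = 269),
    jebsen_taylor_5_object_s = c(myoelectric = 146, bci = 95)
  )
}

#' Outcome summary report
#'
#' Tabulates ARAT totals per condition, release-time descriptives and
#' the two-sample t comparison from the supplied fixtures and/or
#' session logs, and echoes the stored reference scales (Fugl-Meyer,
#' Motricity Index, Stroke Impact Scale, Jebsen-Taylor variant) as data.
#'
#' @param arat ARAT item table (default NULL: section omitted)
#' @param release release-time data.frame with `condition`, `seconds`
#'   (default NULL)
#' @param logs optional list of [session_log][run_closed_loop]s whose
#'   extracted release times are appended as additional conditions
#' @return object of class `outcome_report` (a list); see
#'   [print.outcome_report()] and [write_outcome_report()]
#' @export
outcome_report <- function(arat = NULL, release = NULL, logs = NULL) {
  rep <- list()
  if (!is.null(arat)) {
    conds <- setdiff(names(arat), "item")
    rep$arat_totals <- vapply(conds, function(k) arat_total(arat, k), 0L)
  }
  groups <- list()
  if (!is.null(release)) {
    for (k in unique(release$condition))
      groups[[k]] <- release$seconds[release$condition == k]
  }
  if (!is.null(logs)) {
    for (lg in logs) {
      rt <- release_times_from_log(lg)
      groups[[rt$condition]] <- c(groups[[rt$condition]], rt$times)
    }
  }
  if (length(groups)) {
    rep$release_descriptives <- lapply(groups, function(x)
      list(n = length(x), mean = mean(x), sd = stats::sd(x)))
    if (length(groups) >= 2) {
      nm <- names(groups)[1:2]
      tt <- pooled_t_test(groups[[nm[1]]], groups[[nm[2]]])
      rep$t_test <- c(list(groups = nm), tt)
    }
  }
  rep$reference_scales <- reference_scales()
  structure(rep, class = "outcome_report")
}

#' @param x an `outcome_report`
#' @param ... unused
#' @rdname outcome_report
#' @export
print.outcome_report <- function(x, ...) {
  cat("== Outcome report ==\n")
  if (!is.null(x$arat_totals)) {
    cat("ARAT totals (0-57):\n")
    for (k in names(x$arat_totals))
      cat(sprintf("  %-12s %d\n", k, x$arat_totals[[k]]))
  } else cat("ARAT: no data\n")
  if (!is.null(x$release_descriptives)) {
    cat("Release times (s):\n")
    for (k in names(x$release_descriptives)) {
      d <- x$release_descriptives[[k]]
      cat(sprintf("  %-12s n=%d mean=%.2f sd=%.2f\n", k, d$n, d$mean, d$sd))
    }
    if (!is.null(x$t_test))
      cat(sprintf("  %s vs %s: t=%.3f df=%.1f p=%.4f (pooled two-tailed)\n",
                  x$t_test$groups[1], x$t_test$groups[2],
                  x$t_test$t, x$t_test$df, x$t_test$p))
  } else cat("Release times: no data\n")
  cat("Reference scales (stored measurements, not recomputed):\n")
  cat(sprintf("  Fugl-Meyer UE %s; Motricity %s; SIS %s; Jebsen-Taylor (s) %s\n",
              paste(x$reference_scales$fugl_meyer_ue, collapse = "/"),
              paste(x$reference_scales$motricity_index, collapse = "/"),
              paste(x$reference_scales$stroke_impact_scale, collapse = "/"),
              paste(x$reference_scales$jebsen_taylor_5_object_s, collapse = "/")))
  invisible(x)
}

#' @param path output path; `.json` writes JSON, anything else Markdown
#' @rdname outcome_report
#' @export
write_outcome_report <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    lines <- c("# Outcome report", "",
               utils::capture.output(print(x)))
    writeLines(lines, path)
  }
  invisible(path)
}
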