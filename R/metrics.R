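#' Evaluation windows per stimulus, with transition removal
#'
#' Builds the per-segment evaluation windows used for target-deviation
#' reporting: box windows exclude their first 10 s and last 5 s, ramp
#' windows exclude their last 5 s, half-sine windows and baselines are
#' evaluated in full. A segment too short for its exclusions yields an
#' empty, flagged window.
#'
#' @param protocol A [stimulus_protocol()].
#' @param box_head Seconds removed from the start of each box (default 10).
#' @param box_tail Seconds removed from the end of each box (default 5).
#' @param ramp_tail Seconds removed from the end of each ramp (default 5).
#' @return Data frame with columns `stimulus`, `kind`, `level_percent`,
#'   `seg_start`, `seg_end`, `win_start`, `win_end`, `flagged`.
#' @examples
#' stimulus_windows(default_protocol())
#' @export
stimulus_windows <- function(protocol, box_head = 10, box_tail = 5,
                             ramp_tail = 5) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  durs <- vapply(protocol$segments, function(s) s$duration, numeric(1))
  starts <- cumsum(c(0, durs))
  n <- length(protocol$segments)
  out <- data.frame(stimulus = seq_len(n),
                    kind = vapply(protocol$segments, function(s) s$kind,
                                  character(1)),
                    level_percent = 100 * vapply(protocol$segments,
                                                 function(s) s$level,
                                                 numeric(1)),
                    seg_start = starts[-(n + 1)],
                    seg_end = starts[-1])
  out$win_start <- out$seg_start
  out$win_end <- out$seg_end
  box <- out$kind == "box"
  out$win_start[box] <- out$seg_start[box] + box_head
  out$win_end[box] <- out$seg_end[box] - box_tail
  ramp <- out$kind == "ramp"
  out$win_end[ramp] <- out$seg_end[ramp] - ramp_tail
  out$flagged <- out$win_end <= out$win_start
  out$win_start[out$flagged] <- NA_real_
  out$win_end[out$flagged] <- NA_real_
  out
}

#' Per-stimulus deviation between a measured inspired series and the target
#'
#' For each stimulus window (after transition removal, see
#' [stimulus_windows()]) the deviation `measured - target` is evaluated at
#' the series' time points, and the signed mean, mean absolute deviation
#' and a seeded bootstrap 95 % confidence interval of the signed mean are
#' reported, in volume percentage points. When several runs are supplied
#' the confidence interval is computed across runs; for a single series it
#' is computed across samples within the window (the report records
#' which). The headline statistic is the maximum mean absolute deviation
#' across non-baseline stimuli.
#'
#' @param series Data frame with columns `t_s` and `value` (measured
#'   inspired CO2, percent), an [bin_and_aggregate()] result (its `mean`
#'   column is used), or a list of per-run series.
#' @param protocol The [stimulus_protocol()] that was administered.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @param ... Passed to [stimulus_windows()].
#' @return A data frame of class `"deviation_report"` with one row per
#'   segment (`stimulus`, `kind`, `level_percent`, `n`, `mean_dev`,
#'   `mean_abs_dev`, `ci_low`, `ci_high`, `flagged`), with attributes
#'   `overall_max_abs_dev` (max over non-baseline stimuli) and
#'   `ci_across` (`"runs"` or `"samples"`).
#' @export
mean_target_deviation <- function(series, protocol, n_boot = 1000, seed = 1,
                                  ...) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (inherits(series, "aggregate_series")) {
    series <- data.frame(t_s = series$bin_t_s, value = series$mean)
  }
  multi <- !is.data.frame(series)
  runs <- if (multi) series else list(series)
  for (r in runs) {
    if (is.null(r$t_s) || is.null(r$value)) {
      stop("series needs columns t_s and value", call. = FALSE)
    }
  }
  total <- protocol_duration(protocol)
  tall <- unlist(lapply(runs, function(r) r$t_s))
  if (max(tall) < 0 || min(tall) >= total) {
    stop("series does not overlap the protocol in time", call. = FALSE)
  }
  win <- stimulus_windows(protocol, ...)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  nw <- nrow(win)
  res <- data.frame(win[, c("stimulus", "kind", "level_percent")],
                    n = 0L, mean_dev = NA_real_, mean_abs_dev = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    flagged = win$flagged)
  for (i in seq_len(nw)) {
    if (win$flagged[i]) next
    # half-open window; samples exactly on a boundary belong to the later
    # segment
    devs <- lapply(runs, function(r) {
      sel <- r$t_s >= win$win_start[i] & r$t_s < win$win_end[i] &
        is.finite(r$value) & r$t_s < total
      if (!any(sel)) return(numeric(0))
      r$value[sel] - 100 * target_fco2i(protocol, r$t_s[sel])
    })
    all_dev <- unlist(devs)
    if (length(all_dev) == 0L) {
      res$flagged[i] <- TRUE
      next
    }
    res$n[i] <- length(all_dev)
    res$mean_dev[i] <- mean(all_dev)
    res$mean_abs_dev[i] <- mean(abs(all_dev))
    if (multi && length(runs) > 1L) {
      run_means <- vapply(devs, function(d)
        if (length(d)) mean(d) else NA_real_, numeric(1))
      run_means <- run_means[is.finite(run_means)]
      bm <- vapply(seq_len(n_boot), function(b)
        mean(run_means[sample.int(length(run_means), replace = TRUE)]),
        numeric(1))
    } else {
      bm <- vapply(seq_len(n_boot), function(b)
        mean(all_dev[sample.int(length(all_dev), replace = TRUE)]),
        numeric(1))
    }
    q <- stats::quantile(bm, c(0.025, 0.975), names = FALSE)
    res$ci_low[i] <- q[1]
    res$ci_high[i] <- q[2]
  }
  stim <- res$kind != "baseline" & !res$flagged
  attr(res, "overall_max_abs_dev") <- if (any(stim))
    max(res$mean_abs_dev[stim]) else NA_real_
  attr(res, "ci_across") <- if (multi && length(runs) > 1L) "runs" else
    "samples"
  class(res) <- c("deviation_report", "data.frame")
  res
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("Per-stimulus inspired-CO2 target deviation (percentage points)\n")
  df <- as.data.frame(x)
  df$mean_dev <- round(df$mean_dev, 3)
  df$mean_abs_dev <- round(df$mean_abs_dev, 3)
  df$ci_low <- round(df$ci_low, 3)
  df$ci_high <- round(df$ci_high, 3)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("Overall max |deviation| across stimuli: %.3f pp (CI across %s)\n",
              attr(x, "overall_max_abs_dev"), attr(x, "ci_across")))
  invisible(x)
}
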