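#' Detect breath phases in an analyzer trace
#'
#' Segments a uniformly sampled CO2/O2 trace into expirations and the
#' inspirations between them. Expirations are regions where the (median
#' smoothed) CO2 signal lies above an adaptive threshold, the midpoint of
#' a rolling minimum and maximum. Candidate expirations shorter than
#' `min_duration` or with a CO2 excursion below `min_excursion` (analyzer
#' glitches, artifact spikes) are rejected. In spontaneous mode each
#' candidate must additionally pass an exponential-shape test: an
#' exponential approach to the expiratory plateau is fitted to the first
#' part of the candidate, and the fit's RMSE normalized by the excursion
#' must fall below `shape_nrmse_max`. For ventilated traces that carry a
#' flow channel, segmentation is gated on inspiratory flow instead, since
#' a passive test lung expires gas of the same composition it inspired
#' and so shows no CO2 excursion at steady state.
#'
#' @param trace Data frame with columns `t_s`, `fco2_percent` and
#'   optionally `fo2_percent`, `flow_lpm`, uniformly sampled.
#' @param mode `"ventilated"` or `"spontaneous"`.
#' @param min_duration Minimum accepted phase duration, s (default 0.5).
#' @param min_excursion Minimum CO2 excursion of an expiration,
#'   percentage points (default 0.3).
#' @param shape_nrmse_max Spontaneous-mode acceptance bound on the
#'   normalized RMSE of the exponential fit (default 0.25).
#' @param use_flow Force (`TRUE`) or forbid (`FALSE`) flow-gated
#'   segmentation in ventilated mode; default `NULL` uses flow when a
#'   non-degenerate flow channel is present.
#' @param window Rolling min/max window for the adaptive threshold, s
#'   (default 8; should cover at least one full breath).
#' @return Data frame with one row per breath: `insp_start`, `insp_end`,
#'   `exp_start`, `exp_end` (seconds; `insp_end == exp_start`).
#' @export
detect_breath_phases <- function(trace, mode = c("ventilated", "spontaneous"),
                                 min_duration = 0.5, min_excursion = 0.3,
                                 shape_nrmse_max = 0.25, use_flow = NULL,
                                 window = 8) {
  mode <- match.arg(mode)
  .check_trace(trace)
  t <- trace$t_s
  fs <- 1 / stats::median(diff(t))
  x <- trace$fco2_percent

  flow_ok <- !is.null(trace$flow_lpm) &&
    any(trace$flow_lpm > 0) && any(trace$flow_lpm <= 0)
  if (mode == "ventilated" && isTRUE(use_flow %||% flow_ok)) {
    thr <- 0.05 * max(trace$flow_lpm)
    above <- trace$flow_lpm > thr          # inspiration
    return(.phases_from_runs(!above, t, fs, min_duration,
                             min_excursion = 0, x = NULL))
  }

  k <- max(3L, round(0.15 * fs))
  if (k %% 2L == 0L) k <- k + 1L
  xs <- stats::runmed(x, k)
  if (max(xs) - min(xs) < min_excursion) {
    stop("no breaths detected: trace CO2 excursion below minimum",
         call. = FALSE)
  }
  thr <- .rolling_midline(xs, t, window)
  above <- xs > thr
  .phases_from_runs(above, t, fs, min_duration, min_excursion, xs,
                    shape_test = (mode == "spontaneous"),
                    shape_nrmse_max = shape_nrmse_max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_trace <- function(trace) {
  if (!is.data.frame(trace) || is.null(trace$t_s) ||
      is.null(trace$fco2_percent) || nrow(trace) < 4L) {
    stop("trace must be a data frame with t_s and fco2_percent columns",
         call. = FALSE)
  }
}

# adaptive threshold: midpoint of a rolling min/max. Chunked two-pass
# approximation: per-chunk extrema (chunk = window / 2) combined over each
# chunk and its neighbors give an effective window of 1-1.5x `window` in
# O(n), fast enough for hour-long traces.
.rolling_midline <- function(x, t, window) {
  span <- max(t) - min(t)
  nch <- max(1L, floor(span / (window / 2)))
  brk <- seq(min(t), max(t), length.out = nch + 1L)
  ch <- pmax(1L, pmin(nch, findInterval(t, brk, rightmost.closed = TRUE)))
  lo <- as.numeric(tapply(x, factor(ch, levels = seq_len(nch)), min))
  hi <- as.numeric(tapply(x, factor(ch, levels = seq_len(nch)), max))
  lo[is.na(lo)] <- Inf
  hi[is.na(hi)] <- -Inf
  if (nch > 1L) {
    lo <- pmin(lo, c(lo[-1], Inf), c(Inf, lo[-nch]))
    hi <- pmax(hi, c(hi[-1], -Inf), c(-Inf, hi[-nch]))
  }
  ((lo + hi) / 2)[ch]
}

# normalized RMSE of an exponential-approach fit y = a - b exp(-tau/tau0)
.exp_shape_nrmse <- function(y, fs) {
  n <- length(y)
  if (n < 5L) return(Inf)
  tau <- (seq_len(n) - 1) / fs
  exc <- max(y) - min(y)
  if (exc <= 0) return(Inf)
  best <- Inf
  for (tau0 in c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)) {
    basis <- exp(-tau / tau0)
    fit <- stats::lm.fit(cbind(1, basis), y)
    rmse <- sqrt(mean(fit$residuals^2))
    if (rmse < best) best <- rmse
  }
  best / exc
}

.phases_from_runs <- function(above, t, fs, min_duration, min_excursion,
                              x = NULL, shape_test = FALSE,
                              shape_nrmse_max = 0.25) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i0 <- starts[cand[j]]
    i1 <- ends[cand[j]]
    if (t[i1] - t[i0] < min_duration) next
    if (!is.null(x) && min_excursion > 0) {
      # excursion relative to the preceding below-threshold valley
      prev <- if (cand[j] > 1L) starts[cand[j] - 1L]:(i0 - 1L) else
        integer(0)
      base <- if (length(prev)) min(x[prev]) else min(x[i0:i1])
      if (max(x[i0:i1]) - base < min_excursion) next
    }
    if (shape_test && !is.null(x)) {
      seg <- x[i0:min(i1, i0 + max(5L, round(0.7 * (i1 - i0))))]
      if (.exp_shape_nrmse(seg, fs) > shape_nrmse_max) next
    }
    keep[j] <- TRUE
  }
  cand <- cand[keep]
  if (length(cand) == 0L) {
    stop("no breaths detected: no accepted expiration phases", call. = FALSE)
  }
  i0 <- starts[cand]
  i1 <- ends[cand]
  nr <- length(i0)
  insp0 <- integer(nr)      # inspiration start following each expiration
  if (!is.null(x)) {
    # Refine phase boundaries. The threshold crossing sits mid-rise /
    # mid-fall, so: expiration start is walked back to the rise onset
    # (10 % of the excursion above the preceding valley); expiration end
    # is the end of the near-peak plateau (the end-tidal plateau); the
    # following inspiration starts where the post-plateau fall flattens
    # out. The fall itself belongs to neither phase, which keeps inspired
    # values clean even when early-inspiratory gas is CO2-rich (reservoir
    # traces).
    w <- max(1L, round(0.2 * fs))
    tol <- 0.05
    n <- length(x)
    for (j in seq_len(nr)) {
      lo_lim <- if (j > 1L) i1[j - 1L] + 1L else 1L
      hi_lim <- if (j < nr) i0[j + 1L] - 1L else n
      pk <- max(x[i0[j]:i1[j]])
      vprev <- min(x[lo_lim:i0[j]])
      exc <- pk - vprev
      a <- i0[j]
      while (a > lo_lim && x[a - 1L] > vprev + 0.1 * exc &&
             x[a - 1L] <= x[a] + tol) a <- a - 1L
      run <- i0[j]:i1[j]
      near_pk <- run[x[run] >= pk - max(0.1 * exc, tol)]
      b <- near_pk[length(near_pk)]
      d <- b + 1L
      while (d < hi_lim && x[min(d + w, n)] < x[d] - tol) d <- d + 1L
      i0[j] <- a
      i1[j] <- b
      insp0[j] <- min(d, hi_lim)
    }
  } else {
    insp0 <- i1 + 1L
  }
  exp_start <- t[i0]
  exp_end <- t[i1]
  insp_start <- c(t[1], t[pmin(insp0[-nr], length(t))])
  ok <- (exp_start - insp_start) >= min_duration / 2 &
    exp_end > exp_start & insp_start < exp_start
  data.frame(insp_start = insp_start[ok], insp_end = exp_start[ok],
             exp_start = exp_start[ok], exp_end = exp_end[ok])
}

#' Extract per-breath inspired and end-tidal values
#'
#' For each detected breath, computes the inspired CO2/O2 peak and
#' baseline over the inspiration (windows are trimmed by 10 % at each end
#' so that phase-boundary samples of expired gas do not contaminate the
#' inspired values), a tracked inspired value, and the end-tidal CO2/O2 as
#' the median of the final 100 ms of the expiration. For traces from the
#' reservoir system, where non-excessive fresh-gas flow makes inspired
#' CO2 decline late in inspiration, the tracked inspired value uses only
#' the early inspiration window (first half); for the admixture system it
#' is the mean over the whole trimmed inspiration.
#'
#' @param trace Analyzer trace data frame (see [detect_breath_phases()]).
#' @param phases Data frame of breath phases.
#' @param system `"additional"` or `"reservoir"`.
#' @param trim_frac Fraction trimmed from each end of the inspiration
#'   window (default 0.1).
#' @return Data frame with one row per breath: `t_s` (mid-inspiration),
#'   `insp_co2_peak`, `insp_co2_base`, `insp_o2_peak`, `insp_o2_base`,
#'   `insp_co2`, `insp_o2` (tracked values), `et_co2`, `et_o2` (percent).
#' @export
extract_breath_records <- function(trace, phases,
                                   system = c("additional", "reservoir"),
                                   trim_frac = 0.1) {
  system <- match.arg(system)
  .check_trace(trace)
  if (is.null(phases) || nrow(phases) == 0L) {
    return(data.frame(t_s = numeric(0), insp_co2_peak = numeric(0),
                      insp_co2_base = numeric(0), insp_o2_peak = numeric(0),
                      insp_o2_base = numeric(0), insp_co2 = numeric(0),
                      insp_o2 = numeric(0), et_co2 = numeric(0),
                      et_o2 = numeric(0)))
  }
  t <- trace$t_s
  fs <- 1 / stats::median(diff(t))
  k <- max(3L, round(0.15 * fs)); if (k %% 2L == 0L) k <- k + 1L
  co2 <- stats::runmed(trace$fco2_percent, k)
  has_o2 <- !is.null(trace$fo2_percent)
  o2 <- if (has_o2) stats::runmed(trace$fo2_percent, k) else
    rep(NA_real_, length(t))

  out <- matrix(NA_real_, nrow(phases), 9)
  for (b in seq_len(nrow(phases))) {
    ph <- phases[b, ]
    dur_i <- ph$insp_end - ph$insp_start
    trim <- max(trim_frac * dur_i, 1 / fs)
    w0 <- ph$insp_start + trim
    w1 <- ph$insp_end - trim
    wi <- which(t >= w0 & t <= w1)
    if (length(wi) == 0L) wi <- which(t >= ph$insp_start & t <= ph$insp_end)
    early <- wi[t[wi] <= w0 + (w1 - w0) / 2]
    if (length(early) == 0L) early <- wi
    tracked_i <- if (system == "reservoir") early else wi
    we <- which(t >= ph$exp_end - 0.1 & t <= ph$exp_end)
    if (length(we) == 0L) we <- which.min(abs(t - ph$exp_end))
    out[b, ] <- c((ph$insp_start + ph$insp_end) / 2,
                  max(co2[wi]), min(co2[wi]),
                  if (has_o2) max(o2[wi]) else NA_real_,
                  if (has_o2) min(o2[wi]) else NA_real_,
                  mean(co2[tracked_i]),
                  if (has_o2) mean(o2[tracked_i]) else NA_real_,
                  stats::median(co2[we]),
                  if (has_o2) stats::median(o2[we]) else NA_real_)
  }
  stats::setNames(as.data.frame(out),
                  c("t_s", "insp_co2_peak", "insp_co2_base", "insp_o2_peak",
                    "insp_o2_base", "insp_co2", "insp_o2", "et_co2", "et_o2"))
}

#' Align breath records onto a uniform time grid
#'
#' Linearly interpolates one channel of a breath-record table onto a
#' uniform grid. Ventilated-mode records are time shifted by -8 s first,
#' compensating the 3 s analyzer transit delay plus the multiple-breath
#' washout of the ventilator tubing dead space; spontaneous-mode records
#' are not shifted (coarse binning absorbs the 3 s delay).
#'
#' @param records Breath-record data frame from
#'   [extract_breath_records()].
#' @param mode `"ventilated"` or `"spontaneous"`.
#' @param channel Column to resample (default `"insp_co2"`).
#' @param grid_dt Grid spacing, s (default 1).
#' @param shift_s Ventilated-mode time shift, s (default 8).
#' @return Data frame with columns `t_s`, `value`.
#' @export
align_and_resample <- function(records, mode = c("ventilated", "spontaneous"),
                               channel = "insp_co2", grid_dt = 1,
                               shift_s = 8) {
  mode <- match.arg(mode)
  if (is.null(records) || nrow(records) < 2L) {
    stop("need at least 2 breath records to resample", call. = FALSE)
  }
  if (is.null(records[[channel]])) stop("unknown channel: ", channel,
                                        call. = FALSE)
  tt <- records$t_s - if (mode == "ventilated") shift_s else 0
  grid <- seq(ceiling(min(tt) / grid_dt) * grid_dt,
              floor(max(tt) / grid_dt) * grid_dt, by = grid_dt)
  data.frame(t_s = grid,
             value = stats::approx(tt, records[[channel]], xout = grid)$y)
}

#' Bin and aggregate series across runs
#'
#' Assigns each run's samples to fixed-width time bins, optionally
#' subtracts each run's own initial-window mean first (used for end-tidal
#' channels, removing between-subject baseline variation), and reports the
#' per-bin mean across runs with a seeded nonparametric bootstrap 95 %
#' confidence interval. With several runs the bootstrap resamples runs;
#' with a single run it resamples samples within each bin. Bins with no
#' data are reported as `NA` with `n = 0`, never as zero.
#'
#' By default bins are labeled by their left edge. With the default 5 s
#' bins and a ~3 s sidestream-analyzer transit delay this places the bin
#' label within half a second of the mean stimulus time of the samples in
#' the bin, which is how coarse binning absorbs the sampling delay without
#' an explicit time shift; set `label = "center"` for plain center
#' labeling.
#'
#' @param runs A data frame with columns `t_s`, `value`, or a list of
#'   such data frames (one per run).
#' @param bin_width Bin width, s (default 5).
#' @param baseline_window Initial window for the baseline mean, s
#'   (default 60).
#' @param baseline_subtract Subtract each run's initial-window mean before
#'   aggregating (default `FALSE`).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @param conf Confidence level (default 0.95).
#' @param label Bin labeling: `"left"` edge (default, see above) or
#'   `"center"`.
#' @return Data frame of class `"aggregate_series"` with columns
#'   `bin_t_s` (bin labels), `mean`, `ci_low`, `ci_high`, `n`.
#' @export
bin_and_aggregate <- function(runs, bin_width = 5, baseline_window = 60,
                              baseline_subtract = FALSE, n_boot = 1000,
                              seed = 1, conf = 0.95,
                              label = c("left", "center")) {
  label <- match.arg(label)
  if (is.data.frame(runs)) runs <- list(runs)
  if (length(runs) < 1L) stop("need at least one run", call. = FALSE)
  for (r in runs) {
    if (is.null(r$t_s) || is.null(r$value)) {
      stop("each run needs columns t_s and value", call. = FALSE)
    }
  }
  if (baseline_subtract) {
    runs <- lapply(runs, function(r) {
      base <- mean(r$value[r$t_s < baseline_window], na.rm = TRUE)
      if (!is.finite(base)) base <- 0
      r$value <- r$value - base
      r
    })
  }
  tmax <- max(vapply(runs, function(r) max(r$t_s), numeric(1)))
  nbin <- floor(tmax / bin_width) + 1L
  centers <- (seq_len(nbin) - if (label == "center") 0.5 else 1) * bin_width
  # per-run per-bin means
  m <- matrix(NA_real_, length(runs), nbin)
  per_bin_samples <- vector("list", nbin)
  for (ri in seq_along(runs)) {
    r <- runs[[ri]]
    bi <- floor(r$t_s / bin_width) + 1L
    ok <- bi >= 1L & bi <= nbin & is.finite(r$value)
    mm <- tapply(r$value[ok], bi[ok], mean)
    m[ri, as.integer(names(mm))] <- mm
    if (length(runs) == 1L) {
      for (b in unique(bi[ok])) {
        per_bin_samples[[b]] <- r$value[ok & bi == b]
      }
    }
  }
  n_per_bin <- colSums(!is.na(m))
  mean_b <- ifelse(n_per_bin > 0, colMeans(m, na.rm = TRUE), NA_real_)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  alpha <- (1 - conf) / 2
  ci_low <- rep(NA_real_, nbin)
  ci_high <- rep(NA_real_, nbin)
  if (length(runs) > 1L) {
    boot <- matrix(NA_real_, n_boot, nbin)
    for (bb in seq_len(n_boot)) {
      sel <- sample.int(length(runs), replace = TRUE)
      boot[bb, ] <- colMeans(m[sel, , drop = FALSE], na.rm = TRUE)
    }
    for (b in which(n_per_bin > 0)) {
      q <- stats::quantile(boot[, b], c(alpha, 1 - alpha), na.rm = TRUE,
                           names = FALSE)
      ci_low[b] <- q[1]; ci_high[b] <- q[2]
    }
  } else {
    for (b in which(n_per_bin > 0)) {
      v <- per_bin_samples[[b]]
      if (is.null(v) || length(v) == 0L) next
      bm <- vapply(seq_len(n_boot), function(i)
        mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
      q <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
      ci_low[b] <- q[1]; ci_high[b] <- q[2]
    }
  }
  structure(data.frame(bin_t_s = centers, mean = mean_b, ci_low = ci_low,
                       ci_high = ci_high, n = n_per_bin),
            class = c("aggregate_series", "data.frame"))
}

#' Convert a volume percentage to partial pressure
#'
#' `P = (percent / 100) * (p_atm - p_h2o)`, with defaults of 760 mmHg
#' atmospheric pressure and 47 mmHg water vapor pressure at body
#' temperature, as used when reporting end-tidal values.
#'
#' @param fraction_percent Volume percent in `[0, 100]`.
#' @param p_atm Atmospheric pressure, mmHg.
#' @param p_h2o Water vapor partial pressure, mmHg.
#' @return Partial pressure, mmHg.
#' @examples
#' to_partial_pressure(5) # 35.65
#' @export
to_partial_pressure <- function(fraction_percent, p_atm = 760, p_h2o = 47) {
  if (any(fraction_percent < 0 | fraction_percent > 100)) {
    stop("fraction_percent must lie in [0, 100]", call. = FALSE)
  }
  fraction_percent / 100 * (p_atm - p_h2o)
}
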