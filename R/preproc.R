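#' Uniformly sampled pupil time series
#'
#' Container for a continuous pupil-diameter recording: sample times,
#' diameter, sampling rate, and a run identifier per sample. Sampling
#' must be uniform within a run.
#'
#' @param time Sample times in seconds.
#' @param diameter Pupil diameter (arbitrary units before normalisation,
#'   z-units after).
#' @param fs Sampling rate in Hz.
#' @param run Integer run id per sample (recycled if scalar).
#' @return An object of class `pupil_ts` (a data frame with attribute
#'   `fs`).
#' @export
pupil_ts <- function(time, diameter, fs, run = 1L) {
  stopifnot(length(time) == length(diameter))
  if (length(run) == 1L) run <- rep(as.integer(run), length(time))
  if (is.unsorted(time)) stop("sample times must be non-decreasing")
  for (r in unique(run)) {
    dt <- diff(time[run == r])
    if (length(dt) && (max(dt) - min(dt)) > 1e-6)
      stop("sampling must be uniform within run ", r)
  }
  structure(data.frame(time = time, diameter = diameter, run = run),
            fs = fs, class = c("pupil_ts", "data.frame"))
}

#' @exportS3Method base::print
print.pupil_ts <- function(x, ...) {
  cat(sprintf("pupil_ts: %d samples at %g Hz, %d run(s), %.1f s\n",
              nrow(x), attr(x, "fs"), length(unique(x$run)),
              nrow(x) / attr(x, "fs")))
  invisible(x)
}

## rebuild a pupil_ts with new columns, preserving fs
.pts <- function(template, time, diameter, run)
  pupil_ts(time, diameter, attr(template, "fs"), run)

#' Linear interpolation across blink gaps
#'
#' Replaces all samples from `margin` seconds before each blink start to
#' `margin` seconds after its end with a straight line between the
#' flanking clean samples. Blinks spanning a run boundary are handled
#' within each run separately.
#'
#' @param ts A [pupil_ts()].
#' @param blinks Data frame with `start` and `end` columns (seconds).
#' @param margin Interpolation margin in seconds (default 0.2).
#' @return A `pupil_ts` with no missing values.
#' @export
interpolate_blinks <- function(ts, blinks, margin = 0.2) {
  if (is.null(blinks) || nrow(blinks) == 0) return(ts)
  stopifnot(all(c("start", "end") %in% names(blinks)),
            all(blinks$end >= blinks$start))
  d <- ts$diameter
  bad <- is.na(d)
  for (i in seq_len(nrow(blinks)))
    bad <- bad | (ts$time >= blinks$start[i] - margin &
                  ts$time <= blinks$end[i] + margin)
  for (r in unique(ts$run)) {
    in_run <- ts$run == r
    good <- in_run & !bad
    if (!any(good)) stop("run ", r, " has no clean samples to interpolate from")
    fill <- in_run & bad
    if (any(fill)) {
      d[fill] <- stats::approx(ts$time[good], d[good], xout = ts$time[fill],
                               rule = 2)$y
    }
  }
  .pts(ts, ts$time, d, ts$run)
}

#' Detect unlabeled blink artifacts from the signal's rate of change
#'
#' Flags samples where the absolute first difference exceeds `k` robust
#' standard deviations (median absolute deviation) of the per-run first
#' difference, and merges flagged samples closer than `gap` seconds into
#' intervals. Intended to catch blinks the tracker's own detection
#' missed; feed the result back into [interpolate_blinks()].
#'
#' @param ts A [pupil_ts()] whose labeled blinks are already
#'   interpolated.
#' @param k Threshold in robust SD units (default 6).
#' @param gap Merge distance in seconds (default 0.1).
#' @return Data frame with `start`, `end` columns (possibly 0 rows).
#' @export
detect_residual_blinks <- function(ts, k = 6, gap = 0.1) {
  out <- list()
  for (r in unique(ts$run)) {
    d <- ts$diameter[ts$run == r]
    tt <- ts$time[ts$run == r]
    dd <- diff(d)
    s <- stats::mad(dd)
    if (s == 0) next
    hit <- which(abs(dd) > k * s)
    if (length(hit) == 0) next
    t_hit <- tt[hit]          # time of the sample before the jump
    brk <- c(0, which(diff(t_hit) > gap), length(t_hit))
    for (j in seq_len(length(brk) - 1)) {
      seg <- t_hit[(brk[j] + 1):brk[j + 1]]
      out[[length(out) + 1]] <- data.frame(start = min(seg),
                                           end = max(seg) + 1 / attr(ts, "fs"))
    }
  }
  if (length(out) == 0) data.frame(start = numeric(0), end = numeric(0))
  else do.call(rbind, out)
}

#' Band-pass filter the pupil signal
#'
#' Third-order Butterworth band-pass (0.05-4 Hz by default) applied
#' forward and backward per run, so the output has zero phase shift.
#' Zero phase matters because the deconvolution stage interprets
#' pre-event time.
#'
#' @param ts A [pupil_ts()] with no missing values.
#' @param low,high Band edges in Hz.
#' @param order Butterworth prototype order (default 3).
#' @return Filtered `pupil_ts` with per-run mean ~ 0.
#' @export
pupil_bandpass <- function(ts, low = 0.05, high = 4, order = 3) {
  fs <- attr(ts, "fs")
  if (fs <= 2 * high) stop("sampling rate must exceed twice the upper band edge")
  if (anyNA(ts$diameter)) stop("interpolate blinks before filtering")
  sos <- butter_sos(order, c(low, high), fs, "band")
  padlen <- round(2 * fs / low)
  d <- ts$diameter
  for (r in unique(ts$run)) {
    i <- ts$run == r
    if (sum(i) < fs / low / 4)
      warning("run ", r, " is short relative to the high-pass period; ",
              "edge effects may dominate")
    # demean first: the band rejects DC anyway, and a DC step at the
    # padded edges would otherwise leak a long high-pass transient
    d[i] <- sos_filtfilt(sos, d[i] - mean(d[i]), padlen = padlen)
  }
  .pts(ts, ts$time, d, ts$run)
}

#' Standardise per run and resample
#'
#' Z-scores the signal within each run and decimates to `target_fs` with
#' an anti-aliasing low-pass (third-order Butterworth at 0.4 times the
#' target rate) applied zero-phase before subsampling. The input rate
#' must be an integer multiple of the target rate.
#'
#' @param ts A filtered [pupil_ts()].
#' @param target_fs Output sampling rate in Hz (default 20).
#' @return A `pupil_ts` at `target_fs`.
#' @export
zscore_resample <- function(ts, target_fs = 20) {
  fs <- attr(ts, "fs")
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop("input rate must be an integer multiple of target_fs")
  factor <- as.integer(round(factor))
  d <- ts$diameter
  runs <- unique(ts$run)
  run_stats <- data.frame(run = runs, mean = NA_real_, sd = NA_real_)
  for (r in runs) {
    i <- ts$run == r
    s <- stats::sd(d[i])
    if (s == 0) stop("run ", r, " has zero variance")
    run_stats[run_stats$run == r, c("mean", "sd")] <- c(mean(d[i]), s)
    d[i] <- (d[i] - mean(d[i])) / s
  }
  if (factor == 1L) {
    out <- .pts(ts, ts$time, d, ts$run)
    attr(out, "run_stats") <- run_stats
    return(out)
  }
  sos <- butter_sos(3, 0.4 * target_fs, fs, "low")
  keep <- logical(length(d))
  for (r in unique(ts$run)) {
    i <- which(ts$run == r)
    d[i] <- sos_filtfilt(sos, d[i], padlen = min(length(i) - 1L, 3L * factor * 10L))
    keep[i[seq(1, length(i), by = factor)]] <- TRUE
  }
  out <- pupil_ts(ts$time[keep], d[keep], target_fs, ts$run[keep])
  attr(out, "run_stats") <- run_stats
  out
}

#' Canonical pupil impulse response function
#'
#' The standard single-gamma ("Erlang") pupil IRF,
#' `h(t) = (t / t_max)^w * exp(w * (1 - t / t_max))`, normalised to unit
#' peak at `t_max`; zero for `t < 0`.
#'
#' @param t Time in seconds (vectorised).
#' @param w Shape parameter (default 10.1).
#' @param t_max Time-to-peak in seconds (default 0.93).
#' @return IRF values, unit peak.
#' @export
pupil_irf <- function(t, w = 10.1, t_max = 0.93) {
  h <- numeric(length(t))
  pos <- t > 0
  h[pos] <- (t[pos] / t_max)^w * exp(w * (1 - t[pos] / t_max))
  h
}

## convolve a set of event impulses with a kernel on the ts grid, per run
.event_regressor <- function(ts, event_times, kernel) {
  fs <- attr(ts, "fs")
  out <- numeric(nrow(ts))
  for (r in unique(ts$run)) {
    i <- which(ts$run == r)
    t0 <- ts$time[i[1]]
    ev <- event_times[event_times >= ts$time[i[1]] - 1e-9 &
                      event_times <= ts$time[i[length(i)]] + 1e-9]
    if (length(ev) == 0) next
    stick <- numeric(length(i))
    idx <- round((ev - t0) * fs) + 1L
    idx <- idx[idx >= 1 & idx <= length(i)]
    for (j in idx) stick[j] <- stick[j] + 1
    conv <- .fft_convolve(stick, kernel)[seq_along(i)]
    out[i] <- conv
  }
  out
}

#' Regress out blink and saccade pupil responses
#'
#' Builds two nuisance regressors by convolving blink-end and
#' saccade-onset impulses with the canonical pupil IRF, fits them to the
#' signal by ordinary least squares (with intercept), and returns the
#' residuals. With no events the signal is returned unchanged.
#'
#' @param ts Preprocessed [pupil_ts()] (typically at 20 Hz).
#' @param blink_times Blink-end times in seconds.
#' @param saccade_times Saccade-onset times in seconds.
#' @param irf_w,irf_t_max IRF parameters passed to [pupil_irf()].
#' @param kernel_dur Kernel duration in seconds (default 4).
#' @return A `pupil_ts` of residuals, with the fitted nuisance
#'   coefficients attached as attribute `"nuisance_betas"`.
#' @export
remove_nuisance <- function(ts, blink_times = numeric(0),
                            saccade_times = numeric(0),
                            irf_w = 10.1, irf_t_max = 0.93,
                            kernel_dur = 4) {
  fs <- attr(ts, "fs")
  kernel <- pupil_irf(seq(0, kernel_dur, by = 1 / fs), irf_w, irf_t_max)
  cols <- list()
  if (length(blink_times) > 0)
    cols$blink <- .event_regressor(ts, blink_times, kernel)
  if (length(saccade_times) > 0)
    cols$saccade <- .event_regressor(ts, saccade_times, kernel)
  if (length(cols) == 0) {
    attr(ts, "nuisance_betas") <- numeric(0)
    return(ts)
  }
  X <- cbind(intercept = 1, do.call(cbind, cols))
  fit <- stats::lm.fit(X, ts$diameter)
  res <- .pts(ts, ts$time, ts$diameter - X[, -1, drop = FALSE] %*%
                fit$coefficients[-1], ts$run)
  attr(res, "nuisance_betas") <- fit$coefficients[-1]
  attr(res, "run_stats") <- attr(ts, "run_stats")
  res
}

#' Reject trials on saccades and response times
#'
#' Drops a trial when any saccade during its decision interval (options
#' onset to choice) exceeds `threshold` degrees of visual angle, or when
#' its RT falls outside `[rt_floor, rt_deadline]`.
#'
#' @param trials Completed trial data frame.
#' @param saccades Data frame with `time` and `amplitude` columns, or
#'   `NULL`.
#' @param threshold Saccade amplitude threshold in degrees (default 3.3).
#' @param rt_floor,rt_deadline RT bounds in seconds.
#' @return List with `kept` (the surviving trials), `rejected` (row
#'   indices into `trials`), and `fraction_rejected`.
#' @export
reject_trials <- function(trials, saccades = NULL, threshold = 3.3,
                          rt_floor = 0.15, rt_deadline = 3.5) {
  bad_rt <- !is.na(trials$rt) & (trials$rt < rt_floor | trials$rt > rt_deadline)
  bad_sac <- rep(FALSE, nrow(trials))
  if (!is.null(saccades) && nrow(saccades) > 0) {
    big <- saccades[saccades$amplitude > threshold, , drop = FALSE]
    if (nrow(big) > 0) {
      for (i in seq_len(nrow(trials))) {
        bad_sac[i] <- any(big$time >= trials$t_options_on[i] &
                          big$time <= trials$t_choice[i])
      }
    }
  }
  drop <- which(bad_rt | bad_sac)
  list(kept = if (length(drop)) trials[-drop, ] else trials,
       rejected = drop,
       fraction_rejected = length(drop) / nrow(trials))
}
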