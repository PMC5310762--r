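## Spike-train extraction and oscillation metrics for model trajectories
## and fluorescence-like traces.

#' Detect spikes in a sampled signal
#'
#' Finds local maxima that rise at least `min_prominence` above a running
#' local baseline (10th percentile of the signal in a window around the
#' peak) and are separated by at least `min_separation`; when two candidates
#' are closer, the higher one wins. Peak times are refined by quadratic
#' interpolation through the sampled maximum and its two neighbours, giving
#' sub-sample timing accuracy on smooth peaks.
#'
#' @param time sample times, strictly increasing (any unit; all outputs are
#'   in the same unit).
#' @param signal sampled values, same length as `time`.
#' @param min_prominence minimum peak height above the local baseline.
#' @param min_separation minimum spacing between accepted peaks.
#' @param baseline_halfwidth half-width of the baseline window; default
#'   1.5 times the median candidate-peak spacing (falling back to the full
#'   record when fewer than three candidates exist).
#' @return A data frame of class `"spike_train"` with columns `peak_time`,
#'   `peak_value`, `baseline`. Zero rows is a valid result.
#' @examples
#' t <- seq(0, 300, 0.1)
#' tr <- detect_spikes(t, sin(2 * pi * t / 50), 0.1, 5)
#' diff(tr$peak_time)  # 50, 50, ...
#' @export
detect_spikes <- function(time, signal, min_prominence, min_separation = 0,
                          baseline_halfwidth = NULL) {
  stopifnot(length(time) == length(signal), min_prominence > 0)
  if (length(time) < 3L) return(empty_spike_train())
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  n <- length(signal)
  d <- diff(signal)
  # local maxima; on flat tops, take the first sample of the plateau
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand)) return(empty_spike_train())
  if (is.null(baseline_halfwidth)) {
    baseline_halfwidth <- if (length(cand) >= 3L)
      1.5 * stats::median(diff(time[cand]))
    else diff(range(time))
  }
  baseline <- vapply(cand, function(i) {
    sel <- time >= time[i] - baseline_halfwidth &
      time <= time[i] + baseline_halfwidth
    stats::quantile(signal[sel], 0.1, names = FALSE)
  }, numeric(1))
  keep <- signal[cand] - baseline >= min_prominence
  cand <- cand[keep]
  baseline <- baseline[keep]
  if (!length(cand)) return(empty_spike_train())
  # enforce separation, preferring higher peaks
  ord <- order(signal[cand], decreasing = TRUE)
  accepted <- logical(length(cand))
  for (j in ord) {
    if (!any(accepted & abs(time[cand] - time[cand[j]]) < min_separation))
      accepted[j] <- TRUE
  }
  cand <- cand[accepted]
  baseline <- baseline[accepted]
  o <- order(cand)
  cand <- cand[o]
  baseline <- baseline[o]
  refined <- vapply(cand, function(i) {
    if (i <= 1L || i >= n) return(c(time[i], signal[i]))
    quad_refine(time[(i - 1):(i + 1)], signal[(i - 1):(i + 1)])
  }, numeric(2))
  structure(data.frame(peak_time = refined[1, ], peak_value = refined[2, ],
                       baseline = baseline),
            class = c("spike_train", "data.frame"))
}

empty_spike_train <- function() {
  structure(data.frame(peak_time = numeric(0), peak_value = numeric(0),
                       baseline = numeric(0)),
            class = c("spike_train", "data.frame"))
}

# Vertex of the parabola through three points (t, x); degenerate fits fall
# back to the middle sample.
quad_refine <- function(t, x) {
  A <- cbind(1, t - t[2], (t - t[2])^2)
  cf <- tryCatch(solve(A, x), error = function(e) NULL)
  if (is.null(cf) || cf[3] >= 0) return(c(t[2], x[2]))
  dt <- -cf[2] / (2 * cf[3])
  c(t[2] + dt, cf[1] - cf[2]^2 / (4 * cf[3]))
}

#' Spike train of a trajectory series
#'
#' Convenience wrapper running [detect_spikes()] on one column of a
#' simulated trajectory.
#'
#' @param traj an `"hsy_trajectory"`.
#' @param series column to analyse, e.g. `"C"` or `"P_total"`.
#' @param min_prominence,min_separation,baseline_halfwidth passed on to
#'   [detect_spikes()].
#' @return A `"spike_train"`.
#' @export
trajectory_spikes <- function(traj, series = "C", min_prominence = 0.05,
                              min_separation = 2,
                              baseline_halfwidth = NULL) {
  if (!series %in% names(traj))
    stop("no column '", series, "' in trajectory")
  detect_spikes(traj$time_s, traj[[series]], min_prominence, min_separation,
                baseline_halfwidth)
}

#' Oscillation metrics over an analysis window
#'
#' Period, frequency, and amplitude estimates from a spike train: the mean
#' period is the mean of successive peak-time differences over the window
#' (optionally restricted to the last `last_n` complete cycles), the
#' frequency its reciprocal, and the amplitude the mean peak height above
#' the local baseline.
#'
#' @param train a `"spike_train"`.
#' @param window numeric length-2 interval; default the full train.
#' @param last_n if given, use only the last `last_n` complete cycles
#'   (i.e. the last `last_n + 1` peaks) inside the window.
#' @return A list of class `"oscillation_metrics"`: `mean_period`,
#'   `frequency`, `mean_amplitude`, `n_spikes`, `window`.
#' @examples
#' tr <- structure(data.frame(peak_time = c(0, 62, 124, 186),
#'                            peak_value = 1, baseline = 0),
#'                 class = c("spike_train", "data.frame"))
#' oscillation_metrics(tr)$mean_period  # 62
#' @export
oscillation_metrics <- function(train, window = NULL, last_n = NULL) {
  if (is.null(window))
    window <- if (nrow(train)) range(train$peak_time) else c(0, 0)
  sel <- train$peak_time >= window[1] & train$peak_time <= window[2]
  tr <- train[sel, , drop = FALSE]
  if (!is.null(last_n) && nrow(tr) > last_n + 1L)
    tr <- tr[(nrow(tr) - last_n):nrow(tr), , drop = FALSE]
  if (nrow(tr) < 3L)
    stop("insufficient peaks: need >= 3 in window for period estimation, ",
         "found ", nrow(tr))
  mp <- mean(diff(tr$peak_time))
  structure(list(mean_period = mp, frequency = 1 / mp,
                 mean_amplitude = mean(tr$peak_value - tr$baseline),
                 n_spikes = nrow(tr), window = window),
            class = "oscillation_metrics")
}

#' Mean calcium-to-IP3 peak delay
#'
#' Matches each calcium peak to the nearest subsequent IP3 peak within half
#' a period (delays, fractions of a second, are far smaller than periods of
#' tens of seconds, so the pairing is unambiguous) and returns the mean of
#' the matched time differences. Positive values mean calcium leads.
#'
#' @param ca_train,ip3_train `"spike_train"` objects for the calcium and
#'   IP3 series of the same run.
#' @param max_lag matching horizon; default half the mean calcium period.
#' @return Mean delay (same time unit as the trains).
#' @export
peak_delay <- function(ca_train, ip3_train, max_lag = NULL) {
  if (nrow(ca_train) < 2L || nrow(ip3_train) < 1L)
    stop("pairing failure: need at least two calcium peaks and one IP3 peak")
  if (is.null(max_lag)) max_lag <- 0.5 * mean(diff(ca_train$peak_time))
  delays <- vapply(ca_train$peak_time, function(tc) {
    dt <- ip3_train$peak_time - tc
    dt <- dt[dt >= 0 & dt <= max_lag]
    if (length(dt)) min(dt) else NA_real_
  }, numeric(1))
  matched <- sum(!is.na(delays))
  if (nrow(ca_train) - matched > 1L)
    stop("pairing failure: ", nrow(ca_train) - matched,
         " calcium peaks have no subsequent IP3 peak within ",
         signif(max_lag, 3))
  mean(delays, na.rm = TRUE)
}

#' Percent change in oscillation frequency
#'
#' `100 * (f_after - f_before) / f_before` between two metric sets.
#'
#' @param before,after `"oscillation_metrics"` objects.
#' @return Percent change (positive = faster after).
#' @examples
#' b <- list(frequency = 1 / 62); a <- list(frequency = 1 / 35)
#' frequency_change(b, a)  # +77.1
#' @export
frequency_change <- function(before, after) {
  if (!is.finite(before$frequency) || before$frequency == 0)
    stop("before-frequency is zero or undefined")
  100 * (after$frequency - before$frequency) / before$frequency
}

#' Transient frequency change around an intervention
#'
#' The before/after estimator used for pulse and inhibition protocols:
#' the pre-intervention frequency comes from the last `n_before` interspike
#' intervals ending before `t_star`, the post-intervention frequency from
#' the first `n_after` intervals starting at the first peak after `t_star`.
#' The default single-interval windows measure the instantaneous rate
#' change: the accelerations these interventions cause relax away within
#' two to three spikes, so longer post-windows dilute the effect.
#'
#' @param train a `"spike_train"`.
#' @param t_star intervention time.
#' @param n_before,n_after number of interspike intervals on each side.
#' @return List with `percent_change`, `f_before`, `f_after`,
#'   `period_before`, `period_after`.
#' @export
transient_frequency_change <- function(train, t_star, n_before = 1,
                                       n_after = 1) {
  pre <- train$peak_time[train$peak_time < t_star]
  post <- train$peak_time[train$peak_time >= t_star]
  if (length(pre) < n_before + 1L || length(post) < n_after + 1L)
    stop("insufficient peaks around t_star = ", t_star)
  pre <- utils::tail(pre, n_before + 1L)
  post <- post[seq_len(n_after + 1L)]
  p_before <- mean(diff(pre))
  p_after <- mean(diff(post))
  list(percent_change = 100 * (1 / p_after - 1 / p_before) / (1 / p_before),
       f_before = 1 / p_before, f_after = 1 / p_after,
       period_before = p_before, period_after = p_after)
}

#' Time at which spiking terminates
#'
#' The time of the last detected peak, provided no further peak occurs in
#' the following `horizon`; `NA` if the train is empty or spiking is still
#' ongoing near the end of the record (last peak closer than `horizon` to
#' `t_end`).
#'
#' @param train a `"spike_train"`.
#' @param t_end end time of the record the train came from.
#' @param horizon quiet time required after the last peak.
#' @return Termination time, or `NA` if absent.
#' @export
termination_time <- function(train, t_end, horizon = 300) {
  if (!nrow(train)) return(NA_real_)
  last <- max(train$peak_time)
  if (t_end - last < horizon) return(NA_real_)
  last
}

#' Classify a trajectory window as oscillatory
#'
#' A run is called oscillatory when the analysis window contains at least
#' `min_spikes` spikes with amplitude `min_prominence` or more above the
#' running baseline. The threshold sits far below the model's typical spike
#' amplitudes (of order 1 uM), so the call is insensitive to its exact
#' value.
#'
#' @param traj an `"hsy_trajectory"` (or data frame with `time_s` and the
#'   chosen series).
#' @param window length-2 analysis interval (s); default the final third of
#'   the record.
#' @param series column to analyse.
#' @param min_prominence amplitude threshold (uM).
#' @param min_spikes required spike count.
#' @return Logical.
#' @export
is_oscillatory <- function(traj, window = NULL, series = "C",
                           min_prominence = 0.05, min_spikes = 3) {
  if (is.null(window)) {
    tmax <- max(traj$time_s)
    window <- c(2 / 3 * tmax, tmax)
  }
  sel <- traj$time_s >= window[1] & traj$time_s <= window[2]
  tr <- detect_spikes(traj$time_s[sel], traj[[series]][sel],
                      min_prominence = min_prominence, min_separation = 2)
  nrow(tr) >= min_spikes
}

#' Write oscillation metrics as a one-row CSV report
#'
#' @param metrics an `"oscillation_metrics"`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  df <- data.frame(mean_period = metrics$mean_period,
                   frequency = metrics$frequency,
                   mean_amplitude = metrics$mean_amplitude,
                   n_spikes = metrics$n_spikes,
                   window_start = metrics$window[1],
                   window_end = metrics$window[2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.oscillation_metrics <- function(x, ...) {
  cat(sprintf(
    "Oscillation metrics: %d spikes in [%.4g, %.4g]\n  period %.4g, frequency %.4g, amplitude %.4g\n",
    x$n_spikes, x$window[1], x$window[2], x$mean_period, x$frequency,
    x$mean_amplitude))
  invisible(x)
}
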