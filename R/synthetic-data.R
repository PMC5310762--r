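## Generator of fluorescence-like calcium traces with known ground truth,
## laid out like a frame-indexed imaging export (frame number, time in
## minutes, signal, applied condition).

#' Generate a synthetic fluorescence trace
#'
#' Produces a baseline-spike trace with a piecewise-constant period and
#' amplitude schedule: spikes rise instantaneously and decay exponentially
#' (time constant `decay_frac` times the local period), on top of a
#' baseline with optional linear drift and Gaussian noise. Every generated
#' peak time is recorded as ground truth, so recovery by the trace-analysis
#' functions can be checked exactly.
#'
#' @param schedule data frame with columns `start_min` (segment start,
#'   minutes), `period_s` (interspike interval, seconds) and `amplitude`
#'   (spike height, arbitrary units); segments run to the next start or the
#'   end of the record.
#' @param duration_min record length (minutes).
#' @param frame_rate frames per minute.
#' @param baseline baseline fluorescence level.
#' @param noise_sd Gaussian noise standard deviation.
#' @param drift baseline drift per minute.
#' @param decay_frac spike decay time constant as a fraction of the local
#'   period.
#' @param conditions optional data frame with `start_min`, `label`; the
#'   applied-condition annotation per frame (piecewise constant). Default:
#'   a single `"baseline"` label.
#' @param seed integer seed; the trace is reproducible from it.
#' @return List with `trace` (a `"trace_table"` data frame: `frame`,
#'   `time_min`, `signal`, `condition`) and `ground_truth` (list with
#'   `peak_time_min`, `peak_time_s`, `schedule`, `noise_sd`, `seed`).
#' @examples
#' g <- generate_trace(data.frame(start_min = 0, period_s = 60,
#'                                amplitude = 1), duration_min = 5, seed = 1)
#' head(g$trace)
#' @export
generate_trace <- function(schedule, duration_min = 20, frame_rate = 60,
                           baseline = 1, noise_sd = 0.02, drift = 0,
                           decay_frac = 0.15, conditions = NULL, seed = 1) {
  stopifnot(is.data.frame(schedule),
            all(c("start_min", "period_s", "amplitude") %in%
                  names(schedule)))
  if (any(schedule$period_s <= 0)) stop("periods must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  schedule <- schedule[order(schedule$start_min), , drop = FALSE]
  seg_end_s <- c(schedule$start_min[-1], duration_min) * 60
  # spike width (a few decay constants) must fit inside the period
  if (any(3 * decay_frac * schedule$period_s >= schedule$period_s))
    stop("infeasible schedule: spike width exceeds the period")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  # lay out peak times: one period after each segment start, then stepping
  # by the local period until the segment ends
  peaks_s <- numeric(0)
  taus <- numeric(0)
  amps <- numeric(0)
  t_next <- schedule$start_min[1] * 60 + schedule$period_s[1]
  seg <- 1L
  while (seg <= nrow(schedule)) {
    if (t_next >= seg_end_s[seg]) {
      seg <- seg + 1L
      if (seg <= nrow(schedule))
        t_next <- max(t_next,
                      schedule$start_min[seg] * 60) # keep phase, new period
      next
    }
    peaks_s <- c(peaks_s, t_next)
    taus <- c(taus, decay_frac * schedule$period_s[seg])
    amps <- c(amps, schedule$amplitude[seg])
    t_next <- t_next + schedule$period_s[seg]
  }

  n_frames <- floor(duration_min * frame_rate) + 1L
  frame <- seq_len(n_frames)
  time_min <- (frame - 1) / frame_rate
  t_s <- time_min * 60
  signal <- baseline + drift * time_min
  for (k in seq_along(peaks_s)) {
    on <- t_s >= peaks_s[k]
    signal[on] <- signal[on] + amps[k] * exp(-(t_s[on] - peaks_s[k]) /
                                               taus[k])
  }
  if (noise_sd > 0) signal <- signal + stats::rnorm(n_frames, 0, noise_sd)

  if (is.null(conditions))
    conditions <- data.frame(start_min = 0, label = "baseline")
  cond <- as.character(
    conditions$label[findInterval(time_min, conditions$start_min)])

  trace <- structure(
    data.frame(frame = frame, time_min = time_min, signal = signal,
               condition = cond, stringsAsFactors = FALSE),
    class = c("trace_table", "data.frame"))
  list(trace = trace,
       ground_truth = list(peak_time_min = peaks_s / 60,
                           peak_time_s = peaks_s,
                           amplitude = amps,
                           schedule = schedule, noise_sd = noise_sd,
                           seed = seed))
}

#' Write / read a synthetic trace table
#'
#' CSV layout mirroring a frame-indexed imaging export: column 1 the frame
#' number, column 2 the time in minutes, column 3 the fluorescence signal,
#' column 4 the applied condition (piecewise-constant text label).
#'
#' @param trace a `"trace_table"` data frame.
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` the
#'   validated `"trace_table"`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(all(c("frame", "time_min", "signal", "condition") %in%
                  names(trace)))
  utils::write.csv(trace[, c("frame", "time_min", "signal", "condition")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Run the trace generator from a JSON configuration
#'
#' Reads a JSON object whose fields are the arguments of
#' [generate_trace()] (`schedule` and `conditions` as arrays of records)
#' and invokes the generator, so synthetic datasets can be described in
#' the same structured-config style as protocols.
#'
#' @param path JSON file path.
#' @return As [generate_trace()].
#' @export
generate_trace_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$schedule)) stop("config must contain a 'schedule' table")
  cfg$schedule <- as.data.frame(cfg$schedule)
  if (!is.null(cfg$conditions)) cfg$conditions <- as.data.frame(cfg$conditions)
  do.call(generate_trace, cfg)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_min", "signal", "condition")
  if (!all(need %in% names(df)))
    stop("malformed trace file: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(df$frame != seq_len(nrow(df)))
  if (length(bad))
    stop("malformed trace file: non-consecutive frame number at row ",
         bad[1])
  if (nrow(df) > 2) {
    dt <- diff(df$time_min)
    bad_t <- which(abs(dt - dt[1]) > 1e-8 * max(1, abs(dt[1])))
    if (length(bad_t))
      stop("malformed trace file: time not affine in frame at row ",
           bad_t[1] + 1)
  }
  structure(df, class = c("trace_table", "data.frame"))
}
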