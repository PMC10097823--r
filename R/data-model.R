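# Core containers: traces, datasets, intervals, spike trains.
#
# Conventions used throughout the package:
#   * time is in seconds from recording start; intervals are half-open
#     [start_s, end_s), which keeps overlap arithmetic (Dice) unambiguous;
#   * Vm is stored in mV; LFP is stored in mV (converted on load when a
#     channel declares uV);
#   * multi-channel operations address channels by label, never by index.

#' Construct a single-channel recording trace
#'
#' A trace is one channel's samples together with its sampling rate and
#' channel metadata: the channel kind (extracellular LFP or intracellular
#' Vm), an optional stereotaxic coordinate triple (AP, ML, DV in mm relative
#' to bregma; the ML coordinate drives lag/phase sign conventions), and an
#' optional behavioural state flag.
#'
#' @param samples numeric vector of samples (mV).
#' @param fs sampling rate in Hz (> 0).
#' @param kind `"LFP"` or `"Vm"`.
#' @param label channel label (unique within a dataset).
#' @param coords optional numeric triple `c(ap, ml, dv)` in mm.
#' @param units unit the samples are expressed in; `"uV"` samples are
#'   converted to mV on construction.
#' @param state optional `"anesthetized"` or `"awake"`.
#' @return object of class `theta_trace`.
#' @export
theta_trace <- function(samples, fs, kind = c("LFP", "Vm"), label = "ch1",
                  coords = NULL, units = c("mV", "uV"), state = NULL) {
  kind <- match.arg(kind)
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  if (!all(is.finite(samples)))
    stop("trace '", label, "': samples must be finite")
  if (units == "uV") samples <- samples / 1000
  if (!is.null(coords)) {
    coords <- as.numeric(coords)
    if (length(coords) != 3L || !all(is.finite(coords)))
      stop("'coords' must be a finite (AP, ML, DV) triple in mm")
    names(coords) <- c("ap", "ml", "dv")
  }
  if (!is.null(state)) state <- match.arg(state, c("anesthetized", "awake"))
  structure(
    list(samples = samples, fs = fs, kind = kind, label = label,
         coords = coords, state = state),
    class = "theta_trace")
}

#' @export
print.theta_trace <- function(x, ...) {
  cat(sprintf("<theta_trace> %s [%s] %.1f s @ %g Hz\n",
              x$label, x$kind, length(x$samples) / x$fs, x$fs))
  if (!is.null(x$coords))
    cat(sprintf("  coords AP %.2f ML %.2f DV %.2f mm\n",
                x$coords[1], x$coords[2], x$coords[3]))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param x a `theta_trace`.
#' @return seconds of recording.
#' @export
trace_duration <- function(x) length(x$samples) / x$fs

#' Construct a spike train
#'
#' @param times_s strictly increasing spike times in seconds.
#' @param phases_deg optional per-spike theta phase in degrees, in
#'   \[-180, 180); the convention is 0 deg = theta_Vm peak.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times_s, phases_deg = NULL) {
  times_s <- as.numeric(times_s)
  if (length(times_s) > 1L && any(diff(times_s) <= 0))
    stop("spike times must be strictly increasing")
  if (!is.null(phases_deg)) {
    phases_deg <- as.numeric(phases_deg)
    if (length(phases_deg) != length(times_s))
      stop("'phases_deg' must match 'times_s' in length")
    phases_deg <- wrap_deg(phases_deg)
  }
  structure(list(times_s = times_s, phases_deg = phases_deg),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes%s\n", length(x$times_s),
              if (!is.null(x$phases_deg)) " (phases assigned)" else ""))
  invisible(x)
}

#' Bundle simultaneously recorded traces into a dataset
#'
#' All traces share a common time origin and must cover the same time span.
#'
#' @param traces list of `theta_trace` objects with unique labels.
#' @param spikes optional named list of `spike_train`s; names are the labels
#'   of the Vm channels the spikes belong to.
#' @param meta free-form named list of metadata.
#' @return object of class `theta_dataset` with elements `traces` (named
#'   list), `spikes`, `duration_s`, `meta`.
#' @export
theta_dataset <- function(traces, spikes = NULL, meta = list()) {
  if (inherits(traces, "theta_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  labels <- vapply(traces, function(tr) tr$label, character(1))
  if (anyDuplicated(labels)) stop("trace labels must be unique")
  names(traces) <- labels
  durs <- vapply(traces, trace_duration, numeric(1))
  if (max(durs) - min(durs) > 1 / max(vapply(traces, `[[`, numeric(1), "fs")))
    stop("all traces must cover the same time span")
  if (!is.null(spikes)) {
    stopifnot(is.list(spikes), !is.null(names(spikes)))
    bad <- setdiff(names(spikes), labels)
    if (length(bad))
      stop("spike trains reference unknown channels: ",
           paste(bad, collapse = ", "))
  }
  structure(list(traces = traces, spikes = spikes,
                 duration_s = min(durs), meta = meta),
            class = "theta_dataset")
}

#' @export
print.theta_dataset <- function(x, ...) {
  cat(sprintf("<theta_dataset> %d channel(s), %.1f s\n",
              length(x$traces), x$duration_s))
  for (tr in x$traces)
    cat(sprintf("  %-8s %-3s %g Hz\n", tr$label, tr$kind, tr$fs))
  if (!is.null(x$spikes))
    cat(sprintf("  spikes: %s\n", paste(names(x$spikes), collapse = ", ")))
  invisible(x)
}

#' Half-open time intervals
#'
#' @param start_s,end_s numeric vectors of interval edges in seconds with
#'   `start_s < end_s` elementwise.
#' @return data.frame of class `intervals` with columns `start_s`, `end_s`.
#' @export
intervals <- function(start_s = numeric(0), end_s = numeric(0)) {
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  stopifnot(length(start_s) == length(end_s))
  if (any(end_s <= start_s)) stop("intervals need start_s < end_s")
  out <- data.frame(start_s = start_s, end_s = end_s)
  class(out) <- c("intervals", "data.frame")
  out
}

interval_lengths <- function(iv) iv$end_s - iv$start_s

# Intersection of two half-open interval sets (both assumed sorted,
# non-overlapping). Returns an `intervals` data.frame.
interval_intersect <- function(a, b) {
  res_s <- numeric(0); res_e <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a$start_s[i], b$start_s[j])
    hi <- min(a$end_s[i], b$end_s[j])
    if (hi > lo) { res_s <- c(res_s, lo); res_e <- c(res_e, hi) }
    if (a$end_s[i] < b$end_s[j]) i <- i + 1L else j <- j + 1L
  }
  intervals(res_s, res_e)
}

# Total measure of an interval set.
interval_measure <- function(iv) sum(interval_lengths(iv))

#' Cut a series into fixed-width analysis windows
#'
#' Windows are half-open `[t, t + window_s)` starting at exact multiples of
#' `step_s`; the last partial window is dropped. This is the segmentation
#' used for the 1-s power segments and the prediction windows.
#'
#' @param x numeric vector.
#' @param fs sampling rate of `x` in Hz.
#' @param window_s window length in seconds; `window_s * fs` must be whole.
#' @param step_s step between window starts in seconds (> 0).
#' @return list with `intervals` (data.frame) and `segments` (list of
#'   numeric vectors); empty when the series is shorter than one window.
#' @export
segment_series <- function(x, fs, window_s = 1, step_s = window_s) {
  stopifnot(step_s > 0)
  nwin <- window_s * fs
  if (abs(nwin - round(nwin)) > 1e-8)
    stop("'window_s' must correspond to a whole number of samples")
  nwin <- as.integer(round(nwin))
  n <- length(x)
  dur <- n / fs
  if (nwin > n)
    return(list(intervals = intervals(), segments = list()))
  nseg <- floor((dur - window_s) / step_s + 1e-9) + 1
  starts <- (seq_len(nseg) - 1) * step_s
  i0 <- round(starts * fs) + 1
  keep <- i0 + nwin - 1 <= n
  i0 <- i0[keep]; starts <- starts[keep]
  segs <- lapply(i0, function(i) x[i:(i + nwin - 1L)])
  list(intervals = intervals(starts, starts + window_s), segments = segs)
}

#' Anti-aliased downsampling of a trace
#'
#' Applies a zero-phase low-pass (Butterworth order 8, cutoff
#' `0.4 * target_fs`, forward-backward) and then keeps every
#' `fs / target_fs`-th sample. Only integer decimation factors are
#' supported (the native 20 kHz to the 500 Hz analysis rate is factor 40).
#'
#' @param tr a `theta_trace`.
#' @param target_fs requested output rate in Hz; must divide `tr$fs`.
#' @return a `theta_trace` at `target_fs`.
#' @export
downsample_trace <- function(tr, target_fs) {
  stopifnot(inherits(tr, "theta_trace"))
  if (target_fs > tr$fs) stop("'target_fs' must not exceed the trace rate")
  if (target_fs == tr$fs) return(tr)
  fac <- tr$fs / target_fs
  if (abs(fac - round(fac)) > 1e-8)
    stop("fs / target_fs must be an integer decimation factor")
  fac <- as.integer(round(fac))
  bf <- signal::butter(8, 0.4 * target_fs / (tr$fs / 2), type = "low")
  y <- signal::filtfilt(bf, tr$samples)
  out <- tr
  out$samples <- y[seq(1L, length(y), by = fac)]
  out$fs <- target_fs
  out
}

#' Write a theta-period table to CSV
#'
#' @param periods data.frame with columns `label`, `start_s`, `end_s`,
#'   `peak_freq_hz`, `mean_power` (as returned by [detect_theta_periods()]
#'   after adding a `label` column, or [periods_table()]).
#' @param path output file.
#' @export
write_periods_csv <- function(periods, path) {
  cols <- c("label", "start_s", "end_s", "peak_freq_hz", "mean_power")
  missing_cols <- setdiff(cols, names(periods))
  if (length(missing_cols))
    stop("periods table lacks columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(periods[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a theta-period table written by [write_periods_csv()]
#' @param path CSV file.
#' @return data.frame of periods.
#' @export
read_periods_csv <- function(path) utils::read.csv(path)

#' Stack per-channel period lists into one table
#' @param periods_by_channel named list of `theta_periods` data.frames.
#' @return single data.frame with a `label` column.
#' @export
periods_table <- function(periods_by_channel) {
  rows <- lapply(names(periods_by_channel), function(lb) {
    p <- periods_by_channel[[lb]]
    if (!nrow(p)) return(NULL)
    cbind(label = lb, as.data.frame(p))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = character(0), start_s = numeric(0),
                      end_s = numeric(0), peak_freq_hz = numeric(0),
                      mean_power = numeric(0))
  rownames(out) <- NULL
  out
}

# Wrap degrees into [-180, 180).
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == 180] <- -180
  y
}
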