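#' Zero-phase low-pass filter a calcium dF/F trace
#'
#' 4th-order Butterworth design applied forward and backward
#' (zero phase lag); length is preserved.
#'
#' @param trace a [calcium_trace()].
#' @param cutoff cutoff frequency in Hz (default 0.5 Hz).
#' @return the filtered [calcium_trace()] (raw F reconstructed from F0).
#' @export
lowpass <- function(trace, cutoff = 0.5) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (cutoff >= trace$fs / 2) stop("cutoff must be below Nyquist")
  bf <- signal::butter(4, cutoff / (trace$fs / 2), type = "low")
  # demean before filtering (zero initial conditions) and restore after,
  # so the DC level passes with unit gain and edge transients stay small
  m <- mean(trace$dff)
  dff <- as.numeric(signal::filtfilt(bf, trace$dff - m)) + m
  calcium_trace(dff, fs = trace$fs, f0 = trace$f0, id = trace$id)
}

#' Detect calcium events by MAD thresholding
#'
#' An event is registered at each upward crossing of
#' `threshold = median(dff) + mad_mult * MAD(dff)` (MAD scaled by 1.4826
#' for Gaussian consistency). After a detection, no new event is accepted
#' until the trace has decayed back below threshold and a refractory span
#' of `tau_off` seconds has elapsed since that return. The trace is
#' expected to be low-pass filtered first (see [lowpass()]).
#'
#' @param trace a [calcium_trace()].
#' @param mad_mult threshold multiplier (default 3).
#' @param tau_off refractory/decay span in seconds (default 0.2 s).
#' @return object of class `calcium_events`: list with `times` (s),
#'   `peaks` (per-event maximum dF/F before the trace returns below
#'   threshold), `threshold`, `params`, `trace_id`.
#' @export
detect_events <- function(trace, mad_mult = 3, tau_off = 0.2) {
  stopifnot(inherits(trace, "calcium_trace"))
  x <- trace$dff
  fs <- trace$fs
  m <- stats::median(x)
  madv <- stats::mad(x, constant = 1.4826)
  if (madv == 0) {
    warning("MAD of trace is zero; no events detectable")
    return(structure(list(times = numeric(0), peaks = numeric(0),
                          threshold = NA_real_,
                          params = list(mad_mult = mad_mult,
                                        tau_off = tau_off),
                          trace_id = trace$id),
                     class = "calcium_events"))
  }
  thr <- m + mad_mult * madv
  above <- x > thr
  cross <- which(above & !c(FALSE, above[-length(above)]))
  times <- numeric(0)
  peaks <- numeric(0)
  ready_at <- -Inf   # earliest time the next event may be accepted
  for (i in cross) {
    t_i <- (i - 1) / fs
    if (t_i < ready_at) next
    # end of the supra-threshold excursion started at i
    rel_end <- which(!above[i:length(above)])[1]
    j <- if (is.na(rel_end)) length(x) else i + rel_end - 2L
    times <- c(times, t_i)
    peaks <- c(peaks, max(x[i:j]))
    ready_at <- j / fs + tau_off
  }
  structure(list(times = times, peaks = peaks, threshold = thr,
                 params = list(mad_mult = mad_mult, tau_off = tau_off),
                 trace_id = trace$id),
            class = "calcium_events")
}

#' @export
print.calcium_events <- function(x, ...) {
  cat("Calcium events:", length(x$times), "events (threshold",
      signif(x$threshold, 4), ", mad_mult", x$params$mad_mult, ")\n")
  invisible(x)
}
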