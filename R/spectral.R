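#' Spike-triggered average of an LFP
#'
#' Averages LFP snippets `[t_spike - w/2, t_spike + w/2)` over all
#' eligible spikes. A spike is eligible when its full window lies inside
#' the record and, if a condition mask is given, entirely inside one mask
#' interval (windows crossing a condition boundary are excluded).
#'
#' @param lfp an [lfp_record()].
#' @param spikes numeric spike times (s) or an [event_train()].
#' @param window snippet length in seconds (default 0.2 s, i.e. 100 ms on
#'   each side).
#' @param condition_mask optional data.frame(start, end) of absolute-time
#'   intervals defining the condition (e.g. preCS = the 10 s before each
#'   CS onset, CS = the 10 s stimulus windows).
#' @param condition label stored with the result.
#' @return object of class `sta_result`: list with `sta` (mean snippet,
#'   length `round(window * fs)`), `snippets` (n_spikes x length matrix),
#'   `tau` (snippet time axis, s, centered on the spike), `n_spikes`,
#'   `fs`, `condition`.
#' @export
spike_triggered_average <- function(lfp, spikes, window = 0.2,
                                    condition_mask = NULL,
                                    condition = NA_character_) {
  stopifnot(inherits(lfp, "lfp_record"))
  times <- if (inherits(spikes, "event_train")) spikes$times else
    as.numeric(spikes)
  fs <- lfp$fs
  len <- as.integer(round(window * fs))
  half <- len %/% 2
  n <- length(lfp$samples)
  centers <- round(times * fs) + 1
  ok <- centers - half >= 1 & centers + (len - half - 1) <= n
  if (!is.null(condition_mask)) {
    t_lo <- times - window / 2
    t_hi <- times + window / 2
    in_mask <- vapply(seq_along(times), function(i)
      any(t_lo[i] >= condition_mask$start & t_hi[i] <= condition_mask$end),
      logical(1))
    ok <- ok & in_mask
  }
  centers <- centers[ok]
  if (length(centers) == 0) stop("no eligible spikes for the STA")
  offs <- seq(-half, length.out = len)
  snippets <- matrix(lfp$samples[rep(centers, each = len) +
                                   rep(offs, times = length(centers))],
                     ncol = len, byrow = TRUE)
  structure(list(sta = colMeans(snippets), snippets = snippets,
                 tau = offs / fs, n_spikes = length(centers), fs = fs,
                 window = window, condition = condition,
                 lfp_region = lfp$region),
            class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat("STA over", x$n_spikes, "spikes (", x$window * 1000, "ms window",
      if (!is.na(x$condition)) paste0(", condition ", x$condition) else "",
      ")\n")
  invisible(x)
}

#' Spike-field coherence from an STA and its snippets
#'
#' SFC(f) = power spectrum of the STA divided by the mean of the
#' individual snippet power spectra at the same frequency. Each snippet
#' (and the STA) is Hann-tapered and zero-padded to `nfft` samples before
#' the transform. Perfect phase locking (identical snippets) yields 1 at
#' every frequency with signal power; unlocked spikes yield roughly
#' 1/n_spikes. Frequencies with zero mean snippet power are flagged NaN.
#'
#' @param sta a `sta_result` (carries the snippets).
#' @param nfft FFT length; default the next power of two at or above four
#'   times the snippet length (finer frequency grid than the raw window).
#' @param taper "hann" (default) or "none".
#' @return object of class `sfc_result`: list with `freq` (Hz, in
#'   `(0, fs/2)`), `sfc`, `sta_power` (raw STA spectrum, secondary
#'   output), `mean_power`, `condition`, `n_spikes`, `nfft`, `taper`.
#' @export
spike_field_coherence <- function(sta, nfft = NULL,
                                  taper = c("hann", "none")) {
  stopifnot(inherits(sta, "sta_result"))
  taper <- match.arg(taper)
  len <- length(sta$sta)
  if (nrow(sta$snippets) == 0) stop("no snippets")
  if (is.null(nfft)) nfft <- 2^ceiling(log2(4 * len))
  w <- if (taper == "hann") hann_window(len) else rep(1, len)
  pad <- function(v) c(v * w, numeric(nfft - len))
  pow <- function(v) Mod(stats::fft(pad(v)))^2
  p_sta <- pow(sta$sta)
  p_all <- t(apply(sta$snippets, 1, pow))
  p_mean <- colMeans(p_all)
  keep <- seq(2, nfft %/% 2)   # (0, fs/2) exclusive
  freq <- (keep - 1) * sta$fs / nfft
  sfc <- p_sta[keep] / p_mean[keep]
  # zero (or numerically zero, < 1e-12 of peak) denominator power: the
  # coherence is undefined there and flagged NaN
  zero <- p_mean[keep] <= 1e-12 * max(p_mean)
  sfc[zero] <- NaN
  structure(list(freq = freq, sfc = sfc, sta_power = p_sta[keep],
                 mean_power = p_mean[keep], condition = sta$condition,
                 n_spikes = sta$n_spikes, nfft = nfft, taper = taper,
                 fs = sta$fs),
            class = "sfc_result")
}

#' @export
print.sfc_result <- function(x, ...) {
  pk <- which.max(x$sfc)
  cat("SFC over", x$n_spikes, "spikes: peak", round(x$sfc[pk], 4), "at",
      round(x$freq[pk], 1), "Hz\n")
  invisible(x)
}

#' Compare spike-field coherence between two conditions
#'
#' @param pre,cs `sfc_result`s on identical frequency grids (e.g. preCS
#'   and CS conditions).
#' @return list with `freq`, `difference` (cs - pre), `peak` (data.frame
#'   of peak frequency and SFC per condition).
#' @export
compare_sfc <- function(pre, cs) {
  stopifnot(inherits(pre, "sfc_result"), inherits(cs, "sfc_result"))
  if (length(pre$freq) != length(cs$freq) ||
      max(abs(pre$freq - cs$freq)) > 1e-9)
    stop("frequency grids differ")
  peak <- data.frame(
    condition = c(pre$condition, cs$condition),
    peak_freq = c(pre$freq[which.max(pre$sfc)],
                  cs$freq[which.max(cs$sfc)]),
    peak_sfc = c(max(pre$sfc, na.rm = TRUE), max(cs$sfc, na.rm = TRUE)))
  list(freq = pre$freq, difference = cs$sfc - pre$sfc, peak = peak)
}
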