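#' Bin event trains into a neurons x bins count matrix
#'
#' Bins tile `[t0, t_end)` half-open: an event at an exact bin boundary
#' belongs to the later bin. Events outside the range are dropped and
#' counted in the `dropped` field.
#'
#' @param trains an [event_train()] or a list of them.
#' @param bin_width bin width in seconds (1 s and 0.5 s are the analysis
#'   resolutions).
#' @param t0 start of the first bin (s).
#' @param t_end end of the range (s); the last bin ends at the largest
#'   `t0 + k * bin_width <= t_end`.
#' @return object of class `binned_matrix`: list with `counts`
#'   (neurons x bins integer matrix), `bin_width`, `t0`, `neurons`
#'   (metadata data.frame with neuron_id, region, stage, treatment) and
#'   `dropped` (number of out-of-range events).
#' @export
bin_events <- function(trains, bin_width = 1, t0 = 0, t_end = NULL) {
  if (inherits(trains, "event_train")) trains <- list(trains)
  stopifnot(length(trains) > 0, bin_width > 0)
  if (is.null(t_end)) {
    t_end <- max(vapply(trains, function(tr)
      if (is.finite(tr$session_length)) tr$session_length
      else if (length(tr$times)) max(tr$times) + bin_width else bin_width,
      numeric(1)))
  }
  if (t_end <= t0) stop("t_end must be > t0")
  n_bins <- as.integer(floor((t_end - t0) / bin_width + 1e-9))
  counts <- matrix(0L, nrow = length(trains), ncol = n_bins)
  dropped <- 0L
  for (i in seq_along(trains)) {
    tt <- trains[[i]]$times
    b <- floor((tt - t0) / bin_width) + 1L
    ok <- tt >= t0 & b >= 1L & b <= n_bins
    dropped <- dropped + sum(!ok)
    if (any(ok)) {
      tb <- tabulate(b[ok], nbins = n_bins)
      counts[i, ] <- tb
    }
  }
  if (dropped > 0)
    message(dropped, " events outside [", t0, ", ", t0 + n_bins * bin_width,
            ") dropped")
  meta <- data.frame(
    neuron_id = vapply(trains, function(x) as.integer(x$neuron_id), 1L),
    region = vapply(trains, function(x) as.character(x$region), ""),
    stage = vapply(trains, function(x) as.character(x$stage), ""),
    treatment = vapply(trains, function(x) as.character(x$treatment), ""))
  structure(list(counts = counts, bin_width = bin_width, t0 = t0,
                 neurons = meta, dropped = dropped),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat("Binned matrix:", nrow(x$counts), "neurons x", ncol(x$counts),
      "bins of", x$bin_width, "s;", sum(x$counts), "events\n")
  invisible(x)
}

#' Trial-aligned, z-scored, smoothed peri-event time histograms
#'
#' Extracts the `[-8, 18]` s window around each CS onset from a 500 ms
#' binned matrix, z-scores each neuron against its session-wide (per-stage)
#' mean and SD, smooths along time with a Gaussian kernel, masks shock
#' artifact bins, and replaces bins from blacked-out channels by the
#' population average of the same (trial, bin).
#'
#' @param binned a `binned_matrix` at 0.5 s resolution.
#' @param timeline a [session_timeline()]; CS onsets define the trials.
#' @param smoothing_degree Gaussian kernel SD in bins; either a single value
#'   or `c(IC = 5, CE = 8)` applied by region class (IC = aIC/pIC, CE =
#'   CE_SST/CE_PKCd/CEm).
#' @param shock_mask if TRUE (default), bins overlapping the 1 s window of
#'   each F-type US are masked (NA) in the affected trials; alternatively a
#'   data.frame(start, end) of absolute-time intervals to mask.
#' @param blackout_channels optional data.frame(trial, neuron_row): those
#'   (trial, neuron) rows are replaced by the per-(trial, bin) population
#'   mean over the remaining neurons.
#' @param window PETH window relative to CS onset, seconds.
#' @return object of class `peth`: list with `z` (trials x neurons x
#'   rel-bins array), `mask` (trials x rel-bins logical, TRUE = masked),
#'   `rel_time` (bin start times relative to onset), `trials` (trial
#'   data.frame), `neurons` (metadata).
#' @export
make_peth <- function(binned, timeline, smoothing_degree = c(IC = 5, CE = 8),
                      shock_mask = TRUE, blackout_channels = NULL,
                      window = c(-8, 18)) {
  stopifnot(inherits(binned, "binned_matrix"))
  if (abs(binned$bin_width - 0.5) > 1e-9)
    stop("PETHs are built from 500 ms binned matrices")
  w <- binned$bin_width
  n_rel <- as.integer(round((window[2] - window[1]) / w))
  rel_time <- window[1] + (seq_len(n_rel) - 1) * w

  # z-score per neuron over the whole (per-stage) session
  mu <- rowMeans(binned$counts)
  sd_ <- apply(binned$counts, 1, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- Inf   # zero-variance -> all-zero row
  zmat <- (binned$counts - mu) / sd_

  trials <- timeline$cs_trials
  keep <- trials$onset + window[1] >= binned$t0 &
    trials$onset + window[2] <= binned$t0 + ncol(binned$counts) * w + 1e-9
  if (any(!keep))
    warning(sum(!keep), " trial(s) too close to the session edge skipped")
  trials <- trials[keep, , drop = FALSE]
  n_tr <- nrow(trials)
  n_neu <- nrow(binned$counts)

  z <- array(NA_real_, dim = c(n_tr, n_neu, n_rel))
  mask <- matrix(FALSE, nrow = n_tr, ncol = n_rel)

  mask_iv <- NULL
  if (isTRUE(shock_mask)) {
    us <- timeline$us_events
    us <- us[us$us_type == "F", , drop = FALSE]
    if (nrow(us) > 0) mask_iv <- data.frame(start = us$time,
                                            end = us$time + 1)
  } else if (is.data.frame(shock_mask)) {
    mask_iv <- shock_mask
  }

  for (i in seq_len(n_tr)) {
    b0 <- as.integer(round((trials$onset[i] + window[1] - binned$t0) / w))
    z[i, , ] <- zmat[, b0 + seq_len(n_rel), drop = FALSE]
    if (!is.null(mask_iv)) {
      t_abs <- trials$onset[i] + rel_time
      for (j in seq_len(nrow(mask_iv)))
        mask[i, t_abs + w > mask_iv$start[j] & t_abs < mask_iv$end[j]] <- TRUE
    }
  }
  for (i in seq_len(n_tr)) z[i, , mask[i, ]] <- NA_real_

  # blacked-out channels: replace with the population mean of the same bin
  if (!is.null(blackout_channels) && nrow(blackout_channels) > 0) {
    for (j in seq_len(nrow(blackout_channels))) {
      tr <- blackout_channels$trial[j]
      ne <- blackout_channels$neuron_row[j]
      others <- setdiff(seq_len(n_neu), blackout_channels$neuron_row[
        blackout_channels$trial == tr])
      if (length(others) == 0) next
      z[tr, ne, ] <- apply(z[tr, others, , drop = FALSE], 3, mean,
                           na.rm = TRUE)
      z[tr, ne, mask[tr, ]] <- NA_real_
    }
  }

  # Gaussian smoothing along time, NA-aware (masked bins stay NA and never
  # leak into neighboring bins)
  sdeg <- smoothing_sd_for(binned$neurons$region, smoothing_degree)
  for (ne in seq_len(n_neu)) {
    if (sdeg[ne] <= 0) next
    kern <- gauss_kernel(sdeg[ne])
    for (i in seq_len(n_tr))
      z[i, ne, ] <- smooth_na(z[i, ne, ], kern)
  }

  structure(list(z = z, mask = mask, rel_time = rel_time, trials = trials,
                 neurons = binned$neurons, window = window, bin_width = w,
                 smoothing_degree = smoothing_degree),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  d <- dim(x$z)
  cat("PETH:", d[1], "trials x", d[2], "neurons x", d[3], "bins (",
      x$window[1], "to", x$window[2], "s,", x$bin_width, "s bins);",
      sum(x$mask), "masked (trial,bin) cells\n")
  invisible(x)
}

smoothing_sd_for <- function(regions, smoothing_degree) {
  if (length(smoothing_degree) == 1 && is.null(names(smoothing_degree)))
    return(rep(smoothing_degree, length(regions)))
  cls <- ifelse(regions %in% c("aIC", "pIC"), "IC", "CE")
  out <- unname(smoothing_degree[cls])
  out[is.na(out)] <- smoothing_degree[1]
  out
}

# Gaussian kernel with SD sigma bins, truncated at 4 sigma, normalized
gauss_kernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

# NA-aware convolution: weights renormalized over available samples; NA
# positions remain NA
smooth_na <- function(x, kern) {
  n <- length(x)
  h <- (length(kern) - 1L) / 2L
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  xp <- c(numeric(h), x0, numeric(h))
  okp <- c(numeric(h), as.numeric(ok), numeric(h))
  num <- stats::filter(xp, kern, sides = 2)[(h + 1):(h + n)]
  den <- stats::filter(okp, kern, sides = 2)[(h + 1):(h + n)]
  out <- as.numeric(num) / pmax(as.numeric(den), 1e-12)
  out[!ok] <- NA_real_
  out
}

#' Build a labeled bins x neurons dataset for a decoding task
#'
#' Tasks: `"CS"` — class 0 = the bins immediately before each CS onset,
#' class 1 = the 10 CS bins; `"US"` — class 0 as above, class 1 = the bins
#' after US offset; `"CS3"` — class 0 = pre-CS bins of both CS types,
#' class 1 = R-CS bins, class 2 = F-CS bins. Pre-windows overlapping the
#' previous trial's stimulus windows are truncated (with a message). Rows
#' of `X` are time bins, columns are neurons.
#'
#' @param binned `binned_matrix` at 1 s resolution.
#' @param timeline [session_timeline()].
#' @param task one of "CS", "US", "CS3".
#' @param cs_type which CS type(s) to use for the "CS"/"US" tasks.
#' @param pre_window_bins length of the pre-CS class-0 window (bins).
#' @param post_us_bins length of the post-US class-1 window for the "US"
#'   task (bins).
#' @return object of class `labeled_dataset`: list with `X` (samples x
#'   neurons), `y` (integer classes), `task`, `regions` (per-column region
#'   labels), `bin_index` (session bin of each row), `empty` flag.
#' @export
build_labels <- function(binned, timeline, task = c("CS", "US", "CS3"),
                         cs_type = c("R", "F"), pre_window_bins = 10,
                         post_us_bins = 8) {
  task <- match.arg(task)
  stopifnot(inherits(binned, "binned_matrix"))
  if (abs(binned$bin_width - 1) > 1e-9)
    stop("labeled datasets are built from 1 s binned matrices")
  n_bins <- ncol(binned$counts)
  trials <- timeline$cs_trials
  if (task != "CS3") trials <- trials[trials$cs_type %in% cs_type, ,
                                      drop = FALSE]
  sel_bins <- integer(0)
  sel_y <- integer(0)
  # bins already claimed by a stimulus window of any earlier trial
  claimed <- logical(n_bins)
  all_trials <- timeline$cs_trials
  for (i in seq_len(nrow(all_trials))) {
    cs_b <- bin_range(all_trials$onset[i], all_trials$duration[i],
                      binned$t0, n_bins)
    claimed[cs_b] <- TRUE
  }
  if (nrow(timeline$us_events) > 0) {
    for (i in seq_len(nrow(timeline$us_events))) {
      us_b <- bin_range(timeline$us_events$time[i], 1, binned$t0, n_bins)
      claimed[us_b] <- TRUE
    }
  }
  truncated <- 0L
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset[i]
    cs_b <- bin_range(on, trials$duration[i], binned$t0, n_bins)
    pre_b <- bin_range(on - pre_window_bins, pre_window_bins, binned$t0,
                       n_bins)
    drop_pre <- claimed[pre_b] & !pre_b %in% cs_b
    if (any(drop_pre)) truncated <- truncated + sum(drop_pre)
    pre_b <- pre_b[!drop_pre]
    if (task == "CS") {
      sel_bins <- c(sel_bins, pre_b, cs_b)
      sel_y <- c(sel_y, rep(0L, length(pre_b)), rep(1L, length(cs_b)))
    } else if (task == "US") {
      us <- timeline$us_events
      us_t <- us$time[us$us_type == trials$cs_type[i] &
                        abs(us$time - (on + trials$duration[i])) < 1.5]
      if (length(us_t) == 0) next
      post_b <- bin_range(us_t[1] + 1, post_us_bins, binned$t0, n_bins)
      sel_bins <- c(sel_bins, pre_b, post_b)
      sel_y <- c(sel_y, rep(0L, length(pre_b)), rep(1L, length(post_b)))
    } else {
      cls <- if (trials$cs_type[i] == "R") 1L else 2L
      sel_bins <- c(sel_bins, pre_b, cs_b)
      sel_y <- c(sel_y, rep(0L, length(pre_b)), rep(cls, length(cs_b)))
    }
  }
  if (truncated > 0)
    message(truncated, " pre-window bin(s) truncated (overlap with earlier ",
            "stimulus windows)")
  # a bin must not carry two classes; first assignment wins
  dup <- duplicated(sel_bins)
  sel_bins <- sel_bins[!dup]
  sel_y <- sel_y[!dup]
  X <- t(binned$counts[, sel_bins, drop = FALSE])
  structure(list(X = X, y = sel_y, task = task,
                 regions = binned$neurons$region,
                 neuron_id = binned$neurons$neuron_id,
                 bin_index = sel_bins,
                 empty = length(sel_y) == 0),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset (task ", x$task, "): ", nrow(x$X), " bins x ",
      ncol(x$X), " neurons; classes: ", sep = "")
  print(table(x$y))
  invisible(x)
}

# 1-based indices of the `len`-second window starting at absolute time t
bin_range <- function(t, len, t0, n_bins) {
  b <- (floor(t - t0) + 1L):(floor(t - t0) + as.integer(round(len)))
  b[b >= 1L & b <= n_bins]
}

#' Balance a labeled dataset by random under-sampling
#'
#' Randomly drops samples from the larger classes so every class keeps
#' the minority-class count.
#'
#' @param ds a `labeled_dataset`.
#' @return a balanced `labeled_dataset` (uses the current RNG state).
#' @export
balance_undersample <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  tab <- table(ds$y)
  n_min <- min(tab)
  keep <- unlist(lapply(names(tab), function(cl) {
    idx <- which(ds$y == as.integer(cl))
    sort(idx[sample.int(length(idx), n_min)])
  }))
  keep <- sort(keep)
  ds$X <- ds$X[keep, , drop = FALSE]
  ds$y <- ds$y[keep]
  ds$bin_index <- ds$bin_index[keep]
  ds
}
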