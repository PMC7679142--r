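# Independent oracle implementations used to validate the package's
# estimators. These are deliberately written in the most literal way
# possible (explicit history tables, frame-by-frame loops) and share no
# code with the implementations they check.

# Exhaustive joint-histogram plug-in transfer entropy: builds the full
# (y_next, y_history, x_history) table with string-coded histories and
# sums p * log2(p(y1 | yh, xh) / p(y1 | yh)) cell by cell.
oracle_te <- function(x, y, k) {
  n <- length(x)
  y1 <- character(0); yh <- character(0); xh <- character(0)
  for (t in (k + 1):n) {
    y1 <- c(y1, as.character(y[t]))
    yh <- c(yh, paste(y[(t - k):(t - 1)], collapse = ","))
    xh <- c(xh, paste(x[(t - k):(t - 1)], collapse = ","))
  }
  nt <- length(y1)
  full <- paste(y1, yh, xh, sep = "|")
  te <- 0
  for (cell in unique(full)) {
    idx <- which(full == cell)
    p_cell <- length(idx) / nt
    i <- idx[1]
    p_y1_given_yx <- length(idx) / sum(yh == yh[i] & xh == xh[i])
    p_y1_given_y <- sum(y1 == y1[i] & yh == yh[i]) / sum(yh == yh[i])
    te <- te + p_cell * log2(p_y1_given_yx / p_y1_given_y)
  }
  te
}

# Frame-by-frame freezing scorer: for every window start, compute the
# windowed mean with an explicit loop, then walk the below-threshold
# vector collecting maximal runs.
oracle_freezing <- function(index, fs, threshold, min_dur = 1, window = 1) {
  w <- round(window * fs)
  n <- length(index)
  if (n < w) return(data.frame(onset = numeric(0), duration = numeric(0)))
  below <- logical(n - w + 1)
  for (i in seq_len(n - w + 1)) below[i] <- mean(index[i:(i + w - 1)]) < threshold
  need <- max(1, round((min_dur - window) * fs) + 1)
  onsets <- numeric(0); durations <- numeric(0)
  i <- 1
  while (i <= length(below)) {
    if (below[i]) {
      j <- i
      while (j < length(below) && below[j + 1]) j <- j + 1
      if (j - i + 1 >= need) {
        onsets <- c(onsets, (i - 1) / fs)
        durations <- c(durations, (j - i) / fs + window)
      }
      i <- j + 1
    } else i <- i + 1
  }
  data.frame(onset = onsets, duration = durations)
}

# Interval-membership episode classifier: literal loop over episodes and
# CS trials.
oracle_classify <- function(episodes, cs_trials) {
  out <- character(nrow(episodes))
  for (i in seq_len(nrow(episodes))) {
    want <- if (episodes$kind[i] == "port_visit") "R" else "F"
    out[i] <- "incorrect"
    for (j in seq_len(nrow(cs_trials))) {
      if (cs_trials$cs_type[j] == want &&
          episodes$onset[i] >= cs_trials$onset[j] &&
          episodes$onset[i] < cs_trials$onset[j] + cs_trials$duration[j]) {
        out[i] <- "correct"
        break
      }
    }
  }
  out
}

# Build a labeled dataset with planted class coding: `coding` columns get
# `effect` added for class-1 rows (binary) or per-class effects (list).
make_planted_dataset <- function(n_samples = 240, n_neurons = 40,
                                 coding = seq_len(n_neurons %/% 2),
                                 effect = 2, n_classes = 2,
                                 regions = NULL, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n_samples * n_neurons), n_samples, n_neurons)
  y <- rep(seq_len(n_classes) - 1L, length.out = n_samples)
  if (n_classes == 2) {
    X[y == 1, coding] <- X[y == 1, coding] + effect
  } else if (is.list(coding)) {
    for (cl in seq_along(coding))
      X[y == cl, coding[[cl]]] <- X[y == cl, coding[[cl]]] + effect
  }
  if (is.null(regions)) regions <- rep("aIC", n_neurons)
  structure(list(X = X, y = y, task = if (n_classes == 3) "CS3" else "CS",
                 regions = regions, neuron_id = seq_len(n_neurons),
                 bin_index = seq_len(n_samples), empty = FALSE),
            class = "labeled_dataset")
}

# Small two-region session with a planted lag-1 coupling, used by the
# TE recovery tests. No CS rate modulation (habituation stage).
make_coupled_session <- function(n_per_region = 20, len = 600,
                                 excess = 0.3, seed = 1,
                                 source = "aIC", target = "CE_SST") {
  cfg <- synth_config(
    n_neurons_per_region = stats::setNames(c(n_per_region, n_per_region),
                                           c(source, target)),
    baseline_rate = 0.2,
    coupling = if (excess > 0)
      data.frame(source = source, target = target,
                 excess_prob = excess, lag_bins = 1) else NULL,
    lfp_osc = NULL, session_length = len, n_trials_per_cs = 1,
    stage = "habituation", lfp_fs = 100, calcium_regions = character(0),
    seed = seed)
  generate_session(cfg)
}

# region state matrices (neurons x bins) from a session
region_states <- function(session, region, bin_width = 1) {
  trains <- Filter(function(tr) tr$region == region, session$trains)
  bin_events(trains, bin_width, 0, session$config$session_length)$counts
}
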