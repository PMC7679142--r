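#' Configuration for a synthetic recording session
#'
#' Builds and validates the parameter set for [generate_session()]. Defaults
#' emulate a multi-region Pavlovian conditioning session: five recorded
#' populations (aIC, pIC, CE_SST, CE_PKCd, CEm) with realistic per-session
#' neuron counts, two 10 s conditioned stimuli (R and F) presented in blocks
#' of two, unconditioned stimuli following the reinforced CS type of the
#' stage, stage-dependent CS/US rate modulation, optional directed lag
#' coupling between populations, LFP with phase-locked oscillatory
#' components, calcium traces for the imaged populations, and a motion-index
#' trace coupled to the behavioral episodes.
#'
#' @param n_neurons_per_region named integer vector of neurons per region.
#' @param baseline_rate baseline event rate in events/s; scalar or named per
#'   region.
#' @param cs_response_amp data.frame with columns `region`, `cs_type`,
#'   `stage`, `mult`: rate multiplier applied during matching CS windows.
#'   Rows absent from the table default to multiplier 1. `"*"` wildcards are
#'   allowed in `region`, `cs_type` and `stage`.
#' @param us_response_amp same layout for the 1 s US window.
#' @param coupling data.frame with columns `source`, `target`,
#'   `excess_prob`, `lag_bins`: directed event-probability coupling between
#'   regions (OR-gate on the lagged source state).
#' @param lfp_osc data.frame with columns `region`, `freq`, `amplitude`,
#'   `kappa`: oscillatory LFP components; `kappa` > 0 phase-locks that
#'   region's spikes to the component via von Mises sub-bin placement.
#' @param behavior_correct_prob probability that a trial receives a matching
#'   behavioral episode inside its CS window.
#' @param session_length session duration in seconds.
#' @param n_trials_per_cs trials per CS type.
#' @param stage learning stage label, one of habituation, C_early, C_late,
#'   FC, recall.
#' @param treatment treatment label.
#' @param lfp_fs,ca_fs,motion_fs sampling rates (Hz) of the continuous
#'   signals.
#' @param calcium_regions regions for which calcium traces are synthesized.
#' @param min_iti minimum inter-trial interval (s) between CS offset and the
#'   next CS onset.
#' @param seed integer seed; the whole session is reproducible from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_neurons_per_region = c(aIC = 113, pIC = 98,
                                                  CE_SST = 48, CE_PKCd = 54,
                                                  CEm = 29),
                         baseline_rate = 0.2,
                         cs_response_amp = data.frame(region = "*",
                                                      cs_type = "*",
                                                      stage = c("C_early", "C_late", "FC", "recall"),
                                                      mult = 2),
                         us_response_amp = data.frame(region = "*",
                                                      cs_type = "*",
                                                      stage = c("C_early", "C_late", "FC"),
                                                      mult = 3),
                         coupling = NULL,
                         lfp_osc = data.frame(region = c("aIC", "pIC"),
                                              freq = c(33, 33),
                                              amplitude = c(8, 8),
                                              kappa = c(0, 0)),
                         behavior_correct_prob = 0.8,
                         session_length = 1200,
                         n_trials_per_cs = 12,
                         stage = "recall",
                         treatment = "control",
                         lfp_fs = 1000,
                         ca_fs = 20,
                         motion_fs = 20,
                         calcium_regions = c("CE_SST", "CE_PKCd", "CEm"),
                         min_iti = 20,
                         seed = 1L) {
  stopifnot(length(n_neurons_per_region) >= 1,
            !is.null(names(n_neurons_per_region)),
            all(n_neurons_per_region >= 0))
  if (is.null(names(baseline_rate))) {
    baseline_rate <- stats::setNames(rep(baseline_rate[1],
                                         length(n_neurons_per_region)),
                                     names(n_neurons_per_region))
  }
  if (any(baseline_rate < 0)) stop("baseline rates must be >= 0")
  if (behavior_correct_prob < 0 || behavior_correct_prob > 1)
    stop("behavior_correct_prob must be in [0, 1]")
  if (!stage %in% STAGES) stop("unknown stage: ", stage)
  if (!is.null(coupling)) {
    stopifnot(all(c("source", "target", "excess_prob", "lag_bins") %in%
                    names(coupling)))
    if (any(coupling$excess_prob < 0 | coupling$excess_prob > 1))
      stop("coupling excess_prob must be in [0, 1]")
    if (any(coupling$lag_bins < 1)) stop("coupling lag_bins must be >= 1")
  }
  if (!is.null(lfp_osc) && nrow(lfp_osc) > 0) {
    stopifnot(all(lfp_osc$freq > 0), all(lfp_osc$kappa >= 0))
    if (any(lfp_osc$freq >= lfp_fs / 2))
      stop("LFP oscillation frequency must be below Nyquist")
  }
  # feasibility of the trial schedule: lead-in 10 s, CS 10 s + min ITI each
  n_trials <- 2L * n_trials_per_cs
  if (10 + n_trials * (10 + min_iti) > session_length)
    stop("infeasible trial schedule: ", n_trials,
         " trials do not fit in ", session_length, " s")
  structure(list(n_neurons_per_region = n_neurons_per_region,
                 baseline_rate = baseline_rate,
                 cs_response_amp = cs_response_amp,
                 us_response_amp = us_response_amp,
                 coupling = coupling,
                 lfp_osc = lfp_osc,
                 behavior_correct_prob = behavior_correct_prob,
                 session_length = session_length,
                 n_trials_per_cs = n_trials_per_cs,
                 stage = stage,
                 treatment = treatment,
                 lfp_fs = lfp_fs, ca_fs = ca_fs, motion_fs = motion_fs,
                 calcium_regions = calcium_regions,
                 min_iti = min_iti,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic session config:",
      sum(x$n_neurons_per_region), "neurons in",
      length(x$n_neurons_per_region), "regions;",
      2 * x$n_trials_per_cs, "CS trials;",
      x$session_length, "s; stage", x$stage, "; seed", x$seed, "\n")
  invisible(x)
}

# multiplier lookup with "*" wildcard support; absent -> 1
amp_lookup <- function(map, region, cs_type, stage) {
  if (is.null(map) || nrow(map) == 0) return(1)
  hit <- (map$region == region | map$region == "*") &
    (map$cs_type == cs_type | map$cs_type == "*") &
    (map$stage == stage | map$stage == "*")
  if (!any(hit)) 1 else map$mult[which(hit)[1]]
}

# which CS type is reinforced (followed by a US) at a given stage
reinforced_cs <- function(stage) {
  switch(stage, C_early = "R", C_late = "R", FC = "F", character(0))
}

#' Generate a complete synthetic session
#'
#' Draws spike/calcium event trains, a session timeline (CS trials, US
#' events, behavioral episodes), LFP traces, calcium dF/F traces, and a
#' motion-index trace, all reproducible from the config seed. Events are
#' drawn per 1 s bin as Bernoulli states at the region baseline rate,
#' multiplied during CS and US windows by the configured stage-dependent
#' amplitudes; coupling entries add excess target-event probability at the
#' configured lag given a source event (OR-gate); event times receive
#' uniform sub-bin jitter (von Mises phase placement in phase-locked
#' regions) so that finer binning remains meaningful.
#'
#' @param config a [synth_config()] object.
#' @return an object of class `entrain_session`: list with elements
#'   `trains` (list of `event_train`), `timeline` (`session_timeline`),
#'   `lfp` (named list of `lfp_record`), `calcium` (list of
#'   `calcium_trace`), `motion` (`motion_trace`), and `config`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  len <- config$session_length
  n_bins <- as.integer(floor(len))
  timeline <- make_timeline(config)

  regions <- names(config$n_neurons_per_region)
  # per-bin rate multiplier per region (1 s bins)
  mult <- matrix(1, nrow = length(regions), ncol = n_bins,
                 dimnames = list(regions, NULL))
  for (i in seq_len(nrow(timeline$cs_trials))) {
    tr <- timeline$cs_trials[i, ]
    bins <- which_bins(tr$onset, tr$onset + tr$duration, n_bins)
    for (r in regions)
      mult[r, bins] <- amp_lookup(config$cs_response_amp, r, tr$cs_type,
                                  config$stage)
  }
  if (nrow(timeline$us_events) > 0) {
    for (i in seq_len(nrow(timeline$us_events))) {
      us <- timeline$us_events[i, ]
      bins <- which_bins(us$time, us$time + 1, n_bins)
      for (r in regions)
        mult[r, bins] <- amp_lookup(config$us_response_amp, r, us$us_type,
                                    config$stage)
    }
  }

  # binary states per region: list of n_neurons x n_bins matrices
  states <- list()
  for (r in regions) {
    nn <- config$n_neurons_per_region[[r]]
    p <- pmin(config$baseline_rate[[r]] * mult[r, ], 0.95)
    states[[r]] <- matrix(stats::rbinom(nn * n_bins, 1, rep(p, each = nn)),
                          nrow = nn, ncol = n_bins)
  }
  # directed coupling: target gains excess event probability at t + lag
  # given a source event at t (cyclic neuron pairing source -> target)
  if (!is.null(config$coupling)) {
    for (i in seq_len(nrow(config$coupling))) {
      cp <- config$coupling[i, ]
      src <- states[[cp$source]]
      tgt <- states[[cp$target]]
      lag <- cp$lag_bins
      if (nrow(src) == 0 || nrow(tgt) == 0) next
      pair <- ((seq_len(nrow(tgt)) - 1L) %% nrow(src)) + 1L
      t_src <- seq_len(n_bins - lag)
      lagged <- src[pair, t_src, drop = FALSE]
      extra <- matrix(stats::rbinom(length(lagged), 1,
                                    cp$excess_prob * as.vector(lagged)),
                      nrow = nrow(tgt))
      tgt[, t_src + lag] <- pmax(tgt[, t_src + lag, drop = FALSE], extra)
      states[[cp$target]] <- tgt
    }
  }

  # LFP per region: 1/f background + configured oscillations (sine phase 0)
  lfp <- list()
  n_samp <- as.integer(round(len * config$lfp_fs))
  for (r in regions) {
    x <- pink_noise(n_samp) * 30
    osc <- region_osc(config$lfp_osc, r)
    if (nrow(osc) > 0) {
      tt <- (seq_len(n_samp) - 1) / config$lfp_fs
      for (j in seq_len(nrow(osc)))
        x <- x + osc$amplitude[j] * sin(2 * pi * osc$freq[j] * tt)
    }
    lfp[[r]] <- lfp_record(x, config$lfp_fs, r)
  }

  # event times: bin index + sub-bin placement (uniform, or von Mises phase
  # placement in regions with a kappa > 0 oscillation: preserves bin counts
  # while creating sub-bin phase locking)
  trains <- list()
  id <- 0L
  for (r in regions) {
    st <- states[[r]]
    osc <- region_osc(config$lfp_osc, r)
    lock <- nrow(osc) > 0 && any(osc$kappa > 0)
    if (lock) {
      j <- which.max(osc$kappa)
      f0 <- osc$freq[j]; kap <- osc$kappa[j]
    }
    for (n in seq_len(nrow(st))) {
      id <- id + 1L
      bins <- which(st[n, ] == 1)
      if (length(bins) == 0) {
        times <- numeric(0)
      } else if (!lock) {
        times <- (bins - 1) + stats::runif(length(bins))
      } else {
        # place each event at a von Mises draw around the oscillation peak
        # phase (pi/2 for a sine), within its own 1 s bin
        ph <- rvonmises(length(bins), mu = pi / 2, kappa = kap)
        cyc <- floor(stats::runif(length(bins)) * f0)
        times <- (bins - 1) + (cyc + (ph %% (2 * pi)) / (2 * pi)) / f0
        times <- pmin(times, bins - 1e-9)
      }
      trains[[id]] <- event_train(id, r, config$stage, config$treatment,
                                  sort(times), len)
    }
  }

  # calcium traces for the imaged regions
  calcium <- list()
  ci <- 0L
  for (tr in trains) {
    if (!tr$region %in% config$calcium_regions) next
    ci <- ci + 1L
    calcium[[ci]] <- generate_calcium(tr, amp = 1, tau_decay = 0.5,
                                      noise_sd = 0.05, fs = config$ca_fs,
                                      seed = NULL)
  }

  # motion index: high baseline, near-zero during freezing episodes
  n_m <- as.integer(round(len * config$motion_fs))
  motion <- 50 + stats::rnorm(n_m, sd = 8)
  motion[motion < 1] <- 1
  ep <- timeline$behavior_episodes
  if (nrow(ep) > 0) {
    fr <- ep[ep$kind == "freezing_onset", , drop = FALSE]
    for (i in seq_len(nrow(fr))) {
      i0 <- floor(fr$onset[i] * config$motion_fs) + 1
      i1 <- min(n_m, i0 + as.integer(round(fr$duration[i] * config$motion_fs)) - 1)
      motion[i0:i1] <- abs(stats::rnorm(i1 - i0 + 1, sd = 0.1))
    }
  }
  motion <- motion_trace(motion, config$motion_fs)

  structure(list(trains = trains, timeline = timeline, lfp = lfp,
                 calcium = calcium, motion = motion, config = config),
            class = "entrain_session")
}

#' @export
print.entrain_session <- function(x, ...) {
  cat("Synthetic session:", length(x$trains), "neurons,",
      nrow(x$timeline$cs_trials), "CS trials,",
      x$config$session_length, "s, stage", x$config$stage, "\n")
  invisible(x)
}

# 1-based bin indices (1 s bins) covered by [t0, t1)
which_bins <- function(t0, t1, n_bins) {
  b <- (floor(t0) + 1):(ceiling(t1))
  b[b >= 1 & b <= n_bins & b > floor(t0) & b <= floor(t1 - 1e-9) + 1]
}

region_osc <- function(lfp_osc, r) {
  if (is.null(lfp_osc)) return(data.frame())
  lfp_osc[lfp_osc$region == r, , drop = FALSE]
}

# 1/f-amplitude noise via spectral shaping, unit variance
pink_noise <- function(n) {
  nf <- n %/% 2
  amp <- 1 / sqrt(seq_len(nf))
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 1)] <- Conj(spec)
  x <- Re(stats::fft(full, inverse = TRUE))
  as.numeric(scale(x))
}

# build the CS/US/behavior timeline for a config (assumes RNG already seeded)
make_timeline <- function(config) {
  n_trials <- 2L * config$n_trials_per_cs
  # blocks of two per CS type: R R F F R R F F ...
  blocks <- rep(c("R", "R", "F", "F"), length.out = n_trials)
  slack <- config$session_length - 10 - n_trials * (10 + config$min_iti)
  gaps <- config$min_iti + stats::runif(n_trials, 0, slack / n_trials)
  # CS onsets at whole seconds: aligns stimulus windows with the 1 s
  # analysis bins (events still carry sub-bin jitter)
  onsets <- floor(10 + cumsum(c(0, gaps[-n_trials])) +
                    (seq_len(n_trials) - 1) * 10)
  if (max(onsets) + 10 > config$session_length)
    stop("infeasible trial schedule")
  cs_trials <- data.frame(onset = onsets, cs_type = blocks, duration = 10)

  rf <- reinforced_cs(config$stage)
  us <- cs_trials[cs_trials$cs_type %in% rf, , drop = FALSE]
  us_events <- data.frame(time = us$onset + us$duration,
                          us_type = us$cs_type)

  # behavioral episodes: matching kind inside the CS with probability
  # behavior_correct_prob, otherwise placed in an inter-trial interval at
  # least 5 s away from any CS
  eps <- list()
  for (i in seq_len(nrow(cs_trials))) {
    tr <- cs_trials[i, ]
    kind <- if (tr$cs_type == "R") "port_visit" else "freezing_onset"
    dur <- if (kind == "freezing_onset") stats::runif(1, 2, 5) else 0
    if (stats::runif(1) < config$behavior_correct_prob) {
      onset <- tr$onset + stats::runif(1, 0, tr$duration - 1e-3)
    } else {
      onset <- draw_outside_cs(cs_trials, config$session_length, margin = 5)
      if (is.na(onset)) next
    }
    eps[[length(eps) + 1]] <- data.frame(onset = onset, kind = kind,
                                         duration = dur)
  }
  behavior_episodes <- if (length(eps)) do.call(rbind, eps) else
    data.frame(onset = numeric(0), kind = character(0), duration = numeric(0))
  behavior_episodes <- behavior_episodes[order(behavior_episodes$onset), ,
                                         drop = FALSE]
  rownames(behavior_episodes) <- NULL
  session_timeline(cs_trials, us_events, behavior_episodes,
                   config$session_length)
}

draw_outside_cs <- function(cs_trials, len, margin = 5, tries = 200) {
  for (i in seq_len(tries)) {
    t <- stats::runif(1, 0, len - 1)
    d <- t - cs_trials$onset
    if (all(d < -margin | d > 10 + margin)) return(t)
  }
  NA_real_
}

#' Event train container
#'
#' @param neuron_id integer id.
#' @param region region label.
#' @param stage stage label.
#' @param treatment treatment label.
#' @param times event times in seconds, non-decreasing.
#' @param session_length session duration; events outside error out.
#' @return object of class `event_train`.
#' @export
event_train <- function(neuron_id, region, stage = "recall",
                        treatment = "control", times = numeric(0),
                        session_length = Inf) {
  times <- sort(unique(as.numeric(times)))
  if (length(times) && (min(times) < 0 || max(times) > session_length))
    stop("event times outside [0, session_length]")
  structure(list(neuron_id = neuron_id, region = region, stage = stage,
                 treatment = treatment, times = times,
                 session_length = session_length),
            class = "event_train")
}

#' Session timeline container
#'
#' @param cs_trials data.frame(onset, cs_type, duration).
#' @param us_events data.frame(time, us_type).
#' @param behavior_episodes data.frame(onset, kind, duration).
#' @param session_length duration in seconds.
#' @return object of class `session_timeline`.
#' @export
session_timeline <- function(cs_trials, us_events = NULL,
                             behavior_episodes = NULL,
                             session_length = Inf) {
  if (is.null(us_events))
    us_events <- data.frame(time = numeric(0), us_type = character(0))
  if (is.null(behavior_episodes))
    behavior_episodes <- data.frame(onset = numeric(0), kind = character(0),
                                    duration = numeric(0))
  cs_trials <- cs_trials[order(cs_trials$onset), , drop = FALSE]
  rownames(cs_trials) <- NULL
  if (nrow(cs_trials) > 1 &&
      any(diff(cs_trials$onset) < cs_trials$duration[-nrow(cs_trials)]))
    stop("overlapping CS windows")
  structure(list(cs_trials = cs_trials, us_events = us_events,
                 behavior_episodes = behavior_episodes,
                 session_length = session_length),
            class = "session_timeline")
}

#' LFP record container
#' @param samples numeric vector (microvolt scale).
#' @param fs sampling rate in Hz.
#' @param region region label.
#' @export
lfp_record <- function(samples, fs, region = NA_character_) {
  stopifnot(fs > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), fs = fs, region = region),
            class = "lfp_record")
}

#' Calcium trace container
#'
#' Holds the raw fluorescence F(t), baseline F0 and the relative change
#' dff = (F(t) - F0) / F0.
#'
#' @param dff dF/F series.
#' @param fs sampling rate in Hz.
#' @param f0 positive baseline; raw F is reconstructed as f0 * (1 + dff).
#' @param id source trace id.
#' @export
calcium_trace <- function(dff, fs = 20, f0 = 1, id = NA) {
  stopifnot(fs > 0, f0 > 0)
  structure(list(raw = f0 * (1 + dff), f0 = f0, dff = as.numeric(dff),
                 fs = fs, id = id),
            class = "calcium_trace")
}

#' Motion-index trace container
#' @param index per-frame nonnegative motion index.
#' @param fs frame rate in Hz.
#' @export
motion_trace <- function(index, fs) {
  stopifnot(length(index) > 0, all(index >= 0 | is.na(index)), fs > 0)
  structure(list(index = as.numeric(index), fs = fs), class = "motion_trace")
}

#' Generate a minimal coupled binary pair
#'
#' Produces two binary state series where Y depends on X only at the stated
#' lag: `Y[t] = Base_Y[t] OR (X[t - lag] AND Bernoulli(excess_prob))`.
#' This is the minimal fixture for directed-information tests.
#'
#' @param len_bins length of both series.
#' @param p_base base event probability; scalar or `c(px, py)`.
#' @param excess_prob coupling probability in `[0, 1]`.
#' @param lag positive integer lag in bins.
#' @param seed integer seed.
#' @return list with binary integer vectors `x` and `y`.
#' @export
generate_coupled_pair <- function(len_bins, p_base, excess_prob, lag = 1,
                                  seed = 1) {
  if (any(p_base < 0 | p_base > 1) || excess_prob < 0 || excess_prob > 1)
    stop("probabilities must be in [0, 1]")
  if (len_bins < lag + 2) stop("len_bins must be >= lag + 2")
  px <- p_base[1]
  py <- if (length(p_base) > 1) p_base[2] else p_base[1]
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rbinom(len_bins, 1, px)
  y <- stats::rbinom(len_bins, 1, py)
  t_src <- seq_len(len_bins - lag)
  gate <- stats::rbinom(len_bins - lag, 1, excess_prob) * x[t_src]
  y[t_src + lag] <- pmax(y[t_src + lag], gate)
  list(x = x, y = y)
}

#' Estimate the excess conditional event probability of a lagged coupling
#'
#' Count-based estimate inverting the OR-gate coupling: with
#' `p1 = P(Y[t+lag]=1 | X[t]=1)` and `p0 = P(Y[t+lag]=1 | X[t]=0)`, returns
#' `(p1 - p0) / (1 - p0)`, which converges to the generating `excess_prob`.
#'
#' @param x,y binary series.
#' @param lag lag in bins.
#' @return estimate in `[0, 1]` (NA if X never active or p0 = 1).
#' @export
estimate_excess_prob <- function(x, y, lag = 1) {
  n <- length(x)
  stopifnot(length(y) == n, n > lag)
  xs <- x[seq_len(n - lag)]
  ys <- y[seq_len(n - lag) + lag]
  if (!any(xs == 1) || !any(xs == 0)) return(NA_real_)
  p1 <- mean(ys[xs == 1])
  p0 <- mean(ys[xs == 0])
  if (p0 >= 1) return(NA_real_)
  (p1 - p0) / (1 - p0)
}

#' Synthesize a calcium dF/F trace from an event train
#'
#' Each event adds an instantaneous-rise exponential-decay transient
#' `amp * exp(-(t - t_event) / tau_decay)` for `t >= t_event`; Gaussian
#' noise is added on top.
#'
#' @param events an [event_train()] (or numeric vector of event times).
#' @param amp transient peak amplitude (dF/F units).
#' @param tau_decay decay time constant in seconds.
#' @param noise_sd SD of additive Gaussian noise.
#' @param fs sampling rate in Hz.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param duration trace duration in s (defaults to the train's session
#'   length, or last event + 5 tau).
#' @return a [calcium_trace()].
#' @export
generate_calcium <- function(events, amp = 1, tau_decay = 0.5,
                             noise_sd = 0.05, fs = 20, seed = NULL,
                             duration = NULL) {
  if (amp <= 0 || tau_decay <= 0) stop("amp and tau_decay must be > 0")
  if (fs <= 0) stop("fs must be > 0")
  times <- if (inherits(events, "event_train")) events$times else
    as.numeric(events)
  if (is.null(duration)) {
    duration <- if (inherits(events, "event_train") &&
                    is.finite(events$session_length))
      events$session_length
    else if (length(times)) max(times) + 5 * tau_decay else 1
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration * fs))
  tt <- (seq_len(n) - 1) / fs
  dff <- numeric(n)
  for (te in times) {
    i0 <- which(tt >= te)[1]
    if (is.na(i0)) next
    dff[i0:n] <- dff[i0:n] + amp * exp(-(tt[i0:n] - te) / tau_decay)
  }
  if (noise_sd > 0) dff <- dff + stats::rnorm(n, sd = noise_sd)
  id <- if (inherits(events, "event_train")) events$neuron_id else NA
  calcium_trace(dff, fs = fs, f0 = 1, id = id)
}
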