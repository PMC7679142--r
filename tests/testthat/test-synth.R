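test_that("identical config yields identical sessions", {
  cfg <- synth_config(n_neurons_per_region = c(aIC = 4, pIC = 3,
                                               CE_SST = 2),
                      session_length = 200, n_trials_per_cs = 2,
                      lfp_fs = 100, seed = 11)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1, s2)
})

test_that("trial schedules that cannot fit are rejected", {
  expect_error(synth_config(session_length = 100, n_trials_per_cs = 12),
               "infeasible")
  expect_error(synth_config(behavior_correct_prob = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(coupling = data.frame(source = "aIC",
                                                  target = "pIC",
                                                  excess_prob = 2,
                                                  lag_bins = 1)),
               "excess_prob")
})

test_that("timeline respects CS structure and stage-dependent USs", {
  for (stage in c("habituation", "C_late", "FC", "recall")) {
    cfg <- synth_config(n_neurons_per_region = c(aIC = 2),
                        session_length = 600, n_trials_per_cs = 4,
                        stage = stage, lfp_fs = 100, seed = 5)
    tl <- generate_session(cfg)$timeline
    expect_true(all(tl$cs_trials$duration == 10))
    expect_true(all(diff(tl$cs_trials$onset) >= 10))
    us <- tl$us_events
    if (stage %in% c("habituation", "recall")) {
      expect_equal(nrow(us), 0)
    } else {
      want <- if (stage == "FC") "F" else "R"
      expect_true(all(us$us_type == want))
      # each US follows a CS of its own type at its offset
      for (i in seq_len(nrow(us))) {
        d <- us$time[i] - (tl$cs_trials$onset + 10)
        j <- which(abs(d) < 1e-9)
        expect_length(j, 1)
        expect_equal(tl$cs_trials$cs_type[j], us$us_type[i])
      }
    }
  }
})

test_that("empirical rates match configured rates within 3 SE", {
  cfg <- synth_config(n_neurons_per_region = c(aIC = 30, CE_SST = 20),
                      baseline_rate = c(aIC = 0.2, CE_SST = 0.35),
                      cs_response_amp = NULL, us_response_amp = NULL,
                      session_length = 1000, n_trials_per_cs = 2,
                      stage = "habituation", lfp_fs = 100,
                      calcium_regions = character(0), seed = 7)
  ses <- generate_session(cfg)
  for (r in c("aIC", "CE_SST")) {
    p <- cfg$baseline_rate[[r]]
    counts <- rowSums(region_states(ses, r))
    se <- sqrt(p * (1 - p) / 1000)
    expect_true(all(abs(counts / 1000 - p) < 3.5 * se + 0.02))
    # population-level mean should be tighter
    expect_lt(abs(mean(counts / 1000) - p), 3 * se)
  }
})

test_that("uncoupled regions show baseline conditional probability", {
  cp <- generate_coupled_pair(6000, 0.2, excess_prob = 0, lag = 1,
                              seed = 3)
  p1 <- mean(cp$y[-1][cp$x[-6000] == 1])
  p0 <- mean(cp$y[-1][cp$x[-6000] == 0])
  se <- sqrt(0.2 * 0.8 / sum(cp$x == 1))
  expect_lt(abs(p1 - p0), 3 * se)
})

test_that("planted excess coupling probability is recovered", {
  cp <- generate_coupled_pair(10000, 0.2, excess_prob = 0.3, lag = 1,
                              seed = 4)
  expect_lt(abs(estimate_excess_prob(cp$x, cp$y, 1) - 0.3), 0.03)
  # convergence as bins grow
  est <- vapply(c(2000, 20000, 200000), function(n) {
    cp <- generate_coupled_pair(n, 0.2, 0.3, 1, seed = 9)
    estimate_excess_prob(cp$x, cp$y, 1)
  }, numeric(1))
  expect_lt(abs(est[3] - 0.3), abs(est[1] - 0.3) + 0.005)
})

test_that("full coupling with silent target copies the source", {
  cp <- generate_coupled_pair(500, c(0.5, 0), excess_prob = 1, lag = 1,
                              seed = 2)
  expect_identical(cp$y[-1], cp$x[-500])
  expect_identical(cp$y[1], 0L)
})

test_that("lagged odds ratio matches the analytic 2x2 value", {
  p <- 0.25; e <- 0.5
  cp <- generate_coupled_pair(2e5, p, e, lag = 1, seed = 6)
  tab <- table(source = cp$x[-2e5], target = cp$y[-1])
  or_emp <- (as.numeric(tab["1", "1"]) * as.numeric(tab["0", "0"])) /
    (as.numeric(tab["1", "0"]) * as.numeric(tab["0", "1"]))
  p1 <- p + (1 - p) * e
  or_true <- (p1 / (1 - p1)) / (p / (1 - p))
  expect_lt(abs(or_emp / or_true - 1), 0.1)
})

test_that("coupling independence holds across seeds (chi-square)", {
  nonsig <- 0
  for (s in 1:100) {
    cp <- generate_coupled_pair(600, 0.2, 0, 1, seed = s)
    tab <- table(cp$x[-600], cp$y[-1])
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    if (p > 0.01) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 95)
})

test_that("calcium synthesis matches the closed-form transient", {
  # no events, no noise -> flat zero
  tr <- generate_calcium(numeric(0), amp = 1, tau_decay = 0.2,
                         noise_sd = 0, fs = 20, duration = 5)
  expect_equal(tr$dff, rep(0, 100))
  # one event: peak = amp at the event sample
  tr1 <- generate_calcium(1, amp = 2.5, tau_decay = 0.2, noise_sd = 0,
                          fs = 20, duration = 3)
  expect_equal(max(tr1$dff), 2.5)
  expect_equal(which.max(tr1$dff), 21)  # t = 1 s at fs 20
  # two events 1 s apart: analytic double-exponential at every sample
  tau <- 0.2; amp <- 1.2
  tr2 <- generate_calcium(c(1, 2), amp = amp, tau_decay = tau,
                          noise_sd = 0, fs = 20, duration = 4)
  tt <- (0:79) / 20
  expected <- amp * exp(-(tt - 1) / tau) * (tt >= 1) +
    amp * exp(-(tt - 2) / tau) * (tt >= 2)
  expect_equal(tr2$dff, expected, tolerance = 1e-12)
})

test_that("LFP carries the configured oscillation above its neighbors", {
  cfg <- synth_config(n_neurons_per_region = c(aIC = 1),
                      lfp_osc = data.frame(region = "aIC", freq = 33,
                                           amplitude = 10, kappa = 0),
                      session_length = 200, n_trials_per_cs = 2,
                      lfp_fs = 200, calcium_regions = character(0),
                      seed = 12)
  ses <- generate_session(cfg)
  sp <- stats::spec.pgram(ses$lfp$aIC$samples, taper = 0, plot = FALSE)
  freq_hz <- sp$freq * 200
  at_osc <- mean(sp$spec[abs(freq_hz - 33) < 1])
  neighbor <- mean(sp$spec[abs(freq_hz - 45) < 1])
  expect_gt(at_osc / neighbor, 10)
})

test_that("behavior episodes land inside matching CSs when correct", {
  cfg <- synth_config(n_neurons_per_region = c(aIC = 2),
                      behavior_correct_prob = 1, session_length = 600,
                      n_trials_per_cs = 4, lfp_fs = 100,
                      calcium_regions = character(0), seed = 8)
  tl <- generate_session(cfg)$timeline
  eps <- classify_episodes(tl$behavior_episodes, tl)
  expect_true(all(eps$correctness == "correct"))
  # and outside any CS (>= 5 s margin) when always incorrect
  cfg0 <- synth_config(n_neurons_per_region = c(aIC = 2),
                       behavior_correct_prob = 0, session_length = 600,
                       n_trials_per_cs = 4, lfp_fs = 100,
                       calcium_regions = character(0), seed = 8)
  tl0 <- generate_session(cfg0)$timeline
  for (on in tl0$behavior_episodes$onset) {
    d <- on - tl0$cs_trials$onset
    expect_true(all(d < -5 | d > 15))
  }
})
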