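test_that("events fall into half-open bins with boundary to the right", {
  tr <- event_train(1, "aIC", times = c(0.2, 0.7, 1.5), session_length = 2)
  bm <- bin_events(tr, bin_width = 1, t0 = 0, t_end = 2)
  expect_equal(as.vector(bm$counts), c(2L, 1L))
  # an event exactly on a boundary belongs to the later bin
  bm2 <- bin_events(event_train(1, "aIC", times = 1, session_length = 2),
                    1, 0, 2)
  expect_equal(as.vector(bm2$counts), c(0L, 1L))
})

test_that("empty trains produce all-zero matrices", {
  bm <- bin_events(event_train(1, "pIC", times = numeric(0),
                               session_length = 3), 1, 0, 3)
  expect_true(all(bm$counts == 0L))
  expect_equal(dim(bm$counts), c(1, 3))
})

test_that("out-of-range events are dropped and counted", {
  tr <- event_train(1, "aIC", times = c(0.5, 5.5), session_length = 10)
  expect_message(bm <- bin_events(tr, 1, 0, 3), "dropped")
  expect_equal(bm$dropped, 1L)
  expect_equal(sum(bm$counts), 1L)
})

test_that("binning at 0.5 s refines 1 s binning exactly", {
  set.seed(21)
  trains <- lapply(1:5, function(i)
    event_train(i, "aIC", times = sort(runif(rpois(1, 200), 0, 100)),
                session_length = 100))
  b1 <- bin_events(trains, 1, 0, 100)
  b05 <- bin_events(trains, 0.5, 0, 100)
  summed <- b05$counts[, seq(1, 199, by = 2)] + b05$counts[, seq(2, 200, by = 2)]
  expect_identical(unname(summed), unname(b1$counts))
  # count conservation
  expect_equal(sum(b1$counts), sum(lengths(lapply(trains, `[[`, "times"))))
})

make_step_session <- function(rate_pre = 2, rate_cs = 4, n_trials = 20,
                              seed = 31) {
  # one neuron whose rate doubles during 10 s CS windows, 0.5 s bins
  set.seed(seed)
  len <- n_trials * 40 + 20
  onsets <- 20 + (seq_len(n_trials) - 1) * 40
  tl <- session_timeline(data.frame(onset = onsets, cs_type = "R",
                                    duration = 10),
                         session_length = len)
  n_half <- len * 2
  rate <- rep(rate_pre / 2, n_half)   # events per 0.5 s bin
  for (on in onsets) rate[(on * 2 + 1):(on * 2 + 20)] <- rate_cs / 2
  counts <- rpois(n_half, rate)
  times <- unlist(lapply(which(counts > 0), function(b)
    (b - 1) * 0.5 + runif(counts[b], 0, 0.5)))
  list(train = event_train(1, "aIC", times = sort(times),
                           session_length = len),
       timeline = tl)
}

test_that("constant-rate neurons have near-zero PETH z-scores", {
  ss <- make_step_session(rate_pre = 3, rate_cs = 3, n_trials = 200,
                          seed = 32)
  bm <- bin_events(ss$train, 0.5, 0, ss$train$session_length)
  p <- make_peth(bm, ss$timeline, smoothing_degree = 5)
  expect_lt(max(abs(apply(p$z, 3, mean))), 0.2)
})

test_that("step responses match an unsmoothed z-score oracle", {
  ss <- make_step_session(rate_pre = 2, rate_cs = 4, n_trials = 100)
  bm <- bin_events(ss$train, 0.5, 0, ss$train$session_length)
  p <- make_peth(bm, ss$timeline, smoothing_degree = 2)
  cs_bins <- p$rel_time >= 0 & p$rel_time < 10
  pre_bins <- p$rel_time >= -8 & p$rel_time < 0
  d_pkg <- mean(p$z[, 1, cs_bins]) - mean(p$z[, 1, pre_bins])
  # oracle: z-score the raw counts by hand, no smoothing, same windows
  z_hand <- (bm$counts[1, ] - mean(bm$counts[1, ])) / sd(bm$counts[1, ])
  vals_cs <- c(); vals_pre <- c()
  for (on in ss$timeline$cs_trials$onset) {
    b0 <- on * 2
    vals_cs <- c(vals_cs, z_hand[(b0 + 1):(b0 + 20)])
    vals_pre <- c(vals_pre, z_hand[(b0 - 15):(b0)])
  }
  d_hand <- mean(vals_cs) - mean(vals_pre)
  expect_gt(d_pkg, 0)
  expect_lt(abs(d_pkg - d_hand), 0.15 * abs(d_hand) + 0.05)
})

test_that("masked shock bins stay NA and never enter downstream means", {
  ss <- make_step_session(n_trials = 10)
  tl <- ss$timeline
  # plant an F-type US inside the window of trial 3
  tl$us_events <- data.frame(time = tl$cs_trials$onset[3] + 10,
                             us_type = "F")
  bm <- bin_events(ss$train, 0.5, 0, ss$train$session_length)
  p <- make_peth(bm, tl, smoothing_degree = 2, shock_mask = TRUE)
  expect_true(any(p$mask[3, ]))
  expect_true(all(is.na(p$z[3, 1, p$mask[3, ]])))
  expect_true(all(!is.na(p$z[3, 1, !p$mask[3, ]])))
  # NaN propagation guard: means computed with na.rm are finite
  expect_true(all(is.finite(apply(p$z, 3, mean, na.rm = TRUE))))
})

test_that("blacked-out channels are replaced by the population average", {
  set.seed(33)
  trains <- lapply(1:4, function(i)
    event_train(i, "aIC", times = sort(runif(300, 0, 200)),
                session_length = 200))
  tl <- session_timeline(data.frame(onset = c(50, 100), cs_type = "R",
                                    duration = 10), session_length = 200)
  bm <- bin_events(trains, 0.5, 0, 200)
  p <- make_peth(bm, tl, smoothing_degree = 0,
                 blackout_channels = data.frame(trial = 1, neuron_row = 2))
  pop <- apply(p$z[1, c(1, 3, 4), ], 2, mean)
  expect_equal(p$z[1, 2, ], pop, tolerance = 1e-12)
})

test_that("trials too close to the session start are skipped", {
  tl <- session_timeline(data.frame(onset = c(4, 60), cs_type = "R",
                                    duration = 10), session_length = 100)
  bm <- bin_events(event_train(1, "aIC", times = c(1, 50),
                               session_length = 100), 0.5, 0, 100)
  expect_warning(p <- make_peth(bm, tl, smoothing_degree = 0), "skipped")
  expect_equal(dim(p$z)[1], 1)
})

test_that("CS task labels the pre-window and stimulus bins", {
  tl <- session_timeline(data.frame(onset = 100, cs_type = "R",
                                    duration = 10), session_length = 200)
  bm <- bin_events(event_train(1, "aIC", times = 100.5,
                               session_length = 200), 1, 0, 200)
  ds <- build_labels(bm, tl, task = "CS", pre_window_bins = 10)
  # 0-based session seconds 90..99 are class 0, 100..109 class 1
  expect_equal(ds$bin_index[ds$y == 0], 91:100)
  expect_equal(ds$bin_index[ds$y == 1], 101:110)
})

test_that("US task labels pre-CS and post-US bins", {
  tl <- session_timeline(data.frame(onset = 100, cs_type = "R",
                                    duration = 10),
                         us_events = data.frame(time = 110, us_type = "R"),
                         session_length = 200)
  bm <- bin_events(event_train(1, "aIC", times = 100.5,
                               session_length = 200), 1, 0, 200)
  ds <- build_labels(bm, tl, task = "US", pre_window_bins = 10,
                     post_us_bins = 8)
  expect_equal(ds$bin_index[ds$y == 0], 91:100)
  expect_equal(ds$bin_index[ds$y == 1], 112:119)
})

test_that("zero trials produce an empty flagged dataset", {
  tl <- session_timeline(data.frame(onset = numeric(0),
                                    cs_type = character(0),
                                    duration = numeric(0)),
                         session_length = 100)
  bm <- bin_events(event_train(1, "aIC", times = 5, session_length = 100),
                   1, 0, 100)
  ds <- build_labels(bm, tl, task = "CS")
  expect_true(ds$empty)
  expect_equal(nrow(ds$X), 0)
})

test_that("CS3 class counts match trial structure and labels partition", {
  onsets <- 30 + (0:23) * 40
  tl <- session_timeline(data.frame(onset = onsets,
                                    cs_type = rep(c("R", "F"), 12),
                                    duration = 10),
                         session_length = 1200)
  bm <- bin_events(event_train(1, "aIC", times = 31, session_length = 1200),
                   1, 0, 1200)
  ds <- build_labels(bm, tl, task = "CS3", pre_window_bins = 10)
  expect_equal(as.vector(table(ds$y)), c(24 * 10, 120, 120))
  expect_false(any(duplicated(ds$bin_index)))
})

test_that("overlapping pre-windows are truncated with a message", {
  tl <- session_timeline(data.frame(onset = c(20, 35), cs_type = "R",
                                    duration = 10), session_length = 100)
  bm <- bin_events(event_train(1, "aIC", times = 21, session_length = 100),
                   1, 0, 100)
  expect_message(ds <- build_labels(bm, tl, task = "CS",
                                    pre_window_bins = 10), "truncated")
  # second trial's pre-window loses the 5 bins inside the first CS
  expect_equal(sum(ds$y == 0), 10 + 5)
  expect_false(any(duplicated(ds$bin_index)))
})

test_that("z-scoring is idempotent and balancing equalizes classes", {
  set.seed(41)
  X <- matrix(rnorm(200, mean = 3, sd = 2), 20, 10)
  z1 <- entrain:::zscore_cols(X)
  z2 <- entrain:::zscore_cols(z1)
  expect_equal(z1, z2, tolerance = 1e-12)
  ds <- make_planted_dataset(n_samples = 90, n_neurons = 5)
  ds$y <- rep(c(0L, 0L, 1L), 30)
  bal <- balance_undersample(ds)
  expect_equal(as.vector(table(bal$y)), c(30, 30))
})
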