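test_that("shuffled labels decode at chance and planted coding near perfectly", {
  ds <- make_planted_dataset(n_samples = 240, n_neurons = 40, effect = 2,
                             seed = 81)
  sh <- decode_single_region(ds, repeats = 10, shuffle = TRUE, seed = 1)
  expect_gte(sh$da, 0.42)
  expect_lte(sh$da, 0.58)
  r <- decode_single_region(ds, repeats = 5, seed = 2)
  expect_gte(r$da, 0.85)
  expect_true(all(r$accuracies >= 0 & r$accuracies <= 1))
})

test_that("identical features across classes decode at chance", {
  ds <- make_planted_dataset(n_samples = 200, n_neurons = 20, effect = 0,
                             seed = 82)
  r <- decode_single_region(ds, repeats = 8, seed = 3)
  expect_gte(r$da, 0.40)
  expect_lte(r$da, 0.60)
})

test_that("decoding errors on degenerate requests", {
  ds <- make_planted_dataset(n_samples = 60, n_neurons = 10, seed = 83)
  expect_error(decode_single_region(ds, n_neurons = 99), "exceeds")
  ds1 <- ds; ds1$y <- rep(0L, 60)
  expect_error(decode_single_region(ds1), "two classes")
})

test_that("decoding is reproducible and label-leak free", {
  ds <- make_planted_dataset(n_samples = 120, n_neurons = 12, seed = 84)
  a <- decode_single_region(ds, repeats = 3, seed = 7)$da
  b <- decode_single_region(ds, repeats = 3, seed = 7)$da
  expect_equal(a, b, tolerance = 1e-12)
  # a feature that perfectly encodes the (unshuffled) labels must not
  # lift shuffled-label accuracy if balancing/z-scoring are leak-free
  ds$X[, 1] <- ds$y * 10
  sh <- decode_single_region(ds, repeats = 10, shuffle = TRUE, seed = 8)
  expect_gte(sh$da, 0.42)
  expect_lte(sh$da, 0.58)
})

test_that("accuracy grows with planted effect size", {
  da <- vapply(c(0, 0.5, 1, 2), function(ef)
    decode_single_region(make_planted_dataset(n_samples = 160,
                                              n_neurons = 16,
                                              effect = ef, seed = 85),
                         repeats = 4, seed = 9)$da, numeric(1))
  expect_true(all(diff(da) > -0.05))
  expect_lt(da[1], 0.6)
  expect_gt(da[4], 0.85)
})

test_that("best-neuron ranking finds coders and respects the tie rule", {
  # one perfectly coding neuron among non-coders
  ds <- make_planted_dataset(n_samples = 120, n_neurons = 6, coding = 4,
                             effect = 4, seed = 86)
  rk <- rank_best_neurons(ds, repeats = 3, seed = 10)
  expect_equal(rk$neuron[1], 4)
  # all-identical neurons rank in id order
  ds2 <- make_planted_dataset(n_samples = 80, n_neurons = 5, effect = 0,
                              seed = 87)
  ds2$X <- matrix(rep(ds2$X[, 1], 5), ncol = 5)
  rk2 <- rank_best_neurons(ds2, repeats = 2, seed = 11)
  expect_equal(rk2$da, sort(rk2$da, decreasing = TRUE))
  # graded amplitudes rank by amplitude
  amps <- c(2, 1, 0.5, 0)
  hits <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    X <- matrix(rnorm(200 * 4), 200, 4)
    y <- rep(0:1, each = 100)
    for (j in 1:4) X[y == 1, j] <- X[y == 1, j] + amps[j]
    dsg <- make_planted_dataset(n_samples = 200, n_neurons = 4, seed = 1)
    dsg$X <- X; dsg$y <- y
    rkg <- rank_best_neurons(dsg, repeats = 2, seed = 500 + s)
    if (identical(rkg$neuron, 1:4)) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("cross-stimulus transfer tracks coding overlap", {
  # shared coding: same neurons, same amplitudes in both stimuli
  shared_tr <- make_planted_dataset(240, 30, coding = 1:15, effect = 2,
                                    seed = 88)
  shared_te <- make_planted_dataset(240, 30, coding = 1:15, effect = 2,
                                    seed = 89)
  within <- decode_single_region(shared_te, repeats = 5, seed = 12)$da
  tra <- cross_stimulus_transfer(shared_tr, shared_te, repeats = 10,
                                 seed = 13)
  expect_lt(abs(tra$mean - within), 0.1)
  # shuffled-test control at chance
  expect_gte(mean(tra$shuffled), 0.44)
  expect_lte(mean(tra$shuffled), 0.56)
  # disjoint coding: orthogonal neuron subsets
  dis_tr <- make_planted_dataset(240, 30, coding = 1:15, effect = 2,
                                 seed = 90)
  dis_te <- make_planted_dataset(240, 30, coding = 16:30, effect = 2,
                                 seed = 91)
  within_d <- decode_single_region(dis_te, repeats = 5, seed = 14)$da
  tra_d <- cross_stimulus_transfer(dis_tr, dis_te, repeats = 10, seed = 15)
  expect_gte(within_d, 0.85)
  expect_lte(tra_d$mean, 0.6)
  expect_error(cross_stimulus_transfer(shared_tr,
                                       make_planted_dataset(100, 5)),
               "feature")
})

test_that("conditional CS accuracy separates shared from disjoint R/F coding", {
  # R and F bins generated identically -> CS classes indistinguishable
  same <- make_planted_dataset(240, 20, n_classes = 3,
                               coding = list(1:10, 1:10), effect = 2,
                               seed = 92)
  r_same <- discriminate_cs(same, repeats = 6, seed = 16)
  expect_true(r_same$conditional_defined)
  expect_lt(abs(r_same$conditional - 0.5), 0.1)
  # disjoint R/F coding -> conditional accuracy high
  dis <- make_planted_dataset(240, 20, n_classes = 3,
                              coding = list(1:10, 11:20), effect = 2,
                              seed = 93)
  r_dis <- discriminate_cs(dis, repeats = 6, seed = 17)
  expect_gte(r_dis$conditional, 0.85)
  expect_gt(r_dis$overall, 0.6)
  expect_error(discriminate_cs(make_planted_dataset(60, 5)), "three")
})

test_that("three-class shuffled labels decode at three-way chance", {
  ds <- make_planted_dataset(240, 15, n_classes = 3,
                             coding = list(1:7, 8:15), effect = 2,
                             seed = 94)
  sh <- decode_single_region(ds, repeats = 10, shuffle = TRUE, seed = 18)
  expect_gte(sh$da, 0.28)
  expect_lte(sh$da, 0.39)
})

test_that("multi-region draws are proportional and importances sum to one", {
  expect_equal(entrain:::largest_remainder(c(400, 300, 200, 100), 100),
               c(40L, 30L, 20L, 10L))
  expect_equal(sum(entrain:::largest_remainder(c(113, 98, 48, 54, 29), 100)),
               100L)
  regions <- rep(c("aIC", "pIC", "CE_SST", "CEm"), c(16, 12, 8, 4))
  ds <- make_planted_dataset(160, 40, coding = 1:16, effect = 2,
                             regions = regions, seed = 95)
  mr <- decode_multi_region(ds, n_total = 20, repeats = 6, seed = 19)
  expect_gte(mr$result$da, 0.8)
  # per-iteration importances over drawn neurons sum to 1
  alloc <- entrain:::largest_remainder(c(16, 12, 8, 4), 20)
  sums <- mr$importance$iters %*% alloc
  expect_equal(as.vector(sums), rep(1, 6), tolerance = 1e-9)
  # only aIC carries signal -> highest mean importance
  expect_equal(names(which.max(mr$importance$region_mean)), "aIC")
})

test_that("importance contrasts are null for identical profiles and powered for shifts", {
  base <- matrix(rnorm(40 * 3, mean = 0.2, sd = 0.02), 40, 3,
                 dimnames = list(NULL, c("aIC", "pIC", "CEm")))
  prof <- function(m) structure(list(regions = colnames(m), iters = m,
                                     region_mean = colMeans(m),
                                     neuron_mean = NULL, n_iter = nrow(m)),
                                class = "importance_profile")
  a <- prof(base)
  eq <- contrast_importance(a, a, n_perm = 500, seed = 20)
  expect_true(all(eq$difference == 0))
  expect_true(all(eq$p_value > 0.9))
  # disjoint distributions reach the permutation floor
  b <- prof(base + 1)
  lo <- contrast_importance(a, b, n_perm = 500, seed = 21)
  expect_true(all(lo$p_value <= 1 / 501 + 1e-12))
  # 1 SD shift in one region detected most of the time
  hits <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    m1 <- matrix(rnorm(40 * 2, 0.2, 0.02), 40, 2,
                 dimnames = list(NULL, c("aIC", "pIC")))
    m2 <- m1
    m2[, 1] <- rnorm(40, 0.22, 0.02)
    ct <- contrast_importance(prof(m1), prof(m2), n_perm = 400,
                              seed = 700 + s)
    if (ct$p_value[1] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
  expect_error(contrast_importance(a, prof(base[, 1:2])), "region")
})
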