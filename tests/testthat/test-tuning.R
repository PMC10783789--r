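# Per-neuron tuning scores: TS selectivity, movement tuning, explained
# variance with surrogate significance, PETH onset lags.

test_that("TS selectivity matches hand-computed worked examples", {
  # activity only during TS -> +1
  expect_equal(ts_selectivity(rep(0, 4), c(0, 1, 2)), 1)
  # equal scaled means -> 0
  expect_equal(ts_selectivity(c(0, 0, 2, 2), c(0, 2)), 0)
  # baseline [0,0,0,4], TS [4,4]: scaled means 0.25 and 1 -> 0.6
  expect_equal(ts_selectivity(c(0, 0, 0, 4), c(4, 4)), 0.6)
  # transient mode: rates 0.25 vs 0.5 -> (0.5-0.25)/0.75
  expect_equal(ts_selectivity(c(TRUE, FALSE, FALSE, FALSE), c(TRUE, FALSE),
                              mode = "transient"), 1 / 3)
  # zero denominator -> flagged missing, never 0
  expect_true(is.na(ts_selectivity(c(FALSE, FALSE), c(FALSE, FALSE),
                                   mode = "transient")))
  expect_true(is.na(ts_selectivity(rep(1, 5), rep(1, 5))))  # zero range
})

test_that("TS selectivity is antisymmetric under segment swap", {
  set.seed(7)
  for (i in 1:20) {
    a <- runif(50); b <- runif(30) * 2
    expect_equal(ts_selectivity(a, b), -ts_selectivity(b, a), tolerance = 1e-12)
  }
})

test_that("selectivity classification uses exclusive +/-0.2 boundaries", {
  expect_identical(classify_selectivity(c(0.25, -0.2, 0, 0.2, -0.21, NA)),
                   c("TS", "none", "none", "none", "baseline", "none"))
})

test_that("movement score is Pearson r with affine invariance", {
  expect_equal(movement_score(1:10, 1:10), 1)
  expect_equal(movement_score(1:10, -(1:10)), -1)
  # hand-computed: r = 5 / sqrt(30)
  expect_equal(movement_score(c(0, 1, 2, 3), c(1, 1, 2, 4)), 5 / sqrt(30),
               tolerance = 1e-12)
  set.seed(1)
  sp <- runif(100); tr <- rnorm(100)
  expect_equal(movement_score(2 * sp + 3, 5 * tr + 1), movement_score(sp, tr),
               tolerance = 1e-12)
  expect_true(is.na(movement_score(rep(1, 10), rnorm(10))))
  expect_identical(classify_movement(c(0.3, -0.3, 0.1)),
                   c("struggle", "immobility", "none"))
})

test_that("movement EV is exact for noiseless linear coupling and ~0 otherwise", {
  set.seed(2)
  sp <- runif(2000)
  expect_equal(movement_ev(2 * sp + 1, sp), 1, tolerance = 1e-10)
  evs <- replicate(20, movement_ev(rnorm(10000), runif(10000)))
  expect_lt(mean(evs), 0.02)
})

test_that("EV surrogate significance detects real coupling and is seeded", {
  set.seed(3)
  sp <- as.numeric(arima.sim(list(ar = 0.95), 3000))
  sig <- ev_significance(sp, sp, n_surrogates = 50, frame_rate = 20, seed = 5)
  expect_true(as.logical(sig))
  expect_equal(attr(sig, "ev"), 1, tolerance = 1e-8)
  tr <- rnorm(3000)
  s1 <- ev_significance(tr, sp, n_surrogates = 50, frame_rate = 20, seed = 9)
  s2 <- ev_significance(tr, sp, n_surrogates = 50, frame_rate = 20, seed = 9)
  expect_identical(attr(s1, "threshold"), attr(s2, "threshold"))
  expect_error(ev_significance(rnorm(100), rnorm(100), frame_rate = 20),
               "shift range")
})

test_that("population EV is ~1 when the target equals a predictor", {
  set.seed(4)
  pop <- matrix(rnorm(60 * 1500), 60)
  ev <- population_ev(pop[7, ], pop, n_predictors = 50, seed = 1)
  expect_gt(ev, 0.999)
  # pure-noise target from a noise population
  ev0 <- population_ev(rnorm(1500), pop, n_predictors = 50, seed = 1)
  expect_lt(ev0, 0.05)
  expect_error(population_ev(rnorm(100), matrix(rnorm(100), 10, 10),
                             n_predictors = 50), "fewer than")
})

test_that("PETH lags recover constructed delays and handle degenerate cases", {
  p <- generator_params(n_neurons = 5L, n_frames_baseline = 500L,
                        n_frames_ts = 4000L)
  s <- generate_session(p, seed = 3)$session
  sp <- s$behavior$speed_mean
  lag_fr <- 4L  # +0.2 s at 20 Hz
  s$calcium$values[1, ] <- c(rep(sp[1], lag_fr), head(sp, -lag_fr)) +
    rnorm(length(sp), 0, 1e-6)
  s$calcium$values[2, ] <- sp
  pr <- peth_lag(s, c("struggle", "struggle", rep("none", 3)))
  expect_equal(pr$lag_s[pr$neuron_row == 1], 0.2, tolerance = 0.051)
  expect_equal(pr$lag_s[pr$neuron_row == 2], 0)
  expect_true(all(abs(pr$lag_s) <= 0.5))
  expect_length(attr(pr, "grid_s"), 21)
  # single analyzed neuron: significance SD undefined -> flagged
  pr1 <- peth_lag(s, c("struggle", rep("none", 4)))
  expect_true(all(is.na(pr1$significant)))
  # no neurons of either class -> empty result
  pr0 <- peth_lag(s, rep("none", 5))
  expect_identical(nrow(pr0), 0L)
})

test_that("tuning_table recovers generator structure on a small session", {
  out <- small_session()
  tun <- tuning_table(out$session)
  tr <- out$truth
  expect_true(all(tun$ts_selectivity_raw >= -1 & tun$ts_selectivity_raw <= 1,
                  na.rm = TRUE))
  expect_gt(cor(tr$movement_beta, tun$movement_score_TS, method = "spearman"),
            0.7)
  # movement tuning is TS-specific by construction
  expect_gt(mean(abs(tun$movement_score_TS), na.rm = TRUE),
            mean(abs(tun$movement_score_baseline), na.rm = TRUE))
})
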