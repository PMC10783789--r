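# Balanced cross-validated decoding with circular-shift surrogates.

test_that("balance_binary keeps the minority class and equalizes counts", {
  labels <- rep(c("a", "b"), c(100, 60))
  idx <- balance_binary(labels, seed = 1)
  expect_identical(as.integer(table(labels[idx])), c(60L, 60L))
  expect_true(all(which(labels == "b") %in% idx))
  expect_identical(sort(idx), idx)
  # already balanced -> unchanged
  lab2 <- rep(c("a", "b"), 60)
  expect_identical(balance_binary(lab2, 3), seq_along(lab2))
  # different seeds: same counts, different majority subsets
  i1 <- balance_binary(labels, 1); i2 <- balance_binary(labels, 2)
  expect_identical(length(i1), length(i2))
  expect_false(identical(i1, i2))
  expect_error(balance_binary(rep("a", 5)), "2 classes")
})

test_that("circular-shift surrogates preserve per-neuron marginals and autocovariance", {
  set.seed(5)
  x <- matrix(rnorm(6 * 500), 6)
  sh <- circular_shift_surrogate(x, seed = 2)
  for (i in 1:6) {
    expect_identical(sort(sh[i, ]), sort(x[i, ]))
    # circular autocovariance via the power spectrum is shift-invariant
    expect_equal(Mod(fft(sh[i, ]))^2, Mod(fft(x[i, ]))^2, tolerance = 1e-6)
  }
  expect_false(identical(sh, x))
  expect_identical(circular_shift_surrogate(x, 9), circular_shift_surrogate(x, 9))
})

test_that("decoders find a perfectly informative neuron and stay at chance otherwise", {
  set.seed(6)
  n <- 2000
  labels <- rep(c("struggle", "immobility"), each = n / 2)[sample(n)]
  traces <- matrix(rnorm(12 * n), 12)
  traces[1, ] <- ifelse(labels == "struggle", 1, -1) + rnorm(n, 0, 0.1)
  res <- decode_binary(traces, labels, model = "logistic", C = 0.01, seed = 1)
  expect_gte(res$mean_score, 0.95)
  # labels independent of traces -> accuracy near 0.5
  null <- decode_binary(matrix(rnorm(12 * n), 12), labels, seed = 1)
  expect_within(null$mean_score, 0.5, 0.06)
})

test_that("all four classifier families agree on an informative session", {
  out <- generate_session(small_params(), seed = 17)
  v <- out$session$calcium$values
  cop <- out$session$behavior$coping
  accs <- vapply(c("logistic", "svc", "ridge", "gnb"), function(m)
    decode_binary(v, cop, model = m, C = 0.01, seed = 2)$mean_score, numeric(1))
  expect_true(all(accs > 0.75))
  expect_lt(max(accs) - min(accs), 0.1)
})

test_that("ridge speed decoding recovers linear population coding", {
  set.seed(8)
  n <- 3000
  sp <- as.numeric(arima.sim(list(ar = 0.9), n))
  w <- rnorm(20)
  traces <- outer(w, sp) + matrix(rnorm(20 * n, 0, 0.3), 20)
  res <- decode_speed(traces, sp, seed = 1)
  expect_gte(res$mean_score, 0.9)
  # surrogate traces carry no speed information
  res_s <- decode_speed(traces, sp, n_surrogates = 5, seed = 1)
  expect_within(res_s$surrogate_mean, 0, 0.1)
})

test_that("cross-condition decoding shares fold templates and reduces within-condition", {
  out <- small_session()
  s <- out$session
  v <- s$calcium$values
  sp <- s$behavior$speed_mean
  i_ts <- which(s$behavior$context == "TS")
  i_b <- which(s$behavior$context == "baseline")
  within <- decode_speed(v, sp, idx = i_ts[seq_along(i_b)], seed = 3)
  cross_same <- cross_condition_decode(v, sp, i_ts[seq_along(i_b)],
                                       i_ts[seq_along(i_b)], seed = 3)
  expect_identical(within$fold_scores, cross_same$fold_scores)
  tsb <- cross_condition_decode(v, sp, i_ts, i_b, seed = 3)
  expect_identical(tsb$folds, cross_same$folds[seq_along(tsb$folds)])
  # TS-only movement coding: TS->TS informative, TS->baseline at chance
  tst <- cross_condition_decode(v, sp, i_ts, i_ts, seed = 3)
  expect_gt(tst$mean_score, 0.6)
  expect_within(tsb$mean_score, 0, 0.15)
})

test_that("across-day decoding via registered neurons matches within-day accuracy", {
  p <- generator_params(n_neurons = 80L, n_frames_baseline = 1200L,
                        n_frames_ts = 2400L)
  md <- generate_multiday(p, days = c(1, 3), seed = 13)
  res <- across_day_decode(md$sessions, md$map, "coping", seed = 5)
  expect_named(res, c("day1", "day3"))
  expect_gt(res$day1$mean_score, 0.8)
  expect_lt(abs(res$day3$mean_score - res$day1$mean_score), 0.12)
  # one shared fold partition across test days
  expect_identical(res$day1$folds, res$day3$folds)
  expect_error(across_day_decode(md$sessions, md$map, "coping", train_day = 9),
               "train_day")
})

test_that("compare_to_null summarizes effect and percentile, guarding folds", {
  out <- small_session()
  v <- out$session$calcium$values
  cop <- out$session$behavior$coping
  real <- decode_binary(v, cop, C = 0.01, n_surrogates = 5, seed = 4)
  cmp_self <- compare_to_null(real, real)
  expect_equal(cmp_self$difference, real$mean_score - mean(real$surrogate_means))
  # real far above every surrogate -> percentile 100
  expect_equal(cmp_self$percentile, 100)
  other <- decode_binary(v, cop, C = 0.01, folds = 5, seed = 4)
  expect_error(compare_to_null(real, other), "fold indices differ")
})
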