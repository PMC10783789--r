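# Synthetic-data generator: behavior tiling, latent ring, session synthesis,
# multi-day overlap, cohort structure.

test_that("bout tiling hits the day's immobility-fraction schedule", {
  p <- generator_params(n_frames_baseline = 0L, n_frames_ts = 12000L)
  # schedule (0.4, 0.6, 0.6) for days 1, 3, 9
  for (day in c(1, 3, 9)) {
    b <- generate_behavior(p, day, seed = 21)
    cop <- attr(b, "true_coping")
    ts <- cop[cop != "not_applicable"]
    frac <- mean(ts == "immobility")
    target <- c(`1` = 0.4, `3` = 0.6, `9` = 0.6)[[as.character(day)]]
    expect_within(frac, target, 0.05)
  }
  # degenerate target 1 -> every TS frame immobility
  p1 <- generator_params(n_frames_baseline = 100L, n_frames_ts = 500L,
                         immobility_schedule = c(1, 1, 1))
  b1 <- generate_behavior(p1, 1, seed = 1)
  expect_true(all(attr(b1, "true_coping")[101:600] == "immobility"))
})

test_that("behavior speeds separate coping states and satisfy invariants", {
  b <- generate_behavior(small_params(), 1, seed = 3)
  cop <- attr(b, "true_coping")
  expect_gt(mean(b$speed_mean[cop == "struggle"]),
            mean(b$speed_mean[cop == "immobility"]))
  expect_true(all(b$speed_mean >= 0))
  # ambiguous frames sit only in TS and only near transitions
  expect_true(all(b$context[b$coping == "ambiguous"] == "TS"))
  expect_true(all((b$coping == "not_applicable") == (b$context == "baseline")))
})

test_that("latent phase advances monotonically within epochs and rotates one way", {
  p0 <- generator_params(n_frames_baseline = 0L, n_frames_ts = 2000L,
                         phase_noise_sd = 0, radius_noise_sd = 0)
  b <- generate_behavior(p0, 1, seed = 5)
  lat <- generate_latent(b, p0, seed = 5)
  cop <- attr(b, "true_coping")
  ep <- rle(cop)
  first_struggle <- which(ep$values == "struggle")[1]
  i0 <- sum(ep$lengths[seq_len(first_struggle - 1)]) + 1
  i1 <- i0 + ep$lengths[first_struggle] - 1
  expect_true(all(diff(lat$phase[i0:i1]) > 0))
  # noise-free ring turns one way on every step
  ta <- turn_angles(lat$latent[, 1:2], n_bins = nrow(lat$latent))
  expect_equal(ta$leftward_fraction, 1)
})

test_that("with phase noise 0.1 rad most turns keep one rotational direction", {
  p <- generator_params(n_frames_baseline = 0L, n_frames_ts = 8000L)
  lat <- generate_latent(generate_behavior(p, 1, seed = 2), p, seed = 2)
  ta <- turn_angles(lat$latent[, 1:2], n_bins = 8000)
  expect_gte(ta$leftward_fraction, 0.9)
})

test_that("sessions are deterministic under the seed and satisfy invariants", {
  a <- generate_session(small_params(), seed = 8)
  b <- generate_session(small_params(), seed = 8)
  expect_identical(a$session$calcium$values, b$session$calcium$values)
  expect_identical(a$session$behavior$speed_mean, b$session$behavior$speed_mean)
  expect_identical(a$truth$loadings, b$truth$loadings)
  # traces are z-scored over the full session
  v <- a$session$calcium$values
  expect_lt(max(abs(rowMeans(v))), 1e-10)
  expect_equal(apply(v, 1, sd), rep(1, nrow(v)), tolerance = 1e-10)
})

test_that("ground-truth class labels are recomputable from gain and beta", {
  tr <- small_session()$truth
  expect_identical(tr$true_selectivity_class,
                   ifelse(tr$context_gain > 1, "TS",
                          ifelse(tr$context_gain < 1, "baseline", "none")))
  expect_identical(tr$true_movement_class,
                   ifelse(tr$movement_beta > 0, "struggle",
                          ifelse(tr$movement_beta < 0, "immobility", "none")))
})

test_that("untuned sessions give selectivity scores centered at zero", {
  p <- generator_params(n_neurons = 200L, n_frames_baseline = 2000L,
                        n_frames_ts = 2000L, frac_ts_selective = 0,
                        frac_baseline_selective = 0, frac_struggle_tuned = 0,
                        frac_immobility_tuned = 0)
  out <- generate_session(p, seed = 31)
  tun <- tuning_table(out$session)
  expect_lt(abs(median(tun$ts_selectivity_raw, na.rm = TRUE)), 0.05)
})

test_that("a neuron silenced in TS scores strongly baseline-selective", {
  p <- small_params()
  truth <- generate_ground_truth(p, seed = 12)
  truth$context_gain[1] <- 0
  truth$movement_beta[1] <- 0
  out <- generate_session(p, 1, truth, seed = 12)
  tun <- tuning_table(out$session)
  expect_lt(tun$ts_selectivity_raw[1], -0.8)
})

test_that("multi-day generation keeps per-day counts comparable and maps exact", {
  p <- generator_params(n_neurons = 1000L, n_frames_baseline = 100L,
                        n_frames_ts = 300L)
  md <- generate_multiday(p, days = c(1, 3, 9), seed = 9)
  counts <- vapply(md$sessions, function(s) nrow(s$calcium$values), integer(1))
  expect_lt(max(counts) / min(counts), 1.15)
  # presence probability 1 -> all neurons repeatedly identified
  p1 <- generator_params(n_neurons = 50L, n_frames_baseline = 100L,
                         n_frames_ts = 300L, presence_p = 1)
  md1 <- generate_multiday(p1, days = c(1, 3), seed = 2)
  expect_identical(repeatedly_identified(md1$map), 1:50)
})

test_that("cohort animals get orthogonal latent mixing and independent behavior", {
  p <- generator_params(n_neurons = 30L, n_frames_baseline = 200L,
                        n_frames_ts = 600L)
  coh <- generate_cohort(p, 3, seed = 6, days = 1)
  d <- 2 + p$nuisance_dims
  for (an in coh) {
    expect_lt(max(abs(crossprod(an$truth$mixing) - diag(d))), 1e-10)
  }
  # different mixing across animals, independent behavior realizations
  expect_gt(max(abs(coh[[1]]$truth$mixing - coh[[2]]$truth$mixing)), 0.01)
  expect_false(identical(coh[[1]]$sessions[[1]]$behavior$coping,
                         coh[[2]]$sessions[[1]]$behavior$coping))
})
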