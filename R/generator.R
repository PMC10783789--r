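# Synthetic multi-day, multi-animal session generator with known ground truth.
#
# The generative model: a shared low-dimensional latent trajectory (a ring
# traversed once per struggle/immobility cycle plus white-noise nuisance
# dimensions) drives per-neuron event rates through a softplus-linear link;
# movement-tuned neurons additionally couple to TS speed; context-selective
# neurons carry a multiplicative TS gain. Poisson events are convolved with an
# exponential calcium kernel (tau emulating GCaMP6f), corrupted with additive
# Gaussian noise, and z-scored.

#' Generator parameters
#'
#' Defaults describe the emulated study conditions: 200 neurons, 10 min of
#' baseline followed by 10 min of TS at 20 Hz, lognormal coping bouts whose
#' immobility fraction rises from 0.4 (day 1) to 0.6 (days 3/9), 12% of
#' neurons TS-selective and 20% baseline-selective, 25% struggle- and 25%
#' immobility-tuned during TS only, a GCaMP6f-like kernel (tau 0.6 s) and a
#' high post-denoising SNR (additive noise SD 0.03 on unit-amplitude
#' transients), and 74% per-day detection probability (so about 0.74^3 = 0.41
#' of neurons are detected on all three days).
#'
#' @param ... named overrides of any default.
#' @return A named list of class `generator_params`.
#' @export
generator_params <- function(...) {
  p <- list(
    n_neurons = 200L,
    n_frames_baseline = 12000L,
    n_frames_ts = 12000L,
    frame_rate = 20,
    # behavior
    struggle_bout_mean_s = 4,
    bout_sdlog = 0.6,
    schedule_days = c(1L, 3L, 9L),
    immobility_schedule = c(0.4, 0.6, 0.6),
    ambiguous_margin_frames = 2L,
    baseline_speed_mean = 2,
    struggle_speed_mean = 6,
    immobility_speed_mean = 0.2,
    speed_noise_sd = 1.5,
    # latent ring
    nuisance_dims = 3L,
    phase_noise_sd = 0.1,
    radius_noise_sd = 0.05,
    # neuron tuning
    frac_ts_selective = 0.12,
    frac_baseline_selective = 0.20,
    gain_ts_range = c(3, 6),
    gain_baseline_range = c(1/6, 1/3),
    frac_struggle_tuned = 0.25,
    frac_immobility_tuned = 0.25,
    beta_range = c(1.2, 2.5),
    speed_scale = 4,
    loading_sd_ring = 0.25,
    loading_sd_nuisance = 0.2,
    # calcium synthesis
    rate_hz = 2,
    tau_s = 0.6,
    amp_sdlog = 0.3,
    noise_sd = 0.03,
    # multi-day
    presence_p = 0.74,
    loading_jitter_sd = 0.05,
    activity_drift = 0,
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(p))
    stop_if_not(length(unknown) == 0,
                "unknown generator parameter(s): ", paste(unknown, collapse = ", "))
    p[names(over)] <- over
  }
  stop_if_not(p$tau_s > 0, "generator: tau_s must be > 0")
  stop_if_not(all(p$immobility_schedule >= 0 & p$immobility_schedule <= 1),
              "generator: immobility fractions must be in [0, 1]")
  stop_if_not(p$presence_p >= 0 && p$presence_p <= 1,
              "generator: presence_p must be in [0, 1]")
  stop_if_not(p$frac_ts_selective + p$frac_baseline_selective <= 1,
              "generator: selectivity fractions exceed 1")
  stop_if_not(p$frac_struggle_tuned + p$frac_immobility_tuned <= 1,
              "generator: movement fractions exceed 1")
  structure(p, class = "generator_params")
}

immobility_fraction_for_day <- function(params, day) {
  i <- match(day, params$schedule_days)
  if (is.na(i)) i <- length(params$immobility_schedule)
  params$immobility_schedule[i]
}

# exact-total alternating bout tiling ---------------------------------------

# Draw lognormal bout durations and rescale each coping state's total so the
# realized immobility fraction matches the day target up to frame rounding.
tile_bouts <- function(n_frames, frac_immobility, mean_struggle_frames,
                       sdlog) {
  if (frac_immobility >= 1) return(rep("immobility", n_frames))
  if (frac_immobility <= 0) return(rep("struggle", n_frames))
  mean_imm <- mean_struggle_frames * frac_immobility / (1 - frac_immobility)
  cycle <- mean_struggle_frames + mean_imm
  n_bouts <- max(1L, as.integer(round(n_frames / cycle)))
  meanlog_s <- log(mean_struggle_frames) - sdlog^2 / 2
  meanlog_i <- log(mean_imm) - sdlog^2 / 2
  dur_s <- rlnorm(n_bouts, meanlog_s, sdlog)
  dur_i <- rlnorm(n_bouts, meanlog_i, sdlog)
  dur_s <- dur_s / sum(dur_s) * n_frames * (1 - frac_immobility)
  dur_i <- dur_i / sum(dur_i) * n_frames * frac_immobility
  durs <- as.vector(rbind(dur_s, dur_i))
  edges <- round(cumsum(durs))
  edges[length(edges)] <- n_frames
  edges <- pmin(pmax(edges, 0), n_frames)
  labels <- rep(c("struggle", "immobility"), n_bouts)
  out <- character(n_frames)
  start <- 0
  for (b in seq_along(durs)) {
    if (edges[b] > start) out[(start + 1):edges[b]] <- labels[b]
    start <- max(start, edges[b])
  }
  out
}

# smooth nonnegative speed process
smooth_speed <- function(n, mean, sd, frame_rate, floor = 0) {
  if (n == 0) return(numeric(0))
  x <- gaussian_smooth(rnorm(n), sigma = 0.25 * frame_rate)
  x <- x / max(sd(x), 1e-12) * sd
  pmax(floor, mean + x)
}

#' Generate one day's behavior annotations
#'
#' A baseline segment followed by a TS segment tiled with alternating
#' struggle/immobility bouts of lognormal duration; the day's target
#' immobility fraction is met up to frame rounding. Speed is a high-mean noisy
#' process during struggle, near zero during immobility, and an independent
#' moderate process during baseline. Frames at coping-bout boundaries are
#' labeled ambiguous; the unambiguous bout labels are kept in the
#' `true_coping` attribute (ground truth for the latent trajectory).
#'
#' @param params a [generator_params()].
#' @param day integer day (selects the immobility-fraction schedule entry).
#' @param seed integer seed.
#' @return A [behavior_track()].
#' @export
generate_behavior <- function(params = generator_params(), day = 1,
                              seed = params$seed) {
  with_seed(child_seed(seed, 101, day), {
    n_b <- params$n_frames_baseline
    n_t <- params$n_frames_ts
    fr <- params$frame_rate
    frac <- immobility_fraction_for_day(params, day)
    ts_lab <- tile_bouts(n_t, frac, params$struggle_bout_mean_s * fr,
                         params$bout_sdlog)
    coping <- c(rep("not_applicable", n_b), ts_lab)
    # ambiguous margin around each internal coping transition
    m <- params$ambiguous_margin_frames
    labeled <- coping
    if (m > 0 && n_t > 1) {
      trans <- which(ts_lab[-1] != ts_lab[-n_t])
      for (tt in trans) {
        idx <- (tt - m + 1):(tt + m)
        idx <- idx[idx >= 1 & idx <= n_t]
        labeled[n_b + idx] <- "ambiguous"
      }
    }
    sp <- numeric(n_b + n_t)
    sp[seq_len(n_b)] <- smooth_speed(n_b, params$baseline_speed_mean, 1, fr)
    i_str <- n_b + which(ts_lab == "struggle")
    i_imm <- n_b + which(ts_lab == "immobility")
    sp[i_str] <- smooth_speed(length(i_str), params$struggle_speed_mean,
                              params$speed_noise_sd, fr, floor = 0.5)
    sp[i_imm] <- abs(rnorm(length(i_imm), params$immobility_speed_mean, 0.1))
    parts <- c("nose", "neck", "left_foot", "right_foot")
    speed_parts <- setNames(lapply(parts, function(p) {
      pmax(0, sp * runif(1, 0.9, 1.1) +
             gaussian_smooth(rnorm(length(sp), 0, 0.3), 0.25 * fr))
    }), parts)
    b <- behavior_track(
      context = c(rep("baseline", n_b), rep("TS", n_t)),
      coping = labeled, speed_parts = speed_parts, frame_rate = fr)
    attr(b, "true_coping") <- coping
    b
  })
}

#' Generate the latent trajectory for a behavior track
#'
#' Two ring coordinates (cos phi, sin phi) where the phase advances from 0 to
#' pi across each struggle epoch and from pi to 2*pi across each immobility
#' epoch (one consistent rotation direction), plus configured white-noise
#' nuisance dimensions. Baseline frames carry no ring signal.
#'
#' @param behavior a [behavior_track()] (uses the `true_coping` attribute when
#'   present so ambiguous annotation does not perturb the latent).
#' @param params a [generator_params()].
#' @param seed integer seed.
#' @return List with `phase` (per-frame, NA during baseline) and `latent`
#'   (frames x (2 + nuisance_dims) matrix).
#' @export
generate_latent <- function(behavior, params = generator_params(),
                            seed = params$seed) {
  with_seed(child_seed(seed, 202), {
    coping <- attr(behavior, "true_coping") %||% behavior$coping
    n <- length(coping)
    phase <- rep(NA_real_, n)
    r <- rle(coping)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (e in seq_along(r$values)) {
      v <- r$values[e]
      if (!v %in% c("struggle", "immobility")) next
      L <- r$lengths[e]
      prog <- (seq_len(L) - 0.5) / L * pi
      phase[starts[e]:ends[e]] <- prog + if (v == "struggle") 0 else pi
    }
    # temporally smooth phase jitter (marginal SD = phase_noise_sd); white
    # per-frame jitter would swamp the ~0.04 rad/frame epoch advance
    jitter <- gaussian_smooth(rnorm(n), 0.5 * behavior$frame_rate)
    jitter <- jitter / max(sd(jitter), 1e-12) * params$phase_noise_sd
    phase_noisy <- phase + jitter
    rjit <- gaussian_smooth(rnorm(n), 0.5 * behavior$frame_rate)
    radius <- 1 + rjit / max(sd(rjit), 1e-12) * params$radius_noise_sd
    ring <- cbind(cos(phase_noisy), sin(phase_noisy)) * radius
    ring[is.na(phase), ] <- 0
    nuis <- matrix(rnorm(n * params$nuisance_dims), n, params$nuisance_dims)
    list(phase = phase, latent = cbind(ring, nuis))
  })
}

#' Ground-truth neuron tuning for a simulated animal
#'
#' Draws context gains (g > 1: TS-preferring, g < 1: baseline-preferring),
#' TS-specific movement coefficients, latent loadings, and an optional
#' orthogonal latent mixing matrix; class labels are derived from g and the
#' movement coefficient sign.
#'
#' @param params a [generator_params()].
#' @param seed integer seed.
#' @param mixing optional (2 + nuisance_dims)-square orthogonal matrix rotating
#'   the shared latent into this animal's coordinates (default identity).
#' @return A list of class `ground_truth`.
#' @export
generate_ground_truth <- function(params = generator_params(),
                                  seed = params$seed, mixing = NULL) {
  with_seed(child_seed(seed, 303), {
    n <- params$n_neurons
    d <- 2L + params$nuisance_dims
    if (is.null(mixing)) mixing <- diag(d)
    stop_if_not(max(abs(crossprod(mixing) - diag(d))) < 1e-10,
                "ground truth: mixing matrix must be orthogonal")
    # context selectivity classes and gains
    n_ts <- round(params$frac_ts_selective * n)
    n_base <- round(params$frac_baseline_selective * n)
    sel_class <- rep("none", n)
    ord <- sample.int(n)
    sel_class[ord[seq_len(n_ts)]] <- "TS"
    sel_class[ord[n_ts + seq_len(n_base)]] <- "baseline"
    gain <- rep(1, n)
    gain[sel_class == "TS"] <- runif(n_ts, params$gain_ts_range[1],
                                     params$gain_ts_range[2])
    gain[sel_class == "baseline"] <- runif(n_base, params$gain_baseline_range[1],
                                           params$gain_baseline_range[2])
    # movement tuning (TS-only coupling)
    n_str <- round(params$frac_struggle_tuned * n)
    n_imm <- round(params$frac_immobility_tuned * n)
    mv_class <- rep("none", n)
    ord2 <- sample.int(n)
    mv_class[ord2[seq_len(n_str)]] <- "struggle"
    mv_class[ord2[n_str + seq_len(n_imm)]] <- "immobility"
    beta <- rep(0, n)
    beta[mv_class == "struggle"] <- runif(n_str, params$beta_range[1],
                                          params$beta_range[2])
    beta[mv_class == "immobility"] <- -runif(n_imm, params$beta_range[1],
                                             params$beta_range[2])
    loadings <- cbind(
      matrix(rnorm(n * 2, 0, params$loading_sd_ring), n, 2),
      matrix(rnorm(n * params$nuisance_dims, 0, params$loading_sd_nuisance),
             n, params$nuisance_dims))
    structure(list(
      context_gain = gain,
      movement_beta = beta,
      true_selectivity_class = sel_class,
      true_movement_class = mv_class,
      loadings = loadings,
      mixing = mixing,
      presence = NULL,
      latent = NULL), class = "ground_truth")
  })
}

#' Synthesize one session from behavior, latent, and ground truth
#'
#' Per-neuron instantaneous rate is
#' `rate_hz * softplus(loadings . mixing latent + beta * speed_TS / speed_scale)
#' / softplus(0) * gain^[context == TS]`; Poisson events with lognormal
#' amplitudes are convolved with an exponential kernel `exp(-t / tau)`,
#' Gaussian noise is added, and traces are z-scored over the whole session.
#' Transients are recomputed with [detect_transients()].
#'
#' @param params a [generator_params()].
#' @param day integer day.
#' @param truth optional shared [generate_ground_truth()] (for multi-day /
#'   multi-animal use); drawn fresh when NULL.
#' @param seed integer seed.
#' @param animal_id identifier stored in the session.
#' @param neuron_subset optional integer vector of truth rows present in this
#'   session (multi-day partial overlap); default all.
#' @param loading_jitter multiplicative lognormal jitter SD applied to this
#'   session's loadings (day-to-day variability), default 0.
#' @return `list(session = session_recording, truth = ground_truth)` with the
#'   session's latent stored in `truth$latent`.
#' @export
generate_session <- function(params = generator_params(), day = 1,
                             truth = NULL, seed = params$seed,
                             animal_id = "sim1", neuron_subset = NULL,
                             loading_jitter = 0) {
  behavior <- generate_behavior(params, day, seed)
  lat <- generate_latent(behavior, params, child_seed(seed, 7, day))
  if (is.null(truth)) truth <- generate_ground_truth(params, seed)
  stop_if_not(nrow(truth$loadings) == params$n_neurons,
              "generate_session: truth neuron count differs from params")
  if (is.null(neuron_subset)) neuron_subset <- seq_len(params$n_neurons)

  with_seed(child_seed(seed, 404, day), {
    n <- length(neuron_subset)
    nf <- n_frames(behavior)
    fr <- params$frame_rate
    L <- truth$loadings[neuron_subset, , drop = FALSE]
    if (loading_jitter > 0)
      L <- L * matrix(exp(rnorm(length(L), 0, loading_jitter)), nrow(L))
    z <- lat$latent %*% truth$mixing            # frames x d, animal coordinates
    drive <- L %*% t(z)                         # neurons x frames
    ts_mask <- behavior$context == "TS"
    speed_drive <- ifelse(ts_mask, behavior$speed_mean / params$speed_scale, 0)
    drive <- drive + outer(truth$movement_beta[neuron_subset], speed_drive)
    rate <- params$rate_hz * softplus(drive) / softplus(0)
    gain <- truth$context_gain[neuron_subset]
    rate[, ts_mask] <- rate[, ts_mask] * gain
    events <- matrix(rpois(n * nf, rate / fr), n, nf)
    amps <- matrix(0, n, nf)
    nz <- events > 0
    amps[nz] <- events[nz] * rlnorm(sum(nz), -params$amp_sdlog^2 / 2,
                                    params$amp_sdlog)
    decay <- exp(-1 / (params$tau_s * fr))
    signal <- t(apply(amps, 1, function(x)
      as.numeric(stats::filter(x, decay, method = "recursive"))))
    signal <- signal + matrix(rnorm(n * nf, 0, params$noise_sd), n, nf)
    values <- zscore_trace(signal)
    calcium <- calcium_traces(values, neuron_ids = neuron_subset,
                              frame_rate = fr)
    truth$latent <- lat$latent
    truth$phase <- lat$phase
    # noise-free oracle effect sizes from the underlying rate functions:
    # the net context effect of a neuron combines its gain with any
    # movement/latent drive, so the rate-based score is the honest reference
    # for what the trace-based estimate can recover
    i_base <- which(!ts_mask)
    truth$oracle_selectivity <- vapply(seq_len(n), function(i) {
      sc <- scale_minmax(rate[i, ])
      if (is.null(sc)) return(NA_real_)
      mb <- mean(sc[i_base]); mt <- mean(sc[-i_base])
      if (mb + mt == 0) return(NA_real_)
      (mt - mb) / (mt + mb)
    }, numeric(1))
    truth$oracle_movement <- vapply(seq_len(n), function(i) {
      r <- rate[i, ts_mask]
      if (sd(r) == 0) return(NA_real_)
      cor(behavior$speed_mean[ts_mask], r)
    }, numeric(1))
    list(session = session_recording(animal_id, day, calcium, behavior),
         truth = truth)
  })
}

#' Generate a multi-day recording with partial neuron overlap
#'
#' One shared ground truth; per-day presence is i.i.d. Bernoulli with
#' `presence_p`, present neurons keep their loadings up to small multiplicative
#' jitter, and the emitted registration table reflects presence exactly.
#'
#' @param params a [generator_params()].
#' @param days integer vector of at least 2 days.
#' @param seed integer seed.
#' @param animal_id identifier.
#' @param mixing optional orthogonal latent mixing matrix (see
#'   [generate_ground_truth()]).
#' @return `list(sessions = list of session_recording, map = registration_map,
#'   truth = ground_truth)` (presence matrix in `truth$presence`).
#' @export
generate_multiday <- function(params = generator_params(), days = c(1, 3, 9),
                              seed = params$seed, animal_id = "sim1",
                              mixing = NULL) {
  stop_if_not(length(days) >= 2, "generate_multiday: need at least 2 days")
  truth <- generate_ground_truth(params, seed, mixing = mixing)
  n <- params$n_neurons
  presence <- with_seed(child_seed(seed, 505), {
    matrix(runif(n * length(days)) < params$presence_p, n, length(days),
           dimnames = list(NULL, paste0("day", days)))
  })
  sessions <- vector("list", length(days))
  day_cols <- list()
  for (j in seq_along(days)) {
    subset <- which(presence[, j])
    out <- generate_session(params, days[j], truth,
                            seed = child_seed(seed, 606, days[j]),
                            animal_id = animal_id, neuron_subset = subset,
                            loading_jitter = params$loading_jitter_sd)
    sessions[[j]] <- out$session
    col <- rep(-1L, n)
    col[subset] <- seq_along(subset) - 1L   # 0-based local row index
    day_cols[[paste0("day", days[j])]] <- col
  }
  map <- do.call(registration_map, c(list(global_id = seq_len(n)), day_cols))
  truth$presence <- presence
  list(sessions = sessions, map = map, truth = truth)
}

#' Generate a cohort of animals sharing latent structure
#'
#' All animals share the same behavior-to-phase law; each animal has
#' independent neurons whose loadings act on the shared latent through a
#' per-animal Haar-random orthogonal mixing matrix, and an independent
#' behavior realization.
#'
#' @param params a [generator_params()].
#' @param n_animals number of animals (>= 2).
#' @param seed integer seed.
#' @param days days to simulate per animal (default day 1 only; a single day
#'   yields `map = NULL` for that animal).
#' @param identity_mixing use identity mixing for every animal (degenerate
#'   control in which template manifolds coincide up to noise).
#' @return List of per-animal `list(sessions, map, truth)`.
#' @export
generate_cohort <- function(params = generator_params(), n_animals = 2,
                            seed = params$seed, days = 1,
                            identity_mixing = FALSE) {
  stop_if_not(n_animals >= 2, "generate_cohort: need at least 2 animals")
  d <- 2L + params$nuisance_dims
  lapply(seq_len(n_animals), function(a) {
    s_a <- child_seed(seed, 707, a)
    mixing <- if (identity_mixing) diag(d) else
      with_seed(child_seed(s_a, 1), random_orthogonal(d))
    id <- paste0("animal", a)
    if (length(days) >= 2) {
      generate_multiday(params, days, s_a, animal_id = id, mixing = mixing)
    } else {
      truth <- generate_ground_truth(params, s_a, mixing = mixing)
      out <- generate_session(params, days[1], truth, seed = s_a,
                              animal_id = id)
      list(sessions = list(out$session), map = NULL, truth = out$truth)
    }
  })
}
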