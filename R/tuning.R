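# Per-neuron tuning: TS selectivity, movement tuning, linear-model explained
# variance with circular-shift surrogate significance, and PETH onset lags.

#' TS selectivity score
#'
#' The two context segments are concatenated and min-max scaled to \[0, 1\] per
#' neuron; the score is `(m_TS - m_base) / (m_TS + m_base)` of the scaled
#' means, ranging from -1 (active only during baseline) to +1 (active only
#' during TS). In `transient` mode the same ratio is computed on transient
#' rates from the boolean masks (the rate's time unit cancels in the ratio).
#'
#' @param baseline_trace,ts_trace numeric vectors (raw mode) or logical
#'   transient masks (transient mode) for the two contexts.
#' @param mode `"raw"` or `"transient"`.
#' @return Score in \[-1, 1\]; `NA` when the denominator is zero (flagged
#'   missing, never silently 0).
#' @export
ts_selectivity <- function(baseline_trace, ts_trace,
                           mode = c("raw", "transient")) {
  mode <- match.arg(mode)
  stop_if_not(length(baseline_trace) > 0 && length(ts_trace) > 0,
              "ts_selectivity: empty segment")
  if (mode == "raw") {
    scaled <- scale_minmax(c(baseline_trace, ts_trace))
    if (is.null(scaled)) return(NA_real_)
    m_base <- mean(scaled[seq_along(baseline_trace)])
    m_ts <- mean(scaled[-seq_along(baseline_trace)])
  } else {
    m_base <- mean(as.logical(baseline_trace))
    m_ts <- mean(as.logical(ts_trace))
  }
  if (m_base + m_ts == 0) return(NA_real_)
  (m_ts - m_base) / (m_ts + m_base)
}

#' Classify a TS selectivity score
#'
#' Scores below `-threshold` are baseline selective, above `+threshold` TS
#' selective; boundaries are exclusive. Missing scores classify as `"none"`.
#'
#' @param score numeric vector of selectivity scores.
#' @param threshold classification threshold (default 0.2).
#' @return Character vector in `c("baseline", "TS", "none")`.
#' @export
classify_selectivity <- function(score, threshold = 0.2) {
  out <- rep("none", length(score))
  out[!is.na(score) & score < -threshold] <- "baseline"
  out[!is.na(score) & score > threshold] <- "TS"
  out
}

#' Movement score
#'
#' Pearson correlation between a neuron's calcium trace and the animal's speed
#' within one context. Invariant to positive affine transforms of either input.
#'
#' @param speed,trace equal-length numeric vectors (one context's frames).
#' @return Correlation in \[-1, 1\]; `NA` for constant input.
#' @export
movement_score <- function(speed, trace) {
  stop_if_not(length(speed) == length(trace), "movement_score: length mismatch")
  if (sd(speed) == 0 || sd(trace) == 0) return(NA_real_)
  cor(speed, trace)
}

#' Classify a movement score
#'
#' @param score TS movement score(s).
#' @param threshold classification threshold (default 0.2): above `+threshold`
#'   struggle-selective, below `-threshold` immobility-selective.
#' @return Character vector in `c("struggle", "immobility", "none")`.
#' @export
classify_movement <- function(score, threshold = 0.2) {
  out <- rep("none", length(score))
  out[!is.na(score) & score > threshold] <- "struggle"
  out[!is.na(score) & score < -threshold] <- "immobility"
  out
}

# out-of-fold explained variance of a univariate linear fit; folds are
# contiguous temporal blocks (guards against autocorrelation leakage)
cv_ev_1d <- function(y, x, folds = 10) {
  n <- length(y)
  idx <- make_folds(n, folds)
  evs <- vapply(idx, function(test) {
    train <- setdiff(seq_len(n), test)
    xt <- x[train]; yt <- y[train]
    vx <- var(xt)
    b <- if (vx > 0) cov(xt, yt) / vx else 0
    a <- mean(yt) - b * mean(xt)
    pred <- a + b * x[test]
    sstot <- sum((y[test] - mean(y[test]))^2)
    if (sstot == 0) return(NA_real_)
    1 - sum((y[test] - pred)^2) / sstot
  }, numeric(1))
  if (anyNA(evs)) warning("movement_ev: ", sum(is.na(evs)),
                          " degenerate fold(s) skipped")
  mean(evs, na.rm = TRUE)
}

#' Explained variance of a neuron's trace from movement
#'
#' Cross-validated (contiguous 10-fold) out-of-fold explained variance
#' `1 - SSE/SStot` of a univariate linear regression of the calcium trace on
#' the continuous movement signal; may be negative.
#'
#' @param trace,speed equal-length numeric vectors.
#' @param folds number of contiguous folds.
#' @return Mean out-of-fold explained variance.
#' @export
movement_ev <- function(trace, speed, folds = 10) {
  stop_if_not(length(trace) >= folds, "movement_ev: trace shorter than folds")
  cv_ev_1d(trace, speed, folds)
}

#' Surrogate significance of movement explained variance
#'
#' The movement signal is circularly shifted by a uniform random offset of 20 s
#' to 2 min (either direction), EV is recomputed per surrogate, and the neuron
#' is significant iff the real EV exceeds the 95th percentile of the surrogate
#' EVs.
#'
#' @param trace,speed equal-length numeric vectors.
#' @param n_surrogates surrogate count (default 1000).
#' @param shift_range_s circular shift magnitude range in seconds.
#' @param alpha_percentile surrogate percentile the real EV must exceed.
#' @param frame_rate frames per second.
#' @param folds CV folds per EV evaluation.
#' @param seed integer seed.
#' @return Logical; attributes `ev` (real EV) and `threshold` (surrogate
#'   percentile).
#' @export
ev_significance <- function(trace, speed, n_surrogates = 1000,
                            shift_range_s = c(20, 120), alpha_percentile = 95,
                            frame_rate = 20, folds = 10, seed = 1) {
  n <- length(trace)
  lo <- sec_to_frames(shift_range_s[1], frame_rate)
  hi <- sec_to_frames(shift_range_s[2], frame_rate)
  stop_if_not(hi < n, "ev_significance: shift range exceeds trace length")
  real <- movement_ev(trace, speed, folds)
  surr <- with_seed(child_seed(seed, 11), {
    shifts <- sample(lo:hi, n_surrogates, replace = TRUE) *
      sample(c(-1L, 1L), n_surrogates, replace = TRUE)
    vapply(shifts, function(s) {
      sp <- circular_shift(speed, s)
      cv_ev_1d(trace, sp, folds)
    }, numeric(1))
  })
  thr <- quantile(surr, alpha_percentile / 100, names = FALSE)
  structure(real > thr, ev = real, threshold = thr)
}

# circular rotation by k frames (either sign)
circular_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Explained variance of a neuron from the population
#'
#' Cross-validated EV of a linear model predicting the target trace from
#' `n_predictors` randomly selected other neurons (the target is never among
#' the predictors).
#'
#' @param target_trace numeric vector.
#' @param other_traces neurons x frames matrix excluding the target.
#' @param n_predictors number of predictor neurons (default 50).
#' @param folds contiguous CV folds.
#' @param seed integer seed for predictor selection.
#' @return Mean out-of-fold explained variance.
#' @export
population_ev <- function(target_trace, other_traces, n_predictors = 50,
                          folds = 10, seed = 1) {
  stop_if_not(nrow(other_traces) >= n_predictors,
              "population_ev: fewer than ", n_predictors, " candidate neurons")
  sel <- with_seed(child_seed(seed, 13),
                   sample.int(nrow(other_traces), n_predictors))
  x <- t(other_traces[sel, , drop = FALSE])
  y <- target_trace
  n <- length(y)
  idx <- make_folds(n, folds)
  evs <- vapply(idx, function(test) {
    train <- setdiff(seq_len(n), test)
    fit <- stats::lm.fit(cbind(1, x[train, , drop = FALSE]), y[train])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- cbind(1, x[test, , drop = FALSE]) %*% beta
    sstot <- sum((y[test] - mean(y[test]))^2)
    if (sstot == 0) return(NA_real_)
    1 - sum((y[test] - pred)^2) / sstot
  }, numeric(1))
  mean(evs, na.rm = TRUE)
}

#' Per-neuron tuning table for one session
#'
#' Computes raw and transient-based TS selectivity, selectivity classes,
#' baseline and TS movement scores with movement classes, and (optionally)
#' movement explained variance with surrogate significance for
#' context-selective neurons.
#'
#' @param session a [session_recording()].
#' @param config an [analysis_config()].
#' @param compute_ev also compute `ev_movement` / `ev_significant` /
#'   `ev_population` for context-selective neurons (slower).
#' @param seed seed for the EV surrogates and population predictor draws.
#' @return A data frame with one row per neuron.
#' @export
tuning_table <- function(session, config = analysis_config(),
                         compute_ev = FALSE, seed = config$seed) {
  v <- session$calcium$values
  tr <- session$calcium$transients
  i_base <- context_frames(session, "baseline")
  i_ts <- context_frames(session, "TS")
  speed <- session$behavior$speed_mean
  n <- nrow(v)

  raw <- vapply(seq_len(n), function(i)
    ts_selectivity(v[i, i_base], v[i, i_ts], "raw"), numeric(1))
  trans <- vapply(seq_len(n), function(i)
    ts_selectivity(tr[i, i_base], tr[i, i_ts], "transient"), numeric(1))
  ms_base <- vapply(seq_len(n), function(i)
    movement_score(speed[i_base], v[i, i_base]), numeric(1))
  ms_ts <- vapply(seq_len(n), function(i)
    movement_score(speed[i_ts], v[i, i_ts]), numeric(1))

  out <- data.frame(
    neuron_id = session$calcium$neuron_ids,
    ts_selectivity_raw = raw,
    ts_selectivity_transient = trans,
    selectivity_class = classify_selectivity(raw, config$selectivity_threshold),
    movement_score_baseline = ms_base,
    movement_score_TS = ms_ts,
    movement_class = classify_movement(ms_ts, config$movement_threshold),
    stringsAsFactors = FALSE)

  if (compute_ev) {
    out$ev_movement <- NA_real_
    out$ev_significant <- NA
    out$ev_population <- NA_real_
    for (i in which(out$selectivity_class != "none")) {
      frames <- if (out$selectivity_class[i] == "TS") i_ts else i_base
      sig <- ev_significance(v[i, frames], speed[frames],
                             n_surrogates = config$n_surrogates_ev,
                             shift_range_s = config$shift_range_s,
                             alpha_percentile = config$ev_alpha_percentile,
                             frame_rate = session$behavior$frame_rate,
                             folds = config$folds,
                             seed = child_seed(seed, i))
      out$ev_movement[i] <- attr(sig, "ev")
      out$ev_significant[i] <- as.logical(sig)
      out$ev_population[i] <- population_ev(
        v[i, frames], v[-i, frames, drop = FALSE],
        n_predictors = min(config$population_predictors, n - 1),
        folds = config$folds, seed = child_seed(seed, i, 2))
    }
  }
  out
}

# PETH onset-lag analysis ----------------------------------------------------

# onsets of bouts of one coping type, restricted to events whose full
# [-w, +w] window lies inside the recording
coping_onsets <- function(session, type, window_frames) {
  coping <- attr(session$behavior, "true_coping") %||% session$behavior$coping
  is_type <- coping == type
  on <- which(is_type & !c(FALSE, is_type[-length(is_type)]))
  on[on - window_frames >= 1 & on + window_frames <= length(coping)]
}

# event-triggered average with per-event z-scoring over the window
event_average <- function(x, onsets, w) {
  mats <- lapply(onsets, function(o) {
    seg <- x[(o - w):(o + w)]
    s <- sd(seg)
    if (!is.finite(s) || s == 0) return(NULL)
    (seg - mean(seg)) / s
  })
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) == 0) return(NULL)
  colMeans(do.call(rbind, mats))
}

# cross-correlation of two equal-length series over integer lags -w..w;
# positive lag means `a` follows `b`
lagged_cor <- function(a, b, w) {
  vapply(-w:w, function(k) {
    if (k >= 0) cor(a[(1 + k):length(a)], b[1:(length(b) - k)])
    else cor(a[1:(length(a) + k)], b[(1 - k):length(b)])
  }, numeric(1))
}

#' PETH onset-lag analysis of struggle and immobility neurons
#'
#' Builds peri-event time histograms around coping-bout onsets (0.5 s before to
#' 0.5 s after), per-event z-scores neuron data and speed, averages over
#' events, and cross-correlates the averaged neuron response with the averaged
#' speed over lags of +/- 0.5 s. The lag is the correlation argmax for
#' struggle neurons and argmin for immobility neurons (analysis restricted to
#' struggle neurons at struggle onsets and immobility neurons at immobility
#' onsets). A neuron's lag is significant when its correlation at the lag
#' deviates from the mean of all analyzed same-type neurons' correlations by
#' more than 1 SD of that distribution; significant negative lags classify as
#' `early` (activity precedes behavior), positive as `late`.
#'
#' @param session a [session_recording()].
#' @param movement_class per-neuron class vector from [tuning_table()].
#' @param window_s half window in seconds (default 0.5).
#' @return A data frame of class `peth_result` (one row per analyzed neuron:
#'   lag_s, peak correlation, significance, class) with the response grid in
#'   attribute `responses`; zero valid onsets give an empty result.
#' @export
peth_lag <- function(session, movement_class, window_s = 0.5) {
  fr <- session$behavior$frame_rate
  w <- sec_to_frames(window_s, fr)
  v <- session$calcium$values
  speed <- session$behavior$speed_mean
  rows <- list(); resp <- list()
  for (type in c("struggle", "immobility")) {
    neurons <- which(movement_class == type)
    if (length(neurons) == 0) next
    onsets <- coping_onsets(session, type, w)
    if (length(onsets) == 0) next
    avg_speed <- event_average(speed, onsets, w)
    if (is.null(avg_speed)) next
    lag_frames <- integer(0); peak <- numeric(0); keep <- integer(0)
    for (i in neurons) {
      avg_n <- event_average(v[i, ], onsets, w)
      if (is.null(avg_n)) next
      cc <- lagged_cor(avg_n, avg_speed, w)
      k <- if (type == "struggle") which.max(cc) else which.min(cc)
      lag_frames <- c(lag_frames, k - w - 1L)
      peak <- c(peak, cc[k])
      keep <- c(keep, i)
      resp[[length(resp) + 1L]] <- avg_n
    }
    if (length(keep) == 0) next
    if (length(keep) >= 2) {
      mu <- mean(peak); s <- sd(peak)
      sig <- if (type == "struggle") peak > mu + s else peak < mu - s
    } else {
      sig <- NA  # SD over a single neuron is undefined; flagged, unclassified
    }
    lag_s <- lag_frames / fr
    cls <- rep("none", length(keep))
    cls[!is.na(sig) & sig & lag_s < 0] <- "early"
    cls[!is.na(sig) & sig & lag_s > 0] <- "late"
    if (anyNA(sig)) cls <- rep(NA_character_, length(keep))
    rows[[type]] <- data.frame(
      neuron_row = keep, coping_type = type, lag_s = lag_s,
      peak_correlation = peak, significant = sig, class = cls,
      n_events = length(onsets), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron_row = integer(0), coping_type = character(0),
               lag_s = numeric(0), peak_correlation = numeric(0),
               significant = logical(0), class = character(0),
               n_events = integer(0))
  rownames(out) <- NULL
  attr(out, "responses") <- resp
  attr(out, "grid_s") <- (-w:w) / fr
  class(out) <- c("peth_result", "data.frame")
  out
}
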