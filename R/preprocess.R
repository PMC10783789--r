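# Trace conditioning: percentile detrending, z-scoring, transient masks, and
# the Gaussian-smoothing + quantile feature scaling applied before embedding.

#' Remove slow baseline drift with a running percentile filter
#'
#' Subtracts the centered running 10th percentile (window 30 s by default) from
#' each trace; edge windows are truncated. This removes slow drifts while
#' leaving fast calcium transients essentially untouched.
#'
#' @param trace numeric vector, or a neurons x frames matrix (applied per row).
#' @param window_s window length in seconds.
#' @param percentile percentile in (0, 100).
#' @param frame_rate frames per second.
#' @return Detrended trace(s), same shape as the input.
#' @export
detrend_percentile <- function(trace, window_s = 30, percentile = 10,
                               frame_rate = 20) {
  if (is.matrix(trace)) {
    out <- t(apply(trace, 1, detrend_percentile, window_s = window_s,
                   percentile = percentile, frame_rate = frame_rate))
    dimnames(out) <- dimnames(trace)
    return(out)
  }
  stop_if_not(all(is.finite(trace)), "detrend: non-finite values in trace")
  w <- sec_to_frames(window_s, frame_rate)
  stop_if_not(w >= 2, "detrend: window shorter than 2 frames")
  half <- w %/% 2L
  trace - .running_percentile_cpp(as.numeric(trace), half, percentile / 100)
}

#' Z-score a trace
#'
#' @param trace numeric vector, or a matrix (applied per row). Sessions are
#'   z-scored over the full concatenated baseline + TS recording by default so
#'   that scores comparing contexts share one scale.
#' @return Trace with mean 0 and SD 1. Zero-variance traces are an error
#'   naming the offending neuron row.
#' @export
zscore_trace <- function(trace) {
  if (is.matrix(trace)) {
    sds <- apply(trace, 1, sd)
    bad <- which(sds == 0 | !is.finite(sds))
    stop_if_not(length(bad) == 0,
                "zscore: zero-variance trace for neuron row(s) ",
                paste(head(bad, 5), collapse = ", "))
    return((trace - rowMeans(trace)) / sds)
  }
  s <- sd(trace)
  stop_if_not(is.finite(s) && s > 0, "zscore: zero-variance trace")
  (trace - mean(trace)) / s
}

#' Detect calcium transients
#'
#' A frame is flagged when the (z-scored) signal increases from the previous
#' frame by more than `k` standard deviations of the trace; the first frame is
#' never flagged. Returns a boolean array of the same shape as the trace.
#'
#' @param trace numeric vector or neurons x frames matrix of z-scored traces.
#' @param k threshold in SD units (default 2).
#' @return Logical vector/matrix of the same shape.
#' @export
detect_transients <- function(trace, k = 2) {
  if (is.matrix(trace)) {
    out <- t(apply(trace, 1, detect_transients, k = k))
    dimnames(out) <- dimnames(trace)
    return(out)
  }
  s <- sd(trace)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(trace)))
  c(FALSE, diff(trace) > k * s)
}

#' Gaussian smoothing followed by per-neuron quantile feature scaling
#'
#' Convolves each trace with a Gaussian kernel (sigma 250 ms, truncated at
#' +/- 4 sigma, reflect-padded) and then maps each neuron's empirical
#' quantiles onto a uniform grid on \[0, 1\] (`n_quantiles` = 100), preserving
#' rank order. This is the conditioning applied before manifold embedding.
#'
#' @param traces neurons x frames matrix.
#' @param sigma_s Gaussian kernel sigma in seconds.
#' @param n_quantiles number of quantile anchors of the monotone map.
#' @param frame_rate frames per second.
#' @return A `scaled_traces` object: `$values` in \[0, 1\] with the input
#'   shape, plus the smoothing/scaling provenance.
#' @export
smooth_quantile_scale <- function(traces, sigma_s = 0.25, n_quantiles = 100,
                                  frame_rate = 20) {
  traces <- as.matrix(traces)
  sm <- t(apply(traces, 1, gaussian_smooth, sigma = sigma_s * frame_rate))
  out <- matrix(0, nrow(traces), ncol(traces), dimnames = dimnames(traces))
  probs <- seq(0, 1, length.out = n_quantiles)
  for (i in seq_len(nrow(sm))) {
    x <- sm[i, ]
    if (diff(range(x)) == 0) {
      warning("smooth_quantile_scale: constant neuron row ", i, " mapped to 0.5")
      out[i, ] <- 0.5
      next
    }
    qs <- quantile(x, probs, names = FALSE, type = 7)
    # collapse duplicated anchors so the map stays a function
    keep <- !duplicated(qs)
    y <- approx(qs[keep], probs[keep], xout = x, rule = 2, ties = "ordered")$y
    out[i, ] <- pmin(1, pmax(0, y))
  }
  structure(list(values = out,
                 provenance = list(sigma_s = sigma_s, n_quantiles = n_quantiles,
                                   frame_rate = frame_rate)),
            class = "scaled_traces")
}

# reflect-padded Gaussian convolution, kernel truncated at +/- 4 sigma
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(half, n):1], x, x[n:pmax(1, n - half + 1)])
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Full session preprocessing
#'
#' Applies percentile detrending, z-scoring, and transient detection to every
#' neuron of a session, returning a new session.
#'
#' @param session a [session_recording()].
#' @param config an [analysis_config()].
#' @param detrend apply the running-percentile detrend first? Generator output
#'   is drift-free, so the step is skippable.
#' @return A preprocessed `session_recording`.
#' @export
preprocess_session <- function(session, config = analysis_config(),
                               detrend = TRUE) {
  v <- session$calcium$values
  if (detrend)
    v <- detrend_percentile(v, config$detrend_window_s, config$detrend_percentile,
                            session$behavior$frame_rate)
  v <- zscore_trace(v)
  session$calcium$values <- v
  session$calcium$transients <- detect_transients(v, config$transient_k)
  session
}
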