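# Core data model: behavior tracks, calcium traces, session recordings.

CONTEXT_LEVELS <- c("baseline", "TS")
COPING_LEVELS <- c("immobility", "struggle", "ambiguous", "not_applicable")

#' Per-frame behavior annotations
#'
#' @param context character vector, per frame, in `c("baseline", "TS")`.
#' @param coping character vector, per frame, in
#'   `c("struggle", "immobility", "ambiguous", "not_applicable")`. Must be
#'   `"not_applicable"` exactly on baseline frames.
#' @param speed_parts named list of per-body-part speed traces (same units,
#'   e.g. cm/s), one numeric vector per part, all the same length as `context`.
#' @param frame_rate acquisition rate in Hz (default 20).
#' @return A `behavior_track` with the per-frame mean speed in `$speed_mean`.
#' @export
behavior_track <- function(context, coping, speed_parts, frame_rate = 20) {
  speed_parts <- lapply(speed_parts, as.numeric)
  speed_parts <- speed_parts[order(names(speed_parts))]  # canonical part order
  obj <- structure(
    list(context = as.character(context),
         coping = as.character(coping),
         speed_parts = speed_parts,
         speed_mean = NULL,
         frame_rate = frame_rate),
    class = "behavior_track")
  obj$speed_mean <- rowMeans(do.call(cbind, obj$speed_parts))
  validate_behavior_track(obj)
  obj
}

validate_behavior_track <- function(b) {
  n <- length(b$context)
  stop_if_not(length(b$coping) == n, "behavior: coping length differs from context")
  for (p in names(b$speed_parts))
    stop_if_not(length(b$speed_parts[[p]]) == n,
                "behavior: speed trace '", p, "' length differs from context")
  stop_if_not(all(b$context %in% CONTEXT_LEVELS), "behavior: invalid context label")
  stop_if_not(all(b$coping %in% COPING_LEVELS), "behavior: invalid coping label")
  stop_if_not(all((b$coping == "not_applicable") == (b$context == "baseline")),
              "behavior: coping must be not_applicable exactly on baseline frames")
  sp <- unlist(b$speed_parts, use.names = FALSE)
  stop_if_not(all(is.finite(sp)) && all(sp >= 0), "behavior: speeds must be finite and >= 0")
  stop_if_not(b$frame_rate > 0, "behavior: frame_rate must be > 0")
  invisible(b)
}

n_frames <- function(x) UseMethod("n_frames")
#' @export
n_frames.behavior_track <- function(x) length(x$context)
#' @export
n_frames.calcium_traces <- function(x) ncol(x$values)
#' @export
n_frames.session_recording <- function(x) ncol(x$calcium$values)

#' Z-scored calcium trace matrix with transient mask
#'
#' @param values numeric matrix, neurons x frames, z-scored fluorescence.
#' @param neuron_ids unique per-session integer identifiers (default row index).
#' @param transients logical/0-1 matrix of the same shape flagging frames where
#'   the signal rises by more than the transient threshold; computed with
#'   [detect_transients()] when omitted.
#' @param frame_rate acquisition rate in Hz.
#' @return A `calcium_traces` object.
#' @export
calcium_traces <- function(values, neuron_ids = seq_len(nrow(values)),
                           transients = NULL, frame_rate = 20) {
  values <- as.matrix(values)
  if (is.null(transients)) transients <- detect_transients(values)
  obj <- structure(
    list(values = values,
         neuron_ids = as.integer(neuron_ids),
         transients = matrix(as.logical(transients), nrow(values), ncol(values)),
         frame_rate = frame_rate),
    class = "calcium_traces")
  validate_calcium_traces(obj)
  obj
}

validate_calcium_traces <- function(x) {
  stop_if_not(all(is.finite(x$values)), "calcium: values must be finite")
  stop_if_not(all(dim(x$transients) == dim(x$values)),
              "calcium: transients shape differs from values")
  stop_if_not(length(x$neuron_ids) == nrow(x$values),
              "calcium: one neuron_id per row required")
  stop_if_not(!anyDuplicated(x$neuron_ids), "calcium: neuron_ids must be unique")
  invisible(x)
}

#' One animal-day recording
#'
#' @param animal_id character or integer animal identifier.
#' @param day integer session day (1, 3 and 9 in a typical repeated-TS design).
#' @param calcium a [calcium_traces()] object.
#' @param behavior a [behavior_track()] with the same frame count.
#' @return A `session_recording`.
#' @export
session_recording <- function(animal_id, day, calcium, behavior) {
  obj <- structure(
    list(animal_id = as.character(animal_id), day = as.integer(day),
         calcium = calcium, behavior = behavior),
    class = "session_recording")
  validate_session(obj)
  obj
}

validate_session <- function(s) {
  validate_calcium_traces(s$calcium)
  validate_behavior_track(s$behavior)
  stop_if_not(n_frames(s$calcium) == n_frames(s$behavior),
              "session: calcium and behavior frame counts differ")
  stop_if_not(s$day >= 1, "session: day must be >= 1")
  invisible(s)
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> animal %s, day %d: %d neurons x %d frames (%g Hz)\n",
              x$animal_id, x$day, nrow(x$calcium$values), n_frames(x), x$behavior$frame_rate))
  tb <- table(x$behavior$context)
  cat("  context frames:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# frame index helpers -------------------------------------------------------

context_frames <- function(session, context) {
  which(session$behavior$context == context)
}

# TS frames with an unambiguous coping label
coping_frames <- function(session) {
  which(session$behavior$coping %in% c("struggle", "immobility"))
}
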