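# On-disk formats: HDF5 sessions and registration CSV tables.

COPING_CODES <- c(immobility = 0L, struggle = 1L, ambiguous = 2L, not_applicable = 3L)
CONTEXT_CODES <- c(baseline = 0L, TS = 1L)

#' Write a session recording to HDF5
#'
#' Layout: `/calcium/values` (neurons x frames), `/calcium/transients` (uint8),
#' `/calcium/neuron_ids`, `/behavior/context` (0 = baseline, 1 = TS),
#' `/behavior/coping` (0 = immobility, 1 = struggle, 2 = ambiguous, 3 = n/a),
#' `/behavior/speed/<part>`, `/behavior/speed_mean`; root attributes
#' `animal_id`, `day`, `frame_rate_hz`, `speed_units`. Trace matrices are
#' stored at full double precision so that write/read round-trips are
#' bit-exact.
#'
#' @param session a [session_recording()].
#' @param path output file path.
#' @param overwrite overwrite an existing file? Refused by default.
#' @param compress gzip compression level 0-9 (default 4); arrays read back
#'   identically at any level.
#' @param speed_units free-text unit attribute (default "cm/s").
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, overwrite = FALSE, compress = 4,
                          speed_units = "cm/s") {
  validate_session(session)
  if (file.exists(path)) {
    stop_if_not(isTRUE(overwrite), "file exists (use overwrite = TRUE): ", path)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "calcium")
  rhdf5::h5createGroup(path, "behavior")
  rhdf5::h5createGroup(path, "behavior/speed")

  h5write_ds <- function(obj, name, mode = "double") {
    rhdf5::h5createDataset(path, name, dims = dim(obj) %||% length(obj),
                           storage.mode = mode, level = compress,
                           chunk = dim(obj) %||% length(obj))
    rhdf5::h5write(obj, path, name)
  }
  h5write_ds(session$calcium$values, "calcium/values")
  h5write_ds(matrix(as.integer(session$calcium$transients),
                    nrow(session$calcium$values)), "calcium/transients", "integer")
  h5write_ds(session$calcium$neuron_ids, "calcium/neuron_ids", "integer")
  h5write_ds(unname(CONTEXT_CODES[session$behavior$context]), "behavior/context", "integer")
  h5write_ds(unname(COPING_CODES[session$behavior$coping]), "behavior/coping", "integer")
  for (p in names(session$behavior$speed_parts))
    h5write_ds(session$behavior$speed_parts[[p]], paste0("behavior/speed/", p))
  h5write_ds(session$behavior$speed_mean, "behavior/speed_mean")

  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(session$animal_id, fid, "animal_id")
  rhdf5::h5writeAttribute(session$day, fid, "day")
  rhdf5::h5writeAttribute(session$behavior$frame_rate, fid, "frame_rate_hz")
  rhdf5::h5writeAttribute(speed_units, fid, "speed_units")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a session recording from HDF5
#'
#' Inverse of [write_session()]. Missing required datasets raise a format
#' error naming the dataset; frame-count mismatches raise invariant errors.
#'
#' @param path an HDF5 session file.
#' @return A [session_recording()].
#' @export
read_session <- function(path) {
  stop_if_not(file.exists(path), "no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  present <- file.path(contents$group, contents$name)
  present <- sub("^//", "/", present)
  required <- c("/calcium/values", "/calcium/transients", "/calcium/neuron_ids",
                "/behavior/context", "/behavior/coping", "/behavior/speed_mean")
  for (ds in required)
    stop_if_not(ds %in% present, "session file missing dataset: ", ds)

  att <- rhdf5::h5readAttributes(path, "/")
  values <- rhdf5::h5read(path, "calcium/values")
  transients <- rhdf5::h5read(path, "calcium/transients")
  ids <- as.integer(rhdf5::h5read(path, "calcium/neuron_ids"))
  context_code <- as.integer(rhdf5::h5read(path, "behavior/context"))
  coping_code <- as.integer(rhdf5::h5read(path, "behavior/coping"))
  part_names <- contents$name[contents$group == "/behavior/speed"]
  speed_parts <- setNames(
    lapply(part_names, function(p) as.numeric(rhdf5::h5read(path, paste0("behavior/speed/", p)))),
    part_names)

  behavior <- behavior_track(
    context = names(CONTEXT_CODES)[match(context_code, CONTEXT_CODES)],
    coping = names(COPING_CODES)[match(coping_code, COPING_CODES)],
    speed_parts = speed_parts,
    frame_rate = as.numeric(att$frame_rate_hz))
  calcium <- calcium_traces(values, neuron_ids = ids,
                            transients = transients == 1,
                            frame_rate = as.numeric(att$frame_rate_hz))
  session_recording(att$animal_id, as.integer(att$day), calcium, behavior)
}

# registration -------------------------------------------------------------

#' Construct a cross-day neuron registration table
#'
#' Maps global neuron identities to per-day local trace row indices; `-1`
#' denotes "not detected on this day".
#'
#' @param global_id integer vector of unique global neuron ids.
#' @param ... one integer vector per day, named `day<d>` (e.g. `day1 = ...`),
#'   giving the local row index of each global neuron on that day or -1.
#' @return A data frame of class `registration_map` with attribute `days`.
#' @export
registration_map <- function(global_id, ...) {
  cols <- list(...)
  stop_if_not(length(cols) >= 1, "registration: at least one day column required")
  stop_if_not(all(grepl("^day[0-9]+$", names(cols))),
              "registration: day columns must be named day<d>")
  df <- data.frame(global_id = as.integer(global_id))
  for (k in names(cols)) df[[k]] <- as.integer(cols[[k]])
  validate_registration(df)
  structure(df, class = c("registration_map", "data.frame"),
            days = as.integer(sub("^day", "", names(cols))))
}

validate_registration <- function(df) {
  stop_if_not(!anyDuplicated(df$global_id), "registration: duplicate global_id")
  day_cols <- grep("^day[0-9]+$", names(df), value = TRUE)
  for (k in day_cols) {
    idx <- df[[k]][df[[k]] >= 0]
    stop_if_not(!anyDuplicated(idx),
                "registration: duplicated local row index in ", k)
  }
  invisible(df)
}

#' Read/write a registration CSV
#'
#' Header `global_id,day1,day3,day9` (day columns extensible); absent entries
#' are stored as -1.
#'
#' @param path CSV file path.
#' @return For `read_registration`, a `registration_map`.
#' @export
read_registration <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stop_if_not("global_id" %in% names(df), "registration CSV lacks global_id column")
  day_cols <- grep("^day[0-9]+$", names(df), value = TRUE)
  stop_if_not(length(day_cols) >= 1, "registration CSV lacks day columns")
  do.call(registration_map,
          c(list(global_id = df$global_id), as.list(df[day_cols])))
}

#' @rdname read_registration
#' @param map a `registration_map`.
#' @export
write_registration <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Neurons detected on every requested day
#'
#' "Repeatedly identified" neurons are those registered as active on all
#' listed imaging days; with independent per-day detection probability p over
#' three days the expected fraction is p^3 (about 0.4 at p = 0.74).
#'
#' @param map a `registration_map`.
#' @param days integer days to intersect (default: all days in `map`).
#' @return Ascending integer vector of global ids present on every day.
#' @export
repeatedly_identified <- function(map, days = attr(map, "days")) {
  stop_if_not(length(days) >= 1, "days must be non-empty")
  known <- attr(map, "days")
  unknown <- setdiff(days, known)
  stop_if_not(length(unknown) == 0,
              "unknown day(s): ", paste(unknown, collapse = ", "))
  present <- rep(TRUE, nrow(map))
  for (d in days) present <- present & map[[paste0("day", d)]] >= 0
  sort(map$global_id[present])
}

# Per-day local row indices (1-based) for a set of global ids, in the order of
# sort(global_ids); used to build matched trace matrices across days.
local_rows <- function(map, day, global_ids) {
  ids <- sort(global_ids)
  idx <- map[[paste0("day", day)]][match(ids, map$global_id)]
  stop_if_not(all(idx >= 0), "some neurons absent on day ", day)
  idx + 1L
}
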