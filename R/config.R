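#' Analysis configuration
#'
#' Collects every numeric default used by the pipeline in one validated list.
#' Values follow the analysis conventions for 20 Hz 1-photon calcium data:
#' detrending with a running 10th-percentile filter over a 30 s window,
#' transients defined as frame-to-frame increases above 2 SD, selectivity and
#' movement classification thresholds of +/-0.2, decoder regularization
#' (logistic C = 0.1 for context, C = 0.01 for coping, linear SVC cost 1, ridge
#' penalty 50), 10-fold contiguous cross-validation, isomap with 500 neighbours
#' into 5 dimensions, 20-digit epoch templates, 15 x 15 flow-field bins, and
#' 100 random-rotation repetitions for alignment nulls.
#'
#' @param ... named overrides of any default listed below.
#' @return A named list of class `analysis_config`.
#' @examples
#' cfg <- analysis_config(folds = 5, embed_dims = 5)
#' cfg$coping_C
#' @export
analysis_config <- function(...) {
  cfg <- list(
    frame_rate = 20,
    detrend_window_s = 30,
    detrend_percentile = 10,
    transient_k = 2,
    selectivity_threshold = 0.2,
    movement_threshold = 0.2,
    context_C = 0.1,
    coping_C = 0.01,
    svc_cost = 1,
    ridge_alpha = 50,
    folds = 10,
    smooth_sigma_s = 0.25,
    n_quantiles = 100,
    embed_method = "isomap",
    embed_dims = 5,
    isomap_neighbors = 500,
    spectral_neighbors = 1000,
    fit_fraction = 0.6,
    template_digits = 20,
    flow_bins = 15,
    turn_rate_hz = 2.67,
    rotation_reps = 100,
    n_surrogates_ev = 1000,
    n_surrogates_decode = 20,
    shift_range_s = c(20, 120),
    ev_alpha_percentile = 95,
    population_predictors = 50,
    peth_window_s = 0.5,
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    stop_if_not(length(unknown) == 0,
                "unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  pos <- c("frame_rate", "detrend_window_s", "transient_k",
           "selectivity_threshold", "movement_threshold", "context_C",
           "coping_C", "svc_cost", "ridge_alpha", "smooth_sigma_s")
  for (k in pos) stop_if_not(cfg[[k]] > 0, "config: ", k, " must be > 0")
  stop_if_not(cfg$folds >= 2, "config: folds must be >= 2")
  stop_if_not(cfg$embed_dims >= 2, "config: embed_dims must be >= 2")
  stop_if_not(cfg$detrend_percentile > 0 && cfg$detrend_percentile < 100,
              "config: detrend_percentile must be in (0, 100)")
  stop_if_not(length(cfg$shift_range_s) == 2 && diff(cfg$shift_range_s) > 0,
              "config: shift_range_s must be an increasing pair")
  invisible(cfg)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Flat keys matching [analysis_config()] defaults; unknown keys are an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  stop_if_not(file.exists(path), "config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}
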