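# End-to-end study orchestration on synthetic (or user-provided) sessions,
# and real-vs-null summaries.

#' Run the full analysis pipeline
#'
#' Generates (or loads) a multi-animal, multi-day cohort and runs preprocessing,
#' tuning, decoding, and manifold alignment in order under one master seed,
#' returning a structured report: per-animal-per-day behavior summaries, neuron
#' counts and repeated-identification fractions, selectivity distributions and
#' cross-day correlations, context/coping decoding within and across days with
#' surrogate comparators, movement scores, within/cross-condition speed
#' decoding, manifold alignment across days, and cross-animal alignment over
#' circular pairs.
#'
#' @param config an [analysis_config()].
#' @param params a [generator_params()] (used when `data_dir` is NULL).
#' @param n_animals number of simulated animals.
#' @param days imaging days.
#' @param data_dir optional directory of session HDF5 files plus
#'   `registration_<animal>.csv` tables to analyse instead of simulating;
#'   files are matched by `session_<animal>_day<d>.h5`.
#' @param out_dir optional output directory: writes `report.json` and one
#'   tuning CSV per animal-day.
#' @param align_days run the across-day and cross-animal manifold alignment
#'   stages (the slowest part).
#' @return A `study_report` list; fully deterministic given `config$seed`.
#' @export
run_study <- function(config = analysis_config(), params = generator_params(),
                      n_animals = 2, days = c(1, 3, 9), data_dir = NULL,
                      out_dir = NULL, align_days = TRUE) {
  seed <- config$seed
  cohort <- if (is.null(data_dir)) {
    generate_cohort(params, n_animals, seed = seed, days = days)
  } else {
    load_cohort(data_dir, days)
  }

  report <- list(config = unclass(config), seed = seed,
                 n_animals = length(cohort), days = days, animals = list())
  day1_manifolds <- list()

  for (a in seq_along(cohort)) {
    an <- cohort[[a]]
    animal_id <- an$sessions[[1]]$animal_id
    a_rep <- list(animal_id = animal_id, days = list())
    tunings <- list()

    for (j in seq_along(an$sessions)) {
      s <- an$sessions[[j]]
      fr <- s$behavior$frame_rate
      ts <- context_frames(s, "TS")
      cop <- s$behavior$coping[ts]
      tun <- tuning_table(s, config)
      tunings[[j]] <- tun
      d_rep <- list(
        day = s$day,
        n_neurons = nrow(s$calcium$values),
        n_frames = n_frames(s),
        immobility_time_s = sum(cop == "immobility") / fr,
        struggle_time_s = sum(cop == "struggle") / fr,
        mean_ts_speed = mean(s$behavior$speed_mean[ts]),
        selectivity = list(
          median_raw = median(tun$ts_selectivity_raw, na.rm = TRUE),
          prop_baseline = mean(tun$selectivity_class == "baseline"),
          prop_ts = mean(tun$selectivity_class == "TS")),
        movement = list(
          mean_abs_score_ts = mean(abs(tun$movement_score_TS), na.rm = TRUE),
          mean_abs_score_baseline = mean(abs(tun$movement_score_baseline), na.rm = TRUE),
          prop_struggle = mean(tun$movement_class == "struggle"),
          prop_immobility = mean(tun$movement_class == "immobility")))
      if (j == 1) {
        v <- s$calcium$values
        cop_res <- decode_binary(v, s$behavior$coping, model = "logistic",
                                 C = config$coping_C, folds = config$folds,
                                 n_surrogates = config$n_surrogates_decode,
                                 seed = child_seed(seed, a, 1), task = "coping")
        ctx_res <- decode_binary(v, s$behavior$context, model = "logistic",
                                 C = config$context_C, folds = config$folds,
                                 n_surrogates = 0,
                                 seed = child_seed(seed, a, 2), task = "context")
        i_ts <- ts; i_base <- context_frames(s, "baseline")
        sp <- s$behavior$speed_mean
        speed_res <- list(
          ts_ts = cross_condition_decode(v, sp, i_ts, i_ts, config$ridge_alpha,
                                         config$folds, seed = child_seed(seed, a, 3),
                                         train_condition = "TS", test_condition = "TS"),
          ts_base = cross_condition_decode(v, sp, i_ts, i_base, config$ridge_alpha,
                                           config$folds, seed = child_seed(seed, a, 3),
                                           train_condition = "TS", test_condition = "baseline"),
          base_base = cross_condition_decode(v, sp, i_base, i_base, config$ridge_alpha,
                                             config$folds, seed = child_seed(seed, a, 3),
                                             train_condition = "baseline", test_condition = "baseline"),
          base_ts = cross_condition_decode(v, sp, i_base, i_ts, config$ridge_alpha,
                                           config$folds, seed = child_seed(seed, a, 3),
                                           train_condition = "baseline", test_condition = "TS"))
        d_rep$decoding <- list(
          coping_accuracy = cop_res$mean_score,
          coping_surrogate = cop_res$surrogate_mean,
          context_accuracy = ctx_res$mean_score,
          speed_r = lapply(speed_res, function(r) r$mean_score))
      }
      a_rep$days[[paste0("day", s$day)]] <- d_rep
    }

    # cross-day stability of per-neuron scores (repeatedly identified cells)
    if (!is.null(an$map) && length(an$sessions) >= 2) {
      ids <- repeatedly_identified(an$map, days)
      a_rep$repeated_fraction <- length(ids) / nrow(an$map)
      rows <- lapply(seq_along(days), function(j)
        local_rows(an$map, days[j], ids))
      a_rep$stability <- list(
        selectivity_cor_d1 = vapply(seq_along(days)[-1], function(j)
          cor(tunings[[1]]$ts_selectivity_raw[rows[[1]]],
              tunings[[j]]$ts_selectivity_raw[rows[[j]]],
              use = "complete.obs"), numeric(1)),
        movement_cor_d1 = vapply(seq_along(days)[-1], function(j)
          cor(tunings[[1]]$movement_score_TS[rows[[1]]],
              tunings[[j]]$movement_score_TS[rows[[j]]],
              use = "complete.obs"), numeric(1)))
      acr <- across_day_decode(an$sessions, an$map, "coping",
                               config = config, seed = child_seed(seed, a, 4))
      a_rep$across_day_coping <- lapply(acr, function(r) r$mean_score)
    }

    if (align_days) {
      manifolds <- lapply(an$sessions, ts_manifold, config = config)
      day1_manifolds[[a]] <- manifolds[[1]]
      if (length(manifolds) >= 2) {
        a_rep$aligned_across_day <- lapply(seq_along(manifolds)[-1], function(j) {
          res <- cross_manifold_decode(
            manifolds[[1]], manifolds[[j]], "coping", config,
            n_rotations = config$rotation_reps,
            shuffle = ts_manifold(an$sessions[[j]], config,
                                  shuffle_seed = child_seed(seed, a, 5, j)),
            seed = child_seed(seed, a, 6, j))
          list(test_day = an$sessions[[j]]$day,
               within = res$within$mean_score,
               aligned = res$aligned$mean_score,
               rotation = res$rotation_mean,
               shuffle = res$shuffle$mean_score)
        })
      }
    }
    report$animals[[animal_id]] <- a_rep
  }

  if (align_days && length(cohort) >= 2) {
    pairs <- circular_pairing(seq_along(cohort))
    report$cross_animal <- lapply(pairs, function(p) {
      res <- cross_manifold_decode(day1_manifolds[[p$reference]],
                                   day1_manifolds[[p$target]], "coping",
                                   config, n_rotations = config$rotation_reps,
                                   seed = child_seed(seed, 71, p$target))
      list(reference = cohort[[p$reference]]$sessions[[1]]$animal_id,
           target = cohort[[p$target]]$sessions[[1]]$animal_id,
           within = res$within$mean_score,
           aligned = res$aligned$mean_score,
           rotation = res$rotation_mean)
    })
  }

  class(report) <- "study_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

load_cohort <- function(data_dir, days) {
  files <- list.files(data_dir, "^session_.*\\.h5$", full.names = TRUE)
  stop_if_not(length(files) > 0, "no session files in ", data_dir)
  animals <- unique(sub("^session_([^_]+)_day[0-9]+\\.h5$", "\\1", basename(files)))
  lapply(animals, function(a) {
    sessions <- lapply(days, function(d) {
      f <- file.path(data_dir, sprintf("session_%s_day%d.h5", a, d))
      stop_if_not(file.exists(f), "missing session file: ", f)
      read_session(f)
    })
    mapfile <- file.path(data_dir, sprintf("registration_%s.csv", a))
    map <- if (file.exists(mapfile)) read_registration(mapfile) else NULL
    list(sessions = sessions, map = map, truth = NULL)
  })
}

#' Summarize a real decoding result against its null
#'
#' @param real,null `decoding_result`s computed with identical fold indices
#'   (mismatched folds are an error). The null distribution is the null
#'   result's surrogate means when present, otherwise its fold scores.
#' @return List: real and null means, their difference, and the mid-rank
#'   percentile of the real mean within the null distribution.
#' @export
compare_to_null <- function(real, null) {
  stop_if_not(identical(real$folds, null$folds),
              "compare_to_null: fold indices differ between real and null")
  nd <- if (length(null$surrogate_means)) null$surrogate_means else null$fold_scores
  r <- real$mean_score
  pct <- 100 * (sum(nd < r) + 0.5 * sum(nd == r)) / length(nd)
  list(real_mean = r, null_mean = mean(nd), difference = r - mean(nd),
       percentile = pct)
}
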