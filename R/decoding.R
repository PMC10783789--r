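# Balanced, cross-validated decoding of context, coping style and speed, with
# circular-shift surrogate controls. Folds are contiguous temporal blocks over
# the balanced frame set, and any paired comparison (real vs surrogate,
# condition A vs B, day d vs d') shares one fold partition.

new_decoding_result <- function(task, model, train_condition, test_condition,
                                fold_scores, surrogate_means, n_frames, folds,
                                seed) {
  structure(list(
    task = task, model = model,
    train_condition = train_condition, test_condition = test_condition,
    fold_scores = fold_scores, mean_score = mean(fold_scores, na.rm = TRUE),
    surrogate_means = surrogate_means,
    surrogate_mean = if (length(surrogate_means)) mean(surrogate_means) else NA_real_,
    n_frames = n_frames, folds = folds, seed = seed),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s (%s): %s -> %s\n", x$task, x$model,
              x$train_condition, x$test_condition))
  cat(sprintf("  mean score %.3f over %d folds (n = %d frames)",
              x$mean_score, length(x$fold_scores), x$n_frames))
  if (!is.na(x$surrogate_mean))
    cat(sprintf("; surrogate mean %.3f (%d reps)", x$surrogate_mean,
                length(x$surrogate_means)))
  cat("\n")
  invisible(x)
}

#' Balance a binary label set by subsampling the majority class
#'
#' Keeps every frame of the minority class and a uniform random subset of the
#' majority class of equal count; the returned indices are sorted (time
#' order). Ambiguous frames must be excluded beforehand.
#'
#' @param labels character/factor vector with exactly two distinct values.
#' @param seed integer seed.
#' @return Sorted integer frame indices into `labels`.
#' @export
balance_binary <- function(labels, seed = 1) {
  labels <- as.character(labels)
  lv <- unique(labels)
  stop_if_not(length(lv) == 2, "balance_binary: need exactly 2 classes, got ",
              length(lv))
  counts <- table(labels)
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(lv, minority)
  i_min <- which(labels == minority)
  i_maj <- which(labels == majority)
  keep_maj <- with_seed(child_seed(seed, 21),
                        sample(i_maj, length(i_min)))
  sort(c(i_min, keep_maj))
}

#' Circular-shift surrogate traces
#'
#' Each neuron's trace is circularly rotated by an independent uniform random
#' offset in `[1, n_frames - 1]`, preserving its marginal distribution and
#' autocorrelation exactly while destroying its timing relative to behavior
#' and to other neurons.
#'
#' @param traces neurons x frames matrix.
#' @param seed integer seed.
#' @return Matrix of the same shape.
#' @export
circular_shift_surrogate <- function(traces, seed = 1) {
  n <- ncol(traces)
  stop_if_not(n >= 1, "circular_shift_surrogate: empty traces")
  if (n == 1) return(traces)
  offsets <- with_seed(child_seed(seed, 23),
                       sample.int(n - 1L, nrow(traces), replace = TRUE))
  out <- traces
  for (i in seq_len(nrow(traces))) out[i, ] <- circular_shift(traces[i, ], offsets[i])
  out
}

# shared engine: train on columns train_mat[, frames], test on test_mat.
# `idx_train`/`idx_test` are equal-length frame-index vectors; fold positions
# (contiguous blocks over 1..length(idx)) are shared between them.
cv_engine <- function(train_mat, y_train, test_mat, y_test, idx_train,
                      idx_test, folds, fit_fun, predict_fun, score_fun) {
  vapply(folds, function(test_pos) {
    train_pos <- setdiff(seq_along(idx_train), test_pos)
    xtr <- t(train_mat[, idx_train[train_pos], drop = FALSE])
    xte <- t(test_mat[, idx_test[test_pos], drop = FALSE])
    std <- fit_standardizer(xtr)
    fit <- fit_fun(apply_standardizer(std, xtr), y_train[train_pos])
    pred <- predict_fun(fit, apply_standardizer(std, xte))
    score_fun(pred, y_test[test_pos])
  }, numeric(1))
}

#' Decode a binary behavioral state from traces
#'
#' 10-fold cross-validated classification over a balanced frame set.
#' Standardization is fit on the training folds only. Models: L2 logistic
#' regression (`C` = 0.1 for context, 0.01 for coping), linear SVC (cost 1),
#' ridge classifier (penalty 50), or Gaussian naive Bayes. Chance level is
#' estimated from circular-shift surrogates evaluated with the identical fold
#' partition.
#'
#' @param traces neurons x frames matrix (full session timebase).
#' @param labels per-frame labels; only `idx` frames are used.
#' @param idx balanced frame index set (from [balance_binary()]); when NULL the
#'   labels' two classes are balanced internally.
#' @param model one of `"logistic"`, `"svc"`, `"ridge"`, `"gnb"`.
#' @param C inverse regularization strength for logistic regression.
#' @param cost,alpha SVC cost and ridge penalty.
#' @param folds number of contiguous folds.
#' @param n_surrogates circular-shift surrogate repetitions (0 = none).
#' @param seed integer seed.
#' @param task,train_condition,test_condition metadata stored in the result.
#' @return A `decoding_result` (accuracy per fold).
#' @export
decode_binary <- function(traces, labels, idx = NULL, model = "logistic",
                          C = 0.01, cost = 1, alpha = 50, folds = 10,
                          n_surrogates = 0, seed = 1, task = "coping",
                          train_condition = "within", test_condition = "within") {
  labels <- as.character(labels)
  usable <- NULL
  if (is.null(idx)) {
    usable <- which(!labels %in% c("ambiguous", "not_applicable"))
    idx <- usable[balance_binary(labels[usable], seed)]
  }
  y <- labels[idx]
  fold_idx <- make_folds(length(idx), folds)
  # guard: every training fold must contain both classes; re-draw if not
  for (try in 0:9) {
    ok <- all(vapply(fold_idx, function(te)
      length(unique(y[-te])) == 2, logical(1)))
    if (ok || is.null(usable)) break
    message("decode_binary: single-class training fold, re-drawing balance (try ",
            try + 1, ")")
    idx <- usable[balance_binary(labels[usable], seed + try + 1)]
    y <- labels[idx]
  }
  fit_fun <- function(x, yy) fit_classifier(x, yy, model, C = C, cost = cost,
                                            alpha = alpha)
  acc <- function(pred, truth) mean(pred == truth)
  scores <- cv_engine(traces, y, traces, y, idx, idx, fold_idx,
                      fit_fun, predict_classifier, acc)
  surr <- if (n_surrogates > 0) {
    vapply(seq_len(n_surrogates), function(r) {
      sh <- circular_shift_surrogate(traces, child_seed(seed, 31, r))
      mean(cv_engine(sh, y, sh, y, idx, idx, fold_idx, fit_fun,
                     predict_classifier, acc))
    }, numeric(1))
  } else numeric(0)
  new_decoding_result(task, model, train_condition, test_condition,
                      scores, surr, length(idx), fold_idx, seed)
}

# Pearson r between prediction and truth; NA when the fold's truth is constant
score_pearson <- function(pred, truth) {
  if (sd(truth) == 0 || sd(pred) == 0) {
    warning("decode_speed: constant fold skipped")
    return(NA_real_)
  }
  cor(pred, truth)
}

#' Decode continuous speed from traces with ridge regression
#'
#' @param traces neurons x frames matrix.
#' @param speed per-frame speed.
#' @param idx frame indices to use (default all frames).
#' @param penalty ridge penalty (default 50).
#' @param folds contiguous folds.
#' @param n_surrogates circular-shift surrogate repetitions.
#' @param seed integer seed.
#' @return A `decoding_result` (per-fold Pearson r between predicted and true
#'   speed, averaged).
#' @export
decode_speed <- function(traces, speed, idx = seq_len(ncol(traces)),
                         penalty = 50, folds = 10, n_surrogates = 0, seed = 1) {
  cross_condition_decode(traces, speed, idx, idx, penalty = penalty,
                         folds = folds, n_surrogates = n_surrogates,
                         seed = seed, train_condition = "within",
                         test_condition = "within")
}

#' Cross-condition speed decoding
#'
#' Fits the ridge decoder on one condition's frames and scores it on another's,
#' with the identical contiguous fold template applied to both conditions
#' (after trimming the end of the longer segment so lengths match). The
#' within-condition case (`idx_train == idx_test`) reduces exactly to
#' [decode_speed()].
#'
#' @param traces neurons x frames matrix.
#' @param speed per-frame speed on the same timebase.
#' @param idx_train,idx_test frame indices of the train and test conditions.
#' @param penalty,folds,n_surrogates,seed as in [decode_speed()].
#' @param train_condition,test_condition metadata labels.
#' @return A `decoding_result`.
#' @export
cross_condition_decode <- function(traces, speed, idx_train, idx_test,
                                   penalty = 50, folds = 10, n_surrogates = 0,
                                   seed = 1, train_condition = "train",
                                   test_condition = "test") {
  n <- min(length(idx_train), length(idx_test))
  idx_train <- idx_train[seq_len(n)]   # drop the tail of the longer segment
  idx_test <- idx_test[seq_len(n)]
  fold_idx <- make_folds(n, folds)
  fit_fun <- function(x, y) fit_ridge_regression(x, y, penalty)
  scores <- cv_engine(traces, speed[idx_train], traces, speed[idx_test],
                      idx_train, idx_test, fold_idx, fit_fun,
                      predict_ridge_regression, score_pearson)
  surr <- if (n_surrogates > 0) {
    vapply(seq_len(n_surrogates), function(r) {
      sh <- circular_shift_surrogate(traces, child_seed(seed, 37, r))
      mean(cv_engine(sh, speed[idx_train], sh, speed[idx_test], idx_train,
                     idx_test, fold_idx, fit_fun, predict_ridge_regression,
                     score_pearson), na.rm = TRUE)
    }, numeric(1))
  } else numeric(0)
  new_decoding_result("speed", "ridge", train_condition, test_condition,
                      scores, surr, n, fold_idx, seed)
}

# evenly subsample a balanced index set down to n_target keeping class balance
equalize_balanced <- function(idx, labels, n_target) {
  lv <- unique(labels[idx])
  per <- n_target %/% length(lv)
  out <- integer(0)
  for (l in lv) {
    il <- idx[labels[idx] == l]
    take <- il[round(seq(1, length(il), length.out = per))]
    out <- c(out, take)
  }
  sort(out)
}

#' Across-day decoding with repeatedly identified neurons
#'
#' Restricts every day's trace matrix to neurons registered on all days
#' (rows ordered identically by global id), balances and equalizes frame
#' counts across days, and trains on `train_day` with one fold template shared
#' by all test days; the train-day result equals within-day decoding.
#'
#' @param sessions list of [session_recording()]s (one per day).
#' @param map a `registration_map` covering the sessions' days.
#' @param task `"coping"` (balanced struggle/immobility classification),
#'   `"context"` (balanced baseline/TS classification) or `"speed"` (TS speed
#'   ridge regression).
#' @param train_day day used for training (default the first session's day).
#' @param config an [analysis_config()].
#' @param n_surrogates circular-shift surrogate repetitions per test day.
#' @param seed integer seed.
#' @return Named list of `decoding_result`, one per test day.
#' @export
across_day_decode <- function(sessions, map, task = c("coping", "context", "speed"),
                              train_day = NULL, config = analysis_config(),
                              n_surrogates = 0, seed = config$seed) {
  task <- match.arg(task)
  days <- vapply(sessions, function(s) s$day, integer(1))
  if (is.null(train_day)) train_day <- days[1]
  stop_if_not(train_day %in% days, "train_day not among the sessions' days")
  ids <- repeatedly_identified(map, days)
  stop_if_not(length(ids) > 0, "no repeatedly identified neurons")
  mats <- lapply(seq_along(days), function(j)
    sessions[[j]]$calcium$values[local_rows(map, days[j], ids), , drop = FALSE])

  if (task == "speed") {
    idx_list <- lapply(sessions, function(s) context_frames(s, "TS"))
    n <- min(lengths(idx_list))
    idx_list <- lapply(idx_list, function(ix) ix[seq_len(n)])
  } else {
    idx_list <- lapply(seq_along(sessions), function(j) {
      s <- sessions[[j]]
      if (task == "coping") {
        fr <- coping_frames(s)
        fr[balance_binary(s$behavior$coping[fr], child_seed(seed, 41, j))]
      } else {
        balance_binary(s$behavior$context, child_seed(seed, 41, j))
      }
    })
    n <- min(lengths(idx_list))
    idx_list <- lapply(seq_along(sessions), function(j)
      equalize_balanced(idx_list[[j]],
                        if (task == "coping") sessions[[j]]$behavior$coping
                        else sessions[[j]]$behavior$context, n))
    n <- min(lengths(idx_list))
    idx_list <- lapply(idx_list, function(ix) ix[seq_len(n)])
  }
  fold_idx <- make_folds(n, config$folds)
  j_train <- match(train_day, days)

  results <- lapply(seq_along(days), function(j) {
    if (task == "speed") {
      y_tr <- sessions[[j_train]]$behavior$speed_mean[idx_list[[j_train]]]
      y_te <- sessions[[j]]$behavior$speed_mean[idx_list[[j]]]
      fit_fun <- function(x, y) fit_ridge_regression(x, y, config$ridge_alpha)
      scores <- cv_engine(mats[[j_train]], y_tr, mats[[j]], y_te,
                          idx_list[[j_train]], idx_list[[j]], fold_idx,
                          fit_fun, predict_ridge_regression, score_pearson)
      surr <- surrogate_cross(mats, j_train, j, y_tr, y_te, idx_list, fold_idx,
                              fit_fun, predict_ridge_regression, score_pearson,
                              n_surrogates, seed)
      new_decoding_result("speed", "ridge", paste0("day", train_day),
                          paste0("day", days[j]), scores, surr, n, fold_idx, seed)
    } else {
      lab <- function(jj) {
        s <- sessions[[jj]]
        if (task == "coping") s$behavior$coping[idx_list[[jj]]]
        else s$behavior$context[idx_list[[jj]]]
      }
      C <- if (task == "coping") config$coping_C else config$context_C
      fit_fun <- function(x, y) fit_classifier(x, y, "logistic", C = C)
      acc <- function(pred, truth) mean(pred == truth)
      scores <- cv_engine(mats[[j_train]], lab(j_train), mats[[j]], lab(j),
                          idx_list[[j_train]], idx_list[[j]], fold_idx,
                          fit_fun, predict_classifier, acc)
      surr <- surrogate_cross(mats, j_train, j, lab(j_train), lab(j), idx_list,
                              fold_idx, fit_fun, predict_classifier, acc,
                              n_surrogates, seed)
      new_decoding_result(task, "logistic", paste0("day", train_day),
                          paste0("day", days[j]), scores, surr, n, fold_idx, seed)
    }
  })
  names(results) <- paste0("day", days)
  results
}

surrogate_cross <- function(mats, j_train, j_test, y_tr, y_te, idx_list,
                            fold_idx, fit_fun, predict_fun, score_fun,
                            n_surrogates, seed) {
  if (n_surrogates <= 0) return(numeric(0))
  vapply(seq_len(n_surrogates), function(r) {
    sh_tr <- circular_shift_surrogate(mats[[j_train]], child_seed(seed, 43, r))
    sh_te <- if (j_test == j_train) sh_tr else
      circular_shift_surrogate(mats[[j_test]], child_seed(seed, 47, r))
    mean(cv_engine(sh_tr, y_tr, sh_te, y_te, idx_list[[j_train]],
                   idx_list[[j_test]], fold_idx, fit_fun, predict_fun,
                   score_fun), na.rm = TRUE)
  }, numeric(1))
}
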