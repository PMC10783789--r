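# Template manifolds, orthogonal Procrustes alignment with rotation/shuffle
# nulls, and cross-manifold decoding.

#' Center a manifold and scale it to unit Frobenius norm
#'
#' Shifts the d-dimensional centroid to the origin and divides the whole
#' coordinate matrix by its Frobenius norm, placing every manifold in a common
#' reference frame before alignment. Idempotent up to numerical precision.
#'
#' @param coords frames x d coordinate matrix.
#' @return Matrix with column means 0 and Frobenius norm 1.
#' @export
center_scale_manifold <- function(coords) {
  coords <- as.matrix(coords)
  stop_if_not(nrow(coords) >= 2, "center_scale: need at least 2 frames")
  centered <- sweep(coords, 2, colMeans(coords))
  nrm <- sqrt(sum(centered^2))
  stop_if_not(nrm > 0, "center_scale: all frames identical (zero norm)")
  centered / nrm
}

#' Build an epoch-averaged template manifold
#'
#' Each struggle/immobility epoch is rescaled to `n_digits` evenly spaced
#' progression digits (1 = epoch start, `n_digits` = epoch end) and the
#' manifold coordinates are averaged per digit per dimension over all epochs
#' of each coping class. Columns are struggle digits 1..n then immobility
#' digits 1..n, so the default 5-d embedding yields a 5 x 40 template. Epochs
#' shorter than `n_digits` frames contribute via nearest evenly spaced
#' positions (several digits may share a frame); epochs shorter than 2 frames
#' are excluded.
#'
#' @param coords frames x d coordinates of the TS segment.
#' @param coping per-frame coping labels of the same segment.
#' @param n_digits progression digits per epoch (default 20).
#' @return A `template_manifold` matrix of shape d x (2 * n_digits).
#' @export
build_template <- function(coords, coping, n_digits = 20) {
  coords <- as.matrix(coords)
  stop_if_not(nrow(coords) == length(coping),
              "build_template: coords/coping length mismatch")
  d <- ncol(coords)
  out <- matrix(NA_real_, d, 2 * n_digits)
  r <- rle(as.character(coping))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (class_i in 1:2) {
    cls <- c("struggle", "immobility")[class_i]
    epochs <- which(r$values == cls & r$lengths >= 2)
    stop_if_not(length(epochs) >= 1,
                "build_template: no complete ", cls, " epoch")
    sums <- matrix(0, d, n_digits)
    counts <- matrix(0, d, n_digits)
    for (e in epochs) {
      fr <- starts[e]:ends[e]
      L <- length(fr)
      if (L >= n_digits) {
        digit <- round((seq_len(L) - 1) / (L - 1) * (n_digits - 1)) + 1
        for (k in seq_len(n_digits)) {
          sel <- fr[digit == k]
          if (length(sel)) {
            sums[, k] <- sums[, k] + colSums(coords[sel, , drop = FALSE])
            counts[, k] <- counts[, k] + length(sel)
          }
        }
      } else {
        # short epoch: nearest evenly spaced frame per digit
        pick <- fr[round((seq_len(n_digits) - 1) / (n_digits - 1) * (L - 1)) + 1]
        sums <- sums + t(coords[pick, , drop = FALSE])
        counts <- counts + 1
      }
    }
    empty <- which(counts[1, ] == 0)
    stop_if_not(length(empty) == 0,
                "build_template: ", cls, " digit(s) without frames: ",
                paste(empty, collapse = ", "))
    out[, (class_i - 1) * n_digits + seq_len(n_digits)] <- sums / counts
  }
  structure(out, class = c("template_manifold", "matrix", "array"),
            n_digits = n_digits)
}

#' Orthogonal Procrustes alignment
#'
#' Finds the orthogonal matrix Q minimizing `||A Q - B||_F` for templates A
#' (to be aligned) and B (reference), via the SVD closed form: with
#' `t(A) %*% B = U S t(V)` (singular values decreasing), `Q = U t(V)`. Q may
#' include a reflection. Template manifolds (d x 2*n_digits) are transposed
#' internally so time runs along rows.
#'
#' @param template_a,template_b `template_manifold`s or time x d matrices of
#'   identical shape.
#' @return d x d orthogonal matrix Q with attribute `residual`
#'   (`||A Q - B||_F`); a rank-deficient cross-product still returns Q but
#'   warns that the optimum is not unique.
#' @export
procrustes_align <- function(template_a, template_b) {
  A <- if (inherits(template_a, "template_manifold")) t(unclass(template_a)) else as.matrix(template_a)
  B <- if (inherits(template_b, "template_manifold")) t(unclass(template_b)) else as.matrix(template_b)
  stop_if_not(all(dim(A) == dim(B)), "procrustes: template shapes differ")
  M <- crossprod(A, B)
  sv <- svd(M)
  if (min(sv$d) < 1e-12 * max(sv$d, 1e-300))
    warning("procrustes: rank-deficient cross-product; solution not unique")
  Q <- sv$u %*% t(sv$v)
  attr(Q, "residual") <- sqrt(sum((A %*% Q - B)^2))
  Q
}

#' Apply an alignment transform to a full manifold
#'
#' @param m frames x d (centered/scaled) manifold coordinates.
#' @param q d x d orthogonal transform from [procrustes_align()].
#' @return `m %*% q`; pairwise distances among rows are preserved.
#' @export
apply_alignment <- function(m, q) {
  m <- as.matrix(m)
  stop_if_not(ncol(m) == nrow(q), "apply_alignment: shape mismatch")
  m %*% q
}

#' Haar-random orthogonal and rotation matrices
#'
#' `random_orthogonal` draws from the Haar measure on O(d) (QR of a Gaussian
#' matrix with sign correction); `random_rotation` conditions on determinant
#' +1 (SO(d)), the null used for alignment controls.
#'
#' @param d dimension.
#' @return d x d matrix.
#' @export
random_orthogonal <- function(d) {
  qr_ <- qr(matrix(rnorm(d * d), d, d))
  q <- qr.Q(qr_)
  q <- sweep(q, 2, sign(diag(qr.R(qr_))), "*")
  q
}

#' @rdname random_orthogonal
#' @export
random_rotation <- function(d) {
  q <- random_orthogonal(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Random-rotation null for manifold alignment
#'
#' Applies `reps` independent Haar-uniform rotations (det +1) to a manifold
#' and evaluates a downstream score per repetition; the summary is the mean
#' over repetitions (the performance of an average random rotation).
#'
#' @param m frames x d manifold.
#' @param reps repetitions (default 100).
#' @param seed integer seed.
#' @param score_fun function of the rotated manifold returning a scalar; when
#'   NULL the rotated manifolds themselves are returned.
#' @return Numeric vector of scores (or list of manifolds).
#' @export
random_rotation_null <- function(m, reps = 100, seed = 1, score_fun = NULL) {
  d <- ncol(m)
  stop_if_not(d >= 2, "rotation null: d must be >= 2")
  rots <- with_seed(child_seed(seed, 53),
                    lapply(seq_len(reps), function(r) random_rotation(d)))
  if (is.null(score_fun)) return(lapply(rots, function(q) m %*% q))
  vapply(rots, function(q) score_fun(m %*% q), numeric(1))
}

# -- TS-segment manifold pipeline -------------------------------------------

#' Embed the TS segment of a session into a manifold
#'
#' Runs the embedding pipeline on the TS frames: Gaussian smoothing and
#' quantile feature scaling, embedding, and centering/unit-norm scaling, plus
#' the epoch-averaged template used for alignment. With `shuffle_seed` set,
#' each neuron's TS trace is circularly shifted first (the shuffle null for
#' alignment, destroying inter-neuron timing before embedding).
#'
#' @param session a [session_recording()].
#' @param config an [analysis_config()].
#' @param shuffle_seed NULL, or an integer seed for the circular-shift null.
#' @return A `ts_manifold` list: `coords` (frames x d, centered/scaled),
#'   `template`, per-frame `coping` / `true_coping` / `speed`, and the source
#'   frame indices.
#' @export
ts_manifold <- function(session, config = analysis_config(),
                        shuffle_seed = NULL) {
  frames <- context_frames(session, "TS")
  traces <- session$calcium$values[, frames, drop = FALSE]
  if (!is.null(shuffle_seed))
    traces <- circular_shift_surrogate(traces, shuffle_seed)
  scaled <- smooth_quantile_scale(traces, config$smooth_sigma_s,
                                  config$n_quantiles,
                                  session$behavior$frame_rate)
  emb <- embed_manifold(scaled, config$embed_method, config$embed_dims,
                        n_neighbors = if (config$embed_method == "spectral")
                          config$spectral_neighbors else config$isomap_neighbors,
                        fit_fraction = config$fit_fraction)
  coords <- center_scale_manifold(emb$coords)
  true_cop <- (attr(session$behavior, "true_coping") %||%
                 session$behavior$coping)[frames]
  structure(list(
    coords = coords,
    template = build_template(coords, true_cop, config$template_digits),
    coping = session$behavior$coping[frames],
    true_coping = true_cop,
    speed = session$behavior$speed_mean[frames],
    frames = frames, method = emb$method,
    frame_rate = session$behavior$frame_rate), class = "ts_manifold")
}

#' Align one manifold to a reference
#'
#' @param target,reference `ts_manifold` objects.
#' @return List: `Q` (orthogonal transform from [procrustes_align()] of the
#'   templates), `residual`, and `coords` (the target's aligned full manifold).
#' @export
align_manifolds <- function(target, reference) {
  q <- procrustes_align(target$template, reference$template)
  list(Q = q, residual = attr(q, "residual"),
       coords = apply_alignment(target$coords, q))
}

#' Cross-manifold decoding with alignment, rotation, and shuffle controls
#'
#' Trains a decoder on the relationship between the reference manifold and its
#' behavior and predicts behavior from the (aligned) manifold of a different
#' day or animal. Coping uses logistic regression (C = 0.01) on balanced
#' frames equalized within and between the two datasets; speed uses ridge
#' regression (penalty 50). One contiguous fold template is shared by the
#' within-reference, aligned, random-rotation, and shuffle variants.
#'
#' @param reference,target `ts_manifold` objects.
#' @param task `"coping"` or `"speed"`.
#' @param config an [analysis_config()].
#' @param n_rotations random-rotation repetitions (0 = skip).
#' @param shuffle a `ts_manifold` built with `shuffle_seed` (see
#'   [ts_manifold()]), or NULL to skip the shuffle control.
#' @param seed integer seed.
#' @return List: `within` and `aligned` `decoding_result`s, `rotation_scores`
#'   (mean score per rotation), `rotation_mean`, `shuffle` (result or NULL),
#'   and the alignment `Q`/`residual`.
#' @export
cross_manifold_decode <- function(reference, target, task = c("coping", "speed"),
                                  config = analysis_config(), n_rotations = 100,
                                  shuffle = NULL, seed = config$seed) {
  task <- match.arg(task)
  ali <- align_manifolds(target, reference)
  ref_x <- t(reference$coords)           # d x frames
  tgt_aligned <- t(ali$coords)
  tgt_raw <- t(target$coords)

  if (task == "coping") {
    i_ref <- which(reference$coping %in% c("struggle", "immobility"))
    i_tgt <- which(target$coping %in% c("struggle", "immobility"))
    b_ref <- i_ref[balance_binary(reference$coping[i_ref], child_seed(seed, 61))]
    b_tgt <- i_tgt[balance_binary(target$coping[i_tgt], child_seed(seed, 62))]
    n <- min(length(b_ref), length(b_tgt))
    b_ref <- equalize_balanced(b_ref, reference$coping, n)
    b_tgt <- equalize_balanced(b_tgt, target$coping, n)
    n <- min(length(b_ref), length(b_tgt))
    b_ref <- b_ref[seq_len(n)]; b_tgt <- b_tgt[seq_len(n)]
    y_ref <- reference$coping[b_ref]
    y_tgt <- target$coping[b_tgt]
    fold_idx <- make_folds(n, config$folds)
    fit_fun <- function(x, y) fit_classifier(x, y, "logistic", C = config$coping_C)
    pred_fun <- predict_classifier
    score_fun <- function(pred, truth) mean(pred == truth)
  } else {
    n <- min(nrow(reference$coords), nrow(target$coords))
    b_ref <- seq_len(n); b_tgt <- seq_len(n)
    y_ref <- reference$speed[b_ref]
    y_tgt <- target$speed[b_tgt]
    fold_idx <- make_folds(n, config$folds)
    fit_fun <- function(x, y) fit_ridge_regression(x, y, config$ridge_alpha)
    pred_fun <- predict_ridge_regression
    score_fun <- score_pearson
  }

  run <- function(test_mat, y_test, b_test, label) {
    scores <- cv_engine(ref_x, y_ref, test_mat, y_test, b_ref, b_test,
                        fold_idx, fit_fun, pred_fun, score_fun)
    new_decoding_result(task, if (task == "coping") "logistic" else "ridge",
                        "reference", label, scores, numeric(0), n, fold_idx, seed)
  }
  within <- run(ref_x, y_ref, b_ref, "reference")
  aligned <- run(tgt_aligned, y_tgt, b_tgt, "aligned_target")
  rotation_scores <- if (n_rotations > 0) {
    random_rotation_null(t(tgt_raw), n_rotations, child_seed(seed, 63),
                         score_fun = function(mrot)
                           mean(cv_engine(ref_x, y_ref, t(mrot), y_tgt, b_ref,
                                          b_tgt, fold_idx, fit_fun, pred_fun,
                                          score_fun), na.rm = TRUE))
  } else numeric(0)
  shuffle_res <- NULL
  if (!is.null(shuffle)) {
    ali_sh <- align_manifolds(shuffle, reference)
    y_sh <- if (task == "coping") shuffle$coping[b_tgt] else shuffle$speed[b_tgt]
    shuffle_res <- run(t(ali_sh$coords), y_sh, b_tgt, "shuffle")
  }
  list(within = within, aligned = aligned,
       rotation_scores = rotation_scores,
       rotation_mean = if (length(rotation_scores)) mean(rotation_scores) else NA_real_,
       shuffle = shuffle_res, Q = ali$Q, residual = ali$residual)
}

#' Circular reference/target pairing of animals
#'
#' For animals `(a_1 ... a_n)` returns the n pairs `(a_{i-1} -> a_i)`,
#' wrapping so the first animal's reference is the last animal.
#'
#' @param animals list or vector of at least 2 animals (or identifiers).
#' @return List of `list(reference =, target =)` pairs.
#' @export
circular_pairing <- function(animals) {
  n <- length(animals)
  stop_if_not(n >= 2, "circular_pairing: need at least 2 animals")
  lapply(seq_len(n), function(i) {
    list(reference = animals[[if (i == 1) n else i - 1]],
         target = animals[[i]])
  })
}
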