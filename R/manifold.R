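# Low-dimensional embedding and trajectory characterization.

#' Embed scaled traces into a low-dimensional manifold
#'
#' Methods: `isomap` (kNN graph geodesics + classical MDS, fit on an evenly
#' strided subset of frames and extended to all frames by landmark MDS),
#' `pca`, and `spectral` (normalized graph-Laplacian eigenmaps). PCA and
#' spectral embeddings are fit on the full data.
#'
#' @param scaled a `scaled_traces` object from [smooth_quantile_scale()], or a
#'   neurons x frames matrix with values in \[0, 1\].
#' @param method `"isomap"`, `"pca"`, or `"spectral"`.
#' @param d embedding dimensionality (default 5).
#' @param n_neighbors neighbourhood size of the isomap/spectral graph.
#' @param fit_fraction fraction of frames (even temporal stride) used to fit
#'   the isomap model before embedding the full dataset.
#' @return A `manifold_embedding`: `$coords` (frames x d), method and params.
#' @export
embed_manifold <- function(scaled, method = c("isomap", "pca", "spectral"),
                           d = 5, n_neighbors = 500, fit_fraction = 0.6) {
  method <- match.arg(method)
  values <- if (inherits(scaled, "scaled_traces")) scaled$values else scaled
  x <- t(values)                       # frames x neurons
  n <- nrow(x)
  stop_if_not(d >= 2, "embed: d must be >= 2")
  coords <- switch(method,
    pca = {
      p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = d)
      unname(p$x[, seq_len(d), drop = FALSE])
    },
    isomap = isomap_embed(x, d, n_neighbors, fit_fraction),
    spectral = spectral_embed(x, d, min(n_neighbors, n - 1)))
  structure(list(coords = coords, method = method,
                 params = list(d = d, n_neighbors = n_neighbors,
                               fit_fraction = fit_fraction)),
            class = "manifold_embedding")
}

isomap_embed <- function(x, d, n_neighbors, fit_fraction) {
  n <- nrow(x)
  fit_idx <- unique(round(seq(1, n, length.out = max(2, ceiling(fit_fraction * n)))))
  m <- length(fit_idx)
  stop_if_not(m > n_neighbors,
              "isomap: fit frames (", m, ") must exceed n_neighbors (",
              n_neighbors, ")")
  xf <- x[fit_idx, , drop = FALSE]
  nn <- FNN::get.knn(xf, k = n_neighbors)
  edges <- cbind(rep(seq_len(m), n_neighbors), as.vector(nn$nn.index))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- as.vector(nn$nn.dist)
  g <- igraph::simplify(g, edge.attr.comb = "min")
  comp <- igraph::components(g)
  stop_if_not(comp$no == 1,
              "isomap: neighborhood graph is disconnected (", comp$no,
              " components); increase n_neighbors")
  D <- igraph::distances(g)
  D2 <- D^2
  # classical MDS on geodesic distances
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (sweep(sweep(D2, 1, rm_), 2, rm_) + gm)
  eig <- eigen(B, symmetric = TRUE)
  pos <- which(eig$values > 1e-10)
  if (length(pos) < d)
    warning("isomap: only ", length(pos), " positive eigenvalues; padding with 0")
  keep <- head(pos, d)
  lam <- eig$values[keep]
  V <- eig$vectors[, keep, drop = FALSE]
  Y_fit <- sweep(V, 2, sqrt(lam), "*")
  # landmark-MDS out-of-sample extension: geodesics from each frame to all
  # landmarks approximated through its nearest landmarks
  k_out <- min(n_neighbors, 20L)
  nnx <- FNN::get.knnx(xf, x, k = k_out)
  geo <- matrix(Inf, n, m)
  for (j in seq_len(k_out)) {
    cand <- D[nnx$nn.index[, j], , drop = FALSE] + nnx$nn.dist[, j]
    geo <- pmin(geo, cand)
  }
  Linv <- sweep(t(V), 1, sqrt(lam), "/")     # d x m
  delta_mean <- colMeans(D2)
  Y <- 0.5 * t(Linv %*% (delta_mean - t(geo^2)))
  if (length(keep) < d) Y <- cbind(Y, matrix(0, n, d - length(keep)))
  unname(Y)
}

spectral_embed <- function(x, d, n_neighbors) {
  n <- nrow(x)
  nn <- FNN::get.knn(x, k = n_neighbors)
  W <- matrix(0, n, n)
  for (j in seq_len(n_neighbors)) W[cbind(seq_len(n), nn$nn.index[, j])] <- 1
  W <- pmax(W, t(W))
  deg <- rowSums(W)
  stop_if_not(all(deg > 0), "spectral: isolated vertex in neighborhood graph")
  S <- sweep(sweep(W, 1, sqrt(deg), "/"), 2, sqrt(deg), "/")
  L <- diag(n) - S
  eig <- eigen(L, symmetric = TRUE)
  ord <- order(eig$values)
  unname(eig$vectors[, ord[2:(d + 1)], drop = FALSE])
}

#' Select the 2-d plane with the strongest rotational trajectory
#'
#' Scores every axis pair by `|mean signed turn angle| * resultant length` of
#' the pair's turn-angle distribution (computed on the temporally binned
#' trajectory) and returns the best pair; exact ties break toward the lowest
#' axis indices.
#'
#' @param embedding a `manifold_embedding` or a frames x d coordinate matrix.
#' @param frame_rate frames per second of the embedded segment.
#' @param target_rate_hz temporal binning rate for the turn-angle series.
#' @return Integer axis pair `c(i, j)`.
#' @export
select_plane <- function(embedding, frame_rate = 20, target_rate_hz = 2.67) {
  coords <- if (inherits(embedding, "manifold_embedding")) embedding$coords else embedding
  d <- ncol(coords)
  stop_if_not(d >= 2, "select_plane: need at least 2 dimensions")
  pairs <- utils::combn(d, 2)
  scores <- apply(pairs, 2, function(p) {
    ta <- turn_angles(coords[, p], frame_rate = frame_rate,
                      target_rate_hz = target_rate_hz)
    if (length(ta$angles) == 0) return(0)
    # directional consistency (net leftward minus rightward share, straight
    # steps count 0) weighted by the turn-angle concentration
    s <- ifelse(ta$angles > 0 & ta$angles < pi, 1,
                ifelse(ta$angles > pi, -1, 0))
    abs(mean(s)) * abs(mean(exp(1i * ta$angles)))
  })
  best <- which(scores == max(scores))[1]  # ties -> lowest axis indices
  pairs[, best]
}

#' Flow field of a 2-d manifold plane
#'
#' Velocity vectors between consecutive time points are assigned to a
#' `bins` x `bins` spatial grid over the plane's bounding box (by the position
#' of their starting point) and averaged per bin.
#'
#' @param plane frames x 2 coordinate matrix.
#' @param bins grid resolution per axis (default 15).
#' @return A `flow_field`: bin edges and centers, mean velocity components
#'   (`vx`, `vy`, NA for empty bins), occupancy counts summing to
#'   `n_frames - 1`, and `radial` (per-bin mean radial velocity component
#'   about the plane origin, measured at each step's midpoint; 0 everywhere
#'   for motion tangent to circles around the origin, positive for outward
#'   drift).
#' @export
flow_field <- function(plane, bins = 15) {
  plane <- as.matrix(plane)
  stop_if_not(nrow(plane) >= 2, "flow_field: need at least 2 frames")
  v <- diff(plane)
  pos <- plane[-nrow(plane), , drop = FALSE]
  mid <- (plane[-nrow(plane), , drop = FALSE] + plane[-1, , drop = FALSE]) / 2
  mid_norm <- sqrt(rowSums(mid^2))
  radial_t <- ifelse(mid_norm > 0, rowSums(v * mid) / pmax(mid_norm, 1e-300), 0)
  ex <- seq(min(plane[, 1]), max(plane[, 1]), length.out = bins + 1)
  ey <- seq(min(plane[, 2]), max(plane[, 2]), length.out = bins + 1)
  bx <- pmin(pmax(findInterval(pos[, 1], ex, rightmost.closed = TRUE), 1), bins)
  by <- pmin(pmax(findInterval(pos[, 2], ey, rightmost.closed = TRUE), 1), bins)
  key <- (bx - 1) * bins + by
  vx <- matrix(NA_real_, bins, bins)
  vy <- matrix(NA_real_, bins, bins)
  counts <- matrix(0L, bins, bins)
  radial <- matrix(NA_real_, bins, bins)
  agg_x <- tapply(v[, 1], key, mean)
  agg_y <- tapply(v[, 2], key, mean)
  agg_r <- tapply(radial_t, key, mean)
  agg_n <- tapply(v[, 1], key, length)
  kk <- as.integer(names(agg_x))
  ix <- (kk - 1) %/% bins + 1
  iy <- (kk - 1) %% bins + 1
  vx[cbind(ix, iy)] <- agg_x
  vy[cbind(ix, iy)] <- agg_y
  radial[cbind(ix, iy)] <- agg_r
  counts[cbind(ix, iy)] <- as.integer(agg_n)
  structure(list(edges_x = ex, edges_y = ey,
                 centers_x = (ex[-1] + ex[-(bins + 1)]) / 2,
                 centers_y = (ey[-1] + ey[-(bins + 1)]) / 2,
                 vx = vx, vy = vy, radial = radial, counts = counts),
            class = "flow_field")
}

#' Turn-angle series of a 2-d trajectory
#'
#' The trajectory is mean-binned to roughly `target_rate_hz`, velocity angles
#' are taken with the two-argument arctangent, and consecutive angle
#' differences are reported mod 2*pi. Differences in (0, pi) are leftward
#' (counterclockwise) turns, in (pi, 2*pi) rightward.
#'
#' @param plane frames x 2 coordinate matrix.
#' @param frame_rate frames per second of the trajectory.
#' @param target_rate_hz temporal binning rate (default 2.67 Hz).
#' @param n_bins optionally fix the bin count directly.
#' @return List: `angles` (turn-angle series in \[0, 2*pi)), `leftward_fraction`
#'   (share in the open interval (0, pi)), `n_skipped` (zero-velocity steps).
#' @export
turn_angles <- function(plane, frame_rate = 20, target_rate_hz = 2.67,
                        n_bins = NULL) {
  plane <- as.matrix(plane)
  n <- nrow(plane)
  if (is.null(n_bins)) n_bins <- max(3L, round(n * target_rate_hz / frame_rate))
  n_bins <- min(n_bins, n)
  stop_if_not(n_bins >= 3, "turn_angles: need at least 3 time bins")
  grp <- cut(seq_len(n), breaks = n_bins, labels = FALSE)
  binned <- cbind(tapply(plane[, 1], grp, mean), tapply(plane[, 2], grp, mean))
  v <- diff(binned)
  speed <- sqrt(rowSums(v^2))
  ok <- speed > 0
  theta <- atan2(v[ok, 2], v[ok, 1])
  ang <- diff(theta) %% (2 * pi)
  list(angles = ang,
       leftward_fraction = if (length(ang)) mean(ang > 0 & ang < pi) else NA_real_,
       n_skipped = sum(!ok))
}
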