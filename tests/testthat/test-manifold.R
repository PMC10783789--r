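# Embedding, trajectory characterization, template manifolds, Procrustes
# alignment and its nulls.

test_that("PCA embedding reconstructs an exact linear subspace", {
  set.seed(3)
  basis <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  z <- matrix(rnorm(1000 * 2), 1000, 2)
  X <- z %*% t(basis)                 # frames x 10 ambient
  emb <- embed_manifold(t(X), "pca", d = 5)
  # variance beyond the first two coordinates vanishes
  expect_lt(sum(emb$coords[, 3:5]^2), 1e-16)
  # the first two coordinates span the planted subspace exactly
  fit <- lm.fit(cbind(1, emb$coords[, 1:2]), z)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("isomap agrees with an independent implementation on a noisy ring", {
  skip_if_not_installed("vegan")
  set.seed(5)
  th <- runif(300, 0, 2 * pi)
  X <- cbind(cos(th), sin(th)) %*% matrix(rnorm(20), 2, 10) +
    matrix(rnorm(3000, 0, 0.05), 300, 10)
  mine <- embed_manifold(t(X), "isomap", d = 2, n_neighbors = 12,
                         fit_fraction = 1)$coords
  ref <- vegan::isomap(dist(X), ndim = 2, k = 12)$points
  A <- center_scale_manifold(mine)
  B <- center_scale_manifold(ref)
  q <- procrustes_align(A, B)
  expect_lt(attr(q, "residual"), 1e-6)
})

test_that("isomap out-of-sample extension reproduces fit coordinates", {
  set.seed(6)
  th <- sort(runif(400, 0, 2 * pi))
  X <- cbind(cos(th), sin(th), 0.02 * rnorm(400))
  emb_full <- embed_manifold(t(X), "isomap", d = 2, n_neighbors = 15,
                             fit_fraction = 1)$coords
  emb_sub <- embed_manifold(t(X), "isomap", d = 2, n_neighbors = 15,
                            fit_fraction = 0.6)$coords
  # both capture the ring: binned turn angles nearly all one-signed
  for (coords in list(emb_full, emb_sub)) {
    ta <- turn_angles(coords)
    expect_gt(max(ta$leftward_fraction, 1 - ta$leftward_fraction), 0.8)
  }
  expect_error(embed_manifold(t(X), "isomap", n_neighbors = 500),
               "n_neighbors")
})

test_that("spectral embedding separates two clusters", {
  set.seed(7)
  X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 6), 100, 2))
  emb <- embed_manifold(t(X), "spectral", d = 2, n_neighbors = 10)
  grp <- rep(c(1, 2), each = 100)
  expect_gt(abs(cor(emb$coords[, 1], grp)), 0.9)
})

test_that("select_plane finds the planted rotational plane", {
  set.seed(8)
  th <- seq(0, 2 * pi, length.out = 801)[-801]
  emb <- cbind(cos(th), rnorm(800, 0, 0.1), sin(th),
               rnorm(800, 0, 0.1), rnorm(800, 0, 0.1))
  expect_identical(select_plane(emb), c(1L, 3L))
})

test_that("flow field matches constructed motion and conserves occupancy", {
  # uniform linear motion: every occupied bin's mean vector is the step
  line <- cbind(seq(0, 10, length.out = 200), seq(0, 5, length.out = 200))
  ffl <- flow_field(line)
  step <- c(10, 5) / 199
  occ <- which(!is.na(ffl$vx))
  expect_equal(ffl$vx[occ], rep(step[1], length(occ)), tolerance = 1e-12)
  expect_equal(ffl$vy[occ], rep(step[2], length(occ)), tolerance = 1e-12)
  expect_identical(sum(ffl$counts), nrow(line) - 1L)
  # perfect circle: per-bin radial flow component vanishes
  th <- seq(0, 2 * pi, length.out = 801)[-801]
  ff <- flow_field(cbind(cos(th), sin(th)))
  vmag <- sqrt(ff$vx^2 + ff$vy^2)
  expect_lt(max(abs(ff$radial / vmag), na.rm = TRUE), 1e-6)
  expect_identical(sum(ff$counts), 799L)
})

test_that("turn angles classify rotation direction", {
  th <- seq(0, 2 * pi, length.out = 801)[-801]
  circ <- cbind(cos(th), sin(th))
  expect_equal(turn_angles(circ, n_bins = 800)$leftward_fraction, 1)
  expect_equal(turn_angles(circ[800:1, ], n_bins = 800)$leftward_fraction, 0)
  line <- cbind(1:100, 2 * (1:100))
  expect_equal(turn_angles(line, n_bins = 100)$leftward_fraction, 0)
  # invariance under rotation, flip under reflection
  R <- matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2)
  expect_equal(turn_angles(circ %*% R, n_bins = 800)$leftward_fraction, 1)
  expect_equal(turn_angles(circ %*% diag(c(1, -1)), n_bins = 800)$leftward_fraction, 0)
})

test_that("center_scale_manifold normalizes, is idempotent, and rejects degenerate input", {
  set.seed(9)
  m <- matrix(rnorm(200), 50, 4) + 5
  cs <- center_scale_manifold(m)
  expect_lt(max(abs(colMeans(cs))), 1e-10)
  expect_equal(sum(cs^2), 1, tolerance = 1e-10)
  expect_equal(center_scale_manifold(cs), cs, tolerance = 1e-10)
  expect_error(center_scale_manifold(matrix(c(3, 4, 3, 4), 2, byrow = TRUE)),
               "zero norm")
})

test_that("template construction digitizes epochs as specified", {
  # two epochs per class over 20 frames each: digit k = mean of the k-th values
  coords <- matrix(c(0:19, 100:119, 20:39, 120:139), ncol = 1)
  lab <- rep(c("struggle", "immobility", "struggle", "immobility"), each = 20)
  tm <- build_template(coords, lab, n_digits = 20)
  expect_identical(dim(unclass(tm)), c(1L, 40L))
  expect_equal(tm[1, 1:20], (0:19 + 20:39) / 2)
  expect_equal(tm[1, 21:40], (100:119 + 120:139) / 2)
  # a constant epoch yields a constant template row
  coords2 <- matrix(rep(c(2, 7), each = 30), ncol = 1)
  lab2 <- rep(c("struggle", "immobility"), each = 30)
  tm2 <- build_template(coords2, lab2, 20)
  expect_true(all(tm2[1, 1:20] == 2) && all(tm2[1, 21:40] == 7))
  # short epochs are served by repeated frames
  coords3 <- matrix(c(1, 2, 3, 10, 20), ncol = 1)
  tm3 <- build_template(coords3, c("struggle", "struggle", "struggle",
                                   "immobility", "immobility"), 20)
  expect_identical(dim(unclass(tm3)), c(1L, 40L))
  expect_error(build_template(coords, rep("struggle", 80), 20), "immobility")
})

test_that("Procrustes closed form is exact and optimal", {
  set.seed(10)
  A <- matrix(rnorm(200), 40, 5)
  expect_lt(max(abs(procrustes_align(A, A) - diag(5))), 1e-10)
  R <- random_rotation(5)
  Q <- procrustes_align(A, A %*% R)
  expect_lt(sqrt(sum((A %*% Q - A %*% R)^2)), 1e-8)
  expect_lt(max(abs(Q - R)), 1e-6)
  # orthogonality and residual never worse than identity
  B <- matrix(rnorm(200), 40, 5)
  Q2 <- procrustes_align(A, B)
  expect_lt(max(abs(crossprod(Q2) - diag(5))), 1e-10)
  expect_lte(attr(Q2, "residual"), sqrt(sum((A - B)^2)))
  expect_warning(procrustes_align(matrix(0, 40, 5), B), "rank-deficient")
})

test_that("d = 2 Procrustes matches an angle-grid brute force", {
  set.seed(11)
  A <- matrix(rnorm(80), 40, 2)
  B <- matrix(rnorm(80), 40, 2)
  Q <- procrustes_align(A, B)
  th <- seq(0, 2 * pi, by = 1e-4)
  # residual^2 = ||A||^2 + ||B||^2 - 2 tr(Q' M): scan rotations and reflections
  M <- crossprod(A, B)
  tr_rot <- cos(th) * (M[1, 1] + M[2, 2]) + sin(th) * (M[2, 1] - M[1, 2])
  tr_ref <- cos(th) * (M[1, 1] - M[2, 2]) + sin(th) * (M[2, 1] + M[1, 2])
  best <- sqrt(sum(A^2) + sum(B^2) - 2 * max(tr_rot, tr_ref))
  expect_equal(attr(Q, "residual"), best, tolerance = 1e-6)
})

test_that("alignment application preserves geometry", {
  set.seed(12)
  m <- center_scale_manifold(matrix(rnorm(500), 100, 5))
  q <- random_orthogonal(5)
  out <- apply_alignment(m, q)
  expect_identical(dim(out), dim(m))
  expect_equal(as.numeric(dist(out)), as.numeric(dist(m)), tolerance = 1e-10)
  expect_identical(apply_alignment(m, diag(5)), m)
  expect_error(apply_alignment(m, diag(4)), "shape mismatch")
})

test_that("Haar rotations are orthogonal, det +1, and angle-uniform in 2d", {
  set.seed(13)
  for (d in c(2, 5)) {
    for (i in 1:20) {
      q <- random_rotation(d)
      expect_lt(max(abs(crossprod(q) - diag(d))), 1e-10)
      expect_equal(det(q), 1, tolerance = 1e-10)
    }
  }
  angles <- replicate(10000, {
    q <- random_rotation(2)
    atan2(q[2, 1], q[1, 1])
  })
  ks <- suppressWarnings(ks.test((angles + pi) / (2 * pi), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("circular pairing wraps the animal list", {
  p <- circular_pairing(list("a", "b", "c"))
  expect_identical(vapply(p, `[[`, "", "reference"), c("c", "a", "b"))
  expect_identical(vapply(p, `[[`, "", "target"), c("a", "b", "c"))
  expect_length(circular_pairing(as.list(1:6)), 6)
  p2 <- circular_pairing(list("a", "b"))
  expect_identical(p2[[1]]$reference, "b")
  expect_error(circular_pairing(list("a")), "at least 2")
})
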