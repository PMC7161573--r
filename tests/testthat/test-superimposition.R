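test_that("center_and_scale centers, normalises and reports centroid size", {
  res <- center_and_scale(triangle3d())
  expect_equal(res$centroid_size, sqrt(4 / 3))
  expect_equal(colMeans(res$config), c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(sqrt(sum(res$config^2)), 1)

  # idempotent on an already-normalised shape
  again <- center_and_scale(res$config)
  expect_equal(again$config, res$config)
  expect_equal(again$centroid_size, 1)

  # scale equivariance: scaling by 5 changes only the reported size
  scaled <- center_and_scale(5 * triangle3d())
  expect_equal(scaled$config, res$config)
  expect_equal(scaled$centroid_size, 5 * res$centroid_size)

  expect_error(center_and_scale(matrix(1, 4, 3)), "degenerate")
})

test_that("optimal_rotation recovers rotations and refuses reflections", {
  A <- center_unit(triangle3d())
  R30 <- rotation_z(pi / 6)
  B <- A %*% R30
  R <- optimal_rotation(A, B)
  expect_equal(R, R30, tolerance = 1e-12)
  expect_equal(det(R), 1)
  expect_lt(sum((A %*% R - B)^2), 1e-20)

  # mirror image of a chiral shape cannot be reached with det = +1
  H <- center_unit(chiral_helix())
  Hm <- mirror(H, "x")
  Rm <- optimal_rotation(H, Hm)
  expect_equal(det(Rm), 1, tolerance = 1e-12)
  expect_gt(sum((H %*% Rm - Hm)^2), 1e-3)
})

test_that("optimal rotation and procrustes distance match a planar grid oracle", {
  set.seed(21)
  for (rep in 1:3) {
    A <- center_unit(cbind(matrix(rnorm(10), 5, 2), 0))
    B <- center_unit(cbind(matrix(rnorm(10), 5, 2), 0))
    oracle <- grid_rotation_ss(A, B, step = 0.001)
    R <- optimal_rotation(A, B)
    expect_lte(sum((A %*% R - B)^2), oracle$ss + 1e-9)
    # analytic optimum within grid resolution of the grid-search optimum
    expect_equal(sqrt(sum((A %*% R - B)^2)), sqrt(oracle$ss),
                 tolerance = 0.001)
    expect_equal(procrustes_distance(B, A), sqrt(oracle$ss),
                 tolerance = 0.001)
  }
})

test_that("the ordinary Procrustes fit matches vegan's two-matrix solution", {
  skip_if_not_installed("vegan")
  set.seed(23)
  # a pair where the reflected fit is not optimal, so the det = +1
  # constraint is inactive and both solvers target the same optimum
  A <- center_unit(chiral_helix())
  B <- center_unit(chiral_helix() + matrix(rnorm(36, sd = 0.05), 12, 3))
  R <- optimal_rotation(B, A)
  ours <- sum((B %*% R - A)^2)
  veg <- vegan::procrustes(A, B, scale = FALSE)
  theirs <- sum((veg$Yrot - A)^2)
  expect_equal(ours, theirs, tolerance = 1e-10)
  expect_equal(procrustes_distance(A, B), sqrt(theirs), tolerance = 1e-10)
})

test_that("procrustes_distance is a rotation-invariant premetric", {
  a <- center_unit(chiral_helix())
  expect_equal(procrustes_distance(a, a), 0)
  expect_equal(procrustes_distance(a, a %*% rotation_z(1.1)), 0,
               tolerance = 1e-12)
  b <- center_unit(chiral_helix() + matrix(rnorm(36, sd = .1), 12, 3))
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
               tolerance = 1e-12)
  expect_error(procrustes_distance(a, center_unit(triangle3d())),
               "landmark count")
  expect_error(procrustes_distance(a * 3, a), "unit")
})

test_that("mirror is an involution that preserves centroid size", {
  cfg <- landmark_config(chiral_helix(), "helix")
  expect_equal(mirror(mirror(cfg, "y"), "y"), cfg)
  expect_equal(centroid_size_of(mirror(cfg, "z")), centroid_size_of(cfg))
  # chirality: the mirrored helix is a genuinely different shape
  d <- procrustes_distance(center_unit(cfg$points),
                           center_unit(mirror(cfg, "x")$points))
  expect_gt(d, 0.01)
})

test_that("gpa aligns identical shapes under arbitrary similarity transforms", {
  set.seed(31)
  base <- chiral_helix()
  n <- 6
  A <- array(0, dim = c(nrow(base), 3, n))
  for (i in 1:n) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    A[, , i] <- (base %*% Q) * runif(1, .5, 3) +
      matrix(runif(3, -2, 2), nrow(base), 3, byrow = TRUE)
  }
  fit <- gpa(A)
  for (i in 2:n)
    expect_lt(sqrt(sum((fit$aligned[, , i] - fit$aligned[, , 1])^2)), 1e-8)
  expect_true(all(abs(apply(fit$aligned, 3, centroid_size) - 1) < 1e-10))
  expect_lt(max(abs(colMeans(fit$consensus))), 1e-10)
})

test_that("gpa matches an independently coded brute-force alternating minimizer", {
  # oracle: alternating minimisation with rotations found by 0.001-rad grid
  # search over the plane-preserving proper rotations
  set.seed(32)
  tris <- lapply(1:3, function(i)
    cbind(matrix(rnorm(8, sd = 1), 4, 2), 0))
  A <- array(0, dim = c(4, 3, 3))
  for (i in 1:3) A[, , i] <- center_unit(tris[[i]])
  oracle <- A
  for (pass in 1:40) {
    # reference: first specimen on the first pass (as in gpa), then the mean
    cons <- if (pass == 1) oracle[, , 1] else apply(oracle, c(1, 2), mean)
    for (i in 1:3) {
      best <- grid_rotation_ss(oracle[, , i], cons, step = 1e-3)
      oracle[, , i] <- oracle[, , i] %*% best$R
    }
  }
  oracle_cons <- apply(oracle, c(1, 2), mean)
  fit <- gpa(A)
  # compare via the rotation-invariant Procrustes distance of the consensus
  d <- procrustes_distance(center_unit(fit$consensus),
                           center_unit(oracle_cons))
  expect_lt(d, 1e-3)
  expect_equal(sum(sweep(fit$aligned, c(1, 2), fit$consensus)^2),
               sum(sweep(oracle, c(1, 2), oracle_cons)^2),
               tolerance = 1e-5)
})

test_that("gpa consensus is the mean of aligned specimens and trace is monotone", {
  s <- make_two_group_sample(n_focal = 5, n_other = 7, preset = "tiny",
                             seed = 5)
  fit <- gpa(s)
  expect_equal(fit$consensus, apply(fit$aligned, c(1, 2), mean),
               tolerance = 1e-10)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
})

test_that("gpa recovers a known mean shape from noisy populations", {
  shape <- synthetic_preset("tiny")
  sigma <- 0.01
  n <- 200
  pop <- make_population(shape$config, n = n, within_sd = sigma,
                         scheme = shape$scheme, seed = 77)
  fit <- gpa(pop)
  M <- center_unit(shape$config$points)
  R <- optimal_rotation(M, center_unit(fit$consensus))
  diffs <- abs(M %*% R - center_unit(fit$consensus))
  expect_lt(max(diffs), 3 * sigma / sqrt(n) * 3)  # 3 MC sds, loose per coord
})

test_that("gpa and sliding are invariant to similarity transforms of the input", {
  set.seed(41)
  s <- make_two_group_sample(n_focal = 4, n_other = 6, preset = "tiny",
                             seed = 9)
  A <- s$coords
  B <- A
  for (i in seq_len(dim(A)[3])) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    B[, , i] <- (A[, , i] %*% Q) * runif(1, .25, 4) +
      matrix(runif(3, -5, 5), dim(A)[1], 3, byrow = TRUE)
  }
  for (slide in c(FALSE, TRUE)) {
    fa <- gpa(A); fb <- gpa(B)
    if (slide) {
      fa <- slide_semilandmarks(fa, s$scheme)
      fb <- slide_semilandmarks(fb, s$scheme)
    }
    # the two solutions may differ by one global rotation
    R <- optimal_rotation(center_unit(fa$consensus), center_unit(fb$consensus))
    for (i in seq_len(dim(A)[3]))
      expect_lt(max(abs(fa$aligned[, , i] %*% R - fb$aligned[, , i])), 1e-8)
  }
})

test_that("sliding removes purely tangential deviations", {
  shape <- synthetic_preset("tiny")
  ref <- center_unit(shape$config$points)
  dev <- ref
  # displace one interior semilandmark along its local tangent
  ix <- shape$scheme$curves[[2]]
  j <- ix[3]
  tangent <- ref[ix[4], ] - ref[ix[2], ]
  tangent <- tangent / sqrt(sum(tangent^2))
  dev[j, ] <- dev[j, ] + 0.02 * tangent
  A <- array(0, dim = c(nrow(ref), 3, 4))
  A[, , 1] <- dev
  for (i in 2:4) A[, , i] <- ref
  fit <- slide_semilandmarks(gpa(A), shape$scheme, outer_iter = 10)
  d <- procrustes_distance(center_unit(fit$aligned[, , 1]),
                           center_unit(fit$aligned[, , 2]))
  expect_lt(d, 1e-4)
  expect_lt(d, procrustes_distance(center_unit(dev), ref) / 20)
})

test_that("sliding never increases the total Procrustes sum of squares", {
  for (seed in c(3, 17)) {
    s <- make_two_group_sample(n_focal = 5, n_other = 5, preset = "tiny",
                               within_sd = 0.02, tangential_jitter_sd = 0.02,
                               seed = seed)
    fit <- gpa(s)
    before <- tail(fit$objective_trace, 1)
    slid <- slide_semilandmarks(fit)
    expect_true(slid$slid)
    expect_lte(tail(slid$objective_trace, 1), before + 1e-12)
    expect_true(all(diff(slid$objective_trace) <= 1e-12))
  }
})

test_that("the tangential update matches a 1-D grid search oracle", {
  shape <- synthetic_preset("tiny")
  ref <- center_unit(shape$config$points)
  X <- ref
  ix <- shape$scheme$curves[[1]]
  j <- ix[3]
  tangent <- X[ix[4], ] - X[ix[2], ]
  tangent <- tangent / sqrt(sum(tangent^2))
  X[j, ] <- X[j, ] + 0.015 * tangent + 0.003 * c(0, 0, 1)
  slid <- morphovar:::.slide_specimen(X, ref, shape$scheme)
  # oracle: place the point at every tangential offset on a fine grid and
  # keep the position closest to the reference
  offsets <- seq(-0.05, 0.05, by = 1e-4)
  ss <- vapply(offsets, function(t) sum((X[j, ] + t * tangent - ref[j, ])^2), 0)
  best <- X[j, ] + offsets[which.min(ss)] * tangent
  expect_lt(max(abs(slid[j, ] - best)), 1e-3)
})
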