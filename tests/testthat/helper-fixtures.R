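# fixtures and independent oracles shared across test files

# planar triangle embedded in 3D, centered and unit-sized on request
triangle3d <- function(centered = FALSE) {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  if (centered) {
    X <- sweep(X, 2, colMeans(X))
    X <- X / sqrt(sum(X^2))
  }
  X
}

rotation_z <- function(theta)
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))

# chiral spiral: its mirror image cannot be rotated back onto it
chiral_helix <- function(p = 12) {
  t <- seq(0, 4 * pi, length.out = p)
  cbind(cos(t), sin(t), t / (2 * pi))
}

center_unit <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  X / sqrt(sum(X^2))
}

# independent oracle: best proper rotation between two planar (z = 0 plane)
# centered shapes, by brute-force grid search. Plane-preserving proper
# rotations come in two sheets: in-plane rotations rot_z(theta), and
# rot_z(theta) composed with a flip of the plane (diag(1,-1,-1)), which acts
# as an in-plane reflection.
grid_rotation_ss <- function(A, B, step = 0.001) {
  angles <- seq(0, 2 * pi, by = step)
  flip <- diag(c(1, -1, -1))
  best <- list(ss = Inf, R = diag(3))
  for (sheet in 1:2) {
    ss <- vapply(angles, function(th) {
      R <- rotation_z(th)
      if (sheet == 2) R <- R %*% flip
      sum((A %*% R - B)^2)
    }, 0)
    i <- which.min(ss)
    if (ss[i] < best$ss) {
      R <- rotation_z(angles[i])
      if (sheet == 2) R <- R %*% flip
      best <- list(ss = ss[i], R = R, angle = angles[i], sheet = sheet)
    }
  }
  best
}

# independent oracle: exact permutation p of the one-way pseudo-F over all
# distinct two-group label assignments (via combn)
enum_perm_p <- function(X, labels) {
  labels <- as.character(labels)
  lv <- unique(labels)
  stopifnot(length(lv) == 2)
  n <- nrow(X)
  n1 <- sum(labels == lv[1])
  Xc <- sweep(X, 2, colMeans(X))
  sst <- sum(Xc^2)
  f_of <- function(lab) {
    ssb <- 0
    for (g in lv) {
      rows <- which(lab == g)
      ssb <- ssb + sum(colSums(Xc[rows, , drop = FALSE])^2) / length(rows)
    }
    (ssb / 1) / ((sst - ssb) / (n - 2))
  }
  f_obs <- f_of(labels)
  combos <- combn(n, n1)
  f_all <- apply(combos, 2, function(ix) {
    lab <- rep(lv[2], n)
    lab[ix] <- lv[1]
    f_of(lab)
  })
  list(p = mean(f_all >= f_obs - 1e-12), f_obs = f_obs, f_all = f_all)
}

# independent oracle: Pillai trace and approximate F from the textbook
# H / E definitions, written out long-hand
pillai_direct <- function(Y, labels) {
  Y <- as.matrix(Y)
  labels <- factor(labels)
  n <- nrow(Y); q <- ncol(Y); g <- nlevels(labels)
  grand <- colMeans(Y)
  H <- matrix(0, q, q); E <- matrix(0, q, q)
  for (lev in levels(labels)) {
    rows <- Y[labels == lev, , drop = FALSE]
    m <- colMeans(rows)
    H <- H + nrow(rows) * tcrossprod(m - grand)
    for (r in seq_len(nrow(rows)))
      E <- E + tcrossprod(rows[r, ] - m)
  }
  lambda <- Re(eigen(solve(E) %*% H, only.values = TRUE)$values)
  V <- sum(lambda / (1 + lambda))
  s <- min(q, g - 1)
  m <- (abs(q - g + 1) - 1) / 2
  r <- (n - g - q - 1) / 2
  f <- ((2 * r + s + 1) / (2 * m + s + 1)) * (V / s) / (1 - V / s)
  list(pillai = V, approx_f = f,
       df1 = s * (2 * m + s + 1), df2 = s * (2 * r + s + 1))
}
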