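# internal helpers shared across modules

# run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so package functions do not clobber user seeds
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# flatten a p x 3 x n coordinate array to an n x 3p matrix (x1..xp, y1..yp,
# z1..zp per row); the inverse of unflatten_coords
flatten_coords <- function(A) {
  stopifnot(length(dim(A)) == 3L)
  n <- dim(A)[3L]
  t(matrix(A, nrow = dim(A)[1L] * dim(A)[2L], ncol = n))
}

unflatten_coords <- function(M, p) {
  n <- nrow(M)
  array(t(M), dim = c(p, 3L, n))
}

centroid_size <- function(X) {
  ctr <- colMeans(X)
  sqrt(sum(sweep(X, 2L, ctr)^2))
}

# uniform random rotation in SO(3) (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

# FNV-1a hash of a serialized R object, as a hex string; used for config
# fingerprints in output manifests
object_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 3L)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
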