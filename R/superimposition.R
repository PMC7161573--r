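# Ordinary and Generalised Procrustes Analysis with sliding semilandmarks.
#
# Conventions: configurations are p x 3 matrices; samples are p x 3 x n
# arrays. GPA keeps every specimen at unit centroid size (partial
# Procrustes); the reported consensus is the coordinate-wise mean of the
# aligned specimens.

.centered_scaled <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  cs <- sqrt(sum(Xc^2))
  if (cs < 1e-14 * (1 + max(abs(X))))
    stop("degenerate configuration: all landmarks coincide", call. = FALSE)
  list(points = Xc / cs, centroid_size = cs)
}

#' Center a configuration and scale it to unit centroid size
#'
#' Centroid size is the square root of the summed squared distances of the
#' landmarks to their centroid — the size measure removed by Procrustes
#' superimposition.
#'
#' @param config a [landmark_config()] or p x 3 matrix.
#' @return list with `config` (centered, unit centroid size; same class as
#'   the input) and `centroid_size` (the original size).
#' @examples
#' cs <- center_and_scale(rbind(c(0,0,0), c(1,0,0), c(0,1,0)))
#' cs$centroid_size  # sqrt(4/3)
#' @export
center_and_scale <- function(config) {
  if (inherits(config, "landmark_config")) {
    res <- .centered_scaled(config$points)
    out <- landmark_config(res$points, config$specimen_id, config$labels)
    list(config = out, centroid_size = res$centroid_size)
  } else {
    res <- .centered_scaled(as.matrix(config))
    list(config = res$points, centroid_size = res$centroid_size)
  }
}

#' Centroid size of a configuration
#' @param config a [landmark_config()] or p x 3 matrix.
#' @return the centroid size (a positive real).
#' @export
centroid_size_of <- function(config) {
  X <- if (inherits(config, "landmark_config")) config$points else as.matrix(config)
  centroid_size(X)
}

#' Optimal rotation between two centered configurations
#'
#' Returns the proper rotation R (det = +1) minimising `||A R - B||^2`,
#' via the singular value decomposition of `t(A) B` with a sign flip on the
#' smallest singular direction when needed. Reflections are never returned:
#' chiral structures keep their handedness.
#'
#' @param A,B centered p x 3 matrices.
#' @return 3 x 3 rotation matrix.
#' @export
optimal_rotation <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("A and B must have equal dimensions", call. = FALSE)
  M <- crossprod(A, B)
  sv <- svd(M)
  # rank >= 2 still has a unique proper-rotation optimum (the det sign flip
  # resolves the null direction); only rank <= 1 is genuinely ambiguous
  if (sv$d[1L] > 0 && sv$d[2L] / sv$d[1L] < 1e-12)
    warning("near rank-deficient cross-covariance; rotation may be non-unique",
            call. = FALSE)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
}

#' Procrustes distance between two aligned configurations
#'
#' The root summed squared distance between two centered, unit-centroid-size
#' configurations at their optimal proper rotation.
#'
#' @param a,b centered p x 3 matrices with centroid size 1 (tolerance 1e-6).
#' @return non-negative real; 0 iff the shapes are identical up to rotation.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("configurations differ in landmark count", call. = FALSE)
  for (X in list(a, b)) {
    if (max(abs(colMeans(X))) > 1e-6 || abs(centroid_size(X) - 1) > 1e-6)
      stop("procrustes_distance() expects centered, unit-centroid-size inputs; ",
           "use center_and_scale() first", call. = FALSE)
  }
  R <- optimal_rotation(b, a)       # rotate b onto a
  sqrt(sum((a - b %*% R)^2))
}

#' Mirror a configuration across a coordinate plane
#'
#' Flips the sign of one coordinate axis, e.g. to standardise right-side
#' specimens of a chiral structure to the left before superimposition.
#' Centroid size is unchanged; applying the same mirror twice is the
#' identity.
#'
#' @param config a [landmark_config()] or p x 3 matrix.
#' @param axis which axis to flip: `"x"`, `"y"` or `"z"`.
#' @return the mirrored configuration (same class as the input).
#' @export
mirror <- function(config, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  j <- match(axis, c("x", "y", "z"))
  if (inherits(config, "landmark_config")) {
    pts <- config$points
    pts[, j] <- -pts[, j]
    landmark_config(pts, config$specimen_id, config$labels)
  } else {
    pts <- as.matrix(config)
    pts[, j] <- -pts[, j]
    pts
  }
}

# total Procrustes sum of squares around the coordinate-wise mean
.gpa_objective <- function(A) {
  cons <- apply(A, c(1L, 2L), mean)
  sum(sweep(A, c(1L, 2L), cons)^2)
}

# alternating minimisation: rotate every specimen to the current reference,
# then update the reference to the coordinate-wise mean. A must already be
# centered/unit-size. The recorded objective starts after the first rotation
# pass (the reference is initialised to the first specimen, so the
# pre-rotation dispersion is not comparable); from there each pass is a
# joint minimisation step and the trace is non-increasing.
.gpa_iterate <- function(A, tol, max_iter) {
  n <- dim(A)[3L]
  consensus <- A[, , 1L]
  trace <- numeric(0L)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      R <- optimal_rotation(A[, , i], consensus)
      A[, , i] <- A[, , i] %*% R
    }
    consensus <- apply(A, c(1L, 2L), mean)
    obj <- sum(sweep(A, c(1L, 2L), consensus)^2)
    trace <- c(trace, obj)
    if (iter > 1L && abs(trace[iter - 1L] - obj) < tol) { converged <- TRUE; break }
    # unit-size reference for the next rotation pass (scaling a reference
    # does not change the optimal rotations; kept for a well-defined scale)
    consensus <- consensus / centroid_size(consensus)
  }
  list(A = A, consensus = apply(A, c(1L, 2L), mean), trace = trace,
       iterations = iter, converged = converged)
}

#' Generalised Procrustes Analysis
#'
#' Removes position, scale and orientation from a sample of landmark
#' configurations: each specimen is centered and scaled to unit centroid
#' size, then iteratively rotated to the running consensus until the total
#' Procrustes sum of squares stabilises. Rotations are proper (no
#' reflection); set `mirror_side` to standardise specimens from the other
#' body side first.
#'
#' @param sample a [landmark_sample()], or a p x 3 x n array.
#' @param tol convergence tolerance on the absolute change in total
#'   Procrustes sum of squares (default 1e-9).
#' @param max_iter maximum iterations (default 100); non-convergence
#'   returns the best result with a warning and `converged = FALSE`.
#' @param mirror_side optional: name of the side to mirror before
#'   superimposition (requires `sample$metadata$side`); e.g.
#'   `mirror_side = "right"` reflects right-side specimens across the x
#'   plane so all specimens share handedness. `NULL` mirrors nothing.
#' @return An object of class `procrustes_result`: list with `aligned`
#'   (p x 3 x n), `consensus` (p x 3 mean shape, centered), `centroid_sizes`
#'   (original sizes), `n_iterations`, `objective_trace` (non-increasing),
#'   `converged`, `slid = FALSE`, plus the sample's `scheme`, `groups`,
#'   `metadata`.
#' @export
gpa <- function(sample, tol = 1e-9, max_iter = 100L, mirror_side = NULL) {
  if (inherits(sample, "landmark_sample")) {
    A <- sample$coords
    scheme <- sample$scheme; groups <- sample$groups; metadata <- sample$metadata
  } else {
    A <- sample
    scheme <- NULL; groups <- NULL; metadata <- NULL
  }
  stopifnot(length(dim(A)) == 3L, dim(A)[2L] == 3L)
  n <- dim(A)[3L]
  if (n < 2L) stop("GPA needs at least 2 configurations", call. = FALSE)
  if (!is.null(mirror_side)) {
    if (is.null(metadata) || !"side" %in% names(metadata))
      stop("mirror_side requires metadata with a `side` column", call. = FALSE)
    flip <- which(metadata$side == mirror_side)
    for (i in flip) A[, 1L, i] <- -A[, 1L, i]
  }
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    cs <- .centered_scaled(A[, , i])
    A[, , i] <- cs$points
    sizes[i] <- cs$centroid_size
  }
  fit <- .gpa_iterate(A, tol, max_iter)
  if (!fit$converged)
    warning("GPA did not converge in ", max_iter, " iterations", call. = FALSE)
  structure(list(aligned = fit$A, consensus = fit$consensus,
                 centroid_sizes = sizes, n_iterations = fit$iterations,
                 objective_trace = fit$trace, converged = fit$converged,
                 slid = FALSE, scheme = scheme, groups = groups,
                 metadata = metadata),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat("<procrustes_result>", dim(x$aligned)[3L], "specimens x",
      dim(x$aligned)[1L], "landmarks;",
      x$n_iterations, "iterations; final SS",
      signif(x$objective_trace[length(x$objective_trace)], 6),
      if (x$slid) "(semilandmarks slid)" else "", "\n")
  invisible(x)
}

# slide the non-anchor points of one specimen toward the consensus:
# orthogonal projection of the deviation onto the local curve tangent
# (central difference of the specimen's neighbouring curve points), with the
# step clamped to `clamp` times the distance to the nearest curve neighbour
.slide_specimen <- function(X, consensus, scheme, clamp = 0.45) {
  warned <- FALSE
  for (ix in scheme$curves) {
    if (length(ix) < 3L) next
    for (j in 2:(length(ix) - 1L)) {
      id <- ix[j]; prev <- ix[j - 1L]; nxt <- ix[j + 1L]
      tng <- X[nxt, ] - X[prev, ]
      tl <- sqrt(sum(tng^2))
      if (tl < 1e-12) {
        if (!warned) {
          warning("coincident curve neighbours; point(s) skipped during sliding",
                  call. = FALSE)
          warned <- TRUE
        }
        next
      }
      tng <- tng / tl
      step <- sum((consensus[id, ] - X[id, ]) * tng)
      max_step <- clamp * min(sqrt(sum((X[nxt, ] - X[id, ])^2)),
                              sqrt(sum((X[id, ] - X[prev, ])^2)))
      if (abs(step) > max_step) step <- sign(step) * max_step
      X[id, ] <- X[id, ] + step * tng
    }
  }
  X
}

#' Slide semilandmarks by the Procrustes-distance criterion
#'
#' Starting from a converged GPA, each sliding semilandmark of each
#' specimen is moved along its local curve tangent (central difference of
#' its within-curve neighbours) by the tangential component of its deviation
#' from the consensus — the update that minimises the Procrustes distance.
#' Steps are clamped to 0.45 times the distance to the nearest curve
#' neighbour so points cannot cross. After each sliding pass the sample is
#' re-superimposed by GPA; passes repeat until the total Procrustes sum of
#' squares stabilises. The objective never increases across outer
#' iterations (an increasing pass is reverted and iteration stops).
#'
#' @param result a `procrustes_result` from [gpa()].
#' @param scheme a [curve_scheme()]; defaults to the scheme carried by the
#'   result.
#' @param outer_iter maximum sliding passes (default 5).
#' @param tol stop when the change in total Procrustes SS drops below this
#'   (default 1e-8).
#' @return a `procrustes_result` with `slid = TRUE` and the objective trace
#'   extended by one entry per sliding pass.
#' @export
slide_semilandmarks <- function(result, scheme = NULL, outer_iter = 5L,
                                tol = 1e-8) {
  stopifnot(inherits(result, "procrustes_result"))
  scheme <- scheme %||% result$scheme
  if (is.null(scheme)) stop("no curve scheme available for sliding", call. = FALSE)
  .check_scheme(scheme)
  if (scheme$p != dim(result$aligned)[1L])
    stop("scheme landmark count does not match the aligned sample", call. = FALSE)
  A <- result$aligned
  n <- dim(A)[3L]
  trace <- result$objective_trace
  obj <- trace[length(trace)]
  for (it in seq_len(outer_iter)) {
    A_new <- A
    consensus <- apply(A, c(1L, 2L), mean)
    for (i in seq_len(n)) A_new[, , i] <- .slide_specimen(A_new[, , i], consensus, scheme)
    # re-normalise and re-superimpose after moving points
    for (i in seq_len(n)) A_new[, , i] <- .centered_scaled(A_new[, , i])$points
    fit <- .gpa_iterate(A_new, tol = 1e-9, max_iter = 100L)
    new_obj <- fit$trace[length(fit$trace)]
    if (new_obj > obj + 1e-12) break   # revert: objective must not increase
    A <- fit$A
    trace <- c(trace, new_obj)
    if (obj - new_obj < tol) { obj <- new_obj; break }
    obj <- new_obj
  }
  result$aligned <- A
  result$consensus <- apply(A, c(1L, 2L), mean)
  result$objective_trace <- trace
  result$slid <- TRUE
  result
}
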