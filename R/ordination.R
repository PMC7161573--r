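# Principal component analyses: tangent-space PCA of Procrustes-aligned
# coordinates (covariance, unstandardized) and PCA of linear measurements
# (correlation, standardized).

.pca_result <- function(X, standardized, ids = rownames(X)) {
  n <- nrow(X); d <- ncol(X)
  if (n < 3L) stop("PCA needs at least 3 specimens", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = standardized)
  m <- min(n - 1L, d)
  ev <- pc$sdev^2
  ev <- ev[seq_len(m)]
  axes <- pc$rotation[, seq_len(m), drop = FALSE]
  scores <- pc$x[, seq_len(m), drop = FALSE]
  # sign convention: the largest-magnitude loading on each axis is positive
  for (j in seq_len(m)) {
    k <- which.max(abs(axes[, j]))
    if (axes[k, j] < 0) {
      axes[, j] <- -axes[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- ids
  colnames(scores) <- colnames(axes) <- sprintf("PC%d", seq_len(m))
  structure(list(scores = scores, axes = axes, eigenvalues = ev,
                 proportions = ev / sum(ev), center = pc$center,
                 scale = if (standardized) pc$scale else NULL,
                 standardized = standardized),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  m <- min(5L, length(x$eigenvalues))
  cat("<pca_result>", nrow(x$scores), "specimens,",
      length(x$eigenvalues), "axes;",
      if (x$standardized) "standardized (correlation)" else "covariance", "PCA\n")
  cat("  leading proportions:",
      paste(sprintf("%.4f", x$proportions[seq_len(m)]), collapse = " "), "\n")
  invisible(x)
}

#' Tangent-space PCA of Procrustes-aligned coordinates
#'
#' Flattens the aligned coordinates to an n x 3p matrix, centers the
#' columns and eigen-decomposes their covariance (no column scaling),
#' treating shapes as points in the linearised shape space. Axis signs
#' follow the convention that each axis's largest-magnitude loading is
#' positive; eigenvalues use the sample (n - 1) denominator.
#'
#' @param result a `procrustes_result` from [gpa()] /
#'   [slide_semilandmarks()], or an n x d matrix of shape variables.
#' @return a `pca_result`: `scores` (n x m), `axes` (d x m orthonormal),
#'   `eigenvalues` (descending), `proportions` (sum to 1), `center`,
#'   `standardized = FALSE`; m = min(n - 1, d).
#' @export
tangent_pca <- function(result) {
  if (inherits(result, "procrustes_result")) {
    X <- flatten_coords(result$aligned)
    rownames(X) <- dimnames(result$aligned)[[3L]]
  } else X <- as.matrix(result)
  .pca_result(X, standardized = FALSE)
}

#' PCA of scaled and centred linear measurements
#'
#' Columns are centred and scaled to unit variance before the
#' eigen-decomposition (correlation-matrix PCA), so measurements on
#' different scales contribute equally.
#'
#' @param table a [measurement_table()] (the 12 measurement columns are
#'   used) or a numeric matrix/data.frame.
#' @return a `pca_result` with `standardized = TRUE`.
#' @export
measurement_pca <- function(table) {
  if (inherits(table, "measurement_table")) {
    X <- as.matrix(as.data.frame(table)[, measurement_columns()])
    rownames(X) <- table$specimen_id
  } else X <- as.matrix(table)
  if (any(!is.finite(X))) stop("missing or non-finite measurement values", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(X) %||% as.character(seq_len(ncol(X)))
    stop("zero-variance column(s): ", paste(nm[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  .pca_result(X, standardized = TRUE)
}

#' Number of leading axes reaching a cumulative variance threshold
#'
#' @param pca a `pca_result`.
#' @param threshold cumulative variance proportion in (0, 1]; default 0.95.
#' @return smallest m whose leading-m cumulative proportion meets the
#'   threshold (ties at exact equality take the smaller count).
#' @examples
#' # eigenvalues 3 and 1: one axis already explains 75%
#' @export
axes_for_threshold <- function(pca, threshold = 0.95) {
  stopifnot(inherits(pca, "pca_result"), threshold > 0, threshold <= 1)
  cum <- cumsum(pca$proportions)
  which(cum >= threshold - 1e-12)[1L]
}
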