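# Dispersion statistics: coefficient of variation and disparity metrics.

#' Coefficient of variation
#'
#' `CV = 100 * sd / mean` (sample standard deviation, n - 1 denominator),
#' the scale-free percentage dispersion of a positive-valued measurement.
#'
#' @param values numeric vector, length >= 2, positive mean.
#' @param measurement optional name recorded in the summary.
#' @return list of class `cv_summary`: `measurement`, `cv_pct`, `n`,
#'   `mean`, `sd`.
#' @examples
#' coefficient_of_variation(c(8, 10, 12))$cv_pct  # 20
#' @export
coefficient_of_variation <- function(values, measurement = NA_character_) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("CV needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0)
    stop("CV is undefined for non-positive mean (mean = ", signif(m, 4), ")",
         call. = FALSE)
  s <- stats::sd(values)
  structure(list(measurement = measurement, cv_pct = 100 * s / m,
                 n = length(values), mean = m, sd = s),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat("<cv_summary>", if (!is.na(x$measurement)) x$measurement else "",
      sprintf("CV = %.3f%% (n = %d, mean = %.4g, sd = %.4g)\n",
              x$cv_pct, x$n, x$mean, x$sd))
  invisible(x)
}

#' Average replicates within individuals, then compute CV across individuals
#'
#' For datasets with repeated measurements per individual (e.g. left and
#' right cochleae), replicate values are averaged within each individual
#' first; the CV is then computed across the individual means.
#'
#' @param values numeric vector of measurements.
#' @param individual vector of individual ids, same length as `values`.
#' @param measurement optional name recorded in the summary.
#' @return a `cv_summary` across individual means.
#' @export
mean_by_individual_then_cv <- function(values, individual,
                                       measurement = NA_character_) {
  stopifnot(length(values) == length(individual))
  means <- tapply(as.numeric(values), as.character(individual), mean,
                  na.rm = TRUE)
  if (length(means) < 2L)
    stop("need at least 2 individuals to compute a CV", call. = FALSE)
  coefficient_of_variation(as.numeric(means), measurement)
}

#' Morphological disparity of a set of points in morphospace
#'
#' Two metrics of group dispersion computed on a rows-as-specimens matrix
#' (typically PC scores): `sum_of_variances` is the sum over columns of the
#' sample (n - 1) variance — the trace of the covariance matrix, invariant
#' to orthonormal rotation of the space, so disparity on a full PC-score
#' matrix equals disparity on the centered original variables.
#' `median_centroid_distance` is the median Euclidean distance of the rows
#' to their column-mean centroid.
#'
#' @param points numeric n x m matrix (n >= 2).
#' @param metric `"sum_of_variances"` or `"median_centroid_distance"`.
#' @param group optional group label recorded in the summary.
#' @param n_boot number of bootstrap replicates for a percentile CI
#'   (0 = none, the default: point values are reported).
#' @param conf confidence level of the bootstrap interval.
#' @param seed optional seed for the bootstrap resampling.
#' @return list of class `disparity_summary`: `metric`, `value`, `group`,
#'   `n`, and `bootstrap_ci` (NULL or `c(lower, upper)`).
#' @export
disparity <- function(points,
                      metric = c("sum_of_variances", "median_centroid_distance"),
                      group = NA_character_, n_boot = 0L, conf = 0.95,
                      seed = NULL) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("disparity needs at least 2 rows", call. = FALSE)
  eval_metric <- function(M) {
    if (metric == "sum_of_variances") {
      sum(apply(M, 2L, stats::var))
    } else {
      ctr <- colMeans(M)
      stats::median(sqrt(rowSums(sweep(M, 2L, ctr)^2)))
    }
  }
  value <- eval_metric(points)
  ci <- NULL
  if (n_boot > 0L) {
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      eval_metric(points[sample.int(nrow(points), replace = TRUE), , drop = FALSE])
    }, 0))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha)))
  }
  structure(list(metric = metric, value = value, group = group,
                 n = nrow(points), bootstrap_ci = ci),
            class = "disparity_summary")
}

#' @export
print.disparity_summary <- function(x, ...) {
  cat("<disparity_summary>", x$metric, "=", signif(x$value, 6),
      sprintf("(n = %d%s)\n", x$n,
              if (!is.na(x$group)) paste0(", group = ", x$group) else ""))
  if (!is.null(x$bootstrap_ci))
    cat("  bootstrap CI:", signif(x$bootstrap_ci[1L], 6), "-",
        signif(x$bootstrap_ci[2L], 6), "\n")
  invisible(x)
}

#' CVs for every measurement column of a table
#'
#' @param table a [measurement_table()].
#' @return data.frame with one row per measurement: `measurement`,
#'   `cv_pct`, `n`, `mean`, `sd`.
#' @export
measurement_cv_table <- function(table) {
  stopifnot(inherits(table, "measurement_table"))
  do.call(rbind, lapply(measurement_columns(), function(col) {
    s <- coefficient_of_variation(table[[col]], col)
    data.frame(measurement = col, cv_pct = s$cv_pct, n = s$n,
               mean = s$mean, sd = s$sd)
  }))
}
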