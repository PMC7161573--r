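# Permutation Procrustes ANOVA on aligned coordinates, Pillai-trace MANOVA
# on PC scores, per-axis ANOVAs and Bonferroni correction.

.group_test <- function(test, predictor = NA_character_, df_effect, df_resid,
                        ss_effect = NA_real_, ss_resid = NA_real_,
                        statistic, pillai = NA_real_, p, p_adjusted = NA_real_,
                        n_perm = NA_integer_, seed = NA_integer_,
                        exact = NA) {
  structure(list(test = test, predictor = predictor,
                 df_effect = df_effect, df_resid = df_resid,
                 ss_effect = ss_effect, ss_resid = ss_resid,
                 statistic = statistic, pillai = pillai, p = p,
                 p_adjusted = p_adjusted, n_perm = n_perm, seed = seed,
                 exact = exact),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: df = %s,%s, %s = %.4g%s, p = %.4g%s\n",
              x$test, format(x$df_effect), format(x$df_resid),
              if (x$test == "manova_pillai") "approx F" else "F",
              x$statistic,
              if (!is.na(x$pillai)) sprintf(", Pillai = %.4g", x$pillai) else "",
              x$p,
              if (!is.na(x$n_perm)) sprintf(" (%d permutations)", x$n_perm) else ""))
  invisible(x)
}

#' Bonferroni correction
#'
#' Multiplies a p-value by the number of tests in the family, capped at 1.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param m family size (number of tests), >= 1.
#' @return adjusted p-value(s), `min(1, m * p)`.
#' @examples
#' bonferroni(0.038, 4)  # 0.152
#' @export
bonferroni <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

# coerce response input to an n x d matrix of shape/score variables
.response_matrix <- function(data) {
  if (inherits(data, "procrustes_result")) {
    X <- flatten_coords(data$aligned)
    rownames(X) <- dimnames(data$aligned)[[3L]]
    X
  } else if (length(dim(data)) == 3L) {
    flatten_coords(data)
  } else as.matrix(data)
}

# between-group and total sums of squares for grand-centered rows;
# SSB = sum_g ||group sum||^2 / n_g when rows are centered
.ss_between <- function(Xc, labels) {
  sums <- rowsum(Xc, labels)
  counts <- as.vector(table(labels)[rownames(sums)])
  sum(rowSums(sums^2) / counts)
}

.f_from_ssb <- function(ssb, sst, g, n) {
  ssw <- sst - ssb
  ((ssb / (g - 1)) / (ssw / (n - g)))
}

# all distinct arrangements of a label multiset (as a list of vectors);
# only called when their number is known to be small
.multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  rec <- function(remaining) {
    if (!length(remaining)) return(list(character(0L)))
    out <- list()
    for (u in unique(remaining)) {
      rest <- remaining[-match(u, remaining)]
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(u, tail)
    }
    out
  }
  rec(sort(labels))
}

.n_distinct_arrangements <- function(labels) {
  tab <- table(labels)
  exp(lfactorial(sum(tab)) - sum(lfactorial(tab)))
}

#' Permutation Procrustes ANOVA
#'
#' Distance-based one-way analysis of variance on superimposed landmark
#' coordinates (or any multivariate response): total, within- and
#' between-group sums of squared Euclidean deviations give a pseudo-F
#' statistic whose significance comes from permuting group labels across
#' rows.
#'
#' With the default estimator, `p = (1 + #\{F* >= F\}) / (1 + n_perm)`, so
#' the smallest attainable p is `1 / (n_perm + 1)` (0.001 at the default
#' 999 permutations). With `exact = TRUE` every distinct label arrangement
#' is enumerated and `p = #\{F* >= F\} / N` (the observed arrangement is one
#' of the N); this requires the arrangement count to be modest.
#'
#' @param aligned a `procrustes_result`, a p x 3 x n array, or an n x d
#'   response matrix.
#' @param factor group labels, length n, at least 2 groups.
#' @param n_perm number of random permutations (default 999).
#' @param seed optional seed for the permutations.
#' @param exact enumerate all distinct label arrangements instead of
#'   sampling (errors above `max_exact` arrangements).
#' @param max_exact safety cap on the enumeration size (default 100000).
#' @return a `group_test` with distance-based `ss_effect` / `ss_resid`,
#'   `statistic` (pseudo-F), df `(g - 1, n - g)` and the permutation p.
#' @export
procrustes_anova <- function(aligned, factor, n_perm = 999L, seed = NULL,
                             exact = FALSE, max_exact = 1e5) {
  X <- .response_matrix(aligned)
  labels <- droplevels(base::factor(factor))
  n <- nrow(X)
  if (length(labels) != n) stop("`factor` must have one label per specimen", call. = FALSE)
  g <- nlevels(labels)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  if (n < 3L) stop("need at least 3 specimens", call. = FALSE)
  if (any(table(labels) == n)) stop("a group contains all specimens", call. = FALSE)
  if (!exact && n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  sst <- sum(Xc^2)
  ssb_obs <- .ss_between(Xc, labels)
  f_obs <- .f_from_ssb(ssb_obs, sst, g, n)
  tol <- if (is.finite(f_obs)) 1e-12 * max(1, abs(f_obs)) else 0
  if (exact) {
    n_arr <- .n_distinct_arrangements(labels)
    if (n_arr > max_exact)
      stop("exact enumeration over ", format(n_arr),
           " arrangements exceeds max_exact", call. = FALSE)
    arrangements <- .multiset_permutations(labels)
    f_all <- vapply(arrangements, function(lab)
      .f_from_ssb(.ss_between(Xc, lab), sst, g, n), 0)
    p <- sum(f_all >= f_obs - tol) / length(f_all)
    n_perm_out <- length(f_all)
  } else {
    f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b)
      .f_from_ssb(.ss_between(Xc, labels[sample.int(n)]), sst, g, n), 0))
    p <- (1 + sum(f_perm >= f_obs - tol)) / (1 + n_perm)
    n_perm_out <- as.integer(n_perm)
  }
  .group_test("procrustes_anova", df_effect = g - 1L, df_resid = n - g,
              ss_effect = ssb_obs, ss_resid = sst - ssb_obs,
              statistic = f_obs, p = p, n_perm = n_perm_out,
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
              exact = exact)
}

# Pillai trace and its F approximation for a single-term model.
# Y: n x q response; x: factor (df_h = g - 1) or numeric vector (df_h = 1).
.pillai_fit <- function(Y, x) {
  Y <- as.matrix(Y)
  n <- nrow(Y); q <- ncol(Y)
  Yc <- sweep(Y, 2L, colMeans(Y))
  if (is.factor(x) || is.character(x)) {
    x <- droplevels(base::factor(x))
    g <- nlevels(x)
    if (g < 2L) stop("need at least 2 groups", call. = FALSE)
    df_h <- g - 1L
    sums <- rowsum(Yc, x)
    means <- sums / as.vector(table(x)[rownames(sums)])
    fitted <- means[match(as.character(x), rownames(means)), , drop = FALSE]
    H <- crossprod(fitted)
    E <- crossprod(Yc - fitted)
  } else {
    x <- as.numeric(x)
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx == 0) stop("constant predictor", call. = FALSE)
    df_h <- 1L
    b <- crossprod(Yc, xc) / sxx          # q x 1 slope
    H <- tcrossprod(b) * sxx
    E <- crossprod(Yc) - H
  }
  df_e <- n - df_h - 1L
  if (df_e <= q)
    stop("insufficient residual degrees of freedom (n - g must exceed the ",
         "number of response axes); reduce the number of axes", call. = FALSE)
  Einv_H <- tryCatch(solve(E, H), error = function(e)
    stop("within-group cross-product matrix is singular; ",
         "reduce the number of response axes", call. = FALSE))
  lambda <- Re(eigen(Einv_H, only.values = TRUE)$values)
  lambda <- pmax(lambda, 0)
  V <- sum(lambda / (1 + lambda))
  s <- min(q, df_h)
  m <- (abs(q - df_h) - 1) / 2
  r <- (df_e - q - 1) / 2
  approx_f <- ((2 * r + s + 1) / (2 * m + s + 1)) * (V / s) / (1 - V / s)
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * r + s + 1)
  list(pillai = V, approx_f = approx_f, df1 = df1, df2 = df2, df_h = df_h,
       df_e = df_e, p = stats::pf(approx_f, df1, df2, lower.tail = FALSE))
}

#' Pillai-trace MANOVA
#'
#' One-way multivariate analysis of variance using Pillai's trace
#' `V = sum(lambda / (1 + lambda))` over the eigenvalues of `E^-1 H`
#' (H = between-group, E = within-group cross-product matrices), with the
#' standard F approximation. Requires residual degrees of freedom to exceed
#' the number of response columns (`n - g > q`); reduce the number of axes
#' (e.g. via [axes_for_threshold()]) when violated.
#'
#' At `q = 1` this reduces algebraically to the one-way ANOVA F test.
#'
#' @param scores n x q matrix of response variables (e.g. PC scores).
#' @param factor group labels, length n.
#' @return a `group_test` with `pillai` (V), `statistic` (approximate F),
#'   df of the F approximation and the parametric p-value.
#' @export
manova_pillai <- function(scores, factor) {
  Y <- as.matrix(scores)
  labels <- droplevels(base::factor(factor))
  if (length(labels) != nrow(Y))
    stop("`factor` must have one label per row", call. = FALSE)
  fit <- .pillai_fit(Y, labels)
  .group_test("manova_pillai", df_effect = fit$df_h, df_resid = fit$df_e,
              statistic = fit$approx_f, pillai = fit$pillai, p = fit$p)
}

#' Per-axis ANOVAs with Bonferroni correction
#'
#' One-way ANOVA of each response column on the grouping factor; raw
#' p-values are Bonferroni-adjusted for the number of columns tested.
#'
#' @param scores n x q matrix (e.g. PC scores).
#' @param factor group labels.
#' @return data.frame with one row per axis: `axis`, `df_effect`,
#'   `df_resid`, `ss_effect`, `ss_resid`, `F`, `p_raw`, `p_adjusted`.
#' @export
per_axis_anova <- function(scores, factor) {
  Y <- as.matrix(scores)
  labels <- base::factor(factor)
  q <- ncol(Y)
  rows <- lapply(seq_len(q), function(j) {
    tab <- stats::anova(stats::lm(Y[, j] ~ labels))
    data.frame(axis = colnames(Y)[j] %||% sprintf("V%d", j),
               df_effect = tab$Df[1L], df_resid = tab$Df[2L],
               ss_effect = tab$`Sum Sq`[1L], ss_resid = tab$`Sum Sq`[2L],
               F = tab$`F value`[1L], p_raw = tab$`Pr(>F)`[1L])
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_raw, q)
  out
}

#' Test shape or score variation against an arbitrary predictor
#'
#' Fits a single-predictor model of multivariate variation: categorical
#' predictors give a group test, continuous predictors a single-df
#' regression. With aligned coordinates (`procrustes_result` or p x 3 x n
#' array) the test is distance-based with a permutation p-value; with a
#' score matrix it is a Pillai-trace MANOVA (parametric p). Rows with
#' missing predictor values are dropped with a message.
#'
#' @param data a `procrustes_result`, p x 3 x n array, or n x q score
#'   matrix.
#' @param predictor categorical (factor/character) or numeric vector,
#'   length n.
#' @param n_predictors family size for the Bonferroni-adjusted p (e.g. 4
#'   when side, sex, origin and log skull length are each tested); default
#'   1 (no adjustment).
#' @param n_perm,seed permutation settings for the distance-based variant.
#' @param predictor_name label recorded in the result.
#' @return a `group_test` with `p` (raw) and `p_adjusted`.
#' @export
covariate_test <- function(data, predictor, n_predictors = 1L,
                           n_perm = 999L, seed = NULL,
                           predictor_name = deparse(substitute(predictor))) {
  procrustes_variant <- inherits(data, "procrustes_result") ||
    length(dim(data)) == 3L
  X <- .response_matrix(data)
  if (length(predictor) != nrow(X))
    stop("`predictor` must have one value per specimen", call. = FALSE)
  keep <- !is.na(predictor)
  if (is.character(predictor)) keep <- keep & predictor != "unknown"
  if (any(!keep))
    message(sum(!keep), " specimen(s) dropped for missing predictor values")
  X <- X[keep, , drop = FALSE]
  predictor <- predictor[keep]
  n <- nrow(X)
  if (n < 3L) stop("fewer than 3 usable specimens", call. = FALSE)
  categorical <- is.factor(predictor) || is.character(predictor) ||
    is.logical(predictor)
  if (categorical && nlevels(base::factor(predictor)) < 2L)
    stop("constant predictor", call. = FALSE)
  if (!categorical && stats::var(as.numeric(predictor)) == 0)
    stop("constant predictor", call. = FALSE)

  if (procrustes_variant) {
    if (categorical) {
      res <- procrustes_anova(X, predictor, n_perm = n_perm, seed = seed)
    } else {
      res <- .procrustes_regression(X, as.numeric(predictor),
                                    n_perm = n_perm, seed = seed)
    }
  } else {
    if (categorical) {
      res <- manova_pillai(X, predictor)
    } else {
      fit <- .pillai_fit(X, as.numeric(predictor))
      res <- .group_test("manova_pillai", df_effect = fit$df_h,
                         df_resid = fit$df_e, statistic = fit$approx_f,
                         pillai = fit$pillai, p = fit$p)
    }
  }
  res$predictor <- predictor_name
  res$p_adjusted <- bonferroni(res$p, n_predictors)
  res
}

# distance-based single-df regression with permutation p (predictor values
# permuted across rows)
.procrustes_regression <- function(X, x, n_perm = 999L, seed = NULL) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  sst <- sum(Xc^2)
  f_stat <- function(xv) {
    xc <- xv - mean(xv)
    ss_reg <- sum((crossprod(Xc, xc))^2) / sum(xc^2)
    (ss_reg / 1) / ((sst - ss_reg) / (n - 2))
  }
  f_obs <- f_stat(x)
  tol <- if (is.finite(f_obs)) 1e-12 * max(1, abs(f_obs)) else 0
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b)
    f_stat(x[sample.int(n)]), 0))
  p <- (1 + sum(f_perm >= f_obs - tol)) / (1 + n_perm)
  xc <- x - mean(x)
  ss_reg <- sum((crossprod(Xc, xc))^2) / sum(xc^2)
  .group_test("procrustes_anova", df_effect = 1L, df_resid = n - 2L,
              ss_effect = ss_reg, ss_resid = sst - ss_reg,
              statistic = f_obs, p = p, n_perm = as.integer(n_perm),
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
              exact = FALSE)
}
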