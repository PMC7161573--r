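# Exhaustive specimen-subset re-analysis and restricted-taxon comparisons.

# lexicographic unranking of the `rank`-th k-combination of 1..n
.unrank_combination <- function(rank, n, k) {
  out <- integer(k)
  r <- rank - 1
  x <- 1L
  for (i in seq_len(k)) {
    repeat {
      c_rest <- choose(n - x, k - i)
      if (r < c_rest) break
      r <- r - c_rest
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

#' Run the standard shape-analysis recipe on a sample
#'
#' GPA, optional semilandmark sliding, tangent-space PCA, selection of the
#' leading axes reaching a cumulative-variance threshold (capped so that
#' residual degrees of freedom exceed the axis count), then a Pillai-trace
#' MANOVA of the retained scores on the group factor and (optionally) a
#' permutation Procrustes ANOVA on the aligned coordinates.
#'
#' @param sample a [landmark_sample()] with group labels.
#' @param variance_threshold cumulative-variance rule for axis selection
#'   (default 0.95).
#' @param slide slide semilandmarks after GPA (default: yes, when the
#'   sample carries a curve scheme).
#' @param mirror_side passed to [gpa()].
#' @param n_perm permutations for the Procrustes ANOVA; `NULL` skips that
#'   test.
#' @param seed seed for the permutation test.
#' @return list with `fit` (`procrustes_result`), `pca`, `n_axes`,
#'   `manova` (`group_test` or NULL if infeasible), and `procrustes_anova`
#'   (when requested).
#' @export
shape_recipe <- function(sample, variance_threshold = 0.95,
                         slide = !is.null(sample$scheme),
                         mirror_side = NULL, n_perm = NULL, seed = NULL) {
  stopifnot(inherits(sample, "landmark_sample"))
  if (is.null(sample$groups)) stop("sample has no group labels", call. = FALSE)
  fit <- gpa(sample, mirror_side = mirror_side)
  if (slide) fit <- slide_semilandmarks(fit)
  pca <- tangent_pca(fit)
  n <- nrow(pca$scores)
  g <- nlevels(droplevels(sample$groups))
  n_axes <- axes_for_threshold(pca, variance_threshold)
  q_max <- n - g - 1L   # manova needs n - g > q
  manova_res <- NULL
  if (q_max >= 1L) {
    q <- min(n_axes, q_max)
    manova_res <- manova_pillai(pca$scores[, seq_len(q), drop = FALSE],
                                sample$groups)
  }
  out <- list(fit = fit, pca = pca, n_axes = n_axes,
              n_axes_used = if (q_max >= 1L) min(n_axes, q_max) else NA_integer_,
              manova = manova_res)
  if (!is.null(n_perm))
    out$procrustes_anova <- procrustes_anova(fit, sample$groups,
                                             n_perm = n_perm, seed = seed)
  out
}

#' Exhaustive specimen-subset sensitivity analysis
#'
#' For each subset size k, retains every possible combination of k focal
#' specimens (all non-focal specimens are always kept) and re-runs the full
#' recipe — GPA, sliding, tangent PCA, axis selection, MANOVA — from the raw
#' coordinates, collecting the MANOVA p-value per combination. When
#' `choose(n_focal, k)` exceeds `max_combos`, that many distinct subsets are
#' drawn uniformly instead (seeded).
#'
#' @param sample a [landmark_sample()] with groups.
#' @param focal_group label of the focal group to subsample.
#' @param k_range integer vector of subset sizes, each in
#'   `2 <= k < n_focal`.
#' @param max_combos cap on combinations evaluated per k (default 20000).
#' @param seed seed for the Monte-Carlo subset draws.
#' @param variance_threshold,slide passed to [shape_recipe()].
#' @return list of class `sensitivity_result`; one element per k with
#'   fields `k`, `n_combinations_evaluated`, `exhaustive`, `subsets`
#'   (k x n_combinations matrix of focal indices), `p_values`, `median_p`,
#'   `seed`. Use [as.data.frame()] for a long-format table.
#' @export
subset_analysis <- function(sample, focal_group, k_range,
                            max_combos = 20000L, seed = NULL,
                            variance_threshold = 0.95,
                            slide = !is.null(sample$scheme)) {
  stopifnot(inherits(sample, "landmark_sample"), !is.null(sample$groups))
  focal_idx <- which(sample$groups == focal_group)
  other_idx <- which(sample$groups != focal_group)
  n_focal <- length(focal_idx)
  if (!n_focal) stop("no specimens in focal group '", focal_group, "'",
                     call. = FALSE)
  k_range <- as.integer(k_range)
  if (any(k_range < 2L | k_range >= n_focal))
    stop("subset sizes must satisfy 2 <= k < n_focal (", n_focal, ")",
         call. = FALSE)
  results <- lapply(k_range, function(k) {
    n_comb <- choose(n_focal, k)
    if (n_comb <= max_combos) {
      subsets <- utils::combn(n_focal, k)
      exhaustive <- TRUE
    } else {
      ranks <- with_seed(seed, sample(n_comb, max_combos))
      subsets <- vapply(ranks, .unrank_combination, integer(k),
                        n = n_focal, k = k)
      exhaustive <- FALSE
    }
    p_values <- apply(subsets, 2L, function(sel) {
      sub <- sample[c(focal_idx[sel], other_idx)]
      tryCatch({
        rec <- shape_recipe(sub, variance_threshold = variance_threshold,
                            slide = slide)
        if (is.null(rec$manova)) NA_real_ else rec$manova$p
      }, error = function(e) {
        warning("subset of size ", k, " failed: ", conditionMessage(e),
                call. = FALSE)
        NA_real_
      })
    })
    structure(list(k = k, n_combinations_evaluated = ncol(subsets),
                   exhaustive = exhaustive, subsets = subsets,
                   p_values = p_values,
                   median_p = stats::median(p_values, na.rm = TRUE),
                   seed = seed),
              class = "sensitivity_k")
  })
  structure(results, class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result>\n")
  for (r in x)
    cat(sprintf("  k = %2d: %5d combinations%s, median p = %.4g\n",
                r$k, r$n_combinations_evaluated,
                if (r$exhaustive) " (exhaustive)" else "", r$median_p))
  invisible(x)
}

#' @export
as.data.frame.sensitivity_result <- function(x, ...) {
  do.call(rbind, lapply(x, function(r)
    data.frame(k = r$k,
               combination_index = seq_along(r$p_values),
               subset_ids = apply(r$subsets, 2L, paste, collapse = "+"),
               p = r$p_values)))
}

#' Compare the focal group against a restricted comparator set
#'
#' Re-runs superimposition and ordination on the focal group plus a chosen
#' comparator subset only (e.g. congeneric species), then tests the
#' focal-versus-comparator contrast with both the permutation Procrustes
#' ANOVA and the Pillai MANOVA on the axes reaching the variance threshold
#' (capped by the residual-df rule; if no axes are feasible the MANOVA is
#' skipped with a warning).
#'
#' @param sample a [landmark_sample()] with groups.
#' @param focal_group focal group label.
#' @param comparator_ids specimen ids of the comparators (non-focal,
#'   non-empty).
#' @param variance_threshold,slide passed to [shape_recipe()].
#' @param n_perm,seed permutation settings for the Procrustes ANOVA.
#' @return list with `procrustes_anova`, `manova` (possibly NULL),
#'   `n_axes_used` and the restricted `recipe` output.
#' @export
restricted_comparison <- function(sample, focal_group, comparator_ids,
                                  variance_threshold = 0.95,
                                  slide = !is.null(sample$scheme),
                                  n_perm = 999L, seed = NULL) {
  stopifnot(inherits(sample, "landmark_sample"), !is.null(sample$groups))
  ids <- dimnames(sample$coords)[[3L]]
  focal_ids <- ids[sample$groups == focal_group]
  if (!length(comparator_ids)) stop("empty comparator set", call. = FALSE)
  if (any(comparator_ids %in% focal_ids))
    stop("comparator set overlaps the focal group", call. = FALSE)
  miss <- setdiff(comparator_ids, ids)
  if (length(miss)) stop("unknown specimen id(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sub <- sample[c(focal_ids, comparator_ids)]
  rec <- shape_recipe(sub, variance_threshold = variance_threshold,
                      slide = slide, n_perm = n_perm, seed = seed)
  if (is.null(rec$manova))
    warning("too few specimens for a MANOVA on any axis; ",
            "returning the Procrustes ANOVA only", call. = FALSE)
  list(procrustes_anova = rec$procrustes_anova, manova = rec$manova,
       n_axes_used = rec$n_axes_used, recipe = rec)
}

#' Leave-one-out re-analysis
#'
#' Repeats the full analysis (GPA, sliding, PCA, axis selection, group
#' tests, focal disparity) with one specimen removed, reporting it
#' alongside the full-sample result for qualitative comparison.
#'
#' @param sample a [landmark_sample()] with groups.
#' @param focal_group focal group label (used for the disparity summary).
#' @param drop_id specimen id to remove.
#' @param variance_threshold,slide,n_perm,seed as in [shape_recipe()].
#' @return list with `full` and `dropped`, each containing `manova`,
#'   `procrustes_anova`, `n_axes_used` and `focal_disparity`
#'   (sum-of-variances over the focal rows of the full PC-score matrix).
#' @export
leave_one_out <- function(sample, focal_group, drop_id,
                          variance_threshold = 0.95,
                          slide = !is.null(sample$scheme),
                          n_perm = 999L, seed = NULL) {
  stopifnot(inherits(sample, "landmark_sample"), !is.null(sample$groups))
  ids <- dimnames(sample$coords)[[3L]]
  if (!drop_id %in% ids) stop("unknown specimen id: ", drop_id, call. = FALSE)
  run_one <- function(s) {
    rec <- shape_recipe(s, variance_threshold = variance_threshold,
                        slide = slide, n_perm = n_perm, seed = seed)
    focal_rows <- s$groups == focal_group
    disp <- disparity(rec$pca$scores[focal_rows, , drop = FALSE],
                      metric = "sum_of_variances", group = focal_group)
    list(manova = rec$manova, procrustes_anova = rec$procrustes_anova,
         n_axes_used = rec$n_axes_used, focal_disparity = disp)
  }
  list(full = run_one(sample),
       dropped = run_one(sample[setdiff(ids, drop_id)]))
}
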