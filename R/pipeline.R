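# End-to-end orchestration: run the whole study analysis from a config and
# emit the result set (CV table, test table, disparity, PC variance,
# sensitivity curves) as CSVs with a manifest.

#' Build an analysis configuration
#'
#' Collects every knob of the end-to-end analysis. Inputs may be given as
#' file paths (read via the landmark_io functions) or as in-memory objects
#' (a [landmark_sample()] and/or [measurement_table()]).
#'
#' @param landmarks a [landmark_sample()], or path to a long/wide landmark
#'   CSV.
#' @param scheme optional [curve_scheme()] or path to a scheme CSV/YAML.
#' @param measurements optional [measurement_table()] or CSV path.
#' @param metadata optional metadata data.frame or CSV path (required when
#'   `landmarks` is a path).
#' @param focal_group focal group label (default `"focal"`).
#' @param mirror_side side to mirror before GPA so all specimens share
#'   handedness; the default `"right"` reflects right-side specimens onto
#'   the left. Applied only when the metadata carries a `side` column;
#'   `NULL` disables mirroring.
#' @param slide slide semilandmarks (default TRUE when a scheme exists).
#' @param variance_threshold cumulative-variance axis-selection rule.
#' @param n_perm permutations for distance-based tests.
#' @param seed master seed recorded in every output.
#' @param sensitivity_k integer vector of subset sizes (`NULL` disables the
#'   subset analysis).
#' @param max_combos per-k cap on combinations.
#' @param covariates character vector of metadata columns to test as
#'   predictors of focal-group shape (Bonferroni family = its length).
#' @param out_dir output directory (`NULL` = no files written).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(landmarks, scheme = NULL, measurements = NULL,
                            metadata = NULL, focal_group = "focal",
                            mirror_side = "right", slide = NULL,
                            variance_threshold = 0.95, n_perm = 999L,
                            seed = 1L, sensitivity_k = NULL,
                            max_combos = 20000L,
                            covariates = c("side", "sex", "origin", "cbl_mm"),
                            out_dir = NULL) {
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  structure(list(landmarks = landmarks, scheme = scheme,
                 measurements = measurements, metadata = metadata,
                 focal_group = focal_group, mirror_side = mirror_side,
                 slide = slide, variance_threshold = variance_threshold,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 sensitivity_k = sensitivity_k,
                 max_combos = as.integer(max_combos),
                 covariates = covariates, out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Fields mirror the arguments of [analysis_config()]; path fields are kept
#' as paths and resolved by [run_study()].
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  spec <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(spec), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, spec)
}

.resolve_inputs <- function(config) {
  lm <- config$landmarks
  if (is.character(lm)) {
    configs <- read_landmarks_csv(lm)
    meta <- config$metadata
    if (is.character(meta)) meta <- read_metadata(meta)
    scheme <- config$scheme
    if (is.character(scheme))
      scheme <- read_curve_scheme(scheme, labels = configs[[1L]]$labels)
    lm <- landmark_sample(configs, scheme = scheme, metadata = meta)
  }
  meas <- config$measurements
  if (is.character(meas)) meas <- read_measurements(meas)
  list(sample = lm, measurements = meas)
}

#' Run the full study analysis
#'
#' Executes the end-to-end pipeline: superimposition (GPA + optional
#' sliding), tangent-space PCA, axis selection, group tests (permutation
#' Procrustes ANOVA, Pillai MANOVA, per-axis ANOVAs with Bonferroni
#' correction), focal-group disparity, and — when measurements are supplied
#' — the measurement PCA, CV table, measurement-space MANOVA and disparity.
#' Optional stages: covariate tests over metadata predictors and the
#' subset-sensitivity analysis. When `out_dir` is set, [report_tables()]
#' CSVs and a YAML manifest (seed, config hash) are written; on error any
#' partial outputs are removed.
#'
#' @param config an [analysis_config()].
#' @return list of class `study_bundle` with elements `shape`,
#'   `measurements` (or NULL), `covariates`, `sensitivity`, `config`,
#'   `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- config$out_dir
  written <- character(0L)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (length(written)) unlink(written)
      stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- run_stage("input", .resolve_inputs(config))
  sample <- inputs$sample
  if (is.null(sample$groups))
    stop("[stage: input] sample has no group labels", call. = FALSE)
  slide <- config$slide %||% !is.null(sample$scheme)
  focal <- config$focal_group
  mirror_side <- config$mirror_side
  if (!is.null(mirror_side) &&
      (is.null(sample$metadata) || !"side" %in% names(sample$metadata)))
    mirror_side <- NULL

  shape <- run_stage("superimposition/ordination", {
    rec <- shape_recipe(sample, variance_threshold = config$variance_threshold,
                        slide = slide, mirror_side = mirror_side,
                        n_perm = config$n_perm, seed = config$seed)
    q <- rec$n_axes_used
    focal_rows <- sample$groups == focal
    per_axis <- per_axis_anova(rec$pca$scores[, seq_len(q), drop = FALSE],
                               sample$groups)
    list(recipe = rec, pca = rec$pca, n_axes = rec$n_axes, n_axes_used = q,
         procrustes_anova = rec$procrustes_anova, manova = rec$manova,
         per_axis = per_axis,
         disparity = list(
           sum_of_variances = disparity(
             rec$pca$scores[focal_rows, , drop = FALSE],
             "sum_of_variances", group = focal),
           median_centroid_distance = disparity(
             rec$pca$scores[focal_rows, , drop = FALSE],
             "median_centroid_distance", group = focal)))
  })

  measurements <- NULL
  if (!is.null(inputs$measurements)) {
    measurements <- run_stage("measurements", {
      tab <- inputs$measurements
      pca <- measurement_pca(tab)
      ids <- dimnames(sample$coords)[[3L]]
      grp <- sample$groups[match(tab$specimen_id, ids)]
      n_axes <- axes_for_threshold(pca, config$variance_threshold)
      man <- NULL; per_axis <- NULL; disp <- NULL
      if (!anyNA(grp)) {
        q_max <- nrow(tab) - nlevels(droplevels(grp)) - 1L
        q <- min(n_axes, q_max)
        if (q >= 1L) {
          man <- manova_pillai(pca$scores[, seq_len(q), drop = FALSE], grp)
          per_axis <- per_axis_anova(pca$scores[, seq_len(q), drop = FALSE],
                                     grp)
        }
        focal_rows <- grp == focal
        if (sum(focal_rows) >= 2L)
          disp <- list(
            sum_of_variances = disparity(
              pca$scores[focal_rows, , drop = FALSE],
              "sum_of_variances", group = focal),
            median_centroid_distance = disparity(
              pca$scores[focal_rows, , drop = FALSE],
              "median_centroid_distance", group = focal))
      }
      list(table = tab, cv = measurement_cv_table(tab), pca = pca,
           n_axes = n_axes, manova = man, per_axis = per_axis,
           disparity = disp)
    })
  }

  # covariate tests run on the focal group alone: GPA/PCA are repeated for
  # the focal specimens only, then each metadata predictor is tested against
  # the retained PC scores; the Bonferroni family is the set of testable
  # predictors
  covariates <- NULL
  if (length(config$covariates) && !is.null(sample$metadata)) {
    covariates <- run_stage("covariates", {
      focal_sample <- sample[sample$groups == focal]
      if (dim(focal_sample$coords)[3L] < 4L) NULL else {
        fit <- gpa(focal_sample, mirror_side = mirror_side)
        if (slide) fit <- slide_semilandmarks(fit)
        pca <- tangent_pca(fit)
        n_f <- nrow(pca$scores)
        meta <- focal_sample$metadata
        usable <- function(col) {
          if (!col %in% names(meta)) return(FALSE)
          v <- meta[[col]]
          if (is.numeric(v)) v <- v[!is.na(v)] else v <- v[v != "unknown"]
          length(v) >= 3L && length(unique(v)) >= 2L
        }
        cols <- Filter(usable, config$covariates)
        res <- lapply(cols, function(col) {
          v <- meta[[col]]
          if (is.numeric(v)) {
            pred <- log(v)
            keep <- !is.na(pred)
          } else {
            pred <- v
            keep <- v != "unknown"
          }
          q_max <- sum(keep) -
            (if (is.numeric(v)) 1L else length(unique(pred[keep]))) - 1L
          if (q_max < 1L) return(NULL)
          q <- min(axes_for_threshold(pca, config$variance_threshold), q_max)
          covariate_test(pca$scores[, seq_len(q), drop = FALSE], pred,
                         n_predictors = length(cols), predictor_name = col)
        })
        names(res) <- cols
        Filter(Negate(is.null), res)
      }
    })
  }

  sensitivity <- NULL
  if (!is.null(config$sensitivity_k)) {
    sensitivity <- run_stage("sensitivity", {
      subset_analysis(sample, focal, config$sensitivity_k,
                      max_combos = config$max_combos, seed = config$seed,
                      variance_threshold = config$variance_threshold,
                      slide = slide)
    })
  }

  manifest <- list(package_version = as.character(utils::packageVersion("morphovar")),
                   seed = config$seed,
                   config_hash = object_hash(config[setdiff(names(config),
                                                            "out_dir")]),
                   n_specimens = dim(sample$coords)[3L],
                   n_landmarks = dim(sample$coords)[1L],
                   slide = slide, focal_group = focal)

  bundle <- structure(list(shape = shape, measurements = measurements,
                           covariates = covariates, sensitivity = sensitivity,
                           config = config, manifest = manifest),
                      class = "study_bundle")
  if (!is.null(out_dir)) {
    written <- run_stage("report", report_tables(bundle, out_dir))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  bundle
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>\n")
  cat("  shape: PC1", sprintf("%.2f%%", 100 * x$shape$pca$proportions[1L]),
      "-", x$shape$n_axes, "axes to threshold\n")
  if (!is.null(x$shape$procrustes_anova))
    cat(sprintf("  Procrustes ANOVA: F = %.3f, p = %.4g\n",
                x$shape$procrustes_anova$statistic, x$shape$procrustes_anova$p))
  if (!is.null(x$shape$manova))
    cat(sprintf("  MANOVA: Pillai = %.3f, approx F = %.3f, p = %.4g\n",
                x$shape$manova$pillai, x$shape$manova$statistic,
                x$shape$manova$p))
  invisible(x)
}

.test_row <- function(label, gt) {
  if (is.null(gt)) return(NULL)
  data.frame(test = label,
             df = sprintf("%s,%s", gt$df_effect, gt$df_resid),
             statistic = gt$statistic,
             pillai = ifelse(is.na(gt$pillai), NA, gt$pillai),
             p = gt$p)
}

#' Write the study result tables as CSVs
#'
#' Emits `table1_cv.csv` (measurement, CV%), `table2_tests.csv` (test, df,
#' statistic, Pillai, p; Pillai is NA for distance-based rows),
#' `disparity.csv`, `pc_variance.csv`, `per_axis_anova.csv` and — when a
#' sensitivity analysis ran — `sensitivity_k.csv` (per-k summary) and
#' `sensitivity_long.csv` (one row per combination).
#'
#' @param bundle a `study_bundle` from [run_study()].
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
report_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0L)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }

  if (!is.null(bundle$measurements))
    emit(bundle$measurements$cv[, c("measurement", "cv_pct", "n")],
         "table1_cv.csv")

  tests <- rbind(
    .test_row("procrustes_anova_3d", bundle$shape$procrustes_anova),
    .test_row("manova_3d", bundle$shape$manova),
    if (!is.null(bundle$measurements)) .test_row("manova_linear",
                                                 bundle$measurements$manova))
  emit(tests, "table2_tests.csv")

  disp <- rbind(
    data.frame(data = "3d_shape",
               metric = c("sum_of_variances", "median_centroid_distance"),
               value = c(bundle$shape$disparity$sum_of_variances$value,
                         bundle$shape$disparity$median_centroid_distance$value),
               n = bundle$shape$disparity$sum_of_variances$n),
    if (!is.null(bundle$measurements) && !is.null(bundle$measurements$disparity))
      data.frame(data = "linear",
                 metric = c("sum_of_variances", "median_centroid_distance"),
                 value = c(bundle$measurements$disparity$sum_of_variances$value,
                           bundle$measurements$disparity$median_centroid_distance$value),
                 n = bundle$measurements$disparity$sum_of_variances$n))
  emit(disp, "disparity.csv")

  pc <- data.frame(axis = seq_along(bundle$shape$pca$proportions),
                   data = "3d_shape",
                   eigenvalue = bundle$shape$pca$eigenvalues,
                   proportion = bundle$shape$pca$proportions)
  if (!is.null(bundle$measurements))
    pc <- rbind(pc, data.frame(
      axis = seq_along(bundle$measurements$pca$proportions),
      data = "linear",
      eigenvalue = bundle$measurements$pca$eigenvalues,
      proportion = bundle$measurements$pca$proportions))
  emit(pc, "pc_variance.csv")

  pa <- cbind(data = "3d_shape", bundle$shape$per_axis)
  if (!is.null(bundle$measurements) && !is.null(bundle$measurements$per_axis))
    pa <- rbind(pa, cbind(data = "linear", bundle$measurements$per_axis))
  emit(pa, "per_axis_anova.csv")

  if (!is.null(bundle$covariates) && length(bundle$covariates)) {
    cov <- do.call(rbind, lapply(names(bundle$covariates), function(nm) {
      gt <- bundle$covariates[[nm]]
      data.frame(test = gt$test, predictor = nm,
                 df = sprintf("%s,%s", gt$df_effect, gt$df_resid),
                 statistic = gt$statistic,
                 pillai = ifelse(is.na(gt$pillai), NA, gt$pillai),
                 p_raw = gt$p, p_adjusted = gt$p_adjusted,
                 n_perm = gt$n_perm, seed = gt$seed)
    }))
    emit(cov, "covariates.csv")
  }

  if (!is.null(bundle$sensitivity)) {
    summ <- do.call(rbind, lapply(bundle$sensitivity, function(r)
      data.frame(k = r$k, n_combinations = r$n_combinations_evaluated,
                 exhaustive = r$exhaustive, median_p = r$median_p)))
    emit(summ, "sensitivity_k.csv")
    emit(as.data.frame(bundle$sensitivity), "sensitivity_long.csv")
  }
  invisible(written)
}

#' Minimal PC morphospace scatter with group hulls
#'
#' @param pca a `pca_result`.
#' @param groups group labels (length n).
#' @param axes which two axes to plot (default PC1 vs PC2).
#' @param ... passed to [graphics::plot()].
#' @return NULL, invisibly (draws on the active device).
#' @export
plot_morphospace <- function(pca, groups, axes = c(1L, 2L), ...) {
  stopifnot(inherits(pca, "pca_result"), length(axes) == 2L)
  sc <- pca$scores[, axes, drop = FALSE]
  groups <- base::factor(groups)
  cols <- seq_len(nlevels(groups)) + 1L
  lab <- sprintf("PC%d (%.1f%%)", axes, 100 * pca$proportions[axes])
  graphics::plot(sc, col = cols[as.integer(groups)], pch = 19,
                 xlab = lab[1L], ylab = lab[2L], ...)
  for (g in seq_len(nlevels(groups))) {
    pts <- sc[as.integer(groups) == g, , drop = FALSE]
    if (nrow(pts) >= 3L) {
      h <- grDevices::chull(pts)
      graphics::polygon(pts[h, ], border = cols[g], lty = 2L)
    }
  }
  graphics::legend("topright", legend = levels(groups), col = cols, pch = 19,
                   bty = "n")
  invisible(NULL)
}
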