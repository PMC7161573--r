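# Synthetic landmark samples and measurement tables with known ground
# truth, emulating curve-structured cochlear shape data: a conical-helix
# mean shape, isotropic within-group landmark noise, smooth between-group
# mean deformations, nuisance similarity transforms, and measurement tables
# with specified means and CVs.

#' Conical-helix landmark configuration with curve scheme
#'
#' Builds a cochlea-like spiral: the centerline is a conical helix with
#' radius `r(theta) = (basal_width / 2) * (1 - (1 - taper) * theta / theta_max)`
#' and height `z(theta) = height * theta / theta_max`, `theta_max = 2 * pi *
#' turns`. Each of the `n_curves` curves samples the helix tube: a copy of
#' the centerline offset horizontally by `tube_radius` at a fixed phase
#' around the tube, so the bounding-box height of the configuration equals
#' `height` exactly. Curves are ordered runs of consecutive landmarks;
#' optionally one fixed apex landmark is appended (40 curves x 9 points +
#' apex = 361 landmarks, the scale of real cochlear datasets).
#'
#' @param turns number of turns of the spiral (> 0).
#' @param height cochlear height (> 0, arbitrary units).
#' @param basal_width basal diameter of the spiral (> 0).
#' @param taper apical-to-basal radius ratio in (0, 1]; 1 = constant radius.
#' @param points_per_curve landmarks per curve (>= 3).
#' @param n_curves number of curves (>= 1).
#' @param tube_radius offset of each curve from the centerline; default 5%
#'   of `basal_width`.
#' @param apex append one fixed apex landmark at the top of the centerline.
#' @return list with `config` (a [landmark_config()]) and `scheme`
#'   (a [curve_scheme()]).
#' @export
make_spiral_shape <- function(turns = 1.5, height = 3, basal_width = 6,
                              taper = 0.5, points_per_curve = 9L,
                              n_curves = 40L,
                              tube_radius = 0.05 * basal_width,
                              apex = FALSE) {
  stopifnot(turns > 0, height > 0, basal_width > 0, taper > 0, taper <= 1,
            points_per_curve >= 3L, n_curves >= 1L)
  theta_max <- 2 * pi * turns
  theta <- seq(0, theta_max, length.out = points_per_curve)
  frac <- theta / theta_max
  r <- (basal_width / 2) * (1 - (1 - taper) * frac)
  z <- height * frac
  e_rho <- cbind(cos(theta), sin(theta), 0)
  e_phi <- cbind(-sin(theta), cos(theta), 0)
  pts <- vector("list", n_curves)
  for (j in seq_len(n_curves)) {
    phase <- 2 * pi * (j - 1L) / n_curves
    offset <- tube_radius * (cos(phase) * e_rho + sin(phase) * e_phi)
    pts[[j]] <- cbind(r * cos(theta), r * sin(theta), z) + offset
  }
  points <- do.call(rbind, pts)
  curves <- lapply(seq_len(n_curves), function(j)
    ((j - 1L) * points_per_curve + 1L):(j * points_per_curve))
  if (apex) {
    apex_r <- (basal_width / 2) * taper
    points <- rbind(points, c(apex_r * cos(theta_max), apex_r * sin(theta_max),
                              height))
  }
  config <- landmark_config(points, "mean_shape")
  list(config = config, scheme = curve_scheme(curves, nrow(points)))
}

#' Preset synthetic shape scales
#'
#' `"paper"`: 40 curves x 9 points + apex = 361 landmarks, the scale of
#' real cochlear landmark datasets. `"tiny"`: 4 curves x 5 points = 20
#' landmarks, for fast tests.
#'
#' @param preset `"paper"` or `"tiny"`.
#' @param ... overrides passed to [make_spiral_shape()].
#' @return list with `config` and `scheme` as in [make_spiral_shape()].
#' @export
synthetic_preset <- function(preset = c("tiny", "paper"), ...) {
  preset <- match.arg(preset)
  args <- if (preset == "paper")
    list(points_per_curve = 9L, n_curves = 40L, apex = TRUE)
  else
    list(points_per_curve = 5L, n_curves = 4L, apex = FALSE)
  do.call(make_spiral_shape, utils::modifyList(args, list(...)))
}

.default_transform_ranges <- function()
  list(rotate = TRUE, translate = 1, scale = c(0.8, 1.25))

# apply a random similarity transform drawn from `ranges` to X (p x 3);
# `unit` sets the translation scale (typically the mean centroid size)
.random_transform <- function(X, ranges, unit) {
  if (isTRUE(ranges$rotate)) X <- X %*% random_rotation()
  if (!is.null(ranges$scale)) {
    s <- stats::runif(1L, ranges$scale[1L], ranges$scale[2L])
    X <- X * s
  }
  if (!is.null(ranges$translate) && ranges$translate > 0) {
    tr <- stats::runif(3L, -ranges$translate, ranges$translate) * unit
    X <- sweep(X, 2L, tr, "+")
  }
  X
}

# smooth a p x 3 field along the curves of `scheme` by repeated
# three-point moving averages; landmarks off all curves are untouched
.smooth_along_curves <- function(field, scheme, passes = 4L) {
  for (pass in seq_len(passes)) {
    for (ix in scheme$curves) {
      if (length(ix) < 3L) next
      v <- field[ix, , drop = FALSE]
      sm <- v
      inner <- 2:(length(ix) - 1L)
      sm[inner, ] <- (v[inner - 1L, ] + v[inner, ] + v[inner + 1L, ]) / 3
      sm[1L, ] <- (2 * v[1L, ] + v[2L, ]) / 3
      sm[length(ix), ] <- (2 * v[length(ix), ] + v[length(ix) - 1L, ]) / 3
      field[ix, ] <- sm
    }
  }
  field
}

# draw a smooth unit deformation field (RMS 1 per coordinate)
.smooth_field <- function(p, scheme) {
  field <- matrix(stats::rnorm(p * 3L), p, 3L)
  if (!is.null(scheme)) field <- .smooth_along_curves(field, scheme)
  field / sqrt(mean(field^2))
}

# add noise + jitter + nuisance transform to a mean shape
.perturb_specimen <- function(mean_pts, scheme, within_sd, jitter_sd, ranges,
                              cs) {
  p <- nrow(mean_pts)
  X <- mean_pts
  if (within_sd > 0)
    X <- X + matrix(stats::rnorm(p * 3L, sd = within_sd * cs), p, 3L)
  if (jitter_sd > 0 && !is.null(scheme)) {
    for (ix in scheme$curves) {
      if (length(ix) < 3L) next
      for (j in 2:(length(ix) - 1L)) {
        tng <- mean_pts[ix[j + 1L], ] - mean_pts[ix[j - 1L], ]
        tl <- sqrt(sum(tng^2))
        if (tl < 1e-12) next
        X[ix[j], ] <- X[ix[j], ] +
          stats::rnorm(1L, sd = jitter_sd * cs) * tng / tl
      }
    }
  }
  .random_transform(X, ranges, cs)
}

#' Simulate a population of configurations around a mean shape
#'
#' Each specimen is the mean shape plus isotropic Gaussian landmark noise,
#' optional Gaussian jitter along the local curve tangents (emulating the
#' arbitrary placement of semilandmarks along curves), and a random
#' nuisance rotation/translation/scale. Noise levels are expressed in units
#' of the mean shape's centroid size.
#'
#' @param mean a [landmark_config()] (e.g. from [make_spiral_shape()]).
#' @param n number of specimens (>= 2).
#' @param within_sd isotropic landmark noise sd, in centroid-size units.
#' @param tangential_jitter_sd sd of tangential jitter, centroid-size units.
#' @param transform_ranges list with `rotate` (logical), `translate`
#'   (half-range, centroid-size units) and `scale` (c(min, max) uniform
#'   range); see defaults in the source. `NULL` entries disable a
#'   component.
#' @param scheme optional [curve_scheme()]; required for tangential jitter.
#' @param seed RNG seed (recorded in the truth manifest).
#' @param id_prefix prefix for specimen ids.
#' @param group group label stored in the metadata.
#' @return a [landmark_sample()]; `attr(, "truth")` holds the generating
#'   parameters.
#' @export
make_population <- function(mean, n, within_sd = 0.01,
                            tangential_jitter_sd = 0,
                            transform_ranges = .default_transform_ranges(),
                            scheme = NULL, seed = NULL,
                            id_prefix = "spec", group = "pop") {
  stopifnot(inherits(mean, "landmark_config"), n >= 2L,
            within_sd >= 0, tangential_jitter_sd >= 0)
  cs <- centroid_size(mean$points)
  configs <- with_seed(seed, lapply(seq_len(n), function(i) {
    X <- .perturb_specimen(mean$points, scheme, within_sd,
                           tangential_jitter_sd, transform_ranges, cs)
    landmark_config(X, sprintf("%s%03d", id_prefix, i), mean$labels)
  }))
  metadata <- data.frame(specimen_id = vapply(configs, `[[`, "", "specimen_id"),
                         species = group, group = group,
                         side = "unknown", sex = "unknown", origin = "unknown",
                         cbl_mm = NA_real_)
  out <- landmark_sample(configs, scheme = scheme, metadata = metadata)
  attr(out, "truth") <- list(kind = "population", n = n, within_sd = within_sd,
                             tangential_jitter_sd = tangential_jitter_sd,
                             transform_ranges = transform_ranges,
                             centroid_size = cs, seed = seed)
  out
}

#' Simulate a focal group versus heterogeneous other specimens
#'
#' Emulates the design of intraspecific-versus-interspecific comparisons:
#' `n_focal` specimens are drawn around a single mean shape; each of the
#' `n_other` specimens is drawn around its own perturbed mean — the base
#' shape plus `between_offset` times a smooth deformation field shared by
#' the whole non-focal group (their mean-shape offset from the focal
#' group), plus `between_offset` times the specimen's own smooth field
#' (species-to-species scatter). Both fields have unit per-coordinate RMS,
#' so the group mean shapes differ by `between_offset` (in centroid-size
#' units, per coordinate RMS) and the non-focal dispersion exceeds the
#' focal dispersion by the same scale. With `between_offset = 0` the two
#' groups have identical distributions (a null dataset).
#'
#' @param n_focal,n_other group sizes; defaults 18 and 51, the scale of the
#'   motivating study design.
#' @param preset shape scale passed to [synthetic_preset()].
#' @param within_sd isotropic within-group noise sd (centroid-size units).
#' @param between_offset per-coordinate RMS magnitude of the between-group
#'   mean deformation (centroid-size units).
#' @param tangential_jitter_sd tangential jitter sd (centroid-size units).
#' @param transform_ranges nuisance transform ranges (see
#'   [make_population()]).
#' @param seed RNG seed.
#' @param ... overrides passed to [synthetic_preset()].
#' @return a [landmark_sample()] with groups `focal` / `other`;
#'   `attr(, "truth")` records all generating parameters.
#' @export
make_two_group_sample <- function(n_focal = 18L, n_other = 51L,
                                  preset = "tiny", within_sd = 0.01,
                                  between_offset = 0.05,
                                  tangential_jitter_sd = 0,
                                  transform_ranges = .default_transform_ranges(),
                                  seed = NULL, ...) {
  stopifnot(n_focal >= 1L, n_other >= 1L, within_sd >= 0, between_offset >= 0)
  base <- synthetic_preset(preset, ...)
  mean_pts <- base$config$points
  scheme <- base$scheme
  p <- nrow(mean_pts)
  cs <- centroid_size(mean_pts)
  configs <- with_seed(seed, {
    focal <- lapply(seq_len(n_focal), function(i) {
      X <- .perturb_specimen(mean_pts, scheme, within_sd,
                             tangential_jitter_sd, transform_ranges, cs)
      landmark_config(X, sprintf("focal%03d", i), base$config$labels)
    })
    shared_field <- .smooth_field(p, scheme)   # non-focal group mean offset
    other <- lapply(seq_len(n_other), function(i) {
      own_mean <- mean_pts + between_offset * cs *
        (shared_field + .smooth_field(p, scheme))
      X <- .perturb_specimen(own_mean, scheme, within_sd,
                             tangential_jitter_sd, transform_ranges, cs)
      landmark_config(X, sprintf("other%03d", i), base$config$labels)
    })
    c(focal, other)
  })
  ids <- vapply(configs, `[[`, "", "specimen_id")
  grp <- rep(c("focal", "other"), c(n_focal, n_other))
  species <- c(rep("focal_species", n_focal),
               sprintf("other_species_%02d", seq_len(n_other)))
  metadata <- data.frame(specimen_id = ids, species = species, group = grp,
                         side = "unknown", sex = "unknown", origin = "unknown",
                         cbl_mm = NA_real_)
  out <- landmark_sample(configs, scheme = scheme, metadata = metadata,
                         groups = grp)
  attr(out, "truth") <- list(kind = "two_group", n_focal = n_focal,
                             n_other = n_other, preset = preset,
                             within_sd = within_sd,
                             between_offset = between_offset,
                             tangential_jitter_sd = tangential_jitter_sd,
                             transform_ranges = transform_ranges,
                             centroid_size = cs, seed = seed)
  out
}

#' Default raw-measurement means and CVs for the measurement generator
#'
#' Means are plausible adult harbour-porpoise cochlear dimensions (mm, mm^2,
#' mm^3, turns); default CVs are representative intraspecific values for
#' these measurements (a few percent for most, larger for the fenestra
#' cochlearis area).
#'
#' @return named numeric vector over [raw_measurement_columns()].
#' @export
default_measurement_means <- function()
  c(cochlear_height = 3.4, cochlear_width = 6.7, n_turns = 1.5,
    cochlear_volume = 60, canal_length = 22, ssl_length = 12,
    w2 = 5.0, itd = 1.4, fc_area = 3.5)

#' @rdname default_measurement_means
#' @export
default_measurement_cvs <- function()
  c(cochlear_height = 7.783, cochlear_width = 4.842, n_turns = 3.394,
    cochlear_volume = 8.015, canal_length = 6.189, ssl_length = 6.619,
    w2 = 7.612, itd = 11.93, fc_area = 26.80)

#' Simulate a measurement table with specified means and CVs
#'
#' Raw measurement columns are drawn from a multivariate normal with
#' `sd = mean * cv / 100` and an exchangeable correlation across
#' measurements; derived ratio columns are recomputed from the raw draws
#' (so their CVs are emergent, not specified). Rows with any non-positive
#' raw value are redrawn; more than 10% redraws is an error (choose smaller
#' CVs).
#'
#' @param n number of specimens.
#' @param means named vector of raw-column means (> 0); defaults to
#'   [default_measurement_means()].
#' @param cvs_pct named vector of raw-column CVs in percent (>= 0);
#'   defaults to [default_measurement_cvs()].
#' @param correlation exchangeable correlation in `[0, 1)`.
#' @param seed RNG seed.
#' @return a [measurement_table()]; `attr(, "truth")` records the
#'   generating parameters and redraw count.
#' @export
make_measurement_table <- function(n = 18L,
                                   means = default_measurement_means(),
                                   cvs_pct = default_measurement_cvs(),
                                   correlation = 0.3, seed = NULL) {
  cols <- raw_measurement_columns()
  stopifnot(n >= 2L, correlation >= 0, correlation < 1)
  means <- means[cols]; cvs_pct <- cvs_pct[cols]
  if (anyNA(means) || anyNA(cvs_pct))
    stop("`means` and `cvs_pct` must be named over raw_measurement_columns()",
         call. = FALSE)
  if (any(means <= 0)) stop("means must be positive", call. = FALSE)
  if (any(cvs_pct < 0)) stop("CVs must be non-negative", call. = FALSE)
  k <- length(cols)
  sds <- means * cvs_pct / 100
  R <- matrix(correlation, k, k); diag(R) <- 1
  L <- chol(R)
  draw_rows <- function(m) {
    Z <- matrix(stats::rnorm(m * k), m, k) %*% L
    sweep(sweep(Z, 2L, sds, "*"), 2L, means, "+")
  }
  res <- with_seed(seed, {
    X <- draw_rows(n)
    redrawn <- 0L
    repeat {
      bad <- which(apply(X, 1L, function(r) any(r <= 0)))
      if (!length(bad)) break
      redrawn <- redrawn + length(bad)
      if (redrawn > max(1L, ceiling(0.1 * n)))
        stop("more than 10% of rows redrawn for positivity; reduce CVs",
             call. = FALSE)
      X[bad, ] <- draw_rows(length(bad))
    }
    list(X = X, redrawn = redrawn)
  })
  df <- as.data.frame(res$X)
  names(df) <- cols
  df <- cbind(specimen_id = sprintf("spec%03d", seq_len(n)), df)
  out <- measurement_table(df)
  attr(out, "truth") <- list(kind = "measurements", n = n, means = means,
                             cvs_pct = cvs_pct, correlation = correlation,
                             redrawn = res$redrawn, seed = seed)
  out
}
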