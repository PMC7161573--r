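#' Landmark configuration for a single specimen
#'
#' Bundles an ordered set of 3D landmarks for one specimen. Landmarks are
#' ordered: curve schemes refer to them by position.
#'
#' @param points numeric p x 3 matrix of coordinates (arbitrary length
#'   units; scale is removed downstream by [gpa()]).
#' @param specimen_id single character specimen identifier.
#' @param labels optional character vector of p unique landmark labels;
#'   autogenerated (`L0001`, ...) when missing.
#' @return An object of class `landmark_config`: a list with elements
#'   `specimen_id`, `points` (rownames = labels) and `labels`.
#' @examples
#' cfg <- landmark_config(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), "tri")
#' cfg$labels
#' @export
landmark_config <- function(points, specimen_id = "specimen", labels = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("`points` must be a numeric p x 3 matrix", call. = FALSE)
  p <- nrow(points)
  if (p < 3L) stop("a landmark configuration needs at least 3 landmarks", call. = FALSE)
  if (any(!is.finite(points)))
    stop("non-finite coordinates in configuration '", specimen_id, "'", call. = FALSE)
  if (is.null(labels)) labels <- sprintf("L%04d", seq_len(p))
  labels <- as.character(labels)
  if (length(labels) != p) stop("`labels` must have one entry per landmark", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate landmark labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  dimnames(points) <- list(labels, c("x", "y", "z"))
  structure(list(specimen_id = as.character(specimen_id)[1L],
                 points = points, labels = labels),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("<landmark_config> specimen:", x$specimen_id,
      "-", nrow(x$points), "landmarks\n")
  invisible(x)
}

#' Sliding-semilandmark curve scheme
#'
#' Describes which landmarks form which sliding semilandmark curves. Curves
#' are ordered lists of 1-based landmark indices; the first and last point of
#' every curve are fixed anchors (they are never slid), as are landmarks not
#' on any curve.
#'
#' @param curves list of integer vectors, each an ordered curve of >= 3
#'   landmark indices in `1..p`.
#' @param p total number of landmarks the scheme applies to.
#' @return An object of class `curve_scheme`: list with `curves`, `p` and
#'   `anchors` (logical length p, `TRUE` = fixed).
#' @seealso [validate_scheme()], [read_curve_scheme()]
#' @export
curve_scheme <- function(curves, p) {
  p <- as.integer(p)
  curves <- lapply(curves, function(ix) as.integer(ix))
  scheme <- structure(list(curves = curves, p = p,
                           anchors = .scheme_anchors(curves, p)),
                      class = "curve_scheme")
  .check_scheme(scheme)
  scheme
}

.scheme_anchors <- function(curves, p) {
  anchors <- rep(TRUE, p)
  for (ix in curves) {
    if (length(ix) >= 3L) anchors[ix[-c(1L, length(ix))]] <- FALSE
  }
  anchors
}

.check_scheme <- function(scheme) {
  p <- scheme$p
  seen <- integer(0L)
  for (ci in seq_along(scheme$curves)) {
    ix <- scheme$curves[[ci]]
    if (length(ix) < 3L)
      stop("curve ", ci, " has fewer than 3 points", call. = FALSE)
    if (any(ix < 1L | ix > p))
      stop("curve ", ci, " references landmark index outside 1..", p, call. = FALSE)
    if (anyDuplicated(ix))
      stop("curve ", ci, " repeats a landmark", call. = FALSE)
    dup <- intersect(ix, seen)
    if (length(dup))
      stop("landmark(s) ", paste(dup, collapse = ", "),
           " belong to more than one curve", call. = FALSE)
    seen <- c(seen, ix)
  }
  invisible(scheme)
}

#' @export
print.curve_scheme <- function(x, ...) {
  cat("<curve_scheme>", length(x$curves), "curves over", x$p, "landmarks;",
      sum(!x$anchors), "sliding semilandmarks\n")
  invisible(x)
}

#' Validate a configuration / curve-scheme pair
#'
#' Checks that a curve scheme is internally consistent and applicable to a
#' landmark configuration: indices in range, no landmark on two curves, every
#' curve at least 3 points long.
#'
#' @param config a [landmark_config()].
#' @param scheme a [curve_scheme()].
#' @return the (unchanged) inputs, invisibly, as `list(config, scheme)`.
#' @export
validate_scheme <- function(config, scheme) {
  stopifnot(inherits(config, "landmark_config"), inherits(scheme, "curve_scheme"))
  if (scheme$p != nrow(config$points))
    stop("scheme is for ", scheme$p, " landmarks but configuration '",
         config$specimen_id, "' has ", nrow(config$points), call. = FALSE)
  .check_scheme(scheme)
  invisible(list(config = config, scheme = scheme))
}

#' Collection of landmark configurations with metadata
#'
#' An aligned-in-structure (same p, same curve scheme) set of
#' configurations, the unit on which [gpa()] and the group tests operate.
#'
#' @param configs list of [landmark_config()] objects sharing a common
#'   landmark count and labels.
#' @param scheme optional [curve_scheme()] shared by all configurations.
#' @param metadata optional data.frame with one row per specimen; a
#'   `specimen_id` column must match the configurations. Missing categorical
#'   fields are filled with `"unknown"`.
#' @param groups optional vector of group labels (length n); defaults to
#'   `metadata$group` when present.
#' @return Object of class `landmark_sample`: list with `coords`
#'   (p x 3 x n array, specimen ids as third dimnames), `labels`, `scheme`,
#'   `metadata`, `groups` (factor or NULL).
#' @export
landmark_sample <- function(configs, scheme = NULL, metadata = NULL, groups = NULL) {
  stopifnot(is.list(configs), length(configs) >= 2L)
  lapply(configs, function(cf) stopifnot(inherits(cf, "landmark_config")))
  p <- nrow(configs[[1L]]$points)
  if (!all(vapply(configs, function(cf) nrow(cf$points), 0L) == p))
    stop("all configurations must share the same number of landmarks", call. = FALSE)
  ids <- vapply(configs, function(cf) cf$specimen_id, "")
  if (anyDuplicated(ids))
    stop("duplicate specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  coords <- array(NA_real_, dim = c(p, 3L, length(configs)),
                  dimnames = list(configs[[1L]]$labels, c("x", "y", "z"), ids))
  for (i in seq_along(configs)) coords[, , i] <- configs[[i]]$points
  if (!is.null(scheme)) validate_scheme(configs[[1L]], scheme)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"specimen_id" %in% names(metadata))
      stop("metadata must contain a specimen_id column", call. = FALSE)
    missing_ids <- setdiff(ids, metadata$specimen_id)
    if (length(missing_ids))
      stop("metadata missing specimens: ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    metadata <- metadata[match(ids, metadata$specimen_id), , drop = FALSE]
    rownames(metadata) <- NULL
    for (col in c("side", "sex", "origin"))
      if (col %in% names(metadata)) {
        v <- as.character(metadata[[col]])
        v[is.na(v) | v == ""] <- "unknown"
        metadata[[col]] <- v
      }
  }
  if (is.null(groups) && !is.null(metadata) && "group" %in% names(metadata))
    groups <- metadata$group
  if (!is.null(groups)) {
    groups <- factor(groups)
    if (length(groups) != length(configs))
      stop("`groups` must have one label per specimen", call. = FALSE)
  }
  structure(list(coords = coords, labels = configs[[1L]]$labels,
                 scheme = scheme, metadata = metadata, groups = groups),
            class = "landmark_sample")
}

#' @export
print.landmark_sample <- function(x, ...) {
  cat("<landmark_sample>", dim(x$coords)[3L], "specimens x",
      dim(x$coords)[1L], "landmarks")
  if (!is.null(x$scheme)) cat(";", length(x$scheme$curves), "curves")
  if (!is.null(x$groups)) cat("; groups:",
                              paste(levels(x$groups), collapse = "/"))
  cat("\n")
  invisible(x)
}

#' Subset a landmark sample by specimen
#'
#' @param x a `landmark_sample`.
#' @param i specimen indices, logical mask, or specimen ids.
#' @param ... ignored.
#' @return a `landmark_sample` restricted to the selected specimens.
#' @export
`[.landmark_sample` <- function(x, i, ...) {
  ids <- dimnames(x$coords)[[3L]]
  if (is.character(i)) {
    miss <- setdiff(i, ids)
    if (length(miss)) stop("unknown specimen id(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    i <- match(i, ids)
  }
  idx <- seq_along(ids)[i]
  if (length(idx) < 2L) stop("a landmark_sample needs at least 2 specimens", call. = FALSE)
  out <- x
  out$coords <- x$coords[, , idx, drop = FALSE]
  if (!is.null(x$metadata)) out$metadata <- x$metadata[idx, , drop = FALSE]
  if (!is.null(x$groups)) out$groups <- droplevels(x$groups[idx])
  out
}

#' Extract one specimen as a landmark_config
#' @param sample a `landmark_sample`.
#' @param i specimen index or id.
#' @return a [landmark_config()].
#' @export
get_config <- function(sample, i) {
  stopifnot(inherits(sample, "landmark_sample"))
  ids <- dimnames(sample$coords)[[3L]]
  if (is.character(i)) i <- match(i, ids)
  landmark_config(sample$coords[, , i], ids[i], sample$labels)
}
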