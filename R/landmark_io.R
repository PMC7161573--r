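# Readers/writers for landmark files (.pts, TPS, CSV), curve schemes and
# measurement/metadata tables.

.is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read an IDAV Landmark .pts file
#'
#' Dialect: lines starting with `#`, and lines whose second whitespace-
#' separated token is non-numeric, are treated as comments/headers and
#' skipped. Landmark lines are either `label x y z` or bare `x y z`
#' (labels autogenerated `L0001`, ...). Points are returned in file order.
#'
#' @param path path to a .pts file.
#' @param specimen_id id for the resulting configuration; defaults to the
#'   file name without extension.
#' @return a [landmark_config()].
#' @export
read_pts <- function(path, specimen_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(specimen_id))
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  pts <- list(); labels <- character(0L); auto <- 0L
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "" || startsWith(raw, "#")) next
    tok <- strsplit(raw, "[[:space:]]+")[[1L]]
    if (length(tok) >= 2L && !.is_num(tok[2L])) next  # header line
    if (length(tok) == 3L) {
      if (!all(.is_num(tok)))
        stop("non-numeric coordinate on line ", ln, " of ", path, call. = FALSE)
      auto <- auto + 1L
      labels <- c(labels, sprintf("L%04d", auto))
      pts[[length(pts) + 1L]] <- as.numeric(tok)
    } else if (length(tok) == 4L) {
      if (!all(.is_num(tok[2:4])))
        stop("non-numeric coordinate on line ", ln, " of ", path, call. = FALSE)
      labels <- c(labels, tok[1L])
      pts[[length(pts) + 1L]] <- as.numeric(tok[2:4])
    } else if (length(tok) < 3L) {
      next  # short trailing tokens, e.g. a point count header
    } else {
      stop("line ", ln, " of ", path, " has ", length(tok),
           " columns; expected 3 (x y z) or 4 (label x y z)", call. = FALSE)
    }
  }
  if (!length(pts)) stop("no landmark lines found in ", path, call. = FALSE)
  landmark_config(do.call(rbind, pts), specimen_id, labels)
}

#' Write a configuration to .pts format
#'
#' Writes `label x y z` lines with 17 significant digits, so a
#' write/read roundtrip is bit-exact.
#'
#' @param config a [landmark_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pts <- function(config, path) {
  stopifnot(inherits(config, "landmark_config"))
  lines <- sprintf("%s %.17g %.17g %.17g", config$labels,
                   config$points[, 1L], config$points[, 2L], config$points[, 3L])
  writeLines(c(sprintf("# %s", config$specimen_id), lines), path)
  invisible(path)
}

#' Read a 3D TPS file
#'
#' Parses `LM3=p` blocks with `ID=` keys; one configuration per block.
#'
#' @param path path to a TPS file.
#' @return a list of [landmark_config()] (always a list, even for one block).
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  starts <- grep("^LM3=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM3= blocks in ", path, call. = FALSE)
  configs <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:(bounds[b + 1L] - 1L)]
    p <- as.integer(sub("^LM3=", "", block[1L], ignore.case = TRUE))
    if (is.na(p) || p < 3L) stop("bad LM3= count in block ", b, call. = FALSE)
    coord_lines <- block[2:(1L + p)]
    mat <- t(vapply(strsplit(coord_lines, "[[:space:]]+"), function(tok) {
      if (length(tok) != 3L || !all(.is_num(tok)))
        stop("malformed coordinate line in TPS block ", b, call. = FALSE)
      as.numeric(tok)
    }, numeric(3L)))
    id_line <- grep("^ID=", block, ignore.case = TRUE, value = TRUE)
    id <- if (length(id_line)) sub("^ID=", "", id_line[1L], ignore.case = TRUE)
          else sprintf("specimen%03d", b)
    configs[[b]] <- landmark_config(mat, id)
  }
  configs
}

#' Write configurations to a 3D TPS file
#' @param configs a [landmark_config()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  out <- unlist(lapply(configs, function(cf) {
    c(sprintf("LM3=%d", nrow(cf$points)),
      sprintf("%.17g %.17g %.17g", cf$points[, 1L], cf$points[, 2L], cf$points[, 3L]),
      sprintf("ID=%s", cf$specimen_id))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read landmark coordinates from CSV
#'
#' Two layouts are supported. Long: columns `specimen_id, landmark, x, y, z`
#' (landmark order = first-appearance order). Wide: one row per specimen
#' with a `specimen_id` column and coordinate columns `x1,y1,z1,x2,...`.
#'
#' @param path CSV path.
#' @param layout `"long"` or `"wide"`; guessed from the header by default.
#' @return list of [landmark_config()].
#' @export
read_landmarks_csv <- function(path, layout = c("auto", "long", "wide")) {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "auto")
    layout <- if (all(c("landmark", "x", "y", "z") %in% names(df))) "long" else "wide"
  if (layout == "long") {
    need <- c("specimen_id", "landmark", "x", "y", "z")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    lapply(split(df, factor(df$specimen_id, levels = unique(df$specimen_id))),
           function(d) landmark_config(as.matrix(d[, c("x", "y", "z")]),
                                       d$specimen_id[1L], d$landmark))
  } else {
    if (!"specimen_id" %in% names(df))
      stop("wide layout needs a specimen_id column", call. = FALSE)
    cc <- setdiff(names(df), "specimen_id")
    p <- length(cc) / 3L
    if (p != floor(p)) stop("coordinate columns not a multiple of 3", call. = FALSE)
    expected <- as.vector(t(outer(seq_len(p), c("x", "y", "z"),
                                  function(i, a) paste0(a, i))))
    if (!all(expected %in% cc))
      stop("wide layout columns must be x1,y1,z1,x2,... ", call. = FALSE)
    lapply(seq_len(nrow(df)), function(i) {
      m <- matrix(as.numeric(df[i, expected]), ncol = 3L, byrow = TRUE)
      landmark_config(m, df$specimen_id[i])
    })
  }
}

#' Write landmark coordinates to long CSV
#' @param configs list of [landmark_config()] (or one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(configs, path) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  df <- do.call(rbind, lapply(configs, function(cf)
    data.frame(specimen_id = cf$specimen_id, landmark = cf$labels,
               x = cf$points[, 1L], y = cf$points[, 2L], z = cf$points[, 3L])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a curve scheme from CSV or YAML
#'
#' CSV layout: columns `curve` and `landmark` (label or 1-based index),
#' points ordered within curve by row order. YAML layout: a mapping of curve
#' id to an ordered list of landmark labels/indices.
#'
#' @param path scheme file (.csv, .yml/.yaml).
#' @param labels character vector of landmark labels used to resolve label
#'   references; required when the scheme uses labels.
#' @param p total landmark count; defaults to `length(labels)`.
#' @return a [curve_scheme()].
#' @export
read_curve_scheme <- function(path, labels = NULL, p = length(labels)) {
  ext <- tolower(sub(".*\\.", "", path))
  resolve <- function(v) {
    if (all(.is_num(as.character(v)))) return(as.integer(as.character(v)))
    if (is.null(labels)) stop("scheme uses labels but `labels` not supplied",
                              call. = FALSE)
    ix <- match(as.character(v), labels)
    if (anyNA(ix)) stop("unknown landmark label(s) in scheme: ",
                        paste(v[is.na(ix)], collapse = ", "), call. = FALSE)
    ix
  }
  if (ext %in% c("yml", "yaml")) {
    spec <- yaml::read_yaml(path)
    curves <- lapply(spec, resolve)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("curve", "landmark") %in% names(df)))
      stop("scheme CSV needs columns curve, landmark", call. = FALSE)
    curves <- lapply(split(df$landmark, factor(df$curve, unique(df$curve))),
                     resolve)
  }
  if (p == 0L) p <- max(unlist(curves))
  curve_scheme(curves, p)
}

#' Write a curve scheme to CSV
#' @param scheme a [curve_scheme()].
#' @param path output path.
#' @param labels optional labels; indices written when NULL.
#' @return `path`, invisibly.
#' @export
write_curve_scheme <- function(scheme, path, labels = NULL) {
  stopifnot(inherits(scheme, "curve_scheme"))
  df <- do.call(rbind, lapply(seq_along(scheme$curves), function(ci) {
    ix <- scheme$curves[[ci]]
    data.frame(curve = sprintf("curve%02d", ci),
               landmark = if (is.null(labels)) ix else labels[ix])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- measurement tables -----------------------------------------------------

#' Names of the raw and derived cochlear measurement columns
#'
#' Raw columns are measured quantities; derived columns are ratios
#' recomputed from them: `basal_ratio = cochlear_height / cochlear_width`,
#' `axial_pitch = cochlear_height / n_turns`,
#' `ssl_extent_pct = 100 * ssl_length / canal_length`.
#'
#' @return character vector of column names.
#' @export
measurement_columns <- function() c(raw_measurement_columns(),
                                    derived_measurement_columns())

#' @rdname measurement_columns
#' @export
raw_measurement_columns <- function()
  c("cochlear_height", "cochlear_width", "n_turns", "cochlear_volume",
    "canal_length", "ssl_length", "w2", "itd", "fc_area")

#' @rdname measurement_columns
#' @export
derived_measurement_columns <- function()
  c("basal_ratio", "axial_pitch", "ssl_extent_pct")

.recompute_derived <- function(df) {
  df$basal_ratio <- df$cochlear_height / df$cochlear_width
  df$axial_pitch <- df$cochlear_height / df$n_turns
  df$ssl_extent_pct <- 100 * df$ssl_length / df$canal_length
  df
}

#' Build a validated measurement table
#'
#' Derived columns are always recomputed from the raw measurements; stored
#' values disagreeing by more than 1e-6 relative trigger a warning.
#'
#' @param df data.frame with `specimen_id` and the raw measurement columns
#'   (see [raw_measurement_columns()]).
#' @return data.frame of class `measurement_table` with all 12 measurement
#'   columns.
#' @export
measurement_table <- function(df) {
  df <- as.data.frame(df)
  if (!"specimen_id" %in% names(df))
    stop("measurement table needs a specimen_id column", call. = FALSE)
  miss <- setdiff(raw_measurement_columns(), names(df))
  if (length(miss))
    stop("missing measurement column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in raw_measurement_columns()) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("non-numeric or non-finite values in ", col, call. = FALSE)
    bad <- which(v <= 0)
    if (length(bad))
      stop("non-positive ", col, " for specimen(s): ",
           paste(df$specimen_id[bad], collapse = ", "), call. = FALSE)
  }
  stored <- df[intersect(derived_measurement_columns(), names(df))]
  df <- .recompute_derived(df)
  for (col in names(stored)) {
    rel <- abs(stored[[col]] - df[[col]]) / pmax(abs(df[[col]]), 1e-300)
    if (any(rel > 1e-6, na.rm = TRUE))
      warning("stored ", col, " disagrees with recomputed values ",
              "(max relative difference ", signif(max(rel, na.rm = TRUE), 3),
              "); recomputed values used", call. = FALSE)
  }
  df <- df[, c("specimen_id", measurement_columns())]
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Read a measurement table from CSV
#' @param path CSV with header; raw measurement columns required.
#' @return a [measurement_table()].
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  measurement_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a measurement table to CSV
#' @param table a [measurement_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read specimen metadata from CSV
#'
#' Expected columns: `specimen_id`, and optionally `species`, `group`,
#' `side` (left/right/unknown), `sex` (F/M/unknown), `origin`, `cbl_mm`
#' (condylobasal length, mm; may be missing). Missing categorical values
#' become `"unknown"`.
#'
#' @param path CSV path.
#' @return data.frame of metadata.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(df))
    stop("metadata needs a specimen_id column", call. = FALSE)
  for (col in c("species", "group", "side", "sex", "origin")) {
    if (!col %in% names(df)) df[[col]] <- "unknown"
    v <- as.character(df[[col]])
    v[is.na(v) | v == ""] <- "unknown"
    df[[col]] <- v
  }
  if (!"cbl_mm" %in% names(df)) df$cbl_mm <- NA_real_
  df$cbl_mm <- as.numeric(df$cbl_mm)
  df
}
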