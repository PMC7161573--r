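test_that("read_pts parses labelled, bare and mixed dialects in file order", {
  f <- withr::local_tempfile(fileext = ".pts")
  writeLines(c("A 0 0 0", "B 1 0 0", "C 0 1 0"), f)
  cfg <- read_pts(f)
  expect_equal(cfg$labels, c("A", "B", "C"))
  expect_equal(unname(cfg$points),
               rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))

  # bare x y z columns with headers and comments interleaved
  writeLines(c("Landmark file v1", "# comment", "0 0 0", "1.5 0 0", "0 2 0"), f)
  cfg2 <- read_pts(f)
  expect_equal(cfg2$labels, c("L0001", "L0002", "L0003"))
  expect_equal(cfg2$points[2, 1], 1.5, ignore_attr = TRUE)
})

test_that("read_pts reports malformed lines by number and rejects empty files", {
  f <- withr::local_tempfile(fileext = ".pts")
  writeLines(c("A 0 0 0", "B 1 notanumber 0"), f)
  expect_error(read_pts(f), "line 2")
  writeLines(c("A 1 2 3 4 5"), f)
  expect_error(read_pts(f), "columns")
  writeLines(character(0), f)
  expect_error(read_pts(f), "no landmark")
})

test_that("pts and tps writers roundtrip bit-exactly and preserve order", {
  set.seed(11)
  pts <- matrix(rnorm(30), 10, 3)
  cfg <- landmark_config(pts, "spec1")
  f <- withr::local_tempfile(fileext = ".pts")
  write_pts(cfg, f)
  back <- read_pts(f)
  expect_identical(back$points, cfg$points)
  expect_identical(back$labels, cfg$labels)

  # permuting landmark lines permutes points identically
  lines <- readLines(f)
  perm <- c(1, sample(2:11))  # keep the header comment first
  writeLines(lines[perm], f)
  permuted <- read_pts(f)
  expect_identical(permuted$points, cfg$points[perm[-1] - 1L, ])

  ft <- withr::local_tempfile(fileext = ".tps")
  write_tps(list(cfg, landmark_config(pts + 1, "spec2")), ft)
  both <- read_tps(ft)
  expect_length(both, 2L)
  expect_identical(unname(both[[1]]$points), unname(cfg$points))
  expect_identical(both[[2]]$specimen_id, "spec2")
})

test_that("CSV landmark layouts roundtrip", {
  set.seed(2)
  cfgs <- lapply(1:3, function(i)
    landmark_config(matrix(rnorm(12), 4, 3), paste0("s", i)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(cfgs, f)
  back <- read_landmarks_csv(f)
  expect_equal(unname(back[[2]]$points), unname(cfgs[[2]]$points))

  # wide layout
  wide <- data.frame(specimen_id = "w1",
                     x1 = 0, y1 = 0, z1 = 0,
                     x2 = 1, y2 = 0, z2 = 0,
                     x3 = 0, y3 = 1, z3 = 0)
  write.csv(wide, f, row.names = FALSE)
  w <- read_landmarks_csv(f)
  expect_equal(unname(w[[1]]$points), triangle3d())
})

test_that("curve scheme validation catches the specced failure modes", {
  cfg <- landmark_config(matrix(rnorm(27), 9, 3), "s")
  sch <- curve_scheme(list(1:3, 4:6, 7:9), 9)
  expect_silent(validate_scheme(cfg, sch))
  expect_error(curve_scheme(list(c(1, 2, 10)), 9), "outside")
  expect_error(curve_scheme(list(1:4, 4:6), 9), "more than one curve")
  expect_error(curve_scheme(list(1:2), 9), "fewer than 3")
  # anchors: endpoints fixed, interior points slide
  expect_true(all(sch$anchors[c(1, 3, 4, 6, 7, 9)]))
  expect_false(any(sch$anchors[c(2, 5, 8)]))
})

test_that("curve scheme CSV/YAML readers resolve labels and indices", {
  labels <- sprintf("lm%02d", 1:6)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(curve = rep(c("a", "b"), each = 3),
                       landmark = labels), f, row.names = FALSE)
  sch <- read_curve_scheme(f, labels = labels)
  expect_equal(sch$curves, list(a = 1:3, b = 4:6), ignore_attr = TRUE)

  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(a = 1:3, b = 4:6), fy)
  sch2 <- read_curve_scheme(fy, p = 6)
  expect_equal(lapply(sch2$curves, as.integer), list(a = 1:3, b = 4:6),
               ignore_attr = TRUE)
})

test_that("measurement tables recompute derived ratios from raw columns", {
  df <- data.frame(specimen_id = "s1", cochlear_height = 3.0,
                   cochlear_width = 6.0, n_turns = 1.5, cochlear_volume = 60,
                   canal_length = 16.0, ssl_length = 4.0, w2 = 5, itd = 1.4,
                   fc_area = 3.5)
  tab <- measurement_table(df)
  expect_equal(tab$basal_ratio, 0.5)
  expect_equal(tab$axial_pitch, 2.0)
  expect_equal(tab$ssl_extent_pct, 25.0)

  # stored derived values are overridden, with a warning when inconsistent
  df$basal_ratio <- 0.9
  expect_warning(tab2 <- measurement_table(df), "basal_ratio")
  expect_equal(tab2$basal_ratio, 0.5)

  # duplicated specimens are kept as-is
  tab3 <- measurement_table(rbind(df[1, names(df) != "basal_ratio"],
                                  df[1, names(df) != "basal_ratio"]))
  expect_equal(nrow(tab3), 2L)
  expect_identical(tab3[1, -1], tab3[2, -1], ignore_attr = TRUE)
})

test_that("measurement table errors name missing columns and bad specimens", {
  df <- data.frame(specimen_id = c("a", "b"), cochlear_height = c(3, -1),
                   cochlear_width = 6, n_turns = 1.5, cochlear_volume = 60,
                   canal_length = 16, ssl_length = 4, w2 = 5, itd = 1.4,
                   fc_area = 3.5)
  expect_error(measurement_table(df[, -4]), "n_turns")
  expect_error(measurement_table(df), "b")
})

test_that("metadata reader normalises missing categoricals to unknown", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(specimen_id = c("a", "b"), species = c("x", NA),
                       side = c("left", ""), cbl_mm = c(280, NA)),
            f, row.names = FALSE)
  md <- read_metadata(f)
  expect_equal(md$species[2], "unknown")
  expect_equal(md$side[2], "unknown")
  expect_equal(md$sex, c("unknown", "unknown"))
  expect_true(is.na(md$cbl_mm[2]))
})
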