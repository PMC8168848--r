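grid44 <- function(cell = 25000) build_grid(c(0, 0, 4 * cell, 4 * cell),
                                            cell_size = cell)

test_that("build_grid covers the extent with snapped origin and ceiling division", {
  g <- build_grid(c(0, 0, 100000, 75000), cell_size = 25000)
  expect_equal(c(g$n_rows, g$n_cols), c(3L, 4L))
  expect_equal(squamataxa:::n_cells(g), 12L)
  # padding: 60 km extent needs 3 cells of 25 km
  g2 <- build_grid(c(0, 0, 60000, 60000), cell_size = 25000)
  expect_equal(c(g2$n_rows, g2$n_cols), c(3L, 3L))
  # origin snaps down to a multiple of the cell size
  g3 <- build_grid(c(30000, 55000, 80000, 95000), cell_size = 25000)
  expect_equal(c(g3$x0, g3$y0), c(25000, 50000))
  expect_error(build_grid(c(0, 0, 1000, 1000), cell_size = 0), "positive")
  expect_error(build_grid(c(0, 0, 0, 1000), cell_size = 10), "degenerate")
  expect_error(build_grid(c(0, 0, 10, 10), cell_size = 1, crs = "EPSG:4326"),
               "metric")
})

test_that("occupancy follows the positive-area intersection rule", {
  g <- grid44()
  # polygon strictly inside cell (row 2, col 2) -> exactly that cell
  inside <- rect_range("a", 30000, 30000, 40000, 40000)
  expect_equal(cells_occupied(inside, g), squamataxa:::cell_id(2L, 2L, g))
  # square straddling the shared edge of two cells -> both
  straddle <- rect_range("b", 20000, 5000, 30000, 15000)
  expect_equal(cells_occupied(straddle, g),
               sort(c(squamataxa:::cell_id(1L, 1L, g),
                      squamataxa:::cell_id(1L, 2L, g))))
  # polygon touching a cell only along its boundary -> excluded
  touch <- rect_range("c", 25000, 25000, 50000, 50000)  # exactly cell (2,2)
  expect_equal(cells_occupied(touch, g), squamataxa:::cell_id(2L, 2L, g))
  expect_error(cells_occupied(rect_range("d", 0, 0, 1, 1), grid44(1000),
                              rule = "nope"))
})

test_that("centroid rule assigns a range to a single cell", {
  g <- grid44()
  big <- rect_range("a", 10000, 10000, 60000, 45000)  # centroid (35, 27.5) km
  expect_equal(cells_occupied(big, g, rule = "centroid"),
               squamataxa:::cell_id(2L, 2L, g))
  expect_true(length(cells_occupied(big, g)) > 1)
})

test_that("occupancy matches the exact rectangle oracle over random cases", {
  g <- build_grid(c(0, 0, 12 * 5000, 12 * 5000), cell_size = 5000)
  set.seed(11)
  for (i in 1:25) {
    x <- sort(runif(2, -5000, 65000)); y <- sort(runif(2, -5000, 65000))
    if (diff(x) < 1 || diff(y) < 1) next
    r <- rect_range(paste0("sp", i), x[1], y[1], x[2], y[2])
    expect_equal(cells_occupied(r, g),
                 rect_cells_oracle(x[1], y[1], x[2], y[2], g),
                 info = paste("case", i))
  }
})

test_that("richness adds over species and is zero for empty input", {
  g <- grid44()
  r1 <- rect_range("a", 30000, 30000, 40000, 40000)
  r2 <- rect_range("b", 30000, 30000, 40000, 40000)
  rich <- richness_map(list(r1, r2), g)
  expect_equal(as.matrix(rich)[2, 2], 2)
  expect_equal(sum(as.matrix(rich)), 2)
  expect_equal(sum(as.matrix(richness_map(list(), g))), 0)
  expect_error(richness_map(list(r1, r1), g), "duplicate species_id")
  # double-counting identity
  rngs <- list(r1, rect_range("c", 10000, 10000, 90000, 20000))
  rich2 <- richness_map(rngs, g)
  expect_equal(sum(as.matrix(rich2)),
               sum(vapply(rngs, function(r) length(cells_occupied(r, g)),
                          integer(1))))
})

test_that("mean surface is the per-cell score average, nodata when empty", {
  g <- grid44()
  rngs <- lapply(1:4, function(i)
    rect_range(paste0("sp", i), 30000, 30000, 40000, 40000))
  # binary concern scores -> proportion
  m <- mean_score_map(c(sp1 = 1, sp2 = 0, sp3 = 0, sp4 = 1), rngs, g)
  expect_equal(as.matrix(m)[2, 2], 0.5)
  expect_true(all(is.na(as.matrix(m)[-6])))  # cell (2,2) is entry 6 col-major
  # constancy: shared score s -> mean s
  m2 <- mean_score_map(c(sp1 = 2.5, sp2 = 2.5, sp3 = 2.5, sp4 = 2.5), rngs, g)
  expect_equal(as.matrix(m2)[2, 2], 2.5)
  # sum layer
  s <- sum_score_map(c(sp1 = 1, sp2 = 0, sp3 = 0, sp4 = 1), rngs, g)
  expect_equal(as.matrix(s)[2, 2], 2)
  # a scored species without a range is an error naming it
  expect_error(mean_score_map(c(sp1 = 1, ghost = 2), rngs[1], g), "ghost")
})

test_that("mean values lie within the range of scores present in the cell", {
  cfg <- synthetic_config(n_species = 30, seed = 5,
                          extent = c(0, 0, 500000, 500000),
                          range_area_log_mean = 8, range_area_log_sd = 1)
  ids <- sprintf("sp%02d", 1:30)
  rngs <- generate_ranges(cfg, ids)
  scores <- stats::setNames(runif(30, 0, 4), ids)
  g <- build_grid(cfg$extent, 50000)
  m <- as.matrix(mean_score_map(scores, rngs, g))
  expect_true(all(m >= min(scores) - 1e-12 & m <= max(scores) + 1e-12,
                  na.rm = TRUE))
})

test_that("square-root transform fixes 0 and 1, preserves order and nodata", {
  g <- grid44()
  rngs <- list(rect_range("a", 5000, 5000, 15000, 15000),
               rect_range("b", 30000, 30000, 40000, 40000))
  m <- mean_score_map(c(a = 1, b = 11 / 6), rngs, g)
  sq <- sqrt_transform(m)
  expect_equal(as.matrix(sq)[1, 1], 1)
  expect_equal(as.matrix(sq)[2, 2], sqrt(11 / 6))
  expect_equal(round(as.matrix(sq)[2, 2], 4), 1.3540)
  expect_identical(is.na(as.matrix(sq)), is.na(as.matrix(m)))
  # all-ones layer is a fixed point of repeated transformation
  ones <- mean_score_map(c(a = 1, b = 1), rngs, g)
  twice <- sqrt_transform(sqrt_transform(ones))
  expect_equal(as.matrix(twice), as.matrix(ones))
  # order preservation
  expect_true(as.matrix(sq)[2, 2] > as.matrix(sq)[1, 1])
  # negatives rejected
  neg <- mean_score_map(c(a = -1, b = 1), rngs, g)
  expect_error(sqrt_transform(neg), "negative")
})

test_that("halving the cell size never shrinks the occupied-cell count", {
  cfg <- synthetic_config(n_species = 10, seed = 9,
                          extent = c(0, 0, 400000, 400000),
                          range_area_log_mean = 8, range_area_log_sd = 1)
  rngs <- generate_ranges(cfg, sprintf("sp%02d", 1:10))
  for (r in rngs) {
    g1 <- build_grid(cfg$extent, 50000)
    g2 <- build_grid(cfg$extent, 25000)
    expect_gte(length(cells_occupied(r, g2)), length(cells_occupied(r, g1)))
  }
})

test_that("island subgrids equal the plain 1 km pipeline on the same extent", {
  ext <- c(0, 0, 20000, 20000)
  rngs <- list(rect_range("a", 2000, 2000, 6000, 5000),
               rect_range("b", 3000, 3000, 12000, 9000))
  scores <- c(a = 3, b = 1)
  isl <- island_subgrid_analysis(rngs, scores,
                                 island_extents = list(lord_howe = ext))
  g <- build_grid(ext, cell_size = 1000)
  expect_equal(as.matrix(isl$lord_howe$richness),
               as.matrix(richness_map(rngs, g)))
  expect_equal(as.matrix(isl$lord_howe$mean),
               as.matrix(mean_score_map(scores, rngs, g)))
  expect_equal(as.matrix(isl$lord_howe$sqrt_mean),
               sqrt(as.matrix(mean_score_map(scores, rngs, g))))
  # single-species island: richness 1, mean = that score
  solo <- island_subgrid_analysis(rngs[1], scores[1],
                                  island_extents = list(x = ext))
  expect_equal(max(as.matrix(solo$x$richness)), 1)
  expect_equal(unique(stats::na.omit(c(as.matrix(solo$x$mean)))), 3)
  # no ranges in extent -> all nodata mean
  far <- island_subgrid_analysis(rngs, scores,
    island_extents = list(empty = c(1e6, 1e6, 1.02e6, 1.02e6)))
  expect_true(all(is.na(as.matrix(far$empty$mean))))
})

test_that("geojson ranges round-trip and lon/lat input is projected equal-area", {
  skip_if_not_installed("geosphere")
  # planar round trip
  rngs <- list(rect_range("a", 0, 0, 30000, 20000),
               rect_range("b", 5000, 5000, 9000, 9000))
  path <- tempfile(fileext = ".geojson")
  write_ranges(rngs, path)
  back <- read_ranges(path, crs = "EPSG:3577")
  expect_equal(vapply(back, `[[`, "", "species_id"), c("a", "b"))
  expect_equal(vapply(back, range_area_km2, numeric(1)),
               vapply(rngs, range_area_km2, numeric(1)))
  # lon/lat quad projects with its ellipsoidal area preserved
  lon <- c(146, 147, 147, 146); lat <- c(-43, -43, -42, -42)
  r <- range_map("tas", cbind(lon, lat), crs = "EPSG:4326")
  a_ref <- geosphere::areaPolygon(cbind(lon, lat)) / 1e6
  expect_equal(range_area_km2(r), a_ref, tolerance = 1e-3)
  expect_equal(r$crs, "EPSG:3577")
})

test_that("raster exports carry cell values and georeferencing", {
  g <- build_grid(c(0, 0, 3000, 2000), cell_size = 1000)
  rngs <- list(rect_range("a", 100, 100, 900, 900))
  m <- mean_score_map(c(a = 2), rngs, g)
  csv <- tempfile(fileext = ".csv")
  write_raster_csv(m, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 6)
  expect_equal(df$value[df$row == 1 & df$col == 1], 2)
  asc <- tempfile(fileext = ".asc")
  write_raster_asc(m, asc)
  lines <- readLines(asc)
  expect_match(lines[1], "ncols 3")
  expect_match(lines[6], "NODATA_value -9999")
  last <- as.numeric(strsplit(lines[8], " ")[[1]])  # bottom row written last
  expect_equal(last[1], 2)
})
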