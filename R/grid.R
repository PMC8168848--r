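## Equal-area gridding and per-cell aggregation -------------------------------

# CRS identifiers we refuse as grid CRSs: geographic (degree) systems.
is_geographic_crs <- function(crs) {
  normalize_label(crs) %in%
    c("epsg:4326", "wgs84", "epsg:4283", "gda94", "epsg:4019", "lonlat",
      "longlat")
}

#' Build an equal-area grid specification
#'
#' Defines a regular grid of square cells in a projected, equal-area, metric
#' CRS. Cell `(i, j)` (row `i` from the bottom, column `j` from the left,
#' 1-based) covers the half-open square
#' `[x0 + (j-1) s, x0 + j s) x [y0 + (i-1) s, y0 + i s)`.
#' The origin is snapped down to an integer multiple of the cell size from
#' the CRS origin so that grids built from different extents align, and the
#' grid is extended by ceiling division to cover the extent fully.
#'
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in CRS units (meters).
#' @param cell_size cell edge length in meters; default 25 km as used for
#'   continental mapping (1 km for island subgrids).
#' @param crs CRS identifier; must be metric (degrees are rejected).
#' @return object of class `grid_spec`.
#' @export
build_grid <- function(extent, cell_size = 25000, crs = "EPSG:3577") {
  stopifnot(length(extent) == 4)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a positive length in meters", call. = FALSE)
  if (is_geographic_crs(crs))
    stop("grid CRS must be metric and equal-area; got geographic '",
         crs, "'", call. = FALSE)
  xmin <- extent[1]; ymin <- extent[2]; xmax <- extent[3]; ymax <- extent[4]
  if (!(xmax > xmin && ymax > ymin))
    stop("degenerate extent", call. = FALSE)
  s <- cell_size
  x0 <- floor(xmin / s) * s
  y0 <- floor(ymin / s) * s
  eps <- s * 1e-9
  n_cols <- as.integer(ceiling((xmax - x0) / s - eps))
  n_rows <- as.integer(ceiling((ymax - y0) / s - eps))
  structure(list(crs = crs, cell_size = s, x0 = x0, y0 = y0,
                 n_rows = n_rows, n_cols = n_cols),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g km [%s], origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size / 1000, x$crs, x$x0, x$y0))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

# cell id <-> (row, col); id = (row-1)*n_cols + col, row 1 = bottom.
cell_id <- function(row, col, grid) (row - 1L) * grid$n_cols + col
cell_rowcol <- function(id, grid) {
  row <- (id - 1L) %/% grid$n_cols + 1L
  col <- (id - 1L) %% grid$n_cols + 1L
  cbind(row = row, col = col)
}

cell_bounds <- function(row, col, grid) {
  s <- grid$cell_size
  c(xmin = grid$x0 + (col - 1) * s, ymin = grid$y0 + (row - 1) * s,
    xmax = grid$x0 + col * s, ymax = grid$y0 + row * s)
}

#' Grid cells occupied by a species range
#'
#' Under the default `"any_intersection"` rule a cell is occupied iff the
#' range geometry intersects the cell's interior with positive area (a range
#' merely touching a cell boundary does not occupy it). The alternative
#' `"centroid"` rule assigns the range to the single cell containing its
#' area-weighted centroid.
#'
#' @param range a [range_map()] in the grid's CRS.
#' @param grid a [build_grid()] specification.
#' @param rule occupancy rule.
#' @return sorted integer vector of occupied cell ids
#'   (`id = (row - 1) * n_cols + col`, row 1 at the bottom).
#' @export
cells_occupied <- function(range, grid,
                           rule = c("any_intersection", "centroid")) {
  rule <- match.arg(rule)
  stopifnot(inherits(range, "range_map"), inherits(grid, "grid_spec"))
  if (!identical(range$crs, grid$crs))
    stop("range CRS (", range$crs, ") differs from grid CRS (", grid$crs,
         ")", call. = FALSE)
  if (length(range$geometry) == 0)
    stop("empty geometry for species ", range$species_id, call. = FALSE)
  s <- grid$cell_size

  if (rule == "centroid") {
    cen <- geometry_centroid(range$geometry)
    col <- floor((cen[1] - grid$x0) / s) + 1L
    row <- floor((cen[2] - grid$y0) / s) + 1L
    if (row < 1 || row > grid$n_rows || col < 1 || col > grid$n_cols)
      return(integer(0))
    return(cell_id(as.integer(row), as.integer(col), grid))
  }

  tol <- max(s * s * 1e-12, 1e-6)
  occupied <- integer(0)
  bb <- geometry_bbox(range$geometry)
  c_lo <- max(1L, as.integer(floor((bb[1] - grid$x0) / s)) + 1L)
  c_hi <- min(grid$n_cols, as.integer(floor((bb[3] - grid$x0) / s)) + 1L)
  r_lo <- max(1L, as.integer(floor((bb[2] - grid$y0) / s)) + 1L)
  r_hi <- min(grid$n_rows, as.integer(floor((bb[4] - grid$y0) / s)) + 1L)
  if (c_lo > c_hi || r_lo > r_hi) return(integer(0))
  for (row in r_lo:r_hi) {
    for (col in c_lo:c_hi) {
      b <- cell_bounds(row, col, grid)
      a <- geometry_rect_area(range$geometry, b["xmin"], b["ymin"],
                              b["xmax"], b["ymax"])
      if (a > tol) occupied <- c(occupied, cell_id(row, col, grid))
    }
  }
  sort(occupied)
}

## Score rasters --------------------------------------------------------------

new_score_raster <- function(grid, values, kind) {
  stopifnot(inherits(grid, "grid_spec"),
            kind %in% c("richness", "sum", "mean", "sqrt_mean"))
  structure(list(grid = grid, values = values, kind = kind, nodata = NA_real_),
            class = "score_raster")
}

#' @export
print.score_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "score_raster [%s]: %d x %d cells, %d with data, range [%s, %s]\n",
    x$kind, x$grid$n_rows, x$grid$n_cols, length(v),
    if (length(v)) format(min(v)) else "-",
    if (length(v)) format(max(v)) else "-"))
  invisible(x)
}

#' @export
as.matrix.score_raster <- function(x, ...) x$values

#' @export
plot.score_raster <- function(x, ...) {
  g <- x$grid
  xs <- g$x0 + (seq_len(g$n_cols) - 0.5) * g$cell_size
  ys <- g$y0 + (seq_len(g$n_rows) - 0.5) * g$cell_size
  graphics::image(xs, ys, t(x$values), xlab = "x (m)", ylab = "y (m)",
                  main = x$kind, useRaster = TRUE, ...)
  invisible(x)
}

# Internal: per-cell accumulation of counts and score sums over ranges.
accumulate_cells <- function(ranges, grid, rule, scores = NULL) {
  ids <- vapply(ranges, `[[`, "", "species_id")
  if (anyDuplicated(ids))
    stop("duplicate species_id among ranges: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  count <- matrix(0L, grid$n_rows, grid$n_cols)
  ssum <- matrix(0, grid$n_rows, grid$n_cols)
  for (r in ranges) {
    occ <- cells_occupied(r, grid, rule = rule)
    if (length(occ) == 0) next
    rc <- cell_rowcol(occ, grid)
    idx <- cbind(rc[, "row"], rc[, "col"])
    count[idx] <- count[idx] + 1L
    if (!is.null(scores)) ssum[idx] <- ssum[idx] + scores[[r$species_id]]
  }
  list(count = count, ssum = ssum)
}

#' Species-richness surface
#'
#' Number of species whose range occupies each grid cell. Cells touched by
#' no range hold 0 (richness is a true count, unlike the mean layers where
#' an empty cell is nodata).
#'
#' @param ranges list of [range_map()] objects with unique species ids.
#' @param grid a [build_grid()] specification.
#' @param rule occupancy rule passed to [cells_occupied()].
#' @return `score_raster` of kind `"richness"`.
#' @export
richness_map <- function(ranges, grid, rule = "any_intersection") {
  acc <- accumulate_cells(ranges, grid, rule)
  new_score_raster(grid, acc$count, "richness")
}

# shared checks for the score layers
check_scores_ranges <- function(scores, ranges) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  ids <- vapply(ranges, `[[`, "", "species_id")
  missing <- setdiff(names(scores), ids)
  if (length(missing) > 0)
    stop("scored species lacking a range: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ranges[match(names(scores), ids)]
}

#' Per-cell weighted-mean score surface
#'
#' Each cell holds the sum of the scores of the species present divided by
#' the number of species present — a richness-adjusted cell score (e.g. if a
#' cell holds 6 species with ROI scores 1, 1, 1, 1, 3 and 4, its weighted
#' mean is 11/6 = 1.83). Cells with no species are nodata (`NA`), not 0,
#' since 0 is a meaningful score.
#'
#' @param scores named numeric vector, `species_id -> score`; every scored
#'   species must have a range.
#' @inheritParams richness_map
#' @return `score_raster` of kind `"mean"`.
#' @export
mean_score_map <- function(scores, ranges, grid, rule = "any_intersection") {
  ranges <- check_scores_ranges(scores, ranges)
  acc <- accumulate_cells(ranges, grid, rule, scores = scores)
  vals <- ifelse(acc$count > 0, acc$ssum / acc$count, NA_real_)
  new_score_raster(grid, vals, "mean")
}

#' Per-cell score-sum surface
#'
#' Sum of the scores of species present in each cell; nodata where no
#' species occurs.
#'
#' @inheritParams mean_score_map
#' @return `score_raster` of kind `"sum"`.
#' @export
sum_score_map <- function(scores, ranges, grid, rule = "any_intersection") {
  ranges <- check_scores_ranges(scores, ranges)
  acc <- accumulate_cells(ranges, grid, rule, scores = scores)
  vals <- ifelse(acc$count > 0, acc$ssum, NA_real_)
  new_score_raster(grid, vals, "sum")
}

#' Square-root transform of a mean-score surface
#'
#' Element-wise square root, used to damp the influence of a small number of
#' extreme high-scoring cells on the mapped mean-ROI surface. Nodata cells
#' are preserved; negative values are an error.
#'
#' @param raster a `score_raster` with non-negative values.
#' @return `score_raster` of kind `"sqrt_mean"`.
#' @export
sqrt_transform <- function(raster) {
  stopifnot(inherits(raster, "score_raster"))
  v <- raster$values
  if (any(v < 0, na.rm = TRUE))
    stop("negative cell value; square-root transform undefined", call. = FALSE)
  new_score_raster(raster$grid, sqrt(v), "sqrt_mean")
}

#' Fine-scale island subgrid analysis
#'
#' Repeats the richness / weighted-mean / square-root-mean products on named
#' island extents at a finer resolution (default 1 km), as used for the Lord
#' Howe and Norfolk Island groups where a 25 km continental grid is too
#' coarse to resolve geographic pattern.
#'
#' @param ranges list of [range_map()] objects.
#' @param scores named numeric score vector (see [mean_score_map()]).
#' @param island_extents named list of `c(xmin, ymin, xmax, ymax)` extents.
#' @param cell_size cell edge in meters, default 1,000.
#' @param crs grid CRS.
#' @param rule occupancy rule.
#' @return named list; per island a list with `richness`, `mean` and
#'   `sqrt_mean` rasters.
#' @export
island_subgrid_analysis <- function(ranges, scores, island_extents,
                                    cell_size = 1000, crs = "EPSG:3577",
                                    rule = "any_intersection") {
  stopifnot(is.list(island_extents), length(island_extents) > 0,
            !is.null(names(island_extents)))
  out <- lapply(island_extents, function(ext) {
    grid <- build_grid(ext, cell_size = cell_size, crs = crs)
    keep <- names(scores)
    mean_r <- mean_score_map(scores, ranges, grid, rule = rule)
    ids <- vapply(ranges, `[[`, "", "species_id")
    list(richness = richness_map(ranges[ids %in% keep], grid, rule = rule),
         mean = mean_r,
         sqrt_mean = sqrt_transform(mean_r))
  })
  names(out) <- names(island_extents)
  out
}

## Raster export --------------------------------------------------------------

#' Write a score raster as long-format CSV
#'
#' One row per cell: `row`, `col`, `cell_x`, `cell_y` (cell centers),
#' `layer`, `value`. Nodata cells are written with an empty value.
#'
#' @param raster a `score_raster`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  g <- raster$grid
  idx <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  df <- data.frame(
    row = idx$row, col = idx$col,
    cell_x = g$x0 + (idx$col - 0.5) * g$cell_size,
    cell_y = g$y0 + (idx$row - 0.5) * g$cell_size,
    layer = raster$kind,
    value = raster$values[cbind(idx$row, idx$col)])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a score raster as an ESRI ASCII grid (.asc)
#'
#' Plain-text georeferenced raster readable by standard GIS software.
#'
#' @inheritParams write_raster_csv
#' @param nodata nodata sentinel written to the file (default -9999).
#' @return `path`, invisibly.
#' @export
write_raster_asc <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  v <- raster$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.6f", g$x0),
    sprintf("yllcorner %.6f", g$y0),
    sprintf("cellsize %.6f", g$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  # .asc rows run top to bottom
  for (row in rev(seq_len(g$n_rows)))
    writeLines(paste(format(v[row, ], trim = TRUE), collapse = " "), con)
  invisible(path)
}
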