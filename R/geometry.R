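## Planar polygon primitives -------------------------------------------------
##
## The spatial layer works on simple planar polygons in a projected,
## equal-area, metric CRS. Rings are n x 2 coordinate matrices (not closed;
## the closing edge is implicit). A polygon is a list(outer = ring,
## holes = list of rings); a geometry is a list of such polygons
## (multipolygon). Only the operations the gridding needs are implemented:
## signed area, centroid, clipping against an axis-aligned rectangle.

# Signed shoelace area of one ring (positive = counter-clockwise).
ring_signed_area <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Area of a polygon-with-holes, in CRS units^2 (holes subtract).
polygon_area <- function(poly) {
  a <- abs(ring_signed_area(poly$outer))
  if (length(poly$holes) > 0)
    a <- a - sum(vapply(poly$holes, function(h) abs(ring_signed_area(h)),
                        numeric(1)))
  max(a, 0)
}

geometry_area <- function(geom) {
  sum(vapply(geom, polygon_area, numeric(1)))
}

# Sutherland-Hodgman clip of a ring against the rectangle
# [xmin, xmax] x [ymin, ymax]. Returns a ring matrix (possibly < 3 rows).
clip_ring_rect <- function(ring, xmin, ymin, xmax, ymax) {
  clip_halfplane <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    out
  }
  lerp_x <- function(p, q, x0) {
    t <- (x0 - p[1]) / (q[1] - p[1])
    c(x0, p[2] + t * (q[2] - p[2]))
  }
  lerp_y <- function(p, q, y0) {
    t <- (y0 - p[2]) / (q[2] - p[2])
    c(p[1] + t * (q[1] - p[1]), y0)
  }
  r <- ring
  r <- clip_halfplane(r, function(p) p[1] >= xmin,
                      function(p, q) lerp_x(p, q, xmin))
  r <- clip_halfplane(r, function(p) p[1] <= xmax,
                      function(p, q) lerp_x(p, q, xmax))
  r <- clip_halfplane(r, function(p) p[2] >= ymin,
                      function(p, q) lerp_y(p, q, ymin))
  r <- clip_halfplane(r, function(p) p[2] <= ymax,
                      function(p, q) lerp_y(p, q, ymax))
  r
}

# Area of geometry intersected with a rectangle.
geometry_rect_area <- function(geom, xmin, ymin, xmax, ymax) {
  total <- 0
  for (poly in geom) {
    a <- abs(ring_signed_area(clip_ring_rect(poly$outer, xmin, ymin,
                                             xmax, ymax)))
    if (length(poly$holes) > 0)
      a <- a - sum(vapply(poly$holes, function(h)
        abs(ring_signed_area(clip_ring_rect(h, xmin, ymin, xmax, ymax))),
        numeric(1)))
    total <- total + max(a, 0)
  }
  total
}

# Area-weighted centroid of a geometry (holes subtract).
geometry_centroid <- function(geom) {
  cx <- 0; cy <- 0; atot <- 0
  ring_cent <- function(ring, sign) {
    n <- nrow(ring)
    x <- ring[, 1]; y <- ring[, 2]
    j <- c(n, seq_len(n - 1))
    cross <- x[j] * y - x * y[j]
    a <- sum(cross) / 2
    if (abs(a) < .Machine$double.eps) return(NULL)
    list(a = sign * abs(a),
         gx = sum((x[j] + x) * cross) / (6 * a),
         gy = sum((y[j] + y) * cross) / (6 * a))
  }
  for (poly in geom) {
    rc <- ring_cent(poly$outer, 1)
    if (!is.null(rc)) {
      cx <- cx + rc$a * rc$gx; cy <- cy + rc$a * rc$gy; atot <- atot + rc$a
    }
    for (h in poly$holes) {
      rc <- ring_cent(h, -1)
      if (!is.null(rc)) {
        cx <- cx + rc$a * rc$gx; cy <- cy + rc$a * rc$gy; atot <- atot + rc$a
      }
    }
  }
  if (atot <= 0) stop("degenerate geometry: zero area", call. = FALSE)
  c(cx / atot, cy / atot)
}

# Bounding box over all rings: c(xmin, ymin, xmax, ymax).
geometry_bbox <- function(geom) {
  xs <- unlist(lapply(geom, function(p) p$outer[, 1]))
  ys <- unlist(lapply(geom, function(p) p$outer[, 2]))
  c(min(xs), min(ys), max(xs), max(ys))
}

## Albers equal-area projection ----------------------------------------------

#' Project longitude/latitude to Australian Albers (EPSG:3577)
#'
#' Forward ellipsoidal Albers equal-area conic projection on the GRS80
#' ellipsoid with the EPSG:3577 parameters (standard parallels -18 and -36,
#' central meridian 132 E, latitude of origin 0, false easting/northing 0).
#' Used to bring geographic range polygons supplied in lon/lat into the
#' metric equal-area CRS the gridding requires.
#'
#' @param lon,lat numeric vectors of degrees.
#' @return two-column matrix of easting/northing in meters.
#' @references Snyder, J.P. (1987) Map Projections: A Working Manual,
#'   USGS Professional Paper 1395, pp. 101-102.
#' @export
albers_project <- function(lon, lat) {
  a <- 6378137
  e2 <- 0.00669438002290
  e <- sqrt(e2)
  rad <- pi / 180
  phi1 <- -18 * rad; phi2 <- -36 * rad; phi0 <- 0; lam0 <- 132 * rad

  qf <- function(phi) {
    s <- sin(phi)
    (1 - e2) * (s / (1 - e2 * s^2) - (1 / (2 * e)) *
                  log((1 - e * s) / (1 + e * s)))
  }
  mf <- function(phi) cos(phi) / sqrt(1 - e2 * sin(phi)^2)

  m1 <- mf(phi1); m2 <- mf(phi2)
  q1 <- qf(phi1); q2 <- qf(phi2); q0 <- qf(phi0)
  n <- (m1^2 - m2^2) / (q2 - q1)
  C <- m1^2 + n * q1
  rho0 <- a * sqrt(C - n * q0) / n

  phi <- lat * rad
  lam <- lon * rad
  rho <- a * sqrt(C - n * qf(phi)) / n
  theta <- n * (lam - lam0)
  cbind(x = rho * sin(theta), y = rho0 - rho * cos(theta))
}

## Range maps -----------------------------------------------------------------

#' Construct a species range map
#'
#' Binds a species identifier to a polygonal geographic range in a stated
#' planar equal-area CRS. Coordinates supplied in lon/lat (`crs =
#' "EPSG:4326"`) are reprojected to Australian Albers via [albers_project()].
#' A geometry with zero total area is an error.
#'
#' @param species_id species identifier.
#' @param geometry a single ring matrix, or a list of polygons, each
#'   `list(outer = <n x 2 matrix>, holes = <list of matrices>)`.
#' @param crs CRS identifier of the supplied coordinates; `"EPSG:4326"`
#'   triggers reprojection, any other value is taken to be planar meters.
#' @return object of class `range_map`: list with `species_id`, `geometry`
#'   (planar), `crs` (always the planar target) and `area_km2`.
#' @export
range_map <- function(species_id, geometry, crs = "EPSG:3577") {
  if (is.matrix(geometry)) geometry <- list(list(outer = geometry,
                                                 holes = list()))
  stopifnot(is.list(geometry), length(geometry) > 0)
  geometry <- lapply(geometry, function(p) {
    if (is.matrix(p)) p <- list(outer = p, holes = list())
    if (is.null(p$holes)) p$holes <- list()
    p
  })
  if (identical(crs, "EPSG:4326") || identical(crs, "WGS84")) {
    geometry <- lapply(geometry, function(p) {
      p$outer <- albers_project(p$outer[, 1], p$outer[, 2])
      p$holes <- lapply(p$holes, function(h) albers_project(h[, 1], h[, 2]))
      p
    })
    crs <- "EPSG:3577"
  }
  area_m2 <- geometry_area(geometry)
  if (!is.finite(area_m2) || area_m2 <= 0)
    stop("range geometry for '", species_id, "' has zero area", call. = FALSE)
  structure(list(species_id = as.character(species_id), geometry = geometry,
                 crs = crs, area_km2 = area_m2 / 1e6),
            class = "range_map")
}

#' @export
print.range_map <- function(x, ...) {
  cat(sprintf("range_map '%s': %d polygon(s), %.1f km2 [%s]\n",
              x$species_id, length(x$geometry), x$area_km2, x$crs))
  invisible(x)
}

#' Range area in square kilometers
#' @param x a `range_map`.
#' @return numeric area in km^2.
#' @export
range_area_km2 <- function(x) {
  stopifnot(inherits(x, "range_map"))
  x$area_km2
}

## GeoJSON I/O ----------------------------------------------------------------

#' Read species ranges from a GeoJSON FeatureCollection
#'
#' One feature per species with a `species_id` property; `Polygon` and
#' `MultiPolygon` geometries are supported. Per the GeoJSON specification,
#' coordinates are assumed to be lon/lat (WGS84) unless `crs` says they are
#' already planar; lon/lat input is reprojected to Australian Albers.
#'
#' @param path GeoJSON file path.
#' @param crs CRS of the file's coordinates (default `"EPSG:4326"`).
#' @param id_property property name holding the species identifier.
#' @return list of [range_map()] objects.
#' @export
read_ranges <- function(path, crs = "EPSG:4326", id_property = "species_id") {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  lapply(gj$features, function(f) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature missing property '", id_property, "'",
                          call. = FALSE)
    coords_ring <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    polys <- switch(f$geometry$type,
      Polygon = list(f$geometry$coordinates),
      MultiPolygon = f$geometry$coordinates,
      stop("unsupported geometry type: ", f$geometry$type, call. = FALSE))
    geometry <- lapply(polys, function(rings) {
      rings <- lapply(rings, coords_ring)
      # drop the GeoJSON closing vertex
      rings <- lapply(rings, function(r)
        if (nrow(r) > 1 && all(r[1, ] == r[nrow(r), ])) r[-nrow(r), , drop = FALSE] else r)
      list(outer = rings[[1]],
           holes = if (length(rings) > 1) rings[-1] else list())
    })
    range_map(id, geometry, crs = crs)
  })
}

#' Write species ranges to a GeoJSON FeatureCollection
#'
#' Coordinates are written as stored (planar meters); the CRS is recorded in
#' a top-level `crs_note` member since modern GeoJSON has no CRS slot.
#'
#' @param ranges list of `range_map` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranges <- function(ranges, path) {
  features <- lapply(ranges, function(r) {
    polys <- lapply(r$geometry, function(p) {
      rings <- c(list(p$outer), p$holes)
      lapply(rings, function(ring) {
        ring <- rbind(ring, ring[1, , drop = FALSE])
        lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
      })
    })
    list(type = "Feature",
         properties = list(species_id = r$species_id,
                           area_km2 = r$area_km2),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  obj <- list(type = "FeatureCollection",
              crs_note = unique(vapply(ranges, `[[`, "", "crs")),
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
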