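# Planar polygon primitives. All coordinates are kilometres in a projected
# (Euclidean) plane; no geodesy is performed anywhere in the package.

#' Coerce a polygon specification to a vertex matrix
#'
#' Accepts a two-column matrix or data frame of vertices (open or closed
#' ring), or a list with components `x` and `y`. Returns an open ring
#' (first vertex not repeated) as a two-column matrix.
#'
#' @param poly polygon specification.
#' @return numeric matrix with columns `x`, `y`.
#' @export
as_polygon <- function(poly) {
  if (is.list(poly) && !is.data.frame(poly) && all(c("x", "y") %in% names(poly)))
    poly <- cbind(x = poly$x, y = poly$y)
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    stop("a polygon needs a two-column matrix with at least 3 vertices")
  storage.mode(poly) <- "double"
  if (anyNA(poly)) stop("polygon vertices must be finite")
  # drop a repeated closing vertex
  n <- nrow(poly)
  if (all(poly[1L, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3L) stop("polygon degenerate after closing-vertex removal")
  colnames(poly) <- c("x", "y")
  poly
}

#' Polygon area by the shoelace formula
#'
#' @param poly polygon specification (see [as_polygon()]).
#' @return area in squared coordinate units (km^2).
#' @export
polygon_area <- function(poly) {
  p <- as_polygon(poly)
  x <- p[, 1L]; y <- p[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

#' Point-in-polygon test (ray casting)
#'
#' Vectorised over points. Points exactly on an edge are treated as inside
#' for one crossing direction; mask construction does not rely on boundary
#' points because lattice centres are offset by half a cell.
#'
#' @param x,y point coordinates (km).
#' @param poly polygon specification.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  p <- as_polygon(poly)
  px <- p[, 1L]; py <- p[, 2L]
  n <- nrow(p)
  jx <- c(px[n], px[-n]); jy <- c(py[n], py[-n])
  inside <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    cross <- ((py[k] > y) != (jy[k] > y)) &
      (x < (jx[k] - px[k]) * (y - py[k]) / (jy[k] - py[k]) + px[k])
    inside <- xor(inside, cross)
  }
  inside
}

# distance from points to a segment (a,b); vectorised over points
.dist_to_segment <- function(x, y, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((x - ax)^2 + (y - ay)^2))
  t <- pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
  sqrt((x - (ax + t * dx))^2 + (y - (ay + t * dy))^2)
}

#' Distance from points to a polygon
#'
#' Zero for points inside the polygon, otherwise the Euclidean distance to
#' the nearest boundary segment.
#'
#' @param x,y point coordinates (km).
#' @param poly polygon specification.
#' @return numeric vector of distances (km).
#' @export
dist_to_polygon <- function(x, y, poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  d <- rep(Inf, length(x))
  for (k in seq_len(n)) {
    j <- if (k == n) 1L else k + 1L
    d <- pmin(d, .dist_to_segment(x, y, p[k, 1L], p[k, 2L], p[j, 1L], p[j, 2L]))
  }
  d[point_in_polygon(x, y, p)] <- 0
  d
}

#' Axis-aligned square polygon of a given area
#'
#' Convenience constructor for simulated reserves: a square fence of area
#' `area_km2` with its lower-left corner at `origin`.
#'
#' @param area_km2 reserve area in km^2.
#' @param origin length-2 numeric, lower-left corner (km).
#' @return vertex matrix.
#' @export
square_fence <- function(area_km2, origin = c(0, 0)) {
  stopifnot(is.numeric(area_km2), length(area_km2) == 1L, area_km2 > 0)
  s <- sqrt(area_km2)
  cbind(x = origin[1L] + c(0, s, s, 0), y = origin[2L] + c(0, 0, s, s))
}

#' Read polygons from a GeoJSON file
#'
#' Reads the first (or all) Polygon geometries from a GeoJSON Feature,
#' FeatureCollection or bare geometry. Only the exterior ring is used;
#' coordinates are taken as planar kilometres.
#'
#' @param path file path.
#' @return list of vertex matrices.
#' @export
read_fence_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- list()
  grab <- function(geom) {
    if (is.null(geom$type)) return()
    if (geom$type == "Polygon") {
      ring <- geom$coordinates[[1L]]
      m <- do.call(rbind, lapply(ring, function(v) c(v[[1L]], v[[2L]])))
      polys[[length(polys) + 1L]] <<- as_polygon(m)
    } else if (geom$type == "MultiPolygon") {
      for (pp in geom$coordinates) {
        m <- do.call(rbind, lapply(pp[[1L]], function(v) c(v[[1L]], v[[2L]])))
        polys[[length(polys) + 1L]] <<- as_polygon(m)
      }
    }
  }
  if (!is.null(g$type) && g$type == "FeatureCollection") {
    for (f in g$features) grab(f$geometry)
  } else if (!is.null(g$type) && g$type == "Feature") {
    grab(g$geometry)
  } else grab(g)
  if (!length(polys)) stop("no Polygon geometry found in ", path)
  polys
}

#' Write a polygon to a GeoJSON file
#'
#' @param poly polygon specification.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fence_geojson <- function(poly, path) {
  p <- as_polygon(poly)
  ring <- lapply(seq_len(nrow(p) + 1L), function(i) {
    j <- if (i > nrow(p)) 1L else i
    c(p[j, 1L], p[j, 2L])
  })
  obj <- list(
    type = "Feature",
    properties = list(units = "km"),
    geometry = list(type = "Polygon", coordinates = list(ring))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
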