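# Reserve geometry: fence polygon, exclusion zones and camera stations.

#' Construct a reserve geometry
#'
#' Bundles a fence polygon, optional exclusion polygons (uninhabitable areas
#' wholly inside the fence) and a camera-station table, and validates the
#' invariants: at least two stations, every station inside the fence and
#' outside all exclusions, and a positive reserve area (fence area minus
#' exclusion area).
#'
#' @param fence fence polygon (km; see [as_polygon()]).
#' @param stations data frame with columns `station_id`, `x`, `y` (km).
#' @param exclusions optional list of exclusion polygons.
#' @return an object of class `reserve_geometry`: list with elements
#'   `fence`, `exclusions`, `stations`, `reserve_area` (km^2).
#' @export
reserve_geometry <- function(fence, stations, exclusions = list()) {
  fence <- as_polygon(fence)
  if (!is.data.frame(stations) || !all(c("station_id", "x", "y") %in% names(stations)))
    stop("stations must be a data frame with station_id, x, y")
  if (nrow(stations) < 2L) stop("need at least 2 camera stations")
  if (anyDuplicated(stations$station_id)) stop("station ids must be unique")
  exclusions <- lapply(exclusions, as_polygon)
  inside <- point_in_polygon(stations$x, stations$y, fence)
  if (!all(inside))
    stop("stations outside fence: ",
         paste(stations$station_id[!inside], collapse = ", "))
  for (ex in exclusions) {
    hit <- point_in_polygon(stations$x, stations$y, ex)
    if (any(hit))
      stop("stations inside an exclusion zone: ",
           paste(stations$station_id[hit], collapse = ", "))
  }
  area <- polygon_area(fence) - sum(vapply(exclusions, polygon_area, 0))
  if (area <= 0) stop("reserve area must be positive")
  structure(
    list(fence = fence, exclusions = exclusions,
         stations = stations[, c("station_id", "x", "y")],
         reserve_area = area),
    class = "reserve_geometry")
}

#' @export
print.reserve_geometry <- function(x, ...) {
  cat("Fenced reserve: area", format(x$reserve_area, digits = 5), "km^2,",
      nrow(x$stations), "camera stations,",
      length(x$exclusions), "exclusion polygon(s)\n")
  invisible(x)
}

#' Lay out a jittered camera grid inside a fence
#'
#' Emulates a camera-trap array: candidate sites on a regular lattice at the
#' requested spacing (inset half a spacing from the fence), the `n_stations`
#' sites closest to the array centroid are kept (giving a compact block, as
#' real surveys concentrate cameras away from the boundary), and each is
#' jittered uniformly by up to 15% of the spacing while remaining inside the
#' fence and outside exclusions. Deterministic for a fixed seed.
#'
#' @param shape fence polygon specification (km).
#' @param n_stations number of camera stations.
#' @param spacing target station spacing (km).
#' @param seed integer seed (optional); set for reproducible layouts.
#' @param exclusions optional list of exclusion polygons.
#' @return a [reserve_geometry()].
#' @export
make_reserve <- function(shape, n_stations, spacing, seed = NULL,
                         exclusions = list()) {
  fence <- as_polygon(shape)
  stopifnot(spacing > 0, n_stations >= 2L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  exclusions <- lapply(exclusions, as_polygon)
  bb <- apply(fence, 2L, range)
  gx <- seq(bb[1L, 1L] + spacing / 2, bb[2L, 1L] - spacing / 2, by = spacing)
  gy <- seq(bb[1L, 2L] + spacing / 2, bb[2L, 2L] - spacing / 2, by = spacing)
  if (!length(gx) || !length(gy))
    stop("fence too small to host stations at spacing ", spacing, " km")
  cand <- expand.grid(x = gx, y = gy)
  keep <- point_in_polygon(cand$x, cand$y, fence)
  for (ex in exclusions) keep <- keep & !point_in_polygon(cand$x, cand$y, ex)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) < n_stations)
    stop("fence too small: only ", nrow(cand), " candidate sites for ",
         n_stations, " stations at spacing ", spacing, " km")
  ctr <- colMeans(cand)
  ord <- order((cand$x - ctr[1L])^2 + (cand$y - ctr[2L])^2)
  cand <- cand[ord[seq_len(n_stations)], , drop = FALSE]
  # jitter with rejection so containment survives
  jit <- 0.15 * spacing
  for (i in seq_len(nrow(cand))) {
    for (try in 1:20) {
      nx <- cand$x[i] + stats::runif(1, -jit, jit)
      ny <- cand$y[i] + stats::runif(1, -jit, jit)
      ok <- point_in_polygon(nx, ny, fence)
      if (ok) for (ex in exclusions)
        ok <- ok && !point_in_polygon(nx, ny, ex)
      if (ok) { cand$x[i] <- nx; cand$y[i] <- ny; break }
    }
  }
  stations <- data.frame(
    station_id = sprintf("S%02d", seq_len(n_stations)),
    x = cand$x, y = cand$y)
  reserve_geometry(fence, stations, exclusions)
}

#' Mean nearest-neighbour spacing of stations
#'
#' @param stations data frame with `x`, `y` (km), or a [reserve_geometry()].
#' @return mean distance to the nearest other station (km).
#' @export
station_spacing <- function(stations) {
  if (inherits(stations, "reserve_geometry")) stations <- stations$stations
  d <- as.matrix(stats::dist(stations[, c("x", "y")]))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}
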