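# Synthetic fenced-reserve surveys with known truth. Activity centres follow
# a homogeneous Poisson process extending beyond the fence; detections are
# per-occasion Bernoulli at proximity detectors; a permeability parameter
# rho scales the detectability of animals centred outside the fence
# (rho = 1 fully permeable, rho = 0 impermeable).

#' Simulation configuration
#'
#' Defaults are the reference survey conditions used throughout the
#' package's validation simulations: half-normal detection with
#' `g0 = 0.2`, `sigma = 1` km, true density 5 animals per 100 km^2, and
#' 40 noon-to-noon occasions.
#'
#' @param true_density animals per 100 km^2.
#' @param detfn detection-function name (`"HN"`, `"HR"`, `"EX"`).
#' @param g0_true baseline detection probability.
#' @param sigma_true spatial scale (km).
#' @param shape_true hazard-rate shape (HR only).
#' @param permeability rho in `[0, 1]`: multiplicative factor on the
#'   detection probability of animals centred outside the fence.
#' @param n_occasions number of sampling occasions.
#' @param outer_margin extent of activity-centre generation beyond the
#'   fence (km); default `4 * sigma_true`, covering essentially all
#'   detectable centres.
#' @param seed integer seed driving all randomness in the simulation.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(true_density = 5, detfn = c("HN", "HR", "EX"),
                       g0_true = 0.2, sigma_true = 1, shape_true = 2.5,
                       permeability = 1, n_occasions = 40,
                       outer_margin = 4 * sigma_true, seed = NULL) {
  detfn <- match.arg(detfn)
  stopifnot(true_density >= 0,
            g0_true >= 0, g0_true <= 1, sigma_true > 0,
            permeability >= 0, permeability <= 1,
            n_occasions >= 1, outer_margin >= 0)
  structure(list(true_density = true_density, detfn = detfn,
                 g0_true = g0_true, sigma_true = sigma_true,
                 shape_true = shape_true, permeability = permeability,
                 n_occasions = as.integer(n_occasions),
                 outer_margin = outer_margin, seed = seed),
            class = "sim_config")
}

#' Simulate activity centres around a fenced reserve
#'
#' Homogeneous Poisson point process with intensity
#' `true_density / 100` per km^2 over the fence polygon dilated by
#' `outer_margin`: points are proposed uniformly on the expanded bounding
#' box with a Poisson total and thinned to those within `outer_margin` of
#' the fence, which realises the process exactly on the dilated region.
#'
#' @param geom a [reserve_geometry()].
#' @param config a [sim_config()]. If `config$seed` is set the RNG is
#'   seeded here, making the centre set reproducible.
#' @return object of class `activity_centers`: data frame with
#'   `animal_id`, `x`, `y`, `inside_fence`.
#' @export
simulate_centers <- function(geom, config) {
  stopifnot(inherits(geom, "reserve_geometry"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  lambda <- config$true_density / 100
  m <- config$outer_margin
  bb <- apply(geom$fence, 2L, range)
  lo <- bb[1L, ] - m; hi <- bb[2L, ] + m
  box_area <- prod(hi - lo)
  N <- stats::rpois(1L, lambda * box_area)
  if (N == 0L || lambda == 0) {
    out <- data.frame(animal_id = character(), x = numeric(), y = numeric(),
                      inside_fence = logical())
    class(out) <- c("activity_centers", "data.frame")
    return(out)
  }
  x <- stats::runif(N, lo[1L], hi[1L])
  y <- stats::runif(N, lo[2L], hi[2L])
  keep <- dist_to_polygon(x, y, geom$fence) <= m
  x <- x[keep]; y <- y[keep]
  out <- data.frame(
    animal_id = sprintf("A%04d", seq_along(x)),
    x = x, y = y,
    inside_fence = point_in_polygon(x, y, geom$fence))
  class(out) <- c("activity_centers", "data.frame")
  out
}

#' Simulate a capture history from activity centres
#'
#' Per animal, occasion and station the detection is Bernoulli with
#' probability `m * g(d)` where `d` is the centre-to-station distance,
#' `g` the configured detection function, and `m = 1` for centres inside
#' the fence, `m = permeability` otherwise. Animals never detected are
#' dropped from the returned history but recorded in the `truth`
#' attribute together with the configuration and all centres.
#'
#' @param centers an [simulate_centers()] result.
#' @param geom a [reserve_geometry()].
#' @param config a [sim_config()]. The RNG is *not* reseeded here;
#'   randomness continues from the centre simulation so one seed drives the
#'   whole survey.
#' @param session session label for the returned history.
#' @return a [capture_history()] with attribute `truth` (list: `config`,
#'   `centers`, `n_total`, `n_inside`).
#' @export
simulate_capture_history <- function(centers, geom, config,
                                     session = "sim1") {
  stopifnot(inherits(geom, "reserve_geometry"), inherits(config, "sim_config"))
  st <- geom$stations
  K <- nrow(st); S <- config$n_occasions
  n <- nrow(centers)
  truth <- list(config = config, centers = centers, n_total = n,
                n_inside = sum(centers$inside_fence))
  empty <- function() {
    h <- capture_history(
      array(integer(), dim = c(0L, S, K)),
      st, matrix(1L, S, K), session)
    attr(h, "truth") <- truth
    h
  }
  if (n == 0L || config$g0_true == 0) return(empty())
  dx <- outer(centers$x, st$x, "-")
  dy <- outer(centers$y, st$y, "-")
  d <- sqrt(dx^2 + dy^2)
  g <- .gdet(config$detfn, d, config$g0_true, config$sigma_true,
             config$shape_true)
  g[d == 0] <- config$g0_true
  mlt <- ifelse(centers$inside_fence, 1, config$permeability)
  p <- g * mlt                      # n x K per-occasion probabilities
  omega <- array(0L, dim = c(n, S, K),
                 dimnames = list(centers$animal_id, NULL, st$station_id))
  u <- array(stats::runif(n * S * K), dim = c(n, S, K))
  parr <- aperm(array(rep(p, S), dim = c(n, K, S)), c(1L, 3L, 2L))
  omega[u < parr] <- 1L
  caught <- apply(omega, 1L, sum) > 0L
  if (!any(caught)) return(empty())
  h <- capture_history(omega[caught, , , drop = FALSE], st,
                       matrix(1L, S, K), session)
  attr(h, "truth") <- truth
  h
}

#' Simulate a complete fenced-reserve survey
#'
#' Convenience wrapper: activity centres then capture history, returning
#' both with the geometry.
#'
#' @param geom a [reserve_geometry()].
#' @param config a [sim_config()].
#' @param session session label.
#' @return list with `geom`, `centers`, `history`.
#' @export
simulate_survey <- function(geom, config, session = "sim1") {
  centers <- simulate_centers(geom, config)
  history <- simulate_capture_history(centers, geom, config, session)
  list(geom = geom, centers = centers, history = history)
}

#' Write a simulated survey to disk
#'
#' Detections CSV (`site`, `station_id`, `timestamp`, `species`,
#' `individual_id`, `flank`), stations CSV, fence GeoJSON, and a truth JSON
#' holding the configuration and every activity centre. Timestamps place
#' each detection at 22:00 within its occasion's noon-to-noon window.
#'
#' @param survey result of [simulate_survey()].
#' @param dir output directory (created if needed).
#' @param survey_start date of occasion 1 (its noon opens the survey).
#' @param species species label written to the detections file.
#' @return the directory, invisibly.
#' @export
write_survey <- function(survey, dir, survey_start = as.Date("2016-07-10"),
                         species = "brown_hyaena") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- survey$history
  idx <- which(h$omega == 1L, arr.ind = TRUE)
  ts <- as.POSIXct(paste(as.Date(survey_start) + (idx[, 2L] - 1L), "22:00:00"),
                   tz = "UTC")
  det <- data.frame(
    site = h$session,
    station_id = h$traps$station_id[idx[, 3L]],
    timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
    species = species,
    individual_id = dimnames(h$omega)[[1L]][idx[, 1L]],
    flank = "both")
  det <- det[order(det$timestamp, det$station_id, det$individual_id), ]
  utils::write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  utils::write.csv(survey$geom$stations, file.path(dir, "stations.csv"),
                   row.names = FALSE)
  write_fence_geojson(survey$geom$fence, file.path(dir, "fence.geojson"))
  truth <- attr(h, "truth")
  jsonlite::write_json(
    list(config = unclass(truth$config)[!vapply(unclass(truth$config), is.null, TRUE)],
         n_total = truth$n_total, n_inside = truth$n_inside,
         centers = truth$centers),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
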