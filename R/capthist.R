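# Capture-history container: binary detections of identified individuals at
# proximity detectors, by sampling occasion.

#' Construct a capture history
#'
#' @param omega binary array `individuals x occasions x detectors`; dimnames
#'   on the first margin are individual ids, on the third detector ids.
#' @param traps data frame with `station_id`, `x`, `y` (km) in detector order.
#' @param usage binary `occasions x detectors` matrix (1 = detector active);
#'   defaults to all active.
#' @param session session (site) label.
#' @return object of class `capture_history`.
#' @export
capture_history <- function(omega, traps, usage = NULL, session = "session1") {
  if (length(dim(omega)) != 3L) stop("omega must be a 3-d array (n x S x K)")
  storage.mode(omega) <- "integer"
  if (!all(omega %in% c(0L, 1L))) stop("omega must be binary")
  n <- dim(omega)[1L]; S <- dim(omega)[2L]; K <- dim(omega)[3L]
  if (!is.data.frame(traps) || !all(c("station_id", "x", "y") %in% names(traps)))
    stop("traps must be a data frame with station_id, x, y")
  if (nrow(traps) != K) stop("traps rows must match omega's detector dimension")
  if (is.null(usage)) usage <- matrix(1L, S, K) else {
    usage <- matrix(as.integer(usage), S, K)
    if (!all(usage %in% c(0L, 1L))) stop("usage must be binary")
  }
  if (n > 0L) {
    exposed <- array(rep(usage, each = n), dim = c(n, S, K))
    if (any(omega == 1L & exposed == 0L))
      stop("detections recorded at inactive occasion-detector pairs")
    caught <- apply(omega, 1L, sum) > 0L
    if (!all(caught))
      stop("individuals with all-zero histories: ",
           paste(dimnames(omega)[[1L]][!caught], collapse = ", "))
  }
  if (is.null(dimnames(omega)[[1L]]) && n > 0L)
    dimnames(omega)[[1L]] <- sprintf("ID%03d", seq_len(n))
  structure(list(session = session, omega = omega,
                 traps = traps[, c("station_id", "x", "y")], usage = usage),
            class = "capture_history")
}

#' @export
print.capture_history <- function(x, ...) {
  d <- dim(x$omega)
  cat("Capture history [", x$session, "]: ", d[1L], " individuals, ",
      d[2L], " occasions, ", d[3L], " detectors, ",
      sum(x$omega), " detections\n", sep = "")
  invisible(x)
}

#' @export
summary.capture_history <- function(object, ...) {
  d <- dim(object$omega)
  per <- apply(object$omega, 1L, sum)
  out <- list(session = object$session, n = d[1L], occasions = d[2L],
              detectors = d[3L], detections = sum(object$omega),
              mean_detections = if (d[1L]) mean(per) else NA_real_,
              trap_nights = sum(object$usage))
  class(out) <- "summary.capture_history"
  out
}

#' @export
print.summary.capture_history <- function(x, ...) {
  cat("Session", x$session, "-", x$n, "individuals,", x$detections,
      "detections over", x$occasions, "occasions at", x$detectors,
      "detectors (", x$trap_nights, "trap nights )\n")
  invisible(x)
}

#' Assign noon-to-noon sampling occasions
#'
#' Occasions are 24-h windows running from 12:00 on one day to 11:59 on the
#' next, so that a nocturnal animal photographed either side of midnight
#' falls in a single occasion. Occasion 1 starts at noon on `survey_start`.
#'
#' @param timestamp `POSIXct` vector (or parseable character).
#' @param survey_start survey start `Date` (or parseable character); the
#'   survey window opens at noon on this date.
#' @param n_occasions optional survey length; timestamps past the last
#'   occasion are rejected.
#' @return integer occasion indices (1-based).
#' @export
assign_occasion <- function(timestamp, survey_start, n_occasions = NULL) {
  if (is.character(timestamp))   # accept ISO-8601 'T' separators
    timestamp <- as.POSIXct(sub("T", " ", timestamp, fixed = TRUE), tz = "UTC")
  start_noon <- as.POSIXct(paste(as.Date(survey_start), "12:00:00"), tz = "UTC")
  hrs <- as.numeric(difftime(timestamp, start_noon, units = "hours"))
  occ <- floor(hrs / 24) + 1L
  bad <- occ < 1L
  if (!is.null(n_occasions)) bad <- bad | occ > n_occasions
  if (any(bad))
    stop("timestamps outside the survey window (first offending: ",
         format(timestamp[which(bad)[1L]]), ")")
  as.integer(occ)
}

#' Keep the majority flank at each site
#'
#' Records showing both flanks are always retained. Single-flank records are
#' retained only for the flank most often photographed at that site, so an
#' individual's left and right flanks cannot be counted as two animals.
#' Ties are broken in favour of the left flank (deterministic, logged).
#'
#' @param records data frame with at least `site` and `flank`
#'   (`"left"`, `"right"`, `"both"`, or `"none"`/unknown).
#' @return filtered data frame; attribute `"flank_log"` holds per-site
#'   counts and the chosen flank.
#' @export
select_flanks <- function(records) {
  stopifnot(all(c("site", "flank") %in% names(records)))
  fl <- tolower(as.character(records$flank))
  if (!any(fl %in% c("left", "right"))) {
    warning("no single-flank records with known flank; returning all records")
    attr(records, "flank_log") <- data.frame()
    return(records)
  }
  keep <- rep(TRUE, nrow(records))
  logs <- list()
  for (s in unique(records$site)) {
    i <- records$site == s
    nl <- sum(i & fl == "left"); nr <- sum(i & fl == "right")
    chosen <- if (nr > nl) "right" else "left"
    drop <- i & fl %in% c("left", "right") & fl != chosen
    keep[drop] <- FALSE
    logs[[s]] <- data.frame(site = s, left = nl, right = nr,
                            chosen = chosen, removed = sum(drop))
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "flank_log") <- do.call(rbind, logs)
  out
}

#' Drop records of unidentified individuals
#'
#' Removes records whose `individual_id` is missing, empty or `"unknown"`,
#' reporting how many capture events were discarded and the discard rate.
#'
#' @param records detection records with an `individual_id` column.
#' @return retained records; attributes `n_total`, `n_discarded`,
#'   `discard_rate_pct` (percentage, 2 dp).
#' @export
filter_identified <- function(records) {
  stopifnot("individual_id" %in% names(records))
  id <- as.character(records$individual_id)
  bad <- is.na(id) | id == "" | tolower(id) == "unknown"
  out <- records[!bad, , drop = FALSE]
  attr(out, "n_total") <- nrow(records)
  attr(out, "n_discarded") <- sum(bad)
  attr(out, "discard_rate_pct") <- round(100 * sum(bad) / nrow(records), 2)
  out
}

#' Build a capture history from detection records
#'
#' Binarizes records: `omega[i, s, k] = 1` if individual `i` was recorded at
#' least once at detector `k` during occasion `s`. Detector usage comes from
#' the stations table's `active_from` / `active_to` dates when present
#' (a station is active for the occasions whose noon start falls within its
#' active window), otherwise all detectors are active throughout.
#'
#' @param records data frame with `station_id`, `timestamp`, `individual_id`
#'   (all identified; see [filter_identified()]).
#' @param stations data frame with `station_id`, `x`, `y` and optionally
#'   `active_from`, `active_to` (dates).
#' @param survey_start survey start date (occasion 1 opens at its noon).
#' @param n_occasions number of occasions in the survey.
#' @param session session label.
#' @return a [capture_history()].
#' @export
build_capture_history <- function(records, stations, survey_start, n_occasions,
                                  session = "session1") {
  if (nrow(records) == 0L) stop("no identifiable captures")
  stopifnot(all(c("station_id", "timestamp", "individual_id") %in% names(records)))
  unknown <- !records$station_id %in% stations$station_id
  if (any(unknown))
    stop("records at unknown stations: ",
         paste(unique(records$station_id[unknown]), collapse = ", "))
  occ <- assign_occasion(records$timestamp, survey_start, n_occasions)
  ids <- sort(unique(as.character(records$individual_id)))
  K <- nrow(stations); S <- as.integer(n_occasions)
  usage <- matrix(1L, S, K)
  if (all(c("active_from", "active_to") %in% names(stations))) {
    day0 <- as.Date(survey_start)
    occ_date <- day0 + (seq_len(S) - 1L)   # date of each occasion's noon start
    for (k in seq_len(K)) {
      usage[, k] <- as.integer(occ_date >= as.Date(stations$active_from[k]) &
                               occ_date <= as.Date(stations$active_to[k]))
    }
  }
  omega <- array(0L, dim = c(length(ids), S, K),
                 dimnames = list(ids, NULL, stations$station_id))
  ki <- match(records$station_id, stations$station_id)
  ii <- match(as.character(records$individual_id), ids)
  inactive <- usage[cbind(occ, ki)] == 0L
  if (any(inactive))
    stop("records at inactive detectors (rows ",
         paste(which(inactive), collapse = ", "), ")")
  omega[cbind(ii, occ, ki)] <- 1L
  capture_history(omega, stations, usage, session)
}

#' Relative abundance index with a 30-minute independence filter
#'
#' Consecutive records of the same species at the same station within the
#' filter window collapse to one capture: each retained capture opens a new
#' window (sequential chaining), so records at 10:00, 10:20 and 10:45 count
#' as two captures. RAI is filtered captures per 100 trap-days.
#'
#' @param records data frame with `station_id` and `timestamp` for a single
#'   species (optionally a `species` column, chained within species).
#' @param trap_nights total survey effort in trap nights (> 0).
#' @param window_minutes independence window (default 30).
#' @return RAI value; attribute `"captures"` holds the filtered count.
#' @export
compute_rai <- function(records, trap_nights, window_minutes = 30) {
  if (!is.numeric(trap_nights) || trap_nights <= 0)
    stop("trap_nights must be positive")
  if (nrow(records) == 0L) {
    out <- 0
    attr(out, "captures") <- 0L
    return(out)
  }
  ts <- records$timestamp
  if (is.character(ts)) ts <- as.POSIXct(ts, tz = "UTC")
  sp <- if ("species" %in% names(records)) as.character(records$species) else "sp"
  key <- paste(sp, records$station_id)
  captures <- 0L
  for (k in unique(key)) {
    t <- sort(ts[key == k])
    last <- -Inf
    for (tt in as.numeric(t)) {
      if (tt - last > window_minutes * 60) {
        captures <- captures + 1L
        last <- tt
      }
    }
  }
  out <- 100 * captures / trap_nights
  attr(out, "captures") <- captures
  out
}

#' Standardise a covariate as z-scores
#'
#' @param values numeric vector (one value per session), length >= 2.
#' @param sd_type `"sample"` (n-1 denominator, the default) or
#'   `"population"` (n denominator).
#' @return z-scored values (mean 0, SD 1 under the chosen convention).
#' @export
zscore <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(values) < 2L) stop("z-scoring needs at least 2 sessions")
  m <- mean(values)
  s <- stats::sd(values)
  if (sd_type == "population") s <- s * sqrt((length(values) - 1) / length(values))
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-score")
  (values - m) / s
}

#' Minimum convex polygon area of a camera array
#'
#' Area of the convex hull of station coordinates (shoelace formula on the
#' hull vertices).
#'
#' @param stations data frame or matrix with `x`, `y` columns (km).
#' @return MCP area in km^2.
#' @export
mcp_area <- function(stations) {
  if (inherits(stations, "reserve_geometry")) stations <- stations$stations
  xy <- as.matrix(as.data.frame(stations)[, c("x", "y")])
  if (nrow(xy) < 3L) stop("MCP needs at least 3 stations")
  h <- grDevices::chull(xy)
  if (length(h) < 3L) stop("stations are collinear; MCP undefined")
  polygon_area(xy[h, , drop = FALSE])
}

#' Session covariate table with z-scored columns
#'
#' @param covariates data frame with a `session` column and numeric
#'   covariate columns.
#' @param columns which columns to z-score (default: all numeric).
#' @return the input with added `z.<name>` columns.
#' @export
session_covariates <- function(covariates, columns = NULL) {
  stopifnot("session" %in% names(covariates))
  if (is.null(columns))
    columns <- names(covariates)[vapply(covariates, is.numeric, TRUE)]
  for (cl in columns)
    covariates[[paste0("z.", cl)]] <- zscore(covariates[[cl]])
  covariates
}
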