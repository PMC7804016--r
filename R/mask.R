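# Habitat masks: the discretized state space of candidate activity-centre
# locations over which the SCR likelihood integrates.

.new_mask <- function(cells, spacing, mode, buffer = NA_real_) {
  cells <- as.data.frame(cells)
  if (nrow(cells) == 0L) stop("mask has no cells")
  a <- spacing^2
  structure(cells,
            spacing = spacing, cell_area = a, mode = mode,
            buffer = buffer, total_area = a * nrow(cells),
            class = c("habitat_mask", "data.frame"))
}

#' @export
print.habitat_mask <- function(x, ...) {
  cat("Habitat mask (", attr(x, "mode"), "): ", nrow(x), " cells, spacing ",
      attr(x, "spacing"), " km, total area ",
      format(attr(x, "total_area"), digits = 6), " km^2",
      if (!is.na(attr(x, "buffer"))) paste0(", buffer ", attr(x, "buffer"), " km"),
      "\n", sep = "")
  invisible(x)
}

#' Mask attribute accessors
#'
#' @param mask a habitat mask.
#' @return scalar attribute value.
#' @name mask-attributes
#' @export
mask_area <- function(mask) attr(mask, "total_area")

#' @rdname mask-attributes
#' @export
cell_area <- function(mask) attr(mask, "cell_area")

#' @rdname mask-attributes
#' @export
mask_spacing <- function(mask) attr(mask, "spacing")

# lattice of cell centres covering [x0,x1] x [y0,y1]. The anchor is the
# bounding-box lower-left snapped down to a whole number of spacings, with
# centres offset half a spacing inwards: masks built at the same spacing
# therefore share one absolute lattice, so clipped and buffered masks of a
# reserve have comparable (and nestable) cells.
.lattice <- function(bb, spacing) {
  x0 <- floor(bb[1L, 1L] / spacing) * spacing
  y0 <- floor(bb[1L, 2L] / spacing) * spacing
  gx <- seq(x0 + spacing / 2, bb[2L, 1L], by = spacing)
  gy <- seq(y0 + spacing / 2, bb[2L, 2L], by = spacing)
  expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
}

.drop_excluded <- function(cells, exclusions) {
  for (ex in exclusions)
    cells <- cells[!point_in_polygon(cells$x, cells$y, as_polygon(ex)), ,
                   drop = FALSE]
  cells
}

#' Habitat mask clipped to the fence (impermeable assumption)
#'
#' Lattice cells (centre-point membership) inside the fence polygon and
#' outside all exclusion polygons. The lattice is anchored at the fence
#' bounding-box lower-left corner, centres offset half a spacing inwards.
#'
#' @param fence fence polygon (km).
#' @param exclusions list of exclusion polygons.
#' @param spacing cell side (km); default 0.5 (the home-range-centre spacing
#'   used throughout the analysis).
#' @return a `habitat_mask` with `mode = "clipped"`.
#' @export
build_clipped_mask <- function(fence, exclusions = list(), spacing = 0.5) {
  stopifnot(spacing > 0)
  fence <- as_polygon(fence)
  bb <- apply(fence, 2L, range)
  if (any(bb[2L, ] - bb[1L, ] < spacing))
    stop("fence smaller than one mask cell at spacing ", spacing, " km")
  cells <- .lattice(bb, spacing)
  cells <- cells[point_in_polygon(cells$x, cells$y, fence), , drop = FALSE]
  cells <- .drop_excluded(cells, exclusions)
  if (nrow(cells) == 0L)
    stop("fence smaller than one mask cell at spacing ", spacing, " km")
  .new_mask(cells, spacing, "clipped")
}

#' Habitat mask buffered beyond the fence (permeable assumption)
#'
#' Lattice cells within Euclidean distance `buffer` of any detector and
#' outside all exclusion polygons. The fence plays no clipping role here;
#' the buffer is measured from the detectors so that the state space covers
#' the centres of all detectable animals.
#'
#' @param detectors data frame with `x`, `y` (km), or a station table.
#' @param exclusions list of exclusion polygons.
#' @param spacing cell side (km), default 0.5.
#' @param buffer buffer width W (km), > 0.
#' @return a `habitat_mask` with `mode = "buffered"`.
#' @export
build_buffered_mask <- function(detectors, buffer, exclusions = list(),
                                spacing = 0.5) {
  stopifnot(spacing > 0)
  if (!is.numeric(buffer) || buffer <= 0) stop("buffer width must be positive")
  det <- as.data.frame(detectors)
  stopifnot(all(c("x", "y") %in% names(det)))
  bb <- rbind(c(min(det$x) - buffer, min(det$y) - buffer),
              c(max(det$x) + buffer, max(det$y) + buffer))
  cells <- .lattice(bb, spacing)
  # squared-distance to nearest detector, blockwise
  d2 <- rep(Inf, nrow(cells))
  for (k in seq_len(nrow(det)))
    d2 <- pmin(d2, (cells$x - det$x[k])^2 + (cells$y - det$y[k])^2)
  cells <- cells[d2 <= buffer^2, , drop = FALSE]
  cells <- .drop_excluded(cells, exclusions)
  .new_mask(cells, spacing, "buffered", buffer)
}

#' Pilot estimate of the spatial scale from recaptures
#'
#' Pooled root spatial variance of detection locations about each animal's
#' mean detection point (RPSV): with `m_i` detections of animal `i` at
#' detector coordinates, the pooled variance divides the summed squared
#' deviations in x and y by `2 (sum m_i - n)`, the degrees of freedom left
#' after estimating each animal's centroid, giving an approximately
#' unbiased estimate of sigma under a bivariate-normal use distribution.
#' Detections are weighted by the number of occasions at each detector.
#'
#' @param history a [capture_history()].
#' @return sigma-hat in km.
#' @export
rpsv_sigma <- function(history) {
  stopifnot(inherits(history, "capture_history"))
  om <- history$omega
  n <- dim(om)[1L]
  ss <- 0; df <- 0
  for (i in seq_len(n)) {
    cnt <- apply(om[i, , , drop = FALSE], 3L, sum)  # detections per detector
    m <- sum(cnt)
    if (m < 2L) next
    w <- cnt / m
    cx <- sum(w * history$traps$x); cy <- sum(w * history$traps$y)
    ss <- ss + sum(cnt * ((history$traps$x - cx)^2 + (history$traps$y - cy)^2))
    df <- df + 2 * (m - 1)
  }
  if (df <= 0 || ss <= 0)
    stop("insufficient spatial recaptures to estimate sigma; supply one")
  sqrt(ss / df)
}

#' Suggest a buffer width from a pilot spatial-scale estimate
#'
#' Computes sigma-hat by [rpsv_sigma()] and returns the smallest distance W
#' at which the detection function has decayed to a fraction `tau` of its
#' value at zero, rounded up to a whole number of mask cells (minimum one
#' spacing). Closed forms: half-normal `W = sigma sqrt(2 log(1/tau))`;
#' negative exponential `W = sigma log(1/tau)`; hazard rate
#' `W = sigma (-log(1 - tau))^(-1/z)`.
#'
#' @param history a [capture_history()] (used for the pilot sigma), or a
#'   numeric sigma value.
#' @param detfn detection-function name `"HN"`, `"HR"` or `"EX"`.
#' @param tau tail fraction g(W)/g0; default 1e-4 (large, conservative
#'   buffers appropriate to heavy-tailed hazard-rate fits).
#' @param z hazard-rate shape (required for `"HR"`).
#' @param spacing mask spacing the result is rounded up to (km).
#' @return buffer width W in km.
#' @export
suggest_buffer <- function(history, detfn = c("HN", "HR", "EX"), tau = 1e-4,
                           z = NULL, spacing = 0.5) {
  detfn <- match.arg(detfn)
  stopifnot(tau > 0, tau <= 1, spacing > 0)
  sigma <- if (is.numeric(history)) history else rpsv_sigma(history)
  W <- switch(detfn,
    HN = sigma * sqrt(2 * log(1 / tau)),
    EX = sigma * log(1 / tau),
    HR = {
      if (is.null(z)) stop("hazard-rate buffer needs a shape z")
      if (tau >= 1) 0 else sigma * (-log(1 - tau))^(-1 / z)
    })
  max(spacing, ceiling(W / spacing) * spacing)
}

#' Write a mask to CSV
#'
#' Columns `x`, `y`, `cell_area`, `mode`; a `# buffer` comment line records
#' the buffer width for buffered masks.
#'
#' @param mask habitat mask.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  df <- data.frame(x = mask$x, y = mask$y,
                   cell_area = cell_area(mask), mode = attr(mask, "mode"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a mask written by [write_mask_csv()]
#'
#' @param path CSV path.
#' @return habitat mask.
#' @export
read_mask_csv <- function(path) {
  df <- utils::read.csv(path)
  spacing <- sqrt(df$cell_area[1L])
  .new_mask(df[, c("x", "y")], spacing, as.character(df$mode[1L]))
}
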