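# Detection functions: per-occasion detection probability g(d) between an
# activity centre and a proximity detector at distance d.

.DETFN <- c("HN", "HR", "EX")

#' Detection-function specification
#'
#' @param name one of `"HN"` (half-normal), `"HR"` (hazard rate),
#'   `"EX"` (negative exponential).
#' @param g0 baseline detection probability at distance zero, in (0, 1).
#' @param sigma spatial scale parameter (km), > 0.
#' @param z hazard-rate shape parameter (> 0; fitted values are typically
#'   above 1, giving a flat shoulder and a heavy tail). Ignored for HN/EX.
#' @return object of class `detfn_spec`.
#' @export
detfn_spec <- function(name = c("HN", "HR", "EX"), g0, sigma, z = NULL) {
  name <- match.arg(name)
  stopifnot(is.numeric(g0), length(g0) == 1L, g0 > 0, g0 < 1,
            is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  if (name == "HR") {
    if (is.null(z)) stop("hazard-rate detection function needs a shape z")
    stopifnot(is.numeric(z), length(z) == 1L, z > 0)
  } else z <- NULL
  structure(list(name = name, g0 = g0, sigma = sigma, z = z),
            class = "detfn_spec")
}

# raw evaluation used by the likelihood: vectorised over d, scalar parameters
.gdet <- function(name, d, g0, sigma, z = NULL) {
  switch(name,
    HN = g0 * exp(-d^2 / (2 * sigma^2)),
    EX = g0 * exp(-d / sigma),
    HR = g0 * (1 - exp(-(d / sigma)^(-z))),
    stop("unknown detection function ", name))
}

#' Evaluate a detection function
#'
#' Half-normal: `g0 exp(-d^2 / (2 sigma^2))`; hazard rate:
#' `g0 (1 - exp(-(d/sigma)^(-z)))`; negative exponential:
#' `g0 exp(-d/sigma)`. At `d = 0` all three return `g0` (the hazard-rate
#' value is its limit as d tends to 0 from above).
#'
#' @param detfn a [detfn_spec()].
#' @param d distance(s) in km, >= 0.
#' @return detection probabilities in `[0, g0]`.
#' @export
detection_prob <- function(detfn, d) {
  stopifnot(inherits(detfn, "detfn_spec"))
  if (any(d < 0)) stop("distances must be non-negative")
  g <- .gdet(detfn$name, d, detfn$g0, detfn$sigma, detfn$z)
  g[d == 0] <- detfn$g0
  g
}
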