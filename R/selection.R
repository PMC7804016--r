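# AICc model ranking and derived quantities: Horvitz-Thompson density,
# regional population size, and combined activity-centre surfaces.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 l + 2K + 2K(K+1)/(n - K - 1)`.
#'
#' @param loglik maximised log-likelihood.
#' @param K number of free parameters.
#' @param n effective sample size (here: total individuals across sessions).
#' @return AICc value.
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) stop("AICc undefined: need n > K + 1")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from AICc differences
#'
#' @param delta vector of AICc differences (minimum need not be 0).
#' @return weights summing to 1.
#' @export
akaike_weights <- function(delta) {
  delta <- delta - min(delta)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Rank SCR models by AICc
#'
#' @param fits list of `scr_fit` objects fitted to the same data under the
#'   same likelihood mode.
#' @param n AICc sample size; defaults to the total number of individuals
#'   across sessions of the first fit.
#' @param labels optional model labels (defaults to [model_label()]).
#' @return a `model_table` data frame: `model`, `K`, `logLik`, `AICc`,
#'   `dAICc`, `weight`, `retained` (`dAICc < 2`), sorted by AICc.
#' @export
rank_models <- function(fits, n = NULL, labels = NULL) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "scr_fit")))
  modes <- vapply(fits, function(f) f$model$mode, "")
  if (length(unique(modes)) > 1L)
    stop("cannot rank full and conditional likelihoods together")
  if (any(!vapply(fits, function(f) f$converged, TRUE)))
    warning("ranking includes non-converged fits")
  if (is.null(n)) n <- sum(fits[[1L]]$n)
  if (is.null(labels)) labels <- vapply(fits, model_label, "")
  tab <- data.frame(
    model = labels,
    K = vapply(fits, function(f) f$K, 0L),
    logLik = vapply(fits, function(f) f$loglik, 0))
  tab$AICc <- mapply(aicc, tab$logLik, tab$K, MoreArgs = list(n = n))
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1L]
  tab$weight <- akaike_weights(tab$dAICc)
  tab$retained <- tab$dAICc < 2
  rownames(tab) <- NULL
  class(tab) <- c("model_table", "data.frame")
  tab
}

# effective sampling area a*sum(pdot) of one session at given parameters,
# always using the pre-response g0
.session_ahat <- function(par, fit, r) {
  sdat <- fit$data[[r]]
  theta <- .session_theta(par, fit$model, fit$data, r)
  G <- .gdet(fit$model$detfn, sdat$distm, theta$g0_pre, theta$sigma, theta$z)
  G[sdat$distm == 0] <- theta$g0_pre
  Sk <- colSums(sdat$history$usage)
  pd <- -expm1(log1p(-G) %*% Sk)
  cell_area(sdat$mask) * sum(pd)
}

# per-session model density (animals per km^2): MLE for full fits,
# Horvitz-Thompson n/ahat for conditional fits
.session_density <- function(fit, r) {
  if (fit$model$mode == "full")
    unname(.session_theta(fit$par, fit$model, fit$data, r)$D)
  else
    unname(fit$n[r]) / .session_ahat(fit$par, fit, r)
}

#' Derived per-session density estimates
#'
#' Horvitz-Thompson estimator: with homogeneous detection within a session,
#' `D-hat = n / a-hat` where `a-hat = a sum_x p.(x; theta-hat)` is the
#' effective sampling area. The variance combines the Poisson variance of
#' `n` with detection-parameter uncertainty propagated through `a-hat` by
#' the delta method; the 95% interval is lognormal,
#' `D-hat * exp(+/- 1.96 sqrt(log(1 + CV^2)))`. Densities are reported per
#' 100 km^2.
#'
#' @param fit an `scr_fit` (full or conditional likelihood).
#' @param sessions sessions to report (default all).
#' @return `density_estimate` data frame: `session`, `n`, `esa_km2`,
#'   `D`, `SE`, `lcl`, `ucl`, `mask_mode`.
#' @export
derived_density <- function(fit, sessions = NULL) {
  stopifnot(inherits(fit, "scr_fit"))
  if (!fit$converged) warning("deriving density from a non-converged fit")
  if (is.null(sessions)) sessions <- names(fit$data)
  out <- lapply(sessions, function(s) {
    r <- match(s, names(fit$data))
    n <- fit$n[r]
    ahat <- .session_ahat(fit$par, fit, r)
    if (ahat <= 0) stop("zero effective sampling area in session ", s)
    D <- 100 * n / ahat
    # delta-method CV from the parameter covariance
    h <- 1e-4 * pmax(1, abs(fit$par))
    grad <- numeric(length(fit$par))
    for (j in seq_along(fit$par)) {
      up <- fit$par; up[j] <- up[j] + h[j]
      dn <- fit$par; dn[j] <- dn[j] - h[j]
      grad[j] <- (log(.session_ahat(up, fit, r)) -
                  log(.session_ahat(dn, fit, r))) / (2 * h[j])
    }
    var_theta <- if (all(is.finite(fit$vcov)))
      drop(t(grad) %*% fit$vcov %*% grad) else NA_real_
    cv2 <- 1 / n + max(0, var_theta)
    se <- D * sqrt(cv2)
    cf <- exp(1.96 * sqrt(log(1 + cv2)))
    data.frame(session = s, n = n, esa_km2 = ahat, D = D, SE = se,
               lcl = D / cf, ucl = D * cf,
               mask_mode = attr(fit$data[[r]]$mask, "mode"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("density_estimate", "data.frame")
  out
}

# match region cells to a session's fitted mask lattice
.region_index <- function(fit, r, region) {
  mask <- fit$data[[r]]$mask
  if (is.null(region)) return(seq_len(nrow(mask)))
  sp <- mask_spacing(mask)
  key <- function(m) paste(round(m$x / sp * 2), round(m$y / sp * 2))
  idx <- match(key(as.data.frame(region)), key(mask))
  if (anyNA(idx)) stop("region cells are not a subset of the fitted mask")
  if (!length(idx)) stop("empty region")
  idx
}

#' Expected and realized population size in a region
#'
#' Expected `N = a sum_x D(x)`; realized `N = n + a sum_x D(x)(1 - p.(x))`
#' (the detected animals plus the expected number of undetected centres in
#' the region).
#'
#' @param fit an `scr_fit`.
#' @param session session label (default first).
#' @param region data frame of cell centres forming a subset of the fitted
#'   mask lattice (default: the whole session mask).
#' @return list with `expected`, `realized`, `n`, `area_km2`.
#' @export
region_n <- function(fit, session = NULL, region = NULL) {
  stopifnot(inherits(fit, "scr_fit"))
  if (is.null(session)) session <- names(fit$data)[1L]
  r <- match(session, names(fit$data))
  sdat <- fit$data[[r]]
  idx <- .region_index(fit, r, region)
  a <- cell_area(sdat$mask)
  D <- .session_density(fit, r)             # per km^2, homogeneous
  theta <- .session_theta(fit$par, fit$model, fit$data, r)
  G <- .gdet(fit$model$detfn, sdat$distm, theta$g0_pre, theta$sigma, theta$z)
  G[sdat$distm == 0] <- theta$g0_pre
  pd <- as.numeric(-expm1(log1p(-G) %*% colSums(sdat$history$usage)))
  expected <- a * D * length(idx)
  realized <- unname(fit$n[r]) + a * D * sum(1 - pd[idx])
  list(expected = unname(expected), realized = realized,
       n = unname(fit$n[r]), area_km2 = a * length(idx))
}

#' Combined activity-centre surface
#'
#' For each detected animal the posterior density of its activity centre is
#' `fx_i(x) = D(x) Pr(w_i|x) / (a sum_x' D(x') Pr(w_i|x'))`; the combined
#' surface adds the expected intensity of undetected centres,
#' `D(x)(1 - p.(x))`. The cell-sum times the cell area of the combined
#' surface equals the realized population size `n + a sum D(x)(1 - p.(x))`.
#'
#' @param fit an `scr_fit`.
#' @param session session label (default first).
#' @return `fx_surface` data frame: `x`, `y`, `fx_observed` (summed
#'   animal-wise posteriors), `fx_unobserved`, `fx_total` (per km^2);
#'   attribute `realized_n`.
#' @export
fx_total <- function(fit, session = NULL) {
  stopifnot(inherits(fit, "scr_fit"))
  if (is.null(session)) session <- names(fit$data)[1L]
  r <- match(session, names(fit$data))
  sdat <- fit$data[[r]]
  learned <- fit$model$g0$type == "b"
  counts <- .session_counts(sdat$history, learned)
  theta <- .session_theta(fit$par, fit$model, fit$data, r)
  blk <- .session_blocks(sdat, counts, theta, fit$model$detfn, learned)
  a <- cell_area(sdat$mask)
  D <- .session_density(fit, r)
  fx_obs <- numeric(nrow(sdat$mask))
  if (counts$n > 0L) {
    lse <- .logsumexp_cols(blk$log_pr)
    for (i in seq_len(counts$n)) {
      fxi <- exp(blk$log_pr[, i] - lse[i]) / a   # integrates (cell-sum * a) to 1
      fx_obs <- fx_obs + fxi
    }
  }
  fx_un <- D * (1 - blk$pdot)
  out <- data.frame(x = sdat$mask$x, y = sdat$mask$y,
                    fx_observed = fx_obs, fx_unobserved = fx_un,
                    fx_total = fx_obs + fx_un)
  attr(out, "realized_n") <- counts$n + a * sum(fx_un)
  class(out) <- c("fx_surface", "data.frame")
  out
}

#' @export
plot.fx_surface <- function(x, ...) {
  pal <- grDevices::hcl.colors(32, "viridis")
  v <- x$fx_total
  col <- pal[pmax(1L, ceiling(32 * (v - min(v)) / max(1e-12, diff(range(v)))))]
  graphics::plot(x$x, x$y, col = col, pch = 15, cex = 0.8, asp = 1,
                 xlab = "x (km)", ylab = "y (km)",
                 main = "Activity-centre intensity", ...)
  invisible(x)
}

#' Write a model table to CSV
#'
#' @param table a `model_table` from [rank_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
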