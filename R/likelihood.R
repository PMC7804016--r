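# Multi-session SCR likelihoods. Sessions are independent; within a session
# the animal-level marginal integrates the Bernoulli detection model over
# the habitat mask:
#
#   full:        l = sum_r [ sum_i log( a sum_x D_r(x) Pr(w_i|x) )
#                            - a sum_x D_r(x) p.(x) - log(n_r!) ]
#   conditional: l = sum_r sum_i log( sum_x Pr(w_i|x) / sum_x p.(x) )
#
# with Pr(w_i|x) = prod_{s,k used} g_sk(x)^w (1-g_sk(x))^(1-w) and
# p.(x) = 1 - prod_{s,k used} (1 - g(d(x,k))). Density D is homogeneous
# within a session (session covariates enter on the log link), g0 on the
# logit link, sigma and the hazard-rate shape z on the log link and shared
# across sessions. A learned response b shifts an animal's g0 by a logit
# offset on occasions after its first capture; terms for undetected animals
# always use the pre-response g0.

.LOGFLOOR <- 1e-300

# ---- model specification ---------------------------------------------------

.parse_term <- function(s, what) {
  s <- gsub(" ", "", s)
  if (!startsWith(s, "~")) stop("model terms are written as formulas, e.g. '~1'")
  rhs <- substring(s, 2L)
  if (rhs == "1") return(list(type = "const"))
  if (rhs == "session") return(list(type = "session"))
  if (rhs == "b") {
    if (what != "g0") stop("a learned response applies to g0 only")
    return(list(type = "b"))
  }
  list(type = "cov", cov = rhs)
}

#' Specify an SCR model
#'
#' @param D density structure: `"~1"` (one density, shared), `"~session"`
#'   (one per site) or `"~<covariate>"` (log-linear in one z-scored session
#'   covariate). Ignored under the conditional likelihood.
#' @param g0 baseline-detection structure: `"~1"`, `"~session"`,
#'   `"~<covariate>"` (logit-linear) or `"~b"` (global permanent learned
#'   response: a logit offset after an animal's first capture).
#' @param detfn detection function: `"HN"`, `"HR"` or `"EX"`.
#' @param mode `"full"` (density in the likelihood) or `"conditional"`
#'   (density-free; density recovered afterwards by [derived_density()]).
#' @return object of class `scr_model`.
#' @export
scr_model <- function(D = "~1", g0 = "~1", detfn = c("HN", "HR", "EX"),
                      mode = c("full", "conditional")) {
  detfn <- match.arg(detfn)
  mode <- match.arg(mode)
  structure(list(D = .parse_term(D, "D"), g0 = .parse_term(g0, "g0"),
                 D_label = D, g0_label = g0, detfn = detfn, mode = mode),
            class = "scr_model")
}

#' @export
print.scr_model <- function(x, ...) {
  cat("SCR model: D", x$D_label, " g0", x$g0_label, " detfn", x$detfn,
      paste0("(", x$mode, " likelihood)\n"))
  invisible(x)
}

# ---- data container --------------------------------------------------------

#' Bundle capture histories, masks and covariates for fitting
#'
#' @param histories a [capture_history()] or list of them (one per session).
#' @param masks a habitat mask or list of masks aligned with `histories`.
#' @param covariates optional data frame with a `session` column and one
#'   numeric column per covariate (z-scored where the model expects it).
#' @return object of class `scr_data`: per-session list of `history`,
#'   `mask`, `covariates`, with cached distance matrices.
#' @export
scr_data <- function(histories, masks, covariates = NULL) {
  if (inherits(histories, "capture_history")) histories <- list(histories)
  if (inherits(masks, "habitat_mask")) masks <- rep(list(masks), length(histories))
  if (length(masks) != length(histories))
    stop("need one mask per session")
  sessions <- vapply(histories, function(h) h$session, "")
  if (anyDuplicated(sessions)) stop("duplicate session labels")
  out <- vector("list", length(histories))
  for (r in seq_along(histories)) {
    h <- histories[[r]]; m <- masks[[r]]
    stopifnot(inherits(h, "capture_history"), inherits(m, "habitat_mask"))
    if (dim(h$omega)[2L] < 1L || sum(h$usage) == 0L)
      stop("session ", h$session, " has no sampling effort")
    covs <- list()
    if (!is.null(covariates)) {
      row <- covariates[covariates$session == h$session, , drop = FALSE]
      if (nrow(row) == 1L)
        covs <- as.list(row[, setdiff(names(row), "session"), drop = FALSE])
    }
    distm <- sqrt(outer(m$x, h$traps$x, "-")^2 + outer(m$y, h$traps$y, "-")^2)
    out[[r]] <- list(history = h, mask = m, covariates = covs, distm = distm)
  }
  names(out) <- sessions
  structure(out, class = "scr_data")
}

#' @export
print.scr_data <- function(x, ...) {
  cat("SCR data:", length(x), "session(s)\n")
  for (s in x)
    cat(" ", s$history$session, ":", dim(s$history$omega)[1L], "individuals,",
        nrow(s$mask), "mask cells (", attr(s$mask, "mode"), ")\n")
  invisible(x)
}

# total individuals across sessions (the AICc sample size)
.n_total <- function(data) sum(vapply(data, function(s) dim(s$history$omega)[1L], 0L))

# ---- parameter template ----------------------------------------------------

.param_names <- function(model, data) {
  sess <- names(data)
  nm <- character()
  if (model$mode == "full") {
    nm <- c(nm, switch(model$D$type,
      const = "D",
      session = paste0("D.", sess),
      cov = c("D.(Intercept)", paste0("D.", model$D$cov))))
  }
  nm <- c(nm, switch(model$g0$type,
    const = "g0",
    session = paste0("g0.", sess),
    cov = c("g0.(Intercept)", paste0("g0.", model$g0$cov)),
    b = c("g0", "g0.b")))
  nm <- c(nm, "sigma")
  if (model$detfn == "HR") nm <- c(nm, "z")
  nm
}

.get_cov <- function(sdat, cov) {
  v <- sdat$covariates[[cov]]
  if (is.null(v)) stop("session ", sdat$history$session,
                       " is missing covariate '", cov, "'")
  as.numeric(v)
}

# link-scale parameters -> per-session natural parameters.
# D is parameterised as log(animals per 100 km^2); g0 on the logit scale.
.session_theta <- function(par, model, data, r) {
  sdat <- data[[r]]
  sess <- names(data)[r]
  D <- NA_real_
  if (model$mode == "full") {
    lD <- switch(model$D$type,
      const = par[["D"]],
      session = par[[paste0("D.", sess)]],
      cov = par[["D.(Intercept)"]] +
        par[[paste0("D.", model$D$cov)]] * .get_cov(sdat, model$D$cov))
    D <- exp(lD) / 100   # animals per km^2
  }
  lg0 <- switch(model$g0$type,
    const = par[["g0"]],
    session = par[[paste0("g0.", sess)]],
    cov = par[["g0.(Intercept)"]] +
      par[[paste0("g0.", model$g0$cov)]] * .get_cov(sdat, model$g0$cov),
    b = par[["g0"]])
  g0_pre <- stats::plogis(lg0)
  g0_post <- if (model$g0$type == "b")
    stats::plogis(lg0 + par[["g0.b"]]) else g0_pre
  list(D = D, g0_pre = g0_pre, g0_post = g0_post,
       sigma = exp(par[["sigma"]]),
       z = if (model$detfn == "HR") exp(par[["z"]]) else NULL)
}

# detection counts and exposure per session, split at each animal's first
# capture occasion when a learned response is in the model
.session_counts <- function(h, learned) {
  om <- h$omega
  n <- dim(om)[1L]; S <- dim(om)[2L]; K <- dim(om)[3L]
  Sk <- colSums(h$usage)                       # active occasions per detector
  N <- matrix(0, K, n)
  for (i in seq_len(n)) N[, i] <- apply(om[i, , , drop = FALSE], 3L, sum)
  out <- list(n = n, Sk = Sk, N = N)
  if (learned && n > 0L) {
    f <- integer(n)
    Npre <- matrix(0, K, n); Spre <- matrix(0, K, n)
    for (i in seq_len(n)) {
      occ_hit <- which(apply(om[i, , , drop = FALSE], 2L, sum) > 0L)
      f[i] <- occ_hit[1L]
      Npre[, i] <- apply(om[i, seq_len(f[i]), , drop = FALSE], 3L, sum)
      Spre[, i] <- colSums(h$usage[seq_len(f[i]), , drop = FALSE])
    }
    out$f <- f
    out$Npre <- Npre; out$Spre <- Spre
    out$Npost <- N - Npre; out$Spost <- matrix(Sk, K, n) - Spre
  }
  out
}

# log Pr(w_i | x) for all animals: M x n matrix
.log_pr_matrix <- function(Gpre, Gpost, counts, learned) {
  lg_pre <- log(pmax(Gpre, .LOGFLOOR))
  ls_pre <- log1p(-Gpre)
  if (!learned) {
    SkM <- matrix(counts$Sk, nrow(counts$N), ncol(counts$N))
    return(lg_pre %*% counts$N + ls_pre %*% (SkM - counts$N))
  }
  lg_post <- log(pmax(Gpost, .LOGFLOOR))
  ls_post <- log1p(-Gpost)
  lg_pre %*% counts$Npre + ls_pre %*% (counts$Spre - counts$Npre) +
    lg_post %*% counts$Npost + ls_post %*% (counts$Spost - counts$Npost)
}

.logsumexp_cols <- function(m) {
  mx <- apply(m, 2L, max)
  mx + log(colSums(exp(sweep(m, 2L, mx, "-"))))
}

# per-session building blocks at a given theta
.session_blocks <- function(sdat, counts, theta, detfn, learned) {
  Gpre <- .gdet(detfn, sdat$distm, theta$g0_pre, theta$sigma, theta$z)
  Gpre[sdat$distm == 0] <- theta$g0_pre
  Gpost <- if (learned) {
    gp <- .gdet(detfn, sdat$distm, theta$g0_post, theta$sigma, theta$z)
    gp[sdat$distm == 0] <- theta$g0_post
    gp
  } else Gpre
  log_surv <- log1p(-Gpre) %*% counts$Sk
  pdot <- -expm1(log_surv)
  lpr <- if (counts$n > 0L) .log_pr_matrix(Gpre, Gpost, counts, learned)
         else matrix(0, nrow(sdat$distm), 0L)
  list(pdot = as.numeric(pdot), log_pr = lpr)
}

.loglik_engine <- function(par, model, data, counts_list) {
  learned <- model$g0$type == "b"
  ll <- 0
  for (r in seq_along(data)) {
    sdat <- data[[r]]
    counts <- counts_list[[r]]
    theta <- .session_theta(par, model, data, r)
    blk <- .session_blocks(sdat, counts, theta, model$detfn, learned)
    a <- cell_area(sdat$mask)
    sum_pdot <- sum(blk$pdot)
    if (counts$n > 0L) lse <- .logsumexp_cols(blk$log_pr)
    if (model$mode == "full") {
      ll <- ll +
        (if (counts$n > 0L) sum(log(a * theta$D) + lse) else 0) -
        a * theta$D * sum_pdot - lfactorial(counts$n)
    } else {
      if (sum_pdot <= 0) return(-Inf)
      if (counts$n > 0L) ll <- ll + sum(lse - log(sum_pdot))
    }
    if (!is.finite(ll))
      stop("non-finite log-likelihood in session ", names(data)[r])
  }
  ll
}

# ---- exported likelihood surface ------------------------------------------

#' Overall detection probability over a survey
#'
#' `p.(x) = 1 - prod_{s,k used} (1 - g(d(x, k)))`: the probability that an
#' animal centred at `x` is detected at least once.
#'
#' @param x data frame (or matrix) of centre coordinates `x`, `y` (km).
#' @param detectors data frame with `x`, `y` (km).
#' @param detfn a [detfn_spec()].
#' @param usage binary occasions x detectors matrix, or an integer number
#'   of occasions (all detectors active).
#' @return numeric vector of detection probabilities.
#' @export
pdot <- function(x, detectors, detfn, usage) {
  x <- as.data.frame(x)
  det <- as.data.frame(detectors)
  if (is.matrix(usage)) Sk <- colSums(usage)
  else Sk <- rep(as.integer(usage), nrow(det))
  d <- sqrt(outer(x$x, det$x, "-")^2 + outer(x$y, det$y, "-")^2)
  g <- detection_prob(detfn, d)
  as.numeric(-expm1(log1p(-g) %*% Sk))
}

#' Marginal likelihood of one animal's capture history
#'
#' `a sum_x D Pr(w_i | x)` for a single session with homogeneous density:
#' the animal's contribution to the full likelihood before logging.
#'
#' @param omega_i binary occasions x detectors matrix with at least one 1.
#' @param mask habitat mask.
#' @param detectors data frame with `x`, `y`.
#' @param detfn a [detfn_spec()].
#' @param D density in animals per 100 km^2.
#' @param usage optional binary occasions x detectors matrix.
#' @return scalar marginal likelihood.
#' @export
history_marginal <- function(omega_i, mask, detectors, detfn, D, usage = NULL) {
  omega_i <- as.matrix(omega_i)
  if (sum(omega_i) == 0L)
    stop("all-zero history: undetected animals are marginalised, not listed")
  det <- as.data.frame(detectors)
  S <- nrow(omega_i); K <- ncol(omega_i)
  if (is.null(usage)) usage <- matrix(1L, S, K)
  d <- sqrt(outer(mask$x, det$x, "-")^2 + outer(mask$y, det$y, "-")^2)
  g <- detection_prob(detfn, d)
  lg <- log(pmax(g, .LOGFLOOR)); ls <- log1p(-g)
  nk <- colSums(omega_i * usage)
  Sk <- colSums(usage)
  lpr <- lg %*% nk + ls %*% (Sk - nk)
  cell_area(mask) * (D / 100) * sum(exp(lpr))
}

#' Full multi-session SCR log-likelihood
#'
#' @param par named link-scale parameter vector (see [fit_scr()] for the
#'   layout: `D*` terms are log density per 100 km^2, `g0*` logit, `sigma`
#'   and `z` log).
#' @param data an [scr_data()].
#' @param model an [scr_model()] with `mode = "full"`.
#' @return log-likelihood value.
#' @export
full_loglik <- function(par, data, model) {
  stopifnot(inherits(data, "scr_data"), inherits(model, "scr_model"))
  if (model$mode != "full") stop("model mode is not 'full'")
  counts <- lapply(data, function(s)
    .session_counts(s$history, model$g0$type == "b"))
  .loglik_engine(par, model, data, counts)
}

#' Conditional (density-free) SCR log-likelihood
#'
#' @inheritParams full_loglik
#' @return log-likelihood value.
#' @export
conditional_loglik <- function(par, data, model) {
  stopifnot(inherits(data, "scr_data"), inherits(model, "scr_model"))
  if (model$mode != "conditional") stop("model mode is not 'conditional'")
  counts <- lapply(data, function(s)
    .session_counts(s$history, model$g0$type == "b"))
  .loglik_engine(par, model, data, counts)
}
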