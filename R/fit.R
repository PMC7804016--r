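# Maximum-likelihood fitting: quasi-Newton search on the link scale with a
# central-difference Hessian for the covariance of the estimates.

.num_hessian <- function(f, x, h_rel = 1e-4) {
  p <- length(x)
  h <- h_rel * pmax(1, abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in (i + 1L):p) {
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

.start_values <- function(model, data) {
  nm <- .param_names(model, data)
  par <- stats::setNames(numeric(length(nm)), nm)
  # sigma from pooled RPSV, falling back to half the mean trap spacing
  sig <- NA_real_
  for (s in data) {
    sig <- tryCatch(rpsv_sigma(s$history), error = function(e) NA_real_)
    if (is.finite(sig)) break
  }
  if (!is.finite(sig) || sig <= 0)
    sig <- 0.5 * station_spacing(data[[1L]]$history$traps)
  par[["sigma"]] <- log(sig)
  if (model$detfn == "HR") par[["z"]] <- log(2.5)
  # g0 from the per-animal, per-occasion detection rate
  rate <- mean(vapply(data, function(s) {
    n <- dim(s$history$omega)[1L]
    if (n == 0L) return(0.05)
    sum(s$history$omega) / (n * dim(s$history$omega)[2L])
  }, 0))
  g0s <- min(0.8, max(0.02, rate))
  par[grep("^g0", nm)] <- stats::qlogis(g0s)
  if (model$g0$type == "b") par[["g0.b"]] <- 0
  # D from individuals per mask area (per 100 km^2)
  if (model$mode == "full") {
    Ds <- vapply(data, function(s)
      max(0.2, 100 * dim(s$history$omega)[1L] / mask_area(s$mask)), 0)
    if (model$D$type == "session") {
      par[paste0("D.", names(data))] <- log(Ds)
    } else if (model$D$type == "cov") {
      par[["D.(Intercept)"]] <- log(mean(Ds))
    } else par[["D"]] <- log(mean(Ds))
  }
  par
}

#' Fit a multi-session SCR model by maximum likelihood
#'
#' Maximises the full or conditional likelihood (see [full_loglik()]) by
#' quasi-Newton search ([stats::nlminb()]) on the link scale: log density
#' per 100 km^2, logit g0, log sigma, log z, additive logit offset b.
#' Start values are automatic (g0 from raw detection rates, sigma from the
#' bias-adjusted pooled RPSV, density from individuals per mask area)
#' unless supplied. The covariance of the estimates is the inverse of the
#' central-difference Hessian of the negative log-likelihood.
#'
#' @param model an [scr_model()].
#' @param data an [scr_data()].
#' @param start optional named start vector on the link scale.
#' @param control list passed to [stats::nlminb()] (defaults:
#'   `iter.max = 500`, `eval.max = 1000`, `rel.tol = 1e-10`).
#' @return object of class `scr_fit`: `model`, `data`, `par` (MLE),
#'   `loglik`, `K` (free parameters), `vcov`, `converged`, `boundary`,
#'   `message`, `n` (individuals per session).
#' @export
fit_scr <- function(model, data, start = NULL, control = list()) {
  stopifnot(inherits(model, "scr_model"), inherits(data, "scr_data"))
  if (any(vapply(data, function(s) sum(s$history$usage) == 0L, TRUE)))
    stop("a session has zero sampling effort; the likelihood is flat")
  if (.n_total(data) == 0L)
    stop("no detected individuals in any session")
  learned <- model$g0$type == "b"
  counts <- lapply(data, function(s) .session_counts(s$history, learned))
  nm <- .param_names(model, data)
  if (is.null(start)) start <- .start_values(model, data)
  if (!all(nm %in% names(start)))
    stop("start values missing: ", paste(setdiff(nm, names(start)), collapse = ", "))
  start <- start[nm]
  # validate covariate availability before the guarded optimisation
  for (r in seq_along(data)) .session_theta(start, model, data, r)
  negll <- function(p) {
    names(p) <- nm
    v <- tryCatch(-.loglik_engine(p, model, data, counts),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  ctrl <- utils::modifyList(
    list(iter.max = 500, eval.max = 1000, rel.tol = 1e-10), control)
  opt <- stats::nlminb(start, negll, control = ctrl)
  par <- stats::setNames(opt$par, nm)
  H <- .num_hessian(negll, par)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(par), length(par)))
  dimnames(V) <- list(nm, nm)
  ok_cov <- all(is.finite(diag(V))) && all(diag(V) > 0)
  boundary <- any(abs(par[grep("^g0", nm)]) > 8)
  structure(list(
    model = model, data = data, par = par, loglik = -opt$objective,
    K = length(par), vcov = V, converged = opt$convergence == 0 && ok_cov,
    boundary = boundary, message = opt$message,
    n = vapply(data, function(s) dim(s$history$omega)[1L], 0L)),
    class = "scr_fit")
}

#' @export
print.scr_fit <- function(x, ...) {
  cat("SCR fit (", x$model$mode, " likelihood, ", x$model$detfn, "): D ",
      x$model$D_label, ", g0 ", x$model$g0_label, "\n", sep = "")
  cat("  logLik ", format(x$loglik, digits = 8), "  K ", x$K,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  se <- sqrt(pmax(diag(x$vcov), 0))
  print(round(data.frame(estimate = x$par, SE = se), 4))
  invisible(x)
}

#' @export
coef.scr_fit <- function(object, ...) object$par

#' @export
vcov.scr_fit <- function(object, ...) object$vcov

#' @export
logLik.scr_fit <- function(object, ...) {
  structure(object$loglik, df = object$K, class = "logLik")
}

#' Model label for reporting
#'
#' @param fit an `scr_fit`.
#' @return character label like `"D~session g0~session"`.
#' @export
model_label <- function(fit) {
  if (fit$model$mode == "conditional")
    paste0("g0", fit$model$g0_label)
  else
    paste0("D", fit$model$D_label, " g0", fit$model$g0_label)
}

#' Serialize a fit to JSON
#'
#' Writes the model structure, link-scale estimates with standard errors,
#' log-likelihood, parameter count and convergence flag.
#'
#' @param fit an `scr_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  se <- sqrt(pmax(diag(fit$vcov), 0))
  jsonlite::write_json(list(
    model = list(D = fit$model$D_label, g0 = fit$model$g0_label,
                 detfn = fit$model$detfn, mode = fit$model$mode),
    estimates = data.frame(parameter = names(fit$par),
                           estimate = as.numeric(fit$par), SE = se),
    loglik = fit$loglik, K = fit$K, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
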