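# Independent brute-force implementations of the SCR likelihood, coded as
# plain loops straight from the model definition. They share no code with
# the package's vectorised engine and serve as the reference on tiny
# instances.

gdet_ref <- function(detfn, d, g0, sigma, z = NULL) {
  if (detfn == "HN") return(g0 * exp(-d^2 / (2 * sigma^2)))
  if (detfn == "EX") return(g0 * exp(-d / sigma))
  if (d == 0) return(g0)
  g0 * (1 - exp(-(d / sigma)^(-z)))
}

# Pr(omega_i | x) by looping occasions and detectors; optional permanent
# learned response: g0 becomes plogis(qlogis(g0) + b) on occasions after
# the animal's first detection.
pr_history_ref <- function(om_i, x, y, traps, usage, detfn, g0, sigma,
                           z = NULL, b = NULL) {
  S <- nrow(om_i); K <- ncol(om_i)
  f <- if (!is.null(b)) min(which(rowSums(om_i) > 0)) else Inf
  pr <- 1
  for (s in seq_len(S)) for (k in seq_len(K)) {
    if (usage[s, k] == 0) next
    g0s <- if (!is.null(b) && s > f) plogis(qlogis(g0) + b) else g0
    d <- sqrt((x - traps$x[k])^2 + (y - traps$y[k])^2)
    g <- gdet_ref(detfn, d, g0s, sigma, z)
    pr <- pr * if (om_i[s, k] == 1) g else (1 - g)
  }
  pr
}

pdot_ref <- function(x, y, traps, usage, detfn, g0, sigma, z = NULL) {
  surv <- 1
  for (s in seq_len(nrow(usage))) for (k in seq_len(ncol(usage))) {
    if (usage[s, k] == 0) next
    d <- sqrt((x - traps$x[k])^2 + (y - traps$y[k])^2)
    surv <- surv * (1 - gdet_ref(detfn, d, g0, sigma, z))
  }
  1 - surv
}

slice_animal <- function(omega, i) {
  matrix(omega[i, , , drop = FALSE], dim(omega)[2], dim(omega)[3])
}

# full single-session log-likelihood with homogeneous density D (per km^2)
full_loglik_ref <- function(omega, maskxy, a, traps, usage, detfn, D, g0,
                            sigma, z = NULL, b = NULL) {
  n <- dim(omega)[1]
  ll <- 0
  for (i in seq_len(n)) {
    tot <- 0
    for (m in seq_len(nrow(maskxy)))
      tot <- tot + pr_history_ref(slice_animal(omega, i),
                                  maskxy$x[m], maskxy$y[m], traps, usage,
                                  detfn, g0, sigma, z, b)
    ll <- ll + log(a * D * tot)
  }
  lam <- 0
  for (m in seq_len(nrow(maskxy)))
    lam <- lam + pdot_ref(maskxy$x[m], maskxy$y[m], traps, usage, detfn,
                          g0, sigma, z)
  ll - a * D * lam - lfactorial(n)
}

conditional_loglik_ref <- function(omega, maskxy, traps, usage, detfn, g0,
                                   sigma, z = NULL, b = NULL) {
  n <- dim(omega)[1]
  sumpd <- 0
  for (m in seq_len(nrow(maskxy)))
    sumpd <- sumpd + pdot_ref(maskxy$x[m], maskxy$y[m], traps, usage, detfn,
                              g0, sigma, z)
  ll <- 0
  for (i in seq_len(n)) {
    tot <- 0
    for (m in seq_len(nrow(maskxy)))
      tot <- tot + pr_history_ref(slice_animal(omega, i),
                                  maskxy$x[m], maskxy$y[m], traps, usage,
                                  detfn, g0, sigma, z, b)
    ll <- ll + log(tot / sumpd)
  }
  ll
}

# random tiny instance: <= 6 cells, <= 3 detectors, <= 3 occasions, every
# animal detected at least once
random_tiny_instance <- function(seed) {
  set.seed(seed)
  M <- sample(2:6, 1); K <- sample(1:3, 1); S <- sample(1:3, 1)
  n <- sample(1:3, 1)
  maskxy <- data.frame(x = runif(M, 0, 3), y = runif(M, 0, 3))
  spacing <- runif(1, 0.4, 1.2)
  traps <- data.frame(station_id = sprintf("t%d", 1:K),
                      x = runif(K, 0, 3), y = runif(K, 0, 3))
  usage <- matrix(rbinom(S * K, 1, 0.8), S, K)
  if (all(usage == 0)) usage[1, 1] <- 1L
  omega <- array(0L, dim = c(n, S, K))
  exposed <- which(usage == 1L, arr.ind = TRUE)
  for (i in seq_len(n)) {
    omega[i, , ][usage == 1L] <- rbinom(sum(usage), 1, 0.45)
    if (sum(omega[i, , ]) == 0) {
      pick <- exposed[sample(nrow(exposed), 1), ]
      omega[i, pick[1], pick[2]] <- 1L
    }
  }
  list(maskxy = maskxy, spacing = spacing, a = spacing^2, traps = traps,
       usage = usage, omega = omega,
       D = runif(1, 1, 12), g0 = runif(1, 0.1, 0.6),
       sigma = runif(1, 0.5, 2), z = runif(1, 1.2, 3.5))
}

tiny_to_scr_data <- function(inst, session = "s1") {
  mask <- fencescr:::.new_mask(inst$maskxy, inst$spacing, "clipped")
  h <- capture_history(inst$omega, inst$traps, inst$usage, session)
  scr_data(h, mask)
}

# one simulated reference survey used by several fitting tests
make_test_survey <- function(seed, area = 400, n_stations = 36, spacing = 2,
                             config = sim_config(seed = NULL), buffer = 4,
                             mask_spacing = 1) {
  set.seed(seed)
  geom <- make_reserve(square_fence(area, c(-sqrt(area) / 2, -sqrt(area) / 2)),
                       n_stations, spacing)
  centers <- simulate_centers(geom, config)
  history <- simulate_capture_history(centers, geom, config)
  mask <- build_buffered_mask(geom$stations, buffer, spacing = mask_spacing)
  list(geom = geom, centers = centers, history = history, mask = mask)
}
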