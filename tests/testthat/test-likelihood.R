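test_that("detection functions evaluate their closed forms", {
  hn <- detfn_spec("HN", 0.3, 1)
  hr <- detfn_spec("HR", 0.3, 1, z = 2)
  ex <- detfn_spec("EX", 0.3, 1)
  # g0 at distance zero for all three (hazard-rate limit)
  expect_equal(detection_prob(hn, 0), 0.3)
  expect_equal(detection_prob(hr, 0), 0.3)
  expect_equal(detection_prob(ex, 0), 0.3)
  expect_equal(detection_prob(hn, 1), 0.3 * exp(-0.5))
  expect_equal(detection_prob(ex, 2), 0.3 * exp(-2))
  expect_equal(detection_prob(hr, 2), 0.3 * (1 - exp(-2^(-2))))
  # hazard rate has the heavier tail
  expect_gt(detection_prob(hr, 5), detection_prob(hn, 5))
  expect_error(detection_prob(hn, -1), "non-negative")
  expect_error(detfn_spec("HN", 1.2, 1))
  expect_error(detfn_spec("HR", 0.3, 1))
})

test_that("pdot is the complement product over used occasion-detector pairs", {
  df <- detfn_spec("HN", 0.2, 1)
  det1 <- data.frame(x = 0, y = 0)
  # 1 detector, 1 occasion: pdot = g(d)
  expect_equal(pdot(data.frame(x = 1, y = 0), det1, df, 1L),
               0.2 * exp(-0.5))
  # g = 0.2 at distance 0, 2 occasions: 1 - 0.8^2
  expect_equal(pdot(data.frame(x = 0, y = 0), det1, df, 2L), 0.36)
  # 3 detectors, 4 occasions, random geometry vs explicit product
  set.seed(5)
  det3 <- data.frame(x = runif(3, 0, 3), y = runif(3, 0, 3))
  usage <- matrix(rbinom(12, 1, 0.7), 4, 3)
  pts <- data.frame(x = runif(6, 0, 3), y = runif(6, 0, 3))
  got <- pdot(pts, det3, df, usage)
  want <- vapply(seq_len(6), function(i)
    pdot_ref(pts$x[i], pts$y[i], det3, usage, "HN", 0.2, 1), 0)
  expect_equal(got, want)
})

test_that("history_marginal equals the exhaustive cell sum and normalizes", {
  set.seed(11)
  mask <- build_clipped_mask(square_fence(4), spacing = 1)   # 4 cells
  traps <- data.frame(station_id = c("a", "b"), x = c(0.5, 1.5), y = c(1, 1))
  df <- detfn_spec("HN", 0.25, 0.8)
  om <- matrix(c(1L, 0L, 0L, 1L), 2, 2)   # 2 occasions x 2 detectors
  got <- history_marginal(om, mask, traps, df, D = 6)
  want <- 0
  for (m in seq_len(4))
    want <- want + pr_history_ref(om, mask$x[m], mask$y[m], traps,
                                  matrix(1L, 2, 2), "HN", 0.25, 0.8)
  want <- 1 * (6 / 100) * want
  expect_equal(got, want)
  # single cell, single detector/occasion, detection present: a * D * g(d)
  mask1 <- fencescr:::.new_mask(data.frame(x = 0, y = 0), 1, "clipped")
  d0 <- sqrt(0.5^2 + 1^2)
  expect_equal(history_marginal(matrix(1L, 1, 1), mask1, traps[1, ], df, 6),
               0.06 * detection_prob(df, d0))
  expect_error(history_marginal(matrix(0L, 2, 2), mask, traps, df, 6),
               "all-zero")
  # probabilities over all 2^(S K) histories sum to 1 at any fixed centre
  S <- 2; K <- 2
  tot <- 0
  for (code in 0:(2^(S * K) - 1)) {
    om2 <- matrix(as.integer(intToBits(code)[1:(S * K)]), S, K)
    tot <- tot + pr_history_ref(om2, 0.3, 0.9, traps, matrix(1L, S, K),
                                "HN", 0.25, 0.8)
  }
  expect_equal(tot, 1)
})

test_that("full and conditional likelihoods match the brute-force oracle on tiny instances", {
  for (seed in 1:24) {
    inst <- random_tiny_instance(seed)
    data <- tiny_to_scr_data(inst)
    for (detfn in c("HN", "HR", "EX")) {
      parf <- c(D = log(inst$D), g0 = qlogis(inst$g0), sigma = log(inst$sigma))
      parc <- c(g0 = qlogis(inst$g0), sigma = log(inst$sigma))
      z <- NULL
      if (detfn == "HR") {
        parf <- c(parf, z = log(inst$z)); parc <- c(parc, z = log(inst$z))
        z <- inst$z
      }
      got_f <- full_loglik(parf, data, scr_model("~1", "~1", detfn, "full"))
      want_f <- full_loglik_ref(inst$omega, inst$maskxy, inst$a, inst$traps,
                                inst$usage, detfn, inst$D / 100, inst$g0,
                                inst$sigma, z)
      expect_lt(abs(got_f - want_f), 1e-10)
      got_c <- conditional_loglik(parc, data,
                                  scr_model("~1", "~1", detfn, "conditional"))
      want_c <- conditional_loglik_ref(inst$omega, inst$maskxy, inst$traps,
                                       inst$usage, detfn, inst$g0,
                                       inst$sigma, z)
      expect_lt(abs(got_c - want_c), 1e-10)
    }
  }
})

test_that("the learned-response likelihood matches a first-capture-split oracle", {
  inst <- random_tiny_instance(99)
  # force multiple occasions so the response can switch on
  set.seed(99)
  S <- 3; K <- 2; n <- 2
  traps <- data.frame(station_id = c("a", "b"), x = c(0.5, 2), y = c(1, 1))
  usage <- matrix(1L, S, K)
  omega <- array(0L, dim = c(n, S, K))
  omega[1, 1, 1] <- 1L; omega[1, 3, 2] <- 1L; omega[2, 2, 2] <- 1L
  maskxy <- data.frame(x = c(0, 1, 2, 3), y = rep(1, 4))
  mask <- fencescr:::.new_mask(maskxy, 0.9, "clipped")
  data <- scr_data(capture_history(omega, traps, usage), mask)
  b <- 0.7
  par <- c(D = log(4), g0 = qlogis(0.3), g0.b = b, sigma = log(1.1))
  got <- full_loglik(par, data, scr_model("~1", "~b", "HN", "full"))
  a <- 0.81
  want <- 0
  for (i in 1:2) {
    tot <- 0
    for (m in 1:4)
      tot <- tot + pr_history_ref(slice_animal(omega, i), maskxy$x[m],
                                  maskxy$y[m], traps, usage, "HN", 0.3, 1.1,
                                  b = b)
    want <- want + log(a * 0.04 * tot)
  }
  lam <- 0   # undetected-animal term uses the pre-response g0
  for (m in 1:4)
    lam <- lam + pdot_ref(maskxy$x[m], maskxy$y[m], traps, usage, "HN", 0.3, 1.1)
  want <- want - a * 0.04 * lam - lfactorial(2)
  expect_lt(abs(got - want), 1e-10)
})

test_that("likelihoods obey independence, invariance and scaling identities", {
  inst <- random_tiny_instance(7)
  data1 <- tiny_to_scr_data(inst, "s1")
  m <- scr_model("~1", "~1", "HN", "full")
  par <- c(D = log(inst$D), g0 = qlogis(inst$g0), sigma = log(inst$sigma))
  ll1 <- full_loglik(par, data1, m)
  # two identical independent sessions double the log-likelihood
  mask <- fencescr:::.new_mask(inst$maskxy, inst$spacing, "clipped")
  h1 <- capture_history(inst$omega, inst$traps, inst$usage, "s1")
  h2 <- capture_history(inst$omega, inst$traps, inst$usage, "s2")
  data2 <- scr_data(list(h1, h2), list(mask, mask))
  expect_equal(full_loglik(par, data2, m), 2 * ll1)
  # permuting individuals, detectors or occasions leaves the value unchanged
  set.seed(1)
  pi_i <- sample(dim(inst$omega)[1]); pi_s <- sample(dim(inst$omega)[2])
  pi_k <- sample(dim(inst$omega)[3])
  hp <- capture_history(inst$omega[pi_i, pi_s, pi_k, drop = FALSE],
                        inst$traps[pi_k, ], inst$usage[pi_s, pi_k, drop = FALSE],
                        "s1")
  expect_equal(full_loglik(par, scr_data(hp, mask), m), ll1)
  # doubling D while halving the cell area leaves both the marginal and
  # Poisson terms (hence the whole likelihood) unchanged
  half <- fencescr:::.new_mask(inst$maskxy, inst$spacing / sqrt(2), "clipped")
  par2 <- par; par2["D"] <- par["D"] + log(2)
  expect_equal(full_loglik(par2, scr_data(h1, half), m), ll1)
})
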