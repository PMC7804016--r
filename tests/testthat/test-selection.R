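test_that("aicc implements the small-sample correction", {
  expect_equal(aicc(0, 0, 50), 0)
  expect_equal(aicc(-100, 3, 50), 200 + 6 + 24 / 46)
  # converges to AIC as n grows
  expect_lt(abs(aicc(-100, 3, 1e9) - 206), 1e-6)
  expect_error(aicc(-10, 5, 6), "n > K")
})

test_that("akaike weights follow the exp(-delta/2) rule and known table values", {
  expect_equal(akaike_weights(c(5, 5)), c(0.5, 0.5))
  expect_equal(akaike_weights(0), 1)
  w <- akaike_weights(c(0, 6.212))
  expect_equal(round(w, 4), c(0.9571, 0.0429))
  # invariant to adding a constant to every AICc
  expect_equal(akaike_weights(c(3, 9.212)), w)
})

test_that("rank_models sorts, weights, flags retention and refuses mixed modes", {
  sv <- make_test_survey(60, config = sim_config(true_density = 10,
                                                 n_occasions = 25))
  dat <- scr_data(sv$history, sv$mask)
  f1 <- fit_scr(scr_model("~1", "~1", "HN", "full"), dat)
  f2 <- fit_scr(scr_model("~1", "~1", "EX", "full"), dat)
  tab <- rank_models(list(f1, f2))
  expect_s3_class(tab, "model_table")
  expect_equal(tab$dAICc[1], 0)
  expect_equal(sum(tab$weight), 1)
  expect_true(tab$retained[1])
  expect_true(all(diff(tab$AICc) >= 0))
  single <- rank_models(list(f1))
  expect_equal(single$weight, 1)
  fc <- fit_scr(scr_model("~1", "~1", "HN", "conditional"), dat)
  expect_error(rank_models(list(f1, fc)), "full and conditional")
})

test_that("an irrelevant covariate cannot lower the likelihood but pays in AICc", {
  set.seed(510)
  cfg <- sim_config(true_density = 10, n_occasions = 15)
  svs <- lapply(1:3, function(r) {
    geom <- make_reserve(square_fence(196, c(-7, -7)), 16, 2)
    cs <- simulate_centers(geom, cfg)
    list(h = simulate_capture_history(cs, geom, cfg, session = paste0("r", r)),
         mask = build_buffered_mask(geom$stations, 4, spacing = 1))
  })
  covs <- data.frame(session = c("r1", "r2", "r3"), junk = zscore(rnorm(3)))
  dat <- scr_data(lapply(svs, `[[`, "h"), lapply(svs, `[[`, "mask"), covs)
  f0 <- fit_scr(scr_model("~1", "~1", "HN", "full"), dat)
  f1 <- fit_scr(scr_model("~junk", "~1", "HN", "full"), dat)
  expect_gte(f1$loglik, f0$loglik - 1e-4)
  tab <- rank_models(list(f0, f1))
  expect_lt(f1$loglik - f0$loglik, 2)   # junk adds almost no fit
})

test_that("derived density honours the perfect-detection and area-scaling identities", {
  # saturate detection so pdot ~ 1 over a 100 km^2 mask with n = 7
  mask <- build_clipped_mask(square_fence(100), spacing = 1)
  traps <- expand.grid(x = seq(0.5, 9.5, 1), y = seq(0.5, 9.5, 1))
  traps <- data.frame(station_id = sprintf("t%d", seq_len(nrow(traps))), traps)
  S <- 60
  om <- array(0L, dim = c(7, S, nrow(traps)))
  for (i in 1:7) om[i, 1, i] <- 1L
  h <- capture_history(om, traps, matrix(1L, S, nrow(traps)), "s1")
  dat <- scr_data(h, mask)
  fit <- fit_scr(scr_model("~1", "~1", "HN", "conditional"), dat,
                 start = c(g0 = qlogis(0.9), sigma = log(3)),
                 control = list(iter.max = 5))
  fit$par <- c(g0 = qlogis(0.999), sigma = log(5))  # evaluate identity at fixed theta
  dd <- suppressWarnings(derived_density(fit))
  expect_equal(dd$D, 7, tolerance = 1e-6)
  expect_true(dd$lcl <= dd$D && dd$D <= dd$ucl)
  # halving the mask area at fixed theta and n doubles the estimate
  halfmask <- fencescr:::.new_mask(as.data.frame(mask)[1:50, ], 1, "clipped")
  fit2 <- fit
  fit2$data <- scr_data(h, halfmask)
  dd2 <- suppressWarnings(derived_density(fit2))
  expect_equal(dd2$D, 2 * dd$D, tolerance = 1e-6)
})

test_that("region_n returns expected and realized population sizes", {
  # perfect detection: realized N equals n
  mask <- build_clipped_mask(square_fence(100), spacing = 1)
  traps <- expand.grid(x = seq(0.5, 9.5, 1), y = seq(0.5, 9.5, 1))
  traps <- data.frame(station_id = sprintf("t%d", seq_len(nrow(traps))), traps)
  om <- array(0L, dim = c(7, 60, nrow(traps)))
  for (i in 1:7) om[i, 1, i] <- 1L
  h <- capture_history(om, traps, matrix(1L, 60, nrow(traps)), "s1")
  fit <- fit_scr(scr_model("~1", "~1", "HN", "conditional"),
                 scr_data(h, mask), start = c(g0 = qlogis(0.9), sigma = log(3)),
                 control = list(iter.max = 5))
  fit$par <- c(g0 = qlogis(0.999), sigma = log(5))
  rn <- region_n(fit)
  expect_equal(rn$realized, 7, tolerance = 1e-6)
  expect_equal(rn$expected, 7, tolerance = 1e-6)   # D-hat = 7 per 100 km^2
  # D = 2 per 100 km^2 over a 400 km^2 region: expected N = 8
  sv <- make_test_survey(61, config = sim_config(true_density = 8,
                                                 n_occasions = 20))
  ff <- fit_scr(scr_model("~1", "~1", "HN", "full"),
                scr_data(sv$history, sv$mask))
  ff$par["D"] <- log(2)
  rn2 <- region_n(ff)
  expect_equal(rn2$expected, 2 / 100 * mask_area(sv$mask), tolerance = 1e-9)
  expect_gte(rn2$realized, rn2$n)
  expect_error(region_n(ff, region = data.frame(x = 1e3, y = 1e3)),
               "not a subset")
})

test_that("fx_total integrates to the realized population size", {
  cfg <- sim_config(true_density = 10, n_occasions = 25)
  sv <- make_test_survey(62, config = cfg)
  fit <- fit_scr(scr_model("~1", "~1", "HN", "full"),
                 scr_data(sv$history, sv$mask))
  fx <- fx_total(fit)
  a <- cell_area(sv$mask)
  expect_true(all(fx$fx_total >= 0))
  # each observed animal's posterior integrates to one
  n <- fit$n[[1]]
  expect_equal(a * sum(fx$fx_observed), n, tolerance = 1e-8)
  rn <- region_n(fit)
  expect_equal(a * sum(fx$fx_total), rn$realized, tolerance = 1e-8)
  expect_equal(attr(fx, "realized_n"), rn$realized, tolerance = 1e-8)
  # an animal detected repeatedly at one station peaks beside it
  om <- fit$data[[1]]$history$omega
  counts <- apply(om, 1, sum)
  i <- which.max(counts)
  k <- which.max(apply(om[i, , , drop = FALSE], 3, sum))
  lpr <- fencescr:::.session_blocks(
    fit$data[[1]], fencescr:::.session_counts(fit$data[[1]]$history, FALSE),
    fencescr:::.session_theta(fit$par, fit$model, fit$data, 1),
    "HN", FALSE)$log_pr
  best <- which.max(lpr[, i])
  dpk <- sqrt((fit$data[[1]]$mask$x[best] - fit$data[[1]]$history$traps$x[k])^2 +
              (fit$data[[1]]$mask$y[best] - fit$data[[1]]$history$traps$y[k])^2)
  expect_lt(dpk, 3)
})

test_that("model tables write to CSV", {
  sv <- make_test_survey(63, config = sim_config(true_density = 10,
                                                 n_occasions = 20))
  f1 <- fit_scr(scr_model("~1", "~1", "HN", "full"),
                scr_data(sv$history, sv$mask))
  p <- tempfile(fileext = ".csv")
  write_model_table(rank_models(list(f1)), p)
  back <- read.csv(p)
  expect_equal(back$K, 3)
  expect_equal(back$weight, 1)
})
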