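test_that("fit_scr recovers simulation truth for a standard survey", {
  cfg <- sim_config(true_density = 5, g0_true = 0.2, sigma_true = 1,
                    n_occasions = 40)
  sv <- make_test_survey(2024, config = cfg)
  fit <- fit_scr(scr_model("~1", "~1", "HN", "full"),
                 scr_data(sv$history, sv$mask))
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(coef(fit)["D"] - log(5)) / se["D"], 3)
  expect_lt(abs(coef(fit)["g0"] - qlogis(0.2)) / se["g0"], 3)
  expect_lt(abs(coef(fit)["sigma"] - log(1)) / se["sigma"], 3)
})

test_that("refitting from the MLE is a fixed point and fits are deterministic", {
  cfg <- sim_config(true_density = 8, n_occasions = 20)
  sv <- make_test_survey(5, config = cfg)
  data <- scr_data(sv$history, sv$mask)
  m <- scr_model("~1", "~1", "HN", "full")
  fit1 <- fit_scr(m, data)
  fit2 <- fit_scr(m, data, start = coef(fit1))
  expect_lt(abs(fit1$loglik - fit2$loglik), 1e-6)
  fit3 <- fit_scr(m, data)
  expect_identical(coef(fit1), coef(fit3))
})

test_that("full and conditional fits agree on the detection parameters", {
  # with homogeneous density the full likelihood profiles to the
  # conditional one, so the detection MLEs coincide
  cfg <- sim_config(true_density = 10, n_occasions = 25)
  sv <- make_test_survey(77, config = cfg)
  maskc <- build_buffered_mask(sv$geom$stations, 4, spacing = 1)
  dat <- scr_data(sv$history, maskc)
  ff <- fit_scr(scr_model("~1", "~1", "HN", "full"), dat)
  fc <- fit_scr(scr_model("~1", "~1", "HN", "conditional"), dat)
  expect_lt(abs(coef(ff)["g0"] - coef(fc)["g0"]), 1e-3)
  expect_lt(abs(coef(ff)["sigma"] - coef(fc)["sigma"]), 1e-3)
  # and the Horvitz-Thompson density from the conditional fit matches the
  # full-likelihood density MLE
  dH <- derived_density(fc)$D
  expect_lt(abs(dH - exp(coef(ff)["D"])) / dH, 0.05)
})

test_that("session-structured models expand the parameter vector correctly", {
  cfg <- sim_config(true_density = 10, n_occasions = 15)
  set.seed(300)
  svs <- lapply(1:3, function(r) {
    geom <- make_reserve(square_fence(256, c(-8, -8)), 16, 2)
    cs <- simulate_centers(geom, cfg)
    h <- simulate_capture_history(cs, geom, cfg, session = paste0("r", r))
    list(h = h, mask = build_buffered_mask(geom$stations, 4, spacing = 1))
  })
  dat <- scr_data(lapply(svs, `[[`, "h"), lapply(svs, `[[`, "mask"))
  fit <- fit_scr(scr_model("~session", "~session", "HN", "full"), dat)
  # 3 D + 3 g0 + sigma = 7 free parameters (the Table-2 counting rule)
  expect_equal(fit$K, 7L)
  expect_true(all(c("D.r1", "D.r2", "D.r3", "g0.r1", "sigma") %in%
                  names(coef(fit))))
  fitHR <- scr_model("~session", "~session", "HR", "full")
  expect_equal(length(fencescr:::.param_names(fitHR, dat)), 8L)
})

test_that("covariate models use the session covariate on the link scale", {
  cfg <- sim_config(true_density = 12, n_occasions = 15)
  set.seed(301)
  svs <- lapply(1:3, function(r) {
    geom <- make_reserve(square_fence(196, c(-7, -7)), 16, 2)
    cs <- simulate_centers(geom, cfg)
    h <- simulate_capture_history(cs, geom, cfg, session = paste0("r", r))
    list(h = h, mask = build_buffered_mask(geom$stations, 4, spacing = 1))
  })
  dat <- scr_data(lapply(svs, `[[`, "h"), lapply(svs, `[[`, "mask"),
                  covariates = data.frame(session = c("r1", "r2", "r3"),
                                          prey = c(-1, 0, 1)))
  fit <- fit_scr(scr_model("~prey", "~1", "HN", "full"), dat)
  expect_true(all(c("D.(Intercept)", "D.prey") %in% names(coef(fit))))
  # the fitted session density obeys log D_r = intercept + beta * cov_r
  th <- fencescr:::.session_theta(coef(fit), fit$model, fit$data, 3)
  expect_equal(log(100 * th$D),
               unname(coef(fit)["D.(Intercept)"] + coef(fit)["D.prey"]))
  # a model naming a missing covariate fails loudly
  expect_error(fit_scr(scr_model("~lions", "~1", "HN", "full"), dat),
               "missing covariate")
})

test_that("degenerate inputs are rejected rather than silently fitted", {
  sv <- make_test_survey(8, config = sim_config(true_density = 8,
                                                n_occasions = 10))
  h0 <- sv$history
  h0$usage[] <- 0L
  expect_error(scr_data(h0, sv$mask), "no sampling effort")
  empty <- capture_history(array(integer(), dim = c(0, 5, 36)),
                           sv$geom$stations, matrix(1L, 5, 36), "empty")
  expect_error(fit_scr(scr_model("~1", "~1", "HN", "full"),
                       scr_data(empty, sv$mask)), "no detected individuals")
})

test_that("the density estimate is stable under mask refinement", {
  cfg <- sim_config(true_density = 8, n_occasions = 30)
  sv <- make_test_survey(55, config = cfg)
  m <- scr_model("~1", "~1", "HN", "full")
  coarse <- build_buffered_mask(sv$geom$stations, 4, spacing = 1)
  fine <- build_buffered_mask(sv$geom$stations, 4, spacing = 0.5)
  D1 <- exp(coef(fit_scr(m, scr_data(sv$history, coarse)))["D"])
  D2 <- exp(coef(fit_scr(m, scr_data(sv$history, fine)))["D"])
  expect_lt(abs(D1 - D2) / D2, 0.02)
})

test_that("fitting b to data simulated without a learned response finds none", {
  hits <- 0L
  reps <- 8L
  for (r in seq_len(reps)) {
    cfg <- sim_config(true_density = 10, n_occasions = 30)
    sv <- make_test_survey(400 + r, config = cfg)
    fit <- fit_scr(scr_model("~1", "~b", "HN", "full"),
                   scr_data(sv$history, sv$mask))
    bz <- abs(coef(fit)["g0.b"]) / sqrt(fit$vcov["g0.b", "g0.b"])
    if (is.finite(bz) && bz < 3) hits <- hits + 1L
  }
  expect_gte(hits, reps - 1L)
})

test_that("fits serialize to JSON with estimates and convergence state", {
  sv <- make_test_survey(6, config = sim_config(true_density = 8,
                                                n_occasions = 15))
  fit <- fit_scr(scr_model("~1", "~1", "HN", "full"),
                 scr_data(sv$history, sv$mask))
  p <- tempfile(fileext = ".json")
  write_fit_json(fit, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$loglik, fit$loglik)
  expect_equal(j$K, 3)
  expect_true(j$converged)
})
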