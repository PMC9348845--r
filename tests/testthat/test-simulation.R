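test_that("scenario families map onto their dose designs", {
  s7 <- dr_scenario("7")
  expect_equal(length(s7$doses), 7)
  expect_equal(s7$doses[1], 1 / 30, tolerance = 1e-12)
  expect_equal(s7$doses[7], 30, tolerance = 1e-12)
  expect_equal(dr_scenario("6noL")$doses, s7$doses[-7])
  expect_equal(dr_scenario("6noS")$doses, s7$doses[-1])
  le <- dr_scenario("7lessE")
  expect_equal(range(le$doses), c(0.1, 10), tolerance = 1e-12)
  # the less-extreme design has no design point in the extreme zone
  expect_false(any(classify_extreme(effect_at_dose(le$doses, 0, 1))))
  expect_true(any(classify_extreme(effect_at_dose(s7$doses, 0, 1))))
  expect_equal(dr_scenario("7NCP")$precision_dose_slope, 0.3)
  expect_equal(s7$precision_dose_slope, 0)
})

test_that("dataset generation is deterministic in (seed, replicate)", {
  sc <- dr_scenario("7", seed = 42)
  a <- generate_dataset(sc, 3)
  b <- generate_dataset(sc, 3)
  expect_identical(a, b)
  c2 <- generate_dataset(sc, 4)
  expect_false(identical(a$response, c2$response))
  # different scenario seed, different data
  expect_false(identical(generate_dataset(dr_scenario("7", seed = 43), 3)$response,
                         a$response))
  # and the global RNG stream is left untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_dataset(sc, 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("the noiseless limit reproduces the true curve", {
  sc <- dr_scenario("7", sigma = 1e-8, seed = 5)
  dat <- generate_dataset(sc, 1)
  expect_lt(max(abs(dat$response - effect_at_dose(dat$dose, 0, 1))), 1e-3)
  scb <- dr_scenario("7", error_law = "beta", phi = 1e6, seed = 5)
  datb <- generate_dataset(scb, 1)
  expect_lt(max(abs(datb$response - effect_at_dose(datb$dose, 0, 1))), 1e-2)
})

test_that("beta noise is heteroscedastic: larger variance mid-curve", {
  # doses at effect 0.05 and 0.5; Var = mu(1-mu)/(1+phi)
  sc <- dr_scenario("var-check", doses = c(dose_for_effect(0.05, 0, 1), 1),
                    replicates = 2000, error_law = "beta", seed = 8)
  dat <- generate_dataset(sc, 1)
  v <- tapply(dat$response, dat$dose, var)
  mid <- v[[as.character(1)]]
  edge <- v[[setdiff(names(v), "1")]]
  expect_gt(mid, edge)
  expect_equal(mid, 0.25 / 101, tolerance = 0.15)
  expect_equal(edge, 0.05 * 0.95 / 101, tolerance = 0.2)
})

test_that("extreme-response classification is boundary-inclusive", {
  expect_true(classify_extreme(0.05))
  expect_true(classify_extreme(0.95))
  expect_false(classify_extreme(0.5))
  expect_true(classify_extreme(0.951))
  expect_false(classify_extreme(0.0501))
  expect_equal(classify_extreme(c(0.01, 0.5, 0.99)), c(TRUE, FALSE, TRUE))
})

test_that("least squares recovers noiseless data exactly and respects rescaling", {
  q <- seq(-3, 3, length.out = 7)
  d <- exp(q)
  y <- inv_logit(0.5 + 1.3 * q)
  dat <- dose_response_data(d, y)
  f <- suppressWarnings(fit_lrm(dat))  # lm warns on an exact interpolation
  expect_equal(unname(f$beta[1, ]), c(0.5, 1.3), tolerance = 1e-10)
  f10 <- suppressWarnings(fit_lrm(dose_response_data(d * 10, y)))
  expect_equal(sign(f10$beta[1, 2]), sign(f$beta[1, 2]))
  expect_equal(unname(f10$beta[1, 2]), 1.3, tolerance = 1e-10)
  expect_error(fit_lrm(dose_response_data(c(1, 10), c(0.3, 0.7))),
               "fewer than 3")
})

test_that("heavy-tailed fit agrees with least squares on clean data", {
  dat <- make_beta_dataset(55)
  lf <- fit_lrm(dat)
  hf <- fit_hlrm(dat)
  se <- sqrt(diag(lf$vcov_list[[1]]))
  expect_lt(abs(hf$beta[1, 1] - lf$beta[1, 1]), 3 * se[1])
  expect_lt(abs(hf$beta[1, 2] - lf$beta[1, 2]), 3 * se[2])
  # deterministic given fixed data
  expect_identical(fit_hlrm(dat)$beta, hf$beta)
})

test_that("the perturbed extreme point drags least squares more than the beta fit", {
  clean <- perturbed_oncurve_dataset(low = 0.005)
  dirty <- perturbed_oncurve_dataset(low = 1e-6)
  logdm <- function(beta) -beta[1] / beta[2]
  d_lrm <- abs(logdm(fit_lrm(dirty)$beta[1, ]) - logdm(fit_lrm(clean)$beta[1, ]))
  brm_clean <- suppressWarnings(dosebeta(clean))
  brm_dirty <- suppressWarnings(dosebeta(dirty))
  d_brm <- abs(logdm(brm_dirty$beta[1, ]) - logdm(brm_clean$beta[1, ]))
  expect_lt(d_brm, d_lrm)
})

test_that("the study runner scores estimators and respects its contracts", {
  rep <- run_study(dr_scenario("7lessE"), estimators = c("LRM", "HLRM"),
                   n_datasets = 4, seed = 77)
  expect_s3_class(rep, "dr_sim_report")
  expect_setequal(unique(rep$quantity), c("log_ic50", "log_ic90", "beta0", "beta1"))
  expect_setequal(unique(rep$metric), c("bias", "rmse", "coverage", "ci_width"))
  w <- reshape(as.data.frame(rep), idvar = c("scenario", "estimator", "quantity"),
               timevar = "metric", direction = "wide")
  expect_true(all(w$value.rmse >= abs(w$value.bias) - 1e-12))
  expect_true(all(w$value.coverage >= 0 & w$value.coverage <= 1))
  expect_true(all(w$value.ci_width > 0))
  expect_error(run_study(dr_scenario("7"), estimators = "XGB"),
               "unknown estimator")
})

test_that("rerunning the study under the same seed reproduces the report", {
  r1 <- run_study(dr_scenario("7lessE"), estimators = "LRM", n_datasets = 3,
                  seed = 5)
  r2 <- run_study(dr_scenario("7lessE"), estimators = "LRM", n_datasets = 3,
                  seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})
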