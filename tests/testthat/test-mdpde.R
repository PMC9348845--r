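test_that("beta log-density matches independent evaluation and integrates to one", {
  # Beta(1,1) is uniform
  expect_equal(beta_logdensity(0.3, mu = 0.5, phi = 2), 0)
  # mu = 0.3, phi = 10 is Beta(3, 7); closed form 252 y^2 (1-y)^6
  expect_equal(beta_logdensity(0.2, 0.3, 10), log(252 * 0.2^2 * 0.8^6),
               tolerance = 1e-12)
  # against stats::dbeta over a grid
  y <- seq(0.05, 0.95, by = 0.1)
  for (mu in c(0.2, 0.5, 0.8)) for (phi in c(3, 40)) {
    expect_equal(beta_logdensity(y, mu, phi),
                 dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE),
                 tolerance = 1e-10)
  }
  # normalisation by adaptive quadrature
  I <- integrate(function(y) exp(beta_logdensity(y, 0.3, 10)), 0, 1,
                 rel.tol = 1e-10)$value
  expect_equal(I, 1, tolerance = 1e-8)
  expect_error(beta_logdensity(0, 0.5, 2), "open interval")
  expect_error(beta_logdensity(1, 0.5, 2), "open interval")
})

test_that("closed-form DPD integral equals adaptive quadrature of g^(1+alpha)", {
  expect_equal(dpd_integral_K(0.5, 2, 0.7), 1)   # uniform density
  expect_equal(dpd_integral_K(0.3, 10, 0), 1)    # any density at alpha = 0
  for (mu in c(0.1, 0.5, 0.9)) for (phi in c(5, 100)) for (a in c(0.1, 0.4)) {
    q <- quad_power_integral(mu, phi, a)
    expect_equal(dpd_integral_K(mu, phi, a), q, tolerance = 1e-8)
  }
  # integrability boundary: (1+alpha) mu phi - alpha must stay positive
  expect_error(dpd_integral_K(0.1, 5, 1), "integrab")
})

test_that("DPD objective has its stated closed forms and limits", {
  # single uniform observation at alpha = 0.5: K = 1, g = 1 -> 1 - 3 = -2
  expect_equal(dpd_objective(0.37, mu = 0.5, phi = 2, alpha = 0.5), -2)
  # alpha = 0 is the negative mean log-likelihood
  set.seed(4)
  y <- rbeta(15, 3, 5)
  expect_equal(dpd_objective(y, 0.375, 8, 0),
               -mean(beta_logdensity(y, 0.375, 8)), tolerance = 1e-12)
  expect_error(dpd_objective(c(0.2, 1), 0.5, 5, 0.3), "strictly inside")
})

test_that("the fitted MDPDE is a stationary point of the objective", {
  dat <- make_beta_dataset(11)
  for (a in c(0, 0.4)) {
    fit <- suppressWarnings(dosebeta(dat, alpha = a))
    th <- coef(fit)
    # numerical gradient of the objective through the model surface
    g <- vapply(seq_along(th), function(j) {
      e <- rep(0, length(th)); e[j] <- 1e-6
      mu_p <- function(t) {
        m <- inv_logit(t[1] + t[2] * log(dat$dose))
        list(mu = m, phi = rep(exp(t[3]), nrow(dat)))
      }
      up <- mu_p(th + e); dn <- mu_p(th - e)
      (dpd_objective(dat$response, up$mu, up$phi, a) -
         dpd_objective(dat$response, dn$mu, dn$phi, a)) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(g)), 1e-4)
  }
})

test_that("fitting at alpha 0 agrees with an independent likelihood maximizer", {
  for (seed in c(1, 7, 23)) {
    dat <- make_beta_dataset(seed)
    fit <- suppressWarnings(dosebeta(dat, alpha = 0))
    nll <- function(p) {
      m <- inv_logit(p[1] + p[2] * log(dat$dose))
      -sum(dbeta(dat$response, m * exp(p[3]), (1 - m) * exp(p[3]), log = TRUE))
    }
    ref <- optim(coef(fit), nll, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_lt(max(abs(ref$par - coef(fit))), 1e-4)
    expect_equal(-nll(coef(fit)), as.numeric(logLik(fit)), tolerance = 1e-10)
  }
})

test_that("estimates recover the generating curve within sampling error", {
  dat <- make_beta_dataset(5, beta0 = 1, beta1 = -1)
  fit <- suppressWarnings(dosebeta(dat, alpha = 0))
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)[1] - 1) / se[1], 3)
  expect_lt(abs(coef(fit)[2] + 1) / se[2], 3)
})

test_that("dose rescaling leaves fitted effects invariant at any alpha", {
  dat <- make_beta_dataset(9)
  dat10 <- dose_response_data(dat$dose * 10, dat$response, dat$group)
  for (a in c(0, 0.3)) {
    f1 <- suppressWarnings(dosebeta(dat, alpha = a))
    f2 <- suppressWarnings(dosebeta(dat10, alpha = a))
    expect_equal(unname(coef(f2)[2]), unname(coef(f1)[2]), tolerance = 1e-4)
    expect_equal(unname(coef(f2)[1]), unname(coef(f1)[1] - coef(f1)[2] * log(10)),
                 tolerance = 1e-3)
    expect_equal(fitted(f2), fitted(f1), tolerance = 1e-6)
  }
})

test_that("duplicated identically-labelled groups fit independently and identically", {
  dat <- make_beta_dataset(13)
  two <- dose_response_data(rep(dat$dose, 2), rep(dat$response, 2),
                            rep(c("A", "B"), each = nrow(dat)))
  fit <- suppressWarnings(dosebeta(two, alpha = 0))
  expect_equal(unname(fit$beta["A", ]), unname(fit$beta["B", ]), tolerance = 1e-5)
})

test_that("the covariance is symmetric positive semidefinite", {
  dat <- make_beta_dataset(17)
  for (a in c(0, 0.4)) {
    V <- vcov(suppressWarnings(dosebeta(dat, alpha = a)))
    expect_equal(V, t(V), tolerance = 1e-10)
    expect_gt(min(eigen(V, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("maximum-likelihood covariance matches the inverse observed information", {
  dat <- make_beta_dataset(29)
  fit <- suppressWarnings(dosebeta(dat, alpha = 0))
  th <- coef(fit)
  nll <- function(p) {
    m <- inv_logit(p[1] + p[2] * log(dat$dose))
    -sum(dbeta(dat$response, m * exp(p[3]), (1 - m) * exp(p[3]), log = TRUE))
  }
  H <- matrix(0, 3, 3); h <- 1e-4
  for (j in 1:3) for (k in 1:3) {
    e1 <- e2 <- rep(0, 3); e1[j] <- h; e2[k] <- h
    H[j, k] <- (nll(th + e1 + e2) - nll(th + e1 - e2) -
                  nll(th - e1 + e2) + nll(th - e1 - e2)) / (4 * h^2)
  }
  expect_equal(unname(vcov(fit)), solve((H + t(H)) / 2), tolerance = 1e-2)
})

test_that("standardized quadratic variation behaves like a scaled norm", {
  expect_equal(compute_sqv(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_sqv(c(0, 0, 0), c(3, 0, 0)), 1)
  expect_equal(compute_sqv(c(1, 5), c(2, 1)), compute_sqv(c(2, 1), c(1, 5)))
  expect_error(compute_sqv(1:3, 1:4), "length")
})

test_that("the alpha search returns a grid value and a usable trace", {
  dat <- make_beta_dataset(3)
  sel <- suppressWarnings(select_alpha(dat))
  expect_true(sel$alpha >= 0 && sel$alpha <= 1)
  expect_equal(sel$alpha %% 0.02, 0, tolerance = 1e-12)
  expect_true(is.data.frame(sel$trace) && all(sel$trace$sqv >= 0))
  # clean data should stabilise early
  expect_lte(sel$alpha, 0.1)
})

test_that("precision submodel is a positive log-linear function of dose", {
  expect_equal(precision_submodel(2.7, c(log(100), 0)), 100)
  expect_equal(precision_submodel(exp(1), c(0, 1)), exp(1))
  expect_true(all(precision_submodel(c(0.1, 1, 10), c(-2, 3)) > 0))
  expect_error(precision_submodel(0, c(1, 0)), "positive")
})

test_that("log-dose precision regression recovers a dose-dependent dispersion", {
  set.seed(31)
  d <- rep(doses7(), each = 20)
  mu <- inv_logit(log(d))
  phi_d <- 100 * exp(0.4 * (log(d) - mean(log(doses7()))))
  y <- rbeta(length(d), mu * phi_d, (1 - mu) * phi_d)
  dat <- dose_response_data(d, y)
  fit <- suppressWarnings(dosebeta(dat, alpha = 0, precision = "log_dose"))
  g1 <- coef(fit)[["gamma1"]]
  expect_gt(g1, 0.1)
  expect_lt(abs(g1 - 0.4), 0.25)
})

test_that("one extreme response among 21 moves the robust fit far less than least squares", {
  # 7 doses x 3 replicates; drive one lowest-dose response from a small but
  # ordinary value toward the boundary and watch the induced drift
  base <- make_beta_dataset(41)
  i <- which.min(base$dose)[1]
  make_variant <- function(v) {
    y <- base$response; y[i] <- v
    dose_response_data(base$dose, y, base$group)
  }
  clean <- make_variant(0.005)
  dirty <- make_variant(1e-8)
  drift <- function(fitfun) {
    b1 <- fitfun(clean); b2 <- fitfun(dirty)
    sqrt(sum((b1 - b2)^2))
  }
  lrm_drift <- drift(function(x) fit_lrm(x)$beta[1, ])
  brm_drift <- drift(function(x)
    suppressWarnings(dosebeta(x, alpha = 0.4))$beta[1, ])
  expect_lt(brm_drift, 0.2 * lrm_drift)
})
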