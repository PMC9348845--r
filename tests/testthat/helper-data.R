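# shared fixtures, built in code

doses7 <- function(span = 30, center = 1) center * exp(seq(-log(span), log(span), length.out = 7))

# beta-law draws on the true logit-linear curve (independent of the package's
# own generator, so it can serve as an oracle for it)
make_beta_dataset <- function(seed, doses = doses7(), reps = 3,
                              beta0 = 0, beta1 = 1, phi = 100) {
  set.seed(seed)
  d <- rep(doses, each = reps)
  mu <- 1 / (1 + exp(-(beta1 * log(d) + beta0)))
  y <- rbeta(length(d), mu * phi, (1 - mu) * phi)
  dose_response_data(d, y)
}

# noiseless 7-dose on-curve construction with the lowest response perturbed
# from 0.005 to a near-zero value
perturbed_oncurve_dataset <- function(low = 1e-6) {
  q <- seq(log(0.005 / 0.995), log(0.995 / 0.005), length.out = 7)
  d <- exp(q)  # true curve: beta0 = 0, beta1 = 1
  y <- 1 / (1 + exp(-q))
  y[1] <- low
  dose_response_data(d, y)
}

# adaptive quadrature of the beta density to the power 1 + alpha, computed on
# the logit scale so integrable endpoint singularities are handled smoothly
quad_power_integral <- function(mu, phi, alpha) {
  f <- function(m) function(u) {
    y <- 1 / (1 + exp(-u))
    out <- numeric(length(y))
    ok <- y > 0 & y < 1  # so far out that y rounds to the boundary, the
                         # integrand has already underflowed to zero
    out[ok] <- exp((1 + alpha) * beta_logdensity(y[ok], m, phi)) *
      y[ok] * (1 - y[ok])
    out
  }
  # substituting y -> 1 - y maps the integral onto itself with mu -> 1 - mu,
  # so either orientation is a valid evaluation; collect every successful
  # attempt and keep the one the integrator itself rates most accurate
  best <- NULL
  for (m in c(mu, 1 - mu)) for (tol in c(1e-13, 1e-12, 1e-10)) {
    r <- tryCatch(integrate(f(m), -Inf, Inf, rel.tol = tol,
                            subdivisions = 2000L),
                  error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$abs.error < best$abs.error))
      best <- r
  }
  if (is.null(best)) stop("quadrature failed")
  best$value
}

# step-up false-discovery-rate adjustment written from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(p[o] * m / (m:1)))
  adj[ro]
}

write_two_group_csv <- function(path, seed = 20) {
  set.seed(seed)
  d <- rep(doses7(), each = 3)
  mk <- function(b0) {
    mu <- 1 / (1 + exp(-(log(d) + b0)))
    rbeta(length(d), 100 * mu, 100 * (1 - mu))
  }
  df <- data.frame(concentration = c(d, d),
                   effect = round(c(mk(0), mk(1)), 6),
                   agent = rep(c("drugA", "drugB"), each = length(d)))
  write.csv(df, path, row.names = FALSE)
  path
}
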