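#' Beta log-density in mean/precision form
#'
#' Log-density of the beta law parameterised by mean \eqn{\mu \in (0,1)} and
#' precision \eqn{\phi > 0}, i.e. shapes \eqn{a = \mu\phi}, \eqn{b =
#' (1-\mu)\phi}; the variance is \eqn{\mu(1-\mu)/(1+\phi)}. Computed through
#' `lbeta()` (log-gamma), never by direct gamma evaluation.
#'
#' @param y response values strictly inside (0, 1); vectorised.
#' @param mu mean parameter(s) in (0, 1).
#' @param phi precision parameter(s), positive.
#' @return numeric vector of log-density values.
#' @export
beta_logdensity <- function(y, mu, phi) {
  if (any(y <= 0) || any(y >= 1))
    stop("beta density is supported on the open interval (0, 1)", call. = FALSE)
  if (any(mu <= 0) || any(mu >= 1) || any(phi <= 0))
    stop("require 0 < mu < 1 and phi > 0", call. = FALSE)
  a <- mu * phi
  b <- (1 - mu) * phi
  (a - 1) * log(y) + (b - 1) * log1p(-y) - lbeta(a, b)
}

#' Closed-form integral of the beta density to the power 1 + alpha
#'
#' The model-mass term of the density power divergence objective,
#' \eqn{K_\alpha = \int_0^1 g(y)^{1+\alpha}\,dy} for \eqn{g =
#' \mathrm{Beta}(\mu\phi, (1-\mu)\phi)}:
#' \deqn{K_\alpha = \frac{B\big((1+\alpha)\mu\phi - \alpha,\ (1+\alpha)(1-\mu)\phi -
#'   \alpha\big)}{B(\mu\phi, (1-\mu)\phi)^{1+\alpha}},}
#' finite only when both transformed shapes are positive.
#'
#' @inheritParams beta_logdensity
#' @param alpha nonnegative tuning parameter of the divergence.
#' @return numeric vector of integrals (1 exactly when `alpha = 0`).
#' @export
dpd_integral_K <- function(mu, phi, alpha) {
  a <- mu * phi
  b <- (1 - mu) * phi
  A <- (1 + alpha) * a - alpha
  B <- (1 + alpha) * b - alpha
  if (any(A <= 0) || any(B <= 0))
    stop("g^(1+alpha) is not integrable: shape parameters too small for this alpha",
         call. = FALSE)
  exp(lbeta(A, B) - (1 + alpha) * lbeta(a, b))
}

# Per-observation DPD loss rho_i and its partial derivatives with respect to
# the beta shapes (a, b). For alpha > 0,
#   rho_i = K_{i,alpha} - (1+alpha)/alpha * g_i(y_i)^alpha,
# and for alpha = 0 the likelihood-disparity limit rho_i = -log g_i(y_i).
# Minimising the mean of rho_i over observations is the MDPDE; at alpha = 0 it
# is maximum likelihood. Returns list(rho, da, db).
.dpd_terms <- function(y, mu, phi, alpha, deriv = TRUE) {
  a <- mu * phi
  b <- (1 - mu) * phi
  logg <- (a - 1) * log(y) + (b - 1) * log1p(-y) - lbeta(a, b)
  if (alpha < 1e-8) {
    out <- list(rho = -logg)
    if (deriv) {
      dgab <- digamma(a + b)
      out$da <- -(log(y) - digamma(a) + dgab)
      out$db <- -(log1p(-y) - digamma(b) + dgab)
    }
    return(out)
  }
  A <- (1 + alpha) * a - alpha
  B <- (1 + alpha) * b - alpha
  if (any(A <= 0) || any(B <= 0)) return(list(rho = rep(Inf, length(y))))
  logK <- lbeta(A, B) - (1 + alpha) * lbeta(a, b)
  K <- exp(logK)
  galpha <- exp(alpha * logg)
  rho <- K - (1 + alpha) / alpha * galpha
  out <- list(rho = rho)
  if (deriv) {
    dgab <- digamma(a + b)
    dgAB <- digamma(A + B)
    dlogg_da <- log(y) - digamma(a) + dgab
    dlogg_db <- log1p(-y) - digamma(b) + dgab
    dlogK_da <- (1 + alpha) * ((digamma(A) - dgAB) - (digamma(a) - dgab))
    dlogK_db <- (1 + alpha) * ((digamma(B) - dgAB) - (digamma(b) - dgab))
    out$da <- K * dlogK_da - (1 + alpha) * galpha * dlogg_da
    out$db <- K * dlogK_db - (1 + alpha) * galpha * dlogg_db
  }
  out
}

#' Density power divergence objective for a dose-response dataset
#'
#' Mean per-observation DPD loss \eqn{H_{n,\alpha}(\theta) = n^{-1}\sum_i
#' [K_{i,\alpha} - \frac{1+\alpha}{\alpha} g_i(y_i)^\alpha]} under the beta
#' regression model; at `alpha = 0` it smoothly becomes the negative mean
#' log-likelihood. Mainly exposed for diagnostics and testing; [dosebeta()]
#' minimises it internally.
#'
#' @param y responses strictly inside (0, 1).
#' @param mu fitted means (vectorised, recycled).
#' @param phi fitted precisions (vectorised, recycled).
#' @param alpha nonnegative tuning parameter.
#' @return the scalar objective value.
#' @export
dpd_objective <- function(y, mu, phi, alpha) {
  if (any(y <= 0) || any(y >= 1))
    stop("responses must be strictly inside (0, 1)", call. = FALSE)
  if (alpha < 0) stop("alpha must be nonnegative", call. = FALSE)
  k <- length(y)
  mu <- rep_len(mu, k)
  phi <- rep_len(phi, k)
  mean(.dpd_terms(y, mu, phi, alpha, deriv = FALSE)$rho)
}

#' Dose-dependent precision submodel
#'
#' Log-link precision model \eqn{\phi(d) = \exp(\gamma_0 + \gamma_1 \log d)}.
#' With \eqn{\gamma_1 = 0} this is constant precision; a nonzero slope lets the
#' dispersion shrink or grow with dose, which repeated-measure assay data often
#' show.
#'
#' @param dose positive dose (vectorised).
#' @param gamma numeric vector `c(gamma0)` or `c(gamma0, gamma1)`.
#' @return positive precision values.
#' @export
precision_submodel <- function(dose, gamma) {
  if (any(dose <= 0)) stop("dose must be positive", call. = FALSE)
  g1 <- if (length(gamma) >= 2) gamma[2] else 0
  exp(gamma[1] + g1 * log(dose))
}
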