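#' Potency estimates with delta-method confidence intervals
#'
#' Transforms the fitted curve parameters into drug-activity summaries — the
#' median-effect dose (IC50/EC50 analogue), the dose producing an arbitrary
#' effect level, the Hill coefficient, or the effect at a given dose — with
#' standard errors by the multivariate delta method on the fitted covariance.
#' Dose-type quantities are handled on the log-dose scale and back-transformed,
#' so interval endpoints are always positive; effect-at-dose intervals are
#' built on the logit scale, so they stay inside (0, 1).
#'
#' @param fit a [dosebeta()] fit, or any fit object exposing per-group
#'   `(beta0, beta1)` and their covariance block (the internal linear baselines
#'   do).
#' @param quantity one of `"median_effect_dose"`, `"dose_at_effect"`,
#'   `"hill"`, `"effect_at_dose"`.
#' @param level target effect level in (0, 1) for `"dose_at_effect"`.
#' @param dose dose at which to evaluate `"effect_at_dose"`.
#' @param conf_level confidence level (Student-t quantiles on the residual
#'   degrees of freedom).
#' @param groups groups to report (default all).
#' @return a data frame with one row per group: `group`, `quantity`, `level`,
#'   `estimate`, `se`, `lower`, `upper`, `conf_level`. For dose quantities
#'   `se` is the standard error of the log dose.
#' @export
potency <- function(fit, quantity = c("median_effect_dose", "dose_at_effect",
                                      "hill", "effect_at_dose"),
                    level = 0.5, dose = NULL, conf_level = 0.95,
                    groups = NULL) {
  quantity <- match.arg(quantity)
  if (quantity == "dose_at_effect" && (level <= 0 || level >= 1))
    stop("effect level must be strictly inside (0, 1)", call. = FALSE)
  if (quantity == "effect_at_dose" && (is.null(dose) || any(dose <= 0)))
    stop("effect_at_dose requires a positive dose", call. = FALSE)
  if (is.null(groups)) groups <- .fit_groups(fit)
  z <- .fit_crit(fit, conf_level)
  rows <- lapply(groups, function(g) {
    pr <- .group_params(fit, g)
    .potency_row(pr$beta, pr$V, quantity, level, dose, z, g, conf_level,
                 orientation = .fit_orientation(fit))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.potency_row <- function(beta, V, quantity, level, dose, z, group, conf_level,
                         orientation = "affected") {
  b0 <- beta[1]; b1 <- beta[2]
  if (quantity %in% c("median_effect_dose", "dose_at_effect")) {
    if (abs(b1) < 1e-8)
      stop("dose-type potency undefined: slope is (numerically) zero",
           call. = FALSE)
    q <- if (quantity == "median_effect_dose") 0 else logit(level)
    logD <- (q - b0) / b1
    grad <- c(-1 / b1, -(q - b0) / b1^2)
    se <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
    if (is.finite(logD) && se > 10 * max(abs(logD), 1))
      warning("confidence interval for the dose estimate is unstable ",
              "(delta-scale SE very large relative to the estimate)",
              call. = FALSE)
    lev_out <- if (quantity == "median_effect_dose") 0.5 else level
    return(data.frame(group = group, quantity = quantity, level = lev_out,
                      estimate = exp(logD), se = se,
                      lower = exp(logD - z * se), upper = exp(logD + z * se),
                      conf_level = conf_level, stringsAsFactors = FALSE))
  }
  if (quantity == "hill") {
    sgn <- if (orientation == "affected") 1 else -1
    se <- sqrt(max(0, V[2, 2]))
    est <- sgn * b1
    return(data.frame(group = group, quantity = quantity, level = NA_real_,
                      estimate = est, se = se,
                      lower = est - z * se, upper = est + z * se,
                      conf_level = conf_level, stringsAsFactors = FALSE))
  }
  # effect at dose, on the logit scale
  eta <- b0 + b1 * log(dose)
  grad <- rbind(1, log(dose))
  se_eta <- sqrt(pmax(0, colSums(grad * (V %*% grad))))
  data.frame(group = group, quantity = quantity, level = dose,
             estimate = inv_logit(eta), se = se_eta,
             lower = inv_logit(eta - z * se_eta),
             upper = inv_logit(eta + z * se_eta),
             conf_level = conf_level, stringsAsFactors = FALSE)
}

#' Pointwise confidence band for a fitted dose-response curve
#'
#' Delta-method band for the effect curve over a dose grid, constructed on the
#' logit scale and back-transformed (so it always lies inside the unit
#' interval).
#'
#' @inheritParams potency
#' @param dose_grid positive doses at which to evaluate the band.
#' @param group single group label (defaults to the first group).
#' @return data frame with columns `dose`, `fit`, `lwr`, `upr`.
#' @export
curve_band <- function(fit, dose_grid, group = NULL, conf_level = 0.95) {
  if (any(dose_grid <= 0)) stop("doses must be positive", call. = FALSE)
  if (is.null(group)) group <- .fit_groups(fit)[1]
  pr <- .group_params(fit, group)
  z <- .fit_crit(fit, conf_level)
  eta <- pr$beta[1] + pr$beta[2] * log(dose_grid)
  gr <- rbind(1, log(dose_grid))
  se <- sqrt(pmax(0, colSums(gr * (pr$V %*% gr))))
  data.frame(dose = dose_grid, fit = inv_logit(eta),
             lwr = inv_logit(eta - z * se), upr = inv_logit(eta + z * se))
}

# --- small internal accessors shared by the beta fit and the linear baselines

# small-sample critical value: Student-t with residual df (falls back to the
# normal quantile when the df is not positive); converges to z as n grows
.fit_crit <- function(fit, conf_level) {
  df <- if (inherits(fit, "dr_linfit")) fit$df_residual else fit$n - fit$p
  pr <- 1 - (1 - conf_level) / 2
  if (is.null(df) || !is.finite(df) || df <= 0) stats::qnorm(pr)
  else stats::qt(pr, df)
}

.fit_groups <- function(fit) {
  if (!is.null(fit$groups)) fit$groups else stop("fit has no groups")
}

.fit_orientation <- function(fit) {
  if (!is.null(fit$orientation)) fit$orientation else "affected"
}

# per-group (beta0, beta1) and their 2x2 covariance block
.group_params <- function(fit, group) {
  if (inherits(fit, "dosebeta")) {
    g <- match(group, fit$groups)
    if (is.na(g)) stop(sprintf("unknown group '%s'", group), call. = FALSE)
    idx <- c(2 * g - 1, 2 * g)  # packing order: beta0, beta1 per group
    return(list(beta = unname(fit$coefficients[idx]),
                V = fit$vcov[idx, idx, drop = FALSE]))
  }
  if (inherits(fit, "dr_linfit")) {
    g <- match(group, fit$groups)
    if (is.na(g)) stop(sprintf("unknown group '%s'", group), call. = FALSE)
    return(list(beta = unname(fit$beta[g, ]), V = fit$vcov_list[[g]]))
  }
  stop("unsupported fit object", call. = FALSE)
}
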