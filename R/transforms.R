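#' Logit and inverse-logit transforms
#'
#' The median-effect equation is linear on the logit scale:
#' \eqn{\mathrm{logit}(E) = \beta_1 \log d + \beta_0}. These helpers implement
#' the transform and its inverse in overflow-safe form.
#'
#' @param p numeric vector of fractions, strictly inside (0, 1).
#' @return `logit()` returns \eqn{\log(p/(1-p))}; `inv_logit()` returns values
#'   strictly inside (0, 1) for any finite input.
#' @examples
#' logit(0.5)
#' inv_logit(logit(0.9))
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("logit() requires values strictly inside (0, 1)", call. = FALSE)
  log(p) - log1p(-p)
}

#' @rdname logit
#' @param x numeric vector (any finite value).
#' @export
inv_logit <- function(x) {
  # branch-stable: never exponentiates a large positive argument
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Deterministic median-effect curve quantities
#'
#' Pure transformations between the logit-linear parameters
#' \eqn{(\beta_0, \beta_1)} and pharmacological summaries: the effect at a
#' dose, the median-effect dose \eqn{D_m = \exp(-\beta_0/\beta_1)} (the IC50 /
#' EC50 analogue), the dose producing an arbitrary effect level, and the Hill
#' coefficient. Doses are handled on the natural-log scale throughout.
#'
#' @param d positive dose (vectorised).
#' @param beta0 intercept on the logit scale.
#' @param beta1 slope with respect to log dose; must be nonzero for any
#'   dose-type quantity.
#' @return numeric vector.
#' @examples
#' effect_at_dose(1, beta0 = 0, beta1 = 1)       # 0.5
#' median_effect_dose(beta0 = -2, beta1 = 1)     # exp(2)
#' dose_for_effect(0.9, beta0 = 0, beta1 = 1)    # 9
#' @export
effect_at_dose <- function(d, beta0, beta1) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("doses must be strictly positive", call. = FALSE)
  inv_logit(beta1 * log(d) + beta0)
}

#' @rdname effect_at_dose
#' @export
median_effect_dose <- function(beta0, beta1) {
  if (any(beta1 == 0))
    stop("median effect dose is undefined at zero slope", call. = FALSE)
  exp(-beta0 / beta1)
}

#' @rdname effect_at_dose
#' @param p target effect level, strictly inside (0, 1); `p = 0.5` gives the
#'   median-effect dose.
#' @export
dose_for_effect <- function(p, beta0, beta1) {
  if (any(beta1 == 0))
    stop("dose at effect level is undefined at zero slope", call. = FALSE)
  exp((logit(p) - beta0) / beta1)
}

#' @rdname effect_at_dose
#' @param orientation whether the modelled fraction is the affected
#'   (`"affected"`, default) or unaffected (`"unaffected"`) fraction; flips the
#'   sign of the Hill coefficient.
#' @export
hill_coefficient <- function(beta1, orientation = c("affected", "unaffected")) {
  orientation <- match.arg(orientation)
  if (orientation == "affected") beta1 else -beta1
}
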