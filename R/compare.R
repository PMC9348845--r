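#' Compare dose-response curves between groups
#'
#' Runs the standard battery of between-curve tests on a multi-group fit:
#' \describe{
#'   \item{model equality}{likelihood-ratio test of one common curve
#'     (\eqn{\beta_0, \beta_1} shared) against independent curves; chi-square
#'     with \eqn{2(G-1)} df.}
#'   \item{slope equality}{likelihood-ratio test of a common Hill slope
#'     (\eqn{\beta_1} shared, intercepts free); chi-square with \eqn{G-1} df.}
#'   \item{potency equality}{Wald-type F test that all median-effect doses are
#'     equal, built on the contrast of log-IC50s with the delta-method
#'     covariance; F with \eqn{(G-1,\ N-k)} df.}
#'   \item{pairwise potency}{two-sided t contrasts of log-IC50 for every group
#'     pair, Benjamini-Hochberg adjusted.}
#' }
#' The likelihood-ratio tests are computed from maximum-likelihood refits
#' (tuning parameter 0) regardless of the alpha used for the headline
#' estimates, because the LRT calibration is a likelihood property; the
#' potency F test and pairwise contrasts use the supplied (possibly robust)
#' fit and its covariance. Shared-curve refits constrain only the mean
#' parameters; per-group precisions stay free. Pairwise contrasts are reported
#' unconditionally and should be read as exploratory when the global potency
#' test is not significant.
#'
#' @param fit a multi-group [dosebeta()] fit.
#' @return an object of class `"dosebeta_tests"`: a list with elements
#'   `model_equality`, `slope_equality`, `potency_equality` (each with
#'   `statistic`, `df`, `p_value`) and `pairwise` (a data frame with BH
#'   adjusted p-values).
#' @export
compare_curves <- function(fit) {
  if (!inherits(fit, "dosebeta")) stop("need a dosebeta fit", call. = FALSE)
  G <- length(fit$groups)
  if (G < 2) stop("curve comparison requires at least two groups", call. = FALSE)
  dat <- fit$data
  prec <- fit$precision

  free <- suppressWarnings(.fit_dr(dat, alpha = 0, precision = prec, share = "none"))
  shared_all <- suppressWarnings(.fit_dr(dat, alpha = 0, precision = prec, share = "all"))
  shared_slope <- suppressWarnings(.fit_dr(dat, alpha = 0, precision = prec, share = "slope"))

  lrt <- function(l_free, l_shared, df) {
    stat <- 2 * (l_free - l_shared)
    if (stat < -1e-6 * max(1, abs(l_free)))
      stop("nesting violation: shared fit exceeds free likelihood", call. = FALSE)
    stat <- max(stat, 0)
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  model_eq <- lrt(free$loglik, shared_all$loglik, 2 * (G - 1))
  slope_eq <- lrt(free$loglik, shared_slope$loglik, G - 1)

  pot <- .potency_wald(fit)

  structure(list(model_equality = model_eq, slope_equality = slope_eq,
                 potency_equality = pot$global, pairwise = pot$pairwise,
                 groups = fit$groups, alpha = fit$alpha),
            class = "dosebeta_tests")
}

# Wald F test + pairwise t contrasts on log median-effect dose
.potency_wald <- function(fit) {
  G <- length(fit$groups)
  N <- fit$n
  k <- fit$p
  df2 <- N - k
  # log Dm per group with delta-method covariance across groups
  logD <- numeric(G)
  Grad <- matrix(0, G, length(fit$coefficients))
  for (g in seq_len(G)) {
    pr <- .group_params(fit, fit$groups[g])
    if (abs(pr$beta[2]) < 1e-8)
      stop("potency test undefined: a group slope is (numerically) zero",
           call. = FALSE)
    logD[g] <- -pr$beta[1] / pr$beta[2]
    idx <- c(2 * g - 1, 2 * g)
    Grad[g, idx] <- c(-1 / pr$beta[2], pr$beta[1] / pr$beta[2]^2)
  }
  Vd <- Grad %*% fit$vcov %*% t(Grad)
  # contrasts vs the first group
  C <- cbind(-1, diag(G - 1))
  delta <- drop(C %*% logD)
  Vc <- C %*% Vd %*% t(C)
  stat <- drop(t(delta) %*% .solve_psd(Vc) %*% delta) / (G - 1)
  global <- list(statistic = stat, df = c(G - 1, df2),
                 p_value = stats::pf(stat, G - 1, df2, lower.tail = FALSE))
  pairs <- utils::combn(G, 2)
  pw <- data.frame(
    group_i = fit$groups[pairs[1, ]],
    group_j = fit$groups[pairs[2, ]],
    log_dm_diff = logD[pairs[1, ]] - logD[pairs[2, ]],
    stringsAsFactors = FALSE)
  se <- sqrt(pmax(1e-300, Vd[cbind(pairs[1, ], pairs[1, ])] +
                    Vd[cbind(pairs[2, ], pairs[2, ])] -
                    2 * Vd[cbind(pairs[1, ], pairs[2, ])]))
  pw$t <- pw$log_dm_diff / se
  pw$df <- df2
  pw$p_value <- 2 * stats::pt(-abs(pw$t), df2)
  pw$p_adjusted <- bh_adjust(pw$p_value)
  list(global = global, pairwise = pw)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a validated thin wrapper around
#' `stats::p.adjust(method = "BH")` with input checking. Input order is
#' preserved.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' @export
print.dosebeta_tests <- function(x, digits = 4, ...) {
  cat("Dose-response curve comparison\n")
  cat(sprintf("  groups: %s\n\n", paste(x$groups, collapse = ", ")))
  fmt <- function(name, t) {
    df <- if (length(t$df) == 2) sprintf("(%d, %d)", t$df[1], t$df[2])
          else sprintf("%d", t$df)
    cat(sprintf("  %-18s stat = %8.4g  df = %-8s p = %.4g\n",
                name, t$statistic, df, t$p_value))
  }
  fmt("model equality", x$model_equality)
  fmt("slope equality", x$slope_equality)
  fmt("potency equality", x$potency_equality)
  cat("\n  pairwise log-IC50 contrasts (BH adjusted):\n")
  print(x$pairwise, digits = digits, row.names = FALSE)
  invisible(x)
}
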