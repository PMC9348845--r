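#' Logit-linear least-squares baseline (LRM)
#'
#' The standard estimation approach for the median-effect equation: ordinary
#' least squares of `logit(y)` on `log(d)`, fitted per group. Included as the
#' comparison baseline for the robust beta fit; potency summaries and
#' delta-method intervals come from the same machinery ([potency()],
#' [curve_band()]).
#'
#' @param data a `dose_response_data` (or three-column data frame). Responses
#'   must already be strictly inside (0, 1).
#' @return an object of class `"dr_linfit"` with per-group `beta`
#'   (intercept/slope matrix), `vcov_list` (2x2 covariance blocks),
#'   `df_residual`, `n` and `groups`.
#' @export
fit_lrm <- function(data) {
  dat <- .as_drdata(data)
  lev <- unique(dat$group)
  beta <- matrix(NA_real_, length(lev), 2,
                 dimnames = list(lev, c("beta0", "beta1")))
  vl <- vector("list", length(lev))
  dfres <- 0L
  for (j in seq_along(lev)) {
    idx <- dat$group == lev[j]
    if (sum(idx) < 3) stop("fewer than 3 observations in a group", call. = FALSE)
    z <- logit(dat$response[idx])
    x <- log(dat$dose[idx])
    m <- stats::lm(z ~ x)
    beta[j, ] <- stats::coef(m)
    vl[[j]] <- unname(stats::vcov(m))
    dfres <- dfres + m$df.residual
  }
  structure(list(beta = beta, vcov_list = vl, groups = lev,
                 df_residual = dfres, n = nrow(dat), method = "lrm"),
            class = "dr_linfit")
}

#' Heavy-tailed logit-linear baseline (HLRM)
#'
#' Maximum-likelihood fit of `logit(y) = beta1 log(d) + beta0 + eps` with
#' scaled Student-t errors on 3 degrees of freedom, per group. The heavy tail
#' down-weights extreme logits; the covariance is the inverse observed
#' information from a numerical Hessian.
#'
#' @inheritParams fit_lrm
#' @param df degrees of freedom of the t error law.
#' @return a `"dr_linfit"` object (see [fit_lrm()]).
#' @export
fit_hlrm <- function(data, df = 3) {
  dat <- .as_drdata(data)
  lev <- unique(dat$group)
  beta <- matrix(NA_real_, length(lev), 2,
                 dimnames = list(lev, c("beta0", "beta1")))
  vl <- vector("list", length(lev))
  for (j in seq_along(lev)) {
    idx <- dat$group == lev[j]
    z <- logit(dat$response[idx])
    x <- log(dat$dose[idx])
    nll <- function(th) {
      r <- (z - th[1] - th[2] * x) / exp(th[3])
      -sum(stats::dt(r, df = df, log = TRUE) - th[3])
    }
    st <- stats::coef(stats::lm(z ~ x))
    s0 <- log(max(stats::sd(z - st[1] - st[2] * x), 1e-3))
    opt <- stats::optim(c(st, s0), nll, method = "BFGS",
                        control = list(maxit = 500), hessian = TRUE)
    if (opt$convergence != 0)
      warning("heavy-tailed fit did not report convergence", call. = FALSE)
    beta[j, ] <- opt$par[1:2]
    Vfull <- .solve_psd(opt$hessian)
    vl[[j]] <- Vfull[1:2, 1:2]
  }
  structure(list(beta = beta, vcov_list = vl, groups = lev,
                 df_residual = nrow(dat) - 3L * length(lev), n = nrow(dat),
                 method = "hlrm"), class = "dr_linfit")
}

#' @export
print.dr_linfit <- function(x, digits = 4, ...) {
  cat(sprintf("Logit-linear dose-response fit (%s)\n", toupper(x$method)))
  print(round(x$beta, digits))
  invisible(x)
}

#' @export
coef.dr_linfit <- function(object, ...) object$beta
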