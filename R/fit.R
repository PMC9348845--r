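# Model matrices for the mean (logit link) and precision (log link) submodels.
# share = "none": per-group intercept and slope; "slope": common slope;
# "all": one common curve. Precision always has a per-group intercept, plus a
# shared log-dose slope when precision = "log_dose".
.dr_design <- function(dat, share = c("none", "slope", "all"),
                       precision = c("constant", "log_dose")) {
  share <- match.arg(share)
  precision <- match.arg(precision)
  g <- factor(dat$group, levels = unique(dat$group))
  lev <- levels(g)
  G <- length(lev)
  lnd <- log(dat$dose)
  n <- nrow(dat)
  ind <- vapply(lev, function(l) as.numeric(g == l), numeric(n))
  ind <- matrix(ind, nrow = n)  # n x G indicator

  tag <- function(base, l) if (G == 1) base else paste0(base, "[", l, "]")
  if (share == "none") {
    Xm <- do.call(cbind, lapply(seq_len(G), function(j) cbind(ind[, j], ind[, j] * lnd)))
    mnames <- as.vector(vapply(lev, function(l) c(tag("beta0", l), tag("beta1", l)),
                               character(2)))
  } else if (share == "slope") {
    Xm <- cbind(ind, lnd)
    mnames <- c(vapply(lev, function(l) tag("beta0", l), character(1)), "beta1")
  } else {
    Xm <- cbind(rep(1, n), lnd)
    mnames <- c("beta0", "beta1")
  }
  Xp <- ind
  pnames <- vapply(lev, function(l) tag("gamma0", l), character(1))
  if (precision == "log_dose") {
    Xp <- cbind(Xp, lnd)
    pnames <- c(pnames, "gamma1")
  }
  colnames(Xm) <- mnames
  colnames(Xp) <- pnames
  list(Xm = Xm, Xp = Xp, names = c(mnames, pnames), pm = ncol(Xm), pp = ncol(Xp),
       groups = lev, g = g, lnd = lnd, share = share, precision = precision)
}

# mu, phi and per-observation DPD terms at a packed parameter vector
.dr_state <- function(theta, des, y, alpha, deriv = FALSE) {
  thm <- theta[seq_len(des$pm)]
  thp <- theta[des$pm + seq_len(des$pp)]
  eta <- drop(des$Xm %*% thm)
  mu <- inv_logit(eta)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  phi <- exp(drop(des$Xp %*% thp))
  terms <- .dpd_terms(y, mu, phi, alpha, deriv = deriv)
  list(mu = mu, phi = phi, terms = terms)
}

.dr_objective <- function(theta, des, y, alpha) {
  st <- .dr_state(theta, des, y, alpha)
  val <- mean(st$terms$rho)
  if (!is.finite(val)) 1e10 else val
}

.dr_gradient <- function(theta, des, y, alpha) {
  st <- .dr_state(theta, des, y, alpha, deriv = TRUE)
  if (any(!is.finite(st$terms$rho)) || is.null(st$terms$da))
    return(rep(0, length(theta)))
  deta <- st$phi * st$mu * (1 - st$mu) * (st$terms$da - st$terms$db)
  dzeta <- st$phi * (st$terms$da * st$mu + st$terms$db * (1 - st$mu))
  c(colMeans(des$Xm * deta), colMeans(des$Xp * dzeta))
}

# n x p matrix of per-observation gradient contributions (for the sandwich K)
.dr_score_matrix <- function(theta, des, y, alpha) {
  st <- .dr_state(theta, des, y, alpha, deriv = TRUE)
  deta <- st$phi * st$mu * (1 - st$mu) * (st$terms$da - st$terms$db)
  dzeta <- st$phi * (st$terms$da * st$mu + st$terms$db * (1 - st$mu))
  cbind(des$Xm * deta, des$Xp * dzeta)
}

# central-difference Hessian of the mean objective, from the analytic gradient
.dr_hessian <- function(theta, des, y, alpha) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- 1e-5 * max(1, abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- tp[j] + h
    tm[j] <- tm[j] - h
    H[j, ] <- (.dr_gradient(tp, des, y, alpha) - .dr_gradient(tm, des, y, alpha)) / (2 * h)
  }
  (H + t(H)) / 2
}

.solve_psd <- function(M) {
  out <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(out)) out <- solve(M + diag(1e-8 * max(1, max(abs(diag(M)))), nrow(M)))
  (out + t(out)) / 2
}

# Covariance of the packed estimate. At alpha = 0 this is the inverse observed
# information of the log-likelihood; for alpha > 0 the empirical sandwich
# J^-1 K J^-1 / n with J the Hessian of the mean objective and K the mean
# outer product of per-observation gradients.
.dr_vcov <- function(theta, des, y, alpha) {
  n <- length(y)
  J <- .dr_hessian(theta, des, y, alpha)
  if (alpha < 1e-8) return(.solve_psd(n * J))
  S <- .dr_score_matrix(theta, des, y, alpha)
  K <- crossprod(S) / n
  Jinv <- .solve_psd(J)
  V <- Jinv %*% K %*% Jinv / n
  (V + t(V)) / 2
}

# Moment-based starting values: per-group OLS of logit(y) on log(d), with a
# method-of-moments precision from the response-scale residual variance.
.dr_start <- function(des, y) {
  lev <- des$groups
  b0 <- b1 <- g0 <- numeric(length(lev))
  for (j in seq_along(lev)) {
    idx <- des$g == lev[j]
    z <- logit(pmin(pmax(y[idx], 1e-6), 1 - 1e-6))
    x <- des$lnd[idx]
    cf <- tryCatch(stats::coef(stats::lm(z ~ x)), error = function(e) c(0, 0))
    if (any(!is.finite(cf))) cf <- c(0, 0)
    b0[j] <- cf[1]; b1[j] <- cf[2]
    mu <- inv_logit(cf[1] + cf[2] * x)
    v <- stats::var(y[idx] - mu)
    phi0 <- if (is.finite(v) && v > 0) mean(mu * (1 - mu)) / v - 1 else 50
    g0[j] <- log(min(max(phi0, 1), 1e6))
  }
  thm <- switch(des$share,
    none  = as.vector(rbind(b0, b1)),
    slope = c(b0, mean(b1)),
    all   = c(mean(b0), mean(b1)))
  thp <- g0
  if (des$precision == "log_dose") thp <- c(thp, 0)
  c(thm, thp)
}

.dr_bounds <- function(des) {
  lower <- c(rep(-60, des$pm), rep(-7, des$pp))
  upper <- c(rep(60, des$pm), rep(20, des$pp))
  if (des$precision == "log_dose") {
    lower[des$pm + des$pp] <- -10
    upper[des$pm + des$pp] <- 10
  }
  list(lower = lower, upper = upper)
}

# Workhorse: minimise the DPD objective for one alpha. Multi-start quasi-Newton
# (L-BFGS-B with analytic gradient): the moment start, a conservative flat
# start, and an optional warm start.
.fit_dr <- function(dat, alpha, precision = "constant", share = "none",
                    start = NULL, vcov = TRUE) {
  des <- .dr_design(dat, share = share, precision = precision)
  y <- dat$response
  bounds <- .dr_bounds(des)
  flat <- c(rep(0, des$pm), rep(log(10), des$pp))
  if (des$precision == "log_dose") flat[des$pm + des$pp] <- 0
  starts <- if (is.null(start)) list(.dr_start(des, y), flat)
            else list(start, .dr_start(des, y))
  if (is.null(start) && alpha > 1e-8) {
    # continuation in alpha: the DPD surface can be multimodal, so also start
    # from the likelihood solution
    mle <- tryCatch(suppressWarnings(
      .fit_dr(dat, alpha = 0, precision = precision, share = share,
              vcov = FALSE)),
      error = function(e) NULL)
    if (!is.null(mle)) starts <- c(list(mle$theta), starts)
  }

  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, bounds$lower), bounds$upper)
    res <- tryCatch(
      stats::optim(s, .dr_objective, .dr_gradient, des = des, y = y,
                   alpha = alpha, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("beta regression fit failed to converge from all starting values",
         call. = FALSE)
  theta <- best$par
  names(theta) <- des$names
  st <- .dr_state(theta, des, y, 0)
  eta_hat <- logit(st$mu)
  if (any(abs(eta_hat) > 20))
    warning("fitted values extremely close to 0 or 1 at some design points ",
            "(possible separation)", call. = FALSE)
  V <- if (vcov) .dr_vcov(theta, des, y, alpha) else NULL
  if (!is.null(V)) dimnames(V) <- list(des$names, des$names)
  loglik <- sum(beta_logdensity(y, st$mu, st$phi))
  list(theta = theta, vcov = V, objective = best$value,
       loglik = loglik, converged = best$convergence == 0,
       des = des, alpha = alpha, n = length(y), p = length(theta))
}

#' Control parameters for the data-driven alpha search
#'
#' The robustness tuning parameter \eqn{\alpha} of the divergence objective is
#' chosen by scanning a grid \eqn{0, \rho, 2\rho, \dots, \alpha_{max}} and
#' monitoring the standardized quadratic variation (SQV) between estimates at
#' adjacent grid points; the first window of grid points whose successive SQVs
#' all fall below the stability threshold yields the selected \eqn{\alpha}
#' (the window minimum).
#'
#' @param alpha_max upper end of the grid (1 corresponds to the L2 divergence).
#' @param spacing grid step \eqn{\rho}.
#' @param window number of grid points examined per pass.
#' @param threshold stability threshold L for the SQV.
#' @return a list of class `"alpha_search_control"`.
#' @export
alpha_search_control <- function(alpha_max = 1, spacing = 0.02, window = 6,
                                 threshold = 0.02) {
  stopifnot(spacing > 0, spacing <= alpha_max, window >= 2, threshold > 0)
  structure(list(alpha_max = alpha_max, spacing = spacing, window = window,
                 threshold = threshold), class = "alpha_search_control")
}

#' Standardized quadratic variation between two estimate vectors
#'
#' \eqn{\mathrm{SQV} = p^{-1} \lVert z_k - z_{k+1} \rVert} (Euclidean norm),
#' where the z are standardized estimates \eqn{\hat\theta_j \sqrt{n} /
#' \mathrm{se}(\hat\theta_j)} at adjacent grid values of the tuning parameter.
#'
#' @param z_k,z_next numeric vectors of equal length.
#' @param p the standardisation constant (number of parameters); defaults to
#'   the vector length.
#' @return a nonnegative scalar, zero iff the vectors are equal.
#' @export
compute_sqv <- function(z_k, z_next, p = length(z_k)) {
  if (length(z_k) != length(z_next))
    stop("estimate vectors differ in length", call. = FALSE)
  sqrt(sum((z_k - z_next)^2)) / p
}

#' Data-driven selection of the robustness tuning parameter
#'
#' Implements the iterated-window SQV search over an alpha grid. Estimates are
#' computed at each grid point (warm-started from the previous point) and
#' standardized as \eqn{z_j = \hat\theta_j\sqrt{n}/se(\hat\theta_j)}. If every
#' successive SQV inside the current window falls below the threshold, the
#' window's smallest alpha is returned; otherwise the window restarts at the
#' largest failing grid point. If the grid is exhausted without a stable
#' window, alpha = 0 (maximum likelihood) is returned.
#'
#' @param data a `dose_response_data` (or three-column data frame).
#' @param control an [alpha_search_control()] list.
#' @param precision `"constant"` or `"log_dose"`.
#' @return list with `alpha` (the selection) and `trace` (a data frame of grid
#'   alphas, convergence flags and successive SQVs).
#' @export
select_alpha <- function(data, control = alpha_search_control(),
                         precision = c("constant", "log_dose")) {
  precision <- match.arg(precision)
  dat <- .as_drdata(data)
  grid <- seq(0, control$alpha_max, by = control$spacing)
  m <- length(grid)
  fits <- vector("list", m)       # cache: list(z =, ok =)
  warm <- NULL
  zfun <- function(k) {
    if (!is.null(fits[[k]])) return(fits[[k]])
    f <- tryCatch(suppressWarnings(.fit_dr(dat, alpha = grid[k],
                                           precision = precision,
                                           share = "none", start = warm)),
                  error = function(e) NULL)
    if (is.null(f)) {
      warning(sprintf("alpha search: fit failed at alpha = %.3f (skipped)",
                      grid[k]), call. = FALSE)
      fits[[k]] <<- list(ok = FALSE)
    } else {
      se <- sqrt(pmax(diag(f$vcov), 0))
      z <- ifelse(se > 0, f$theta * sqrt(f$n) / se, 0)
      warm <<- f$theta
      fits[[k]] <<- list(ok = TRUE, z = z, p = f$p)
    }
    fits[[k]]
  }

  trace <- data.frame(alpha = numeric(0), sqv = numeric(0))
  s <- 1
  repeat {
    last <- s + control$window - 1
    if (last > m) return(list(alpha = 0, trace = trace))
    idx <- s:last
    res <- lapply(idx, zfun)
    ok <- vapply(res, `[[`, logical(1), "ok")
    usable <- idx[ok]
    if (length(usable) < 2) return(list(alpha = 0, trace = trace))
    sqv <- numeric(length(usable) - 1)
    for (j in seq_len(length(usable) - 1)) {
      a <- fits[[usable[j]]]; b <- fits[[usable[j + 1]]]
      sqv[j] <- compute_sqv(a$z, b$z, a$p)
    }
    trace <- rbind(trace, data.frame(alpha = grid[usable[-length(usable)]],
                                     sqv = sqv))
    fail <- which(sqv >= control$threshold)
    if (length(fail) == 0)
      return(list(alpha = grid[min(usable)], trace = trace))
    s_new <- match(grid[usable[max(fail)]], grid)
    s <- if (s_new > s) s_new else s + 1
  }
}
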