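#' Run the estimator-comparison simulation study
#'
#' For each scenario and each estimator, fits `n_datasets` simulated datasets
#' and scores four quantities — log IC50, log IC90 (doses on the natural-log
#' scale), `beta0`, `beta1` — on bias, RMSE, empirical coverage of the nominal
#' 95% CI and mean CI width. Estimators:
#' \describe{
#'   \item{LRM}{logit-linear least squares ([fit_lrm()]).}
#'   \item{HLRM}{logit-linear with t(3) errors ([fit_hlrm()]).}
#'   \item{BRM}{robust beta regression ([dosebeta()]) with the data-driven
#'     alpha search (or a fixed `brm_alpha`).}
#'   \item{LRM_truncated}{LRM after deleting records flagged by
#'     [classify_extreme()].}
#' }
#' All estimators see the identical dataset for a given
#' (scenario, replicate) pair, so comparisons are paired. Replicates where an
#' estimator fails are excluded from that estimator's metrics and counted.
#'
#' @param scenarios a [dr_scenario()] or list of them.
#' @param estimators character subset of
#'   `c("LRM", "HLRM", "BRM", "LRM_truncated")`.
#' @param n_datasets number of simulated datasets per scenario.
#' @param seed master seed (overrides each scenario's own seed).
#' @param brm_alpha fixed tuning parameter for BRM, or `NULL` for the SQV
#'   search.
#' @param conf_level nominal CI level scored.
#' @return a long-format data frame of class `"dr_sim_report"`: columns
#'   `scenario`, `estimator`, `quantity`, `metric`, `value`; failure counts in
#'   `attr(, "failures")`.
#' @export
run_study <- function(scenarios, estimators = c("LRM", "HLRM", "BRM",
                                                "LRM_truncated"),
                      n_datasets = 100, seed = NULL, brm_alpha = NULL,
                      conf_level = 0.95) {
  if (inherits(scenarios, "dr_scenario")) scenarios <- list(scenarios)
  valid <- c("LRM", "HLRM", "BRM", "LRM_truncated")
  bad <- setdiff(estimators, valid)
  if (length(bad))
    stop(sprintf("unknown estimator(s): %s (valid: %s)",
                 paste(bad, collapse = ", "), paste(valid, collapse = ", ")),
         call. = FALSE)
  quantities <- c("log_ic50", "log_ic90", "beta0", "beta1")
  rows <- list()
  failures <- list()
  for (sc in scenarios) {
    if (!is.null(seed)) sc$seed <- as.integer(seed)
    truth <- c(
      log_ic50 = (logit(0.5) - sc$beta0) / sc$beta1,
      log_ic90 = (logit(0.9) - sc$beta0) / sc$beta1,
      beta0 = sc$beta0, beta1 = sc$beta1)
    est_store <- lapply(estimators, function(e)
      lapply(quantities, function(q) matrix(NA_real_, n_datasets, 3)))
    names(est_store) <- estimators
    for (e in estimators) names(est_store[[e]]) <- quantities
    nfail <- stats::setNames(integer(length(estimators)), estimators)

    for (r in seq_len(n_datasets)) {
      dat <- generate_dataset(sc, r)
      for (e in estimators) {
        ex <- tryCatch(
          suppressWarnings(.fit_and_extract(e, dat, brm_alpha, conf_level)),
          error = function(err) NULL)
        if (is.null(ex)) { nfail[e] <- nfail[e] + 1L; next }
        for (q in quantities) est_store[[e]][[q]][r, ] <- ex[[q]]
      }
    }

    for (e in estimators) for (q in quantities) {
      M <- est_store[[e]][[q]]
      ok <- stats::complete.cases(M)
      M <- M[ok, , drop = FALSE]
      tv <- truth[[q]]
      vals <- if (nrow(M) == 0) {
        c(bias = NA, rmse = NA, coverage = NA, ci_width = NA)
      } else c(
        bias = mean(M[, 1]) - tv,
        rmse = sqrt(mean((M[, 1] - tv)^2)),
        coverage = mean(M[, 2] <= tv & tv <= M[, 3]),
        ci_width = mean(M[, 3] - M[, 2]))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$name, estimator = e, quantity = q,
        metric = names(vals), value = unname(vals),
        stringsAsFactors = FALSE)
    }
    failures[[sc$name]] <- nfail
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  class(out) <- c("dr_sim_report", "data.frame")
  out
}

# fit one estimator and return list(quantity -> c(est, lwr, upr))
.fit_and_extract <- function(estimator, dat, brm_alpha, conf_level) {
  if (estimator == "LRM_truncated") {
    keep <- !classify_extreme(dat$response)
    sub <- dat[keep, , drop = FALSE]
    if (nrow(sub) < 3 || length(unique(sub$dose)) < 2)
      stop("too few interior records after deleting extremes")
    dat <- dose_response_data(sub$dose, sub$response, sub$group)
    estimator <- "LRM"
  }
  fit <- switch(estimator,
    LRM = fit_lrm(dat),
    HLRM = fit_hlrm(dat),
    BRM = dosebeta(dat, alpha = brm_alpha))
  g <- .fit_groups(fit)[1]
  pr <- .group_params(fit, g)
  z <- .fit_crit(fit, conf_level)
  out <- list()
  for (p in c(0.5, 0.9)) {
    q <- logit(p)
    logD <- (q - pr$beta[1]) / pr$beta[2]
    gr <- c(-1 / pr$beta[2], -(q - pr$beta[1]) / pr$beta[2]^2)
    se <- sqrt(max(0, drop(t(gr) %*% pr$V %*% gr)))
    out[[if (p == 0.5) "log_ic50" else "log_ic90"]] <-
      c(logD, logD - z * se, logD + z * se)
  }
  se0 <- sqrt(max(0, pr$V[1, 1])); se1 <- sqrt(max(0, pr$V[2, 2]))
  out$beta0 <- c(pr$beta[1], pr$beta[1] - z * se0, pr$beta[1] + z * se0)
  out$beta1 <- c(pr$beta[2], pr$beta[2] - z * se1, pr$beta[2] + z * se1)
  out
}

#' @export
print.dr_sim_report <- function(x, digits = 3, ...) {
  cat("Simulation study report\n")
  w <- stats::reshape(as.data.frame(x), idvar = c("scenario", "estimator", "quantity"),
                      timevar = "metric", direction = "wide")
  names(w) <- sub("^value\\.", "", names(w))
  print(w, digits = digits, row.names = FALSE)
  fl <- attr(x, "failures")
  if (!is.null(fl)) {
    for (s in names(fl)) if (any(fl[[s]] > 0))
      cat(sprintf("  failures in '%s': %s\n", s,
                  paste(names(fl[[s]]), fl[[s]], sep = "=", collapse = ", ")))
  }
  invisible(x)
}
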