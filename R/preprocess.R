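#' Assemble and validate a dose-response dataset
#'
#' Builds the canonical dataset used by [dosebeta()]: a data frame with columns
#' `dose`, `response`, `group` plus a `flag` column recording what
#' preprocessing did to each record (`"raw"`, `"truncated"`, `"dropped"`).
#' Records with nonpositive dose are dropped (log dose is undefined there, and
#' a zero-dose well is a control, not a point on the log-linear curve);
#' responses outside the open unit interval are mapped just inside it by the
#' chosen truncation method, applied per group.
#'
#' If more than half of the responses exceed 1.5 the column is assumed to be in
#' percent and rescaled by 1/100 with a warning.
#'
#' @param dose positive numeric vector of concentrations.
#' @param response numeric vector of effects, nominally in (0, 1).
#' @param group character or factor of group labels (defaults to one group).
#' @param truncation `"sequential"` (default) perturbs only offending values;
#'   `"conventional"` applies \eqn{(y (n - 1) + 0.5)/n} to every value in the
#'   group.
#' @return a `data.frame` of class `"dose_response_data"` with attributes
#'   `log` (character vector of preprocessing messages).
#' @seealso [read_dose_response()] for the CSV front end.
#' @export
dose_response_data <- function(dose, response, group = NULL,
                               truncation = c("sequential", "conventional")) {
  truncation <- match.arg(truncation)
  n <- length(dose)
  if (length(response) != n)
    stop("dose and response lengths differ", call. = FALSE)
  if (is.null(group)) group <- rep("1", n)
  group <- as.character(group)
  if (length(group) != n)
    stop("group length differs from dose length", call. = FALSE)
  if (any(is.na(dose)) || any(is.na(response)))
    stop("missing values in dose or response", call. = FALSE)
  if (any(!nzchar(group)) || any(is.na(group)))
    stop("group labels must be non-empty", call. = FALSE)

  log_lines <- character(0)

  # percent-scale detection
  if (mean(response > 1.5) > 0.5) {
    response <- response / 100
    warning("responses look like percentages (>50% of values exceed 1.5); ",
            "rescaled by 1/100", call. = FALSE)
    log_lines <- c(log_lines, "responses rescaled from percent to fraction")
  }

  flag <- rep("raw", n)

  # drop nonpositive doses
  bad_dose <- dose <= 0 | !is.finite(dose)
  if (any(bad_dose)) {
    warning(sprintf("dropping %d record(s) with nonpositive dose (rows: %s)",
                    sum(bad_dose), paste(which(bad_dose), collapse = ", ")),
            call. = FALSE)
    log_lines <- c(log_lines,
                   sprintf("dropped %d nonpositive-dose record(s)", sum(bad_dose)))
    flag[bad_dose] <- "dropped"
  }
  keep <- !bad_dose
  d <- dose[keep]; y <- response[keep]; g <- group[keep]; f <- flag[keep]

  # per-group unit-interval truncation
  for (gr in unique(g)) {
    idx <- g == gr
    tr <- truncate_unit_interval(y[idx], method = truncation)
    y[idx] <- tr$values
    f[idx][tr$flags] <- "truncated"
    if (any(tr$flags))
      log_lines <- c(log_lines,
                     sprintf("group '%s': %d response(s) truncated into (0,1) [%s]",
                             gr, sum(tr$flags), truncation))
  }

  for (gr in unique(g)) {
    if (length(unique(d[g == gr])) < 2)
      stop(sprintf("group '%s' has fewer than 2 distinct positive doses", gr),
           call. = FALSE)
  }

  out <- data.frame(dose = d, response = y, group = g, flag = f,
                    stringsAsFactors = FALSE)
  attr(out, "log") <- log_lines
  attr(out, "truncation") <- truncation
  class(out) <- c("dose_response_data", "data.frame")
  out
}

#' Map responses strictly inside the unit interval
#'
#' Two strategies for boundary or out-of-range unit-interval responses.
#' `"conventional"` is the textbook shrink \eqn{y \mapsto (y(n-1)+0.5)/n}
#' applied to all values (n = group sample size), which disturbs every
#' observation. `"sequential"` leaves interior values untouched and maps only
#' offending values just inside the boundary: the j-th most extreme value at or
#' above 1 goes to \eqn{1 - j\delta} and the j-th at or below 0 to
#' \eqn{j\delta}, with \eqn{\delta = \min(\mathrm{gap}/2,\ 1/(2n),\ 10^{-3})}
#' where gap is the distance from the most extreme interior value to that
#' boundary. Rank order is preserved and truncated values never collide with
#' interior ones.
#'
#' @param y finite numeric vector (one group).
#' @param method `"sequential"` or `"conventional"`.
#' @return list with `values` (the mapped vector) and `flags` (logical, `TRUE`
#'   where a value was changed).
#' @export
truncate_unit_interval <- function(y, method = c("sequential", "conventional")) {
  method <- match.arg(method)
  if (any(!is.finite(y))) stop("responses must be finite", call. = FALSE)
  n <- length(y)
  if (method == "conventional") {
    out <- (y * (n - 1) + 0.5) / n
    return(list(values = out, flags = rep(TRUE, n)))
  }
  out <- y
  flags <- rep(FALSE, n)
  hi <- which(y >= 1)
  lo <- which(y <= 0)
  if (length(hi)) {
    interior_max <- suppressWarnings(max(y[y < 1 & y > 0], 0))
    delta <- min((1 - interior_max) / 2, 1 / (2 * n), 1e-3)
    ord <- hi[order(y[hi], decreasing = TRUE)]  # most extreme first
    out[ord] <- 1 - seq_along(ord) * delta
    flags[hi] <- TRUE
  }
  if (length(lo)) {
    interior_min <- suppressWarnings(min(y[y > 0 & y < 1], 1))
    delta <- min(interior_min / 2, 1 / (2 * n), 1e-3)
    ord <- lo[order(y[lo])]  # most extreme (most negative) first
    out[ord] <- seq_along(ord) * delta
    flags[lo] <- TRUE
  }
  list(values = out, flags = flags)
}

#' Read a three-column dose-response CSV
#'
#' Expects a comma-separated file with one header row and at least three
#' columns interpreted positionally as dose, response and group name, the
#' common export format of plate-reader summaries. Parsing failures are
#' reported with their (data) row numbers. The result is validated and
#' preprocessed by [dose_response_data()].
#'
#' @param path path to a CSV file.
#' @inheritParams dose_response_data
#' @return a `dose_response_data` data frame.
#' @export
read_dose_response <- function(path,
                               truncation = c("sequential", "conventional")) {
  truncation <- match.arg(truncation)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (ncol(raw) < 3)
    stop(sprintf("need >= 3 columns (dose, response, group); found %d",
                 ncol(raw)), call. = FALSE)
  dose <- suppressWarnings(as.numeric(raw[[1]]))
  resp <- suppressWarnings(as.numeric(raw[[2]]))
  if (any(is.na(dose)))
    stop(sprintf("non-numeric dose in row(s): %s",
                 paste(which(is.na(dose)), collapse = ", ")), call. = FALSE)
  if (any(is.na(resp)))
    stop(sprintf("non-numeric response in row(s): %s",
                 paste(which(is.na(resp)), collapse = ", ")), call. = FALSE)
  dose_response_data(dose, resp, raw[[3]], truncation = truncation)
}
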