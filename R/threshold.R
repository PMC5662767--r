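#' Recover the per-cell activation-threshold distribution
#'
#' Under the threshold model, the expected responder fraction at ligand dose
#' `d` equals the cumulative distribution of per-cell activation thresholds at
#' `d`. Assuming log-normal thresholds, this fits
#' `F(d; mu_theta, sigma_theta) = plnorm(d, mu_theta, sigma_theta)` to the
#' observed per-dose responder fractions by weighted least squares (weights =
#' events per well), via bounded quasi-Newton optimization initialized from a
#' probit regression of the fractions on log dose. Confidence intervals come
#' from a nonparametric bootstrap that resamples wells.
#'
#' @param series `data.frame` with columns `dose` (in \[0, 1\]), `fraction`
#'   (responder fraction in \[0, 1\], `NA` allowed and dropped) and optionally
#'   `n_events` (weights; default equal). At least 4 distinct non-zero doses
#'   with defined fractions are required, and the fractions must not all be 0
#'   or all 1 (unidentifiable).
#' @param n_boot Bootstrap replicates for the CIs (default 200; 0 disables).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `threshold_model`: `mu_theta_hat`,
#'   `sigma_theta_hat`, `per_dose` (the data used), `fit_rss` (weighted
#'   residual sum of squares), `ci` (matrix of bootstrap percentile intervals,
#'   or `NULL`), `n_boot_ok`.
#' @export
fit_threshold_distribution <- function(series, n_boot = 200, seed = NULL,
                                       conf = 0.95) {
  stopifnot(is.data.frame(series))
  if (!all(c("dose", "fraction") %in% names(series)))
    stop("series must have columns dose and fraction", call. = FALSE)
  if (is.null(series$n_events)) series$n_events <- 1
  d <- series[!is.na(series$fraction) & series$dose > 0, , drop = FALSE]
  if (length(unique(d$dose)) < 4L)
    stop("need responder fractions at >= 4 distinct non-zero doses",
         call. = FALSE)
  if (any(d$fraction < 0 | d$fraction > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (all(d$fraction == 0) || all(d$fraction == 1))
    stop("threshold distribution unidentifiable: all fractions are ",
         if (all(d$fraction == 0)) "0" else "1", call. = FALSE)
  est <- fit_theta_wls(d)
  ci <- NULL; n_ok <- 0L
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    boot <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(d), replace = TRUE)
      db <- d[idx, , drop = FALSE]
      if (length(unique(db$dose)) < 4L || all(db$fraction == 0) ||
          all(db$fraction == 1)) next
      fb <- try(fit_theta_wls(db), silent = TRUE)
      if (!inherits(fb, "try-error")) boot[b, ] <- fb$par
    }
    ok <- stats::complete.cases(boot)
    n_ok <- sum(ok)
    if (n_ok >= 10) {
      a <- (1 - conf) / 2
      ci <- rbind(mu_theta = stats::quantile(boot[ok, 1], c(a, 1 - a)),
                  sigma_theta = stats::quantile(boot[ok, 2], c(a, 1 - a)))
    }
  }
  structure(list(mu_theta_hat = est$par[1], sigma_theta_hat = est$par[2],
                 per_dose = d, fit_rss = est$value, ci = ci,
                 n_boot_ok = n_ok),
            class = "threshold_model")
}

# Weighted least squares of the log-normal CDF; probit-regression start.
fit_theta_wls <- function(d) {
  z <- stats::qnorm(pmin(pmax(d$fraction, 1e-4), 1 - 1e-4))
  ld <- log(d$dose)
  start <- c(stats::median(ld), 1)
  if (length(unique(ld)) >= 2 && stats::sd(z) > 0) {
    co <- stats::coef(stats::lm(z ~ ld, weights = d$n_events))
    if (is.finite(co[2]) && co[2] > 1e-6)
      start <- c(-co[1] / co[2], 1 / co[2])
  }
  start[2] <- min(max(start[2], 1e-3), 10)
  start[1] <- min(max(start[1], -30), 10)
  obj <- function(p) sum(d$n_events *
                           (d$fraction - stats::plnorm(d$dose, p[1], p[2]))^2)
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(-30, 1e-3), upper = c(10, 10))
  list(par = fit$par, value = fit$value)
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "Activation-threshold distribution: median dose %.4g (mu %.3f), sigma %.3f log units\n",
    exp(x$mu_theta_hat), x$mu_theta_hat, x$sigma_theta_hat))
  cat(sprintf("  fitted on %d wells, weighted RSS %.4g\n", nrow(x$per_dose),
              x$fit_rss))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap CI (n = %d): mu [%.3f, %.3f], sigma [%.3f, %.3f]\n",
                x$n_boot_ok, x$ci[1, 1], x$ci[1, 2], x$ci[2, 1], x$ci[2, 2]))
  }
  invisible(x)
}

#' Dose at which a given fraction of cells respond
#'
#' Inverse of the fitted threshold CDF: the dose `d` with `F(d) = level`. At
#' `level = 0.5` this is the median activation threshold `exp(mu_theta_hat)`;
#' `level = 0.95` gives a saturation dose in the sense that 95% of cells are
#' above threshold.
#'
#' @param model A `threshold_model`.
#' @param level Target responder fraction in (0, 1). Default 0.95.
#' @return Dose (volume fraction of conditioned medium).
#' @export
saturation_dose <- function(model, level = 0.95) {
  stopifnot(inherits(model, "threshold_model"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)", call. = FALSE)
  stats::qlnorm(level, model$mu_theta_hat, model$sigma_theta_hat)
}

#' Convert a conditioned:fresh mixing ratio to a dose fraction
#'
#' Dilution ratios are written `"a:b"` meaning `a` parts conditioned medium to
#' `b` parts fresh medium; the dose variable of this package is the volume
#' fraction of conditioned medium, `a / (a + b)`. So `"1:1"` parses to 0.5 and
#' `"1:5"` to 1/6.
#'
#' @param ratio Character vector of ratios (`"1:5"`), or numeric values in
#'   \[0, 1\] passed through unchanged.
#' @return Numeric dose fraction(s).
#' @export
parse_dilution_ratio <- function(ratio) {
  if (is.numeric(ratio)) {
    if (any(ratio < 0 | ratio > 1))
      stop("numeric doses must lie in [0, 1]", call. = FALSE)
    return(ratio)
  }
  vapply(as.character(ratio), function(r) {
    parts <- strsplit(r, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed ratio '", r, "'; expected 'a:b'", call. = FALSE)
    a <- suppressWarnings(as.numeric(parts[1]))
    b <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(a) || is.na(b) || a < 0 || b < 0 || a + b == 0)
      stop("malformed ratio '", r, "'", call. = FALSE)
    a / (a + b)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Descriptive time-course summary
#'
#' Sorts per-time-point well summaries by stimulation time. Purely
#' descriptive: no kinetic model is fitted.
#'
#' @param wells `data.frame` with columns `time_h`, `median_fl` and optionally
#'   `normalized_response` (>= 2 time points).
#' @return The same columns, sorted by `time_h`.
#' @export
summarize_time_course <- function(wells) {
  stopifnot(is.data.frame(wells))
  if (!all(c("time_h", "median_fl") %in% names(wells)))
    stop("wells must have columns time_h and median_fl", call. = FALSE)
  if (nrow(wells) < 2L)
    stop("need at least 2 time points", call. = FALSE)
  out <- wells[order(wells$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate per-dose responder fractions for a dilution series
#'
#' Convenience wrapper: gates each well of a dilution series (optional),
#' estimates the responder fraction of each via the mixture route, and returns
#' the table [fit_threshold_distribution()] consumes. The zero-dose well (if
#' present) supplies the unstimulated reference fit.
#'
#' @param tables Named list of [event_table()]s (e.g. from
#'   [simulate_dilution_series()]).
#' @param doses Numeric vector of doses, parallel to `tables`.
#' @param gate Optional `scatter_gate`; when given, wells are gated first and
#'   QC-failing wells get `NA` fractions.
#' @param seed Passed through to the mixture fits.
#' @return `data.frame` with columns `well_id`, `dose`, `fraction`,
#'   `n_events`.
#' @export
dilution_responder_fractions <- function(tables, doses, gate = NULL,
                                         seed = NULL) {
  stopifnot(length(tables) == length(doses))
  fls <- vector("list", length(tables))
  qc <- rep(TRUE, length(tables))
  for (i in seq_along(tables)) {
    if (!is.null(gate)) {
      g <- apply_gate(tables[[i]], gate)
      qc[i] <- g$qc_pass
      fls[[i]] <- g$gated_events$fl
    } else fls[[i]] <- tables[[i]]$fl
  }
  ref <- NULL
  zero <- which(doses == 0)
  if (length(zero))
    ref <- fit_mixture(fls[[zero[1]]], k = 1, seed = seed)
  frac <- rep(NA_real_, length(tables))
  for (i in seq_along(tables)) {
    if (!qc[i] || length(fls[[i]]) < 50L) next
    frac[i] <- suppressWarnings(
      responder_fraction(fls[[i]], reference_off = ref, seed = seed))
  }
  data.frame(well_id = vapply(tables, well_id, character(1)),
             dose = as.numeric(doses), fraction = frac,
             n_events = vapply(fls, length, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
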