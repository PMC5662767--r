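#' Fit a one- or two-component Gaussian mixture to log fluorescence
#'
#' The quantitative counterpart of the bimodal histograms seen at intermediate
#' ligand doses: cells sit in either a low ("off") or a high ("on")
#' fluorescence state, so log fluorescence is modelled as a mixture of one or
#' two Gaussians fitted by expectation-maximization. Initialization for
#' `k = 2` is a deterministic split at the sample median (means/SDs of the two
#' halves, equal weights); EM stops when the log-likelihood improves by less
#' than `tol` or after `max_iter` iterations. Component scales are floored at
#' `scale_floor` log units to prevent single-point collapse. With the default
#' deterministic initialization the fit does not consume randomness; `seed`
#' controls the optional random restart.
#'
#' @param fl_values Linear fluorescence values (>= 50 of them, all positive).
#' @param k Number of components, 1 or 2.
#' @param seed Seed for the optional random restart.
#' @param max_iter,tol EM iteration cap (500) and log-likelihood tolerance
#'   (1e-8).
#' @param scale_floor Minimum component scale in log units (1e-3).
#' @param random_restart If `TRUE`, one additional EM run from a random
#'   responsibility split is performed and the better likelihood kept.
#' @return Object of class `mixture_fit`: `k`, `weights`, `locations`
#'   (ascending for `k = 2`), `scales`, `loglik`, `bic`, `converged`,
#'   `n_iter`, `n`, `degenerate` (constant-data fit) and, for `k = 2`,
#'   `degenerate_bimodal` (a vanishing or unseparated second component).
#' @export
fit_mixture <- function(fl_values, k = 2, seed = NULL, max_iter = 500,
                        tol = 1e-8, scale_floor = 1e-3,
                        random_restart = FALSE) {
  if (!k %in% c(1, 2)) stop("k must be 1 or 2", call. = FALSE)
  fl <- as.numeric(fl_values)
  if (length(fl) < 50L)
    stop("need at least 50 fluorescence values", call. = FALSE)
  if (anyNA(fl) || any(fl <= 0))
    stop("fluorescence values must be positive and non-missing",
         call. = FALSE)
  x <- log(fl)
  n <- length(x)
  if (stats::sd(x) < 1e-12) {
    warning("all fluorescence values identical; returning degenerate ",
            "single-component fit")
    ll <- sum(stats::dnorm(x, mean(x), scale_floor, log = TRUE))
    return(new_mixture_fit(1, 1, mean(x), scale_floor, ll, n,
                           converged = TRUE, n_iter = 0L, degenerate = TRUE))
  }
  if (k == 1) {
    mu <- mean(x)
    s <- max(sqrt(mean((x - mu)^2)), scale_floor)
    ll <- sum(stats::dnorm(x, mu, s, log = TRUE))
    return(new_mixture_fit(1, 1, mu, s, ll, n, converged = TRUE,
                           n_iter = 0L))
  }
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (length(hi) == 0L) { hi <- max(x); lo <- x[x < max(x)] }
  init <- list(w = c(length(lo), length(hi)) / n,
               mu = c(mean(lo), mean(hi)),
               s = pmax(c(stats::sd(lo), stats::sd(hi)), scale_floor))
  fit <- em2(x, init, max_iter, tol, scale_floor)
  if (random_restart) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    g <- stats::runif(n) < 0.5
    if (any(g) && any(!g)) {
      init2 <- list(w = c(mean(!g), mean(g)),
                    mu = c(mean(x[!g]), mean(x[g])),
                    s = pmax(c(stats::sd(x[!g]), stats::sd(x[g])),
                             scale_floor, na.rm = TRUE))
      alt <- em2(x, init2, max_iter, tol, scale_floor)
      if (alt$loglik > fit$loglik) fit <- alt
    }
  }
  ord <- order(fit$mu)
  out <- new_mixture_fit(2, fit$w[ord], fit$mu[ord], fit$s[ord], fit$loglik,
                         n, converged = fit$converged, n_iter = fit$n_iter)
  # two overlapping half-components on unimodal data are not two modes:
  # flag a vanishing component, near-identical locations, or separation
  # below 2 pooled scales as a degenerate bimodal fit
  pooled <- sqrt(sum(out$weights * out$scales^2))
  out$degenerate_bimodal <- min(out$weights) < 0.05 ||
    abs(diff(out$locations)) < 0.1 ||
    abs(diff(out$locations)) < 2 * pooled
  out
}

# Two-component EM on log values; log-sum-exp responsibilities.
em2 <- function(x, init, max_iter, tol, scale_floor) {
  n <- length(x)
  w <- init$w; mu <- init$mu; s <- init$s
  ll_prev <- -Inf; ll <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    la <- cbind(log(w[1]) + stats::dnorm(x, mu[1], s[1], log = TRUE),
                log(w[2]) + stats::dnorm(x, mu[2], s[2], log = TRUE))
    m <- pmax(la[, 1], la[, 2])
    lse <- m + log(exp(la[, 1] - m) + exp(la[, 2] - m))
    ll <- sum(lse)
    g2 <- exp(la[, 2] - lse)
    g1 <- 1 - g2
    n1 <- sum(g1); n2 <- sum(g2)
    if (n1 < 1e-10 || n2 < 1e-10) break
    w <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
    s <- pmax(c(sqrt(sum(g1 * (x - mu[1])^2) / n1),
                sqrt(sum(g2 * (x - mu[2])^2) / n2)), scale_floor)
    if (is.finite(ll_prev) && ll - ll_prev < tol) { converged <- TRUE; break }
    ll_prev <- ll
  }
  list(w = w, mu = mu, s = s, loglik = ll, converged = converged, n_iter = it)
}

new_mixture_fit <- function(k, w, mu, s, ll, n, converged, n_iter,
                            degenerate = FALSE) {
  p <- if (k == 1) 2 else 5
  structure(list(k = k, weights = as.numeric(w), locations = as.numeric(mu),
                 scales = as.numeric(s), loglik = ll,
                 bic = -2 * ll + p * log(n), converged = converged,
                 n_iter = n_iter, n = n, degenerate = degenerate),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Log-normal mixture fit (k = %d, n = %d): logLik %.2f, BIC %.2f%s\n",
              x$k, x$n, x$loglik, x$bic,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  for (i in seq_len(x$k))
    cat(sprintf("  comp %d: weight %.3f, medFL %.3g, scale %.3f log units\n",
                i, x$weights[i], exp(x$locations[i]), x$scales[i]))
  invisible(x)
}

#' Decide whether a fluorescence histogram is bimodal
#'
#' Fits one- and two-component mixtures and calls the well bimodal when the
#' two-component model is decisively better (`BIC(1) - BIC(2) > delta_bic`)
#' AND the minority component carries at least `min_weight` of the cells AND
#' the component locations are separated by at least `min_separation` pooled
#' scales. Constant data is unimodal by the degenerate rule.
#'
#' @param fl_values Linear fluorescence values (>= 50).
#' @param seed Passed to [fit_mixture()].
#' @param delta_bic BIC margin required to prefer two components (default 10).
#' @param min_weight Minimum minority-component weight (default 0.05).
#' @param min_separation Minimum location separation in pooled-scale units
#'   (default 2).
#' @return List with `call` (`"unimodal"` or `"bimodal"`), `delta_bic`,
#'   `fit1`, `fit2`.
#' @export
bimodality_decision <- function(fl_values, seed = NULL, delta_bic = 10,
                                min_weight = 0.05, min_separation = 2) {
  fit1 <- fit_mixture(fl_values, k = 1, seed = seed)
  if (isTRUE(fit1$degenerate))
    return(list(call = "unimodal", delta_bic = 0, fit1 = fit1, fit2 = fit1))
  fit2 <- fit_mixture(fl_values, k = 2, seed = seed)
  dbic <- fit1$bic - fit2$bic
  pooled <- sqrt(sum(fit2$weights * fit2$scales^2))
  sep <- abs(diff(fit2$locations)) / pooled
  bim <- dbic > delta_bic && min(fit2$weights) >= min_weight &&
    sep >= min_separation
  list(call = if (bim) "bimodal" else "unimodal", delta_bic = dbic,
       fit1 = fit1, fit2 = fit2)
}

#' Estimate the responder fraction of a well
#'
#' The fraction of cells whose sensor is in the high-fluorescence state. If
#' the well is bimodal, this is the mixture weight of the upper component. If
#' it is unimodal, the single component is classified against the unstimulated
#' control's off-state location: within `2` control scales it is the off state
#' (fraction 0), otherwise the whole well has activated (fraction 1). A
#' unimodal well with no reference is indeterminate: the function returns `NA`
#' with a warning.
#'
#' @param fl_values Linear fluorescence values (>= 50).
#' @param reference_off Optional `mixture_fit` of an unstimulated control well
#'   (its lowest component anchors the off state).
#' @param seed,... Passed to [bimodality_decision()].
#' @return Responder fraction in \[0, 1\], or `NA` when indeterminate.
#' @export
responder_fraction <- function(fl_values, reference_off = NULL, seed = NULL,
                               ...) {
  dec <- bimodality_decision(fl_values, seed = seed, ...)
  if (dec$call == "bimodal") return(dec$fit2$weights[2])
  loc <- dec$fit1$locations[1]
  if (is.null(reference_off)) {
    warning("indeterminate responder fraction: unimodal well with no ",
            "unstimulated reference")
    return(NA_real_)
  }
  stopifnot(inherits(reference_off, "mixture_fit"))
  i <- which.min(reference_off$locations)
  ref_loc <- reference_off$locations[i]
  ref_scale <- reference_off$scales[i]
  if (abs(loc - ref_loc) <= 2 * ref_scale) 0 else 1
}
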