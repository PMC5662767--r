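#' Fit a viable-cell scatter gate from control wells
#'
#' Fits an ellipsoidal gate in log FSC/SSC space to control events, standing
#' in for the manual scatter gate drawn "according to the control cells" in
#' interactive flow software, but deterministic and auditable. Location and
#' dispersion are estimated robustly (minimum volume ellipsoid via
#' [MASS::cov.rob()]) so debris contamination of the controls does not inflate
#' the gate; the gate radius is the empirical `coverage_quantile` of the
#' control events' Mahalanobis distances, so the realized in-gate fraction of
#' the control events is within `1/n` of the requested coverage.
#'
#' @param control_events An [event_table()] or a list of them (pooled).
#' @param coverage_quantile Target fraction of control events inside the gate,
#'   in (0, 1). Default 0.90.
#' @return An object of class `scatter_gate`: `center` (log-scatter
#'   location), `shape` (2x2 dispersion matrix), `radius2` (squared
#'   Mahalanobis radius), `coverage_quantile`.
#' @export
fit_gate <- function(control_events, coverage_quantile = 0.9) {
  if (inherits(control_events, "event_table"))
    control_events <- list(control_events)
  stopifnot(is.list(control_events), length(control_events) >= 1L)
  xs <- do.call(rbind, lapply(control_events, function(e) {
    stopifnot(inherits(e, "event_table"))
    cbind(log(e$fsc), log(e$ssc))
  }))
  if (!is.numeric(coverage_quantile) || length(coverage_quantile) != 1L ||
      coverage_quantile <= 0 || coverage_quantile >= 1)
    stop("coverage_quantile must lie in (0, 1)", call. = FALSE)
  n <- nrow(xs)
  if (n < 50) stop("need at least 50 control events to fit a gate",
                   call. = FALSE)
  ev <- eigen(stats::cov(xs), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10)
    stop("degenerate control scatter: log FSC/SSC covariance is rank deficient",
         call. = FALSE)
  rob <- MASS::cov.rob(xs, method = "mve")
  shape <- rob$cov
  center <- rob$center
  d2 <- stats::mahalanobis(xs, center, shape)
  # type-1 (left-continuous inverse ECDF) quantile: the in-gate control count
  # is exactly ceiling(q * n) when distances are distinct
  r2 <- sort(d2)[ceiling(coverage_quantile * n)]
  structure(list(center = center, shape = shape, radius2 = r2,
                 coverage_quantile = coverage_quantile,
                 n_control_events = n),
            class = "scatter_gate")
}

#' @export
print.scatter_gate <- function(x, ...) {
  cat(sprintf(
    "Scatter gate: center (logFSC %.2f, logSSC %.2f), radius %.3f, coverage %.2f (fit on %d events)\n",
    x$center[1], x$center[2], sqrt(x$radius2), x$coverage_quantile,
    x$n_control_events))
  invisible(x)
}

#' Apply a scatter gate to a well
#'
#' Gate membership is decided by Mahalanobis distance in log FSC/SSC space:
#' events with squared distance less than or equal to the gate radius are
#' inside (boundary events count as inside). Fluorescence values are not
#' touched. The QC flag implements the screen inclusion rule: a well passes
#' only if strictly more than half of its events fall inside the gate.
#'
#' @param events Non-empty [event_table()].
#' @param gate A `scatter_gate` from [fit_gate()].
#' @param qc_threshold Gated-fraction QC cut; a well passes when
#'   `gated_fraction > qc_threshold` (strict). Default 0.5.
#' @return An object of class `gated_well`: `well_id`, `n_total`, `n_gated`,
#'   `gated_fraction`, `qc_pass`, and `gated_events` (the in-gate
#'   [event_table()]).
#' @export
apply_gate <- function(events, gate, qc_threshold = 0.5) {
  stopifnot(inherits(gate, "scatter_gate"))
  if (!inherits(events, "event_table") || nrow(events) == 0L)
    stop("events must be a non-empty event_table", call. = FALSE)
  d2 <- stats::mahalanobis(cbind(log(events$fsc), log(events$ssc)),
                           gate$center, gate$shape)
  inside <- d2 <= gate$radius2
  gated <- events[inside, , drop = FALSE]
  attr(gated, "well_id") <- well_id(events)
  class(gated) <- c("event_table", "data.frame")
  frac <- sum(inside) / nrow(events)
  structure(list(well_id = well_id(events),
                 n_total = nrow(events),
                 n_gated = sum(inside),
                 gated_fraction = frac,
                 qc_pass = frac > qc_threshold,
                 gated_events = gated),
            class = "gated_well")
}

#' @export
print.gated_well <- function(x, ...) {
  cat(sprintf("Gated well %s: %d/%d events in gate (%.1f%%), QC %s\n",
              x$well_id, x$n_gated, x$n_total, 100 * x$gated_fraction,
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

#' Per-well gating QC report
#'
#' @param gated_wells List of `gated_well` objects.
#' @return A `data.frame` with one row per well (`well_id`, `n_total`,
#'   `n_gated`, `gated_fraction`, `qc_pass`, `reason`); excluded wells carry
#'   a human-readable reason.
#' @export
qc_report <- function(gated_wells) {
  if (length(gated_wells) == 0L)
    return(data.frame(well_id = character(), n_total = integer(),
                      n_gated = integer(), gated_fraction = numeric(),
                      qc_pass = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(gated_wells, function(g) {
    stopifnot(inherits(g, "gated_well"))
    data.frame(well_id = g$well_id, n_total = g$n_total, n_gated = g$n_gated,
               gated_fraction = g$gated_fraction, qc_pass = g$qc_pass,
               reason = if (g$qc_pass) "" else
                 sprintf("gated fraction %.3f not > 0.5", g$gated_fraction),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
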