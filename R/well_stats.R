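#' Median fluorescence of a gated population
#'
#' Exact median of the in-gate fluorescence values (midpoint convention for
#' even counts). Optionally subsamples the gated events without replacement to
#' a fixed acquisition count first — emulating a cytometer that stops at a set
#' number of cells per well — deterministically under the given seed.
#'
#' @param gated A `gated_well` from [apply_gate()] or an [event_table()].
#' @param subsample_n Optional number of events to subsample to (without
#'   replacement; no-op when the well has fewer events).
#' @param seed Seed for the subsample; required when `subsample_n` is given.
#' @return Median fluorescence in linear units.
#' @export
median_fluorescence <- function(gated, subsample_n = NULL, seed = NULL) {
  fl <- if (inherits(gated, "gated_well")) gated$gated_events$fl
        else if (inherits(gated, "event_table")) gated$fl
        else stop("gated must be a gated_well or event_table", call. = FALSE)
  if (length(fl) == 0L)
    stop("empty gated population", call. = FALSE)
  if (!is.null(subsample_n) && length(fl) > subsample_n) {
    if (is.null(seed))
      stop("a seed is required for subsampling", call. = FALSE)
    set.seed(as.integer(seed))
    fl <- fl[sample.int(length(fl), subsample_n)]
  }
  stats::median(fl)
}

#' Control pair for the dual-control normalization
#'
#' @param med_pos Median fluorescence of the ligand-stimulated control.
#' @param med_neg Median fluorescence of the non-stimulated (mock) control.
#' @return An object of class `control_pair`.
#' @export
control_pair <- function(med_pos, med_neg) {
  if (!is.finite(med_pos) || !is.finite(med_neg) || med_pos <= 0 ||
      med_neg <= 0)
    stop("control medians must be positive and finite", call. = FALSE)
  if (med_pos == med_neg)
    stop("stimulated and unstimulated control medians are identical",
         call. = FALSE)
  structure(list(med_pos = med_pos, med_neg = med_neg),
            class = "control_pair")
}

#' Normalized response of a treated well
#'
#' The screen's per-well statistic: the difference between the treated well's
#' median fluorescence and the non-stimulated control, normalized to the
#' difference between the stimulated and non-stimulated controls and expressed
#' in percent,
#' \deqn{100 (m_{treat} - m_{neg}) / (m_{pos} - m_{neg}).}
#' A treated median equal to the stimulated control maps to 100% and one equal
#' to the mock control to 0%; values above 100% (activators) and below 0%
#' (suppression beneath the unstimulated baseline) are reported as-is.
#'
#' @param med_treat Treated-well median fluorescence (may be a vector).
#' @param controls A [control_pair()].
#' @param rel_tol Failed-assay guard: the control difference must exceed
#'   `rel_tol * med_neg` in absolute value.
#' @return Normalized response in percent.
#' @export
normalized_response <- function(med_treat, controls, rel_tol = 1e-6) {
  stopifnot(inherits(controls, "control_pair"))
  denom <- controls$med_pos - controls$med_neg
  if (abs(denom) <= rel_tol * controls$med_neg)
    stop("failed assay: stimulated and unstimulated controls are ",
         "indistinguishable on this plate", call. = FALSE)
  100 * (med_treat - controls$med_neg) / denom
}

# Exact two-sided Mann-Whitney p-value by full enumeration of the
# C(n1 + n2, n1) label assignments (permutation null on the rank statistic;
# correct under ties).
mann_whitney_exact <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Normal approximation with tie correction.
mann_whitney_normal <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  2 * stats::pnorm(-abs((u - mu) / sqrt(sig2)))
}

#' Compare treated and control replicates (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test of treated vs control normalized responses.
#' For total sample size up to `exact_max` the p-value is computed from the
#' exact permutation null by full enumeration of label assignments (valid
#' under ties); above that, the normal approximation with tie correction is
#' used.
#'
#' @param treated_replicates,control_replicates Numeric vectors, each of
#'   length >= 2.
#' @param exact_max Largest total sample size for the exact path (default 10).
#' @return Two-sided p-value.
#' @export
compare_to_control <- function(treated_replicates, control_replicates,
                               exact_max = 10) {
  x <- as.numeric(treated_replicates)
  y <- as.numeric(control_replicates)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 replicate values", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("replicate values must not be missing", call. = FALSE)
  if (length(x) + length(y) <= exact_max) mann_whitney_exact(x, y)
  else mann_whitney_normal(x, y)
}

#' Summarize all wells of a gated screen
#'
#' Computes per-well median fluorescence and, for QC-passing wells, the
#' normalized response against the plate's control pair. Control medians are
#' the per-plate medians of the respective control wells' median fluorescence
#' values (robust to a single bad control well); the same plate pair
#' normalizes both ligand-stimulated and mock-stimulated sample wells, so the
#' screen reads out effects on both baselines on one scale.
#'
#' @param gated_wells Named list of `gated_well` objects keyed
#'   `<plate>_<well>`.
#' @param plate_map Plate-map `data.frame` (see [make_plate_map()]).
#' @param subsample_n,seed Optional per-well subsampling passed to
#'   [median_fluorescence()].
#' @return A `data.frame` (one row per well) with columns `plate_id`,
#'   `well_id`, `role`, `compound_id`, `concentration`, `stimulated`,
#'   `n_total`, `n_gated`, `gated_fraction`, `qc_pass`, `median_fl`,
#'   `normalized_response`. `normalized_response` is `NA` for QC-failed wells.
#' @export
summarize_wells <- function(gated_wells, plate_map, subsample_n = NULL,
                            seed = NULL) {
  pm <- validate_plate_map(plate_map)
  pm <- pm[pm$role != "empty", , drop = FALSE]
  keys <- paste(pm$plate_id, pm$well_id, sep = "_")
  missing <- setdiff(keys, names(gated_wells))
  if (length(missing))
    stop("no gated events for well(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  out <- pm
  out$n_total <- NA_integer_; out$n_gated <- NA_integer_
  out$gated_fraction <- NA_real_; out$qc_pass <- NA
  out$median_fl <- NA_real_
  for (i in seq_len(nrow(out))) {
    g <- gated_wells[[keys[i]]]
    out$n_total[i] <- g$n_total
    out$n_gated[i] <- g$n_gated
    out$gated_fraction[i] <- g$gated_fraction
    out$qc_pass[i] <- g$qc_pass
    if (g$n_gated > 0)
      out$median_fl[i] <- median_fluorescence(
        g, subsample_n = subsample_n,
        seed = if (is.null(seed)) NULL else derive_seed(seed, keys[i]))
  }
  out$normalized_response <- NA_real_
  for (pl in unique(out$plate_id)) {
    sel <- out$plate_id == pl
    ctrl <- plate_controls(out[sel, , drop = FALSE])
    ok <- sel & out$qc_pass & !is.na(out$median_fl)
    out$normalized_response[ok] <- normalized_response(out$median_fl[ok], ctrl)
  }
  rownames(out) <- NULL
  out
}

# Per-plate control pair: medians over the QC-passing control wells.
plate_controls <- function(well_summary) {
  pos <- well_summary$median_fl[well_summary$role == "pos_ctrl" &
                                  well_summary$qc_pass]
  neg <- well_summary$median_fl[well_summary$role == "neg_ctrl" &
                                  well_summary$qc_pass]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("plate has no QC-passing control wells of both roles", call. = FALSE)
  control_pair(stats::median(pos), stats::median(neg))
}
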