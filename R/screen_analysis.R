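#' Aggregate compound responses into target-class clusters
#'
#' Groups screened compounds by their annotated primary molecular target and
#' computes the median normalized response per class. Classes with fewer than
#' `min_cluster_size` QC-passing members are suppressed from the cluster table
#' (but reported, so the clustering partitions every QC-passing compound).
#' Clusters are sorted by median response, descending.
#'
#' The input must be a single analysis stratum: if `concentration` or
#' `stimulated` columns are present they must be constant (compounds measured
#' at both screen concentrations are analysed per concentration, not pooled).
#'
#' @param responses `data.frame` with columns `compound_id`,
#'   `normalized_response`, and optionally `qc_pass` (default all `TRUE`),
#'   one row per compound.
#' @param annotation `data.frame` mapping `compound_id` to `target_class`
#'   (see [read_annotation()]); every screened compound must be annotated.
#' @param min_cluster_size Minimum QC-passing members for a reported cluster.
#' @return A `data.frame` of class `cluster_summary` with columns
#'   `target_class`, `n_compounds`, `median_response` and a list-column
#'   `responses` of member values, sorted by `median_response` descending.
#'   Suppressed small clusters are attached as `attr(, "suppressed")` in the
#'   same format.
#' @export
aggregate_by_target <- function(responses, annotation, min_cluster_size = 3) {
  stopifnot(is.data.frame(responses))
  if (nrow(responses) == 0L)
    stop("empty response table", call. = FALSE)
  if (!all(c("compound_id", "normalized_response") %in% names(responses)))
    stop("responses must have compound_id and normalized_response columns",
         call. = FALSE)
  for (strat in c("concentration", "stimulated")) {
    v <- responses[[strat]]
    if (!is.null(v) && length(unique(v[!is.na(v)])) > 1L)
      stop("responses mix more than one '", strat,
           "' stratum; analyse strata separately", call. = FALSE)
  }
  if (is.null(responses$qc_pass)) responses$qc_pass <- TRUE
  ann <- validate_annotation(annotation)
  unknown <- setdiff(unique(responses$compound_id), ann$compound_id)
  if (length(unknown))
    stop("compound(s) missing from the annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ok <- responses$qc_pass & !is.na(responses$normalized_response)
  kept <- responses[ok, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("all compounds QC-failed; no clusters formed")
    empty <- cluster_frame(character(), integer(), numeric(), list())
    attr(empty, "suppressed") <- empty
    return(empty)
  }
  kept$target_class <- ann$target_class[match(kept$compound_id,
                                              ann$compound_id)]
  grp <- split(kept$normalized_response, kept$target_class)
  cl <- cluster_frame(names(grp),
                      vapply(grp, length, integer(1)),
                      vapply(grp, stats::median, numeric(1)),
                      unname(grp))
  big <- cl$n_compounds >= min_cluster_size
  main <- cl[big, , drop = FALSE]
  main <- main[order(-main$median_response, main$target_class), , drop = FALSE]
  rownames(main) <- NULL
  supp <- cl[!big, , drop = FALSE]
  rownames(supp) <- NULL
  attr(main, "suppressed") <- supp
  class(main) <- c("cluster_summary", "data.frame")
  main
}

cluster_frame <- function(target_class, n, med, members) {
  df <- data.frame(target_class = as.character(target_class),
                   n_compounds = as.integer(n),
                   median_response = as.numeric(med),
                   stringsAsFactors = FALSE)
  df$responses <- members
  df
}

#' Rank concordance between two screen conditions
#'
#' Spearman rank correlation between two sets of per-compound (or per-cluster)
#' responses measured under different conditions — e.g. the two screening
#' concentrations, or stimulated vs unstimulated baselines. Entries are paired
#' by name over the intersection; a pairing audit reports how many values were
#' used and dropped.
#'
#' @param responses_a,responses_b Named numeric vectors (names = compound or
#'   cluster ids). `NA` values are dropped.
#' @return List with `rho` (Spearman correlation), `n_used`, `n_dropped`.
#' @export
concordance <- function(responses_a, responses_b) {
  if (is.null(names(responses_a)) || is.null(names(responses_b)))
    stop("responses must be named vectors", call. = FALSE)
  a <- responses_a[!is.na(responses_a)]
  b <- responses_b[!is.na(responses_b)]
  shared <- intersect(names(a), names(b))
  n_total <- length(union(names(responses_a), names(responses_b)))
  if (length(shared) < 3L)
    stop("need at least 3 paired values for concordance", call. = FALSE)
  rho <- stats::cor(a[shared], b[shared], method = "spearman")
  list(rho = unname(rho), n_used = length(shared),
       n_dropped = n_total - length(shared))
}

#' Call hit clusters
#'
#' Labels each target-class cluster an up-hit (median response at or above
#' `up_threshold`), a down-hit (at or below `down_threshold`), or none. Also
#' reports, per cluster, the fraction of member compounds individually beyond
#' the same thresholds — the consistency statistic behind statements like
#' "15 of 23 compounds of this class reduced the response by at least 20%"
#' (normalized response <= 80).
#'
#' @param clusters A `cluster_summary` from [aggregate_by_target()].
#' @param up_threshold Up-hit cut in percent (> 100). Default 150.
#' @param down_threshold Down-hit cut in percent (< 100). Default 80, i.e. a
#'   reduction of the stimulated response by at least 20%.
#' @return `data.frame` with `target_class`, `n_compounds`, `median_response`,
#'   `call` (`"up"`, `"down"`, `"none"`), `frac_members_up`,
#'   `frac_members_down`, `n_members_up`, `n_members_down`.
#' @export
call_hits <- function(clusters, up_threshold = 150, down_threshold = 80) {
  stopifnot(is.data.frame(clusters))
  if (!(down_threshold < 100 && 100 < up_threshold))
    stop("need down_threshold < 100 < up_threshold", call. = FALSE)
  n_up <- vapply(clusters$responses, function(v) sum(v >= up_threshold),
                 integer(1))
  n_dn <- vapply(clusters$responses, function(v) sum(v <= down_threshold),
                 integer(1))
  out <- data.frame(target_class = clusters$target_class,
                    n_compounds = clusters$n_compounds,
                    median_response = clusters$median_response,
                    call = ifelse(clusters$median_response >= up_threshold,
                                  "up",
                                  ifelse(clusters$median_response <=
                                           down_threshold, "down", "none")),
                    n_members_up = n_up,
                    n_members_down = n_dn,
                    frac_members_up = ifelse(clusters$n_compounds > 0,
                                             n_up / clusters$n_compounds, NA),
                    frac_members_down = ifelse(clusters$n_compounds > 0,
                                               n_dn / clusters$n_compounds,
                                               NA),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-cluster significance against plate controls
#'
#' Runs [compare_to_control()] for every cluster's member responses against a
#' vector of control responses and applies Benjamini-Hochberg adjustment
#' across clusters. Reported alongside the medians, never instead of them.
#'
#' @param clusters A `cluster_summary`.
#' @param control_responses Numeric vector of control normalized responses
#'   (length >= 2).
#' @return `data.frame` with `target_class`, `p_value`, `p_adjusted`.
#' @export
cluster_significance <- function(clusters, control_responses) {
  p <- vapply(clusters$responses, function(v) {
    if (length(v) < 2L) return(NA_real_)
    compare_to_control(v, control_responses)
  }, numeric(1))
  data.frame(target_class = clusters$target_class, p_value = p,
             p_adjusted = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}
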