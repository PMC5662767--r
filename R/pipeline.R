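#' Run the full screen analysis pipeline
#'
#' Orchestrates gate fitting, gating + QC, per-well summaries, dual-control
#' normalized responses, target-class aggregation and hit calling, and writes
#' every result table plus a provenance log to an output directory. Events
#' come either from a simulated screen (`config$simulate = TRUE`) or from
#' files on disk.
#'
#' Recognized configuration keys (a named list, or a YAML file read with
#' [read_run_config()]):
#' \describe{
#'   \item{outdir}{Output directory (required).}
#'   \item{seed}{Master seed (required).}
#'   \item{simulate}{If `TRUE`, events are generated with
#'     [simulate_screen()] from `population` (arguments to
#'     [population_config()]), `effects` (list of [compound_effect()]
#'     argument lists) and `stim_dose`.}
#'   \item{events_path / events_dir}{Alternatively, a multi-well CSV or a
#'     directory of per-well FCS files named `<plate>_<well>.fcs`.}
#'   \item{plate_map}{Plate-map `data.frame` or CSV path (required).}
#'   \item{annotation}{Compound annotation `data.frame` or CSV path
#'     (required when sample wells carry compounds).}
#'   \item{coverage_quantile}{Gate coverage, default 0.9.}
#'   \item{qc_threshold}{Gated-fraction QC cut (strict), default 0.5.}
#'   \item{gate_on}{Control role the gate is fitted on, default
#'     `"neg_ctrl"`.}
#'   \item{subsample_n}{Optional per-well event subsample.}
#'   \item{up_threshold, down_threshold, min_cluster_size}{Hit-calling
#'     parameters, defaults 150 / 80 / 3.}
#' }
#'
#' Output files: `well_summary.csv`, `qc_report.csv`, `clusters.csv`,
#' `hits.csv`, `gate_<plate>.json`, `manifest.csv` (simulated runs),
#' `run_log.txt`, `config.yaml`. Reruns with identical config and inputs are
#' byte-identical.
#'
#' @param config Named list or path to a YAML config file.
#' @return The output directory, invisibly; the parsed tables are attached as
#'   attributes `well_summary`, `qc`, `clusters`, `hits`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  cfg <- config
  if (is.null(cfg$outdir)) stop("config$outdir is required", call. = FALSE)
  if (is.null(cfg$seed)) stop("config$seed is required", call. = FALSE)
  cq <- cfg$coverage_quantile %||% 0.9
  qct <- cfg$qc_threshold %||% 0.5
  gate_on <- cfg$gate_on %||% "neg_ctrl"
  if (!(cq > 0 && cq < 1)) stop("coverage_quantile outside (0,1)",
                                call. = FALSE)
  if (!(qct >= 0 && qct < 1)) stop("qc_threshold outside [0,1)",
                                   call. = FALSE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  pm <- cfg$plate_map
  if (is.character(pm)) pm <- read_plate_map(pm)
  if (is.null(pm)) stop("config$plate_map is required", call. = FALSE)
  pm <- validate_plate_map(pm)
  for (pl in unique(pm$plate_id)) {
    roles <- pm$role[pm$plate_id == pl]
    if (!any(roles == "pos_ctrl"))
      stop("validation: plate ", pl, " has no pos_ctrl well", call. = FALSE)
    if (!any(roles == "neg_ctrl"))
      stop("validation: plate ", pl, " has no neg_ctrl well", call. = FALSE)
  }

  ann <- cfg$annotation
  if (is.character(ann)) ann <- read_annotation(ann)

  checksums <- character(0)
  manifest <- NULL
  if (isTRUE(cfg$simulate)) {
    pop <- do.call(population_config, cfg$population %||% list())
    effects <- lapply(cfg$effects %||% list(),
                      function(e) do.call(compound_effect, e))
    scr <- simulate_screen(pop, pm, effects, seed = cfg$seed,
                           stim_dose = cfg$stim_dose %||% (1 / 6))
    events <- scr$events
    pm <- scr$plate_map
    manifest <- scr$manifest
  } else if (!is.null(cfg$events_path)) {
    events <- read_events(cfg$events_path)
    if (inherits(events, "event_table"))
      events <- stats::setNames(list(events), well_id(events))
    checksums <- tools::md5sum(cfg$events_path)
  } else if (!is.null(cfg$events_dir)) {
    pm_use <- pm[pm$role != "empty", , drop = FALSE]
    keys <- paste(pm_use$plate_id, pm_use$well_id, sep = "_")
    paths <- file.path(cfg$events_dir, paste0(keys, ".fcs"))
    miss <- !file.exists(paths)
    if (any(miss))
      stop("stage read_events: missing FCS file(s): ",
           paste(utils::head(basename(paths[miss]), 5), collapse = ", "),
           call. = FALSE)
    events <- lapply(paths, read_events)
    names(events) <- keys
    checksums <- tools::md5sum(paths)
  } else {
    stop("config must set simulate = TRUE, events_path or events_dir",
         call. = FALSE)
  }

  pm_use <- pm[pm$role != "empty", , drop = FALSE]
  gated <- vector("list", nrow(pm_use))
  keys <- paste(pm_use$plate_id, pm_use$well_id, sep = "_")
  names(gated) <- keys
  for (pl in unique(pm_use$plate_id)) {
    ctrl_keys <- keys[pm_use$plate_id == pl & pm_use$role == gate_on]
    if (length(ctrl_keys) == 0L)
      stop("stage fit_gate: plate ", pl, " has no '", gate_on,
           "' wells to fit the gate on", call. = FALSE)
    gate <- fit_gate(events[ctrl_keys], coverage_quantile = cq)
    write_gate_json(gate, file.path(cfg$outdir,
                                    paste0("gate_", pl, ".json")))
    for (k in keys[pm_use$plate_id == pl])
      gated[[k]] <- apply_gate(events[[k]], gate, qc_threshold = qct)
  }

  qc <- qc_report(gated)
  summary <- summarize_wells(gated, pm_use, subsample_n = cfg$subsample_n,
                             seed = cfg$seed)

  samples <- summary[summary$role == "sample", , drop = FALSE]
  clusters_all <- NULL; hits_all <- NULL
  if (nrow(samples) > 0) {
    if (is.null(ann)) {
      ann <- unique(data.frame(
        compound_id = samples$compound_id,
        target_class = if (!is.null(manifest))
          manifest$target_class[match(samples$compound_id,
                                      manifest$compound_id)]
        else NA_character_,
        stringsAsFactors = FALSE))
      ann <- ann[!is.na(ann$compound_id), , drop = FALSE]
      ann$target_class[is.na(ann$target_class)] <- "unannotated"
    }
    strata <- unique(samples[, c("concentration", "stimulated")])
    for (si in seq_len(nrow(strata))) {
      sel <- samples[
        (is.na(samples$concentration) &
           is.na(strata$concentration[si]) |
           !is.na(samples$concentration) &
           !is.na(strata$concentration[si]) &
           samples$concentration == strata$concentration[si]) &
          samples$stimulated == strata$stimulated[si], , drop = FALSE]
      if (nrow(sel) == 0L) next
      cl <- suppressWarnings(
        aggregate_by_target(sel, ann,
                            min_cluster_size = cfg$min_cluster_size %||% 3))
      if (nrow(cl) == 0L) next
      ht <- call_hits(cl, up_threshold = cfg$up_threshold %||% 150,
                      down_threshold = cfg$down_threshold %||% 80)
      cl_out <- cl[, c("target_class", "n_compounds", "median_response")]
      cl_out$concentration <- strata$concentration[si]
      cl_out$stimulated <- strata$stimulated[si]
      ht$concentration <- strata$concentration[si]
      ht$stimulated <- strata$stimulated[si]
      clusters_all <- rbind(clusters_all, cl_out)
      hits_all <- rbind(hits_all, ht)
    }
  }

  write_ordered_csv <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    utils::write.csv(df, file.path(cfg$outdir, name), row.names = FALSE)
  }
  cols <- c("plate_id", "well_id", "role", "compound_id", "concentration",
            "stimulated", "n_total", "n_gated", "gated_fraction", "qc_pass",
            "median_fl", "normalized_response")
  write_ordered_csv(summary[, cols], "well_summary.csv")
  write_ordered_csv(qc, "qc_report.csv")
  write_ordered_csv(clusters_all, "clusters.csv")
  write_ordered_csv(hits_all, "hits.csv")
  if (!is.null(manifest)) write_ordered_csv(manifest, "manifest.csv")

  cfg_out <- cfg
  cfg_out$plate_map <- NULL; cfg_out$annotation <- NULL
  yaml::write_yaml(cfg_out, file.path(cfg$outdir, "config.yaml"))
  log_lines <- c(
    sprintf("smoscreen %s", as.character(utils::packageVersion("smoscreen"))),
    sprintf("seed: %s", cfg$seed),
    sprintf("coverage_quantile: %s  qc_threshold: %s  gate_on: %s",
            cq, qct, gate_on),
    sprintf("wells analysed: %d  qc failed: %d", nrow(qc), sum(!qc$qc_pass)),
    if (length(checksums))
      paste0("input md5 ", names(checksums), ": ", checksums) else
        "inputs: simulated in-memory")
  writeLines(log_lines, file.path(cfg$outdir, "run_log.txt"))

  out <- cfg$outdir
  attr(out, "well_summary") <- summary
  attr(out, "qc") <- qc
  attr(out, "clusters") <- clusters_all
  attr(out, "hits") <- hits_all
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Histogram panel across a dilution series
#'
#' Base-graphics panel of log10 fluorescence histograms, one per dose, laid
#' out in reading order — the visual check that intermediate doses are
#' bimodal while the extremes are not.
#'
#' @param tables List of [event_table()]s.
#' @param doses Doses, parallel to `tables` (panel titles).
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @return Invisibly, `NULL`.
#' @export
plot_dose_histograms <- function(tables, doses, breaks = 50) {
  stopifnot(length(tables) == length(doses))
  nt <- length(tables)
  nc <- ceiling(sqrt(nt))
  nr <- ceiling(nt / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(3, 3, 2, 0.5))
  on.exit(graphics::par(op))
  for (i in seq_len(nt)) {
    graphics::hist(log10(tables[[i]]$fl), breaks = breaks, main =
                     sprintf("dose %.3g", doses[i]),
                   xlab = "log10 FL", col = "grey80", border = NA)
  }
  invisible(NULL)
}
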