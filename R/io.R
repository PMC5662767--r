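#' Write event tables in the long CSV dialect
#'
#' One row per event with columns `well_id`, `fsc`, `ssc`, `fl` and, when
#' present, `truth_label`. Several wells may share one file. UTF-8, comma
#' separated, header mandatory, '.' decimal separator.
#'
#' @param events An [event_table()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  if (inherits(events, "event_table")) events <- list(events)
  rows <- lapply(events, function(e) {
    df <- data.frame(well_id = well_id(e), fsc = e$fsc, ssc = e$ssc,
                     fl = e$fl, stringsAsFactors = FALSE)
    if (!is.null(e$label)) df$truth_label <- e$label
    df
  })
  has_label <- vapply(rows, function(r) "truth_label" %in% names(r),
                      logical(1))
  if (any(has_label) && !all(has_label))
    rows <- lapply(rows, function(r) {
      if (is.null(r$truth_label)) r$truth_label <- NA_character_
      r
    })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read per-well flow events
#'
#' Dispatches on file content: FCS 3.x files go through [read_fcs()];
#' anything else is parsed as the long CSV dialect (`well_id`, `fsc`, `ssc`,
#' `fl`, optional `truth_label`). Channel values are validated strictly
#' positive and finite, with offending rows reported.
#'
#' @param path Path to an FCS file or a CSV file.
#' @param ... Passed to [read_fcs()] (e.g. `channel_patterns`).
#' @return An [event_table()] (single-well input) or a named list of them
#'   (multi-well CSV).
#' @export
read_events <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("empty input file: ", path, call. = FALSE)
  magic <- rawToChar(readBin(path, "raw", n = 6L))
  if (startsWith(magic, "FCS3")) return(read_fcs(path, ...))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("empty input file: ", path, call. = FALSE)
  need <- c("well_id", "fsc", "ssc", "fl")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (ch in c("fsc", "ssc", "fl")) {
    v <- df[[ch]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stop("non-positive or non-finite '", ch, "' values in ", path,
           " at data row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
  }
  split_wells <- split(df, df$well_id)
  tabs <- lapply(names(split_wells), function(w) {
    s <- split_wells[[w]]
    event_table(s$fsc, s$ssc, s$fl,
                label = if ("truth_label" %in% names(s) &&
                            !anyNA(s$truth_label)) s$truth_label else NULL,
                well_id = w)
  })
  names(tabs) <- names(split_wells)
  if (length(tabs) == 1L) tabs[[1]] else tabs
}

#' Read a plate map
#'
#' CSV with header `plate_id,well_id,role,compound_id,concentration,stimulated`
#' (`plate_id` optional, defaulting to `P1`). Roles must be one of `sample`,
#' `pos_ctrl`, `neg_ctrl`, `empty`; well ids must be unique within a plate and
#' lie on the 384-well grid A1-P24; concentrations must be numeric (micromolar)
#' or empty; duplicate wells are rejected with their line numbers.
#'
#' @param path CSV path.
#' @return A validated plate-map `data.frame`.
#' @export
read_plate_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$concentration) && !is.numeric(df$concentration)) {
    conc <- suppressWarnings(as.numeric(df$concentration))
    bad <- which(!is.na(df$concentration) & df$concentration != "" &
                   is.na(conc))
    if (length(bad))
      stop("malformed concentration in ", path, " at line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    df$concentration <- conc
  }
  validate_plate_map(df)
}

#' Read a compound annotation table
#'
#' CSV mapping `compound_id` to `target_class`, with an optional `pathway`
#' column for user-supplied pathway-level regrouping. Duplicate compounds are
#' rejected with their line numbers.
#'
#' @param path CSV path.
#' @return `data.frame` with `compound_id`, `target_class` and optional
#'   `pathway`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotation(df, source = path)
}

validate_annotation <- function(df, source = "annotation") {
  stopifnot(is.data.frame(df))
  if (!all(c("compound_id", "target_class") %in% names(df)))
    stop(source, " must have columns compound_id and target_class",
         call. = FALSE)
  if (anyDuplicated(df$compound_id)) {
    d <- df$compound_id[duplicated(df$compound_id)][1]
    lines <- which(df$compound_id == d) + 1L # +1 for the header line
    stop("duplicate compound ", d, " in ", source, " (lines ",
         paste(lines, collapse = " and "), ")", call. = FALSE)
  }
  df
}

#' Serialize / restore a scatter gate as JSON
#'
#' The gate audit document: center, dispersion matrix, squared radius and
#' coverage quantile, written with full double precision.
#'
#' @param gate A `scatter_gate`.
#' @param path JSON path.
#' @return `write_gate_json()` returns `path` invisibly; `read_gate_json()`
#'   returns the `scatter_gate`.
#' @export
write_gate_json <- function(gate, path) {
  stopifnot(inherits(gate, "scatter_gate"))
  jsonlite::write_json(
    list(center = unname(as.numeric(gate$center)),
         shape = unname(apply(gate$shape, 1, as.numeric, simplify = FALSE)),
         radius2 = gate$radius2,
         coverage_quantile = gate$coverage_quantile,
         n_control_events = gate$n_control_events),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gate_json
#' @export
read_gate_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = as.numeric(j$center),
                 shape = matrix(unlist(j$shape), 2, 2, byrow = TRUE),
                 radius2 = j$radius2,
                 coverage_quantile = j$coverage_quantile,
                 n_control_events = j$n_control_events),
            class = "scatter_gate")
}

#' Write the ground-truth manifest of a simulated screen
#'
#' @param screen A `screen_dataset` from [simulate_screen()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(screen, path) {
  stopifnot(inherits(screen, "screen_dataset"))
  utils::write.csv(screen$manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML (or flat `key: value`) file with the fields of the pipeline
#' configuration; see [run_pipeline()] for the recognized keys.
#'
#' @param path YAML path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
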