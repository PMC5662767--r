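#' Derive a per-well random seed from a master seed
#'
#' Deterministic integer mixing of a master seed with a string key (typically
#' the well identifier). The mixing function is the explicit recurrence
#' `s <- (s * 31 + byte) mod (2^31 - 1)` over the UTF-8 bytes of the key,
#' started from `master mod (2^31 - 1)`. It is defined entirely by this
#' formula — no language hash functions — so derived streams are reproducible
#' across platforms and sessions.
#'
#' @param master Integer master seed.
#' @param key Character key (e.g. `"P1_A01"` or `"dose_3"`).
#' @return An integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1; all intermediates stay exact in doubles
  s <- abs(as.numeric(master)) %% m
  for (byte in utf8ToInt(as.character(key))) s <- (s * 31 + byte) %% m
  as.integer(s)
}

# Correlated bivariate log-normal scatter draws.
rscatter <- function(n, p) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  lf <- p$mu_fsc + p$sigma_fsc * z1
  ls <- p$mu_ssc + p$sigma_ssc * (p$rho * z1 + sqrt(1 - p$rho^2) * z2)
  cbind(exp(lf), exp(ls))
}

# Apply a compound effect to a population config; multiplicative effects act
# on the natural-scale medians, i.e. additively on the log locations.
apply_compound_effect <- function(cfg, effect) {
  if (is.null(effect)) return(cfg)
  stopifnot(inherits(effect, "compound_effect"))
  cfg$mu_off <- cfg$mu_off + log(effect$effect_on_off_state)
  cfg$mu_on <- cfg$mu_on + log(effect$effect_on_on_state)
  cfg$mu_theta <- cfg$mu_theta + log(effect$effect_on_threshold)
  cfg$debris_fraction <- min(max(cfg$debris_fraction +
                                   effect$toxicity_debris_shift, 0), 0.95)
  # a strong off-state boost can push mu_off past mu_on; keep the on state on top
  if (cfg$mu_on <= cfg$mu_off) cfg$mu_on <- cfg$mu_off + 1e-6
  cfg
}

#' Simulate one well of flow-cytometry events
#'
#' Draws `n_events` events for a single well. Each viable event activates
#' ("on") with probability `F_theta(dose)`, the log-normal CDF of the per-cell
#' activation thresholds; dose 0 activates nobody by convention, so
#' unstimulated wells are clean negatives. On-events draw fluorescence from
#' the on-state log-normal, off-events and debris from the off-state
#' log-normal; debris additionally has its own low-scatter FSC/SSC
#' distribution. All channel values are clipped below at `1e-6` so log
#' transforms stay defined.
#'
#' An optional stimulation time rescales the on/off log-location separation by
#' the saturating factor `time_h / (time_h + tau)`, emulating the slow
#' accumulation of activated sensor (weak signal at 4 h, near-maximal at
#' 24 h with the default `tau = 6`).
#'
#' @param config A [population_config()].
#' @param dose Volume fraction of conditioned medium in \[0, 1\].
#' @param effect Optional [compound_effect()] applied to the well.
#' @param seed Integer seed; defaults to `config$seed`. Fixed seed gives
#'   bit-identical output.
#' @param well_id Well identifier stored on the returned table.
#' @param time_h Optional stimulation time in hours; `NULL` (default) means
#'   fully developed signal.
#' @param tau Saturation time constant in hours for the time-course factor.
#' @return An [event_table()] with ground-truth `label` column.
#' @export
simulate_well <- function(config, dose, effect = NULL, seed = config$seed,
                          well_id = "W01", time_h = NULL, tau = 6) {
  validate_population_config(config)
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) ||
      dose < 0 || dose > 1)
    stop("dose must be a single number in [0, 1]", call. = FALSE)
  if (is.null(seed))
    stop("a seed is required (argument or config$seed)", call. = FALSE)
  cfg <- apply_compound_effect(config, effect)
  if (!is.null(time_h)) {
    stopifnot(is.numeric(time_h), time_h >= 0, tau > 0)
    cfg$mu_on <- cfg$mu_off + (cfg$mu_on - cfg$mu_off) * time_h / (time_h + tau)
    if (cfg$mu_on <= cfg$mu_off) cfg$mu_on <- cfg$mu_off + 1e-9
  }
  n <- as.integer(cfg$n_events)
  p_on <- if (dose == 0) 0 else
    stats::plnorm(dose, meanlog = cfg$mu_theta, sdlog = cfg$sigma_theta)

  set.seed(as.integer(seed))
  is_debris <- stats::runif(n) < cfg$debris_fraction
  is_on <- !is_debris & (stats::runif(n) < p_on)
  label <- ifelse(is_debris, "debris", ifelse(is_on, "on", "off"))

  fl <- numeric(n)
  n_on <- sum(is_on)
  fl[is_on] <- stats::rlnorm(n_on, cfg$mu_on, cfg$sigma_on)
  fl[!is_on] <- stats::rlnorm(n - n_on, cfg$mu_off, cfg$sigma_off)

  sc <- matrix(0, n, 2)
  n_deb <- sum(is_debris)
  sc[!is_debris, ] <- rscatter(n - n_deb, cfg$scatter_params)
  sc[is_debris, ] <- rscatter(n_deb, cfg$debris_params)

  event_table(fsc = pmax(sc[, 1], 1e-6), ssc = pmax(sc[, 2], 1e-6),
              fl = pmax(fl, 1e-6), label = label, well_id = well_id)
}

#' Simulate a dilution series
#'
#' One well per dose, with per-well seeds derived deterministically from the
#' master seed via [derive_seed()] (so two identical doses give distinct wells
#' with the same expected responder fraction).
#'
#' @param config A [population_config()].
#' @param doses Non-empty numeric vector of doses in \[0, 1\].
#' @param seed Master seed.
#' @param effect Optional [compound_effect()] applied to every well.
#' @return Named list of [event_table()]s, one per dose, named `D01`, `D02`, ...
#' @export
simulate_dilution_series <- function(config, doses, seed = config$seed,
                                     effect = NULL) {
  if (length(doses) == 0L)
    stop("doses must be a non-empty vector", call. = FALSE)
  if (is.null(seed)) stop("a master seed is required", call. = FALSE)
  ids <- sprintf("D%02d", seq_along(doses))
  out <- vector("list", length(doses))
  for (i in seq_along(doses)) {
    out[[i]] <- simulate_well(config, doses[i], effect = effect,
                              seed = derive_seed(seed, paste0(ids[i], "#", i)),
                              well_id = ids[i])
  }
  names(out) <- ids
  attr(out, "doses") <- as.numeric(doses)
  out
}

#' Simulate a full multi-well screen
#'
#' Simulates one well per plate-map entry. Positive-control wells (role
#' `pos_ctrl`) are stimulated at `stim_dose` with no compound; negative
#' controls (`neg_ctrl`) receive dose 0; sample wells receive `stim_dose` or 0
#' according to their `stimulated` flag and the compound effect looked up by
#' `compound_id`. `empty` wells are skipped. A ground-truth manifest of the
#' true per-compound effects and per-well doses is returned alongside the
#' events.
#'
#' @param config A [population_config()].
#' @param plate_map A plate-map `data.frame` as returned by [make_plate_map()]
#'   or [read_plate_map()]; must contain at least one `pos_ctrl` and one
#'   `neg_ctrl` well per plate.
#' @param effects List of [compound_effect()]s; every `compound_id` in the
#'   plate map must be present. Compounds without an entry get no effect if
#'   `default_null_effect = TRUE`.
#' @param seed Master seed; per-well seeds derived via [derive_seed()] on
#'   `"<plate>_<well>"`.
#' @param stim_dose Dose given to stimulated wells; the default 1/6 is the
#'   volume fraction obtained by adding one part conditioned medium to five
#'   parts of culture (5 uL onto 25 uL).
#' @param default_null_effect If `TRUE`, compounds absent from `effects` are
#'   simulated with no effect; if `FALSE` this is an error.
#' @return A list of class `screen_dataset` with elements `events` (named list
#'   of [event_table()]s keyed `<plate>_<well>`), `plate_map`, and `manifest`
#'   (ground-truth `data.frame`: one row per well with compound, target class,
#'   the four effect fields, and the dose).
#' @export
simulate_screen <- function(config, plate_map, effects = list(),
                            seed = config$seed, stim_dose = 1 / 6,
                            default_null_effect = TRUE) {
  validate_population_config(config)
  pm <- validate_plate_map(plate_map)
  if (is.null(seed)) stop("a master seed is required", call. = FALSE)
  for (pl in unique(pm$plate_id)) {
    roles <- pm$role[pm$plate_id == pl]
    if (!any(roles == "pos_ctrl") || !any(roles == "neg_ctrl"))
      stop("plate ", pl, " lacks a pos_ctrl or neg_ctrl well", call. = FALSE)
  }
  eff_map <- list()
  for (e in effects) {
    stopifnot(inherits(e, "compound_effect"))
    eff_map[[e$compound_id]] <- e
  }
  pm <- pm[pm$role != "empty", , drop = FALSE]
  keys <- paste(pm$plate_id, pm$well_id, sep = "_")
  events <- vector("list", nrow(pm))
  manifest <- pm
  manifest$dose <- ifelse(pm$role == "neg_ctrl", 0,
                          ifelse(pm$role == "pos_ctrl", stim_dose,
                                 ifelse(pm$stimulated, stim_dose, 0)))
  eff_cols <- c("effect_on_off_state", "effect_on_on_state",
                "effect_on_threshold", "toxicity_debris_shift")
  for (cn in eff_cols) manifest[[cn]] <- c(1, 1, 1, 0)[match(cn, eff_cols)]
  manifest$target_class <- NA_character_
  for (i in seq_len(nrow(pm))) {
    eff <- NULL
    if (pm$role[i] == "sample" && !is.na(pm$compound_id[i])) {
      eff <- eff_map[[pm$compound_id[i]]]
      if (is.null(eff) && !default_null_effect)
        stop("no effect defined for compound ", pm$compound_id[i],
             call. = FALSE)
      if (!is.null(eff)) {
        for (cn in eff_cols) manifest[[cn]][i] <- eff[[cn]]
        manifest$target_class[i] <- eff$target_class
      }
    }
    events[[i]] <- simulate_well(config, manifest$dose[i], effect = eff,
                                 seed = derive_seed(seed, keys[i]),
                                 well_id = keys[i])
  }
  names(events) <- keys
  structure(list(events = events, plate_map = pm, manifest = manifest),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("Simulated screen: %d wells on %d plate(s)\n",
              length(x$events), length(unique(x$plate_map$plate_id))))
  print(table(x$plate_map$role))
  invisible(x)
}

#' Build a plate map
#'
#' Lays out a single plate on the standard 384-well A1-P24 grid: control wells
#' first (positive = stimulated / negative = mock, no compound), then one well
#' per requested compound, in column-major order.
#'
#' @param compounds Character vector of compound identifiers (one well each);
#'   may be empty.
#' @param n_pos,n_neg Number of stimulated / unstimulated control wells.
#' @param plate_id Plate identifier.
#' @param concentration Compound concentration in micromolar, recycled over
#'   compound wells.
#' @param stimulated Logical, recycled over compound wells: whether sample
#'   wells receive ligand.
#' @return A plate-map `data.frame` with columns `plate_id`, `well_id`,
#'   `role`, `compound_id`, `concentration`, `stimulated`.
#' @export
make_plate_map <- function(compounds = character(), n_pos = 8, n_neg = 8,
                           plate_id = "P1", concentration = 15,
                           stimulated = TRUE) {
  wells <- as.vector(outer(LETTERS[1:16], 1:24,
                           function(r, c) paste0(r, c)))
  n <- n_pos + n_neg + length(compounds)
  if (n > 384) stop("layout exceeds 384 wells", call. = FALSE)
  role <- c(rep("pos_ctrl", n_pos), rep("neg_ctrl", n_neg),
            rep("sample", length(compounds)))
  pm <- data.frame(
    plate_id = plate_id,
    well_id = wells[seq_len(n)],
    role = role,
    compound_id = c(rep(NA_character_, n_pos + n_neg), as.character(compounds)),
    concentration = c(rep(NA_real_, n_pos + n_neg),
                      rep_len(concentration, length(compounds))),
    stimulated = c(rep(TRUE, n_pos), rep(FALSE, n_neg),
                   rep_len(stimulated, length(compounds))),
    stringsAsFactors = FALSE)
  validate_plate_map(pm)
}

validate_plate_map <- function(pm) {
  stopifnot(is.data.frame(pm))
  need <- c("well_id", "role")
  if (!all(need %in% names(pm)))
    stop("plate map must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(pm$plate_id)) pm$plate_id <- "P1"
  if (is.null(pm$compound_id)) pm$compound_id <- NA_character_
  if (is.null(pm$concentration)) pm$concentration <- NA_real_
  if (is.null(pm$stimulated)) pm$stimulated <- pm$role == "pos_ctrl"
  bad_role <- setdiff(unique(pm$role),
                      c("sample", "pos_ctrl", "neg_ctrl", "empty"))
  if (length(bad_role))
    stop("unknown role token(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  grid <- as.vector(outer(LETTERS[1:16], 1:24, function(r, c) paste0(r, c)))
  bad_well <- setdiff(unique(pm$well_id), grid)
  if (length(bad_well))
    stop("well ids outside the 384-well grid A1-P24: ",
         paste(utils::head(bad_well, 5), collapse = ", "), call. = FALSE)
  key <- paste(pm$plate_id, pm$well_id)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    lines <- which(key == d)
    stop("duplicate well ", d, " (rows ", paste(lines, collapse = " and "),
         ")", call. = FALSE)
  }
  pm$stimulated <- as.logical(pm$stimulated)
  pm
}
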