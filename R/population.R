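#' Population model for a clonal sensor cell line
#'
#' Describes the event-level generative model used by the simulator: a viable
#' cell population whose forward/side scatter is bivariate log-normal, whose
#' sensor fluorescence is drawn from one of two log-normal states ("off" and
#' "on"), and whose per-cell activation threshold — the minimal ligand dose at
#' which a cell switches its sensor on — is log-normally distributed across
#' the population. A separate, low-scatter debris population contaminates a
#' configurable fraction of events.
#'
#' Defaults describe a sensor line whose stimulated/unstimulated fluorescence
#' medians differ 10-fold (well separated relative to the within-state spread,
#' so intermediate doses produce clearly bimodal histograms), whose median
#' activation threshold sits at a conditioned-medium volume fraction of 0.05,
#' and whose responder fraction saturates (reaches 95%) near a 1:5
#' conditioned:fresh mixing ratio (dose 1/6). 4000 events per well matches a
#' typical per-well acquisition count in 384-well screening mode.
#'
#' @param mu_off,sigma_off Location and scale of log fluorescence for
#'   non-activated ("off") cells, natural-log units of arbitrary linear
#'   fluorescence.
#' @param mu_on,sigma_on Location and scale of log fluorescence for activated
#'   ("on") cells. `mu_on` must exceed `mu_off`.
#' @param mu_theta,sigma_theta Location and scale of the log activation
#'   threshold distribution. Thresholds are expressed on the dose scale
#'   (volume fraction of conditioned medium in \[0, 1\]); the expected
#'   responder fraction at dose `d > 0` is `plnorm(d, mu_theta, sigma_theta)`.
#' @param scatter_params List with `mu_fsc`, `mu_ssc`, `sigma_fsc`,
#'   `sigma_ssc`, `rho`: location/scale/correlation of the bivariate
#'   log-normal FSC/SSC distribution of viable cells.
#' @param debris_fraction Proportion of events drawn from the debris scatter
#'   population, in \[0, 1).
#' @param debris_params As `scatter_params`, for the debris population.
#'   Debris fluorescence is drawn from the off-state distribution.
#' @param n_events Events acquired per well (positive integer).
#' @param seed Optional default random seed used when an operation is called
#'   without one.
#'
#' @return An object of class `population_config`.
#' @seealso [simulate_well()], [simulate_dilution_series()],
#'   [simulate_screen()]
#' @export
#' @examples
#' cfg <- population_config(n_events = 1000)
#' tab <- simulate_well(cfg, dose = 0.05, seed = 1)
#' mean(tab$label == "on")
population_config <- function(mu_off = log(100), sigma_off = 0.4,
                              mu_on = log(1000), sigma_on = 0.4,
                              mu_theta = log(0.05), sigma_theta = 0.73,
                              scatter_params = list(mu_fsc = log(5e4),
                                                    mu_ssc = log(2e4),
                                                    sigma_fsc = 0.25,
                                                    sigma_ssc = 0.25,
                                                    rho = 0.6),
                              debris_fraction = 0.05,
                              debris_params = list(mu_fsc = log(8e3),
                                                   mu_ssc = log(4e3),
                                                   sigma_fsc = 0.5,
                                                   sigma_ssc = 0.5,
                                                   rho = 0.3),
                              n_events = 4000,
                              seed = NULL) {
  cfg <- list(mu_off = mu_off, sigma_off = sigma_off,
              mu_on = mu_on, sigma_on = sigma_on,
              mu_theta = mu_theta, sigma_theta = sigma_theta,
              scatter_params = scatter_params,
              debris_fraction = debris_fraction,
              debris_params = debris_params,
              n_events = n_events,
              seed = seed)
  class(cfg) <- "population_config"
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  stopifnot(inherits(cfg, "population_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$sigma_off) || cfg$sigma_off <= 0)
    stop("sigma_off must be a positive number", call. = FALSE)
  if (!num1(cfg$sigma_on) || cfg$sigma_on <= 0)
    stop("sigma_on must be a positive number", call. = FALSE)
  if (!num1(cfg$sigma_theta) || cfg$sigma_theta <= 0)
    stop("sigma_theta must be a positive number", call. = FALSE)
  if (!num1(cfg$mu_off) || !num1(cfg$mu_on) || cfg$mu_on <= cfg$mu_off)
    stop("mu_on must exceed mu_off", call. = FALSE)
  if (!num1(cfg$debris_fraction) || cfg$debris_fraction < 0 ||
      cfg$debris_fraction >= 1)
    stop("debris_fraction must lie in [0, 1)", call. = FALSE)
  if (!num1(cfg$n_events) || cfg$n_events < 1 ||
      cfg$n_events != round(cfg$n_events))
    stop("n_events must be a positive integer", call. = FALSE)
  for (p in list(cfg$scatter_params, cfg$debris_params)) {
    stopifnot(is.list(p))
    need <- c("mu_fsc", "mu_ssc", "sigma_fsc", "sigma_ssc", "rho")
    if (!all(need %in% names(p)))
      stop("scatter parameter list must name ",
           paste(need, collapse = ", "), call. = FALSE)
    if (p$sigma_fsc <= 0 || p$sigma_ssc <= 0 || abs(p$rho) >= 1)
      stop("scatter scales must be positive and |rho| < 1", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.population_config <- function(x, ...) {
  cat("Sensor population model\n")
  cat(sprintf("  off state : medFL %.3g (sigma %.2f log units)\n",
              exp(x$mu_off), x$sigma_off))
  cat(sprintf("  on state  : medFL %.3g (sigma %.2f log units)\n",
              exp(x$mu_on), x$sigma_on))
  cat(sprintf("  thresholds: median dose %.3g (sigma %.2f log units)\n",
              exp(x$mu_theta), x$sigma_theta))
  cat(sprintf("  debris    : %.1f%% of events\n", 100 * x$debris_fraction))
  cat(sprintf("  events/well: %d\n", as.integer(x$n_events)))
  invisible(x)
}

#' Ground-truth compound effect for the simulator
#'
#' Encodes how a library compound perturbs the sensor population. Effects are
#' multiplicative on the natural-scale medians (off-state fluorescence,
#' on-state fluorescence, activation-threshold dose) and additive on the
#' debris fraction (crude toxicity), mirroring the screen phenotypes the
#' analysis is meant to recover: compounds that raise baseline or induced
#' sensor fluorescence, compounds that shift the dose needed for activation,
#' and compounds that kill cells.
#'
#' @param compound_id Compound identifier.
#' @param target_class Annotated primary target class of the compound.
#' @param effect_on_off_state Multiplicative shift of the off-state median
#'   fluorescence (> 0; 1 = no effect).
#' @param effect_on_on_state Multiplicative shift of the on-state median
#'   fluorescence (> 0).
#' @param effect_on_threshold Multiplicative shift of the median activation
#'   threshold dose (> 0; values < 1 sensitize cells).
#' @param toxicity_debris_shift Additive change to the debris fraction; the
#'   resulting fraction is clamped to \[0, 0.95\].
#'
#' @return An object of class `compound_effect`.
#' @export
compound_effect <- function(compound_id, target_class,
                            effect_on_off_state = 1,
                            effect_on_on_state = 1,
                            effect_on_threshold = 1,
                            toxicity_debris_shift = 0) {
  if (effect_on_off_state <= 0 || effect_on_on_state <= 0 ||
      effect_on_threshold <= 0)
    stop("multiplicative compound effects must be > 0", call. = FALSE)
  structure(list(compound_id = as.character(compound_id),
                 target_class = as.character(target_class),
                 effect_on_off_state = effect_on_off_state,
                 effect_on_on_state = effect_on_on_state,
                 effect_on_threshold = effect_on_threshold,
                 toxicity_debris_shift = toxicity_debris_shift),
            class = "compound_effect")
}

#' Per-well event table
#'
#' The package's event container: one row per acquired event with strictly
#' positive, finite linear-scale channels `fsc`, `ssc`, `fl`, an optional
#' ground-truth `label` column (`"off"`, `"on"`, `"debris"`; simulator output
#' only), and the well identifier stored as an attribute.
#'
#' @param fsc,ssc,fl Numeric vectors of equal length; linear channel values,
#'   strictly positive and finite.
#' @param label Optional character/factor vector of per-event ground-truth
#'   labels, same length as the channels.
#' @param well_id Well identifier.
#' @return A `data.frame` of class `event_table`.
#' @export
event_table <- function(fsc, ssc, fl, label = NULL, well_id = "W01") {
  n <- length(fsc)
  if (length(ssc) != n || length(fl) != n)
    stop("fsc, ssc and fl must have equal length", call. = FALSE)
  for (nm in c("fsc", "ssc", "fl")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0))
      stop("channel '", nm, "' must be finite and strictly positive",
           call. = FALSE)
  }
  df <- data.frame(fsc = as.numeric(fsc), ssc = as.numeric(ssc),
                   fl = as.numeric(fl))
  if (!is.null(label)) {
    if (length(label) != n)
      stop("label length must equal the number of events", call. = FALSE)
    label <- as.character(label)
    bad <- setdiff(unique(label), c("off", "on", "debris"))
    if (length(bad))
      stop("unknown event labels: ", paste(bad, collapse = ", "),
           call. = FALSE)
    df$label <- label
  }
  attr(df, "well_id") <- as.character(well_id)
  class(df) <- c("event_table", "data.frame")
  df
}

#' Well identifier of an event table
#' @param x An `event_table`.
#' @return The well identifier string.
#' @export
well_id <- function(x) attr(x, "well_id")

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table for well %s: %d events\n", well_id(x), nrow(x)))
  if (!is.null(x$label)) {
    tab <- table(x$label)
    cat("  labels:", paste(names(tab), as.integer(tab), sep = "=",
                           collapse = ", "), "\n")
  }
  NextMethod()
}
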