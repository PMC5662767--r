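# Shared fixtures: small configurations and layouts used across test files.

# default population, scaled down for speed
small_config <- function(n_events = 2000, ...) {
  population_config(n_events = n_events, ...)
}

# clean population: no debris, for tests that need exact viable counts
clean_config <- function(n_events = 2000, ...) {
  population_config(n_events = n_events, debris_fraction = 0, ...)
}

# a tiny screen layout: n_classes target classes x 3 compounds each
tiny_screen_layout <- function(n_classes = 4, per_class = 3, n_ctrl = 4,
                               stimulated = TRUE, concentration = 15) {
  compounds <- sprintf("c%02d_%02d", rep(seq_len(n_classes), each = per_class),
                       rep(seq_len(per_class), n_classes))
  ann <- data.frame(
    compound_id = compounds,
    target_class = sprintf("class%02d", rep(seq_len(n_classes),
                                            each = per_class)),
    stringsAsFactors = FALSE)
  pm <- make_plate_map(compounds, n_pos = n_ctrl, n_neg = n_ctrl,
                       stimulated = stimulated, concentration = concentration)
  list(plate_map = pm, annotation = ann, compounds = compounds)
}

# brute-force point-in-ellipse oracle: explicit quadratic form per event
in_ellipse_oracle <- function(events, gate) {
  inv <- solve(gate$shape)
  apply(cbind(log(events$fsc), log(events$ssc)), 1, function(p) {
    d <- p - gate$center
    as.numeric(t(d) %*% inv %*% d) <= gate$radius2
  })
}
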