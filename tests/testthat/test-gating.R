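test_that("realized control coverage matches the requested quantile", {
  cfg <- clean_config(n_events = 10000)
  ctrl <- simulate_well(cfg, 0, seed = 11)
  gate <- fit_gate(ctrl, coverage_quantile = 0.90)
  frac <- apply_gate(ctrl, gate)$gated_fraction
  expect_gte(frac, 0.89)
  expect_lte(frac, 0.91)
})

test_that("identical events give a degenerate-scatter error", {
  tab <- event_table(fsc = rep(100, 60), ssc = rep(50, 60), fl = rep(1, 60))
  expect_error(fit_gate(tab), "degenerate")
  expect_error(fit_gate(simulate_well(clean_config(30), 0, seed = 1)),
               "at least 50")
  expect_error(fit_gate(simulate_well(clean_config(100), 0, seed = 1),
                        coverage_quantile = 1), "coverage_quantile")
})

test_that("coverage 0.5 keeps exactly the nearest half of the events", {
  # sort-and-count oracle: rank control events by Mahalanobis distance under
  # the fitted gate; the gate must contain precisely the nearest ceiling(n/2)
  cfg <- clean_config(n_events = 1000)
  ctrl <- simulate_well(cfg, 0, seed = 12)
  gate <- fit_gate(ctrl, coverage_quantile = 0.5)
  d2 <- mahalanobis(cbind(log(ctrl$fsc), log(ctrl$ssc)), gate$center,
                    gate$shape)
  nearest_half <- rank(d2, ties.method = "first") <= ceiling(0.5 * nrow(ctrl))
  gw <- apply_gate(ctrl, gate)
  inside <- in_ellipse_oracle(ctrl, gate)
  expect_equal(sum(inside), sum(nearest_half))
  expect_equal(gw$n_gated, sum(nearest_half))
})

test_that("gate membership equals brute-force point-in-ellipse enumeration", {
  cfg <- small_config(n_events = 800, debris_fraction = 0.2)
  ctrl <- simulate_well(cfg, 0, seed = 13)
  gate <- fit_gate(ctrl, 0.9)
  test <- simulate_well(cfg, 0.1, seed = 14)
  gw <- apply_gate(test, gate)
  oracle <- in_ellipse_oracle(test, gate)
  expect_equal(gw$n_gated, sum(oracle))
  expect_equal(gw$gated_events$fl, test$fl[oracle])
})

test_that("toy wells gate by exact counts and the QC rule is strict", {
  # hand-built gate: unit shape, radius 1, centered at log(100), log(100)
  gate <- structure(list(center = c(log(100), log(100)),
                         shape = diag(2), radius2 = 1,
                         coverage_quantile = 0.9, n_control_events = 100),
                    class = "scatter_gate")
  inside_pt <- c(100, 100)
  outside_pt <- c(100 * exp(2), 100)
  mk <- function(n_in, n_out) {
    event_table(fsc = c(rep(inside_pt[1], n_in), rep(outside_pt[1], n_out)),
                ssc = rep(100, n_in + n_out), fl = rep(5, n_in + n_out))
  }
  gw6 <- apply_gate(mk(6, 4), gate)
  expect_equal(gw6$gated_fraction, 0.6)
  expect_true(gw6$qc_pass)
  gw5 <- apply_gate(mk(5, 5), gate)
  expect_equal(gw5$gated_fraction, 0.5)
  expect_false(gw5$qc_pass) # "more than 50%" is strict
  gw10 <- apply_gate(mk(10, 0), gate)
  expect_equal(gw10$gated_fraction, 1.0)
  expect_true(gw10$qc_pass)
  # boundary events (distance exactly the radius) count as inside
  on_boundary <- event_table(fsc = rep(100 * exp(1), 10), ssc = rep(100, 10),
                             fl = rep(5, 10))
  expect_equal(apply_gate(on_boundary, gate)$gated_fraction, 1.0)
  expect_error(apply_gate(mk(1, 0)[0, ], gate), "non-empty")
})

test_that("gate membership is invariant under event order", {
  cfg <- small_config(500)
  ctrl <- simulate_well(cfg, 0, seed = 15)
  gate <- fit_gate(ctrl, 0.9)
  test <- simulate_well(cfg, 0.2, seed = 16)
  perm <- sample(nrow(test))
  shuffled <- event_table(test$fsc[perm], test$ssc[perm], test$fl[perm],
                          well_id = well_id(test))
  expect_equal(apply_gate(shuffled, gate)$n_gated,
               apply_gate(test, gate)$n_gated)
})

test_that("larger coverage quantiles give nested gates", {
  cfg <- small_config(2000, debris_fraction = 0.1)
  ctrl <- simulate_well(cfg, 0, seed = 17)
  test <- simulate_well(cfg, 0.3, seed = 18)
  fracs <- vapply(c(0.5, 0.7, 0.9, 0.95), function(q) {
    apply_gate(test, fit_gate(ctrl, q))$gated_fraction
  }, numeric(1))
  expect_false(is.unsorted(fracs))
})

test_that("gated fraction tracks one minus the debris fraction", {
  for (delta in c(0.1, 0.3, 0.6)) {
    cfg <- population_config(n_events = 4000, debris_fraction = delta)
    ctrl <- simulate_well(population_config(n_events = 4000,
                                            debris_fraction = 0),
                          0, seed = 19)
    gate <- fit_gate(ctrl, 0.995)
    gw <- apply_gate(simulate_well(cfg, 0, seed = 20), gate)
    expect_lt(abs(gw$gated_fraction - (1 - delta)), 0.03)
  }
})

test_that("qc_report tabulates wells and flags failures with reasons", {
  expect_equal(nrow(qc_report(list())), 0)
  cfg_ok <- clean_config(1000)
  cfg_bad <- population_config(n_events = 1000, debris_fraction = 0.6)
  ctrl <- simulate_well(cfg_ok, 0, seed = 30)
  gate <- fit_gate(ctrl, 0.9)
  wells <- list(apply_gate(simulate_well(cfg_ok, 0, seed = 31), gate),
                apply_gate(simulate_well(cfg_bad, 0, seed = 32), gate))
  rep <- qc_report(wells)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$qc_pass, c(TRUE, FALSE))
  expect_match(rep$reason[2], "not > 0.5")
})
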