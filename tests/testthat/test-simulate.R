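test_that("zero dose yields all-off wells by convention", {
  cfg <- clean_config(n_events = 500)
  tab <- simulate_well(cfg, dose = 0, seed = 1)
  expect_true(all(tab$label == "off"))
  expect_equal(mean(tab$label == "on"), 0)
})

test_that("responder fraction at the median threshold dose is ~ 0.5", {
  # binomial oracle: at dose = exp(mu_theta), F_theta = 0.5 exactly, so the
  # observed on-fraction among viable cells is Binomial(n, 0.5)/n
  cfg <- clean_config(n_events = 10000)
  tab <- simulate_well(cfg, dose = exp(cfg$mu_theta), seed = 42)
  expect_lt(abs(mean(tab$label == "on") - 0.5), 0.02)
})

test_that("saturating doses activate essentially every viable cell", {
  cfg <- clean_config(n_events = 10000)
  # dose 1 is far in the threshold CDF tail for the default parameters
  p <- plnorm(1, cfg$mu_theta, cfg$sigma_theta)
  expect_gt(p, 0.9999)
  hits <- vapply(1:100, function(s) {
    mean(simulate_well(cfg, dose = 1, seed = s)$label == "on") >= 0.999
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("responder fraction converges to the threshold CDF", {
  cfg <- clean_config(n_events = 1e5)
  for (dose in c(0.02, 0.05, 0.15)) {
    tab <- simulate_well(cfg, dose, seed = 7)
    expect_lt(abs(mean(tab$label == "on") -
                    plnorm(dose, cfg$mu_theta, cfg$sigma_theta)), 0.01)
  }
})

test_that("fixed seed gives bit-identical event tables", {
  cfg <- small_config(n_events = 1000)
  a <- simulate_well(cfg, 0.05, seed = 99)
  b <- simulate_well(cfg, 0.05, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, simulate_well(cfg, 0.05, seed = 100)))
})

test_that("no debris labels when debris_fraction is zero", {
  tab <- simulate_well(clean_config(500), 0.5, seed = 3)
  expect_false("debris" %in% tab$label)
  tab2 <- simulate_well(small_config(2000, debris_fraction = 0.3), 0.5,
                        seed = 3)
  expect_gt(mean(tab2$label == "debris"), 0.2)
})

test_that("dose validation and config invariants are enforced", {
  cfg <- small_config(100)
  expect_error(simulate_well(cfg, -0.1, seed = 1), "dose")
  expect_error(simulate_well(cfg, 1.5, seed = 1), "dose")
  expect_error(population_config(sigma_off = 0), "sigma_off")
  expect_error(population_config(mu_on = log(10), mu_off = log(100)), "mu_on")
  expect_error(population_config(debris_fraction = 1), "debris_fraction")
  expect_error(compound_effect("x", "t", effect_on_off_state = 0),
               "multiplicative")
})

test_that("dilution series derives distinct per-well seeds deterministically", {
  cfg <- small_config(500)
  expect_error(simulate_dilution_series(cfg, numeric(0), seed = 1),
               "non-empty")
  one <- simulate_dilution_series(cfg, 0, seed = 1)
  expect_length(one, 1)
  expect_true(all(one[[1]]$label != "on"))
  # two identical doses: distinct wells, same expected responder fraction
  two <- simulate_dilution_series(cfg, c(0.05, 0.05), seed = 1)
  expect_false(identical(two[[1]]$fl, two[[2]]$fl))
  rerun <- simulate_dilution_series(cfg, c(0.05, 0.05), seed = 1)
  expect_identical(two[[1]], rerun[[1]])
})

test_that("mean responder fraction is monotone in dose across seeds", {
  cfg <- clean_config(n_events = 1500)
  doses <- c(0.01, 0.03, 0.06, 0.12, 0.3)
  fracs <- sapply(1:20, function(s) {
    tabs <- simulate_dilution_series(cfg, doses, seed = s)
    vapply(tabs, function(t) mean(t$label == "on"), numeric(1))
  })
  expect_false(is.unsorted(rowMeans(fracs)))
})

test_that("compound off-state effects scale the unstimulated median", {
  # log-normal median scaling oracle: a 5x off-state effect multiplies the
  # well's median fluorescence by 5 in an unstimulated well
  cfg <- clean_config(n_events = 4000)
  eff <- compound_effect("cmp", "cls", effect_on_off_state = 5)
  base <- median(simulate_well(cfg, 0, seed = 21)$fl)
  shifted <- median(simulate_well(cfg, 0, effect = eff, seed = 22)$fl)
  expect_lt(abs(shifted / base - 5) / 5, 0.10)
})

test_that("threshold and toxicity effects act on the advertised knobs", {
  cfg <- clean_config(n_events = 5000)
  sens <- compound_effect("s", "cls", effect_on_threshold = 0.2)
  lo <- mean(simulate_well(cfg, 0.02, seed = 5)$label == "on")
  hi <- mean(simulate_well(cfg, 0.02, effect = sens, seed = 5)$label == "on")
  expect_gt(hi, lo)
  tox <- compound_effect("t", "cls", toxicity_debris_shift = 2)
  tab <- simulate_well(small_config(5000), 0, effect = tox, seed = 5)
  expect_lt(abs(mean(tab$label == "debris") - 0.95), 0.02) # clamped at 0.95
})

test_that("time course factor saturates the on/off separation", {
  cfg <- clean_config(n_events = 3000)
  med_at <- function(t, s) {
    tab <- simulate_well(cfg, dose = 0.5, seed = s, time_h = t, tau = 6)
    median(tab$fl[tab$label == "on"])
  }
  meds <- sapply(1:20, function(s) vapply(c(4, 8, 16, 24), med_at, numeric(1),
                                          s = s))
  avg <- rowMeans(meds)
  expect_false(is.unsorted(avg))
  # near-max at 24 h: within the 24/(24+6) = 0.8 saturating factor of full
  expect_gt(avg[4] / exp(cfg$mu_off + 0.8 * (cfg$mu_on - cfg$mu_off)), 0.9)
})

test_that("seed derivation is a pure function of master seed and key", {
  expect_identical(derive_seed(7, "P1_A01"), derive_seed(7, "P1_A01"))
  expect_false(derive_seed(7, "P1_A01") == derive_seed(7, "P1_A02"))
  expect_false(derive_seed(7, "X") == derive_seed(8, "X"))
  expect_true(derive_seed(2^30, paste(rep("z", 100), collapse = "")) <
                2^31)
})

test_that("simulate_screen honours controls and emits a truth manifest", {
  cfg <- clean_config(n_events = 300)
  lay <- tiny_screen_layout(n_classes = 2, n_ctrl = 2)
  eff <- list(compound_effect("c01_01", "class01", effect_on_on_state = 3))
  scr <- simulate_screen(cfg, lay$plate_map, eff, seed = 4)
  expect_s3_class(scr, "screen_dataset")
  expect_length(scr$events, nrow(lay$plate_map))
  neg <- scr$events[[paste0("P1_", lay$plate_map$well_id[
    which(lay$plate_map$role == "neg_ctrl")[1]])]]
  expect_true(all(neg$label == "off"))
  m <- scr$manifest
  expect_equal(m$effect_on_on_state[m$compound_id %in% "c01_01"], 3)
  expect_equal(m$dose[m$role == "neg_ctrl"], rep(0, 2))
  # all-unstimulated plate: every well all-off
  pm0 <- lay$plate_map
  pm0$stimulated <- FALSE
  scr0 <- simulate_screen(cfg, pm0, list(), seed = 4)
  expect_true(all(vapply(scr0$events[pm0$role != "pos_ctrl"],
                         function(e) all(e$label == "off"), logical(1))))
  # missing control role is an error
  pm_bad <- lay$plate_map[lay$plate_map$role != "neg_ctrl", ]
  expect_error(simulate_screen(cfg, pm_bad, list(), seed = 1), "neg_ctrl")
})
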