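resp_row <- function(compound, value, qc = TRUE) {
  data.frame(compound_id = compound, normalized_response = value,
             qc_pass = qc, stringsAsFactors = FALSE)
}

test_that("cluster medians and the size cutoff follow their definitions", {
  ann <- data.frame(compound_id = c("a1", "a2", "a3", "b1", "b2"),
                    target_class = c("A", "A", "A", "B", "B"))
  resp <- rbind(resp_row(c("a1", "a2", "a3"), c(90, 110, 400)),
                resp_row(c("b1", "b2"), c(50, 60)))
  cl <- aggregate_by_target(resp, ann, min_cluster_size = 3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$target_class, "A")
  expect_equal(cl$median_response, 110)
  supp <- attr(cl, "suppressed")
  expect_equal(supp$target_class, "B")
  expect_equal(supp$n_compounds, 2L)
})

test_that("all-QC-failed input yields an empty result with a warning", {
  ann <- data.frame(compound_id = c("a1", "a2", "a3"),
                    target_class = rep("A", 3))
  resp <- resp_row(c("a1", "a2", "a3"), c(1, 2, 3), qc = FALSE)
  expect_warning(cl <- aggregate_by_target(resp, ann), "QC-failed")
  expect_equal(nrow(cl), 0)
})

test_that("unannotated compounds and mixed strata are rejected by name", {
  ann <- data.frame(compound_id = "a1", target_class = "A")
  expect_error(aggregate_by_target(resp_row(c("a1", "zz9"), c(1, 2)), ann),
               "zz9")
  resp <- resp_row(c("a1", "a1"), c(1, 2))
  resp$concentration <- c(2, 15)
  expect_error(aggregate_by_target(resp, ann), "stratum")
  empty <- data.frame(compound_id = character(),
                      normalized_response = numeric(), qc_pass = logical())
  expect_error(aggregate_by_target(empty, ann), "empty")
})

test_that("clustering partitions QC-passing compounds and is stable", {
  set.seed(6)
  n <- 40
  ann <- data.frame(compound_id = sprintf("c%02d", 1:n),
                    target_class = sample(sprintf("T%d", 1:8), n,
                                          replace = TRUE))
  resp <- resp_row(ann$compound_id, rnorm(n, 100, 40),
                   qc = runif(n) > 0.2)
  cl <- aggregate_by_target(resp, ann, min_cluster_size = 3)
  supp <- attr(cl, "suppressed")
  counted <- sum(cl$n_compounds) + sum(supp$n_compounds)
  expect_equal(counted, sum(resp$qc_pass))
  # sorted by median response, descending
  expect_false(is.unsorted(rev(cl$median_response)))
  # duplicating members an odd number of times preserves the medians
  resp3 <- do.call(rbind, list(resp, resp, resp))
  resp3$compound_id <- sprintf("c%03d", seq_len(nrow(resp3)))
  ann3 <- data.frame(compound_id = resp3$compound_id,
                     target_class = rep(ann$target_class, 3))
  cl3 <- aggregate_by_target(resp3, ann3, min_cluster_size = 3)
  shared <- intersect(cl3$target_class, cl$target_class)
  expect_equal(cl3$median_response[match(shared, cl3$target_class)],
               cl$median_response[match(shared, cl$target_class)])
  # raising the cutoff never adds clusters
  for (m in c(4, 5, 8))
    expect_true(all(aggregate_by_target(resp, ann, m)$target_class %in%
                      cl$target_class))
})

test_that("concordance is Spearman over the paired intersection", {
  a <- c(x = 1, y = 2, z = 3, w = 4)
  expect_equal(concordance(a, a)$rho, 1.0)
  expect_equal(concordance(a, -a)$rho, -1.0)
  b <- c(y = 5, z = 1, w = 2, v = 9)
  out <- concordance(a, b)
  expect_equal(out$n_used, 3)
  expect_equal(out$n_dropped, 2)
  expect_error(concordance(c(x = 1, y = 2), c(x = 1, y = 2)), "at least 3")
})

test_that("replicate screens of one ground truth are rank-concordant", {
  set.seed(7)
  n <- 100
  truth <- rnorm(n, 100, 40)
  names(truth) <- sprintf("c%03d", 1:n)
  rep1 <- truth + rnorm(n, 0, 15)
  rep2 <- truth + rnorm(n, 0, 15)
  names(rep1) <- names(rep2) <- names(truth)
  expect_gt(concordance(rep1, rep2)$rho, 0.8)
})

test_that("hit calls and member-fraction counting follow the thresholds", {
  cl <- aggregate_by_target(
    rbind(resp_row(c("u1", "u2", "u3"), c(240, 250, 260)),
          resp_row(c("d1", "d2", "d3", "d4"), c(70, 75, 78, 95)),
          resp_row(c("n1", "n2", "n3"), c(95, 100, 105))),
    data.frame(compound_id = c("u1", "u2", "u3", "d1", "d2", "d3", "d4",
                               "n1", "n2", "n3"),
               target_class = rep(c("UP", "DOWN", "NONE"), c(3, 4, 3))))
  hits <- call_hits(cl, up_threshold = 150, down_threshold = 80)
  expect_equal(hits$call[hits$target_class == "UP"], "up")
  expect_equal(hits$call[hits$target_class == "DOWN"], "down")
  expect_equal(hits$call[hits$target_class == "NONE"], "none")
  # counting rule: 3 of the 4 DOWN members are <= 80
  expect_equal(hits$frac_members_down[hits$target_class == "DOWN"], 3 / 4)
  expect_equal(hits$n_members_down[hits$target_class == "DOWN"], 3L)
  expect_error(call_hits(cl, up_threshold = 90, down_threshold = 80),
               "down_threshold")
})

test_that("cluster significance reports BH-adjusted Mann-Whitney p-values", {
  cl <- aggregate_by_target(
    rbind(resp_row(sprintf("a%d", 1:4), c(300, 310, 320, 330)),
          resp_row(sprintf("b%d", 1:4), c(99, 101, 100, 102))),
    data.frame(compound_id = c(sprintf("a%d", 1:4), sprintf("b%d", 1:4)),
               target_class = rep(c("A", "B"), each = 4)))
  sig <- cluster_significance(cl, control_responses = c(98, 100, 101, 103))
  expect_equal(nrow(sig), 2)
  expect_lt(sig$p_value[sig$target_class == "A"], 0.05)
  expect_true(all(sig$p_adjusted >= sig$p_value - 1e-12))
})
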