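# beta MLE, sequential modality rules, spurious-bimodality correction and
# modality dynamics

test_that("beta likelihood fit matches an independent optimizer", {
  set.seed(21)
  for (shape in list(c(2, 5), c(5, 2), c(3, 3))) {
    x <- rbeta(400, shape[1], shape[2])
    ours <- fit_beta_mle(x)
    xc <- pmin(pmax(x, 1e-3), 1 - 1e-3)
    ref <- fitdistrplus::fitdist(xc, "beta")$estimate
    expect_equal(unname(ours[["alpha"]]), unname(ref[["shape1"]]),
                 tolerance = 1e-3)
    expect_equal(unname(ours[["beta"]]), unname(ref[["shape2"]]),
                 tolerance = 1e-3)
  }
})

test_that("constant PSI input yields a flagged degenerate fit", {
  expect_warning(fit <- fit_beta_mle(rep(0.4, 20)), "degenerate")
  expect_true(attr(fit, "degenerate"))
  expect_equal(fit[["alpha"]] / (fit[["alpha"]] + fit[["beta"]]), 0.4)
})

test_that("modality rules apply in the documented precedence order", {
  cl <- function(a, b) classify_modality(a, b, 0.1)$modality
  # a bimodal-range parameter wins over the inclusion ratio rule
  expect_equal(cl(0.4, 3), "bimodal")
  expect_equal(cl(3, 0.4), "bimodal")
  expect_equal(cl(3, 0.9), "included")    # alpha > 2 & beta < 1
  expect_equal(cl(2.5, 1.2), "included")  # ratio > 2
  expect_equal(cl(0.9, 3), "excluded")
  expect_equal(cl(1.2, 2.5), "excluded")
  expect_equal(cl(4, 4), "middle")
  expect_equal(cl(4, 3.9), "middle")      # within 5% relative tolerance
  expect_equal(cl(4, 3.7), "multimodal")  # outside tolerance
  expect_equal(cl(1.5, 1.1), "multimodal")
})

test_that("sub-modality splits on the 0.001 variance threshold", {
  r_lo <- classify_modality(10, 1, 0.0005)
  r_hi <- classify_modality(10, 1, 0.001)
  expect_equal(r_lo$sub_modality, "primary")
  expect_equal(r_hi$sub_modality, "dispersed")
  expect_equal(classify_modality(4, 4, 0.0005)$sub_modality, "none")
})

test_that("balanced extreme PSI distributions survive the bimodal check", {
  x <- c(rep(0.95, 10), rep(0.05, 8), rep(0.5, 2))
  adj <- adjust_bimodality(x)
  expect_true(adj$is_true_bimodal)
  expect_equal(adj$modality, "bimodal")
})

test_that("one-sided extremes are reassigned by their mean PSI", {
  hi <- c(rep(0.95, 16), rep(0.05, 4))  # fold 4, skewed high
  adj_hi <- adjust_bimodality(hi)
  expect_false(adj_hi$is_true_bimodal)
  expect_equal(adj_hi$modality, "included")
  lo <- c(rep(0.05, 16), rep(0.95, 4))
  expect_equal(adjust_bimodality(lo)$modality, "excluded")
  # one empty side gives an infinite fold and always fails
  one_side <- c(rep(0.95, 15), rep(0.5, 5))
  adj1 <- adjust_bimodality(one_side)
  expect_false(adj1$is_true_bimodal)
  expect_equal(adj1$fold, Inf)
})

test_that("bimodality thresholds are strict at fold 3 and difference 0.5", {
  # p_hi = 0.45, p_lo = 0.15: fold exactly 3 (not < 3) -> reassigned
  x3 <- c(rep(0.9, 9), rep(0.1, 3), rep(0.5, 8))
  adj3 <- adjust_bimodality(x3)
  expect_equal(adj3$fold, 3)
  expect_false(adj3$is_true_bimodal)
  # p_hi = 0.75, p_lo = 0.25: difference exactly 0.50 (not < 0.50)
  x5 <- c(rep(0.9, 15), rep(0.1, 5))
  adj5 <- adjust_bimodality(x5)
  expect_equal(adj5$diff, 0.5)
  expect_false(adj5$is_true_bimodal)
  # just inside both strict thresholds: retained
  xin <- c(rep(0.9, 8), rep(0.1, 4), rep(0.5, 8))  # fold 2, diff 0.2
  expect_true(adjust_bimodality(xin)$is_true_bimodal)
})

test_that("planted archetypes are recovered across the modality classes", {
  sim <- simulate_plate(modality_plan(6), n_cells_per_group = 50,
                        seed = 31, depth_mean = 300)
  ps <- compute_psi_plate(sim$events, sim$junction_counts)
  calls <- assign_modalities(ps$psi)
  m <- merge(calls, sim$truth[, c("event_id", "modality_truth")],
             by = "event_id")
  expect_gte(mean(m$modality == m$modality_truth), 0.9)
  expect_true(all(c("pre_adjustment_modality", "bimodal_adjusted")
                  %in% names(calls)))
})

test_that("all-or-none capture artifacts are corrected out of bimodal", {
  plan <- data.frame(type = "SE", alpha_g1 = 8, beta_g1 = 2,
                     alpha_g2 = 8, beta_g2 = 2, artifact = TRUE,
                     relation = "null", expr_log2fc = 0)
  sim <- simulate_plate(plan[rep(1, 10), ], n_cells_per_group = 50,
                        seed = 32)
  ps <- compute_psi_plate(sim$events, sim$junction_counts)
  calls <- assign_modalities(ps$psi)
  expect_true(all(calls$pre_adjustment_modality == "bimodal"))
  expect_true(all(calls$bimodal_adjusted))
  expect_true(all(calls$modality == "included"))  # mean psi 0.8
  # without the correction the spurious calls persist
  raw <- assign_modalities(ps$psi, bimodal_adjust = FALSE)
  expect_true(all(raw$modality == "bimodal"))
})

test_that("modality dynamics distinguish explicit, implicit, restricted", {
  g1 <- data.frame(event_id = c("e1", "e2", "e3", "e4"),
                   modality = c("included", "included", "middle", "middle"),
                   sub_modality = c("primary", "primary", "none", "none"),
                   stringsAsFactors = FALSE)
  g2 <- data.frame(event_id = c("e1", "e2", "e3"),
                   modality = c("excluded", "included", "middle"),
                   sub_modality = c("dispersed", "dispersed", "none"),
                   stringsAsFactors = FALSE)
  dyn <- classify_modality_dynamics(g1, g2)
  expect_equal(dyn$dynamics[dyn$event_id == "e1"], "explicit")
  expect_equal(dyn$dynamics[dyn$event_id == "e2"], "implicit")
  expect_equal(dyn$dynamics[dyn$event_id == "e3"], "restricted")
  expect_equal(dyn$dynamics[dyn$event_id == "e4"], "undefined")
})
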