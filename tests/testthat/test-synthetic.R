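test_that("panel generation is deterministic given the seed", {
  cfg <- small_panel_cfg(seed = 11)
  a <- generate_clone_panel(cfg)
  b <- generate_clone_panel(cfg)
  expect_identical(a, b)
  c2 <- generate_clone_panel(small_panel_cfg(seed = 12))
  expect_false(identical(a$truth, c2$truth))
})

test_that("count and flow tables have the documented structure", {
  pan <- generate_clone_panel(small_panel_cfg(n_clones = 2))
  expect_named(pan$counts, c("clone_id", "condition", "cell_id", "mrna_count"))
  expect_true(all(pan$counts$mrna_count >= 0))
  expect_true(all(pan$counts$mrna_count == floor(pan$counts$mrna_count)))
  expect_true(all(c("fsc", "ssc", "mesf", "protein", "extrinsic")
                  %in% names(pan$flow)))
  expect_true(all(pan$flow$mesf >= 0))
  expect_equal(nrow(pan$flow), 2 * 400)
})

test_that("without extrinsic noise and background, flow CV2 is the protein CV2", {
  cfg <- small_panel_cfg(n_clones = 2, n_events_flow = 500,
                         extrinsic_cv = 0, autofluorescence_mean = 0,
                         autofluorescence_sd = 0)
  pan <- generate_clone_panel(cfg)
  g <- pan$flow[pan$flow$clone_id == "clone_01", ]
  expect_equal(var(g$mesf) / mean(g$mesf)^2,
               var(g$protein) / mean(g$protein)^2, tolerance = 1e-12)
})

test_that("bursting-regime violations are warned about", {
  expect_warning(clone_params(b = 2, f = 10), "bursting regime")
  expect_silent(clone_params(b = 2, f = 1))
})

test_that("identity perturbation leaves the panel unchanged", {
  cfg <- small_panel_cfg()
  truth <- generate_clone_panel(cfg, flow = FALSE)$truth
  pcfg <- perturbation_config(freq_fold_change = 1, size_fold_change = 1)
  after <- apply_perturbation(truth, pcfg, cfg)
  expect_equal(after$k_on, truth$k_on)
  expect_equal(after$T, truth$T)
  expect_equal(after$analytic_mean, truth$analytic_mean)
})

test_that("below-threshold clones keep their burst size but gain mean", {
  cfg <- small_panel_cfg()
  truth <- generate_clone_panel(cfg, flow = FALSE)$truth
  pcfg <- perturbation_config(freq_fold_change = 5,
                              size_threshold_mean = Inf)
  after <- apply_perturbation(truth, pcfg, cfg)
  expect_equal(after$b, truth$b)
  expect_true(all(after$analytic_mean > truth$analytic_mean))
  expect_false(any(after$size_modulated))
})

test_that("above-threshold clones double their burst size", {
  cfg <- small_panel_cfg()
  truth <- generate_clone_panel(cfg, flow = FALSE)$truth
  pcfg <- perturbation_config(freq_fold_change = 5,
                              size_threshold_mean = 0, size_fold_change = 2)
  after <- apply_perturbation(truth, pcfg, cfg)
  expect_equal(after$b, truth$b * 2)
  expect_equal(after$T / after$k_off, truth$b * 2)  # k_off unchanged
  expect_equal(after$k_off, truth$k_off)
  expect_true(all(after$size_modulated))
  expect_true(all(after$analytic_mean > truth$analytic_mean))
})

test_that("noiseless counts recover the analytic Fano factor", {
  cfg <- clone_panel_config(n_clones = 2, n_cells_fish = 5000,
                            extrinsic_cv = 0, seed = 303)
  truth <- panel_truth(b = c(3, 8), f = c(0.5, 1), cfg)
  pan <- generate_clone_panel(cfg, truth = truth, flow = FALSE)
  sm <- summarize_table(pan$counts, "mrna_count")
  sm <- sm[match(pan$truth$clone_id, sm$clone_id), ]
  expect_equal(burst_size_fish(sm), pan$truth$analytic_fano, tolerance = 0.1)
})
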