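test_that("population summaries use the unbiased variance", {
  s <- summarize_population(c(5, 5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$cv2, 0)
  expect_equal(s$fano, 0)
  s <- summarize_population(c(0, 10), clone_id = "a", condition = "x")
  expect_equal(s$mean, 5)
  expect_equal(s$variance, 50)
  expect_equal(s$cv2, 2)
  expect_equal(s$fano, 10)
  expect_error(summarize_population(3), "at least 2")
  expect_error(summarize_population(c(0, 0, 0)), "undefined")
  expect_error(summarize_population(c(-1, 2)), "negative")
})

test_that("CV2 is scale-free while the Fano factor scales linearly", {
  set.seed(5)
  for (i in 1:5) {
    v <- rpois(50, 6) + 1
    c_ <- runif(1, 0.5, 100)
    s1 <- summarize_population(v)
    s2 <- summarize_population(c_ * v)
    expect_equal(s2$cv2, s1$cv2)
    expect_equal(s2$fano, c_ * s1$fano)
  }
})

test_that("a large Poisson sample has unit Fano factor", {
  set.seed(8)
  s <- summarize_population(rpois(20000, 8))
  expect_equal(s$fano, 1, tolerance = 0.05)
})

test_that("summarize_table groups by clone and condition", {
  pan <- generate_clone_panel(small_panel_cfg(n_clones = 2), flow = FALSE)
  sm <- summarize_table(pan$counts)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$n, c(60, 60))
  expect_error(summarize_table(data.frame(x = 1)), "value column|clone_id")
})

test_that("sub-gating returns exactly the requested events, deterministically", {
  pan <- generate_clone_panel(small_panel_cfg(n_clones = 1,
                                              n_events_flow = 2000))
  g <- pan$flow
  expect_identical(subgate(g, nrow(g)), g)
  sub <- subgate(g, 300)
  expect_equal(nrow(sub), 300)
  expect_identical(sub, subgate(g, 300))
  expect_error(subgate(g, nrow(g) + 1), "exceeds")
})

test_that("sub-gating strips extrinsic noise and lowers measured CV2", {
  cfg <- clone_panel_config(n_clones = 2, n_cells_fish = 10,
                            n_events_flow = 20000, extrinsic_cv = 0.3,
                            autofluorescence_mean = 0,
                            autofluorescence_sd = 0, seed = 77)
  pan <- generate_clone_panel(cfg)
  for (cl in unique(pan$flow$clone_id)) {
    g <- pan$flow[pan$flow$clone_id == cl, ]
    gated <- subgate(g, 2000)
    cv2_all <- var(g$mesf) / mean(g$mesf)^2
    cv2_gated <- var(gated$mesf) / mean(gated$mesf)^2
    expect_lt(cv2_gated, cv2_all)
    # gated extrinsic factor should be nearly constant
    expect_lt(sd(gated$extrinsic) / mean(gated$extrinsic), 0.1)
  }
})

test_that("autofluorescence correction subtracts mean and variance", {
  s <- summary_row(1100, 30000 / 1100^2)
  s$variance <- 30000
  s$fano <- 30000 / 1100
  corr <- correct_autofluorescence(s, af_mean = 100, af_variance = 5000)
  expect_equal(corr$mean, 1000)
  expect_equal(corr$variance, 25000)
  expect_equal(corr$cv2, 0.025)
  ident <- correct_autofluorescence(s, 0, 0)
  expect_equal(ident$cv2, s$cv2)
  expect_error(correct_autofluorescence(s, af_mean = 1200, af_variance = 0),
               "background")
  floored <- correct_autofluorescence(s, af_mean = 100, af_variance = 4e4)
  expect_true(attr(floored, "variance_floored"))
  expect_gt(floored$variance, 0)
})

test_that("batch-means standard errors scale as expected", {
  set.seed(12)
  v <- rnorm(10000, 100, 5)
  bm <- batch_moment_se(v, n_batches = 100)
  expect_equal(bm$se_mean, 5 / sqrt(10000), tolerance = 0.25)
  expect_error(batch_moment_se(1:10, n_batches = 100), "per batch")
})
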