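test_that("smFISH burst size is CV2 times the mean", {
  expect_equal(burst_size_fish(summary_row(10, 0)), 0)
  expect_equal(burst_size_fish(summary_row(10, 0.3)), 3.0)
  expect_error(burst_size_fish(summary_row(-1, 0.3)), "mean")
})

test_that("smFISH burst size is identically the Fano factor", {
  set.seed(42)
  for (i in 1:50) {
    v <- rgamma(25, shape = 2, rate = 0.2)
    s <- summarize_population(v)
    expect_equal(burst_size_fish(s), s$fano, tolerance = 1e-14)
    expect_equal(burst_size_fish(s), var(v) / mean(v), tolerance = 1e-12)
  }
})

test_that("MESF burst size applies the 5000-MESF calibration", {
  expect_equal(as.numeric(burst_size_mesf(summary_row(60000, 0.5))), 5.0)
  expect_equal(as.numeric(burst_size_mesf(summary_row(100000, 0.2))), 3.0)
  # formula zero point at cv2 * mean = 5000
  expect_equal(as.numeric(burst_size_mesf(summary_row(10000, 0.5))), 0)
  dim_clone <- burst_size_mesf(summary_row(2000, 0.5))
  expect_equal(as.numeric(dim_clone), 0)
  expect_true(attr(dim_clone, "floored"))
})

test_that("burst frequency is mean over burst size", {
  s <- summary_row(10, 0.5)
  expect_equal(burst_frequency(s, 5), 2.0)
  expect_equal(burst_frequency(summary_row(20, 0.25), 5), 4.0)
  expect_error(burst_frequency(s, 0), "burst_size")
})

test_that("manifold assignment rounds half-up and clamps to the grid", {
  m <- assign_manifold(c(3.2, 2.5, 14.1))
  expect_equal(as.integer(m), c(3L, 3L, 12L))
  expect_equal(attr(m, "out_of_grid"), c(FALSE, FALSE, TRUE))
  expect_error(assign_manifold(-0.1), ">= 0")
})

test_that("estimate_bursts assembles the full estimate table", {
  sm <- rbind(summary_row(10, 0.5, clone_id = "a"),
              summary_row(100, 0.08, clone_id = "b"))
  est <- estimate_bursts(sm, source = "fish")
  expect_s3_class(est, "burst_estimates")
  expect_equal(est$burst_size, c(5, 8))
  expect_equal(est$burst_size_geom, c(4, 7))
  expect_equal(est$burst_frequency, c(2, 12.5))
  expect_equal(est$manifold, c(5L, 8L))
  mest <- estimate_bursts(summary_row(60000, 0.5), source = "mesf")
  expect_equal(mest$burst_size, 5)
  expect_equal(mest$burst_size_geom, 5)
})

test_that("the Fano estimate converges to the analytic value with n", {
  p <- telegraph_params(k_on = 1, k_off = 50, T = 250, d_m = 1)
  target <- analytic_mrna_moments(p)$fano
  err <- sapply(c(500, 3000, 10000), function(n) {
    cells <- sample_steady_state(p, n, seed = 500 + n)
    s <- summarize_population(cells$mrna)
    abs(burst_size_fish(s) - target) / target
  })
  # generous 8-sigma bands around the sqrt(n) convergence rate
  expect_lt(err[1], 8 * sqrt(2 / 500))
  expect_lt(err[2], 8 * sqrt(2 / 3000))
  expect_lt(err[3], 8 * sqrt(2 / 10000))
})

test_that("estimated frequency rank-correlates with the true k_on", {
  cfg <- clone_panel_config(n_clones = 12, n_cells_fish = 2000,
                            extrinsic_cv = 0, seed = 202)
  pan <- generate_clone_panel(cfg, flow = FALSE)
  sm <- summarize_table(pan$counts)
  est <- estimate_bursts(sm)
  est <- est[match(pan$truth$clone_id, est$clone_id), ]
  expect_gte(cor(est$burst_frequency, pan$truth$k_on, method = "spearman"),
             0.9)
})
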