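test_that("manifold curves are decreasing hyperbolae ordered by burst size", {
  mset <- manifold_set(c(2, 8))
  cur <- manifold_curves(mset, mean_grid = c(1, 10, 100))
  expect_equal(cur$cv2[cur$B == 2], 2 / c(1, 10, 100))
  b2 <- cur$cv2[cur$B == 2]; b8 <- cur$cv2[cur$B == 8]
  expect_true(all(diff(b2) < 0))
  expect_true(all(b8 > b2))
  # MESF units invert the MESF burst formula
  msetm <- manifold_set(5, units = "mesf")
  curm <- manifold_curves(msetm, 60000)
  expect_equal(curm$cv2, 5000 * 6 / 60000)
  expect_error(manifold_set(-1), ">= 0")
})

test_that("extreme manifolds pass through the extreme clones", {
  est <- estimates_at(means = c(100, 10000), Bs = c(2, 8))
  fit <- fit_extreme_manifolds(est)
  expect_equal(fit$B_min, 2)
  expect_equal(fit$B_max, 8)
  # degenerate: identical clones collapse the band
  est1 <- estimates_at(means = c(50, 50, 50), Bs = c(4, 4, 4))
  fit1 <- fit_extreme_manifolds(est1)
  expect_equal(fit1$B_min, fit1$B_max)
  expect_error(fit_extreme_manifolds(est[1, ]), "at least 2")
})

test_that("brightness- and range-based extreme fits agree when brightness ranks with burst size", {
  est <- estimates_at(means = c(100, 800, 10000), Bs = c(2, 5, 8))
  expect_equal(fit_extreme_manifolds(est, method = "range")[c("B_min", "B_max")],
               fit_extreme_manifolds(est, method = "brightness")[c("B_min", "B_max")])
  # and differ when it does not: the range method still bounds the panel
  est2 <- estimates_at(means = c(100, 10000), Bs = c(8, 2))
  fitr <- fit_extreme_manifolds(est2, method = "range")
  fitb <- fit_extreme_manifolds(est2, method = "brightness")
  expect_equal(c(fitr$B_min, fitr$B_max), c(2, 8))
  expect_equal(c(fitb$B_min, fitb$B_max), c(8, 2))
})

test_that("points on one manifold regress with slope -1 and intercept log B", {
  sm <- do.call(rbind, lapply(c(2, 7, 30, 120), function(m)
    summary_row(m, 4 / m)))
  fit <- loglog_slope(sm)
  expect_equal(fit$slope, -1)
  expect_equal(fit$intercept, log(4))
  expect_equal(fit$r, -1)
  # scale-independent noise floor: constant cv2 gives slope 0
  smc <- do.call(rbind, lapply(c(2, 7, 30), function(m) summary_row(m, 0.1)))
  expect_equal(loglog_slope(smc)$slope, 0)
  expect_error(loglog_slope(sm[1:2, ]), "at least 3")
  expect_error(loglog_slope(do.call(rbind, lapply(1:3, function(i)
    summary_row(10, 0.5)))), "degenerate")
})

test_that("identity perturbation shows no contraction and pure frequency calls", {
  est <- estimates_at(means = c(10, 100, 400), Bs = c(2, 5, 8))
  after <- est
  after$condition <- "tnfa"
  pa <- perturbation_analysis(est, after)
  expect_equal(pa$contraction_fraction, 0)
  expect_equal(pa$containment_fraction, 1)
  expect_true(all(pa$clones$modulation == "frequency"))
})

test_that("a pure frequency shift contracts CV2 and stays contained", {
  est <- estimates_at(means = c(10, 100, 400), Bs = c(2, 5, 8))
  after <- estimates_at(means = 5 * c(10, 100, 400), Bs = c(2, 5, 8),
                        condition = "tnfa")
  pa <- perturbation_analysis(est, after)
  expect_equal(pa$contraction_fraction, 1)
  expect_equal(pa$containment_fraction, 1)
  expect_true(all(pa$clones$modulation == "frequency"))
  expect_equal(pa$exclusion$n_above + pa$exclusion$n_below, 0)
})

test_that("burst-size doubling above threshold is classified as size modulation", {
  est <- estimates_at(means = c(10, 400), Bs = c(2, 8))
  after <- estimates_at(means = c(50, 4000), Bs = c(2, 16),
                        condition = "tnfa")
  pa <- perturbation_analysis(est, after)
  expect_equal(pa$clones$modulation, c("frequency", "size"))
  # the doubled-B point escapes the baseline band
  expect_lt(pa$containment_fraction, 1)
})

test_that("unmatched clones are reported by id", {
  est <- estimates_at(means = c(10, 100), Bs = c(2, 5))
  after <- est[1, ]
  expect_error(perturbation_analysis(est, after), "clone_02")
})
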