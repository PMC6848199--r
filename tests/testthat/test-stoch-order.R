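curve <- function(cum, n) list(n = n, cum = cum)

test_that("pooled proportions drop degenerate breakpoints", {
  pp <- pooled_probs(curve(c(0.5, 1), 10), curve(c(0.5, 1), 10))
  expect_equal(pp$p, 0.5)
  expect_equal(pp$kept, 1L)  # the final breakpoint (pooled 1) is dropped

  pp2 <- pooled_probs(curve(c(0.2, 1), 50), curve(c(0.4, 1), 50))
  expect_equal(pp2$p, 0.3)

  self <- pooled_probs(curve(c(0.25, 0.75, 1), 30), curve(c(0.25, 0.75, 1), 70))
  expect_equal(self$p, c(0.25, 0.75))

  expect_error(pooled_probs(curve(c(0, 1), 5), curve(c(0, 1), 5)), "degenerate pair")
})

test_that("bridge covariance matches the closed form and is PSD", {
  sig <- bridge_covariance(c(0.25, 0.5, 0.75))
  expect_equal(sig, matrix(c(0.1875, 0.125, 0.0625,
                             0.125, 0.25, 0.125,
                             0.0625, 0.125, 0.1875), 3, 3))
  expect_equal(bridge_covariance(0.5), matrix(0.25))
  expect_error(bridge_covariance(c(0.2, 1.2)), "strictly in")

  set.seed(12)
  for (i in 1:30) {
    p <- sort(runif(sample(1:12, 1), 0.01, 0.99))
    sig <- bridge_covariance(p)
    expect_equal(sig, t(sig))
    for (a in seq_along(p)) for (b in seq_along(p)) {
      expect_equal(sig[a, b], min(p[a], p[b]) * (1 - max(p[a], p[b])))
    }
    expect_gte(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  }
})

test_that("max-modulus quantile matches normal quantiles at k = 1 and is monotone", {
  c50 <- max_modulus_quantile(matrix(0.25), alpha = 0.5, n_mc = 1e5, seed = 2)
  expect_equal(c50, qnorm(0.75), tolerance = 0.02)

  sig <- bridge_covariance(c(0.2, 0.4, 0.6, 0.8))
  c05 <- max_modulus_quantile(sig, alpha = 0.05, n_mc = 1e4, seed = 3)
  c10 <- max_modulus_quantile(sig, alpha = 0.10, n_mc = 1e4, seed = 3)
  expect_gte(c05, c10)
  # more coordinates can only push the maximum up (same seed)
  c1 <- max_modulus_quantile(matrix(0.25), alpha = 0.05, n_mc = 1e4, seed = 3)
  expect_gte(c05, c1)
  # bit-reproducible under the seed
  expect_identical(c05, max_modulus_quantile(sig, alpha = 0.05, n_mc = 1e4, seed = 3))
})

test_that("joint band is centered on D with width 2 c_alpha se", {
  set.seed(21)
  v <- sample.int(16, 300, TRUE, prob = default_base_profile(16))
  a <- build_distribution(v, tl16(), "A")
  b <- build_distribution(v, tl16(), "B")
  band <- joint_band(a, b, alpha = 0.05, n_mc = 1e4, seed = 5)
  expect_true(all(band$D == 0))
  expect_equal(band$band_low, -band$band_high)
  c_alpha <- attr(band, "c_alpha")
  expect_equal(band$band_high - band$band_low, 2 * c_alpha * band$se)
})

test_that("stochastic order verdicts: dominance, identity, crossing", {
  tl <- tl16()
  a <- build_distribution(rep(16L, 100), tl, "all_young")
  b <- build_distribution(rep(1L, 100), tl, "all_old")
  fit <- stochastic_order_test(a, b, n_mc = 1e4, seed = 7)
  expect_equal(fit$verdict, "A_younger")
  expect_lte(fit$p_two_sided, 0.001)

  set.seed(3)
  v <- sample.int(16, 150, TRUE)
  same <- stochastic_order_test(build_distribution(v, tl, "x"),
                                build_distribution(v, tl, "y"),
                                n_mc = 1e4, seed = 8)
  expect_equal(same$verdict, "no_difference")
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_two_sided, 1)

  tlx <- tl4()
  cross_a <- build_distribution(c(rep(1L, 250), rep(4L, 250)), tlx, "spread")
  cross_b <- build_distribution(c(rep(2L, 250), rep(3L, 250)), tlx, "middle")
  cr <- stochastic_order_test(cross_a, cross_b, n_mc = 1e4, seed = 9)
  expect_equal(cr$verdict, "crossing")
})

test_that("swapping the pair negates D, keeps p, and mirrors the verdict", {
  tl <- tl16()
  set.seed(33)
  pi0 <- default_base_profile(16)
  a <- build_distribution(sample.int(16, 400, TRUE, prob = pi0), tl, "A")
  b <- build_distribution(sample.int(16, 300, TRUE, prob = shift_rootward(pi0, 2)),
                          tl, "B")
  f_ab <- stochastic_order_test(a, b, n_mc = 2e4, seed = 13)
  f_ba <- stochastic_order_test(b, a, n_mc = 2e4, seed = 13)
  expect_equal(f_ab$band$D, -f_ba$band$D)
  expect_equal(f_ab$p_two_sided, f_ba$p_two_sided)
  expect_equal(f_ab$t_stat, f_ba$t_stat)
  swap <- c(A_younger = "B_younger", B_younger = "A_younger",
            crossing = "crossing", no_difference = "no_difference")
  expect_equal(unname(swap[f_ab$verdict]), f_ba$verdict)
})

test_that("the Scheffe-style calibration is at least as wide as max-modulus", {
  set.seed(17)
  pi0 <- default_base_profile(16)
  a <- build_distribution(sample.int(16, 200, TRUE, prob = pi0), tl16(), "A")
  b <- build_distribution(sample.int(16, 200, TRUE, prob = pi0), tl16(), "B")
  mm <- stochastic_order_test(a, b, n_mc = 1e4, seed = 2, method = "max_modulus")
  sc <- stochastic_order_test(a, b, seed = 2, method = "scheffe")
  expect_gte(sc$c_alpha, mm$c_alpha)
})

test_that("tidy and glance expose the band and the one-row summary", {
  a <- build_distribution(rep(16L, 50), tl16(), "young")
  b <- build_distribution(rep(1L, 50), tl16(), "old")
  fit <- stochastic_order_test(a, b, n_mc = 1e4, seed = 1)
  td <- tidy(fit)
  expect_true(all(c("class_a", "D", "band_low", "band_high", "excludes_zero")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$verdict, "A_younger")
  expect_equal(gl$class_a, "young")
})
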