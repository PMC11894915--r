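test_that("likelihood weights follow the binomial factorisation", {
  # identical draws share the mass regardless of the data
  d <- posterior_draws(data.frame(prevalence = c(0.5, 0.5),
                                  sensitivity = c(0.5, 0.5),
                                  specificity = c(0.5, 0.5)))
  w <- likelihood_weights(d, future_sample(3, 1, 4, 2))
  expect_equal(w$weights, c(0.5, 0.5))
  expect_equal(sum(exp(w$log_weights)), 1, tolerance = 1e-12)

  # hand-computed pmf ratio: sens/spec factors shared, prevalence differs
  d2 <- posterior_draws(data.frame(prevalence = c(0.9, 0.1),
                                   sensitivity = c(0.7, 0.7),
                                   specificity = c(0.6, 0.6)))
  fut <- future_sample(n_tp = 6, n_fn = 3, n_tn = 1, n_fp = 0) # N+ = 9, N = 10
  w2 <- likelihood_weights(d2, fut)
  expect_equal(w2$weights[1] / w2$weights[2],
               dbinom(9, 10, 0.9) / dbinom(9, 10, 0.1))

  # impossible data under a draw: exactly zero weight
  d3 <- posterior_draws(data.frame(prevalence = c(0.3, 0.3),
                                   sensitivity = c(0, 0.8),
                                   specificity = c(0.5, 0.5)))
  w3 <- likelihood_weights(d3, future_sample(2, 1, 3, 1))
  expect_identical(w3$weights[1], 0)
  expect_false(w3$degenerate)

  # zero likelihood everywhere: flagged degenerate
  d4 <- posterior_draws(data.frame(prevalence = c(0.3, 0.4),
                                   sensitivity = c(0, 0),
                                   specificity = c(0.5, 0.5)))
  w4 <- likelihood_weights(d4, future_sample(2, 1, 3, 1))
  expect_true(w4$degenerate)
  expect_true(is.na(ess_diagnostic(w4)))

  # a zero-size future study leaves the weights uniform (0-trial pmf = 1)
  w0 <- likelihood_weights(d2, future_sample(0, 0, 0, 0))
  expect_equal(w0$weights, c(0.5, 0.5))
})

test_that("effective sample size diagnoses weight degeneracy", {
  expect_equal(ess_diagnostic(rep(1 / 7, 7)), 7)
  expect_equal(ess_diagnostic(c(1, 0, 0)), 1)
  expect_equal(ess_diagnostic(c(0.5, 0.25, 0.25)), 1 / (0.25 + 2 * 0.0625))
  expect_error(ess_diagnostic(c(0.5, 0.2)), "normalised")
})

test_that("a point-mass posterior has no value of information", {
  d <- posterior_draws(data.frame(prevalence = rep(0.1, 10),
                                  sensitivity = rep(0.8, 10),
                                  specificity = rep(0.7, 10)))
  r <- evsi_general(d, 0.05, n_future = 200, seed = 1)
  expect_equal(r$evpi, 0)
  expect_equal(r$evsi, 0)
  expect_equal(r$ess_min, 10)
})

test_that("zero-size future study short-circuits to zero EVSI", {
  d <- sample_case_study_draws(500, seed = 2)
  r <- evsi_general(d, 0.02, n_future = 0, seed = 3)
  expect_identical(r$evsi, 0)
  expect_equal(r$enb_sample, r$enb_current)
})

test_that("the exhaustive small-M algorithm matches full enumeration", {
  # chosen so a single future observation can flip the argmax: treat-all is
  # best on average but the low-prevalence draw favours the model
  d <- posterior_draws(data.frame(
    prevalence = c(0.1, 0.5, 0.3),
    sensitivity = c(0.9, 0.6, 0.4),
    specificity = c(0.9, 0.2, 0.5)
  ))
  exact <- enumerate_evsi_general(d, z = 0.2, N = 1)
  expect_gt(exact, 0)
  set.seed(17)
  reps <- vapply(1:2000, function(k) {
    evsi_general(d, 0.2, n_future = 1)$evsi
  }, numeric(1))
  mc <- mean(reps)
  se <- sd(reps) / sqrt(length(reps))
  expect_gt(se, 0)
  expect_lt(abs(mc - exact), 3 * se)
})

test_that("general and beta-binomial algorithms agree on shared posteriors", {
  d <- sample_case_study_draws(2e4, seed = 4)
  g <- evsi_general(d, 0.02, 1000, n_outer = 2000, seed = 5)
  b <- evsi_beta_binomial(case_study_posterior(), 0.02, 1000, n_sim = 2e5,
                          seed = 6)
  # the finite draw sample adds its own error beyond the outer-loop MCSE
  draw_se <- 3e-5
  expect_lt(abs(g$evsi - b$evsi),
            3 * (g$mcse_evsi + b$mcse_evsi) + 3 * draw_se)
  expect_lt(abs(g$evpi - b$evpi), 3 * (g$mcse_evpi + b$mcse_evpi) +
              3 * draw_se)
  expect_gte(g$ess_median, 1)
  expect_lte(g$ess_median, 2e4)
})
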