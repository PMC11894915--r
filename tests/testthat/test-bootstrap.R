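test_that("bootstrap weights have the right support and moments", {
  set.seed(1)
  expect_equal(draw_weights(1, "bayesian")$weights, 1)
  expect_error(draw_weights(0), "positive integer")
  w <- draw_weights(1e5, "bayesian")$weights
  expect_equal(sum(w), 1)
  expect_equal(mean(w), 1e-5)
  # Dirichlet(1,...,1): Var(w_i) = (n-1)/(n^2 (n+1)) ~ 1/n^2
  expect_equal(var(w) * 1e10, 1, tolerance = 0.05)
  wo <- draw_weights(4, "ordinary")$weights
  expect_true(all(abs(wo * 4 - round(wo * 4)) < 1e-12))
  expect_equal(sum(wo), 1)
})

test_that("weighted theta reduces to plug-in proportions under uniform weights", {
  s <- gusto_like_fixture()
  uni <- structure(list(weights = rep(1 / 500, 500), scheme = "bayesian"),
                   class = "bootstrap_weights")
  th <- weighted_theta(s, uni, 0.02)
  expect_equal(th$prevalence, 43 / 500)
  expect_equal(th$sensitivity, 41 / 43)
  expect_equal(th$specificity, 147 / 457)
  expect_false(attr(th, "degenerate"))
  plug <- theta_from_counts(counts_from_sample(s, 0.02))
  expect_equal(th$prevalence, plug$prevalence)
  # all mass on a single treated event: specificity undefined
  w1 <- c(1, rep(0, 499)) # row 1 is an event with risk >= 0.02
  th1 <- weighted_theta(s, w1, 0.02)
  expect_true(attr(th1, "degenerate"))
  expect_equal(th1$prevalence, 1)
  expect_equal(th1$sensitivity, 1)
  expect_true(is.nan(th1$specificity))
  expect_error(weighted_theta(s, rep(1, 500), 0.02), "sum to 1")
})

test_that("one-class samples are rejected with a pointer to the Bayesian route", {
  all_ev <- validation_sample(risk = runif(10), outcome = rep(1, 10))
  expect_error(voi_bootstrap(all_ev, 0.1, 100, n_sim = 10),
               "beta-binomial")
})

test_that("VoI is exactly zero when the model dominates every bootstrap draw", {
  # perfect classification at z = 0.5: sens = spec = 1 for any weighting,
  # so the model's NB beats both defaults in every iteration
  s <- validation_sample(risk = c(rep(0.9, 5), rep(0.1, 20)),
                         outcome = c(rep(1, 5), rep(0, 20)))
  r <- voi_bootstrap(s, 0.5, n_future = 50, n_sim = 2000, seed = 2)
  expect_equal(r$evpi, 0)
  expect_equal(r$evsi, 0)
  expect_identical(r$best_strategy, 1L)
})

test_that("ordinary and Bayesian schemes give compatible estimates", {
  s <- gusto_like_fixture()
  a <- voi_bootstrap(s, 0.02, 1000, n_sim = 1e4, scheme = "bayesian",
                     seed = 3)
  b <- voi_bootstrap(s, 0.02, 1000, n_sim = 1e4, scheme = "ordinary",
                     seed = 4)
  expect_lt(abs(a$evpi - b$evpi), 3 * (a$mcse_evpi + b$mcse_evpi))
  expect_lt(abs(a$evsi - b$evsi), 3 * (a$mcse_evsi + b$mcse_evsi))
  # identities and ordering hold for both schemes
  for (r in list(a, b)) {
    expect_equal(r$evpi, r$enb_truth - r$enb_current)
    expect_gte(r$evpi, 0)
    expect_lte(r$evsi, r$evpi + 3 * (r$mcse_evsi + r$mcse_evpi))
  }
})

test_that("EVSI of a zero-size future study is zero for the bootstrap too", {
  r <- voi_bootstrap(gusto_like_fixture(), 0.02, n_future = 0, n_sim = 500,
                     seed = 5)
  expect_identical(r$evsi, 0)
})

test_that("incremental NB point estimate matches closed-form arithmetic", {
  s <- gusto_like_fixture()
  ci <- incremental_nb_ci(s, 0.02, n_boot = 2000, seed = 6)
  omega <- 0.02 / 0.98
  expect_equal(ci$inb,
               (41 / 500 - omega * 310 / 500) -
                 max(0, 43 / 500 - omega * 457 / 500))
  expect_lte(ci$lower, ci$inb)
  expect_gte(ci$upper, ci$inb)
  # a sample of identical records has a zero-width interval
  s0 <- validation_sample(risk = rep(0.3, 8), outcome = rep(1, 8))
  ci0 <- incremental_nb_ci(s0, 0.1, n_boot = 100, seed = 7)
  expect_equal(ci0$lower, ci0$upper)
  expect_error(incremental_nb_ci(s, numeric(0)))
  expect_error(incremental_nb_ci(s, 0.02, n_boot = 1))
})

test_that("percentile intervals cover the generating truth near nominal rate", {
  # known truth from a large reference sample of the same generator
  spec_big <- generator_spec(2e5, seed = 100)
  ref <- generate_sample(spec_big)
  truth <- incremental_nb_ci(ref, 0.05, n_boot = 2, seed = 1)$inb
  hits <- vapply(1:60, function(k) {
    s <- generate_sample(generator_spec(400, seed = 200 + k))
    ci <- incremental_nb_ci(s, 0.05, n_boot = 300, seed = 300 + k)
    ci$lower <= truth && truth <= ci$upper
  }, logical(1))
  # 95% nominal; allow for the finite replication count and small n_boot
  expect_gte(mean(hits), 0.85)
})
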