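test_that("net benefit follows the three-strategy definition", {
  thr <- risk_threshold(0.10)
  th <- theta_triplet(0.10, 0.80, 0.90)
  expect_identical(net_benefit(0, th, thr), 0)
  # hand arithmetic: 0.08 - 0.9*0.1*(1/9)
  expect_equal(net_benefit(1, th, thr), 0.07)
  # treat-all is exactly zero when prevalence equals the threshold
  expect_equal(net_benefit(2, theta_triplet(0.3, 0.5, 0.5), 0.3), 0)
  expect_error(net_benefit(3, th, thr), "strategy")
})

test_that("threshold construction derives omega and rejects invalid z", {
  thr <- risk_threshold(0.02)
  expect_equal(thr$omega, 0.02 / 0.98)
  for (z in c(0, 1, -0.1, 1.5, NA)) expect_error(risk_threshold(z))
  expect_error(theta_triplet(1.2, 0.5, 0.5))
})

test_that("NB is linear in each theta component and obeys the treat-all identity", {
  set.seed(42)
  for (k in 1:50) {
    z <- runif(1, 0.01, 0.9)
    thr <- risk_threshold(z)
    p <- runif(3)
    th <- theta_triplet(p[1], p[2], p[3])
    # algebraic identity NB2 - NB1 = prev(1-sens) - (1-prev)*spec*omega
    expect_equal(net_benefit(2, th, thr) - net_benefit(1, th, thr),
                 p[1] * (1 - p[2]) - (1 - p[1]) * p[3] * thr$omega)
    # linearity: finite differences in each component are constant
    h <- 1e-3
    for (i in 1:3) {
      bump <- function(delta) {
        q <- p; q[i] <- q[i] * (1 - h) + delta
        net_benefit(1, theta_triplet(q[1], q[2], q[3]), thr)
      }
      d1 <- bump(h * p[i]) - bump(0)
      d2 <- bump(2 * h * p[i]) - bump(h * p[i])
      expect_equal(d1, d2, tolerance = 1e-8)
    }
  }
})

test_that("best-current-strategy plug-in picks the argmax with lowest-index ties", {
  # case-study posterior means at z = 0.02: the model wins
  th <- theta_triplet(0.086, 42 / 45, 148 / 459)
  res <- enb_current_plugin(th, 0.02)
  expect_identical(res$strategy, 1L)
  expect_equal(res$enb, max(res$nb))
  # symmetric point: all three NBs are 0, tie resolves to treat-none
  expect_identical(enb_current_plugin(theta_triplet(0.5, 0.5, 0.5),
                                      0.5)$strategy, 0L)
  # prevalence and sensitivity 1: model ties treat-all at NB = 1, index 1 wins
  expect_identical(enb_current_plugin(theta_triplet(1, 1, 0.3),
                                      0.2)$strategy, 1L)
  # counts path: plug-in from counts, degenerate margins rejected
  expect_identical(
    enb_current_plugin(confusion_counts(41, 2, 147, 310), 0.02)$strategy, 1L)
  expect_error(enb_current_plugin(confusion_counts(0, 0, 0, 0), 0.02))
  expect_error(enb_current_plugin(confusion_counts(0, 0, 10, 5), 0.02),
               "no events")
})

test_that("population scaling is linear with FP/TP ratio (1-z)/z", {
  expect_equal(scale_to_population(0, 0.02, 8e5), 0)
  expect_equal(scale_to_population(0.00101, 0.02, 8e5), 808)
  expect_equal(scale_to_population(0.00125, 0.02, 8e5, "false_positive"),
               0.00125 * 0.98 / 0.02 * 8e5)
  set.seed(1)
  for (k in 1:20) {
    z <- runif(1, 0.01, 0.99); v <- runif(1); K <- runif(1, 0, 1e6)
    expect_equal(scale_to_population(v, z, K, "false_positive") /
                   scale_to_population(v, z, K), (1 - z) / z)
  }
  expect_error(scale_to_population(-0.1, 0.02, 8e5))
})

test_that("decision curve equals plug-in net benefit from the same counts", {
  s <- gusto_like_fixture()
  dc <- decision_curve(s, c(0.01, 0.02, 0.05))
  expect_equal(names(dc), c("z", "nb_none", "nb_model", "nb_all"))
  expect_true(all(dc$nb_none == 0))
  expect_equal(dc$nb_model[dc$z == 0.02], 41 / 500 - (310 / 500) * 0.02 / 0.98)
  # treat-all row only needs plug-in prevalence
  expect_equal(dc$nb_all, 43 / 500 - (457 / 500) * dc$z / (1 - dc$z))
  # internal consistency with net_benefit at the plug-in theta
  for (z in dc$z) {
    th <- theta_from_counts(counts_from_sample(s, z))
    expect_equal(dc$nb_model[dc$z == z], net_benefit(1, th, z))
  }
  # a sample with no events can never profit from treating
  s0 <- validation_sample(risk = c(0.1, 0.4, 0.02), outcome = c(0, 0, 0))
  dc0 <- decision_curve(s0, 0.05)
  expect_lte(dc0$nb_model, 0)
  expect_lt(dc0$nb_all, 0)
  expect_error(decision_curve(s, numeric(0)))
})

test_that("risk exactly at the threshold is classified positive", {
  s <- validation_sample(risk = c(0.02, 0.019999), outcome = c(1, 0))
  cc <- counts_from_sample(s, 0.02)
  expect_equal(c(cc$n_tp, cc$n_fn, cc$n_tn, cc$n_fp), c(1, 0, 1, 0))
})
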