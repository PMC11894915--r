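# Independent oracles and small utilities shared across tests.

# beta-binomial pmf: P(X = x | size, shape1, shape2), marginal of
# Binomial(size, p) with p ~ Beta(shape1, shape2)
dbetabinom <- function(x, size, shape1, shape2) {
  exp(lchoose(size, x) + lbeta(shape1 + x, shape2 + size - x) -
        lbeta(shape1, shape2))
}

case_study_counts <- function() confusion_counts(41, 2, 147, 310)

case_study_posterior <- function() {
  beta_posterior(prev = c(44, 458), sens = c(42, 3), spec = c(148, 311))
}

# Exact EVSI under independent beta posteriors by exhaustive enumeration of
# the future confusion table (N+, Ntp, Ntn), each stratum marginally
# beta-binomial. Because NB is linear in the components of theta and the
# posteriors are independent, the posterior-expected NB of each strategy is
# NB at the posterior means, so the inner argmax can be evaluated in closed
# form. Feasible only for tiny N.
enumerate_evsi_beta_binomial <- function(post, z, N) {
  omega <- z / (1 - z)
  nb_at <- function(prev, sens, spec) {
    c(0, prev * sens - (1 - prev) * (1 - spec) * omega,
      prev - (1 - prev) * omega)
  }
  pm <- function(s) s[1] / (s[1] + s[2])
  enb_current <- max(nb_at(pm(post$prev), pm(post$sens), pm(post$spec)))
  enb_sample <- 0
  for (n_pos in 0:N) {
    p_pos <- dbetabinom(n_pos, N, post$prev[1], post$prev[2])
    for (n_tp in 0:n_pos) {
      p_tp <- dbetabinom(n_tp, n_pos, post$sens[1], post$sens[2])
      for (n_tn in 0:(N - n_pos)) {
        p_tn <- dbetabinom(n_tn, N - n_pos, post$spec[1], post$spec[2])
        prev_u <- (post$prev[1] + n_pos) / (sum(post$prev) + N)
        sens_u <- (post$sens[1] + n_tp) / (sum(post$sens) + n_pos)
        spec_u <- (post$spec[1] + n_tn) / (sum(post$spec) + N - n_pos)
        enb_sample <- enb_sample +
          p_pos * p_tp * p_tn * max(nb_at(prev_u, sens_u, spec_u))
      }
    }
  }
  enb_sample - enb_current
}

# Exact expected EVSI of the general algorithm for tiny M and N: enumerate
# every future table D and average, over the truths, the NB (at the truth) of
# the strategy maximising the likelihood-weighted mean NB given D. Matches
# the estimand of the exhaustive outer loop.
enumerate_evsi_general <- function(draws, z, N) {
  omega <- z / (1 - z)
  M <- nrow(draws)
  nb1 <- with(draws, prevalence * sensitivity -
                (1 - prevalence) * (1 - specificity) * omega)
  nb2 <- with(draws, prevalence - (1 - prevalence) * omega)
  enb_current <- max(0, mean(nb1), mean(nb2))
  lik <- function(th, n_pos, n_tp, n_tn) {
    dbinom(n_pos, N, th[1]) * dbinom(n_tp, n_pos, th[2]) *
      dbinom(n_tn, N - n_pos, th[3])
  }
  enb_sample <- 0
  for (i in seq_len(M)) {
    th_star <- as.numeric(draws[i, ])
    for (n_pos in 0:N) for (n_tp in 0:n_pos) for (n_tn in 0:(N - n_pos)) {
      p_d <- lik(th_star, n_pos, n_tp, n_tn)
      if (p_d == 0) next
      w <- vapply(seq_len(M), function(k) {
        lik(as.numeric(draws[k, ]), n_pos, n_tp, n_tn)
      }, numeric(1))
      if (sum(w) == 0) next
      nb1_u <- sum(w * nb1) / sum(w)
      nb2_u <- sum(w * nb2) / sum(w)
      l <- which.max(c(0, nb1_u, nb2_u))
      enb_sample <- enb_sample + p_d * c(0, nb1[i], nb2[i])[l] / M
    }
  }
  enb_sample - enb_current
}

# posterior draws sampled from independent case-study betas
sample_case_study_draws <- function(M, seed) {
  set.seed(seed)
  posterior_draws(data.frame(
    prevalence = rbeta(M, 44, 458),
    sensitivity = rbeta(M, 42, 3),
    specificity = rbeta(M, 148, 311)
  ))
}
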