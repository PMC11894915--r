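#' Independent beta posteriors for prevalence, sensitivity and specificity
#'
#' Current information about the theta triplet expressed as three independent
#' beta distributions — the conjugate form that arises from beta priors and
#' binomial confusion counts. All six shape parameters must be strictly
#' positive (proper distributions); the improper Beta(0, 0) limit underlying
#' the Bayesian bootstrap is reached through [voi_bootstrap()], not here.
#'
#' @param prev,sens,spec Length-2 numeric vectors `c(alpha, beta)` of strictly
#'   positive shape parameters.
#' @return An object of class `beta_posterior`.
#' @examples
#' beta_posterior(prev = c(44, 458), sens = c(42, 3), spec = c(148, 311))
#' @export
beta_posterior <- function(prev, sens, spec) {
  check_shape <- function(x, name) {
    if (!is.numeric(x) || length(x) != 2L || anyNA(x) || any(x <= 0)) {
      stop("`", name, "` must be two strictly positive shape parameters ",
           "c(alpha, beta)", call. = FALSE)
    }
    as.numeric(x)
  }
  structure(list(prev = check_shape(prev, "prev"),
                 sens = check_shape(sens, "sens"),
                 spec = check_shape(spec, "spec")),
            class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  f <- function(s) sprintf("Beta(%g, %g)", s[1], s[2])
  cat(sprintf("prevalence ~ %s, sensitivity ~ %s, specificity ~ %s\n",
              f(x$prev), f(x$sens), f(x$spec)))
  invisible(x)
}

#' Flat Beta(1, 1) prior on each component of theta
#' @return A [beta_posterior()] with all shapes 1.
#' @export
flat_beta_prior <- function() {
  beta_posterior(c(1, 1), c(1, 1), c(1, 1))
}

#' Posterior means of a beta posterior
#' @param post A [beta_posterior()].
#' @return A [theta_triplet()] of the three posterior means.
#' @export
posterior_means <- function(post) {
  stopifnot(inherits(post, "beta_posterior"))
  m <- function(s) s[1] / (s[1] + s[2])
  theta_triplet(m(post$prev), m(post$sens), m(post$spec))
}

#' Conjugate update of beta priors with confusion counts
#'
#' Beta-binomial conjugacy applied independently to the three components:
#' prevalence is updated with events vs non-events, sensitivity with true
#' positives vs false negatives, specificity with true negatives vs false
#' positives.
#'
#' @param counts A [confusion_counts()] object.
#' @param prior A [beta_posterior()]; defaults to flat Beta(1, 1) priors.
#' @return The updated [beta_posterior()].
#' @examples
#' # the case-study sample: 43/500 events, counts (41, 2, 147, 310) at z = 0.02
#' posterior_from_counts(confusion_counts(41, 2, 147, 310))
#' @export
posterior_from_counts <- function(counts, prior = flat_beta_prior()) {
  stopifnot(inherits(counts, "confusion_counts"),
            inherits(prior, "beta_posterior"))
  beta_posterior(
    prev = c(prior$prev[1] + counts$n_tp + counts$n_fn,
             prior$prev[2] + counts$n_tn + counts$n_fp),
    sens = c(prior$sens[1] + counts$n_tp, prior$sens[2] + counts$n_fn),
    spec = c(prior$spec[1] + counts$n_tn, prior$spec[2] + counts$n_fp)
  )
}

# Draw n_sim theta triplets and their per-draw strategy NBs. Every
# beta-binomial VoI quantity is built on these shared draws.
draw_theta_nb <- function(post, thr, n_sim) {
  prev <- rbeta(n_sim, post$prev[1], post$prev[2])
  sens <- rbeta(n_sim, post$sens[1], post$sens[2])
  spec <- rbeta(n_sim, post$spec[1], post$spec[2])
  nb1 <- nb_model_vec(prev, sens, spec, thr$omega)
  nb2 <- nb_all_vec(prev, thr$omega)
  list(prev = prev, sens = sens, spec = spec, nb1 = nb1, nb2 = nb2)
}

# ENB under current information: max over strategies of the per-draw average
# NB. Averaging the same draws used for the truth/sample terms keeps the two
# terms positively correlated, which sharpens the difference estimate and
# avoids occasional negative VoI values.
enb_current_from_draws <- function(nb1, nb2) {
  means <- c(0, mean(nb1), mean(nb2))
  i <- which.max(means)
  list(value = means[i], strategy = i - 1L, means = means)
}

#' EVPI under independent beta posteriors
#'
#' Monte Carlo estimate of the expected value of perfect information: the
#' expected gain in net benefit from fully resolving uncertainty about
#' (prevalence, sensitivity, specificity) before choosing among treat-none,
#' use-model and treat-all. Per draw the maximum strategy NB is recorded; the
#' mean of those maxima minus the ENB under current information is the EVPI.
#'
#' @param post A [beta_posterior()].
#' @param threshold A [risk_threshold()] or bare `z`.
#' @param n_sim Number of Monte Carlo draws (default 10^6).
#' @param seed Optional integer seed; the global RNG state is restored.
#' @return A `voi_result` with `evpi`, the ENB terms and a batch-means MCSE.
#' @examples
#' post <- posterior_from_counts(confusion_counts(41, 2, 147, 310))
#' evpi_beta_binomial(post, 0.02, n_sim = 1e4, seed = 1)
#' @export
evpi_beta_binomial <- function(post, threshold, n_sim = 1e6, seed = NULL) {
  thr <- as_risk_threshold(threshold)
  stopifnot(inherits(post, "beta_posterior"))
  if (!is.numeric(n_sim) || n_sim < 1) stop("`n_sim` must be >= 1",
                                            call. = FALSE)
  n_sim <- as.integer(n_sim)
  d <- with_seed(seed, draw_theta_nb(post, thr, n_sim))
  nb_truth <- pmax(0, d$nb1, d$nb2)
  cur <- enb_current_from_draws(d$nb1, d$nb2)
  nb_cur_draw <- per_draw_current(cur$strategy, d$nb1, d$nb2)
  evpi <- mean(nb_truth) - cur$value
  new_voi_result("beta_binomial", thr, n_sim, seed,
                 enb_current = cur$value, enb_truth = mean(nb_truth),
                 evpi = evpi,
                 mcse_evpi = mcse_batch_means(nb_truth - nb_cur_draw),
                 best_strategy = cur$strategy)
}

per_draw_current <- function(strategy, nb1, nb2) {
  switch(as.character(strategy),
         "0" = rep(0, length(nb1)), "1" = nb1, "2" = nb2)
}

#' EVSI for a planned validation sample under independent beta posteriors
#'
#' Monte Carlo estimate of the expected value of sample information for a
#' future validation study of `n_future` subjects. Per draw, a "true" theta is
#' sampled from the posterior; a future confusion table is generated
#' hierarchically (events ~ Binomial(N, prev), true positives ~
#' Binomial(events, sens), true negatives ~ Binomial(non-events, spec)); the
#' conjugate posterior-mean update gives the revised theta; the strategy that
#' maximises NB at the revised theta is chosen and its NB *at the true theta*
#' is credited. The mean of those credited NBs minus the ENB under current
#' information is the EVSI.
#'
#' A study of size 0 carries no information and cannot change the decision,
#' so `n_future = 0` returns an EVSI of exactly zero.
#'
#' @inheritParams evpi_beta_binomial
#' @param n_future Planned future sample size N (>= 0).
#' @return A `voi_result` with both `evsi` and `evpi` (the same draws serve
#'   both), ENB terms, and batch-means MCSEs.
#' @examples
#' post <- posterior_from_counts(confusion_counts(41, 2, 147, 310))
#' evsi_beta_binomial(post, 0.02, n_future = 1000, n_sim = 1e4, seed = 1)
#' @export
evsi_beta_binomial <- function(post, threshold, n_future, n_sim = 1e6,
                               seed = NULL) {
  thr <- as_risk_threshold(threshold)
  stopifnot(inherits(post, "beta_posterior"))
  if (!is.numeric(n_future) || length(n_future) != 1L || n_future < 0 ||
      n_future != round(n_future)) {
    stop("`n_future` must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(n_sim) || n_sim < 1) stop("`n_sim` must be >= 1",
                                            call. = FALSE)
  n_sim <- as.integer(n_sim)
  N <- n_future

  sim <- with_seed(seed, {
    d <- draw_theta_nb(post, thr, n_sim)
    if (N > 0) {
      # future confusion table given the drawn truth
      d$n_pos <- rbinom(n_sim, N, d$prev)
      d$n_tp <- rbinom(n_sim, d$n_pos, d$sens)
      d$n_tn <- rbinom(n_sim, N - d$n_pos, d$spec)
    }
    d
  })
  nb_truth <- pmax(0, sim$nb1, sim$nb2)
  cur <- enb_current_from_draws(sim$nb1, sim$nb2)
  nb_cur_draw <- per_draw_current(cur$strategy, sim$nb1, sim$nb2)
  evpi <- mean(nb_truth) - cur$value
  mcse_evpi <- mcse_batch_means(nb_truth - nb_cur_draw)

  if (N == 0) {
    return(new_voi_result("beta_binomial", thr, n_sim, seed,
                          enb_current = cur$value,
                          enb_truth = mean(nb_truth), evpi = evpi,
                          mcse_evpi = mcse_evpi,
                          best_strategy = cur$strategy,
                          enb_sample = cur$value, evsi = 0,
                          mcse_evsi = 0, n_future = 0))
  }

  # conjugate posterior-mean update after seeing the future table
  prev_u <- (post$prev[1] + sim$n_pos) / (post$prev[1] + post$prev[2] + N)
  sens_u <- (post$sens[1] + sim$n_tp) /
    (post$sens[1] + post$sens[2] + sim$n_pos)
  spec_u <- (post$spec[1] + sim$n_tn) /
    (post$spec[1] + post$spec[2] + N - sim$n_pos)

  nb1_u <- nb_model_vec(prev_u, sens_u, spec_u, thr$omega)
  nb2_u <- nb_all_vec(prev_u, thr$omega)
  l <- max.col(cbind(0, nb1_u, nb2_u), ties.method = "first")
  nb_sample <- cbind(0, sim$nb1, sim$nb2)[cbind(seq_len(n_sim), l)]

  new_voi_result("beta_binomial", thr, n_sim, seed,
                 enb_current = cur$value, enb_truth = mean(nb_truth),
                 evpi = evpi, mcse_evpi = mcse_evpi,
                 best_strategy = cur$strategy,
                 enb_sample = mean(nb_sample),
                 evsi = mean(nb_sample) - cur$value,
                 mcse_evsi = mcse_batch_means(nb_sample - nb_cur_draw),
                 n_future = N)
}

#' EVSI as a function of the planned sample size
#'
#' Evaluates [evsi_beta_binomial()] over a grid of future sample sizes with
#' common random numbers for the "true" theta draws (the same seed is used at
#' every grid point), so that the estimated curve is monotone nondecreasing up
#' to residual noise, and appends the EVPI as the N -> infinity asymptote.
#'
#' @inheritParams evsi_beta_binomial
#' @param n_grid Vector of future sample sizes, sorted ascending.
#' @return A data frame of class `evsi_curve` with columns `n_future`, `evsi`,
#'   `mcse`, and the EVPI (with its MCSE) as attributes.
#' @export
evsi_curve <- function(post, threshold, n_grid, n_sim = 1e6, seed = NULL) {
  thr <- as_risk_threshold(threshold)
  if (length(n_grid) == 0L) stop("`n_grid` is empty", call. = FALSE)
  if (is.unsorted(n_grid)) stop("`n_grid` must be sorted ascending",
                                call. = FALSE)
  if (is.null(seed)) {
    # a concrete seed is required so all grid points share the theta draws
    seed <- sample.int(.Machine$integer.max, 1L)
  }
  fits <- lapply(n_grid, function(N) {
    evsi_beta_binomial(post, thr, n_future = N, n_sim = n_sim, seed = seed)
  })
  out <- data.frame(
    n_future = n_grid,
    evsi = vapply(fits, `[[`, numeric(1), "evsi"),
    mcse = vapply(fits, `[[`, numeric(1), "mcse_evsi")
  )
  class(out) <- c("evsi_curve", "data.frame")
  attr(out, "evpi") <- fits[[1L]]$evpi
  attr(out, "mcse_evpi") <- fits[[1L]]$mcse_evpi
  attr(out, "z") <- thr$z
  attr(out, "seed") <- seed
  out
}

#' @export
plot.evsi_curve <- function(x, ...) {
  ggplot2::ggplot(as.data.frame(x),
                  ggplot2::aes(x = .data$n_future, y = .data$evsi)) +
    ggplot2::geom_hline(yintercept = attr(x, "evpi"), linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "future validation sample size N",
                  y = "EVSI (net TP units per decision)",
                  subtitle = sprintf("z = %g; dashed line: EVPI",
                                     attr(x, "z"))) +
    ggplot2::theme_minimal()
}
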