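#' Posterior draws of theta from an arbitrary joint distribution
#'
#' The input of the general algorithm: a Monte Carlo sample from the joint
#' posterior of (prevalence, sensitivity, specificity), e.g. MCMC output from
#' a meta-analytic model. Draws need not be independent across components.
#'
#' @param x A matrix or data frame with at least the columns `prevalence`,
#'   `sensitivity`, `specificity` (or exactly 3 unnamed columns in that
#'   order), each in \[0, 1\], and at least 2 rows.
#' @return A data frame of class `posterior_draws`.
#' @export
posterior_draws <- function(x) {
  x <- as.data.frame(x)
  cols <- c("prevalence", "sensitivity", "specificity")
  if (!all(cols %in% names(x))) {
    if (ncol(x) == 3L) names(x) <- cols
    else stop("expected columns prevalence, sensitivity, specificity",
              call. = FALSE)
  }
  x <- x[cols]
  if (nrow(x) < 2L) stop("need at least 2 posterior draws", call. = FALSE)
  for (cl in cols) {
    bad <- which(!is.finite(x[[cl]]) | x[[cl]] < 0 | x[[cl]] > 1)
    if (length(bad)) {
      stop(sprintf("`%s` outside [0, 1] at row(s): %s", cl,
                   paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  class(x) <- c("posterior_draws", "data.frame")
  x
}

#' Read posterior draws from a 3-column CSV
#'
#' Interchange point for users bringing MCMC output: columns `prevalence`,
#' `sensitivity`, `specificity`, one row per draw.
#'
#' @param path Path to a CSV file.
#' @return A [posterior_draws()] object.
#' @export
read_posterior_draws <- function(path) {
  posterior_draws(utils::read.csv(path))
}

#' Future confusion table of a planned validation study
#'
#' @param n_tp,n_fn,n_tn,n_fp Non-negative counts; their sum is the planned
#'   sample size.
#' @return An object of class `future_sample` with the counts and `n_total`.
#' @export
future_sample <- function(n_tp, n_fn, n_tn, n_fp) {
  cc <- confusion_counts(n_tp, n_fn, n_tn, n_fp)
  structure(c(unclass(cc), list(n_total = total_counts(cc))),
            class = "future_sample")
}

#' Likelihood reweighting of posterior draws given a future confusion table
#'
#' Bayes updating by importance weights: each draw's weight is proportional to
#' the binomial likelihood of the observed future table under that draw —
#' events among N trials under the prevalence, true positives among events
#' under the sensitivity, true negatives among non-events under the
#' specificity. All arithmetic is in log space; normalisation subtracts the
#' log-sum-exp. Zero-trial factors contribute probability one.
#'
#' @param draws A [posterior_draws()] object.
#' @param future A [future_sample()] object.
#' @return An object of class `likelihood_weights`: `log_weights`
#'   (normalised, so `sum(exp(log_weights)) == 1`), `weights`, `ess`
#'   (effective sample size), and `degenerate` (`TRUE` when every draw has
#'   zero likelihood).
#' @export
likelihood_weights <- function(draws, future) {
  draws <- posterior_draws(draws)
  stopifnot(inherits(future, "future_sample"))
  lw <- log_lik_future(draws$prevalence, draws$sensitivity,
                       draws$specificity,
                       n_pos = future$n_tp + future$n_fn,
                       n_tp = future$n_tp, n_tn = future$n_tn,
                       n_total = future$n_total)
  m <- max(lw)
  if (!is.finite(m)) {
    return(structure(list(log_weights = lw, weights = rep(0, length(lw)),
                          ess = NA_real_, degenerate = TRUE),
                     class = "likelihood_weights"))
  }
  lw <- lw - (m + log(sum(exp(lw - m))))
  w <- exp(lw)
  structure(list(log_weights = lw, weights = w,
                 ess = 1 / sum(w^2), degenerate = FALSE),
            class = "likelihood_weights")
}

# log P(D | theta) for the binomial factorisation of a confusion table
log_lik_future <- function(prev, sens, spec, n_pos, n_tp, n_tn, n_total) {
  dbinom(n_pos, n_total, prev, log = TRUE) +
    dbinom(n_tp, n_pos, sens, log = TRUE) +
    dbinom(n_tn, n_total - n_pos, spec, log = TRUE)
}

#' Effective sample size of normalised importance weights
#'
#' `1 / sum(w^2)` for weights summing to one: M for uniform weights, 1 when a
#' single draw carries all the mass. Low values diagnose weight degeneracy —
#' the documented failure mode of the general algorithm with few posterior
#' draws.
#'
#' @param w A [likelihood_weights()] object or bare normalised weights.
#' @return Effective sample size in \[1, M\].
#' @export
ess_diagnostic <- function(w) {
  if (inherits(w, "likelihood_weights")) {
    if (w$degenerate) return(NA_real_)
    w <- w$weights
  }
  if (abs(sum(w) - 1) > 1e-8) stop("weights must be normalised",
                                   call. = FALSE)
  1 / sum(w^2)
}

#' EVSI from arbitrary posterior draws by likelihood reweighting
#'
#' The nonconjugate algorithm: current information is the empirical
#' distribution of `draws`. Each outer iteration takes one draw as the truth,
#' simulates a future confusion table from it, reweights *all* draws by the
#' binomial likelihood of that table, and credits the strategy with the
#' highest weighted-mean NB with its NB at the truth. The ENB under current
#' information is the max over strategies of the unweighted mean NB over the
#' draws; the ENB with perfect information is the mean of the per-draw
#' maximum NB, so EVPI comes for free.
#'
#' By default the outer loop visits every draw; above `exhaustive_cap` draws
#' it instead samples `n_outer` truths at random (with replacement), keeping
#' the cost independent of M.
#'
#' Iterations whose future table has zero likelihood under every draw are
#' flagged degenerate and dropped; the run fails if more than
#' `max_degenerate_frac` of iterations degenerate.
#'
#' @param draws A [posterior_draws()] object (M rows).
#' @param threshold A [risk_threshold()] or bare `z`.
#' @param n_future Planned future sample size N (>= 0); 0 returns EVSI = 0.
#' @param n_outer Number of outer iterations when M exceeds `exhaustive_cap`
#'   (default `min(M, 10^4)`); ignored (set to M) below the cap.
#' @param exhaustive_cap Largest M for which the outer loop visits every draw
#'   (default 10^4).
#' @param max_degenerate_frac Maximal tolerated fraction of degenerate
#'   iterations (default 0.01).
#' @param seed Optional integer seed.
#' @return A `voi_result` with `evsi`, `evpi`, ENB terms, MCSEs and the
#'   min/median effective sample size over iterations (`ess_min`,
#'   `ess_median`, plus `n_degenerate`).
#' @export
evsi_general <- function(draws, threshold, n_future, n_outer = NULL,
                         exhaustive_cap = 1e4, max_degenerate_frac = 0.01,
                         seed = NULL) {
  draws <- posterior_draws(draws)
  thr <- as_risk_threshold(threshold)
  if (!is.numeric(n_future) || n_future < 0 || n_future != round(n_future)) {
    stop("`n_future` must be a non-negative integer", call. = FALSE)
  }
  M <- nrow(draws)
  N <- as.integer(n_future)
  prev <- draws$prevalence; sens <- draws$sensitivity
  spec <- draws$specificity

  nb1 <- nb_model_vec(prev, sens, spec, thr$omega)
  nb2 <- nb_all_vec(prev, thr$omega)
  nb_truth_all <- pmax(0, nb1, nb2)
  cur <- enb_current_from_draws(nb1, nb2)
  nb_cur_all <- per_draw_current(cur$strategy, nb1, nb2)
  evpi <- mean(nb_truth_all) - cur$value
  mcse_evpi <- mcse_batch_means(nb_truth_all - nb_cur_all)

  exhaustive <- M <= exhaustive_cap
  if (exhaustive) {
    n_outer <- M
  } else if (is.null(n_outer)) {
    n_outer <- min(M, 1e4)
  }
  n_outer <- as.integer(n_outer)
  if (n_outer < 1L) stop("`n_outer` must be >= 1", call. = FALSE)

  if (N == 0) {
    return(new_voi_result("general", thr, n_outer, seed,
                          enb_current = cur$value,
                          enb_truth = mean(nb_truth_all), evpi = evpi,
                          mcse_evpi = mcse_evpi,
                          best_strategy = cur$strategy,
                          enb_sample = cur$value, evsi = 0, mcse_evsi = 0,
                          n_future = 0,
                          extra = list(ess_min = M, ess_median = M,
                                       n_degenerate = 0L)))
  }

  sim <- with_seed(seed, {
    idx <- if (exhaustive) seq_len(M) else
      sample.int(M, n_outer, replace = TRUE)
    nb_sample <- numeric(n_outer)
    nb_cur_j <- numeric(n_outer)
    ess <- numeric(n_outer)
    degenerate <- logical(n_outer)
    for (j in seq_len(n_outer)) {
      i <- idx[j]
      n_pos <- rbinom(1L, N, prev[i])
      n_tp <- rbinom(1L, n_pos, sens[i])
      n_tn <- rbinom(1L, N - n_pos, spec[i])

      lw <- log_lik_future(prev, sens, spec, n_pos, n_tp, n_tn, N)
      m <- max(lw)
      if (!is.finite(m)) {
        degenerate[j] <- TRUE
        next
      }
      w <- exp(lw - m)
      sw <- sum(w)
      nb1_u <- sum(w * nb1) / sw
      nb2_u <- sum(w * nb2) / sw
      l <- which.max(c(0, nb1_u, nb2_u))
      nb_sample[j] <- c(0, nb1[i], nb2[i])[l]
      nb_cur_j[j] <- nb_cur_all[i]
      ess[j] <- (sw / sqrt(sum(w^2)))^2
    }
    list(nb_sample = nb_sample, nb_cur = nb_cur_j, ess = ess,
         degenerate = degenerate)
  })

  n_deg <- sum(sim$degenerate)
  if (n_deg > max_degenerate_frac * n_outer) {
    stop(sprintf(paste0("%d of %d iterations had numerically zero ",
                        "likelihood for every posterior draw; increase M or ",
                        "inspect the draws"), n_deg, n_outer), call. = FALSE)
  }
  keep <- !sim$degenerate
  # paired difference against the best-current strategy at the same truths;
  # its mean is the EVSI estimate (in the exhaustive loop the subtracted
  # term averages exactly to ENB current)
  d <- sim$nb_sample[keep] - sim$nb_cur[keep]
  evsi <- mean(d)
  enb_sample <- cur$value + evsi
  new_voi_result("general", thr, n_outer, seed,
                 enb_current = cur$value, enb_truth = mean(nb_truth_all),
                 evpi = evpi, mcse_evpi = mcse_evpi,
                 best_strategy = cur$strategy,
                 enb_sample = enb_sample,
                 evsi = evsi,
                 mcse_evsi = mcse_batch_means(d),
                 n_future = N,
                 extra = list(ess_min = min(sim$ess[keep]),
                              ess_median = stats::median(sim$ess[keep]),
                              n_degenerate = n_deg))
}
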