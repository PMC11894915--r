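#' Bootstrap weights over a validation sample
#'
#' One posterior draw of the generating population in the resampling
#' algorithms. The Bayesian scheme draws continuous Dirichlet(1, ..., 1)
#' weights (n exponential(1) variables scaled to sum to one); the ordinary
#' scheme draws multinomial resampling counts divided by n, so every weight is
#' a multiple of 1/n.
#'
#' @param n Sample size (>= 1).
#' @param scheme `"bayesian"` (default) or `"ordinary"`.
#' @return An object of class `bootstrap_weights`: list with `weights`
#'   (summing to 1) and `scheme`.
#' @export
draw_weights <- function(n, scheme = c("bayesian", "ordinary")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  w <- if (scheme == "bayesian") {
    e <- rexp(n)
    e / sum(e)
  } else {
    tabulate(sample.int(n, n, replace = TRUE), nbins = n) / n
  }
  structure(list(weights = w, scheme = scheme), class = "bootstrap_weights")
}

#' Weighted theta of a validation sample
#'
#' Prevalence, sensitivity and specificity of the weighted population implied
#' by one draw of bootstrap weights: prevalence is the weighted event mass;
#' sensitivity (specificity) is the weighted mass of correctly classified
#' events (non-events) divided by the event (non-event) mass.
#'
#' If the weighted event or non-event mass is zero the corresponding ratio is
#' undefined; the triplet is returned with that component `NaN` and attribute
#' `degenerate = TRUE`. Net benefit remains well defined for such draws
#' because the undefined ratio only ever appears multiplied by its (zero)
#' mass: `prev * sens` equals the weighted mass of true positives.
#'
#' @param sample A [validation_sample()].
#' @param weights A [draw_weights()] object (or bare numeric weights
#'   summing to 1).
#' @param threshold A [risk_threshold()] or bare `z`.
#' @return A `theta_triplet` (possibly flagged degenerate).
#' @export
weighted_theta <- function(sample, weights, threshold) {
  sample <- as_validation_sample(sample)
  thr <- as_risk_threshold(threshold)
  w <- if (inherits(weights, "bootstrap_weights")) weights$weights else weights
  if (length(w) != nrow(sample)) {
    stop("weights and sample have different lengths", call. = FALSE)
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  pos <- sample$risk >= thr$z
  ev <- sample$outcome == 1L
  m_tp <- sum(w[ev & pos])
  m_ev <- sum(w[ev])
  m_tn <- sum(w[!ev & !pos])
  m_ne <- sum(w[!ev])
  theta <- structure(list(prevalence = m_ev,
                          sensitivity = if (m_ev > 0) m_tp / m_ev else NaN,
                          specificity = if (m_ne > 0) m_tn / m_ne else NaN),
                     class = "theta_triplet")
  attr(theta, "degenerate") <- (m_ev == 0 || m_ne == 0)
  theta
}

#' EVPI and EVSI by two-level bootstrap of a pilot validation sample
#'
#' The resampling algorithm for individual-level current data. Each iteration
#' draws a population from the posterior of the sampling distribution — a
#' Bayesian bootstrap (Dirichlet(1, ..., 1) weights on the records) or an
#' ordinary bootstrap — and treats its prevalence/sensitivity/specificity as
#' the truth of that iteration. The maximum strategy NB at that truth feeds
#' the EVPI; for the EVSI a future study of `n_future` records is drawn with
#' replacement from the weighted population, pooled with the original sample
#' (each record with unit weight), and the strategy maximising the plug-in NB
#' of the pooled data is credited with its NB at the iteration's truth.
#'
#' Because NB at a fixed threshold depends on a record only through its
#' confusion cell, the future draw is realised directly as a multinomial over
#' the four cells with the weighted cell masses as probabilities — exactly the
#' distribution of resampling individual records with the Dirichlet weights
#' as probabilities, at a fraction of the cost.
#'
#' The ENB under current information is the max over strategies of the
#' bootstrap-averaged NBs (the paired-difference form keeps the Monte Carlo
#' error of the VoI estimates small and non-negative).
#'
#' @param sample A [validation_sample()] with at least one event and one
#'   non-event.
#' @param threshold A [risk_threshold()] or bare `z`.
#' @param n_future Planned future sample size N (>= 0); 0 returns EVSI = 0.
#' @param n_sim Number of bootstrap iterations (default 10^4; use 10^5 or
#'   more for production estimates).
#' @param scheme `"bayesian"` (default) or `"ordinary"` bootstrap.
#' @param seed Optional integer seed.
#' @return A `voi_result` with `evpi`, `evsi`, ENB terms and MCSEs.
#' @examples
#' s <- gusto_like_fixture()
#' voi_bootstrap(s, 0.02, n_future = 1000, n_sim = 2000, seed = 1)
#' @export
voi_bootstrap <- function(sample, threshold, n_future, n_sim = 1e4,
                          scheme = c("bayesian", "ordinary"), seed = NULL) {
  sample <- as_validation_sample(sample)
  thr <- as_risk_threshold(threshold)
  scheme <- match.arg(scheme)
  if (!is.numeric(n_future) || n_future < 0 || n_future != round(n_future)) {
    stop("`n_future` must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(n_sim) || n_sim < 1) stop("`n_sim` must be >= 1",
                                            call. = FALSE)
  n_sim <- as.integer(n_sim)
  n <- nrow(sample)
  n_ev <- sum(sample$outcome)
  if (n_ev == 0L || n_ev == n) {
    stop("the bootstrap needs at least one event and one non-event; for ",
         "such samples use the beta-binomial algorithm with a proper prior ",
         "(e.g. posterior_from_counts with Beta(1,1) priors)", call. = FALSE)
  }
  N <- as.integer(n_future)

  # cell of each record at z: 1 = TP, 2 = FN, 3 = TN, 4 = FP
  pos <- sample$risk >= thr$z
  cell <- ifelse(sample$outcome == 1L, ifelse(pos, 1L, 2L),
                 ifelse(pos, 4L, 3L))
  ind <- matrix(0, n, 4L)
  ind[cbind(seq_len(n), cell)] <- 1
  base_counts <- colSums(ind)

  nb1s <- numeric(n_sim); nb2s <- numeric(n_sim)
  nb_truth <- numeric(n_sim); nb_sample <- numeric(n_sim)

  with_seed(seed, for (j in seq_len(n_sim)) {
    w <- if (scheme == "bayesian") {
      e <- rexp(n)
      e / sum(e)
    } else {
      tabulate(sample.int(n, n, replace = TRUE), nbins = n) / n
    }
    wc <- as.vector(w %*% ind) # weighted mass per confusion cell

    # truth of this iteration; NB in mass form (degeneracy-safe:
    # prev*sens = TP mass, (1-prev)(1-spec) = FP mass)
    nb1 <- wc[1L] - thr$omega * wc[4L]
    nb2 <- (wc[1L] + wc[2L]) - thr$omega * (wc[3L] + wc[4L])
    nb1s[j] <- nb1; nb2s[j] <- nb2
    nb_truth[j] <- max(0, nb1, nb2)

    if (N > 0L) {
      # future study resampled from the weighted population, pooled with
      # the original sample at unit weight
      fut <- as.vector(rmultinom(1L, N, wc))
      pooled <- base_counts + fut
      nb1_u <- (pooled[1L] - thr$omega * pooled[4L]) / (n + N)
      nb2_u <- ((pooled[1L] + pooled[2L]) -
                  thr$omega * (pooled[3L] + pooled[4L])) / (n + N)
      l <- which.max(c(0, nb1_u, nb2_u))
      nb_sample[j] <- c(0, nb1, nb2)[l]
    }
  })

  cur <- enb_current_from_draws(nb1s, nb2s)
  nb_cur_draw <- per_draw_current(cur$strategy, nb1s, nb2s)
  evpi <- mean(nb_truth) - cur$value

  if (N == 0L) {
    enb_sample <- cur$value; evsi <- 0; mcse_evsi <- 0
  } else {
    enb_sample <- mean(nb_sample)
    evsi <- enb_sample - cur$value
    mcse_evsi <- mcse_batch_means(nb_sample - nb_cur_draw)
  }

  new_voi_result(paste0("bootstrap_", scheme), thr, n_sim, seed,
                 enb_current = cur$value, enb_truth = mean(nb_truth),
                 evpi = evpi,
                 mcse_evpi = mcse_batch_means(nb_truth - nb_cur_draw),
                 best_strategy = cur$strategy,
                 enb_sample = enb_sample, evsi = evsi,
                 mcse_evsi = mcse_evsi, n_future = N)
}

#' Percentile-bootstrap interval for the incremental net benefit
#'
#' The incremental net benefit (INB) of the model is its plug-in NB minus
#' that of the best default strategy (treat none or treat all) at each
#' threshold. The interval is the percentile interval over ordinary bootstrap
#' resamples of the records.
#'
#' @param sample A [validation_sample()].
#' @param thresholds Numeric vector of thresholds in (0, 1).
#' @param n_boot Number of bootstrap resamples (>= 2; default 10^4).
#' @param level Interval coverage level (default 0.95).
#' @param seed Optional integer seed.
#' @return Data frame with columns `z`, `inb`, `lower`, `upper`.
#' @export
incremental_nb_ci <- function(sample, thresholds, n_boot = 1e4,
                              level = 0.95, seed = NULL) {
  sample <- as_validation_sample(sample)
  if (length(thresholds) == 0L) stop("no thresholds supplied", call. = FALSE)
  if (!is.numeric(n_boot) || n_boot < 2) stop("`n_boot` must be >= 2",
                                              call. = FALSE)
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  thrs <- lapply(thresholds, as_risk_threshold)
  n <- nrow(sample)
  n_boot <- as.integer(n_boot)

  inb_of <- function(y, pos_mat, omega) {
    # pos_mat: n x n_z logical matrix of risk >= z
    vapply(seq_along(omega), function(k) {
      pos <- pos_mat[, k]
      ntp <- sum(y & pos); nfn <- sum(y & !pos)
      ntn <- sum(!y & !pos); nfp <- sum(!y & pos)
      nb_model <- (ntp - omega[k] * nfp) / n
      nb_all <- ((ntp + nfn) - omega[k] * (ntn + nfp)) / n
      nb_model - max(0, nb_all)
    }, numeric(1))
  }

  omega <- vapply(thrs, `[[`, numeric(1), "omega")
  pos_mat <- vapply(thrs, function(t) sample$risk >= t$z, logical(n))
  pos_mat <- matrix(pos_mat, nrow = n)
  y <- sample$outcome == 1L
  point <- inb_of(y, pos_mat, omega)

  boot <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, length(omega))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      out[b, ] <- inb_of(y[idx], pos_mat[idx, , drop = FALSE], omega)
    }
    out
  })
  alpha <- (1 - level) / 2
  data.frame(
    z = vapply(thrs, `[[`, numeric(1), "z"),
    inb = point,
    lower = apply(boot, 2L, quantile, probs = alpha, names = FALSE),
    upper = apply(boot, 2L, quantile, probs = 1 - alpha, names = FALSE)
  )
}
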