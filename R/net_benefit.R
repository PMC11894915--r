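#' Risk threshold and its implied exchange rate
#'
#' The risk threshold `z` is the predicted-risk cutoff at or above which
#' treatment is given. A decision maker who is ambivalent about treating a
#' patient whose risk is exactly `z` implicitly values one true positive the
#' same as `(1 - z) / z` false positives; the exchange rate
#' `omega = z / (1 - z)` is therefore derived from `z` and never set directly.
#'
#' @param z Risk threshold, a single number strictly inside (0, 1).
#' @return An object of class `risk_threshold` with elements `z` and `omega`.
#' @examples
#' thr <- risk_threshold(0.02)
#' thr$omega # 0.02/0.98
#' @export
risk_threshold <- function(z) {
  if (!is.numeric(z) || length(z) != 1L || is.na(z) || z <= 0 || z >= 1) {
    stop("`z` must be a single number strictly inside (0, 1), got: ",
         deparse(z), call. = FALSE)
  }
  structure(list(z = as.numeric(z), omega = z / (1 - z)),
            class = "risk_threshold")
}

#' @export
print.risk_threshold <- function(x, ...) {
  cat(sprintf("Risk threshold z = %g (exchange rate omega = %.6g)\n",
              x$z, x$omega))
  invisible(x)
}

as_risk_threshold <- function(thr) {
  if (inherits(thr, "risk_threshold")) thr else risk_threshold(thr)
}

#' Triplet of prevalence, sensitivity and specificity
#'
#' The parameter of the net-benefit calculation at a fixed threshold: outcome
#' prevalence in the target population together with the model's sensitivity
#' and specificity there. Implies true/false-positive probabilities
#' `p_tp = prevalence * sensitivity` and
#' `p_fp = (1 - prevalence) * (1 - specificity)`.
#'
#' @param prevalence,sensitivity,specificity Probabilities in \[0, 1\].
#' @return An object of class `theta_triplet`.
#' @export
theta_triplet <- function(prevalence, sensitivity, specificity) {
  x <- c(prevalence = prevalence, sensitivity = sensitivity,
         specificity = specificity)
  if (!is.numeric(x) || length(x) != 3L || anyNA(x) || any(x < 0 | x > 1)) {
    stop("prevalence, sensitivity and specificity must each be a single ",
         "probability in [0, 1]", call. = FALSE)
  }
  structure(as.list(x), class = "theta_triplet")
}

#' @export
print.theta_triplet <- function(x, ...) {
  cat(sprintf("theta: prevalence %.4g, sensitivity %.4g, specificity %.4g\n",
              x$prevalence, x$sensitivity, x$specificity))
  invisible(x)
}

#' Confusion counts of a binary validation sample at a threshold
#'
#' @param n_tp,n_fn,n_tn,n_fp Non-negative counts of true positives, false
#'   negatives, true negatives and false positives.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(n_tp, n_fn, n_tn, n_fp) {
  x <- c(n_tp = n_tp, n_fn = n_fn, n_tn = n_tn, n_fp = n_fp)
  if (!is.numeric(x) || length(x) != 4L || anyNA(x) || any(x < 0) ||
      any(x != round(x))) {
    stop("confusion counts must be four non-negative integers", call. = FALSE)
  }
  structure(as.list(x), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("counts: TP %d, FN %d, TN %d, FP %d (n = %d)\n",
              x$n_tp, x$n_fn, x$n_tn, x$n_fp,
              x$n_tp + x$n_fn + x$n_tn + x$n_fp))
  invisible(x)
}

total_counts <- function(counts) {
  counts$n_tp + counts$n_fn + counts$n_tn + counts$n_fp
}

#' Plug-in theta from confusion counts
#'
#' Empirical prevalence, sensitivity and specificity. Requires at least one
#' event and one non-event; with a zero denominator the plug-in sensitivity or
#' specificity is undefined and this (frequentist) path refuses it — the
#' Bayesian algorithms handle such samples through their priors.
#'
#' @param counts A [confusion_counts()] object.
#' @return A [theta_triplet()].
#' @export
theta_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- total_counts(counts)
  if (n == 0) stop("cannot form plug-in estimates from zero counts",
                   call. = FALSE)
  n_event <- counts$n_tp + counts$n_fn
  n_nonev <- counts$n_tn + counts$n_fp
  if (n_event == 0 || n_nonev == 0) {
    stop("plug-in sensitivity/specificity undefined: sample has ",
         if (n_event == 0) "no events" else "no non-events",
         "; use the Bayesian algorithms with a proper prior", call. = FALSE)
  }
  theta_triplet(n_event / n, counts$n_tp / n_event, counts$n_tn / n_nonev)
}

# Vectorised NB kernels used by every algorithm. NB is in net true-positive
# units; omega converts false positives to that scale.
nb_model_vec <- function(prev, sens, spec, omega) {
  prev * sens - (1 - prev) * (1 - spec) * omega
}
nb_all_vec <- function(prev, omega) {
  prev - (1 - prev) * omega
}

#' Net benefit of a classification strategy
#'
#' Net benefit (NB) in net true-positive units of one of the three strategies
#' at risk threshold `z`: treating no one (strategy 0, NB = 0 by definition),
#' treating according to the model (strategy 1,
#' `prev * sens - (1 - prev) * (1 - spec) * omega`), or treating everyone
#' (strategy 2, `prev - (1 - prev) * omega`), where `omega = z / (1 - z)`.
#'
#' @param strategy Strategy index: 0 (treat none), 1 (use model), 2 (treat all).
#' @param theta A [theta_triplet()].
#' @param threshold A [risk_threshold()] or a bare `z` value.
#' @return A single NB value (may be negative).
#' @examples
#' net_benefit(1, theta_triplet(0.10, 0.80, 0.90), risk_threshold(0.10))
#' @export
net_benefit <- function(strategy, theta, threshold) {
  thr <- as_risk_threshold(threshold)
  stopifnot(inherits(theta, "theta_triplet"))
  if (!is.numeric(strategy) || length(strategy) != 1L ||
      !strategy %in% c(0, 1, 2)) {
    stop("`strategy` must be 0 (treat none), 1 (use model) or 2 (treat all)",
         call. = FALSE)
  }
  switch(as.character(strategy),
    "0" = 0,
    "1" = nb_model_vec(theta$prevalence, theta$sensitivity,
                       theta$specificity, thr$omega),
    "2" = nb_all_vec(theta$prevalence, thr$omega))
}

strategy_labels <- c("treat none", "use model", "treat all")

# argmax over strategies with the lowest index winning ties (the less
# interventionist default); which.max already returns the first maximum.
argmax_strategy <- function(nb0, nb1, nb2) {
  which.max(c(nb0, nb1, nb2)) - 1L
}

#' Best strategy under current information (plug-in)
#'
#' Evaluates the three strategy NBs at a point estimate of theta — either a
#' [theta_triplet()] directly or the plug-in from [confusion_counts()] — and
#' returns the maximising strategy. Because NB is linear in the elements of
#' theta, the plug-in at posterior means equals the posterior-mean NB, so this
#' is also the expected NB under current information for conjugate posteriors.
#' Ties go to the lowest strategy index.
#'
#' @param x A [theta_triplet()] or [confusion_counts()].
#' @param threshold A [risk_threshold()] or bare `z`.
#' @return A list with `strategy` (0/1/2), `label`, `enb`, and the three
#'   per-strategy NBs `nb`.
#' @export
enb_current_plugin <- function(x, threshold) {
  thr <- as_risk_threshold(threshold)
  theta <- if (inherits(x, "confusion_counts")) theta_from_counts(x) else x
  stopifnot(inherits(theta, "theta_triplet"))
  nb <- c(net_benefit(0, theta, thr), net_benefit(1, theta, thr),
          net_benefit(2, theta, thr))
  i <- argmax_strategy(nb[1], nb[2], nb[3])
  list(strategy = i, label = strategy_labels[i + 1L], enb = nb[i + 1L],
       nb = stats::setNames(nb, c("none", "model", "all")))
}

#' Scale a per-decision value-of-information estimate to a population
#'
#' EVPI and EVSI are per-decision quantities; multiplying by the number of
#' decision instances per period (e.g., annual disease events in the target
#' population) expresses them as net true positives gained per period, or —
#' dividing by the exchange rate — as false positives averted per period.
#'
#' @param per_decision_voi Non-negative per-decision EVPI or EVSI in net
#'   true-positive units.
#' @param threshold A [risk_threshold()] or bare `z`.
#' @param decisions_per_period Number of decision instances per period.
#' @param unit `"true_positive"` (default) or `"false_positive"`.
#' @return Population value per period in the requested unit.
#' @examples
#' scale_to_population(0.00101, 0.02, 8e5) # ~808 TP/yr
#' scale_to_population(0.00101, 0.02, 8e5, "false_positive")
#' @export
scale_to_population <- function(per_decision_voi, threshold,
                                decisions_per_period,
                                unit = c("true_positive", "false_positive")) {
  thr <- as_risk_threshold(threshold)
  unit <- match.arg(unit)
  stopifnot(is.numeric(per_decision_voi), length(per_decision_voi) == 1L,
            per_decision_voi >= 0,
            is.numeric(decisions_per_period), decisions_per_period >= 0)
  v <- per_decision_voi * decisions_per_period
  if (unit == "false_positive") v <- v * (1 - thr$z) / thr$z
  v
}

#' Decision curve of a validation sample
#'
#' Plug-in net benefit of the three strategies across a grid of thresholds,
#' from the empirical confusion counts of the sample at each threshold
#' (predicted risk >= z classified positive).
#'
#' @param sample A [validation_sample()].
#' @param thresholds Numeric vector of thresholds strictly inside (0, 1).
#' @return A data frame of class `nb_decision_curve` with columns `z`,
#'   `nb_none`, `nb_model`, `nb_all`.
#' @seealso [incremental_nb_ci()] for percentile-bootstrap intervals around
#'   the model-vs-best-default difference.
#' @export
decision_curve <- function(sample, thresholds) {
  sample <- as_validation_sample(sample)
  if (nrow(sample) == 0L) stop("sample is empty", call. = FALSE)
  if (length(thresholds) == 0L) stop("no thresholds supplied", call. = FALSE)
  thrs <- lapply(thresholds, as_risk_threshold)
  n <- nrow(sample)
  rows <- lapply(thrs, function(thr) {
    cc <- counts_at_threshold(sample$risk, sample$outcome, thr$z)
    # counts-based NB: valid even when a margin is empty (no 0/0)
    data.frame(
      z = thr$z,
      nb_none = 0,
      nb_model = (cc["n_tp"] - thr$omega * cc["n_fp"]) / n,
      nb_all = ((cc["n_tp"] + cc["n_fn"]) -
                  thr$omega * (cc["n_tn"] + cc["n_fp"])) / n,
      row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("nb_decision_curve", "data.frame")
  attr(out, "n") <- n
  out
}

# confusion counts of risk/outcome vectors at z; risk == z counts positive
counts_at_threshold <- function(risk, outcome, z) {
  pos <- risk >= z
  c(n_tp = sum(outcome == 1L & pos),
    n_fn = sum(outcome == 1L & !pos),
    n_tn = sum(outcome == 0L & !pos),
    n_fp = sum(outcome == 0L & pos))
}

#' @export
plot.nb_decision_curve <- function(x, ...) {
  df <- data.frame(
    z = rep(x$z, 3L),
    nb = c(x$nb_none, x$nb_model, x$nb_all),
    strategy = rep(c("treat none", "use model", "treat all"),
                   each = nrow(x))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$nb,
                                   colour = .data$strategy,
                                   linetype = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "risk threshold z", y = "net benefit (TP units)",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
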