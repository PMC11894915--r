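# Shared result container and Monte Carlo plumbing for the three algorithms.

new_voi_result <- function(algorithm, threshold, n_sim, seed,
                           enb_current, enb_truth, evpi, mcse_evpi,
                           best_strategy,
                           enb_sample = NA_real_, evsi = NA_real_,
                           mcse_evsi = NA_real_, n_future = NA_real_,
                           extra = list()) {
  out <- c(list(
    algorithm = algorithm,
    z = threshold$z,
    n_future = as.integer(n_future),
    enb_current = enb_current,
    enb_truth = enb_truth,
    enb_sample = enb_sample,
    evpi = evpi,
    evsi = evsi,
    mcse_evpi = mcse_evpi,
    mcse_evsi = mcse_evsi,
    best_strategy = as.integer(best_strategy),
    n_sim = as.integer(n_sim),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), extra)
  structure(out, class = "voi_result")
}

#' @export
print.voi_result <- function(x, ...) {
  cat(sprintf("Value-of-information result (%s algorithm)\n", x$algorithm))
  cat(sprintf("  threshold z = %g, simulations = %g, seed = %s\n",
              x$z, x$n_sim, ifelse(is.null(x$seed), "none", x$seed)))
  cat(sprintf("  ENB current  = %.6g (best strategy: %s)\n",
              x$enb_current, strategy_labels[x$best_strategy + 1L]))
  cat(sprintf("  ENB truth    = %.6g\n", x$enb_truth))
  cat(sprintf("  EVPI         = %.6g (MCSE %.2g)\n", x$evpi, x$mcse_evpi))
  if (!is.na(x$evsi)) {
    cat(sprintf("  ENB sample   = %.6g (future N = %g)\n",
                x$enb_sample, x$n_future))
    cat(sprintf("  EVSI         = %.6g (MCSE %.2g)\n", x$evsi, x$mcse_evsi))
  }
  invisible(x)
}

# Batch-means Monte Carlo standard error of mean(x). The VoI estimators are
# means of per-draw paired differences (value term minus the contribution of
# the currently-best strategy), so the MCSE is taken on that difference.
mcse_batch_means <- function(x, n_batch = 100L) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  n_batch <- min(n_batch, n)
  size <- n %/% n_batch
  use <- size * n_batch
  bm <- colMeans(matrix(x[seq_len(use)], nrow = size))
  stats::sd(bm) / sqrt(n_batch)
}

# Set the RNG locally: restores the caller's .Random.seed on exit. A NULL
# seed leaves the global stream untouched (still consumed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
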