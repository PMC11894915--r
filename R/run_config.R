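# Configuration-driven runs: one entry point behind the command-line script,
# reading YAML/JSON configs and writing CSV + JSON result tables.

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The configuration as a named list (validated lazily by
#'   [run_voi()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("config must be .yaml, .yml or .json, got .", ext, call. = FALSE))
  if (!is.list(cfg)) stop("config did not parse to a list", call. = FALSE)
  cfg
}

validate_config <- function(cfg) {
  req <- function(field) {
    if (is.null(cfg[[field]])) {
      stop("config field `", field, "` is required", call. = FALSE)
    }
    cfg[[field]]
  }
  algorithm <- match.arg(req("algorithm"),
                         c("beta_binomial", "bootstrap", "general"))
  thresholds <- req("thresholds")
  if (!is.numeric(thresholds) || !length(thresholds) ||
      any(thresholds <= 0 | thresholds >= 1)) {
    stop("config `thresholds` must be probabilities strictly inside (0, 1)",
         call. = FALSE)
  }
  n_grid <- req("n_grid")
  if (!is.numeric(n_grid) || !length(n_grid) || any(n_grid < 0)) {
    stop("config `n_grid` must be non-negative sample sizes", call. = FALSE)
  }
  # algorithm-specific inputs, checked before any computation
  if (algorithm == "beta_binomial") {
    if (is.null(cfg$counts) && is.null(cfg$posterior)) {
      stop("beta_binomial config needs `counts` (n_tp, n_fn, n_tn, n_fp) ",
           "or `posterior` (prev/sens/spec shape pairs)", call. = FALSE)
    }
  } else if (is.null(cfg$input)) {
    stop(algorithm, " config needs `input`: a CSV path", call. = FALSE)
  }
  cfg$algorithm <- algorithm
  cfg
}

config_posterior <- function(cfg) {
  if (!is.null(cfg$posterior)) {
    p <- cfg$posterior
    beta_posterior(unlist(p$prev), unlist(p$sens), unlist(p$spec))
  } else {
    cc <- cfg$counts
    prior <- if (is.null(cfg$prior)) flat_beta_prior() else {
      beta_posterior(unlist(cfg$prior$prev), unlist(cfg$prior$sens),
                     unlist(cfg$prior$spec))
    }
    posterior_from_counts(
      confusion_counts(cc$n_tp, cc$n_fn, cc$n_tn, cc$n_fp), prior)
  }
}

#' Run a value-of-information analysis from a configuration
#'
#' Executes one of the three algorithms over a grid of thresholds and future
#' sample sizes and (optionally) writes a CSV results table and a JSON file
#' mirroring the full `voi_result` objects. Stored results are per-decision
#' NB units; population scaling, when a `population` block is present, is
#' applied as extra reporting columns only.
#'
#' Config fields: `algorithm` (`beta_binomial`, `bootstrap` or `general`);
#' `thresholds`; `n_grid`; `seed`; `n_sim` (beta_binomial/bootstrap) or
#' `n_outer` (general); `counts` + optional `prior`, or `posterior`
#' (beta_binomial); `input` CSV path (bootstrap: validation sample; general:
#' posterior draws); `scheme` (bootstrap); `population:
#' {decisions_per_period}`; `output: {dir, prefix}`.
#'
#' @param config A named list or a path to a YAML/JSON file
#'   ([read_run_config()]).
#' @param quiet Suppress the per-run log line.
#' @return Invisibly, a list with `table` (data frame) and `results` (list of
#'   `voi_result`).
#' @export
run_voi <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_config(config)
  seed <- cfg$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)

  fit_one <- switch(cfg$algorithm,
    beta_binomial = {
      post <- config_posterior(cfg)
      n_sim <- if (is.null(cfg$n_sim)) 1e6 else cfg$n_sim
      function(z, N) evsi_beta_binomial(post, z, N, n_sim = n_sim,
                                        seed = seed)
    },
    bootstrap = {
      sample <- read_validation_sample(cfg$input)
      n_sim <- if (is.null(cfg$n_sim)) 1e4 else cfg$n_sim
      scheme <- if (is.null(cfg$scheme)) "bayesian" else cfg$scheme
      function(z, N) voi_bootstrap(sample, z, N, n_sim = n_sim,
                                   scheme = scheme, seed = seed)
    },
    general = {
      draws <- read_posterior_draws(cfg$input)
      function(z, N) evsi_general(draws, z, N, n_outer = cfg$n_outer,
                                  seed = seed)
    })

  t0 <- Sys.time()
  grid <- expand.grid(z = cfg$thresholds, n_future = cfg$n_grid,
                      KEEP.OUT.ATTRS = FALSE)
  results <- lapply(seq_len(nrow(grid)),
                    function(k) fit_one(grid$z[k], grid$n_future[k]))

  tab <- do.call(rbind, lapply(results, function(r) {
    row <- data.frame(algorithm = r$algorithm, z = r$z,
                      n_future = r$n_future,
                      enb_current = r$enb_current,
                      evpi = r$evpi, mcse_evpi = r$mcse_evpi,
                      evsi = r$evsi, mcse_evsi = r$mcse_evsi)
    if (!is.null(cfg$population)) {
      k <- cfg$population$decisions_per_period
      row$pop_evpi_tp <- scale_to_population(max(0, r$evpi), r$z, k)
      row$pop_evpi_fp <- scale_to_population(max(0, r$evpi), r$z, k,
                                             "false_positive")
      row$pop_evsi_tp <- scale_to_population(max(0, r$evsi), r$z, k)
      row$pop_evsi_fp <- scale_to_population(max(0, r$evsi), r$z, k,
                                             "false_positive")
    }
    row
  }))

  if (!quiet) {
    message(sprintf(
      "nbvoi run: algorithm=%s seed=%d rows=%d elapsed=%.1fs",
      cfg$algorithm, seed, nrow(tab),
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  if (!is.null(cfg$output)) {
    dir <- if (is.null(cfg$output$dir)) "." else cfg$output$dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    prefix <- if (is.null(cfg$output$prefix)) "nbvoi" else cfg$output$prefix
    utils::write.csv(tab, file.path(dir, paste0(prefix, "_results.csv")),
                     row.names = FALSE)
    write_voi_json(results, file.path(dir, paste0(prefix, "_results.json")))
  }

  invisible(list(table = tab, results = results))
}

#' Write / read `voi_result` objects as JSON
#'
#' Full-precision round trip: numbers are written unrounded so a re-read
#' reproduces every field exactly.
#'
#' @param results A `voi_result` or list of them.
#' @param path Output path.
#' @return [write_voi_json()] returns `path` invisibly; [read_voi_json()]
#'   returns a list of `voi_result` objects.
#' @export
write_voi_json <- function(results, path) {
  if (inherits(results, "voi_result")) results <- list(results)
  payload <- lapply(results, unclass)
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_voi_json
#' @export
read_voi_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(payload, function(x) {
    x[sapply(x, is.null)] <- NA
    structure(x, class = "voi_result")
  })
}
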