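# nbvoi

Value-of-information analysis for external validation of clinical risk
prediction models.

## What problem this solves

Before a risk prediction model is adopted in a new population, its clinical
utility there — its **net benefit** (NB) relative to treating no one or
treating everyone at a risk threshold `z` — must be estimated from a
validation sample, and any finite sample leaves that estimate uncertain.
Conventional practice sizes validation studies with confidence-interval
arguments that do not translate into better decisions. `nbvoi` instead
quantifies, in clinical-utility units, what a validation study of a given
size is *worth*:

- **EVPI** — the expected gain in NB from completely resolving uncertainty
  about the population's outcome prevalence and the model's sensitivity and
  specificity, `θ = (θ_p, θ_se, θ_sp)`; the ceiling on any study's value.
- **EVSI(N)** — the expected gain in NB from observing a future validation
  sample of N subjects before deciding which strategy to use.

Both derive from the three-strategy net benefit at threshold `z`
(exchange rate `ω = z/(1−z)`):

```
NB(treat none)  = 0
NB(use model)   = θ_p·θ_se − (1−θ_p)(1−θ_sp)·ω
NB(treat all)   = θ_p − (1−θ_p)·ω
```

with `EVPI = E[max_i NB(i,θ)] − max_i E[NB(i,θ)]` and
`EVSI = E_D[max_i E[NB(i,θ)|D]] − max_i E[NB(i,θ)]`, expectations over the
posterior `P(θ|d)` given current information `d`. Per-decision values scale
to a population by the number of decision instances per period
(true-positive units, or false-positive units via the factor `(1−z)/z`).

It is intended for biostatisticians and prediction-model researchers
planning or arguing for external validation studies.

## Three algorithms

| function | current information | approach |
|---|---|---|
| `voi_bootstrap()` | individual-level pilot sample | two-level Bayesian (Dirichlet-weight) or ordinary bootstrap |
| `evpi_beta_binomial()`, `evsi_beta_binomial()`, `evsi_curve()` | independent beta posteriors on θ | conjugate beta-binomial Monte Carlo (fastest) |
| `evsi_general()` | arbitrary posterior draws (e.g. MCMC) | binomial-likelihood reweighting of the draws |

Supporting tools: `decision_curve()`, `incremental_nb_ci()` (percentile
bootstrap), `scale_to_population()`, `posterior_from_counts()`,
`generate_sample()` (synthetic validation samples), `gusto_like_fixture()`
(a packaged 500-record case-study-like sample), `run_voi()` +
`inst/cli/nbvoi.R` (config-driven runs from the shell).

## Worked example

Current information: a 500-subject pilot validation sample with 43 events;
at `z = 0.02` the confusion counts are TP 41, FN 2, TN 147, FP 310. With
flat Beta(1, 1) priors:

```r
library(nbvoi)
post <- posterior_from_counts(counts_from_sample(gusto_like_fixture(), 0.02))
post
#> prevalence ~ Beta(44, 458), sensitivity ~ Beta(42, 3), specificity ~ Beta(148, 311)

evsi_beta_binomial(post, 0.02, n_future = 1000, n_sim = 1e6, seed = 11)
#> Value-of-information result (beta_binomial algorithm)
#>   threshold z = 0.02, simulations = 1e+06, seed = 11
#>   ENB current  = 0.0691933 (best strategy: use model)
#>   ENB truth    = 0.0704515
#>   EVPI         = 0.00125826 (MCSE 2.3e-06)
#>   ENB sample   = 0.0702053 (future N = 1000)
#>   EVSI         = 0.00101206 (MCSE 2.5e-06)
```

Reading: using the model is already the best bet (ENB 0.0692 net true
positives per decision), but uncertainty about θ costs 0.00126 per decision
in expectation (EVPI); a 1,000-subject validation study would recover
0.00101 of that (EVSI). Scaled by, say, 800,000 annual events:

```r
r <- evsi_beta_binomial(post, 0.02, n_future = 1000, n_sim = 1e6, seed = 11)
scale_to_population(r$evsi, 0.02, 8e5)                    # ~810 TP gained/yr
scale_to_population(r$evsi, 0.02, 8e5, "false_positive")  # ~39,700 FP averted/yr
```

`evsi_curve(post, 0.02, c(250, 1000, 4000, 16000))` traces the diminishing
returns toward the EVPI asymptote (little is gained beyond N ≈ 4,000 here);
`plot()` methods draw the decision and EVSI curves.

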