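---
title: "Value of information for external validation of risk prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value of information for external validation of risk prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbvoi)
```

## The decision problem

A risk prediction model maps patient characteristics to a probability of a
binary clinical event. Before the model is used in a new target population, a
decision maker must choose among three strategies at a risk threshold $z$:
treat no one, treat those the model flags (predicted risk $\ge z$), or treat
everyone. The clinical utility of a strategy is its net benefit (NB), in net
true-positive units:

$$\mathrm{NB} = p_{tp} - \omega \, p_{fp}, \qquad \omega = \frac{z}{1-z},$$

where $p_{tp}$ and $p_{fp}$ are the probabilities of a true- and
false-positive classification and $\omega$ is the exchange rate implied by
the threshold (treating a patient with risk exactly $z$ is utility-neutral).
Writing $\theta = (\theta_p, \theta_{se}, \theta_{sp})$ for prevalence,
sensitivity and specificity, $p_{tp} = \theta_p\theta_{se}$ and
$p_{fp} = (1-\theta_p)(1-\theta_{sp})$, so the three strategies have

$$\mathrm{NB}(0,\theta) = 0,\qquad
\mathrm{NB}(1,\theta) = \theta_p\theta_{se} -
  (1-\theta_p)(1-\theta_{sp})\,\omega,\qquad
\mathrm{NB}(2,\theta) = \theta_p - (1-\theta_p)\,\omega.$$

With finite validation data $\theta$ is uncertain, described by a posterior
$P(\theta \mid d)$. The decision maker's best achievable expected NB today is
$\mathrm{ENB}_{\mathrm{current}} = \max_i E_{\theta\mid d}\,
\mathrm{NB}(i,\theta)$. Two value-of-information quantities measure what
further data are worth, both per decision instance:

* **EVPI** $= E_{\theta\mid d}[\max_i \mathrm{NB}(i,\theta)] -
  \mathrm{ENB}_{\mathrm{current}}$ — the gain from resolving uncertainty
  completely; an upper bound for any study.
* **EVSI**($N$) $= E_{D\mid d}[\max_i E_{\theta\mid d,D}\,
  \mathrm{NB}(i,\theta)] - \mathrm{ENB}_{\mathrm{current}}$ — the gain from
  first observing a future validation sample $D$ of size $N$ and then
  deciding.

Multiplying either by the number of decision instances per period (e.g.
annual disease events in the target population) gives a population value in
true positives gained per period, or, dividing by $\omega$, in false
positives averted (`scale_to_population()`); the FP/TP ratio is
$(1-z)/z$ exactly.

## The three computation algorithms

The obstacle in EVSI is the nested expectation: an inner posterior update for
every realisation of the future data. The package implements three Monte
Carlo routes, all sharing the same NB kernel.

**Two-level bootstrap** (`voi_bootstrap()`), for individual-level pilot data.
Each iteration draws a population from the posterior of the data-generating
distribution — Dirichlet$(1,\dots,1)$ weights on the observed records (the
Bayesian bootstrap, realised as $n$ exponential(1) draws scaled to sum to 1)
or an ordinary bootstrap — and treats the weighted prevalence/sensitivity/
specificity as that iteration's truth. The future study is drawn with
replacement from the weighted population, pooled with the original records at
unit weight, and the strategy maximising the pooled plug-in NB is credited
with its NB at the truth. Because NB at a fixed threshold depends on a record
only through its confusion cell, the future draw is realised as a single
multinomial over the four cells with the weighted cell masses as
probabilities — distributionally identical to resampling records one by one,
at far lower cost. Degenerate weight draws (zero event mass) need no special
casing: the weighted NB is computed in mass form
($\theta_p\theta_{se}$ = true-positive mass), which stays well defined.

**Conjugate beta-binomial** (`evpi_beta_binomial()`,
`evsi_beta_binomial()`), when current information is three independent beta
distributions. Per draw, a truth $\theta^*$ is sampled; the future confusion
table is generated hierarchically (events $\sim$ Binomial($N, \theta_p^*$),
true positives $\sim$ Binomial(events, $\theta_{se}^*$), true negatives
$\sim$ Binomial(non-events, $\theta_{sp}^*$)); the conjugate posterior-mean
update gives the revised $\theta^+$, and the strategy maximising NB at
$\theta^+$ is credited at $\theta^*$. For binary outcomes without missing
data the Bayesian bootstrap is exactly this model with the improper
Beta$(0,0)$ limit — the count-based posterior
Dirichlet$(n_{tp}, n_{fn}, n_{tn}, n_{fp})$ — which the test suite uses as
the package's central cross-validation: both routes must agree within Monte
Carlo error on the same sample.

**General likelihood reweighting** (`evsi_general()`), for an arbitrary
Monte Carlo sample from $P(\theta\mid d)$ (e.g. MCMC output of a
meta-analysis). Current information is the empirical distribution of the $M$
draws. Each outer iteration takes one draw as the truth, simulates a future
table from it, and reweights *all* draws by the binomial likelihood of that
table, since $P(\theta\mid d, D) \propto P(\theta\mid d)\,P(D\mid\theta)$;
the strategy maximising the weighted-mean NB is credited at the truth.
Weights are computed entirely in log space with log-sum-exp normalisation
(zero-trial binomial factors contribute probability one); iterations whose
table has numerically zero likelihood under every draw are dropped and
counted, and the run aborts if more than 1% degenerate. The per-iteration
effective sample size $1/\sum_k w_k^2$ is summarised (`ess_min`,
`ess_median`) because weight degeneracy — not the outer loop — is the
algorithm's practical failure mode when $M$ is small: with $M = 100$ the
run-to-run coefficient of variation of EVSI is an order of magnitude larger
than with $M = 10^4$ (the test suite demonstrates exactly this).

## Numerical and design choices

* **ENB under current information** is the maximum of the *bootstrap- or
  draw-averaged* per-strategy NBs, not the plug-in at point estimates. The
  same draws then serve the truth and sample terms, so the VoI estimate is a
  mean of positively correlated paired differences: tighter, and never
  negative for EVPI (within a run, EVSI $\le$ EVPI holds exactly because the
  credited NB can never exceed the per-draw maximum).
* **Monte Carlo standard errors** are batch means (100 batches) of the
  paired difference between the value term and the per-draw NB of the
  currently-best strategy, matching the difference structure of the
  estimators.
* **Ties** in every argmax over strategies go to the lowest index — the less
  interventionist default — making runs reproducible.
* **$N = 0$** short-circuits to EVSI exactly 0 in all three algorithms: an
  empty study cannot change the argmax. (Without the short-circuit the
  estimate could be a hair negative when the plug-in argmax at posterior
  means disagrees with the in-sample argmax of averaged NBs.)
* **Thresholds** are validated at construction: $z$ must lie strictly inside
  $(0,1)$, and a predicted risk exactly equal to $z$ is classified positive.
* **Common random numbers**: `evsi_curve()` reuses one seed across the $N$
  grid, so the truth draws are shared and the estimated curve is monotone up
  to residual noise; a duplicated $N$ gives bit-identical estimates.
* **Outer loop of the general algorithm**: exhaustive over the $M$ draws up
  to a cap (default $10^4$), random truths above it, with the iteration
  count configurable — cost grows as $n_{\mathrm{outer}} \times M$
  likelihood evaluations.
* **Default simulation sizes**: $10^6$ draws for the conjugate algorithm
  (sub-second; MCSE near $2\times10^{-6}$ on the case study), $10^4$
  bootstrap iterations by default with $10^5$ recommended for production.
  The vignette and test suite use smaller sizes where a property, not a
  headline number, is being checked.

## The synthetic generator and the packaged fixture

`generate_sample()` emulates a single-centre external validation sample:
predicted risks are logit-normal (right-skewed, realistic at low prevalence;
defaults give a prevalence near 0.09, comparable to short-term mortality
after myocardial infarction), and outcomes are Bernoulli with event
probability linked to the predicted risk through a calibration intercept and
slope on the logit scale. It does *not* emulate miscalibration drift across
subgroups, clustering, missing data, or measurement error — properties real
validation samples may have; passing tests therefore demonstrate correctness
of the VoI computations under clean sampling uncertainty, not robustness to
those complications.

`gusto_like_fixture()` is a fixed 500-record sample whose classification
margins at $z = 0.02$ reproduce a published external-validation pilot for
30-day mortality after myocardial infarction: 43 events; confusion counts
(TP 41, FN 2, TN 147, FP 310); with flat priors the conjugate posteriors are
Beta(44, 458), Beta(42, 3), Beta(148, 311). Individual risk values are
synthetic constants (one false-positive risk sits exactly on the threshold
to pin the $\ge z$ convention); only the margins are contractual.

```{r case-study}
post <- posterior_from_counts(counts_from_sample(gusto_like_fixture(), 0.02))
post
evsi_beta_binomial(post, 0.02, n_future = 1000, n_sim = 1e5, seed = 1)
```

At production size ($10^6$ draws) the per-decision EVPI at $z=0.02$ is about
0.00125 and the EVSI of a 1,000-subject study about 0.00101; scaled by
800,000 annual decisions these are roughly 1,000 true positives (49,000
false positives averted) and 810 true positives (39,700 false positives)
per year — diminishing returns set in beyond $N \approx 4{,}000$, where EVSI
approaches the EVPI ceiling.

## Limitations

* Binary outcomes only: no time-to-event NB, no treatment-benefit models.
* The three components of $\theta$ are tied to a single threshold; curves
  across thresholds re-run the algorithms per threshold with
  threshold-specific counts.
* The bootstrap offers no missing-data imputation; the general algorithm
  contains no MCMC — posterior draws are produced elsewhere.
* VoI is computed under sampling uncertainty in a single homogeneous target
  population; transportability discounts and multicentre heterogeneity are
  out of scope.
* No monetary conversion or optimal-sample-size decision rule is provided:
  outputs are in net true-positive (or false-positive) units for the user
  to weigh against study cost.
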