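---
title: "Modelling response inhibition under DRL schedules with a timing mixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling response inhibition under DRL schedules with a timing mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drlmix)
```

## The behavioral problem

Under a differential-reinforcement-of-low-rates (DRL) schedule an animal is
reinforced only when it withholds responding long enough: a response earns a
reward only if the inter-response time (IRT) since the previous response
strictly exceeds the criterion (15 s for DRL15). The efficiency of
reinforcement, `100 * reinforcers / responses`, is therefore an inverse
index of impulsivity: premature responses reset the clock and earn nothing.
`drlmix` packages the full analysis chain for such experiments — schedule
scoring, a generative IRT model, per-subject mixture fitting, descriptive
statistics and effect sizes — together with a synthetic-cohort generator so
the whole pipeline is testable without animal data.

## The timing mixture

IRTs under DRL are well described as a three-part mixture. With probability
$p$ an IRT is *timed*: gamma-distributed with shape $N$ and scale $c$,
centred near the criterion in trained animals. The non-timed remainder
splits into *bursts* — very short IRTs with a fast exponential decay rate
$L$ — with probability $q(1-p)$, and *long pauses* (task-delinquent
responses) with slow decay $L'$ and probability $(1-q)(1-p)$. All three
components are shifted right by $\delta$, the smallest IRT the animal can
physically emit:

$$
f(t) = p\,\Gamma(t-\delta;\,N,c)
 + q(1-p)\,L e^{-L(t-\delta)}
 + (1-q)(1-p)\,L' e^{-L'(t-\delta)}, \qquad t \ge \delta .
$$

Derived indices summarise response inhibition:

* **Response threshold** $\theta = Nc/\mathrm{criterion}$ — the mean timed
  IRT relative to the criterion; $\theta < 1$ marks premature timing.
* **Proportions** of timed ($p$), burst ($q(1-p)$) and long ($(1-q)(1-p)$)
  responses, summing to one by construction.
* **Weber fraction** $\omega$ — the relative precision of timed intervals.
  The field does not agree on a unique formula; we use the coefficient of
  variation of the gamma timed component, $\omega = 1/\sqrt{N}$, the
  standard scalar-timing choice, and document it as such.

```{r mixture}
pars <- default_tr_params()
pars
tr_cdf(15, pars)            # mass below the DRL15 criterion
response_threshold(6, 2.67) # theta just above 1: timed mean ~16 s
```

## Fitting

`fit_tr_model()` estimates $(p, q, N, c, L, L')$ per subject.

* **Objectives.** Maximum likelihood (`mode = "mle"`) is the default. A
  second objective, `"cdf_lsq"`, minimises the squared deviation between
  the empirical cumulative frequency and the model CDF over the 120
  half-second bin edges; it reproduces the spreadsheet-style fit of binned
  cumulative IRT distributions that is common in this literature, and the
  two agree on component proportions for well-separated mixtures.
* **The shift.** $\delta$ is fixed at `min(irts) - 1 ms` rather than
  estimated jointly: the likelihood is unbounded as $\delta$ approaches the
  sample minimum, so joint estimation is a singularity, while the smallest
  observed IRT is itself the natural estimator of the smallest elicitable
  IRT.
* **Parameterisation and search.** Optimisation runs unconstrained on
  $(\mathrm{logit}\,p, \mathrm{logit}\,q, \log N, \log c, \log L, \log L')$
  with Nelder–Mead, from a data-driven start ($p_0$ = fraction of IRTs
  between half and twice the criterion, gamma moments from that stratum,
  $L_0$ from IRTs under 2 s, $L'_0$ from IRTs beyond twice the criterion,
  with fallbacks for empty strata). Five jittered restarts guard against
  local optima; the best objective wins, a final polish pass tightens it,
  and the whole search is deterministic given its `seed` argument and
  leaves the caller's RNG untouched.
* **Degenerate inputs.** Fewer than 2 IRTs or an all-identical sample is an
  error; fewer than 30 IRTs warns; IRTs at or below $\delta$ (possible
  after rounding) contribute a floor density of $10^{-12}$ so the
  log-likelihood stays finite; non-convergence is reported in the
  `converged` flag, never raised.

```{r fit}
set.seed(1)
irts <- sample_irt(2000, pars)
fit <- fit_tr_model(irts, seed = 1)
fit
```

On samples of 2000 IRTs from the default generator, 20-replicate recovery
runs give median errors of about 0.02 on $\hat p$, under 10% on $\hat L$
and about 1% on $\widehat{Nc}$ (these are recomputed by the test suite and
by `scripts/acceptance.R`; the thresholds asserted there are 0.05, 15% and
10%).

## The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` emulates the design of a chronic-intermittent-ethanol
(CIE) dependence experiment: two groups (CIE vs air-exposed controls, 8
subjects each), a 12-week timeline (week 0 pre-vapor, weeks 1–6 vapor
exposure, weeks 7–11 forced abstinence), 5 daily 30-min DRL15 sessions per
week. Sessions are renewal processes: IRTs are drawn i.i.d. from the
mixture and summed until the session clock runs out. The defaults are the
study conditions, chosen once:

* **Baseline** `p = 0.7, q = 0.6, N = 6, c = 2.67, L = 2, L' = 0.05,
  delta = 0.3 s`. The timed mean is 16.02 s ($\theta \approx 1.07$, just
  above criterion, as in trained rats), and the derived proportions
  (timed 0.70, burst 0.18, long 0.12) bracket the per-group values reported
  for trained animals in this paradigm (timed 0.67–0.78, burst 0.07–0.29).
  The resulting DRL15 efficiency of ~42% is in the range typical of trained
  rats.
* **CIE abstinence phenotype** (`cie_effects()`): at abstinence weeks 9–11
  the burst decay $L$ is halved and the timed mean shifts right by 5%.
  These encode the *direction* of the reported protracted-abstinence
  effect — shallower burst decay and a rightward timed shift, i.e. improved
  response inhibition — with magnitudes that are fixture choices, not
  empirical claims.
* **Heterogeneity.** Subject-level log-normal multipliers (sd 0.1 on the
  log scale) on the timed mean and burst rate add realistic between-animal
  spread without destroying group effects.
* **Reproducibility.** Each subject runs on its own stream derived from
  `(seed, subject index)`, so cohorts are byte-reproducible and robust to
  generation order.

What the generator does **not** emulate: within-session drift (satiation,
warm-up), post-reinforcement pauses, consumption time, session-to-session
learning, and any pharmacokinetics (CIE exists only as a group label plus
the blood-ethanol utilities). IRTs are exchangeable within a session by
construction. Passing tests therefore demonstrate that the estimators and
pipeline recover what the model puts in — not that real rat data satisfy
the renewal or i.i.d. assumptions.

## Schedule engine conventions

Choices the schedule literature leaves open, fixed here:

* The first response of a session is timed from session start (time 0),
  matching the timer-since-last-event behaviour of operant chambers and
  making the empty-history case well defined.
* Reinforcement requires IRT **strictly greater** than the criterion.
* Adjusting DRL multiplies the criterion by 1.0075 after each *reinforced*
  response, saturates exactly at 15 s and carries the reached criterion to
  the next session. Closed form and iteration agree that the 2 s start
  needs 270 reinforced responses to reach 15 s.
* Progressive ratio: the hang limit (15 min) is checked between
  consecutive presses and from session start to the first press; the
  breakpoint is the last completed ratio. The default progression is a
  test scaffold — real experiments should pass their own, which is why it
  is an explicit configuration field.
* Stability is `< 10%` variation in efficiency over 3 consecutive
  sessions, with "variation" read as range over mean; the rule's source
  gives no formula, so the coefficient-of-range is our documented choice.
* IRT bins are half-open `[k/2, (k+1)/2)` seconds; IRTs of 60 s or more go
  to an explicit overflow counter rather than being silently dropped.
* Zero-response sessions have undefined efficiency and propagate as
  missing values, excluded from weekly averages with a warning.

## Statistics

Week-level group comparisons use the effect-size chain
$d = t\sqrt{1/n_1 + 1/n_2}$, $r = d/\sqrt{d^2+4}$; this independent-samples
conversion is the one consistent with published paired values of $t$, $d$
and $r$ in this paradigm ($t(12) = 2.27$ with $n = 7$ per group gives
$d = 1.213$, $r = 0.52$). Cumulative progressive-ratio response records are
compared with an exact two-sample Kolmogorov–Smirnov statistic (supremum
over pooled sample points, ties handled exactly); since group sizes are
small, a seeded permutation p-value is offered instead of the asymptotic
one. Blood-ethanol readings subtract a 3.9 mg/dL instrument noise floor
(clamped at zero) and are checked against the 125–250 mg/dL maintenance
range with inclusive bounds; the mg/dL-to-mM conversion uses the 46.07
g/mol molar mass and is provided for convenience only. Repeated-measures
ANOVA is deliberately out of scope — the pipeline exports tidy per-session,
weekly and binned tables for external statistics software.

## Pipeline and problem sizes

`drl_pipeline()` chains simulate → fit → analyze → report. Every stage
writes plain CSV plus a JSON manifest (config echo, seed, package version —
no timestamps), output directories are versioned rather than overwritten,
and rerunning with the same seed is byte-identical; `fit` pools each
subject's Tuesday–Thursday sessions per week, the default weekly-averaging
convention (Monday and Friday sessions are excluded as weekend- and
blood-draw-adjacent).

The verification runs use deliberately scaled problem sizes: parameter
recovery uses 20 replicates of 2000 IRTs; the directional CIE check fits 50
replicate cohorts of 8 subjects per group, pooling each group's week-11
IRTs into a single fit per group (a pooling choice that tests the same
direction as per-rat fits at a fraction of the cost); the challenge check
simulates 100 subjects; the packaged fixture cohort uses 2 subjects per
group, weeks 0 and 11, and 10-min sessions.

## Known limitations

* The timed and long components overlap (a gamma with mean 16 s against an
  exponential with mean 20 s), so $\hat L'$ and the long proportion are the
  least identified quantities at realistic sample sizes; $p$, $Nc$ and $L$
  are the well-recovered ones.
* $\delta$ fixed at the sample minimum slightly underestimates the true
  shift for small samples (the minimum is a biased estimator of the
  support boundary); at session-pooled sample sizes the effect is
  negligible relative to the 0.5 s bin width.
* The fitter assumes pooled IRTs are exchangeable; if within-session drift
  matters, fit per session and compare.
* `bin_irt_distribution()` percentages are relative to *all* IRTs
  including overflow, so the 120 bins sum to less than 100 when overflow
  occurs — conservation is explicit, not hidden.
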