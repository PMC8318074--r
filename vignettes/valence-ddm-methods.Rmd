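---
title: "Valence-dependent evidence accumulation: models, simulator, and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valence-dependent evidence accumulation: models, simulator, and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In the incentivized "factory" task, a participant watches a stream of
televisions and telephones and must judge which of two hidden factory types
they are in. One factory type is *desirable* (visiting it yields net gains)
and the other *undesirable* (net losses); which type is desirable is
assigned randomly per participant. Each item in the stream matches the true
factory type with probability 0.6, the true type is drawn with equal
probability on every trial, and the participant is free to respond whenever
they wish. Because the desirability of the conclusion is independent of the
evidence, any systematic asymmetry in how quickly people reach desirable
versus undesirable conclusions reveals a *valence* effect on evidence
accumulation, not on the stimulus.

Two mechanisms can produce such an asymmetry, and telling them apart is the
core purpose of this package:

* a **starting-point bias**: the accumulator begins closer to one boundary
  (a prior predisposition, before any evidence arrives);
* a **drift-rate bias**: evidence toward one conclusion is accumulated
  faster (a process bias).

## The diffusion model

Judgments and response times are modeled as a two-boundary Wiener
diffusion. Evidence $x(t)$ starts at a relative point $z \in (0,1)$ between
the boundaries $0$ and $\alpha$, drifts at rate $v$ with unit diffusion
coefficient, and the first boundary reached determines the judgment (upper
boundary $=$ desirable-state judgment, a fixed orientation convention
throughout the package) while the passage time plus a non-decision offset
$t_0$ determines the response time.

**The accumulator runs on the natural-log scale of the response time in
milliseconds.** Fitted non-decision times around 7.5 and thresholds around
2.5 are only interpretable under this convention ($\ln 1800 \approx 7.5$):
the likelihood of a trial is the first-passage density evaluated at
$\log(\mathrm{rt_{ms}})$. The scale is a property of the modeled variable,
not a display choice, and every parameter in the package is quoted in these
units. (Seconds-scale fitting would yield the same model with shifted
$t_0$; the millisecond convention was adopted because it matches the
magnitudes of the reference estimates, and it is configurable simply by
transforming the input response times.)

Because empirical error responses can be fast, all model variants include
an across-trial starting-point range $sz$: on each trial the start is drawn
uniformly on $z \pm sz/2$. Across-trial drift variability and non-decision
variability are deliberately excluded — the model family under study does
not contain them.

The drift magnitude on a trial is a linear function of the true state's
desirability $d \in \{0, 1\}$:

$$v = \beta_0 + \beta_1 d,$$

and its sign always points toward the correct boundary ($+v$ on
desirable-state trials, $-v$ on undesirable-state trials). A positive
$\beta_1$ therefore means faster accumulation toward desirable conclusions.
Four nested specifications are compared:

| model | starting point | drift |
|---|---|---|
| 1 | $z = 0.5$ | symmetric $v$ / $-v$ |
| 2 | $0 < z < 1$ free | symmetric $v$ / $-v$ |
| 3 | $z = 0.5$ | $\beta_0 + \beta_1 d$ |
| 4 | $0 < z < 1$ free | $\beta_0 + \beta_1 d$ |

## Numerics of the first-passage density

`wfpt_density()` implements the standard series representation of the
Wiener first-passage density with the usual small-time / large-time switch;
the number of series terms is chosen from a truncation tolerance of
$10^{-7}$. The upper boundary is obtained by reflection
($v \to -v$, $z \to 1 - z$), which makes the reflection symmetry of the
density exact by construction. When $sz > 0$ the density is averaged over
the uniform starting-point range by 11-node Gauss–Legendre quadrature — the
integrand is smooth, so the quadrature is exact to more than 6 digits (the
test suite checks it against both adaptive quadrature and brute-force
Monte-Carlo averaging).

`simulate_first_passage()` is a deliberately independent oracle: an
Euler–Maruyama path simulator with a Brownian-bridge correction for
crossings between grid points, which reduces the boundary-crossing bias
from $O(\sqrt{dt})$ to $O(dt)$. At the default step `dt = 1e-3` the
absorption probabilities agree with the closed form to about $10^{-3}$ and
mean passage times to about 0.3%, good enough that the simulator can serve
both as the generative engine of the synthetic datasets and as a
brute-force check on the analytic density. Datasets used for recovery are
thus simulated by a numerical route (paths) and fitted by an analytic route
(series density), so agreement between the two is informative rather than
circular.

## Hierarchical estimation

`sample_posterior()` fits any of the four specifications to one group by
Metropolis-within-Gibbs MCMC, written for this package (no off-the-shelf
hierarchical Wiener sampler exists in the R ecosystem this package builds
on):

* Subject-level parameters are sampled on transformed scales — $\log
  \alpha$, $t_0$, $\mathrm{logit}\, z$, $\beta_0$, $\beta_1$ — each drawn
  from a group-level normal distribution, so subjects "contribute to and
  are constrained by" the group estimate.
* Group-level means carry flat priors over generous, physically sensible
  ranges ($\alpha \in (0.3, 6)$, $t_0 \in (0, 10)$, $z \in (0.05, 0.95)$,
  drift terms in $(-5, 5)$); group-level spreads carry half-normal(0.5)
  priors. The flat-within-bounds choice operationalizes "equal probability
  to all possible values" while keeping the sampler inside the region where
  the density is defined.
* $sz$ is a single group-level scalar with a flat prior on $(0, 0.6)$,
  mirroring common practice for inter-trial parameters (whether the
  original analyses estimated it per subject is not documented; the
  group-scalar choice is the more parsimonious and is what the recovery
  study validates). Because $sz$ is weakly identified, its Metropolis
  kernel mixes an adaptive random walk with occasional independence draws
  from the prior.
* Random-walk scales adapt toward a 35% acceptance rate during burn-in
  only, so the retained chain is a valid time-homogeneous MCMC.
* Initialization is data-informed but neutral: each subject starts at
  $t_0 = \min \log \mathrm{rt} - 0.5$, $\alpha = 2.5$, $z = 0.5$, seeded
  jitter, with bounded retries if the starting likelihood is not finite.

Group-level estimates are reported as posterior means of the
back-transformed group location (e.g. $E[e^{\mu_{\log\alpha}}]$), which is
also how the generating values of the simulator are defined — simulator and
fitter share one hierarchical family, so recovery is a fixed-point check.

Convergence is assessed with the Gelman–Rubin statistic on multiple chains
(`gelman_rubin()`, converged below 1.1), and models are compared with the
deviance information criterion: $\mathrm{DIC} = D(\bar\theta) + 2 p_D$,
$p_D = \bar D - D(\bar\theta)$, where $D(\bar\theta)$ evaluates each
parameter at its posterior mean *on the sampling scale* — DIC is not
invariant to that choice, so it is fixed and documented here.

## The synthetic-data generator

The generator's defaults are the task's study conditions: 80 trials per
subject, match probability 0.6, equal state prior, ~521 ms mean stimulus
presentation with uniform jitter (half-width 150 ms, the simplest
distribution consistent with the reported means) and a fixed 150 ms lag.
The reference group-level generating values
(`factory_group_params("control")` / `"threat"`) are the fitted winning
model estimates for the two experimental groups, e.g. control: $\alpha =
2.67$, $t_0 = 7.55$, $z = 0.48$, $sz = 0.18$, $\beta_0 = 0.46$, $\beta_1 =
0.17$.

Subject-level spreads are not reported anywhere, so they were chosen once,
a priori, at values a practitioner would call realistic for this task and
were not revisited: sd 0.10 for $\log \alpha$ and $t_0$, 0.25 for
$\mathrm{logit}\, z$ (subjects visibly differ in starting-point bias —
their bias correlates with judgment bias — so $z$ spans roughly 0.37–0.60
across subjects), 0.15 for $\beta_0$ and 0.10 for $\beta_1$.

Two generative paths are deliberately distinct, matching the analysis each
feeds:

* **Diffusion path** (`simulate_ddm_dataset()`): the fitted DDM ignores the
  discrete stimulus structure, so (choice, log-RT) pairs are sampled
  directly from the diffusion and a stream is attached whose length is the
  number of stimuli presentable within the realized RT. Stimulus *counts*
  are drawn from the matching binomial — distributionally identical to
  materializing the stream item by item.
* **Psychometric path** (`simulate_psychometric_dataset()`): a stream is
  truncated at a sampled stopping count (default $2 +$ negative binomial
  with mean 6, giving a realistic mean of ~8 items; the real stopping
  distribution is unreported, so the rule is a configurable argument) and
  the judgment is drawn from the logistic model itself.

What passing recovery tests therefore show is that *each estimator
recovers the generative model it assumes* at the study's scale — they do
not show that real behavior follows either generative model, that stimulus
streams drive individual choices (the diffusion path attaches streams only
descriptively), or anything about the stopping policy of real participants.

## Psychometric function

The probability of judging the factory a TV factory is modeled as
$P(\mathrm{TV}) = 1 / (1 + e^{-(\beta_1 X - \beta_0)})$, with $X$ the
centered proportion of TV items observed ($X = 0.5$ when all items were
TVs). The indifference point — the evidence at which TV is chosen half the
time — is $\beta_0 / \beta_1$. The package follows this printed
parameterization verbatim, including its sign convention for $\beta_0$;
note that under this formula a *larger* $\beta_0$ shifts the curve right
(more TV evidence needed), which is worth keeping in mind when comparing
verbal descriptions of "left/right shifts" of fitted curves, as prose and
formula are easy to de-synchronize on this point.

Fits are per condition (group × whether TV was desirable), pooled across
subjects by maximum likelihood with subject-resampling (cluster) bootstrap
95% intervals. A hierarchical mixed-effects logistic would target the same
fixed effects at this simulator's scale; the pooled estimator was chosen as
the primary method because it is simpler, fully testable, and its recovery
bias is below 10% across the tested parameter grid. Complete separation
(e.g. a condition in which every response is TV) falls back to a small
ridge penalty with a warning.

## Exclusion rules and model-free statistics

`apply_exclusions()` fixes an order the verbal rules leave open: flag
trials answered before the second item; drop subjects flagged on *more
than half* of their trials (exactly half is retained); drop remaining
flagged trials; then drop subjects below 50% accuracy on what remains
("below chance" is strict; exactly 0.5 is retained). The order matters —
accuracy is only meaningful on trials with at least two pieces of evidence
— and re-application is idempotent.

The valence-dependent judgment bias is the per-subject difference in
proportion correct between desirable and undesirable trials;
`correlate_bias()` relates it to subject-level posterior means of the
drift-rate bias or the starting-point bias. The group × valence interaction
is tested with a seeded permutation test on per-subject biases rather than
a mixed-effects F-test: the permutation test is self-contained, exact under
the null, and assertable on synthetic data.

## Problem sizes and reproducibility

Full-scale estimation settings are 20,000 MCMC samples, 5,000 burn-in,
thinning 5, five chains (`paper_mcmc_config()`). Recovery runs use the
recovery-scale settings of 2,000 samples with 500 burn-in; the test
suite's replicate studies simulate 20 subjects × 80 trials, while the
bundled acceptance script simulates each group at the study's own size (43
control / 40 threat subjects × 80 trials, two chains). At these sizes a
full simulate→fit→recover cycle runs in a few minutes on a single core
while leaving the posterior-mean group estimates stable to well within
their credible intervals. Every stochastic stage
(design, simulation, chains, bootstrap, permutations) is seeded, and equal
seeds reproduce results bit for bit.

## Known limitations

* The threat group's generating drift bias (−0.08) is small relative to its
  posterior uncertainty at recovery scale, so its recovered point estimate
  fluctuates around the generating value across seeds; the recovery
  property asserted is sign/near-zero pattern plus credible-interval
  coverage, not a sharp point match.
* DIC comparisons at 20 subjects are coarser than at full scale; the
  package asserts the qualitative ordering (the valence-dependent model
  wins on its own data, and is not preferred beyond its complexity penalty
  on bias-free data).
* The simulator does not model point totals, practice trials, or
  attention/urgency dynamics, and the diffusion path's streams are
  descriptive attachments, not causes of the simulated choices.
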