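---
title: "Bout microstructure of operant extinction: model, inference and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bout microstructure of operant extinction: model, inference and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dberm)
```

## The model

Free-operant responding is organised in *bouts*: bursts of closely spaced
responses separated by longer pauses. `dberm` implements a dynamic
bi-exponential refractory model of this microstructure during extinction.
Conditional on the session time $t$ at which an inter-response time (IRT)
starts, its duration $\tau$ follows a refractory-shifted mixture of two
exponentials,

$$
\Pr(\mathrm{IRT}_t = \tau) =
\begin{cases}
0 & \tau < \delta\\
p_t\, w_t e^{-w_t(\tau-\delta)} + (1-p_t)\, b_t e^{-b_t(\tau-\delta)} &
\tau \ge \delta,
\end{cases}
\qquad w_t > b_t,
$$

where $w_t$ is the fast within-bout response rate, $b_t$ the slow
bout-initiation rate, $\delta$ the refractory period (the minimum possible
spacing of two responses), and $p_t = L_t/(1+L_t)$ the probability of
remaining within a bout, with $L_t$ the mean bout length (responses beyond
the bout-initiating response). Extinction is expressed as exponential decay
of the dynamic parameters from their baselines,

$$
L_t = L_0 e^{-\gamma t},\qquad
w_t = (w_0-\Omega)e^{-\alpha t} + \Omega,\qquad
b_t = (b_0-\Omega)e^{-\beta t} + \Omega,
$$

with constraints $w_0 > b_0 \ge \Omega \ge 0$, $\beta \ge \alpha \ge 0$ and
$\gamma \ge 0$: both rates share the asymptote $\Omega$ (a candidate operant
level), and the bout-initiation rate never decays more slowly than the
within-bout rate. Decay rates are reported as half-lives,
$H = \ln 2 / \text{rate}$, which are easier to read (e.g. "bout length
halves every 19 min"). A second extinction session is linked to the first by
multiplicative *recovery coefficients*, one per parameter: baselines,
$\delta$ and $\Omega$ are multiplied by their coefficient and half-lives by
theirs (so decay rates are divided). A coefficient of 1 means perfect
carry-over; $C(L_0)=0.5$ means the session-2 baseline bout length is half
the session-1 value.

Key modelling conventions:

* **Units.** Minutes everywhere internally (rates per minute, $\delta$ in
  minutes); $\delta$ is converted to seconds only at reporting and file
  boundaries, where operant hardware conventions use seconds.
* **Frozen dynamics within an IRT.** The mixture parameters of an IRT are
  evaluated at the IRT's *start* time and do not decay within the interval.
* **Half-life cap.** Decay rates indistinguishable from zero imply unbounded
  half-lives and improper half-life summaries, so all three half-lives are
  truncated at $5.6\times 10^6$ min (about ten years) with a `capped` flag,
  and decay rates are bounded below by $\ln 2 / 5.6\times 10^6$ per minute.
  The cap is applied to all three half-lives, since the impropriety argument
  applies equally to $\gamma$, $\alpha$ and $\beta$.
* **Closed support.** The density at exactly $\tau=\delta$ takes the mixture
  value (support is $[\delta,\infty)$). Mixing is computed by log-sum-exp,
  so very long IRTs produce large negative but finite log-densities; only
  $\tau<\delta$ maps to $-\infty$. This keeps MCMC arithmetic stable.

## The synthetic-cohort generator

`simulate_session()` is a direct sequential Monte-Carlo sampler of the
model: starting from $t_1=0$ it (1) updates $(L_t, w_t, b_t)$ at the current
time, (2) samples the bout state (within-bout with probability $p_t$),
(3) samples an exponential pause with mean $1/w_t$ or $1/b_t$, and (4) adds
$\delta$ and advances the clock, stopping when the clock passes the session
end. The final overshooting response is discarded — the session truncates
the process. The latency from lever extension to the first response is
generated by the same mixture (a bout-state draw at $t=0$) and flagged on
the record so that inference can include or exclude it symmetrically.

`simulate_cohort()` emulates the design the package targets: two strains
(an SHR-like ADHD model and a WKY-like control), six rats per strain, one or
two 65-min extinction sessions. Individual parameters are log-normally
distributed around strain medians; the built-in `reference_medians()` and
`reference_recovery()` provide realistic generative values (SHR: higher
bout-initiation rate, essentially non-decaying bout length; WKY: longer
baseline bouts with a ~19-min half-life). Draws violating the ordering
constraints are rejected and redrawn (budget 1000); with realistic
dispersion rejections are rare, and this is simpler and exact compared with
truncated-distribution sampling. The generative log-scale population SD is
not derivable from published group summaries; the package default of 0.2
(a ~±40% spread across rats at 2 SD) was chosen once as a realistic
between-rat heterogeneity and is used everywhere.

Randomness is organised as one root seed with per-rat and per-session
substreams derived by a deterministic counter hash, so enlarging a cohort
never reshuffles existing rats and every dataset is reproducible
byte-for-byte.

What the generator does *not* emulate: the maintenance phase
(variable-interval training), reinforcer deliveries, inter-trial intervals,
tone stimuli, satiation or warm-up within sessions, and any non-exponential
pause structure. Passing tests on synthetic data therefore demonstrate
internal consistency of model, simulator and estimator — not that real rats
obey the model.

## Hierarchical inference

Each rat contributes the likelihood of its IRT sequence, with dynamics
evaluated at each interval's start time; session-2 intervals use the
recovery-mapped parameters with the clock restarted at zero. Two data
conventions are controlled by flags, both on by default:

* the first latency enters as an ordinary model interval, and
* the pause from the last response to session end enters as a right-censored
  survival term. Ignoring this long terminal pause in extinction would bias
  rate estimates upward; turning the flags off reproduces the stricter
  "IRTs only" convention.

Individual log-parameters are normal around strain-level locations $\mu$
with population SDs; back-transformed, $e^\mu$ estimates the strain's median
parameter. Hyperpriors are flat with explicit supports (required for a
proper posterior): each $\mu$ uniform on $[\log 10^{-4}, \log 10^{4}]$ in
canonical units, decay-rate locations extending down to the half-life-cap
floor, and population SDs uniform on $(0, 5]$.

Sampling is adaptive Metropolis-within-Gibbs: every scalar — 8 log
parameters per rat, 8 log recovery coefficients per two-session rat, and
$(\mu, \mathrm{SD})$ per strain and parameter — is updated by a Gaussian
random walk whose scale adapts toward 44% acceptance during burn-in
(diminishing adaptation, frozen afterwards). Proposals are made on the log
of each natural parameter and rejected when they violate an ordering
constraint. We preferred this to an unconstrained difference
parameterisation (e.g. sampling $\log(w_0-b_0)$) because the population
model is log-normal on the natural parameters: proposing on that scale keeps
the prior density Jacobian-free, and at realistic parameter values the
constraints bind rarely, so rejection costs little. One consequence is that
the population density is effectively a *truncated* log-normal whose
normalisation constant depends weakly on the hyperparameters; the hyper
updates ignore that constant, which is negligible whenever rejections are
rare (always the case in the regimes exercised here).

Defaults mirror the package's standard analysis: 20,100 retained samples
after a 5,000-sample burn-in, single chain, with a split-half R-hat
reported per hyperparameter as a stationarity guard. The refractory period
is sampled freely per rat (and per session through $C(\delta)$); any
proposal exceeding the rat's smallest observed interval is rejected by the
likelihood's $-\infty$, which handles the boundary without special-casing.
Initial values are crude data-driven moments (a geometric-midpoint split of
IRTs into short and long classes); burn-in adaptation does the rest, and a
non-finite likelihood at initialisation aborts with the offending rat named.

Strain comparisons use the posterior of $E_x = \mu_x(\text{strain}_1) -
\mu_x(\text{strain}_2)$; $e^{E_x}$ is the ratio of strain medians, declared
significant when the central 95% credible interval of $E_x$ excludes 0.
Half-life labels flip the sign of the rate effect so that a ratio above 1
always reads "larger (longer) in strain 1". No multiple-comparison
correction is applied across the 16 parameters; users comparing many
parameters should bear that in mind.

## Posterior-predictive checks and recovery experiments

Two complementary checks mirror how this model family is validated:

* **Binned response rates** (`binned_response_rates()`,
  `posterior_predictive_rates()`): sessions are divided into eight
  8.125-min bins; for each posterior draw every rat's sessions are
  re-simulated and binned, and the strain-averaged curves (mean and central
  95% band over draws) are compared with the observed rates. Draws are taken
  without replacement when the chain is long enough, with replacement (and a
  warning) otherwise.
* **Log-survivor envelopes** (`log_survivor_curve()`,
  `ppc_survivor_envelope()`): the log of the proportion of IRTs exceeding
  each duration, computed over the IRTs whose *start* times fall in a
  window (the canonical windows are the first 10 and last 15 min of each
  session). Bi-exponential mixtures give the diagnostic "broken-stick"
  shape. Simulated curves are interpolated onto a common 200-point duration
  grid before pointwise medians and 2.5/97.5 percentiles are taken, since
  each draw supports different durations. Rate exports use log10
  conventions and survivor curves natural logs, recorded in the outputs.

`recovery_experiment()` closes the loop: simulate cohorts from known group
distributions, fit, and record per parameter whether the 95% credible
interval covers the generative median and the log-scale bias. Two
preconfigured stress scenarios (`recovery_scenario()`) probe a specific
artifact worry: `"hl_swap"` gives SHR-like rats (short bouts) the WKY
bout-length half-life, and `"hl_swap_l0_third"` additionally shortens the
generative $L_0$ threefold. Unbiased recovery under these scenarios shows
that a long estimated $H_L$ in a short-bout strain is not an estimation
artifact of having few within-bout responses.

## Numerical and design notes

* Problem sizes in the test suite are deliberately modest so the whole suite
  runs in minutes: recovery fits use 6 rats × one 65-min session with
  3,000 retained samples after 1,500 burn-in; the calibration experiment
  uses 20 replicates of 4 rats × 65 min with 1,200 retained samples. The
  65-min session length is retained even in the smallest experiments
  because the asymptotic rate $\Omega$ is only identified once the
  within-session decline has flattened; truncated sessions confound
  calibration with non-identification.
* With 6 rats and population SD 0.2, the cohort's geometric-mean parameter
  itself scatters with SD $0.2/\sqrt{6} \approx 8\%$ around the strain
  median. Point estimates from single small cohorts inherit that scatter —
  interval coverage, not point agreement, is the meaningful calibration
  statement at this size. At 24 rats and SD 0.05, posterior group medians
  land within a few percent of the cohort truth on every parameter.
* Degenerate inputs are handled explicitly: empty sessions contribute only
  their censoring term (or nothing when censoring is off); $L_0=0$ reduces
  the model to a single shifted-exponential process; a refractory period
  exceeding an observed interval yields a $-\infty$ likelihood rather than
  an error; zero decay rates are valid parameters and report as capped
  half-lives.
* Event files are plain comma-separated text with seconds at the boundary
  (exact division by 60 on read); chains persist as a CSV sample matrix plus
  a JSON metadata file carrying the resolved configuration, seed, acceptance
  rates and package version, so any artifact can be reproduced from its own
  provenance.

## Limitations

The package fits exactly the model above: alternative bout structures
(single-exponential, log-normal pauses), model selection across parameter
subsets, and more than two sessions per rat are out of scope. The
multiplicative recovery description is itself an assumption; with only two
sessions it is exactly identified and cannot be tested against richer
between-session dynamics. Posterior summaries assume the single-chain run
has mixed; the split-half R-hat flags gross failures, but users running
production analyses should compare several seeds.
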