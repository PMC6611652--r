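---
title: "Belief-state analysis of the cyclic triad task: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief-state analysis of the cyclic triad task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadhmm)
```

## The task and the inference problem

In the cumulative handling time task, a rat holds a lever for a cumulative
time — the *price* P (s) — to earn rewarding brain stimulation at a pulse
*frequency* f (Hz). Trials come in a deterministic cyclic triad: a *lead*
trial (fixed high frequency, price 1 s, highly rewarding), a *test* trial
(frequency and price drawn from a survey grid, variably rewarding) and a
*trail* trial (fixed low frequency, price 1 s, nearly worthless). Trial
duration is 25 times the price, floored at 25 s for sub-second prices. One
*survey* visits each of the 126 grid conditions once; the first survey of a
data set is excluded as adjustment.

The subject's initial response on each trial — whether it engages at all
(engagement probability, EP) and how quickly it first presses (initial
response time, IRT) — reveals its belief about the upcoming trial type
before it has any within-trial evidence. Trained subjects respond fast and
reliably on lead and test trials and slowly or not at all on trail trials;
but after a test trial whose frequency and price *resembled* a lead or
trail trial, they sometimes respond fast on the worthless trail trial.
These short trail IRTs are the behavioural signature of mistaken state
inference, and the package's purpose is to model and quantify them.

## The recognition model

The task is a hidden Markov model over the three types with a deterministic
permutation transition matrix **A** (lead → test → trail → lead). The model
observer is certain of its state at the end of a lead trial, hence certain
that a test trial comes next. During the test trial its trust in that past
evidence is imperfect, which we encode with a belief-transition matrix
**B**(γ):

  B = (1 − γ) I + (γ/3) J,   γ ∈ [0, 1],

so γ = 0 means the past fully determines the state and γ = 1 means the past
is ignored and the three types are a priori equally likely. Only the two
endpoints are pinned by the behavioural argument; the linear blend is the
minimal one-parameter row-stochastic interpolation between them, and is the
package's choice. An asymmetric variant gives premature *forward*
transitions (test → trail, with the cycle) and *backward* ones (test →
lead) separate rates γ_f/3 and γ_b/3, with the remainder on staying; it
nests the symmetric form at γ_f = γ_b = γ, which the BIC comparison
requires.

The within-trial evidence o = (log10 f, log10 P) enters through a
likelihood P(o | s): a mixture of isotropic 2-D Gaussians centred on the
points the subject actually experienced for each type, with weights
proportional to how often each point occurred and one shared standard
deviation σ (log10 units). Isotropy in log10 space is our reading of the
shared-width assumption; duration is deliberately not an observation
coordinate because it is (almost) proportional to price.

At the end of the test trial the posterior belief is

  P(s3 | o3, s2) ∝ P(o3 | s3) · P(s3 | s2),

with the prior term equal to **B**'s test row, and the belief at the start
of the trail trial follows by applying **A**. The predicted response there
is a belief-weighted mixture of three per-type response models: the
no-engagement mass is Σ s4_i (1 − EP_i) and the engaged-IRT density is
Σ s4_i EP_i f_i(irt).

## Response models

Per-type EPs are empirical engagement fractions (engagement = at least one
reward earned) and the IRT densities are Gaussian kernel density estimates
with Silverman's rule-of-thumb bandwidth, truncated to their support and
renormalised. Truncation (rather than boundary reflection) at 0 and at the
24 s censoring bound is a package choice; initial responses after 24 s on
lead and trail trials are impossible because no time would remain to earn
the reward, so such records are rejected as malformed. The trail component
is estimated only from trail trials whose preceding test trial fell in the
unambiguous λ region — intermediate frequency and long price — because
unfiltered trail responses are contaminated by exactly the confusion the
model is meant to explain. The EPs and densities are plugged into the
response mixture; they are not free parameters of the fit. Only γ and σ are
estimated by maximum likelihood.

## Fitting, uncertainty and model comparison

The log likelihood sums, over triads, the log probability of the observed
trail response given the preceding test observation. Maximisation is a
deterministic two-stage search: a coarse grid (γ linear in [0, 1] step
0.05; σ log-spaced over [0.01, 1] with 25 points) followed by Nelder–Mead
refinement from the best grid point with bounds enforced by rejection
(γ ∈ [0, 1], σ ∈ [0.005, 2]). Grid ties are broken toward the
first-visited candidate with a 1e-9 tolerance; this matters only on
degenerate data (e.g. a γ = 0 ground truth makes the surface a flat ridge
in σ) and keeps fits reproducible there.

Standard errors come from the central-finite-difference Hessian of the log
likelihood at the MLE (step 1e-4 × max(|θ|, 0.1)): T = −H⁻¹ estimates the
asymptotic covariance, SE_i = √T_ii and ρ_ij = T_ij/√(T_ii T_jj). On
recovery fixtures ρ(γ̂, σ̂) is reliably negative — more uncertainty about
the past can be partially traded against sharper perception — a moderate
anticorrelation, typically between −0.3 and −0.7.

BIC = −2 logL + N_M ln N_D with N_D the number of triads (the likelihood
is one term per triad; whether the original count was triads or trials is
unstated, and triads is our reading). Because the data are split into three
sequential tertiles and fitted independently, per-subject BICs are sums of
per-tertile BICs. The γ-fixed variants estimate σ only (N_M = 1) — note
that at γ = 0 the observation never enters the likelihood, so σ is
unidentified there and its "estimate" is arbitrary; the asymmetric variant
has N_M = 3.

## Statistical tests

Two-tailed Monte-Carlo permutation tests use the add-one convention
p = (1 + #{|T_perm| ≥ |T_obs|})/(1 + n_perm), with 1000 permutations by
default. The binomial proportion test uses the pooled-variance Z statistic
with a normal-approximation p-value. Earth mover's similarity is 1 minus
the first Wasserstein distance after rescaling the support to [0, 1] by the
24 s censoring bound; this normalisation is a package choice, so absolute
similarity values depend on it but similarity *differences* and the
permutation tests built on them do not. Short IRTs
are those at or below the 95th percentile of the test-trial IRT
distribution, and the short-IRT fraction divides by all trail trials
(engaged or not), tracking confusion per opportunity. The change in fitted
parameters from first to last tertile is tested by refitting under random
permutations of the triads' time labels and asking whether the observed
absolute change exceeds the null's 95th percentile.

## What the synthetic world is — and is not

No behavioural data are distributed with the package, so a generative
simulator stands in for them. Its stated conditions follow the experiment
where the experiment pins them down: per-subject frequency/price constants
and region boundaries for six subjects; 126-condition surveys (the exact
survey composition is not available, so we use 14 log-spaced frequencies
spanning the trail-to-lead range × 9 log-spaced prices in [0.25, 25] s,
which gives the required 126 triads per survey and covers all four
regions for every subject, and we randomise condition order within each
survey); 10 s intertrial intervals; the 25× duration rule; first-survey
exclusion; sessions of roughly 8–13 surveys.

Where the experiment is silent, the generator's defaults describe a
moderately trained subject and were chosen once: engagement probabilities
0.99 / 0.98 / 0.25 for lead / test / trail, and truncated log-normal IRT
distributions centred near 1 s (lead), 2.5 s (test) and 12 s (trail) on
(0, 24]. The trail centre is deliberately slow and tight (log-mean log 12,
log-sd 0.4): genuine trail responses in the task are distinctly slow, and a
baseline trail distribution with substantial mass below the test trials'
95th percentile would conflate ordinary slowness with the confusion
signature the analyses measure. Trail responses are generated from the
model's own predictive mixture given the agent's (γ, σ), so downstream
recovery is a well-specified estimation problem up to the nonparametric
re-estimation of the response components. IRT draws exceeding the trial's
engagement window (duration minus price, capped at 24 s) are rejected and
redrawn, mirroring the engagement definition.

A green recovery or selection test therefore establishes that the
estimation and testing machinery is correct and well calibrated on data
generated by the model itself — not that the model is true of rats, and not
that real data would yield any particular parameter values; the original
behavioural data set is not available. Real data differ in ways the generator does
not emulate: value-dependent test-trial engagement, within-trial response
microstructure, slow drifts in motivation, and any history dependence
beyond the one-step belief update.

Two sizing consequences of the synthetic world are worth knowing. The λ
region occupies only 8 of the 126 grid conditions for subject 1, so
λ-filtered trail KDEs need sessions of several surveys (the estimator
requires 10 engaged λ-preceded IRTs by default; `min_n` can be lowered for
small fixtures). And calibration studies of the MLE-change test use the
generator's true parametric response model rather than re-estimating it per
replicate, which keeps the null exactly exchangeable and the study cheap;
the test applied to data uses the estimated response model.

## Numerical choices and degenerate inputs

Region rectangles are closed (boundary points belong to the named region);
the α/β price band and the λ price bound are disjoint, which keeps the
four labels a partition even for subjects whose λ frequency band overlaps
the α band. Beliefs are renormalised after every product; posteriors are
normalised three-vectors by construction and an all-zero posterior (only
possible with a broken likelihood) raises an error rather than NaN.
Likelihood evaluations that assign an observed response probability zero
return +Inf for the negative log likelihood, which the optimiser treats as
out of bounds — if a fit reports this everywhere, the response-model
supports are misconfigured. Finite-difference Hessians at a boundary MLE
are computed on a slightly extended γ domain and flagged with a warning,
since Wald intervals are invalid on the boundary.

## Known limitations

The package models the initial response only; within-trial pressing
microstructure, black-out delay bookkeeping and the labour/leisure
economics of the source experiment are out of scope, as is any mechanism
for the price sensitivity of sub-second-price test trials (the
corresponding contrast is reported but not modelled). The belief update
consumes the test observation once, at the end of the trial; "forgetting"
and "wrong generative model" interpretations of γ are not distinguishable
here. Survey randomisation within sessions is assumed, not known.
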