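---
title: "The mutation sampler: model, fitting and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mutation sampler: model, fitting and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutationsampler)
```

## The scientific problem

Human causal inferences are close to those licensed by causal Bayesian
networks, but they deviate systematically. The best documented deviation is
the *Markov violation*: when a shared cause X of two effects YA and YB is
known, the state of YB should tell a reasoner nothing further about YA
(X *screens off* YA from YB), yet people reliably judge
p(YA=1 | X, YB=1) > p(YA=1 | X, YB=0).

The **mutation sampler** is a rational process model of this behavior. It
assumes that a reasoner answers a conditional-probability query by running
a short Metropolis–Hastings chain over the network's 2^n system states and
reading the answer off the visited-state frequencies. Two resource
assumptions distort the answer away from normativity:

1. **Limited chain length.** Only λ samples are taken (a dozen or so,
   not thousands).
2. **Biased starting point.** Sampling begins at a *prototype state*: a
   full assignment qualitatively consistent with every causal link —
   equal values across a generative link, opposite values across an
   inhibitory one, ignoring direction and strength. For an all-generative
   network the prototypes are the all-present and all-absent states.

Short chains keep the occupancy distribution close to the start states, so
prototype-started chains over-represent "all present" and "all absent",
which makes YA and YB look dependent even given X: a positive Markov
violation. When a network admits *no* qualitatively consistent state — for
instance a diamond X → YA → Z, X → YB → Z in which exactly one of the four
links is inhibitory, so X apparently both promotes and prevents Z — the
model's start bias disappears (sampling starts at a uniformly random
state), and with it the predicted Markov violation. That disappearance is
the headline qualitative prediction this package is built to compute,
test and recover.

## Model components

### Exact engine

A `causal_network()` is a DAG over named binary variables with per-link
polarity. Non-root variables carry logistic conditional probability
tables: with parents coded +1 (present) / −1 (absent),

p(v = 1 | pa(v)) = logistic( Σ_j w_j c_j + w_exo ),

where w_j is the link weight (≥ 0 generative, ≤ 0 inhibitory) and w_exo an
exogenous background weight. Multiple parents combine additively inside
one logistic — the natural multi-parent extension of the single-parent
form, consistent with fitting a single tied generative strength. Root
variables take their base rate directly as a probability (fitted base
rates of roughly 0.6–0.7 live naturally on the probability scale, not the
logistic scale). `joint_distribution()` multiplies the tables over all 2^n
states; states are indexed 0..2^n−1 with the first declared variable as
the most significant bit, so "1111" and "0000" read left to right in
declaration order.

### Prototypes and the chain

`derive_prototypes()` enumerates all states and keeps those satisfying
every link's qualitative constraint; the set may be empty.
`transition_matrix()` implements Metropolis–Hastings with the *mutation*
proposal: flip one of the n variables chosen uniformly (probability 1/n
each) and accept with min(1, π(s′)/π(s)). The matrix is column-stochastic
and satisfies detailed balance with respect to the exact joint π exactly
(the flows π_i P(i→j) are min(π_i, π_j)/n on both sides), which the tests
assert to 1e−12.

`occupancy_distribution()` is the deterministic expectation of a finite
chain: (1/L) Σ_{t=0}^{L−1} T^t s₀. Three choices matter:

* **The start state counts as the first sample.** λ = 1 then reproduces a
  pure prototype response — the model's resource-starved limit.
* **No burn-in and no thinning.** The bias of the early samples *is* the
  psychological mechanism; discarding them would remove the phenomenon
  being modeled.
* **Non-integer λ interpolates linearly** between the occupancies at
  ⌊λ⌋ and ⌈λ⌉, keeping the least-squares objective continuous in λ during
  fitting. An alternative — averaging over a distribution of integer
  lengths with mean λ — would also smooth the objective; fixed length with
  interpolation was chosen as the simpler mechanism with one fewer
  distributional assumption.

`sampler_predictions()` answers a query battery from the occupancy
distribution. In prototype mode the start is the uniform mixture over the
prototype set (the model picks one of the prototypes at random; with two
prototypes, ½/½). If the derived set is empty, prototype mode refuses and
directs the caller to uniform mode — the no-prototype variant, which
starts at a state chosen uniformly from all 2^n. Queries whose evidence
receives zero occupancy mass (possible at very small λ with point-mass
starts) return a fallback of 0.5, the maximally uninformative judgment;
exact joints are strictly positive so the fallback never fires for them.

`simulate_chain()` is the stochastic counterpart (a real seeded MH
trajectory) for studying within-subject variability; the deterministic
occupancy is its expectation, and the default generator and fitting
pipeline use the deterministic form only.

## The query battery and the violation score

`markov_battery()` builds the 12 screening-off probes: for each ordered
pair (Yi, Yj) and each x ∈ {0,1}, the triplet p(Yi=1|X=x, Yj=0),
p(Yi=1|X=x), p(Yi=1|X=x, Yj=1). `default_battery_32()` embeds them in a
32-query battery covering the rest of the diamond (queries about Z given
the Ys, X given a Y or Z, and so on). The experiment's full query set
beyond the 12 Markov probes is not fully pinned down by its published
description, so the remaining 20 are a documented package default and can
be replaced wholesale via `extra_queries` or config when an external data
set defines the true membership.

`markov_violation_score()` averages, over the four (Yi, x) cells,
(value with Yj present) − (value with Yj absent), on the 0–100 rating
scale (model probabilities are multiplied by 100 first). **Sign
convention:** present-minus-absent, so the classic positive violation
yields a positive score and the exact model scores 0. The convention is
chosen so that reported positive group means correspond to positive
violations; descriptions of the score as "subtracting the present value
from the absent one" with positive reported means are treated as a wording
slip.

A property worth knowing: with prototype starts on the all-generative
diamond the *mean* score is strictly positive across the whole realistic
parameter box (base rate 0.4–0.8, generative strength 0.2–1.0, exogenous
weight 0–1, λ 2–50). The stronger cell-by-cell version holds everywhere
except one extreme corner (λ = 2, base rate 0.8, link strength 0.2), where
the two rarely-visited X = 0 cells dip marginally negative (−0.011) while
the X = 1 cells exceed +0.6; the test suite documents that boundary
explicitly.

## Per-subject fitting

`fit_subject()` minimizes Σ (100·prediction − rating)² for one subject
under one of three `model_spec()` variants:

| variant | start | free parameters | p |
|---|---|---|---|
| `normative` | — (exact joint) | wX, wgen, (winh), wexo | 3–4 |
| `ms_prototypes` | ½ all-absent + ½ all-present | + λ | 4–5 |
| `ms_noprototypes` | uniform over all states | + λ | 4–5 |

A single wgen is tied across all generative links and a single wexo across
non-root variables; winh enters only for networks with an inhibitory
link. Note that the fitted prototype variant uses the *fixed*
all-absent/all-present pair even on networks whose derived prototype set
is empty — that is precisely the theoretical contrast of interest: does a
subject in an inhibitory condition behave as if they still used the
generative prototypes, or not?

Numerical choices:

* **Bounds** wX ∈ [0.01, 0.99], wgen ∈ [0, 5], winh ∈ [−5, 0],
  wexo ∈ [−5, 5], λ ∈ [1, 100]. The λ upper bound brackets group-level
  chain-length estimates (≈ 16–36) with ample headroom; at λ = 100 the
  uniform-start sampler is empirically indistinguishable from the
  normative model on this state space, which the tests verify.
* **λ is optimized on the log scale**, matching its right-skewed
  distribution across subjects; group summaries use the geometric mean.
* **Optimizer**: Nelder–Mead on a logit-transformed box (derivative-free,
  every iterate feasible), with a seeded multi-start: 20 starts (one
  canonical, the rest uniform over the box, λ log-uniform), short
  screening runs for all starts and full-precision polishing of the
  leaders. Refits under the same seed are bit-identical.
* **AIC** uses the least-squares form n·ln(SSE/n) + 2(p+1) with the
  natural logarithm; a perfect fit (SSE = 0) returns −Inf with a warning.
  Best-fit percentages split exact AIC ties equally.

## Synthetic cohorts

`generate_experiment()` emulates the study's design: 56 subjects reasoning
about the all-generative diamond and 28 about each one-inhibitory diamond
(three content-domain labels cycled within condition, labels only), each
answering the 32-query battery once. Per-subject true parameters are drawn
from ranges bracketing typical fitted values — wX ~ U(0.4, 0.8),
wgen ~ U(0.2, 1.0), winh ~ U(−1, −0.2), wexo ~ U(0, 1), λ log-uniform on
[8, 40] — and ratings are 100·prediction + Gaussian noise clipped to
[0, 100], the simplest response model consistent with a bounded slider.
The default noise sd of 10 rating points was chosen once as a realistic
judgment-noise magnitude for this kind of slider task; it is a config
knob, and the recovery analyses also exercise sd 0 and sd 5. By default
the generative condition is generated by the prototype-start sampler and
the inhibitory conditions by the uniform-start sampler — the generating
configuration the group-level analyses are designed to detect.

What the generator does *not* emulate: trial-level sampling noise within a
single rating (each synthetic rating is the model's expectation plus
response noise, not a fresh stochastic chain), individual differences in
which queries are answered, order effects, and anchoring or rounding on
the slider. Passing tests therefore show that the pipeline recovers the
structure the generator put in — prototype-driven violations and their
absence — not that real subjects contain no further structure.

## Group-level statistics

`subject_markov_scores()` + `markov_stats_report()` reproduce the standard
statistics block: per-condition mean violation with a classical per-group
95% t interval (the interval construction is not otherwise constrained, so
the classical choice is used), a one-way between-subjects ANOVA across the
three conditions, and per-condition one-sample t tests with a JZS Bayes
factor. The Bayes factor integrates the noncentral-t likelihood over a
Cauchy(0, √2/2) prior on the standardized effect (the conventional
"medium" scale, configurable), and is cross-checked in the tests against
an independent quadrature of the equivalent g-mixture integral to four
significant digits.

## Problem sizes used by the shipped analyses

The `analysis/` drivers and the acceptance script run the full
study-scale cohort (112 subjects × 32 queries; three fitted variants per
subject at 20 optimizer starts each — a few minutes of compute), while the
unit and property tests use smaller cohorts (4–50 subjects) and the
recovery check uses 20 prototype-sampler subjects at noise sd 5. These
sizes were chosen to mirror the study's scale where the quantity of
interest is group-level and to keep the routine test suite fast where it
is not.

## Known limitations and extension points

* Prototypes are all-or-none. A graded variant — starting probability a
  decreasing function of the number of qualitatively broken links — is a
  natural extension point of `derive_prototypes()` but is deliberately not
  implemented.
* The exact-occupancy computation enumerates 2^n states and is intended
  for n ≤ 16; the experiments here use n = 3–4.
* The fitted optimum is reproducible but, as with any multi-start local
  search on a non-convex objective, not guaranteed global; independently
  published parameter estimates are therefore matched qualitatively, not
  bit-exactly.
* `read_ratings()` adapts external CSV layouts via a column mapping
  (including per-trial layouts through aggregation) but ships no
  hard-coded adapter for any particular deposit.
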