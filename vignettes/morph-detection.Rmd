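---
title: "Component-based gestural repertoires: models, thresholds and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Component-based gestural repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphrep)
```

## The two-level repertoire model

Gesture coding yields one row per *token*: an instance of a *gesture
action* used by a signaller toward a recipient, annotated with four
categorical modifiers — body part, contact with the recipient, lateral
use, repetition — plus interaction metadata (communication id, behavioural
context after the communication, group, season, chronological order
index, outcome).

The repertoire is built at two granularities:

* **Actions.** An action is in the repertoire once observed at least
  `min_tokens = 3` times. The contribution table reports per-action token
  counts, percentages (half-away-from-zero, one decimal), cumulative
  percentages in descending frequency order, and the deviation from the
  *average contribution* `total/n_actions` — the count expected if
  signallers drew actions uniformly from the repertoire. The *repertoire
  of regular use* is the minimal frequency-ordered prefix whose unrounded
  cumulative share reaches `regular_use_target = 0.695`; 0.695 rather
  than 0.70 tolerates the one-decimal presentation rounding of published
  cumulative columns while preserving the intended "~70 %" reading.
* **Morphs.** Within each action with `action_min = 10` clear tokens, a
  multinomial latent-class mixture over the applicable modifiers is
  fitted by EM; mixture components with at least `morph_min = 5`
  hard-assigned tokens are morphs. Actions resolve to unimorphic (one
  morph), polymorphic (two or more), or unspecified (3–9 tokens; counted
  as one repertoire unit each but not analyzed). Tokens in sub-threshold
  classes are *unassigned* — they are not merged into a neighbouring
  class, because a residual unassigned fraction is a meaningful output of
  this procedure, and merging would silently inflate morphs.

Latent-class machinery. For token $i$ with modifier vector $x_i$,
$P(x_i) = \sum_k \pi_k \prod_m p_{k,m,x_{im}}$. EM uses Dirichlet(1)
random initialization, `n_restarts = 20`, relative log-likelihood
tolerance $10^{-8}$, at most 1000 iterations, and is deterministic given a
seed; duplicated modifier vectors are collapsed to weighted unique
patterns, so cost scales with distinct configurations, not tokens. The
log-likelihood trace is returned and asserted non-decreasing in the test
suite. For $k = 1$ the maximum is closed form (empirical marginals) and is
computed directly — this closed form doubles as an independent oracle for
the EM path. Model selection minimizes
$\mathrm{BIC} = -2\,\mathrm{LL} + d\log n$ with
$d = (k-1) + k\sum_m (L_m - 1)$, ties to the smaller $k$. BIC is this
package's explicit choice; the field literature this mirrors defers model
selection to cited software without printing a criterion, so the
criterion is stated here rather than inherited. Posterior ties in hard
assignment go to the lower class index; surviving classes are renumbered
by descending size as `<action>.<i>_<K>`.

Two practical details: modifiers that are invariant within an action are
dropped before fitting (they contribute a constant likelihood factor and
would inflate the BIC dimension), and the applicability map declares which
modifiers are meaningful per action — `"not_applicable"` levels never
reach the model.

## Individual, context and reliability statistics

*IRS_1* counts an individual's distinct actions (even $n=1$); *IRS_3*
applies a three-token threshold per action per signaller. *IGR_obs*
divides the individual's tokens by the follow hours of their group over
the seasons they appear in the effort table; *IGR_vid* divides by hours
of footage featuring them. Undefined rates (zero denominator) are `NA`,
never 0. Maturation classes: infants 0–3 y; juveniles >3–6; subadults
>6–8 (both sexes), blackback males >8–12 and nulliparous females 8–<12;
adults are males >12, parous females, and nulliparous females ≥12 —
parity overrides age for females, and a first birth within a season makes
the female parous for that whole season. An individual occupies exactly
one class per season; a within-season boundary crossing resolves to the
class holding the majority of that season's tokens (age at the season
midpoint decides when no token counts are supplied — the evaluation date
within a season is not standardized in the field literature, and the
midpoint is the symmetric choice). Across seasons an individual may
contribute one data point per class occupied.

Context is a property of the communication (the signaller's behaviour at
its end), so counts are per communication; contexts under 1 % of the raw
distribution pool into "Other", while "Unknown" is kept separate and
never pooled. Reliability uses an unweighted Cohen's kappa (categories
are unordered) on a subsample allocated per action by largest remainder —
"proportional" needs a rounding rule, and largest remainder is the one
that never misses the total.

## The synthetic world

`generate_dataset()` realizes a declarative config: planted actions with
token counts, per-action mixtures of modifier configurations, a noise
model, an unclear-coding model, a population, effort, contexts and
communication sizes. Design choices, fixed once:

* **Deterministic counts, random everything else.** Per-action token
  counts (and within them, component counts) are largest-remainder images
  of the planted shares. Randomness enters through modifier noise, unclear
  placement, token order, signaller/recipient attribution, seasons,
  contexts and outcomes. Repertoire-level integer statistics are thereby
  identical across seeds, which is what a calibrated profile is for; the
  spec-level property "empirical shares converge to targets" holds
  trivially.
* **Noise model.** Each applicable modifier flips independently with
  probability ε (default 0.02 in the calibrated profile) to a uniformly
  random other level. This is the simplest model that makes classes
  non-degenerate without invalidating them.
* **Planted components.** The k components of an action are drawn from a
  fixed table of eight configurations, any two differing in ≥ 2 modifiers
  (the first four pairwise ≥ 3), and mixture weights are skewed but keep
  every component far enough above `morph_min` that detectability under
  BIC does not hinge on a noise realization. With ε = 0 and these
  separations, grouping identical vectors recovers the planted partition
  exactly — the brute-force oracle used against the EM path in the tests.
* **Unclear coding.** The calibrated profile places unclear modifiers by
  exact stratified counts: all 17 tokens of the 12 below-threshold
  actions, plus 80 tokens inside unimorphic actions, total 97 (≈ 3 % of
  3220). The stratification reconciles the published filter cascade
  (3220 − 97 − 99 = 3024 analyzed instances alongside a 3203-token
  repertoire), which is arithmetically consistent only if the
  sub-threshold tokens are themselves the unclear ones; keeping unclear
  tokens out of polymorphic actions protects planted component sizes. A
  uniform-rate mode (`unclear = list(rate = ...)`) remains the default
  for non-calibrated configs.
* **Ordering.** The detection asymptote is operationalized as the index
  of the final first occurrence (the published asymptote is a visual
  judgement; the last-novelty index is the sharp version, and a
  permutation envelope is available as the principled rarefaction
  alternative). The generator can plant this index exactly: one token of
  each other action is seeded before it, the designated action's first
  token lands on it, the rest after.
* **Population.** 49 individuals in four social units, 27 in the two
  focal units, with birth dates, parity and season windows arranged so
  the four maturation classes are populated and six individuals cross a
  class boundary between seasons (27 signallers, 33 class data points).
  Per-individual token weights are set so the focal silverback expects
  ~73 tokens against 143 follow-hours (≈ 0.51 tokens/h). Real
  per-individual token counts are unpublished; these weights are a
  realistic stipulation, not an estimate.

What a green test does *not* establish: the generator makes tokens
exchangeable within strata — no gesture sequences or exchanges, no
signaller-specific modifier styles, no season effects on behaviour, no
correlation between context and action. Results about those structures
cannot be read off this package's tests. The planted world also recovers
0 % unassigned tokens (every planted class clears the morph threshold);
the unassigned mechanism is exercised by unit tests with sub-threshold
classes instead. A published residual of ~4 % unassigned could arise
from low-confidence posteriors as well as from the class-size rule; this
package implements only the class-size rule and reports the fraction.

## Numerical choices and degenerate inputs

Percent presentation rounds half away from zero (matching printed
tables); all decisions use unrounded values. Ties in token counts break
alphabetically for stable output. `fit_lca` refuses k above the number of
distinct vectors (`morphrep_reduce_k_error`); zero-column inputs (all
modifiers invariant) fit k = 1 with log-likelihood 0. Empty token tables
are an error for the contribution table ("empty repertoire") but not for
thresholding. Item-response probabilities may reach exact 0/1 (no
smoothing — the k = 1 closed-form equivalence is exact); logs are floored
at 1e-300 only inside the E-step to avoid `-Inf - -Inf` arithmetic.

## Known limitations

* EM with 20 restarts and BIC over k ≤ 8 costs a few minutes on the full
  calibrated dataset on one CPU; the collapse to unique patterns is the
  implemented mitigation.
* IGR denominators assume individuals are present for all of their
  group's follow hours in seasons of membership; partial-season absences
  are not modelled (the effort table is the place to encode them if
  known).
* The shared/species-specific flag on actions is an input, not derived;
  cross-species repertoire comparison is out of scope.
* Confidence intervals for kappa and bootstrap stability of latent
  classes are not provided.
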