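---
title: "Methods: herd-based wrapper feature selection in whoselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: herd-based wrapper feature selection in whoselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whoselect)
```

## Scope and model

`whoselect` implements feature-subset selection for binary diagnostic tasks
(the motivating case: melanoma screening from deep features of dermoscopic
images) as a continuous optimization solved by the Wildebeest Herd
Optimization (WHO) metaheuristic, together with two classical filter scores
(tree-ensemble Gini importance and a chi-square dependency statistic), a
diagnostic metric suite, and a synthetic data generator. The package starts
from a numeric feature matrix; image handling and network training are out
of scope by design — any extractor that produces a labeled matrix can feed
it.

## The optimizer

WHO is a population method over a box `[lower, upper]^d`, minimizing by
convention. Each candidate, per iteration, passes through five phases:
milling (local probes `z = x + ε·θ·ν`, keep the best of `n`), a local blend
`x ← α₁ z* + β₁ (x − z*)`, herd instinct toward a random fitter peer
`x ← α₂ x + β₂ x_h`, starvation avoidance (a step of up to the full bound
range along a random direction), and herd pressure (replacement by
`x* + ε·n̂` when the distance to the global best lies in the window
`(pressure_lower_bound, η)`). Once per iteration the worst candidate is
re-seeded within `social_memory_radius` of the global best. The best-ever
candidate is retained across iterations, so the reported trace is
monotonically nonincreasing for any objective and seed.

### Parameters, defaults and rationale

| parameter | default | meaning |
|---|---|---|
| `population_size` | 30 | herd size N (reference experimental protocol) |
| `iterations` | 15 | fixed-count termination (same protocol) |
| `milling_steps` | 3 | local probes per candidate per iteration |
| `learning_rate` ε | `0.1·mean(upper−lower)` | probe / pressure step length, in position units |
| `alpha1, beta1` | 0.9, 0.3 | local blend weights |
| `alpha2, beta2` | 0.2, 0.8 | peer-following weights (strong pull toward better peers) |
| `crowding_threshold` η | `0.3·‖upper−lower‖` | upper edge of the pressure window |
| `pressure_lower_bound` | 1 | lower edge of the pressure window |
| `social_memory_radius` | 0.1 | re-seed radius around the best |

The source description of the dynamics names the parameters but gives no
numeric values compatible with them (the parameter table it prints lists
genetic-algorithm-style quantities — crossover and mutation probabilities —
that map to no symbol in the update equations; they are recorded nowhere in
code because nothing consumes them). The defaults above are therefore this
package's own calibration, chosen once by the small-local-step /
strong-peer-pull heuristic and never revisited: ε at 10% of the mean range
keeps milling local; `alpha2 = 0.2, beta2 = 0.8` makes peer attraction the
main exploitation force; η at 30% of the domain diagonal makes the pressure
rule active on wide domains and inert on the unit cube used for selection.
Every value is overridable through `who_config()`.

Three ambiguities in the printed dynamics were resolved as follows and are
frozen as the package contract:

* the compound pressure condition (distance simultaneously "below η" and
  "above 1") is implemented literally on the Euclidean norm, with the
  constant 1 exposed as `pressure_lower_bound`; when `η ≤ 1` the rule never
  fires, which is exactly what happens on `[0,1]^p` selection domains;
* the four distinct unit-vector symbols in the update equations are all
  treated as independent uniform random unit directions (only one of them
  is ever defined);
* the range term of the escape step is computed componentwise:
  `θ · (upper − lower) ⊙ v̄`.

Gating is conditional where the narrative implies a precondition: the peer
move applies only when the peer is strictly fitter ("proper food source"),
and the escape step only when the candidate's fitness worsened within the
current iteration ("insufficient food source"). Unconditional application
turns both into random-walk noise; the collapse test (ε = 0, α₁ = 1,
β₁ = 0, α₂ = 1, β₂ = 0, social memory off ⇒ stationary population) pins
the gated semantics.

### Numerical choices

Out-of-bounds positions are clamped to the nearest bound — the simplest
rule that preserves the containment invariant. Ties for the best or worst
candidate resolve to the lowest index. A run draws from a single seeded
stream in a fixed documented order (initialization, then per candidate:
milling θ/ν pairs, peer index, conditional escape draws, conditional
pressure direction; then the social-memory direction), so identical seeds
give bit-identical results; the stream is isolated from R's global RNG
state. Objectives must return finite scalars; a non-finite value aborts
with the offending position in the message.

## Wrapper selection

Subset search runs WHO on `[0,1]^p`; a position becomes a mask by
`selected[j] = position[j] > 0.5`, with an all-zero mask repaired to the
argmax component. The fitness is the standard wrapper objective

`Fit(mask) = α · err_CV(mask) + (1 − α) · |mask|/p`, `α = 0.99`.

The reference study reports fitness statistics but never defines its
fitness function or downstream classifier; this functional form, the error
weight, and the k-NN (k = 5) classifier are the package's largest
inferences, chosen for determinism and speed and recorded here
prominently. Stratified 5-fold assignment is derived from the fitness seed,
making fitness a pure function of the mask — which also allows the
searchers to cache fitness per mask (the landscape has at most `2^p − 1`
points). k-NN breaks distance ties by training index and vote ties by the
nearest neighbour, so fitness is deterministic bit-for-bit. A `"linear"`
classifier (logistic regression; a linear decision boundary standing in for
a linear SVM, which no available dependency provides) is selectable.

Baselines are budget-matched using `N · iterations · (milling_steps + 3)`,
an upper bound on WHO's per-run objective calls (probes plus the at most
three conditional re-evaluations per candidate-iteration): uniform random
mask sampling and best-improvement single-bit hill climbing. Repeated runs
use seeds `seed, seed+1, …` with the fitness seed held fixed, so all runs
explore the same landscape; their best fitness values are summarized with
the sample-SD statistics.

## Filters

Gini importance follows the impurity-decrease chain: node importance
`w_k C_k − w_l C_l − w_r C_r`; per-tree raw importance of a feature = sum
over its splitting nodes divided by the sum over all internal nodes of the
same tree (the denominator is read as per-tree, the only reading that
makes the subsequent normalization meaningful); normalized to sum to 1;
forest importance = mean of normalized vectors over trees. "Contamination"
is read as Gini impurity. Since the source never specifies how the
ensemble is built, the module accepts externally supplied trees in a
minimal node representation and also provides a bagged CART grower
(Gini criterion, depth limit 5, 50 trees, `mtry = ⌊√p⌋`) for end-to-end
use — the formulas, not the training recipe, are the contract.

The chi-square filter scores each feature by the Pearson statistic of its
bin-by-class contingency table, with 5 equal-frequency bins (duplicated
quantiles merged; a constant feature scores 0 with a warning). Expected
counts come from the margins. Scores are used for ranking only; no
p-values. Both filters are optional stages before the wrapper — the source
pipeline does not state whether they run before or instead of the wrapper,
so the CLI exposes them independently.

## Metrics

`compute_metrics()` reports ACC, SNS, SPC, PPV, NPV, Dice
(`2TP/(2TP+FP+FN)`) and an F-score defined as the harmonic mean of SPC and
SNS. Two conventions deserve emphasis: the F-score follows the source's
printed definition rather than the conventional precision–recall F1 (the
Dice value equals the positive-class F1 if that is wanted); and the
accuracy denominator is the standard `TP+TN+FP+FN` — the printed form
omits TN and doubles TP, which cannot represent an accuracy, so it is
treated as a typographical slip but preserved behind
`strict_literal = TRUE` for auditability. Zero-denominator metrics return
`NA`, never 0 or an error.

## Synthetic data: what it emulates and what it does not

The generator emulates the statistics that make deep-feature selection
hard: a few class-informative columns (Gaussian, unit variance, class
means `±effect/2`), redundant copies correlated at `ρ` with a random
informative source, and independent noise columns, shuffled with the
ground-truth roles tracked. Defaults (n = 300, 5 informative, 10 redundant,
35 noise, effect 1.5, ρ = 0.8, balanced classes) state a moderately hard,
high-redundancy regime: effect 1.5 gives near-complete per-feature t-test
power at n = 300 while single features remain imperfect classifiers, and
ρ = 0.8 makes redundant copies nearly substitutable for their sources —
the property the source attributes to deep features. An optional
`rectify` flag clamps negatives at zero to mimic rectified activations.

What a green test does *not* establish: real deep features are
non-Gaussian, heteroscedastic, and correlated in blocks rather than pairs,
and real class structure is not linearly separable per-feature. The
generator supports no claim about any specific image corpus — which is
also why the acceptance suite is property-based rather than an attempt to
reproduce corpus-level headline numbers.

One measured consequence of the stated redundancy: in the planted-recovery
experiment (10 runs at the default world), the median number of *informative*
features recovered sits at the criterion boundary (4 of 5 at the default
dataset seed, 3 of 5 at another seed tried during development), because a
redundant copy at ρ = 0.8 is an almost-perfect substitute for its source
under any error-based objective. The feature-*reduction* half (median
selected count far below p) is robust across seeds. This is a property of
the stated world, not a tuning target; no parameter was adjusted after
measurement.

A second measured limitation, recorded in the development notes: on the
1-D quadratic benchmark, WHO and uniform random search at a matched
~18k-evaluation budget both reach ≈1e−8 fitness (random search is
near-optimal on a short interval at that budget), so a paired win-rate
comparison there is uninformative; the optimizer-sanity property is
therefore tested on the 10-D sphere, where random search degrades with
dimension and WHO wins every paired run, and the quadratic is checked by
absolute recovery (`median |x−2| < 0.05`; observed ≈ 1e−4).

## Known limitations

* Box constraints only; no constraint handling, no parallel evaluation.
* The wrapper's fitness definition is an inference (see above); fitness
  magnitudes are comparable within this package, not to any external
  report.
* The CART grower is written for clarity at test scale (hundreds of
  samples, tens of features); it is not an optimized random-forest
  implementation.
* k-NN fitness is O(n²·|mask|) per evaluation; mask caching keeps the
  default protocols fast, but very large n calls for a cheaper classifier.
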