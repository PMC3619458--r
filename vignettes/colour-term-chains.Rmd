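---
title: "Simulating the cultural evolution of colour-term systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the cultural evolution of colour-term systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colchain)
```

## The question and the modelling strategy

Colour lexicons with two to six terms recur across unrelated languages
with very similar category layouts. If learners share perceptual and
inductive biases, repeated cultural transmission should amplify those
biases until naming systems converge on the forms the biases favour,
with no selection between speakers required. `colchain` packages that
argument twice over:

* **Theory**, on spaces small enough to enumerate: the neutral
  replicator dynamics, the iterated-learning Markov chain, and the
  Bayesian learner's prior all single out the same distribution, and
  the package verifies the three-way identity exactly.
* **Simulation**, at the scale of the World Color Survey (WCS): chains
  of synthetic learners transmit naming systems over the 330-chip
  Munsell array, and the pipeline measures their convergence towards a
  reference corpus with variation of information (VI), guards the
  result with a rotation null control, and contrasts it with a
  second-corpus control.

Human participants and the WCS field data themselves are outside the
package's scope; a synthetic corpus generator and a parameterised
learner stand in for both, which makes every analysis reproducible
from a seed and lets the test suite exercise the full pipeline.

## The stimulus array and its geometry

`build_wcs_array()` returns the canonical 330-chip grid: 40 hue
columns at 8 lightness rows plus a 10-level achromatic column. Hue is
circular (column 40 neighbours column 1); rows are indexed 0–9 from
light to dark so real WCS charts map onto the grid by a thin adapter,
and an adapter for files with a different hue origin only needs to
rotate columns. `perceptual_embedding()` places chips on a cylinder —
hue angle on a circle of radius `rho`, lightness on the axis — giving
the synthetic learner a geometry in which both hue and lightness
distances are meaningful.

Two embedding parameters matter:

* `rho` (default **3.0**, in lightness-row units): with 40 uniform hue
  steps, adjacent hues are `2 rho sin(pi/40) ≈ 0.47` rows apart, finer
  than the unit lightness spacing, so hue-contiguous categories are
  easier to carry across generations than arbitrary chip sets. The
  value is tunable; anything that keeps hue spacing below lightness
  spacing behaves similarly.
* `warp` (default **0** in the embedding; the study regime uses
  **0.8**): widens the angular step at six *anchor boundaries* (after
  hue columns 6, 14, 24, 29, 33, 40) by a factor `1/(1 − warp)`. This
  models a shared, non-uniform perceptual metric — the package's
  analogue of the biases human learners bring. Category boundaries
  are cheapest to maintain inside the stretched gaps, so transmission
  drifts systems onto the anchors. The anchor set is deliberately
  aperiodic (gaps 6, 8, 10, 5, 4, 7): no non-zero rotation of the hue
  circle maps more than one anchor back onto the set, which is what
  gives the rotation null control its contrast. With a periodic
  anchor set the rotation profile would itself be periodic and
  rotations by the period would spuriously fit.

## Naming systems and initial partitions

A naming system maps chips to terms; partial labellings are allowed so
aggregate field data with unlabelled chips can be represented. The
three initial-partition generators mirror the standard chain design:

* `hue_partition()`: k contiguous hue bands of near-equal width
  (widths differ by at most one column, wider bands leftmost — the
  deterministic choice among the "approximately equal" splits), with
  the achromatic column attached to a seeded random band since it has
  no hue of its own.
* `lightness_partition()`: k contiguous row groups (sizes again ±1,
  larger groups at the light end), fully deterministic.
* `random_partition()`: a seeded uniform shuffle with balanced term
  counts (exactly equal when k divides 330, otherwise ±1 — the closest
  realisable version of "equal numbers of each term").

`rotate_hue()` shifts labels rightward around the hue circle, leaves
the achromatic column fixed (it has no hue), and reduces steps modulo
40. `minority_terms()` flags terms labelling strictly fewer than 5% of
chips, the conventional threshold for reporting vestigial categories.

## The VI metric and corpus averaging

All information quantities use natural logarithms (nats); the base
only rescales VI, and no published value constrains it. Pairs of
systems are always compared over the chips labelled by both, which is
what makes partial (aggregate) systems comparable — `log(n)` bounds
then refer to the common-chip count. Internally systems are
integer-coded once per corpus, so corpus-scale comparisons (hundreds
of thousands of pairs) stay fast in plain R.

Corpus comparisons average in two stages — speakers within a language,
then languages — so that heavily sampled languages do not dominate.
Weighted averaging is deliberately not the default; it would change
the baseline against which chains are judged. The corpus-internal
baseline (`corpus_pairwise_vi()`) averages all cross-language speaker
pairs within each language pair before averaging over language pairs,
and per-language scores for the pooled two-sample comparison are row
means of the same language-pair matrix, computed once.

`closest_language()` averages over a window of iterations, default
4–13: early iterations still carry the arbitrary initial partition,
and the window matches the chain length of the standard design.
Within-window ties between languages resolve lexicographically, making
reports deterministic.

## The synthetic learner

`exemplar_learner()` labels chip *c* with term *t* with probability
proportional to `Σ_e exp(−d(c, e)/tau)` over training exemplars *e* of
term *t*, with *d* the Euclidean distance in the embedding. `tau`
(default **0.3**, in embedding-distance units) sets generalisation
noise: roughly e-fold weight decay per 0.3 rows of distance, i.e.
sharp but not deterministic category edges. `tau = 0` is the exact
nearest-exemplar rule with uniform tie-breaking. Only terms present in
the training data can be produced, so inventories are upper bounds and
rarely-sampled terms can die out along a chain — the source of
minority terms and term loss in long runs.

The learner is a stand-in, not a model of human colour cognition: it
has no memory limits, no pragmatics, and its biases live entirely in
the embedding geometry (`rho`, `warp`). Those two knobs are exposed in
the study configuration precisely because they *are* the hypothesis
under study: with `warp = 0` the learner still compacts systems (VI to
any coherent corpus falls) but has no preferred hue positions, and the
rotation control correctly reports nothing.

## The synthetic reference corpus

`generate_synthetic_corpus()` emulates a WCS-scale corpus with
defaults of **110 languages × 10 speakers**. Each language draws a
term count from 2–6 and a template of contiguous hue bands whose
boundaries sit on the anchor columns (a random starting anchor, then
near-evenly spread); with probability `p_lightness` (default **0.3**)
one term instead covers the darkest rows, giving the corpus a share of
dark/light-stripe systems alongside pure hue systems. Speakers
reproduce their language's template with per-chip noise `noise_eps`
(default **0.05**): a flipped chip takes the template label of a
random grid neighbour, so disagreement concentrates at category
boundaries, as in real naming data, rather than appearing as salt-and-
pepper noise. `noise_eps = 0` collapses each language to identical
speakers, a useful degenerate case in tests.

What the generator does *not* emulate: focal-colour prototypes and
graded membership, informant-specific response styles, within-language
dialect structure, and any non-category structure of real Munsell
colorimetry. Passing tests therefore show that the pipeline detects
hue-anchored convergence when it exists by construction; they do not
certify the learner or corpus as models of human data.

The second (control) corpus defaults to a single 6-term language of 9
tightly coherent speakers (`noise_eps = 0.02`) whose anchor structure
is rotated 2 columns off the shared anchors. Converged chains stay far
from it relative to its internal coherence, with a pooled two-sample
t on 20 + 9 − 2 = 27 degrees of freedom — the analogue of checking
that chains are not simply reproducing the majority language of the
experimenters.

## Chains, design, and reproducibility

`build_experiment_design()` fixes the standard 30-chain design: per
term count k ∈ {2,…,6}, four random-initial chains plus one hue and
one lightness chain, 13 learner generations each, training sets of
`6k` chips drawn without replacement (training data are "shown", so
duplicates would be wasted slots). All randomness flows from one
master seed through a named-stream hash (chain id × generation ×
role), so any chain can be re-simulated in isolation and full studies
are byte-identical on rerun.

## The evolutionary-dynamics module

`replicator_derivative()` implements
`dx_i/dt = Σ_j Q[i,j] f_j x_j − φ x_i`; with uniform fitness the
simplex constraint reduces it to the linear neutral model
`dx/dt = Qx − x` (the suite checks the reduction to 1e−14 on random
states). **Q is column-stochastic** — `Q[i,j]` is the probability of
acquiring hypothesis *i* from a teacher holding *j*; the literature
splits on this orientation, hence the prominent note.

`stationary_distribution()` refuses to answer when the unit-circle
eigenvalue is not unique (reducible or periodic chains) rather than
returning an arbitrary vector. `integrate_dynamics()` uses `lsoda` at
`rtol = 1e-12`, `atol = 1e-14`; at these tolerances trajectories
conserve the simplex to better than 1e−12 without any projection step,
so conservation is a genuine accuracy check rather than an enforced
invariant.

The enumerable hypothesis space is a ring of `n` sites with two
categories, restricted by default to contiguous systems (the two
uniform labellings plus every labelled arc, `n(n−1) + 2` hypotheses) —
the smallest structure that is colour-like (circular) while keeping a
non-uniform prior `∝ exp(−β · boundaries)` that favours simple
systems. The full `2^n` labelling space is available via
`contiguous = FALSE`. Likelihoods observe a uniformly chosen site with
label-flip noise ε. `build_q_matrix()` sums over *all*
`(2n)^data_size` data sequences, so the stationary-equals-prior
identity is checked by exact enumeration (it holds to machine
precision, ~1e−16); a Monte-Carlo path exists for spaces too large to
enumerate, with error of order `1/sqrt(mc_samples)`.

The demonstration space is fixed at `n = 5, β = 2, ε = 0.2,
data_size = 3` (22 hypotheses). The choice is a statistical design
decision made up front: the empirical-chain comparison runs 1e5 steps,
and a total-variation gap below 0.01 requires a small space with a
concentrated prior — the expected sampling TV for this configuration
is ≈0.005. Larger, flatter spaces would need chain lengths that buy no
additional insight, since the exact enumeration identity already
carries the theorem at any size.

## The three analyses and their statistics

* **Convergence** (`convergence_analysis()`): per-chain, per-iteration
  mean VI to the reference, the across-chain curve, a paired t between
  iteration 0 and the final iteration, and a Spearman trend test on
  the averaged curve. The corpus-internal baseline and a pooled
  two-sample t (20 chains vs 110 per-language scores → 128 df) locate
  the converged level relative to cross-language diversity.
* **Rotation null** (`rotation_analysis()`): mean VI of each final
  system rotated 0–20 hue columns; paired t tests compare offset 0
  with the landmark offsets 5, 15 and 20 — quarter, three-quarter and
  maximum of the tested range. ("Quarter" could also mean 10 of the
  40 columns; the landmarks are an argument, so either reading is a
  one-line change.) A genuinely hue-anchored match is minimised at
  offset 0; rotation by 40 is the identity by construction.
* **Second corpus** (`second_corpus_comparison()`): per-final VI to
  the control corpus versus the control speakers' internal coherence,
  pooled two-sample t.

t statistics use the classical pooled form by default (Welch is a
switch) because the pooled degrees of freedom are the quantity of
record for this design. Degenerate zero-variance inputs return `t = 0`
when the means agree and are an error otherwise.

## Problem sizes and runtime

The default study — 110 × 10 corpus, 30 chains × 13 generations,
21-offset rotation profile — runs in about a minute on one core; the
package's test suite runs the same conditions. The VI hot path is
integer-coded tabulation, so the ~10⁶ pairwise comparisons behind a
full study need no compiled code.

## Known limitations

* The warped embedding is a minimal stand-in for shared perceptual
  structure; it produces anchored convergence but no focal-colour or
  lightness asymmetries beyond what the templates impose.
* VI between systems with very different term counts is dominated by
  the entropy difference; the `language_filter` argument supports
  restricting comparisons to equal-term-count languages, but that
  restriction is not the default.
* The Bayesian theory checks cover posterior-*sampling* learners only;
  maximising (MAP) learners have a different stationary distribution
  and are not implemented.
* Chain serialisation stores every generation's labelling but not the
  training sets; re-read chains support all analyses, not re-simulation.
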