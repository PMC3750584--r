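---
title: "Target Inhibition Maps: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target Inhibition Maps: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timkit)
```

## The problem and the modeling assumptions

A targeted drug screen applies m multi-target kinase inhibitors to a
primary tumor culture and records one IC50 per drug.  Independently, each
drug carries a panel of EC50 values — the concentration at which it
half-inhibits each kinase target — which is a property of the compound,
fixed across tumors.  `timkit` treats the screen as a set of *functional
perturbations of unknown combination*: each drug simultaneously knocks
down the targets whose EC50 is commensurate with the concentration that
killed the culture, and the response pattern across drugs is used to
infer which target combinations the tumor's survival actually depends on.

The framework rests on three assumptions:

1. **Kinase inhibition is the mechanism.**  A drug's effect on viability
   is attributed entirely to the targets it inhibits at the relevant
   concentration; off-mechanism toxicity is absorbed into the window
   parameters.
2. **Targets act as tumor promoters.**  Inhibiting a superset of an
   effective combination stays effective, and a subset of an ineffective
   combination stays ineffective.  Tumor-suppressor (NOT) and XOR
   relationships are out of scope.
3. **The circuit is static.**  Screens measure a steady-state snapshot;
   the inferred map constrains, but does not determine, dynamics (see the
   dynamics section).

## From IC50 to sensitivity, and from EC50 to binary hits

`scale_sensitivity()` maps IC50 to y ∈ [0,1]: y = 1 below Cmax (the
maximum clinically achievable dose, in nM), y = 0 at or above MaxDose
(the maximum screened dose) or when no IC50 was reached, and
y = c·(1 − log(IC50)/log(MaxDose)) in between.  The constant
c = 1/(1 − log(Cmax)/log(MaxDose)) makes the two branches continuous at
Cmax; the alternative constant 1 − log(Cmax)/log(MaxDose), which leaves a
jump at Cmax (y(Cmax) = (1 − log(Cmax)/log(MaxDose))², not 1), is kept
behind `continuity_fix = FALSE` for compatibility.  Scores are optionally
min–max rescaled per culture (default on) so the screened panel spans
[0, 1].

`binarize_targets()` calls target j a hit for drug i when
α·log(IC50ᵢ) ≤ log(EC50ᵢⱼ) ≤ β·log(IC50ᵢ).  Parameters, all
configurable via `binarization_config()`:

* **α (default 0)** — lower window multiplier.  0 keeps every strong
  (low-EC50) side target in scope, which matters because synergy between
  a strong and a weak target is common.
* **β (default 2)** — upper window multiplier.  β = 2 admits side targets
  with EC50 up to IC50² (on the log10 scale) without letting far-off
  interactions into the profile; values of 3–4 are reasonable for noisier
  panels.
* **log base 10, floor 1.01 nM** — all concentrations are floored just
  above 1 nM before logs so that every log is strictly positive;
  sub-nanomolar IC50s would otherwise flip the window inequality.

A drug whose window captures no target is flagged `excluded` and never
reaches target selection — it carries no usable inhibition information.
A drug whose IC50 was *not reached* scores y = 0 but is still binarized,
using MaxDose as the window anchor: its achievable inhibition profile is
informative negative evidence, and the published cross-validation tables
this design mirrors keep such drugs in training.

## Target selection

`gamma_score()` implements the target-set objective: within-bin absolute
deviation from bin means, plus |P(bin) − y(drug)| for every drug/bin pair
violating the promoter rules (a bin whose pattern is a strict subset of
the drug's with a *higher* mean, or a strict superset with a *lower*
mean).  Score comparisons use a strictness tolerance ε = 10⁻⁹ so float
noise never counts as a violation.  The penalty sums over *all* related
bins, not just the nearest, which penalizes globally inconsistent
partitions more strongly.  Evaluation is O(m²) in the number of drugs.

`sffs_select()` minimizes Γ by sequential floating forward search: the
forward step adds the candidate minimizing Γ (ties toward the lowest
target index); the floating backward step repeatedly removes the member
whose removal scores best, as long as the reduced set beats the best set
previously recorded at that cardinality.  The search runs to the
cardinality cap (default 20 in the API, 8–12 in the harnesses) rather
than stopping at the first pass without improvement — in testing, the
early-stopping variant matched the exhaustive optimum on only ~83% of
random instances, while the floating variant with per-cardinality records
matches it essentially always at these sizes.  The final set is pruned so
that no member can be removed without increasing Γ, implementing the
minimal-cardinality aim; remaining ties break toward smaller sets.

## The Target Inhibition Map

`build_tim()` stores the experimental bin means (several drugs sharing a
restricted pattern are averaged, keeping the map consistent with Γ) and
anchors all-zeros at 0 ("no treatment does nothing") and all-ones at 1
("inhibiting every relevant target is effective") unless experimental
entries override them.  For an unknown combination, `tim_bounds()` finds
the best known subset (y_l) and worst known superset (y_u) — ties toward
the Hamming-closest combination, then the smallest pattern — and the
pairwise interpolant adds the weighted fraction of transition targets,
raised to the discount n:

* **discount n (default 1)** — linear interpolation.  Larger n is more
  pessimistic about partial inhibition; smaller n more optimistic (every
  strictly interior prediction increases as n decreases).
* **weights α (default uniform)** — per-target relevance scores from
  prior knowledge; uniform weights reduce the ratio to d/h exactly.

**Monotone envelope.**  The pairwise interpolant alone is not globally
monotone: two nested queries can snap to different anchor pairs, and a
well-supported subset (tight superset anchor) can out-predict a sparsely
supported superset.  A concrete 6-target counterexample with perfectly
consistent data arose in testing.  `infer_sensitivity()` therefore
returns the monotone envelope — the maximum of the interpolant over all
subsets of the query.  The envelope still respects the subset/superset
bounds (a superset's upper bound is never tighter than its subsets', so
the maximum cannot exceed y_u) and restores the monotonicity the promoter
rules promise.  Experimentally observed combinations always return their
stored value, so non-monotonicity present in the data itself stays
localized to known entries; when bounds cross (y_l > y_u) the upper bound
is clamped up to y_l with a warning naming the offending combinations.

Dense mode (automatic for ≤ 16 targets) materializes the full table with
a subset-maximum sweep, one pass per bit; lazy mode enumerates the
query's subsets and is intended for sparse queries over large maps (it
refuses queries with more than 22 inhibited targets).

## Circuits

`minimal_equation()` searches combinations breadth-first by size up to M
(default 4, keeping the O(n^M) search desk-scale for ~20 targets),
accepting a combination when its sensitivity meets the binarization
threshold — θ_e (default 0.5) for experimentally observed combinations,
θ_i (default 0.5) for inferred ones; 0.5 is the natural midpoint of the
sensitivity scale.  Monotonicity lets accepted branches close: any
superset is also effective, so the result is the set of minimal effective
combinations.  Experimental combinations of any size above θ_e are
admitted as terms but not expanded further.  An inference-only term
contradicted by a sub-threshold experimental *superset* is dropped with a
warning (a low experimental superset is the only observation that can
contradict a claimed effective term under monotone semantics).  The
no-treatment combination is never a candidate term, even in the
degenerate case where its experimental value exceeds θ.

`group_blocks()` renders the equation as the block circuit: it greedily
factors the target shared by the most uncovered terms into its own line
and recurses on the cofactors; term groups that do not form an exact
cartesian product fall back to singleton blocks.  The expansion of every
block is checked against the covered terms, so the heuristic can never
change the equation's semantics — only its layout.  `render_circuit()`
emits deterministic DOT.

## Cross-validation

`loo_evaluate()` and `kfold_evaluate()` retrain the *entire* pipeline —
target selection included — on every training split; reusing a globally
selected target set would leak test information through the target set.
Binarization-excluded drugs are listed in the report but excluded from
denominators.  k-fold partitions are drawn from the supplied seed and the
caller's RNG state is restored afterwards; k equal to the number of
usable drugs with one repeat reduces exactly to LOO.  Reports carry the
per-drug error table (drug, error, predicted, experimental), the MAE and
the Pearson correlation (per culture; pooled over repeats for k-fold).

`drug_similarity()` implements the EC50-overlap measure
Λ = Σ min(E₁, E₂)·V₁·V₂ / Σ max(E₁, E₂) exactly as stated: shared
targets contribute their smaller EC50 to the numerator, the union
contributes its larger EC50s to the denominator.  Note the formula does
*not* give 0.5 for two drugs sharing half their targets at equal EC50s in
general — the denominator includes the non-shared EC50s — and no
correction is applied here.

## The synthetic benchmark

`run_benchmark()` emulates the study conditions of the synthetic
pathway-recovery experiments: for each active-target count n ∈ {6,…,10},
40 replicate random block pathways; each pathway embedded in a universe
of n active plus 10 decoy targets; a 1000-drug library in which each drug
inhibits a Poisson(λ = 3, minimum 1) number of uniformly drawn targets;
60 training and 40 disjoint test drugs; Boolean ground-truth
sensitivities (1 exactly when the drug cuts every parallel line of some
serial block); predictions thresholded at 0.5; a coin-flip baseline
reported alongside.  The pathway generator partitions the active targets
into at most 3 serial blocks of at most 3 parallel lines by uniform
random composition.  The library and pathway distributions are not
published, so these defaults are this package's own calibration, chosen
as desk-scale values a screen designer would consider realistic and kept
fixed; all results are reproducible from a single RNG seed.

What passing this benchmark shows — and does not show: the generator
produces exactly Boolean, noise-free responses from promoter-rule
pathways, so high accuracy demonstrates that the selection + inference
machinery recovers monotone Boolean structure from sparse combinatorial
sampling.  It does not demonstrate robustness to EC50 curation errors,
window misspecification or non-kinase mechanisms, which real screens
contain.

The acceptance script (`scripts/acceptance.R`) runs this benchmark at
full size (40 replicates × 5 active-target counts, 8 000 test
predictions) in a few seconds; the test suite runs a reduced 8-replicate
version against the same 89% floor.

## Parameter recovery under noise

The recovery experiment in the test suite synthesizes a screen from a
known two-block pathway — two parallel single-target lines (cut set
{K1, K2}) in series with one two-target line (cut sets {K3}, {K4}) —
among 3 decoys, with Gaussian readout noise σ = 0.05.  Two design points
matter:

* **Replication.**  The screen covers every singleton and pair three
  times; bin means then average the noise, and LOO errors stay near σ.
* **Search depth matches screen depth.**  The equation search cap is set
  to the screened combination depth (M = 2): terms deeper than the
  deepest screened combination are supported only by interpolation and
  are not identifiable from such a screen.  With a dense random screen
  instead, the Γ penalty term — which charges every noisy subset/superset
  bin pair — grows with the number of comparable bins and biases
  selection toward coarser target sets; a designed combination screen
  avoids this regime.

## Network dynamics layer

`pathway_to_bn()` converts a directional acyclic activation pathway into
a deterministic Boolean network over 2^(n+1) states (n target bits plus a
phenotype bit, the least significant).  Transition rules: mutated or
latently activated targets switch on within one step; other targets copy
their gate (OR by default — the relation most commonly found in curated
pathways — AND configurable per node) over upstream activators, and
switch off when upstream support vanishes; the phenotype bit copies the
tumor driver's activation of the previous step.  `apply_inhibition()`
forces the inhibited targets to 0 in every successor state (an idempotent
transform; the empty set is the identity), and `tim_from_bn()` scores
each of the 2^n inhibition combinations by the attractor reached from the
all-active state.  For limit cycles (possible under mixed gates) the
convention here — a stated choice, conservative for treatment decisions —
is that a cycle visiting any tumorous state counts as tumorous.
`structure_to_bn()` lays a block structure out as one concrete
directional network whose dynamics-derived map provably coincides with
the static Boolean sensitivity, which the tests use as a cross-module
consistency oracle.

`count_models()` evaluates the L!·∏(b_j^i)! ceiling on distinct dynamic
models consistent with a block structure, and `experiment_bounds()` the
experiment-design bounds for orienting it: expected (2L−1)/3 steady-state
perturbation experiments to order L ≥ 2 serial blocks (0 for a single
block), plus per-block worst-case and expected-case terms.  Numerical
conventions (the source expressions are partly garbled): the inner
expected-case numerator is read as Σ_j(2b_j − a), the trailing symbol as
−1, per-block terms are floored at 0 (a negative experiment count is
meaningless, e.g. for single-target lines), and the ceiling term is
skipped for single-line blocks.  With these conventions the worst-case
bound dominates the expected-case bound on every structure tested.

## Degenerate inputs and numerical conventions

* Ties in SFFS break toward the lowest target index, then smaller sets.
* An empty selected target set (nothing separates the drugs) predicts the
  grand-mean sensitivity for everything.
* A test drug hitting no selected target projects onto the all-zeros
  combination (prediction 0 unless an experimental empty-pattern bin
  exists).
* Both-empty drug profiles get similarity 0 with a warning.
* JSON artifacts are versioned, sorted by pattern, and byte-identical
  across runs; DOT output is deterministic.

## Known limitations

* No NOT/XOR circuit elements (tumor suppressors are out of scope).
* Continuous inhibition profiles bridge to the binary map only by
  thresholding at 0.5; no fully continuous map lookup is provided.
* Lazy (non-dense) inference is exponential in the number of *inhibited*
  targets of a query due to the monotone envelope.
* Hyperparameters (α, β, θ, n, M) are configuration inputs; no nested
  cross-validation is provided for tuning them.
* The dynamics layer requires an acyclic activation graph and n ≤ 16
  targets for exhaustive attractor scans.
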