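---
title: "Merging genome-scale metabolic models into a consensus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging genome-scale metabolic models into a consensus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmerge)
```

# The problem

Genome-scale constraint-based metabolic models (GSMs) of the same organism,
built independently, agree on surprisingly little: different metabolite
namespaces, different granularity (lumped pathways, polymer subunit counts),
different cofactor choices, different compartment layouts. A consensus model
that unites two or more initial GSMs is more comprehensive and more
consolidated than any single input, but building one by hand takes expert
communities years. `gsmerge` automates the identification of the
inconsistency classes that arise in merging and resolves the unambiguous
ones automatically, recording every action in a replayable decision log; the
genuinely ambiguous cases are returned as pending items for user review.

The package covers three coupled inconsistency levels:

* **Metabolites** — identical compounds under different identifiers, and
  distinct compounds that play the same role in their network context
  (granularity variants such as `glucose` vs `alpha-D-glucose`, polymers
  with different subunit counts).
* **Reactions** — identical net reactions written in opposite directions,
  alternative stoichiometries, redox-pair swaps (NADH vs NADPH), nested
  (cofactor-optional) reactions, partially overlapping reactions, and lumped
  vs step-wise pathway representations.
* **Compartments** — 2- vs 3-compartment layouts, alternative and invalid
  transport reactions, boundary reactions placed on intracellular species,
  and species parked in an explicit unknown compartment (`UNK_COMP`).

# Network-context metabolite matching

The core novel step characterises each metabolite by *which other
metabolites and genes share a reaction with it*. A boolean
metabolite-by-metabolite co-occurrence block is stacked on a boolean
gene-by-metabolite block; each row (attribute) is divided by its row sum, so
an attribute connected to few metabolites is more *defining* than a hub
(currency metabolites contribute almost nothing). Rows for entities absent
from either model are dropped — only context shared by both models can
identify a match — and columns are computed per source model.

Candidate cross-model pairs are scored by the Pearson correlation of their
attribute columns. The decision threshold is not fixed: it is a percentile
(default 5) of the score distribution of metabolites *known* to be shared
between the models, each scored between its two per-model context columns.
This calibrates the cutoff to however noisy the two models happen to be.
Proposals are assigned greedily one-to-one by descending score with a
lexicographic tie-break.

Numerical choices: a column with zero variance has no usable context signal;
its Pearson correlation is undefined and the metabolite is excluded from
scoring rather than scored 0, since a silent 0 would compete with genuine
negatives. Matching is per-compartment; cross-compartment identity is the
business of the compartment methods.

Merging a confirmed pair re-points stoichiometries and cancels exact
same-metabolite contributions. When both members carry elemental formulas
and the formulas disagree, the pair is **held** instead of merged: merging a
4-subunit with a 5-subunit polymer would let the model create mass from
nothing. Automatic confirmation is available but off by default.

# Reaction-level detectors

All detectors work on views of the stoichiometric matrix $S$ ($m \times r$):

* **Identical net reactions** use the double matrix $[S, -S]$: a canonical
  signature takes the lexicographically smaller of a column and its
  negation, so opposite writings of the same conversion collide. With the
  currency filter enabled (default), proton and water rows are zeroed first
  ("practically identical" nets).
* **Alternative stoichiometries** compare the boolean support of columns;
  groups with equal support but unequal coefficients are reported. A group
  auto-resolves only when elemental formulas are known for every member and
  *exactly one* member is balanced.
* **Redox variants** substitute each known redox couple (NAD/NADH,
  NADP/NADPH, FAD/FADH2, ...) by a unit entry in an artificial "redox pair"
  row, then reuse the support comparison. Candidate couples can be suggested
  from the data: pairs sitting on opposite sides of the same reactions in at
  least 80% of their occurrences.
* **Nested reactions** are support-subset pairs confirmed by a
  side-agreement rule: at least two metabolites sharing a side in the inner
  reaction also share a side in the outer one. Requiring two shared-side
  metabolites is stated behaviour; a single shared metabolite per side is
  not taken as confirmation.
* **Similar reactions** are cross-model pairs sharing at least a configured
  number of genes, substrates and products (all three jointly).

## Lumped reactions by linear programming

A lumped reaction and its step-wise representation cancel at steady state
when run in opposite directions. The model is made all-forward (backward
reactions reversed, reversible reactions split; boundary columns removed)
and we solve

$$\max c'x \quad \text{s.t.} \quad S_{irr} x = 0,\; lb \le x \le ub$$

with $c_j = -1$ everywhere (minimal total flux) except $c_{LR} = -1000$ for
the candidate, whose lower bound is relaxed to $-1$. A nonzero optimum means
a pathway can compensate a unit of backward flux through the candidate; its
support is a non-lumped set. Found sets are penalised by tripling their
objective coefficients and the LP is re-solved, so alternative pathways
surface, until the solution is zero, a set recurs, or a set exceeds the size
cap (default 5). Sets are filtered by gene overlap with the candidate
(default: at least one shared gene; skipped when the candidate has no GPR).
When the candidate itself is reversible, its own reverse split column is
clamped to zero during its run — otherwise the trivial self-cancellation
would always "explain" it.

The LP core is a bounded-variable two-phase primal simplex implemented in
the package (`lp_solve()`). Steady-state instances are maximally degenerate
(every right-hand side is zero), so the pivoting rule switches to Bland's
rule after an iteration threshold, the basis inverse is refactorised
periodically, and fluxes below 1e-9 are treated as zero when supports are
read. The solver is validated against a vertex-enumeration oracle on small
random LPs in the test suite.

# Compartment-level methods

A transport reaction is operationally a reaction in which the same
metabolite id appears in two compartments. From this follow: the compartment
connectivity graph (edges the user can flag invalid, yielding the invalid
transport report); alternative-transport groups (two or more reactions
moving one metabolite across the same membrane); and per-compartment
matrices whose identical compartment-stripped columns reveal the same
conversion placed in two compartments.

Transport splitting replaces a direct A→C transport by A→B and B→C legs with
the same net reaction. The chemistry (protons, ATP cost) is assigned to one
leg — default the target-side leg, a choice the format cannot decide and the
log records — and the other leg is plain diffusion. During automatic
refinement a direct transport is split only when another source model moves
the *same metabolite* through an intermediate compartment; this
metabolite-specific rule avoids splitting everything that crosses a membrane
merely because two models have different compartment counts.

Removing a compartment re-points every removed-compartment species to the
target compartment with exact cancellation. The four published reaction
categories fall out of one rule: intra-compartment reactions move; pure
removed-target transports cancel completely and disappear; transports with
chemistry keep their conversion; reactions touching third compartments keep
their transport role. Orphaned metabolites are pruned and the model's
exchangeable-metabolite set is unchanged.

Boundary reactions belong on the extracellular compartment. An invalid
boundary (a merging artefact on a cytosolic species) is repaired by
re-pointing it to the extracellular instance and adding a reversible
transport, which preserves net exchange capability.

# The pipeline and the decision log

`build_bcm()` harmonizes compartment naming (alias map; cytosol, periplasm,
extracellular and mitochondrion aliases ship with the package), takes the
naive union with full per-entity provenance, and merges *strictly* identical
cross-model reactions. `auto_refine()` then runs the four automatic steps in
a fixed order: (1) metabolite matching and merging, (2) transport splitting,
(3) merging of practically identical nets (currency species ignored), (4)
unique-balanced selection among alternative stoichiometries. Direction
conflicts become reversible under the default policy; a pluggable predictor
hook can decide instead (no predictor ships with the package). GPR conflicts
merge by OR under the `union` policy; the `strict` policy keeps a rule only
when one gene set contains the other and otherwise holds the group for
review.

Every applied resolution is one log entry; `replay()` re-derives the output
from the inputs and the log byte-identically, after verifying input digests.
Pending items are returned, never dropped, and can be answered headlessly
through `review_answers()`.

# The synthetic fixture generator

`generate_fixtures()` is first-class, tested code, not a throwaway test
helper: it builds a pair of models that *share* a linear backbone (uptake →
chain → biomass → export) with branch pathways and a currency layer (ATP,
NAD pools, proton exchange), then plants one labelled instance per requested
inconsistency class, exactly mirroring the classes above: synonym renames,
a balanced-vs-unbalanced stoichiometry pair, a polymer pair with no usable
formulas, cross-model duplicates differing only by a proton, NADH/NADPH
twins, a cofactor-optional nested pair, a lumped reaction against one or two
explicit chains, alternative transporters, direct-shortcut invalid
transports, an invalid boundary, and unknown-compartment reactions with and
without a resolvable twin. Model A routes uptake (and proton export) through
a periplasm while model B transports directly, so the 2- vs 3-compartment
harmonization is exercised on every run.

Default sizes (8-metabolite backbone, 4 branches, 1–3 instances per class)
keep a full pipeline run under a second while leaving enough shared context
for threshold calibration. Generation is deterministic given the spec and
seed. The generator emulates the *classes* of disagreement between real
model pairs, not real stoichiometry: real GSMs have thousands of reactions,
heavier hubs, and much sparser gene annotations, so perfect recovery on
fixtures demonstrates correctness of the algorithms, not expected field
performance on organisms.

# Evaluation

Growth phenotypes are predicted by flux balance analysis: the medium sets
uptake bounds on boundary reactions, knockouts zero the bounds of reactions
whose GPR evaluates false, and biomass flux is maximised. A wild type grows
iff its flux exceeds 1e-6; a mutant grows iff it reaches 30% of the
wild-type flux — both printed defaults, both configurable, and both tested
at their boundary values. Confusion-matrix summaries report sensitivity,
specificity, accuracy and the Matthews correlation coefficient (defined 0
when a denominator factor vanishes). Reaction activity uses flux variability
with an open objective and a 1e-9 tolerance.

One property deserves a caveat: "every active input reaction stays active in
the consensus" is checked by tracing each input reaction through the
decision log to its consensus descendants. Reactions whose currency-filtered
net stoichiometry is empty (pure proton/water plumbing) are excluded from
the property — under a policy that deliberately ignores protons in net
comparisons, a merge may legitimately adopt the proton-free writing and idle
the proton drain.

# Design decisions and limitations

* **Doubles, not exact rationals.** Coefficients are stored as doubles with
  canonical 9-digit rounding inside comparison signatures and a 1e-9
  cancellation tolerance. No rational-arithmetic dependency is available to
  the package, and the coefficients occurring in practice (small integers
  and simple fractions) are exactly representable; the signature rounding
  makes the comparisons robust to the residual risk.
* **Offline namespace mapping.** Identifier conversion applies a local
  MNXref-style table with a reviewable proposal list; no web service is
  contacted. Same-reaction collisions are flagged `conflict` and never
  auto-merged.
* **Overlap denominator.** Shared fractions use |intersection| / |union| by
  default; a per-smaller-model convention (|intersection| / min(|A|,|B|)) is
  available via `overlap_denominator = "min"`. Both compartment-distinguished
  instances and unique compounds are reported, since published percentages
  rarely state which convention they count.
* **Survivor and tie-breaks.** Merges keep the lexicographically smallest
  reaction id (radix order, locale-independent); score ties break
  lexicographically; recurring lumped sets are detected by sorted-id
  hashing. These choices make whole runs reproducible bit-for-bit.
* **Biomass.** Biomass reactions are never matched — models write them too
  differently — so the user picks one input's biomass reaction and the
  others are retained with zero bounds.
* **Not goals.** No thermodynamic direction assignment, no
  chemical-structure similarity, no gap-filling, no fitting of the model to
  phenotype data: the consensus represents the union of the inputs'
  knowledge, not a model optimised for predictive scores.

# Problem sizes used in the shipped checks

The test-suite and the acceptance script run the full pipeline on generated
pairs of roughly 45–70 reactions, the detector-vs-oracle comparisons on 200
random models of 15–100 reactions, and the matching degradation protocol at
0/30/60/90% hidden context over 20 random repeats. These sizes give stable
statistics and complete in a few minutes on one CPU; all of them are
parameters of `fixture_spec()` and scale up directly.
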