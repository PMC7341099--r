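---
title: "Methods: models, parameters and design choices in loopscreen"
author: "loopscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in loopscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscreen)
```

# The problem

Mature miRNAs guide Argonaute to their target mRNAs; the imperfect hybrid
the two strands form leaves unpaired regions — loops — that concentrate
near the miRNA seed (positions 1–10) and constitute structurally defined,
potentially druggable pockets. `loopscreen` provides the pieces of a
loop-centred virtual screen: a folding engine for the joined miRNA–mRNA
strand, loop detection and profiling, seed-constrained target-site
prediction, an accessibility-corrected interaction-energy model, a
1250-dimensional interaction featurization, a knowledge-based classifier,
docking-score bookkeeping, and consensus ranking.

This vignette documents the models, their assumptions, the tunable
parameters (with units and defaults), the numerical choices, and the
points where the design was genuinely open and a decision had to be made.
It claims no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

# Secondary structure

## Model and constraints

A secondary structure is a set of canonical pairs (Watson–Crick plus G·U)
subject to three constraints: a hairpin loop encloses at least three
bases (j − i > 3), each base has at most one partner, and pairs are
nested (pseudoknots excluded — a prerequisite of the dynamic program).
Every pair closes exactly one *loop* — the pair itself, the pairs
immediately interior to it, and the unpaired bases between them. A
stacked pair is a loop of size zero. Unpaired bases outside all pairs
form the exterior loop. The structure energy is the sum of its loop
energies; this additivity is what makes both the Zuker-style minimization
and the McCaskill-style partition function exact, and it is asserted
bit-for-bit in the tests.

## The embedded energy model

No parameter table accompanies the original loop-energy formulation, so
the package ships a small self-contained nearest-neighbour-style set
(`defaultEnergyModel()`), chosen once and used everywhere:

| term | default (kcal/mol) |
|---|---|
| closing-pair energy G·C / A·U / G·U | −3.0 / −2.0 / −1.0 |
| stack bonus (size-0 loop) | −0.5 |
| hairpin loop | 1.0 + 0.1·size |
| bulge loop | 2.0 + 0.3·size |
| interior loop | 1.5 + 0.25·size |
| multiloop | 3.0 + 0.4·branch + 0.1·unpaired |
| exterior loop | 0 |
| duplex initiation (intermolecular) | +4.1 |
| dangling flank | −0.3 per available base |

Temperature enters through RT with T = 310.15 K (37 °C) and
R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹. The magnitudes were fixed a priori to
reproduce qualitative RNA behaviour — G·C-rich helices dominate, a single
G·C-closed minimal hairpin is marginally stable (−1.7), an isolated
G·U-closed one is not — and were not adjusted afterwards. The model is a
plug-in: any `LoopEnergyModel` object can be substituted, so an external
thermodynamic parameterization can stand in without touching the
algorithms. All tests and the acceptance script run on the embedded
model, which keeps every number verifiable by exhaustive enumeration.

## Numerical choices

* **Tie-breaking.** Co-optimal structures are resolved by a deterministic
  traceback with a fixed exploration order (unpaired before paired,
  5′-most pairs first, hairpin before two-loop before multiloop). This
  yields a canonical, reproducible minimizer; it is not guaranteed to be
  the lexicographic minimum over the co-optimal set, only deterministic,
  which is the contract the tests rely on.
* **Placeholder linkers.** The joined miRNA–mRNA convention inserts an
  optional linker at the junction. Linker positions are encoded as a
  dedicated symbol (`N`) that can never pair and is excluded from
  composition features but counted as unpaired in structural state
  features. With unpairable semantics, the observed invariance of the
  fold to inserted placeholders holds by construction for the duplex
  pairs; `placeholderRobustness()` quantifies it as the fraction of
  0-linker pairs recovered after mapping to linker-free coordinates
  (1.0 when the 0-linker structure has no pairs).
* **Exact probabilities.** `unpairedProbability()` offers two exact
  routes: Boltzmann-weighted enumeration of all admissible structures
  (practical to ~30 nt) and a partition function evaluated twice — once
  unconstrained, once with the interval forced unpaired — whose ratio is
  Pu. Both recursions mirror the energy model exactly and agree to
  better than 1e−9 across randomized batteries; the `"dp"` route is the
  default at every length.
* **Degenerate inputs.** A sequence with no admissible pair folds to the
  all-unpaired structure with energy 0, has Pu = 1 for every interval,
  and ED = 0.

# Target-site prediction

The aligner performs a weighted dynamic-programming complementarity
search: global in the miRNA (whose first 5′ base and last two 3′ bases
are excluded from the alignment entirely), local in the UTR, against the
reversed UTR so the duplex is antiparallel. Defaults
(`siteScoringParams()`): score cutoff 120, gap open −9 charged on the
first gap base, gap extension −4 per additional base, match +5, G·U
wobble +2, mismatch −3, seed positions 2–8 weighted ×2. At most one
G·U-or-mismatch event is allowed at seed positions 2–7, and gap columns
are disallowed there (an open design point: the constraint names only
"a single G:U or mismatch", and a seed gap is at least as disruptive).
Canonical sites are those with a perfect, gap-free Watson–Crick 6-mer at
positions 2–7. Overlapping sites are resolved greedily by score, then
5′-most — the source protocol is silent on overlap handling, and greedy
by score is the common miRanda-style behaviour.

The substitution scores and the ×2 seed weight are documented
approximations of published miRanda-style defaults; only the cutoff and
gap penalties are fixed by the protocol. With these weights a perfectly
complementary 22-nt miRNA earns 130 (7 × 10 + 12 × 5), so a seed G·U
(−6) stays above the 120 cutoff while a seed mismatch (−16) does not —
single seed wobbles survive, everything weaker must compensate.

# Interaction energy

For a miRNA interval (i,k) against an mRNA interval (j,l), the combined
energy adds the minimal intermolecular duplex energy (ends required to
pair; interior bulges/interior loops scored as in the intramolecular
model; +4.1 initiation), the accessibility penalties
ED = −RT·log Pu of both intervals, and flank dangle terms weighted by
the conditional probability that the flanking base is unpaired given the
interval is — computed as Pu(flank ∪ interval)/Pu(interval), the natural
reading of the conditional that the formulation leaves implicit. A
missing flank (interval at a sequence end) contributes zero. Dangle
energy defaults to −0.3 kcal/mol per available flank base (configurable);
the per-position "pair position penalty" of the hybrid term defaults to
zero. `minimumEnergyInteraction()` minimizes the total over all interval
quadruples with lengths up to `maxInterval` (default 20, bounding the
quartic search), breaking ties 5′-most on the miRNA then the mRNA.

# Features

`defaultFeatureManifest()` fixes a versioned 226-entry schema: an
86-dimensional global block (length, GC content, 4 mononucleotide, 16
dinucleotide and 64 trinucleotide ratios) and a 140-dimensional structure
block (pair count and density; stack/hairpin/bulge/interior/multiloop
counts; mean and max loop size; mean base-pair densities in sliding
windows of 5–50 nt; 8 paired-state mononucleotide ratios; 64 paired-state
dinucleotide ratios; paired indicators for positions 1–50, padded or
truncated; unpaired fraction). The published description enumerates only
examples ("… and so on"), so the schema is data, not code: a manifest
with different rows reproduces a different published layout without
touching the extractors. Ratio families each sum to 1; k-mers spanning a
placeholder are skipped.

Molecules contribute a 1024-bit hashed circular fingerprint
(radius 2, ECFP4-equivalent — the bit size is prescribed, the radius is
our choice) computed on the canonicalized structure via Open Babel and
folded modulo 1024, making equivalent SMILES spellings identical. The
interaction vector is the RNA block followed by the fingerprint:
226 + 1024 = 1250 dimensions.

# The knowledge-based classifier

Curation removes records with non-ACGU(/T) sequences or unparseable
SMILES, logging each removal. Negatives are drawn uniformly without
replacement from the RNA × molecule combinations never observed as
paired, at 3 per positive; the split is 4/5 train (floor convention on
the total), and both split and 10 cross-validation folds are stratified
by label — the protocol says only "randomly", and stratification is the
defensible choice at a fixed 1:3 imbalance. All sampling is
seed-deterministic.

`compareModels()` runs the seven classical families (logistic regression,
LDA, k-NN, decision tree, naive Bayes, SVM, random forest) through the
same folds and flags a family when mean > 0.8 **and** SD < 0.2 for
*both* accuracy and ROC AUC — the bound is stated once for "the values",
and applying it jointly is the stricter, unambiguous reading. A family
that fails to fit (LDA can, legitimately, on p ≫ n fold layouts) is
reported as failed rather than dropped. Zero-variance columns are removed
inside each fit; "ros_auc" in the source protocol is read as ROC AUC.

The production specification (`defaultRandomForestSpec()`) records the
published hyperparameter block verbatim: criterion "entropy",
n_estimators 200, random_state 100, min_samples_leaf 1,
min_samples_split 2, bootstrap true, max_features "auto" (interpreted as
√p, the classical classification convention), min_impurity_decrease 0
(the printed pair None/1e−07 is internally inconsistent; 0 is the
functional reading). The fitting backend is `ranger`, mapped as
num.trees = 200, seed = 100, min.node.size = 1, mtry = ⌊√p⌋,
replace = TRUE, probability forests, one thread for determinism. One
deviation is unavoidable: ranger offers Gini-family split criteria only,
so the recorded "entropy" criterion is honoured in the specification but
fitted with Gini — for 200-tree probability forests on these data the
two impurity measures are practically indistinguishable, and every other
constant is mapped exactly. Trained models embed the manifest, the
specification and the seed; a reloaded model reproduces identical
probabilities.

# Structure-based score and consensus

Docking logs in the standard mode/affinity/rmsd table dialect are parsed
tolerantly of banners; at most nine conformations are retained, matching
the search cap. The structure-based score of a candidate is the
arithmetic mean of its mode affinities (kcal/mol). The two rankings are
combined by rank sum by default — the combination rule is unspecified in
the source protocol; Borda and top-K-intersection are provided behind a
flag — with ties broken by the better knowledge-based rank, then the
molecule id, and a `dual_high` flag marking candidates in the top 10
(configurable) of both lists, the post-hoc "high in both" criterion.

# Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, deterministic
under a seed. Interaction tables plant a learnable association between
two RNA classes and two molecule chemotypes: ~90% of RNAs carry a
GC-rich stem with a purine (GAAA-type) apical loop and interact with a
small aromatic/flavonoid-like family; the remaining AU-stem/UUCG-loop
RNAs interact with a larger aliphatic family. The asymmetry is
deliberate: negatives sampled from the unobserved grid are then almost
entirely cross-channel, so at `motifStrength = 1` the planted
class↔chemotype conjunction is recoverable from the features, while at
`motifStrength = 0` pairing is uniform and classifiers must sit at
chance. RNA lengths (miRNA 20–24 nt, sites/motifs ~20–40 nt) match the
scale of miRNA–mRNA work; molecules come from a small embedded library
of valid drug-like SMILES; stated fractions of corrupt SMILES/sequences
exercise curation; docking logs carry known affinities.

What passing on these fixtures shows: the protocol constants, the exact
oracle agreements, and that the learning machinery recovers a signal of
the planted kind at the stated sizes. What it does not show: performance
on real curated interaction data — real RNA–ligand specificity is not a
clean two-channel conjunction, real chemotypes overlap, and real
sequence families are phylogenetically correlated. The generator is a
test harness, not a chemistry simulator.

# Problem sizes used in the checks

The test suite and acceptance script size their batteries so every
claimed number is recomputed from scratch on one CPU in minutes: 200
random sequences of 8–22 nt for folding-vs-enumeration (the enumeration
oracle is exact and feasible to ~25 nt), 100 sequences of 8–25 nt for
the dual-route unpaired probabilities, 15×30-nt toys for the alignment
oracle (compared exactly whenever the DP optimum uses at most the
oracle's two gap columns), n = 400 interaction records (100 positives ×
1:3) over ten seeds for planted-signal learning, and three seeds of the
motifStrength = 0 null for chance calibration.

# Known limitations

* The embedded energy model is deliberately simple — no sequence-specific
  stacking table, no terminal-AU or special-hairpin corrections — so
  absolute energies are model units, comparable within the package only.
* Pseudoknots, suboptimal-structure ensembles, 3D modelling and the
  execution of docking itself are out of scope; docking enters only
  through its text output.
* The exact 226-feature schema, position-weight vector and substitution
  matrix of the original tooling are not published; the package's
  versioned defaults are documented stand-ins designed to be swappable.
* LDA on 1250-dimensional, fold-sized training sets is rank-deficient
  and may be reported as failed — by design, not silently.
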