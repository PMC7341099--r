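# loopscreen

Virtual screening of small molecules that target the **loops formed during
Argonaute-mediated miRNA–mRNA interactions**.

When a mature miRNA binds its target mRNA inside the RISC, the imperfect
hybrid leaves unpaired regions — loops — whose position (typically near the
seed region, miRNA positions 1–10), size, energy and base composition make
them drug-targetable pockets. `loopscreen` implements the computational
machinery to find and exploit them:

* **Secondary structure.** The miRNA and an mRNA site are joined 5′→3′ into
  one strand (optionally separated by an unpairable placeholder linker) and
  folded by a constrained dynamic program under a loop-additive energy
  model: hairpins enclose at least three bases (j − i > 3), every base has
  at most one partner, and structures are nested (no pseudoknots). The
  energy of a structure is exactly the sum of its loop energies, so every
  fold decomposes into stacks, hairpins, bulges, interior loops and
  multiloops (`foldMFE()`, `detectLoops()`, `mutationEnergyScan()`,
  `placeholderRobustness()`).
* **Target sites.** A seed-constrained weighted alignment in the style of a
  modified miRanda search: score cutoff 120, affine gaps −9/−4, miRNA
  position 1 and the last two 3′ bases excluded, at most one G:U or
  mismatch at seed positions 2–7, canonical sites requiring a perfect
  6-mer Watson–Crick match at positions 2–7 (`scanUtr()`,
  `alignDuplex()`, `isCanonicalSite()`).
* **Interaction energy.** The accessibility-corrected combined energy of a
  candidate duplex,

  `E[i,k;j,l] = Ehybrid[i,k;j,l] + ED_miRNA[i,k] + Pru(i−1|i..k)·Edangle +
  Pru(k+1|i..k)·Edangle + ED_mRNA[j,l] + …`

  where `ED = −RT·log Pu` is the energetic cost of opening intramolecular
  structure and `Pu` is the exact Boltzmann probability that a subsequence
  is unpaired, computed both by structure enumeration and by a
  partition-function dynamic program (`hybridEnergy()`,
  `unpairedProbability()`, `combinedEnergy()`,
  `minimumEnergyInteraction()`).
* **Features and the knowledge-based model.** Each RNA is described by 226
  features (86 global sequence features, 140 secondary-structure features)
  and each molecule by a 1024-bit circular (Morgan-type) fingerprint,
  giving 1250-dimensional interaction vectors. Datasets carry 3 sampled
  negatives per curated positive and a 4/5 train split with 10-fold
  cross-validation; seven classifier families are compared and flagged when
  mean score > 0.8 with SD < 0.2; the production model is a 200-tree
  random forest with the published hyperparameter block
  (`loadInteractionTable()`, `buildDataset()`, `compareModels()`,
  `trainModel()`, `predictScores()`, `featureImportance()`).
* **Structure-based score and consensus.** Docking logs (Vina-style mode
  tables, at most nine conformations) are parsed, candidates scored by
  their mean binding energy, and the knowledge-based and structure-based
  rankings combined by rank sum with a `dual_high` flag for candidates in
  both top-10 lists (`parseDockingLog()`, `averageBindingEnergy()`,
  `combineRankings()`).
* **Synthetic data.** Seed-deterministic generators emulate every input —
  interaction tables with plantable motif→chemotype signal and stated
  fractions of corrupt records, miRNA/UTR pairs with planted or
  sequestered sites, and docking logs with known affinities — so the whole
  pipeline is testable offline (`generateInteractionTable()`,
  `generateMirnaMrnaPair()`, `generateDockingLogs()`).

## Worked example

```r
library(loopscreen)

## fold a joined miRNA-mRNA interaction and look at its loops
ji <- joinInteraction("UGCCUGUCUACACUUGCUGUGC",
                      "GCACAGCAAGUGUAGACAGGCA", linkerLength = 0)
st <- foldMFE(ji)
st
#> UGCCUGUCUACACUUGCUGUGCGCACAGCAAGUGUAGACAGGCA
#> ((((((((((((((((((((....)))))))))))))))))))) (-58.10)
detectLoops(st)[1:3, c("closing_i", "closing_j", "loop_class", "size",
                       "energy")]
#>   closing_i closing_j loop_class size energy
#> 1         1        44      stack    0   -2.5
#> 2         2        43      stack    0   -3.5
#> 3         3        42      stack    0   -3.5

## find the target site on a synthetic UTR with a planted complement
p <- generateMirnaMrnaPair(seed = 3)
scanUtr(p$mirna, p$utr)[, 1:6]
#>   utr_id start end score seed_events canonical
#> 1  utr_3    11  29   130           0      TRUE

## train the knowledge-based model on synthetic interactions and rank
sim <- generateInteractionTable(generatorConfig(nPositive = 100, seed = 42))
cur <- loadInteractionTable(sim$table)
ds  <- splitDataset(buildDataset(cur$records, negRatio = 3, seed = 42),
                    seed = 42)
model <- trainModel(ds)           # 200-tree RF, seed 100, sqrt features
featureImportance(model)$category_share
#>       rna  molecule
#> 0.4793527 0.5206473
```

The score of 130 above is what a perfectly complementary site earns under
the default weights (7 doubly weighted seed matches + 12 plain matches at
+5 each); `category_share` splits the forest's variable importance between
the RNA-side and fingerprint-side features.

A thin command-line wrapper covering the whole pipeline
(`fold`, `sites`, `energy`, `curate`, `build-dataset`, `compare`, `train`,
`screen`, `rank`, `simulate`, …) is installed at
`inst/scripts/loopscreen`.

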