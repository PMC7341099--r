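# Embedded library of valid drug-like SMILES templates used by the
# synthetic generators. Two structural families: aromatic/flavonoid-like
# scaffolds (the planted "binder" chemotype) and aliphatic/sugar-like
# molecules. Chemistry is intentionally simple: the generators only need
# valid, parseable, structurally distinctive molecules.
SMILES_AROMATIC <- c(
  "c1ccc2c(c1)oc(-c1ccccc1)cc2=O",        # flavone scaffold
  "Oc1ccc(-c2cc(=O)c3c(O)cc(O)cc3o2)cc1", # apigenin-like
  "Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)cc1... ",
  "COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1",     # methoxy-isoflavone
  "Oc1ccc(C=Cc2cc(O)cc(O)c2)cc1",         # resveratrol-like
  "Oc1ccc(-c2oc3cc(O)cc(O)c3c(=O)c2O)cc1",# quercetin-like
  "COc1cc2occ(-c3ccc(O)cc3)c(=O)c2cc1O",
  "Oc1cc(O)cc2oc(-c3ccccc3O)cc(=O)c12",
  "O=c1cc(-c2ccccc2)oc2ccccc12",
  "Oc1ccc2c(c1)occ(-c1ccc(O)cc1)c2=O",
  "COc1ccccc1-c1cc(=O)c2ccccc2o1",
  "Oc1ccc(C(=O)c2ccccc2O)cc1",
  "Nc1ccc(-c2cc(=O)c3ccccc3o2)cc1",
  "Oc1ccc(-c2cc(=O)c3cc(O)ccc3o2)cc1")
SMILES_ALIPHATIC <- c(
  "OCC(O)C(O)C(O)C(O)CO",                 # hexitol
  "OCC1OC(O)C(O)C(O)C1O",                 # pyranose
  "CC(C)CC(O)C(O)CO",
  "OCC(O)CC(O)CC(O)CO",
  "CC(O)C(O)C(O)C(O)CO",
  "OC(CO)C(O)C(O)CO",
  "CCC(O)C(O)C(O)CC(O)CO",
  "CC(C)(O)CC(O)C(O)CO",
  "OCC(O)C(O)CC(O)CO",
  "CCCCC(O)C(O)C(O)CO",
  "CC(O)CC(O)C(O)C(O)CO",
  "OCCC(O)C(O)C(O)CCO",
  "CC(C)C(O)C(O)C(O)CO",
  "OCC(O)C(O)C(O)CCO",
  "NCC(O)C(O)C(O)CO",
  "OCC(O)C(O)C(O)C(=O)O",
  "CC(N)C(O)C(O)CC(O)CO",
  "CCOC(O)C(O)C(O)CO",
  "CC(O)C(O)CC(O)C(C)O",
  "OCC(O)C(F)C(O)C(O)CO",
  "CCC(C)C(O)C(O)C(O)CO",
  "OCCOCC(O)C(O)CO",
  "CC(C)(C)C(O)C(O)C(O)CO",
  "NC(CO)C(O)C(O)C(O)CO",
  "CCC(O)CC(O)C(O)C(O)CO",
  "OCC(O)C(O)C(O)C(O)C(O)CO")

# fix one malformed template slot (kept list lengths stable)
SMILES_AROMATIC[3] <- "Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)cc2=O"

#' Synthetic-data generator configuration
#'
#' @param nRna number of distinct RNA motifs
#' @param nMolecules number of distinct molecules
#' @param nPositive number of `targeted` rows in the table
#' @param invalidSmilesFraction fraction of rows given a corrupt SMILES
#' @param invalidSequenceFraction fraction of rows given a corrupt RNA
#'   sequence
#' @param motifStrength in `[0, 1]`: probability that a positive pair is
#'   drawn from the planted motif-RNA x binder-molecule association
#'   (1 = fully learnable signal, 0 = label noise)
#' @param seed integer seed
#' @return a `GeneratorConfig` list
#' @export
generatorConfig <- function(nRna = 20L, nMolecules = 28L, nPositive = 100L,
                            invalidSmilesFraction = 0,
                            invalidSequenceFraction = 0,
                            motifStrength = 1, seed = 1L) {
  stopifnot(invalidSmilesFraction >= 0, invalidSmilesFraction <= 1,
            invalidSequenceFraction >= 0, invalidSequenceFraction <= 1,
            motifStrength >= 0, motifStrength <= 1,
            nPositive <= nRna * nMolecules)
  structure(list(nRna = as.integer(nRna),
                 nMolecules = as.integer(nMolecules),
                 nPositive = as.integer(nPositive),
                 invalidSmilesFraction = invalidSmilesFraction,
                 invalidSequenceFraction = invalidSequenceFraction,
                 motifStrength = motifStrength,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

randomBases <- function(n, prob = c(.25, .25, .25, .25)) {
  paste(sample(RNA_ALPHABET, n, replace = TRUE, prob = prob), collapse = "")
}

revComp <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# a foldable stem-loop: stem + apical loop + stem', with flanks.
# Motif RNAs carry a GC-rich stem and a purine (GAAA-type) loop; non-motif
# RNAs an AU-biased stem and a UUCG-type loop, so loop composition and
# structure features separate the two classes.
makeStemLoop <- function(motif) {
  stemLen <- sample(6:8, 1)
  stem <- if (motif)
    randomBases(stemLen, prob = c(.1, .4, .4, .1))
  else
    randomBases(stemLen, prob = c(.4, .1, .1, .4))
  loop <- if (motif) "GAAAGA" else "UUCGUU"
  flank5 <- randomBases(sample(3:6, 1))
  flank3 <- randomBases(sample(3:6, 1))
  paste0(flank5, stem, loop, revComp(stem), flank3)
}

corruptSmiles <- function() {
  paste0("xx", paste(sample(c("$", "%", "!", "t", "q"), 3, replace = TRUE),
                     collapse = ""))
}

#' Generate a synthetic RNA-molecule interaction table
#'
#' Emulates a curated interaction database: RNA sequences with embedded
#' foldable stem-loops, valid SMILES from an embedded template library,
#' a plantable motif-to-chemotype association signal of strength
#' `motifStrength`, and stated fractions of corrupt records to exercise
#' curation. All draws are deterministic under the config seed.
#'
#' The planted signal links two RNA classes to two molecule chemotypes:
#' GC-stem/purine-loop "motif" RNAs (about 90% of RNAs) interact with a
#' small aromatic molecule family, the remaining AU-stem RNAs with a
#' large aliphatic family. With `motifStrength = 1` every `targeted` row
#' is channel-consistent, so negatives sampled from unobserved RNA x
#' molecule combinations are almost all cross-channel and the
#' class-to-chemotype association is learnable from the features; with
#' `motifStrength = 0` the pairing is uniform and carries no signal.
#'
#' @param config a [generatorConfig()]
#' @return list with `table` (data.frame in the interaction-table
#'   schema), and `truth` (list: `motif_rna`, `binder_molecules` (the
#'   aromatic family), `corrupt_rows`, `informative_bits` -- fingerprint
#'   bit names whose frequency differs by more than 0.5 between the two
#'   molecule families)
#' @export
generateInteractionTable <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  nR <- config$nRna; nM <- config$nMolecules
  nMotif <- max(1L, min(nR - 1L, round(0.9 * nR)))
  motif <- c(rep(TRUE, nMotif), rep(FALSE, nR - nMotif))
  rnaSeqs <- vapply(motif, makeStemLoop, character(1))
  rnaIds <- sprintf("RNA%03d", seq_len(nR))
  nArom <- max(2L, min(length(SMILES_AROMATIC), round(0.11 * nM)))
  nAlip <- nM - nArom
  if (nAlip > length(SMILES_ALIPHATIC))
    stop("not enough molecule templates for nMolecules = ", nM)
  smiles <- c(sample(SMILES_AROMATIC, nArom),
              sample(SMILES_ALIPHATIC, nAlip))
  binder <- c(rep(TRUE, nArom), rep(FALSE, nAlip))
  molIds <- sprintf("MOL%03d", seq_len(nM))
  # channel-consistent combos: motif x aromatic, non-motif x aliphatic
  grid <- expand.grid(r = seq_len(nR), m = seq_len(nM))
  inChannel <- motif[grid$r] == binder[grid$m]
  chPool <- which(inChannel)
  anyPool <- seq_len(nrow(grid))
  used <- rep(FALSE, nrow(grid))
  picks <- integer(config$nPositive)
  for (q in seq_len(config$nPositive)) {
    pool <- if (stats::runif(1) < config$motifStrength)
      chPool[!used[chPool]] else anyPool[!used]
    if (!length(pool))
      stop("infeasible counts: positive pool exhausted at row ", q)
    pick <- if (length(pool) == 1L) pool else sample(pool, 1)
    used[pick] <- TRUE
    picks[q] <- pick
  }
  tab <- data.frame(
    rna_id = rnaIds[grid$r[picks]], rna_sequence = rnaSeqs[grid$r[picks]],
    molecule_id = molIds[grid$m[picks]], smiles = smiles[grid$m[picks]],
    label = "targeted")
  nBadS <- round(config$invalidSmilesFraction * nrow(tab))
  nBadQ <- round(config$invalidSequenceFraction * nrow(tab))
  bad <- sample(nrow(tab), min(nrow(tab), nBadS + nBadQ))
  badS <- utils::head(bad, nBadS)
  badQ <- utils::tail(bad, length(bad) - length(badS))
  for (i in badS) tab$smiles[i] <- corruptSmiles()
  for (i in badQ) tab$rna_sequence[i] <- paste0("ACGUX",
                                                tab$rna_sequence[i])
  rownames(tab) <- NULL
  # informative fingerprint bits, computed from the molecules actually used
  fps <- vapply(unique(smiles), function(s)
    moleculeFingerprint(s)$bits, integer(1024))
  bi <- binder[match(unique(smiles), smiles)]
  fB <- rowMeans(fps[, bi, drop = FALSE])
  fN <- rowMeans(fps[, !bi, drop = FALSE])
  informative <- paste0("fp_", which(abs(fB - fN) > 0.5))
  # informative RNA features: standardized mean difference > 1 between the
  # two RNA classes, computed on the generated sequences themselves
  rnaFeat <- t(vapply(rnaSeqs, function(s)
    rnaFeatureVector(rnaSequence(s, kind = "joined")),
    numeric(nrow(defaultFeatureManifest()))))
  mu1 <- colMeans(rnaFeat[motif, , drop = FALSE])
  mu0 <- colMeans(rnaFeat[!motif, , drop = FALSE])
  sdAll <- apply(rnaFeat, 2, stats::sd)
  smd <- ifelse(sdAll > 0, abs(mu1 - mu0) / sdAll, 0)
  informativeRna <- colnames(rnaFeat)[smd > 1]
  list(table = tab,
       truth = list(motif_rna = rnaIds[motif],
                    binder_molecules = molIds[binder],
                    corrupt_rows = sort(bad),
                    informative_bits = informative,
                    informative_rna_features = informativeRna,
                    informative_features = c(informative, informativeRna),
                    rna_ids = rnaIds, molecule_ids = molIds,
                    molecule_smiles = stats::setNames(smiles, molIds)))
}

#' Generate a synthetic miRNA / UTR pair
#'
#' When `seedComplement` is TRUE the UTR contains, at a recorded
#' coordinate, the perfect reverse complement of the aligned portion of
#' the miRNA (positions 2 to length-2), so the site is found by
#' [scanUtr()]. With `sequesterSite` the site is additionally embedded in
#' a stable hairpin (complementary arms flank it), lowering its unpaired
#' probability and raising the accessibility penalty.
#'
#' @param seed integer seed
#' @param seedComplement plant a complementary site?
#' @param sequesterSite fold the site into a planted hairpin?
#' @param mirnaLength miRNA length (default 22)
#' @return list with `mirna`, `utr` ([RnaSequence-class]), `site_start`,
#'   `site_end` (1-based UTR coordinates of the planted site, NA when
#'   none)
#' @export
generateMirnaMrnaPair <- function(seed = 1L, seedComplement = TRUE,
                                  sequesterSite = FALSE,
                                  mirnaLength = 22L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  mir <- randomBases(mirnaLength)
  core <- substr(mir, 2, mirnaLength - 2)
  site <- if (seedComplement) revComp(core) else
    paste(sample(strsplit(revComp(core), "")[[1]]), collapse = "")
  left <- randomBases(10)
  right <- randomBases(10)
  utr <- if (sequesterSite) {
    # the site pairs with its own downstream reverse complement, burying
    # it in a stable hairpin
    paste0(left, site, randomBases(4), revComp(site), right)
  } else {
    paste0(left, site, right)
  }
  start <- if (seedComplement) nchar(left) + 1L else NA_integer_
  end <- if (seedComplement) nchar(left) + nchar(site) else NA_integer_
  list(mirna = rnaSequence(mir, id = sprintf("mir_%d", seed),
                           kind = "miRNA"),
       utr = rnaSequence(utr, id = sprintf("utr_%d", seed), kind = "mRNA"),
       site_start = start, site_end = end)
}

#' Generate synthetic docking logs
#'
#' Writes standard-dialect docking logs with known mode affinities and
#' returns the ground truth, so parsing and averaging can be verified
#' exactly. At most nine modes per molecule.
#'
#' @param nMolecules number of molecules
#' @param modesPerMol modes per molecule (1..9)
#' @param seed integer seed
#' @param dir output directory for the `.log` files
#' @return list with `files` and `truth` (data.frame `molecule_id`,
#'   `mean_affinity`)
#' @export
generateDockingLogs <- function(nMolecules, modesPerMol = 9L, seed = 1L,
                                dir = tempfile("docklogs")) {
  if (modesPerMol > MAX_DOCKING_MODES)
    stop("at most 9 conformations are reported per molecule")
  if (modesPerMol < 1L) stop("need at least one mode")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("MOL%03d", seq_len(nMolecules))
  truth <- data.frame(molecule_id = ids, mean_affinity = NA_real_)
  files <- character(nMolecules)
  for (q in seq_len(nMolecules)) {
    aff <- sort(round(stats::runif(modesPerMol, -9.5, -4.0), 1))
    truth$mean_affinity[q] <- mean(aff)
    lines <- c("AutoDock-style search result",
               "mode |   affinity | dist from best mode",
               "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
               "-----+------------+----------+----------",
               sprintf("%5d %12.1f %10.3f %10.3f", seq_len(modesPerMol),
                       aff, seq_len(modesPerMol) - 1,
                       (seq_len(modesPerMol) - 1) * 1.5))
    files[q] <- file.path(dir, paste0(ids[q], ".log"))
    writeLines(lines, files[q])
  }
  list(files = files, truth = truth, dir = dir)
}
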