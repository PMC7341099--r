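#' ScreenDataset: labeled RNA-molecule interaction dataset
#'
#' Feature matrix (n x 1250 with the default manifest), labels
#' (`targeted` / `non_targeted`), train/test split and cross-validation
#' fold assignments. Built by [buildDataset()] with exactly `negRatio`
#' negatives per positive, sampled from RNA x molecule combinations never
#' observed as paired.
#'
#' @slot records data.frame of record metadata (`rna_id`, `rna_sequence`,
#'   `molecule_id`, `smiles`, `label`)
#' @slot features numeric matrix, one row per record
#' @slot labels factor with levels `targeted`, `non_targeted`
#' @slot manifest the RNA feature manifest used
#' @slot split character vector (`train`/`test`, or NA before splitting)
#' @slot fold integer CV fold within the training set (NA elsewhere)
#' @slot seed integer seed the dataset was built with
#' @exportClass ScreenDataset
setClass("ScreenDataset",
  representation(records = "data.frame", features = "matrix",
                 labels = "factor", manifest = "data.frame",
                 split = "character", fold = "integer", seed = "integer"))

setValidity("ScreenDataset", function(object) {
  n <- nrow(object@records)
  if (nrow(object@features) != n || length(object@labels) != n)
    return("records/features/labels sizes differ")
  if (!all(levels(object@labels) == c("targeted", "non_targeted")))
    return("labels must have levels targeted, non_targeted")
  TRUE
})

setMethod("show", "ScreenDataset", function(object) {
  tab <- table(object@labels)
  cat(sprintf("ScreenDataset: %d records (%d targeted, %d non-targeted), %d features\n",
              nrow(object@records), tab["targeted"], tab["non_targeted"],
              ncol(object@features)))
  if (!all(is.na(object@split)))
    cat(sprintf("  split: %d train / %d test\n",
                sum(object@split == "train", na.rm = TRUE),
                sum(object@split == "test", na.rm = TRUE)))
})

REQUIRED_COLUMNS <- c("rna_id", "rna_sequence", "molecule_id", "smiles",
                      "label")

validRnaSequenceString <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  s <- chartr("T", "U", toupper(s))
  !grepl(paste0("[^", paste(RNA_ALPHABET, collapse = ""), "]"), s)
}

#' Load and curate an RNA-molecule interaction table
#'
#' Reads the curated interaction table (CSV or data.frame with columns
#' `rna_id`, `rna_sequence`, `molecule_id`, `smiles`, `label`), removes
#' records whose RNA sequence is invalid (characters outside A/C/G/U/T)
#' or whose SMILES cannot be parsed, and reports each removal with its
#' reason.
#'
#' @param table path to a CSV file, or a data.frame
#' @return list with `records` (curated data.frame, with an added
#'   `smiles_canonical` column), `rejected` (data.frame with `row`,
#'   `reason`), and `n_valid`
#' @export
loadInteractionTable <- function(table) {
  df <- if (is.character(table))
    utils::read.csv(table, stringsAsFactors = FALSE) else as.data.frame(table)
  missing <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing))
    stop("interaction table lacks required columns: ",
         paste(missing, collapse = ", "))
  if (!nrow(df)) stop("interaction table is empty")
  seqOk <- vapply(df$rna_sequence, validRnaSequenceString, logical(1),
                  USE.NAMES = FALSE)
  can <- rep(NA_character_, nrow(df))
  can[seqOk] <- vapply(df$smiles[seqOk], canonicalSmiles, character(1),
                       USE.NAMES = FALSE)
  smilesOk <- !is.na(can)
  keep <- seqOk & smilesOk
  reason <- ifelse(!seqOk, "invalid RNA sequence",
                   ifelse(!smilesOk, "unparseable SMILES", NA))
  rejected <- data.frame(row = which(!keep), rna_id = df$rna_id[!keep],
                         molecule_id = df$molecule_id[!keep],
                         reason = reason[!keep])
  records <- df[keep, , drop = FALSE]
  records$rna_sequence <- chartr("T", "U", toupper(records$rna_sequence))
  records$smiles_canonical <- can[keep]
  rownames(records) <- NULL
  list(records = records, rejected = rejected, n_valid = nrow(records))
}

featurizeRecords <- function(rnaSeqs, smiles, manifest, model,
                             nBits = 1024L, radius = 2L) {
  # cache per unique RNA and molecule: featurization cost is dominated by
  # folding and fingerprinting
  uR <- unique(rnaSeqs)
  rnaF <- lapply(uR, function(s)
    rnaFeatureVector(rnaSequence(s, kind = "joined"), manifest, model))
  names(rnaF) <- uR
  uM <- unique(smiles)
  fpF <- lapply(uM, function(s)
    moleculeFingerprint(s, nBits = nBits, radius = radius)$bits)
  names(fpF) <- uM
  mat <- t(vapply(seq_along(rnaSeqs), function(q)
    c(rnaF[[rnaSeqs[q]]],
      setNames(as.numeric(fpF[[smiles[q]]]), paste0("fp_", seq_len(nBits)))),
    numeric(nrow(manifest) + nBits)))
  mat
}

#' Build a balanced labeled dataset from curated records
#'
#' Positives are the curated (RNA, molecule) pairs labeled `targeted`.
#' Negatives are sampled uniformly without replacement from the RNA x
#' molecule combinations never observed as paired, at `negRatio` per
#' positive (default 3, the published 1:3 targeted:non-targeted ratio).
#' Deterministic under `seed`.
#'
#' @param records curated records from [loadInteractionTable()]
#' @param negRatio negatives per positive (>= 0)
#' @param seed integer seed
#' @param manifest RNA feature manifest
#' @param model a [LoopEnergyModel-class]
#' @return a [ScreenDataset-class]
#' @export
buildDataset <- function(records, negRatio = 3L, seed = 1L,
                         manifest = defaultFeatureManifest(),
                         model = defaultEnergyModel()) {
  pos <- records[records$label == "targeted", , drop = FALSE]
  if (!nrow(pos)) stop("no targeted records")
  rnas <- unique(pos[, c("rna_id", "rna_sequence")])
  mols <- unique(pos[, c("molecule_id", "smiles")])
  posKey <- paste(pos$rna_id, pos$molecule_id)
  grid <- expand.grid(r = seq_len(nrow(rnas)), m = seq_len(nrow(mols)))
  gridKey <- paste(rnas$rna_id[grid$r], mols$molecule_id[grid$m])
  unobserved <- which(!gridKey %in% posKey)
  nNeg <- as.integer(negRatio) * nrow(pos)
  if (nNeg > length(unobserved))
    stop(sprintf(
      "not enough unobserved combinations for %d negatives (max ratio %.2f)",
      nNeg, length(unobserved) / nrow(pos)))
  pick <- if (nNeg > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    sample(unobserved, nNeg)
  } else integer(0)
  neg <- data.frame(
    rna_id = rnas$rna_id[grid$r[pick]],
    rna_sequence = rnas$rna_sequence[grid$r[pick]],
    molecule_id = mols$molecule_id[grid$m[pick]],
    smiles = mols$smiles[grid$m[pick]],
    label = rep("non_targeted", length(pick)))
  all <- rbind(pos[, REQUIRED_COLUMNS], neg)
  rownames(all) <- NULL
  feat <- featurizeRecords(all$rna_sequence, all$smiles, manifest, model)
  rownames(feat) <- NULL
  new("ScreenDataset", records = all, features = feat,
      labels = factor(all$label, levels = c("targeted", "non_targeted")),
      manifest = manifest,
      split = rep(NA_character_, nrow(all)),
      fold = rep(NA_integer_, nrow(all)),
      seed = as.integer(seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

stratifiedTake <- function(strata, targetTotal, seed) {
  # per-stratum floor allocation, remainders to the largest fractions
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  idxByS <- split(seq_along(strata), strata)
  frac <- targetTotal / length(strata)
  nPer <- vapply(idxByS, function(ix) floor(length(ix) * frac), numeric(1))
  rem <- targetTotal - sum(nPer)
  if (rem > 0) {
    fracPart <- vapply(idxByS, function(ix) length(ix) * frac, numeric(1)) -
      nPer
    bump <- order(-fracPart)[seq_len(rem)]
    nPer[bump] <- nPer[bump] + 1
  }
  unlist(lapply(seq_along(idxByS), function(q)
    sample(idxByS[[q]], nPer[q])), use.names = FALSE)
}

#' Split a dataset into training and test sets
#'
#' Label-stratified random split; the training fraction defaults to 4/5
#' with a floor convention on the total (`floor(n * trainFraction)` train
#' records). Also assigns stratified cross-validation folds 1..10 within
#' the training set. Deterministic under `seed`.
#'
#' @param dataset a [ScreenDataset-class]
#' @param trainFraction fraction assigned to training (default 0.8)
#' @param k number of CV folds assigned within the training set
#' @param seed integer seed
#' @return the dataset with `split` and `fold` filled in
#' @export
splitDataset <- function(dataset, trainFraction = 0.8, k = 10L, seed = 1L) {
  n <- nrow(dataset@records)
  if (n < 5) stop("need at least 5 records to split")
  nTrain <- floor(n * trainFraction)
  trainIdx <- stratifiedTake(as.character(dataset@labels), nTrain, seed)
  split <- rep("test", n)
  split[trainIdx] <- "train"
  fold <- rep(NA_integer_, n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed) + 1L)
  for (lab in levels(dataset@labels)) {
    ix <- which(split == "train" & dataset@labels == lab)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  dataset@split <- split
  dataset@fold <- fold
  dataset
}
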