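DI_NAMES <- as.vector(outer(RNA_ALPHABET, RNA_ALPHABET, paste0))
TRI_NAMES <- as.vector(outer(as.vector(outer(RNA_ALPHABET, RNA_ALPHABET,
                                             paste0)),
                             RNA_ALPHABET, paste0))
WINDOW_SIZES <- c(5L, 10L, 15L, 20L, 25L, 30L, 40L, 50L)
POSITIONAL_N <- 50L

#' The default RNA feature manifest (226 features)
#'
#' Ordered schema of the RNA feature vector: an 86-dimensional global
#' block (sequence length, GC content, 4 mononucleotide ratios, 16
#' dinucleotide ratios, 64 trinucleotide ratios) followed by a
#' 140-dimensional secondary-structure block (base-pair count and
#' density, five loop-class counts, mean and max loop size, base-pair
#' densities in 8 window sizes, 8 paired-state mononucleotide ratios,
#' 64 paired-state dinucleotide ratios, paired indicators for positions
#' 1-50, unpaired fraction). The manifest is data: any reordering or
#' subset produces a feature vector in the manifest's order.
#'
#' @return data.frame with columns `name`, `category`, `extractor`,
#'   `parameter`
#' @export
defaultFeatureManifest <- function() {
  glob <- data.frame(
    name = c("length", "gc_content",
             paste0("mono_", RNA_ALPHABET),
             paste0("di_", DI_NAMES),
             paste0("tri_", TRI_NAMES)),
    category = "global")
  struct <- data.frame(
    name = c("bp_count", "bp_density",
             paste0("n_", c("stack", "hairpin", "bulge", "interior",
                            "multiloop")),
             "mean_loop_size", "max_loop_size",
             paste0("win_bp_density_", WINDOW_SIZES),
             paste0("state_", RNA_ALPHABET, "_paired"),
             paste0("state_", RNA_ALPHABET, "_unpaired"),
             paste0("distate_", rep(DI_NAMES, each = 4), "_",
                    c("pp", "pu", "up", "uu")),
             paste0("pos_paired_", seq_len(POSITIONAL_N)),
             "unpaired_fraction"),
    category = "structure")
  man <- rbind(glob, struct)
  man$extractor <- ifelse(man$category == "global", "rnaGlobalFeatures",
                          "rnaStructureFeatures")
  man$parameter <- ""
  man
}

#' Global sequence features of an RNA
#'
#' Length, GC content and mono-/di-/trinucleotide ratios, computed over
#' non-placeholder positions only (k-mers spanning a linker are skipped).
#' Each ratio family sums to 1 when at least one k-mer exists.
#'
#' @param x sequence input as in [foldMFE()]
#' @return named numeric vector (the manifest's global block)
#' @export
rnaGlobalFeatures <- function(x) {
  seq <- asRnaSeq(x)
  ch <- strsplit(seq@bases, "")[[1]]
  eff <- ch[ch != LINKER_CHAR]
  if (!length(eff)) stop("empty effective sequence")
  mono <- table(factor(eff, levels = RNA_ALPHABET)) / length(eff)
  kmerRatio <- function(k, lv) {
    n <- length(ch)
    if (n < k) return(setNames(rep(0, length(lv)), lv))
    km <- vapply(seq_len(n - k + 1L), function(i)
      paste(ch[i:(i + k - 1L)], collapse = ""), character(1))
    km <- km[!grepl(LINKER_CHAR, km, fixed = TRUE)]
    if (!length(km)) return(setNames(rep(0, length(lv)), lv))
    as.vector(table(factor(km, levels = lv)) / length(km))
  }
  di <- kmerRatio(2L, DI_NAMES)
  tri <- kmerRatio(3L, TRI_NAMES)
  out <- c(length = length(eff),
           gc_content = unname(mono["G"] + mono["C"]),
           setNames(as.vector(mono), paste0("mono_", RNA_ALPHABET)),
           setNames(as.vector(di), paste0("di_", DI_NAMES)),
           setNames(as.vector(tri), paste0("tri_", TRI_NAMES)))
  out
}

#' Secondary-structure features of an RNA
#'
#' Base-pair counts and densities, loop-class counts from the loop
#' decomposition, windowed base-pair densities, paired/unpaired
#' mono- and di-nucleotide state ratios, positional paired indicators
#' (positions 1-50, padded with zeros / truncated) and the unpaired
#' fraction. Placeholder positions count as unpaired in structural state
#' features and are excluded from composition-state ratios.
#'
#' @param x sequence input as in [foldMFE()]
#' @param structure its [SecondaryStructure-class] (default: [foldMFE()])
#' @param model energy model used when folding is needed
#' @return named numeric vector (the manifest's structure block)
#' @export
rnaStructureFeatures <- function(x, structure = NULL,
                                 model = defaultEnergyModel()) {
  seq <- asRnaSeq(x)
  if (is.null(structure)) structure <- foldMFE(seq, model)
  ch <- strsplit(seq@bases, "")[[1]]
  n <- length(ch)
  pt <- structure@pairTable
  if (length(pt) != n) stop("structure/sequence length mismatch")
  paired <- pt > 0L
  nbp <- sum(paired) / 2
  loops <- detectLoops(structure, model = model)
  closed <- loops[loops$loop_class != "exterior", , drop = FALSE]
  classCount <- function(cl) sum(closed$loop_class == cl)
  sizes <- closed$size
  winDens <- vapply(WINDOW_SIZES, function(w) {
    if (n < 1) return(0)
    starts <- seq_len(max(1L, n - w + 1L))
    dens <- vapply(starts, function(s) {
      e <- min(n, s + w - 1L)
      sum(paired[s:e]) / (e - s + 1L)
    }, numeric(1))
    mean(dens)
  }, numeric(1))
  isBase <- ch != LINKER_CHAR
  stateOf <- ifelse(paired, "p", "u")
  monoState <- vapply(RNA_ALPHABET, function(b) c(
    sum(isBase & ch == b & paired), sum(isBase & ch == b & !paired)),
    numeric(2))
  monoTot <- sum(monoState)
  monoState <- if (monoTot > 0) monoState / monoTot else monoState
  diKeys <- paste0("distate_", rep(DI_NAMES, each = 4), "_",
                   c("pp", "pu", "up", "uu"))
  diCount <- setNames(numeric(length(diKeys)), diKeys)
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      if (!isBase[i] || !isBase[i + 1L]) next
      key <- paste0("distate_", ch[i], ch[i + 1L], "_",
                    stateOf[i], stateOf[i + 1L])
      diCount[key] <- diCount[key] + 1
    }
  }
  if (sum(diCount) > 0) diCount <- diCount / sum(diCount)
  posPaired <- as.numeric(paired[seq_len(POSITIONAL_N)])
  posPaired[is.na(posPaired)] <- 0
  c(bp_count = nbp,
    bp_density = nbp / n,
    n_stack = classCount("stack"), n_hairpin = classCount("hairpin"),
    n_bulge = classCount("bulge"), n_interior = classCount("interior"),
    n_multiloop = classCount("multiloop"),
    mean_loop_size = if (nrow(closed)) mean(sizes) else 0,
    max_loop_size = if (nrow(closed)) max(sizes) else 0,
    setNames(winDens, paste0("win_bp_density_", WINDOW_SIZES)),
    setNames(c(monoState[1, ], monoState[2, ]),
             c(paste0("state_", RNA_ALPHABET, "_paired"),
               paste0("state_", RNA_ALPHABET, "_unpaired"))),
    diCount,
    setNames(posPaired, paste0("pos_paired_", seq_len(POSITIONAL_N))),
    unpaired_fraction = sum(!paired) / n)
}

#' RNA feature vector of a joined interaction
#'
#' Folds the joined strand and concatenates the global and structure
#' features in manifest order (default length 226).
#'
#' @param x a [JoinedInteraction-class], [RnaSequence-class] or string
#' @param manifest a feature manifest (see [defaultFeatureManifest()])
#' @param model a [LoopEnergyModel-class]
#' @return named numeric vector ordered as the manifest
#' @export
rnaFeatureVector <- function(x, manifest = defaultFeatureManifest(),
                             model = defaultEnergyModel()) {
  seq <- asRnaSeq(x)
  vals <- c(rnaGlobalFeatures(seq),
            rnaStructureFeatures(seq, model = model))
  missing <- setdiff(manifest$name, names(vals))
  if (length(missing))
    stop("manifest names without extractor values: ",
         paste(utils::head(missing, 3), collapse = ", "))
  out <- vals[manifest$name]
  if (any(!is.finite(out))) stop("non-finite feature value")
  out
}

#' Interaction feature vector: RNA features joined with a fingerprint
#'
#' @param x RNA input as in [rnaFeatureVector()]
#' @param smiles molecule SMILES string
#' @param manifest RNA feature manifest
#' @param nBits,radius fingerprint parameters (see [moleculeFingerprint()])
#' @param model a [LoopEnergyModel-class]
#' @return numeric vector of length `nrow(manifest) + nBits` (default
#'   226 + 1024 = 1250); the RNA block comes first
#' @export
interactionFeatures <- function(x, smiles,
                                manifest = defaultFeatureManifest(),
                                nBits = 1024L, radius = 2L,
                                model = defaultEnergyModel()) {
  rna <- rnaFeatureVector(x, manifest, model)
  fp <- moleculeFingerprint(smiles, nBits = nBits, radius = radius)
  c(rna, setNames(as.numeric(fp$bits), paste0("fp_", seq_len(nBits))))
}
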