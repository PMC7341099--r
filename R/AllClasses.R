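#' @import methods
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")
LINKER_CHAR <- "N"

#' RnaSequence: a single RNA strand
#'
#' Holds an identifier, the 5'->3' base string over \{A,C,G,U\} (T is
#' converted to U on construction; `N` marks unpairable placeholder/linker
#' positions) and the kind of molecule. Positions are 1-based inclusive
#' from the 5' end throughout the package.
#'
#' @slot id single identifier string
#' @slot bases character scalar, normalized base string
#' @slot kind one of `"miRNA"`, `"mRNA"`, `"joined"`
#' @exportClass RnaSequence
setClass("RnaSequence",
  representation(id = "character", bases = "character", kind = "character"))

setValidity("RnaSequence", function(object) {
  if (length(object@bases) != 1L || nchar(object@bases) < 1L)
    return("bases must be a single non-empty string")
  ch <- strsplit(object@bases, "")[[1]]
  bad <- setdiff(unique(ch), c(RNA_ALPHABET, LINKER_CHAR))
  if (length(bad))
    return(paste0("invalid characters after normalization: ",
                  paste(bad, collapse = ",")))
  if (!object@kind %in% c("miRNA", "mRNA", "joined"))
    return("kind must be miRNA, mRNA or joined")
  TRUE
})

#' Construct an RnaSequence
#'
#' @param bases base string; `T`/`t` are converted to `U`, case is folded
#'   to upper. `N` denotes an unpairable placeholder position.
#' @param id identifier
#' @param kind `"miRNA"`, `"mRNA"` or `"joined"`
#' @return an [RnaSequence-class] object
#' @examples
#' rnaSequence("UGCCUGUCUACACUUGCUGUGC", id = "miR-214", kind = "miRNA")
#' @export
rnaSequence <- function(bases, id = "rna", kind = c("miRNA", "mRNA", "joined")) {
  kind <- match.arg(kind)
  if (is(bases, "RnaSequence")) return(bases)
  bases <- toupper(as.character(bases))
  bases <- chartr("T", "U", bases)
  new("RnaSequence", id = as.character(id), bases = bases, kind = kind)
}

#' JoinedInteraction: a miRNA and an mRNA site on one strand
#'
#' The two molecules are concatenated 5'->3' (miRNA first) with an optional
#' unpairable linker of placeholder bases between them, mirroring the
#' single-sequence input convention used for secondary-structure
#' prediction of an interacting duplex.
#'
#' @slot mirna,mrnaSite the component [RnaSequence-class] objects
#' @slot linkerLength number of placeholder bases inserted at the junction
#' @slot joined the concatenated [RnaSequence-class]
#' @slot mirnaSpan,mrnaSpan 1-based inclusive `c(start, end)` of each
#'   component within the joined strand
#' @exportClass JoinedInteraction
setClass("JoinedInteraction",
  representation(mirna = "RnaSequence", mrnaSite = "RnaSequence",
                 linkerLength = "integer", joined = "RnaSequence",
                 mirnaSpan = "integer", mrnaSpan = "integer"))

setValidity("JoinedInteraction", function(object) {
  nm <- nchar(object@mirna@bases); ns <- nchar(object@mrnaSite@bases)
  L <- object@linkerLength
  if (L < 0L) return("linkerLength must be >= 0")
  expect <- paste0(object@mirna@bases,
                   strrep(LINKER_CHAR, L), object@mrnaSite@bases)
  if (object@joined@bases != expect)
    return("joined bases do not equal mirna + linker + mrna_site")
  if (!identical(object@mirnaSpan, c(1L, nm)))
    return("mirnaSpan inconsistent")
  if (!identical(object@mrnaSpan, c(nm + L + 1L, nm + L + ns)))
    return("mrnaSpan inconsistent")
  TRUE
})

#' SecondaryStructure: nested RNA secondary structure
#'
#' A pair table (0 = unpaired) with its dot-bracket string, the sequence it
#' belongs to (if known) and its energy under the loop-additive model
#' (NA when not evaluated). Valid objects contain only canonical
#' Watson-Crick or G-U pairs among known bases, hairpins enclose at least
#' three bases, no base has two partners, and pairs are nested.
#'
#' @slot pairTable integer vector, position -> partner (0 = unpaired)
#' @slot dotBracket dot-bracket string consistent with `pairTable`
#' @slot sequence base string ("" when the structure was parsed without one)
#' @slot energy model energy in kcal/mol (NA if unknown)
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
  representation(pairTable = "integer", dotBracket = "character",
                 sequence = "character", energy = "numeric"))

PAIRABLE <- c("AU", "UA", "CG", "GC", "GU", "UG")

setValidity("SecondaryStructure", function(object) {
  pt <- object@pairTable
  n <- length(pt)
  if (nchar(object@dotBracket) != n)
    return("dot_bracket length does not match pair table")
  if (any(pt < 0L | pt > n)) return("pair table entries out of range")
  paired <- which(pt > 0L)
  if (any(pt[pt[paired]] != paired))
    return("pair table is not symmetric")
  if (any(pt[paired] == paired)) return("self pairing")
  ij <- cbind(paired, pt[paired])
  ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  if (nrow(ij)) {
    if (any(ij[, 2] - ij[, 1] <= 3L))
      return("hairpin constraint violated (need j - i > 3)")
    if (nzchar(object@sequence)) {
      ch <- strsplit(object@sequence, "")[[1]]
      pp <- paste0(ch[ij[, 1]], ch[ij[, 2]])
      known <- !grepl(LINKER_CHAR, pp, fixed = TRUE)
      if (any(ch[ij[, 1]] == LINKER_CHAR | ch[ij[, 2]] == LINKER_CHAR))
        return("linker positions must be unpaired")
      if (any(!pp[known] %in% PAIRABLE))
        return("non-canonical base pair")
    }
    # nestedness: for i < k with both paired, forbid i < k < j < l
    if (nrow(ij) > 1) {
      o <- order(ij[, 1])
      ij <- ij[o, , drop = FALSE]
      for (r in seq_len(nrow(ij) - 1)) {
        i <- ij[r, 1]; j <- ij[r, 2]
        k <- ij[-seq_len(r), 1]; l <- ij[-seq_len(r), 2]
        if (any(k < j & l > j)) return("pseudoknot detected")
      }
    }
  }
  db <- dotBracketFromPairTable(pt)
  if (db != object@dotBracket)
    return("dot_bracket inconsistent with pair table")
  TRUE
})

#' SiteScoringParams: parameters of the seed-constrained site alignment
#'
#' Defaults follow the modified miRanda-style settings: score cutoff 120,
#' affine gap penalties of -9 (opening, charged on the first gap base) and
#' -4 (each further base), match +5, G:U wobble +2, mismatch -3, with
#' seed positions 2-8 of the miRNA weighted x2. miRNA position 1 and the
#' last two 3' bases are excluded from the alignment altogether, and at
#' most one G:U-or-mismatch event is tolerated at seed positions 2-7.
#'
#' @slot scoreCutoff minimal reported alignment score
#' @slot gapOpen,gapExtend affine gap penalties (<= 0)
#' @slot matchScore,wobbleScore,mismatchScore per-column scores
#' @slot seedWeight multiplicative weight for seed positions
#' @slot seedWeightRange,seedConstraintRange 1-based miRNA position ranges
#' @exportClass SiteScoringParams
setClass("SiteScoringParams",
  representation(scoreCutoff = "numeric", gapOpen = "numeric",
                 gapExtend = "numeric", matchScore = "numeric",
                 wobbleScore = "numeric", mismatchScore = "numeric",
                 seedWeight = "numeric", seedWeightRange = "integer",
                 seedConstraintRange = "integer"))

setValidity("SiteScoringParams", function(object) {
  if (object@scoreCutoff <= 0) return("cutoff must be > 0")
  if (object@gapOpen > 0 || object@gapExtend > 0)
    return("gap penalties must be <= 0")
  TRUE
})

#' @param scoreCutoff,gapOpen,gapExtend,matchScore,wobbleScore,mismatchScore
#'   see slot documentation
#' @param seedWeight position-specific weight applied in the seed
#' @param seedWeightRange positions receiving `seedWeight`
#' @param seedConstraintRange positions where at most one G:U/mismatch is
#'   allowed
#' @rdname SiteScoringParams-class
#' @export
siteScoringParams <- function(scoreCutoff = 120, gapOpen = -9, gapExtend = -4,
                              matchScore = 5, wobbleScore = 2,
                              mismatchScore = -3, seedWeight = 2,
                              seedWeightRange = c(2L, 8L),
                              seedConstraintRange = c(2L, 7L)) {
  new("SiteScoringParams", scoreCutoff = scoreCutoff, gapOpen = gapOpen,
      gapExtend = gapExtend, matchScore = matchScore,
      wobbleScore = wobbleScore, mismatchScore = mismatchScore,
      seedWeight = seedWeight,
      seedWeightRange = as.integer(seedWeightRange),
      seedConstraintRange = as.integer(seedConstraintRange))
}

#' LoopEnergyModel: embedded loop-additive energy parameters
#'
#' A small nearest-neighbor-style parameter set. The energy of a structure
#' is the sum over its loops; each closed loop contributes the energy of
#' its closing pair plus a class/size term, the exterior loop contributes
#' zero. See [defaultEnergyModel()].
#'
#' @slot pairEnergy 4x4 matrix of closing-pair energies (A,C,G,U order;
#'   `Inf` marks a forbidden pair)
#' @slot stackBonus extra stabilization of a stacked pair (size-0 loop)
#' @slot hairpinBase,hairpinPerNt hairpin loop penalty: base + per-nt
#' @slot bulgeBase,bulgePerNt bulge loop penalty
#' @slot interiorBase,interiorPerNt interior loop penalty
#' @slot multiloopClose,multiloopBranch,multiloopUnpaired multiloop linear
#'   model: closing + per-branch + per-unpaired-base
#' @slot duplexInit intermolecular duplex initiation penalty (kcal/mol)
#' @slot dangle energy per available flank base of a hybrid site
#' @slot rt product R*T in kcal/mol (T = 310.15 K)
#' @exportClass LoopEnergyModel
setClass("LoopEnergyModel",
  representation(pairEnergy = "matrix", stackBonus = "numeric",
                 hairpinBase = "numeric", hairpinPerNt = "numeric",
                 bulgeBase = "numeric", bulgePerNt = "numeric",
                 interiorBase = "numeric", interiorPerNt = "numeric",
                 multiloopClose = "numeric", multiloopBranch = "numeric",
                 multiloopUnpaired = "numeric", duplexInit = "numeric",
                 dangle = "numeric", rt = "numeric"))

#' The default embedded energy model
#'
#' Pair energies: GC/CG -3.0, AU/UA -2.0, GU/UG -1.0 kcal/mol. Stacked
#' pairs gain an extra -0.5. Loop penalties: hairpin 1.0 + 0.1/nt, bulge
#' 2.0 + 0.3/nt, interior 1.5 + 0.25/nt, multiloop 3.0 + 0.4/branch +
#' 0.1/unpaired nt; the exterior loop is free. Duplex initiation +4.1,
#' dangling flank -0.3 per available base. RT uses T = 310.15 K and
#' R = 1.987e-3 kcal/(mol K).
#'
#' @return a [LoopEnergyModel-class]
#' @export
defaultEnergyModel <- function() {
  pe <- matrix(Inf, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  pe["G", "C"] <- pe["C", "G"] <- -3.0
  pe["A", "U"] <- pe["U", "A"] <- -2.0
  pe["G", "U"] <- pe["U", "G"] <- -1.0
  new("LoopEnergyModel", pairEnergy = pe, stackBonus = -0.5,
      hairpinBase = 1.0, hairpinPerNt = 0.1,
      bulgeBase = 2.0, bulgePerNt = 0.3,
      interiorBase = 1.5, interiorPerNt = 0.25,
      multiloopClose = 3.0, multiloopBranch = 0.4, multiloopUnpaired = 0.1,
      duplexInit = 4.1, dangle = -0.3,
      rt = 1.987e-3 * 310.15)
}

setMethod("show", "RnaSequence", function(object) {
  cat(sprintf("RnaSequence '%s' (%s), %d nt\n  %s\n", object@id, object@kind,
              nchar(object@bases), object@bases))
})

setMethod("show", "JoinedInteraction", function(object) {
  cat(sprintf(
    "JoinedInteraction: %s (1-%d) + linker(%d) + %s (%d-%d), %d nt\n",
    object@mirna@id, object@mirnaSpan[2], object@linkerLength,
    object@mrnaSite@id, object@mrnaSpan[1], object@mrnaSpan[2],
    nchar(object@joined@bases)))
})

setMethod("show", "SecondaryStructure", function(object) {
  if (nzchar(object@sequence)) cat(object@sequence, "\n")
  cat(object@dotBracket)
  if (!is.na(object@energy)) cat(sprintf(" (%.2f)", object@energy))
  cat("\n")
})
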