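#' @useDynLib loopscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

encodeBases <- function(bases) {
  ch <- strsplit(bases, "")[[1]]
  code <- match(ch, RNA_ALPHABET) - 1L
  code[is.na(code)] <- -1L  # linker / placeholder: unpairable
  code
}

modelToList <- function(model) {
  list(pair_energy = model@pairEnergy,
       stack_bonus = model@stackBonus,
       hairpin_base = model@hairpinBase, hairpin_per_nt = model@hairpinPerNt,
       bulge_base = model@bulgeBase, bulge_per_nt = model@bulgePerNt,
       interior_base = model@interiorBase, interior_per_nt = model@interiorPerNt,
       multiloop_close = model@multiloopClose,
       multiloop_branch = model@multiloopBranch,
       multiloop_unpaired = model@multiloopUnpaired,
       rt = model@rt)
}

dotBracketFromPairTable <- function(pt) {
  ch <- rep(".", length(pt))
  opens <- which(pt > seq_along(pt))
  ch[opens] <- "("
  ch[pt[opens]] <- ")"
  paste(ch, collapse = "")
}

#' Parse a dot-bracket string into a SecondaryStructure
#'
#' @param db dot-bracket string over `.`, `(`, `)`
#' @param sequence optional base string of matching length
#' @param energy optional known energy
#' @return a [SecondaryStructure-class]
#' @examples
#' parseDotBracket("((..((...))..))")
#' @export
parseDotBracket <- function(db, sequence = NULL, energy = NA_real_) {
  ch <- strsplit(db, "")[[1]]
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad))
    stop("invalid dot-bracket character at position ", bad[1])
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack))
        stop("unbalanced brackets: unmatched ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced brackets: unmatched '(' at position ", stack[1])
  seqStr <- if (is.null(sequence)) "" else {
    s <- rnaSequence(sequence, kind = "joined")@bases
    if (nchar(s) != length(ch)) stop("sequence/structure length mismatch")
    s
  }
  new("SecondaryStructure", pairTable = pt, dotBracket = db,
      sequence = seqStr, energy = energy)
}

#' Predict the minimum-free-energy secondary structure
#'
#' Constrained Zuker-style dynamic program under the package's
#' loop-additive energy model. The returned structure satisfies the three
#' folding constraints (hairpins enclose at least three bases, at most one
#' partner per base, nested pairs only), its energy equals the sum of its
#' loop energies, and placeholder/linker positions never pair. A sequence
#' with no admissible pair folds to the all-unpaired structure with
#' energy 0. Co-optimal structures are resolved by a deterministic
#' traceback preferring unpaired bases and 5'-most pairs.
#'
#' @param x an [RnaSequence-class], [JoinedInteraction-class] or base string
#' @param model a [LoopEnergyModel-class]
#' @return a [SecondaryStructure-class]
#' @examples
#' foldMFE("GGGAAACCC")
#' @export
foldMFE <- function(x, model = defaultEnergyModel()) {
  seq <- asRnaSeq(x)
  code <- encodeBases(seq@bases)
  res <- cpp_fold(code, modelToList(model))
  pt <- as.integer(res$pair_table)
  new("SecondaryStructure", pairTable = pt,
      dotBracket = dotBracketFromPairTable(pt),
      sequence = seq@bases, energy = res$energy)
}

asRnaSeq <- function(x) {
  if (is(x, "JoinedInteraction")) return(x@joined)
  if (is(x, "RnaSequence")) return(x)
  rnaSequence(x, kind = "joined")
}

#' Energy of a given structure under the loop-additive model
#'
#' Sums the loop energies of the structure's decomposition (see
#' [detectLoops()]); the exterior loop contributes zero.
#'
#' @param structure a [SecondaryStructure-class] carrying its sequence
#' @param model a [LoopEnergyModel-class]
#' @return energy in kcal/mol
#' @export
evaluateStructureEnergy <- function(structure, model = defaultEnergyModel()) {
  loops <- detectLoops(structure, model = model)
  sum(loops$energy)
}

#' Enumerate all admissible nested structures of a short sequence
#'
#' Exhaustive recursion over all structures satisfying the folding
#' constraints (used as the exact small-n route for unpaired
#' probabilities; feasible up to roughly 25-30 nt).
#'
#' @param x sequence input as in [foldMFE()]
#' @return list of pair tables (integer vectors, 0 = unpaired)
#' @export
enumerateStructures <- function(x) {
  seq <- asRnaSeq(x)
  ch <- strsplit(seq@bases, "")[[1]]
  n <- length(ch)
  ok <- function(i, j) {
    j - i > 3 && ch[i] != LINKER_CHAR && ch[j] != LINKER_CHAR &&
      paste0(ch[i], ch[j]) %in% PAIRABLE
  }
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- gen(i + 1L, j)                    # i unpaired
    for (k in (if (j - i > 3L) seq.int(i + 4L, j) else integer(0))) {
      if (!ok(i, k)) next
      inner <- gen(i + 1L, k - 1L)
      outer <- gen(k + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
    }
    memo[[key]] <- out
    out
  }
  lapply(gen(1L, n), function(prs) {
    pt <- integer(n)
    for (p in prs) { pt[p[1]] <- p[2]; pt[p[2]] <- p[1] }
    pt
  })
}

# fast loop-additive energy of a pair table (no object construction);
# the walk visits each closed loop once, as in detectLoops()
pairTableEnergy <- function(ch, pt, model) {
  n <- length(pt)
  E <- 0
  opens <- which(pt > seq_len(n))
  for (i in opens) {
    j <- pt[i]
    unp <- 0L; nInt <- 0L; k1 <- 0L; l1 <- 0L
    pos <- i + 1L
    while (pos < j) {
      q <- pt[pos]
      if (q > pos) {
        nInt <- nInt + 1L
        if (nInt == 1L) { k1 <- pos; l1 <- q }
        pos <- q + 1L
      } else {
        unp <- unp + 1L
        pos <- pos + 1L
      }
    }
    pe <- model@pairEnergy[ch[i], ch[j]]
    E <- E + if (nInt == 0L) {
      pe + model@hairpinBase + model@hairpinPerNt * unp
    } else if (nInt >= 2L) {
      pe + model@multiloopClose + model@multiloopBranch * nInt +
        model@multiloopUnpaired * unp
    } else if (unp == 0L) {
      pe + model@stackBonus
    } else if (k1 - i - 1L == 0L || j - l1 - 1L == 0L) {
      pe + model@bulgeBase + model@bulgePerNt * unp
    } else {
      pe + model@interiorBase + model@interiorPerNt * unp
    }
  }
  E
}

#' Unpaired probability of a subsequence
#'
#' Boltzmann probability, under the energy model at T = 310.15 K, that all
#' positions `i..k` are simultaneously unpaired. Two exact routes are
#' provided: full structure enumeration (short sequences) and a
#' McCaskill-style partition function evaluated with the interval forced
#' unpaired (any length); they agree to numerical precision.
#'
#' @param x sequence input as in [foldMFE()]
#' @param i,k 1-based inclusive interval
#' @param model a [LoopEnergyModel-class]
#' @param method `"dp"` (partition function, default), `"enumerate"`, or
#'   `"auto"` (enumeration up to 30 nt, partition function beyond)
#' @return probability in (0, 1]
#' @export
unpairedProbability <- function(x, i, k, model = defaultEnergyModel(),
                                method = c("dp", "enumerate", "auto")) {
  method <- match.arg(method)
  seq <- asRnaSeq(x)
  n <- nchar(seq@bases)
  if (i < 1 || k > n || i > k) stop("empty or out-of-range interval")
  if (method == "auto") method <- if (n <= 30) "enumerate" else "dp"
  if (method == "dp") {
    return(cpp_unpaired_prob(encodeBases(seq@bases), modelToList(model),
                             as.integer(i), as.integer(k)))
  }
  pts <- enumerateStructures(seq)
  ch <- strsplit(seq@bases, "")[[1]]
  w <- vapply(pts, function(pt)
    exp(-pairTableEnergy(ch, pt, model) / model@rt), numeric(1))
  un <- vapply(pts, function(pt) all(pt[i:k] == 0L), logical(1))
  sum(w[un]) / sum(w)
}

#' Unpaired-probability matrix for all short intervals
#'
#' @param x sequence input as in [foldMFE()]
#' @param maxSpan largest interval length to evaluate
#' @param model a [LoopEnergyModel-class]
#' @return matrix `P` with `P[i, k]` = Pu(i..k), NA beyond `maxSpan`
#' @export
unpairedProbabilityMatrix <- function(x, maxSpan,
                                      model = defaultEnergyModel()) {
  seq <- asRnaSeq(x)
  cpp_pu_matrix(encodeBases(seq@bases), modelToList(model),
                as.integer(maxSpan))
}
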