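#' Join a miRNA and an mRNA site into a single strand
#'
#' Concatenates miRNA + linker + mRNA site 5'->3'. Linker positions are
#' placeholder bases (`N`) that can never pair and are excluded from
#' composition features, so inserting them does not perturb the base pairs
#' available to the duplex.
#'
#' @param mirna,mrnaSite [RnaSequence-class] objects or base strings
#' @param linkerLength number of placeholder bases (>= 0)
#' @return a [JoinedInteraction-class]
#' @examples
#' ji <- joinInteraction("UGACGGAAGCUU", "AAGCUUCCGUCA", linkerLength = 3)
#' mirnaSpan(ji); mrnaSpan(ji)
#' @export
joinInteraction <- function(mirna, mrnaSite, linkerLength = 0L) {
  mirna <- if (is(mirna, "RnaSequence")) mirna else
    rnaSequence(mirna, id = "miRNA", kind = "miRNA")
  mrnaSite <- if (is(mrnaSite, "RnaSequence")) mrnaSite else
    rnaSequence(mrnaSite, id = "mRNA", kind = "mRNA")
  L <- as.integer(linkerLength)
  stopifnot(L >= 0L)
  nm <- nchar(mirna@bases); ns <- nchar(mrnaSite@bases)
  joined <- new("RnaSequence",
                id = paste0(mirna@id, "::", mrnaSite@id),
                bases = paste0(mirna@bases, strrep(LINKER_CHAR, L),
                               mrnaSite@bases),
                kind = "joined")
  new("JoinedInteraction", mirna = mirna, mrnaSite = mrnaSite,
      linkerLength = L, joined = joined,
      mirnaSpan = c(1L, nm),
      mrnaSpan = c(nm + L + 1L, nm + L + ns))
}

loopClassOf <- function(nInterior, nUnpaired, g5, g3) {
  if (nInterior == 0L) return("hairpin")
  if (nInterior >= 2L) return("multiloop")
  if (nUnpaired == 0L) return("stack")
  if (g5 == 0L || g3 == 0L) return("bulge")
  "interior"
}

loopEnergyOf <- function(model, class, closing, nUnpaired, nInterior) {
  pe <- model@pairEnergy[closing[1], closing[2]]
  switch(class,
    stack     = pe + model@stackBonus,
    hairpin   = pe + model@hairpinBase + model@hairpinPerNt * nUnpaired,
    bulge     = pe + model@bulgeBase + model@bulgePerNt * nUnpaired,
    interior  = pe + model@interiorBase + model@interiorPerNt * nUnpaired,
    multiloop = pe + model@multiloopClose +
      model@multiloopBranch * nInterior +
      model@multiloopUnpaired * nUnpaired,
    exterior  = 0)
}

#' Decompose a structure into its loops
#'
#' Every base pair (i, j) closes exactly one loop consisting of the pair
#' itself, the pairs immediately interior to it and the unpaired regions
#' between them; a stacked pair is a loop of size zero. Unpaired bases
#' outside any pair form the exterior loop (energy 0). The loop energies
#' sum exactly to the structure energy.
#'
#' @param structure a [SecondaryStructure-class]
#' @param model a [LoopEnergyModel-class] used for per-loop energies
#' @return a data.frame with one row per loop: `closing_i`, `closing_j`
#'   (NA for the exterior loop), `loop_class`, `size`, `n_interior`,
#'   `energy`, base-composition counts `A`,`C`,`G`,`U` over the unpaired
#'   positions, and a list column `unpaired` of sorted positions
#' @examples
#' detectLoops(foldMFE("GGGAAACCC"))
#' @export
detectLoops <- function(structure, model = defaultEnergyModel()) {
  stopifnot(is(structure, "SecondaryStructure"))
  validObject(structure)
  pt <- structure@pairTable
  n <- length(pt)
  ch <- if (nzchar(structure@sequence)) strsplit(structure@sequence, "")[[1]]
        else rep(LINKER_CHAR, n)
  scanRegion <- function(from, to) {
    # walk positions from..to at the current nesting level
    unp <- integer(0); interior <- list()
    pos <- from
    while (pos <= to) {
      q <- pt[pos]
      if (q > pos) {
        interior[[length(interior) + 1L]] <- c(pos, q)
        pos <- q + 1L
      } else {
        unp <- c(unp, pos)
        pos <- pos + 1L
      }
    }
    list(unpaired = unp, interior = interior)
  }
  rows <- list()
  addRow <- function(i, j, cls, unp, nInt) {
    comp <- table(factor(ch[unp], levels = RNA_ALPHABET))
    closing <- if (is.na(i)) NULL else c(ch[i], ch[j])
    en <- if (is.na(i)) 0 else
      loopEnergyOf(model, cls, closing, length(unp), nInt)
    df <- data.frame(
      closing_i = i, closing_j = j, loop_class = cls,
      size = length(unp), n_interior = nInt, energy = en,
      A = as.integer(comp["A"]), C = as.integer(comp["C"]),
      G = as.integer(comp["G"]), U = as.integer(comp["U"]))
    df$unpaired <- I(list(sort(unp)))
    rows[[length(rows) + 1L]] <<- df
  }
  opens <- which(pt > seq_len(n))
  for (i in opens) {
    j <- pt[i]
    reg <- scanRegion(i + 1L, j - 1L)
    nInt <- length(reg$interior)
    g5 <- if (nInt == 1L) reg$interior[[1]][1] - i - 1L else NA_integer_
    g3 <- if (nInt == 1L) j - reg$interior[[1]][2] - 1L else NA_integer_
    cls <- loopClassOf(nInt, length(reg$unpaired), g5, g3)
    addRow(i, j, cls, reg$unpaired, nInt)
  }
  ext <- scanRegion(1L, n)
  addRow(NA_integer_, NA_integer_, "exterior", ext$unpaired,
         length(ext$interior))
  do.call(rbind, rows)
}

#' Count loop membership per miRNA position
#'
#' For each miRNA position of a joined interaction, counts how many loops
#' of the folded structure cover it with an unpaired base. Positions 1-10
#' are flagged as the (extended) seed region.
#'
#' @param loops loop table from [detectLoops()] on the interaction's fold
#' @param interaction the [JoinedInteraction-class]
#' @return data.frame with `position`, `count`, `in_seed`
#' @export
loopPositionProfile <- function(loops, interaction) {
  span <- interaction@mirnaSpan
  counts <- integer(span[2] - span[1] + 1L)
  for (r in seq_len(nrow(loops))) {
    unp <- loops$unpaired[[r]]
    hit <- unp[unp >= span[1] & unp <= span[2]] - span[1] + 1L
    counts[hit] <- counts[hit] + 1L
  }
  data.frame(position = seq_along(counts), count = counts,
             in_seed = seq_along(counts) <= 10L)
}

#' Single-base mutation energy scan of a joined interaction
#'
#' Replaces the base at each requested position by every other base,
#' refolds, and reports the energy change relative to the wild-type fold.
#'
#' @param interaction a [JoinedInteraction-class]
#' @param positions 1-based positions within the joined strand (default:
#'   every non-linker position); linker positions are an error
#' @param alphabet substitution bases
#' @param model a [LoopEnergyModel-class]
#' @return data.frame with `position`, `wild_base`, `mutant_base`,
#'   `wild_energy`, `mutant_energy`, `delta`
#' @export
mutationEnergyScan <- function(interaction, positions = NULL,
                               alphabet = RNA_ALPHABET,
                               model = defaultEnergyModel()) {
  joined <- interaction@joined@bases
  ch <- strsplit(joined, "")[[1]]
  linker <- which(ch == LINKER_CHAR)
  if (is.null(positions)) positions <- setdiff(seq_along(ch), linker)
  if (any(positions %in% linker))
    stop("cannot mutate linker positions")
  if (any(positions < 1 | positions > length(ch)))
    stop("position out of range")
  wild <- foldMFE(interaction, model)@energy
  out <- list()
  for (p in positions) {
    for (b in setdiff(alphabet, ch[p])) {
      mut <- ch; mut[p] <- b
      e <- foldMFE(paste(mut, collapse = ""), model)@energy
      out[[length(out) + 1L]] <- data.frame(
        position = p, wild_base = ch[p], mutant_base = b,
        wild_energy = wild, mutant_energy = e, delta = e - wild)
    }
  }
  do.call(rbind, out)
}

#' Placeholder-robustness check of the joined-sequence convention
#'
#' Folds the miRNA-mRNA pair joined with each requested linker length and
#' reports, per linker, the fraction of the 0-linker structure's base
#' pairs recovered after mapping both structures to linker-free
#' coordinates. Agreement 1.0 means the inserted random-placeholder linker
#' leaves the duplex structure untouched.
#'
#' @param mirna,mrnaSite sequences as in [joinInteraction()]
#' @param linkerLengths integer vector, must include 0
#' @param model a [LoopEnergyModel-class]
#' @return data.frame with `linker_length`, `n_pairs`, `agreement`,
#'   `dot_bracket`
#' @export
placeholderRobustness <- function(mirna, mrnaSite, linkerLengths = c(0, 2, 5),
                                  model = defaultEnergyModel()) {
  linkerLengths <- as.integer(linkerLengths)
  if (!0L %in% linkerLengths)
    stop("linkerLengths must include 0")
  pairSet <- function(L) {
    ji <- joinInteraction(mirna, mrnaSite, L)
    st <- foldMFE(ji, model)
    pt <- st@pairTable
    nm <- ji@mirnaSpan[2]
    shift <- function(p) ifelse(p > nm, p - L, p)  # linker-free coordinates
    opens <- which(pt > seq_along(pt))
    list(pairs = if (length(opens))
           paste(shift(opens), shift(pt[opens]), sep = ":")
         else character(0),
         db = st@dotBracket)
  }
  ref <- pairSet(0L)
  out <- lapply(linkerLengths, function(L) {
    cur <- pairSet(L)
    agreement <- if (length(ref$pairs) == 0) 1 else
      length(intersect(cur$pairs, ref$pairs)) / length(ref$pairs)
    data.frame(linker_length = L, n_pairs = length(cur$pairs),
               agreement = agreement, dot_bracket = cur$db)
  })
  do.call(rbind, out)
}
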