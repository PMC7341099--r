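# Independent oracles used across the suite. These deliberately avoid the
# package's production code paths: energies are recomputed by a per-pair
# scanner over explicit pair sets, alignments by bounded enumeration, and
# rankings by a naive sorter.

ALPH <- c("A", "C", "G", "U")
CAN_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

randomRna <- function(n, bases = ALPH) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# ---- loop scanner oracle -------------------------------------------------
# For each closing pair, find the immediately interior pairs by a direct
# nesting test over all pairs (no positional walk), then classify.
oracleLoops <- function(seq, pt, model = defaultEnergyModel()) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(pt)
  opens <- which(pt > seq_len(n))
  pairs <- cbind(opens, pt[opens])
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    inside <- pairs[pairs[, 1] > i & pairs[, 2] < j, , drop = FALSE]
    immediate <- if (nrow(inside)) {
      keep <- vapply(seq_len(nrow(inside)), function(a) {
        k <- inside[a, 1]; l <- inside[a, 2]
        !any(inside[, 1] < k & inside[, 2] > l)
      }, logical(1))
      inside[keep, , drop = FALSE]
    } else inside
    covered <- unique(unlist(lapply(seq_len(nrow(immediate)), function(a)
      immediate[a, 1]:immediate[a, 2])))
    unpaired <- setdiff(setdiff((i + 1):(j - 1), covered),
                        c(pairs[, 1], pairs[, 2]))
    nInt <- nrow(immediate); unp <- length(unpaired)
    cls <- if (nInt == 0) "hairpin"
      else if (nInt >= 2) "multiloop"
      else if (unp == 0) "stack"
      else if (immediate[1, 1] - i - 1 == 0 ||
               j - immediate[1, 2] - 1 == 0) "bulge"
      else "interior"
    pe <- model@pairEnergy[ch[i], ch[j]]
    en <- switch(cls,
      stack = pe + model@stackBonus,
      hairpin = pe + model@hairpinBase + model@hairpinPerNt * unp,
      bulge = pe + model@bulgeBase + model@bulgePerNt * unp,
      interior = pe + model@interiorBase + model@interiorPerNt * unp,
      multiloop = pe + model@multiloopClose + model@multiloopBranch * nInt +
        model@multiloopUnpaired * unp)
    list(i = i, j = j, class = cls, size = unp, n_interior = nInt,
         energy = en, unpaired = sort(unpaired))
  })
  rows
}

oracleStructureEnergy <- function(seq, pt, model = defaultEnergyModel()) {
  sum(vapply(oracleLoops(seq, pt, model), `[[`, numeric(1), "energy"))
}

# minimum energy over all admissible structures, by full enumeration
oracleMfe <- function(seq, model = defaultEnergyModel()) {
  pts <- enumerateStructures(seq)
  min(vapply(pts, function(pt) oracleStructureEnergy(seq, pt, model),
             numeric(1)))
}

# structural constraint audit used by property tests
expectValidStructure <- function(st, seq = NULL) {
  pt <- pairTable(st)
  n <- length(pt)
  paired <- which(pt > 0L)
  expect_true(all(pt[pt[paired]] == paired))           # one partner each
  ij <- cbind(paired, pt[paired]); ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  if (nrow(ij)) {
    expect_true(all(ij[, 2] - ij[, 1] > 3))            # hairpin constraint
    if (!is.null(seq)) {
      ch <- strsplit(seq, "")[[1]]
      expect_true(all(paste0(ch[ij[, 1]], ch[ij[, 2]]) %in% CAN_PAIRS))
    }
    if (nrow(ij) > 1)                                   # nestedness
      for (r in seq_len(nrow(ij) - 1)) {
        k <- ij[-seq_len(r), 1]; l <- ij[-seq_len(r), 2]
        expect_false(any(k < ij[r, 2] & l > ij[r, 2] & k > ij[r, 1]))
      }
  }
  invisible(TRUE)
}

# ---- intermolecular duplex oracle ---------------------------------------
# all legal pairings of s1[i..k] x s2[j..l] (antiparallel, ends fixed),
# enumerated recursively over increasing pair chains
oracleHybrid <- function(s1, s2, i, k, j, l, model = defaultEnergyModel()) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  pairOk <- function(a, b) paste0(c1[a], c2[b]) %in% CAN_PAIRS
  if (!pairOk(i, l) || !pairOk(k, j)) stop("ends not pairable")
  gapE <- function(g1, g2) {
    if (g1 == 0 && g2 == 0) model@stackBonus
    else if (g1 == 0 || g2 == 0) model@bulgeBase + model@bulgePerNt * (g1 + g2)
    else model@interiorBase + model@interiorPerNt * (g1 + g2)
  }
  peOf <- function(a, b) model@pairEnergy[c1[a], c2[b]]
  best <- Inf
  rec <- function(a, b, acc) {
    # extend the chain from current pair (a, b) toward the mandatory end
    if (a == k && b == j) {
      best <<- min(best, acc)
      return()
    }
    if (a >= k || b <= j) return()
    for (a2 in (a + 1):k) for (b2 in (b - 1):j) {
      if ((a2 == k) != (b2 == j)) next
      if (!pairOk(a2, b2)) next
      rec(a2, b2, acc + gapE(a2 - a - 1, b - b2 - 1) + peOf(a2, b2))
    }
  }
  if (i == k && l == j) best <- peOf(i, l)
  else rec(i, l, peOf(i, l))
  best + model@duplexInit
}

# ---- bounded-gap alignment oracle ---------------------------------------
# all alignments of miRNA core positions 2..n-2 against the UTR with at
# most maxGapCols gap columns, honoring the seed constraints; returns the
# best score (or -Inf)
oracleAlign <- function(mir, utr, params = siteScoringParams(),
                        maxGapCols = 2L) {
  n <- nchar(mir)
  core <- strsplit(substr(mir, 2, n - 2), "")[[1]]
  m <- length(core)
  r <- rev(strsplit(utr, "")[[1]])
  U <- length(r)
  typeOf <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("AU", "UA", "GC", "CG")) "match"
    else if (p %in% c("GU", "UG")) "wobble" else "mismatch"
  }
  wOf <- function(pos) if (pos >= params@seedWeightRange[1] &&
                           pos <= params@seedWeightRange[2])
    params@seedWeight else 1
  sOf <- function(ty) switch(ty, match = params@matchScore,
                             wobble = params@wobbleScore,
                             mismatch = params@mismatchScore)
  seedLo <- params@seedConstraintRange[1]
  seedHi <- params@seedConstraintRange[2]
  best <- -Inf
  rec <- function(t, u, events, gaps, score, lastGap) {
    # column choices; alignment must end with an aligned column at t = m
    if (t > m) {
      if (lastGap == "") best <<- max(best, score)
      return()
    }
    pos <- t + 1
    if (u <= U) {
      ty <- typeOf(core[t], r[u])
      ev <- events + (ty != "match" && pos >= seedLo && pos <= seedHi)
      if (ev <= 1)
        rec(t + 1, u + 1, ev, gaps, score + sOf(ty) * wOf(pos),
            if (t == m) "" else "")
    }
    if (gaps < maxGapCols && t > 1 && t <= m &&
        !(pos >= seedLo && pos <= seedHi)) {
      pen <- if (lastGap == "X") params@gapExtend else params@gapOpen
      rec(t + 1, u, events, gaps + 1, score + pen, "X")
    }
    # insertion sits after the last consumed miRNA position, i.e. t
    if (gaps < maxGapCols && u <= U && t > 1 && t <= m &&
        !(t >= seedLo && t < seedHi)) {
      pen <- if (lastGap == "Y") params@gapExtend else params@gapOpen
      rec(t, u + 1, events, gaps + 1, score + pen, "Y")
    }
  }
  for (u0 in seq_len(U)) rec(1, u0, 0, 0, 0, "")
  best
}

# ---- rank-sum oracle -----------------------------------------------------
oracleRankSum <- function(kb, sb) {
  kb <- kb[order(-kb$probability, kb$molecule_id), ]
  kbr <- setNames(seq_len(nrow(kb)), kb$molecule_id)
  sb <- sb[order(sb$mean_affinity, sb$molecule_id), ]
  sbr <- setNames(seq_len(nrow(sb)), sb$molecule_id)
  ids <- sort(names(kbr))
  rs <- kbr[ids] + sbr[ids]
  ord <- order(rs, kbr[ids], ids)
  data.frame(molecule_id = ids[ord], rank_sum = as.integer(rs[ord]),
             combined_rank = seq_along(ids))
}

# small curated toy table used by dataset tests
toyRecords <- function(nRna = 10, nMol = 15, nPos = 20, seed = 5) {
  set.seed(seed)
  rna <- vapply(seq_len(nRna), function(q) randomRna(24), character(1))
  smiles <- c(loopscreen:::SMILES_AROMATIC,
              loopscreen:::SMILES_ALIPHATIC)[seq_len(nMol)]
  combos <- expand.grid(r = seq_len(nRna), m = seq_len(nMol))
  take <- sample(nrow(combos), nPos)
  data.frame(rna_id = sprintf("R%02d", combos$r[take]),
             rna_sequence = rna[combos$r[take]],
             molecule_id = sprintf("M%02d", combos$m[take]),
             smiles = smiles[combos$m[take]],
             label = "targeted")
}
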