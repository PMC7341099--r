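#' DuplexAlignment: one predicted miRNA::target duplex
#'
#' The miRNA is written 5'->3', the target strand 3'->5' beneath it
#' (antiparallel duplex convention). miRNA position 1 and the last two 3'
#' bases are excluded from the alignment; `mirnaInterval` therefore starts
#' at 2. `mrnaInterval` is in 1-based 5'->3' UTR coordinates.
#'
#' @slot mirnaAligned,mrnaAligned gapped strings of equal length
#' @slot score alignment score (reproducible by [rescoreAlignment()])
#' @slot mirnaInterval,mrnaInterval 1-based inclusive intervals
#' @slot seedEvents G:U-or-mismatch count at miRNA seed positions 2-7
#' @slot canonical TRUE iff positions 2-7 are perfect Watson-Crick,
#'   gap-free
#' @exportClass DuplexAlignment
setClass("DuplexAlignment",
  representation(mirnaAligned = "character", mrnaAligned = "character",
                 score = "numeric", mirnaInterval = "integer",
                 mrnaInterval = "integer", seedEvents = "integer",
                 canonical = "logical"))

setMethod("show", "DuplexAlignment", function(object) {
  cat(sprintf("DuplexAlignment score %.1f, UTR %d-%d, seed events %d%s\n",
              object@score, object@mrnaInterval[1], object@mrnaInterval[2],
              object@seedEvents, if (object@canonical) " (canonical)" else ""))
  cat("  miRNA 5' ", object@mirnaAligned, " 3'\n", sep = "")
  cat("  UTR   3' ", object@mrnaAligned, " 5'\n", sep = "")
})

WC <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE)
WOBBLE <- c(GU = TRUE, UG = TRUE)

colType <- function(a, b) {
  key <- paste0(a, b)
  if (isTRUE(WC[key])) "match" else if (isTRUE(WOBBLE[key])) "wobble"
  else "mismatch"
}

colScore <- function(type, pos, params) {
  s <- switch(type, match = params@matchScore,
              wobble = params@wobbleScore, mismatch = params@mismatchScore)
  w <- if (pos >= params@seedWeightRange[1] &&
           pos <= params@seedWeightRange[2]) params@seedWeight else 1
  s * w
}

inSeed <- function(pos, params) {
  pos >= params@seedConstraintRange[1] && pos <= params@seedConstraintRange[2]
}

#' Predict target sites by seed-constrained weighted alignment
#'
#' Computes optimal complementarity alignments between a miRNA and a UTR
#' with a weighted dynamic program: matches at seed positions carry higher
#' position-specific weights, gaps are affine, at most one G:U or mismatch
#' is tolerated at miRNA positions 2-7 (gaps are disallowed there), and
#' miRNA position 1 plus the last two 3' bases are excluded from the
#' alignment. Sites scoring below the cutoff are discarded; overlapping
#' sites on the UTR are resolved greedily by score, then 5'-most.
#'
#' @param mirna,utr [RnaSequence-class] objects or base strings (miRNA
#'   length >= 10, UTR length >= 6)
#' @param params a [SiteScoringParams-class]
#' @return list of [DuplexAlignment-class], sorted by descending score
#' @export
alignDuplex <- function(mirna, utr, params = siteScoringParams()) {
  mir <- asRnaSeq(mirna)@bases
  ut <- asRnaSeq(utr)@bases
  n <- nchar(mir); U <- nchar(ut)
  if (n < 10) stop("miRNA must be at least 10 nt")
  if (U < 6) stop("UTR must be at least 6 nt")
  mch <- strsplit(mir, "")[[1]]
  core <- mch[2:(n - 2)]                 # scored miRNA positions 2..n-2
  m <- length(core)
  rch <- rev(strsplit(ut, "")[[1]])      # UTR 3'->5' for antiparallel walk
  NEG <- -1e9
  # DP states: M aligned column, X miRNA base over gap, Y UTR base over gap
  M <- array(NEG, c(m, U + 1, 2))
  X <- array(NEG, c(m, U + 1, 2))
  Y <- array(NEG, c(m, U + 1, 2))
  for (t in seq_len(m)) {
    a <- t + 1L                          # original miRNA position
    for (u in seq_len(U)) {
      ty <- colType(core[t], rch[u])
      ev <- ty != "match" && inSeed(a, params)
      sc <- colScore(ty, a, params)
      for (e in 1:2) {
        ep <- e - (if (ev) 1L else 0L)   # predecessor event count index
        if (ep < 1) next
        prev <- if (t == 1L) 0 else
          max(M[t - 1, u, ep], X[t - 1, u, ep], Y[t - 1, u, ep])
        # Y/X predecessors are indexed with UTR column u (they consumed u-1
        # or u); M/X consumed rU up to u-1 -> index u; Y consumed u-1 -> u
        if (t == 1L) prev <- 0
        M[t, u + 1, e] <- sc + prev
      }
      # X: miRNA base t over a gap (disallowed in the seed-constraint range)
      if (t > 1L && !inSeed(a, params)) {
        for (e in 1:2) {
          open <- M[t - 1, u + 1, e] + params@gapOpen
          ext <- X[t - 1, u + 1, e] + params@gapExtend
          X[t, u + 1, e] <- max(open, ext)
        }
      }
      # Y: UTR base u over a gap, inserted after miRNA position a = t+1
      if (t < m && !(a >= params@seedConstraintRange[1] &&
                     a < params@seedConstraintRange[2])) {
        for (e in 1:2) {
          open <- M[t, u, e] + params@gapOpen
          ext <- Y[t, u, e] + params@gapExtend
          Y[t, u + 1, e] <- max(open, ext)
        }
      }
    }
  }
  # collect candidate end columns (alignments end on an aligned column)
  cands <- list()
  for (u in seq_len(U)) {
    best <- max(M[m, u + 1, ])
    if (best >= params@scoreCutoff)
      cands[[length(cands) + 1L]] <- c(u = u, score = best)
  }
  if (!length(cands)) return(list())
  alns <- lapply(cands, function(cd)
    tracebackAlignment(M, X, Y, m, cd["u"], core, rch, U, params))
  scores <- vapply(alns, function(a) a@score, numeric(1))
  starts <- vapply(alns, function(a) a@mrnaInterval[1], integer(1))
  ord <- order(-scores, starts)
  alns <- alns[ord]
  # greedy non-overlapping site reporting on the UTR
  kept <- list(); used <- rep(FALSE, U)
  for (a in alns) {
    iv <- a@mrnaInterval[1]:a@mrnaInterval[2]
    if (!any(used[iv])) { kept[[length(kept) + 1L]] <- a; used[iv] <- TRUE }
  }
  kept
}

tracebackAlignment <- function(M, X, Y, m, uEnd, core, rch, U, params) {
  e <- which.max(M[m, uEnd + 1, ])
  score <- M[m, uEnd + 1, e]
  t <- m; u <- as.integer(uEnd); state <- "M"
  topCols <- character(0); botCols <- character(0)
  tol <- 1e-9
  repeat {
    a <- t + 1L
    if (state == "M") {
      ty <- colType(core[t], rch[u])
      ev <- ty != "match" && inSeed(a, params)
      sc <- colScore(ty, a, params)
      topCols <- c(core[t], topCols); botCols <- c(rch[u], botCols)
      if (t == 1L) { u <- u - 1L; break }
      ep <- e - (if (ev) 1L else 0L)
      target <- M[t, u + 1, e] - sc
      prevM <- M[t - 1, u, ep]; prevX <- X[t - 1, u, ep]
      prevY <- Y[t - 1, u, ep]
      if (abs(prevM - target) < tol) { state <- "M"; t <- t - 1L; u <- u - 1L }
      else if (abs(prevX - target) < tol) { state <- "X"; t <- t - 1L; u <- u - 1L }
      else if (abs(prevY - target) < tol) { state <- "Y"; t <- t - 1L; u <- u - 1L }
      else stop("alignment traceback failure")
      e <- ep
    } else if (state == "X") {
      topCols <- c(core[t], topCols); botCols <- c("-", botCols)
      target <- X[t, u + 1, e]
      if (abs(M[t - 1, u + 1, e] + params@gapOpen - target) < tol) {
        state <- "M"
      } else state <- "X"
      t <- t - 1L
    } else {
      topCols <- c("-", topCols); botCols <- c(rch[u], botCols)
      target <- Y[t, u + 1, e]
      if (abs(M[t, u, e] + params@gapOpen - target) < tol) state <- "M"
      else state <- "Y"
      u <- u - 1L
    }
  }
  uStart <- u + 1L
  # map reversed-UTR columns back to 5'->3' UTR coordinates
  utrIv <- sort(c(U + 1L - uStart, U + 1L - as.integer(uEnd)))
  aln <- new("DuplexAlignment",
             mirnaAligned = paste(topCols, collapse = ""),
             mrnaAligned = paste(botCols, collapse = ""),
             score = score,
             mirnaInterval = c(2L, m + 1L),
             mrnaInterval = as.integer(utrIv),
             seedEvents = countSeedEvents(topCols, botCols, params),
             canonical = NA)
  aln@canonical <- isCanonicalSite(aln)
  aln
}

countSeedEvents <- function(topCols, botCols, params) {
  pos <- 2L; events <- 0L
  for (i in seq_along(topCols)) {
    if (topCols[i] != "-") {
      if (inSeed(pos, params)) {
        if (botCols[i] == "-" ||
            colType(topCols[i], botCols[i]) != "match")
          events <- events + 1L
      }
      pos <- pos + 1L
    }
  }
  events
}

#' Is a duplex alignment a canonical site?
#'
#' Canonical target sites contain minimally a perfect, gap-free 6-mer
#' Watson-Crick match at miRNA positions 2-7.
#'
#' @param alignment a [DuplexAlignment-class]
#' @return logical
#' @export
isCanonicalSite <- function(alignment) {
  top <- strsplit(alignment@mirnaAligned, "")[[1]]
  bot <- strsplit(alignment@mrnaAligned, "")[[1]]
  pos <- alignment@mirnaInterval[1]
  for (i in seq_along(top)) {
    if (top[i] == "-") {
      if (pos >= 2L && pos <= 7L) return(FALSE)  # gap inside the seed
      next
    }
    if (pos >= 2L && pos <= 7L) {
      if (bot[i] == "-" || colType(top[i], bot[i]) != "match") return(FALSE)
    }
    pos <- pos + 1L
  }
  TRUE
}

#' Rescore a duplex alignment from its gapped strings
#'
#' Recomputes the weighted alignment score (matches/wobbles/mismatches
#' with seed weighting, affine gap runs at -9 for the first gap base and
#' -4 for each additional one). For any alignment returned by
#' [alignDuplex()], this reproduces `score` exactly.
#'
#' @param alignment a [DuplexAlignment-class]
#' @param params the [SiteScoringParams-class] used to produce it
#' @return numeric score
#' @export
rescoreAlignment <- function(alignment, params = siteScoringParams()) {
  top <- strsplit(alignment@mirnaAligned, "")[[1]]
  bot <- strsplit(alignment@mrnaAligned, "")[[1]]
  pos <- alignment@mirnaInterval[1]
  score <- 0; inGap <- FALSE
  for (i in seq_along(top)) {
    if (top[i] == "-" || bot[i] == "-") {
      score <- score + if (inGap) params@gapExtend else params@gapOpen
      inGap <- TRUE
      if (top[i] != "-") pos <- pos + 1L
      next
    }
    inGap <- FALSE
    score <- score + colScore(colType(top[i], bot[i]), pos, params)
    pos <- pos + 1L
  }
  score
}

#' Scan a UTR for target sites
#'
#' Batch wrapper over [alignDuplex()] returning a site table in full-UTR
#' coordinates with deterministic ordering (score descending, then
#' 5'-most).
#'
#' @inheritParams alignDuplex
#' @param utrId identifier reported in the table
#' @return data.frame with columns `utr_id`, `start`, `end`, `score`,
#'   `seed_events`, `canonical`, `mirna_aligned`, `utr_aligned`
#' @export
scanUtr <- function(mirna, utr, params = siteScoringParams(),
                    utrId = NULL) {
  useq <- asRnaSeq(utr)
  if (is.null(utrId)) utrId <- useq@id
  alns <- alignDuplex(mirna, useq, params)
  if (!length(alns))
    return(data.frame(utr_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      seed_events = integer(0), canonical = logical(0),
                      mirna_aligned = character(0),
                      utr_aligned = character(0)))
  do.call(rbind, lapply(alns, function(a) data.frame(
    utr_id = utrId, start = a@mrnaInterval[1], end = a@mrnaInterval[2],
    score = a@score, seed_events = a@seedEvents, canonical = a@canonical,
    mirna_aligned = a@mirnaAligned, utr_aligned = a@mrnaAligned)))
}
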