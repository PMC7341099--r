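#' Minimal intermolecular hybrid energy of two subsequences
#'
#' Minimal duplex energy over all intermolecular pairings of the miRNA
#' subsequence `i..k` and the mRNA subsequence `j..l`, under the condition
#' that the subsequence ends form base pairs (miRNA `i` with mRNA `l`,
#' miRNA `k` with mRNA `j`; antiparallel convention). Consecutive duplex
#' pairs are scored as stacks, bulges or interior loops, and a constant
#' duplex-initiation penalty is added.
#'
#' @param mirna,mrna sequences ([RnaSequence-class] or strings)
#' @param i,k 1-based inclusive miRNA interval
#' @param j,l 1-based inclusive mRNA interval
#' @param model a [LoopEnergyModel-class]
#' @return list with `energy` (kcal/mol, including initiation),
#'   `mirna_interval`, `mrna_interval`
#' @export
hybridEnergy <- function(mirna, mrna, i, k, j, l,
                         model = defaultEnergyModel()) {
  s1 <- asRnaSeq(mirna)@bases; s2 <- asRnaSeq(mrna)@bases
  if (i < 1 || k > nchar(s1) || i > k) stop("invalid miRNA interval")
  if (j < 1 || l > nchar(s2) || j > l) stop("invalid mRNA interval")
  c1 <- encodeBases(s1); c2 <- encodeBases(s2)
  pairable <- function(a, b)
    a >= 0 && b >= 0 && is.finite(model@pairEnergy[a + 1, b + 1])
  if (!pairable(c1[i], c2[l]) || !pairable(c1[k], c2[j]))
    stop("terminal bases of the intervals cannot form base pairs")
  D <- cpp_hybrid_anchor(c1, c2, modelToList(model), as.integer(i),
                         as.integer(l),
                         as.integer(max(k - i + 1L, l - j + 1L)))
  e <- D[k, j]
  if (!is.finite(e)) stop("no admissible duplex for the given intervals")
  list(energy = e + model@duplexInit,
       mirna_interval = c(i, k), mrna_interval = c(j, l))
}

#' Accessibility penalty ED of an interval
#'
#' `ED = -RT log Pu(i..k)`: the energetic cost of opening the
#' intramolecular structure so that the interval is single-stranded.
#' Always >= 0, zero exactly when the interval is certainly unpaired.
#'
#' @inheritParams unpairedProbability
#' @return list with `pu` and `ed`
#' @export
accessibilityPenalty <- function(x, i, k, model = defaultEnergyModel(),
                                 method = "dp") {
  pu <- unpairedProbability(x, i, k, model, method)
  list(pu = pu, ed = -model@rt * log(pu))
}

dangleTermsFor <- function(puMat, iv, n, model) {
  # conditional flank probabilities Pru(flank | interval unpaired) and the
  # flank-weighted dangle contributions; a missing flank contributes 0
  i <- iv[1]; k <- iv[2]
  pu <- puMat[i, k]
  t5 <- if (i > 1) (puMat[i - 1, k] / pu) * model@dangle else 0
  t3 <- if (k < n) (puMat[i, k + 1] / pu) * model@dangle else 0
  list(ed = -model@rt * log(pu), dangle5 = t5, dangle3 = t3, pu = pu)
}

#' Combined accessibility-corrected interaction energy
#'
#' Assembles the combined energy of a miRNA subsequence `i..k` binding an
#' mRNA subsequence `j..l`:
#' hybrid energy + ED(miRNA interval) + conditional-flank-weighted miRNA
#' dangle terms + ED(mRNA interval) + flank-weighted mRNA dangle terms.
#' Flank weights are the conditional probabilities that the flanking base
#' is also unpaired given the interval is unpaired,
#' `Pu(flank ∪ interval) / Pu(interval)`.
#'
#' @inheritParams hybridEnergy
#' @return list with components `e_hybrid`, `ed_mirna`, `ed_mrna`,
#'   `dangle_mirna5`, `dangle_mirna3`, `dangle_mrna5`, `dangle_mrna3`,
#'   `total`, and the two intervals
#' @export
combinedEnergy <- function(mirna, mrna, i, k, j, l,
                           model = defaultEnergyModel()) {
  s1 <- asRnaSeq(mirna); s2 <- asRnaSeq(mrna)
  hy <- hybridEnergy(s1, s2, i, k, j, l, model)
  n1 <- nchar(s1@bases); n2 <- nchar(s2@bases)
  pu1 <- unpairedProbabilityMatrix(s1, maxSpan = (k - i + 1L) + 2L, model)
  pu2 <- unpairedProbabilityMatrix(s2, maxSpan = (l - j + 1L) + 2L, model)
  d1 <- dangleTermsFor(pu1, c(i, k), n1, model)
  d2 <- dangleTermsFor(pu2, c(j, l), n2, model)
  total <- hy$energy + d1$ed + d1$dangle5 + d1$dangle3 +
    d2$ed + d2$dangle5 + d2$dangle3
  list(e_hybrid = hy$energy, ed_mirna = d1$ed, ed_mrna = d2$ed,
       dangle_mirna5 = d1$dangle5, dangle_mirna3 = d1$dangle3,
       dangle_mrna5 = d2$dangle5, dangle_mrna3 = d2$dangle3,
       total = total,
       mirna_interval = c(i, k), mrna_interval = c(j, l))
}

#' Minimize the combined interaction energy over interval pairs
#'
#' Exhaustive search over all miRNA/mRNA interval quadruples (i,k;j,l)
#' with interval lengths up to `maxInterval` whose ends can pair,
#' returning the quadruple with the lowest combined energy. Ties break
#' deterministically 5'-most on the miRNA, then on the mRNA.
#'
#' @inheritParams hybridEnergy
#' @param maxInterval largest interval length considered (>= 4)
#' @return the best [combinedEnergy()] result, or NULL if no quadruple is
#'   pairable
#' @export
minimumEnergyInteraction <- function(mirna, mrna, maxInterval = 20L,
                                     model = defaultEnergyModel()) {
  if (maxInterval < 4) stop("maxInterval must be >= 4")
  s1 <- asRnaSeq(mirna); s2 <- asRnaSeq(mrna)
  c1 <- encodeBases(s1@bases); c2 <- encodeBases(s2@bases)
  n1 <- length(c1); n2 <- length(c2)
  pu1 <- unpairedProbabilityMatrix(s1, maxSpan = maxInterval + 2L, model)
  pu2 <- unpairedProbabilityMatrix(s2, maxSpan = maxInterval + 2L, model)
  pl <- modelToList(model)
  pairable <- function(a, b)
    a >= 0 && b >= 0 && is.finite(model@pairEnergy[a + 1, b + 1])
  best <- NULL; bestKey <- NULL
  for (i in seq_len(n1)) {
    for (l in seq_len(n2)) {
      if (!pairable(c1[i], c2[l])) next
      D <- cpp_hybrid_anchor(c1, c2, pl, i, l, as.integer(maxInterval))
      ends <- which(is.finite(D), arr.ind = TRUE)
      for (r in seq_len(nrow(ends))) {
        k <- ends[r, 1]; j <- ends[r, 2]
        if (k - i + 1L > maxInterval || l - j + 1L > maxInterval) next
        d1 <- dangleTermsFor(pu1, c(i, k), n1, model)
        d2 <- dangleTermsFor(pu2, c(j, l), n2, model)
        total <- D[k, j] + model@duplexInit + d1$ed + d1$dangle5 +
          d1$dangle3 + d2$ed + d2$dangle5 + d2$dangle3
        key <- c(total, i, k, j, l)
        if (is.null(best) || total < best$total - 1e-12 ||
            (abs(total - best$total) <= 1e-12 &&
             isLexBefore(key[-1], bestKey))) {
          best <- list(e_hybrid = D[k, j] + model@duplexInit,
                       ed_mirna = d1$ed, ed_mrna = d2$ed,
                       dangle_mirna5 = d1$dangle5, dangle_mirna3 = d1$dangle3,
                       dangle_mrna5 = d2$dangle5, dangle_mrna3 = d2$dangle3,
                       total = total,
                       mirna_interval = c(i, k), mrna_interval = c(j, l))
          bestKey <- key[-1]
        }
      }
    }
  }
  best
}

isLexBefore <- function(a, b) {
  for (q in seq_along(a)) {
    if (a[q] < b[q]) return(TRUE)
    if (a[q] > b[q]) return(FALSE)
  }
  FALSE
}
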