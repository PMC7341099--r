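test_that("perfect planted complements give canonical top sites", {
  p <- generateMirnaMrnaPair(seed = 3)
  tab <- scanUtr(p$mirna, p$utr)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$start, p$site_start)
  expect_equal(tab$end, p$site_end)
  expect_true(tab$canonical)
  expect_equal(tab$seed_events, 0L)
  # reversing the UTR destroys the site
  revUtr <- paste(rev(strsplit(seqBases(p$utr), "")[[1]]), collapse = "")
  expect_equal(nrow(scanUtr(p$mirna, revUtr)), 0L)
  # no complementarity at all
  expect_equal(nrow(scanUtr(strrep("A", 20), strrep("A", 40))), 0L)
})

test_that("at most one seed event passes, two reject despite 3' pairing", {
  set.seed(31)
  # miRNA with G at seed positions 4 and 6 so G:U wobbles can be planted
  mch <- strsplit(randomRna(22), "")[[1]]
  mch[c(4, 6)] <- "G"
  mir <- paste(mch, collapse = "")
  perfect <- loopscreen:::revComp(substr(mir, 2, 20))
  wobble <- function(site, mirPositions) {
    # replace the C opposite a seed G by U: a G:U event, still pairable
    sch <- strsplit(site, "")[[1]]
    for (p in mirPositions) sch[nchar(site) - (p - 2)] <- "U"
    paste(sch, collapse = "")
  }
  utrOf <- function(site) paste0(randomRna(8), site, randomRna(8))
  one <- scanUtr(mir, utrOf(wobble(perfect, 4)))
  expect_equal(nrow(one), 1L)       # a single seed G:U is tolerated
  expect_equal(one$seed_events, 1L)
  expect_false(one$canonical)
  # two seed events: rejected by the seed constraint itself, even at a
  # cutoff the 3'-compensated alignment would otherwise clear easily
  two <- scanUtr(mir, utrOf(wobble(perfect, c(4, 6))),
                 siteScoringParams(scoreCutoff = 80))
  expect_true(nrow(two) == 0L || all(two$seed_events <= 1L))
  expect_false(any(two$start <= 9 + 10 & two$end >= 9 + 10))
})

test_that("canonicality requires a perfect gap-free 2-7 Watson-Crick core", {
  aln <- new("DuplexAlignment", mirnaAligned = "ACGUACGUAC",
             mrnaAligned = "UGCAUGCAUG", score = 150,
             mirnaInterval = c(2L, 11L), mrnaInterval = c(1L, 10L),
             seedEvents = 0L, canonical = NA)
  expect_true(isCanonicalSite(aln))
  # G:U wobble at miRNA position 4 breaks canonicality
  gu <- aln; gu@mirnaAligned <- "ACGUACGUAC"; gu@mrnaAligned <- "UGUAUGCAUG"
  expect_false(isCanonicalSite(gu))
  # a gap inside the seed breaks canonicality
  gap <- aln
  gap@mirnaAligned <- "ACG-UACGUAC"; gap@mrnaAligned <- "UGCAAUGCAUG"
  expect_false(isCanonicalSite(gap))
})

test_that("returned scores are reproducible and obey the seed constraint", {
  set.seed(57)
  nSites <- 0
  for (q in 1:25) {
    mir <- randomRna(20)
    utr <- paste0(randomRna(12),
                  loopscreen:::revComp(substr(mir, 2, 18)), randomRna(12))
    alns <- alignDuplex(mir, utr)
    for (a in alns) {
      nSites <- nSites + 1
      expect_equal(rescoreAlignment(a), a@score, tolerance = 1e-9)
      expect_lte(a@seedEvents, 1L)
      expect_gte(a@score, 120)
    }
  }
  expect_gt(nSites, 10)
})

test_that("lowering the cutoff never removes previously reported sites", {
  set.seed(77)
  mir <- randomRna(20)
  utr <- paste0(randomRna(10), loopscreen:::revComp(substr(mir, 2, 18)),
                randomRna(20), loopscreen:::revComp(substr(mir, 2, 14)),
                randomRna(10))
  high <- scanUtr(mir, utr, siteScoringParams(scoreCutoff = 120))
  low <- scanUtr(mir, utr, siteScoringParams(scoreCutoff = 60))
  keyOf <- function(t) paste(t$start, t$end, round(t$score, 6))
  expect_true(all(keyOf(high) %in% keyOf(low)))
  expect_gte(nrow(low), nrow(high))
})

test_that("constrained DP scores match the bounded-gap exhaustive oracle", {
  set.seed(404)
  params <- siteScoringParams(scoreCutoff = 30)
  checked <- 0
  for (q in 1:12) {
    mir <- randomRna(15)
    utr <- paste0(randomRna(sample(4:8, 1)),
                  loopscreen:::revComp(substr(mir, 2, 13)),
                  randomRna(sample(4:8, 1)))
    utr <- substr(utr, 1, 30)
    alns <- alignDuplex(mir, utr, params)
    if (!length(alns)) next
    best <- alns[[1]]@score
    nGapCols <- sum(strsplit(paste0(alns[[1]]@mirnaAligned,
                                    alns[[1]]@mrnaAligned), "")[[1]] == "-")
    oracle <- oracleAlign(mir, utr, params, maxGapCols = 2L)
    if (nGapCols <= 2) {
      expect_equal(best, oracle, tolerance = 1e-9,
                   label = paste("best score for", mir))
      checked <- checked + 1
    } else {
      expect_gte(best, oracle)
    }
  }
  expect_gt(checked, 6)
})
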