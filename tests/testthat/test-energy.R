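test_that("hybrid energies: perfect duplexes, mismatch penalty, oracle", {
  m <- defaultEnergyModel()
  # perfectly complementary 6-mers: 6 pair terms + 5 stacks + initiation
  h <- hybridEnergy("GGGGGG", "CCCCCC", 1, 6, 1, 6)
  expect_equal(h$energy,
               6 * m@pairEnergy["G", "C"] + 5 * m@stackBonus + m@duplexInit,
               tolerance = 1e-12)
  # one interior mismatch is strictly worse than the perfect duplex
  hMis <- hybridEnergy("GGGAGG", "CCCCCC", 1, 6, 1, 6)
  expect_gt(hMis$energy, h$energy)
  # non-pairable terminal bases violate the precondition
  expect_error(hybridEnergy("AGGGGA", "CCCCCC", 1, 6, 1, 6), "terminal")
  # random subsequences against the brute-force duplex oracle
  set.seed(88)
  tried <- 0
  while (tried < 10) {
    s1 <- randomRna(8); s2 <- randomRna(10)
    ok <- tryCatch({
      o <- oracleHybrid(s1, s2, 1, 8, 1, 10)
      h <- hybridEnergy(s1, s2, 1, 8, 1, 10)
      expect_equal(h$energy, o, tolerance = 1e-9,
                   label = paste("hybrid", s1, s2))
      TRUE
    }, error = function(e) FALSE)
    if (ok) tried <- tried + 1
  }
})

test_that("unpaired probabilities are exact and consistent across routes", {
  # no admissible pair anywhere: every interval is certainly unpaired
  s <- "ACCACACACCAA"
  for (iv in list(c(1, 1), c(3, 7), c(1, 12)))
    expect_equal(unpairedProbability(s, iv[1], iv[2]), 1)
  # hairpin-loop bases of GAAAC are unpaired in both enumerable structures
  expect_equal(unpairedProbability("GAAAC", 2, 4, method = "enumerate"), 1)
  expect_equal(unpairedProbability("GAAAC", 2, 4, method = "dp"), 1,
               tolerance = 1e-12)
  # event containment: superinterval probability never exceeds subinterval
  set.seed(12)
  for (q in 1:10) {
    s <- randomRna(sample(10:20, 1))
    n <- nchar(s)
    i <- sample(2:(n - 2), 1)
    puSub <- unpairedProbability(s, i, i + 1)
    puSuper <- unpairedProbability(s, i - 1, min(n, i + 2))
    expect_lte(puSuper, puSub + 1e-12)
  }
  # enumeration and partition-function routes agree to 1e-9
  set.seed(13)
  for (q in 1:20) {
    s <- randomRna(sample(8:20, 1))
    n <- nchar(s)
    i <- sample(seq_len(n - 2), 1)
    k <- min(n, i + sample(0:4, 1))
    expect_lt(abs(unpairedProbability(s, i, k, method = "dp") -
                  unpairedProbability(s, i, k, method = "enumerate")), 1e-9)
  }
  expect_error(unpairedProbability("GAAAC", 4, 2), "interval")
})

test_that("accessibility penalties are nonnegative and vanish iff Pu = 1", {
  ap <- accessibilityPenalty("ACCACACACCAA", 2, 6)
  expect_equal(ap$pu, 1)
  expect_equal(ap$ed, 0)
  set.seed(14)
  for (q in 1:10) {
    s <- randomRna(15)
    ap <- accessibilityPenalty(s, 4, 9)
    expect_gte(ap$ed, 0)
    if (ap$pu < 1) expect_gt(ap$ed, 0)
  }
})

test_that("combined energy assembles exactly from its components", {
  m <- defaultEnergyModel()
  # fully accessible strands (no intramolecular pair possible):
  # EDs are zero and each flank dangle contributes the full dangle term
  ce <- combinedEnergy("CCCCCCCC", "GGGGGGGG", 2, 7, 2, 7)
  expect_equal(ce$ed_mirna, 0, tolerance = 1e-12)
  expect_equal(ce$ed_mrna, 0, tolerance = 1e-12)
  expect_equal(ce$dangle_mirna5, m@dangle, tolerance = 1e-12)
  expect_equal(ce$total,
               ce$e_hybrid + ce$ed_mirna + ce$dangle_mirna5 +
                 ce$dangle_mirna3 + ce$ed_mrna + ce$dangle_mrna5 +
                 ce$dangle_mrna3, tolerance = 1e-12)
  # interval at the 5' terminus: no 5' flank, no 5' dangle
  ce5 <- combinedEnergy("CCCCCCCC", "GGGGGGGG", 1, 6, 2, 7)
  expect_equal(ce5$dangle_mirna5, 0)
  # toy pair: total equals a hand-assembled sum of independently computed
  # components (hybrid DP, Pu ratios, dangles), to 1e-12
  set.seed(15)
  tried <- 0
  while (tried < 6) {
    s1 <- randomRna(14); s2 <- randomRna(16)
    ce <- tryCatch(combinedEnergy(s1, s2, 3, 9, 4, 10),
                   error = function(e) NULL)
    if (is.null(ce)) next
    tried <- tried + 1
    hy <- hybridEnergy(s1, s2, 3, 9, 4, 10)$energy
    edOf <- function(s, i, k) -m@rt * log(unpairedProbability(s, i, k))
    condDangle <- function(s, i, k) {
      pu <- unpairedProbability(s, i, k)
      n <- nchar(s)
      c(if (i > 1) unpairedProbability(s, i - 1, k) / pu * m@dangle else 0,
        if (k < n) unpairedProbability(s, i, k + 1) / pu * m@dangle else 0)
    }
    d1 <- condDangle(s1, 3, 9); d2 <- condDangle(s2, 4, 10)
    expect_equal(ce$total,
                 hy + edOf(s1, 3, 9) + d1[1] + d1[2] +
                   edOf(s2, 4, 10) + d2[1] + d2[2],
                 tolerance = 1e-10)
  }
})

test_that("minimum-energy search finds accessible planted sites", {
  p <- generateMirnaMrnaPair(seed = 5, mirnaLength = 16)
  best <- minimumEnergyInteraction(p$mirna, p$utr, maxInterval = 12)
  expect_false(is.null(best))
  # the minimizer overlaps the planted complementary site on the UTR
  expect_lt(best$mrna_interval[1], p$site_end)
  expect_gt(best$mrna_interval[2], p$site_start)
  # sequestering the same site in a planted hairpin raises the combined
  # energy evaluated at the site (the hybrid term is unchanged, the
  # accessibility penalty grows)
  pSeq <- generateMirnaMrnaPair(seed = 5, mirnaLength = 16,
                                sequesterSite = TRUE)
  iv <- c(2, 10)
  jl <- c(p$site_start + 3, p$site_start + 11)
  ceOpen <- tryCatch(combinedEnergy(p$mirna, p$utr, iv[1], iv[2],
                                    jl[1], jl[2]), error = function(e) NULL)
  ceSeq <- tryCatch(combinedEnergy(pSeq$mirna, pSeq$utr, iv[1], iv[2],
                                   jl[1], jl[2]), error = function(e) NULL)
  if (!is.null(ceOpen) && !is.null(ceSeq)) {
    expect_equal(ceSeq$e_hybrid, ceOpen$e_hybrid, tolerance = 1e-9)
    expect_gt(ceSeq$total, ceOpen$total)
  } else {
    # interval ends not pairable for this draw; compare the best totals
    b1 <- minimumEnergyInteraction(p$mirna, p$utr, maxInterval = 10)
    b2 <- minimumEnergyInteraction(pSeq$mirna, pSeq$utr, maxInterval = 10)
    expect_gt(b2$total, b1$total)
  }
  # role swap: the hybrid component is symmetric, the EDs exchange
  ce <- combinedEnergy("GGGGGGGG", "CCCCCCCC", 2, 7, 3, 8)
  sw <- combinedEnergy("CCCCCCCC", "GGGGGGGG", 3, 8, 2, 7)
  expect_equal(ce$e_hybrid, sw$e_hybrid, tolerance = 1e-9)
  expect_equal(ce$ed_mirna, sw$ed_mrna, tolerance = 1e-12)
})

test_that("seed-region loop mutations stabilize the joined complex most", {
  # duplexes with a non-complementary bubble at miRNA positions 4-6:
  # mutating inside the bubble can restore pairing (energy drops), while
  # positions far from the seed mostly cannot
  set.seed(19)
  seedDeltas <- c(); farDeltas <- c()
  for (q in 1:6) {
    mir <- randomRna(16)
    sch <- strsplit(loopscreen:::revComp(mir), "")[[1]]
    for (p in 4:6) {
      col <- 16 - p + 1
      mch <- substr(mir, p, p)
      sch[col] <- setdiff(c("A", "C"),
                          c(chartr("ACGU", "UGCA", mch), mch))[1]
    }
    ji <- joinInteraction(mir, paste(sch, collapse = ""), 3)
    scan <- mutationEnergyScan(ji, positions = c(4:6, 12:14))
    seedDeltas <- c(seedDeltas, scan$delta[scan$position %in% 4:6])
    farDeltas <- c(farDeltas, scan$delta[scan$position %in% 12:14])
  }
  expect_lt(mean(seedDeltas), mean(farDeltas))
  expect_gt(mean(seedDeltas < 0), mean(farDeltas < 0))
})
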