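test_that("dot-bracket parsing handles the basic shapes and round-trips", {
  expect_equal(pairTable(parseDotBracket("....")), rep(0L, 4))
  expect_equal(pairTable(parseDotBracket("(...)")), c(5L, 0L, 0L, 0L, 1L))
  # stack-based oracle for a nested two-helix structure
  st <- parseDotBracket("((..((...))..))")
  got <- which(pairTable(st) > seq_along(pairTable(st)))
  expect_equal(lapply(got, function(i) c(i, pairTable(st)[i])),
               list(c(1L, 15L), c(2L, 14L), c(5L, 11L), c(6L, 10L)))
  expect_error(parseDotBracket("(()"), "unbalanced")
  expect_error(parseDotBracket("())"), "position 3")
  expect_error(parseDotBracket("..x."), "invalid dot-bracket")
  # parse . to_dotbracket is the identity on random folded structures
  set.seed(41)
  for (q in 1:20) {
    db <- dotBracket(foldMFE(randomRna(sample(10:30, 1))))
    expect_identical(dotBracket(parseDotBracket(db)), db)
  }
})

test_that("folding degenerate and single-pair sequences", {
  st <- foldMFE("AAAA")
  expect_equal(dotBracket(st), "....")
  expect_equal(structureEnergy(st), 0)
  # G-C hairpin at minimal separation: stable under the default model
  st <- foldMFE("GAAAC")
  expect_equal(dotBracket(st), "(...)")
  expect_lt(structureEnergy(st), 0)
  # all A/C: no admissible pair at all
  expect_equal(dotBracket(foldMFE("ACCACACACCAA")),
               strrep(".", 12))
})

test_that("MFE equals the exhaustive enumeration minimum on short RNAs", {
  set.seed(2024)
  for (q in 1:60) {
    s <- randomRna(sample(8:22, 1))
    st <- foldMFE(s)
    expectValidStructure(st, s)
    expect_equal(structureEnergy(st), oracleMfe(s), tolerance = 1e-9,
                 label = paste("MFE of", s))
    # fold energy also equals the loop-decomposition sum of its own output
    expect_equal(structureEnergy(st),
                 oracleStructureEnergy(s, pairTable(st)), tolerance = 1e-9)
  }
})

test_that("joined interactions keep spans and exclude linkers from pairing", {
  mir <- randomRna(22); site <- randomRna(25)
  ji <- joinInteraction(mir, site, 0)
  expect_equal(nchar(seqBases(joinedSequence(ji))), 47)
  ji3 <- joinInteraction(mir, site, 3)
  expect_equal(nchar(seqBases(joinedSequence(ji3))), 50)
  expect_equal(substr(seqBases(joinedSequence(ji3)), mirnaSpan(ji3)[1],
                      mirnaSpan(ji3)[2]), mir)
  expect_equal(substr(seqBases(joinedSequence(ji3)), mrnaSpan(ji3)[1],
                      mrnaSpan(ji3)[2]), site)
  # linker positions never pair, for any linker length
  set.seed(7)
  for (L in c(1, 3, 6)) {
    jj <- joinInteraction(randomRna(16), randomRna(16), L)
    pt <- pairTable(foldMFE(jj))
    linkerPos <- (mirnaSpan(jj)[2] + 1):(mrnaSpan(jj)[1] - 1)
    expect_true(all(pt[linkerPos] == 0L))
  }
})

test_that("loop decomposition matches the per-pair scanner and is additive", {
  # canonical shapes first
  loops <- detectLoops(foldMFE("GGGAAACCC"))
  closed <- loops[loops$loop_class != "exterior", ]
  expect_equal(sum(closed$loop_class == "stack"), 2L)
  expect_equal(sum(closed$loop_class == "hairpin"), 1L)
  expect_equal(closed$size[closed$loop_class == "hairpin"], 3L)
  expect_true(all(closed$size[closed$loop_class == "stack"] == 0L))

  st <- parseDotBracket("((..((...))..))", sequence = "GGAAGGAAACCAACC")
  cls <- detectLoops(st)$loop_class
  expect_equal(sort(cls), sort(c("stack", "interior", "stack", "hairpin",
                                 "exterior")))

  allUn <- detectLoops(parseDotBracket("......", sequence = "AACCAA"))
  expect_equal(allUn$loop_class, "exterior")
  expect_equal(allUn$size, 6L)

  set.seed(99)
  for (q in 1:25) {
    s <- randomRna(sample(12:30, 1))
    st <- foldMFE(s)
    loops <- detectLoops(st)
    # additivity: loop energies sum exactly to the structure energy
    expect_equal(sum(loops$energy), structureEnergy(st), tolerance = 1e-12)
    # agreement with the brute-force scanner, pair by pair
    orac <- oracleLoops(s, pairTable(st))
    closed <- loops[loops$loop_class != "exterior", , drop = FALSE]
    expect_equal(nrow(closed), length(orac))
    for (r in seq_along(orac)) {
      row <- closed[closed$closing_i == orac[[r]]$i, ]
      expect_equal(row$loop_class, orac[[r]]$class)
      expect_equal(row$size, orac[[r]]$size)
      expect_equal(row$energy, orac[[r]]$energy, tolerance = 1e-12)
      expect_equal(row$unpaired[[1]], orac[[r]]$unpaired)
    }
    # every unpaired non-exterior base belongs to exactly one loop
    allUnp <- unlist(loops$unpaired)
    expect_equal(sort(allUnp), which(pairTable(st) == 0L))
    expect_false(any(duplicated(allUnp)))
  }
})

test_that("loop position profiles count miRNA loop membership", {
  mir <- randomRna(22); site <- randomRna(20)
  ji <- joinInteraction(mir, site, 0)
  noLoops <- detectLoops(parseDotBracket(strrep(".", 42)))[0, ]
  prof <- loopPositionProfile(noLoops, ji)
  expect_true(all(prof$count == 0))
  expect_equal(prof$in_seed, seq_len(22) <= 10)
  # single hairpin covering miRNA positions 4-6
  one <- data.frame(closing_i = 3L, closing_j = 7L, loop_class = "hairpin",
                    size = 3L, n_interior = 0L, energy = 0,
                    A = 0L, C = 0L, G = 0L, U = 0L)
  one$unpaired <- I(list(4:6))
  prof <- loopPositionProfile(one, ji)
  expect_equal(which(prof$count == 1L), 4:6)
  expect_true(all(prof$count[-(4:6)] == 0))
})

test_that("loops concentrate near the seed when bubbles are planted there", {
  # imperfect duplexes whose non-complementary bubble sits at miRNA
  # positions 4-6: the resulting loops should put their mass at
  # positions 1-10 of the miRNA
  set.seed(17)
  seedMass <- 0; totalMass <- 0
  for (q in 1:8) {
    mir <- randomRna(20)
    site <- loopscreen:::revComp(mir)
    sch <- strsplit(site, "")[[1]]
    # disrupt complementarity opposite miRNA positions 4-6
    for (p in 4:6) sch[20 - p + 1] <- setdiff(c("A", "C"),
                                              sch[20 - p + 1])[1]
    ji <- joinInteraction(mir, paste(sch, collapse = ""), 3)
    loops <- detectLoops(foldMFE(ji))
    prof <- loopPositionProfile(loops, ji)
    seedMass <- seedMass + sum(prof$count[prof$in_seed])
    totalMass <- totalMass + sum(prof$count)
  }
  expect_gt(seedMass / totalMass, 0.5)
})

test_that("mutation scans refold and report exact energy deltas", {
  # mutation in a long unpaired tail leaves the fold untouched
  s <- joinInteraction("GGGGGAAAACCCCC", "AAAAAAAAAA", 0)
  scan <- mutationEnergyScan(s, positions = 20, alphabet = "C")
  expect_equal(scan$delta, 0)
  # destroying the only pair of a minimal hairpin raises the energy to 0
  h <- joinInteraction("GAAAC", "ACACA", 0)
  scan <- mutationEnergyScan(h, positions = 1)
  expect_true(all(scan$delta > 0))
  # A/C substitutions admit no pair at all; U can open a weaker A-U hairpin
  expect_true(all(abs(scan$mutant_energy[scan$mutant_base != "U"]) < 1e-9))
  # wild energy is constant across all scan entries
  ji <- joinInteraction(randomRna(10), randomRna(10), 2)
  scan <- mutationEnergyScan(ji)
  expect_equal(length(unique(scan$wild_energy)), 1L)
  expect_equal(scan$wild_energy[1], structureEnergy(foldMFE(ji)))
  # deltas equal independently recomputed enumeration MFEs
  ch <- strsplit(seqBases(joinedSequence(ji)), "")[[1]]
  wildOracle <- oracleMfe(seqBases(joinedSequence(ji)))
  for (r in sample(nrow(scan), 6)) {
    mch <- ch; mch[scan$position[r]] <- scan$mutant_base[r]
    expect_equal(scan$delta[r],
                 oracleMfe(paste(mch, collapse = "")) - wildOracle,
                 tolerance = 1e-9)
  }
  # linker positions cannot be mutated
  expect_error(mutationEnergyScan(ji, positions = 11), "linker")
})

test_that("placeholder linkers hardly influence the folded duplex", {
  expect_equal(placeholderRobustness("GAAAC", "GAAAC",
                                     linkerLengths = 0)$agreement, 1)
  # strongly seed-complementary synthetic pair
  set.seed(23)
  mir <- randomRna(20)
  site <- loopscreen:::revComp(mir)
  rep <- placeholderRobustness(mir, site, linkerLengths = c(0, 2, 5))
  expect_true(all(rep$agreement >= 0.9))
  # oracle: recompute the agreement by explicit pair-set intersection
  for (L in c(2, 5)) {
    p0 <- foldMFE(joinInteraction(mir, site, 0))
    pL <- foldMFE(joinInteraction(mir, site, L))
    toSet <- function(st, lk) {
      pt <- pairTable(st)
      op <- which(pt > seq_along(pt))
      shift <- function(p) ifelse(p > 20, p - lk, p)
      paste(shift(op), shift(pt[op]))
    }
    expected <- length(intersect(toSet(pL, L), toSet(p0, 0))) /
      length(toSet(p0, 0))
    expect_equal(rep$agreement[rep$linker_length == L], expected)
  }
  expect_error(placeholderRobustness("GAAAC", "GAAAC", linkerLengths = c(2)),
               "include 0")
})
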