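test_that("hand-built sites are found at their exact type and position", {
  # miRNA positions 2-8 = GCUGGUC; target carries its reverse complement
  mir <- paste0("U", "GCUGGUC", "AAAAAAAAAAAAAA")
  site8 <- paste0("GACCAGC", "A")
  target <- paste0("CCGCC", site8, "GGCGG")
  s <- findSeedSites(mir, target)
  expect_equal(nrow(s), 1)
  expect_identical(s$site_type, "8mer")
  expect_identical(s$start, 5L)

  # without the opposite-position-1 A it degrades to 7mer-m8
  target2 <- paste0("CCGCC", "GACCAGC", "GGCGG")
  expect_identical(findSeedSites(mir, target2)$site_type, "7mer-m8")

  # seed 2-7 only (break the position-8 pair) with A -> 7mer-A1, else 6mer
  target3 <- paste0("CCGCC", "ACCAGC", "A", "GGCG")
  expect_identical(findSeedSites(mir, target3)$site_type, "7mer-A1")
  target4 <- paste0("CCGCC", "ACCAGC", "GGGCG")
  expect_identical(findSeedSites(mir, target4)$site_type, "6mer")

  # no complement, no sites
  expect_equal(nrow(findSeedSites(mir, "CCCCCCCCCCCC")), 0)
  expect_error(findSeedSites("ACGTN123", target), "outside")
})

test_that("junction-spanning sites are found only on circular targets", {
  set.seed(21)
  mir <- randomRna(22)
  site <- plantSite8mer(mir)
  base <- paste(rep("C", 20), collapse = "")
  # plant so the site wraps: starts 4 nt before the junction
  circ <- writeIntoCircle(base, site, 17)
  sc <- findSeedSites(mir, circ, circular = TRUE)
  expect_equal(nrow(sc), 1)
  expect_identical(sc$start, 16L)
  expect_identical(sc$site_type, "8mer")
  sl <- findSeedSites(mir, circ, circular = FALSE)
  expect_equal(nrow(sl), 0)
})

test_that("scanner agrees with the brute-force oracle on random pairs", {
  set.seed(42)
  for (i in 1:30) {
    mir <- randomRna(22)
    L <- sample(30:400, 1)
    circular <- i %% 2 == 0
    target <- randomRna(L)
    if (i %% 3 == 0) # enrich with a planted site to guarantee hits
      target <- writeIntoCircle(target, plantSite8mer(mir),
                                sample(L, 1))
    got <- findSeedSites(mir, target, circular = circular)
    want <- bruteSeedSites(mir, target, circular = circular)
    expect_identical(got[c("site_type", "start")],
                     want[c("site_type", "start")],
                     info = paste("case", i))
  }
})

test_that("AU score counts flanking A/U content with truncation and wrap", {
  mir <- paste0("U", "GCUGGUC", randomRna(14))
  # site at position 10 (0-based), all-AU flanks
  target <- paste0(strrep("A", 10), "GACCAGCA", strrep("U", 40))
  s <- findSeedSites(mir, target)
  expect_equal(s$au_score, 1.0)
  # all-GC flanks
  target2 <- paste0(strrep("G", 10), "GACCAGCA", strrep("C", 40))
  expect_equal(findSeedSites(mir, target2)$au_score, 0.0)
  # half AU on each side: 15 of 30 per flank
  half <- paste0(strrep("A", 15), strrep("C", 15))
  target3 <- paste0(strrep("C", 15), strrep("A", 15), "GACCAGCA", half,
                    "GG")
  s3 <- findSeedSites(mir, target3)
  expect_equal(s3$au_score[1], 0.5)
  # direct call with truncated flank at a sequence end
  expect_equal(auScore("GACCAGCAUUUU", 0, "8mer", flank = 30), 1.0)
})

test_that("miRNA ranking follows tier, site count, AU score, then id", {
  set.seed(5)
  base <- strrep("G", 200)
  m8 <- "UGCUGGUCAAAAAAAAAAAAAA"    # seed rc GACCAGC
  m6 <- "UAAGGCAGAAAAAAAAAAAAAA"    # seed 2-7 AAGGCA -> rc UGCCUU
  circ <- writeIntoCircle(base, "GACCAGCA", 20)
  circ <- writeIntoCircle(circ, "UGCCUUG", 60)   # 6mer only (G after)
  circ <- writeIntoCircle(circ, "UGCCUUG", 100)  # second 6mer
  lib <- c(mir8 = m8, mir6 = m6)
  rk <- rankMirnasForCirc(circ, lib, k = 5)
  expect_identical(rk$mirna_id, c("mir8", "mir6"))
  expect_identical(rk$best_site_type, c("8mer", "6mer"))
  expect_identical(rk$n_sites, c(1L, 2L))

  # only one miRNA has a site
  rk1 <- rankMirnasForCirc(writeIntoCircle(base, "GACCAGCA", 20), lib, 5)
  expect_identical(rk1$mirna_id, "mir8")

  expect_error(rankMirnasForCirc(circ, lib, k = 0), "k must be")
})

test_that("top-k selection is invariant to library shuffling", {
  set.seed(33)
  circ <- randomRna(300)
  lib <- stats::setNames(vapply(1:12, function(i) randomRna(22), ""),
                         sprintf("m%02d", 1:12))
  for (mi in names(lib)[1:7])
    circ <- writeIntoCircle(circ, plantSite8mer(lib[[mi]]),
                            20 + 25 * match(mi, names(lib)))
  ref <- rankMirnasForCirc(circ, lib, k = 5)
  expect_equal(nrow(ref), 5)
  for (i in 1:5) {
    shuffled <- lib[sample(length(lib))]
    expect_identical(rankMirnasForCirc(circ, shuffled, k = 5), ref)
  }
})

test_that("rotating a circular target leaves site multisets invariant", {
  set.seed(8)
  mir <- randomRna(22)
  circ <- writeIntoCircle(randomRna(60), plantSite8mer(mir), 57)
  ref <- findSeedSites(mir, circ, circular = TRUE)
  for (off in c(1, 13, 30, 59)) {
    rot <- findSeedSites(mir, rotateSeq(circ, off), circular = TRUE)
    expect_identical(sort(rot$site_type), sort(ref$site_type))
    expect_equal(nrow(rot), nrow(ref))
  }
})

test_that("gene-target prediction respects the tier threshold exactly", {
  mir <- "UGCUGGUCAAAAAAAAAAAAAA"
  utrs <- c(
    g8   = paste0(strrep("C", 30), "GACCAGCA", strrep("C", 30)),  # 8mer
    g7m8 = paste0(strrep("C", 30), "GACCAGCG", strrep("C", 30)),  # 7mer-m8
    g7a1 = paste0(strrep("C", 30), "CACCAGCA", strrep("C", 30)),  # 7mer-A1
    g6   = paste0(strrep("C", 30), "CACCAGCG", strrep("C", 30)),  # 6mer
    gNo  = strrep("C", 68))
  expect_identical(predictGeneTargets(mir, utrs, minTier = "8mer"), "g8")
  expect_identical(predictGeneTargets(mir, utrs, minTier = "7mer-m8"),
                   c("g7m8", "g8"))
  expect_identical(predictGeneTargets(mir, utrs, minTier = "7mer-A1"),
                   c("g7a1", "g7m8", "g8"))
  expect_identical(predictGeneTargets(mir, utrs, minTier = "6mer"),
                   c("g6", "g7a1", "g7m8", "g8"))
})

test_that("planted UTR targets are recovered exactly on a clean background", {
  set.seed(55)
  mir <- "UACGUAAGCUAAGGCAUUGGAC"  # seed rc contains A/U, absent from GC bg
  utrs <- stats::setNames(
    vapply(1:20, function(i)
      paste(sample(c("G", "C"), 120, replace = TRUE), collapse = ""), ""),
    sprintf("g%02d", 1:20))
  planted <- sprintf("g%02d", sample(20, 12))
  for (g in planted)
    utrs[[g]] <- writeIntoCircle(utrs[[g]], plantSite8mer(mir), 40)
  expect_identical(predictGeneTargets(mir, utrs), sort(planted))
})
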