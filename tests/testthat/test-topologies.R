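test_that("linearPolymer builds the furan homopolymer with exact conservation", {
  p <- linearPolymer(furanM, 5, cfg0)
  g <- polymerGraph(p)

  expect_equal(countSubstructure(g, "c1ccoc1"), 5)
  expect_equal(natoms(p), 5 * A_FURAN - 2 * 4)   # 37
  expect_equal(nbonds(p), 5 * B_FURAN - 4)       # 41
  cnt <- elementCounts(g)                        # C20H12O5
  expect_equal(as.integer(cnt[c("C", "H", "O")]), c(20L, 12L, 5L))
  expect_length(findPlaceholders(g, "Br"), 0)
  expect_true(checkValences(g))
  expect_identical(monomerSequence(p), rep("A", 5))

  # single unit degenerates to the capped monomer (furan, C4H4O)
  p1 <- linearPolymer(furanM, 1, cfg0)
  expect_equal(toSmiles(polymerGraph(p1)), toSmiles(readStructure("c1ccoc1")))

  expect_error(linearPolymer(furanM, 0, cfg0), "topology error")
  threePh <- loadMonomer("BrC(Br)CBr", placeholder = "Br")
  expect_error(linearPolymer(threePh, 3, cfg0), "exactly 2")
})

test_that("linear conservation identities hold across randomized monomer/length combinations", {
  pool <- list(furanM, thiopheneM, benzeneM,
               loadMonomer("BrCCBr", placeholder = "Br"),
               loadMonomer("Brc1ccc(Br)[nH]1", placeholder = "Br"))
  set.seed(11)
  for (rep_ in 1:25) {
    m <- pool[[sample.int(length(pool), 1)]]
    n <- sample(1:8, 1)
    A <- natoms(m); B <- nbonds(m)
    p <- linearPolymer(m, n, cfg0)
    expect_equal(natoms(p), n * A - 2 * (n - 1))
    expect_equal(nbonds(p), n * B - (n - 1))
    expect_length(findPlaceholders(polymerGraph(p), "Br"), 0)
    expect_true(checkValences(polymerGraph(p)))
  }
})

test_that("diblockCopolymer stacks two blocks with matching placeholder element", {
  p <- diblockCopolymer(furanM, thiopheneM, 2, 3, cfg0)
  expect_identical(paste(monomerSequence(p), collapse = ""), "AABBB")
  g <- polymerGraph(p)
  expect_equal(countSubstructure(g, "c1ccoc1"), 2)
  expect_equal(countSubstructure(g, "c1ccsc1"), 3)
  expect_length(findPlaceholders(g, "Br"), 0)

  expect_error(diblockCopolymer(furanM, thiopheneM, 1, 0, cfg0), ">= 1")
  ptM <- loadMonomer("[Pt]c1ccc([Pt])s1", placeholder = "Pt")
  expect_error(diblockCopolymer(furanM, ptM, 2, 2, cfg0), "placeholder")
})

test_that("random copolymer unit counts follow round(p*len) exactly, with seed replay", {
  p <- randomAbCopolymer(furanM, thiopheneM, 10, 0.4,
                         BuildConfig(ffIterations = 0L, seed = 7L))
  expect_equal(sum(monomerSequence(p) == "A"), 4)
  expect_equal(sum(monomerSequence(p) == "B"), 6)
  expect_equal(seedUsed(p), 7L)

  # identical seed => identical sequence; different seeds explore orderings
  p2 <- randomAbCopolymer(furanM, thiopheneM, 10, 0.4,
                          BuildConfig(ffIterations = 0L, seed = 7L))
  expect_identical(monomerSequence(p), monomerSequence(p2))
  seqs <- vapply(1:30, function(s)
    paste(monomerSequence(randomAbCopolymer(furanM, thiopheneM, 8, 0.5,
      BuildConfig(ffIterations = 0L, seed = s))), collapse = ""),
    character(1))
  expect_gt(length(unique(seqs)), 10)
  expect_true(all(vapply(seqs, function(s)
    sum(strsplit(s, "")[[1]] == "A") == 4L, logical(1))))

  # count formula over a p x len grid (graph build skipped: formula check
  # via length-1 chains would be slow; sequences are what the formula fixes)
  for (pA in seq(0, 1, by = 0.25)) for (len in c(1, 5, 12)) {
    pp <- randomAbCopolymer(furanM, thiopheneM, len, pA,
                            BuildConfig(ffIterations = 0L, seed = 3L))
    expect_equal(sum(monomerSequence(pp) == "A"), as.integer(floor(pA * len + 0.5)))
    expect_length(monomerSequence(pp), len)
  }

  # degenerate probability: homopolymer, graph-isomorphic to linearPolymer
  ph <- randomAbCopolymer(furanM, thiopheneM, 4, 1.0,
                          BuildConfig(ffIterations = 0L, seed = 1L))
  expect_true(isIsomorphicGraph(polymerGraph(ph),
                                polymerGraph(linearPolymer(furanM, 4, cfg0))))

  expect_error(randomAbCopolymer(furanM, thiopheneM, 5, 1.2, cfg0),
               "probability error")
})

test_that("three-monomer random copolymer counts sum to length", {
  pyrM <- loadMonomer("Brc1ccc(Br)[nH]1", placeholder = "Br")
  p <- randomAbcCopolymer(furanM, thiopheneM, pyrM, 10, 0.4, 0.2,
                          BuildConfig(ffIterations = 0L, seed = 5L))
  tab <- table(factor(monomerSequence(p), levels = c("A", "B", "C")))
  expect_equal(unname(c(tab)), c(4L, 2L, 4L))

  # counts always sum to length for random (pA, pB, length) triples
  set.seed(23)
  for (k in 1:200) {
    pA <- runif(1); pB <- runif(1, 0, 1 - pA); len <- sample(1:20, 1)
    pp <- randomAbcCopolymer(furanM, thiopheneM, pyrM, len, pA, pB,
                             BuildConfig(ffIterations = 0L, seed = k))
    expect_length(monomerSequence(pp), len)
    n1 <- sum(monomerSequence(pp) == "A")
    expect_equal(n1, as.integer(floor(pA * len + 0.5)))
  }

  # pA = pB = 0 gives a homopolymer of the third monomer
  p0 <- randomAbcCopolymer(furanM, thiopheneM, pyrM, 3, 0, 0,
                           BuildConfig(ffIterations = 0L, seed = 1L))
  expect_identical(monomerSequence(p0), rep("C", 3))

  expect_error(randomAbcCopolymer(furanM, thiopheneM, pyrM, 5, 0.7, 0.7, cfg0),
               "probability error")
})

test_that("ringPolymer closes the macrocycle with exact ring arithmetic", {
  for (m in list(benzeneM, furanM)) {
    n <- 5
    r <- ringPolymer(m, n, cfg0)
    g <- polymerGraph(r)
    expect_equal(natoms(r), n * (natoms(m) - 2))
    expect_equal(nbonds(r), n * (nbonds(m) - 1))
    expect_length(findPlaceholders(g, "Br"), 0)
    # one macrocycle on top of the monomers' own rings
    cMon <- cyclomaticNumber(monomerGraph(m))
    expect_equal(cyclomaticNumber(g), n * cMon + 1)
    # ...which exceeds the open-chain value by exactly 1
    chain <- linearPolymer(m, n, cfg0)
    expect_equal(cyclomaticNumber(g),
                 cyclomaticNumber(polymerGraph(chain)) + 1)
    expect_true(checkValences(g))
  }
  expect_equal(countSubstructure(polymerGraph(ringPolymer(benzeneM, 5, cfg0)),
                                 "c1ccccc1"), 5)
  expect_error(ringPolymer(furanM, 2, cfg0), "topology error")
})

test_that("a diblock chain built uncapped can be closed into a copolymer ring", {
  # module composition: diblock -> monomer -> ring (alternating AB ring)
  db <- diblockCopolymer(benzeneM, thiopheneM, 1, 1, cfg0, cap = FALSE)
  unit <- asMonomer(db, "Br")
  ring <- ringPolymer(unit, 3, cfg0)
  g <- polymerGraph(ring)
  expect_equal(countSubstructure(g, "c1ccccc1"), 3)
  expect_equal(countSubstructure(g, "c1ccsc1"), 3)
  expect_equal(cyclomaticNumber(g), 6 + 1)
  expect_length(findPlaceholders(g, "Br"), 0)
})

test_that("branchedPolymer attaches one arm per core placeholder", {
  cat_ <- monomerCatalog()
  core <- cat_$ethylenediamine_core
  arm <- cat_$benzene_arm
  expect_length(findPlaceholders(monomerGraph(core), "Br"), 4)

  b <- branchedPolymer(core, arm, cfg0)
  g <- polymerGraph(b)
  expect_equal(countSubstructure(g, "c1ccccc1"), 4)
  expect_length(findPlaceholders(g, "Br"), 0)
  expect_equal(topologyType(b), "branched")
  expect_equal(natoms(b), natoms(core) + 4 * natoms(arm) - 2 * 4)
  expect_true(checkValences(g))

  # degenerate single-placeholder core: a plain two-unit molecule
  one <- loadMonomer("BrCC", placeholder = "Br")
  b1 <- branchedPolymer(one, arm, cfg0)
  expect_equal(countSubstructure(polymerGraph(b1), "c1ccccc1"), 1)

  # an oligomer arm made from a chain with one retained terminal site
  chain <- linearPolymer(furanM, 2, cfg0, cap = FALSE)
  keep <- findPlaceholders(polymerGraph(chain), "Br")[1]
  oligArm <- asMonomer(capPlaceholders(polymerGraph(chain), "Br", except = keep),
                       "Br")
  b2 <- branchedPolymer(core, oligArm, cfg0)
  expect_equal(countSubstructure(polymerGraph(b2), "c1ccoc1"), 8)

  expect_error(branchedPolymer(core, furanM, cfg0), "exactly 1")
})

test_that("patternedPolymer realizes the exact backbone sequence", {
  cat_ <- monomerCatalog()
  mono3 <- list(cat_$thiophene, cat_$furan, cat_$benzene)

  p <- patternedPolymer("ABC", mono3, cfg0)
  expect_identical(monomerSequence(p), c("A", "B", "C"))
  g <- polymerGraph(p)
  expect_equal(countSubstructure(g, "c1ccsc1"), 1)
  expect_equal(countSubstructure(g, "c1ccoc1"), 1)
  expect_equal(countSubstructure(g, "c1ccccc1"), 1)

  p2 <- patternedPolymer("ABBACC", mono3, cfg0)
  expect_identical(paste(monomerSequence(p2), collapse = ""), "ABBACC")
  g2 <- polymerGraph(p2)
  expect_equal(countSubstructure(g2, "c1ccsc1"), 2)
  expect_equal(countSubstructure(g2, "c1ccoc1"), 2)
  expect_equal(countSubstructure(g2, "c1ccccc1"), 2)

  # single-letter pattern is the capped monomer
  p1 <- patternedPolymer("A", mono3, cfg0)
  expect_equal(toSmiles(polymerGraph(p1)), toSmiles(readStructure("c1ccsc1")))

  # A^n is graph-isomorphic to the linear homopolymer
  pa <- patternedPolymer("AAAA", list(cat_$furan), cfg0)
  expect_true(isIsomorphicGraph(polymerGraph(pa),
                                polymerGraph(linearPolymer(cat_$furan, 4, cfg0))))

  expect_error(patternedPolymer("ABD", mono3, cfg0), "no monomer mapping")
  expect_error(patternedPolymer("", mono3, cfg0), "nonempty")
})

test_that("uniquePatternPermutations matches brute-force multiset dedup", {
  bruteForce <- function(pattern) {
    chars <- strsplit(pattern, "")[[1]]
    if (length(chars) == 1L) return(pattern)
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
      out
    }
    sort(unique(vapply(perms(chars), paste, character(1), collapse = "")))
  }
  for (pat in c("ABC", "AA", "AAB", "AABB", "ABCD", "AAAB", "ABCAB", "AABBCC")) {
    expect_identical(uniquePatternPermutations(pat), bruteForce(pat),
                     label = pat)
  }
  expect_identical(uniquePatternPermutations("AA"), "AA")
  expect_length(uniquePatternPermutations("ABC"), 6)
  expect_length(uniquePatternPermutations("AAB"), 3)
})
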