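test_that("loadMonomer parses SMILES, materializes hydrogens and validates decoration", {
  # 2,5-dibromofuran: 4 C, 1 O, 2 Br, 2 H after H materialization
  expect_s4_class(furanM, "Monomer")
  cnt <- elementCounts(monomerGraph(furanM))
  expect_equal(cnt[["C"]], 4)
  expect_equal(cnt[["Br"]], 2)
  expect_equal(cnt[["H"]], 2)
  expect_length(findPlaceholders(monomerGraph(furanM), "Br"), 2)

  # ethylene dibromide: 2 C + 2 Br + 4 H = 8 atoms
  edb <- loadMonomer("BrCCBr", placeholder = "Br")
  expect_equal(natoms(edb), 8)

  # undecorated input is a decoration error; garbage is a parse error
  expect_error(loadMonomer("c1ccoc1", placeholder = "Br"), "decoration")
  expect_error(readStructure("not(a(smiles", "smiles"), "parsed")

  # placeholder element is arbitrary: Pt works the same way
  pt <- loadMonomer("[Pt]c1ccc([Pt])o1", placeholder = "Pt")
  expect_length(findPlaceholders(monomerGraph(pt), "Pt"), 2)
})

test_that("findPlaceholders returns ascending indices, empty when absent", {
  g <- monomerGraph(furanM)
  ph <- findPlaceholders(g, "Br")
  expect_identical(ph, sort(ph))
  expect_identical(atomElements(g)[ph], rep("Br", 2))
  expect_length(findPlaceholders(readStructure("c1ccoc1"), "Br"), 0)
  g3 <- readStructure("[Pt]C([Pt])C[Pt]")
  expect_length(findPlaceholders(g3, "Pt"), 3)
})

test_that("joinGraphs consumes placeholders, conserves counts and maps indices", {
  g <- monomerGraph(furanM)
  ph <- findPlaceholders(g, "Br")
  j <- joinGraphs(g, ph[2], g, ph[1])

  # conservation: |atoms| - 2, |bonds| - 1
  expect_equal(natoms(j), 2 * natoms(g) - 2)
  expect_equal(nbonds(j), 2 * nbonds(g) - 1)
  expect_length(findPlaceholders(j, "Br"), 2)  # one survivor per side

  # provenance maps: consumed placeholders map to NA, everything else remaps
  md <- S4Vectors::metadata(j)
  expect_true(is.na(md$mapA[ph[2]]))
  expect_true(is.na(md$mapB[ph[1]]))
  expect_equal(sort(c(stats::na.omit(md$mapA), stats::na.omit(md$mapB))),
               seq_len(natoms(j)))
  # the new bond connects the placeholders' former neighbors
  nb <- md$newBond
  key <- paste(bondMatrix(j)[, 1], bondMatrix(j)[, 2])
  expect_true(paste(nb[1], nb[2]) %in% key)

  # capped bifuran is 2,2'-bifuran
  expect_equal(toSmiles(capPlaceholders(j, "Br")),
               toSmiles(readStructure("c1ccc(o1)c1ccco1")))

  # joining at a non-terminal atom is a structure error
  carbon <- which(atomElements(g) == "C")[1]
  expect_error(joinGraphs(g, carbon, g, ph[1]), "structure error")
})

test_that("capPlaceholders rewrites to H, is idempotent and count-preserving", {
  g <- monomerGraph(furanM)
  capped <- capPlaceholders(g, "Br")
  expect_equal(natoms(capped), natoms(g))
  expect_equal(nbonds(capped), nbonds(g))
  expect_length(findPlaceholders(capped, "Br"), 0)
  expect_true(checkValences(capped))
  # dibromofuran caps to furan itself
  expect_equal(toSmiles(capped), toSmiles(readStructure("c1ccoc1")))
  # idempotent; identity on placeholder-free graphs
  expect_identical(capPlaceholders(capped, "Br"), capped)
})

test_that("structures round-trip through all four formats", {
  m <- loadMonomer("Brc1ccc(Br)o1", placeholder = "Br")
  g <- capPlaceholders(monomerGraph(m), "Br")
  g <- minimizeGeometry(embedCoords(g), BuildConfig("MMFF", 100L))

  for (fmt in c("mol", "xyz", "pdb", "smiles")) {
    path <- tempfile(fileext = paste0(".", sub("smiles", "smi", fmt)))
    writeStructure(g, path, fmt)
    back <- readStructure(path)
    expect_identical(sort(atomElements(back)), sort(atomElements(g)),
                     label = paste(fmt, "element multiset"))
    expect_identical(bondMultiset(back), bondMultiset(g),
                     label = paste(fmt, "bond multiset"))
    unlink(path)
  }

  # XYZ of the capped furan pentamer has one line per atom (37) plus header
  p5 <- linearPolymer(m, 5, BuildConfig("MMFF", 50L))
  xyz <- tempfile(fileext = ".xyz")
  writeStructure(polymerGraph(p5), xyz)
  expect_equal(as.integer(readLines(xyz, n = 1)), 37)
  expect_equal(length(readLines(xyz)), 37 + 2)
  unlink(xyz)

  # coordinate formats refuse graphs without geometry
  expect_error(writeStructure(monomerGraph(m), tempfile(fileext = ".xyz")),
               "coordinates")
})

test_that("MOL and PDB files load as monomers too", {
  g <- embedCoords(monomerGraph(furanM))
  molf <- tempfile(fileext = ".mol")
  pdbf <- tempfile(fileext = ".pdb")
  writeStructure(g, molf)
  writeStructure(g, pdbf)
  for (f in c(molf, pdbf)) {
    m2 <- loadMonomer(f, placeholder = "Br")
    expect_length(findPlaceholders(monomerGraph(m2), "Br"), 2)
    expect_equal(natoms(m2), natoms(furanM))
  }
  unlink(c(molf, pdbf))
})
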