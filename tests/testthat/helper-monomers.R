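# Shared fixtures: decorated monomers parsed once per test run.
# cfg0 disables geometry so graph-level properties run fast.

cfg0 <- BuildConfig(ffIterations = 0L)

furanM     <- loadMonomer("Brc1ccc(Br)o1",   placeholder = "Br")
thiopheneM <- loadMonomer("Brc1ccc(Br)s1",   placeholder = "Br")
benzeneM   <- loadMonomer("Brc1ccc(Br)cc1",  placeholder = "Br")

# decorated-monomer atom/bond counts with explicit hydrogens
A_FURAN <- natoms(furanM)   # 9
B_FURAN <- nbonds(furanM)   # 9

elementCounts <- function(g) table(atomElements(g))

# unordered bond multiset fingerprint (order-insensitive endpoints)
bondMultiset <- function(g) {
  b <- bondMatrix(g)
  e1 <- atomElements(g)[b[, 1]]
  e2 <- atomElements(g)[b[, 2]]
  sort(paste(pmin(e1, e2), pmax(e1, e2), b[, 3]))
}
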