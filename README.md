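# polyforge

Building a molecular model of a polymer is routinely the most tedious step
of a soft-matter simulation workflow. **polyforge** automates it: a repeat
unit (monomer) is supplied as a SMILES string or a MOL/SDF, PDB or XYZ
file, with *placeholder atoms* — any element the user likes, Br and Pt by
convention — marking the sites where inter-monomer bonds form. The package
then assembles

* **linear homopolymers** — `linearPolymer(m, n)`,
* **diblock copolymers** — `diblockCopolymer(ma, mb, lenA, lenB)`,
* **random AB / ABC copolymers** — unit counts fixed at
  `round(pA·len)`, `round(pB·len)` and the remainder, order drawn from a
  seeded uniform shuffle,
* **ring (cyclic) polymers** — a chain whose two terminal placeholders are
  consumed to close the macrocycle,
* **branched (star) polymers** — one arm joined at every placeholder of a
  core, and
* **pattern-specified polymers** — an alphabetic string (`"ABBACC"`) mapped
  onto an ordered monomer list,

caps leftover placeholders with hydrogen, and relaxes the geometry with
MMFF94 or UFF (via Open Babel). Every join obeys exact conservation
arithmetic — `atoms = n·A − 2(n−1)`, `bonds = n·B − (n−1)` for a chain of
`n` units of a monomer with `A` atoms and `B` bonds — which the test suite
verifies across randomized builds.

For conjugated polymers, the **torsional module** treats the molecule as a
graph (atoms = nodes, covalent bonds = edges) and finds every *linker
bond* — a bond that is not itself in a ring but connects two in-ring
atoms — then enumerates all dihedral quadruples `a–b–c–d` about those
central bonds and renders 2D sketches with the atoms labelled. These are
exactly the backbone dihedrals that generic force fields describe poorly
and that users re-parametrize from *ab initio* scans.

High-throughput helpers round the package out: uniquely named folder
creation, relocation of files into one folder per file
(`filesToDirs("smi", root)`), order-stable parallel dispatch with per-task
error capture, and assembly (not execution) of GFN2-xTB / GFN-FF / SCF
command lines.

## Worked example

```r
library(polyforge)

furan <- loadMonomer("Brc1ccc(Br)o1", placeholder = "Br")
furan
#> Monomer: 9 atoms, 9 bonds, 2 'Br' placeholder sites

p <- linearPolymer(furan, 5, BuildConfig("MMFF", ffIterations = 350L))
p
#> PolymerResult (linear): 5 units [AAAAA], 37 atoms, 41 bonds

countSubstructure(polymerGraph(p), "c1ccoc1")
#> [1] 5
toSmiles(polymerGraph(p))
#> [1] "c1coc(c1)c1ccc(o1)c1ccc(o1)c1ccc(o1)c1ccco1"

writeStructure(polymerGraph(p), "pentamer.xyz")   # 37 atom lines

bi <- readStructure("c1ccc(-c2ccccc2)cc1")        # biphenyl
detectLinkerBonds(bi)
#>      i j
#> [1,] 4 5
enumerateTorsions(bi)
#>    a b c  d
#> 1  3 4 5  6
#> 2  3 4 5 10
#> 3 11 4 5  6
#> 4 11 4 5 10
```

The five-unit chain has 37 atoms (C20H12O5): five nine-atom decorated
monomers lose two atoms at each of the four junctions, and the two
surviving terminal placeholders are converted to hydrogens. Biphenyl has
one inter-ring linker bond and 2 × 2 = 4 heavy-atom torsions about it.

A thin CLI wraps the same functions:

```sh
$(Rscript -e 'cat(system.file("cli","polyforge",package="polyforge"))') \
    build linear -m 'Brc1ccc(Br)o1' --n 5 --out pentamer.mol
```

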