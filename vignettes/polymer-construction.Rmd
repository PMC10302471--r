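---
title: "Constructing polymer models from placeholder-decorated monomers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing polymer models from placeholder-decorated monomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyforge)
```

## The model

A polymer build starts from a *monomer*: a small molecule in which every
polymerization site is marked by a placeholder atom. The placeholder
element is arbitrary — anything the parser accepts (Br, Pt, ...) — because
the atom never survives: during a join, the two placeholder atoms are
deleted and their former neighbors are connected by a new single-order
bond; after construction, any placeholder still present is rewritten to
hydrogen. Two modelling assumptions follow from this design:

* **the formed linkage is a single bond.** The placeholder stands in for
  one substituent on an otherwise complete (explicit-hydrogen) structure,
  so replacing it forms one sigma bond. Aromaticity within each monomer is
  untouched; the inter-monomer bond is the rotatable backbone bond that
  the torsional module later looks for.
* **hydrogens are explicit from the moment of loading.** The conservation
  identities (below) and the torsion enumeration both need the full graph;
  implicit-hydrogen bookkeeping would make every count conditional.

Because each join removes exactly two atoms and two bonds and adds one
bond, closed-form conservation identities hold for every topology. With a
decorated monomer of $A$ atoms and $B$ bonds (explicit H):

| topology | atoms | bonds |
|---|---|---|
| chain of $n$ | $nA - 2(n-1)$ | $nB - (n-1)$ |
| ring of $n$ | $n(A-2)$ | $n(B-1)$ |

Capping converts atoms (placeholder to H), it never adds them. A ring's
cyclomatic number (bonds − atoms + components) exceeds the sum of its
monomers' ring counts by exactly one — the macrocycle — and exceeds the
open chain's value by exactly one.

## Head/tail convention and determinism

A two-placeholder monomer has a *head* (its lower-index placeholder) and a
*tail* (the other). Chains are assembled by joining the tail of the
growing chain to the head of the incoming unit. This convention is
invisible chemistry-wise for symmetric monomers but makes every build a
pure function of its inputs: the same monomers, lengths and seed give the
same graph, atom order included.

Random copolymers follow the count-exact reading of the sequence model:
the number of A units is fixed at round-half-up$(p_A \cdot \mathrm{len})$
(and $n_2 = \mathrm{round}(p_B \cdot \mathrm{len})$, remainder to the
last-listed monomer, for three monomers), and only the *order* is random —
a seeded uniform shuffle of the count-exact multiset. The alternative
reading (independent per-position Bernoulli draws) would make the
composition itself a random variable; the count-exact form is what the
stated $p \cdot \mathrm{len}$ unit-count formulas describe. One edge case
is resolved here: round-half-up can make $n_1 + n_2$ exceed the chain
length (e.g. $p_A = p_B = 0.5$, len = 5 gives 3 + 3); $n_2$ is clamped to
$\mathrm{len} - n_1$ so counts always sum to the chain length.

Ring closure requires at least three units: a two-unit "ring" would be a
double bridge between the same pair of neighbors, which the duplicate-bond
invariant of the graph model rejects.

## Tunable parameters

* `forceField` — `"MMFF"` (MMFF94, default) or `"UFF"`. MMFF94 is the
  better organic-chemistry choice; UFF covers the whole periodic table.
  When the chosen field cannot type an atom (a Pt placeholder, say), the
  build falls back to the other field with a warning rather than dying
  mid-batch.
* `ffIterations` — minimization steps, default 500. Zero disables
  geometry work entirely, which also makes builders pure graph
  operations; this is what the property tests use.
* `shift` — distance in Å between consecutive monomer copies along the
  placement axis (default 3.0 Å, x axis). The value only sets the
  pre-minimization layout; after relaxation the backbone geometry is
  force-field-determined.
* `seed` — integer seed for the random-sequence builders. Identical seeds
  reproduce identical sequences; the seed is recorded in the result.

## Numerical choices and degenerate inputs

* Energies are compared with a small absolute slack (the final
  conjugate-gradient step can wobble by ~1e-5 in the last digit), and the
  minimizer's energies are reported in the force field's native units
  (kcal/mol for MMFF94, kJ/mol for UFF) — only before/after comparisons
  within one field are meaningful.
* 3D embedding uses Open Babel's structure builder. Its conformer search
  draws randomness that cannot be seeded from the outside, so *coordinates
  may differ slightly between runs*; every graph-level result (atom
  counts, sequences, torsion labels) is exactly reproducible. This is a
  known limitation: a fully seed-reproducible embedding would need a
  different backend.
* Atom indices are 1-based and contiguous; every deletion re-compacts
  them, and the old→new maps (`NA` for deleted atoms) ride along in
  `metadata()` so callers can track sites through edits.
* `n_copies = 1` chains degenerate to the capped monomer; a
  single-placeholder core with one arm degenerates to a plain two-unit
  molecule; a pattern of one letter is the capped monomer. All are valid.
* Unit counts of zero are permitted in random copolymers (`pA = 0` is a
  homopolymer of the other monomer); no minimum-representation rule is
  imposed.

## Torsion detection

The molecular graph is scanned for *linker bonds*: bonds that are not in
any ring but whose two end atoms are each in a ring. Ring membership is
decided by the cycle criterion — a bond is in-ring iff it lies on some
cycle, which coincides with membership in at least one SSSR ring and is
computed as "not a bridge" of the graph. This criterion was chosen over a
literal neighbor-count rule ("three inner neighbors plus one from the next
monomer"), which over-constrains sp² carbons once hydrogens are explicit;
the ring-exclusion step makes the two readings agree on conjugated
backbones.

For each linker bond $b$–$c$, all quadruples $a$–$b$–$c$–$d$ are listed
with $a$ a neighbor of $b$ (≠ $c$) and $d$ a neighbor of $c$ (≠ $b$).
Hydrogens are excluded by default, matching the heavy-atom dihedral
definition conventional for backbone scans (`includeH = TRUE` lifts
this). Quadruples are stored in canonical orientation (central bond with
$b < c$), so a torsion and its reversal are never double-counted, and the
per-bond count equals $(\mathrm{deg}_\mathrm{heavy}(b) - 1)
(\mathrm{deg}_\mathrm{heavy}(c) - 1)$.

Only the atom labels are reported — measuring or scanning the dihedral is
the downstream quantum-chemistry engine's job, which is also why the HTC
module assembles calculator command lines without executing them.

## What the synthetic fixtures emulate — and what they do not

`monomerCatalog()` provides the worked-example repeat units (furan,
thiophene, benzene, pyrrole, silanol, a four-site ethylenediamine core, a
single-site benzene arm), each decorated with Br. `randomRingAssembly()`
generates seeded chains of aromatic rings with a construction-time record
of every inter-ring bond formed; that record is ground truth for the
torsion detector, independent of any ring-perception code.

These fixtures exercise graph logic, not polymer physics: assemblies are
short (≤ ~8 rings), compositions are uniform draws, and geometries are
quick classical relaxations of single conformers. Passing tests therefore
demonstrate correctness of construction, bookkeeping and detection — they
say nothing about conformational ensembles, packing, or the realism of
any particular force-field geometry for a real material.

## Problem sizes

The shipped tests build chains of up to ~20 units (graph-only) and
minimize pentamers (~40 atoms, ≤ 350 steps); the torsion oracle runs over
50 seeded assemblies of up to 6 rings. These sizes were chosen so the
whole suite documents the method's behaviour in seconds while still
covering every code path; nothing in the implementation caps molecule
size below the MOL V2000 limit of 999 atoms per record (larger structures
can still be written as XYZ/PDB).

## Known limitations

* Stereochemistry is not preserved through joins; tautomers are not
  handled; charges beyond what the parser reports are not assigned.
* No packing into simulation cells and no MD topology/parameter export.
* One level of branching (core + arms); deeper dendrimers require feeding
  a built star back in as a core, which the placeholder mechanism permits
  but no convenience wrapper automates.
* Coordinate-level reproducibility across runs is limited by the
  embedding backend, as noted above.
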