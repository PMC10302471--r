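# Programmatic test inputs: the worked-example monomers (decorated with Br
# placeholders) and a seeded generator of small ring assemblies with known
# linker bonds, used as ground truth for the torsion detector.

.CATALOG_SMILES <- c(
  furan                = "Brc1ccc(Br)o1",        # 2,5-dibromofuran
  thiophene            = "Brc1ccc(Br)s1",
  benzene              = "Brc1ccc(Br)cc1",       # 1,4-dibromobenzene
  pyrrole              = "Brc1ccc(Br)[nH]1",
  silanol              = "Br[SiH](Br)O",         # Si(H)(OH) with 2 sites
  ethylenediamine_core = "BrN(Br)CCN(Br)Br",     # one site per amine H
  benzene_arm          = "Brc1ccccc1"            # single-site arm
)

.pkgCache <- new.env(parent = emptyenv())

#' Catalog of decorated example monomers
#'
#' The worked-example repeat units, each decorated with Br placeholder
#' atoms: two-site furan, thiophene, benzene, pyrrole and silanol; a
#' four-site ethylenediamine core (one placeholder per amine hydrogen);
#' and a single-site benzene arm. Every entry passes monomer validation.
#' Parsed once per session and cached.
#'
#' @return named list of [Monomer-class] objects.
#' @examples
#' names(monomerCatalog())
#' @export
monomerCatalog <- function() {
  if (is.null(.pkgCache$catalog)) {
    .pkgCache$catalog <- lapply(.CATALOG_SMILES, loadMonomer,
                                format = "smiles", placeholder = "Br")
  }
  .pkgCache$catalog
}

#' Generate a random chain of aromatic rings with known linker bonds
#'
#' Draws \code{nRings} rings uniformly from a small aromatic vocabulary
#' (benzene, furan, thiophene, pyrrole) and joins them into a chain, so
#' the product has exactly \code{nRings - 1} acyclic inter-ring single
#' bonds. The construction bookkeeping tracks each bond formed, giving a
#' ground-truth linker-bond list that is independent of any ring-perception
#' code; the torsion detector is validated against it.
#'
#' @param nRings number of rings (>= 1).
#' @param seed integer seed; fixed seed gives a reproducible molecule.
#' @return list with \code{graph} (a capped, valence-valid
#'   [MolecularGraph-class]), \code{linkers} (integer matrix, columns i/j,
#'   sorted, possibly 0 rows) and \code{rings} (the drawn ring names).
#' @export
randomRingAssembly <- function(nRings, seed = 1L) {
  if (nRings < 1L) stop("nRings must be >= 1")
  vocab <- c("benzene", "furan", "thiophene", "pyrrole")
  cat_ <- monomerCatalog()
  picks <- .withSeed(as.integer(seed),
                     function() sample(vocab, nRings, replace = TRUE))
  acc <- monomerGraph(cat_[[picks[1]]])
  linkers <- matrix(integer(0), ncol = 2)
  for (k in seq_len(nRings - 1L)) {
    nxt <- monomerGraph(cat_[[picks[k + 1L]]])
    acc <- joinGraphs(acc, max(findPlaceholders(acc, "Br")),
                      nxt, min(findPlaceholders(nxt, "Br")))
    md <- metadata(acc)
    if (nrow(linkers))  # carry earlier linker indices through the re-compaction
      linkers <- cbind(md$mapA[linkers[, 1]], md$mapA[linkers[, 2]])
    linkers <- rbind(linkers, md$newBond)
  }
  g <- capPlaceholders(acc, "Br")
  if (nrow(linkers)) {
    linkers <- cbind(pmin(linkers[, 1], linkers[, 2]),
                     pmax(linkers[, 1], linkers[, 2]))
    linkers <- linkers[order(linkers[, 1], linkers[, 2]), , drop = FALSE]
  }
  dimnames(linkers) <- list(NULL, c("i", "j"))
  storage.mode(linkers) <- "integer"
  list(graph = g, linkers = linkers, rings = picks)
}
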