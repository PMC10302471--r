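# Placeholder-atom editing primitives: these implement the polymerization
# chemistry (join at placeholder sites, cap leftovers with hydrogen) that
# every topology builder composes.

#' Locate placeholder atoms
#'
#' @param g a [MolecularGraph-class].
#' @param placeholder element symbol.
#' @return ascending integer vector of atom indices whose element equals
#'   \code{placeholder} (empty when none).
#' @export
findPlaceholders <- function(g, placeholder) {
  which(g@elements == placeholder)
}

.degrees <- function(g) tabulate(g@bonds[, 1:2], nbins = natoms(g))

.neighborsOf <- function(g, i) {
  b <- g@bonds
  sort(c(b[b[, 1] == i, 2], b[b[, 2] == i, 1]))
}

# Delete atoms, re-compact indices, return graph + old->new provenance map
# (NA for deleted atoms).
.deleteAtoms <- function(g, idx) {
  n <- natoms(g)
  keep <- setdiff(seq_len(n), idx)
  map <- rep(NA_integer_, n)
  map[keep] <- seq_along(keep)
  b <- g@bonds
  b <- b[!(b[, 1] %in% idx | b[, 2] %in% idx), , drop = FALSE]
  b[, 1] <- map[b[, 1]]
  b[, 2] <- map[b[, 2]]
  coords <- if (hasCoords(g)) g@coords[keep, , drop = FALSE] else NULL
  out <- MolecularGraph(g@elements[keep], b, coords, g@charges[keep])
  list(graph = out, map = map)
}

.addBond <- function(g, i, j, order = 1L) {
  MolecularGraph(g@elements, rbind(g@bonds, c(i, j, order)),
                 if (hasCoords(g)) g@coords else NULL, g@charges)
}

.disjointUnion <- function(ga, gb) {
  na <- natoms(ga)
  shifted <- gb@bonds
  if (nrow(shifted)) shifted[, 1:2] <- shifted[, 1:2] + na
  bonds <- rbind(ga@bonds, shifted)
  coords <- NULL
  if (hasCoords(ga) && hasCoords(gb)) coords <- rbind(ga@coords, gb@coords)
  MolecularGraph(c(ga@elements, gb@elements), bonds, coords,
                 c(ga@charges, gb@charges))
}

#' Join two molecular graphs at placeholder atoms
#'
#' Forms the inter-monomer bond: the two placeholder atoms are deleted and
#' their former (unique) neighbors are connected by a new single bond, so
#' the product has \code{natoms(ga) + natoms(gb) - 2} atoms and
#' \code{nbonds(ga) + nbonds(gb) - 1} bonds. Atom indices are re-compacted;
#' \code{metadata()} of the result carries \code{mapA}/\code{mapB}
#' (old-to-new index maps, NA for the consumed placeholders) and
#' \code{newBond}, the endpoints of the freshly formed bond.
#'
#' @param ga,gb [MolecularGraph-class] objects.
#' @param ia,ib indices of the placeholder atoms to consume; each must have
#'   exactly one bonded neighbor.
#' @return the joined [MolecularGraph-class].
#' @examples
#' m <- loadMonomer("Brc1ccc(Br)o1", placeholder = "Br")
#' g <- monomerGraph(m)
#' ph <- findPlaceholders(g, "Br")
#' bifuran <- joinGraphs(g, ph[2], g, ph[1])
#' natoms(bifuran)  # 2 * 9 - 2
#' @export
joinGraphs <- function(ga, ia, gb, ib) {
  for (chk in list(list(g = ga, i = ia, which = "ia"),
                   list(g = gb, i = ib, which = "ib"))) {
    if (length(chk$i) != 1L || is.na(chk$i) || chk$i < 1L ||
        chk$i > natoms(chk$g))
      stop(sprintf("structure error: %s is not a valid atom index", chk$which))
    if (length(.neighborsOf(chk$g, chk$i)) != 1L)
      stop(sprintf(paste0("structure error: atom %d ('%s') has %d neighbors; ",
                          "a placeholder must have exactly one"),
                   chk$i, chk$g@elements[chk$i],
                   length(.neighborsOf(chk$g, chk$i))))
  }
  na <- natoms(ga)
  nbrA <- .neighborsOf(ga, ia)
  nbrB <- .neighborsOf(gb, ib) + na
  u <- .disjointUnion(ga, gb)
  del <- .deleteAtoms(u, c(ia, ib + na))
  g <- .addBond(del$graph, del$map[nbrA], del$map[nbrB], 1L)
  metadata(g) <- list(mapA = del$map[seq_len(na)],
                      mapB = del$map[na + seq_len(natoms(gb))],
                      newBond = sort(c(del$map[nbrA], del$map[nbrB])))
  g
}

# Same-graph variant used for macrocycle closure: consumes two placeholder
# atoms of one graph and bonds their former neighbors.
.closeRing <- function(g, ia, ib) {
  for (i in c(ia, ib))
    if (length(.neighborsOf(g, i)) != 1L)
      stop(sprintf("structure error: atom %d must have exactly one neighbor", i))
  nbrA <- .neighborsOf(g, ia)
  nbrB <- .neighborsOf(g, ib)
  del <- .deleteAtoms(g, c(ia, ib))
  out <- .addBond(del$graph, del$map[nbrA], del$map[nbrB], 1L)
  metadata(out) <- list(map = del$map,
                        newBond = sort(c(del$map[nbrA], del$map[nbrB])))
  out
}

#' Replace leftover placeholder atoms with hydrogen
#'
#' Rewrites the element of every placeholder atom to H, leaving the graph
#' topology, atom count and bond count unchanged (caps convert atoms, they
#' do not add them). Idempotent.
#'
#' @param g a [MolecularGraph-class].
#' @param placeholder element symbol to cap.
#' @param except atom indices to leave decorated (used to turn chain
#'   products into single-site monomers, e.g. oligomer arms).
#' @return the capped [MolecularGraph-class].
#' @export
capPlaceholders <- function(g, placeholder, except = integer(0)) {
  idx <- setdiff(findPlaceholders(g, placeholder), except)
  if (length(idx)) g@elements[idx] <- "H"
  g
}

#' Re-wrap a built structure as a monomer
#'
#' Lets products of one builder feed another ("polymers as monomers"): a
#' chain built with \code{cap = FALSE} keeps its terminal placeholders and
#' can be rung, patterned or used as a branched-polymer arm.
#'
#' @param x a [MolecularGraph-class] or [PolymerResult-class].
#' @param placeholder the placeholder element of the retained sites.
#' @return a [Monomer-class].
#' @export
asMonomer <- function(x, placeholder) {
  g <- if (is(x, "PolymerResult")) polymerGraph(x) else x
  new("Monomer", graph = g, placeholder = placeholder)
}

# ---- graph analysis --------------------------------------------------------

#' Convert to an igraph object
#'
#' Vertices carry an \code{element} attribute, edges an \code{order}
#' attribute.
#'
#' @param g a [MolecularGraph-class].
#' @return an undirected \pkg{igraph} graph.
#' @export
asIgraph <- function(g) {
  ig <- igraph::make_empty_graph(n = natoms(g), directed = FALSE)
  igraph::V(ig)$element <- g@elements
  if (nbonds(g) > 0) {
    ig <- igraph::add_edges(ig, t(g@bonds[, 1:2, drop = FALSE]))
    igraph::E(ig)$order <- g@bonds[, 3]
  }
  ig
}

#' Ring membership of atoms and bonds
#'
#' A bond is in a ring iff it lies on some cycle (equivalently: it is in at
#' least one SSSR ring, equivalently: it is not a bridge of the molecular
#' graph); an atom is in a ring iff it is incident to such a bond.
#'
#' @param g a [MolecularGraph-class].
#' @return list with logical vectors \code{atoms} (per atom) and
#'   \code{bonds} (per row of \code{bondMatrix(g)}).
#' @export
ringMembership <- function(g) {
  nb <- nbonds(g)
  if (nb == 0L)
    return(list(atoms = logical(natoms(g)), bonds = logical(0)))
  ig <- asIgraph(g)
  bridgeIdx <- igraph::bridges(ig)
  bondIn <- rep(TRUE, nb)
  bondIn[as.integer(bridgeIdx)] <- FALSE
  atomIn <- logical(natoms(g))
  inRing <- g@bonds[bondIn, 1:2, drop = FALSE]
  atomIn[unique(as.integer(inRing))] <- TRUE
  list(atoms = atomIn, bonds = bondIn)
}

#' Cyclomatic number (number of independent rings)
#'
#' @param g a [MolecularGraph-class].
#' @return \code{nbonds - natoms + components}, an integer.
#' @export
cyclomaticNumber <- function(g) {
  comp <- igraph::components(asIgraph(g))$no
  nbonds(g) - natoms(g) + comp
}

# standard valences used by checkValences(); multiple entries = allowed states
.VALENCES <- list(H = 1, B = 3, C = 4, N = c(3, 5), O = 2, F = 1,
                  Si = 4, P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1)

#' Validate atom valences
#'
#' Checks each atom whose element has a tabulated standard valence against
#' the sum of its bond orders (aromatic file bonds counted as 1.5, with the
#' total rounded); a formal charge of +1/-1 shifts the expectation by one.
#' Elements without a tabulated valence (metals, exotic placeholders) are
#' skipped.
#'
#' @param g a [MolecularGraph-class].
#' @return logical scalar; attribute \code{"failures"} lists offending atoms.
#' @export
checkValences <- function(g) {
  ordv <- ifelse(g@bonds[, 3] == 4L, 1.5, g@bonds[, 3])
  val <- numeric(natoms(g))
  for (k in seq_len(nbonds(g))) {
    val[g@bonds[k, 1]] <- val[g@bonds[k, 1]] + ordv[k]
    val[g@bonds[k, 2]] <- val[g@bonds[k, 2]] + ordv[k]
  }
  val <- round(val)
  bad <- integer(0)
  for (i in seq_len(natoms(g))) {
    allowed <- .VALENCES[[g@elements[i]]]
    if (is.null(allowed)) next
    if (!(val[i] - g@charges[i]) %in% allowed && !val[i] %in% allowed)
      bad <- c(bad, i)
  }
  out <- length(bad) == 0L
  attr(out, "failures") <- bad
  out
}

#' Count substructure occurrences
#'
#' Element-colored subgraph matching (VF2): counts the distinct atom sets of
#' the target on which the query graph can be overlaid with matching
#' elements and connectivity. Hydrogens are dropped from both graphs first,
#' so an aromatic-SMILES query like \code{"c1ccoc1"} counts furan units
#' regardless of kekulization.
#'
#' @param g target [MolecularGraph-class].
#' @param query a [MolecularGraph-class] or a SMILES string.
#' @return integer count of distinct matched atom sets.
#' @examples
#' p <- linearPolymer(loadMonomer("Brc1ccc(Br)o1", placeholder = "Br"), 5,
#'                    BuildConfig(ffIterations = 0L))
#' countSubstructure(polymerGraph(p), "c1ccoc1")  # 5
#' @export
countSubstructure <- function(g, query) {
  if (is.character(query)) query <- readStructure(query, "smiles")
  strip <- function(x) .deleteAtoms(x, which(x@elements == "H"))$graph
  gt <- strip(g)
  qt <- strip(query)
  if (natoms(qt) == 0L || natoms(qt) > natoms(gt)) return(0L)
  pal <- unique(c(gt@elements, qt@elements))
  igT <- asIgraph(gt)
  igQ <- asIgraph(qt)
  # vf2 passes (target, pattern) down, so color1 belongs to the target
  ms <- igraph::subgraph_isomorphisms(igQ, igT, method = "vf2",
    vertex.color1 = match(gt@elements, pal),
    vertex.color2 = match(qt@elements, pal))
  length(unique(lapply(ms, function(m) sort(as.integer(m)))))
}

#' Test two molecular graphs for colored-graph isomorphism
#'
#' @param ga,gb [MolecularGraph-class] objects.
#' @return TRUE iff the graphs are isomorphic with matching elements.
#' @export
isIsomorphicGraph <- function(ga, gb) {
  if (natoms(ga) != natoms(gb) || nbonds(ga) != nbonds(gb)) return(FALSE)
  pal <- unique(c(ga@elements, gb@elements))
  igraph::is_isomorphic_to(asIgraph(ga), asIgraph(gb), method = "vf2",
    vertex.color1 = match(ga@elements, pal),
    vertex.color2 = match(gb@elements, pal))
}
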