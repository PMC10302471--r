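#' @import methods
#' @importFrom S4Vectors metadata metadata<-
NULL

#' MolecularGraph: atoms, bonds and optional 3D coordinates
#'
#' The universal molecule representation used throughout the package: a
#' labelled graph whose nodes are atoms and whose edges are covalent bonds.
#' Atom indices are 1-based and contiguous; every editing operation
#' re-compacts them and records an old-to-new provenance map in
#' \code{metadata()}.
#'
#' @slot elements character vector of element symbols, one per atom.
#' @slot charges integer vector of formal charges, one per atom.
#' @slot bonds integer matrix with columns \code{i}, \code{j}, \code{order}
#'   (1 = single, 2 = double, 3 = triple, 4 = aromatic as read from a file;
#'   structures born from SMILES arrive kekulized). Stored normalized with
#'   \code{i < j} and no duplicates.
#' @slot coords numeric matrix with columns x, y, z in Angstrom and one row
#'   per atom, or a 0-row matrix when no geometry is attached.
#'
#' @seealso [loadMonomer()], [joinGraphs()], [capPlaceholders()]
#' @export
setClass("MolecularGraph",
  contains = "Annotated",
  slots = c(
    elements = "character",
    charges  = "integer",
    bonds    = "matrix",
    coords   = "matrix"
  ),
  prototype = prototype(
    elements = character(0),
    charges  = integer(0),
    bonds    = matrix(integer(0), ncol = 3,
                      dimnames = list(NULL, c("i", "j", "order"))),
    coords   = matrix(numeric(0), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  )
)

setValidity("MolecularGraph", function(object) {
  n <- length(object@elements)
  msg <- character(0)
  if (length(object@charges) != n)
    msg <- c(msg, "charges must have one entry per atom")
  b <- object@bonds
  if (ncol(b) != 3)
    msg <- c(msg, "bonds must have columns i, j, order")
  if (nrow(b) > 0) {
    if (any(b[, 1:2] < 1) || any(b[, 1:2] > n))
      msg <- c(msg, "bond endpoints must reference existing atoms")
    if (any(b[, 1] == b[, 2]))
      msg <- c(msg, "bonds must connect two distinct atoms")
    key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate bonds are not allowed")
    if (!all(b[, 3] %in% 1:4))
      msg <- c(msg, "bond order must be 1, 2, 3 or 4 (aromatic)")
  }
  cc <- object@coords
  if (nrow(cc) > 0) {
    if (nrow(cc) != n)
      msg <- c(msg, "coords must have one row per atom")
    if (!all(is.finite(cc)))
      msg <- c(msg, "coords must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Monomer: a molecular graph decorated with placeholder atoms
#'
#' A repeat unit whose polymerization sites are marked by atoms of an
#' arbitrary placeholder element (for example Br or Pt). Each placeholder
#' must have exactly one bonded neighbor: it stands in for the single
#' substituent that the new inter-monomer bond replaces.
#'
#' @slot graph a [MolecularGraph-class] with explicit hydrogens.
#' @slot placeholder single element symbol marking the polymerization sites.
#' @export
setClass("Monomer",
  slots = c(graph = "MolecularGraph", placeholder = "character")
)

setValidity("Monomer", function(object) {
  msg <- character(0)
  if (length(object@placeholder) != 1L || !nzchar(object@placeholder))
    msg <- c(msg, "placeholder must be a single element symbol")
  idx <- which(object@graph@elements == object@placeholder)
  if (length(idx) == 0L)
    msg <- c(msg, sprintf("monomer carries no '%s' placeholder atom",
                          object@placeholder))
  if (length(idx)) {
    deg <- tabulate(object@graph@bonds[, 1:2],
                    nbins = length(object@graph@elements))
    if (any(deg[idx] != 1L))
      msg <- c(msg, "every placeholder atom must have exactly one neighbor")
  }
  if (length(msg)) msg else TRUE
})

#' BuildConfig: force-field and geometry parameters for polymer builds
#'
#' @slot forceField "MMFF" or "UFF"; on an atom-typing failure the builder
#'   falls back to the other force field with a warning.
#' @slot ffIterations number of minimization steps; 0 skips relaxation and
#'   leaves input coordinates untouched.
#' @slot shift distance in Angstrom between consecutive monomer copies when
#'   they are laid out along the placement axis.
#' @slot seed optional integer seed for the random-sequence builders
#'   (NA leaves the RNG alone).
#' @export
setClass("BuildConfig",
  slots = c(forceField = "character", ffIterations = "integer",
            shift = "numeric", seed = "integer")
)

setValidity("BuildConfig", function(object) {
  msg <- character(0)
  if (!object@forceField %in% c("MMFF", "UFF"))
    msg <- c(msg, "forceField must be 'MMFF' or 'UFF'")
  if (length(object@ffIterations) != 1L || is.na(object@ffIterations) ||
      object@ffIterations < 0L)
    msg <- c(msg, "ffIterations must be a single non-negative integer")
  if (length(object@shift) != 1L || is.na(object@shift) || object@shift <= 0)
    msg <- c(msg, "shift must be a single positive distance in Angstrom")
  if (length(object@seed) != 1L)
    msg <- c(msg, "seed must be a single integer or NA")
  if (length(msg)) msg else TRUE
})

#' PolymerResult: a built polymer plus its provenance
#'
#' @slot graph the product [MolecularGraph-class]; contains no placeholder
#'   atoms (all were consumed by joins or capped with hydrogen).
#' @slot topology "linear", "ring" or "branched".
#' @slot sequence monomer labels in backbone order, one per incorporated unit.
#' @slot seedUsed the seed the random builders drew from (NA otherwise).
#' @export
setClass("PolymerResult",
  slots = c(graph = "MolecularGraph", topology = "character",
            sequence = "character", seedUsed = "integer")
)

setValidity("PolymerResult", function(object) {
  if (!object@topology %in% c("linear", "ring", "branched"))
    return("topology must be 'linear', 'ring' or 'branched'")
  TRUE
})

#' EmbeddingPlan: initial placement of monomer copies along an axis
#'
#' @slot axis unit vector of length 3 giving the placement direction.
#' @slot shift distance in Angstrom between consecutive copies.
#' @export
setClass("EmbeddingPlan",
  slots = c(axis = "numeric", shift = "numeric")
)

setValidity("EmbeddingPlan", function(object) {
  msg <- character(0)
  if (length(object@axis) != 3L || !all(is.finite(object@axis)))
    msg <- c(msg, "axis must be a finite length-3 vector")
  else if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    msg <- c(msg, "axis must be normalized")
  if (length(object@shift) != 1L || is.na(object@shift) || object@shift <= 0)
    msg <- c(msg, "shift must be positive")
  if (length(msg)) msg else TRUE
})

#' DispatchPlan: worker layout for high-throughput task dispatch
#'
#' @slot nWorkers number of concurrently executing workers.
#' @slot coresPerTask cores handed to each external calculation.
#' @export
setClass("DispatchPlan",
  slots = c(nWorkers = "integer", coresPerTask = "integer")
)

setValidity("DispatchPlan", function(object) {
  if (object@nWorkers < 1L || object@coresPerTask < 1L)
    return("nWorkers and coresPerTask must both be >= 1")
  TRUE
})

# ---- constructors ----------------------------------------------------------

#' Create a MolecularGraph from atom and bond tables
#'
#' @param elements character vector of element symbols.
#' @param bonds integer matrix (or data.frame) with columns i, j, order.
#' @param coords optional n x 3 numeric matrix of coordinates in Angstrom.
#' @param charges integer vector of formal charges (default all 0).
#' @return a validated [MolecularGraph-class].
#' @examples
#' g <- MolecularGraph(c("O", "H", "H"),
#'                     rbind(c(1, 2, 1), c(1, 3, 1)))
#' natoms(g)
#' @export
MolecularGraph <- function(elements, bonds = NULL, coords = NULL,
                           charges = NULL) {
  elements <- as.character(elements)
  n <- length(elements)
  if (is.null(charges)) charges <- integer(n)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 3)
  } else {
    bonds <- as.matrix(bonds)
    storage.mode(bonds) <- "integer"
    ij <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    bonds <- cbind(ij, bonds[, 3])
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  }
  colnames(bonds) <- c("i", "j", "order")
  if (is.null(coords)) {
    coords <- matrix(numeric(0), ncol = 3)
  } else {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
  }
  colnames(coords) <- c("x", "y", "z")
  new("MolecularGraph", elements = elements, charges = as.integer(charges),
      bonds = bonds, coords = coords)
}

#' Create a build configuration
#'
#' @param forceField "MMFF" (default) or "UFF".
#' @param ffIterations minimization steps (default 500; 0 disables).
#' @param shift inter-copy placement distance in Angstrom (default 3.0).
#' @param seed optional integer seed for random-sequence builders.
#' @return a [BuildConfig-class].
#' @export
BuildConfig <- function(forceField = c("MMFF", "UFF"), ffIterations = 500L,
                        shift = 3.0, seed = NA_integer_) {
  forceField <- match.arg(forceField)
  new("BuildConfig", forceField = forceField,
      ffIterations = as.integer(ffIterations), shift = as.numeric(shift),
      seed = as.integer(seed))
}

#' Create an embedding plan
#'
#' @param axis placement direction (normalized internally); default x axis.
#' @param shift inter-copy distance in Angstrom.
#' @return an [EmbeddingPlan-class].
#' @export
EmbeddingPlan <- function(axis = c(1, 0, 0), shift = 3.0) {
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm == 0) stop("axis must be a nonzero vector")
  new("EmbeddingPlan", axis = axis / nrm, shift = as.numeric(shift))
}

#' Create a dispatch plan
#'
#' @param nWorkers concurrent workers (default 1).
#' @param coresPerTask cores per external calculation (default 1).
#' @return a [DispatchPlan-class].
#' @export
DispatchPlan <- function(nWorkers = 1L, coresPerTask = 1L) {
  new("DispatchPlan", nWorkers = as.integer(nWorkers),
      coresPerTask = as.integer(coresPerTask))
}
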