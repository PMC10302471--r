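# Initial 3D placement and classical force-field relaxation. Embedding and
# minimization are delegated to Open Babel (deterministic builder path and
# MMFF94/UFF implementations); the graph itself is never touched here.

.FF_OB <- c(MMFF = "MMFF94", UFF = "UFF")

#' Attach 3D coordinates by rule-based embedding
#'
#' Runs Open Babel's 3D structure builder on the graph. Atom order is
#' preserved (verified; a mismatch aborts), so indices remain stable. The
#' builder's conformer search draws its own randomness, so coordinates may
#' differ slightly between runs; the molecular graph, and everything
#' derived from it, is unaffected.
#'
#' @param g a [MolecularGraph-class] (coordinates, if any, are replaced).
#' @return the graph with a populated coordinate block.
#' @export
embedCoords <- function(g) {
  tin <- tempfile(fileext = ".mol")
  tout <- tempfile(fileext = ".mol")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  .writeMolFile(g, tin)
  .obabelConvert(tin, tout, c("-imol", "-omol", "--gen3d"))
  emb <- .molFileToGraph(tout)
  if (!identical(emb@elements, g@elements))
    stop("embedding changed the atom order; cannot map coordinates back")
  atomCoords(g) <- emb@coords
  g
}

#' Lay out translated copies of a monomer along an axis
#'
#' Returns the disjoint union of \code{n} copies of the monomer graph, copy
#' \code{i} rigidly translated by \code{(i-1) * shift} along the plan's
#' axis. No bonds are created between copies; this is the pre-merge layout
#' of the linear-polymer construction.
#'
#' @param m a [Monomer-class] or [MolecularGraph-class]; embedded first if
#'   it carries no coordinates.
#' @param n number of copies (>= 1).
#' @param plan an [EmbeddingPlan-class] (axis + shift).
#' @return a [MolecularGraph-class] of \code{n} unbonded copies.
#' @export
placeCopies <- function(m, n, plan = EmbeddingPlan()) {
  if (n < 1L) stop("n must be >= 1")
  g <- if (is(m, "Monomer")) monomerGraph(m) else m
  if (!hasCoords(g)) g <- embedCoords(g)
  out <- g
  for (i in seq_len(n - 1L)) {
    shifted <- g
    atomCoords(shifted) <- sweep(g@coords, 2, i * plan@shift * plan@axis, "+")
    out <- .disjointUnion(out, shifted)
  }
  out
}

.obEnergy <- function(molfile, ff) {
  out <- suppressWarnings(system2("obenergy",
    c("-ff", .FF_OB[[ff]], shQuote(molfile)), stdout = TRUE, stderr = TRUE))
  txt <- paste(out, collapse = "\n")
  if (grepl("could not setup force field", txt, ignore.case = TRUE))
    return(NA_real_)
  m <- regmatches(txt, regexpr("TOTAL ENERGY = *[-0-9.eE+]+", txt))
  if (!length(m)) return(NA_real_)
  as.numeric(sub("TOTAL ENERGY = *", "", m))
}

#' Relax a structure with a classical force field
#'
#' Conjugate-gradient minimization with MMFF94 or UFF through Open Babel.
#' The molecular graph (elements, bond multiset) is preserved exactly; only
#' coordinates change. When the chosen force field cannot type an atom
#' (e.g. an exotic placeholder element), the other force field is tried
#' with a warning; if both fail, an error is raised.
#' \code{metadata()} of the result records \code{energyInitial},
#' \code{energyFinal} (in the force field's native units: kcal/mol for
#' MMFF94, kJ/mol for UFF) and \code{forceFieldUsed}.
#'
#' @param g a [MolecularGraph-class] with 3D coordinates.
#' @param cfg a [BuildConfig-class]; \code{ffIterations = 0} returns the
#'   input unchanged.
#' @return the relaxed [MolecularGraph-class].
#' @export
minimizeGeometry <- function(g, cfg = BuildConfig()) {
  if (cfg@ffIterations == 0L) return(g)
  if (!hasCoords(g))
    stop("minimization requires coordinates; run embedCoords() first")
  tin <- tempfile(fileext = ".mol")
  tout <- tempfile(fileext = ".mol")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  .writeMolFile(g, tin)

  ff <- cfg@forceField
  e0 <- .obEnergy(tin, ff)
  if (is.na(e0)) {
    alt <- setdiff(names(.FF_OB), ff)
    warning(sprintf("%s could not type all atoms; falling back to %s",
                    ff, alt))
    ff <- alt
    e0 <- .obEnergy(tin, ff)
    if (is.na(e0))
      stop("minimization error: neither MMFF nor UFF can type this structure")
  }
  .obabelConvert(tin, tout, c("-imol", "-omol", "--minimize",
                              "--ff", .FF_OB[[ff]],
                              "--steps", as.character(cfg@ffIterations)))
  minb <- .molFileToGraph(tout)
  if (!identical(minb@elements, g@elements))
    stop("minimization changed the atom order; cannot map coordinates back")
  e1 <- .obEnergy(tout, ff)
  atomCoords(g) <- minb@coords
  md <- metadata(g)
  md$energyInitial <- e0
  md$energyFinal <- e1
  md$forceFieldUsed <- ff
  metadata(g) <- md
  g
}
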