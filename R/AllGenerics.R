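#' @rdname MolecularGraph-class
#' @param x,object a MolecularGraph (or object wrapping one).
#' @export
setGeneric("natoms", function(x) standardGeneric("natoms"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("nbonds", function(x) standardGeneric("nbonds"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("formalCharges", function(x) standardGeneric("formalCharges"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("bondMatrix", function(x) standardGeneric("bondMatrix"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @rdname MolecularGraph-class
#' @param value replacement value.
#' @export
setGeneric("atomCoords<-", function(x, value) standardGeneric("atomCoords<-"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("hasCoords", function(x) standardGeneric("hasCoords"))

#' @rdname Monomer-class
#' @param x a Monomer.
#' @export
setGeneric("monomerGraph", function(x) standardGeneric("monomerGraph"))

#' @rdname Monomer-class
#' @export
setGeneric("placeholderElement",
           function(x) standardGeneric("placeholderElement"))

#' @rdname PolymerResult-class
#' @param x a PolymerResult.
#' @export
setGeneric("polymerGraph", function(x) standardGeneric("polymerGraph"))

#' @rdname PolymerResult-class
#' @export
setGeneric("topologyType", function(x) standardGeneric("topologyType"))

#' @rdname PolymerResult-class
#' @export
setGeneric("monomerSequence", function(x) standardGeneric("monomerSequence"))

#' @rdname PolymerResult-class
#' @export
setGeneric("seedUsed", function(x) standardGeneric("seedUsed"))

# ---- accessor methods ------------------------------------------------------

#' @rdname MolecularGraph-class
#' @export
setMethod("natoms", "MolecularGraph", function(x) length(x@elements))

#' @rdname MolecularGraph-class
#' @export
setMethod("nbonds", "MolecularGraph", function(x) nrow(x@bonds))

#' @rdname MolecularGraph-class
#' @export
setMethod("atomElements", "MolecularGraph", function(x) x@elements)

#' @rdname MolecularGraph-class
#' @export
setMethod("formalCharges", "MolecularGraph", function(x) x@charges)

#' @rdname MolecularGraph-class
#' @export
setMethod("bondMatrix", "MolecularGraph", function(x) x@bonds)

#' @rdname MolecularGraph-class
#' @export
setMethod("atomCoords", "MolecularGraph", function(x) x@coords)

#' @rdname MolecularGraph-class
#' @export
setReplaceMethod("atomCoords", "MolecularGraph", function(x, value) {
  value <- as.matrix(value)
  storage.mode(value) <- "double"
  colnames(value) <- c("x", "y", "z")
  x@coords <- value
  validObject(x)
  x
})

#' @rdname MolecularGraph-class
#' @export
setMethod("hasCoords", "MolecularGraph", function(x) nrow(x@coords) > 0L)

#' @rdname Monomer-class
#' @export
setMethod("monomerGraph", "Monomer", function(x) x@graph)

#' @rdname Monomer-class
#' @export
setMethod("placeholderElement", "Monomer", function(x) x@placeholder)

#' @rdname Monomer-class
#' @export
setMethod("natoms", "Monomer", function(x) natoms(x@graph))

#' @rdname Monomer-class
#' @export
setMethod("nbonds", "Monomer", function(x) nbonds(x@graph))

#' @rdname PolymerResult-class
#' @export
setMethod("polymerGraph", "PolymerResult", function(x) x@graph)

#' @rdname PolymerResult-class
#' @export
setMethod("topologyType", "PolymerResult", function(x) x@topology)

#' @rdname PolymerResult-class
#' @export
setMethod("monomerSequence", "PolymerResult", function(x) x@sequence)

#' @rdname PolymerResult-class
#' @export
setMethod("seedUsed", "PolymerResult", function(x) x@seedUsed)

#' @rdname PolymerResult-class
#' @export
setMethod("natoms", "PolymerResult", function(x) natoms(x@graph))

#' @rdname PolymerResult-class
#' @export
setMethod("nbonds", "PolymerResult", function(x) nbonds(x@graph))

# ---- show methods ----------------------------------------------------------

.formulaString <- function(g) {
  tab <- table(g@elements)
  ord <- c(intersect(c("C", "H"), names(tab)),
           sort(setdiff(names(tab), c("C", "H"))))
  paste0(vapply(ord, function(e)
    paste0(e, if (tab[[e]] > 1L) tab[[e]] else ""), character(1)),
    collapse = "")
}

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d atoms, %d bonds (%s)%s\n",
              natoms(object), nbonds(object), .formulaString(object),
              if (hasCoords(object)) ", 3D coordinates" else ""))
})

setMethod("show", "Monomer", function(object) {
  nph <- sum(object@graph@elements == object@placeholder)
  cat(sprintf("Monomer: %d atoms, %d bonds, %d '%s' placeholder site%s\n",
              natoms(object), nbonds(object), nph, object@placeholder,
              if (nph == 1L) "" else "s"))
})

setMethod("show", "PolymerResult", function(object) {
  cat(sprintf("PolymerResult (%s): %d units [%s], %d atoms, %d bonds\n",
              object@topology, length(object@sequence),
              paste(object@sequence, collapse = ""),
              natoms(object), nbonds(object)))
})

setMethod("show", "BuildConfig", function(object) {
  cat(sprintf("BuildConfig: %s, %d steps, shift %.2f A, seed %s\n",
              object@forceField, object@ffIterations, object@shift,
              ifelse(is.na(object@seed), "unset", object@seed)))
})
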