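# Format IO. Parsing of every standard format is delegated to Open Babel
# (obabel on the PATH) and ChemmineR; only the fixed-width V2000 *writer* is
# local. All structures come back with explicit hydrogens.

.obabelBin <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("Open Babel ('obabel') was not found on the PATH")
  p
}

.runObabel <- function(args) {
  out <- suppressWarnings(system2(.obabelBin(), args = args,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(log = paste(out, collapse = "\n"), status = if (is.null(status)) 0L else status)
}

.obabelConvert <- function(infile, outfile, extraArgs = character(0)) {
  res <- .runObabel(c(shQuote(infile), "-O", shQuote(outfile), extraArgs))
  ok <- file.exists(outfile) && file.size(outfile) > 0 &&
    !grepl("0 molecules converted", res$log, fixed = TRUE)
  if (!ok)
    stop(sprintf("Open Babel failed to convert '%s': %s", infile, res$log))
  invisible(outfile)
}

# ---- MOL text <-> MolecularGraph -------------------------------------------

.parseMolCharges <- function(molText, n) {
  charges <- integer(n)
  for (ln in grep("^M  CHG", strsplit(molText, "\n", fixed = TRUE)[[1]],
                  value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (p in seq_len(k)) charges[f[2 * p]] <- f[2 * p + 1]
  }
  charges
}

.molFileToGraph <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  if (length(sdf) < 1L) stop(sprintf("no molecule could be read from '%s'", path))
  sdf1 <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  elements <- sub("_\\d+$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- if (NROW(bb) > 0) unname(as.matrix(bb[, 1:3, drop = FALSE])) else NULL
  charges <- .parseMolCharges(paste(readLines(path, warn = FALSE),
                                    collapse = "\n"), length(elements))
  g <- MolecularGraph(elements, bonds, coords, charges)
  # all-zero coordinate blocks mean "no geometry" (e.g. SMILES-born input)
  if (natoms(g) > 1L && all(g@coords == 0)) g@coords <- matrix(numeric(0), ncol = 3,
      dimnames = list(NULL, c("x", "y", "z")))
  g
}

.graphToMolText <- function(g, title = "polyforge") {
  n <- natoms(g)
  if (n > 999L || nbonds(g) > 999L)
    stop("V2000 MOL format supports at most 999 atoms/bonds")
  xyz <- if (hasCoords(g)) g@coords else matrix(0, n, 3)
  atomLines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       xyz[, 1], xyz[, 2], xyz[, 3], g@elements)
  b <- g@bonds
  bondLines <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", b[, 1], b[, 2], b[, 3])
               else character(0)
  chgLines <- character(0)
  hot <- which(g@charges != 0L)
  if (length(hot)) {
    # M CHG lines carry at most 8 (index, charge) pairs each
    for (chunk in split(hot, ceiling(seq_along(hot) / 8))) {
      chgLines <- c(chgLines, paste0("M  CHG", sprintf("%3d", length(chunk)),
        paste(sprintf("%4d%4d", chunk, g@charges[chunk]), collapse = "")))
    }
  }
  paste(c(title, " polyforge", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)),
          atomLines, bondLines, chgLines, "M  END", ""),
        collapse = "\n")
}

.writeMolFile <- function(g, path) {
  writeLines(.graphToMolText(g), path)
  invisible(path)
}

# ---- user-facing readers ---------------------------------------------------

.guessFormat <- function(source) {
  if (file.exists(source)) {
    ext <- tolower(tools::file_ext(source))
    fmt <- switch(ext, mol = "mol", sdf = "mol", sd = "mol",
                  pdb = "pdb", xyz = "xyz", smi = "smiles", smiles = "smiles",
                  NULL)
    if (is.null(fmt))
      stop(sprintf("cannot infer a format from '%s'; pass format= explicitly",
                   source))
    fmt
  } else "smiles"  # bare strings default to SMILES
}

#' Read a molecular structure from SMILES or a standard chemical file
#'
#' Accepts a SMILES string or a MOL/SDF, PDB or XYZ file and returns a
#' [MolecularGraph-class] with explicit hydrogens. XYZ and PDB connectivity
#' is perceived by Open Babel from the geometry. SMILES-born structures
#' carry no coordinates until [embedCoords()] or a builder attaches them.
#'
#' @param source SMILES string or path to a structure file.
#' @param format "smiles", "mol", "pdb", "xyz" or "auto" (default: infer
#'   from the file extension; bare strings are treated as SMILES).
#' @return a [MolecularGraph-class].
#' @examples
#' g <- readStructure("c1ccoc1")   # furan
#' natoms(g)                       # 9 with explicit hydrogens
#' @export
readStructure <- function(source,
                          format = c("auto", "smiles", "mol", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(source)
  tmpOut <- tempfile(fileext = ".mol")
  on.exit(unlink(tmpOut), add = TRUE)
  if (format == "smiles") {
    src <- if (file.exists(source)) readLines(source, warn = FALSE)[1] else source
    tmpIn <- tempfile(fileext = ".smi")
    on.exit(unlink(tmpIn), add = TRUE)
    writeLines(src, tmpIn)
    ok <- tryCatch(.obabelConvert(tmpIn, tmpOut, c("-ismi", "-omol", "-h")),
                   error = function(e) e)
    if (inherits(ok, "error"))
      stop(sprintf("'%s' could not be parsed as SMILES", src))
  } else {
    if (!file.exists(source))
      stop(sprintf("file '%s' does not exist", source))
    flag <- c(mol = "-imol", pdb = "-ipdb", xyz = "-ixyz")[[format]]
    ok <- tryCatch(.obabelConvert(source, tmpOut, c(flag, "-omol", "-h")),
                   error = function(e) e)
    if (inherits(ok, "error"))
      stop(sprintf("'%s' could not be parsed as %s: %s", source, format,
                   conditionMessage(ok)))
  }
  .molFileToGraph(tmpOut)
}

#' Load a placeholder-decorated monomer
#'
#' Reads a structure (see [readStructure()]) and validates it as a monomer:
#' it must contain at least one atom of the placeholder element, and every
#' placeholder atom must have exactly one bonded neighbor. The choice of
#' placeholder element is entirely free (Br and Pt are conventional).
#'
#' @inheritParams readStructure
#' @param placeholder element symbol marking the polymerization sites.
#' @return a [Monomer-class].
#' @examples
#' m <- loadMonomer("Brc1ccc(Br)o1", placeholder = "Br")  # 2,5-dibromofuran
#' findPlaceholders(monomerGraph(m), "Br")
#' @export
loadMonomer <- function(source,
                        format = c("auto", "smiles", "mol", "pdb", "xyz"),
                        placeholder = "Br") {
  g <- readStructure(source, format)
  if (!any(g@elements == placeholder))
    stop(sprintf(paste0("decoration error: '%s' contains no '%s' placeholder ",
                        "atom"), if (nchar(source) < 200) source else "input",
                 placeholder))
  new("Monomer", graph = g, placeholder = placeholder)
}

# ---- writers ---------------------------------------------------------------

#' Write a structure to SMILES, MOL, XYZ or PDB
#'
#' XYZ and PDB require 3D coordinates; MOL falls back to an all-zero
#' coordinate block when none are attached. Written files round-trip through
#' [readStructure()] with identical element and bond multisets.
#'
#' @param g a [MolecularGraph-class].
#' @param path output file path.
#' @param format "smiles", "mol", "xyz", "pdb" or "auto" (from extension).
#' @return the path, invisibly.
#' @export
writeStructure <- function(g, path,
                           format = c("auto", "smiles", "mol", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mol = "mol", sdf = "mol", smi = "smiles",
                     smiles = "smiles", xyz = "xyz", pdb = "pdb",
                     stop(sprintf("cannot infer output format from '%s'", path)))
  }
  if (format %in% c("xyz", "pdb") && !hasCoords(g))
    stop(sprintf("%s output requires 3D coordinates; run embedCoords() first",
                 format))
  if (format == "mol") {
    .writeMolFile(g, path)
  } else if (format == "smiles") {
    writeLines(toSmiles(g), path)
  } else {
    tmp <- tempfile(fileext = ".mol")
    on.exit(unlink(tmp), add = TRUE)
    .writeMolFile(g, tmp)
    .obabelConvert(tmp, path, c("-imol", paste0("-o", format)))
  }
  invisible(path)
}

#' Canonical SMILES of a molecular graph
#'
#' @param g a [MolecularGraph-class].
#' @param canonical return the canonical form (default) or a plain SMILES.
#' @return a single SMILES string.
#' @export
toSmiles <- function(g, canonical = TRUE) {
  out <- ChemmineOB::convertFormat("SDF", if (canonical) "CAN" else "SMI",
                                   .graphToMolText(g))
  sub("[\t ].*$", "", trimws(out))
}
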