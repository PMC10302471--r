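# Inter-ring torsion detection for conjugated polymers. The molecular graph
# (atoms = nodes, covalent bonds = edges) is reduced to its ring-linking
# bonds: a linker bond is acyclic itself but connects two in-ring atoms.
# Every dihedral about such a bond is a backbone torsion that classical
# force fields tend to describe poorly, so these are the quadruples a user
# would feed to a dihedral scan.

#' Detect inter-ring linker bonds
#'
#' A linker bond is a bond that (i) is not a member of any ring and (ii)
#' joins two atoms that are each members of a ring. Ring membership is the
#' SSSR criterion: a bond is in-ring iff it lies on some cycle of the
#' molecular graph.
#'
#' @param g a [MolecularGraph-class].
#' @return integer matrix with columns \code{i}, \code{j} (one row per
#'   linker bond, \code{i < j}, sorted), 0 rows when the molecule is
#'   acyclic or all its rings are isolated.
#' @examples
#' biphenyl <- readStructure("c1ccc(-c2ccccc2)cc1")
#' detectLinkerBonds(biphenyl)  # exactly one inter-ring bond
#' @export
detectLinkerBonds <- function(g) {
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (nbonds(g) == 0L) return(empty)
  rm_ <- ringMembership(g)
  b <- g@bonds
  sel <- !rm_$bonds & rm_$atoms[b[, 1]] & rm_$atoms[b[, 2]]
  if (!any(sel)) return(empty)
  out <- b[sel, 1:2, drop = FALSE]
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

#' Enumerate torsion quadruples about linker bonds
#'
#' For every linker bond b-c, lists all dihedrals a-b-c-d with a a neighbor
#' of b (other than c) and d a neighbor of c (other than b). Hydrogens are
#' excluded unless \code{includeH = TRUE}, matching the heavy-atom dihedral
#' definition conventional for conjugated-backbone scans. Each quadruple is
#' stored once in canonical form (central bond with b < c), so reversed
#' duplicates never appear; rows are sorted by (b, c, a, d).
#'
#' @param g a [MolecularGraph-class].
#' @param bonds linker bonds as returned by [detectLinkerBonds()] (the
#'   default recomputes them).
#' @param includeH also emit quadruples whose outer atoms are hydrogen.
#' @return data.frame with integer columns \code{a}, \code{b}, \code{c},
#'   \code{d}.
#' @export
enumerateTorsions <- function(g, bonds = detectLinkerBonds(g),
                              includeH = FALSE) {
  res <- matrix(integer(0), ncol = 4)
  for (r in seq_len(nrow(bonds))) {
    b <- bonds[r, 1]; cc <- bonds[r, 2]  # already i < j
    aCand <- setdiff(.neighborsOf(g, b), cc)
    dCand <- setdiff(.neighborsOf(g, cc), b)
    if (!includeH) {
      aCand <- aCand[g@elements[aCand] != "H"]
      dCand <- dCand[g@elements[dCand] != "H"]
    }
    if (!length(aCand) || !length(dCand)) next
    quad <- as.matrix(expand.grid(a = aCand, d = dCand,
                                  KEEP.OUT.ATTRS = FALSE))
    res <- rbind(res, cbind(quad[, 1], b, cc, quad[, 2]))
  }
  out <- data.frame(a = as.integer(res[, 1]), b = as.integer(res[, 2]),
                    c = as.integer(res[, 3]), d = as.integer(res[, 4]))
  out[order(out$b, out$c, out$a, out$d), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Render 2D sketches of detected torsions
#'
#' Writes one PNG per torsion quadruple: the molecule drawn from 2D
#' coordinates (generated by Open Babel when absent) with the four torsion
#' atoms highlighted and labeled by atom index. Filenames encode the
#' quadruple, \code{torsion_a-b-c-d.png}, for traceability.
#'
#' @param g a [MolecularGraph-class].
#' @param torsions data.frame from [enumerateTorsions()].
#' @param outdir output directory (created if missing).
#' @param width,height image size in pixels.
#' @return character vector of the written file paths (empty for an empty
#'   torsion list).
#' @export
renderTorsionSketches <- function(g, torsions, outdir,
                                  width = 600, height = 450) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", outdir))
  if (file.access(outdir, mode = 2) != 0)
    stop(sprintf("output directory '%s' is not writable", outdir))
  if (nrow(torsions) == 0L) return(character(0))

  xy <- .sketchCoords(g)
  files <- character(nrow(torsions))
  for (r in seq_len(nrow(torsions))) {
    quad <- as.integer(torsions[r, c("a", "b", "c", "d")])
    files[r] <- file.path(outdir,
      sprintf("torsion_%d-%d-%d-%d.png", quad[1], quad[2], quad[3], quad[4]))
    grDevices::png(files[r], width = width, height = height)
    tryCatch(.drawSketch(g, xy, quad), finally = grDevices::dev.off())
  }
  files
}

# 2D depiction coordinates via Open Babel's layout engine.
.sketchCoords <- function(g) {
  tin <- tempfile(fileext = ".mol")
  tout <- tempfile(fileext = ".mol")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  gg <- g
  gg@coords <- matrix(numeric(0), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  .writeMolFile(gg, tin)
  .obabelConvert(tin, tout, c("-imol", "-omol", "--gen2d"))
  lay <- .molFileToGraph(tout)
  if (!identical(lay@elements, g@elements))
    stop("2D layout changed the atom order")
  lay@coords[, 1:2, drop = FALSE]
}

.drawSketch <- function(g, xy, quad) {
  graphics::par(mar = c(1, 1, 2, 1))
  rng <- apply(xy, 2, range)
  pad <- 0.08 * pmax(rng[2, ] - rng[1, ], 1)
  graphics::plot(NA, xlim = rng[, 1] + c(-pad[1], pad[1]),
                 ylim = rng[, 2] + c(-pad[2], pad[2]),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = sprintf("torsion %d-%d-%d-%d",
                                quad[1], quad[2], quad[3], quad[4]))
  b <- g@bonds
  graphics::segments(xy[b[, 1], 1], xy[b[, 1], 2],
                     xy[b[, 2], 1], xy[b[, 2], 2], col = "grey40")
  path <- cbind(xy[quad, 1], xy[quad, 2])
  graphics::lines(path, col = "red", lwd = 3)
  heavy <- g@elements != "H"
  graphics::points(xy[heavy, 1], xy[heavy, 2], pch = 21, cex = 2.2,
                   bg = ifelse(seq_len(nrow(xy))[heavy] %in% quad,
                               "tomato", "white"))
  graphics::text(xy[heavy, 1], xy[heavy, 2],
                 labels = paste0(g@elements[heavy],
                                 which(heavy)), cex = 0.6)
}
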