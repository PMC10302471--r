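# Polymer topology builders. All of them compose the same primitives:
# lay copies out along an axis, consume placeholder pairs with joinGraphs(),
# cap the leftovers with hydrogen, then relax with the configured force
# field. The head of a two-placeholder monomer is its lower-index
# placeholder; joins consume tail(i) <-> head(i+1), which makes every build
# deterministic without user intervention.

.rhalfup <- function(x) as.integer(floor(x + 0.5))

.withSeed <- function(seed, fun) {
  if (is.na(seed)) return(fun())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  fun()
}

.checkChainMonomer <- function(m, who) {
  nph <- length(findPlaceholders(monomerGraph(m), placeholderElement(m)))
  if (nph != 2L)
    stop(sprintf("topology error: %s must carry exactly 2 '%s' placeholders (found %d)",
                 who, placeholderElement(m), nph))
}

.samePlaceholder <- function(units) {
  els <- vapply(units, placeholderElement, character(1))
  if (length(unique(els)) != 1L)
    stop(sprintf("placeholder elements differ between monomers (%s); they must match",
                 paste(unique(els), collapse = ", ")))
  els[[1]]
}

# Core chain assembler. units: list of unique monomers; seqIdx: which unit
# occupies each backbone position; labels: recorded sequence.
.buildChain <- function(units, seqIdx, labels, cfg, cap = TRUE,
                        topology = "linear", close = FALSE,
                        seedUsed = NA_integer_) {
  el <- .samePlaceholder(units)
  lapply(units, .checkChainMonomer, who = "every chain monomer")
  n <- length(seqIdx)

  withGeometry <- cfg@ffIterations > 0L
  graphs <- lapply(units, function(m) monomerGraph(m))
  if (withGeometry)
    graphs <- lapply(graphs, function(g) if (hasCoords(g)) g else embedCoords(g))
  else if (!all(vapply(graphs, hasCoords, logical(1))))
    graphs <- lapply(graphs, function(g) { # drop partial geometry: all or none
      g@coords <- matrix(numeric(0), ncol = 3,
                         dimnames = list(NULL, c("x", "y", "z")))
      g })

  plan <- EmbeddingPlan(shift = cfg@shift)
  placed <- vector("list", n)
  for (k in seq_len(n)) {
    g <- graphs[[seqIdx[k]]]
    if (hasCoords(g)) {
      gk <- g
      atomCoords(gk) <- sweep(g@coords, 2, (k - 1) * plan@shift * plan@axis,
                              "+")
      placed[[k]] <- gk
    } else placed[[k]] <- g
  }

  acc <- placed[[1L]]
  for (k in seq_len(n)[-1L]) {
    phAcc <- findPlaceholders(acc, el)
    phNew <- findPlaceholders(placed[[k]], el)
    acc <- joinGraphs(acc, max(phAcc), placed[[k]], min(phNew))
  }

  if (close) {
    ph <- findPlaceholders(acc, el)
    acc <- .closeRing(acc, ph[1L], ph[2L])
  } else if (cap) {
    acc <- capPlaceholders(acc, el)
  }
  if (withGeometry && hasCoords(acc)) acc <- minimizeGeometry(acc, cfg)
  new("PolymerResult", graph = acc, topology = topology, sequence = labels,
      seedUsed = as.integer(seedUsed))
}

#' Build a linear homopolymer
#'
#' Joins \code{nCopies} copies of a two-placeholder monomer head-to-tail,
#' caps the two surviving terminal placeholders with hydrogen and relaxes
#' the geometry. Atom/bond counts obey the conservation identities
#' \code{natoms = n*A - 2*(n-1)} and \code{nbonds = n*B - (n-1)} where A/B
#' count the decorated monomer with explicit hydrogens.
#'
#' @param m a [Monomer-class] with exactly 2 placeholder sites.
#' @param nCopies number of repeat units (>= 1).
#' @param cfg a [BuildConfig-class].
#' @param cap cap surviving placeholders with H (default). \code{FALSE}
#'   keeps them, so the chain can be re-wrapped with [asMonomer()].
#' @return a [PolymerResult-class].
#' @examples
#' furan <- loadMonomer("Brc1ccc(Br)o1", placeholder = "Br")
#' p <- linearPolymer(furan, 5, BuildConfig(ffIterations = 0L))
#' natoms(p)  # 37
#' @export
linearPolymer <- function(m, nCopies, cfg = BuildConfig(), cap = TRUE) {
  if (nCopies < 1L) stop("topology error: nCopies must be >= 1")
  .buildChain(list(m), rep(1L, nCopies), rep("A", nCopies), cfg, cap = cap)
}

#' Build a linear diblock copolymer
#'
#' A block of \code{lenA} copies of \code{ma} followed by \code{lenB}
#' copies of \code{mb}. Both monomers must share the same placeholder
#' element.
#'
#' @param ma,mb [Monomer-class] objects with exactly 2 placeholders each.
#' @param lenA,lenB block lengths (both >= 1).
#' @inheritParams linearPolymer
#' @return a [PolymerResult-class] with sequence \code{A...AB...B}.
#' @export
diblockCopolymer <- function(ma, mb, lenA, lenB, cfg = BuildConfig(),
                             cap = TRUE) {
  if (lenA < 1L || lenB < 1L)
    stop("topology error: block lengths must be >= 1")
  .buildChain(list(ma, mb), rep(c(1L, 2L), c(lenA, lenB)),
              rep(c("A", "B"), c(lenA, lenB)), cfg, cap = cap)
}

#' Build a random two-monomer copolymer
#'
#' The chain contains exactly \code{round(pA * length)} units of \code{m1}
#' (round-half-up) and the remainder of \code{m2}, in a uniformly random
#' order drawn from the configured seed; the realized sequence is recorded
#' in the result.
#'
#' @param m1,m2 [Monomer-class] objects with exactly 2 placeholders each.
#' @param length total number of units.
#' @param pA probability weight of \code{m1}, in [0, 1].
#' @param cfg a [BuildConfig-class]; \code{seed} makes the sequence
#'   reproducible.
#' @return a [PolymerResult-class].
#' @export
randomAbCopolymer <- function(m1, m2, length, pA, cfg = BuildConfig()) {
  if (length < 1L) stop("topology error: length must be >= 1")
  if (is.na(pA) || pA < 0 || pA > 1)
    stop("probability error: pA must lie in [0, 1]")
  nA <- .rhalfup(pA * length)
  labels <- rep(c("A", "B"), c(nA, length - nA))
  labels <- .withSeed(cfg@seed, function() sample(labels))
  .buildChain(list(m1, m2), match(labels, c("A", "B")), labels, cfg,
              seedUsed = cfg@seed)
}

#' Build a random three-monomer copolymer
#'
#' Unit counts are \code{n1 = round(pA*length)}, \code{n2 = round(pB*length)}
#' (round-half-up, with \code{n2} clamped so the counts never exceed the
#' chain) and \code{n3 = length - n1 - n2} for the last-listed monomer,
#' randomly ordered.
#'
#' @param m1,m2,m3 [Monomer-class] objects with exactly 2 placeholders each.
#' @param length total number of units.
#' @param pA,pB probability weights; \code{pA + pB} must not exceed 1.
#' @inheritParams randomAbCopolymer
#' @return a [PolymerResult-class].
#' @export
randomAbcCopolymer <- function(m1, m2, m3, length, pA, pB,
                               cfg = BuildConfig()) {
  if (length < 1L) stop("topology error: length must be >= 1")
  if (any(is.na(c(pA, pB))) || pA < 0 || pB < 0)
    stop("probability error: pA and pB must be >= 0")
  if (pA + pB > 1)
    stop("probability error: pA + pB must not exceed 1")
  n1 <- .rhalfup(pA * length)
  n2 <- min(.rhalfup(pB * length), length - n1)
  n3 <- length - n1 - n2
  labels <- rep(c("A", "B", "C"), c(n1, n2, n3))
  labels <- .withSeed(cfg@seed, function() sample(labels))
  .buildChain(list(m1, m2, m3), match(labels, c("A", "B", "C")), labels, cfg,
              seedUsed = cfg@seed)
}

#' Build a ring (cyclic) polymer
#'
#' A linear chain is built first; its two terminal placeholders are then
#' consumed to form one additional bond, closing the macrocycle (no capping
#' is needed). The product's cyclomatic number exceeds the sum of the
#' monomer ring counts by exactly one.
#'
#' @param m a [Monomer-class] with exactly 2 placeholders; a chain product
#'   re-wrapped with [asMonomer()] works too, which is how copolymer rings
#'   are made.
#' @param length number of units (>= 3: smaller macrocycles would collapse
#'   onto a double bridge between two neighbors).
#' @param cfg a [BuildConfig-class].
#' @return a [PolymerResult-class] with topology "ring".
#' @export
ringPolymer <- function(m, length, cfg = BuildConfig()) {
  if (length < 3L) stop("topology error: ring length must be >= 3")
  .buildChain(list(m), rep(1L, length), rep("A", length), cfg,
              topology = "ring", close = TRUE)
}

#' Build a branched (star) polymer
#'
#' Attaches one copy of the arm at every placeholder site of the core: a
#' core with k placeholders yields k arms, and no placeholder survives.
#'
#' @param core a [Monomer-class] with k >= 1 placeholder sites.
#' @param arm a [Monomer-class] with exactly 1 placeholder site (an
#'   oligomer arm can be made by capping all but one site of a chain built
#'   with \code{cap = FALSE}).
#' @param cfg a [BuildConfig-class].
#' @return a [PolymerResult-class] with topology "branched" and sequence
#'   \code{core, arm, arm, ...}.
#' @export
branchedPolymer <- function(core, arm, cfg = BuildConfig()) {
  el <- .samePlaceholder(list(core, arm))
  armPh <- findPlaceholders(monomerGraph(arm), el)
  if (length(armPh) != 1L)
    stop(sprintf("topology error: arm must carry exactly 1 '%s' placeholder (found %d)",
                 el, length(armPh)))
  coreG <- monomerGraph(core)
  k <- length(findPlaceholders(coreG, el))
  if (k < 1L)
    stop("topology error: core carries no placeholder sites")

  withGeometry <- cfg@ffIterations > 0L
  armG <- monomerGraph(arm)
  if (withGeometry) {
    if (!hasCoords(coreG)) coreG <- embedCoords(coreG)
    if (!hasCoords(armG)) armG <- embedCoords(armG)
  } else if (!hasCoords(coreG) || !hasCoords(armG)) {
    blank <- matrix(numeric(0), ncol = 3,
                    dimnames = list(NULL, c("x", "y", "z")))
    coreG@coords <- blank
    armG@coords <- blank
  }

  acc <- coreG
  for (i in seq_len(k)) {
    ph <- findPlaceholders(acc, el)
    armI <- armG
    if (hasCoords(armI))
      atomCoords(armI) <- sweep(armG@coords, 2, c(i * cfg@shift + 5, 0, 0), "+")
    acc <- joinGraphs(acc, ph[1L], armI, findPlaceholders(armI, el)[1L])
  }
  if (withGeometry && hasCoords(acc)) acc <- minimizeGeometry(acc, cfg)
  new("PolymerResult", graph = acc, topology = "branched",
      sequence = c("core", rep("arm", k)), seedUsed = NA_integer_)
}

#' Build a polymer with an absolute monomer sequence
#'
#' The backbone follows the pattern string exactly: letter \code{i} of the
#' pattern selects \code{monomers[[letter - 'A' + 1]]}. Combined with
#' \code{cap = FALSE} and [asMonomer()], patterned products can themselves
#' serve as repeat units ("polymers as monomers").
#'
#' @param pattern string over A..Z.
#' @param monomers ordered list of [Monomer-class] objects; the first is A,
#'   the second B, and so on. Each needs exactly 2 placeholders.
#' @inheritParams linearPolymer
#' @return a [PolymerResult-class] whose sequence equals the pattern.
#' @examples
#' cat <- monomerCatalog()
#' p <- patternedPolymer("ABC", list(cat$thiophene, cat$furan, cat$benzene),
#'                       BuildConfig(ffIterations = 0L))
#' monomerSequence(p)
#' @export
patternedPolymer <- function(pattern, monomers, cfg = BuildConfig(),
                             cap = TRUE) {
  if (length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a nonempty string")
  letters_ <- strsplit(pattern, "")[[1]]
  if (!all(letters_ %in% LETTERS))
    stop("pattern may only contain uppercase letters A..Z")
  idx <- match(letters_, LETTERS)
  if (max(idx) > length(monomers))
    stop(sprintf("pattern letter '%s' has no monomer mapping (only %d supplied)",
                 LETTERS[max(idx)], length(monomers)))
  .buildChain(monomers[seq_len(max(idx))], idx, letters_, cfg, cap = cap)
}

#' Enumerate the distinct permutations of a pattern
#'
#' All unique orderings of the pattern's letters (multiset permutations),
#' lexicographically sorted; repeated letters collapse duplicates, so
#' "AAB" yields 3 strings rather than 6.
#'
#' @param pattern nonempty string.
#' @return sorted character vector of distinct permutations.
#' @examples
#' uniquePatternPermutations("ABC")  # 6 strings
#' uniquePatternPermutations("AA")   # "AA"
#' @export
uniquePatternPermutations <- function(pattern) {
  if (length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a nonempty string")
  chars <- sort(strsplit(pattern, "")[[1]])
  if (length(chars) > 10L)
    stop("patterns longer than 10 letters are not enumerated")
  recurse <- function(remaining) {
    if (!length(remaining)) return("")
    out <- character(0)
    for (ch in unique(remaining)) {
      rest <- remaining[-match(ch, remaining)]
      out <- c(out, paste0(ch, recurse(rest)))
    }
    out
  }
  sort(recurse(chars))
}
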