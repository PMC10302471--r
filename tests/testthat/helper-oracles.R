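# Brute-force oracle: a linker bond is any bond not on a cycle whose two
# endpoints both lie on cycles; cycle membership of a bond is decided by
# exhaustive path search with that bond removed. Deliberately independent
# of the package's ring perception (no igraph).
oracleLinkerBonds <- function(g) {
  b <- bondMatrix(g)
  n <- natoms(g)
  adj <- lapply(seq_len(n), function(i)
    c(b[b[, 1] == i, 2], b[b[, 2] == i, 1]))
  reachable <- function(from, to, skipBond) {
    seen <- logical(n); stack <- from
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v == to) return(TRUE)
      if (seen[v]) next
      seen[v] <- TRUE
      for (w in adj[[v]]) {
        if ((v == skipBond[1] && w == skipBond[2]) ||
            (v == skipBond[2] && w == skipBond[1])) next
        if (!seen[w]) stack <- c(stack, w)
      }
    }
    FALSE
  }
  bondInRing <- vapply(seq_len(nrow(b)), function(k)
    reachable(b[k, 1], b[k, 2], b[k, 1:2]), logical(1))
  atomInRing <- logical(n)
  for (k in which(bondInRing)) atomInRing[b[k, 1:2]] <- TRUE
  sel <- !bondInRing & atomInRing[b[, 1]] & atomInRing[b[, 2]]
  out <- b[sel, 1:2, drop = FALSE]
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}
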