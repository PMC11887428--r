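#' Classify rotatable bonds
#'
#' Glycans have few rotatable bonds relative to their size: ring bonds are
#' locked, and the anomeric configuration is stereochemistry that is never
#' sampled as a rotation.  A bond is classified rotatable when it is a
#' single, acyclic bond whose two endpoints each carry at least one further
#' neighbour, excluding torsionally degenerate symmetric tops (an endpoint
#' whose remaining substituents are two or more identical monovalent
#' atoms, e.g. a methyl group).  Under this rule the exocyclic glycosidic
#' C-O bonds (the phi/psi torsions), hydroxyl C-OH bonds and exocyclic
#' CH2OH bonds of a sugar are all rotatable; ring bonds, bonds to
#' monovalent atoms, amide C-N bonds and multiple bonds are not.
#'
#' @param m a `glyccs_molecule` with perceived bonds.
#' @return A data frame with one row per bond: `a1`, `a2`, `order`,
#'   `rotatable` (logical) and `reason` (one of `rotatable-glycosidic`,
#'   `rotatable`, `ring`, `terminal`, `order`, `amide`, `symmetric-top`).
#' @export
find_rotatable_bonds <- function(m) {
  nb <- nrow(m$bonds)
  out <- cbind(m$bonds,
               data.frame(rotatable = logical(nb), reason = character(nb)))
  if (nb == 0) return(out)
  adj <- adjacency(m)
  ring <- ring_bonds(m)
  el <- m$atoms$element
  deg <- lengths(adj)
  in_ring_atom <- rep(FALSE, n_atoms(m))
  if (any(ring)) {
    ra <- unique(c(m$bonds$a1[ring], m$bonds$a2[ring]))
    in_ring_atom[ra] <- TRUE
  }
  # carbonyl carbons, for the amide rule
  carbonyl_c <- unique(c(
    m$bonds$a1[m$bonds$order == 2 & el[m$bonds$a2] == "O" & el[m$bonds$a1] == "C"],
    m$bonds$a2[m$bonds$order == 2 & el[m$bonds$a1] == "O" & el[m$bonds$a2] == "C"]))

  symmetric_top <- function(i, partner) {
    rest <- setdiff(adj[[i]], partner)
    length(rest) >= 2 && all(deg[rest] == 1) && length(unique(el[rest])) == 1
  }

  for (b in seq_len(nb)) {
    i <- out$a1[b]; j <- out$a2[b]
    if (out$order[b] != 1) { out$reason[b] <- "order"; next }
    if (ring[b]) { out$reason[b] <- "ring"; next }
    if (deg[i] < 2 || deg[j] < 2) { out$reason[b] <- "terminal"; next }
    amide <- (el[i] == "N" && j %in% carbonyl_c) ||
             (el[j] == "N" && i %in% carbonyl_c)
    if (amide) { out$reason[b] <- "amide"; next }
    if (symmetric_top(i, j) || symmetric_top(j, i)) {
      out$reason[b] <- "symmetric-top"; next
    }
    out$rotatable[b] <- TRUE
    glyco <- (el[i] == "O" && in_ring_atom[j]) || (el[j] == "O" && in_ring_atom[i])
    out$reason[b] <- if (glyco) "rotatable-glycosidic" else "rotatable"
  }
  out
}
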