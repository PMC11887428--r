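#' Construct a molecule
#'
#' The molecule is the unit of all geometry work in the package: an ordered
#' atom list with 3D coordinates and explicit hydrogens, a bond list with
#' orders, perceived stereo descriptors, and a net charge.  Atom indices are
#' 1-based throughout; file formats keep their native serial numbers at the
#' I/O boundary.
#'
#' Hydrogens are never added implicitly.  The charge-model stage moves
#' protons, so implicit-hydrogen ambiguity is unacceptable; inputs must
#' carry explicit H.
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `formal_charge` (integer e) and `partial_charge`
#'   (fraction of e).
#' @param bonds data frame with columns `a1`, `a2` (1-based atom indices)
#'   and `order` (1, 2 or 3).  May have zero rows for a single atom.
#' @param label free-text name carried through all outputs.
#' @param perceive_stereo compute stereo descriptors at construction
#'   (CIP-like priorities by atomic number, then graph refinement).  The
#'   descriptors are carried as labels and asserted, not recomputed, after
#'   geometry changes.
#' @return An object of class `glyccs_molecule`.
#' @export
molecule <- function(atoms, bonds = NULL, label = "molecule",
                     perceive_stereo = TRUE) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(bonds)) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  atoms$element <- as.character(atoms$element)
  element_row(atoms$element)  # errors on unknown symbols
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- rep(0L, nrow(atoms))
  if (is.null(atoms$partial_charge)) atoms$partial_charge <- rep(NA_real_, nrow(atoms))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atomic coordinates", call. = FALSE)
  n <- nrow(atoms)
  if (nrow(bonds) > 0) {
    bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
    if (is.null(bonds$order)) bonds$order <- 1L
    bonds$order <- as.integer(bonds$order)
    if (any(bonds$a1 < 1 | bonds$a1 > n | bonds$a2 < 1 | bonds$a2 > n))
      stop("bond atom index out of range", call. = FALSE)
    if (any(bonds$a1 == bonds$a2))
      stop("bond connects an atom to itself", call. = FALSE)
  }
  m <- structure(
    list(atoms = atoms[, c("element", "x", "y", "z",
                           "formal_charge", "partial_charge")],
         bonds = bonds[, c("a1", "a2", "order")],
         stereo = NULL,
         net_charge = sum(atoms$formal_charge),
         label = label),
    class = "glyccs_molecule")
  if (perceive_stereo) m$stereo <- perceive_stereo(m)
  m
}

#' @export
print.glyccs_molecule <- function(x, ...) {
  nh <- sum(x$atoms$element == "H")
  cat(sprintf("<glyccs_molecule> %s: %d atoms (%d H), %d bonds, net charge %+d\n",
              x$label, n_atoms(x), nh, nrow(x$bonds), x$net_charge))
  cat(sprintf("  formula %s, monoisotopic mass %.4f Da\n",
              molecular_formula(x), monoisotopic_mass(x)))
  if (!is.null(x$stereo) && nrow(x$stereo$centers) > 0)
    cat(sprintf("  %d stereocenters: %s\n", nrow(x$stereo$centers),
                paste0(x$stereo$centers$atom, x$stereo$centers$label,
                       collapse = " ")))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param m a `glyccs_molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' Get or set the coordinate matrix of a molecule
#' @param m a `glyccs_molecule`.
#' @return `coords()` returns an N x 3 numeric matrix in Angstrom.
#' @export
coords <- function(m) {
  as.matrix(m$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @param value an N x 3 numeric matrix.
#' @export
`coords<-` <- function(m, value) {
  stopifnot(is.matrix(value), nrow(value) == n_atoms(m), ncol(value) == 3)
  m$atoms$x <- value[, 1]; m$atoms$y <- value[, 2]; m$atoms$z <- value[, 3]
  m
}

#' Molecular formula in Hill order
#' @param m a `glyccs_molecule`.
#' @return Character scalar, e.g. `"C6H12O6"`.
#' @export
molecular_formula <- function(m) {
  tab <- table(m$atoms$element)
  els <- names(tab)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (tab[[e]] == 1) e else paste0(e, tab[[e]])
  }, ""), collapse = "")
}

#' Monoisotopic mass
#'
#' Sum of principal-isotope masses of all atoms.  For ions the electron
#' mass is ignored by convention: a protonation/deprotonation changes the
#' mass by exactly the mass of a hydrogen atom (1.00783 Da).
#'
#' @param m a `glyccs_molecule`.
#' @return Mass in Da; 0 for an empty molecule.
#' @export
monoisotopic_mass <- function(m) {
  if (n_atoms(m) == 0) return(0)
  sum(element_row(m$atoms$element)$mass)
}

## adjacency list: integer vector of neighbours per atom
adjacency <- function(m) {
  n <- n_atoms(m)
  adj <- vector("list", n)
  if (nrow(m$bonds) > 0) {
    for (b in seq_len(nrow(m$bonds))) {
      i <- m$bonds$a1[b]; j <- m$bonds$a2[b]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  lapply(adj, function(v) if (is.null(v)) integer() else sort(v))
}

mol_graph <- function(m) {
  igraph::graph_from_edgelist(as.matrix(m$bonds[, c("a1", "a2")]),
                              directed = FALSE) |>
    igraph::add_vertices(max(0, n_atoms(m) - max(c(0, m$bonds$a1, m$bonds$a2))))
}

## bonds that lie in a ring: removing the bond keeps endpoints connected
ring_bonds <- function(m) {
  if (nrow(m$bonds) == 0) return(logical(0))
  g <- mol_graph(m)
  vapply(seq_len(nrow(m$bonds)), function(b) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, c(m$bonds$a1[b], m$bonds$a2[b])))
    igraph::distances(g2, v = m$bonds$a1[b], to = m$bonds$a2[b]) < Inf
  }, logical(1))
}

## number of bonds separating atom pairs (topological distance)
bond_distances <- function(m) {
  g <- mol_graph(m)
  igraph::distances(g)
}

#' Validate molecule invariants
#'
#' Checks the structural invariants: known elements, finite coordinates,
#' valid bond indices, no self-loops, net charge equal to the sum of formal
#' charges, and positive monoisotopic mass for non-empty molecules.
#'
#' @param m a `glyccs_molecule`.
#' @return `m`, invisibly; errors describe the first violated invariant.
#' @export
validate_molecule <- function(m) {
  stopifnot(inherits(m, "glyccs_molecule"))
  element_row(m$atoms$element)
  if (!all(is.finite(coords(m)))) stop("non-finite coordinates")
  if (m$net_charge != sum(m$atoms$formal_charge))
    stop("net_charge does not equal the sum of formal charges")
  if (nrow(m$bonds) > 0) {
    if (any(m$bonds$a1 == m$bonds$a2)) stop("self-loop bond")
    if (max(m$bonds$a1, m$bonds$a2) > n_atoms(m)) stop("bond index out of range")
  }
  if (n_atoms(m) > 0 && monoisotopic_mass(m) <= 0) stop("non-positive mass")
  invisible(m)
}
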