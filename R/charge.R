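#' Find titratable sites
#'
#' Surveys all probable acidic or basic heteroatom sites of a seed
#' structure.  Site classes are perceived from local graph patterns:
#'
#' * `hydroxyl_O`: O bearing one H and one heavy neighbour;
#' * `carboxyl_O`: hydroxyl O whose carbon also carries a double-bonded O;
#' * `carbonyl_O`: O double-bonded to C;
#' * `ether_or_ring_O`: O with two heavy neighbours and no H;
#' * `amine_N`: N not adjacent to a carbonyl carbon;
#' * `amide_N`: N adjacent to a carbonyl carbon.
#'
#' Negative mode returns sites with at least one O-H or N-H to remove;
#' positive mode returns sites with an available lone pair (hydroxyl,
#' carbonyl and ether/ring oxygens and amine nitrogens).  Amide nitrogens
#' are excluded from protonation by default (O-protonation of amides is
#' preferred); set `include_amide_n = TRUE` to override.  Ring and other
#' ether oxygens are included by default; set `include_ether_o = FALSE`
#' to restrict protonation to hydroxyl-type sites.
#'
#' @param m a [molecule()] with explicit hydrogens.
#' @param mode `"neg"` for \[M - H\]- or `"pos"` for \[M + H\]+.
#' @param include_amide_n allow protonation at amide N (default `FALSE`).
#' @param include_ether_o allow protonation at ether/ring O (default `TRUE`).
#' @return A data frame ordered by atom index: `atom`, `class`, `n_h`
#'   (hydrogens bonded to the site atom), `eligible`.  Zero rows is a
#'   valid result.
#' @export
find_titratable_sites <- function(m, mode = c("neg", "pos"),
                                  include_amide_n = FALSE,
                                  include_ether_o = TRUE) {
  mode <- match.arg(mode)
  adj <- adjacency(m)
  el <- m$atoms$element
  n <- n_atoms(m)
  dbl_to <- function(i) {
    b <- m$bonds[m$bonds$order == 2 & (m$bonds$a1 == i | m$bonds$a2 == i), ]
    unique(c(b$a1, b$a2))
  }
  carbonyl_c <- integer()
  for (b in which(m$bonds$order == 2)) {
    i <- m$bonds$a1[b]; j <- m$bonds$a2[b]
    if (el[i] == "C" && el[j] == "O") carbonyl_c <- c(carbonyl_c, i)
    if (el[j] == "C" && el[i] == "O") carbonyl_c <- c(carbonyl_c, j)
  }
  rows <- list()
  for (i in seq_len(n)) {
    if (!el[i] %in% c("O", "N")) next
    nb <- adj[[i]]
    hs <- nb[el[nb] == "H"]
    heavy <- nb[el[nb] != "H"]
    cls <- NULL
    if (el[i] == "O") {
      if (length(intersect(dbl_to(i), which(el == "C"))) > 0) {
        cls <- "carbonyl_O"
      } else if (length(hs) >= 1 && length(heavy) == 1) {
        cls <- if (heavy %in% carbonyl_c) "carboxyl_O" else "hydroxyl_O"
      } else if (length(heavy) == 2 && length(hs) == 0) {
        cls <- "ether_or_ring_O"
      }
    } else {  # N
      cls <- if (length(intersect(heavy, carbonyl_c)) > 0) "amide_N" else "amine_N"
    }
    if (is.null(cls)) next
    deprot_ok <- length(hs) >= 1
    prot_ok <- switch(cls,
                      hydroxyl_O = TRUE,
                      carboxyl_O = TRUE,
                      carbonyl_O = TRUE,
                      ether_or_ring_O = include_ether_o,
                      amine_N = length(nb) <= 3,
                      amide_N = include_amide_n)
    keep <- if (mode == "neg") deprot_ok else prot_ok
    if (keep)
      rows[[length(rows) + 1]] <- data.frame(atom = i, class = cls,
                                             n_h = length(hs))
  }
  if (length(rows) == 0)
    return(data.frame(atom = integer(), class = character(), n_h = integer()))
  do.call(rbind, rows)
}

#' Enumerate charge models
#'
#' Systematically cycles through the titratable sites of a seed structure,
#' deprotonating (negative mode, \[M - H\]-) or protonating (positive
#' mode, \[M + H\]+) one site per model while leaving the seed geometry
#' otherwise untouched.  Deprotonation deletes the site's hydrogen (the
#' first by index if the site oxygen unusually bears two).  Protonation
#' places the new hydrogen at the standard bond length (0.96 Angstrom
#' from O, 1.01 from N) along the lone-pair bisector, i.e. the negative
#' of the sum of unit vectors to the site's bonded neighbours; the
#' surrogate optimizer relaxes it downstream.
#'
#' @param m seed [molecule()] with explicit hydrogens.
#' @param mode `"neg"` or `"pos"`.
#' @param ... passed to [find_titratable_sites()].
#' @return A list of `glyccs_charge_model` objects, one per site, labelled
#'   with roman numerals in site order.  Empty list (with a warning) if the
#'   seed has no eligible sites.
#' @export
enumerate_charge_models <- function(m, mode = c("neg", "pos"), ...) {
  mode <- match.arg(mode)
  sites <- find_titratable_sites(m, mode, ...)
  if (nrow(sites) == 0) {
    warning("no titratable sites found for mode '", mode, "'")
    return(list())
  }
  adj <- adjacency(m)
  lapply(seq_len(nrow(sites)), function(k) {
    site <- sites[k, ]
    i <- site$atom
    atoms <- m$atoms
    if (mode == "neg") {
      hs <- adj[[i]][m$atoms$element[adj[[i]]] == "H"]
      if (length(hs) == 0)
        stop("internal error: deprotonation site without removable H")
      if (length(hs) > 1)
        message("site atom ", i, " bears ", length(hs),
                " hydrogens; removing the first by index")
      h <- hs[1]
      atoms <- atoms[-h, , drop = FALSE]
      atoms$formal_charge[if (i > h) i - 1L else i] <-
        atoms$formal_charge[if (i > h) i - 1L else i] - 1L
      bonds <- m$bonds[!(m$bonds$a1 == h | m$bonds$a2 == h), , drop = FALSE]
      bonds$a1 <- bonds$a1 - (bonds$a1 > h)
      bonds$a2 <- bonds$a2 - (bonds$a2 > h)
      index_map <- seq_len(n_atoms(m)) - (seq_len(n_atoms(m)) > h)
      index_map[h] <- NA_integer_
    } else {
      X <- coords(m)
      nb <- adj[[i]]
      dir <- -colSums(matrix(apply(X[nb, , drop = FALSE], 1,
                                   function(p) {
                                     v <- p - X[i, ]; v / sqrt(sum(v^2))
                                   }), nrow = 3, byrow = FALSE) |> t())
      if (sqrt(sum(dir^2)) < 1e-6) dir <- c(1, 0, 0)  # linear site: arbitrary
      dir <- dir / sqrt(sum(dir^2))
      blen <- if (m$atoms$element[i] == "N") 1.01 else 0.96
      hpos <- X[i, ] + blen * dir
      atoms <- rbind(atoms,
                     data.frame(element = "H", x = hpos[1], y = hpos[2],
                                z = hpos[3], formal_charge = 0L,
                                partial_charge = NA_real_))
      atoms$formal_charge[i] <- atoms$formal_charge[i] + 1L
      bonds <- rbind(m$bonds,
                     data.frame(a1 = i, a2 = nrow(atoms), order = 1L))
      index_map <- seq_len(n_atoms(m))
    }
    mol <- molecule(atoms, bonds,
                    label = sprintf("%s_%s_%s", m$label, mode, roman(k)))
    assert_stereo(mol, reference = m$stereo, index_map = index_map)
    structure(list(molecule = mol, mode = mode, site = site,
                   parent_label = m$label, parent_stereo = m$stereo,
                   index_map = index_map, enum_label = roman(k), index = k),
              class = "glyccs_charge_model")
  })
}

roman <- function(k) as.character(utils::as.roman(k))

#' @export
print.glyccs_charge_model <- function(x, ...) {
  cat(sprintf("<charge model %s> %s of %s at atom %d (%s), net %+d\n",
              x$enum_label,
              if (x$mode == "neg") "[M - H]-" else "[M + H]+",
              x$parent_label, x$site$atom, x$site$class,
              x$molecule$net_charge))
  invisible(x)
}

#' Remove symmetry-equivalent charge models
#'
#' Models from one seed and mode whose modified molecules are
#' graph-isomorphic, including the location of the charge site, are
#' redundant; only the model with the lowest enumeration index is kept.
#' Isomorphism is tested with VF2 on element/formal-charge vertex colours
#' and bond-order edge colours.
#'
#' @param models list of charge models from [enumerate_charge_models()].
#' @return Filtered list, enumeration order preserved.
#' @export
deduplicate_models <- function(models) {
  if (length(models) <= 1) return(models)
  gof <- function(cm) {
    m <- cm$molecule
    g <- igraph::graph_from_data_frame(
      data.frame(from = m$bonds$a1, to = m$bonds$a2),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n_atoms(m))))
    col <- match(m$atoms$element, .ELEMENTS$symbol) * 8 +
      (m$atoms$formal_charge + 4)
    list(g = g, vcol = col, ecol = m$bonds$order)
  }
  gs <- lapply(models, gof)
  keep <- rep(TRUE, length(models))
  for (i in seq_along(models)) {
    if (!keep[i]) next
    for (j in seq_along(models)) {
      if (j <= i || !keep[j]) next
      iso <- igraph::isomorphic(
        gs[[i]]$g, gs[[j]]$g, method = "vf2",
        vertex.color1 = gs[[i]]$vcol, vertex.color2 = gs[[j]]$vcol,
        edge.color1 = gs[[i]]$ecol, edge.color2 = gs[[j]]$ecol)
      if (iso) keep[j] <- FALSE
    }
  }
  models[keep]
}
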