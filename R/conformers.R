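#' Optimal-superposition RMSD between two coordinate sets
#'
#' Minimum root-mean-square deviation over rigid superposition (optimal
#' rotation by the Kabsch/SVD solution, reflections excluded), symmetric
#' in its arguments.  Hydrogens are excluded by default: their positions
#' are noise after minimisation.
#'
#' @param a,b N x 3 coordinate matrices over identical atom lists, or
#'   [molecule()] objects.
#' @param heavy_only when inputs are molecules, superpose heavy atoms only.
#' @return RMSD in Angstrom.
#' @export
align_rmsd <- function(a, b, heavy_only = TRUE) {
  if (inherits(a, "glyccs_molecule")) {
    stopifnot(inherits(b, "glyccs_molecule"),
              identical(a$atoms$element, b$atoms$element))
    sel <- if (heavy_only) which(a$atoms$element != "H") else seq_len(n_atoms(a))
    a <- coords(a)[sel, , drop = FALSE]
    b <- coords(b)[sel, , drop = FALSE]
  }
  if (!identical(dim(a), dim(b)))
    stop("coordinate sets have different atom counts", call. = FALSE)
  .kabsch_rmsd(a, b)
}

## rotate the a2-side of a rotatable bond so the (i, a1, a2, l) dihedral
## reaches `angle` (radians); reference atoms are the lowest-index heavy
## neighbours (any neighbour if no heavy one exists).
set_torsion <- function(m, a1, a2, angle) {
  adj <- adjacency(m)
  pick_ref <- function(center, exclude) {
    nb <- setdiff(adj[[center]], exclude)
    heavy <- nb[m$atoms$element[nb] != "H"]
    if (length(heavy) > 0) min(heavy) else min(nb)
  }
  i <- pick_ref(a1, a2); l <- pick_ref(a2, a1)
  X <- coords(m)
  cur <- dihedral_angle(X[i, ], X[a1, ], X[a2, ], X[l, ])
  delta <- angle - cur
  # side = component containing a2 after deleting the bond
  g <- mol_graph(m)
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a1, a2)))
  comp <- igraph::components(g2)$membership
  side <- which(comp == comp[a2])
  axis <- X[a2, ] - X[a1, ]
  axis <- axis / sqrt(sum(axis^2))
  # Rodrigues rotation about the bond axis through a1
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(delta) * K + (1 - cos(delta)) * (K %*% K)
  Xs <- sweep(X[side, , drop = FALSE], 2, X[a1, ])
  X[side, ] <- Xs %*% t(R) + matrix(X[a1, ], length(side), 3, byrow = TRUE)
  coords(m) <- X
  m
}

#' Generate a conformer ensemble for a charge model
#'
#' Stochastic torsion sampling on the rotatable bonds: each attempt draws
#' every rotatable torsion uniformly from a 60-degree grid with +/-15
#' degree jitter, relieves clashes by a short surrogate minimisation, and
#' is kept if its heavy-atom RMSD to every conformer already kept is at
#' least 0.1 Angstrom.  The target count is 1000 by default; systems with
#' few degrees of freedom saturate below it (a molecule with zero
#' rotatable bonds yields a single-conformer ensemble, which is logged,
#' not an error).  Stereo descriptors are asserted on every conformer.
#'
#' @param model a `glyccs_charge_model` or bare [molecule()].
#' @param target number of conformers to aim for.
#' @param seed RNG seed; fixed seed gives an exactly reproducible ensemble.
#' @param relax_steps minimiser iterations used for clash relief.
#' @param max_attempts sampling attempts before giving up (default
#'   `4 * target`).
#' @return A `glyccs_ensemble`: `molecule` (parent), `coords` (list of
#'   N x 3 matrices), `energy`, `re`, plus clustering fields filled by
#'   [cluster_ensemble()].
#' @export
generate_conformers <- function(model, target = 1000, seed = 1,
                                relax_steps = 400, max_attempts = 4 * target) {
  m <- if (inherits(model, "glyccs_charge_model")) model$molecule else model
  set.seed(seed)
  rot <- find_rotatable_bonds(m)
  rot <- rot[rot$rotatable, , drop = FALSE]
  params <- ff_params(m)
  relax <- function(mol) {
    fit <- .ff_minimize(coords(mol), params, as.integer(relax_steps), 1e-4)
    coords(mol) <- fit$coords
    list(mol = mol, energy = fit$energy)
  }
  base <- relax(m)
  assert_stereo(base$mol, reference = m$stereo)
  kept <- list(base$mol)
  energy <- base$energy
  if (nrow(rot) == 0) {
    message("no rotatable bonds: single-conformer ensemble")
  } else {
    grid <- seq(0, 300, by = 60) * pi / 180
    heavy <- which(m$atoms$element != "H")
    attempts <- 0
    while (length(kept) < target && attempts < max_attempts) {
      attempts <- attempts + 1
      cand <- m
      for (b in seq_len(nrow(rot))) {
        ang <- sample(grid, 1) + runif(1, -15, 15) * pi / 180
        cand <- set_torsion(cand, rot$a1[b], rot$a2[b], ang)
      }
      rl <- tryCatch(relax(cand), error = function(e) NULL)
      if (is.null(rl)) next
      ok <- tryCatch({
        assert_stereo(rl$mol, reference = m$stereo); TRUE
      }, error = function(e) FALSE)
      if (!ok) next  # sampling must never invert a stereocenter
      dup <- FALSE
      cc <- coords(rl$mol)[heavy, , drop = FALSE]
      for (kmol in kept) {
        if (.kabsch_rmsd(cc, coords(kmol)[heavy, , drop = FALSE]) < 0.1) {
          dup <- TRUE; break
        }
      }
      if (dup) next
      kept[[length(kept) + 1]] <- rl$mol
      energy <- c(energy, rl$energy)
    }
  }
  re <- energy - min(energy)
  structure(list(molecule = m,
                 model = if (inherits(model, "glyccs_charge_model")) model else NULL,
                 coords = lapply(kept, coords),
                 energy = energy, re = re,
                 cluster = rep(NA_integer_, length(kept)),
                 is_center = rep(TRUE, length(kept)),
                 params = list(target = target, seed = seed,
                               torsion_grid_deg = 60, jitter_deg = 15,
                               n_rotatable = nrow(rot))),
            class = "glyccs_ensemble")
}

#' @export
print.glyccs_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %s: %d conformers (%d rotatable bonds), RE span %.2f kcal/mol\n",
              x$molecule$label, length(x$coords), x$params$n_rotatable,
              max(x$re)))
  if (!all(is.na(x$cluster)))
    cat(sprintf("  %d clusters, %d centers\n", length(unique(x$cluster)),
                sum(x$is_center)))
  invisible(x)
}

#' Length of an ensemble
#' @param x a `glyccs_ensemble`.
#' @export
length.glyccs_ensemble <- function(x) length(x$coords)

#' Cluster a conformer ensemble and pick representative centers
#'
#' Ensembles at or below the threshold count pass through with every
#' conformer its own center.  Larger ensembles are reduced: the pairwise
#' heavy-atom aligned RMSD matrix is converted to a Gaussian affinity
#' (bandwidth = median off-diagonal RMSD), and a deterministic modularity
#' community detection (Louvain, internally seeded, resolution fixed by a
#' three-bundle calibration fixture) partitions the conformers.  The
#' representative center of each cluster is its lowest-energy member, so
#' the global minimum conformer is always promoted to a center.
#'
#' @param ens a `glyccs_ensemble` with per-conformer energies.
#' @param threshold_count pass-through limit (default 50, i.e. only
#'   ensembles with more than 50 conformers are clustered).
#' @param resolution Louvain resolution parameter (calibrated default 1).
#' @return The ensemble with `cluster` and `is_center` filled in, and a
#'   `summary` field: `n_clusters`, `centers`, `rmsd_stats`, `method`.
#' @export
cluster_ensemble <- function(ens, threshold_count = 50, resolution = 1) {
  n <- length(ens$coords)
  heavy <- which(ens$molecule$atoms$element != "H")
  if (n <= threshold_count) {
    ens$cluster <- seq_len(n)
    ens$is_center <- rep(TRUE, n)
    ens$summary <- list(n_clusters = n, centers = seq_len(n),
                        rmsd_stats = NULL, method = "pass-through")
    return(ens)
  }
  D <- .rmsd_matrix(lapply(ens$coords, function(x) x[heavy, , drop = FALSE]))
  off <- D[upper.tri(D)]
  # local bandwidth: lower-quartile pairwise RMSD, so that well-separated
  # conformer families do not inflate the affinity scale
  bw <- stats::quantile(off, 0.25, names = FALSE)
  if (bw <= 0) bw <- 1e-3
  W <- exp(-D^2 / (2 * bw^2))
  diag(W) <- 0
  W[W < 0.01] <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  memb <- withr_seed(20240601, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  memb <- as.integer(memb)
  centers <- vapply(sort(unique(memb)), function(cl) {
    members <- which(memb == cl)
    members[which.min(ens$energy[members])]
  }, integer(1))
  ens$cluster <- memb
  ens$is_center <- seq_len(n) %in% centers
  ens$summary <- list(n_clusters = length(centers), centers = centers,
                      rmsd_stats = c(min = min(off), median = bw, max = max(off)),
                      method = "louvain-gaussian-affinity")
  ens
}

## evaluate expr under a fixed RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Extract a conformer as a molecule
#' @param ens a `glyccs_ensemble`.
#' @param i conformer index.
#' @return A [molecule()] with that conformer's coordinates.
#' @export
ensemble_molecule <- function(ens, i) {
  m <- ens$molecule
  coords(m) <- ens$coords[[i]]
  m
}

#' Write an ensemble as a multi-record SDF
#'
#' One record per conformer with properties `CONF_ID`, `ENERGY`, `RE`,
#' `CLUSTER`, `IS_CENTER`.
#'
#' @param ens a `glyccs_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  mols <- lapply(seq_along(ens$coords), function(i) ensemble_molecule(ens, i))
  props <- lapply(seq_along(mols), function(i) {
    list(CONF_ID = as.character(i),
         ENERGY = sprintf("%.6f", ens$energy[i]),
         RE = sprintf("%.6f", ens$re[i]),
         CLUSTER = as.character(ens$cluster[i]),
         IS_CENTER = as.character(ens$is_center[i]))
  })
  write_sdf_multi(mols, path, props)
}
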