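## Surrogate energy backend.
##
## The pipeline's contract with its energy provider is: single-point
## energy, locally relaxed geometry, and per-atom partial charges, all
## deterministic for a fixed input.  The built-in backend is a classical
## surrogate potential -- harmonic bonds and angles with generic
## element-pair constants, threefold cosine torsions, 12-6 van der Waals
## and Coulomb terms over charges from an electronegativity-equalisation
## (EEQ) scheme.  Only energy differences are meaningful; the zero point
## is backend-defined.

#' Electronegativity-equalisation partial charges
#'
#' Minimises sum(chi_i q_i) + 1/2 sum_ij A_ij q_i q_j subject to sum(q)
#' equal to the molecular net charge, with the shielded Coulomb kernel
#' A_ij = 332.0637 / sqrt(r_ij^2 + d_i d_j) and atomic shielding lengths
#' d_i = 332.0637 / (2 eta_i), so the diagonal equals twice the atomic
#' hardness (A_ii = 2 eta_i) and the interaction smoothly reaches the
#' bare Coulomb limit at long range.  Parameters are the Mulliken
#' electronegativities and hardnesses of [element_table()].  The
#' constraint is enforced exactly by a Lagrange multiplier, so the
#' charges sum to the net charge to machine precision.
#'
#' @param m a [molecule()].
#' @return Numeric vector of partial charges (e), one per atom.
#' @export
eeq_charges <- function(m) {
  n <- n_atoms(m)
  if (n == 1) return(as.numeric(m$net_charge))
  er <- element_row(m$atoms$element)
  chi <- er$chi_eV * EV_TO_KCAL
  eta <- er$eta_eV * EV_TO_KCAL
  d <- 332.0637 / (2 * eta)
  D <- as.matrix(stats::dist(coords(m)))
  A <- 332.0637 / sqrt(D^2 + outer(d, d))
  M <- rbind(cbind(A, rep(1, n)), c(rep(1, n), 0))
  rhs <- c(-chi, m$net_charge)
  sol <- solve(M, rhs)
  sol[seq_len(n)]
}

## assemble force-field parameter lists consumed by the C++ evaluator;
## 0-based indices for C++.
ff_params <- function(m, charges = NULL) {
  if (is.null(charges)) {
    charges <- if (!anyNA(m$atoms$partial_charge)) m$atoms$partial_charge
               else eeq_charges(m)
  }
  adj <- adjacency(m)
  er <- element_row(m$atoms$element)
  el <- m$atoms$element
  n <- n_atoms(m)

  # bonds: r0 = sum of covalent radii, k = 700 / r0 (stiffer short bonds)
  nb <- nrow(m$bonds)
  r0 <- er$r_cov[m$bonds$a1] + er$r_cov[m$bonds$a2]
  bond_ij <- cbind(m$bonds$a1, m$bonds$a2) - 1L
  bond_k <- if (nb) 700 / r0 else numeric()

  # angles at every atom with >= 2 neighbours
  ang <- list()
  has_double <- rep(FALSE, n)
  if (nb) {
    dd <- m$bonds[m$bonds$order >= 2, ]
    has_double[c(dd$a1, dd$a2)] <- TRUE
  }
  for (j in seq_len(n)) {
    nbj <- adj[[j]]
    if (length(nbj) < 2) next
    th0 <- if (has_double[j]) 120 else 109.47
    prs <- utils::combn(nbj, 2)
    for (c1 in seq_len(ncol(prs)))
      ang[[length(ang) + 1]] <- c(prs[1, c1], j, prs[2, c1], th0)
  }
  ang <- if (length(ang)) do.call(rbind, ang) else matrix(0, 0, 4)

  # torsions: one cosine term per (i, j-k, l) path over every bond
  tor <- list()
  for (b in seq_len(nb)) {
    j <- m$bonds$a1[b]; k <- m$bonds$a2[b]
    is <- setdiff(adj[[j]], k); ls <- setdiff(adj[[k]], j)
    if (length(is) == 0 || length(ls) == 0) next
    npath <- length(is) * length(ls)
    if (m$bonds$order[b] == 1) {
      kt <- 0.6 / npath; nn <- 3; dlt <- 0
    } else {
      kt <- 25 / npath; nn <- 2; dlt <- pi
    }
    for (i in is) for (l in ls) {
      if (i == l) next  # three-membered ring
      tor[[length(tor) + 1]] <- c(i, j, k, l, kt, nn, dlt)
    }
  }
  tor <- if (length(tor)) do.call(rbind, tor) else matrix(0, 0, 7)

  # nonbonded pairs: topological distance >= 3 bonds; 1-4 pairs scaled 0.5
  eps_el <- c(H = 0.020, C = 0.070, N = 0.070, O = 0.060, F = 0.050,
              P = 0.200, S = 0.250, Cl = 0.230)
  gd <- bond_distances(m)
  pair <- which(upper.tri(gd) & gd >= 3, arr.ind = TRUE)
  if (nrow(pair)) {
    i <- pair[, 1]; j <- pair[, 2]
    scale <- ifelse(gd[pair] == 3, 0.5, 1.0)
    sig <- (er$r_vdw[i] + er$r_vdw[j]) / 2^(1 / 6)
    eps <- sqrt(eps_el[el[i]] * eps_el[el[j]]) * scale
    qq <- charges[i] * charges[j] * scale
    nb_ij <- cbind(i, j) - 1L
  } else {
    nb_ij <- matrix(0L, 0, 2); eps <- sig <- qq <- numeric()
  }

  list(bond_ij = bond_ij, bond_k = bond_k, bond_r0 = if (nb) r0 else numeric(),
       ang_ijk = matrix(as.integer(ang[, 1:3, drop = FALSE] - 1L), ncol = 3),
       ang_k = rep(60, nrow(ang)), ang_th0 = ang[, 4] * pi / 180,
       tor_ijkl = matrix(as.integer(tor[, 1:4, drop = FALSE] - 1L), ncol = 4),
       tor_k = tor[, 5], tor_n = as.integer(tor[, 6]), tor_d = tor[, 7],
       nb_ij = nb_ij, nb_eps = unname(eps), nb_sig = unname(sig),
       nb_qq = unname(qq),
       charges = charges)
}

#' Surrogate single-point energy
#'
#' @param m a [molecule()].
#' @param params optional precomputed parameter list from the internal
#'   builder; recomputed from `m` when `NULL`.
#' @return Energy in kcal/mol (backend scale; only differences are
#'   meaningful).
#' @export
surrogate_energy <- function(m, params = NULL) {
  if (is.null(params)) params <- ff_params(m)
  .ff_energy_gradient(coords(m), params)$energy
}

#' Evaluate a charge model with the surrogate backend
#'
#' Relaxes the geometry by deterministic L-BFGS minimisation of the
#' surrogate potential from the input coordinates and reports the
#' minimised energy together with the partial charges used.  Charges
#' already stored on the molecule are reused; otherwise the EEQ scheme is
#' evaluated once at the input geometry and held fixed during the
#' relaxation, which makes re-evaluating an already-minimized structure
#' an exact fixed point.
#' Non-convergence (gradient above tolerance after `max_steps`) is flagged
#' on the result, not raised as an error; ranked selection excludes
#' flagged results with a warning.
#'
#' @param model a `glyccs_charge_model`, or a bare [molecule()].
#' @param max_steps maximum minimiser iterations.
#' @param grad_tol convergence threshold on the maximum gradient
#'   component, kcal/mol/Angstrom.
#' @return A `glyccs_energy_result`: `energy` (kcal/mol), `molecule`
#'   (relaxed geometry, partial charges filled in), `converged`,
#'   `grad_max`, `steps`, `backend`.
#' @export
evaluate_energy <- function(model, max_steps = 2000, grad_tol = 1e-4) {
  m <- if (inherits(model, "glyccs_charge_model")) model$molecule else model
  params <- ff_params(m)
  fit <- .ff_minimize(coords(m), params, as.integer(max_steps), grad_tol)
  m2 <- m
  coords(m2) <- fit$coords
  m2$atoms$partial_charge <- params$charges
  structure(list(energy = fit$energy, molecule = m2,
                 converged = isTRUE(fit$converged),
                 grad_max = fit$grad_max, steps = fit$steps,
                 backend = "surrogate",
                 model = if (inherits(model, "glyccs_charge_model")) model else NULL),
            class = "glyccs_energy_result")
}

#' @export
print.glyccs_energy_result <- function(x, ...) {
  cat(sprintf("<energy result> E = %.4f kcal/mol, %s after %d steps (max|g| = %.2e)\n",
              x$energy, if (x$converged) "converged" else "NOT converged",
              x$steps, x$grad_max))
  invisible(x)
}

#' Rank charge models by relative energy and retain a candidate window
#'
#' Computes relative energies RE_i = E_i - E_min against the converged
#' global minimum and retains every model with RE at or below the window
#' (boundary inclusive), mirroring the 10 kcal/mol relative-energy screen
#' applied after per-model relaxation.  Results are sorted ascending by
#' RE with ties broken by enumeration index; non-converged results are
#' excluded with a warning.
#'
#' @param results list of `glyccs_energy_result` objects.
#' @param window retention window in kcal/mol (default 10).
#' @return A `glyccs_candidate_set`: data frame `table` (`index`,
#'   `enum_label`, `energy`, `re`, `converged`, `retained`), `e_min`,
#'   `results` (sorted, converged results), `window`.
#' @export
rank_and_filter <- function(results, window = 10) {
  stopifnot(length(results) > 0)
  conv <- vapply(results, function(r) isTRUE(r$converged), logical(1))
  if (!any(conv)) stop("no converged energy results to rank", call. = FALSE)
  if (any(!conv))
    warning(sum(!conv), " non-converged result(s) excluded from ranking")
  en <- vapply(results, function(r) r$energy, numeric(1))
  idx <- vapply(results, function(r) {
    if (!is.null(r$model)) r$model$index else NA_integer_
  }, integer(1))
  if (anyNA(idx)) idx <- seq_along(results)
  lab <- vapply(results, function(r) {
    if (!is.null(r$model)) r$model$enum_label else NA_character_
  }, character(1))
  lab[is.na(lab)] <- as.character(idx[is.na(lab)])
  e_min <- min(en[conv])
  re <- en - e_min
  tab <- data.frame(index = idx, enum_label = lab, energy = en, re = re,
                    converged = conv,
                    retained = conv & re <= window)
  ord <- order(!tab$converged, tab$re, tab$index)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab, e_min = e_min,
                 results = results[ord][tab$converged],
                 window = window),
            class = "glyccs_candidate_set")
}

#' @export
print.glyccs_candidate_set <- function(x, ...) {
  cat(sprintf("<candidate set> %d models, window %.1f kcal/mol, %d retained\n",
              nrow(x$table), x$window, sum(x$table$retained)))
  print(x$table, digits = 4)
  invisible(x)
}
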