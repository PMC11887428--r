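# Independent oracles used by the tests.  Each is written against the
# definition of the quantity, not against the package's implementation.

extdata <- function(name) {
  system.file("extdata", name, package = "glyccs", mustWork = TRUE)
}

# Neufeld-Janzen-Aziz correlation for the reduced Lennard-Jones collision
# integral Omega*(1,1)(T*) (accurate to ~0.1% over 0.3 <= T* <= 100)
omega11_star_lj <- function(Tstar) {
  1.06036 / Tstar^0.15610 + 0.19300 * exp(-0.47635 * Tstar) +
    1.03587 * exp(-1.52996 * Tstar) + 1.76474 * exp(-3.89411 * Tstar)
}

# brute-force rotatable-bond oracle: enumerates bonds and applies the rule
# (single, acyclic, both endpoints multivalent, no symmetric-top rotor)
# using adjacency-matrix reachability instead of the package's graph code
oracle_rotatable_count <- function(m) {
  n <- n_atoms(m)
  A <- matrix(0L, n, n)
  for (b in seq_len(nrow(m$bonds))) {
    A[m$bonds$a1[b], m$bonds$a2[b]] <- 1L
    A[m$bonds$a2[b], m$bonds$a1[b]] <- 1L
  }
  deg <- rowSums(A)
  reachable <- function(A, from, to) {
    seen <- rep(FALSE, nrow(A)); seen[from] <- TRUE
    front <- from
    while (length(front) > 0) {
      nxt <- which(colSums(A[front, , drop = FALSE]) > 0 & !seen)
      if (to %in% nxt) return(TRUE)
      seen[nxt] <- TRUE
      front <- nxt
    }
    FALSE
  }
  cnt <- 0
  for (b in seq_len(nrow(m$bonds))) {
    i <- m$bonds$a1[b]; j <- m$bonds$a2[b]
    if (m$bonds$order[b] != 1) next
    if (deg[i] < 2 || deg[j] < 2) next
    A2 <- A; A2[i, j] <- A2[j, i] <- 0L
    if (reachable(A2, i, j)) next  # ring bond
    sym_top <- function(ctr, other) {
      rest <- setdiff(which(A[ctr, ] == 1L), other)
      length(rest) >= 2 && all(deg[rest] == 1) &&
        length(unique(m$atoms$element[rest])) == 1
    }
    if (sym_top(i, j) || sym_top(j, i)) next
    cnt <- cnt + 1
  }
  cnt
}

# dense-grid rasterization oracle for the projected area of a union of
# disks, averaged over a fixed set of orientations
oracle_projected_area <- function(coords, radii, n_orient = 400,
                                  grid = 0.02, seed = 1234) {
  set.seed(seed)
  areas <- numeric(n_orient)
  for (o in seq_len(n_orient)) {
    # uniform random rotation via QR of a Gaussian matrix
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    P <- coords %*% t(q)
    xs <- seq(min(P[, 1] - radii), max(P[, 1] + radii), by = grid)
    ys <- seq(min(P[, 2] - radii), max(P[, 2] + radii), by = grid)
    gx <- rep(xs, times = length(ys))
    gy <- rep(ys, each = length(xs))
    inside <- rep(FALSE, length(gx))
    for (i in seq_len(nrow(P)))
      inside <- inside | ((gx - P[i, 1])^2 + (gy - P[i, 2])^2 <= radii[i]^2)
    areas[o] <- sum(inside) * grid^2
  }
  mean(areas)
}

# rotation-grid RMSD oracle: Euler-angle grid search, coarse-to-fine
oracle_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rmsd_at <- function(al, be, ga) {
    Rz1 <- matrix(c(cos(al), -sin(al), 0, sin(al), cos(al), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(be), 0, sin(be), 0, 1, 0, -sin(be), 0, cos(be)), 3, 3)
    Rz2 <- matrix(c(cos(ga), -sin(ga), 0, sin(ga), cos(ga), 0, 0, 0, 1), 3, 3)
    d <- ac %*% (Rz1 %*% Ry %*% Rz2) - bc
    sqrt(mean(rowSums(d^2)))
  }
  search <- function(c0, width, step) {
    best <- c(Inf, 0, 0, 0)
    for (al in seq(c0[1] - width, c0[1] + width, by = step))
      for (be in seq(c0[2] - width, c0[2] + width, by = step))
        for (ga in seq(c0[3] - width, c0[3] + width, by = step)) {
          v <- rmsd_at(al, be, ga)
          if (v < best[1]) best <- c(v, al, be, ga)
        }
    best
  }
  b0 <- search(c(pi, pi / 2, pi), pi, 12 * pi / 180)
  b1 <- search(b0[2:4], 12 * pi / 180, 1 * pi / 180)
  b2 <- search(b1[2:4], 1 * pi / 180, 0.05 * pi / 180)
  b2[1]
}

# minimal stand-in energy results for rank_and_filter tests
fake_energy_results <- function(energies, converged = rep(TRUE, length(energies))) {
  lapply(seq_along(energies), function(i) {
    structure(list(energy = energies[i], converged = converged[i],
                   molecule = NULL, grad_max = 0, steps = 0,
                   backend = "fake",
                   model = list(index = i, enum_label = as.character(i),
                                site = list(atom = i, class = "hydroxyl_O"))),
              class = "glyccs_energy_result")
  })
}
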