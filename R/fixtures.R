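#' Deterministic toy-molecule fixtures
#'
#' Small synthetic molecules for tests, benchmarks and pipeline smoke
#' runs.  All geometries are constructed analytically and are identical
#' for a given spec; none is a real compound's refined structure.
#'
#' Families:
#' * `"single_sphere"`: one carbon atom -- its projection-approximation
#'   CCS is analytic, `pi (r_vdw + probe)^2`;
#' * `"dumbbell"`: two carbons at separation `size` (default 2.0 A);
#' * `"alkane"`: an n-carbon chain (default `size = 4`) with idealized
#'   zigzag geometry and explicit hydrogens;
#' * `"rigid_ring"`: chair cyclohexane -- no rotatable bonds;
#' * `"disaccharide_like"`: two oxane (tetrahydropyran) rings joined by
#'   a C-O-C bridge, one hydroxyl on each ring: a minimal stand-in with
#'   glycosidic phi/psi torsions and at least two titratable sites.
#'
#' @param family fixture family name.
#' @param size family-specific size parameter (atom count or separation).
#' @return A [molecule()].
#' @export
make_fixture <- function(family = c("single_sphere", "dumbbell", "alkane",
                                    "rigid_ring", "disaccharide_like"),
                         size = NULL) {
  if (!is.character(family) || !family[1] %in%
      c("single_sphere", "dumbbell", "alkane", "rigid_ring",
        "disaccharide_like"))
    stop("unknown fixture family '", family[1], "'; families: ",
         "single_sphere, dumbbell, alkane, rigid_ring, disaccharide_like",
         call. = FALSE)
  family <- family[1]
  switch(family,
         single_sphere = molecule(
           data.frame(element = "C", x = 0, y = 0, z = 0),
           label = "single_sphere"),
         dumbbell = {
           d <- if (is.null(size)) 2.0 else size
           molecule(data.frame(element = c("C", "C"),
                               x = c(0, d), y = 0, z = 0),
                    data.frame(a1 = 1, a2 = 2, order = 1),
                    label = "dumbbell")
         },
         alkane = fixture_alkane(if (is.null(size)) 4 else size),
         rigid_ring = fixture_ring(substituents = list()),
         disaccharide_like = fixture_disaccharide())
}

fixture_alkane <- function(n) {
  stopifnot(n >= 1)
  # zigzag backbone in the xz plane, 1.54 A bonds, 111 degree angles
  ang <- 111 * pi / 180
  dx <- 1.54 * sin(ang / 2); dz <- 1.54 * cos(ang / 2)
  cx <- (seq_len(n) - 1) * dx
  cz <- rep(c(0, dz), length.out = n)
  atoms <- data.frame(element = rep("C", n), x = cx, y = 0, z = cz)
  bonds <- if (n > 1) data.frame(a1 = 1:(n - 1), a2 = 2:n, order = 1) else NULL
  # hydrogens: fill each carbon to 4 bonds, alternating +/- y and z
  for (i in seq_len(n)) {
    need <- 4 - sum(bonds$a1 == i | bonds$a2 == i)
    zsgn <- if (cz[i] > 0) 1 else -1
    xdir <- if (i == 1) -1 else 1   # terminal in-plane H points off-chain
    dirs <- list(c(0, 0.82, 0.57 * zsgn), c(0, -0.82, 0.57 * zsgn),
                 c(xdir * 0.94, 0, 0.34 * zsgn), c(0, 0, zsgn))
    for (k in seq_len(need)) {
      d <- dirs[[k]] / sqrt(sum(dirs[[k]]^2))
      atoms <- rbind(atoms, data.frame(element = "H",
                                       x = cx[i] + 1.09 * d[1],
                                       y = 0 + 1.09 * d[2],
                                       z = cz[i] + 1.09 * d[3]))
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = nrow(atoms), order = 1))
    }
  }
  molecule(atoms, bonds, label = sprintf("alkane_C%d", n))
}

## chair six-ring template; hetero[i] = "O" drops that position's hydrogens.
## substituents: list(ring_index = list(element-chain)) is handled by the
## disaccharide builder directly; here we only emit ring + H.
fixture_ring <- function(hetero = rep("C", 6), substituents = list(),
                         label = "rigid_ring") {
  a <- 1.455; h <- 0.25
  th <- (0:5) * pi / 3
  pos <- cbind(a * cos(th), a * sin(th), h * rep(c(1, -1), 3))
  atoms <- data.frame(element = hetero, x = pos[, 1], y = pos[, 2],
                      z = pos[, 3])
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 1)
  for (i in 1:6) {
    if (hetero[i] == "O") next
    zs <- if (pos[i, 3] > 0) 1 else -1
    ax <- c(0, 0, zs)                                   # axial
    eq <- c(cos(th[i]), sin(th[i]), -0.45 * zs)         # equatorial
    eq <- eq / sqrt(sum(eq^2))
    for (d in list(ax, eq)) {
      atoms <- rbind(atoms, data.frame(element = "H",
                                       x = pos[i, 1] + 1.09 * d[1],
                                       y = pos[i, 2] + 1.09 * d[2],
                                       z = pos[i, 3] + 1.09 * d[3]))
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = nrow(atoms), order = 1))
    }
  }
  molecule(atoms, bonds, label = label)
}

## replace hydrogen `h` of atom `i` with a new atom `el` at distance `len`
## along the old C-H direction; returns updated atoms/bonds and new index
swap_h_for <- function(atoms, bonds, i, el, len) {
  hs <- bonds[(bonds$a1 == i | bonds$a2 == i), ]
  hs <- setdiff(c(hs$a1, hs$a2), i)
  hs <- hs[atoms$element[hs] == "H"]
  stopifnot(length(hs) >= 1)
  h <- hs[1]
  dir <- as.numeric(atoms[h, c("x", "y", "z")] - atoms[i, c("x", "y", "z")])
  dir <- dir / sqrt(sum(dir^2))
  newpos <- as.numeric(atoms[i, c("x", "y", "z")]) + len * dir
  atoms[h, c("x", "y", "z")] <- as.list(newpos)
  atoms$element[h] <- el
  list(atoms = atoms, bonds = bonds, idx = h, dir = dir)
}

fixture_disaccharide <- function() {
  mk <- function() {
    m <- fixture_ring(hetero = c("O", rep("C", 5)), label = "oxane")
    list(atoms = m$atoms, bonds = m$bonds)
  }
  ra <- mk()
  # hydroxyl on ring-A carbon 4 (para-ish to the ring O)
  s <- swap_h_for(ra$atoms, ra$bonds, 4, "O", 1.43)
  oh_dir <- s$dir
  opos <- as.numeric(s$atoms[s$idx, c("x", "y", "z")])
  s$atoms <- rbind(s$atoms, data.frame(element = "H",
                                       x = opos[1] + 0.96 * oh_dir[1],
                                       y = opos[2] + 0.96 * oh_dir[2],
                                       z = opos[3] + 0.96 * oh_dir[3],
                                       formal_charge = 0L,
                                       partial_charge = NA_real_))
  s$bonds <- rbind(s$bonds, data.frame(a1 = s$idx, a2 = nrow(s$atoms),
                                       order = 1))
  ra <- s
  # glycosidic oxygen off ring-A carbon 2 (the anomeric-like position)
  s <- swap_h_for(ra$atoms, ra$bonds, 2, "O", 1.43)
  og <- s$idx; og_dir <- s$dir
  ra <- s
  na <- nrow(ra$atoms)

  rb <- mk()
  # hydroxyl on ring-B carbon 4
  s <- swap_h_for(rb$atoms, rb$bonds, 4, "O", 1.43)
  opos <- as.numeric(s$atoms[s$idx, c("x", "y", "z")])
  dirb <- s$dir
  s$atoms <- rbind(s$atoms, data.frame(element = "H",
                                       x = opos[1] + 0.96 * dirb[1],
                                       y = opos[2] + 0.96 * dirb[2],
                                       z = opos[3] + 0.96 * dirb[3],
                                       formal_charge = 0L,
                                       partial_charge = NA_real_))
  s$bonds <- rbind(s$bonds, data.frame(a1 = s$idx, a2 = nrow(s$atoms),
                                       order = 1))
  rb <- s
  # drop one H from ring-B carbon 2; that carbon bonds to the bridge O
  hs <- rb$bonds[(rb$bonds$a1 == 2 | rb$bonds$a2 == 2), ]
  hs <- setdiff(c(hs$a1, hs$a2), 2)
  hs <- hs[rb$atoms$element[hs] == "H"][1]
  rb$atoms <- rb$atoms[-hs, , drop = FALSE]
  rb$bonds <- rb$bonds[!(rb$bonds$a1 == hs | rb$bonds$a2 == hs), ]
  rb$bonds$a1 <- rb$bonds$a1 - (rb$bonds$a1 > hs)
  rb$bonds$a2 <- rb$bonds$a2 - (rb$bonds$a2 > hs)

  # place ring B: its C2 sits 1.43 A beyond the bridge O, continuing the
  # C2(A) -> O direction; ring B is pushed further along the same axis
  og_pos <- as.numeric(ra$atoms[og, c("x", "y", "z")])
  target_c2b <- og_pos + 1.43 * og_dir
  shift <- target_c2b - as.numeric(rb$atoms[2, c("x", "y", "z")])
  # reflect ring B through the bridge point so it extends away from ring A
  Xb <- as.matrix(rb$atoms[, c("x", "y", "z")])
  Xb <- -(Xb - matrix(as.numeric(rb$atoms[2, c("x", "y", "z")]),
                      nrow(Xb), 3, byrow = TRUE))
  Xb <- Xb + matrix(target_c2b, nrow(Xb), 3, byrow = TRUE)
  rb$atoms$x <- Xb[, 1]; rb$atoms$y <- Xb[, 2]; rb$atoms$z <- Xb[, 3]

  atoms <- rbind(ra$atoms, rb$atoms)
  bonds <- rbind(ra$bonds,
                 data.frame(a1 = rb$bonds$a1 + na, a2 = rb$bonds$a2 + na,
                            order = rb$bonds$order),
                 data.frame(a1 = og, a2 = 2 + na, order = 1))
  molecule(atoms, bonds, label = "disaccharide_like")
}
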