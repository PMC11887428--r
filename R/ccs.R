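#' Buffer-gas model
#'
#' The buffer gas is treated as a single-site isotropic pseudo-atom with
#' an effective mass, a dipole polarizability, a per-element table of 12-6
#' Lennard-Jones parameters for the solute-gas interaction, and a
#' hard-sphere probe radius for the projection approximation.  The
#' default nitrogen parametrization uses alpha = 1.710 A^3 and LJ well
#' depths/diameters of the magnitude used by nitrogen-buffer trajectory
#' parametrizations for H/C/N/O; the table is the package's declared
#' compatibility surface and every entry can be overridden.  The
#' quadrupole moment of N2 and orientation-dependent anisotropy are
#' outside the single-site model (see the vignette).
#'
#' @param species `"n2"` (the only built-in).
#' @param probe_radius hard-sphere probe radius for the projection
#'   approximation, Angstrom.
#' @param lj optional replacement LJ table: data frame with `element`,
#'   `eps` (kcal/mol), `sigma` (Angstrom).
#' @return A `glyccs_gas` list: `species`, `mass` (Da), `alpha` (A^3),
#'   `lj`, `probe_radius`.
#' @export
gas_model <- function(species = "n2", probe_radius = 1.5, lj = NULL) {
  species <- match.arg(species)
  if (is.null(lj)) {
    lj <- data.frame(
      element = c("H", "C", "N", "O", "F", "P", "S", "Cl"),
      eps = c(0.0309, 0.1072, 0.1183, 0.1259, 0.110, 0.220, 0.260, 0.250),
      sigma = c(2.22, 3.50, 3.32, 3.25, 3.15, 3.70, 3.65, 3.60))
  }
  structure(list(species = species, mass = 28.0134, alpha = 1.710,
                 lj = lj, probe_radius = probe_radius),
            class = "glyccs_gas")
}

gas_lj_for <- function(gas, elements) {
  idx <- match(elements, gas$lj$element)
  if (anyNA(idx))
    stop("no gas-interaction parameters for element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "), call. = FALSE)
  gas$lj[idx, c("eps", "sigma")]
}

#' Trajectory-method settings
#'
#' Defaults follow the standard high-performance trajectory-method
#' parameter set: 10 complete cycles, 20 velocity-integration points,
#' 500 impact-parameter Monte-Carlo integrations per velocity point,
#' 1000 rotations, 298 K.  The velocity integration is implemented as
#' Gauss-Legendre quadrature on the transformed Maxwell-Boltzmann
#' integrand with the stated number of nodes.
#'
#' @param cycles complete independent cycles (standard error comes from
#'   their spread).
#' @param vel_points velocity quadrature nodes.
#' @param mc_points impact-parameter Monte-Carlo samples per node.
#' @param orientations rotation count; used to scale the deterministic
#'   orientation sample of the impact-parameter calibration.
#' @param temperature simulation temperature, K.
#' @param max_steps per-trajectory integration step cap.
#' @return A `glyccs_tm_settings` list.
#' @export
tm_settings <- function(cycles = 10, vel_points = 20, mc_points = 500,
                        orientations = 1000, temperature = 298,
                        max_steps = 100000) {
  stopifnot(cycles >= 1, vel_points >= 1, mc_points >= 1,
            orientations >= 1, temperature > 0)
  structure(list(cycles = as.integer(cycles),
                 vel_points = as.integer(vel_points),
                 mc_points = as.integer(mc_points),
                 orientations = as.integer(orientations),
                 temperature = temperature,
                 max_steps = as.integer(max_steps)),
            class = "glyccs_tm_settings")
}

#' Projection-approximation CCS
#'
#' Monte-Carlo average, over uniformly random orientations, of the
#' projected area of the union of atom-centred disks of radius
#' (van der Waals radius + probe radius).  A fast lower-fidelity screen
#' next to the trajectory method.
#'
#' @param m a [molecule()].
#' @param gas a [gas_model()].
#' @param n_orientations Monte-Carlo orientations.
#' @param seed RNG seed (fixed seed gives bit-identical results).
#' @param n_darts area-sampling points per orientation.
#' @return A `glyccs_ccs` result: `omega` (A^2), `stderr` (A^2, over
#'   orientations), `method = "PA"`, `settings`.
#' @export
pa_ccs <- function(m, gas = gas_model(), n_orientations = 1000, seed = 1,
                   n_darts = 256) {
  stopifnot(all(is.finite(coords(m))))
  radii <- element_row(m$atoms$element)$r_vdw + gas$probe_radius
  set.seed(seed)
  r <- .pa_ccs(coords(m), radii, as.integer(n_orientations),
               as.integer(n_darts))
  structure(list(omega = r$omega, stderr = r$stderr, method = "PA",
                 settings = list(n_orientations = n_orientations,
                                 n_darts = n_darts, seed = seed,
                                 probe_radius = gas$probe_radius),
                 label = m$label, n_failed = 0L),
            class = "glyccs_ccs")
}

#' Trajectory-method CCS
#'
#' Momentum-transfer collision integral Omega(1,1) at temperature T:
#' Maxwell-Boltzmann average over relative speed (Gauss-Legendre
#' quadrature), uniform average over orientations, and impact-parameter
#' Monte-Carlo integration of (1 - cos chi) 2 pi b db, with the
#' deflection angle chi obtained from classical trajectories in the
#' solute-gas potential
#' V = sum_i 4 eps_i \[(sig_i/r_i)^12 - (sig_i/r_i)^6\] - (alpha/2)|E|^2,
#' where E is the electric field of the solute partial charges at the gas
#' position.  The impact-parameter upper bound is chosen adaptively per
#' velocity node so the deflection at b_max falls below 1e-3 rad;
#' trajectories are integrated by adaptive-step velocity Verlet with a
#' relative energy-conservation tolerance of 1e-4 (failing trajectories
#' are excluded, counted, and reported).
#'
#' @param m a [molecule()] with partial charges present (use
#'   [evaluate_energy()] or [eeq_charges()] first), or a neutral molecule
#'   with all-zero charges.
#' @param gas a [gas_model()].
#' @param settings a [tm_settings()].
#' @param seed RNG seed.
#' @return A `glyccs_ccs` result: `omega` (A^2), `stderr` (A^2, standard
#'   error over cycles), `method = "TM"`, `settings`, `n_failed`.
#' @export
tm_ccs <- function(m, gas = gas_model(), settings = tm_settings(), seed = 1) {
  pc <- m$atoms$partial_charge
  if (all(is.na(pc))) {
    if (m$net_charge != 0)
      stop("charged molecule without partial charges; run evaluate_energy() ",
           "or eeq_charges() first", call. = FALSE)
    pc <- rep(0, n_atoms(m))
  }
  lj <- gas_lj_for(gas, m$atoms$element)
  kT <- 1.987204e-3 * settings$temperature
  mu <- gas$mass * monoisotopic_mass(m) / (gas$mass + monoisotopic_mass(m))
  gl <- pracma::gaussLegendre(settings$vel_points, 0, 1)
  set.seed(seed)
  r <- .tm_ccs(coords(m), lj$eps, lj$sigma, pc, gas$alpha, mu, kT,
               settings$cycles, gl$x, gl$w, settings$mc_points,
               settings$orientations, settings$max_steps)
  structure(list(omega = r$omega, stderr = r$stderr, method = "TM",
                 omega_cycles = as.numeric(r$omega_cycles),
                 n_failed = r$n_failed, b_max = as.numeric(r$b_max),
                 settings = c(unclass(settings), list(seed = seed)),
                 label = m$label),
            class = "glyccs_ccs")
}

#' @export
print.glyccs_ccs <- function(x, ...) {
  cat(sprintf("<ccs %s> Omega = %.2f +/- %.2f A^2 (%s)%s\n", x$method,
              x$omega, x$stderr, x$label,
              if (x$n_failed > 0) sprintf(" [%d failed trajectories]",
                                          x$n_failed) else ""))
  invisible(x)
}

#' Mason-Schamp conversion between reduced mobility and CCS
#'
#' Standard low-field Mason-Schamp relation,
#' Omega = (3 z e)/(16 N0 K0) sqrt(2 pi / (mu kB T)),
#' with mu the reduced mass of ion and buffer gas and N0 the Loschmidt
#' number density.  `ccs_to_mobility()` is the exact inverse.
#'
#' @param K0 reduced mobility, cm^2 V^-1 s^-1.
#' @param ion_mass ion mass, Da.
#' @param gas a [gas_model()].
#' @param temperature temperature, K.
#' @param z charge state (positive integer).
#' @return CCS in A^2.
#' @export
mason_schamp <- function(K0, ion_mass, gas = gas_model(), temperature = 298,
                         z = 1) {
  stopifnot(K0 > 0, ion_mass > 0, temperature > 0, z >= 1)
  e <- 1.602176634e-19            # C
  kB <- 1.380649e-23              # J/K
  N0 <- 2.6867811e25              # m^-3
  amu <- 1.66053907e-27           # kg
  mu <- ion_mass * gas$mass / (ion_mass + gas$mass) * amu
  K <- K0 * 1e-4                  # m^2/Vs
  omega_m2 <- 3 * z * e / (16 * N0 * K) * sqrt(2 * pi / (mu * kB * temperature))
  omega_m2 * 1e20
}

#' @rdname mason_schamp
#' @param omega CCS in A^2.
#' @return `ccs_to_mobility()`: reduced mobility in cm^2 V^-1 s^-1.
#' @export
ccs_to_mobility <- function(omega, ion_mass, gas = gas_model(),
                            temperature = 298, z = 1) {
  stopifnot(omega > 0, ion_mass > 0, temperature > 0, z >= 1)
  e <- 1.602176634e-19
  kB <- 1.380649e-23
  N0 <- 2.6867811e25
  amu <- 1.66053907e-27
  mu <- ion_mass * gas$mass / (ion_mass + gas$mass) * amu
  omega_m2 <- omega * 1e-20
  K <- 3 * z * e / (16 * N0 * omega_m2) * sqrt(2 * pi / (mu * kB * temperature))
  K * 1e4
}
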