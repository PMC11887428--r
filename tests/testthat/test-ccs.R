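test_that("projection approximation reproduces analytic disk areas", {
  sph <- make_fixture("single_sphere")
  gas <- gas_model(probe_radius = 1.5)
  r <- pa_ccs(sph, gas, n_orientations = 2000, seed = 1)
  analytic <- pi * (1.70 + 1.5)^2          # C vdW radius + probe
  expect_equal(r$omega, analytic, tolerance = 5e-3)

  # two coincident spheres project like one
  twin <- molecule(data.frame(element = c("C", "C"), x = 0, y = 0, z = 0),
                   perceive_stereo = FALSE)
  r2 <- pa_ccs(twin, gas, n_orientations = 2000, seed = 2)
  expect_equal(r2$omega, analytic, tolerance = 5e-3)
})

test_that("projection approximation matches a grid-rasterization oracle", {
  db <- make_fixture("dumbbell", 2.0)
  gas <- gas_model(probe_radius = 1.0)
  radii <- rep(1.5 + 1.0, 2)
  r <- pa_ccs(db, gas = gas_model(probe_radius = 1.0),
              n_orientations = 4000, seed = 3)
  # the dumbbell uses carbon vdW 1.70; build the oracle on the same disks
  oracle <- oracle_projected_area(coords(db), rep(1.70 + 1.0, 2),
                                  n_orient = 1200, grid = 0.02)
  expect_equal(r$omega, oracle, tolerance = 5e-3)
})

test_that("PA omega never shrinks when atoms are added", {
  gas <- gas_model()
  grow <- lapply(1:4, function(n) {
    molecule(data.frame(element = rep("C", n),
                        x = 1.8 * (seq_len(n) - 1), y = 0, z = 0),
             perceive_stereo = FALSE)
  })
  om <- vapply(grow, function(m) pa_ccs(m, gas, 1500, seed = 5)$omega, 0)
  expect_true(all(diff(om) > -0.5))  # monotone within MC noise
  expect_gt(om[4], om[1])
})

test_that("fixed seeds give bit-identical CCS for both methods", {
  db <- make_fixture("dumbbell")
  expect_identical(pa_ccs(db, n_orientations = 500, seed = 9)$omega,
                   pa_ccs(db, n_orientations = 500, seed = 9)$omega)
  st <- tm_settings(cycles = 2, vel_points = 5, mc_points = 20)
  expect_identical(tm_ccs(db, settings = st, seed = 9)$omega,
                   tm_ccs(db, settings = st, seed = 9)$omega)
})

test_that("TM standard error shrinks roughly as 1/sqrt(cycles)", {
  sph <- make_fixture("single_sphere")
  st <- function(cy) tm_settings(cycles = cy, vel_points = 5, mc_points = 30)
  se <- vapply(c(2, 8, 32), function(cy)
    tm_ccs(sph, settings = st(cy), seed = 4)$stderr, 0)
  # ratio over a 16-fold cycle increase should be ~4, allow 2x slack
  expect_gt(se[1] / se[3], 2)
  expect_lt(se[1] / se[3], 8)
})

test_that("an ion's induced-dipole attraction enlarges its TM cross section", {
  g <- read_structure(extdata("beta_d_glucose.sdf"))
  cm <- enumerate_charge_models(g, "neg")[[1]]
  er <- evaluate_energy(cm)
  charged <- er$molecule
  neutral <- charged
  neutral$atoms$partial_charge <- rep(0, n_atoms(neutral))
  neutral$atoms$formal_charge <- rep(0L, n_atoms(neutral))
  neutral$net_charge <- 0L
  st <- tm_settings(cycles = 2, vel_points = 8, mc_points = 40)
  oc <- tm_ccs(charged, settings = st, seed = 21)
  on <- tm_ccs(neutral, settings = st, seed = 21)
  expect_gt(oc$omega, on$omega)
})

test_that("Mason-Schamp conversion round-trips and scales with charge", {
  gas <- gas_model()
  K0 <- 1.0
  om <- mason_schamp(K0, ion_mass = 500, gas = gas)
  expect_equal(ccs_to_mobility(om, ion_mass = 500, gas = gas), K0,
               tolerance = 1e-9)
  expect_equal(mason_schamp(K0, 500, gas, z = 2), 2 * om, tolerance = 1e-12)

  # literal one-line evaluation of the low-field formula
  e <- 1.602176634e-19; kB <- 1.380649e-23; N0 <- 2.6867811e25
  amu <- 1.66053907e-27
  mu <- 500 * 28.0134 / (500 + 28.0134) * amu
  lit <- 3 * e / (16 * N0 * 1e-4) * sqrt(2 * pi / (mu * kB * 298)) * 1e20
  expect_equal(om, lit, tolerance = 1e-12)

  expect_error(mason_schamp(-1, 500), "K0")
})

test_that("missing gas parameters for an element raise an error", {
  m <- molecule(data.frame(element = "P", x = 0, y = 0, z = 0))
  gas <- gas_model(lj = data.frame(element = c("H", "C"), eps = c(0.03, 0.1),
                                   sigma = c(2.2, 3.5)))
  m$atoms$partial_charge <- 0
  expect_error(tm_ccs(m, gas), "P")
})
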