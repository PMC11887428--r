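test_that("monoisotopic masses match isotope-table sums", {
  water <- molecule(data.frame(element = c("O", "H", "H"),
                               x = c(0, 0.96, -0.24), y = c(0, 0, 0.93),
                               z = 0),
                    data.frame(a1 = c(1, 1), a2 = c(2, 3), order = 1))
  expect_equal(monoisotopic_mass(water), 18.0106, tolerance = 1e-4)

  glc <- read_structure(extdata("beta_d_glucose.sdf"))
  expect_equal(monoisotopic_mass(glc), 180.0634, tolerance = 1e-4)

  empty <- molecule(data.frame(element = character(), x = numeric(),
                               y = numeric(), z = numeric()))
  expect_identical(monoisotopic_mass(empty), 0)

  # additivity over disconnected components: two waters, no bonds between
  two <- molecule(data.frame(element = rep(c("O", "H", "H"), 2),
                             x = c(0, 0.96, -0.24, 10, 10.96, 9.76),
                             y = c(0, 0, 0.93, 0, 0, 0.93), z = 0),
                  data.frame(a1 = c(1, 1, 4, 4), a2 = c(2, 3, 5, 6)))
  expect_equal(monoisotopic_mass(two), 2 * monoisotopic_mass(water))
})

test_that("glucose SDF parses to the expected structure", {
  g <- read_structure(extdata("beta_d_glucose.sdf"))
  expect_equal(n_atoms(g), 24)
  expect_equal(nrow(g$bonds), 24)
  expect_equal(g$net_charge, 0)
  expect_equal(molecular_formula(g), "C6H12O6")
  expect_equal(sum(g$atoms$element == "H"), 12)  # explicit H preserved
})

test_that("structure files round-trip through every format", {
  g <- read_structure(extdata("beta_d_glucose.sdf"))
  g$atoms$formal_charge[4] <- -1L
  g$net_charge <- -1L
  g$atoms$partial_charge <- eeq_charges(g)

  withr::with_tempdir({
    write_structure(g, "m.sdf")
    r <- read_structure("m.sdf")
    expect_identical(r$atoms$element, g$atoms$element)
    expect_identical(r$bonds, g$bonds)
    expect_identical(r$atoms$formal_charge, g$atoms$formal_charge)
    expect_lt(max(abs(coords(r) - coords(g))), 1e-4)
    expect_lt(max(abs(r$atoms$partial_charge - g$atoms$partial_charge)), 1e-5)

    write_structure(g, "m.xyz")
    rx <- read_structure("m.xyz")
    expect_identical(rx$atoms$element, g$atoms$element)
    expect_identical(rx$atoms$formal_charge, g$atoms$formal_charge)
    expect_lt(max(abs(coords(rx) - coords(g))), 1e-4)

    write_structure(g, "m.pdb")
    rp <- read_structure("m.pdb")
    expect_identical(toupper(rp$atoms$element), toupper(g$atoms$element))
    expect_lt(max(abs(coords(rp) - coords(g))), 1e-3)  # fixed-width precision
    # perceived bonds recover the true connectivity
    key <- function(b) sort(paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2)))
    expect_setequal(key(rp$bonds), key(g$bonds))
  })
})

test_that("malformed and unknown-element inputs error, not skip", {
  withr::with_tempdir({
    writeLines(c("junk", "", "", "  x  y junk counts line"), "bad.sdf")
    expect_error(read_structure("bad.sdf"), "parse error")

    writeLines(c(
      "HETATM    1 XX   LIG A   1       0.000   0.000   0.000  1.00  0.00          XX",
      "END"), "bad.pdb")
    expect_error(read_structure("bad.pdb"), "Xx")

    writeLines(c("2", "charge=0", "C 0 0 0"), "trunc.xyz")
    expect_error(read_structure("trunc.xyz"), "truncated")
  })
  expect_error(read_structure("no/such/file.sdf"), "not found")
})

test_that("rotatable-bond classification follows the graph rule", {
  expect_equal(sum(find_rotatable_bonds(make_fixture("alkane", 2))$rotatable), 0)
  expect_equal(sum(find_rotatable_bonds(make_fixture("alkane", 4))$rotatable), 1)

  cb <- read_structure(extdata("cellobiose.sdf"))
  rb <- find_rotatable_bonds(cb)
  expect_equal(sum(rb$rotatable), oracle_rotatable_count(cb))
  # ring bonds never rotatable; phi/psi glycosidic torsions are
  expect_false(any(rb$rotatable[rb$reason == "ring"]))
  expect_gte(sum(rb$reason == "rotatable-glycosidic"), 2)
})

test_that("rotatable-bond output is invariant under atom reordering", {
  cb <- read_structure(extdata("cellobiose.sdf"))
  set.seed(7)
  perm <- sample(n_atoms(cb))
  inv <- order(perm)
  atoms2 <- cb$atoms[inv, ]
  bonds2 <- data.frame(a1 = perm[cb$bonds$a1], a2 = perm[cb$bonds$a2],
                       order = cb$bonds$order)
  cb2 <- molecule(atoms2, bonds2, perceive_stereo = FALSE)
  expect_equal(sum(find_rotatable_bonds(cb2)$rotatable),
               sum(find_rotatable_bonds(cb)$rotatable))
})

test_that("stereo descriptors are perceived and survive rigid motion", {
  g <- read_structure(extdata("beta_d_glucose.sdf"))
  expect_equal(nrow(g$stereo$centers), 5)  # five ring stereocenters
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  g2 <- g
  coords(g2) <- coords(g) %*% R + 3
  expect_true(assert_stereo(g2, reference = g$stereo))
})

test_that("molecule invariants are validated", {
  expect_error(molecule(data.frame(element = "Zz", x = 0, y = 0, z = 0)),
               "Zz")
  expect_error(molecule(data.frame(element = "C", x = NaN, y = 0, z = 0)),
               "finite")
  expect_error(molecule(data.frame(element = c("C", "C"), x = c(0, 1.5),
                                   y = 0, z = 0),
                        data.frame(a1 = 1, a2 = 1)), "itself")
})
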