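test_that("titratable-site census matches substructure counts", {
  methane <- molecule(
    data.frame(element = c("C", "H", "H", "H", "H"),
               x = c(0, 1.09, -0.36, -0.36, -0.36),
               y = c(0, 0, 1.03, -0.51, -0.51),
               z = c(0, 0, 0, 0.89, -0.89)),
    data.frame(a1 = 1, a2 = 2:5))
  expect_equal(nrow(find_titratable_sites(methane, "neg")), 0)
  expect_equal(nrow(find_titratable_sites(methane, "pos")), 0)

  g <- read_structure(extdata("beta_d_glucose.sdf"))
  neg <- find_titratable_sites(g, "neg")
  pos <- find_titratable_sites(g, "pos")
  expect_equal(nrow(neg), 5)                       # five hydroxyls
  expect_true(all(neg$class == "hydroxyl_O"))
  expect_equal(nrow(pos), 6)                       # five OH + ring O
  expect_equal(sum(pos$class == "ether_or_ring_O"), 1)
  # restricting protonation to hydroxyl-type sites drops the ring O
  expect_equal(nrow(find_titratable_sites(g, "pos", include_ether_o = FALSE)), 5)
  # deterministic, ordered by atom index
  expect_true(!is.unsorted(neg$atom))
})

test_that("deprotonation yields one model per hydroxyl with the right mass shift", {
  mz <- read_structure(extdata("melezitose.sdf"))
  mods <- enumerate_charge_models(mz, "neg")
  expect_length(mods, 11)                          # trisaccharide: 11 OH
  for (cm in mods) {
    expect_equal(cm$molecule$net_charge, -1)
    expect_equal(n_atoms(cm$molecule), n_atoms(mz) - 1)
    expect_equal(monoisotopic_mass(cm$molecule) - monoisotopic_mass(mz),
                 -1.00783, tolerance = 1e-4)
  }
  expect_identical(vapply(mods, `[[`, "", "enum_label")[1:4],
                   c("I", "II", "III", "IV"))
})

test_that("protonation adds one H at the standard bond length", {
  g <- read_structure(extdata("beta_d_glucose.sdf"))
  mods <- enumerate_charge_models(g, "pos")
  expect_length(mods, 6)
  for (cm in mods) {
    m <- cm$molecule
    expect_equal(m$net_charge, 1)
    expect_equal(n_atoms(m), n_atoms(g) + 1)
    expect_equal(monoisotopic_mass(m) - monoisotopic_mass(g),
                 1.00783, tolerance = 1e-4)
    h <- n_atoms(m)  # appended proton
    site <- cm$site$atom
    d <- sqrt(sum((coords(m)[h, ] - coords(m)[site, ])^2))
    expect_equal(d, 0.96, tolerance = 0.02)
  }
})

test_that("stereo descriptors survive every charge model", {
  mz <- read_structure(extdata("melezitose.sdf"))
  for (mode in c("neg", "pos")) {
    for (cm in enumerate_charge_models(mz, mode)) {
      expect_true(assert_stereo(cm$molecule, reference = mz$stereo,
                                index_map = cm$index_map))
    }
  }
})

test_that("symmetry-equivalent charge models deduplicate", {
  # ethylene glycol: the two hydroxyls are graph-equivalent
  glycol <- molecule(
    data.frame(element = c("C", "C", "O", "O", "H", "H", "H", "H", "H", "H"),
               x = c(0, 1.52, -0.70, 2.22, -0.21, 2.92, -0.36, -0.36,
                     1.88, 1.88),
               y = c(0, 0, 1.10, 1.10, 1.85, 1.85, -0.55, -0.55, -0.52,
                     -0.52),
               z = c(0, 0, 0, 0, 0, 0, 0.89, -0.89, 0.89, -0.89)),
    data.frame(a1 = c(1, 1, 2, 3, 4, 1, 1, 2, 2),
               a2 = c(2, 3, 4, 5, 6, 7, 8, 9, 10)))
  mods <- enumerate_charge_models(glycol, "neg")
  expect_length(mods, 2)
  dd <- deduplicate_models(mods)
  expect_length(dd, 1)
  expect_identical(dd[[1]]$enum_label, "I")  # lowest enumeration index kept

  # all-distinct sites stay; empty input passes through
  g <- read_structure(extdata("beta_d_glucose.sdf"))
  mods_g <- enumerate_charge_models(g, "neg")
  expect_length(deduplicate_models(mods_g), length(mods_g))
  expect_identical(deduplicate_models(list()), list())
})

test_that("a molecule with no sites warns and returns an empty list", {
  et <- make_fixture("alkane", 2)
  expect_warning(mods <- enumerate_charge_models(et, "neg"), "no titratable")
  expect_length(mods, 0)
})
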