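test_that("align_rmsd is a proper superposition metric", {
  set.seed(11)
  a <- matrix(rnorm(30), 10, 3)
  expect_lt(align_rmsd(a, a), 1e-6)

  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- a %*% R + matrix(c(5, -2, 1), 10, 3, byrow = TRUE)
  expect_lt(align_rmsd(a, b), 1e-6)
  set.seed(12)
  b2 <- b + matrix(rnorm(30, 0, 0.3), 10, 3)
  expect_equal(align_rmsd(a, b2), align_rmsd(b2, a), tolerance = 1e-9)

  expect_error(align_rmsd(a, a[1:5, ]), "different atom counts")
})

test_that("align_rmsd matches a rotation-grid search oracle", {
  # two 4-point toy configurations
  a <- matrix(c(0, 0, 0,   1.5, 0, 0,   0, 2, 0,   0.5, 0.5, 1.2),
              4, 3, byrow = TRUE)
  b <- matrix(c(0, 0, 0,   1.4, 0.3, 0,   -0.2, 1.9, 0.4,   0.9, 0.2, 1.0),
              4, 3, byrow = TRUE)
  expect_equal(align_rmsd(a, b), oracle_rmsd(a, b), tolerance = 1e-3)
})

test_that("rigid rings give a single-conformer ensemble", {
  rr <- make_fixture("rigid_ring")
  expect_message(ens <- generate_conformers(rr, target = 1000, seed = 1),
                 "no rotatable bonds")
  expect_equal(length(ens), 1)
  expect_equal(ens$re, 0)
})

test_that("butane collapses to at most three torsional wells", {
  ens <- generate_conformers(make_fixture("alkane", 4), target = 100, seed = 3)
  expect_lte(length(ens), 3)
  expect_gte(length(ens), 2)       # anti and at least one gauche
  expect_equal(min(ens$re), 0)
  # exact reproducibility under a fixed seed
  ens2 <- generate_conformers(make_fixture("alkane", 4), target = 100, seed = 3)
  expect_identical(ens$coords, ens2$coords)
  expect_identical(ens$energy, ens2$energy)
})

test_that("ensembles preserve the parent's stereo descriptors", {
  dl <- make_fixture("disaccharide_like")
  cm <- enumerate_charge_models(dl, "neg")[[1]]
  ens <- generate_conformers(cm, target = 20, seed = 5)
  for (i in seq_along(ens$coords)) {
    m <- ensemble_molecule(ens, i)
    expect_true(assert_stereo(m, reference = cm$molecule$stereo))
  }
})

test_that("ensembles at or below the threshold pass through unclustered", {
  dl <- make_fixture("disaccharide_like")
  ens <- generate_conformers(dl, target = 40, seed = 9)
  cl <- cluster_ensemble(ens, threshold_count = 50)
  expect_identical(cl$summary$method, "pass-through")
  expect_equal(sum(cl$is_center), length(ens))
})

# bundles are distinct conformations (different glycosidic torsions plus
# small Cartesian noise); superposition removes translations, so bundles
# must differ in shape, not position
make_bundle_ensemble <- function(torsions_deg, n_per, spread, seed = 5) {
  set.seed(seed)
  dl <- make_fixture("disaccharide_like")
  rot <- find_rotatable_bonds(dl)
  rot <- rot[rot$rotatable & rot$reason == "rotatable-glycosidic", ][1, ]
  cc <- unlist(lapply(torsions_deg, function(ang) {
    mt <- glyccs:::set_torsion(dl, rot$a1, rot$a2, ang * pi / 180)
    base <- coords(mt)
    lapply(seq_len(n_per), function(i)
      base + matrix(rnorm(length(base), 0, spread), nrow(base)))
  }), recursive = FALSE)
  en <- rnorm(length(cc))
  structure(list(molecule = dl, coords = cc, energy = en, re = en - min(en),
                 cluster = rep(NA_integer_, length(cc)),
                 is_center = rep(TRUE, length(cc)),
                 params = list(n_rotatable = 4)),
            class = "glyccs_ensemble")
}

test_that("well-separated bundles are recovered as clusters", {
  two <- make_bundle_ensemble(c(60, 180), 26, 0.02)
  cl <- cluster_ensemble(two, threshold_count = 50)
  expect_equal(cl$summary$n_clusters, 2)
  # each center is its cluster's lowest-energy member
  for (cid in unique(cl$cluster)) {
    members <- which(cl$cluster == cid)
    expect_true(members[which.min(cl$energy[members])] %in% cl$summary$centers)
  }
  # the calibration fixture: three bundles -> exactly three clusters
  three <- make_bundle_ensemble(c(60, 180, 300), 20, 0.05)
  expect_equal(cluster_ensemble(three, 50)$summary$n_clusters, 3)
})

test_that("the global-minimum conformer is always promoted to a center", {
  ens <- make_bundle_ensemble(c(60, 180), 30, 0.05, seed = 17)
  cl <- cluster_ensemble(ens, threshold_count = 50)
  gmin <- which.min(cl$energy)
  expect_true(cl$is_center[gmin])
})

test_that("clustering is invariant to conformer order", {
  ens <- make_bundle_ensemble(c(60, 180, 300), 18, 0.05, seed = 23)
  cl <- cluster_ensemble(ens, 50)
  set.seed(2)
  perm <- sample(length(ens$coords))
  ens2 <- ens
  ens2$coords <- ens$coords[perm]
  ens2$energy <- ens$energy[perm]
  ens2$re <- ens$re[perm]
  cl2 <- cluster_ensemble(ens2, 50)
  # same partition as a set of sets (labels may be permuted)
  p1 <- lapply(split(seq_along(perm), cl$cluster), sort)
  p2 <- lapply(split(perm, cl2$cluster), sort)
  expect_setequal(unname(lapply(p1, paste, collapse = ",")),
                  unname(lapply(p2, paste, collapse = ",")))
})

test_that("ensemble SDF serialization carries conformer properties", {
  dl <- make_fixture("disaccharide_like")
  ens <- generate_conformers(dl, target = 5, seed = 2)
  withr::with_tempdir({
    write_ensemble(ens, "ens.sdf")
    mols <- glyccs:::read_sdf("ens.sdf")
    expect_length(mols, length(ens))
    p1 <- attr(mols[[1]], "sdf_properties")
    expect_identical(p1$CONF_ID, "1")
    expect_equal(as.numeric(p1$RE), ens$re[1], tolerance = 1e-5)
  })
})
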