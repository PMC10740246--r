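# ARMSD, labelling and the seeded conformer generator.

test_that("armsd is zero on identity and rigid motions, and symmetric", {
  dec <- decane_confs()
  A <- dec$confs[[1]]$coords
  expect_equal(armsd(A, A, dec$mol), 0, tolerance = 1e-9)
  set.seed(3)
  for (k in 1:5) {
    R <- random_rotation()
    moved <- A %*% R + matrix(stats::rnorm(3, sd = 10), nrow(A), 3,
                              byrow = TRUE)
    expect_lt(armsd(A, moved, dec$mol), 1e-6)
  }
  B <- dec$confs[[2]]$coords
  expect_equal(armsd(A, B, dec$mol), armsd(B, A, dec$mol), tolerance = 1e-6)
})

test_that("armsd matches the closed-form collinear fixture", {
  cp <- toy$collinear_pair
  expect_equal(armsd(cp$a, cp$b, cp$mol), cp$expected$armsd, tolerance = 1e-9)
})

test_that("automorphism-aware armsd is bounded by the identity mapping", {
  bz <- toy$benzene_rotation
  expect_lt(armsd(bz$a, bz$b, bz$mol), 1e-9)          # ring rotation
  dec <- decane_confs()
  # chain reversal is an automorphism: symmetry-aware ARMSD sees through it,
  # the identity mapping does not
  A <- dec$confs[[3]]$coords
  expect_lt(armsd(A, A[10:1, ], dec$mol), 1e-9)
  expect_gt(armsd(A, A[10:1, ], mol = NULL), 0.1)
  for (k in c(2, 5, 9)) {
    with_sym <- armsd(dec$confs[[1]], dec$confs[[k]], dec$mol)
    identity_only <- armsd(dec$confs[[1]], dec$confs[[k]], mol = NULL)
    expect_lte(with_sym, identity_only + 1e-9)
  }
})

test_that("igraph automorphism enumeration agrees with brute force", {
  for (mol in list(chain_mol(4), chain_mol(6), toy$benzene_rotation$mol,
                   acetate_mol())) {
    got <- molecule_automorphisms(mol)
    want <- brute_force_automorphisms(mol)
    canon <- function(perms) sort(vapply(perms, paste, "", collapse = ","))
    expect_identical(canon(got), canon(want))
  }
  # benzene has the full dihedral symmetry of the (bond-colour merged) ring
  expect_length(molecule_automorphisms(toy$benzene_rotation$mol), 12L)
})

test_that("armsd_bio is the minimum over references", {
  dec <- decane_confs()
  refs <- dec$confs[2:4]
  conf <- dec$confs[[1]]
  singles <- vapply(refs, function(r) armsd(conf, r, dec$mol), 0)
  expect_equal(armsd_bio(conf, refs, dec$mol), min(singles))
  expect_equal(armsd_bio(conf, refs[1], dec$mol), singles[1])
  expect_equal(armsd_bio(conf, list(conf), dec$mol), 0, tolerance = 1e-9)
  expect_error(armsd_bio(conf, list(), dec$mol), "empty")
  # union property
  s1 <- refs[1:2]; s2 <- refs[3]
  expect_equal(armsd_bio(conf, c(s1, s2), dec$mol),
               min(armsd_bio(conf, s1, dec$mol), armsd_bio(conf, s2, dec$mol)))
})

test_that("classification uses strict 1 and 2.5 Angstrom thresholds", {
  expect_identical(classify_conformer(0.99), "bio_like")
  expect_identical(classify_conformer(2.51), "non_bio")
  expect_identical(classify_conformer(1.0), "intermediate")
  expect_identical(classify_conformer(2.5), "intermediate")
  expect_identical(classify_conformer(0), "bio_like")
  expect_error(classify_conformer(-0.1), "non-negative")
  # the three labels partition [0, Inf)
  x <- seq(0, 6, by = 0.01)
  expect_true(all(classify_conformer(x) %in%
                    c("bio_like", "intermediate", "non_bio")))
})

test_that("labelled ensembles record retrieval and label fractions", {
  dec <- decane_confs()
  gen <- dec$confs[1:20]
  bio <- list(dec$confs[[1]])
  ens <- build_labelled_ensemble(dec$mol, gen, bio)
  expect_true(ens$retrieved)
  expect_identical(ens$labels[1], "bio_like")
  expect_equal(ens$armsd_bio[1], 0, tolerance = 1e-9)
  # rigid-rotated copies of the bioactive all label bio_like at 0
  set.seed(8)
  rotated <- lapply(1:4, function(k) {
    conformer_record("decane", k, bio[[1]]$coords %*% random_rotation(),
                     gen_order = k)
  })
  ens2 <- build_labelled_ensemble(dec$mol, rotated, bio)
  expect_true(all(ens2$armsd_bio < 1e-6))
  expect_true(all(ens2$labels == "bio_like"))
})

test_that("the generator is seeded, bounded and order-preserving", {
  bz <- benzene_confs()
  expect_length(bz$confs, 1L)                 # rigid molecule collapses
  dec <- decane_confs()
  expect_gt(length(dec$confs), 100L)          # flexible chain fills out
  expect_lte(length(dec$confs), 250L)
  expect_identical(vapply(dec$confs, function(cf) cf$gen_order, 0L),
                   seq_along(dec$confs))
  # same seed, bitwise-identical coordinates
  again <- generate_conformers(dec$mol, max_n = 250, seed = 7)
  expect_identical(dec$confs[[10]]$coords, again[[10]]$coords)
  expect_error(generate_conformers(chain_mol(3)), "no SMILES")
})

test_that("torsions can be measured and driven", {
  dec <- decane_confs()
  quads <- torsion_quadruples(dec$mol)
  expect_equal(nrow(quads), 7L)   # decane has 7 rotatable bonds
  coords <- dec$confs[[1]]$coords
  set.seed(2)
  for (k in c(1, 4, 7)) {
    target <- stats::runif(1, -179, 179)
    out <- set_torsion(dec$mol, coords, quads[k, ], target)
    expect_equal(get_torsion(out, quads[k, ]), target, tolerance = 1e-6)
  }
  # driving a torsion preserves bond lengths
  out <- set_torsion(dec$mol, coords, quads[4, ], 60)
  d0 <- sqrt(rowSums((coords[1:9, ] - coords[2:10, ])^2))
  d1 <- sqrt(rowSums((out[1:9, ] - out[2:10, ])^2))
  expect_equal(d0, d1, tolerance = 1e-9)
})
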