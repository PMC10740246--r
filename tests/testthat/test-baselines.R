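# The six ranking baselines and their MCS/TFD machinery.

test_that("random ranking is seeded and covers permutations uniformly", {
  ens <- fake_ensemble(c("bio_like", "non_bio", "non_bio", "non_bio"))
  expect_identical(rank_random(ens, seed = 5)$order,
                   rank_random(ens, seed = 5)$order)
  single <- fake_ensemble("bio_like")
  expect_identical(rank_random(single, seed = 1)$order, 1L)
  # each of the 24 permutations of 4 conformers appears at its expected
  # frequency over many seeded draws (multinomial 3-sigma band); seeds are
  # drawn from one stream to avoid the correlation of consecutive RNG seeds
  n_draw <- 10000L
  set.seed(99)
  seeds <- sample.int(1e7, n_draw)
  seen <- table(vapply(seeds, function(s)
    paste(rank_random(ens, seed = s)$order, collapse = ""), ""))
  expect_length(seen, 24L)
  p <- 1 / 24
  band <- 3 * sqrt(n_draw * p * (1 - p))
  expect_true(all(abs(seen - n_draw * p) < band + 1))
})

test_that("generator-order ranking follows gen_order and is idempotent", {
  ens <- fake_ensemble(rep("non_bio", 3), gen_order = c(2L, 3L, 1L))
  rk <- rank_generator_order(ens)
  expect_identical(rk$order, c(3L, 1L, 2L))
  sorted <- fake_ensemble(rep("non_bio", 3))
  expect_identical(rank_generator_order(sorted)$order, 1:3)
  # re-ranking the already-ranked ensemble changes nothing
  expect_identical(rank_generator_order(sorted)$order,
                   rank_generator_order(sorted)$order)
  no_go <- fake_ensemble("non_bio")
  no_go$conformers[[1]]$gen_order <- NA_integer_
  expect_error(rank_generator_order(no_go), "gen_order")
})

test_that("energy ranking prefers anti over eclipsed butane", {
  mol <- chain_mol(4, "butane")
  quads <- torsion_quadruples(mol)
  base <- chain_coords(4)
  anti <- set_torsion(mol, base, quads[1, ], 180)
  eclipsed <- set_torsion(mol, base, quads[1, ], 0)
  ens <- structure(list(mol = mol, conformers = list(
    conformer_record("butane", 1L, eclipsed, gen_order = 1L),
    conformer_record("butane", 2L, anti, gen_order = 2L)),
    bioactive = list(), armsd_bio = c(1, 1),
    labels = c("intermediate", "intermediate"), retrieved = FALSE),
    class = "cb_ensemble")
  en <- conformer_energy(ens)
  expect_lt(en[2], en[1])
  rk <- rank_energy(ens)
  expect_identical(rk$order[1], 2L)
  # energies are internal-coordinate properties: rigid motion leaves the
  # ranking unchanged
  set.seed(3)
  moved <- lapply(ens$conformers, function(cf) {
    cf$coords <- cf$coords %*% random_rotation() +
      matrix(stats::rnorm(3, sd = 5), nrow(cf$coords), 3, byrow = TRUE)
    cf
  })
  ens2 <- ens; ens2$conformers <- moved
  expect_equal(conformer_energy(ens2), en, tolerance = 1e-3)
})

test_that("sasa ranking prefers extended conformations", {
  dec <- decane_confs()
  mol <- dec$mol
  quads <- torsion_quadruples(mol)
  ext <- dec$confs[[1]]$coords
  for (k in seq_len(nrow(quads))) ext <- set_torsion(mol, ext, quads[k, ], 180)
  folded <- ext
  for (k in c(3, 4, 5)) folded <- set_torsion(mol, folded, quads[k, ], 60)
  s_ext <- conformer_sasa(ext, mol$elements)
  s_fold <- conformer_sasa(folded, mol$elements)
  expect_gt(s_ext, 0)
  expect_gt(s_ext, s_fold)
  set.seed(1)
  moved <- ext %*% random_rotation() + matrix(2, nrow(ext), 3)
  expect_equal(conformer_sasa(moved, mol$elements), s_ext, tolerance = 1e-6)
  ens <- structure(list(mol = mol, conformers = list(
    conformer_record("d", 1L, folded, gen_order = 1L),
    conformer_record("d", 2L, ext, gen_order = 2L)),
    bioactive = list(), armsd_bio = c(1, 1),
    labels = c("intermediate", "intermediate"), retrieved = FALSE),
    class = "cb_ensemble")
  expect_identical(rank_sasa(ens)$order[1], 2L)
  expect_identical(rank_rgyr(ens)$order[1], 2L)   # extended also wins RGyr
})

test_that("radius of gyration follows its closed form", {
  # two equal-mass atoms 2 A apart: RGyr = 1
  expect_equal(conformer_rgyr(cbind(c(-1, 1), 0, 0), c(6L, 6L)), 1)
  expect_equal(conformer_rgyr(matrix(5, 1, 3), 6L), 0)
  # unequal masses shift the centre of mass accordingly
  m <- atomic_mass(c(6L, 8L))
  want <- sqrt(sum(m * (c(2 * m[2], 2 * m[1]) / sum(m))^2) / sum(m))
  expect_equal(conformer_rgyr(cbind(c(-1, 1), 0, 0), c(6L, 8L)), want)
})

test_that("nearest-reference search uses Tanimoto with lexicographic ties", {
  bz <- toy$benzene_rotation$mol; bz$mol_id <- "benzene"
  hexane <- chain_mol(6, "hexane")
  toluene <- molecule_record("toluene", rep(6L, 7),
                             rbind(bz$bonds, data.frame(i = 1L, j = 7L,
                                                        order = 1)))
  refs <- list(benzene = bz, hexane = hexane)
  expect_identical(find_nearest_reference(toluene, refs), "benzene")
  expect_identical(find_nearest_reference(bz, refs), "benzene")
  # no overlap at all: the lexicographically first reference wins
  sulfur <- molecule_record("s8", c(16L, 16L),
                            data.frame(i = 1L, j = 2L, order = 1))
  expect_identical(find_nearest_reference(sulfur, refs), "benzene")
  expect_error(find_nearest_reference(bz, list()), "empty")
})

test_that("the MCS respects elements, bond orders and chirality", {
  dec <- decane_confs()
  m <- mcs(dec$mol, dec$mol, time_cap = 5)
  expect_equal(m$n_heavy, 10L)
  expect_false(m$timed_out)
  # disjoint element sets share nothing
  s2 <- molecule_record("s", c(16L, 16L), data.frame(i = 1L, j = 2L, order = 1))
  expect_equal(mcs(chain_mol(3), s2)$n_heavy, 0L)
  # enantiomers: the chirality-mismatched centre cannot be fully mapped
  ch <- toy$chiral_center
  m_r <- assign_stereo_from_3d(ch$mol, ch$r_coords)
  m_s <- assign_stereo_from_3d(ch$mol, ch$s_coords)
  m_rs <- mcs(m_r, m_s, time_cap = 5)
  expect_lt(m_rs$n_heavy, 4L)
  expect_equal(mcs(m_r, m_r, time_cap = 5)$n_heavy, 4L)
})

test_that("TFD over the MCS reacts to torsion deviations only", {
  dec <- decane_confs()
  m <- mcs(dec$mol, dec$mol, time_cap = 5)
  expect_gt(nrow(m$torsions), 0L)
  A <- dec$confs[[1]]$coords
  expect_equal(tfd_mcs(A, A, m, dec$mol), 0, tolerance = 1e-9)
  # a rigidly moved copy still deviates by nothing
  set.seed(2)
  expect_equal(tfd_mcs(A, A %*% random_rotation(), m, dec$mol), 0,
               tolerance = 1e-6)
  B <- dec$confs[[5]]$coords
  expect_equal(tfd_mcs(A, B, m, dec$mol), tfd_mcs(B, A, m, dec$mol),
               tolerance = 1e-9)
  # single-torsion MCS at 180 degrees deviation attains the maximum 1
  but <- chain_mol(4, "butane")
  mb <- mcs(but, but, time_cap = 5)
  qb <- torsion_quadruples(but)
  base <- chain_coords(4)
  flipped <- set_torsion(but, base, qb[1, ],
                         get_torsion(base, qb[1, ]) + 180)
  expect_equal(tfd_mcs(base, flipped, mb, but), 1, tolerance = 1e-6)
})

test_that("the bioactivity-based ranker puts the reference conformer first", {
  dec <- decane_confs()
  bio <- dec$confs[[3]]
  ens <- build_labelled_ensemble(dec$mol, dec$confs[1:10], list(bio))
  refs <- list(decane = list(mol = dec$mol, bioactive = list(bio)))
  rk <- rank_tfd2simrefmcs(ens, refs)
  expect_identical(rk$ranker_name, "tfd2simrefmcs")
  expect_identical(rk$order[1], 3L)
  expect_equal(rk$scores[1], 0, tolerance = 1e-9)
  expect_setequal(rk$order, 1:10)
  expect_identical(attr(rk, "reference_mol_id"), "decane")
  # no-torsion MCS falls back to generation order with a flag
  bz <- benzene_confs()
  ens_bz <- build_labelled_ensemble(bz$mol, bz$confs, bz$confs)
  refs_bz <- list(benzene = list(mol = bz$mol, bioactive = bz$confs))
  rk_bz <- rank_tfd2simrefmcs(ens_bz, refs_bz)
  expect_true(isTRUE(attr(rk_bz, "no_torsion_fallback")))
})

test_that("conformer matching by binned MCS torsions is bin-monotone", {
  dec <- decane_confs()
  ens <- build_labelled_ensemble(dec$mol, dec$confs[1:12],
                                 list(dec$confs[[1]]))
  m <- mcs(dec$mol, dec$mol, time_cap = 5)
  p10 <- match_conformers_by_mcs_torsions(ens, ens, m, 10)
  p20 <- match_conformers_by_mcs_torsions(ens, ens, m, 20)
  # identity MCS: every conformer pairs with itself
  expect_true(all(seq_len(12) %in% p10$conf_a[p10$conf_a == p10$conf_b]))
  expect_gte(nrow(p20), nrow(p10))
  # bin membership on a hand-made single-torsion case
  but <- chain_mol(4, "butane")
  mb <- mcs(but, but, time_cap = 5)
  qb <- torsion_quadruples(but)
  mk <- function(angle, id) {
    co <- set_torsion(but, chain_coords(4), qb[1, ], angle)
    structure(list(mol = but,
                   conformers = list(conformer_record("butane", id, co,
                                                      gen_order = 1L)),
                   bioactive = list(), armsd_bio = 1, labels = "intermediate",
                   retrieved = FALSE), class = "cb_ensemble")
  }
  expect_equal(nrow(match_conformers_by_mcs_torsions(mk(4, 1L), mk(6, 2L),
                                                     mb, 10)), 1L)
  expect_equal(nrow(match_conformers_by_mcs_torsions(mk(4, 1L), mk(14, 2L),
                                                     mb, 10)), 0L)
})

test_that("the thermal energy window reproduces its printed values", {
  expect_equal(thermal_energy_window(3, 298), 1.78, tolerance = 0.005)
  expect_equal(thermal_energy_window(0, 298), 0)
  expect_equal(thermal_energy_window(1, 298), 0.592, tolerance = 5e-4)
  expect_error(thermal_energy_window(-1, 298))
})

test_that("every ranker yields a permutation and deterministic output", {
  dec <- decane_confs()
  ens <- build_labelled_ensemble(dec$mol, dec$confs[1:8],
                                 list(dec$confs[[2]]))
  refs <- list(decane = list(mol = dec$mol,
                             bioactive = list(dec$confs[[2]])))
  rankers <- list(function(e) rank_random(e, seed = 3),
                  rank_generator_order, rank_sasa, rank_rgyr, rank_oracle,
                  function(e) rank_tfd2simrefmcs(e, refs))
  for (f in rankers) {
    rk1 <- f(ens); rk2 <- f(ens)
    expect_setequal(rk1$order, confbias:::.cb_conf_ids(ens))
    expect_identical(rk1$order, rk2$order)
  }
})
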