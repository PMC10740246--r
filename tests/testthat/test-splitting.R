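# Random and scaffold-cluster splits.

test_that("random splits slice exact ratios and are seed-reproducible", {
  ids <- sprintf("m%02d", 1:10)
  s <- random_split(ids, seed = 3)
  tab <- table(factor(s$assignment, c("train", "val", "test")))
  expect_equal(as.integer(tab), c(8L, 1L, 1L))
  expect_identical(s$assignment, random_split(ids, seed = 3)$assignment)
  expect_false(identical(s$assignment, random_split(ids, seed = 4)$assignment))
  # every molecule lands in exactly one subset
  expect_setequal(names(s$assignment), ids)
  expect_error(random_split(ids[1:2]), "at least 3")
})

test_that("train-set overlap across seeds matches the 0.8^2 expectation", {
  ids <- sprintf("m%03d", 1:100)
  splits <- lapply(1:5, function(s) random_split(ids, seed = s))
  trains <- lapply(splits, function(s) names(s$assignment)[s$assignment == "train"])
  overlaps <- c()
  for (a in 1:4) for (b in (a + 1):5)
    overlaps <- c(overlaps, length(intersect(trains[[a]], trains[[b]])))
  # expected overlap fraction 0.64; hypergeometric sd is ~2.4 molecules
  expect_gt(mean(overlaps), 55)
  expect_lt(mean(overlaps), 73)
  expect_gt(length(unique(lapply(splits, function(s) s$assignment))), 1L)
})

# three synthetic scaffold families: members share a ring system and differ
# by alkyl tail length
scaffold_family_mols <- function(n_per = 10L) {
  bz <- toy$benzene_rotation$mol
  naph_bonds <- data.frame(
    i = c(1, 2, 3, 4, 5, 6, 1, 6, 7, 8, 9),
    j = c(2, 3, 4, 5, 6, 1, 7, 10, 8, 9, 10),
    order = c(2, 1, 2, 1, 2, 1, 1, 1, 2, 1, 2))
  naphthalene <- molecule_record("naph", rep(6L, 10), naph_bonds)
  pyridine <- molecule_record("pyr", c(7L, rep(6L, 5)), bz$bonds)
  out <- list()
  for (fam in list(list(core = bz, name = "bz"),
                   list(core = naphthalene, name = "na"),
                   list(core = pyridine, name = "py"))) {
    nc <- n_heavy_atoms(fam$core)
    for (k in seq_len(n_per)) {
      tail_len <- k
      mol <- molecule_record(
        sprintf("%s_%02d", fam$name, k),
        c(fam$core$elements, rep(6L, tail_len)),
        rbind(fam$core$bonds,
              data.frame(i = c(2L, nc + seq_len(tail_len - 1)),
                         j = nc + seq_len(tail_len), order = 1)))
      out[[mol$mol_id]] <- mol
    }
  }
  out
}

test_that("scaffold splits keep families whole and similar clusters tight", {
  mols <- scaffold_family_mols(10L)
  weights <- rep(c(30, 60), length.out = length(mols))
  s <- scaffold_split(mols, weights, seed = 2)
  clusters <- attr(s, "clusters")
  fams <- sub("_.*", "", names(clusters))
  # the three ring systems give exactly three clusters, none spanning subsets
  expect_equal(length(unique(clusters)), 3L)
  expect_true(all(tapply(clusters, fams, function(x) length(unique(x)) == 1L)))
  for (cl in unique(clusters)) {
    subsets <- unique(s$assignment[clusters == cl])
    expect_length(subsets, 1L)
  }
  # coverage: train holds at least 80% of conformations, bounded by the
  # largest cluster weight
  wt_by_cl <- tapply(weights, clusters, sum)
  train_wt <- sum(weights[s$assignment == "train"])
  expect_gte(train_wt, 0.8 * sum(weights))
  expect_lt(train_wt, 0.8 * sum(weights) + max(wt_by_cl))
  # within-cluster pairwise Tanimoto >= 0.5, checked exhaustively
  fps <- lapply(mols, function(m) morgan_fp(murcko_scaffold(m)))
  for (cl in unique(clusters)) {
    members <- which(clusters == cl)
    for (a in members) for (b in members)
      expect_gte(tanimoto(fps[[a]], fps[[b]]), 0.5)
  }
  # determinism
  expect_identical(s$assignment, scaffold_split(mols, weights, seed = 2)$assignment)
})

test_that("scaffold extraction keeps rings, linkers and exocyclic oxygens", {
  mols <- scaffold_family_mols(3L)
  # tails prune back to the bare ring system
  sc <- murcko_scaffold(mols$bz_03)
  expect_equal(n_heavy_atoms(sc), 6L)
  # acyclic molecules fall back to the whole molecule
  expect_equal(n_heavy_atoms(murcko_scaffold(chain_mol(5))), 5L)
  # an acyl side chain is pruned entirely (acetophenone-like -> bare ring)
  phenone <- molecule_record("phk", c(rep(6L, 7), 8L),
                             rbind(toy$benzene_rotation$mol$bonds,
                                   data.frame(i = c(1L, 7L), j = c(7L, 8L),
                                              order = c(1, 2))))
  expect_equal(n_heavy_atoms(murcko_scaffold(phenone)), 6L)
  # but the carbonyl oxygen on a ring-ring linker is part of the scaffold
  bz2 <- toy$benzene_rotation$mol$bonds
  benzophenone <- molecule_record(
    "bzp", c(rep(6L, 6), 6L, 8L, rep(6L, 6)),
    rbind(bz2,
          data.frame(i = c(1L, 7L, 7L), j = c(7L, 8L, 9L), order = c(1, 2, 1)),
          transform(bz2, i = i + 8L, j = j + 8L)))
  expect_equal(n_heavy_atoms(murcko_scaffold(benzophenone)), 14L)
  # two molecules with identical scaffolds cluster together; orthogonal
  # fingerprints do not
  fp1 <- morgan_fp(murcko_scaffold(mols$bz_01))
  fp2 <- morgan_fp(murcko_scaffold(mols$bz_02))
  expect_equal(tanimoto(fp1, fp2), 1)
  cl <- cluster_scaffold_fps(list(fp1, morgan_fp(chain_mol(3))))
  expect_length(unique(cl), 2L)
})
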