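# Shared fixtures: tiny molecules built in code and a memoized synthetic
# benchmark so the expensive embedding step runs once per test session.

.fixture_env <- new.env()

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env, inherits = FALSE)
}

toy <- make_toy_geometries()

# Linear alkane chain of n carbons (graph only).
chain_mol <- function(n, id = paste0("chain", n)) {
  molecule_record(id, rep(6L, n),
                  if (n > 1) data.frame(i = seq_len(n - 1), j = 2:n, order = 1)
                  else data.frame(i = integer(), j = integer(), order = numeric()))
}

# Planar zigzag coordinates for a chain with ideal-ish geometry.
chain_coords <- function(n, bond = 1.54, angle = 111) {
  coords <- matrix(0, n, 3)
  dir <- 0
  for (k in 2:n) {
    dir <- if (k %% 2 == 0) (180 - angle) / 2 else -(180 - angle) / 2
    coords[k, ] <- coords[k - 1, ] +
      bond * c(cos(dir * pi / 180), sin(dir * pi / 180), 0)
  }
  coords
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Acetate anion built atom by atom: CH3-C(=O)-O(-)
acetate_mol <- function() {
  molecule_record("acetate", c(6L, 6L, 8L, 8L),
                  data.frame(i = c(1L, 2L, 2L), j = c(2L, 3L, 4L),
                             order = c(1, 2, 1)),
                  charges = c(0L, 0L, 0L, -1L))
}

acetic_acid_mol <- function() {
  molecule_record("acetic", c(6L, 6L, 8L, 8L),
                  data.frame(i = c(1L, 2L, 2L), j = c(2L, 3L, 4L),
                             order = c(1, 2, 1)))
}

# Small shared conformer fixtures (one embedding helper call each, memoized).
decane_confs <- function() memo("decane_confs", {
  mol <- chain_mol(10, "decane")
  mol$smiles <- "CCCCCCCCCC"
  list(mol = mol, confs = generate_conformers(mol, max_n = 250, seed = 7))
})

benzene_confs <- function() memo("benzene_confs", {
  mol <- toy$benzene_rotation$mol
  mol$smiles <- "c1ccccc1"
  list(mol = mol, confs = generate_conformers(mol, max_n = 250, seed = 7))
})

# A small family-structured benchmark shared by the module tests.
small_benchmark <- function() memo("small_benchmark", {
  make_benchmark(synthetic_spec(n_molecules = 12, max_conformers = 40,
                                seed = 7))
})

# The acceptance-scale benchmark (built once; used by test-acceptance.R).
acceptance_benchmark <- function() memo("acceptance_benchmark", {
  make_benchmark(synthetic_spec(n_molecules = 54, max_conformers = 80,
                                seed = 42))
})

# Direct-summation BEDROC oracle, independent of the implementation: the
# RIE denominator (the expected positive weight under a random ranking) is
# summed explicitly over every rank instead of using the geometric-series
# closed form.
bedroc_oracle <- function(labels, alpha = 20) {
  N <- length(labels); n <- sum(labels)
  ranks <- which(as.logical(labels))
  s <- 0
  for (r in ranks) s <- s + exp(-alpha * r / N)
  denom <- sum(exp(-alpha * seq_len(N) / N)) / N
  rie <- (s / n) / denom
  ra <- n / N
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

# Brute-force graph automorphisms for small molecules: all permutations
# preserving elements, charges and adjacency with bond colours.
brute_force_automorphisms <- function(mol) {
  n <- length(mol$elements)
  stopifnot(n <= 8)
  adj <- matrix(0, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[i, j] <- adj[j, i] <- confbias:::.cb_bond_colors(mol)[k]
  }
  vc <- confbias:::.cb_vertex_colors(mol)
  all_perms <- function(m) {
    if (m == 1L) return(list(1L))
    out <- list()
    for (p in all_perms(m - 1L))
      for (pos in seq_len(m))
        out[[length(out) + 1L]] <- append(p, m, after = pos - 1L)
    out
  }
  Filter(function(p) all(vc[p] == vc) && all(adj[p, p] == adj), all_perms(n))
}

# Minimal hand-built labelled ensemble for evaluation tests (no geometry).
fake_ensemble <- function(labels, mol_id = "fake", gen_order = NULL) {
  n <- length(labels)
  ab <- ifelse(labels == "bio_like", 0.5,
               ifelse(labels == "non_bio", 3.0, 1.5))
  mol <- chain_mol(2, mol_id)
  confs <- lapply(seq_len(n), function(k)
    conformer_record(mol_id, k, cbind(c(0, 1.54), 0, 0),
                     gen_order = if (is.null(gen_order)) k else gen_order[k]))
  structure(list(mol = mol, conformers = confs, bioactive = list(),
                 armsd_bio = ab, labels = labels,
                 retrieved = any(labels == "bio_like")),
            class = "cb_ensemble")
}
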