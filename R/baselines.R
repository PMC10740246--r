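# Conformer ranking baselines: five bioactivity-unaware rankers (random,
# generator order, force-field energy, SASA, radius of gyration) and the
# bioactivity-based TFD-over-MCS ranker, with the MCS and torsion
# fingerprint machinery they need.

#' Construct a ranking result
#'
#' @param mol_id molecule id.
#' @param ranker_name short ranker label.
#' @param order vector of `conf_id`s, best first (a permutation of the
#'   ensemble's conformers).
#' @param scores raw per-conformer scores aligned with `order`.
#' @param direction sort direction applied to the raw score.
#' @return Object of class `cb_ranking`.
#' @export
ranking_result <- function(mol_id, ranker_name, order, scores,
                           direction = c("ascending", "descending")) {
  structure(list(mol_id = mol_id, ranker_name = ranker_name,
                 order = as.integer(order), scores = as.numeric(scores),
                 direction = match.arg(direction)),
            class = "cb_ranking")
}

#' @export
print.cb_ranking <- function(x, ...) {
  cat(sprintf("<cb_ranking %s by %s: %d conformers (%s)>\n", x$mol_id,
              x$ranker_name, length(x$order), x$direction))
  invisible(x)
}

.cb_conf_ids <- function(ensemble)
  vapply(ensemble$conformers, function(cf) cf$conf_id, 0L)

.cb_gen_orders <- function(ensemble) {
  go <- vapply(ensemble$conformers, function(cf) cf$gen_order, 0L)
  if (anyNA(go)) stop("ensemble ", ensemble$mol$mol_id,
                      " has conformers without gen_order")
  go
}

.cb_rank_by <- function(ensemble, name, scores, direction) {
  ids <- .cb_conf_ids(ensemble)
  ord <- stable_order(scores, .cb_gen_orders(ensemble),
                      decreasing = direction == "descending")
  ranking_result(ensemble$mol$mol_id, name, ids[ord], scores[ord], direction)
}

#' Random-order baseline
#'
#' Scores every conformer with a standard-normal draw and sorts ascending;
#' the chance level against which all other rankers are compared.
#'
#' @param ensemble a `cb_ensemble`.
#' @param seed integer seed.
#' @return A `cb_ranking`.
#' @export
rank_random <- function(ensemble, seed = 1L) {
  scores <- with_seed(seed, stats::rnorm(length(ensemble$conformers)))
  .cb_rank_by(ensemble, "random", scores, "ascending")
}

#' Generator-order baseline
#'
#' Keeps the conformer generator's native output order (the analogue of
#' ranking by torsion-likelihood in knowledge-based generators).
#'
#' @param ensemble a `cb_ensemble`.
#' @return A `cb_ranking`.
#' @export
rank_generator_order <- function(ensemble) {
  go <- .cb_gen_orders(ensemble)
  .cb_rank_by(ensemble, "generator_order", as.numeric(go), "ascending")
}

#' Single-point force-field energies of an ensemble
#'
#' Writes the heavy-atom conformers to SDF, adds hydrogens with OpenBabel,
#' and evaluates single-point MMFF94 energies with `obenergy`.
#'
#' @param ensemble a `cb_ensemble`.
#' @param forcefield force field name understood by `obenergy`.
#' @return Numeric vector of energies (kcal/mol), `NA` where typing failed.
#' @export
conformer_energy <- function(ensemble, forcefield = "MMFF94") {
  tmp <- tempfile(fileext = ".sdf"); tmph <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp, tmph)))
  bare <- list(list(mol = ensemble$mol, conformers = ensemble$conformers))
  write_sdf_ensembles(bare, tmp)
  system2(.cb_tool("obabel"), c(tmp, "-osdf", "-O", tmph, "-h"),
          stdout = FALSE, stderr = FALSE)
  out <- suppressWarnings(
    system2(.cb_tool("obenergy"), c("-ff", forcefield, tmph),
            stdout = TRUE, stderr = FALSE))
  vals <- as.numeric(sub(".*TOTAL ENERGY =\\s*([-0-9.eE+]+).*", "\\1",
                         grep("TOTAL ENERGY", out, value = TRUE)))
  n <- length(ensemble$conformers)
  if (length(vals) != n) {
    warning("force-field typing failed for ", ensemble$mol$mol_id,
            ": got ", length(vals), " energies for ", n, " conformers")
    return(rep(NA_real_, n))
  }
  vals
}

#' Ascending potential-energy baseline
#'
#' @param ensemble a `cb_ensemble`.
#' @param forcefield passed to [conformer_energy()].
#' @return A `cb_ranking`, or `NULL` (skip signal) when the force field
#'   cannot type the molecule.
#' @export
rank_energy <- function(ensemble, forcefield = "MMFF94") {
  en <- conformer_energy(ensemble, forcefield)
  if (anyNA(en)) return(NULL)
  .cb_rank_by(ensemble, "energy", en, "ascending")
}

# Deterministic unit sphere points (golden-spiral construction).
.cb_sphere_points <- function(n = 256L) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area of a conformer
#'
#' Shrake-Rupley over the heavy atoms with Bondi radii and a water-probe
#' radius of 1.4 Angstrom, using a fixed deterministic point set.
#'
#' @param coords N x 3 coordinates (Angstrom).
#' @param z atomic numbers.
#' @param probe probe radius in Angstrom.
#' @param n_points sphere points per atom.
#' @return SASA in square Angstrom.
#' @export
conformer_sasa <- function(coords, z, probe = 1.4, n_points = 256L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  radii <- vdw_radius(z) + probe
  sphere <- .cb_sphere_points(n_points)
  # sample directions in the conformer's principal-axis frame so the
  # discretized area is invariant under rigid motion; axes are oriented by
  # the sign of the coordinate skewness along each axis (itself a rigid
  # invariant). Exactly degenerate or symmetric shapes may pick either
  # orientation, where the area is symmetric anyway.
  if (n >= 3) {
    centred <- sweep(coords, 2, colMeans(coords))
    ev <- eigen(stats::cov(coords), symmetric = TRUE)$vectors
    for (k in 1:3) {
      skew <- sum((centred %*% ev[, k])^3)
      if (skew < 0) ev[, k] <- -ev[, k]
    }
    if (det(ev) < 0) ev[, 3] <- -ev[, 3]
    sphere <- sphere %*% t(ev)
  }
  total <- 0
  for (a in seq_len(n)) {
    pts <- sweep(sphere * radii[a], 2, coords[a, ], "+")
    others <- setdiff(seq_len(n), a)
    close <- others[sqrt(rowSums(sweep(coords[others, , drop = FALSE], 2,
                                       coords[a, ])^2)) < radii[a] + radii[others]]
    acc <- rep(TRUE, n_points)
    for (b in close) {
      d2 <- rowSums(sweep(pts, 2, coords[b, ])^2)
      acc <- acc & d2 > radii[b]^2
      if (!any(acc)) break
    }
    total <- total + 4 * pi * radii[a]^2 * mean(acc)
  }
  total
}

#' Descending-SASA baseline
#'
#' @param ensemble a `cb_ensemble`.
#' @return A `cb_ranking`.
#' @export
rank_sasa <- function(ensemble) {
  z <- ensemble$mol$elements
  scores <- vapply(ensemble$conformers,
                   function(cf) conformer_sasa(cf$coords, z), 0)
  .cb_rank_by(ensemble, "sasa", scores, "descending")
}

#' Mass-weighted radius of gyration
#'
#' @param coords N x 3 coordinates.
#' @param z atomic numbers (for masses).
#' @return RGyr in Angstrom.
#' @export
conformer_rgyr <- function(coords, z) {
  coords <- as.matrix(coords)
  m <- atomic_mass(z)
  com <- colSums(coords * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(coords, 2, com)^2)) / sum(m))
}

#' Descending radius-of-gyration baseline
#'
#' @param ensemble a `cb_ensemble`.
#' @return A `cb_ranking`.
#' @export
rank_rgyr <- function(ensemble) {
  z <- ensemble$mol$elements
  scores <- vapply(ensemble$conformers,
                   function(cf) conformer_rgyr(cf$coords, z), 0)
  .cb_rank_by(ensemble, "rgyr", scores, "descending")
}

#' Oracle ranker by true ARMSD_bio
#'
#' Ranks by the true label value; the ceiling every practical ranker is
#' compared against.
#'
#' @param ensemble a labelled `cb_ensemble`.
#' @return A `cb_ranking`.
#' @export
rank_oracle <- function(ensemble) {
  .cb_rank_by(ensemble, "oracle", ensemble$armsd_bio, "ascending")
}

# ---- nearest reference / MCS / TFD ---------------------------------------

#' Nearest reference molecule by fingerprint Tanimoto
#'
#' @param test_mol a `cb_molecule`.
#' @param reference_set named list of reference `cb_molecule` (names =
#'   mol_ids) or list carrying `mol` fields.
#' @return The mol_id of the most similar reference (ties broken by
#'   lexicographic mol_id).
#' @export
find_nearest_reference <- function(test_mol, reference_set) {
  if (!length(reference_set)) stop("reference set is empty")
  mols <- lapply(reference_set, function(r) {
    if (inherits(r, "cb_molecule")) r else r[["mol"]]
  })
  fp_t <- morgan_fp(test_mol)
  ids <- vapply(mols, function(m) m$mol_id, "")
  sims <- vapply(mols, function(m) tanimoto(fp_t, morgan_fp(m)), 0)
  ord <- order(-sims, ids)
  unname(ids[ord][1])
}

# Maximum common (connected, induced) substructure by McGregor-style
# backtracking with a wall-clock cap. Atoms are compatible when element and
# formal charge agree; bonds when their normalized colours agree; fully
# mapped tetrahedral centres must agree in parity when both are specified.
#' Maximum common substructure between two molecules
#'
#' @param test_mol,ref_mol standardized `cb_molecule` objects.
#' @param time_cap seconds of search budget; on expiry the best mapping
#'   found so far is returned with `timed_out = TRUE`.
#' @return Object of class `cb_mcs`: `reference_mol_id`, `pairs` (test,
#'   reference index matrix), `n_heavy`, `torsions` (test-side quadruples
#'   whose four atoms are all mapped), `timed_out`.
#' @export
mcs <- function(test_mol, ref_mol, time_cap = 10) {
  n1 <- n_heavy_atoms(test_mol); n2 <- n_heavy_atoms(ref_mol)
  adj1 <- adjacency_list(test_mol); adj2 <- adjacency_list(ref_mol)
  vc1 <- .cb_vertex_colors(test_mol); vc2 <- .cb_vertex_colors(ref_mol)
  bc <- function(mol, colmap) {
    e <- new.env(hash = TRUE)
    col <- .cb_bond_colors(mol)
    for (k in seq_len(nrow(mol$bonds)))
      assign(paste(mol$bonds$i[k], mol$bonds$j[k]), col[k], e)
    e
  }
  e1 <- bc(test_mol); e2 <- bc(ref_mol)
  col1 <- function(a, b) {
    key <- if (a < b) paste(a, b) else paste(b, a)
    if (exists(key, e1)) get(key, e1) else NA_integer_
  }
  col2 <- function(a, b) {
    key <- if (a < b) paste(a, b) else paste(b, a)
    if (exists(key, e2)) get(key, e2) else NA_integer_
  }
  deadline <- Sys.time() + time_cap
  state <- new.env()
  state$best <- integer(0)      # map1: test index -> ref index (NA unmapped)
  state$best_size <- 0L
  state$timed_out <- FALSE
  upper <- min(n1, n2)

  chirality_ok <- function(map1, a) {
    # check parity of a fully mapped specified stereocentre
    if (test_mol$chiral[a] == 0L) return(TRUE)
    b <- map1[a]
    if (is.na(b) || b < 0 || ref_mol$chiral[b] == 0L) return(TRUE)
    nb <- adj1[[a]]
    if (any(is.na(map1[nb]) | map1[nb] < 0)) return(TRUE)  # not fully mapped
    if (length(nb) != length(adj2[[b]])) return(TRUE)
    sgn <- .cb_perm_sign(rank(map1[nb]))
    test_mol$chiral[a] * sgn == ref_mol$chiral[b]
  }

  extend <- function(map1, map2, size) {
    if (state$timed_out) return()
    if (size > state$best_size) {
      state$best <- map1
      state$best_size <- size
    }
    if (state$best_size >= upper) return()
    if (Sys.time() > deadline) { state$timed_out <- TRUE; return() }
    un1 <- sum(is.na(map1))          # excluded atoms (-1) no longer count
    if (size + min(un1, sum(is.na(map2))) <= state$best_size) return()
    # frontier: unmapped, not-excluded test atoms adjacent to the mapped core
    mapped1 <- which(!is.na(map1) & map1 > 0)
    cand_a <- if (length(mapped1))
      intersect(setdiff(unique(unlist(adj1[mapped1])), which(!is.na(map1))),
                which(is.na(map1)))
    else which(is.na(map1))
    if (!length(cand_a)) return()
    # branch on the frontier atom with the fewest compatible images
    opts <- lapply(cand_a, function(a) {
      anchors <- intersect(adj1[[a]], mapped1)
      base <- if (length(anchors))
        intersect(adj2[[map1[anchors[1]]]], which(is.na(map2)))
      else which(is.na(map2))
      Filter(function(b) {
        if (vc1[a] != vc2[b]) return(FALSE)
        # induced consistency both ways over the mapped core
        for (x in mapped1) {
          cab <- col1(a, x); cxy <- col2(b, map1[x])
          if (!identical(is.na(cab), is.na(cxy))) return(FALSE)
          if (!is.na(cab) && cab != cxy) return(FALSE)
        }
        TRUE
      }, base)
    })
    k <- which.min(lengths(opts))
    a <- cand_a[k]
    for (b in opts[[k]]) {
      map1[a] <- b; map2[b] <- a
      if (chirality_ok(map1, a) && all(vapply(adj1[[a]], function(x) {
        is.na(map1[x]) || chirality_ok(map1, x)
      }, TRUE)))
        extend(map1, map2, size + 1L)
      map1[a] <- NA_integer_; map2[b] <- NA_integer_
      if (state$timed_out) return()
    }
    # also allow excluding this frontier atom entirely
    map1[a] <- -1L   # sentinel: excluded
    extend(map1, map2, size)
    map1[a] <- NA_integer_
  }

  # seed pairs: rarest element first tends to land inside a shared core.
  # each seed commits one test atom to the mapping; further seeds are tried
  # until the bound is provably reached, time expires, or the search found a
  # mapping covering most of the smaller molecule (good-enough heuristic).
  seeds <- order(table(vc1)[as.character(vc1)], -lengths(adj1))
  map1 <- rep(NA_integer_, n1); map2 <- rep(NA_integer_, n2)
  for (a in seeds) {
    if (state$best_size >= upper || state$timed_out) break
    if (state$best_size >= ceiling(0.8 * upper) && state$best_size > 0L) break
    for (b in which(vc2 == vc1[a])) {
      map1[a] <- b; map2[b] <- a
      extend(map1, map2, 1L)
      map1[a] <- NA_integer_; map2[b] <- NA_integer_
      if (state$best_size >= upper || state$timed_out) break
    }
  }
  best <- state$best
  best[!is.na(best) & best < 0] <- NA_integer_
  mapped <- which(!is.na(best))
  quads <- torsion_quadruples(test_mol)
  in_mcs <- apply(as.matrix(quads), 1, function(q) all(q %in% mapped))
  structure(list(reference_mol_id = ref_mol$mol_id,
                 pairs = cbind(test = mapped, reference = best[mapped]),
                 n_heavy = length(mapped),
                 torsions = quads[which(in_mcs), , drop = FALSE],
                 timed_out = state$timed_out),
            class = "cb_mcs")
}

#' @export
print.cb_mcs <- function(x, ...) {
  cat(sprintf("<cb_mcs vs %s: %d heavy atoms, %d torsions%s>\n",
              x$reference_mol_id, x$n_heavy, nrow(x$torsions),
              if (x$timed_out) ", timed out (best so far)" else ""))
  invisible(x)
}

# Torsion weights: 2^(-d) with d the topological distance of the torsion's
# central bond from the graph centre (minimum-eccentricity atoms).
.cb_torsion_weights <- function(mol, quads) {
  g <- mol_graph(mol)
  dmat <- igraph::distances(g)
  ecc <- apply(dmat, 1, max)
  centre <- which(ecc == min(ecc))
  vapply(seq_len(nrow(quads)), function(k) {
    d <- min(dmat[quads$a[k], centre], dmat[quads$b[k], centre])
    2^(-d)
  }, 0)
}

#' Torsion fingerprint deviation over MCS torsions
#'
#' The normalized, centre-weighted aggregate of torsion-angle deviations
#' between a test conformer and the reference bioactive conformation,
#' restricted to torsions whose four atoms all lie in the MCS. Each
#' deviation is |delta| / 180 with delta the circular angle difference;
#' weights halve with every bond separating the torsion from the molecular
#' centre and are computed on the whole test molecule, restricted to the
#' MCS torsion set.
#'
#' @param test_conf `cb_conformer` (or coordinates) of the test molecule.
#' @param ref_conf `cb_conformer` (or coordinates) of the reference.
#' @param match a `cb_mcs` between test and reference molecules.
#' @param test_mol the test `cb_molecule`.
#' @return TFD in \[0, 1\]; `NA` with class attribute when the MCS carries
#'   no torsion.
#' @export
tfd_mcs <- function(test_conf, ref_conf, match, test_mol) {
  quads <- match$torsions
  if (!nrow(quads)) return(structure(NA_real_, no_torsion = TRUE))
  A <- if (inherits(test_conf, "cb_conformer")) test_conf$coords else test_conf
  B <- if (inherits(ref_conf, "cb_conformer")) ref_conf$coords else ref_conf
  sigma <- rep(NA_integer_, n_heavy_atoms(test_mol))
  sigma[match$pairs[, "test"]] <- match$pairs[, "reference"]
  w <- .cb_torsion_weights(test_mol, quads)
  dev <- vapply(seq_len(nrow(quads)), function(k) {
    q <- as.integer(unlist(quads[k, ]))
    ta <- get_torsion(A, q)
    tb <- get_torsion(B, sigma[q])
    d <- abs(ta - tb) %% 360
    min(d, 360 - d) / 180
  }, 0)
  sum(w * dev) / sum(w)
}

#' Bioactivity-based TFD2SimRefMCS ranker
#'
#' For a test ensemble: find the nearest reference molecule by fingerprint
#' Tanimoto, compute the chirality-respecting MCS, and rank conformers by
#' ascending TFD (over MCS torsions) to the reference's bioactive
#' conformation. When the MCS carries no torsion the ranker falls back to
#' the generator order and flags it.
#'
#' @param ensemble the test `cb_ensemble`.
#' @param reference_set named list of reference ensembles (each with `mol`
#'   and non-empty `bioactive`).
#' @param time_cap MCS search budget in seconds.
#' @return A `cb_ranking` with attributes `reference_mol_id`, `mcs_n_heavy`
#'   and (on fallback) `no_torsion_fallback = TRUE`.
#' @export
rank_tfd2simrefmcs <- function(ensemble, reference_set, time_cap = 10) {
  ref_id <- find_nearest_reference(ensemble$mol, reference_set)
  ref <- reference_set[[ref_id]]
  if (!length(ref$bioactive))
    stop("reference ", ref_id, " carries no bioactive conformation")
  m <- mcs(ensemble$mol, ref$mol, time_cap = time_cap)
  ref_conf <- ref$bioactive[[1]]
  scores <- vapply(ensemble$conformers, function(cf) {
    as.numeric(tfd_mcs(cf, ref_conf, m, ensemble$mol))
  }, 0)
  if (anyNA(scores)) {
    rk <- rank_generator_order(ensemble)
    rk$ranker_name <- "tfd2simrefmcs"
    attr(rk, "no_torsion_fallback") <- TRUE
    attr(rk, "reference_mol_id") <- ref_id
    return(rk)
  }
  rk <- .cb_rank_by(ensemble, "tfd2simrefmcs", scores, "ascending")
  attr(rk, "reference_mol_id") <- ref_id
  attr(rk, "mcs_n_heavy") <- m$n_heavy
  rk
}

#' Pair conformers of two molecules by binned MCS torsions
#'
#' Two conformers pair when every MCS torsion falls into the same angular
#' bin; bins tile \[-180, 180) degrees. Used to compare model predictions
#' across molecules sharing a substructure.
#'
#' @param ensemble_a,ensemble_b ensembles of the two molecules.
#' @param match `cb_mcs` from molecule A to molecule B.
#' @param bin_width_deg angular bin width (10 or 20 typical).
#' @return data.frame of paired `conf_a`, `conf_b` ids.
#' @export
match_conformers_by_mcs_torsions <- function(ensemble_a, ensemble_b, match,
                                             bin_width_deg = 10) {
  quads <- match$torsions
  if (!nrow(quads)) return(data.frame(conf_a = integer(), conf_b = integer()))
  sigma <- rep(NA_integer_, n_heavy_atoms(ensemble_a$mol))
  sigma[match$pairs[, "test"]] <- match$pairs[, "reference"]
  bin_of <- function(coords, q) {
    ang <- get_torsion(coords, q)
    floor((ang + 180) / bin_width_deg)
  }
  key_a <- vapply(ensemble_a$conformers, function(cf) {
    paste(vapply(seq_len(nrow(quads)), function(k)
      bin_of(cf$coords, as.integer(unlist(quads[k, ]))), 0), collapse = ",")
  }, "")
  key_b <- vapply(ensemble_b$conformers, function(cf) {
    paste(vapply(seq_len(nrow(quads)), function(k)
      bin_of(cf$coords, sigma[as.integer(unlist(quads[k, ]))]), 0), collapse = ",")
  }, "")
  ids_a <- .cb_conf_ids(ensemble_a); ids_b <- .cb_conf_ids(ensemble_b)
  pairs <- which(outer(key_a, key_b, "=="), arr.ind = TRUE)
  data.frame(conf_a = ids_a[pairs[, 1]], conf_b = ids_b[pairs[, 2]])
}

#' Thermal energy window
#'
#' `multiple * kB * T` in kcal/mol with kB = 1.987e-3 kcal/(mol K); e.g.
#' three thermal quanta at 298 K are 1.78 kcal/mol, a common strain-energy
#' window when screening conformers by energy.
#'
#' @param multiple non-negative multiple of kB T.
#' @param temperature_K absolute temperature.
#' @return Energy in kcal/mol.
#' @export
thermal_energy_window <- function(multiple, temperature_K) {
  stopifnot(multiple >= 0, temperature_K > 0)
  multiple * 1.987e-3 * temperature_K
}

#' Write rankings as a TSV table
#'
#' @param rankings list of `cb_ranking`.
#' @param path output path.
#' @return The table, invisibly.
#' @export
write_ranking_table <- function(rankings, path) {
  tab <- do.call(rbind, lapply(rankings, function(rk) {
    data.frame(mol_id = rk$mol_id, ranker = rk$ranker_name,
               rank = seq_along(rk$order), conf_id = rk$order,
               score = rk$scores)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
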