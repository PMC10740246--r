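# Self-contained synthetic benchmarks that emulate a curated set of
# protein-ligand complex ligands: drug-like molecules, each with one or two
# designated "bioactive" 3D references and a generated conformer ensemble
# whose ARMSD_bio spectrum spans the bioactive-like (< 1 A) and
# non-bioactive (> 2.5 A) regimes. Family mode produces groups of molecules
# sharing a large (>= 20 heavy atom) core with consistent core torsions in
# their bioactive references, reproducing the situation in which
# similarity-based ranking methods and substructure-memorizing models
# thrive.

#' Built-in pool of drug-like structures
#'
#' A small set of known drug molecules spanning roughly 1-12 rotatable
#' bonds, used by the plain (non-family) synthetic benchmark.
#'
#' @return Named character vector of SMILES.
#' @export
drug_smiles_pool <- function() {
  c(aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    naproxen = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    diphenhydramine = "CN(C)CCOC(c1ccccc1)c1ccccc1",
    chlorpromazine = "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",
    atenolol = "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
    lidocaine = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
    procaine = "CCN(CC)CCOC(=O)c1ccc(N)cc1",
    tolbutamide = "CCCCNC(=O)NS(=O)(=O)c1ccc(C)cc1",
    warfarin_like = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
    sulfamethoxazole = "Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1",
    melatonin = "COc1ccc2[nH]cc(CCNC(C)=O)c2c1",
    benzocaine = "CCOC(=O)c1ccc(N)cc1",
    phenylbutyrate = "OC(=O)CCCc1ccccc1",
    fenofibrate_like = "CC(C)OC(=O)C(C)(C)Oc1ccc(cc1)C(=O)c1ccc(Cl)cc1")
}

#' Shared-core family templates
#'
#' Six sprintf templates, each a drug-like core of at least 20 heavy atoms
#' with a terminal substitution point, plus the substituent set used to
#' derive family members. Substituent atoms always follow the core atoms in
#' the SMILES, so the core occupies the same atom indices in every member.
#'
#' @return List with `templates` (named character) and `substituents`.
#' @export
family_templates <- function() {
  list(
    # six families spanning the flexibility range of a curated ligand set:
    # two highly flexible cores (12-13 rotatable bonds, rich in
    # non-bioactive conformers), two moderate ones, and two low-flexibility
    # cores (4-6 rotatable bonds, dense in bioactive-like conformers)
    templates = c(
      famA = "O=C(c1ccc(OCCCc2ccccc2)cc1)NCCCN(C)Cc1ccc(cc1)%s",
      famB = "O=C(c1ccc(CN(C)Cc2ccccc2)cc1)NCCOCCOc1ccc(cc1)%s",
      famC = "O=C(N1CCOCC1)COc1ccc(cc1)NC(=O)Cc1ccc(cc1)%s",
      famD = "CS(=O)(=O)NCCN(C)C(=O)c1ccc(cc1)Cc1ccc(cc1)%s",
      famE = "O=C(Nc1ccc2ccccc2c1)c1ccc(cc1)O%s",
      famF = "CC(C)(C)c1ccc(cc1)S(=O)(=O)Nc1ccc(cc1)C%s"),
    substituents = c("", "C", "CC", "O", "OC", "N", "F", "Cl", "Br",
                     "C(C)C", "CO", "OCC", "C(F)(F)F", "CN"))
}

#' Specification of a synthetic benchmark
#'
#' @param n_molecules number of molecules to produce.
#' @param max_conformers generated ensemble budget per molecule.
#' @param family_structure build shared-core families (TRUE) or sample the
#'   plain drug pool (FALSE).
#' @param target_frac_with_bio_like fraction of molecules whose bioactive
#'   reference is designed to be retrievable by the generator (at least one
#'   bioactive-like conformer).
#' @param p_second_bioactive probability a molecule carries two bioactive
#'   references.
#' @param jitter_sd_deg torsion jitter (degrees) applied when deriving a
#'   bioactive reference from a generated conformer.
#' @param seed master seed; the whole benchmark is reproducible from it.
#' @return List of class `cb_synth_spec`.
#' @export
synthetic_spec <- function(n_molecules = 60L, max_conformers = 250L,
                           family_structure = TRUE,
                           target_frac_with_bio_like = 0.8,
                           p_second_bioactive = 0.3,
                           jitter_sd_deg = 5, seed = 1L) {
  stopifnot(n_molecules >= 1, max_conformers >= 1,
            target_frac_with_bio_like >= 0, target_frac_with_bio_like <= 1,
            p_second_bioactive >= 0, p_second_bioactive <= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 max_conformers = as.integer(max_conformers),
                 family_structure = isTRUE(family_structure),
                 target_frac_with_bio_like = target_frac_with_bio_like,
                 p_second_bioactive = p_second_bioactive,
                 jitter_sd_deg = jitter_sd_deg, seed = as.integer(seed)),
            class = "cb_synth_spec")
}

# Torsion quadruples fully contained in the first n_core atoms, with
# index-based neighbour convention so they are identical across family
# members sharing the core numbering.
.cb_core_quads <- function(mol, n_core) {
  quads <- torsion_quadruples(mol, convention = "index")
  keep <- quads$na <= n_core & quads$a <= n_core & quads$b <= n_core &
    quads$nb <= n_core
  quads[keep, , drop = FALSE]
}

.cb_circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Derive a bioactive reference from a generated conformer: set the listed
# torsions to target angles plus jitter; remaining torsions keep the base
# conformer's values (side chains differ between reference and ensemble).
.cb_make_reference <- function(mol, base_coords, quads, targets, jitter_sd) {
  coords <- base_coords
  for (k in seq_len(nrow(quads))) {
    coords <- set_torsion(mol, coords, as.integer(unlist(quads[k, ])),
                          targets[k] + stats::rnorm(1, 0, jitter_sd))
  }
  coords
}

#' Generate a synthetic benchmark dataset
#'
#' For every molecule, a conformer ensemble is generated with the seeded
#' distance-geometry generator; one (sometimes two) bioactive references
#' are derived as torsion-jittered copies of generated conformers and
#' withheld from the ensemble, and ARMSD_bio labels are computed. In family
#' mode, members of a family share a core and their bioactive references
#' share the family's canonical core torsions, so that a reference-based
#' torsion comparison can recognize bioactive-like conformers of unseen
#' members. A controlled fraction of molecules receives a deliberately
#' unretrievable reference (core torsions pushed off the generator's
#' rotamer wells).
#'
#' @param spec a [synthetic_spec()].
#' @return List of class `cb_benchmark`: `ensembles` (named list of
#'   labelled `cb_ensemble`), `class_labels` (data.frame mol_id/group, the
#'   family label in family mode), `flags` (per-molecule notes where the
#'   design target could not be met after retries).
#' @export
make_benchmark <- function(spec = synthetic_spec()) {
  fam <- family_templates()
  with_seed(spec$seed, {
    if (spec$family_structure) {
      fam_names <- names(fam$templates)
      fam_assign <- sort(rep(fam_names, length.out = spec$n_molecules))
      smiles <- character(0); mol_ids <- character(0); groups <- character(0)
      for (f in fam_names) {
        nmem <- sum(fam_assign == f)
        if (!nmem) next
        subs <- rep(fam$substituents, length.out = nmem)  # first is "", the bare core
        for (k in seq_len(nmem)) {
          smiles <- c(smiles, sprintf(fam$templates[[f]], subs[k]))
          mol_ids <- c(mol_ids, sprintf("%s_%02d", f, k))
          groups <- c(groups, f)
        }
      }
    } else {
      pool <- drug_smiles_pool()
      pick <- sample(length(pool), spec$n_molecules, replace = TRUE)
      smiles <- unname(pool[pick])
      mol_ids <- sprintf("%s_%02d", names(pool)[pick], seq_len(spec$n_molecules))
      groups <- rep(NA_character_, spec$n_molecules)
    }
    raw <- generate_conformer_ensembles(smiles, mol_ids,
                                        max_n = spec$max_conformers,
                                        seed = spec$seed)
    flags <- attr(raw, "failures")
    if (length(flags)) flags <- paste0(flags, ": embedding failure")
    # per-family canonical core torsions, taken from the first member
    core_info <- list()
    if (spec$family_structure) {
      n_core <- vapply(names(fam$templates), function(f) {
        bare <- raw[[paste0(f, "_01")]]
        if (is.null(bare)) return(NA_integer_)
        # substituent "" on member 1: whole molecule is the core
        n_heavy_atoms(bare$mol)
      }, 0L)
      for (f in names(fam$templates)) {
        first <- raw[[paste0(f, "_01")]]
        if (is.null(first)) next
        quads <- .cb_core_quads(first$mol, n_core[[f]])
        # canonical family torsions: the dominant rotamer well per core
        # torsion, as the circular mean of the most-populated 30-degree bin
        # over the first member's ensemble
        theta <- vapply(seq_len(nrow(quads)), function(k) {
          q <- as.integer(unlist(quads[k, ]))
          tors <- vapply(first$conformers, function(cf)
            get_torsion(cf$coords, q), 0)
          bin <- floor((tors + 180) / 30)
          top <- as.integer(names(which.max(table(bin))))
          inb <- tors[bin == top]
          atan2(mean(sin(inb * pi / 180)), mean(cos(inb * pi / 180))) * 180 / pi
        }, 0)
        core_info[[f]] <- list(n_core = n_core[[f]], quads = quads,
                               theta = theta)
      }
    }
    ensembles <- list()
    for (m in seq_along(mol_ids)) {
      id <- mol_ids[m]
      ens <- raw[[id]]
      if (is.null(ens)) next
      mol <- ens$mol
      mol$smiles <- smiles[m]
      retrievable <- stats::runif(1) < spec$target_frac_with_bio_like
      n_bio <- 1L + stats::rbinom(1, 1, spec$p_second_bioactive)
      ci <- if (spec$family_structure) core_info[[groups[m]]] else NULL
      quads <- if (!is.null(ci)) ci$quads else torsion_quadruples(mol)
      # unretrievable design: push every core torsion off the rotamer wells
      # the generator samples (roughly half-way between wells), so no
      # generated conformer comes close to the reference
      draw_offsets <- function() {
        if (retrievable || nrow(quads) == 0) return(numeric(nrow(quads)))
        stats::runif(nrow(quads), 35, 55) *
          sample(c(-1, 1), nrow(quads), replace = TRUE)
      }
      offsets <- draw_offsets()
      pick_base <- function(exclude = integer(0)) {
        cand <- setdiff(seq_along(ens$conformers), exclude)
        if (!is.null(ci) && nrow(quads) > 0) {
          dist <- vapply(cand, function(j) {
            tors <- vapply(seq_len(nrow(quads)), function(k)
              get_torsion(ens$conformers[[j]]$coords,
                          as.integer(unlist(quads[k, ]))), 0)
            sum(.cb_circ_diff(tors, ci$theta))
          }, 0)
          cand[order(dist)][1]
        } else cand[sample.int(length(cand), 1)]
      }
      labelled <- NULL; used <- integer(0)
      for (attempt in seq_len(5L)) {
        bases <- integer(0)
        bio <- list()
        for (bidx in seq_len(n_bio)) {
          base_j <- pick_base(exclude = c(used, bases))
          bases <- c(bases, base_j)
          base <- ens$conformers[[base_j]]
          # the reference is a torsion-jittered copy of the base conformer;
          # for unretrievable designs every torsion is additionally pushed
          # off its rotamer well
          targets <- if (nrow(quads) > 0)
            vapply(seq_len(nrow(quads)), function(k)
              get_torsion(base$coords, as.integer(unlist(quads[k, ]))), 0) +
            offsets
          else numeric(0)
          coords <- .cb_make_reference(mol, base$coords, quads, targets,
                                       spec$jitter_sd_deg)
          bio[[bidx]] <- conformer_record(id, 1000L + bidx, coords,
                                          source = "bioactive")
        }
        labelled <- build_labelled_ensemble(mol, ens$conformers, bio)
        ok_bio <- if (retrievable) labelled$retrieved else !labelled$retrieved
        ok_non <- any(labelled$labels == "non_bio")
        if (ok_bio && ok_non) break
        used <- c(used, bases)
        offsets <- draw_offsets()
        if (length(used) >= length(ens$conformers) - n_bio) break
      }
      if (retrievable && !labelled$retrieved)
        flags <- c(flags, paste0(id, ": designed retrieval not met"))
      if (!retrievable && labelled$retrieved)
        flags <- c(flags, paste0(id, ": designed non-retrieval not met"))
      if (!any(labelled$labels == "non_bio"))
        flags <- c(flags, paste0(id, ": no non-bioactive conformer"))
      labelled$family <- groups[m]
      ensembles[[id]] <- labelled
    }
    structure(list(ensembles = ensembles,
                   class_labels = data.frame(
                     mol_id = names(ensembles),
                     group = vapply(ensembles, function(e)
                       if (is.null(e$family)) NA_character_ else e$family, "")),
                   flags = flags, spec = spec),
              class = "cb_benchmark")
  })
}

#' @export
print.cb_benchmark <- function(x, ...) {
  nb <- vapply(x$ensembles, function(e) sum(e$labels == "bio_like"), 0)
  cat(sprintf(
    "<cb_benchmark: %d molecules, %d retrieved, median %d conformers, %d flags>\n",
    length(x$ensembles),
    sum(vapply(x$ensembles, function(e) e$retrieved, TRUE)),
    as.integer(stats::median(vapply(x$ensembles,
                                    function(e) length(e$labels), 0))),
    length(x$flags)))
  invisible(x)
}

#' Closed-form toy geometries used across the test-suite
#'
#' Small fixtures with analytically known expected values: a collinear
#' two-atom pair (ARMSD exactly 1 A), a benzene ring and its rotated atom
#' relabelling (ARMSD 0 under symmetry), a tetrahedral chiral centre in
#' both mirror forms, and a two-copy "supermolecule" placed beyond any
#' reasonable neighbourhood cutoff (network output exactly twice the
#' single copy).
#'
#' @return Named list of fixtures, each carrying its `expected` values.
#' @export
make_toy_geometries <- function() {
  ethane_like <- molecule_record("pair", c(6L, 6L),
                                 data.frame(i = 1L, j = 2L, order = 1))
  hexagon <- function(r) t(vapply(0:5, function(k)
    c(r * cos(k * pi / 3), r * sin(k * pi / 3), 0), numeric(3)))
  benz_bonds <- data.frame(i = 1:6, j = c(2:6, 1L),
                           order = c(2, 1, 2, 1, 2, 1))
  benzene <- molecule_record("benzene", rep(6L, 6), benz_bonds)
  chiral_mol <- molecule_record("chfclbr", c(6L, 9L, 17L, 35L),
                                data.frame(i = 1L, j = 2:4, order = 1))
  tet <- rbind(c(0, 0, 0),
               c(-0.816, -0.471, 0.333) * 1.35,   # F
               c(0.816, -0.471, 0.333) * 1.77,    # Cl
               c(0, 0.943, 0.333) * 1.94)         # Br (H implicit at -z)
  butane <- molecule_record("butane", rep(6L, 4),
                            data.frame(i = 1:3, j = 2:4, order = 1))
  but_coords <- cbind(c(0, 1.54, 2.05, 3.59),
                      c(0, 0, 1.45, 1.45), c(0, 0, 0, 0))
  list(
    collinear_pair = list(
      mol = ethane_like,
      a = cbind(c(-1, 1), 0, 0), b = cbind(c(-2, 2), 0, 0),
      expected = list(armsd = 1.0)),
    benzene_rotation = list(
      mol = benzene, a = hexagon(1.39),
      b = hexagon(1.39)[c(2:6, 1), ],
      expected = list(armsd = 0.0)),
    chiral_center = list(
      mol = chiral_mol, r_coords = tet,
      s_coords = tet %*% diag(c(-1, 1, 1)),
      expected = list(r_parity_differs_from_s = TRUE)),
    two_copy = list(
      mol = butane, single = but_coords,
      double = rbind(but_coords,
                     sweep(but_coords, 2, c(30, 0, 0), "+")),
      z_single = rep(6L, 4), z_double = rep(6L, 8),
      expected = list(output_ratio = 2.0))
  )
}
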