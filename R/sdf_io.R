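# SDF (V2000) input/output via ChemmineR, converting between SDF records and
# the package's molecule/conformer records.

#' Construct a conformer record
#'
#' One 3D geometry of a molecule over its heavy atoms.
#'
#' @param mol_id molecule identifier the geometry belongs to.
#' @param conf_id integer conformer identifier, unique within the molecule.
#' @param coords numeric N x 3 matrix of Cartesian coordinates in Angstrom,
#'   rows in molecule atom order.
#' @param source `"generated"` or `"bioactive"`.
#' @param gen_order integer rank in the generator's native output sequence
#'   (generated conformers only).
#' @return An object of class `cb_conformer`.
#' @export
conformer_record <- function(mol_id, conf_id, coords,
                             source = c("generated", "bioactive"),
                             gen_order = NA_integer_) {
  source <- match.arg(source)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  if (!all(is.finite(coords))) stop("non-finite coordinates in conformer ",
                                    conf_id, " of ", mol_id)
  dimnames(coords) <- NULL
  structure(list(mol_id = as.character(mol_id),
                 conf_id = as.integer(conf_id),
                 coords = coords, source = source,
                 gen_order = as.integer(gen_order)),
            class = "cb_conformer")
}

#' @export
print.cb_conformer <- function(x, ...) {
  cat(sprintf("<cb_conformer %s/%d: %d atoms, %s%s>\n", x$mol_id, x$conf_id,
              nrow(x$coords), x$source,
              if (is.na(x$gen_order)) "" else paste0(", gen_order ", x$gen_order)))
  invisible(x)
}

# Convert one ChemmineR SDF object (plus its raw text lines, for M CHG) into
# a molecule record and coordinate matrix. Hydrogens are dropped on read.
.cb_from_sdf <- function(sdf, lines, mol_id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  syms <- gsub("_[0-9]+$", "", rownames(ab))
  z <- symbol_to_z(syms)
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  nb <- if (is.null(dim(bb))) 0L else nrow(bb)
  bonds <- if (nb) data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                              order = as.numeric(bb[, 3]))
           else data.frame(i = integer(), j = integer(), order = numeric())
  charges <- integer(length(z))
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    cnt <- f[1]
    for (k in seq_len(cnt)) charges[f[2 * k]] <- f[2 * k + 1]
  }
  heavy <- z != 1L
  if (!all(heavy)) {
    idx_map <- cumsum(heavy)
    keep_bond <- heavy[bonds$i] & heavy[bonds$j]
    bonds <- bonds[keep_bond, , drop = FALSE]
    bonds$i <- idx_map[bonds$i]; bonds$j <- idx_map[bonds$j]
    z <- z[heavy]; coords <- coords[heavy, , drop = FALSE]
    charges <- charges[heavy]
  }
  list(mol = molecule_record(mol_id, z, bonds, charges), coords = coords)
}

# Split raw SDF text into per-record line chunks.
.cb_sdf_chunks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1) + 1L)
  Map(function(s, e) lines[s:e], starts, ends)
}

#' Read molecules and conformers from an SDF file
#'
#' Reads a (possibly multi-record) V2000 SDF file. Hydrogens are stripped;
#' each record becomes a conformer of the molecule named by its `mol_id`
#' property (falling back to the title line). Records sharing a `mol_id` are
#' collected into one ensemble; the molecular graph is taken from the first
#' record of each molecule.
#'
#' @param path SDF file path.
#' @return A list with one element per molecule: `mol` (cb_molecule) and
#'   `conformers` (list of cb_conformer). Conformer `source` and `gen_order`
#'   are taken from identically named SDF properties when present.
#' @export
read_sdf_ensembles <- function(path) {
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(path))
  chunks <- .cb_sdf_chunks(path)
  out <- list()
  for (k in seq_along(chunks)) {
    sdf <- sdfset[[k]]
    db <- ChemmineR::datablock(sdf)
    prop <- function(name, default) {
      if (length(db) && name %in% names(db)) db[[name]] else default
    }
    title <- ChemmineR::header(sdf)[["Molecule_Name"]]
    mol_id <- as.character(prop("mol_id", if (nzchar(title)) title
                                          else paste0("mol", k)))
    rec <- .cb_from_sdf(sdf, chunks[[k]], mol_id)
    src <- prop("source", "generated")
    go <- suppressWarnings(as.integer(prop("gen_order", NA)))
    cid <- suppressWarnings(as.integer(prop("conf_id", NA)))
    if (is.null(out[[mol_id]]))
      out[[mol_id]] <- list(mol = rec$mol, conformers = list())
    nconf <- length(out[[mol_id]]$conformers)
    conf <- conformer_record(mol_id,
                             if (is.na(cid)) nconf + 1L else cid,
                             rec$coords, source = src,
                             gen_order = if (is.na(go) && src == "generated")
                               nconf + 1L else go)
    out[[mol_id]]$conformers <- c(out[[mol_id]]$conformers, list(conf))
  }
  out
}

# Assemble a V2000 record as text for one conformer of a molecule.
.cb_sdf_record <- function(mol, coords, props = list()) {
  n <- n_heavy_atoms(mol)
  nb <- nrow(mol$bonds)
  lines <- c(mol$mol_id, "  confbias          3D", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  syms <- z_to_symbol(mol$elements)
  lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            coords[, 1], coords[, 2], coords[, 3], syms))
  if (nb)
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i,
                              mol$bonds$j, as.integer(round(mol$bonds$order))))
  chg <- which(mol$charges != 0L)
  if (length(chg))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, mol$charges[chg]),
                                    collapse = "")))
  lines <- c(lines, "M  END")
  for (nm in names(props))
    lines <- c(lines, sprintf(">  <%s>", nm), as.character(props[[nm]]), "")
  c(lines, "$$$$")
}

#' Write conformer ensembles to an SDF file
#'
#' One record per conformer with `mol_id`, `conf_id`, `source` and
#' `gen_order` properties; labelled ensembles additionally carry `armsd_bio`
#' and `label`.
#'
#' @param ensembles list as returned by [read_sdf_ensembles()] or a list of
#'   labelled ensembles from [build_labelled_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf_ensembles <- function(ensembles, path) {
  out <- character(0)
  for (ens in ensembles) {
    confs <- c(ens$conformers, ens$bioactive)
    for (k in seq_along(confs)) {
      cf <- confs[[k]]
      props <- list(mol_id = cf$mol_id, conf_id = cf$conf_id,
                    source = cf$source)
      if (!is.na(cf$gen_order)) props$gen_order <- cf$gen_order
      if (!is.null(ens$armsd_bio) && cf$source == "generated" &&
          k <= length(ens$armsd_bio)) {
        props$armsd_bio <- sprintf("%.6f", ens$armsd_bio[k])
        props$label <- ens$labels[k]
      }
      out <- c(out, .cb_sdf_record(ens$mol, cf$coords, props))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a standardized molecule table as TSV
#'
#' @param mols list of `cb_molecule`.
#' @param path output TSV path.
#' @return The table, invisibly.
#' @export
write_molecule_table <- function(mols, path) {
  tab <- data.frame(
    mol_id = vapply(mols, function(m) m$mol_id, ""),
    reference_structure = vapply(mols, function(m) m$smiles, ""),
    n_heavy_atoms = vapply(mols, n_heavy_atoms, 0L)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
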