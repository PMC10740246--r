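# Internal helpers shared across modules: element tables, deterministic
# hashing, scoped RNG, and wrappers around the external command-line tools.

# Element symbol <-> atomic number for the organic subset handled here.
.cb_elements <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53
)

# Average atomic masses (amu), used for mass-weighted radius of gyration.
.cb_masses <- c(
  `1` = 1.008, `5` = 10.81, `6` = 12.011, `7` = 14.007, `8` = 15.999,
  `9` = 18.998, `14` = 28.085, `15` = 30.974, `16` = 32.06,
  `17` = 35.45, `34` = 78.971, `35` = 79.904, `53` = 126.904
)

# Bondi van der Waals radii (Angstrom) for solvent-accessible surface area.
.cb_vdw <- c(
  `1` = 1.20, `5` = 1.92, `6` = 1.70, `7` = 1.55, `8` = 1.52, `9` = 1.47,
  `14` = 2.10, `15` = 1.80, `16` = 1.80, `17` = 1.75, `34` = 1.90,
  `35` = 1.85, `53` = 1.98
)

symbol_to_z <- function(sym) {
  z <- .cb_elements[sym]
  if (anyNA(z)) stop("unknown element symbol(s): ",
                     paste(unique(sym[is.na(z)]), collapse = ", "))
  unname(as.integer(z))
}

z_to_symbol <- function(z) {
  idx <- match(z, .cb_elements)
  if (anyNA(idx)) stop("unknown atomic number(s): ",
                       paste(unique(z[is.na(idx)]), collapse = ", "))
  names(.cb_elements)[idx]
}

atomic_mass <- function(z) unname(.cb_masses[as.character(z)])

vdw_radius <- function(z) {
  r <- .cb_vdw[as.character(z)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Deterministic polynomial hash of an integer vector. Modulus and base are
# kept small enough that all intermediates stay exactly representable in
# doubles (p * b < 2^53), so results are identical on every platform.
.cb_hash <- function(x) {
  p <- 67108859   # prime < 2^26
  b <- 1000003
  h <- 17
  x <- as.numeric(x) %% p
  for (v in x) h <- (h * b + v) %% p
  h
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

# Fan a master seed out to per-item seeds without exceeding .Machine 32-bit
# integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}

.cb_tool <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path)) stop("required external tool not found on PATH: ", name)
  unname(path)
}

# Stable order: primary key ascending/descending with gen_order as the
# deterministic tie-break used by every ranker.
stable_order <- function(score, tie, decreasing = FALSE) {
  order(if (decreasing) -score else score, tie)
}
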