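## Van der Waals radii sets (angstrom), keyed by element symbol. "protor"
## carries element-collapsed ProtOr-style values; "naccess" the classic
## NACCESS-like set. Unknown elements fall back per `unknown_radius` policy.
VDW_RADII_SETS <- list(
  protor = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
             H = 1.09, SE = 1.90, FE = 1.40, ZN = 1.39, MG = 1.73),
  naccess = c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
              H = 1.00, SE = 1.90, FE = 1.40, ZN = 1.39, MG = 1.73)
)

## Reference maximum accessible surface areas per residue type (angstrom^2),
## theoretical Gly-X-Gly extended-state values (Tien et al. 2013 style).
## Used to express residue SASA on a relative (0-1) scale.
MAX_ASA_TABLE <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

## Deterministic quasi-uniform unit-sphere points (golden-section spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(atoms, radii_set, radii_override, unknown_radius) {
  if (is.character(radii_set)) {
    if (!radii_set %in% names(VDW_RADII_SETS))
      stop("unknown radii set: ", radii_set)
    radii <- VDW_RADII_SETS[[radii_set]]
  } else radii <- radii_set
  if (length(radii_override)) radii[names(radii_override)] <- radii_override
  r <- unname(radii[atoms$element])
  if (anyNA(r)) {
    missing_el <- unique(atoms$element[is.na(r)])
    if (is.na(unknown_radius))
      stop("no van der Waals radius for element(s): ",
           paste(missing_el, collapse = ", "))
    warning("no radius for element(s) ", paste(missing_el, collapse = ", "),
            "; using default ", unknown_radius, " A")
    r[is.na(r)] <- unknown_radius
  }
  r
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numeric probe-rolling SASA: each heavy atom is sampled with a
#' deterministic golden-spiral point set on its solvent-expanded sphere
#' (radius + probe) and a point counts as accessible when it lies outside
#' every other atom's expanded sphere. Deterministic for fixed
#' (probe, n_points, radii set). Hydrogens are ignored.
#'
#' @param model a [structure_model()].
#' @param probe probe radius, angstrom (water: 1.4).
#' @param n_points sphere sample points per atom.
#' @param radii_set name of a built-in radii table (`"protor"`, `"naccess"`)
#'   or a named numeric vector keyed by element symbol.
#' @param radii_override named numeric vector merged over the set (useful
#'   for pseudo-atoms in synthetic fixtures).
#' @param unknown_radius fallback radius for elements missing from the
#'   table (default 1.8 A with a warning); set to `NA` to error instead.
#' @return An object of class `sasa_result` with `per_atom` (A^2, heavy
#'   atoms in table order), `per_residue` (named by `chain:resno`), `total`,
#'   and the sampling parameters (`probe`, `n_sphere_points`,
#'   `radii_set_tag`).
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L, radii_set = "protor",
                 radii_override = numeric(0), unknown_radius = 1.8) {
  at <- heavy_atoms(model$atoms)
  if (nrow(at) == 0L) stop("structure has no heavy atoms")
  r <- atom_radii(at, radii_set, radii_override, unknown_radius) + probe
  xyz <- as.matrix(at[, c("x", "y", "z")])
  sp <- sphere_points(n_points)
  n <- nrow(at)
  per_atom <- numeric(n)
  ## exactly coincident atoms of equal radius contribute no extra surface
  ## (degenerate duplicates count once)
  dup <- duplicated(cbind(round(xyz, 6), round(r, 6)))
  for (i in seq_len(n)) {
    if (dup[i]) next
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + r)^2 & d2 > 0 & !dup)
    if (!length(nb)) { per_atom[i] <- 4 * pi * r[i]^2; next }
    pts <- sp * r[i]
    pts <- sweep(pts, 2L, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      accessible <- accessible & (dj2 >= r[j]^2)
      if (!any(accessible)) break
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(accessible) / n_points
  }
  rk <- residue_key(at)
  per_residue <- tapply(per_atom, rk, sum)
  structure(list(per_atom = per_atom,
                 per_residue = per_residue[unique(rk)],
                 total = sum(per_atom), probe = probe,
                 n_sphere_points = n_points,
                 radii_set_tag = if (is.character(radii_set)) radii_set else
                   "custom",
                 atoms = at),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(
    "SASA: %.1f A^2 over %d atoms (%d residues); probe %.2f A, %d points, radii '%s'\n",
    x$total, length(x$per_atom), length(x$per_residue), x$probe,
    x$n_sphere_points, x$radii_set_tag))
  invisible(x)
}

## Per-residue relative SASA against the extended-state reference table.
## Residues of types missing from the table get NA.
relative_sasa <- function(sasa_res, ref_table = MAX_ASA_TABLE) {
  at <- sasa_res$atoms
  rk <- residue_key(at)
  restype <- tapply(at$resid, rk, function(z) z[1L])[names(sasa_res$per_residue)]
  ref <- ref_table[restype]
  out <- as.numeric(sasa_res$per_residue) / as.numeric(ref)
  names(out) <- names(sasa_res$per_residue)
  out
}
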