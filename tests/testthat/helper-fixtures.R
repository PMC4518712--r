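# Shared fixture builders. Everything is generated in code; no binary data.

# Fast SE design used by unit tests that do not need the full instrument
# grid: one speed, two loadings, coarser radial spacing.
quick_se_design <- function(noise_sigma = 0.005) {
  d <- synthetic_defaults()$se
  d$speeds_rpm <- c(12800)
  d$loadings_mgml <- c(1.0, 0.25)
  d$radial_spacing <- 0.005
  d$noise_sigma <- noise_sigma
  d
}

# A noise-free experiment whose channels still carry a usable weighting
# sigma (zero-noise data with zero sigma would make the chi-square weights
# degenerate).
gen_se_noisefree <- function(scheme, properties, design = synthetic_defaults()$se) {
  design$noise_sigma <- 0
  e <- gen_se(scheme, properties, design, seed = 1)
  e$channels <- lapply(e$channels, function(ch) { ch$noise_sigma <- 0.005; ch })
  e
}

# Minimal PDB text fixtures written to a temp file.
write_pdb_lines <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, element = substr(name, 1, 1),
                          altloc = " ") {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), altloc, resid, chain, resno,
          x, y, z, occ, 0, element)
}

# Burial fixture: chain B is an octahedral cage of large pseudo-atoms that
# fully encloses chain A residue 1 (GLY at the origin); A residue 2 sits at
# the cage mouth (partially occluded, rim); A residue 3 is far away.
burial_fixture <- function() {
  cage <- rbind(c(6, 0, 0), c(-6, 0, 0), c(0, 6, 0),
                c(0, -6, 0), c(0, 0, 6), c(0, 0, -6))
  atoms <- data.frame(
    chain = c(rep("A", 3), rep("B", 6)),
    resno = c(1L, 2L, 3L, 1:6),
    insert = "",
    resid = c("GLY", "GLY", "GLY", rep("SPH", 6)),
    elety = c("CA", "CA", "CA", rep("X", 6)),
    element = c("C", "C", "C", rep("X", 6)),
    x = c(0, 14, 40, cage[, 1]),
    y = c(0, 0, 0, cage[, 2]),
    z = c(0, 0, 0, cage[, 3]),
    occupancy = 1, altloc = "",
    stringsAsFactors = FALSE)
  structure_model(atoms)
}

# Rotation matrix from three Euler-like angles.
rotation_matrix <- function(theta) {
  Rx <- matrix(c(1, 0, 0,
                 0, cos(theta[1]), -sin(theta[1]),
                 0, sin(theta[1]), cos(theta[1])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(theta[3]), -sin(theta[3]), 0,
                 sin(theta[3]), cos(theta[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Rx %*% Rz
}

# Independent coupled-equilibria oracle for the trace-label MST model:
# species L, U, LU, LL, UU with homodimer constant kd (monomer units) for
# LL and UU and the heterodimer constant kd/2 (statistical factor), or with
# the UU step switched off. Solved by nested root bracketing on the two
# free-monomer concentrations. Returns the bound fraction of the label.
oracle_label_bound <- function(L_tot, U_tot, kd, uu_dimerizes = TRUE) {
  kd_het <- kd / 2
  l_of_u <- function(u) {
    # l + l*u/kd_het + 2*l^2/kd = L_tot  (quadratic in l)
    a <- 2 / kd
    b <- 1 + u / kd_het
    (-b + sqrt(b^2 + 4 * a * L_tot)) / (2 * a)
  }
  u_balance <- function(u) {
    l <- l_of_u(u)
    uu <- if (uu_dimerizes) 2 * u^2 / kd else 0
    u + uu + l * u / kd_het - U_tot
  }
  u <- stats::uniroot(u_balance, c(0, U_tot), tol = 1e-18)$root
  l <- l_of_u(u)
  (L_tot - l) / L_tot
}
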