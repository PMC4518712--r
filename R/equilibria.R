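#' Define a self-association scheme
#'
#' A self-association pathway is described by the ordered stoichiometries of
#' the species present (always starting with the monomer) and one dissociation
#' constant per oligomeric species. All constants are defined on monomer
#' units: for a dimer \eqn{K_{d,2} = [M]^2/[D]}, for a tetramer the overall
#' \eqn{K_{d,4} = [M]^4/[T]}. A dimer-of-dimers constant \eqn{K' = [D]^2/[T]}
#' converts to the overall constant as \eqn{K_{d,4} = K' \cdot K_{d,2}^2}.
#'
#' @param stoichiometries integer vector, strictly increasing, first element 1.
#'   Typical schemes are `c(1, 2)` (monomer-dimer) and `c(1, 2, 4)`
#'   (monomer-dimer-tetramer).
#' @param kd_steps numeric vector of dissociation constants, one per
#'   non-monomer species, in molar units raised to the power
#'   \eqn{n_i - 1} (so molar for a dimer, molar^3 for a tetramer).
#' @return An object of class `association_scheme`.
#' @examples
#' association_scheme(c(1, 2), 7e-6)            # monomer-dimer, Kd = 7 uM
#' association_scheme(c(1, 2, 4), c(1e-6, 1e-18))
#' @export
association_scheme <- function(stoichiometries, kd_steps) {
  stoichiometries <- as.integer(stoichiometries)
  kd_steps <- as.numeric(kd_steps)
  if (length(stoichiometries) < 1L || stoichiometries[1L] != 1L)
    stop("stoichiometries must start with 1 (the monomer)")
  if (any(diff(stoichiometries) <= 0L))
    stop("stoichiometries must be strictly increasing")
  if (length(kd_steps) != length(stoichiometries) - 1L)
    stop("need one dissociation constant per non-monomer species")
  if (length(kd_steps) && (any(!is.finite(kd_steps) & !is.infinite(kd_steps)) ||
                           any(kd_steps <= 0)))
    stop("all dissociation constants must be positive")
  structure(list(stoichiometries = stoichiometries, kd_steps = kd_steps),
            class = "association_scheme")
}

#' @export
print.association_scheme <- function(x, ...) {
  cat("Self-association scheme: species n =",
      paste(x$stoichiometries, collapse = ", "), "\n")
  if (length(x$kd_steps)) {
    for (i in seq_along(x$kd_steps)) {
      n <- x$stoichiometries[i + 1L]
      cat(sprintf("  Kd(%d-mer) = %.4g M^%d  ([M]^%d/[%d-mer])\n",
                  n, x$kd_steps[i], n - 1L, n, n))
    }
  } else cat("  (single species, no association)\n")
  invisible(x)
}

## Total monomer units as a function of free monomer m:
##   total(m) = m + sum_i n_i * m^n_i / Kd_i^(n_i - 1)
## Strictly increasing in m, so the root in [0, total] is unique.
total_units_of_free <- function(scheme, m) {
  tot <- m
  ns <- scheme$stoichiometries
  for (i in seq_along(scheme$kd_steps)) {
    n <- ns[i + 1L]
    tot <- tot + n * m^n / scheme$kd_steps[i]
  }
  tot
}

species_conc_of_free <- function(scheme, m) {
  ns <- scheme$stoichiometries
  conc <- numeric(length(ns))
  conc[1L] <- m
  for (i in seq_along(scheme$kd_steps)) {
    n <- ns[i + 1L]
    conc[i + 1L] <- m^n / scheme$kd_steps[i]
  }
  conc
}

#' Solve the mass-action species distribution
#'
#' Given a self-association scheme and the total protein concentration in
#' monomer units, finds the unique free-monomer concentration satisfying
#' mass balance
#' \deqn{c_{tot} = m + \sum_i n_i \, m^{n_i} / K_{d,i}}
#' (each \eqn{K_{d,i}} in \eqn{M^{n_i - 1}}, so \eqn{[n\textrm{-mer}] =
#' m^{n_i}/K_{d,i}}) by bracketed bisection on \eqn{[0, c_{tot}]}, then
#' evaluates every
#' species concentration.
#'
#' @param scheme an [association_scheme()].
#' @param total total concentration in monomer units, molar.
#' @param rel_tol relative tolerance on the free-monomer root.
#' @param max_iter iteration cap for the bisection.
#' @return An object of class `species_state` with elements `free_monomer`
#'   (molar), `species_conc` (molar, one per species, monomer first) and
#'   `total_monomer_units`.
#' @examples
#' sch <- association_scheme(c(1, 2), 7e-6)
#' solve_species(sch, 7e-6)   # at total = Kd half the protomers are paired
#' @export
solve_species <- function(scheme, total, rel_tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(scheme, "association_scheme"))
  if (!is.finite(total) || total < 0) stop("total must be finite and >= 0")
  if (total == 0) {
    return(structure(list(free_monomer = 0,
                          species_conc = numeric(length(scheme$stoichiometries)),
                          total_monomer_units = 0),
                     class = "species_state"))
  }
  lo <- 0
  hi <- total  # total(m) >= m, so root is below total
  for (iter in seq_len(max_iter)) {
    mid <- 0.5 * (lo + hi)
    if (total_units_of_free(scheme, mid) > total) hi <- mid else lo <- mid
    if ((hi - lo) <= rel_tol * hi) break
  }
  if (iter == max_iter && (hi - lo) > rel_tol * hi)
    stop(sprintf(
      "species solver did not converge: total=%.6g, bracket [%.6g, %.6g] after %d iterations",
      total, lo, hi, max_iter))
  m <- 0.5 * (lo + hi)
  conc <- species_conc_of_free(scheme, m)
  structure(list(free_monomer = m, species_conc = conc,
                 total_monomer_units = sum(scheme$stoichiometries * conc)),
            class = "species_state")
}

#' Gibbs free energy from a dissociation constant
#'
#' \eqn{\Delta G = R T \ln(K_d / 1\,\mathrm{M})}, with
#' \eqn{R = 8.314\ \mathrm{J\,mol^{-1}\,K^{-1}}}. Negative for
#' sub-molar dissociation constants (favourable binding).
#'
#' @param kd dissociation constant, molar.
#' @param temperature kelvin.
#' @return Free energy change in kJ/mol.
#' @examples
#' gibbs_from_kd(23.3e-6, 298.15)  # about -26.4 kJ/mol
#' @export
gibbs_from_kd <- function(kd, temperature) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("kd must be positive and finite")
  if (any(temperature <= 0)) stop("temperature must be positive (kelvin)")
  GAS_CONSTANT_J * temperature * log(kd) / 1000
}

## J/(mol K)
GAS_CONSTANT_J <- 8.314

#' Entropic term of a binding reaction
#'
#' \eqn{T\Delta S = \Delta H - \Delta G}.
#'
#' @param dH enthalpy change, kJ/mol.
#' @param dG free energy change, kJ/mol.
#' @return \eqn{T\Delta S} in kJ/mol.
#' @export
entropy_term <- function(dH, dG) dH - dG

#' Construct a binding-thermodynamics record
#'
#' Bundles a dissociation constant with its derived thermodynamic quantities
#' at a stated temperature. \eqn{\Delta G} is computed from `kd` and
#' `temperature`, and \eqn{T\Delta S = \Delta H - \Delta G}, so the
#' thermodynamic identities hold by construction.
#'
#' @param kd dissociation constant, molar.
#' @param dH enthalpy change, kJ/mol.
#' @param temperature kelvin.
#' @param n_stoich binding stoichiometry (dimensionless), default 1.
#' @return An object of class `thermo_result` with fields `kd`, `dG`, `dH`,
#'   `TdS` (all kJ/mol except `kd`), `n_stoich` and `temperature`.
#' @examples
#' thermo_result(23.3e-6, dH = -4.9, temperature = 298.15, n_stoich = 1.06)
#' @export
thermo_result <- function(kd, dH, temperature, n_stoich = 1) {
  dG <- gibbs_from_kd(kd, temperature)
  structure(list(kd = kd, dG = dG, dH = dH, TdS = entropy_term(dH, dG),
                 n_stoich = n_stoich, temperature = temperature),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Binding thermodynamics at %.2f K\n", x$temperature))
  cat(sprintf("  Kd  = %.4g M (%.3g uM)\n", x$kd, x$kd * 1e6))
  cat(sprintf("  dG  = %.2f kJ/mol\n  dH  = %.2f kJ/mol\n  TdS = %.2f kJ/mol\n",
              x$dG, x$dH, x$TdS))
  cat(sprintf("  N   = %.3g\n", x$n_stoich))
  invisible(x)
}

#' Fraction of protomers in the dimer
#'
#' Convenience summary for a monomer-dimer scheme: \eqn{2[D]/c_{tot}}.
#'
#' @param scheme an [association_scheme()] whose second species is a dimer.
#' @param total total concentration in monomer units, molar.
#' @return Fraction in \[0, 1\].
#' @export
protomer_dimer_fraction <- function(scheme, total) {
  stopifnot(length(scheme$stoichiometries) >= 2L,
            scheme$stoichiometries[2L] == 2L)
  if (total == 0) return(0)
  st <- solve_species(scheme, total)
  2 * st$species_conc[2L] / st$total_monomer_units
}

## Unit helpers used across interfaces: inputs in uM / nM / Celsius.
uM_to_M <- function(x) x * 1e-6
nM_to_M <- function(x) x * 1e-9
celsius_to_K <- function(x) x + 273.15
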