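#' Default synthetic study designs
#'
#' The generators default to the experimental designs of the biophysical
#' study they emulate: sedimentation equilibrium at 11.8/12.8/13.8 krpm
#' with loadings 1.0/0.5/0.25 mg/ml read at 280 nm and 20 C in 12-mm
#' cells; thermophoresis with 20 nM labeled protein titrated by a 16-point
#' 1:1 serial dilution from 50,000 nM; calorimetry with 19 x 2 ul
#' injections of 10x ligand into a 100 uM, 200 ul cell at 25 C. Noise
#' defaults (SE 0.005 AU, MST 1% of the amplitude, ITC 0.1 ucal) are
#' typical instrument magnitudes.
#'
#' @return A nested list of design parameters; pass a modified copy to the
#'   generators.
#' @export
synthetic_defaults <- function() {
  list(
    se = list(speeds_rpm = c(11800, 12800, 13800),
              loadings_mgml = c(1.0, 0.5, 0.25),
              meniscus = 6.95, bottom = 7.25, radial_spacing = 0.001,
              edge_margin = 0.005, noise_sigma = 0.005),
    mst = list(top_nM = 50000, ratio = 0.5, n_points = 16L,
               labeled_nM = 20, f_free = 800, f_bound = 850,
               noise_frac_amplitude = 0.01),
    itc = list(cell_ul = 200, cell_uM = 100, syringe_uM = 1000,
               n_injections = 19L, injection_ul = 2,
               temperature = 298.15, noise_ucal = 0.1)
  )
}

#' Generate a synthetic sedimentation-equilibrium experiment
#'
#' Simulates the full multi-speed x multi-loading design through the
#' equilibrium forward model with mass conservation (the reference
#' free-monomer concentration of each channel is chosen so the sector
#' average equals the loading), then adds Gaussian measurement noise.
#'
#' @param scheme generating [association_scheme()] (the truth).
#' @param properties a [solution_properties()] object.
#' @param design the `se` element of [synthetic_defaults()] (or a modified
#'   copy).
#' @param seed integer seed; fixed seed gives identical output.
#' @return An [se_experiment()]; the generating truth is attached as
#'   attribute `"truth"`.
#' @export
gen_se <- function(scheme, properties, design = synthetic_defaults()$se,
                   seed = 1L) {
  set.seed(seed)
  radii <- seq(design$meniscus + design$edge_margin,
               design$bottom - design$edge_margin,
               by = design$radial_spacing)
  channels <- list()
  for (rpm in design$speeds_rpm) {
    sigma1 <- reduced_buoyant_sigma(properties, rpm)
    for (load in design$loadings_mgml) {
      loading_molar <- load / properties$monomer_mass  # mg/ml = g/l -> M
      loading_signal <- loading_molar * properties$molar_signal *
        properties$pathlength
      ref_radius <- 0.5 * (design$meniscus + design$bottom)
      m_ref <- ref_monomer_for_loading(scheme, sigma1, ref_radius,
                                       design$meniscus, design$bottom,
                                       loading_molar)
      clean <- tryCatch(
        se_profile(scheme, sigma1, ref_radius, m_ref, radii,
                   baseline = 0, properties = properties),
        error = function(e) stop(
          sprintf("design error in channel rpm=%d, loading=%.2f mg/ml: %s",
                  rpm, load, conditionMessage(e))))
      noisy <- clean + stats::rnorm(length(clean), 0, design$noise_sigma)
      channels[[length(channels) + 1L]] <-
        se_channel(radii, noisy, rotor_speed = rpm,
                   loading_signal = loading_signal,
                   meniscus = design$meniscus, bottom = design$bottom,
                   noise_sigma = design$noise_sigma)
    }
  }
  out <- se_experiment(channels, properties, scheme)
  attr(out, "truth") <- list(scheme = scheme$stoichiometries,
                             kd_steps = scheme$kd_steps, seed = seed,
                             noise_sigma = design$noise_sigma)
  out
}

#' Generate a synthetic MST dose-response series
#'
#' Serial-dilution titration of a trace-labeled protein, evaluated through
#' the requested isotherm model with Gaussian noise on the normalised
#' fluorescence.
#'
#' @param kd generating dissociation constant, molar (for the
#'   self-association model this is the homodimerization constant).
#' @param design the `mst` element of [synthetic_defaults()].
#' @param model_tag `"self_association"` (default) or `"one_to_one"`.
#' @param statistical_factor see [fraction_bound_self()].
#' @param seed integer seed.
#' @return An [mst_series()] with attribute `"truth"`.
#' @export
gen_mst <- function(kd, design = synthetic_defaults()$mst,
                    model_tag = c("self_association", "one_to_one"),
                    statistical_factor = TRUE, seed = 1L) {
  model_tag <- match.arg(model_tag)
  set.seed(seed)
  titr <- dilution_series(design$top_nM, design$ratio, design$n_points)
  series <- mst_series(titr, design$labeled_nM,
                       fnorm = rep(design$f_free, length(titr)))
  fb <- mst_model_fraction(series, kd, model_tag, statistical_factor)
  clean <- design$f_free + (design$f_bound - design$f_free) * fb
  sigma <- design$noise_frac_amplitude * abs(design$f_bound - design$f_free)
  series$fnorm <- clean + stats::rnorm(length(clean), 0, sigma)
  attr(series, "truth") <- list(kd = kd, model_tag = model_tag,
                                f_free = design$f_free,
                                f_bound = design$f_bound,
                                noise_sigma = sigma, seed = seed)
  series
}

#' Generate a synthetic ITC titration
#'
#' @param kd generating dissociation constant, molar.
#' @param dH generating enthalpy, kJ/mol.
#' @param n_stoich generating stoichiometry.
#' @param design the `itc` element of [synthetic_defaults()].
#' @param q_dil dilution-heat offset per injection, ucal.
#' @param seed integer seed.
#' @return An [itc_experiment()] with measured heats and attribute
#'   `"truth"`.
#' @export
gen_itc <- function(kd, dH, n_stoich = 1, design = synthetic_defaults()$itc,
                    q_dil = 0, seed = 1L) {
  set.seed(seed)
  exp0 <- itc_experiment(design$cell_ul, design$cell_uM, design$syringe_uM,
                         rep(design$injection_ul, design$n_injections),
                         temperature = design$temperature)
  clean <- itc_heats(exp0, kd, dH, n_stoich, q_dil)
  exp0$heats <- clean + stats::rnorm(length(clean), 0, design$noise_ucal)
  attr(exp0, "truth") <- list(kd = kd, dH = dH, n_stoich = n_stoich,
                              q_dil = q_dil, noise_ucal = design$noise_ucal,
                              seed = seed)
  exp0
}

#' Generate a toy two-chain dimer with analytically known interface
#'
#' Builds pseudo-atomic fixtures for exercising the surface-area and
#' constraint machinery:
#' \describe{
#'   \item{`mode = "spheres"`}{two one-atom chains of sphere radius
#'     `sphere_radius`. The centre separation is chosen so the buried
#'     area per monomer equals `buried_area` by the spherical-cap formula
#'     \eqn{A_{cap} = 2\pi\rho h} with \eqn{\rho} the solvent-expanded
#'     radius and \eqn{h = \rho - d/2}; pass `distance` instead to set the
#'     separation directly.}
#'   \item{`mode = "symmetric"`}{two copies of a small rigid multi-atom
#'     chain related by an exact 180-degree rotation about the z axis,
#'     i.e. a perfect two-fold homodimer.}
#' }
#' The pseudo-atom element is `"X"`; give [sasa()] and friends
#' `radii_override = c(X = sphere_radius)`.
#'
#' @param mode `"spheres"` or `"symmetric"`.
#' @param sphere_radius pseudo-atom van der Waals radius, angstrom.
#' @param buried_area target buried area per monomer, A^2 (spheres mode).
#' @param distance centre separation, angstrom (overrides `buried_area`).
#' @param probe probe radius used in the cap calculation.
#' @param n_atoms atoms per chain in symmetric mode.
#' @param jitter_seed seed for the symmetric-mode chain geometry.
#' @return A [structure_model()]; in spheres mode the attribute
#'   `"expected_buried"` records the analytic cap area.
#' @export
gen_toy_dimer <- function(mode = c("spheres", "symmetric"),
                          sphere_radius = 10, buried_area = 500,
                          distance = NULL, probe = 1.4, n_atoms = 5L,
                          jitter_seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "spheres") {
    rho <- sphere_radius + probe
    if (is.null(distance)) {
      h <- buried_area / (2 * pi * rho)
      if (h >= rho) stop("requested buried area exceeds the hemisphere cap")
      distance <- 2 * (rho - h)
    }
    expected <- if (distance >= 2 * rho) 0 else
      2 * pi * rho * (rho - distance / 2)
    atoms <- data.frame(
      chain = c("A", "B"), resno = c(1L, 1L), insert = "",
      resid = "SPH", elety = "X", element = "X",
      x = c(0, distance), y = 0, z = 0, occupancy = 1, altloc = "",
      stringsAsFactors = FALSE)
    out <- structure_model(atoms)
    attr(out, "expected_buried") <- expected
    attr(out, "distance") <- distance
    return(out)
  }
  ## symmetric mode: rigid chain A, chain B = 180-degree rotation about z
  set.seed(jitter_seed)
  base <- cbind(x = seq(4, 4 + 3 * (n_atoms - 1L), by = 3) +
                  stats::runif(n_atoms, -0.5, 0.5),
                y = stats::runif(n_atoms, -2, 2),
                z = stats::runif(n_atoms, -2, 2))
  rot <- base %*% diag(c(-1, -1, 1))  # exact C2 about the z axis
  atoms <- data.frame(
    chain = rep(c("A", "B"), each = n_atoms),
    resno = rep(seq_len(n_atoms), 2L), insert = "",
    resid = "SPH", elety = "X", element = "X",
    x = c(base[, 1], rot[, 1]), y = c(base[, 2], rot[, 2]),
    z = c(base[, 3], rot[, 3]), occupancy = 1, altloc = "",
    stringsAsFactors = FALSE)
  structure_model(atoms)
}
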