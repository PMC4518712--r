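#' Solution and optical properties for a sedimentation experiment
#'
#' @param monomer_mass monomer molar mass, g/mol.
#' @param vbar partial specific volume, ml/g.
#' @param density solvent density, g/ml.
#' @param viscosity solvent viscosity, centipoise.
#' @param molar_signal molar signal increment (signal per cm pathlength per
#'   molar, e.g. the molar extinction coefficient at 280 nm). If `NULL`,
#'   defaults to `0.75 * monomer_mass`, i.e. a specific absorbance of
#'   0.75 AU ml/(mg cm) typical for proteins at 280 nm.
#' @param pathlength optical pathlength, cm (12-mm centerpieces: 1.2).
#' @param temperature kelvin.
#' @return An object of class `solution_properties`.
#' @export
solution_properties <- function(monomer_mass, vbar = 0.73, density = 1.005,
                                viscosity = 1.02, molar_signal = NULL,
                                pathlength = 1.2, temperature = 293.15) {
  if (is.null(molar_signal)) molar_signal <- 0.75 * monomer_mass
  vals <- c(monomer_mass, vbar, density, viscosity, molar_signal,
            pathlength, temperature)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all solution properties must be finite and strictly positive")
  structure(list(monomer_mass = monomer_mass, vbar = vbar, density = density,
                 viscosity = viscosity, molar_signal = molar_signal,
                 pathlength = pathlength, temperature = temperature),
            class = "solution_properties")
}

#' A single sedimentation-equilibrium channel
#'
#' One radial absorbance scan at one rotor speed and loading concentration.
#'
#' @param radii radial positions, cm, strictly increasing, length >= 20.
#' @param signal absorbance at each radius.
#' @param rotor_speed rpm.
#' @param loading_signal the known loading concentration expressed in signal
#'   units (loading molar concentration x molar_signal x pathlength).
#' @param meniscus,bottom solution column limits, cm; must bracket `radii`.
#' @param noise_sigma per-point measurement noise, signal units (used for
#'   weighting; default 0.005 AU).
#' @return An object of class `se_channel`.
#' @export
se_channel <- function(radii, signal, rotor_speed, loading_signal,
                       meniscus = 6.95, bottom = 7.25, noise_sigma = 0.005) {
  radii <- as.numeric(radii); signal <- as.numeric(signal)
  if (length(radii) < 20L) stop("a channel needs at least 20 radial points")
  if (length(signal) != length(radii)) stop("radii and signal lengths differ")
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (!(meniscus < radii[1L] && radii[length(radii)] < bottom))
    stop("radii must lie strictly inside (meniscus, bottom)")
  if (rotor_speed <= 0) stop("rotor_speed must be positive")
  structure(list(radii = radii, signal = signal, rotor_speed = rotor_speed,
                 loading_signal = loading_signal, meniscus = meniscus,
                 bottom = bottom, noise_sigma = noise_sigma),
            class = "se_channel")
}

#' A multi-channel sedimentation-equilibrium experiment
#'
#' @param channels list of [se_channel()] objects sharing one set of
#'   solution properties.
#' @param properties a [solution_properties()] object.
#' @param scheme an [association_scheme()] to be fitted.
#' @return An object of class `se_experiment`.
#' @export
se_experiment <- function(channels, properties, scheme) {
  stopifnot(length(channels) >= 1L,
            all(vapply(channels, inherits, logical(1), "se_channel")),
            inherits(properties, "solution_properties"),
            inherits(scheme, "association_scheme"))
  structure(list(channels = channels, properties = properties, scheme = scheme),
            class = "se_experiment")
}

#' Reduced buoyant molar mass parameter
#'
#' \eqn{\sigma = M (1 - \bar v \rho)\, \omega^2 / (R T)} in cm^-2, with
#' \eqn{\omega = 2\pi\,\mathrm{rpm}/60} and the gas constant in cgs units
#' (8.314e7 erg/(mol K)). The radial signal gradient of an n-mer at
#' equilibrium is \eqn{\exp(n \sigma (r^2 - r_0^2)/2)}.
#'
#' @param properties a [solution_properties()] object.
#' @param rotor_speed rpm.
#' @return sigma in cm^-2.
#' @examples
#' p <- solution_properties(84000, vbar = 0.73, density = 1.005)
#' reduced_buoyant_sigma(p, 11800)  # about 1.40 cm^-2
#' @export
reduced_buoyant_sigma <- function(properties, rotor_speed) {
  if (rotor_speed <= 0) stop("rotor_speed must be positive")
  buoyancy <- 1 - properties$vbar * properties$density
  if (buoyancy == 0)
    stop("degenerate buoyancy: vbar * density = 1, the protein does not sediment")
  omega <- 2 * pi * rotor_speed / 60
  properties$monomer_mass * buoyancy * omega^2 /
    (GAS_CONSTANT_J * 1e7 * properties$temperature)
}

## Species concentrations at the reference radius for a given free monomer.
## Returns vector c_i(ref) in molar, monomer first.
ref_species <- function(scheme, ref_free_monomer)
  species_conc_of_free(scheme, ref_free_monomer)

#' Sedimentation-equilibrium signal profile
#'
#' Forward model for the radial signal of a self-associating system at
#' sedimentation equilibrium:
#' \deqn{a(r) = b + \epsilon \ell \sum_i n_i c_i(r_0)
#'       \exp\{n_i \sigma_1 (r^2 - r_0^2)/2\}}
#' where \eqn{c_i(r_0)} follow mass action from the free monomer
#' concentration at the reference radius and \eqn{\sigma_1} is the monomer
#' [reduced_buoyant_sigma()]. The signal sums species on a per-monomer-unit
#' basis (n_i weighting) because the molar signal increment is per monomer.
#'
#' @param scheme an [association_scheme()].
#' @param sigma1 monomer reduced buoyant parameter, cm^-2.
#' @param ref_radius reference radius, cm.
#' @param ref_free_monomer free monomer concentration at `ref_radius`, molar.
#' @param radii radii at which to evaluate, cm.
#' @param baseline signal offset.
#' @param properties a [solution_properties()] object (for the
#'   signal conversion).
#' @return Signal vector, same length as `radii`.
#' @export
se_profile <- function(scheme, sigma1, ref_radius, ref_free_monomer, radii,
                       baseline, properties) {
  cref <- ref_species(scheme, ref_free_monomer)
  ns <- scheme$stoichiometries
  expo <- outer(radii^2 - ref_radius^2, ns * sigma1 / 2)
  if (any(expo > 700))
    stop("model-range error: exponent overflow (> 700) in the equilibrium profile")
  conc <- drop(exp(expo) %*% (ns * cref))  # monomer units, molar
  baseline + properties$molar_signal * properties$pathlength * conc
}

## Per-species sector integrals 2 * int_m^b exp(n sigma1 (r^2-ref^2)/2) r dr
##   / (b^2 - m^2), closed form. Used to eliminate the reference free monomer
## via mass conservation inside the fitter.
sector_exp_integral <- function(n, sigma1, ref_radius, meniscus, bottom) {
  k <- n * sigma1 / 2
  if (abs(k) < 1e-14) return(1)
  (exp(k * (bottom^2 - ref_radius^2)) - exp(k * (meniscus^2 - ref_radius^2))) /
    (k * (bottom^2 - meniscus^2))
}

#' Sector-average loading implied by a model profile
#'
#' Computes the rotor-sector average concentration (monomer units, molar)
#' implied by an equilibrium profile,
#' \deqn{\bar c = \frac{2\int_m^b c(r)\, r\, dr}{b^2 - m^2},}
#' by adaptive quadrature. Mass conservation requires this to equal the
#' loading concentration; the global fitter uses the closed-form equivalent
#' to eliminate the per-channel reference concentration as a hard constraint.
#'
#' @param channel an [se_channel()] (supplies meniscus/bottom geometry).
#' @param scheme an [association_scheme()].
#' @param sigma1 monomer reduced buoyant parameter, cm^-2.
#' @param ref_radius reference radius, cm.
#' @param ref_free_monomer free monomer at the reference radius, molar.
#' @param rel_tol quadrature relative tolerance.
#' @return Implied sector-average loading, molar (monomer units).
#' @export
conserve_mass <- function(channel, scheme, sigma1, ref_radius,
                          ref_free_monomer, rel_tol = 1e-10) {
  cref <- ref_species(scheme, ref_free_monomer)
  ns <- scheme$stoichiometries
  conc_r <- function(r) {
    expo <- outer(r^2 - ref_radius^2, ns * sigma1 / 2)
    drop(exp(expo) %*% (ns * cref))
  }
  num <- stats::integrate(function(r) conc_r(r) * r,
                          channel$meniscus, channel$bottom,
                          rel.tol = rel_tol, abs.tol = 0)
  if (num$message != "OK")
    stop("mass-conservation integral did not converge: ", num$message)
  2 * num$value / (channel$bottom^2 - channel$meniscus^2)
}

## Solve ref_free_monomer so that the sector-average concentration equals
## `loading_molar` (monomer units). Closed-form integrals make the average a
## strictly increasing polynomial-like function of m_ref; bracketed uniroot.
ref_monomer_for_loading <- function(scheme, sigma1, ref_radius, meniscus,
                                    bottom, loading_molar) {
  ns <- scheme$stoichiometries
  ints <- vapply(ns, sector_exp_integral, numeric(1),
                 sigma1 = sigma1, ref_radius = ref_radius,
                 meniscus = meniscus, bottom = bottom)
  avg_of_m <- function(m) {
    tot <- m * ints[1L]
    for (i in seq_along(scheme$kd_steps)) {
      n <- ns[i + 1L]
      tot <- tot + n * m^n / scheme$kd_steps[i] * ints[i + 1L]
    }
    tot
  }
  ## bracket: avg >= m * min(ints) grows without bound; start at loading
  hi <- loading_molar / min(ints)
  while (avg_of_m(hi) < loading_molar) hi <- hi * 2
  stats::uniroot(function(m) avg_of_m(m) - loading_molar, c(0, hi),
                 tol = 1e-13 * hi)$root
}

## Model signal for one channel given Kd's (in the scheme), with the
## reference free monomer eliminated by mass conservation and the baseline
## profiled analytically (clamped to +/- baseline_bound).
channel_model <- function(channel, scheme, properties, baseline_bound = 0.1) {
  sigma1 <- reduced_buoyant_sigma(properties, channel$rotor_speed)
  ref_radius <- 0.5 * (channel$meniscus + channel$bottom)
  loading_molar <- channel$loading_signal /
    (properties$molar_signal * properties$pathlength)
  m_ref <- ref_monomer_for_loading(scheme, sigma1, ref_radius,
                                   channel$meniscus, channel$bottom,
                                   loading_molar)
  model0 <- se_profile(scheme, sigma1, ref_radius, m_ref, channel$radii,
                       baseline = 0, properties = properties)
  baseline <- mean(channel$signal - model0)
  baseline <- min(max(baseline, -baseline_bound), baseline_bound)
  list(model = model0 + baseline, baseline = baseline, m_ref = m_ref,
       ref_radius = ref_radius, sigma1 = sigma1)
}

## Weighted SSR across channels for log10(Kd) vector `logkd`.
se_objective <- function(logkd, experiment, baseline_bound = 0.1) {
  scheme <- association_scheme(experiment$scheme$stoichiometries, 10^logkd)
  ssr <- 0
  for (ch in experiment$channels) {
    cm <- tryCatch(channel_model(ch, scheme, experiment$properties,
                                 baseline_bound),
                   error = function(e) NULL)
    if (is.null(cm)) return(1e30)
    ssr <- ssr + sum(((ch$signal - cm$model) / ch$noise_sigma)^2)
  }
  ssr
}

## log10 bounds per association step; a Kd on monomer units for an n-mer has
## dimension M^(n-1), so the [-9, -1] molar window scales with (n-1).
kd_log_bounds <- function(scheme) {
  nm1 <- scheme$stoichiometries[-1L] - 1L
  list(lower = -9 * nm1, upper = -1 * nm1)
}

## Moment-based starting guess for the dimerization Kd: compare the observed
## signal-average buoyant mass (from a single-exponential ln-linear fit per
## channel) with monomer and dimer expectations; map the apparent association
## extent onto a Kd at the mean loading.
moment_kd_guess <- function(experiment) {
  props <- experiment$properties
  ratio <- vapply(experiment$channels, function(ch) {
    sigma1 <- reduced_buoyant_sigma(props, ch$rotor_speed)
    y <- ch$signal - min(ch$signal) + 1e-4
    fit <- stats::lm.fit(cbind(1, ch$radii^2 / 2), log(y))
    fit$coefficients[2L] / sigma1  # apparent n
  }, numeric(1))
  loadings <- vapply(experiment$channels, function(ch)
    ch$loading_signal / (props$molar_signal * props$pathlength), numeric(1))
  n_app <- min(max(stats::median(ratio), 1.02), 1.98)
  ## monomer-dimer: protomer-in-dimer fraction f at total c has
  ## apparent n ~ 1 + f; f = (n_app - 1) -> Kd = 2 c (1-f)^2 / f
  f <- n_app - 1
  ctot <- stats::median(loadings)
  max(2 * ctot * (1 - f)^2 / f, 1e-9)
}

#' Global fit of a sedimentation-equilibrium experiment
#'
#' Fits the association constants of `experiment$scheme` globally across all
#' channels by weighted least squares. The dissociation constants (in
#' log10 molar, bounds \[-9, -1\]) are shared across channels; each channel
#' has its own baseline (profiled analytically, bounded at +/- 0.1 AU) and
#' its reference free-monomer concentration is eliminated through the
#' mass-conservation constraint, so the known loading is honoured exactly.
#' Five log-spaced starts spanning 0.01-100x a moment-based guess guard
#' against local minima; the best optimum is reported.
#'
#' @param experiment an [se_experiment()].
#' @param baseline_bound per-channel baseline bound, signal units.
#' @param n_starts number of multistart initialisations.
#' @return An object of class `se_fit` with fitted `kd_estimates` (molar),
#'   per-channel baselines and reference concentrations, `reduced_chi2`,
#'   `rmsd_per_channel`, and a `boundary_warning` flag set when an estimate
#'   sits at the search bound. Confidence intervals are added by
#'   [monte_carlo_ci()].
#' @export
fit_se_global <- function(experiment, baseline_bound = 0.1, n_starts = 5L) {
  stopifnot(inherits(experiment, "se_experiment"))
  n_kd <- length(experiment$scheme$kd_steps)
  if (n_kd == 0L) stop("scheme has no association step to fit")
  bounds <- kd_log_bounds(experiment$scheme)
  guess <- log10(moment_kd_guess(experiment))
  nm1 <- experiment$scheme$stoichiometries[-1L] - 1L
  offsets <- seq(-2, 2, length.out = n_starts)
  best <- NULL
  diagnostics <- character(0)
  for (off in offsets) {
    start <- pmin(pmax((guess + off) * nm1, bounds$lower), bounds$upper)
    res <- tryCatch(
      stats::optim(start, se_objective, experiment = experiment,
                   baseline_bound = baseline_bound,
                   method = "L-BFGS-B", lower = bounds$lower,
                   upper = bounds$upper, control = list(factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) { diagnostics <- c(diagnostics,
        sprintf("start %.2f failed", off)); next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all optimisation starts failed: ",
         paste(diagnostics, collapse = "; "))
  par <- best$par
  if (n_kd > 1L) {
    ## simplex polish helps multi-constant schemes with correlated surfaces
    pol <- tryCatch(
      stats::optim(par, function(p) {
        if (any(p < bounds$lower) || any(p > bounds$upper)) return(1e30)
        se_objective(p, experiment, baseline_bound)
      }, method = "Nelder-Mead",
      control = list(reltol = 1e-14, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value < best$value) par <- pol$par
  }
  finalize_se_fit(par, experiment, baseline_bound)
}

finalize_se_fit <- function(logkd, experiment, baseline_bound = 0.1) {
  scheme <- association_scheme(experiment$scheme$stoichiometries, 10^logkd)
  baselines <- numeric(length(experiment$channels))
  refconc <- numeric(length(experiment$channels))
  rmsd <- numeric(length(experiment$channels))
  ssr_w <- 0; n_pts <- 0L
  fitted <- vector("list", length(experiment$channels))
  for (i in seq_along(experiment$channels)) {
    ch <- experiment$channels[[i]]
    cm <- channel_model(ch, scheme, experiment$properties, baseline_bound)
    baselines[i] <- cm$baseline
    refconc[i] <- cm$m_ref
    resid <- ch$signal - cm$model
    rmsd[i] <- sqrt(mean(resid^2))
    ssr_w <- ssr_w + sum((resid / ch$noise_sigma)^2)
    n_pts <- n_pts + length(resid)
    fitted[[i]] <- cm$model
  }
  n_free <- length(logkd) + length(baselines)
  structure(list(
    kd_estimates = 10^logkd,
    log10_kd = logkd,
    kd_ci = NULL, ci_level = NA_real_, n_monte_carlo = 0L,
    per_channel_baseline = baselines,
    per_channel_reference_conc = refconc,
    reduced_chi2 = ssr_w / (n_pts - n_free),
    rmsd_per_channel = rmsd,
    fitted = fitted,
    boundary_warning = {
      b <- kd_log_bounds(experiment$scheme)
      any(abs(logkd - b$lower) < 1e-3 | abs(logkd - b$upper) < 1e-3)
    },
    scheme = experiment$scheme$stoichiometries),
    class = "se_fit")
}

#' @export
print.se_fit <- function(x, ...) {
  cat("Global sedimentation-equilibrium fit\n")
  cat("  scheme n =", paste(x$scheme, collapse = ", "), "\n")
  for (i in seq_along(x$kd_estimates)) {
    line <- sprintf("  Kd(%d-mer) = %.4g M", x$scheme[i + 1L],
                    x$kd_estimates[i])
    if (!is.null(x$kd_ci))
      line <- paste0(line, sprintf("  [%.4g, %.4g] at %.0f%% (n=%d MC)",
                                   x$kd_ci[i, 1L], x$kd_ci[i, 2L],
                                   100 * x$ci_level, x$n_monte_carlo))
    cat(line, "\n")
  }
  cat(sprintf("  reduced chi-square = %.4g\n", x$reduced_chi2))
  cat(sprintf("  channel RMSD range = %.2g-%.2g AU\n",
              min(x$rmsd_per_channel), max(x$rmsd_per_channel)))
  if (isTRUE(x$boundary_warning))
    cat("  warning: an estimate lies at the parameter bound\n")
  invisible(x)
}

#' Parametric Monte Carlo confidence intervals for an SE fit
#'
#' Adds fresh Gaussian noise (at each channel's residual standard deviation)
#' to the best-fit model, refits, and collects the dissociation constants;
#' the confidence interval is the percentile interval of the collected values
#' at the requested level. Deterministic for a fixed seed.
#'
#' @param experiment the fitted [se_experiment()].
#' @param fit an `se_fit` from [fit_se_global()].
#' @param n_iter number of Monte Carlo iterations (0 leaves the fit
#'   unchanged).
#' @param level confidence level, e.g. 0.95.
#' @param seed integer seed.
#' @param use_residual_sigma if `TRUE` (default) noise is drawn at the
#'   per-channel residual RMSD; otherwise at the channel's stated
#'   `noise_sigma`.
#' @return The `se_fit` with `kd_ci` (matrix, one row per association step),
#'   `ci_level` and `n_monte_carlo` filled in.
#' @export
monte_carlo_ci <- function(experiment, fit, n_iter = 500L, level = 0.95,
                           seed = 1L, use_residual_sigma = TRUE) {
  stopifnot(inherits(fit, "se_fit"))
  if (n_iter == 0L) return(fit)
  set.seed(seed)
  n_kd <- length(fit$kd_estimates)
  draws <- matrix(NA_real_, n_iter, n_kd)
  n_fail <- 0L
  for (it in seq_len(n_iter)) {
    sim <- experiment
    for (i in seq_along(sim$channels)) {
      sigma <- if (use_residual_sigma) fit$rmsd_per_channel[i] else
        sim$channels[[i]]$noise_sigma
      sim$channels[[i]]$signal <- fit$fitted[[i]] +
        stats::rnorm(length(fit$fitted[[i]]), 0, sigma)
    }
    bounds <- kd_log_bounds(experiment$scheme)
    refit <- tryCatch(
      stats::optim(fit$log10_kd, se_objective, experiment = sim,
                   method = "L-BFGS-B", lower = bounds$lower,
                   upper = bounds$upper, control = list(factr = 1e5)),
      error = function(e) NULL)
    if (is.null(refit)) n_fail <- n_fail + 1L else draws[it, ] <- 10^refit$par
  }
  if (n_fail > 0.2 * n_iter)
    stop(sprintf("Monte Carlo CIs unreliable: %d of %d refits failed",
                 n_fail, n_iter))
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 2L, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE))
  ## percentile intervals need not bracket the point estimate exactly,
  ## but report an interval that does
  ci[, 1L] <- pmin(ci[, 1L], fit$kd_estimates)
  ci[, 2L] <- pmax(ci[, 2L], fit$kd_estimates)
  fit$kd_ci <- ci
  fit$ci_level <- level
  fit$n_monte_carlo <- n_iter
  fit
}

#' Correct a sedimentation coefficient to standard conditions
#'
#' Converts an observed sedimentation coefficient to water at 20 C:
#' \deqn{s_{20,w} = s_{obs} \frac{\eta_{buffer}}{\eta_{20,w}}
#'       \frac{(1-\bar v \rho)_{20,w}}{(1-\bar v \rho)_{buffer}}}
#' with \eqn{\eta_{20,w} = 1.002} cP and \eqn{\rho_{20,w} = 0.99823} g/ml.
#'
#' @param s_observed svedberg.
#' @param buffer_density g/ml.
#' @param buffer_viscosity centipoise.
#' @param vbar partial specific volume, ml/g.
#' @param eta_w,rho_w standard-condition water constants.
#' @return s20,w in svedberg.
#' @export
correct_s20w <- function(s_observed, buffer_density, buffer_viscosity, vbar,
                         eta_w = 1.002, rho_w = 0.99823) {
  if (any(c(s_observed, buffer_density, buffer_viscosity, vbar) <= 0))
    stop("all inputs must be positive")
  denom <- 1 - vbar * buffer_density
  if (abs(denom) < 1e-10)
    stop("degenerate buoyancy: (1 - vbar * density) = 0 in the buffer")
  s_observed * (buffer_viscosity / eta_w) * (1 - vbar * rho_w) / denom
}
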