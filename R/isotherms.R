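#' Bound fraction of a labeled species for 1:1 binding
#'
#' Exact closed-form solution of the 1:1 binding mass balance
#' (quadratic in the complex concentration): the fraction of the labeled
#' species bound at total label concentration `labeled_total` and total
#' titrant concentration `titrant_total`.
#'
#' @param labeled_total total labeled species, molar.
#' @param titrant_total total titrant, molar (vectorised).
#' @param kd dissociation constant, molar.
#' @return Bound fraction in \[0, 1\].
#' @export
fraction_bound_1to1 <- function(labeled_total, titrant_total, kd) {
  if (any(c(labeled_total, titrant_total, kd) < 0))
    stop("inputs must be non-negative")
  if (labeled_total == 0) return(rep(0, length(titrant_total)))
  s <- labeled_total + titrant_total + kd
  complex <- (s - sqrt(s^2 - 4 * labeled_total * titrant_total)) / 2
  pmin(pmax(complex / labeled_total, 0), 1)
}

#' Bound fraction of a trace label in a self-associating titration
#'
#' Model for a thermophoresis experiment in which a trace-labeled protein is
#' titrated with the unlabeled protein of the same species. The free
#' unlabeled monomer `u` is obtained from the homodimerization quadratic
#' \eqn{u + 2u^2/K_d = U_{tot}}; the label partitions into heterodimers
#' according to \eqn{f_{bound} = u/(K_{het} + u)}. With the statistical
#' factor on (the default), \eqn{K_{het} = K_{d}/2}: a labeled-unlabeled
#' pair has twice the combinatoric weight of either homodimer.
#'
#' @param labeled_total total labeled protein, molar (assumed trace relative
#'   to the titrant; enters only through the approximation that the label
#'   does not perturb the unlabeled monomer-dimer equilibrium).
#' @param unlabeled_total total unlabeled protein, molar (vectorised).
#' @param kd_dim homodimerization constant \eqn{[M]^2/[D]}, molar.
#' @param statistical_factor use \eqn{K_{het} = K_d/2} (default TRUE).
#' @return Bound fraction of the label in \[0, 1\].
#' @export
fraction_bound_self <- function(labeled_total, unlabeled_total, kd_dim,
                                statistical_factor = TRUE) {
  if (any(c(labeled_total, unlabeled_total) < 0) || kd_dim <= 0)
    stop("concentrations must be non-negative and kd_dim positive")
  if (is.infinite(kd_dim)) return(rep(0, length(unlabeled_total)))
  ## free unlabeled monomer from u + 2 u^2 / kd = U
  u <- (kd_dim / 4) * (sqrt(1 + 8 * unlabeled_total / kd_dim) - 1)
  kd_het <- if (statistical_factor) kd_dim / 2 else kd_dim
  pmin(pmax(u / (kd_het + u), 0), 1)
}

#' Serial-dilution concentration series
#'
#' Geometric dilution series `top * ratio^k`, `k = 0 ... n_points - 1`
#' (a 1:1 serial dilution corresponds to `ratio = 0.5`).
#'
#' @param top starting concentration (any unit; returned in the same unit).
#' @param ratio dilution ratio per step, in (0, 1).
#' @param n_points number of points, at least 2.
#' @return Strictly decreasing concentration vector.
#' @export
dilution_series <- function(top, ratio = 0.5, n_points = 16L) {
  if (n_points < 2L) stop("n_points must be at least 2")
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0, 1)")
  top * ratio^(seq_len(n_points) - 1L)
}

#' Construct an MST dose-response series
#'
#' @param titrant_total titrant totals, nM, strictly decreasing
#'   (serial dilution), at least 8 points.
#' @param labeled_total labeled protein, nM.
#' @param fnorm normalised fluorescence readout, per mil.
#' @return An object of class `mst_series`.
#' @export
mst_series <- function(titrant_total, labeled_total, fnorm) {
  titrant_total <- as.numeric(titrant_total); fnorm <- as.numeric(fnorm)
  if (length(titrant_total) < 8L) stop("an MST series needs at least 8 points")
  if (any(diff(titrant_total) >= 0))
    stop("titrant_total must be strictly decreasing (serial dilution)")
  if (length(fnorm) != length(titrant_total))
    stop("fnorm and titrant_total lengths differ")
  structure(list(titrant_total = titrant_total,
                 labeled_total = labeled_total, fnorm = fnorm),
            class = "mst_series")
}

mst_model_fraction <- function(series, kd, model_tag, statistical_factor) {
  titr <- nM_to_M(series$titrant_total)
  lab <- nM_to_M(series$labeled_total)
  switch(model_tag,
    one_to_one = fraction_bound_1to1(lab, titr, kd),
    self_association = fraction_bound_self(lab, titr, kd, statistical_factor),
    stop("unknown MST model tag: ", model_tag))
}

#' Fit an MST dose-response series
#'
#' Least-squares fit of (Kd, Fnorm of the free state, Fnorm of the bound
#' state). The two endpoint amplitudes enter the model linearly and are
#' profiled out analytically; the search over log10(Kd) uses a coarse grid
#' across \[-9, -1\] molar followed by Brent refinement, which is robust for
#' this one-dimensional smooth objective. An optional parametric Monte Carlo
#' resample provides a percentile confidence interval.
#'
#' @param series an [mst_series()].
#' @param model_tag `"self_association"` (trace-label homodimerization,
#'   default) or `"one_to_one"`.
#' @param statistical_factor for the self-association model, see
#'   [fraction_bound_self()].
#' @param n_mc Monte Carlo iterations for the CI (0 = none).
#' @param ci_level confidence level for the percentile interval.
#' @param seed integer seed for the Monte Carlo resample.
#' @return An object of class `mst_fit` with `kd` (molar), `f_free`,
#'   `f_bound` (per mil), `model_tag`, `residual_rms` and optionally `kd_ci`.
#' @export
fit_mst <- function(series, model_tag = c("self_association", "one_to_one"),
                    statistical_factor = TRUE, n_mc = 0L, ci_level = 0.95,
                    seed = 1L) {
  stopifnot(inherits(series, "mst_series"))
  model_tag <- match.arg(model_tag)
  fit1 <- mst_fit_core(series, model_tag, statistical_factor)
  amplitude <- abs(fit1$f_bound - fit1$f_free)
  if (amplitude < 3 * fit1$residual_rms)
    stop(sprintf(
      "unidentifiable amplitude: |f_bound - f_free| = %.3g is below 3x residual RMS (%.3g)",
      amplitude, fit1$residual_rms))
  if (n_mc > 0L) {
    set.seed(seed)
    model <- fit1$f_free + (fit1$f_bound - fit1$f_free) *
      mst_model_fraction(series, fit1$kd, model_tag, statistical_factor)
    ## unbiased noise estimate: SSR/(n - p) with p = 3 fitted parameters
    sigma_hat <- fit1$residual_rms *
      sqrt(length(series$fnorm) / max(length(series$fnorm) - 3L, 1L))
    draws <- vapply(seq_len(n_mc), function(i) {
      sim <- series
      sim$fnorm <- model + stats::rnorm(length(model), 0, sigma_hat)
      mst_fit_core(sim, model_tag, statistical_factor,
                   center = log10(fit1$kd))$kd
    }, numeric(1))
    alpha <- (1 - ci_level) / 2
    fit1$kd_ci <- unname(stats::quantile(draws, c(alpha, 1 - alpha)))
    fit1$ci_level <- ci_level
    fit1$n_monte_carlo <- n_mc
  }
  fit1
}

## Profiled 1-D fit: for each log10(kd) the endpoints solve a 2-parameter
## linear least squares. `center` narrows the grid for Monte Carlo refits.
mst_fit_core <- function(series, model_tag, statistical_factor,
                         center = NULL) {
  obj <- function(logkd) {
    fb <- mst_model_fraction(series, 10^logkd, model_tag, statistical_factor)
    X <- cbind(1, fb)
    fit <- stats::lm.fit(X, series$fnorm)
    sum(fit$residuals^2)
  }
  grid <- if (is.null(center)) seq(-9, -1, by = 0.25) else
    seq(center - 1.5, center + 1.5, by = 0.25)
  vals <- vapply(grid, obj, numeric(1))
  g0 <- grid[which.min(vals)]
  opt <- stats::optimize(obj, c(g0 - 0.3, g0 + 0.3), tol = 1e-8)
  logkd <- opt$minimum
  fb <- mst_model_fraction(series, 10^logkd, model_tag, statistical_factor)
  coefs <- stats::lm.fit(cbind(1, fb), series$fnorm)$coefficients
  resid <- series$fnorm - (coefs[1L] + coefs[2L] * fb)
  structure(list(kd = 10^logkd, f_free = unname(coefs[1L]),
                 f_bound = unname(coefs[1L] + coefs[2L]),
                 model_tag = model_tag, kd_ci = NULL,
                 residual_rms = sqrt(mean(resid^2))),
            class = "mst_fit")
}

#' @export
print.mst_fit <- function(x, ...) {
  cat(sprintf("MST fit (%s model)\n", x$model_tag))
  cat(sprintf("  Kd = %.4g M (%.3g uM)\n", x$kd, x$kd * 1e6))
  if (!is.null(x$kd_ci))
    cat(sprintf("  Kd CI [%.4g, %.4g] M at %.0f%% (n=%d MC)\n",
                x$kd_ci[1L], x$kd_ci[2L], 100 * x$ci_level, x$n_monte_carlo))
  cat(sprintf("  Fnorm free = %.2f, bound = %.2f per mil; residual RMS = %.3g\n",
              x$f_free, x$f_bound, x$residual_rms))
  invisible(x)
}

#' Construct an ITC titration record
#'
#' @param cell_volume active cell volume, microlitres.
#' @param cell_conc cell (macromolecule) concentration, micromolar.
#' @param syringe_conc syringe (ligand) concentration, micromolar.
#' @param injection_volumes per-injection volumes, microlitres.
#' @param heats integrated heat per injection, microcalories (may be `NULL`
#'   for a design used only in simulation).
#' @param temperature kelvin.
#' @return An object of class `itc_experiment`.
#' @export
itc_experiment <- function(cell_volume, cell_conc, syringe_conc,
                           injection_volumes, heats = NULL,
                           temperature = 298.15) {
  injection_volumes <- as.numeric(injection_volumes)
  if (any(c(cell_volume, cell_conc, syringe_conc, injection_volumes) <= 0))
    stop("volumes and concentrations must be positive")
  if (!is.null(heats) && length(heats) != length(injection_volumes))
    stop("heats and injection_volumes lengths differ")
  if (sum(injection_volumes) > 0.5 * cell_volume)
    warning("cumulative injected volume exceeds half the cell volume; ",
            "the perfusion approximation degrades")
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = injection_volumes,
                 heats = heats, temperature = temperature),
            class = "itc_experiment")
}

## One-site bound concentration in the cell (molar), sites = n * P.
one_site_bound <- function(P_tot, L_tot, kd, n_stoich) {
  S <- n_stoich * P_tot
  s <- S + L_tot + kd
  (s - sqrt(s^2 - 4 * S * L_tot)) / 2
}

#' One-site ITC injection-heat model
#'
#' Forward model for integrated injection heats in a perfusion-cell
#' calorimeter. After each injection of volume \eqn{v} into active volume
#' \eqn{V}, existing cell contents are diluted by \eqn{(1 - v/V)}; cell and
#' ligand totals are updated accordingly, the bound concentration follows
#' the exact one-site quadratic with stoichiometry \eqn{N}, and the heat of
#' injection \eqn{i} is
#' \deqn{q_i = \Delta H \, V \, (b_i - b_{i-1}(1 - v_i/V)) + q_{dil}}
#' converted to microcalories (1 cal = 4.184 J).
#'
#' @param exp an [itc_experiment()] (its `heats` field is ignored).
#' @param kd dissociation constant, molar.
#' @param dH enthalpy change, kJ/mol.
#' @param n_stoich stoichiometry (sites per macromolecule).
#' @param q_dil constant dilution-heat offset per injection, microcalories.
#' @return Heat per injection, microcalories.
#' @export
itc_heats <- function(exp, kd, dH, n_stoich = 1, q_dil = 0) {
  stopifnot(inherits(exp, "itc_experiment"))
  V <- exp$cell_volume * 1e-6            # litres
  P <- uM_to_M(exp$cell_conc)
  L <- 0
  b_prev <- 0
  q <- numeric(length(exp$injection_volumes))
  for (i in seq_along(exp$injection_volumes)) {
    v <- exp$injection_volumes[i] * 1e-6
    f <- 1 - v / V
    P <- P * f
    L <- L * f + uM_to_M(exp$syringe_conc) * v / V
    b <- one_site_bound(P, L, kd, n_stoich)
    q_joule <- dH * 1000 * V * (b - b_prev * f)
    q[i] <- q_joule / 4.184 * 1e6 + q_dil
    b_prev <- b
  }
  q
}

#' Fit a one-site ITC titration
#'
#' Least squares over (log10 Kd, N, dH, q_dil). The enthalpy and the
#' dilution offset enter the model linearly and are profiled out; the
#' nonlinear search over (log10 Kd, N) runs Nelder-Mead from five log-spaced
#' Kd starts. Thermodynamic quantities (dG, TdS) are derived at the
#' experiment temperature into a [thermo_result()].
#'
#' @param exp an [itc_experiment()] with measured `heats`.
#' @param discard_first drop the first injection before fitting (common
#'   practice for diffusion-corrupted first injections; default FALSE).
#' @param n_starts multistart count for log10(Kd).
#' @return An object of class `itc_fit` with elements `thermo`
#'   (a [thermo_result()]), `q_dilution` (ucal), `residual_rms` (ucal) and
#'   `c_value_warning` (TRUE when \eqn{c = N [cell]/K_d} falls outside
#'   \[0.05, 5000\], where the isotherm poorly constrains the parameters).
#' @export
fit_itc <- function(exp, discard_first = FALSE, n_starts = 5L) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (is.null(exp$heats)) stop("experiment carries no measured heats")
  if (length(exp$heats) < 8L) stop("need at least 8 injections to fit")
  keep <- if (discard_first) -1L else seq_along(exp$heats)
  design <- exp

  obj_linear <- function(logkd, n_stoich) {
    ## unit-dH heats (kJ/mol = 1) with zero offset give the linear basis
    base <- itc_heats(design, 10^logkd, dH = 1, n_stoich = n_stoich,
                      q_dil = 0)[keep]
    y <- exp$heats[keep]
    X <- cbind(base, 1)
    cf <- stats::lm.fit(X, y)$coefficients
    resid <- y - X %*% cf
    list(ssr = sum(resid^2), dH = unname(cf[1L]), q_dil = unname(cf[2L]),
         resid = resid)
  }
  obj <- function(par) {
    if (par[2L] <= 0.05 || par[2L] > 10) return(1e30)
    obj_linear(par[1L], par[2L])$ssr
  }
  starts <- seq(-7, -3, length.out = n_starts)
  best <- NULL
  for (s0 in starts) {
    res <- tryCatch(stats::optim(c(s0, 1), obj, method = "Nelder-Mead",
                                 control = list(reltol = 1e-12,
                                                maxit = 2000)),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("all ITC optimisation starts failed")
  kd <- 10^best$par[1L]; n_stoich <- best$par[2L]
  lin <- obj_linear(best$par[1L], n_stoich)
  thermo <- thermo_result(kd, dH = lin$dH, temperature = exp$temperature,
                          n_stoich = n_stoich)
  c_value <- n_stoich * uM_to_M(exp$cell_conc) / kd
  structure(list(thermo = thermo, q_dilution = lin$q_dil,
                 residual_rms = sqrt(mean(lin$resid^2)),
                 c_value = c_value,
                 c_value_warning = (c_value < 0.05 || c_value > 5000)),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-site ITC fit\n")
  print(x$thermo)
  cat(sprintf("  q_dil = %.3g ucal/injection; residual RMS = %.3g ucal\n",
              x$q_dilution, x$residual_rms))
  cat(sprintf("  c-value = %.3g%s\n", x$c_value,
              if (x$c_value_warning) "  (outside [0.05, 5000]: low reliability)" else ""))
  invisible(x)
}
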