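props_fl <- solution_properties(84000, vbar = 0.73, density = 1.005)

test_that("reduced buoyant sigma matches the cgs hand computation", {
  # M = 84 kDa, vbar 0.73 ml/g, rho 1.005 g/ml, 11.8 krpm, 20 C:
  # omega = 2*pi*11800/60; sigma = M(1-vbar*rho)omega^2/(R_cgs*T)
  omega <- 2 * pi * 11800 / 60
  by_hand <- 84000 * (1 - 0.73 * 1.005) * omega^2 / (8.314e7 * 293.15)
  expect_equal(reduced_buoyant_sigma(props_fl, 11800), by_hand,
               tolerance = 1e-12)
  expect_equal(by_hand, 1.402, tolerance = 1e-3)
})

test_that("sigma scales quadratically with rotor speed and rejects neutral buoyancy", {
  expect_equal(reduced_buoyant_sigma(props_fl, 23600),
               4 * reduced_buoyant_sigma(props_fl, 11800), tolerance = 1e-12)
  neutral <- solution_properties(84000, vbar = 1, density = 1)
  expect_error(reduced_buoyant_sigma(neutral, 11800), "buoyancy")
})

test_that("single-species profiles are exactly log-linear in r^2", {
  sch1 <- association_scheme(1L, numeric(0))
  radii <- seq(6.96, 7.24, by = 0.001)
  sigma1 <- reduced_buoyant_sigma(props_fl, 11800)
  prof <- se_profile(sch1, sigma1, 7.1, 2e-6, radii, baseline = 0, props_fl)
  fit <- stats::lm(log(prof) ~ I(radii^2))
  expect_equal(unname(stats::coef(fit)[2]), sigma1 / 2, tolerance = 1e-9)
  expect_gt(summary(fit)$r.squared, 0.9999)
  # flat limit: sigma1 = 0 returns baseline plus the reference signal
  flat <- se_profile(sch1, 0, 7.1, 2e-6, radii, baseline = 0.05, props_fl)
  expect_equal(flat, rep(0.05 + props_fl$molar_signal * props_fl$pathlength *
                           2e-6, length(radii)), tolerance = 1e-12)
})

test_that("monomer-dimer profile equals a per-radius sum of two exponentials", {
  sch <- association_scheme(c(1, 2), 7e-6)
  radii <- seq(6.96, 7.24, by = 0.01)
  sigma1 <- 1.4
  m_ref <- 3e-6
  prof <- se_profile(sch, sigma1, 7.1, m_ref, radii, baseline = 0.02, props_fl)
  # independent per-point evaluation
  eps_l <- props_fl$molar_signal * props_fl$pathlength
  byhand <- vapply(radii, function(r) {
    mono <- m_ref * exp(sigma1 * (r^2 - 7.1^2) / 2)
    dim <- (m_ref^2 / 7e-6) * exp(2 * sigma1 * (r^2 - 7.1^2) / 2)
    0.02 + eps_l * (mono + 2 * dim)
  }, numeric(1))
  expect_equal(prof, byhand, tolerance = 1e-12)
})

test_that("se_profile guards against exponent overflow", {
  sch1 <- association_scheme(1L, numeric(0))
  expect_error(se_profile(sch1, 1e4, 6.0, 1e-6, seq(6.96, 7.24, by = 0.01),
                          0, props_fl), "model-range")
})

test_that("sector-average mass conservation matches closed forms", {
  sch1 <- association_scheme(1L, numeric(0))
  radii <- seq(6.96, 7.24, by = 0.01)
  ch <- se_channel(radii, rep(0.5, length(radii)), 11800, 0.5)
  # flat profile: sigma1 = 0 returns the reference concentration exactly
  expect_equal(conserve_mass(ch, sch1, 0, 7.1, 3e-6), 3e-6,
               tolerance = 1e-10)
  # exponential single species: symbolic integral
  # 2 int exp(k(r^2-ref^2)) r dr / (b^2-m^2) with k = sigma/2
  sigma1 <- 1.4; k <- sigma1 / 2
  analytic <- 3e-6 * (exp(k * (7.25^2 - 7.1^2)) - exp(k * (6.95^2 - 7.1^2))) /
    (k * (7.25^2 - 6.95^2))
  expect_equal(conserve_mass(ch, sch1, sigma1, 7.1, 3e-6), analytic,
               tolerance = 1e-9)
})

test_that("reference concentration solved from loading restores the loading", {
  sch <- association_scheme(c(1, 2), 7e-6)
  for (loading in c(1e-6, 5e-6, 2e-5)) {
    m_ref <- assocfit:::ref_monomer_for_loading(sch, 1.4, 7.1, 6.95, 7.25,
                                                loading)
    radii <- seq(6.96, 7.24, by = 0.01)
    ch <- se_channel(radii, rep(0.5, length(radii)), 11800, 0.5)
    expect_lt(abs(conserve_mass(ch, sch, 1.4, 7.1, m_ref) - loading) /
                loading, 1e-8)
  }
})

test_that("noise-free generator-to-fitter round trips are exact", {
  # monomer-dimer
  sch <- association_scheme(c(1, 2), 7e-6)
  e <- gen_se_noisefree(sch, props_fl, quick_se_design())
  f <- fit_se_global(e)
  expect_lt(abs(f$log10_kd - log10(7e-6)), 1e-4)
  expect_lt(max(abs(f$per_channel_baseline)), 1e-8)

  # monomer-dimer-tetramer with all species populated
  sch4 <- association_scheme(c(1, 2, 4), c(7e-6, 3e-15))
  e4 <- gen_se_noisefree(sch4, props_fl)
  f4 <- fit_se_global(e4)
  expect_lt(max(abs(f4$log10_kd - log10(c(7e-6, 3e-15)))), 1e-4)
})

test_that("mass conservation holds for every fitted channel", {
  sch <- association_scheme(c(1, 2), 7e-6)
  e <- gen_se(sch, props_fl, quick_se_design(), seed = 3)
  f <- fit_se_global(e)
  fitted_scheme <- association_scheme(c(1, 2), f$kd_estimates)
  for (i in seq_along(e$channels)) {
    ch <- e$channels[[i]]
    loading_molar <- ch$loading_signal /
      (props_fl$molar_signal * props_fl$pathlength)
    sigma1 <- reduced_buoyant_sigma(props_fl, ch$rotor_speed)
    implied <- conserve_mass(ch, fitted_scheme, sigma1,
                             0.5 * (ch$meniscus + ch$bottom),
                             f$per_channel_reference_conc[i])
    expect_lt(abs(implied - loading_molar) / loading_molar, 1e-8)
  }
})

test_that("monomer-only data fitted with a dimer scheme push Kd out of range", {
  mono <- association_scheme(c(1, 2), Inf)
  e <- gen_se(mono, props_fl, quick_se_design(), seed = 2)
  e$scheme <- association_scheme(c(1, 2), 1e-6)
  f <- fit_se_global(e)
  top_loading <- max(vapply(e$channels, function(ch) ch$loading_signal,
                            numeric(1))) /
    (props_fl$molar_signal * props_fl$pathlength)
  expect_gt(f$kd_estimates, 100 * top_loading)
  # a fit pinned at the search bound raises the boundary flag
  at_bound <- assocfit:::finalize_se_fit(-1, e)
  expect_true(at_bound$boundary_warning)
})

test_that("Monte Carlo confidence intervals behave in the limits", {
  sch <- association_scheme(c(1, 2), 7e-6)
  e <- gen_se(sch, props_fl, quick_se_design(), seed = 5)
  f <- fit_se_global(e)
  # n_iter = 0 leaves the result untouched
  f0 <- monte_carlo_ci(e, f, n_iter = 0)
  expect_identical(f0$kd_ci, NULL)
  # tiny noise gives a tiny interval around the estimate
  e_small <- gen_se_noisefree(sch, props_fl, quick_se_design())
  f_small <- fit_se_global(e_small)
  f_small <- monte_carlo_ci(e_small, f_small, n_iter = 30, seed = 1)
  width_rel <- diff(f_small$kd_ci[1, ]) / f_small$kd_estimates
  expect_lt(width_rel, 1e-3)
  expect_true(f_small$kd_ci[1, 1] <= f_small$kd_estimates &&
                f_small$kd_estimates <= f_small$kd_ci[1, 2])
  # determinism under a fixed seed
  f_a <- monte_carlo_ci(e, f, n_iter = 20, seed = 42)
  f_b <- monte_carlo_ci(e, f, n_iter = 20, seed = 42)
  expect_identical(f_a$kd_ci, f_b$kd_ci)
})

test_that("s20w correction is exact for water at 20 C and scales with buoyancy", {
  expect_equal(correct_s20w(4.0, 0.99823, 1.002, 0.73), 4.0,
               tolerance = 1e-12)
  # hand-computed example
  byhand <- 4.0 * (1.05 / 1.002) * (1 - 0.73 * 0.99823) / (1 - 0.73 * 1.005)
  expect_equal(correct_s20w(4.0, 1.005, 1.05, 0.73), byhand,
               tolerance = 1e-12)
  expect_equal(byhand, 4.2694, tolerance = 1e-4)
  # halving the buffer buoyancy factor doubles s20w
  vbar <- 0.73
  rho1 <- (1 - 0.2) / vbar   # (1 - vbar*rho) = 0.2
  rho2 <- (1 - 0.1) / vbar   # (1 - vbar*rho) = 0.1
  expect_equal(correct_s20w(4.0, rho2, 1.0, vbar),
               2 * correct_s20w(4.0, rho1, 1.0, vbar), tolerance = 1e-12)
  expect_error(correct_s20w(4.0, 1 / 0.73, 1.0, 0.73), "buoyancy")
})
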