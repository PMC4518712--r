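test_that("1:1 bound fraction hits its limits and matches a root-scan oracle", {
  expect_equal(fraction_bound_1to1(20e-9, 0, 5e-6), 0)
  expect_equal(fraction_bound_1to1(20e-9, 1, 5e-6), 1, tolerance = 1e-4)
  # independent oracle: bisect the mass balance for free titrant t:
  # bound = L*t/(Kd+t); t + L*t/(Kd+t) = T
  L <- 20e-9; Tt <- 5e-6; kd <- 5e-6
  t_free <- stats::uniroot(function(t) t + L * t / (kd + t) - Tt,
                           c(0, Tt), tol = 1e-18)$root
  expect_equal(fraction_bound_1to1(L, Tt, kd), t_free / (kd + t_free),
               tolerance = 1e-9)
})

test_that("trace-label self-association matches the coupled-equilibria oracle", {
  expect_equal(fraction_bound_self(20e-9, 0, 7e-6), 0, tolerance = 1e-9)
  expect_equal(fraction_bound_self(20e-9, 1e-5, Inf), 0)
  # full five-species oracle (L, U, LU, LL, UU): the trace-label
  # approximation is accurate to a few parts in 10^3 at 20 nM label
  # (exact at the design point 12.5 uM) and converges as the label thins
  for (U in c(1e-6, 12.5e-6, 5e-5)) {
    expect_lt(abs(fraction_bound_self(20e-9, U, 7e-6) -
                    oracle_label_bound(20e-9, U, 7e-6)), 5e-3)
  }
  expect_equal(fraction_bound_self(1e-11, 12.5e-6, 7e-6),
               oracle_label_bound(1e-11, 12.5e-6, 7e-6),
               tolerance = 1e-6)
})

test_that("self-association isotherm reduces to 1:1 when the titrant cannot homodimerize", {
  # oracle with the U*U step off and a genuinely trace label: free titrant
  # equals total titrant, giving the 1:1 isotherm at kd_het
  U <- 10^seq(-7, -4.3, length.out = 8)
  oracle_no_uu <- vapply(U, function(u)
    oracle_label_bound(1e-10, u, 7e-6, uu_dimerizes = FALSE), numeric(1))
  direct_11 <- fraction_bound_1to1(1e-10, U, 3.5e-6)
  expect_equal(oracle_no_uu, direct_11, tolerance = 1e-3)
})

test_that("bound fractions are monotone in titrant and stay in [0, 1]", {
  titr <- 10^seq(-9, -3, length.out = 200)
  for (fb in list(fraction_bound_1to1(20e-9, titr, 5e-6),
                  fraction_bound_self(20e-9, titr, 7e-6))) {
    expect_true(all(fb >= 0 & fb <= 1))
    expect_true(all(diff(fb) >= -1e-12))
  }
})

test_that("dilution series is the expected geometric sequence", {
  s <- dilution_series(50000, 0.5, 16)
  expect_equal(s[1:3], c(50000, 25000, 12500))
  expect_equal(s[16], 50000 * 0.5^15)
  expect_equal(dilution_series(10, 0.5, 2), c(10, 5))
  expect_error(dilution_series(10, 0.5, 1), "at least 2")
  expect_error(dilution_series(10, 1.2, 8), "ratio")
})

test_that("MST fits recover generating parameters at zero noise", {
  d <- synthetic_defaults()$mst
  d$noise_frac_amplitude <- 0
  for (model in c("self_association", "one_to_one")) {
    s <- gen_mst(3.9e-6, design = d, model_tag = model, seed = 1)
    f <- fit_mst(s, model)
    expect_equal(f$kd, 3.9e-6, tolerance = 1e-6)
    expect_equal(f$f_free, d$f_free, tolerance = 1e-6)
    expect_equal(f$f_bound, d$f_bound, tolerance = 1e-6)
  }
})

test_that("fitting the wrong MST model shifts the apparent Kd about two-fold", {
  d <- synthetic_defaults()$mst
  d$noise_frac_amplitude <- 0.001
  s <- gen_mst(3.9e-6, design = d, seed = 1)  # self-association truth
  f_self <- fit_mst(s, "self_association")
  f_11 <- fit_mst(s, "one_to_one")
  ratio <- f_11$kd / f_self$kd
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.8)
})

test_that("a flat series is rejected as amplitude-unidentifiable", {
  titr <- dilution_series(50000, 0.5, 16)
  set.seed(4)
  s <- mst_series(titr, 20, 800 + stats::rnorm(16, 0, 1))
  expect_error(fit_mst(s), "unidentifiable")
})

test_that("ITC heats obey the trivial and conservation limits", {
  e <- itc_experiment(200, 100, 1000, rep(2, 19))
  expect_equal(itc_heats(e, 24e-6, dH = 0, q_dil = 0.3), rep(0.3, 19))
  # enthalpy conservation at saturation: sum of heats ~ dH * N * cell moles
  e_sat <- itc_experiment(200, 20, 2000, rep(2, 30))
  q <- itc_heats(e_sat, 1e-7, dH = -10, n_stoich = 1)
  cell_moles <- 20e-6 * 200e-6
  expected_ucal <- -10 * 1000 * cell_moles / 4.184 * 1e6
  expect_equal(sum(q), expected_ucal, tolerance = 0.02)
})

test_that("ITC heats match an independent cumulative-binding oracle", {
  kd <- 24e-6; dH <- -4.9; n <- 1.0
  e <- itc_experiment(200, 100, 1000, rep(2, 19))
  q <- itc_heats(e, kd, dH, n)
  # independent implementation from closed-form dilution expressions:
  # after k injections of volume v, f = 1 - v/V:
  #   P_k = P0 f^k,  L_k = Ls (1 - f^k)
  V <- 200e-6; v <- 2e-6; f <- 1 - v / V
  bound <- function(P, L) {
    s <- n * P + L + kd
    (s - sqrt(s^2 - 4 * n * P * L)) / 2
  }
  q_oracle <- numeric(19); b_prev <- 0
  for (k in 1:19) {
    P_k <- 100e-6 * f^k
    L_k <- 1000e-6 * (1 - f^k)
    b_k <- bound(P_k, L_k)
    q_oracle[k] <- dH * 1000 * V * (b_k - b_prev * f) / 4.184 * 1e6
    b_prev <- b_k
  }
  expect_equal(q, q_oracle, tolerance = 1e-10)
})

test_that("ITC fits recover the generating parameters at zero noise", {
  d <- synthetic_defaults()$itc
  d$noise_ucal <- 0
  e <- gen_itc(24e-6, -4.9, 1.06, design = d, q_dil = 0.2, seed = 1)
  f <- fit_itc(e)
  expect_equal(f$thermo$kd, 24e-6, tolerance = 1e-4)
  expect_equal(f$thermo$dH, -4.9, tolerance = 1e-4)
  expect_equal(f$thermo$n_stoich, 1.06, tolerance = 1e-4)
  expect_equal(f$q_dilution, 0.2, tolerance = 1e-4)
  # thermodynamic identity holds in the derived result
  expect_equal(f$thermo$dG, f$thermo$dH - f$thermo$TdS, tolerance = 1e-9)
  expect_equal(f$thermo$dG, 8.314 * e$temperature * log(f$thermo$kd) / 1000,
               tolerance = 1e-9)
})

test_that("discarding the first injection still recovers the parameters", {
  d <- synthetic_defaults()$itc
  d$noise_ucal <- 0
  e <- gen_itc(24e-6, -4.9, 1.0, design = d, seed = 1)
  f <- fit_itc(e, discard_first = TRUE)
  expect_equal(f$thermo$kd, 24e-6, tolerance = 1e-3)
})

test_that("extreme c-values raise the reliability flag", {
  d <- synthetic_defaults()$itc
  d$noise_ucal <- 0.02
  e <- gen_itc(5e-3, -40, 1.0, design = d, seed = 1)  # c ~ 0.02
  f <- fit_itc(e)
  expect_true(f$c_value_warning)
})
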