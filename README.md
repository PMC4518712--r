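# assocfit

Quantifying protein self-association — the monomer–homodimer (and
higher-order) equilibria that regulate signalling proteins such as the
PI3K regulatory subunit p85α — from three orthogonal biophysical readouts,
plus structure-based auditing of the resulting dimer models.

The package is aimed at biophysicists and structural biologists who need a
scriptable, testable alternative to instrument-vendor fitting software
for:

* **Sedimentation equilibrium (AUC).** At equilibrium an ideal n-mer
  distributes radially as `c_n(r) = c_n(r0) exp[n σ (r² − r0²)/2]` with
  the reduced buoyant molar mass `σ = M(1 − v̄ρ)ω²/(RT)`. `fit_se_global()`
  fits the dissociation constants of a monomer–dimer(–tetramer) scheme
  globally over every rotor speed × loading channel, with each channel's
  reference concentration eliminated through exact mass conservation
  (`loading = 2∫ c(r) r dr / (b² − m²)`) and per-channel baselines.
  Parametric Monte Carlo resampling (`monte_carlo_ci()`) gives percentile
  confidence intervals; `correct_s20w()` applies the standard s20,w
  buffer correction.
* **Microscale thermophoresis.** `fit_mst()` fits dose–response series
  with either the exact 1:1 quadratic isotherm or a trace-label
  self-association model in which the free unlabeled monomer follows the
  dimerization quadratic and the label partitions with the statistical
  factor `K_het = K_d/2`.
* **Isothermal titration calorimetry.** `itc_heats()` implements the
  one-site perfusion-cell injection-heat model; `fit_itc()` recovers
  (K_d, ΔH, N, q_dil) and derives ΔG = RT ln K_d and TΔS = ΔH − ΔG.
* **Structure.** `sasa()` (Shrake–Rupley), `interface_area()` (buried
  area per monomer and core/rim residue classes), `contact_residues()`,
  `linker_feasible()` (can a linker of n residues span two anchors in
  cis?) and `audit_constraints()`, a declarative pass/fail engine for
  contact, burial, accessibility, interface-membership, disjointness and
  two-fold-symmetry constraints on candidate assemblies.
* **Synthetic data.** `gen_se()`, `gen_mst()`, `gen_itc()` and
  `gen_toy_dimer()` are seeded generators that emulate the corresponding
  instrument designs (3 speeds × 3 loadings at 280 nm; 16-point 1:1
  dilution from 50 μM with a 20 nM label; 19 × 2 μl injections of 10×
  ligand) so every fitting stage can be exercised end to end without raw
  data.

## Worked example

Simulate a full-length p85α-like sedimentation-equilibrium experiment
(84 kDa monomer, K_d = 7 μM truth, 0.005 AU noise), fit it globally and
attach Monte Carlo confidence intervals:

```r
library(assocfit)

scheme <- association_scheme(c(1, 2), 7e-6)           # monomer-dimer, 7 uM
props  <- solution_properties(monomer_mass = 84000)   # vbar 0.73, rho 1.005
exp_se <- gen_se(scheme, props, seed = 1)             # 3 speeds x 3 loadings
fit    <- fit_se_global(exp_se)
fit    <- monte_carlo_ci(exp_se, fit, n_iter = 100, level = 0.95, seed = 1)
fit
#> Global sedimentation-equilibrium fit
#>   scheme n = 1, 2
#>   Kd(2-mer) = 6.995e-06 M  [6.976e-06, 7.023e-06] at 95% (n=100 MC)
#>   reduced chi-square = 1.067
#>   channel RMSD range = 0.0048-0.0055 AU
```

The fitted constant recovers the generating 7 μM within the confidence
interval; a reduced χ² near 1 says the residuals match the injected
0.005 AU noise, and the per-channel RMSDs are of the same magnitude.
The same round trip for thermophoresis and calorimetry:

```r
fit_mst(gen_mst(3.9e-6, seed = 1))
#> MST fit (self_association model)
#>   Kd = 3.721e-06 M (3.72 uM)
#>   Fnorm free = 799.98, bound = 849.55 per mil; residual RMS = 0.463

fit_itc(gen_itc(24e-6, dH = -4.9, n_stoich = 1.06, seed = 4))
#> One-site ITC fit
#> Binding thermodynamics at 298.15 K
#>   Kd  = 2.595e-05 M (25.9 uM)
#>   dG  = -26.17 kJ/mol
#>   dH  = -5.00 kJ/mol
#>   TdS = 21.17 kJ/mol
#>   N   = 0.998
#>   q_dil = -0.00299 ucal/injection; residual RMS = 0.0763 ucal
#>   c-value = 3.84
```

Single noisy realisations scatter around the truth (the ITC fit above
reads 25.9 μM for a 24 μM truth); medians over many seeds, as used in the
acceptance checks, centre on the generating constants. A thin command
line with the same functionality ships in `inst/cli/assocfit.R`
(`simulate`, `fit` and `struct` subcommands).

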