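---
title: "Models and methods behind assocfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind assocfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocfit)
```

assocfit quantifies reversible protein self-association — typified by the
monomer–homodimer equilibrium of the PI3K regulatory subunit p85α — from
sedimentation equilibrium, thermophoresis and calorimetry, and audits
structural models of the resulting dimer. This vignette documents the
models, the numerical choices, the defaults and their rationale, and what
the synthetic-data generators do and do not emulate.

## Mass-action equilibria and conventions

A self-association pathway is a set of stoichiometries $(1, n_2, \dots)$
with one dissociation constant per oligomer, **always defined on monomer
units**: $K_{d,n} = [M]^n/[\text{n-mer}]$, with units $M^{n-1}$. For the
monomer–dimer–tetramer scheme the tetramer constant is therefore the
overall $[M]^4/[T]$; a dimer-of-dimers constant $K' = [D]^2/[T]$ converts
as $K_{d,4} = K' K_{d,2}^2$. We chose the overall convention because it
maps directly onto the sedimentation-equilibrium exponential model and is
unambiguous when intermediate species are not populated.

`solve_species()` finds the free monomer from
$c_\mathrm{tot} = m + \sum_i n_i m^{n_i}/K_{d,i}$ by bracketed bisection
on $[0, c_\mathrm{tot}]$ to a relative tolerance of $10^{-12}$. The
left-hand side is strictly increasing in $m$, so the root is unique and
bisection cannot fail; one code path serves every scheme, and the
closed-form dimerization quadratic is kept only as a test oracle.

Thermodynamic derivation uses $\Delta G = RT\ln(K_d/1\,\mathrm{M})$ with
$R = 8.314\ \mathrm{J\,mol^{-1}K^{-1}}$ and $T\Delta S = \Delta H -
\Delta G$, so both identities hold exactly by construction in every
`thermo_result`. Internal units are molar, kelvin and kJ/mol throughout;
the experiment constructors accept the units the instruments report
(nM for MST, μM and μl for ITC, mg/ml for AUC loadings).

## Sedimentation equilibrium

At equilibrium an ideal species of stoichiometry $n$ follows
$c_n(r) = c_n(r_0)\exp[n\sigma_1(r^2 - r_0^2)/2]$, where
$\sigma_1 = M_1(1-\bar v\rho)\omega^2/(RT)$ is the monomer reduced
buoyant molar mass (cm$^{-2}$; cgs gas constant $8.314\times 10^7$
erg mol$^{-1}$K$^{-1}$). The observed signal is
$a(r) = b + \epsilon\ell\sum_i n_i c_i(r)$ with the species linked by
mass action at the reference radius.

**Global fitting.** The dissociation constants (as $\log_{10} K_d$,
bounds $[-9,-1]$ per molar order — scaled by $n-1$ for higher oligomers)
are shared across all channels. Two nuisance groups are handled inside
the objective rather than by the optimizer:

* *Mass conservation as a hard constraint.* For each channel the
  reference free-monomer concentration is solved so that the
  sector-average concentration $2\int_m^b c(r)\,r\,dr/(b^2-m^2)$ equals
  the known loading. The per-species sector integrals have closed forms,
  so this is a fast bracketed root solve; the public `conserve_mass()`
  recomputes the average by adaptive quadrature as an independent check,
  and a fitted experiment satisfies the constraint to better than
  $10^{-8}$ relative by construction.
* *Baselines.* Each channel has its own additive baseline (optical
  offsets differ between cells), profiled analytically as the residual
  mean and clamped to ±0.1 AU. Whether the original analyses shared
  baselines across channels is not documented; per-channel fitting is the
  conservative standard choice and costs little given thousands of radial
  points.

The remaining 1–2 dimensional search runs L-BFGS-B from five starts
log-spaced two decades either side of a moment-based guess (the apparent
association state from single-exponential slopes, mapped to a $K_d$ at
the median loading); multi-constant schemes get a Nelder–Mead polish
because the dimer and tetramer constants are strongly correlated. The
weighted objective uses each channel's stated noise level, and the
reported reduced $\chi^2$ divides by $N - (\text{constants} +
\text{baselines})$.

**Monte Carlo confidence intervals.** Parametric resampling, matching
common AUC practice: Gaussian noise at the per-channel residual scale is
added to the best-fit model, each replicate is refit from the best-fit
parameters, and the percentile interval at the requested level is
reported (deterministic under a fixed seed; a residual-bootstrap variant
is available through the noise option). For the small-sample isotherm
fits the resampling noise uses the degrees-of-freedom-corrected estimate
$\sqrt{SSR/(n-p)}$ — with 16 points and 3 parameters the raw residual RMS
underestimates the noise by ~10% and the intervals would undercover.

**Geometry and optics defaults.** Column geometry is not something the
study protocols record, so the generator uses a conventional short
column: meniscus 6.95 cm, bottom 7.25 cm, radial spacing 0.001 cm (the
acquisition setting), pathlength 1.2 cm for 12-mm cells. The molar signal
defaults to $0.75 \times M$ per monomer — a specific absorbance of 0.75
AU·ml·mg$^{-1}$·cm$^{-1}$ at 280 nm, a typical protein value chosen so a
1.0 mg/ml loading reads ≈0.9 AU — and is a configuration field shared by
generator and fitter, never a fitted parameter. Solution properties
default to $\bar v = 0.73$ ml/g, $\rho = 1.005$ g/ml, $T = 293.15$ K;
`correct_s20w()` uses $\eta_{20,w} = 1.002$ cP and $\rho_{20,w} =
0.99823$ g/ml.

## Binding isotherms

**MST.** The readout is modelled as
$F(c) = F_\mathrm{free} + (F_\mathrm{bound}-F_\mathrm{free})\,f_b(c)$.
For a 1:1 interaction $f_b$ is the exact quadratic solution of the mass
balance. For a self-associating titration — trace-labeled protein
titrated with its unlabeled self — the free unlabeled monomer $u$ comes
from the dimerization quadratic $u + 2u^2/K_d = U$, and the label
partitions as $f_b = u/(K_\mathrm{het}+u)$. By default
$K_\mathrm{het} = K_d/2$: a labeled–unlabeled pair forms in two
indistinguishable ways while either homodimer forms in one, so the
heterodimer is statistically favoured two-fold. The toggle exists because
vendor software typically fits a plain 1:1 isotherm without the factor —
fitting the wrong model shifts the apparent $K_d$ about two-fold, which
is of the same order as the AUC/MST discrepancies often seen for
self-associating systems. The label concentration (20 nM) is assumed not
to perturb the unlabeled equilibrium; against a full five-species
(L, U, LU, LL, UU) reference solution the approximation is exact to a few
parts in $10^3$ at that label level.

The two endpoint amplitudes are linear parameters and are profiled by
linear least squares at each trial $K_d$, leaving a smooth 1-D objective
over $\log_{10} K_d$ that a coarse grid plus Brent refinement solves
reliably in milliseconds. A fit whose amplitude falls below three times
the residual RMS is rejected as unidentifiable rather than reported.

**ITC.** The one-site injection-heat model updates cell contents with the
perfusion dilution factor $(1-v/V)$ per injection, solves the exact
binding quadratic with stoichiometry $N$, and reports
$q_i = \Delta H\,V\,(b_i - b_{i-1}(1-v_i/V)) + q_\mathrm{dil}$ in μcal
(1 cal = 4.184 J). $\Delta H$ and $q_\mathrm{dil}$ are linear and
profiled; Nelder–Mead searches $(\log_{10}K_d, N)$ from five starts. The
c-value $N[\mathrm{cell}]/K_d$ is attached with a reliability flag
outside $[0.05, 5000]$. The first injection is retained by default (the
generator injects no first-injection artifact); `discard_first` mirrors
the common practice for real data. The default design — 19 × 2 μl of
1 mM ligand into a 100 μM, 200 μl cell at 25 °C — gives c ≈ 4 at a 24 μM
constant: heats of a couple of μcal against 0.1 μcal noise, which is why
single realisations scatter by tens of percent while 50-seed medians
centre within a few percent.

## Structural interface analysis

**SASA.** Shrake–Rupley sampling with a deterministic golden-spiral point
set (default 960 points, probe 1.4 Å) over element-keyed van der Waals
radii ("protor"-style by default, a NACCESS-style alternative, both
tagged in every result, with per-element overrides for pseudo-atoms).
Published buried-area figures rarely state their algorithm or radii, and
across radii sets our areas vary by several percent — hence comparisons
against literature areas should allow ±10%. Deterministic sampling makes
results exactly reproducible; the residual direction dependence decays as
1/points (≈0.3% at 960, below 0.05% at 12000), so invariance-critical
comparisons should raise `n_points`. Exactly coincident equal-radius
atoms are counted once; unknown elements fall back to 1.8 Å with a
warning (or an error on request). Hydrogens are ignored.

**Interfaces.** Buried area per monomer is
$(SASA_A + SASA_B - SASA_{AB})/2$. Residues touched by the interface
(ΔSASA > 0) are *core* when essentially buried in the complex (relative
SASA < 7%, against extended-state reference areas per residue type)
while accessible in the free monomer, otherwise *rim* — the standard
relative-accessibility partition of protein interfaces. Contact pairs
use an inclusive 4.5 Å heavy-atom cutoff.

**Linker feasibility.** A linker of $n$ residues can span at most
$n \times d_\mathrm{max}$ between anchors; the default
$d_\mathrm{max} = 3.8$ Å (Cα–Cα virtual bond) is a deliberate upper
bound — a verdict of *infeasible in cis* is then conservative and robust,
which is the direction this test is used in. The trans-peptide contour
length 3.63 Å/residue is selectable.

**Constraint audit.** Declarative records (contact, interface-membership,
burial, accessibility, set-disjointness, two-fold symmetry) are evaluated
independently against a model; a constraint naming an absent residue is
reported *unevaluable*, never failed, so partial models can be audited.
Two-fold symmetry superposes chain A onto B (Kabsch) and applies the same
transform again: for a true C2 the transform is an involution, and the
round-trip RMSD is the reported deviation. A default constraint file for
the homodimeric p85α:PTEN assembly ships in
`inst/extdata/p85a_pten_constraints.txt`; it encodes the main-text
constraints (the M176-centred BH:BH contacts, PTEN-surface membership of
I127/I133/E137, burial of the PTEN ubiquitination site K13, W298/PR2
proximity, GTPase-site disjointness, dimer symmetry) and is
user-extensible — the full original constraint list is not public, so the
file is a starting point, not a reproduction. Crystal-symmetry mate
generation is out of scope: dimers must be provided as two-chain files.

## Synthetic data: what it does and does not emulate

The generators reproduce the *designs* of the underlying study: SE at
11.8/12.8/13.8 krpm × 1.0/0.5/0.25 mg/ml, 280 nm, 20 °C (monomer masses
84/37/25 kDa for the full-length, SH3-PR1-BH-PR2 and PR1-BH constructs);
MST with a 20 nM label and a 16-point 1:1 dilution from 50,000 nM; ITC
as above. Noise is i.i.d. Gaussian at realistic instrument magnitudes
(SE 0.005 AU per point; MST 1% of the response amplitude, i.e. 0.5‰ for
the default 50‰ window; ITC 0.1 μcal), with all randomness governed by a
single integer seed giving byte-identical reruns.

Real data additionally contain systematic structure the generators omit:
time-invariant and radial-invariant noise components, meniscus and
baseline drifts, nonideality at high loading, aggregation, incompetent
fractions, labeling artifacts and first-injection anomalies. Passing
recovery tests therefore demonstrates that the estimators are unbiased
and well-conditioned *under the stated designs and noise model* — not
that every systematic effect in real experiments is handled. The MST
point count (16) and the ITC injection count (19) are instrument
conventions, not published values.

## Problem sizes and test design

The test-suite recovery checks use the full instrument design: 25 seeded
SE datasets per construct (9 channels × ~290 radial points each) and 50
seeded MST/ITC series, matching the replication used by the acceptance
script; confidence-interval coverage (≥ 90/100 at the 95% level) is
measured on the MST fitter, where one fit costs milliseconds, with 100
replications × 100 Monte Carlo iterations. SE Monte Carlo intervals are
exercised at 100 iterations. Unit tests that probe fitter mechanics
rather than study designs use a reduced single-speed, two-loading layout.

## Known limitations

* Ideal sedimentation only: no Lamm-equation solving, no c(s)/c(M)
  distributions, no nonideality coefficients.
* The MST model describes equilibrium partitioning amplitudes, not
  thermophoresis physics (temperature-jump kinetics, photobleaching).
* ITC is one-site only; no displacement or multi-site schemes.
* The SE fitter assumes the monomer molar mass is known (from sequence),
  as in the reference workflow; it is not a fitted parameter.
* SASA is pure R and aimed at the asymptotically small structures used
  here (interfaces of a few hundred residues take seconds, not
  milliseconds).
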