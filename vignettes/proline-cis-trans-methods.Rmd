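---
title: "Methods: proline cis/trans subensemble analysis"
author: "ProlineEnsembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proline cis/trans subensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProlineEnsembles)
```

## The scientific problem

Intrinsically disordered peptides with proline residues populate two
slowly exchanging families of conformers distinguished by the peptide-bond
torsion preceding the proline: trans (omega near 180 degrees, the dominant
form) and cis (omega near 0, typically 5--10% in disordered chains).
Because the interconversion takes seconds to minutes, NMR resolves
separate signals for the two states, while conformer ensembles from
enhanced-sampling simulations can be decomposed frame-by-frame into cis
and trans subensembles.  This package implements the analysis chain that
connects these two views for a 21-residue disordered peptide with a single
proline (the default sequence SKSLTENKYSQLDEEQPMEID carries it at
position 17):

1. geometric analysis of conformer ensembles (dihedrals, radius of
   gyration, end-to-end distance, contact maps, CV series);
2. a synthetic conformer generator that stands in for microsecond-scale
   enhanced-sampling trajectories at desk scale;
3. SAXS forward modelling (Debye formula, Guinier analysis) and
   Bayesian/maximum-entropy (BME) reweighting of frame weights against
   experimental SAXS intensities;
4. convergence assessment of weighted CV series by blocking analysis;
5. cis/trans subensemble statistics (populations, weighted kernel density
   estimates, split-half uncertainties, secondary-structure populations);
6. NMR observable analyses: slow-exchange populations from peak volumes,
   van 't Hoff thermodynamics, amide temperature coefficients, secondary
   structure propensity scores, the proline Cb--Cg isomer diagnostic,
   15N relaxation with reduced spectral density mapping, and DOSY
   diffusion with Kirkwood/Stokes--Einstein forward models.

## Conformer model

Chains are built in internal coordinates (NeRF-style extension) from
per-residue phi/psi/omega torsions with canonical bond geometry
(N--CA 0.1458 nm, CA--C 0.1525 nm, C--N 0.1329 nm, C=O 0.1231 nm;
standard planar/tetrahedral angles, all configurable through
`backboneGeometry()`).  Only backbone atoms (N, CA, C, O) plus the proline
CD are constructed: CD is what the zeta improper dihedral
(CA[i-1], O[i-1], CD[i], CA[i]) needs, and zeta together with the
preceding psi is the CV pair that reports on isomerization.  Torsions
follow the IUPAC sign convention (0 = cis/syn, right-handed positive);
the implementation is pinned by tests against an independent
rotation-matrix construction and a direct atan2 torsion oracle.

Isomer classification uses |omega| < 90 as cis, with the boundary value
assigned trans.  The 90-degree midpoint cleanly separates the two narrow
planarity basins (the generator's omega spread is 8 degrees, so the
boundary region is effectively unpopulated).

The contact map uses CA--CA distances with a 0.8 nm default cutoff.  This
is a deliberate, documented choice: the heavy-atom "minimum distance"
variant is not available for backbone-only synthetic chains, and 0.8 nm
is a common CA contact threshold.  The cutoff is exposed as a parameter.

## Synthetic ensemble generator

`sampleEnsemble()` draws each residue's (phi, psi) from a three-basin
mixture -- PPII (-75, 150) with probability 0.45, beta (-120, 130) with
0.35, alpha-R (-60, -45) with 0.20, angular SD 15 degrees, proline phi
fixed at -65 -- which emulates coil-library statistics of a disordered
chain.  All peptide bonds are trans (180 +/- 8 degrees SD) except the
proline bond, which is cis (0 +/- 8) with probability `cisFraction`.
The default `cisFraction = 0.10` matches the typical cis-proline content
of disordered chains and the population regime the NMR analyses address.

Self-clashing frames (any atom pair three or more bonds apart closer than
0.25 nm) are rejected and redrawn.  Compactness is tunable through
rejection sampling: a frame is accepted with probability
min(1, (rgRef/Rg)^c), where c is the `compaction` exponent (default 0,
i.e. off) and rgRef defaults to 1.0 nm, a typical coil dimension for a
21-mer.  The bias can be restricted to cis or trans frames
(`compactIsomer`), which provides ensembles in which one isomer is
deliberately more compact -- the configuration used to exercise the
subensemble comparisons.  Rejection sampling (rather than MCMC) keeps
frames exactly independent and bit-reproducible for a given seed.

Two properties of the generator deserve emphasis:

* **The isomer label is drawn before the conformation.**  Cis frames
  clash more often than trans frames (the cis bond folds the chain back
  on itself), so rejection operates conditionally on the label; otherwise
  the realized cis fraction would be biased well below the requested one.
  With this design the realized fraction is exactly binomial.
* **Cis frames are inherently slightly more compact.**  Even with
  identical basin sampling and no compaction bias, the chain-reversing
  geometry of a cis bond lowers the mean Rg of the cis subset by roughly
  0.1 nm for this 21-mer.  This is physically expected -- it matches the
  experimental observation that the cis subensemble diffuses faster --
  and tests assert the direction and smallness of the offset rather than
  pretending the two subsets are exchangeable.

What the generator does *not* emulate: force-field energetics, realistic
absolute Rg values (backbone-only chains are systematically smaller than
all-atom ensembles), side chains beyond the proline CD, and any coupling
between sequence and local conformational preferences.  Tests passing on
generated ensembles therefore validate the analysis machinery, not
force-field accuracy.

## SAXS forward model and BME reweighting

The Debye formula with one unit-amplitude scattering centre per residue
at CA gives I(q) = sum_ij f_i f_j sinc(q r_ij).  This coarse model is
deliberate: reweighting mechanics only require per-frame observables that
respond to global dimensions, not atomic-detail form factors or hydration
shells.  Per-residue amplitudes are configurable for users who want a
residue-weighted variant, and the predictor behind `saxsPerFrameMatrix()`
is the single place a more detailed forward model would plug in.

Guinier analysis fits ln I against q^2 by weighted least squares on the
low-q window with q Rg <= 1.3 (standard for disordered proteins),
iterating the window twice to self-consistency; Rg = sqrt(-3 slope).
A positive slope is reported as "Rg undefined" rather than NaN.

BME reweighting minimizes the convex dual
Gamma(lambda) = ln Z(lambda) + sum_j lambda_j o_j +
(theta/2) sum_j lambda_j^2 sigma_j^2
from lambda = 0 with BFGS followed by damped Newton polishing (the
Hessian Cov_w(F) + theta diag(sigma^2) is analytic and positive
definite), giving gradient norms at machine precision; convergence is
judged relative to the scale of the observables so intensity units do not
matter.  Posterior weights below 1e-300 are floored to zero and
renormalized.  For SAXS restraints, `reweightSAXS()` alternates
scale/offset refitting of the calculated curve (offset on by default;
both variants available) with weight updates for five rounds.  theta is
chosen from `thetaScan()` as the largest value with reduced posterior
chi-squared at or below 1.2 -- the gentlest reweighting that still fits,
a "minimal perturbation" criterion.  The scan's chi-squared and phi_eff
are monotone in theta, which the tests verify.

## Blocking analysis

Convergence of weighted CV series is assessed with a weighted
Flyvbjerg--Petersen scheme: contiguous blocks of b frames contribute
weighted block means with block weight sums as masses, and
SE^2 = sum_k p_k (m_k - M)^2 / (K - 1).  Block sizes default to powers
of 2 up to n/4.  The plateau criterion declares convergence when the SE
changes by less than 10% (configurable) across the last three block
sizes, reporting their mean as the plateau SE.  For assertions against
analytic values the tests cap block sizes at n/64, because SE estimates
from fewer than ~16 blocks are themselves too noisy to test tightly;
the default ladder is still available for exploratory use.  Free-energy
surfaces use -ln p of weighted histograms with per-bin errors propagated
from block-to-block probability spread (SE_F = SE_p / p); bins empty in
any block report NA errors rather than a misleading zero.

## Subensemble statistics

`splitByIsomer()` classifies every frame, sums prior weights per isomer
(the populations add to 1 exactly) and renormalizes weights within each
subensemble.  Weighted KDEs use a direct Gaussian kernel sum -- exact, so
the full-ensemble KDE equals the population-weighted mixture of
subensemble KDEs to machine precision -- with Silverman's bandwidth
evaluated at the weighted effective sample size n_eff = 1/sum(w^2).
Split-half uncertainties evaluate a metric on the first and second halves
of the frames in order (mirroring trajectory-half error bars) and report
|a - b|/sqrt(2).

Secondary structure is assigned from (phi, psi) regions -- helix for phi
in (-100, -30) and psi in (-77, -7), strand for phi in (-180, -90) with
psi in (90, 180] or below -170, coil otherwise -- because backbone-only
chains lack the hydrogen-bond geometry a DSSP-style assignment needs.
The regions are documented and configurable in source; they are a
substitute for, not a reimplementation of, H-bond-based assignment.

## NMR thermodynamics

In slow exchange, peak volumes are proportional to state concentrations,
so p_cis = V_cis/(V_cis + V_trans) per residue; the aggregate is the mean
and SD across reporter residues.  Equilibrium constants K = p/(1-p) enter
the van 't Hoff regression of ln K on 1/T (weighted by 1/sigma_lnK^2 when
uncertainties are given): dH = -R x slope, dS = R x intercept,
R = 8.314 J K^-1 mol^-1, standard errors from the regression covariance.
Populations at any temperature follow from
K(T) = exp(-(dH - T dS)/(R T)).  Temperatures are kelvin internally
(37 C = 310.15 K; 15 C = 288.15 K) to avoid 0.15 K drift.  The fixture
generator reproduces these relations exactly at zero noise, which pins
the regression implementation.

Amide temperature coefficients are least-squares slopes in ppb/K; slopes
more negative than -4.5 ppb/K flag amides without persistent
intramolecular hydrogen bonds.  The proline isomer diagnostic uses the
Cb--Cg shift difference with a conservative band: cis for >= 8 ppm,
trans for <= 6 ppm, ambiguous between (the literature anchors are near
9.5 and 4.5 ppm).

The SSP-style score sums secondary shifts (observed minus random coil)
over a 5-residue window and all available nuclei (1Ha, 13Ca, 13Cb) and
normalizes positive sums by the magnitude of the full-helix reference sum
and negative sums by the full-strand magnitude, capped to [-1, 1].  The
random-coil and secondary-shift reference table ships as an editable CSV
(`shiftReferences()`) because the reference choice materially affects
scores; the shipped HA/CB secondary offsets are symmetric simplifications
of literature values, which keeps the windowed sums sign-definite.  The
window (default 5, odd, end-truncated) is configurable.

## Relaxation and diffusion

R1 and R1rho are obtained from monoexponential fits (log-linear start,
Levenberg--Marquardt refinement, covariance SEs); R2 follows from the
rotating-frame tilt correction R2 = (R1rho - R1 cos^2 theta)/sin^2 theta
with quadrature error propagation.  Reduced spectral density mapping uses
the standard 0.87 omega_H high-frequency approximation with the
coefficient set written out in `reducedSpectralDensity()`; rather than
trusting transcription, the coefficients are pinned by a round trip
against the exact forward dipolar+CSA rate equations
(`forwardRelaxationRates()`).  At 14.1 T with r_NH = 1.02 Angstrom and
Delta-sigma = -160 ppm, the mapped J(0) is within 0.5% of truth for a
2 ns single-Lorentzian spectral density, within 5% for correlation times
of 1--5 ns, and approximately 5% at 0.5 ns (fast tumbling is where the
high-frequency approximation is weakest).  The exchange-free comparison
Rex = R2 - kappa Rdd takes kappa as configuration (default 1 at matched
conditions) and flags |Rex| < 2 SE as no detectable exchange.

DOSY decays follow the Stejskal--Tanner equation
I = I0 exp(-D gamma^2 g^2 delta^2 (Delta - delta/3)); D is fitted on a
1e-10 m^2/s scale for conditioning and the fit is invariant under
intensity rescaling.  Ensemble-side diffusion predictions use the
Kirkwood approximation Rh^-1 = (1/N^2) sum_{i != j} r_ij^-1 over CA
centres, harmonically averaged over frames (mobilities, not radii,
average under fast exchange within a subensemble), and Stokes--Einstein
D = kB T/(6 pi eta Rh) with water viscosity 1.138e-3 Pa s at 288.15 K
by default.  The cis-versus-trans diffusion comparison uses a one-tailed
Welch t-test from summary statistics with Satterthwaite degrees of
freedom; the tail direction must be stated explicitly.  Printed test
statistics computed from rounded summary inputs can differ in the second
decimal from values computed on unrounded data; the implementation
reports the textbook values for the inputs it is given.

## Problem sizes and determinism

The test suite and the reproduction script generate everything they
consume.  Ensemble sizes are chosen to make each statistical assertion
sharp at desk scale: 5000 frames for binomial recovery of a 10% cis
fraction (3 binomial SDs = 1.3 points), 1200 for the cis/trans Rg offset,
100--300 frames for reweighting and diffusion directionality, 2^14 and
2^17 points for iid and AR(1) blocking checks.  Every stochastic step is
seeded; identical configuration and seed reproduce outputs bit for bit
(the RNG state is restored afterwards).

## Worked example

```{r example, eval = FALSE}
cfg <- generatorConfig(nConformers = 500, cisFraction = 0.10, seed = 7)
ens <- sampleEnsemble(cfg)

## isomer decomposition
sp <- splitByIsomer(ens, prolineResid = 17)
sp$populations

## SAXS: forward profile, Guinier Rg, BME reweighting against a profile
q <- seq(0.05, 2, length.out = 40)
prof <- saxsDebye(ens, q)
guinierFit(prof)$rg

## thermodynamics from synthetic peak volumes
tt <- seq(275.65, 313.15, length.out = 10)
tab <- peakVolumeTable(dH = 16000, dS = 34, temperatures = tt)
K <- sapply(tt, function(T) {
  equilibriumConstant(cisPopulation(tab[tab$temperature == T, ])$mean)
})
vf <- vantHoffFit(tt, K)
100 * populationAtTemperature(vf$dH, vf$dS, 310.15)
```

## Known limitations

* Backbone-only geometry: absolute Rg, Rh and contact statistics differ
  systematically from all-atom ensembles; only relative and mechanistic
  statements transfer.
* The Debye model ignores atomic form factors, excluded-volume and
  hydration effects; calculated intensities are on an arbitrary scale and
  always pass through scale/offset fitting.
* The dihedral-region secondary-structure classifier and the simplified
  SSP normalization are documented substitutes for DSSP-style assignment
  and the original SSP software.
* Chemical shifts serve as validation inputs only; no shift prediction
  beyond the random-coil table is provided, and shifts are not used as
  reweighting restraints.
* theta selection reports a documented default (largest theta with
  reduced chi-squared <= 1.2); it is a model-selection convention, not a
  reproduction of any particular published value.
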