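# ProlineEnsembles

Integrative analysis of **proline cis/trans conformational subensembles**
in intrinsically disordered peptides.

Disordered peptides containing proline exchange between two families of
conformers on the seconds-to-minutes timescale, distinguished by the
peptide-bond torsion preceding the proline: *trans* (ω ≈ 180°) and *cis*
(ω ≈ 0°, typically 5–10% of the population).  Characterizing the two
subensembles requires combining conformer ensembles (where every frame can
be classified by ω) with ensemble-averaged experiments: SAXS for global
dimensions, NMR for populations, thermodynamics, dynamics and diffusion.
This package provides that analysis chain for structural biologists and
simulators working on disordered systems, built around a 21-residue
single-proline peptide (sequence `SKSLTENKYSQLDEEQPMEID`, proline at
position 17) as the default model system.

## What it computes

| Stage | Core quantity |
|---|---|
| Conformer geometry | φ/ψ/ω/ζ torsions, Rg, end-to-end distance, CA contact maps, CV series |
| Synthetic ensembles | seeded conformer generator with tunable cis fraction and compactness |
| SAXS | Debye profiles I(q) = Σᵢⱼ fᵢfⱼ sin(q·rᵢⱼ)/(q·rᵢⱼ), Guinier Rg = √(−3·slope of ln I vs q²) |
| BME reweighting | posterior weights wᵢ ∝ w⁰ᵢ·exp(−Σⱼ λⱼFᵢⱼ) minimizing Γ(λ) = ln Z + λᵀo + (θ/2)Σλ²σ² |
| Convergence | weighted Flyvbjerg–Petersen blocking curves, FES errors, plateau detection |
| Subensembles | cis/trans populations, weighted KDEs, split-half errors, secondary-structure populations |
| NMR thermodynamics | p = V_cis/(V_cis+V_trans); ln K vs 1/T with ΔH = −R·slope, ΔS = R·intercept; amide temperature coefficients; SSP scores; the ¹³Cβ−¹³Cγ isomer diagnostic |
| Relaxation & diffusion | monoexponential R1/R1ρ fits, R2 from the tilt correction, hetNOE, reduced spectral density mapping J(0), J(ωN), J(0.87ωH), Stejskal–Tanner diffusion, Kirkwood/Stokes–Einstein forward models, one-tailed Welch tests |

The central object is the S4 `ConformerEnsemble`: ordered conformers
sharing one atom table, with normalized per-frame statistical weights and
provenance metadata.  Ensembles round-trip through multi-model PDB plus a
plain-text weight file; SAXS profiles and all NMR tables are plain text.

## Worked example

```r
library(ProlineEnsembles)

cfg <- generatorConfig(nConformers = 500, cisFraction = 0.10, seed = 7)
ens <- sampleEnsemble(cfg)

splitByIsomer(ens, prolineResid = 17)$populations
#>  cis trans
#>  0.1   0.9

prof <- saxsDebye(ens, q = seq(0.05, 2, length.out = 40))
guinierFit(prof)$rg
#> [1] 1.2966

tt  <- seq(275.65, 313.15, length.out = 10)      # ten temperatures, 2.5-40 C
tab <- peakVolumeTable(dH = 16000, dS = 34, temperatures = tt)
K   <- sapply(tt, function(T)
  equilibriumConstant(cisPopulation(tab[tab$temperature == T, ])$mean))
vf  <- vantHoffFit(tt, K)
c(dH_kJ = vf$dH / 1000, dS = vf$dS)
#>  dH_kJ     dS
#>     16     34

100 * populationAtTemperature(vf$dH, vf$dS, 310.15)
#> [1] 10.76032
```

Reading the numbers: 500 generated conformers realize the requested 10%
cis fraction exactly on this seed; the ensemble-averaged Guinier radius of
the backbone model is 1.30 nm; a noiseless synthetic peak-volume table
generated with ΔH = 16 kJ mol⁻¹ and ΔS = 34 J K⁻¹ mol⁻¹ is recovered
exactly by the van 't Hoff regression, and those parameters predict a
10.8% cis population at 37 °C — cis formation is enthalpically disfavored
but entropically favored, so the population grows with temperature.

## Documentation

The methods vignette (`vignettes/proline-cis-trans-methods.Rmd`) explains
the models, default parameters and their units, what the synthetic
generator does and does not emulate, the numerical choices (tolerances,
initialization, degenerate-input handling), and known limitations.
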