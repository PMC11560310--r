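Package: ProlineEnsembles
Title: Proline Cis/Trans Conformational Subensembles of Disordered Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of proline cis and trans conformational
    subensembles in intrinsically disordered peptides. Provides internal
    coordinate backbone construction and dihedral analysis, synthetic
    conformer-ensemble generation with a tunable cis-proline fraction,
    Debye-formula SAXS forward modelling with Guinier analysis,
    Bayesian/maximum-entropy (BME) ensemble reweighting against SAXS
    restraints, blocking analysis of weighted collective-variable series,
    cis/trans subensemble statistics (populations, weighted kernel density
    estimates, contact maps), van 't Hoff thermodynamics of the cis/trans
    equilibrium from NMR peak volumes, amide temperature coefficients,
    secondary structure propensity scores, 15N spin-relaxation analysis with
    reduced spectral density mapping, and DOSY diffusion analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
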