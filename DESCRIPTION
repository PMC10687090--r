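Package: dimerfit
Title: Monomer-Dimer Equilibrium Analysis of SAXS Concentration Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies protein homodimerization equilibria from small-angle
    X-ray scattering (SAXS) dilution series. Implements Guinier analysis with
    automatic low-q range selection, a closed-form mass-action model linking
    the apparent radius of gyration of a two-state monomer/dimer mixture to
    total protein concentration, nonlinear regression of the dissociation
    constant from Rg-versus-concentration and dimer-mole-fraction series,
    non-negative least-squares decomposition of scattering curves into
    monomer and dimer components, a Debye-formula bead-model simulator for
    generating synthetic dilution series, and Shannon-entropy conservation
    profiling of multiple sequence alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
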