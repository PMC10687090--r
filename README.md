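# dimerfit

Quantifying protein homodimerization from small-angle X-ray scattering
(SAXS) dilution series.

Many extracellular protein domains self-associate with dissociation
constants in the micromolar range — too weak for a crystal structure alone
to prove the dimer exists in solution, but strong enough to matter
physiologically. A SAXS concentration series resolves this: as total
protein concentration rises, the monomer–dimer equilibrium shifts and the
apparent radius of gyration R<sub>g</sub> grows from the monomer value
towards the dimer value. `dimerfit` turns that shift into a dissociation
constant. It was built around the dilution series of an adhesion-GPCR
N-terminal pentraxin-like domain (a ~30.5 kDa β-sandwich that forms a
two-fold symmetric homodimer), but every component is generic.

## The model

For the equilibrium M + M ⇌ D with K<sub>D</sub> = [M]²/[D], mass action
gives the free monomer concentration at total chain concentration [M]₀:

    [M] = ( −K_D + √(K_D² + 8 [M]₀ K_D) ) / 4,     f_M = [M]/[M]₀

Because a scatterer's forward intensity is proportional to its mass, a
dimer contributes twice per chain, and the apparent (z-average) squared
radius of gyration of the mixture is

    R_g² = ( f_M R_g,M² + 2 (1 − f_M) R_g,D² ) / (2 − f_M)

where R<sub>g,M</sub> and R<sub>g,D</sub> are the monomer and dimer
reference values. Composing the two expressions yields a closed-form
R<sub>g</sub>²(c) regression model with K<sub>D</sub> as the only free
parameter. An equivalent route fits the dimer mole fraction
x<sub>D</sub> = [D]/([M]+[D]) obtained by decomposing each curve into
monomer and dimer components by non-negative least squares.

The package provides, as plain R functions:

* **Guinier analysis** — `guinier_fit()`, `auto_guinier()`: weighted
  ln I vs q² regression with deterministic automatic range selection
  (qR<sub>g</sub> ≤ 1.3).
* **Equilibrium model** — `monomer_conc()`, `apparent_rg2()`,
  `rg2_vs_concentration()`, `dimer_mass_fraction_from_rg()`,
  `dimer_mole_fraction()`, `binding_free_energy()`.
* **K_D regression** — `fit_kd_from_rg()`, `fit_kd_from_xd()`,
  `fit_report()`.
* **Mixture decomposition** — `nnls_fractions()`, `series_xd()`:
  σ-weighted NNLS of an experimental curve onto per-unit-mass monomer and
  dimer curves; weights are mass fractions, converted explicitly to mole
  fractions.
* **Synthetic data** — `make_globule()`, `make_dimer()`, `debye_curve()`,
  `simulate_series()`: bead models, exact Debye-formula scattering, and
  mass-action dilution series with counting-statistics noise.
* **Conservation profiling** — `read_fasta_alignment()`,
  `conservation_profile()`: per-residue Shannon entropy (bits) of a
  multiple sequence alignment mapped to a reference sequence, with the
  conventional H < 2.0 conservation threshold.

## Worked example

The package ships the published eight-point dilution series of the
pentraxin-like domain (0.27–9.15 mg/ml) as a fixture. Fitting K_D for
each of the three theoretical glycosylation-state (R_g,M, R_g,D) pairs:

```r
library(dimerfit)
series <- g4ptx_series()
fits <- lapply(names(glyco_pairs), \(p) fit_kd_from_rg(series, p))
names(fits) <- names(glyco_pairs)
str(fit_report(fits)[c("kd_min_uM", "kd_max_uM")])
#> List of 2
#>  $ kd_min_uM: num 6.7
#>  $ kd_max_uM: num 31.7
```

So the fitted dissociation constant lies between ~7 and ~32 μM depending
on which glycosylation state is assumed for the reference radii — a weak,
transient homodimer. At the highest well-measured concentration the
observed R<sub>g</sub> of 30.4 Å implies

```r
dimer_mass_fraction_from_rg(30.4, "double")
#> [1] 0.8793702
```

i.e. ~88% of chains are dimeric. A K_D of 40 μM corresponds to a binding
free energy at 37 °C of

```r
binding_free_energy(40e-6, 310.15)
#> [1] -26.1124
```

kJ/mol on the 1 M standard state.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/dimerfit` (subcommands `guinier`, `fit-kd`, `fit-xd`,
`mixture`, `simulate`, `entropy`; all emit JSON).

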