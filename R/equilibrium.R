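#' Glycosylation-state theoretical Rg pairs
#'
#' Theoretical monomer/dimer radii of gyration (Angstrom) of the ADGRG4
#' pentraxin-like domain, averaged over conformer pools built at three
#' N-glycosylation states: `none` (unglycosylated), `single` (one occupied
#' site) and `double` (both sites occupied).
#'
#' @format A named list of `glyco_pair` objects with fields `name`, `rg_m`,
#'   `rg_d`.
#' @export
glyco_pairs <- list(
  none   = structure(list(name = "none",   rg_m = 21.94, rg_d = 29.55), class = "glyco_pair"),
  single = structure(list(name = "single", rg_m = 22.50, rg_d = 30.38), class = "glyco_pair"),
  double = structure(list(name = "double", rg_m = 23.05, rg_d = 30.84), class = "glyco_pair")
)

#' Construct a monomer/dimer theoretical Rg pair
#'
#' @param rg_m Monomer radius of gyration, Angstrom.
#' @param rg_d Dimer radius of gyration, Angstrom; must exceed `rg_m`.
#' @param name Label.
#' @return A `glyco_pair`.
#' @export
glyco_pair <- function(rg_m, rg_d, name = "custom") {
  if (!(rg_d > rg_m && rg_m > 0))
    stop("require rg_d > rg_m > 0")
  structure(list(name = name, rg_m = rg_m, rg_d = rg_d), class = "glyco_pair")
}

as_glyco_pair <- function(pair) {
  if (inherits(pair, "glyco_pair")) return(pair)
  if (is.character(pair) && pair %in% names(glyco_pairs))
    return(glyco_pairs[[pair]])
  stop("pair must be a glyco_pair or one of ",
       paste(names(glyco_pairs), collapse = "/"))
}

# gas constant, J / (mol K)
.R_GAS <- 8.314

#' Default monomer molecular mass of the G4-PTX construct, Da
#' @export
DEFAULT_MW_MONOMER <- 30500

#' Total molar chain concentration from mass concentration
#'
#' Converts a mass concentration (mg/ml, i.e. g/L) to the total molar
#' protein concentration in monomer units, `[M]0 = c / MW`.
#'
#' @param c_mg_ml Mass concentration, mg/ml.
#' @param mw_monomer Monomer molecular mass, Da.
#' @return Molar concentration, mol/L. 1 mg/ml at 30500 Da gives 3.279e-5.
#' @export
molar_from_mass_conc <- function(c_mg_ml, mw_monomer = DEFAULT_MW_MONOMER) {
  if (any(c_mg_ml <= 0)) stop("mass concentration must be positive")
  if (any(mw_monomer <= 0)) stop("molecular mass must be positive")
  c_mg_ml / mw_monomer   # (g/L) / (g/mol) = mol/L
}

#' Free monomer concentration under the mass-action dimer equilibrium
#'
#' Physical root of the mass-action quadratic `2[M]^2 + KD [M] - KD [M]0 = 0`
#' for the equilibrium M + M = D with `KD = [M]^2/[D]`:
#' `[M] = (-KD + sqrt(KD^2 + 8 [M]0 KD)) / 4`.
#'
#' @param kd Dissociation constant, mol/L.
#' @param m0 Total chain concentration, mol/L (monomer units).
#' @return Free monomer concentration `[M]`, mol/L.
#' @export
monomer_conc <- function(kd, m0) {
  if (any(kd <= 0)) stop("kd must be positive")
  if (any(m0 < 0)) stop("m0 must be non-negative")
  # algebraically equal to (-kd + sqrt(kd^2 + 8 m0 kd)) / 4, but immune to
  # the catastrophic cancellation of that form when m0 << kd
  2 * m0 / (1 + sqrt(1 + 8 * m0 / kd))
}

#' Monomer fraction f_M = [M]/[M]0
#'
#' @inheritParams monomer_conc
#' @return Fraction of chains free as monomer, in (0, 1].
#' @export
monomer_fraction <- function(kd, m0) {
  if (any(m0 <= 0)) stop("m0 must be positive")
  monomer_conc(kd, m0) / m0
}

#' Apparent squared radius of gyration of a monomer/dimer mixture
#'
#' z-average of the two species' Rg^2, weighted by their forward-scattering
#' contributions (a dimer scatters per chain twice as strongly as a
#' monomer), as a function of the monomer fraction:
#' `Rg^2 = (f_M Rg_M^2 + 2 (1 - f_M) Rg_D^2) / (2 - f_M)`.
#'
#' @param f_m Monomer fraction in `[0, 1]`.
#' @param pair A `glyco_pair` or the name of a packaged one.
#' @return Apparent Rg^2, Angstrom^2.
#' @export
apparent_rg2 <- function(f_m, pair) {
  pair <- as_glyco_pair(pair)
  if (any(f_m < 0 | f_m > 1)) stop("f_m must lie in [0, 1]")
  (f_m * pair$rg_m^2 + 2 * (1 - f_m) * pair$rg_d^2) / (2 - f_m)
}

#' Apparent Rg^2 versus total concentration (regression model)
#'
#' Closed-form composition of the mass-action monomer fraction with the
#' mixture z-average, used directly as the fit function for KD regression:
#' with `A = sqrt(KD^2 + 8 [M]0 KD)`,
#' `Rg^2 = (Rg_M^2 (A - KD) + Rg_D^2 (8 [M]0 + 2 KD - 2 A)) / (8 [M]0 + KD - A)`.
#'
#' Algebraically identical to
#' `apparent_rg2(monomer_fraction(kd, m0), pair)`.
#'
#' @param m0 Total chain concentration, mol/L.
#' @param kd Dissociation constant, mol/L.
#' @param pair A `glyco_pair` or packaged-pair name.
#' @return Apparent Rg^2, Angstrom^2.
#' @export
rg2_vs_concentration <- function(m0, kd, pair) {
  pair <- as_glyco_pair(pair)
  if (any(m0 <= 0)) stop("m0 must be positive")
  if (any(kd <= 0)) stop("kd must be positive")
  A <- sqrt(kd^2 + 8 * m0 * kd)
  (pair$rg_m^2 * (A - kd) + pair$rg_d^2 * (8 * m0 + 2 * kd - 2 * A)) /
    (8 * m0 + kd - A)
}

#' Fraction of chains in dimers from an observed Rg
#'
#' Inverts the mixture z-average for the monomer fraction at an observed
#' (Guinier) radius of gyration and returns the mass fraction of chains
#' residing in dimers, `1 - f_M`. Observed values up to 2 percent outside
#' the `[Rg_M, Rg_D]` interval are clamped with a warning; beyond that the
#' observation is inconsistent with the two-state model and an error is
#' raised.
#'
#' @param rg_obs Observed radius of gyration, Angstrom.
#' @param pair A `glyco_pair` or packaged-pair name.
#' @return Fraction of chains in dimers, in `[0, 1]`.
#' @export
dimer_mass_fraction_from_rg <- function(rg_obs, pair) {
  pair <- as_glyco_pair(pair)
  lo <- pair$rg_m; hi <- pair$rg_d
  if (rg_obs < lo * 0.98 || rg_obs > hi * 1.02)
    stop(sprintf("observed Rg %.2f A is more than 2%% outside [%.2f, %.2f]",
                 rg_obs, lo, hi))
  if (rg_obs < lo || rg_obs > hi) {
    warning(sprintf("observed Rg %.2f A clamped into [%.2f, %.2f]",
                    rg_obs, lo, hi))
    rg_obs <- min(max(rg_obs, lo), hi)
  }
  # solve rg2 (2 - f) = f rgm2 + 2 (1 - f) rgd2 for f
  f_m <- 2 * (rg_obs^2 - pair$rg_d^2) /
    (pair$rg_m^2 - 2 * pair$rg_d^2 + rg_obs^2)
  1 - min(max(f_m, 0), 1)
}

#' Dimer mole fraction x_D among particles
#'
#' Mole fraction of dimer particles, `x_D = [D]/([M] + [D])`, evaluated in
#' closed form as `x_D = x_Dmax / (1 + 4 KD / (A - KD))` with
#' `A = sqrt(KD^2 + 8 [M]0 KD)`. The saturation value `x_Dmax` rescales the
#' plateau; the physical mass-action curve has `x_Dmax = 1`.
#'
#' @inheritParams rg2_vs_concentration
#' @param xd_max Saturation mole fraction in `(0, 1]`.
#' @return Dimer mole fraction.
#' @export
dimer_mole_fraction <- function(kd, m0, xd_max = 1) {
  if (any(kd <= 0) || any(m0 <= 0)) stop("kd and m0 must be positive")
  if (any(xd_max <= 0 | xd_max > 1)) stop("xd_max must lie in (0, 1]")
  A <- sqrt(kd^2 + 8 * m0 * kd)
  xd_max / (1 + 4 * kd / (A - kd))
}

#' Standard binding free energy from a dissociation constant
#'
#' `dG = R T ln KD` on the 1 M standard state, R = 8.314 J/(mol K).
#'
#' @param kd Dissociation constant, mol/L.
#' @param temperature_k Temperature, Kelvin (310.15 K is 37 C).
#' @return Free energy, kJ/mol (negative for sub-molar KD).
#' @export
binding_free_energy <- function(kd, temperature_k = 310.15) {
  if (any(kd <= 0) || any(temperature_k <= 0))
    stop("kd and temperature must be positive")
  .R_GAS * temperature_k * log(kd) / 1000
}

#' Span of a fully extended polypeptide
#'
#' Contour span of an extended chain at a fixed rise per residue, as used
#' for stiffened, heavily O-glycosylated mucin-like stalks (2.5 Angstrom
#' per residue; an unfolded chain without stiffening is closer to 4).
#'
#' @param n_residues Number of residues.
#' @param pitch_angstrom Rise per residue, Angstrom.
#' @return Span in micrometres.
#' @export
extended_chain_span <- function(n_residues, pitch_angstrom = 2.5) {
  if (any(n_residues <= 0)) stop("n_residues must be positive")
  n_residues * pitch_angstrom * 1e-4
}
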