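# Synthetic SAXS generator: coarse-grained bead models with equal
# scattering lengths, exact Debye-formula profiles, and mass-action
# dilution series with photon-counting-style noise. Atomic detail is not
# required here: the downstream analyses only see Rg ratios and two-state
# mixing.

# run expr with a private RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Coordinate radius of gyration of a bead model
#'
#' Root-mean-square distance of the beads from their centroid, equal
#' weights.
#'
#' @param model A `bead_model` or plain Nx3 coordinate matrix (Angstrom).
#' @return Rg in Angstrom.
#' @export
coordinate_rg <- function(model) {
  xyz <- if (inherits(model, "bead_model")) model$coordinates else model
  xyz <- as.matrix(xyz)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Random compact bead model with an exact target Rg
#'
#' Beads are sampled uniformly inside a sphere and the whole cloud is
#' rescaled isotropically so that its coordinate Rg equals `rg_target`
#' exactly. Deterministic for a given seed.
#'
#' @param n_beads Number of beads (>= 10).
#' @param rg_target Target radius of gyration, Angstrom.
#' @param seed Integer RNG seed.
#' @param label Model label.
#' @return A `bead_model` with fields `coordinates` (Nx3) and `label`.
#' @export
make_globule <- function(n_beads, rg_target, seed, label = "globule") {
  stopifnot(n_beads >= 10, rg_target > 0)
  xyz <- .with_seed(seed, {
    # uniform in the unit ball: isotropic direction, radius ~ u^(1/3)
    v <- matrix(rnorm(3 * n_beads), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    v * runif(n_beads)^(1 / 3)
  })
  xyz <- sweep(xyz, 2, colMeans(xyz))
  rg0 <- sqrt(mean(rowSums(xyz^2)))
  xyz <- xyz * (rg_target / rg0)
  structure(list(coordinates = xyz, label = label), class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("Bead model '%s': %d beads, Rg = %.3f A\n",
              x$label, nrow(x$coordinates), coordinate_rg(x)))
  invisible(x)
}

#' Two-fold symmetric dimer from a monomer bead model
#'
#' The partner protomer is the monomer rotated 180 degrees about the z axis
#' through its centroid and translated by `separation` along x — the
#' C2-symmetric arrangement of a crystallographic two-fold dimer. A
#' centre-to-centre separation leaving less than 1 Angstrom between closest
#' beads triggers a steric-clash warning (not an error).
#'
#' @param monomer A `bead_model`.
#' @param separation Centre-to-centre distance, Angstrom.
#' @return A `bead_model` with twice the beads.
#' @export
make_dimer <- function(monomer, separation) {
  stopifnot(inherits(monomer, "bead_model"), separation > 0)
  a <- sweep(monomer$coordinates, 2, colMeans(monomer$coordinates))
  b <- a
  b[, 1] <- -b[, 1]; b[, 2] <- -b[, 2]      # 180 deg about z
  b[, 1] <- b[, 1] + separation
  # nearest inter-protomer approach (subsample large models for speed)
  ia <- if (nrow(a) > 400) a[seq(1, nrow(a), length.out = 400), , drop = FALSE] else a
  ib <- if (nrow(b) > 400) b[seq(1, nrow(b), length.out = 400), , drop = FALSE] else b
  d2 <- outer(rowSums(ia^2), rowSums(ib^2), "+") - 2 * tcrossprod(ia, ib)
  if (min(d2) < 1)
    warning("steric overlap: closest inter-protomer bead distance < 1 A")
  structure(list(coordinates = rbind(a, b),
                 label = paste0(monomer$label, "_dimer")),
            class = "bead_model")
}

#' Pick the dimer separation that realises a target Rg ratio
#'
#' Bisection on the centre-to-centre separation until
#' `Rg(dimer)/Rg(monomer)` matches `ratio` (the parallel-axis theorem makes
#' the dimer Rg strictly increasing in separation).
#'
#' @param monomer A `bead_model`.
#' @param ratio Target dimer/monomer Rg ratio (> 1).
#' @param tol Relative tolerance on the ratio.
#' @return Separation in Angstrom.
#' @export
dimer_separation_for_ratio <- function(monomer, ratio, tol = 1e-6) {
  stopifnot(ratio > 1)
  rg_m <- coordinate_rg(monomer)
  target <- ratio * rg_m
  # parallel-axis: Rg_D^2 = Rg_M^2 + (sep/2)^2 for identical protomers
  sep <- 2 * sqrt(target^2 - rg_m^2)
  lo <- 0.5 * sep; hi <- 2 * sep
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    r <- suppressWarnings(coordinate_rg(make_dimer(monomer, mid))) / rg_m
    if (abs(r - ratio) < tol * ratio) return(mid)
    if (r < ratio) lo <- mid else hi <- mid
  }
  mid
}

#' Exact orientation-averaged scattering of a bead model (Debye formula)
#'
#' `I(q) = sum_ij sin(q r_ij)/(q r_ij)` over all bead pairs, with equal
#' bead form factors, so `I(0) = N^2`. O(N^2) per q value; intended for
#' coarse models (N <= 2000).
#'
#' @param model A `bead_model`.
#' @param q_grid Momentum-transfer grid, 1/Angstrom.
#' @param sigma Optional sigma vector for the returned curve; defaults to
#'   a nominal 1 percent of I.
#' @return A [scattering_curve].
#' @export
debye_curve <- function(model, q_grid, sigma = NULL) {
  stopifnot(inherits(model, "bead_model"))
  n <- nrow(model$coordinates)
  if (n > 2000) stop("bead model too large for O(N^2) Debye sum (N > 2000)")
  q_grid <- as.numeric(q_grid)
  if (n == 1L) {
    I <- rep(1, length(q_grid))
  } else {
    d <- as.numeric(stats::dist(model$coordinates))
    I <- vapply(q_grid, function(q) {
      qd <- q * d
      n + 2 * sum(ifelse(qd == 0, 1, sin(qd) / qd))
    }, numeric(1))
  }
  if (is.null(sigma)) sigma <- pmax(0.01 * abs(I), 1e-12)
  scattering_curve(q_grid, I, sigma, label = model$label)
}

#' Default synthetic q-grid
#'
#' 512 points from 0.005 to 0.5 1/Angstrom, the data-range scale of a
#' typical reduced biological SAXS profile.
#' @return Numeric vector.
#' @export
default_q_grid <- function() seq(0.005, 0.5, length.out = 512)

#' Photon-counting-style noise model
#'
#' Gaussian noise with `sigma(q) = a * sqrt(I(q)/c) + b`: the Poisson-like
#' term shrinks with concentration (dilute samples are noisier, as in real
#' dilution series) on top of a constant floor.
#'
#' @param a Intensity-proportional coefficient (>= 0).
#' @param b Floor (> 0), in curve intensity units.
#' @param seed Integer RNG seed.
#' @return A `noise_model`.
#' @export
noise_model <- function(a = 0.005, b = 0.002, seed = 1) {
  stopifnot(a >= 0, b > 0)
  structure(list(a = a, b = b, seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a mass-action monomer/dimer dilution series
#'
#' For each concentration the monomer fraction `f_M` follows from the
#' mass-action equilibrium at `kd`; the noise-free profile is
#' `I(q) = c (f_M sM(q) + (1 - f_M) sD(q))` with the species curves
#' normalised per unit mass (`sD(0) = 2 sM(0) = 2`), reproducing the
#' z-average weighting that yields the `(2 - f_M)` denominator of the
#' apparent-Rg mixture relation. Gaussian noise `sigma(q) = a sqrt(I/c) + b`
#' is then added; everything is deterministic per noise-model seed.
#'
#' @param kd Dissociation constant, mol/L.
#' @param concentrations Mass concentrations, mg/ml.
#' @param monomer_model,dimer_model `bead_model`s with
#'   `Rg(dimer) > Rg(monomer)`.
#' @param noise A [noise_model()], or `NULL` for noise-free curves (sigma
#'   is then the noise model's nominal level with `a = 0`, i.e. constant).
#' @param mw_monomer Monomer molecular mass, Da.
#' @param q_grid Momentum-transfer grid.
#' @return A [concentration_series] of curves; attribute `truth` records
#'   the generating parameters and per-point `f_M`.
#' @export
simulate_series <- function(kd, concentrations, monomer_model, dimer_model,
                            noise = noise_model(), mw_monomer = DEFAULT_MW_MONOMER,
                            q_grid = default_q_grid()) {
  stopifnot(kd > 0, all(concentrations > 0))
  rg_m <- coordinate_rg(monomer_model); rg_d <- coordinate_rg(dimer_model)
  if (rg_d <= rg_m) stop("dimer model Rg must exceed monomer model Rg")
  s_m <- debye_curve(monomer_model, q_grid)
  s_d <- debye_curve(dimer_model, q_grid)
  # per-unit-mass normalisation: s(0) = stoichiometry, using I(0) = N^2
  sm <- s_m$intensity / nrow(monomer_model$coordinates)^2
  sd2 <- 2 * s_d$intensity / nrow(dimer_model$coordinates)^2
  f_m <- monomer_fraction(kd, molar_from_mass_conc(concentrations, mw_monomer))
  noisy <- !is.null(noise)
  curves <- .with_seed(if (noisy) noise$seed else 0L, {
    lapply(seq_along(concentrations), function(i) {
      c_i <- concentrations[i]
      I <- c_i * (f_m[i] * sm + (1 - f_m[i]) * sd2)
      if (noisy) {
        sig <- noise$a * sqrt(I / c_i) + noise$b
        I <- I + rnorm(length(I), sd = sig)
      } else {
        sig <- rep(noise_model()$b, length(I))
      }
      list(c = c_i,
           curve = scattering_curve(q_grid, I, sig,
                                    label = sprintf("sim_c%.3g", c_i)))
    })
  })
  out <- concentration_series(curves)
  attr(out, "truth") <- list(kd = kd, mw_monomer = mw_monomer,
                             rg_m = rg_m, rg_d = rg_d, f_m = f_m,
                             concentrations = sort(concentrations))
  out
}
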