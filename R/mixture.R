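#' Interpolate a scattering curve onto a new q-grid
#'
#' Linear interpolation of intensity and sigma onto `q_grid`, which must lie
#' within the source curve's q range (no extrapolation).
#'
#' @param curve A [scattering_curve].
#' @param q_grid Target momentum-transfer grid, 1/Angstrom.
#' @return A [scattering_curve] on `q_grid`.
#' @export
regrid <- function(curve, q_grid) {
  stopifnot(inherits(curve, "scattering_curve"))
  q_grid <- as.numeric(q_grid)
  if (min(q_grid) < min(curve$q) || max(q_grid) > max(curve$q))
    stop(sprintf("regrid would extrapolate: target [%.4g, %.4g] outside source [%.4g, %.4g]",
                 min(q_grid), max(q_grid), min(curve$q), max(curve$q)))
  I <- stats::approx(curve$q, curve$intensity, xout = q_grid)$y
  s <- stats::approx(curve$q, curve$sigma, xout = q_grid)$y
  scattering_curve(q_grid, I, s, label = curve$label)
}

#' Build a species pool for mixture decomposition
#'
#' @param entries List of entries, each a list with `curve` (a
#'   [scattering_curve]; all on the identical q-grid), `stoichiometry`
#'   (chains per particle, 1 for monomer, 2 for dimer) and `label`.
#' @return A `species_pool`.
#' @export
species_pool <- function(entries) {
  if (length(entries) < 2L) stop("pool needs at least two entries")
  q0 <- entries[[1]]$curve$q
  for (e in entries) {
    if (!inherits(e$curve, "scattering_curve")) stop("pool entry lacks a curve")
    if (!isTRUE(all.equal(e$curve$q, q0)))
      stop("all pool curves must share an identical q-grid")
    if (!e$stoichiometry %in% c(1, 2))
      stop("stoichiometry must be 1 (monomer) or 2 (dimer)")
  }
  st <- vapply(entries, function(e) e$stoichiometry, numeric(1))
  if (!any(st == 1) || !any(st == 2))
    stop("equilibrium pool needs at least one monomer and one dimer entry")
  structure(list(entries = entries), class = "species_pool")
}

# nonnegative least squares min ||A x - b||, x >= 0. Columns are scaled to
# unit norm before pracma's Lawson-Hanson solver; if that fails to converge
# (it can on exactly collinear/degenerate inputs), fall back to exact
# enumeration of active sets, which is cheap for the small pools used here.
.nnls <- function(A, b) {
  nrm <- sqrt(colSums(A^2))
  nrm[nrm == 0] <- 1
  As <- sweep(A, 2, nrm, "/")
  x <- tryCatch(pracma::lsqnonneg(As, b)$x, error = function(e) NULL)
  if (is.null(x)) {
    k <- ncol(A)
    if (k > 12) stop("NNLS failed and pool too large for exact enumeration")
    best <- rep(0, k); best_rss <- sum(b^2)
    for (bits in 1:(2^k - 1)) {
      on <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
      cf <- tryCatch(qr.coef(qr(As[, on, drop = FALSE]), b),
                     error = function(e) NULL)
      if (is.null(cf) || anyNA(cf) || any(cf < 0)) next
      rss <- sum((b - As[, on, drop = FALSE] %*% cf)^2)
      if (rss < best_rss - 1e-12) {
        best_rss <- rss; best <- rep(0, k); best[on] <- cf
      }
    }
    x <- best
  }
  x / nrm
}

# forward-scattering estimate of a (noise-free model) curve: Guinier
# extrapolation over the points with q * rg_pilot <= 1
.forward_intensity <- function(curve) {
  n <- length(curve$q)
  g <- tryCatch({
    pilot <- guinier_fit(curve, c(1L, min(10L, n)))
    imax <- max(which(curve$q * pilot$rg <= 1), 3L)
    guinier_fit(curve, c(1L, min(imax, n)))
  }, error = function(e) NULL)
  if (is.null(g)) stop("cannot estimate I(0) of pool curve '", curve$label, "'")
  g$i0
}

#' Decompose an experimental curve into nonnegative species contributions
#'
#' Fits `I_exp(q)` as a nonnegative linear combination of the pool curves
#' by sigma-weighted non-negative least squares. Each species curve is
#' first normalised to equal mass concentration — its forward scattering
#' `s_i(0)` is set proportional to the particle mass (stoichiometry), so a
#' dimer curve starts at twice the monomer's `s(0)` — which makes the
#' renormalised NNLS weights mass fractions directly.
#'
#' @param exp_curve Experimental [scattering_curve].
#' @param pool A [species_pool] (curves are regridded onto the experimental
#'   grid internally).
#' @param q_max_fit Upper q cutoff for the fit, 1/Angstrom; discards the
#'   noisy high-q region.
#' @return A `mixture_fit`: `weights` (mass fractions, sum 1), `scale`
#'   (global factor), `chi2` (reduced chi-square), `xd` (dimer mole
#'   fraction aggregated by stoichiometry).
#' @export
nnls_fractions <- function(exp_curve, pool, q_max_fit = 0.3) {
  stopifnot(inherits(exp_curve, "scattering_curve"),
            inherits(pool, "species_pool"))
  keep <- exp_curve$q <= q_max_fit
  if (sum(keep) < 10L) stop("fewer than 10 experimental points below q_max_fit")
  q <- exp_curve$q[keep]
  I <- exp_curve$intensity[keep]
  s <- exp_curve$sigma[keep]
  basis <- vapply(pool$entries, function(e) {
    cv <- regrid(e$curve, q)
    cv$intensity / .forward_intensity(e$curve) * e$stoichiometry
  }, numeric(length(q)))
  A <- basis / s
  b <- I / s
  w_raw <- .nnls(A, b)
  if (all(w_raw <= 0)) stop("degenerate mixture fit: all weights zero")
  fitted <- as.numeric(basis %*% w_raw)
  chi2 <- sum(((fitted - I) / s)^2) / (length(q) - 1)
  weights <- w_raw / sum(w_raw)
  st <- vapply(pool$entries, function(e) e$stoichiometry, numeric(1))
  w_m <- sum(weights[st == 1]); w_d <- sum(weights[st == 2])
  structure(list(weights = weights, scale = sum(w_raw), chi2 = chi2,
                 xd = mole_fraction_from_mass(w_m, w_d),
                 stoichiometry = st,
                 labels = vapply(pool$entries, function(e)
                   e$label %||% "", character(1))),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Mixture fit: x_D = %.3f, reduced chi^2 = %.4g\n", x$xd, x$chi2))
  cat("  mass fractions:",
      paste(sprintf("%s=%.3f", x$labels, x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Dimer mole fraction from monomer/dimer mass fractions
#'
#' Equal mass of dimer contains half as many particles as the same mass of
#' monomer, so `x_D = (w_D / 2) / (w_M + w_D / 2)`.
#'
#' @param w_m,w_d Mass fractions of monomer and dimer, non-negative,
#'   summing to 1.
#' @return Dimer mole fraction among particles.
#' @export
mole_fraction_from_mass <- function(w_m, w_d) {
  if (w_m < 0 || w_d < 0) stop("mass fractions must be non-negative")
  if (abs(w_m + w_d - 1) > 1e-8) stop("mass fractions must sum to 1")
  (w_d / 2) / (w_m + w_d / 2)
}

#' Per-concentration mixture decomposition of a dilution series
#'
#' Runs [nnls_fractions()] on every curve of the series and returns the
#' `(concentration, x_D)` pairs ready for [fit_kd_from_xd()].
#'
#' @param series A [concentration_series] whose points carry curves.
#' @param pool A [species_pool].
#' @param q_max_fit Upper q cutoff, 1/Angstrom.
#' @return Data frame with columns `conc_mg_ml`, `xd`, `chi2`.
#' @export
series_xd <- function(series, pool, q_max_fit = 0.3) {
  stopifnot(inherits(series, "concentration_series"))
  rows <- lapply(seq_along(series$points), function(i) {
    p <- series$points[[i]]
    if (is.null(p$curve))
      stop("series point ", i, " (c = ", p$c, " mg/ml) carries no curve")
    fit <- tryCatch(nnls_fractions(p$curve, pool, q_max_fit),
                    error = function(e)
                      stop("mixture fit failed at point ", i, " (c = ", p$c,
                           " mg/ml): ", conditionMessage(e)))
    data.frame(conc_mg_ml = p$c, xd = fit$xd, chi2 = fit$chi2)
  })
  do.call(rbind, rows)
}
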