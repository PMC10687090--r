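#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# shared nls.lm driver: multi-start Levenberg-Marquardt over log10(KD)
# (and optionally xd_max), best objective wins.
.kd_optimize <- function(resid_fun, log10kd_starts, xd_max_start = NULL) {
  best <- NULL
  for (s in log10kd_starts) {
    par <- c(log10kd = s)
    lower <- -12; upper <- 0
    if (!is.null(xd_max_start)) {
      par <- c(par, xd_max = xd_max_start)
      lower <- c(lower, 1e-6); upper <- c(upper, 1)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par, fn = resid_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-12, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

# asymptotic SE of KD from the nls.lm fit (delta method on log10 KD)
.kd_se <- function(fit, kd) {
  se_log <- tryCatch({
    dof <- length(fit$fvec) - length(fit$par)
    if (dof < 1) return(NA_real_)
    covm <- fit$deviance / dof * tryCatch(solve(fit$hessian),
                                          error = function(e) NULL)
    if (is.null(covm)) return(NA_real_)
    sqrt(covm[1, 1])
  }, error = function(e) NA_real_)
  kd * log(10) * se_log
}

.initial_log10kd <- function(m0, response) {
  # concentration at half-maximal rise of the response, fallback 10 uM
  rng <- range(response)
  if (diff(rng) <= 0) return(log10(1e-5))
  half <- rng[1] + 0.5 * diff(rng)
  i <- which(response >= half)[1]
  if (is.na(i)) log10(1e-5) else log10(max(m0[i], 1e-9))
}

.kd_result <- function(fit, xd_max, pair, n_points, weighted = FALSE) {
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, kd_err = NA_real_, xd_max = xd_max,
                          pair = pair, residuals = rep(NA_real_, n_points),
                          converged = FALSE, n_points = n_points),
                     class = "kd_fit"))
  }
  kd <- 10^fit$par[["log10kd"]]
  if ("xd_max" %in% names(fit$par)) xd_max <- fit$par[["xd_max"]]
  structure(list(
    kd = kd, kd_err = .kd_se(fit, kd), xd_max = xd_max, pair = pair,
    residuals = as.numeric(fit$fvec), converged = fit$info %in% 1:4,
    n_points = n_points), class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  if (!is.na(x$kd))
    cat(sprintf("KD fit: %.3g uM (+/- %.2g), xd_max = %.3g, %d points, converged: %s\n",
                x$kd * 1e6, x$kd_err * 1e6, x$xd_max, x$n_points, x$converged))
  else cat("KD fit: did not converge\n")
  invisible(x)
}

#' Fit a dissociation constant to an Rg-versus-concentration series
#'
#' Nonlinear least squares of the mass-action mixture model
#' [rg2_vs_concentration()] to squared (Guinier) radii of gyration against
#' total molar concentration. The free parameter is `log10 KD`, which keeps
#' KD positive and conditions the problem; three Levenberg-Marquardt starts
#' a factor 10 apart guard against local minima, deterministically.
#' Residuals are unweighted on Rg^2 by default (published per-point Rg
#' errors are partly zero, which makes inverse-variance weighting
#' ill-posed); supply `rg_err` weights via `weighted = TRUE` to override.
#'
#' @param series A [concentration_series] whose points carry `rg` values,
#'   or a data frame with columns `conc_mg_ml` and `rg`.
#' @param pair A `glyco_pair` or packaged-pair name (see [glyco_pairs]).
#' @param mw_monomer Monomer molecular mass, Da, for the molar conversion.
#' @param weighted If `TRUE`, weight residuals by `1/rg2_err` where
#'   positive errors are available.
#' @param rg_column Which stored Rg column to fit (`"guinier"` default).
#' @return A `kd_fit` with fields `kd` (mol/L), `kd_err`, `pair`,
#'   `residuals`, `converged`, `n_points`.
#' @export
fit_kd_from_rg <- function(series, pair, mw_monomer = DEFAULT_MW_MONOMER,
                           weighted = FALSE,
                           rg_column = c("guinier", "real_space")) {
  pair <- as_glyco_pair(pair)
  rg_column <- match.arg(rg_column)
  if (is.data.frame(series)) {
    conc <- series$conc_mg_ml; rg <- series$rg
    rg_err <- if ("rg_err" %in% names(series)) series$rg_err else NULL
  } else {
    conc <- concentrations(series)
    rg <- series_rg(series, rg_column)
    rg_err <- vapply(series$points, function(p)
      if (is.null(p$rg_err)) NA_real_ else p$rg_err, numeric(1))
  }
  keep <- is.finite(rg)
  conc <- conc[keep]; rg <- rg[keep]
  if (!is.null(rg_err)) rg_err <- rg_err[keep]
  if (length(conc) < 3L) stop("need at least 3 (concentration, Rg) points")
  m0 <- molar_from_mass_conc(conc, mw_monomer)
  y <- rg^2
  w <- rep(1, length(y))
  if (weighted && !is.null(rg_err)) {
    rg2_err <- 2 * rg * rg_err
    ok <- is.finite(rg2_err) & rg2_err > 0
    if (any(ok)) w[ok] <- 1 / rg2_err[ok]
  }
  resid_fun <- function(p)
    w * (rg2_vs_concentration(m0, 10^p[["log10kd"]], pair) - y)
  g0 <- .initial_log10kd(m0, y)
  fit <- .kd_optimize(resid_fun, c(g0, g0 - 1, g0 + 1))
  .kd_result(fit, xd_max = 1, pair = pair, n_points = length(y))
}

#' Fit a dissociation constant to a dimer-mole-fraction series
#'
#' Nonlinear least squares of [dimer_mole_fraction()] to observed dimer
#' mole fractions `x_D` against total molar concentration, optionally
#' fitting the saturation value `x_Dmax` (constrained to (0, 1]) when the
#' observed fractions plateau below 1, as ensemble-decomposition fractions
#' of partially mis-modelled pools do.
#'
#' @param series_of_xd Data frame with columns `conc_mg_ml` and `xd`, or a
#'   list of `(c, xd)` pairs as returned by [series_xd()].
#' @param mw_monomer Monomer molecular mass, Da.
#' @param fit_xd_max If `TRUE`, fit `x_Dmax` as a second parameter
#'   (requires at least 4 points).
#' @return A `kd_fit`; `xd_max` holds the fitted or fixed saturation value.
#' @export
fit_kd_from_xd <- function(series_of_xd, mw_monomer = DEFAULT_MW_MONOMER,
                           fit_xd_max = FALSE) {
  if (is.data.frame(series_of_xd)) {
    conc <- series_of_xd$conc_mg_ml; xd <- series_of_xd$xd
  } else {
    conc <- vapply(series_of_xd, function(p) p$c, numeric(1))
    xd <- vapply(series_of_xd, function(p) p$xd, numeric(1))
  }
  if (any(xd < 0 | xd > 1)) stop("x_D values must lie in [0, 1]")
  need <- if (fit_xd_max) 4L else 3L
  if (length(conc) < need)
    stop("need at least ", need, " points for this fit")
  if (diff(range(xd)) < 1e-10)   # flat response: KD unidentifiable
    return(.kd_result(NULL, xd_max = 1, pair = NULL, n_points = length(xd)))
  m0 <- molar_from_mass_conc(conc, mw_monomer)
  resid_fun <- function(p) {
    xdm <- if ("xd_max" %in% names(p)) p[["xd_max"]] else 1
    dimer_mole_fraction(10^p[["log10kd"]], m0, xdm) - xd
  }
  g0 <- .initial_log10kd(m0, xd)
  fit <- .kd_optimize(resid_fun, c(g0, g0 - 1, g0 + 1),
                      xd_max_start = if (fit_xd_max) 0.9 else NULL)
  .kd_result(fit, xd_max = 1, pair = NULL, n_points = length(xd))
}

#' Summarise KD fits across glycosylation states
#'
#' @param results_per_pair Named list of `kd_fit` objects (one per
#'   glycosylation state).
#' @param temperature_k Temperature for the free-energy column, Kelvin.
#' @return JSON-serialisable list: per-state KD (uM), standard error, and
#'   binding free energy (kJ/mol), plus the min/max KD across states.
#' @export
fit_report <- function(results_per_pair, temperature_k = 310.15) {
  stopifnot(length(results_per_pair) >= 1)
  kd_um <- vapply(results_per_pair, function(r) r$kd * 1e6, numeric(1))
  states <- lapply(seq_along(results_per_pair), function(i) {
    r <- results_per_pair[[i]]
    list(state = names(results_per_pair)[i] %||% paste0("fit", i),
         kd_uM = r$kd * 1e6,
         kd_err_uM = r$kd_err * 1e6,
         delta_g_kj_mol = binding_free_energy(r$kd, temperature_k),
         converged = r$converged)
  })
  list(states = states,
       kd_min_uM = min(kd_um), kd_max_uM = max(kd_um),
       temperature_k = temperature_k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
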