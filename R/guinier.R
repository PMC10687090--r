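#' @importFrom stats coef lm approx rnorm sd median
NULL

# weighted straight-line fit y = a + b x with weights w; returns estimates,
# covariance and weighted R^2
.wlinfit <- function(x, y, w) {
  W <- sum(w); wx <- sum(w * x); wy <- sum(w * y)
  sxx <- sum(w * x * x) - wx^2 / W
  sxy <- sum(w * x * y) - wx * wy / W
  syy <- sum(w * y * y) - wy^2 / W
  slope <- sxy / sxx
  intercept <- (wy - slope * wx) / W
  resid <- y - intercept - slope * x
  n <- length(x)
  s2 <- sum(w * resid^2) / max(n - 2, 1)
  list(slope = slope, intercept = intercept,
       slope_var = s2 / sxx,
       intercept_var = s2 * (1 / W + (wx / W)^2 / sxx),
       r_squared = if (syy > 0) 1 - sum(w * resid^2) / syy else 1,
       residuals = resid)
}

#' Guinier fit on a fixed window
#'
#' Weighted linear regression of `ln I` against `q^2` over a window of the
#' curve. In the Guinier limit `I(q) = I0 exp(-q^2 Rg^2 / 3)`, so
#' `Rg = sqrt(-3 slope)` and `I0 = exp(intercept)`. Weights are
#' `(I/sigma)^2`, the first-order error propagation of `sigma` onto `ln I`;
#' parameter errors come from the regression covariance.
#'
#' @param curve A [scattering_curve].
#' @param window Integer pair `(first, last)` of point indices to fit.
#' @return A `guinier_result` with fields `rg`, `rg_err`, `i0`, `i0_err`,
#'   `window`, `qrg_min`, `qrg_max`, `r_squared`.
#' @export
guinier_fit <- function(curve, window) {
  stopifnot(inherits(curve, "scattering_curve"))
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[2] > length(curve$q) ||
      window[2] < window[1])
    stop("window must be a valid (first, last) index pair")
  idx <- window[1]:window[2]
  if (length(idx) < 3L) stop("Guinier window needs at least 3 points")
  I <- curve$intensity[idx]
  if (any(I <= 0)) stop("non-positive intensity inside Guinier window")
  q <- curve$q[idx]
  w <- (I / curve$sigma[idx])^2
  fit <- .wlinfit(q^2, log(I), w)
  if (fit$slope >= 0)
    stop("no Guinier decay: fitted slope of ln I vs q^2 is non-negative")
  rg <- sqrt(-3 * fit$slope)
  rg_err <- 3 * sqrt(fit$slope_var) / (2 * rg)
  i0 <- exp(fit$intercept)
  structure(list(
    rg = rg, rg_err = rg_err,
    i0 = i0, i0_err = i0 * sqrt(fit$intercept_var),
    window = c(window[1], window[2]),
    qrg_min = q[1] * rg, qrg_max = q[length(q)] * rg,
    r_squared = fit$r_squared), class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.2f +/- %.2f A, I(0) = %.4g, qRg = %.2f-%.2f, R^2 = %.4f\n",
              x$rg, x$rg_err, x$i0, x$qrg_min, x$qrg_max, x$r_squared))
  invisible(x)
}

#' Automatic Guinier range selection
#'
#' Deterministic replacement for interactive low-q range picking: among all
#' windows of at least `min_points` points whose fitted `q Rg` at the upper
#' edge stays below `qrg_limit` and whose weighted R^2 reaches
#' `r2_threshold`, the longest window wins; ties are broken by higher R^2,
#' then by smaller start index.
#'
#' The search is restricted to the low-q region via a pilot fit on the
#' first `min_points` points (falling back to the full admissible prefix
#' when the pilot fails), keeping the exhaustive scan cheap.
#'
#' @param curve A [scattering_curve].
#' @param qrg_limit Upper validity limit on q*Rg (1.3 for globular
#'   particles).
#' @param min_points Minimum window length.
#' @param r2_threshold Minimum weighted R^2 for an admissible window.
#' @return A `guinier_result` (see [guinier_fit()]).
#' @export
auto_guinier <- function(curve, qrg_limit = 1.3, min_points = 10,
                         r2_threshold = 0.99) {
  stopifnot(inherits(curve, "scattering_curve"))
  n <- length(curve$q)
  pos <- curve$intensity > 0
  # pilot Rg to bound the search region
  first_ok <- which(cumsum(pos) == seq_len(n) & pos)
  rg_pilot <- NA_real_
  if (length(first_ok) >= min_points) {
    rg_pilot <- tryCatch(
      guinier_fit(curve, c(1L, as.integer(min_points)))$rg,
      error = function(e) NA_real_)
  }
  q_cap <- if (is.finite(rg_pilot)) 1.5 * qrg_limit / rg_pilot else Inf
  i_max <- max(which(curve$q <= q_cap), min_points)
  i_max <- min(i_max, n, 200L)  # bounds the exhaustive scan

  best <- NULL
  for (start in 1L:(i_max - min_points + 1L)) {
    for (end in seq.int(start + min_points - 1L, i_max)) {
      if (!all(pos[start:end])) next
      res <- tryCatch(guinier_fit(curve, c(start, end)),
                      error = function(e) NULL)
      if (is.null(res)) next
      if (res$qrg_max > qrg_limit || res$r_squared < r2_threshold) next
      len <- end - start + 1L
      if (is.null(best) ||
          len > best$len ||
          (len == best$len && res$r_squared > best$res$r_squared)) {
        best <- list(len = len, res = res)
      }
    }
  }
  if (is.null(best))
    stop("no admissible Guinier region (qRg <= ", qrg_limit,
         ", >= ", min_points, " points, R^2 >= ", r2_threshold, ")")
  best$res
}

#' Guinier Rg for every curve of a concentration series
#'
#' Runs [auto_guinier()] on each curve and returns the
#' `(concentration, Rg)` table consumed by [fit_kd_from_rg()]. The default
#' R^2 admissibility is relaxed to 0.9 because even a perfectly Gaussian
#' decay scores a low weighted R^2 at the signal-to-noise of dilute
#' experimental curves.
#'
#' @param series A [concentration_series] whose points carry curves.
#' @param qrg_limit,min_points,r2_threshold Passed to [auto_guinier()].
#' @return Data frame with columns `conc_mg_ml`, `rg`, `rg_err`, `i0`.
#' @export
series_guinier_rg <- function(series, qrg_limit = 1.3, min_points = 10,
                              r2_threshold = 0.9) {
  stopifnot(inherits(series, "concentration_series"))
  rows <- lapply(series$points, function(p) {
    if (is.null(p$curve)) stop("series point at c = ", p$c, " carries no curve")
    g <- auto_guinier(p$curve, qrg_limit, min_points, r2_threshold)
    data.frame(conc_mg_ml = p$c, rg = g$rg, rg_err = g$rg_err, i0 = g$i0)
  })
  do.call(rbind, rows)
}
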