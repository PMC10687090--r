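#' Construct a validated SAXS scattering curve
#'
#' A `scattering_curve` holds one reduced one-dimensional SAXS profile:
#' momentum transfer `q` (reciprocal Angstrom), intensity `I` (arbitrary
#' units) and the intensity standard error `sigma` (same units as `I`).
#'
#' @param q Numeric vector of momentum transfer values, strictly increasing,
#'   all positive, in 1/Angstrom.
#' @param intensity Numeric vector of scattered intensities.
#' @param sigma Numeric vector of per-point standard errors, all positive.
#' @param label Free-text label carried through I/O.
#' @return An object of class `scattering_curve` with fields `q`,
#'   `intensity`, `sigma`, `label`.
#' @export
scattering_curve <- function(q, intensity, sigma, label = "") {
  q <- as.numeric(q); intensity <- as.numeric(intensity); sigma <- as.numeric(sigma)
  n <- length(q)
  if (length(intensity) != n || length(sigma) != n)
    stop("q, intensity and sigma must have equal length")
  if (n < 10L)
    stop("a scattering curve needs at least 10 points, got ", n)
  if (any(!is.finite(q)) || any(!is.finite(intensity)) || any(!is.finite(sigma)))
    stop("non-finite values in scattering curve")
  if (any(q <= 0)) stop("all q must be positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(sigma <= 0)) stop("all sigma must be positive")
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 label = as.character(label)[1]),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("SAXS curve '%s': %d points, q = [%.4g, %.4g] 1/A\n",
              x$label, length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
length.scattering_curve <- function(x) length(x$q)

#' Read a three-column SAXS profile from a text file
#'
#' Parses the plain-text `.dat` dialect written by beamline reduction
#' pipelines: whitespace-separated columns q, I, sigma. Lines starting with
#' `#` and bare text header lines are skipped. Rows with non-positive q or
#' sigma are dropped (a message reports the count).
#'
#' @param path Path to the file.
#' @param label Curve label; defaults to the file name.
#' @return A [scattering_curve].
#' @export
read_dat <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(strsplit(lines, "[ \t,]+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok))
    if (length(v) >= 3 && !anyNA(v[1:3])) v[1:3] else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 10L)
    stop("malformed SAXS file (fewer than 10 numeric rows): ", path)
  m <- do.call(rbind, rows)
  bad <- m[, 1] <= 0 | m[, 3] <= 0
  if (any(bad)) {
    message(sum(bad), " point(s) with non-positive q or sigma dropped from ", path)
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) < 10L)
    stop("malformed SAXS file (fewer than 10 valid rows): ", path)
  scattering_curve(m[, 1], m[, 2], m[, 3], label = label)
}

#' Write a SAXS profile as three-column text
#'
#' Emits one `#`-prefixed header line carrying the label, then q, I, sigma
#' columns re-readable by [read_dat()].
#'
#' @param curve A [scattering_curve].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dat <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(paste0("# ", curve$label), con)
  writeLines(sprintf("%.8e %.8e %.8e", curve$q, curve$intensity, curve$sigma), con)
  invisible(path)
}

#' Construct a concentration series
#'
#' Ordered dilution-series container: each point carries a mass
#' concentration (mg/ml) plus either a full scattering curve or a
#' precomputed radius of gyration (with optional error). Points are sorted
#' by concentration.
#'
#' @param points A list; each element is a list with `c` (mg/ml) and either
#'   `curve` (a [scattering_curve]) or `rg` (Angstrom, optionally with
#'   `rg_err` and `rg_real_space`).
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(points) {
  if (length(points) < 1L) stop("empty series")
  cs <- vapply(points, function(p) as.numeric(p$c), numeric(1))
  if (any(!is.finite(cs)) || any(cs <= 0)) stop("concentrations must be positive")
  if (anyDuplicated(cs)) stop("duplicate concentrations in series")
  for (p in points) {
    if (is.null(p$curve) && is.null(p$rg))
      stop("series point at c = ", p$c, " has neither curve nor rg")
    if (!is.null(p$curve) && !inherits(p$curve, "scattering_curve"))
      stop("curve entry is not a scattering_curve")
  }
  structure(list(points = points[order(cs)]), class = "concentration_series")
}

#' @export
length.concentration_series <- function(x) length(x$points)

#' @export
print.concentration_series <- function(x, ...) {
  cs <- concentrations(x)
  cat(sprintf("Concentration series: %d points, %.3g-%.3g mg/ml\n",
              length(cs), min(cs), max(cs)))
  invisible(x)
}

#' Concentrations of a series
#' @param series A `concentration_series`.
#' @return Numeric vector, mg/ml, increasing.
#' @export
concentrations <- function(series) {
  vapply(series$points, function(p) p$c, numeric(1))
}

#' Guinier Rg values stored in a series
#'
#' @param series A `concentration_series` whose points carry `rg` values.
#' @param column `"guinier"` (default) or `"real_space"` for series loaded
#'   from manifests that provide both.
#' @return Numeric vector of Rg in Angstrom (NA where absent).
#' @export
series_rg <- function(series, column = c("guinier", "real_space")) {
  column <- match.arg(column)
  vapply(series$points, function(p) {
    v <- if (column == "guinier") p$rg else p$rg_real_space
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
}

#' Load a concentration series from a CSV manifest
#'
#' Two manifest layouts are supported and may not be mixed:
#' \describe{
#'   \item{curve manifest}{columns `file`, `conc_mg_ml`; each row points to a
#'     three-column `.dat` profile, resolved relative to the manifest.}
#'   \item{Rg manifest}{columns `conc_mg_ml`, `rg` and optionally `rg_err`,
#'     `rg_real_space`; rows carry precomputed Guinier radii.}
#' }
#' Rows are sorted by concentration; duplicate concentrations are an error.
#'
#' @param manifest_path Path to the CSV manifest.
#' @return A [concentration_series].
#' @export
load_series <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("no such manifest: ", manifest_path)
  df <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!"conc_mg_ml" %in% names(df)) stop("manifest lacks a conc_mg_ml column")
  has_file <- "file" %in% names(df)
  has_rg <- "rg" %in% names(df)
  if (has_file && has_rg)
    stop("manifest mixes curve rows (file) and rg rows; use one layout")
  if (!has_file && !has_rg)
    stop("manifest needs either a file or an rg column")
  points <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    if (has_file) {
      f <- file.path(dirname(manifest_path), row$file)
      if (!file.exists(f))
        stop("manifest row ", i, ": missing file ", row$file)
      list(c = row$conc_mg_ml, curve = read_dat(f))
    } else {
      p <- list(c = row$conc_mg_ml, rg = row$rg)
      if ("rg_err" %in% names(df)) p$rg_err <- row$rg_err
      if ("rg_real_space" %in% names(df)) p$rg_real_space <- row$rg_real_space
      p
    }
  })
  concentration_series(points)
}

#' The packaged G4-PTX dilution-series fixture
#'
#' Eight-point concentration series of the ADGRG4 pentraxin-like domain
#' (0.27-9.15 mg/ml) with the published Guinier radii of gyration and, as a
#' second column, the real-space (P(r)-derived) radii. The Guinier column is
#' the default regression input for [fit_kd_from_rg()].
#'
#' @return A [concentration_series] of 8 Rg points.
#' @export
g4ptx_series <- function() {
  path <- system.file("extdata", "g4ptx_table_series.csv", package = "dimerfit",
                      mustWork = TRUE)
  load_series(path)
}
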