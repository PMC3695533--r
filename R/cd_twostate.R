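#' Circular dichroism spectral series
#'
#' CD intensity over a wavelength grid at several temperatures, the raw
#' material for two-state diagnostics: a two-species interconversion makes
#' every spectrum a convex mixture of the folded and unfolded basis
#' spectra, so all spectra intersect where the bases are equal (isosbestic
#' point) and intensities at any two wavelengths are perfectly collinear
#' across temperature.
#'
#' @param wavelengths_nm strictly increasing wavelength grid.
#' @param temperatures_C temperature list (>= 3 for isosbestic analysis).
#' @param intensity matrix (mdeg), rows = temperatures, cols = wavelengths.
#' @return object of class `spectrum_series`.
#' @export
spectrum_series <- function(wavelengths_nm, temperatures_C, intensity) {
  intensity <- as.matrix(intensity)
  if (any(diff(wavelengths_nm) <= 0) ||
      (length(temperatures_C) > 1 && any(diff(temperatures_C) <= 0)))
    stop_quadstall("grids must be strictly increasing", "quadstall_bad_series")
  if (!all(dim(intensity) == c(length(temperatures_C), length(wavelengths_nm))))
    stop_quadstall("intensity must be temperatures x wavelengths",
                   "quadstall_bad_series")
  structure(list(wavelengths_nm = wavelengths_nm,
                 temperatures_C = temperatures_C,
                 intensity = intensity),
            class = "spectrum_series")
}

.match_wavelength <- function(series, lambda, tol = 1) {
  i <- which.min(abs(series$wavelengths_nm - lambda))
  if (abs(series$wavelengths_nm[i] - lambda) > tol)
    stop_quadstall(sprintf("no grid point within %g nm of %g nm", tol, lambda),
                   "quadstall_bad_wavelength")
  i
}

#' Parallel-topology CD signature
#'
#' Classifies a single spectrum as parallel-quadruplex-like when it shows a
#' positive maximum in 260-270 nm and a negative minimum in 235-245 nm,
#' both exceeding an amplitude threshold. The 2 mdeg default threshold is a
#' package choice; no field-standard numeric cutoff exists.
#'
#' @param wavelengths_nm wavelength grid covering at least 230-300 nm.
#' @param intensity_mdeg spectrum at one temperature.
#' @param threshold_mdeg minimal |peak| amplitude.
#' @return list: `classification` ("parallel-like" or "other"),
#'   `peak_nm`/`peak_mdeg` (positive band), `trough_nm`/`trough_mdeg`.
#' @export
topology_signature <- function(wavelengths_nm, intensity_mdeg,
                               threshold_mdeg = 2) {
  if (min(wavelengths_nm) > 230 || max(wavelengths_nm) < 300)
    stop_quadstall("wavelength range must cover 230-300 nm",
                   "quadstall_bad_series")
  in_peak <- wavelengths_nm >= 260 & wavelengths_nm <= 270
  in_trough <- wavelengths_nm >= 235 & wavelengths_nm <= 245
  ip <- which(in_peak)[which.max(intensity_mdeg[in_peak])]
  it <- which(in_trough)[which.min(intensity_mdeg[in_trough])]
  ok <- intensity_mdeg[ip] > threshold_mdeg &&
    intensity_mdeg[it] < -threshold_mdeg
  list(classification = if (ok) "parallel-like" else "other",
       peak_nm = wavelengths_nm[ip], peak_mdeg = intensity_mdeg[ip],
       trough_nm = wavelengths_nm[it], trough_mdeg = intensity_mdeg[it])
}

#' Isosbestic point of a spectral series
#'
#' The wavelength at which intensity varies least across temperature: the
#' argmin over the grid of the cross-temperature variance of the raw
#' intensities. For an exact two-state series the spread is zero wherever
#' the two basis spectra are equal. Ties break to the lowest wavelength.
#'
#' @param series a [spectrum_series] with >= 3 temperatures.
#' @return list: `wavelength_nm`, `spread` (the minimal variance, mdeg^2).
#' @export
isosbestic_point <- function(series) {
  stopifnot(inherits(series, "spectrum_series"))
  if (length(series$temperatures_C) < 3L)
    stop_quadstall("isosbestic analysis needs >= 3 temperatures",
                   "quadstall_bad_series")
  v <- apply(series$intensity, 2, stats::var)
  i <- which(v <= min(v) + 0)[1L]   # lowest-wavelength tie-break
  list(wavelength_nm = series$wavelengths_nm[i], spread = v[i])
}

#' Two-state linearity between two wavelengths
#'
#' Pearson correlation and linear fit of intensity at `lambda1` against
#' intensity at `lambda2` across the temperature series. Any two-basis
#' (two-state) series gives |r| = 1 to numerical tolerance; deviation from
#' collinearity flags a third species.
#'
#' @param series a [spectrum_series].
#' @param lambda1,lambda2 wavelengths (nearest grid point within 1 nm).
#' @return list: `r`, `slope`, `intercept`, `constant_signal` flag (TRUE
#'   when either wavelength's intensity is constant and r is undefined).
#' @export
two_state_linearity <- function(series, lambda1 = 265, lambda2 = 242) {
  stopifnot(inherits(series, "spectrum_series"))
  y1 <- series$intensity[, .match_wavelength(series, lambda1)]
  y2 <- series$intensity[, .match_wavelength(series, lambda2)]
  if (stats::sd(y1) < 1e-14 || stats::sd(y2) < 1e-14)
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                constant_signal = TRUE))
  fit <- stats::lm(y1 ~ y2)
  list(r = stats::cor(y1, y2),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       constant_signal = FALSE)
}

#' Melting curve extracted from a CD series at one wavelength
#'
#' Pulls the temperature profile at a wavelength (e.g. the 265 nm positive
#' band) for fitting with [fit_two_state()]; ties the CD melting transition
#' to the UV-derived thermodynamics.
#'
#' @inheritParams two_state_linearity
#' @param lambda wavelength, nm.
#' @return a [melting_curve] (signal in mdeg).
#' @export
cd_melting_curve <- function(series, lambda = 265) {
  i <- .match_wavelength(series, lambda)
  melting_curve(series$temperatures_C, series$intensity[, i],
                wavelength_nm = series$wavelengths_nm[i], replicate = "cd")
}

#' Read or write a CD series CSV (long format)
#'
#' Schema: `temperature_C, wavelength_nm, intensity_mdeg`.
#'
#' @param path CSV path.
#' @return `read_cd_csv`: a [spectrum_series].
#' @export
read_cd_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("temperature_C", "wavelength_nm", "intensity_mdeg")
  if (!all(need %in% names(d)))
    stop_quadstall(paste("CD CSV must have columns",
                         paste(need, collapse = ", ")),
                   "quadstall_bad_schema")
  wl <- sort(unique(d$wavelength_nm))
  tc <- sort(unique(d$temperature_C))
  m <- matrix(NA_real_, length(tc), length(wl))
  m[cbind(match(d$temperature_C, tc), match(d$wavelength_nm, wl))] <-
    d$intensity_mdeg
  if (anyNA(m))
    stop_quadstall("CD CSV is not a complete temperature x wavelength grid",
                   "quadstall_bad_schema")
  spectrum_series(wl, tc, m)
}

#' @param series a [spectrum_series].
#' @rdname read_cd_csv
#' @export
write_cd_csv <- function(series, path) {
  d <- expand.grid(temperature_C = series$temperatures_C,
                   wavelength_nm = series$wavelengths_nm)
  d$intensity_mdeg <- as.vector(series$intensity)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
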