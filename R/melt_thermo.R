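#' Two-state intramolecular folding parameters
#'
#' Parameterises the two-state van't Hoff model of an intramolecular
#' (unimolecular) folding equilibrium by the folding enthalpy and the
#' melting temperature. The entropy and the standard free energy at 37 C
#' follow from the two-state constraint dS = dH/Tm:
#' \deqn{\Delta G(T) = \Delta H (1 - T/T_m)}
#'
#' @param dH folding enthalpy, kcal/mol (negative for a folding transition).
#' @param Tm_K melting temperature, K.
#' @return object of class `two_state_params` with fields `dH`, `Tm_K`,
#'   `dS` (kcal/mol/K) and `dG37` (kcal/mol).
#' @examples
#' p <- two_state_params(dH = -45.69, Tm_K = 349.55)
#' p$dG37   # -5.15
#' @export
two_state_params <- function(dH, Tm_K) {
  stopifnot(is.finite(dH), is.finite(Tm_K), Tm_K > 0)
  structure(list(dH = dH, Tm_K = Tm_K, dS = dH / Tm_K,
                 dG37 = dH * (1 - T37_K / Tm_K)),
            class = "two_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf(
    "two-state: dH %.2f kcal/mol, Tm %.2f K (%.1f C), dS %.2f cal/mol/K, dG37 %.2f kcal/mol\n",
    x$dH, x$Tm_K, kelvin_to_celsius(x$Tm_K), 1000 * x$dS, x$dG37))
  invisible(x)
}

#' Free energy of folding at a temperature
#'
#' \eqn{\Delta G(T) = \Delta H (1 - T/T_m)}; zero at `T = Tm` exactly.
#'
#' @param T_K temperature(s), K.
#' @param params a [two_state_params].
#' @return kcal/mol, same length as `T_K`.
#' @export
dG_at <- function(T_K, params) {
  stopifnot(inherits(params, "two_state_params"), all(T_K > 0))
  params$dH * (1 - T_K / params$Tm_K)
}

#' Equilibrium fraction folded
#'
#' \eqn{f(T) = K/(1+K)} with \eqn{K = \exp(-\Delta G(T)/RT)}. Equals 1/2 at
#' the melting temperature and is strictly decreasing in T for a negative
#' folding enthalpy.
#'
#' @inheritParams dG_at
#' @return fraction in (0, 1).
#' @export
fraction_folded <- function(T_K, params) {
  dG <- dG_at(T_K, params)
  ## 1/(1+exp(dG/RT)) is the numerically stable form of K/(1+K)
  1 / (1 + exp(dG / (R_KCAL * T_K)))
}

#' Melting curve container
#'
#' @param temperature_C strictly increasing temperatures, degrees C;
#'   at least 20 points.
#' @param signal absorbance (dimensionless) or CD signal (mdeg).
#' @param wavelength_nm monitoring wavelength.
#' @param replicate replicate label.
#' @param heating_rate_C_min heating-rate metadata, carried but not
#'   modelled (equilibrium analysis).
#' @return data.frame of class `melting_curve` with the curve in columns
#'   `temperature_C`, `signal` and metadata in attributes.
#' @export
melting_curve <- function(temperature_C, signal, wavelength_nm = 295,
                          replicate = "r1", heating_rate_C_min = 0.2) {
  stopifnot(length(temperature_C) == length(signal))
  if (length(temperature_C) < 20L)
    stop_quadstall("melting curve needs >= 20 points", "quadstall_bad_curve")
  if (any(diff(temperature_C) <= 0))
    stop_quadstall("temperatures must be strictly increasing",
                   "quadstall_bad_curve")
  if (!all(is.finite(signal)))
    stop_quadstall("non-finite signal", "quadstall_bad_curve")
  structure(data.frame(temperature_C = temperature_C, signal = signal),
            wavelength_nm = wavelength_nm, replicate = replicate,
            heating_rate_C_min = heating_rate_C_min,
            class = c("melting_curve", "data.frame"))
}

#' Simulate a two-state melting curve
#'
#' Forward model with linear folded/unfolded baselines and additive
#' Gaussian noise:
#' \deqn{A(T) = f(T)(a_f + b_f T) + (1-f(T))(a_u + b_u T) + \epsilon}
#' Baseline slopes/intercepts are in signal units per degree C of the
#' Celsius grid. Deterministic for a given seed; `noise_sd = 0` returns the
#' exact forward model.
#'
#' @param params a [two_state_params].
#' @param baselines list with `a_f`, `b_f`, `a_u`, `b_u`.
#' @param T_grid_C increasing Celsius grid.
#' @param noise_sd Gaussian noise SD in signal units.
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @inheritParams melting_curve
#' @return a [melting_curve].
#' @export
simulate_melting_curve <- function(params,
                                   baselines = list(a_f = 0.30, b_f = -1e-4,
                                                    a_u = 0.20, b_u = -2e-4),
                                   T_grid_C = seq(20, 95, by = 0.5),
                                   noise_sd = 0, seed = 1,
                                   wavelength_nm = 295, replicate = "r1") {
  if (length(T_grid_C) == 0L)
    stop_quadstall("empty temperature grid", "quadstall_bad_curve")
  stopifnot(noise_sd >= 0)
  f <- fraction_folded(celsius_to_kelvin(T_grid_C), params)
  a <- f * (baselines$a_f + baselines$b_f * T_grid_C) +
    (1 - f) * (baselines$a_u + baselines$b_u * T_grid_C)
  if (noise_sd > 0) {
    set.seed(seed)
    a <- a + stats::rnorm(length(a), sd = noise_sd)
  }
  melting_curve(T_grid_C, a, wavelength_nm = wavelength_nm,
                replicate = replicate)
}

## Tm initialisation: extremum of the smoothed numerical derivative dA/dT.
.init_from_derivative <- function(Tc, A) {
  dAdT <- diff(A) / diff(Tc)
  mid <- (Tc[-1] + Tc[-length(Tc)]) / 2
  k <- max(3L, round(length(dAdT) / 15))
  sm <- stats::filter(dAdT, rep(1 / k, k), sides = 2)
  ok <- which(!is.na(sm))
  i <- ok[which.max(abs(sm[ok]))]
  list(Tm_C = mid[i], slope = sm[i])
}

.fit_one_curve <- function(curve, amplitude_noise_ratio = 5) {
  Tc <- curve$temperature_C
  A <- curve$signal
  n <- length(Tc)
  init <- .init_from_derivative(Tc, A)
  ## end-segment linear baselines for starting values
  lo <- seq_len(max(4L, round(n / 6)))
  hi <- seq(n - max(4L, round(n / 6)) + 1L, n)
  bl_f <- stats::coef(stats::lm(A[lo] ~ Tc[lo]))
  bl_u <- stats::coef(stats::lm(A[hi] ~ Tc[hi]))
  amp0 <- (bl_f[1] + bl_f[2] * init$Tm_C) - (bl_u[1] + bl_u[2] * init$Tm_C)
  Tm0_K <- celsius_to_kelvin(init$Tm_C)
  ## |dH| ~ 4 R Tm^2 |df/dT| at Tm on the normalised curve
  dfdT <- if (abs(amp0) > 0) abs(init$slope / amp0) else 0.02
  dH0 <- -max(10, min(150, 4 * R_KCAL * Tm0_K^2 * dfdT))

  model <- function(dH, Tm_K, a_f, b_f, a_u, b_u) {
    f <- fraction_folded(celsius_to_kelvin(Tc), two_state_params(dH, Tm_K))
    f * (a_f + b_f * Tc) + (1 - f) * (a_u + b_u * Tc)
  }
  best <- NULL
  for (shift in c(0, -5, 5)) {
    start <- list(dH = dH0, Tm_K = Tm0_K + shift,
                  a_f = unname(bl_f[1]), b_f = unname(bl_f[2]),
                  a_u = unname(bl_u[1]), b_u = unname(bl_u[2]))
    fit <- tryCatch(
      minpack.lm::nlsLM(A ~ model(dH, Tm_K, a_f, b_f, a_u, b_u),
                        start = start,
                        lower = c(-300, 250, -Inf, -Inf, -Inf, -Inf),
                        upper = c(-0.1, 450, Inf, Inf, Inf, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop_quadstall("two-state fit failed to converge from all starts",
                   "quadstall_fit_failure")
  cf <- stats::coef(best$fit)
  rms <- sqrt(best$rss / n)
  ## transition must rise above the noise floor: amplitude between the
  ## fitted baselines at Tm compared with the residual scale
  TmC_hat <- kelvin_to_celsius(cf[["Tm_K"]])
  amp <- abs((cf[["a_f"]] + cf[["b_f"]] * TmC_hat) -
             (cf[["a_u"]] + cf[["b_u"]] * TmC_hat))
  in_range <- TmC_hat > min(Tc) && TmC_hat < max(Tc)
  if (!in_range || amp < amplitude_noise_ratio * max(rms, 1e-12))
    stop_quadstall(
      "no transition: amplitude below noise floor or Tm outside scan range",
      "quadstall_no_transition")
  list(params = two_state_params(cf[["dH"]], cf[["Tm_K"]]),
       baselines = list(a_f = cf[["a_f"]], b_f = cf[["b_f"]],
                        a_u = cf[["a_u"]], b_u = cf[["b_u"]]),
       residual_rms = rms)
}

#' Fit the two-state intramolecular model to melting curves
#'
#' Nonlinear least squares over (dH, Tm, and two linear baselines), with the
#' entropy tied to dH/Tm by the two-state parameterisation. The melting
#' temperature is initialised at the extremum of the smoothed derivative
#' dA/dT (with a multi-start at +-5 C), the enthalpy from
#' |dH| ~ 4 R Tm^2 |df/dT| on the normalised curve. A monotone curve whose
#' fitted amplitude does not exceed `amplitude_noise_ratio` times the
#' residual RMS raises a "no transition" error, as does a fitted Tm outside
#' the scanned range. Replicates are fitted independently and aggregated as
#' mean +- SD, the uncertainty model used for replicate melting profiles.
#'
#' @param curves a [melting_curve] or a list of replicate curves.
#' @param amplitude_noise_ratio required ratio of transition amplitude to
#'   residual RMS (default 5).
#' @return object of class `two_state_fit`: `params` (replicate-mean dH and
#'   Tm), `baselines` (first replicate), `residual_rms`,
#'   `replicates` (per-replicate data.frame of dH, Tm, dG37), and
#'   `summary` (mean and SD of dH, Tm_C, dG37; SD is NA with one replicate).
#' @examples
#' p <- two_state_params(-45.69, 349.55)
#' cv <- simulate_melting_curve(p)
#' fit <- fit_two_state(cv)
#' round(kelvin_to_celsius(fit$params$Tm_K), 1)  # 76.4
#' @export
fit_two_state <- function(curves, amplitude_noise_ratio = 5) {
  if (inherits(curves, "melting_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L)
  fits <- lapply(curves, .fit_one_curve,
                 amplitude_noise_ratio = amplitude_noise_ratio)
  per <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(replicate = attr(curves[[i]], "replicate") %||% paste0("r", i),
               dH = f$params$dH, Tm_C = kelvin_to_celsius(f$params$Tm_K),
               dG37 = f$params$dG37, residual_rms = f$residual_rms)
  }))
  sds <- if (nrow(per) >= 2L) {
    vapply(per[c("dH", "Tm_C", "dG37")], stats::sd, 0)
  } else c(dH = NA_real_, Tm_C = NA_real_, dG37 = NA_real_)
  structure(list(
    params = two_state_params(mean(per$dH),
                              celsius_to_kelvin(mean(per$Tm_C))),
    baselines = fits[[1L]]$baselines,
    residual_rms = fits[[1L]]$residual_rms,
    replicates = per,
    summary = list(mean = colMeans(per[c("dH", "Tm_C", "dG37")]), sd = sds)),
    class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  m <- x$summary$mean; s <- x$summary$sd
  cat(sprintf("two-state fit over %d replicate(s)\n", nrow(x$replicates)))
  cat(sprintf("  dH   %.2f +- %.2f kcal/mol\n", m[["dH"]], s[["dH"]]))
  cat(sprintf("  Tm   %.1f +- %.1f C\n", m[["Tm_C"]], s[["Tm_C"]]))
  cat(sprintf("  dG37 %.2f +- %.2f kcal/mol\n", m[["dG37"]], s[["dG37"]]))
  invisible(x)
}

#' Normalise a melting curve to fraction folded
#'
#' \eqn{\theta(T) = (A - \mathrm{unfolded})/(\mathrm{folded} -
#' \mathrm{unfolded})} using the fitted baselines; values outside
#' \[-0.05, 1.05\] are clipped and the number of clipped points recorded in
#' attribute `n_clipped`.
#'
#' @param curve a [melting_curve].
#' @param fit a [fit_two_state()] result supplying baselines.
#' @return a [melting_curve] with signal in \[0, 1\] (approximately).
#' @export
normalize_curve <- function(curve, fit) {
  stopifnot(inherits(curve, "melting_curve"), inherits(fit, "two_state_fit"))
  b <- fit$baselines
  Tc <- curve$temperature_C
  folded <- b$a_f + b$b_f * Tc
  unfolded <- b$a_u + b$b_u * Tc
  if (max(abs(folded - unfolded)) < 1e-12)
    stop_quadstall("degenerate (identical) baselines", "quadstall_bad_curve")
  th <- (curve$signal - unfolded) / (folded - unfolded)
  n_clip <- sum(th < -0.05 | th > 1.05)
  th <- pmin(pmax(th, -0.05), 1.05)
  out <- melting_curve(Tc, th, wavelength_nm = attr(curve, "wavelength_nm"),
                       replicate = attr(curve, "replicate"))
  attr(out, "n_clipped") <- n_clip
  out
}

#' Read or write melting-curve CSV
#'
#' Schema: `temperature_C, signal, wavelength_nm, replicate` (header
#' required, comma-separated). One file may carry several replicates.
#'
#' @param path CSV path.
#' @return `read_melting_csv`: list of [melting_curve], one per replicate.
#' @export
read_melting_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("temperature_C", "signal", "wavelength_nm", "replicate")
  if (!all(need %in% names(d)))
    stop_quadstall(paste("melting CSV must have columns",
                         paste(need, collapse = ", ")),
                   "quadstall_bad_schema")
  lapply(split(d, d$replicate), function(g)
    melting_curve(g$temperature_C, g$signal,
                  wavelength_nm = g$wavelength_nm[1],
                  replicate = as.character(g$replicate[1])))
}

#' @param curves list of [melting_curve].
#' @rdname read_melting_csv
#' @export
write_melting_csv <- function(curves, path) {
  if (inherits(curves, "melting_curve")) curves <- list(curves)
  d <- do.call(rbind, lapply(curves, function(cv)
    data.frame(temperature_C = cv$temperature_C, signal = cv$signal,
               wavelength_nm = attr(cv, "wavelength_nm"),
               replicate = attr(cv, "replicate"))))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
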