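#' Run the full analysis pipeline on an input bundle
#'
#' Reproduces the study's analysis flow end to end on a directory of input
#' CSVs (as produced by [generate_bundle()] or exported from instruments in
#' the same schemas): per-variant two-state melting fits with replicate
#' mean +- SD (the thermodynamic-stability table), CD two-state diagnostics
#' (isosbestic point, 265/242 linearity, topology signature at the lowest
#' temperature), the stall-escape kinetic fit, and the exponential
#' cleavage-ratio fit. A melting set with no detectable transition is
#' flagged "ND" and the pipeline continues. All fits are deterministic
#' given the inputs, so rerunning reproduces the same report.
#'
#' @param data_dir directory containing `melting_<variant>.csv` files and
#'   optionally `cd_series.csv`, `stall_timecourse.csv`, `cleavage.csv`.
#' @param out optional path for a JSON copy of the report.
#' @return list of class `run_report`: `thermo` (data.frame: variant, dH,
#'   Tm_C, dG37, SDs, status), `cd`, `stall`, `cleavage`, `provenance`.
#' @export
run_pipeline <- function(data_dir, out = NULL) {
  if (!dir.exists(data_dir))
    stop_quadstall(paste("no such directory:", data_dir),
                   "quadstall_missing_input")
  melt_files <- sort(list.files(data_dir, "^melting_.*\\.csv$",
                                full.names = TRUE))
  if (!length(melt_files))
    stop_quadstall("no melting_*.csv files found", "quadstall_missing_input")
  thermo <- do.call(rbind, lapply(melt_files, function(f) {
    variant <- sub("^melting_(.*)\\.csv$", "\\1", basename(f))
    curves <- read_melting_csv(f)
    fit <- tryCatch(fit_two_state(curves), quadstall_no_transition = identity,
                    quadstall_fit_failure = identity)
    if (inherits(fit, "condition")) {
      data.frame(variant = variant, dH = NA, dH_sd = NA, Tm_C = NA,
                 Tm_sd = NA, dG37 = NA, dG37_sd = NA,
                 n_replicates = length(curves), status = "ND")
    } else {
      m <- fit$summary$mean; s <- fit$summary$sd
      data.frame(variant = variant, dH = m[["dH"]], dH_sd = s[["dH"]],
                 Tm_C = m[["Tm_C"]], Tm_sd = s[["Tm_C"]],
                 dG37 = m[["dG37"]], dG37_sd = s[["dG37"]],
                 n_replicates = length(curves), status = "ok")
    }
  }))
  rownames(thermo) <- NULL

  cd_path <- file.path(data_dir, "cd_series.csv")
  cd_report <- if (file.exists(cd_path)) {
    series <- read_cd_csv(cd_path)
    sig <- topology_signature(series$wavelengths_nm, series$intensity[1, ])
    list(isosbestic = isosbestic_point(series),
         linearity = two_state_linearity(series),
         signature = sig,
         melt_fit_265 = tryCatch({
           f <- fit_two_state(cd_melting_curve(series, 265))
           list(Tm_C = kelvin_to_celsius(f$params$Tm_K),
                dG37 = f$params$dG37)
         }, error = function(e) NULL))
  } else NULL

  stall_path <- file.path(data_dir, "stall_timecourse.csv")
  stall_report <- if (file.exists(stall_path)) {
    recs <- read_stall_csv(stall_path)
    fit <- fit_escape(recs)
    list(k0 = fit$k0, alpha = fit$alpha, phi = as.list(fit$phi),
         ci_alpha = fit$ci_alpha, residual_rms = fit$residual_rms)
  } else NULL

  cleave_path <- file.path(data_dir, "cleavage.csv")
  cleave_report <- if (file.exists(cleave_path)) {
    ratios <- relative_ratios(read_cleavage_csv(cleave_path))
    fit <- fit_exponential(ratios$x, ratios$rho_mean, sd = ratios$rho_sd)
    list(ratios = ratios, b = fit$b, form_id = fit$form_id,
         residual_rms = fit$residual_rms)
  } else NULL

  report <- structure(list(
    thermo = thermo, cd = cd_report, stall = stall_report,
    cleavage = cleave_report,
    provenance = list(data_dir = normalizePath(data_dir),
                      files = basename(c(melt_files,
                                         Filter(file.exists,
                                                c(cd_path, stall_path,
                                                  cleave_path)))),
                      package_version =
                        as.character(utils::packageVersion("quadstall")))),
    class = "run_report")
  if (!is.null(out)) {
    rep_json <- report
    rep_json$provenance$data_dir <- NULL  # keep the JSON machine-portable
    jsonlite::write_json(rep_json, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("== thermodynamic stabilities (two-state UV melting fits) ==\n")
  th <- x$thermo
  for (i in seq_len(nrow(th))) {
    if (th$status[i] == "ND") {
      cat(sprintf("  %-10s ND\n", th$variant[i]))
    } else {
      cat(sprintf("  %-10s dG37 %6.2f +- %.2f kcal/mol   Tm %5.1f +- %.1f C\n",
                  th$variant[i], th$dG37[i], th$dG37_sd[i],
                  th$Tm_C[i], th$Tm_sd[i]))
    }
  }
  if (!is.null(x$cd)) {
    cat(sprintf("== CD: isosbestic %g nm (spread %.3g), r(265,242) = %.6f, %s ==\n",
                x$cd$isosbestic$wavelength_nm, x$cd$isosbestic$spread,
                x$cd$linearity$r, x$cd$signature$classification))
  }
  if (!is.null(x$stall))
    cat(sprintf("== stall: k0 %.4g 1/s, alpha %.3f ==\n",
                x$stall$k0, x$stall$alpha))
  if (!is.null(x$cleavage))
    cat(sprintf("== cleavage: rho = exp(b x), b = %.3f (kcal/mol)^-1 ==\n",
                x$cleavage$b))
  invisible(x)
}
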