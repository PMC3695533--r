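## deterministic sub-seed spawning: one master seed, one stream per file
.sub_seed <- function(master, k) (as.integer(master) * 97L + k) %% 2147483647L

#' Scenario configuration reproducing the published study design
#'
#' Builds the default synthetic scenario: five synonymous QFP variants with
#' the published stabilities, melting enthalpies back-computed from the
#' printed (dG37, Tm) pairs via dH = dG37 / (1 - 310.15/Tm_K), the
#' quadruplex-free variant flagged as transition-free, five melting
#' replicates per variant on a 20-95 C grid, a CD series built from two
#' basis spectra crossing exactly at 250 nm, stall time courses sampled at
#' 0/20/60/120/300/600 s, and a three-replicate cleavage table following
#' rho = exp(b x). Default noise levels: additive Gaussian 0.002 on
#' absorbance and 0.3 mdeg on CD; multiplicative log-normal 5% on band
#' intensities (gel error is multiplicative). Every derived quantity is
#' recomputable from the config alone.
#'
#' @param seed master seed; per-file sub-seeds are spawned from it
#'   deterministically.
#' @param noise_scale scalar multiplying every noise level (0 gives exact
#'   forward models).
#' @return list of class `scenario_config`.
#' @examples
#' cfg <- make_table1_scenario(seed = 42)
#' cfg$variants$dH[1]   # -45.69 (wild-type)
#' @export
make_table1_scenario <- function(seed = 42, noise_scale = 1) {
  v <- data.frame(
    name = c("wild_type", "A_mutant", "C_mutant", "G_mutant", "U_mutant"),
    dG37 = c(-5.15, 0, -4.77, -5.86, -0.47),
    Tm_C = c(76.4, NA, 72.6, 82.4, 39.9),
    folded = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    phi = c(1, 0, 1, 1, 0.5))
  v$dH <- ifelse(v$folded,
                 v$dG37 / (1 - T37_K / celsius_to_kelvin(v$Tm_C)), NA)
  structure(list(
    variants = v,
    melt = list(T_grid_C = seq(20, 95, by = 0.5),
                noise_sd = 0.002 * noise_scale, n_replicates = 5L,
                baselines = list(a_f = 0.30, b_f = -1e-4,
                                 a_u = 0.20, b_u = -2e-4)),
    cd = list(wavelengths_nm = 220:320,
              temperatures_C = seq(20, 95, by = 5),
              noise_sd = 0.3 * noise_scale,
              peak = list(center = 265, height = 8, width = 8),
              trough = list(center = 241, height = -5, width = 6),
              unfolded_gamma = 0.25, isosbestic_nm = 250),
    stall = list(k0 = 0.03, alpha = 0.6, k_fast = 1,
                 times_s = c(0, 20, 60, 120, 300, 600),
                 noise_cv = 0.05 * noise_scale),
    cleavage = list(b = 0.3, ratio_std = 0.2, n_replicates = 3L,
                    noise_cv = 0.05 * noise_scale, full_intensity = 100),
    seed = as.integer(seed)),
    class = "scenario_config")
}

.cd_basis <- function(cd) {
  wl <- cd$wavelengths_nm
  g <- function(p) p$height * exp(-(wl - p$center)^2 / (2 * p$width^2))
  b_f <- g(cd$peak) + g(cd$trough)
  at_iso <- b_f[match(cd$isosbestic_nm, wl)]
  b_u <- cd$unfolded_gamma * b_f + (1 - cd$unfolded_gamma) * at_iso
  list(folded = b_f, unfolded = b_u)
}

#' Simulate a CD spectral series from two basis spectra
#'
#' Spectra are the two-state mixture f(T) B_folded + (1 - f(T)) B_unfolded
#' with additive Gaussian noise; with zero noise the series has an exact
#' isosbestic point where the bases agree and |r| = 1 between any two
#' wavelengths.
#'
#' @param config a [make_table1_scenario()] config.
#' @param params a [two_state_params] driving f(T).
#' @param seed integer seed.
#' @return a [spectrum_series].
#' @export
simulate_cd_series <- function(config, params, seed = 1) {
  cd <- config$cd
  basis <- .cd_basis(cd)
  f <- fraction_folded(celsius_to_kelvin(cd$temperatures_C), params)
  m <- outer(f, basis$folded) + outer(1 - f, basis$unfolded)
  if (cd$noise_sd > 0) {
    set.seed(seed)
    m <- m + matrix(stats::rnorm(length(m), sd = cd$noise_sd), nrow(m))
  }
  spectrum_series(cd$wavelengths_nm, cd$temperatures_C, m)
}

.lognorm_noise <- function(x, cv, seed) {
  if (cv <= 0) return(x)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate the full synthetic input bundle
#'
#' Writes, under `out_dir`: one melting CSV per variant (five replicates
#' stacked; the transition-free variant gets a pure sloped baseline), a CD
#' series CSV for the wild-type, a stall band CSV across all variants at
#' the standard sample times, a three-replicate cleavage CSV, and
#' `manifest.json` recording the ground-truth parameters. Outputs are
#' byte-identical for a given config (one master seed spawns per-file
#' sub-seeds).
#'
#' @param config a [make_table1_scenario()] config.
#' @param out_dir writable directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
generate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- config$variants
  ml <- config$melt
  k <- 0L
  for (i in seq_len(nrow(v))) {
    curves <- lapply(seq_len(ml$n_replicates), function(r) {
      k <<- k + 1L
      if (v$folded[i]) {
        simulate_melting_curve(
          two_state_params(v$dH[i], celsius_to_kelvin(v$Tm_C[i])),
          baselines = ml$baselines, T_grid_C = ml$T_grid_C,
          noise_sd = ml$noise_sd, seed = .sub_seed(config$seed, k),
          replicate = paste0("r", r))
      } else {
        ## no quadruplex: the unfolded baseline alone
        a <- ml$baselines$a_u + ml$baselines$b_u * ml$T_grid_C
        if (ml$noise_sd > 0) {
          set.seed(.sub_seed(config$seed, k))
          a <- a + stats::rnorm(length(a), sd = ml$noise_sd)
        }
        melting_curve(ml$T_grid_C, a, replicate = paste0("r", r))
      }
    })
    write_melting_csv(curves, file.path(out_dir,
                                        paste0("melting_", v$name[i], ".csv")))
  }
  ## CD series for the wild-type variant
  wt <- which(v$name == "wild_type")
  cd <- simulate_cd_series(config,
                           two_state_params(v$dH[wt],
                                            celsius_to_kelvin(v$Tm_C[wt])),
                           seed = .sub_seed(config$seed, 900L))
  write_cd_csv(cd, file.path(out_dir, "cd_series.csv"))
  ## stall time courses
  st <- config$stall
  base_model <- stall_model(k0 = st$k0, alpha = st$alpha, phi = 1,
                            k_fast = st$k_fast)
  records <- lapply(seq_len(nrow(v)), function(i) {
    tc <- simulate_timecourse(base_model, min(v$dG37[i], 0), st$times_s,
                              phi = v$phi[i])
    for (j in seq_along(c("H", "I", "F"))) {
      band <- c("H", "I", "F")[j]
      tc[[band]] <- .lognorm_noise(tc[[band]], st$noise_cv,
                                   .sub_seed(config$seed, 900L + 10L * i + j))
    }
    list(name = v$name[i], dG37 = v$dG37[i], tc = tc)
  })
  write_stall_csv(records, file.path(out_dir, "stall_timecourse.csv"))
  ## cleavage table
  cl <- config$cleavage
  rows <- do.call(rbind, lapply(seq_len(nrow(v)), function(i) {
    x <- -v$dG37[i]
    data.frame(variant = v$name[i], dG37_kcal_mol = v$dG37[i],
               replicate = paste0("n", seq_len(cl$n_replicates)),
               intensity_full = cl$full_intensity,
               intensity_cleaved = cl$full_intensity * cl$ratio_std *
                 exp(cl$b * x))
  }))
  rows$intensity_full <- .lognorm_noise(rows$intensity_full, cl$noise_cv,
                                        .sub_seed(config$seed, 980L))
  rows$intensity_cleaved <- .lognorm_noise(rows$intensity_cleaved, cl$noise_cv,
                                           .sub_seed(config$seed, 981L))
  utils::write.csv(rows, file.path(out_dir, "cleavage.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = config$seed,
    variants = v,
    stall = list(k0 = st$k0, alpha = st$alpha, k_fast = st$k_fast),
    cleavage = list(b = cl$b, ratio_std = cl$ratio_std),
    noise = list(melt_sd = ml$noise_sd, cd_sd = config$cd$noise_sd,
                 band_cv = st$noise_cv))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
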