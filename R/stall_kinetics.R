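#' Kinetic model of ribosome stall escape at a G-quadruplex
#'
#' Two-path, first-order model of a synchronized-translation experiment.
#' At t = 0 all ribosomes sit at the artificial halt site (species H). A
#' fraction `phi` of mRNA molecules carry a folded quadruplex: on these the
#' ribosome runs to the stall site (H -> I, rate `k_fast`) and then escapes
#' with rate k given by [escape_rate()] (I -> F). On the remaining
#' `1 - phi` the ribosome elongates straight to the full-length product
#' (H -> F, rate `k_fast`). The escape activation energy is taken
#' proportional to the quadruplex stability, making k exponential in the
#' folding free energy:
#' \deqn{k = k_0 \exp(\alpha\,\Delta G^{\circ}_{37}/RT)}
#'
#' @param k0 pre-exponential escape rate, 1/s.
#' @param alpha dimensionless proportionality of the activation energy to
#'   |dG37|.
#' @param phi fraction of mRNA molecules with a folded quadruplex, in
#'   \[0, 1\].
#' @param k_fast rate of the unhindered elongation step, 1/s; must be at
#'   least 10 k0 so the stall is rate-limiting.
#' @return object of class `stall_model`.
#' @export
stall_model <- function(k0 = 0.01, alpha = 1, phi = 1, k_fast = 1) {
  stopifnot(k0 > 0, alpha >= 0, phi >= 0, phi <= 1)
  if (k_fast < 10 * k0)
    stop_quadstall("k_fast must be >= 10 * k0 (stall rate-limiting)",
                   "quadstall_bad_model")
  structure(list(k0 = k0, alpha = alpha, phi = phi, k_fast = k_fast),
            class = "stall_model")
}

#' Stall escape rate from quadruplex stability
#'
#' \eqn{k = k_0 \exp(\alpha \Delta G^{\circ}_{37} / RT)}: equals k0 when
#' there is no quadruplex (dG37 = 0) or when alpha = 0, and decreases as
#' the quadruplex becomes more stable (more negative dG37).
#'
#' @param dG37 folding free energy at 37 C, kcal/mol (<= 0; 0 encodes "no
#'   quadruplex").
#' @param model a [stall_model].
#' @param T_K temperature, K (reactions at 37 C).
#' @return escape rate, 1/s.
#' @export
escape_rate <- function(dG37, model, T_K = T37_K) {
  stopifnot(inherits(model, "stall_model"), all(dG37 <= 0))
  model$k0 * exp(model$alpha * dG37 / (R_KCAL * T_K))
}

#' Simulate a stall-escape time course
#'
#' Closed-form solution of the two-path model (sums of exponentials; band
#' intensities are ensemble averages, so no stochastic simulation is
#' needed). Mass conservation H + I + F = 1 holds exactly at every time.
#'
#' @param model a [stall_model].
#' @param dG37 quadruplex stability, kcal/mol.
#' @param times_s increasing sample times, s.
#' @param phi optional override of the model's folded-mRNA fraction (the
#'   per-variant parameter).
#' @return data.frame of class `time_course`: `time_s`, `H`, `I`, `F`.
#' @export
simulate_timecourse <- function(model, dG37, times_s = c(0, 20, 60, 120, 300, 600),
                                phi = NULL) {
  stopifnot(inherits(model, "stall_model"), all(times_s >= 0),
            !is.unsorted(times_s))
  phi <- phi %||% model$phi
  kf <- model$k_fast
  k <- escape_rate(dG37, model)
  t <- times_s
  H <- exp(-kf * t)
  ## sequential H -> I -> F on the stalled path
  I <- if (abs(kf - k) > 1e-12 * kf) {
    phi * kf / (kf - k) * (exp(-k * t) - exp(-kf * t))
  } else {
    phi * kf * t * exp(-kf * t)
  }
  F_ <- 1 - H - I
  structure(data.frame(time_s = t, H = H, I = I, F = F_),
            dG37 = dG37, phi = phi, class = c("time_course", "data.frame"))
}

## model-predicted (I, F) stacked across variants; used by fit_escape.
## Closed forms inlined so the optimiser may probe alpha < 0 transiently.
.stall_predict <- function(k0, alpha, phis, dG_list, times_list, k_fast) {
  unlist(lapply(seq_along(dG_list), function(i) {
    k <- k0 * exp(alpha * dG_list[[i]] / (R_KCAL * T37_K))
    t <- times_list[[i]]
    H <- exp(-k_fast * t)
    I <- if (abs(k_fast - k) > 1e-12 * k_fast) {
      phis[i] * k_fast / (k_fast - k) * (exp(-k * t) - exp(-k_fast * t))
    } else {
      phis[i] * k_fast * t * exp(-k_fast * t)
    }
    c(I, 1 - H - I)
  }))
}

#' Fit the stall-escape model to band time courses
#'
#' Least-squares fit of (k0, alpha, and a folded fraction phi per variant)
#' to the intermediate (I) and full-length (F) band trajectories of several
#' variants of known stability. `k_fast` is held at the model default (the
#' unhindered step is not resolved by the sampled times). Starting values
#' come from per-variant single-rate estimates regressed on dG37/RT;
#' uncertainties are Wald intervals from the numerical Hessian of the
#' residual sum of squares over (log k0, alpha), with the folded fractions
#' held at their estimates.
#'
#' @param timecourses list; each element a list with `dG37` and `tc` (a
#'   data.frame with `time_s`, `I`, `F`). At least 2 distinct stabilities
#'   and 3 time points each.
#' @param k_fast fixed fast-step rate, 1/s.
#' @return list of class `stall_fit`: `k0`, `alpha`, `phi` (named per
#'   variant), `ci_alpha` (95%), `ci_k0`, `residual_rms`, `convergence`.
#' @export
fit_escape <- function(timecourses, k_fast = 1) {
  if (length(timecourses) < 2L)
    stop_quadstall("need >= 2 time courses", "quadstall_bad_input")
  dG <- vapply(timecourses, function(x) x$dG37, 0)
  if (length(unique(dG)) < 2L)
    stop_quadstall("need >= 2 distinct dG37 values", "quadstall_bad_input")
  times_list <- lapply(timecourses, function(x) x$tc$time_s)
  if (any(vapply(times_list, length, 0L) < 3L))
    stop_quadstall("each time course needs >= 3 time points",
                   "quadstall_bad_input")
  obs <- unlist(lapply(timecourses, function(x) c(x$tc$I, x$tc$F)))
  nv <- length(timecourses)

  ## starts: phi from the largest observed I (plus late F deficit on slow
  ## variants); per-variant k from a 1-D profile, then log-linear regression
  phi0 <- vapply(timecourses, function(x) {
    max(min(max(x$tc$I) + max(0, 1 - max(x$tc$F) - max(x$tc$I)), 1), 0.01)
  }, 0)
  k_hat <- vapply(seq_len(nv), function(i) {
    x <- timecourses[[i]]
    f <- function(lk) {
      m <- stall_model(k0 = exp(lk), alpha = 0, phi = phi0[i], k_fast = k_fast)
      tc <- simulate_timecourse(m, 0, x$tc$time_s)
      sum((tc$I - x$tc$I)^2 + (tc$F - x$tc$F)^2)
    }
    exp(stats::optimize(f, c(log(1e-6), log(k_fast / 10.5)))$minimum)
  }, 0)
  w <- phi0 > 0.05   # phi ~ 0 variants carry no rate information
  xreg <- dG[w] / (R_KCAL * T37_K)
  if (sum(w) >= 2L && stats::sd(xreg) > 0) {
    cf <- stats::coef(stats::lm(log(k_hat[w]) ~ xreg))
    k0_0 <- exp(unname(cf[1])); alpha0 <- unname(cf[2])
  } else {
    k0_0 <- stats::median(k_hat); alpha0 <- 1
  }
  k0_0 <- min(max(k0_0, 1e-5), k_fast / 20)

  par0 <- c(log(k0_0), alpha0, stats::qlogis(pmin(pmax(phi0, 0.01), 0.99)))
  sse <- function(p) {
    k0 <- exp(p[1]); alpha <- p[2]; phis <- stats::plogis(p[-(1:2)])
    if (!is.finite(k0) || k0 <= 0 || k0 > k_fast / 10) return(1e10)
    pred <- .stall_predict(k0, alpha, phis, as.list(dG), times_list, k_fast)
    sum((pred - obs)^2)
  }
  opt <- stats::optim(par0, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  opt <- stats::optim(opt$par, sse, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  k0 <- unname(exp(opt$par[1])); alpha <- unname(opt$par[2])
  phis <- stats::plogis(opt$par[-(1:2)])
  names(phis) <- vapply(seq_len(nv), function(i)
    timecourses[[i]]$name %||% paste0("v", i), "")
  n_obs <- length(obs)
  sigma2 <- opt$value / max(n_obs - length(opt$par), 1)
  ## Wald intervals from the (log k0, alpha) sub-Hessian, folded fractions
  ## held at their estimates: the full Hessian is singular when a phi sits
  ## at its boundary, but the rate parameters remain well conditioned.
  ci_alpha <- ci_k0 <- c(NA_real_, NA_real_)
  h <- c(max(abs(opt$par[1]), 1) * 1e-4, max(abs(opt$par[2]), 1) * 1e-4)
  H2 <- matrix(NA_real_, 2, 2)
  f0 <- opt$value
  for (a in 1:2) for (b in 1:2) {
    ea <- eb <- numeric(length(opt$par)); ea[a] <- h[a]; eb[b] <- h[b]
    H2[a, b] <- (sse(opt$par + ea + eb) - sse(opt$par + ea - eb) -
                 sse(opt$par - ea + eb) + sse(opt$par - ea - eb)) /
      (4 * h[a] * h[b])
  }
  cov <- tryCatch(solve(H2 / 2) * sigma2, error = function(e) NULL)
  if (!is.null(cov) && all(is.finite(diag(cov))) && all(diag(cov) >= 0)) {
    se <- sqrt(diag(cov))
    ci_alpha <- alpha + c(-1, 1) * 1.96 * se[2]
    ci_k0 <- exp(unname(opt$par[1]) + c(-1, 1) * 1.96 * se[1])
  }
  structure(list(k0 = k0, alpha = alpha, phi = phis,
                 ci_alpha = ci_alpha, ci_k0 = ci_k0,
                 residual_rms = sqrt(opt$value / n_obs),
                 convergence = opt$convergence),
            class = "stall_fit")
}

#' @export
print.stall_fit <- function(x, ...) {
  cat(sprintf("stall-escape fit: k0 = %.4g 1/s, alpha = %.3f [%.3f, %.3f]\n",
              x$k0, x$alpha, x$ci_alpha[1], x$ci_alpha[2]))
  cat("phi:", paste(sprintf("%s=%.2f", names(x$phi), x$phi), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read or write stall band-intensity CSV
#'
#' Schema: `variant, dG37_kcal_mol, time_s, band, intensity` with band one
#' of H, I, F. Intensities are normalised within each (variant, time) so
#' the three bands sum to 1 before fitting.
#'
#' @param path CSV path.
#' @return `read_stall_csv`: list (one per variant) with `name`, `dG37`,
#'   `tc` (data.frame `time_s`, `H`, `I`, `F`).
#' @export
read_stall_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("variant", "dG37_kcal_mol", "time_s", "band", "intensity")
  if (!all(need %in% names(d)))
    stop_quadstall(paste("stall CSV must have columns",
                         paste(need, collapse = ", ")),
                   "quadstall_bad_schema")
  lapply(split(d, d$variant), function(g) {
    wide <- stats::reshape(
      g[c("time_s", "band", "intensity")], direction = "wide",
      idvar = "time_s", timevar = "band")
    names(wide) <- sub("^intensity\\.", "", names(wide))
    wide <- wide[order(wide$time_s), ]
    tot <- wide$H + wide$I + wide$F
    list(name = as.character(g$variant[1]), dG37 = g$dG37_kcal_mol[1],
         tc = data.frame(time_s = wide$time_s, H = wide$H / tot,
                         I = wide$I / tot, F = wide$F / tot))
  })
}

#' @param records list as returned by `read_stall_csv`.
#' @rdname read_stall_csv
#' @export
write_stall_csv <- function(records, path) {
  d <- do.call(rbind, lapply(records, function(r) {
    long <- data.frame(
      variant = r$name, dG37_kcal_mol = r$dG37,
      time_s = rep(r$tc$time_s, 3L),
      band = rep(c("H", "I", "F"), each = nrow(r$tc)),
      intensity = c(r$tc$H, r$tc$I, r$tc$F))
    long
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
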