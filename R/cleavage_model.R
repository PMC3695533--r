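#' Validate a cleavage band-intensity table
#'
#' Per-variant full-length and cleaved band intensities with the folding
#' free energy as covariate. The quadruplex-free standard variant carries
#' `dG37 = 0` and must be present: all ratios are expressed relative to it.
#'
#' @param table data.frame with columns `variant`, `dG37_kcal_mol`,
#'   `replicate`, `intensity_full`, `intensity_cleaved`.
#' @return the table, validated, with class `cleavage_table` prepended.
#' @export
cleavage_table <- function(table) {
  need <- c("variant", "dG37_kcal_mol", "replicate",
            "intensity_full", "intensity_cleaved")
  if (!all(need %in% names(table)))
    stop_quadstall(paste("cleavage table must have columns",
                         paste(need, collapse = ", ")),
                   "quadstall_bad_schema")
  if (any(table$intensity_full <= 0) || any(table$intensity_cleaved <= 0))
    stop_quadstall("band intensities must be positive",
                   "quadstall_bad_input")
  if (!any(table$dG37_kcal_mol == 0))
    stop_quadstall("no standard (dG37 = 0) variant in table",
                   "quadstall_bad_input")
  class(table) <- unique(c("cleavage_table", class(table)))
  table
}

#' Cleaved-to-full ratios relative to the quadruplex-free standard
#'
#' Computes, replicate-wise, rho = (cleaved/full) / (cleaved/full of the
#' dG37 = 0 standard in the same replicate), then summarises mean +- SD per
#' variant. The standard has rho = 1 by construction, and rho is invariant
#' to any per-lane rescaling of intensities.
#'
#' @param table a [cleavage_table] (or coercible data.frame).
#' @return data.frame: `variant`, `dG37_kcal_mol`, `x` (= -dG37),
#'   `rho_mean`, `rho_sd`, `n`.
#' @export
relative_ratios <- function(table) {
  table <- cleavage_table(as.data.frame(table))
  table$ratio <- table$intensity_cleaved / table$intensity_full
  std <- table[table$dG37_kcal_mol == 0, ]
  std_by_rep <- tapply(std$ratio, std$replicate, mean)
  table$rho <- table$ratio / std_by_rep[as.character(table$replicate)]
  if (anyNA(table$rho))
    stop_quadstall("replicate without a matching standard lane",
                   "quadstall_bad_input")
  agg <- do.call(rbind, lapply(split(table, table$variant), function(g)
    data.frame(variant = g$variant[1], dG37_kcal_mol = g$dG37_kcal_mol[1],
               x = -g$dG37_kcal_mol[1],
               rho_mean = mean(g$rho),
               rho_sd = if (nrow(g) >= 2) stats::sd(g$rho) else NA_real_,
               n = nrow(g))))
  agg[order(agg$x), ]
}

#' Fit the single-exponential stability-cleavage relation
#'
#' Fits rho(x) against x = -dG37. The default anchored form
#' \eqn{\rho = \exp(bx)} passes through (0, 1) exactly, since the
#' quadruplex-free standard defines rho = 1; the affine form
#' \eqn{\rho = c + a\exp(bx)} is available for sensitivity analysis.
#' Fitting is least squares on the rho scale (uncertainties are reported
#' on rho, not log rho), optionally inverse-variance weighted.
#'
#' @param x numeric -dG37 values (>= 0), at least 3 distinct including 0.
#' @param rho relative ratios (> 0).
#' @param sd optional SDs for weighting (zero/NA SDs get unit weight).
#' @param form "anchored" or "affine".
#' @return list of class `exp_fit`: `b` (1/(kcal/mol)), `a`, `c`,
#'   `residual_rms`, `form_id`, `warning` (non-NULL when all rho equal and
#'   b = 0 is returned).
#' @examples
#' x <- c(0, 0.47, 4.77, 5.15, 5.86)
#' f <- fit_exponential(x, exp(0.3 * x))
#' f$b   # 0.3
#' @export
fit_exponential <- function(x, rho, sd = NULL, form = c("anchored", "affine")) {
  form <- match.arg(form)
  stopifnot(length(x) == length(rho))
  if (any(rho <= 0))
    stop_quadstall("rho must be positive", "quadstall_bad_input")
  if (length(unique(x)) < 3L || !any(x == 0))
    stop_quadstall("need >= 3 distinct x values including x = 0",
                   "quadstall_bad_input")
  warn <- NULL
  if (max(rho) - min(rho) < 1e-12) {
    warn <- "all rho equal; returning b = 0"
    return(structure(list(b = 0, a = 1, c = 0, residual_rms = 0,
                          form_id = form, warning = warn),
                     class = "exp_fit"))
  }
  w <- if (is.null(sd) || !any(sd > 0, na.rm = TRUE)) rep(1, length(x)) else {
    s <- ifelse(is.na(sd) | sd <= 0, stats::median(sd[sd > 0], na.rm = TRUE), sd)
    1 / s^2
  }
  b0 <- unname(stats::coef(stats::lm(log(rho) ~ x))[2])
  d <- data.frame(x = x, rho = rho)
  fit <- if (form == "anchored") {
    minpack.lm::nlsLM(rho ~ exp(b * x), data = d, start = list(b = b0),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    ## start slightly off the anchored solution: an exact-fit start leaves
    ## the optimiser with a degenerate gradient
    minpack.lm::nlsLM(rho ~ cc + a * exp(b * x), data = d,
                      start = list(cc = 0.05, a = 0.9, b = b0), weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  structure(list(b = unname(cf[["b"]]),
                 a = if (form == "affine") unname(cf[["a"]]) else 1,
                 c = if (form == "affine") unname(cf[["cc"]]) else 0,
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 form_id = form, warning = warn),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exponential fit (%s): rho = %s, b = %.4f (kcal/mol)^-1, rms %.3g\n",
              x$form_id,
              if (x$form_id == "anchored") "exp(b x)" else "c + a exp(b x)",
              x$b, x$residual_rms))
  invisible(x)
}

#' Predict a relative cleavage ratio
#'
#' @param x -dG37 values (>= 0).
#' @param fit an [fit_exponential()] result.
#' @return predicted rho, monotone non-decreasing in x for b >= 0;
#'   rho(0) = 1 for the anchored form.
#' @export
predict_ratio <- function(x, fit) {
  stopifnot(inherits(fit, "exp_fit"), all(x >= 0))
  fit$c + fit$a * exp(fit$b * x)
}

#' Read a cleavage CSV
#'
#' Schema: `variant, dG37_kcal_mol, replicate, intensity_full,
#' intensity_cleaved`.
#'
#' @param path CSV path.
#' @return a [cleavage_table].
#' @export
read_cleavage_csv <- function(path) {
  cleavage_table(utils::read.csv(path))
}
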