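# Constant-retentate-volume diafiltration dilution model
#
#   C(N) = C0 * exp(-N * S)
#
# where N is the number of diavolumes exchanged and S the sieving
# coefficient of the solute through the ultrafiltration membrane. S = 1 is
# ideal washout; S < 1 indicates retention (membrane rejection or weak
# association with the retained protein); S slightly above 1 occurs for
# solutes electrostatically repelled by the protein, and is deliberately not
# clipped.

#' Impurity concentration after N diavolumes
#'
#' @param c0 Initial concentration at the start of diafiltration, ug/ml (> 0).
#' @param n Diavolumes exchanged (>= 0).
#' @param s Sieving coefficient (>= 0).
#' @return Concentration `c0 * exp(-n * s)` in ug/ml.
#' @examples
#' predict_concentration(100, 6, 1.02)  # ~0.22 ug/ml
#' @export
predict_concentration <- function(c0, n, s) {
  if (!is.finite(c0) || c0 <= 0) stop("c0 must be > 0", call. = FALSE)
  if (any(!is.finite(n)) || any(n < 0)) stop("n must be >= 0", call. = FALSE)
  if (!is.finite(s) || s < 0) stop("s must be >= 0", call. = FALSE)
  c0 * exp(-n * s)
}

#' Clearance fold achieved by N diavolumes
#'
#' The inverse concentration ratio `exp(n * s)`; equals
#' `c0 / predict_concentration(c0, n, s)` for any `c0`.
#'
#' @inheritParams predict_concentration
#' @return Fold (>= 1).
#' @examples
#' clearance_after_dv(6, 1.02)  # ~455-fold
#' @export
clearance_after_dv <- function(n, s) {
  if (any(!is.finite(n)) || any(n < 0)) stop("n must be >= 0", call. = FALSE)
  if (!is.finite(s) || s < 0) stop("s must be >= 0", call. = FALSE)
  exp(n * s)
}

#' Diavolumes needed for a target clearance fold
#'
#' Analytic inversion of the dilution model: `n = log(fold) / s`. The exact
#' round-trip identity `clearance_after_dv(dv_for_target(f, s), s) == f`
#' holds to floating tolerance.
#'
#' @param fold Target clearance fold (> 1).
#' @param s Sieving coefficient (> 0); a solute with `s = 0` never clears,
#'   so the target is unreachable and an error is raised.
#' @return Required diavolumes.
#' @examples
#' dv_for_target(100, 0.81)  # ~5.7 DV
#' @export
dv_for_target <- function(fold, s) {
  if (!is.finite(fold) || fold <= 1)
    stop("fold must be > 1", call. = FALSE)
  if (!is.finite(s) || s <= 0)
    stop("target unreachable: sieving coefficient must be > 0", call. = FALSE)
  log(fold) / s
}

#' Log-linear closed-form sieving estimate
#'
#' Ordinary least squares of `log(C)` on diavolume; the negated slope
#' estimates S. Used as the initializer for the nonlinear fit and exposed for
#' transparency. At-LOD points are excluded.
#'
#' @param profile A [diafiltration_profile()].
#' @return Estimated sieving coefficient.
#' @export
loglinear_sieving <- function(profile) {
  stopifnot(inherits(profile, "diafiltration_profile"))
  pts <- profile$points[!profile$points$is_lod, , drop = FALSE]
  if (nrow(pts) < 2)
    stop("log-linear estimate needs >= 2 above-LOD points", call. = FALSE)
  -unname(stats::coef(stats::lm(log(concentration) ~ diavolume, data = pts))[2])
}

#' Fit the sieving coefficient to a washout profile
#'
#' One-parameter nonlinear least squares of `C = c0 * exp(-N * S)` on the
#' concentration scale, with `c0` fixed at the profile's stated initial
#' concentration and the log-linear estimate as initializer. Points flagged
#' at the assay LOD are excluded rather than substituted, since substitution
#' would bias S low (this deliberately differs from the clearance-fold LOD
#' rule, which needs a value to form a finite ratio).
#'
#' `r_squared` is computed on the concentration scale as 1 - SS_res/SS_tot;
#' fits below the acceptance threshold are flagged `accepted = FALSE`, never
#' silently dropped.
#'
#' @param profile A [diafiltration_profile()] with at least 3 above-LOD
#'   points.
#' @param r2_threshold Acceptance threshold on R-squared (default 0.95).
#' @return A `sieving_fit`: list with `s`, `r_squared`, `accepted`,
#'   `residuals` (concentration scale), `loglinear_s` and `n_points`.
#' @examples
#' prof <- generate_diafiltration_profile(c0 = 100, s = 1.09, n_points = 6)
#' fit_sieving(prof)$s  # 1.09
#' @export
fit_sieving <- function(profile, r2_threshold = 0.95) {
  stopifnot(inherits(profile, "diafiltration_profile"))
  pts <- profile$points[!profile$points$is_lod, , drop = FALSE]
  if (nrow(pts) < 3)
    stop("sieving fit needs at least 3 above-LOD points", call. = FALSE)
  if (stats::sd(pts$concentration) == 0)
    stop("degenerate profile: constant concentrations", call. = FALSE)
  s0 <- tryCatch(loglinear_sieving(profile), error = function(e) 0.5)
  c0 <- profile$c0
  fit <- stats::nls(concentration ~ c0 * exp(-diavolume * s), data = pts,
                    start = list(s = max(s0, 1e-6)),
                    # scaleOffset makes the convergence test well-defined on
                    # zero-residual (noiseless) profiles
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1))
  s_hat <- unname(stats::coef(fit)[["s"]])
  pred <- c0 * exp(-pts$diavolume * s_hat)
  res <- pts$concentration - pred
  ss_res <- sum(res^2)
  ss_tot <- sum((pts$concentration - mean(pts$concentration))^2)
  r2 <- 1 - ss_res / ss_tot
  structure(list(s = s_hat, r_squared = r2, accepted = r2 >= r2_threshold,
                 residuals = res, loglinear_s = s0, n_points = nrow(pts)),
            class = "sieving_fit")
}

#' @export
print.sieving_fit <- function(x, ...) {
  cat(sprintf("<sieving_fit> S = %.4g (log-linear %.4g), R^2 = %.4f%s, %d points\n",
              x$s, x$loglinear_s, x$r_squared,
              if (x$accepted) "" else " [REJECTED]", x$n_points))
  invisible(x)
}

#' Micelle guard for surfactant spiking studies
#'
#' Diafiltration clears a surfactant only below its critical micelle
#' concentration (CMC): micelles are larger than the membrane cut-off and do
#' not pass. This guard warns when a planned spike concentration of a
#' surfactant exceeds its CMC, and notes when the CMC is unknown.
#'
#' @param pri A [pri_record()].
#' @param spike_concentration Planned spike concentration, ug/ml.
#' @return A list with `ok` (logical) and `message`; additionally raises an R
#'   warning when the CMC is exceeded.
#' @examples
#' poloxamer <- pri_record("F68", "poloxamer 188", "upstream", 450,
#'                         "medium_toxicity", surfactant = TRUE,
#'                         critical_micelle_concentration = 1900)
#' cmc_guard(poloxamer, 450)$ok  # TRUE
#' @export
cmc_guard <- function(pri, spike_concentration) {
  stopifnot(inherits(pri, "pri_record"))
  if (!pri$surfactant)
    return(list(ok = TRUE, message = "not a surfactant; no micelle concern"))
  if (is.na(pri$critical_micelle_concentration))
    return(list(ok = TRUE,
                message = "surfactant with unknown CMC: verify micelle formation before relying on diafiltration clearance"))
  if (spike_concentration > pri$critical_micelle_concentration) {
    msg <- sprintf(
      "spike %.4g ug/ml exceeds CMC %.4g ug/ml: micelles exceed the membrane cut-off, poor clearance expected",
      spike_concentration, pri$critical_micelle_concentration)
    warning(msg, call. = FALSE)
    return(list(ok = FALSE, message = msg))
  }
  list(ok = TRUE,
       message = sprintf("spike %.4g ug/ml is below CMC %.4g ug/ml",
                         spike_concentration,
                         pri$critical_micelle_concentration))
}
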