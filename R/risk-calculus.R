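# Dose/toxicology arithmetic: PDE derivation, PRI dose per product dose,
# impurity safety factor, and strict comparisons against a daily limit.

#' Permitted daily exposure from a point of departure
#'
#' Derives the PDE as
#' \deqn{PDE = \frac{POD \times BW}{F1 \cdot F2 \cdot F3 \cdot F4 \cdot F5}}
#' where the point of departure (POD) is the NOEL in mg/kg/day, falling back
#' to the LOEL when no NOEL exists. The result is returned in ug/day. When the
#' LOEL is the point of departure, F5 must have been set above 1 (the
#' LOEL-to-NOEL extrapolation factor); refusing F5 = 1 there keeps a silent
#' non-conservative derivation impossible.
#'
#' @param tox A [toxicity_profile()]; `noel` or `loel` must be present.
#' @param ctx A [dose_context()] supplying body weight and modifying factors.
#' @return PDE in ug/day (single numeric).
#' @examples
#' ctx <- dose_context(500, 50, body_weight = 50,
#'                     factors = modifying_factors(f1 = 5, f2 = 10))
#' compute_pde(toxicity_profile(noel = 10), ctx)  # 10*50/(5*10) mg = 10,000 ug
#' @export
compute_pde <- function(tox, ctx) {
  stopifnot(inherits(tox, "toxicity_profile"), inherits(ctx, "dose_context"))
  f <- ctx$factors
  if (!is.na(tox$noel)) {
    pod <- tox$noel
  } else if (!is.na(tox$loel)) {
    if (f$f5 <= 1)
      stop("PDE from LOEL requires modifying factor f5 > 1", call. = FALSE)
    pod <- tox$loel
  } else {
    stop("PDE not derivable: neither NOEL nor LOEL present", call. = FALSE)
  }
  pde_mg_day <- pod * ctx$body_weight / (f$f1 * f$f2 * f$f3 * f$f4 * f$f5)
  pde_mg_day * 1000  # mg/day -> ug/day
}

#' Is a PDE available or derivable?
#'
#' @param tox A [toxicity_profile()].
#' @return `TRUE` when an established PDE exists or one can be derived from
#'   NOEL/LOEL.
#' @export
pde_available <- function(tox) {
  !is.na(tox$established_pde) || !is.na(tox$noel) || !is.na(tox$loel)
}

# Established PDE if present, else derived. ug/day.
effective_pde <- function(tox, ctx) {
  if (!is.na(tox$established_pde)) tox$established_pde
  else compute_pde(tox, ctx)
}

#' Impurity dose contained in one product dose
#'
#' The impurity mass co-administered with one product dose, assuming the
#' impurity-to-protein mass ratio of the supplied concentrations:
#' \deqn{dose = \frac{C_{PRI}}{C_{protein}} \times D_{product}}
#' With the fixed internal units (ug/ml, mg/ml, mg) the result is in ug.
#'
#' @param pri_concentration Impurity concentration, ug/ml (> 0; zero is only
#'   admissible through LOD substitution upstream).
#' @param protein_concentration Protein concentration, mg/ml (> 0).
#' @param product_dose Product dose, mg (> 0).
#' @return Impurity dose in ug per product dose.
#' @examples
#' compute_pri_dose(1, 50, 500)  # 10 ug
#' @export
compute_pri_dose <- function(pri_concentration, protein_concentration,
                             product_dose) {
  if (!is.finite(pri_concentration) || pri_concentration <= 0)
    stop("pri_concentration must be > 0 (substitute the assay LOD for non-detects)",
         call. = FALSE)
  if (!is.finite(protein_concentration) || protein_concentration <= 0)
    stop("protein_concentration must be > 0", call. = FALSE)
  if (!is.finite(product_dose) || product_dose <= 0)
    stop("product_dose must be > 0", call. = FALSE)
  pri_concentration / protein_concentration * product_dose
}

#' Impurity safety factor
#'
#' The ratio of a toxicity dose to the impurity dose in one product dose;
#' the larger the ISF, the lower the safety risk. Both arguments must be on
#' the same basis (the decision engine converts a per-kg LD50 to a per-patient
#' dose via body weight before calling this). The pass decision against a
#' threshold is strict: an ISF exactly equal to the threshold fails.
#'
#' @param toxicity_dose Toxicity reference dose, ug (same basis as
#'   `pri_dose`).
#' @param pri_dose Impurity dose per product dose, ug.
#' @return Dimensionless ISF.
#' @examples
#' compute_isf(1e6, 10)  # 100,000
#' @export
compute_isf <- function(toxicity_dose, pri_dose) {
  if (!is.finite(toxicity_dose) || toxicity_dose <= 0)
    stop("toxicity_dose must be > 0", call. = FALSE)
  if (!is.finite(pri_dose) || pri_dose <= 0)
    stop("pri_dose must be > 0", call. = FALSE)
  toxicity_dose / pri_dose
}

#' Compare an impurity dose against a daily limit
#'
#' Strict comparison of a daily impurity dose against a limit (PDE or TTC):
#' pass only when strictly below the limit; a dose exactly at the limit fails
#' (conservative tie-break used throughout the decision tree).
#'
#' @param pri_dose Impurity dose, ug/day.
#' @param limit Limit, ug/day (> 0).
#' @return A list with `pass` (logical) and `margin` (`limit / pri_dose`; a
#'   margin above 1 means the dose sits below the limit).
#' @examples
#' margin_vs_limit(1.4, 1.5)  # pass, margin ~ 1.07
#' @export
margin_vs_limit <- function(pri_dose, limit) {
  if (!is.finite(limit) || limit <= 0) stop("limit must be > 0", call. = FALSE)
  if (!is.finite(pri_dose) || pri_dose <= 0)
    stop("pri_dose must be > 0 (LOD substitution is the only zero path)",
         call. = FALSE)
  list(pass = pri_dose < limit, margin = limit / pri_dose)
}
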