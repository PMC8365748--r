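# Domain types shared by all modules. Units are fixed per field:
# PRI concentrations in ug/ml, protein concentrations in mg/ml, product dose
# in mg, NOEL/LOEL in mg/kg/day, LD50 in mg/kg, PDE and TTC in ug/day.
# Converters exist only at the I/O boundary (see convert_concentration), so
# all internal arithmetic is unit-consistent by construction.

CHARGE_CLASSES <- c("positive", "negative", "neutral", "zwitterionic", "unknown")
HYDROPHOBICITY_CLASSES <- c("hydrophilic", "moderate", "hydrophobic", "unknown")
USAGE_STAGES <- c("cell_banking", "upstream", "harvest", "downstream_pre_proA",
                  "downstream_pre_CEX", "downstream_post_CEX", "formulation")
EVIDENCE_CODES <- c("metabolite", "GRAS", "approved_excipient",
                    "medium_toxicity", "genotoxic", "carcinogenic", "no_data")
SAFE_EVIDENCE_CODES <- c("metabolite", "GRAS", "approved_excipient")
SEVERE_EVIDENCE_CODES <- c("genotoxic", "carcinogenic")
LD50_ROUTES <- c("iv", "sc", "oral", "other")
TEST_POINTS <- c("proA_pool", "cex_pool", "viral_filtration_pool")

#' Process-related impurity record
#'
#' One low-molecular-weight process-related impurity (LMW PRI): its identity,
#' physicochemical class, the process stage where it is introduced, the
#' concentration at which it is used there, and the toxicity-evidence codes
#' that drive categorization.
#'
#' Evidence codes are a set drawn from
#' `r paste(EVIDENCE_CODES, collapse = ", ")`. The "safe" codes (metabolite,
#' GRAS, approved_excipient) are mutually exclusive with the severe-toxicity
#' codes (genotoxic, carcinogenic) in one record: conflicting literature is a
#' validation error, never a silent worst case. `no_data` must appear alone.
#'
#' @param id Opaque unique identifier (string).
#' @param name Human-readable impurity name.
#' @param usage_stage Stage where the impurity enters the process; one of
#'   `r paste(USAGE_STAGES, collapse = ", ")`.
#' @param usage_concentration Concentration at the introduction point, ug/ml.
#' @param evidence_codes Character vector of toxicity-evidence codes.
#' @param molecular_weight Optional molecular weight, g/mol (> 0).
#' @param charge_class,hydrophobicity_class Physicochemical class enums.
#' @param surfactant Logical; is the impurity a surfactant?
#' @param critical_micelle_concentration Optional CMC, ug/ml; relevant to the
#'   diafiltration micelle guard for surfactants.
#' @return An object of class `pri_record`.
#' @seealso [validate_inventory()], [categorize_pri()]
#' @examples
#' pri_record("P1", "methionine sulfoximine", "cell_banking", 25,
#'            evidence_codes = "medium_toxicity", molecular_weight = 180.2)
#' @export
pri_record <- function(id, name, usage_stage, usage_concentration,
                       evidence_codes, molecular_weight = NA_real_,
                       charge_class = "unknown",
                       hydrophobicity_class = "unknown",
                       surfactant = FALSE,
                       critical_micelle_concentration = NA_real_) {
  x <- structure(
    list(id = as.character(id), name = as.character(name),
         usage_stage = as.character(usage_stage),
         usage_concentration = as.numeric(usage_concentration),
         evidence_codes = sort(unique(as.character(evidence_codes))),
         molecular_weight = as.numeric(molecular_weight),
         charge_class = as.character(charge_class),
         hydrophobicity_class = as.character(hydrophobicity_class),
         surfactant = isTRUE(surfactant),
         critical_micelle_concentration =
           as.numeric(critical_micelle_concentration)),
    class = "pri_record")
  stop_on_invalid(validate_pri_record(x), x$id)
  x
}

# Returns character vector of problems (empty when valid). Total: never errors.
validate_pri_record <- function(x) {
  p <- character()
  if (!is.character(x$id) || length(x$id) != 1 || is.na(x$id) || !nzchar(x$id))
    p <- c(p, "id must be a non-empty string")
  if (length(x$name) != 1 || is.na(x$name) || !nzchar(x$name))
    p <- c(p, "name must be a non-empty string")
  if (length(x$usage_stage) != 1 || !x$usage_stage %in% USAGE_STAGES)
    p <- c(p, sprintf("usage_stage must be one of: %s",
                      paste(USAGE_STAGES, collapse = ", ")))
  if (length(x$usage_concentration) != 1 || is.na(x$usage_concentration) ||
      x$usage_concentration < 0)
    p <- c(p, "usage_concentration must be >= 0 (ug/ml)")
  if (!is.na(x$molecular_weight) && x$molecular_weight <= 0)
    p <- c(p, "molecular_weight must be > 0 when present (g/mol)")
  if (!x$charge_class %in% CHARGE_CLASSES)
    p <- c(p, "charge_class not recognised")
  if (!x$hydrophobicity_class %in% HYDROPHOBICITY_CLASSES)
    p <- c(p, "hydrophobicity_class not recognised")
  if (!is.na(x$critical_micelle_concentration) &&
      x$critical_micelle_concentration <= 0)
    p <- c(p, "critical_micelle_concentration must be > 0 when present (ug/ml)")
  p <- c(p, validate_evidence_codes(x$evidence_codes))
  p
}

validate_evidence_codes <- function(codes) {
  p <- character()
  if (length(codes) == 0) {
    return("evidence_codes must contain at least one code (use 'no_data')")
  }
  unknown <- setdiff(codes, EVIDENCE_CODES)
  if (length(unknown) > 0)
    p <- c(p, sprintf("unknown evidence codes: %s",
                      paste(unknown, collapse = ", ")))
  safe <- intersect(codes, SAFE_EVIDENCE_CODES)
  severe <- intersect(codes, SEVERE_EVIDENCE_CODES)
  if (length(safe) > 0 && length(severe) > 0)
    p <- c(p, sprintf("contradictory evidence_codes: {%s} conflict with {%s}",
                      paste(safe, collapse = ", "),
                      paste(severe, collapse = ", ")))
  if ("no_data" %in% codes && length(codes) > 1)
    p <- c(p, "evidence code 'no_data' cannot be combined with other codes")
  p
}

stop_on_invalid <- function(problems, label) {
  if (length(problems) > 0)
    stop(sprintf("invalid %s: %s", label, paste(problems, collapse = "; ")),
         call. = FALSE)
  invisible(NULL)
}

#' @export
print.pri_record <- function(x, ...) {
  cat(sprintf("<pri_record> %s (%s)\n", x$id, x$name))
  cat(sprintf("  stage: %s at %.4g ug/ml; evidence: %s\n",
              x$usage_stage, x$usage_concentration,
              paste(x$evidence_codes, collapse = ";")))
  invisible(x)
}

#' Toxicity profile for one impurity
#'
#' Toxicology reference data used to derive a permitted daily exposure (PDE)
#' or an impurity safety factor (ISF). The PDE is derived preferentially from
#' NOEL (no-observed-effect level), falling back to LOEL; the ISF path uses
#' the median lethal dose LD50.
#'
#' @param noel,loel Optional points of departure, mg/kg/day.
#' @param ld50 Optional median lethal dose, mg/kg; `ld50_route` names the
#'   administration route.
#' @param established_pde Optional regulatory PDE, ug/day (takes precedence
#'   over derivation from NOEL/LOEL when present).
#' @param severe_toxicity Logical genotoxicity/carcinogenicity flag; must
#'   agree with the matching record's evidence codes.
#' @return An object of class `toxicity_profile`.
#' @examples
#' toxicity_profile(noel = 5)                 # PDE derivable
#' toxicity_profile(ld50 = 250, ld50_route = "iv")  # ISF path only
#' @export
toxicity_profile <- function(noel = NA_real_, loel = NA_real_,
                             ld50 = NA_real_, ld50_route = "other",
                             established_pde = NA_real_,
                             severe_toxicity = FALSE) {
  x <- structure(
    list(noel = as.numeric(noel), loel = as.numeric(loel),
         ld50 = as.numeric(ld50), ld50_route = as.character(ld50_route),
         established_pde = as.numeric(established_pde),
         severe_toxicity = isTRUE(severe_toxicity)),
    class = "toxicity_profile")
  p <- character()
  for (f in c("noel", "loel", "ld50", "established_pde")) {
    v <- x[[f]]
    if (!is.na(v) && v < 0) p <- c(p, sprintf("%s must be >= 0", f))
  }
  if (!x$ld50_route %in% LD50_ROUTES)
    p <- c(p, sprintf("ld50_route must be one of: %s",
                      paste(LD50_ROUTES, collapse = ", ")))
  stop_on_invalid(p, "toxicity_profile")
  x
}

#' Modifying factors for PDE derivation
#'
#' The five multiplicative safety factors dividing the point of departure in
#' the PDE formula: F1 interspecies extrapolation, F2 inter-individual
#' variability (fixed convention of 10), F3 study-duration, F4 severe-toxicity,
#' F5 LOEL-to-NOEL extrapolation. All must be >= 1. F1, F3, F4 and F5 default
#' to 1 and must be set deliberately: the package does not invent
#' toxicological judgment.
#'
#' @param f1,f2,f3,f4,f5 Dimensionless multipliers, each >= 1.
#' @return An object of class `modifying_factors`.
#' @export
modifying_factors <- function(f1 = 1, f2 = 10, f3 = 1, f4 = 1, f5 = 1) {
  x <- structure(list(f1 = as.numeric(f1), f2 = as.numeric(f2),
                      f3 = as.numeric(f3), f4 = as.numeric(f4),
                      f5 = as.numeric(f5)),
                 class = "modifying_factors")
  bad <- vapply(x, function(v) length(v) != 1 || is.na(v) || v < 1, logical(1))
  if (any(bad))
    stop("modifying factors must all be single values >= 1: ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  x
}

#' Dose context for a product
#'
#' The product-side quantities every dose comparison needs: the maximum
#' product dose, protein concentrations (overall and optionally per process
#' stage, used as the worst-case copurification basis), patient body weight,
#' PDE modifying factors, the threshold of toxicological concern (TTC) and
#' the ISF acceptance threshold.
#'
#' @param product_dose Maximum product dose, mg (> 0).
#' @param product_protein_concentration Protein concentration used as default
#'   basis for the impurity-to-protein ratio, mg/ml (> 0).
#' @param body_weight Patient body weight, kg; default 50 kg, the conventional
#'   conservative adult figure in impurity guidelines.
#' @param factors A [modifying_factors()] object.
#' @param ttc Threshold of toxicological concern, ug/day; default 1.5 ug/day
#'   (lifelong exposure).
#' @param isf_threshold ISF acceptance threshold (dimensionless, > 0). No
#'   default: it must be set from compound data before the ISF path can pass.
#' @param stage_protein_concentrations Optional named numeric vector (mg/ml)
#'   keyed by usage stage, giving the protein concentration at each
#'   introduction point; stages absent fall back to
#'   `product_protein_concentration`.
#' @return An object of class `dose_context`.
#' @examples
#' dose_context(product_dose = 500, product_protein_concentration = 50)
#' @export
dose_context <- function(product_dose, product_protein_concentration,
                         body_weight = 50, factors = modifying_factors(),
                         ttc = 1.5, isf_threshold = NA_real_,
                         stage_protein_concentrations = NULL) {
  x <- structure(
    list(product_dose = as.numeric(product_dose),
         product_protein_concentration =
           as.numeric(product_protein_concentration),
         body_weight = as.numeric(body_weight),
         factors = factors, ttc = as.numeric(ttc),
         isf_threshold = as.numeric(isf_threshold),
         stage_protein_concentrations = stage_protein_concentrations),
    class = "dose_context")
  p <- character()
  if (is.na(x$product_dose) || x$product_dose <= 0)
    p <- c(p, "product_dose must be > 0 (mg)")
  if (is.na(x$product_protein_concentration) ||
      x$product_protein_concentration <= 0)
    p <- c(p, "product_protein_concentration must be > 0 (mg/ml)")
  if (is.na(x$body_weight) || x$body_weight <= 0)
    p <- c(p, "body_weight must be > 0 (kg)")
  if (is.na(x$ttc) || x$ttc <= 0) p <- c(p, "ttc must be > 0 (ug/day)")
  if (!is.na(x$isf_threshold) && x$isf_threshold <= 0)
    p <- c(p, "isf_threshold must be > 0 when set")
  if (!inherits(x$factors, "modifying_factors"))
    p <- c(p, "factors must be a modifying_factors object")
  if (!is.null(x$stage_protein_concentrations)) {
    spc <- x$stage_protein_concentrations
    if (is.null(names(spc)) || !all(names(spc) %in% USAGE_STAGES) ||
        any(!is.finite(spc)) || any(spc <= 0))
      p <- c(p, "stage_protein_concentrations must be positive and named by usage stage")
  }
  stop_on_invalid(p, "dose_context")
  x
}

# Protein concentration (mg/ml) at a PRI's introduction point.
stage_protein <- function(ctx, stage) {
  spc <- ctx$stage_protein_concentrations
  if (!is.null(spc) && stage %in% names(spc)) unname(spc[[stage]])
  else ctx$product_protein_concentration
}

#' Paired impurity/protein measurement across one unit operation
#'
#' Concentrations of an impurity and of product protein immediately before
#' and after a purification step, as used by the clearance-fold formula.
#' Non-detects must be substituted with the assay limit of detection (LOD)
#' *before* construction, with `final_is_lod = TRUE`; zero and negative
#' concentrations are rejected so that every fold is finite.
#'
#' @param step_name Name of the unit operation (non-empty).
#' @param initial_pri,final_pri Impurity concentration before/after, ug/ml.
#' @param initial_protein,final_protein Protein concentration before/after,
#'   mg/ml.
#' @param final_is_lod `TRUE` when `final_pri` is an LOD substitute for a
#'   "not detectable" result, making the fold a lower bound.
#' @return An object of class `clearance_measurement`.
#' @seealso [clearance_fold()]
#' @export
clearance_measurement <- function(step_name, initial_pri, initial_protein,
                                  final_pri, final_protein,
                                  final_is_lod = FALSE) {
  x <- structure(
    list(step_name = as.character(step_name),
         initial_pri = as.numeric(initial_pri),
         initial_protein = as.numeric(initial_protein),
         final_pri = as.numeric(final_pri),
         final_protein = as.numeric(final_protein),
         final_is_lod = isTRUE(final_is_lod)),
    class = "clearance_measurement")
  p <- character()
  if (length(x$step_name) != 1 || is.na(x$step_name) || !nzchar(x$step_name))
    p <- c(p, "step_name must be non-empty")
  for (f in c("initial_pri", "initial_protein", "final_pri", "final_protein"))
    if (length(x[[f]]) != 1 || !is.finite(x[[f]]) || x[[f]] <= 0)
      p <- c(p, sprintf("%s must be > 0 (substitute the assay LOD before construction)", f))
  stop_on_invalid(p, "clearance_measurement")
  x
}

#' Diafiltration concentration-vs-diavolume profile
#'
#' An impurity washout series during constant-retentate-volume diafiltration:
#' strictly increasing diavolumes starting at N = 0, where the concentration
#' must equal the stated initial concentration `c0` within a small relative
#' tolerance. Points flagged `is_lod` sit at the assay detection limit and are
#' excluded from sieving fits.
#'
#' @param c0 Initial impurity concentration at N = 0, ug/ml (> 0).
#' @param diavolume Numeric vector of diavolumes, strictly increasing from 0.
#' @param concentration Numeric vector of concentrations, ug/ml (> 0).
#' @param is_lod Logical vector (recycled) flagging at-LOD points.
#' @return An object of class `diafiltration_profile`.
#' @seealso [fit_sieving()], [generate_diafiltration_profile()]
#' @export
diafiltration_profile <- function(c0, diavolume, concentration,
                                  is_lod = FALSE) {
  is_lod <- rep_len(as.logical(is_lod), length(diavolume))
  x <- structure(
    list(c0 = as.numeric(c0),
         points = data.frame(diavolume = as.numeric(diavolume),
                             concentration = as.numeric(concentration),
                             is_lod = is_lod)),
    class = "diafiltration_profile")
  p <- character()
  if (length(x$c0) != 1 || !is.finite(x$c0) || x$c0 <= 0)
    p <- c(p, "c0 must be > 0 (ug/ml)")
  pts <- x$points
  if (nrow(pts) < 1) {
    p <- c(p, "profile needs at least one point")
  } else {
    if (any(!is.finite(pts$diavolume)) || any(pts$diavolume < 0))
      p <- c(p, "diavolumes must be finite and >= 0")
    if (any(diff(pts$diavolume) <= 0))
      p <- c(p, "diavolumes must be strictly increasing")
    if (any(!is.finite(pts$concentration)) || any(pts$concentration <= 0))
      p <- c(p, "concentrations must be > 0")
    if (pts$diavolume[1] != 0)
      p <- c(p, "first point must be at diavolume 0")
    else if (is.finite(pts$concentration[1]) && is.finite(x$c0) && x$c0 > 0 &&
             abs(pts$concentration[1] - x$c0) > 0.05 * x$c0)
      p <- c(p, "concentration at diavolume 0 must match c0 within 5%")
  }
  stop_on_invalid(p, "diafiltration_profile")
  x
}

#' @export
print.diafiltration_profile <- function(x, ...) {
  cat(sprintf("<diafiltration_profile> c0 = %.4g ug/ml, %d points over %g DV\n",
              x$c0, nrow(x$points), max(x$points$diavolume)))
  invisible(x)
}

#' Validate an impurity inventory
#'
#' Runs every record through the field and evidence-consistency checks and
#' reports duplicates. Validation is total: a malformed record yields a
#' diagnostic row, never an uncaught error.
#'
#' @param records A list of [pri_record()] objects, or raw lists with the same
#'   fields (as produced by the readers before construction).
#' @return A data.frame with one row per record: `id`, `valid` (logical) and
#'   `message` (empty when valid).
#' @examples
#' inv <- list(pri_record("P1", "sodium chloride", "downstream_pre_CEX", 9000,
#'                        "GRAS"))
#' validate_inventory(inv)
#' @export
validate_inventory <- function(records) {
  if (length(records) == 0)
    return(data.frame(id = character(), valid = logical(),
                      message = character(), stringsAsFactors = FALSE))
  ids <- vapply(records, function(r) {
    id <- tryCatch(as.character(r$id), error = function(e) NA_character_)
    if (length(id) != 1) NA_character_ else id
  }, character(1))
  dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
  msgs <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    probs <- tryCatch({
      if (!inherits(r, "pri_record")) r <- structure(r, class = "pri_record")
      validate_pri_record(r)
    }, error = function(e) sprintf("malformed record: %s", conditionMessage(e)))
    if (dup[i] && !is.na(ids[i]))
      probs <- c(probs, sprintf("duplicate id '%s'", ids[i]))
    paste(probs, collapse = "; ")
  }, character(1))
  data.frame(id = ids, valid = !nzchar(msgs), message = msgs,
             stringsAsFactors = FALSE)
}

#' Convert a concentration to the package's internal units
#'
#' I/O-boundary unit converter. Impurity concentrations are held in ug/ml
#' internally and protein concentrations in mg/ml; external tables in other
#' units are normalised once on the way in.
#'
#' @param value Numeric vector of concentrations.
#' @param from Unit of `value`: one of `"ug/ml"`, `"mg/ml"`, `"g/l"`,
#'   `"ng/ml"`, `"mg/l"`.
#' @param to Target unit, same choices; default `"ug/ml"`.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_concentration(1.5, from = "mg/ml")  # 1500 ug/ml
#' @export
convert_concentration <- function(value, from, to = "ug/ml") {
  to_ug_ml <- c("ug/ml" = 1, "mg/ml" = 1000, "g/l" = 1000,
                "ng/ml" = 1e-3, "mg/l" = 1)
  if (!from %in% names(to_ug_ml) || !to %in% names(to_ug_ml))
    stop("unknown concentration unit; supported: ",
         paste(names(to_ug_ml), collapse = ", "), call. = FALSE)
  value * to_ug_ml[[from]] / to_ug_ml[[to]]
}
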