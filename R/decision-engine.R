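# Two-step decision tree for LMW PRI risk assessment and the workflow
# orchestration that turns an inventory into dispositions and a testing plan.
#
# Step 1 assigns categories from toxicity evidence:
#   A  known-to-be-safe (metabolites, GRAS substances, approved excipients)
#   B  medium toxicity; split B2 (PDE established or derivable) vs B1 (ISF)
#   C  severe toxicity (genotoxic/carcinogenic); no-data impurities are
#      assessed on the C branch as the most conservative assumption
# Step 2a assesses the worst case: the impurity is assumed copurified with
# the product (no clearance credit), carrying its impurity-to-protein mass
# ratio at the introduction point unchanged into drug substance.
# Step 2b re-assesses with an in-process measurement (or its assay LOD).

CATEGORIES <- c("A", "B1", "B2", "C")
DISPOSITIONS <- c("no_safety_risk", "testing_required", "action_required")

#' Categorize one impurity (Step 1)
#'
#' @param pri A validated [pri_record()].
#' @param tox The matching [toxicity_profile()] (may be an empty profile).
#' @return One of `"A"`, `"B1"`, `"B2"`, `"C"`.
#' @details Severe evidence (genotoxic/carcinogenic) always wins over mixed
#'   medium-toxicity evidence; `no_data` maps to the C branch. A record is
#'   Category A only when every code it carries is in the safe set.
#' @examples
#' categorize_pri(pri_record("P1", "salt", "upstream", 100, "GRAS"),
#'                toxicity_profile())
#' @export
categorize_pri <- function(pri, tox) {
  stopifnot(inherits(pri, "pri_record"), inherits(tox, "toxicity_profile"))
  codes <- pri$evidence_codes
  if (any(codes %in% SEVERE_EVIDENCE_CODES)) return("C")
  if ("no_data" %in% codes) return("C")
  if (all(codes %in% SAFE_EVIDENCE_CODES)) return("A")
  if (pde_available(tox)) "B2" else "B1"
}

new_outcome <- function(pri_id, category, stage, disposition, metrics,
                        rationale) {
  structure(list(pri_id = pri_id, category = category, stage = stage,
                 disposition = disposition, metrics = metrics,
                 rationale = rationale),
            class = "assessment_outcome")
}

#' @export
print.assessment_outcome <- function(x, ...) {
  cat(sprintf("<assessment_outcome> %s: category %s, %s -> %s\n",
              x$pri_id, x$category, x$stage, x$disposition))
  cat(" ", x$rationale, "\n")
  invisible(x)
}

# Shared Step 2 limit comparison for a computed dose. Returns outcome fields.
assess_against_limits <- function(pri, tox, ctx, category, dose_ug, stage,
                                  bound_based = FALSE) {
  note <- if (bound_based) " (dose is an upper bound at the assay LOD)" else ""
  if (category == "B2") {
    pde <- effective_pde(tox, ctx)
    cmp <- margin_vs_limit(dose_ug, pde)
    metrics <- list(pde = pde, pri_dose = dose_ug, margin = cmp$margin,
                    limit = pde, limit_type = "PDE")
    pass <- cmp$pass
    rationale <- sprintf(
      "Category B2: dose %.4g ug/day vs PDE %.4g ug/day (margin %.3g)%s",
      dose_ug, pde, cmp$margin, note)
  } else if (category == "B1" && !is.na(tox$ld50) &&
             !is.na(ctx$isf_threshold)) {
    tox_dose_ug <- tox$ld50 * ctx$body_weight * 1000  # mg/kg -> ug per patient
    isf <- compute_isf(tox_dose_ug, dose_ug)
    pass <- isf > ctx$isf_threshold  # strict
    metrics <- list(isf = isf, pri_dose = dose_ug,
                    limit = ctx$isf_threshold, limit_type = "ISF threshold")
    rationale <- sprintf(
      "Category B1: ISF %.4g vs threshold %.4g (LD50 basis per %g kg patient)%s",
      isf, ctx$isf_threshold, ctx$body_weight, note)
  } else {
    # C branch; also the escalation path for B1 lacking LD50 or a threshold
    cmp <- margin_vs_limit(dose_ug, ctx$ttc)
    escalated <- category == "B1"
    metrics <- list(pri_dose = dose_ug, margin = cmp$margin,
                    limit = ctx$ttc, limit_type = "TTC")
    pass <- cmp$pass
    rationale <- sprintf(
      "%s: dose %.4g ug/day vs TTC %.4g ug/day (margin %.3g)%s%s",
      if (escalated) "Category B1 escalated to TTC (no LD50 or no ISF threshold)"
      else "Category C branch",
      dose_ug, ctx$ttc, cmp$margin, note, "")
  }
  list(pass = pass, metrics = metrics, rationale = rationale)
}

#' Worst-case risk assessment (Step 2a)
#'
#' Computes the worst-case impurity dose per product dose assuming pure
#' copurification: the impurity-to-protein mass ratio at the introduction
#' point is carried unchanged into drug substance, so no clearance credit is
#' taken. The dose is compared against the PDE (Category B2), the ISF
#' threshold (B1, requiring an LD50 and a configured threshold; otherwise the
#' impurity is escalated to the TTC branch), or the TTC (Category C and
#' no-data impurities).
#'
#' @param pri,tox,ctx The impurity record, toxicity profile and dose context.
#' @param category Optional pre-computed category; defaults to
#'   [categorize_pri()].
#' @return An `assessment_outcome` with disposition `no_safety_risk` or
#'   `testing_required`.
#' @export
step2a_worst_case <- function(pri, tox, ctx, category = NULL) {
  stopifnot(inherits(ctx, "dose_context"))
  if (is.null(category)) category <- categorize_pri(pri, tox)
  if (category == "A")
    stop("Category A impurities are eliminated at Step 1, not assessed",
         call. = FALSE)
  protein <- stage_protein(ctx, pri$usage_stage)
  dose <- compute_pri_dose(pri$usage_concentration, protein, ctx$product_dose)
  a <- assess_against_limits(pri, tox, ctx, category, dose, "step2a")
  new_outcome(pri$id, category, "step2a",
              if (a$pass) "no_safety_risk" else "testing_required",
              c(a$metrics, list(worst_case_protein = protein)),
              paste0("Worst case (copurification, no clearance credit). ",
                     a$rationale))
}

#' Risk assessment with in-process testing results (Step 2b)
#'
#' Re-runs the Step 2a limit comparison using the measured impurity
#' concentration at the test point — or the assay LOD when the result was
#' "not detectable" — together with the protein concentration of the tested
#' pool. A pass obtained at the LOD is annotated as bound-based. A failure
#' means either the process or the assay must be improved:
#' disposition `action_required`.
#'
#' @param pri,tox,ctx As in [step2a_worst_case()].
#' @param measured_concentration Measured (or LOD) impurity concentration at
#'   the test point, ug/ml.
#' @param measurement_protein Protein concentration of the tested pool, mg/ml.
#' @param is_lod `TRUE` when `measured_concentration` is the assay LOD.
#' @param category Optional pre-computed category.
#' @return An `assessment_outcome` with disposition `no_safety_risk` or
#'   `action_required`.
#' @export
step2b_with_results <- function(pri, tox, ctx, measured_concentration,
                                measurement_protein, is_lod = FALSE,
                                category = NULL) {
  if (is.null(category)) category <- categorize_pri(pri, tox)
  if (category == "A")
    stop("Category A impurities are eliminated at Step 1, not assessed",
         call. = FALSE)
  dose <- compute_pri_dose(measured_concentration, measurement_protein,
                           ctx$product_dose)
  a <- assess_against_limits(pri, tox, ctx, category, dose, "step2b",
                             bound_based = isTRUE(is_lod))
  new_outcome(pri$id, category, "step2b",
              if (a$pass) "no_safety_risk" else "action_required",
              c(a$metrics, list(measured_concentration = measured_concentration,
                                measurement_is_lod = isTRUE(is_lod))),
              paste0("In-process result. ", a$rationale))
}

#' Default in-process test point for an impurity
#'
#' Leverages downstream clearance: impurities introduced at or before the
#' Protein A capture step are tested in the Protein A pool, impurities
#' introduced downstream but before cation exchange in the CEX pool, and
#' later ones in the viral filtration pool. `mode = "platform"` instead puts
#' every test at the viral filtration pool (the conservative platform
#' default that captures the whole downstream clearance and avoids the
#' high-protein UFDF pool).
#'
#' @param usage_stage The impurity's introduction stage.
#' @param mode `"staged"` (default) or `"platform"`.
#' @return One of `"proA_pool"`, `"cex_pool"`, `"viral_filtration_pool"`.
#' @export
default_test_point <- function(usage_stage, mode = c("staged", "platform")) {
  mode <- match.arg(mode)
  if (mode == "platform") return("viral_filtration_pool")
  stopifnot(usage_stage %in% USAGE_STAGES)
  switch(usage_stage,
         cell_banking = , upstream = , harvest = ,
         downstream_pre_proA = "proA_pool",
         downstream_pre_CEX = "cex_pool",
         "viral_filtration_pool")
}

#' Run the full risk-management workflow over an inventory
#'
#' Orchestrates Step 1 categorization for every impurity, eliminates
#' Category A, runs the Step 2a worst-case assessment on the remainder, and
#' where measurements are supplied runs Step 2b on the impurities whose
#' Step 2a disposition was `testing_required`. Output ordering is
#' deterministic (by impurity id).
#'
#' @param inventory List of validated [pri_record()]s.
#' @param tox_map Named list of [toxicity_profile()]s keyed by impurity id;
#'   impurities without an entry are assessed with an empty profile.
#' @param ctx A [dose_context()].
#' @param measurements Optional data.frame with columns `pri_id`,
#'   `test_point`, `concentration` (ug/ml), `is_lod`, `protein_concentration`
#'   (mg/ml). Partial sets are allowed; measurements for unknown ids are
#'   reported, not applied.
#' @param test_point_mode Passed to [default_test_point()].
#' @return A `workflow_report`: list with `outcomes` (list of
#'   `assessment_outcome`s), `table` (tidy per-impurity data.frame),
#'   `testing_plan` (data.frame `pri_id`, `test_point`, `assay_lod`),
#'   `summary` (counts by category and disposition), `unmatched_measurements`
#'   and `config` snapshot.
#' @examples
#' fx <- generate_example_inventory(seed = 1)
#' rep <- run_workflow(fx$inventory, fx$tox, fx$context, fx$measurements)
#' rep$summary$by_disposition
#' @export
run_workflow <- function(inventory, tox_map, ctx, measurements = NULL,
                         test_point_mode = c("staged", "platform")) {
  test_point_mode <- match.arg(test_point_mode)
  vr <- validate_inventory(inventory)
  if (any(!vr$valid))
    stop("inventory failed validation: ",
         paste(sprintf("%s (%s)", vr$id[!vr$valid], vr$message[!vr$valid]),
               collapse = "; "), call. = FALSE)
  ids <- vapply(inventory, `[[`, character(1), "id")
  ord <- order(ids)
  inventory <- inventory[ord]
  ids <- ids[ord]

  empty_tox <- toxicity_profile()
  unmatched <- character()
  if (!is.null(measurements)) {
    need <- c("pri_id", "concentration", "is_lod", "protein_concentration")
    miss <- setdiff(need, names(measurements))
    if (length(miss) > 0)
      stop("measurements missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    unmatched <- setdiff(measurements$pri_id, ids)
  }

  outcomes <- vector("list", length(inventory))
  plan <- list()
  for (i in seq_along(inventory)) {
    pri <- inventory[[i]]
    tox <- tox_map[[pri$id]] %||% empty_tox
    cat_i <- categorize_pri(pri, tox)
    if (cat_i == "A") {
      outcomes[[i]] <- new_outcome(
        pri$id, "A", "step1", "no_safety_risk", list(),
        sprintf("Known-to-be-safe evidence (%s); eliminated at Step 1.",
                paste(pri$evidence_codes, collapse = ";")))
      next
    }
    out <- step2a_worst_case(pri, tox, ctx, category = cat_i)
    if (out$disposition == "testing_required") {
      m <- NULL
      if (!is.null(measurements)) {
        hit <- measurements[measurements$pri_id == pri$id, , drop = FALSE]
        if (nrow(hit) > 0) m <- hit[1, ]
      }
      tp <- if (!is.null(m) && "test_point" %in% names(m) &&
                !is.na(m$test_point)) as.character(m$test_point)
            else default_test_point(pri$usage_stage, test_point_mode)
      plan[[length(plan) + 1]] <- data.frame(
        pri_id = pri$id, test_point = tp,
        assay_lod = if (!is.null(m) && isTRUE(as.logical(m$is_lod)))
          as.numeric(m$concentration) else NA_real_,
        stringsAsFactors = FALSE)
      if (!is.null(m)) {
        out <- step2b_with_results(pri, tox, ctx,
                                   measured_concentration = as.numeric(m$concentration),
                                   measurement_protein = as.numeric(m$protein_concentration),
                                   is_lod = isTRUE(as.logical(m$is_lod)),
                                   category = cat_i)
      }
    }
    outcomes[[i]] <- out
  }

  tab <- do.call(rbind, lapply(outcomes, function(o) {
    data.frame(pri_id = o$pri_id, category = o$category, stage = o$stage,
               disposition = o$disposition,
               pri_dose = o$metrics$pri_dose %||% NA_real_,
               limit = o$metrics$limit %||% NA_real_,
               limit_type = o$metrics$limit_type %||% NA_character_,
               margin = o$metrics$margin %||% NA_real_,
               isf = o$metrics$isf %||% NA_real_,
               rationale = o$rationale, stringsAsFactors = FALSE)
  }))
  if (is.null(tab))
    tab <- data.frame(pri_id = character(), category = character(),
                      stage = character(), disposition = character(),
                      pri_dose = numeric(), limit = numeric(),
                      limit_type = character(), margin = numeric(),
                      isf = numeric(), rationale = character(),
                      stringsAsFactors = FALSE)
  plan <- if (length(plan) > 0) do.call(rbind, plan)
          else data.frame(pri_id = character(), test_point = character(),
                          assay_lod = numeric(), stringsAsFactors = FALSE)

  summary <- list(
    n = length(inventory),
    by_category = table(factor(tab$category, levels = CATEGORIES)),
    by_disposition = table(factor(tab$disposition, levels = DISPOSITIONS)))

  structure(list(outcomes = outcomes, table = tab, testing_plan = plan,
                 summary = summary, unmatched_measurements = unmatched,
                 config = list(product_dose = ctx$product_dose,
                               product_protein_concentration =
                                 ctx$product_protein_concentration,
                               body_weight = ctx$body_weight,
                               factors = unclass(ctx$factors),
                               ttc = ctx$ttc,
                               isf_threshold = ctx$isf_threshold,
                               test_point_mode = test_point_mode)),
            class = "workflow_report")
}

#' @export
print.workflow_report <- function(x, ...) {
  cat(sprintf("<workflow_report> %d impurities\n", x$summary$n))
  cat("  categories:  ",
      paste(sprintf("%s=%d", names(x$summary$by_category),
                    as.integer(x$summary$by_category)), collapse = "  "), "\n")
  cat("  dispositions:",
      paste(sprintf("%s=%d", names(x$summary$by_disposition),
                    as.integer(x$summary$by_disposition)), collapse = "  "), "\n")
  if (nrow(x$testing_plan) > 0) {
    cat(sprintf("  testing plan: %d entries (%s)\n", nrow(x$testing_plan),
                paste(x$testing_plan$pri_id, collapse = ", ")))
  }
  if (length(x$unmatched_measurements) > 0)
    cat("  unmatched measurement ids:",
        paste(x$unmatched_measurements, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
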