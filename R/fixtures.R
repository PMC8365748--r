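# Synthetic fixtures and packaged reference tables.
#
# The example inventory emulates the shape of a realistic early-phase mAb
# impurity assessment: a large majority of known-to-be-safe nutrients,
# buffers and excipients, a handful of medium-toxicity impurities with
# derivable PDEs, and in-process LOD results for the few that fail the
# worst-case screen. All generators are seed-deterministic.

# Run code under a local RNG state so generators never disturb the caller's.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Reference sieving coefficients for common impurities
#'
#' Sieving coefficients determined in published diafiltration spiking
#' studies on a 30 kDa cut-off membrane at 100 mg/ml protein: copper(II)
#' 1.09 (slightly above 1 from electrostatic repulsion by the positively
#' charged antibody), methionine sulfoximine 1.02 (near-ideal washout),
#' caprolactam 0.6 and tropolone ~0.7 (hydrophobic retention), EDTA 0.81
#' (electrostatic attraction; chosen within the reported 0.58-0.83 range as
#' the value consistent with the reported ~5.7 DV for 100-fold clearance),
#' and poloxamer 188 (Pluronic F68) 0.11 (surfactant, poorly transmitted).
#' Tropolone is carried under two names because the two reported figures for
#' it disagree: `tropolone_fit` is the reported fitted coefficient (0.7),
#' `tropolone_dv` the value implied by the reported ~8.2 DV for 100-fold
#' clearance (`log(100)/8.2`); neither reading is privileged.
#'
#' @return Named numeric vector of sieving coefficients.
#' @examples
#' sieving_reference()[["copper"]]
#' @export
sieving_reference <- function() {
  c(copper = 1.09, msx = 1.02, edta = 0.81, tropolone_fit = 0.7,
    tropolone_dv = log(100) / 8.2, caprolactam = 0.6, pluronic_f68 = 0.11)
}

#' Generate a diafiltration washout profile
#'
#' Forward-simulates `C(N) = c0 * exp(-N * s)` at integer diavolumes
#' 0..`n_points`, optionally multiplied by lognormal measurement noise
#' (`exp(rnorm(0, noise_sigma))`). The N = 0 point is the known spike
#' concentration and is never noised, so the profile invariant C(0) = c0
#' holds by construction. With `noise_sigma = 0` the points are exact model
#' values.
#'
#' @param c0 Initial concentration, ug/ml.
#' @param s True sieving coefficient.
#' @param n_points Last integer diavolume (default 6, a typical process).
#' @param noise_sigma Lognormal sigma of multiplicative noise (default 0).
#' @param seed RNG seed used when `noise_sigma > 0`.
#' @return A [diafiltration_profile()].
#' @examples
#' prof <- generate_diafiltration_profile(100, s = 1.02)
#' fit_sieving(prof)$s
#' @export
generate_diafiltration_profile <- function(c0, s, n_points = 6,
                                           noise_sigma = 0, seed = 1) {
  stopifnot(n_points >= 1, noise_sigma >= 0)
  n <- 0:n_points
  conc <- predict_concentration(c0, n, s)
  if (noise_sigma > 0) {
    noise <- with_local_seed(seed,
                             exp(stats::rnorm(length(n), 0, noise_sigma)))
    noise[1] <- 1
    conc <- conc * noise
  }
  diafiltration_profile(c0 = c0, diavolume = n, concentration = conc)
}

#' Specification for the synthetic example inventory
#'
#' Composition and dose parameters of the synthetic worked-example inventory
#' (the counts are data, not constants baked into the decision engine). The
#' defaults reproduce the composition of a published worked example: 105
#' impurities of which 96 are known-to-be-safe, 9 are Category B2 with
#' derivable PDEs, 6 of those pass the worst-case screen and 3 require
#' in-process testing and pass at the assay LOD.
#'
#' Doses of the B2 impurities are placed a `separation` factor (default 4)
#' away from their PDE on either side, so pass/fail is robust to numerical
#' noise.
#'
#' @param n_safe Number of Category A impurities.
#' @param n_b2_pass,n_b2_fail Category B2 impurities passing/failing the
#'   worst-case screen.
#' @param n_c Category C impurities (severe toxicity); default 0 as in the
#'   worked example.
#' @param separation Fold separation of each B2 dose from its PDE (> 1).
#' @param product_dose,product_protein_concentration,body_weight,ttc Dose
#'   context values (mg, mg/ml, kg, ug/day).
#' @param vf_pool_protein Protein concentration of the viral filtration pool
#'   where flagged impurities are tested, mg/ml.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_safe = 96, n_b2_pass = 6, n_b2_fail = 3, n_c = 0,
                         separation = 4, product_dose = 500,
                         product_protein_concentration = 50,
                         body_weight = 50, ttc = 1.5,
                         vf_pool_protein = 10) {
  x <- structure(list(n_safe = as.integer(n_safe),
                      n_b2_pass = as.integer(n_b2_pass),
                      n_b2_fail = as.integer(n_b2_fail),
                      n_c = as.integer(n_c),
                      separation = as.numeric(separation),
                      product_dose = as.numeric(product_dose),
                      product_protein_concentration =
                        as.numeric(product_protein_concentration),
                      body_weight = as.numeric(body_weight),
                      ttc = as.numeric(ttc),
                      vf_pool_protein = as.numeric(vf_pool_protein)),
                 class = "fixture_spec")
  if (any(c(x$n_safe, x$n_b2_pass, x$n_b2_fail, x$n_c) < 0))
    stop("fixture counts must be >= 0", call. = FALSE)
  if (!is.finite(x$separation) || x$separation <= 1)
    stop("infeasible fixture_spec: separation must be > 1 so a dose cannot sit on both sides of its PDE",
         call. = FALSE)
  x
}

# Stage-wise protein concentrations (mg/ml) used by the fixture: cell culture
# titer ~5 mg/ml up to capture, partially concentrated mid-downstream, and
# formulated drug substance at the product concentration.
fixture_stage_proteins <- function(spec) {
  c(cell_banking = 5, upstream = 5, harvest = 5, downstream_pre_proA = 5,
    downstream_pre_CEX = 10, downstream_post_CEX = 20,
    formulation = spec$product_protein_concentration)
}

#' Generate the synthetic worked-example inventory
#'
#' Builds a seed-deterministic inventory, toxicity map, dose context and
#' LOD-based in-process measurements matching a [fixture_spec()]. Category A
#' impurities carry safe evidence codes and realistic lognormal usage
#' concentrations; Category B2 impurities carry `medium_toxicity` evidence
#' with a NOEL, and their usage concentrations are back-computed so the
#' worst-case dose lands `separation`-fold below (pass) or above (fail) the
#' derived PDE. Each failing impurity gets a viral-filtration-pool LOD
#' measurement placing its Step 2b dose `separation`-fold below the PDE.
#'
#' @param spec A [fixture_spec()].
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @return List with `inventory` (list of [pri_record()]), `tox` (named list
#'   of [toxicity_profile()]), `measurements` (data.frame), `context`
#'   ([dose_context()]) and `spec`.
#' @examples
#' fx <- generate_example_inventory(seed = 1)
#' length(fx$inventory)  # 105
#' @export
generate_example_inventory <- function(spec = fixture_spec(), seed = 1) {
  stopifnot(inherits(spec, "fixture_spec"))
  stage_prot <- fixture_stage_proteins(spec)
  ctx <- dose_context(product_dose = spec$product_dose,
                      product_protein_concentration =
                        spec$product_protein_concentration,
                      body_weight = spec$body_weight,
                      factors = modifying_factors(),  # f2 = 10 only
                      ttc = spec$ttc,
                      stage_protein_concentrations = stage_prot)

  safe_codes <- SAFE_EVIDENCE_CODES
  safe_stages <- c("upstream", "upstream", "cell_banking", "harvest",
                   "downstream_pre_CEX", "downstream_post_CEX", "formulation")
  inventory <- list()
  tox <- list()

  with_local_seed(seed, {
    if (spec$n_safe > 0) {
      conc <- exp(stats::rnorm(spec$n_safe, mean = log(500), sd = 1.2))
      for (i in seq_len(spec$n_safe)) {
        id <- sprintf("A%03d", i)
        inventory[[id]] <- pri_record(
          id, sprintf("safe component %03d", i),
          usage_stage = safe_stages[(i - 1) %% length(safe_stages) + 1],
          usage_concentration = conc[i],
          evidence_codes = safe_codes[(i - 1) %% length(safe_codes) + 1])
        tox[[id]] <- toxicity_profile()
      }
    }

    n_b2 <- spec$n_b2_pass + spec$n_b2_fail
    if (n_b2 > 0) {
      # NOELs (mg/kg/day) spread over a realistic medium-toxicity range
      noels <- exp(seq(log(0.5), log(20), length.out = max(n_b2, 2)))[seq_len(n_b2)]
      b2_stages <- rep(c("upstream", "cell_banking", "harvest"),
                       length.out = n_b2)
      for (i in seq_len(n_b2)) {
        id <- sprintf("B%03d", i)
        failing <- i > spec$n_b2_pass
        t <- toxicity_profile(noel = noels[i])
        pde <- compute_pde(t, ctx)  # ug/day
        dose_target <- if (failing) pde * spec$separation
                       else pde / spec$separation
        protein_i <- stage_prot[[b2_stages[i]]]
        usage <- dose_target * protein_i / spec$product_dose
        inventory[[id]] <- pri_record(
          id,
          sprintf("%s %03d",
                  if (failing) c("antifoam agent", "shear protectant",
                                 "selection reagent")[(i - spec$n_b2_pass - 1) %% 3 + 1]
                  else "process reagent", i),
          usage_stage = b2_stages[i], usage_concentration = usage,
          evidence_codes = "medium_toxicity")
        tox[[id]] <- t
      }
    }

    if (spec$n_c > 0) {
      for (i in seq_len(spec$n_c)) {
        id <- sprintf("C%03d", i)
        inventory[[id]] <- pri_record(
          id, sprintf("severe-toxicity reagent %03d", i),
          usage_stage = "upstream",
          usage_concentration = exp(stats::rnorm(1, log(1), 0.5)),
          evidence_codes = "genotoxic")
        tox[[id]] <- toxicity_profile(severe_toxicity = TRUE)
      }
    }
  })

  # LOD measurements for the failing B2 impurities: assay LODs chosen so the
  # Step 2b dose at the viral filtration pool sits separation-fold below PDE.
  meas <- NULL
  if (spec$n_b2_fail > 0) {
    rows <- lapply(seq_len(spec$n_b2_fail) + spec$n_b2_pass, function(i) {
      id <- sprintf("B%03d", i)
      pde <- effective_pde(tox[[id]], ctx)
      lod <- (pde / spec$separation) * spec$vf_pool_protein / spec$product_dose
      data.frame(pri_id = id, test_point = "viral_filtration_pool",
                 concentration = lod, is_lod = TRUE,
                 protein_concentration = spec$vf_pool_protein,
                 stringsAsFactors = FALSE)
    })
    meas <- do.call(rbind, rows)
  } else {
    meas <- data.frame(pri_id = character(), test_point = character(),
                       concentration = numeric(), is_lod = logical(),
                       protein_concentration = numeric(),
                       stringsAsFactors = FALSE)
  }

  list(inventory = unname(inventory), tox = tox, measurements = meas,
       context = ctx, spec = spec)
}

#' Packaged clearance-study reference tables
#'
#' Returns the transcribed published spiking-study tables shipped with the
#' package: impurity metadata (identity, molecular weight, physical
#' properties, usage purpose), Protein A chromatography fraction
#' concentrations (feed, flow-through, wash, eluate) and cation exchange
#' fraction concentrations (load, flow-through, eluate). "Below detection"
#' cells are stored as the assay LOD value with a companion `*_is_lod`
#' logical column, so the clearance-fold LOD rule applies mechanically.
#'
#' @return List of data.frames `pri_metadata`, `protein_a`, `cex`.
#' @examples
#' tabs <- packaged_tables()
#' subset(tabs$protein_a, pri == "BME")
#' @export
packaged_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "prisafe",
                                  mustWork = TRUE)
  rd <- function(f) utils::read.delim(path(f), stringsAsFactors = FALSE)
  list(pri_metadata = rd("pri_metadata.tsv"),
       protein_a = rd("protein_a_clearance.tsv"),
       cex = rd("cex_clearance.tsv"))
}

#' Clearance measurements from a packaged chromatography table
#'
#' Converts one packaged fraction table into [clearance_measurement()]s from
#' the load/feed to the eluate, under an equal-protein-concentration
#' assumption (load protein = pool protein): eluate protein concentrations
#' were not reported, so folds computed this way are indicative, not the
#' study's exact figures.
#'
#' @param table One of the chromatography data.frames from
#'   [packaged_tables()] (`protein_a` or `cex`).
#' @param protein Assumed protein concentration on both sides, mg/ml
#'   (default 5, the reported load concentration).
#' @return Named list of [clearance_measurement()]s keyed by impurity.
#' @export
table_to_measurements <- function(table, protein = 5) {
  stopifnot(all(c("pri", "eluate", "eluate_is_lod") %in% names(table)),
            any(c("feed", "load") %in% names(table)))
  ini <- if ("feed" %in% names(table)) table$feed else table$load
  fin <- table$eluate
  lod <- table$eluate_is_lod
  out <- lapply(seq_len(nrow(table)), function(i)
    clearance_measurement(step_name = table$pri[i], initial_pri = ini[i],
                          initial_protein = protein, final_pri = fin[i],
                          final_protein = protein,
                          final_is_lod = as.logical(lod[i])))
  names(out) <- table$pri
  out
}
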