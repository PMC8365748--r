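test_that("categorization follows the evidence rules", {
  ctx <- simple_ctx()
  expect_equal(categorize_pri(simple_pri(codes = "GRAS"),
                              toxicity_profile()), "A")
  expect_equal(categorize_pri(simple_pri(codes = c("GRAS", "metabolite")),
                              toxicity_profile()), "A")
  expect_equal(categorize_pri(simple_pri(codes = "medium_toxicity"),
                              toxicity_profile(noel = 5)), "B2")
  expect_equal(categorize_pri(simple_pri(codes = "medium_toxicity"),
                              toxicity_profile(established_pde = 100)), "B2")
  expect_equal(categorize_pri(simple_pri(codes = "medium_toxicity"),
                              toxicity_profile(ld50 = 200)), "B1")
  expect_equal(categorize_pri(simple_pri(codes = "genotoxic"),
                              toxicity_profile(noel = 5,
                                               severe_toxicity = TRUE)), "C")
  # no toxicity data at all -> most conservative branch
  expect_equal(categorize_pri(simple_pri(codes = "no_data"),
                              toxicity_profile()), "C")
  # mixed evidence: the more severe branch wins
  expect_equal(categorize_pri(simple_pri(codes = c("metabolite",
                                                   "medium_toxicity")),
                              toxicity_profile(noel = 1)), "B2")
})

test_that("worst-case assessment compares the copurified dose to the limit", {
  ctx <- simple_ctx(stage_protein_concentrations = c(upstream = 5))
  # B2 pass: dose well under PDE. NOEL 10 -> PDE = 10*50/10 mg = 50,000 ug/day
  tox <- toxicity_profile(noel = 10)
  pri <- simple_pri(conc = 10, stage = "upstream")  # dose = 10/5*500 = 1000 ug
  out <- step2a_worst_case(pri, tox, ctx)
  expect_equal(out$disposition, "no_safety_risk")
  expect_equal(out$metrics$pri_dose, 1000)
  expect_equal(out$metrics$pde, 50000)
  # B2 fail -> testing_required
  pri_hi <- simple_pri(conc = 1000, stage = "upstream")  # dose = 100,000 ug
  expect_equal(step2a_worst_case(pri_hi, tox, ctx)$disposition,
               "testing_required")
  # C branch vs TTC: dose 0.1 ug vs 1.5 ug/day
  pri_c <- simple_pri(conc = 0.001, stage = "upstream", codes = "no_data")
  out_c <- step2a_worst_case(pri_c, toxicity_profile(), ctx)
  expect_equal(out_c$category, "C")
  expect_equal(out_c$disposition, "no_safety_risk")
  expect_error(step2a_worst_case(simple_pri(codes = "GRAS"),
                                 toxicity_profile(), ctx), "Step 1")
})

test_that("B1 uses the ISF path when equipped, escalates to TTC otherwise", {
  tox <- toxicity_profile(ld50 = 200)  # mg/kg
  pri <- simple_pri(conc = 1)  # dose = 1/50*500 = 10 ug
  ctx_isf <- simple_ctx(isf_threshold = 1e5)
  out <- step2a_worst_case(pri, tox, ctx_isf)
  # ISF = 200*50*1000/10 = 1e6 > 1e5 -> pass
  expect_equal(out$metrics$isf, 1e6)
  expect_equal(out$disposition, "no_safety_risk")
  # ISF exactly at threshold must fail (strict comparison)
  ctx_tie <- simple_ctx(isf_threshold = 1e6)
  expect_equal(step2a_worst_case(pri, tox, ctx_tie)$disposition,
               "testing_required")
  # no threshold configured -> TTC escalation (10 ug vs 1.5 ug/day: fail)
  out_esc <- step2a_worst_case(pri, tox, simple_ctx())
  expect_match(out_esc$rationale, "TTC")
  expect_equal(out_esc$disposition, "testing_required")
})

test_that("step 2b re-assesses at the measured or LOD concentration", {
  ctx <- simple_ctx(stage_protein_concentrations = c(upstream = 5))
  tox <- toxicity_profile(noel = 1)  # PDE = 5,000 ug/day
  pri <- simple_pri(conc = 1000, stage = "upstream")  # worst case 100,000 ug
  expect_equal(step2a_worst_case(pri, tox, ctx)$disposition,
               "testing_required")
  # LOD result placing the dose far below PDE
  out <- step2b_with_results(pri, tox, ctx, measured_concentration = 1,
                             measurement_protein = 10, is_lod = TRUE)
  expect_equal(out$disposition, "no_safety_risk")
  expect_match(out$rationale, "bound")  # LOD pass annotated as bound-based
  # measured dose above PDE -> action_required
  out2 <- step2b_with_results(pri, tox, ctx, measured_concentration = 500,
                              measurement_protein = 10, is_lod = FALSE)
  expect_equal(out2$disposition, "action_required")
})

test_that("decision tree reaches exactly one terminal for every input combo", {
  # exhaustive enumeration of the finite combination space:
  # valid evidence sets x NOEL presence x established-PDE presence x
  # LD50 presence x ISF-threshold configured
  codes_sets <- list("GRAS", "metabolite", "approved_excipient",
                     c("GRAS", "approved_excipient"), "medium_toxicity",
                     c("metabolite", "medium_toxicity"), "genotoxic",
                     "carcinogenic", c("medium_toxicity", "genotoxic"),
                     "no_data")
  grid <- expand.grid(cs = seq_along(codes_sets), noel = c(TRUE, FALSE),
                      pde = c(TRUE, FALSE), ld50 = c(TRUE, FALSE),
                      thr = c(TRUE, FALSE))
  for (g in seq_len(nrow(grid))) {
    codes <- codes_sets[[grid$cs[g]]]
    tox <- toxicity_profile(
      noel = if (grid$noel[g]) 5 else NA_real_,
      established_pde = if (grid$pde[g]) 2000 else NA_real_,
      ld50 = if (grid$ld50[g]) 300 else NA_real_,
      severe_toxicity = any(codes %in% c("genotoxic", "carcinogenic")))
    ctx <- simple_ctx(isf_threshold = if (grid$thr[g]) 1000 else NA_real_,
                      stage_protein_concentrations = c(upstream = 5))
    pri <- simple_pri(conc = 5, codes = codes)
    category <- categorize_pri(pri, tox)
    expect_true(category %in% c("A", "B1", "B2", "C"))
    if (category == "A") next
    out <- step2a_worst_case(pri, tox, ctx, category = category)
    expect_length(out$disposition, 1)
    expect_true(out$disposition %in% c("no_safety_risk", "testing_required"))
    out_b <- step2b_with_results(pri, tox, ctx, 0.001, 10, is_lod = TRUE,
                                 category = category)
    expect_true(out_b$disposition %in% c("no_safety_risk", "action_required"))
  }
})

test_that("lowering usage concentration never flips a pass into a fail", {
  set.seed(23)
  ctx <- simple_ctx(isf_threshold = 1e4,
                    stage_protein_concentrations = c(upstream = 5))
  for (k in 1:40) {
    codes <- sample(list("medium_toxicity", "no_data", "genotoxic"), 1)[[1]]
    tox <- toxicity_profile(
      noel = if (runif(1) < 0.5) runif(1, 0.1, 10) else NA_real_,
      ld50 = if (runif(1) < 0.5) runif(1, 10, 1000) else NA_real_,
      severe_toxicity = identical(codes, "genotoxic"))
    conc <- runif(1, 0.001, 100)
    out_hi <- step2a_worst_case(simple_pri(conc = conc, codes = codes),
                                tox, ctx)
    out_lo <- step2a_worst_case(simple_pri(conc = conc / 2, codes = codes),
                                tox, ctx)
    if (out_hi$disposition == "no_safety_risk")
      expect_equal(out_lo$disposition, "no_safety_risk")
  }
})

test_that("workflow orchestration matches the staged narrative", {
  fx <- generate_example_inventory(seed = 1)
  rep <- run_workflow(fx$inventory, fx$tox, fx$context, fx$measurements)
  expect_equal(rep$summary$n, 105)
  expect_equal(unname(rep$summary$by_category[["A"]]), 96)
  expect_equal(unname(rep$summary$by_category[["B2"]]), 9)
  expect_equal(nrow(rep$testing_plan), 3)
  expect_equal(unname(rep$summary$by_disposition[["no_safety_risk"]]), 105)
  # Category A impurities never appear in the testing plan
  a_ids <- rep$table$pri_id[rep$table$category == "A"]
  expect_length(intersect(a_ids, rep$testing_plan$pri_id), 0)
  # without measurements the flagged impurities stay testing_required
  rep0 <- run_workflow(fx$inventory, fx$tox, fx$context)
  expect_equal(unname(rep0$summary$by_disposition[["testing_required"]]), 3)
  # counts always sum to inventory size
  expect_equal(sum(rep$summary$by_category), rep$summary$n)
  expect_equal(sum(rep$summary$by_disposition), rep$summary$n)
})

test_that("workflow handles empty inventories, single impurities, unmatched ids", {
  ctx <- simple_ctx()
  rep <- run_workflow(list(), list(), ctx)
  expect_equal(rep$summary$n, 0)
  expect_equal(nrow(rep$testing_plan), 0)
  # one genotoxic impurity below TTC -> single no_safety_risk trace
  pri <- simple_pri("G1", conc = 1e-4, codes = "genotoxic")
  rep1 <- run_workflow(list(pri),
                       list(G1 = toxicity_profile(severe_toxicity = TRUE)),
                       simple_ctx(stage_protein_concentrations =
                                    c(upstream = 5)))
  expect_equal(rep1$table$disposition, "no_safety_risk")
  expect_equal(rep1$table$category, "C")
  # unmatched measurement ids are reported, not applied
  m <- data.frame(pri_id = "ghost", test_point = "cex_pool",
                  concentration = 1, is_lod = FALSE,
                  protein_concentration = 10)
  rep2 <- run_workflow(list(pri),
                       list(G1 = toxicity_profile(severe_toxicity = TRUE)),
                       ctx, m)
  expect_equal(rep2$unmatched_measurements, "ghost")
})

test_that("reports are deterministic and ordered by impurity id", {
  fx <- generate_example_inventory(seed = 9)
  r1 <- run_workflow(fx$inventory, fx$tox, fx$context, fx$measurements)
  r2 <- run_workflow(rev(fx$inventory), fx$tox, fx$context, fx$measurements)
  expect_identical(r1$table, r2$table)
  expect_equal(r1$table$pri_id, sort(r1$table$pri_id))
})

test_that("test points follow the staged clearance placement", {
  expect_equal(default_test_point("upstream"), "proA_pool")
  expect_equal(default_test_point("harvest"), "proA_pool")
  expect_equal(default_test_point("downstream_pre_proA"), "proA_pool")
  expect_equal(default_test_point("downstream_pre_CEX"), "cex_pool")
  expect_equal(default_test_point("downstream_post_CEX"),
               "viral_filtration_pool")
  expect_equal(default_test_point("upstream", mode = "platform"),
               "viral_filtration_pool")
})
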