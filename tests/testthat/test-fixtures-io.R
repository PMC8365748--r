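test_that("example inventory matches its composition spec and is deterministic", {
  fx1 <- generate_example_inventory(seed = 4)
  fx2 <- generate_example_inventory(seed = 4)
  expect_identical(fx1$inventory, fx2$inventory)
  expect_identical(fx1$measurements, fx2$measurements)
  fx3 <- generate_example_inventory(seed = 5)
  expect_false(identical(fx1$inventory, fx3$inventory))
  expect_equal(length(fx1$inventory), 105)
  expect_true(all(validate_inventory(fx1$inventory)$valid))
  # B2 doses sit a robust factor away from their PDE on either side
  rep <- run_workflow(fx1$inventory, fx1$tox, fx1$context)
  b2 <- rep$table[rep$table$category == "B2", ]
  sep <- b2$pri_dose / b2$limit
  expect_true(all(sep < 0.5 | sep > 2))
})

test_that("fixture composition parameters are data, not engine constants", {
  fx <- generate_example_inventory(fixture_spec(n_safe = 5, n_b2_pass = 2,
                                                n_b2_fail = 0), seed = 2)
  rep <- run_workflow(fx$inventory, fx$tox, fx$context, fx$measurements)
  expect_equal(rep$summary$n, 7)
  expect_equal(nrow(rep$testing_plan), 0)  # no B2 failures -> empty plan
  fx_c <- generate_example_inventory(fixture_spec(n_safe = 1, n_b2_pass = 0,
                                                  n_b2_fail = 0, n_c = 2),
                                     seed = 2)
  rep_c <- run_workflow(fx_c$inventory, fx_c$tox, fx_c$context)
  expect_equal(unname(rep_c$summary$by_category[["C"]]), 2)
  expect_error(fixture_spec(separation = 1), "infeasible")
  expect_error(fixture_spec(n_safe = -1), ">= 0")
})

test_that("diafiltration profile generator is exact at zero noise and reproducible", {
  p <- generate_diafiltration_profile(100, s = 1.02, n_points = 6)
  expect_equal(p$points$diavolume, 0:6)
  expect_equal(p$points$concentration, 100 * exp(-(0:6) * 1.02))
  n1 <- generate_diafiltration_profile(100, 0.7, noise_sigma = 0.05, seed = 8)
  n2 <- generate_diafiltration_profile(100, 0.7, noise_sigma = 0.05, seed = 8)
  expect_identical(n1, n2)
  # generators leave the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99)
  invisible(generate_diafiltration_profile(10, 0.5, noise_sigma = 0.1,
                                           seed = 3))
  expect_identical(runif(1), before)
})

test_that("packaged table transcriptions are intact (checksums)", {
  path <- function(f) system.file("extdata", f, package = "prisafe",
                                  mustWork = TRUE)
  expect_equal(unname(tools::md5sum(path("pri_metadata.tsv"))),
               "8d75e9722cfe5f3943d91640c88cac57")
  expect_equal(unname(tools::md5sum(path("protein_a_clearance.tsv"))),
               "1f5edad7d6ee57aeb8a6b841fcb6c861")
  expect_equal(unname(tools::md5sum(path("cex_clearance.tsv"))),
               "1bebaeadad3319329796b63647662c7d")
  tabs <- packaged_tables()
  # spot checks against the published rows
  bme <- tabs$protein_a[tabs$protein_a$pri == "BME", ]
  expect_equal(bme$feed, 1005)
  expect_equal(bme$flow_through, 931)
  expect_true(bme$wash_is_lod && bme$eluate_is_lod)
  dx <- tabs$cex[tabs$cex$pri == "Dextran sulfate", ]
  expect_equal(c(dx$load, dx$flow_through, dx$eluate), c(643, 330, 45.6))
  tx <- tabs$pri_metadata[tabs$pri_metadata$pri == "Triton X-100", ]
  expect_equal(tx$molecular_weight, 625)
  expect_match(tx$physical_properties, "nonionic surfactant")
})

test_that("inventory files round-trip exactly through CSV and JSON", {
  inv <- c(small_inventory(),
           list(pri_record("S1", "poloxamer 188", "upstream", 450,
                           "medium_toxicity", molecular_weight = 8000,
                           charge_class = "neutral", surfactant = TRUE,
                           critical_micelle_concentration = 1900)))
  for (ext in c("csv", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_inventory(inv, f)
    back <- read_inventory(f)
    expect_identical(back, inv)
  }
  expect_error(read_inventory("inv.xlsx"), "unsupported")
})

test_that("toxicity tables round-trip with empty cells as missing data", {
  tox <- list(B1 = toxicity_profile(noel = 5),
              B2 = toxicity_profile(ld50 = 300, ld50_route = "iv"),
              B3 = toxicity_profile(established_pde = 2000,
                                    severe_toxicity = TRUE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_toxicity(tox, f)
  back <- read_toxicity(f)
  expect_identical(back, tox)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_toxicity(bad), "pri_id")
})

test_that("measurement and profile files round-trip", {
  fx <- generate_example_inventory(seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements(fx$measurements, f)
  expect_equal(read_measurements(f), fx$measurements)
  p <- generate_diafiltration_profile(100, 0.81, noise_sigma = 0.05, seed = 2)
  fp <- withr::local_tempfile(fileext = ".csv")
  write_profile(p, fp)
  back <- read_profile(fp)
  expect_equal(back$points$concentration, p$points$concentration)
  expect_equal(back$c0, p$c0)
  # missing columns are structural errors, not silent drops
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_measurements(bad), "missing columns")
  expect_error(read_profile(bad), "missing columns")
})

test_that("config files populate the dose context with defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("product_dose: 750", "product_protein_concentration: 60",
               "isf_threshold: 10000", "factors:", "  f1: 5",
               "stage_protein_concentrations:", "  upstream: 5"), f)
  cfg <- read_config(f)
  ctx <- cfg$context
  expect_equal(ctx$product_dose, 750)
  expect_equal(ctx$body_weight, 50)       # default
  expect_equal(ctx$ttc, 1.5)              # default
  expect_equal(ctx$factors$f1, 5)
  expect_equal(ctx$factors$f2, 10)        # fixed default
  expect_equal(ctx$isf_threshold, 10000)
  expect_equal(cfg$fit_r2_threshold, 0.95)
  expect_equal(stats::setNames(ctx$stage_protein_concentrations["upstream"],
                               "upstream"),
               c(upstream = 5))
})

test_that("report rendering: JSON validates against the schema, Markdown tallies", {
  fx <- generate_example_inventory(seed = 1)
  rep <- run_workflow(fx$inventory, fx$tox, fx$context, fx$measurements)
  fj <- withr::local_tempfile(fileext = ".json")
  render_report(rep, "json", fj, seed = 1)
  expect_true(validate_report_json(fj))
  md <- render_report(rep, "markdown")
  expect_match(md, "\\| A \\| 96 \\|")
  expect_match(md, "Testing plan")
  # empty report is still valid JSON with zero counts
  rep0 <- run_workflow(list(), list(), simple_ctx())
  f0 <- withr::local_tempfile(fileext = ".json")
  render_report(rep0, "json", f0)
  expect_true(validate_report_json(f0))
  expect_error(render_report(rep, "xml"), "arg")
  # determinism: identical inputs render byte-identical reports
  expect_identical(render_report(rep, "json", seed = 1),
                   render_report(rep, "json", seed = 1))
})
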