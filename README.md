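# prisafe

Safety risk management for low-molecular-weight process-related impurities
(LMW PRIs) in monoclonal-antibody manufacturing.

Biologics processes introduce dozens of small-molecule substances — media
components, buffers, antifoams, shear protectants, selection reagents,
detergents — that may remain at trace levels in drug substance. Routine
release testing for every one of them is neither realistic nor necessary;
the accepted alternative is a risk-assessment-guided strategy. `prisafe`
implements that strategy as a reusable R library and command-line tool for
process-development and CMC scientists:

- **Categorization and decision tree.** Impurities are classed from
  toxicity evidence: Category A (known-to-be-safe: human metabolites, GRAS
  substances, approved excipients — eliminated immediately), Category B
  (medium toxicity; B2 when a permitted daily exposure is established or
  derivable, else B1), and Category C (genotoxic/carcinogenic; impurities
  with no data at all are assessed on the C branch as the most conservative
  assumption). Step 2a assesses the worst case — the impurity copurifies
  with product, no clearance credit; Step 2b re-assesses with in-process
  results, substituting the assay limit of detection (LOD) for non-detects.
- **Dose calculus.** Permitted daily exposure
  `PDE = NOEL × BW / (F1·F2·F3·F4·F5)`; impurity dose per product dose
  `dose = C_PRI / C_protein × D_product`; impurity safety factor
  `ISF = toxicity dose / impurity dose`; threshold of toxicological concern
  (TTC, default 1.5 µg/day). All pass/fail comparisons are strict — ties
  fail.
- **Clearance accounting.** Per-step clearance fold
  `(C_PRI,in / C_prot,in) / (C_PRI,out / C_prot,out)`, LOD lower-bound
  flags, multiplicative cumulative clearance, and the conservative platform
  budget for a typical mAb downstream process
  (100-fold Protein A × 10-fold CEX × 5-fold diafiltration = 5,000-fold).
- **Diafiltration model.** Constant-volume washout `C = C0·e^(−N·S)` with
  sieving-coefficient fitting (nonlinear least squares, log-linear
  initializer, R² acceptance), diavolume planning `N = ln(fold)/S`, and a
  critical-micelle-concentration guard for surfactants.

Transcribed published spiking-study tables (impurity metadata, Protein A
and cation-exchange fraction concentrations) ship in `inst/extdata`, and a
deterministic synthetic fixture generator reproduces the shape of a
realistic 105-impurity assessment.

## Worked example

```r
library(prisafe)

fx  <- generate_example_inventory(seed = 1)   # 105 impurities + tox data
rep <- run_workflow(fx$inventory, fx$tox, fx$context, fx$measurements)
rep
#> <workflow_report> 105 impurities
#>   categories:   A=96  B1=0  B2=9  C=0
#>   dispositions: no_safety_risk=105  testing_required=0  action_required=0
#>   testing plan: 3 entries (B007, B008, B009)
```

96 impurities are eliminated at Step 1 as known-to-be-safe; the nine
Category B2 impurities go through the worst-case assessment, six pass
outright, three need in-process testing, and with LOD-based results all 105
end with no safety risk.

```r
platform_minimum_budget()$cumulative   # 5000
clearance_after_dv(6, s = 1.02)        # 454.86-fold after 6 diavolumes
dv_for_target(100, s = 0.81)           # 5.69 DV for 100-fold clearance
fit_sieving(generate_diafiltration_profile(100, s = 1.09))$s   # 1.09
```

The command-line front end lives at `inst/cli/prisafe.R`:

```sh
Rscript inst/cli/prisafe.R fixtures --out-dir work --seed 1
Rscript inst/cli/prisafe.R assess --inventory work/inventory.csv \
    --config cfg.yaml --toxicity work/toxicity.csv \
    --measurements work/measurements.csv --out report.json
Rscript inst/cli/prisafe.R diafilt-plan --fold 100 --s 0.81
```

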