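---
title: "Risk management for low-molecular-weight process-related impurities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk management for low-molecular-weight process-related impurities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prisafe)
```

## The problem

Monoclonal-antibody manufacturing introduces many low-molecular-weight
substances — nutrients, buffers, antifoams, shear protectants, selection
reagents, leachates, detergents — that are not the product and may persist
at trace levels into drug substance. Unlike biological process-related
impurities (host-cell protein, DNA), these LMW PRIs are too numerous and
too heterogeneous for blanket release testing. `prisafe` implements the
risk-assessment-guided alternative: categorize each impurity by toxicity
evidence, quantify the worst case it could pose in a dose of product,
demand in-process testing only where the worst case is not already safe,
and account for the downstream process's demonstrated or assumed clearance.

## Units

Internal units are fixed per field and never converted mid-calculation:
impurity concentrations in µg/ml, protein concentrations in mg/ml, product
dose in mg, NOEL/LOEL in mg/kg/day, LD50 in mg/kg, PDE and TTC in µg/day.
`convert_concentration()` exists only at the I/O boundary. The motivation
is defensive: published process data mix µg/ml, mg/ml and mg/kg freely, and
a single internal convention makes 1000× unit errors structurally
impossible rather than merely unlikely.

## The dose calculus

**Permitted daily exposure.** For an impurity with a point of departure,

$$PDE\;[\mu g/day] = \frac{POD\;[mg/kg/day] \times BW\;[kg]}{F_1 F_2 F_3 F_4 F_5} \times 1000$$

The POD is the NOEL, falling back to the LOEL. F2 defaults to 10
(inter-individual variability, the fixed convention); F1, F3, F4, F5
default to 1 and must be set deliberately — the package refuses to invent
toxicological judgment, and a LOEL-based derivation is rejected outright
unless F5 > 1 has been configured. Body weight defaults to 50 kg, the
conventional conservative adult figure in impurity guidelines, and is
configurable; every report snapshot records it.

**Impurity dose per product dose.**
$dose\;[\mu g] = C_{PRI}\,[\mu g/ml] / C_{protein}\,[mg/ml] \times D\,[mg]$.
Working on the impurity-to-protein *mass ratio* rather than a volumetric
concentration makes the quantity invariant to dilution and concentration
steps, which is what lets the worst-case assumption ("the ratio at the
introduction point is carried unchanged into drug substance") be stated as
a single number.

**Impurity safety factor.** $ISF = \text{toxicity dose} / \text{impurity
dose}$. The basis of the numerator is genuinely open in the field's usage;
this package converts an LD50 in mg/kg to a per-patient absolute dose via
body weight before forming the ratio, so both sides are µg per patient.
That choice is recorded here as the package's own and is visible in every
B1 rationale string. The ISF acceptance threshold has *no default*: it must
be chosen from compound-specific dose–response data, so it is a required
configuration parameter, and a B1 impurity lacking either an LD50 or a
configured threshold escalates to the TTC branch rather than passing.

**Comparisons.** Every pass/fail comparison in the package is a strict
inequality — a dose exactly at its PDE, an ISF exactly at its threshold,
fail. Ties are the conservative direction.

**Daily-dose basis.** The impurity dose per *product dose* is compared
directly against per-*day* limits (PDE, TTC), i.e. the worst case of one
product dose per day. For less-frequent dosing this is conservative;
schedule-adjusted TTC tables are out of scope.

## The decision tree

Step 1 categorizes from evidence codes: Category A when every code is in
the safe set (metabolite, GRAS, approved excipient); C when genotoxic or
carcinogenic evidence is present, and also for `no_data` impurities (the
most conservative assumption); otherwise B, split B2/B1 by whether a PDE is
established or derivable. Mixed evidence (e.g. metabolite + medium
toxicity) sends the record down the more severe branch. *Contradictory*
evidence — a safe code together with a severe one — is a validation error,
not a silent worst case: conflicting literature deserves a human eye, and
the categorical space the field defines gives no principled tie-break.

Step 2a computes the worst-case dose from the usage concentration and the
protein concentration at the introduction point (configurable per stage;
cell-culture stages around 5 mg/ml in the synthetic fixture). Step 2b
recomputes the same comparison from a measured (or LOD) concentration at
the test point; an LOD-based pass is annotated as bound-based in the
rationale. Failures at Step 2b are `action_required` — improve the process
or the assay.

Default test points leverage clearance placement: impurities introduced at
or before the Protein A capture step are tested at the Protein A pool,
pre-CEX downstream impurities at the CEX pool, later ones at the viral
filtration pool. A `platform` mode instead tests everything at the viral
filtration pool — the whole-downstream-clearance default, which also avoids
the assay interference of the high-protein UFDF pool.

## Clearance accounting

The per-step clearance fold is the ratio of impurity-to-protein mass
ratios across the step. Folds compose **multiplicatively** across a process
train — clearance accumulates on the log scale, consistent with the
platform arithmetic 100 × 10 × 5 = 5,000. Non-detects substitute the assay
LOD, and the resulting fold carries an `is_lower_bound` flag that
propagates by disjunction through `cumulative_clearance()`; a boolean flag
matches how such results are reported ("greater than N-fold") without the
machinery of interval arithmetic.

The packaged chromatography tables report load/feed concentrations at
5 mg/ml protein but no eluate protein concentrations, so exact study folds
cannot be reproduced from them. `table_to_measurements()` therefore applies
an explicit equal-protein assumption (pool = load), and the regression
tests label the resulting folds as assumption-dependent bounds: all
Protein A rows clear more than 100-fold under that assumption, most more
than 1,000-fold; with the (unreported) higher eluate protein
concentrations the true folds are higher still.

## The diafiltration model

Constant-retentate-volume diafiltration dilutes a freely permeating solute
exponentially:

$$C(N) = C_0\, e^{-N S}$$

with $N$ diavolumes exchanged and $S$ the sieving coefficient. $S = 1$ is
ideal washout; $S < 1$ retention (membrane rejection or weak association
with the retained antibody — negatively charged and hydrophobic solutes);
$S$ slightly above 1 occurs for solutes electrostatically repelled by a
positively charged antibody and is deliberately **not clipped**. The
reference coefficients in `sieving_reference()` span this range, from
copper(II) at 1.09 down to the poloxamer surfactant at 0.11; the tropolone
entry carries two readings under distinct names because the two published
figures for it (a fitted 0.7 vs ~8.2 DV for 100-fold, implying ~0.56) are
mutually inconsistent and neither is privileged. The EDTA coefficient is
0.81 — inside the published 0.58–0.83 range and the value consistent with
the published ~5.7 DV for 100-fold clearance.

**Fitting.** `fit_sieving()` is one-parameter nonlinear least squares on
the concentration scale with $C_0$ fixed at the profile's known spike
concentration and the closed-form log-linear slope as initializer (also
exposed via `loglinear_sieving()` for transparency). `nls()` is run with a
`scaleOffset` so that noiseless profiles — zero residual — converge
cleanly. $R^2 = 1 - SS_{res}/SS_{tot}$ is computed on the concentration
scale, and fits below the acceptance threshold (default 0.95,
configurable) are flagged rejected, never silently dropped. Points at the
assay LOD are **excluded** from the fit rather than substituted: a
substituted floor flattens the tail and biases $S$ low. This deliberately
differs from the clearance-fold LOD rule, which needs a value to form a
finite ratio.

**Planning.** $N = \ln(fold)/S$ inverts the model exactly;
`dv_for_target()` and `clearance_after_dv()` are mutual inverses to
1e-10 relative tolerance (property-tested). A solute with $S = 0$ never
clears: the planner raises a "target unreachable" error rather than
returning infinity.

**Surfactant caveat.** Above the critical micelle concentration a
surfactant travels as micelles larger than the membrane cut-off and is not
cleared; `cmc_guard()` warns when a planned spike exceeds the CMC and notes
when the CMC is unknown.

## The synthetic fixture

`generate_example_inventory()` emulates the composition of a published
worked example: 105 impurities — 96 Category A, 9 Category B2 with
NOEL-derivable PDEs, of which 6 pass the worst-case screen and 3 require
testing and then pass at the assay LOD. The counts, dose parameters and
separation are data in `fixture_spec()`, not constants in the engine. The
published example reports only the counts, so the numbers are synthetic by
necessity: B2 usage concentrations are back-computed so each worst-case
dose lands a 4-fold `separation` below (pass) or above (fail) its PDE,
making pass/fail robust to floating-point noise, and the three assay LODs
are placed so the Step 2b dose at the 10 mg/ml viral-filtration pool sits
the same factor below the PDE. Fixture stage protein concentrations
(5 mg/ml through capture, 10 then 20 mg/ml mid-downstream, product
concentration at formulation) and the 500 mg dose at 50 mg/ml are typical
mAb figures chosen once. Profiles are simulated at integer diavolumes 0–6
(a typical 6-DV process) with optional multiplicative lognormal noise; the
N = 0 point is the known spike concentration and is never noised. All
generators are seed-deterministic and restore the caller's RNG state.

What the fixture does *not* emulate: correlated assay error, drift within
a chromatography fraction, impurity–impurity interactions, or real
usage-concentration distributions. Passing tests on the fixture therefore
demonstrate that the *decision logic and arithmetic* are correct under the
stated composition, not that any particular real inventory is safe.

## Problem sizes and numerical choices

The test suite runs property sweeps at modest sizes chosen as adequate for
the properties checked: 20–40 randomized cases per invariant, the full
finite enumeration (160 combinations) for decision-tree exhaustiveness,
and diafiltration sweeps over $S \in [0.05, 1.2]$. The noisy-recovery test
uses $\sigma = 0.05$ lognormal noise at a fixed seed with tolerance ±0.05,
calibrated by simulation before freezing.

## Known limitations

- No route-to-route extrapolation, no schedule-adjusted TTC tables, no
  toxicity-database retrieval: toxicity inputs are the user's.
- No mechanistic chromatography or membrane-transport modeling; clearance
  is accounting over measured or assumed folds, and the diafiltration
  model ignores concentration polarization and the ultrafiltration stage.
- The equal-protein folds from the packaged tables are indicative bounds,
  not the original study's exact figures (eluate protein unreported).
- Chemical identity handling (SMILES/InChI) is out of scope; physicochemical
  classes are metadata used for warnings only.
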