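---
title: "Methods: comparative risk assessment of a free-sugars reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative risk assessment of a free-sugars reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugarcra)
```

# The model

`sugarcra` implements a cross-sectional comparative risk assessment (CRA)
macrosimulation for diet policy scenarios. The question it answers: if the
free-sugars content of foods and beverages were systematically reduced by a
fraction *r*, how many deaths from BMI-mediated non-communicable diseases
(NCDs) would be averted or delayed annually?

The causal chain is

1. **Reformulation** — each food record's free sugars shrink from *s* to
   (1 − *r*)·*s*; its energy changes by −κ·*f*·*r*·*s* kcal, where *f* = 4
   kcal/g is the carbohydrate energy factor and κ is the *calorie response*
   (κ = 1: every removed sugar calorie is removed from the item; κ < 1:
   partial replacement by fats/starches; κ > 1: co-removal of other energy).
   Energy is clamped from below at the remaining sugar energy.
2. **Energy to BMI** — each sex × age stratum's mean daily intake change
   Δ*E* maps to a body-weight change through a steady-state inversion of a
   Schofield-type linear expenditure relation, TEE = PAL·(*a·W* + *b*)
   MJ/day, so Δ*W* = Δ*E*<sub>MJ</sub>/(PAL·*a*) and ΔBMI = Δ*W*/height².
3. **Potential impact fraction** — each stratum's BMI is modelled as
   lognormal; the counterfactual distribution is the baseline shifted to the
   new mean with the log-scale spread preserved. For each cause with a
   log-linear relative risk RR(*b*) = exp(ln(RR<sub>unit</sub>)/unit ·
   max(0, *b* − *b*<sub>ref</sub>)), the PIF is
   1 − E<sub>cf</sub>[RR]/E<sub>base</sub>[RR].
4. **Attribution** — deaths averted = PIF × observed deaths per cause, sex
   and five-year age band; aggregation produces cause rows, disease-group
   subtotals, an under-75 subtotal and the overall total, with shares and
   percent-of-actual-deaths ratios.
5. **Uncertainty** — relative-risk parameters are redrawn lognormally
   (exp(N(ln RR, se²))) over many iterations; 95% uncertainty intervals are
   the 2.5th/97.5th percentiles of the recomputed deaths averted.

Being cross-sectional, the model has no time dimension: "deaths averted or
delayed" is the difference between two annual equilibria, not a forecast for
any particular year. Morbidity, time lags, and the blood-pressure and
cholesterol pathways of the wider CRA family are out of scope; the
multiplicative pathway combiner (`combine_pathways()`) exists so
multi-pathway configurations remain expressible.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `reduction_fraction` (*r*) | 0.2 | — | the scenario's systematic free-sugars cut |
| `calorie_response` (κ) | 1.335 | kcal/kcal | calibrated via `calibrate_kappa(56.2, 60, 0.2)` so a 20% cut of a 56.2 g/day mean removes 60 kcal/day, the observed aggregate response of reformulated products; κ = 1 would assume fully calorie-reducing reformulation |
| energy factor *f* | 4 | kcal/g | standard carbohydrate Atwater factor; configurable |
| PAL | 1.6 | — | light-activity adult population average |
| Schofield coefficients | per sex × age range | MJ/day, MJ/day/kg | the linear BMR relation; user-replaceable via YAML |
| `ref_bmi` | 21 | kg/m² | RR = 1 below this reference, the usual CRA floor |
| `unit` | 5 | kg/m² | RRs are conventionally reported per 5 BMI units |
| `sd_bmi` | 5.0 | kg/m² | population BMI spread; see below |
| `iterations` | 10 000 | — | Monte Carlo size; percentile UIs stabilise well below this |

Two parameter choices deserve comment.

**Population BMI spread.** Survey tables print the *standard error of the
mean* BMI (≈ 0.2–0.5 kg/m²), a sampling quantity. The PIF integral needs the
*population* SD. Converting SE → SD by √n overstates the spread when design
effects inflate the SE, so the package requires an explicit `sd_bmi` and
defaults the synthetic generator to 5.0 kg/m², a typical adult population
value. `se_to_sd()` is provided for users who do want the √n conversion.

**The energy→weight linkage.** Applying PAL·Schofield to *self-reported*
intakes yields implausible absolute steady-state weights (survey intakes are
under-reported). Only the weight *difference* enters the BMI shift, and in
the linear model Δ*W* depends only on Δ*E*, PAL and the slope *a* — the
intercept and the absolute level cancel. The `"proportional"` strategy
(BMI′ = BMI·E′/E) is included as a sensitivity alternative; it produces
smaller shifts at these intake levels.

# Numerical choices

* **Quadrature.** E[RR] is integrated over BMI ∈ [10, 80] kg/m² and
  normalised to the truncated mass. The integral is evaluated in
  standard-normal space (*b* = exp(μ + σ·*z*), |*z*| ≤ 12), which stays well
  conditioned for any σ; below the reference BMI the integrand is exactly 1
  and contributes a closed-form normal probability. Adaptive quadrature
  (`stats::integrate`, relative tolerance 1e-8) serves the deterministic
  path; the Monte Carlo loop evaluates the same integrand on 160
  Gauss–Legendre nodes, so E[RR] across all draws is one matrix product.
  The two routes agree to ~1e-9 on realistic inputs (tested).
* **Degenerate spreads.** σ < 1e-8 is treated as a point mass and evaluated
  in closed form; the quadrature converges to that closed form as sd → 0
  (tested to 1e-6), so the analytic oracle for degenerate synthetic bundles
  is exact.
* **Percentiles.** Uncertainty intervals interpolate order statistics at
  position *p*(n−1)+1 (the type-7 convention), which is well defined from a
  single draw upward; the convention matters at small iteration counts and
  is therefore fixed and documented.
* **Shared draws.** An RR specification with `sex = "both"` is *one*
  epidemiological parameter: both sexes share each Monte Carlo draw. Only
  sex-specific rows (e.g. breast, endometrial cancer) get independent
  streams. Draws are independent across causes — no correlation structure is
  asserted.
* **Ties and degenerates.** Records with zero energy pass through the
  reformulation unchanged; energy is clamped at the remaining sugar energy
  for extreme κ; negative PIFs (a worse counterfactual) propagate to
  negative deaths averted without clamping; an all-zero run suppresses
  shares rather than dividing by zero.

# Design decisions where the design was open

* **DRI ↔ five-year-band join.** Intake data live on Dietary Reference
  Intake groups (19–30, 31–50, 51–70, 71+); mortality lives on five-year
  bands. Each band is assigned to the DRI group containing its midpoint
  (open-ended top band: lower bound + 2.5), and exposure values broadcast
  uniformly to all constituent bands. This is deterministic, order-free and
  total on adult bands; bands with midpoint < 19 are excluded (adult-only
  model).
* **Under-75 subtotal** counts bands whose upper bound is ≤ 75, matching
  half-open band semantics.
* **Lognormal BMI.** Right-skewed with positive support, matching the shape
  of adult BMI distributions; moment-matched from (mean, sd) and shifted
  mean-targeted with σ preserved, so the coefficient of variation is
  scenario-invariant. Whether a real population shifts its whole
  distribution or only its mean under reformulation is unknowable from
  aggregate data; preserving relative spread is the least-informative
  choice.
* **Single-pathway totals are sums.** With one intermediate risk factor
  (BMI) and disjoint ICD-10 cause ranges, group subtotals equal plain sums.
  Published tables from multi-pathway tools can show subcategory sums
  exceeding totals because of multiplicative double-counting corrections;
  the combiner is exported for that configuration but is the identity here.
* **Deterministic point estimate and MC mean are both reported** (`point`,
  `mc_mean`), since conventions differ on which belongs in a summary table.

# What the synthetic generator emulates — and what it does not

`generate_bundle()` produces every input the pipeline needs at national
scale: a plausible adult age pyramid (~29 M adults), annual cause-specific
deaths (~90 k across 13 causes, group totals following published 2019
Canadian registry totals, with *synthetic* per-cause splits inside the
cardiovascular and cancer groups), survey-style exposure targets per sex ×
DRI cell (the published baseline means: 1515–2091 kcal/day, BMI 25.0–29.0),
recall microdata whose free-sugars share of energy targets 12.1%TE, and
labelled-synthetic relative risks (plausible per-5-kg/m² values; the
underlying meta-analytic values are not printed in the source material).

Per-person recalls draw total energy from a gamma distribution (CV 0.30),
category energy shares from a Dirichlet (concentration 20) and per-category
free-sugar energy shares from betas (concentration 30) whose means are
scaled so the expected cohort share equals the target exactly.

The generator does **not** emulate: survey sampling design or weights,
usual-intake (measurement-error) modelling, dietary misreporting, intra-person
day-to-day variance, or product-level category substitutions. Passing tests
on synthetic bundles therefore demonstrates the *internal* correctness of the
arithmetic chain, not that the defaults reproduce any real population's
estimates — the published headline totals depend on unprinted RR parameters
and registry extracts and are deliberately not a test target; only the
published *derived ratios* (shares, percent-of-actual) are, since those are
exact arithmetic on printed numbers.

# Problem sizes

The test suite exercises the full pipeline on an 8-cell × 2-cause toy bundle
(hundreds of Monte Carlo iterations), the synthetic national bundle with up
to 5000 respondents and 10 000 iterations in the acceptance script, 1e6-draw
brute-force integration checks, and a 500-replicate coverage experiment at
1500 iterations each. These sizes give Monte Carlo error comfortably below
the tolerances asserted while keeping the whole suite around a minute on one
core.

# Known limitations

* Steady-state energy→weight linkage: no dynamic weight trajectory (a
  Hall-type model would give smaller shifts over finite horizons); the
  published tool's internal linkage is not printed, so numerical agreement
  with it cannot be verified from aggregate outputs alone.
* Exposure means are fixed in the default Monte Carlo; `vary_exposures`
  adds survey sampling error of the means but not correlation between
  baseline and counterfactual draws (they are drawn independently, which is
  conservative for the difference).
* Equal-weight person means stand in for survey-weighted usual intakes.
* RR uncertainty is the only epidemiological uncertainty propagated;
  mortality counts are treated as exact registry quantities.

# A worked example

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1, n_persons = 5000)
gen <- generate_bundle(cfg)
res <- run_mc(gen$bundle, mc_config(iterations = 10000, seed = 2))
print(render_summary(res, gen$bundle$causes))
```

The same run is scripted, with a fixed seed, in `scripts/acceptance.R`,
which writes every headline quantity the package computes to JSON.
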