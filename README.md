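# amlsim

Deterministic simulation of first-line induction chemotherapy in acute
myeloid leukemia (AML), for systems-biology and clinical-modelling work on
treatment protocols. The package answers questions of the form: *over the
whole plane of chemotherapy intensities, where does a given induction
regimen achieve complete remission, where does it undertreat, where does it
kill the marrow — and how do two regimens differ?*

## The model

Four compartments (cells/kg body weight): hematopoietic stem cells
`c1`, differentiated healthy cells `c2`, leukemic stem cells `l1`,
non-proliferating leukemic cells `l2`. Stem cells divide at rate `p`; the
self-renewing fraction `a·s(t)` is regulated by a feedback signal
`s = 1/(1 + k_c c2)` produced in response to healthy differentiated cells
only — the leukemic bulk senses the signal but does not down-regulate it,
which is how a clone with self-renewal `a_l > a_c` outcompetes healthy
hematopoiesis. Marrow-resident cells die at an extra rate
`d(x) = 1e-10 · max(0, x − 4e9)` once cellularity `x = c1 + l1 + l2`
exceeds its physiological equilibrium. Chemotherapy enters as log-kill
terms: cytarabine-like intensity `k_cyt` hits proliferating cells in
proportion to their proliferation rate; anthracycline-like `k_anthra`
additionally clears non-proliferating cells directly.

Two protocols are compared, both triggered when the marrow blast fraction
`(l1+l2)/(c1+l1+l2)` first reaches 20%:

* **standard** — a single 7+3 course (7 days cytarabine, anthracycline on
  the first 3);
* **evaluation** — 7+3 plus bone-marrow evaluations on days 14/21 after
  treatment start; ≥5.5% (day 14) or ≥5% (day 21) blasts trigger one 5+2
  re-induction at the same intensities.

Endpoints per simulated patient: time from diagnosis to complete remission
(blasts ≤5% with surviving HSC, assessed after course completion), CR
duration until relapse / HSC depletion / censoring, outcome class
(effective / undertreatment / overtreatment), and the day-29 log10
cytoreduction. Grid sweeps aggregate these into the therapeutic width (share
of intensity combinations achieving CR) and region shares, and
`compare_arms()` builds "evaluation − standard" difference maps.

The model's one unpublished scalar — the clearance rate `d2_l` of
non-proliferating leukemic cells — is calibrated by `calibrate_d2l()` so
that the untreated fast leukemia (`a_l = 1`, `p_l = 2`) is diagnosed on
day 63 after the first leukemic cell appears; the same value then puts the
intermediate pace at day 317 and the slow pace at day 2767. See the
methods vignette (`vignettes/induction-model.Rmd`) for the full model
account, conventions and limitations.

## Worked example

```r
library(amlsim)

cal <- calibrate_d2l()        # pin d2_l to the day-63 diagnosis anchor
cal$d2_l
#> [1] 0.1134334

p <- aml_parameters(pace = "fast", d2_l = cal$d2_l)
traj <- simulate_therapy(p, "standard", k_cyt = 2.5, k_anthra = 0)
print(traj)
#> AML trajectory: days 1..326 (horizon 2000)
#>   diagnosis (20% blasts) on day 63
#>    7 + 3 course @ day 63
#>   stopped early: remaining course fully determined
extract_outcome(traj)
#>   diagnosis_day cr_day time_to_cr cr_duration       cr_end_reason
#> 1            63     90         27        1910 censored_at_horizon
#>   classification       cr_class cytoreduction_log10_day29
#> 1      effective quasi_infinite                  1.485627
```

The fast leukemia is diagnosed on day 63; a cytarabine-only 7+3 at
intensity 2.5 reaches remission 27 days after treatment start, the leukemic
clone is eradicated (remission censored at the 2000-day horizon —
"quasi-infinite"), and by day 29 the leukemic mass has fallen by 1.49
orders of magnitude (cytarabine does not touch the non-proliferating
compartment, which decays only at `d2_l`).

A coarse sweep of the intensity plane (step 0.5; the reference grid uses
step 0.1):

```r
sw <- sweep_intensities(p, "standard", seq(0, 10, 0.5), seq(0, 10, 0.5))
summary(sw)
#> Intensity sweep, standard arm (441 combinations)
#>   Time to CR (range):    8 to 68 days
#>   Therapeutic width:     68.25%
#>   Overtreatment region:  28.34%
#>   Undertreatment region: 3.40%
#>   quasi-infinite CR 63.72% | short CR 4.54% | other 0.00%
#>   earliest CR (day 8): 33.56% of all, 49.17% of CR cells
```

`run_induction_study("results/")` runs the full pipeline (calibration, all
paces × both arms, difference maps, TSV tables, heatmaps, JSON report);
`inst/cli/amlsim` exposes the same steps as shell subcommands
(`simulate`, `sweep`, `compare`, `landscape`, `calibrate`, `reproduce`).

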