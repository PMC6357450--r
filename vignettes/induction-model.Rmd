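---
title: "A feedback-regulated hematopoiesis model of AML induction therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A feedback-regulated hematopoiesis model of AML induction therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`amlsim` implements a deterministic four-compartment model of coupled
healthy and leukemic hematopoiesis. Hematopoietic stem cells $c_1$ divide
at rate $p_c$; a feedback-regulated fraction $a_c\,s(t)$ of divisions
self-renews, the rest differentiates into post-mitotic cells $c_2$
(calibrated to neutrophil counts) that are cleared at rate $d_2^c$.
Leukemic stem cells $l_1$ and their non-proliferating progeny $l_2$ follow
the same architecture with their own parameters $(a_l, p_l, d_2^l)$:

$$
\begin{aligned}
\dot c_1 &= 2 a_c p_c s c_1 - p_c c_1 - d(x)\,c_1
            - k_{cyt} p_c c_1 - k_{anthra} p_c c_1\\
\dot c_2 &= 2 p_c c_1 - 2 a_c p_c s c_1 - d_2^c c_2 - k_{anthra} c_2\\
\dot l_1 &= 2 a_l s p_l l_1 - p_l l_1 - d(x)\,l_1
            - k_{cyt} p_l l_1 - k_{anthra} p_l l_1\\
\dot l_2 &= 2 p_l l_1 - 2 a_l s p_l l_1 - d_2^l l_2 - d(x)\,l_2
            - k_{anthra} l_2
\end{aligned}
$$

with marrow cellularity $x = c_1 + l_1 + l_2$, crowding death
$d(x) = 10^{-10}\max(0, x - 4\times 10^9)$ per day, and the G-CSF-like
feedback $s = 1/(1 + k_c c_2)$. The feedback is produced only in response
to healthy differentiated cells: a large subset of AML shows dysregulated
STAT3/SOCS signalling, so the leukemic bulk is assumed not to down-regulate
the signal while leukemic self-renewal still responds to it. That asymmetry
is what lets a clone with $a_l > a_c$ outcompete healthy hematopoiesis.
Note $a_l\,s$ may exceed values seen at homeostasis during aplasia
($s \to 1$); the equations are integrated literally, with no clipping —
rebound kinetics after chemotherapy depend on this.

Chemotherapy enters as two log-kill terms: a cytarabine-like agent
$k_{cyt}$ acting on proliferating cells in proportion to their
proliferation rate (S-phase specificity), and an anthracycline-like agent
$k_{anthra}$ acting on proliferating cells via the proliferation rate and
on non-proliferating cells directly. Intensities are effectiveness
parameters (1/day), not doses in mg/m²; no pharmacokinetic mapping is
attempted.

## Parameters and closures

All abundances are per kg body weight. The healthy side is pinned by its
steady state: solving $\dot c_1 = \dot c_2 = 0$ at
$(c_1^*, c_2^*) = (2\times 10^9, 3.9\times 10^9)$ cells/kg gives

$$k_c = \frac{2 a_c - 1}{c_2^*}, \qquad d_2^c = \frac{p_c\,c_1^*}{c_2^*},$$

which requires $a_c > 1/2$ (`derive_steady_parameters()` refuses the
closure otherwise). With the healthy parametrisation $a_c = 0.87$,
$p_c = 0.42$/day this yields $k_c \approx 1.897\times10^{-10}$ kg/cells and
$d_2^c \approx 0.215$/day, and the steady-state feedback is
$s^* = 1/(2a_c) \approx 0.575$.

Leukemias are characterised by their pace — the time from one seeded LSC to
the 20% diagnostic blast threshold: fast $(a_l = 1, p_l = 2)$,
intermediate $(0.92, 1)$ and slow $(0.9, 0.2)$, available via
`pace_preset()`.

The one scalar without a published value is $d_2^l$, the clearance of
non-proliferating leukemic cells. `calibrate_d2l()` pins it to an in-model
anchor: the untreated fast-pace leukemia must reach 20% blasts on day 63.
Because diagnosis moves in whole days, a whole interval of $d_2^l$
(about 0.038–0.189/day) is compatible; the midpoint (~0.113/day) is used.
As a cross-validation, the same value puts the intermediate pace at day 317
and the slow pace at day 2767, each within 0.5% of their reference values
(316 and 2756) — evidence that a single clearance rate underlies all three.

**Day-count convention.** Days are counted 1-based: the single LSC
(1 cell/kg) is seeded on day 1, and all event days (diagnosis, remission)
are grid days of that counting. This convention was chosen because it is
the only one under which one $d_2^l$ reproduces all three reference
diagnosis days simultaneously; under 0-based counting the fast anchor
forces $d_2^l \in (0.19, 0.43]$, which puts the other two paces 2–4% off.
The pre-diagnosis system is linear (the feedback depends only on $c_2$,
which is driven only by $c_1$, and both stay at steady state), so this
analysis is exact, not numerical.

## Treatment protocols

Diagnosis is the first grid day with blast fraction
$(l_1+l_2)/(c_1+l_1+l_2) \ge 0.2$; treatment starts immediately.

* **Standard arm** — one 7 + 3 induction: cytarabine-like therapy on
  $[d_x, d_x+7)$, anthracycline-like on $[d_x, d_x+3)$.
* **Evaluation arm** — 7 + 3 plus bone-marrow evaluations 14 and 21 days
  after treatment start: blasts $\ge 5.5\%$ on day 14 trigger an immediate
  5 + 2 re-induction; otherwise blasts $\ge 5\%$ on day 21 do. Comparisons
  are inclusive and unrounded; at most one re-induction is given, at the
  same preset intensities. A non-evaluable marrow (total cellularity below
  one cell per patient) never triggers re-induction.

The re-induction starts on the evaluation day itself — no administrative
gap is modelled, consistent with the prolonged neutropenia beginning within
the day-14-to-21 window in reference trajectories.

## Outcomes

* **Complete remission (CR)**: blast fraction $\le 5\%$ with HSC present
  ($c_1 > 0$; a totally aplastic marrow is "not evaluable" rather than in
  remission, which avoids 0/0 artifacts). CR is assessed on the daily grid
  but only on days strictly after the end of any chemotherapy course that
  has begun, so the earliest possible remission is 8 days after treatment
  start. Rationale: while drugs are being infused the blast *fraction* can
  transiently dip below 5% on days 1–2 (the leukemic compartments die
  faster than HSC) even though the marrow is in free fall; clinically,
  response is assessed after the course, and the reference analysis reports
  8 days as the fastest CR in every arm and pace, which this rule
  reproduces exactly.
* **CR duration**: from CR to relapse (blasts $> 5\%$), HSC depletion
  ($c_1 = 0$), or censoring at the simulation end. Remissions are classed
  structurally: *quasi-infinite* (censored — the clone was eradicated, and
  in a single-clone model without resistance nothing can bring it back),
  *short* (ended by regrowth of a residual clone within days; durations
  1–24 days in the intermediate-pace sweeps), *other* (ended by HSC
  depletion; rare).
* **Classification**: *effective* if CR is reached; otherwise
  *overtreatment* if therapy depleted every marrow compartment
  ($c_1 = l_1 = l_2 = 0$), else *undertreatment*. Overtreatment requires
  leukemic extinction too: a persisting leukemia also extinguishes HSC (via
  crowding), and counting that as overtreatment would misattribute
  treatment failure to toxicity.
* **Day-29 cytoreduction**: $\log_{10}$ reduction of $l_1 + l_2$ between
  diagnosis and 29 days after treatment start; `Inf` flags eradication.
  Under cytarabine monotherapy this is modest (~1.5 log10) even for
  curative intensities, because the drug does not touch $l_2$, which decays
  only at $d_2^l$; cells that relapse before day 29 can even show negative
  values. The published claim that every CR combination exceeds 3 log10
  does not hold under the printed equations (see Limitations).

## Numerics

Integration uses `deSolve::lsoda` (stiff-capable, automatic method
switching) with `rtol = 1e-8`, `atol = 1e-4`. The absolute tolerance sits
three orders of magnitude below the extinction threshold (1/70 cells/kg,
one cell in a 70 kg patient), so near-extinct compartments remain resolved.
Integration is restarted at every therapy on/off switch, so the
discontinuous right-hand side is never stepped across, and after every
1-day output step any compartment below 1/70 cells/kg is set to zero
(cells, not fractions of cells, repopulate a marrow). Diagnosis, remission
and evaluation readings are taken on the daily grid — event times are
reported in whole days throughout — rather than by continuous
root-finding. Once therapy is over, the leukemic compartments are extinct
and the day-29 reading has passed, the remainder of a trajectory is fully
determined (a recovering healthy system cannot lose $c_1$, and blasts stay
at zero), so the engine may stop early (`early_stop`); the test suite
verifies extracted outcomes are unchanged by this. Fixed-step RK4 at 0.01
day with the same daily clamp serves as the independent reference
integrator in the tests (agreement better than $10^{-4}$ relative over the
first 100 days).

## Problem sizes

The reference grid is $k_{cyt}, k_{anthra} \in \{0, 0.1, \ldots, 10\}$,
10,201 combinations per pace and arm (`sweep_intensities()` defaults;
`run_induction_study()` runs all of them). The package's own test suite
exercises the same pipeline on the step-0.5 subgrid (441 cells per sweep,
step 1 for the slow pace), which reproduces the full-grid region shares to
within a few percentage points while keeping a full test run in minutes;
the comparisons there use ±3 percentage points. Horizons are 2000 days
(5000 for the slow pace), counted from seeding.

## Design choices and limitations

* Single dominant clone, no acquired resistance, no consolidation: after
  eradication no relapse is possible, so quasi-infinite remissions are a
  model feature, not a prediction about patients.
* Intensities are abstract effectiveness values; cross-arm and cross-pace
  *comparisons* are meaningful, absolute dose equivalents are not.
* Between-arm differences at zero intensity vanish identically (verified to
  solver precision), so any arm difference is attributable to the
  protocols.
* The monotherapy CR minima are reproduced qualitatively but not exactly
  (we find the standard-arm cytarabine minimum at $k_{cyt} = 2.1$ versus a
  reference 2.5). The reference values for the CR minimum and the
  overtreatment bound are mutually inconsistent under the printed
  equations: LSC extinction over the 7-day course at $k_1$ implies a mean
  feedback $\bar s = (k_1 - 0.617)/2$ while HSC extinction at $k_2$ implies
  $\bar s = (k_2 - 7.728)/1.74$, and the same $s(t)$ governs both —
  the reference pair (2.5, 8.8) would need $\bar s$ of 0.94 and 0.65 at
  once. This implementation reproduces the overtreatment bounds (standard
  8.9 vs 8.8; evaluation 5.8 exactly) and the minimal cytarabine-mono
  time-to-CR (~25/~35 days), and accepts the discrepancy in the CR minima
  rather than distorting the published equations to chase them.
* Relatedly, region shares land within ~5 percentage points of the
  reference values (therapeutic width high, overtreatment low by that
  margin), traceable to the same lower CR boundary; quantities orthogonal
  to that boundary — undertreatment share, time-to-CR range (8–70 days),
  short-CR share and durations — reproduce closely.

## A worked example

```{r example}
library(amlsim)

cal <- calibrate_d2l()                       # pin d2_l to the day-63 anchor
p <- aml_parameters(pace = "fast", d2_l = cal$d2_l)

traj <- simulate_therapy(p, "standard", k_cyt = 2.5, k_anthra = 0)
extract_outcome(traj)                        # CR on day 90, quasi-infinite

sw_std <- sweep_intensities(p, "standard",  seq(0, 10, 0.5), seq(0, 10, 0.5))
sw_ev  <- sweep_intensities(p, "evaluation", seq(0, 10, 0.5), seq(0, 10, 0.5))
summary(sw_std)
compare_arms(sw_std, sw_ev)
plot_sweep(sw_std, "time_to_cr")
```
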