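---
title: "A middle-out PBPK workflow for mithramycin and MTMSA-Trp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A middle-out PBPK workflow for mithramycin and MTMSA-Trp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mtmpbpk implements an openly reproducible middle-out physiologically based
pharmacokinetic (PBPK) workflow for mithramycin (MTM) and its
tryptophan-conjugated analog MTMSA-Trp: a permeability-limited whole-body
simulator calibrated on mouse plasma PK, evaluated in rat and cynomolgus
monkey, and used to project first-in-human plasma and exploratory liver
exposure under three alternative human-clearance prediction methods. This
vignette explains the model, its assumptions, the parameters that matter, and
the design decisions taken where the published description left the design
open.

## The whole-body model

The body is represented as venous and arterial blood pools plus twelve
tissues (lung, liver, kidney, gut, spleen, heart, brain, muscle, adipose,
skin, bone and a rest-of-body compartment that closes the volume and flow
balances). The lung carries the full cardiac output in series between the
venous and arterial pools; the liver receives the hepatic artery plus the
portal outflow of gut and spleen; every other tissue returns its venous
outflow directly to the venous pool, so the non-lung flows sum exactly to the
cardiac output.

Both compounds are large (1085 and 1227 g/mol), very highly protein bound,
and distribute in a permeability-limited fashion, so each tissue is split
into two well-stirred spaces:

* an **extracellular space** (interstitium plus tissue vasculature,
  a fraction `ecf` of the tissue volume), connected to blood by flow —
  inflow $Q_t\,C_{art,blood}$, outflow $Q_t\,BPR\,C_{ec,t}$, where the
  extracellular space is carried in plasma-equivalent concentration units and
  $C_{blood} = BPR \times C_{plasma}$ defines the blood-to-plasma ratio
  convention throughout;
* an **intracellular space**, exchanging with the extracellular space through
  a permeability term with conductance
  $PS_t = SpecPStc \times V_{ic,t}$ — the specific permeability–surface-area
  product (mL/s per mL of cell volume, converted to L/h) scaled by
  intracellular volume. The alternative normalization by total tissue volume
  is a one-line change; intracellular volume was chosen because the parameter
  is defined per mL of *cell* volume.

At equilibrium the intracellular-to-extracellular concentration ratio
approaches the tissue-to-plasma partition coefficient $Kp_t$ (next section).

**Unbound-driven membrane exchange.** The exchange flux is
$PS_t\,fu_t\,(C_{ec,t} - C_{ic,t}/Kp_t)$: only unbound drug crosses the cell
membrane, so the rate carries the tissue extracellular unbound fraction
$fu_t$. This is the convention under which the bundled `SpecPStc` values were
calibrated, and it matters enormously here: MTMSA-Trp has a plasma unbound
fraction of 0.1%, so at the same `SpecPStc` it enters cells roughly three
orders of magnitude more slowly than a moderately bound compound. Dropping
the $fu_t$ factor (available as `ps_driving = "total"` in `pbpk_model()`)
would let MTMSA-Trp equilibrate with tissue within a day and roughly halve
its projected 24-h plasma exposure relative to MTM; under the unbound
convention the analog stays largely confined to plasma, extracellular water
and the (unbound-accessible) adipose space, which is what the projected
exposure contrast reflects. Only the *rate* differs between the two
conventions — the equilibrium ratio, mass balance, dose linearity and the
$AUC_{0-\infty} = Dose/CL$ identity are unaffected.

**Clearance construct.** The elimination pathways of both compounds are not
mechanistically resolved, so the model uses an empirical systemic clearance
acting on total venous plasma concentration at rate
$CL \times C_{plasma}$. Observed (NCA-derived) clearances are supplied as
inputs in the preclinical models, and projected clearances in the human
model. Because all elimination is proportional to the sampled plasma
concentration, $AUC_{0-\infty} = Dose/CL$ holds exactly and independently of
every distribution parameter — the workhorse oracle of the test suite.

## Tissue partition coefficients

`predict_kp()` implements the Poulin–Theil tissue-composition method with the
extracellular-protein unbound-fraction derivation. For non-adipose tissue

$$Kp_t=\frac{P\,V_{nl,t}+(0.3P+0.7)\,V_{ph,t}+V_{w,t}}
            {P\,V_{nl,p}+(0.3P+0.7)\,V_{ph,p}+V_{w,p}}
      \times\frac{fu_p}{fu_t},\qquad P = 10^{logP},$$

with the tissue unbound fraction derived from the plasma unbound fraction
through the tissue-to-plasma extracellular protein ratio $RA$:

$$fu_t = \frac{1}{1 + RA\,(1-fu_p)/fu_p}.$$

Adipose uses the method's variant with the vegetable-oil/water partition
$D^{*} = 10^{1.115\,logP - 1.35}$ in place of $P$ and $fu_t = 1$. The
composition constants (neutral lipid, phospholipid and water volume
fractions per tissue, and rodent vs primate plasma composition) are bundled
from the original method publication and recorded in the physiology data
files; $RA$ is 0.5 for all tissues except brain (0.15, reflecting the low
protein content of brain interstitial fluid). Ionization is deliberately
ignored: the method as published uses logP, not logD, and no logD values are
available for these compounds. The commercial implementation that produced
the reference projections uses a proprietary extracellular-fu derivation, so
some Kp discrepancy is expected and is absorbed by the 2-fold evaluation
band used throughout.

## Species physiology

The bundled physiologies (mouse 0.025 kg, rat 0.25 kg, cynomolgus monkey
5 kg, and a 13-year-old 50-kg male human chosen to match the adolescent
Ewing-sarcoma setting) are assembled from open literature: fractional organ
weights and flows from the Brown et al. (1997) compilation, cardiac output,
blood volume and GFR from Davies & Morris (1993) and related sources. Key
constants, all overridable from the YAML files or `species_physiology()`
overrides:

| species | body weight | cardiac output | GFR |
|---|---|---|---|
| mouse | 0.025 kg | 0.84 L/h | 14 mL/min/kg |
| rat | 0.25 kg | 4.44 L/h | 5.2 mL/min/kg |
| monkey | 5 kg | 65.2 L/h | 2.5 mL/min/kg |
| human (13 y male) | 50 kg | 276 L/h | 100 mL/min absolute |

The monkey GFR sits mid-range of reported cynomolgus iohexol/creatinine
clearances (2.0–3.5 mL/min/kg); the human value is the documented constant
for a 13-year-old 50-kg male (about 120 mL/min/1.73 m² at a body surface
area of 1.5 m²). Every physiology is validated on load: positive finite
volumes and flows, extracellular fractions in (0, 1), and non-lung flows
summing to cardiac output within 1%.

## The middle-out workflow

1. **Observed clearances.** Raw preclinical concentration data are not
   publicly printed; observed clearances are derived as $CL = Dose/AUC$ from
   the published study-level AUCs bundled in
   `inst/extdata/observed_auc.csv`. Where a species was studied at two dose
   levels (monkey), the higher dose is used — the published low-dose
   MTMSA-Trp study itself fell outside the 2-fold acceptance band.
2. **Calibration.** `fit_spec_pstc()` optimizes `SpecPStc` against mouse
   plasma PK with the relative least-squares objective
   $\sum_i (C_{obs,i}-C_{pred,i})^2 / C_{pred,i}^2$ (1/prediction² weights),
   searched on $\log_{10}$ scale over $[10^{-6}, 1]$ mL/s/mL — the two
   compounds' calibrated values (2.95×10⁻², 1.23×10⁻⁴) span two orders of
   magnitude. Clearance stays fixed at its NCA value during calibration. The
   parameter is informed almost entirely by the distribution phase, so the
   calibration design samples densely before 30 minutes; with sparse early
   sampling the fit is noise-dominated.
3. **Cross-species evaluation.** The calibrated permeability is held constant
   and the rat/monkey studies are simulated with species-specific physiology,
   fup and BPR; `evaluate_profile()` scores each study (below). The monkey
   BPR of MTMSA-Trp is the published fit-adjusted 0.02 — an input, not a
   fitted quantity here.
4. **Human clearance** by three methods (`project_human_clearance()`):
   * *additional clearance* — each species' observed clearance is split into
     renal filtration $CL_R = fu_p \times GFR$ and a residual $CL_{add}$;
     the percentage $\%CL_{add} = CL_{add}/CL_{obs}\times 100$ is averaged
     geometrically across mouse, rat and monkey, and
     $CL_{human} = CL_{R,human}/(100-\overline{\%CL_{add}})\times 100$;
   * *allometry* — $CL = a\,BW^b$ fitted by ordinary least squares on
     log-log scale to the three species' **absolute** clearances (the
     standard unit convention for the power law; per-kg inputs are converted
     first) and extrapolated to 50 kg;
   * *single-species scaling* — monkey clearance scaled by
     $(50/5)^{0.75}$.
5. **Human simulation.** MTM: 13 µg/kg as a 6-h infusion daily ×7 (the
   clinical regimen), evaluated over the 24 h after the first dose; both
   compounds: 13 µg/kg single IV bolus for 24 h at 30-minute intervals,
   summarized as plasma and liver AUC, liver partition
   ($AUC_{liver}/AUC_{plasma}$), and exposure ratios versus the MTM
   comparator (which uses the additional-clearance method, the best
   performer against the clinical MTM data).
6. **Sensitivity analysis** (`psa()`): one-at-a-time scans of BPR
   ({0.02, base, 1} — the monkey-adjusted lower value and a generally
   accepted upper assumption), fup (10-fold either side) and logP (3-fold
   change in $P=10^{logP}$, i.e. ±log₁₀3; the alternative reading of ±3 logP
   units is exposed via `logp_scan_scale = "units"`), under the
   allometric-method human clearance. Because clearance is an input, the fup
   scan barely moves exposure; BPR dominates, via both the blood-side
   drug-carrying capacity and the plasma/blood conversion.

`run_workflow()` executes all stages end to end, deterministically for a
fixed seed, and writes one CSV per stage.

## Evaluation statistics

`evaluate_profile()` reports, for a time-matched predicted/observed pair:
the AUC ratio over a stated window (both AUCs by the log-linear trapezoidal
rule: logarithmic trapezoid on strictly decreasing positive intervals,
linear otherwise), the average fold error
$AFE = 10^{\operatorname{mean}(\log_{10}(pred/obs))}$, the log-scale
$RMSE = \sqrt{\operatorname{mean}((\log_{10}pred-\log_{10}obs)^2)}$, and the
acceptance flag $0.5 \le$ AUC ratio $\le 2$. Logs are base 10 (the AFE
definition, written as a power of 10, fixes the base). Predictions are
matched to observed timestamps by log-linear interpolation of the densely
sampled predicted curve — the same convention as the AUC rule — and
below-quantification observations are excluded with a count.

## Synthetic "observed" studies

The raw concentration data behind the published study-level AUCs are not
public, so `make_study()` generates synthetic stand-ins: the engine simulates
the study design, a clearance is found by root-finding so the noise-free
log-trapezoid AUC over the sampling window matches the published AUC within
0.5%, and multiplicative log-normal noise (default CV 15%, the typical
LC-MS/MS bioanalytical scale) is applied with a fixed seed, with optional
LLOQ censoring. Sampling schedules default to a typical serial design
(0.083–24 h, denser before 30 min for the mouse calibration species); they
are configurable. One study — low-dose monkey MTMSA-Trp — has a published
AUC above what any clearance can produce in this model (the published model
underpredicted it 0.46-fold too); for that study `make_study_set()` rescales
the noise-free profile to the published level, with a warning.

These stand-ins reproduce study-level exposure and realistic assay noise;
they do not reproduce the true curve shapes, inter-animal variability, or
dose-dependent disposition of the real datasets, so passing recovery and
evaluation tests demonstrates internal consistency of the pipeline, not
fidelity to the unpublished raw data.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable), rtol 1e-8, atol 1e-12 in
  amount units (µg); both overridable. Integration restarts at every dose
  boundary so zero-order infusion forcing is exact; at a bolus time the
  post-dose value is reported.
* An IV bolus enters the venous pool directly, producing a short venous
  spike that decays on the venous-transit timescale (seconds). On a 30-min
  output grid the first interval therefore carries a small
  positive bias in the trapezoid AUC; integrating a bolus profile to
  infinity in the tests uses sub-mixing-time resolution near $t=0$.
* Blood volume splits 2/3 venous, 1/3 arterial.
* The calibration search is bounded scalar minimization
  (`stats::optimize`) on $\log_{10}SpecPStc$; a fit at a search bound is
  flagged and warned.
* Duplicated NCA timestamps are rejected rather than averaged; AUC window
  truncation interpolates log-linearly at the window end.
* Workflow problem sizes: 24-h simulations on 30-minute grids (49 points),
  a 7-day human multiple-dose run, and 20-replicate noise studies for the
  calibration recovery checks.

## Known limitations

* **Liver (tissue) exposures are structurally different from the reference
  projections.** With a flow-connected extracellular space, total liver
  concentration cannot fall below roughly $f_{EC} \times C_{plasma}$
  (about 0.25 of plasma), whereas the reference workflow reported liver
  partitions of 0.06 (MTM) and 0.01 (MTMSA-Trp) — values that depend on the
  proprietary internal representation of tissue spaces and unbound fractions
  in the original software. This package's liver partitions come out an
  order of magnitude higher; the liver-to-liver exposure *ratio* between the
  compounds is much more robust. The original report itself labels tissue
  outputs exploratory and conditional on distribution assumptions; treat
  them the same way here.
* Plasma-side projections inherit the open-literature physiology; individual
  AUCs are verified only to the field-standard 2-fold band, while
  between-compound ratios, which share the physiology, are tighter.
* No oral absorption, enterohepatic recycling, metabolite tracking or
  saturable clearance: all regimens are IV and the system is linear by
  construction, so dose-dependent disposition reported for MTMSA-Trp in mice
  at higher doses is out of scope.
* Single fixed human (13 y, 50 kg male); no ontogeny or population
  variability.

## Reproducing the headline numbers

```{r, eval = FALSE}
library(mtmpbpk)
tab <- human_exposure_table()           # bolus comparison, 24 h
wf  <- run_workflow(seed = 1)           # the full pipeline
```

`scripts/acceptance.R` recomputes the seven headline quantities (three
plasma exposure ratios, two liver partitions, the liver exposure ratio, and
the multiple-dose MTM plasma AUC) from scratch and writes them as JSON; see
the README for invocation.
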