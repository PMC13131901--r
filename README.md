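# mtmpbpk

Whole-body, permeability-limited PBPK modeling for mithramycin (MTM) and its
tryptophan-conjugated analog MTMSA-Trp, built for the translational question
that motivates the compounds: *what plasma (and, exploratively, liver)
exposure should a first-in-human dose of MTMSA-Trp produce, given mouse, rat
and cynomolgus monkey pharmacokinetics and clinical MTM data?* The package is
aimed at DMPK / pharmacometrics scientists who want the full middle-out
workflow — calibration, cross-species evaluation, human clearance projection,
simulation, and sensitivity analysis — as ordinary, testable R functions with
tibbles in and out.

## The model

Each of twelve tissues is split into a flow-connected extracellular space and
an intracellular space exchanging through a permeability term; the lung sits
in series with the cardiac output, and the liver receives hepatic artery plus
portal flow. For tissue *t*:

```
V_ec dC_ec/dt = Q_t (C_art,b − BPR·C_ec) − PS_t fu_t (C_ec − C_ic/Kp_t)
V_ic dC_ic/dt =                            PS_t fu_t (C_ec − C_ic/Kp_t)
PS_t = SpecPStc × V_ic,t ,   C_blood = BPR × C_plasma
```

with Kp from the Poulin–Theil tissue-composition method (extracellular-
protein fu_t derivation; adipose uses the vegetable-oil variant), and an
empirical systemic clearance acting on venous plasma — so
`AUC(0–∞) = Dose/CL` exactly, the invariant the test suite leans on.
Human clearance is projected three ways: an additional-clearance approach
(renal filtration `fup×GFR` plus the geometric-mean non-filtration
percentage across species), three-species allometry `CL = a·BW^b`, and
single-species scaling from monkey with exponent 0.75.

## Worked example

```r
library(mtmpbpk)

# Method-1 human clearance for MTM, from the bundled published study AUCs
cl <- project_human_clearance("MTM", "additional")
cat(sprintf("human MTM CL %.2f L/h (CL_R %.2f L/h, mean %%CL_add %.1f)\n",
            cl$cl_human_L_h, cl$details$cl_r_human, cl$details$pct_cl_add_mean))
#> human MTM CL 7.69 L/h (CL_R 1.10 L/h, mean %CL_add 85.8)

# Human exposure comparison: both compounds at 13 ug/kg IV bolus, 24 h
tab <- human_exposure_table()
print(as.data.frame(tab[1:7]), digits = 3)
#>    compound         method cl_human_L_h auc_plasma auc_liver liver_partition
#> 1       MTM     additional        7.695        132      56.3           0.428
#> 2 MTMSA-Trp     additional        0.112       1363     332.0           0.244
#> 3 MTMSA-Trp     allometric        1.148        574     130.2           0.227
#> 4 MTMSA-Trp single_species        0.651        820     193.3           0.236
#>   ratio_plasma_vs_mtm
#> 1                1.00
#> 2               10.36
#> 3                4.36
#> 4                6.23
```

Reading the table: at an equal 13 µg/kg dose the model projects MTMSA-Trp to
reach roughly 4- to 10-fold higher human plasma exposure than MTM depending
on which clearance method is trusted (the additional-clearance method, which
best described the clinical MTM data, gives the largest contrast), driven by
its far lower projected clearance (0.11 vs 7.7 L/h). `auc_plasma` and
`auc_liver` are 24-h AUCs in ng/mL·h; `liver_partition` is their quotient.

The full pipeline — synthetic study generation, mouse SpecPStc calibration,
rat/monkey evaluation, clearance projection, human simulation and parameter
sensitivity analysis — runs with:

```r
wf <- run_workflow(seed = 1, out_dir = "outputs")
wf$psa_ranking   # BPR is the most influential parameter scanned
```

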