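# nirsrep

Test–retest reproducibility analysis for functional near-infrared
spectroscopy (fNIRS).

Within-subject fNIRS activation maps from repeated sessions of the same
task are notoriously variable, and the blame is usually put on global
systemic physiology. An alternative explanation is spatial: optodes are
repositioned imperfectly between sessions, so different channels sample
different cortex. `nirsrep` implements, end to end, the analysis needed
to weigh these explanations — and a forward simulator of the
acquisition, so every stage is testable against known ground truth.

The package is aimed at fNIRS methodologists and anyone running
longitudinal or multi-session optical brain-imaging protocols.

## What it computes

From dual-wavelength intensities to reproducibility statistics:

1. **Preprocessing** — SNR pruning (mean/SD < 8 at either wavelength),
   decadic optical density, spline (MARA-style) then wavelet
   (Daubechies-2, Tukey-fence thresholding) motion correction, the
   modified Beer–Lambert law with DPF = 6, and a zero-phase
   0.005–0.5 Hz Butterworth bandpass.
2. **Activation inference** — per-channel, per-chromophore GLM with a
   unit-peak gamma HRF, the nearest short-separation channel as a
   superficial nuisance regressor, AR prewhitening (Burg/AIC) with
   robust bisquare refitting, and the dual-chromophore rule: a channel
   is activated iff p(HbO) < 0.05, p(HbR) < 0.05, β(HbO) > 0 and
   β(HbR) < 0.
3. **Reproducibility** — for sessions *i*, *j* with activated-channel
   counts *A*:

       R_q = 1 − |A_i − A_j| / (A_i + A_j)     (size)
       R_o = 2 · A_overlap / (A_i + A_j)       (overlap, Dice-type)

   plus channel-frequency maps, inverse-variance-weighted group betas,
   group medians, and the regression of the variability complement
   v_q = 1 − R̄_q on relative heart-rate and blood-pressure changes,
   v_q = α + β·ΔHR + γ·ΔMAP.
4. **Registration** — SVD (Kabsch) rigid landmark alignment with
   fiducial registration error, the basis of neuronavigation-guided
   probe placement, with the 6 mm on-position check.
5. **Simulation** — complete synthetic test–retest studies: a
   14-source / 32-detector bilateral probe (64 long channels at 3 cm,
   4 short at 0.8 cm, 8.9 Hz), randomized finger-tapping block design,
   evoked responses under a Gaussian spatial sensitivity kernel,
   shared cardiac/respiratory/Mayer physiology, motion artifacts, and
   per-session probe displacement whose scale distinguishes guided
   (≤ 0.6 cm) from standard (~1.5 cm) placement.

## Worked example

```r
library(nirsrep)

## published per-subject benchmark values, shipped as plain text
tab <- benchmark_table("sessions")
summarize_medians(tab, by = "condition")
#>     condition delta_map_pct delta_hr_pct  R_q  R_o
#> 1    same_day           5.5         11.8 0.73 0.36
#> 2 across_days           8.3          8.9 0.66 0.04

## does systemic physiology predict variability? (it does not)
tab$v_q <- 1 - tab$R_q
variability_regression(tab, covariates = "fraction")
#>        term   estimate        se          t         p
#> 1     alpha  0.6326344 0.4728726  1.3378539 0.2227715
#> 2   beta_hr -0.4164669 2.9789823 -0.1398017 0.8927541
#> 3 gamma_map -1.6637679 3.8257886 -0.4348824 0.6767399

## simulate one session and recover the injected response
probe <- make_probe()
sched <- make_stim_schedule(seed = 1)          # 30 x 2 s blocks
truth <- make_ground_truth(probe)              # +0.8 / -0.3 uM focal response
rec   <- simulate_session(probe, sched, truth, seed = 1)
hb    <- preprocess(rec)
res   <- fit_session_glm(hb)
res[res$channel == which(truth$active), ]
#>   channel chromophore       beta         se         t            p ar_order converged
#> 1       1         HbO  0.8051846 0.04916774  16.37628 1.145414e-58       36      TRUE
#> 2       1         HbR -0.2793082 0.01817531 -15.36745 4.851147e-52       36      TRUE
```

The same-day medians (R_q 0.73, R_o 0.36) versus across-days medians
(0.66, 0.04) quantify how poorly a standard-placed probe reproduces an
activation map a day later; the regression shows heart-rate and
blood-pressure changes explain essentially none of that variability
(all p > 0.2). The simulated session demonstrates the chain recovering
an injected +0.8 µM HbO / −0.3 µM HbR focal response to within its
standard error through pruning, motion correction, Beer–Lambert
inversion, filtering and the prewhitened robust GLM.

For multi-session studies, `simulate_study()` + `run_pipeline()` take a
whole subjects × sessions design to per-subject R_q/R_o tables in one
call; `write_results()` emits the TSV bundle. A thin command-line
driver with `simulate` / `preprocess` / `activate` / `retest` /
`register` / `run` subcommands ships in `inst/cli/nirsrep`.

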