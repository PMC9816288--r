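# spbif

Kinetic modeling of dynamic [18F]-FDG PET with **abbreviated acquisition
protocols**: population-based input functions (PBIF), late-window tail-AUC
scaling, and Patlak graphical analysis — plus a synthetic dynamic-PET data
generator so the whole pipeline is testable without patient data.

## The problem

Quantitative FDG kinetic modeling needs the arterial input function (AIF),
the plasma tracer concentration over the whole scan. Long axial field-of-view
(LAFOV) scanners make a non-invasive image-derived input function (IDIF) from
the descending aorta practical, but capturing the bolus peak still forces an
hour-long dynamic acquisition. A way out is to use a *population* input
shape for the early curve and only measure the late tail:

1. **PBIF construction.** Training-set IDIFs are normalized to unit area,
   fitted with Feng's seven-parameter input model

   *C*p(*t*) = (*A*₁*t*′ − *A*₂ − *A*₃)·e^(−λ₁*t*′) + *A*₂·e^(−λ₂*t*′) +
   *A*₃·e^(−λ₃*t*′),  *t*′ = *t* − τ,

   aligned to the population mean delay τ, and averaged.
2. **Tail scaling (sPBIF).** For a new subject the PBIF is rescaled so its
   tail area matches the subject's measured IDIF tail AUC over a late window
   (35–65 … 55–65 min) — the only part of the scan that must be acquired.
3. **Patlak analysis.** Net influx *K*ᵢ (ml g⁻¹ min⁻¹) and distribution
   volume *V* are the slope/intercept of *C*t(*t*)/*C*p(*t*) against
   ∫₀ᵗ*C*p/*C*p(*t*) for frames after a start time *t**; raising *t**
   emulates a shorter scan.
4. **Evaluation.** Per-lesion percent bias against the IDIF/*t** = 35 min
   reference, precision (SD of bias), regression R², paired Wilcoxon tests
   on full-curve AUCs, and voxel-wise parametric-map fidelity (relative
   change, SSIM, PSNR).

The synthetic generator emulates an oncological cohort: Feng-shaped AIFs
with log-normal inter-subject variability and uniform delays, tumor and
gray-matter curves from the irreversible two-tissue-compartment model
(*K*ᵢ = *K*₁*k*₃/(*k*₂+*k*₃)), the 62-frame/65-min framing schedule, optional
variance ∝ value/duration frame noise, and small 4D phantoms.

## Worked example

```r
library(spbif)
res <- run_experiment(run_config(seed = 1, n_generation = 8, n_validation = 8),
                      outdir = "exp_out")
print(res)
```

prints (abridged):

```
Population-based input function (n = 8 subjects, T_ref = 65 min)
  mean delay: 0.692 min; unit-area dense curve on 0.01-min grid
  tau  = 0.6923 min
  A1   = 13.96   A2 = 0.01787   A3 = 0.01838
  lam1 = 17.34   lam2 = 0.2001   lam3 = 0.01022  [1/min]
AUC comparison over [0, 65] min, 8 subjects
      window auc_idif auc_spbif n_nonzero statistic p_value
 sPBIF_55-65    545.8     536.2         8        12  0.4609
 window t_star      tissue mean_bias precision r_squared  n failed
  35-65     35       tumor     0.859      1.21     1.000 32  FALSE
  55-65     35       tumor     0.998      2.31     0.999 32  FALSE
```

Reading this: the refit PBIF parameters sit near the canonical population
values (τ ≈ 0.69 min, λ₁ ≈ 17 min⁻¹); sPBIF and IDIF full-curve AUCs are
statistically indistinguishable (Wilcoxon p > 0.05); and tumor-lesion *K*ᵢ
from the sPBIF agrees with the IDIF reference to ~1% mean bias with ~1–2%
precision and R² > 0.99, pooled over 32 lesions. `exp_out/` holds the
evaluation table, AUC tables, the PBIF (JSON + dense-curve CSV),
parametric-map metrics, and a manifest with the full seed fan-out.

Individual stages are plain functions/S3 fits: `feng_fit()`,
`build_pbif()`, `scale_pbif()`, `patlak_transform()` + `patlak_fit()`,
`roi_patlak()`, `run_factorial()`, `generate_population()`,
`generate_phantom()`, `voxelwise_patlak()`, `image_metrics()`. A thin CLI
over the same functions lives at `inst/cli/spbif-cli.R`
(`simulate`, `make-pbif`, `scale-pbif`, `patlak`, `run-all`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the self-consistency
refit of the canonical population input parameters: it evaluates the Feng
model at the 62-frame schedule mid-times (no noise), runs the multi-start
bounded least-squares fitter, and reports the recovered amplitude `A1` (t3)
and fast eigenvalue `lam1` (t4) as JSON.

## Column orders

- TAC CSV: `frame_start_min,frame_end_min,value_kBq_ml`
- `eval_table.csv`: `window,t_star,tissue,mean_bias,precision,r_squared,n,failed`
- `auc_table.csv`: `subject,window,auc_idif,auc_spbif`
- `auc_tests.csv`: `window,n_nonzero,statistic,p_value`
- frame-timing sidecar JSON: `FrameTimesStart`, `FrameDuration` (seconds)
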