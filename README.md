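# dcepbpk

Subject-specific prediction of monoclonal antibody (mAb) concentrations in
solid tumors is hard: tumor perfusion and vascular permeability vary widely
between subjects and cannot be measured from a biopsy. `dcepbpk` implements an
MRI-informed PBPK workflow for R: dynamic contrast-enhanced MRI (DCE-MRI)
kinetic parameters, obtained with a small contrast agent, are used as
covariates on the transport parameters of a mechanistic tumor PBPK model, so
that a target-binding antibody's tumor pharmacokinetics can be predicted *a
priori* for each subject from that subject's own scan.

The package is aimed at quantitative pharmacologists and imaging scientists
working on antibody delivery in oncology, and at anyone who needs a tested,
reproducible reference implementation of this analysis chain.

## What it computes

**DCE-MRI kinetics.** Saturation-recovery T1 mapping
(`S(TR) = M0 (1 − e^(−TR/T1))`), spoiled-gradient-echo (SPGR)
signal-to-concentration inversion calibrated from pre-injection baseline
frames, and per-subject Patlak fitting with the subject's own arterial input
function:

    Ct(t) = Ktrans ∫₀ᵗ Cp dτ + Vp · Cp(t),   Ktrans ≥ 0, 0 ≤ Vp ≤ 1

solved exactly as a constrained linear least-squares problem (no iterative
optimizer).

**Tumor PBPK model.** A tumor compartment with vascular, endosomal and
interstitial spaces plus a cellular target layer: plasma flow `Q_TU`,
convective extravasation through a vascular reflection coefficient `σ_TU^V`,
lymphatic drainage, endosomal uptake with FcRn salvage and recycling, and
quasi-equilibrium EGFR binding with internalization of the complex
(`Cl_TMD = Kint · VI_TU`). Compiled-C right-hand side, stiff integration via
deSolve; `pbpk_equations()` prints the exact ODE system.

**Covariate modelling.** Candidate structures map Ktrans and/or Vp onto the
PBPK parameters,

    Q_TU = θ_Q · x        σ_TU^V = 1 / (1 + θ_σ · x)

fitted by maximum likelihood (proportional error, profiled variance, seeded
multi-start, weakly-informative shrinkage against a known identifiability
ridge) on a **non-binding** antibody cohort, compared by AIC, and then used
without refitting to predict a **target-binding** antibody per subject.

**Evaluation and synthesis.** Mean prediction error (absolute and signed),
AIC comparison tables, tumor-to-plasma ratio summaries by group and antibody,
a synthetic four-xenograft cohort generator, replicated operating-
characteristics studies (`covariate_study()`, `patlak_noise_study()`), and an
end-to-end pipeline driver (`run_pipeline()`) that writes CSVs plus a JSON
manifest.

## Worked example

Simulate the two study arms under a known Ktrans covariate structure, fit the
candidate structures to the non-binding arm, and predict the target-binding
arm a priori:

```r
library(dcepbpk)

truth  <- true_covariate_model()     # theta_q = 3.3e-3 L, theta_sigma = 12 min
noise  <- noise_model(obs_cv = 0.2)
nonbinding <- generate_cohort(group_phenotypes("non-binding"), truth,
                              tumor_params(), plasma_pk(), noise, seed = 42)
binding    <- generate_cohort(group_phenotypes("target-binding"), truth,
                              tumor_params(), plasma_pk(), noise, seed = 43,
                              antibody = "target-binding")

fits <- lapply(c(base = "base", population = "population", ktrans = "ktrans"),
               function(st) fit_population(nonbinding, st, tumor_params(),
                                           plasma_pk()))
tidy(fits$ktrans)
#> # A tibble: 2 × 3
#>   term               estimate unit
#>   <chr>                 <dbl> <chr>
#> 1 theta_q.ktrans      0.00591 L
#> 2 theta_sigma.ktrans 12.8     min

preds <- lapply(fits, predict_cohort, cohort = binding,
                base = tumor_params(), plasma = plasma_pk())
aic_table(unname(fits), unname(preds))
#> # A tibble: 3 × 7
#>   structure  n_params loglik   aic delta_aic   mpe mpe_signed
#>   <chr>         <dbl>  <dbl> <dbl>     <dbl> <dbl>      <dbl>
#> 1 ktrans            3   476. -946.       0    27.6       12.1
#> 2 population        3   445. -884.      62.4 177.       149.
#> 3 base              1   439. -876.      69.5 241.       227.
```

Reading the output: the fitted slopes land close to the generating values
(`θ_σ` 12.8 vs 12; `θ_Q` is recovered less sharply — it is weakly identified
from single terminal observations, see the vignette). AIC decisively prefers
the generating Ktrans structure, and the a priori mean prediction error on
the binding arm drops from 241% (fixed base parameters) and 177% (covariate-
free population fit) to 27.6% with the MRI covariate — the qualitative
pattern this workflow exists to deliver. `autoplot()` on a fit, a simulation,
or `plot_obs_pred()` on a prediction table give the standard diagnostics.

The methods vignette (`vignettes/mri-informed-pbpk.Rmd`) documents the model
equations, the error model, every tunable parameter with units and defaults,
what the synthetic cohorts do and do not emulate, and known limitations.

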