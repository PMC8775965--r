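---
title: "MRI-informed PBPK prediction of antibody tumor disposition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRI-informed PBPK prediction of antibody tumor disposition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcepbpk)
library(dplyr)
```

Monoclonal antibody concentrations achieved inside a solid tumor vary widely
between subjects, largely through differences in tumor perfusion and vascular
permeability that cannot be measured from a biopsy. DCE-MRI probes exactly
those transport properties with a small contrast agent. This package
implements the full chain that turns a subject's DCE-MRI examination into an
a priori, subject-specific PBPK prediction of antibody tumor pharmacokinetics:

1. **DCE-MRI kinetics** — saturation-recovery T1 mapping, SPGR
   signal-to-concentration conversion, and Patlak model fitting per subject
   with that subject's own arterial input function (AIF), yielding
   $K^{trans}$ and $V_p$.
2. **Tumor PBPK model** — a mechanistic tumor compartment (vascular,
   endosomal, interstitial spaces plus a cellular target layer) driven by the
   systemic plasma concentration, with FcRn salvage and target-mediated
   disposition.
3. **Covariate models** — slope relationships mapping the MRI parameters onto
   the PBPK parameters for tumor plasma flow ($Q_{TU}$) and the vascular
   reflection coefficient ($\sigma^V_{TU}$), fitted by maximum likelihood on a
   non-binding-antibody cohort and then used, without refitting, to predict a
   target-binding antibody in new subjects.
4. **Evaluation** — mean prediction error (MPE), AIC structure selection, and
   tumor-to-plasma ratio summaries.
5. **Synthetic cohorts** — a generator that emulates the four-xenograft study
   design so the whole chain is testable without any animal data.

## The DCE-MRI kinetic layer

Pre-contrast T1 is estimated from a saturation-recovery series
$S(TR) = M_0\,(1 - e^{-TR/T_1})$ by profiled least squares: $M_0$ is linear
given $T_1$, so a one-dimensional search over $\log T_1$ suffices and needs no
starting values. T1 values outside the range resolvable by the sampled
recovery times (default 200–5000 ms) are flagged as degenerate rather than
silently clipped.

Dynamic signal is converted to contrast concentration by inverting the
spoiled-gradient-echo steady-state equation
$S = M_0 \sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)$, $E_1 = e^{-TR \cdot R_1}$,
with $M_0$ calibrated from the mean of the pre-injection baseline frames and
$R_{10} = 1/T_{10}$. Concentration then follows from linear relaxivity,
$C(t) = (R_1(t) - R_{10})/r_1$. The relaxivity default (3.3 L mmol⁻¹ s⁻¹,
about right for gadobutrol at high field) is a package assumption and should
be set per agent and field strength. Frames whose signal implies $E_1$
outside $(0,1)$ — e.g. above the SPGR saturation ceiling — are flagged and
excluded from fitting.

The Patlak model assumes no reflux of contrast agent from the interstitium
(hence no $K_{ep}$ or $V_e$):

$$C_t(t) = K^{trans}\int_0^t C_p(\tau)\,d\tau + V_p\,C_p(t).$$

Because this is linear in $(K^{trans}, V_p)$, the constrained least-squares
problem ($K^{trans} \ge 0$, $0 \le V_p \le 1$) is solved exactly by
enumerating the KKT candidates of the two-parameter normal equations — no
iterative optimizer, no tuning, deterministic by construction. The plasma
integral uses the trapezoid rule on the frame grid, always from scan start;
the default fit window is all post-injection frames (configurable). Whether
$V_p$ should also be capped at 1 is not settled usage; the package constrains
to $[0,1]$ and reports which constraints are active.

## The tumor PBPK compartment

States are molar *amounts* in the vascular, endosomal and interstitial
sub-compartments. All volumes grow as $V_0 e^{k_{growth} t}$, so dilution by
growth is implicit in the amount-to-concentration map. Exact equations are
printed by `pbpk_equations()`. Transport terms:

* vascular exchange with plasma: in $Q_{TU} C_p$, out $(Q_{TU}-L_{TU}) C_v$;
* convective extravasation $(1-\sigma^V_{TU}) L_{TU} C_v$ and lymphatic
  drainage $(1-\sigma^L_{TU}) L_{TU} C_{i,free}$;
* endosomal uptake $Clup_{TU}$ from both the vascular and interstitial sides;
  FcRn-bound antibody is recycled ($FR$ to vascular, $1-FR$ to interstitial)
  and unbound antibody is catabolized at $Cl_{TU}$;
* interstitial EGFR binding at quasi-equilibrium, with the complex
  internalized at $Cl_{TMD} = K_{int} \cdot VI_{TU}$.

Two binding treatments are deliberately different. EGFR binding solves the
full quadratic mass balance on totals (`egfr_bound()`), because interstitial
antibody and receptor concentrations are commensurate and saturation is the
phenomenon of interest. FcRn binding uses the receptor-excess limit — a
constant bound fraction $C_{FcRn}/(C_{FcRn}+K_{D,FcRn}) \approx 0.956$ —
because endosomal FcRn (16.4 µM) exceeds tracer-dose antibody by orders of
magnitude; this matches the lineage of tumor PBPK models this compartment
descends from and keeps the no-target system exactly linear in dose (a
property the test suite checks to 10⁻⁸). The dissociation constants are
treated as molar quantities throughout.

The systemic side is a *forcing function* — biexponential disposition or a
tabulated plasma curve — not a whole-body model. This is the single largest
structural simplification in the package: tumor uptake is assumed not to
feed back measurably on plasma kinetics, which is excellent for a tumor
compartment this small. The biexponential defaults (mouse, 1 mg/kg, central
volume 1.2 mL, half-lives ≈ 8 h and 4 d) are generic murine IgG kinetics.
For the mass-balance audit the model can be flipped to a closed
configuration (`closed = TRUE`) in which plasma is a finite compartment and
lymph returns to it; with catabolism and target binding off, total antibody
is conserved to solver precision.

The right-hand side is compiled C integrated with `deSolve::lsoda` (relative
tolerance 10⁻⁸, absolute tolerance 10⁻¹² of the molar dose, both
configurable). Population fitting evaluates many subjects per likelihood
call, so all subjects of a cohort are integrated as one block-diagonal system
with a banded Jacobian — identical dynamics, one solver call instead of 26.

## Covariate models and population fitting

The candidate structures relate the MRI parameters to $Q_{TU}$ and
$\sigma^V_{TU}$:

$$Q_{TU} = \theta_Q \cdot x, \qquad
  \sigma^V_{TU} = \frac{1}{1 + \theta_\sigma \cdot x},$$

where $x$ is $K^{trans}$, $V_p$, or (two-covariate structure) the additive
linear predictor $\theta_1 K^{trans} + \theta_2 V_p$ in both equations — the
simplest extension that preserves the single-covariate forms, since no
functional form for the combination is established. The reciprocal form keeps
$\sigma^V_{TU}$ in $(0,1]$ for any non-negative slope and covariate. A
subject whose predictor is exactly zero has $Q_{TU}=0$ and is not predictable
under the slope model; the package raises an error naming the subject rather
than imputing. Under the two-covariate structure a $V_p=0$ subject is
retained (the predictor simply loses its $V_p$ term).

One modelling choice is ours: lymph flow. The base parameter set has
$L_{TU} = 0.04\,Q_{TU}$, and when a covariate rescales $Q_{TU}$ over more
than an order of magnitude, keeping $L_{TU}$ fixed would let lymph flow
exceed plasma flow for poorly perfused tumors, which is unphysical (lymph is
filtrate of the perfusing plasma). The package therefore preserves the base
lymph:plasma flow ratio whenever $Q_{TU}$ is set by a covariate or a
population fit.

Fitting uses each subject's single terminal tumor observation under a
proportional (lognormal) error model. The residual variance is profiled out
analytically; the remaining fixed effects are optimized by Nelder-Mead on the
log (slopes) or log/logit (population $Q_{TU}$, $\sigma^V_{TU}$) scale with
seeded multi-start. Two stabilizers are built in and documented in
`fit_settings()`:

* a generous finite search box (±12 log units around the physiological
  initial values), because slope values many orders of magnitude from any
  physiology only stiffen the ODEs;
* weakly-informative shrinkage (log-scale SD of one order of magnitude)
  toward the physiological initial values. With one observation per subject
  the two slopes share an identifiability ridge: as $\theta_\sigma \to 0$
  the wall becomes fully reflective for every subject and only the product
  $\theta_Q\theta_\sigma$ is determined, so pure maximum likelihood
  occasionally runs to arbitrarily extreme slope pairs on noisy cohorts.
  The penalty is negligible within an order of magnitude of the initial
  values, rules out the ridge endpoints, and can be switched off
  (`prior_sd = Inf`). Reported log-likelihoods and AIC are always the
  unpenalized likelihood at the estimate.

Each subject contributes one observation, so inter-individual random effects
on the slopes are not identifiable; the model fits fixed effects only.
Model comparison uses $AIC = -2\,\mathrm{loglik} + 2p$ with $p$ = fitted
fixed effects + 1 error parameter, ties broken by fewer parameters. The
population fit is assessed with a single $(Q_{TU}, \sigma^V_{TU})$ pair
shared across tumor groups by default (per-group fits are possible by
fitting groups separately). Published AIC values from other estimation
machinery are not comparable in absolute terms; only orderings are
meaningful, and orderings are what the package's acceptance checks assert.

A priori prediction of a target-binding antibody uses the slopes fitted on
the non-binding cohort, the subject's own MRI parameters, and the group's
EGFR expression — no refitting to binding-arm data (`predict_individual()`,
`predict_cohort()`).

## Evaluation conventions

MPE is reported as mean *absolute* percent error,
$100/N \sum_i |pred_i - obs_i|/obs_i$; since the convention is not universal,
the signed variant is always computed alongside under a distinct name.
Tumor-to-plasma ratio tables report group means to two decimals and compute
each group's binding/non-binding ratio from those two-decimal means (matching
how such summary tables are typically printed), with full precision retained
internally everywhere else.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` reproduces the statistical structure the analysis
assumes: four xenograft groups with distinct vascular phenotypes (two
well-perfused lines; an anti-angiogenic-treated line with ~10-fold lower
$K^{trans}$; a stroma-rich line with frequent $V_p = 0$, implemented as a
point mass), 26 non-binding and 23 target-binding subjects (10/7/5/4 and
9/6/5/3 per group), one terminal observation per subject allocated
round-robin over {3 h, 8 h, 1 d, 3 d, 6 d} within each group so even the
smallest group covers early and late times, 70 DCE frames at 17 s with
injection 2 min into the scan, per-subject AIF jitter, and proportional
(lognormal) observation error with 20% CV as the default study condition.
Inter-individual variability magnitudes for $K^{trans}$ and $V_p$ are not
established quantities; the defaults (log-SD 0.4 for $K^{trans}$; truncated
normal $V_p$) are fixed, realistic choices, not measurements. The AIF is a
bolus biexponential stand-in — every downstream operation accepts arbitrary
tabulated AIFs, as real analyses use measured per-subject input functions.

Not emulated: voxel-level images, Rician noise, motion, segmentation error,
field inhomogeneity, injection failures. Passing tests on synthetic cohorts
therefore demonstrate the *estimation machinery* — recovery of generating
parameters, correct model selection under the assumed error structure — not
robustness to the full messiness of in vivo imaging data.

## Numerical choices and problem sizes

* Patlak and T1 fits are deterministic linear/1-D problems; no seeds.
* ODE tolerances: rtol 10⁻⁸, atol 10⁻¹² × molar dose; mass balance in the
  closed configuration holds to ~10⁻¹⁵ over six simulated days.
* All randomness flows through explicit integer seeds (`withr::with_seed`);
  fixed seed means byte-identical cohorts, curves and pipeline outputs.
* The built-in operating-characteristics study (`covariate_study()`) uses 20
  replicates of the full 26 + 23 subject design at 20% observation CV, and
  the Patlak noise study uses 200 simulated tumors at 5% signal noise —
  sizes chosen to estimate bias/RMSE and selection frequencies on a single
  CPU in a few minutes while keeping Monte Carlo error well below the
  effects being measured.

## Known limitations

* The plasma forcing function ignores any feedback of tumor binding on
  systemic kinetics and, by default, uses generic murine IgG disposition.
* Free EGFR is held at constant total expression (no synthesis/degradation
  dynamics beyond complex internalization).
* $\theta_Q$ is weakly identified from single terminal observations; its
  reported RMSE at 20% observation CV is large and heavy-tailed even with
  shrinkage. Richer sampling designs (serial observations per subject) would
  be needed to pin it down — the estimator is honest about this.
* The covariate search space is fixed to the candidate set described above;
  no structure discovery beyond it.
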