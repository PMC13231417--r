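# ribopk

Translational pharmacokinetics of mRNA-encoded antibodies.

mRNA-LNP therapeutics deliver a nucleoside-modified mRNA, packaged in a
lipid nanoparticle, that is taken up mainly by hepatocytes and
translated there into a secreted therapeutic protein — including full
antibodies ("RiboMabs") and antibody-like formats. Selecting a
first-in-human dose for such a product requires predicting the human
exposure of the *translated* protein from preclinical data, which
confounds two cross-species trends: antibody disposition (which scales
like recombinant antibodies) and translational efficiency (which
decreases with body weight). `ribopk` implements both prediction layers
used for this problem, for pharmacometricians and DMPK scientists:

1. **Simple allometric scaling** of dose-normalized exposure. Exposure
   metrics obtained by noncompartmental analysis — DCmax = Cmax/Dose
   (1/mL) and DAUC = AUC<sub>0–∞</sub>/Dose (h/mL) — follow the power
   law *P = P₀·Wᵅ* across species. Human values are projected from a
   single species with generalized exponents (−1.26 from mouse, −0.75
   from NHP), and a grid search over candidate exponents selects the
   value whose geometric-mean prediction error is closest to 1.

2. **A mechanistic translational model.** A linear ODE system couples
   first-order mRNA-LNP elimination (*k*<sub>elim</sub>), first-order,
   non-consumptive translation into antibody (*k*<sub>translate</sub>),
   and one- or two-compartment antibody disposition (CL, V₁, V₂, Q):

   dM/dt = −*k*<sub>elim</sub>·W^α · M
   dA₁/dt = *k*<sub>translate</sub>·W^α · M − (CL/V₁)·A₁ − (Q/V₁)·A₁ + (Q/V₂)·A₂
   dA₂/dt = (Q/V₁)·A₁ − (Q/V₂)·A₂

   with every parameter carrying its own body-weight power law. The
   model is fitted to multispecies concentration–time data by pooled
   maximum likelihood with proportional residual error, or to a single
   species and then projected to human with fixed exponents
   (*k*<sub>elim</sub> −0.10, CL 0.80, V₁/V₂ 1, Q 0.65,
   *k*<sub>translate</sub> −0.51 from mouse and 0 from NHP). The
   dose-normalized AUC has the closed form
   DAUC = *k*<sub>translate,eff</sub> / (*k*<sub>elim,eff</sub> · CL<sub>eff</sub>),
   independent of dose and volumes.

Prediction accuracy is reported as fold error,
max(pred/obs, obs/pred), with ≤ 2-fold the conventional acceptance
bar. Because the underlying clinical datasets are not public, the
package ships a synthetic-study generator with the stated statistical
structure (log-normal between-subject variability, proportional
residual error, BLQ flagging) so every analysis is runnable end to end.

## Worked example

```r
library(ribopk)

params <- ribomab01_params()             # published RiboMab01 model
params$omega <- c(cl = 0.25, k_translate = 0.25)
design <- default_study_designs()[["bnt141-like"]]
ds <- generate_study(design, params, seed = 11, sigma = 0.15)
ds
#> PK dataset: 48 subjects, 540 observations, 48 dose events
#> Species: human (108 obs), mouse (144 obs), nhp (144 obs), rat (144 obs)

res <- nca(ds)                            # per-subject NCA
subset(summary(res), parameter == "dcmax" & species == "nhp")
#>    species dose parameter  n       mean         sd   cv_pct     median
#> 17     nhp  500     dcmax 12 0.02779288 0.00435203 15.65880 0.02728889
#>      geo_mean geo_cv_pct        min        max
#> 17 0.02748304   15.76311 0.02043679 0.03684613

# multispecies power law on the geometric-mean DCmax
gm <- aggregate(dcmax ~ species + weight, data = res,
                FUN = function(x) exp(mean(log(x))))
fit_power_law(gm$weight, gm$dcmax)
#> Allometric power law: P = 0.08005 * W^-1.304  (n = 4, R^2 = 0.9996)
#>   exponent SE = 0.01783

# fold errors recomputed from the published observed/predicted values
summary(prediction_report(reference_exposure_predictions()))
#>      method source_species n max_fold geo_mean_fold
#> 1 allometry          mouse 4 4.444444      2.381952
#> 2 allometry            nhp 6 2.210526      1.539873
#> 3     model          mouse 4 3.589744      2.776143
#> 4     model            nhp 6 1.500000      1.258240

closed_form_dauc(params, weight = 70)     # human DAUC, h/mL
#> [1] 0.2391751
```

The NCA table shows the synthetic NHP arm's dose-normalized Cmax
(geometric mean ≈ 0.027 1/mL at the 2.5 kg default weight); the
power-law fit recovers a multispecies DCmax exponent near −1.3, the
inverse exposure–weight relationship characteristic of these products.
In the fold-error summary, mouse-based allometry errs up to 4.4-fold
while NHP-based predictions stay near the 2-fold bar (the 2.21 NHP
entry is the external-validation compound), and the model-based NHP
projections are the tightest at ≤ 1.5-fold. The closed-form human DAUC
of the fitted RiboMab01 model is 0.239 h/mL.

Single-species projection to human follows the same grammar:

```r
nhp_fit <- fit_single_species(nhp_data, fixed = c(v1 = 100.25, v2 = 114),
                              seed = 1)
wf <- model_projection_workflow(nhp_fit, scaling_config("nhp"),
                                dose_regimen(0, 3000, duration = 1),
                                human_observed = obs_table)
wf$report                                  # DCmax/DAUC fold errors
```

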