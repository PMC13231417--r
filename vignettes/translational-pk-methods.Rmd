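---
title: "Methods: allometric scaling and translational modelling of mRNA-encoded antibodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allometric scaling and translational modelling of mRNA-encoded antibodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopk)
```

## The scientific problem

After intravenous administration of an mRNA-LNP, the lipid
nanoparticles are cleared from circulation (enzymatic degradation,
hepatic uptake), the mRNA is translated in hepatocytes, and the encoded
antibody is secreted into plasma where it distributes and is eliminated
like a recombinant antibody. The observable is the plasma concentration
of the *translated* antibody; the administered dose is micrograms of
mRNA-LNP. Exposure per unit dose falls steeply with species size: both
because clearance grows with weight (roughly $W^{0.75\text{–}0.8}$, as
for recombinant antibodies) and because translational efficiency per
unit mRNA decreases in larger species, in line with the general decline
of cellular metabolic rates with body size. Predicting first-in-human
exposure therefore requires either an empirical exponent that lumps
both effects, or a mechanistic model that separates them. `ribopk`
implements both.

## Layer 1: allometry of dose-normalized exposure

Noncompartmental analysis (`nca()`) reduces each concentration–time
profile to Cmax, AUC$_{0\text{–last}}$, AUC$_{0\text{–}\infty}$,
$\lambda_z$ and half-life, and the dose-normalized DCmax $=$ Cmax/Dose
(1/mL) and DAUC $=$ AUC$_{0\text{–}\infty}$/Dose (h/mL). Numerical
choices, all standard NCA practice but worth stating because no single
convention is universal:

* **AUC rule.** Linear trapezoid on rising or zero-bounded segments,
  log trapezoid $(C_1-C_2)\,\Delta t/\ln(C_1/C_2)$ on strictly
  descending positive segments (`linuplogdown`, the common IV default);
  a pure linear rule is available.
* **Terminal slope.** $\lambda_z$ is the negated OLS slope of
  $\ln C$ vs $t$ over a terminal window. The automatic selector scans
  all windows ending at the last point, from 3 points up to every point
  strictly after tmax (tmax excluded), and keeps the window with the
  best adjusted $R^2$; ties within $10^{-4}$ go to the longer window.
  A non-negative slope or fewer than 3 usable points gives a flagged
  not-estimable result, not an error.
* **Extrapolation.** AUC$_{0\text{–}\infty}$ adds
  $\hat C_{\mathrm{last}}/\lambda_z$ using the *regression-predicted*
  concentration at $t_{\mathrm{last}}$ (switchable to the observed
  value); the extrapolated percentage is reported.
* **BLQ.** Observations below the limit of quantification are excluded
  from every computation (the simplest defensible rule; an LLOQ value
  is retained on the records for plotting).
* **Multiple dosing.** By default exposure is derived from the first
  dosing interval, with DAUC extrapolated to infinity from it —
  dose-1-based evaluation. `per_interval = TRUE` reports
  AUC$_{0-\tau}$ per interval instead; which convention a clinical
  summary used is often ambiguous, so both are available.

Across species, `fit_power_law()` fits $P = P_0\,W^{\alpha}$ by OLS of
$\ln P$ on $\ln W$ — the standard log-log treatment, matching the
straight-line behaviour of these data, rather than a weighted nonlinear
fit in the original scale. Single-species projection multiplies by
$(W_{\mathrm{target}}/W_{\mathrm{source}})^{\alpha}$ with the
generalized exponents $-1.26$ (mouse) and $-0.75$ (NHP).

`grid_search_exponent()` reproduces how such generalized exponents are
chosen: for each candidate $\alpha$ on a grid (default step 0.01, a
value we fixed since none is published), every source-species exposure
is projected to 70 kg and the geometric mean of predicted/observed
ratios is computed. The selected exponent minimizes
$|\ln(\text{geometric mean})|$ — i.e. no *systematic* over- or
under-prediction. An alternative reading averages folded ($\ge 1$)
errors; it is available via `fold = TRUE` but not the default, because
the ratio version is the one consistent with signed
"fold-difference of predicted over observed" errors and admits exact
cancellation. Ties prefer the exponent nearest the grid midpoint, then
the smaller magnitude. When DCmax and DAUC from several compounds are
supplied together, one joint exponent is selected — combined selection
is the default since the published exponents are shared across both
metrics.

## Layer 2: the translational model

States: mRNA-LNP amount $M$ (µg), central and peripheral antibody
amounts $A_1, A_2$ (µg). With effective (weight-scaled) parameters,

$$\frac{dM}{dt} = u(t) - k_{\mathrm{elim}}M, \qquad
\frac{dA_1}{dt} = k_{\mathrm{tr}}M
  - \frac{CL}{V_1}A_1 - \frac{Q}{V_1}A_1 + \frac{Q}{V_2}A_2, \qquad
\frac{dA_2}{dt} = \frac{Q}{V_1}A_1 - \frac{Q}{V_2}A_2,$$

observed concentration $C = A_1/V_1$ in µg/mL. Doses enter $M$ (no
other input is admissible in this structure) as bolus jumps or
zero-order infusions; a zero-duration infusion is treated as a bolus.
Translation does **not** consume mRNA: $k_{\mathrm{tr}}$ is a net
first-order production rate per unit of remaining mRNA-LNP, so total
antibody production for a dose $D$ is
$k_{\mathrm{tr}} D/k_{\mathrm{elim}}$ and

$$\mathrm{DAUC} =
\frac{k_{\mathrm{tr,eff}}}{k_{\mathrm{elim,eff}}\,CL_{\mathrm{eff}}},$$

independent of dose (linearity) and of $V_1, V_2, Q$. This closed form
(`closed_form_dauc()`) is used as an internal oracle throughout the
test suite. The model deliberately excludes saturation of hepatic
translational capacity, time-decaying translation, target-mediated
disposition, FcRn recycling and immunogenicity on repeat dosing.

**Parameter semantics.** Stored parameter values are the power-law
coefficients — the values of a 1 kg reference animal — with
per-parameter exponents: $p_{\mathrm{eff}} = p \cdot W^{\alpha_p}$.
Units like "mL/h/kg" in published tables are read this way (coefficient
at $W = 1$ kg), which is the only reading consistent with the scaled
differential equations. Reference sets: `ribomab01_params()`
(two-compartment; volumes fixed to the recombinant reference antibody,
volume exponents fixed at 1) and `ribomab02_params()` (one-compartment:
only one elimination phase is observable for that molecule, so $V_2$
and $Q$ are omitted).

**Simulation.** The system is linear with constant coefficients within
each dosing segment, so the default solver is exact: a spectral
(eigendecomposition) solution applied piecewise between dose
discontinuities, with boluses as state jumps and infusions via the
particular solution $-K^{-1}b$. When eigenvalues nearly coincide
(relative gap $< 10^{-8}$) the spectral route declines and
`tm_simulate()` falls back to a stiff-capable numeric route
(`deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-10}$ µg) that is
hard-restarted at every dose event so discontinuities are never stepped
over. The two routes serve as mutual cross-checks (agreement to
$10^{-6}$ relative in the test suite), and `closed_form_profile()`
exposes the single-bolus analytic solution directly.

**Cross-species projection.** `project_params()` carries effective
parameters between weights with fixed exponents
(`scaling_config()`): $-0.10$ for $k_{\mathrm{elim}}$, $0.80$ for $CL$,
$1$ for both volumes, $0.65$ for $Q$, and for $k_{\mathrm{tr}}$
$-0.51$ from mouse but $0$ from NHP — no translation-rate adjustment is
needed between NHP and human, the central empirical observation behind
NHP-based scaling of these products.

**Prediction bands.** Published profile figures show 10th/50th/90th
percentile bands without stating their construction; we compute them by
Monte Carlo over the log-normal between-subject distribution (default
500 seeded replicates, `tm_percentile_bands()`).

## Estimation

Population PK analyses of such data conventionally use nonlinear
mixed-effects estimation (FOCE-I or similar). `ribopk` deliberately
does not reimplement that machinery; its estimator is **pooled maximum
likelihood on log concentrations**:

$$\log C_{\mathrm{obs}} = \log C_{\mathrm{pred}}(\theta) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

the small-$\sigma$ limit of the proportional error model, with
$\sigma$ profiled analytically
($\hat\sigma^2 = $ mean squared log residual). The rationale: with
unpublished raw data, the reproducible quantity is recovery of the
fixed effects from synthetic data generated under the stated
variability structure, for which pooled ML is consistent and far
lighter; subject-level random effects are omitted from the likelihood.
When between-subject variability itself is of interest, a two-stage
mode is provided (`fit_two_stage()`): per-subject fits, then the SD of
log estimates as the empirical $\omega$. Single-subject fits of the
full structure are poorly identified (flip-flop between the mRNA and
disposition eigenvalues), so the supported pattern is to pool-fit the
structural parameters first and free only the variability-carrying
parameter(s) per subject — the classic "two-stage with population
constants" approach.

Technical choices: positivity of structural values via log transform,
exponents unconstrained; BFGS in transformed space with an accurate
central-difference gradient. The likelihood surface of the joint
multispecies problem is multimodal — a spurious mode exists in which
the mRNA and antibody disposition time scales partially exchange roles
(flip-flop) — so the fitter combines a deterministic *staged start*
(fit each species separately with exponents pinned, regress log
effective values on log weight) with multiple seeded jittered starts
around both anchors (default 10; best objective wins), from
literature-informed generic initial values (mRNA-LNP half-life of
order a day; antibody clearance $\sim$0.3 mL/h/kg with exponent 0.75).
Candidate parameter sets whose
simulation fails or leaves plausibility bounds return a large penalty
so the optimizer survives; standard errors by the delta method from the
inverse numeric Hessian of the profiled objective, reported as RSE%;
convergence flagged when the gradient norm is below $10^{-4}$ relative
to the objective magnitude. Identifiability guards reject a free
exponent with a single body weight and designs with fewer usable
observations than free parameters. BLQ observations are excluded from
the likelihood (M3-style censored likelihood is out of scope).

## The synthetic-study generator

`generate_study()` emulates the multispecies IV studies this framework
was built on: per subject, structural parameters are multiplied by
$e^{\eta}$, $\eta \sim N(0, \omega^2)$; profiles are simulated at the
arm's schedule; residual noise is
$C_{\mathrm{obs}} = C_{\mathrm{pred}}(1+\varepsilon)$,
$\varepsilon \sim N(0, \sigma^2)$, truncated at zero (the literal
proportional-error statement; a log-normal option matches the
estimator's log-scale likelihood — the difference at realistic
$\sigma$ is a $-\sigma^2/2$ log-bias, covered by a test). Observations
below the LLOQ — by default 1% of the arm's median Cmax, since only an
unannotated LLOQ line is published — are flagged BLQ. Each arm draws
from its own seed offset, so arms are independently reproducible.

Conditions the generator fixes (published): species weights 0.025,
0.25, 2.5, 70 kg; human sampling at end of infusion and 3, 6, 24, 48,
72, 168, 336, 504 h (one compound) or end of infusion and 3, 6, 10,
24, 48, 168 h (the other). Conditions that are *not* published and were
fixed here once as field-typical conventions: group sizes
(n = 12/species), preclinical dose levels (~1 µg in mouse to ~3 mg in
human — immaterial for estimation since the model is dose-linear),
1 h human infusions, the rich preclinical sampling grid (1–504 h,
12 samples), and $\omega$ magnitudes (unreported; the recovery
experiments therefore use residual noise only, $\sigma = 0.15$, and
test fixed effects — IIV recovery is exercised separately at
$\omega_{CL} = 0.3$). What passing recovery tests show is that the
estimator recovers the generating mechanism under the stated noise
structure; they cannot show robustness to model misspecification,
assay artefacts, immunogenicity or sparse clinical designs, none of
which the generator emulates.

One deliberate deviation from the stated error-model contract: a
warning for "more than half of residual draws truncated" can never
fire, since $P(1+\varepsilon < 0) = \Phi(-1/\sigma) < 1/2$ for every
$\sigma$; the guard therefore fires at 25% truncation, which already
indicates an implausible $\sigma$.

## Problem sizes and reproducibility

The recovery experiment behind the headline checks uses the
four-species, 12-subjects/species, single-bolus rich-sampling design
(576 observations) with $\sigma = 0.15$ — rich enough that pooled ML
recovers the generating rates within a few percent, small enough to
run in seconds thanks to the spectral simulator. The exponent-recovery
experiment uses 200 replicate four-species exposure sets at log-normal
CV 10%. All randomness flows from explicit integer seeds; the
acceptance script (`scripts/acceptance.R`) derives every stream from
its `--seed` argument.

## Known limitations

* Pooled ML understates uncertainty relative to mixed-effects
  estimation and can be biased when IIV is large; it targets fixed
  effects only.
* The model assumes constant translational capacity; sustained or
  repeated dosing that stresses hepatic production would violate it,
  as would target-mediated disposition of the antibody.
* Generalized exponents were derived from liver-targeting LNP products;
  other tissue tropism may scale differently.
* Published figure curves and the species-level exposure values behind
  the multispecies regressions are not printed and cannot be
  reproduced; the package's claims are anchored to the printed
  observed/predicted tables and to internal cross-route consistency.
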