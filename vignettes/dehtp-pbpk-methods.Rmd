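---
title: "A PBPK model for DEHTP with Bayesian calibration against urinary biomonitoring"
author: "dehtpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A PBPK model for DEHTP with Bayesian calibration against urinary biomonitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dehtpk)
```

## The problem

Di-(2-ethylhexyl) terephthalate (DEHTP) is a high-production-volume
substitute plasticiser. After an oral dose, the diester is hydrolysed to
its monoester MEHTP, which is oxidised further to the urinary
biomarkers 5OH-MEHTP, 2cx-MMHTP and 5cx-MEPTP; a large non-specific
fraction leaves as terephthalic acid (TPA). Human biomonitoring of such
a chemical yields a single informative data stream: metabolite
concentrations in timed urine voids. `dehtpk` implements a
physiologically based pharmacokinetic (PBPK) model for DEHTP and MEHTP,
derives its kinetic parameters from in vitro and in silico inputs,
converts urine-void records into bladder deposition rates, and
calibrates the model hierarchically with MCMC under a zero-truncated
normal error model. Because the original volunteer data are not
deposited, the package also generates fully synthetic volunteer studies
with the same statistical structure, which is what every end-to-end
test runs on.

## Parameter derivation

**In vitro intrinsic clearance.** MEHTP depletion in human liver
microsomes is summarised by a first-order decay constant $k$, fitted by
ordinary least squares of $\log$ concentration on time (replicate
incubations are fitted independently; their sampling schedules differ).
Then

$$ T_{1/2} = \ln 2 / k, \qquad
   CL_{in\,vitro} = \frac{\ln 2}{T_{1/2}}
     \cdot \frac{\text{ml incubation}}{\text{mg microsomes}}, $$

with the default assay geometry 1 ml incubation and 0.5 mg microsomal
protein. Scale-up to the organ uses the microsomal protein yield (MPY,
mg/g) and the organ mass $V$ (g):
$CL_{int} = CL_{in\,vitro} \cdot MPY \cdot V \cdot 60/1000$ L/h. The
printed form of this scale-up yields ml/h; the division by 1000 makes
the unit label (L/h) dimensionally consistent with the well-stirred
clearance formula

$$ CL_H = \frac{Q_H\, fu\, CL_{int,H}}
               {Q_H + fu\, CL_{int,H}/(C_{RBC}/C_P)}, $$

whose denominator follows the printed operator precedence. A gut-wall
intrinsic clearance is derived the same way from $MPY_{gut}$ and the
gut mass; it is reported by `buildModel()` but does not enter the
differential equations, because metabolism of MEHTP is ascribed to the
liver alone. This also explains why calibration leaves $MPY_{gut}$ at
its prior: the likelihood cannot see it.

**Binding.** The plasma fraction unbound is predicted from
$\log P_{ow}$ by $fu = 1/(10^x+1)$ with $x = 0.4485 \log P - 0.4782$,
valid for chemicals essentially uncharged at pH 7.4. For DEHTP
($\log P = 9.54$) this gives $1.58\times10^{-4}$; the calibrated bound
fractions (FB $\approx$ 0.86) show the algorithm overpredicts binding
for such lipophilic chemicals by more than two orders of magnitude —
which is why FB is a calibrated parameter rather than an input.

**Partition coefficients.** Tissue:blood PCs predicted by
tissue-composition algorithms are inputs, managed by a table with
surrogate fallbacks: compartments without a direct prediction borrow
the value of a tissue with similar perfusion (stomach from gut, rapidly
perfused from spleen, slowly perfused from muscle), resolved in exactly
one hop.

## Model structure

All first-order, amounts in mg, volumes in L (density 1), flows in L/h,
time in h. An oral bolus splits structurally into three streams that
sum to unity: a fraction `FracDOSEHep` enters the stomach lumen and is
absorbed into venous blood (stomach uptake `BELLYPERM`, gut-1 uptake
`GIPERM1`, gut-2 uptake `GIPERM2`); a fraction `FracDoseLymph` is taken
up via the intestinal lacteals and reaches venous blood at the thoracic
duct after the transport delay `Lymphlag`, bypassing first-pass
metabolism; the remainder passes through to faeces. DEHTP is
hydrolysed to MEHTP in the first intestinal segment (rate
$60\ln 2/T_{1/2,gut}$) and in the liver (rate $60\ln 2/T_{1/2}$).
Enterohepatic recirculation takes liver DEHTP into bile (first-order
`K1_DEHTP_Liver` on the liver amount) and returns it to the second
intestinal segment after a bile transit delay, where `GIPERM2` can
reabsorb it.

Distribution is flow-limited: each tissue exchanges with arterial blood
at its regional flow against its tissue:blood PC, and only the unbound
arterial fraction $(1-FB)$ distributes and is metabolised; the bound
stream passes to venous blood. Gut and stomach tissues drain portally
into the liver. Blood is modelled as whole blood; the plasma and
red-cell PCs (`Pbab`, `Prbcb` and MEHTP analogues) define an
equilibrium plasma/red-cell split (haematocrit 0.45) used for reported
concentrations and the $C_{RBC}/C_P$ ratio — they have no kinetic role
here, which is the package's reading of their near-uninformative
posteriors.

MEHTP formed in gut-1 splits three ways: a fraction `escapeFracgu`
enters venous blood directly (incomplete first-pass availability); of
the remaining portal stream, `escapeFracli` survives the first liver
pass into the MEHTP liver compartment and the rest is metabolised
immediately. Liver-formed MEHTP enters the MEHTP liver compartment.
Hepatic MEHTP metabolism is intrinsic clearance acting on the
venous-equivalent liver concentration, $CL_{int}\cdot
A_{li}/(V_{li}P_{li})$. Metabolised MEHTP splits instantaneously into
three tracked pools (fractions `FracMetabMOH`, `FracMetab2cx`,
`FracMetab5cx`) that drain into urine with first-order rates `K1_MOH`,
`K1_2cx`, `K1_5cx`, and a terminal TPA/non-specific pool (the
$1-\sum$ remainder, constrained to 0.3–0.6 by the priors) with no
kinetics of its own. 5oxo-MEHTP is not simulated (it is a metabolite of
5OH-MEHTP). Second-order metabolites are tracked in MEHTP-equivalent
mass and converted to their own molecular weights (294.35, 308.33,
308.33 g/mol; DEHTP 390.56, MEHTP 278.35) only at the urine output.

**Delays.** The lymph delay is exact: the lymph-destined bolus
undergoes no processing before arrival, so it is a scheduled state jump
at dose time + `Lymphlag`; that sharpness is what produces the distinct
second deposition peak seen in strongly lymphatic volunteers (e.g.
lymph fraction 0.26 with a 4.7 h lag). `Gutlag` is realised as a
five-stage Erlang chain forming the first intestinal segment — uptake
and gut metabolism act throughout the residence, and material reaches
the second segment after a mean delay `Gutlag`. Bile transit is a
five-stage Erlang chain with a fixed 2 h mean.

**Fixed structural parameters** the published tables do not provide,
chosen once on physiological grounds: gastric emptying 2 h$^{-1}$,
bile transit 2 h, MEHTP renal elimination from kidney 0.1 h$^{-1}$,
haematocrit 0.45, arterial fraction of blood volume 0.25.

**Numerics.** lsoda with relative tolerance $10^{-8}$ and absolute
$10^{-10}$ ($10^{-6}/10^{-9}$ inside the MCMC likelihood), compiled C
derivatives cross-checked against a pure-R reference implementation.
Integration restarts at every dose and lymph-arrival time; stored
trajectories are right-continuous at jumps. Mass balance is audited in
DEHTP equivalents, counting lymph-destined mass in transit during its
delay; the residual stays below $10^{-6}$ of dose, and every flux is
written so conservation is exact up to solver error (the tolerance
sweep in the tests shows the residual growing as tolerances loosen).

## Observation model and calibration

Void records (time, volume, concentration per metabolite) become
deposition-rate observations: rate$_i$ = concentration$_i$ ×
volume$_i$ / (t$_i$ − t$_{i-1}$), associated with the interval
midpoint; the first interval is anchored at the dose time, taking the
bladder as emptied at dosing. The likelihood compares each observation
with the model's interval-average deposition rate over the same
interval (not the instantaneous rate at the midpoint — consistent with
how the observations are derived), under independent zero-truncated
normal errors per metabolite:
$R_{ij} \sim N(\mu_{ij},\sigma)[0,\infty)$, whose log density includes
the $-\log \Phi(\mu/\sigma)$ normalisation (verified against quadrature
to $10^{-8}$).

Fifteen global kinetic parameters plus three error SDs are shared
across volunteers; nineteen local parameters are calibrated per
volunteer. Priors follow the published specification: uniforms and
(half-)normals as tabulated, half-normal(1) for the error SDs, and —
for parameters specified only through a printed median $m$ and 95%
interval $(l,u)$ — uniforms back-solved as $m \pm (u-l)/1.9$ (a
$U(a,b)$ sample has median $(a+b)/2$ and 95% interval
$a+0.025(b-a), b-0.025(b-a)$). Where the distribution table and the
printed prior summaries disagree (the bile uptake rate, $MPY_{gut}$,
$Q_{gut}$ fraction), the printed summaries win, because they are the
realised prior. Physiological locals are normals truncated at their
5th/95th percentiles. FB_DEHTP and FB_MEHTP share one prior
specification but are sampled independently.

Sampling is adaptive block random-walk Metropolis: two global blocks,
one block per volunteer's locals and a log-scale block for the error
SDs, so an iteration costs one forward solve per volunteer for each
global block and one solve for each local block, while SD updates reuse
cached model means. Scales (and late in burn-in, marginal proposal SDs)
adapt towards 20–35% acceptance during the burn-in (first 25% of
iterations, excluded from summaries) and are frozen afterwards. Chains
are reproducible under a fixed seed. The posterior mode is the retained
sample with the highest log posterior; predictive bands are pointwise
2.5/97.5 percentiles over retained draws, and the mode trace may step
outside them. Thermodynamic integration is not used: plain Metropolis
suffices for parameter inference at this scale.

Known non-identifiabilities, documented rather than fought: the plasma
and red-cell PCs (no kinetic role), $MPY_{gut}$ (no likelihood path),
and partial FB-versus-PC trade-offs; their posteriors essentially
return the prior, as in the source calibration.

## Synthetic studies

The generator's defaults are the study conditions: three volunteers of
94, 85 and 95 kg, a 52.2 mg oral bolus each (the published per-kg doses
times the body weights all round to 52.2 mg), 20–23 voids over 48 h
with 3.62–5.59 L total urine, and truncated-normal deposition-rate
noise with SDs 0.0059, 0.00057 and 0.023 mg/h for 5OH, 2cx and 5cx (the
published posterior error SDs, so synthetic data carry the real study's
noise scale). Void gaps are gamma distributed with a diurnal stretch
overnight — an invention, since only counts and totals are reported —
and the last void falls exactly at the window end so 48-h measured and
predicted excretions are comparable without extrapolation. Noisy rates
are converted back to concentrations (rate × interval / volume), so
`voidsToRates()` recovers them exactly: the round trip is an identity
by construction.

What passing tests on these data do show: the estimation machinery
recovers the parameters that generated data of the assumed structure,
at realistic noise and sampling density. What they cannot show:
robustness to model misspecification, secondary uptake events from food
(visible in one real volunteer as extra spikes — reproducible here with
multi-bolus dosing, but not calibrated), assay censoring at the limit
of quantification, or circadian physiology.

## Problem sizes used in the shipped checks

Prior-reproduction checks use 15,000 draws (matching the printed
Monte-Carlo summaries they are compared against). The parameter
recovery study calibrates a full three-volunteer synthetic study with
20,000 iterations thinned by 10 — scaled down from the source's
150,000, which is more than this desk-scale recovery needs — and
checks that the generating values of the dose-fraction, lag and 5cx
elimination parameters fall inside their 95% credible intervals.
Mass-balance checks run 50 prior-sampled parameter sets over 48 h.

## Limitations

The bile-uptake ablation is not purely a late-time intervention: bile
uptake competes with hepatic metabolism at the liver node, so removing
it also raises early deposition by a few percent — an inherent property
of first-order uptake on the liver amount, not a numerical artefact.
Blood concentrations of DEHTP/MEHTP are reported but uncalibrated here
(no blood data stream), so they carry the full prior uncertainty of the
binding parameters. Dermal and inhalation routes, age and renal
covariates, and tissue distribution of the second-order metabolites are
out of scope.
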