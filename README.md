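# dehtpk

Physiologically based pharmacokinetic (PBPK) modelling and hierarchical
Bayesian calibration for the plasticiser **di-(2-ethylhexyl)
terephthalate (DEHTP)** and its monoester metabolite **MEHTP**.

DEHTP is a widely used substitute plasticiser whose human exposure is
assessed through urinary biomarkers: after an oral dose, DEHTP is
hydrolysed to MEHTP, which is oxidised to 5OH-MEHTP, 2cx-MMHTP and
5cx-MEPTP (measured in urine), with a large non-specific remainder
leaving as terephthalic acid (TPA). `dehtpk` is aimed at toxicokinetic
modellers who want to interpret such urine-void biomonitoring data
mechanistically: it provides the forward model, the in-vitro/in-silico
parameter derivation around it, the observation operator that turns
void records into bladder deposition rates, an MCMC calibration of
global (shared) and local (per-volunteer) parameters, and a synthetic
study generator so the whole chain can be exercised and tested without
access to the original volunteer data.

## The model in brief

A whole-body flow-limited PBPK model (amounts mg, volumes L, flows
L/h, time h), all kinetics first order:

- **Absorption.** An oral bolus splits into a hepatic stream
  (stomach/two-stage intestine with uptake rates `BELLYPERM`,
  `GIPERM1`, `GIPERM2` and a gut transit delay `Gutlag`), a lymphatic
  stream that reaches venous blood after a transport delay `Lymphlag`
  (bypassing first-pass metabolism), and a faecal pass-through; the
  three fractions sum to one.
- **Metabolism.** DEHTP → MEHTP in gut-1 and liver with rates
  k = 60·ln2/T½ from in vivo half-lives; MEHTP is cleared in the liver
  by intrinsic clearance scaled from an in vitro microsomal depletion
  half-life: CL_in vitro = ln2/T½ × ml incubation / mg microsomes, then
  CL_int = CL_in vitro × MPY × V_liver × 60/1000 (L/h). Metabolised
  MEHTP splits into the three urinary metabolite pools (fractions
  `FracMetab*`) plus a terminal TPA pool, and the pools drain to urine
  with rates `K1_MOH`, `K1_2cx`, `K1_5cx`.
- **Binding and distribution.** Only the unbound arterial fraction
  (1 − FB) distributes; tissue exchange is flow-limited against
  tissue:blood partition coefficients, with surrogate-tissue fallbacks
  (stomach←gut, rapidly perfused←spleen, slowly perfused←muscle). The
  fraction unbound is predicted from log P by
  fu = 1/(10^(0.4485·logP − 0.4782) + 1).
- **Enterohepatic recirculation.** First-order liver→bile uptake
  (`K1_DEHTP_Liver`) with a bile transit delay back into gut-2.
- **Calibration.** Deposition-rate observations
  r_i = c_i·V_i/(t_i − t_{i−1}) at interval midpoints; zero-truncated
  normal likelihood N(μ, σ)[0,∞) with one σ per metabolite; adaptive
  block random-walk Metropolis over 15 globals + 3 error SDs + 19
  locals per volunteer; posterior mode, credible intervals and
  pointwise predictive bands.

See the methods vignette (`vignettes/dehtp-pbpk-methods.Rmd`) for the
full structure, priors, delay realisations and design choices.

## Worked example

```r
library(dehtpk)

ctx <- buildModel()   # reference physiology + baseline kinetics
sim <- simulatePBPK(ctx, doses = data.frame(time = 0, amount = 52.2))
print(sim)
#> <dehtpSim> 961 time points over 48.0 h, dose 52.2 mg
#>   48-h style totals: 5OH 1.229, 2cx 0.198, 5cx 8.416 mg; |mass residual| <= 1.22e-12 mg
```

At baseline, 52.2 mg oral DEHTP yields 8.42 mg of 5cx-MEPTP, 1.23 mg of
5OH-MEHTP and 0.20 mg of 2cx-MMHTP in urine over 48 h — the same order
as measured 48-h excretions in volunteers (2.9–8.4 mg 5cx) — while
25.8 mg passes unabsorbed to faeces and the mass balance closes to
2×10⁻¹⁴ of the dose.

A full synthetic calibration round trip:

```r
study <- generateStudy(studyDesign(), defaultTruth(), seed = 1)
chain <- runMCMC(study$data, iterations = 20000, thin = 10, seed = 1)
ps    <- posteriorSummary(chain)
compare48h(ps$mode, study$data)   # measured vs predicted 48-h excretion
```

`posteriorSummary()` reports medians and 95% credible intervals for
every calibrated parameter plus each volunteer's derived absorbed
fraction (FracDOSEHep + FracDoseLymph).

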