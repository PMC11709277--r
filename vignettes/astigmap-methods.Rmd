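---
title: "Reconstructing and predicting corneal astigmatism: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and predicting corneal astigmatism: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astigmap)
```

## The problem

Keratometers measure the corneal front surface; the astigmatism that
actually needs correcting in a pseudophakic eye also carries the corneal
back surface, lens tilt and decentration, and any surgically induced
change. After cataract surgery with a non-toric IOL, the *total* corneal
power can be back-calculated from the spectacle refraction, the IOL power
and position, and the axial length. astigmap implements that
reconstruction, and models that predict it from preoperative measurements —
the mapping a surgeon would apply before choosing a toric IOL.

## Power-vector conventions

A spherocylinder (S, C, axis) is decomposed as

$$EQ = S + C/2, \qquad C_0 = C\cos 2\alpha, \qquad C_{45} = C\sin 2\alpha .$$

These are **full-cylinder** projections, not the half-magnitude
Jackson-cross (J0, J45). Two facts pin this convention down: the defocus
equivalent used for refraction data, $DEQ = \sqrt{EQ^2 + C_0^2/4 +
C_{45}^2/4}$, reduces to the familiar $\sqrt{M^2 + (C/2)^2}$ only with
full-cylinder components; and typical cohort SDs of corneal $C_0$
(≈ 0.67–0.88 dpt) are on the full-cylinder scale. With-the-rule astigmatism
(steep meridian near 90°) has $C_0 > 0$, so a *negative* $C_0$ correction
means "add against-the-rule". Axes are degrees mod 180, the axis of a zero
cylinder is reported as 0, and the cylinder acts at axis + 90°
(keratometric flat/steep readings enter through the plus-cylinder form with
axis = flat meridian). Left eyes are pooled with right eyes by flipping the
sign of $C_{45}$ (an involution, undone on output).

## The reconstruction chain

The pseudophakic eye is modelled with three refracting elements — spectacle
plane at a 12 mm vertex distance, thin-lens cornea, thin-lens IOL at the
effective lens position (ELP) — with $n = 1.0$ in air and
$n_A = n_V = 1.336$ behind the cornea. The ELP is the Haigis linear
regression $a_0 + a_1\,ACD + a_2\,AL$ (defaults are the IOLCon-optimised
MX60P constants 0.1835/0.3153/0.1725); it is used as the distance from the
corneal front vertex, i.e. corneal thickness is folded into the thin-lens
cornea.

Vergences are reciprocals of reduced distances, $v = n/d$ with $d$ in
metres, transferred between planes by $v' = v/(1 - v\,d/n)$ with $d$
signed (negative = backwards against the light). Two points deserve
emphasis because getting either sign wrong produces corneas of ~65 dpt
instead of ~43 dpt:

* the vergence at the IOL plane of a pencil focusing on the retina is the
  *reciprocal* of the reduced distance $(AL-ELP)/n_V$;
* after subtracting the IOL power, the transfer to the cornea runs
  *backwards*, i.e. over $-ELP$.

On the refraction side, a −1/6 dpt lane vergence (6 m refraction lane) is
added to the spectacle's meridional powers before the vertex transfer. The
chain is evaluated per principal meridian, which is exact here because only
rotationally symmetric elements (air gap, spherical IOL) separate the
planes, so principal axes are preserved; the reconstructed corneal power is
the meridional difference of the two vergences at the corneal plane.
`forward_refraction()` is the analytic inverse of this chain and round-trips
with `reconstruct_corneal_power()` to 10⁻⁹ dpt; the test suite also checks
the reconstruction against an independent forward-trace oracle that finds
the corneal power by root search on the focus condition.

## Prediction models

Only the astigmatism components (C0, C45) are modelled; the equivalent
power never enters the fits.

**Constant model.** `x + offset`, with `offset` the training centroid
difference. It shifts the error distribution to the origin without changing
the error-ellipse area — the baseline every better model must beat.

**Bivariate regression.** `A·x + b` fitted by least squares per output
component. For complete data this *is* the maximum-likelihood solution
under a bivariate-normal residual model (the ECM iteration for missing data
collapses to OLS at its fixed point, and this package requires complete
cases), so we implement OLS directly and report the log-likelihood at the
ML (divide-by-N) residual covariance. Collinear designs are rejected.

**Shallow network.** 2 → 12 → 12 → 2 with tanh hidden layers and linear
output. Implementation choices that the architecture alone does not fix:
inputs and outputs are range-scaled to [−1, 1] by the training extremes;
weights are Glorot-uniform initialised from a caller-supplied seed (the
global RNG state is saved and restored, so fits are reproducible and
side-effect free); training is full-batch Adam (step 0.02) on the mean
squared 2-D error, at most 1000 epochs; the validation MSE is checked every
10 epochs and training stops after 6 checks without improvement, returning
the best-on-validation weights. With ~300 training eyes and 230 weights the
net can overfit, which is exactly the behaviour the validation split is
there to curb — and a behaviour the test suite measures rather than hides
(mean test MSE ≥ mean training MSE over 20 seeds).

## Evaluation statistics

Prediction errors `actual − predicted` are summarised by their centroid,
the 95% error ellipse, the mean vector difference (MVD, dpt) and the mean
squared error (MSE, dpt² — the mean *squared* 2-D error length, so
MSE ≥ MVD² by Jensen's inequality). Assuming bivariate normality, the 95%
ellipse has semi-axes $\sqrt{\chi^2_{2,0.95}\,\lambda_i}$ along the
eigenvectors of the sample covariance (n−1 denominator) and area
$\pi\,\chi^2_{2,0.95}\sqrt{\det\Sigma}$ with $\chi^2_{2,0.95} = 5.991465$.
That scaling constant is the one consistent with quoting the *area of the
region containing 95% of the distribution*; Monte-Carlo coverage at
n = 10⁵ confirms 0.95 within ±0.003. A degenerate error cloud (perfect
predictor) is reported with area 0 rather than an error when evaluated
through `evaluate_predictions()`. Descriptive tables use the n−1 SD and
type-7 (linear-interpolation) quantiles, configurable.

## The synthetic cohort

`generate_cohort()` emulates a pseudophakic cataract cohort:

* biometry from truncated normals — AL 24.03 ± 1.45 mm on [21, 30],
  ACD 3.32 ± 0.40 mm, LT 4.58 ± 0.46 mm, CD 12.02 ± 0.55 mm. The ACD SD is
  deliberately 0.40 mm: an SD of ~1.5 mm would be physiologically
  implausible for a 2.50–4.05 mm 95% range, so the generator uses the value
  implied by that range;
* a true corneal power vector with EQ ~ N(43.0, 1.5²) dpt and (C0, C45)
  bivariate normal, mean (−0.3149, −0.0498), SDs (0.6706, 0.4482) dpt,
  correlation 0 by default (no published value; configurable);
* the IOL power that targets −0.25 dpt spherical equivalent, rounded to
  0.5 dpt steps, and the *exact* refraction from the forward vergence
  model, optionally quantized to clinical granularity (0.25 dpt, 5°);
* modality readings linked to the truth by *inverting* the fixed reference
  regressions: $x_m = A_m^{-1}(c_{true} - b_m) + \varepsilon_m$, with
  isotropic noise $\sigma_m$ (default 0.1 dpt) and a plausible equivalent
  power. Refitting the regression on generated data therefore recovers
  $(A_m, b_m)$ — exactly at $\sigma_m = 0$, and within Monte-Carlo bounds
  for small noise. Because the noise sits on the *measurement* side, large
  $\sigma_m$ induces the classical errors-in-variables attenuation; the
  recovery property is therefore only asserted for $\sigma_m \le 0.1$ dpt,
  and coefficient-recovery harnesses with noise on the response are used
  when an unbiased 3-SE check is wanted.

What the generator does **not** emulate: correlations between biometry and
corneal power, non-linear measurement↔recCP structure, axis-dependent
measurement error, bilateral correlation between a patient's eyes, or the
true joint distribution of the five modalities (they are conditionally
independent given the truth here). Consequently, passing tests demonstrate
the *machinery* — reconstruction, fitting, statistics — not clinical
performance figures; synthetic-model MSEs are far below the ~0.2–0.45 dpt²
seen on real eyes because the synthetic linkage is nearly exact by
construction.

## Splits, seeds and sizes

Datasets are split 60/20/20 by a uniform random permutation with sizes
round(0.6 n) / round(0.2 n) / remainder — 305/102/102 at n = 509. All
pipeline randomness derives from one master seed (sub-seeds for
simulation, splitting and network initialisation), making
`run_pipeline()` byte-reproducible. The test suite uses cohorts of
120–5000 eyes, 10⁴ random eyes for round-trip properties, 10⁵ draws for
ellipse coverage, and 20 seeds × 300 eyes for the overfitting direction —
sizes chosen so each property's Monte-Carlo error is well below the
asserted margin while the whole suite stays interactive.

## Degenerate inputs and tie-breaks

Zero cylinders report axis 0; a zero astigmatism vector maps to axis 0 in
both cylinder forms. Vergence transfers refuse a focus exactly at the
target plane; the reconstruction refuses AL ≤ ELP. Regression refuses
collinear designs and fewer than 3 pairs; the net accepts any finite input
(range scaling extrapolates linearly outside the training box). Cohort CSV
readers name the missing column on schema errors and normalise
out-of-range axes with a warning rather than failing.

## Known limitations

The eye model is paraxial and thin-lens: no thick-lens cornea, no toric
IOLs, no IOL tilt or decentration, no higher-order aberrations. The
published-coefficient models are fixed numbers applicable to the lens and
devices they were derived with; applying them elsewhere is an
extrapolation. The network's hyperparameters (activation, optimiser, epoch
budget, patience) are documented package defaults, not clinically
validated choices.
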