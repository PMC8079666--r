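---
title: "Three-pool analysis of complex mGRE data: models, operators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-pool analysis of complex mGRE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdm3pool)
```

## The signal model

White matter sampled with a multi-echo gradient-recalled echo (mGRE)
sequence does not decay mono-exponentially: water trapped between the
myelin lamellae (myelin water, `m`), water inside axons (`a`), and water
outside them (`e`) contribute distinct signal fractions, effective decay
rates and — because the myelin sheath perturbs the local field — distinct
frequency offsets. The package models the complex ROI signal as

$$ S(t) \;=\; f_a\,e^{(i\omega_a - R^{*}_{2,a})\,t} \;+\; f_e\,e^{-R^{*}_{2,e}\,t}
\;+\; f_m\,e^{(i\omega_m - R^{*}_{2,m})\,t}, $$

with the extra-axonal pool as the frequency reference ($\omega_e = 0$).
Echo times are handled in milliseconds at every interface and converted
to seconds inside the exponentials; offsets are accepted and reported in
Hz ($\omega/2\pi$) and stored in rad/s; rates are in 1/s. The two
myelin-sensitive outputs of the analysis are the myelin water signal
fraction $f_m$ (a myelin-content proxy) and the myelin–axonal offset
difference $\Delta\omega/2\pi = (\omega_m-\omega_a)/2\pi$, which carries
susceptibility and g-ratio information. Chemical exchange between pools,
fibre-orientation dependence (the mid-sagittal corpus callosum is treated
as perpendicular to the main field throughout) and any T1/flip-angle
weighting (absorbed into the curve normalisation) are outside the model.

The emulated protocol is a single mid-sagittal 5 mm slice, 1×1 mm² over
256×256 mm², TE1/ΔTE/TR = 1.62/1.23/100 ms, 25 bipolar echoes (maximum TE
31.14 ms), acquired 20 times with the read-gradient polarity inverted
half-way — 512 s in total.

## Frequency difference mapping

The phase of the raw signal mixes the microstructural evolution of
interest with a TE-independent receive/RF phase and a linear-in-TE
contribution from the non-local static field. The package's
frequency-difference operator removes exactly those two terms: per pixel,
the phase is unwrapped along TE only (ΔTE is short enough that
per-echo increments stay well inside ±π at tissue frequencies, so no
spatial unwrapping is needed), a linear reference through the first two
echoes is subtracted, and the residual is normalised:

$$ \mathrm{FDM}(t_n) = \frac{\varphi(t_n) - \varphi_{\mathrm{lin}}(t_n)}
{2\pi\,(t_n - t_1)}, \qquad n \ge 3, $$

with the first two echoes zero by construction. Adding any static phase
map or any static frequency map to the input leaves the output unchanged
to machine precision — the two invariances the preprocessing chain relies
on. Because the reference is anchored on the first two echoes rather
than on a fitted frequency map, absolute FDM amplitudes depend on this
operator choice; the package therefore applies the *same* operator to
the model curve inside the fit, so the choice cancels from the estimated
parameters.

Residual eddy-current structure is removed by fitting, per echo, an
ordinary least-squares 2D polynomial of total degree 3 over valid
pixels and subtracting it. The polynomial is estimated on tissue
*outside* the corpus-callosum mask and subtracted everywhere: the
instrumental residual is global and smooth, while the callosum is the
structure being quantified — estimating the trend through it absorbs
roughly a tenth of the genuine callosal FDM amplitude (about a 0.03
downward bias on $f_m$ in simulation), which the exclusion removes. The
operator remains a linear projection: it annihilates polynomial inputs,
is idempotent, and preserves localized structure exactly.

## Preprocessing the raw acquisition

Bipolar readouts alternate an eddy-current phase offset with echo parity,
with opposite sign in the two polarity groups. Complex multiplication of
the two groups cancels it exactly: the combined pixel has magnitude
$\sqrt{|S^+||S^-|}$ and phase $\angle(S^+S^-)/2$, with the half-angle
branch chosen circularly closest to the phase of $S^+$ (this makes the
$S^+=S^-$ identity exact). Coil combination uses image-based sensitivity
estimates — each channel's first-echo complex image smoothed with an
8 mm Gaussian and normalised to unit root-sum-of-squares — in the usual
least-squares combination $\sum_c \hat s_c^* S_c / \sum_c |\hat s_c|^2$.
Neither step touches the FDM invariances: whatever static phase the
sensitivity estimate absorbs cancels in the FDM operator.

The corpus callosum is split into anterior/mid/posterior thirds of equal
extent along its principal axis (projected pixel positions on the first
principal component of the mask coordinates, grouped to the pixel grid
and divided into three contiguous runs; a remainder goes to the anterior
bin; anterior = lower image column). Magnitude and FDM values are then
averaged over each segment per echo — magnitude-and-FDM averaging, not
complex averaging, which is also why the fit tolerates between-pixel
parameter scatter only to first order (about 2% curve distortion at the
default scatter).

## The joint fit and its identifiability

Per segment, the normalised magnitude and FDM curves are fitted jointly
by bounded Levenberg–Marquardt (minpack.lm), minimising

$$ \sum_n \left(m_n - \frac{|S(t_n)|}{|S(t_1)|}\right)^2
 + \lambda \sum_n \left(\frac{\mathrm{FDM}_n - \mathrm{FDM}^{\mathrm{model}}_n}{1\,\mathrm{Hz}}\right)^2 $$

with $\lambda = 1$ by default (the two curve families have comparable
numeric scale once FDM is expressed in Hz). Initial values and box
bounds follow the standard literature choices (fractions start at 0.5 in
[0,1]; $\omega_a/2\pi$ at −8 Hz in [−30, 0]; $\omega_m/2\pi$ at 30 Hz in
[0, 50]; $R^*_{2,m}$ at 150/s in [50, 300]; $R^*_{2,e}$ at 25/s in
[0, 100]). $R^*_{2,a}$ is held at 0 — with a 31 ms maximum TE the slow
intra-axonal decay is not identifiable, and freeing it mostly inflates
variance. The cost of the constraint is quantified by
`r2a_constraint_bias()`: at a true $R^*_{2,a}$ of 10/s the intra-axonal
fraction is underestimated by ≈0.20 and the extra-axonal fraction
overestimated by about the same amount, while $f_m$ moves by less than
0.01.

Two numerical properties of this objective shaped the implementation:

* **Fraction scale is a gauge freedom.** Both curves are invariant under
  $f \mapsto c f$, so the raw fraction triple is identified only up to a
  common scale. Reported fractions are therefore the sum-normalised
  $f/(f_m+f_a+f_e)$ — the unique identifiable representation (and the one
  consistent with published fraction triples summing to ≈1); the raw
  solver output is retained in the result object. A gauge residual
  $(f_m+f_a+f_e-1)$ is appended to the residual vector: it is free at the
  optimum but removes the exactly flat valley that otherwise stalls the
  Levenberg–Marquardt steps.
* **Distant local minima exist.** A small fraction of noisy fits lands in
  minima with residuals an order of magnitude above a successful fit's.
  The fit therefore restarts deterministically (a fixed ladder of
  myelin-offset starting values, then seeded perturbations) whenever the
  best residual norm exceeds a threshold (0.04 by default, chosen above
  the residual scale of successful fits at the emulated protocol noise);
  optional multi-start uses the same ladder. Ties between equally good
  starts break toward the lower $f_m$.

## Reproducibility and group statistics

Test–retest similarity of FDM curves is summarised by the discrete
Fréchet distance (dynamic programme over order-preserving couplings) on
(TE ms, FDM Hz) points, with configurable axis weights; per-metric
coefficients of variation use the sample SD over visits, and the
per-segment summary is the mean of per-subject CVs (with five visits per
subject, pooling values across subjects would conflate between-subject
spread with test–retest error). Equality of CVs across segments is
tested with a modified signed-likelihood ratio test: the common-CV null
is profiled by one-dimensional optimisation (per-group means have a
closed-form profile), and — because the χ² approximation is poor at
n = 5–6 — the signed root is moment-matched to the χ(k−1) distribution
using a seeded parametric bootstrap at the fitted null before being
referred to χ²(k−1). At n = 6 per group this brings the empirical size
from ≈0.09 (uncorrected) to ≈0.05; at n = 500 the corrected and
uncorrected p-values agree to ≈0.01.

Group inference mirrors the study design: OLS of the posterior-segment
metric on group (0 = control, 1 = patient), age and their product, with
age uncentred by default (centring is exposed as an option; with an
interaction term present the group coefficient is the contrast at age
zero, which is also why the power of that test depends on where the
group gap is largest). Within patients, Spearman correlations of $f_m$
with the executive score and with the disease burden score
DBS = age × (CAG − 35.5) form a Bonferroni family of two; a rank-based
partial correlation (rank residuals on the ranked covariate) controls
for age.

## What the generator emulates — and what it does not

The synthetic phantom is a 2D head ellipse with an arch-shaped callosum
(geometry scales with the grid; 256×256 by default, smaller grids in
tests), segment labels by equal anterior–posterior extent, per-pixel
three-pool parameters jittered around the published segment means with
fractions summing to one, and surrounding tissue with no compartmental
frequency structure (its FDM is identically zero). Instrumental effects
are a degree-3 polynomial background frequency map, a smooth
TE-independent RF phase, an alternating eddy phase that inverts with
read polarity, four smooth complex coil profiles (32 in the real
protocol; four exercise the combination logic), and complex Gaussian
noise at pixel SNR 100 per channel. The 20 repeats are not simulated
individually: one image per polarity group represents the 10-average,
and the fast curve-level generators use an ROI noise of 1.1×10⁻⁴ of the
first-echo signal — pixel SNR 100 propagated through repeat averaging,
polarity combination, 4-channel combination and ≈400-pixel segment
averaging. A single 5 mm slice is modelled as 2D; through-slice
dephasing, motion, flow and k-space effects are not modelled. In
particular the anterior segment's poor reproducibility, attributed in
vivo to arterial in-flow, is emulated phenomenologically by
segment-graded visit noise (set to the published per-segment test-retest
SDs), not mechanistically.

The cross-sectional cohort (19 carriers, 21 controls, ages ≈21–71, CAG
37–45 around a mean of 41.3) carries a true group deficit in $f_m$ that
is largest at young ages and narrows with age (control mean 0.16 at age
45 with slope −8×10⁻⁴/yr; patient mean 0.112 with slope −1×10⁻⁴/yr;
between-subject SD 0.01, residual SD 0.005), no group effect on
$\Delta\omega$ (age slope +0.05 Hz/yr), and an executive score with a
group-by-age interaction plus a direct coupling to the subject's myelin
fraction (70 score-units per unit $f_m$, landing the within-patient rank
correlation near 0.5). These effect sizes are the package's definition
of its study conditions: chosen once so that the qualitative pattern —
myelin deficit detectable, offset difference null, posterior segment
most reproducible — is recovered in ≈95% of replicates, and not adjusted
thereafter. Passing tests therefore demonstrate that the pipeline
recovers what the generator put in, at realistic noise; they cannot
certify the biological claims, the behaviour of real coil arrays, or
segmentation/slice-positioning variability beyond what the visit-noise
model captures.

## Problem sizes and numerical conventions

Unit tests run the imaging chain at 48–96 px grids (the geometry scales,
so segment pixel counts shrink accordingly); the acceptance analyses use
100 study replicates (each 40 fitted subjects plus a 6×5×3 reproducibility
arm), 2000 null simulations for the CV-equality size check with a
600-replicate bootstrap per test, and 1000-replicate bootstraps
elsewhere. Solver tolerances are 10⁻¹³ (ftol/ptol) with at most 150
iterations; bound hits are flagged at 10⁻⁶ of the box width; the
three-way mask split sends remainder columns to the anterior bin;
degenerate inputs (empty masks or segments, all-zero channels, zero-mean
or zero-variance CV groups, fewer than three echoes) raise errors rather
than propagating NaN.

## Known limitations

The FDM operator's absolute amplitude is anchored to the first two
echoes; a different anchoring (e.g. a fitted frequency map) would scale
FDM curves by a TE-dependent factor, and although the shared-operator
design cancels this inside the fit, FDM values themselves are
operator-relative. Fraction estimates from normalised curves are
scale-free by construction, so only normalised fractions are
comparable across studies. At curve-level noise much above the emulated
protocol level the joint objective's myelin-fraction error grows
steeply (≈0.1 at curve SNR 100), a regime the averaging in the emulated
protocol avoids. The partial-correlation variant (rank residuals) and
the per-subject CV aggregation are reasonable defaults among several
published conventions; both alternatives are one line away in the code.
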