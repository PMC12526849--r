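---
title: "Three-surface corneal model fitting and repeatability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-surface corneal model fitting and repeatability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cornfit)
```

## The measurement model

High-resolution anterior-segment OCT tomographers export corneal height
maps for three refracting surfaces: the corneal front surface
(*epithelium*), the epithelium–stroma interface (*stroma*), and the back
surface (*endothelium*).  Because the epithelium has a higher refractive
index (1.41) than the stroma (1.376), the cornea behaves as a three-surface
optical system rather than the classical single- or dual-surface
simplification, and all three interfaces contribute to total corneal power.

`cornfit` works with maps organised in cylindrical coordinates: 256
meridians by 31 concentric rings from 0.0 to 6.0 mm radius in 0.2 mm
steps (7936 grid cells), with invalid cells carrying the sentinel value
−1000.  The CSV dialect read and written by [read_map_csv()] /
[write_map_csv()] is documented in their help pages; since vendors do not
publish their export layouts byte-for-byte, the dialect here is an explicit,
loudly-validated definition rather than an attempt to guess a proprietary
format.  Two conventions in the dialect are deliberate assumptions and are
worth restating:

* **Units and sign.** Heights are stored in mm with positive z pointing
  posterior (into the eye), so all three corneal surfaces are "bowls"
  opening toward +z and carry positive apical radii, matching keratometric
  convention.
* **Angles.** Meridian 0 lies along +x in the examiner's view and angles
  increase counterclockwise, identically for right (OD) and left (OS)
  eyes; left-eye mirroring is a *statistical* operation
  ([mirror_left_eyes()]) applied only when pooling astigmatism across
  lateralities, never at the file level.

When a map is unpacked to a Cartesian point cloud
([to_cartesian_points()]), the radius-0 ring — which is one physical
point stored once per meridian — contributes exactly one point.  Keeping
all 256 copies would weight the apex 256-fold in every least-squares fit.
ROI membership is the closed condition $r \le \mathrm{ROI}/2$, so the
1.4 mm and 3.0 mm rings fall naturally inside the 3 and 6 mm regions of
interest (1793 and 3841 points on a fully valid map).

## The model surfaces

Three nested *floating* surfaces are fitted, "floating" meaning the apex
position $(X_0, Y_0, Z_0)$ is estimated rather than pinned to the
instrument axis:

| model | parameters | DoF |
|---|---|---|
| spherocylinder (`SphCyl`) | $R_1, R_2, A_1, X_0, Y_0, Z_0$ | 6 |
| cylindrical conoid (`CylConoid`) | + common asphericity $Q$ | 7 |
| biconic (`Biconic`) | + separate $Q_1, Q_2$ | 8 |

$R_1$ is the apical radius in the *flat* meridian at axis $A_1$ and $R_2$
the radius in the orthogonal *steep* meridian ($R_1 \ge R_2$ in canonical
labelling, enforced by [canonicalize()]).  With $(u, v)$ the lateral
offsets from the apex rotated by $-A_1$ and $c_x = 1/R_1$, $c_y = 1/R_2$,
the sag is the standard biconic

$$ z = Z_0 + \frac{c_x u^2 + c_y v^2}
   {1 + \sqrt{1 - (1+Q_1)\,c_x^2 u^2 - (1+Q_2)\,c_y^2 v^2}}, $$

with the spherocylinder and conoid as the $Q_1 = Q_2 = 0$ and
$Q_1 = Q_2 = Q$ specialisations.  One convention needs emphasising because
the literature is split between conic constants $k$ and $k + 1$: here the
factor $(1+Q)$ multiplies $c^2 u^2$ in the radicand, so $Q = 0$ is the
sphere, $Q < 0$ prolate (the typical cornea) and $Q > 0$ oblate.  Surface
tilt about the x/y axes is intentionally not modelled.  Outside the
radicand's domain the public `sag()` raises a domain error rather than
returning complex or clamped values — silent extrapolation would corrupt
fits downstream.

## Fitting

[fit_surface()] minimises the RMS height residual
$\sqrt{\tfrac1n \sum_i (z_i - \mathrm{sag}(\theta; x_i, y_i))^2}$
within box bounds ($R \in [3, 15]$ mm, $Q \in [-3, 2]$,
$|X_0|, |Y_0| \le 1.5$ mm, $Z_0 \in [-2, 2]$ mm) using bounded
Levenberg–Marquardt least squares, a quasi-Newton method appropriate for
this small, smooth problem.  Tolerances default to $10^{-12}$ mm² on the
cost and $10^{-9}$ relative on parameters, with at most 500 iterations;
non-convergence is flagged in the result, never silent.

Initialisation is deterministic, with no random restarts:

1. an algebraic least-squares sphere (linear system in centre and radius)
   refined by a short geometric Gauss–Newton pass gives $R$, $X_0$, $Y_0$,
   $Z_0$ — the refinement matters because the purely algebraic estimator
   amplifies height noise roughly five-fold on a shallow 6 mm corneal cap;
2. the principal directions of a full quadratic surface fitted to the
   heights give the flat axis $A_1$ and the meridional curvature split;
   when the astigmatic height signal is below $10^{-6}$ mm the axis
   starts at 0°.

During the search a negative radicand is clamped to zero (the bounds make
this rare at the solution; the result reports whether the optimum sits on
the clamp).  All ROI points are weighted equally.  When the fitted
astigmatism is below resolution ($R_1 - R_2 < 10^{-6}$ mm) the axis is
fundamentally unidentifiable; it is reported as 0° by convention and
flagged, and such fits are excluded from axis-repeatability statistics.

## From geometry to optics

Radii convert to surface powers through $F = \Delta n / R$ with the
refractive index chain air 1.0 → epithelium 1.41 → stroma 1.376 → aqueous
1.336 ([refractive_index_chain()]).  The index *steps* fix the power
signs: the epithelial surface contributes a large positive power (about
+53 D at $R = 7.7$ mm, versus +48–49 D for a single-surface cornea,
because of the larger 1.0 → 1.41 step), partly compensated by negative
powers at the epithelium–stroma interface (≈ −4.4 D) and endothelium
(≈ −6 D).

Principal powers and the flat axis are decomposed into power vectors
$(\mathrm{SEQ}, C_0, C_{45})$:
$\mathrm{SEQ} = (F_\mathrm{flat} + F_\mathrm{steep})/2$, and the cylinder
$C = F_\mathrm{steep} - F_\mathrm{flat}$ projected as
$C_0 = C \cos 2A_1$, $C_{45} = C \sin 2A_1$.  Two conventions coexist in
the literature; `cornfit` uses the **full** cylinder magnitude rather than
the half-magnitude (J0/J45) convention, consistent with reported
endothelial mean astigmatism magnitudes in the −0.24 to −0.26 D range.
The choice is isolated in [to_power_vector()] so it can be flipped without
touching anything else.  With-the-rule astigmatism (steep meridian
vertical) gives $C_0 > 0$ for the epithelium in this convention.

Layer thicknesses are differences of fitted apex Z positions —
epithelium $= Z_0^{stroma} - Z_0^{epi}$, stroma
$= Z_0^{endo} - Z_0^{stroma}$ — not pointwise map differences, so
`total = epithelium + stroma` holds exactly.

## Repeatability statistics

Each eye is measured three times.  Averaging astigmatic results in
(radius, axis) space is ill-defined — cylinders at axes 0° and 90° should
cancel, not average to 45° — so the per-eye mean is taken component-wise in
$(\mathrm{SEQ}, C_0, C_{45})$ and asphericity space
([mean_of_repeats()]), and mean radii/axis are re-derived from the mean
power vector through the surface's index step (arithmetic radius means are
available as an option).  Deviations of the three repeats from their
component means ([deviations_from_mean()]) sum to zero exactly and carry
the within-subject variability; descriptive rows report mean, sample SD,
median and the empirical 2.5%/97.5% quantiles (linear-interpolation
quantiles, `type = 7`; the quantile method matters when comparing tables
across software).

The axis is 180°-periodic, so its repeat SD is computed on the
doubled-angle circle ([axis_sd()]): axes are doubled, unwrapped about
their circular mean direction, the ordinary SD taken, and halved.  This is
invariant under adding 180° to any input and equivariant under global
rotation; a triad with zero resultant (e.g. 0°/60°/120°) has no preferred
axis and is flagged as maximal dispersion.  The axis of a nearly spherical
surface is poorly determined, so axis SD rises steeply as
$\Delta R = R_1 - R_2 \to 0$; [axis_sd_vs_dR_envelope()] summarises this
by binning $\Delta R$ (0.05 mm bins), taking the RMS axis SD per bin, and
least-squares fitting the monotone envelope $s(\Delta R) = a/(\Delta R +
b) + c$ with $a \ge 0$.  The hyperbolic form is this package's choice —
any decreasing envelope family would serve; it matches the $1/\Delta R$
scaling of axis error under isotropic height noise.

## Bivariate astigmatism summaries

Population scatter of $(C_0, C_{45})$ is summarised per surface, model and
ROI by the branching rule: the Henze–Zirkler test of bivariate normality
([henze_zirkler()]) at $\alpha = 0.05$ selects either the centroid with a
parametric 95% error ellipse (axes from the covariance eigendecomposition
scaled by $\sqrt{\chi^2_2(0.95)}$, area $\pi \sqrt{\det \Sigma}\,
\chi^2_2(0.95)$) or, under non-normality, the nonparametric medoid (the
sample point minimising total Euclidean distance, ties broken by lowest
lexicographic index) with a convex-hull-peeling 95% region.

The Henze–Zirkler statistic is the standard weighted $L^2$ distance
between empirical and Gaussian characteristic functions, with smoothing
parameter $\beta = ((n(2d+1))/4)^{1/(d+4)}/\sqrt 2$, maximum-likelihood
covariance in the Mahalanobis distances, and the lognormal approximation
of the null for p-values.  Its empirical type-I error at $\alpha = 0.05$
is verified by simulation in the test suite, and the implementation is
cross-checked against an independent reference implementation on frozen
fixtures.

Hull peeling removes *entire* convex-hull layers while at least
$\lceil 0.95 n \rceil$ points would remain — the canonical definition of
convex-hull peeling.  Whole-layer granularity means the retained fraction
can exceed the nominal coverage; it is reported alongside the area so the
approximation is visible rather than hidden.  When pooling both eyes, OS
points are first mirrored ($C_{45} \to -C_{45}$), reflecting the
approximate mirror symmetry of astigmatism about the facial axis;
per-laterality analyses skip the mirroring.

## The synthetic cohort generator

No public dataset of such repeat measurements exists, so
[generate_cohort()] produces cohorts with the statistical structure the
analysis expects: `n_patients` patients, two eyes each, three repeats per
eye.  The defaults of [population_spec()] describe a cataract-age
population: per-surface biconic truth parameters with means/SDs such as
epithelium $R_1$ 7.79 ± 0.35 mm and endothelium $R_1$ 6.54 ± 0.33 mm,
asphericities around −0.16 to −0.34, epithelial thickness 54.7 ± 4.4 µm
and stromal thickness 485.6 ± 38.8 µm, and a wrapped-normal flat axis
(mean 0°, SD 25°) shared by the three surfaces of an eye and mirrored for
OS eyes.

Within-subject variation is injected at **two independent levels**,
because parameter-level repeatability is what the analysis measures while
the raw instrument noise process is unobservable:

* per-repeat parameter jitter with SDs of roughly 11 µm (epithelium) to
  30 µm (endothelium) on radii, 0.03–0.05 on asphericities, 2° on the
  axis, 0.5 µm on apex Z (giving thickness repeat SDs near 0.7 µm), plus
  one common lateral alignment shift per repeat (20 µm SD); and
* i.i.d. Gaussian height noise, default σ = 2 µm, plus a Bernoulli
  dropout (default 2%) of cells to the sentinel.

The two knobs are separate config entries.  Pointwise height noise is what
makes the 3 mm ROI fits less repeatable than the 6 mm fits — the repeat
jitter itself is identical for both ROIs since they are fitted to the same
rendered maps — so the ROI effect seen in the pipeline output emerges from
the geometry, not from an explicit per-ROI setting.

Because corneal layers are nearly parallel, radii and asphericities of the
three surfaces are drawn from shared eye-level latent factors (loading
0.8) mixed with per-surface residuals, preserving each surface's marginal
moments while correlating the layers; the flat/steep meridians correlate
at 0.9 (radii) and 0.7 (asphericities) within a surface, with
$R_1 \ge R_2$ enforced by sorting.

**What the generator does not emulate.** Real maps contain spatially
correlated segmentation error, eye-motion artefacts, tilt, and pathology
(ectasia, post-refractive-surgery epithelial remodelling) — none are
modelled.  Exact conic truths also mean the adjacent-layer surfaces can
cross in the far periphery of the 12 mm map (the epithelium–stroma apex
gap is only ~55 µm while peripheral sag differences from asphericity
divergence reach ±60 µm); layer ordering is guaranteed only across the
central $r \le 3$ mm zone that both fitting ROIs use.  Similarly, a steep
endothelium can be undefined at the outermost rings; such cells are coded
with the sentinel, as an instrument marks unreliable peripheral points.
Passing tests on synthetic cohorts therefore validate the *pipeline
machinery* — recovery of known truth under the stated noise model — and
do not by themselves certify behaviour on real clinical maps.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds; a cohort, study or report
  is byte-identical under a repeated seed.
* Fits are deterministic (no multi-start); the fitted objective is
  invariant under reordering of the input points up to floating-point
  summation order.
* Descriptive rows require ≥ 2 values, the Henze–Zirkler test ≥ 8 points
  and a non-singular covariance, hull peeling ≥ 10 points, envelopes ≥ 20
  records and ≥ 3 non-empty bins — each failure mode is a named error,
  and the study driver skips (rather than fabricates) summaries whose
  preconditions fail on tiny cohorts.
* A cylinder of exactly zero returns axis 0° by convention in
  [from_power_vector()].
* Eyes without exactly three readable repeat measurements are excluded
  and listed with reasons ([validate_cohort()]), mirroring how a
  repeatability study reduces its raw dataset.

## Validation problem sizes

The package's own validation (test suite and `scripts/acceptance.R`) runs
the full pipeline on a 100-patient synthetic cohort (200 eyes, 600
measurements) with the biconic model at both ROIs — 3600 surface fits —
and checks that population means of radii and thicknesses are recovered
within two standard errors, within-subject SDs within 20%, power signs
and magnitudes at the three-surface scale, and the 3 vs 6 mm
repeatability ordering.  Oracle-level checks use closed-form sphere sags,
exhaustive medoid search, χ² ellipse areas, uniform-disc hull geometry,
and Monte-Carlo calibration of the normality test.

## Limitations

Beyond the generator caveats above: the fitted models assume orthogonal
principal meridians and no tilt; only descriptive statistics are produced
(no mixed-effects modelling of the inter-eye correlation within patients,
which the pipeline pools over); and the power-vector convention (full
cylinder) must be kept in mind when comparing C0/C45 magnitudes with
J0/J45-based reports, which differ by a factor of two.
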