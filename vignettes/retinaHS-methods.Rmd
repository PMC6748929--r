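---
title: "Hyperspectral retinal discrimination with retinaHS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral retinal discrimination with retinaHS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaHS)
```

## The problem

Retinal reflectance measured across many narrow wavelength bands is, in
principle, sensitive to amyloid-beta (Aβ) accumulating in the retina of
people with high brain amyloid load. In practice the signal is buried:
between-subject differences in lens yellowing, fundus pigmentation
(melanin), macular pigment and blood content each perturb the spectrum far
more than the disease does, and they do so along consistent spectral
directions. `retinaHS` implements an analysis built around that
observation: estimate the dominant *within-group* spectral directions,
project them out, and discriminate along what is left.

## Data model and preprocessing

A hyperspectral acquisition is a stack of frames, one per illumination
wavelength (the human instrument scans 900 nm down to 450 nm in 5 nm steps,
91 frames; frames are always stored ascending). Raw counts become
reflectance via the standard calibration

$$R(\lambda) = \frac{C(\lambda) - D - I(\lambda)}{W(\lambda) - D},$$

with dark counts $D$, white (Spectralon model-eye) reference $W$, and an
optional internal-reflection offset $I$ (default 0: its estimation is
instrument-specific and not modelled here). Negative values are clipped at
zero; no upper clip is applied. Residual inter-frame motion is compensated
by integer-pixel translation maximising normalised cross-correlation
between neighbouring frames, with shifts accumulated to a reference frame;
pixels shifted in from outside the field are flagged invalid and excluded
from every spatial average. Sub-pixel and rotational registration are
deliberately out of scope — the synthetic data this package is exercised on
has no optics-induced warping, and the stage exists to keep the pipeline
faithful end to end.

Spectra are analysed in natural-log space (log turns the multiplicative
interaction of illumination, media transmission and tissue reflectance into
additive terms; the base only rescales every downstream linear quantity). A
reflectance floor of $10^{-6}$ (configurable) guards shot-noise zeros
before the log. Region-mean spectra are smoothed with a Savitzky-Golay
filter, 5th-order kernel of width 13 samples; the terminal half-windows are
handled by evaluating the polynomial fitted to the first/last full window.
Smoothing is applied to the region mean only, after log and averaging —
the order is: log-transform pixels, average over the region, smooth.

## Systematic sampling

Six regions are sampled on a template oriented by the temporal raphe (the
fovea-to-optic-nerve-head line): a 60 px foveolar disc (F1), a 100–200 px
parafoveal annulus (F2), and four 200 × 200 px squares superior and
inferior to the fovea (S1, I1) and to the ONH (S2, I2), sides aligned with
the raphe. The square-centre offsets are not quantified in the source
imagery, so they are explicit template parameters (default 300 px
perpendicular displacement); all geometry uses 1-based (row, col)
coordinates with the origin at top left, and disc/annulus membership is
Euclidean distance ≤ radius. The template therefore needs roughly a
1024 × 1024 px field at default scale; tests exercise proportionally scaled
templates on smaller images, which preserves every geometric property
except the ±1 % rasterisation bound on rotation equivariance (boundary
pixels are a larger share of a small region, so that bound is checked at
full scale).

Vessels are excluded per region via a difference-of-Gaussians operator on
the green channel of the false-colour composite. "Variance parameters 1 and
20" are interpreted as Gaussian standard deviations in pixels (the common
DoG usage), and the sign convention is large-σ blur minus small-σ blur so
that dark vessels score high. The top 40 % of pixels by response are
flagged; ties are broken towards the lowest (row, col) so the flagged count
is exactly $\lceil 0.4 N \rceil$ for *any* input, including degenerate
constant images. That contract is why the blur is computed by direct
separable convolution (replicate boundary): an FFT-based convolution makes
a constant image blur to an almost-but-not-exactly constant image and the
tie-break becomes arithmetic noise rather than a documented rule. The mouse
variant takes the pointwise maximum of the signed DoG over σ-small 1–5
(step 0.2) × σ-large 4–14 (step 1) pairs (max is our reading of the
"series of DoG"; a sum would weight mid-calibre vessels more but not change
the flagged set much at 40 %), evaluates on the 390–460 nm mean image, and
adds the ONH disc to the exclusion. The 40 % fraction is reused for mice
(unstated in the source; configurable).

## DROP-D

Given log-spectra $X \in \mathbb{R}^{n \times p}$ with two classes, the
discriminant is built in two steps:

1. **Within-class axis removal.** Centre each row by its class mean and
   take the top $k$ right singular vectors of the result as
   $W \in \mathbb{R}^{p \times k}$ (orthonormal). These are the dominant
   nuisance directions, in our data chiefly mixtures of the ocular-media,
   melanin, macular-pigment and haemoglobin shapes.
2. **Between-class axis.** Deflate the grand-mean-centred data onto the
   orthogonal complement of $\mathrm{span}(W)$ and take the principal axis
   of the between-class scatter of the deflated class means. For two
   classes this is the deflated class-mean difference, normalised:
   $b \propto (I - WW^\top)(\mu_{case} - \mu_{control})$, $\|b\| = 1$.

The HS score of a spectrum is $(x - \mu) \cdot b$. Because $b \perp W$ by
construction, explicit deflation of $x$ is unnecessary — an equivalence the
test suite asserts rather than assumes. Signs are pinned for bit
reproducibility: each column of $W$ has its largest-magnitude entry
positive, and $b$ is oriented so training cases score above controls. The
class-size weighting of the between-class scatter is irrelevant to the axis
direction for two classes, so the closed form is used.

$k$ is selected by leave-one-out cross-validation: for each candidate $k$,
each subject is held out, the model refitted, and the held-out subject
scored; the criterion is the AUC of held-out scores, with ties broken
towards smaller $k$ (parsimony — the source describes only "optimising
discrimination", and AUC is the discrimination metric used throughout).
Two cautions the tests encode: LOO scoring under null labels is
*pessimistically* biased (each held-out subject drags its own class mean
away from itself, so held-out AUC can fall well below 0.5), and the curve
is flagged non-informative when no $k$ beats chance by more than two null
standard errors.

Removed axes are decomposed by ordinary least squares onto parametric
constituent shapes plus an intercept, reporting
$\mathrm{RMSE}\,\% = 100\sqrt{\mathrm{mean}(r^2)}$ on the unit-norm axis —
the normalisation that makes sub-percent residuals meaningful. Rank-deficient
bases fall back to the minimum-norm solution with a condition warning.

**Recalibration.** To score data from an instrument with a narrower range
(mouse, 450–680 nm), the training spectra are linearly resampled onto the
target grid and the model refitted. Nothing else changes; the planted
signature lives below 565 nm, so restriction to 450–680 nm preserves
discrimination (a property the acceptance tests measure).

## Mouse pipeline

Mouse cubes are segmented (multi-scale DoG + ONH), averaged to a single
whole-retina spectrum (the mouse retina is too small for regional
sampling), log-transformed, resampled to 450–680 nm in 5 nm steps, screened
for outliers, session-compensated, and scored with the recalibrated human
model. The outlier rule: per wavelength, the cohort median and *unscaled*
median absolute deviation (no 1.4826 consistency factor — the source says
"median absolute deviations" with no scaling); an animal is flagged where
its value is strictly below median − 3·MAD and excluded when flagged at
strictly more than 50 % of wavelengths. Both strictness choices matter only
at degenerate ties (identical spectra have MAD 0 and are all kept).
Session compensation subtracts, from every spectrum in a session, that
session's mean control spectrum minus the pooled control mean — applied
after the log transform, where illumination differences are additive
offsets; it provably preserves every within-session contrast.

## Synthetic data: what it emulates, and what it does not

The clinical data behind the original study are not publicly available, so
the generator is a first-class module. Cohort log-spectra follow

$$x_i = m + \textstyle\sum_j c_{ij} A_j + s_i\, d\, \sigma\, \beta + \varepsilon_i,$$

with a fixed smooth baseline $m$ (fundus reflectance rising towards the
near-infrared), unit-norm constituent shapes $A_j$ with loadings
$c_{ij} \sim N(0, \mathrm{sd}_j)$, the planted signature $\beta$ (the
amyloid stand-in), group indicator $s_i$, effect size $d$ in units of the
residual noise SD $\sigma$, and i.i.d. per-wavelength noise. The
constituent shapes are parametric stand-ins, not digitised literature
extinction curves: a decaying exponential (ocular media), a 460 nm Gaussian
band zeroed above 550 nm (macular pigment), a $\lambda^{-3}$ power law
(melanin), Gaussian bands at 542 and 577 nm (oxyhaemoglobin), and a
logistic step high below 565 nm (amyloid stand-in — the measured
in-solution spectrum is not printed anywhere we can reproduce from, so this
is a declared approximation). They preserve the features the analysis
exploits (short-wavelength concentration, the haemoglobin double band,
macular-pigment support) and nothing else.

Default conditions mirror the study: 15 cases / 20 controls (principal),
4 / 13 (validation), the 91-wavelength grid, and $d = 1.3$, chosen because
the oracle AUC of the score along $\beta$ is $\Phi(d/\sqrt{2})$ and
$d = 1.3$ corresponds to the reported discrimination level (AUC ≈ 0.82).
Nuisance loading SDs (0.10 ocular media, 0.08 melanin, 0.04 haemoglobin,
0.06 macular pigment at foveal locations only) place constituent
variability a few-fold above the signal, and $\sigma = 0.02$ is a few
percent of log-reflectance — plausible for averaged regions. Two honest
consequences of this calibration, visible in the acceptance report: with an
*estimated* axis at $n = 35$ the held-out AUC is below the oracle value
(axis-estimation noise eats part of the signal), and the validation AUC at
$n = 17$ is extremely variable. Passing tests on this generator show the
pipeline recovers what was planted under the assumed mixture-plus-noise
structure; they say nothing about spatial registration artefacts, focal
pathology, instrument drift, or constituent spectra that differ from the
parametric shapes.

Cube rendering adds spatial structure — a fan of curvilinear vessels with
Gaussian cross-section absorbing as haemoglobin, a foveal macular-pigment
disc, a flat-bright ONH disc — with the true vessel mask and landmarks
returned as ground truth. Generation is a pure function of its
configuration (local RNG, state restored), so identical seeds give
bit-identical cohorts.

## Statistics

The inferential battery matches the study's reporting conventions: unpaired
two-tailed t tests with the difference-of-means effect size and 95 % CI
(pooled variance by default — that is what reproduces the cohort table's
MMSE interval exactly; Welch by flag); 2×2 tables via the odds ratio with
Woolf log-CI and chi-square *without* continuity correction (again what
reproduces the printed p values); Pearson correlation with Fisher-z CI;
AUC as the Mann-Whitney statistic with Hanley-McNeil CI by default
(the source's CI method is unstated; a stratified bootstrap is available);
Benjamini-Yekutieli FDR control (valid under arbitrary dependence); and
the group main effect of the two-way repeated-measures design, tested
against subjects-within-groups on (1, n−2) df. The 2×2 orientation (which
category is the event, which group the numerator) is an explicit argument
throughout, because published tables are not always internally consistent
about it. Every statistic is checked against an independent brute-force or
base-R oracle in the test suite.

## Numerical choices and degenerate inputs

* Wavelengths ascending everywhere; scan order is metadata.
* Grid construction requires the step to divide the range exactly
  (tolerance $10^{-9}$ nm); length mismatches raise, never truncate.
* TIFF pages are stored as 32-bit floats on [0, 1] with an offset/scale
  recorded in a JSON sidecar, making cube round-trips lossless to float
  precision even for reflectance above 1.
* Constant registration frames yield zero shift with a warning; NCC ties
  prefer the smaller shift.
* Vessel thresholding flags exactly $\lceil f N \rceil$ pixels with
  lexicographic tie-break (see above).
* `fit_dropd` refuses $k > \min(n-2, p)$ and classes that become
  indistinguishable after deflation; LOO clips $k_{\max}$ to $n - 3$ with a
  warning.
* Zero-variance t tests report `NaN`/`Inf` rather than fabricating a value;
  zero-cell odds-ratio CIs are `NA` (no continuity fudge).

## Problem sizes

The test suite and acceptance script run everything at sizes a laptop
handles in seconds: cohorts of 35–80 spectra at 91 wavelengths (2000 for
the covariance-convergence check), cubes of 48–96 px at 24–47 wavelengths
for cube-level stages, the full-scale 1100 px canvas only for the
rotation-equivariance geometry check, and 10-seed replications for the
stochastic recovery criteria. These sizes were chosen to make the checks
sharp (they are well past where the asymptotics settle), not because the
pipeline is limited to them.

## Known limitations

Registration is integer-shift translational only. The constituent basis is
parametric, so constituent *coefficients* are not comparable to literature
extinction values — only the decomposition structure is. The amyloid
stand-in is an assumption, not a measurement. Discrimination, not
quantification: DROP-D scores rank subjects but are not calibrated to
amyloid burden. Multi-class discrimination and sparse/kernel variants are
out of scope.
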