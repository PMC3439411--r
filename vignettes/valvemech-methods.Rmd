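---
title: "Methods: multi-scale biomechanics of micro-scale planar tissues"
author: "valvemech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale biomechanics of micro-scale planar tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvemech)
```

## The measurement problem

Planar soft tissues at the millimeter scale — the murine mitral valve
leaflet is the motivating case, roughly 1 mm across and 30–40 µm thick —
are too small for conventional tensile grips and load cells, yet their
mechanics couple three length scales: global tissue stiffness, the
deformation of resident interstitial cells, and the reorientation of
collagen fibers. `valvemech` implements the full analysis chain for a
two-post stretch experiment in which the specimen spans two elastomeric
cantilever posts that double as the force transducer, while fluorescence
imaging follows cells and matrix fibers at each stretch increment, and
stained sections quantify matrix composition.

Because real specimens of this kind are not distributable, every stage is
paired with a synthetic-data generator that produces inputs with known
ground truth. The generators are first-class, tested code: they define the
study conditions under which the analysis stages are validated.

## Force transduction and the constitutive fit

Each post is a cylindrical Euler–Bernoulli cantilever loaded at its free
tip, with bending stiffness

$$k = \frac{3 E I}{L^3}, \qquad I = \frac{\pi d^4}{64},$$

so a measured tip deflection $v$ reads out the tissue force $F = k v$.
With the default post (diameter 2 mm, free length 6 mm, elastomer modulus
1 MPa) $k \approx 10.91$ N/m, which resolves the µN–mN range these tissues
produce. Tissue tension is loaded at the post tip; if a mounting places
the line of action lower, the free length is a constructor argument.

Global stretch is the tip-to-tip separation ratio $\lambda = s/s_0$
(rest separation $s_0 = 500$ µm by default; separations below $s_0$ are
flagged as compression and excluded from tensile analysis). Stress is
nominal (first Piola): force over the *undeformed* cross-section. The
deformed thickness of a loaded leaflet is not measurable in this setup,
so a true-stress referent would be speculative.

Stress–stretch records are fitted to the exponential constitutive law
standard for soft collagenous tissue,

$$\sigma(\epsilon) = \alpha\,(e^{\beta \epsilon} - 1),$$

with engineering strain $\epsilon = \lambda - 1$. The strain measure is a
convention choice (the exponential-law literature uses several); the
engineering form is the simplest one consistent with moduli reported in
MPa, and every comparison the package makes uses the same convention, so
group contrasts are convention-invariant. Fitting is nonlinear least
squares (Levenberg–Marquardt): $\beta_0$ from the log-slope of the upper
third of the curve, $\alpha_0$ matched to the peak stress, and a bounded,
deterministic grid of perturbed restarts before declaring failure.
Records with non-increasing stress or constant stress are rejected as
data-quality errors rather than fitted.

The reported stiffness is the tangent (effective) modulus

$$E_{\mathrm{eff}} = \left.\frac{d\sigma}{d\epsilon}\right|_{\epsilon_{ref}}
  = \alpha \beta e^{\beta \epsilon_{ref}},$$

at a configurable reference strain, default $\epsilon_{ref} = 0.3$ — the
midpoint of the $\lambda \le 1.6$ loading protocol. The exact
effective-modulus convention in the tissue-mechanics literature varies;
the tangent at a fixed reference strain is an explicit, reproducible
choice, and all within-study comparisons share it.

### The simulated two-post experiment

`simulateTwoPostTest()` closes the loop: each post base moves outward by
$d$, tissue tension pulls each tip back by $v$, the tissue length is
$s_0 + 2d - 2v$, and the scalar equilibrium $F_{tissue}(\lambda) = k v$
is solved per step by bracketed root-finding on $v \in [0, d]$ with a
$10^{-12}$ m tolerance. The residual is strictly monotone in $v$, so the
root is unique; the force-balance residual at returned steps is below
$10^{-9}$ N. The noiseless round trip — simulate, convert to stress,
refit — recovers the generating $(\alpha, \beta)$ to well under 1%,
which is the package's primary end-to-end self-check.

## Cell circularity

Cell deformation is summarized by the circularity index

$$CI = \frac{4\pi A}{P^2},$$

1 for a circle, decreasing toward 0 as cells elongate under stretch. Area
comes from the shoelace formula and perimeter from summed edge lengths of
the outline polygon. On rasters, outlines are the 8-connected boundary
chains of Otsu-thresholded, area-filtered connected components, smoothed
by a closed-chain moving average (window 7 vertices by default) before
measurement: a raw pixel chain overestimates perimeter by its staircase
structure and would bias CI low by several percent, while the smoothed
polygon measures a rasterized circle of the cell sizes used here at
CI ≥ 0.99. Touching cells merge into one component — a documented
limitation of connectivity-based segmentation; the synthetic generator
therefore places cells without contact.

Cells are matched across stretch frames by greedy nearest-centroid
assignment under a gating radius (injective per frame pair, ties broken
by distance then label). The trajectory statistic is the ordinary
least-squares slope of *mean* CI against stretch — one curve per test,
matching how such data are summarized in practice — while the per-cell CI
table is retained so a pooled per-cell regression can be formed if
wanted. Whether a published CI slope derives from mean-CI or pooled
per-cell fits is generally ambiguous; mean-CI is the headline here.

Local (midline) stretch can be measured independently of the posts by
tracking virtual fiducial markers with normalized cross-correlation
template matching (frame-to-frame, subpixel parabolic refinement, lost
below a correlation floor of 0.5, trajectories truncated rather than
interpolated) and projecting marker-pair separations on the loading axis.

## Fiber alignment by Fourier analysis

A fiber image's orientation content is read from its 2D power spectrum:
mean subtraction, Hann apodization (suppresses edge-discontinuity
leakage), FFT, then integration of the centered power spectrum over a
radial annulus (default $[0.1, 0.8]$ of Nyquist, excluding DC and corner
frequencies). Because the square frequency lattice is angularly
non-uniform — axis-aligned directions collect roughly three times more
lattice samples than oblique ones — the spectrum is resampled on a
uniform polar grid (three rays per 1° bin, bilinear interpolation,
radial Jacobian weighting) rather than binned by lattice-sample counts;
without this correction even an isotropic image shows spurious lattice
structure. A grating concentrates spectral power perpendicular to its
stripes, so spectral angles are rotated by 90° to refer to fiber
orientation, with 0° the image horizontal = loading axis.

The fiber alignment index (FAI) is the fraction of angular power within
±10° (axial distance, period 180°) of the loading axis: exactly
$20/180 \approx 0.111$ for a flat spectrum, 1 for perfectly aligned
power, 0 for purely transverse power. "Within ten degrees of the
horizontal" is read as a ±10° window; a ±5° reading is available through
`halfWidth`. The index is deliberately normalized to a fraction of
annulus power: absolute values of unnormalized alignment measures do not
transfer between implementations, so only orderings, signs and trends of
FAI should be compared across studies. Alignment trajectories are OLS
fits of FAI on stretch, like the CI trajectories.

## Histology composition

Stained sections (Movat pentachrome, Masson's trichrome, VVG) are
quantified by per-constituent color rules collected in an editable
`StainProfile`: Movat collagen via the CMYK yellow channel, GAGs via the
blue-minus-red RGB difference, trichrome connective tissue via
blue-minus-red, VVG elastin via inverted luminance. Per-constituent
channels are thresholded by Otsu with a fixed-value override per rule.
Since the stain colors are saturated in their rule channels, a channel
whose 99th percentile stays below 0.25 is treated as holding no
constituent; without this floor Otsu would split background noise on
blank slides. Whether trichrome "connective tissue" should exclude
nuclei is left as a profile decision — the default counts all
blue-classified pixels.

Fractions are normalized to the area of a supplied leaflet mask (mask
ingestion replaces manual outline tracing; automatic leaflet detection is
out of scope), the collagen/GAG ratio is attached when both constituents
are defined (flagged undefined at zero GAG area rather than emitting a
number), and cohorts can be rescaled so a reference group has mean
exactly 1.

## The synthetic generators

* **Fibers** — polylines with orientations drawn from an axial
  (period-π) von Mises-type law about the loading axis, concentration
  $\kappa \ge 0$ ($\kappa = 0$ isotropic). No specific orientation law is
  implied by real leaflets; the axial von Mises form is the standard
  model for axial data and is isotropic at zero concentration. Crimp is a
  sinusoidal perpendicular perturbation (default amplitude 1.5 px,
  wavelength 64 px — small enough that a fully concentrated field stays
  mostly within the ±10° FAI window, as strongly aligned mature tissue
  does). Stretch acts as the affine map
  $(x, y) \mapsto (\lambda x, \lambda^{-\nu} y)$ about the image center,
  which simultaneously rotates fibers toward the axis and flattens crimp.
  The transverse exponent $\nu$ (default 0.5) stands in for the
  unmeasured in-plane contraction visible as necking in real strip tests;
  it is a free, configurable parameter. Every scene carries its analytic
  post-stretch segment orientations, so an image-free brute-force FAI is
  always available as an oracle.
* **Cells** — non-overlapping ellipses whose target CI is
  $\mathrm{base} + \mathrm{slope}\,(\lambda - 1)$ plus Gaussian noise,
  with aspect ratio solved from the Ramanujan perimeter approximation,
  centroids following the same affine map, and labels stable across
  stretch so matching can be scored against ground truth. Cell radii
  (≈2% of the frame) keep rasterization error in measured CI below 0.01.
* **Stress records and two-post records** — drawn exactly from the
  exponential law with additive Gaussian noise (noise is additive
  Gaussian throughout the generators; no specific noise law is claimed
  for real instruments, and seeds are mandatory in every spec).
* **Slides** — constituents painted as contiguous blobs inside an
  elliptical leaflet mask by quantile-thresholding a smoothed Gaussian
  random field, which hits requested area fractions to within a pixel.

What the generators deliberately do *not* emulate: confocal PSF and
z-stack physics, photobleaching, fiber branching and crimp
heterogeneity, cell-cell contact, layered (fibrosa/atrialis) structure,
and real stain variability. Passing the recovery tests therefore
demonstrates that the analysis chain is correct and unbiased under
controlled conditions — not that it is robust to every artifact of real
microscopy.

## Statistics

Group comparisons follow the field's standard procedures: one-way ANOVA
with all-pairs Tukey HSD (the Tukey–Kramer form, so unequal group sizes
are allowed) summarized as a compact letter display — groups sharing no
letter differ at the chosen level — and pooled-variance Student's
t-tests for two-group contrasts (Welch by flag). An optional log
transform is available as a variance-stabilizing option, off by default.
Letters are assigned by the insert-and-absorb algorithm after ordering
groups by descending mean (ties by label), which makes the display
deterministic; a property test verifies that two groups share a letter
exactly when their Tukey-adjusted p is at or above the level.

## Determinism and numerical choices

Identical spec + seed reproduces every generator output bit-for-bit; the
RNG state is saved and restored around every seeded block, so package
calls never disturb the caller's stream. Per-frame noise derives from a
child seed of (spec seed, stretch), keeping any (spec, stretch) pair
reproducible in isolation. `runPipeline()` hashes its config, derives all
specimen seeds from the master seed, and reruns byte-identically.

Other numerical decisions, in one place: equilibrium root tolerance
$10^{-12}$ m (residual < $10^{-9}$ N); Fung fit restarts on a fixed
multiplier grid; orientation bins of 1° with centers at half-degrees (so
the ±10° window tiles exactly 20 of 180 degrees of support); annulus
$[0.1, 0.8]$ of Nyquist; contour smoothing window 7; matching ties by
distance then lowest label; compression flagged, never silently dropped.

## Problem sizes

The shipped validation suite runs the generators at 128–512 px rasters,
6–50 cells or 30–60 fibers per scene, 3–7 stretch levels spanning
$\lambda \in [1, 1.6]$, cohorts of 3–6 specimens, 20-seed replicates for
trajectory-recovery checks and 100-seed Monte Carlo for the constitutive
fit. These sizes were chosen to estimate every recovery statistic
stably; all scale linearly if larger studies are needed.

## Known limitations

* The two-post model treats the tissue as a uniaxial element; bending of
  the specimen between posts and grip compliance are not modeled.
* Connectivity segmentation merges touching cells; real confluent fields
  need external tracings (the CSV ingestion path).
* FAI absolute values depend on the spectrum normalization; compare
  trends, not magnitudes, across implementations.
* The histology rules are color heuristics, not stain-vector
  deconvolution (explicitly out of scope), and assume reasonably pure
  stain colors.
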