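---
title: "Methods: automated morphometry, mechanics and expression analysis for murine emphysema models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated morphometry, mechanics and expression analysis for murine emphysema models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`lungmorph` implements the quantitative chain of a 2x2 factorial mouse
emphysema study — diet (control vs. vitamin D deficient) crossed with
exposure (filtered air vs. cigarette smoke), giving groups CD-NS, CD-CSE,
VDD-NS and VDD-CSE. Four readout families are covered: mean linear
intercept morphometry on H&E parenchyma images, forced-oscillation and
pressure-volume respiratory mechanics, housekeeping-normalized qPCR
expression, and the factorial inference layer. A synthetic-cohort
generator with known ground truth drives validation throughout; nothing
in the analysis code depends on data being synthetic.

## Mean linear intercept morphometry

The per-image chain is:

1. **Segmentation.** Pixels are clustered into two classes on their raw
   RGB vectors by K-means (Lloyd iterations). Initialization is
   deterministic — the two centroids start at the darkest and brightest
   pixel colors by Rec. 601 luminance — so a given image always produces
   the same mask. The cluster with the higher mean luminance is airspace.
   A single-color image leaves the split undefined; it is signalled as a
   degenerate input, and the composed pipeline falls back to comparing
   the color against mid-gray (luminance 0.5).
2. **Small-component exclusion.** Airspace components (8-connectivity)
   with area *strictly below* 500 px are reassigned to tissue. This keeps
   vessel lumens and stray white pixels out of the intercept count. The
   threshold is read strictly: a 500-px component is retained, a 499-px
   component removed. The filter is idempotent and can only shrink the
   airspace class.
3. **Line grid.** Horizontal test lines of full image width at rows
   0, 69, 138, ... px (69 px = 25 um at the 2.764 px/um calibration).
   Starting at row 0 with stride 69 is the placement rule that gives
   N = 18 lines on a 1200-row image and the standard total scanned
   length N x l = 28,800 px (10,420 um to the nearest micron).
4. **Intercept counting.** Each grid line is scanned left to right; a
   position where an airspace pixel is immediately followed by a tissue
   pixel is one intercept. Only the airspace-to-tissue direction counts
   by default, and image borders are never transitions. Counting one
   direction makes L_M a period-like measure (mean air chord plus one
   septum) rather than a pure air-chord mean; `count_direction = "both"`
   is available for the conventional two-direction count but is off by
   default, favouring fidelity to the one-directional definition.
5. **L_M.** \(L_M = (N \times l)/\sum I\), converted to microns. A mask
   with no intercepts (all airspace or all tissue) is reported as a
   failed image, never as zero or infinity.

Aggregation averages images within mouse (unweighted) and then mice
within group; group SEM uses n = mice. Because group dispersion could
also be computed over the 10 x 11 = 110 images, an image-level summary is
emitted alongside, but the mouse-level one is primary.

## Respiratory mechanics

The package adopts the standard model forms behind the named ventilator
perturbations, since the perturbations conventionally feed exactly these
models:

* **Single-compartment equation of motion** for the fixed-frequency
  (2.5 Hz) oscillation: \(P = R\dot V + V/C + P_0\), solved by ordinary
  least squares. Rank-deficient designs (e.g. zero flow) are reported as
  singular rather than producing arbitrary coefficients.
* **Constant-phase impedance model** for the multi-frequency
  perturbation: \(Z(f) = R_n + j\omega I_{aw} + (G - jH)/\omega^{\alpha}\)
  with \(\alpha = (2/\pi)\arctan(H/G)\) and \(\omega = 2\pi f\). The fit
  is bounded Levenberg-Marquardt on stacked real/imaginary residuals,
  multistarted from three fixed points and therefore deterministic; the
  lower bounds exclude negative parameters. Noise-free spectra are
  recovered to better than 1e-6 relative error across the physiological
  parameter range.
* **Salazar-Knowles relation** for the pressure-volume loop:
  \(V = A - Be^{-KP}\), fitted to the deflation limb. Static compliance
  is the fitted slope \(BKe^{-KP^*}\) at \(P^* = 5\) cmH2O and TLC the
  fitted volume at 30 cmH2O; both pressures are configuration defaults
  since no standard value is implied by the model itself. Hysteresis is
  the absolute shoelace area of the closed loop polygon (absolute, since
  orientation conventions differ between acquisition systems). A limb
  that is better described by a straight line — the K -> 0 limit — falls
  back to a linear compliance fit; the linear model is preferred whenever
  it fits at least as well as the exponential.

## Expression

Relative expression is \(2^{-\Delta Ct}\) with
\(\Delta Ct = Ct_{gene} - Ct_{RPL13a}\), the 100%-efficiency assumption;
an optional per-gene efficiency base generalizes this to
\(E^{-\Delta Ct}\). The housekeeping gene self-normalizes to exactly 1.
The per-animal MMP-9:TIMP-1 ratio cancels the housekeeping Ct
algebraically, a property verified numerically in the tests. Group
summaries of the ratio are reported as arithmetic mean +/- SEM to mirror
the usual display, although ratios are log-normal; a log2-scale summary
is emitted alongside for that reason.

## Inference

The factorial layer is a between-subjects 2x2 ANOVA. Balanced data follow
the textbook orthogonal partition; unbalanced data (realistic group sizes
in mechanics arms run 14-17) use Type III sums of squares with
sum-to-zero contrasts, which coincides with the textbook partition when
balanced. A saturated fit with zero residual is partitioned directly from
the model matrix with the convention F = Inf, p = 0 for non-zero effects
(and F = 0, p = 1 when everything is constant). Planned pairwise
comparisons use the Welch (unequal-variance) t statistic — chosen over the
pooled form because equal variances are not guaranteed across exposure
groups — with Bonferroni adjustment \(p_{adj} = \min(1, m\,p)\). The
default family is the five contrasts such a study reports: each treated
group vs. control, plus the combined-insult group vs. each single-insult
group.

Pathology scores (0, +, ++, +++) are binarized to presence/absence before
a Kruskal-Wallis test with the standard tie correction, because sparse
upper tiers make the ordinal scale nearly binary in practice; a
configuration switch allows testing the raw 0-3 scale. The
everything-identical case is reported as H = 0, p = 1 by convention.

## The synthetic cohort

The parenchyma phantom is a Poisson-Voronoi tessellation: cell centers
are a Poisson process with intensity \(4/(\pi d^2)\) so the mean cell
area matches a disk of the target diameter \(d\); pixels within half a
septal thickness of a cell boundary (exact point-to-bisector distance)
are tissue, the rest airspace. This produces contiguous airspaces
separated by thin septa, the geometry an alveolar field presents at this
magnification. The ground-truth mean airspace chord is *measured* from
the mask by exhaustive horizontal run-length scanning (border chords
included, matching a border-to-border test line), never assumed from the
parameters.

Two artefact classes reproduce the known confounders of automated L_M:

* **Pigmented macrophages** — disks placed entirely inside airspaces,
  rendered in a dusty brown-pink that is deliberately *closer in RGB to
  tissue than tissue is to white*. Two-class clustering therefore counts
  them as tissue, which adds intercepts and shortens measured L_M — the
  mechanism by which macrophage accumulation in smoke-exposed lungs
  biases morphometry downward. (A very dark brown would instead make the
  deterministic extreme-pixel initialization split "macrophage vs.
  everything else", destroying the tissue/airspace separation; the
  palette is configuration, and this choice preserves the confounding
  mechanism being modelled.)
* **Speckles** — white components of area < 500 px placed on tissue,
  isolated from airspaces so each remains a sub-threshold component;
  they are exactly what the 500-px exclusion exists to remove.

Group defaults emulate the study structure: 11 mice per group, 10 images
per mouse (440 images), 1600 x 1200 px at 2.764 px/um. Target cell
diameters (39 / 35 / 39.5 / 44 um for CD-NS / CD-CSE / VDD-NS / VDD-CSE)
were set once so that measured control L_M sits in the low-30s um range
typical of healthy adult mice, the combined-insult group runs ~10%
larger, and the CD-CSE group combines *smaller* measured L_M with heavy
macrophage load — the dissociation between morphometry and mechanics that
makes the smoke-only condition interesting. Mechanics truth values
(Rn ~ 0.3 cmH2O.s/mL, G ~ 4, H ~ 16-22 cmH2O/mL, Cst ~ 0.06 mL/cmH2O,
TLC ~ 1-1.3 mL) are typical adult-mouse values with raised
compliance/TLC and lowered H in smoke-exposed groups; between-animal
variation is lognormal with 8% CV. Expression fold-changes program the
proteolytic shift (MMP9 up, TIMP1 and A1AT down in VDD-CSE); pathology
prevalences follow the per-group percentages of the study's histology
table. One RNG stream per animal and substream is derived from the master
seed by a fixed counter scheme, so a cohort is byte-identical across runs
and a single animal can be regenerated independently of cohort order.

What the generator does *not* emulate: staining variability, uneven
illumination, compression artefacts, vessel/airway lumens larger than
500 px, partial-volume pixels at septal boundaries, or biological
correlation between an animal's morphometry and its mechanics (each
modality draws its own stream). Passing tests therefore demonstrate
algorithmic correctness and statistical calibration, not robustness to
every real-world imaging artefact.

## Numerical choices

* K-means runs on raw RGB with extreme-pixel initialization (feature
  space and initialization are otherwise unconstrained choices;
  determinism is the requirement). Ties in the distance comparison go to
  the first cluster.
* 8-connectivity for components; union-find labelling.
* The printed total of 10,420 um is the nearest-micron rounding of
  28,800 px / 2.764 px/um = 10,419.68 um; L_M is reported at 0.01 um.
* Constant-phase multistart points are fixed at (0.2, 0.001, 1, 5),
  (0.5, 0.01, 5, 25) and (1.0, 0.005, 10, 50); the optimum is always at
  or below every start's residual.
* The 500-px filter applies to the binary mask after clustering (the
  order is not otherwise constrained).
* Test and validation problem sizes: oracle fuzzing uses ~100 masks of
  ~20 x 30 px; mechanics sweeps 10 parameter points; null calibration
  2000 replicates at n = 6/cell (ANOVA) and n = 11/group (Kruskal-
  Wallis); end-to-end effect detection 20 repetitions of two 11-mouse
  cohorts at 10 images each on 480 x 360 px phantoms, a size at which
  the per-image intercept count still gives high per-mouse precision.

## Known limitations

* One-directional intercept counting (the default) measures air chord
  plus septum; comparisons against two-direction implementations need
  `count_direction = "both"`.
* The chi-square approximation behind Kruskal-Wallis is marginal for
  heavily tied binary data at small n; with four groups of 11 binary
  scores it is slightly conservative.
* The Voronoi phantom has convex-ish airspaces; destructive emphysema
  produces fused, highly non-convex spaces whose chord distribution is
  heavier-tailed than the phantom's.
* Salazar-Knowles parameters are only identifiable when the pressure
  range covers meaningful curvature; fits from 0-30 cmH2O are
  well-conditioned, short ranges may fall back to the linear model.
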