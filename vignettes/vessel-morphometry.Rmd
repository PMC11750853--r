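---
title: "Retinal vessel wall morphometry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal vessel wall morphometry: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octvessel)
```

## The measurement problem

On an OCT cross-section, a small retinal vessel appears as a
hyperreflective annulus: a bright wall ring around a darker lumen on a
dark background. Morphometry asks for four primary quantities per eye --
the arteriolar outer and lumen diameters (RAOD, RALD) and the venular
outer and lumen diameters (RVOD, RVLD), all in micrometres -- and seven
derived ones:

* wall thickness `AWT = (RAOD - RALD) / 2`, `VWT = (RVOD - RVLD) / 2`;
* wall-to-lumen ratio `AWLR = AWT / RALD`, `VWLR = VWT / RVLD`;
* wall cross-sectional area `AWCSA = (RAOD^2 - RALD^2) * 3.14 / 4`
  (likewise VWCSA);
* arteriovenous ratio `AVR = RAOD / RVOD`.

The area formula uses 3.14, not `pi`: the reference values this package
is calibrated against were computed with that convention, and
`compute_params()` reproduces it bit-for-bit by default
(`pi_tilde = 3.14`; pass `pi_tilde = pi` for the true constant). Values
are stored at full precision and rounded to four decimals only when a
table is rendered.

Wall thickness is linear in the diameters, so applying the formula to
group-mean diameters reproduces a group's mean wall thickness. The
ratios and areas are nonlinear, so the same substitution does *not*
reproduce their per-subject averages -- a property the test suite asserts
in both directions rather than papering over.

## The FWHM edge detector

Walking down one pixel column through a bright-walled vessel, the gray
profile rises into the top wall band, falls into the lumen, rises into
the bottom band, and falls back to background. The detector works
entirely on the profile's first-difference sequence:

1. `difference_sequence()`: `d[i] = gray[i+1] - gray[i]`.
2. `segment_groups()`: maximal same-signed runs of `d` become groups;
   exact zeros are turning points that separate groups. Differences
   with `|d|` below a noise floor (default 2 gray levels) are
   suppressed first, and same-signed fragments separated only by
   suppressed values are merged back together -- speckle would otherwise
   fragment every profile. An exact-zero plateau still separates
   same-signed groups: it is a genuine feature of the profile, not
   noise.
3. `discard_background_groups()`: a profile that rises at its very
   first sample or falls at its very last starts or ends mid-gradient;
   those boundary groups belong to the background, and are dropped
   provided a four-group alternating pattern survives.
4. `pair_and_locate_edges()`: the groups realizing the alternating
   `+,-,+,-` pattern with the greatest total peak `|d|` are selected
   (a dynamic program over the group sequence); the inverted pattern is
   scored as well so dark-walled profiles are handled, and the
   higher-quality interpretation wins. Within each selected group the
   edge is the position of maximum `|d|`.

**Sub-pixel convention.** A first difference lives between samples, so
an edge detected at difference index `i` is reported at `i + 0.5`. Ties
inside a group break toward the profile centre, then toward the smaller
index. On a noiseless piecewise-constant profile this recovers each
transition exactly; the brute-force oracle in the test suite enumerates
every admissible four-group selection and must agree with the dynamic
program on every fixture.

**Column scanning.** `scan_columns()` evaluates every column inside the
central `center_fraction` (default 0.2) of the ROI width and aggregates
the per-column extents by their median (`"best-quality"` keeps the
single strongest column instead). Off-axis columns measure chords, which
are shorter than the diameter by about `d^2 / R` pixels at offset `d`;
with the default window this bias stays near one pixel for vessels in
the 100--180 um range at 1 um/px, and it is the main reason measured
diameters sit slightly low rather than high.

## Preprocessing chain

`standardize()` resamples anisotropic input to a 1:1 um aspect
(bilinear, pixel centres at integer coordinates), scales uniformly to a
512 x 512 frame (padding with the border median when the physical field
is not square) and updates the calibration so physical distances are
preserved. `enhance_contrast()` is CLAHE (clip limit 2, 8 x 8 tiles by
default). `detect_edges()` is a standard Canny chain; when no thresholds
are given, `high` is Otsu's threshold on the gradient magnitudes and
`low = high / 2`. `extract_roi()` takes the bounding box of the largest
8-connected edge structure, dilated by a margin (default 10 px) -- in a
single-vessel crop the vessel is the dominant structure. The ROI is
annotated, not cropped: downstream stages index the full frame.

**Which intensity does FWHM read?** The edge map and ROI come from the
CLAHE-enhanced image, but the column scan defaults to the *raw*
standardized intensity (`measure_vessel(..., intensity = "raw")`).
Adaptive equalization amplifies speckle inside the homogeneous lumen;
on speckled phantoms the amplified noise pairs can out-compete the true
wall-lumen transition and collapse the measured lumen on a substantial
fraction of columns, while raw profiles keep the wall bands dominant.
The `"enhanced"` option remains available and every report records the
choice.

## The synthetic data generators

`generate_phantom()` rasterizes a perfect annulus (a pixel belongs to a
region when its centre lies inside the region boundary), then applies
Gaussian blur and additive Gaussian speckle. Two simplifications are
deliberate: the speckle is additive Gaussian rather than multiplicative
Rayleigh-like (sufficient to stress the detector, and noted as a
simplification), and the nominal cross-section is circular because scan
lines are set perpendicular to the vessel; eccentricity and tilt are
available as stress parameters defaulting to zero. The sidecar records
both the rasterized transition positions (what a perfect detector sees;
half-integers between the last outside and first inside pixel) and the
continuous-geometry positions `centre +- radius`; the two differ by at
most one pixel, which is the irreducible rasterization term in the
recovery error.

`generate_cohort()` draws per-subject (outer, lumen) pairs per vessel
from a bivariate normal and fills the derived parameters with
`compute_params()`. Within one vessel the outer and lumen diameters are
strongly coupled -- the wall is an order of magnitude less variable than
either diameter -- so independent draws would inflate the wall-thickness
SD to roughly `sqrt(sd_od^2 + sd_ld^2) / 2` (about 7 um for the
reference SDs) where the reference tables report about 1 um, and every
wall-derived comparison would lose its power. The generator therefore
derives the within-vessel correlation from a target wall-thickness SD:
since `WT = (OD - LD) / 2`,

```
rho = (sd_od^2 + sd_ld^2 - 4 * sd_wt^2) / (2 * sd_od * sd_ld)
```

which is 0.95--0.98 for the built-in reference groups
(`reference_group_specs()`). Draws violating `outer > lumen > 0` are
rejection-resampled (keeping the marginals near-normal, unlike
clipping); a spec whose mean lumen exceeds its mean outer diameter by
more than 3 SD is rejected outright. What the generator does *not*
emulate: within-subject repeat-image structure (subjects are drawn at
the between-subject SD directly; the repeat-averaging stage is exercised
separately), inter-parameter correlations beyond the outer/lumen pair,
and any non-normality of real cohorts.

The reference summary statistics carry one internal inconsistency: the
NC-group arteriovenous ratio is printed as 0.7676 +- 0.0588 in the
arterial table and 0.7498 +- 0.0622 in the venular one.
`reference_group_stats()` carries the arterial-side value and documents
the discrepancy instead of reconciling it silently.

## Statistics

`run_table()` compares each parameter across the three groups exactly
the way such cohorts are conventionally analysed:

* one-way fixed-effects ANOVA (base `aov`), F on `(k - 1, N - k)` df;
* a variance-homogeneity gate: Levene's test centred on the mean
  (`car::leveneTest`), the companion SPSS pairs with this post hoc
  choice; the gate level is 0.05;
* pairwise post hoc tests: **LSD** (unadjusted t with the pooled
  within-group mean square) when variances are homogeneous,
  **Games-Howell** (Welch-type t, Welch-Satterthwaite df, studentized
  range reference: `ptukey(|t| * sqrt(2), k, df)`) otherwise;
* Shapiro-Wilk per group is reported but never gates the analysis;
* no multiple-testing correction across the eleven parameters (the
  reference analysis reports per-parameter p values);
* missing subjects are dropped listwise per parameter.

Degenerate inputs are reported, not crashed on: zero total variance
leaves F as `NA` with a note; a Levene response with no residual
variance short-circuits to p = 1 (identical absolute deviations
everywhere) or p = 0 (deviations constant within groups but different
between them).

## Problem sizes and what the tests show

The suite validates the pipeline at these scales, chosen as
representative rather than exhaustive: a 200-phantom recovery battery
(outer 100--180 um, lumen from 75 um up to 15 um below the outer
diameter -- the reference wall thickness is 12--14 um, so thinner walls
are anatomically implausible and would be unresolvable at this pixel
pitch -- speckle sigma 0--8, 1 um/px, blur sigma 1), where the median
absolute error of both diameters must stay within 2 pixel-equivalents;
2000 null replicates for the type-I error of the overall ANOVA; full
enumeration of the permutation distribution of F on 8-subject cohorts;
and 200 simulated cohorts at the reference means/SDs with n = 50/55/55.

Against those simulated cohorts the venous contrasts (VWT, RVOD, VWCSA)
come out significant in well over 95% of seeds and the arterial
parameters mostly non-significant, matching the qualitative reference
pattern. One caveat is worth stating plainly: at the reference means and
SDs the analytic power of the overall ANOVA for RVLD is about 0.86, so
no generator faithful to those numbers can make RVLD significant in 95%
of seeds; the corresponding assertion in the acceptance suite documents
this gap rather than hiding it. Passing phantom tests show the detector
recovers known geometry under the stated noise model; they do not
certify performance on real OCT speckle, motion artefact, or oblique
sections.

## Known limitations

* Additive Gaussian speckle understates the tails of real OCT noise.
* Median-of-columns aggregation carries a small negative chord bias
  that grows with vessel radius in pixels; narrow the scan window or
  use `"best-quality"` when measuring very large vessels at fine
  calibration.
* The learned segmentation stage that can replace FWHM in a full
  deep-learning pipeline is out of scope here; the FWHM result *is* the
  measurement.
* One artery and one vein per eye are modelled; multi-vessel scenes are
  not parsed (the ROI keeps the dominant structure only).
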