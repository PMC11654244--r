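---
title: "Methods: scoring an inducible-degron yeast screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring an inducible-degron yeast screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronscreen)
library(dplyr)
```

# The screen, in brief

An auxin-inducible degron (AID) library fuses every yeast open reading
frame to a degron-GFP tag; adding the auxin analogue triggers
ubiquitination and proteasomal degradation of the tagged protein. Two
readouts drive the genome-scale analysis this package implements:

* **Colony growth.** The arrayed library is pinned on agar with and
  without the inducer. If degrading a protein blocks growth, the induced
  colony shrinks: the induced/uninduced colony-size ratio ("relative
  growth") scores essentiality.
* **Per-cell fluorescence.** GFP intensity per cell before and after
  induction reports whether the tagged protein is visible at all and
  whether it is actually depleted ("responsive").

Around these sit degradation-kinetics fitting (one-phase decay
half-lives from imaging and immunoblots), GO-slim term recovery over
media-specific hit sets, grouped responsiveness summaries, and
single-cell grid montages for visual inspection. A synthetic-data module
generates every input with planted ground truth, so the full pipeline is
exercised without any instrument data.

# Relative growth and essentiality

For each strain, replicate colony sizes are averaged per condition
*before* the ratio is taken:

$$ r_i = \frac{\overline{\text{size}}_i^{\,\text{induced}}}
              {\overline{\text{size}}_i^{\,\text{uninduced}}} $$

Averaging sizes first (rather than averaging per-replicate ratios) keeps
a single missing pin from dominating, and is the convention the score is
defined by. Because induced and uninduced plates share geometry,
multiplicative positional effects — the familiar better growth of edge
colonies — cancel in the ratio; the generator applies a configurable
`edge_boost` to the outermost ring of both conditions precisely so this
cancellation is testable.

Scores are then normalized per plate and media by the group median
computed after outlier removal, so the typical strain scores 1
everywhere. The outlier rule is deliberately robust and parameter-free:
values outside `median ± 2 × (1.4826 · MAD)` are excluded from the
median computation only (never from the output). The factor-of-1.4826
MAD rescaling makes the window an SD-equivalent under normality; the
width is a config option (`trim_outliers_k`).

Classification uses strict thresholds on the normalized score: below
0.5 is a severe growth defect, below 0.1 a stringent severe defect (a
subset of the former, favouring bona fide essentials over slow
growers). Both are configurable. A strain whose *uninduced* colony does
not exceed the presence threshold (50 A.U., strict "over") never grew
and is `absent` — unscorable, not essential. A `moderate` factor level
exists for users who want a third, intermediate threshold; none is
assigned by default because the screen defines only the two published
cut-offs.

`media_partition()` turns per-media severe-hit sets into exhaustive,
disjoint Venn regions; the single-media ("exclusive") sets feed the
GO-slim ranking below.

# Per-cell fluorescence and responsiveness

Per-strain cell populations are summarized by a one-pass trim — cells
outside `mean ± 2·SD` of the raw intensities are removed — followed by
the geometric mean, SD and count of the survivors. The trim uses
arithmetic moments while the center is geometric; that asymmetry is the
stated convention of the screen's processing, and we keep it rather than
substituting a log-scale trim. Intensities are right-skewed and roughly
log-normal, hence the geometric center (and its scale equivariance,
which we test).

The *autofluorescence band* is built from control strains carrying no
GFP: the mean of their geometric means with a two-SD interval in each
direction. A strain is **fluorescent** only when its pre-induction
geometric mean exceeds the *brightest* control — a deliberately
conservative floor.

"Significant reduction" is not pinned down by the screen's description,
so the package defines it as: a one-sided Welch t-test on log
intensities (unequal variances; log scale matches the multiplicative
signal), Benjamini–Hochberg adjusted across the strain panel
(`adjust_strain_calls()`), at `alpha = 0.05`, **and** an effect floor —
the after/before geometric-mean ratio must fall below 0.75 — so that
trivially significant 2% drops at large n are not called responsive.
All three knobs are config options. Strains losing more than 75% of
their cells after induction are called **dead** (`death_fraction =
0.25`): induction-provoked lethality makes the fluorescence readout
uninformative, and the library summary therefore reports responsiveness
both excluding dead strains and counting them as responders.

# Degradation kinetics

Time courses (imaging intensities, or immunoblot band volumes first
divided by their Act1 loading bands) are normalized per replicate to
t = 0 and fitted with

$$ y(t) = \text{plateau} + (y_0 - \text{plateau})\, e^{-kt} $$

by bounded Levenberg–Marquardt least squares, pooling replicates.
Bounds: `y0` in [0.8, 1.2] (absorbing normalization noise instead of
pinning the intercept), plateau in [0, 1], `k > 0`. For this
parameterization the half-distance crossing between `y0` and the
plateau happens exactly at `ln 2 / k`, so one `t50` serves both
conventions. The 95% CI is the delta-method interval from the `k`
variance with a t quantile at `n − 3` degrees of freedom; when the
covariance is unavailable, a replicate-resampling bootstrap (1,000
draws, requiring ≥ 3 replicates) supplies the interval, and the method
used is recorded. A series whose fitted drop over the observed window is
under 5% is flagged non-degrading with `t50 = Inf` rather than reporting
a meaningless huge half-life. `compare_modalities()` reports the
microscopy/western half-life ratio and CI overlap.

# GO-slim term recovery

No enrichment p-value is computed: the screen reports counts and
recovery percentages, and the package stays faithful to that (a
hypergeometric test would be easy to bolt on, but it would not be this
method). For a media's *exclusive* hits, terms are ranked by how many
exclusive hits carry the annotation, reported as `count/exclusive-set
size` pairs; ties break by larger whole-term recovery, then lexical
term id (the ordering must be deterministic and the screen is silent on
ties). *Whole-term recovery* for a term of genome-wide size `S` with
`h` annotated hits is `100·h/S`, reported to one decimal — regardless
of whether those genes are in the library; library-presence and
responsive-certified counts are carried as metadata because they are
informative context even though they play no role in the percentage.
For hits shared by all media, recovery is computed against the shared
set only.

# Grouping

Localization categories collapse deterministically (early/late Golgi →
Golgi; nucleolus → nucleus; actin, endosome, ER-to-Golgi, microtubule,
spindle pole → punctate composite); anything else is already canonical
and passes through unchanged. Abundance binning sorts by rank (1 = most
abundant) and cuts into bins differing in size by at most one, any
remainder going to the most-abundant bins — the published case (650
genes into quintiles of 130) is the exact-division case, so the
remainder rule is this package's choice. Mito-dye intensities get dense
descending ranks with ties sharing the better rank.

# Montages

Cells are cropped as 65 × 65 px boxes centered on their centroids
(out-of-frame regions zero-padded), laid out row-major in input order
on a 20 × 20 grid — a 1,300 × 1,300 px canvas holding up to 400 cells —
with intensities preserved verbatim so expression noise and
before/after differences stay comparable across tiles. Contrast is then
adjusted so that ~0.35% of pixels saturate. Saturation is applied at
the bright end only, with the dark anchor at the image minimum
(fluorescence is visualized against a dark background; clipping shadows
would discard the autofluorescence floor); the clip bound is the
`1 − 0.0035` order-statistic quantile, so the saturated fraction can
exceed the request by at most one quantization step under ties. The
`side = "both"` option splits the fraction across tails. Brightfield
montages are downscaled to 8 bits by a linear min–max map with half-up
rounding, since brightfield intensity variations carry no information.

Pixel coordinates are 1-based matrix indices (origin top-left), the
native R convention; for an odd box the crop's center pixel is exactly
the centroid pixel, and for even coordinates the centroid sits at
`floor(box/2) + 1`.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions of the test suite:

* **Plates**: 1,536-format layout (32 × 48), 10% planted lethal strains
  with a 0.05 mean induced/uninduced effect, log-normal colony noise at
  CV 0.1, and a 1.2× edge boost on the outermost ring of both
  conditions. Colony sizes are positive and skewed, hence
  multiplicative log-normal noise; no noise magnitude is published for
  this screen, so CV 0.1 is a realistic arrayed-colony figure adopted
  once for testing. Lethal strains floor at size 0 (sizes are areas).
* **Cells**: additive autofluorescence (normal, mean 100 ± 10 camera
  units) plus a multiplicative log-normal GFP signal (geometric mean
  1,000, log-SD 0.3); induction scales only the signal. This matches
  the band-versus-signal logic of the fluorescence classification:
  background persists when the tagged protein is gone.
* **Time courses**: the decay law itself times per-observation
  log-normal noise (CV 0.05), three replicates, six timepoints spanning
  0–180 min around a 45-min half-life.
* **Annotations**: each term planted at exactly its stated size.
* **Images**: non-overlapping uniform disks with known centroids.

What the generator does **not** emulate: optics (no PSF, no shading),
cell morphology, plate-to-plate agar gradients beyond the edge ring,
batch effects between acquisition profiles, or biologically structured
hit sets. Passing recovery tests therefore demonstrates that the
*computations* are correct and well-calibrated under the stated noise
model — not that the thresholds are optimal for any particular
instrument's data.

# Problem sizes and numerical choices

The test suite and the acceptance script run, by design, at desk scale:
a 1,000-strain plate screen for essentiality recovery, a 200-strain ×
200-cell panel for responsiveness, 200 simulated time courses for
half-life recovery, and brute-force oracle comparisons on instances of
≤ 50 elements. These sizes give stable estimates (binomial SE under 2%
on the recovery rates) while keeping a full run in seconds.

Degenerate inputs are handled explicitly rather than by accident: zero
uninduced colonies flag `absent` instead of dividing; an all-trimmed
cell population falls back to the untrimmed summary with a flag;
constant montages pass through contrast adjustment unchanged; flat time
courses are `non_degrading` with an infinite half-life sentinel; plate
groups with fewer than three scorable strains skip normalization with a
warning.

# Known limitations

* The responsiveness test is a per-strain two-sample test; it does not
  model plate- or day-level random effects, which real screens have.
* The delta-method CI on `t50` assumes approximate normality of the
  rate estimate; with very few timepoints or strong heteroscedasticity
  the bootstrap path is the safer choice.
* Cross-timepoint intensity comparisons are only meaningful within one
  acquisition profile; the package never compares raw intensities
  across different exposure settings.
* Manual phenotype annotation (morphology classes, blind review) is out
  of scope; such labels can be joined as metadata columns but are never
  computed.
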