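---
title: "Methods: microcharcoal quantification and fire-regime statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microcharcoal quantification and fire-regime statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microfire)
```

## The problem

Vegetation fires leave microscopic carbonized particles — microcharcoal —
that wind and rivers deliver to sediment basins within months of a fire.
In deep-sea cores off the European margin, a depth-resolved microcharcoal
record is therefore a proxy for regional biomass burning over the last
glacial cycle, at the tempo of the millennial Dansgaard–Oeschger
oscillation: warm/wet Greenland Interstadials (GI) grow fuel (forest,
heathland) and burn more; cold/dry Greenland Stadials (GS) and the extreme
Heinrich Stadials (HS) carry semi-desert vegetation and burn less.

`microfire` implements the full measurement-and-analysis chain for this
kind of record: particle detection in transmitted-light micrographs, the
CCsurf concentration proxy, piecewise-linear age-depth modelling, and
phase-stratified statistics of the fuel–fire coupling. Because original
core material and slide scans are generally not public, the package also
ships generators for synthetic micrographs and synthetic core records with
known ground truth; every stage is validated against data whose answer is
known by construction.

## Particle detection and CCsurf

Charcoal in transmitted light is black, opaque, and angular with sharp
edges. The main false positive is vitrinite — unburnt organic matter
eroded from sedimentary basins — which is also dark but rounded and
slightly less opaque; in the original laboratory workflow it is identified
by reflectance petrography and used to calibrate the detection threshold.
The detector models this as a two-screen classification on connected
components of the thresholded image:

1. **Binarize**: pixel is foreground iff intensity `<=`
   `binarization_threshold` (default 100 on the 8-bit scale).
2. **Label**: connected components under 8-connectivity (4 available for
   sensitivity analysis); components below `min_particle_pixels`
   (default 4) are discarded as noise. Particles touching the field edge
   are kept; flip this by filtering on the reported bounding boxes.
3. **Classify**: a particle is charcoal iff it is *opaque*
   (`mean_intensity <= opacity_cutoff`, default 50) and *angular*
   (`circularity <= max_circularity`, default 0.9). Solidity is reported
   for audit but does not gate by default.

The charcoal pixel count $P$ of the accepted particles is converted to the
concentration of microcharcoal surface area per gram of dry sediment,

$$\mathrm{CC_{surf}} = \frac{P \, S_p \, S_r}{D\, W\, S_s}
\quad [\mu m^2\,g^{-1}],$$

with $S_p$ the pixel area, $S_r$ the filter area, $D$ the residue
dilution, $W$ the dry sediment weight and $S_s$ the scanned area. Surface
area, not particle number, is accumulated: taphonomic fragmentation
multiplies counts but conserves area. Defaults encode the standard
extraction protocol ($W = 0.2$ g, $D = 0.1$, 47 mm filter); $S_p$ and
$S_s$ depend on the microscope set-up, are not standardized, and must be
supplied per study — the defaults (0.25 um^2, 1e8 um^2) are placeholders.

### Shape-metric conventions

Circularity is $4\pi A / P^2$ computed in pixel units with the perimeter
counted as **exposed pixel edges** (unit edges between a particle pixel
and background or the image border). The convention is exact and
deterministic: a digitized square of side $s$ has perimeter $4s$ and
circularity $\approx 0.785$; elongated or spiky shapes score lower. Note
that under edge counting a rasterized disk scores *below* a square
($\approx 0.62$), so the circularity ceiling is a screen against thin or
ragged over-segmented detections rather than a circle detector; in
practice the opacity screen is what rejects the rounded, semi-opaque
vitrinite. Solidity is pixel count divided by the number of lattice pixels
inside the convex hull of the particle's pixel centres, enumerated
exhaustively (no polygon-area approximation), so its unit tests are exact.

### Threshold calibration

The laboratory "best-fit threshold" is petrographic and cannot be
reproduced without the original slides, so the threshold is explicit
configuration. Two helpers replace the calibration loop:
`auto_threshold()` (Otsu's between-class-variance argmax on the 256-bin
histogram; when the histogram has an empty gap between modes the argmax is
a plateau and we take its first point) and `calibrate_threshold()`, which
sweeps candidate thresholds against labelled fields and reports the pixel
recovery error. On synthetic fields any threshold in the wide gap between
the charcoal and background modes recovers ground truth exactly.

### What counts as $P$

The pixel count sums **accepted particles only**, not all sub-threshold
pixels. This is the stricter reading of "pixels identified as charcoal":
pixels of rejected (vitrinite-like) components do not contribute. With the
default configuration the two readings differ exactly by the rejected
components' pixels, which the per-particle audit table makes explicit.

## Chronology

Age-depth models are piecewise linear through dated control points —
the convention implicit in control-point chronologies; no spline option
is offered. Validation rejects duplicate depths and age reversals (naming
the offending pair). Interpolation is exact at control points;
extrapolation beyond the dated span is refused unless explicitly enabled
(linear continuation of the end segments), because analyses should stay
inside the dated 70–10 kyr window. Sedimentation rates are per control
interval ($\Delta d / \Delta a$, cm kyr$^{-1}$), with a per-sample lookup.
Ages are kyr cal BP throughout; sampling resolution is reported in years.

A phase table may declare `HIATUS` intervals (a real feature of one of the
cores this workflow was designed around); samples inside a hiatus are
unassigned and excluded from every statistic.

## Phase stratification and fire statistics

Phase membership on the BP scale uses half-open intervals with the *older*
bound inclusive: age $a$ belongs to a phase when
$\mathrm{age\_end} < a \le \mathrm{age\_start}$. The single youngest phase
also includes its young edge, so a record ending exactly at the table's
young terminus keeps its last sample. This makes phase assignment a
partition: every sample lands in at most one phase.

Per-phase summaries are unweighted means and sample SDs over all samples
assigned to the phase; empty phases are reported with $n = 0$, and SD is
undefined below $n = 2$.

**Fuel–fire coupling.** The coupling between the biomass index $B$ (a
pollen-percentage sum: Ericaceae + open Mediterranean forest for Iberia,
arboreal pollen excluding the over-represented *Pinus* for France) and
CCsurf is fitted as $\mathrm{CC_{surf}} = \alpha + \beta \ln B$. The
headline statistic $b$ is reported as the Pearson correlation between
CCsurf and $\ln B$ — the reading under which published values such as 0.79
and 0.525 satisfy $|b| \le 1$ — while the slope $\beta$ and its standard
error are reported separately, so either reading of a printed "b" can be
checked. The p-value is the two-sided t-test for zero correlation; an
exact permutation p-value (`n_perm` shuffles) is available as a
distribution-free cross-check. Phase-level fits use the per-phase means;
HS phases are kept separate from GS by default and can be pooled with
`pool_hs_with_gs`. No multiplicity correction is applied by default (none
is standard in this literature); users running families of per-phase tests
can pass the collected p-values through `stats::p.adjust(method = "BH")`.

**Confidence ellipses.** The 95% ellipse for a phase's
$(B, \mathrm{CC_{surf}})$ cloud is the normal-theory ellipse: centred at
the sample mean, axes along the covariance eigenvectors, squared
semi-axes equal to eigenvalue times $\chi^2_{2}(0.95)$. For two degrees of
freedom the quantile has the closed form $-2\ln(1-p)$, which the tests use
as an independent oracle. Collinear clouds raise an error naming the
collapsed direction rather than returning a degenerate ellipse.

**Independence checks.** If CCsurf tracked sedimentary input or dilution
rather than fire, it would correlate with sedimentation rate.
`independence_check()` reports Pearson $r$ with a two-sided p-value on the
aligned sample series and, when a phase table is supplied, on per-phase
means (the climatic-event-level control).

**Long-term trend.** Least squares of CCsurf on age within a window. The
slope is per kyr of *age*, so a positive slope means the fire regime
decreases toward the present.

## The synthetic-data generators

**Micrographs.** Three particle classes on a uniform background
(default 200): charcoal as random star-shaped polygons with 3–8 vertices
at intensity 15 (opaque, angular), vitrinite as rotated ellipses at 90
(dark but above the opacity cutoff, rounded), debris as low-contrast
ellipses at 170. A rasterized particle is forced to be a single
8-connected blob of at least 4 pixels (near-degenerate slivers are
redrawn), particles are placed with a minimum 3-pixel gap and never
overlap (a crowded field errors out rather than overlapping silently),
and Gaussian intensity noise (default SD 5) is added last, rounded and
clipped to [0, 255]. Ground truth (per-particle class, pixel mask, area)
is returned with the field, and identical parameters give bit-identical
output. Intensity levels are free parameters, not calibrated to any real
slide material: the generator preserves the *structure* of the
classification problem (ordered opacity levels, shape contrast), not the
photometry of a particular microscope. There is no point-spread blur,
no uneven illumination, and no taphonomic fragmentation, so a perfect
pixel-recovery score on synthetic fields demonstrates the correctness of
the detection chain, not expected performance on real slides.

**Core records.** Samples every 10 cm over 420–2000 cm, dated by 10
control points spanning 10–70 kyr whose ages are jittered independently
of everything else (so sedimentation rate is independent of the fire
proxy by construction). Phases alternate GI (1.75 kyr) and GS (1.25 kyr)
with every 4th stadial an extended HS (2.5 kyr) — the D–O tempo. The
biomass index is drawn per sample around the phase-class mean (GI 40%,
GS/HS 8%, free parameters reproducing the interstadial/stadial fuel
contrast), truncated into [0.1, 100] *before* the coupling is applied;
CCsurf is $\alpha + \beta \ln B$ plus additive Gaussian noise, floored at
zero ($\alpha = 10^5$, $\beta = 5 \times 10^4$, noise SD
$3 \times 10^4$ um^2/g, chosen to give stadial/interstadial levels around
$2$–$3 \times 10^5$ um^2/g and a phase-level correlation near 0.9). The
default biomass noise SD is 2%: a quarter of the stadial mean, so the
Gaussian draw respects the index's support and truncation stays
negligible — with a larger SD the truncation floor would bias the
log-coupling and the generator would violate its own recovery contract.
Each sample also carries the implied charcoal pixel count
$P = \mathrm{round}(\mathrm{CC_{surf}} / c)$, where $c$ is the
concentration value of one pixel under the sample's measurement
constants, so imaging-free pipeline runs still exercise the CCsurf
arithmetic end to end (round-trip exact to half a pixel's worth of area).

## Numerical and design choices

* **RNG discipline**: generators take a seed, run in a restored-on-exit
  RNG scope, and derive deterministic sub-streams per internal call;
  identical inputs give byte-identical outputs (file checksums are
  compared in the tests).
* **Degenerate inputs** error loudly and specifically: age reversals name
  the pair, collinear ellipses name the direction, constant series refuse
  a correlation, uncovered phase ranges list the uncovered interval,
  missing taxon groups are not silent zeros.
* **Calibration of the independence check**: Pearson's nominal level
  presumes exchangeable draws. Under the default GI/GS structure both the
  sample-level series (alternating phase pattern) and the sedimentation
  rate (a 9-step function) are autocorrelated, and the test is measurably
  *conservative* (about 3% rejection at the 0.05 level). The calibration
  experiment in the acceptance suite therefore uses records with a single
  phase covering the record — the configuration in which the fire proxy
  is i.i.d. and a nominal 5% rate is the correct expectation — while the
  default-structure series are used to verify the absence of spurious
  correlation ($|r| < 0.2$ in well over 95% of replicates).
* **Problem sizes**: the validation suite uses 50–100 synthetic fields of
  256 x 256 px, 200–500 synthetic cores of ~160–500 samples, and 200
  replicates of n = 1000 for ellipse coverage; these sizes put the
  Monte-Carlo error of each calibrated rate near or below one percentage
  point, which is what the stated tolerances require.

## Known limitations

* The detector assumes well-separated particles; touching particles merge
  into one detection (no watershed splitting).
* Circularity under edge-counted perimeters saturates near 0.785 for
  compact shapes; it cannot distinguish circles from squares and is not
  intended to.
* The generators emulate statistical structure, not optics or taphonomy;
  validation results transfer to real material only to the extent that
  real charcoal/vitrinite intensities are separated the way the level
  parameters assume.
* Radiocarbon calibration, reservoir corrections and ice-core tuning are
  out of scope: control points are taken as already calibrated.
* Pollen counting itself is out of scope; biomass indices start from
  tabulated taxon-group percentages.
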