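---
title: "Quantifying mitochondrial dynamics in germline stem cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial dynamics in germline stem cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodynamics)
```

## The problem

Ovarian germline stem cells (GSCs) of *Drosophila* sit in a niche at the
anterior tip of the germarium and are progressively lost with age. One
cellular correlate of that loss is a shift in mitochondrial dynamics: the
balance of fusion (which builds elongated, networked mitochondria) and
fission (which produces small fragments) tilts toward fission as the cell
ages, and mitochondria smaller than 0.05 um^3 accumulate. Quantifying
that shift requires several distinct measurements — 3D segmentation and
size classification of mitochondria in volumetric stacks, time-lapse
tracking with fission/fusion event detection, 2D morphometry of
electron-microscopy sections, and clonal (mosaic) statistics of stem-cell
division and maintenance.

`mitodynamics` implements that whole measurement chain, together with a
ground-truthed synthetic-scene simulator, so every stage can be exercised
against data whose true answer is known. The package is organized as a
set of small, composable functions plus a `run_pipeline()` driver; the
`analysis/` scripts in the source repository run the five canonical
analyses end to end.

## Segmentation model

An acquired time point is an `image_stack`: a 3D grid of non-negative
intensities with a physical voxel size in micrometres. Segmentation is
hysteresis thresholding: a voxel is foreground when its intensity is at
least the *low* threshold **and** it is connected, under the declared
connectivity, to at least one voxel at or above the *high* threshold.
Weak object peripheries therefore survive only when attached to a strong
core, and isolated background fluctuations in the `[low, high)` band are
discarded. Connected components of the surviving foreground are the
mitochondria.

Numerical choices:

* **Connectivity** defaults to 26 in 3D (8 in 2D): a diagonal touch joins
  voxels. It is configurable; the default is the permissive convention,
  chosen so that thin diagonal necks do not artificially split objects.
* **Thresholds** are user inputs. `auto_thresholds()` offers a heuristic
  (`high` = Otsu on frame 1, `low = high/2`), flagged as such — it is a
  starting point, not a calibration.
* **Volume** is voxel count times voxel volume; an object is *fragmented*
  when its volume is strictly below the 0.05 um^3 cut. The boundary case
  (exactly 0.05) is *not* fragmented: the rule is a strict "smaller
  than", and we resolve the tie deterministically on the large side.
* **Mitochondrial content** is total mitochondrial volume over the cell
  volume, reported as a percentage. Cell volume is a supplied number:
  cell boundaries come from independent markers, and their segmentation
  is out of scope.

**Photobleaching correction** rescales every frame multiplicatively so
its global mean matches frame 1. This is the simplest correction
consistent with a named "bleach correction" step: it preserves
within-frame rank order exactly (so thresholding geometry is unchanged)
and removes the first-order intensity decay. It does not model
background-versus-foreground differential bleaching.

## Tracking model

Objects in adjacent frames are linked when their voxel masks share at
least `min_overlap` voxels (default 1). Working on exact voxel masks
makes linking parameter-free; the minimum-overlap parameter exists only
to emulate the slack of sphere-approximation trackers. Track IDs are the
connected components of the graph whose nodes are `(frame, object)`
pairs and whose edges are links — any two objects that ever share
material share a track.

Events fall out of link multiplicities at each transition: out-degree
d >= 2 at frame *t* is one fission with *d* children; in-degree d >= 2 at
frame *t+1* is one fusion with *d* parents; one-to-one links are mere
persistence. Unlinked objects are births or deaths — bookkeeping records,
not events: with no gap closing (a design choice; the acquisition this
models has no systematic dropout), a disappearance is simply the end of
a track. Simultaneous split-and-merge patterns at one transition are
decomposed into these degree-based events; no composite event type is
inferred.

The counting identity

```
N(t+1) - N(t) = sum(children - 1 | fissions) - sum(parents - 1 | fusions)
              + births - deaths
```

is a theorem of these definitions and is asserted over enumerated link
graphs in the test suite.

## Window-capped dynamics statistics

Live recordings are analysed over three windows of time points, 1–4, 4–7
and 7–10 (1-based, inclusive; consecutive windows share exactly their
boundary time point, so the transition sets partition). Per track and
window **at most one event is counted**; a track can therefore total at
most three counted events. When several events fall in one window the
earliest transition wins, and if a fission and a fusion tie at one
transition, fission is counted. That tie-break makes the cap an exact
theorem of the counting rule rather than an empirical upper bound; raw
multiplicities are retained for diagnostics.

Tracks are then typed from their counted events: *balanced* (equal
fissions and fusions, at least one of each), *fission-dominant*,
*fusion-dominant*, *quiescent* (nothing counted). Reported class
proportions are over non-quiescent tracks, because a three-class
breakdown summing to ~100% is only meaningful over tracks that did
something; the quiescent count is reported alongside. The *balanced*
class generalizes "one fission and one fusion" to equal counts, which
under the cap can only be 1-and-1 within three windows unless all three
windows fire.

Two scalar summaries:

* **Proportional difference** `(F - f)/(F + f)` in `[-1, 1]`, positive
  under fission preference. The raw difference `F - f` is available, but
  the normalized form is comparable across cells with different event
  totals. It is undefined (and excluded) when `F + f = 0`.
* **Fluctuation series**: the per-frame fragmented-object count and its
  consecutive differences (`+1` when a fragmented mitochondrion appears,
  `-1` when one is absorbed), with the telescoping identity
  `sum(delta) = last - first`. `trend_slope()` is a plain OLS slope and
  can be fitted to any of the series.

On the choice of series for trend analysis: the averaged delta series is
the conventional display of this statistic, but its OLS slope is *not* a reliable sign
readout of a constant fission/fusion excess — a constant net rate gives a
constant delta level and hence zero expected slope, and simulations
confirm the slope of the delta (and even of the fragmented-count series)
is dominated by which objects happen to be eligible for events. The
direct, construction-exact readout of net balance is the **total
object-count series**: every fission adds one object, every fusion
removes one. The pipeline reports OLS trends of all three (total count,
fragmented count, averaged delta); the sign-recovery property in the
test suite is asserted on the total-count trend.

Between-group comparisons of class tallies use the Pearson chi-squared
test on the count table (no continuity correction for tables beyond
2×2; Yates optional for 2×2), computed by `stats::chisq.test`.

## TEM-style 2D morphometry

Thin-section profiles are measured by area (pixel count × pixel area)
and the width-to-height ratio W/H >= 1. W and H are the side lengths of
the **minimum-area rotated bounding rectangle** of the pixel set, plus
one pixel so that pixel extent rather than centre spread is measured.
This definition is rotation-robust, gives a disc ratio of 1 and an
axis-aligned a×b rectangle exactly a and b. The frequently used
max/min-Feret alternative is available (`mode = "feret"`), but note that
the maximum Feret diameter of a rectangle is its diagonal, so Feret W/H
of a 2:1 rectangle is ~2.24, not 2; we prefer the bounding-rectangle
convention precisely because elongation of near-rectangular profiles
reads off directly.

Classification is anchored at the reference (young) sample means — by
default area A* = 0.11 um^2 and ratio R* = 2.34, the published young-GSC
anchors: area > A* and ratio > R* is *elongated*; area > A* with ratio
<= R* is *medium*; area <= A* is *fragmented* regardless of shape.
Boundary equalities fall to the "smaller" class, a deterministic
resolution of cases the strict published inequalities do not cover.
Thresholds are frozen from the reference sample and never re-derived
from a comparison sample. Section-orientation bias (a 3D organelle cut
obliquely looks smaller and rounder) is acknowledged but not modelled
beyond the synthetic population's dispersion.

## Clonal-mosaic statistics

In marker-loss mosaics, the clone lineage is marker-negative. For a
germarium with at least one GSC of each lineage, the **relative division
rate** is

```
(progeny_neg / GSC_neg) / (progeny_pos / GSC_pos)
```

with the numerator lineage set by an explicit `orientation` flag
(published descriptions of the ratio disagree between their methods text
and figure legends on which lineage sits on top, so every output labels
the convention; the default puts the marker-negative clone in the
numerator, making values < 1 mean "the clone divides slower"). Germaria
missing a lineage, or with zero progeny in the denominator lineage, are
excluded with a recorded reason — never coerced to 0 or infinity.

Two aggregates are computed. The per-germarium mean (± SEM) mirrors
published bar plots but is *biased upward* at realistic progeny counts:
with X, Y independent Poisson(lambda) counts, E[X/Y | Y>0] =
lambda · E[1/Y | Y>0] ≈ 1 + 1/lambda + O(1/lambda^2), about +25% at
lambda = 5. The package's headline estimate is therefore the **pooled
ratio of means**, `(sum prog_neg / sum GSC_neg) / (sum prog_pos / sum
GSC_pos)`, which is consistent under the null and is what the
calibration check compares to 1.0. Both numbers appear in
`clonal_summary()`; the test suite checks the simulated per-germarium
mean against the analytic biased expectation as an oracle.

**Maintenance** at week *w* is the percentage of assessed germaria
retaining at least one marker-negative GSC; **clone composition** splits
clone-bearing germaria into *partial* (mixed GSCs) and *full* (all
marker-negative), summing to 100.

## The synthetic-scene generator

The simulator is the package's oracle: it produces 4D scenes with a full
per-frame object table, an event log, and true counts, so segmentation
and tracking can be scored exactly.

What it emulates:

* 50–200 ellipsoidal mitochondria in a GSC-sized voxel grid (default
  96×96×48 voxels at 0.1 um — a 9.6 × 9.6 × 4.8 um field). Individual
  volumes are lognormal with arithmetic mean 0.4 um^3 (the measured mean
  individual volume) and a wide spread whose lower tail crosses the 0.05
  um^3 fragmentation cut; aspect ratios are uniform on [1, 2.5].
* 10 frames by default. The emulated acquisition runs hundreds of ~2 s
  frames, but quantitative analysis is restricted to the first ten
  stacks (beyond which photobleaching and laser-induced fission distort
  counts), so ten frames is the analysis-relevant scene size.
* Brownian-like motion: independent Gaussian displacements, default sd
  0.05 um/frame per axis — small against object size, as expected at a
  ~2 s frame interval, which is the regime in which overlap tracking is
  well-posed. No measured motility statistics exist for this system;
  the scale is a free parameter.
* A fission/fusion program, either scheduled (exact transitions, types,
  optionally targets) or stochastic (Poisson counts per transition).
  Fission splits a parent's volume at a uniform fraction in [0.3, 0.7];
  fusion conserves the summed volume.
* Optics: flat background, uniform foreground, multiplicative
  photobleaching `exp(-b (k-1))`, optional isotropic Gaussian blur and
  Poisson shot noise.

Geometry guarantees, which make "exact recovery on noiseless scenes" a
designed property rather than an accident (all ellipsoids are
axis-aligned; orientation is not modelled):

* Distinct objects always keep a bounding-sphere surface gap of at least
  `min_gap` (default 0.2 um = two voxels, enforced by iterative
  push-apart with reflecting boundaries each frame), so a 26-connected
  segmentation can never merge two true objects.
* Fission children are centred inside the parent's current ellipsoid at
  ±0.6 of its longest semi-axis (guaranteeing parent–child voxel
  overlap, hence a detectable 1→2 link) while being separated from each
  other by a slab of >= 0.3 of that semi-axis (guaranteeing they
  segment as two objects). This requires parents of a minimum size
  (longest semi-axis >= 0.45 um, volume >= 0.12 um^3).
* Fusion first draws the two parents to tangency-plus-gap along one
  coordinate axis — only if each parent's jump keeps a thick overlap
  with its own previous position and lands clear of bystanders — and
  then places a volume-conserving child across the contact gap,
  penetrating both parents' previous masks by ~0.18 um.

What it does **not** emulate, and what that means for the tests: there
is no instrument point-spread function, no axial anisotropy, no
deconvolution artefacts, no clustered spatial organisation near the
fusome, no intensity heterogeneity within or between organelles, and no
correlated (directed) motion. Passing the exact-recovery and
segmentation properties therefore demonstrates that the *algorithms* are
correct under their stated assumptions — separated objects, adequate
sampling, monotone intensity — not that the thresholds or the tracker
would perform at that level on real light-sheet data, where contact,
blur and noise violate those assumptions routinely.

The mosaic and 2D-population simulators are deliberately plain
(Bernoulli loss per GSC per week, Poisson progeny, lognormal
area/ratio): they exist to give the clonal and morphometry statistics
known expectations (closed-form survival `(1-h)^w`, symmetric-null rate
1.0, configured means), not to model germarium biology.

## Reproducibility and problem sizes

Every stochastic function takes its seed from its config, and identical
configs reproduce byte-identical outputs; rendering derives a per-frame
noise seed from the scene seed. The test suite and the analysis scripts
use desk-scale sizes chosen to keep the full suite comfortably fast
while staying in the regime the methods target: scenes of 20–50 objects
over 6–12 frames, 100 random 20^3 grids for the segmentation oracle,
exhaustive 3+3 (plus sampled 4+4) link graphs for the event identity,
20 replicates per arm for sign-recovery, 500-germarium mosaics and
10,000-draw populations for the statistical calibrations.

`scripts/acceptance.R` recomputes the headline calibration — the pooled
relative division rate of a symmetric 500-germarium null mosaic — from a
fresh simulation at a caller-supplied seed and writes it as JSON.

## Known limitations

* Hysteresis thresholds are not auto-calibrated; the Otsu heuristic is a
  convenience, and vendor-software equivalence (surface models, spot
  spheres) is not claimable.
* No gap closing or re-identification: occlusion or a missed frame ends
  a track.
* The event model is pairwise-in/out-degree; a genuinely simultaneous
  three-way interaction at one transition is reported as its degree
  pattern, not as a composite.
* Cell boundaries are not segmented; mitochondrial content requires the
  cell volume as input.
* The 2D morphometry consumes masks or tabulated records; raw
  micrograph segmentation/denoising is out of scope.
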