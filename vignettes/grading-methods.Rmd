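---
title: "Morphometric mushroom grading: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric mushroom grading: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mushgrade)
```

mushgrade grades single specimens of *Stropharia rugoso-annulata* into
three appearance classes from a per-pixel cap/stalk segmentation. This
vignette is the package's account of the science: the measurement model
and its assumptions, every convention that affects a number, the
parameters worth tuning, what the synthetic test bed does and does not
emulate, and the places where the design was genuinely open.

## The measurement model

The input contract is a `label_mask`: an integer matrix over the image
grid with 0 = background, 1 = cap, 2 = stalk. Where the mask comes from is
deliberately outside the model — a trained instance-segmentation network
in production, the bundled colour-rule segmenter for rendered fixtures, or
PNG label maps from disk. Everything downstream consumes only the mask.

Morphometry proceeds in a fixed order:

1. **Component selection.** Per class, only the largest 8-connected
   component is measured; smaller components are treated as segmentation
   speckle. The component count is retained because it drives
   broken-specimen detection.
2. **Cap fit.** The cap's minimum-area *rotated* rectangle gives
   `D1` (long side), `H` (short side), and the tilt. The species
   assumption doing the work here is that a healthy cap is wider than
   tall, so long-side = diameter needs no further disambiguation.
3. **Upright rotation.** The whole mask is rotated by the negative tilt
   (nearest-neighbour, expanded canvas), bringing the cap's H-axis to
   image vertical.
4. **Stalk fit.** The stalk rectangle is re-fitted on the rotated mask.
   Its length `L` is the side whose axis is *closer to vertical*; `D2` is
   the perpendicular side. The rule is directional on purpose: a squat or
   bent stalk wider than long still reads correctly, because growth
   direction — not magnitude — defines length.
5. **Indexes.** `RDHP = D1/H` and `RLDS = L/D2`. Both are unitless, which
   is why the pipeline never needs pixel-to-millimetre calibration: a
   fixed camera geometry is sufficient.

### Why a rotated rectangle

An axis-aligned bounding box yields two side lengths but no orientation,
and the pipeline must *rotate* the image to make the stalk rule
meaningful. Only a rotated minimum-area rectangle supplies both
measurements and the angle in one primitive, so that is what the package
fits — rotating calipers over the convex hull of foreground pixel
centres, with the axis-aligned orientation always included as a
candidate so the fit can never be worse than the naive box. Side lengths
are reported as pixel-centre extent plus one pixel, so a filled
axis-aligned 40 × 20 block measures exactly 40 × 20.

### Coordinate and angle conventions

One set of conventions is used everywhere and exercised by fixtures:
image origin top-left, x rightward (columns), y downward (rows); angles in
degrees from the image x-axis to the rectangle's *long* side, normalised
into [-90, 90). Under these conventions the cap's tilt — the deviation of
its H-axis from vertical — numerically equals the cap rectangle's angle.

### Ties and degenerate inputs

* **Near-square cap** (`D1 − H` below `tie_tol`, default 1 px): the
  D1 > H rule cannot orient the mushroom. The fit is still returned, an
  ambiguity warning is raised, and the pipeline falls back to using the
  stalk's long axis as the vertical reference — the anatomically natural
  substitute.
* **Stalk at exactly 45°:** both sides are equidistant from vertical; the
  tie breaks deterministically to `L = long side` (the common anatomy)
  with a warning.
* **Empty, single-pixel or collinear masks** raise a typed
  degenerate-geometry error rather than returning a meaningless
  rectangle; an absent class raises a typed empty-class error.
* **Boundary pixels:** nearest-neighbour resampling keeps labels
  categorical during rotation; foreground count is conserved to within a
  few percent and the canvas is expanded so nothing clips.

## Grading rules

The three grades are half-open bands `[lo, hi)` of each index (table in
the README). The published criteria leave two things unstated, and the
package fixes both by convention:

* **Boundary ownership.** Printed ranges touch ("1.5 ~ 2.5" next to
  "1.0 ~ 1.5") without saying who owns 1.5. Half-open intervals make
  every boundary belong to the band that starts there; the convention is
  validated at construction, so user-supplied criteria that overlap or
  leave gaps are rejected.
* **RDHP above 2.5** belongs to no band. Since the published rule already
  says RLDS prevails whenever the indexes disagree, an out-of-band RDHP is
  treated as an automatic conflict and the RLDS band decides alone. The
  RLDS bands are therefore required to tile (0, ∞); the RDHP bands may
  stop at a finite top.

The conflict rule itself is simple dominance: the assigned grade *is* the
RLDS grade; `conflict` records whether RDHP agreed. Property tests sweep
10,000 random ratio pairs for totality and dominance.

**Broken specimens.** The deployed behaviour — broken mushrooms skip the
blowers — needs an operational definition of "broken", which the source
material does not give. The package uses three tests, in order: cap class
absent; stalk class absent; either class split into more than one
component each holding at least `min_fraction` (default 10%) of that
class's pixels. The threshold separates true fragmentation from
segmentation speckle and lives in the pipeline config.

## Segmentation metrics

`precision_recall_f1()` works on whatever counts the caller supplies —
instance counts (how many stalks were recognised) or pixel counts — since
both usages occur in practice; the mode is the caller's choice, never
guessed. Pixel metrics (`miou()`, `mpa()`, `pa()`) follow the standard
confusion-matrix formulas over k object classes plus background; the
background row/column is included by default with a flag to exclude it,
because both conventions appear in published comparisons. Batch
evaluation pools pixels across images (micro) by default, with a macro
flag, the aggregation being otherwise ambiguous. The grading score is the
unweighted mean of per-grade correct rates, reported to two decimals with
half-up rounding — the rounding that matches printed tables, not R's
half-even default.

## Air-blow physics

The sorting model is elementary mechanics with two deliberate readings:

* **Impulse.** The blow enters as `Vy1 = (F·Δt0 + m·Vy0)/m` with
  `F = P·S`: pressure must be multiplied by the tube cross-section before
  it can act as a force. This is the only dimensionally consistent
  reading of an impulse expression involving a pressure.
* **Friction sign.** Written literally, the crossing equations add the
  friction term to the velocity — friction *accelerating* the mushroom
  across the belt. Physically friction opposes the crossing. The package
  implements both: `mode = "friction_decelerates"` (default) uses
  `Vy2 = sqrt(Vy1² − 2·a·d)` with stall detection when the discriminant
  goes negative, and `mode = "as_printed"` reproduces the literal plus
  sign. The closed forms are verified against a 10 µs-step numerical
  integrator of the same ODE to within 0.1% over a 100-point random
  parameter sweep.

A consequence worth stating because it is easy to get backwards: the
downstream displacement `X = Δt1·Vx` *decreases* with ejection speed and
*increases* with friction and with mass — a faster crossing simply leaves
less time for the belt to carry the specimen downstream. The displacement
envelope over a mass range therefore has its maximum at the heaviest
specimen that still crosses.

`pi_const` defaults to 3.14 so that the worked constants come out exactly
as conventionally printed (tube section 50.24 mm², force 40.19 N,
break-even mass 41.01 kg); full-precision π is one argument away and
shifts the third significant figure.

**Defaults without a printed source.** Blow duration (1 ms), belt speed
(0.10 m/s) and belt width (0.20 m) are not stated in the source material;
they are chosen once here as plausible values for a small conveyor rig
and documented as such. For this reason the deployed system's printed
2.25–6.00 cm displacement range is *not* reproducible from first
principles; `displacement_envelope()` exposes the calculation for any
user-supplied values instead.

## The synthetic test bed

`render_mushroom()` rasterises a parametric mushroom — cap as a
half-ellipse of width `D1` and height `H`, stalk as a `D2 × L` rectangle
attached under the cap's midpoint with a 2 px overlap so the seam never
fragments — by testing every pixel centre in the shape's own frame, so
any rotation renders exactly with no resampling. Membership is half-open
(a region of width D covers on average D pixel centres), which makes the
rectangle-fit side lengths unbiased estimators of the rendered
dimensions. The ground-truth mask is always rendered before noise.

What it emulates: one mushroom per frame, arbitrary in-plane pose, the
cap-wider-than-tall anatomy, broken variants (missing cap, missing stalk,
fragmented stalk), mild Gaussian blur and brightness shift. What it does
not: photorealistic texture, shadows, belt background, occlusion,
out-of-plane pose, multi-instance frames, or the failure modes of a real
segmentation network. Passing round-trip tests therefore validate the
*geometry* — that measurement inverts rendering — not field segmentation
robustness.

**Study conditions.** The default generator draws on a 384 px canvas with
cap height 54–90 px and stalk diameter 30–48 px, rotation uniform in
[0°, 360°), and index values uniform inside the target grade's band inset
by 0.05 from each boundary. The scale sits a factor of roughly four below
the real imaging geometry (a stalk at 40 cm from a 1280 × 960 camera
spans hundreds of pixels), keeping pixel-quantisation error — about
±1–2 px per dimension after nearest-neighbour rotation — a small fraction
of each measured quantity while the 300-fixture round-trip suite runs in
well under a minute. Grade-3 fixtures deserve a note: their nominal RDHP
band lies below 1, which no renderable cap can satisfy under the D1 ≥ H
anatomy, so they carry a grade-2 RDHP and reach grade 3 through the
RLDS-prevails rule — exactly the conflict path the criteria define.
Balanced mixes are apportioned by largest remainder, so requested
proportions are hit within one fixture.

All sampling flows from a single integer seed; rendering given a spec is
fully deterministic, and identical seeds give byte-identical datasets and
reports.

## Problem sizes and verification

The test suite (and the acceptance script) uses: a 300-fixture balanced
noiseless set for round-trip parameter recovery; 100 random convex blobs
at 64 px for equivalence of the calipers fit with a 0.1°-step brute-force
sweep (within 1% area); 100 random parameter draws for the
kinematics-vs-integrator comparison (within 0.1%); and 10,000 random
ratio pairs for the grading-rule properties. These sizes make the whole
suite complete in about a minute on one core while leaving the sampling
dense enough that the property checks are not vacuous.

## Known limitations

* Measurements are max-extent based (a bounding rectangle), so a single
  protruding mislabelled pixel inflates a dimension; the largest-component
  filter removes detached speckle but not attached protrusions.
* The stalk is measured after one nearest-neighbour rotation, which adds
  up to about a pixel of jagged-edge error on each dimension; at realistic
  image scales this is negligible, on very small masks it is not.
* The vertical-side rule misreads stalks that emerge from the cap at
  large angles (bent specimens), and the half-ellipse cap model has no
  analogue of in-rolled or wavy cap margins.
* The physics model omits aerodynamic drag, jet spreading, tumbling and
  actuator delays; it is a placement model for collection boxes, not a
  flight simulator.
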