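---
title: "Canopy traits and decision indicators for spaced lettuce: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy traits and decision indicators for spaced lettuce: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lettucecv)
```

## The measurement problem

Greenhouse lettuce on a spacing system starts at 92 heads/m² and is
periodically re-laid down the density ladder 92 → 60 → 45 → 30 → 23 → 18 →
15 heads/m² as the heads grow. Two operational decisions dominate the
economics of a batch: *when to space* (too late and overlapping leaves stop
intercepting light per head; too early and light falls on empty floor) and
*when to harvest* (the sellable target is a 250 g head). Both can be driven
from a fixed top-down RGB-D camera about 1 m above the crop.

This package implements that measurement chain and the two indicators built
on it, together with a synthetic scene generator that supplies ground truth
for every stage.

## Canopy traits from one RGB-D frame

**Segmentation and coverage.** A binary lettuce/background mask comes either
from an external (typically learned) segmenter supplied as 0/255 PNGs, or
from the built-in classical baseline: a pixel is lettuce when its
excess-green index $2G - R - B$ exceeds a threshold (default 20 on 8-bit
channels; `"otsu"` picks it from the index histogram). Coverage is the
lettuce-pixel fraction of the frame in percent. Mask quality is scored by
the mean of the per-class intersection-over-union of lettuce and background
(mIoU); a class absent from both masks contributes IoU 1, which makes the
metric total (the 0/0 convention is a design choice, the definition is
otherwise standard).

**Ground plane and heights.** Depth pixels are back-projected through the
pinhole intrinsics ($x = (u - c_x)z/f_x$, 0-based pixel coordinates,
camera $+z$ into the scene). On the planting-day frame the non-lettuce
points are fit with a RANSAC plane (defaults: 1000 minimal samples, 5 mm
inlier threshold, seeded RNG, total-least-squares refinement on the inlier
set), which absorbs slight skewness in camera mounting. The plane is fitted
once per batch and reused, assuming a static camera. Canopy height of a
lettuce pixel is its point-to-plane distance in cm (a vertical-difference
variant is available; the point-to-plane form is the default because the
distance to a tilted gutter plane is the physically meaningful elevation).
Heights that come out negative under sensor noise are clipped to zero
before any summation so noise cannot bias volumes.

**Volume and the harvest indicator.** Canopy volume is the height sum times
the pixel ground area, divided by the number of heads in the imaged area
(density × area), giving cm³/plant. Because the mask is flat, overlapping
leaves are counted once — volume under-reads biomass at high density, which
is precisely why volume alone is a poor harvest criterion. The harvest
indicator instead multiplies *area per plant*,
$(\mathrm{coverage}/100)/\mathrm{density} \times 10^4$ cm², by the maximum
canopy height (cm). The pixel-size factor in the volume formula is handled
as explicit dimensional bookkeeping (mm → cm at each step) and is validated
against closed-form oracles rather than carried as a single magic constant.

## The two decision indicators

**Light loss.** For a spacing event at time $t$ with coverages just before
($c_{t-1}$) and just after ($c_t$) and densities $d_{t-1} > d_t$:

$$\mathrm{LL}_{\mathrm{current}} = 100 - c_t, \qquad
  \mathrm{LL}_{\mathrm{before}} = c_t - c_{t-1}\frac{d_t}{d_{t-1}}, \qquad
  \mathrm{LL} = \mathrm{LL}_{\mathrm{current}} - \mathrm{LL}_{\mathrm{before}}.$$

The projection $c_{t-1} d_t / d_{t-1}$ is the coverage the move would give
if no leaf area had been hidden; any excess of the observed $c_t$ over it
measures overlap revealed by the move. $\mathrm{LL} \approx 0$ marks a
well-timed spacing, negative values mean too late, large positive values
too early. `evaluate_schedule()` applies this to the last frame before and
first frame after each density transition; events without both flanking
frames are skipped with a warning. The "near-optimal" label uses a ±5
percentage-point band — a reporting convenience, since the indicator's
narrative reading ("close to zero", "clearly negative") has no canonical
numeric band.

**Harvest.** Fresh weight is regressed on the indicator with a quadratic,
$w = c_0 + c_1 x + c_2 x^2$, fitted by least squares on calibration pairs
(destructive weighings against the indicator on the same dates). The
harvest threshold is the smallest indicator whose predicted weight reaches
the target (250 g); the package default of 7840 cm³ is used when no
calibration pairs are supplied. The recommended harvest date is the first
frame at or above the threshold; a series that never crosses reports
absence rather than erroring.

One scale subtlety matters in practice: when leaves overlap, the
image-derived indicator under-reads the true per-plant area × height, so a
threshold derived on the true scale may never be reached by the measured
series. Calibrating against the *measured* indicator (as one would with
real camera data, where no other scale exists) absorbs the compression;
the pipeline supports both, and the harvest-date route uses the measured
scale.

## Economics

Income is the class-price average (A 0.50 €, B 0.40 €, C 0 € per head)
times the average crop density — the harmonic mean
$D / \sum_d (1/\mathrm{density}_d)$ of the daily densities over the $D$
cultivation days, which is the correct per-m² basis because a head
occupies area in inverse proportion to its density. Costs are heating
(metered MJ/m², priced per kWh at 0.0375 €, with 1 kWh = 3.6 MJ exact),
electricity split by clock hour into on-peak [07:00, 23:00) at 0.125 €/kWh
and off-peak at 0.075 €/kWh (the half-open convention is a design choice;
the tariff statement gives only the interval endpoints), CO₂ at 0.12 €/kg,
fixed costs as a ledger input (their composition — plant material,
maintenance, depreciation — is not modelled), and 1 € per manual
intervention. Net profit is income minus the operational total minus the
intervention penalty. The ledger accepts a pre-totalled operational figure
because published breakdowns are often rounded per row independently of
their total.

## The synthetic scene generator

The generator emulates what the pipeline needs to see, not what lettuce
looks like.

* **Plant shape** is a spherical cap of base radius $a$ and apex height
  $h$ standing on the ground, restricted to $h \le a$ (at most a
  hemisphere). The restriction is load-bearing: a taller cap overhangs its
  base disc, the top-view height field becomes multivalued, and the
  closed-form area ($\pi a^2$) and volume ($\pi h (3a^2 + h^2)/6$) oracles
  no longer describe what a nadir camera integrates. Defaults keep
  $h = 0.8\,a$ throughout growth.
* **Growth** is discrete logistic per frame interval for both radius and
  height (defaults: initial 15/12 mm, asymptotes 160/128 mm, rate
  0.13/day), with optional per-plant asymptote jitter (CV 0.05). The
  asymptotes put a mature head at ~32 cm diameter and the 250 g crossing
  around day 35 of a 50-day cultivation, matching commercial timing; the
  rate follows from spanning that range in the cultivation window.
* **Layout** is a square grid at the pitch $1000/\sqrt{d}$ mm with one
  plant anchored on the optical axis, extended one mature radius beyond
  the imaged window so border pixels see clipped neighbours. Anchoring
  keeps successive layouts in phase, so window-sampled coverage responds
  to spacing the way an interior region of a large gutter would.
  Re-spacing maps plants centre-outward with their growth state untouched.
* **Rendering**: canopy elevation is the per-pixel maximum over plant
  fields (overlap occludes, hidden leaves contribute nothing); each pixel
  ray is intersected with the tilted ground plane exactly, and depth is
  the ground depth minus the elevation, plus Gaussian noise (default
  2 mm). The tilt (default 1°, supported to just under 10°) lives on the
  plane, not the camera, so the back-projection code is exercised against
  a known analytic plane. RGB is grey background with per-plant-jittered
  green, constructed so the excess-green baseline reproduces the
  ground-truth mask exactly — segmentation error can be injected by a
  user-supplied mask, it is not simulated.
* **Fresh weight** is quadratic in the true indicator with per-plant
  scatter (default SD 20 g), never negative; coefficients default to
  $c_0 = 10$, $c_1 = 0.0212$, $c_2 = 1.2 \times 10^{-6}$, placing the
  250 g crossing at ≈ 7841 cm³ — the published scale of the indicator.
  Quality classes follow the weight bounds (A ≥ 250 g, B 220–250 g,
  C below).

What the generator deliberately does **not** emulate: leaf morphology and
texture, stereo-matching artefacts of a real depth camera, instance-level
occlusion patterns, climate-driven growth variation, or segmentation
errors. Passing tests therefore demonstrate the correctness of the
measurement chain and the indicator arithmetic on dome-shaped crops — not
segmentation robustness on real imagery.

## Constructing near-optimal (and deliberately bad) schedules

`plan_balanced_schedule()` places each ladder transition at the frame
interval where the light-loss indicator of the event crosses zero,
scanning the generator's own noise-free masks (nominal, jitter-free
trajectory). A geometric point worth recording: for disc-shaped plants the
zero crossing sits slightly *past* the moment the heads touch at the
incoming density — spacing exactly at tangency of the outgoing density
leaves LL at roughly +30 to +49, and at tangency of the incoming density
still +6 to +17, because the floor-light term is still ahead of the
overlap term. Real lettuce deforms to fill space (coverage near 98% when
touching), which is why the same "just touching" intuition lands near zero
in practice while rigid discs need a little overlap to balance the books.
Spacing granularity matters: with the default growth rate the indicator
moves several points per day around an event, so the planner is normally
run at 4 frames/day. `delay_event()` shifts one transition later to
construct too-late scenarios, which score negative light loss as expected.

## Numerical and procedural choices

* Pixel coordinates are 0-based in the camera model ((row, col) 1-based
  inside R matrices); depth unit scaling is explicit (`depth_scale` mm per
  stored unit); invalid (zero) depth pixels are omitted, not imputed.
* The RANSAC refinement is a total-least-squares plane via SVD on the
  inlier set; degenerate (collinear) support is a reported failure, not a
  silent fallback. Normals are oriented toward the camera so heights are
  positive above the gutter.
* `max_height()` defaults to the true maximum; an order-statistic quantile
  (e.g. 0.99) is available because a single-pixel depth spike otherwise
  propagates into the harvest indicator.
* The quadratic's threshold is the smallest non-negative upward crossing
  of the target, computed from the closed-form roots; a flat or
  never-crossing fit reports absence.
* Determinism: one seed drives the generator (plant pool, then per-frame
  noise, in a fixed draw order) and a separate explicit seed drives
  RANSAC; `run_pipeline()` writes a config hash (excluding the output
  location) into every output, and identical configurations reproduce
  reports byte for byte.
* Problem sizes in the shipped tests and the acceptance script — 96–256 px
  rasters, 3–4 mm GSD, 40–50 day batches, 100-trial plane studies — are
  chosen so the full suite runs in a few minutes on one CPU while keeping
  every oracle comparison well inside its tolerance; the geometry is
  scale-free, so nothing changes qualitatively at camera-native
  resolution beyond runtime.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 9, days = 48, frames_per_day = 4,
                  image_size = c(128, 128), gsd = 3, growth = list(cv = 0))
cfg$schedule <- plan_balanced_schedule(cfg)
batch <- simulate_batch(cfg)
res <- analyze_batch(batch)
res$spacing[, c("time_days", "density_prev", "density_curr", "light_loss", "verdict")]
harvest_date(res$traits, threshold = 7840)
```

## Known limitations

* The classical excess-green baseline is exact on synthetic frames and
  useless as a statement about real-greenhouse segmentation accuracy;
  plug in a learned segmenter's masks for real data.
* Volume and the indicator inherit the flat-mask overlap bias; on real
  crops the bias depends on canopy architecture, and the measured-scale
  calibration is the supported way to absorb it.
* The economics module prices resource *use*; it does not model resource
  use from climate control, and market prices are fixed inputs.
* Heights assume a static camera after planting; camera motion
  compensation and multi-view fusion are out of scope.
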