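---
title: "Tracking label-free cells in phase contrast: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking label-free cells in phase contrast: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasetrack)
```

## The problem and the model

Unlabelled cells imaged in phase contrast cannot be segmented by their
outline — the cytoplasm boundary is faint and fluctuates — but their nuclei
reliably appear as the darkest compact structures on a bright background.
`phasetrack` therefore tracks *nucleus centroids*: it never attempts a
cytoplasm outline, and everything downstream (sizes, velocities) refers to
the dark nuclear region, whose equivalent circular diameter is smaller than
the visible cell.

The pipeline assumes: (i) grey levels in [0, 255] with cells darker than
background; (ii) lateral (translation-only) frame misalignment; (iii) cell
displacement per frame below a known physical bound; (iv) the background
grey distribution is unimodal and dominates the histogram. Fluorescence-like
series (bright cells) are handled by contrast reversal, `g -> 255 - g`.

## Registration

Consecutive frames from incubator microscopes are misaligned by a few
pixels even on repositioning plates. Frame *k* is registered to frame
*k − 1* by an integer grid search over ±`max_shift_search` px (default 20)
minimising the mean absolute grey difference on the overlap region,
followed by an independent 1-D parabola fit through the cost at the optimum
and its two neighbours in x and in y. The resulting fractional shift is
applied by bilinear resampling with edge replication, *cumulatively*, so
the whole series shares frame 1's coordinates (one consistent frame for all
trajectories). Two guards matter in practice: when the integer optimum sits
on the search boundary no refinement is attempted (and a warning is
recorded), and when the optimum cost is exactly zero — a perfect integer
match — refinement is skipped, because the parabola vertex would only add
boundary-induced bias. Crop margins applied downstream discard the
edge-replicated borders.

The mean absolute difference was chosen over correlation because it is
robust, cheap, and minimised by the true shift on every synthetic scene we
generate; any cost with that property would do. Registration needs static
image content: on a scene containing nothing but a handful of moving cells
the estimate degrades gracefully (each cell's own motion biases it by
roughly σ/√n cells), which is why the registration tests use scenes with
static background texture, as real series always have.

The *velocity sum per cell* — the magnitude of the mean displacement vector
of all matched cells between two frames, per unit time — is the exposed
diagnostic: random migration cancels in the vector mean, so values above
about 0.1 µm/min indicate residual global misalignment, and a single
uncorrected shift of *s* µm at interval Δt contributes at most *s*/Δt of
spurious velocity.

## Segmentation

Frames are first smoothed with an isotropic Gaussian of standard deviation
`gaussian_radius / pixel_size` pixels. "Radius" is interpreted as the
kernel σ in micrometres; the value should be large enough to smear the dark
intra-nuclear speckle into one basin (a few µm; the 10 µm default suits
25 µm nuclei at 0.645 µm/px) but well below the nucleus diameter.

The grey-level limit is then either **manual** — `mean(g) + z·sd(g)` with a
negative user z-score, the behaviour selected by any negative
`segmentation_limit` — or **automatic**: the background is modelled from
the dominant histogram peak, its σ estimated from the *bright* side of the
peak only (cells only darken pixels), via the half-width at half maximum
(σ = HWHM/√(2 ln 2), floored at 0.5 grey levels), and the limit set to
µ_bg − 3σ_bg. The manual rule is preferred for synthetic imagery with very
clean backgrounds, where σ_bg collapses and the auto limit hugs the
background peak.

Pixels below the limit are labelled with 8-connectivity. Touching cells are
separated by a boundary-curvature routine: the boundary of any region
larger than one `cutting_cell_diameter` disc is traced (Moore
neighbourhood), the signed turning angle computed over a ±m window
(m = max(3, 0.25·d_cut in px)), and concave local minima below −35° become
"neck" candidates. Necks are paired when the straight line between them is
shorter than `cutting_cell_diameter` *and* more than twice shorter than the
boundary path between them — the path condition prevents cutting across a
single bulge. The 1 px straight line between each accepted pair is set to
background; up to 3 passes split triplets. All four constants (window,
angle, path ratio, passes) are function arguments with these defaults; they
were fixed once against disc-dumbbell fixtures and not revisited.

Finally regions are gated by equivalent circular diameter
(`2·sqrt(area/π)`, from area, not perimeter) between
`smallest_cell_diameter` and `largest_cell_diameter`; scrapped regions are
counted by cause. Centroids are unweighted pixel-centre means, reported in
micrometres of the *uncropped* frame, so cropping never changes reported
coordinates.

## Tracking

Matching is greedy by displacement: all previous/current pairs within
`highest_cell_velocity × Δt` are sorted ascending and accepted while both
cells are free, with a deterministic tie-break (smaller previous label,
then smaller current label). The cells that moved least are matched first
because they are the most certain matches; on 5-cell jitter scenes the
greedy solution coincides with the brute-force minimum-total-distance
assignment in well over 95% of trials, and unlike the optimal assignment it
is linear-time in the number of candidate pairs and deterministic.

A detection with no match one frame back is offered to tracks that ended
two frames back, within `2 × max_step` (twice the one-frame bound, the
natural two-frame limit — the acceptance radius is otherwise unspecified in
the field). Accepted repairs insert an observation at the *midpoint* of the
flanking detections, flagged `repaired`; by the midpoint construction each
flanking step is again within the one-frame bound. Tracks unmatched for two
consecutive frames end; remaining detections start new tracks. Divisions
are *not* detected: the nearest daughter simply continues the track and the
other starts a new one, an emergent property of distance matching.

Optional track smoothing replaces each interior point by the
(¼, ½, ¼)-average of its neighbours, holding endpoints fixed; it is the
minimal endpoint-preserving low-pass, strictly contracts accumulated
distance on zigzags, and leaves collinear equally-spaced tracks unchanged.
It is applied only to finished tracks, never before matching. Only tracks
with at least `shortest_cell_track` observations enter metrics and
overlays.

## Metrics

Per track: duration `n_steps·Δt`; accumulated distance (sum of step
lengths); Euclidean distance (start to end); mean step velocity
(accumulated/duration); Euclidean velocity; directness
(Euclidean/accumulated); FMI per axis (net signed axis displacement /
accumulated distance, the convention of the standard chemotaxis analysis
tools). Perfectly static tracks report `NA`, not zero, for directness and
FMI, so population means skip them explicitly. In wound mode the wound
midline is the mean y of all track starting points and FMIy is sign-flipped
for tracks starting below it, making positive FMIy mean "into the wound"
from either side. Population velocity is computed in two stages — averaged
within each time step, then across time steps — so frames with many cells
do not dominate; per-track summaries weight tracks equally (the natural
choice when track lengths differ; length-weighting would re-derive the
per-step mean).

Velocity and distance distributions share one histogram engine: fixed-width
bins (1 µm for distances), normalised to 100%, accumulated; the mode is the
vertex of a least-squares parabola through the peak bin ±2 bins (5 bins,
closed-form), the median linearly interpolated within the median bin, and
tail fractions interpolated on the accumulated curve. A peak at the
histogram edge falls back to the peak-bin centre with a warning.

## The synthetic generator

The generator emulates exactly the features the pipeline's assumptions
touch: bright background (level 150), dark Gaussian-profile elliptical
nuclei (depression 60, diameter 16 ± 1.5 µm by default), optional static
etching cross and speckle texture, global frame jitter applied *after*
rendering (ground truth stores pre-jitter world coordinates), iid pixel
noise added last, and motion by drift + isotropic Gaussian steps
(σ = 2 µm per 10-min step by default) with border reflection. Two choices
deserve note. Overlapping nuclei composite by *darkest-wins*, not
additively — nuclei are opaque objects, and additive shading would create
artificial dark bridges between near cells that no threshold could break.
And nuclei exclude each other: pairs closer than 1.1× their mean diameter
are relaxed apart, as real nuclei cannot interpenetrate. Divisions replace
a cell by two daughters offset 0.6 diameters to each side (then relaxed),
which keeps both daughters in range so the tracker's nearest-daughter
behaviour is exercised deterministically per seed.

What the generator does **not** emulate: optics (defocus, phase halo beyond
a cosmetic ring), intensity heterogeneity within and between nuclei, shape
change, cell death, or non-rigid image distortion. Passing tests therefore
demonstrate the pipeline's algorithmic correctness under its stated
assumptions, not its performance on any particular microscope; settings
still need tuning per cell line on real data, as with any threshold-based
segmenter.

## Numerical and interface choices

Coordinates: pixel (0, 0) at top-left, x rightward, y downward; positions
in µm = pixel index × pixel size at pixel centres; all tables in µm and
minutes. Settings files are `Key = value` text with case-insensitive keys;
both the ASCII minus and the typographic en-dash/minus are accepted
(defaults listings in circulation print the latter). The segmentation limit
default is `"auto"`; any negative number switches to the z-score rule.
TIFF is the image interchange format on both ends — lossless, so
write-then-read round-trips exactly after 8-bit quantisation; no AVI codec
is bundled, users export AVI to TIFF first. Overlay "videos" are multi-page
RGB TIFFs with green cell outlines and coloured track trails; only tracks
whose cell is present in the frame are drawn, so the trajectory plots are
the place to see *all* valid tracks. Flat-field correction exists in two
forms: per-frame (subtract a wide Gaussian background, for single frames
and smooth illumination ramps) and per-series (subtract the lightly-blurred
temporal median frame). The temporal median is used by the pipeline because
a static artefact only a few cell diameters wide cannot be separated from
cells by spatial scale alone, while it vanishes from the pixelwise median
of frames between which cells move.

Problem sizes in the test-suite and acceptance script (chosen as the
smallest scenes that make each statistical check sharp): 150-cell,
16-frame, 900² px videos for the alignment diagnostic and Brownian
recovery (≈2200 steps); 30-frame 300² px speckled scenes for jitter
recovery; 200 five-cell trials for the linker audit; 5000 Rayleigh draws
for the distribution machinery; a 24-frame, 3-h-interval series for
proliferation-rate recovery.

## Known limitations

No cytoplasm outlines, no division detection or lineages, no track
editing, translation-only registration, and tracks fragment in confluent
scenes (wound fronts): directness, accumulated/Euclidean distance and FMI
from fragmented tracks should be interpreted with caution even though
front velocities remain reliable. The velocity measured for slow cells is
inflated by nucleus-centre jitter between frames; longer sampling
intervals (frame skipping) or track smoothing reduce it, at the price of
clipping genuinely fast excursions.
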