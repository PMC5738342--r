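---
title: "PhaseTrack: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PhaseTrack: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(PhaseTrack)
```

PhaseTrack quantifies the morphodynamics of confluent endothelial
monolayers from phase-contrast time-lapse movies. This vignette is the
package's own account of the models it implements, the parameters that
matter, the numerical choices behind them, and what the synthetic
validation does and does not demonstrate.

# The segmentation model

Each frame is treated independently. A binary labelling $x$ of the
pixel grid (foreground = cell material, background = free substrate)
is scored by the energy

$$E(x) \;=\; \lambda \sum_p u_{x_p}(p)
\;+\; \beta \sum_{(p,q) \in \mathcal N} [x_p \neq x_q]
\;+\; \sum_{c \in \mathcal C} \min\!\Big(\gamma, \;
  \gamma \frac{m_c(x)}{q\,|c|}\Big),$$

with $\mathcal N$ the 4-neighbour pairs and $\mathcal C$ a set of
higher-order cliques. The clique term is the *robust* form of the
P^n^-Potts potential: within a clique the penalty grows linearly with
the number $m_c$ of minority-label pixels and saturates at $\gamma$
once a fraction $q$ (`truncationQ`, default 0.1) of the clique
dissents. The robust form was chosen over the strict one because the
cliques come from an automatic oversegmentation whose regions
occasionally straddle a true boundary; a strict P^n^-Potts would pay
the full penalty for a single stray pixel and so would effectively
reduce to noise amplification, whereas the truncated penalty tolerates
imperfect cliques.

## The data term

Phase-contrast optics gives no direct intensity-to-foreground mapping,
but it does impose a reliable *three-level* structure: cell bodies lie
below the background grey level, each cell is rimmed by a bright halo,
and the background itself is flat and intermediate. The data term
therefore fits a three-component intensity model to the lightly
(3 x 3) smoothed frame and scores each pixel by how much closer its
intensity is to one of the two foreground levels (body or halo) than
to the background level, in squared standardised units. Two numerical
details matter:

* The three class centres are found by an **exact** one-dimensional
  3-means (a dynamic programme over 256 histogram bins). The halo
  occupies only a few percent of the pixels, and an ordinary
  local-search k-means routinely merges it into the background mode,
  which inverts the classification of the background; the exact
  programme cannot.
* The level model is fitted on a 3 x 3 smoothed frame. Halo rims are
  only ~2 px wide; stronger smoothing (we first used the `radius`/8
  window) visibly washes the halo mode out of the histogram and the
  3-means again returns a wrong background level.

`extractUnaryFeatures(frame, radius)` exposes the score map; `radius`
(default 24 px) should be of the order of the cell radius and bounds
the minimum frame size. The score is invariant under positive
rescaling of all intensities (everything is standardised by the global
s.d.), and a constant frame scores identically zero everywhere.

## Cliques

Cliques are the regions of a seeded oversegmentation
(`buildCliques`): seeds on a regular grid, assignment by a
compactness-weighted distance in (x, y, local mean intensity), three
relocation iterations, then a connectivity pass that keeps each
label's largest 4-connected fragment and merges orphaned fragments
into the neighbouring clique they touch most. The default budget is
`nCliques = 64` regions per frame; at 512 x 512 px this makes cliques
of roughly one cell's area, which is the scale at which "this region
is one kind of material" is a useful prior.

## From energies to probabilities

The tracker wants per-pixel foreground *probabilities* — Gibbs
marginals at temperature $T$ — not a single hard labelling. We
estimate them with a Rao-Blackwellised single-site Gibbs sampler
implemented in C++: sites are scanned in a fixed order, each update
draws from the exact full conditional, and the marginal estimate is
the average of those conditional probabilities (not of the binary
states) over the kept sweeps, which cuts the estimator variance
substantially. The sampler runs on a private xorshift64* RNG stream
seeded by `sweepSeed` (default 0), so for identical inputs the output
is identical bit for bit and R's own RNG state is never touched.

We first implemented two deterministic alternatives — damped mean
field and tree-reweighted belief propagation with exact
count-distribution clique messages. Both are fast, but both polarise
near the Potts critical coupling when the data term is weak (mean
field catastrophically, TRW mildly), and neither could guarantee the
0.05 marginal accuracy we validate against exhaustive enumeration on
small frames. The seeded sampler is asymptotically exact, equally
deterministic in the reproducibility sense that matters for testing,
and its compiled sweep is cheap enough for movie-scale frames
(defaults: 100 sweeps, 30 burn-in; small-frame validation uses 30 000
sweeps, which costs milliseconds). With $\beta = \gamma = 0$ the model
factorises and `segmentFrame` returns the closed-form per-pixel
logistic exactly.

Default weights: `unaryScale` 1, `beta` 0.5, `gammaMax` 0.5,
`temperature` 1, threshold `tau` 0.5 for binary masks,
4-connectivity. These defaults are deliberately mild: the data term
does most of the work on clean renders and the coupling terms serve to
regularise speckle and halo gaps.

# Cell candidates: maximal ellipses

`generateHypotheses` converts a probability map into elliptical blob
candidates. Seeds are local maxima of the smoothed map above the
threshold with a minimum separation of `minAxis` px. Around each seed
the thresholded component is moment-fitted (centre = centroid, axes
and orientation from second central moments, rescaled so ellipse area
equals pixel count), and the fitted shape is then scaled isotropically
about its centre — growth in 5% then 1% steps — to the largest factor
at which the *support*, the mean interior probability, still reaches
`tau`, subject to the semi-major axis staying within `maxAxis`. Every
emitted ellipse therefore fails the 1.05-scaling test by
construction, which is exactly the maximality property the test-suite
re-checks with an independent pixel-counting oracle.

Two conventions deserve comment:

* **Support is a mean, and the default threshold is high
  (`tau = 0.88`).** A mean-interior-support criterion with a
  permissive threshold lets an ellipse absorb low-probability
  surround: for a binary disk of radius $r$ the maximal ellipse has
  radius $r/\sqrt{\tau}$, i.e. 41% too large at $\tau = 0.5$ and 7%
  too large at $\tau = 0.88$. The high default keeps hypotheses
  tightly inside their cells while remaining size-independent.
* **Re-centring.** Scaling is about the ellipse centre, so an
  off-centre initial fit (typical when halo bridges merge two cells
  into one thresholded component) would stay off-centre. The search
  therefore alternates maximal scaling with re-centring at the
  probability-weighted interior centroid (up to three rounds,
  stopping below 0.25 px shift), followed by a final maximal-scaling
  pass so the emitted ellipse is again maximal about its final
  centre.

Near-duplicates are pruned greedily by descending support (ties by
smaller id) at interior IoU > `maxIou` (default 0.6). Overcounting is
otherwise deliberate: hypotheses are a superset of the true cells and
the trajectory model makes the final call.

# The trajectory model

A trajectory is a temporally contiguous sequence of hypotheses, one
per frame. Its log-score is

`logBirth + logDeath + sum(transitions) + sum(log support + logCoverage)`.

A transition scores the next ellipse against a constant-velocity
prediction: isotropic Gaussian on the centre deviation (s.d.
`sigmaPos`, default 2 px/frame), Gaussians on the increments of
$\log a$ and $\log b$ (`sigmaShape`, default 0.05), and a wrapped
Gaussian with period $\pi$ on the orientation change (`sigmaTheta`,
default 0.2 rad). The velocity entering each prediction is the
previously observed displacement; the first transition of a trajectory
has no velocity estimate, so it uses zero velocity with `sigmaPos`
inflated by 2 — a mild, declared convention that keeps track starts
from being punished for unknown motion.

Collections of trajectories interact only through a same-frame
overlap penalty: `kappaOverlap` per px^2 of pairwise interior
overlap, with `Inf` encoding the hard constraint that cells in a
confluent monolayer cannot overlap. Overlap areas are computed by
interior sampling on a 1 px grid; the exact ellipse-intersection area
has no convenient closed form and the sampling error is far below the
penalty scale. The finite default (`kappaOverlap = 0.005` per px^2)
reflects the geometry of the candidates: maximal ellipses
deliberately overshoot their cells by a few percent, so neighbouring
*correct* candidates overlap by up to a few hundred px^2 — which must
stay affordable — while two candidates on the *same* cell overlap by
thousands of px^2 — which must not. At typical cell sizes the default
puts roughly 1-2 log-units on neighbour contact and 15+ log-units on
duplicates. Birth and death penalties (-2 each) and the coverage
reward (+4 per assigned hypothesis) make large consistent collections
win over fragmented ones.

## Sampling and the decision

Collections are explored by Metropolis-Hastings over five structural
moves (birth of a singleton on a free hypothesis, death of a
singleton, extension at either trajectory end, truncation of an end,
and a tail switch between two trajectories alive in consecutive
frames), drawn from a fixed mixture (0.2/0.2/0.25/0.15/0.2). Every
move carries its exact proposal ratio, so the chain is reversible; the
test-suite verifies invariance directly by comparing long-run visit
frequencies with Boltzmann weights on an enumerable instance. Deaths
are restricted to singletons (longer trajectories must be truncated
first) — this keeps every move's reverse within the move set. Scoring
is incremental: a move re-scores only the trajectories it touches and
the overlap terms of the single ellipse it adds or removes; a tail
switch leaves the per-frame ellipse sets, and hence the overlap
penalty, unchanged.

The final tracking minimises the Bayes risk under a symmetric 0-1
loss on every possible link and inclusion, which reduces to keeping
exactly the events whose marginal posterior frequency over the
post-burn-in samples (default burn-in 0.3) exceeds 0.5. Retained
links are assembled greedily by descending frequency under the
one-in/one-out constraint; retained inclusions not covered by a link
become singletons. On movie-scale problems the sampler is warm-started
from a deterministic greedy frame-to-frame linking
(`greedyLinkCollection`); the chain then repairs the greedy mistakes
rather than rediscovering the obvious assignments.

Missed detections terminate a trajectory: trajectories are strictly
contiguous and no gap bridging or interpolation is performed. Cell
division and merging are not modelled.

# Morphometrics

All quantifications take calibrated units (um via `pixelSize`, hours
via `frameIntervalS`). The elongation factor of a polygon outline uses
closed-form polygon second moments (shoelace integrals), so it is
exact for the polygon rather than a rasterisation. Rel-VEcad-C divides
the integrated junction intensity of an ROI by the junction length of
the ROI (a.u./um); when only a polyline is given it is rasterised into
a 3 px ribbon. Background subtraction (median of the 2 px dilation
ring around the ribbon) is on by default — raw integrals are also
obtainable with `backgroundSubtract = FALSE`. Plaque (JAIL) metrics
count 8-connected components above a minimum area and report areas in
um^2; whether plaque "size" means area or length is ambiguous in
common usage, and we report areas. The pole/lateral partition labels
boundary points within `halfAngleDeg` (default 45 degrees) of the
major axis as pole, and is only defined for cells with elongation
factor above 1.5 — for rounder cells the axis itself is unstable.

# The synthetic monolayer

`simulateTracks` generates the study condition used throughout
validation: by default 30 cells on a 512 x 512 px field (0.65 um/px,
300 s/frame) over 60 frames, total cell area 52% of the field, initial
speeds ~0.8 px/frame, acceleration noise 0.3 px/frame^2, log-axis
drift 0.005/frame, 30% of cells elongating at 1% per frame with
$\pi a b$ held constant, reflecting boundaries, and no division. Cell
interiors are kept disjoint by an iterated pairwise spring that
resolves radial overlaps with a 0.5 px clearance; the ground-truth
invariant (no same-frame overlap beyond 2% of the smaller area) is
re-checked by pixel sampling in the tests. The phase-contrast render
is background 100, body 30 below, a 2 px halo band 40 above, additive
Gaussian noise with s.d. 5 (8-bit scale). Junction fluorescence
assigns every pixel to the cell with the smallest normalised
elliptical distance (an influence tessellation), deposits each cell's
fixed budget (5000 a.u.) uniformly over the 1 px ribbon of its own
territory, and returns ribbon masks, boundary polygons (marching
squares on the zero-padded territory mask, so border-touching cells
still close) and junction lengths — the bookkeeping that the
conservation tests integrate against.

What the simulator does *not* emulate: phase-contrast transfer-function
optics (shade-off, non-uniform halos), intracellular texture, cell
division and extrusion, imaging drift, and junctional intensity
heterogeneity along a single border. Passing the recovery tests
therefore demonstrates that the pipeline's inference machinery is
correct under its own model assumptions — calibrated imagery with
halo-rimmed, non-overlapping, smoothly moving elliptical cells — not
that the default parameters transfer to any particular microscope
without adjustment. The parameters most worth revisiting on real data
are `featureRadius` (cell scale), `tau`, the axis bounds, and
`sigmaPos` relative to the true frame interval.

# Validation sizes and numerical conventions

The oracle-equivalence checks compare `segmentFrame` to exhaustive
2^16 enumeration on 4 x 4 frames with two cliques and weights drawn
uniformly from [0, 1]; the tracking checks compare the sampled Bayes
decision at 20 000 iterations with exhaustively enumerated MAP
collections on instances of at most 3 frames x 3 hypotheses whose top
two scores differ by more than 2 log-units; end-to-end recovery runs
the full default monolayer. These sizes were chosen so that the
brute-force oracles are exact and the whole suite remains comfortably
runnable on a laptop.

Conventions used throughout: pixel centres at integer 0-based (x, y)
coordinates; frames 0-based in all CSV interfaces; orientations in
radians wrapped to [0, pi); CSV floats at 6 significant digits;
degenerate inputs (collinear regions, sub-minimum polygons, zero-length
ROIs, inapplicable partitions) raise classed errors rather than
returning sentinel values.
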