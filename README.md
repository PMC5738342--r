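# PhaseTrack

Segmentation, tracking and junction morphometrics for confluent
endothelial monolayers imaged by phase-contrast microscopy.

Endothelial cells in a confluent monolayer tile the substrate without
gaps, migrate, elongate and continuously remodel their VE-cadherin
junctions. Quantifying that behaviour from label-free phase-contrast
movies requires (i) deciding, per pixel, what is cell and what is
background in images where cells appear only as dark bodies rimmed by a
bright optical halo, (ii) following tens of touching, shape-changing
cells through hundreds of frames without identity switches, and (iii)
turning the resulting outlines and tracks into the morphometric
quantities used in junction biology. PhaseTrack implements that pipeline
for R, together with a synthetic monolayer generator that provides
ground truth for every stage.

## The model

**Segmentation.** Each frame is segmented independently with a binary
Markov random field. For a labelling $x \in \{0,1\}^{H\times W}$ the
energy is

$$E(x) = \lambda \sum_p u_{x_p}(p) \;+\; \beta \sum_{(p,q)\in\mathcal N} [x_p \ne x_q] \;+\; \sum_{c\in\mathcal C} \min\!\Big(\gamma,\; \gamma\,\frac{m_c(x)}{q\,|c|}\Big),$$

a data term from a three-level (body / background / halo) intensity
model, a pairwise Potts coupling on the 4-neighbour grid, and robust
higher-order P<sup>n</sup>-Potts potentials over cliques $c$ from a
seeded oversegmentation, where $m_c$ is the clique's minority-label
count: label disagreement inside a clique is penalised linearly and the
penalty saturates once a fraction $q$ of the clique dissents. Per-pixel
foreground probabilities are the Gibbs marginals
$P(x_p = 1) \propto \sum_x [x_p=1]\, e^{-E(x)/T}$, estimated by a
Rao-Blackwellised Gibbs sampler on a fixed private RNG stream (so the
output is reproducible bit for bit).

**Cell candidates.** Elliptical blob hypotheses are grown around local
maxima of the probability map: each moment-fitted ellipse is scaled
isotropically to the largest factor at which its mean interior
probability still reaches the detection threshold. Hypotheses form a
superset of the true cells; the final decision is left to the tracker.

**Tracking.** Collections of interacting trajectories are scored
jointly: each trajectory is a Markov chain over consecutive frames with
a constant-velocity Gaussian motion model, smooth shape change
(Gaussian increments of $\log a$, $\log b$ and wrapped-Gaussian
orientation steps), per-trajectory birth/death penalties, a per-cell
coverage reward, and a same-frame overlap penalty encoding that cells
in a confluent layer do not overlap. Collections are sampled by
Metropolis-Hastings over structural moves (birth, death, extend,
truncate, tail switch) and the final tracking minimises the Bayes risk
under a symmetric per-link 0-1 loss: exactly the links and inclusions
with posterior marginal frequency above 0.5 are kept.

**Morphometrics.** Elongation factor (major over minor axis of the
best-fit ellipse), cell perimeter, accumulated and Euclidean migration
distance, relative VE-cadherin concentration (Rel-VEcad-C: integrated
junction intensity divided by junction length), the total-VE-cadherin
estimate (mean perimeter x mean Rel-VEcad-C), junction-associated
plaque (JAIL) counts and sizes, and a pole/lateral partition of the
boundary of elongated cells.

## Worked example

```r
library(PhaseTrack)

cfg   <- SimConfig(nCells = 8, fieldSize = c(256, 256), nFrames = 6, seed = 3)
gt    <- simulateTracks(cfg)
stack <- renderPhaseContrast(gt, cfg)
stack
#> ImageStack: 6 frame(s) of 256 x 256 px (0.65 um/px, 300 s/frame)

maps <- segmentStack(stack, MrfParams())
hyps <- generateHypothesesStack(maps, tau = 0.88, minAxis = 8, maxAxis = 60)
nrow(hyps)
#> [1] 48

post   <- samplePosterior(hyps, MotionModel(), CollectionPrior(),
                          nIter = 4000, seed = 3,
                          init = greedyLinkCollection(hyps))
tracks <- bayesDecision(post, hyps, MotionModel(), CollectionPrior())
tracks
#> TrackCollection: 9 trajectories (median length 6), logScore 166.826

evaluateTracking(tracks, gt)
#> EvaluationReport: match rate 1.000, 1 id switches, centre RMSE 0.47 px

averageTrackedCells(tracks, 0:5)
#> [1] 8

head(morphometricsTable(tracks, pixelSize = cfg@pixelSizeUm,
                        frameIntervalS = cfg@frameIntervalS), 3)
#>   cell_id n_frames elongation perimeter_um accumulated_um euclidean_um
#> 1       1        6   1.060348     168.9491       1.451826    0.2483091
#> 2       2        6   1.228488     172.5158       1.375686    1.2195647
#> 3       3        6   1.136938     154.7825       3.184422    2.9116066
#>   mean_velocity_um_h directionality
#> 1           3.484383      0.1710322
#> 2           3.301645      0.8865141
#> 3           7.642613      0.9143281
```

All 8 simulated cells are recovered in every frame (`match rate 1.000`,
centre error half a pixel); the morphometric table reports per-cell
shape and motility: `elongation` is the aspect ratio of the mean
best-fit ellipse, `accumulated_um` the total path length of the
centroid, `euclidean_um` the start-to-end displacement, and
`directionality` their ratio.

A command-line front end covering
`simulate / segment / detect / track / morph / evaluate` is installed at
`system.file("scripts", "phasetrack", package = "PhaseTrack")`.

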