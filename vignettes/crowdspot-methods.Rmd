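---
title: "Methods: simulating, merging and tuning crowdsourced spot annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, merging and tuning crowdsourced spot annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdspot)
```

# The problem

Imaging-based transcriptomics (smFISH, in situ sequencing) renders RNA
molecules as bright, diffraction-limited spots. Spot-calling algorithms
need per-dataset parameters — a spot-size band, an intensity cutoff — and
tuning them requires ground truth, which is expensive when it must come
from experts. Redundant point annotations from many non-expert annotators
are a cheap alternative, but raw crowd clicks contain false positives,
are jittered, and lump adjacent spots together. `crowdspot` implements
the full loop: prepare images so annotators can succeed, merge redundant
clicks into consensus spot locations with explicit quality control, and
use the consensus to extract and tune detector parameters — all testable
end to end on synthetic images with simulated annotators, so no
crowdsourcing service is needed to validate the machinery.

# The synthetic image model

`simulate_spot_image()` renders isotropic 2-D Gaussians,

$$I(p) = B(p) + \sum_i A_i \exp\!\left(-\frac{(x-x_i)^2 + (y-y_i)^2}{2\sigma_i^2}\right),$$

on a background $B$ that is either Gaussian noise (optionally low-pass
textured) or any user-supplied image. Spot centers are drawn by rejection
sampling: uniform in the field, at least $3\sigma$ from every border (so
spots are fully rendered and fittable) and at least `min_nnd` pixels from
each other. Sampling aborts with a packing error after $10^4 \cdot
n_{\text{spots}}$ proposals.

**SNR definition.** The literature often quotes a spot's signal-to-noise
ratio without a formula; this package fixes one: the fitted Gaussian
amplitude above the local background offset divided by the robust
standard deviation ($1.4826 \times$ MAD) of an annulus $[4\sigma,
8\sigma]$ around the center (`measure_snr()`). The MAD-based estimate is
insensitive to neighboring spots contaminating the annulus, and the
ratio is invariant under intensity rescaling.

**Amplitude calibration.** To hit a target SNR the renderer sets $A_i =
\mathrm{SNR}_i \times \hat\sigma_{bg,i}$ with $\hat\sigma_{bg,i}$
measured on the background *before any spot is added*, avoiding the
circularity of measuring noise on an image that already contains signal.
Per-spot targets are drawn from $N(\mu_{\mathrm{SNR}},
s_{\mathrm{SNR}})$ truncated at 0.5. On a noiseless background the
amplitude falls back to the SNR value in intensity units. The
simulator's fidelity is itself under test: re-measured SNR agrees with
the target within 10% in the mean, and sigma round-trips through
`fit_gaussian_sigma()` to well under 1% on noiseless renders.

**Defaults as study conditions.** The default configuration — a 300x300
field, 100 spots, $\sigma = 1.5$ px, mean SNR 15, `min_nnd` 10 px —
reproduces a moderately dense, well-resolved field with a mean
nearest-neighbor distance around 15-18 px, the density regime where
consensus QC is most informative: sparse enough for annotators to
resolve most spots, dense enough that adjacent-spot merging actually
occurs. Spot shape is limited to isotropic Gaussians; anisotropic or 3-D
point-spread functions are out of scope.

# The simulated annotator

No generative model of crowd workers exists in the literature; the
`worker_model()` is an invented stand-in whose *behaviors* — not its
numbers — mirror empirical findings about crowd annotators:

- **Detection** is Bernoulli with logistic probability in SNR
  (midpoint 5, slope 1 by default); spots narrower than 1 px have their
  effective SNR halved, reflecting that small spots need to be brighter
  to be seen.
- **Click jitter** is isotropic Gaussian (1 px default).
- **False positives** arrive as Poisson-many uniform clicks (mean 2).
- **Click budget**: at most 120 clicks per worker per image, the
  empirical ceiling of what one annotator will click; when the budget
  binds, detections are kept preferentially over false positives
  (which clicks a real worker drops is unknown; keeping detections is
  the conservative choice for studying QC).
- **Marker occlusion / merging**: the marker an annotation interface
  draws has a finite radius, limiting discernible spot spacing to about
  4% of the displayed width. Detected spot pairs closer than that are,
  with probability 0.6, annotated by a single click near the pair
  midpoint; with probability 0.3 the same worker adds a second click
  inside the pair region (drawn uniformly along the middle half of the
  segment, plus jitter). This is the mechanism that produces *clumpy*
  clusters downstream.

Worker streams are seeded as `seed xor hash(worker_id)`, so enlarging a
crowd never perturbs existing workers — important for reproducible
incremental experiments. All defaults are configurable and none is an
empirical estimate; accordingly, no validation here asserts equality
with any real crowdsourced percentage, only directions and orders of
magnitude.

# Consensus building and quality control

`run_qc()` applies a fixed stage order: cluster, size-threshold, flag
clumps, declump.

**Clustering.** Clicks are clustered by affinity propagation on negative
squared Euclidean distances (no a-priori cluster count), preference set
to the median similarity over all pairs, damping 0.9, at most 300
iterations. Two stabilizing choices were made after observing the
message passing at crowd scale (~2,500 clicks): run it *within spatial
components* (single linkage at 5 px) rather than on the full similarity
matrix, and keep the global-median preference. Full-matrix propagation
at this scale either fails to converge or lets one exemplar serve
several distant click clouds, collapsing well-separated spots into a
handful of clusters; the component partition removes exactly that
degeneracy while leaving the per-component problem unchanged. A
component whose propagation still fails to converge falls back to
single-linkage clustering at a configured radius, with a warning, so
batch runs never abort. The clustering is deterministic: no tie-breaking
noise is added.

**Size thresholding.** Clusters supported by few annotators tend to be
false positives, and support counts are strongly bimodal. A 1-D k-means
with $k = 2$ (deterministically initialized at the observed minimum and
maximum, Lloyd iterations) splits the distribution; the threshold is the
midpoint of the final centers. The statistic is the number of *unique
contributing workers* by default rather than the raw click count:
clumped clusters collect extra clicks from multi-clicking workers, and
on dense fields the inflated counts can drag a click-count threshold
above the true-cluster mode, removing nearly everything. Unique-worker
counts are immune to that inflation (a clump and a clean spot are backed
by the same crowd), while false-positive clusters remain tiny under
either statistic. `stat = "annotations"` restores the raw-count
behavior.

**Clump detection.** When adjacent spots are lumped into one cluster,
some workers still resolve them and click more than once inside the
cluster. The fraction of unique workers contributing multiple clicks
(`multi_frac`) is therefore elevated for clumps. The fractions are
histogrammed (10 bins over [0, 1]); scanning from just past the main
mode toward 1, the threshold is the left edge of the bin with the
largest positive count increase — the point of steepest increase between
mode and tail. Counts, not densities, are scanned. Clusters at or above
the threshold are flagged; with no increase beyond the mode nothing is
flagged.

**Declumping.** Flagged clusters are split by 2-D k-means (default
$k = 2$, the adjacent-pair case; configurable, no automatic selection)
with deterministic farthest-point seeding. Children inherit a
`declumped` origin and together contain exactly the parent's members.
Flagged clusters are *routed to declumping* rather than discarded —
discarding them would throw away two real spots to remove one artifact;
splitting recovers both. Declumping runs after size thresholding so that
noise clusters cannot be "rescued" by splitting.

On the default study conditions (50 seeded crowds), size thresholding
raises precision in essentially every run and full QC reaches mean
precision above 0.95 and mean recall above 0.90 against the simulation
truth; the acceptance script recomputes these numbers.

# Image preparation

`preprocess_stack()` follows the order high-pass (subtract a Gaussian
blur), Laplacian, rectify, then maximum-intensity projection over z.
Filtering precedes projection because projecting first would fold
plane-specific noise into the filtered result. The Laplacian uses the
sign convention that bright blobs respond positively, so rectification
keeps spots. The default high-pass sigma is three times the expected
spot sigma (a rule of thumb, not an estimate).

`log_detect()` is a standard scale-normalized Laplacian-of-Gaussian
detector: responses $\sigma^2 \nabla^2 (G_\sigma * I)$ over a geometric
sigma grid, local maxima in $(x, y, \text{scale})$, overlap pruning
(centers closer than $\sqrt{2}\sigma$ of the larger detection keep only
the stronger). Responses below $10^{-8} \times$ the image scale are
ignored so structureless images yield no detections. The implementation
is checked against an independent dense-scan oracle on small images.

`recursive_subdivide()` splits any region that would be hard to
annotate — more than 100 spots per crop, or a displayed
nearest-neighbor distance under 4% of the displayed width — into the
2x2 quadrants of its crowded bounding box with a 10% overlap margin,
recursively to depth 4. Overlap prevents losing boundary spots; the
deduplication step of `reassemble()` (single-linkage merge at the
dedup radius) removes the resulting duplicates. Quadrant splitting was
chosen over data-driven boxes for predictability; the split geometry is
otherwise unconstrained by any requirement. Regions still violating the
guidelines at maximum depth are flagged `saturated` — some spots are so
close that no amount of zooming separates them — rather than recursing
forever. Coordinates are 0-based with pixel centers at integers,
x = column; crop mapping (`map_to_parent()`) is exact arithmetic, so
the crop/reassemble round trip is lossless, a property verified over
seeded images. Crops are upscaled bilinearly by default (nearest
neighbor available); which interpolation an annotation service applies
is generally unknown, so it is configurable.

# Parameter extraction and tuning

`fit_gaussian_sigma()` least-squares fits $I = \text{offset} + A
e^{-r^2/2\sigma^2}$ in a window around each annotated center (center
refined within 2 px), falling back to a flagged second-moment estimate
on non-convergence. `extract_spot_params()` turns annotated examples
into detector settings:

- sigma band = fitted range with 10% guard margins (floored at 0.5 px):
  annotators mark centers, not extents, and a finite sample
  under-covers the true sigma range;
- intensity threshold = the grid value maximizing precision x recall of
  the detector against the annotations, ties broken toward the *larger*
  threshold — missing a spot is preferred to detecting a false one;
- candidate thresholds are capped 10% below the response of the dimmest
  annotated spot. The threshold is a lower bound on the brightness of a
  detectable spot, so it must admit every annotated spot; the margin,
  mirroring the sigma margins, admits unannotated spots of the same
  brightness class. Without the cap, a sparse annotation sample
  (e.g. 15 of 200 spots) drives the optimizer to a threshold just above
  the sample's dimmest member, silently discarding the dimmest several
  percent of real spots.

The grid is geometric with 50 points over the detector's response range;
its spacing is a numerical choice, not a tuned constant.

`local_max_peakfind()` reconstructs the integer "stringency" knob found
on local-max peak finders: candidate cutoffs span the local-maximum
intensity range (uniform grid of 100), runs of cutoffs yielding the same
detection count form plateaus, the base cutoff is the start of the
longest plateau (the operating point least sensitive to the cutoff), and
stringency $s$ selects the cutoff $s$ plateaus higher. The count is
non-increasing in stringency by construction, and stringencies beyond
the available plateaus clamp with a warning. This plateau mechanism is a
deliberate reconstruction — scale-invariant and implementation-neutral —
not a clone of any particular peak finder; the exact numeric meaning of
stringency in existing tools is undocumented. The peak finder expects a
matched-filtered image (e.g. `gaussian_blur()` at the spot sigma);
applied to a sharpened or raw noisy image, pixel-noise maxima dominate
the count curve and the plateau structure degrades.

`tune_stringency()` sweeps the grid, scores each stringency against any
ground truth (expert, consensus, or simulation truth) and returns the
full curves plus the precision-x-recall argmax, ties toward higher
stringency. `training_curve()` repeats extraction from random
ground-truth subsets to show how many annotations are enough; on
synthetic 200-spot images, 15 annotations reach over 95% of full-truth
performance, consistent with the idea that a handful of examples
suffices to cover the sigma and brightness range.

# Evaluation

`match_points()` builds a one-to-one matching under a correctness
radius (default 4 px — deliberately user-set, since the right radius
depends on magnification): pairs are scanned by ascending distance and
accepted when both endpoints are unclaimed. Greedy matching is
order-stable and fast; an augmenting-path maximum-cardinality matcher is
provided as well (`method = "optimal"`) because which assignment
procedure historical pipelines used is generally unstated. On
spot-matching geometry — separated truth points, jittered predictions —
the two agree exactly; greedy's 1/2-approximation worst case requires
denser threshold graphs than point annotation produces. Conventions for
empty sets are explicit: precision is 1 when nothing was predicted and
nothing missed, 0 when there are predictions but no matches; recall is
1 when there is no truth. Jaccard is $TP/(TP+FP+FN)$.

# Numerical and degenerate-input choices

- All k-means initializations are deterministic (extremes in 1-D,
  farthest-point in 2-D), so QC is bit-reproducible for fixed inputs.
- Every stochastic routine takes a seed and restores the caller's RNG
  state; derived seeds (`seed xor hash(label)`) keep sub-streams
  independent and below $2^{31}$.
- Constant images: preprocessing returns (numerically) zero, detection
  returns nothing, SNR is 0, Gaussian fits are flagged.
- A cluster with fewer members than `k` is returned unsplit with a
  warning; fewer than two clusters (or fewer than two distinct sizes)
  skip size thresholding.
- Tie-breaks consistently favor precision (larger threshold, higher
  stringency) and lowest-index otherwise.

# What the synthetic validation does and does not show

The simulator and worker model exercise every code path the pipeline
has — SNR-dependent misses, false-positive clusters, merged adjacent
spots, budget truncation, crop round trips — so passing tests show the
*machinery* is correct and the QC rules act in the right direction
under controlled conditions. They do not certify performance on real
crowdsourced data: real annotator behavior is not logistic-with-jitter,
real backgrounds have structured debris that attracts systematic false
positives, and real images carry optical aberrations the Gaussian spot
model ignores. Quantities measured on real crowd annotations in the
literature are therefore not reproduced here, by design. Problem sizes
throughout the validation studies (300-420 px fields, 50-20 replicates)
were chosen so the full suite characterizes the pipeline's behavior at
realistic densities.
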