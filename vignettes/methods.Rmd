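---
title: "Methods: the retinopipe detection and grading pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the retinopipe detection and grading pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinopipe)
```

## The problem

Diabetic retinopathy (DR) damages the retinal microvasculature; its lesions
— microaneurysms (small sharp-margined red dots), hemorrhages
(irregular-margined red blobs) and hard exudates (yellowish-white lipid
deposits) — are visible in colour fundus photographs.  When lesions
concentrate in the macula the condition is diabetic macular edema (DME).
`retinopipe` implements a complete detection pipeline: image restoration,
optic-disc removal and vessel segmentation, lesion feature extraction, a
three-class (normal / DR / DME) random-subspace CNN ensemble, and
lesion-count severity grading.  Every stage is exercised end-to-end on a
bundled synthetic fundus generator, so the package is buildable and
testable with no external data.

## The synthetic fundus generator

`generateFundus()` renders, in order: a reddish-orange background with a
mild vignette; a darker macular region whose fovea sits 2.5 disc-diameters
temporal to the optic disc (macular radius = one disc diameter); a seeded
recursive binary vessel tree rooted at the disc centre (child width 0.7 of
the parent, branch-angle jitter uniform within ±25°); the bright optic
disc; and the requested lesions.  Corruption — Gaussian blur, a
multiplicative linear illumination ramp, then salt-and-pepper noise hitting
exactly `round(density·H·W)` pixels — is applied after the ground-truth
masks are recorded, so masks mark true lesion support.

Study conditions fixed once and used throughout the tests: DR images carry
1–10 microaneurysms, 0–4 hemorrhages and 0–2 extramacular exudates; DME
images carry 1–8 exudates (at least one macular) plus 0–4 microaneurysms
and 0–2 hemorrhages; severity follows the total lesion count (mild 1–3,
moderate 4–9, severe ≥ 10).  Lesion centres are kept off the dilated vessel
tree: the lesion-candidate contract requires candidate regions disjoint
from vessels, so overlapping ground truth would be unrecoverable by
construction (and microaneurysms are capillary lesions off the major
arcades anyway).  Default image size is 224×224 (the classifier's native
input); the desk-scale experiments use 64×64.

What the generator does **not** emulate: photographic texture and sensor
noise correlations, anatomical variability of the disc and arcades,
cotton-wool spots, neovascularisation, media opacities, and the smooth
intensity transitions of real lesions.  Passing tests therefore demonstrate
internal correctness and end-to-end plumbing under controlled conditions,
not clinical performance.

## Impulse denoising (iterative EM)

Salt-and-pepper pixels are flagged by a dynamic threshold: a pixel is an
impulse candidate when it deviates from its local window median by more
than `thresholdK` (default 6) times the local MAD, floored at
`madFloor = 0.06` so that genuine thin dark structures (vessels deviate
about 0.3 from the local median in the green channel, while impulses
deviate 0.4–0.9) are not flagged on clean images.  Flagged pixels are
revisited in a zig-zag (boustrophedon) scan — odd rows left-to-right, even
rows right-to-left, each replacement seeing previously cleaned neighbours —
and replaced by the posterior-mean clean estimate of a two-component
mixture (Gaussian clean + uniform impulse) fitted by EM inside the window,
stopping at `maxEmIters` or when the parameter change drops below `tol`.
Unflagged pixels are never altered.

## Artifact removal (anisotropic diffusion)

`diffusionFilter()` runs explicit Perona–Malik diffusion with conductance
`g(|∇I|) = exp(−(|∇I|/κ)²)`, four-neighbour fluxes and Neumann boundaries.
The explicit scheme is stable for `dt ≤ 0.25` (enforced) and conserves the
image mean exactly because opposing fluxes cancel pairwise.  Defaults:
10 iterations, `dt = 0.2`, `κ = 0.1` intensity units — below the
vessel/background contrast, so edges are preserved while background
shading and residual noise diffuse.

## Contrast enhancement as optimization

Contrast is scored by `contrastFitness()`:
`f(I) = H(I) · (E/N) · log(log(S + e))`, with `H` the Shannon entropy
(bits) of the 256-bin histogram, `E` the count of Sobel-magnitude edge
pixels above 0.1, `N` the pixel count and `S` the **per-pixel** edge
strength (the raw sum divided by `N`; an unnormalised sum would grow with
image area and break scale invariance).  Sobel statistics are computed on
the 1-px-cropped interior because replicate-padding makes border gradients
artificial.  A constant image scores exactly 0.

The enhancement mapping is the monotone sigmoid-gamma transform
`T(v) = [1/(1+(m/(v+ε))^α)]^γ`, min-max rescaled to [0, 1], with the three
decision variables searched inside α ∈ [1, 20], m ∈ [0.05, 0.95],
γ ∈ [0.3, 3].  A parametric monotone mapping (rather than a single scalar
threshold) keeps intensity ranks intact, so no lesion/background ordering
can invert.  The search is run by the package's Harris hawks optimizer,
per image (enhancement is posed as a per-image optimization problem; a
per-dataset variant would merely fix one transform).  On RGB input the
mapping acts on the Rec. 601 luminance and the chroma ratios are
preserved.  A guard returns the identity transform whenever the best
sampled transform does not beat the input's fitness, so enhancement never
lowers the score.

## The Harris hawks optimizer

`hhoOptimize()` is a generic box-constrained minimizer.  Each hawk redraws
its initial energy `E0 ~ U(−1, 1)` every iteration; the escaping energy
`Ep = 2·E0·(1 − iter/Tm)` decays linearly.  `|Ep| ≥ 1` selects exploration
(a random-hawk move or a mean-position move, equal probability); otherwise
the escape draw `r` and `|Ep|` select among soft besiege, hard besiege,
and the two progressive-rapid-dive variants.  Dive candidates `Y` (and the
Lévy-perturbed `Z = Y + B∘Lévy`, `B ~ U(0,1)^d`) are accepted only when
fitter than the current hawk; the hard-besiege dive aims relative to the
population mean.  Lévy steps use the Mantegna construction with β = 1.5,
the standard choice for this family of optimizers.  Positions are clipped
to the box; the prey is the best-so-far hawk, so the fitness history is
non-increasing by construction.  Minimization is the single repo-wide
convention; the contrast fitness is negated before search.

## Vessel segmentation (density-based clustering)

The optic disc — the brightest compact region — is found by
luminance-percentile thresholding (top 2%) followed by
largest-circular-component selection (circularity `4πA/P²` ≥ 0.35), then
inpainted with the median background colour.  Pixels are then sampled by a
vesselness response (white top-hat of the inverted green channel with a
disc brush, high for thin dark curvilinear structures), and each sample
carries the 4-vector (row/H, col/W, inverted green, vesselness); spatial
coordinates are normalised to [0, 1] so `eps` is commensurate across image
sizes.

The samples are ordered by OPTICS: the core distance of a point is the
distance to its `MinPts`-th nearest neighbour, defined only when its
ε-neighbourhood holds at least `MinPts` samples; the reachability of `p`
from a core point `o` is `max(core(o), D(p, o))`.  The ordering processes
unvisited points in index order and always expands the pending point with
the smallest tentative reachability, ties broken by lowest index — both
rules fixed for determinism.  Note that a point's reachability bounds the
core distance of its *predecessor*, not its own; profiles therefore only
assert non-negativity.  Clusters are cut at a reachability threshold;
clusters whose dilated pixel footprints lie within Jaccard distance 0.3
are merged (the Jaccard statistic's role in this pipeline is cluster
merging and overlap evaluation); and only clusters whose elongation —
squared spatial diameter over pixel count, large for curvilinear
structures — exceeds 3.5 are rasterised into the vessel mask.  Compact
clumps (lesions) fail the elongation gate and stay out of the mask.

## Lesion candidates and features

Dark lesion candidates are pixels below both the 10th percentile and the
absolute level 0.1 of the green channel; bright candidates are above the
97th luminance percentile and 0.72 with a yellow hue (blue clearly below
the red/green mean).  Vessel and disc pixels, dilated by 1 px, are
excluded; components are labelled with 8-connectivity; dark components of
at most 30 px² are typed MA, larger ones HE, bright ones EX.  All gates
are configuration values; the defaults were fixed once against the
generator and are documented here rather than hidden.

`lesionFeatures()` produces a fixed 40-entry schema: per-type counts,
total lesion area fraction, macular lesion count (ground-truth macula at
train time, a disc-offset estimate — fovea 2.5 disc-diameters temporal —
at inference), mean eccentricity and circularity, an 8-bin histogram of
region major-axis angles (one defensible reading of "orientation
features"), mean/sd of each RGB and HSV channel inside lesions and in the
background, and the vessel density.

## The ensemble classifier

Each member is a VGG-style CNN: five blocks of (2, 2, 4, 4, 4) 3×3
stride-1 pad-1 convolutions with 64/128/256/512/512 filters and ReLU,
each block closed by a 2×2 stride-2 max-pool, then a 4096-unit fully
connected layer, ReLU, and an M-way softmax.  `scale` multiplies all
widths for desk-scale runs.  The engine (im2col + GEMM convolutions,
softmax cross-entropy, Adam at learning rate 1e-3 — the optimizer's
default — and batch size 32) is implemented in C++ with single-precision
arithmetic and an explicit Mersenne-Twister seed; its gradients are
verified against finite differences in the test suite.

The random-subspace construction operates on input *planes*: RGB plus two
derived cue maps (vesselness and a lesion-probability map combining
yellow-deposit and dark-red evidence), R = 5 planes in total.  Each of the
L members receives a uniform random subset of ⌈r·R⌉ planes (default
r = 0.8) and sees zeros elsewhere.  Sampling feature subspaces at a
convolutional input has to happen somewhere concrete; channel subsets are
the natural image-domain realisation.  Fusion is the weighted average
G = Σ wⱼ sⱼ with wⱼ ≥ 0, Σ wⱼ = 1 — uniform 1/L by default, optionally
proportional to held-out validation accuracy; the predicted class is
argmax G with ties to the lowest index.  Ensemble size L = 3 is the desk
default (the member count is a free parameter of the method).  Classifier
diversity is the fraction of test samples two members label differently;
ensemble diversity is its mean over ordered pairs.

Geometric augmentation (rotation, width/height shift, shear, zoom,
horizontal flip) is implemented and seeded, but all ranges default to zero
in the desk profile: the generator supplies arbitrarily many fresh images,
so augmentation adds cost without information there.  Batch normalisation
is available as an off-by-default flag; it is not part of the reference
layer table.

## Severity grading

Severity is graded from the lesion count through two cut points
`t1 < t2`: mild ≤ t1 < moderate ≤ t2 < severe.  The cut points are fitted
by exhaustively minimising the conditional entropy H(label | bin) —
base-2, with 0·log 0 = 0 — over all pairs of observed count values, ties
broken toward the smallest pair.  "Minimum conditional entropy over
two-threshold binnings" is the operational form chosen for a quantity that
is otherwise only named; the exhaustive search is cheap because candidate
cuts are the distinct observed counts.  All lesion types count equally by
default.  The fitted conditional entropy can never exceed the marginal
label entropy, and perfectly separable counts reach exactly zero.

## Evaluation

Metrics follow the standard one-vs-rest confusion counts: accuracy
`(T1+T2)/total`, precision `T1/(T1+F1)`, recall `T1/(T1+F2)`, F-score
`2PR/(P+R)`, error rate = errors/samples (so accuracy + error rate = 1).
Multi-class results are reported per class and macro-averaged over classes
whose metric is defined; undefined cells (empty denominators) are flagged
`NA` and excluded from the macro mean.  Wall-clock timings are logged in
reports but never asserted — they are hardware facts, not method facts.

## Numerical choices and problem sizes

* Desk-scale reference experiment (`runScaledBenchmark()`): 64×64 inputs,
  width scale 0.125, L = 3, 150 training and 50 test images per class,
  15 epochs, batch 32 — sized so the whole experiment runs in minutes on
  one CPU.  The full-width 224×224 / 235-epoch configuration remains
  available through `defaultConfig("full")`.
* OPTICS oracle fixtures use ≤ 200 points so the O(n²) brute-force
  reference is exact and fast; the queue implementation must match it to
  1e-9.
* EM windows floor the Gaussian scale at 5e-3 to avoid degenerate
  zero-variance fits; the mixture weight is clamped to [0.05, 0.999].
* All stochastic stages draw from explicitly seeded generators and
  restore the caller's RNG state; regeneration from a spec is
  byte-identical.

## Known limitations

* The generator's colours are flat and exact, so the frozen candidate
  gates are sharper than anything achievable on photographic data; on real
  images every threshold in `features:` and `segment:` would need
  re-tuning.
* The elongation gate can reject very short vessel stubs and accept long
  thin artefacts; it is a heuristic chosen for the generator's geometry.
* Severity grading consumes the *detected* lesion count, so segmentation
  errors propagate into the grade.
* Training determinism holds for the bundled engine (single-threaded,
  seeded); linking a different BLAS may reorder floating-point reductions
  in GEMM and perturb the last bits of trained weights.
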