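---
title: "Block-based neural-network segmentation with genetic-algorithm initialization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{obstruseg methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(obstruseg)
```

## The problem

On abdominal MRI of mechanical bowel obstruction (ileus), the diagnostic
structures are dilated bowel loops containing an air–fluid level — dark gas
above a horizontal interface, bright fluid below it on T2-weighted images —
and, in the malignant forms, a soft-tissue mass with an irregularly
thickened wall narrowing the lumen.  `obstruseg` segments 2-D grayscale
images of this kind by classifying overlapping image blocks with a small
feedforward neural network whose starting weights are located by a
genetic algorithm, then refining the resulting per-pixel probability map
with exact graph cuts.  Because no public MRI cohort of this kind exists,
the package ships a phantom generator that emulates the morphology above
with pixel-exact ground truth, and every claim the package makes is tested
against that synthetic world.

## The segmentation model

**Blocking.**  An image of height $H$ and width $W$ is cut into square
blocks of side $b$ (default 32 px) at sliding stride $s$ (the *overlap
step*, default 16 px, i.e. 50 % overlap).  Origins enumerate every stride
position plus, when $(L-b)$ is not a multiple of $s$, one final origin
flush with the image edge, so every pixel is covered by at least one
block.  "Overlap step" is read as the stride in pixels — the only reading
under which step 8 or 16 is compatible with 32–48 px blocks.

**Features.**  Each block is summarized by six numbers: mean, variance,
histogram entropy (32 bins over the block's own range, in bits), gradient
energy (mean squared forward difference), and co-occurrence contrast and
homogeneity (8 gray levels, offset (0,1), symmetrized).  Computing
entropy and co-occurrence on the block-relative range makes every feature
except the mean invariant to intensity offsets.  The exact feature family
is a declared choice — a minimal standard first-order + gradient + texture
set — and its bin counts are configuration keys.

**Classifier.**  A three-layer network $y = \sigma(W_2\,\sigma(W_1 x +
b_1) + b_2)$ with logistic $\sigma$ on both layers, trained by online
error back-propagation on squared error with seeded per-epoch shuffling;
training stops at a mean-squared-error goal (default $10^{-3}$) or an
epoch budget (default 200).  Classes are decoded by argmax.  The block
head distinguishes five classes: background, lumen, and one lesion class
per lesion-bearing archetype.  Pooling all lesion appearances into one
output measurably starves the minority class; keeping them separate also
yields the case-level category for free.

**Genetic-algorithm initialization.**  The GA's individuals are flat real
vectors holding all weights and thresholds (column-major $W_1$, $b_1$,
column-major $W_2$, $b_2$); "decoding" is reshaping.  Per generation:
fitness $1/(1+\mathrm{MSE})$ is evaluated; the best individual is carried
over (elitism); parents are drawn by *sorting-based* selection — Baker's
linear ranking, where the individual of rank $r$ (worst $r=1$) is chosen
with probability $(2-sp)/N + 2(r-1)(sp-1)/(N(N-1))$, pressure $sp=1.8$;
a $1-\phi$ share of the offspring comes from uniform crossover (rate 0.8)
plus Gaussian mutation (rate 0.05, sd 0.1), and a $\phi = 0.3$ share is
drawn from an $n$-branch Gaussian mixture fitted by EM to the pooled
fittest half of the fitness-sorted population groups — new individuals
that match the characteristics of the current species.  Evolution stops
when the best fitness has improved by less than $10^{-6}$ over 20
generations, or at the generation cap.  The best chromosome is decoded
and fine-tuned by back-propagation.

The mixture density is the standard one,
$p(a) = \sum_{x=1}^{n} b_x\, \mathcal{N}(a;\mu_x,\Sigma_x)$, with weights
summing to one and a diagonal floor $\varepsilon = 10^{-6}$ added to every
covariance so EM stays well-posed on small, nearly degenerate gene pools.

**Reassembly and graph-cut refinement.**  Per-block class scores are
averaged over all blocks covering each pixel (the fusion rule for
overlapping predictions; majority voting is available behind a flag),
giving a per-pixel probability map that is collapsed to three channels —
background, lumen, lesion.  The map is refined by minimum s–t cuts on the
4-connected pixel lattice: terminal capacities $-\ln(1-p)$ (source) and
$-\ln p$ (sink) with $p$ clamped to $[\delta, 1-\delta]$,
$\delta = 10^{-6}$; neighbor capacities $\lambda \exp(-(I_p-I_q)^2 /
2\sigma^2)$ with $\sigma = 0.1$.  Flows are computed exactly by Dinic's
breadth-first shortest-augmenting-path algorithm (compiled), and the
partition is residual reachability, so flow value equals cut capacity on
every instance — the max-flow/min-cut theorem, asserted directly in the
tests.  Multi-class masks use one-vs-rest cuts in *descending* label
order: the rare structures cut first, because an ascending order lets the
huge background class absorb the boundary bands; pixels no cut claims
fall back to the argmax.

## Tunable parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `blocks$block_size` | 32 | px | reference block size; swept 32/48 |
| `blocks$overlap_step` | 16 | px | 50 % overlap; swept 8/16 |
| `bpnn$n_hidden` | 6 | nodes | see "hidden-layer size" below |
| `bpnn$error_goal` | 1e-3 | MSE | unreported in the source method; config |
| `bpnn$balance_per_class` | 1200 | blocks | background:lesion blocks ≈ 50:1 |
| `ga$population_size` | 40 | — | desk-scale default |
| `ga$gmm_offspring_fraction` | 0.3 | — | mixture channel share |
| `graphcut$lambda_grid` | 1,2,5,10 | — | selected on training Dice |
| `graphcut$sigma` | 0.1 | intensity | edge-stopping scale |
| `phantom$noise_sd` | 0.05 | intensity | stated acquisition-noise level |
| `phantom$size` | 256 | px | structures sized for 32-px blocks |

**Hidden-layer size.**  The package keeps the cross-validation sweep
(`hl_sweep`, 2–8 nodes) as a first-class operation.  On the phantom
world's 5-class block problem two hidden nodes collapse the three lesion
archetypes into one (block accuracy ≈ 0.94, lesion recall ≈ 0.1) while
six nodes separate them (block accuracy ≈ 0.98); the pipeline default is
therefore 6.  Two nodes *do* suffice for the plain 3-class
background/lumen/lesion problem, consistent with the idea that a small
single-hidden-layer network is enough once the classes are compact.

**Smoothness weight.**  Averaging block scores quantizes probability
boundaries to the stride lattice, so the unary term near region borders
is soft over a band of up to $b/2$ pixels; at $\lambda = 1$ the cut
essentially reproduces the argmax.  Rather than pinning a magic value,
`train_segmenter` selects $\lambda$ from a small grid by foreground Dice
on its *training* phantoms (never the evaluation set); on the default
world it selects 10 and the cut then snaps boundaries onto intensity
edges.

## The phantom world — what it does and does not establish

Each phantom is built from parameter templates, one per morphology
archetype: `sist` (one dilated loop, a large round mass with a thin
wall), `colon_cancer` (two loops, an elongated mass with a very thick
irregular wall), `adhesive` (three small loops, no mass), `volvulus`
(two long crossed loops, a small bright mass).  Geometry is jittered per
phantom (centers ±3 % of the image, axes ×0.85–1.15, angles ±0.2 rad)
and intensities are soft tissue 0.40, gas 0.05, fluid 0.85, masses
0.58–0.78 with walls at 0.20–0.25, all in normalized units, with
additive zero-mean Gaussian noise (sd 0.05, clipped to [0,1]; a Rician
magnitude model is available by flag since the true MR noise model is
magnitude-Rician).  The truth mask (0 background, 1 lumen, 2 lesion) is
drawn before noise.

The generator emulates *morphology and contrast*, not MR physics: no
k-space sampling, no bias fields, no partial-volume blur, no 3-D
geometry, and its four "diagnoses" are geometric archetypes, not
pathology.  A green end-to-end test therefore establishes that the
pipeline recovers planted structure at stated noise from features it was
trained on — it says nothing about clinical MRI performance, and the
package deliberately reports no clinical accuracy claims.

## Numerical choices and degenerate inputs

- Constant images min–max normalize to all zeros; Otsu on a constant
  image warns and returns an all-zero mask.
- Probability clamping at $\delta = 10^{-6}$ bounds terminal capacities;
  capacities are compared against a $10^{-12}$ saturation epsilon inside
  the flow solver.
- Argmax ties break toward the lower class index everywhere (blocks,
  masks, labels); fitness ties rank by original index; case-vote ties
  break toward the earlier archetype.
- EM covariance floor $10^{-6}$; empty-component masses floored at
  $10^{-12}$.
- A case is called lesion-free ("adhesive") when the refined lesion
  region is under 0.5 % of the image — about a quarter of the smallest
  archetype's template mass — because a single false-positive block must
  not flip the call; the archetype itself is the majority vote over
  predicted lesion blocks.
- The scaler uses the population standard deviation (two points scale to
  exactly ±1); zero-spread features pass through with scale 1.

## Known limitations

- 2-D only; single-slice NIfTI is accepted but volumes must be sliced.
- PNG export is 8-bit (the available PNG backend writes 8-bit); NIfTI
  float32 is the lossless path.  TIFF is not supported in this build.
- The one-vs-rest multi-class cut is ordered, not a move-making
  multi-label optimizer; with many classes of similar prevalence an
  α-expansion scheme would be preferable.
- Online back-propagation in R is the throughput bottleneck; the
  class-rebalanced sample cap (`balance_per_class`) is what keeps
  training at minutes, and lowering it trades accuracy for speed.
- The GA's mixture offspring fit full covariances over the whole gene
  vector; for networks much larger than the default topology the pool
  would need to grow (or the covariance be restricted to diagonal) to
  keep EM meaningful.

Every number quoted above (block accuracies, Dice, selected λ) is
recomputed by the test suite (`tests/testthat/test-acceptance.R`) or the
acceptance script (`scripts/acceptance.R`); none is asserted from this
text.
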