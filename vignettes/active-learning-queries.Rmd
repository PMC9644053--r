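---
title: "Pool-based active learning for hip-radiograph segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-based active learning for hip-radiograph segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alseg)
```

## The problem

Pixel-wise annotation of joint radiographs is slow and requires anatomical
expertise: around the canine hip the femoral head and the acetabulum
overlap, contrast is low, and the joint gap is narrow. Active learning (AL)
tries to spend that scarce annotation effort where it matters: starting
from a small labeled set $L_0$ and a large unlabeled pool $U_0$, an
*acquisition query* repeatedly picks the next batch of $n$ images for
annotation, the model is retrained from scratch, and the test performance
is tracked as a learning curve over $|L_t|$.

`alseg` implements that experiment end to end: the pool bookkeeping, five
acquisition queries, the dice / dice+focal objectives, a synthetic
"hip phantom" corpus generator, and a small dropout-capable reference
segmenter so the whole study runs in minutes on one CPU.

## The AL cycle

Given disjoint test and validation sets (held fixed throughout) and a pool
split into $L_t$ / $U_t$:

1. the query scores $U_t$ and selects $\min(n, |U_t|)$ ids (timed);
2. the oracle reveals the held ground-truth masks of the selected batch
   (the simulated analogue of expert annotation);
3. $L_{t+1} = L_t \cup B$, $U_{t+1} = U_t \setminus B$;
4. a fresh model is trained on $L_{t+1}$ (never fine-tuned — retraining
   from scratch avoids curriculum artifacts) and evaluated on the test set.

The loop ends when $U = \emptyset$, after exactly $\lceil |U_0|/n \rceil$
acquisitions; with $|U_0| = 131$ and $n = 15$ that is 9 iterations, and the
last batch holds the 11 remaining images. `run_experiment()` repeats the
cycle (default 10 times) with seeds derived from one master seed by a fixed
counter scheme, and averages the per-iteration metrics. The fully
supervised ceiling is available as `run_upper_bound()`.

## The five queries

**Random** — uniform sampling without replacement; the baseline.

**Cluster-based diversity** — images are flattened (optionally thumbnailed;
default 64×64), each feature column is min–max normalized
$x' = (x - \min)/(\max - \min)$, the matrix is reduced by PCA keeping the
minimal number of components reaching 99% explained variance, and
K-Means++ partitions the reduced pool into $n$ clusters. For each centroid
the nearest pool element (Euclidean) is selected. When two centroids share
a nearest element, assignment proceeds greedily by ascending
centroid-to-element distance with each element used once, so the batch
always holds $n$ distinct samples.

**Representative** — labeled and unlabeled images are normalized and
PCA-reduced *jointly* (a shared basis is required for the distances below
to be comparable), and each unlabeled $x$ is scored

$$R(x) = d(x, \mu_{L}) - d(x, \mu_{U}),$$

where $\mu_L, \mu_U$ are the centroids of the labeled and unlabeled
reduced features (a single K-Means cluster converges to the arithmetic
mean, so the means are computed directly). High $R$ marks samples typical
of the pool yet unlike the current training data; the top $n$ are taken,
ties broken by stable id order.

**CWE-MCD (class-wise entropy over Monte Carlo Dropout)** — with dropout
active at inference, $k = 30$ stochastic passes approximate the predictive
distribution; their mean $\bar P$ is scored per sample by

$$\mathcal{E} = \frac{1}{2}\sum_{c=1}^{2}
  \frac{1}{HW}\sum_{h,w} \left(-\bar p_{hwc}\log_2 \bar p_{hwc}\right),$$

i.e. the single-term entropy averaged over pixels, then over the two
sigmoid foreground channels. The top-$n$ most uncertain samples are taken.
The formula is implemented literally; because one may also read it as
shorthand for the full two-outcome Shannon entropy
$-p\log_2 p - (1-p)\log_2(1-p)$, that variant ships as
`entropy = "binary"` (with probabilities clipped to $[10^{-7},
1-10^{-7}]$ before the logs; the literal form is finite on all of
$[0,1]$ with $0\log 0 := 0$). Both variants are zero exactly on certain
predictions; the literal form peaks at $p = 1/e$, the binary form at
$p = 1/2$.

**Representative CWE-MCD** — $R$ and $\mathcal{E}$ are computed separately
over $U$ and fused by Borda count: within each criterion the best of $m$
ids receives $m-1$ points down to 0, tied ids share the mean of their
point block, combined points are summed, and the top $n$ by combined
points are selected. Borda *points maximization* rather than rank-sum
minimization was chosen; the two agree in the absence of ties, and the
points convention extends to ties through fractional ranking. The fusion
is invariant to criterion order and to monotone transformations of either
score.

All queries return ids, never positional indices, so pool mutation cannot
corrupt references, and all return every remaining id when $|U| < n$ (the
final iteration).

## Objectives

Evaluation uses the dice overlap per foreground class,
$\mathrm{Dice}(P,G) = 2|G \cap P| / (|G| + |P|)$, with predictions
binarized at 0.5, a class empty in both prediction and truth scoring 1,
and the macro average over the two classes reported (the stacked-channel
"joint" dice is reported alongside, since either reading of a per-image
dice is defensible).

Training minimizes a soft-dice term $1 - 2\sum PG / (\sum P + \sum G)$
(per channel, averaged) plus a focal term
$\alpha (1-p_t)^\gamma (-\log p_t)$ with $\alpha = 0.25$, $\gamma = 2$,
natural log, averaged over pixels and channels, where $p_t = P$ on
foreground pixels and $1 - P$ on background. The focal term as sometimes
printed omits the ground-truth dependence; the standard $p_t$ convention
is required for a supervised loss and is what is implemented.

## Synthetic phantoms

`generate_phantoms()` emulates the *structure* of a hip radiograph around
one joint, not its appearance: a bright femoral-head ellipse partially
seated in an acetabular annulus sector ("crescent") whose inner radius is
smaller than the head radius, so the two binary mask channels genuinely
overlap and a narrow-gap geometry arises; geometry is jittered per
patient; contrast between bone and background is deliberately low
(default 0.6) with additive Gaussian noise (default $\sigma = 0.08$).
The background mask channel is defined as the complement of the union of
the foreground channels, so a full three-channel mask is generable from
foreground annotations alone. Optional *clone groups* insert exact
duplicate images to make diversity-query behavior assertable.

Defaults mirror the study conditions: 202 patients, split 15% test / 15%
validation / 3% initial labeled (sizes rounded half-up, remainder to the
pool — at $N = 202$ this yields 30/30/6/136), $n = 15$, $k = 30$. Test
images default to 64×64 so a full five-query experiment runs in minutes;
the 544×448 working resolution remains available, with bilinear
resampling for images and nearest-neighbor for masks.

What passing tests on phantoms do **not** show: real radiographs have
texture, exposure variation, anatomy and pathology that the phantoms lack,
so learning-curve *orderings* among queries observed here need not carry
over to clinical data. The phantoms exercise the machinery — bookkeeping,
scoring, ranking, fusion, training dynamics — not the clinical claim.

## The reference segmenter

The experiment needs a trainable, dropout-capable model that is cheap on a
CPU. `reference_segmenter()` is a pixel-wise MLP: each pixel is described
by 9 features (intensity, its square, Gaussian blurs at $\sigma = 1, 2, 4$
with the $\sigma=1$ blur also squared, row, column, and radial position),
passed through one ReLU hidden layer (default 32 units) with channel-wise
dropout (whole hidden feature maps are dropped, as in spatial dropout for
convnets — this is also what makes $k$ Monte Carlo passes cheap: the
hidden activations are computed once and each pass only re-applies its
mask through the output weights), and mapped to two sigmoid outputs.
The squared-intensity features matter: the acetabulum occupies a
mid-intensity band, which no linear threshold on raw intensity can carve.

Training is Adam on the dice+focal objective over class-stratified pixel
subsamples (a quarter of each image's pixel budget goes to each foreground
class when available — the crescent covers only a few percent of the image
and starves under uniform sampling), monitoring validation macro dice with
learning-rate reduction on plateau (factor 0.1, patience 8) and early
stopping (patience 10). `training_config()` defaults follow the full-scale
protocol (learning rate $10^{-2}$, batch 8 images, up to 500 epochs); for
this small model a learning rate of $2\times10^{-2}$ escapes a saddle in
which the acetabulum channel stalls, and the desk-scale runs below use it
together with 512 pixels per image.

Any model honoring the segmenter contract (`seg_train`, `seg_predict`,
`seg_predict_stochastic`, `seg_supports_dropout`) can replace it; a
dropout-free factory is rejected before an MCD experiment starts rather
than mid-loop.

## Numerical and design choices

- Constant feature columns min–max normalize to 0 with a warning rather
  than erroring (degenerate fixtures stay usable).
- PCA retains the *minimal* component count reaching the variance target;
  a zero-variance matrix is rejected as having no informative features.
- All score ties break by stable input (id) order, making every selection
  deterministic and testable.
- Seeded operations restore the caller's RNG state; repeat seeds derive
  from the master seed by a fixed counter scheme, so a whole experiment is
  reproducible from one integer.
- `write_results()` splits deterministic metrics (`results.csv`) from
  measured query wall times (`timings.csv`): under a fixed master seed the
  metrics file is byte-reproducible, which wall time by nature is not.
- Desk-scale problem sizes used by the shipped tests and acceptance
  script: 64×64 phantoms, $N = 202$, three repeats, 15-epoch training for
  the simulation sweep, 40–60 epochs where a single well-trained model is
  needed. These are the package's own choices of scale; the protocol
  constants ($n$, $k$, split fractions, callbacks) are unchanged.

## Known limitations

- The split arithmetic of the emulated study is internally inconsistent
  (202 images at 15/15/3% leaves 136 unlabeled, while the reported pool
  size is 131); split sizes are therefore parameters, and the bookkeeping
  checks use the reported counts directly.
- The representative query's cost is dominated by PCA on the pool; no
  complexity claims are made — wall times are recorded per iteration
  instead.
- The reference segmenter has no shape prior and labels each pixel
  independently; it saturates quickly with training data, so its learning
  curves compress the differences between queries that a full
  encoder-decoder would show.
- DICOM input is not supported; the manifest pathway reads PNG and TIFF.
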