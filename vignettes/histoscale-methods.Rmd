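---
title: "Bi-scale expression prediction from histology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-scale expression prediction from histology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Whole-slide images (WSIs) of stained tumor tissue are routine clinical
artifacts, while transcriptomic profiling — bulk RNA-seq of a whole sample,
or spatial (Visium-style) profiling of ~55 µm spots — is expensive and
sparse. Morphology carries molecular signal, so a model that predicts gene
expression from image patches can act as a cost-effective surrogate at two
resolutions at once: slide-level (bulk) profiles that capture inter-patient
variation, and spot-level profiles that resolve intra-tumoral heterogeneity.
`histoscale` implements such a bi-scale predictor end to end: expression
normalization, slide tiling and patch embedding, a gated causal-recurrence
fusion model with scale-specific output heads, two-stage training, a
multi-scale evaluation suite, and the downstream analyses that consume the
predictions. A synthetic-cohort generator with a known
embedding-to-expression mapping makes the whole pipeline testable without
any external data.

# Expression preprocessing

Bulk counts are converted to TPM (length-corrected rates rescaled to one
million per sample); spot counts to CPM. Each spatial sample additionally
yields a *pseudo-bulk* profile — gene-wise sums of spot counts, CPM
normalized — which serves as the slide-level target for spatial samples.
All normalized values are transformed by $v \mapsto \log_2(v + 1)$ so both
scales share a dynamic range under a single MSE objective. Spots with fewer
than 100 detected genes are dropped (the boundary is inclusive: exactly 100
is kept). All-zero samples stay all-zero under TPM/CPM and are flagged
rather than becoming `NaN`.

Two ordering choices here were genuinely open and are fixed as follows:
pseudo-bulk is computed **after** spot filtering (the filtered spots are the
ones the model trains on, so the slide-level target should aggregate the
same spots), and the gene-panel correlations are computed on
$\log_2(v+1)$ values (consistent with the model's training targets).

## Target-gene selection

Only a subset of genes is predictable from morphology. Per gene and per
scale the package computes an image-association score, ranks genes within
each scale (rank 1 = highest, ties averaged), averages the two ranks, and
keeps the top $K$ (default 1000) genes, breaking residual ties by
lexicographic gene id so the panel is deterministic. The per-gene score
collapses the $d$-dimensional feature block to one number as the **maximum
absolute Pearson correlation** over feature dimensions — the strongest
single linear link; a mean-of-top-$k$ variant is available
(`score_fun = "mean_top_k"`). Bulk-level image features for a sample are
the mean of its slide's patch embeddings, the natural slide summary.

# Slide preprocessing

Slides are tiled into non-overlapping 256 × 256 px patches (partial border
tiles dropped), ordered lexicographically by their $(x, y)$ origin
(x-major by default and configurable — the recurrence is order-sensitive,
so the convention is recorded in every checkpoint and embedding sidecar).
Patches with tissue coverage strictly below 15 % are discarded (exactly
15 % is kept), and a slide passes QC only with strictly more than
`min_tiles` retained tiles (1000 for full-size slides; small values in
tests). Tissue is defined per pixel as $\min(R,G,B) < 220/255$ — a
deterministic stand-in for any segmentation method, with the cutoff
configurable. Spot patches are 256 × 256 px windows centered on the spot's
pixel coordinate; near borders the window is shifted inward so it always
contains real pixels, and the shift is flagged per spot. Inputs are assumed
already resampled to 20× magnification (0.5 µm/px); no pyramidal WSI
decoder is bundled, and precomputed embedding matrices can bypass the image
path entirely.

Patch embedding is a pluggable contract: any deterministic function from an
RGB patch to a fixed-length vector. Pretrained pathology foundation
encoders plug in through `make_encoder(fn = ...)`; the built-in
`"projection"` encoder (seeded random projection of per-quadrant channel
statistics) exists so synthetic pipelines exercise the real code path.

# The fusion model

For one slide, let $x_1, \dots, x_n$ be the ordered patch embeddings
($x_i \in \mathbb{R}^d$). A first-order gated causal recurrence fuses the
sequence:

$$h_i = a_i \odot h_{i-1} + b_i \odot x_i, \qquad
  y_i = g_i \odot (c_i \odot h_i), \qquad h_0 = 0,$$

where the memory-decay $a_i$, input-injection $b_i$, read $c_i$ and gating
$g_i$ coefficients are learned affine maps of $x_i$ — taken literally as
raw affine outputs, with an optional sigmoid on $a_i$ behind a flag
(`sigmoid_a`, default off) for bounded memory decay. A learnable CLS token
is appended **after** the last patch, so its hidden state has integrated
the entire slide; its coefficients come from the same affine maps applied
to the CLS embedding. Two independent MLP heads (one hidden layer of width
$d$, GELU) map each $y_i$ to a local (spot-level) prediction
$\hat z_i \in \mathbb{R}^G$ and $y_{\mathrm{CLS}}$ to the global
(slide-level) prediction $\hat z_{\mathrm{global}}$.

The scan is unidirectional (the equations are first-order causal) and a
single recurrence layer is used; depth is not stacked. $h_0 = 0$ is the
only symmetric choice of initial state.

**Loss conventions.** The local loss is the mean over positions of the
squared error, and squared errors are averaged over genes (so local and
global losses live on the same scale regardless of panel size $G$); a
sum-over-genes variant is available (`loss_reduce = "sum"`). At perfect
prediction both losses are zero; a uniform offset $\delta$ costs exactly
$\delta^2$.

**Initialization.** The paper-style recurrence leaves initialization open,
and it matters: with all-zero coefficient biases, $b_i \odot x_i$ is
quadratic in the embedding and $|a_i| \ll 1$, so the hidden state forgets
all but the last few patches and carries no linear copy of the slide mean —
the quantity the global target depends on. `histoscale` therefore follows
the state-space-model convention of initializing near an exponential moving
average: decay bias 0.9, injection bias 0.1 (their sum ≈ 1 keeps the state
scale independent of sequence length), read/gate biases 1 (gates open), and
small uniform noise ($0.1/\sqrt d$) on the coefficient weights. The model
starts as a near-linear, scale-stable sequence summarizer; training only
has to reshape it. Head weights use the standard
$\mathcal U(-1/\sqrt d, 1/\sqrt d)$ with zero biases.

# Two-stage training

**Stage 1 — scale-specific pretraining.** A bulk-focused model is trained
on bulk (and pseudo-bulk) samples with the global loss only; a separate
spot-focused model is trained on spatial samples with the sum of local and
global losses, the pseudo-bulk profile supplying the global target. Each
optimization step consumes one patient-level sample (batch size 1).

**Stage 2 — joint bi-scale fine-tuning.** Both models continue training on
paired steps: the spatial pool is up-sampled (repeated, truncated to the
bulk sample count, reshuffled per epoch under the seed) so each step pairs
one spatial sample — contributing the local loss and its pseudo-bulk
global term — with one bulk sample contributing a global term; the two
global terms are averaged. The bulk-focused model minimizes
$\lambda \cdot \mathrm{Loss_{local}} + (1-\lambda) \cdot
\mathrm{Loss_{global}}$ and the spot-focused model the mirrored
combination, where $\lambda$ (0.1 breast, 0.05 colon/kidney) is the
reciprocal of the up-sampling factor. The pair of losses always sums to
$\mathrm{Loss_{local}} + \mathrm{Loss_{global}}$, a useful conservation
invariant.

**Optimization.** Rectified Adam with batch size 1, learning rate
$2\times10^{-4}$ for pretraining and $2\times10^{-5}$ for fine-tuning,
decoupled weight decay $5\times10^{-3}$, default betas (0.9, 0.999), no
gradient accumulation. Gradients are clipped to a global norm of 1 before
every step: with batch size 1, RAdam's first few steps are un-rectified
momentum updates, and a single long spot sequence evaluated under the
wrong-scale head can produce gradient norms above $10^6$ — without
clipping, fine-tuning diverges at its first step.

**Validation and early stopping.** 10 % of the training patients form an
internal validation set. The "MSE-based loss" monitored for stopping is the
stage's full objective on that set; the correlation is the mean per-gene
Pearson correlation at the level the model focuses on (global for the bulk
model, local for the spot model). During pretraining a checkpoint is saved
whenever the loss reaches a new minimum; after 20 consecutive epochs
without a loss improvement, training stops unless the correlation exceeded
its best-so-far value inside the window (either kind of improvement resets
the counter). Fine-tuning saves and stops on correlation alone, and the
controller is seeded with the pretrained model's validation correlation, so
the saved fine-tuned checkpoint can never be worse than the pretrained one
under that criterion.

Cross-validation is patient-wise: five folds, each holding ~20 % of
patients out for testing, with the validation split carved from the
remaining 80 %. All slides of one patient stay in one partition.

# Evaluation

Per-gene accuracy is computed over predictions concatenated across all
samples (or spots): Pearson $r$ with a two-sided $p$-value from the
$t$-approximation, plus MSE. A gene is *well-predicted* when $r > 0.4$
(bulk) or $r > 0.2$ (spot) with $p < 0.05$ — all inequalities strict, so a
gene at exactly the threshold is excluded. Genes constant in either vector
get $r = 0$, a degenerate flag, and are excluded from the summary median.
No multiple-testing correction is applied to these per-gene calls. When
metrics aggregate over CV folds they are computed on the concatenation of
all test folds, not averaged per fold.

The bulk–spot similarity AUC asks whether predicted spot profiles rank
spots (by mean correlation to bulk profiles) the way ground truth does:
compute the $n \times m$ spot-by-bulk correlation matrix of predictions,
average per spot, repeat on ground truth, binarize true scores at their
median (strictly above ⇒ 1; ties at the median ⇒ 0), and score the
predicted ranking by the rank-formula AUC with midranks — so
$\mathrm{AUC}(s) + \mathrm{AUC}(-s) = 1$ holds exactly.

# Downstream procedures

* **Risk scores**: $\sum_i C_i \cdot \mathrm{Exp}_i$ with coefficients from
  an externally fitted penalized Cox model (fitting, survival curves, and
  log-rank tests are out of scope; `glmnet`/`survival` cover them).
  Samples strictly above the median score are "high risk"; ties go low.
* **Stage binarization**: stages I–II → low, III–IV → high, after
  normalizing case, `Stage` prefixes, and sub-stage letters (IIA → II).
* **Differential expression**: per gene a Wilcoxon signed-rank (paired) or
  rank-sum (unpaired) test, Benjamini–Hochberg FDR, and fold change as the
  ratio of group means on the linear scale (log2(x+1) input is de-logged
  first; a log-difference variant would change fold-change values but not
  the rank tests). DE calls require FDR < 0.05 and fold change > 1.25, with
  the reciprocal rule (< 1/1.25) for down-regulation. Note the rank tests
  are normalization-insensitive but fold changes depend on the stated
  scale.
* **Meta-program spatial correlation**: per slide, pairwise Pearson
  correlations among program genes over spots, averaged across slides;
  hierarchical clustering with average linkage on the correlation distance
  $1 - r$ (no linkage was prescribed; average linkage is the conventional
  choice for correlation matrices). Genes constant on every slide are
  flagged and their rows zeroed.
* **Phenotype-linked selection fractions** (3 % tumor/normal, 10 %
  recurrence) ship as named constants for external subpopulation-selection
  tools; the selection algorithm itself is not reimplemented.

# The synthetic cohort

`generate_cohort()` emulates paired bulk + spatial data with a known
generative map: per slide, patch latents come from a smooth spatial field
(three low-frequency cosine waves per latent factor plus a slide-level
offset — cheap, seedable, and smooth, in place of Gaussian-process
sampling); embeddings are an affine map of the latents plus optional
Gaussian noise; per-patch mean log-expression is a second, known affine
map. With `count_depth = Inf` the log-scale expression is exact (the
noiseless linear regime used for recovery tests); with finite depth, spot
counts are Poisson(depth × softmax(expression)) — giving realistic
sparsity — bulk counts are sums of patch counts, and log2(CPM+1) values
become the targets. Negative-binomial overdispersion is deliberately not
the default: Poisson keeps the generator dependency-light and fully
deterministic under one seed.

The default configuration **is** the study condition used by the package's
recovery experiments: 40 bulk slides × 30 patches, 10 spatial slides × 50
spots, $d = 16$, 4 latent factors, 20 genes, no noise. At these sizes the
full two-stage experiment runs in about a minute on one CPU. What passing
these tests shows is that the architecture, losses, optimizer, and
controller can extract a signal that is present by construction; it does
not show that real H&E morphology predicts real transcript abundance —
that claim needs real cohorts, pretrained pathology encoders, and
GPU-scale training, all outside this package's scope.

# Numerical choices and degenerate inputs

* TPM/CPM column sums are validated to 1e-3 relative tolerance; all-zero
  columns are preserved and flagged.
* Correlations of constant vectors are defined as 0 (with a warning or
  flag) everywhere one can arise: gene selection, evaluation, similarity
  profiles, meta-program matrices.
* Rank ties: average ranks within a selection level; lexicographic gene-id
  tie-break for the panel; midranks in the AUC.
* Median splits are strict (`> median`); ties go to the low group. With an
  even count and distinct scores this gives an exact half split.
* `upsample_factor = round(1/λ)`; when the bulk count is not a multiple of
  the spatial count the repeated spatial pool is truncated to match.
* All randomness flows from one master seed through named substreams
  (`make_rng(seed, name)`), so a stage's draws never shift another's.
* Checkpoints store every parameter array plus a JSON header (dims, gene
  panel, ordering convention, stage); coordinates everywhere are 0-based
  pixels, x = column, y = row, half-open intervals.

# Known limitations

* No pretrained pathology encoder is bundled; the built-in projection
  encoder is a plumbing stand-in, not a morphology model.
* No pyramidal WSI (SVS) decoding or stain normalization.
* One recurrence layer; no parallel scan, no positional encodings, no
  mixed precision or distributed training.
* Pathway scoring (ssGSEA), enrichment testing, deconvolution, and
  phenotype-linked cell selection are consumers of this package's outputs,
  not components; gene-level tables are exported for them.
* Training at published-cohort scale (thousands of slides, 512-d
  embeddings) is out of reach of the pure-R optimizer here; the package
  targets method correctness and desk-scale experiments.
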