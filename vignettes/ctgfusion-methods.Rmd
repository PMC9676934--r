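---
title: "Multimodal image-text fusion for fetal distress diagnosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal image-text fusion for fetal distress diagnosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ctgfusion)
```

## The problem

Cardiotocography (CTG) records the fetal heart rate (FHR) during late
pregnancy and labour. Obstetricians read these 4 Hz traces for the signs of
compromised fetal oxygenation — baseline shifts, loss of beat-to-beat
variability, deep repetitive decelerations — and the postnatal gold
standards (umbilical-artery pH, Apgar scores) confirm or refute the call.
`ctgfusion` implements an intelligent CTG classifier that treats the
problem as *multimodal learning*: the FHR trace becomes an image modality,
the diagnostic label becomes a tiny text modality, and a transformer
aligns the two so that, at deployment time, images alone suffice.

## From a trace to an image stack

A 30-minute window (7200 samples at 4 Hz) is taken from the end of the
recording, where intrapartum distress is expressed. Records with more than
10% missing samples in that window are excluded; the remainder are
gap-filled by linear interpolation with nearest-value edge padding (a
deterministic, parameter-free substitute for dictionary-learning
reconstruction, which would add unquotable tuning choices; at the
tolerated 10% missingness the difference is confined to short gap
interiors, and the mask is kept for audit so the fill is idempotent).

The trace $X_s$ is min-max scaled to $[-1, 1]$ and mapped to polar angles
$\phi_i = \arccos(\tilde x_i)$. The Gramian angular difference field
(GADF)

$$\mathrm{GADF}[i,j] = \sin(\phi_i - \phi_j)
  = \sqrt{1-\tilde x_i^2}\,\tilde x_j - \tilde x_i\sqrt{1-\tilde x_j^2}$$

is antisymmetric with a zero diagonal and entries in $[-1,1]$; it encodes
every pairwise temporal relation of the trace. Because a $7200^2$ field is
wasteful alone, the trace is first reduced by piecewise aggregate
approximation (PAA) to each dimension of the schedule
$d \in \{7200, 7020, \ldots, 180\}$ (step 180), giving a 40-image
multiscale stack per record. Each field is rendered to a
$224 \times 224$ RGB image by the affine map $(v+1)/2$, bilinear resizing
and channel replication.

Numerical choices worth stating:

* **Fractional-weight PAA.** Most schedule dimensions do not divide 7200,
  so boundary samples contribute fractional weight to adjacent segments;
  every segment covers exactly $L/d$ samples. A brute-force overlap
  integration serves as the test oracle.
* **Constant traces** scale to all zeros ($\arccos 0 = \pi/2$ gives a
  well-defined all-zero field).
* **Clamping** at $\pm 1$ absorbs rounding up to $10^{-9}$ before
  $\arccos$; anything further out is an error.
* **Rendering** uses align-corners bilinear interpolation (an exact
  identity when the field is already $224\times224$) and channel
  replication rather than a colormap — deterministic and invertible.

## The text modality

Labels are verbalised with two fixed templates — "This object is normal" /
"This object is pathological" — tokenized word-level over the closed
five-word vocabulary, embedded via a learnable $5 \times d_t$ table with
additive position embeddings ($d_t = 224$ in the reference configuration).
Four words give the $4 \times d_t$ text matrix; a learnable `[class_text]`
token is prepended inside the decoder rather than counted among the four.

## Architecture

The backbone is a *parallel* pair with no cross-attention between them:

* **Image encoder** — a ViT (default B/16: 16-pixel patches, width 768,
  6 blocks, 16 heads). Patch embeddings plus positions run through
  pre-LayerNorm transformer blocks; a learnable image query token
  $q_{img}$ is appended before the final block and an MLP head closes the
  encoder. The query row is the image's summary token for cross-modal
  work.
* **Unimodal text decoder** — 6 blocks of causal masked self-attention,
  self-attention and a feed-forward network over the 5-token text stream,
  then a linear map. Its class row is the text outcome token $Txt$.

The **multimodal alignment decoder** fuses the two streams in three
stages. Stage 1 refreshes the image side through a cross-attention block
(CAB) and LayerNorm and splits off the image class token $Img$ (the
appended query row). Stage 2 alternates, six times, a decoder block on the
text stream with a CAB whose context is the image features projected to
the text width. Stage 3 normalises and emits the joint sequence $X_m'$
and the multimodal class token $Mul$. A CAB is two windowed *inner-patch
self-attentions* (default window: 7 tokens) around one *cross-patch
attention* onto the context, each sublayer with a residual around a
pre-LayerNorm.

Where the architecture description is genuinely open, this package
decides:

* **Attention scaling** divides logits by $\sqrt{d_{head}}$ (the cited
  standard); a `scale = "linear"` switch reproduces the plain $1/d$
  variant.
* **Width reconciliation**: $d_i \ne d_t$, so image features are linearly
  projected to $d_t$ before stage-2 cross-attention, and $Img$ is
  projected to $d_t$ and L2-normalised (as is $Txt$) before the
  contrastive loss, making logits cosines over temperature.
* **Class-token placement**: prepended on the text side, appended on the
  image side.
* **Stage-2 blocks are untied** across the six repeats.
* **Dropout** 0.1 inside blocks.

## Objectives

Training minimises $L = \alpha L_{con} + \beta L_{cap}$ with
$\alpha = 0.3$, $\beta = 0.7$, $\alpha + \beta = 1$ enforced.

$L_{con}$ is the bidirectional temperature-scaled InfoNCE between $Img$
and $Txt$ batches ($\tau = 0.07$), computed with a stable log-sum-exp.
Closed forms pin the implementation: a batch of one gives 0; identical
rows give $2\ln N$; orthonormal matched rows give 0 as $\tau \to 0$ and
$2\ln N$ as $\tau \to \infty$.

$L_{cap}$ is the softmax cross-entropy between the $Mul$-token classifier
and the text-derived label. The printed binary form of this loss pairs
$\log p$ with the pathological label while defining $p$ as the
probability of *normal*; taken literally that is maximised, not
minimised, by correct predictions, so the package implements standard
binary cross-entropy with $p = P(\text{class } 1)$. Probabilities are
clipped at $10^{-7}$.

## Training protocol

Records are split 1:1 into training and test sets, stratified by label;
the training half is further divided by stratified 5-fold
cross-validation. Splitting is *record-level*: all 40 images of a record
stay on one side of every boundary, because images of one patient are not
independent. Each image is an independent training pair sharing its
record's caption, which with 160 records gives the reference pair counts
of 2560 training and 640 validation pairs per fold.

Optimisation is AdamW — the stated moment constants (0.9, 0.999) and
*decoupled* weight decay ($10^{-4}$) only exist in Adam-family methods,
so the named AdaGrad is offered only as a config switch — with learning
rate $10^{-3}$, batch size 32 and 10 epochs at full scale. Since no
deep-learning framework ships with this R stack, the package carries a
small reverse-mode autodiff engine with fused layers (LayerNorm, scaled
dot-product attention, both losses) whose hand-derived backward passes
are pinned by finite-difference tests.

Three optimisation choices matter at small scale and are deliberate:

* **Initialisation** is Glorot for weight matrices and truncated normal
  (0.02) for token/position/vocabulary embeddings. A blanket 0.02 — the
  large-model ViT convention — starves narrow models of signal.
* **Global gradient-norm clipping at 1.0**, the standard transformer
  stabiliser; without it small-batch contrastive training occasionally
  collapses. (Learning-rate schedules, including warmup, are out of
  scope by design.)
* **Checkpoint selection** is by highest validation record-level
  accuracy with validation loss as tiebreak. Selecting on the loss alone
  proved degenerate: with duplicated captions the pooled contrastive
  term has a composition-dependent floor and can drift upward while the
  classifier still improves, so a loss-only rule repeatedly preferred
  epoch-2 checkpoints that classified at chance.

## Image-only diagnosis

Deployment cannot assume a text input — producing the label *is* the
task. The test model therefore freezes the trained image encoder, adds a
fresh CAB + LayerNorm + linear softmax head over the feature tokens and
the query token, and fits only that head (5 epochs, training split only,
same optimiser). Encoder features are computed outside the gradient tape,
so frozen tensors provably receive zero gradient. A record is diagnosed
by majority vote over its per-image probabilities: pathological when the
votes exceed half; an exact tie also resolves to pathological, a clinical
fail-safe where the cost of a missed distress dwarfs a false alarm.
Metrics are ACC, F1 (pathological class), rank-statistic AUC over the
record score (mean per-image probability), and the coefficient of
determination $R^2$ between outcome labels and text labels as the
cross-modal alignment measure.

The multimodal model itself classifies images zero-shot through the
alignment route: cosine similarity of the image class embedding against
the two caption class embeddings, softmaxed at $\tau$.

## The synthetic generator: what it emulates, what it does not

Real CTG archives cannot be bundled, so all tests run on a synthetic
generator that emulates the statistical structure the pipeline assumes:
30-minute 4 Hz traces with class-dependent baseline (normal preset
140 bpm within the clinical 110–160 band; pathological 135 bpm),
band-limited Gaussian variability (FFT low-pass at 0.5 Hz; peak-to-peak
amplitude 15 bpm normal vs 4 bpm pathological), negative-Gaussian
deceleration bumps (normal: expected 1 shallow 20 bpm/30 s event;
pathological: expected 6 deep 45 bpm/60 s events), Bernoulli missingness
(5%), and class-consistent metadata (pH ~ 7.18–7.38 with Apgar 9–10
versus pH 6.85–7.04). Every record is fully determined by its seed, and
every preset record passes the inclusion rules with its intended label.
A single windowed-SD threshold separates the presets with at least 90%
accuracy, which is what makes the scaled-down end-to-end test winnable
*in principle* — so a green run establishes that the pipeline can learn
and transfer a genuinely separable signal, not that it reaches clinical
performance. The generator does not emulate accelerations, contraction
coupling, sensor artefact bursts, or the hard intermediate cases that
make real cardiotocography difficult; headline clinical accuracies are
out of reach at desk scale by construction.

## Scaled-down experiment

The tested end-to-end configuration shrinks everything that scales:
64-pixel images with 8-pixel patches, widths 64, depth-2 blocks, 4 heads,
5 images per record (schedule 900…180), 40 records per class, one
cross-validation fold per seed, three seeds. Batch size is scaled with
the dataset (8 rather than 32, keeping the number of optimisation steps
per epoch commensurate with the full-scale protocol). Its acceptance
bar — mean held-out record-level accuracy at least 0.90, with the
frozen-encoder test model within 0.1 of the multimodal route — is
computed by `tests/testthat/test-acceptance.R` and re-run by
`scripts/acceptance.R`.

## Known limitations

* The WFDB reader covers the format-16, FHR-first-channel layout of the
  public intrapartum CTG archive, not the full WFDB zoo.
* GADF rendering to a fixed 224-pixel canvas discards sub-pixel detail
  for dimensions above ~224 and interpolates for those below; the
  multiscale schedule is the intended mitigation.
* Inclusion rules implement the published pH/Apgar bands; records in the
  intermediate band [7.05, 7.15) are excluded rather than labelled, so
  cohort sizes depend on that convention.
* The engine is CPU-only, single-threaded R with BLAS matrix products;
  it is sized for the scaled-down regime, not for full ViT-B/16 training.
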