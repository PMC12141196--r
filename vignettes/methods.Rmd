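---
title: "Graph-guided cross-attention integration of multiomics data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-guided cross-attention integration of multiomics data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fuseomics)
```

## The problem

Each omics layer (copy-number variation, transcript abundance, miRNA
expression, DNA methylation, proteomics, ...) is a partial, noisy view of the
same biological state. For phenotype classification — most prominently
cancer-type prediction — integrating layers should exploit both their
redundancy (robustness to noise) and their complementarity (signals visible
only jointly). Early fusion (concatenate everything) is sensitive to the
dimensionality and distributional differences of the layers; late fusion
(combine per-layer predictions) cannot represent interactions at all.
`fuseomics` implements an intermediate-fusion architecture in which
modality-specific encoders first compress each layer, and *cross-attention*
modules then compute directed interactions between encoded layers — but only
along the edges of a user-supplied modality-interaction graph encoding known
regulatory links (e.g. CNV dosage drives mRNA; mRNA abundance drives protein
abundance). Restricting attention to curated edges keeps the number of
interaction modules linear in the number of known links rather than quadratic
in modalities, and makes each module biologically nameable — which is what
later lets layer-wise relevance propagation (LRP) report *interaction*
importance per cancer type.

## Model

### Grouped encoders

A modality with $p_i$ features is far too wide for attention over features.
Each feature vector $X_i \in \mathbb{R}^{p_i}$ is therefore randomly split
into $k_i$ near-equal groups (a fixed, seeded partition stored with the
model). Each group passes through its own fully connected stack
$\mathrm{FCL}(x) = \mathrm{ReLU}(Wx + b)$ (two layers by default,
$p_i/k_i \to 2s_i \to s_i$), and multi-head self-attention over the $k_i$
group embeddings lets every group attend to every other:
$$U_{g_j}^i = A_{g_j}^i \cdot [X'_{g_1} W^V, \ldots, X'_{g_{k_i}} W^V]^{\top},$$
with the usual scaled dot-product attention per head (scale
$\sqrt{s_i/H}$) and heads concatenated back to $s_i$ dimensions. The encoder
output $U^i$ is a $k_i \times s_i$ matrix of group embeddings.

### Cross-attention along the interaction graph

For every directed edge (source $i$ → target $j$) of the modality graph, a
cross-attention module computes a target-shaped embedding enriched by the
source: per head $h$, queries come from the target's groups
($W^{Q_j}_h : s_j \to l_j$), keys and values from the source's groups
($W^{K_i}_h, W^{V_i}_h : s_i \to l_j$), with $l_j = s_j / H$:
$$Z_{g_p}^{i\to j} = A_{g_p}^{i \to j} \cdot
  [U_{g_1}^i W_h^{V_i}, \ldots, U_{g_{k_i}}^i W_h^{V_i}]^{\top}, \qquad
  a_{g_p, g_q} = \frac{(U_{g_p}^j W_h^{Q_j})^{\top} (U_{g_q}^i W_h^{K_i})}{s_j}.$$
Head outputs are concatenated and fused by $W^O$ back to $s_j$ dimensions; a
residual connection adds the (pre-normalization) target embeddings, and both
inputs are layer-normalized. $Z^{i\to j}$ always has the *target's* group
count.

Two printed-form subtleties are worth documenting:

* **Attention scale.** The defining equation divides the logits by $s_j$
  itself, while the surrounding text appeals to the usual dot-product
  attention, which divides by a square root. We implement the literal $s_j$
  as the default and expose `scale = c("sj", "sqrt_sj", "sqrt_lj")`; the
  choice is serialized with the model.
* **Head-fusion dimension.** The head outputs concatenate to
  $H \cdot l_j = s_j$ dimensions, and the residual with $U^j$ forces the
  fused space to be $s_j$-dimensional (a description of it as
  $s_i$-dimensional cannot type-check); $W^O$ is therefore
  $s_j \times s_j$.

### Fusion and prediction

For each distinct edge target $j$, all $Z^{i \to j}$ and $U^j$ form one
ensemble of group vectors; multi-head self-attention over the ensemble (own
parameters per branch) enriches it, and the result is flattened into a branch
vector. Modalities with zero in-degree in the graph contribute their flat
$U^i$ as unimodal branches. One consequence that surprises users: a modality
that only ever acts as an edge *source* (nonzero out-degree, zero in-degree)
gets a unimodal branch, but a source with nonzero in-degree does not — branch
membership is decided by in-degree alone. Branches are concatenated in a
fixed, serialized order (edge targets in config order, then zero-in-degree
nodes in node order) and classified by an FCN with one output neuron per
class and a softmax. Whether $U^j$'s (post-MHSA) slots join the concatenated
branch vector is controlled by `include_target_in_branch` (default `TRUE`;
the ensemble itself always contains them, since the attention is defined over
embeddings *and* $U^j$).

### Two-phase training

Phase 1 trains each encoder individually, end-to-end with a one-layer softmax
head, under the class-weighted cross-entropy
$L(\theta_i) = -\sum_c w_c Y_c \log p_c$ with inverse-frequency weights
$w_c = n/(C n_c)$ (mean one under the class distribution, so the loss scale
is comparable across imbalance levels — the proportionality constant is a
free choice and this one keeps learning rates transferable). Phase 2 freezes
all encoder parameters — asserted by checksum before/after — and trains only
the cross-attention, fusion-branch and predictor weights. Because encoders
are frozen, every sample's encoded representation is computed once and
cached; phase 2 never touches raw features, which is what makes CPU training
fast. End-to-end (unfrozen) fine-tuning is not implemented: it would require
a second, composed backward path used by nothing else in the package, and
two-phase training is the procedure the architecture is designed around.

Optimization is Adam (default learning rate `1e-3`, minibatch 32), early
stopping on validation loss with patience 20, best-validation weights
restored. Phase 2 adds three regularization controls that matter at
desk-scale sample sizes:

* **Decoupled weight decay with a deliberate asymmetry.** `weight_decay`
  shrinks the predictor and fusion-branch parameters, while the
  cross-attention projections and layer norms are governed by a separate
  `attention_decay` (default 0). The reason is mechanistic: the predictor FCN
  holds nearly all of the memorization capacity, whereas shrinking
  $W^Q, W^K$ toward zero pins every attention distribution at uniform and
  disables precisely the bilinear pathway that cross-attention exists to
  learn.
* **Label smoothing** (`label_smoothing`). Without it the validation
  cross-entropy rewards overconfidence and starts rising within a few epochs
  even while the validation accuracy still improves, which defeats both
  early stopping and checkpoint selection; smoothing keeps the loss
  calibrated.
* **Checkpoint selection** (`select`). Early *stopping* always watches the
  validation loss (with its patience), but the restored weights default to
  the epoch with the best validation *accuracy* (ties broken by lower loss),
  which is the quantity the classifier is evaluated on.

### Modality dropout and missingness

With `dropout_p` $= P > 0$, each training iteration independently drops each
modality with probability $P$, re-keeping uniformly chosen dropped modalities
whenever more than `max_dropped` were drawn. Dropped modalities are zeroed at
the *encoded* level ($U^i := 0$), not the input level: phase-2 encoders are
frozen, and a zero input vector would produce an arbitrary (and
training-unseen) embedding, whereas a zeroed representation is exactly what
inference-time masking applies. `evaluate_model(missing = ...)` and
`missingness_grid()` use the same masking, so train- and test-time
missingness are identical by construction.

### LRP interaction importance

`lrp_relevance()` back-propagates the pre-softmax score of a target class
with the $\varepsilon$-rule through every affine layer
($R_i = \sum_j \frac{x_i w_{ij}}{z_j + \varepsilon\,\mathrm{sign}(z_j)} R_j$,
$\varepsilon = 10^{-6}$), treats attention weights as fixed mixing
coefficients (relevance distributed proportionally to the $A \cdot$ value
contributions — the standard treatment for attention), splits residual sums
proportionally to each summand, and passes layer normalization as a fixed
per-coordinate scaling. Relevance absorbed by bias terms is tracked and
reported rather than silently lost. Seeding from the logit rather than the
literal predicted probability avoids softmax cross-talk between classes; the
flag `seed_from_probability` restores the literal reading.

The importance of an interaction edge is the mean relevance *magnitude* over
the output neurons of its cross-modal embedding, measured on the relevance
attributed to the cross-attention path at the residual split. Two aggregation
details matter and both were decided on measurement:

* **Residual split.** A dead edge ($W^O = 0$) contributes nothing to the
  prediction, and under this definition it scores exactly zero instead of
  inheriting whatever relevance the residual merely passes through.
* **Magnitude, not signed mean.** Relevance is a signed decomposition
  (evidence for and against the class score); summed over an edge's hundreds
  of output neurons the signs cancel to numerical noise even for edges that
  knock-out ablation shows to be decisive, whereas the mean magnitude tracks
  the ablation ordering. `signed = TRUE` restores the literal signed mean.

One caveat for interpreting edge importance on real data: a cross-attention
edge transports its *source modality's own signal* through the value path,
so an edge can be genuinely important without any interaction between the
two layers — importance means the edge carries used information, not
necessarily synergy. The bundled planted-edge recovery test therefore gives
its control edge an inert source; with an informative control source the
model may legitimately rely on the control edge, and ablation confirms it.
Class-level scores average per-sample scores within true-label classes by
default (`use_predicted` switches to predicted labels); they are
re-derivable from the per-sample table, which the tests assert.

## The synthetic generator

The generator (`synthetic_spec()`, `generate_multiomics()`) emulates the
structure the architecture targets, with ground truth for every pipeline
stage:

* **Unimodal signal**: per class and modality, a random 10% of features
  (minimum 4) receives a mean shift of $\pm d_i$ (random signs).
* **Planted interaction**: per designated edge, a per-sample latent factor
  $z \sim N(0,1)$ loads with $+\gamma$ on a random subset of source features
  and with $\sigma_c \gamma$ on a subset of target features, where
  $\sigma_c \in \{-1, 0, +1\}$ is a scalar per-class sign. The class is then
  decodable from the *sign of source × target products*
  ($\mathbb{E}[x_s x_t] = \sigma_c \gamma^2$) but not from either modality's
  marginal means, variances, or within-modality covariances. The sign must be
  a scalar per class: a per-feature sign vector would imprint a
  class-specific covariance pattern inside the target modality and leak the
  class unimodally.
* **Noise**: i.i.d. Gaussian, `noise_sd` (default 1).

The default desk-scale spec is $n = 600$, four balanced classes, three
modalities of 200 features ($d = 0.25$, weak), and two planted interactions
($\gamma = 2$) on the chain `cnv -> mrna -> prot` with complementary sign
groupings $(+,+,-,-)$ and $(+,-,+,-)$: jointly the two products identify all
four classes, marginally each modality is only weakly informative. The chain
(rather than two edges converging on one target) is deliberate: if two
class-signed loadings shared a target, the product of their sign vectors
would surface in that modality's covariance and make the class pair-decodable
unimodally, defeating the design. With one class-signed loading per modality,
no single layer betrays the class structure.

What the generator does *not* emulate: realistic omics marginals (counts,
beta-values), feature-feature correlation beyond the planted factors, batch
effects, or missing entries. Passing the capability tests therefore shows the
architecture can learn planted cross-modal structure at realistic sample
sizes — not that it will match any particular cohort's accuracy.

## Numerical choices and degenerate inputs

* Standardization uses the sample standard deviation (denominator $n-1$),
  fitted on the training split only (leakage-safe; whether the original
  experiments fitted on all data is not documented — train-only is the
  defensible default). Zero-variance features map to all-zeros with a
  warning.
* Stratified splitting uses largest-remainder rounding per class; ties in the
  fractional remainders break toward the earlier partition (train before
  validation before test). Classes with fewer than three samples are
  rejected.
* Subsampling keeps $\max(1, \mathrm{round}(n_c f))$ per class, rounding half
  away from zero.
* Layer normalization uses variance denominator $k = s$ (population form)
  with $\epsilon = 10^{-5}$ inside the square root, so zeroed (dropped)
  modality vectors normalize to the bias vector rather than NaN.
* Attention softmax subtracts the row maximum before exponentiation.
* Group partitions chunk a seeded permutation into sizes differing by at most
  one, larger groups first; the partition seed is independent of the training
  seed and serialized in checkpoints.
* Checkpoints are JSON (`jsonlite::serializeJSON`), which round-trips R
  doubles exactly; exported TSV matrices print 17 significant digits so a
  write/read cycle is lossless.

## Problem sizes in the test suite

The bundled tests and the acceptance script train on the default spec
($n = 600$; 420/90/90 after the 70/15/15 split) with $k = 8$, $s = 64$,
2-head encoders and 4-head cross-attention/fusion modules, 30 phase-1 and 60
phase-2 epochs — a couple of minutes per model on one CPU core. The encoder
width matters more than its training length here: measured on the generator's
ground truth, recovering the planted latent factor from the encoded groups
requires the encoding to be wide relative to the modality ($k \cdot s
\gtrsim 2 p$); narrow encoders ($k = 4$, $s = 16$) compress the interaction
away and cap every downstream learner near the unimodal ceiling, trained or
untrained alike. These sizes are the package's chosen desk-scale defaults:
large enough for the planted structure to be learnable, small enough to
iterate on a laptop.

## Known limitations

* No end-to-end fine-tuning (see above); no GPU path; no sparse attention.
* The LRP treatment of attention (weights as constants) is the standard
  pragmatic choice, not an axiomatic decomposition; conservation is exact
  through bias-free affine paths only, and bias-absorbed relevance is
  reported separately.
* Modality dropout applies in phase 2 only; the phase-1 encoders never see
  missingness.
* The shipped interaction graph is a plausible reconstruction of canonical
  regulatory directions, not a curated database export.
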