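---
title: "Interpretable deep learning on regulatory networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable deep learning on regulatory networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpnn)
```

## The model

A knowledge-primed neural network (KPNN) is a feed-forward neural network
whose topology is not a generic layered grid but a directed acyclic graph
distilled from prior biological knowledge. Input nodes are genes whose
expression is measured by single-cell RNA-seq; hidden nodes are
transcription factors and signaling proteins whose activity is not
measured but inferred; output nodes represent the phenotype being
predicted (in the canonical construction, a cell-surface receptor whose
stimulation state is the class label). Every edge is a documented
regulatory relation, so a fitted model can be read as a quantitative
hypothesis about which regulators matter for the phenotype.

Networks are assembled by `build_kpnn()`: shortest paths are traced from
the output node to every reachable transcription factor through the prior
signaling graph (all equal-length paths are retained, matching
all-shortest-paths semantics), TFs are joined to their target genes, and
the whole graph is reversed into data-flow orientation. Genes targeted by
more than 25 TFs are dropped by default (`max_regulators`), because
promiscuously annotated genes mostly add noise edges. `extend_acyclic()`
grows a network with shortest paths from additional receptors under a
depth rule — an edge is admitted only if its parent (output-rooted) is
strictly shallower than its child, or the child is new — with TF and gene
depths forced above all signaling depths, so no feedback cycles can enter.
Depth here is shortest-path distance from the output nodes; the
`node_depths()` accessor also offers the longest-path variant used for
layer layouts.

Each non-input node computes a sigmoid of its weighted parents plus a
bias. Biases are included although the original description leaves them
implicit: without them, a sigmoid chain pins every activation to 0.5 at
zero input and the network cannot represent class-unbalanced baselines.

## Training

`train_kpnn()` minimizes a class-weighted sigmoid cross-entropy with L2
regularization using Adam. The per-class weight is
$(1/N_\mathrm{classes})/(N_x/N)$, so weighted sample counts always sum to
$N$. The cross-entropy is *summed* over samples and outputs rather than
averaged: with a mean reduction, the documented regularization strengths
($\lambda = 0.1$–$0.2$ applied to $\lambda\sum w^2$) provably drive every
weight to zero (the loss converges to $\log 2$ and the AUC to chance),
while the summed form keeps their intended relative strength. Adam is
scale-invariant, so this choice only affects the loss scale, not the
dynamics.

Expression values are scaled per cell to TPM using the per-cell totals
recorded when the dataset was created (so subsetting genes to a network's
inputs does not distort the scaling), transformed as $\log(\mathrm{TPM}+1)$,
and min–max normalized per gene with factors computed on the training
split only; validation and test values may therefore fall outside
$[0,1]$, and genes constant in training are mapped to zero and flagged.
Data are split 60/20/20 into train/validation/test with largest-remainder
rounding.

Early stopping follows the checkpoint/patience scheme: an epoch is
*failed* if the training loss plateaus (relative decrease below
`plateau_tolerance`, default $10^{-3}$; the loss used for this signal is
recomputed without dropout at epoch end, because the dropout-noisy
minimized loss makes "plateau" ill-defined) or the validation error rises
above the checkpointed best (the overfitting signal). A checkpoint is
saved when the validation error improves by at least `save_improvement`
(default 20%) relative to the last checkpoint, which resets the
failed-epoch counter; after `patience` (default 20) failed epochs the
checkpoint is restored for test-set evaluation. A run that never
checkpoints returns the initial model with a failure flag, and replicate
drivers exclude such runs — non-converging replicates are an expected
part of the protocol, which interprets only highly predictive networks.

Dropout is the interpretability mechanism, not merely a regularizer.
Hidden-node dropout (fresh Bernoulli masks per sample and step, inverted
scaling on retained nodes) forces the fit to spread weight across
redundant paths; in sparse biological networks it is capped per node by
parent count (never for one parent, 10% for two, 30% for three,
uncapped above) because sparsely fed nodes otherwise lose their entire
input. Input-node dropout spreads weight across input genes and sharpens
the quantitative meaning of node weights. Output nodes are never dropped.

## Node weights and their statistics

The importance of hidden node $h$ is measured by perturbation:
$w_h = |\overline{p_{+\varepsilon} - p_{-\varepsilon}}| / 2\varepsilon$,
the absolute mean (over cells and outputs) change in predicted class
probability under a $\pm\varepsilon$ shift of the node's activation
($\varepsilon = 10^{-3}$). The absolute value is taken after averaging
because the sign of a hidden node's contribution is arbitrary across
replicates. `node_gradients()` computes the same quantity analytically by
backpropagation and serves as an independent oracle; the two agree to
second order in $\varepsilon$.

Node weights are computed by default from the **final** training state
rather than the restored checkpoint: the checkpoint exists to give an
unbiased test-set estimate, while interpretation benefits from the
additional epochs in which dropout continues to equilibrate weights
across redundant nodes; checkpoint-based test metrics are unaffected by
the choice. `node_weights(state = "checkpoint")` restores the
alternative.

Replicate analysis follows the protocol used for differential expression:
`run_replicates()` retrains with derived seeds; `aggregate_replicates()`
drops replicates above a test-error ceiling (0.1 for simulated data, 0.2
is the documented real-data default), downsamples groups to the smallest
group, and quantile-normalizes weights across replicates (via limma);
`differential_node_weights()` applies per-node two-sided Welch t-tests
(or a linear model with covariate coefficients) with Benjamini–Hochberg
correction at $p_\mathrm{adj} < 0.05$. Zero-variance nodes receive
$p = 1$ and a `degenerate` flag. Nodes adjacent to the output saturate
under both actual and control inputs and should be read with care; the
differential contrast, not the raw weight, carries the interpretation.

Control inputs (`make_control_inputs()`) normalize for uneven
connectivity: counts of one class are summed into an average profile, a
two-fold change with random sign is applied to *every* gene, and cells
are redrawn binomially at the original per-cell depths. Weights learned
from control inputs reflect network structure alone, so the differential
contrast actual-vs-control isolates the data-driven part of a node's
importance.

## The simulator and what it does (not) emulate

`simulate_cells()` draws per-gene counts as independent binomials with
the cell's read target as size and the profile fraction as probability —
the expectation matches a multinomial read-sampling model, and per-gene
binomial draws are the documented procedure. The default baseline
(`default_baseline_profile()`) is a seeded heavy-tailed profile (gamma
magnitudes with power-law rank decay over 1000 genes) standing in for an
average transcriptome, since deriving the baseline from a real dataset
must not be a build dependency. Predictive genes carry a two-fold change
with a fair-coin sign per gene; class sizes follow the balance exactly
(2000 cells, 50/50 by default; 10,000 reads per cell, a typical droplet
depth).

The simulator does not model experimental dropout noise, doublets, batch
effects, or library-size heterogeneity beyond the specified read targets.
Passing tests on these data show that the learning and interpretation
machinery behaves as designed under a known ground truth; they do not
show robustness to the full noise structure of real single-cell data.

`toy_scenario()` packages the validation networks: `single_node` (one
predictive hidden node among non-predictive siblings), `redundant_pair`
(two hidden nodes sharing all inputs), `weak_strong` (three hidden nodes
with five predictive inputs each vs three with one, filler inputs topping
all six up to equal fan-in), and `uneven_connectivity` (top nodes A and B
parenting 2 and 8 bottom nodes; predictive genes under both of A's
children but only one of B's) with its `_control` twin trained on control
inputs. Scenario input genes are drawn from the upper expression half of
the baseline so that counts carry signal; the number of filler genes per
hidden node (default 10) is exposed because the original description does
not fix it. Training presets (`scenario_train_config()`) use learning
rate 0.05 with $\lambda = 0.1$ for the redundant pair and $\lambda = 0.2$
elsewhere, 30% dropout where enabled, patience 20, and 20% checkpoint
improvement.

## Design choices where the method was open

* **Weight initialization** is Glorot-uniform per edge
  ($\pm\sqrt{6/(f_\mathrm{in}+f_\mathrm{out})}$), seeded; the original
  states only random initialization.
* **Plateau tolerance** defaults to $10^{-3}$ relative; the source leaves
  "training loss plateaued" numeric. Smaller values lengthen training
  toward full convergence, which blurs the redundancy bifurcation that
  generic (dropout-free) learning is supposed to exhibit.
* **Minibatching** is off by default; `minibatch_size = 1000` mirrors the
  configuration documented for atlas-scale data.
* **Shortest-path ties** through complexes or families are all retained;
  no prioritization is attempted.
* **Shuffling** visits edges in stored order, swaps each at most once,
  and skips edges without an admissible partner.
* **Multi-output networks** average probability differences over outputs
  before the absolute value; validation error averages over outputs.
* **Two-sided tests** are used for differential node weights; the source
  does not state sidedness.
* **Degenerate inputs**: genes constant in the training split map to
  zero with a warning; cells with zero totals are scaled as depth-1
  cells; empty classes, cyclic graphs, and out-of-range MTX entries are
  rejected with informative errors.

## Problem sizes used in the validation suite

The bundled experiments are deliberately desk-scale: 1000-gene
transcriptomes, 2000 cells, networks of 2–20 hidden nodes, and 20–50
replicates per condition (the redundancy benchmark trains 50 replicates
per arm and filters to test error < 0.1 before correlating, mirroring the
documented interpretation filter). These sizes reproduce the qualitative
and quantitative behavior of the published simulations while keeping a
full run in minutes on one CPU core.

## Known limitations

One design goal of the optimized learning method is not met by this
implementation: in the weak/strong scenario, training
with input-node dropout does not yield a strict all-strong-above-all-weak
ordering of median node weights (the corresponding check in the
validation suite documents the failure rather than hiding it). The
mechanism appears to be the loss scale: with the summed cross-entropy
that the documented regularization strengths require, the L2 penalty
exerts essentially no pruning pressure, so single-gene backup channels
retain large output weights under input dropout instead of being demoted.
The no-dropout half of that experiment (node weights failing to reflect
the designed strong/weak structure) and all redundancy, connectivity, and
structural findings reproduce.

* Cycles in the prior must be broken at construction time; feedback is
  not modeled.
* The training engine is plain R (vectorized over cells); it is sized
  for desk-scale networks, not for atlas-scale data or GPU execution.
* Hyperparameters are not auto-tuned; the documented presets are starting
  points, and the original work tuned stopping parameters per dataset.
* Node weights of output-adjacent nodes saturate and are reported but
  annotated as such; interpretation should rely on the differential
  contrast against control inputs.
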