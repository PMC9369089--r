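---
title: "Predicting 6mA sites from 41-bp windows: methods and design"
author: "sixmApred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 6mA sites from 41-bp windows: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixmApred)
```

# The problem

DNA N6-methyladenine (6mA) is an epigenetic mark on the adenine base,
widespread in plant genomes and linked to gene regulation. Experimental
mapping of 6mA sites is expensive, so sequence-based classifiers are
used to call candidate sites in silico. The standard benchmark framing
is a binary classification of fixed 41-bp windows centred on a
candidate adenine: label 1 if the central adenine is methylated, 0
otherwise, with balanced benchmark sets per species and deliberately
imbalanced (1:5, 1:10) variants to probe realistic prevalence.

`sixmApred` implements this pipeline end to end: triple per-nucleotide
encoding, elastic-net feature reduction, a small one-dimensional
convolutional network, and an evaluation harness built for imbalanced,
cross-species testing.

# Encoding

Each residue of a window contributes an 8-dimensional feature block,
the column-wise concatenation of three encodings in a fixed order:

* **one-hot** (4 values): A = (1,0,0,0), T = (0,1,0,0), C = (0,0,1,0),
  G = (0,0,0,1);
* **NCP**, nucleotide chemical properties (3 values): ring structure,
  hydrogen-bond strength, amino/keto group — A = (1,1,1), T = (0,1,0),
  C = (0,0,1), G = (1,0,0);
* **EIIP**, the electron–ion interaction potential scalar:
  A = 0.1260, T = 0.1335, C = 0.1340, G = 0.0806.

A 41-bp window therefore encodes to a 41 × 8 matrix, flattened
position-major (each residue's 8 features stay contiguous) into a
length-328 vector. The within-block order (one-hot, NCP, EIIP) and the
position-major flattening are frozen conventions: any fixed order is
equivalent for the model, but the choice must be stable for saved
models and selector index sets to be transferable. The EIIP scalars
are used exactly as printed, with no rescaling.

# Elastic-net feature selection

The 328 features are redundant by construction (the one-hot block
alone determines the residue), so the pipeline fits a linear
elastic-net regression of the 0/1 labels on the flattened features —
penalized least squares with an L1 weight $\lambda_1$ and an L2 weight
$\lambda_2$:

$$\hat\beta = \Big(1 + \tfrac{\lambda_2}{n}\Big)\,
\arg\min_\beta \;\|y - X\beta\|^2
+ \lambda_1 \|\beta\|_1 + \lambda_2 \|\beta\|_2^2$$

solved by cyclic coordinate descent (tolerance $10^{-6}$ on the
largest per-sweep coefficient change, at most 10,000 sweeps). The
leading factor is the classical naive-elastic-net rescaling; it never
changes which coefficients are zero. The retained feature set is
exactly the solver's nonzero set — no magnitude threshold, no fixed
top-k — and that index set, not the coefficients, is what transfers to
held-out data: `applySelector()` is a pure column gather, so test
features are never refit. `topKSelector()` exists only as a
compatibility switch for users who want a fixed published
dimensionality such as 173.

Design choices worth stating explicitly:

* **Least-squares, not logistic.** The labels enter as 0/1 numeric
  responses; the objective is the penalized least-squares form above.
  A logistic elastic net would also be defensible, but the
  least-squares form is the one this pipeline is defined around, and
  for screening purposes the two select very similar supports.
* **Standardization.** Features are standardized to zero mean and
  unit variance using *training* statistics before the fit (binary
  one-hot columns and 0.08–0.13 EIIP values live on very different
  scales, and both L1 and L2 penalties are scale-sensitive). The
  statistics are stored on the fitted object; reduction of held-out
  data remains a raw column gather.
* **Default penalties.** With no penalties supplied, the package uses
  $\lambda_1 = 0.01\,\lambda_1^{max}$, where
  $\lambda_1^{max} = 2\max_j |X_s^\top y_c|$ is the smallest L1 weight
  that zeroes every coefficient, and $\lambda_2 = \lambda_1$ (an equal
  mix of the two penalties). One percent of the path maximum is a
  conventional pathwise endpoint that keeps clearly informative
  columns while discarding most noise; the retained count is a
  data-dependent *outcome* reported by `selectorReport()`, not a
  target the fit aims at.
* **Closed forms at the boundary.** $\lambda_1 = 0$ (ridge, or OLS
  when $\lambda_2 = 0$ too) is solved directly rather than iterated,
  so the penalty-free limit is exact.

# The convolutional classifier

The reduced feature vector of length $d$ is treated as a 1-D signal
with one channel:

```
conv(64 filters, kernel 7, stride 1, valid padding)
 -> batch normalization (momentum 0.8, epsilon 1e-5)
 -> ELU (alpha = 1)
 -> flatten ((d - 6) x 64)
 -> dense(16, ELU) -> dense(8, ELU) -> dense(1, sigmoid)
```

with $f(x) = x$ for $x > 0$ and $\alpha(e^x - 1)$ otherwise for the
ELU, and $\sigma(x) = 1/(1+e^{-x})$ at the output, read as the 6mA
probability. A score $\ge 0.5$ is called 6mA; the behaviour at exact
equality is a documented tie-break (positive), since only the strict
inequalities are conventionally specified.

The implementation is authored in vectorized base R — an im2col
convolution, explicit batch-norm forward/backward, and dense layers as
matrix products — with gradients verified against central finite
differences in the test suite. Training is stochastic gradient descent
(learning rate 0.001, momentum 0.9) on mean binary cross-entropy, the
only standard pairing with a single sigmoid output. Batch-norm
momentum follows the moving-average convention
`new = 0.8 * old + 0.2 * batch`, pinned by a unit test because
frameworks disagree on which side the momentum weighs; inference uses
the running statistics.

Unstated-by-convention choices, all exposed as configuration:

* **Valid padding** (no zero padding): the common default in this
  family of sequence CNNs, keeping the receptive field inside the
  window; the convolved length is $d - 6$.
* **Dense-layer activations**: ELU, matching the network's stated
  activation; the dense widths 16 and 8 are fixed topology.
* **Early stopping** monitors accuracy on a stratified 10% validation
  split of the training partition (seeded), stops after 10 epochs
  without improvement, and restores the best epoch's weights.
* **Batch size 256, at most 100 epochs** by default — safe CPU
  settings for a model of this size.
* All randomness (initialization, shuffling, the validation split)
  derives from one integer seed through named substreams, so training
  is reproducible run to run.

# Evaluation

`classificationMetrics()` computes accuracy, sensitivity, specificity
and the Matthews correlation coefficient from the confusion counts;
an MCC whose denominator vanishes is defined as 0, the conventional
completion. `rocAUC()` is the trapezoidal ROC area with tied scores
grouped, which makes it exactly the Mann–Whitney probability that a
random positive outscores a random negative (ties counting one half) —
the suite asserts this equality against an all-pairs oracle.
`prCurve()` uses step interpolation (the average-precision
convention), because linear interpolation in PR space is known to be
optimistic; a trapezoidal mode exists behind a switch. The no-skill
AUPRC baseline is the positive fraction, so on a 15%-positive set an
uninformative scorer sits at 0.15 — the package's acceptance script
recomputes exactly this quantity.

`kFoldCV()` runs stratified, seeded five-fold cross-validation of the
*whole* pipeline: the selector is refit per fold on the training
partition only and its index set transferred to the test fold, so no
test-fold row can reach selector fitting or network training. An
`instrument` hook exposes the row indices each stage receives, and the
suite audits them. Stratification is not stated in the benchmark
protocol but is standard for balanced sets and keeps per-fold metrics
stable; it is a documented choice here. Per-fold refitting (rather
than one selector on all training data) is the leakage-safe reading of
"training data only"; the per-fold retained counts are reported.

`subsampleRatio()` builds the 1:5 / 1:10 imbalanced variants by
keeping **all** negatives and drawing $\lfloor N/r \rfloor$ positives
uniformly without replacement under a seed. This is the only rule
consistent with all the printed benchmark split counts (e.g. 1966
negatives give 393 positives at 1:5 and 196 at 1:10; 813 give 162 and
81; 31,873 give 6374 and 3187), all of which the suite reproduces.

# The synthetic generator

Real 6mA benchmark sets are large external downloads, so the package
ships a generator whose datasets exercise every stage:
`simulateDataset()` draws 41-bp windows from a background composition
(uniform by default), forces the central adenine (as candidate-site
windows do), and plants a short motif by substitution at a fixed
offset — "GAGG" at offset 4 by default, a motif family enriched around
rice 6mA sites (a naming motivation only, not a modelled claim). A
positive carries the motif with probability `signalStrength`, a
negative with the complementary probability; unplanted windows are
scrubbed of incidental matches at that offset so strength 1 is exactly
separable. Strength 0.5 makes the classes exchangeable by construction
and serves as the chance-level null.

A second negative control used in the suite is label shuffling: keep
the reduced features of an informative fit, permute the labels in
*both* the training and evaluation partitions, and retrain. The
permuted labels carry no sequence signal, so any predictor's expected
held-out accuracy on a balanced set is exactly one half. Evaluating a
noise-trained model against the *true* labels would not be a valid
null here: the retained features encode motif carriage, so even an
arbitrary function of them deviates systematically from 0.5 against
labels that do track the motif.

What passing tests on this fixture do and do not show: they verify
that the pipeline's machinery — encoding, selection, training,
transfer, evaluation — recovers a localized, deterministic sequence
signal and collapses to chance when the signal is destroyed. They do
not show that real 6mA context statistics (degenerate motifs,
position-dependent composition, species shift) are captured; claims
about real data require the external benchmark sets, for which the
package provides the I/O and protocol but not the download.

# Problem sizes and numerical notes

The shipped tests run the end-to-end recovery at 800+800 training and
200+200 held-out windows with at most 40 epochs, cross-validation
checks at 250+250, and the uninformative-scorer AUPRC at n = 10,000
over 100 seeds; these sizes give stable statistics for the properties
asserted while keeping the suite quick on one CPU. Degenerate inputs
are rejected loudly rather than silently repaired: single-class
labels, non-finite designs, empty selections (a hard error before
network training, since a 7-wide kernel needs at least 7 features),
and sub-kernel input dimensions are all errors; empty FASTA classes
and missing central adenines are warnings, since neither breaks the
arithmetic. Sequence length is a constant defaulting to 41 from which
every downstream shape derives; other window sizes work, but the
defaults reproduce the benchmark geometry.

# Known limitations

* The network trains on one CPU in pure R; it is sized for desk-scale
  experiments (thousands of windows), not for the 308,000-window rice
  benchmark, which is hours of compute regardless of implementation.
* The elastic net is linear least-squares screening; features whose
  effect is purely interactive could in principle be screened out
  before the network sees them.
* No genome scanning: inputs are pre-windowed sequences, as in the
  benchmark packaging.
* Ambiguity codes (N, IUPAC) are rejected rather than imputed; the
  encodings define only the four bases.
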