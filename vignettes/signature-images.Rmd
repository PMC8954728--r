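---
title: "Signature-image encoding and affinity regression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-image encoding and affinity regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigdta)
```

## The problem

Predicting the binding affinity of a small molecule (drug) to a protein
(target) from their sequences alone is a standard regression task in
computational drug discovery: affinities are expensive to assay, and a
model that ranks candidate pairs well can focus experimental effort.
`sigdta` implements an alignment-free, embedding-free approach: both the
molecule's SMILES string and the protein's amino-acid sequence are mapped
to fixed-size grayscale "signature images" built from k-mer frequencies,
and a dual-branch convolutional network regresses the affinity from the
image pair.

## The encoder

A sequence $s = [s_1, \dots, s_c]$ over an ordered alphabet $\Sigma$ of
size $n$ is scanned with a sliding window of length $k$, giving
$l = c - k + 1$ overlapping k-mers.  Each of the $n^k$ possible k-mers has
a fixed rank: its row-major lexicographic position with respect to the
printed alphabet order (the first symbol repeated $k$ times has rank 0).
The counting vector $c \in \mathbb{N}^{n^k}$ tallies window occurrences,
so $\sum_i c_i = l$.  It is normalized by its maximum,
$f = c / \max(c)$, giving values in $[0, 1]$ with maximum exactly 1, and
reshaped row-major into an $m \times m$ matrix with
$m = \lceil \sqrt{n^k} \rceil$; when $n^k < m^2$, the missing
$e = m^2 - n^k$ cells are filled with zeros appended at the end of the
flat vector.

Two alphabets are fixed.  The molecule alphabet has 36 symbols (element
letters, aromatic lowercase letters, digits, brackets and bond
punctuation); with the conventional $k = 2$ this gives $36^2 = 1296$
2-mers and a $36 \times 36$ image with no padding.  The protein alphabet
has the 20 amino-acid letters plus the ambiguity code X; with $k = 3$
there are $21^3 = 9261$ 3-mers and a $97 \times 97$ image with 148
padding cells.  Both $k$ values are overridable.

Decisions the encoder takes where the construction is underdetermined:

* **Character-level tokenization.**  Two-letter element symbols are read
  as two characters (`"Cl"` is `'C','l'`): the alphabet contains
  lowercase `l` and `r` as symbols in their own right and no two-character
  tokens.
* **Out-of-alphabet characters.**  Real SMILES contain characters the
  36-symbol alphabet cannot represent (`@`, `/`, `%` ...), and protein
  sequences occasionally contain `U`, `B`, `Z`.  The default policy drops
  them and reports the count (`dropped_count`) for audit; a strict policy
  aborts naming the character and position.  Windows are taken over the
  *cleaned* sequence, keeping $l = c - k + 1$ exact.
* **k-mer order.**  Any fixed bijection from k-mers to pixels yields an
  equivalent model; the row-major lexicographic order by printed alphabet
  position is the only canonical choice available, and is what
  `kmer_index()` implements.
* **Short sequences.**  A sequence shorter than $k$ is rejected rather
  than zero-padded: its count vector would be all zero and the
  max-normalization undefined.
* **Precision.**  Pixels are stored as doubles; the optional PNG export
  quantizes to 8-bit grayscale and is documented as lossy.

## The network

Each branch applies three blocks of 3x3 valid convolution (ReLU) followed
by 2x2 max-pooling, then flattens:

* molecule branch: 36 > 34 > 17 > 15 > 7 > 5 > 2, flatten $2^2 \cdot 32 = 128$;
* protein branch: 97 > 95 > 47 > 45 > 22 > 20 > 10, flatten $10^2 \cdot 32 = 3200$.

The two flatten vectors are concatenated (width 3328 under the default
filter counts), passed through dropout (rate 0.4), a 512-unit ReLU dense
layer, dropout again, and a single linear output unit.  Kernel sizes,
strides, padding and filter counts are not uniquely determined by the
reference description, which fixes only the layer sequence and the
concatenation width; the defaults here (3x3 kernels, stride 1, valid
padding, 2x2 pools, 32 filters per block) are the minimal conventional
setting whose flatten widths reproduce 3328 exactly.  All are
configurable, and `architecture_spec(strict = TRUE)` enforces the 3328
constraint, rejecting any spec with the width it computes instead.

Training minimizes the mean squared error with Adam (learning rate 0.001,
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-7}$), batch size
256, and a reference schedule of 1000 epochs.  Weight initialization
(He-normal for ReLU layers, scaled-normal for the linear output, zero
biases), minibatch shuffling and dropout masks are all driven by a single
seed, so a fit is exactly reproducible.  `training_config(patience = p)`
enables early stopping on the validation loss and returns the
best-validation weights; the CLI uses it by default, with
`--paper-protocol` restoring the fixed 1000-epoch schedule.

The engine itself is written in RcppArmadillo: convolutions run as
im2col + BLAS GEMM in single precision, gradients are analytic (verified
against finite differences in the test suite), and minibatches are
processed in small chunks so memory stays bounded at any batch size.
Since the MSE loss is sample-separable, chunked forward/backward passes
accumulate exact whole-batch gradients.

## Experiment plan

The interaction set (non-missing cells of the drugs x targets affinity
matrix, enumerated drug-major) is split into six disjoint, exhaustive,
near-equal parts: five cross-validation folds and one held-out test part.
For fold $k$, the other four folds train and fold $k$ validates; the
fitted model is persisted, then evaluated once on the test part
(`train_fold()`'s two phases).  Published DeepDTA fold files, when
present in a benchmark directory, are used verbatim (their 0-based
indices converted to 1-based); otherwise the partition is a seeded
uniform shuffle.  Interactions - not drugs or proteins - are the unit of
splitting, matching the published split sizes, so the same molecule or
protein can appear on both sides of a split; reported scores measure
in-chemical-space interpolation, not generalization to unseen entities.

## Metrics

* **MSE** - mean squared difference.
* **Concordance index** - over every ordered pair with distinct true
  affinities, credit 1 when the predictions rank the pair correctly, 0.5
  when the predictions tie, 0 otherwise, divided by the number of
  comparable pairs.  Ties in the *true* affinity contribute no pair.  The
  normalizer is read as the number of comparable pairs (the standard
  definition); reading it as "pairs in the correct order" would make the
  index identically 1.
* **rm2** - $r^2 (1 - \sqrt{r^2 - r_0^2})$, where $r^2$ is the squared
  Pearson correlation and $r_0^2$ the through-origin counterpart computed
  with the least-squares origin slope $k = \sum y \hat y / \sum \hat y^2$.
  Since the through-origin fit is nested in the affine fit,
  $r_0^2 \le r^2$ mathematically; if floating-point noise ever produces a
  negative square-root argument it is clamped at zero with a warning.
  Values above 0.5 conventionally indicate an acceptable model.
* **AUC-PR and accuracy** - computed after binarizing affinities: pKd
  $\ge 7$ (i.e. Kd $\le$ 100 nM) is "binding" for Davis-style data;
  KIBA score strictly $< 12.1$ for KIBA.  The PR curve uses step-wise
  (non-interpolated) summation over distinct score thresholds - the
  average-precision convention, which avoids the optimism of trapezoidal
  interpolation; for KIBA the sweep uses negated predictions since lower
  scores mean stronger binding.  A constant score therefore yields the
  positive prevalence.

Degenerate inputs (constant observations, single-class labels) are
reported as `NA` with a warning by `evaluate_predictions()` rather than
silently averaged - the individual metric functions reject them.

## The synthetic generator

`generate_synthetic()` exists so the whole pipeline is testable without
downloading benchmarks.  It emulates the *format* and summary statistics
of the public kinase benchmarks, not their chemistry:

* sequences are uniform-random over the two alphabets, with clipped
  log-normal lengths defaulting to the published summaries (SMILES mean
  about 64 characters in range 20-590; proteins mean about 728 residues
  in range 215-4128);
* the affinity of drug $d$ and target $t$ is
  $g = a \langle u, f_{mol}(d)\rangle + b \langle v, f_{prot}(t)\rangle +
  c \langle u, f_{mol}\rangle \langle v, f_{prot}\rangle$, built from the
  same normalized k-mer profiles the encoder produces, standardized over
  the sampled interactions to mean 7 and unit SD (a pKd-like scale,
  placing the Davis binarization threshold at the signal center), plus
  Gaussian noise whose SD is expressed in units of the signal SD
  (default 0.2);
* the latent weights $u, v$ are *sparse*: 40 molecule k-mers and 60
  protein k-mers (defaults) carry independent Gaussian weights and all
  other k-mers carry zero.  This encodes the motif view of molecular
  recognition - binding driven by a limited set of substructures - and
  it is what makes the signal learnable by a convolutional network at
  desk scale: a signal diffused over all 9261 k-mers is spread across
  every pooled region of the image and is not recoverable in a few
  hundred gradient steps;
* the default problem size is 200 drugs x 50 targets at density 0.2
  (2000 interactions), and everything - lengths, sequences, weights,
  measured cells, noise - derives from one integer seed, so the same
  spec is bit-reproducible.

Ground truth (weights, term coefficients, the standardization, the
noiseless signal) is attached to the generated table for recovery tests.
With zero noise and no interaction term the affinities are exactly affine
in the concatenated profiles; the test suite verifies that an ordinary
least-squares fit on the profiles reproduces them (using $k = 1$ spaces,
where the OLS problem is determined).

What passing tests on this generator do **not** show: real SMILES/protein
sequences are highly non-uniform, real affinity surfaces are not sparse
linear functionals of k-mer content, and real benchmarks carry assay
noise structure and censoring that the generator does not emulate.
Desk-scale results validate the machinery (encoding, splitting, training
dynamics, metrics), not benchmark-level accuracy.

## Problem sizes used by the test suite

The suite favors a few deep, seeded checks over exhaustive sweeps: the
counting oracle runs 1000 random sequences; the concordance oracle 100
instances up to n = 500; the learnability check trains the default
architecture for 20 epochs on the default 2000-interaction fixture and
asks for held-out CI above 0.70 and rm2 above 0.5 - deliberately modest
bounds, as 20 epochs is a small fraction of the reference 1000-epoch
schedule; the idempotence check runs the CLI pipeline twice on a
300-interaction fixture at 2 epochs and requires bit-identical reports.

## Known limitations

* The engine is CPU-only and single-threaded beyond what BLAS provides;
  it is sized for desk-scale experiments, not benchmark-scale training.
* Convolution kernels other than 3x3 and pools other than 2x2 are not
  implemented (the architecture spec validates this).
* Benchmark affinity matrices are read as delimited text; the original
  Python-pickled matrices must be exported to text first.
* Single-precision arithmetic bounds gradient accuracy near the float
  noise floor; the finite-difference test accounts for this.
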