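# sigdta

Drug–target binding affinity prediction from k-mer **signature images**.

`sigdta` is for computational chemists and method developers who want an
alignment-free, embedding-free baseline for sequence-based affinity
regression. Instead of treating SMILES strings and protein sequences as
text for an NLP-style model, it maps each sequence to a fixed-size
grayscale image summarizing its k-mer content, and regresses binding
affinity from the image pair with a dual-branch convolutional network.

## The method in brief

For a sequence $s = [s_1,\dots,s_c]$ over an ordered alphabet $\Sigma$,
$|\Sigma| = n$:

1. slide a window of length $k$: the $l = c - k + 1$ overlapping k-mers;
2. tally them into the counting vector $c \in \mathbb{N}^{n^k}$, indexed
   by the row-major lexicographic rank of each k-mer ($\sum_i c_i = l$);
3. max-normalize: $f = c / \max(c) \in [0,1]^{n^k}$;
4. reshape $f$ row-major into an $m \times m$ image,
   $m = \lceil\sqrt{n^k}\rceil$, appending $e = m^2 - n^k$ zeros.

Molecules use a 36-symbol SMILES character alphabet with $k = 2$
($36\times36$ image, no padding); proteins use the 20 amino-acid letters
plus `X` with $k = 3$ ($97\times97$ image, 148 padding cells). Each image
branch of the network applies three (3×3 convolution → ReLU → 2×2
max-pool) blocks and flattens (128 and 3200 units); the concatenated 3328
features pass through dropout 0.4, a 512-unit ReLU layer, dropout 0.4 and
a linear output. Training minimizes MSE with Adam (lr 0.001, batch 256);
evaluation uses MSE, concordance index, rm², and AUC-PR/accuracy after
binarizing affinities (pKd ≥ 7 for Davis-style data, KIBA score < 12.1).
The CNN engine is built into the package (RcppArmadillo, im2col + BLAS,
analytic gradients); no external deep-learning framework is required.

A seeded synthetic-data generator produces benchmark-layout fixtures whose
affinity is a known sparse ("motif-like") function of k-mer content, so
the full pipeline — encoding, experiment plan, training, metrics — is
testable at desk scale. See the methods vignette
(`vignettes/signature-images.Rmd`) for the model, the design decisions and
the generator's scope.

## Worked example

```r
library(sigdta)

## encode the 14-character thienopyrimidine SMILES as a signature image
img <- encode_molecule("Nc1ncnc2sccc12")
dim(img)                      # [1] 36 36
attr(img, "l")                # [1] 13      (l = c - k + 1 windows)
max(img)                      # [1] 1       (max-normalized)
sum(img > 0)                  # [1] 10      (10 distinct 2-mers)

## a protein encodes to the 97 x 97 space
pimg <- encode_protein(paste(rep("MSSSEEVSW", 24), collapse = ""))
dim(pimg)                     # [1] 97 97

## end-to-end at desk scale: 2000 synthetic interactions, 20 epochs
tb   <- generate_synthetic(synthetic_spec(seed = 11))
plan <- make_plan(tb, seed = 11)          # 5 CV folds + held-out test
res  <- train_fold(tb, plan, fold = 1,
                   config = training_config(epochs = 20, seed = 11))
res$metrics
#>         mse        ci      rm2     aucpr       acc
#> 1 0.4024532 0.8037375 0.612271 0.8697605 0.8108108
```

The last block trains the default dual-branch network on a seeded
synthetic benchmark (affinities on a pKd-like scale: mean 7, unit signal
SD, 20% noise) and evaluates the persisted model on the held-out test
part: after 20 epochs it ranks unseen pairs with concordance 0.80,
explains the affinity scale with rm² 0.61 (above the conventional 0.5
acceptability bound), and separates "binders" (pKd ≥ 7) with AUC-PR 0.87.
Runtime is a few minutes on one CPU.

A thin command-line wrapper is installed with the package
(`system.file("cli", "sigdta", package = "sigdta")`) exposing
`encode`, `synth`, `prepare`, `train`, `crossval` and `evaluate`
subcommands; every run writes a `run_manifest.json` with the effective
options, seed and input digests.

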