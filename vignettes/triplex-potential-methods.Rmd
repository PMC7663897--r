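---
title: "Predicting DNA:RNA triplex-forming potential from sequence composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA:RNA triplex-forming potential from sequence composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Some long non-coding RNAs (lncRNAs) regulate chromatin by binding duplex DNA
as a third strand, forming DNA:RNA triplexes through Hoogsteen or
reverse-Hoogsteen pairing with the purine-rich strand. Rule-based scanners
(Triplexator, Triplex Domain Finder and relatives) enumerate sequences with
the *theoretical* capacity to form triplexes, but they flag far more lncRNAs
than experiments ever confirm. `triplexpot` addresses the complementary
question: among sequences that pass the theoretical filters, which look like
the ones that form triplexes *in practice*? It learns that distinction from
labeled sequence sets — one model for lncRNA transcripts, one for DNA sites —
using nothing but sequence composition.

This vignette explains the representation, the model, the imbalance-handling
training protocol, the evaluation harnesses, and the design decisions taken
where more than one reasonable choice existed.

## Sequence representation

Every sequence (RNA transcripts are mapped to the DNA alphabet by `U -> T`)
is reduced to a fixed 90-dimensional vector with two kinds of entries.

**Overlapping k-mer frequencies (84 entries).** For word length $k$ and a
sequence of length $n$, every one of the $n - k + 1$ overlapping windows is
counted and divided by the window count:

$$\mathrm{kmer}(i) = \frac{\#\{\text{windows equal to word } i\}}{n - k + 1}.$$

For `"AAAAC"` and $k = 3$ this gives 2/3 for `AAA`, 1/3 for `AAC` and zero
elsewhere. The vector concatenates $k = 1, 2, 3$ (4 + 16 + 64 entries), each
block in lexicographic order over `A < C < G < T`. The order within a block
is a convention — any fixed order carries the same information — and
lexicographic is the testable, conventional choice.

**kmerscores (6 entries).** A single log-odds summary of composition bias per
word length $k = 1, \dots, 6$. Let $M_{pos}$ and $M_{neg}$ be the mean k-mer
frequency vectors of the positive and negative *training* sequences, and
$h_1 \dots h_{n-k+1}$ the sequence's windows. Then

$$\mathrm{kmerscore} = \frac{1}{n-k+1} \sum_{i=1}^{n-k+1}
  \log \frac{M_{neg}(h_i)}{M_{pos}(h_i)}.$$

Higher values mean "more negative-class-like". The windowed sum is exactly
equal to the frequency-weighted form $\sum_i f_i \log(M_{neg}(i)/M_{pos}(i))$
where $f$ is the sequence's own k-mer vector; the test suite verifies the two
routes agree to numerical tolerance.

Three numerical choices deserve mention:

* **Logarithm base.** Natural log. The base only rescales the feature, which
  is irrelevant to the downstream learner, but it must be fixed for
  reproducibility.
* **Pseudocount smoothing.** The log-ratio is undefined when a k-mer is
  absent from one class mean — essentially certain for $k = 6$ (4096 words)
  on small training sets. `fit_class_means()` therefore adds a pseudocount
  (default `1e-6`) to every entry of each class mean and renormalizes,
  making all entries strictly positive. The default is small enough to leave
  well-populated entries untouched to ~5 significant digits. Fitting with
  `pseudocount = 0` is allowed, but scoring then fails loudly on any unseen
  word rather than silently producing infinities.
* **Minimum length.** `featurize()` requires sequences of at least 6 nt (the
  largest kmerscore word). Shorter records are an error, not zero-padded:
  a padded score would be a number with no meaning.

**Leakage rule.** The class means are *fitted state*, exactly like the
centering vector of a normalization: they must be computed from training data
only and then applied unchanged to test data. The cross-validation harness
refits the profile inside every fold, and a test asserts that the stored
per-fold profile equals one refitted from the training records alone. A
trained model carries its profile with it (`save_model()` serializes it), so
prediction on new data always reuses the training-time means.

In this package's cross-validation the profile is fitted on the un-bagged
training positives and the full (pre-down-sampling) training negatives of the
fold: bagging duplicates records and would only reweight the mean, and the
down-sample is a random subset whose expectation is the full-pool mean, so
the full pool is the lower-variance choice. Only the train/test boundary is
a correctness constraint.

## The classifier

The 90-dimensional vector is consumed as a length-90, single-channel 1-D
signal by a small convolutional network: two stages of
convolution + activation + non-overlapping max-pooling, then a dense layer
with dropout and a sigmoid output giving the probability of the positive
class. The same architecture is trained twice — once on lncRNA data, once on
DNA-site data — giving two independent models that differ only in weights
and stored profiles.

The defaults are:

| parameter | default | notes |
|---|---|---|
| conv filters | 32, 32 | per stage |
| kernel sizes | 7, 13 | signal lengths 90 → 84 → 42 → 30 → 15 |
| pool sizes | 2, 2 | non-overlapping max |
| final map length | 15 | validated contract, see below |
| activation | ReLU | `tanh`/`sigmoid` available |
| dense units | 32 | |
| dropout | 0.3 | training only, inverted scaling |
| optimizer | Adam, lr 1e-3 | binary cross-entropy |
| epochs / batch | 100 / 32 | |

The one binding architectural contract is that the final convolutional stage
emits feature maps of **length 15** per filter; `cnn_config()` validates the
stage arithmetic and rejects any configuration that lands elsewhere, printing
the computed per-stage lengths. With non-overlapping pooling, kernels of
(7, 6) cannot reach 15 (84/2 = 42, 42−6+1 = 37, and 37 pools to 18, not 15),
so the default pairs kernel 7 with kernel 13. Every knob is exposed in
`cnn_config()`, so other settings satisfying the length-15 contract can be
dropped in directly. The kernel sizes, filter counts and optimizer defaults
are this package's choices, not recovered originals.

The network is implemented inside the package (vectorized im2col
forward/backward passes, Adam) rather than through an external deep-learning
framework. With a 90-dimensional input and two small stages the model has
only a few thousand parameters; a from-scratch implementation keeps training
single-threaded and **bit-reproducible**: the same `cnn_config()` (including
its seed) and the same inputs give identical weights and probabilities on
every run. The backward pass is verified against central finite differences
in development, and the test suite asserts determinism directly. The 90-dim
vector is deliberately *not* reshaped into a 2-D image: any such reshape
imposes an arbitrary adjacency between feature blocks, and a display-oriented
grid is not a modeling assumption.

Prediction thresholds default to 0.5 with `>=` mapping to positive; the
threshold is stored in the model and adjustable at prediction time.

## Class imbalance and the training protocol

Realistic datasets here are heavily imbalanced — on the order of 1:68
(lncRNA) and 1:5 (DNA sites) — and the positive class of the lncRNA problem
is itself a mixture of two subtypes in roughly 2.5:1 ratio: a CG-rich
majority (peak-supported transcripts) and an AT-rich minority (literature-
reported triplex lncRNAs) whose composition resembles the negatives. Two
mechanisms address this, both applied to **training data only**:

* **Random down-sampling of negatives** (`downsample_negatives()`): training
  negatives are drawn uniformly without replacement to match the size of the
  (augmented) positive training set, with a fresh draw in every fold or
  repetition.
* **Weighted bagging** (`weighted_bagging()`): the positive training set is
  tripled by bootstrap, with two-thirds of the draws taken from all positives
  and one-third restricted to the `weak` subtype. This forces the model to
  see the minority subtype often enough that it cannot simply learn "CG-rich
  means positive". Draws in the two-thirds share may also hit weak records —
  the unrestricted pool is the whole positive set. With multiplier $m$ and
  weak fraction $w$, the output has exactly $m \cdot n$ records of which
  $\mathrm{round}((1-w)\,m\,n)$ come from the full pool; bagged records keep
  their source id plus a replicate suffix, and a `bag_pool` column records
  the provenance of every draw for auditing.

Test folds are never resampled: evaluation happens at the natural imbalance,
which is why the rank-based AUROC and especially AUPRC are reported alongside
accuracy, sensitivity (Sn), specificity (Sp), their harmonic mean
$\mathrm{Hm} = 2\,\mathrm{Sn}\,\mathrm{Sp}/(\mathrm{Sn}+\mathrm{Sp})$ and F1.
A metric whose denominator is zero on a degenerate fold is reported as `NA`
with a warning, never coerced to 0. ROC areas use trapezoidal integration
with tied scores processed as blocks (thresholds placed only between distinct
values); PR areas use step-wise precision-at-recall summation (the
average-precision convention), not linear interpolation, which would be
optimistic.

## Evaluation harnesses

**Stratified five-fold cross-validation** (`run_cross_validation()`) assigns
each class to folds round-robin after a seeded shuffle (fold sizes within one
record per class), and per fold: fits the profile on training folds, bags
training positives if configured, down-samples training negatives to the
augmented positive count, trains, and evaluates the untouched fold.

**Leave-gene-out validation** (`run_leave_gene_out()`) holds out every
transcript variant of one gene as the positive test set. This exists because
variants of the same gene are near-duplicates: plain cross-validation lets a
model score a test variant by recognizing its sibling in the training set,
inflating performance without generalization. Each of the `reps` repetitions
takes its test negatives from one fold of a stratified negative split and
draws a fresh training down-sample from the remainder.

**Approximate redundancy filtering** (`greedy_redundancy_filter()`) offers an
identity-threshold de-duplication in the CD-HIT style: records sorted by
decreasing length are clustered greedily on cosine similarity of word-k-mer
count vectors, keeping representatives. It is deliberately *not* bit-exact
CD-HIT (different algorithm, no alignment); it exists so the
redundancy-removal experiments can be exercised at desk scale. Thresholds
like 0.9/0.8 map directly onto the cosine cutoff. The length sort makes the
output independent of input order.

## The synthetic data generator

`synthetic_design()` + `generate_dataset()` produce labeled datasets with the
compositional structure the method exploits, so the entire pipeline is
testable without downloads:

* positives from two subtypes — `strong` (CG-rich, default base probabilities
  (0.1, 0.4, 0.4, 0.1) for A, C, G, T) and `weak` (AT-rich) — in the 2.5:1
  ratio; negatives AT-rich (default (0.4, 0.1, 0.1, 0.4));
* the weak subtype sits a composition offset `delta` away from the negatives
  (probability mass `delta` moved from A/T to C/G). `delta` defaults to 0.05:
  the true separation of literature-reported triplex lncRNAs from negatives
  is unknown and evidently small (leave-out results on such genes can fall
  to chance or below), so the default keeps the weak subtype hard without
  making it impossible. `delta = 0` makes weak positives statistically
  identical to negatives;
* class imbalance defaults of 1:68 (lncRNA mode) and 1:5 (DNA-site mode),
  with lengths 200–2000 nt and 60–400 nt respectively — plausible ranges;
  all features are length-normalized, so length mainly affects the variance
  of the composition estimates;
* positives are organized into genes: each gene has an archetype sequence
  and up to `max_variants_per_gene` (default 5) variants produced as
  point-mutated copies (default per-base substitution rate 0.02), giving
  leave-gene-out and redundancy filtering realistic within-gene structure;
* an optional motif can be planted to probe what the 3-mer features capture
  beyond mononucleotide bias; the default effect structure is
  composition-only, because the feature set itself is composition-based.

What the generator does **not** emulate: triplex thermodynamics, Hoogsteen
pairing rules, genomic context, splice structure, or any sequence property
beyond base composition and within-gene redundancy. Tests passing on this
generator show that the software implements its contracts — they are not
evidence about biological data.

One interaction is worth understanding because it reproduces a known
evaluation pitfall. With gene blocks enabled, near-duplicate variants land in
both training and test folds of a plain cross-validation, and even classes
with *identical* composition become separable at the record level — the
model recognizes specific training sequences rather than class structure.
The package's end-to-end null check ("no composition gap gives AUROC around
0.5") therefore generates independent records (`max_variants_per_gene = 1`);
with gene blocks enabled the same null scenario scores far above chance,
which is precisely the redundancy inflation that leave-gene-out validation
is designed to expose.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on generated data at
desk scale: recovery and null checks use 100 positives vs 500 negatives
(five-fold CV, three seeds); the lncRNA-mode emulation uses 70 positives at
the full 1:68 imbalance (4760 negatives); leave-gene-out uses a 12-variant
held-out gene with 5 repetitions. Training in these runs uses the default
architecture at 60 epochs, batch 32 — on trivially separable data the loss
plateaus well before that, and on null data extra epochs only overfit
training folds without moving held-out AUROC. The package defaults
(100 epochs) remain the recommendation for real analyses.

## Known limitations

* Composition features cannot represent positional information; two
  sequences with the same 3-mer spectrum are indistinguishable regardless of
  the CNN on top.
* The redundancy filter approximates identity clustering; cluster membership
  can differ from alignment-based tools near the threshold.
* The CNN is pure R: fast at the problem sizes above (a fold trains in
  seconds), but not intended for feature vectors orders of magnitude longer.
* Undefined metrics on degenerate folds propagate as `NA` into fold means;
  with very small classes prefer AUROC/AUPRC, which are always defined when
  both classes are present.
* The generator's gene variants are point mutations of an archetype at a
  single rate; real transcript variants differ by splicing, which changes
  composition in a more structured way.
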