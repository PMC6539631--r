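---
title: "Property tri-gram encoding for apoptosis protein localization: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Property tri-gram encoding for apoptosis protein localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# chunks are illustrative; heavy pipeline runs are not executed at build time
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Apoptosis proteins act where they reside, so assigning a subcellular
location (cytoplasm, membrane, mitochondrion, nucleus, endoplasmic
reticulum, secreted) to a protein sequence is a multi-class classification
problem. `popmtrigram` implements an alignment-free predictor: no database
search, no profile construction — features come from the primary sequence
alone.

**Encoding.** Each residue is mapped to a 10-bit vector over Taylor's
overlapping physicochemical groups, in fixed order Polar, Positive,
Negative, Charged, Hydrophobic, Aliphatic, Aromatic, Small, Tiny, Proline.
The groups overlap: lysine, for instance, is simultaneously Polar,
Positive, Charged, and Hydrophobic. Stacking the row vectors for a
sequence of length $L$ gives the protein overlapping property matrix
(POPM), an $L \times 10$ binary matrix $M$ with $M_{ij} = 1$ iff residue
$i$ belongs to group $j$.

**Tri-gram features.** For each ordered property triple
$(x, y, z) \in \{1..10\}^3$:

$$\mathrm{gram}(x,y,z) \;=\; \frac{1}{L-2}\sum_{i=1}^{L-2}
  M_{i,x}\, M_{i+1,y}\, M_{i+2,z},$$

the relative frequency with which properties $x$, $y$, $z$ co-occur at
three adjacent positions. There are exactly $10^3 = 1000$ features, each in
$[0, 1]$. Features are stored in lexicographic $(x, y, z)$ order — the flat
zero-based offset is $(x{-}1)\cdot100 + (y{-}1)\cdot10 + (z{-}1)$ — so that
feature rankings are stable and invertible across runs.

**Selection and classification.** Features are ranked by SVM-RFE: a linear
SVM is fit on the surviving features, each feature is scored by its squared
weight component (summed over all one-vs-one class-pair machines in the
multi-class case), and the lowest-scoring `step` features are discarded;
the ranking is the reverse removal order. The classifier is a linear-kernel
one-vs-one SVM (libsvm via e1071). Evaluation is the leave-one-out
jackknife, reporting per-class sensitivity, specificity, and Matthews
correlation coefficient, plus overall accuracy (OA):

$$\mathrm{Sens}_j = \frac{TP_j}{TP_j + FN_j},\quad
  \mathrm{Spec}_j = \frac{TN_j}{TN_j + FP_j},\quad
  \mathrm{OA} = \frac{\sum_j TP_j}{\sum_j |C_j|},$$

$$\mathrm{MCC}_j = \frac{TP_j\,TN_j - FP_j\,FN_j}
  {\sqrt{(TP_j{+}FP_j)(TP_j{+}FN_j)(TN_j{+}FP_j)(TN_j{+}FN_j)}}.$$

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 120 | Number of top-ranked features given to the classifier. 120 is the operating point at which the top-K accuracy curve peaks on the 4-class apoptosis benchmark; sweep it with `sweep_top_k()` (grid 10, 20, ..., 300 by default) for new data. |
| `cost` | 1.0 | SVM cost parameter C. The linear kernel leaves C as the only SVM hyperparameter; 1.0 is the conventional default and is exposed everywhere. |
| `rfe_step` | 1 | Features eliminated per RFE iteration. 1 is the classical schedule and the most fine-grained ranking; larger steps (25–200) give near-identical top ranks at a fraction of the cost and are used in several tests. |
| `mode` | `"paper"` | Where selection sits relative to the jackknife (see below). |

Features are never rescaled: tri-gram values already live in $[0,1]$ on a
common scale, and unscaled features keep RFE weights directly comparable.
(`e1071::svm` is always called with `scale = FALSE`.)

## Selection inside or outside the jackknife

Protocols that report one ranked feature list per dataset rank on the full
matrix once and then run the leave-one-out loop on the selected columns
(`mode = "paper"`). This lets every held-out sample influence selection.
The package ships both this protocol and `mode = "leak_free"`, which
re-ranks inside each fold on the $n-1$ training samples.

The difference is not cosmetic, and null data (identical residue profiles
for all classes, so the labels carry no signal) exposes both protocols'
pathologies at once. Rank-once selection of 120 from 1000 features
inflates leave-one-out OA to roughly 0.8 on a balanced 4-class,
$n = 200$ design — pure selection bias. Fold-internal selection removes
that bias but does *not* land at chance: measured OA is approximately 0,
with an exactly empty confusion diagonal. This is leave-one-out
*anti-learning*: tri-gram features of same-profile sequences concentrate
tightly around the shared composition statistics, the classes are
inseparable, and an SVM on inseparable data degenerates toward a majority
vote — and in every leave-one-out fold the held-out sample's own class is
the one with one fewer training member, so every one-vs-one vote tips
against it. The effect reproduces with plain libsvm on the raw feature
matrix with no selection at all, so it is a property of the
classifier/protocol pair, not of the selection step. Exchangeable labels
therefore do **not** guarantee chance-level jackknife accuracy for this
pipeline; the honest statement is that leave-one-out OA on null data is
*at or below* chance once selection is fold-internal, and any OA
substantially above chance under rank-once selection measures leakage,
not signal. The acceptance suite runs the null check in `leak_free` mode
on the balanced design (where chance is exactly $1/C$) and records the
measured value.

`leak_free` is the recommended mode for honest error estimates on new
applications; `paper` mode is the default because it matches the protocol
under which the published operating point $k = 120$ was chosen.

On genuinely separable data the two modes agree (tested: leak-free OA is
within 0.05 of rank-once OA).

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws sequences with i.i.d. residues from
class-specific composition profiles
$p_c(r) = (1-s)/20 + s\,[r \in S_c]/|S_c|$, where $S_c$ is a
property-aligned residue set (aromatic, aliphatic, charged, tiny, ...) and
the strength $s \in [0,1]$ sets the separation; $s = 0$ is the exchangeable
null. Lengths are uniform on (50, 500), spanning typical benchmark protein
lengths; encoder behaviour at the benchmark extremes (76 and 3037 residues)
is covered by dedicated tests. `default_benchmark_spec()` reproduces the
class counts of the two standard apoptosis benchmarks (4 classes,
41/70/25/89, total 225; 6 classes, 112/47/55/34/52/17, total 317) with
$s = 0.5$, a separation a composition-based classifier should resolve
cleanly.

i.i.d. sampling is a deliberate simplification: tri-gram features depend
only on short-range property co-occurrence, and composition separation in
property space is exactly the signal they detect. The generator does *not*
emulate real apoptosis sequences, positional or Markov structure, homology,
or redundancy. Consequently, passing tests show that the pipeline's
machinery is correct and that it recovers composition-borne class signal;
they say nothing about accuracy on real proteins, which also depends on
how much localization signal real sequences carry in this feature space.
Reproducing the published benchmark accuracies requires the external
datasets (see `inst/scripts/fetch_benchmarks.R`, network-gated, untested).

## Numerical choices and degenerate inputs

* **Property order** is the table's top-to-bottom order (Polar = 1 ...
  Proline = 10); this reproduces the documented bit pattern V →
  `0000110100`. The table itself is the normative definition of
  membership: alanine is Hydrophobic + Small + Tiny (`0000100110`) because
  Tiny is a subset of Small in Taylor's scheme.
* **Non-standard residue codes** (B, J, O, U, X, Z) become all-zero POPM
  rows with a warning rather than being dropped: dropping would shift the
  tri-gram windows of everything downstream. Windows containing a zero row
  contribute nothing to any feature but still count in the $L-2$
  denominator — the defining formula is applied literally.
* **Sequences shorter than 3** have no tri-gram window and are an error at
  encoding time (the CLI `predict` command instead flags the offending
  query row and continues).
* **RFE ties** are broken by removing the feature with the larger column
  position first; with a deterministic solver this makes rankings
  bit-reproducible, which tests assert.
* **Zero-denominator metrics** (e.g., specificity when everything is
  predicted into one class) are reported as 0 with a `degenerate` flag
  rather than NaN, keeping sweep tables total.
* **Fold order** is dataset order; the only randomness in the pipeline is
  synthetic data generation, which is governed by the spec seed and
  restores the caller's RNG state.

## Problem sizes used by the test and acceptance suites

The suites run entirely on generated data at desk scale, chosen as the
smallest designs that still exercise each property: the full pipeline
check uses the 225-sequence 4-class benchmark shape with the default
step-1 RFE; the null check uses a balanced $4\times50$ design with a
coarse fold-internal elimination schedule (step 440, i.e., two
eliminations per fold) since ranking resolution is irrelevant on noise;
the class-imbalance variance check runs the benchmark imbalance at 1/5
scale (9/14/5/18) over 10 seeds without selection; oracle-equivalence
checks use 100 random sequences of length 3–60 against a naive
triple-loop evaluation at $10^{-12}$.

## Known limitations

* Composition-only features: two sequences with the same local property
  co-occurrence statistics are indistinguishable regardless of global
  arrangement.
* `paper`-mode accuracy estimates are optimistically biased whenever the
  feature ranking was computed on the evaluated data; use `leak_free` for
  reporting.
* The multi-class RFE criterion (sum of squared one-vs-one weights) and
  the elimination schedule are conventional choices; the method's
  published description fixes neither, and both are exposed as
  configuration.
* Only the 20 standard residues carry information; heavily ambiguous
  sequences (many X/B/Z codes) degrade gracefully but uninformatively
  toward the zero vector.
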