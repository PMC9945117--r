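---
title: "Classifying phage virion proteins from sequence composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying phage virion proteins from sequence composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virionRF)
```

## The problem

Phage-encoded proteins fall into two functional classes: virion proteins,
which are packaged into the mature particle (capsid and envelope
proteins, tail fibers, virion enzymes), and non-virion proteins, which
act in the infected cell — replication, transcription and regulatory
enzymes — but never join the particle. Distinguishing the two from
sequence alone is a binary classification problem with the virion class
as the positive label. virionRF implements a composition-based pipeline
for it: four per-sequence descriptors, their concatenation into one
feature vector, and a cross-validated random-forest classifier with
classical baselines.

The pipeline deliberately uses only composition statistics — no
alignments, profiles, or structural features — so it applies to any set
of protein sequences over the 20-letter alphabet, at the cost of
ignoring positional homology signal.

## The four descriptors

For a sequence of length $L$ with residues indexed over the fixed
alphabet `ACDEFGHIKLMNPQRSTVWY` (all feature blocks use this order,
first position major for pairs):

**AAC** (amino acid composition, 20 features): the frequency of each
residue, $\mathrm{count}(a)/L$. The entries sum to 1 and the descriptor
is invariant under any reordering of the sequence.

**CKSAAP** (composition of $k$-spaced amino acid pairs,
$400(k_{\max}+1)$ features): for each gap $k = 0, \dots, k_{\max}$, the
frequency of each ordered residue pair separated by exactly $k$
intervening residues,
$$\mathrm{CKSAAP}_k(ab) = \frac{N_{ab}(k)}{L - k - 1},$$
where $N_{ab}(k)$ counts index pairs $(i, i+k+1)$ and $L - k - 1$ is the
number of such pairs, so each gap sub-block sums to 1. Gap 0 recovers
adjacent pairs. The default $k_{\max} = 3$ gives $4 \times 400 = 1600$
features. We read the descriptor's published size of 1600 at $n = 3$ as
fixing the concatenation-over-gaps convention (gap-3 alone would give
400); the per-gap denominator is our choice of the unique normalization
that makes every sub-block a probability vector, since descriptions of
the encoder commonly leave the denominator implicit.

**DPC** (dipeptide composition, 400 features): adjacent-pair
frequencies $N_{ab}/(L-1)$; identical to the CKSAAP gap-0 block and
kept as its own block so the descriptor sets can be compared
like-for-like.

**DDE** (dipeptide deviation from expected mean, 400 features): each
observed dipeptide frequency standardized against a theoretical null
derived from the genetic code. With $N = L - 1$ dipeptides and codon
multiplicities $C_a$ (4 for A, 6 for L, 1 for M and W, ..., summing to
61 sense codons):
$$D_c(ab) = \frac{n_{ab}}{N}, \qquad
  T_m(ab) = \frac{C_a}{61}\cdot\frac{C_b}{61}, \qquad
  T_v(ab) = \frac{T_m(1 - T_m)}{N},$$
$$\mathrm{DDE}(ab) = \frac{D_c - T_m}{\sqrt{T_v}}.$$
Two interpretation points are worth recording. First, $T_m$ is built
from codon multiplicities, not from the sequence's own residue counts: a
per-sequence reading would make the "theoretical average" depend on the
observed sequence and collapse the descriptor toward zero by
construction. Second, some statements of the statistic divide by $T_v$
itself rather than its square root; standardizing by the standard
deviation is the established form and the default here, with
`ddeSqrtVariance = FALSE` available for the literal variance reading.
Because $0 < T_m < 1$ and $N \ge 1$, $T_v$ is strictly positive and no
zero-division guard is needed (asserted in the tests). A dipeptide
absent from the sequence always scores strictly negative.

Concatenation order is fixed: AAC, CKSAAP, DPC, DDE — 2420 features with
everything enabled — and feature names follow the grammar `AAC.<a>`,
`CKSAAP.<ab>.gap<k>`, `DPC.<ab>`, `DDE.<ab>`, which is stable across
runs and used in CSV headers and model bundles so column identity can be
enforced at prediction time.

## Classifier and evaluation protocol

The primary model is a random forest; its prediction score is the
fraction of trees voting for the positive class, thresholded at 0.5 with
ties broken toward negative. Defaults: 500 trees (vote fractions are
stable at that size for datasets of a few hundred to a few thousand
sequences; tests and examples use smaller forests where the extra trees
change nothing) and the host implementation's standard `mtry`
($\sqrt{p}$). Baselines — linear discriminant, RBF-kernel SVM with
probability estimates, and a CART decision tree — use their packages'
standard defaults, recorded in the model's config; constant columns are
dropped for LD/SVM, which cannot use them, and the dropped names are
recorded so the original matrix layout is still accepted at prediction.

Evaluation is stratified 5-fold cross-validation. Out-of-fold scores are
pooled into a single confusion table from which Sn, Sp, Acc, F1 and MCC
are computed once (the pooled protocol); per-fold metrics are retained
alongside, since summary tables in the literature rarely state which of
the two protocols produced them and the two can differ at small $n$.
MCC is set to 0 when any denominator factor vanishes — the standard
convention for degenerate predictors, needed because an all-negative
classifier is a real outcome (and note that with $TP = 0$ the F1
formula is identically 0; published tables occasionally pair zero
sensitivity with a large F1, which the formula cannot produce, and this
package makes no attempt to imitate that). ROC curves sweep the
distinct score values as thresholds with ties grouped; the AUC is the
trapezoidal area and equals the positive-negative pair concordance
(ties counted one half), which the tests verify against a brute-force
pairwise oracle.

Leave-one-out is supported (`folds = n`, unstratified); single-sample
folds have undefined per-fold metrics, reported as `NA`, while pooled
metrics remain well-defined.

## The synthetic generator

Real virion benchmarks are external and their curation (identity
filtering, class balance) is rarely fully specified, so the package
ships a generator that emulates the *shape* of such a benchmark — a
balanced two-class set, default 500 sequences per class, lengths drawn
uniformly on 50–400 residues, a typical span for phage structural
proteins — with a controllable, known class signal:

- **composition mode**: positive-class residues are drawn i.i.d. from
  $(1 - e)\,\mathrm{background} + e\,\mathrm{signature}$, the signature
  being uniform over {A, G, T, V}; the signal lives chiefly in the AAC
  block.
- **dipeptide_motif mode**: the 3-mer `WWH` is spliced into each
  positive sequence with probability $e$; W and H are rare, so the
  signal lives in the pair blocks and lets tests attribute performance
  to specific encodings.
- **mixed**: both; **none** (or $e = 0$): the classes are identically
  distributed.

The background is uniform over the 20 residues by default so that DDE
entries exercise both signs; a codon-multiplicity background is
available and is the null under which every DDE entry has expectation
zero (since $E[D_c] = T_m$ there), which the tests check empirically.

What the generator does *not* emulate: real phage protein statistics —
domain architecture, signal peptides, compositional autocorrelation,
homology between train and test sequences. Passing the synthetic tests
therefore demonstrates that the pipeline recovers planted signal of a
known kind and size, not that any particular accuracy will be achieved
on curated biological benchmarks; results on a real balanced virion
set depend on that dataset's curation and evaluation protocol, which is
why this package reports published combined-feature forest figures
(Sp ≈ 93%, Sn ≈ 90%, Acc ≈ 92%, MCC ≈ 0.84) as context only.

## Numerical and design choices

- **Residue policy**: sequences with non-standard characters
  (B, J, O, U, X, Z, gaps) fail loudly under the default `reject`
  policy — an explicit error beats silently distorted compositions —
  with `strip` available when ambiguity codes are known to be sparse.
  Lowercase is normalized before validation.
- **Preconditions**: AAC needs $L \ge 1$, pair encoders $L \ge 2$,
  CKSAAP $L \ge k_{\max} + 2$; violations abort with the offending
  record id rather than producing NaN columns.
- **Determinism**: one user seed drives everything; fold assignment and
  each per-fold fit get deterministic child seeds, recorded in the run
  log, and repeated runs are bit-identical.
- **Tie-breaks**: hard labels use score > 0.5 (exact 0.5 goes
  negative); ROC ties are grouped into one point per distinct score.
- **Feature/column identity**: models refuse prediction matrices whose
  columns differ from training — including permutations — instead of
  reordering silently.

## Test problem sizes

The package's statistical tests run at sizes chosen to make their
assertions sharp yet quick on a single CPU: the null-accuracy check uses
100 sequences per class over 20 generator seeds, each pooled accuracy
required to sit within three binomial standard deviations of 0.5; the
full-signal check uses 100 per class at effect size 1 (accuracy ≥ 0.95);
the combined-versus-best-block property uses 60 per class, mixed signal
at effect 0.5, 150 trees, over 10 seeds, with a 0.05 tolerance; encoder
oracles run on 100 random sequences of lengths 5–500. `scripts/acceptance.R`
additionally exercises the full 2420-feature forest at the benchmark
shape of 500 sequences per class.

## Limitations

- Composition descriptors discard positional and homology information;
  two sequences with the same dipeptide spectrum are indistinguishable.
- The feature space (2420) typically exceeds the sample count;  the
  forest tolerates this, but the LD baseline becomes rank-deficient
  (it runs, with collinearity warnings suppressed, on a
  reduced-rank fit) and its combined-feature results should be read
  accordingly.
- No feature selection or dimensionality reduction is included, and no
  probability calibration is applied to the vote fractions.
- The generator's i.i.d. residue model understates the difficulty of
  real benchmarks; treat synthetic accuracies as upper bounds.
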