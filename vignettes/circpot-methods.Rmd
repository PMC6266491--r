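---
title: "Methods: classifying circRNA potential from primary sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying circRNA potential from primary sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circpot)
```

## The problem and the model

Circular RNAs (circRNAs) arise when a downstream splice donor backsplices
to an upstream acceptor, producing a covalently closed transcript. Whether
a given gene can produce a circRNA isoform — and whether a circRNA is
expressed in stem cells — is predictable to a useful degree from primary
sequence alone. `circpot` implements that predictor as three random-forest
classifiers sharing one feature encoding and one scoring scheme:

* **CP-PCG** — circRNA potential of protein-coding genes (circRNA vs PCG),
* **CP-lncRNA** — circRNA potential of long noncoding RNAs,
* **SP-circRNA** — stem-cell expression potential of circRNAs.

Each classifier is a five-fold cross-validation ensemble of probability
forests. A new sequence is scored by all five fold models; each raw score
is converted to a *fractile* — its mid-rank quantile position within that
fold's held-out validation score distribution — and the five fractiles are
averaged. Averaging fractiles is rank aggregation: because the fold
validation sets are equally sized, the mean fractile equals the mean rank
of the sequence across the ensemble. The mean fractile (displayed as a
percentage) is finally calibrated against a table of empirical false
positive rates (FPR) tabulated on negative data, so a score of, say, 0.9
comes with the fraction of negatives that would have scored as high.

## Feature encoding (178 features)

The full profile concatenates four groups, min-max normalized to [0, 1]
using bounds learned on the training set (test values are clipped):

* **Basic (70)** — sequence length; the AG, GT, GTAG and AGGT frequencies
  (the donor/acceptor dinucleotides and their backsplice-like
  juxtapositions); GC content; and the 64 overlapping trinucleotide
  frequencies.
* **Graph (101)** — hashed neighborhood-pair features on the sequence path
  graph (below), reduced to the Top 101 by forest impurity importance.
* **Conservation (2)** — mean and population standard deviation of a
  per-base conservation track over the transcript interval.
* **Other (5)** — ALU overlap fraction from a repeat track, exact tandem
  repeat coverage, longest-ORF length and ORF propensity (ORF length over
  transcript length), and variant density from a position track.

Three profiles are selectable, mirroring the feature-set comparisons used
to probe what drives performance: `gc_len` (GC content + length only),
`sequence_only` (basic + graph; the natural profile for plain FASTA
input, where no genomic tracks apply), and `all` (178 features; requires
intervals plus annotation tracks).

Frequency denominators are overlapping-window counts per motif length, so
features are scale-free in sequence length; windows containing N are
excluded from numerator and denominator alike, because an ambiguous base
neither confirms nor denies a motif. The length feature enters raw and is
min-max normalized like everything else.

### Graph features

Each sequence is a labeled path graph: one node per nucleotide, backbone
edges between neighbors, no secondary-structure edges. For every radius
r ≤ R and every unordered pair of roots at backbone distance d ≤ D, the
pair of rooted radius-r neighborhoods is canonicalized and hashed into a
fixed-dimension count vector (defaults R = 2, D = 4, 32,768 dimensions).
A rooted neighborhood of a path is itself a path whose only non-trivial
automorphism is reflection about the root, so its canonical form is the
root label plus the lexicographically sorted pair of outward-read arms.

Two numerical choices matter:

* **No boundary truncation.** A radius-r neighborhood is emitted only when
  the full ball fits inside the sequence. This makes the encoding
  shift-covariant — the feature multiset of a subsequence is always
  contained in that of a supersequence — which is the invariant the tests
  verify. Truncated boundary windows would break it.
* **Hashing.** Canonical keys are mapped by a seedable polynomial string
  hash; collisions are accepted, as usual for hashed kernel encodings. The
  hash seed is part of the feature definition: changing it relabels the
  feature space, so it is stored with the model.

A consequence of unordered root pairs on a symmetric path is that a
sequence and its reverse encode identically; the basic features (which are
orientation-sensitive) disambiguate.

Feature reduction fits a 100-tree forest on the hashed counts of a
class-balanced subset (capped at 1747 sequences per class) and keeps the
Top-K by impurity importance, ties broken toward the lower feature id for
determinism. K defaults to 101; 50 and 200 are supported since nearby
values perform near-identically downstream.

## Forests, tuning and importance

Each fold model is a probability forest of unpruned trees grown on
bootstrap samples (sampling with replacement, so about 2/3 of rows train
each tree and the remaining out-of-bag (OOB) third validates it). The tree
count is tuned by five-fold cross-validated AUC over a grid of 10 to 100
in steps of 10, with the same folds reused for every candidate so the
comparison is exact, and ties resolved toward the smaller count.

Feature importance uses the OOB permutation scheme: per tree, the OOB rows
are scored before and after shuffling one feature's values over those
rows, and the importance is the mean increase in misclassification error
across trees. This is implemented in the package (on top of per-tree
forest predictions) rather than taken from the forest library, because the
exact per-tree OOB procedure — including skipping trees with no OOB rows —
is part of the method's definition. A constant feature has exactly zero
importance; a lone informative feature among dozens of noise features
should, and in the tests does, rank first.

## Fractiles and FPR calibration

The fractile of score *s* against sorted validation scores *v* is
(#{v < s} + 0.5 · #{v = s}) / |v| — the mid-rank convention, fixed so that
ties are handled deterministically and fractiles of a validation set
against itself are exactly uniform. The FPR table tabulates, on a grid of
cutoffs (default step 0.01), the fraction of negative mean fractiles at or
above each cutoff; lookup is by step function (largest tabulated cutoff at
or below the query), chosen over interpolation so that the table
reproduces its own empirical tail fractions exactly.

Calibration negatives should be held out from training: `circ_train()`
accepts a `cal_records` set for this purpose. When none is supplied the
training negatives are scored through the standard predict path — a
documented, slightly optimistic fallback, since four of the five fold
models have seen each training negative.

## The synthetic data generator

Real training data for this problem comes from circRNA databases and
genome annotation, which cannot be bundled or downloaded here. The
generator instead emulates a labeled dataset with explicit, tunable class
signal, touching every feature group so that each code path carries
variance in tests:

* per-base background composition with class GC probabilities
  (defaults 0.55 vs 0.45),
* Poisson-planted GTAG motifs at class rates (defaults 2.0 vs 0.5 per
  100 nt — the backsplice-signal analogue),
* transcript lengths uniform on 200-1000 nt (all above the 200 nt
  dataset filter; desk-scale rather than genome-scale),
* placement on a toy multi-chromosome genome with random strand, so BED
  extraction and strand handling are exercised,
* a segmented conservation track with a class mean shift (default +0.5
  for positives, unit noise),
* ALU intervals at class-dependent density (default probability 0.3 for
  positives, half for negatives) plus non-ALU decoys,
* uniform variant positions with no class signal.

The reference simulation is 500 transcripts per class. The null generator
draws both classes from the positive distribution, so labels carry no
information; the pipeline's out-of-fold AUC on such data stays near 0.5.

What passing tests on this generator shows is that the machinery —
encoding, selection, ensembling, fractiles, calibration — recovers known
signal and does not invent absent signal. It does not show that the
classifiers reach any particular accuracy on real transcripts: real
circRNA signal involves splicing structure, flanking intronic
complementarity and expression context that i.i.d. backgrounds with
planted motifs do not emulate.

## Numerical and design choices

* Coordinates are BED-convention 0-based half-open throughout; minus-strand
  intervals yield reverse-complemented sequence; a missing BED strand
  defaults to `+`.
* The dataset length filter keeps transcripts of exactly the minimum
  length ("shorter than" is removed); exclusion-overlap filtering is
  strand-agnostic single-base overlap, the most conservative reading
  against label leakage.
* ORFs are scanned on the three forward frames and require a stop codon;
  the length includes start and stop. This replaces heuristic
  coding-potential tools with a deterministic, oracle-checkable
  definition.
* Tandem repeats are exact maximal arrays (period ≤ 12, ≥ 2 copies,
  span ≥ 6 nt by default) — a deterministic replacement for
  alignment-scored repeat finders, with configurable parameters.
* Conservation uses the population standard deviation; missing track bases
  are skipped, not zero-filled, since zero is a meaningful conservation
  score.
* Ambiguity codes other than A/C/G/T/U are collapsed to N on input; U maps
  to T.
* All randomness flows from explicit integer seeds; forests run
  single-threaded so results are reproducible bit-for-bit, and
  sub-seeds are derived arithmetically (kept within 32-bit range) so
  stages are independently reproducible.
* Only single-interval BED entries are supported; multi-exon (BED12)
  structures are out of scope.

## Worked example

```{r example, eval = FALSE}
library(circpot)

sim <- generate_classification_dataset(synthetic_config(seed = 1))
model <- circ_train(sim$records, "cp-pcg", profile = "sequence_only",
                    top_k = 101, n_trees = 80, seed = 1)
glance(model)

test <- generate_classification_dataset(synthetic_config(seed = 2))
circ_evaluate(model, test$records)
head(circ_predict(test$records, model))
autoplot(model)               # out-of-fold ROC
autoplot(model$calibration)   # FPR vs cutoff
```

## Problem sizes used in the tests

The shipped tests run the reference simulation (500 + 500 transcripts of
200-1000 nt) for signal recovery and FPR calibration, 2000 fresh
negatives for calibration consistency, the complete enumeration of all
5460 sequences up to length 6 for graph-encoder equivalence, 200 random
sequences of 50-2000 nt for feature-oracle equivalence, and ten seeded
runs of 150 x 51 feature matrices for importance recovery. These sizes
were chosen as the smallest at which the checked properties are stable
across seeds.

## Known limitations

* Trained models are only as good as their training labels; the shipped
  pipeline ships no pre-trained human models and makes no claims about
  accuracy on real genomes.
* FASTA-only input cannot carry conservation/repeat/variant features; the
  `sequence_only` profile is the supported path there.
* The graph encoder operates on the structure-free sequence graph; RNA
  secondary-structure graphs are deliberately out of scope.
* Percentage display rounds to whole percent; ranking applications should
  use the underlying `mean_fractile`.
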