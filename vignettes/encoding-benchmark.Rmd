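---
title: "Benchmarking peptide sequence encodings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking peptide sequence encodings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepBench)
```

## The problem

Machine-learning models for peptide classification — antimicrobial
activity, cell penetration, epitope prediction and similar two-class
tasks — need a fixed-length numeric representation of each sequence.
Dozens of *encodings* exist for this purpose: functions $f : s \mapsto
\hat{s} \in \mathbb{R}^p$ mapping an amino-acid sequence
$s = (a_1, \dots, a_k)$, $a_i$ one of the 20 natural residues, to a
feature vector. Many are parameterized (window sizes, gaps, lags, tuple
sizes, reduced-alphabet resolutions), so a single dataset
$D = \{s_1, \dots, s_n\}$ spawns hundreds of encoded datasets
$\hat{D}_1, \dots, \hat{D}_d$, where
$d = \sum_i |\vec{x}_1(i) \times \cdots \times \vec{x}_n(i)|$ is the
product-sum over each encoding group's parameter axes.

pepBench implements this encoding layer together with the machinery to
compare encoded datasets fairly: redundancy filtering, a repeated
stratified cross-validation harness, per-fold performance metrics, and
the rank-based statistics (Friedman test with the Iman–Davenport
correction and Nemenyi critical differences), classifier-similarity and
matrix-correlation measures used to decide whether encodings differ in
any meaningful way.

## Encodings and their conventions

All encoders are pure, deterministic functions from a `PeptideSet` to an
`EncodedSet` (a numeric matrix plus drop bookkeeping). Rows follow input
order; a record a spec cannot encode — a sequence shorter than the
window, lag, $\lambda$, or tuple span — is dropped and listed with a
reason, never NA-filled. `|rows| + |dropped| = |input|` holds for every
encoder, and an encoding in which every record is dropped is an error.

Conventions worth knowing (each is exercised by the test suite's
brute-force oracles):

* **Composition families** (`aac`/`dpc`/`tpc`, grouped `g*` variants
  over the five physicochemical classes, `ngram`, `psekraac`) count
  overlapping k-mers and normalize to relative frequencies, so each row
  (or per-gap/per-k block for `cksaap`, `cksaagp`, `ksctriad`) sums
  to 1.
* **Autocorrelation** (`moran`, `geary`, `nmbroto`) z-standardizes each
  20-valued amino-acid index before use; a zero-variance index is
  rejected. For a sequence of one repeated residue the Moran and Geary
  statistics are 0/0; both are reported as 0. The per-residue `aaindex`
  encoder uses the same standardized scale.
* **Sliding-window composition** (`eaac`, `egaac`) must return a
  rectangular matrix on length-heterogeneous input; the window count is
  taken from the shortest retained sequence, so longer sequences
  contribute their leading windows only. Equal-length input reproduces
  the usual definition exactly.
* **CTD** uses the seven classic 3-class physicochemical partitions
  (hydrophobicity, van der Waals volume, polarity, polarizability,
  charge, secondary structure, solvent accessibility); transitions are
  normalized by $k - 1$, distribution landmarks (first/25/50/75/100% of
  each class's occurrences) are reported as percent of sequence length.
* **Conjoint triads** use the seven dipole/volume classes with triad
  positions $(i,\ i+k+1,\ i+2k+2)$, min–max normalized within each
  343-feature block; a sequence needs $2k + 3$ residues for skip $k$.
* **Sequence-order encoders** (`socnumber`, `qsorder`) take a list of
  residue distance matrices. Two are bundled: the Grantham distance,
  recomputed from the published composition/polarity/volume table and
  weights (scaled to mean 100 over residue pairs), and a *constructed*
  Euclidean distance over the three standardized pseudo-composition
  scales — the latter is our own asset, labelled as such, not a
  published table.
* **Pseudo amino-acid composition** (`paac`, `apaac`) uses the standard
  hydrophobicity / hydrophilicity / side-chain-mass scales,
  standardized; features sum to 1, and weight $\to 0$ reduces the first
  20 features to `aac`.
* **Per-residue encoders** (`binary`, `blosum62`, `zscale`, `aaindex`)
  require equal-length (pre-aligned) input and raise an
  alignment-required error otherwise; alignment itself is a pluggable
  external step. The gap character `-` encodes as a zero block.
* **FCGR** reduces the sequence to four symbols (default: nonpolar /
  polar-uncharged / positive / negative), iterates the corner-midpoint
  chaos game from the square's center and histograms the orbit on a
  power-of-two grid, normalized by sequence length.
* **`distance_frequency`** is a documented reconstruction: for each
  residue, the fraction of its occurrences falling in each equal-width
  bin of the normalized position $(i-1)/(k-1)$. Per-residue bins sum to
  the residue's `aac` value, and `bins = 1` collapses to `aac` exactly.
  The original algorithmic source for this descriptor is not public;
  treat the definition here as this package's own.

Identity anchors tie the families together and are asserted exactly:
`ngram(1) = aac`, `ngram(2) = dpc`, `distance_frequency(bins = 1) =
aac`, `psekraac(clusters = 20, ktuple = 1, gap = 0) = aac`.

The `psekraac` reduced alphabets are a single bundled nested hierarchy
(sizes 2, 3, 4, 5, 7, 10, 20; size 5 equals the composition groups,
size 7 the conjoint-triad classes, size 20 the identity). Published
reduced-alphabet schemes come in many variants; one self-consistent
family keeps the parameter grid meaningful without pretending to
reproduce any specific catalogue.

## Grid expansion and redundancy filtering

`expandEncodingGrid()` builds the union of per-group Cartesian products,
deduplicating axis values and identical parameter combinations — the
spec count is exactly the product-sum of axis sizes.

Two greedy filters reduce redundancy before benchmarking. Both use a
first-kept strategy in input order so the result is deterministic, and
both are idempotent:

* `filterIndexTables()` clusters amino-acid indices on absolute Pearson
  correlation of their 20 values (default threshold 0.8) and keeps the
  highest-variance member per cluster, ties broken lexicographically.
* `filterSpecsByProbe()` encodes a probe dataset under every spec and
  drops any spec whose matrix has adjusted RV-coefficient at or above
  the threshold (default 0.95) with an already-retained one.

The thresholds are package defaults, configurable per run; greedy
first-kept was chosen over global optimization because determinism and
order stability matter more here than minimality.

## Structure approximation

`approximateStructures()` assigns each query peptide an approximate
tertiary structure by sequence search against a database of chains with
known structures (`buildStructureDb()`), selecting the hit with the
lowest e-value and clipping the matched residue range from the template.
E-value ties are broken by higher identity, then lexicographic database
id. The search engine is pluggable; the bundled deterministic backend
finds exact substring matches, which keeps tests offline, while a
BLAST-compatible tool can be wrapped with the same hit-table contract.
Queries without a hit are omitted (and later encoding steps simply lack
those records — the paired CV below exists precisely to handle that).
A clip whose residues disagree with the matched query subsequence, or
that lacks coordinates, is omitted with a reason; the identity
`|clips| + |omitted| = |queries|` is asserted.

## Cross-validation and metrics

`repeatedStratifiedCV()` runs $k$-fold CV (default $k = 5$) repeated
$r$ times (default 10), i.e. 50 fold rows, storing per fold the held-out
ids, true classes, predicted probabilities and thresholded classes.
Stratification deals each class round-robin after a seeded shuffle, so
per-fold class counts are within one of proportional. Repetition $j$
shuffles with seed $s + j$; each fit runs under seed
$s + 1000j + \text{fold}$, making results byte-identical across reruns,
including for the default random-forest classifier (library defaults,
no hyper-parameter optimization — deliberately, so encodings rather
than tuning are compared). The classifier is injectable: anything with
`fit(x, y)` and `predictProb(model, x)` works, and
`centroidClassifier()` provides an RNG-free stub. Probabilities at or
above 0.5 predict class 1.

`pairedTwoGroupCV()` intersects the record ids of two encoded datasets
and applies one fold partition to both, so row $i$ of both results
covers identical test records — the precondition for the similarity
measures.

`computeMetrics()` reports F1, MCC, precision, recall and specificity
per fold row. Zero-denominator conventions: undefined fractions are 0,
except F1 = 1 when the fold has no true positives and none were
predicted (nothing to find, nothing claimed); MCC with a zero
denominator is 0.

## Comparison statistics

Ranks are computed per fold row (rank 1 = highest metric, ties
averaged); with the defaults that makes $N = 50$ paired observations
per model. The Friedman statistic
$\chi^2_F = \frac{12N}{k(k+1)}\bigl[\sum_j R_j^2 -
\frac{k(k+1)^2}{4}\bigr]$ and its Iman–Davenport correction
$F_F = \frac{(N-1)\chi^2_F}{N(k-1) - \chi^2_F}$ (F-distributed with
$k-1$ and $(k-1)(N-1)$ degrees of freedom) test the global null; the
Nemenyi critical difference $CD = q_\alpha\sqrt{k(k+1)/(6N)}$ flags
pairs with $|R_j - R_{\hat{j}}| \ge CD$. The critical value $q_\alpha$
is evaluated from the Studentized range distribution with $k(N-1)$
degrees of freedom (divided by $\sqrt 2$) rather than from a printed
table; $k \le 20$ and $\alpha \in \{0.05, 0.10\}$ are supported, and
the tests cross-check the values against the standard published
constants in the large-$N$ limit. A perfectly concordant rank table
drives the Iman–Davenport denominator to zero; that case is flagged,
not silently truncated.

Classifier similarity uses the disagreement measure
$D_{i,j} = \frac{1}{n}\sum_k |o^i_k - o^j_k|$ and the Phi coefficient
of the 2×2 agreement table, computed per fold row on paired results and
averaged. Phi is undefined for a constant prediction vector and
reported as NA with a warning — never silently 0; fold rows with NA phi
are excluded from the average.

Encoded-dataset correlation uses the adjusted RV-coefficient built from
$r^2_{adj}(x, y) = 1 - \frac{n-1}{n-2}(1 - r^2(x, y))$, summed over all
column pairs and normalized by the geometric mean of the within-matrix
sums, so $RV_{adj}(X, X) = 1$. Zero-variance columns (residues absent
from every sequence are common in composition encodings) carry no
correlation information and are removed first. Because all-vs-all
correlation is expensive, `topKCorrelation()` restricts it to the best
specs by mean F1 (ties lexicographic).

Class separation uses the Davies–Bouldin index over the two class
clusters (Euclidean centroids, mean intra-cluster distance). We follow
the standard convention — *lower* is better separation. Source
literature in this area sometimes describes an increased score as
better separation; that reading contradicts the index's definition, so
the implementation keeps the standard direction and this paragraph is
the flag.

For cross-dataset views, `rankGroups()` scores each encoder group per
dataset by its best member's mean F1 (group/dataset cells with no
scored member are imputed as 0 — mirroring encodings that drop all
records on short-sequence datasets) and ranks groups per dataset;
`upgmaCluster()` clusters datasets or groups by average linkage on
Euclidean distances, exportable as Newick.

## The synthetic fixture generator

`generateSyntheticDataset()` emulates a curated two-class peptide
collection: lengths follow a log-normal model (median 26, mean ≈ 55
residues) truncated to [3, 255], matching the length profile typical of
biomedical peptide datasets; the negative class draws residues
uniformly; the positive class moves a fraction `biasStrength` (default
0.3) of per-position probability mass onto `biasResidues` (default K
and R). Class counts are exact: `round(imbalance * n)` positives.
Identical seeds give byte-identical datasets.

What it does *not* emulate: positional motifs, length–class
association, phylogenetic relatedness, duplicated or near-duplicated
sequences, and label noise. Passing benchmarks on these fixtures
therefore demonstrates that the harness recovers a composition signal
and that the statistics behave as defined — not that any encoding will
perform comparably on real data.

## Problem sizes and numerical choices

The test suite checks every encoder exhaustively against independent
brute-force oracles on all sequences of length ≤ 6 over the 4-letter
sub-alphabet {A, C, D, K} (chosen to span four physicochemical
classes), and the statistics on small random instances against
double-loop evaluations. The signal-recovery check uses n = 200
records with bias 0.3 under 5×10 CV across five seeds, comparing
against a label-permutation control at the same seeds. The bundled
acceptance script (`scripts/acceptance.R`) re-runs that setup end to
end. These sizes were chosen as the smallest at which every property is
informative; all are package choices and scale up linearly.

Ties and degenerate inputs follow one rule throughout: break
deterministically (lexicographic ids, first-kept greedy order,
average ranks) and flag rather than guess (NA + warning for undefined
phi and adjusted $r^2$, errors for single-class CV inputs, zero-variance
indices and ragged per-residue input).

## Limitations

* Only binary classification; multi-class labels are out of scope.
* Structure-derived feature encodings (electrostatics,
  secondary-structure composition, Delaunay descriptors) are not
  implemented; only the structure *approximation* step is.
* No built-in aligner for the per-residue encoders; supply pre-aligned
  FASTA or wrap an external tool.
* No hyper-parameter optimization of the classifier, by design.
* The probe-based spec filter's result depends on the probe dataset;
  use a probe representative of the target data.
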