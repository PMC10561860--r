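---
title: "Methods: hairpin feature extraction and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hairpin feature extraction and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinclass)
```

`hairpinclass` classifies candidate RNA stem-loops as true pre-miRNA
precursors or pseudo hairpins. This vignette records the model, the
conventions and the genuinely open design choices, so that results computed
with the package can be interpreted (and criticized) precisely.

## The descriptor

Each example is a pair: an RNA sequence over {A, C, G, U} (length $L$,
1-based positions) and a secondary structure in dot-bracket notation with a
minimum free energy (MFE, kcal/mol) and, for the ensemble block, a matrix of
base-pair probabilities $p_{ij}$. The descriptor has exactly 93 values in a
fixed, versioned order (`feature_manifest()`), in four blocks.

**Triplet elements (32).** For every window of three adjacent positions the
structure pattern is read after collapsing `)` to `(`, so both partners of a
pair count as paired; the window is binned by (middle nucleotide, pattern).
With 4 nucleotides and $2^3$ patterns there are 32 bins. Values are
frequencies, each window contributing $1/(L-2)$; a raw-count interpretation
would differ only by the factor $L-2$, and the frequency convention keeps
sequences of different lengths comparable, which is the convention of the
triplet-feature lineage this block follows.

**Composition (45).** Mononucleotide counts and percentages
($\%X = |X|/L \cdot 100$), overlapping dinucleotide counts and percentages
($\%XY = |XY|/(L-1) \cdot 100$), combined $|G|+|C|$ and $|A|+|U|$ counts and
percentages, and $L$ itself. Counts are carried alongside percentages
because the manifest must reach 93 features and the count scale carries the
length information that percentages deliberately discard.

**Structural motifs (4).** A *stem* is a maximal run of stacked pairs —
$(i,j)$ and $(i+1,j-1)$ in direct contact — of run length at least 4,
reading "more than three contiguous base pairs" literally; a 3-pair helix is
not a stem (set `min_stack = 3` in `annotate_motifs()` to compare against
tools that count it). A *hairpin loop* is a maximal unpaired run enclosed by
a single pair, i.e. a dot-bracket substring `(\.+)`; internal loops, bulges
and multibranch loops are deliberately not counted in `n_loops`, because the
loop count normalizes energy-per-loop features and only hairpin loops mark
arms from which mature miRNAs can be cleaved. `loop_length` is the total
unpaired length across hairpin loops (multi-loop precursors exist, so a sum
is well defined; `loop_length_mode = "longest"` is available for
comparison). `tot_bp` is the number of base pairs.

**Thermodynamics and ensemble (12).** With $\%(G{+}C)$ in percent:

$$dG = \frac{MFE}{L},\quad dP = \frac{tot_{bp}}{L},\quad
MFE1 = \frac{dG}{\%(G{+}C)},\quad MFE2 = \frac{dG}{n_{stems}},\quad
MFE3 = \frac{dG}{n_{loops}},$$

$$MFE4 = \frac{dG}{tot_{bp}},\quad avg_{bp} = \frac{tot_{bp}}{n_{stems}},$$

$$Q = -\sum_{i<j} p_{ij}\log_2 p_{ij},\quad dQ = Q/L,\quad
dD = \frac{1}{L}\sum_{i<j} p_{ij}(1-p_{ij}),$$

and $zD$ is the z-score of $dD$ against a null of $M$
dinucleotide-preserving shuffles (Altschul–Erickson Euler-path algorithm)
refolded by the active backend, $M = 100$ by default and seedable. Three
conventions deserve emphasis:

* *`tot_bases` means base pairs.* The denominators of `MFE4` and `avg_bp`
  are described ambiguously in the lineage of these features (total bases
  vs. total base pairs). We use `tot_bp`: it makes `MFE4` distinct from
  `dG` rather than a duplicate, which is the only reading under which both
  features carry information.
* *Zero denominators yield 0*, never `NaN`/`Inf`. A completely unpaired
  sequence has no stems, loops or pairs; it must still be featurizable,
  since such degenerate candidates are exactly the ones a classifier should
  label negative.
* *Entropy uses log base 2* and zero-probability terms contribute zero.
  `Q` (the unnormalized entropy) and `dQ` are both in the manifest; they are
  distinct features on different scales.

The 93-name manifest is the package's own canonical ordering, enforced at
featurization time and versioned (`manifest_version()`); models record the
version and refuse to predict on mismatched layouts.

## Folding backends

Structures are obtained through a two-method contract (`fold()`,
`pair_probabilities()`), so the feature code never depends on a particular
folding engine. `vienna_backend()` shells out to `RNAfold` (partition
function via `-p`; probabilities read from the dot-plot file as
$p = (\sqrt{p})^2$). `stacking_backend()` is a deterministic greedy folder:
it extends the longest complementary stem (Watson–Crick plus G–U wobble,
hairpin loop ≥ 3 nt) and scores it −2 kcal/mol per stacked pair with a
+3 kcal/mol hairpin-loop penalty. Its energies are a coarse surrogate — not
nearest-neighbour thermodynamics — chosen so that every formula, filter and
model in the package can be exercised reproducibly with no external
software; its probability "ensemble" is degenerate (0.95 on each predicted
pair), which keeps `dQ`/`dD` nonzero and well-defined on fixtures.

## Dataset assembly

Candidates are retained iff length < 250 nt, $-180 \le MFE \le -5$ kcal/mol
and $10 \le GC\% \le 85$ (all known insect precursors lie inside these
windows; the longest is 222 nt and extremes of −174.9 and −5.4 kcal/mol and
12.28% GC motivate them). The length bound is strict (`< 250`) and the MFE
and GC windows are inclusive; the motivating extremes lie strictly inside
every window, so the boundary convention is unobservable on real data and
is simply fixed and documented here. Rejections carry the first failing
rule, checked in the order length, MFE, GC.

The train/test split is 75/25, stratified by label with a largest-remainder
allocation (exact within one row per class) and seeded. Stratification is
not optional in this domain: real corpora are imbalanced by a factor of
about six, and an unstratified split can starve a fold of positives.

## Class imbalance

Two strategies are implemented, both operating on *training rows only*,
after scaling and after the split — synthetic or discarded points must
never appear in evaluation data:

* **SMOTE**: each synthetic minority point is $x + u(x' - x)$, $u \sim
  U(0,1)$, where $x'$ is one of the $k = 5$ nearest minority neighbours of
  minority point $x$ (Euclidean distance on scaled features). $k = 5$ is
  the classical default. The minority class is raised exactly to the
  majority count; synthetic rows are flagged.
* **Near-Miss version 1**: majority points are ranked by mean Euclidean
  distance to their $k = 3$ nearest minority points and the closest are
  kept, down to the minority count. Version 2 (farthest minority points) is
  available behind a flag. No synthetic rows are created.

## Classifiers, tuning and evaluation

Four families are supported: SVM (`e1071`, Platt-style probabilities),
random forest (`ranger`, probability forests; `bootstrap = FALSE` maps to
sampling the whole data without replacement), ridge-penalized logistic
regression (`glmnet`, with the inverse-regularization parameter $C$ mapped
to $\lambda = 1/(Cn)$ on the mean-loss scale), and an internal exact k-NN
supporting Euclidean, Manhattan and Minkowski distances (Minkowski order
$p = 3$ by default, since the metric family is offered with a free order
and some order must be fixed; it is configurable). Every stochastic element
(fold assignment, random search, forest resampling) flows from one run-level
seed stored in the model.

Model selection uses stratified 10-fold CV mean accuracy. `tune()` follows
a two-stage protocol: uniform random draws from the declared space, then
coordinate-wise grid refinement — one parameter swept over a local grid
while the others are fixed, repeated until no parameter changes — with ties
broken toward the simpler model (smaller numeric values: fewer trees,
smaller cost, fewer neighbours). The twelve published best-parameter sets
(4 algorithms × SMOTE / Near-Miss / unbalanced) ship as
`published_params()`.

Evaluation thresholds probabilities at 0.5 and derives SN, SP, accuracy,
precision, F1 and MCC from the counts; AUC is the trapezoidal sum over
threshold-swept (FPR, TPR) points, which for binary 0/1 outputs collapses
to a single operating point and reduces exactly to $(SN + SP)/2$; AUPRC is
the average-precision step sum. MCC uses the standard subtracted numerator
$(TP \cdot TN - FP \cdot FN)$: recomputing the published imbalance-test
rows from their printed confusion counts confirms this form (e.g. MCC
0.12395 and 0.252656), whereas the additive variant that sometimes appears
in print does not reproduce them. Zero-denominator metrics are reported as
0, matching how degenerate classifiers (everything-negative) are tabulated
in the literature this package follows.

## Mature-arm extraction

Given a precursor and a chosen hairpin loop (1-based index, 5′→3′), the 5p
candidate is the `length` nucleotides ending immediately before the loop's
first unpaired base and the 3p candidate starts immediately after its last
unpaired base. Cleavage is flush with the loop: no Drosha/Dicer offset
model is applied, a deliberate simplification (offset models require
knowledge the structure alone does not provide). Default length is 22 nt,
the typical mature-miRNA length; arms shorter than requested yield
truncated candidates with a warning.

## The synthetic-data generator

`generate_fixtures()` emulates the two classes the classifier must
separate: positives are constructed stem-loops (stem of 15–40 pairs with
G·U wobble substituted at rate 0.1, hairpin loop of 3–10 nt, unpaired tails
of 0–12 nt, free energy from the stacking score — every positive passes the
default filters by construction); negatives are dinucleotide-preserving
shuffles of positives (composition-matched) alternating with uniform-random
sequences, folded by the greedy backend. These ranges are typical of insect
precursor stems and loops while keeping fixtures short enough for fast
tests.

What the generator does *not* emulate: imperfect stems (internal loops and
bulges), multibranch precursors, realistic nearest-neighbour energies, the
genomic composition biases of real pseudo hairpins, or the extreme class
imbalance of genome-scale screens. Consequently, the perfect or
near-perfect accuracies the package reaches on fixtures demonstrate that
the pipeline (features → scaling → balancing → model → metrics) is wired
correctly and that the feature set separates strong hairpins from
non-hairpins; they say nothing about accuracy on real insect data, which
requires the curated corpora and is out of scope here.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately desk-scale
problems: 500/500 fixtures for the learning-sanity checks (held-out
accuracy of SVM and RF, separability AUC), 120 rows for the permuted-label
CV null, 200 random fixtures for the brute-force oracle comparison at
$10^{-9}$, and 1,000 random structures for the motif-oracle property. The
scaler uses population standard deviation (so a two-point column scales to
±1) and maps constant columns to 0. Probability matrices are validated on
construction ($p_{ij} \in [0,1]$, per-position totals ≤ 1 up to $10^{-6}$).
Dot-bracket parsing is strict: pseudoknot alphabets are rejected, and
unbalanced strings report the first offending index.

## Known limitations

* The greedy backend folds a single helix; candidates whose discriminating
  signal lies in branched structure need `vienna_backend()`.
* `zD` is expensive ($M$ refolds per sequence) and defaults to 0 when no
  backend is supplied at featurization time; models trained with `zD`
  disabled are internally consistent (the scaler maps the constant column
  to 0) but not comparable to models trained with it enabled.
* Ambiguity codes (N, R, …) are rejected at ingest rather than imputed;
  the permissive mode skips such records, it does not repair them.
* The k-NN implementation is exact and $O(n_{train})$ per query; it is
  meant for the corpus sizes this package targets, not genome-scale
  scanning.
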