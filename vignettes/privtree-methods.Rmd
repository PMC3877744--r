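---
title: "Methods: protecting tabular data for outsourced decision-tree analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protecting tabular data for outsourced decision-tree analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privtree)
```

## The model

`privtree` addresses a concrete outsourcing problem: a data owner holds a
flat classification table (numeric and categorical attributes, a categorical
class) that may not leave the organisation in plaintext, yet wants an
external analyst to induce a decision tree from it. The package's protection
map sends a dataset $D$ to a protected dataset $D'$ cell by cell:

* each attribute name and each non-missing nominal cell $v$ of attribute $A$
  becomes a deterministic ciphertext $E_{k_A}(v)$, where
  $k_A = \mathrm{SHA256}(k \,\|\, 0 \,\|\, A)$ is derived from the 256-bit
  master key $k$ and the attribute name;
* each non-missing numeric cell $v$ of attribute $A$ becomes
  $T_A(v) = a_A v + b_A$ with $a_A > 0$ (default $(a, b) = (2, 1)$ for every
  attribute);
* missing markers pass through unchanged.

Deterministic encryption is essential, not incidental. A C4.5-style learner
consults the data only through two relations — token equality within a
column, and numeric order within a column — and the two transform families
above are precisely the maps that preserve those relations: deterministic
injective encryption preserves the equality partition of a nominal column,
and a strictly increasing map preserves the rank vector of a numeric column.
Every quantity the learner computes (class counts, entropies, information
gains, gain ratios, pruning estimates) is a function of counts induced by
those relations, so it takes *identical floating-point values* on both sides.
With value-independent tie-breaking the induced trees are therefore
structurally identical, with numeric thresholds related by $T_A$. This is an
exact invariance, not an approximation, and the test suite exercises it as a
property over randomized datasets.

The encryption itself is AES-256 in CBC mode with a fixed, salt-derived IV
per protection run, implemented in `src/` (the package needs only the
forward direction: protected values are mapped back through the lookup
table, never by cipher decryption). A fixed IV is a deliberate trade: it
makes equal plaintexts encrypt equally, which is the property the method
requires, at the acknowledged cost of revealing within-column equality — a
leak the analysis itself needs anyway. CBC under a fixed key and IV is
injective, so distinct tokens cannot collide; a collision (which would merge
two categories and silently change the induced tree) is checked for
defensively and aborts the run.

What the protected file still reveals: dimensions, missingness pattern,
nominal cardinalities, and the order (hence rough distributional shape) of
each numeric column. Order leakage is the price of keeping threshold splits
possible; stronger hiding would require order-revealing encryption with a
trusted comparator or homomorphic machinery, both out of scope.

## The lookup table

The owner-side `lookup_table` records attribute renames, every
(attribute, plaintext, protected) value pair — for numeric attributes, every
*distinct observed* value — and the affine coefficients per numeric
attribute. Decryption of an induced rule resolves attribute names through
the rename map and values through the value map; a protected numeric
threshold absent from the value map (possible in principle after pruning,
though the inducer's threshold convention below avoids it) falls back to the
closed-form inverse $T_A^{-1}(w) = (w - b_A)/a_A$, making rule decryption
total.

The persisted store is tab-separated with the column header
`renamed_attribute / original_atribute / attribute_name / encrypted_value /
original_value`. The second column's spelling is the one published with the
scheme's relational query interface and is kept verbatim so that existing
SQL queries against a bulk-loaded store run unchanged.

## The inducer

The learner is a C4.5-family gain-ratio tree with pessimistic pruning,
deliberately close to the J48 defaults without reproducing that
implementation bit for bit:

* **Candidate splits.** Nominal: one branch per declared domain token,
  admissible when at least two branches hold `min_leaf` (default 2)
  instances. Numeric: binary `<= θ` splits; every boundary between
  consecutive distinct sorted values is evaluated and the
  information-gain-maximizing cut chosen, with the reported threshold
  snapped to the **largest observed training value not exceeding the
  optimal midpoint**. Snapping guarantees thresholds are observed values,
  so protected thresholds decrypt exactly through the lookup table and
  $T(\theta_{\text{orig}}) = \theta_{\text{prot}}$ holds with no rounding.
* **Selection.** Among attributes whose best candidate has positive gain,
  the maximal gain ratio wins. Exact ties are resolved by attribute
  position (`tie_break = "attribute_index"`, the default), which is
  invariant under renaming and hence under encryption; the alternative
  `"attribute_name"` (lexicographic) exists to demonstrate how a
  name-sensitive learner can, on an exact tie, choose a different but
  equally accurate tree on the encrypted side, because ciphertext names do
  not preserve name order.
* **Missing values.** A candidate's gain is computed on the rows where the
  attribute is observed and scaled by the observed fraction; at split time
  (and at prediction time) missing rows follow the branch with the larger
  training mass. This is simpler than fractional-instance weighting; it is
  applied identically on both sides of protection, so invariance is
  unaffected. It is a documented divergence from J48, which is one reason
  per-dataset results of other implementations are not bit-targets.
* **Pruning.** Pessimistic subtree replacement: a subtree collapses to a
  leaf when the upper confidence bound on the leaf's training error — the
  normal-approximation binomial bound at confidence `confidence` (default
  0.25, $z = \Phi^{-1}(0.75) \approx 0.674$) — does not exceed the sum of
  its leaves' bounds. Subtree raising is not performed.
* **Evaluation.** A seeded unstratified shuffle assigns the first
  $\lceil 0.66\, n \rceil$ rows to training, the rest to testing; the split
  depends only on row count and seed, never on cell values, so both sides
  of a protection run receive the same row partition. Accuracy is the
  percentage of correctly classified test rows, reported to 2 decimals.

All comparisons in the inducer are exact floating-point comparisons. This is
intentional: both sides of a protection run compute gains from identical
counts, so their floats are bit-identical and tie behaviour coincides;
introducing tolerances would create artificial near-ties that differ between
sides.

## Statistical comparison

Across a corpus, each dataset is one subject observed under two conditions
(tree from original data, tree from protected data), so differences are
paired. `compare_report()` produces per-metric paired summaries (mean,
sample SD, SEM; accuracy as a proportion) and `bootstrap_paired()` tests a
zero mean difference by resampling the $n$ differences with replacement $B$
times (default $B = 1000$): bias, the SD of replicate means, a percentile
95% CI, and the two-sided achieved significance level
$p = 2 \min(\Pr(\bar d^* \ge 0), \Pr(\bar d^* \le 0))$, clipped to
$[1/B, 1]$. A bootstrap is used instead of a paired $t$ test because tree
sizes across heterogeneous datasets are heavily outlier-driven, which
inflates the variance estimate of a parametric test. The percentile CI and
the sign-fraction $p$ are the package's own choices; reference values
produced by other bootstrap implementations (unspecified $B$, seed and CI
type) are treated as qualitative context, not as reproduction targets. For
the packaged 30-dataset metrics table the size difference is a single
tie-broken tree out of 30, and the test is, as expected, far from
significance.

The packaged table itself (`table1_fixture()`) is transcribed verbatim from
its source, including two rows whose published summary statistics are
internally inconsistent with the table (the leaves-pair means and the
accuracy SEM round differently than the column data imply); the fixture is
not "corrected" toward those summaries, and tests assert the definitional
identities instead.

## The synthetic generator

`generate_dataset()` emulates the kind of mixed-type classification tables
the method targets, with a known ground truth. Defaults, fixed once:
300 rows; 4 numeric attributes, each a two-component normal mixture with
random location ($\mathcal N(0, 2^2)$) and scale ($U(0.5, 1.5)$) so split
boundaries overlap realistically; 4 nominal attributes with 3 uniform
tokens; 2 classes; labels assigned by a randomly planted decision tree of
depth ≤ 3 (thresholds drawn from the attribute's own law, no attribute
reuse along a path, stop probability 0.25), then flipped with probability
0.05; 2% of predictor cells masked as missing (the class column is never
masked — the learner has nothing to learn from unlabeled rows). Everything
is deterministic given the seed.

What the generator does *not* emulate: correlated attributes, class
imbalance beyond what the planted tree induces, measurement error
structure, and the scale of the largest real corpora (tens of thousands of
rows, hundreds of categories). Passing invariance tests on synthetic data
therefore demonstrates the algebraic property — which holds for any data —
but calibrates nothing about absolute accuracy on real clinical tables.
The invariance suite runs 30 generator seeds at the default 300×8 size,
which keeps the full comparison (protect, two inductions, two evaluations,
equivalence walk, thirty times) under a minute on one core.

`pima_schema_toy()` is a 40-row synthetic table carrying the classic
8-attribute diabetes-screening schema and guaranteed occurrences of the
values 127 (glucose), 26.4 (BMI) and 28 (age), so the canonical
rule-decryption example — protected thresholds 255, 53.8, 57 — can be
exercised end to end. It is synthetic; only its schema mirrors the
well-known screening dataset.

## Numerical and format choices

* Numerics are written (ARFF cells, lookup values, rule thresholds) in the
  shortest decimal form that parses back to the identical double, so `53.8`
  prints as `53.8` and round-trips exactly.
* The ARFF dialect covers `@relation`/`@attribute`/`@data`, `%` comments,
  quoted tokens, `numeric`/`real`/`integer`, declared nominal domains, and
  `string` (read as nominal with the observed domain, since string values
  are encrypted like any nominal). Date and sparse ARFF are rejected:
  neither participates in the protection scheme. The missing marker is the
  unquoted `?`. Parse errors carry line numbers.
* Ciphertext tokens are base64 and therefore quoted on ARFF output (they
  contain `/`, `+`, `=`); the writer quotes any token containing characters
  outside `[A-Za-z0-9_.-]`.
* Threshold comparison in `trees_equivalent()` uses an absolute tolerance
  of `1e-9`: transforms are exact on the worked decimal examples, but
  general affine maps accumulate one or two ulps.
* Degenerate inputs: an empty test partition, a training set with no
  labeled rows, non-positive transform scales, and malformed stores all
  fail loudly rather than degrade; an all-zero difference vector yields the
  null bootstrap result ($se = 0$, $p = 1$) by convention rather than
  resampling a constant.

## Open design decisions, resolved

* **Per-attribute keys.** Identical tokens in different columns encrypt
  differently. Induction never compares across columns, so this costs
  nothing and removes cross-column linkage.
* **The class attribute is encrypted like any nominal attribute** — the
  analyst learns tree structure and counts, not label semantics.
* **Generalized affine transform.** The scheme admits any
  order-preserving numeric map; the package exposes per-attribute $(a, b)$
  with $(2, 1)$ as the default rather than hard-coding the doubling map.
* **One session salt per protection run**, stored in the owner-side lookup
  store. Re-running with the same key and salt is byte-reproducible (the
  CLI exposes `--salt` for exactly this); a fresh salt per run prevents
  cross-run ciphertext linkage.
* **Missing markers are not encrypted.** Both inducers must see the same
  missingness to make the same decisions; the leaked pattern is accepted
  and documented above.
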