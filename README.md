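# privtree

Privacy-preserving decision-tree induction on encrypted tabular data.

Health-care providers often cannot hand clinical datasets to an outside
analyst: the records are protected health information, and exporting them in
plaintext is either forbidden or triggers heavy regulatory obligations.
`privtree` implements a protection scheme under which the analysis itself can
be outsourced: the data owner encrypts the file, the analyst induces a
decision tree on the *encrypted* file, and the owner decrypts the resulting
rules — obtaining the same tree that plaintext analysis would have produced.

The scheme rests on one observation: C4.5-style tree induction never looks at
what a value *is*, only at

* **equality** between nominal tokens (multiway splits, class counts), and
* **order** among numeric values within one attribute (threshold splits).

So any protection that preserves exactly those two relations leaves the
induced tree invariant. `privtree` protects a dataset `D` by

* replacing every attribute name and every nominal cell `v` with a
  **deterministic AES-256 ciphertext** `E_k(v)` under a per-attribute derived
  key (equal plaintexts ⇢ equal ciphertexts, so within-column equality is
  preserved; different columns use different keys, so nothing links across
  columns), and
* replacing every numeric cell `v` with a **strictly increasing affine
  transform** `T(v) = a·v + b`, `a > 0` (default `a = 2`, `b = 1`), which
  preserves the within-column order, hence every candidate threshold split.

The owner keeps a **lookup table** of every `(attribute, plaintext,
protected)` pair. Gain-ratio induction with pessimistic pruning (a J48-like
learner, included) then produces on the protected file a tree whose topology,
leaf counts and accuracy are identical to the plaintext tree, with numeric
thresholds related by `θ_protected = T(θ_original)`; rules such as

```
IF E(glucose) <= 255 AND E(bmi) > 53.8 AND E(age) <= 57 THEN E(class)
```

decrypt through the lookup table to

```
IF 2_hr_postload_plasma_glucose <= 127 AND body_mass_idx > 26.4 AND age <= 28
THEN tested_negative
```

The package also ships the paired statistical machinery used to compare
original-versus-protected runs across a corpus of datasets (paired summary
statistics and a bootstrapped paired test of zero mean difference), a
synthetic mixed-type data generator with planted decision structure, and a
command-line interface (`inst/scripts/privtree`) covering the
protect → induce → decrypt-rules → compare workflow.

## Worked example

```r
library(privtree)

toy <- pima_schema_toy()                # 40-row synthetic diabetes-schema data
cfg <- protection_config(
  master_key   = strrep("ab", 32),      # 256-bit key (hex); owner-side secret
  session_salt = as.raw(1:16)
)
bundle <- protect_dataset(toy, cfg)
bundle
#> <protected_bundle> 40 rows x 9 attributes protected; lookup: 9 attribute
#>   renames, 243 value mappings

split   <- train_test_split(toy, 0.66, seed = 1)
split_p <- train_test_split(bundle$protected, 0.66, seed = 1)
fit   <- induce(split$train)            # plaintext tree (owner's reference)
fit_p <- induce(split_p$train)          # what the analyst computes
fit
#> body_mass_idx <= 26.4: tested_positive (13/0)
#> body_mass_idx > 26.4
#> |   body_mass_idx <= 29.4: tested_negative (2/0)
#> |   body_mass_idx > 29.4
#> |   |   body_mass_idx <= 40.6
#> |   |   |   2_hr_postload_plasma_glucose <= 107: tested_negative (3/1)
#> |   |   |   2_hr_postload_plasma_glucose > 107: tested_positive (7/0)
#> |   |   body_mass_idx > 40.6: tested_negative (2/0)
#>
#> Number of Leaves  : 5
#> Size of the tree : 9

evaluate(fit,   split$test)             # 84.62
evaluate(fit_p, split_p$test)           # 84.62  — identical on both sides
trees_equivalent(fit, fit_p, bundle$lookup)
#> [1] TRUE
```

The analyst's tree splits on ciphertext names with transformed thresholds
(its root tests `<= 53.8`, i.e. `2 * 26.4 + 1`); the owner decrypts its rules:

```r
decrypt_rules(extract_rules(fit_p), bundle$lookup)$text[1:2]
#> [1] "body_mass_idx <= 26.4 -> tested_positive"
#> [2] "body_mass_idx > 26.4 AND body_mass_idx <= 29.4 -> tested_negative"
```

A corpus-level comparison uses `compare_run()` per dataset and
`compare_report()` over the collected rows:

```r
rows <- dplyr::bind_rows(lapply(1:30, function(s) {
  d <- generate_dataset(generator_spec(seed = s))$dataset
  compare_run(d, cfg, inducer_config(), dataset_id = paste0("synthetic_", s))
}))
mean(rows$accuracy_orig == rows$accuracy_prot)   # 1: invariant on all 30
all(rows$equivalent)                             # TRUE
```

`tidy()`, `glance()` and `autoplot()` methods are provided for trees and
bootstrap results; `table1_fixture()` returns the packaged 30-dataset
reference metrics table, and `compare_report(table1_fixture())` reproduces
its published summary statistics (original-size mean 1118.1, SD 5432.1,
accuracy mean 0.763 as a proportion, paired size-difference mean −0.5).

## Limitations

* The protection hides values, not structure: row count, attribute count,
  missingness pattern, nominal cardinalities and numeric order (hence
  approximate distribution shape) remain visible. This is inherent to any
  scheme that keeps order-based analyses possible.
* Equal gain-ratio ties are resolved by attribute position by default, which
  makes induction invariant under renaming. The `attribute_name` tie-break
  mode reproduces the behaviour of name-sensitive learners, where an exact
  tie can make the encrypted run pick a different — equally accurate — tree.
* Free-text attributes are out of scope; cells must be numeric or
  categorical.
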