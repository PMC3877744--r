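#' Decide whether two trees are the same tree under protection
#'
#' Recursive label-mapped comparison with ordered children (`<=` branch
#' first for numeric splits, domain order for nominal splits): split
#' attributes must correspond under the attribute map, numeric thresholds
#' must satisfy `|transform(theta_orig) - theta_prot| <= tol`, nominal
#' branch tokens and leaf classes must correspond under the value map. On
#' failure the path to the first divergence is reported.
#'
#' @param orig Tree induced on the original data.
#' @param prot Tree induced on the protected data.
#' @param lk The [lookup_table()] of the protection run.
#' @param tol Absolute threshold tolerance (default `1e-9`; transforms are
#'   exact on decimal examples but accumulate float error in general).
#' @return `TRUE`, or `FALSE` carrying a `divergence` attribute with the
#'   path to the first mismatch.
#' @export
trees_equivalent <- function(orig, prot, lk, tol = 1e-9) {
  stopifnot(
    inherits(orig, "c45_tree"), inherits(prot, "c45_tree"),
    inherits(lk, "lookup_table")
  )
  diverge <- function(path, why) {
    structure(FALSE, divergence = sprintf("%s: %s", path, why))
  }
  map_token <- function(attribute, token) {
    as.character(original_value_for(lk, attribute, token))
  }
  walk <- function(a, b, path) {
    if (a$kind != b$kind) {
      return(diverge(path, sprintf("node kind %s vs %s", a$kind, b$kind)))
    }
    if (a$kind == "leaf") {
      prot_class <- map_token(
        original_attribute_for(lk, prot$schema$name[[prot$class_index]]),
        b$class
      )
      if (!identical(a$class, prot_class)) {
        return(diverge(path, sprintf(
          "leaf class %s vs %s (decrypted)", a$class, prot_class
        )))
      }
      return(TRUE)
    }
    prot_attr <- original_attribute_for(lk, b$attribute)
    if (!identical(a$attribute, prot_attr)) {
      return(diverge(path, sprintf(
        "split attribute %s vs %s (decrypted)", a$attribute, prot_attr
      )))
    }
    if (length(a$children) != length(b$children)) {
      return(diverge(path, "different branch counts"))
    }
    if (a$kind == "numeric") {
      cc <- lk$coeffs[lk$coeffs$attribute_name == a$attribute, ]
      if (nrow(cc) != 1L) {
        lookup_miss(sprintf("no coefficients for attribute '%s'", a$attribute))
      }
      expected <- transform_numeric(a$threshold, cc$a[[1]], cc$b[[1]])
      if (abs(expected - b$threshold) > tol) {
        return(diverge(path, sprintf(
          "threshold %s maps to %s but protected tree has %s",
          fmt_num(a$threshold), fmt_num(expected), fmt_num(b$threshold)
        )))
      }
    } else {
      mapped <- vapply(b$branch_tokens, map_token,
        character(1),
        attribute = a$attribute
      )
      if (!identical(unname(mapped), a$branch_tokens)) {
        return(diverge(path, "nominal branch tokens do not correspond"))
      }
    }
    for (i in seq_along(a$children)) {
      res <- walk(
        a$children[[i]], b$children[[i]],
        sprintf("%s/%s[%d]", path, a$attribute, i)
      )
      if (!isTRUE(res)) {
        return(res)
      }
    }
    TRUE
  }
  walk(orig$root, prot$root, "root")
}

#' Run the full original-versus-protected comparison on one dataset
#'
#' The per-dataset experiment: protect the dataset, apply the identical
#' seeded train/test split and inducer configuration to both the plaintext
#' and the protected file, measure tree size, leaf count and held-out
#' accuracy on each side, and check structural equivalence of the two
#' trees under the protection mapping.
#'
#' @param d A [ptd_dataset][as_dataset] or coercible data frame.
#' @param pcfg A [protection_config()].
#' @param icfg An [inducer_config()].
#' @param dataset_id Label for the output row.
#' @return A one-row tibble: `dataset_id`, `size_orig`, `leaves_orig`,
#'   `accuracy_orig`, `size_prot`, `leaves_prot`, `accuracy_prot`,
#'   `equivalent`, `divergence`.
#' @examples
#' spec <- generator_spec(n_rows = 80, seed = 11)
#' d <- generate_dataset(spec)$dataset
#' compare_run(d, protection_config(strrep("aa", 32)), inducer_config())
#' @export
compare_run <- function(d, pcfg = protection_config(),
                        icfg = inducer_config(), dataset_id = NULL) {
  d <- as_dataset(d)
  dataset_id <- dataset_id %||% d$relation
  bundle <- protect_dataset(d, pcfg)

  split_o <- train_test_split(d, icfg$train_fraction, icfg$seed)
  split_p <- train_test_split(
    bundle$protected, icfg$train_fraction, icfg$seed
  )
  stopifnot(identical(split_o$train_idx, split_p$train_idx))

  tree_o <- induce(split_o$train, icfg)
  tree_p <- induce(split_p$train, icfg)
  m_o <- tree_metrics(tree_o)
  m_p <- tree_metrics(tree_p)
  verdict <- trees_equivalent(tree_o, tree_p, bundle$lookup)

  tibble(
    dataset_id = dataset_id,
    size_orig = m_o$size, leaves_orig = m_o$leaves,
    accuracy_orig = evaluate(tree_o, split_o$test),
    size_prot = m_p$size, leaves_prot = m_p$leaves,
    accuracy_prot = evaluate(tree_p, split_p$test),
    equivalent = isTRUE(verdict),
    divergence = attr(verdict, "divergence") %||% NA_character_
  )
}
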