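#' Inducer configuration
#'
#' Settings of the C4.5-style gain-ratio tree learner. Defaults mirror the
#' conventional J48 surface: at least 2 instances per leaf, pruning
#' confidence 0.25, a 66% training split, seed 1. `tie_break` decides which
#' attribute wins when several candidate splits have exactly equal gain
#' ratio: `"attribute_index"` (column position, the default) makes induction
#' invariant under attribute renaming — and hence under encryption of
#' attribute names — while `"attribute_name"` (lexicographic) reproduces the
#' name-sensitive behaviour that can make an encrypted run choose a
#' different but equally accurate tree.
#'
#' @param min_leaf Minimum training instances per leaf (>= 1).
#' @param confidence Pruning confidence factor in (0, 0.5].
#' @param train_fraction Fraction of rows used for training, in (0, 1).
#' @param seed Integer RNG seed for the train/test shuffle.
#' @param tie_break `"attribute_index"` or `"attribute_name"`.
#' @param prune Logical; set `FALSE` to grow the unpruned tree.
#' @return An object of class `inducer_config`.
#' @export
inducer_config <- function(min_leaf = 2L, confidence = 0.25,
                           train_fraction = 0.66, seed = 1L,
                           tie_break = c("attribute_index", "attribute_name"),
                           prune = TRUE) {
  tie_break <- match.arg(tie_break)
  if (min_leaf < 1L) abort("min_leaf must be >= 1")
  if (!(confidence > 0 && confidence <= 0.5)) {
    abort("confidence must lie in (0, 0.5]")
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("train_fraction must lie in (0, 1)")
  }
  structure(
    list(
      min_leaf = as.integer(min_leaf), confidence = confidence,
      train_fraction = train_fraction, seed = as.integer(seed),
      tie_break = tie_break, prune = isTRUE(prune)
    ),
    class = "inducer_config"
  )
}

#' Seeded percentage split into training and test sets
#'
#' Shuffles the row indices with a seeded RNG and assigns the first
#' `ceiling(fraction * n)` rows to training, the rest to testing. The
#' partition depends only on the row count and the seed — never on cell
#' values — so a dataset and its protected image receive the identical row
#' partition.
#'
#' @param d A [ptd_dataset][as_dataset] or coercible data frame.
#' @param fraction Training fraction in (0, 1); default 0.66.
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (both `ptd_dataset`) and
#'   `train_idx` / `test_idx` (the row index partition).
#' @export
train_test_split <- function(d, fraction = 0.66, seed = 1L) {
  d <- as_dataset(d)
  n <- nrow(d$data)
  if (n < 2L) abort("need at least 2 rows to split")
  if (!(fraction > 0 && fraction < 1)) abort("fraction must lie in (0, 1)")
  perm <- with_preserved_rng(seed, sample.int(n))
  n_train <- ceiling(fraction * n)
  if (n_train >= n) abort("split leaves an empty test partition")
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[seq(n_train + 1L, n)])
  list(
    train = subset_rows(d, train_idx),
    test = subset_rows(d, test_idx),
    train_idx = train_idx, test_idx = test_idx
  )
}

subset_rows <- function(d, idx) {
  out <- d
  out$data <- d$data[idx, , drop = FALSE]
  out
}

# runs `code` under a fixed seed without disturbing the caller's RNG stream
with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Shannon entropy of class counts
#'
#' @param class_counts Nonnegative counts, at least one positive.
#' @return Entropy in bits, with the convention `0 * log2(0) = 0`.
#' @examples
#' entropy(c(2, 2)) # 1
#' entropy(c(3, 1)) # 0.8112781
#' @export
entropy <- function(class_counts) {
  if (anyNA(class_counts) || any(class_counts < 0)) {
    abort("class counts must be nonnegative")
  }
  n <- sum(class_counts)
  if (n <= 0) abort("at least one class count must be positive")
  p <- class_counts[class_counts > 0] / n
  -sum(p * log2(p))
}

# entropy from a counts vector, tolerating the all-zero case (returns 0)
entropy0 <- function(counts) {
  n <- sum(counts)
  if (n <= 0) {
    return(0)
  }
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# internal frame: columns pre-coded for fast recursive partitioning
make_frame <- function(d) {
  y_raw <- d$data[[d$class_index]]
  keep <- which(!is.na(y_raw)) # rows without a class label cannot train
  class_domain <- d$schema$domain[[d$class_index]]
  attrs <- list()
  for (j in seq_len(nrow(d$schema))) {
    if (j == d$class_index) next
    col <- d$data[[j]][keep]
    if (d$schema$kind[[j]] == "nominal") {
      col <- match(col, d$schema$domain[[j]])
    }
    attrs[[length(attrs) + 1L]] <- list(
      index = j, name = d$schema$name[[j]], kind = d$schema$kind[[j]],
      domain = d$schema$domain[[j]], x = col
    )
  }
  list(
    y = match(y_raw[keep], class_domain),
    k = length(class_domain),
    class_domain = class_domain,
    attrs = attrs,
    n = length(keep)
  )
}

# best admissible split of `idx` on one pre-coded attribute, or NULL;
# gain is scaled by the observed (non-missing) fraction, split information
# is computed over the known-value branch proportions
best_split_coded <- function(frame, attr, idx, min_leaf) {
  x <- attr$x[idx]
  known <- !is.na(x)
  nk <- sum(known)
  n <- length(idx)
  if (nk < 2L * min_leaf) {
    return(NULL)
  }
  yk <- frame$y[idx][known]
  xk <- x[known]
  base <- entropy0(tabulate(yk, frame$k))

  if (attr$kind == "numeric") {
    ord <- order(xk)
    xs <- xk[ord]
    ys <- yk[ord]
    onehot <- matrix(0L, nk, frame$k)
    onehot[cbind(seq_len(nk), ys)] <- 1L
    cum <- apply(onehot, 2, cumsum)
    if (frame$k == 1L) cum <- matrix(cum, ncol = 1L)
    cuts <- which(xs[-nk] < xs[-1L]) # boundaries between distinct values
    cuts <- cuts[cuts >= min_leaf & (nk - cuts) >= min_leaf]
    if (length(cuts) == 0L) {
      return(NULL)
    }
    left <- cum[cuts, , drop = FALSE]
    tot <- cum[nk, ]
    right <- sweep(left, 2, tot, function(l, t) t - l)
    nl <- rowSums(left)
    nr <- nk - nl
    h <- function(m, nn) {
      p <- m / nn
      rowSums(ifelse(p > 0, -p * log2(p), 0))
    }
    cond <- (nl / nk) * h(left, nl) + (nr / nk) * h(right, nr)
    gain <- (nk / n) * (base - cond)
    best <- which.max(gain) # ties: lowest threshold wins (first index)
    if (gain[[best]] <= 1e-12) {
      return(NULL)
    }
    pl <- nl[[best]] / nk
    si <- entropy0(c(nl[[best]], nr[[best]]))
    list(
      kind = "numeric", attribute = attr$name, attr_index = attr$index,
      threshold = xs[[cuts[[best]]]], # largest observed value <= the midpoint
      gain = gain[[best]], split_info = si,
      gain_ratio = if (si > 0) gain[[best]] / si else Inf
    )
  } else {
    counts <- matrix(0L, length(attr$domain), frame$k)
    tab <- table(
      factor(xk, levels = seq_along(attr$domain)),
      factor(yk, levels = seq_len(frame$k))
    )
    counts[] <- as.integer(tab)
    nb <- rowSums(counts)
    if (sum(nb > 0L) < 2L || sum(nb >= min_leaf) < 2L) {
      return(NULL)
    }
    cond <- sum(vapply(seq_len(nrow(counts)), function(b) {
      if (nb[[b]] == 0L) 0 else (nb[[b]] / nk) * entropy0(counts[b, ])
    }, numeric(1)))
    gain <- (nk / n) * (base - cond)
    if (gain <= 1e-12) {
      return(NULL)
    }
    si <- entropy0(nb)
    list(
      kind = "nominal", attribute = attr$name, attr_index = attr$index,
      gain = gain, split_info = si,
      gain_ratio = if (si > 0) gain / si else Inf
    )
  }
}

#' Evaluate the best candidate split for one attribute
#'
#' For a numeric attribute, evaluates every boundary between consecutive
#' distinct sorted values, picks the information-gain-maximizing cut, and
#' reports the threshold snapped to the largest observed value not
#' exceeding the optimal midpoint — so thresholds are always observed
#' training values and decrypt exactly through the lookup table. For a
#' nominal attribute, the candidate is the multiway partition by domain
#' token. Returns `NULL` when no admissible split has positive gain or the
#' instance floor is violated.
#'
#' @param train A [ptd_dataset][as_dataset] or coercible data frame.
#' @param attribute Attribute name (must not be the class attribute).
#' @param min_leaf Minimum instances per branch side.
#' @return A list with `kind`, `gain`, `split_info`, `gain_ratio` and (for
#'   numeric attributes) `threshold`, or `NULL`.
#' @export
best_split <- function(train, attribute, min_leaf = 2L) {
  d <- as_dataset(train)
  frame <- make_frame(d)
  hit <- purrr::detect(frame$attrs, ~ .x$name == attribute)
  if (is.null(hit)) {
    abort(sprintf("'%s' is not a non-class attribute", attribute))
  }
  best_split_coded(frame, hit, seq_len(frame$n), as.integer(min_leaf))
}

# C4.5 pessimistic error: upper confidence bound on the binomial error
# rate at confidence `cf` (normal approximation), times the leaf mass
pessimistic_errors <- function(n, e, cf) {
  if (n == 0) {
    return(0)
  }
  z <- qnorm(1 - cf)
  f <- e / n
  ub <- (f + z^2 / (2 * n) + z * sqrt(f * (1 - f) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  n * ub
}

grow_node <- function(frame, idx, cfg, parent_majority = 1L) {
  counts <- tabulate(frame$y[idx], frame$k)
  n <- length(idx)
  majority <- if (n == 0L) parent_majority else which.max(counts)
  make_leaf <- function() {
    list(
      kind = "leaf", counts = counts, n = n,
      class = frame$class_domain[[majority]], class_idx = majority
    )
  }
  if (n < 2L * cfg$min_leaf || sum(counts > 0L) <= 1L) {
    return(make_leaf())
  }

  attrs <- frame$attrs
  if (cfg$tie_break == "attribute_name") {
    attrs <- attrs[order(vapply(attrs, `[[`, "", "name"), method = "radix")]
  }
  best <- NULL
  for (attr in attrs) {
    cand <- best_split_coded(frame, attr, idx, cfg$min_leaf)
    if (!is.null(cand) &&
      (is.null(best) || cand$gain_ratio > best$gain_ratio)) {
      best <- cand # ties keep the earlier attribute in scan order
    }
  }
  if (is.null(best)) {
    return(make_leaf())
  }

  attr <- purrr::detect(frame$attrs, ~ .x$index == best$attr_index)
  x <- attr$x[idx]
  if (best$kind == "numeric") {
    groups <- list(idx[!is.na(x) & x <= best$threshold],
                   idx[!is.na(x) & x > best$threshold])
    branch_tokens <- NULL
  } else {
    groups <- lapply(seq_along(attr$domain), function(b) idx[!is.na(x) & x == b])
    branch_tokens <- attr$domain
  }
  mass <- lengths(groups)
  # missing split values go down the branch with the larger training mass
  miss <- idx[is.na(x)]
  if (length(miss) > 0L) {
    groups[[which.max(mass)]] <- c(groups[[which.max(mass)]], miss)
  }
  children <- lapply(groups, grow_node, frame = frame, cfg = cfg,
                     parent_majority = majority)
  list(
    kind = best$kind, counts = counts, n = n,
    class = frame$class_domain[[majority]], class_idx = majority,
    attribute = best$attribute, attr_index = best$attr_index,
    threshold = best$threshold, branch_tokens = branch_tokens,
    branch_mass = mass, children = children
  )
}

prune_node <- function(node, cf) {
  if (node$kind == "leaf") {
    return(node)
  }
  node$children <- lapply(node$children, prune_node, cf = cf)
  subtree_err <- sum(vapply(node$children, subtree_errors, numeric(1), cf = cf))
  leaf_err <- pessimistic_errors(node$n, node$n - max(node$counts), cf)
  if (leaf_err <= subtree_err + 1e-9) {
    return(list(
      kind = "leaf", counts = node$counts, n = node$n,
      class = node$class, class_idx = node$class_idx
    ))
  }
  node
}

subtree_errors <- function(node, cf) {
  if (node$kind == "leaf") {
    e <- if (node$n == 0L) 0 else node$n - max(node$counts)
    return(pessimistic_errors(node$n, e, cf))
  }
  sum(vapply(node$children, subtree_errors, numeric(1), cf = cf))
}

#' Induce a C4.5-style decision tree
#'
#' Recursive top-down growth: at each node the admissible candidate split
#' (positive information gain, instance floor respected) with the maximal
#' gain ratio is chosen, ties resolved by the configured tie-break; leaves
#' form on purity, the instance floor, or when no admissible split remains.
#' The grown tree is post-pruned by pessimistic-error subtree replacement
#' at the configured confidence. Induction is fully deterministic given
#' the training data and configuration, and all split decisions depend
#' only on class counts, value order, and token equality — the invariants
#' the protection transform preserves.
#'
#' @param train A [ptd_dataset][as_dataset] or coercible data frame; rows
#'   with a missing class label are ignored.
#' @param cfg An [inducer_config()].
#' @return An object of class `c45_tree`.
#' @examples
#' d <- as_dataset(data.frame(
#'   x = c(1, 2, 3, 4), cls = c("a", "a", "b", "b")
#' ))
#' fit <- induce(d, inducer_config(min_leaf = 1, prune = FALSE))
#' glance(fit)
#' @export
induce <- function(train, cfg = inducer_config()) {
  d <- as_dataset(train)
  stopifnot(inherits(cfg, "inducer_config"))
  frame <- make_frame(d)
  if (frame$n < 1L) abort("training data has no rows with a class label")
  root <- grow_node(frame, seq_len(frame$n), cfg)
  if (cfg$prune) {
    root <- prune_node(root, cfg$confidence)
  }
  structure(
    list(
      root = root, schema = d$schema, class_index = d$class_index,
      class_domain = frame$class_domain, config = cfg
    ),
    class = "c45_tree"
  )
}

# routes one row (a list of cells in schema order) to a leaf
route_row <- function(node, cells) {
  while (node$kind != "leaf") {
    v <- cells[[node$attr_index]]
    child <- if (node$kind == "numeric") {
      if (is.na(v)) {
        which.max(node$branch_mass)
      } else if (v <= node$threshold) 1L else 2L
    } else {
      b <- if (is.na(v)) NA_integer_ else match(v, node$branch_tokens)
      if (is.na(b)) which.max(node$branch_mass) else b
    }
    node <- node$children[[child]]
  }
  node
}

#' Classify rows with an induced tree
#'
#' @param object A `c45_tree`.
#' @param newdata A [ptd_dataset][as_dataset] or coercible data frame with
#'   the training schema. Missing split values are routed down the branch
#'   that carried the larger training mass.
#' @param ... Unused.
#' @return Character vector of predicted class tokens.
#' @export
predict.c45_tree <- function(object, newdata, ...) {
  d <- as_dataset(newdata)
  if (!identical(d$schema$name, object$schema$name)) {
    abort("newdata schema does not match the training schema")
  }
  vapply(seq_len(nrow(d$data)), function(i) {
    route_row(object$root, lapply(d$data, `[[`, i))$class
  }, character(1))
}

#' Held-out accuracy of a tree
#'
#' Routes every test row to a leaf and returns the percentage of correctly
#' classified instances, rounded to 2 decimals for reporting. Rows with a
#' missing class label are excluded from the denominator.
#'
#' @param t A `c45_tree`.
#' @param test A [ptd_dataset][as_dataset] with the training schema.
#' @return Accuracy in percent (0–100).
#' @export
evaluate <- function(t, test) {
  stopifnot(inherits(t, "c45_tree"))
  d <- as_dataset(test)
  truth <- d$data[[t$class_index]]
  keep <- !is.na(truth)
  if (!any(keep)) abort("test data has no rows with a class label")
  pred <- predict(t, subset_rows(d, which(keep)))
  round(100 * mean(pred == truth[keep]), 2)
}

#' Size and leaf count of a tree
#'
#' The tree size is the total node count; the number of leaves equals the
#' number of decision rules the tree encodes.
#'
#' @param t A `c45_tree`.
#' @return A tibble with columns `size` and `leaves`.
#' @export
tree_metrics <- function(t) {
  stopifnot(inherits(t, "c45_tree"))
  count <- function(node) {
    if (node$kind == "leaf") {
      return(c(size = 1L, leaves = 1L))
    }
    kids <- vapply(node$children, count, c(size = 0L, leaves = 0L))
    c(size = 1L + sum(kids["size", ]), leaves = sum(kids["leaves", ]))
  }
  res <- count(t$root)
  tibble(size = res[["size"]], leaves = res[["leaves"]])
}
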