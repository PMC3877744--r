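# Shared fixtures and independent oracles used across the suite.

fixed_key <- function() strrep("ab", 32)

fixed_cfg <- function(...) {
  protection_config(
    master_key = fixed_key(), session_salt = as.raw(1:16), ...
  )
}

# small mixed-type dataset with one missing cell per kind
toy_mixed <- function() {
  as_dataset(
    data.frame(
      glucose = c(127, 90, NA, 155, 110, 170),
      age = c(28, 45, 33, NA, 51, 24),
      smoker = c("yes", "no", "yes", NA, "no", "no"),
      cls = c("neg", "neg", "pos", "pos", "neg", "pos"),
      stringsAsFactors = FALSE
    ),
    relation = "toy_mixed"
  )
}

# reference tree builder used as the induction oracle: exhaustive recursive
# search over all (attribute, observed-value threshold) binary splits,
# choosing the split by direct enumeration of the class partitions it
# produces (maximal information gain, computed from first principles),
# growing to purity; numeric attributes only, no missing values
oracle_grow <- function(x, y) {
  ent <- function(labels) {
    p <- table(labels) / length(labels)
    -sum(p * log2(p))
  }
  if (length(unique(y)) == 1L) {
    return(list(kind = "leaf", class = y[[1]]))
  }
  best <- NULL
  for (j in seq_len(ncol(x))) {
    for (thr in sort(unique(x[[j]]))) {
      left <- x[[j]] <= thr
      if (!any(left) || all(left)) next
      gain <- ent(y) -
        mean(left) * ent(y[left]) - mean(!left) * ent(y[!left])
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(j = j, thr = thr, gain = gain)
      }
    }
  }
  if (is.null(best) || best$gain <= 1e-12) {
    tab <- table(y)
    return(list(kind = "leaf", class = names(tab)[[which.max(tab)]]))
  }
  left <- x[[best$j]] <= best$thr
  list(
    kind = "split", j = best$j, thr = best$thr,
    left = oracle_grow(x[left, , drop = FALSE], y[left]),
    right = oracle_grow(x[!left, , drop = FALSE], y[!left])
  )
}

oracle_predict <- function(node, x) {
  vapply(seq_len(nrow(x)), function(i) {
    nd <- node
    while (nd$kind != "leaf") {
      nd <- if (x[[nd$j]][[i]] <= nd$thr) nd$left else nd$right
    }
    nd$class
  }, character(1))
}

# brute-force single-split oracle: best information-gain binary cut of a
# numeric column, evaluated by direct enumeration over observed thresholds
oracle_best_cut <- function(x, y) {
  ent <- function(labels) {
    p <- table(labels) / length(labels)
    -sum(p * log2(p))
  }
  best <- NULL
  for (thr in sort(unique(x))) {
    left <- x <= thr
    if (!any(left) || all(left)) next
    gain <- ent(y) - mean(left) * ent(y[left]) - mean(!left) * ent(y[!left])
    if (is.null(best) || gain > best$gain + 1e-12) {
      best <- list(thr = thr, gain = gain)
    }
  }
  best
}

# exhaustive bootstrap distribution for tiny n: every one of the n^n
# equally likely resamples of the differences
enumerate_bootstrap_means <- function(diffs) {
  n <- length(diffs)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  apply(grid, 1, function(idx) mean(diffs[idx]))
}
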