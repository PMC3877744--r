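test_that("entropy follows the Shannon definition", {
  expect_equal(entropy(c(2, 2)), 1)
  expect_equal(entropy(c(4, 0)), 0)
  expect_equal(entropy(c(3, 1)), 0.811278, tolerance = 1e-6)
  expect_error(entropy(c(0, 0)), "positive")
  expect_error(entropy(c(-1, 2)), "nonnegative")
})

test_that("the seeded percentage split is deterministic and value-blind", {
  d <- generate_dataset(generator_spec(n_rows = 100, seed = 5))$dataset
  s1 <- train_test_split(d, 0.66, seed = 3)
  expect_equal(nrow(s1$train$data), 66L)
  expect_equal(nrow(s1$test$data), 34L)
  s2 <- train_test_split(d, 0.66, seed = 3)
  expect_identical(s1$train_idx, s2$train_idx)

  prot <- protect_dataset(d, fixed_cfg())$protected
  sp <- train_test_split(prot, 0.66, seed = 3)
  expect_identical(s1$train_idx, sp$train_idx)
  expect_identical(s1$test_idx, sp$test_idx)
})

test_that("best numeric cut maximizes gain with the threshold snapped down", {
  d <- as_dataset(
    data.frame(
      x = c(1, 2, 3, 4), cls = c("A", "A", "B", "B"),
      stringsAsFactors = FALSE
    )
  )
  cand <- best_split(d, "x", min_leaf = 1)
  expect_equal(cand$threshold, 2)
  expect_equal(cand$gain, 1)

  # the protected image of the same column yields the transformed threshold
  dp <- as_dataset(
    data.frame(
      x = 2 * c(1, 2, 3, 4) + 1, cls = c("A", "A", "B", "B"),
      stringsAsFactors = FALSE
    )
  )
  candp <- best_split(dp, "x", min_leaf = 1)
  expect_equal(candp$threshold, 5)
  expect_equal(candp$gain, cand$gain)

  # a pure node offers no admissible split
  pure <- as_dataset(
    data.frame(x = 1:4, cls = rep("A", 4), stringsAsFactors = FALSE),
    schema = dplyr::bind_rows(
      attribute_spec("x", "numeric"),
      attribute_spec("cls", "nominal", c("A", "B"))
    )
  )
  expect_null(best_split(pure, "x", min_leaf = 1))
})

test_that("best_split agrees with brute-force enumeration on small inputs", {
  withr::local_seed(11)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    x <- round(runif(n, 0, 10), 1)
    y <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(y)) < 2L || length(unique(x)) < 2L) next
    d <- as_dataset(
      data.frame(x = x, cls = y, stringsAsFactors = FALSE),
      schema = dplyr::bind_rows(
        attribute_spec("x", "numeric"),
        attribute_spec("cls", "nominal", c("A", "B"))
      )
    )
    ours <- best_split(d, "x", min_leaf = 1)
    ref <- oracle_best_cut(x, y)
    if (is.null(ref) || ref$gain <= 1e-12) {
      expect_null(ours)
    } else {
      expect_equal(ours$threshold, ref$thr)
      expect_equal(ours$gain, ref$gain, tolerance = 1e-12)
    }
  }
})

test_that("induction handles pure data, perfect separators and ties", {
  pure <- as_dataset(
    data.frame(x = 1:6, cls = rep("A", 6), stringsAsFactors = FALSE),
    schema = dplyr::bind_rows(
      attribute_spec("x", "numeric"),
      attribute_spec("cls", "nominal", c("A", "B"))
    )
  )
  fit <- induce(pure)
  expect_equal(tree_metrics(fit), tibble::tibble(size = 1L, leaves = 1L))

  sep <- as_dataset(
    data.frame(
      x = c(1, 2, 3, 4), cls = c("A", "A", "B", "B"),
      stringsAsFactors = FALSE
    )
  )
  fit2 <- induce(sep, inducer_config(min_leaf = 1, prune = FALSE))
  m <- tree_metrics(fit2)
  expect_equal(m$size, 3L)
  expect_equal(m$leaves, 2L)
  expect_equal(fit2$root$attribute, "x")
  expect_equal(evaluate(fit2, sep), 100)

  # two byte-identical columns: index tie-breaking picks the first
  dup <- as_dataset(
    data.frame(
      zz_first = c(1, 2, 3, 4), aa_second = c(1, 2, 3, 4),
      cls = c("A", "A", "B", "B"), stringsAsFactors = FALSE
    )
  )
  fit3 <- induce(dup, inducer_config(min_leaf = 1, prune = FALSE))
  expect_equal(fit3$root$attribute, "zz_first")
  fit4 <- induce(
    dup, inducer_config(min_leaf = 1, prune = FALSE, tie_break = "attribute_name")
  )
  expect_equal(fit4$root$attribute, "aa_second")
})

test_that("evaluation reports percent correct to two decimals", {
  leaf_data <- as_dataset(
    data.frame(x = c(1, 2), cls = c("A", "A"), stringsAsFactors = FALSE),
    schema = dplyr::bind_rows(
      attribute_spec("x", "numeric"),
      attribute_spec("cls", "nominal", c("A", "B"))
    )
  )
  fit <- induce(leaf_data)
  all_a <- leaf_data
  expect_equal(evaluate(fit, all_a), 100)
  half <- as_dataset(
    data.frame(
      x = c(1, 2), cls = c("A", "B"), stringsAsFactors = FALSE
    ),
    schema = dataset_schema(leaf_data)
  )
  expect_equal(evaluate(fit, half), 50)
  third <- as_dataset(
    data.frame(
      x = c(1, 2, 3), cls = c("A", "B", "B"), stringsAsFactors = FALSE
    ),
    schema = dataset_schema(leaf_data)
  )
  expect_equal(evaluate(fit, third), 33.33)
})

test_that("training predictions match the exhaustive-search reference", {
  withr::local_seed(23)
  for (rep in 1:20) {
    n <- 6
    x <- data.frame(
      a = round(runif(n, 0, 10), 2), b = round(runif(n, 0, 10), 2),
      c = round(runif(n, 0, 10), 2)
    )
    y <- sample(c("p", "q"), n, replace = TRUE)
    # skip degenerate draws the oracle cannot separate
    if (anyDuplicated(x) || length(unique(y)) < 2L) next
    d <- as_dataset(
      cbind(x, cls = y, stringsAsFactors = FALSE),
      schema = dplyr::bind_rows(
        attribute_spec("a", "numeric"), attribute_spec("b", "numeric"),
        attribute_spec("c", "numeric"),
        attribute_spec("cls", "nominal", c("p", "q"))
      )
    )
    fit <- induce(d, inducer_config(min_leaf = 1, prune = FALSE))
    ref <- oracle_grow(x, y)
    expect_identical(predict(fit, d), oracle_predict(ref, x))
    expect_identical(predict(fit, d), y) # both reach training purity
  }
})

test_that("rule extraction yields exactly one rule per leaf, root to leaf", {
  d <- generate_dataset(generator_spec(n_rows = 150, seed = 8))$dataset
  fit <- induce(train_test_split(d, seed = 1)$train)
  rules <- extract_rules(fit)
  expect_equal(nrow(rules), tree_metrics(fit)$leaves)
  expect_true(all(rules$class %in% fit$class_domain))
  # depth-ordered conjunctions: first condition uses the root attribute
  deep <- rules$rule[[which.max(vapply(
    rules$rule, function(r) nrow(r$conditions), integer(1)
  ))]]
  if (nrow(deep$conditions) > 0L) {
    expect_equal(deep$conditions$attribute[[1]], fit$root$attribute)
  }
})

test_that("induction is deterministic and serializes losslessly", {
  d <- generate_dataset(generator_spec(n_rows = 120, seed = 14))$dataset
  train <- train_test_split(d, seed = 2)$train
  f1 <- induce(train)
  f2 <- induce(train)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_tree(f1, p1)
  write_tree(f2, p2)
  expect_identical(readLines(p1), readLines(p2))

  back <- read_tree(p1)
  expect_identical(predict(back, d), predict(f1, d))
  expect_equal(tree_metrics(back), tree_metrics(f1))
})

test_that("any strictly increasing remap of a numeric column is immaterial", {
  d <- generate_dataset(generator_spec(n_rows = 150, seed = 17))$dataset
  warped <- d
  j <- 1L # numeric attribute
  warped$data[[j]] <- exp(warped$data[[j]] / 4) # strictly increasing, nonlinear
  split_o <- train_test_split(d, seed = 1)
  split_w <- train_test_split(warped, seed = 1)
  f_o <- induce(split_o$train)
  f_w <- induce(split_w$train)
  expect_equal(tree_metrics(f_w), tree_metrics(f_o))
  expect_equal(evaluate(f_w, split_w$test), evaluate(f_o, split_o$test))
  # thresholds on the warped attribute are the mapped original thresholds
  t_o <- tidy(f_o)
  t_w <- tidy(f_w)
  on_j <- which(!is.na(t_o$attribute) & t_o$attribute == d$schema$name[[j]])
  expect_equal(
    t_w$threshold[on_j], exp(t_o$threshold[on_j] / 4),
    tolerance = 1e-12
  )
})

test_that("pruning never enlarges the tree and handles missing values", {
  d <- generate_dataset(
    generator_spec(n_rows = 200, seed = 19, missing_rate = 0.1)
  )$dataset
  train <- train_test_split(d, seed = 1)$train
  full <- induce(train, inducer_config(prune = FALSE))
  pruned <- induce(train, inducer_config(prune = TRUE))
  expect_lte(tree_metrics(pruned)$size, tree_metrics(full)$size)
  # prediction tolerates missing values in every column
  test <- train_test_split(d, seed = 1)$test
  expect_true(all(predict(pruned, test) %in% pruned$class_domain))
})
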