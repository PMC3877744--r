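#' Specification for the synthetic mixed-type data generator
#'
#' The generator stands in for a corpus of real tabular classification
#' files: numeric attributes drawn from per-attribute two-component normal
#' mixtures (overlapping modes give non-degenerate split thresholds),
#' nominal attributes uniform over small token domains, and the class
#' assigned by a randomly constructed ground-truth decision tree over the
#' attributes, then corrupted by label noise and cell-wise missingness.
#'
#' @param n_rows Number of rows.
#' @param n_numeric,n_nominal Attribute counts.
#' @param nominal_domain_sizes Domain size per nominal attribute (recycled).
#' @param n_classes Number of class tokens.
#' @param planted_depth Maximum depth of the ground-truth rule tree; must
#'   not exceed the attribute count.
#' @param label_noise Probability a generated class label is flipped to a
#'   different class.
#' @param missing_rate Per-cell missingness probability (non-class cells).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_rows = 300L, n_numeric = 4L, n_nominal = 4L,
                           nominal_domain_sizes = 3L, n_classes = 2L,
                           planted_depth = 3L, label_noise = 0.05,
                           missing_rate = 0.02, seed = 1L) {
  if (n_rows < 1L || n_numeric < 0L || n_nominal < 0L || n_classes < 1L) {
    abort("counts must be positive")
  }
  if (n_numeric + n_nominal < 1L) abort("need at least one attribute")
  if (label_noise < 0 || label_noise > 1 || missing_rate < 0 ||
    missing_rate > 1) {
    abort("probabilities must lie in [0, 1]")
  }
  if (planted_depth < 0L) abort("planted_depth must be >= 0")
  if (planted_depth > n_numeric + n_nominal) {
    abort("planted_depth cannot exceed the attribute count")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_numeric = as.integer(n_numeric),
      n_nominal = as.integer(n_nominal),
      nominal_domain_sizes = rep_len(
        as.integer(nominal_domain_sizes),
        max(1L, n_nominal)
      ),
      n_classes = as.integer(n_classes),
      planted_depth = as.integer(planted_depth),
      label_noise = label_noise, missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
}

#' Generate a dataset with planted decision structure
#'
#' @param spec A [generator_spec()].
#' @return A list with `dataset` (a [ptd_dataset][as_dataset] whose class
#'   attribute is last) and `truth` (the planted rule tree as a `c45_tree`,
#'   usable with [predict.c45_tree()]).
#' @examples
#' out <- generate_dataset(generator_spec(n_rows = 50, seed = 7))
#' dim(out$dataset)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_preserved_rng(spec$seed, {
    n <- spec$n_rows
    classes <- paste0("class_", seq_len(spec$n_classes))

    num_names <- if (spec$n_numeric > 0L) {
      paste0("num_", seq_len(spec$n_numeric))
    } else {
      character(0)
    }
    nom_names <- if (spec$n_nominal > 0L) {
      paste0("cat_", seq_len(spec$n_nominal))
    } else {
      character(0)
    }

    # two-component normal mixture per numeric attribute
    num_params <- purrr::map(seq_len(spec$n_numeric), function(j) {
      list(
        mu = rnorm(2, 0, 2), sigma = runif(2, 0.5, 1.5)
      )
    })
    draw_numeric <- function(j, m) {
      comp <- sample.int(2L, m, replace = TRUE)
      rnorm(m, num_params[[j]]$mu[comp], num_params[[j]]$sigma[comp])
    }
    cols <- c(
      purrr::map(seq_len(spec$n_numeric), draw_numeric, m = n),
      purrr::map(seq_len(spec$n_nominal), function(j) {
        k <- spec$nominal_domain_sizes[[j]]
        sample(paste0("v", seq_len(k)), n, replace = TRUE)
      })
    )
    names(cols) <- c(num_names, nom_names)

    attrs <- c(
      purrr::map(num_names, attribute_spec, kind = "numeric"),
      purrr::map2(
        nom_names, spec$nominal_domain_sizes[seq_along(nom_names)],
        function(nm, k) attribute_spec(nm, "nominal", paste0("v", seq_len(k)))
      )
    )
    p <- length(attrs)

    # random ground-truth tree; attributes are not reused along a path
    plant <- function(depth, avail) {
      if (depth >= spec$planted_depth || length(avail) == 0L ||
        (depth > 0L && runif(1) < 0.25)) {
        return(list(
          kind = "leaf", counts = integer(spec$n_classes), n = 0L,
          class = sample(classes, 1L)
        ))
      }
      j <- avail[[sample.int(length(avail), 1L)]]
      spec_j <- attrs[[j]]
      rest <- setdiff(avail, j)
      if (spec_j$kind[[1]] == "numeric") {
        thr <- draw_numeric(j, 1L) # threshold drawn from the attribute's law
        children <- list(plant(depth + 1L, rest), plant(depth + 1L, rest))
        list(
          kind = "numeric", counts = integer(spec$n_classes), n = 0L,
          class = children[[1]]$class, attribute = spec_j$name[[1]],
          attr_index = j, threshold = thr, branch_mass = c(1L, 1L),
          children = children
        )
      } else {
        domain <- spec_j$domain[[1]]
        children <- purrr::map(domain, ~ plant(depth + 1L, rest))
        list(
          kind = "nominal", counts = integer(spec$n_classes), n = 0L,
          class = children[[1]]$class, attribute = spec_j$name[[1]],
          attr_index = j, branch_tokens = domain,
          branch_mass = rep(1L, length(domain)), children = children
        )
      }
    }
    truth_root <- plant(0L, seq_len(p))

    label <- vapply(seq_len(n), function(i) {
      route_row(truth_root, lapply(cols, `[[`, i))$class
    }, character(1))
    flip <- runif(n) < spec$label_noise
    if (any(flip) && spec$n_classes > 1L) {
      label[flip] <- vapply(label[flip], function(cl) {
        sample(setdiff(classes, cl), 1L)
      }, character(1))
    }

    # cell-wise missingness on the predictor columns only
    if (spec$missing_rate > 0) {
      for (j in seq_len(p)) {
        cols[[j]][runif(n) < spec$missing_rate] <- NA
      }
    }

    cols$class <- label
    schema <- dplyr::bind_rows(c(attrs, list(
      attribute_spec("class", "nominal", classes)
    )))
    dataset <- structure(
      list(
        relation = sprintf("synthetic_seed%d", spec$seed),
        schema = schema, class_index = p + 1L,
        data = as_tibble(cols)
      ),
      class = "ptd_dataset"
    )
    validate_dataset(dataset)

    truth <- structure(
      list(
        root = truth_root, schema = schema, class_index = p + 1L,
        class_domain = classes, config = inducer_config()
      ),
      class = "c45_tree"
    )
    list(dataset = dataset, truth = truth)
  })
}

#' Published per-dataset paired tree metrics (30 datasets)
#'
#' A packaged transcription of the reference experiment's per-dataset
#' results: tree size, leaf count and held-out accuracy (percent, 2
#' decimals) for trees induced on the original and on the protected
#' version of each of 30 public life-sciences classification datasets.
#' Accuracy is stored as printed percentages; [compare_report()] converts
#' to proportions.
#'
#' @return A 30-row tibble with columns `dataset_id`, `size_orig`,
#'   `leaves_orig`, `accuracy_orig`, `size_prot`, `leaves_prot`,
#'   `accuracy_prot`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_metrics.tsv", package = "privtree")
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  as_tibble(raw)
}

#' A small diabetes-screening-shaped toy dataset
#'
#' A seeded ~40-row synthetic dataset with the classic 8-attribute
#' diabetes screening schema (pregnancies, 2-hour postload plasma glucose,
#' blood pressure, skin fold, serum insulin, BMI, pedigree function, age)
#' and the class tokens `tested_negative` / `tested_positive`. The data
#' are synthetic; the schema and the guaranteed presence of the values
#' 127 (glucose), 26.4 (BMI) and 28 (age) exist so the canonical
#' rule-decryption example can be exercised end to end: under the default
#' `(2, 1)` transform those cells protect to 255, 53.8 and 57.
#'
#' @param n_rows Number of rows (>= 1; default 40).
#' @param seed Integer seed.
#' @return A [ptd_dataset][as_dataset].
#' @export
pima_schema_toy <- function(n_rows = 40L, seed = 42L) {
  stopifnot(n_rows >= 1L)
  with_preserved_rng(seed, {
    n <- n_rows
    d <- tibble(
      num_times_pregnant = as.double(sample(0:12, n, replace = TRUE)),
      `2_hr_postload_plasma_glucose` = round(runif(n, 60, 200)),
      diastolic_blood_pressure = round(runif(n, 40, 110)),
      triceps_skin_fold_thickness = round(runif(n, 5, 50)),
      `2_hr_serum_insulin` = round(runif(n, 0, 300)),
      body_mass_idx = round(runif(n, 18, 45), 1),
      diabetes_pedigree_fn = round(runif(n, 0.08, 1.5), 3),
      age = round(runif(n, 21, 70))
    )
    # pin the worked-example values into the first row
    d$`2_hr_postload_plasma_glucose`[[1]] <- 127
    d$body_mass_idx[[1]] <- 26.4
    d$age[[1]] <- 28
    cls <- ifelse(
      d$`2_hr_postload_plasma_glucose` <= 127 & d$body_mass_idx > 26.4,
      "tested_negative", "tested_positive"
    )
    flip <- runif(n) < 0.05
    cls[flip] <- ifelse(
      cls[flip] == "tested_negative", "tested_positive", "tested_negative"
    )
    d$Class <- cls
    schema <- dplyr::bind_rows(
      purrr::map(names(d)[1:8], attribute_spec, kind = "numeric"),
      attribute_spec("Class", "nominal", c("tested_negative", "tested_positive"))
    )
    as_dataset(d, relation = "diabetes_toy", schema = schema)
  })
}
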