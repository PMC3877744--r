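pima_bundle <- function() {
  protect_dataset(pima_schema_toy(), fixed_cfg())
}

test_that("attribute and value queries invert the protection maps", {
  bundle <- pima_bundle()
  lk <- bundle$lookup
  renamed <- lk$attribute_map$renamed_attribute[
    lk$attribute_map$original_attribute == "2_hr_postload_plasma_glucose"
  ]
  expect_equal(
    original_attribute_for(lk, renamed), "2_hr_postload_plasma_glucose"
  )
  expect_equal(
    original_value_for(lk, "2_hr_postload_plasma_glucose", 255), 127
  )
  expect_equal(original_value_for(lk, "age", 57), 28)
  expect_equal(original_value_for(lk, "body_mass_idx", 53.8), 26.4)

  # the class token decrypts like any nominal value
  ct <- lk$value_map$protected_value[
    lk$value_map$attribute_name == "Class" &
      lk$value_map$original_value == "tested_negative"
  ]
  expect_equal(original_value_for(lk, "Class", ct), "tested_negative")

  expect_error(
    original_attribute_for(lk, "never-issued"),
    class = "privtree_lookup_miss"
  )
  expect_error(
    original_value_for(lk, "no_such_attr", 1),
    class = "privtree_lookup_miss"
  )
})

test_that("numeric queries fall back to closed-form inversion", {
  bundle <- pima_bundle()
  # 999 was never observed, so it is absent from the value map
  expect_equal(original_value_for(bundle$lookup, "age", 999), (999 - 1) / 2)
})

test_that("queries on issued values are total inverses of protection", {
  d <- toy_mixed()
  bundle <- protect_dataset(d, fixed_cfg())
  lk <- bundle$lookup
  vm <- lk$value_map
  for (i in seq_len(nrow(vm))) {
    got <- original_value_for(
      lk, vm$attribute_name[[i]],
      if (vm$kind[[i]] == "numeric") {
        as.numeric(vm$protected_value[[i]])
      } else {
        vm$protected_value[[i]]
      }
    )
    if (vm$kind[[i]] == "numeric") {
      expect_equal(as.numeric(got), as.numeric(vm$original_value[[i]]))
    } else {
      expect_identical(got, vm$original_value[[i]])
    }
  }
})

test_that("decrypting rules from a protected tree recovers plaintext rules", {
  d <- pima_schema_toy(n_rows = 60)
  bundle <- protect_dataset(d, fixed_cfg())
  icfg <- inducer_config()
  tr_o <- induce(train_test_split(d, seed = 1)$train, icfg)
  tr_p <- induce(train_test_split(bundle$protected, seed = 1)$train, icfg)

  rules_o <- extract_rules(tr_o)
  rules_p <- decrypt_rules(extract_rules(tr_p), bundle$lookup)
  expect_equal(nrow(rules_p), nrow(rules_o))
  expect_equal(rules_p$text, rules_o$text)
})

test_that("a root-leaf rule decrypts to the same leaf with plaintext class", {
  d <- as_dataset(
    data.frame(x = c(1, 2), cls = c("a", "a"), stringsAsFactors = FALSE),
    schema = dplyr::bind_rows(
      attribute_spec("x", "numeric"),
      attribute_spec("cls", "nominal", c("a", "b"))
    )
  )
  bundle <- protect_dataset(d, fixed_cfg())
  fit <- induce(bundle$protected)
  rules <- decrypt_rules(extract_rules(fit), bundle$lookup)
  expect_equal(nrow(rules), 1L)
  expect_equal(nrow(rules$rule[[1]]$conditions), 0L)
  expect_equal(rules$class, "a")
})

test_that("rules containing unissued tokens fail with a named lookup miss", {
  bundle <- pima_bundle()
  fake <- privtree:::new_decision_rule(
    tibble::tibble(
      attribute = "bogus-token", op = "<=", value = "255", kind = "numeric"
    ),
    class = "x", class_attribute = "also-bogus"
  )
  expect_error(
    decrypt_rule(fake, bundle$lookup),
    "bogus-token",
    class = "privtree_lookup_miss"
  )
})

test_that("lookup persistence round-trips, including large tables", {
  d <- generate_dataset(generator_spec(n_rows = 400, seed = 21))$dataset
  lk <- protect_dataset(d, fixed_cfg())$lookup
  expect_gt(nrow(lk$value_map), 1000L) # distinct numerics dominate
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lookup(lk, path)
  back <- read_lookup(path)
  expect_equal(back$attribute_map, lk$attribute_map)
  expect_equal(
    dplyr::arrange(back$value_map, attribute_name, protected_value),
    dplyr::arrange(lk$value_map, attribute_name, protected_value)
  )
  expect_equal(back$coeffs, lk$coeffs)
  expect_identical(back$session_salt, lk$session_salt)

  # the stored header speaks the published relational schema
  expect_match(
    readLines(path)[sum(startsWith(readLines(path), "#")) + 1L],
    "renamed_attribute\toriginal_atribute\tattribute_name\tencrypted_value\toriginal_value",
    fixed = TRUE
  )
})

test_that("empty lookup tables survive persistence", {
  lk <- lookup_table(
    tibble::tibble(
      original_attribute = character(), renamed_attribute = character()
    ),
    tibble::tibble(
      attribute_name = character(), kind = character(),
      original_value = character(), protected_value = character()
    )
  )
  path <- withr::local_tempfile()
  write_lookup(lk, path)
  back <- read_lookup(path)
  expect_equal(nrow(back$attribute_map), 0L)
  expect_equal(nrow(back$value_map), 0L)
})

test_that("a store whose value map references unknown attributes is rejected", {
  lk <- protect_dataset(toy_mixed(), fixed_cfg())$lookup
  path <- withr::local_tempfile()
  write_lookup(lk, path)
  lines <- readLines(path)
  # drop the attribute-rename rows, leaving orphaned value rows
  keep <- !grepl("^[^\t#]+\t[^\t]+\t\t\t$", lines)
  writeLines(lines[keep], path)
  expect_error(read_lookup(path), "absent from the attribute map")
})
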