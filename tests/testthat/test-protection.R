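test_that("attribute key derivation is deterministic, case-sensitive, 256-bit", {
  k1 <- derive_attribute_key(fixed_key(), "Age")
  expect_identical(k1, derive_attribute_key(fixed_key(), "Age"))
  expect_false(identical(k1, derive_attribute_key(fixed_key(), "age")))
  expect_length(k1, 32L)
  expect_length(derive_attribute_key(fixed_key(), "x"), 32L)
})

test_that("token encryption is deterministic, injective and context-bound", {
  salt <- as.raw(1:16)
  ka <- derive_attribute_key(fixed_key(), "smoker")
  kb <- derive_attribute_key(fixed_key(), "class")
  expect_identical(
    encrypt_token("yes", ka, salt), encrypt_token("yes", ka, salt)
  )
  expect_false(encrypt_token("yes", ka, salt) == encrypt_token("no", ka, salt))
  # same plaintext under keys of two attributes differs
  expect_false(encrypt_token("yes", ka, salt) == encrypt_token("yes", kb, salt))
  # ciphertexts are printable base64, usable as (quoted) ARFF tokens
  ct <- encrypt_token("tested_negative", ka, salt)
  expect_match(ct, "^[A-Za-z0-9+/=]+$")
})

test_that("numeric transform matches the worked protection examples", {
  expect_equal(transform_numeric(127, 2, 1), 255)
  expect_equal(transform_numeric(26.4, 2, 1), 53.8)
  expect_equal(transform_numeric(28, 2, 1), 57)
  expect_equal(invert_numeric(255, 2, 1), 127)
  expect_equal(invert_numeric(5, 1, 0), 5)
  expect_error(transform_numeric(1, 0, 1), "a must be > 0")
  expect_error(invert_numeric(1, -2, 1), "a must be > 0")
})

test_that("transform/invert round-trips 1000 random reals to 1e-9 relative", {
  withr::local_seed(7)
  v <- runif(1000, -1e4, 1e4)
  a <- runif(1, 0.5, 5)
  b <- runif(1, -10, 10)
  back <- invert_numeric(transform_numeric(v, a, b), a, b)
  expect_lt(max(abs(back - v) / pmax(abs(v), 1)), 1e-9)
})

test_that("protection preserves shape, missingness, order and equality", {
  d <- toy_mixed()
  bundle <- protect_dataset(d, fixed_cfg())
  prot <- bundle$protected
  expect_equal(dim(prot), dim(d))
  expect_identical(
    unname(is.na(as.matrix(prot$data))), unname(is.na(as.matrix(d$data)))
  )

  # order preservation: rank vectors of numeric columns are unchanged
  for (j in 1:2) {
    expect_identical(
      rank(d$data[[j]], na.last = "keep"),
      rank(prot$data[[j]], na.last = "keep")
    )
  }
  # equality preservation within nominal columns
  for (j in 3:4) {
    expect_identical(
      outer(d$data[[j]], d$data[[j]], `==`),
      outer(prot$data[[j]], prot$data[[j]], `==`)
    )
    expect_equal(
      length(unique(stats::na.omit(d$data[[j]]))),
      length(unique(stats::na.omit(prot$data[[j]])))
    )
  }
  # protected nominal domains are the encrypted images of the originals
  expect_equal(
    sort(dataset_schema(prot)$domain[[3]]),
    sort(unname(bundle$lookup$value_map$protected_value[
      bundle$lookup$value_map$attribute_name == "smoker"
    ]))
  )
})

test_that("an all-missing column passes through as all missing", {
  d <- as_dataset(
    data.frame(
      x = c(NA_real_, NA_real_), cls = c("a", "b"),
      stringsAsFactors = FALSE
    )
  )
  bundle <- protect_dataset(d, fixed_cfg())
  expect_true(all(is.na(bundle$protected$data[[1]])))
})

test_that("owner round trip through the lookup reproduces the plaintext", {
  for (seed in c(4, 13)) {
    d <- generate_dataset(generator_spec(n_rows = 80, seed = seed))$dataset
    bundle <- protect_dataset(d, fixed_cfg())
    back <- decrypt_dataset(bundle$protected, bundle$lookup)
    expect_equal(back$schema$name, d$schema$name)
    for (j in seq_len(nrow(d$schema))) {
      if (d$schema$kind[[j]] == "numeric") {
        expect_equal(back$data[[j]], d$data[[j]], tolerance = 1e-9)
      } else {
        expect_identical(back$data[[j]], d$data[[j]])
      }
    }
  }
})

test_that("serialized protected output leaks no key material", {
  d <- toy_mixed()
  cfg <- fixed_cfg()
  bundle <- protect_dataset(d, cfg)
  txt <- paste(write_arff(bundle$protected), collapse = "\n")
  key_hex <- fixed_key()
  expect_false(grepl(key_hex, txt, fixed = TRUE))
  expect_false(grepl(substr(key_hex, 1, 16), txt, fixed = TRUE))
  # nor any derived key's base64 or hex
  dk <- derive_attribute_key(cfg$master_key, "smoker")
  expect_false(grepl(paste(format(dk), collapse = ""), txt, fixed = TRUE))
  expect_false(grepl(as.character(jsonlite::base64_enc(dk)), txt, fixed = TRUE))
})

test_that("identity cipher mode passes tokens through for pipeline testing", {
  d <- toy_mixed()
  cfg <- protection_config(
    master_key = fixed_key(), session_salt = as.raw(1:16),
    numeric_coeffs = list(glucose = c(1, 0), age = c(1, 0)),
    default_coeffs = c(1, 0), token_cipher = "identity"
  )
  bundle <- protect_dataset(d, cfg)
  expect_equal(bundle$protected$data, d$data)
})

test_that("protection config rejects invalid keys and coefficients", {
  expect_error(protection_config(master_key = "zz"), "64-hex")
  expect_error(protection_config(master_key = as.raw(1:5)), "32 bytes")
  expect_error(
    protection_config(
      master_key = fixed_key(), default_coeffs = c(-1, 0)
    ),
    "a must be > 0"
  )
})
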