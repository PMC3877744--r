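#' Protection configuration
#'
#' Holds the owner-side secrets and coefficients of a protection run: a
#' 256-bit master key, a session salt fixed per run, and per-attribute
#' coefficients of the strictly increasing affine transform `a * v + b`
#' applied to numeric cells. The defaults `(a, b) = (2, 1)` double every
#' numeric value and add one, which hides magnitudes while preserving the
#' ordering that threshold splits depend on; any `a > 0` is admissible.
#'
#' @param master_key A 32-byte raw vector, or a 64-hex-character string.
#'   Default: a fresh random key.
#' @param session_salt A raw vector recorded per protection run (default: 16
#'   fresh random bytes). Fixing the salt makes reruns byte-identical.
#' @param numeric_coeffs Named list mapping attribute names to `c(a, b)`
#'   pairs; unnamed entry `.default` (or absent attributes) fall back to
#'   `default_coeffs`.
#' @param default_coeffs Length-2 numeric `c(a, b)` with `a > 0`.
#' @param token_cipher `"aes"` (AES-256-CBC deterministic tokens) or
#'   `"identity"` (tokens pass through unchanged; for pipeline testing
#'   only, offers no protection).
#' @return An object of class `protection_config`.
#' @examples
#' cfg <- protection_config(master_key = strrep("ab", 32))
#' transform_numeric(127, 2, 1)
#' @export
protection_config <- function(master_key = NULL, session_salt = NULL,
                              numeric_coeffs = list(),
                              default_coeffs = c(2, 1),
                              token_cipher = c("aes", "identity")) {
  token_cipher <- match.arg(token_cipher)
  if (is.null(master_key)) {
    master_key <- as.raw(sample.int(256L, 32L, replace = TRUE) - 1L)
  } else {
    master_key <- as_key_bytes(master_key)
  }
  if (is.null(session_salt)) {
    session_salt <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  } else {
    session_salt <- as.raw(session_salt)
  }
  check_coeffs(default_coeffs)
  for (cc in numeric_coeffs) check_coeffs(cc)
  structure(
    list(
      master_key = master_key, session_salt = session_salt,
      numeric_coeffs = numeric_coeffs, default_coeffs = default_coeffs,
      token_cipher = token_cipher
    ),
    class = "protection_config"
  )
}

#' @export
print.protection_config <- function(x, ...) {
  # never echoes key material
  cat(sprintf(
    "<protection_config> cipher %s, default numeric transform %s*v + %s, %d per-attribute coefficient override(s)\n",
    x$token_cipher, fmt_num(x$default_coeffs[[1]]),
    fmt_num(x$default_coeffs[[2]]), length(x$numeric_coeffs)
  ))
  invisible(x)
}

as_key_bytes <- function(key) {
  if (is.raw(key)) {
    if (length(key) != 32L) abort("master key must be exactly 32 bytes")
    return(key)
  }
  if (is.character(key) && length(key) == 1L &&
    grepl("^[0-9a-fA-F]{64}$", key)) {
    return(as.raw(strtoi(
      substring(key, seq(1, 63, 2), seq(2, 64, 2)),
      base = 16L
    )))
  }
  abort("master key must be 32 raw bytes or a 64-hex-character string")
}

check_coeffs <- function(cc) {
  if (length(cc) != 2L || !is.numeric(cc) || anyNA(cc)) {
    abort("numeric coefficients must be a finite pair c(a, b)")
  }
  if (cc[[1]] <= 0) {
    abort("transform scale a must be > 0 (strict monotonicity)")
  }
  invisible(cc)
}

coeffs_for <- function(cfg, attribute) {
  cc <- cfg$numeric_coeffs[[attribute]] %||% cfg$default_coeffs
  check_coeffs(cc)
  cc
}

#' Derive a per-attribute encryption key
#'
#' Context separation: each attribute gets its own 256-bit key derived from
#' the master key and the (case-sensitive) attribute name, so identical
#' plaintext tokens in different columns encrypt differently. Tree induction
#' only ever compares values within a column, so this costs nothing while
#' blocking cross-column linkage.
#'
#' @param master_key 32 raw bytes or 64 hex characters.
#' @param attribute_name Nonempty attribute name.
#' @return A 32-byte raw key.
#' @export
derive_attribute_key <- function(master_key, attribute_name) {
  master_key <- as_key_bytes(master_key)
  if (!nzchar(attribute_name)) abort("attribute name must be nonempty")
  .sha256_raw(c(master_key, as.raw(0L), charToRaw(enc2utf8(attribute_name))))
}

#' Deterministically encrypt a token
#'
#' AES-256 in CBC mode with an IV derived from the session salt and the
#' key, so a fixed `(token, key, salt)` triple always yields the same
#' ciphertext and distinct tokens yield distinct ciphertexts (CBC under a
#' fixed key and IV is injective). Determinism is what keeps equality
#' comparisons — and hence nominal splits — intact on the protected file;
#' conventional randomized encryption would break the method.
#'
#' @param token Nonempty character vector of plaintext tokens.
#' @param key 32-byte raw key (see [derive_attribute_key()]).
#' @param salt Raw session salt.
#' @return Base64 ciphertext tokens, one per input token.
#' @export
encrypt_token <- function(token, key, salt) {
  stopifnot(is.raw(key), length(key) == 32L, is.raw(salt))
  if (any(!nzchar(token)) || anyNA(token)) {
    abort("tokens must be nonempty and non-missing")
  }
  iv <- .sha256_raw(c(salt, as.raw(1L), key))[1:16]
  vapply(token, function(tok) {
    ct <- .aes256_cbc_encrypt(key, iv, charToRaw(enc2utf8(tok)))
    as.character(jsonlite::base64_enc(ct))
  }, character(1), USE.NAMES = FALSE)
}

#' Strictly increasing affine transform of numeric values
#'
#' `transform_numeric()` maps `v` to `a * v + b` with `a > 0`;
#' `invert_numeric()` is its exact inverse `(w - b) / a`. With the default
#' coefficients `(2, 1)`, the plasma-glucose value 127 becomes 255, BMI
#' 26.4 becomes 53.8, and age 28 becomes 57. Any strictly increasing map
#' preserves the rank order of a column, so every threshold split found on
#' one side has an exact counterpart on the other.
#'
#' @param v,w Numeric vectors (plaintext and protected, respectively).
#' @param a Positive scale.
#' @param b Offset.
#' @return Numeric vector; `NA` passes through.
#' @examples
#' transform_numeric(c(127, 26.4, 28), 2, 1)
#' invert_numeric(255, 2, 1)
#' @export
transform_numeric <- function(v, a = 2, b = 1) {
  check_coeffs(c(a, b))
  a * v + b
}

#' @rdname transform_numeric
#' @export
invert_numeric <- function(w, a = 2, b = 1) {
  check_coeffs(c(a, b))
  (w - b) / a
}

#' Protect a dataset for outsourced analysis
#'
#' The core operation: attribute names and every non-missing nominal cell
#' (including the class) are replaced by deterministic AES-256 ciphertexts
#' under per-attribute derived keys; every non-missing numeric cell is
#' mapped through its strictly increasing affine transform; missing markers
#' pass through unchanged so both sides see the same missingness. The
#' returned bundle carries the protected dataset (same shape, same missing
#' cells) and the owner-side [lookup table][lookup_table] recording every
#' (attribute, plaintext, protected) correspondence for names, nominal
#' values, and each distinct observed numeric value.
#'
#' A ciphertext collision within one attribute would silently merge two
#' categories and change the induced tree, so collisions abort the run.
#'
#' @param d A [ptd_dataset][as_dataset] or coercible data frame.
#' @param cfg A [protection_config()].
#' @return An object of class `protected_bundle`: list with elements
#'   `protected` (a `ptd_dataset`) and `lookup` (a `lookup_table`).
#' @examples
#' d <- as_dataset(data.frame(age = c(28, 40), cls = c("neg", "pos")))
#' bundle <- protect_dataset(d, protection_config(strrep("0f", 32)))
#' bundle$protected$data[[1]] # 57, 81: the transformed ages
#' @export
protect_dataset <- function(d, cfg = protection_config()) {
  d <- as_dataset(d)
  stopifnot(inherits(cfg, "protection_config"))
  p <- nrow(d$schema)

  name_key <- derive_attribute_key(cfg$master_key, "@attribute-names")
  enc_names <- cipher_tokens(d$schema$name, name_key, cfg)
  if (anyDuplicated(enc_names)) abort("ciphertext collision among attribute names; protection aborted")

  attribute_map <- tibble(
    original_attribute = d$schema$name,
    renamed_attribute = enc_names
  )

  new_schema <- list()
  new_cols <- vector("list", p)
  value_rows <- vector("list", p)
  coeff_rows <- vector("list", p)

  for (j in seq_len(p)) {
    nm <- d$schema$name[[j]]
    col <- d$data[[j]]
    if (d$schema$kind[[j]] == "numeric") {
      cc <- coeffs_for(cfg, nm)
      prot <- transform_numeric(col, cc[[1]], cc[[2]])
      new_cols[[j]] <- prot
      new_schema[[j]] <- attribute_spec(enc_names[[j]], "numeric")
      vals <- sort(unique(col[!is.na(col)]))
      value_rows[[j]] <- tibble(
        attribute_name = nm, kind = "numeric",
        original_value = fmt_num(vals),
        protected_value = fmt_num(transform_numeric(vals, cc[[1]], cc[[2]]))
      )
      coeff_rows[[j]] <- tibble(attribute_name = nm, a = cc[[1]], b = cc[[2]])
    } else {
      key <- derive_attribute_key(cfg$master_key, nm)
      domain <- d$schema$domain[[j]]
      enc_domain <- cipher_tokens(domain, key, cfg)
      if (anyDuplicated(enc_domain)) {
        abort(sprintf(
          "ciphertext collision within attribute '%s'; protection aborted", nm
        ))
      }
      new_cols[[j]] <- unname(setNames(enc_domain, domain)[col])
      new_schema[[j]] <- attribute_spec(enc_names[[j]], "nominal", enc_domain)
      value_rows[[j]] <- tibble(
        attribute_name = nm, kind = "nominal",
        original_value = domain, protected_value = enc_domain
      )
    }
  }

  names(new_cols) <- enc_names
  protected <- structure(
    list(
      relation = "protected", # the plaintext relation name is not disclosed
      schema = dplyr::bind_rows(new_schema),
      class_index = d$class_index,
      data = as_tibble(new_cols)
    ),
    class = "ptd_dataset"
  )
  validate_dataset(protected)

  lookup <- lookup_table(
    attribute_map = attribute_map,
    value_map = dplyr::bind_rows(value_rows),
    coeffs = dplyr::bind_rows(coeff_rows),
    session_salt = cfg$session_salt
  )

  structure(
    list(protected = protected, lookup = lookup),
    class = "protected_bundle"
  )
}

cipher_tokens <- function(tokens, key, cfg) {
  if (cfg$token_cipher == "identity") {
    return(tokens)
  }
  encrypt_token(tokens, key, cfg$session_salt)
}

#' @export
print.protected_bundle <- function(x, ...) {
  cat(sprintf(
    "<protected_bundle> %d rows x %d attributes protected; lookup: %d attribute renames, %d value mappings\n",
    nrow(x$protected$data), nrow(x$protected$schema),
    nrow(x$lookup$attribute_map), nrow(x$lookup$value_map)
  ))
  invisible(x)
}
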