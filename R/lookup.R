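#' Owner-side lookup table
#'
#' The mapping the data owner keeps to decrypt analysis output: attribute
#' renames (`original_attribute` / `renamed_attribute`), value mappings
#' (`attribute_name`, `original_value`, `protected_value` — keyed by the
#' *original* attribute name, matching the query interface of a relational
#' lookup table), and the affine coefficients of each numeric attribute so
#' protected thresholds that never occurred in the data (e.g. produced by
#' pruning) can still be inverted in closed form.
#'
#' @param attribute_map Tibble with columns `original_attribute`,
#'   `renamed_attribute` (unique).
#' @param value_map Tibble with columns `attribute_name`, `kind`,
#'   `original_value`, `protected_value` (characters; numerics in shortest
#'   round-trip decimal form).
#' @param coeffs Tibble with columns `attribute_name`, `a`, `b`, one row per
#'   numeric attribute.
#' @param session_salt Raw session salt of the protection run.
#' @return An object of class `lookup_table`.
#' @export
lookup_table <- function(attribute_map, value_map, coeffs = NULL,
                         session_salt = raw(0)) {
  attribute_map <- as_tibble(attribute_map)
  value_map <- as_tibble(value_map)
  coeffs <- if (is.null(coeffs) || nrow(as_tibble(coeffs)) == 0L) {
    tibble(attribute_name = character(), a = double(), b = double())
  } else {
    as_tibble(coeffs)
  }
  lk <- structure(
    list(
      attribute_map = attribute_map, value_map = value_map,
      coeffs = coeffs, session_salt = as.raw(session_salt)
    ),
    class = "lookup_table"
  )
  validate_lookup(lk)
}

validate_lookup <- function(lk) {
  am <- lk$attribute_map
  vm <- lk$value_map
  if (anyDuplicated(am$renamed_attribute)) {
    abort("renamed attribute tokens must be unique")
  }
  if (nrow(vm) > 0L &&
    anyDuplicated(vm[, c("attribute_name", "protected_value")])) {
    abort("(attribute, protected value) pairs must be unique")
  }
  orphan <- setdiff(vm$attribute_name, am$original_attribute)
  if (length(orphan) > 0L) {
    abort(sprintf(
      "value map references attribute '%s' absent from the attribute map",
      orphan[[1]]
    ))
  }
  lk
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf(
    "<lookup_table> %d attribute renames, %d value mappings (%d numeric attributes with coefficients)\n",
    nrow(x$attribute_map), nrow(x$value_map), nrow(x$coeffs)
  ))
  invisible(x)
}

lookup_miss <- function(msg) {
  abort(msg, class = "privtree_lookup_miss")
}

#' Resolve a renamed attribute back to its original name
#'
#' @param lk A [lookup_table()].
#' @param renamed The protected attribute name token.
#' @return The original attribute name.
#' @export
original_attribute_for <- function(lk, renamed) {
  stopifnot(inherits(lk, "lookup_table"))
  hit <- match(renamed, lk$attribute_map$renamed_attribute)
  if (is.na(hit)) {
    lookup_miss(sprintf("renamed attribute '%s' was never issued", renamed))
  }
  lk$attribute_map$original_attribute[[hit]]
}

#' Resolve a protected value back to its plaintext
#'
#' For nominal attributes the ciphertext token is looked up directly; for
#' numeric attributes the protected value is matched against the recorded
#' observed values and, failing that, inverted in closed form through the
#' attribute's affine coefficients (a threshold introduced by pruning need
#' not equal any observed value).
#'
#' @param lk A [lookup_table()].
#' @param attribute The *original* attribute name.
#' @param protected_value Ciphertext token (character) or protected numeric.
#' @return Plaintext token (character) or original numeric value.
#' @export
original_value_for <- function(lk, attribute, protected_value) {
  stopifnot(inherits(lk, "lookup_table"))
  if (!(attribute %in% lk$attribute_map$original_attribute)) {
    lookup_miss(sprintf("unknown attribute '%s'", attribute))
  }
  cidx <- match(attribute, lk$coeffs$attribute_name)
  is_numeric <- !is.na(cidx)
  key <- if (is.numeric(protected_value)) {
    fmt_num(protected_value)
  } else {
    as.character(protected_value)
  }
  vm <- lk$value_map
  hit <- which(vm$attribute_name == attribute & vm$protected_value == key)
  if (length(hit) > 0L) {
    orig <- vm$original_value[[hit[[1]]]]
    return(if (is_numeric) as.numeric(orig) else orig)
  }
  if (is_numeric) {
    w <- suppressWarnings(as.numeric(key))
    if (!is.na(w)) {
      return(invert_numeric(w, lk$coeffs$a[[cidx]], lk$coeffs$b[[cidx]]))
    }
  }
  lookup_miss(sprintf(
    "protected value '%s' of attribute '%s' was never issued", key, attribute
  ))
}

#' Decrypt a decision rule through the lookup table
#'
#' Takes a root-to-leaf rule extracted from a tree induced on protected
#' data and rewrites every term to plaintext: renamed attributes via the
#' attribute map, numeric thresholds via the numeric value map (with
#' closed-form inversion as fallback), nominal branch tokens and the
#' consequent class via the value map. Conjunction structure and comparison
#' operators are untouched.
#'
#' @param rule A `decision_rule` (see [extract_rules()]).
#' @param lk A [lookup_table()].
#' @return The decrypted `decision_rule`.
#' @export
decrypt_rule <- function(rule, lk) {
  stopifnot(inherits(rule, "decision_rule"), inherits(lk, "lookup_table"))
  conds <- rule$conditions
  if (nrow(conds) > 0L) {
    orig_attr <- vapply(conds$attribute, function(a) {
      original_attribute_for(lk, a)
    }, character(1))
    value <- character(nrow(conds))
    for (i in seq_len(nrow(conds))) {
      v <- original_value_for(
        lk, orig_attr[[i]],
        if (conds$kind[[i]] == "numeric") {
          as.numeric(conds$value[[i]])
        } else {
          conds$value[[i]]
        }
      )
      value[[i]] <- if (is.numeric(v)) fmt_num(v) else v
    }
    conds$attribute <- unname(orig_attr)
    conds$value <- value
  }
  class_attr <- original_attribute_for(lk, rule$class_attribute)
  cls <- original_value_for(lk, class_attr, rule$class)
  new_decision_rule(conds, as.character(cls), class_attr)
}

#' @rdname decrypt_rule
#' @param rules A rules tibble as returned by [extract_rules()].
#' @return For `decrypt_rules()`: the rules tibble with every rule decrypted.
#' @export
decrypt_rules <- function(rules, lk) {
  rules$rule <- purrr::map(rules$rule, decrypt_rule, lk = lk)
  rules$text <- purrr::map_chr(rules$rule, format_rule)
  rules$class <- purrr::map_chr(rules$rule, "class")
  rules
}

#' Decrypt a whole protected dataset
#'
#' Owner-side inverse of [protect_dataset()]: resolves every attribute name
#' through the attribute map and every non-missing cell through the value
#' map (numeric cells by closed-form inversion), reproducing the plaintext
#' dataset; missing cells stay missing.
#'
#' @param protected The protected [ptd_dataset][as_dataset].
#' @param lk The [lookup_table()] of the protection run.
#' @return A `ptd_dataset` with plaintext names, domains and cells.
#' @export
decrypt_dataset <- function(protected, lk) {
  protected <- as_dataset(protected)
  stopifnot(inherits(lk, "lookup_table"))
  p <- nrow(protected$schema)
  orig_names <- vapply(
    protected$schema$name, original_attribute_for,
    character(1),
    lk = lk
  )
  cols <- vector("list", p)
  schema_rows <- vector("list", p)
  for (j in seq_len(p)) {
    nm <- orig_names[[j]]
    col <- protected$data[[j]]
    if (protected$schema$kind[[j]] == "numeric") {
      cidx <- match(nm, lk$coeffs$attribute_name)
      if (is.na(cidx)) lookup_miss(sprintf("no coefficients for '%s'", nm))
      cols[[j]] <- invert_numeric(col, lk$coeffs$a[[cidx]], lk$coeffs$b[[cidx]])
      schema_rows[[j]] <- attribute_spec(nm, "numeric")
    } else {
      domain <- protected$schema$domain[[j]]
      orig_domain <- vapply(domain, function(tok) {
        as.character(original_value_for(lk, nm, tok))
      }, character(1))
      cols[[j]] <- unname(setNames(orig_domain, domain)[col])
      schema_rows[[j]] <- attribute_spec(nm, "nominal", unname(orig_domain))
    }
  }
  names(cols) <- orig_names
  out <- structure(
    list(
      relation = "decrypted", schema = dplyr::bind_rows(schema_rows),
      class_index = protected$class_index, data = as_tibble(cols)
    ),
    class = "ptd_dataset"
  )
  validate_dataset(out)
}

# persistence ---------------------------------------------------------------

#' Save or load a lookup table as delimited text
#'
#' The store is a tab-separated file with the columns of the demonstrated
#' relational interface — `renamed_attribute`, `original_atribute` (the
#' published spelling, kept so existing SQL queries run verbatim against a
#' bulk-loaded copy), `attribute_name`, `encrypted_value`, `original_value`
#' — preceded by `#`-prefixed metadata lines holding the session salt and
#' the numeric coefficients. Attribute renames and value mappings occupy
#' disjoint rows, empty fields elsewhere. The store lives only on the
#' owner side.
#'
#' @param lk A [lookup_table()].
#' @param file Path to write to / read from.
#' @return `write_lookup()` returns `file` invisibly; `read_lookup()` the
#'   reconstructed `lookup_table`.
#' @export
write_lookup <- function(lk, file) {
  stopifnot(inherits(lk, "lookup_table"))
  meta <- c(
    sprintf("#salt\t%s", paste(format(lk$session_salt), collapse = "")),
    sprintf(
      "#coeffs\t%s\t%s\t%s",
      lk$coeffs$attribute_name, fmt_num(lk$coeffs$a), fmt_num(lk$coeffs$b)
    )
  )
  header <- paste(c(
    "renamed_attribute", "original_atribute", "attribute_name",
    "encrypted_value", "original_value"
  ), collapse = "\t")
  am <- sprintf(
    "%s\t%s\t\t\t",
    lk$attribute_map$renamed_attribute, lk$attribute_map$original_attribute
  )
  vm <- sprintf(
    "\t\t%s\t%s\t%s",
    lk$value_map$attribute_name, lk$value_map$protected_value,
    lk$value_map$original_value
  )
  writeLines(c(meta, header, am, vm), file)
  invisible(file)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(file) {
  lines <- as_lines(file)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) < 1L) abort("malformed lookup store: missing header")
  header <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
  expected <- c(
    "renamed_attribute", "original_atribute", "attribute_name",
    "encrypted_value", "original_value"
  )
  if (!identical(header, expected)) {
    abort("malformed lookup store: unexpected column header")
  }

  salt <- raw(0)
  coeff_rows <- list()
  for (m in meta) {
    parts <- strsplit(m, "\t", fixed = TRUE)[[1]]
    if (parts[[1]] == "#salt" && length(parts) == 2L && nzchar(parts[[2]])) {
      hx <- parts[[2]]
      salt <- as.raw(strtoi(
        substring(hx, seq(1, nchar(hx) - 1, 2), seq(2, nchar(hx), 2)),
        base = 16L
      ))
    } else if (parts[[1]] == "#coeffs" && length(parts) == 4L) {
      coeff_rows[[length(coeff_rows) + 1L]] <- tibble(
        attribute_name = parts[[2]],
        a = as.numeric(parts[[3]]), b = as.numeric(parts[[4]])
      )
    }
  }

  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  rows <- lapply(rows, function(r) c(r, rep("", 5L - length(r)))[1:5])
  mat <- do.call(rbind, rows)
  if (is.null(mat)) mat <- matrix(character(0), 0L, 5L)
  is_rename <- nzchar(mat[, 1L])
  am <- tibble(
    original_attribute = mat[is_rename, 2L],
    renamed_attribute = mat[is_rename, 1L]
  )
  vm_mat <- mat[!is_rename, , drop = FALSE]
  coeffs <- if (length(coeff_rows) == 0L) {
    tibble(attribute_name = character(), a = double(), b = double())
  } else {
    dplyr::bind_rows(coeff_rows)
  }
  vm <- tibble(
    attribute_name = vm_mat[, 3L],
    kind = ifelse(vm_mat[, 3L] %in% coeffs$attribute_name, "numeric", "nominal"),
    original_value = vm_mat[, 5L],
    protected_value = vm_mat[, 4L]
  )
  lookup_table(am, vm, coeffs, salt)
}
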