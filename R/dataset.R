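#' Typed flat-table container
#'
#' A `ptd_dataset` is the unit both protection and tree induction consume: a
#' relation name, an ordered schema of typed attributes (numeric, or nominal
#' with a declared token domain), the index of the nominal class attribute,
#' and a tibble of rows. Missing cells are `NA` in memory and `?` on disk.
#'
#' @param data A data frame; numeric columns become numeric attributes,
#'   character/factor/logical columns nominal attributes whose domain is the
#'   declared factor levels or the distinct observed tokens in row order.
#' @param relation Relation name written to the ARFF header.
#' @param class_index Position of the class attribute (default: last column).
#'   The class attribute must be nominal.
#' @param schema Optional schema tibble as returned by [dataset_schema()],
#'   with columns `name`, `kind` and `domain` (list of character vectors,
#'   `NULL` for numeric attributes). When supplied it overrides inference,
#'   and cells of columns forced to nominal are stored as their tokens.
#'
#' @return An object of class `ptd_dataset`: a list with elements `relation`,
#'   `schema`, `class_index` and `data` (a tibble).
#' @examples
#' d <- as_dataset(data.frame(x = c(1, 2), cls = c("a", "b")))
#' dataset_schema(d)
#' @export
as_dataset <- function(data, relation = "data", class_index = NULL,
                       schema = NULL) {
  if (inherits(data, "ptd_dataset")) {
    return(data)
  }
  stopifnot(is.data.frame(data))
  if (ncol(data) < 1L) {
    abort("a dataset needs at least one attribute")
  }
  df <- as_tibble(data)
  if (is.null(schema)) {
    schema <- infer_schema(df)
  } else {
    schema <- validate_schema_shape(schema)
    if (!identical(schema$name, names(df))) {
      abort("schema attribute names do not match the data columns")
    }
  }
  cols <- purrr::map2(df, seq_len(ncol(df)), function(col, j) {
    if (schema$kind[[j]] == "numeric") {
      if (!is.numeric(col)) {
        col <- suppressWarnings(as.numeric(as.character(col)))
      }
      as.double(col)
    } else {
      as.character(col)
    }
  })
  out <- structure(
    list(
      relation = as.character(relation),
      schema = schema,
      class_index = as.integer(class_index %||% ncol(df)),
      data = as_tibble(cols)
    ),
    class = "ptd_dataset"
  )
  validate_dataset(out)
}

#' Construct an attribute specification row
#'
#' @param name Attribute name (nonempty).
#' @param kind `"numeric"` or `"nominal"`.
#' @param domain Character vector of category tokens (nominal only).
#' @return A one-row schema tibble.
#' @export
attribute_spec <- function(name, kind = c("numeric", "nominal"),
                           domain = NULL) {
  kind <- match.arg(kind)
  if (!nzchar(name)) abort("attribute name must be nonempty")
  if (kind == "nominal") {
    if (length(domain) == 0L) abort("nominal attributes need a nonempty domain")
    if (anyDuplicated(domain)) abort("nominal domain tokens must be distinct")
    domain <- as.character(domain)
  } else {
    domain <- NULL
  }
  tibble(name = name, kind = kind, domain = list(domain))
}

#' @rdname as_dataset
#' @param x A `ptd_dataset`.
#' @export
dataset_schema <- function(x) {
  stopifnot(inherits(x, "ptd_dataset"))
  x$schema
}

#' @rdname as_dataset
#' @export
class_attribute <- function(x) {
  stopifnot(inherits(x, "ptd_dataset"))
  x$schema$name[[x$class_index]]
}

infer_schema <- function(df) {
  rows <- purrr::imap(df, function(col, nm) {
    if (is.numeric(col)) {
      attribute_spec(nm, "numeric")
    } else if (is.factor(col)) {
      attribute_spec(nm, "nominal", levels(col))
    } else {
      toks <- unique(as.character(col))
      toks <- toks[!is.na(toks)]
      if (length(toks) == 0L) toks <- "?" # degenerate all-missing column
      attribute_spec(nm, "nominal", toks)
    }
  })
  dplyr::bind_rows(rows)
}

validate_schema_shape <- function(schema) {
  schema <- as_tibble(schema)
  stopifnot(all(c("name", "kind", "domain") %in% names(schema)))
  if (anyDuplicated(schema$name)) {
    abort("attribute names must be unique within a schema")
  }
  if (!all(schema$kind %in% c("numeric", "nominal"))) {
    abort("attribute kind must be 'numeric' or 'nominal'")
  }
  schema
}

#' Validate dataset invariants
#'
#' Checks that every row has one cell per attribute, non-missing nominal
#' cells lie in their declared domain, and the class attribute is nominal.
#'
#' @param x A `ptd_dataset`.
#' @return `x`, invisibly usable, after validation (errors otherwise).
#' @export
validate_dataset <- function(x) {
  stopifnot(inherits(x, "ptd_dataset"))
  validate_schema_shape(x$schema)
  if (!identical(names(x$data), x$schema$name)) {
    abort("data columns do not match schema attribute order")
  }
  if (x$class_index < 1L || x$class_index > nrow(x$schema)) {
    abort("class_index out of range")
  }
  if (x$schema$kind[[x$class_index]] != "nominal") {
    abort("the class attribute must be nominal")
  }
  for (j in seq_len(nrow(x$schema))) {
    if (x$schema$kind[[j]] == "nominal") {
      cells <- x$data[[j]]
      bad <- !is.na(cells) & !(cells %in% x$schema$domain[[j]])
      if (any(bad)) {
        abort(sprintf(
          "attribute '%s': token '%s' not in declared domain",
          x$schema$name[[j]], cells[bad][[1]]
        ))
      }
    }
  }
  x
}

#' @export
print.ptd_dataset <- function(x, ...) {
  cat(sprintf(
    "<ptd_dataset> relation '%s': %d rows x %d attributes (class: %s)\n",
    x$relation, nrow(x$data), nrow(x$schema), class_attribute(x)
  ))
  kinds <- table(x$schema$kind)
  cat(sprintf(
    "  %d numeric, %d nominal; %d missing cells\n",
    kinds["numeric"] %||% 0L, kinds["nominal"] %||% 0L,
    sum(is.na(as.matrix(x$data)))
  ))
  print(head(x$data, 6))
  invisible(x)
}

#' @export
dim.ptd_dataset <- function(x) dim(x$data)

#' @importFrom tibble as_tibble
#' @method as_tibble ptd_dataset
#' @export
as_tibble.ptd_dataset <- function(x, ...) x$data

#' Tidy a dataset's schema
#'
#' @param x A `ptd_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per attribute: name, kind, domain size,
#'   missing-cell count, and whether it is the class attribute.
#' @method tidy ptd_dataset
#' @export
tidy.ptd_dataset <- function(x, ...) {
  tibble(
    attribute = x$schema$name,
    kind = x$schema$kind,
    n_levels = purrr::map_int(x$schema$domain, length),
    n_missing = purrr::map_int(x$data, ~ sum(is.na(.x))),
    is_class = seq_len(nrow(x$schema)) == x$class_index
  )
}

# shared helpers ------------------------------------------------------------

#' Shortest round-trip decimal formatting
#'
#' Formats doubles with the fewest significant digits that still parse back
#' to the identical double, so protected thresholds like 53.8 print exactly.
#' @param x Numeric vector.
#' @return Character vector; `NA` stays `NA`.
#' @keywords internal
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) {
      return(NA_character_)
    }
    if (v == trunc(v) && abs(v) < 1e15) {
      return(format(v, scientific = FALSE))
    }
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g", width = -1)
      if (as.numeric(s) == v) {
        return(s)
      }
    }
    sprintf("%.17g", v)
  }, character(1))
}
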