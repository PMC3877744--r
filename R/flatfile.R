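#' Read an ARFF flat file
#'
#' Parses the Weka ARFF dialect subset used by tabular classification data:
#' `@relation`, `@attribute` declarations of kind `numeric`/`real`/`integer`,
#' `{...}` nominal, or `string` (treated as nominal with the domain observed
#' in the data), a `@data` section with comma-separated rows, `%` comments,
#' quoted tokens, and unquoted `?` as the missing marker. Date and sparse
#' ARFF are rejected. Malformed input is reported with its line number.
#'
#' @param file Path to an ARFF file, or ARFF text (a string containing
#'   newlines, or a character vector of lines).
#' @param class_index Position of the class attribute; default last.
#' @return A [ptd_dataset][as_dataset].
#' @examples
#' txt <- c(
#'   "@relation toy", "@attribute x numeric",
#'   "@attribute cls {yes,no}", "@data", "1,yes", "?,no"
#' )
#' d <- read_arff(txt)
#' dim(d)
#' @export
read_arff <- function(file, class_index = NULL) {
  lines <- as_lines(file)
  n <- length(lines)
  relation <- NULL
  schema <- list()
  open_domain <- logical()
  i <- 1L
  data_start <- NA_integer_

  while (i <= n) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "%")) {
      i <- i + 1L
      next
    }
    low <- tolower(line)
    if (startsWith(low, "@relation")) {
      relation <- parse_quoted(trimws(substring(line, 10L)), i)
    } else if (startsWith(low, "@attribute")) {
      rest <- trimws(substring(line, 11L))
      at <- parse_attribute_decl(rest, i)
      schema[[length(schema) + 1L]] <- at$spec
      open_domain[length(schema)] <- at$open
    } else if (startsWith(low, "@data")) {
      data_start <- i + 1L
      break
    } else {
      abort(sprintf("line %d: unrecognized ARFF header line: %s", i, line))
    }
    i <- i + 1L
  }

  if (is.null(relation)) abort("missing @relation declaration")
  if (length(schema) == 0L) abort("missing @attribute declarations")
  if (is.na(data_start)) abort("missing @data section")
  schema_tbl <- dplyr::bind_rows(schema)
  if (anyDuplicated(schema_tbl$name)) {
    abort("duplicate attribute name in ARFF header")
  }
  p <- nrow(schema_tbl)

  cells <- vector("list", 0L)
  for (i in seq(data_start, length.out = max(0L, n - data_start + 1L))) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "%")) next
    if (startsWith(line, "{")) {
      abort(sprintf("line %d: sparse ARFF data is not supported", i))
    }
    toks <- split_delimited(line, ",", i)
    if (length(toks) != p) {
      abort(sprintf(
        "line %d: row has %d cells, expected %d", i, length(toks), p
      ))
    }
    cells[[length(cells) + 1L]] <- toks
  }

  build_dataset_from_cells(
    relation, schema_tbl, open_domain, cells, class_index,
    line_of = function(r) data_start + r - 1L
  )
}

#' Write a dataset as ARFF text
#'
#' Emits a parseable ARFF document: tokens containing characters outside
#' `[A-Za-z0-9_.-]` (spaces, commas, or base64 characters such as `/` and
#' `=`) are single-quoted, missing cells become `?`, and numerics use the
#' shortest decimal representation that round-trips, so protected
#' thresholds like `53.8` print exactly.
#'
#' @param d A [ptd_dataset][as_dataset] (or coercible data frame).
#' @param file Optional path; when given the text is also written there.
#' @return The ARFF document as a character vector of lines, invisibly when
#'   `file` is given.
#' @export
write_arff <- function(d, file = NULL) {
  d <- as_dataset(d)
  header <- c(
    sprintf("@relation %s", quote_token(d$relation)),
    purrr::map2_chr(d$schema$name, seq_len(nrow(d$schema)), function(nm, j) {
      if (d$schema$kind[[j]] == "numeric") {
        sprintf("@attribute %s numeric", quote_token(nm))
      } else {
        sprintf(
          "@attribute %s {%s}", quote_token(nm),
          paste(vapply(d$schema$domain[[j]], quote_token, ""), collapse = ",")
        )
      }
    }),
    "@data"
  )
  rows <- character(0)
  if (nrow(d$data) > 0L) {
    cols <- purrr::map2(d$data, d$schema$kind, function(col, kind) {
      out <- if (kind == "numeric") {
        fmt_num(col)
      } else {
        vapply(col, function(x) if (is.na(x)) NA_character_ else quote_token(x), "")
      }
      ifelse(is.na(out), "?", out)
    })
    rows <- do.call(paste, c(cols, sep = ","))
  }
  out <- c(header, rows)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read a headered comma-separated flat file
#'
#' The simple comma-delimited dialect the protection method operates on:
#' first line is the header, `?` marks missing cells, no quoting. Without a
#' schema, a column whose every non-missing cell parses as a decimal number
#' is numeric; anything else is nominal with the observed token domain.
#'
#' @param file Path or text as in [read_arff()].
#' @param schema Optional schema tibble (see [attribute_spec()]); forcing a
#'   numeric-looking column to nominal stores its cells as tokens.
#' @param relation Relation name for the resulting dataset.
#' @param class_index Position of the class attribute; default last.
#' @return A [ptd_dataset][as_dataset].
#' @export
read_flat_csv <- function(file, schema = NULL, relation = "data",
                          class_index = NULL) {
  lines <- as_lines(file)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) < 1L) abort("empty flat file: no header line")
  header <- trimws(strsplit(lines[[1]], ",", fixed = TRUE)[[1]])
  p <- length(header)

  if (!is.null(schema)) {
    schema <- validate_schema_shape(schema)
    if (!identical(schema$name, header)) {
      abort("schema attribute names do not match the file header")
    }
  }

  raw <- vector("list", max(0L, length(lines) - 1L))
  for (r in seq_along(raw)) {
    toks <- trimws(strsplit(lines[[r + 1L]], ",", fixed = TRUE)[[1]])
    if (length(toks) != p) {
      abort(sprintf(
        "line %d: row has %d cells, expected %d",
        lineno[[r + 1L]], length(toks), p
      ))
    }
    raw[[r]] <- toks
  }

  if (is.null(schema)) {
    schema_rows <- purrr::map(seq_len(p), function(j) {
      col <- vapply(raw, `[[`, "", j)
      col <- col[col != "?"]
      num <- suppressWarnings(as.numeric(col))
      if (length(col) > 0L && !anyNA(num)) {
        attribute_spec(header[[j]], "numeric")
      } else {
        toks <- unique(col)
        if (length(toks) == 0L) toks <- "?"
        attribute_spec(header[[j]], "nominal", toks)
      }
    })
    schema <- dplyr::bind_rows(schema_rows)
    open <- rep(TRUE, p)
  } else {
    open <- purrr::map_lgl(schema$domain, is.null) & schema$kind == "nominal"
  }

  build_dataset_from_cells(
    relation, schema, open, raw, class_index,
    line_of = function(r) lineno[[r + 1L]]
  )
}

# internal ------------------------------------------------------------------

as_lines <- function(file) {
  if (length(file) == 1L && !grepl("\n", file, fixed = TRUE) &&
    file.exists(file)) {
    return(readLines(file, warn = FALSE))
  }
  unlist(strsplit(as.character(file), "\n", fixed = TRUE), use.names = FALSE)
}

# assembles the dataset shared by both readers; `open_domain[j]` marks
# attributes whose nominal domain is collected from the data rather than
# declared (ARFF string attributes, inferred CSV columns)
build_dataset_from_cells <- function(relation, schema, open_domain, cells,
                                     class_index, line_of) {
  p <- nrow(schema)
  n <- length(cells)
  mat <- if (n > 0L) {
    matrix(unlist(cells, use.names = FALSE), nrow = n, ncol = p, byrow = TRUE)
  } else {
    matrix(character(0), 0L, p)
  }
  cols <- vector("list", p)
  for (j in seq_len(p)) {
    col <- mat[, j]
    miss <- col == "?"
    if (schema$kind[[j]] == "numeric") {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!miss & is.na(num))
      if (length(bad) > 0L) {
        abort(sprintf(
          "line %d: '%s' is not a number for numeric attribute '%s'",
          line_of(bad[[1]]), col[bad[[1]]], schema$name[[j]]
        ))
      }
      num[miss] <- NA_real_
      cols[[j]] <- num
    } else {
      if (isTRUE(open_domain[[j]])) {
        toks <- unique(col[!miss])
        if (length(toks) == 0L) toks <- "?"
        schema$domain[[j]] <- toks
      } else {
        bad <- which(!miss & !(col %in% schema$domain[[j]]))
        if (length(bad) > 0L) {
          abort(sprintf(
            "line %d: token '%s' not in the declared domain of '%s'",
            line_of(bad[[1]]), col[bad[[1]]], schema$name[[j]]
          ))
        }
      }
      col[miss] <- NA_character_
      cols[[j]] <- col
    }
  }
  names(cols) <- schema$name
  out <- structure(
    list(
      relation = relation,
      schema = schema,
      class_index = as.integer(class_index %||% p),
      data = as_tibble(cols)
    ),
    class = "ptd_dataset"
  )
  validate_dataset(out)
}

parse_attribute_decl <- function(rest, lineno) {
  nm <- scan_token(rest, lineno)
  type <- trimws(substring(rest, nm$end + 1L))
  low <- tolower(type)
  if (low %in% c("numeric", "real", "integer")) {
    list(spec = attribute_spec(nm$token, "numeric"), open = FALSE)
  } else if (low == "string") {
    list(spec = attribute_spec(nm$token, "nominal", "?"), open = TRUE)
  } else if (startsWith(type, "{")) {
    if (!endsWith(type, "}")) {
      abort(sprintf("line %d: unterminated nominal domain", lineno))
    }
    body <- substring(type, 2L, nchar(type) - 1L)
    toks <- split_delimited(body, ",", lineno)
    if (length(toks) == 0L || any(is.na(toks))) {
      abort(sprintf("line %d: empty or invalid nominal domain", lineno))
    }
    list(spec = attribute_spec(nm$token, "nominal", toks), open = FALSE)
  } else if (startsWith(low, "date")) {
    abort(sprintf("line %d: date attributes are not supported", lineno))
  } else {
    abort(sprintf("line %d: unknown attribute type '%s'", lineno, type))
  }
}

# splits a delimited record honoring single/double quotes and backslash
# escapes; an unquoted bare ? becomes NA (the missing marker)
split_delimited <- function(line, sep, lineno) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  toks <- character(0)
  cur <- character(0)
  quoted_cur <- FALSE
  in_quote <- FALSE
  quote_char <- ""
  k <- 1L
  flush <- function() {
    tok <- paste(cur, collapse = "")
    if (!quoted_cur) {
      tok <- trimws(tok)
      if (tok == "?") tok <- NA_character_
    }
    toks[[length(toks) + 1L]] <<- tok
    cur <<- character(0)
    quoted_cur <<- FALSE
  }
  while (k <= length(chars)) {
    ch <- chars[[k]]
    if (in_quote) {
      if (ch == "\\" && k < length(chars)) {
        cur <- c(cur, chars[[k + 1L]])
        k <- k + 2L
        next
      }
      if (ch == quote_char) {
        in_quote <- FALSE
      } else {
        cur <- c(cur, ch)
      }
    } else if (ch %in% c("'", "\"") &&
      !nzchar(trimws(paste(cur, collapse = "")))) {
      in_quote <- TRUE
      quote_char <- ch
      quoted_cur <- TRUE
      cur <- character(0)
    } else if (ch == sep) {
      flush()
    } else {
      cur <- c(cur, ch)
    }
    k <- k + 1L
  }
  if (in_quote) {
    abort(sprintf("line %d: unterminated quoted token", lineno))
  }
  flush()
  toks
}

scan_token <- function(text, lineno) {
  if (startsWith(text, "'") || startsWith(text, "\"")) {
    q <- substring(text, 1L, 1L)
    body <- character(0)
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    k <- 2L
    while (k <= length(chars)) {
      if (chars[[k]] == "\\" && k < length(chars)) {
        body <- c(body, chars[[k + 1L]])
        k <- k + 2L
        next
      }
      if (chars[[k]] == q) {
        return(list(token = paste(body, collapse = ""), end = k))
      }
      body <- c(body, chars[[k]])
      k <- k + 1L
    }
    abort(sprintf("line %d: unterminated quoted name", lineno))
  }
  m <- regexpr("^[^ \t]+", text)
  list(
    token = substring(text, 1L, attr(m, "match.length")),
    end = attr(m, "match.length")
  )
}

parse_quoted <- function(text, lineno) {
  scan_token(text, lineno)$token
}

quote_token <- function(tok) {
  if (is.na(tok) || !nzchar(tok) || tok == "?" ||
    grepl("[^A-Za-z0-9_.-]", tok)) {
    inner <- gsub("\\", "\\\\", tok %||% "", fixed = TRUE)
    inner <- gsub("'", "\\'", inner, fixed = TRUE)
    sprintf("'%s'", inner)
  } else {
    tok
  }
}
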