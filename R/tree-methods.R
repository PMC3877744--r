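new_decision_rule <- function(conditions, class, class_attribute) {
  structure(
    list(
      conditions = conditions, class = class,
      class_attribute = class_attribute
    ),
    class = "decision_rule"
  )
}

format_rule <- function(rule) {
  if (nrow(rule$conditions) == 0L) {
    return(sprintf("TRUE -> %s", rule$class))
  }
  lhs <- paste(
    sprintf(
      "%s %s %s", rule$conditions$attribute, rule$conditions$op,
      rule$conditions$value
    ),
    collapse = " AND "
  )
  sprintf("%s -> %s", lhs, rule$class)
}

#' @export
print.decision_rule <- function(x, ...) {
  cat("IF", format_rule(x), "\n")
  invisible(x)
}

#' Extract the decision rules of a tree
#'
#' Walks every root-to-leaf path and emits one conjunction rule per leaf
#' (conjunct order is root-to-leaf), so the number of rules always equals
#' the leaf count.
#'
#' @param t A `c45_tree`.
#' @return A tibble with one row per rule: `rule_id`, `text` (readable
#'   conjunction), `class`, `n` (training instances at the leaf), and
#'   `rule` (a list column of `decision_rule` objects consumable by
#'   [decrypt_rule()]).
#' @export
extract_rules <- function(t) {
  stopifnot(inherits(t, "c45_tree"))
  class_attr <- t$schema$name[[t$class_index]]
  empty <- tibble(
    attribute = character(), op = character(), value = character(),
    kind = character()
  )
  rules <- list()
  walk <- function(node, conds) {
    if (node$kind == "leaf") {
      rules[[length(rules) + 1L]] <<- new_decision_rule(
        conds,
        node$class, class_attr
      )
      return(invisible())
    }
    for (b in seq_along(node$children)) {
      step <- if (node$kind == "numeric") {
        tibble(
          attribute = node$attribute,
          op = if (b == 1L) "<=" else ">",
          value = fmt_num(node$threshold), kind = "numeric"
        )
      } else {
        tibble(
          attribute = node$attribute, op = "=",
          value = node$branch_tokens[[b]], kind = "nominal"
        )
      }
      walk(node$children[[b]], dplyr::bind_rows(conds, step))
    }
  }
  walk(t$root, empty)
  tibble(
    rule_id = seq_along(rules),
    text = purrr::map_chr(rules, format_rule),
    class = purrr::map_chr(rules, "class"),
    n = NA_integer_,
    rule = rules
  ) |>
    fill_rule_support(t)
}

fill_rule_support <- function(rules_tbl, t) {
  support <- integer(0)
  walk <- function(node) {
    if (node$kind == "leaf") {
      support[length(support) + 1L] <<- node$n
      return(invisible())
    }
    for (ch in node$children) walk(ch)
  }
  walk(t$root)
  rules_tbl$n <- support
  rules_tbl
}

# indented text rendering in the familiar J48 style
format_node <- function(node, depth = 0L) {
  pad <- strrep("|   ", depth)
  if (node$kind == "leaf") {
    err <- if (node$n == 0L) 0L else node$n - max(node$counts)
    return(sprintf(": %s (%d/%d)", node$class, node$n, err))
  }
  out <- character(0)
  for (b in seq_along(node$children)) {
    label <- if (node$kind == "numeric") {
      sprintf(
        "%s %s %s", node$attribute, if (b == 1L) "<=" else ">",
        fmt_num(node$threshold)
      )
    } else {
      sprintf("%s = %s", node$attribute, node$branch_tokens[[b]])
    }
    child <- node$children[[b]]
    rendered <- format_node(child, depth + 1L)
    if (child$kind == "leaf") {
      out <- c(out, paste0(pad, label, rendered))
    } else {
      out <- c(out, paste0(pad, label), rendered)
    }
  }
  out
}

#' @export
format.c45_tree <- function(x, ...) {
  m <- tree_metrics(x)
  body <- if (x$root$kind == "leaf") {
    sub("^: ", "", format_node(x$root))
  } else {
    format_node(x$root)
  }
  c(body, "", sprintf("Number of Leaves  : %d", m$leaves),
    sprintf("Size of the tree : %d", m$size))
}

#' @export
print.c45_tree <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}

#' Flatten a tree into a node table
#'
#' One row per node: identifier, parent, depth, node kind, split attribute
#' and threshold (numeric splits), incoming branch token (children of
#' nominal splits), predicted class, and training mass. This is also the
#' machine-readable serialization written by [write_tree()].
#'
#' @param x A `c45_tree`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy c45_tree
#' @export
tidy.c45_tree <- function(x, ...) {
  rows <- list()
  walk <- function(node, parent, branch, depth) {
    id <- length(rows) + 1L
    kind <- node$kind
    attribute <- if (kind == "leaf") NA_character_ else node$attribute
    threshold <- if (identical(kind, "numeric")) node$threshold else NA_real_
    cls <- node$class
    n <- node$n
    counts <- list(setNames(node$counts, NULL))
    rows[[id]] <<- tibble(
      node = id, parent = parent, depth = depth, branch = branch,
      kind = kind, attribute = attribute, threshold = threshold,
      class = cls, n = n, counts = counts
    )
    if (node$kind != "leaf") {
      for (b in seq_along(node$children)) {
        lab <- if (node$kind == "numeric") {
          if (b == 1L) "<=" else ">"
        } else {
          node$branch_tokens[[b]]
        }
        walk(node$children[[b]], id, lab, depth + 1L)
      }
    }
  }
  walk(x$root, NA_integer_, NA_character_, 0L)
  dplyr::bind_rows(rows)
}

#' One-row summary of a tree
#'
#' @param x A `c45_tree`.
#' @param ... Unused.
#' @return A tibble with `size`, `leaves`, `depth`, and `n_train`.
#' @method glance c45_tree
#' @export
glance.c45_tree <- function(x, ...) {
  nodes <- tidy(x)
  m <- tree_metrics(x)
  tibble(
    size = m$size, leaves = m$leaves,
    depth = max(nodes$depth), n_train = x$root$n
  )
}

#' Serialize / restore a tree as delimited text
#'
#' The store is one node per record (tab-separated), preceded by metadata
#' lines recording the schema, class attribute and class domain, so an
#' analyst-side tree file can be shipped back to the owner and its rules
#' decrypted.
#'
#' @param t A `c45_tree`.
#' @param file Path.
#' @return `write_tree()` returns `file` invisibly; `read_tree()` the
#'   restored `c45_tree`.
#' @export
write_tree <- function(t, file) {
  stopifnot(inherits(t, "c45_tree"))
  nodes <- tidy(t)
  meta <- c(
    sprintf(
      "#schema\t%s", paste(sprintf(
        "%s:%s", t$schema$name, t$schema$kind
      ), collapse = "\t")
    ),
    sprintf("#class_index\t%d", t$class_index),
    sprintf("#class_domain\t%s", paste(t$class_domain, collapse = "\t"))
  )
  recs <- sprintf(
    "%d\t%s\t%s\t%s\t%s\t%s\t%s\t%d\t%s",
    nodes$node, ifelse(is.na(nodes$parent), "", nodes$parent),
    ifelse(is.na(nodes$branch), "", nodes$branch), nodes$kind,
    ifelse(is.na(nodes$attribute), "", nodes$attribute),
    ifelse(is.na(nodes$threshold), "", fmt_num(nodes$threshold)),
    nodes$class, nodes$n,
    vapply(nodes$counts, function(cc) paste(cc, collapse = ","), "")
  )
  writeLines(c(meta, "node\tparent\tbranch\tkind\tattribute\tthreshold\tclass\tn\tcounts", recs), file)
  invisible(file)
}

#' @rdname write_tree
#' @export
read_tree <- function(file) {
  lines <- as_lines(file)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) < 2L) abort("malformed tree store")
  schema_parts <- strsplit(sub("^#schema\t", "", meta[startsWith(meta, "#schema")]), "\t")[[1]]
  class_index <- as.integer(sub("^#class_index\t", "", meta[startsWith(meta, "#class_index")]))
  class_domain <- strsplit(sub("^#class_domain\t", "", meta[startsWith(meta, "#class_domain")]), "\t")[[1]]
  schema <- dplyr::bind_rows(purrr::map(schema_parts, function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (kv[[2]] == "numeric") {
      attribute_spec(kv[[1]], "numeric")
    } else {
      attribute_spec(kv[[1]], "nominal", "?") # domains not needed for decryption
    }
  }))

  recs <- strsplit(body[-1L], "\t", fixed = TRUE)
  recs <- lapply(recs, function(r) c(r, rep("", 9L - length(r)))[1:9])
  mat <- do.call(rbind, recs)
  ids <- as.integer(mat[, 1L])
  parents <- suppressWarnings(as.integer(mat[, 2L]))

  build <- function(id) {
    r <- which(ids == id)
    kind <- mat[r, 4L]
    counts <- as.integer(strsplit(mat[r, 9L], ",", fixed = TRUE)[[1]])
    node <- list(
      kind = kind, counts = counts, n = as.integer(mat[r, 8L]),
      class = mat[r, 7L], class_idx = match(mat[r, 7L], class_domain)
    )
    if (kind != "leaf") {
      kid_ids <- ids[which(parents == id)]
      node$attribute <- mat[r, 5L]
      node$attr_index <- match(mat[r, 5L], schema$name)
      node$children <- lapply(kid_ids, build)
      if (kind == "numeric") {
        node$threshold <- as.numeric(mat[r, 6L])
      } else {
        node$branch_tokens <- mat[match(kid_ids, ids), 3L]
      }
      node$branch_mass <- vapply(node$children, function(ch) ch$n, integer(1))
    }
    node
  }

  structure(
    list(
      root = build(ids[[1L]]), schema = schema, class_index = class_index,
      class_domain = class_domain, config = inducer_config()
    ),
    class = "c45_tree"
  )
}

#' Plot an induced decision tree
#'
#' A compact dendrogram-style rendering: internal nodes show their split
#' attribute, edges their branch condition, leaves their class and
#' training mass.
#'
#' @param object A `c45_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot c45_tree
#' @export
autoplot.c45_tree <- function(object, ...) {
  nodes <- tidy(object)
  # x position: leaves spread uniformly, internals centered over children
  leaf_ids <- nodes$node[nodes$kind == "leaf"]
  xpos <- setNames(rep(NA_real_, nrow(nodes)), nodes$node)
  xpos[as.character(leaf_ids)] <- seq_along(leaf_ids)
  for (id in rev(nodes$node)) {
    if (is.na(xpos[[as.character(id)]])) {
      kids <- nodes$node[which(nodes$parent == id)]
      xpos[[as.character(id)]] <- mean(xpos[as.character(kids)])
    }
  }
  nodes$x <- unname(xpos[as.character(nodes$node)])
  nodes$y <- -nodes$depth
  nodes$label <- ifelse(
    nodes$kind == "leaf",
    sprintf("%s\n(n=%d)", nodes$class, nodes$n),
    ifelse(
      nodes$kind == "numeric",
      sprintf("%s <= %s ?", nodes$attribute, fmt_num(nodes$threshold)),
      nodes$attribute
    )
  )
  edges <- nodes[!is.na(nodes$parent), ]
  edges$xend <- nodes$x[match(edges$parent, nodes$node)]
  edges$yend <- nodes$y[match(edges$parent, nodes$node)]

  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      colour = "grey60"
    ) +
    ggplot2::geom_label(
      ggplot2::aes(label = .data$label, fill = .data$kind == "leaf"),
      size = 3, show.legend = FALSE
    ) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d8ecd4", `FALSE` = "white")) +
    ggplot2::theme_void()
}
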