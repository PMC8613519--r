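# Class expressions for the Manchester-syntax subset used in semantic
# phenotype axioms: atomic classes, intersection ('and'), complement ('not'),
# existential restriction ('some'), and exact cardinality ('exactly n').
#
# Expressions are canonical by construction: nested intersections are
# flattened and operands ordered by a registry-free structural key, so that
# parse(serialize(e)) is identical() to e and identical serializations imply
# identical trees.

MANCHESTER_KEYWORDS <- c("and", "not", "some", "exactly")
UNSUPPORTED_KEYWORDS <- c("min", "max", "only", "value", "or")

#' Class-expression constructors
#'
#' @param term,property CURIEs of a class / object property.
#' @param operands list of class expressions (`ce_and`).
#' @param operand a single class expression (`ce_not`).
#' @param filler filler class expression (`ce_some`, `ce_exactly`).
#' @param n non-negative integer cardinality.
#' @return A `phenokg_expr` list with a `node_kind` field.
#' @export
ce_atomic <- function(term) {
  structure(list(node_kind = "atomic", term = term), class = "phenokg_expr")
}

#' @rdname ce_atomic
#' @export
ce_and <- function(operands) {
  flat <- list()
  for (op in operands) {
    stopifnot(inherits(op, "phenokg_expr"))
    if (op$node_kind == "and") flat <- c(flat, op$operands) else flat <- c(flat, list(op))
  }
  if (length(flat) == 1) return(flat[[1]])
  if (length(flat) < 2) {
    stop_phenokg("phenokg_domain_error", "intersection needs at least two operands")
  }
  keys <- vapply(flat, expr_key, character(1))
  structure(list(node_kind = "and", operands = flat[order(keys, method = "radix")]),
            class = "phenokg_expr")
}

#' @rdname ce_atomic
#' @export
ce_not <- function(operand) {
  stopifnot(inherits(operand, "phenokg_expr"))
  structure(list(node_kind = "not", operand = operand), class = "phenokg_expr")
}

#' @rdname ce_atomic
#' @export
ce_some <- function(property, filler) {
  stopifnot(inherits(filler, "phenokg_expr"))
  structure(list(node_kind = "some", property = property, filler = filler),
            class = "phenokg_expr")
}

#' @rdname ce_atomic
#' @export
ce_exactly <- function(property, n, filler) {
  stopifnot(inherits(filler, "phenokg_expr"))
  if (length(n) != 1 || is.na(n) || n < 0 || n != as.integer(n)) {
    stop_phenokg("phenokg_domain_error", "cardinality must be a non-negative integer")
  }
  structure(list(node_kind = "exactly", property = property, n = as.integer(n),
                 filler = filler),
            class = "phenokg_expr")
}

# Registry-free canonical key; determines 'and'-operand order.
expr_key <- function(e) {
  switch(e$node_kind,
    atomic  = e$term,
    and     = paste0("(", paste(vapply(e$operands, expr_key, character(1)),
                                collapse = " & "), ")"),
    not     = paste0("!(", expr_key(e$operand), ")"),
    some    = paste0("[", e$property, " some ", expr_key(e$filler), "]"),
    exactly = paste0("[", e$property, " exactly ", e$n, " ", expr_key(e$filler), "]"))
}

expr_nodes <- function(e) {
  1L + switch(e$node_kind,
    atomic  = 0L,
    and     = sum(vapply(e$operands, expr_nodes, integer(1))),
    not     = expr_nodes(e$operand),
    some    = expr_nodes(e$filler),
    exactly = expr_nodes(e$filler))
}

# all curies referenced by an expression
expr_curies <- function(e) {
  switch(e$node_kind,
    atomic  = e$term,
    and     = unique(unlist(lapply(e$operands, expr_curies))),
    not     = expr_curies(e$operand),
    some    = unique(c(e$property, expr_curies(e$filler))),
    exactly = unique(c(e$property, expr_curies(e$filler))))
}

# --- tokenizer --------------------------------------------------------------

manchester_tokens <- function(text, registry) {
  text <- gsub("[ \t\r\n]+", " ", text)
  text <- sub("^ ", "", sub(" $", "", text))
  if (!nzchar(text)) stop_syntax("empty expression")
  labels <- registry_label_table(registry)
  labels <- labels[order(-nchar(labels$label), labels$label, method = "radix"), , drop = FALSE]

  is_boundary <- function(pos) {
    pos > nchar(text) || substring(text, pos, pos) %in% c(" ", "(", ")")
  }
  tokens <- list()
  push <- function(type, value, at) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, at = at)
  }
  pos <- 1L
  expect_integer <- FALSE
  while (pos <= nchar(text)) {
    ch <- substring(text, pos, pos)
    if (ch == " ") { pos <- pos + 1L; next }
    if (ch == "(") { push("lparen", "(", pos); pos <- pos + 1L; next }
    if (ch == ")") { push("rparen", ")", pos); pos <- pos + 1L; next }
    if (expect_integer) {
      m <- regexpr("^[0-9]+", substring(text, pos))
      if (m < 0) stop_syntax("'exactly' must be followed by an integer", pos)
      val <- regmatches(substring(text, pos), m)
      push("integer", as.integer(val), pos)
      pos <- pos + nchar(val)
      expect_integer <- FALSE
      next
    }
    matched <- FALSE
    for (kw in c(MANCHESTER_KEYWORDS, UNSUPPORTED_KEYWORDS)) {  # keyword-first
      if (startsWith(substring(text, pos), kw) && is_boundary(pos + nchar(kw))) {
        if (kw %in% UNSUPPORTED_KEYWORDS) {
          stop_syntax(sprintf("keyword '%s' is not part of the supported subset", kw), pos)
        }
        push("keyword", kw, pos)
        if (kw == "exactly") expect_integer <- TRUE
        pos <- pos + nchar(kw)
        matched <- TRUE
        break
      }
    }
    if (matched) next
    for (k in seq_len(nrow(labels))) {       # labels longest-first, case-sensitive
      lb <- labels$label[k]
      if (startsWith(substring(text, pos), lb) && is_boundary(pos + nchar(lb))) {
        push(if (labels$kind[k] == "object-property") "property" else "class",
             labels$curie[k], pos)
        pos <- pos + nchar(lb)
        matched <- TRUE
        break
      }
    }
    if (matched) next
    bad <- sub(" .*$", "", substring(text, pos))
    bad <- sub("\\).*$", "", bad)
    stop_phenokg("phenokg_unknown_term_error",
                 sprintf("token '%s' (position %d) is neither a keyword nor a registry label",
                         bad, pos),
                 token = bad)
  }
  tokens
}

# --- parser -----------------------------------------------------------------

#' Parse a Manchester-syntax class expression
#'
#' Supports parentheses, `and` (flattened, canonically ordered), `not`,
#' `some`, and `exactly <n>`. Atomic tokens are matched against registry
#' labels (multi-word allowed, longest match first, case-sensitive); keywords
#' win over labels. `min`/`max`/`only`/`value`/`or` are rejected explicitly.
#'
#' @param text expression text; whitespace-insensitive.
#' @param registry a `phenokg_registry` supplying the label vocabulary.
#' @return A canonical `phenokg_expr`.
#' @export
#' @examples
#' reg <- build_fixture_registry()
#' e <- parse_manchester("not ( has part some ovipositor )", reg)
#' e$node_kind
parse_manchester <- function(text, registry) {
  tokens <- manchester_tokens(text, registry)
  i <- 1L
  peek <- function() if (i <= length(tokens)) tokens[[i]] else NULL
  take <- function() { t <- peek(); i <<- i + 1L; t }

  parse_term <- function() {
    tok <- peek()
    if (is.null(tok)) stop_syntax("unexpected end of expression")
    if (tok$type == "lparen") {
      take()
      inner <- parse_expr()
      close <- take()
      if (is.null(close) || close$type != "rparen") {
        stop_syntax("unbalanced parentheses: missing ')'", tok$at)
      }
      return(inner)
    }
    if (tok$type == "keyword" && tok$value == "not") {
      take()
      return(ce_not(parse_term()))
    }
    if (tok$type == "class") {
      take()
      return(ce_atomic(tok$value))
    }
    if (tok$type == "property") {
      take()
      kw <- take()
      if (is.null(kw) || kw$type != "keyword" || !(kw$value %in% c("some", "exactly"))) {
        stop_syntax(sprintf("property '%s' must be followed by 'some' or 'exactly'",
                            resolve_term_label_safe(registry, tok$value)), tok$at)
      }
      if (kw$value == "some") {
        return(ce_some(tok$value, parse_term()))
      }
      card <- take()
      if (is.null(card) || card$type != "integer") {
        stop_syntax("'exactly' must be followed by an integer", kw$at)
      }
      return(ce_exactly(tok$value, card$value, parse_term()))
    }
    if (tok$type == "rparen") stop_syntax("unbalanced parentheses: unexpected ')'", tok$at)
    stop_syntax(sprintf("unexpected token '%s'", tok$value), tok$at)
  }

  parse_expr <- function() {
    ops <- list(parse_term())
    while (!is.null(peek()) && peek()$type == "keyword" && peek()$value == "and") {
      take()
      ops[[length(ops) + 1L]] <- parse_term()
    }
    if (length(ops) == 1) ops[[1]] else ce_and(ops)
  }

  out <- parse_expr()
  left <- peek()
  if (!is.null(left)) {
    if (left$type == "rparen") stop_syntax("unbalanced parentheses: unexpected ')'", left$at)
    stop_syntax(sprintf("trailing input at position %d", left$at), left$at)
  }
  out
}

resolve_term_label_safe <- function(registry, curie) {
  if (term_exists(registry, curie)) registry$terms[[curie]]$label else curie
}

#' Serialize a class expression to canonical Manchester text
#'
#' Single spaces, parentheses around every non-atomic operand; labels come
#' from the registry. Parsing the result yields a structurally identical
#' expression.
#'
#' @param expr a `phenokg_expr`.
#' @param registry a `phenokg_registry`; every referenced CURIE must resolve.
#' @return Expression text.
#' @export
serialize_manchester <- function(expr, registry) {
  lbl <- function(curie) resolve_term(registry, curie)$label
  wrap <- function(e) {
    s <- ser(e)
    if (e$node_kind == "atomic") s else paste0("( ", s, " )")
  }
  ser <- function(e) {
    switch(e$node_kind,
      atomic  = lbl(e$term),
      and     = paste(vapply(e$operands, wrap, character(1)), collapse = " and "),
      not     = paste("not", wrap(e$operand)),
      some    = paste(lbl(e$property), "some", wrap(e$filler)),
      exactly = paste(lbl(e$property), "exactly", e$n, wrap(e$filler)))
  }
  ser(expr)
}

#' @export
print.phenokg_expr <- function(x, ...) {
  cat("<phenokg_expr>", expr_key(x), "\n")
  invisible(x)
}

# --- JSON AST export --------------------------------------------------------

expr_to_list <- function(e) {
  switch(e$node_kind,
    atomic  = list(node_kind = "atomic", term = e$term),
    and     = list(node_kind = "and", operands = lapply(e$operands, expr_to_list)),
    not     = list(node_kind = "not", operand = expr_to_list(e$operand)),
    some    = list(node_kind = "some", property = e$property,
                   filler = expr_to_list(e$filler)),
    exactly = list(node_kind = "exactly", property = e$property,
                   cardinality = e$n, filler = expr_to_list(e$filler)))
}

#' Export / import a class-expression AST as JSON
#'
#' Node objects carry `node_kind` plus `term`, `operands`, `operand`,
#' `property`, `cardinality`, and `filler` fields as applicable; intended for
#' debugging and comparison against external oracles.
#'
#' @param expr a `phenokg_expr`.
#' @param file optional path.
#' @return JSON text for `expr_to_json`; a `phenokg_expr` for `expr_from_json`.
#' @export
expr_to_json <- function(expr, file = NULL) {
  txt <- jsonlite::toJSON(expr_to_list(expr), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @param json JSON text or file path.
#' @rdname expr_to_json
#' @export
expr_from_json <- function(json) {
  if (length(json) == 1 && !grepl("[{]", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  from_list <- function(x) {
    switch(x$node_kind,
      atomic  = ce_atomic(x$term),
      and     = ce_and(lapply(x$operands, from_list)),
      not     = ce_not(from_list(x$operand)),
      some    = ce_some(x$property, from_list(x$filler)),
      exactly = ce_exactly(x$property, x$cardinality, from_list(x$filler)))
  }
  from_list(jsonlite::fromJSON(json, simplifyVector = FALSE))
}
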