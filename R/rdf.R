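# Minimal RDF triple/quad layer.
#
# Statements are kept in plain data frames with columns
#   g      graph URI (NA for plain triples / default graph)
#   s      subject URI
#   p      predicate URI
#   o      object: a URI or the lexical form of a literal
#   o_kind one of "iri", "string", "decimal", "integer"
# Serialization is deliberately one-statement-per-line Turtle/TriG (no ';'/','
# abbreviation): output is byte-stable under canonical ordering, and the
# bundled parser only has to cover what the writer emits. The parser also
# reads ';'-free output of other tools as long as it sticks to IRIs, prefixed
# names, and plain/typed string literals.

XSD_DECIMAL <- "http://www.w3.org/2001/XMLSchema#decimal"
XSD_INTEGER <- "http://www.w3.org/2001/XMLSchema#integer"

#' Build an RDF statement table
#'
#' @param s,p,o character vectors of subject, predicate, object.
#' @param o_kind object kind: `"iri"`, `"string"`, `"decimal"` or `"integer"`.
#' @param g graph URI, `NA` for the default graph / plain triples.
#' @return A data frame with columns `g`, `s`, `p`, `o`, `o_kind`.
#' @export
rdf_statements <- function(s = character(), p = character(), o = character(),
                           o_kind = "iri", g = NA_character_) {
  n <- max(length(s), length(p), length(o))
  data.frame(g = rep_len(as.character(g), n),
             s = rep_len(as.character(s), n),
             p = rep_len(as.character(p), n),
             o = rep_len(as.character(o), n),
             o_kind = rep_len(as.character(o_kind), n),
             stringsAsFactors = FALSE)
}

rdf_empty <- function() rdf_statements()

rdf_bind <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0) return(rdf_empty())
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

# Locale-independent canonical ordering (graph, subject, predicate, object).
rdf_canonical <- function(df) {
  if (nrow(df) == 0) return(df)
  df <- unique(df)
  key_g <- ifelse(is.na(df$g), "", df$g)
  ord <- order(key_g, df$s, df$p, df$o_kind, df$o, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

rdf_drop_graph <- function(df) {
  df$g <- NA_character_
  rdf_canonical(df)
}

#' Set equality of two statement tables
#'
#' Compares after canonicalization (deduplication plus locale-independent
#' ordering), so row order and duplicates do not matter.
#'
#' @param a,b statement tables (see [rdf_statements()]).
#' @export
rdf_equal <- function(a, b) {
  identical(rdf_canonical(a), rdf_canonical(b))
}

# --- URI <-> CURIE ----------------------------------------------------------

curie_to_uri <- function(curie, prefix_map) {
  parts <- strsplit(curie, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2 || !(parts[1] %in% names(prefix_map))) {
    stop_lookup(curie)
  }
  paste0(prefix_map[[parts[1]]], paste(parts[-1], collapse = ":"))
}

uri_to_curie <- function(uri, prefix_map) {
  bases <- unlist(prefix_map)
  hit <- which(startsWith(uri, bases))
  if (length(hit) == 0) return(NA_character_)
  best <- hit[which.max(nchar(bases[hit]))]
  local <- substring(uri, nchar(bases[best]) + 1L)
  if (!grepl("^[A-Za-z0-9_.-]+$", local)) return(NA_character_)
  paste0(names(bases)[best], ":", local)
}

# --- writers ----------------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

format_term <- function(x, kind, prefix_map) {
  if (kind == "iri") {
    curie <- uri_to_curie(x, prefix_map)
    if (!is.na(curie)) curie else paste0("<", x, ">")
  } else if (kind == "string") {
    paste0("\"", escape_literal(x), "\"")
  } else if (kind == "decimal") {
    paste0("\"", x, "\"^^", format_term(XSD_DECIMAL, "iri", prefix_map))
  } else if (kind == "integer") {
    paste0("\"", x, "\"^^", format_term(XSD_INTEGER, "iri", prefix_map))
  } else {
    stop_phenokg("phenokg_domain_error", sprintf("unknown object kind '%s'", kind))
  }
}

prefix_header <- function(prefix_map) {
  pm <- prefix_map[order(names(prefix_map), method = "radix")]
  sprintf("@prefix %s: <%s> .", names(pm), unlist(pm))
}

statement_lines <- function(df, prefix_map, indent = "") {
  if (nrow(df) == 0) return(character())
  vapply(seq_len(nrow(df)), function(i) {
    paste0(indent,
           format_term(df$s[i], "iri", prefix_map), " ",
           format_term(df$p[i], "iri", prefix_map), " ",
           format_term(df$o[i], df$o_kind[i], prefix_map), " .")
  }, character(1))
}

#' Serialize plain triples as Turtle
#'
#' Graph components are ignored. Output is canonically ordered and
#' byte-stable for a given statement set and prefix map.
#'
#' @param df statement table (see [rdf_statements()]).
#' @param prefix_map named character vector, prefix to IRI base.
#' @param file optional path; when given, the text is written there.
#' @return The Turtle text, invisibly when `file` is given.
#' @export
write_turtle <- function(df, prefix_map, file = NULL) {
  df <- rdf_canonical(df)
  txt <- paste(c(prefix_header(prefix_map), "", statement_lines(df, prefix_map)),
               collapse = "\n")
  txt <- paste0(txt, "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Serialize quads as TriG
#'
#' Statements with `NA` graph go to the default graph; the rest are grouped
#' into `GRAPH <uri> { ... }`-style blocks, ordered canonically.
#'
#' @inheritParams write_turtle
#' @export
write_trig <- function(df, prefix_map, file = NULL) {
  df <- rdf_canonical(df)
  out <- prefix_header(prefix_map)
  dflt <- df[is.na(df$g), , drop = FALSE]
  if (nrow(dflt) > 0) out <- c(out, "", statement_lines(dflt, prefix_map))
  for (g in unique(df$g[!is.na(df$g)])) {
    block <- df[!is.na(df$g) & df$g == g, , drop = FALSE]
    out <- c(out, "",
             paste0(format_term(g, "iri", prefix_map), " {"),
             statement_lines(block, prefix_map, indent = "    "),
             "}")
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Serialize quads as N-Quads
#'
#' @inheritParams write_turtle
#' @export
write_nquads <- function(df, file = NULL) {
  df <- rdf_canonical(df)
  none <- character(0)
  lines <- vapply(seq_len(nrow(df)), function(i) {
    obj <- format_term(df$o[i], df$o_kind[i], none)
    gpart <- if (is.na(df$g[i])) "" else paste0(" <", df$g[i], ">")
    paste0("<", df$s[i], "> <", df$p[i], "> ", obj, gpart, " .")
  }, character(1))
  txt <- paste0(paste(lines, collapse = "\n"), if (nrow(df) > 0) "\n" else "")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

# --- parser -----------------------------------------------------------------

tokenize_rdf <- function(text) {
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  push <- function(type, value) tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  while (pos <= n) {
    ch <- substring(text, pos, pos)
    if (grepl("^[ \t\r\n]$", ch)) { pos <- pos + 1L; next }
    rest <- substring(text, pos)
    if (ch == "#") {                      # comment to end of line
      nl <- regexpr("\n", rest, fixed = TRUE)
      pos <- if (nl < 0) n + 1L else pos + nl
      next
    }
    if (ch == "<") {
      m <- regexpr("^<([^>]*)>", rest)
      if (m < 0) stop_syntax("unterminated IRI", pos)
      push("iri", sub("^<([^>]*)>.*$", "\\1", regmatches(rest, m)))
      pos <- pos + attr(m, "match.length")
      next
    }
    if (ch == "\"") {
      m <- regexpr('^"((?:[^"\\\\]|\\\\.)*)"', rest)
      if (m < 0) stop_syntax("unterminated literal", pos)
      raw <- sub('^"((?:[^"\\\\]|\\\\.)*)".*$', "\\1", regmatches(rest, m))
      raw <- gsub("\\n", "\n", raw, fixed = TRUE)
      raw <- gsub("\\\"", "\"", raw, fixed = TRUE)
      raw <- gsub("\\\\", "\\", raw, fixed = TRUE)
      push("literal", raw)
      pos <- pos + attr(m, "match.length")
      next
    }
    if (startsWith(rest, "^^")) { push("datatype_marker", "^^"); pos <- pos + 2L; next }
    if (ch %in% c(".", "{", "}", ";", ",")) { push(ch, ch); pos <- pos + 1L; next }
    if (startsWith(rest, "@prefix")) { push("at_prefix", "@prefix"); pos <- pos + 7L; next }
    m <- regexpr("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*", rest)
    if (m > 0) {
      push("pname", regmatches(rest, m))
      pos <- pos + attr(m, "match.length")
      next
    }
    m <- regexpr("^[A-Za-z][A-Za-z0-9_-]*", rest)
    if (m > 0) {                           # bare word, e.g. 'a' or PREFIX
      push("word", regmatches(rest, m))
      pos <- pos + attr(m, "match.length")
      next
    }
    stop_syntax(sprintf("unexpected character '%s'", ch), pos)
  }
  tokens
}

parse_rdf_text <- function(text) {
  tokens <- tokenize_rdf(text)
  prefixes <- character(0)
  i <- 1L
  ntok <- length(tokens)
  peek <- function() if (i <= ntok) tokens[[i]] else NULL
  take <- function() { t <- peek(); i <<- i + 1L; t }

  resolve_iri <- function(tok) {
    if (tok$type == "iri") return(tok$value)
    if (tok$type == "word" && tok$value == "a") {
      return("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
    }
    if (tok$type == "pname") {
      parts <- strsplit(tok$value, ":", fixed = TRUE)[[1]]
      pfx <- parts[1]
      if (!(pfx %in% names(prefixes))) stop_syntax(sprintf("undeclared prefix '%s'", pfx))
      return(paste0(prefixes[[pfx]], if (length(parts) > 1) parts[2] else ""))
    }
    stop_syntax(sprintf("expected IRI, got %s", tok$type))
  }

  read_object <- function() {
    tok <- take()
    if (tok$type == "literal") {
      kind <- "string"
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "datatype_marker") {
        take()
        dt <- resolve_iri(take())
        kind <- if (dt == XSD_DECIMAL) "decimal"
                else if (dt == XSD_INTEGER) "integer"
                else "string"
      }
      list(o = tok$value, o_kind = kind)
    } else {
      list(o = resolve_iri(tok), o_kind = "iri")
    }
  }

  rows <- vector("list", 0L)
  read_triple_block <- function(graph) {
    # one subject with ';'/',' continuation, terminated by '.'
    s <- resolve_iri(take())
    repeat {
      p <- resolve_iri(take())
      repeat {
        obj <- read_object()
        rows[[length(rows) + 1L]] <<- data.frame(
          g = graph, s = s, p = p, o = obj$o, o_kind = obj$o_kind,
          stringsAsFactors = FALSE)
        nxt <- peek()
        if (!is.null(nxt) && nxt$type == ",") { take(); next }
        break
      }
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == ";") { take(); next }
      break
    }
    nxt <- take()
    if (is.null(nxt) || nxt$type != ".") stop_syntax("expected '.' after statement")
  }

  while (!is.null(peek())) {
    tok <- peek()
    if (tok$type == "at_prefix" || (tok$type == "word" && toupper(tok$value) == "PREFIX")) {
      is_sparql <- tok$type == "word"
      take()
      pn <- take()
      if (pn$type != "pname") stop_syntax("expected prefix name in @prefix")
      base <- take()
      if (base$type != "iri") stop_syntax("expected IRI in @prefix")
      prefixes[sub(":$", "", sub(":.*$", "", pn$value))] <- base$value
      if (!is_sparql) {
        dot <- take()
        if (is.null(dot) || dot$type != ".") stop_syntax("expected '.' after @prefix")
      }
      next
    }
    # graph block?  <iri> { ... }   or plain triple in default graph
    if (tok$type %in% c("iri", "pname", "word")) {
      save_i <- i
      head_iri <- tryCatch(resolve_iri(take()), error = function(e) NULL)
      nxt <- peek()
      if (!is.null(head_iri) && !is.null(nxt) && nxt$type == "{") {
        take()
        while (!is.null(peek()) && peek()$type != "}") read_triple_block(head_iri)
        if (is.null(peek())) stop_syntax("unterminated graph block")
        take()
        next
      }
      i <- save_i
      read_triple_block(NA_character_)
      next
    }
    stop_syntax(sprintf("unexpected token '%s'", tok$value))
  }

  out <- if (length(rows) == 0) rdf_empty() else do.call(rbind, rows)
  rdf_canonical(out)
}

#' Parse Turtle text or file
#'
#' Covers the subset this package writes: `@prefix` declarations, IRIs,
#' prefixed names, plain and `^^`-typed string literals, `;`/`,`
#' continuations, and (for TriG) `<graph> { ... }` blocks.
#'
#' @param x Turtle/TriG text, or a path to a file containing it.
#' @return A canonical statement table (see [rdf_statements()]).
#' @export
read_turtle <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  parse_rdf_text(paste(x, collapse = "\n"))
}

#' @rdname read_turtle
#' @export
read_trig <- read_turtle

# --- misc -------------------------------------------------------------------

# djb2 string hash; used for deterministic URIs derived from canonical
# serializations (stable across sessions and platforms).
string_hash <- function(x) {
  h <- 5381
  for (code in utf8ToInt(x)) {
    h <- (h * 33 + code) %% 4294967296
  }
  # split into two 16-bit halves: sprintf("%x") needs integers
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

format_decimal <- function(value) {
  s <- format(value, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  if (!grepl("\\.", s)) s <- paste0(s, ".0")
  s
}
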