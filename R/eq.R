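# Entity-Quality (EQ) phenotype statements and their compilation to / from
# class expressions.
#
# Composition schemes (E = entity, Q = quality, RE = related entity,
# C = count):
#   E + Q     ->  has part some ( E and ( bearer of some Q ) )
#   E alone   ->  has part some E
#   E(QRE)    ->  has part some ( E and ( bearer of some
#                   ( Q and ( <rel> some RE ) ) ) )
#                 with <rel> defaulting to 'increased in magnitude relative to'
#   E(QC)     ->  has component exactly C E, conjoined with the plain scheme
#                 when a quality is present
#
# The optional EAV attribute is carried on the statement but not compiled
# into the expression: with hierarchically organized quality terms the
# attribute is the quality's parent (red implies color), so it is recoverable
# from the registry rather than from the tree.

#' Construct an EQ statement
#'
#' @param entity CURIE of the bearer entity (required).
#' @param quality CURIE of the quality, or `NULL`.
#' @param attribute CURIE of the EAV attribute (e.g. color for red), or `NULL`.
#' @param related_entity CURIE of the related entity (relational qualities),
#'   or `NULL`; requires `quality` and excludes `count`.
#' @param count non-negative integer part count, or `NULL`; excludes
#'   `related_entity`.
#' @return An `phenokg_eq` list.
#' @export
#' @examples
#' eq_statement("MA:0000261", "PATO:0000322")   # eye + red
eq_statement <- function(entity, quality = NULL, attribute = NULL,
                         related_entity = NULL, count = NULL) {
  if (is.null(entity)) {
    stop_phenokg("phenokg_domain_error", "EQ statement requires an entity")
  }
  if (!is.null(related_entity) && is.null(quality)) {
    stop_phenokg("phenokg_domain_error",
                 "related entity requires a quality to relate through")
  }
  if (!is.null(related_entity) && !is.null(count)) {
    stop_phenokg("phenokg_domain_error",
                 "count and related entity are mutually exclusive")
  }
  if (!is.null(count) && (count < 0 || count != as.integer(count))) {
    stop_phenokg("phenokg_domain_error", "count must be a non-negative integer")
  }
  structure(list(entity = entity, quality = quality, attribute = attribute,
                 related_entity = related_entity,
                 count = if (is.null(count)) NULL else as.integer(count)),
            class = "phenokg_eq")
}

#' Compile an EQ statement to a class expression
#'
#' @param eq an `phenokg_eq`.
#' @param registry a `phenokg_registry`; all CURIEs must resolve.
#' @param relating_property property used for the related-entity scheme;
#'   defaults to `increased in magnitude relative to`.
#' @return A `phenokg_expr`. Never contains a `not` node.
#' @export
eq_to_expression <- function(eq, registry, relating_property = P_INCREASED) {
  for (cu in c(eq$entity, eq$quality, eq$attribute, eq$related_entity)) {
    resolve_term(registry, cu)
  }
  entity <- ce_atomic(eq$entity)
  plain <- if (is.null(eq$quality)) {
    ce_some(P_HAS_PART, entity)
  } else {
    q <- ce_atomic(eq$quality)
    if (!is.null(eq$related_entity)) {
      q <- ce_and(list(q, ce_some(relating_property, ce_atomic(eq$related_entity))))
    }
    ce_some(P_HAS_PART, ce_and(list(entity, ce_some(P_BEARER_OF, q))))
  }
  if (is.null(eq$count)) return(plain)
  counted <- ce_exactly(P_HAS_COMPONENT, eq$count, entity)
  if (is.null(eq$quality)) counted else ce_and(list(plain, counted))
}

#' Recover an EQ statement from a class expression
#'
#' Structural pattern match on the image of [eq_to_expression()]; no
#' reasoning. Expressions outside that subset (negation, nested multi-quality
#' conjunctions, unexpected properties) raise a condition of class
#' `phenokg_not_representable` naming the offending node.
#'
#' @param expr a `phenokg_expr`.
#' @return An `phenokg_eq` (attribute always absent; see the vignette).
#' @export
expression_to_eq <- function(expr) {
  fail <- function(e, why) {
    stop_phenokg("phenokg_not_representable",
                 sprintf("expression is not EQ-representable: %s (node: %s)",
                         why, expr_key(e)),
                 node = expr_key(e))
  }
  reject_not <- function(e) {
    if (e$node_kind == "not") fail(e, "negation is outside the EQ subset")
    switch(e$node_kind,
      and = lapply(e$operands, reject_not),
      some = reject_not(e$filler),
      exactly = reject_not(e$filler))
    invisible(NULL)
  }
  reject_not(expr)

  match_quality_filler <- function(q) {
    # atomic quality, or quality and (rel some RE)
    if (q$node_kind == "atomic") {
      return(list(quality = q$term, related_entity = NULL))
    }
    if (q$node_kind == "and" && length(q$operands) == 2) {
      kinds <- vapply(q$operands, `[[`, character(1), "node_kind")
      at <- which(kinds == "atomic")
      sm <- which(kinds == "some")
      if (length(at) == 1 && length(sm) == 1 &&
          q$operands[[sm]]$filler$node_kind == "atomic") {
        return(list(quality = q$operands[[at]]$term,
                    related_entity = q$operands[[sm]]$filler$term))
      }
    }
    fail(q, "quality filler is not atomic or quality-with-related-entity")
  }

  match_plain <- function(e) {
    # has part some E | has part some (E and (bearer of some Q...))
    if (e$node_kind != "some" || e$property != P_HAS_PART) {
      fail(e, "expected a 'has part some' restriction")
    }
    f <- e$filler
    if (f$node_kind == "atomic") {
      return(list(entity = f$term, quality = NULL, related_entity = NULL))
    }
    if (f$node_kind == "and" && length(f$operands) == 2) {
      kinds <- vapply(f$operands, `[[`, character(1), "node_kind")
      at <- which(kinds == "atomic")
      sm <- which(kinds == "some")
      if (length(at) == 1 && length(sm) == 1 &&
          f$operands[[sm]]$property == P_BEARER_OF) {
        q <- match_quality_filler(f$operands[[sm]]$filler)
        return(c(list(entity = f$operands[[at]]$term), q))
      }
    }
    fail(f, "filler is not an entity with a single borne quality")
  }

  match_count <- function(e) {
    if (e$node_kind == "exactly" && e$property == P_HAS_COMPONENT &&
        e$filler$node_kind == "atomic") {
      return(list(entity = e$filler$term, count = e$n))
    }
    NULL
  }

  if (expr$node_kind == "exactly") {
    m <- match_count(expr)
    if (is.null(m)) fail(expr, "unsupported cardinality restriction")
    return(eq_statement(m$entity, count = m$count))
  }
  if (expr$node_kind == "and" && length(expr$operands) == 2) {
    counts <- lapply(expr$operands, match_count)
    has_count <- !vapply(counts, is.null, logical(1))
    if (sum(has_count) == 1) {
      cnt <- counts[[which(has_count)]]
      plain <- match_plain(expr$operands[[which(!has_count)]])
      if (!identical(plain$entity, cnt$entity)) {
        fail(expr, "count restriction names a different entity than the quality scheme")
      }
      return(eq_statement(plain$entity, quality = plain$quality,
                          related_entity = plain$related_entity, count = cnt$count))
    }
  }
  m <- match_plain(expr)
  eq_statement(m$entity, quality = m$quality, related_entity = m$related_entity)
}

#' Attribute of an EQ statement, stated or inferred
#'
#' Returns the stated attribute if present, otherwise the quality's parent in
#' the registry hierarchy (e.g. color for red), or `NULL` when neither exists.
#'
#' @inheritParams eq_to_expression
#' @export
eq_attribute <- function(eq, registry) {
  if (!is.null(eq$attribute)) return(eq$attribute)
  if (is.null(eq$quality)) return(NULL)
  parents <- resolve_term(registry, eq$quality)$parents
  if (length(parents) > 0) parents[[1]] else NULL
}

#' @export
print.phenokg_eq <- function(x, ...) {
  bits <- c(sprintf("E=%s", x$entity),
            if (!is.null(x$quality)) sprintf("Q=%s", x$quality),
            if (!is.null(x$attribute)) sprintf("A=%s", x$attribute),
            if (!is.null(x$related_entity)) sprintf("RE=%s", x$related_entity),
            if (!is.null(x$count)) sprintf("C=%d", x$count))
  cat("<phenokg_eq>", paste(bits, collapse = " "), "\n")
  invisible(x)
}
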