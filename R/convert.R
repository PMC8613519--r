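# Conversion between the class-based (TBox) and instance-based (ABox)
# representations.
#
# Expansion reads a class expression as a recipe for a minimal witness model:
# every `some` restriction mints exactly one witness with its own URI
# (skolemized existential instantiation), `exactly n` mints n witnesses and
# keeps the cardinality as a hybrid class assertion so the count survives the
# open-world assumption, and `not` mints nothing but is kept as a hybrid
# absence assertion. Roll-up is the inverse: it reads the partonomy and the
# borne qualities back into a conjunction of restrictions. Measurements are
# never rolled up -- compiling numeric data into class axioms is exactly
# what the class-based form cannot do without one phenotype class per value
# combination -- they are reported on a skip list instead.

EXPANDABLE_PART_PROPERTIES <- c(P_HAS_PART, P_HAS_COMPONENT)

# perceptual category for a quality class, via its quality-family ancestor;
# qualities outside the mapped families are not expandable (they carry no
# observational question) and end up in the residue
quality_category <- function(registry, quality_class) {
  anc <- superclass_closure(registry, quality_class)
  if ("PATO:0000020" %in% anc) return(CAT_COLOR)
  if ("EX:shapeQuality" %in% anc) return(CAT_SHAPE)
  if ("EX:weightQuality" %in% anc) return(CAT_WEIGHT)
  if ("EX:lengthQuality" %in% anc) return(CAT_LENGTH)
  if ("EX:volumeQuality" %in% anc) return(CAT_VOLUME)
  NULL
}

# split a filler into its named head class and remaining conjuncts
filler_parts <- function(f) {
  if (f$node_kind == "atomic") return(list(head = f$term, rest = list()))
  if (f$node_kind == "and") {
    kinds <- vapply(f$operands, `[[`, character(1), "node_kind")
    at <- which(kinds == "atomic")
    if (length(at) > 0) {
      return(list(head = f$operands[[at[1]]]$term,
                  rest = f$operands[-at[1]]))
    }
  }
  list(head = NULL, rest = NULL)
}

hybrid_class_curie <- function(expr) {
  paste0("PHENO:p", string_hash(expr_key(expr)))
}

#' Expand a class expression into an instance-based description
#'
#' Total: every subexpression is either expanded into minted instances,
#' recorded as a hybrid (absence / exact-count) class assertion on its
#' bearer, or reported in the residue with a reason. Nothing ever raises.
#'
#' @param expr a `phenokg_expr`.
#' @param registry a `phenokg_registry`.
#' @param odu_class CURIE of the class the root instance instantiates.
#' @param minting a [minting_policy()].
#' @param odu_label label for the root instance.
#' @return A `phenokg_expansion`: `pkg` (the description), `residue` (list of
#'   bearer / expression / reason), `hybrid` (list of bearer / kind /
#'   expression / class curie), `hybrid_classes` (curie -> expression), and
#'   `handled_nodes` (AST accounting).
#' @export
#' @examples
#' reg <- build_fixture_registry()
#' e <- parse_manchester("has component exactly 3 ocellus", reg)
#' res <- expand_to_abox(e, reg, "UBERON:6000004")
#' length(res$pkg$instances)   # head + 3 ocelli
expand_to_abox <- function(expr, registry, odu_class,
                           minting = minting_policy(), odu_label = NULL) {
  resolve_term(registry, odu_class)
  if (is.null(odu_label)) odu_label <- resolve_term(registry, odu_class)$label
  pkg <- create_description(registry, odu_class, odu_label, minting)
  acc <- new.env(parent = emptyenv())
  acc$residue <- list()
  acc$hybrid <- list()
  acc$hybrid_classes <- list()
  acc$handled <- 0L
  acc$count_nodes <- TRUE   # node accounting is per unique AST node: when the
                            # same filler is expanded once per witness, only the
                            # first pass tallies

  tally <- function(k) if (acc$count_nodes) acc$handled <- acc$handled + k
  rest_nodes <- function(rest) {
    if (length(rest) == 0) 0L else sum(vapply(rest, expr_nodes, integer(1)))
  }

  note_residue <- function(bearer, e, reason) {
    tally(expr_nodes(e))
    acc$residue[[length(acc$residue) + 1L]] <-
      list(bearer = bearer, expr = e, reason = reason)
  }
  note_hybrid <- function(bearer, kind, e) {
    cu <- hybrid_class_curie(e)
    acc$hybrid_classes[[cu]] <- e
    assert_class(pkg, bearer, cu)
    acc$hybrid[[length(acc$hybrid) + 1L]] <-
      list(bearer = bearer, kind = kind, expr = e, class_curie = cu)
  }

  walk <- function(e, bearer) {
    if (e$node_kind == "atomic") {
      tally(1L)
      assert_class(pkg, bearer, e$term)
      return(invisible(NULL))
    }
    if (e$node_kind == "and") {
      tally(1L)
      for (op in e$operands) walk(op, bearer)
      return(invisible(NULL))
    }
    if (e$node_kind == "not") {
      tally(expr_nodes(e))
      note_hybrid(bearer, "absence", e)
      return(invisible(NULL))
    }
    # restrictions
    fp <- filler_parts(e$filler)
    if (e$property %in% EXPANDABLE_PART_PROPERTIES) {
      if (is.null(fp$head)) {
        return(note_residue(bearer, e, "restriction filler has no named class"))
      }
      # restriction node + filler's own structural nodes (and-node, head atom);
      # the remaining conjuncts tally inside the first witness's walk
      tally(1L + expr_nodes(e$filler) - rest_nodes(fp$rest))
      n_mint <- if (e$node_kind == "some") 1L else e$n
      for (k in seq_len(n_mint)) {
        w <- add_part(pkg, bearer, fp$head)
        prev <- acc$count_nodes
        if (k > 1) acc$count_nodes <- FALSE
        for (r in fp$rest) walk(r, w)
        acc$count_nodes <- prev
      }
      if (n_mint == 0L) tally(rest_nodes(fp$rest))
      if (e$node_kind == "exactly") note_hybrid(bearer, "exact-count", e)
      return(invisible(NULL))
    }
    if (e$property == P_BEARER_OF && e$node_kind == "some") {
      if (is.null(fp$head)) {
        return(note_residue(bearer, e, "quality filler has no named class"))
      }
      cat_ <- quality_category(registry, fp$head)
      if (is.null(cat_)) {
        return(note_residue(bearer, e,
                            sprintf("no perceptual category for quality class %s", fp$head)))
      }
      tally(1L + expr_nodes(e$filler) - rest_nodes(fp$rest))
      q <- add_quality(pkg, bearer, fp$head, cat_)
      for (r in fp$rest) walk(r, q)
      return(invisible(NULL))
    }
    note_residue(bearer, e,
                 sprintf("property %s is not expandable to instances", e$property))
  }

  walk(expr, pkg$odu_uri)
  structure(list(pkg = pkg, residue = acc$residue, hybrid = acc$hybrid,
                 hybrid_classes = acc$hybrid_classes, handled_nodes = acc$handled),
            class = "phenokg_expansion")
}

#' @export
print.phenokg_expansion <- function(x, ...) {
  cat(sprintf("<phenokg_expansion> %d instances, %d hybrid assertions, %d residue entries\n",
              length(x$pkg$instances), length(x$hybrid), length(x$residue)))
  invisible(x)
}

#' Roll an instance-based description up into a class expression
#'
#' Recursively conjoins the root's asserted classes with one restriction per
#' borne quality and per child part. Under `closed_world`, sibling parts with
#' identical rolled subtrees are grouped into a single
#' `exactly(has part, n, subtree)` cardinality restriction, so
#' [expand_to_abox()] recovers the original structure; otherwise each child
#' contributes an existential restriction and identical conjuncts collapse
#' (the open-world form cannot express counts). Measurements are not rolled
#' up; they are reported in the `skipped` attribute of the result.
#'
#' @param pkg a `phenokg_description`.
#' @param root URI to roll up from; defaults to the ODU.
#' @param closed_world emit exact cardinalities for sibling part groups?
#' @param include_root_classes conjoin the root instance's own classes? Set
#'   to `FALSE` to obtain the bare EQ-scheme expression for the root's
#'   description.
#' @return A `phenokg_expr`; `attr(, "skipped")` lists measurement
#'   assertions that could not be represented.
#' @export
rollup_to_tbox <- function(pkg, root = pkg$odu_uri, closed_world = FALSE,
                           include_root_classes = TRUE) {
  require_instance(pkg, root)
  parts <- list()
  qualities <- list()
  skipped <- list()
  for (a in pkg$assertions) {
    if (a$kind == "parthood") parts[[a$subject]] <- c(parts[[a$subject]], a$object)
    if (a$kind == "quality") {
      qualities[[a$subject]] <- c(qualities[[a$subject]], a$object_class)
    }
    if (a$kind == "measurement") {
      skipped[[length(skipped) + 1L]] <-
        list(bearer = a$subject, kind_class = a$object_class,
             value = a$value, unit = a$unit)
    }
  }
  roll <- function(uri, with_classes) {
    conj <- list()
    if (with_classes) {
      for (cl in pkg$instances[[uri]]$classes) {
        if (term_exists(pkg$registry, cl)) {
          conj[[length(conj) + 1L]] <- ce_atomic(cl)
        }
      }
    }
    for (q in qualities[[uri]] %||% character(0)) {
      conj[[length(conj) + 1L]] <- ce_some(P_BEARER_OF, ce_atomic(q))
    }
    subtrees <- lapply(parts[[uri]] %||% character(0), roll, with_classes = TRUE)
    if (closed_world) {
      keys <- vapply(subtrees, expr_key, character(1))
      for (k in unique(keys)) {
        grp <- subtrees[keys == k]
        conj[[length(conj) + 1L]] <-
          ce_exactly(P_HAS_PART, length(grp), grp[[1]])
      }
    } else {
      seen <- character(0)
      for (s in subtrees) {
        k <- expr_key(s)
        if (!(k %in% seen)) {
          seen <- c(seen, k)
          conj[[length(conj) + 1L]] <- ce_some(P_HAS_PART, s)
        }
      }
    }
    if (length(conj) == 0) {
      # instance whose only classes are hybrid phenotype classes
      return(ce_atomic(pkg$instances[[uri]]$classes[[1]]))
    }
    if (length(conj) == 1) conj[[1]] else ce_and(conj)
  }
  out <- roll(root, with_classes = include_root_classes)
  attr(out, "skipped") <- skipped
  out
}

# --- absence and exact-count builders (Figs. of the two modeling variants) --

OWL_EQUIVALENT <- "http://www.w3.org/2002/07/owl#equivalentClass"
OWL_COMPLEMENT <- "http://www.w3.org/2002/07/owl#complementOf"
OWL_RESTRICTION <- "http://www.w3.org/2002/07/owl#Restriction"
OWL_ON_PROPERTY <- "http://www.w3.org/2002/07/owl#onProperty"
OWL_SOME_VALUES <- "http://www.w3.org/2002/07/owl#someValuesFrom"
OWL_QUALIFIED_CARD <- "http://www.w3.org/2002/07/owl#qualifiedCardinality"
OWL_ON_CLASS <- "http://www.w3.org/2002/07/owl#onClass"

#' Model the absence of a part
#'
#' Two alternative encodings of "the bearer lacks any part of this class".
#' The `abox-only` variant uses the object property *has not part any* with a
#' class as its object: a single quad-able assertion, but outside OWL syntax
#' and flagged non-compliant with description logics. The `hybrid` variant
#' asserts a minted phenotype class on the bearer, defined as the complement
#' of `has part some <class>` (skolemized restriction nodes, no blanks):
#' DL-compliant and directly machine-actionable.
#'
#' @param variant `"abox-only"` or `"hybrid"`.
#' @param registry a `phenokg_registry`.
#' @param bearer URI of the bearer instance.
#' @param absent_class CURIE of the absent part's class.
#' @return A `phenokg_pattern`: `variant`, `dl_compliant`, `statements`
#'   (triples), `pattern` (class expression, hybrid only), `construct`
#'   (offending construct label, abox-only), `class_curie` (hybrid only).
#' @export
build_absence <- function(variant = c("abox-only", "hybrid"), registry, bearer,
                          absent_class) {
  variant <- match.arg(variant)
  resolve_term(registry, absent_class)
  pm <- registry$prefix_map
  if (variant == "abox-only") {
    df <- rdf_statements(bearer, term_uri(registry, P_HAS_NOT_PART),
                         curie_to_uri(absent_class, pm))
    return(structure(list(variant = variant, dl_compliant = FALSE,
                          statements = df, pattern = NULL,
                          construct = "has not part any"),
                     class = "phenokg_pattern"))
  }
  expr <- ce_not(ce_some(P_HAS_PART, ce_atomic(absent_class)))
  cu <- hybrid_class_curie(expr)
  cls <- curie_to_uri(cu, pm)
  k1 <- paste0(cls, "#complement")
  k2 <- paste0(cls, "#restriction")
  df <- rdf_bind(
    rdf_statements(bearer, RDF_TYPE_URI, cls),
    rdf_statements(cls, OWL_EQUIVALENT, k1),
    rdf_statements(k1, OWL_COMPLEMENT, k2),
    rdf_statements(k2, RDF_TYPE_URI, OWL_RESTRICTION),
    rdf_statements(k2, OWL_ON_PROPERTY, term_uri(registry, P_HAS_PART)),
    rdf_statements(k2, OWL_SOME_VALUES, curie_to_uri(absent_class, pm)))
  structure(list(variant = variant, dl_compliant = TRUE,
                 statements = rdf_canonical(df), pattern = expr,
                 construct = NULL, class_curie = cu),
            class = "phenokg_pattern")
}

#' Model an exact count of parts
#'
#' Two alternative encodings of "the bearer has exactly n parts of this
#' class". The `abox-only` variant mints a count-quality instance with a
#' *towards class* link to the part class and the integer value -- an
#' instance-to-class property outside description logics, flagged
#' non-compliant. The `hybrid` variant asserts a minted phenotype class
#' defined by a qualified cardinality restriction
#' `has component exactly n <class>`: DL-compliant.
#'
#' @inheritParams build_absence
#' @param part_class CURIE of the counted part's class.
#' @param n non-negative integer count (`0` expresses absence in intent,
#'   though no logical equivalence is asserted).
#' @export
build_exact_count <- function(variant = c("abox-only", "hybrid"), registry,
                              bearer, part_class, n) {
  variant <- match.arg(variant)
  resolve_term(registry, part_class)
  if (length(n) != 1 || is.na(n) || n < 0 || n != as.integer(n)) {
    stop_phenokg("phenokg_domain_error", "count must be a non-negative integer")
  }
  n <- as.integer(n)
  pm <- registry$prefix_map
  if (variant == "abox-only") {
    inst <- paste0(bearer, "#count-", string_hash(paste(part_class, n)))
    df <- rdf_bind(
      rdf_statements(bearer, term_uri(registry, P_BEARER_OF), inst),
      rdf_statements(inst, RDF_TYPE_URI, term_uri(registry, "EX:countQuality")),
      rdf_statements(inst, term_uri(registry, P_TOWARDS_CLASS),
                     curie_to_uri(part_class, pm)),
      rdf_statements(inst, term_uri(registry, P_HAS_VALUE), as.character(n),
                     o_kind = "integer"))
    return(structure(list(variant = variant, dl_compliant = FALSE,
                          statements = rdf_canonical(df), pattern = NULL,
                          construct = "towards class"),
                     class = "phenokg_pattern"))
  }
  expr <- ce_exactly(P_HAS_COMPONENT, n, ce_atomic(part_class))
  cu <- hybrid_class_curie(expr)
  cls <- curie_to_uri(cu, pm)
  k1 <- paste0(cls, "#restriction")
  df <- rdf_bind(
    rdf_statements(bearer, RDF_TYPE_URI, cls),
    rdf_statements(cls, OWL_EQUIVALENT, k1),
    rdf_statements(k1, RDF_TYPE_URI, OWL_RESTRICTION),
    rdf_statements(k1, OWL_ON_PROPERTY, term_uri(registry, P_HAS_COMPONENT)),
    rdf_statements(k1, OWL_QUALIFIED_CARD, as.character(n), o_kind = "integer"),
    rdf_statements(k1, OWL_ON_CLASS, curie_to_uri(part_class, pm)))
  structure(list(variant = variant, dl_compliant = TRUE,
                 statements = rdf_canonical(df), pattern = expr,
                 construct = NULL, class_curie = cu),
            class = "phenokg_pattern")
}

# --- comparative statements -------------------------------------------------

#' Comparative and bounded direct statements
#'
#' A comparative statement ("increased length of abdomen") describes a
#' specimen against a reference state; without the reference value it cannot
#' be turned into a statement about the specimen alone. With the reference
#' value it converts to a bounded direct statement ("length of abdomen above
#' 2.6 mm"): `increased` becomes an exclusive lower bound at the reference,
#' `decreased` an exclusive upper bound.
#'
#' @param quality_kind CURIE of the compared quality kind (e.g. length).
#' @param bearer_class CURIE of the bearer's class.
#' @param direction `"increased"` or `"decreased"`.
#' @param reference_value reference magnitude, or `NULL` when unknown.
#' @param reference_unit CURIE of the reference's unit, or `NULL`.
#' @export
comparative_statement <- function(quality_kind, bearer_class,
                                  direction = c("increased", "decreased"),
                                  reference_value = NULL, reference_unit = NULL) {
  direction <- match.arg(direction)
  structure(list(quality_kind = quality_kind, bearer_class = bearer_class,
                 direction = direction, reference_value = reference_value,
                 reference_unit = reference_unit),
            class = "phenokg_comparative")
}

#' @param stmt a [comparative_statement()] with reference value and unit.
#' @return For `comparative_to_direct`, a `phenokg_bounded` with
#'   `bound_kind` (`"exclusive-lower"` / `"exclusive-upper"`), `bound_value`,
#'   and `unit`. A missing reference raises a condition of class
#'   `phenokg_unresolvable_comparative`.
#' @rdname comparative_statement
#' @export
comparative_to_direct <- function(stmt) {
  if (is.null(stmt$reference_value) || is.null(stmt$reference_unit)) {
    stop_phenokg("phenokg_unresolvable_comparative",
                 "comparative statement has no reference value: the described magnitude cannot be recovered without consulting the reference description")
  }
  if (!is.finite(stmt$reference_value)) {
    stop_phenokg("phenokg_domain_error", "reference value must be finite")
  }
  structure(list(quality_kind = stmt$quality_kind, bearer_class = stmt$bearer_class,
                 bound_kind = if (stmt$direction == "increased") "exclusive-lower"
                              else "exclusive-upper",
                 bound_value = stmt$reference_value, unit = stmt$reference_unit),
            class = "phenokg_bounded")
}
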