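# Well-formedness checks, the shape-template content standard, DL-compliance
# detection, and criteria-based querying over stores of descriptions.

#' Validation report
#'
#' @param findings data frame with columns `severity` ("error"/"warning"),
#'   `target` (graph or instance IRI), `message`.
#' @return A `phenokg_report`; `ok` is true iff no error-severity findings.
#' @export
validation_report <- function(findings = NULL) {
  if (is.null(findings) || nrow(findings) == 0) {
    findings <- data.frame(severity = character(), target = character(),
                           message = character(), stringsAsFactors = FALSE)
  }
  structure(list(ok = !any(findings$severity == "error"), findings = findings),
            class = "phenokg_report")
}

finding <- function(severity, target, message) {
  data.frame(severity = severity, target = target, message = message,
             stringsAsFactors = FALSE)
}

#' @export
print.phenokg_report <- function(x, ...) {
  cat(sprintf("<phenokg_report> ok: %s (%d errors, %d warnings)\n",
              x$ok, sum(x$findings$severity == "error"),
              sum(x$findings$severity == "warning")))
  if (nrow(x$findings) > 0) {
    for (i in seq_len(nrow(x$findings))) {
      cat(sprintf("  [%s] %s: %s\n", x$findings$severity[i], x$findings$target[i],
                  x$findings$message[i]))
    }
  }
  invisible(x)
}

#' Check well-formedness of a description
#'
#' Errors: instances without a class assertion, blank or relative URIs,
#' parthood cycles or multiple parents, measurements without a unit.
#' Warnings: anatomical-entity instances without a label. Always returns a
#' report, never throws.
#'
#' @param pkg a `phenokg_description`.
#' @return A `phenokg_report`.
#' @export
check_wellformed <- function(pkg) {
  f <- list()
  reg <- pkg$registry
  for (inst in pkg$instances) {
    if (length(inst$classes) == 0) {
      f[[length(f) + 1L]] <- finding("error", inst$uri, "instance has no class assertion")
    }
    if (!grepl("^[a-z][a-z0-9+.-]*://", inst$uri) || startsWith(inst$uri, "_:")) {
      f[[length(f) + 1L]] <- finding("error", inst$uri,
                                     "instance URI is blank or not absolute")
    }
    if (any(vapply(inst$classes, function(cl) is_anatomical_term(reg, cl), logical(1))) &&
        (is.na(inst$label) || !nzchar(inst$label))) {
      f[[length(f) + 1L]] <- finding("warning", inst$uri,
                                     "anatomical-entity instance has no human-readable label")
    }
  }
  part_objects <- character(0)
  edges <- list()
  for (a in pkg$assertions) {
    if (a$kind == "parthood") {
      part_objects <- c(part_objects, a$object)
      edges[[a$subject]] <- c(edges[[a$subject]], a$object)
      if (is.null(pkg$instances[[a$subject]]) || is.null(pkg$instances[[a$object]])) {
        f[[length(f) + 1L]] <- finding("error", a$object %||% "?",
                                       "parthood assertion references a missing instance")
      }
    }
    if (a$kind == "measurement" && (is.null(a$unit) || !is_unit_term(reg, a$unit))) {
      f[[length(f) + 1L]] <- finding("error", a$object, "measurement without a unit term")
    }
  }
  parent_count <- table(part_objects)
  multi <- names(parent_count)[parent_count > 1]
  for (u in multi) {
    f[[length(f) + 1L]] <- finding("error", u, "part has more than one parent")
  }
  # cycle check by depth-limited walk from the ODU
  visited <- character(0)
  frontier <- pkg$odu_uri
  while (length(frontier) > 0) {
    if (any(frontier %in% visited)) {
      f[[length(f) + 1L]] <- finding("error", frontier[frontier %in% visited][1],
                                     "parthood cycle detected")
      break
    }
    visited <- c(visited, frontier)
    frontier <- unlist(edges[frontier], use.names = FALSE)
  }
  validation_report(if (length(f) > 0) do.call(rbind, f))
}

# --- shape templates (content standard) -------------------------------------

#' Shape template for a named-graph category
#'
#' The content standard: a semantic graph pattern stating which roles a
#' descriptive statement of this category must fill and what fills them.
#' Supported roles: `whole`, `part` (parthood), `bearer`, `quality`
#' (qualitative statements), `value`, `unit`, `kind` (measurements).
#' Value constraints map a role to a datatype (`"decimal"`, `"integer"`) or
#' a term-domain CURIE the filler's class must fall under.
#'
#' @param category CURIE of the category the template covers.
#' @param required_roles character vector of role names (non-empty).
#' @param value_constraints named list, role -> constraint.
#' @export
shape_template <- function(category, required_roles, value_constraints = list()) {
  if (length(required_roles) == 0) {
    stop_phenokg("phenokg_domain_error", "shape template needs at least one role")
  }
  structure(list(category = category, required_roles = required_roles,
                 value_constraints = value_constraints),
            class = "phenokg_shape")
}

#' Default shape catalog
#'
#' Templates for parthood, shape, and color statements and for
#' weight/length/volume measurements (bearer + value + unit, value decimal,
#' unit in the unit term-domain).
#'
#' @export
default_shape_catalog <- function() {
  meas <- function(cat) {
    shape_template(cat, c("bearer", "kind", "value", "unit"),
                   list(value = "decimal", unit = C_UNIT))
  }
  list(shape_template(CAT_PARTHOOD, c("whole", "part")),
       shape_template(CAT_SHAPE, c("bearer", "quality")),
       shape_template(CAT_COLOR, c("bearer", "quality")),
       meas(CAT_WEIGHT), meas(CAT_LENGTH), meas(CAT_VOLUME))
}

# extract role fillers from a descriptive named graph
graph_roles <- function(graph, registry) {
  q <- graph$quads
  pu <- function(curie) term_uri(registry, curie)
  roles <- list()
  part_rows <- q[q$p == pu(P_HAS_PART), , drop = FALSE]
  if (nrow(part_rows) > 0) {
    roles$whole <- part_rows$s
    roles$part <- part_rows$o
  }
  bear_rows <- q[q$p == pu(P_BEARER_OF), , drop = FALSE]
  if (nrow(bear_rows) > 0) {
    roles$bearer <- bear_rows$s
    roles$quality <- bear_rows$o
    types <- q[q$p == RDF_TYPE_URI & q$s %in% bear_rows$o, , drop = FALSE]
    if (nrow(types) > 0) roles$kind <- types$o
  }
  val_rows <- q[q$p == pu(P_HAS_VALUE), , drop = FALSE]
  if (nrow(val_rows) > 0) {
    roles$value <- val_rows$o
    roles$value_kind <- val_rows$o_kind
  }
  unit_rows <- q[q$p == pu(P_HAS_UNIT), , drop = FALSE]
  if (nrow(unit_rows) > 0) roles$unit <- unit_rows$o
  roles
}

#' Check a named graph against a shape catalog
#'
#' Role-by-role presence and constraint check against the template for the
#' graph's category; a category without a template yields a warning, not an
#' error.
#'
#' @param graph a `phenokg_named_graph`.
#' @param catalog list of [shape_template()]; defaults to
#'   [default_shape_catalog()].
#' @param registry a `phenokg_registry`.
#' @return A `phenokg_report`.
#' @export
check_shape <- function(graph, catalog = default_shape_catalog(), registry) {
  tpl <- Filter(function(t) t$category == graph$category, catalog)
  if (length(tpl) == 0) {
    return(validation_report(finding("warning", graph$uri,
                                     sprintf("no shape template for category %s",
                                             graph$category))))
  }
  tpl <- tpl[[1]]
  roles <- graph_roles(graph, registry)
  f <- list()
  for (r in tpl$required_roles) {
    if (is.null(roles[[r]])) {
      f[[length(f) + 1L]] <- finding("error", graph$uri,
                                     sprintf("required role '%s' is not filled", r))
    }
  }
  for (r in names(tpl$value_constraints)) {
    cons <- tpl$value_constraints[[r]]
    filler <- roles[[r]]
    if (is.null(filler)) next
    if (cons %in% c("decimal", "integer")) {
      if (!all(roles$value_kind == cons)) {
        f[[length(f) + 1L]] <- finding("error", graph$uri,
                                       sprintf("role '%s' must be a %s literal", r, cons))
      }
    } else {
      domain <- subclass_closure(registry, cons)
      domain_uris <- vapply(domain, term_uri, character(1), registry = registry)
      if (!all(filler %in% domain_uris)) {
        f[[length(f) + 1L]] <- finding("error", graph$uri,
                                       sprintf("role '%s' filler outside term domain %s",
                                               r, cons))
      }
    }
  }
  validation_report(if (length(f) > 0) do.call(rbind, f))
}

#' Read / write a shape catalog as YAML
#'
#' Shape templates are data, not code: a catalog file carries one entry per
#' category with `category`, `required_roles`, and `value_constraints`.
#'
#' @param catalog list of [shape_template()].
#' @param file path.
#' @export
shape_catalog_to_yaml <- function(catalog, file = NULL) {
  x <- lapply(catalog, function(t) {
    list(category = t$category,
         required_roles = as.list(t$required_roles),
         value_constraints = t$value_constraints)
  })
  txt <- yaml::as.yaml(x)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @rdname shape_catalog_to_yaml
#' @export
shape_catalog_from_yaml <- function(file) {
  x <- yaml::read_yaml(file)
  lapply(x, function(t) {
    shape_template(t$category, unlist(t$required_roles),
                   t$value_constraints %||% list())
  })
}

#' Export a shape catalog as SHACL node shapes
#'
#' Interoperability export only; validation always runs on the internal
#' engine. Each template becomes a `sh:NodeShape` targeting the category
#' class with one `sh:property` (minCount 1) per required role.
#'
#' @inheritParams shape_catalog_to_yaml
#' @param registry a `phenokg_registry`.
#' @export
shape_catalog_to_shacl <- function(catalog, registry, file = NULL) {
  sh <- "http://www.w3.org/ns/shacl#"
  pm <- c(registry$prefix_map, sh = sh)
  rows <- list()
  role_path <- c(whole = P_HAS_PART, part = P_HAS_PART, bearer = P_BEARER_OF,
                 quality = P_BEARER_OF, kind = RDF_TYPE, value = P_HAS_VALUE,
                 unit = P_HAS_UNIT)
  for (t in catalog) {
    s <- paste0(pm[["EX"]], "shape-", category_slug(registry, t$category))
    rows[[length(rows) + 1L]] <- rdf_bind(
      rdf_statements(s, RDF_TYPE_URI, paste0(sh, "NodeShape")),
      rdf_statements(s, paste0(sh, "targetClass"), term_uri(registry, t$category)))
    for (r in t$required_roles) {
      ps <- paste0(s, "#", r)
      rows[[length(rows) + 1L]] <- rdf_bind(
        rdf_statements(s, paste0(sh, "property"), ps),
        rdf_statements(ps, paste0(sh, "path"), term_uri(registry, role_path[[r]])),
        rdf_statements(ps, paste0(sh, "minCount"), "1", o_kind = "integer"))
    }
  }
  write_turtle(do.call(rdf_bind, rows), pm, file = file)
}

# --- DL compliance ----------------------------------------------------------

#' Detect non-DL constructs in statements
#'
#' Flags the two deliberately non-OWL properties -- *has not part any*
#' (instance-to-class absence link) and *towards class* (relational count
#' quality) -- in a statement table or in the output of [build_absence()] /
#' [build_exact_count()]. Compliant hybrid patterns pass.
#'
#' @param statements a statement table, or a `phenokg_pattern`.
#' @param registry a `phenokg_registry`.
#' @return List with `compliant` flag and `offending` construct labels.
#' @export
dl_compliance <- function(statements, registry) {
  if (inherits(statements, "phenokg_pattern")) statements <- statements$statements
  non_dl <- Filter(function(tm) isTRUE(tm$non_dl), registry$terms)
  offending <- character(0)
  for (tm in non_dl) {
    if (term_uri(registry, tm$curie) %in% statements$p) {
      offending <- c(offending, tm$label)
    }
  }
  list(compliant = length(offending) == 0, offending = offending)
}

# --- criteria queries -------------------------------------------------------

#' Query criteria over a description store
#'
#' At least one criterion must be present. Measurement criteria are
#' unit-checked with no unit conversion: a 10 mg threshold never matches a
#' measurement recorded in grams.
#'
#' @param part_classes character vector of part-class CURIEs the description
#'   must contain instances of; names are ignored, closure matching is
#'   controlled per entry by `part_closure` (recycled).
#' @param part_closure logical, match subclasses of each part class too.
#' @param parthood_pairs list of `c(whole_class, part_class)` pairs that must
#'   occur as a direct parthood link.
#' @param measurements list of `list(kind, comparator, value, unit)` with
#'   comparator one of `>`, `>=`, `<`, `<=`, `=`.
#' @param taxon_class CURIE matched as a class assertion on the ODU, or `NULL`.
#' @export
query_criteria <- function(part_classes = character(), part_closure = TRUE,
                           parthood_pairs = list(), measurements = list(),
                           taxon_class = NULL) {
  if (length(part_classes) == 0 && length(parthood_pairs) == 0 &&
      length(measurements) == 0 && is.null(taxon_class)) {
    stop_phenokg("phenokg_domain_error", "query needs at least one criterion")
  }
  structure(list(part_classes = part_classes,
                 part_closure = rep_len(part_closure, length(part_classes)),
                 parthood_pairs = parthood_pairs, measurements = measurements,
                 taxon_class = taxon_class),
            class = "phenokg_query")
}

class_match_uris <- function(registry, curie, closure) {
  cus <- if (closure) subclass_closure(registry, curie) else curie
  vapply(cus, term_uri, character(1), registry = registry, USE.NAMES = FALSE)
}

#' Run a criteria query against a store
#'
#' Plain pattern matching over the ABox content of each description's active
#' named graphs: no entailment, no reasoning. Returns descriptions
#' satisfying all criteria.
#'
#' @param store a `phenokg_store`.
#' @param criteria a [query_criteria()].
#' @param registry a `phenokg_registry` (defaults to the store's).
#' @return Character vector of description URIs (sorted).
#' @export
run_query <- function(store, criteria, registry = store$registry) {
  for (m in criteria$measurements) {
    if (!is_unit_term(registry, m$unit)) {
      stop_phenokg("phenokg_domain_error",
                   sprintf("'%s' is not a unit term", m$unit))
    }
  }
  pu <- function(curie) term_uri(registry, curie)
  hits <- character(0)
  for (d in names(store$descriptions)) {
    graphs <- active_graphs(store, d)
    triples <- union_graphs(graphs)
    types <- triples[triples$p == RDF_TYPE_URI, , drop = FALSE]
    odu <- graphs[[which(vapply(graphs, `[[`, character(1), "category") ==
                           CAT_INSTANTIATION)[1]]]$subject_part
    ok <- TRUE
    for (i in seq_along(criteria$part_classes)) {
      want <- class_match_uris(registry, criteria$part_classes[i],
                               criteria$part_closure[i])
      if (!any(types$o %in% want)) { ok <- FALSE; break }
    }
    if (ok) for (pp in criteria$parthood_pairs) {
      whole_uris <- types$s[types$o %in% class_match_uris(registry, pp[1], TRUE)]
      part_uris <- types$s[types$o %in% class_match_uris(registry, pp[2], TRUE)]
      links <- triples[triples$p == pu(P_HAS_PART), , drop = FALSE]
      if (!any(links$s %in% whole_uris & links$o %in% part_uris)) { ok <- FALSE; break }
    }
    if (ok) for (m in criteria$measurements) {
      vals <- measurement_values(triples, registry, m$kind)
      match_unit <- vals$unit == pu(m$unit)
      cmp <- switch(m$comparator,
                    ">" = vals$value > m$value, ">=" = vals$value >= m$value,
                    "<" = vals$value < m$value, "<=" = vals$value <= m$value,
                    "=" = vals$value == m$value,
                    stop_phenokg("phenokg_domain_error",
                                 sprintf("unknown comparator '%s'", m$comparator)))
      if (!any(match_unit & cmp)) { ok <- FALSE; break }
    }
    if (ok && !is.null(criteria$taxon_class)) {
      taxon_uris <- class_match_uris(registry, criteria$taxon_class, TRUE)
      if (!any(types$s == odu & types$o %in% taxon_uris)) ok <- FALSE
    }
    if (ok) hits <- c(hits, d)
  }
  sort(hits, method = "radix")
}

# measurement instances of a kind (closure) with value and unit
measurement_values <- function(triples, registry, kind) {
  kind_uris <- class_match_uris(registry, kind, TRUE)
  insts <- triples$s[triples$p == RDF_TYPE_URI & triples$o %in% kind_uris]
  vals <- triples[triples$p == term_uri(registry, P_HAS_VALUE) &
                    triples$s %in% insts, , drop = FALSE]
  units <- triples[triples$p == term_uri(registry, P_HAS_UNIT) &
                     triples$s %in% insts, , drop = FALSE]
  unit_for <- stats::setNames(units$o, units$s)
  data.frame(instance = vals$s, value = as.numeric(vals$o),
             unit = unname(unit_for[vals$s]), stringsAsFactors = FALSE)
}
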