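# Term registry: the vocabulary layer every other module resolves CURIEs
# against. The fixture registry stands in for the domain ontologies (UBERON,
# PATO, MA, MP) with the handful of terms the worked examples need, plus an
# EX: namespace for terms those ontologies are not consulted for here
# (properties, perceptual categories, units, extra anatomy).

new_term <- function(curie, label, kind, parents = character(), non_dl = FALSE) {
  list(curie = curie, label = label, term_kind = kind,
       parents = parents, non_dl = non_dl)
}

#' Build the fixture term registry
#'
#' Constructs the small vocabulary used throughout the package: the cited
#' UBERON/PATO/MA/MP terms, object properties (parthood, quality bearing,
#' measurement value/unit, the two deliberately non-DL properties), the
#' perceptual-category terms that classify descriptive named graphs, unit
#' terms, and supporting anatomy/quality classes in an `EX:` namespace.
#' Construction is deterministic: repeated calls serialize identically.
#'
#' @return A `phenokg_registry` object: a list with `terms` (named list of
#'   term records), `prefix_map`, and `category_terms`.
#' @export
#' @examples
#' reg <- build_fixture_registry()
#' resolve_term(reg, "UBERON:0000972")$label
build_fixture_registry <- function() {
  t <- list()
  add <- function(curie, label, kind = "class", parents = character(), non_dl = FALSE) {
    t[[curie]] <<- new_term(curie, label, kind, parents, non_dl)
  }

  # roots
  add(C_ANATOMICAL, "anatomical entity")
  add(C_QUALITY, "quality")
  add(C_UNIT, "unit")

  # anatomy
  ana <- function(curie, label, parents = C_ANATOMICAL) add(curie, label, parents = parents)
  ana("UBERON:6000004", "insect head")
  ana("UBERON:0000972", "antenna")
  ana("MA:0000261", "eye")
  ana("EX:multicellularOrganism", "multicellular organism")
  ana("EX:head", "head")
  ana("EX:abdomen", "abdomen")
  ana("EX:ovipositor", "ovipositor")
  ana("EX:ocellus", "ocellus")
  ana("EX:clypeus", "clypeus")
  ana("EX:mandible", "mandible")
  ana("EX:labialPalp", "labial palp")
  ana("EX:maxillaryPalp", "maxillary palp")
  ana("EX:occiput", "occiput")
  ana("EX:postgena", "postgena")
  ana("EX:scape", "scape")
  ana("EX:vertex", "vertex")
  ana("EX:pedicel", "pedicel")
  ana("EX:flagellomere", "flagellomere")
  ordinals <- c("first", "second", "third", "fourth", "fifth", "sixth", "seventh",
                "eighth", "ninth", "tenth", "eleventh", "twelfth", "thirteenth")
  for (k in seq_along(ordinals)) {
    ana(sprintf("EX:flagellomere%d", k), paste(ordinals[k], "flagellomere"),
        parents = "EX:flagellomere")
  }
  ana("EX:flagellomere14", "flagellomere 14", parents = "EX:flagellomere")

  # qualities
  add("PATO:0000020", "color", parents = C_QUALITY)
  add("PATO:0000322", "red", parents = "PATO:0000020")
  add("EX:yellow", "yellow", parents = "PATO:0000020")
  add("EX:darkBrown", "dark brown", parents = "PATO:0000020")
  add("EX:lightBrown", "light brown", parents = "PATO:0000020")
  add("EX:colorBrightness", "color brightness", parents = "PATO:0000020")
  add("EX:shapeQuality", "shape quality", parents = C_QUALITY)
  add("PATO:0002254", "flattened", parents = "EX:shapeQuality")
  add("EX:weightQuality", "weight", parents = C_QUALITY)
  add("EX:liveWeight", "live weight", parents = "EX:weightQuality")
  add("EX:lengthQuality", "length", parents = C_QUALITY)
  add("EX:volumeQuality", "volume", parents = C_QUALITY)
  add("MP:0001259", "abnormal body weight", parents = C_QUALITY)
  add("EX:countQuality", "count", parents = C_QUALITY)

  # units
  add("EX:milligram", "milligram", parents = C_UNIT)
  add("EX:millimetre", "millimetre", parents = C_UNIT)

  # taxa (query scenarios restrict to a taxonomic group via a class assertion)
  add("EX:insecta", "Insecta")

  # object properties
  op <- function(curie, label, non_dl = FALSE) {
    add(curie, label, kind = "object-property", non_dl = non_dl)
  }
  op(P_HAS_PART, "has part")
  op(P_PART_OF, "part of")
  op(P_BEARER_OF, "bearer of")
  op(P_INHERES_IN, "inheres in")
  op(P_HAS_COMPONENT, "has component")
  op(P_INCREASED, "increased in magnitude relative to")
  op(RDF_TYPE, "type")
  op(RDFS_LABEL, "label")
  op(P_HAS_NOT_PART, "has not part any", non_dl = TRUE)
  op(P_TOWARDS_CLASS, "towards class", non_dl = TRUE)
  op(P_HAS_VALUE, "has value")
  op(P_HAS_UNIT, "has unit")
  op(P_ABOUT, "about")
  op(P_SUPERSEDES, "supersedes")
  op("EX:agent", "agent")
  op("EX:date", "date")
  op("EX:source", "source")
  op("EX:instrument", "instrument")
  op("EX:hasAssertion", "has assertion")
  op("EX:hasProvenance", "has provenance")
  op("EX:hasPublicationInfo", "has publication info")

  # perceptual categories: one per observational question, plus the structural
  # parthood/instantiation categories; measurements share a category parent
  cat_ <- function(curie, label, parents = character()) {
    add(curie, label, kind = "category", parents = parents)
  }
  cat_(CAT_PARTHOOD, "parthood")
  cat_(CAT_INSTANTIATION, "instantiation")
  cat_(CAT_MEASUREMENT, "measurement")
  cat_(CAT_WEIGHT, "weight", CAT_MEASUREMENT)
  cat_(CAT_LENGTH, "length", CAT_MEASUREMENT)
  cat_(CAT_VOLUME, "volume", CAT_MEASUREMENT)
  cat_(CAT_POSITION, "position")
  cat_(CAT_COLOR, "color")
  cat_(CAT_SHAPE, "shape")
  cat_(CAT_FUNCTION, "function")
  cat_(CAT_DEVELOPMENT, "development")

  reg <- structure(
    list(terms = t,
         prefix_map = FIXTURE_PREFIXES,
         category_terms = names(t)[vapply(t, function(x) x$term_kind == "category", logical(1))]),
    class = "phenokg_registry")
  validate_registry(reg)
  reg
}

validate_registry <- function(registry) {
  terms <- registry$terms
  if (anyDuplicated(names(terms)) > 0) {
    stop_phenokg("phenokg_domain_error", "duplicate curies in registry")
  }
  for (tm in terms) {
    if (!nzchar(tm$label)) {
      stop_phenokg("phenokg_domain_error", sprintf("term %s has empty label", tm$curie))
    }
    pfx <- sub(":.*$", "", tm$curie)
    if (!(pfx %in% names(registry$prefix_map))) stop_lookup(tm$curie)
    for (p in tm$parents) {
      if (!(p %in% names(terms))) stop_lookup(p)
      if (terms[[p]]$term_kind != tm$term_kind) {
        stop_phenokg("phenokg_domain_error",
                     sprintf("parent %s of %s has a different term kind", p, tm$curie))
      }
    }
  }
  # acyclicity of the parent graph, by repeated leaf stripping
  remaining <- names(terms)
  repeat {
    leaves <- remaining[vapply(remaining, function(cu) {
      !any(terms[[cu]]$parents %in% remaining)
    }, logical(1))]
    if (length(leaves) == 0) break
    remaining <- setdiff(remaining, leaves)
  }
  if (length(remaining) > 0) {
    stop_phenokg("phenokg_domain_error",
                 sprintf("cycle in subclass graph involving: %s",
                         paste(remaining, collapse = ", ")))
  }
  invisible(registry)
}

#' Resolve a CURIE in a registry
#'
#' @param registry a `phenokg_registry`.
#' @param curie prefixed identifier, e.g. `"PATO:0000322"`.
#' @return The term record (curie, label, term_kind, parents, non_dl).
#' @export
resolve_term <- function(registry, curie) {
  tm <- registry$terms[[curie]]
  if (is.null(tm)) stop_lookup(curie)
  tm
}

#' Absolute IRI of a registry term
#' @inheritParams resolve_term
#' @export
term_uri <- function(registry, curie) {
  resolve_term(registry, curie)
  curie_to_uri(curie, registry$prefix_map)
}

term_exists <- function(registry, curie) !is.null(registry$terms[[curie]])

#' Reflexive-transitive subclass closure
#'
#' Returns the term and all its descendants through the `parents` relation,
#' e.g. the closure of `color` contains `red`. Used for data views and
#' closure-flagged query criteria ("all classes that contain measurements in
#' general").
#'
#' @inheritParams resolve_term
#' @return Character vector of CURIEs including `curie` itself.
#' @export
subclass_closure <- function(registry, curie) {
  resolve_term(registry, curie)
  children <- registry_children_index(registry)
  seen <- character(0)
  frontier <- curie
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    nxt <- unlist(children[frontier], use.names = FALSE)
    frontier <- setdiff(nxt, seen)
  }
  sort(unique(seen), method = "radix")
}

registry_children_index <- function(registry) {
  idx <- list()
  for (tm in registry$terms) {
    for (p in tm$parents) idx[[p]] <- c(idx[[p]], tm$curie)
  }
  idx
}

# upward closure (term plus all ancestors)
superclass_closure <- function(registry, curie) {
  seen <- character(0)
  frontier <- curie
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    nxt <- unlist(lapply(frontier, function(cu) registry$terms[[cu]]$parents),
                  use.names = FALSE)
    frontier <- setdiff(nxt, seen)
  }
  unique(seen)
}

is_unit_term <- function(registry, curie) {
  term_exists(registry, curie) && C_UNIT %in% superclass_closure(registry, curie)
}

is_anatomical_term <- function(registry, curie) {
  term_exists(registry, curie) && C_ANATOMICAL %in% superclass_closure(registry, curie)
}

is_measurement_category <- function(registry, curie) {
  term_exists(registry, curie) && CAT_MEASUREMENT %in% superclass_closure(registry, curie)
}

# label -> curie lookup for the Manchester tokenizer (classes and properties
# only; category labels are not expression tokens)
registry_label_table <- function(registry, kinds = c("class", "object-property")) {
  keep <- Filter(function(tm) tm$term_kind %in% kinds, registry$terms)
  data.frame(label = vapply(keep, `[[`, character(1), "label"),
             curie = vapply(keep, `[[`, character(1), "curie"),
             kind = vapply(keep, `[[`, character(1), "term_kind"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# --- Turtle I/O -------------------------------------------------------------

OWL_CLASS <- "http://www.w3.org/2002/07/owl#Class"
OWL_OBJECT_PROPERTY <- "http://www.w3.org/2002/07/owl#ObjectProperty"
RDF_TYPE_URI <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_LABEL_URI <- "http://www.w3.org/2000/01/rdf-schema#label"
RDFS_SUBCLASS_URI <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
RDFS_SUBPROP_URI <- "http://www.w3.org/2000/01/rdf-schema#subPropertyOf"
EX_CATEGORY_CLASS <- "http://example.org/phenokg/vocab#PerceptualCategory"
EX_NON_STANDARD <- "http://example.org/phenokg/vocab#nonStandard"

#' Serialize a registry as Turtle
#'
#' Terms become typed resources (`owl:Class`, `owl:ObjectProperty`, or the
#' category marker class) with `rdfs:label` annotations and subclass /
#' subproperty axioms for parent links; the two non-OWL properties carry an
#' `EX:nonStandard "true"` marker. The prefix map is emitted as `@prefix`
#' declarations, so the file round-trips through [registry_from_turtle()].
#'
#' @inheritParams resolve_term
#' @param file optional output path.
#' @return Turtle text (invisibly when `file` is given).
#' @export
registry_to_turtle <- function(registry, file = NULL) {
  pm <- registry$prefix_map
  rows <- list()
  for (tm in registry$terms) {
    uri <- curie_to_uri(tm$curie, pm)
    type_uri <- switch(tm$term_kind,
                       "class" = OWL_CLASS,
                       "object-property" = OWL_OBJECT_PROPERTY,
                       "category" = EX_CATEGORY_CLASS)
    parent_pred <- if (tm$term_kind == "object-property") RDFS_SUBPROP_URI else RDFS_SUBCLASS_URI
    rows[[length(rows) + 1L]] <- rdf_bind(
      rdf_statements(uri, RDF_TYPE_URI, type_uri),
      rdf_statements(uri, RDFS_LABEL_URI, tm$label, o_kind = "string"),
      if (length(tm$parents) > 0) {
        rdf_statements(uri, parent_pred,
                       vapply(tm$parents, curie_to_uri, character(1), prefix_map = pm))
      },
      if (isTRUE(tm$non_dl)) {
        rdf_statements(uri, EX_NON_STANDARD, "true", o_kind = "string")
      })
  }
  write_turtle(do.call(rdf_bind, rows), pm, file = file)
}

#' Load a registry from its Turtle serialization
#'
#' @param x Turtle text or a file path.
#' @return A `phenokg_registry`.
#' @export
registry_from_turtle <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  text <- paste(x, collapse = "\n")
  pm_lines <- regmatches(text, gregexpr("@prefix\\s+([A-Za-z][A-Za-z0-9_-]*):\\s+<([^>]*)>", text))[[1]]
  pm <- vapply(pm_lines, function(l) sub(".*<([^>]*)>.*", "\\1", l), character(1))
  names(pm) <- vapply(pm_lines, function(l) sub("@prefix\\s+([A-Za-z][A-Za-z0-9_-]*):.*", "\\1", l), character(1))

  df <- parse_rdf_text(text)
  curie_of <- function(uri) {
    cu <- uri_to_curie(uri, pm)
    if (is.na(cu)) stop_lookup(uri)
    cu
  }
  subjects <- unique(df$s[df$p == RDF_TYPE_URI])
  terms <- list()
  cats <- character(0)
  for (uri in subjects) {
    mine <- df[df$s == uri, , drop = FALSE]
    type_uri <- mine$o[mine$p == RDF_TYPE_URI][1]
    kind <- if (type_uri == OWL_CLASS) "class"
            else if (type_uri == OWL_OBJECT_PROPERTY) "object-property"
            else if (type_uri == EX_CATEGORY_CLASS) "category"
            else next
    label <- mine$o[mine$p == RDFS_LABEL_URI][1]
    parents <- vapply(mine$o[mine$p %in% c(RDFS_SUBCLASS_URI, RDFS_SUBPROP_URI)],
                      curie_of, character(1), USE.NAMES = FALSE)
    non_dl <- any(mine$p == EX_NON_STANDARD & mine$o == "true")
    cu <- curie_of(uri)
    terms[[cu]] <- new_term(cu, label, kind, parents, non_dl)
    if (kind == "category") cats <- c(cats, cu)
  }
  reg <- structure(list(terms = terms, prefix_map = pm,
                        category_terms = sort(cats, method = "radix")),
                   class = "phenokg_registry")
  validate_registry(reg)
  reg
}

#' @export
print.phenokg_registry <- function(x, ...) {
  kinds <- table(vapply(x$terms, `[[`, character(1), "term_kind"))
  cat(sprintf("<phenokg_registry> %d terms (%s)\n", length(x$terms),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", ")))
  invisible(x)
}
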