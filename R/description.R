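# Instance-based phenotype descriptions (the ABox core).
#
# A description is a mutable environment holding the described individual
# (the operational descriptive unit, ODU), the instances minted for its
# parts, qualities, and measurements -- every one with its own URI, never a
# blank node -- and an ordered list of assertions. Parthood assertions form a
# tree rooted at the ODU: the partonomy backbone. Builder functions mutate
# the description in place and return the minted URI, so construction scripts
# read like the descriptions they encode.

#' URI minting policy
#'
#' Deterministic minting derives instance URIs from (namespace, seed,
#' insertion counter), so identical construction scripts produce
#' byte-identical serializations. The `"random"` scheme draws hexadecimal
#' suffixes from the session RNG instead.
#'
#' @param namespace IRI base for minted resources.
#' @param seed integer discriminating descriptions sharing a namespace.
#' @param scheme `"counter"` (deterministic, default) or `"random"`.
#' @export
minting_policy <- function(namespace = "http://example.org/phenokg/data/",
                           seed = 1L, scheme = c("counter", "random")) {
  scheme <- match.arg(scheme)
  list(namespace = namespace, seed = as.integer(seed), scheme = scheme)
}

mint_uri <- function(pkg) {
  pkg$counter <- pkg$counter + 1L
  m <- pkg$minting
  if (m$scheme == "counter") {
    paste0(m$namespace, "d", m$seed, "/i", sprintf("%04d", pkg$counter))
  } else {
    paste0(m$namespace, "d", m$seed, "/u",
           paste(sample(c(0:9, letters[1:6]), 16, replace = TRUE), collapse = ""))
  }
}

#' Create a phenotype description
#'
#' Mints the root instance (the ODU) with an instantiation and a labeling
#' assertion; parts, qualities, and measurements are then attached with
#' [add_part()], [add_quality()], and [add_measurement()].
#'
#' @param registry a `phenokg_registry`.
#' @param root_class CURIE of the class the ODU instantiates.
#' @param label human-readable label for the ODU.
#' @param minting a [minting_policy()].
#' @return A `phenokg_description` (environment; mutated in place by the
#'   builder functions).
#' @export
#' @examples
#' reg <- build_fixture_registry()
#' d <- create_description(reg, "EX:multicellularOrganism", "specimen 1")
#' head <- add_part(d, d$odu_uri, "UBERON:6000004", "its head")
create_description <- function(registry, root_class, label,
                               minting = minting_policy()) {
  resolve_term(registry, root_class)
  pkg <- new.env(parent = emptyenv())
  pkg$registry <- registry
  pkg$minting <- minting
  pkg$counter <- 0L
  pkg$instances <- list()
  pkg$assertions <- list()
  pkg$description_uri <- paste0(minting$namespace, "d", minting$seed)
  class(pkg) <- "phenokg_description"

  odu <- mint_uri(pkg)
  pkg$odu_uri <- odu
  pkg$instances[[odu]] <- list(uri = odu, classes = root_class, label = label,
                               parent = NA_character_)
  record_assertion(pkg, list(kind = "instantiation", subject = odu, class = root_class))
  record_assertion(pkg, list(kind = "labeling", subject = odu, value = label))
  pkg
}

record_assertion <- function(pkg, a) {
  a$ordinal <- length(pkg$assertions) + 1L
  pkg$assertions[[a$ordinal]] <- a
  invisible(a)
}

require_instance <- function(pkg, uri) {
  if (is.null(pkg$instances[[uri]])) {
    stop_phenokg("phenokg_reference_error",
                 sprintf("no instance with URI <%s> in this description", uri))
  }
  invisible(uri)
}

#' Describe a part of an existing instance
#'
#' Mints a fresh instance of `part_class`, records a parthood assertion
#' linking it to `whole_uri`, and returns the new URI. Parthood assertions
#' always grow the tree, so the partonomy stays acyclic with one parent per
#' part.
#'
#' @param pkg a `phenokg_description`.
#' @param whole_uri URI of the whole (must exist in the description).
#' @param part_class CURIE of the part's class.
#' @param label label for the part; defaults to the class label.
#' @return The minted part URI.
#' @export
add_part <- function(pkg, whole_uri, part_class, label = NULL) {
  require_instance(pkg, whole_uri)
  resolve_term(pkg$registry, part_class)
  if (is.null(label)) label <- resolve_term(pkg$registry, part_class)$label
  part <- mint_uri(pkg)
  pkg$instances[[part]] <- list(uri = part, classes = part_class, label = label,
                                parent = whole_uri)
  record_assertion(pkg, list(kind = "parthood", subject = whole_uri, object = part,
                             object_class = part_class, object_label = label,
                             category = CAT_PARTHOOD))
  part
}

#' Describe a quality of an instance
#'
#' Mints a quality instance with its own URI (e.g. a particular flattenedness
#' borne by a particular head) and links it to the bearer, tagged with the
#' perceptual category the observation answers (shape, color, ...).
#'
#' @inheritParams add_part
#' @param bearer_uri URI of the bearer.
#' @param quality_class CURIE of the quality's class.
#' @param category CURIE of a perceptual-category term.
#' @return The minted quality-instance URI.
#' @export
add_quality <- function(pkg, bearer_uri, quality_class, category) {
  require_instance(pkg, bearer_uri)
  resolve_term(pkg$registry, quality_class)
  if (!(category %in% pkg$registry$category_terms)) {
    stop_phenokg("phenokg_domain_error",
                 sprintf("'%s' is not a perceptual-category term", category))
  }
  q <- mint_uri(pkg)
  pkg$instances[[q]] <- list(uri = q, classes = quality_class, label = NA_character_,
                             parent = NA_character_)
  record_assertion(pkg, list(kind = "quality", subject = bearer_uri, object = q,
                             object_class = quality_class, category = category))
  q
}

#' Record a measurement on an instance
#'
#' Mints a measurement-quality instance (e.g. a particular live weight) and
#' records its numeric value and unit, tagged with a measurement category.
#'
#' @inheritParams add_quality
#' @param kind_class CURIE of the measured quality kind (e.g. live weight).
#' @param value numeric magnitude (zero allowed).
#' @param unit CURIE of a unit term.
#' @return The minted measurement-instance URI.
#' @export
add_measurement <- function(pkg, bearer_uri, kind_class, value, unit, category) {
  require_instance(pkg, bearer_uri)
  resolve_term(pkg$registry, kind_class)
  if (!is.numeric(value) || length(value) != 1 || is.na(value)) {
    stop_phenokg("phenokg_type_error", "measurement value must be a single number")
  }
  if (!is_unit_term(pkg$registry, unit)) {
    stop_phenokg("phenokg_domain_error",
                 sprintf("'%s' is not a unit term", unit))
  }
  if (!is_measurement_category(pkg$registry, category)) {
    stop_phenokg("phenokg_domain_error",
                 sprintf("'%s' is not a measurement category", category))
  }
  m <- mint_uri(pkg)
  pkg$instances[[m]] <- list(uri = m, classes = kind_class, label = NA_character_,
                             parent = NA_character_)
  record_assertion(pkg, list(kind = "measurement", subject = bearer_uri, object = m,
                             object_class = kind_class, value = value, unit = unit,
                             category = category))
  m
}

# Assert an additional class on an existing instance (used by the TBox
# expansion for atomic conjuncts and hybrid phenotype classes). `class_uri`
# may be given for classes that are not registry terms.
assert_class <- function(pkg, uri, class_curie) {
  require_instance(pkg, uri)
  inst <- pkg$instances[[uri]]
  if (!(class_curie %in% inst$classes)) {
    pkg$instances[[uri]]$classes <- c(inst$classes, class_curie)
    record_assertion(pkg, list(kind = "instantiation", subject = uri,
                               class = class_curie))
  }
  invisible(uri)
}

#' Partonomy backbone of a description
#'
#' @param pkg a `phenokg_description`.
#' @return A nested list rooted at the ODU; each node has `uri`, `class`
#'   (first asserted class), `label`, and `children` (insertion order).
#' @export
partonomy_tree <- function(pkg) {
  children <- list()
  for (a in pkg$assertions) {
    if (a$kind == "parthood") children[[a$subject]] <- c(children[[a$subject]], a$object)
  }
  build <- function(uri) {
    inst <- pkg$instances[[uri]]
    list(uri = uri, class = inst$classes[[1]], label = inst$label,
         children = lapply(children[[uri]] %||% character(0), build))
  }
  build(pkg$odu_uri)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

partonomy_size <- function(tree) {
  1L + sum(vapply(tree$children, partonomy_size, integer(1)))
}

# --- triples ----------------------------------------------------------------

uri_of_class <- function(pkg, curie) {
  # hybrid phenotype classes minted during expansion are PHENO:-prefixed and
  # live outside the registry's term list but inside its prefix map
  if (term_exists(pkg$registry, curie)) {
    term_uri(pkg$registry, curie)
  } else {
    curie_to_uri(curie, pkg$registry$prefix_map)
  }
}

prop_uri <- function(pkg, curie) term_uri(pkg$registry, curie)

# Triples carried by one assertion: the statement itself plus the
# instantiation (and, for parts, labeling) triples of the instance it minted.
assertion_triples <- function(pkg, a) {
  reg <- pkg$registry
  switch(a$kind,
    instantiation = rdf_statements(a$subject, prop_uri(pkg, RDF_TYPE),
                                   uri_of_class(pkg, a$class)),
    labeling = rdf_statements(a$subject, prop_uri(pkg, RDFS_LABEL), a$value,
                              o_kind = "string"),
    parthood = rdf_bind(
      rdf_statements(a$subject, prop_uri(pkg, P_HAS_PART), a$object),
      rdf_statements(a$object, prop_uri(pkg, RDF_TYPE),
                     uri_of_class(pkg, a$object_class)),
      rdf_statements(a$object, prop_uri(pkg, RDFS_LABEL), a$object_label,
                     o_kind = "string")),
    quality = rdf_bind(
      rdf_statements(a$subject, prop_uri(pkg, P_BEARER_OF), a$object),
      rdf_statements(a$object, prop_uri(pkg, RDF_TYPE),
                     uri_of_class(pkg, a$object_class))),
    measurement = rdf_bind(
      rdf_statements(a$subject, prop_uri(pkg, P_BEARER_OF), a$object),
      rdf_statements(a$object, prop_uri(pkg, RDF_TYPE),
                     uri_of_class(pkg, a$object_class)),
      rdf_statements(a$object, prop_uri(pkg, P_HAS_VALUE), format_decimal(a$value),
                     o_kind = "decimal"),
      rdf_statements(a$object, prop_uri(pkg, P_HAS_UNIT), term_uri(reg, a$unit))),
    stop_phenokg("phenokg_domain_error", sprintf("unknown assertion kind '%s'", a$kind)))
}

#' All triples of a description
#'
#' @param pkg a `phenokg_description`.
#' @return A canonical statement table (no graph component, no blank nodes).
#' @export
pkg_triples <- function(pkg) {
  rdf_canonical(do.call(rdf_bind, lapply(pkg$assertions, assertion_triples, pkg = pkg)))
}

#' Serialize a description as Turtle
#'
#' Canonical ordering makes the output byte-stable: identical construction
#' scripts under the same minting policy serialize identically.
#'
#' @inheritParams pkg_triples
#' @param file optional output path.
#' @export
pkg_to_turtle <- function(pkg, file = NULL) {
  write_turtle(pkg_triples(pkg), pkg$registry$prefix_map, file = file)
}

#' Deep copy of a description
#' @inheritParams pkg_triples
#' @export
pkg_clone <- function(pkg) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(pkg, all.names = TRUE)) assign(nm, get(nm, envir = pkg), envir = out)
  class(out) <- "phenokg_description"
  out
}

descriptive_assertions <- function(pkg) {
  Filter(function(a) a$kind %in% c("parthood", "quality", "measurement"),
         pkg$assertions)
}

#' @export
print.phenokg_description <- function(x, ...) {
  cat(sprintf("<phenokg_description> %s\n  %d instances, %d assertions (%d descriptive)\n",
              x$odu_uri, length(x$instances), length(x$assertions),
              length(descriptive_assertions(x))))
  invisible(x)
}
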