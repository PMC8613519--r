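# Canned worked examples: the descriptions and expressions used throughout
# the documentation and tests. They mirror the canonical illustrations of
# the two representations: a flattened insect head with two antennae (class
# axiom and instance graph), an organism partonomy with a flattened shape
# and an 84.3 mg live weight fragmented into named graphs with statement-
# level metadata, the eye + red EQ example, and the absence / exact-count
# modeling variants.

#' Worked-example class expressions
#'
#' `head_axiom_manchester()` is the class axiom of the flattened,
#' two-antenna insect head phenotype; `absence_manchester()` and
#' `exact_count_manchester()` are the absence and exact-count class
#' patterns; `relational_manchester()` is the "antenna longer than eye"
#' relational phenotype; `head_color_expression()` returns the large
#' head-coloration axiom shipped as a parser stress fixture.
#'
#' @return Manchester-syntax text.
#' @export
head_axiom_manchester <- function() {
  "insect head and ( bearer of some flattened ) and ( has part exactly 2 antenna )"
}

#' @rdname head_axiom_manchester
#' @export
absence_manchester <- function() "not ( has part some ovipositor )"

#' @rdname head_axiom_manchester
#' @export
exact_count_manchester <- function() "has component exactly 3 ocellus"

#' @rdname head_axiom_manchester
#' @export
relational_manchester <- function() {
  paste("has part some ( antenna and bearer of some ( length and",
        "increased in magnitude relative to some ( length and inheres in some eye ) ) )")
}

#' @rdname head_axiom_manchester
#' @export
head_color_expression <- function() {
  path <- system.file("extdata", "head-color-expression.txt", package = "phenokg",
                      mustWork = TRUE)
  paste(readLines(path, warn = FALSE), collapse = " ")
}

#' Build the organism worked-example description
#'
#' A multicellular organism that possesses an insect head which in turn
#' possesses an antenna (the partonomy backbone), bears a flattened shape,
#' and has a measured live weight of 84.3 milligrams.
#'
#' @param registry a `phenokg_registry`.
#' @param seed minting seed (determines the description URI).
#' @return A `phenokg_description`.
#' @export
build_organism_example <- function(registry, seed = 12L) {
  pkg <- create_description(registry, "EX:multicellularOrganism",
                            "this multicellular organism",
                            minting_policy(seed = seed))
  head <- add_part(pkg, pkg$odu_uri, "UBERON:6000004", "this insect head")
  add_part(pkg, head, "UBERON:0000972", "this antenna")
  add_quality(pkg, pkg$odu_uri, "PATO:0002254", CAT_SHAPE)
  add_measurement(pkg, pkg$odu_uri, "EX:liveWeight", 84.3, "EX:milligram", CAT_WEIGHT)
  pkg
}

#' Build the instance-graph form of the head worked example
#'
#' An insect head with a flattened shape and two antenna instances, each
#' part and quality with its own URI.
#'
#' @inheritParams build_organism_example
#' @export
build_head_example <- function(registry, seed = 11L) {
  pkg <- create_description(registry, "UBERON:6000004", "this insect head",
                            minting_policy(seed = seed))
  add_quality(pkg, pkg$odu_uri, "PATO:0002254", CAT_SHAPE)
  add_part(pkg, pkg$odu_uri, "UBERON:0000972", "antenna 1")
  add_part(pkg, pkg$odu_uri, "UBERON:0000972", "antenna 2")
  pkg
}

#' Absence / exact-count pattern variants of the worked examples
#'
#' The four outputs of [build_absence()] and [build_exact_count()] for
#' "abdomen lacks an ovipositor" and "head has exactly 3 ocelli", in both
#' the ABox-only (non-DL) and hybrid (DL-compliant) encodings.
#'
#' @inheritParams build_organism_example
#' @return Named list of `phenokg_pattern` objects.
#' @export
worked_example_patterns <- function(registry) {
  abdomen <- "http://example.org/phenokg/data/d14/i0001"
  head <- "http://example.org/phenokg/data/d15/i0001"
  list(absence_abox = build_absence("abox-only", registry, abdomen, "EX:ovipositor"),
       absence_hybrid = build_absence("hybrid", registry, abdomen, "EX:ovipositor"),
       count_abox = build_exact_count("abox-only", registry, head, "EX:ocellus", 3L),
       count_hybrid = build_exact_count("hybrid", registry, head, "EX:ocellus", 3L))
}

#' Assemble the worked-example store
#'
#' Fragments and stores: the two-antenna head description, the organism
#' description (with its statement-level metadata records: one on the shape
#' graph, one on the weight graph, one targeting the union of the two
#' parthood graphs), the eye + red description, and the hybrid-variant
#' absence and exact-count descriptions obtained by expanding their class
#' patterns. Description URIs are available in `store$examples`.
#'
#' @param registry a `phenokg_registry`.
#' @return A `phenokg_store`.
#' @export
build_worked_examples <- function(registry) {
  store <- store_create(registry)
  ex <- list()

  head_pkg <- build_head_example(registry)
  ex$head <- store_add_description(store, head_pkg)

  organism <- build_organism_example(registry)
  ex$organism <- store_add_description(store, organism)
  graphs <- store$graphs[store$descriptions[[ex$organism]]]
  cat_of <- vapply(graphs, `[[`, character(1), "category")
  uris <- vapply(graphs, `[[`, character(1), "uri")
  attach_metadata(store, metadata_record(
    uris[cat_of == CAT_SHAPE], agent = "observer A", date = "2021-06-01",
    instrument = "stereo microscope"))
  attach_metadata(store, metadata_record(
    uris[cat_of == CAT_WEIGHT], agent = "observer A", date = "2021-06-01",
    instrument = "precision balance"))
  attach_metadata(store, metadata_record(
    uris[cat_of == CAT_PARTHOOD], agent = "observer B", date = "2021-06-02",
    source = "dissection protocol 7"))

  eye_red <- create_description(registry, "EX:multicellularOrganism",
                                "specimen with red eye", minting_policy(seed = 13L))
  eye <- add_part(eye_red, eye_red$odu_uri, "MA:0000261", "this eye")
  add_quality(eye_red, eye, "PATO:0000322", CAT_COLOR)
  ex$eye_red <- store_add_description(store, eye_red)

  absent <- expand_to_abox(parse_manchester(absence_manchester(), registry),
                           registry, "EX:abdomen",
                           minting_policy(seed = 14L), "this abdomen")
  ex$absence <- store_add_description(store, absent$pkg)

  counted <- expand_to_abox(parse_manchester(exact_count_manchester(), registry),
                            registry, "UBERON:6000004",
                            minting_policy(seed = 15L), "this insect head")
  ex$count <- store_add_description(store, counted$pkg)

  store$examples <- ex
  store
}
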