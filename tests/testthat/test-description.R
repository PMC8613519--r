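test_that("a fresh description is a single labeled, typed instance", {
  reg <- the_registry
  d <- create_description(reg, "EX:multicellularOrganism", "specimen 1")
  expect_equal(length(d$instances), 1)
  expect_equal(length(phenokg:::descriptive_assertions(d)), 0)
  tree <- partonomy_tree(d)
  expect_equal(length(tree$children), 0)
  expect_error(create_description(reg, "XX:1", "x"), class = "phenokg_lookup_error")
})

test_that("identical construction scripts mint identical URIs and bytes", {
  reg <- the_registry
  build <- function() {
    d <- create_description(reg, "EX:multicellularOrganism", "s",
                            minting_policy(seed = 9L))
    h <- add_part(d, d$odu_uri, "UBERON:6000004")
    add_part(d, h, "UBERON:0000972")
    d
  }
  expect_identical(pkg_to_turtle(build()), pkg_to_turtle(build()))
})

test_that("the organism partonomy forms the captioned chain", {
  reg <- the_registry
  pkg <- build_organism_example(reg)
  tree <- partonomy_tree(pkg)
  expect_equal(tree$class, "EX:multicellularOrganism")
  expect_equal(length(tree$children), 1)
  expect_equal(tree$children[[1]]$class, "UBERON:6000004")
  expect_equal(tree$children[[1]]$children[[1]]$class, "UBERON:0000972")
})

test_that("repeated parts of the same class get distinct URIs", {
  reg <- the_registry
  pkg <- build_head_example(reg)
  antennae <- Filter(function(i) i$classes[[1]] == "UBERON:0000972", pkg$instances)
  expect_equal(length(antennae), 2)
  expect_equal(length(unique(vapply(antennae, `[[`, character(1), "uri"))), 2)
})

test_that("n part additions grow the partonomy to n + 1 nodes", {
  reg <- the_registry
  set.seed(8)
  for (trial in 1:5) {
    d <- create_description(reg, "EX:multicellularOrganism", "s",
                            minting_policy(seed = trial))
    uris <- d$odu_uri
    n <- sample(3:15, 1)
    for (k in seq_len(n)) {
      uris <- c(uris, add_part(d, sample(uris, 1), "EX:ocellus"))
    }
    expect_equal(phenokg:::partonomy_size(partonomy_tree(d)), n + 1L)
  }
})

test_that("partonomy_tree agrees with an independent edge reconstruction", {
  reg <- the_registry
  d <- generate_pkg(generator_params(seed = 21), reg)
  # oracle: re-derive parent->children edges straight from the assertions
  edges <- list()
  for (a in d$assertions) {
    if (a$kind == "parthood") edges[[a$subject]] <- c(edges[[a$subject]], a$object)
  }
  flatten <- function(node) {
    c(node$uri, unlist(lapply(node$children, flatten)))
  }
  oracle_nodes <- function(uri) {
    c(uri, unlist(lapply(edges[[uri]], oracle_nodes)))
  }
  expect_identical(flatten(partonomy_tree(d)), oracle_nodes(d$odu_uri))
})

test_that("quality instances are fresh and typed", {
  reg <- the_registry
  d <- create_description(reg, "EX:multicellularOrganism", "s")
  before <- names(d$instances)
  q <- add_quality(d, d$odu_uri, "PATO:0002254", "EX:catShape")
  expect_false(q %in% before)
  expect_equal(d$instances[[q]]$classes, "PATO:0002254")
  expect_error(add_quality(d, "urn:nope", "PATO:0000322", "EX:catColor"),
               class = "phenokg_reference_error")
  expect_error(add_quality(d, d$odu_uri, "PATO:0000322", "UBERON:0000972"),
               class = "phenokg_domain_error")
})

test_that("measurements validate value, unit, and category", {
  reg <- the_registry
  d <- create_description(reg, "EX:multicellularOrganism", "s")
  m <- add_measurement(d, d$odu_uri, "EX:liveWeight", 84.3, "EX:milligram", "EX:catWeight")
  a <- d$assertions[[length(d$assertions)]]
  expect_equal(a$value, 84.3)
  expect_equal(a$unit, "EX:milligram")
  # zero is a legal magnitude
  expect_no_error(add_measurement(d, d$odu_uri, "EX:liveWeight", 0, "EX:milligram",
                                  "EX:catWeight"))
  expect_error(add_measurement(d, d$odu_uri, "EX:liveWeight", "heavy", "EX:milligram",
                               "EX:catWeight"),
               class = "phenokg_type_error")
  expect_error(add_measurement(d, d$odu_uri, "EX:liveWeight", 1, "UBERON:0000972",
                               "EX:catWeight"),
               class = "phenokg_domain_error")
  expect_error(add_measurement(d, d$odu_uri, "EX:liveWeight", 1, "EX:milligram",
                               "EX:catShape"),
               class = "phenokg_domain_error")
})

test_that("serialized descriptions contain no blank nodes and label anatomy", {
  reg <- the_registry
  pkg <- build_organism_example(reg)
  ttl <- pkg_to_turtle(pkg)
  expect_false(grepl("_:", ttl, fixed = TRUE))
  triples <- pkg_triples(pkg)
  label_pred <- "http://www.w3.org/2000/01/rdf-schema#label"
  for (inst in pkg$instances) {
    expect_true(any(triples$s == inst$uri &
                      triples$p == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"),
                label = sprintf("%s instantiates a class", inst$uri))
    if (any(vapply(inst$classes, function(cl) phenokg:::is_anatomical_term(reg, cl),
                   logical(1)))) {
      expect_true(any(triples$s == inst$uri & triples$p == label_pred),
                  label = sprintf("%s carries a label", inst$uri))
    }
  }
})

test_that("decimal literals serialize at the printed precision", {
  reg <- the_registry
  pkg <- build_organism_example(reg)
  ttl <- pkg_to_turtle(pkg)
  expect_match(ttl, "\"84.3\"^^xsd:decimal", fixed = TRUE)
})
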