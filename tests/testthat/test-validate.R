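test_that("the worked examples and generator outputs are well-formed", {
  reg <- the_registry
  expect_true(check_wellformed(build_organism_example(reg))$ok)
  expect_true(check_wellformed(build_head_example(reg))$ok)
  for (s in 1:100) {
    expect_true(check_wellformed(generate_pkg(generator_params(seed = s), reg))$ok,
                label = sprintf("generator output %d well-formed", s))
  }
})

test_that("hand-injected violations are reported, never thrown", {
  reg <- the_registry
  d <- build_organism_example(reg)
  victim <- setdiff(names(d$instances), d$odu_uri)[1]
  d$instances[[victim]]$classes <- character(0)
  rep <- check_wellformed(d)
  expect_false(rep$ok)
  expect_true(any(rep$findings$severity == "error" & rep$findings$target == victim))

  d2 <- build_organism_example(reg)
  head_uri <- partonomy_tree(d2)$children[[1]]$uri
  # second parent for the head: multi-parent violation
  phenokg:::record_assertion(d2, list(kind = "parthood", subject = d2$odu_uri,
                                      object = head_uri,
                                      object_class = "UBERON:6000004",
                                      object_label = "dup", category = "EX:catParthood"))
  rep2 <- check_wellformed(d2)
  expect_false(rep2$ok)
  expect_true(any(grepl("more than one parent", rep2$findings$message)))

  d3 <- build_organism_example(reg)
  d3$instances[[d3$odu_uri]]$label <- NA_character_
  rep3 <- check_wellformed(d3)
  expect_true(rep3$ok)   # missing label is a warning, not an error
  expect_true(any(rep3$findings$severity == "warning"))
})

test_that("shape templates validate the worked-example graphs", {
  reg <- the_registry
  graphs <- fragment_description(build_organism_example(reg))
  cats <- vapply(graphs, `[[`, character(1), "category")
  weight <- graphs[[which(cats == "EX:catWeight")]]
  expect_true(check_shape(weight, registry = reg)$ok)

  # deleting the unit triple breaks the weight shape, naming the role
  broken <- weight
  broken$quads <- broken$quads[broken$quads$p != term_uri(reg, "EX:hasUnit"), ]
  rep <- check_shape(broken, registry = reg)
  expect_false(rep$ok)
  expect_true(any(grepl("'unit'", rep$findings$message)))

  # a category without a template warns instead of erroring
  inst <- graphs[[which(cats == "EX:catInstantiation")]]
  rep2 <- check_shape(inst, registry = reg)
  expect_true(rep2$ok)
  expect_true(any(rep2$findings$severity == "warning"))
})

test_that("shape checking agrees with a per-role triple-scan oracle", {
  reg <- the_registry
  catalog <- default_shape_catalog()
  covered <- vapply(catalog, `[[`, character(1), "category")
  role_oracle <- function(g) {
    # independent scan: which roles have at least one filling triple
    has <- function(p) any(g$quads$p == term_uri(reg, p))
    ok <- switch(g$category,
      "EX:catParthood" = has("EX:hasPart"),
      "EX:catShape" = ,
      "EX:catColor" = has("EX:bearerOf"),
      has("EX:bearerOf") && has("EX:hasValue") && has("EX:hasUnit"))
    ok
  }
  n_checked <- 0
  for (s in 61:75) {
    d <- generate_pkg(generator_params(seed = s), reg)
    for (g in fragment_description(d)) {
      if (!(g$category %in% covered)) next
      expect_equal(check_shape(g, catalog, reg)$ok, role_oracle(g),
                   label = sprintf("shape vs oracle, seed %d graph %s", s, g$uri))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 50)
})

test_that("shape catalogs round-trip through YAML and export to SHACL", {
  reg <- the_registry
  catalog <- default_shape_catalog()
  f <- withr::local_tempfile(fileext = ".yaml")
  shape_catalog_to_yaml(catalog, f)
  back <- shape_catalog_from_yaml(f)
  expect_equal(length(back), length(catalog))
  expect_identical(lapply(back, unclass), lapply(catalog, unclass))
  shacl <- shape_catalog_to_shacl(catalog, reg)
  parsed <- read_turtle(shacl)
  expect_true(any(grepl("shacl#NodeShape", parsed$o)))
  expect_true(any(grepl("shacl#minCount", parsed$p)))
})

test_that("DL-compliance flags the two non-OWL constructs and passes plain graphs", {
  reg <- the_registry
  bearer <- "http://example.org/phenokg/data/d97/i0001"
  verdict <- dl_compliance(build_absence("abox-only", reg, bearer, "EX:ovipositor"), reg)
  expect_false(verdict$compliant)
  expect_equal(verdict$offending, "has not part any")
  expect_true(dl_compliance(build_absence("hybrid", reg, bearer, "EX:ovipositor"),
                            reg)$compliant)
  expect_true(dl_compliance(pkg_triples(build_organism_example(reg)), reg)$compliant)
})

test_that("the weight query scenario retrieves only the heavy specimen", {
  reg <- the_registry
  st <- store_create(reg)
  heavy <- store_add_description(st, build_organism_example(reg))          # 84.3 mg
  light_pkg <- create_description(reg, "EX:multicellularOrganism", "light one",
                                  minting_policy(seed = 41L))
  add_measurement(light_pkg, light_pkg$odu_uri, "EX:liveWeight", 5, "EX:milligram",
                  "EX:catWeight")
  light <- store_add_description(st, light_pkg)

  crit <- query_criteria(measurements = list(
    list(kind = "EX:weightQuality", comparator = ">", value = 10, unit = "EX:milligram")))
  expect_identical(run_query(st, crit), heavy)

  # manual-filter oracle over the two fixtures
  oracle <- Filter(function(d) {
    u <- union_graphs(active_graphs(st, d))
    vals <- as.numeric(u$o[u$o_kind == "decimal"])
    any(vals > 10)
  }, names(st$descriptions))
  expect_identical(run_query(st, crit), sort(unlist(oracle)))

  empty <- store_create(reg)
  expect_identical(run_query(empty, crit), character(0))
  # mismatched units never match (no unit conversion)
  crit_mm <- query_criteria(measurements = list(
    list(kind = "EX:weightQuality", comparator = ">", value = 10, unit = "EX:millimetre")))
  expect_identical(run_query(st, crit_mm), character(0))
  expect_error(run_query(st, query_criteria(measurements = list(
    list(kind = "EX:weightQuality", comparator = ">", value = 10, unit = "XX:9")))),
    class = "phenokg_domain_error")
})

test_that("parthood-pair and taxon criteria match the worked example", {
  reg <- the_registry
  st <- build_worked_examples(reg)
  crit <- query_criteria(parthood_pairs = list(c("UBERON:6000004", "UBERON:0000972")))
  hits <- run_query(st, crit)
  expect_true(st$examples$organism %in% hits)
  expect_false(st$examples$eye_red %in% hits)

  # taxon restriction: nothing carries the Insecta assertion yet
  expect_identical(run_query(st, query_criteria(taxon_class = "EX:insecta")),
                   character(0))
  expect_error(query_criteria(), class = "phenokg_domain_error")
})

test_that("queries are monotone-decreasing and closure reduces to exact on flat pools", {
  reg <- the_registry
  st <- store_create(reg)
  for (s in 81:90) store_add_description(st, generate_pkg(generator_params(seed = s), reg))

  pool <- c("UBERON:6000004", "UBERON:0000972", "EX:ocellus", "EX:abdomen")
  set.seed(303)
  for (trial in 1:20) {
    picked <- sample(pool, sample(1:3, 1))
    prev <- run_query(st, query_criteria(part_classes = picked[1]))
    for (k in seq_along(picked)[-1]) {
      cur <- run_query(st, query_criteria(part_classes = picked[seq_len(k)]))
      expect_true(all(cur %in% prev),
                  label = sprintf("adding a criterion never enlarges results (trial %d)", trial))
      prev <- cur
    }
  }
  # the generator's part classes have no subclasses: closure = exact matching
  for (cls in pool) {
    expect_identical(
      run_query(st, query_criteria(part_classes = cls, part_closure = TRUE)),
      run_query(st, query_criteria(part_classes = cls, part_closure = FALSE)))
  }
})
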