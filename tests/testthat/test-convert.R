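test_that("expanding the head axiom mints the captioned instances", {
  reg <- the_registry
  res <- expand_to_abox(parse_manchester(head_axiom_manchester(), reg),
                        reg, "UBERON:6000004")
  cls <- vapply(res$pkg$instances, function(i) i$classes[[1]], character(1))
  expect_equal(sum(cls == "UBERON:6000004"), 1)   # exactly one insect head (the ODU)
  expect_equal(sum(cls == "UBERON:0000972"), 2)   # exactly two antennae
  expect_equal(sum(cls == "PATO:0002254"), 1)     # one flattened quality instance
  expect_equal(length(res$hybrid), 1)             # the antenna exact-count survives OWA
  expect_equal(res$hybrid[[1]]$kind, "exact-count")
  expect_equal(length(res$residue), 0)
})

test_that("atomic and absence expressions expand to the degenerate graphs", {
  reg <- the_registry
  solo <- expand_to_abox(ce_atomic("UBERON:6000004"), reg, "UBERON:6000004")
  expect_equal(length(solo$pkg$instances), 1)
  expect_equal(length(solo$residue), 0)

  absent <- expand_to_abox(parse_manchester(absence_manchester(), reg),
                           reg, "EX:abdomen")
  expect_equal(length(absent$pkg$instances), 1)   # nothing minted for the negation
  expect_equal(length(absent$hybrid), 1)
  expect_equal(absent$hybrid[[1]]$kind, "absence")
  # the hybrid class is asserted on the bearer
  expect_true(absent$hybrid[[1]]$class_curie %in%
                absent$pkg$instances[[absent$pkg$odu_uri]]$classes)
})

test_that("witness counts match the AST-interpreter oracle on random expressions", {
  reg <- the_registry
  set.seed(202)
  for (i in 1:100) {
    e <- rand_expr(depth = sample(2:5, 1))
    res <- expand_to_abox(e, reg, "EX:multicellularOrganism",
                          minting_policy(seed = i))
    expect_identical(minted_counts(res), expected_mint_counts(e, reg),
                     label = sprintf("witness counts, expression %d", i))
    # totality: every AST node is accounted for
    expect_equal(res$handled_nodes, phenokg:::expr_nodes(e),
                 label = sprintf("node accounting, expression %d", i))
  }
})

test_that("residue carries unexpandable subexpressions with reasons", {
  reg <- the_registry
  e <- parse_manchester(relational_manchester(), reg)
  res <- expand_to_abox(e, reg, "EX:multicellularOrganism")
  expect_gt(length(res$residue), 0)
  expect_true(all(vapply(res$residue, function(r) {
    r$bearer %in% names(res$pkg$instances)
  }, logical(1))))
  expect_match(res$residue[[1]]$reason, "not expandable")
})

test_that("roll-up inverts the EQ composition and handles degenerate graphs", {
  reg <- the_registry
  d <- create_description(reg, "EX:multicellularOrganism", "s")
  eye <- add_part(d, d$odu_uri, "MA:0000261", "this eye")
  add_quality(d, eye, "PATO:0000322", "EX:catColor")
  expr <- rollup_to_tbox(d, include_root_classes = FALSE)
  eq <- expression_to_eq(expr)
  expect_equal(eq$entity, "MA:0000261")
  expect_equal(eq$quality, "PATO:0000322")

  solo <- create_description(reg, "UBERON:6000004", "just a head")
  rolled <- rollup_to_tbox(solo)
  expect_length(attr(rolled, "skipped"), 0)
  attr(rolled, "skipped") <- NULL
  expect_identical(rolled, ce_atomic("UBERON:6000004"))
  expect_error(rollup_to_tbox(d, root = "urn:nope"), class = "phenokg_reference_error")
})

test_that("measurements are excluded from roll-up and reported", {
  reg <- the_registry
  pkg <- build_organism_example(reg)
  expr <- rollup_to_tbox(pkg)
  skipped <- attr(expr, "skipped")
  expect_equal(length(skipped), 1)
  expect_equal(skipped[[1]]$value, 84.3)
  expect_false(grepl("has value", serialize_manchester(expr, reg)))
})

test_that("closed-world roll-up then expansion reproduces the graph up to URIs", {
  reg <- the_registry
  for (s in 1:100) {
    p <- generate_pkg(generator_params(seed = s, p_measurement = 0), reg)
    expr <- rollup_to_tbox(p, closed_world = TRUE)
    res <- expand_to_abox(expr, reg, "EX:multicellularOrganism",
                          minting_policy(seed = s + 5000L))
    expect_identical(pkg_signature(res$pkg), pkg_signature(p),
                     label = sprintf("expand(rollup(pkg)) isomorphism, seed %d", s))
  }
})

test_that("absence builders produce the two modeling variants with correct flags", {
  reg <- the_registry
  bearer <- "http://example.org/phenokg/data/d99/i0001"
  abox <- build_absence("abox-only", reg, bearer, "EX:ovipositor")
  expect_false(abox$dl_compliant)
  expect_equal(abox$construct, "has not part any")
  expect_equal(nrow(abox$statements), 1)

  hybrid <- build_absence("hybrid", reg, bearer, "EX:ovipositor")
  expect_true(hybrid$dl_compliant)
  expect_equal(serialize_manchester(hybrid$pattern, reg),
               "not ( has part some ovipositor )")
  # skolemized class definition, no blank nodes
  expect_false(any(grepl("^_:", unlist(hybrid$statements[c("s", "o")]))))
})

test_that("exact-count builders produce the two modeling variants with correct flags", {
  reg <- the_registry
  bearer <- "http://example.org/phenokg/data/d98/i0001"
  abox <- build_exact_count("abox-only", reg, bearer, "EX:ocellus", 3)
  expect_false(abox$dl_compliant)
  expect_equal(abox$construct, "towards class")
  expect_true(any(abox$statements$o == "3" & abox$statements$o_kind == "integer"))

  hybrid <- build_exact_count("hybrid", reg, bearer, "EX:ocellus", 3)
  expect_true(hybrid$dl_compliant)
  expect_equal(serialize_manchester(hybrid$pattern, reg),
               "has component exactly 3 ocellus")
  # cardinality zero is legal (absence in intent)
  zero <- build_exact_count("hybrid", reg, bearer, "EX:ocellus", 0)
  expect_equal(zero$pattern$n, 0L)
  expect_error(build_exact_count("hybrid", reg, bearer, "EX:ocellus", -1),
               class = "phenokg_domain_error")
})

test_that("dl_compliance agrees with the builders' flags on all four variants", {
  reg <- the_registry
  pats <- worked_example_patterns(reg)
  for (nm in names(pats)) {
    verdict <- dl_compliance(pats[[nm]], reg)
    expect_equal(verdict$compliant, pats[[nm]]$dl_compliant,
                 label = sprintf("flag agreement for %s", nm))
    if (!verdict$compliant) {
      expect_equal(verdict$offending, pats[[nm]]$construct)
    }
  }
})

test_that("comparative statements convert to the stated bounds or fail loudly", {
  inc <- comparative_statement("EX:lengthQuality", "EX:abdomen", "increased",
                               reference_value = 2.6,
                               reference_unit = "EX:millimetre")
  direct <- comparative_to_direct(inc)
  expect_equal(direct$bound_kind, "exclusive-lower")
  expect_equal(direct$bound_value, 2.6)
  expect_equal(direct$unit, "EX:millimetre")

  dec <- comparative_statement("EX:lengthQuality", "EX:abdomen", "decreased",
                               reference_value = 2.6,
                               reference_unit = "EX:millimetre")
  mirror <- comparative_to_direct(dec)
  expect_equal(mirror$bound_kind, "exclusive-upper")
  expect_equal(mirror$bound_value, direct$bound_value)   # direction-antisymmetric
  expect_equal(mirror$unit, direct$unit)                 # unit-preserving

  unresolved <- comparative_statement("EX:lengthQuality", "EX:abdomen", "increased")
  expect_error(comparative_to_direct(unresolved),
               class = "phenokg_unresolvable_comparative")
})
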