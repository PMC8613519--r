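example_store <- function() build_worked_examples(the_registry)

test_that("the organism description fragments into the captioned named graphs", {
  pkg <- build_organism_example(the_registry)
  graphs <- fragment_description(pkg)
  cats <- table(vapply(graphs, `[[`, character(1), "category"))
  expect_equal(unname(cats[["EX:catParthood"]]), 2)
  expect_equal(unname(cats[["EX:catShape"]]), 1)
  expect_equal(unname(cats[["EX:catWeight"]]), 1)
  expect_equal(unname(cats[["EX:catInstantiation"]]), 1)
  # all quads carry their graph's URI
  for (g in graphs) expect_true(all(g$quads$g == g$uri))
})

test_that("an undescribed specimen fragments to the instantiation graph only", {
  d <- create_description(the_registry, "EX:multicellularOrganism", "s")
  graphs <- fragment_description(d)
  expect_equal(length(graphs), 1)
  expect_equal(graphs[[1]]$category, "EX:catInstantiation")
})

test_that("descriptive graph count equals the descriptive assertion count", {
  for (s in c(31, 32, 33, 34, 35)) {
    d <- generate_pkg(generator_params(seed = s), the_registry)
    graphs <- fragment_description(d)
    expect_equal(length(graphs) - 1L,       # minus the instantiation graph
                 length(phenokg:::descriptive_assertions(d)))
  }
})

test_that("union of the fragments returns the description's triple set exactly", {
  pkg <- build_organism_example(the_registry)
  expect_true(rdf_equal(union_graphs(fragment_description(pkg)), pkg_triples(pkg)))
  expect_equal(nrow(union_graphs(list())), 0)
  for (s in 1:100) {
    d <- generate_pkg(generator_params(seed = s), the_registry)
    expect_true(rdf_equal(union_graphs(fragment_description(d)), pkg_triples(d)),
                label = sprintf("union(fragment(pkg)) identity, seed %d", s))
  }
})

test_that("fragmentation partitions descriptive content up to shared type triples", {
  n_pairs <- 0L
  for (s in 51:60) {
    d <- generate_pkg(generator_params(seed = s), the_registry)
    graphs <- fragment_description(d)
    descriptive <- Filter(function(g) g$category != "EX:catInstantiation", graphs)
    if (length(descriptive) < 2) next
    combos <- utils::combn(length(descriptive), 2)
    for (k in seq_len(ncol(combos))) {
      a <- descriptive[[combos[1, k]]]$quads
      b <- descriptive[[combos[2, k]]]$quads
      shared <- merge(a[, c("s", "p", "o")], b[, c("s", "p", "o")])
      expect_equal(nrow(shared), 0,
                   label = sprintf("graphs pairwise disjoint (seed %d)", s))
      n_pairs <- n_pairs + 1L
    }
  }
  expect_gt(n_pairs, 10)
})

test_that("the weight data view returns the captioned measurement", {
  st <- example_store()
  v <- apply_view(st, st$examples$organism, data_view("weights", "EX:catWeight"))
  expect_true(any(v$o == "84.3" & v$o_kind == "decimal"))
  expect_true(any(v$o == term_uri(the_registry, "EX:milligram")))
  # the measurement-category view with closure is a superset
  vm <- apply_view(st, st$examples$organism,
                   data_view("measurements", "EX:catMeasurement", use_closure = TRUE))
  expect_true(all(apply(v, 1, paste, collapse = "\r") %in%
                    apply(vm, 1, paste, collapse = "\r")))
  # a category no graph carries selects nothing
  empty <- apply_view(st, st$examples$organism, data_view("dev", "EX:catDevelopment"))
  expect_equal(nrow(empty), 0)
  expect_error(apply_view(st, "http://nope/", data_view("w", "EX:catWeight")),
               class = "phenokg_lookup_error")
})

test_that("data views are monotone in the category set", {
  st <- example_store()
  cats <- c("EX:catWeight", "EX:catShape", "EX:catParthood", "EX:catInstantiation")
  for (k in 1:3) {
    a_cats <- cats[seq_len(k)]
    b_cats <- cats[seq_len(k + 1)]
    a <- apply_view(st, st$examples$organism, data_view("a", a_cats))
    b <- apply_view(st, st$examples$organism, data_view("b", b_cats))
    expect_true(nrow(merge(a, b)) == nrow(a),
                label = sprintf("view(%d cats) within view(%d cats)", k, k + 1))
  }
})

test_that("metadata records attach as separate named graphs with correct targets", {
  st <- example_store()
  graphs <- st$graphs[st$descriptions[[st$examples$organism]]]
  cats <- vapply(graphs, `[[`, character(1), "category")
  uris <- vapply(graphs, `[[`, character(1), "uri")
  shape_uri <- uris[cats == "EX:catShape"]
  about <- term_uri(the_registry, "EX:about")
  shape_meta <- Filter(function(q) any(q$p == about & q$o == shape_uri),
                       st$meta_graphs)
  expect_equal(length(shape_meta), 1)
  # one record targets both parthood graphs through a single metadata graph
  parthood_uris <- uris[cats == "EX:catParthood"]
  both <- Filter(function(q) all(parthood_uris %in% q$o[q$p == about]),
                 st$meta_graphs)
  expect_equal(length(both), 1)
  expect_error(attach_metadata(st, metadata_record("http://nope/", "a", "2021-01-01")),
               class = "phenokg_reference_error")
  expect_error(metadata_record("http://x/", "a", "not a date"),
               class = "phenokg_domain_error")
  expect_error(metadata_record(character(0), "a", "2021-01-01"),
               class = "phenokg_domain_error")
})

test_that("micro-publication content rides in reserved free fields", {
  st <- example_store()
  wg <- names(Filter(function(g) g$category == "EX:catWeight", st$graphs))[1]
  mg <- attach_metadata(st, metadata_record(
    wg, "observer A", "2021-06-03",
    free_fields = list(text = "live weight measured before fixation",
                       media = "http://example.org/media/scale-photo-1")))
  q <- st$meta_graphs[[mg]]
  expect_true(any(grepl("vocab#text$", q$p) &
                    q$o == "live weight measured before fixation"))
  expect_true(any(grepl("vocab#media$", q$p)))
})

test_that("nanopublication export bundles four linked, disjoint graphs", {
  st <- example_store()
  wg <- names(Filter(function(g) g$category == "EX:catWeight", st$graphs))[1]
  np <- export_nanopublication(st, wg, exported_by = "curator",
                               export_date = "2021-07-01")
  quads <- nanopub_quads(np)
  graph_uris <- unique(quads$g)
  expect_equal(length(graph_uris), 4)
  head_g <- np$head
  for (target in setdiff(graph_uris, unique(np$head$g))) {
    expect_true(any(head_g$o == target) || target == wg,
                label = sprintf("head references %s", target))
  }
  expect_true(any(head_g$o == wg))
  # TriG round trip preserves the quad multiset
  expect_true(rdf_equal(read_trig(nanopub_to_trig(np)), quads))
  # a graph without metadata cannot be published
  hg <- names(Filter(function(g) g$category == "EX:catColor", st$graphs))
  eye_graphs <- st$descriptions[[st$examples$eye_red]]
  expect_error(export_nanopublication(st, eye_graphs[[2]]),
               class = "phenokg_precondition_error")
})

test_that("revision replaces the active graph and keeps walkable history", {
  st <- example_store()
  wg <- names(Filter(function(g) g$category == "EX:catWeight", st$graphs))[1]
  old <- st$graphs[[wg]]
  fix_value <- function(g, uri, val) {
    q <- g$quads
    q$o[q$o_kind == "decimal"] <- val
    named_graph(uri, g$category, g$subject_part, q)
  }
  repl <- fix_value(old, paste0(old$uri, "-r1"), "48.3")
  ch <- revise_graph(st, wg, repl, metadata_record(wg, "corrector", "2021-07-02"))
  expect_equal(ch$superseded, wg)
  v <- apply_view(st, st$examples$organism, data_view("w", "EX:catWeight"))
  expect_true(any(v$o == "48.3"))
  expect_false(any(v$o == "84.3"))
  # history retained with a supersedes link in the change metadata graph
  expect_true(wg %in% names(st$graphs))
  link <- st$meta_graphs[[ch$metadata_graph]]
  expect_true(any(link$s == repl$uri & link$o == wg))
  # revising the superseded graph is stale; category mismatch is a domain error
  expect_error(revise_graph(st, wg, fix_value(old, paste0(old$uri, "-r2"), "1.0"),
                            metadata_record(wg, "x", "2021-07-03")),
               class = "phenokg_staleness_error")
  bad_cat <- named_graph(paste0(old$uri, "-r9"), "EX:catShape", old$subject_part,
                         old$quads)
  expect_error(revise_graph(st, repl$uri, bad_cat,
                            metadata_record(repl$uri, "x", "2021-07-03")),
               class = "phenokg_domain_error")
  # second successive revision gives a chain of length 3, newest first
  repl2 <- fix_value(repl, paste0(old$uri, "-r2"), "48.4")
  revise_graph(st, repl$uri, repl2, metadata_record(repl$uri, "x", "2021-07-04"))
  expect_equal(revision_chain(st, repl2$uri), c(repl2$uri, repl$uri, wg))
  # union identity holds on the active graph set after revision
  active <- active_graphs(st, st$examples$organism)
  u <- union_graphs(active)
  expect_true(any(u$o == "48.4"))
  expect_false(any(u$o %in% c("48.3", "84.3")))
})

test_that("a store survives a save/load round trip", {
  st <- example_store()
  wg <- names(Filter(function(g) g$category == "EX:catWeight", st$graphs))[1]
  dir <- withr::local_tempdir()
  store_save(st, dir)
  st2 <- store_load(dir)
  expect_true(rdf_equal(store_quads(st2), store_quads(st)))
  expect_setequal(names(st2$descriptions), names(st$descriptions))
  crit <- query_criteria(measurements = list(
    list(kind = "EX:weightQuality", comparator = ">", value = 10, unit = "EX:milligram")))
  expect_identical(run_query(st2, crit), run_query(st, crit))
  np <- export_nanopublication(st2, wg, export_date = "2021-07-01")
  expect_s3_class(np, "phenokg_nanopub")
})

test_that("every named graph instantiates exactly one category in exported quads", {
  st <- example_store()
  quads <- store_quads(st)
  type_p <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  for (g in st$graphs) {
    cat_triples <- quads[is.na(quads$g) & quads$s == g$uri & quads$p == type_p, ]
    expect_equal(nrow(cat_triples), 1, label = sprintf("category triple for %s", g$uri))
    expect_equal(cat_triples$o, term_uri(the_registry, g$category))
  }
})
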