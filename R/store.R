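# Named-graph fragmentation and the quad store.
#
# A description fragments into one named graph per descriptive assertion --
# the smallest unit of empirical information: a parthood link, a quality, a
# measurement -- plus one instantiation graph for the ODU's own type/label
# statements. Each named graph has its own URI and a category term; the
# description is the union of its graphs. The store keeps fragmented
# descriptions, statement-level metadata (each in its own named graph),
# nanopublication export, and revision chains.

#' Construct a descriptive named graph
#'
#' @param uri graph URI.
#' @param category CURIE of the category term the graph instantiates.
#' @param subject_part URI of the part the statement is about.
#' @param statements statement table; the graph component is overwritten
#'   with `uri` ("turning the triples into quads").
#' @return A `phenokg_named_graph`.
#' @export
named_graph <- function(uri, category, subject_part, statements) {
  statements$g <- uri
  structure(list(uri = uri, category = category, subject_part = subject_part,
                 quads = rdf_canonical(statements)),
            class = "phenokg_named_graph")
}

category_slug <- function(registry, category) {
  gsub(" ", "-", resolve_term(registry, category)$label)
}

#' Fragment a description into descriptive named graphs
#'
#' Produces exactly one named graph per descriptive assertion, carrying that
#' assertion's triples plus the type/label triples of the instance the
#' assertion minted; the ODU's own instantiation and labeling triples (and
#' any later standalone class assertions) go into a single instantiation
#' graph. Graph URIs are deterministic in (description URI, ordinal,
#' category), so re-fragmenting the same description is byte-stable.
#'
#' @param pkg a `phenokg_description`.
#' @return List of `phenokg_named_graph`, instantiation graph first.
#' @export
fragment_description <- function(pkg) {
  reg <- pkg$registry
  inst_assertions <- Filter(function(a) a$kind %in% c("instantiation", "labeling"),
                            pkg$assertions)
  inst_uri <- paste0(pkg$description_uri, "/graph/instantiation")
  graphs <- list(named_graph(
    inst_uri, CAT_INSTANTIATION, pkg$odu_uri,
    do.call(rdf_bind, lapply(inst_assertions, assertion_triples, pkg = pkg))))
  for (a in descriptive_assertions(pkg)) {
    g_uri <- paste0(pkg$description_uri, "/graph/",
                    sprintf("%03d", a$ordinal), "-", category_slug(reg, a$category))
    graphs[[length(graphs) + 1L]] <-
      named_graph(g_uri, a$category, a$subject, assertion_triples(pkg, a))
  }
  graphs
}

#' Union of named graphs
#'
#' Drops the graph component and returns the set union of the member
#' statements: applied to all fragments of a description it returns the
#' description's triple set exactly.
#'
#' @param graphs list of `phenokg_named_graph`.
#' @return Canonical statement table.
#' @export
union_graphs <- function(graphs) {
  if (length(graphs) == 0) return(rdf_empty())
  rdf_drop_graph(do.call(rdf_bind, lapply(graphs, `[[`, "quads")))
}

# --- store ------------------------------------------------------------------

#' Create an empty description store
#'
#' @param registry a `phenokg_registry`.
#' @param namespace IRI base for minted metadata-graph URIs.
#' @return A `phenokg_store` (environment).
#' @export
store_create <- function(registry, namespace = "http://example.org/phenokg/store/") {
  st <- new.env(parent = emptyenv())
  st$registry <- registry
  st$namespace <- namespace
  st$graphs <- list()        # graph uri -> phenokg_named_graph
  st$descriptions <- list()  # description uri -> character vector of graph uris
  st$active <- logical(0)    # named by graph uri
  st$metadata <- list()      # metadata records (with minted graph uri)
  st$meta_graphs <- list()   # metadata graph uri -> quads
  st$revisions <- list()     # change records
  st$meta_counter <- 0L
  class(st) <- "phenokg_store"
  st
}

#' Add a description to a store
#'
#' Fragments the description and registers all its named graphs as active.
#'
#' @param store a `phenokg_store`.
#' @param pkg a `phenokg_description`.
#' @return The description URI.
#' @export
store_add_description <- function(store, pkg) {
  graphs <- fragment_description(pkg)
  uris <- vapply(graphs, `[[`, character(1), "uri")
  for (g in graphs) store$graphs[[g$uri]] <- g
  store$descriptions[[pkg$description_uri]] <- uris
  store$active[uris] <- TRUE
  pkg$description_uri
}

require_description <- function(store, description) {
  if (is.null(store$descriptions[[description]])) stop_lookup(description)
  invisible(description)
}

#' Active named graphs of a description
#' @inheritParams store_add_description
#' @param description description URI.
#' @export
active_graphs <- function(store, description) {
  require_description(store, description)
  uris <- store$descriptions[[description]]
  store$graphs[uris[store$active[uris]]]
}

#' Define a data view
#'
#' A data view selects the named graphs of a description whose category falls
#' in a category set -- e.g. all weight measurements, or (with
#' `use_closure`) everything under the measurement category.
#'
#' @param name view name.
#' @param categories CURIEs of category terms.
#' @param use_closure expand categories through [subclass_closure()]?
#' @export
data_view <- function(name, categories, use_closure = FALSE) {
  structure(list(name = name, categories = categories, use_closure = use_closure),
            class = "phenokg_data_view")
}

#' Apply a data view to a stored description
#'
#' @inheritParams active_graphs
#' @param view a [data_view()].
#' @return Union (triples) of the active named graphs whose category is in
#'   the view's (optionally closure-expanded) category set.
#' @export
apply_view <- function(store, description, view) {
  require_description(store, description)
  cats <- view$categories
  for (cu in cats) resolve_term(store$registry, cu)
  if (isTRUE(view$use_closure)) {
    cats <- unique(unlist(lapply(cats, subclass_closure, registry = store$registry)))
  }
  keep <- Filter(function(g) g$category %in% cats, active_graphs(store, description))
  union_graphs(keep)
}

# --- metadata ---------------------------------------------------------------

#' Construct a metadata record
#'
#' Metadata are statements about descriptive statements: who observed what,
#' when, with which instrument, from which source. A record may target
#' several named graphs (a statement about the union of two parthood graphs
#' is one record with two targets). The reserved free-field keys `text` and
#' `media` carry natural-language fragments and media links
#' (micro-publication content).
#'
#' @param target_graphs URIs of the described named graphs (non-empty).
#' @param agent who made or entered the observation.
#' @param date ISO-8601 date or date-time text.
#' @param source,instrument optional provenance detail.
#' @param free_fields named list of further text fields.
#' @export
metadata_record <- function(target_graphs, agent, date, source = NULL,
                            instrument = NULL, free_fields = list()) {
  if (length(target_graphs) == 0) {
    stop_phenokg("phenokg_domain_error", "metadata record needs at least one target graph")
  }
  parsed <- tryCatch(as.POSIXct(date, tz = "UTC",
                                tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d")),
                     error = function(e) NA)
  if (is.na(parsed)) {
    stop_phenokg("phenokg_domain_error",
                 sprintf("metadata date '%s' is not ISO-8601", date))
  }
  structure(list(target_graphs = target_graphs, agent = agent, date = date,
                 source = source, instrument = instrument, free_fields = free_fields),
            class = "phenokg_metadata")
}

metadata_quads <- function(store, mg_uri, record) {
  reg <- store$registry
  ex <- function(local) paste0(reg$prefix_map[["EX"]], local)
  rows <- list(
    rdf_statements(mg_uri, term_uri(reg, P_ABOUT), record$target_graphs, g = mg_uri),
    rdf_statements(mg_uri, ex("agent"), record$agent, o_kind = "string", g = mg_uri),
    rdf_statements(mg_uri, ex("date"), record$date, o_kind = "string", g = mg_uri))
  if (!is.null(record$source)) {
    rows <- c(rows, list(rdf_statements(mg_uri, ex("source"), record$source,
                                        o_kind = "string", g = mg_uri)))
  }
  if (!is.null(record$instrument)) {
    rows <- c(rows, list(rdf_statements(mg_uri, ex("instrument"), record$instrument,
                                        o_kind = "string", g = mg_uri)))
  }
  for (key in names(record$free_fields)) {
    pred <- ex(gsub("[^A-Za-z0-9_-]", "-", key))
    rows <- c(rows, list(rdf_statements(mg_uri, pred,
                                        as.character(record$free_fields[[key]]),
                                        o_kind = "string", g = mg_uri)))
  }
  rdf_canonical(do.call(rdf_bind, rows))
}

#' Attach metadata to named graphs
#'
#' Stores the record in its own metadata named graph, clearly separated from
#' the descriptive content it is about.
#'
#' @inheritParams store_add_description
#' @param record a [metadata_record()]; all targets must exist in the store.
#' @return The minted metadata-graph URI.
#' @export
attach_metadata <- function(store, record) {
  for (tg in record$target_graphs) {
    if (is.null(store$graphs[[tg]])) {
      stop_phenokg("phenokg_reference_error",
                   sprintf("metadata target graph <%s> is not in the store", tg))
    }
  }
  store$meta_counter <- store$meta_counter + 1L
  mg <- paste0(store$namespace, "meta/", sprintf("%03d", store$meta_counter))
  store$meta_graphs[[mg]] <- metadata_quads(store, mg, record)
  record$graph_uri <- mg
  store$metadata[[length(store$metadata) + 1L]] <- record
  mg
}

metadata_for_graph <- function(store, graph_uri) {
  Filter(function(r) graph_uri %in% r$target_graphs, store$metadata)
}

# --- nanopublications -------------------------------------------------------

#' Export a named graph as a nanopublication
#'
#' Bundles the descriptive graph (assertion), provenance derived from its
#' metadata records, and publication info into the conventional four-graph
#' layout linked by a head graph. Requires at least one metadata record
#' targeting the graph: a nanopublication without provenance is not
#' publishable.
#'
#' @inheritParams store_add_description
#' @param graph_uri URI of a descriptive named graph in the store.
#' @param exported_by agent recorded in the publication-info graph.
#' @param export_date ISO-8601 date recorded in the publication-info graph.
#' @return A `phenokg_nanopub` with `head`, `assertion`, `provenance`,
#'   `pubinfo` quad tables.
#' @export
export_nanopublication <- function(store, graph_uri, exported_by = "phenokg",
                                   export_date = format(Sys.Date())) {
  g <- store$graphs[[graph_uri]]
  if (is.null(g)) stop_lookup(graph_uri)
  records <- metadata_for_graph(store, graph_uri)
  if (length(records) == 0) {
    stop_phenokg("phenokg_precondition_error",
                 sprintf("graph <%s> has no metadata; nanopublications require provenance",
                         graph_uri))
  }
  reg <- store$registry
  ex <- function(local) paste0(reg$prefix_map[["EX"]], local)
  np <- paste0(graph_uri, "/np")
  head_uri <- paste0(np, "#head")
  prov_uri <- paste0(np, "#provenance")
  pub_uri <- paste0(np, "#pubinfo")

  head <- rdf_bind(
    rdf_statements(np, RDF_TYPE_URI, ex("Nanopublication"), g = head_uri),
    rdf_statements(np, ex("hasAssertion"), graph_uri, g = head_uri),
    rdf_statements(np, ex("hasProvenance"), prov_uri, g = head_uri),
    rdf_statements(np, ex("hasPublicationInfo"), pub_uri, g = head_uri))
  prov <- do.call(rdf_bind, lapply(records, function(r) {
    q <- store$meta_graphs[[r$graph_uri]]
    q$g <- prov_uri
    q
  }))
  pubinfo <- rdf_bind(
    rdf_statements(np, ex("agent"), exported_by, o_kind = "string", g = pub_uri),
    rdf_statements(np, ex("date"), export_date, o_kind = "string", g = pub_uri))

  structure(list(uri = np, head = rdf_canonical(head), assertion = g$quads,
                 provenance = rdf_canonical(prov), pubinfo = rdf_canonical(pubinfo),
                 prefix_map = reg$prefix_map),
            class = "phenokg_nanopub")
}

#' Quads of a nanopublication
#' @param np a `phenokg_nanopub`.
#' @export
nanopub_quads <- function(np) {
  rdf_canonical(rdf_bind(np$head, np$assertion, np$provenance, np$pubinfo))
}

#' Serialize a nanopublication as TriG
#' @inheritParams nanopub_quads
#' @param file optional output path.
#' @export
nanopub_to_trig <- function(np, file = NULL) {
  write_trig(nanopub_quads(np), np$prefix_map, file = file)
}

# --- revisions --------------------------------------------------------------

#' Replace a descriptive named graph, keeping history
#'
#' The replacement (fresh URI, same category) becomes the active graph; the
#' superseded graph stays in the store's history with a supersedes link
#' recorded, in RDF, inside the change's metadata graph. Revising an
#' already-superseded graph is a staleness error.
#'
#' @inheritParams store_add_description
#' @param graph_uri URI of the active graph being corrected.
#' @param replacement a [named_graph()] with a URI not yet in the store and
#'   the same category as the graph it replaces.
#' @param record a [metadata_record()] documenting the change (targets are
#'   overridden to the replacement graph).
#' @return A `phenokg_change` record (superseded, replacement, metadata
#'   graph URI).
#' @export
revise_graph <- function(store, graph_uri, replacement, record) {
  old <- store$graphs[[graph_uri]]
  if (is.null(old)) stop_lookup(graph_uri)
  if (!isTRUE(store$active[[graph_uri]])) {
    stop_phenokg("phenokg_staleness_error",
                 sprintf("graph <%s> is already superseded", graph_uri))
  }
  if (!inherits(replacement, "phenokg_named_graph") ||
      !is.null(store$graphs[[replacement$uri]])) {
    stop_phenokg("phenokg_domain_error",
                 "replacement must be a fresh named graph not yet in the store")
  }
  if (!identical(replacement$category, old$category)) {
    stop_phenokg("phenokg_domain_error",
                 sprintf("replacement category %s does not match %s",
                         replacement$category, old$category))
  }
  store$graphs[[replacement$uri]] <- replacement
  store$active[[graph_uri]] <- FALSE
  store$active[[replacement$uri]] <- TRUE
  for (d in names(store$descriptions)) {
    if (graph_uri %in% store$descriptions[[d]]) {
      store$descriptions[[d]] <- c(store$descriptions[[d]], replacement$uri)
    }
  }
  record$target_graphs <- replacement$uri
  mg <- attach_metadata(store, record)
  link <- rdf_statements(replacement$uri, term_uri(store$registry, P_SUPERSEDES),
                         graph_uri, g = mg)
  store$meta_graphs[[mg]] <- rdf_canonical(rdf_bind(store$meta_graphs[[mg]], link))
  change <- structure(list(superseded = graph_uri, replacement = replacement$uri,
                           metadata_graph = mg, record = record),
                      class = "phenokg_change")
  store$revisions[[length(store$revisions) + 1L]] <- change
  change
}

#' Supersedes chain for a graph, newest first
#' @inheritParams store_add_description
#' @param graph_uri URI of the newest graph in the chain.
#' @export
revision_chain <- function(store, graph_uri) {
  chain <- graph_uri
  repeat {
    prev <- Filter(function(ch) ch$replacement == chain[length(chain)], store$revisions)
    if (length(prev) == 0) break
    chain <- c(chain, prev[[1]]$superseded)
  }
  chain
}

#' All quads of a store
#'
#' Descriptive named graphs (active and superseded) plus metadata graphs,
#' with one default-graph category-instantiation triple per named graph.
#'
#' @inheritParams store_add_description
#' @export
store_quads <- function(store) {
  reg <- store$registry
  cat_triples <- do.call(rdf_bind, c(list(rdf_empty()), lapply(store$graphs, function(g) {
    rdf_statements(g$uri, RDF_TYPE_URI, term_uri(reg, g$category))
  })))
  rdf_canonical(rdf_bind(
    do.call(rdf_bind, c(list(rdf_empty()), lapply(store$graphs, `[[`, "quads"))),
    do.call(rdf_bind, c(list(rdf_empty()), unname(store$meta_graphs))),
    cat_triples))
}

# --- persistence ------------------------------------------------------------

#' Save / load a store
#'
#' A store persists as a directory: `registry.ttl`, `graphs.trig` (all quads)
#' and `manifest.json` (description membership, graph categories and subject
#' parts, active flags, metadata records, revision chains).
#'
#' @inheritParams store_add_description
#' @param dir directory path.
#' @export
store_save <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  registry_to_turtle(store$registry, file.path(dir, "registry.ttl"))
  write_trig(store_quads(store), store$registry$prefix_map,
             file.path(dir, "graphs.trig"))
  manifest <- list(
    namespace = store$namespace,
    meta_counter = store$meta_counter,
    descriptions = store$descriptions,
    graphs = lapply(unname(store$graphs), function(g) {
      list(uri = g$uri, category = g$category, subject_part = g$subject_part)
    }),
    active = as.list(store$active),
    metadata = lapply(store$metadata, function(r) {
      list(graph_uri = r$graph_uri, target_graphs = as.list(r$target_graphs),
           agent = r$agent, date = r$date, source = r$source,
           instrument = r$instrument, free_fields = r$free_fields)
    }),
    revisions = lapply(store$revisions, function(ch) {
      list(superseded = ch$superseded, replacement = ch$replacement,
           metadata_graph = ch$metadata_graph)
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(dir)
}

#' @rdname store_save
#' @export
store_load <- function(dir) {
  registry <- registry_from_turtle(file.path(dir, "registry.ttl"))
  quads <- read_trig(file.path(dir, "graphs.trig"))
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = FALSE)
  st <- store_create(registry, namespace = manifest$namespace)
  st$meta_counter <- as.integer(manifest$meta_counter)
  meta_uris <- vapply(manifest$metadata, function(r) r$graph_uri, character(1))
  for (gm in manifest$graphs) {
    q <- quads[!is.na(quads$g) & quads$g == gm$uri, , drop = FALSE]
    st$graphs[[gm$uri]] <- named_graph(gm$uri, gm$category, gm$subject_part, q)
  }
  for (mg in meta_uris) {
    st$meta_graphs[[mg]] <- rdf_canonical(
      quads[!is.na(quads$g) & quads$g == mg, , drop = FALSE])
  }
  st$descriptions <- lapply(manifest$descriptions, function(x) {
    unlist(x, use.names = FALSE)
  })
  st$active <- vapply(manifest$active, isTRUE, logical(1))
  st$metadata <- lapply(manifest$metadata, function(r) {
    rec <- metadata_record(unlist(r$target_graphs, use.names = FALSE), r$agent,
                           r$date, r$source, r$instrument,
                           r$free_fields %||% list())
    rec$graph_uri <- r$graph_uri
    rec
  })
  st$revisions <- lapply(manifest$revisions, function(ch) {
    structure(list(superseded = ch$superseded, replacement = ch$replacement,
                   metadata_graph = ch$metadata_graph, record = NULL),
              class = "phenokg_change")
  })
  st
}

#' @export
print.phenokg_store <- function(x, ...) {
  cat(sprintf("<phenokg_store> %d descriptions, %d named graphs (%d active), %d metadata records, %d revisions\n",
              length(x$descriptions), length(x$graphs), sum(x$active),
              length(x$metadata), length(x$revisions)))
  invisible(x)
}
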