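# Deterministic synthetic-description generator. Targets structural
# coverage (partonomy depth/branching, qualities, measurements), not
# biological realism: every other module is testable without external data.

#' Generator parameters
#'
#' Defaults describe a small insect-like specimen: a partonomy up to three
#' levels deep with up to two parts per node, roughly one node in three
#' bearing a quality and one in three a measurement, weights of 1-100 mg and
#' lengths of 0.5-20 mm rounded to one decimal (the precision measurements
#' are printed at throughout).
#'
#' @param seed integer seed; draws use R's Mersenne-Twister stream.
#' @param max_depth maximum partonomy depth below the root (>= 0).
#' @param branching maximum child count per node (>= 0).
#' @param p_quality,p_measurement per-node Bernoulli probabilities in `[0, 1]`.
#' @param class_pool anatomical classes parts are drawn from.
#' @param quality_pool quality classes (each must map to a perceptual
#'   category through its quality family).
#' @param measurement_kinds list of `list(kind, unit, range, category)`.
#' @export
generator_params <- function(seed = 1L, max_depth = 3L, branching = 2L,
                             p_quality = 0.3, p_measurement = 0.3,
                             class_pool = c("UBERON:6000004", "UBERON:0000972",
                                            "EX:abdomen", "EX:ocellus", "EX:mandible",
                                            "EX:scape", "EX:pedicel", "MA:0000261"),
                             quality_pool = c("PATO:0002254", "PATO:0000322",
                                              "EX:yellow", "EX:darkBrown"),
                             measurement_kinds = list(
                               list(kind = "EX:liveWeight", unit = "EX:milligram",
                                    range = c(1, 100), category = CAT_WEIGHT),
                               list(kind = "EX:lengthQuality", unit = "EX:millimetre",
                                    range = c(0.5, 20), category = CAT_LENGTH))) {
  if (max_depth < 0 || branching < 0) {
    stop_phenokg("phenokg_domain_error", "max_depth and branching must be >= 0")
  }
  if (p_quality < 0 || p_quality > 1 || p_measurement < 0 || p_measurement > 1) {
    stop_phenokg("phenokg_domain_error", "probabilities must lie in [0, 1]")
  }
  if (p_quality > 0 && length(quality_pool) == 0) {
    stop_phenokg("phenokg_domain_error", "quality_pool empty with p_quality > 0")
  }
  if (p_measurement > 0 && length(measurement_kinds) == 0) {
    stop_phenokg("phenokg_domain_error", "measurement_kinds empty with p_measurement > 0")
  }
  if (branching > 0 && length(class_pool) == 0) {
    stop_phenokg("phenokg_domain_error", "class_pool empty with branching > 0")
  }
  structure(list(seed = as.integer(seed), max_depth = as.integer(max_depth),
                 branching = as.integer(branching), p_quality = p_quality,
                 p_measurement = p_measurement, class_pool = class_pool,
                 quality_pool = quality_pool, measurement_kinds = measurement_kinds),
            class = "phenokg_generator_params")
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  force(code)
}

#' Generate a random phenotype description
#'
#' Fully deterministic in the seed: the partonomy is grown breadth-first
#' with per-node child counts drawn uniformly on `0:branching`, part classes
#' drawn from the class pool, and qualities/measurements attached by
#' Bernoulli draws. The minting policy reuses the generator seed, so two
#' runs with the same parameters serialize byte-identically.
#'
#' @param params a [generator_params()].
#' @param registry a `phenokg_registry`.
#' @return A `phenokg_description` rooted at a multicellular organism.
#' @export
generate_pkg <- function(params, registry) {
  if (!inherits(params, "phenokg_generator_params")) {
    stop_phenokg("phenokg_domain_error", "params must come from generator_params()")
  }
  with_preserved_rng({
    set.seed(params$seed)
    pkg <- create_description(registry, "EX:multicellularOrganism",
                              sprintf("synthetic specimen %d", params$seed),
                              minting_policy(seed = params$seed))
    decorate <- function(uri) {
      if (stats::runif(1) < params$p_quality) {
        q <- params$quality_pool[[sample.int(length(params$quality_pool), 1)]]
        add_quality(pkg, uri, q, quality_category(registry, q))
      }
      if (stats::runif(1) < params$p_measurement) {
        mk <- params$measurement_kinds[[sample.int(length(params$measurement_kinds), 1)]]
        val <- round(stats::runif(1, mk$range[1], mk$range[2]), 1)
        add_measurement(pkg, uri, mk$kind, val, mk$unit, mk$category)
      }
    }
    decorate(pkg$odu_uri)
    frontier <- list(list(uri = pkg$odu_uri, depth = 0L))
    while (length(frontier) > 0) {
      node <- frontier[[1]]
      frontier <- frontier[-1]
      if (node$depth >= params$max_depth || params$branching == 0) next
      n_children <- sample.int(params$branching + 1L, 1) - 1L
      for (k in seq_len(n_children)) {
        cls <- params$class_pool[[sample.int(length(params$class_pool), 1)]]
        child <- add_part(pkg, node$uri, cls)
        decorate(child)
        frontier[[length(frontier) + 1L]] <- list(uri = child, depth = node$depth + 1L)
      }
    }
    pkg
  })
}
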