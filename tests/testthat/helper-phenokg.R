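# Shared fixtures and independent oracles. Oracles deliberately re-derive
# expected values through a different code path than the implementation they
# check.

the_registry <- build_fixture_registry()

# breadth-first closure oracle over explicit parent edges (child -> parents)
bfs_closure_oracle <- function(parents_of, curie) {
  children_of <- list()
  for (child in names(parents_of)) {
    for (p in parents_of[[child]]) children_of[[p]] <- c(children_of[[p]], child)
  }
  seen <- character(0)
  queue <- curie
  while (length(queue) > 0) {
    x <- queue[[1]]
    queue <- queue[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    queue <- c(queue, children_of[[x]])
  }
  sort(seen, method = "radix")
}

# random canonical class expression (registry terms only)
rand_expr <- function(depth = 4L,
                      classes = c("UBERON:6000004", "UBERON:0000972", "EX:ocellus",
                                  "EX:abdomen", "MA:0000261", "EX:mandible"),
                      qualities = c("PATO:0002254", "PATO:0000322", "EX:yellow"),
                      p_not = 0.1) {
  if (depth <= 0 || stats::runif(1) < 0.35) {
    return(ce_atomic(sample(classes, 1)))
  }
  r <- stats::runif(1)
  if (r < p_not) return(ce_not(rand_expr(depth - 1L, classes, qualities, p_not)))
  if (r < 0.35) {
    n <- sample(2:3, 1)
    return(ce_and(lapply(seq_len(n), function(i) {
      rand_expr(depth - 1L, classes, qualities, p_not)
    })))
  }
  if (r < 0.5) {
    return(ce_some("EX:bearerOf", ce_atomic(sample(qualities, 1))))
  }
  prop <- sample(c("EX:hasPart", "EX:hasComponent"), 1)
  filler <- if (stats::runif(1) < 0.5) {
    ce_atomic(sample(classes, 1))
  } else {
    ce_and(list(ce_atomic(sample(classes, 1)),
                rand_expr(depth - 1L, classes, qualities, p_not)))
  }
  if (stats::runif(1) < 0.4) {
    ce_exactly(prop, sample(0:3, 1), filler)
  } else {
    ce_some(prop, filler)
  }
}

# independent AST interpreter: expected minted-instance count per class
# (1 per expandable `some`, n per `exactly`, recursing fillers per witness)
expected_mint_counts <- function(expr, registry) {
  counts <- new.env(parent = emptyenv())
  bump <- function(cls, k) {
    assign(cls, (if (exists(cls, counts)) get(cls, counts) else 0L) + k, counts)
  }
  head_and_rest <- function(f) {
    if (f$node_kind == "atomic") return(list(head = f$term, rest = list()))
    if (f$node_kind == "and") {
      at <- which(vapply(f$operands, `[[`, character(1), "node_kind") == "atomic")
      if (length(at) > 0) {
        return(list(head = f$operands[[at[1]]]$term, rest = f$operands[-at[1]]))
      }
    }
    list(head = NULL, rest = NULL)
  }
  q_ok <- function(cls) {
    anc <- phenokg:::superclass_closure(registry, cls)
    any(c("PATO:0000020", "EX:shapeQuality", "EX:weightQuality",
          "EX:lengthQuality", "EX:volumeQuality") %in% anc)
  }
  visit <- function(e, mult) {
    if (e$node_kind == "atomic" || e$node_kind == "not") return(invisible(NULL))
    if (e$node_kind == "and") {
      for (op in e$operands) visit(op, mult)
      return(invisible(NULL))
    }
    hr <- head_and_rest(e$filler)
    if (e$property %in% c("EX:hasPart", "EX:hasComponent")) {
      if (is.null(hr$head)) return(invisible(NULL))
      k <- if (e$node_kind == "some") 1L else e$n
      if (mult * k > 0) {
        bump(hr$head, mult * k)
        for (r in hr$rest) visit(r, mult * k)
      }
    } else if (e$property == "EX:bearerOf" && e$node_kind == "some") {
      if (is.null(hr$head) || !q_ok(hr$head)) return(invisible(NULL))
      bump(hr$head, mult)
      for (r in hr$rest) visit(r, mult)
    }
    invisible(NULL)
  }
  visit(expr, 1L)
  if (length(ls(counts)) == 0) return(list())
  out <- mget(ls(counts), envir = counts)
  out[order(names(out), method = "radix")]
}

# minting class (first asserted class) of every non-root instance
minted_counts <- function(expansion) {
  insts <- expansion$pkg$instances
  insts[[expansion$pkg$odu_uri]] <- NULL
  if (length(insts) == 0) return(list())
  tab <- table(vapply(insts, function(i) i$classes[[1]], character(1)))
  out <- as.list(as.integer(tab))
  names(out) <- names(tab)
  out[order(names(out), method = "radix")]
}

# structural signature of a description, invariant under URI renaming
pkg_signature <- function(pkg, uri = pkg$odu_uri) {
  inst <- pkg$instances[[uri]]
  kids <- character(0)
  quals <- character(0)
  for (a in pkg$assertions) {
    if (a$kind == "parthood" && a$subject == uri) {
      kids <- c(kids, pkg_signature(pkg, a$object))
    }
    if (a$kind == "quality" && a$subject == uri) {
      quals <- c(quals, a$object_class)
    }
  }
  cls <- sort(Filter(function(x) !startsWith(x, "PHENO:"), inst$classes),
              method = "radix")
  paste0("{", paste(cls, collapse = ","),
         "|q:", paste(sort(quals, method = "radix"), collapse = ","),
         "|c:", paste(sort(kids, method = "radix"), collapse = ";"), "}")
}

count_has_part_some_nodes <- function(e) {
  n <- if (e$node_kind == "some" && e$property == "EX:hasPart") 1L else 0L
  n + switch(e$node_kind,
             atomic = 0L,
             and = sum(vapply(e$operands, count_has_part_some_nodes, integer(1))),
             not = count_has_part_some_nodes(e$operand),
             some = count_has_part_some_nodes(e$filler),
             exactly = count_has_part_some_nodes(e$filler))
}

random_eq <- function() {
  entity <- sample(c("MA:0000261", "UBERON:0000972", "EX:abdomen", "EX:ocellus"), 1)
  shape <- sample(1:4, 1)
  switch(shape,
         eq_statement(entity),
         eq_statement(entity, quality = sample(c("PATO:0000322", "PATO:0002254"), 1)),
         eq_statement(entity, quality = "EX:lengthQuality",
                      related_entity = "MA:0000261"),
         eq_statement(entity, quality = if (stats::runif(1) < 0.5) "PATO:0000322",
                      count = sample(0:4, 1)))
}
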