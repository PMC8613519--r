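# phenokg

Phenotype descriptions — "this specimen's head is flattened, carries two
antennae, and weighs 84.3 mg" — are still mostly published as free text,
which makes them nearly unusable as data. **phenokg** implements the two
ways such descriptions are put into RDF semantic graphs, for morphologists,
taxonomists, and knowledge-engineering developers building phenotype data
pipelines:

* the **instance-based ABox form** (*phenotype knowledge graph*): every
  described part, quality, and measurement is an individual with its own
  URI, organized along a parthood backbone rooted at the described
  specimen (the operational descriptive unit, ODU);
* the **class-based TBox form** (*semantic phenotype*): the description is
  the axiom of a phenotype class, written in an OWL Manchester-syntax
  subset (`and`, `not`, `some`, `exactly n`) composed from Entity–Quality
  (EQ) statements — `E + Q`, `E(QRE)` with a related entity, `E(QC)` with
  a count.

Around the core representations the package provides:

* **bidirectional conversion** — `expand_to_abox()` skolemizes a class
  expression into minted witness instances (one per `some`, *n* per
  `exactly n`, with absence and exact-count constructs preserved as
  DL-compliant hybrid class assertions so they survive the open-world
  assumption); `rollup_to_tbox()` reconstructs the class expression, with
  a closed-world mode under which `expand(rollup(pkg))` reproduces the
  graph up to URI renaming;
* **named-graph fragmentation** — one named graph per descriptive
  statement (quads), recomposable by union, filtered through data views,
  annotated with statement-level metadata, exported as four-graph
  nanopublications, and revised with walkable supersedes history;
* **validation and querying** — well-formedness reports, a shape-template
  content standard (YAML catalog, SHACL export), detection of the two
  non-DL constructs (*has not part any*, *towards class*), and
  entailment-free criteria queries (parts, parthood pairs, unit-checked
  measurement thresholds, taxon);
* a **fixture vocabulary** standing in for UBERON/PATO/MA/MP, a
  **deterministic synthetic-description generator**, and a thin CLI
  (`inst/exec/phenokg`).

All RDF I/O (Turtle, TriG, N-Quads) is deterministic: equal graphs
serialize to equal bytes.

## Worked example

Build the organism description (a multicellular organism possessing an
insect head that possesses an antenna, bearing a flattened shape and a
measured live weight of 84.3 mg), fragment it into named graphs with its
metadata, and apply the weight data view:

```r
library(phenokg)
reg <- build_fixture_registry()
st  <- build_worked_examples(reg)
st
#> <phenokg_store> 5 descriptions, 17 named graphs (17 active), 3 metadata records, 0 revisions

v <- apply_view(st, st$examples$organism, data_view("weights", "EX:catWeight"))
cat(write_turtle(v, reg$prefix_map))
#> ...
#> <http://example.org/phenokg/data/d12/i0001> EX:bearerOf <http://example.org/phenokg/data/d12/i0005> .
#> <http://example.org/phenokg/data/d12/i0005> EX:hasUnit EX:milligram .
#> <http://example.org/phenokg/data/d12/i0005> EX:hasValue "84.3"^^xsd:decimal .
#> <http://example.org/phenokg/data/d12/i0005> rdf:type EX:liveWeight .
```

The view returns exactly the weight named graph: the organism instance
(`...i0001`) bears a measurement individual (`...i0005`) typed as a live
weight, with the decimal value 84.3 and the milligram unit — every node a
URI, no blanks.

Expanding the class axiom of the flattened two-antenna head phenotype
mints the matching instance graph:

```r
res <- expand_to_abox(parse_manchester(head_axiom_manchester(), reg),
                      reg, "UBERON:6000004")
res
#> <phenokg_expansion> 4 instances, 1 hybrid assertions, 0 residue entries
serialize_manchester(res$hybrid[[1]]$expr, reg)
#> [1] "has part exactly 2 antenna"
```

Four instances — the head, its flattened quality, two antennae — plus a
hybrid exact-count class assertion that records "exactly two" in
DL-compliant form (a bare ABox graph with two antenna parts could never
rule out a third).

Querying follows the repository scenario "descriptions with a weight larger
than 10 mg":

```r
crit <- query_criteria(measurements = list(
  list(kind = "EX:weightQuality", comparator = ">", value = 10, unit = "EX:milligram")))
run_query(st, crit)
#> [1] "http://example.org/phenokg/data/d12"
```

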