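---
title: "Representing phenotype descriptions as instance-based and class-based semantic graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing phenotype descriptions as instance-based and class-based semantic graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenokg)
```

## The two representations

An empirical phenotype description — "this specimen's head is flattened and
carries two antennae; its live weight is 84.3 mg" — can be put into a
semantic graph in two structurally different ways.

In the **class-based (TBox) form**, usually called a *semantic phenotype*,
the description lives inside the axiom of a phenotype class, and the
described specimen merely instantiates that class. The axiom is written as
an OWL class expression, conventionally composed from **Entity–Quality (EQ)
statements**: a bearer entity from an anatomy ontology (UBERON, MA) paired
with a quality from PATO, following fixed composition schemes. The printed
form of such axioms is Manchester syntax:

```{r}
reg <- build_fixture_registry()
head_axiom_manchester()
```

In the **instance-based (ABox) form**, a *phenotype knowledge graph*, every
described part, quality, and measurement is an individual with its own URI.
Parts hang off the described individual (the *operational descriptive unit*,
ODU) through parthood assertions, forming a partonomy backbone; qualities
and measurements attach to their bearers. Nothing is anonymous, so every
statement can be referenced, fragmented, annotated, corrected, and queried
without entailment reasoning.

```{r}
organism <- build_organism_example(reg)
partonomy_tree(organism)$children[[1]]$class   # the head under the organism
```

The package implements both forms, the conversion between them, and the
infrastructure the instance-based form enables: named-graph fragmentation,
data views, statement-level metadata, nanopublication export, revision
tracking, shape validation, and criteria queries.

## The fixture vocabulary

No ontology is downloaded. `build_fixture_registry()` mints the handful of
UBERON/PATO/MA/MP terms the worked examples cite (`UBERON:0000972` antenna,
`PATO:0002254` flattened, `MA:0000261` eye, ...) with their published
labels, and adds, in an `EX:` namespace, everything those ontologies are not
consulted for here: the object properties (*has part*, *bearer of*, *has
component*, *inheres in*, *increased in magnitude relative to*), the unit
terms milligram and millimetre, additional anatomy for the parser fixtures,
and the perceptual-category terms. Two properties — *has not part any* and
*towards class* — are deliberately **not** OWL-expressible and carry a
non-DL marker; they exist so that the ABox-only absence and exact-count
variants can be built and flagged.

Perceptual categories are ontology terms (`term_kind = "category"`), not a
hard-coded enumeration: one per observational question (weight, length,
volume, position, color, shape, function, development) plus the structural
parthood and instantiation categories. Weight, length, and volume sit under
a shared *measurement* parent so that closure-expanded data views can select
"all measurements". Users can extend the catalog by adding terms.

The property IRIs are minted rather than taken from BFO/RO: the source
material never fixes which variant is meant, so the registry documents its
own choice and keeps it swappable (the registry round-trips through Turtle,
and every module resolves CURIEs only through it).

## The Manchester subset and its canonical form

The parser covers exactly the constructs the EQ composition schemes
produce: atomic class labels (multi-word, matched longest-first,
case-sensitive, keywords win), `and`, `not`, `some`, `exactly n`, and
parentheses. `min`, `max`, `only`, `value`, and `or` are rejected with an
explicit syntax error rather than silently misparsed.

Expressions are **canonical by construction**: nested intersections are
flattened and operands ordered by a registry-free structural key. That makes
round-tripping exact in both directions (`parse(serialize(e))` is
`identical()` to `e`) and gives identical patterns identical serializations,
which in turn gives hybrid phenotype classes deterministic URIs (a string
hash of the canonical serialization). The cost is that operand order in the
input is not preserved; intersection is commutative, so no meaning is lost.

The EQ layer supports the plain `E + Q` scheme, the quality-free degenerate
case, related entities (`E(QRE)`, with the relating property a parameter
defaulting to *increased in magnitude relative to*), and counts (`E(QC)`,
compiled onto a `has component exactly C E` cardinality — the only printed
count construct). The EAV **attribute is not compiled into the expression**:
the inverse mapping works without a registry and could not decide which
conjunct of `Q and A` is the value and which the attribute, whereas with
hierarchically organized quality terms the attribute is simply the
quality's parent (red implies color) — `eq_attribute()` recovers it. Nested
EQ statements (composite characters) are not rolled into a single
`phenokg_eq`; deeper structure stays in class-expression form.

## Building and fragmenting descriptions

`create_description()` mints the ODU; `add_part()`, `add_quality()`, and
`add_measurement()` grow the graph. URI minting is deterministic from
(namespace, seed, insertion counter) by default — reproducible tests need
stable URIs, and nothing in the modeled domain constrains minting — with a
random scheme available. Parthood edges are only ever created toward a
freshly minted instance, so the partonomy is a tree by construction: one
parent per part, no cycles. Shared parts (a DAG partonomy) are a documented
extension point, deliberately rejected in this version.

`fragment_description()` produces **one named graph per descriptive
assertion** — the smallest semantically meaningful unit of empirical
information: one parthood link, one borne quality, one measurement — plus a
single instantiation graph for the ODU's own type and label statements. A
minted instance's type/label triples travel in the graph of the assertion
that minted it, keeping each named graph self-describing; that placement is
also exactly the exception set of the strict-partition property (descriptive
graphs are pairwise quad-disjoint). The category-instantiation triple of
each named graph is emitted into the TriG default graph at export time, not
into the graph itself — otherwise the union of the fragments would not
equal the description's triple set, and that identity
(`union(fragment(pkg)) == pkg_triples(pkg)`) is the design's anchor
property, tested on 100 generated descriptions.

Data views select graphs by category, optionally expanded through the
subclass closure; monotonicity in the category set is property-tested.
Metadata records live in their own named graphs (one record may target
several descriptive graphs), nanopublications follow the conventional
four-graph head/assertion/provenance/pubinfo layout (the source material
cites nanopublications without fixing a structure), and micro-publication
content — natural-language fragments, media links — rides in the reserved
free-field keys `text` and `media`. Revisions replace a graph with a
fresh-URI successor of the same category, keep the superseded graph in
history behind a supersedes link recorded in RDF, and leave the description
URI stable (trackability is the requirement; nothing demands a new
description identity per correction).

## Conversion and the open-world constructs

`expand_to_abox()` reads a class expression as a recipe for a minimal
witness model. `some` mints **exactly one** witness (skolemized existential
instantiation — the minimal-model reading; cardinalities are what `exactly`
is for). `exactly n` mints n witnesses *and* asserts a hybrid phenotype
class on the bearer so the count survives the open-world assumption; `not`
mints nothing and becomes a hybrid absence class. Quality restrictions
inside an `exactly` filler are expanded once per witness — each witness
gets its own quality instance. Everything else (relational qualities
through *increased in magnitude relative to*, fillers with no named class)
goes to the residue with a reason; expansion is total and never raises, and
a node-accounting check verifies that minted structure, hybrid entries, and
residue jointly cover every AST node.

`rollup_to_tbox()` inverts this. Under the open-world flag it emits one
existential restriction per distinct child subtree — identical siblings
collapse, which is precisely the representational loss the instance-based
form exists to avoid. Under `closed_world = TRUE` it groups sibling parts
by canonical rolled subtree and emits one `exactly(has part, n, subtree)`
per group (n = 1 included). Emitting an existential per child *plus* a
per-class cardinality was considered and rejected: expansion would then
mint 2n witnesses and the round trip (`expand(rollup(pkg))` isomorphic to
`pkg` up to URI renaming, property-tested on 100 measurement-free
descriptions) would fail. Measurements are never rolled up — compiling
numeric magnitudes into class axioms needs one phenotype class per value
combination, the class-based form's documented failure mode — they are
returned on a skip list instead.

`build_absence()` and `build_exact_count()` expose the two modeling
variants side by side: the ABox-only encodings (via *has not part any* /
*towards class*) are single quad-able statements but flagged
`dl_compliant = FALSE`; the hybrid encodings assert a minted phenotype
class (complement / qualified-cardinality definition, skolemized restriction
nodes, no blank nodes) and are flagged compliant. `dl_compliance()`
re-derives the same verdict from the emitted statements, and the agreement
of the two routes is tested. `has component exactly 0 C` is noted as
absence-in-intent; no logical equivalence is asserted, because the package
does no reasoning.

Comparative statements ("increased length of abdomen") convert to bounded
direct statements only when the reference magnitude is supplied
(`increased` → exclusive lower bound, `decreased` → exclusive upper);
without it, `comparative_to_direct()` raises
`phenokg_unresolvable_comparative` — the magnitude genuinely cannot be
recovered from the comparative statement alone.

## Validation and querying

`check_wellformed()` reports (never throws): missing class assertions,
blank or relative URIs, multi-parent or cyclic parthood, unitless
measurements as errors; unlabeled anatomical-entity instances as warnings.
`check_shape()` implements the content standard: a catalog of shape
templates — data, loadable from YAML, exportable to SHACL for
interoperability — one per named-graph category, checked role by role
(parthood: whole/part; qualitative: bearer/quality; measurements:
bearer/kind/value/unit with a decimal value and a unit-domain filler).

`run_query()` is plain pattern matching over the active named graphs — no
entailment, matching the representational argument that instance graphs
should be queryable without it. Criteria compose conjunctively
(monotone-decreasing, property-tested): part classes (with or without
subclass closure), direct parthood pairs, unit-checked measurement
comparisons, and a taxon class matched as an assertion on the ODU. There is
**no unit conversion**: a 10 mg threshold never matches a measurement in
grams or millimetres. Silent conversion without a unit ontology risks wrong
matches; the mismatch is loud by design. Superseded graphs are excluded — a
corrected value replaces the erroneous one in every view and query.

## The synthetic generator and what passing tests show

`generate_pkg()` grows a partonomy breadth-first (child counts uniform on
`0:branching`, classes from a pool) and attaches qualities and measurements
by Bernoulli draws, using R's Mersenne–Twister stream under an explicit
seed; the caller's RNG state is preserved. Defaults — depth ≤ 3, branching
≤ 2, attachment probabilities 0.3, weights 1–100 mg and lengths 0.5–20 mm
rounded to one decimal — describe a small insect-like specimen at the
precision the worked examples print. The generator targets structural
coverage: every partonomy shape, category mix, and measurement pattern the
store and validators must handle. It does not emulate real anatomical
ontology breadth (eight part classes, not eight thousand), inter-specimen
correlation, or annotation noise, so green property suites certify the
algebra of the representations — fragmentation identities, round trips,
monotonicity — not robustness to messy real-world annotation practice.

Problem sizes in the shipped suites: 100 cases per property (50 for the
expansion round trip in the acceptance script), partonomies of up to ~15
nodes; the whole suite runs in well under a minute on one CPU.

## Numerical and formatting choices

RDF statements live in plain data frames; serialization is one statement
per line with canonical, locale-independent (radix) ordering, so equal
statement sets produce byte-equal files — determinism contracts are tested
as string identity, not graph isomorphism. The bundled Turtle/TriG parser
covers the subset the writers emit (plus `;`/`,` continuations and `a`);
an external RDF library is used in one test as an independent oracle that
the exported TriG is standard-conformant. Decimal literals keep the lexical
form they were written with (`84.3`, one decimal), avoiding float-printing
drift.

## Known limitations

No reasoning or entailment-regime querying (explicitly a non-goal); no
unit conversion; partonomies are trees, not DAGs; EQ statements are one
level deep; the Manchester subset excludes `min`/`max`/`only`/`value`/`or`
and datatype restrictions; nanopublications are not cryptographically
hashed or signed; the store is single-writer and in-memory with
directory persistence, not a SPARQL endpoint. Similarity measurement and
alignment between descriptions is out of scope.
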