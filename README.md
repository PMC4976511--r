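# elrepo — an OWL-EL ontology repository with saturation-based reasoning

Biomedical ontologies (anatomy, phenotypes, diseases, processes) carry
description-logic semantics: a class may be entailed to be a subclass of
another through definitions, conjunctions and existential restrictions,
with no direct edge between them. Answering such queries over many
ontologies at interactive speed is infeasible with full OWL 2 DL
reasoning, but becomes polynomial when reasoning is restricted to the
OWL 2 EL profile (conjunction and existential restriction only), ignoring
everything outside that fragment.

`elrepo` implements that architecture end to end, for ontology engineers
and tool builders who want reproducible EL reasoning without a server
stack:

* **I/O** — OWL 2 Functional-Style Syntax reader/writer; constructs
  outside the fragment are preserved as flagged `Unsupported` axioms, and
  only token-level malformation is a parse error.
* **Reasoner** — normalization into the EL normal forms
  (A ⊑ B, A₁ ⊓ A₂ ⊑ B, A ⊑ ∃r.B, ∃r.A ⊑ B, role hierarchies and chains of
  length ≤ 2), then a worklist saturation computing the least fixpoint of
  the EL completion rules; taxonomy with equivalence groups, transitive
  reduction, unsatisfiable classes and a consistency flag.
* **Query engine** — Manchester-syntax queries (`A`, `A and B`,
  `R some A`, `A and R some B`, nested, quoted labels, `<IRI>` fallback)
  resolved through `rdfs:label`s, answered in subclass / superclass /
  equivalent modes by inserting a fresh query class into the cached
  saturation and rolling it back afterwards; per-query engine-side timing.
* **Repository** — multi-ontology store with load-outcome accounting
  (non-parseable / inconsistent / no-labels / used), aggregate statistics,
  query-all.
* **Benchmark** — seeded generation of 300 fresh expressions per template
  (1200 per ontology), three-way mode partition, a bounded-concurrency
  executor at 1/100/1000 queries in flight, and Pearson correlations of
  query time with ontology size and with load.
* **Enrichment** — materializes inferred subsumptions (transitive
  reduction by default, full closure optionally) and removes non-EL
  axioms, producing an ontology that answers the same EL queries from told
  axioms.
* **Verification** — a separately coded brute-force oracle, hand-closed
  fixtures, and a seeded synthetic-ontology generator.

## Worked example

A mitral valve is told to be a valve and part of some heart — but never
told to be a heart valve, which is *defined* as exactly that conjunction:

```r
library(elrepo)
O <- Ontology(list(
  declaration("objectProperty", "http://ex.org/partOf"),
  annotationAssertion("http://ex.org/partOf",
    "http://www.w3.org/2000/01/rdf-schema#label", "part of"),
  annotationAssertion("http://ex.org/Valve",
    "http://www.w3.org/2000/01/rdf-schema#label", "valve"),
  annotationAssertion("http://ex.org/Heart",
    "http://www.w3.org/2000/01/rdf-schema#label", "heart"),
  equivalentClasses(
    ceNamed("http://ex.org/HeartValve"),
    ceAnd(ceNamed("http://ex.org/Valve"),
          ceSome("http://ex.org/partOf", ceNamed("http://ex.org/Heart")))),
  subClassOf(ceNamed("http://ex.org/MitralValve"), ceNamed("http://ex.org/Valve")),
  subClassOf(ceNamed("http://ex.org/MitralValve"),
             ceSome("http://ex.org/partOf", ceNamed("http://ex.org/Heart")))))
ro <- reasonedOntology(O)
answerQuery(ro, "valve and 'part of' some heart", "subclasses")
#> QueryResult [subclasses] ((<http://ex.org/partOf> some <http://ex.org/Heart>) and <http://ex.org/Valve>)
#>   1 answers in 2.00 ms
#>   - <http://ex.org/MitralValve>
classify(ro)
#> Taxonomy: 4 equivalence groups, 2 direct edges, 0 unsatisfiable, consistent
answerQuery(ro, "valve and 'part of' some heart", "equivalents")$answers
#> [1] "http://ex.org/HeartValve"
```

The subclass answer is the derived fact; the defined class itself comes
back in the equivalents mode, and the two strict modes never repeat it.

A command-line front end with `synth`, `filter`, `classify`, `stats`,
`query`, `query-all`, `benchmark` and `enrich` subcommands is installed at
`system.file("exec", "elrepo", package = "elrepo")`.

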