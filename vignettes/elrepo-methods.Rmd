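---
title: "Saturation-based reasoning over an OWL-EL ontology repository"
author: "elrepo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation-based reasoning over an OWL-EL ontology repository}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elrepo)
```

## The problem

Biomedical terminologies — anatomy, phenotype, disease and process
ontologies — are published as OWL documents whose description-logic
semantics licenses inferences beyond the told axioms: a class can be
subsumed by another through chains of definitions, conjunctions and
existential restrictions without any direct edge between them. Serving
those inferences interactively over many ontologies at once is hard with
full OWL 2 DL reasoning, whose worst case is intractable. The pragmatic
compromise adopted by large ontology repositories, and implemented here, is
to restrict reasoning to the OWL 2 EL profile — conjunction and existential
restriction only, no negation, disjunction or universal quantification —
where classification is polynomial, and to simply ignore axioms and queries
outside that fragment.

`elrepo` is a self-contained implementation of that architecture: a
functional-syntax reader/writer, an EL filter, a completion-rule
(saturation) classifier, a Manchester-syntax query engine resolving classes
and properties by their `rdfs:label`s, a multi-ontology store with
load-outcome accounting, a randomized query benchmark, and an
inferred-axiom materialization step that rewrites an ontology so the same
queries can be answered from told axioms alone.

## The calculus

Classification works on four normal forms over named classes ($A$, $B$,
$C$; $\top$ allowed on left sides, $\bot$ on right sides) and roles $r$,
$s$:

$$A \sqsubseteq B \quad\quad A_1 \sqcap A_2 \sqsubseteq B \quad\quad
A \sqsubseteq \exists r.B \quad\quad \exists r.A \sqsubseteq B$$

plus role axioms $r \sqsubseteq s$ and chains $r_1 \circ r_2 \sqsubseteq
s$. `normalizeOntology()` rewrites arbitrary EL axioms into these shapes by
introducing fresh names in the reserved namespace `urn:normform:N`:
equivalences expand into mutual inclusions, disjointness pairs into
inclusions of $\bot$, and each complex subexpression receives one fresh
name (identical subexpressions share it; each definitional direction is
emitted at most once). The result is a conservative extension: no
subsumption between original names is gained or lost, which the test suite
checks against an independent oracle.

`saturate()` then computes the least fixpoint of the standard EL completion
rules (told subsumption, conjunction, existential introduction and
propagation, bottom propagation, role hierarchy, role chain) with a
worklist over subsumer sets $S(\cdot)$ and role-successor relations
$R(\cdot)$, both indexed for constant-time rule dispatch. Termination is
guaranteed because both structures are bounded by the squared signature.
An ontology is inconsistent iff $\bot \in S(\top)$; a class $A$ is
unsatisfiable iff $\bot \in S(A)$. `classify()` projects fresh names out,
groups mutually subsuming classes, and reduces the remaining order to its
transitive reduction (ties in group representatives broken
lexicographically by IRI).

### Queries and incremental insertion

A query expression $C$ is answered by inserting a fresh class $Q \equiv C$
into the *live* saturation, extending the fixpoint incrementally, reading
off

* subclasses: named $A$ with $A \sqsubseteq C$ entailed and $C
  \sqsubseteq A$ not entailed,
* superclasses: symmetrically,
* equivalents: mutual subsumption,

and rolling the insertion back from a journal of every mutation, so
repeated queries always see the identical cached saturation. Unsatisfiable
named classes do appear among subclass answers (they are genuinely
subsumed by every expression); the query's own equivalence class is
excluded from the two strict modes so the three modes partition the related
classes. Reported `executionTimeMs` covers evaluation only — parsing is
excluded, matching a service-side notion of query time that ignores
transport.

### The independent oracle

`bruteForceOracle()` is a separately coded, deliberately naive decision
procedure: it takes the subexpression closure of the *un-normalized*
axioms, represents candidate subsumption as one dense logical matrix (plus
one successor matrix per role), and re-applies structural rules until
nothing changes. It shares no code with the worklist engine and is
quadratic-to-quartic everywhere, which is exactly why it is trusted: the
acceptance suite requires exact agreement with `classify()` on 1,000
seeded random ontologies (up to 15 classes, 3 roles), and the fixture set
in `builtinFixtures()` was additionally closed by hand.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `nPerType` | `generateRandomQueries` | 300 | queries per template; 1200 per ontology in total, matching the benchmark protocol |
| `parallelismLevels` | `runBenchmark` | 1, 100, 1000 | maximum queries in flight per batch |
| `maxClasses`, `maxRoles` | `bruteForceOracle` | 20, 4 | size guard for the naive oracle |
| `labelFraction` | `generateOntology` | 1.0 | fraction of classes given an `rdfs:label` |
| `nonELFraction` | `generateOntology` | 0.0 | non-EL placeholder axioms as a fraction of the EL class axioms |
| `fullClosure` | `enrichOntology` | `FALSE` | materialize all entailed pairs instead of the transitive reduction |

Label matching is case-insensitive with whitespace collapsed; an
exact-case match wins before a label is declared ambiguous, and ambiguity
is an error rather than a silent union — silent unions would make
benchmark results irreproducible.

## The benchmark and its concurrency model

The protocol draws four template families over an ontology's labeled
signature — `A`, `A and B`, `R some A`, `A and R some B` — 300 of each,
all pairwise distinct by canonical form so that a cache of previously
answered expressions can never satisfy a query. Each template's 300
expressions are shuffled and split into three 100-expression subsets
assigned to superclass, equivalent and subclass queries.

R is single-threaded in process, so "k queries in parallel" is implemented
as a bounded-concurrency batch executor: at most k queries are dispatched
per batch, and each record carries two times — `executionTimeMs`, the
engine-side evaluation of that query alone, and `responseTimeMs`, measured
from batch dispatch to that query's completion, which includes queue wait
and is the analogue of a server response time without network latency.
Correlation of query time with ontology size uses execution time;
correlation with the parallelism level uses response time. The engine
itself is evaluated strictly sequentially and queries are rolled back in
between, so answer sets are identical at every level — an invariant the
acceptance suite asserts rather than assumes. Timing magnitudes are
machine-dependent and are therefore never asserted in tests; only
directions (non-decreasing in load, positively correlated with axiom
count) are checked, with a small jitter allowance between levels whose
batches coincide.

The correlation study runs on synthetic ontologies of roughly $10^2$ to
$10^4$ logical axioms (four sizes). That upper bound is a deliberate
choice: it keeps a full repository build plus a 3,600-execution protocol
in the low minutes on one core while spanning two orders of magnitude,
which is ample for a direction-only claim.

## What the synthetic generator emulates — and what it does not

`generateOntology()` emulates the axiom mix of biomedical terminologies: a
SubClassOf-dominated acyclic hierarchy (every told edge points from a
higher to a lower index, so told cycles are impossible and equivalence
classes are controlled solely by the explicit definitional equivalences),
conjunction axioms, existential restrictions, a small role hierarchy, and
unique human-ish two-word labels with occasional capitalization to
exercise quoting and case normalization in the Manchester parser. Defaults
(400 classes, 5 roles, ~660 logical axioms) give a medium ontology large
enough to support the full 1200-query protocol. `nonELFraction` injects
well-formed universal-restriction/union placeholders to exercise the EL
filter, and `injectInconsistency` adds a $\top \sqsubseteq X$, $X
\sqsubseteq A \sqcap B$, $A$-disjoint-$B$ pattern entailing $\top
\sqsubseteq \bot$.

It does **not** emulate scale-free degree distributions, deep existential
nesting, annotation richness, or the idiosyncrasies of specific public
terminologies; passing tests on generated data therefore demonstrate
correctness of the machinery, not performance characteristics of any
particular real ontology.

## Numerical and design choices

* **Set semantics everywhere.** Axioms are deduplicated by a canonical
  key; conjunctions are flattened n-ary sets with sorted operands, so
  structural equality is order-insensitive and `A and B` equals
  `B and A`.
* **Serialization is deterministic** (kind order, then lexicographic
  rendering): equal ontologies produce byte-identical documents, and the
  source document's prefix declarations are retained so echoed unsupported
  axioms keep resolving on a round trip.
* **Unknown constructs are preserved, not rejected.** A well-bracketed
  axiom outside the fragment becomes an `Unsupported` axiom carrying its
  construct name and raw text; only token-level malformation is a parse
  error. This keeps load-report accounting faithful while mirroring the
  ignore-non-EL posture.
* **Enrichment materializes the transitive reduction** plus one
  `EquivalentClasses` axiom per group and an explicit bottom edge per
  unsatisfiable class. The reduction is answer-preserving because the
  reasoner recovers transitivity, and it keeps the added-axiom count
  near-minimal; `fullClosure = TRUE` emits every entailed pair instead.
  Because classification here is the package's own EL saturation,
  EL-expressible consequences of removed non-EL axioms are not derived; an
  externally computed classification can be supplied as told pairs via
  `inferredFrom` to reproduce the stronger preprocessing variant.
* **Role chains are limited to length 2** (longer chains raise a
  normalization error) and reflexivity, range restrictions and other EL⁺⁺
  extensions are out of fragment.
* **Inconsistency is TBox-only** ($\bot \in S(\top)$); there are no
  individuals in the model.

## Worked example

```{r example}
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
answerQuery(ro, "valve and 'part of' some heart", "subclasses")$answers
classify(ro)
```

The mitral valve is never told to be a heart valve; it satisfies the
definition and the saturation derives it.

## Known limitations

* Pure-R saturation handles $10^4$ logical axioms in tens of seconds;
  ontologies at the scale of the largest public terminologies ($10^5$ or more
  axioms) classify, but not interactively.
* The concurrency model measures queueing under a sequential engine; it
  cannot expose race conditions of a truly multi-threaded reasoner.
* RDF/XML and other serializations are not read; the functional-style
  syntax is the single supported dialect, and Manchester syntax is
  supported for queries only.
* ABox content (individuals), data properties and datatypes are outside
  the model.
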