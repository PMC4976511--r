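# Label resolution, Manchester parsing, query execution.

rdfsLabel <- "http://www.w3.org/2000/01/rdf-schema#label"

labeledOntology <- function() {
  Ontology(list(
    declaration("class", ex("Apoptosis")),
    declaration("class", ex("Mitosis")),
    declaration("class", ex("Membrane")),
    declaration("objectProperty", ex("partOf")),
    declaration("objectProperty", ex("regulates")),
    annotationAssertion(ex("Apoptosis"), rdfsLabel, "apoptosis"),
    annotationAssertion(ex("Mitosis"), rdfsLabel, "mitosis"),
    annotationAssertion(ex("Membrane"), rdfsLabel, "membrane"),
    annotationAssertion(ex("partOf"), rdfsLabel, "part of"),
    annotationAssertion(ex("regulates"), rdfsLabel, "regulates")))
}

test_that("label index construction and normalization", {
  O <- Ontology(list(declaration("class", ex("A")),
                     annotationAssertion(ex("A"), rdfsLabel, "heart")))
  idx <- buildLabelIndex(O)
  expect_identical(idx@byLabel[["heart"]], ex("A"))
  expect_identical(resolveLabel(idx, "  Heart "), ex("A"))
  # ambiguity preserved in the index, surfaced at resolution
  O2 <- Ontology(list(declaration("class", ex("A")),
                      declaration("class", ex("B")),
                      annotationAssertion(ex("A"), rdfsLabel, "cell"),
                      annotationAssertion(ex("B"), rdfsLabel, "cell")))
  idx2 <- buildLabelIndex(O2)
  expect_length(idx2@byLabel[["cell"]], 2L)
  expect_error(resolveLabel(idx2, "cell"), class = "elrepo_ambiguous_label")
  # exact-case match wins before ambiguity is declared
  O3 <- Ontology(list(declaration("class", ex("A")),
                      declaration("class", ex("B")),
                      annotationAssertion(ex("A"), rdfsLabel, "Golgi"),
                      annotationAssertion(ex("B"), rdfsLabel, "golgi")))
  expect_identical(resolveLabel(buildLabelIndex(O3), "Golgi"), ex("A"))
  # label on an undeclared/unused IRI is not indexed
  O4 <- Ontology(list(annotationAssertion(ex("ghost"), rdfsLabel, "ghost")))
  expect_length(buildLabelIndex(O4)@byLabel, 0L)
})

test_that("the four query templates parse to the expected expressions", {
  idx <- buildLabelIndex(labeledOntology())
  expect_identical(ceKey(parseQuery("apoptosis", idx)),
                   ceKey(ceNamed(ex("Apoptosis"))))
  expect_identical(ceKey(parseQuery("apoptosis and mitosis", idx)),
                   ceKey(ceAnd(ceNamed(ex("Apoptosis")), ceNamed(ex("Mitosis")))))
  expect_identical(ceKey(parseQuery("'part of' some membrane", idx)),
                   ceKey(ceSome(ex("partOf"), ceNamed(ex("Membrane")))))
  expect_identical(
    ceKey(parseQuery("apoptosis and 'regulates' some mitosis", idx)),
    ceKey(ceAnd(ceNamed(ex("Apoptosis")),
                ceSome(ex("regulates"), ceNamed(ex("Mitosis"))))))
  # parenthesized nesting and IRI fallback
  expect_identical(
    ceKey(parseQuery("(apoptosis and ('part of' some (membrane and mitosis)))", idx)),
    ceKey(ceAnd(ceNamed(ex("Apoptosis")),
                ceSome(ex("partOf"),
                       ceAnd(ceNamed(ex("Membrane")), ceNamed(ex("Mitosis")))))))
  expect_identical(ceKey(parseQuery("<http://other.org/X>", idx)),
                   ceKey(ceNamed("http://other.org/X")))
})

test_that("query parse errors carry their condition classes", {
  idx <- buildLabelIndex(labeledOntology())
  expect_error(parseQuery("nosuchlabel", idx), class = "elrepo_unknown_label")
  expect_error(parseQuery("apoptosis and", idx), class = "elrepo_query_syntax")
  expect_error(parseQuery("(apoptosis", idx), class = "elrepo_query_syntax")
  for (bad in c("apoptosis or mitosis", "not apoptosis",
                "'part of' only membrane", "'part of' min 2 membrane",
                "'part of' value membrane"))
    expect_error(parseQuery(bad, idx), class = "elrepo_out_of_fragment")
})

test_that("execute_query returns transitive answers with mode exclusions", {
  O <- Ontology(list(subClassOf(nm("A"), nm("B")), subClassOf(nm("C"), nm("B"))))
  r <- executeQuery(O, nm("B"), "subclasses")
  expect_identical(r$answers, sort(c(ex("A"), ex("C"))))
  expect_gte(r$executionTimeMs, 0)
  expect_true(r$satisfiableQuery)

  # definition ontology: equivalents are excluded from the strict modes
  O2 <- Ontology(list(
    declaration("objectProperty", ex("r")),
    equivalentClasses(nm("A"), ceAnd(nm("B"), ceSome(ex("r"), nm("C")))),
    subClassOf(nm("D"), nm("B")), subClassOf(nm("D"), ceSome(ex("r"), nm("C")))))
  q <- ceAnd(nm("B"), ceSome(ex("r"), nm("C")))
  expect_identical(executeQuery(O2, q, "equivalents")$answers, ex("A"))
  expect_identical(executeQuery(O2, q, "subclasses")$answers, ex("D"))
  expect_identical(executeQuery(O2, q, "superclasses")$answers, ex("B"))

  # equivalents of top in an empty ontology: no named classes at all
  expect_identical(executeQuery(Ontology(), ceTop(), "equivalents")$answers,
                   character(0))
})

test_that("unsatisfiable named classes appear among subclass answers", {
  O <- Ontology(list(subClassOf(nm("U"), nm("B")), subClassOf(nm("U"), nm("C")),
                     disjointClasses(nm("B"), nm("C")),
                     subClassOf(nm("A"), nm("B"))))
  r <- executeQuery(O, nm("B"), "subclasses")
  expect_true(ex("U") %in% r$answers)   # U <= bottom <= everything
  expect_true(ex("A") %in% r$answers)
  ru <- executeQuery(O, nm("U"), "superclasses")
  expect_false(ru$satisfiableQuery)
  expect_setequal(ru$answers, ex(c("A", "B", "C")))
})

test_that("querying an inconsistent ontology is refused", {
  O <- Ontology(list(subClassOf(ceTop(), ceBottom()),
                     declaration("class", ex("A"))))
  expect_error(executeQuery(O, nm("A"), "subclasses"),
               class = "elrepo_inconsistent_ontology")
})

test_that("answers cohere with entailment, exhaustively on fixtures", {
  for (f in builtinFixtures()) {
    if (!f$expectedConsistent) next
    ro <- reasonedOntology(f$ontology)
    cls <- signatureOf(f$ontology)$classIRIs
    rls <- signatureOf(f$ontology)$roleIRIs
    exprs <- c(lapply(cls, ceNamed),
               if (length(cls) >= 2)
                 list(ceAnd(ceNamed(cls[1]), ceNamed(cls[2]))),
               if (length(rls) >= 1)
                 list(ceSome(rls[1], ceNamed(cls[1]))))
    for (q in exprs) {
      subs <- executeQuery(ro, q, "subclasses")$answers
      sups <- executeQuery(ro, q, "superclasses")$answers
      eqs <- executeQuery(ro, q, "equivalents")$answers
      for (a in cls) {
        below <- entailsSubsumption(ro, ceNamed(a), q)
        above <- entailsSubsumption(ro, q, ceNamed(a))
        expect_identical(a %in% subs, below && !above)
        expect_identical(a %in% sups, above && !below)
        expect_identical(a %in% eqs, above && below)
      }
    }
  }
})

test_that("repeated identical queries return identical results", {
  O <- withr::with_seed(9, tinyRandomOntology(9))
  ro <- reasonedOntology(O)
  idx <- buildLabelIndex(O)
  lab <- paste0("'", names(idx@byLabel)[1L], "'")
  r1 <- answerQuery(ro, lab, "subclasses")
  for (k in 1:5)
    expect_identical(answerQuery(ro, lab, "subclasses")$answers, r1$answers)
})
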