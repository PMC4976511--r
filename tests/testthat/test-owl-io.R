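# Functional-syntax reader/writer.

test_that("a minimal document parses to the expected model", {
  p <- parseSnippet("SubClassOf(:A :B)")
  expect_identical(p$report$axiomsParsed, 1L)
  expect_length(p$report$unsupportedConstructs, 0L)
  ax <- axioms(p$ontology)[[1L]]
  expect_identical(ax$kind, "SubClassOf")
  expect_identical(ax$sub$iri, ex("A"))
  expect_identical(ontologyIRI(p$ontology), "http://ex.org/onto")
})

test_that("non-EL constructs are preserved as Unsupported with counts", {
  p <- parseSnippet(c("SubClassOf(:A ObjectAllValuesFrom(:r :B))",
                      "SubClassOf(:A :B)",
                      "EquivalentClasses(:C ObjectUnionOf(:A :B))"))
  expect_identical(p$report$axiomsParsed, 1L)
  expect_identical(p$report$unsupportedConstructs,
                   c(ObjectAllValuesFrom = 1L, ObjectUnionOf = 1L))
  kinds <- vapply(axioms(p$ontology), `[[`, character(1), "kind")
  expect_identical(sum(kinds == "Unsupported"), 2L)
  # raw text is preserved verbatim
  uns <- Filter(function(a) a$kind == "Unsupported", axioms(p$ontology))
  expect_identical(uns[[1L]]$rawText, "SubClassOf(:A ObjectAllValuesFrom(:r :B))")
  # nothing silently dropped: parsed + unsupported = top-level axiom forms
  expect_identical(p$report$axiomsParsed +
                     sum(p$report$unsupportedConstructs), 3L)
})

test_that("token-level malformation raises a parse error with a position", {
  expect_error(parseFunctional("Ontology(<http://x/o> SubClassOf(:A :B"),
               class = "elrepo_parse_error")
  err <- tryCatch(parseSnippet("SubClassOf(undeclared:A :B)"),
                  error = function(e) e)
  expect_s3_class(err, "elrepo_parse_error")
  expect_true(err$line >= 1L && err$col >= 1L)
  expect_error(parseFunctional("Ontology(<http://x/o>)extra"),
               class = "elrepo_parse_error")
})

test_that("annotation literals accept language tags and datatypes", {
  p <- parseSnippet(c(
    'AnnotationAssertion(rdfs:label :A "heart"@en)',
    'AnnotationAssertion(rdfs:label :B "lung"^^<http://www.w3.org/2001/XMLSchema#string>)',
    'AnnotationAssertion(rdfs:label :C "esca\\"ped")'))
  labs <- vapply(axioms(p$ontology), `[[`, character(1), "value")
  expect_setequal(labs, c("heart", "lung", "esca\"ped"))
})

test_that("serialization is deterministic and round-trips structurally", {
  for (seed in 1:15) {
    O <- withr::with_seed(seed, tinyRandomOntology(seed, nonEL = 0.15))
    doc <- serializeFunctional(O, echoUnsupported = TRUE)
    expect_identical(serializeFunctional(O, echoUnsupported = TRUE), doc)
    O2 <- parseFunctional(doc)$ontology
    expect_identical(sort(vapply(axioms(O2), axiomKey, character(1))),
                     sort(vapply(axioms(O), axiomKey, character(1))))
  }
  # empty ontology: just the wrapper
  doc0 <- serializeFunctional(Ontology(iri = "http://x/o"))
  expect_match(doc0, "Ontology\\(<http://x/o>\\n\\)")
  expect_length(axioms(parseFunctional(doc0)$ontology), 0L)
})

test_that("unsupported axioms are only serialized when echoing is requested", {
  O <- Ontology(list(unsupportedAxiom("ObjectUnionOf",
                                      "SubClassOf(<http://x/A> ObjectUnionOf(<http://x/B> <http://x/C>))")))
  expect_error(serializeFunctional(O), class = "elrepo_serialize_error")
  expect_silent(serializeFunctional(O, echoUnsupported = TRUE))
  expect_error(serializeFunctional(
    Ontology(list(unsupportedAxiom("X", NA_character_))),
    echoUnsupported = TRUE), class = "elrepo_serialize_error")
})

test_that("file round trip via readOntology/writeOntology", {
  O <- withr::with_seed(1, tinyRandomOntology(1))
  path <- withr::local_tempfile(fileext = ".ofn")
  writeOntology(O, path)
  p <- readOntology(path)
  expect_identical(sort(vapply(axioms(p$ontology), axiomKey, character(1))),
                   sort(vapply(axioms(O), axiomKey, character(1))))
  expect_identical(sourceName(p$ontology), basename(path))
})

test_that("imports and role chains are read faithfully", {
  p <- parseSnippet(c("Import(<http://ex.org/other>)",
                      "SubObjectPropertyOf(ObjectPropertyChain(:r :s) :t)",
                      "SubObjectPropertyOf(:r :t)",
                      "EquivalentObjectProperties(:r :s)"))
  expect_identical(p$ontology@imports, "http://ex.org/other")
  ax <- axioms(p$ontology)
  chains <- Filter(function(a) a$kind == "SubObjectPropertyOf", ax)
  expect_identical(chains[[1L]]$subChain, c(ex("r"), ex("s")))
  expect_identical(chains[[2L]]$subChain, ex("r"))
})
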