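# Random query generation, mode partitioning, the bounded-concurrency
# executor, and the correlation analysis.

benchOntology <- function(seed = 11)
  generateOntology(nClasses = 40, nRoles = 3, nSubClassAxioms = 35,
                   nConjunctionAxioms = 5, nExistentialAxioms = 10,
                   nEquivalenceAxioms = 2, seed = seed)

test_that("generation is seeded, template-balanced and duplicate-free", {
  O <- benchOntology()
  qs <- generateRandomQueries(O, nPerType = 12, seed = 5)
  expect_length(qs, 48L)
  tmpl <- vapply(qs, `[[`, character(1), "template")
  expect_identical(as.integer(table(tmpl)), rep(12L, 4L))
  keys <- vapply(qs, function(q) ceKey(q$expression), character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(
    vapply(generateRandomQueries(O, nPerType = 12, seed = 5),
           function(q) ceKey(q$expression), character(1)), keys)
  qs2 <- generateRandomQueries(O, nPerType = 12, seed = 6)
  expect_false(identical(vapply(qs2, function(q) ceKey(q$expression),
                                character(1)), keys))
  # conjunctive operands are distinct after canonicalization
  conj <- Filter(function(q) q$template == "conjunctive", qs)
  expect_true(all(vapply(conj, function(q) length(q$expression$ops) == 2L,
                         logical(1))))
})

test_that("insufficient signatures are rejected, exhaustion is detected", {
  twoClasses <- Ontology(list(
    declaration("class", ex("A")), declaration("class", ex("B")),
    declaration("objectProperty", ex("r")),
    annotationAssertion(ex("A"), "http://www.w3.org/2000/01/rdf-schema#label", "a"),
    annotationAssertion(ex("B"), "http://www.w3.org/2000/01/rdf-schema#label", "b"),
    annotationAssertion(ex("r"), "http://www.w3.org/2000/01/rdf-schema#label", "r")))
  # conjunctive template has C(2,2) = 1 distinct unordered pair: exhaustion
  expect_error(generateRandomQueries(twoClasses, nPerType = 5, seed = 1),
               class = "elrepo_insufficient_signature")
  oneClass <- Ontology(list(
    declaration("class", ex("A")),
    annotationAssertion(ex("A"), "http://www.w3.org/2000/01/rdf-schema#label", "a")))
  expect_error(generateRandomQueries(oneClass, nPerType = 1, seed = 1),
               class = "elrepo_insufficient_signature")
  noProps <- Ontology(list(
    declaration("class", ex("A")), declaration("class", ex("B")),
    declaration("class", ex("C")), declaration("class", ex("D")),
    annotationAssertion(ex("A"), "http://www.w3.org/2000/01/rdf-schema#label", "a"),
    annotationAssertion(ex("B"), "http://www.w3.org/2000/01/rdf-schema#label", "b"),
    annotationAssertion(ex("C"), "http://www.w3.org/2000/01/rdf-schema#label", "c"),
    annotationAssertion(ex("D"), "http://www.w3.org/2000/01/rdf-schema#label", "d")))
  expect_error(generateRandomQueries(noProps, nPerType = 2, seed = 1),
               class = "elrepo_insufficient_signature")
  expect_warning(qs <- generateRandomQueries(noProps, nPerType = 2, seed = 1,
                                             lenient = TRUE))
  expect_setequal(unique(vapply(qs, `[[`, character(1), "template")),
                  c("primitive", "conjunctive"))
})

test_that("partitioning is an equal seeded three-way split per template", {
  O <- benchOntology()
  qs <- generateRandomQueries(O, nPerType = 9, seed = 2)
  plan <- partitionQuerySet(qs, seed = 3)
  expect_identical(names(plan), c("superclasses", "equivalents", "subclasses"))
  expect_identical(lengths(plan), c(superclasses = 12L, equivalents = 12L,
                                    subclasses = 12L))
  for (mode in names(plan)) {
    tmpl <- vapply(plan[[mode]], `[[`, character(1), "template")
    expect_identical(as.integer(table(tmpl)), rep(3L, 4L))
  }
  # union = input, disjoint
  keyOf <- function(qset) sort(vapply(qset, function(q) ceKey(q$expression),
                                      character(1)))
  expect_identical(keyOf(c(plan[[1]], plan[[2]], plan[[3]])), keyOf(qs))
  # minimal divisible case and the non-divisible error
  plan1 <- partitionQuerySet(generateRandomQueries(O, nPerType = 3, seed = 1),
                             seed = 1)
  expect_identical(lengths(plan1),
                   c(superclasses = 4L, equivalents = 4L, subclasses = 4L))
  expect_error(partitionQuerySet(generateRandomQueries(O, nPerType = 4, seed = 1),
                                 seed = 1),
               class = "elrepo_partition_error")
})

test_that("the executor records every query at every level, k=1 sequentially", {
  dir <- withr::local_tempdir()
  writeOntology(benchOntology(), file.path(dir, "bench.ofn"))
  repo <- loadOntologies(file.path(dir, "bench.ofn"))
  qs <- generateRandomQueries(repoOntology(repo, "bench.ofn")@ontology,
                              nPerType = 3, seed = 4)
  plan <- partitionQuerySet(qs, seed = 4)
  expect_identical(formals(runBenchmark)$parallelismLevels,
                   quote(c(1L, 100L, 1000L)))
  rec <- runBenchmark(repo, list(bench.ofn = plan),
                      parallelismLevels = c(1L, 4L), keepAnswers = TRUE)
  expect_identical(nrow(rec), 24L)  # 12 queries x 2 levels
  expect_false(any(rec$failed))
  expect_true(all(rec$executionTimeMs >= 0))
  expect_true(all(rec$responseTimeMs + 1e-9 >= rec$executionTimeMs))
  # answers identical across parallelism levels
  k1 <- rec[rec$parallelism == 1L, ]
  k4 <- rec[rec$parallelism == 4L, ]
  expect_identical(k1$answerKey, k4$answerKey)
  expect_identical(k1$answerCount, k4$answerCount)
})

test_that("analysis computes strata and product-moment correlations", {
  # perfectly linear synthetic records: r = 1
  rec <- data.frame(
    ontologyName = rep(c("a", "b"), each = 4),
    template = "primitive", mode = "subclasses",
    parallelism = rep(c(1L, 1L, 2L, 2L), 2),
    executionTimeMs = rep(c(2, 6), each = 4),  # 2 * axioms
    responseTimeMs = rep(c(1, 2, 3, 4), 2),
    answerCount = 1L, failed = FALSE)
  statsPer <- list(a = list(logicalAxiomCount = 1), b = list(logicalAxiomCount = 3))
  s <- analyzeBenchmark(rec, statsPer)
  expect_equal(s$pearsonTimeVsAxioms, 1.0)
  expect_length(s$undefinedCorrelations, 0L)
  expect_true(all(c("meanMs", "sdMs") %in% names(s$perStratum)))
  # constant axis: flagged undefined
  rec2 <- rec; rec2$executionTimeMs <- 5
  s2 <- analyzeBenchmark(rec2, statsPer)
  expect_true(is.na(s2$pearsonTimeVsAxioms))
  expect_true("timeVsAxioms" %in% s2$undefinedCorrelations)
  # hand-computed four-point product-moment: r = 3 / 5 = 0.6
  rec3 <- data.frame(
    ontologyName = "a", template = "primitive", mode = "subclasses",
    parallelism = c(1L, 2L, 3L, 4L),
    executionTimeMs = c(2, 1, 4, 3),
    responseTimeMs = c(2, 1, 4, 3),
    answerCount = 1L, failed = FALSE)
  s3 <- analyzeBenchmark(rec3, list(a = list(logicalAxiomCount = 1)))
  expect_equal(s3$pearsonTimeVsParallelism, 0.6)
})
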