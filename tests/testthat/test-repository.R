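# Multi-ontology store: load-outcome accounting, query-all, aggregation.

makeRepoDir <- function(dir) {
  clean <- lapply(1:3, function(s)
    generateOntology(nClasses = 10, nRoles = 2, nSubClassAxioms = 8,
                     nConjunctionAxioms = 2, nExistentialAxioms = 3,
                     nEquivalenceAxioms = 1, seed = s))
  for (i in seq_along(clean))
    writeOntology(clean[[i]], file.path(dir, sprintf("clean%d.ofn", i)))
  writeLines("Ontology(<http://bad> SubClassOf(:A", file.path(dir, "bad.ofn"))
  writeOntology(generateOntology(nClasses = 5, nRoles = 1,
                                 nSubClassAxioms = 3, nConjunctionAxioms = 0,
                                 nExistentialAxioms = 1, nEquivalenceAxioms = 0,
                                 injectInconsistency = TRUE, seed = 99),
                file.path(dir, "incons.ofn"))
  invisible(dir)
}

test_that("load statuses partition the inputs as defined", {
  dir <- withr::local_tempdir()
  makeRepoDir(dir)
  repo <- loadOntologies(list.files(dir, full.names = TRUE))
  r <- loadReport(repo)
  expect_identical(r$total, 5L)
  expect_identical(r$nonParseable, 1L)
  expect_identical(r$loadable, 4L)
  expect_identical(r$inconsistent, 1L)
  expect_identical(r$noLabels, 0L)
  expect_identical(r$used, 3L)
  expect_identical(r$used, r$loadable - r$inconsistent - r$noLabels)
  expect_setequal(names(r$perOntology), basename(list.files(dir)))
  expect_identical(sort(usedOntologies(repo)),
                   c("clean1.ofn", "clean2.ofn", "clean3.ofn"))
})

test_that("an empty path list yields an all-zero report", {
  r <- loadReport(loadOntologies(character(0)))
  expect_true(all(unlist(r[c("total", "loadable", "nonParseable",
                             "inconsistent", "noLabels", "used")]) == 0L))
})

test_that("a label-free but consistent ontology is set aside, not queryable", {
  dir <- withr::local_tempdir()
  writeOntology(generateOntology(nClasses = 5, nRoles = 1, labelFraction = 0,
                                 nSubClassAxioms = 3, nConjunctionAxioms = 0,
                                 nExistentialAxioms = 0, nEquivalenceAxioms = 0,
                                 seed = 7),
                file.path(dir, "nolab.ofn"))
  repo <- loadOntologies(list.files(dir, full.names = TRUE))
  r <- loadReport(repo)
  expect_identical(r$noLabels, 1L)
  expect_identical(r$used, 0L)
  expect_identical(r$perOntology$nolab.ofn$status, "no-labels")
  expect_error(repoOntology(repo, "nolab.ofn"), class = "elrepo_unknown_ontology")
  expect_error(queryAll(repo, "anything", "subclasses"),
               class = "elrepo_empty_repository")
})

test_that("the partition invariant holds for random corrupted mixes", {
  for (trial in 1:5) {
    dir <- withr::local_tempdir()
    n <- 0L
    withr::with_seed(trial, {
      for (i in 1:6) {
        n <- n + 1L
        kind <- sample(c("clean", "bad", "incons", "nolab"), 1)
        path <- file.path(dir, sprintf("f%d.ofn", i))
        if (kind == "bad") writeLines("Ontology(<u> Declaration(Class", path)
        else writeOntology(generateOntology(
          nClasses = 6, nRoles = 1, nSubClassAxioms = 4,
          nConjunctionAxioms = 1, nExistentialAxioms = 1,
          nEquivalenceAxioms = 0,
          labelFraction = if (kind == "nolab") 0 else 1,
          injectInconsistency = kind == "incons", seed = i * 100 + trial), path)
      }
    })
    r <- loadReport(loadOntologies(list.files(dir, full.names = TRUE)))
    expect_identical(r$total, n)
    expect_identical(r$loadable, r$total - r$nonParseable)
    expect_identical(r$used, r$loadable - r$inconsistent - r$noLabels)
    statuses <- vapply(r$perOntology, `[[`, character(1), "status")
    expect_identical(sum(statuses == "used"), r$used)
    expect_length(statuses, n)
  }
})

test_that("query_all answers per ontology and flags unresolvable labels", {
  dir <- withr::local_tempdir()
  makeRepoDir(dir)
  repo <- loadOntologies(list.files(dir, full.names = TRUE))
  # pick a label known to one used ontology
  ro1 <- repoOntology(repo, "clean1.ofn")
  idx1 <- buildLabelIndex(ro1@ontology)
  lab <- paste0("'", names(idx1@byLabel)[1L], "'")
  res <- queryAll(repo, lab, "subclasses")
  expect_setequal(names(res), usedOntologies(repo))
  # per-ontology result equals a direct executeQuery on that ontology
  direct <- answerQuery(ro1, lab, "subclasses")
  expect_identical(res$clean1.ofn$answers, direct$answers)
  flagged <- vapply(res, function(x) isTRUE(x$labelNotFound), logical(1))
  for (nmx in names(res)[flagged])
    expect_identical(res[[nmx]]$answers, character(0))
  # determinism
  res2 <- queryAll(repo, lab, "subclasses")
  expect_identical(lapply(res, `[[`, "answers"), lapply(res2, `[[`, "answers"))
})

test_that("aggregate statistics are element-wise sums over used ontologies", {
  dir <- withr::local_tempdir()
  makeRepoDir(dir)
  repo <- loadOntologies(list.files(dir, full.names = TRUE))
  agg <- aggregateStats(repo)
  per <- lapply(usedOntologies(repo), function(nmx)
    computeStats(repoOntology(repo, nmx)@ontology))
  for (f in c("classCount", "objectPropertyCount", "logicalAxiomCount",
              "rboxAxiomCount", "labeledClassCount"))
    expect_identical(agg[[f]], sum(vapply(per, `[[`, integer(1), f)))
  expect_identical(sum(agg$axiomTypeHistogram),
                   sum(vapply(per, function(s) sum(s$axiomTypeHistogram),
                              integer(1))))
  expect_true(all(unlist(aggregateStats(loadOntologies(character(0)))[
    c("classCount", "logicalAxiomCount")]) == 0L))
})
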