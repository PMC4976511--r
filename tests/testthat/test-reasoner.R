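# Saturation, classification, expression entailment, and the brute-force
# oracle they are checked against.

test_that("saturation derives the textbook inferences", {
  # transitivity through told subsumptions
  st <- saturate(normalizeOntology(Ontology(list(
    subClassOf(nm("A"), nm("B")), subClassOf(nm("B"), nm("C"))))))
  expect_true(ex("C") %in% subsumersOf(st, ex("A")))
  # no axioms: S(A) = {A, top}
  st0 <- saturate(normalizeOntology(Ontology(list(
    declaration("class", ex("A")), declaration("class", ex("B"))))))
  expect_identical(subsumersOf(st0, ex("A")), ex("A"))
  expect_identical(subsumersOf(st0, ex("A"), namedOnly = FALSE),
                   sort(c(ex("A"), "http://www.w3.org/2002/07/owl#Thing")))
  # existential propagation via NF3 + NF4
  st1 <- saturate(normalizeOntology(Ontology(list(
    subClassOf(nm("A"), ceSome(ex("r"), nm("B"))),
    subClassOf(ceSome(ex("r"), nm("B")), nm("C"))))))
  expect_true(ex("C") %in% subsumersOf(st1, ex("A")))
  # bottom through a disjointness
  st2 <- saturate(normalizeOntology(Ontology(list(
    subClassOf(nm("A"), nm("B")), subClassOf(nm("A"), nm("C")),
    subClassOf(ceAnd(nm("B"), nm("C")), ceBottom())))))
  expect_identical(subsumersOf(st2, ex("A")),
                   sort(c(ex("A"), ex("B"), ex("C"))))  # unsat: all named
  expect_true(isConsistent(st2))
})

test_that("role hierarchies and chains propagate successors", {
  # r <= s and Es.B <= C
  O <- Ontology(list(
    subClassOf(nm("A"), ceSome(ex("r"), nm("B"))),
    subObjectPropertyOf(ex("r"), ex("s")),
    subClassOf(ceSome(ex("s"), nm("B")), nm("C"))))
  expect_true(entailsSubsumption(O, nm("A"), nm("C")))
  # r o r <= t (transitivity-style chain)
  O2 <- Ontology(list(
    subClassOf(nm("A"), ceSome(ex("r"), nm("B"))),
    subClassOf(nm("B"), ceSome(ex("r"), nm("C"))),
    subObjectPropertyOf(c(ex("r"), ex("r")), ex("t")),
    subClassOf(ceSome(ex("t"), nm("C")), nm("D"))))
  expect_true(entailsSubsumption(O2, nm("A"), nm("D")))
  expect_false(entailsSubsumption(O2, nm("B"), nm("D")))
})

test_that("classify arranges groups, direct edges and consistency", {
  tax <- classify(Ontology(list(equivalentClasses(nm("A"), nm("B")))))
  expect_length(taxonomyGroups(tax), 1L)
  expect_identical(taxonomyGroups(tax)[[1L]], c(ex("A"), ex("B")))

  # direct edges are the transitive reduction: A -> B -> C, no A -> C
  tax2 <- classify(Ontology(list(
    subClassOf(nm("A"), nm("B")), subClassOf(nm("B"), nm("C")))))
  e <- taxonomyDirectEdges(tax2)
  expect_identical(strictKeys(e[, c("child", "parent"), drop = FALSE]),
                   c(paste(ex("A"), ex("B"), sep = ">"),
                     paste(ex("B"), ex("C"), sep = ">")))

  tax3 <- classify(Ontology(list(subClassOf(ceTop(), ceBottom()),
                                 declaration("class", ex("A")))))
  expect_false(taxonomyConsistent(tax3))
  expect_identical(taxonomyUnsatisfiable(tax3), ex("A"))
})

test_that("entailsSubsumption covers reflexivity, top and composed queries", {
  O <- Ontology(list(subClassOf(nm("D"), nm("B")),
                     subClassOf(nm("D"), ceSome(ex("r"), nm("C")))))
  C <- ceAnd(nm("B"), ceSome(ex("r"), nm("C")))
  expect_true(entailsSubsumption(O, C, C))
  expect_true(entailsSubsumption(O, C, ceTop()))
  expect_true(entailsSubsumption(O, nm("D"), C))
  expect_false(entailsSubsumption(O, nm("B"), C))
})

test_that("the oracle refuses oversized inputs and handles the empty case", {
  expect_identical(nrow(bruteForceOracle(Ontology(list(
    declaration("class", ex("A")))))), 1L)  # reflexive pair only
  big <- generateOntology(nClasses = 30, nRoles = 2, nSubClassAxioms = 10,
                          nConjunctionAxioms = 0, nExistentialAxioms = 0,
                          nEquivalenceAxioms = 0, seed = 1)
  expect_error(bruteForceOracle(big), class = "elrepo_oracle_too_large")
})

test_that("classification agrees with the oracle on random ontologies", {
  for (seed in 101:200) {
    O <- withr::with_seed(seed, tinyRandomOntology(seed))
    expect_identical(pairKeys(entailedSubsumptions(O)),
                     pairKeys(bruteForceOracle(O)),
                     label = sprintf("seed %d", seed))
  }
})

test_that("entailments are monotone under axiom addition", {
  for (seed in 1:15) {
    O <- withr::with_seed(seed, tinyRandomOntology(seed))
    base <- pairKeys(entailedSubsumptions(O))
    cls <- signatureOf(O)$classIRIs
    if (length(cls) < 2) next
    extra <- withr::with_seed(seed, subClassOf(ceNamed(sample(cls, 1)),
                                               ceNamed(sample(cls, 1))))
    O2 <- Ontology(c(axioms(O), list(extra)))
    expect_true(all(base %in% pairKeys(entailedSubsumptions(O2))))
  }
})

test_that("classification commutes with a bijective signature renaming", {
  renameCE <- function(ce, map) switch(ce$type,
    named = ceNamed(map[[ce$iri]]),
    top = ce, bottom = ce,
    and = ceAnd(lapply(ce$ops, renameCE, map = map)),
    some = ceSome(map[[ce$role]], renameCE(ce$filler, map)))
  for (seed in 1:8) {
    O <- withr::with_seed(seed, tinyRandomOntology(seed))
    sig <- signatureOf(O)
    all <- c(sig$classIRIs, sig$roleIRIs)
    map <- stats::setNames(paste0("http://renamed.org/", seq_along(all)), all)
    newAx <- lapply(axioms(O), function(ax) switch(ax$kind,
      SubClassOf = subClassOf(renameCE(ax$sub, map), renameCE(ax$sup, map)),
      EquivalentClasses = equivalentClasses(lapply(ax$members, renameCE, map = map)),
      DisjointClasses = disjointClasses(lapply(ax$members, renameCE, map = map)),
      SubObjectPropertyOf = subObjectPropertyOf(unname(map[ax$subChain]),
                                                unname(map[ax$sup])),
      EquivalentObjectProperties = equivalentObjectProperties(unname(map[ax$members])),
      Declaration = declaration(ax$declKind, unname(map[[ax$iri]])),
      NULL))
    O2 <- Ontology(Filter(Negate(is.null), newAx))
    got <- entailedSubsumptions(O2)
    want <- entailedSubsumptions(O)
    want <- matrix(unname(map[want]), ncol = 2L)
    expect_identical(pairKeys(got), pairKeys(want))
  }
})

test_that("incremental query insertion matches fresh classification and rolls back", {
  for (seed in 1:10) {
    O <- withr::with_seed(seed, tinyRandomOntology(seed))
    ro <- reasonedOntology(O)
    closure <- pairKeys(entailedSubsumptions(ro))
    cls <- signatureOf(O)$classIRIs
    before <- sum(lengths(elrepo:::.roEnsureState(ro)@env$S))
    pairs <- withr::with_seed(seed, cbind(sample(cls, 12, replace = TRUE),
                                          sample(cls, 12, replace = TRUE)))
    for (i in seq_len(nrow(pairs))) {
      got <- entailsSubsumption(ro, ceNamed(pairs[i, 1]), ceNamed(pairs[i, 2]))
      expect_identical(got, paste(pairs[i, 1], pairs[i, 2], sep = ">") %in% closure)
    }
    after <- sum(lengths(elrepo:::.roEnsureState(ro)@env$S))
    expect_identical(before, after)  # rollback leaves no residue
  }
})
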