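# Synthetic labeled EL ontologies: a seeded generator emulating the axiom
# mix of biomedical terminologies (a SubClassOf-dominated acyclic hierarchy
# with conjunction and existential axioms, a few equivalence definitions, a
# small role hierarchy, rdfs:labels), plus deliberately non-EL and
# inconsistent variants, and a set of tiny hand-closed fixtures.

.SYNTH_NS <- "http://example.org/synth#"

.SYNTH_NOUNS <- c("cell", "tissue", "membrane", "nucleus", "organ", "vessel",
                  "neuron", "receptor", "enzyme", "ligand", "kinase", "channel",
                  "fibroblast", "epithelium", "cortex", "ganglion", "plasma",
                  "lesion", "tumor", "antigen", "antibody", "cytokine",
                  "hormone", "synapse", "axon", "dendrite", "organelle",
                  "ribosome", "vesicle", "mitochondrion")
.SYNTH_ADJS <- c("cardiac", "hepatic", "renal", "neural", "epithelial",
                 "basal", "apical", "cortical", "vascular", "lymphoid",
                 "smooth", "striated", "embryonic", "mature", "primary",
                 "secondary", "activated", "resting", "malignant", "benign",
                 "proximal", "distal", "anterior", "posterior", "medial",
                 "lateral", "superior", "inferior", "dorsal", "ventral")
.SYNTH_VERBS <- c("part of", "regulates", "develops from", "adjacent to",
                  "located in", "has part", "participates in", "produces")

#' Generate a random labeled EL ontology
#'
#' Classes form an acyclic told hierarchy: a SubClassOf axiom always points
#' from a higher-indexed class to a lower-indexed one, so equivalence
#' classes are controlled by the explicit equivalence axioms alone.
#' Conjunction axioms are \code{Ci <= Ca n Cb}, existential axioms
#' \code{Ci <= Er.Cj}, and equivalence axioms \code{Ci == Ca n Er.Cb}
#' (definitional style). Labels are human-ish word pairs over a fixed
#' vocabulary, with occasional capitalization, to exercise quoting and case
#' normalization in the query parser; every class label is unique.
#' \code{nonELFraction} of the class axioms are emitted as additional
#' non-EL placeholder axioms (universal restrictions / unions, carried as
#' \code{Unsupported}); \code{injectInconsistency} adds a pattern entailing
#' \code{owl:Thing <= owl:Nothing}. Output is deterministic per seed.
#'
#' @param nClasses,nRoles signature sizes.
#' @param nSubClassAxioms,nConjunctionAxioms,nExistentialAxioms,nEquivalenceAxioms
#'   axiom counts per type (dropped to the feasible maximum for tiny
#'   signatures).
#' @param labelFraction fraction of classes carrying an \code{rdfs:label}.
#' @param nonELFraction fraction (of the EL class axioms) of non-EL
#'   placeholder axioms to add.
#' @param injectInconsistency add an inconsistency pattern.
#' @param seed integer seed.
#' @return an \code{Ontology}.
#' @export
generateOntology <- function(nClasses = 400L, nRoles = 5L,
                             nSubClassAxioms = 500L,
                             nConjunctionAxioms = 40L,
                             nExistentialAxioms = 100L,
                             nEquivalenceAxioms = 20L,
                             labelFraction = 1.0, nonELFraction = 0.0,
                             injectInconsistency = FALSE, seed = 1L) {
  stopifnot(nClasses >= 0L, nRoles >= 0L, labelFraction >= 0, labelFraction <= 1,
            nonELFraction >= 0, nonELFraction <= 1)
  cIRI <- sprintf("%sC%04d", .SYNTH_NS, seq_len(nClasses))
  rIRI <- sprintf("%sR%02d", .SYNTH_NS, seq_len(nRoles))
  axs <- list()
  add <- function(ax) axs[[length(axs) + 1L]] <<- ax

  .withSeed(seed, {
    for (iri in cIRI) add(declaration("class", iri))
    for (iri in rIRI) add(declaration("objectProperty", iri))

    # unique two-word labels; occasional capitalization
    if (nClasses > 0L && labelFraction > 0) {
      grid <- expand.grid(a = .SYNTH_ADJS, n = .SYNTH_NOUNS,
                          stringsAsFactors = FALSE)
      labs <- paste(grid$a, grid$n)
      labs <- sample(labs, nClasses, replace = nClasses > length(labs))
      if (anyDuplicated(labs))
        labs <- paste(labs, seq_along(labs))
      caps <- stats::runif(nClasses) < 0.2
      labs[caps] <- sub("^(.)", "\\U\\1", labs[caps], perl = TRUE)
      nLab <- ceiling(labelFraction * nClasses)
      which <- sample.int(nClasses, nLab)
      for (i in which) add(annotationAssertion(cIRI[i], RDFS_LABEL, labs[i]))
    }
    for (i in seq_len(nRoles))
      add(annotationAssertion(rIRI[i], RDFS_LABEL,
                              .SYNTH_VERBS[(i - 1L) %% length(.SYNTH_VERBS) + 1L]))
    if (nRoles >= 2L)  # small role hierarchy
      for (i in 2L:nRoles)
        if (stats::runif(1) < 0.5)
          add(subObjectPropertyOf(rIRI[i], rIRI[sample.int(i - 1L, 1L)]))

    pick <- function(v) v[sample.int(length(v), 1L)]  # safe for length 1
    samplePair <- function() {  # (i, j) with j < i, for acyclicity
      i <- pick(2:nClasses)
      c(i, sample.int(i - 1L, 1L))
    }
    if (nClasses >= 2L) {
      seen <- new.env(parent = emptyenv())
      made <- 0L; tries <- 0L
      while (made < nSubClassAxioms && tries < 50L * (nSubClassAxioms + 1L)) {
        tries <- tries + 1L
        p <- samplePair()
        key <- paste(p, collapse = "|")
        if (!is.null(get0(key, envir = seen, inherits = FALSE))) next
        assign(key, TRUE, envir = seen)
        add(subClassOf(ceNamed(cIRI[p[1L]]), ceNamed(cIRI[p[2L]])))
        made <- made + 1L
      }
    }
    if (nClasses >= 3L)
      for (k in seq_len(nConjunctionAxioms)) {
        i <- pick(3:nClasses)
        ab <- sample.int(i - 1L, 2L)
        add(subClassOf(ceNamed(cIRI[i]),
                       ceAnd(ceNamed(cIRI[ab[1L]]), ceNamed(cIRI[ab[2L]]))))
      }
    if (nClasses >= 2L && nRoles >= 1L)
      for (k in seq_len(nExistentialAxioms)) {
        p <- samplePair()
        add(subClassOf(ceNamed(cIRI[p[1L]]),
                       ceSome(rIRI[sample.int(nRoles, 1L)],
                              ceNamed(cIRI[p[2L]]))))
      }
    if (nClasses >= 3L && nRoles >= 1L)
      for (k in seq_len(nEquivalenceAxioms)) {
        i <- pick(3:nClasses)
        ab <- sample.int(i - 1L, 2L)
        add(equivalentClasses(
          ceNamed(cIRI[i]),
          ceAnd(ceNamed(cIRI[ab[1L]]),
                ceSome(rIRI[sample.int(nRoles, 1L)], ceNamed(cIRI[ab[2L]])))))
      }
    if (nonELFraction > 0 && nClasses >= 2L) {
      nLogical <- sum(vapply(axs, .isLogicalAxiom, logical(1)))
      nNonEL <- round(nonELFraction * nLogical)
      for (k in seq_len(nNonEL)) {
        p <- samplePair()
        r <- if (nRoles) rIRI[sample.int(nRoles, 1L)] else
          paste0(.SYNTH_NS, "R01")
        form <- sample(c("all", "union"), 1L)
        raw <- if (form == "all")
          sprintf("SubClassOf(<%s> ObjectAllValuesFrom(<%s> <%s>))",
                  cIRI[p[1L]], r, cIRI[p[2L]])
        else
          sprintf("SubClassOf(<%s> ObjectUnionOf(<%s> <%s>))",
                  cIRI[p[1L]], r, cIRI[p[2L]])
        add(unsupportedAxiom(
          if (form == "all") "ObjectAllValuesFrom" else "ObjectUnionOf", raw))
      }
    }
    if (injectInconsistency && nClasses >= 3L) {
      add(subClassOf(ceTop(), ceNamed(cIRI[nClasses])))
      add(subClassOf(ceNamed(cIRI[nClasses]), ceNamed(cIRI[1L])))
      add(subClassOf(ceNamed(cIRI[nClasses]), ceNamed(cIRI[2L])))
      add(disjointClasses(ceNamed(cIRI[1L]), ceNamed(cIRI[2L])))
    }
  })
  Ontology(axs, iri = sprintf("http://example.org/synth/onto-%d", seed),
           sourceName = sprintf("synthetic-%d", seed))
}

.FIX_NS <- "http://example.org/fix#"
.fixC <- function(x) paste0(.FIX_NS, x)

.fixOntology <- function(name, axioms, labels = NULL) {
  cls <- signatureOf(Ontology(axioms))$classIRIs
  decls <- lapply(cls, function(iri) declaration("class", iri))
  labAx <- list()
  if (!is.null(labels))
    labAx <- mapply(function(iri, lab) annotationAssertion(iri, RDFS_LABEL, lab),
                    .fixC(names(labels)), unname(labels), SIMPLIFY = FALSE)
  Ontology(c(decls, labAx, axioms),
           iri = paste0("http://example.org/fix/", name), sourceName = name)
}

.fixPairs <- function(...) {
  v <- c(...)
  m <- matrix(.fixC(v), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("sub", "sup")))
  m[order(m[, 1L], m[, 2L], method = "radix"), , drop = FALSE]
}

#' Built-in hand-closed fixture ontologies
#'
#' Seven toy ontologies whose entailed strict named subsumption pairs,
#' unsatisfiable classes and consistency flags were derived by exhaustive
#' rule application by hand. Used throughout the test suite as ground
#' truth, cross-checked against [bruteForceOracle()].
#'
#' @return named list; each element has \code{ontology},
#'   \code{expectedSubsumptions} (two-column character matrix of strict,
#'   non-reflexive entailed pairs over satisfiable classes; for
#'   unsatisfiable classes every outgoing pair is listed),
#'   \code{expectedUnsatisfiable} (character), \code{expectedConsistent}
#'   (logical).
#' @export
builtinFixtures <- function() {
  A <- ceNamed(.fixC("A")); B <- ceNamed(.fixC("B"))
  C <- ceNamed(.fixC("C")); D <- ceNamed(.fixC("D"))
  r <- paste0(.FIX_NS, "r")
  fix <- list()

  fix$chain <- list(
    ontology = .fixOntology("chain",
      list(subClassOf(A, B), subClassOf(B, C)),
      labels = c(A = "alpha", B = "beta", C = "gamma")),
    expectedSubsumptions = .fixPairs("A","B", "A","C", "B","C"),
    expectedUnsatisfiable = character(0), expectedConsistent = TRUE)

  fix$diamond <- list(
    ontology = .fixOntology("diamond",
      list(subClassOf(A, B), subClassOf(A, C), subClassOf(B, D),
           subClassOf(C, D)),
      labels = c(A = "apex", B = "left side", C = "right side", D = "base")),
    expectedSubsumptions = .fixPairs("A","B", "A","C", "A","D", "B","D",
                                     "C","D"),
    expectedUnsatisfiable = character(0), expectedConsistent = TRUE)

  fix$definition <- list(
    ontology = .fixOntology("definition",
      list(declaration("objectProperty", r),
           annotationAssertion(r, RDFS_LABEL, "part of"),
           equivalentClasses(A, ceAnd(B, ceSome(r, C))),
           subClassOf(D, B), subClassOf(D, ceSome(r, C))),
      labels = c(A = "defined thing", B = "bearer", C = "component",
                 D = "deduced thing")),
    expectedSubsumptions = .fixPairs("A","B", "D","A", "D","B"),
    expectedUnsatisfiable = character(0), expectedConsistent = TRUE)

  fix$existentialPropagation <- list(
    ontology = .fixOntology("existentialPropagation",
      list(declaration("objectProperty", r),
           annotationAssertion(r, RDFS_LABEL, "located in"),
           subClassOf(A, ceSome(r, B)), subClassOf(B, C),
           subClassOf(ceSome(r, C), D)),
      labels = c(A = "starter", B = "narrow site", C = "wide site",
                 D = "classified")),
    expectedSubsumptions = .fixPairs("A","D", "B","C"),
    expectedUnsatisfiable = character(0), expectedConsistent = TRUE)

  fix$equivalence <- list(
    ontology = .fixOntology("equivalence",
      list(equivalentClasses(A, B), subClassOf(B, C)),
      labels = c(A = "first name", B = "second name", C = "ancestor")),
    expectedSubsumptions = .fixPairs("A","B", "B","A", "A","C", "B","C"),
    expectedUnsatisfiable = character(0), expectedConsistent = TRUE)

  fix$unsatisfiableClass <- list(
    ontology = .fixOntology("unsatisfiableClass",
      list(subClassOf(A, B), subClassOf(A, C), disjointClasses(B, C),
           subClassOf(D, A)),
      labels = c(A = "impossible", B = "this", C = "that", D = "doomed")),
    # unsatisfiable classes entail subsumption by every named class
    expectedSubsumptions = .fixPairs("A","B", "A","C", "A","D",
                                     "D","A", "D","B", "D","C"),
    expectedUnsatisfiable = .fixC(c("A", "D")), expectedConsistent = TRUE)

  fix$inconsistent <- list(
    ontology = .fixOntology("inconsistent",
      list(subClassOf(ceTop(), A), subClassOf(A, B), subClassOf(A, C),
           disjointClasses(B, C)),
      labels = c(A = "universal", B = "one half", C = "other half")),
    expectedSubsumptions = .fixPairs("A","B", "A","C", "B","A", "B","C",
                                     "C","A", "C","B"),
    expectedUnsatisfiable = .fixC(c("A", "B", "C")),
    expectedConsistent = FALSE)

  fix
}
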