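# Inferred-axiom enrichment: classify, then materialize the entailed
# direct subsumption edges and equivalence groups into the EL-filtered
# ontology, so the same EL queries can be answered from told axioms alone.
# Non-EL (Unsupported) axioms are removed; annotations and declarations are
# preserved.

#' Enrich an ontology with its inferred subsumptions
#'
#' The output is \code{filterToEL(ontology)} plus one \code{SubClassOf}
#' axiom per entailed direct subsumption edge between equivalence-group
#' representatives (told axioms and reflexive pairs excluded) and one
#' \code{EquivalentClasses} axiom per equivalence group of two or more
#' classes. By default only the transitive reduction is materialized —
#' answer-preserving, since the reasoner recovers transitivity — while
#' \code{fullClosure = TRUE} materializes every entailed non-reflexive
#' pair. Every logical axiom of the output is within the EL fragment, and
#' re-enriching an enriched ontology adds nothing (idempotence).
#'
#' Classification here is the package's own EL saturation; EL-expressible
#' consequences of the removed non-EL axioms are therefore not derived. An
#' externally computed classification (e.g. from a full OWL DL reasoner)
#' can be supplied via \code{inferredFrom} as extra told subsumption pairs.
#'
#' @param ontology an \code{Ontology}.
#' @param fullClosure materialize all entailed pairs instead of the
#'   transitive reduction.
#' @param inferredFrom optional two-column character matrix/data.frame of
#'   (sub, sup) class IRI pairs to add as \code{SubClassOf} axioms before
#'   classification.
#' @return list with \code{ontology} (the enriched \code{Ontology}) and
#'   \code{report}, an \code{EnrichmentReport}: \code{inferredAxiomsAdded},
#'   \code{nonELAxiomsRemoved}, \code{inputStats}, \code{outputStats}.
#' @section Errors: \code{elrepo_inconsistent_ontology} — enrichment of an
#'   inconsistent ontology is refused.
#' @export
enrichOntology <- function(ontology, fullClosure = FALSE, inferredFrom = NULL) {
  stopifnot(is(ontology, "Ontology"))
  inputStats <- computeStats(ontology)
  filtered <- filterToEL(ontology)
  base <- filtered$ontology
  if (!is.null(inferredFrom)) {
    inferredFrom <- as.matrix(inferredFrom)
    extra <- lapply(seq_len(nrow(inferredFrom)), function(i)
      subClassOf(ceNamed(inferredFrom[i, 1L]), ceNamed(inferredFrom[i, 2L])))
    base <- Ontology(c(base@axioms, extra), iri = base@iri,
                     sourceName = base@sourceName, imports = base@imports)
  }
  tax <- classify(base)
  if (!taxonomyConsistent(tax))
    .elStop("elrepo_inconsistent_ontology",
            "refusing to enrich an inconsistent ontology")

  told <- vapply(base@axioms, axiomKey, character(1))
  newAxioms <- list()
  addIfNew <- function(ax) {
    if (!axiomKey(ax) %in% told) newAxioms[[length(newAxioms) + 1L]] <<- ax
  }
  if (fullClosure) {
    for (a in names(tax@subsumers))
      for (b in tax@subsumers[[a]])
        addIfNew(subClassOf(ceNamed(a), ceNamed(b)))
  } else {
    edges <- tax@directEdges
    for (i in seq_len(nrow(edges)))
      addIfNew(subClassOf(ceNamed(edges[i, "child"]),
                          ceNamed(edges[i, "parent"])))
    for (g in tax@groups)
      if (length(g) >= 2L)
        addIfNew(equivalentClasses(lapply(g, ceNamed)))
    # an unsatisfiable class is equivalent to bottom: keep that entailment told
    for (u in tax@unsatisfiable)
      addIfNew(subClassOf(ceNamed(u), ceBottom()))
  }
  out <- Ontology(c(base@axioms, newAxioms), iri = ontology@iri,
                  sourceName = ontology@sourceName,
                  imports = ontology@imports, prefixes = ontology@prefixes)
  outputStats <- computeStats(out)
  list(ontology = out,
       report = structure(list(
         inferredAxiomsAdded = length(newAxioms),
         nonELAxiomsRemoved = filtered$report$droppedCount,
         inputStats = inputStats, outputStats = outputStats),
         class = "EnrichmentReport"))
}

#' @export
print.EnrichmentReport <- function(x, ...) {
  cat("EnrichmentReport:", x$inferredAxiomsAdded, "inferred axioms added,",
      x$nonELAxiomsRemoved, "non-EL axioms removed\n")
  cat(sprintf("  logical axioms: %d -> %d\n",
              x$inputStats$logicalAxiomCount, x$outputStats$logicalAxiomCount))
  invisible(x)
}

#' Verify that enrichment preserves query answers
#'
#' Runs each sample query in all three modes against both ontologies and
#' compares the answer sets. With \code{sampleQueries = NULL}, every named
#' class common to both signatures is queried as a primitive expression —
#' an exhaustive check of the named subsumption relation.
#'
#' @param original,enriched two \code{Ontology}/\code{ReasonedOntology}
#'   objects to compare.
#' @param sampleQueries optional list of \code{ClassExpr} queries.
#' @return \code{TRUE} if all answer sets agree; otherwise \code{FALSE}
#'   with a \code{"mismatches"} attribute describing the disagreements.
#' @export
verifyQueryPreservation <- function(original, enriched, sampleQueries = NULL) {
  roO <- reasonedOntology(original)
  roE <- reasonedOntology(enriched)
  if (is.null(sampleQueries)) {
    common <- intersect(signatureOf(roO@ontology)$classIRIs,
                        signatureOf(roE@ontology)$classIRIs)
    sampleQueries <- lapply(common, ceNamed)
  }
  mismatches <- list()
  for (q in sampleQueries)
    for (mode in QUERY_MODES) {
      ansO <- executeQuery(roO, q, mode)$answers
      ansE <- executeQuery(roE, q, mode)$answers
      if (!identical(ansO, ansE))
        mismatches[[length(mismatches) + 1L]] <-
          list(query = ceKey(q), mode = mode,
               onlyOriginal = setdiff(ansO, ansE),
               onlyEnriched = setdiff(ansE, ansO))
    }
  if (length(mismatches)) {
    res <- FALSE
    attr(res, "mismatches") <- mismatches
    res
  } else TRUE
}
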