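# Label index: rdfs:label annotations on declared/used classes and object
# properties, normalized for lookup, original spellings retained.

#' Build a label index for an ontology
#'
#' Indexes every \code{rdfs:label} annotation whose subject is a class or
#' object property of the ontology's signature. Lookup keys are normalized
#' with [normalizeLabel()]; ambiguity (one label, several IRIs) is
#' preserved and surfaced at resolution time.
#'
#' @param ontology an \code{Ontology}.
#' @return a \code{LabelIndex}.
#' @export
buildLabelIndex <- function(ontology) {
  stopifnot(is(ontology, "Ontology"))
  sig <- signatureOf(ontology)
  kind <- c(stats::setNames(rep("class", length(sig$classIRIs)), sig$classIRIs),
            stats::setNames(rep("objectProperty", length(sig$roleIRIs)),
                            sig$roleIRIs))
  byLabel <- list(); byIRI <- list()
  for (ax in ontology@axioms) {
    if (ax$kind != "AnnotationAssertion" || ax$property != RDFS_LABEL) next
    if (!ax$subject %in% names(kind)) next
    key <- normalizeLabel(ax$value)
    if (!nzchar(key)) next
    byLabel[[key]] <- unique(c(byLabel[[key]], ax$subject))
    byIRI[[ax$subject]] <- unique(c(byIRI[[ax$subject]], ax$value))
  }
  new("LabelIndex", byLabel = byLabel, byIRI = byIRI, kind = kind)
}

#' Resolve a label to a single IRI
#'
#' Matching is case-insensitive with whitespace collapsing; when several
#' IRIs share the normalized label, an exact-case match wins before
#' ambiguity is declared.
#'
#' @param index a \code{LabelIndex}.
#' @param label the label as written in the query.
#' @param kind restrict to \code{"class"} or \code{"objectProperty"}
#'   (\code{NULL}: no restriction).
#' @return a single IRI.
#' @export
resolveLabel <- function(index, label, kind = NULL) {
  stopifnot(is(index, "LabelIndex"))
  cands <- index@byLabel[[normalizeLabel(label)]] %||% character(0)
  if (!is.null(kind)) cands <- cands[index@kind[cands] == kind]
  if (!length(cands))
    .elStop("elrepo_unknown_label",
            sprintf("no %s found for label '%s'", kind %||% "entity", label))
  if (length(cands) > 1L) {
    exact <- cands[vapply(cands, function(iri)
      label %in% index@byIRI[[iri]], logical(1))]
    if (length(exact) == 1L) return(exact)
    .elStop("elrepo_ambiguous_label",
            sprintf("label '%s' is ambiguous: %s", label,
                    paste0("<", sort(cands), ">", collapse = ", ")))
  }
  cands
}

#' Display labels for a set of IRIs
#'
#' @param index a \code{LabelIndex}.
#' @param iris character vector of IRIs.
#' @return named character vector IRI -> first label (or \code{NA}).
#' @export
labelsFor <- function(index, iris) {
  stats::setNames(vapply(iris, function(iri) {
    ls <- index@byIRI[[iri]]
    if (is.null(ls)) NA_character_ else ls[[1L]]
  }, character(1)), iris)
}

setMethod("show", "LabelIndex", function(object) {
  cat("LabelIndex:", length(object@byLabel), "distinct labels over",
      length(object@byIRI), "entities (",
      sum(object@kind[names(object@byIRI)] == "class"), "classes )\n")
})
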