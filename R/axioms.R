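# Axiom constructors. Axioms are tagged lists with a canonical key; an
# Ontology stores them with set semantics (duplicates by key are dropped).

LOGICAL_AXIOM_KINDS <- c("SubClassOf", "EquivalentClasses", "DisjointClasses",
                         "SubObjectPropertyOf", "EquivalentObjectProperties")
RBOX_AXIOM_KINDS <- c("SubObjectPropertyOf", "EquivalentObjectProperties")

.newAxiom <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "Axiom")
}

#' Axiom constructors
#'
#' Build the TBox, RBox and annotation axioms of the supported fragment.
#' \code{EquivalentClasses}/\code{DisjointClasses} are stored n-ary with
#' canonically ordered, deduplicated members; \code{subObjectPropertyOf}
#' accepts a role chain of one or more property IRIs on the subproperty
#' side. \code{unsupportedAxiom} records a well-formed construct outside the
#' fragment; it carries no logical content.
#'
#' @param sub,sup class expressions (or, for property axioms, IRIs).
#' @param ... class expressions (members), or a single list of them.
#' @param subChain character vector of property IRIs (the chain).
#' @param kind declaration kind, \code{"class"} or \code{"objectProperty"}.
#' @param iri,subject,property character IRI.
#' @param value character literal (annotation value).
#' @param constructName name of the unrecognized OWL construct.
#' @param rawText original text of the unsupported axiom (may be \code{NA}).
#' @return an object of class \code{Axiom}.
#' @name axioms
NULL

#' @rdname axioms
#' @export
subClassOf <- function(sub, sup) {
  stopifnot(inherits(sub, "ClassExpr"), inherits(sup, "ClassExpr"))
  .newAxiom("SubClassOf", sub = sub, sup = sup)
}

.memberList <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1L]]) && !inherits(ms[[1L]], "ClassExpr"))
    ms <- ms[[1L]]
  for (m in ms) stopifnot(inherits(m, "ClassExpr"))
  keys <- vapply(ms, ceKey, character(1))
  keep <- !duplicated(keys)
  ms[keep][order(keys[keep])]
}

#' @rdname axioms
#' @export
equivalentClasses <- function(...) {
  ms <- .memberList(...)
  if (length(ms) < 2L)
    .elStop("elrepo_invalid_axiom",
            "EquivalentClasses needs >= 2 distinct member expressions")
  .newAxiom("EquivalentClasses", members = ms)
}

#' @rdname axioms
#' @export
disjointClasses <- function(...) {
  ms <- .memberList(...)
  if (length(ms) < 2L)
    .elStop("elrepo_invalid_axiom",
            "DisjointClasses needs >= 2 distinct member expressions")
  .newAxiom("DisjointClasses", members = ms)
}

#' @rdname axioms
#' @export
subObjectPropertyOf <- function(subChain, sup) {
  stopifnot(is.character(subChain), length(subChain) >= 1L,
            is.character(sup), length(sup) == 1L)
  .newAxiom("SubObjectPropertyOf", subChain = subChain, sup = sup)
}

#' @rdname axioms
#' @export
equivalentObjectProperties <- function(...) {
  ms <- unlist(list(...), use.names = FALSE)
  stopifnot(is.character(ms))
  ms <- sort(unique(ms))
  if (length(ms) < 2L)
    .elStop("elrepo_invalid_axiom",
            "EquivalentObjectProperties needs >= 2 distinct properties")
  .newAxiom("EquivalentObjectProperties", members = ms)
}

#' @rdname axioms
#' @export
declaration <- function(kind, iri) {
  kind <- match.arg(kind, c("class", "objectProperty"))
  stopifnot(is.character(iri), length(iri) == 1L, nzchar(iri))
  .newAxiom("Declaration", declKind = kind, iri = iri)
}

#' @rdname axioms
#' @export
annotationAssertion <- function(subject, property, value) {
  stopifnot(is.character(subject), length(subject) == 1L,
            is.character(property), length(property) == 1L,
            is.character(value), length(value) == 1L)
  .newAxiom("AnnotationAssertion", subject = subject, property = property,
            value = value)
}

#' @rdname axioms
#' @export
unsupportedAxiom <- function(constructName, rawText = NA_character_) {
  stopifnot(is.character(constructName), length(constructName) == 1L)
  .newAxiom("Unsupported", constructName = constructName,
            rawText = as.character(rawText))
}

#' Canonical key of an axiom
#'
#' Used for set-semantics deduplication and deterministic serialization
#' order. Two axioms with the same key are structurally equal.
#'
#' @param ax an \code{Axiom}.
#' @return length-1 character.
#' @export
axiomKey <- function(ax) {
  switch(ax$kind,
    SubClassOf = paste0("Sub|", ceKey(ax$sub), "|", ceKey(ax$sup)),
    EquivalentClasses = paste0(
      "Eqv|", paste(vapply(ax$members, ceKey, character(1)), collapse = "|")),
    DisjointClasses = paste0(
      "Dis|", paste(vapply(ax$members, ceKey, character(1)), collapse = "|")),
    SubObjectPropertyOf = paste0(
      "SubP|", paste(ax$subChain, collapse = ","), "|", ax$sup),
    EquivalentObjectProperties = paste0(
      "EqvP|", paste(ax$members, collapse = "|")),
    Declaration = paste0("Dec|", ax$declKind, "|", ax$iri),
    AnnotationAssertion = paste0("Ann|", ax$subject, "|", ax$property, "|",
                                 ax$value),
    Unsupported = paste0("Uns|", ax$constructName, "|", ax$rawText),
    stop("unknown axiom kind: ", ax$kind)
  )
}

.isLogicalAxiom <- function(ax) ax$kind %in% LOGICAL_AXIOM_KINDS
.isRBoxAxiom <- function(ax) ax$kind %in% RBOX_AXIOM_KINDS

#' @export
print.Axiom <- function(x, ...) {
  cat("Axiom:", .renderAxiom(x), "\n")
  invisible(x)
}
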