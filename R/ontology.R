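# Ontology constructor, accessors, signature and per-ontology statistics.

#' Construct an Ontology
#'
#' @param axioms list of \code{Axiom} objects; duplicates (by canonical key)
#'   are dropped, keeping first occurrence order.
#' @param iri optional ontology IRI.
#' @param sourceName name used in reports; defaults to the IRI or
#'   \code{"<anonymous>"}.
#' @param imports character vector of imported ontology IRIs (recorded, not
#'   resolved).
#' @param prefixes named character vector of source prefix declarations.
#' @return an \code{Ontology}.
#' @examples
#' A <- ceNamed("http://ex.org/A"); B <- ceNamed("http://ex.org/B")
#' Ontology(list(subClassOf(A, B)), iri = "http://ex.org/onto")
#' @export
Ontology <- function(axioms = list(), iri = character(0),
                     sourceName = NULL, imports = character(0),
                     prefixes = character(0)) {
  keys <- vapply(axioms, axiomKey, character(1))
  axioms <- axioms[!duplicated(keys)]
  if (is.null(sourceName))
    sourceName <- if (length(iri)) iri else "<anonymous>"
  new("Ontology", iri = as.character(iri), axioms = axioms,
      sourceName = as.character(sourceName), imports = as.character(imports),
      prefixes = prefixes)
}

#' @describeIn Ontology-accessors the axiom list.
#' @export
axioms <- function(x) x@axioms

#' Ontology accessors
#'
#' @param x an \code{Ontology}.
#' @name Ontology-accessors
NULL

#' @describeIn Ontology-accessors the ontology IRI (length 0 if absent).
#' @export
ontologyIRI <- function(x) x@iri

#' @describeIn Ontology-accessors the source name used in reports.
#' @export
sourceName <- function(x) x@sourceName

.axiomSignature <- function(ax) {
  cls <- .chr0; rls <- .chr0
  addCE <- function(ce) {
    s <- .ceSignature(ce)
    cls <<- c(cls, s$classes); rls <<- c(rls, s$roles)
  }
  switch(ax$kind,
    SubClassOf = { addCE(ax$sub); addCE(ax$sup) },
    EquivalentClasses = ,
    DisjointClasses = for (m in ax$members) addCE(m),
    SubObjectPropertyOf = rls <- c(rls, ax$subChain, ax$sup),
    EquivalentObjectProperties = rls <- c(rls, ax$members),
    Declaration = if (ax$declKind == "class") cls <- c(cls, ax$iri)
                  else rls <- c(rls, ax$iri),
    NULL  # annotations and Unsupported carry no logical content
  )
  list(classes = cls, roles = rls)
}

#' Signature of an ontology
#'
#' Every IRI used in class position or role position across all logical
#' axioms, unioned with declarations. Top and bottom are excluded;
#' \code{Unsupported} axioms and annotations contribute nothing.
#'
#' @param ontology an \code{Ontology}.
#' @return list with sorted character vectors \code{classIRIs},
#'   \code{roleIRIs}.
#' @export
signatureOf <- function(ontology) {
  stopifnot(is(ontology, "Ontology"))
  parts <- lapply(ontology@axioms, .axiomSignature)
  cls <- unique(unlist(lapply(parts, `[[`, "classes")))
  rls <- unique(unlist(lapply(parts, `[[`, "roles")))
  list(classIRIs = sort(as.character(setdiff(cls, c(OWL_THING, OWL_NOTHING)))),
       roleIRIs = sort(as.character(rls %||% .chr0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-ontology statistics
#'
#' Counts classes, object properties, logical axioms (the five logical
#' kinds), RBox axioms (the two role kinds), an axiom-type histogram over
#' all axioms, and the number of classes carrying at least one
#' \code{rdfs:label}.
#'
#' @param ontology an \code{Ontology}.
#' @return an object of class \code{OntologyStats}: a list with fields
#'   \code{classCount}, \code{objectPropertyCount}, \code{logicalAxiomCount},
#'   \code{rboxAxiomCount}, \code{axiomTypeHistogram}, \code{labeledClassCount}.
#' @export
computeStats <- function(ontology) {
  stopifnot(is(ontology, "Ontology"))
  sig <- signatureOf(ontology)
  kinds <- vapply(ontology@axioms, `[[`, character(1), "kind")
  hist <- if (length(kinds)) table(kinds) else table(character(0))
  hist <- stats::setNames(as.integer(hist), names(hist))
  labeled <- .chr0
  for (ax in ontology@axioms)
    if (ax$kind == "AnnotationAssertion" && ax$property == RDFS_LABEL &&
        ax$subject %in% sig$classIRIs)
      labeled <- c(labeled, ax$subject)
  structure(list(
    classCount = length(sig$classIRIs),
    objectPropertyCount = length(sig$roleIRIs),
    logicalAxiomCount = sum(kinds %in% LOGICAL_AXIOM_KINDS),
    rboxAxiomCount = sum(kinds %in% RBOX_AXIOM_KINDS),
    axiomTypeHistogram = hist,
    labeledClassCount = length(unique(labeled))
  ), class = "OntologyStats")
}

#' @export
print.OntologyStats <- function(x, ...) {
  cat("OntologyStats:", x$classCount, "classes,",
      x$objectPropertyCount, "properties,",
      x$logicalAxiomCount, "logical axioms (",
      x$rboxAxiomCount, "RBox ),",
      x$labeledClassCount, "labeled classes\n")
  invisible(x)
}

setMethod("show", "Ontology", function(object) {
  cat("Ontology", if (length(object@iri)) paste0("<", object@iri, ">")
      else "<anonymous>", "\n")
  cat("  source:", object@sourceName, "\n")
  cat("  axioms:", length(object@axioms), "\n")
  kinds <- vapply(object@axioms, `[[`, character(1), "kind")
  if (length(kinds)) {
    tb <- table(kinds)
    cat("  ", paste0(names(tb), "=", as.integer(tb), collapse = ", "), "\n")
  }
  if (length(object@imports))
    cat("  imports:", length(object@imports), "(unresolved)\n")
})
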