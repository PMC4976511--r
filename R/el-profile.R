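# EL-profile membership per axiom and the ontology-level filter. Because the
# reader only materializes EL-compatible class expressions (anything else
# arrives as an Unsupported axiom), membership reduces to an axiom-kind
# check; it is kept as a distinct operation so alternative ingestion paths
# can reuse the contract.

#' Is an axiom within the supported OWL-EL fragment?
#'
#' Logical axioms built only from named classes, top, bottom, conjunction
#' and existential restriction are in the fragment (this includes
#' \code{DisjointClasses} over EL expressions). \code{Unsupported} axioms
#' are not. Declarations and annotations carry no logical content; they are
#' reported as in-fragment so the filter passes them through.
#'
#' @param axiom an \code{Axiom}.
#' @return list with \code{inEL} (logical) and \code{reason} (character,
#'   empty when \code{inEL} is \code{TRUE}).
#' @export
axiomInEL <- function(axiom) {
  stopifnot(inherits(axiom, "Axiom"))
  if (axiom$kind == "Unsupported")
    return(list(inEL = FALSE, reason = "unsupported-construct"))
  list(inEL = TRUE, reason = "")
}

#' Filter an ontology to its EL fragment
#'
#' Keeps exactly the axioms with \code{axiomInEL(..)$inEL}, plus all
#' declarations and annotations (labels must survive filtering because
#' queries are constructed from labels). Idempotent.
#'
#' @param ontology an \code{Ontology}.
#' @return list with \code{ontology} (the filtered \code{Ontology}) and
#'   \code{report}, a \code{FilterReport}: \code{keptCount},
#'   \code{droppedCount} (over logical + unsupported axioms) and
#'   \code{droppedByReason} (named integer vector).
#' @export
filterToEL <- function(ontology) {
  stopifnot(is(ontology, "Ontology"))
  kept <- 0L; droppedReasons <- character(0)
  keepAx <- logical(length(ontology@axioms))
  for (i in seq_along(ontology@axioms)) {
    ax <- ontology@axioms[[i]]
    if (ax$kind %in% c("Declaration", "AnnotationAssertion")) {
      keepAx[i] <- TRUE
      next
    }
    chk <- axiomInEL(ax)
    if (chk$inEL) {
      keepAx[i] <- TRUE
      kept <- kept + 1L
    } else {
      droppedReasons <- c(droppedReasons, chk$reason)
    }
  }
  out <- Ontology(ontology@axioms[keepAx], iri = ontology@iri,
                  sourceName = ontology@sourceName,
                  imports = ontology@imports, prefixes = ontology@prefixes)
  byReason <- if (length(droppedReasons)) table(droppedReasons)
              else table(character(0))
  list(ontology = out,
       report = list(keptCount = kept,
                     droppedCount = length(droppedReasons),
                     droppedByReason = stats::setNames(as.integer(byReason),
                                                       names(byReason))))
}
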