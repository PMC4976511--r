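#' @import methods
NULL

#' Ontology: a named set of axioms
#'
#' The central container: an (optional) ontology IRI, a set of axioms (set
#' semantics — duplicates are dropped at construction), a source name used
#' in reports, and any recorded-but-unresolved import IRIs.
#'
#' @slot iri character, the ontology IRI (length 0 if absent).
#' @slot axioms list of \code{Axiom} objects, deduplicated by canonical key.
#' @slot sourceName character scalar naming the source (file name or label).
#' @slot imports character vector of imported ontology IRIs (not resolved).
#' @slot prefixes named character vector of prefix declarations from the
#'   source document (name \code{""} is the default prefix); re-emitted on
#'   serialization so echoed \code{Unsupported} axioms keep resolving.
#' @export
setClass("Ontology", representation(
  iri = "character", axioms = "list", sourceName = "character",
  imports = "character", prefixes = "character"
))

setValidity("Ontology", function(object) {
  if (length(object@iri) > 1L) return("iri must have length 0 or 1")
  if (length(object@sourceName) != 1L) return("sourceName must be length 1")
  ok <- vapply(object@axioms, inherits, logical(1), what = "Axiom")
  if (!all(ok)) return("axioms must all be Axiom objects")
  keys <- vapply(object@axioms, axiomKey, character(1))
  if (anyDuplicated(keys)) return("duplicate axioms (set semantics violated)")
  TRUE
})

#' Normalized ontology (EL normal forms)
#'
#' The four GCI normal forms and the role normal form consumed by the
#' saturation calculus, over an integer-coded signature. Indices 1 and 2 are
#' reserved for top and bottom.
#'
#' @slot classTable character vector, IRI (or reserved fresh IRI) per class id.
#' @slot roleTable character vector, IRI per role id.
#' @slot nf1 integer matrix (sub, sup) for A \eqn{\sqsubseteq} B.
#' @slot nf2 integer matrix (a1, a2, sup) for A1 \eqn{\sqcap} A2
#'   \eqn{\sqsubseteq} B.
#' @slot nf3 integer matrix (sub, role, filler) for A \eqn{\sqsubseteq}
#'   \eqn{\exists}r.B.
#' @slot nf4 integer matrix (role, filler, sup) for \eqn{\exists}r.A
#'   \eqn{\sqsubseteq} B.
#' @slot roleNF list of (subChain integer vector of length 1-2, sup integer).
#' @slot freshNameMap named list: fresh IRI -> original \code{ClassExpr}.
#' @slot origClassIRIs character vector of the input's named classes.
#' @export
setClass("NormalizedOntology", representation(
  classTable = "character", roleTable = "character",
  nf1 = "matrix", nf2 = "matrix", nf3 = "matrix", nf4 = "matrix",
  roleNF = "list", freshNameMap = "list", origClassIRIs = "character"
))

#' Saturation state
#'
#' Subsumer sets S(.) and role-successor relations R(.) computed to
#' fixpoint, held in an environment so incremental query insertion and
#' rollback can mutate in place. Use \code{subsumersOf} to inspect.
#'
#' @slot env environment holding the worklist saturation structures.
#' @export
setClass("SaturationState", representation(env = "environment"))

#' Taxonomy of a classified ontology
#'
#' @slot groups list of character vectors: equivalence classes of
#'   satisfiable named classes (mutual subsumption), each sorted, keyed by
#'   their lexicographically least member (the representative).
#' @slot directEdges character matrix, columns \code{child}, \code{parent}
#'   (group representatives); the transitive reduction of entailed
#'   subsumption between groups.
#' @slot unsatisfiable character vector of unsatisfiable named classes.
#' @slot consistent logical scalar.
#' @slot subsumers named list: class IRI -> all entailed strict named
#'   subsumers (transitive closure, equivalents included).
#' @export
setClass("Taxonomy", representation(
  groups = "list", directEdges = "matrix", unsatisfiable = "character",
  consistent = "logical", subsumers = "list"
))

setValidity("Taxonomy", function(object) {
  if (length(object@consistent) != 1L) return("consistent must be length 1")
  if (!identical(colnames(object@directEdges), c("child", "parent")))
    return("directEdges must have columns child, parent")
  TRUE
})

#' Label index
#'
#' Bidirectional label/IRI maps used to resolve Manchester-syntax query
#' tokens. Labels are matched after \code{normalizeLabel}; the original
#' spellings are retained for exact-case tie-breaking and display.
#'
#' @slot byLabel named list: normalized label -> character vector of IRIs.
#' @slot byIRI named list: IRI -> character vector of original label strings.
#' @slot kind named character: IRI -> "class" or "objectProperty".
#' @export
setClass("LabelIndex", representation(
  byLabel = "list", byIRI = "list", kind = "character"
))

#' An ontology with cached reasoning artifacts
#'
#' Wraps an \code{Ontology} together with a lazily computed EL filter,
#' normalization, saturation, taxonomy and label index. All query-engine
#' entry points accept either an \code{Ontology} (classified on the fly) or
#' a \code{ReasonedOntology} (classification cached across calls).
#'
#' @slot ontology the wrapped \code{Ontology}.
#' @slot cache environment holding \code{norm}, \code{state},
#'   \code{taxonomy}, \code{labelIndex}, \code{stats} once computed.
#' @export
setClass("ReasonedOntology", representation(
  ontology = "Ontology", cache = "environment"
))

#' Multi-ontology repository
#'
#' @slot entries named list; per loaded-and-usable ontology a list with
#'   elements \code{reasoned} (\code{ReasonedOntology}), \code{stats}
#'   (\code{OntologyStats}), \code{contentHash} (md5 of the source file, if
#'   loaded from disk).
#' @slot loadReport the load-outcome accounting (see \code{loadOntologies}).
#' @export
setClass("OntologyRepository", representation(
  entries = "list", loadReport = "list"
))
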