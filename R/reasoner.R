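# Classification: EL filter -> normalization -> saturation -> taxonomy
# (equivalence classes, transitive-reduction direct edges, unsatisfiable
# classes, consistency), plus expression-level subsumption entailment via
# incremental query-class insertion.

#' Wrap an ontology with cached reasoning artifacts
#'
#' @param ontology an \code{Ontology} (or an existing
#'   \code{ReasonedOntology}, returned unchanged).
#' @return a \code{ReasonedOntology}; classification is computed lazily on
#'   first use and cached.
#' @export
reasonedOntology <- function(ontology) {
  if (is(ontology, "ReasonedOntology")) return(ontology)
  stopifnot(is(ontology, "Ontology"))
  new("ReasonedOntology", ontology = ontology,
      cache = new.env(parent = emptyenv()))
}

.roEnsureState <- function(ro) {
  cache <- ro@cache
  if (is.null(cache$state)) {
    filtered <- filterToEL(ro@ontology)$ontology
    cache$norm <- normalizeOntology(filtered)
    cache$state <- saturate(cache$norm)
    cache$filtered <- filtered
  }
  cache$state
}

.roLabelIndex <- function(ro) {
  cache <- ro@cache
  if (is.null(cache$labelIndex))
    cache$labelIndex <- buildLabelIndex(ro@ontology)
  cache$labelIndex
}

setMethod("show", "ReasonedOntology", function(object) {
  cat("ReasonedOntology (", if (is.null(object@cache$state)) "not yet"
      else "", " classified)\n", sep = "")
  show(object@ontology)
})

# Entailed named subsumption pairs (incl. reflexive) from a saturation,
# projected onto the original named classes.
.satNamedPairs <- function(state) {
  st <- state@env
  origIds <- which(st$isOrig)
  iris <- st$classTable
  subs <- character(0); sups <- character(0)
  allNamed <- iris[origIds]
  for (a in origIds) {
    Sa <- .lget(st$S, a)
    bs <- if (st$inconsistent || .BOT %in% Sa) allNamed
          else iris[Sa[st$isOrig[Sa]]]
    subs <- c(subs, rep(iris[a], length(bs)))
    sups <- c(sups, bs)
  }
  m <- cbind(sub = subs, sup = sups)
  m[order(m[, 1L], m[, 2L], method = "radix"), , drop = FALSE]
}

#' Classify an ontology
#'
#' Applies the EL filter, normalizes, saturates, and arranges the entailed
#' named subsumptions as a taxonomy. Subsumptions involving normalization
#' fresh names are projected out. An inconsistent ontology yields
#' \code{consistent = FALSE} with every named class unsatisfiable.
#'
#' @param ontology an \code{Ontology} or \code{ReasonedOntology}.
#' @return a \code{Taxonomy}.
#' @export
classify <- function(ontology) {
  ro <- reasonedOntology(ontology)
  cache <- ro@cache
  if (!is.null(cache$taxonomy)) return(cache$taxonomy)
  state <- .roEnsureState(ro)
  st <- state@env
  origIds <- which(st$isOrig)
  iris <- st$classTable

  unsat <- vapply(origIds, function(a)
    st$inconsistent || .BOT %in% .lget(st$S, a), logical(1))
  unsatIRIs <- sort(iris[origIds[unsat]])
  satIds <- origIds[!unsat]

  # strict named subsumers (equivalents included) per satisfiable class
  subsumers <- list()
  for (a in satIds) {
    Sa <- .lget(st$S, a)
    Sa <- Sa[st$isOrig[Sa] & Sa != a]
    subsumers[[iris[a]]] <- sort(iris[Sa])
  }

  # equivalence groups: mutual subsumption
  groupOf <- character(0)
  groups <- list()
  for (a in satIds) {
    ia <- iris[a]
    Sa <- .lget(st$S, a)
    eq <- Sa[st$isOrig[Sa]]
    eq <- eq[vapply(eq, function(b) a %in% .lget(st$S, b), logical(1))]
    members <- sort(iris[eq])
    rep <- members[1L]
    groupOf[ia] <- rep
    if (is.null(groups[[rep]])) groups[[rep]] <- members
  }

  # direct edges: transitive reduction over group representatives
  reps <- sort(names(groups))
  repSups <- lapply(reps, function(g) {
    s <- subsumers[[g]]
    unique(groupOf[s[groupOf[s] != g]])
  })
  names(repSups) <- reps
  children <- character(0); parents <- character(0)
  for (g in reps) {
    sups <- repSups[[g]]
    for (p in sups) {
      inter <- any(vapply(setdiff(sups, p), function(q) p %in% repSups[[q]],
                          logical(1)))
      if (!inter) {
        children <- c(children, g)
        parents <- c(parents, p)
      }
    }
  }
  edges <- cbind(child = children, parent = parents)
  if (length(children))
    edges <- edges[order(children, parents, method = "radix"), , drop = FALSE]

  tax <- new("Taxonomy", groups = groups[reps], directEdges = edges,
             unsatisfiable = unsatIRIs,
             consistent = !st$inconsistent, subsumers = subsumers)
  cache$taxonomy <- tax
  tax
}

#' All entailed named subsumption pairs
#'
#' The full (reflexive, transitive) entailed subsumption relation over the
#' ontology's named classes — the same relation [bruteForceOracle()]
#' computes independently.
#'
#' @param ontology an \code{Ontology} or \code{ReasonedOntology}.
#' @return two-column character matrix (\code{sub}, \code{sup}), sorted.
#' @export
entailedSubsumptions <- function(ontology) {
  ro <- reasonedOntology(ontology)
  .satNamedPairs(.roEnsureState(ro))
}

#' Decide an expression-level subsumption
#'
#' Tests whether the ontology entails \code{sub} \eqn{\sqsubseteq}
#' \code{sup} by inserting fresh query classes equivalent to the two
#' expressions into the cached saturation, extending the fixpoint
#' incrementally, and rolling the insertion back afterwards.
#'
#' @param ontology an \code{Ontology} or \code{ReasonedOntology}.
#' @param sub,sup EL class expressions (\code{ClassExpr}).
#' @return logical.
#' @examples
#' A <- ceNamed("http://ex.org/A"); B <- ceNamed("http://ex.org/B")
#' O <- Ontology(list(subClassOf(A, B)))
#' entailsSubsumption(O, A, B)
#' @export
entailsSubsumption <- function(ontology, sub, sup) {
  stopifnot(inherits(sub, "ClassExpr"), inherits(sup, "ClassExpr"))
  ro <- reasonedOntology(ontology)
  st <- .roEnsureState(ro)@env
  mark <- .satMark(st)
  on.exit(.satRollback(st, mark))
  qsub <- .satInsertExpr(st, sub)
  qsup <- .satInsertExpr(st, sup)
  st$inconsistent || qsup %in% .lget(st$S, qsub) || .BOT %in% .lget(st$S, qsub)
}

setMethod("show", "Taxonomy", function(object) {
  cat("Taxonomy:", length(object@groups), "equivalence groups,",
      nrow(object@directEdges), "direct edges,",
      length(object@unsatisfiable), "unsatisfiable,",
      if (object@consistent) "consistent" else "INCONSISTENT", "\n")
})

#' Taxonomy accessors
#'
#' @param x a \code{Taxonomy}.
#' @name Taxonomy-accessors
NULL

#' @describeIn Taxonomy-accessors equivalence groups (list of sorted
#'   character vectors keyed by representative).
#' @export
taxonomyGroups <- function(x) x@groups

#' @describeIn Taxonomy-accessors direct subsumption edges between group
#'   representatives (character matrix with columns child, parent).
#' @export
taxonomyDirectEdges <- function(x) x@directEdges

#' @describeIn Taxonomy-accessors unsatisfiable named classes.
#' @export
taxonomyUnsatisfiable <- function(x) x@unsatisfiable

#' @describeIn Taxonomy-accessors consistency flag.
#' @export
taxonomyConsistent <- function(x) x@consistent
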