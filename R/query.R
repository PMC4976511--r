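# Query execution: subclass / superclass / equivalent queries over a
# classified ontology, answered from the saturation by inserting a fresh
# query class (rolled back afterwards) and timed around engine evaluation
# only — parsing and any transport are excluded from the reported time.

QUERY_MODES <- c("subclasses", "superclasses", "equivalents")

#' Execute a class-expression query
#'
#' Returns all (not only direct) answers: \code{subclasses} are the named
#' classes strictly subsumed by the expression, \code{superclasses} the
#' named classes strictly subsuming it, and \code{equivalents} the named
#' classes mutually subsuming with it. The query's own equivalence class is
#' excluded from the two strict modes, so the three modes partition the
#' classes related to the query. Answers never contain normalization fresh
#' names, top, or bottom.
#'
#' @param ontology an \code{Ontology} or \code{ReasonedOntology}
#'   (classification is computed lazily and cached on the latter).
#' @param expression a \code{ClassExpr} (e.g. from [parseQuery()]).
#' @param mode one of \code{"subclasses"}, \code{"superclasses"},
#'   \code{"equivalents"}.
#' @return a \code{QueryResult}: list with \code{mode}, \code{expression},
#'   \code{answers} (character IRIs, sorted), \code{labels} (display labels
#'   for the answers), \code{executionTimeMs}, \code{satisfiableQuery}.
#' @section Errors: \code{elrepo_inconsistent_ontology} if the ontology is
#'   inconsistent.
#' @export
executeQuery <- function(ontology, expression, mode = QUERY_MODES) {
  mode <- match.arg(mode)
  stopifnot(inherits(expression, "ClassExpr"))
  ro <- reasonedOntology(ontology)
  st <- .roEnsureState(ro)@env
  if (st$inconsistent)
    .elStop("elrepo_inconsistent_ontology",
            "cannot query an inconsistent ontology")

  t0 <- proc.time()[["elapsed"]]
  mark <- .satMark(st)
  qid <- .satInsertExpr(st, expression)
  Sq <- .lget(st$S, qid)
  qUnsat <- .BOT %in% Sq
  iris <- st$classTable

  entailsBelowQ <- function(ids) { # ids a: a <= query?
    ids[vapply(ids, function(a) qid %in% .lget(st$S, a) ||
                 .BOT %in% .lget(st$S, a), logical(1))]
  }
  aboveQ <- if (qUnsat) which(st$isOrig) else Sq[st$isOrig[Sq]]
  belowQ <- entailsBelowQ(unique(c(.lget(st$revS, qid),
                                   .lget(st$revS, .BOT))))
  belowQ <- belowQ[st$isOrig[belowQ]]
  eq <- intersect(aboveQ, belowQ)
  answers <- switch(mode,
    subclasses   = setdiff(belowQ, eq),
    superclasses = setdiff(aboveQ, eq),
    equivalents  = eq)
  answers <- sort(iris[answers])
  .satRollback(st, mark)
  dt <- (proc.time()[["elapsed"]] - t0) * 1000

  idx <- .roLabelIndex(ro)
  structure(list(mode = mode, expression = expression, answers = answers,
                 labels = labelsFor(idx, answers),
                 executionTimeMs = dt, satisfiableQuery = !qUnsat),
            class = "QueryResult")
}

#' @export
print.QueryResult <- function(x, ...) {
  cat(sprintf("QueryResult [%s] %s\n", x$mode, format(x$expression)))
  cat(sprintf("  %d answers in %.2f ms%s\n", length(x$answers),
              x$executionTimeMs,
              if (x$satisfiableQuery) "" else " (unsatisfiable query)"))
  if (length(x$answers)) {
    shown <- utils::head(x$answers, 8L)
    lab <- x$labels[shown]
    cat(paste0("  - <", shown, ">",
               ifelse(is.na(lab), "", paste0(" \"", lab, "\"")),
               collapse = "\n"), "\n")
    if (length(x$answers) > 8L)
      cat("  ... and", length(x$answers) - 8L, "more\n")
  }
  invisible(x)
}

#' Parse and execute a Manchester query in one call
#'
#' @inheritParams executeQuery
#' @param text Manchester-syntax query string.
#' @return a \code{QueryResult} (timing covers evaluation only, not the
#'   parse).
#' @export
answerQuery <- function(ontology, text, mode = QUERY_MODES) {
  ro <- reasonedOntology(ontology)
  expr <- parseQuery(text, .roLabelIndex(ro))
  executeQuery(ro, expr, mode)
}
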