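# Multi-ontology repository: load-outcome accounting, aggregate statistics,
# query-all. Load statuses mirror the repository life cycle: a file that
# fails the parser is non-parseable; a parsed ontology that saturates to an
# inconsistency is inconsistent; a consistent ontology without any class
# label cannot be queried by label and is set aside; everything else is
# "used" and queryable.

#' Load ontologies into a repository
#'
#' Each file is parsed, filtered to EL, and saturated. Per-file failures
#' never abort the load; they are recorded as statuses. The resulting
#' report satisfies \code{total = nonParseable + loadable} and
#' \code{used = loadable - inconsistent - noLabels}.
#'
#' @param paths character vector of \code{.ofn} file paths.
#' @param preclassify if \code{TRUE} (default), saturation is computed at
#'   load; if \code{FALSE}, consistency/label checks still run but the
#'   saturation of used ontologies is dropped and recomputed lazily on
#'   first query.
#' @return an \code{OntologyRepository}.
#' @export
loadOntologies <- function(paths, preclassify = TRUE) {
  entries <- list()
  statuses <- list()
  nParse <- 0L; nIncons <- 0L; nNoLab <- 0L
  for (path in paths) {
    nm <- basename(path)
    parsed <- tryCatch(readOntology(path), elrepo_parse_error = function(e) e)
    if (inherits(parsed, "condition")) {
      nParse <- nParse + 1L
      statuses[[nm]] <- list(status = "non-parseable",
                             message = conditionMessage(parsed))
      next
    }
    ont <- parsed$ontology
    ro <- reasonedOntology(ont)
    state <- .roEnsureState(ro)
    if (!isConsistent(state)) {
      nIncons <- nIncons + 1L
      statuses[[nm]] <- list(status = "inconsistent", message = "")
      next
    }
    stats <- computeStats(ont)
    if (stats$labeledClassCount == 0L) {
      nNoLab <- nNoLab + 1L
      statuses[[nm]] <- list(status = "no-labels", message = "")
      next
    }
    if (!preclassify) {
      ro <- reasonedOntology(ont)  # fresh cache; recomputed on first query
    }
    statuses[[nm]] <- list(status = "used", message = "")
    entries[[nm]] <- list(reasoned = ro, stats = stats,
                          contentHash = unname(tools::md5sum(path)))
  }
  total <- length(paths)
  report <- list(
    total = total,
    loadable = total - nParse,
    nonParseable = nParse,
    inconsistent = nIncons,
    noLabels = nNoLab,
    used = total - nParse - nIncons - nNoLab,
    perOntology = statuses
  )
  new("OntologyRepository", entries = entries, loadReport = report)
}

#' @describeIn loadOntologies the load-outcome report of a repository.
#' @param repo an \code{OntologyRepository}.
#' @export
loadReport <- function(repo) repo@loadReport

#' Names of the queryable ("used") ontologies
#' @param repo an \code{OntologyRepository}.
#' @return character vector.
#' @export
usedOntologies <- function(repo) names(repo@entries)

#' Retrieve a loaded ontology by name
#' @param repo an \code{OntologyRepository}.
#' @param name source name (file name) of a used ontology.
#' @return a \code{ReasonedOntology}.
#' @export
repoOntology <- function(repo, name) {
  e <- repo@entries[[name]]
  if (is.null(e))
    .elStop("elrepo_unknown_ontology",
            sprintf("no used ontology named '%s' in the repository", name))
  e$reasoned
}

#' Query every ontology in the repository
#'
#' Parses and executes the query against each used ontology. Ontologies
#' where a label does not resolve return an empty result flagged
#' \code{labelNotFound} instead of failing the whole call.
#'
#' @param repo an \code{OntologyRepository} with at least one used ontology.
#' @param text Manchester-syntax query string.
#' @param mode query mode (see [executeQuery()]).
#' @return named list, ontology name -> \code{QueryResult} or a
#'   label-not-found marker (list with \code{labelNotFound = TRUE}).
#' @export
queryAll <- function(repo, text, mode = QUERY_MODES) {
  mode <- match.arg(mode)
  if (!length(repo@entries))
    .elStop("elrepo_empty_repository", "repository has no used ontologies")
  out <- list()
  for (nm in names(repo@entries)) {
    ro <- repo@entries[[nm]]$reasoned
    out[[nm]] <- tryCatch(
      answerQuery(ro, text, mode),
      elrepo_unknown_label = function(e)
        list(labelNotFound = TRUE, answers = character(0),
             message = conditionMessage(e))
    )
  }
  out
}

#' Aggregate statistics over the used ontologies
#'
#' Element-wise sums of the per-ontology statistics; the axiom-type
#' histogram is summed by type.
#'
#' @param repo an \code{OntologyRepository}.
#' @return an \code{OntologyStats}.
#' @export
aggregateStats <- function(repo) {
  agg <- list(classCount = 0L, objectPropertyCount = 0L,
              logicalAxiomCount = 0L, rboxAxiomCount = 0L,
              axiomTypeHistogram = stats::setNames(integer(0), character(0)),
              labeledClassCount = 0L)
  for (e in repo@entries) {
    s <- e$stats
    for (f in c("classCount", "objectPropertyCount", "logicalAxiomCount",
                "rboxAxiomCount", "labeledClassCount"))
      agg[[f]] <- agg[[f]] + s[[f]]
    for (k in names(s$axiomTypeHistogram))
      agg$axiomTypeHistogram[k] <-
        (if (k %in% names(agg$axiomTypeHistogram))
           agg$axiomTypeHistogram[[k]] else 0L) + s$axiomTypeHistogram[[k]]
  }
  structure(agg, class = "OntologyStats")
}

#' Approximate memory footprint of a classified ontology
#'
#' Instrumentation only: the object sizes of the cached normalization and
#' saturation structures, in bytes.
#'
#' @param ro a \code{ReasonedOntology}.
#' @return numeric (bytes).
#' @export
stateFootprint <- function(ro) {
  stopifnot(is(ro, "ReasonedOntology"))
  st <- .roEnsureState(ro)@env
  tot <- 0
  for (nm in ls(st)) tot <- tot + as.numeric(utils::object.size(st[[nm]]))
  tot
}

setMethod("show", "OntologyRepository", function(object) {
  r <- object@loadReport
  cat("OntologyRepository:", r$used, "used /", r$total, "total",
      sprintf("(non-parseable %d, inconsistent %d, no labels %d)\n",
              r$nonParseable, r$inconsistent, r$noLabels))
})
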