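# Randomized query benchmark: seeded generation of fresh class expressions
# over an ontology's labeled signature (four template types), a seeded
# three-way mode partition, a bounded-concurrency executor, and correlation
# analysis of per-query times against ontology size and parallelism.

QUERY_TEMPLATES <- c("primitive", "conjunctive", "existential",
                     "conjunctiveExistential")

.labeledSignature <- function(ontology) {
  idx <- if (is(ontology, "ReasonedOntology")) .roLabelIndex(ontology)
         else buildLabelIndex(ontology)
  iris <- names(idx@byIRI)
  list(classes = sort(iris[idx@kind[iris] == "class"]),
       roles = sort(iris[idx@kind[iris] == "objectProperty"]))
}

#' Generate random benchmark queries
#'
#' Draws \code{nPerType} class expressions for each of the four query
#' templates — a primitive class \code{A}, a conjunction \code{A and B}, an
#' existential \code{R some A}, and a conjunctive existential
#' \code{A and R some B} — with classes and properties sampled uniformly
#' from the ontology's labeled signature. All generated expressions are
#' pairwise distinct (by canonical form), so a reasoner cache of previously
#' answered expressions can never be hit; duplicates are rejection-sampled
#' away with a cap of \code{100 * nPerType} draws per template. Fully
#' deterministic for a given (ontology, \code{nPerType}, \code{seed}).
#'
#' In conjunctive templates the two classes are required distinct
#' (\code{A and A} is degenerate and \code{A and B} equals \code{B and A}
#' after canonicalization).
#'
#' @param ontology an \code{Ontology} or \code{ReasonedOntology} with at
#'   least 2 labeled classes (existential templates additionally need a
#'   labeled object property).
#' @param nPerType queries per template (default 300, i.e. 1200 in total).
#' @param seed integer seed.
#' @param lenient if \code{TRUE}, existential templates are skipped with a
#'   warning when no labeled property exists, instead of erroring.
#' @return list of records, each \code{list(template, expression)}.
#' @export
generateRandomQueries <- function(ontology, nPerType = 300L, seed = 1L,
                                  lenient = FALSE) {
  stopifnot(nPerType >= 1L)
  sig <- .labeledSignature(ontology)
  cls <- sig$classes; rls <- sig$roles
  if (length(cls) < 2L)
    .elStop("elrepo_insufficient_signature",
            "need at least 2 labeled classes to generate queries")
  templates <- QUERY_TEMPLATES
  if (!length(rls)) {
    if (!lenient)
      .elStop("elrepo_insufficient_signature",
              "existential templates need a labeled object property")
    warning("no labeled object property: skipping existential templates")
    templates <- c("primitive", "conjunctive")
  }
  .withSeed(seed, {
    out <- vector("list", nPerType * length(templates))
    k <- 0L
    for (tmpl in templates) {
      seen <- new.env(parent = emptyenv())
      made <- 0L; draws <- 0L
      while (made < nPerType) {
        draws <- draws + 1L
        if (draws > 100L * nPerType)
          .elStop("elrepo_insufficient_signature",
                  sprintf("template '%s': distinct expressions exhausted after %d draws",
                          tmpl, draws - 1L))
        expr <- switch(tmpl,
          primitive = ceNamed(sample(cls, 1L)),
          conjunctive = {
            ab <- sample(cls, 2L)
            ceAnd(ceNamed(ab[1L]), ceNamed(ab[2L]))
          },
          existential = ceSome(sample(rls, 1L), ceNamed(sample(cls, 1L))),
          conjunctiveExistential = ceAnd(
            ceNamed(sample(cls, 1L)),
            ceSome(sample(rls, 1L), ceNamed(sample(cls, 1L))))
        )
        if (tmpl == "conjunctiveExistential" && expr$type != "and") next
        key <- ceKey(expr)
        if (!is.null(get0(key, envir = seen, inherits = FALSE))) next
        assign(key, TRUE, envir = seen)
        made <- made + 1L; k <- k + 1L
        out[[k]] <- list(template = tmpl, expression = expr)
      }
    }
    out[seq_len(k)]
  })
}

#' Partition a query set over the three query modes
#'
#' Per template, shuffles the queries with the given seed and splits them
#' into three equal subsets assigned to superclass, equivalent and subclass
#' queries. The union of the subsets is the input set and the subsets are
#' disjoint.
#'
#' @param queries output of [generateRandomQueries()].
#' @param seed integer seed for the shuffle.
#' @return named list \code{superclasses}/\code{equivalents}/\code{subclasses},
#'   each a list of query records.
#' @export
partitionQuerySet <- function(queries, seed = 1L) {
  tmpl <- vapply(queries, `[[`, character(1), "template")
  out <- list(superclasses = list(), equivalents = list(), subclasses = list())
  .withSeed(seed, {
    for (tt in unique(tmpl)) {
      idx <- which(tmpl == tt)
      if (length(idx) %% 3L != 0L)
        .elStop("elrepo_partition_error",
                sprintf("template '%s' has %d queries, not divisible by 3",
                        tt, length(idx)))
      idx <- sample(idx)
      third <- length(idx) / 3L
      out$superclasses <- c(out$superclasses, queries[idx[seq_len(third)]])
      out$equivalents <- c(out$equivalents,
                           queries[idx[third + seq_len(third)]])
      out$subclasses <- c(out$subclasses,
                          queries[idx[2L * third + seq_len(third)]])
    }
  })
  out
}

#' Run the query benchmark
#'
#' Executes a partitioned query plan against one or more repository
#' ontologies at each configured parallelism level. The executor dispatches
#' at most \code{k} queries per batch; within a batch, each record's
#' \code{executionTimeMs} is the engine-side evaluation time of that query
#' alone, while \code{responseTimeMs} is measured from batch dispatch to
#' that query's completion and therefore includes queue wait — the
#' repository-side analogue of a response time that excludes network
#' latency. Individual query failures are recorded (\code{failed = TRUE})
#' and the run continues.
#'
#' @param repo an \code{OntologyRepository}.
#' @param plans named list: ontology name (a used ontology of \code{repo})
#'   -> partitioned plan from [partitionQuerySet()].
#' @param parallelismLevels integer vector of in-flight levels
#'   (default \code{c(1, 100, 1000)}).
#' @param keepAnswers also record an \code{answerKey} column (the sorted
#'   answer IRIs collapsed to one string), so answer sets can be compared
#'   across parallelism levels.
#' @return data.frame with columns \code{ontologyName}, \code{template},
#'   \code{mode}, \code{parallelism}, \code{executionTimeMs},
#'   \code{responseTimeMs}, \code{answerCount}, \code{failed} (and
#'   \code{answerKey} if requested).
#' @export
runBenchmark <- function(repo, plans, parallelismLevels = c(1L, 100L, 1000L),
                         keepAnswers = FALSE) {
  stopifnot(is(repo, "OntologyRepository"), length(plans) >= 1L,
            !is.null(names(plans)))
  rows <- list()
  for (nm in names(plans)) {
    ro <- repoOntology(repo, nm)
    .roEnsureState(ro)
    plan <- plans[[nm]]
    flat <- list()
    for (mode in names(plan))
      for (q in plan[[mode]])
        flat[[length(flat) + 1L]] <- list(mode = mode, q = q)
    for (k in parallelismLevels) {
      i <- 1L
      while (i <= length(flat)) {
        batch <- flat[seq.int(i, min(i + k - 1L, length(flat)))]
        t0 <- proc.time()[["elapsed"]]
        for (item in batch) {
          res <- tryCatch(
            executeQuery(ro, item$q$expression, item$mode),
            elrepo_error = function(e) e)
          tNow <- proc.time()[["elapsed"]]
          ok <- inherits(res, "QueryResult")
          row <- data.frame(
            ontologyName = nm,
            template = item$q$template,
            mode = item$mode,
            parallelism = k,
            executionTimeMs = if (ok) res$executionTimeMs else NA_real_,
            responseTimeMs = (tNow - t0) * 1000,
            answerCount = if (ok) length(res$answers) else NA_integer_,
            failed = !ok,
            stringsAsFactors = FALSE)
          if (keepAnswers)
            row$answerKey <- if (ok) paste(res$answers, collapse = "|")
                             else NA_character_
          rows[[length(rows) + 1L]] <- row
        }
        i <- i + k
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize benchmark records
#'
#' Means and standard deviations per (ontology, template, mode,
#' parallelism) stratum, plus two product-moment correlations: engine
#' execution time against the ontology's logical axiom count, and response
#' time against the parallelism level. A correlation whose axis is constant
#' is flagged undefined and reported as \code{NA}.
#'
#' @param records data.frame from [runBenchmark()].
#' @param statsPerOntology named list: ontology name -> \code{OntologyStats}
#'   (or any list with \code{logicalAxiomCount}).
#' @return a \code{BenchmarkSummary}: list with \code{perStratum}
#'   (data.frame of \code{meanMs}/\code{sdMs}), \code{pearsonTimeVsAxioms},
#'   \code{pearsonTimeVsParallelism}, \code{undefinedCorrelations}
#'   (character vector).
#' @export
analyzeBenchmark <- function(records, statsPerOntology) {
  stopifnot(is.data.frame(records), nrow(records) >= 2L)
  ok <- records[!records$failed, , drop = FALSE]
  per <- stats::aggregate(
    cbind(meanMs = executionTimeMs) ~ ontologyName + template + mode + parallelism,
    data = ok, FUN = mean)
  persd <- stats::aggregate(
    cbind(sdMs = executionTimeMs) ~ ontologyName + template + mode + parallelism,
    data = ok, FUN = stats::sd)
  per <- merge(per, persd,
               by = c("ontologyName", "template", "mode", "parallelism"))

  undef <- character(0)
  axioms <- vapply(ok$ontologyName, function(nm)
    as.numeric(statsPerOntology[[nm]]$logicalAxiomCount), numeric(1))
  rAx <- if (length(unique(axioms)) < 2L ||
             length(unique(ok$executionTimeMs)) < 2L) {
    undef <- c(undef, "timeVsAxioms"); NA_real_
  } else stats::cor(ok$executionTimeMs, axioms)
  rPar <- if (length(unique(ok$parallelism)) < 2L ||
              length(unique(ok$responseTimeMs)) < 2L) {
    undef <- c(undef, "timeVsParallelism"); NA_real_
  } else stats::cor(ok$responseTimeMs, as.numeric(ok$parallelism))
  structure(list(perStratum = per, pearsonTimeVsAxioms = rAx,
                 pearsonTimeVsParallelism = rPar,
                 undefinedCorrelations = undef),
            class = "BenchmarkSummary")
}

#' @export
print.BenchmarkSummary <- function(x, ...) {
  cat("BenchmarkSummary:", nrow(x$perStratum), "strata\n")
  cat(sprintf("  Pearson r (exec time vs logical axioms):  %s\n",
              format(x$pearsonTimeVsAxioms, digits = 3)))
  cat(sprintf("  Pearson r (response time vs parallelism): %s\n",
              format(x$pearsonTimeVsParallelism, digits = 3)))
  if (length(x$undefinedCorrelations))
    cat("  undefined:", paste(x$undefinedCorrelations, collapse = ", "), "\n")
  invisible(x)
}
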