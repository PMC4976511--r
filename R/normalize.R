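# EL normalization: rewrite filtered axioms into the four GCI normal forms
#   NF1  A \subseteq B        NF2  A1 n A2 \subseteq B
#   NF3  A \subseteq Er.B     NF4  Er.A \subseteq B
# plus a role normal form (chains of length 1 or 2), introducing fresh class
# names for complex subexpressions. Identical subexpressions share one fresh
# name (hash-consing); each definitional direction is emitted at most once.
# The result is a conservative extension over the original signature.
#
# The same rewriting core is reused at query time to push a fresh query
# class into a live saturation state, so the emit functions are pluggable.

.FRESH_NS <- "urn:normform:"

.normCtx <- function(emitNF1, emitNF2, emitNF3, emitNF4,
                     counterStart = 0L) {
  ctx <- new.env(parent = emptyenv())
  ctx$counter <- as.integer(counterStart)
  ctx$defined <- new.env(parent = emptyenv())   # expr key -> fresh IRI
  ctx$dirs <- new.env(parent = emptyenv())      # "<iri>|pos/neg" -> TRUE
  ctx$freshNameMap <- list()                    # fresh IRI -> ClassExpr
  ctx$onNewFresh <- NULL                        # hook for journaling
  ctx$onDirEmitted <- NULL
  ctx$nf1 <- emitNF1; ctx$nf2 <- emitNF2; ctx$nf3 <- emitNF3
  ctx$nf4 <- emitNF4
  ctx
}

.ctxFreshIRI <- function(ctx, key, expr) {
  iri <- get0(key, envir = ctx$defined, inherits = FALSE)
  if (!is.null(iri)) return(iri)
  ctx$counter <- ctx$counter + 1L
  iri <- paste0(.FRESH_NS, ctx$counter)
  assign(key, iri, envir = ctx$defined)
  ctx$freshNameMap[[iri]] <- expr
  if (!is.null(ctx$onNewFresh)) ctx$onNewFresh(key, iri)
  iri
}

# Name a complex expression, emitting its definitional GCI in the required
# direction: "neg" emits expr <= X (for use of X on the left of a GCI),
# "pos" emits X <= expr (for use on the right).
.ctxNameFor <- function(ctx, expr, dir) {
  nm <- switch(expr$type, named = expr$iri, top = OWL_THING,
               bottom = OWL_NOTHING, NULL)
  if (!is.null(nm)) return(nm)
  key <- ceKey(expr)
  iri <- .ctxFreshIRI(ctx, key, expr)
  dkey <- paste0(iri, "|", dir)
  if (is.null(get0(dkey, envir = ctx$dirs, inherits = FALSE))) {
    assign(dkey, TRUE, envir = ctx$dirs)
    if (!is.null(ctx$onDirEmitted)) ctx$onDirEmitted(dkey)
    if (dir == "neg") .normGCI(ctx, expr, ceNamed(iri))
    else .normGCI(ctx, ceNamed(iri), expr)
  }
  iri
}

.normGCI <- function(ctx, sub, sup) {
  if (sup$type == "and") {
    for (op in sup$ops) .normGCI(ctx, sub, op)
    return(invisible())
  }
  if (sup$type == "top") return(invisible())    # tautology
  if (sub$type == "bottom") return(invisible()) # vacuous
  subAtomic <- sub$type %in% c("named", "top")
  supAtomic <- sup$type %in% c("named", "bottom")

  if (supAtomic) {
    supName <- if (sup$type == "bottom") OWL_NOTHING else sup$iri
    if (subAtomic) {
      ctx$nf1(if (sub$type == "top") OWL_THING else sub$iri, supName)
    } else if (sub$type == "and") {
      opNames <- sort(vapply(sub$ops, .ctxNameFor, character(1),
                             ctx = ctx, dir = "neg"))
      cur <- opNames[1L]
      n <- length(opNames)
      if (n >= 3L) for (i in 2L:(n - 1L)) {
        # partial conjunction gets its own (hash-consed) fresh name
        pkey <- paste0("P(", cur, "&", opNames[i], ")")
        w <- .ctxFreshIRI(ctx, pkey,
                          ceAnd(ceNamed(cur), ceNamed(opNames[i])))
        ctx$nf2(cur, opNames[i], w)
        cur <- w
      }
      ctx$nf2(cur, opNames[n], supName)
    } else { # existential on the left
      f <- .ctxNameFor(ctx, sub$filler, "neg")
      ctx$nf4(sub$role, f, supName)
    }
    return(invisible())
  }

  # sup is an existential restriction
  if (subAtomic) {
    subName <- if (sub$type == "top") OWL_THING else sub$iri
    f <- .ctxNameFor(ctx, sup$filler, "pos")
    ctx$nf3(subName, sup$role, f)
  } else {
    # both sides complex: split through a fresh intermediate name
    x <- .ctxNameFor(ctx, sub, "neg")
    .normGCI(ctx, ceNamed(x), sup)
  }
  invisible()
}

.normClassAxiom <- function(ctx, ax) {
  switch(ax$kind,
    SubClassOf = .normGCI(ctx, ax$sub, ax$sup),
    EquivalentClasses = {
      # star expansion around the first member; transitivity recovers the rest
      first <- ax$members[[1L]]
      for (m in ax$members[-1L]) {
        .normGCI(ctx, first, m)
        .normGCI(ctx, m, first)
      }
    },
    DisjointClasses = {
      n <- length(ax$members)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        .normGCI(ctx, ceAnd(ax$members[[i]], ax$members[[j]]), ceBottom())
    }
  )
  invisible()
}

.normRoleAxioms <- function(axioms) {
  out <- list()
  for (ax in axioms) {
    if (ax$kind == "SubObjectPropertyOf") {
      if (length(ax$subChain) > 2L)
        .elStop("elrepo_normalization_error",
                sprintf("role chain of length %d not supported (max 2)",
                        length(ax$subChain)))
      out[[length(out) + 1L]] <- list(subChain = ax$subChain, sup = ax$sup)
    } else if (ax$kind == "EquivalentObjectProperties") {
      first <- ax$members[1L]
      for (m in ax$members[-1L]) {
        out[[length(out) + 1L]] <- list(subChain = first, sup = m)
        out[[length(out) + 1L]] <- list(subChain = m, sup = first)
      }
    }
  }
  out
}

#' Normalize an EL ontology for saturation
#'
#' Expands \code{EquivalentClasses} into mutual inclusions and
#' \code{DisjointClasses} pairwise into inclusions of bottom, then
#' decomposes complex expressions into the four GCI normal forms by
#' introducing fresh class names in a reserved namespace
#' (\code{urn:normform:N}). Fresh names are assigned in a stable traversal
#' order and identical subexpressions share a name, so the output is fully
#' deterministic for a given input. Role chains longer than 2 raise a
#' normalization error.
#'
#' The ontology should already be within the EL fragment (pass it through
#' [filterToEL()]); \code{Unsupported} axioms, declarations and annotations
#' are ignored here.
#'
#' @param ontology an \code{Ontology}.
#' @return a \code{NormalizedOntology}.
#' @export
normalizeOntology <- function(ontology) {
  stopifnot(is(ontology, "Ontology"))
  sig <- signatureOf(ontology)
  if (any(startsWith(sig$classIRIs, .FRESH_NS)))
    .elStop("elrepo_normalization_error",
            "input signature collides with the reserved fresh-name namespace")
  nf1 <- list(); nf2 <- list(); nf3 <- list(); nf4 <- list()
  ctx <- .normCtx(
    function(a, b) nf1[[length(nf1) + 1L]] <<- c(a, b),
    function(a1, a2, b) nf2[[length(nf2) + 1L]] <<- c(a1, a2, b),
    function(a, r, b) nf3[[length(nf3) + 1L]] <<- c(a, r, b),
    function(r, a, b) nf4[[length(nf4) + 1L]] <<- c(r, a, b)
  )
  logical <- Filter(.isLogicalAxiom, ontology@axioms)
  for (ax in logical) .normClassAxiom(ctx, ax)
  roleNFStr <- .normRoleAxioms(logical)

  fresh <- names(ctx$freshNameMap)
  classTable <- c(OWL_THING, OWL_NOTHING, sig$classIRIs, fresh)
  roleIRIs <- unique(c(sig$roleIRIs,
                       unlist(lapply(roleNFStr, function(x) c(x$subChain, x$sup)))))
  roleTable <- sort(roleIRIs)
  cid <- function(x) match(x, classTable)
  rid <- function(x) match(x, roleTable)
  toMat <- function(lst, ncol) {
    if (!length(lst)) return(matrix(integer(0), ncol = ncol))
    do.call(rbind, lst)
  }
  m1 <- toMat(lapply(nf1, function(x) cid(x)), 2L)
  m2 <- toMat(lapply(nf2, function(x) cid(x)), 3L)
  m3 <- toMat(lapply(nf3, function(x) c(cid(x[1L]), rid(x[2L]), cid(x[3L]))), 3L)
  m4 <- toMat(lapply(nf4, function(x) c(rid(x[1L]), cid(x[2L]), cid(x[3L]))), 3L)
  roleNF <- lapply(roleNFStr, function(x)
    list(subChain = rid(x$subChain), sup = rid(x$sup)))
  new("NormalizedOntology",
      classTable = classTable, roleTable = roleTable,
      nf1 = m1, nf2 = m2, nf3 = m3, nf4 = m4,
      roleNF = roleNF, freshNameMap = ctx$freshNameMap,
      origClassIRIs = sig$classIRIs)
}

setMethod("show", "NormalizedOntology", function(object) {
  cat("NormalizedOntology:",
      length(object@origClassIRIs), "named classes,",
      length(object@freshNameMap), "fresh names,",
      length(object@roleTable), "roles\n")
  cat(sprintf("  NF1: %d  NF2: %d  NF3: %d  NF4: %d  role axioms: %d\n",
              nrow(object@nf1), nrow(object@nf2), nrow(object@nf3),
              nrow(object@nf4), length(object@roleNF)))
})
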