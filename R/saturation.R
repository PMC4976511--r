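# Worklist (semi-naive) EL saturation. Completion rules:
#   R1  A' in S(A), (A',B) in NF1            =>  B in S(A)
#   R2  A1,A2 in S(A), (A1,A2,B) in NF2      =>  B in S(A)
#   R3  A' in S(A), (A',r,B) in NF3          =>  (A,B) in R(r)
#   R4  (A,B) in R(r), B' in S(B), (r,B',C) in NF4  =>  C in S(A)
#   Rbot (A,B) in R(r), bot in S(B)          =>  bot in S(A)
#   Rh  (A,B) in R(r), r <= s                =>  (A,B) in R(s)
#   Rc  (A,B) in R(r1), (B,C) in R(r2), r1 o r2 <= s  =>  (A,C) in R(s)
# Saturation always terminates: S and R are bounded by signature^2.
#
# The state is a closure environment: subsumer sets S(.) with a reverse
# index, role-successor relations R(.) indexed by source and target,
# per-name indexes of the normal forms, and a flat integer worklist with a
# tail pointer. All mutators are closures updating local bindings via <<-,
# which R modifies in place — the only representation we found that keeps
# a fixpoint of ~10^5 derivations inside R loops tractable. Every mutation
# can be journaled so a query class is inserted incrementally and rolled
# back, leaving the cached saturation untouched (queries never pollute the
# repository's saturations).

.TOP <- 1L
.BOT <- 2L

.lget <- function(lst, i) {
  if (i > length(lst)) integer(0) else lst[[i]] %||% integer(0)
}

.newSatState <- function(nPrealloc = 0L) {
  n0 <- nPrealloc
  classTable <- character(n0); nClass <- 0L
  idOf <- new.env(parent = emptyenv())
  roleTable <- character(0)
  roleIdOf <- new.env(parent = emptyenv())
  isOrig <- logical(n0)
  S <- vector("list", n0); revS <- vector("list", n0)
  nf1sup <- vector("list", n0)
  nf2other <- vector("list", n0); nf2sup <- vector("list", n0)
  nf3role <- vector("list", n0); nf3tgt <- vector("list", n0)
  nf4fRole <- vector("list", n0); nf4fSup <- vector("list", n0)
  nf4rFiller <- list(); nf4rSup <- list()
  roleParents <- list()
  chainF2 <- list(); chainFS <- list()
  chainS1 <- list(); chainSS <- list()
  Rsrc <- list(); Rtgt <- list()
  qa <- integer(4096); qb <- integer(4096)
  qc <- integer(4096); qd <- integer(4096)
  qtail <- 0L; qhead <- 1L
  journal <- list(); jtail <- 0L; journalOn <- FALSE
  inconsistent <- FALSE
  queryCounter <- 0L
  freshCounter <- 0L
  freshKeyToIRI <- new.env(parent = emptyenv())
  qctx <- NULL

  jpush <- function(entry) {
    jtail <<- jtail + 1L
    if (jtail > length(journal)) length(journal) <<- max(64L, 2L * length(journal))
    journal[[jtail]] <<- entry
    invisible()
  }

  qpush <- function(t, x, y, z) {
    i <- qtail + 1L
    qtail <<- i
    if (i > length(qa)) {
      grow <- length(qa)
      qa <<- c(qa, integer(grow)); qb <<- c(qb, integer(grow))
      qc <<- c(qc, integer(grow)); qd <<- c(qd, integer(grow))
    }
    qa[i] <<- t; qb[i] <<- x; qc[i] <<- y; qd[i] <<- z
    invisible()
  }

  addS <- function(a, b) {
    cur <- if (a > length(S)) NULL else S[[a]]
    if (!is.null(cur) && b %in% cur) return(invisible())
    S[[a]] <<- c(cur, b)
    revS[[b]] <<- c(if (b > length(revS)) NULL else revS[[b]], a)
    if (journalOn) jpush(list(t = "S", a = a, b = b))
    qpush(1L, a, b, 0L)
    invisible()
  }

  addEdge <- function(r, a, b) {
    rs <- Rsrc[[r]]
    cur <- if (a > length(rs)) NULL else rs[[a]]
    if (!is.null(cur) && b %in% cur) return(invisible())
    Rsrc[[r]][[a]] <<- c(cur, b)
    rt <- Rtgt[[r]]
    Rtgt[[r]][[b]] <<- c(if (b > length(rt)) NULL else rt[[b]], a)
    if (journalOn) jpush(list(t = "E", r = r, a = a, b = b))
    qpush(2L, r, a, b)
    invisible()
  }

  ensureClass <- function(iri, orig = FALSE) {
    id <- get0(iri, envir = idOf, inherits = FALSE)
    if (!is.null(id)) return(id)
    id <- nClass + 1L
    nClass <<- id
    classTable[id] <<- iri
    assign(iri, id, envir = idOf)
    isOrig[id] <<- orig
    if (journalOn) jpush(list(t = "class", iri = iri))
    addS(id, id)
    if (id != .TOP) addS(id, .TOP)
    id
  }

  ensureRole <- function(iri) {
    id <- get0(iri, envir = roleIdOf, inherits = FALSE)
    if (!is.null(id)) return(id)
    id <- length(roleTable) + 1L
    roleTable[id] <<- iri
    assign(iri, id, envir = roleIdOf)
    Rsrc[[id]] <<- list(); Rtgt[[id]] <<- list()
    nf4rFiller[[id]] <<- integer(0); nf4rSup[[id]] <<- integer(0)
    if (journalOn) jpush(list(t = "role", iri = iri))
    id
  }

  addNF1 <- function(a, b) {
    cur <- .lget(nf1sup, a)
    if (b %in% cur) return(invisible())
    nf1sup[[a]] <<- c(cur, b)
    if (journalOn) jpush(list(t = "nf1", a = a))
    for (x in .lget(revS, a)) addS(x, b)
    invisible()
  }

  addNF2 <- function(a1, a2, b) {
    o <- .lget(nf2other, a1); s <- .lget(nf2sup, a1)
    if (any(o == a2 & s == b)) return(invisible())
    nf2other[[a1]] <<- c(o, a2); nf2sup[[a1]] <<- c(s, b)
    both <- a1 == a2
    if (!both) {
      nf2other[[a2]] <<- c(.lget(nf2other, a2), a1)
      nf2sup[[a2]] <<- c(.lget(nf2sup, a2), b)
    }
    if (journalOn) jpush(list(t = "nf2", a1 = a1, a2 = a2))
    for (x in .lget(revS, a1))
      if (both || a2 %in% S[[x]]) addS(x, b)
    invisible()
  }

  addNF3 <- function(a, r, b) {
    rv <- .lget(nf3role, a); tv <- .lget(nf3tgt, a)
    if (any(rv == r & tv == b)) return(invisible())
    nf3role[[a]] <<- c(rv, r); nf3tgt[[a]] <<- c(tv, b)
    if (journalOn) jpush(list(t = "nf3", a = a))
    for (x in .lget(revS, a)) addEdge(r, x, b)
    invisible()
  }

  addNF4 <- function(r, f, cc) {
    rv <- .lget(nf4fRole, f); sv <- .lget(nf4fSup, f)
    if (any(rv == r & sv == cc)) return(invisible())
    nf4fRole[[f]] <<- c(rv, r); nf4fSup[[f]] <<- c(sv, cc)
    nf4rFiller[[r]] <<- c(nf4rFiller[[r]], f)
    nf4rSup[[r]] <<- c(nf4rSup[[r]], cc)
    if (journalOn) jpush(list(t = "nf4", r = r, f = f))
    rt <- Rtgt[[r]]
    for (y in .lget(revS, f))
      for (x in .lget(rt, y)) addS(x, cc)
    invisible()
  }

  addRoleParent <- function(r, s) {
    if (s %in% .lget(roleParents, r)) return(invisible())
    roleParents[[r]] <<- c(.lget(roleParents, r), s)
    if (journalOn) jpush(list(t = "rp", r = r))
    for (a in seq_len(length(Rsrc[[r]])))
      for (b in .lget(Rsrc[[r]], a)) addEdge(s, a, b)
    invisible()
  }

  addChain <- function(r1, r2, s) {
    cf <- .lget(chainF2, r1); cfs <- .lget(chainFS, r1)
    if (any(cf == r2 & cfs == s)) return(invisible())
    chainF2[[r1]] <<- c(cf, r2); chainFS[[r1]] <<- c(cfs, s)
    chainS1[[r2]] <<- c(.lget(chainS1, r2), r1)
    chainSS[[r2]] <<- c(.lget(chainSS, r2), s)
    if (journalOn) jpush(list(t = "chain", r1 = r1, r2 = r2))
    for (a in seq_len(length(Rsrc[[r1]])))
      for (b in .lget(Rsrc[[r1]], a))
        for (cc in .lget(Rsrc[[r2]], b)) addEdge(s, a, cc)
    invisible()
  }

  drain <- function() {
    while (qhead <= qtail) {
      i <- qhead
      qhead <<- i + 1L
      if (qa[i] == 1L) {
        a <- qb[i]; b <- qc[i]
        for (sup in .lget(nf1sup, b)) addS(a, sup)
        o <- .lget(nf2other, b); s2 <- .lget(nf2sup, b)
        for (k in seq_along(o)) if (o[k] %in% S[[a]]) addS(a, s2[k])
        rv <- .lget(nf3role, b); tv <- .lget(nf3tgt, b)
        for (k in seq_along(rv)) addEdge(rv[k], a, tv[k])
        fr <- .lget(nf4fRole, b); fs <- .lget(nf4fSup, b)
        for (k in seq_along(fr))
          for (x in .lget(Rtgt[[fr[k]]], a)) addS(x, fs[k])
        if (b == .BOT) {
          if (a == .TOP) inconsistent <<- TRUE
          for (r in seq_along(Rtgt))
            for (x in .lget(Rtgt[[r]], a)) addS(x, .BOT)
        }
      } else {
        r <- qb[i]; a <- qc[i]; b <- qd[i]
        fi <- nf4rFiller[[r]]; si <- nf4rSup[[r]]
        for (k in seq_along(fi)) if (fi[k] %in% S[[b]]) addS(a, si[k])
        if (.BOT %in% S[[b]]) addS(a, .BOT)
        for (s in .lget(roleParents, r)) addEdge(s, a, b)
        c2 <- .lget(chainF2, r); cs <- .lget(chainFS, r)
        for (k in seq_along(c2))
          for (cc in .lget(Rsrc[[c2[k]]], b)) addEdge(cs[k], a, cc)
        c1 <- .lget(chainS1, r); css <- .lget(chainSS, r)
        for (k in seq_along(c1))
          for (x in .lget(Rtgt[[c1[k]]], a)) addEdge(css[k], x, b)
      }
    }
    invisible()
  }

  resetQueue <- function() { qtail <<- 0L; qhead <<- 1L; invisible() }

  mark <- function() { journalOn <<- TRUE; jtail }

  rollback <- function(markPos) {
    n <- jtail
    while (n > markPos) {
      e <- journal[[n]]
      switch(e$t,
        S = {
          v <- S[[e$a]]; S[[e$a]] <<- v[-length(v)]
          v <- revS[[e$b]]; revS[[e$b]] <<- v[-length(v)]
        },
        E = {
          v <- Rsrc[[e$r]][[e$a]]; Rsrc[[e$r]][[e$a]] <<- v[-length(v)]
          v <- Rtgt[[e$r]][[e$b]]; Rtgt[[e$r]][[e$b]] <<- v[-length(v)]
        },
        nf1 = { v <- nf1sup[[e$a]]; nf1sup[[e$a]] <<- v[-length(v)] },
        nf2 = {
          v <- nf2other[[e$a1]]; nf2other[[e$a1]] <<- v[-length(v)]
          v <- nf2sup[[e$a1]]; nf2sup[[e$a1]] <<- v[-length(v)]
          if (e$a1 != e$a2) {
            v <- nf2other[[e$a2]]; nf2other[[e$a2]] <<- v[-length(v)]
            v <- nf2sup[[e$a2]]; nf2sup[[e$a2]] <<- v[-length(v)]
          }
        },
        nf3 = {
          v <- nf3role[[e$a]]; nf3role[[e$a]] <<- v[-length(v)]
          v <- nf3tgt[[e$a]]; nf3tgt[[e$a]] <<- v[-length(v)]
        },
        nf4 = {
          v <- nf4fRole[[e$f]]; nf4fRole[[e$f]] <<- v[-length(v)]
          v <- nf4fSup[[e$f]]; nf4fSup[[e$f]] <<- v[-length(v)]
          v <- nf4rFiller[[e$r]]; nf4rFiller[[e$r]] <<- v[-length(v)]
          v <- nf4rSup[[e$r]]; nf4rSup[[e$r]] <<- v[-length(v)]
        },
        rp = { v <- roleParents[[e$r]]; roleParents[[e$r]] <<- v[-length(v)] },
        chain = {
          v <- chainF2[[e$r1]]; chainF2[[e$r1]] <<- v[-length(v)]
          v <- chainFS[[e$r1]]; chainFS[[e$r1]] <<- v[-length(v)]
          v <- chainS1[[e$r2]]; chainS1[[e$r2]] <<- v[-length(v)]
          v <- chainSS[[e$r2]]; chainSS[[e$r2]] <<- v[-length(v)]
        },
        class = {
          id <- get(e$iri, envir = idOf, inherits = FALSE)
          rm(list = e$iri, envir = idOf)
          nClass <<- id - 1L
          length(classTable) <<- id - 1L
          length(isOrig) <<- id - 1L
          if (length(S) >= id) length(S) <<- id - 1L
          if (length(revS) >= id) length(revS) <<- id - 1L
          if (length(nf1sup) >= id) length(nf1sup) <<- id - 1L
          if (length(nf2other) >= id) length(nf2other) <<- id - 1L
          if (length(nf2sup) >= id) length(nf2sup) <<- id - 1L
          if (length(nf3role) >= id) length(nf3role) <<- id - 1L
          if (length(nf3tgt) >= id) length(nf3tgt) <<- id - 1L
          if (length(nf4fRole) >= id) length(nf4fRole) <<- id - 1L
          if (length(nf4fSup) >= id) length(nf4fSup) <<- id - 1L
        },
        role = {
          id <- get(e$iri, envir = roleIdOf, inherits = FALSE)
          rm(list = e$iri, envir = roleIdOf)
          length(roleTable) <<- id - 1L
          length(nf4rFiller) <<- id - 1L
          length(nf4rSup) <<- id - 1L
          if (length(roleParents) >= id) length(roleParents) <<- id - 1L
          if (length(chainF2) >= id) length(chainF2) <<- id - 1L
          if (length(chainFS) >= id) length(chainFS) <<- id - 1L
          if (length(chainS1) >= id) length(chainS1) <<- id - 1L
          if (length(chainSS) >= id) length(chainSS) <<- id - 1L
          length(Rsrc) <<- id - 1L
          length(Rtgt) <<- id - 1L
        },
        dir = rm(list = e$key, envir = qctx$dirs),
        def = {
          rm(list = e$key, envir = qctx$defined)
          qctx$freshNameMap[[e$iri]] <- NULL
        },
        stop("unknown journal entry ", e$t)
      )
      n <- n - 1L
    }
    jtail <<- markPos
    journalOn <<- FALSE
    resetQueue()
    invisible()
  }

  environment()
}

#' Saturate a normalized ontology
#'
#' Computes the least fixpoint of the EL completion rules over the normal
#' forms of \code{norm}; the result supports incremental, rolled-back
#' insertion of query classes.
#'
#' @param norm a \code{NormalizedOntology}.
#' @return a \code{SaturationState}.
#' @export
saturate <- function(norm) {
  stopifnot(is(norm, "NormalizedOntology"))
  st <- .newSatState(length(norm@classTable))
  st$freshCounter <- length(norm@freshNameMap)

  orig <- norm@origClassIRIs
  for (i in seq_along(norm@classTable))
    st$ensureClass(norm@classTable[i], orig = norm@classTable[i] %in% orig)
  for (r in norm@roleTable) st$ensureRole(r)
  # invert the fresh-name map so query-time normalization can share names
  for (iri in names(norm@freshNameMap))
    assign(ceKey(norm@freshNameMap[[iri]]), iri, envir = st$freshKeyToIRI)

  for (x in norm@roleNF) {
    if (length(x$subChain) == 1L) st$addRoleParent(x$subChain, x$sup)
    else st$addChain(x$subChain[1L], x$subChain[2L], x$sup)
  }
  m <- norm@nf1
  for (i in seq_len(nrow(m))) st$addNF1(m[i, 1L], m[i, 2L])
  m <- norm@nf2
  for (i in seq_len(nrow(m))) st$addNF2(m[i, 1L], m[i, 2L], m[i, 3L])
  m <- norm@nf3
  for (i in seq_len(nrow(m))) st$addNF3(m[i, 1L], m[i, 2L], m[i, 3L])
  m <- norm@nf4
  for (i in seq_len(nrow(m))) st$addNF4(m[i, 1L], m[i, 2L], m[i, 3L])
  st$drain()
  st$resetQueue()
  new("SaturationState", env = st)
}

#' Subsumers of a named class
#'
#' @param state a \code{SaturationState}.
#' @param iri class IRI.
#' @param namedOnly return only the input's named classes (drop top and
#'   normalization fresh names).
#' @return character vector of subsumer IRIs (including \code{iri} itself);
#'   for an unsatisfiable class, all named classes.
#' @export
subsumersOf <- function(state, iri, namedOnly = TRUE) {
  st <- state@env
  id <- get0(iri, envir = st$idOf, inherits = FALSE)
  if (is.null(id)) .elStop("elrepo_unknown_class",
                           sprintf("class <%s> not in the saturation", iri))
  ids <- if (.BOT %in% .lget(st$S, id) || st$inconsistent)
    which(st$isOrig) else .lget(st$S, id)
  if (namedOnly) ids <- ids[st$isOrig[ids]]
  sort(st$classTable[ids])
}

#' Is the saturated ontology consistent?
#' @param state a \code{SaturationState}.
#' @return logical.
#' @export
isConsistent <- function(state) !state@env$inconsistent

setMethod("show", "SaturationState", function(object) {
  st <- object@env
  cat("SaturationState:", st$nClass, "names,",
      length(st$roleTable), "roles,",
      sum(lengths(st$S)), "subsumer entries,",
      if (st$inconsistent) "INCONSISTENT" else "consistent", "\n")
})

# ---- incremental query insertion --------------------------------------

.satMark <- function(st) st$mark()

.satRollback <- function(st, markPos) st$rollback(markPos)

# Query-time normalization context: emits straight into the live state.
.satQueryCtx <- function(st) {
  if (!is.null(st$qctx)) return(st$qctx)
  ctx <- .normCtx(
    function(a, b) st$addNF1(st$ensureClass(a), st$ensureClass(b)),
    function(a1, a2, b) st$addNF2(st$ensureClass(a1), st$ensureClass(a2),
                                  st$ensureClass(b)),
    function(a, r, b) st$addNF3(st$ensureClass(a), st$ensureRole(r),
                                st$ensureClass(b)),
    function(r, a, b) st$addNF4(st$ensureRole(r), st$ensureClass(a),
                                st$ensureClass(b)),
    counterStart = st$freshCounter
  )
  # share fresh names with the ontology's own normalization
  for (key in ls(st$freshKeyToIRI))
    assign(key, get(key, envir = st$freshKeyToIRI), envir = ctx$defined)
  ctx$onNewFresh <- function(key, iri) {
    if (st$journalOn) st$jpush(list(t = "def", key = key, iri = iri))
  }
  ctx$onDirEmitted <- function(dkey) {
    if (st$journalOn) st$jpush(list(t = "dir", key = dkey))
  }
  st$qctx <- ctx
  ctx
}

# Insert a fresh query class Q with Q == expr; returns its id. The caller
# is responsible for .satMark()/.satRollback().
.satInsertExpr <- function(st, expr) {
  ctx <- .satQueryCtx(st)
  st$queryCounter <- st$queryCounter + 1L
  qiri <- paste0("urn:query:", st$queryCounter)
  qid <- st$ensureClass(qiri)
  qce <- ceNamed(qiri)
  .normGCI(ctx, qce, expr)
  .normGCI(ctx, expr, qce)
  st$drain()
  qid
}
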