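# Brute-force entailment oracle: a deliberately naive, separately coded
# fixpoint over the subexpression closure of the *un-normalized* axioms.
# Every subexpression is a node; dense logical matrices hold the candidate
# subsumption relation and one successor relation per role, and all rules
# are re-applied until nothing changes. Used only for verification of the
# worklist reasoner on small inputs — it shares no code with it.

#' Brute-force subsumption oracle
#'
#' Computes all entailed subsumptions between named classes by exhaustive
#' rule application over the subexpression closure of the ontology's EL
#' axioms. Quadratic-to-quartic everywhere by construction; refuses inputs
#' above \code{maxClasses}/\code{maxRoles}.
#'
#' @param ontology an \code{Ontology}.
#' @param maxClasses,maxRoles size guard (defaults 20 classes, 4 roles).
#' @return two-column character matrix (\code{sub}, \code{sup}) of all
#'   entailed named subsumption pairs, reflexive pairs included, sorted.
#' @export
bruteForceOracle <- function(ontology, maxClasses = 20L, maxRoles = 4L) {
  stopifnot(is(ontology, "Ontology"))
  sig <- signatureOf(ontology)
  if (length(sig$classIRIs) > maxClasses || length(sig$roleIRIs) > maxRoles)
    .elStop("elrepo_oracle_too_large",
            sprintf("signature %d classes / %d roles exceeds oracle bound %d/%d",
                    length(sig$classIRIs), length(sig$roleIRIs),
                    maxClasses, maxRoles))

  axs <- Filter(function(ax) .isLogicalAxiom(ax) &&
                  !ax$kind %in% RBOX_AXIOM_KINDS, ontology@axioms)
  raxs <- Filter(.isRBoxAxiom, ontology@axioms)

  # ---- subexpression closure -------------------------------------------
  exprs <- list(); keyIdx <- new.env(parent = emptyenv())
  addExpr <- function(ce) {
    k <- ceKey(ce)
    id <- get0(k, envir = keyIdx, inherits = FALSE)
    if (!is.null(id)) return(id)
    id <- length(exprs) + 1L
    exprs[[id]] <<- ce
    assign(k, id, envir = keyIdx)
    if (ce$type == "and") for (op in ce$ops) addExpr(op)
    if (ce$type == "some") addExpr(ce$filler)
    id
  }
  topId <- addExpr(ceTop()); botId <- addExpr(ceBottom())
  for (iri in sig$classIRIs) addExpr(ceNamed(iri))
  gcis <- list()       # told pairs (subId, supId)
  disjPairs <- list()  # pairs (i, j) of member ids
  for (ax in axs) {
    if (ax$kind == "SubClassOf") {
      gcis[[length(gcis) + 1L]] <- c(addExpr(ax$sub), addExpr(ax$sup))
    } else if (ax$kind == "EquivalentClasses") {
      ids <- vapply(ax$members, addExpr, integer(1))
      for (i in seq_along(ids)[-1L]) {
        gcis[[length(gcis) + 1L]] <- c(ids[1L], ids[i])
        gcis[[length(gcis) + 1L]] <- c(ids[i], ids[1L])
      }
    } else { # DisjointClasses
      ids <- vapply(ax$members, addExpr, integer(1))
      n <- length(ids)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        disjPairs[[length(disjPairs) + 1L]] <- c(ids[i], ids[j])
    }
  }
  n <- length(exprs)
  types <- vapply(exprs, `[[`, character(1), "type")
  andIds <- which(types == "and")
  someIds <- which(types == "some")

  # ---- role machinery ---------------------------------------------------
  roles <- sig$roleIRIs
  nr <- length(roles)
  rid <- function(x) match(x, roles)
  subRole <- diag(nr) > 0
  chains <- list()
  for (ax in raxs) {
    if (ax$kind == "SubObjectPropertyOf") {
      if (length(ax$subChain) == 1L)
        subRole[rid(ax$subChain), rid(ax$sup)] <- TRUE
      else if (length(ax$subChain) == 2L)
        chains[[length(chains) + 1L]] <-
          c(rid(ax$subChain[1L]), rid(ax$subChain[2L]), rid(ax$sup))
      else .elStop("elrepo_normalization_error",
                   "role chain longer than 2 in oracle input")
    } else {
      ids <- rid(ax$members)
      for (i in seq_along(ids)[-1L]) {
        subRole[ids[1L], ids[i]] <- TRUE
        subRole[ids[i], ids[1L]] <- TRUE
      }
    }
  }
  # reflexive-transitive closure of the role hierarchy (naive)
  if (nr) repeat {
    nxt <- subRole | ((subRole %*% subRole) > 0)
    if (identical(nxt, subRole)) break
    subRole <- nxt
  }

  sub <- diag(n) > 0
  sub[, topId] <- TRUE
  rel <- rep(list(matrix(FALSE, n, n)), nr)

  repeat {
    before <- list(sub, rel)
    for (g in gcis) sub[sub[, g[1L]], g[2L]] <- TRUE
    for (x in andIds) {
      ops <- vapply(exprs[[x]]$ops, function(o)
        get(ceKey(o), envir = keyIdx), integer(1))
      sub[x, ops] <- TRUE
      hit <- rep(TRUE, n)
      for (o in ops) hit <- hit & sub[, o]
      sub[hit, x] <- TRUE
    }
    for (x in someIds) {
      e <- exprs[[x]]
      r <- rid(e$role)
      f <- get(ceKey(e$filler), envir = keyIdx)
      # introduction: Y <= Er.F gives an r-successor
      rel[[r]][sub[, x], f] <- TRUE
      # classification: an r'-successor (r' <= r) inside F gives Y <= Er.F
      eff <- matrix(FALSE, n, n)
      for (rp in which(subRole[, r])) eff <- eff | rel[[rp]]
      sub[(eff %*% sub[, f]) > 0, x] <- TRUE
    }
    for (ch in chains)
      rel[[ch[3L]]] <- rel[[ch[3L]]] | ((rel[[ch[1L]]] %*% rel[[ch[2L]]]) > 0)
    if (nr) for (r in seq_len(nr)) for (s in which(subRole[r, ]))
      rel[[s]] <- rel[[s]] | rel[[r]]
    for (d in disjPairs) sub[sub[, d[1L]] & sub[, d[2L]], botId] <- TRUE
    if (nr) for (r in seq_len(nr))
      sub[(rel[[r]] %*% sub[, botId]) > 0, botId] <- TRUE
    sub[sub[, botId], ] <- TRUE
    sub <- sub | ((sub %*% sub) > 0)
    if (identical(list(sub, rel), before)) break
  }

  named <- vapply(sig$classIRIs, function(iri)
    get(ceKey(ceNamed(iri)), envir = keyIdx), integer(1))
  if (length(named) && sub[topId, botId]) {
    m <- as.matrix(expand.grid(sub = sig$classIRIs, sup = sig$classIRIs,
                               stringsAsFactors = FALSE))
  } else {
    hits <- which(sub[named, named, drop = FALSE], arr.ind = TRUE)
    m <- cbind(sub = sig$classIRIs[hits[, 1L]],
               sup = sig$classIRIs[hits[, 2L]])
  }
  m[order(m[, 1L], m[, 2L], method = "radix"), , drop = FALSE]
}
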