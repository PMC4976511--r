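# EL class expressions: named classes, top, bottom, n-ary conjunction and
# existential restriction. Expressions are plain tagged lists with a stable
# canonical key used for structural equality, deduplication and ordering.

#' Class expression constructors
#'
#' Build the class expressions of the supported EL fragment: named classes,
#' \code{owl:Thing} (top), \code{owl:Nothing} (bottom), conjunctions and
#' existential restrictions. Conjunctions are flattened n-ary sets: nested
#' conjunctions are merged, duplicate operands removed, and operands kept in
#' canonical order, so structural equality is order-insensitive. A
#' conjunction that collapses to a single operand returns that operand.
#'
#' @param iri absolute IRI of a named class or object property.
#' @param ... class expressions (operands of the conjunction), or a single
#'   list of them.
#' @param role object-property IRI of the existential restriction.
#' @param filler class expression restricted over.
#' @return an object of class \code{ClassExpr}.
#' @examples
#' ceAnd(ceNamed("http://ex.org/A"),
#'       ceSome("http://ex.org/r", ceNamed("http://ex.org/B")))
#' @name class-expressions
NULL

#' @rdname class-expressions
#' @export
ceNamed <- function(iri) {
  stopifnot(is.character(iri), length(iri) == 1L, nzchar(iri))
  if (iri == OWL_THING) return(ceTop())
  if (iri == OWL_NOTHING) return(ceBottom())
  structure(list(type = "named", iri = iri), class = "ClassExpr")
}

#' @rdname class-expressions
#' @export
ceTop <- function() structure(list(type = "top"), class = "ClassExpr")

#' @rdname class-expressions
#' @export
ceBottom <- function() structure(list(type = "bottom"), class = "ClassExpr")

#' @rdname class-expressions
#' @export
ceAnd <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && is.list(ops[[1L]]) && !inherits(ops[[1L]], "ClassExpr"))
    ops <- ops[[1L]]
  stopifnot(length(ops) >= 1L)
  flat <- list()
  for (op in ops) {
    stopifnot(inherits(op, "ClassExpr"))
    if (op$type == "and") flat <- c(flat, op$ops) else flat <- c(flat, list(op))
  }
  keys <- vapply(flat, ceKey, character(1))
  keep <- !duplicated(keys)
  flat <- flat[keep][order(keys[keep])]
  if (length(flat) == 1L) return(flat[[1L]])
  structure(list(type = "and", ops = flat), class = "ClassExpr")
}

#' @rdname class-expressions
#' @export
ceSome <- function(role, filler) {
  stopifnot(is.character(role), length(role) == 1L, nzchar(role),
            inherits(filler, "ClassExpr"))
  structure(list(type = "some", role = role, filler = filler),
            class = "ClassExpr")
}

#' Canonical key of a class expression
#'
#' A string uniquely identifying the expression's structure; equal keys mean
#' structural equality (modulo conjunction flattening/ordering, which the
#' constructors already canonicalize).
#'
#' @param ce a \code{ClassExpr}.
#' @return length-1 character.
#' @export
ceKey <- function(ce) {
  switch(ce$type,
    named  = paste0("N<", ce$iri, ">"),
    top    = "T",
    bottom = "B",
    and    = paste0("A(", paste(vapply(ce$ops, ceKey, character(1)),
                                collapse = ","), ")"),
    some   = paste0("E(<", ce$role, ">,", ceKey(ce$filler), ")"),
    stop("unknown expression type: ", ce$type)
  )
}

# All IRIs in class position / role position inside an expression.
.ceSignature <- function(ce) {
  switch(ce$type,
    named  = list(classes = ce$iri, roles = .chr0),
    top    = ,
    bottom = list(classes = .chr0, roles = .chr0),
    and    = {
      parts <- lapply(ce$ops, .ceSignature)
      list(classes = unique(unlist(lapply(parts, `[[`, "classes"))),
           roles   = unique(unlist(lapply(parts, `[[`, "roles"))))
    },
    some   = {
      f <- .ceSignature(ce$filler)
      list(classes = f$classes, roles = unique(c(ce$role, f$roles)))
    }
  )
}

.ceIsNamed <- function(ce) ce$type %in% c("named", "top", "bottom")

#' @export
format.ClassExpr <- function(x, ...) {
  switch(x$type,
    named  = paste0("<", x$iri, ">"),
    top    = "owl:Thing",
    bottom = "owl:Nothing",
    and    = paste0("(", paste(vapply(x$ops, format, character(1)),
                               collapse = " and "), ")"),
    some   = paste0("(<", x$role, "> some ", format(x$filler), ")")
  )
}

#' @export
print.ClassExpr <- function(x, ...) {
  cat("ClassExpr:", format(x), "\n")
  invisible(x)
}
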