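# Manchester-syntax query parser for the EL subset: bare or single-quoted
# labels, `and`, `some`, parentheses, and <IRI> fallback. Constructs outside
# the fragment (`or`, `not`, `only`, `min`, `max`, `exactly`, `value`) are
# recognized and rejected with an out-of-fragment error, mirroring the
# repository's posture of ignoring non-EL queries.

.MS_NONEL_KEYWORDS <- c("or", "not", "only", "min", "max", "exactly", "value")

.msTokenize <- function(text) {
  re <- "'(?:[^'\\\\]|\\\\.)*'|<[^<>[:space:]]*>|\\(|\\)|[^()'<[:space:]]+"
  m <- gregexpr(re, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(list())
  starts <- as.integer(m); lens <- attr(m, "match.length")
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts))
    covered[seq.int(starts[i], length.out = lens[i])] <- TRUE
  chars <- strsplit(text, "")[[1L]]
  bad <- which(!covered & !grepl("^[[:space:]]$", chars))
  if (length(bad))
    .elStop("elrepo_query_syntax",
            sprintf("bad character '%s' at position %d", chars[bad[1L]], bad[1L]))
  vals <- substring(text, starts, starts + lens - 1L)
  lapply(vals, function(v) {
    if (v == "(") list(type = "lpar", val = v)
    else if (v == ")") list(type = "rpar", val = v)
    else if (startsWith(v, "<"))
      list(type = "iri", val = substr(v, 2L, nchar(v) - 1L))
    else if (startsWith(v, "'"))
      list(type = "quoted",
           val = gsub("\\\\(['\\\\])", "\\1",
                      substr(v, 2L, nchar(v) - 1L)))
    else list(type = "word", val = v)
  })
}

#' Parse a Manchester-syntax query expression
#'
#' Supports the query grammar \code{A}, \code{A and B}, \code{R some A},
#' \code{A and R some B} (arbitrarily nested, with parentheses). Class and
#' property names are labels resolved through \code{index}; single quotes
#' allow labels with spaces, and \code{<IRI>} bypasses the index.
#'
#' @param text the query string.
#' @param index a \code{LabelIndex} for label resolution.
#' @return a \code{ClassExpr}.
#' @section Errors: \code{elrepo_query_syntax} on bad grammar,
#'   \code{elrepo_unknown_label} / \code{elrepo_ambiguous_label} on label
#'   resolution failure, \code{elrepo_out_of_fragment} for Manchester
#'   constructs outside EL.
#' @export
parseQuery <- function(text, index) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  toks <- .msTokenize(text)
  pos <- 1L
  peek <- function() if (pos > length(toks)) NULL else toks[[pos]]
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  syntaxStop <- function(msg)
    .elStop("elrepo_query_syntax", sprintf("%s (near token %d)", msg, pos))
  outOfFragment <- function(kw)
    .elStop("elrepo_out_of_fragment",
            sprintf("Manchester construct '%s' is outside the EL fragment", kw))

  resolveEntity <- function(tok, kind) {
    if (tok$type == "iri") return(tok$val)
    resolveLabel(index, tok$val, kind)
  }

  parseUnit <- function() {
    t <- peek()
    if (is.null(t)) syntaxStop("unexpected end of query")
    if (t$type == "lpar") {
      advance()
      e <- parseConj()
      if (is.null(peek()) || peek()$type != "rpar")
        syntaxStop("missing ')'")
      advance()
      return(e)
    }
    if (t$type == "rpar") syntaxStop("unexpected ')'")
    if (t$type == "word" && t$val %in% .MS_NONEL_KEYWORDS) outOfFragment(t$val)
    atom <- advance()
    nxt <- peek()
    if (!is.null(nxt) && nxt$type == "word") {
      if (nxt$val == "some") {
        advance()
        role <- resolveEntity(atom, "objectProperty")
        return(ceSome(role, parseUnit()))
      }
      if (nxt$val %in% .MS_NONEL_KEYWORDS) outOfFragment(nxt$val)
    }
    ceNamed(resolveEntity(atom, "class"))
  }

  parseConj <- function() {
    ops <- list(parseUnit())
    repeat {
      t <- peek()
      if (is.null(t)) break
      if (t$type == "word" && t$val == "and") {
        advance()
        ops[[length(ops) + 1L]] <- parseUnit()
      } else if (t$type == "word" && t$val %in% .MS_NONEL_KEYWORDS) {
        outOfFragment(t$val)
      } else break
    }
    if (length(ops) == 1L) ops[[1L]] else ceAnd(ops)
  }

  e <- parseConj()
  if (!is.null(peek()))
    syntaxStop(sprintf("trailing input '%s'", peek()$val))
  e
}
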