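# OWL 2 Functional-Style Syntax reader and writer. The reader materializes
# the supported fragment (Prefix, Ontology, Import, Declaration, SubClassOf,
# EquivalentClasses, DisjointClasses, SubObjectPropertyOf incl.
# ObjectPropertyChain, EquivalentObjectProperties, AnnotationAssertion with
# a string literal, ObjectIntersectionOf, ObjectSomeValuesFrom, owl:Thing,
# owl:Nothing); any other well-bracketed axiom is preserved as an
# Unsupported axiom with its construct name recorded. Token-level
# malformation (unbalanced parentheses, bad IRIs, undefined prefixes) raises
# a parse error carrying line and column.

.DEFAULT_PREFIXES <- c(
  owl  = "http://www.w3.org/2002/07/owl#",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  xml  = "http://www.w3.org/XML/1998/namespace"
)

.TOKEN_RE <- paste0(
  "\\(|\\)|",
  "<[^<>\"{}|^`\\\\[:space:]]*>|",
  "\"(?:[^\"\\\\]|\\\\.)*\"|",
  "[^()\"<[:space:]]+"
)

.lineCol <- function(text, offset) {
  pre <- substr(text, 1L, offset - 1L)
  nl <- gregexpr("\n", pre, fixed = TRUE)[[1L]]
  if (nl[1L] == -1L) list(line = 1L, col = offset)
  else list(line = length(nl) + 1L, col = offset - nl[length(nl)])
}

.parseStop <- function(text, offset, message) {
  lc <- .lineCol(text, offset)
  .elStop("elrepo_parse_error",
          sprintf("parse error at line %d, column %d: %s",
                  lc$line, lc$col, message),
          line = lc$line, col = lc$col)
}

.tokenize <- function(text) {
  m <- gregexpr(.TOKEN_RE, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    starts <- integer(0); lens <- integer(0)
  } else {
    starts <- as.integer(m); lens <- attr(m, "match.length")
  }
  # every character outside a token must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts))
    covered[seq.int(starts[i], length.out = lens[i])] <- TRUE
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- which(!covered & !grepl("^[[:space:]]$", chars))
  if (length(bad))
    .parseStop(text, bad[1L], paste0("unexpected character '", chars[bad[1L]], "'"))
  vals <- substring(text, starts, starts + lens - 1L)
  types <- ifelse(vals == "(", "lpar",
           ifelse(vals == ")", "rpar",
           ifelse(startsWith(vals, "<"), "iriref",
           ifelse(startsWith(vals, "\""), "string", "atom"))))
  list(vals = vals, types = types, starts = starts,
       ends = starts + lens - 1L, n = length(vals))
}

.unescapeString <- function(s) {
  s <- substr(s, 2L, nchar(s) - 1L)
  gsub("\\\\([\"\\\\])", "\\1", s)
}

.escapeString <- function(s) {
  paste0("\"", gsub("([\"\\\\])", "\\\\\\1", s), "\"")
}

# Parser state: environment with tokens, position, prefixes, source text.
.psNew <- function(text) {
  ps <- new.env(parent = emptyenv())
  ps$text <- text
  ps$tok <- .tokenize(text)
  ps$pos <- 1L
  ps$prefixes <- as.list(.DEFAULT_PREFIXES)
  ps
}

.psEOF <- function(ps) ps$pos > ps$tok$n
.psPeek <- function(ps, what = "value") {
  if (.psEOF(ps)) return(NA_character_)
  if (what == "type") ps$tok$types[ps$pos] else ps$tok$vals[ps$pos]
}
.psNext <- function(ps) {
  if (.psEOF(ps)) .parseStop(ps$text, nchar(ps$text) + 1L, "unexpected end of input")
  i <- ps$pos; ps$pos <- i + 1L
  list(val = ps$tok$vals[i], type = ps$tok$types[i], start = ps$tok$starts[i],
       end = ps$tok$ends[i])
}
.psExpect <- function(ps, type, val = NULL) {
  t <- .psNext(ps)
  ok <- t$type == type && (is.null(val) || t$val == val)
  if (!ok)
    .parseStop(ps$text, t$start,
               sprintf("expected %s, found '%s'", val %||% type, t$val))
  t
}

.psIRI <- function(ps) {
  t <- .psNext(ps)
  if (t$type == "iriref") {
    iri <- substr(t$val, 2L, nchar(t$val) - 1L)
    if (!nzchar(iri)) .parseStop(ps$text, t$start, "empty IRI")
    return(iri)
  }
  if (t$type != "atom")
    .parseStop(ps$text, t$start, sprintf("expected an IRI, found '%s'", t$val))
  colon <- regexpr(":", t$val, fixed = TRUE)
  if (colon == -1L)
    .parseStop(ps$text, t$start, sprintf("bad IRI '%s' (no prefix)", t$val))
  pfx <- substr(t$val, 1L, colon - 1L)
  key <- if (nzchar(pfx)) pfx else ".default."
  local <- substr(t$val, colon + 1L, nchar(t$val))
  base <- ps$prefixes[[key]]
  if (is.null(base))
    .parseStop(ps$text, t$start, sprintf("undefined prefix '%s:'", pfx))
  paste0(base, local)
}

# Skip a balanced ( ... ) whose opening paren is at token index `from`;
# returns index just past the matching close paren.
.skipBalanced <- function(ps, from) {
  depth <- 0L; i <- from
  repeat {
    if (i > ps$tok$n)
      .parseStop(ps$text, nchar(ps$text) + 1L, "unbalanced parentheses")
    ty <- ps$tok$types[i]
    if (ty == "lpar") depth <- depth + 1L
    else if (ty == "rpar") {
      depth <- depth - 1L
      if (depth == 0L) return(i + 1L)
    }
    i <- i + 1L
  }
}

.unsupportedCond <- function(name) {
  structure(class = c("elrepo_unsupported_construct", "condition"),
            list(message = name, constructName = name))
}

.psClassExpr <- function(ps) {
  ty <- .psPeek(ps, "type")
  if (ty %in% c("iriref", "atom")) {
    save <- ps$pos
    head <- .psNext(ps)
    if (head$type == "atom" && .psPeek(ps, "type") == "lpar") {
      # constructor application
      if (head$val == "ObjectIntersectionOf") {
        .psExpect(ps, "lpar")
        ops <- list()
        while (!identical(.psPeek(ps, "type"), "rpar"))
          ops[[length(ops) + 1L]] <- .psClassExpr(ps)
        .psExpect(ps, "rpar")
        if (length(ops) < 2L)
          .parseStop(ps$text, head$start, "ObjectIntersectionOf needs >= 2 operands")
        return(ceAnd(ops))
      }
      if (head$val == "ObjectSomeValuesFrom") {
        .psExpect(ps, "lpar")
        role <- .psIRI(ps)
        filler <- .psClassExpr(ps)
        .psExpect(ps, "rpar")
        return(ceSome(role, filler))
      }
      stop(.unsupportedCond(head$val))
    }
    ps$pos <- save
    return(ceNamed(.psIRI(ps)))  # maps owl:Thing / owl:Nothing to top/bottom
  }
  t <- .psNext(ps)
  .parseStop(ps$text, t$start,
             sprintf("expected a class expression, found '%s'", t$val))
}

.psLiteral <- function(ps) {
  t <- .psNext(ps)
  if (t$type != "string") stop(.unsupportedCond("AnnotationAssertion/non-literal"))
  val <- .unescapeString(t$val)
  # optional @lang or ^^datatype suffix, tokenized as a following atom
  if (identical(.psPeek(ps, "type"), "atom")) {
    nxt <- .psPeek(ps)
    if (startsWith(nxt, "@")) .psNext(ps)
    else if (startsWith(nxt, "^^")) {
      .psNext(ps)
      if (identical(.psPeek(ps, "type"), "iriref")) .psNext(ps)
    }
  }
  val
}

.psAxiom <- function(ps, report) {
  head <- .psExpect(ps, "atom")
  name <- head$val
  axStart <- head$start
  openIdx <- ps$pos
  .psExpect(ps, "lpar")
  endIdx <- .skipBalanced(ps, openIdx)
  rawText <- substr(ps$text, axStart, ps$tok$ends[endIdx - 1L])

  asUnsupported <- function(construct) {
    ps$pos <- endIdx
    report$unsupported[[construct]] <-
      (report$unsupported[[construct]] %||% 0L) + 1L
    unsupportedAxiom(construct, rawText)
  }

  supported <- c("Declaration", "SubClassOf", "EquivalentClasses",
                 "DisjointClasses", "SubObjectPropertyOf",
                 "EquivalentObjectProperties", "AnnotationAssertion")
  if (!name %in% supported) return(asUnsupported(name))

  ax <- tryCatch({
      res <- switch(name,
        Declaration = {
          inner <- .psExpect(ps, "atom")
          .psExpect(ps, "lpar")
          if (!inner$val %in% c("Class", "ObjectProperty"))
            stop(.unsupportedCond(paste0("Declaration/", inner$val)))
          iri <- .psIRI(ps)
          .psExpect(ps, "rpar")
          declaration(if (inner$val == "Class") "class" else "objectProperty", iri)
        },
        SubClassOf = subClassOf(.psClassExpr(ps), .psClassExpr(ps)),
        EquivalentClasses = {
          ms <- list()
          while (!identical(.psPeek(ps, "type"), "rpar"))
            ms[[length(ms) + 1L]] <- .psClassExpr(ps)
          equivalentClasses(ms)
        },
        DisjointClasses = {
          ms <- list()
          while (!identical(.psPeek(ps, "type"), "rpar"))
            ms[[length(ms) + 1L]] <- .psClassExpr(ps)
          disjointClasses(ms)
        },
        SubObjectPropertyOf = {
          chain <- if (identical(.psPeek(ps), "ObjectPropertyChain")) {
            .psNext(ps); .psExpect(ps, "lpar")
            ch <- character(0)
            while (!identical(.psPeek(ps, "type"), "rpar"))
              ch <- c(ch, .psIRI(ps))
            .psExpect(ps, "rpar")
            ch
          } else .psIRI(ps)
          subObjectPropertyOf(chain, .psIRI(ps))
        },
        EquivalentObjectProperties = {
          ms <- character(0)
          while (!identical(.psPeek(ps, "type"), "rpar"))
            ms <- c(ms, .psIRI(ps))
          equivalentObjectProperties(ms)
        },
        AnnotationAssertion = {
          prop <- .psIRI(ps)
          subj <- .psIRI(ps)
          annotationAssertion(subj, prop, .psLiteral(ps))
        }
      )
      .psExpect(ps, "rpar")
      res
    },
    elrepo_unsupported_construct = function(c) asUnsupported(c$constructName),
    elrepo_invalid_axiom = function(c) asUnsupported(paste0(name, "/degenerate"))
  )
  if (ax$kind != "Unsupported")
    report$parsed <- report$parsed + 1L
  ax
}

#' Parse an OWL 2 Functional-Style Syntax document
#'
#' @param text the document as a single string (UTF-8).
#' @param sourceName name recorded on the resulting ontology.
#' @return list with elements \code{ontology} (an \code{Ontology}) and
#'   \code{report}, a \code{ParseReport}: \code{axiomsParsed} (count of
#'   non-Unsupported axioms produced), \code{unsupportedConstructs} (named
#'   integer vector, construct name to count) and \code{warnings} (list of
#'   \code{line}/\code{message} pairs).
#' @seealso [serializeFunctional()], [readOntology()]
#' @examples
#' doc <- paste0("Prefix(:=<http://ex.org/>)\n",
#'               "Ontology(<http://ex.org/o>\nSubClassOf(:A :B)\n)")
#' parseFunctional(doc)$report$axiomsParsed
#' @export
parseFunctional <- function(text, sourceName = "<string>") {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  ps <- .psNew(text)
  report <- new.env(parent = emptyenv())
  report$parsed <- 0L
  report$unsupported <- list()
  report$warnings <- list()

  declared <- character(0)
  while (identical(.psPeek(ps), "Prefix")) {
    .psNext(ps); .psExpect(ps, "lpar")
    t <- .psExpect(ps, "atom")
    if (!endsWith(t$val, ":="))
      .parseStop(ps$text, t$start, "malformed prefix declaration")
    pname <- substr(t$val, 1L, nchar(t$val) - 2L)
    iritok <- .psExpect(ps, "iriref")
    iriVal <- substr(iritok$val, 2L, nchar(iritok$val) - 1L)
    ps$prefixes[[if (nzchar(pname)) pname else ".default."]] <- iriVal
    declared[pname] <- iriVal
    .psExpect(ps, "rpar")
  }

  .psExpect(ps, "atom", "Ontology")
  .psExpect(ps, "lpar")
  iri <- character(0)
  while (.psPeek(ps, "type") == "iriref") {
    t <- .psNext(ps)  # ontology IRI then optional version IRI
    if (!length(iri)) iri <- substr(t$val, 2L, nchar(t$val) - 1L)
  }
  imports <- character(0)
  axs <- list()
  while (!identical(.psPeek(ps, "type"), "rpar")) {
    if (.psEOF(ps))
      .parseStop(text, nchar(text) + 1L, "unbalanced parentheses (missing ')')")
    if (identical(.psPeek(ps), "Import")) {
      .psNext(ps); .psExpect(ps, "lpar")
      imports <- c(imports, .psIRI(ps))
      .psExpect(ps, "rpar")
      next
    }
    axs[[length(axs) + 1L]] <- .psAxiom(ps, report)
  }
  .psExpect(ps, "rpar")
  if (!.psEOF(ps)) {
    t <- .psNext(ps)
    .parseStop(text, t$start, sprintf("trailing content '%s'", t$val))
  }
  if (length(imports))
    report$warnings[[length(report$warnings) + 1L]] <-
      list(line = 1L, message = paste("imports recorded but not resolved:",
                                      paste(imports, collapse = ", ")))
  unsup <- vapply(report$unsupported, as.integer, integer(1))
  list(
    ontology = Ontology(axs, iri = iri, sourceName = sourceName,
                        imports = imports, prefixes = declared),
    report = list(axiomsParsed = report$parsed,
                  unsupportedConstructs = unsup,
                  warnings = report$warnings)
  )
}

#' Read an ontology document from a file
#'
#' @param path path to a \code{.ofn} file.
#' @return as [parseFunctional()].
#' @export
readOntology <- function(path) {
  parseFunctional(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                        collapse = "\n"),
                  sourceName = basename(path))
}

.renderCE <- function(ce) {
  switch(ce$type,
    named  = paste0("<", ce$iri, ">"),
    top    = "owl:Thing",
    bottom = "owl:Nothing",
    and    = paste0("ObjectIntersectionOf(",
                    paste(vapply(ce$ops, .renderCE, character(1)),
                          collapse = " "), ")"),
    some   = paste0("ObjectSomeValuesFrom(<", ce$role, "> ",
                    .renderCE(ce$filler), ")")
  )
}

.renderAxiom <- function(ax) {
  switch(ax$kind,
    SubClassOf = paste0("SubClassOf(", .renderCE(ax$sub), " ",
                        .renderCE(ax$sup), ")"),
    EquivalentClasses = paste0(
      "EquivalentClasses(",
      paste(vapply(ax$members, .renderCE, character(1)), collapse = " "), ")"),
    DisjointClasses = paste0(
      "DisjointClasses(",
      paste(vapply(ax$members, .renderCE, character(1)), collapse = " "), ")"),
    SubObjectPropertyOf = paste0(
      "SubObjectPropertyOf(",
      if (length(ax$subChain) > 1L)
        paste0("ObjectPropertyChain(",
               paste0("<", ax$subChain, ">", collapse = " "), ")")
      else paste0("<", ax$subChain, ">"),
      " <", ax$sup, ">)"),
    EquivalentObjectProperties = paste0(
      "EquivalentObjectProperties(",
      paste0("<", ax$members, ">", collapse = " "), ")"),
    Declaration = paste0(
      "Declaration(", if (ax$declKind == "class") "Class" else "ObjectProperty",
      "(<", ax$iri, ">))"),
    AnnotationAssertion = paste0(
      "AnnotationAssertion(<", ax$property, "> <", ax$subject, "> ",
      .escapeString(ax$value), ")"),
    Unsupported = ax$rawText
  )
}

.AXIOM_KIND_ORDER <- c(Declaration = 1L, SubClassOf = 2L,
                       EquivalentClasses = 3L, DisjointClasses = 4L,
                       SubObjectPropertyOf = 5L,
                       EquivalentObjectProperties = 6L,
                       AnnotationAssertion = 7L, Unsupported = 8L)

#' Serialize an ontology to Functional-Style Syntax
#'
#' Output is deterministic: axioms are ordered by kind and then by their
#' lexicographic rendering, so two serializations of structurally equal
#' ontologies are byte-identical, and re-parsing the output yields a
#' structurally equal ontology.
#'
#' @param ontology an \code{Ontology}.
#' @param echoUnsupported if \code{TRUE}, \code{Unsupported} axioms are
#'   echoed verbatim from their recorded raw text; otherwise their presence
#'   is an error.
#' @return the document as a single string.
#' @export
serializeFunctional <- function(ontology, echoUnsupported = FALSE) {
  stopifnot(is(ontology, "Ontology"))
  for (ax in ontology@axioms)
    if (ax$kind == "Unsupported") {
      if (!echoUnsupported)
        .elStop("elrepo_serialize_error",
                "ontology contains Unsupported axioms; set echoUnsupported = TRUE")
      if (is.na(ax$rawText))
        .elStop("elrepo_serialize_error",
                sprintf("Unsupported axiom '%s' has no raw text to echo",
                        ax$constructName))
    }
  rendered <- vapply(ontology@axioms, .renderAxiom, character(1))
  kinds <- vapply(ontology@axioms, `[[`, character(1), "kind")
  ord <- order(.AXIOM_KIND_ORDER[kinds], rendered, method = "radix")
  pfx <- ontology@prefixes
  if (!"owl" %in% names(pfx)) pfx["owl"] <- .DEFAULT_PREFIXES[["owl"]]
  pfx <- pfx[order(names(pfx), method = "radix")]
  header <- sprintf("Prefix(%s:=<%s>)", names(pfx), unname(pfx))
  irihead <- if (length(ontology@iri)) paste0("<", ontology@iri, ">") else ""
  body <- c(sprintf("Ontology(%s", irihead),
            sprintf("Import(<%s>)", sort(ontology@imports)),
            rendered[ord], ")")
  paste(c(header, body), collapse = "\n")
}

#' Write an ontology to a \code{.ofn} file
#'
#' @inheritParams serializeFunctional
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeOntology <- function(ontology, path, echoUnsupported = FALSE) {
  writeLines(serializeFunctional(ontology, echoUnsupported), path,
             useBytes = TRUE)
  invisible(path)
}
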