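# Shared helpers: compact IRI builders, tiny ontologies, pair-set utilities.

ex <- function(x) paste0("http://ex.org/", x)
nm <- function(x) ceNamed(ex(x))

# strict (non-reflexive) pairs of a closure matrix, as sorted "sub>sup" keys
strictKeys <- function(m) {
  m <- m[m[, 1L] != m[, 2L], , drop = FALSE]
  sort(paste(m[, 1L], m[, 2L], sep = ">"))
}

pairKeys <- function(m) sort(paste(m[, 1L], m[, 2L], sep = ">"))

# a small random EL ontology within the oracle's size bounds
tinyRandomOntology <- function(seed, nonEL = 0) {
  generateOntology(
    nClasses = sample(3:15, 1), nRoles = sample(1:3, 1),
    nSubClassAxioms = sample(0:10, 1), nConjunctionAxioms = sample(0:5, 1),
    nExistentialAxioms = sample(0:6, 1), nEquivalenceAxioms = sample(0:3, 1),
    labelFraction = 1, nonELFraction = nonEL, seed = seed)
}

# parse a functional-syntax snippet with a default prefix
parseSnippet <- function(axiomLines, prefix = "http://ex.org/") {
  parseFunctional(paste0(
    "Prefix(:=<", prefix, ">)\n",
    "Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)\n",
    "Ontology(<http://ex.org/onto>\n",
    paste(axiomLines, collapse = "\n"), "\n)"))
}
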