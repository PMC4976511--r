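# Shared helpers: classed conditions, seeded evaluation, label normalization.

.elCondition <- function(subclass, message, call = sys.call(-1), ...) {
  structure(
    class = c(subclass, "elrepo_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

.elStop <- function(subclass, message, ...) {
  stop(.elCondition(subclass, message, ...))
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Normalize a label for index lookup
#'
#' Case-folds and collapses internal whitespace; leading/trailing whitespace
#' is removed. All label matching in the query engine goes through this.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
normalizeLabel <- function(x) {
  tolower(trimws(gsub("[[:space:]]+", " ", x)))
}

# rdfs:label is the annotation property the label index understands.
RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
OWL_THING <- "http://www.w3.org/2002/07/owl#Thing"
OWL_NOTHING <- "http://www.w3.org/2002/07/owl#Nothing"

.chr0 <- character(0)
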