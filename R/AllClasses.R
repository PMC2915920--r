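#' @import methods
NULL

#' The 20 standard amino-acid one-letter codes
#'
#' Ambiguity and non-standard codes (B, J, O, U, X, Z) are deliberately
#' excluded: class and exclusion positions never accept them.
#'
#' @export
STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## A PositionSpec is a plain list with fields
##   kind:      "class" | "exclusion" | "wildcard"
##   residues:  character vector of standard residues (class/exclusion)
##   span_min, span_max: integer extents (1,1 for class/exclusion)
## kept as a list rather than an S4 class: patterns hold many of them and
## they are never mutated independently of their pattern.

.validPositionSpec <- function(ps) {
  if (!is.list(ps) || is.null(ps$kind))
    return("position spec must be a list with a 'kind' field")
  if (!ps$kind %in% c("class", "exclusion", "wildcard"))
    return(sprintf("unknown position kind '%s'", ps$kind))
  if (ps$kind %in% c("class", "exclusion")) {
    if (length(ps$residues) == 0)
      return("class/exclusion position with empty residue set")
    if (!all(ps$residues %in% STANDARD_AA))
      return(sprintf("non-standard residue(s) in position spec: %s",
                     paste(setdiff(ps$residues, STANDARD_AA), collapse = "")))
    if (ps$span_min != 1L || ps$span_max != 1L)
      return("class/exclusion positions must have extent (1,1)")
  } else {
    if (ps$span_min < 0L || ps$span_max < ps$span_min)
      return("wildcard extents must satisfy 0 <= span_min <= span_max")
    if (ps$span_max < 1L)
      return("wildcard with span_max < 1")
  }
  TRUE
}

#' MotifPattern: a PROSITE-dialect motif
#'
#' An ordered list of position specifications, each one of
#' \itemize{
#'   \item a residue class \code{[LIMV]}: exactly one residue drawn from the
#'     listed set;
#'   \item an exclusion class \code{\{G\}}: exactly one standard residue
#'     \emph{not} in the listed set;
#'   \item a bounded wildcard \code{X}, \code{X(n)} or \code{X(m,n)}: a run
#'     of between \code{m} and \code{n} arbitrary residues.
#' }
#'
#' @slot positions list of position specs (see [parsePattern()]).
#' @slot name single character, a label carried into match reports.
#' @slot source free-text provenance (e.g. \code{"general"},
#'   \code{"stringent"}, \code{"refined"}).
#'
#' @seealso [parsePattern()], [patternString()], [scanSequence()]
#' @export
setClass("MotifPattern",
         representation(positions = "list",
                        name = "character",
                        source = "character"),
         prototype(name = "motif", source = ""))

setValidity("MotifPattern", function(object) {
  if (length(object@positions) == 0)
    return("pattern has no positions")
  for (i in seq_along(object@positions)) {
    ok <- .validPositionSpec(object@positions[[i]])
    if (!isTRUE(ok)) return(sprintf("position %d: %s", i, ok))
  }
  if (length(object@name) != 1L)
    return("'name' must be a single string")
  TRUE
})

#' @describeIn MotifPattern-class display a pattern
#' @param object a MotifPattern
#' @export
setMethod("show", "MotifPattern", function(object) {
  sr <- spanRange(object)
  cat(sprintf("MotifPattern '%s'%s: %s\n", object@name,
              if (nzchar(object@source)) paste0(" [", object@source, "]") else "",
              patternString(object)))
  cat(sprintf("  %d position specs, %d key positions, span %d-%d residues\n",
              length(object@positions), keyPositionCount(object),
              sr[[1]], sr[[2]]))
})

#' DiscoveredPattern: a pattern reported by <L,W,K> discovery
#'
#' Positions are expanded to one element per residue column:
#' \code{"X"} (wildcard), a single letter (literal), or a multi-letter
#' string (an equivalence group, e.g. \code{"LIMV"}).
#'
#' @slot positions character vector of column elements.
#' @slot support number of distinct input sequences with >= 1 occurrence.
#' @slot occurrences data.frame with columns \code{seq} (1-based input
#'   sequence index) and \code{offset} (1-based start of the occurrence).
#'
#' @seealso [discoverPatterns()], [asMotifPattern()]
#' @export
setClass("DiscoveredPattern",
         representation(positions = "character",
                        support = "integer",
                        occurrences = "data.frame"))

setValidity("DiscoveredPattern", function(object) {
  p <- object@positions
  if (length(p) == 0) return("empty pattern")
  if (p[1] == "X" || p[length(p)] == "X")
    return("pattern must not start or end with a wildcard")
  occ <- object@occurrences
  if (!all(c("seq", "offset") %in% names(occ)))
    return("occurrences must have columns 'seq' and 'offset'")
  if (object@support != length(unique(occ$seq)))
    return("support must equal the number of distinct sequences in occurrences")
  TRUE
})

#' @describeIn DiscoveredPattern-class display a discovered pattern
#' @param object a DiscoveredPattern
#' @export
setMethod("show", "DiscoveredPattern", function(object) {
  cat(sprintf("DiscoveredPattern %s  (support %d, %d occurrences)\n",
              discoveredString(object), object@support,
              nrow(object@occurrences)))
})

#' PeptideAlignment: labeled peptides placed into a fixed motif frame
#'
#' @slot frame_length number of motif positions (columns).
#' @slot assignment character matrix, one row per peptide, one column per
#'   frame position; gaps are \code{"-"}.
#' @slot gap_position frame column at which short peptides gap (the
#'   \code{X(0,1)} column of the refined motif).
#' @slot peptides the input peptide table (sequence, label, source, note).
#'
#' @seealso [alignPeptides()], [buildUnionMotif()]
#' @export
setClass("PeptideAlignment",
         representation(frame_length = "integer",
                        assignment = "matrix",
                        gap_position = "integer",
                        peptides = "data.frame"))

setValidity("PeptideAlignment", function(object) {
  if (ncol(object@assignment) != object@frame_length)
    return("assignment matrix must have frame_length columns")
  if (nrow(object@assignment) != nrow(object@peptides))
    return("one assignment row per peptide required")
  if (any(object@assignment[, 1] == "-") ||
      any(object@assignment[, object@frame_length] == "-"))
    return("anchored terminal positions must never be gapped")
  TRUE
})

#' @describeIn PeptideAlignment-class display an alignment
#' @param object a PeptideAlignment
#' @export
setMethod("show", "PeptideAlignment", function(object) {
  cat(sprintf("PeptideAlignment: %d peptides x %d frame positions (gap column %d)\n",
              nrow(object@assignment), object@frame_length,
              object@gap_position))
  lab <- object@peptides$label
  for (i in seq_len(min(nrow(object@assignment), 20L)))
    cat(sprintf("  %s  %s\n", paste(object@assignment[i, ], collapse = ""),
                lab[i]))
  if (nrow(object@assignment) > 20L) cat("  ...\n")
})

#' Ontology: a minimal is_a DAG with one root per namespace
#'
#' @slot terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace}.
#' @slot parents named list: term id -> character vector of is_a parents.
#' @slot roots named character vector: namespace -> root term id.
#'
#' @seealso [parseOBO()], [propagateAnnotations()], [enrichTerms()]
#' @export
setClass("Ontology",
         representation(terms = "data.frame",
                        parents = "list",
                        roots = "character"))

setValidity("Ontology", function(object) {
  if (!all(c("id", "name", "namespace") %in% names(object@terms)))
    return("terms must have columns id, name, namespace")
  if (anyDuplicated(object@terms$id))
    return("duplicated term ids")
  TRUE
})

#' @describeIn Ontology-class display an ontology
#' @param object an Ontology
#' @export
setMethod("show", "Ontology", function(object) {
  cat(sprintf("Ontology: %d terms, %d is_a edges, namespaces: %s\n",
              nrow(object@terms),
              sum(lengths(object@parents)),
              paste(names(object@roots), collapse = ", ")))
})
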