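## PROSITE-dialect parser and serializer.
##
## Supported constructs (the dialect used for protease cleavage motifs):
##   [ABC]    residue class        {ABC}  exclusion class
##   X        single wildcard      X(4)   fixed spacer      X(0,1) bounded gap
## Hyphens and whitespace between tokens are optional; residues are
## case-insensitive. Anchors (< >) and class repetition are not part of the
## dialect and are rejected.

.posClass <- function(residues) {
  list(kind = "class", residues = unique(residues),
       span_min = 1L, span_max = 1L)
}

.posExclusion <- function(residues) {
  list(kind = "exclusion", residues = unique(residues),
       span_min = 1L, span_max = 1L)
}

.posWildcard <- function(span_min = 1L, span_max = span_min) {
  list(kind = "wildcard", residues = character(0),
       span_min = as.integer(span_min), span_max = as.integer(span_max))
}

#' Construct a MotifPattern from position specs
#'
#' Low-level constructor; most users will call [parsePattern()].
#'
#' @param positions list of position specs.
#' @param name pattern label carried into match reports.
#' @param source free-text provenance tag.
#' @return a validated [MotifPattern-class] object.
#' @export
newMotifPattern <- function(positions, name = "motif", source = "") {
  new("MotifPattern", positions = positions, name = name, source = source)
}

.parseError <- function(text, offset, msg) {
  stop(sprintf("pattern syntax error at character %d of \"%s\": %s",
               offset, text, msg), call. = FALSE)
}

#' Parse a PROSITE-dialect pattern string
#'
#' Accepts residue classes `[LIMV]`, exclusion classes `{G}`, and bounded
#' wildcards `X`, `X(n)`, `X(m,n)`. Hyphens between tokens are optional and
#' residue letters are case-insensitive. Anything else is a syntax error
#' reported with its character offset.
#'
#' @param text pattern string, e.g. `"[LIMV]X(4)[LIMV]X(2)[LIMV][DE]"`.
#' @param name,source labels stored on the pattern.
#' @return a [MotifPattern-class].
#' @examples
#' p <- parsePattern("[LIMV]X(4)[LIMV]X(2)[LIMV][DE]", name = "general")
#' spanRange(p)          # 10 10
#' keyPositionCount(p)   # 4
#' @export
parsePattern <- function(text, name = "motif", source = "") {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("'text' must be a single non-empty string", call. = FALSE)
  raw <- toupper(text)
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  n <- length(chars)
  positions <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", " ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("[", "{")) {
      closer <- if (ch == "[") "]" else "}"
      j <- i + 1L
      res <- character(0)
      while (j <= n && chars[j] != closer) {
        if (!chars[j] %in% STANDARD_AA)
          .parseError(text, j, sprintf("'%s' is not a standard amino-acid letter",
                                       chars[j]))
        res <- c(res, chars[j])
        j <- j + 1L
      }
      if (j > n) .parseError(text, i, sprintf("unbalanced '%s'", ch))
      if (length(res) == 0) .parseError(text, i, "empty residue class")
      positions[[length(positions) + 1L]] <-
        if (ch == "[") .posClass(res) else .posExclusion(res)
      i <- j + 1L
    } else if (ch == "X") {
      if (i < n && chars[i + 1L] == "(") {
        j <- i + 2L
        num <- character(0)
        while (j <= n && chars[j] != ")") { num <- c(num, chars[j]); j <- j + 1L }
        if (j > n) .parseError(text, i + 1L, "unbalanced '('")
        spec <- paste(num, collapse = "")
        if (!grepl("^[0-9]+(,[0-9]+)?$", spec))
          .parseError(text, i + 2L, sprintf("bad wildcard extent '(%s)'", spec))
        parts <- as.integer(strsplit(spec, ",", fixed = TRUE)[[1]])
        lo <- parts[1]; hi <- if (length(parts) == 2L) parts[2] else parts[1]
        if (lo > hi)
          .parseError(text, i + 2L,
                      sprintf("span_min %d exceeds span_max %d", lo, hi))
        if (hi < 1L)
          .parseError(text, i + 2L, "wildcard extent must allow >= 1 residue")
        positions[[length(positions) + 1L]] <- .posWildcard(lo, hi)
        i <- j + 1L
      } else {
        positions[[length(positions) + 1L]] <- .posWildcard(1L, 1L)
        i <- i + 1L
      }
    } else {
      .parseError(text, i,
                  sprintf("unexpected character '%s' (expected '[', '{' or 'X')",
                          ch))
    }
  }
  if (length(positions) == 0)
    .parseError(text, 1L, "no position specs found")
  newMotifPattern(positions, name = name, source = source)
}

#' Serialize a MotifPattern back to PROSITE-dialect text
#'
#' Inverse of [parsePattern()]: `parsePattern(patternString(p))` reproduces
#' an equal pattern.
#'
#' @param pattern a [MotifPattern-class].
#' @return single character string.
#' @export
patternString <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  vapply(pattern@positions, function(ps) {
    switch(ps$kind,
           class = paste0("[", paste(ps$residues, collapse = ""), "]"),
           exclusion = paste0("{", paste(ps$residues, collapse = ""), "}"),
           wildcard = {
             if (ps$span_min == 1L && ps$span_max == 1L) "X"
             else if (ps$span_min == ps$span_max)
               sprintf("X(%d)", ps$span_min)
             else sprintf("X(%d,%d)", ps$span_min, ps$span_max)
           })
  }, "") |> paste(collapse = "")
}

#' Minimal and maximal residue extent of a pattern match
#'
#' @param pattern a [MotifPattern-class].
#' @return integer vector `c(min_len, max_len)`: the sum of minimal and of
#'   maximal per-position extents.
#' @export
spanRange <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  mins <- vapply(pattern@positions, function(p) p$span_min, 1L)
  maxs <- vapply(pattern@positions, function(p) p$span_max, 1L)
  c(min_len = sum(mins), max_len = sum(maxs))
}

#' Number of constrained (non-wildcard) positions
#'
#' Counts residue classes and exclusion classes; wildcard spacers are
#' backbone and do not count. The general cleavage motif has 4 such key
#' positions within its 10-residue span.
#'
#' @param pattern a [MotifPattern-class].
#' @return integer.
#' @export
keyPositionCount <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  sum(vapply(pattern@positions, function(p) p$kind != "wildcard", NA))
}

## Set-semantics equality (residue order within a class is irrelevant).
samePattern <- function(a, b) {
  if (length(a@positions) != length(b@positions)) return(FALSE)
  for (i in seq_along(a@positions)) {
    pa <- a@positions[[i]]; pb <- b@positions[[i]]
    if (pa$kind != pb$kind) return(FALSE)
    if (pa$span_min != pb$span_min || pa$span_max != pb$span_max) return(FALSE)
    if (!setequal(pa$residues, pb$residues)) return(FALSE)
  }
  TRUE
}
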