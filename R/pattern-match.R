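## ScanProsite-compatible matching.
##
## A match of a pattern is described by a span assignment: one extent per
## position (always 1 for class/exclusion positions, between span_min and
## span_max for wildcards). The not-greedy policy (the ScanProsite default
## used throughout) tries shorter wildcard extents first, leftmost wildcard
## most significant, and returns the first full-pattern success; greedy is
## the exact reverse order.

.MAX_ASSIGNMENTS <- 10000L

## All span assignments of a pattern as an integer matrix (one row per
## assignment, one column per position), in policy order.
.assignments <- function(pattern, greedy = FALSE) {
  ranges <- lapply(pattern@positions,
                   function(p) seq.int(p$span_min, p$span_max))
  ncomb <- prod(lengths(ranges))
  if (ncomb > .MAX_ASSIGNMENTS)
    stop(sprintf("pattern has %d span assignments (limit %d)",
                 ncomb, .MAX_ASSIGNMENTS), call. = FALSE)
  grid <- expand.grid(rev(ranges), KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid[, rev(seq_along(ranges)), drop = FALSE])
  dimnames(grid) <- NULL
  if (greedy) grid <- grid[rev(seq_len(nrow(grid))), , drop = FALSE]
  grid
}

## residues accepted by one position spec
.allowedResidues <- function(ps, strictExclusions = TRUE) {
  switch(ps$kind,
         class = ps$residues,
         exclusion = if (strictExclusions)
           setdiff(STANDARD_AA, ps$residues)
         else setdiff(LETTERS, ps$residues),
         wildcard = LETTERS)
}

## per-position logical membership vectors over a character vector
.membership <- function(pattern, chars, strictExclusions = TRUE) {
  lapply(pattern@positions, function(ps) {
    if (ps$kind == "wildcard") NULL
    else chars %in% .allowedResidues(ps, strictExclusions)
  })
}

#' Anchored pattern match at a fixed offset
#'
#' Attempts to match `pattern` starting exactly at `offset` (1-based).
#' Under the default not-greedy policy wildcard runs try their shortest
#' extent first and the first full-pattern success is returned; with
#' `greedy = TRUE` the longest. Class positions accept only their listed
#' standard residues; exclusion positions accept any standard residue not
#' listed; ambiguity codes (B, J, O, U, X, Z) match neither, only
#' wildcards.
#'
#' @param pattern a [MotifPattern-class].
#' @param sequence protein sequence (character scalar; case-insensitive).
#' @param offset 1-based start position.
#' @param greedy logical wildcard-extent policy.
#' @param strictExclusions if `FALSE`, exclusion classes accept any letter
#'   not listed, including non-standard codes.
#' @return the 1-based inclusive end coordinate of the match, or
#'   `NA_integer_` if the pattern does not match at `offset`.
#' @examples
#' general <- parsePattern("[LIMV]X(4)[LIMV]X(2)[LIMV][DE]")
#' matchAt(general, "VPSANIEGLE", 1)   # 10
#' matchAt(general, "VPDVSLEGPE", 1)   # NA: proline at position 9
#' @export
matchAt <- function(pattern, sequence, offset, greedy = FALSE,
                    strictExclusions = TRUE) {
  stopifnot(is(pattern, "MotifPattern"), is.character(sequence),
            length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (offset < 1L || offset > n)
    stop(sprintf("offset %d out of range 1..%d", offset, n), call. = FALSE)
  mem <- .membership(pattern, chars, strictExclusions)
  asg <- .assignments(pattern, greedy)
  for (r in seq_len(nrow(asg))) {
    ext <- asg[r, ]
    total <- sum(ext)
    if (offset + total - 1L > n) next
    rel <- cumsum(c(0L, ext[-length(ext)]))
    ok <- TRUE
    for (j in seq_along(mem)) {
      if (is.null(mem[[j]])) next
      if (!mem[[j]][offset + rel[j]]) { ok <- FALSE; break }
    }
    if (ok) return(offset + total - 1L)
  }
  NA_integer_
}

## Vectorized single-assignment test: for every offset 1..(n-total+1),
## does this assignment match? Returns a logical vector.
.assignmentHits <- function(mem, positions, ext, n) {
  total <- sum(ext)
  nOff <- n - total + 1L
  if (nOff < 1L) return(logical(0))
  ok <- rep(TRUE, nOff)
  rel <- cumsum(c(0L, ext[-length(ext)]))
  for (j in seq_along(positions)) {
    if (is.null(mem[[j]])) next
    ok <- ok & mem[[j]][seq_len(nOff) + rel[j]]
    if (!any(ok)) break
  }
  ok
}

#' Scan one sequence for motif occurrences
#'
#' Left-to-right scan. Under the default no-overlap policy (the
#' ScanProsite default) the attempt after a hit resumes at `end + 1`;
#' with `overlap = TRUE` every matching offset is reported. The match end
#' at each offset is decided by the wildcard-extent policy (not-greedy
#' default, see [matchAt()]).
#'
#' @inheritParams matchAt
#' @param overlap logical; report overlapping hits?
#' @param sequence_id identifier carried into the hit table.
#' @return data.frame with columns `sequence_id`, `start`, `end` (1-based
#'   inclusive), `matched`, `pattern_name`; zero rows when nothing matches.
#' @examples
#' aa <- parsePattern("[A][A]", name = "AA")
#' scanSequence(aa, "AAAA")                  # hits (1,2) and (3,4)
#' scanSequence(aa, "AAAA", overlap = TRUE)  # hits (1,2), (2,3), (3,4)
#' @export
scanSequence <- function(pattern, sequence, overlap = FALSE, greedy = FALSE,
                         strictExclusions = TRUE, sequence_id = "seq") {
  stopifnot(is(pattern, "MotifPattern"), is.character(sequence),
            length(sequence) == 1L)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  empty <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      pattern_name = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  mem <- .membership(pattern, chars, strictExclusions)
  asg <- .assignments(pattern, greedy)
  endv <- rep(NA_integer_, n)
  for (r in seq_len(nrow(asg))) {
    ext <- asg[r, ]
    hit <- .assignmentHits(mem, pattern@positions, ext, n)
    if (!length(hit)) next
    idx <- which(hit)
    idx <- idx[is.na(endv[idx])]
    endv[idx] <- idx + sum(ext) - 1L
  }
  starts <- which(!is.na(endv))
  if (!length(starts)) return(empty)
  if (!overlap) {
    keep <- integer(0)
    nextpos <- 1L
    for (o in starts) {
      if (o < nextpos) next
      keep <- c(keep, o)
      nextpos <- endv[o] + 1L
    }
    starts <- keep
  }
  data.frame(sequence_id = sequence_id, start = starts,
             end = endv[starts],
             matched = substring(sequence, starts, endv[starts]),
             pattern_name = pattern@name, stringsAsFactors = FALSE)
}

#' Scan a protein database for motif occurrences
#'
#' @inheritParams scanSequence
#' @param db a FASTA file path, a [Biostrings::AAStringSet], or a named
#'   character vector of sequences.
#' @return list with `hits` (the concatenated hit table, input order then
#'   coordinate order) and `protein_count` (number of records with at
#'   least one hit).
#' @export
scanDatabase <- function(pattern, db, overlap = FALSE, greedy = FALSE,
                         strictExclusions = TRUE) {
  seqs <- .asSequenceSet(db)
  tabs <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    tabs[[i]] <- scanSequence(pattern, seqs[[i]], overlap = overlap,
                              greedy = greedy,
                              strictExclusions = strictExclusions,
                              sequence_id = names(seqs)[i])
  }
  hits <- if (length(tabs) == 0L)
    data.frame(sequence_id = character(0), start = integer(0),
               end = integer(0), matched = character(0),
               pattern_name = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, tabs)
  rownames(hits) <- NULL
  list(hits = hits,
       protein_count = sum(vapply(tabs, nrow, 0L) > 0L))
}

## Normalize db input to a named list of upper-case character sequences.
.asSequenceSet <- function(db) {
  if (is(db, "AAStringSet") || is(db, "BStringSet")) {
    seqs <- as.character(db)
  } else if (is.character(db) && length(db) == 1L && file.exists(db)) {
    seqs <- tryCatch(as.character(Biostrings::readAAStringSet(db)),
                     error = function(e)
                       stop(sprintf("cannot read FASTA '%s': %s",
                                    db, conditionMessage(e)), call. = FALSE))
  } else if (is.character(db)) {
    seqs <- db
  } else {
    stop("'db' must be a FASTA path, an AAStringSet, or a character vector",
         call. = FALSE)
  }
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("record_%04d", seq_along(seqs))
  blank <- !nzchar(names(seqs))
  names(seqs)[blank] <- sprintf("record_%04d", which(blank))
  ## FASTA headers: keep the first whitespace-delimited word as the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as.list(toupper(seqs))
}

#' Per-position violations of a pattern by a peptide
#'
#' Aligns the whole peptide against the whole pattern (the peptide length
#' must lie within the pattern's span range) and reports every constrained
#' position whose aligned residue fails its class or exclusion spec. For
#' variable-span patterns, the alignment minimizing the number of
#' violations is evaluated; ties prefer earlier wildcards taking shorter
#' extents. An empty result is equivalent to a full-length anchored match.
#'
#' Positions are reported as 1-based residue coordinates within the
#' aligned peptide (the motif's "site" numbering): the uncleaved
#' AHNAK-repeat peptide VPDVSLEGPE deviates from the general cleavage
#' motif only at position 9, where it carries a proline.
#'
#' @inheritParams matchAt
#' @param peptide peptide sequence whose length is within the pattern span
#'   range.
#' @return data.frame with columns `position` (1-based residue coordinate)
#'   and `observed` (the offending residue); zero rows iff the peptide
#'   matches.
#' @examples
#' general <- parsePattern("[LIMV]X(4)[LIMV]X(2)[LIMV][DE]")
#' violations(general, "VPDVSLEGPE")   # position 9, observed "P"
#' @export
violations <- function(pattern, peptide, strictExclusions = TRUE) {
  stopifnot(is(pattern, "MotifPattern"), is.character(peptide),
            length(peptide) == 1L)
  chars <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  len <- length(chars)
  sr <- spanRange(pattern)
  if (len < sr[[1]] || len > sr[[2]])
    stop(sprintf("peptide length %d outside pattern span range %d-%d",
                 len, sr[[1]], sr[[2]]), call. = FALSE)
  asg <- .assignments(pattern, greedy = FALSE)
  asg <- asg[rowSums(asg) == len, , drop = FALSE]
  if (nrow(asg) == 0L)
    stop("no span assignment consumes the whole peptide", call. = FALSE)
  best <- NULL
  for (r in seq_len(nrow(asg))) {
    ext <- asg[r, ]
    rel <- cumsum(c(0L, ext[-length(ext)]))
    pos <- integer(0); obs <- character(0)
    for (j in seq_along(pattern@positions)) {
      ps <- pattern@positions[[j]]
      if (ps$kind == "wildcard") next
      at <- rel[j] + 1L
      if (!chars[at] %in% .allowedResidues(ps, strictExclusions)) {
        pos <- c(pos, at); obs <- c(obs, chars[at])
      }
    }
    if (is.null(best) || length(pos) < nrow(best)) {
      best <- data.frame(position = pos, observed = obs,
                         stringsAsFactors = FALSE)
      if (nrow(best) == 0L) break
    }
  }
  best
}
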