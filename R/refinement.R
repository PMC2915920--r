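## Motif refinement from labeled cleavage peptides.
##
## The route: place peptides into a fixed 10-position frame anchored at
## both ends (length-9 peptides gap at the frame's variable-spacing
## column), take the position-wise union of residues seen in cleaved
## peptides ("adding" the peptides), turn over-diverse positions into
## wildcards, and finally convert wildcard positions where uncleaved
## peptides — and only uncleaved peptides — show particular residues into
## exclusion classes (the route by which glycine at site 4 becomes {G}).

PEPTIDE_LABELS <- c("cleaved", "partial", "not_cleaved", "nd")

#' Build a labeled-peptide table
#'
#' @param sequence character vector of peptide sequences (standard
#'   residues only).
#' @param label cleavage call, one of `"cleaved"`, `"partial"`,
#'   `"not_cleaved"`, `"nd"` per peptide.
#' @param source source protein/gene per peptide.
#' @param note free text.
#' @return data.frame with columns sequence, label, source, note.
#' @export
labeledPeptides <- function(sequence, label, source = "", note = "") {
  sequence <- toupper(sequence)
  bad <- grepl(sprintf("[^%s]", paste(STANDARD_AA, collapse = "")), sequence)
  if (any(bad))
    stop(sprintf("non-standard residues in peptide(s): %s",
                 paste(sequence[bad], collapse = ", ")), call. = FALSE)
  if (!all(label %in% PEPTIDE_LABELS))
    stop(sprintf("labels must be one of: %s",
                 paste(PEPTIDE_LABELS, collapse = ", ")), call. = FALSE)
  data.frame(sequence = sequence,
             label = rep_len(label, length(sequence)),
             source = rep_len(source, length(sequence)),
             note = rep_len(note, length(sequence)),
             stringsAsFactors = FALSE)
}

#' Read / write a labeled peptide panel as TSV
#'
#' Tab-separated columns `sequence`, `label`, `source`, `note`; lines
#' starting with `#` are treated as provenance headers and skipped.
#'
#' @param path file path.
#' @return `readPeptides`: the validated peptide data.frame.
#' @export
readPeptides <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sequence", "label")
  if (!all(need %in% names(tab)))
    stop(sprintf("peptide TSV must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  labeledPeptides(tab$sequence, tab$label,
                  source = if ("source" %in% names(tab)) tab$source else "",
                  note = if ("note" %in% names(tab)) tab$note else "")
}

#' @rdname readPeptides
#' @param peptides peptide data.frame as from [labeledPeptides()].
#' @param header optional character vector of provenance lines written as
#'   `#`-prefixed comments.
#' @export
writePeptides <- function(peptides, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(peptides, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The in-panel cleavage peptides shipped with the package
#'
#' The 14 sequence-bearing peptides of the published substrate panel:
#' 13 motif-bearing peptides (cleaved, partially cleaved or untested in
#' the fusion-protein assay) plus the uncleaved AHNAK-repeat peptide.
#'
#' @return labeled peptide data.frame (see [labeledPeptides()]).
#' @examples
#' panel <- substratePanel()
#' table(panel$label)
#' @export
substratePanel <- function() {
  readPeptides(system.file("extdata", "capn3_peptides.tsv",
                           package = "CleaveScan", mustWork = TRUE))
}

#' Align labeled peptides into a fixed motif frame
#'
#' Peptides are anchored at frame positions 1 and `frame_length`.
#' Full-length peptides map one residue per position; peptides one residue
#' short place a gap at `gap_position` (the frame column that the refined
#' motif's `X(0,1)` spacer absorbs). Other lengths cannot be reconciled
#' with the frame and error.
#'
#' @param peptides labeled peptide data.frame ([labeledPeptides()]).
#' @param frame a [MotifPattern-class] defining the frame, or an integer
#'   frame length (default a 10-position frame).
#' @param gap_position frame column gapped in short peptides.
#' @return a [PeptideAlignment-class].
#' @export
alignPeptides <- function(peptides, frame = 10L, gap_position = 5L) {
  flen <- if (is(frame, "MotifPattern")) spanRange(frame)[[2]]
          else as.integer(frame)
  if (flen < 2L) stop("frame must have at least 2 positions", call. = FALSE)
  gap_position <- as.integer(gap_position)
  if (gap_position < 2L)
    stop("gap_position must be an interior frame column", call. = FALSE)
  n <- nrow(peptides)
  if (n == 0L) stop("no peptides to align", call. = FALSE)
  mat <- matrix("-", nrow = n, ncol = flen)
  for (i in seq_len(n)) {
    chars <- strsplit(peptides$sequence[i], "", fixed = TRUE)[[1]]
    len <- length(chars)
    if (len == flen) {
      mat[i, ] <- chars
    } else if (len == flen - 1L) {
      if (gap_position >= flen)
        stop("gap_position must be an interior frame column", call. = FALSE)
      mat[i, seq_len(gap_position - 1L)] <- chars[seq_len(gap_position - 1L)]
      mat[i, seq.int(gap_position + 1L, flen)] <-
        chars[seq.int(gap_position, len)]
    } else {
      stop(sprintf(
        "peptide '%s' (length %d) cannot be reconciled with a %d-position frame",
        peptides$sequence[i], len, flen), call. = FALSE)
    }
  }
  new("PeptideAlignment", frame_length = as.integer(flen), assignment = mat,
      gap_position = as.integer(gap_position), peptides = peptides)
}

.positiveRows <- function(alignment, includePartial = TRUE) {
  lab <- alignment@peptides$label
  which(lab == "cleaved" | (includePartial & lab == "partial"))
}

#' Build the position-wise union motif from positive peptides
#'
#' Each frame position becomes the residue class containing every residue
#' observed there among positive (cleaved, and by default partially
#' cleaved) peptides. Positions whose union reaches
#' `diversity_threshold` residues are considered unconstrained backbone
#' and become wildcards (candidate sites for exclusion classes, see
#' [addExclusions()]). A position gapped in any positive peptide becomes
#' the variable spacer `X(0,1)`.
#'
#' @param alignment a [PeptideAlignment-class].
#' @param includePartial count partially cleaved peptides as positives?
#' @param diversity_threshold union size at which a position turns into a
#'   wildcard.
#' @param name,source labels for the motif.
#' @return a [MotifPattern-class].
#' @export
buildUnionMotif <- function(alignment, includePartial = TRUE,
                            diversity_threshold = 7L,
                            name = "refined", source = "refined") {
  pos_rows <- .positiveRows(alignment, includePartial)
  if (length(pos_rows) == 0L)
    stop("no positive peptides in the alignment", call. = FALSE)
  mat <- alignment@assignment[pos_rows, , drop = FALSE]
  positions <- vector("list", alignment@frame_length)
  for (c in seq_len(alignment@frame_length)) {
    col <- mat[, c]
    gapped <- any(col == "-")
    res <- unique(col[col != "-"])
    if (gapped) {
      positions[[c]] <- .posWildcard(0L, 1L)
    } else if (length(res) >= diversity_threshold) {
      positions[[c]] <- .posWildcard(1L, 1L)
    } else {
      positions[[c]] <- .posClass(res)
    }
  }
  newMotifPattern(positions, name = name, source = source)
}

#' Add negative-only exclusion classes to wildcard positions
#'
#' For each single-residue wildcard position of the motif, residues
#' observed there in not-cleaved peptides but never in positive peptides
#' become an exclusion class (any standard residue except those). This is
#' the step that places `{G}` at a backbone site where glycine appears
#' only in dysfunctional peptides. Positions with no negative-only
#' residue, and the variable `X(0,1)` spacer, are left unchanged; with no
#' negative peptides the motif is returned unchanged.
#'
#' @param motif the union motif from [buildUnionMotif()].
#' @param alignment the [PeptideAlignment-class] the motif was built from.
#' @param includePartial same setting as used for the union motif.
#' @return a [MotifPattern-class].
#' @export
addExclusions <- function(motif, alignment, includePartial = TRUE) {
  stopifnot(is(motif, "MotifPattern"))
  neg_rows <- which(alignment@peptides$label == "not_cleaved")
  if (length(neg_rows) == 0L) return(motif)
  pos_rows <- .positiveRows(alignment, includePartial)
  positions <- motif@positions
  if (length(positions) != alignment@frame_length)
    stop("motif positions do not map onto the alignment frame", call. = FALSE)
  for (c in seq_along(positions)) {
    ps <- positions[[c]]
    if (ps$kind != "wildcard" || ps$span_min != 1L || ps$span_max != 1L)
      next
    neg_res <- unique(alignment@assignment[neg_rows, c])
    pos_res <- unique(alignment@assignment[pos_rows, c])
    only_neg <- setdiff(setdiff(neg_res, "-"), pos_res)
    if (length(only_neg) > 0L)
      positions[[c]] <- .posExclusion(only_neg)
  }
  newMotifPattern(positions, name = motif@name, source = motif@source)
}

#' Refine a motif from a labeled peptide panel
#'
#' Convenience wrapper: [alignPeptides()], [buildUnionMotif()],
#' [addExclusions()] in sequence.
#'
#' @inheritParams alignPeptides
#' @inheritParams buildUnionMotif
#' @return a [MotifPattern-class].
#' @export
refineMotif <- function(peptides, frame = 10L, gap_position = 5L,
                        includePartial = TRUE, diversity_threshold = 7L,
                        name = "refined") {
  aln <- alignPeptides(peptides, frame = frame, gap_position = gap_position)
  motif <- buildUnionMotif(aln, includePartial = includePartial,
                           diversity_threshold = diversity_threshold,
                           name = name)
  addExclusions(motif, aln, includePartial = includePartial)
}

#' Jackknife contribution of each construction peptide to a motif
#'
#' The motif's residue classes are a set of (position, residue) pairs.
#' The contribution of a peptide is the fraction of those pairs that its
#' own aligned residues support; the mean over construction peptides
#' summarizes how much any single peptide accounts for the motif (1 iff
#' all peptides are identical, small when the classes pool diverse
#' residues).
#'
#' @param motif the refined [MotifPattern-class].
#' @param alignment the [PeptideAlignment-class] it was built from.
#' @param includePartial same setting as used for the union motif.
#' @return list with `per_peptide` (named numeric fractions in \[0, 1\])
#'   and `mean`.
#' @export
jackknifeContribution <- function(motif, alignment, includePartial = TRUE) {
  stopifnot(is(motif, "MotifPattern"))
  pos_rows <- .positiveRows(alignment, includePartial)
  if (length(pos_rows) == 0L)
    stop("no positive peptides", call. = FALSE)
  if (length(motif@positions) != alignment@frame_length)
    stop("motif positions do not map onto the alignment frame", call. = FALSE)
  pairs <- list()  # per class position: residue vector
  for (c in seq_along(motif@positions)) {
    ps <- motif@positions[[c]]
    if (ps$kind == "class")
      pairs[[as.character(c)]] <- ps$residues
  }
  total <- sum(lengths(pairs))
  if (total == 0L)
    stop("motif has no residue classes to attribute", call. = FALSE)
  per <- vapply(pos_rows, function(i) {
    supported <- 0L
    for (c in names(pairs)) {
      r <- alignment@assignment[i, as.integer(c)]
      if (r %in% pairs[[c]]) supported <- supported + 1L
    }
    supported / total
  }, 0)
  names(per) <- alignment@peptides$sequence[pos_rows]
  list(per_peptide = per, mean = mean(per))
}
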