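## <L,W,K> pattern discovery over a chemical-equivalence alphabet.
##
## A pattern is a vector of column elements: "X" (wildcard), a single
## residue letter (literal), or an equivalence group (multi-letter string,
## e.g. "LIMV"). <L,W>-validity: every run of exactly L consecutive
## non-wildcard elements spans <= W columns. A reported pattern occurs in
## >= K input sequences, carries its exact occurrence list, and is maximal:
## no more specific or longer valid pattern retains all its occurrences.
##
## The implementation follows the scan/convolve decomposition of TEIRESIAS
## at desk scale: elementary patterns (exactly L non-wildcard elements) are
## enumerated exhaustively, then combined by occurrence-list intersection
## and closed under agreement-preserving specialization and extension. The
## original algorithm's performance engineering (prefix trees, offset-list
## compression) is intentionally absent.

#' Default chemical-equivalence grouping of the 20 amino acids
#'
#' Residues grouped by chemical property: aliphatic (L, I, M, V), acidic
#' (D, E), basic (K, R), aromatic (F, Y, W), hydroxyl (S, T), amide
#' (N, Q), small (A, G), and singleton groups for C, P and H. The grouping
#' is a partition; alternatives can be supplied to [discoverPatterns()].
#'
#' @return named list of character vectors partitioning [STANDARD_AA].
#' @export
defaultGrouping <- function() {
  list(aliphatic = c("L", "I", "M", "V"),
       acidic    = c("D", "E"),
       basic     = c("K", "R"),
       aromatic  = c("F", "Y", "W"),
       hydroxyl  = c("S", "T"),
       amide     = c("N", "Q"),
       small     = c("A", "G"),
       cysteine  = "C",
       proline   = "P",
       histidine = "H")
}

.checkGrouping <- function(grouping) {
  all_res <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(all_res))
    stop("equivalence groups must be pairwise disjoint", call. = FALSE)
  if (!setequal(all_res, STANDARD_AA))
    stop("equivalence groups must cover exactly the 20 standard residues",
         call. = FALSE)
  invisible(grouping)
}

## residue -> group element string ("LIMV", "DE", ...)
.groupMap <- function(grouping) {
  m <- character(0)
  for (g in grouping) {
    el <- paste(g, collapse = "")
    m[g] <- el
  }
  m
}

## does element match residue?
.elementMatches <- function(element, residue) {
  element == "X" || grepl(residue, element, fixed = TRUE)
}

## full occurrence list of an element-vector pattern over a corpus
.naiveOccurrences <- function(elements, seqChars) {
  len <- length(elements)
  out_seq <- integer(0); out_off <- integer(0)
  for (si in seq_along(seqChars)) {
    chars <- seqChars[[si]]
    n <- length(chars)
    if (n < len) next
    for (o in seq_len(n - len + 1L)) {
      ok <- TRUE
      for (c in seq_len(len)) {
        e <- elements[c]
        if (e == "X") next
        if (!grepl(chars[o + c - 1L], e, fixed = TRUE)) { ok <- FALSE; break }
      }
      if (ok) { out_seq <- c(out_seq, si); out_off <- c(out_off, o) }
    }
  }
  data.frame(seq = out_seq, offset = out_off)
}

.supportOf <- function(occ, mode = "sequence") {
  if (mode == "occurrence") nrow(occ) else length(unique(occ$seq))
}

## <L,W>-validity for a sorted vector of specified (non-wildcard) column
## positions; patterns with fewer than L specified columns are vacuously
## valid.
.lwValid <- function(cols, L, W) {
  m <- length(cols)
  if (m < L) return(TRUE)
  for (i in seq_len(m - L + 1L))
    if (cols[i + L - 1L] - cols[i] + 1L > W) return(FALSE)
  TRUE
}

.patternKey <- function(elements) paste(elements, collapse = "|")

.newDiscovered <- function(elements, occ, supportMode = "sequence") {
  occ <- occ[order(occ$seq, occ$offset), , drop = FALSE]
  rownames(occ) <- NULL
  new("DiscoveredPattern", positions = elements,
      support = as.integer(length(unique(occ$seq))),
      occurrences = occ)
}

#' Enumerate elementary <L,W,K> patterns
#'
#' An elementary pattern has exactly `L` non-wildcard elements spanning at
#' most `W` columns. All elementary patterns with support at least `K` are
#' returned with exact occurrence lists, including every specialization
#' (group element resolved to a literal) that itself keeps support at
#' least `K`.
#'
#' @param seqs character vector of protein/peptide sequences.
#' @param grouping equivalence grouping, see [defaultGrouping()].
#' @param L minimum number of non-wildcard elements (>= 2).
#' @param W maximum extent (columns) of any L consecutive non-wildcard
#'   elements (>= L).
#' @param K minimum support (>= 2).
#' @param supportMode `"sequence"` counts distinct sequences containing
#'   the pattern (the usual reading of "number of proteins"),
#'   `"occurrence"` counts total occurrences.
#' @return list of [DiscoveredPattern-class] objects.
#' @export
enumerateElementary <- function(seqs, grouping = defaultGrouping(),
                                L, W, K, supportMode = c("sequence",
                                                         "occurrence")) {
  supportMode <- match.arg(supportMode)
  .checkDiscoveryParams(seqs, L, W, K)
  .checkGrouping(grouping)
  gmap <- .groupMap(grouping)
  seqChars <- lapply(toupper(seqs), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])

  ## pass 1: group-level patterns, aggregated by key
  acc <- new.env(parent = emptyenv())
  for (si in seq_along(seqChars)) {
    chars <- seqChars[[si]]
    n <- length(chars)
    if (n < L) next
    for (i in seq_len(n - L + 1L)) {
      hi <- min(i + W - 1L, n)
      pool <- seq.int(i + 1L, hi)
      if (length(pool) < L - 1L) next
      combs <- if (length(pool) == L - 1L) list(pool)
               else utils::combn(pool, L - 1L, simplify = FALSE)
      for (cc in combs) {
        cols <- c(i, cc)
        len <- cols[L] - i + 1L
        elements <- rep("X", len)
        resi <- chars[cols]
        if (!all(resi %in% STANDARD_AA)) next
        elements[cols - i + 1L] <- gmap[resi]
        key <- .patternKey(elements)
        rec <- acc[[key]]
        if (is.null(rec)) {
          acc[[key]] <- list(elements = elements, seq = si, offset = i)
        } else {
          rec$seq <- c(rec$seq, si); rec$offset <- c(rec$offset, i)
          acc[[key]] <- rec
        }
      }
    }
  }

  out <- list()
  for (key in ls(acc)) {
    rec <- acc[[key]]
    occ <- data.frame(seq = rec$seq, offset = rec$offset)
    if (.supportOf(occ, supportMode) < K) next
    ## pass 2: expand specializations (group -> observed literal) that
    ## keep support; the group-level pattern itself is always kept
    nw <- which(rec$elements != "X")
    choices <- lapply(nw, function(c) {
      obs <- unique(vapply(seq_len(nrow(occ)), function(r)
        seqChars[[occ$seq[r]]][occ$offset[r] + c - 1L], ""))
      grp <- rec$elements[c]
      if (nchar(grp) > 1L) c(grp, obs) else grp
    })
    grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      el <- rec$elements
      el[nw] <- unlist(grid[r, ], use.names = FALSE)
      keep <- vapply(seq_len(nrow(occ)), function(q) {
        chars <- seqChars[[occ$seq[q]]]
        all(vapply(seq_along(nw), function(t) {
          grepl(chars[occ$offset[q] + nw[t] - 1L], el[nw[t]], fixed = TRUE)
        }, NA))
      }, NA)
      socc <- occ[keep, , drop = FALSE]
      if (.supportOf(socc, supportMode) < K) next
      out[[.patternKey(el)]] <- .newDiscovered(el, socc, supportMode)
    }
  }
  unname(out)
}

.checkDiscoveryParams <- function(seqs, L, W, K) {
  if (length(seqs) == 0) stop("'seqs' must be non-empty", call. = FALSE)
  if (L < 2L) stop("L must be >= 2", call. = FALSE)
  if (W < L) stop("W must be >= L", call. = FALSE)
  if (K < 2L) stop("support threshold K must be >= 2", call. = FALSE)
  invisible(TRUE)
}

## Most specific common refinement of two elements; NULL if incomparable.
.meetElements <- function(a, b) {
  if (a == b) return(a)
  if (a == "X") return(b)
  if (b == "X") return(a)
  if (nchar(a) == 1L && grepl(a, b, fixed = TRUE)) return(a)
  if (nchar(b) == 1L && grepl(b, a, fixed = TRUE)) return(b)
  NULL
}

## Close a pattern over its (exact) occurrence list: specialize group
## columns to literals and add flanking/interior columns wherever every
## occurrence agrees, as far as <L,W>-validity allows. Returns a list of
## one or more closed patterns (several when validity forces a choice
## among addable columns), each as list(elements, occ).
.closePattern <- function(elements, occ, seqChars, gmap, L, W) {
  len <- length(elements)
  nocc <- nrow(occ)
  ## column window reachable by every occurrence
  left_room <- min(occ$offset) - 1L
  right_room <- min(vapply(seq_len(nocc), function(r)
    length(seqChars[[occ$seq[r]]]) - (occ$offset[r] + len - 1L), 0L))
  cand_cols <- seq.int(1L - left_room, len + right_room)
  consensus <- vapply(cand_cols, function(c) {
    resi <- vapply(seq_len(nocc), function(r)
      seqChars[[occ$seq[r]]][occ$offset[r] + c - 1L], "")
    if (!all(resi %in% STANDARD_AA)) return(NA_character_)
    if (all(resi == resi[1])) return(resi[1])
    g <- unique(gmap[resi])
    if (length(g) == 1L) g else NA_character_
  }, "")
  names(consensus) <- as.character(cand_cols)

  base <- elements
  ## specialization of existing columns never affects validity
  for (c in seq_len(len)) {
    cons <- consensus[[as.character(c)]]
    if (!is.na(cons)) {
      m <- .meetElements(base[c], cons)
      if (!is.null(m)) base[c] <- m
    }
  }
  spec_cols <- which(base != "X")
  addable <- cand_cols[!is.na(consensus)]
  addable <- setdiff(addable, spec_cols)
  if (length(addable) == 0L)
    return(list(.rebase(base, spec_cols, occ)))

  ## common case: everything can be added at once
  if (.lwValid(sort(c(spec_cols, addable)), L, W)) {
    full <- sort(c(spec_cols, addable))
    out <- rep("X", max(full) - min(full) + 1L)
    for (c in full) {
      v <- if (c >= 1L && c <= len) base[c] else consensus[[as.character(c)]]
      if (c >= 1L && c <= len && base[c] == "X") v <- consensus[[as.character(c)]]
      out[c - min(full) + 1L] <- v
    }
    occ2 <- occ; occ2$offset <- occ2$offset + (min(full) - 1L)
    return(list(list(elements = out, occ = occ2)))
  }

  ## validity forces a choice: enumerate maximal valid supersets
  if (length(addable) > 14L) addable <- addable[seq_len(14L)]
  results <- list()
  subsets <- .maximalValidSupersets(spec_cols, addable, L, W)
  for (ss in subsets) {
    full <- sort(c(spec_cols, ss))
    out <- rep("X", max(full) - min(full) + 1L)
    for (c in full) {
      v <- if (c >= 1L && c <= len && base[c] != "X") base[c]
      else consensus[[as.character(c)]]
      out[c - min(full) + 1L] <- v
    }
    occ2 <- occ; occ2$offset <- occ2$offset + (min(full) - 1L)
    results[[length(results) + 1L]] <- list(elements = out, occ = occ2)
  }
  results
}

.rebase <- function(base, spec_cols, occ) {
  lo <- min(spec_cols); hi <- max(spec_cols)
  occ2 <- occ; occ2$offset <- occ2$offset + (lo - 1L)
  list(elements = base[lo:hi], occ = occ2)
}

## All maximal (by inclusion) subsets S of 'addable' such that
## fixed ∪ S is <L,W>-valid.
.maximalValidSupersets <- function(fixed, addable, L, W) {
  n <- length(addable)
  valid <- list()
  for (mask in seq.int(2^n - 1L, 0L)) {
    sel <- addable[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    cols <- sort(c(fixed, sel))
    if (.lwValid(cols, L, W)) valid[[length(valid) + 1L]] <- sel
  }
  ## keep maximal by inclusion
  keep <- rep(TRUE, length(valid))
  for (i in seq_along(valid)) for (j in seq_along(valid)) {
    if (i != j && keep[i] && all(valid[[i]] %in% valid[[j]]) &&
        length(valid[[j]]) > length(valid[[i]])) keep[i] <- FALSE
  }
  valid[keep]
}

#' Combine elementary patterns into maximal patterns
#'
#' Convolution phase: patterns are pairwise merged wherever their column
#' elements are compatible on the overlap, the merged occurrence list is
#' the intersection of the parents' lists (support recomputed exactly),
#' and every pattern is closed under agreement-preserving specialization
#' and extension. Only maximal patterns survive: a pattern is dropped when
#' a strictly more specific or longer pattern retains exactly the same
#' occurrences.
#'
#' @param elementary list of [DiscoveredPattern-class] from
#'   [enumerateElementary()].
#' @param seqs the corpus the elementary patterns were discovered in.
#' @inheritParams enumerateElementary
#' @return list of maximal [DiscoveredPattern-class] objects.
#' @export
convolvePatterns <- function(elementary, seqs, grouping = defaultGrouping(),
                             L, W, K, supportMode = c("sequence",
                                                      "occurrence")) {
  supportMode <- match.arg(supportMode)
  .checkGrouping(grouping)
  gmap <- .groupMap(grouping)
  seqChars <- lapply(toupper(seqs), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])

  pool <- new.env(parent = emptyenv())   # key -> list(elements, occ)
  queue <- list()
  addPattern <- function(elements, occ) {
    if (.supportOf(occ, supportMode) < K) return(invisible(NULL))
    closed <- .closePattern(elements, occ, seqChars, gmap, L, W)
    for (cl in closed) {
      key <- .patternKey(cl$elements)
      if (is.null(pool[[key]])) {
        pool[[key]] <- cl
        queue[[length(queue) + 1L]] <<- cl
      }
    }
    invisible(NULL)
  }
  for (p in elementary) addPattern(p@positions, p@occurrences)

  guard <- 0L
  while (length(queue) > 0L) {
    guard <- guard + 1L
    if (guard > 20000L) stop("convolution did not converge", call. = FALSE)
    p <- queue[[1L]]; queue <- queue[-1L]
    others <- ls(pool)
    for (key in others) {
      q <- pool[[key]]
      for (merged in .mergePatterns(p, q, L, W))
        addPattern(merged$elements, merged$occ)
    }
  }

  all_pat <- lapply(ls(pool), function(k) pool[[k]])
  all_pat <- Filter(function(p) sum(p$elements != "X") >= L, all_pat)
  keep <- .maximalOnly(all_pat)
  res <- lapply(keep, function(p)
    .newDiscovered(p$elements, p$occ, supportMode))
  res
}

## Try every alignment of q against p with a compatible overlap of at
## least one column; return the list of genuine merges.
.mergePatterns <- function(p, q, L, W) {
  lp <- length(p$elements); lq <- length(q$elements)
  merges <- list()
  for (d in seq.int(-(lq - 1L), lp - 1L)) {
    ## q's column c aligns to p's column c + d
    lo <- min(1L, 1L + d); hi <- max(lp, lq + d)
    mel <- rep("X", hi - lo + 1L)
    ok <- TRUE
    for (c in seq.int(lo, hi)) {
      a <- if (c >= 1L && c <= lp) p$elements[c] else "X"
      bq <- c - d
      b <- if (bq >= 1L && bq <= lq) q$elements[bq] else "X"
      m <- .meetElements(a, b)
      if (is.null(m)) { ok <- FALSE; break }
      mel[c - lo + 1L] <- m
    }
    if (!ok) next
    cols <- which(mel != "X")
    if (!.lwValid(cols, L, W)) next
    ## occurrence intersection (offsets are pattern starts)
    po <- p$occ; qo <- q$occ
    pk <- paste(po$seq, po$offset, sep = ":")
    qk <- paste(qo$seq, qo$offset - d, sep = ":")
    common <- intersect(pk, qk)
    if (length(common) == 0L) next
    sel <- po[pk %in% common, , drop = FALSE]
    ## re-anchor at merged pattern start
    sel$offset <- sel$offset + (lo - 1L)
    ## only a genuine combination is interesting
    if (identical(mel, p$elements) || identical(mel, q$elements)) next
    merges[[length(merges) + 1L]] <- list(elements = mel, occ = sel)
  }
  merges
}

## drop patterns subsumed by a strictly more specific/longer pattern with
## identical occurrences
.maximalOnly <- function(pats) {
  n <- length(pats)
  if (n <= 1L) return(pats)
  keep <- rep(TRUE, n)
  sig <- vapply(pats, function(p) {
    o <- p$occ[order(p$occ$seq, p$occ$offset), ]
    paste(nrow(o), paste(o$seq, collapse = ","))
  }, "")
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j || sig[i] != sig[j]) next
      if (.subsumedBy(pats[[i]], pats[[j]])) { keep[i] <- FALSE; break }
    }
  }
  pats[keep]
}

## TRUE if p's occurrence set equals q's (up to a constant shift) and q is
## strictly more specific or longer than p.
.subsumedBy <- function(p, q) {
  po <- p$occ[order(p$occ$seq, p$occ$offset), ]
  qo <- q$occ[order(q$occ$seq, q$occ$offset), ]
  if (nrow(po) != nrow(qo)) return(FALSE)
  if (!all(po$seq == qo$seq)) return(FALSE)
  d <- po$offset[1] - qo$offset[1]
  if (!all(po$offset - qo$offset == d)) return(FALSE)
  ## q column c sits at p column c - d
  lp <- length(p$elements); lq <- length(q$elements)
  strictly <- FALSE
  for (c in seq_len(lq)) {
    pc <- c - d
    a <- if (pc >= 1L && pc <= lp) p$elements[pc] else "X"
    b <- q$elements[c]
    m <- .meetElements(a, b)
    if (is.null(m) || m != b) return(FALSE)  # q must refine p columnwise
    if (b != a) strictly <- TRUE
  }
  ## every specified column of p must be covered by q
  for (c in which(p$elements != "X")) {
    qc <- c + d
    if (qc < 1L || qc > lq || q$elements[qc] == "X") return(FALSE)
  }
  strictly || lq > lp
}

#' Discover maximal <L,W,K> patterns in a sequence corpus
#'
#' Runs [enumerateElementary()] followed by [convolvePatterns()] and ranks
#' the maximal patterns by support (descending), number of non-wildcard
#' elements (descending), span (ascending), then pattern text. Applied to
#' the panel of cleaved protease-substrate peptides with L = 4, W = 10,
#' K = panel size, this is the route that yields the general cleavage
#' motif.
#'
#' @inheritParams enumerateElementary
#' @return list of [DiscoveredPattern-class], best first.
#' @examples
#' seqs <- rep("LAAAALAALD", 10)
#' top <- discoverPatterns(seqs, L = 4, W = 10, K = 10)[[1]]
#' discoveredString(top)   # the sequence itself is the maximal pattern
#' @export
discoverPatterns <- function(seqs, grouping = defaultGrouping(), L, W, K,
                             supportMode = c("sequence", "occurrence")) {
  supportMode <- match.arg(supportMode)
  elem <- enumerateElementary(seqs, grouping, L, W, K, supportMode)
  maximal <- convolvePatterns(elem, seqs, grouping, L, W, K, supportMode)
  if (length(maximal) == 0L) return(list())
  supp <- vapply(maximal, function(p)
    .supportOf(p@occurrences, supportMode), 0L)
  nspec <- vapply(maximal, function(p) sum(p@positions != "X"), 0L)
  span <- vapply(maximal, function(p) length(p@positions), 0L)
  txt <- vapply(maximal, discoveredString, "")
  maximal[order(-supp, -nspec, span, txt)]
}

#' Render a discovered pattern as PROSITE-dialect text
#'
#' Literals print as bare letters, groups as bracketed classes, wildcard
#' runs as `X(n)`.
#'
#' @param pattern a [DiscoveredPattern-class].
#' @return character scalar.
#' @export
discoveredString <- function(pattern) {
  el <- if (is(pattern, "DiscoveredPattern")) pattern@positions else pattern
  out <- character(0)
  i <- 1L
  while (i <= length(el)) {
    if (el[i] == "X") {
      j <- i
      while (j < length(el) && el[j + 1L] == "X") j <- j + 1L
      n <- j - i + 1L
      out <- c(out, if (n == 1L) "X" else sprintf("X(%d)", n))
      i <- j + 1L
    } else {
      out <- c(out, if (nchar(el[i]) == 1L) el[i]
               else paste0("[", el[i], "]"))
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

#' Convert a discovered pattern to a MotifPattern
#'
#' @param pattern a [DiscoveredPattern-class].
#' @param name,source labels for the resulting motif.
#' @return a [MotifPattern-class] usable with [scanSequence()] etc.
#' @export
asMotifPattern <- function(pattern, name = "discovered", source = "discovery") {
  stopifnot(is(pattern, "DiscoveredPattern"))
  positions <- list()
  i <- 1L
  el <- pattern@positions
  while (i <= length(el)) {
    if (el[i] == "X") {
      j <- i
      while (j < length(el) && el[j + 1L] == "X") j <- j + 1L
      positions[[length(positions) + 1L]] <- .posWildcard(j - i + 1L)
      i <- j + 1L
    } else {
      positions[[length(positions) + 1L]] <-
        .posClass(strsplit(el[i], "", fixed = TRUE)[[1]])
      i <- i + 1L
    }
  }
  newMotifPattern(positions, name = name, source = source)
}
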