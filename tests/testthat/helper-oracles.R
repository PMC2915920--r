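## Independent oracles used across the suite. Deliberately implemented by
## plain recursion / exhaustive enumeration, sharing no code with the
## package's matching and discovery engines.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## residues a position spec accepts, re-derived from first principles
oracleAllowed <- function(ps) {
  if (ps$kind == "class") return(ps$residues)
  if (ps$kind == "exclusion") return(setdiff(AA20, ps$residues))
  LETTERS
}

## every end coordinate reachable by the full pattern anchored at offset
oracleMatchEnds <- function(pattern, chars, offset) {
  specs <- pattern@positions
  rec <- function(pi, pos) {
    if (pi > length(specs)) return(pos - 1L)
    ps <- specs[[pi]]
    ends <- integer(0)
    if (ps$kind == "wildcard") {
      for (e in seq.int(ps$span_min, ps$span_max)) {
        if (pos + e - 1L > length(chars)) break
        ends <- c(ends, rec(pi + 1L, pos + e))
      }
    } else {
      if (pos <= length(chars) && chars[pos] %in% oracleAllowed(ps))
        ends <- rec(pi + 1L, pos + 1L)
    }
    ends
  }
  rec(1L, offset)
}

## overlap-mode hit set by brute force: enumerate all (offset,
## span-assignment) combinations, then keep one hit per matching offset
## at the not-greedy (shortest) extent
oracleScanOverlap <- function(pattern, sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  hits <- data.frame(start = integer(0), end = integer(0))
  for (o in seq_along(chars)) {
    ends <- oracleMatchEnds(pattern, chars, o)
    if (length(ends) > 0L)
      hits <- rbind(hits, data.frame(start = o, end = min(ends)))
  }
  hits
}

## random pattern over the supported dialect
randomPattern <- function(max_positions = 6L) {
  n <- sample.int(max_positions, 1L)
  positions <- lapply(seq_len(n), function(i) {
    kind <- sample(c("class", "exclusion", "wildcard"), 1L,
                   prob = c(0.5, 0.2, 0.3))
    if (kind == "wildcard") {
      lo <- sample(0:2, 1L)
      list(kind = "wildcard", residues = character(0),
           span_min = lo, span_max = lo + sample(0:2, 1L))
    } else {
      list(kind = kind,
           residues = sample(AA20, sample.int(6L, 1L)),
           span_min = 1L, span_max = 1L)
    }
  })
  ## keep at least one constrained position and a legal first wildcard
  if (all(vapply(positions, function(p) p$kind == "wildcard", NA)))
    positions[[1]] <- list(kind = "class", residues = sample(AA20, 3L),
                           span_min = 1L, span_max = 1L)
  for (i in seq_along(positions))
    if (positions[[i]]$kind == "wildcard" && positions[[i]]$span_max == 0L)
      positions[[i]]$span_max <- 1L
  newMotifPattern(positions, name = "random")
}

randomSequence <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## ---- hypergeometric tail by exhaustive subset enumeration -------------

## P(overlap >= k) when drawing n from N with K marked, by enumerating
## all C(N, n) subsets
oracleHyperTail <- function(k, K, n, N) {
  mean(oracleOverlapCounts(K, n, N) >= k)
}

## overlap with the first K elements for every n-subset of 1..N
oracleOverlapCounts <- function(K, n, N) {
  if (n == 0L || N == 0L) return(0L)
  subsets <- utils::combn(N, n)
  colSums(matrix(subsets <= K, nrow = nrow(subsets)))
}

## ---- ancestor closure by BFS over an edge list ------------------------

oracleAncestors <- function(parents, id) {
  out <- character(0)
  frontier <- parents[[id]]
  while (length(frontier) > 0L) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), out)
  }
  out
}

## ---- exhaustive <L,W,K> maximal-pattern oracle ------------------------

## element vocabulary per residue: itself, its group, or X
oracleGroupMap <- function(grouping) {
  m <- character(0)
  for (g in grouping) m[g] <- paste(g, collapse = "")
  m
}

oracleElementMatch <- function(element, residue) {
  element == "X" || grepl(residue, element, fixed = TRUE)
}

oracleOccurrences <- function(elements, seqChars) {
  len <- length(elements)
  res <- list()
  for (si in seq_along(seqChars)) {
    chars <- seqChars[[si]]
    if (length(chars) < len) next
    for (o in seq_len(length(chars) - len + 1L)) {
      ok <- all(vapply(seq_len(len), function(c)
        oracleElementMatch(elements[c], chars[o + c - 1L]), NA))
      if (ok) res[[length(res) + 1L]] <- c(si, o)
    }
  }
  if (length(res) == 0L) return(data.frame(seq = integer(0),
                                           offset = integer(0)))
  m <- do.call(rbind, res)
  data.frame(seq = m[, 1], offset = m[, 2])
}

oracleLWValid <- function(cols, L, W) {
  m <- length(cols)
  if (m < L) return(TRUE)
  all(vapply(seq_len(m - L + 1L), function(i)
    cols[i + L - 1L] - cols[i] + 1L <= W, NA))
}

## all <L,W>-valid candidate patterns that occur somewhere in the corpus,
## with support >= K (sequence mode)
oracleCandidates <- function(seqChars, grouping, L, W, K) {
  gmap <- oracleGroupMap(grouping)
  seen <- new.env(parent = emptyenv())
  for (si in seq_along(seqChars)) {
    chars <- seqChars[[si]]
    n <- length(chars)
    for (i in seq_len(n)) {
      for (j in seq.int(i, n)) {
        w <- j - i + 1L
        ## enumerate element choices column by column
        build <- function(c, acc) {
          if (c > j) {
            if (acc[1] == "X" || acc[w] == "X") return(invisible(NULL))
            cols <- which(acc != "X")
            if (length(cols) < L) return(invisible(NULL))
            if (!oracleLWValid(cols, L, W)) return(invisible(NULL))
            seen[[paste(acc, collapse = "|")]] <- acc
            return(invisible(NULL))
          }
          r <- chars[c - i + 1L + i - 1L]
          for (el in unique(c("X", gmap[[r]], r)))
            build(c + 1L, c(acc, el))
          invisible(NULL)
        }
        build(i, character(0))
      }
    }
  }
  out <- list()
  for (key in ls(seen)) {
    elements <- seen[[key]]
    occ <- oracleOccurrences(elements, seqChars)
    if (length(unique(occ$seq)) >= K)
      out[[key]] <- list(elements = elements, occ = occ)
  }
  out
}

## q strictly refines p (same occurrence set up to shift, more specific
## or longer)
oracleRefines <- function(p, q) {
  po <- p$occ[order(p$occ$seq, p$occ$offset), ]
  qo <- q$occ[order(q$occ$seq, q$occ$offset), ]
  if (nrow(po) != nrow(qo) || !all(po$seq == qo$seq)) return(FALSE)
  d <- po$offset[1] - qo$offset[1]
  if (!all(po$offset - qo$offset == d)) return(FALSE)
  lp <- length(p$elements); lq <- length(q$elements)
  strict <- lq > lp
  for (c in seq_len(lq)) {
    pc <- c - d
    a <- if (pc >= 1L && pc <= lp) p$elements[pc] else "X"
    b <- q$elements[c]
    ok <- (a == b) || (a == "X") ||
      (nchar(b) == 1L && grepl(b, a, fixed = TRUE))
    if (!ok) return(FALSE)
    if (a != b) strict <- TRUE
  }
  for (c in which(p$elements != "X")) {
    qc <- c + d
    if (qc < 1L || qc > lq || q$elements[qc] == "X") return(FALSE)
  }
  strict
}

## the exact maximal <L,W,K> pattern set, as canonical "elements@occ"
## signature strings
oracleMaximal <- function(seqs, grouping, L, W, K) {
  seqChars <- lapply(toupper(seqs), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  cand <- oracleCandidates(seqChars, grouping, L, W, K)
  keep <- vapply(cand, function(p) {
    !any(vapply(cand, function(q)
      !identical(p, q) && oracleRefines(p, q), NA))
  }, NA)
  res <- cand[keep]
  sort(unname(vapply(res, patternSignature, "")))
}

patternSignature <- function(p) {
  elements <- if (is(p, "DiscoveredPattern")) p@positions else p$elements
  occ <- if (is(p, "DiscoveredPattern")) p@occurrences else p$occ
  occ <- occ[order(occ$seq, occ$offset), ]
  paste(paste(elements, collapse = "|"),
        paste(occ$seq, occ$offset, sep = ":", collapse = ","),
        sep = "@")
}
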