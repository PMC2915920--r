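## Synthetic fixtures with known ground truth: random proteomes, planted
## motif instances, labeled peptide panels drawn from a generating
## pattern, and toy ontologies with a controlled enriched term. All
## generators are seed-deterministic; planting overwrites residues in
## place so that recorded coordinates stay valid.

## evaluate expr under a fixed RNG seed without disturbing the caller's
## RNG state
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Uniform residue composition
#'
#' @return named numeric: each of the 20 standard residues at 0.05.
#' @export
uniformComposition <- function() {
  stats::setNames(rep(1 / 20, 20), STANDARD_AA)
}

#' A vertebrate-like residue composition
#'
#' Rounded average residue frequencies typical of vertebrate proteomes,
#' normalized to sum to 1; an alternative background to
#' [uniformComposition()] for scan-statistics experiments.
#'
#' @return named numeric over the 20 standard residues.
#' @export
vertebrateComposition <- function() {
  x <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.6, G = 6.6, H = 2.6,
         I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6, P = 6.3, Q = 4.8,
         R = 5.6, S = 8.3, T = 5.3, V = 6.0, W = 1.2, Y = 2.7)
  x[STANDARD_AA] / sum(x)
}

.checkComposition <- function(composition) {
  if (is.null(names(composition)) ||
      !setequal(names(composition), STANDARD_AA))
    stop("composition must be named over the 20 standard residues",
         call. = FALSE)
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-8)
    stop("composition frequencies must be non-negative and sum to 1",
         call. = FALSE)
  composition[STANDARD_AA]
}

#' Generate a random proteome
#'
#' Sequences of iid residues under `composition`, lengths uniform over
#' `length_range`, records named `synth_0001`, `synth_0002`, ...
#' Byte-identical output for identical seed and parameters.
#'
#' @param n_proteins number of records (>= 0).
#' @param length_range integer length bounds `c(min, max)`.
#' @param composition residue frequencies, see [uniformComposition()].
#' @param seed RNG seed.
#' @return list with `sequences` (named character vector) and `truth`
#'   (empty planted-coordinate data.frame).
#' @export
generateProteome <- function(n_proteins, length_range = c(200L, 400L),
                             composition = uniformComposition(),
                             seed = 1L) {
  composition <- .checkComposition(composition)
  stopifnot(n_proteins >= 0, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[1] <= length_range[2])
  seqs <- .withSeed(seed, {
    out <- character(n_proteins)
    for (i in seq_len(n_proteins)) {
      len <- sample.int(length_range[2] - length_range[1] + 1L, 1L) +
        length_range[1] - 1L
      out[i] <- paste(sample(STANDARD_AA, len, replace = TRUE,
                             prob = composition), collapse = "")
    }
    out
  })
  names(seqs) <- sprintf("synth_%04d", seq_len(n_proteins))
  list(sequences = seqs, truth = .emptyTruth())
}

.emptyTruth <- function() {
  data.frame(protein = character(0), start = integer(0), end = integer(0),
             planted = character(0), stringsAsFactors = FALSE)
}

#' Sample one sequence from a pattern's language
#'
#' Classes draw uniformly over their members, exclusions uniformly over
#' the allowed standard residues, wildcards first draw an extent
#' uniformly over their span and then residues uniformly over the 20
#' standard letters. Not seed-wrapped: call inside your own RNG context
#' or via the generators that use it.
#'
#' @param pattern a [MotifPattern-class].
#' @return character scalar matching `pattern`.
#' @export
samplePatternInstance <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  parts <- vapply(pattern@positions, function(ps) {
    if (ps$kind == "wildcard") {
      ext <- if (ps$span_max > ps$span_min)
        sample(seq.int(ps$span_min, ps$span_max), 1L) else ps$span_min
      paste(sample(STANDARD_AA, ext, replace = TRUE), collapse = "")
    } else {
      allowed <- .allowedResidues(ps)
      if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    }
  }, "")
  paste(parts, collapse = "")
}

#' Plant motif instances into a proteome at recorded coordinates
#'
#' Each instance is sampled from the pattern's language and overwrites
#' the sequence in place (coordinates stay stable). Placement is uniform
#' with non-overlap enforced by rejection sampling (up to 1000 attempts
#' per instance, then an error).
#'
#' @param proteome result of [generateProteome()] or a named character
#'   vector of sequences.
#' @param pattern the generating [MotifPattern-class].
#' @param instances_per_protein number of instances to plant per record.
#' @param seed RNG seed.
#' @return list with `sequences` and `truth` (protein, start, end,
#'   planted).
#' @export
plantMotifs <- function(proteome, pattern, instances_per_protein = 1L,
                        seed = 1L) {
  seqs <- if (is.list(proteome)) proteome$sequences else proteome
  stopifnot(is(pattern, "MotifPattern"), instances_per_protein >= 0)
  res <- .withSeed(seed, {
    truth <- list()
    for (i in seq_along(seqs)) {
      placed <- integer(0)  # occupied residue positions
      n <- nchar(seqs[i])
      for (j in seq_len(instances_per_protein)) {
        inst <- samplePatternInstance(pattern)
        w <- nchar(inst)
        if (w > n)
          stop(sprintf("protein %s (length %d) too short for a %d-residue instance",
                       names(seqs)[i], n, w), call. = FALSE)
        ok <- FALSE
        for (attempt in seq_len(1000L)) {
          start <- sample.int(n - w + 1L, 1L)
          span <- seq.int(start, start + w - 1L)
          if (!any(span %in% placed)) { ok <- TRUE; break }
        }
        if (!ok)
          stop(sprintf("could not place %d non-overlapping instances in %s",
                       instances_per_protein, names(seqs)[i]), call. = FALSE)
        placed <- c(placed, span)
        substr(seqs[i], start, start + w - 1L) <- inst
        truth[[length(truth) + 1L]] <-
          data.frame(protein = names(seqs)[i], start = start,
                     end = start + w - 1L, planted = inst,
                     stringsAsFactors = FALSE)
      }
    }
    list(sequences = seqs,
         truth = if (length(truth)) do.call(rbind, truth) else .emptyTruth())
  })
  res
}

#' Sample a labeled peptide panel from a generating pattern
#'
#' Positives are drawn from the pattern's language (label `cleaved`);
#' negatives take a fresh positive and mutate one key (class or
#' exclusion) position to a disallowed residue (label `not_cleaved`).
#' The mutated residue coordinate of each negative is recorded in the
#' returned `truth` table and in the peptide's `note` field.
#'
#' @param pattern generating [MotifPattern-class]; must have at least one
#'   key position with a disallowed residue.
#' @param n_pos number of positives (>= 1).
#' @param n_neg number of negatives (>= 0).
#' @param seed RNG seed.
#' @return list with `peptides` (labeled peptide data.frame) and `truth`
#'   (`sequence`, `mutated_position`, one row per negative).
#' @export
samplePeptidePanel <- function(pattern, n_pos, n_neg = 0L, seed = 1L) {
  stopifnot(is(pattern, "MotifPattern"), n_pos >= 1L, n_neg >= 0L)
  key_specs <- Filter(function(ps) ps$kind != "wildcard" &&
                        length(.allowedResidues(ps)) < 20L,
                      pattern@positions)
  if (n_neg > 0L && length(key_specs) == 0L)
    stop("pattern has no mutable key position", call. = FALSE)
  .withSeed(seed, {
    pos <- vapply(seq_len(n_pos), function(i) samplePatternInstance(pattern),
                  "")
    peptides <- labeledPeptides(pos, "cleaved", source = "synthetic")
    truth <- data.frame(sequence = character(0),
                        mutated_position = integer(0),
                        stringsAsFactors = FALSE)
    if (n_neg > 0L) {
      negs <- character(n_neg); mpos <- integer(n_neg)
      ## key residue coordinates under the minimal-extent assignment used
      ## by the sampler are recomputed per sampled instance
      for (i in seq_len(n_neg)) {
        repeat {
          base <- samplePatternInstance(pattern)
          coords <- .keyCoordinates(pattern, base)
          mutable <- coords[vapply(coords$spec, function(j)
            length(.allowedResidues(pattern@positions[[j]])) < 20L, NA), ,
            drop = FALSE]
          if (nrow(mutable) > 0L) break
        }
        pick <- mutable[sample.int(nrow(mutable), 1L), ]
        ps <- pattern@positions[[pick$spec]]
        disallowed <- setdiff(STANDARD_AA, .allowedResidues(ps))
        res <- if (length(disallowed) == 1L) disallowed
               else sample(disallowed, 1L)
        substr(base, pick$coord, pick$coord) <- res
        negs[i] <- base; mpos[i] <- pick$coord
      }
      peptides <- rbind(peptides,
                        labeledPeptides(negs, "not_cleaved",
                                        source = "synthetic",
                                        note = sprintf("mut_pos=%d", mpos)))
      truth <- data.frame(sequence = negs, mutated_position = mpos,
                          stringsAsFactors = FALSE)
    }
    list(peptides = peptides, truth = truth)
  })
}

## residue coordinates of the key positions of 'pattern' within an
## instance 'inst' (full-length anchored match; unique assignment assumed
## for the dialect's single bounded gap)
.keyCoordinates <- function(pattern, inst) {
  len <- nchar(inst)
  asg <- .assignments(pattern, greedy = FALSE)
  asg <- asg[rowSums(asg) == len, , drop = FALSE]
  ext <- asg[1L, ]
  rel <- cumsum(c(0L, ext[-length(ext)]))
  spec <- which(vapply(pattern@positions, function(p) p$kind != "wildcard",
                       NA))
  data.frame(spec = spec, coord = rel[spec] + 1L)
}

#' Analytic per-offset match probability under an iid background
#'
#' The probability that a pattern match starts at a given alignment
#' offset of an iid sequence with the given residue composition: the sum
#' over span assignments of the product of per-position acceptance
#' probabilities (wildcards contribute 1). Exact for fixed-span patterns;
#' for variable-span patterns the assignments overlap as events and the
#' sum is a tight upper approximation.
#'
#' @param pattern a [MotifPattern-class].
#' @param composition residue frequencies.
#' @return probability per alignment offset.
#' @examples
#' general <- parsePattern("[LIMV]X(4)[LIMV]X(2)[LIMV][DE]")
#' expectedMatchRate(general, uniformComposition())  # (4/20)^3 * (2/20)
#' @export
expectedMatchRate <- function(pattern, composition = uniformComposition()) {
  stopifnot(is(pattern, "MotifPattern"))
  composition <- .checkComposition(composition)
  asg <- .assignments(pattern, greedy = FALSE)
  probs <- vapply(pattern@positions, function(ps) {
    if (ps$kind == "wildcard") 1
    else sum(composition[.allowedResidues(ps)])
  }, 0)
  ## per-position probabilities do not depend on wildcard extents, so
  ## each assignment contributes the same product
  nrow(asg) * prod(probs[vapply(pattern@positions,
                                function(p) p$kind != "wildcard", NA)])
}

#' Generate a toy ontology with a controlled enriched term
#'
#' Builds a single-namespace is_a DAG of `n_terms` terms arranged in
#' `depth` levels below the root (each term drawing one parent from the
#' level above), annotates every protein to the root, and annotates the
#' deepest leaf (the enriched term) to substrate proteins with
#' probability `p_in` and to background proteins with probability `p_out`
#' (`p_in > p_out` required). Every other non-root term receives
#' background annotations at `p_out` for all proteins, so ancestors of
#' the enriched term accumulate background signal and the enriched leaf
#' itself carries the extreme overlap.
#'
#' @param n_terms total number of terms including the root (>= 3).
#' @param depth number of levels below the root (>= 1).
#' @param n_proteins number of background proteins (ids `prot_0001`...).
#' @param substrates character vector of substrate ids (subset of the
#'   proteins, or new ids which are appended).
#' @param p_in,p_out annotation probabilities for the enriched term.
#' @param namespace namespace name for all terms.
#' @param seed RNG seed.
#' @return list with `ontology` ([Ontology-class]), `annotations`
#'   (protein_id/term_id data.frame, direct annotations), and `truth`
#'   (list with `enriched_term`).
#' @export
generateOntologyAnnotations <- function(n_terms, depth, n_proteins,
                                        substrates, p_in = 0.8,
                                        p_out = 0.1,
                                        namespace = "biological_process",
                                        seed = 1L) {
  stopifnot(n_terms >= 3L, depth >= 1L, n_proteins >= 1L)
  if (p_in <= p_out)
    stop("p_in must exceed p_out", call. = FALSE)
  if (p_in > 1 || p_out < 0)
    stop("p_in and p_out must be probabilities", call. = FALSE)
  proteins <- sprintf("prot_%04d", seq_len(n_proteins))
  substrates <- unique(substrates)
  proteins <- union(proteins, substrates)
  .withSeed(seed, {
    ids <- c("T:0000", sprintf("T:%04d", seq_len(n_terms - 1L)))
    level <- c(0L, sort(rep_len(seq_len(depth), n_terms - 1L)))
    parents <- stats::setNames(vector("list", n_terms), ids)
    parents[[ids[1]]] <- character(0)
    for (i in seq.int(2L, n_terms)) {
      pool <- ids[level == level[i] - 1L]
      parents[[ids[i]]] <- sample(pool, 1L)
    }
    terms <- data.frame(id = ids,
                        name = c("root", sprintf("term %d",
                                                 seq_len(n_terms - 1L))),
                        namespace = namespace, stringsAsFactors = FALSE)
    onto <- new("Ontology", terms = terms, parents = parents,
                roots = stats::setNames(ids[1], namespace))
    leaves <- ids[!ids %in% unlist(parents, use.names = FALSE)]
    enriched <- leaves[which.max(level[match(leaves, ids)])]

    ann <- data.frame(protein_id = proteins, term_id = ids[1],
                      stringsAsFactors = FALSE)
    for (tid in ids[-1L]) {
      if (tid == enriched) {
        is_sub <- proteins %in% substrates
        hit <- stats::runif(length(proteins)) <
          ifelse(is_sub, p_in, p_out)
      } else {
        hit <- stats::runif(length(proteins)) < p_out
      }
      if (any(hit))
        ann <- rbind(ann, data.frame(protein_id = proteins[hit],
                                     term_id = tid,
                                     stringsAsFactors = FALSE))
    }
    list(ontology = onto, annotations = unique(ann),
         truth = list(enriched_term = enriched))
  })
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
writeFasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
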