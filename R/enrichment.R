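## Ontology-based characterization of predicted substrate sets.
##
## Annotations follow the true-path rule (a protein annotated to a term is
## annotated to all its is_a ancestors). Each namespace is evaluated
## individually against its own root: a term annotated to k of n substrates
## and K of N background proteins scores the upper-tail hypergeometric
## probability p = P(X >= k), and its information content is -log p. The
## root term always has p = 1 and information content 0.

#' Parse a minimal OBO ontology
#'
#' Supports `[Term]` stanzas with `id`, `name`, `namespace` and `is_a`
#' tags; obsolete terms are skipped. The is_a graph must be acyclic and
#' every term must reach a single root in its namespace.
#'
#' @param path OBO file path (or connection readable by [readLines()]).
#' @return an [Ontology-class].
#' @export
parseOBO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete)) {
      if (is.null(cur$id)) stop("[Term] stanza without id", call. = FALSE)
      terms[[cur$id]] <- cur
    }
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)           # trailing OBO comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(is_a = character(0))
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {     # other stanza types
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) != 3L) next
      key <- kv[2]; val <- trimws(kv[3])
      if (key == "id") cur$id <- val
      else if (key == "name") cur$name <- val
      else if (key == "namespace") cur$namespace <- val
      else if (key == "is_a") cur$is_a <- c(cur$is_a, sub("\\s.*$", "", val))
      else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0L) stop("no [Term] stanzas found", call. = FALSE)

  ids <- names(terms)
  parents <- lapply(terms, `[[`, "is_a")
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown) > 0L)
    stop(sprintf("is_a reference(s) to unknown term id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  tab <- data.frame(
    id = ids,
    name = vapply(terms, function(t) t$name %||% t$id, ""),
    namespace = vapply(terms, function(t) t$namespace %||% "default", ""),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  onto <- new("Ontology", terms = tab, parents = parents,
              roots = .findRoots(tab, parents))
  .checkAcyclic(onto)
  onto
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.findRoots <- function(tab, parents) {
  roots <- character(0)
  for (ns in unique(tab$namespace)) {
    ids <- tab$id[tab$namespace == ns]
    r <- ids[lengths(parents[ids]) == 0L]
    if (length(r) != 1L)
      stop(sprintf("namespace '%s' must have exactly one root (found %d)",
                   ns, length(r)), call. = FALSE)
    roots[ns] <- r
  }
  roots
}

.checkAcyclic <- function(onto) {
  state <- new.env(parent = emptyenv())  # 1 = visiting, 2 = done
  visit <- function(id) {
    s <- state[[id]]
    if (identical(s, 2L)) return(invisible(NULL))
    if (identical(s, 1L))
      stop(sprintf("cycle detected in is_a graph at term '%s'", id),
           call. = FALSE)
    state[[id]] <- 1L
    for (p in onto@parents[[id]]) visit(p)
    state[[id]] <- 2L
    invisible(NULL)
  }
  for (id in onto@terms$id) visit(id)
  invisible(TRUE)
}

#' All is_a ancestors of a term (excluding the term itself)
#'
#' @param onto an [Ontology-class].
#' @param id term id.
#' @return character vector of ancestor ids.
#' @export
termAncestors <- function(onto, id) {
  if (!id %in% onto@terms$id)
    stop(sprintf("unknown term id '%s'", id), call. = FALSE)
  seen <- character(0)
  frontier <- onto@parents[[id]]
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(onto@parents[frontier],
                                      use.names = FALSE)), seen)
  }
  seen
}

#' Serialize an ontology back to minimal OBO
#'
#' @param onto an [Ontology-class].
#' @param path output file path.
#' @export
writeOBO <- function(onto, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(onto@terms))) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", onto@terms$id[i]), con)
    writeLines(paste0("name: ", onto@terms$name[i]), con)
    writeLines(paste0("namespace: ", onto@terms$namespace[i]), con)
    for (p in onto@parents[[onto@terms$id[i]]])
      writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Read / write protein-to-term annotations as TSV
#'
#' Two tab-separated columns, `protein_id` and `term_id`; `#` lines are
#' provenance headers.
#'
#' @param path file path.
#' @return data.frame with columns protein_id, term_id.
#' @export
readAnnotations <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("protein_id", "term_id") %in% names(tab)))
    stop("annotation TSV must have columns protein_id, term_id",
         call. = FALSE)
  unique(tab[c("protein_id", "term_id")])
}

#' @rdname readAnnotations
#' @param annotations annotation data.frame.
#' @param header provenance lines written as `#` comments.
#' @export
writeAnnotations <- function(annotations, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(annotations, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Every (protein, term) pair implies (protein, ancestor) for all is_a
#' ancestors within the same namespace. Idempotent: propagating a
#' propagated table changes nothing.
#'
#' @param annotations data.frame with columns `protein_id`, `term_id`.
#' @param onto an [Ontology-class].
#' @return propagated annotation data.frame (unique pairs, sorted).
#' @export
propagateAnnotations <- function(annotations, onto) {
  unknown <- setdiff(unique(annotations$term_id), onto@terms$id)
  if (length(unknown) > 0L)
    stop(sprintf("annotation(s) to unknown term id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  anc <- lapply(unique(annotations$term_id),
                function(id) c(id, termAncestors(onto, id)))
  names(anc) <- unique(annotations$term_id)
  out <- do.call(rbind, lapply(seq_len(nrow(annotations)), function(i) {
    data.frame(protein_id = annotations$protein_id[i],
               term_id = anc[[annotations$term_id[i]]],
               stringsAsFactors = FALSE)
  }))
  out <- unique(out)
  out <- out[order(out$protein_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ hypergeometric: drawing `n` proteins from a
#' background of `N` of which `K` carry the annotation. This is the
#' probability of observing an overlap at least as large as the one seen,
#' the usual over-representation reading. With `point = TRUE` the point
#' probability P(X = k) is returned instead.
#'
#' @param k substrates annotated to the term.
#' @param K background proteins annotated to the term.
#' @param n substrate-set size (annotated within the namespace).
#' @param N background size (the namespace root count).
#' @param point return the point probability instead of the tail.
#' @return probability in (0, 1].
#' @examples
#' hypergeomTail(2, 2, 2, 4)  # 1/6: both draws hit the 2 marked of 4
#' @export
hypergeomTail <- function(k, K, n, N, point = FALSE) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (k < 0 || K < 0 || n < 0 || N < 0 || k > min(n, K) || K > N || n > N)
    stop("counts must satisfy 0 <= k <= min(n, K), K <= N, n <= N",
         call. = FALSE)
  if (point) return(stats::dhyper(k, K, N - K, n))
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Information content of a probability
#'
#' `-log(p)` in the configured base; `p = 1` gives exactly 0 (the root
#' term of every namespace).
#'
#' @param p probability in (0, 1].
#' @param base logarithm base (default natural).
#' @return non-negative numeric.
#' @export
informationContent <- function(p, base = exp(1)) {
  if (any(p <= 0 | p > 1))
    stop("p must lie in (0, 1]", call. = FALSE)
  ifelse(p == 1, 0, -log(p) / log(base))
}

#' Rank ontology terms by information content for a substrate set
#'
#' For every term annotated to at least one substrate, computes the
#' hypergeometric tail probability of the observed overlap and its
#' information content. Namespaces are evaluated individually: the
#' background size N is the number of proteins annotated (after
#' propagation) to the namespace root, and n is the number of substrates
#' annotated within the namespace. Root terms therefore always score
#' p = 1, information content 0.
#'
#' @param substrates character vector of substrate protein ids.
#' @param onto an [Ontology-class].
#' @param annotations annotation data.frame; propagated internally if
#'   `propagate = TRUE` (default).
#' @param ic_cut optional information-content cutoff; rows scoring below
#'   it are dropped.
#' @param base log base for the information content.
#' @param point use point instead of tail probabilities.
#' @param propagate set `FALSE` if `annotations` is already propagated.
#' @return data.frame sorted by `ic` descending (ties by term id) with
#'   columns `term_id`, `namespace`, `name`, `k`, `K`, `n`, `N`, `p`,
#'   `ic`, `bh` (Benjamini-Hochberg adjusted p across all rows,
#'   informational only — ranking is by information content).
#' @export
enrichTerms <- function(substrates, onto, annotations, ic_cut = NULL,
                        base = exp(1), point = FALSE, propagate = TRUE) {
  if (propagate)
    annotations <- propagateAnnotations(annotations, onto)
  substrates <- unique(substrates)
  rows <- list()
  for (ns in names(onto@roots)) {
    root <- onto@roots[[ns]]
    ns_terms <- onto@terms$id[onto@terms$namespace == ns]
    ann <- annotations[annotations$term_id %in% ns_terms, , drop = FALSE]
    root_prot <- unique(ann$protein_id[ann$term_id == root])
    N <- length(root_prot)
    n <- sum(substrates %in% root_prot)
    if (N == 0L || n == 0L) next
    for (tid in ns_terms) {
      prot <- unique(ann$protein_id[ann$term_id == tid])
      K <- length(prot)
      k <- sum(substrates %in% prot)
      if (k < 1L) next
      p <- hypergeomTail(k, K, n, N, point = point)
      rows[[length(rows) + 1L]] <-
        data.frame(term_id = tid, namespace = ns,
                   name = onto@terms$name[onto@terms$id == tid],
                   k = k, K = K, n = n, N = N, p = p,
                   ic = informationContent(p, base = base),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(term_id = character(0), namespace = character(0),
                      name = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      ic = numeric(0), bh = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$bh <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-out$ic, out$term_id), , drop = FALSE]
  if (!is.null(ic_cut)) out <- out[out$ic >= ic_cut, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment report as TSV
#'
#' Columns mirror the published layout: information content first, then
#' the count quadruple k|K|N|n, term id, namespace and term name.
#'
#' @param rows result of [enrichTerms()].
#' @param path output path.
#' @param header provenance lines written as `#` comments.
#' @export
writeEnrichment <- function(rows, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  out <- rows[c("ic", "k", "K", "N", "n", "term_id", "namespace", "name")]
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
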