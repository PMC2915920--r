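## Shared readers/writers and the end-to-end pipeline
## (refine -> scan -> enrich). All tabular outputs carry `#`-prefixed
## provenance headers recording the package version and the run
## configuration, so a re-run with the same inputs reproduces identical
## files.

.provenance <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("CleaveScan"))
  head <- sprintf("CleaveScan %s", ver)
  if (is.null(config) || length(config) == 0L) return(head)
  kv <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s=%s", k, paste(format(v), collapse = ","))
  }, "")
  c(head, paste("config:", paste(kv, collapse = " ")))
}

#' Write / read a motif pattern file
#'
#' A pattern file holds one PROSITE-dialect pattern per non-comment line;
#' `#` lines are provenance headers.
#'
#' @param pattern a [MotifPattern-class].
#' @param path file path.
#' @param header extra provenance lines.
#' @return `readMotif`: a [MotifPattern-class] (first pattern in the
#'   file).
#' @export
writeMotif <- function(pattern, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in c(.provenance(), header)) writeLines(paste0("# ", h), con)
  writeLines(patternString(pattern), con)
  invisible(path)
}

#' @rdname writeMotif
#' @param name,source labels for the pattern read.
#' @export
readMotif <- function(path, name = "motif", source = "file") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  if (length(lines) == 0L)
    stop(sprintf("no pattern found in '%s'", path), call. = FALSE)
  parsePattern(lines[1], name = name, source = source)
}

#' Write / read a motif hit table as TSV
#'
#' Columns: sequence_id, start, end, matched, pattern_name.
#'
#' @param hits hit data.frame from [scanSequence()] / [scanDatabase()].
#' @param path file path.
#' @param header extra provenance lines.
#' @export
writeHits <- function(hits, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in c(.provenance(), header)) writeLines(paste0("# ", h), con)
  utils::write.table(hits, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeHits
#' @export
readHits <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("sequence_id", "start", "end", "matched", "pattern_name")
  if (!all(need %in% names(tab)))
    stop(sprintf("hit TSV must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  tab[need]
}

.PIPELINE_KEYS <- c("peptides", "frame_length", "gap_position",
                    "diversity_threshold", "include_partial", "fasta",
                    "overlap", "greedy", "obo", "annotations", "ic_cut",
                    "ic_base", "out_dir", "motif_name")

#' Validate a pipeline run configuration
#'
#' @param config named list of pipeline parameters; unknown keys are
#'   rejected before any computation.
#' @return the config with defaults filled in.
#' @export
pipelineConfig <- function(config) {
  unknown <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(unknown) > 0L)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  defaults <- list(frame_length = 10L, gap_position = 5L,
                   diversity_threshold = 7L, include_partial = TRUE,
                   overlap = FALSE, greedy = FALSE, ic_cut = NULL,
                   ic_base = exp(1), motif_name = "refined",
                   out_dir = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[k] <- defaults[k]
  for (k in c("peptides", "fasta"))
    if (is.null(config[[k]]))
      stop(sprintf("configuration key '%s' is required", k), call. = FALSE)
  config
}

#' Run the substrate-prediction pipeline end to end
#'
#' Refines a motif from a labeled peptide panel, scans a protein database
#' for the refined motif, and (when an ontology and annotations are
#' configured) characterizes the proteins carrying hits by
#' information-content enrichment. Stage outputs are written under
#' `out_dir` (when set) with provenance headers; stage counts are
#' returned in `counts`.
#'
#' @param config named list, see [pipelineConfig()]: `peptides` (TSV path
#'   or peptide data.frame), `fasta` (path or named sequences), optional
#'   `obo` + `annotations` (paths or objects), frame and scan parameters,
#'   optional `ic_cut`, `out_dir`.
#' @return list with `motif`, `hits`, `protein_count`, `substrates`,
#'   `enrichment` (NULL without ontology inputs) and `counts`.
#' @export
runPipeline <- function(config) {
  config <- pipelineConfig(config)
  peptides <- if (is.character(config$peptides))
    readPeptides(config$peptides) else config$peptides
  motif <- refineMotif(peptides, frame = config$frame_length,
                       gap_position = config$gap_position,
                       includePartial = config$include_partial,
                       diversity_threshold = config$diversity_threshold,
                       name = config$motif_name)
  scan <- scanDatabase(motif, config$fasta, overlap = config$overlap,
                       greedy = config$greedy)
  substrates <- unique(scan$hits$sequence_id)

  enrichment <- NULL
  if (!is.null(config$obo) && !is.null(config$annotations)) {
    onto <- if (is.character(config$obo)) parseOBO(config$obo)
            else config$obo
    ann <- if (is.character(config$annotations))
      readAnnotations(config$annotations) else config$annotations
    enrichment <- enrichTerms(substrates, onto, ann,
                              ic_cut = config$ic_cut,
                              base = config$ic_base)
  }

  counts <- c(peptides_in = nrow(peptides),
              positives = length(.positiveRows(
                alignPeptides(peptides, config$frame_length,
                              config$gap_position),
                config$include_partial)),
              hits = nrow(scan$hits),
              proteins_with_hits = scan$protein_count,
              enriched_terms = if (is.null(enrichment)) NA_integer_
                               else nrow(enrichment))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    scalar <- vapply(config, function(v)
      is.atomic(v) && length(v) == 1L, NA)
    hdr <- .provenance(config[scalar & names(config) != "out_dir"])[-1]
    writeMotif(motif, file.path(config$out_dir, "motif.txt"), header = hdr)
    writeHits(scan$hits, file.path(config$out_dir, "hits.tsv"),
              header = hdr)
    if (!is.null(enrichment))
      writeEnrichment(enrichment,
                      file.path(config$out_dir, "enrichment.tsv"),
                      header = c(.provenance(), hdr,
                                 sprintf("log_base=%g", config$ic_base)))
  }

  list(motif = motif, hits = scan$hits,
       protein_count = scan$protein_count, substrates = substrates,
       enrichment = enrichment, counts = counts)
}
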