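general <- parsePattern("[LIMV]X(4)[LIMV]X(2)[LIMV][DE]", name = "general")
stringent <- parsePattern(
  "[VLM][PGED][SAGEKL]{G}X(0,1)[VAIML][ESPQLK][GKEY][VLA][ED]",
  name = "stringent")

test_that("parser reproduces the dialect's constructs", {
  expect_length(general@positions, 6L)
  expect_equal(unname(spanRange(general)), c(10L, 10L))
  expect_equal(keyPositionCount(general), 4L)

  expect_length(stringent@positions, 10L)
  expect_equal(unname(spanRange(stringent)), c(9L, 10L))
  expect_equal(keyPositionCount(stringent), 9L)
  expect_identical(stringent@positions[[4]]$kind, "exclusion")
  expect_identical(stringent@positions[[4]]$residues, "G")

  x <- parsePattern("X")
  expect_length(x@positions, 1L)
  expect_equal(unname(spanRange(x)), c(1L, 1L))

  ## hyphens and case are tolerated
  expect_identical(patternString(parsePattern("[limv]-x(4)-[LIMV]-X(2)-[limv]-[de]")),
                   patternString(general))
})

test_that("span range sums per-position extents", {
  expect_equal(unname(spanRange(parsePattern("X(0,3)[A]"))), c(1L, 4L))
  expect_equal(unname(spanRange(parsePattern("[AC]X(2,5){G}"))), c(4L, 7L))
})

test_that("malformed patterns are syntax errors with offsets", {
  expect_error(parsePattern("[LIMV"), "unbalanced")
  expect_error(parsePattern("[]X"), "empty residue class")
  expect_error(parsePattern("[LZ1]"), "not a standard amino-acid")
  expect_error(parsePattern("X(3,1)"), "exceeds")
  expect_error(parsePattern("[AC]Y"), "unexpected character")
  expect_error(parsePattern(""), "non-empty")
})

test_that("serialization round-trips parsing", {
  expect_identical(patternString(general),
                   "[LIMV]X(4)[LIMV]X(2)[LIMV][DE]")
  set.seed(101)
  for (i in 1:50) {
    p <- randomPattern()
    q <- parsePattern(patternString(p))
    expect_identical(patternString(q), patternString(p))
    expect_true(CleaveScan:::samePattern(p, q))
  }
})

test_that("anchored matching reproduces the peptide-panel calls", {
  expect_equal(matchAt(general, "VPSANIEGLE", 1), 10L)
  expect_true(is.na(matchAt(general, "VPDVSLEGPE", 1)))
  expect_true(is.na(matchAt(general, "AAAAAAAAAA", 1)))
  expect_false(is.na(matchAt(stringent, "VPSANIEGLE", 1)))

  panel <- substratePanel()
  bearing <- panel$sequence[panel$label != "not_cleaved"]
  expect_length(bearing, 13L)
  expect_true(all(vapply(bearing, function(s)
    !is.na(matchAt(general, s, 1)), NA)))

  expect_error(matchAt(general, "VPSANIEGLE", 0), "out of range")
  expect_error(matchAt(general, "VPSANIEGLE", 11), "out of range")
})

test_that("ambiguity codes match wildcards but never classes", {
  expect_error(parsePattern("[AX]"), "not a standard amino-acid")
  expect_true(is.na(matchAt(parsePattern("[LIMV]"), "B", 1)))
  expect_true(is.na(matchAt(parsePattern("{G}"), "U", 1)))
  expect_equal(matchAt(parsePattern("[A]X[A]"), "AUA", 1), 3L)
  ## relaxed exclusions accept non-standard codes
  expect_equal(matchAt(parsePattern("{G}"), "U", 1,
                       strictExclusions = FALSE), 1L)
})

test_that("violations localize failing key residues in frame coordinates", {
  v <- violations(general, "VPDVSLEGPE")
  expect_equal(v$position, 9L)
  expect_equal(v$observed, "P")

  expect_equal(nrow(violations(general, "VPSANIEGLE")), 0L)

  v2 <- violations(general, "APSANIEGLA")
  expect_equal(v2$position, c(1L, 10L))
  expect_equal(v2$observed, c("A", "A"))

  expect_error(violations(general, "VPSANIEGL"), "outside pattern span")
  ## variable-span: a 9-mer aligns against the stringent motif with the
  ## gap taken at the X(0,1) spacer
  expect_equal(nrow(violations(stringent, "VPSAIEGLE")), 0L)
})

test_that("scanning honours overlap policy and coordinates", {
  aa <- parsePattern("[A][A]", name = "AA")
  no <- scanSequence(aa, "AAAA")
  expect_equal(no$start, c(1L, 3L))
  expect_equal(no$end, c(2L, 4L))
  ov <- scanSequence(aa, "AAAA", overlap = TRUE)
  expect_equal(ov$start, 1:3)
  expect_equal(ov$matched, rep("AA", 3))
  expect_equal(nrow(scanSequence(aa, "")), 0L)

  ## one planted instance in an inert background is found exactly once
  seqc <- paste0(strrep("G", 400), "LAAAALAALD", strrep("G", 590))
  hits <- scanSequence(general, seqc)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 401L)
  expect_equal(hits$end, 410L)
  expect_equal(hits$matched, "LAAAALAALD")
})

test_that("database scans group hits per record with exact counts", {
  db <- c(p1 = paste0(strrep("G", 50), "LAAAALAALD", strrep("G", 40)),
          p2 = strrep("G", 80),
          p3 = paste0("LAAAALAALD", strrep("G", 30)),
          p4 = strrep("A", 60),
          p5 = paste0(strrep("G", 20), "VPSANIEGLE"))
  res <- scanDatabase(general, db)
  expect_equal(res$protein_count, 3L)
  expect_setequal(unique(res$hits$sequence_id), c("p1", "p3", "p5"))

  empty <- scanDatabase(general, character(0))
  expect_equal(empty$protein_count, 0L)
  expect_equal(nrow(empty$hits), 0L)
})

test_that("the uncleaved AHNAK repeat is the panel's only zero-hit record", {
  panel <- substratePanel()
  fa <- tempfile(fileext = ".fasta")
  writeFasta(setNames(panel$sequence,
                      sprintf("pep%02d_%s", seq_len(nrow(panel)),
                              panel$source)), fa)
  res <- scanDatabase(general, fa)
  expect_equal(res$protein_count, 13L)
  hit_ids <- unique(res$hits$sequence_id)
  all_ids <- sprintf("pep%02d_%s", seq_len(nrow(panel)), panel$source)
  miss <- setdiff(all_ids, hit_ids)
  expect_equal(miss, "pep14_AHNAK")   # AHNAK-R
})

test_that("overlap-mode scanning equals the brute-force matcher", {
  set.seed(202)
  for (i in 1:200) {
    p <- randomPattern()
    s <- randomSequence(sample(20:120, 1L))
    got <- scanSequence(p, s, overlap = TRUE)
    want <- oracleScanOverlap(p, s)
    expect_equal(got$start, want$start, info = patternString(p))
    expect_equal(got$end, want$end, info = patternString(p))
  }
})

test_that("widening a class never loses hits; hits re-match at their offset", {
  set.seed(303)
  db <- replicate(20, randomSequence(80))
  names(db) <- sprintf("s%02d", 1:20)
  for (i in 1:25) {
    p <- randomPattern()
    base_hits <- scanDatabase(p, db, overlap = TRUE)$hits
    ## widen one class position
    ci <- which(vapply(p@positions, function(x) x$kind == "class", NA))
    if (length(ci) > 0L) {
      j <- ci[1]
      extra <- setdiff(AA20, p@positions[[j]]$residues)
      if (length(extra) > 0L) {
        q <- p
        q@positions[[j]]$residues <- c(p@positions[[j]]$residues, extra[1])
        wide_hits <- scanDatabase(q, db, overlap = TRUE)$hits
        expect_gte(nrow(wide_hits), nrow(base_hits))
      }
    }
    for (r in seq_len(nrow(base_hits))) {
      e <- matchAt(p, db[[base_hits$sequence_id[r]]], base_hits$start[r])
      expect_false(is.na(e))
    }
  }
})

test_that("greedy policy returns the longest extent first", {
  p <- parsePattern("[A]X(0,2)[C]", name = "gap")
  expect_equal(matchAt(p, "ACC", 1), 2L)            # not greedy: shortest
  expect_equal(matchAt(p, "ACC", 1, greedy = TRUE), 3L)
})
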