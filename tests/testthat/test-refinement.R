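test_that("peptide tables validate sequences and labels", {
  p <- labeledPeptides(c("vpsanIEGLE", "AAAA"), c("cleaved", "nd"))
  expect_equal(p$sequence[1], "VPSANIEGLE")
  expect_error(labeledPeptides("VPXANIEGLE", "cleaved"), "non-standard")
  expect_error(labeledPeptides("AAAA", "yes"), "labels must")

  tf <- tempfile(fileext = ".tsv")
  writePeptides(p, tf, header = "unit-test panel")
  expect_identical(readPeptides(tf), p)
})

test_that("alignment anchors both termini and gaps short peptides at the spacer", {
  p10 <- labeledPeptides(c("VPSANIEGLE", "LPAIHVEGLD"), "cleaved")
  a <- alignPeptides(p10)
  expect_equal(a@assignment[1, ], strsplit("VPSANIEGLE", "")[[1]])

  p9 <- labeledPeptides(c("VPSANIEGLE", "VPSAIEGLE"), "cleaved")
  a9 <- alignPeptides(p9)
  expect_equal(a9@assignment[2, 5], "-")
  expect_equal(a9@assignment[2, c(1:4, 6:10)], strsplit("VPSAIEGLE", "")[[1]])

  p12 <- labeledPeptides("VPSANIEGLEAA", "cleaved")
  expect_error(alignPeptides(p12), "cannot be reconciled")
  p11 <- labeledPeptides("VPSANIEGLEA", "cleaved")
  expect_error(alignPeptides(p11), "cannot be reconciled")
})

test_that("union motif pools residues position-wise over positives", {
  two <- labeledPeptides(c("VA", "LG"), "cleaved")
  m <- buildUnionMotif(alignPeptides(two, frame = 2L, gap_position = 2L))
  expect_identical(patternString(m), "[VL][AG]")

  one <- labeledPeptides("VPSANIEGLE", "cleaved")
  m1 <- buildUnionMotif(alignPeptides(one))
  expect_identical(patternString(m1), "[V][P][S][A][N][I][E][G][L][E]")
  expect_equal(matchAt(m1, "VPSANIEGLE", 1), 10L)
  expect_true(is.na(matchAt(m1, "LPSANIEGLE", 1)))

  panel <- substratePanel()
  mp <- buildUnionMotif(alignPeptides(panel))
  expect_true(all(mp@positions[[1]]$residues %in% c("V", "L", "I")))
  expect_true(all(mp@positions[[10]]$residues %in% c("D", "E")))
})

test_that("positions reaching the diversity threshold become wildcards", {
  seqs <- c("AV", "CV", "DV", "EV", "FV", "GV", "HV")
  m <- buildUnionMotif(alignPeptides(labeledPeptides(seqs, "cleaved"),
                                     frame = 2L, gap_position = 2L))
  expect_identical(m@positions[[1]]$kind, "wildcard")
  expect_identical(patternString(m), "X[V]")
  ## below the threshold the class is kept
  m6 <- buildUnionMotif(alignPeptides(labeledPeptides(seqs[1:6], "cleaved"),
                                      frame = 2L, gap_position = 2L))
  expect_identical(m6@positions[[1]]$kind, "class")
})

test_that("exclusion classes arise only from negative-only residues", {
  ## wildcard position where negatives carry G and positives never do
  pos <- labeledPeptides(c("AV", "CV", "DV", "EV", "FV", "HV", "KV"),
                         "cleaved")
  neg <- labeledPeptides(c("GV", "GA"), "not_cleaved")
  aln <- alignPeptides(rbind(pos, neg), frame = 2L, gap_position = 2L)
  m <- buildUnionMotif(aln)
  expect_identical(m@positions[[1]]$kind, "wildcard")
  m2 <- addExclusions(m, aln)
  expect_identical(m2@positions[[1]]$kind, "exclusion")
  expect_identical(m2@positions[[1]]$residues, "G")
  expect_true(is.na(matchAt(m2, "GV", 1)))

  ## residue also present in a positive is never excluded
  pos2 <- labeledPeptides(c("AV", "CV", "DV", "EV", "FV", "HV", "GV"),
                          "cleaved")
  aln2 <- alignPeptides(rbind(pos2, neg), frame = 2L, gap_position = 2L)
  m3 <- addExclusions(buildUnionMotif(aln2), aln2)
  expect_identical(m3@positions[[1]]$kind, "wildcard")

  ## no negatives: identity
  aln3 <- alignPeptides(pos, frame = 2L, gap_position = 2L)
  m4 <- buildUnionMotif(aln3)
  expect_identical(addExclusions(m4, aln3), m4)
})

test_that("refined motif is sound for its construction panel", {
  panel <- substratePanel()
  aln <- alignPeptides(panel)
  motif <- addExclusions(buildUnionMotif(aln), aln)
  positives <- panel$sequence[panel$label %in% c("cleaved", "partial")]
  for (s in positives)
    expect_false(is.na(matchAt(motif, s, 1)), label = s)
  expect_true(is.na(matchAt(motif, "VPDVSLEGPE", 1)))
})

test_that("adding a positive peptide never shrinks a position class", {
  set.seed(77)
  gen <- parsePattern("[VL][PGED][SAK][IM][EK][GE][LV][TS][DE]")
  pan <- samplePeptidePanel(gen, 15, 0, seed = 99)$peptides
  grow <- function(peps) {
    a <- alignPeptides(peps, frame = 9L, gap_position = 5L)
    buildUnionMotif(a)
  }
  for (n in 2:14) {
    m_small <- grow(pan[1:n, ])
    m_big <- grow(pan[1:(n + 1), ])
    for (c in seq_along(m_small@positions)) {
      if (m_small@positions[[c]]$kind == "class" &&
          m_big@positions[[c]]$kind == "class")
        expect_true(all(m_small@positions[[c]]$residues %in%
                          m_big@positions[[c]]$residues))
    }
  }
})

test_that("panels from a generating pattern reconstruct its classes", {
  ## small classes, 30 positives: >= 3 expected samples per class residue
  gen <- parsePattern("[VL][PGED][SAK][IM][EK][GE][LV][TS][DE]",
                      name = "generator")
  pan <- samplePeptidePanel(gen, 30, 0, seed = 1234)
  aln <- alignPeptides(pan$peptides, frame = 9L, gap_position = 5L)
  m <- buildUnionMotif(aln)
  for (c in seq_along(gen@positions)) {
    expect_identical(m@positions[[c]]$kind, "class")
    expect_setequal(m@positions[[c]]$residues, gen@positions[[c]]$residues)
  }
})

test_that("jackknife contributions are pair-support fractions", {
  two <- labeledPeptides(c("VA", "LG"), "cleaved")
  aln <- alignPeptides(two, frame = 2L, gap_position = 2L)
  m <- buildUnionMotif(aln)
  jk <- jackknifeContribution(m, aln)
  expect_equal(unname(jk$per_peptide), c(0.5, 0.5))
  expect_equal(jk$mean, 0.5)

  one <- labeledPeptides("VPSANIEGLE", "cleaved")
  a1 <- alignPeptides(one)
  expect_equal(jackknifeContribution(buildUnionMotif(a1), a1)$mean, 1)

  twin <- labeledPeptides(c("VPSANIEGLE", "VPSANIEGLE"), "cleaved")
  a2 <- alignPeptides(twin)
  jk2 <- jackknifeContribution(buildUnionMotif(a2), a2)
  expect_equal(unname(jk2$per_peptide), c(1, 1))
  expect_equal(jk2$mean, 1)

  panel <- substratePanel()
  a3 <- alignPeptides(panel)
  jk3 <- jackknifeContribution(buildUnionMotif(a3), a3)
  expect_true(jk3$mean > 0 && jk3$mean <= 1)
})
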