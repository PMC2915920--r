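makeChainOBO <- function() {
  tf <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0002", "name: mid",
    "namespace: biological_process", "is_a: GO:0001 ! root", "",
    "[Term]", "id: GO:0003", "name: leaf",
    "namespace: biological_process", "is_a: GO:0002 ! mid"), tf)
  tf
}

test_that("minimal OBO parsing builds a rooted DAG", {
  onto <- parseOBO(makeChainOBO())
  expect_equal(nrow(onto@terms), 3L)
  expect_equal(sum(lengths(onto@parents)), 2L)
  expect_equal(unname(onto@roots["biological_process"]), "GO:0001")
  expect_setequal(termAncestors(onto, "GO:0003"), c("GO:0002", "GO:0001"))

  tf <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A:1", "name: a",
               "namespace: ns", "is_a: A:9"), tf)
  expect_error(parseOBO(tf), "A:9")

  tf2 <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A:1", "name: a", "namespace: ns",
               "is_a: A:2", "",
               "[Term]", "id: A:2", "name: b", "namespace: ns",
               "is_a: A:1"), tf2)
  expect_error(parseOBO(tf2), "cycle|root")

  ## obsolete terms are skipped
  tf3 <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A:1", "name: a", "namespace: ns", "",
               "[Term]", "id: A:2", "name: b", "namespace: ns",
               "is_a: A:1", "is_obsolete: true"), tf3)
  expect_equal(nrow(parseOBO(tf3)@terms), 1L)
})

test_that("generated ontologies round-trip through the OBO serializer", {
  go <- generateOntologyAnnotations(15, 3, 50, substrates = "prot_0001",
                                    seed = 5)
  tf <- tempfile(fileext = ".obo")
  writeOBO(go$ontology, tf)
  back <- parseOBO(tf)
  expect_equal(back@terms[order(back@terms$id), ],
               go$ontology@terms[order(go$ontology@terms$id), ],
               ignore_attr = TRUE)
  expect_identical(back@parents[go$ontology@terms$id],
                   go$ontology@parents[go$ontology@terms$id])
})

test_that("true-path propagation is the ancestor closure and is idempotent", {
  onto <- parseOBO(makeChainOBO())
  ann <- data.frame(protein_id = "p1", term_id = "GO:0003")
  pr <- propagateAnnotations(ann, onto)
  expect_setequal(pr$term_id, c("GO:0001", "GO:0002", "GO:0003"))
  expect_identical(propagateAnnotations(pr, onto), pr)
  expect_error(propagateAnnotations(
    data.frame(protein_id = "p1", term_id = "GO:9999"), onto), "GO:9999")

  ## random toy DAG vs brute-force ancestor closure
  go <- generateOntologyAnnotations(20, 4, 80,
                                    substrates = sprintf("prot_%04d", 1:8),
                                    seed = 31)
  pr2 <- propagateAnnotations(go$annotations, go$ontology)
  for (i in sample(nrow(go$annotations), 25)) {
    want <- c(go$annotations$term_id[i],
              oracleAncestors(go$ontology@parents, go$annotations$term_id[i]))
    prot <- go$annotations$protein_id[i]
    expect_true(all(want %in% pr2$term_id[pr2$protein_id == prot]))
  }
})

test_that("hypergeometric tail equals exhaustive subset enumeration", {
  expect_equal(hypergeomTail(2, 2, 2, 4), 1 / 6)
  expect_equal(hypergeomTail(0, 3, 2, 8), 1)
  expect_equal(hypergeomTail(4, 4, 4, 4), 1)
  expect_error(hypergeomTail(3, 2, 3, 4), "counts must")

  for (N in c(5L, 9L)) {
    for (K in 0:N) for (n in 0:N) {
      for (k in max(0L, n + K - N):min(n, K)) {
        expect_equal(hypergeomTail(k, K, n, N), oracleHyperTail(k, K, n, N),
                     tolerance = 1e-12,
                     info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
      }
    }
  }
})

test_that("information content is -log p, zero at certainty, monotone", {
  expect_identical(informationContent(1), 0)
  expect_equal(informationContent(1 / 6), log(6))
  expect_equal(informationContent(exp(-1)), 1)
  expect_equal(informationContent(0.25, base = 2), 2)
  expect_error(informationContent(0), "must lie")
  expect_error(informationContent(1.1), "must lie")
  p <- sort(runif(20, 0.01, 1))
  expect_true(all(diff(informationContent(p)) <= 0))
})

test_that("enrichment ranks a planted term first and scores roots zero", {
  go <- generateOntologyAnnotations(12, 3, 500,
                                    substrates = sprintf("prot_%04d", 1:50),
                                    p_in = 0.8, p_out = 0.1, seed = 11)
  er <- enrichTerms(sprintf("prot_%04d", 1:50), go$ontology,
                    go$annotations)
  expect_equal(er$term_id[1], go$truth$enriched_term)
  root_row <- er[er$term_id == unname(go$ontology@roots[1]), ]
  expect_equal(root_row$p, 1)
  expect_identical(root_row$ic, 0)
  ## row invariants
  expect_true(all(er$k >= 1 & er$k <= pmin(er$n, er$K)))
  expect_true(all(er$K <= er$N & er$n <= er$N))
  expect_true(all(er$p > 0 & er$p <= 1))
  expect_true(all(er$ic >= 0))
  expect_true(all(diff(er$ic) <= 0))

  ## ic cut drops rows below the threshold
  cut <- stats::median(er$ic)
  expect_true(all(enrichTerms(sprintf("prot_%04d", 1:50), go$ontology,
                              go$annotations, ic_cut = cut)$ic >= cut))

  ## empty substrate set is an empty result, not an error
  expect_equal(nrow(enrichTerms(character(0), go$ontology,
                                go$annotations)), 0L)
})

test_that("enrichment is invariant under protein relabeling", {
  go <- generateOntologyAnnotations(10, 2, 60,
                                    substrates = sprintf("prot_%04d", 1:10),
                                    seed = 17)
  er1 <- enrichTerms(sprintf("prot_%04d", 1:10), go$ontology,
                     go$annotations)
  relab <- go$annotations
  map <- setNames(sprintf("x%03d", seq_along(unique(relab$protein_id))),
                  unique(relab$protein_id))
  relab$protein_id <- unname(map[relab$protein_id])
  er2 <- enrichTerms(unname(map[sprintf("prot_%04d", 1:10)]), go$ontology,
                     relab)
  expect_equal(er1[c("term_id", "k", "K", "n", "N", "p", "ic")],
               er2[c("term_id", "k", "K", "n", "N", "p", "ic")])
})

test_that("enrichment reports round-trip through the TSV writer", {
  go <- generateOntologyAnnotations(10, 2, 60,
                                    substrates = sprintf("prot_%04d", 1:10),
                                    seed = 19)
  er <- enrichTerms(sprintf("prot_%04d", 1:10), go$ontology,
                    go$annotations)
  tf <- tempfile(fileext = ".tsv")
  writeEnrichment(er, tf, header = "unit test")
  back <- utils::read.delim(tf, comment.char = "#")
  expect_equal(back$term_id, er$term_id)
  expect_equal(back$ic, er$ic, tolerance = 1e-6)

  ta <- tempfile(fileext = ".tsv")
  writeAnnotations(go$annotations, ta, header = "unit test")
  expect_equal(readAnnotations(ta), go$annotations, ignore_attr = TRUE)
})
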