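hit <- function(score_parts = c(60, 0, 5, 2, 1), tName = "chr1", tStart = 0,
                tEnd = 100, qName = "q") {
  tibble::tibble(matches = score_parts[1], repMatches = score_parts[2],
                 misMatches = score_parts[3], qNumInsert = score_parts[4],
                 tNumInsert = score_parts[5], qName = qName, tName = tName,
                 tStart = tStart, tEnd = tEnd)
}

test_that("blat_score follows the browser-BLAT formula", {
  expect_equal(blat_score(hit(c(60, 0, 5, 2, 1))), 52L)
  expect_equal(blat_score(hit(c(100, 0, 0, 0, 0))), 100L)
  expect_equal(blat_score(hit(c(30, 0, 30, 0, 0))), 0L)
  expect_equal(blat_score(hit(c(50, 10, 5, 1, 2))), 52L)  # repMatches count
})

test_that("significant_hits keeps strictly > 50 and matches a brute force", {
  hits <- dplyr::bind_rows(
    hit(c(52, 0, 0, 0, 0), tStart = 5),
    hit(c(50, 0, 0, 0, 0), tStart = 1),
    hit(c(49, 0, 0, 0, 0), tStart = 2)
  ) |> score_hits()
  expect_equal(significant_hits(hits)$score, 52L)
  expect_equal(nrow(significant_hits(hits[0, ])), 0)

  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:100, 1)
    h <- tibble::tibble(
      matches = sample(0:120, n, replace = TRUE), repMatches = 0L,
      misMatches = sample(0:20, n, replace = TRUE),
      qNumInsert = sample(0:3, n, replace = TRUE),
      tNumInsert = sample(0:3, n, replace = TRUE),
      tName = sample(c("chr1", "chr2", "chrZ"), n, replace = TRUE),
      tStart = sample(0:1000, n, replace = TRUE)
    ) |> score_hits()
    got <- significant_hits(h)
    want <- h[h$score > 50, ]
    want <- want[order(-want$score, want$tName, want$tStart), ]
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("reciprocal_top_hit requires the top back-hit at the expected locus", {
  own <- list(seqid = "chr5", start = 1000, end = 2000)
  top_own <- score_hits(hit(c(90, 0, 0, 0, 0), "chr5", 1500, 1800))
  expect_true(reciprocal_top_hit(top_own, own))

  # top back-hit at a paralog locus, second at the expected locus
  para_first <- score_hits(dplyr::bind_rows(
    hit(c(95, 0, 0, 0, 0), "chr8", 100, 500),
    hit(c(80, 0, 0, 0, 0), "chr5", 1200, 1700)
  ))
  res <- reciprocal_top_hit(para_first, own)
  expect_false(as.logical(res))
  expect_equal(attr(res, "reason"), "wrong-locus")

  res2 <- reciprocal_top_hit(score_hits(hit()[0, ]), own)
  expect_false(as.logical(res2))
  expect_equal(attr(res2, "reason"), "no-back-hit")

  # exact score tie between distinct loci is not guessed
  tied <- score_hits(dplyr::bind_rows(
    hit(c(90, 0, 0, 0, 0), "chr5", 1500, 1800),
    hit(c(90, 0, 0, 0, 0), "chr8", 100, 400)
  ))
  res3 <- reciprocal_top_hit(tied, own)
  expect_false(as.logical(res3))
  expect_equal(attr(res3, "reason"), "tied-top")
})

test_that("verify_secondary_hits accepts family loci and excludes chrUn", {
  hits <- score_hits(dplyr::bind_rows(
    hit(c(200, 0, 0, 0, 0), "chr1", 0, 1000),      # top
    hit(c(100, 0, 0, 0, 0), "chr2", 500, 900),     # paralog A
    hit(c(80, 0, 0, 0, 0), "chr3", 100, 300)       # paralog B
  ))
  fam <- tibble::tibble(seqid = c("chr2", "chr3"), start = c(0, 0),
                        end = c(2000, 2000))
  expect_true(verify_secondary_hits(hits, fam))
  # one secondary hit at a non-family locus: candidate novel paralog
  expect_false(verify_secondary_hits(hits, fam[1, ]))
  # hits on unplaced sequence are allelic variants, not paralogs
  un <- score_hits(dplyr::bind_rows(
    hit(c(200, 0, 0, 0, 0), "chr1", 0, 1000),
    hit(c(100, 0, 0, 0, 0), "chrUn", 0, 400),
    hit(c(90, 0, 0, 0, 0), "chr13_random", 0, 400)
  ))
  expect_true(verify_secondary_hits(un, fam[0, ]))
})

evidence <- function(...) {
  defaults <- list(gene = "G", n_models = 1, n_caret_models = 0,
                   has_taegut1_locus = FALSE, has_pacbio_locus = FALSE,
                   reciprocal_ok = TRUE, synteny = "direct",
                   found_via = "human-query", aligned_fraction = 1,
                   gapless = TRUE, flanks_adjacent_gapless = FALSE,
                   completeness_flag = FALSE)
  utils::modifyList(defaults, list(...))
}

test_that("classify_gene routes the canonical evidence patterns", {
  # annotated model, reciprocal ok, direct synteny, complete
  r <- classify_gene(evidence())
  expect_equal(r$status, "PRESENT_ANNOTATED")
  expect_equal(r$markers, character())

  # long-read-only locus, synteny traced through phylogeny
  r <- classify_gene(evidence(n_models = 0, has_pacbio_locus = TRUE,
                              synteny = "phylo-linked"))
  expect_equal(r$status, "PRESENT_PACBIO_ONLY")
  expect_equal(r$markers, "dollar")

  # severely truncated remnant on a gapless scaffold
  r <- classify_gene(evidence(n_models = 0, has_pacbio_locus = TRUE,
                              found_via = "other-species-query",
                              aligned_fraction = 0.01))
  expect_equal(r$status, "TRUNCATED")
  expect_setequal(r$markers, c("nabla", "diamond"))

  # novel-gene models take the caret
  r <- classify_gene(evidence(n_caret_models = 2, completeness_flag = TRUE))
  expect_equal(r$status, "PRESENT_NOVEL_MODEL")
  expect_setequal(r$markers, c("caret", "star"))

  # no locus + flanks adjacent on gapless scaffold = missing, no markers
  r <- classify_gene(evidence(n_models = 0, flanks_adjacent_gapless = TRUE))
  expect_equal(r$status, "MISSING")
  expect_equal(r$markers, character())

  # no locus, no flank evidence
  r <- classify_gene(evidence(n_models = 0))
  expect_equal(r$status, "UNRESOLVED")

  # contradictory evidence errors out
  expect_error(classify_gene(evidence(flanks_adjacent_gapless = TRUE)),
               "contradictory")
})

test_that("classification is a pure function of the evidence", {
  set.seed(23)
  for (i in 1:50) {
    ev <- evidence(
      n_models = sample(0:3, 1), n_caret_models = 0,
      has_taegut1_locus = sample(c(TRUE, FALSE), 1),
      has_pacbio_locus = sample(c(TRUE, FALSE), 1),
      reciprocal_ok = sample(c(TRUE, FALSE), 1),
      synteny = sample(c("direct", "phylo-linked", "unresolved", "divergent"), 1),
      found_via = sample(c("human-query", "other-species-query"), 1),
      aligned_fraction = stats::runif(1), gapless = sample(c(TRUE, FALSE), 1),
      completeness_flag = sample(c(TRUE, FALSE), 1)
    )
    ev$n_caret_models <- sample(0:ev$n_models, 1)
    a <- classify_gene(ev); b <- classify_gene(ev)
    expect_identical(a, b)
    expect_true(!identical(a$status, "TRUNCATED") || "nabla" %in% a$markers)
    expect_true(!identical(a$status, "MISSING") || length(a$markers) == 0)
  }
})
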