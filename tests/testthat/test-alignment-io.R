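psl_line <- function(...) paste(..., sep = "\t")

test_that("read_psl parses headered and headerless files and maps blocks", {
  rec <- psl_line(76, 4, 0, 0, 0, 0, 1, 120, "+", "GENE_A", 100, 10, 90,
                  "chr2", 50000, 1000, 1200, 2, "50,30,", "10,60,", "100,200,")
  f <- withr::local_tempfile(lines = rec)
  psl <- read_psl(f)
  expect_equal(nrow(psl), 1)
  expect_equal(psl$blockSizes[[1]], c(50L, 30L))
  blocks <- psl_target_blocks(psl)
  expect_equal(blocks$start, c(100L, 200L))
  expect_equal(blocks$end, c(150L, 230L))

  hdr <- c("psLayout version 3", "", "match\tmis-", "     \tmatch",
           paste(rep("-", 30), collapse = ""), rec)
  f2 <- withr::local_tempfile(lines = hdr)
  expect_equal(read_psl(f2), psl)

  f3 <- withr::local_tempfile(lines = character())
  expect_equal(nrow(read_psl(f3)), 0)
})

test_that("read_psl rejects malformed records with informative errors", {
  bad_cols <- psl_line(76, 4, 0, 0, 0, 0, 1, 120, "+", "G", 100, 10, 90,
                       "chr2", 50000, 1000, 1200, 2, "50,30,")
  f <- withr::local_tempfile(lines = bad_cols)
  expect_error(read_psl(f), "21 columns")

  # blockSizes of length 2 but tStarts of length 3
  mismatch <- psl_line(80, 0, 0, 0, 0, 0, 1, 120, "+", "G", 100, 10, 90,
                       "chr2", 50000, 1000, 1200, 2, "50,30,", "10,60,",
                       "100,200,300,")
  f2 <- withr::local_tempfile(lines = mismatch)
  expect_error(read_psl(f2), "block list lengths")

  # block sizes must sum to matches + misMatches + repMatches + nCount
  badsum <- psl_line(70, 4, 0, 0, 0, 0, 1, 120, "+", "G", 100, 10, 90,
                     "chr2", 50000, 1000, 1200, 2, "50,30,", "10,60,",
                     "100,200,")
  f3 <- withr::local_tempfile(lines = badsum)
  expect_error(read_psl(f3), "sum")
})

test_that("PSL round-trips are lossless on random records, both strands", {
  psl <- random_psl(200, seed = 41)
  f <- withr::local_tempfile()
  write_psl(psl, f)
  back <- read_psl(f)
  expect_equal(as.data.frame(back), as.data.frame(psl))
  # and the written file itself is stable
  f2 <- withr::local_tempfile()
  write_psl(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("minus-strand query coordinates are converted to forward strand", {
  rec <- psl_line(60, 0, 0, 0, 0, 0, 0, 0, "-", "G", 80, 10, 70,
                  "chr3", 40000, 2000, 2060, 1, "60,", "10,", "2000,")
  f <- withr::local_tempfile(lines = rec)
  psl <- read_psl(f)
  # reverse-query start 10, size 60, qSize 80 -> forward start 80-10-60 = 10
  expect_equal(psl$qStarts[[1]], 10L)
  f2 <- withr::local_tempfile()
  write_psl(psl, f2)
  expect_identical(readLines(f2), rec)
})

test_that("BED round-trip is lossless and invalid records are refused", {
  iv <- tibble::tibble(
    seqid = sample(c("chr1", "chr2"), 100, replace = TRUE),
    start = sample(0:10000, 100), name = sprintf("iv%03d", 1:100)
  )
  iv$end <- iv$start + sample(1:500, 100, replace = TRUE)
  f <- withr::local_tempfile()
  write_bed(iv, f)
  back <- read_bed(f)
  expect_setequal(paste(back$seqid, back$start, back$end, back$name),
                  paste(iv$seqid, iv$start, iv$end, iv$name))
  # sorted by (seqid, start)
  expect_false(is.unsorted(order(back$seqid, back$start)))

  f2 <- withr::local_tempfile()
  expect_warning(
    write_bed(tibble::tibble(seqid = "chr2", start = c(100, 150), end = c(150, 150),
                             name = c("CACNA2D2_rec", "bad")), f2),
    "start >= end")
  out <- read_bed(f2)
  expect_equal(nrow(out), 1)
  expect_equal(out$name, "CACNA2D2_rec")

  f3 <- withr::local_tempfile()
  write_bed(iv[0, ], f3)
  expect_equal(nrow(read_bed(f3)), 0)
})

test_that("read_annotation sums split models and catches duplicates", {
  tsv <- c("species\tgene\tseqid\tstart\tend\tstrand\tmodel_id\tmodel_length",
           "finch\tCACNA2D2\tchr12\t100\t700\t+\tm1\t400",
           "finch\tCACNA2D2\tchr12\t900\t1500\t+\tm2\t600",
           "finch\tSCN3A\tchr9\t0\t2000\t-\tm3\t2000")
  f <- withr::local_tempfile(lines = tsv)
  ann <- read_annotation(f)
  expect_equal(ann$model_length[ann$gene == "CACNA2D2"], 1000L)
  expect_equal(ann$model_length[ann$gene == "SCN3A"], 2000L)
  expect_equal(ann$model_ids[[which(ann$gene == "CACNA2D2")]], c("m1", "m2"))

  f2 <- withr::local_tempfile(lines = c(tsv, tsv[2]))
  expect_error(read_annotation(f2), "duplicate")

  f3 <- withr::local_tempfile(
    lines = "species\tgene\tseqid\tstart\tend\tstrand\tmodel_id\tmodel_length")
  expect_equal(nrow(read_annotation(f3)), 0)

  # rows with missing coordinates are skipped with a warning
  f4 <- withr::local_tempfile(lines = c(tsv, "finch\tXX\t\t\t\t+\tm4\t10"))
  expect_warning(ann4 <- read_annotation(f4), "missing coordinates")
  expect_false("XX" %in% ann4$gene)
})

test_that("read_annotation maps GFF3 gene lines only, converting coordinates", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;Name=SCN8A",
           "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
           "chr1\tsrc\texon\t101\t150\t.\t+\t.\tParent=t1",
           "chr2\tsrc\tgene\t501\t900\t.\t-\t.\tID=g2")
  f <- withr::local_tempfile(lines = gff)
  ann <- read_annotation(f, format = "gff3", species = "finch")
  expect_equal(nrow(ann), 2)
  expect_equal(ann$start[ann$gene == "SCN8A"], 100L)  # 1-based -> 0-based
  expect_equal(ann$end[ann$gene == "SCN8A"], 200L)
  expect_true("g2" %in% ann$gene)  # falls back to ID
})

test_that("read_species_tree validates rootedness and label uniqueness", {
  f <- withr::local_tempfile(lines = "(alligator,(ratite,(chicken,finch)));")
  tr <- read_species_tree(f)
  expect_equal(length(tr$tip.label), 4)
  br <- tree_branches(tr)
  neog <- br[vapply(br$leaves, function(l) setequal(l, c("chicken", "finch")),
                    NA), ]
  expect_equal(nrow(neog), 1)

  f2 <- withr::local_tempfile(lines = "(a,(b,(a,c)));")
  expect_error(read_species_tree(f2), "duplicate")

  f3 <- withr::local_tempfile(lines = "(a,b,(c,d));")
  expect_error(read_species_tree(f3), "unrooted")

  f4 <- withr::local_tempfile(lines = c("(a,(b,c));", "(a,(b,c));"))
  expect_error(read_species_tree(f4), "more than one tree")

  # parse/serialize round trip preserves the leaf set
  set.seed(5)
  tr20 <- ape::rtree(20, rooted = TRUE)
  f5 <- withr::local_tempfile()
  ape::write.tree(tr20, f5)
  expect_setequal(read_species_tree(f5)$tip.label, tr20$tip.label)
})
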