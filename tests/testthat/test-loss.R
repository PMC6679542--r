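test_that("call_missing_locus follows the adjacency/gap decision rule", {
  expect_equal(as.character(call_missing_locus(TRUE, TRUE, TRUE)), "missing-high")
  expect_equal(as.character(call_missing_locus(TRUE, TRUE, FALSE)),
               "missing-tentative")
  # flanks at the ends of different scaffolds
  v <- call_missing_locus(FALSE, NA, NA)
  expect_equal(as.character(v), "undetermined")
  expect_equal(attr(v, "reason"), "flanks-not-colocated")
  # a surviving significant intergenic hit blocks the call
  hits <- score_hits(tibble::tibble(matches = 80L, repMatches = 0L,
                                    misMatches = 0L, qNumInsert = 0L,
                                    tNumInsert = 0L, tName = "s", tStart = 1L))
  expect_equal(as.character(call_missing_locus(TRUE, TRUE, TRUE, hits)),
               "undetermined")
  # sub-significant intergenic hits do not
  weak <- score_hits(tibble::tibble(matches = 40L, repMatches = 0L,
                                    misMatches = 0L, qNumInsert = 0L,
                                    tNumInsert = 0L, tName = "s", tStart = 1L))
  expect_equal(as.character(call_missing_locus(TRUE, TRUE, TRUE, weak)),
               "missing-high")
  expect_equal(as.character(call_missing_locus(TRUE, FALSE, TRUE)),
               "undetermined")
})

test_that("call_truncation separates pseudogenes from partial models", {
  expect_equal(call_truncation(0.02, TRUE, FALSE), "truncated-pseudogene")
  expect_equal(call_truncation(0.02, FALSE, FALSE), "partial-model")
  expect_equal(call_truncation(0.02, TRUE, TRUE), "partial-model")
  expect_equal(call_truncation(0.95, TRUE, TRUE), "intact")
  expect_equal(call_truncation(0.25, TRUE, FALSE), "intact")  # strict <
})

test_that("place_loss recovers the canonical avian loss patterns", {
  tr <- ape::read.tree(text = "(((finch,chicken)Neognathae,ratite)Aves,alligator)Root;")
  p <- tibble::tibble(species = c("finch", "chicken", "ratite", "alligator"),
                      state = c("absent", "absent", "present", "present"),
                      quality = c("gapless", "gapless", "gapless", "gapless"))
  pl <- place_loss(p, tr)
  expect_equal(pl$branch_label, "Neognathae")
  expect_equal(attr(pl, "n_losses"), 1L)
  expect_equal(attr(pl, "confidence"), "high")

  # with the ratite absent as well, only the avian stem explains one loss
  p2 <- p; p2$state <- c("absent", "absent", "absent", "present")
  pl2 <- place_loss(p2, tr)
  expect_equal(pl2$branch_label, "Aves")

  # unknown relatives widen the candidate set but keep the terminal branch
  tr2 <- ape::read.tree(
    text = "(((zf,(bf,gf)inner)finches,tit)Passeriformes,out)Root;")
  p3 <- tibble::tibble(
    species = c("zf", "bf", "gf", "tit", "out"),
    state = c("absent", "unknown", "unknown", "present", "present"))
  pl3 <- place_loss(p3, tr2)
  expect_setequal(pl3$branch_label, c("zf", "finches"))
  expect_true(pl3$maximal[pl3$branch_label == "finches"])

  # gappy evidence downgrades confidence
  p$quality[1] <- "fragmented"
  expect_equal(attr(place_loss(p, tr), "confidence"), "tentative")

  # all-present profile: nothing to place
  p4 <- p; p4$state <- rep("present", 4)
  expect_equal(nrow(place_loss(p4, tr)), 0)
  # no present leaf: unplaceable
  p5 <- p; p5$state <- rep("absent", 4)
  expect_error(place_loss(p5, tr), "not in clade")
})

test_that("place_loss equals exhaustive minimal-Dollo enumeration", {
  # all rooted labelled topologies on 4 leaves x all state assignments
  trees4 <- lapply(phangorn::allTrees(4, rooted = TRUE), function(tr) {
    tr$tip.label <- c("a", "b", "c", "d"); tr
  })
  states4 <- expand.grid(rep(list(c("present", "absent", "unknown")), 4),
                         stringsAsFactors = FALSE)
  for (tr in trees4) {
    for (i in seq_len(nrow(states4))) {
      st <- stats::setNames(unlist(states4[i, ]), c("a", "b", "c", "d"))
      if (!any(st == "present")) next
      oracle <- dollo_oracle(tr, st)
      prof <- tibble::tibble(species = names(st), state = unname(st))
      pl <- place_loss(prof, tr)
      expect_equal(attr(pl, "n_losses"), oracle$k,
                   info = paste(ape::write.tree(tr), paste(st, collapse = ",")))
      expect_setequal(pl$node, oracle$nodes)
    }
  }
})

test_that("Dollo placement matches enumeration on random larger trees", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(6:8, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    tr$tip.label <- letters[seq_len(n)]
    st <- stats::setNames(sample(c("present", "absent", "unknown"), n,
                                 replace = TRUE, prob = c(.5, .3, .2)),
                          tr$tip.label)
    if (!any(st == "present")) st[sample(n, 1)] <- "present"
    oracle <- dollo_oracle(tr, st)
    pl <- place_loss(tibble::tibble(species = names(st), state = unname(st)), tr)
    expect_equal(attr(pl, "n_losses"), oracle$k)
    expect_setequal(pl$node, oracle$nodes)
    # no-unknown profiles give exactly one branch per loss event
    if (!any(st == "unknown")) {
      expect_equal(nrow(pl), attr(pl, "n_losses"))
    }
  }
})

test_that("masking a leaf to unknown never shrinks the ambiguity set", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    tr$tip.label <- letters[seq_len(n)]
    st <- stats::setNames(sample(c("present", "absent"), n, replace = TRUE),
                          tr$tip.label)
    if (!any(st == "present")) st[sample(n, 1)] <- "present"
    if (!any(st == "absent")) st[sample(n, 1)] <- "absent"
    before <- place_loss(tibble::tibble(species = names(st), state = unname(st)), tr)
    # the monotonicity guarantee concerns single-loss profiles; masking a
    # present leaf that separates two loss events can merge them instead
    if (attr(before, "n_losses") != 1) next
    mask <- sample(names(st), 1)
    st2 <- st; st2[mask] <- "unknown"
    if (!any(st2 == "present") || !any(st2 == "absent")) next
    after <- place_loss(tibble::tibble(species = names(st2), state = unname(st2)), tr)
    expect_true(all(before$node %in% after$node))
  }
})

test_that("loss_category labels clades and detects lineage-specific gains", {
  tree <- load_paper_fixture("species_tree")
  profs <- load_paper_fixture("loss_profiles")
  p <- profs[profs$gene == "CACNG6", ]
  pl <- place_loss(p, tree)
  expect_equal(loss_category(pl, tree, p), "Missing in all birds")
  p2 <- profs[profs$gene == "SCN7A", ]
  expect_equal(loss_category(place_loss(p2, tree), tree, p2),
               "Unique to mammals")
})
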