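#' BLAT alignment score
#'
#' The browser-BLAT score: `matches + repMatches - misMatches - qNumInsert -
#' tNumInsert`. Hits scoring above 50 are treated as significant throughout
#' the pipeline.
#'
#' @param psl A PSL tibble ([read_psl()]) or any data frame with the five
#'   component columns.
#' @return Integer vector of scores, one per record.
#' @examples
#' blat_score(tibble::tibble(matches = 60, repMatches = 0, misMatches = 5,
#'                           qNumInsert = 2, tNumInsert = 1))  # 52
#' @export
blat_score <- function(psl) {
  as.integer(psl$matches + psl$repMatches - psl$misMatches -
               psl$qNumInsert - psl$tNumInsert)
}

#' Filter and rank significant hits
#'
#' Keeps hits with score strictly above `min_score` (default 50), sorted by
#' descending score with deterministic `(tName, tStart)` tie-breaking.
#'
#' @param hits Tibble with at least `score`, `tName`, `tStart` columns
#'   (a scored PSL tibble; see [score_hits()]).
#' @param min_score Significance cutoff; hits must score strictly above it.
#' @return The significant subset of `hits`, ranked.
#' @export
significant_hits <- function(hits, min_score = 50) {
  hits |>
    filter(.data$score > min_score) |>
    arrange(dplyr::desc(.data$score), .data$tName, .data$tStart)
}

#' Attach BLAT scores to a PSL tibble
#'
#' @param psl A PSL tibble.
#' @return `psl` with a `score` column appended.
#' @export
score_hits <- function(psl) {
  mutate(psl, score = blat_score(psl))
}

#' Reciprocal top-hit test
#'
#' A candidate ortholog passes when the top significant back-alignment of
#' its model overlaps the expected query locus by at least one base. An
#' exact score tie between distinct top back-hits is treated as a failure
#' (no guessing), and an empty significant back-hit list fails with reason
#' `"no-back-hit"`.
#'
#' @param back_hits Scored PSL tibble of the model aligned back to the
#'   query genome.
#' @param expected_locus One-row data frame or list with `seqid`, `start`,
#'   `end` (0-based half-open) of the original query gene.
#' @param min_score Significance cutoff.
#' @return Logical scalar with attribute `reason` (`"ok"`, `"no-back-hit"`,
#'   `"wrong-locus"`, or `"tied-top"`).
#' @export
reciprocal_top_hit <- function(back_hits, expected_locus, min_score = 50) {
  sig <- significant_hits(back_hits, min_score)
  if (nrow(sig) == 0) return(structure(FALSE, reason = "no-back-hit"))
  if (nrow(sig) > 1 && sig$score[2] == sig$score[1] &&
      !(sig$tName[2] == sig$tName[1] && overlaps(sig[2, ], sig[1, ]))) {
    return(structure(FALSE, reason = "tied-top"))
  }
  top <- sig[1, ]
  hit <- top$tName == expected_locus$seqid &&
    top$tStart < expected_locus$end && top$tEnd > expected_locus$start
  structure(isTRUE(hit), reason = if (isTRUE(hit)) "ok" else "wrong-locus")
}

overlaps <- function(a, b) a$tStart < b$tEnd && a$tEnd > b$tStart

#' Verify that secondary alignments land on known family loci
#'
#' The significant non-top hits of a query must all overlap a known locus of
#' a same-family gene; a secondary hit elsewhere flags a candidate novel
#' paralog. Hits on unplaced sequence (`chrUn*`, `*_random`) are excluded
#' before the check, as those represent allelic variants rather than
#' paralogs.
#'
#' @param hits Scored PSL tibble, all hits for one query against one genome.
#' @param family_loci Tibble of known same-family loci with `seqid`,
#'   `start`, `end`.
#' @param min_score Significance cutoff.
#' @return Logical: `TRUE` when every retained secondary hit is accounted
#'   for by a family locus.
#' @export
verify_secondary_hits <- function(hits, family_loci, min_score = 50) {
  sig <- significant_hits(hits, min_score)
  if (nrow(sig) <= 1) return(TRUE)
  sec <- sig[-1, , drop = FALSE]
  sec <- sec[!is_unplaced_seq(sec$tName), , drop = FALSE]
  if (nrow(sec) == 0) return(TRUE)
  if (is.null(family_loci) || nrow(family_loci) == 0) return(FALSE)
  ok <- vapply(seq_len(nrow(sec)), function(i) {
    any(family_loci$seqid == sec$tName[i] &
          family_loci$start < sec$tEnd[i] &
          family_loci$end > sec$tStart[i])
  }, logical(1))
  all(ok)
}

#' Classify one gene's evidence into a status tier and marker set
#'
#' Deterministic routing of accumulated per-gene evidence into the final
#' status used in the complement report:
#'
#' * a locus with a severely truncated alignment (`aligned_fraction` below
#'   `truncation_fraction`) on a gapless scaffold is `TRUNCATED` (marker
#'   `nabla`);
#' * otherwise a reciprocally confirmed locus with direct synteny -- or one
#'   whose synteny was traced through phylogenetic relationships
#'   (`phylo-linked`, marker `dollar`) or could not be linked (`unresolved`,
#'   marker `hash`) -- is `PRESENT_*`, tiered by model evidence:
#'   `PRESENT_ANNOTATED` (correctly annotated model), `PRESENT_NOVEL_MODEL`
#'   ("novel gene" model(s), marker `caret`), `PRESENT_NO_MODEL` (assembly
#'   locus without a prediction), `PRESENT_PACBIO_ONLY` (locus only in the
#'   long-read assembly);
#' * a gene with no locus anywhere whose syntenic flanks sit adjacent on a
#'   gapless scaffold is `MISSING` (no markers); without that flank evidence
#'   it is `UNRESOLVED`.
#'
#' Additional markers: `diamond` when the locus was found with a non-focal
#' (other-species) query, `star` when the model failed the completeness
#' check.
#'
#' @param evidence One-row data frame or list with fields `gene`,
#'   `n_models`, `n_caret_models`, `has_taegut1_locus` (any placed-assembly
#'   locus), `has_pacbio_locus`, `reciprocal_ok`, `synteny` (one of
#'   `direct`, `phylo-linked`, `unresolved`, `divergent`), `found_via`
#'   (`human-query` / `other-species-query`), `aligned_fraction`, `gapless`,
#'   `flanks_adjacent_gapless`, `completeness_flag`.
#' @param truncation_fraction Truncation threshold on the aligned fraction
#'   of the ortholog (strict `<`).
#' @return A list with `gene`, `status`, `markers` (character vector).
#' @export
classify_gene <- function(evidence, truncation_fraction = 0.25) {
  e <- as.list(evidence)
  has_model <- isTRUE(e$n_models > 0)
  has_locus <- has_model || isTRUE(e$has_taegut1_locus) || isTRUE(e$has_pacbio_locus)

  if (!has_locus) {
    if (isTRUE(e$flanks_adjacent_gapless)) {
      return(list(gene = e$gene, status = "MISSING", markers = character()))
    }
    return(list(gene = e$gene, status = "UNRESOLVED", markers = character()))
  }
  if (isTRUE(e$flanks_adjacent_gapless)) {
    abort(sprintf("contradictory evidence for %s: locus found but flanks adjacent (missing-gene evidence)",
                  e$gene))
  }

  markers <- character()
  if (isTRUE(e$n_caret_models > 0)) markers <- c(markers, "caret")
  if (identical(e$synteny, "phylo-linked")) markers <- c(markers, "dollar")
  if (identical(e$synteny, "unresolved")) markers <- c(markers, "hash")
  if (identical(e$found_via, "other-species-query")) markers <- c(markers, "diamond")
  if (isTRUE(e$completeness_flag)) markers <- c(markers, "star")

  if (!is.null(e$aligned_fraction) && !is.na(e$aligned_fraction) &&
      e$aligned_fraction < truncation_fraction && isTRUE(e$gapless)) {
    return(list(gene = e$gene, status = "TRUNCATED",
                markers = sort(unique(c(markers, "nabla")))))
  }

  placed <- (isTRUE(e$reciprocal_ok) && identical(e$synteny, "direct")) ||
    identical(e$synteny, "phylo-linked") || identical(e$synteny, "unresolved")
  if (!placed) {
    return(list(gene = e$gene, status = "UNRESOLVED", markers = character()))
  }
  status <- if (has_model) {
    if (isTRUE(e$n_caret_models > 0)) "PRESENT_NOVEL_MODEL" else "PRESENT_ANNOTATED"
  } else if (isTRUE(e$has_taegut1_locus)) {
    "PRESENT_NO_MODEL"
  } else {
    "PRESENT_PACBIO_ONLY"
  }
  list(gene = e$gene, status = status, markers = sort(unique(markers)))
}

#' Classify a table of gene evidence rows
#'
#' Vectorised wrapper around [classify_gene()].
#'
#' @param evidence Tibble with one row per gene (see [classify_gene()]).
#' @param truncation_fraction Truncation threshold.
#' @return Tibble with columns `gene`, `status`, `markers` (semicolon-joined
#'   string), `marker_list` (list-column).
#' @export
classify_genes <- function(evidence, truncation_fraction = 0.25) {
  res <- lapply(seq_len(nrow(evidence)),
                function(i) classify_gene(evidence[i, ], truncation_fraction))
  tibble(
    gene = vapply(res, `[[`, character(1), "gene"),
    status = vapply(res, `[[`, character(1), "status"),
    markers = vapply(res, function(r) paste(r$markers, collapse = ";"), character(1)),
    marker_list = lapply(res, `[[`, "markers")
  )
}
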