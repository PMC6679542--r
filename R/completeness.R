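#' Model length ratio against the reference ortholog
#'
#' Split (non-overlapping) models at one locus are summed before dividing by
#' the reference model length; ratios above 1 are possible.
#'
#' @param focal_lengths Numeric vector of focal-species model lengths at the
#'   locus (bases); must be non-empty.
#' @param reference_length Reference (e.g. human) model length in bases;
#'   must be positive.
#' @return The length ratio `sum(focal_lengths) / reference_length`.
#' @examples
#' length_ratio(c(400, 600), 2000)  # 0.5
#' @export
length_ratio <- function(focal_lengths, reference_length) {
  if (length(focal_lengths) == 0) abort("focal_lengths must be non-empty")
  if (!is.numeric(reference_length) || reference_length <= 0) {
    abort("reference_length must be a positive number")
  }
  sum(focal_lengths) / reference_length
}

#' Subtract one set of alignment blocks from another
#'
#' Both interval sets live on the same target genome and are merged per
#' sequence before the set difference `reference \ target` is taken,
#' returning the maximal disjoint intervals of reference-aligned sequence
#' not covered by any target block. This is the core of sequence recovery:
#' blocks where a more complete cross-species model aligns but the focal
#' model does not.
#'
#' @param reference_blocks,target_blocks Tibbles of 0-based half-open
#'   intervals with columns `seqid`, `start`, `end`; blocks within a set may
#'   overlap.
#' @return Tibble of disjoint intervals (`seqid`, `start`, `end`), sorted.
#' @examples
#' subtract_blocks(
#'   tibble::tibble(seqid = "chr1", start = c(100, 300), end = c(200, 400)),
#'   tibble::tibble(seqid = "chr1", start = 150, end = 350)
#' )
#' @export
subtract_blocks <- function(reference_blocks, target_blocks) {
  empty <- tibble(seqid = character(), start = integer(), end = integer())
  if (is.null(reference_blocks) || nrow(reference_blocks) == 0) return(empty)
  if (is.null(target_blocks)) target_blocks <- empty
  out <- lapply(sort(unique(reference_blocks$seqid)), function(sq) {
    ref <- reference_blocks[reference_blocks$seqid == sq, ]
    tgt <- target_blocks[target_blocks$seqid == sq, ]
    # IRanges works on 1-based closed intervals; shift on the way in/out
    r <- IRanges::reduce(IRanges::IRanges(start = ref$start + 1L, end = ref$end))
    t <- if (nrow(tgt) == 0) IRanges::IRanges()
    else IRanges::reduce(IRanges::IRanges(start = tgt$start + 1L, end = tgt$end))
    d <- IRanges::setdiff(r, t)
    tibble(seqid = sq, start = IRanges::start(d) - 1L, end = IRanges::end(d))
  })
  bind_rows(out) |> arrange(.data$seqid, .data$start)
}

#' Per-gene sequence recovery statistics
#'
#' Compares the top-scoring alignment of a complete reference-species model
#' with that of the focal-species model at the same locus. Reference blocks
#' not covered by any focal block are "recovered" sequence the focal model
#' is missing; the percent-of-post-recovery length is
#' `model_length / (model_length + bases_recovered)`, and models below
#' `flag_threshold` (strictly) are flagged incomplete.
#'
#' @param gene Gene symbol.
#' @param ref_alignment One-row PSL tibble: top-scoring alignment of the
#'   reference model to the focal genome. If absent (`NULL` or zero rows)
#'   the gene is excluded and `NULL` is returned.
#' @param focal_alignment One-row PSL tibble for the focal model, or `NULL`
#'   when the locus has no focal model alignment.
#' @param focal_model_length Focal model length in bases (split models
#'   summed).
#' @param reference_model_length Optional reference model length for the
#'   companion length ratio.
#' @param flag_threshold Completeness flag threshold (strict `<`).
#' @return One-row tibble with `gene`, `model_length`, `length_ratio`,
#'   `bases_recovered`, `percent_post_recovery`, `flagged`,
#'   `recovered_blocks` (list-column of interval tibbles); or `NULL` when
#'   the gene is excluded.
#' @export
recovery_stats <- function(gene, ref_alignment, focal_alignment,
                           focal_model_length, reference_model_length = NA,
                           flag_threshold = 0.90) {
  if (is.null(ref_alignment) || nrow(ref_alignment) == 0) return(NULL)
  ref_blocks <- psl_target_blocks(ref_alignment[1, ])[, c("seqid", "start", "end")]
  focal_blocks <- if (is.null(focal_alignment) || nrow(focal_alignment) == 0) {
    NULL
  } else {
    psl_target_blocks(focal_alignment[1, ])[, c("seqid", "start", "end")]
  }
  rec <- subtract_blocks(ref_blocks, focal_blocks)
  bases <- sum(rec$end - rec$start)
  ppr <- focal_model_length / (focal_model_length + bases)
  tibble(
    gene = gene,
    model_length = as.integer(focal_model_length),
    length_ratio = if (is.na(reference_model_length)) NA_real_
    else length_ratio(focal_model_length, reference_model_length),
    bases_recovered = as.integer(bases),
    percent_post_recovery = ppr,
    flagged = ppr < flag_threshold,
    recovered_blocks = list(rec)
  )
}

#' Export recovered sequence blocks as a BED track
#'
#' One BED6 record per recovered block, named `<gene>_rec<N>`, sorted.
#'
#' @param records Tibble of recovery records ([recovery_stats()] rows).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
export_recovery_track <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    return(write_bed(tibble(seqid = character(), start = integer(),
                            end = integer(), name = character()), path))
  }
  blocks <- purrr::map2(records$recovered_blocks, records$gene, function(b, g) {
    if (nrow(b) == 0) return(NULL)
    mutate(b, name = paste0(g, "_rec", row_number()))
  }) |> bind_rows()
  if (is.null(blocks) || nrow(blocks) == 0) {
    blocks <- tibble(seqid = character(), start = integer(),
                     end = integer(), name = character())
  }
  write_bed(blocks, path)
}

#' Completeness bin counts for a model-quality table
#'
#' Tallies how many genes fall below the 90% and 75% cutoffs (strict `<`)
#' on the two completeness metrics.
#'
#' @param table Tibble with columns `length_ratio` and
#'   `percent_post_recovery` (NAs are ignored per metric).
#' @return Tibble with one row: `ratio_lt_90`, `ratio_lt_75`, `ppr_lt_90`,
#'   `ppr_lt_75`.
#' @export
completeness_bins <- function(table) {
  tibble(
    ratio_lt_90 = sum(table$length_ratio < 0.90, na.rm = TRUE),
    ratio_lt_75 = sum(table$length_ratio < 0.75, na.rm = TRUE),
    ppr_lt_90 = sum(table$percent_post_recovery < 0.90, na.rm = TRUE),
    ppr_lt_75 = sum(table$percent_post_recovery < 0.75, na.rm = TRUE)
  )
}
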