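#' Call a missing locus from flanking-gene evidence
#'
#' Encodes the decision rule for candidate gene losses: when the two
#' syntenic flanking genes sit adjacent on a single scaffold and no
#' significant alignment of the gene can be found between them, the locus is
#' called missing -- with high confidence when the scaffold is gapless (as
#' long-read assemblies are), tentatively when the intergenic region
#' contains assembly gaps. Flanks at the ends of different scaffolds, flanks
#' that could not be located, or a surviving significant intergenic hit all
#' leave the call undetermined.
#'
#' @param same_scaffold Logical: both flanks located on one scaffold.
#' @param adjacent Logical: no other annotated gene intervenes between the
#'   flanks.
#' @param gapless Logical: the intergenic region carries no assembly gaps.
#' @param intergenic_hits Scored PSL tibble of gene alignments falling
#'   between the flanks (may be empty or `NULL`).
#' @param min_score Significance cutoff for intergenic hits.
#' @return One of `"missing-high"`, `"missing-tentative"`,
#'   `"undetermined"`, with attribute `reason`.
#' @export
call_missing_locus <- function(same_scaffold, adjacent, gapless,
                               intergenic_hits = NULL, min_score = 50) {
  if (is.na(same_scaffold) || !isTRUE(same_scaffold)) {
    return(structure("undetermined", reason = "flanks-not-colocated"))
  }
  n_sig <- if (is.null(intergenic_hits) || nrow(intergenic_hits) == 0) 0L
  else nrow(significant_hits(intergenic_hits, min_score))
  if (n_sig > 0) {
    return(structure("undetermined", reason = "significant-intergenic-hit"))
  }
  if (!isTRUE(adjacent)) {
    return(structure("undetermined", reason = "flanks-not-adjacent"))
  }
  if (isTRUE(gapless)) {
    structure("missing-high", reason = "adjacent-gapless-no-hit")
  } else {
    structure("missing-tentative", reason = "adjacent-gappy-no-hit")
  }
}

#' Call truncation / pseudogenization from aligned fraction
#'
#' A locus retaining only a small fraction of its ortholog on a gapless
#' scaffold, with no expression evidence, is a likely pseudogene; the same
#' fraction on a gappy scaffold (where sequence may be hidden in gaps) or
#' with expression support is merely a partial model.
#'
#' @param aligned_fraction Fraction of the ortholog covered by the aligned
#'   locus, in `[0, 1]`.
#' @param gapless Logical: scaffold free of assembly gaps.
#' @param expression_evidence Logical: EST or other expression support.
#' @param threshold Truncation threshold (strict `<`), shared with
#'   [classify_gene()].
#' @return One of `"truncated-pseudogene"`, `"partial-model"`, `"intact"`.
#' @export
call_truncation <- function(aligned_fraction, gapless, expression_evidence,
                            threshold = 0.25) {
  stopifnot(aligned_fraction >= 0, aligned_fraction <= 1)
  if (aligned_fraction >= threshold) return("intact")
  if (isTRUE(gapless) && !isTRUE(expression_evidence)) "truncated-pseudogene"
  else "partial-model"
}

#' Place gene losses on a species tree by Dollo parsimony
#'
#' Under a Dollo model (one gain, possibly several losses) the minimal
#' explanation of a presence/absence/unknown profile is one loss on the stem
#' of each maximal clade whose known states are all absent. Unknown-state
#' leaves widen each placement into an ambiguity set: every branch that
#' subtends all of that clade's absent leaves and no present leaf is
#' compatible with the observations. The maximal compatible branch is always
#' included, and adding unknowns can only grow the set.
#'
#' @param profile Tibble with columns `species`, `state`
#'   (`present`/`absent`/`unknown`) and optionally `quality`
#'   (`gapless`/`gappy`/`fragmented`). At least one present leaf is
#'   required; species missing from the profile are treated as unknown.
#' @param tree Rooted [ape::phylo] whose tips cover the profiled species.
#' @return An object of class `loss_placement`: a tibble of candidate loss
#'   branches with columns `component` (one per independent loss event),
#'   `branch_label`, `node`, `n_leaves`, `leaves` (list-column), `maximal`
#'   (flags the maximal branch of each component). Attributes: `gene` (if a
#'   `gene` column was present), `confidence` (`"high"` when every absence
#'   is backed by gapless evidence, else `"tentative"`), `n_losses`.
#' @export
place_loss <- function(profile, tree) {
  profile <- as_tibble(profile)
  missing_sp <- setdiff(profile$species, tree$tip.label)
  if (length(missing_sp) > 0) {
    abort(paste0("profile species not in tree: ", paste(missing_sp, collapse = ", ")))
  }
  states <- stats::setNames(rep("unknown", length(tree$tip.label)), tree$tip.label)
  states[profile$species] <- profile$state
  present <- names(states)[states == "present"]
  absent <- names(states)[states == "absent"]
  if (length(present) == 0) {
    abort("no present leaf: the gene cannot be placed on this tree (not in clade)")
  }

  br <- tree_branches(tree)
  empty <- br[0, ]
  empty$component <- integer(); empty$maximal <- logical()
  if (length(absent) == 0) {
    out <- empty[, c("component", "label", "node", "n_leaves", "leaves", "maximal")]
    names(out)[2] <- "branch_label"
    return(structure(out, class = c("loss_placement", class(out)),
                     confidence = "high", n_losses = 0L,
                     gene = profile_gene(profile)))
  }

  no_present <- map_lgl(br$leaves, function(l) length(intersect(l, present)) == 0)
  has_absent <- map_lgl(br$leaves, function(l) length(intersect(l, absent)) > 0)
  cand <- br[no_present & has_absent, , drop = FALSE]
  # maximal candidates = independent loss events
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    !any(vapply(seq_len(nrow(cand)), function(j) {
      j != i && all(cand$leaves[[i]] %in% cand$leaves[[j]])
    }, logical(1)))
  }, logical(1))
  maximal <- cand[is_max, , drop = FALSE]

  rows <- list()
  for (ci in seq_len(nrow(maximal))) {
    comp_leaves <- maximal$leaves[[ci]]
    comp_absent <- intersect(comp_leaves, absent)
    # every compatible branch subtends all of this component's absents
    keep <- map_lgl(cand$leaves, function(l) {
      all(l %in% comp_leaves) && all(comp_absent %in% l)
    })
    comp <- cand[keep, , drop = FALSE]
    comp$component <- ci
    comp$maximal <- map_lgl(comp$leaves, function(l) setequal(l, comp_leaves))
    rows[[ci]] <- comp
  }
  out <- bind_rows(rows) |>
    select(component = "component", branch_label = "label", "node",
           "n_leaves", "leaves", "maximal") |>
    arrange(.data$component, .data$n_leaves)

  conf <- "high"
  if ("quality" %in% names(profile)) {
    q <- profile$quality[profile$state == "absent"]
    if (any(!is.na(q) & q != "gapless")) conf <- "tentative"
  }
  structure(out, class = c("loss_placement", class(out)),
            confidence = conf, n_losses = nrow(maximal),
            gene = profile_gene(profile))
}

profile_gene <- function(profile) {
  if ("gene" %in% names(profile)) profile$gene[1] else NA_character_
}

#' @export
print.loss_placement <- function(x, ...) {
  gene <- attr(x, "gene")
  cat(sprintf("<loss placement>%s %d loss event(s), confidence %s\n",
              if (!is.na(gene)) paste0(" ", gene, ":") else "",
              attr(x, "n_losses"), attr(x, "confidence")))
  NextMethod()
}

#' Derive a loss-category label from a placement
#'
#' Maps the maximal candidate branch of each loss event to a human-readable
#' category ("Missing in <clade>"). When every present leaf falls inside a
#' designated ingroup-external clade (by default one labelled `Mammalia`),
#' the more parsimonious reading is a lineage-specific gain and the gene is
#' labelled unique to that clade.
#'
#' @param placement A `loss_placement`.
#' @param tree The tree used for placement.
#' @param profile The profile used for placement.
#' @param label_map Named character vector translating branch labels to
#'   display names (e.g. `c(Aves = "all birds")`).
#' @param gain_clade_label Label of the clade treated as a potential
#'   lineage-specific gain.
#' @param gain_display Display name for that clade in the category string.
#' @return A single category string.
#' @export
loss_category <- function(placement, tree, profile,
                          label_map = c(Aves = "all birds"),
                          gain_clade_label = "Mammalia",
                          gain_display = "mammals") {
  br <- tree_branches(tree)
  gain <- br[br$label == gain_clade_label, ]
  present <- profile$species[profile$state == "present"]
  if (nrow(gain) == 1 && length(present) > 0 &&
      all(present %in% gain$leaves[[1]])) {
    return(paste0("Unique to ", gain_display))
  }
  if (nrow(placement) == 0) return("No loss")
  maxima <- placement$branch_label[placement$maximal]
  # the widest loss event names the category
  widest <- maxima[which.max(placement$n_leaves[placement$maximal])]
  shown <- if (widest %in% names(label_map)) label_map[[widest]] else widest
  paste0("Missing in ", shown)
}
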