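#' Configuration for the synthetic comparative-genomics generator
#'
#' Bundles and validates every rate the generator uses. The defaults are
#' the package's reference study conditions: a handful of species related
#' by a random rooted tree, gene neighbourhoods perturbed by rare
#' inversions and translocations (avian genomes are deeply syntenic),
#' 5% planted losses and 5% planted truncations, gapless long-read-like
#' focal assemblies, and alignment scores without jitter. See the methods
#' vignette for the rationale behind each value.
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param n_species Number of leaf species on the simulated tree.
#' @param n_genes Number of genes in the ancestral genome.
#' @param n_families Number of gene families (paralogy groups).
#' @param cluster_fraction Fraction of genes arranged in tandem family
#'   clusters in the ancestral genome.
#' @param inversion_rate,translocation_rate Expected rearrangement events
#'   per branch.
#' @param loss_rate Per-gene probability of a planted loss (on a random
#'   branch). Losses leave the flanking genes adjacent, emulating clean
#'   deletion of the locus.
#' @param truncation_rate Per-gene probability of a planted truncation in
#'   one random species; the remnant retains 8--20% of the gene, enough to
#'   stay above the hit-significance cutoff.
#' @param gap_rate Probability that a scaffold is gappy rather than
#'   gapless.
#' @param scaffold_break_rate Per-junction probability of a scaffold break.
#' @param alignment_score_noise Standard deviation (bases) of jitter
#'   applied to each alignment's aligned length.
#' @param ish_availability_rate Probability a gene has an in situ probe.
#' @param assay_disagreement_rate Probability the microarray call differs
#'   from the true (in situ) call.
#' @param unknown_rate Probability a leaf's presence state is masked to
#'   unknown in the emitted profile.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_species = 6, n_genes = 60, n_families = 12,
                       cluster_fraction = 0.2, inversion_rate = 0.2,
                       translocation_rate = 0.05, loss_rate = 0.05,
                       truncation_rate = 0.05, gap_rate = 0,
                       scaffold_break_rate = 0.05, alignment_score_noise = 0,
                       ish_availability_rate = 0.6,
                       assay_disagreement_rate = 0.1, unknown_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_species = n_species, n_genes = n_genes,
              n_families = n_families, cluster_fraction = cluster_fraction,
              inversion_rate = inversion_rate,
              translocation_rate = translocation_rate, loss_rate = loss_rate,
              truncation_rate = truncation_rate, gap_rate = gap_rate,
              scaffold_break_rate = scaffold_break_rate,
              alignment_score_noise = alignment_score_noise,
              ish_availability_rate = ish_availability_rate,
              assay_disagreement_rate = assay_disagreement_rate,
              unknown_rate = unknown_rate)
  probs <- c("cluster_fraction", "loss_rate", "truncation_rate", "gap_rate",
             "scaffold_break_rate", "ish_availability_rate",
             "assay_disagreement_rate", "unknown_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(sprintf("%s must be in [0, 1]", p))
  }
  if (cfg$inversion_rate < 0 || cfg$translocation_rate < 0 ||
      cfg$alignment_score_noise < 0) {
    abort("event rates and score noise must be non-negative")
  }
  if (cfg$n_families > cfg$n_genes) {
    abort("infeasible config: more families (clusters) than genes")
  }
  if (cfg$n_species < 3) abort("need at least 3 species")
  structure(cfg, class = "sim_config")
}

# all-or-none window constraint for glued gene sets (lost genes + flanks)
window_ok <- function(ord, i, j, glued) {
  for (set in glued) {
    pos <- which(ord %in% set)
    if (length(pos) < 2) next
    inside <- pos >= i & pos <= j
    if (any(inside) && !all(inside)) return(FALSE)
  }
  TRUE
}

junction_protected <- function(ord, p, glued) {
  # junction between positions p and p+1
  for (set in glued) {
    if (ord[p] %in% set && ord[p + 1] %in% set) return(TRUE)
  }
  FALSE
}

apply_rearrangements <- function(ord, strand, cfg, glued) {
  n <- length(ord)
  n_inv <- stats::rpois(1, cfg$inversion_rate)
  for (e in seq_len(n_inv)) {
    for (try in 1:20) {
      i <- sample.int(n - 1, 1)
      j <- min(n, i + sample.int(6, 1))
      if (window_ok(ord, i, j, glued)) {
        ord[i:j] <- rev(ord[i:j])
        strand[i:j] <- rev(ifelse(strand[i:j] == "+", "-", "+"))
        break
      }
    }
  }
  n_trans <- stats::rpois(1, cfg$translocation_rate)
  for (e in seq_len(n_trans)) {
    movable <- which(!ord %in% unlist(glued))
    if (length(movable) == 0) break
    for (try in 1:20) {
      src <- movable[sample.int(length(movable), 1)]
      g <- ord[src]; s <- strand[src]
      ord2 <- ord[-src]; strand2 <- strand[-src]
      # insertion splits the junction (dest, dest + 1) of the post-removal
      # order, so protection is checked there
      dest <- sample.int(length(ord2) - 1, 1)
      if (!junction_protected(ord2, dest, glued)) {
        ord <- append(ord2, g, after = dest)
        strand <- append(strand2, s, after = dest)
        break
      }
    }
  }
  list(ord = ord, strand = strand)
}

#' Simulate a ground-truthed comparative-genomics dataset
#'
#' Generates, deterministically under `config$seed`: a random rooted
#' species tree; an ancestral gene order (with tandem family clusters)
#' evolved down the tree by inversions and translocations; planted gene
#' losses (flanks kept adjacent) and truncations; fragmented assemblies
#' with per-scaffold gap status; block-level PSL alignments of every query
#' gene against every species (orthologs outscore paralogs; optional score
#' jitter) and of every species model back to the query genome; a
#' tri-state presence profile; two-assay expression calls; and the ground
#' truth for all of it.
#'
#' @param config A [sim_config()].
#' @return A list of class `ion_sim` with elements `config`, `tree`,
#'   `genes`, `query_annotation`, `annotations`, `scaffolds`, `psl_fwd`,
#'   `psl_back`, `profiles`, `expression`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  tree <- ape::rtree(cfg$n_species, rooted = TRUE)
  tree$tip.label <- sprintf("sp%02d", seq_len(cfg$n_species))
  tree$node.label <- sprintf("anc%02d", seq_len(tree$Nnode))

  fam <- rep(seq_len(cfg$n_families), length.out = cfg$n_genes)
  genes <- tibble(
    gene = sprintf("FAM%02d_G%03d", fam, seq_len(cfg$n_genes)),
    family = sprintf("FAM%02d", fam),
    length = sample(900:6000, cfg$n_genes, replace = TRUE)
  )

  # ancestral order: some families as tandem cluster blocks, rest shuffled
  n_clustered_target <- round(cfg$cluster_fraction * cfg$n_genes)
  fams <- split(genes$gene, genes$family)
  fam_order <- sample(names(fams))
  clustered_fams <- character()
  tot <- 0
  for (f in fam_order) {
    if (tot >= n_clustered_target) break
    if (length(fams[[f]]) >= 2) {
      clustered_fams <- c(clustered_fams, f)
      tot <- tot + length(fams[[f]])
    }
  }
  units <- c(lapply(clustered_fams, function(f) fams[[f]]),
             as.list(unlist(fams[setdiff(names(fams), clustered_fams)],
                            use.names = FALSE)))
  root_ord <- unlist(units[sample.int(length(units))], use.names = FALSE)
  root_strand <- sample(c("+", "-"), length(root_ord), replace = TRUE)

  br <- tree_branches(tree)
  # planted losses: interior, mutually non-adjacent genes
  lost <- tibble(gene = character(), node = integer(), label = character(),
                 leaves = list())
  cand <- sample(genes$gene)
  taken_pos <- integer()
  for (g in cand) {
    if (stats::runif(1) >= cfg$loss_rate) next
    p <- match(g, root_ord)
    if (p <= 1 || p >= length(root_ord)) next
    if (any(abs(taken_pos - p) <= 1)) next
    bi <- sample.int(nrow(br), 1)
    lost <- bind_rows(lost, tibble(gene = g, node = br$node[bi],
                                   label = br$label[bi],
                                   leaves = br$leaves[bi]))
    taken_pos <- c(taken_pos, p)
  }
  glued <- lapply(match(lost$gene, root_ord), function(p) root_ord[(p - 1):(p + 1)])

  # planted truncations in one random species each (never on lost genes)
  trunc <- tibble(gene = character(), species = character(), fraction = double())
  for (g in setdiff(genes$gene, lost$gene)) {
    if (stats::runif(1) < cfg$truncation_rate) {
      trunc <- bind_rows(trunc, tibble(
        gene = g, species = sample(tree$tip.label, 1),
        fraction = stats::runif(1, 0.08, 0.20)
      ))
    }
  }

  # evolve orders down the tree (preorder over edges)
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  orders <- vector("list", ntip + tree$Nnode)
  strands <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  orders[[root]] <- root_ord; strands[[root]] <- root_strand
  for (ei in seq_len(nrow(tree_cw$edge))) {
    par <- tree_cw$edge[ei, 1]; child <- tree_cw$edge[ei, 2]
    ord <- orders[[par]]; strand <- strands[[par]]
    drop <- lost$gene[lost$node == child]
    if (length(drop) > 0) {
      keep <- !ord %in% drop
      ord <- ord[keep]; strand <- strand[keep]
    }
    res <- apply_rearrangements(ord, strand, cfg, glued)
    orders[[child]] <- res$ord; strands[[child]] <- res$strand
  }

  glen <- stats::setNames(genes$length, genes$gene)
  build_annotation <- function(species, ord, strand, scaffold_of, lengths) {
    starts <- integer(length(ord)); ends <- integer(length(ord))
    pos <- 0L; cur <- scaffold_of[1]
    for (i in seq_along(ord)) {
      if (scaffold_of[i] != cur) { cur <- scaffold_of[i]; pos <- 0L }
      starts[i] <- pos + 500L
      ends[i] <- starts[i] + as.integer(lengths[i])
      pos <- ends[i]
    }
    tibble(species = species, gene = ord, seqid = scaffold_of,
           start = starts, end = ends, strand = strand,
           model_id = paste0(species, "_", ord),
           model_length = as.integer(lengths))
  }

  annotations <- list(); scaffolds <- list()
  for (sp_i in seq_len(ntip)) {
    sp <- tree$tip.label[sp_i]
    ord <- orders[[sp_i]]; strand <- strands[[sp_i]]
    # scaffold breaks, avoiding the protected flank junctions of lost genes
    breaks <- logical(length(ord) - 1)
    for (p in seq_along(breaks)) {
      if (stats::runif(1) < cfg$scaffold_break_rate &&
          !junction_protected(ord, p, glued)) breaks[p] <- TRUE
    }
    scaf_idx <- cumsum(c(1L, as.integer(breaks)))
    scaf_names <- sprintf("%s_scaf%02d", sp, scaf_idx)
    lens <- glen[ord]
    tr <- trunc[trunc$species == sp, ]
    if (nrow(tr) > 0) {
      m <- match(tr$gene, ord)
      lens[m[!is.na(m)]] <- round(lens[m[!is.na(m)]] * tr$fraction[!is.na(m)])
    }
    annotations[[sp]] <- build_annotation(sp, ord, strand, scaf_names, lens)
    scaffolds[[sp]] <- tibble(
      species = sp, seqid = unique(scaf_names),
      gapless = stats::runif(length(unique(scaf_names))) >= cfg$gap_rate
    )
  }
  annotations <- bind_rows(annotations)
  scaffolds <- bind_rows(scaffolds)

  query_annotation <- build_annotation("query", root_ord, root_strand,
                                       rep("q_chr1", length(root_ord)),
                                       glen[root_ord])

  # vectorised PSL construction from (qName, qSize, tName, tStart, aligned)
  make_psl_batch <- function(df) {
    aligned <- pmax(50L, pmin(as.integer(df$qSize), as.integer(round(df$aligned))))
    mis <- as.integer(round(0.05 * aligned))
    two <- aligned > 400
    a1 <- aligned %/% 2L
    tibble(
      matches = aligned - mis, misMatches = mis, repMatches = 0L, nCount = 0L,
      qNumInsert = 0L, qBaseInsert = 0L,
      tNumInsert = ifelse(two, 1L, 0L), tBaseInsert = ifelse(two, 100L, 0L),
      # alignment orientation, not gene strand; simulated hits are co-oriented
      strand = "+", qName = df$qName, qSize = as.integer(df$qSize),
      qStart = 0L, qEnd = aligned, tName = df$tName, tSize = 10000000L,
      tStart = as.integer(df$tStart),
      tEnd = as.integer(df$tStart + aligned + ifelse(two, 100L, 0L)),
      blockCount = ifelse(two, 2L, 1L),
      blockSizes = purrr::map2(aligned, a1, function(al, a) {
        if (al > 400) c(a, al - a) else al
      }),
      qStarts = purrr::map2(aligned, a1, function(al, a) {
        if (al > 400) c(0L, a) else 0L
      }),
      tStarts = purrr::pmap(list(df$tStart, aligned, a1), function(t0, al, a) {
        if (al > 400) c(as.integer(t0), as.integer(t0 + a + 100L)) else as.integer(t0)
      }),
      species = df$species
    )
  }
  jitter <- function(x) {
    if (cfg$alignment_score_noise == 0) return(x)
    x + stats::rnorm(length(x), 0, cfg$alignment_score_noise)
  }

  fam_of <- stats::setNames(genes$family, genes$gene)
  q_start <- stats::setNames(query_annotation$start, query_annotation$gene)
  q_strand <- stats::setNames(query_annotation$strand, query_annotation$gene)

  ann <- annotations
  # ortholog alignments: query gene onto its true locus, and the model back
  fwd_spec <- tibble(qName = ann$gene, qSize = glen[ann$gene],
                     tName = ann$seqid, tStart = ann$start,
                     aligned = jitter(0.95 * ann$model_length),
                     strand = ann$strand, species = ann$species)
  back_spec <- tibble(qName = ann$model_id, qSize = ann$model_length,
                      tName = "q_chr1", tStart = q_start[ann$gene],
                      aligned = jitter(0.95 * ann$model_length),
                      strand = q_strand[ann$gene], species = ann$species)
  # paralog cross-hits within each family, both directions
  pairs <- ann |>
    mutate(family = fam_of[.data$gene]) |>
    dplyr::inner_join(
      ann |> mutate(family = fam_of[.data$gene]) |>
        select(species2 = "species", gene2 = "gene", seqid2 = "seqid",
               start2 = "start", strand2 = "strand", "family"),
      by = "family", relationship = "many-to-many") |>
    filter(.data$species == .data$species2, .data$gene != .data$gene2) |>
    mutate(pal = 0.40 * pmin(glen[.data$gene], glen[.data$gene2])) |>
    filter(.data$pal > 60)
  fwd_spec <- bind_rows(fwd_spec, tibble(
    qName = pairs$gene, qSize = glen[pairs$gene], tName = pairs$seqid2,
    tStart = pairs$start2, aligned = jitter(pairs$pal),
    strand = pairs$strand2, species = pairs$species))
  back_spec <- bind_rows(back_spec, tibble(
    qName = pairs$model_id, qSize = pairs$model_length, tName = "q_chr1",
    tStart = q_start[pairs$gene2],
    aligned = jitter(pmin(pairs$pal, 0.4 * pairs$model_length)),
    strand = q_strand[pairs$gene2], species = pairs$species))
  psl_fwd <- make_psl_batch(fwd_spec)
  psl_back <- make_psl_batch(back_spec)

  # tri-state profile with per-leaf evidence quality
  scaf_gapless <- stats::setNames(scaffolds$gapless,
                                  paste(scaffolds$species, scaffolds$seqid))
  left_flank <- stats::setNames(vapply(glued, `[`, character(1), 1), lost$gene)
  ann_seq <- stats::setNames(annotations$seqid,
                             paste(annotations$species, annotations$gene))
  lost_leaves <- stats::setNames(lost$leaves, lost$gene)
  profiles <- tidyr::expand_grid(gene = genes$gene, species = tree$tip.label) |>
    mutate(
      state = purrr::map2_chr(.data$gene, .data$species, function(g, sp) {
        if (!is.null(lost_leaves[[g]]) && sp %in% lost_leaves[[g]]) "absent" else "present"
      }),
      state = ifelse(cfg$unknown_rate > 0 &
                       stats::runif(n()) < cfg$unknown_rate, "unknown", .data$state),
      seqid = purrr::pmap_chr(list(.data$gene, .data$species, .data$state),
                              function(g, sp, st) {
        key <- paste(sp, g)
        if (st == "present" && !is.na(ann_seq[key])) return(ann_seq[[key]])
        if (!is.na(left_flank[g])) {
          fkey <- paste(sp, left_flank[[g]])
          if (!is.na(ann_seq[fkey])) return(ann_seq[[fkey]])
        }
        NA_character_
      }),
      quality = dplyr::case_when(
        is.na(.data$seqid) ~ "fragmented",
        purrr::map2_lgl(.data$species, .data$seqid, function(sp, sq) {
          !is.na(sq) && isTRUE(scaf_gapless[paste(sp, sq)][[1]])
        }) ~ "gapless",
        TRUE ~ "gappy"
      ),
      seqid = NULL
    )
  # keep every gene placeable: at least one present leaf survives masking
  fix <- profiles |> group_by(.data$gene) |>
    summarise(ok = any(.data$state == "present"), .groups = "drop")
  for (g in fix$gene[!fix$ok]) {
    lost_in <- if (g %in% lost$gene) lost$leaves[[match(g, lost$gene)]] else character()
    sp_ok <- setdiff(tree$tip.label, lost_in)[1]
    profiles$state[profiles$gene == g & profiles$species == sp_ok] <- "present"
  }

  # two-assay expression calls over the song nuclei
  nuclei <- c("HVC", "RA", "AreaX", "LMAN", "nXIIts", "DLM", "Uva", "NIf")
  calls <- c("higher", "lower", "nondifferential")
  expr_truth <- tidyr::expand_grid(gene = genes$gene, nucleus = nuclei) |>
    mutate(true_call = sample(calls, n(), replace = TRUE, prob = c(.25, .25, .5)))
  has_ish <- stats::setNames(stats::runif(nrow(genes)) < cfg$ish_availability_rate,
                             genes$gene)
  expression <- expr_truth |>
    mutate(
      ish = ifelse(has_ish[.data$gene], .data$true_call, NA_character_),
      flip = stats::runif(n()) < cfg$assay_disagreement_rate,
      microarray = ifelse(
        .data$flip,
        purrr::map_chr(.data$true_call, function(tc) sample(setdiff(calls, tc), 1)),
        .data$true_call)
    ) |>
    select("gene", "nucleus", "microarray", "ish") |>
    tidyr::pivot_longer(c("microarray", "ish"), names_to = "assay",
                        values_to = "call") |>
    filter(!is.na(.data$call)) |>
    mutate(sparse = FALSE)

  truth_status <- tidyr::expand_grid(gene = genes$gene, species = tree$tip.label) |>
    mutate(status = dplyr::case_when(
      purrr::map2_lgl(.data$gene, .data$species, function(g, sp) {
        g %in% lost$gene && sp %in% lost$leaves[[match(g, lost$gene)]]
      }) ~ "missing",
      purrr::map2_lgl(.data$gene, .data$species, function(g, sp) {
        any(trunc$gene == g & trunc$species == sp)
      }) ~ "truncated",
      TRUE ~ "present"
    ))

  structure(list(
    config = cfg, tree = tree, genes = genes,
    query_annotation = query_annotation, annotations = annotations,
    scaffolds = scaffolds, psl_fwd = psl_fwd, psl_back = psl_back,
    profiles = profiles, expression = expression,
    truth = list(losses = lost, truncations = trunc,
                 status = truth_status, expression = expr_truth)
  ), class = "ion_sim")
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits exactly what the analysis functions consume: a Newick tree,
#' per-species annotation TSVs and forward/back PSL files, the query
#' annotation, the tri-state profile matrix, and the expression calls.
#'
#' @param sim An `ion_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  flat <- function(a) mutate(a, model_ids = NULL)
  readr::write_tsv(flat(sim$query_annotation), file.path(dir, "query_annotation.tsv"))
  for (sp in unique(sim$annotations$species)) {
    readr::write_tsv(flat(sim$annotations[sim$annotations$species == sp, ]),
                     file.path(dir, paste0("annotation_", sp, ".tsv")))
    write_psl(sim$psl_fwd[sim$psl_fwd$species == sp,
                          setdiff(names(sim$psl_fwd), "species")],
              file.path(dir, paste0("fwd_", sp, ".psl")))
    write_psl(sim$psl_back[sim$psl_back$species == sp,
                           setdiff(names(sim$psl_back), "species")],
              file.path(dir, paste0("back_", sp, ".psl")))
  }
  readr::write_tsv(sim$profiles, file.path(dir, "profiles.tsv"))
  readr::write_tsv(sim$expression, file.path(dir, "expression.tsv"))
  invisible(dir)
}
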