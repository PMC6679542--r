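#' Build the oriented flanking-gene context of a locus
#'
#' Returns the `k` nearest annotated genes on each side of the focal gene on
#' its scaffold, ordered by increasing distance. A side cut short by a
#' scaffold end is flagged, since an absent neighbour then carries no
#' evidence.
#'
#' @param annotation Annotation tibble ([read_annotation()]) for one species.
#' @param gene Focal gene symbol (must be present in `annotation`).
#' @param k Number of flanking genes per side.
#' @return An object of class `synteny_context`: a list with `gene`, `k`,
#'   `upstream` / `downstream` (tibbles with `gene`, `strand`, ordered
#'   nearest-first), and `edge_upstream` / `edge_downstream` flags.
#' @export
flanking_context <- function(annotation, gene, k = 2) {
  hit <- filter(annotation, .data$gene == !!gene)
  if (nrow(hit) == 0) abort(sprintf("gene %s not found in annotation", gene))
  hit <- hit[1, ]
  scaf <- annotation |>
    filter(.data$seqid == hit$seqid,
           if ("species" %in% names(annotation)) .data$species == hit$species else TRUE) |>
    arrange(.data$start)
  pos <- which(scaf$gene == gene)[1]
  up_idx <- rev(seq_len(pos - 1))            # nearest first
  down_idx <- seq(pos + 1, length.out = max(0, nrow(scaf) - pos))
  up <- scaf[utils::head(up_idx, k), c("gene", "strand")]
  down <- scaf[utils::head(down_idx, k), c("gene", "strand")]
  structure(list(
    gene = gene, k = k,
    upstream = up, downstream = down,
    edge_upstream = length(up_idx) < k,
    edge_downstream = length(down_idx) < k
  ), class = "synteny_context")
}

#' @export
print.synteny_context <- function(x, ...) {
  cat(sprintf("<synteny context> %s (k = %d)\n", x$gene, x$k))
  cat(" upstream:  ", paste0(x$upstream$gene, "(", x$upstream$strand, ")", collapse = " "),
      if (x$edge_upstream) " [scaffold edge]" else "", "\n", sep = "")
  cat(" downstream:", paste0(x$downstream$gene, "(", x$downstream$strand, ")", collapse = " "),
      if (x$edge_downstream) " [scaffold edge]" else "", "\n", sep = "")
  invisible(x)
}

#' Test synteny conservation between two flanking contexts
#'
#' Conservation is deliberately tolerant of rearrangement: a context side
#' counts as matched when at least one of its gene symbols occurs anywhere
#' among the other context's flanks (either side -- inversions may swap
#' sides; order and orientation are not required to agree). The verdict is
#' `"direct"` when both sides of both contexts are matched, `"divergent"`
#' when no symbol is shared at all, and `"unresolvable"` when an unmatched
#' side is truncated by a scaffold edge in either context (the test could
#' not be performed there). The function is symmetric in its arguments.
#'
#' @param ctx_a,ctx_b `synteny_context` objects built with the same `k`.
#' @return `"direct"`, `"divergent"`, or `"unresolvable"`.
#' @export
synteny_conserved <- function(ctx_a, ctx_b) {
  all_a <- c(ctx_a$upstream$gene, ctx_a$downstream$gene)
  all_b <- c(ctx_b$upstream$gene, ctx_b$downstream$gene)
  side_ok <- function(side_genes, other_all) length(intersect(side_genes, other_all)) > 0
  checks <- c(
    up_a = side_ok(ctx_a$upstream$gene, all_b),
    down_a = side_ok(ctx_a$downstream$gene, all_b),
    up_b = side_ok(ctx_b$upstream$gene, all_a),
    down_b = side_ok(ctx_b$downstream$gene, all_a)
  )
  if (all(checks)) return("direct")
  edges <- c(
    up_a = ctx_a$edge_upstream, down_a = ctx_a$edge_downstream,
    up_b = ctx_b$edge_upstream, down_b = ctx_b$edge_downstream
  )
  if (length(intersect(all_a, all_b)) == 0 && !any(edges)) return("divergent")
  if (any(!checks & edges)) return("unresolvable")
  "divergent"
}

#' Link syntenies through intermediate species
#'
#' When the focal-species context does not directly match the query-species
#' context, conservation may still be traceable through a chain of
#' intermediate species, each of which must (1) share conserved synteny
#' with its chain neighbours and (2) itself align preferentially back to
#' the correct query locus. A breadth-first search returns the shortest
#' such chain.
#'
#' @param contexts Named list of `synteny_context` objects, one per species.
#' @param back_hit_ok Named logical vector: does each species' model align
#'   preferentially back to the correct query locus?
#' @param query_species,target_species Chain endpoints.
#' @param tree Optional [ape::phylo]; when given, neighbour expansion is
#'   ordered by phylogenetic proximity to keep chains biologically short.
#' @return A list with `verdict` (`"direct"`, `"phylo-linked"`, or
#'   `"unresolved"`) and `chain` (species vector, empty when unresolved).
#' @export
link_via_phylogeny <- function(contexts, back_hit_ok, query_species,
                               target_species, tree = NULL) {
  stopifnot(query_species %in% names(contexts), target_species %in% names(contexts))
  direct <- synteny_conserved(contexts[[query_species]], contexts[[target_species]])
  if (direct == "direct") {
    return(list(verdict = "direct", chain = c(query_species, target_species)))
  }
  species <- names(contexts)
  order_by <- function(cands, from) {
    if (!is.null(tree) && all(c(cands, from) %in% tree$tip.label)) {
      d <- ape::cophenetic.phylo(tree)[from, cands]
      cands[order(d, cands)]
    } else sort(cands)
  }
  conserved <- function(a, b) synteny_conserved(contexts[[a]], contexts[[b]]) == "direct"
  usable <- function(s) isTRUE(back_hit_ok[[s]])
  # BFS for the shortest chain; intermediates must pass both criteria
  queue <- list(query_species)
  parent <- stats::setNames(vector("list", length(species)), species)
  visited <- query_species
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    cands <- setdiff(species, visited)
    for (nxt in order_by(cands, cur)) {
      if (!conserved(cur, nxt)) next
      if (nxt != target_species && !usable(nxt)) next
      parent[[nxt]] <- cur
      if (nxt == target_species) {
        chain <- nxt
        while (chain[1] != query_species) chain <- c(parent[[chain[1]]], chain)
        return(list(verdict = "phylo-linked", chain = chain))
      }
      visited <- c(visited, nxt)
      queue <- c(queue, nxt)
    }
  }
  list(verdict = "unresolved", chain = character())
}

#' Resolve orthology within a tandem gene cluster
#'
#' BLAT hits within clusters of tandem family members often smear across
#' the cluster; member-level orthology is decided by the one-to-one
#' assignment of query members to target members that maximises the number
#' of order-consistent pairs, allowing a whole-cluster reversal. Clusters of
#' unequal size yield a partial assignment with the leftovers reported.
#'
#' @param query_cluster Character vector of query cluster members, in
#'   scaffold order.
#' @param target_cluster Character vector of target cluster members (gene
#'   symbols or locus names), in scaffold order.
#' @return A list with `assignment` (tibble `query`, `target`), `unassigned`
#'   (character), `reversed` (logical), `consistent_pairs` (count).
#' @export
resolve_cluster <- function(query_cluster, target_cluster) {
  nq <- length(query_cluster); nt <- length(target_cluster)
  if (nq == 0 || nt == 0) {
    return(list(assignment = tibble(query = character(), target = character()),
                unassigned = query_cluster, reversed = FALSE, consistent_pairs = 0L))
  }
  if (max(nq, nt) > 8) abort("cluster too large for exhaustive assignment (> 8 members)")
  k <- min(nq, nt)
  q_sets <- utils::combn(nq, k, simplify = FALSE)
  t_perms <- perms(nt, k)
  best <- NULL
  for (qs in q_sets) {
    for (tp in seq_len(nrow(t_perms))) {
      tpos <- t_perms[tp, ]
      fwd <- count_consistent(qs, tpos)
      rev_ <- count_consistent(qs, -tpos)
      score <- max(fwd, rev_)
      # shared symbols break ties between equally order-consistent maps
      sym <- sum(query_cluster[qs] == target_cluster[tpos])
      cand <- list(qs = qs, tpos = tpos, score = score, sym = sym,
                   reversed = rev_ > fwd)
      if (is.null(best) || score > best$score ||
          (score == best$score && sym > best$sym) ||
          (score == best$score && sym == best$sym &&
             assignment_key(cand) < assignment_key(best))) {
        best <- cand
      }
    }
  }
  assignment <- tibble(query = query_cluster[best$qs],
                       target = target_cluster[best$tpos])
  list(
    assignment = assignment,
    unassigned = setdiff(query_cluster, assignment$query),
    reversed = best$reversed,
    consistent_pairs = as.integer(best$score)
  )
}

# all ordered k-selections from 1..n (rows)
perms <- function(n, k) {
  if (k == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (comb in utils::combn(n, k, simplify = FALSE)) {
    p <- permutations_of(comb)
    out <- rbind(out, p)
  }
  out
}

permutations_of <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], permutations_of(v[-i]))
  }))
}

count_consistent <- function(qpos, tpos) {
  k <- length(qpos)
  if (k < 2) return(0L)
  pairs <- utils::combn(k, 2)
  sum((qpos[pairs[1, ]] - qpos[pairs[2, ]]) * (tpos[pairs[1, ]] - tpos[pairs[2, ]]) > 0)
}

assignment_key <- function(cand) paste(cand$qs, cand$tpos, collapse = "-")
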