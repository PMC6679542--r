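# Independent brute-force oracles and random-input generators.

# random valid PSL tibble in the package's internal representation
random_psl <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    nb <- sample(1:4, 1)
    bs <- sample(20:200, nb, replace = TRUE)
    gaps_t <- if (nb > 1) sample(0:300, nb - 1, replace = TRUE) else integer()
    ts0 <- sample(0:5000, 1)
    ts <- ts0 + cumsum(c(0L, utils::head(bs, -1) + gaps_t))
    strand <- sample(c("+", "-"), 1)
    qsize <- sum(bs) + sample(0:100, 1)
    # forward-query starts, contiguous blocks (descending for minus strand)
    qs_fwd <- if (strand == "+") cumsum(c(0L, utils::head(bs, -1)))
    else rev(cumsum(c(0L, utils::head(rev(bs), -1)))) + (qsize - sum(bs))
    mis <- sample(0:5, 1)
    tot <- sum(bs)
    tibble::tibble(
      matches = tot - mis, misMatches = mis, repMatches = 0L, nCount = 0L,
      qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = nb - 1L,
      tBaseInsert = sum(gaps_t), strand = strand,
      qName = sprintf("q%03d", i), qSize = qsize,
      qStart = min(qs_fwd), qEnd = max(qs_fwd + bs),
      tName = sample(c("chr1", "chr2", "scafA"), 1), tSize = 100000L,
      tStart = ts[1], tEnd = ts[nb] + bs[nb], blockCount = nb,
      blockSizes = list(as.integer(bs)), qStarts = list(as.integer(qs_fwd)),
      tStarts = list(as.integer(ts))
    )
  })
  dplyr::bind_rows(rows)
}

random_intervals <- function(n, max_coord = 10000, seqids = c("chr1", "chr2")) {
  start <- sample(0:(max_coord - 2), n, replace = TRUE)
  len <- sample(1:500, n, replace = TRUE)
  tibble::tibble(
    seqid = sample(seqids, n, replace = TRUE),
    start = start, end = pmin(start + len, max_coord)
  )
}

# per-base membership oracle for interval subtraction
subtract_oracle <- function(ref, tgt, max_coord = 10000) {
  out <- lapply(sort(unique(ref$seqid)), function(sq) {
    covered_ref <- rep(FALSE, max_coord)
    for (i in which(ref$seqid == sq)) {
      covered_ref[(ref$start[i] + 1):ref$end[i]] <- TRUE
    }
    covered_tgt <- rep(FALSE, max_coord)
    for (i in which(tgt$seqid == sq)) {
      covered_tgt[(tgt$start[i] + 1):tgt$end[i]] <- TRUE
    }
    keep <- which(covered_ref & !covered_tgt)
    if (length(keep) == 0) return(NULL)
    runs <- split(keep, cumsum(c(1, diff(keep) != 1)))
    dplyr::bind_rows(lapply(runs, function(r) {
      tibble::tibble(seqid = sq, start = min(r) - 1L, end = max(r))
    }))
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(seqid = character(), start = integer(), end = integer()))
  }
  dplyr::arrange(res, seqid, start)
}

# exhaustive minimal-Dollo enumeration: minimal sets of loss branches whose
# induced absence pattern is compatible with the observed states
dollo_oracle <- function(tree, states) {
  br <- tree_branches(tree)
  known <- states[states != "unknown"]
  absent <- names(known)[known == "absent"]
  compatible <- function(nodes) {
    under <- unique(unlist(br$leaves[br$node %in% nodes]))
    all(names(known)[known == "absent"] %in% under) &&
      !any(names(known)[known == "present"] %in% under)
  }
  if (length(absent) == 0) return(list(k = 0L, nodes = integer()))
  for (k in 1:nrow(br)) {
    subsets <- utils::combn(br$node, k, simplify = FALSE)
    ok <- Filter(compatible, subsets)
    if (length(ok) > 0) {
      return(list(k = k, nodes = sort(unique(unlist(ok)))))
    }
  }
  list(k = NA_integer_, nodes = integer())
}

random_annotation <- function(n_genes = 50, seqid = "scaf1", species = "spX",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- sort(sample(0:100000, n_genes))
  tibble::tibble(
    species = species,
    gene = sprintf("G%03d", sample(seq_len(n_genes))),
    seqid = seqid, start = starts, end = starts + 400L,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    model_length = 400L
  )
}

# exhaustive best assignment between two ordered clusters (reversal allowed)
cluster_oracle <- function(qc, tc) {
  k <- min(length(qc), length(tc))
  best <- -1L
  qsets <- utils::combn(seq_along(qc), k, simplify = FALSE)
  perm_all <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perm_all(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  tperms <- unlist(lapply(utils::combn(seq_along(tc), k, simplify = FALSE),
                          perm_all), recursive = FALSE)
  consistent <- function(qp, tp) {
    if (k < 2) return(0L)
    pr <- utils::combn(k, 2)
    fw <- sum((qp[pr[1, ]] - qp[pr[2, ]]) * (tp[pr[1, ]] - tp[pr[2, ]]) > 0)
    rv <- sum((qp[pr[1, ]] - qp[pr[2, ]]) * (tp[pr[2, ]] - tp[pr[1, ]]) > 0)
    max(fw, rv)
  }
  for (qs in qsets) for (tp in tperms) {
    best <- max(best, consistent(qs, tp))
  }
  best
}
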