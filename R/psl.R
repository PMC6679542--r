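#' Read a PSL (BLAT) alignment file
#'
#' Parses the tab-delimited 21-column PSL format produced by BLAT, with or
#' without the 5-line `psLayout` header. Block lists (`blockSizes`,
#' `qStarts`, `tStarts`) are returned as list-columns of integers.
#'
#' Coordinates are kept 0-based half-open throughout. For minus-strand
#' records the per-block query starts are converted to forward-strand query
#' coordinates on read (`qSize - qStart - blockSize`), so that all downstream
#' interval arithmetic is strand-free; [write_psl()] reverses the
#' conversion, making the round trip lossless.
#'
#' @param path Path to a PSL file.
#' @return A tibble with one row per alignment and columns `matches`,
#'   `misMatches`, `repMatches`, `nCount`, `qNumInsert`, `qBaseInsert`,
#'   `tNumInsert`, `tBaseInsert`, `strand`, `qName`, `qSize`, `qStart`,
#'   `qEnd`, `tName`, `tSize`, `tStart`, `tEnd`, `blockCount`, and
#'   list-columns `blockSizes`, `qStarts`, `tStarts`.
#' @examples
#' psl <- read_psl(system.file("extdata", "example.psl", package = "orthochannel"))
#' @export
read_psl <- function(path) {
  lines <- readr::read_lines(path)
  # drop the optional 5-line header: "psLayout ..." down to the dashed rule
  rule <- grep("^-{10,}", lines)
  if (length(rule) > 0) lines <- lines[-seq_len(rule[1])]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_psl())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 21L)
  if (length(bad) > 0) {
    abort(sprintf("PSL parse error at line %d: expected 21 columns, found %d",
                  bad[1], length(fields[[bad[1]]])))
  }
  m <- do.call(rbind, fields)
  psl <- tibble(
    matches = as.integer(m[, 1]), misMatches = as.integer(m[, 2]),
    repMatches = as.integer(m[, 3]), nCount = as.integer(m[, 4]),
    qNumInsert = as.integer(m[, 5]), qBaseInsert = as.integer(m[, 6]),
    tNumInsert = as.integer(m[, 7]), tBaseInsert = as.integer(m[, 8]),
    strand = m[, 9], qName = m[, 10], qSize = as.integer(m[, 11]),
    qStart = as.integer(m[, 12]), qEnd = as.integer(m[, 13]),
    tName = m[, 14], tSize = as.integer(m[, 15]),
    tStart = as.integer(m[, 16]), tEnd = as.integer(m[, 17]),
    blockCount = as.integer(m[, 18]),
    blockSizes = split_int_list(m[, 19]),
    qStarts = split_int_list(m[, 20]),
    tStarts = split_int_list(m[, 21])
  )
  # minus strand: query block starts arrive in reverse-complemented query
  # coordinates; convert to forward-query so downstream math is strand-free.
  # Block order (ascending in target) is left untouched.
  minus <- psl$strand == "-"
  if (any(minus)) {
    psl$qStarts[minus] <- purrr::pmap(
      list(psl$qStarts[minus], psl$blockSizes[minus], psl$qSize[minus]),
      function(q, s, size) size - q - s
    )
  }
  validate_psl(psl)
  psl
}

empty_psl <- function() {
  tibble(
    matches = integer(), misMatches = integer(), repMatches = integer(),
    nCount = integer(), qNumInsert = integer(), qBaseInsert = integer(),
    tNumInsert = integer(), tBaseInsert = integer(), strand = character(),
    qName = character(), qSize = integer(), qStart = integer(),
    qEnd = integer(), tName = character(), tSize = integer(),
    tStart = integer(), tEnd = integer(), blockCount = integer(),
    blockSizes = list(), qStarts = list(), tStarts = list()
  )
}

validate_psl <- function(psl) {
  for (i in seq_len(nrow(psl))) {
    bs <- psl$blockSizes[[i]]; qs <- psl$qStarts[[i]]; ts <- psl$tStarts[[i]]
    if (length(bs) != length(qs) || length(bs) != length(ts)) {
      abort(sprintf("PSL record %d (%s): block list lengths differ (%d sizes, %d qStarts, %d tStarts)",
                    i, psl$qName[i], length(bs), length(qs), length(ts)))
    }
    if (length(bs) != psl$blockCount[i]) {
      abort(sprintf("PSL record %d (%s): blockCount %d but %d blocks listed",
                    i, psl$qName[i], psl$blockCount[i], length(bs)))
    }
    tot <- psl$matches[i] + psl$misMatches[i] + psl$repMatches[i] + psl$nCount[i]
    if (sum(bs) != tot) {
      abort(sprintf("PSL record %d (%s): block sizes sum to %d but matches+misMatches+repMatches+nCount = %d",
                    i, psl$qName[i], sum(bs), tot))
    }
    if (length(ts) > 1) {
      ends <- ts + bs
      if (any(ts[-1] < ends[-length(ends)])) {
        abort(sprintf("PSL record %d (%s): target blocks overlap or are unsorted",
                      i, psl$qName[i]))
      }
    }
  }
  invisible(psl)
}

#' Write alignments back to PSL
#'
#' Inverse of [read_psl()]; minus-strand query block coordinates are
#' converted back to the PSL convention before writing.
#'
#' @param psl A tibble as returned by [read_psl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psl <- function(psl, path) {
  out <- psl
  minus <- out$strand == "-"
  if (any(minus)) {
    out$qStarts[minus] <- purrr::pmap(
      list(out$qStarts[minus], out$blockSizes[minus], out$qSize[minus]),
      function(q, s, size) size - q - s
    )
  }
  lines <- purrr::pmap_chr(out, function(...) {
    r <- list(...)
    paste(r$matches, r$misMatches, r$repMatches, r$nCount, r$qNumInsert,
          r$qBaseInsert, r$tNumInsert, r$tBaseInsert, r$strand, r$qName,
          r$qSize, r$qStart, r$qEnd, r$tName, r$tSize, r$tStart, r$tEnd,
          r$blockCount, fmt_int_list(list(r$blockSizes)),
          fmt_int_list(list(r$qStarts)), fmt_int_list(list(r$tStarts)),
          sep = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Expand PSL records into per-block target intervals
#'
#' @param psl A PSL tibble.
#' @return A tibble of 0-based half-open target intervals with columns
#'   `record` (row index into `psl`), `qName`, `seqid`, `start`, `end`.
#' @export
psl_target_blocks <- function(psl) {
  if (nrow(psl) == 0) {
    return(tibble(record = integer(), qName = character(),
                  seqid = character(), start = integer(), end = integer()))
  }
  tibble(
    record = rep(seq_len(nrow(psl)), psl$blockCount),
    qName = rep(psl$qName, psl$blockCount),
    seqid = rep(psl$tName, psl$blockCount),
    start = unlist(psl$tStarts),
    end = unlist(psl$tStarts) + unlist(psl$blockSizes)
  )
}
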