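#' Write genomic intervals as BED6
#'
#' Intervals are 0-based half-open, written sorted by `(seqid, start)`.
#' Records with `start >= end` are refused and reported with a warning.
#'
#' @param intervals Tibble with columns `seqid`, `start`, `end`, `name`, and
#'   optionally `score` and `strand` (defaults 0 and ".").
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  iv <- as_tibble(intervals)
  if (nrow(iv) > 0) {
    if (!"score" %in% names(iv)) iv$score <- 0L
    if (!"strand" %in% names(iv)) iv$strand <- "."
    bad <- iv$start >= iv$end
    if (any(bad)) {
      warn(sprintf("dropping %d BED record(s) with start >= end: %s",
                   sum(bad), paste(utils::head(iv$name[bad], 5), collapse = ", ")))
      iv <- iv[!bad, , drop = FALSE]
    }
    iv <- arrange(iv, .data$seqid, .data$start, .data$end)
  }
  if (nrow(iv) == 0) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  readr::write_tsv(select(iv, "seqid", "start", "end", "name", "score", "strand"),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 file into a tibble of 0-based half-open intervals
#'
#' @param path Path to a BED file (3 to 6 columns).
#' @return Tibble with columns `seqid`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  empty <- tibble(seqid = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character())
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(lengths(fields))
  if (nf < 3) abort("BED parse error: fewer than 3 columns")
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  tibble(
    seqid = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    name = if (nf >= 4) m[, 4] else NA_character_,
    score = if (nf >= 5) as.double(m[, 5]) else NA_real_,
    strand = if (nf >= 6) m[, 6] else "."
  )
}
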