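#' Read a gene annotation table
#'
#' Reads per-model gene annotations and aggregates them to one row per
#' `(species, gene, seqid)` locus. Where a locus carries several
#' non-overlapping ("split") models, their lengths are summed into
#' `model_length`, mirroring how partial predictions at one locus are
#' treated throughout the pipeline.
#'
#' Two source formats are supported:
#' * `"tsv"`: a headered table with columns `species`, `gene`, `seqid`,
#'   `start`, `end`, `strand`, and optionally `model_id` and `model_length`
#'   (one row per model; coordinates 0-based half-open).
#' * `"gff3"`: only `gene`-type lines are used (mRNA/exon lines ignored);
#'   the gene symbol is taken from the `Name=` (else `ID=`) attribute and
#'   1-based inclusive coordinates are converted to 0-based half-open.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gff3"`; guessed from the file extension by
#'   default.
#' @param species Species label to attach when reading GFF3 (which carries
#'   none).
#' @return Tibble with columns `species`, `gene`, `seqid`, `start`, `end`,
#'   `strand`, `model_ids` (list-column), `model_length`.
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "gff3"),
                            species = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    raw <- read_gff3_genes(path, species)
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
    needed <- c("species", "gene", "seqid", "start", "end", "strand")
    missing <- setdiff(needed, names(raw))
    if (length(missing) > 0) {
      abort(paste0("annotation TSV is missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
    if (!"model_id" %in% names(raw)) raw$model_id <- NA_character_
    raw <- mutate(raw, start = as.integer(.data$start), end = as.integer(.data$end))
    if (!"model_length" %in% names(raw)) {
      raw$model_length <- raw$end - raw$start
    } else {
      raw$model_length <- as.integer(raw$model_length)
    }
  }
  incomplete <- is.na(raw$start) | is.na(raw$end) | is.na(raw$seqid)
  if (any(incomplete)) {
    warn(sprintf("skipping %d annotation row(s) with missing coordinates", sum(incomplete)))
    raw <- raw[!incomplete, , drop = FALSE]
  }
  if (nrow(raw) == 0) {
    return(tibble(species = character(), gene = character(), seqid = character(),
                  start = integer(), end = integer(), strand = character(),
                  model_ids = list(), model_length = integer()))
  }
  dup <- duplicated(raw[, c("species", "gene", "seqid", "start", "end", "model_id")])
  if (any(dup)) {
    abort(sprintf("duplicate annotation row(s) for %s",
                  paste(unique(raw$gene[dup]), collapse = ", ")))
  }
  raw |>
    group_by(.data$species, .data$gene, .data$seqid) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      strand = .data$strand[1],
      model_ids = list(.data$model_id[!is.na(.data$model_id)]),
      model_length = sum(.data$model_length),
      .groups = "drop"
    ) |>
    arrange(.data$species, .data$seqid, .data$start)
}

read_gff3_genes <- function(path, species) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[lengths(fields) == 9L]
  keep <- vapply(fields, function(f) f[3] == "gene", logical(1))
  fields <- fields[keep]
  if (length(fields) == 0) {
    return(tibble(species = character(), gene = character(), seqid = character(),
                  start = integer(), end = integer(), strand = character(),
                  model_id = character(), model_length = integer()))
  }
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
  }
  attrs <- vapply(fields, `[`, character(1), 9)
  gene <- attr_get(attrs, "Name")
  gene <- ifelse(is.na(gene), attr_get(attrs, "ID"), gene)
  start1 <- as.integer(vapply(fields, `[`, character(1), 4))
  end1 <- as.integer(vapply(fields, `[`, character(1), 5))
  tibble(
    species = species,
    gene = gene,
    seqid = vapply(fields, `[`, character(1), 1),
    start = start1 - 1L,   # GFF3 is 1-based inclusive
    end = end1,
    strand = vapply(fields, `[`, character(1), 7),
    model_id = attr_get(attrs, "ID"),
    model_length = end1 - start1 + 1L
  )
}
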