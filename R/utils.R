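#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join row_number n distinct across rename count pull
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 map_int map_dbl map_lgl map_chr pmap
#' @keywords internal
"_PACKAGE"

# split a comma-separated PSL list field ("50,30," -> c(50L, 30L))
split_int_list <- function(x) {
  lapply(strsplit(sub(",$", "", x), ","), function(v) as.integer(v[nzchar(v)]))
}

fmt_int_list <- function(x) {
  vapply(x, function(v) paste0(paste(v, collapse = ","), ","), character(1))
}

is_unplaced_seq <- function(seqid) {
  grepl("^chrUn", seqid) | grepl("_random$", seqid)
}
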