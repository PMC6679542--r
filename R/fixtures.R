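#' Load a packaged worked-example table
#'
#' The package ships the zebra finch ion-channel worked example as plain
#' tables: the 94-gene complement with per-gene evidence, expected status
#' and marker sets (`"table1"`); the 15 genes missing relative to mammals
#' with their phylogenetic loss categories (`"table2"`); the tri-state
#' presence/absence/unknown profiles behind those categories
#' (`"loss_profiles"`); the species tree they are placed on
#' (`"species_tree"`); and the differential-expression calls stated in the
#' accompanying results (`"results_expression"`).
#'
#' @param name One of `"table1"`, `"table2"`, `"loss_profiles"`,
#'   `"species_tree"`, `"results_expression"`.
#' @return A tibble, except `"species_tree"` which returns an
#'   [ape::phylo].
#' @examples
#' t2 <- load_paper_fixture("table2")
#' subset(t2, category == "Missing in finches")
#' @export
load_paper_fixture <- function(name = c("table1", "table2", "loss_profiles",
                                        "species_tree", "results_expression")) {
  name <- rlang::arg_match(name)
  file <- c(
    table1 = "table1_genes.tsv", table2 = "table2_missing.tsv",
    loss_profiles = "loss_profiles.tsv", species_tree = "species_tree.nwk",
    results_expression = "results_expression.tsv"
  )[[name]]
  path <- system.file("extdata", file, package = "orthochannel", mustWork = TRUE)
  if (name == "species_tree") return(read_species_tree(path))
  # empty strings are data here (e.g. an empty marker set), not missing
  readr::read_tsv(path, show_col_types = FALSE, na = "NA")
}
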