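#' Pipeline configuration
#'
#' One declarative object holding every tunable threshold, each at its
#' conventional default: hit significance above a BLAT score of 50,
#' truncation below 25% of the ortholog aligned, the completeness flag
#' below 90% of post-recovery length (with 75% as the severe bin), and two
#' flanking genes per side for synteny.
#'
#' @param mode `"fixture"` to run over the packaged worked-example tables,
#'   `"simulation"` to generate and analyse a synthetic dataset.
#' @param sim A [sim_config()] (simulation mode only).
#' @param blat_score_min Hit-significance cutoff (strict `>`).
#' @param truncation_fraction Truncation threshold (strict `<`).
#' @param completeness_flag Completeness flag threshold (strict `<`).
#' @param secondary_bin Severe-incompleteness bin threshold (strict `<`).
#' @param flanking_k Flanking genes per side.
#' @param out_dir Optional directory for TSV reports.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("fixture", "simulation"),
                            sim = sim_config(), blat_score_min = 50,
                            truncation_fraction = 0.25,
                            completeness_flag = 0.90, secondary_bin = 0.75,
                            flanking_k = 2, out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(truncation_fraction > 0, truncation_fraction <= 1,
            completeness_flag > 0, completeness_flag <= 1,
            secondary_bin > 0, secondary_bin <= 1,
            flanking_k >= 1, blat_score_min >= 0)
  structure(list(mode = mode, sim = sim, blat_score_min = blat_score_min,
                 truncation_fraction = truncation_fraction,
                 completeness_flag = completeness_flag,
                 secondary_bin = secondary_bin, flanking_k = flanking_k,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' In fixture mode, classifies the packaged 94-gene evidence table,
#' places every recorded loss profile on the packaged species tree,
#' reconciles the packaged expression calls, and reports the complement
#' counts. In simulation mode, generates a synthetic dataset under the
#' configured seed, runs [analyze_simulation()] end to end, places the
#' planted losses, and reports the same counts plus recovery accuracy.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `ion_report`; see [glance.ion_report()] and
#'   [tidy.ion_report()].
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- if (config$mode == "fixture") run_fixture_pipeline(config)
  else run_simulation_pipeline(config)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

run_fixture_pipeline <- function(config) {
  t1 <- load_paper_fixture("table1")
  t2 <- load_paper_fixture("table2")
  tree <- load_paper_fixture("species_tree")
  profiles <- load_paper_fixture("loss_profiles")
  expr <- load_paper_fixture("results_expression")

  status <- classify_genes(t1, config$truncation_fraction) |>
    left_join(select(t1, "gene", "family", "subfamily", "synteny",
                     "found_via", "n_caret_models", "chicken_present"),
              by = "gene")

  losses <- profiles |>
    group_by(.data$gene) |>
    dplyr::group_map(function(df, key) {
      pl <- place_loss(df, tree)
      tibble(
        gene = key$gene,
        category = loss_category(pl, tree, df,
                                 label_map = c(Aves = "all birds")),
        confidence = attr(pl, "confidence"),
        n_losses = attr(pl, "n_losses"),
        branches = paste(pl$branch_label[pl$maximal], collapse = ";"),
        ambiguity = paste(pl$branch_label, collapse = ";")
      )
    }) |>
    bind_rows() |>
    left_join(select(t2, "gene", expected_category = "category", "family",
                     "chicken_present"), by = "gene")

  mat <- reconcile_calls(mutate(expr, assay = "ish"))
  expr_summary <- summarize_expression(
    mat, families = distinct(select(expr, "gene", "family")))

  by_family <- count(status, .data$family)
  summary <- tibble(
    metric = c("genes_total", "genes_sodium", "genes_calcium", "genes_chloride",
               "chicken_total", "missing_total", "novel_model_genes",
               "novel_models", "truncated_genes",
               "loss_category_concordance"),
    value = c(nrow(status),
              by_family$n[by_family$family == "sodium"],
              by_family$n[by_family$family == "calcium"],
              by_family$n[by_family$family == "chloride"],
              sum(t1$chicken_present) + sum(t2$chicken_present),
              nrow(t2),
              sum(status$markers != "" &
                    vapply(status$marker_list, function(m) "caret" %in% m, NA)),
              sum(status$n_caret_models),
              sum(status$status == "TRUNCATED"),
              mean(losses$category == losses$expected_category))
  )
  structure(list(mode = "fixture", summary = summary, status = status,
                 losses = losses, expression = mat,
                 expression_summary = expr_summary, config = config),
            class = "ion_report")
}

run_simulation_pipeline <- function(config) {
  sim <- simulate_dataset(config$sim)
  analysis <- analyze_simulation(sim, k = config$flanking_k,
                                 min_score = config$blat_score_min,
                                 truncation_fraction = config$truncation_fraction)
  calls <- analysis$calls

  # completeness screen: annotated model length against the query ortholog
  glen <- stats::setNames(sim$genes$length, sim$genes$gene)
  ratios <- sim$annotations |>
    mutate(length_ratio = .data$model_length / glen[.data$gene])
  flagged <- sum(ratios$length_ratio < config$completeness_flag)

  # place every planted loss back on the tree from the emitted profile
  lost_genes <- sim$truth$losses$gene
  placements <- lapply(lost_genes, function(g) {
    pl <- place_loss(sim$profiles[sim$profiles$gene == g, ], sim$tree)
    truth_label <- sim$truth$losses$label[match(g, lost_genes)]
    tibble(gene = g, true_branch = truth_label,
           recovered = truth_label %in% pl$branch_label,
           n_candidates = nrow(pl))
  }) |> bind_rows()

  mat <- reconcile_calls(sim$expression)
  summary <- tibble(
    metric = c("genes_total", "species", "calls_present", "calls_missing",
               "calls_truncated", "calls_unresolved", "flagged_incomplete",
               "status_accuracy", "top_hit_accuracy", "loss_branch_recovery"),
    value = c(nrow(sim$genes), length(sim$tree$tip.label),
              sum(startsWith(calls$status, "PRESENT")),
              sum(calls$status == "MISSING"),
              sum(calls$status == "TRUNCATED"),
              sum(calls$status == "UNRESOLVED"),
              flagged,
              analysis$status_accuracy, analysis$top_hit_accuracy,
              if (nrow(placements) == 0) 1 else mean(placements$recovered))
  )
  structure(list(mode = "simulation", summary = summary, status = calls,
                 losses = placements, expression = mat, sim = sim,
                 analysis = analysis, config = config),
            class = "ion_report")
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- report$status
  st$marker_list <- NULL
  readr::write_tsv(st, file.path(dir, "gene_status.tsv"))
  readr::write_tsv(report$losses, file.path(dir, "loss_report.tsv"))
  readr::write_tsv(as_tibble(report$expression),
                   file.path(dir, "expression_matrix.tsv"))
  readr::write_tsv(report$summary, file.path(dir, "summary.tsv"))
  invisible(dir)
}

#' @export
print.ion_report <- function(x, ...) {
  cat(sprintf("<ion channel complement report> mode: %s\n", x$mode))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-26s %s\n", s$metric[i],
                format(s$value[i], digits = 4)))
  }
  invisible(x)
}

#' Glance at a pipeline report
#'
#' One-row summary in the broom style.
#'
#' @param x An `ion_report`.
#' @param ... Unused.
#' @return A one-row tibble, one column per summary metric.
#' @export
#' @exportS3Method generics::glance
glance.ion_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric", values_from = "value")
}

#' Tidy a pipeline report
#'
#' Per-gene status rows in the broom style.
#'
#' @param x An `ion_report`.
#' @param ... Unused.
#' @return A tibble with one row per gene (and species, in simulation
#'   mode).
#' @export
#' @exportS3Method generics::tidy
tidy.ion_report <- function(x, ...) {
  out <- as_tibble(x$status)
  out$marker_list <- NULL
  out
}

#' Bar chart of complement statuses
#'
#' @param object An `ion_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ion_report <- function(object, ...) {
  df <- count(as_tibble(object$status), .data$status)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = "#33648d") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}
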