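#' Reconcile microarray and in situ hybridization calls
#'
#' In situ hybridization is the arbiter: when both assays were assessed and
#' disagree, the in situ designation is the final outcome. Cells assessed by
#' only one assay inherit that assay's call, with provenance recording the
#' evidence source.
#'
#' @param microarray,ish Character vectors of calls, each `"higher"`,
#'   `"lower"`, `"nondifferential"`, or `"not-assessed"` (NA is treated as
#'   not-assessed). Recycled to a common length.
#' @return Tibble with columns `call` and `provenance` (`"agreement"`,
#'   `"ish"`, `"microarray-only"`, `"ish-only"`, or `"not-assessed"`).
#' @examples
#' reconcile_call("higher", "lower")        # lower, ish
#' reconcile_call("higher", "not-assessed") # higher, microarray-only
#' @export
reconcile_call <- function(microarray, ish) {
  n <- max(length(microarray), length(ish))
  ma <- rep_len(ifelse(is.na(microarray), "not-assessed", microarray), n)
  is_ <- rep_len(ifelse(is.na(ish), "not-assessed", ish), n)
  valid <- c("higher", "lower", "nondifferential", "not-assessed")
  bad <- setdiff(unique(c(ma, is_)), valid)
  if (length(bad) > 0) abort(paste0("invalid call value(s): ", paste(bad, collapse = ", ")))
  call <- character(n); prov <- character(n)
  for (i in seq_len(n)) {
    if (is_[i] != "not-assessed" && ma[i] != "not-assessed") {
      call[i] <- is_[i]
      prov[i] <- if (is_[i] == ma[i]) "agreement" else "ish"
    } else if (is_[i] != "not-assessed") {
      call[i] <- is_[i]; prov[i] <- "ish-only"
    } else if (ma[i] != "not-assessed") {
      call[i] <- ma[i]; prov[i] <- "microarray-only"
    } else {
      call[i] <- "not-assessed"; prov[i] <- "not-assessed"
    }
  }
  tibble(call = call, provenance = prov)
}

#' Build the final per-gene, per-nucleus call matrix
#'
#' Takes long-format two-assay calls and reconciles them cell by cell.
#'
#' @param calls Tibble with columns `gene`, `nucleus`, `assay`
#'   (`"microarray"` / `"ish"`), `call`, and optionally `sparse` (logical
#'   flag for expression confined to a sparse cell population; meaningful
#'   for in situ data only).
#' @return Tibble of class `expression_matrix` with columns `gene`,
#'   `nucleus`, `call`, `provenance`, `sparse`.
#' @export
reconcile_calls <- function(calls) {
  calls <- as_tibble(calls)
  if (!"sparse" %in% names(calls)) calls$sparse <- FALSE
  dup <- duplicated(calls[, c("gene", "nucleus", "assay")])
  if (any(dup)) abort("multiple calls for the same (gene, nucleus, assay)")
  wide <- calls |>
    select("gene", "nucleus", "assay", "call") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "call")
  if (!"microarray" %in% names(wide)) wide$microarray <- NA_character_
  if (!"ish" %in% names(wide)) wide$ish <- NA_character_
  rec <- reconcile_call(wide$microarray, wide$ish)
  sparse <- calls |>
    filter(.data$assay == "ish") |>
    group_by(.data$gene, .data$nucleus) |>
    summarise(sparse = any(.data$sparse), .groups = "drop")
  out <- wide |>
    mutate(call = rec$call, provenance = rec$provenance) |>
    select("gene", "nucleus", "call", "provenance") |>
    left_join(sparse, by = c("gene", "nucleus")) |>
    mutate(sparse = !is.na(.data$sparse) & .data$sparse)
  class(out) <- c("expression_matrix", class(out))
  out
}

#' Summarise a final call matrix
#'
#' Counts higher / lower / nondifferential calls per song nucleus and,
#' when a gene-to-family map is given, per gene family. Not-assessed cells
#' are excluded from all denominators.
#'
#' @param matrix An `expression_matrix` ([reconcile_calls()]) or any tibble
#'   with `gene`, `nucleus`, `call`.
#' @param families Optional tibble with `gene`, `family`.
#' @return A list with `by_nucleus` and (if `families` given) `by_family`
#'   count tibbles, each with columns `higher`, `lower`, `nondifferential`,
#'   `assessed`.
#' @export
summarize_expression <- function(matrix, families = NULL) {
  assessed <- filter(as_tibble(matrix), .data$call != "not-assessed")
  tally <- function(df, key) {
    df |>
      group_by(dplyr::across(dplyr::all_of(key))) |>
      summarise(
        higher = sum(.data$call == "higher"),
        lower = sum(.data$call == "lower"),
        nondifferential = sum(.data$call == "nondifferential"),
        assessed = n(),
        .groups = "drop"
      )
  }
  out <- list(by_nucleus = tally(assessed, "nucleus"))
  if (!is.null(families)) {
    out$by_family <- assessed |>
      left_join(families, by = "gene") |>
      tally("family")
  }
  out
}

#' Heat-table plot of a final expression call matrix
#'
#' @param object An `expression_matrix`.
#' @param ... Unused.
#' @return A ggplot object: genes by nuclei, filled by call (higher green,
#'   lower red, nondifferential tan, not-assessed grey); sparse-population
#'   cells are dotted.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.expression_matrix <- function(object, ...) {
  df <- as_tibble(object)
  df$call <- factor(df$call, c("higher", "lower", "nondifferential", "not-assessed"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$nucleus, y = .data$gene,
                                        fill = .data$call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      higher = "#2e7d32", lower = "#c62828",
      nondifferential = "#d7c9a7", `not-assessed` = "grey80"
    ), drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "call") +
    ggplot2::theme_minimal()
  if (any(df$sparse)) {
    p <- p + ggplot2::geom_point(data = df[df$sparse, ], shape = 20, size = 1)
  }
  p
}
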