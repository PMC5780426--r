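#' Load a multi-source miRNA-target prediction table
#'
#' Reads a TSV with columns `source`, `mirna`, `gene`, `score` (score in
#' [0, 1]), as exported from an integrative target-prediction resource.
#' Records duplicated on (source, mirna, gene) are collapsed to the maximum
#' score with a message; gene symbols are uppercased and miRNA ids keep their
#' input spelling (matching later is prefix- and case-insensitive, see
#' [canonical_mirna()]).
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `source`, `mirna`, `gene`, `score`.
#' @export
load_targets <- function(path) {
  if (!file.exists(path)) abort(sprintf("Target table not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    source = readr::col_character(),
    mirna = readr::col_character(),
    gene = readr::col_character(),
    score = readr::col_double()
  ))
  missing_cols <- setdiff(c("source", "mirna", "gene", "score"), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Target table missing column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    warn("Target table is empty.")
    return(df)
  }
  if (anyNA(df$score) || any(df$score < 0 | df$score > 1)) {
    abort("Target scores must lie in [0, 1].")
  }
  df$gene <- canonical_gene(df$gene)
  n0 <- nrow(df)
  df <- df |>
    dplyr::group_by(.data$source, .data$mirna, .data$gene) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
  if (nrow(df) < n0) {
    inform(sprintf(
      "Collapsed %d duplicated (source, mirna, gene) record(s), keeping the maximum score.",
      n0 - nrow(df)
    ))
  }
  df
}

#' Consensus filter over prediction sources
#'
#' Restricts predictions to the selected cargo miRNAs and keeps only
#' miRNA-gene pairs supported by at least `min_support` distinct sources —
#' the multi-database agreement filter that trades recall for precision. Each
#' retained edge carries its support count and an integrated confidence score
#' (mean of the per-source scores by default, or their maximum).
#'
#' @param records Prediction tibble from [load_targets()].
#' @param mirnas Character vector of selected miRNA ids (matching is
#'   `hsa-`-prefix- and case-insensitive).
#' @param min_support Minimum number of distinct supporting sources
#'   (default 5).
#' @param score_mode `"mean"` (default) or `"max"`.
#' @return A `consensus_targets` object with elements `edges` (tibble
#'   `mirna`, `gene`, `support`, `integrated_score`), `genes` (sorted unique
#'   gene universe of retained edges) and `params`.
#' @export
consensus_filter <- function(records, mirnas, min_support = 5,
                             score_mode = c("mean", "max")) {
  score_mode <- match.arg(score_mode)
  check_number(min_support, "min_support", lower = 1)
  records <- as_tibble(records)
  n_sources <- dplyr::n_distinct(records$source)
  if (nrow(records) > 0 && min_support > n_sources) {
    warn(sprintf(
      "min_support (%d) exceeds the %d source(s) present; result is empty.",
      min_support, n_sources
    ))
  }
  keys <- canonical_mirna(mirnas)
  edges <- records |>
    dplyr::filter(canonical_mirna(.data$mirna) %in% keys) |>
    dplyr::mutate(.mkey = canonical_mirna(.data$mirna)) |>
    dplyr::group_by(.data$.mkey, .data$gene) |>
    dplyr::summarise(
      mirna = dplyr::first(sort(.data$mirna)),
      support = dplyr::n_distinct(.data$source),
      integrated_score = if (score_mode == "mean") mean(.data$score) else max(.data$score),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::arrange(.data$mirna, .data$gene) |>
    dplyr::select("mirna", "gene", "support", "integrated_score")
  structure(
    list(
      edges = edges,
      genes = sort(unique(edges$gene)),
      params = list(
        min_support = min_support, score_mode = score_mode,
        n_sources = n_sources, band_rule = NULL
      )
    ),
    class = "consensus_targets"
  )
}

#' Assign empirical confidence bands
#'
#' Splits retained consensus edges into bottom / middle / top thirds of the
#' integrated-score distribution (empirical 1/3 and 2/3 quantiles). Edges
#' tied exactly at a boundary stay in the upper band, so "above the bottom
#' third" is a strict statement about the score, not the rank.
#'
#' @param cts A `consensus_targets` object.
#' @return The same object with a `band` column added to `edges` and the
#'   realized quantile boundaries recorded in `params$band_rule`.
#' @export
confidence_bands <- function(cts) {
  stopifnot(inherits(cts, "consensus_targets"))
  edges <- cts$edges
  if (nrow(edges) == 0) abort("No retained edges to band.")
  s <- edges$integrated_score
  if (length(unique(s)) == 1) {
    warn("All integrated scores identical; every edge assigned to band 'top'.")
    edges$band <- "top"
    cts$edges <- edges
    cts$params$band_rule <- list(q13 = unique(s), q23 = unique(s))
    return(cts)
  }
  q <- quantile(s, probs = c(1 / 3, 2 / 3), names = FALSE, type = 7)
  edges$band <- dplyr::case_when(
    s < q[1] ~ "bottom",
    s < q[2] ~ "middle",
    TRUE ~ "top"
  )
  cts$edges <- edges
  cts$params$band_rule <- list(q13 = q[1], q23 = q[2])
  cts
}

#' Drop the bottom confidence band
#'
#' The "top two-thirds in confidence" view: removes edges in the bottom band
#' and recomputes the gene universe from the survivors.
#'
#' @param cts A banded `consensus_targets` (see [confidence_bands()]).
#' @return A `consensus_targets` object restricted to middle + top bands.
#' @export
keep_top_two_thirds <- function(cts) {
  stopifnot(inherits(cts, "consensus_targets"))
  if (!"band" %in% names(cts$edges)) cts <- confidence_bands(cts)
  cts$edges <- dplyr::filter(cts$edges, .data$band != "bottom")
  cts$genes <- sort(unique(cts$edges$gene))
  cts$params$kept_bands <- c("middle", "top")
  cts
}

#' @export
print.consensus_targets <- function(x, ...) {
  cat(sprintf(
    "<consensus_targets> %d edges, %d genes, %d miRNAs (min_support = %d of %d sources)\n",
    nrow(x$edges), length(x$genes), dplyr::n_distinct(x$edges$mirna),
    x$params$min_support, x$params$n_sources
  ))
  if ("band" %in% names(x$edges)) {
    print(table(x$edges$band))
  }
  invisible(x)
}

#' Tidy a consensus target set
#'
#' @param x A `consensus_targets`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.consensus_targets <- function(x, ...) x$edges

#' @describeIn tidy.consensus_targets One-row summary with edge/gene/miRNA
#'   counts and the support parameters used.
#' @export
glance.consensus_targets <- function(x, ...) {
  tibble(
    n_edges = nrow(x$edges),
    n_genes = length(x$genes),
    n_mirnas = dplyr::n_distinct(x$edges$mirna),
    min_support = x$params$min_support,
    n_sources = x$params$n_sources,
    score_mode = x$params$score_mode,
    mean_support = if (nrow(x$edges) > 0) mean(x$edges$support) else NA_real_
  )
}

#' Write consensus outputs
#'
#' @param cts A `consensus_targets`.
#' @param edges_path TSV for the edge table; `NULL` to skip.
#' @param genes_path Plain-text gene list, one symbol per line; `NULL` to skip.
#' @return `cts`, invisibly.
#' @export
write_consensus <- function(cts, edges_path = NULL, genes_path = NULL) {
  if (!is.null(edges_path)) readr::write_tsv(cts$edges, edges_path)
  if (!is.null(genes_path)) writeLines(cts$genes, genes_path)
  invisible(cts)
}
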