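#' Rank miRNAs by normalized abundance
#'
#' Orders endogenous miRNAs from highest to lowest normalized value and
#' attaches each miRNA's share of the total signal and the running cumulative
#' share. Ties are broken lexicographically by miRNA id so the ranking is
#' deterministic under row permutation.
#'
#' @param profile A [normalize_counts()] result (ranked on the mean of the
#'   replicate-merged group profiles) or a data frame with columns `mirna`
#'   (or `probe_id`) and `value`.
#' @return Tibble with columns `mirna`, `value`, `share`, `cumulative`,
#'   sorted by decreasing value.
#' @export
rank_mirnas <- function(profile) {
  df <- cargo_values(profile)
  if (nrow(df) == 0 || all(df$value == 0)) {
    abort("Cannot rank an all-zero profile.")
  }
  if (any(df$value < 0)) abort("Negative abundance values.")
  df <- df[order(-df$value, df$mirna), ]
  total <- sum(df$value)
  df$share <- df$value / total
  df$cumulative <- cumsum(df$share)
  as_tibble(df)
}

cargo_values <- function(profile) {
  if (inherits(profile, "normalized_profile")) {
    merged <- profile$merged
    endo <- merged$probe_class == "endogenous"
    gcols <- setdiff(names(merged), c("probe_id", "probe_class", "expected_conc"))
    return(tibble(
      mirna = merged$probe_id[endo],
      value = rowMeans(as.matrix(merged[endo, gcols, drop = FALSE]))
    ))
  }
  df <- as_tibble(profile)
  if (!"mirna" %in% names(df) && "probe_id" %in% names(df)) {
    df <- dplyr::rename(df, mirna = "probe_id")
  }
  if (!all(c("mirna", "value") %in% names(df))) {
    abort("`profile` needs columns `mirna` (or `probe_id`) and `value`.")
  }
  if (anyDuplicated(df$mirna)) abort("Duplicated miRNA ids in profile.")
  df[c("mirna", "value")]
}

#' Select dominant cargo by per-miRNA share floor
#'
#' Keeps every miRNA whose individual share of total signal exceeds `floor`.
#' The default floor of 0.007 reflects the convention that cargo species below
#' ~0.7% of the pool are unlikely to carry biological weight relative to the
#' abundant set.
#'
#' @param ranked A ranked table from [rank_mirnas()].
#' @param floor Share threshold in (0, 1); strictly-greater comparison.
#' @return A `cargo_selection` object; see [tidy.cargo_selection()].
#' @export
select_by_share_floor <- function(ranked, floor = 0.007) {
  check_number(floor, "floor", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  ranked <- validate_ranked(ranked)
  selected <- ranked$mirna[ranked$share > floor]
  if (length(selected) == 0) {
    abort(sprintf(
      "No miRNA exceeds share floor %.4g (max share %.4g); lower the floor.",
      floor, max(ranked$share)
    ))
  }
  new_cargo_selection(ranked, selected,
                      rule = list(rule = "share_floor", floor = floor))
}

#' Select dominant cargo by cumulative share
#'
#' Keeps the minimal top-ranked prefix whose cumulative share reaches `f`; the
#' default 0.79 targets the regime in which the dominant set carries about
#' four-fifths of the total cargo signal.
#'
#' @param ranked A ranked table from [rank_mirnas()].
#' @param f Target cumulative fraction in (0, 1].
#' @return A `cargo_selection` object.
#' @export
select_by_cumulative_fraction <- function(ranked, f = 0.79) {
  check_number(f, "f", lower = 0, upper = 1, open_lower = TRUE)
  ranked <- validate_ranked(ranked)
  k <- match(TRUE, ranked$cumulative >= f - 1e-12)
  if (is.na(k)) k <- nrow(ranked) # guard against rounding at f = 1
  new_cargo_selection(ranked, ranked$mirna[seq_len(k)],
                      rule = list(rule = "cumulative_fraction", f = f))
}

#' Dominance ratio of a cargo selection
#'
#' Mean abundance of the selected miRNAs divided by the mean abundance of the
#' excluded tail — how many times more abundant the average selected species
#' is than the average excluded one.
#'
#' @param ranked A ranked table from [rank_mirnas()].
#' @param selected Character vector of selected miRNA ids.
#' @return A positive number; `Inf` (with a warning) when the excluded tail
#'   has mean zero.
#' @export
dominance_ratio <- function(ranked, selected) {
  ranked <- validate_ranked(ranked)
  sel <- ranked$mirna %in% selected
  if (!any(sel) || all(sel)) {
    abort("dominance_ratio() needs both a selected set and a non-empty tail.")
  }
  m_out <- mean(ranked$value[!sel])
  if (m_out == 0) {
    warn("Excluded tail has mean abundance zero; dominance ratio is infinite.")
    return(Inf)
  }
  mean(ranked$value[sel]) / m_out
}

new_cargo_selection <- function(ranked, selected, rule) {
  ranked$selected <- ranked$mirna %in% selected
  coverage <- sum(ranked$share[ranked$selected])
  dr <- if (any(ranked$selected) && !all(ranked$selected)) {
    m_out <- mean(ranked$value[!ranked$selected])
    if (m_out == 0) Inf else mean(ranked$value[ranked$selected]) / m_out
  } else {
    NA_real_
  }
  structure(
    list(
      ranked = ranked,
      selected = ranked$mirna[ranked$selected],
      rule = rule,
      coverage = coverage,
      dominance_ratio = dr
    ),
    class = "cargo_selection"
  )
}

validate_ranked <- function(ranked) {
  ranked <- as_tibble(ranked)
  need <- c("mirna", "value", "share", "cumulative")
  if (!all(need %in% names(ranked))) {
    abort("`ranked` must come from rank_mirnas() (columns mirna, value, share, cumulative).")
  }
  if (is.unsorted(rev(ranked$value))) abort("`ranked` is not sorted by decreasing value.")
  ranked
}

#' @export
print.cargo_selection <- function(x, ...) {
  cat(sprintf(
    "<cargo_selection> %d of %d miRNAs selected (%s), coverage %.1f%%, dominance ratio %.1f\n",
    length(x$selected), nrow(x$ranked),
    paste(names(x$rule), unlist(x$rule), sep = "=", collapse = ", "),
    100 * x$coverage, x$dominance_ratio
  ))
  invisible(x)
}

#' Tidy a cargo selection
#'
#' @param x A `cargo_selection`.
#' @param ... Unused.
#' @return The ranked tibble (`mirna`, `value`, `share`, `cumulative`,
#'   `selected`).
#' @export
tidy.cargo_selection <- function(x, ...) x$ranked

#' @describeIn tidy.cargo_selection One-row selection summary: rule, counts,
#'   coverage and dominance ratio.
#' @export
glance.cargo_selection <- function(x, ...) {
  tibble(
    rule = x$rule$rule,
    rule_parameter = unlist(x$rule[setdiff(names(x$rule), "rule")])[[1]],
    n_total = nrow(x$ranked),
    n_selected = length(x$selected),
    n_excluded = nrow(x$ranked) - length(x$selected),
    coverage = x$coverage,
    dominance_ratio = x$dominance_ratio,
    min_selected_share = min(x$ranked$share[x$ranked$selected]),
    max_excluded_share = if (any(!x$ranked$selected)) max(x$ranked$share[!x$ranked$selected]) else NA_real_
  )
}

#' Cumulative-share curve of a cargo selection
#'
#' Rank versus cumulative share, with the selected prefix highlighted — the
#' visual argument for where the dominant cargo set ends.
#'
#' @param object A `cargo_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cargo_selection <- function(object, ...) {
  df <- dplyr::mutate(object$ranked, rank = dplyr::row_number())
  ggplot(df, aes(x = .data$rank, y = .data$cumulative)) +
    geom_step() +
    geom_point(aes(colour = .data$selected), size = 1.5) +
    scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60")) +
    labs(
      x = "Abundance rank", y = "Cumulative share",
      colour = "Selected",
      subtitle = sprintf(
        "%d selected, coverage %.1f%%",
        length(object$selected), 100 * object$coverage
      )
    ) +
    theme_minimal()
}

#' Write selection outputs
#'
#' Writes the ranked table as TSV and the selection summary (rule, parameters,
#' coverage, dominance ratio, selected ids) as JSON.
#'
#' @param sel A `cargo_selection`.
#' @param table_path,report_path Output paths (either may be `NULL` to skip).
#' @return `sel`, invisibly.
#' @export
write_selection <- function(sel, table_path = NULL, report_path = NULL) {
  if (!is.null(table_path)) readr::write_tsv(sel$ranked, table_path)
  if (!is.null(report_path)) {
    jsonlite::write_json(
      list(
        rule = sel$rule,
        n_selected = length(sel$selected),
        coverage = sel$coverage,
        dominance_ratio = sel$dominance_ratio,
        selected = sel$selected
      ),
      report_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(sel)
}
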