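#' Read gene sets from a GMT file
#'
#' Standard GMT: one term per line, tab-separated as
#' `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`. Gene symbols are
#' uppercased; duplicate genes within a term are collapsed. Terms are kept as
#' flat sets — no ontology-graph propagation is performed.
#'
#' @param path Path to a GMT file.
#' @return An `annotation_set`: list with `terms` (tibble `term_id`,
#'   `term_name`, `genes` list-column, `size`) and `universe` (sorted union
#'   of all annotated genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("GMT file contains no terms.")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line(s) %s have fewer than 3 fields.", paste(bad, collapse = ", ")))
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "Duplicated term id(s): %s.",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  genes <- lapply(parts, function(p) sort(unique(canonical_gene(p[-(1:2)]))))
  annotation_set(tibble(
    term_id = ids,
    term_name = vapply(parts, `[[`, character(1), 2),
    genes = genes
  ))
}

#' Construct an annotation set from a term table
#'
#' @param terms Tibble with columns `term_id`, `term_name` and a `genes`
#'   list-column of symbol vectors.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(terms) {
  terms <- as_tibble(terms)
  stopifnot(all(c("term_id", "term_name", "genes") %in% names(terms)))
  terms$genes <- lapply(terms$genes, function(g) sort(unique(canonical_gene(g))))
  terms$size <- lengths(terms$genes)
  structure(
    list(terms = terms, universe = sort(unique(unlist(terms$genes)))),
    class = "annotation_set"
  )
}

#' Write an annotation set as GMT
#'
#' @param anno An `annotation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(anno, path) {
  stopifnot(inherits(anno, "annotation_set"))
  lines <- purrr::pmap_chr(
    anno$terms[c("term_id", "term_name", "genes")],
    function(term_id, term_name, genes) {
      paste(c(term_id, term_name, genes), collapse = "\t")
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %d terms over %d genes (term sizes %d-%d)\n",
    nrow(x$terms), length(x$universe), min(x$terms$size), max(x$terms$size)
  ))
  invisible(x)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) for X ~ Hypergeometric(N, K, n): the
#' chance that a random draw of `n` genes from a universe of `N`, of which
#' `K` belong to the term, contains at least the observed `k` term genes.
#' Identical to the one-sided Fisher exact test on the 2x2 table.
#'
#' @param k Observed overlap between query and term.
#' @param n Query size within the universe.
#' @param K Term size within the universe.
#' @param N Universe size.
#' @return Vectorized p-values in (0, 1].
#' @examples
#' hypergeom_pvalue(4, 5, 5, 20) # 76 / choose(20, 5)
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  args <- vctrs_recycle(k = k, n = n, K = K, N = N)
  with(args, {
    if (any(k < 0 | n < 0 | K < 0 | N < 0)) abort("Counts must be non-negative.")
    if (any(n > N | K > N)) abort("Margins exceed universe size.")
    if (any(k > pmin(n, K))) abort("Overlap k exceeds min(n, K).")
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  })
}

# base recycling helper (keeps the dependency surface small)
vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, rep_len, length.out = len)
}

#' Over-representation analysis of a gene set
#'
#' Tests each annotation term for over-representation of the query genes with
#' the hypergeometric model. The background defaults to the annotation
#' universe; a custom background (e.g. all genes targeted by any profiled
#' miRNA) is intersected with the universe first, and all counts are computed
#' on that common background. Fold enrichment is `(k/n) / (K/N)`; q-values
#' are Benjamini-Hochberg across the tested terms. Terms with no background
#' genes are skipped.
#'
#' @param query Character vector of gene symbols.
#' @param annotations An `annotation_set` (see [read_gmt()]).
#' @param background Optional character vector restricting the reference
#'   universe.
#' @return An `enrichment_result`: list with `table` (per-term tibble
#'   `term_id`, `term_name`, `K`, `k`, `n`, `N`, `fold`, `p`, `q`) and
#'   `params`.
#' @examples
#' anno <- annotation_set(tibble::tibble(
#'   term_id = "T1", term_name = "demo",
#'   genes = list(paste0("G", 1:5))
#' ))
#' @export
run_ora <- function(query, annotations, background = NULL) {
  stopifnot(inherits(annotations, "annotation_set"))
  query <- unique(canonical_gene(query))
  bg <- if (is.null(background)) {
    annotations$universe
  } else {
    intersect(sort(unique(canonical_gene(background))), annotations$universe)
  }
  N <- length(bg)
  if (N == 0) abort("Effective background is empty.")
  eff_query <- intersect(query, bg)
  if (length(eff_query) == 0) {
    unmatched <- head(setdiff(query, bg), 10)
    abort(sprintf(
      "No query gene is present in the background; unmatched examples: %s.",
      paste(unmatched, collapse = ", ")
    ))
  }
  n <- length(eff_query)
  tab <- annotations$terms |>
    dplyr::mutate(
      K = vapply(.data$genes, function(g) length(intersect(g, bg)), integer(1)),
      k = vapply(.data$genes, function(g) length(intersect(g, eff_query)), integer(1))
    ) |>
    dplyr::filter(.data$K > 0) |>
    dplyr::mutate(
      n = n, N = N,
      fold = (.data$k / n) / (.data$K / N),
      p = hypergeom_pvalue(.data$k, n, .data$K, N)
    ) |>
    dplyr::select("term_id", "term_name", "K", "k", "n", "N", "fold", "p")
  tab$q <- p.adjust(tab$p, method = "BH")
  structure(
    list(
      table = as_tibble(tab),
      params = list(
        n_query = length(query), n_query_effective = n,
        background = if (is.null(background)) "universe" else "custom",
        N = N
      )
    ),
    class = "enrichment_result"
  )
}

#' Fold-above-mean-plus-SD significance filter
#'
#' Flags terms as significant when they clear two independent bars: (1) a raw
#' hypergeometric p-value below `p_max` (default 1e-6), and (2) a fold
#' enrichment strictly greater than the mean plus `sd_mult` standard
#' deviations of the fold distribution over terms with at least one
#' overlapping gene. The realized fold threshold is data-dependent and
#' reported in the result so it can be quoted alongside the term lists.
#'
#' @param res An `enrichment_result` from [run_ora()].
#' @param p_max Raw p-value cutoff (default 1e-6).
#' @param sd_mult Multiplier on the fold SD (default 1).
#' @return The result with columns `passes_fold`, `passes_p`, `significant`
#'   added and a `summary` element (`fold_mean`, `fold_sd`, `fold_threshold`,
#'   `p_max`, `sd_mult`, `n_significant`).
#' @export
bespoke_filter <- function(res, p_max = 1e-6, sd_mult = 1.0) {
  stopifnot(inherits(res, "enrichment_result"))
  check_number(p_max, "p_max", lower = 0, upper = 1, open_lower = TRUE)
  check_number(sd_mult, "sd_mult", lower = 0)
  tab <- res$table
  eligible <- tab$k >= 1
  if (sum(eligible) < 2) {
    abort("Need at least 2 terms with non-zero overlap to set a fold threshold.")
  }
  fold_mean <- mean(tab$fold[eligible])
  fold_sd <- sd(tab$fold[eligible])
  threshold <- fold_mean + sd_mult * fold_sd
  tab$passes_fold <- eligible & tab$fold > threshold
  tab$passes_p <- tab$p < p_max
  tab$significant <- tab$passes_fold & tab$passes_p
  res$table <- tab
  res$summary <- list(
    fold_mean = fold_mean, fold_sd = fold_sd, fold_threshold = threshold,
    p_max = p_max, sd_mult = sd_mult, n_significant = sum(tab$significant)
  )
  res
}

#' Significant terms of a filtered enrichment result
#'
#' @param res A filtered `enrichment_result` (see [bespoke_filter()]).
#' @return Tibble of significant terms, ordered by p-value.
#' @export
significant_terms <- function(res) {
  stopifnot(inherits(res, "enrichment_result"))
  if (!"significant" %in% names(res$table)) {
    abort("Apply bespoke_filter() before extracting significant terms.")
  }
  res$table |>
    dplyr::filter(.data$significant) |>
    dplyr::arrange(.data$p, .data$term_id)
}

#' Terms trending towards enrichment
#'
#' Terms that fail the significance filter but whose raw p-value lies in
#' `[p_lo, p_hi)` — worth reporting as suggestive even though they miss the
#' stringent cutoff.
#'
#' @param res A filtered `enrichment_result`.
#' @param p_lo,p_hi Bounds of the trend window (defaults 1e-6 and 0.1).
#' @return Tibble of trend terms with a `label` column set to `"trend"`.
#' @export
trend_report <- function(res, p_lo = 1e-6, p_hi = 0.1) {
  stopifnot(inherits(res, "enrichment_result"))
  tab <- res$table
  sig <- if ("significant" %in% names(tab)) tab$significant else FALSE
  tab |>
    dplyr::filter(!sig, .data$p >= p_lo, .data$p < p_hi) |>
    dplyr::arrange(.data$p, .data$term_id) |>
    dplyr::mutate(label = "trend")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %d terms tested, query n = %d, background N = %d\n",
    nrow(x$table), x$params$n_query_effective, x$params$N
  ))
  if (!is.null(x$summary)) {
    cat(sprintf(
      "  fold threshold %.2f (mean %.2f + %.1f sd %.2f); %d significant at p < %g\n",
      x$summary$fold_threshold, x$summary$fold_mean, x$summary$sd_mult,
      x$summary$fold_sd, x$summary$n_significant, x$summary$p_max
    ))
  }
  invisible(x)
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return The per-term tibble.
#' @export
tidy.enrichment_result <- function(x, ...) x$table

#' @describeIn tidy.enrichment_result One-row summary including the realized
#'   fold threshold when the filter has been applied.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_terms = nrow(x$table),
    n_query = x$params$n_query_effective,
    N = x$params$N,
    min_p = min(x$table$p),
    fold_mean = x$summary$fold_mean %||% NA_real_,
    fold_sd = x$summary$fold_sd %||% NA_real_,
    fold_threshold = x$summary$fold_threshold %||% NA_real_,
    n_significant = x$summary$n_significant %||% NA_integer_
  )
}

#' Volcano-style enrichment plot
#'
#' Fold enrichment against -log10 p for every tested term, with the realized
#' fold threshold and p cutoff drawn when the significance filter has been
#' applied.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  tab <- dplyr::mutate(
    object$table,
    neglogp = -log10(pmax(.data$p, 1e-300)),
    status = if ("significant" %in% names(object$table)) {
      dplyr::if_else(.data$significant, "significant", "not significant")
    } else {
      "tested"
    }
  )
  p <- ggplot(tab, aes(x = .data$fold, y = .data$neglogp, colour = .data$status)) +
    geom_point() +
    labs(x = "Fold enrichment", y = expression(-log[10] ~ p), colour = NULL) +
    theme_minimal()
  if (!is.null(object$summary)) {
    p <- p +
      geom_vline(xintercept = object$summary$fold_threshold, linetype = 2) +
      geom_hline(yintercept = -log10(object$summary$p_max), linetype = 2)
  }
  p
}

#' Write enrichment outputs
#'
#' @param res An `enrichment_result`.
#' @param table_path TSV of the per-term table; `NULL` to skip.
#' @param summary_path JSON of the filter summary; `NULL` to skip.
#' @return `res`, invisibly.
#' @export
write_enrichment <- function(res, table_path = NULL, summary_path = NULL) {
  if (!is.null(table_path)) readr::write_tsv(res$table, table_path)
  if (!is.null(summary_path) && !is.null(res$summary)) {
    jsonlite::write_json(res$summary, summary_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
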