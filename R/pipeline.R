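#' Assemble a validated run configuration
#'
#' Collects the file paths and stage parameters of a full pipeline run, with
#' the pipeline's documented defaults filled in. Every parameter recorded
#' here is echoed into the run summary, so no default is silently applied.
#'
#' @param counts,targets,gmt Input file paths (counts CSV, target TSV, GMT).
#' @param outdir Output directory for all artifacts.
#' @param replicate_groups Optional named vector, sample -> group.
#' @param k_sd,background_mode,top_n,pseudocount,mean_type Normalization
#'   parameters (see [normalize_counts()]).
#' @param selection_rule `"share_floor"` or `"cumulative_fraction"`.
#' @param share_floor,cumulative_f The rule parameters.
#' @param min_support,score_mode Consensus parameters (see
#'   [consensus_filter()]).
#' @param keep_top_two_thirds Drop the bottom confidence band before
#'   enrichment (default `TRUE`).
#' @param p_max,sd_mult Enrichment filter parameters (see [bespoke_filter()]).
#' @param enrichment_background `"universe"` (annotation universe) or
#'   `"targets"` (all genes predicted for any covered miRNA).
#' @param rank_scope Term ids for candidate ranking; `NULL` ranks over all
#'   significant terms.
#' @param seed Seed recorded in the summary (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `run_config` list.
#' @export
run_config <- function(counts, targets, gmt, outdir,
                       replicate_groups = NULL,
                       k_sd = 2, background_mode = "floor", top_n = 100,
                       pseudocount = 0.5, mean_type = "arithmetic",
                       selection_rule = c("share_floor", "cumulative_fraction"),
                       share_floor = 0.007, cumulative_f = 0.79,
                       min_support = 5, score_mode = "mean",
                       keep_top_two_thirds = TRUE,
                       p_max = 1e-6, sd_mult = 1.0,
                       enrichment_background = c("universe", "targets"),
                       rank_scope = NULL,
                       seed = 1) {
  selection_rule <- match.arg(selection_rule)
  enrichment_background <- match.arg(enrichment_background)
  cfg <- as.list(environment())
  for (f in c("counts", "targets", "gmt")) {
    if (!file.exists(cfg[[f]])) {
      abort(sprintf("Configured %s file does not exist: %s", f, cfg[[f]]))
    }
  }
  check_number(cfg$share_floor, "share_floor", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(cfg$cumulative_f, "cumulative_f", lower = 0, upper = 1, open_lower = TRUE)
  check_number(cfg$k_sd, "k_sd", lower = 0)
  check_number(cfg$min_support, "min_support", lower = 1)
  check_number(cfg$p_max, "p_max", lower = 0, upper = 1, open_lower = TRUE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' The JSON object mirrors the arguments of [run_config()]; `replicate_groups`
#' is an object mapping sample ids to group labels. Unknown keys are an
#' error, so typos never turn into silent defaults.
#'
#' @param path Path to a JSON config file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$replicate_groups)) {
    raw$replicate_groups <- unlist(raw$replicate_groups)
  }
  if (!is.null(raw$rank_scope)) raw$rank_scope <- unlist(raw$rank_scope)
  do.call(run_config, raw)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full cargo-to-network pipeline
#'
#' Executes normalize -> select -> consensus -> enrich -> network from one
#' configuration, writing every intermediate artifact (QC report, ranked
#' table, selection report, consensus edges and gene list, enrichment table
#' and summary, GraphML/SIF network, per-miRNA term counts, candidate
#' ranking) plus a machine-readable `summary.json` into the configured
#' output directory. Stage failures are reported with the failing stage
#' named.
#'
#' @param config A `run_config` (see [run_config()]) or a path to a JSON
#'   config file.
#' @return A `pipeline_result`: list with the fitted stage objects
#'   (`profile`, `selection`, `consensus`, `banded`, `enrichment`, `network`)
#'   and the `summary` list.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' sim <- simulate_inputs(sim_config(seed = 7, n_mirnas = 80), dir)
#' cfg <- run_config(sim$paths$counts, sim$paths$targets, sim$paths$gmt,
#'                   outdir = file.path(dir, "out"),
#'                   replicate_groups = unlist(sim$truth$replicate_groups))
#' res <- run_pipeline(cfg)
#' res$summary$n_selected
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  profile <- run_stage("normalize", {
    cm <- read_counts(config$counts, replicate_groups = config$replicate_groups)
    np <- normalize_counts(
      cm,
      k_sd = config$k_sd, background_mode = config$background_mode,
      top_n = config$top_n, pseudocount = config$pseudocount,
      mean_type = config$mean_type
    )
    readr::write_tsv(
      dplyr::left_join(np$factors, np$thresholds, by = "sample"),
      file.path(outdir, "qc_report.tsv")
    )
    readr::write_tsv(np$values, file.path(outdir, "normalized_values.tsv"))
    if (nrow(np$qc) > 0) {
      readr::write_tsv(np$qc, file.path(outdir, "replicate_qc.tsv"))
    }
    np
  })

  selection <- run_stage("select", {
    ranked <- rank_mirnas(profile)
    sel <- switch(config$selection_rule,
      share_floor = select_by_share_floor(ranked, config$share_floor),
      cumulative_fraction = select_by_cumulative_fraction(ranked, config$cumulative_f)
    )
    inform(sprintf(
      "Selected %d of %d miRNAs (%s), coverage %.1f%%, dominance ratio %.1f.",
      length(sel$selected), nrow(ranked), config$selection_rule,
      100 * sel$coverage, sel$dominance_ratio
    ))
    write_selection(sel,
                    table_path = file.path(outdir, "ranked_mirnas.tsv"),
                    report_path = file.path(outdir, "selection.json"))
    sel
  })

  consensus_stage <- run_stage("consensus", {
    records <- load_targets(config$targets)
    sel_keys <- canonical_mirna(selection$selected)
    union_genes <- unique(records$gene[canonical_mirna(records$mirna) %in% sel_keys])
    cts <- consensus_filter(records, selection$selected,
                            min_support = config$min_support,
                            score_mode = config$score_mode)
    cts <- confidence_bands(cts)
    banded <- if (config$keep_top_two_thirds) keep_top_two_thirds(cts) else cts
    write_consensus(cts,
                    edges_path = file.path(outdir, "consensus_edges.tsv"),
                    genes_path = file.path(outdir, "consensus_genes.txt"))
    writeLines(banded$genes, file.path(outdir, "enrichment_query_genes.txt"))
    list(records = records, union_genes = union_genes, cts = cts, banded = banded)
  })

  enrichment <- run_stage("enrich", {
    annotations <- read_gmt(config$gmt)
    background <- if (config$enrichment_background == "targets") {
      consensus_stage$union_genes
    } else {
      NULL
    }
    res <- run_ora(consensus_stage$banded$genes, annotations, background = background)
    res <- bespoke_filter(res, p_max = config$p_max, sd_mult = config$sd_mult)
    write_enrichment(res,
                     table_path = file.path(outdir, "enrichment.tsv"),
                     summary_path = file.path(outdir, "enrichment_summary.json"))
    trends <- trend_report(res)
    if (nrow(trends) > 0) {
      readr::write_tsv(trends, file.path(outdir, "enrichment_trends.tsv"))
    }
    list(annotations = annotations, res = res, trends = trends)
  })

  network_stage <- run_stage("network", {
    net <- build_network(consensus_stage$banded, enrichment$res,
                         enrichment$annotations)
    export_graph(net, file.path(outdir, "network.graphml"), format = "graphml")
    export_graph(net, file.path(outdir, "network.sif"), format = "sif")
    counts_tab <- per_mirna_term_counts(net)
    readr::write_tsv(counts_tab, file.path(outdir, "mirna_term_counts.tsv"))
    scope <- config$rank_scope %||% net$nodes$id[net$nodes$kind == "term"]
    ranking <- rank_candidates(net, scope)
    readr::write_tsv(ranking, file.path(outdir, "candidate_ranking.tsv"))
    list(net = net, counts = counts_tab, ranking = ranking, scope = scope)
  })

  sig <- significant_terms(enrichment$res)
  summary <- list(
    config = config[setdiff(names(config), "replicate_groups")],
    replicate_groups = as.list(config$replicate_groups %||% list()),
    n_samples = nrow(profile$factors),
    replicate_pearson_r = if (nrow(profile$qc) > 0) profile$qc$pearson_r else NULL,
    n_mirnas_profiled = sum(profile$values$probe_class == "endogenous"),
    n_selected = length(selection$selected),
    n_excluded = nrow(selection$ranked) - length(selection$selected),
    selected = selection$selected,
    coverage = selection$coverage,
    dominance_ratio = selection$dominance_ratio,
    n_genes_union = length(consensus_stage$union_genes),
    n_genes_consensus = length(consensus_stage$cts$genes),
    n_genes_banded = length(consensus_stage$banded$genes),
    fold_threshold = enrichment$res$summary$fold_threshold,
    fold_mean = enrichment$res$summary$fold_mean,
    fold_sd = enrichment$res$summary$fold_sd,
    n_terms_tested = nrow(enrichment$res$table),
    n_significant_terms = nrow(sig),
    significant_terms = sig$term_id,
    n_trend_terms = nrow(enrichment$trends),
    rank_scope = network_stage$scope,
    candidate_ranking = as.list(setNames(network_stage$ranking$n_targets,
                                         network_stage$ranking$mirna))
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(
    list(
      profile = profile,
      selection = selection,
      consensus = consensus_stage$cts,
      banded = consensus_stage$banded,
      enrichment = enrichment$res,
      network = network_stage$net,
      summary = summary
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<pipeline_result>\n",
      "  miRNAs: %d profiled, %d selected (coverage %.1f%%, dominance %.1f)\n",
      "  genes: %d union -> %d consensus -> %d banded\n",
      "  terms: %d tested, %d significant (fold threshold %.2f)\n"
    ),
    s$n_mirnas_profiled, s$n_selected, 100 * s$coverage, s$dominance_ratio,
    s$n_genes_union, s$n_genes_consensus, s$n_genes_banded,
    s$n_terms_tested, s$n_significant_terms, s$fold_threshold
  ))
  invisible(x)
}

#' @describeIn run_pipeline One-row tibble of the headline run quantities.
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @export
glance.pipeline_result <- function(x, ...) {
  s <- x$summary
  tibble(
    n_selected = s$n_selected,
    coverage = s$coverage,
    dominance_ratio = s$dominance_ratio,
    n_genes_consensus = s$n_genes_consensus,
    n_genes_banded = s$n_genes_banded,
    n_significant_terms = s$n_significant_terms,
    fold_threshold = s$fold_threshold,
    top_candidate = names(s$candidate_ranking)[1] %||% NA_character_
  )
}
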