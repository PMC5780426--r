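#' Build the tripartite miRNA-gene-term network
#'
#' Assembles the regulatory map connecting the selected cargo miRNAs to the
#' genes of significantly enriched terms: `targets` edges (miRNA -> gene) from
#' the consensus target set, `annotated` edges (gene -> term) from the
#' annotation membership, and aggregated `summary` edges (miRNA -> term)
#' weighted by the number of distinct term genes the miRNA targets. Gene
#' nodes are restricted to genes of significant terms; gene nodes carry a
#' `processes` attribute listing their significant-term memberships.
#'
#' @param cts A `consensus_targets` object.
#' @param res A filtered `enrichment_result` with at least one significant
#'   term (see [bespoke_filter()]).
#' @param annotations The `annotation_set` the enrichment was run against.
#' @return A `mirna_network`: list with `nodes` (tibble `id`, `kind`,
#'   `label`, `processes`), `edges` (tibble `from`, `to`, `kind`, `weight`)
#'   and `params`.
#' @export
build_network <- function(cts, res, annotations) {
  stopifnot(inherits(cts, "consensus_targets"), inherits(annotations, "annotation_set"))
  sig <- significant_terms(res)
  if (nrow(sig) == 0) abort("No significant terms; nothing to build.")
  term_tab <- annotations$terms[annotations$terms$term_id %in% sig$term_id, ]
  membership <- tidyr::unnest(
    term_tab[c("term_id", "term_name", "genes")],
    cols = "genes"
  ) |>
    dplyr::rename(gene = "genes")

  target_edges <- cts$edges |>
    dplyr::filter(.data$gene %in% membership$gene) |>
    dplyr::distinct(.data$mirna, .data$gene)
  if (nrow(target_edges) == 0) {
    abort("No consensus target falls in any significant term; network is empty.")
  }
  genes_kept <- sort(unique(target_edges$gene))
  membership <- dplyr::filter(membership, .data$gene %in% genes_kept)
  mirnas_kept <- sort(unique(target_edges$mirna))
  terms_kept <- sort(unique(membership$term_id))

  processes <- membership |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(processes = paste(sort(unique(.data$term_id)), collapse = ";"),
                     .groups = "drop")

  nodes <- dplyr::bind_rows(
    tibble(id = mirnas_kept, kind = "mirna", label = mirnas_kept, processes = ""),
    tibble(id = genes_kept, kind = "gene", label = genes_kept) |>
      dplyr::left_join(processes, by = c(id = "gene")),
    tibble(
      id = terms_kept, kind = "term",
      label = term_tab$term_name[match(terms_kept, term_tab$term_id)],
      processes = ""
    )
  )

  summary_edges <- target_edges |>
    dplyr::inner_join(membership[c("gene", "term_id")], by = "gene",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$mirna, .data$term_id) |>
    dplyr::summarise(weight = dplyr::n_distinct(.data$gene), .groups = "drop")

  edges <- dplyr::bind_rows(
    tibble(from = target_edges$mirna, to = target_edges$gene,
           kind = "targets", weight = 1L),
    membership |>
      dplyr::distinct(.data$gene, .data$term_id) |>
      (\(d) tibble(from = d$gene, to = d$term_id, kind = "annotated", weight = 1L))(),
    tibble(from = summary_edges$mirna, to = summary_edges$term_id,
           kind = "summary", weight = as.integer(summary_edges$weight))
  ) |>
    dplyr::arrange(.data$kind, .data$from, .data$to)

  structure(
    list(
      nodes = nodes,
      edges = edges,
      params = list(
        consensus = cts$params,
        enrichment = res$summary,
        n_significant_terms = nrow(sig)
      )
    ),
    class = "mirna_network"
  )
}

#' @export
print.mirna_network <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat(sprintf(
    "<mirna_network> %d nodes (%s), %d edges\n",
    nrow(x$nodes),
    paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", "),
    nrow(x$edges)
  ))
  invisible(x)
}

#' Tidy a miRNA network
#'
#' @param x A `mirna_network`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.mirna_network <- function(x, ...) x$edges

#' @describeIn tidy.mirna_network One-row node/edge census.
#' @export
glance.mirna_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_mirnas = sum(x$nodes$kind == "mirna"),
    n_genes = sum(x$nodes$kind == "gene"),
    n_terms = sum(x$nodes$kind == "term"),
    n_target_edges = sum(x$edges$kind == "targets"),
    n_annotated_edges = sum(x$edges$kind == "annotated"),
    n_summary_edges = sum(x$edges$kind == "summary")
  )
}

#' Distinct term-gene targets per miRNA and term
#'
#' The weight of every miRNA -> term summary edge: how many distinct genes of
#' the term the miRNA targets. Zero-weight pairs are never materialized.
#'
#' @param net A `mirna_network`.
#' @return Tibble `mirna`, `term_id`, `n_genes`, sorted by decreasing count.
#' @export
per_mirna_term_counts <- function(net) {
  stopifnot(inherits(net, "mirna_network"))
  net$edges |>
    dplyr::filter(.data$kind == "summary") |>
    dplyr::transmute(mirna = .data$from, term_id = .data$to,
                     n_genes = .data$weight) |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$mirna, .data$term_id)
}

#' Genes targeted exclusively by one miRNA
#'
#' Targets of `mirna` in the network (optionally restricted to genes of a set
#' of terms) that no other cargo miRNA in the network targets — the leverage
#' a single species has that the rest of the cargo cannot replace.
#'
#' @param net A `mirna_network`.
#' @param mirna miRNA id (prefix-/case-insensitive match).
#' @param term_scope Optional character vector of term ids restricting the
#'   gene universe considered.
#' @return Sorted character vector of gene symbols.
#' @export
unique_targets <- function(net, mirna, term_scope = NULL) {
  stopifnot(inherits(net, "mirna_network"))
  targets <- net$edges[net$edges$kind == "targets", ]
  key <- canonical_mirna(mirna)
  hit <- unique(targets$from[canonical_mirna(targets$from) == key])
  if (length(hit) == 0) {
    abort(sprintf("miRNA '%s' is not present in the network.", mirna))
  }
  own <- targets$to[targets$from %in% hit]
  others <- targets$to[!targets$from %in% hit]
  out <- setdiff(own, others)
  if (!is.null(term_scope)) {
    scope_genes <- scope_gene_set(net, term_scope)
    out <- intersect(out, scope_genes)
  }
  sort(out)
}

#' Rank cargo-loading candidate miRNAs for a term scope
#'
#' Orders the cargo miRNAs by how many distinct genes they target within a
#' bundle of terms (e.g. all vasculature-development processes), descending,
#' ties broken lexicographically — the logic used to nominate which miRNA to
#' load into vesicles to push a phenotype.
#'
#' @param net A `mirna_network`.
#' @param term_scope Character vector of term ids present in the network.
#' @return Tibble `mirna`, `n_targets`, ordered best-first.
#' @export
rank_candidates <- function(net, term_scope) {
  stopifnot(inherits(net, "mirna_network"))
  if (length(term_scope) == 0) abort("`term_scope` must name at least one term.")
  scope_genes <- scope_gene_set(net, term_scope)
  targets <- net$edges[net$edges$kind == "targets" & net$edges$to %in% scope_genes, ]
  all_mirnas <- net$nodes$id[net$nodes$kind == "mirna"]
  counts <- targets |>
    dplyr::group_by(mirna = .data$from) |>
    dplyr::summarise(n_targets = dplyr::n_distinct(.data$to), .groups = "drop")
  tibble(mirna = all_mirnas) |>
    dplyr::left_join(counts, by = "mirna") |>
    dplyr::mutate(n_targets = dplyr::coalesce(.data$n_targets, 0L)) |>
    dplyr::arrange(dplyr::desc(.data$n_targets), .data$mirna)
}

scope_gene_set <- function(net, term_scope) {
  known <- net$nodes$id[net$nodes$kind == "term"]
  missing_t <- setdiff(term_scope, known)
  if (length(missing_t) > 0) {
    abort(sprintf(
      "Term(s) not in network: %s.",
      paste(missing_t, collapse = ", ")
    ))
  }
  ann <- net$edges[net$edges$kind == "annotated" & net$edges$to %in% term_scope, ]
  unique(ann$from)
}

#' Convert a miRNA network to igraph
#'
#' @param net A `mirna_network`.
#' @return A directed `igraph` graph with node attributes `kind`, `label`,
#'   `processes` and edge attributes `kind`, `weight`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mirna_network"))
  igraph::graph_from_data_frame(
    d = net$edges,
    directed = TRUE,
    vertices = dplyr::rename(net$nodes, name = "id")
  )
}

#' Export a miRNA network for external viewers
#'
#' GraphML (typed node/edge attributes; round-trips through
#' [import_graphml()]) or SIF (`source<TAB>kind<TAB>target`, the Cytoscape
#' simple-interaction dialect).
#'
#' @param net A `mirna_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    writeLines(
      sprintf("%s\t%s\t%s", net$edges$from, net$edges$kind, net$edges$to),
      path
    )
  }
  invisible(path)
}

#' Read a GraphML export back into a miRNA network
#'
#' Inverse of [export_graph()] for the GraphML format; node/edge tables are
#' restored in canonical order so an export/import round trip is the
#' identity.
#'
#' @param path Path to a GraphML file written by [export_graph()].
#' @return A `mirna_network`.
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vdf <- igraph::as_data_frame(g, what = "vertices")
  edf <- igraph::as_data_frame(g, what = "edges")
  nodes <- tibble(
    id = vdf$name, kind = vdf$kind, label = vdf$label,
    processes = vdf$processes %||% ""
  )
  edges <- tibble(
    from = edf$from, to = edf$to, kind = edf$kind,
    weight = as.integer(round(edf$weight))
  ) |>
    dplyr::arrange(.data$kind, .data$from, .data$to)
  structure(
    list(nodes = nodes[order(match(nodes$kind, c("mirna", "gene", "term")), nodes$id), ],
         edges = edges, params = list(imported_from = path)),
    class = "mirna_network"
  )
}
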