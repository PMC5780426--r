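test_that("the tripartite network enumerates nodes and typed edges exactly", {
  toy <- toy_network()
  net <- build_network(toy$cts, toy$res, toy$anno)
  # 2 miRNAs + 3 genes + 1 significant term
  expect_equal(glance(net)$n_nodes, 6)
  expect_equal(glance(net)$n_terms, 1)
  expect_equal(glance(net)$n_target_edges, 4)
  expect_equal(glance(net)$n_annotated_edges, 3)
  expect_equal(glance(net)$n_summary_edges, 2)
  # summary weights: miR-a covers G1,G2 of TERM1; miR-b covers G2,G3
  s <- net$edges[net$edges$kind == "summary", ]
  expect_equal(s$weight[s$from == "miR-a"], 2L)
  expect_equal(s$weight[s$from == "miR-b"], 2L)
  # gene processes attribute lists the significant term
  expect_equal(unique(net$nodes$processes[net$nodes$kind == "gene"]), "TERM1")
  # no dangling endpoints
  expect_true(all(c(net$edges$from, net$edges$to) %in% net$nodes$id))
})

test_that("network construction fails cleanly without significant overlap", {
  toy <- toy_network()
  none <- toy$res
  none$table$significant <- FALSE
  expect_error(build_network(toy$cts, none, toy$anno), "No significant")

  disjoint <- toy$cts
  disjoint$edges$gene <- c("X1", "X2", "X2", "X3")
  disjoint$genes <- c("X1", "X2", "X3")
  expect_error(build_network(disjoint, toy$res, toy$anno), "empty")
})

test_that("per-miRNA term counts equal brute-force set intersections", {
  toy <- toy_network()
  # miRNA targeting {G1, G2}, term containing {G2, X}: count 1
  cts <- toy$cts
  cts$edges <- tibble::tibble(mirna = c("miR-a", "miR-a"), gene = c("G1", "G2"),
                              support = 5L, integrated_score = 0.9)
  cts$genes <- c("G1", "G2")
  anno <- annotation_set(tibble::tibble(
    term_id = "TERM1", term_name = "toy process", genes = list(c("G2", "G9"))
  ))
  net <- build_network(cts, toy$res, anno)
  counts <- per_mirna_term_counts(net)
  expect_equal(counts$n_genes, 1L)

  # randomized fixture checked by explicit intersection
  set.seed(42)
  mirnas <- paste0("miR-", letters[1:4])
  genes <- sprintf("G%02d", 1:30)
  edges <- tidyr::expand_grid(mirna = mirnas, gene = genes) |>
    dplyr::slice_sample(prop = 0.4) |>
    dplyr::mutate(support = 5L, integrated_score = 0.9)
  cts$edges <- edges
  cts$genes <- sort(unique(edges$gene))
  anno2 <- annotation_set(tibble::tibble(
    term_id = c("TERM1", "TERM2"), term_name = c("p1", "p2"),
    genes = list(sample(genes, 12), sample(genes, 8))
  ))
  res2 <- fake_enrichment(c(3, 3), p = c(1e-9, 1e-9), k = c(2L, 2L))
  res2$table$term_id <- c("TERM1", "TERM2")
  res2 <- bespoke_filter(res2, sd_mult = 0)
  res2$table$significant <- TRUE # both terms in scope for the census
  net2 <- build_network(cts, res2, anno2)
  counts2 <- per_mirna_term_counts(net2)
  for (i in seq_len(nrow(counts2))) {
    m <- counts2$mirna[i]; tid <- counts2$term_id[i]
    brute <- length(intersect(
      edges$gene[edges$mirna == m],
      anno2$terms$genes[[match(tid, anno2$terms$term_id)]]
    ))
    expect_equal(counts2$n_genes[i], brute)
  }
  # gene degree over targets edges = number of miRNAs targeting the gene
  tgt <- net2$edges[net2$edges$kind == "targets", ]
  kept <- net2$nodes$id[net2$nodes$kind == "gene"]
  for (g in kept) {
    expect_equal(sum(tgt$to == g), sum(edges$gene == g))
  }
})

test_that("unique-target sets are exact set differences", {
  toy <- toy_network()
  net <- build_network(toy$cts, toy$res, toy$anno)
  # miR-a targets G1,G2; miR-b targets G2,G3 -> unique are G1 / G3
  expect_equal(unique_targets(net, "miR-a"), "G1")
  expect_equal(unique_targets(net, "miR-b"), "G3")
  expect_equal(unique_targets(net, "miR-a", term_scope = "TERM1"), "G1")
  expect_error(unique_targets(net, "miR-zzz"), "not present")

  # identical target sets leave nothing unique
  cts <- toy$cts
  cts$edges <- tidyr::expand_grid(mirna = c("miR-a", "miR-b"),
                                  gene = c("G1", "G2")) |>
    dplyr::mutate(support = 5L, integrated_score = 0.9)
  cts$genes <- c("G1", "G2")
  net2 <- build_network(cts, toy$res, toy$anno)
  expect_equal(unique_targets(net2, "miR-a"), character(0))

  # sole miRNA keeps all its targets
  solo <- toy$cts
  solo$edges <- solo$edges[solo$edges$mirna == "miR-a", ]
  solo$genes <- unique(solo$edges$gene)
  net3 <- build_network(solo, toy$res, toy$anno)
  expect_equal(unique_targets(net3, "miR-a"), c("G1", "G2"))
})

test_that("candidate ranking orders by scoped distinct targets with lexical ties", {
  toy <- toy_network()
  net <- build_network(toy$cts, toy$res, toy$anno)
  ranking <- rank_candidates(net, "TERM1")
  counts <- per_mirna_term_counts(net)
  expect_equal(ranking$n_targets,
               counts$n_genes[match(ranking$mirna, counts$mirna)])
  # tie on 2 targets each -> lexicographic
  expect_equal(ranking$mirna, c("miR-a", "miR-b"))
  expect_error(rank_candidates(net, "TERM404"), "not in network")
  expect_error(rank_candidates(net, character(0)), "at least one")
})

test_that("graph exports round-trip (GraphML) and enumerate edges (SIF)", {
  toy <- toy_network()
  net <- build_network(toy$cts, toy$res, toy$anno)

  gpath <- tempfile(fileext = ".graphml")
  export_graph(net, gpath, format = "graphml")
  back <- import_graphml(gpath)
  expect_equal(as.data.frame(back$nodes), as.data.frame(net$nodes))
  expect_equal(as.data.frame(back$edges), as.data.frame(net$edges))

  spath <- tempfile(fileext = ".sif")
  export_graph(net, spath, format = "sif")
  lines <- readLines(spath)
  expect_equal(length(lines), nrow(net$edges))
  expect_true(all(grepl("^[^\t]+\t(targets|annotated|summary)\t[^\t]+$", lines)))

  expect_error(export_graph(net, tempfile(), format = "dot"), "arg")
})

test_that("network invariants hold across random synthetic runs", {
  mirnas <- sprintf("hsa-miR-%04d", 1:10)
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, n_genes = 250, n_terms = 15,
                      planted_terms = c(angio = "strong"))
    db <- simulate_target_db(cfg, mirnas, planted_mirna = mirnas[1])
    cts <- keep_top_two_thirds(confidence_bands(
      consensus_filter(db$targets, mirnas, min_support = 5)
    ))
    ann <- simulate_annotations(cfg, db$truth$genes, db$truth$true_edges,
                                selected = mirnas, planted_mirna = mirnas[1])
    res <- bespoke_filter(run_ora(cts$genes, ann$annotations))
    if (nrow(significant_terms(res)) == 0) next
    net <- build_network(cts, res, ann$annotations)
    expect_true(all(c(net$edges$from, net$edges$to) %in% net$nodes$id))
    # summary edges run mirna -> term with weight >= 1
    s <- net$edges[net$edges$kind == "summary", ]
    expect_true(all(s$weight >= 1))
    kinds <- setNames(net$nodes$kind, net$nodes$id)
    expect_true(all(kinds[s$from] == "mirna") && all(kinds[s$to] == "term"))
    # sum of summary weights >= distinct targeted genes in the term union
    tgt <- net$edges[net$edges$kind == "targets", ]
    for (m in unique(s$from)) {
      expect_gte(sum(s$weight[s$from == m]), length(unique(tgt$to[tgt$from == m])))
    }
  }
})
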