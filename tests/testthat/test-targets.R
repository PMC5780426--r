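write_targets_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

test_that("target tables load, deduplicate to max score, and validate", {
  df <- tibble::tibble(
    source = c("s1", "s1", "s2"),
    mirna = c("hsa-miR-1", "hsa-miR-1", "hsa-miR-2"),
    gene = c("tp53", "MYC", "TP53"),
    score = c(0.5, 0.9, 0.7)
  )
  rec <- load_targets(write_targets_tsv(df))
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$gene %in% c("TP53", "MYC")))

  dup <- dplyr::bind_rows(df[1, ], dplyr::mutate(df[1, ], score = 0.4))
  expect_message(rec2 <- load_targets(write_targets_tsv(dup)), "Collapsed 1")
  expect_equal(nrow(rec2), 1)
  expect_equal(rec2$score, 0.5)

  expect_warning(
    empty <- load_targets(write_targets_tsv(df[0, ])),
    "empty"
  )
  expect_equal(nrow(empty), 0)

  bad <- dplyr::mutate(df, score = c(0.5, 1.2, 0.7))
  expect_error(load_targets(write_targets_tsv(bad)), "\\[0, 1\\]")
})

three_source_records <- function() {
  tibble::tibble(
    source = c("s1", "s2", "s3", "s1", "s2", "s1"),
    mirna = "hsa-miR-9",
    gene = c("A", "A", "A", "B", "B", "C"),
    score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  )
}

test_that("consensus support counts distinct sources and filters by k", {
  rec <- three_source_records()
  cts <- consensus_filter(rec, "hsa-miR-9", min_support = 2)
  expect_equal(cts$edges$gene, c("A", "B"))
  expect_equal(cts$edges$support, c(3L, 2L))
  expect_equal(cts$edges$integrated_score, c(mean(c(0.9, 0.8, 0.7)), 0.55))
  expect_equal(cts$genes, c("A", "B"))

  # min_support = 1 is the union, = n_sources the intersection
  expect_equal(consensus_filter(rec, "hsa-miR-9", min_support = 1)$edges$gene,
               c("A", "B", "C"))
  expect_equal(consensus_filter(rec, "hsa-miR-9", min_support = 3)$edges$gene, "A")

  expect_warning(
    none <- consensus_filter(rec, "hsa-miR-9", min_support = 7),
    "exceeds"
  )
  expect_equal(nrow(none$edges), 0)

  # max score mode
  cmax <- consensus_filter(rec, "hsa-miR-9", min_support = 2, score_mode = "max")
  expect_equal(cmax$edges$integrated_score, c(0.9, 0.6))
})

test_that("miRNA matching ignores the species prefix and case", {
  rec <- three_source_records()
  expect_equal(nrow(consensus_filter(rec, "MIR-9", min_support = 1)$edges), 3)
  expect_equal(nrow(consensus_filter(rec, "hsa-mir-9", min_support = 1)$edges), 3)
  expect_equal(nrow(consensus_filter(rec, "miR-7", min_support = 1)$edges), 0)
})

test_that("confidence bands split retained edges into empirical tertiles", {
  rec <- tibble::tibble(
    source = "s1",
    mirna = "m",
    gene = LETTERS[1:9],
    score = seq(0.1, 0.9, by = 0.1)
  )
  cts <- confidence_bands(consensus_filter(rec, "m", min_support = 1))
  expect_equal(as.integer(table(cts$edges$band)[c("bottom", "middle", "top")]),
               c(3L, 3L, 3L))
  expect_equal(sort(cts$edges$gene[cts$edges$band == "bottom"]), c("A", "B", "C"))

  kept <- keep_top_two_thirds(cts)
  expect_equal(nrow(kept$edges), 6)
  expect_true(all(kept$genes %in% cts$genes))

  single <- consensus_filter(rec[1, ], "m", min_support = 1)
  expect_warning(b1 <- confidence_bands(single), "identical")
  expect_equal(b1$edges$band, "top")
})

test_that("consensus is monotone in the support threshold", {
  cfg <- sim_config(seed = 5, n_genes = 200)
  mirnas <- sprintf("hsa-miR-%04d", 1:8)
  db <- simulate_target_db(cfg, mirnas, planted_mirna = mirnas[1])
  prev <- NULL
  for (k in 1:6) {
    cts <- consensus_filter(db$targets, mirnas, min_support = k)
    key <- paste(cts$edges$mirna, cts$edges$gene)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
    expect_true(all(cts$edges$support <= 6))
  }
})

test_that("multi-database agreement enriches for true target relations", {
  prec <- function(cts, truth) {
    if (nrow(cts$edges) == 0) return(NA_real_)
    key <- paste(canonical_mirna(cts$edges$mirna), cts$edges$gene)
    truth_key <- paste(canonical_mirna(truth$mirna), truth$gene)
    mean(key %in% truth_key)
  }
  p1 <- p5 <- numeric(0)
  mirnas <- sprintf("hsa-miR-%04d", 1:8)
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_genes = 200)
    db <- simulate_target_db(cfg, mirnas, planted_mirna = mirnas[1])
    p1 <- c(p1, prec(consensus_filter(db$targets, mirnas, min_support = 1),
                     db$truth$true_edges))
    p5 <- c(p5, prec(consensus_filter(db$targets, mirnas, min_support = 5),
                     db$truth$true_edges))
  }
  expect_true(all(p5 > p1, na.rm = TRUE))
  expect_gt(mean(p5, na.rm = TRUE), 0.95)
})
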