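test_that("geometric mean matches closed form and rejects bad input", {
  expect_equal(geometric_mean(c(7, 7, 7)), 7)
  expect_equal(geometric_mean(c(2, 8)), 4)
  expect_equal(geometric_mean(c(1, 2, 4, 8)), 2 * sqrt(2))
  expect_error(geometric_mean(numeric(0)), "empty")
  expect_error(geometric_mean(c(0, 2)), "non-positive")
  expect_equal(geometric_mean(c(0, 2), pseudocount = 2), 2)
})

test_that("positive-control factors follow the reference-over-sample rule", {
  # one positive probe with counts 10 and 20 -> geomeans 10, 20; reference 15
  tbl <- tibble::tibble(
    probe_id = c("m1", "m2", "POS_A", "NEG_01"),
    probe_class = c("endogenous", "endogenous", "positive", "negative"),
    expected_conc = c(NA, NA, 128, NA),
    a = c(100, 40, 10, 0), b = c(60, 80, 20, 1)
  )
  cm <- as_count_matrix(tbl)
  pc <- positive_control_normalize(cm)
  expect_equal(pc$factors$factor, c(1.5, 0.75))
  expect_equal(pc$values$a, tbl$a * 1.5)
  expect_equal(pc$values$b, tbl$b * 0.75)

  # single sample: factor is exactly 1
  single <- as_count_matrix(tbl[, 1:4])
  pc1 <- positive_control_normalize(single)
  expect_equal(pc1$factors$factor, 1)
  expect_equal(pc1$values$a, tbl$a)

  # doubling every count of one sample halves its factor relative to the
  # others and leaves the normalized values unchanged up to the shared
  # reference rescale (between-sample ratios are exactly invariant)
  doubled <- tbl
  doubled$a <- doubled$a * 2
  pc2 <- positive_control_normalize(as_count_matrix(doubled))
  expect_equal(pc2$factors$factor[1] / pc2$factors$factor[2],
               (pc$factors$factor[1] / pc$factors$factor[2]) / 2)
  expect_equal(pc2$values$a / pc2$values$b, pc$values$a / pc$values$b)

  zero <- tbl
  zero$a[3] <- 0
  expect_error(positive_control_normalize(as_count_matrix(zero)), "sample 'a'")
})

test_that("background thresholds use mean + k_sd * sd of negatives", {
  tbl <- tibble::tibble(
    probe_id = c("m1", "m2", "POS_A", "NEG_01", "NEG_02", "NEG_03"),
    probe_class = c("endogenous", "endogenous", "positive", "negative", "negative", "negative"),
    expected_conc = c(NA, NA, 128, NA, NA, NA),
    a = c(8, 50, 100, 2, 4, 6)
  )
  # negatives (2, 4, 6): mean 4, sample sd 2 -> threshold 8 at k_sd = 2
  bg <- background_threshold(tbl, k_sd = 2)
  expect_equal(bg$thresholds$threshold, 8)
  # endogenous value equal to the threshold is floored (inclusive boundary)
  expect_equal(bg$values$a[1], 0)
  expect_equal(bg$values$a[2], 50)
  expect_equal(bg$values$a[3], 100) # controls untouched

  sub <- background_threshold(tbl, k_sd = 2, mode = "subtract")
  expect_equal(sub$values$a[1:2], c(0, 42))

  # all-zero negatives: threshold 0, everything above survives
  z <- tbl
  z$a[4:6] <- 0
  bg0 <- background_threshold(z, k_sd = 2)
  expect_equal(bg0$thresholds$threshold, 0)
  expect_equal(bg0$values$a[1:2], c(8, 50))

  expect_error(background_threshold(tbl, k_sd = -1), "k_sd")
})

test_that("content normalization anchors on the fixed top-N probe set", {
  # probe means put A and B on top; factors from geomeans of A, B only:
  # sample x: gm(4, 16) = 8; sample y: gm(16, 64) = 32; mean 20 -> 2.5, 0.625
  tbl <- tibble::tibble(
    probe_id = c("A", "B", "C", "D", "E"),
    probe_class = "endogenous",
    expected_conc = NA_real_,
    x = c(4, 16, 1, 2, 1),
    y = c(16, 64, 2, 1, 3)
  )
  cn <- content_normalize(tbl, top_n = 2)
  expect_equal(cn$anchor_probes, c("B", "A"))
  expect_equal(cn$factors$factor, c(2.5, 0.625))
  expect_equal(cn$values$x, tbl$x * 2.5)

  # identical samples: all factors 1
  same <- tbl
  same$y <- same$x
  expect_equal(content_normalize(same, top_n = 2)$factors$factor, c(1, 1))

  # uniform x3 scaling of one sample: normalized tables equal
  scaled <- tbl
  scaled$y <- tbl$x * 3
  cn2 <- content_normalize(scaled, top_n = 3)
  expect_equal(cn2$values$x, cn2$values$y)

  expect_warning(content_normalize(tbl, top_n = 10), "using all")

  zero <- tbl
  zero$x <- 0
  expect_error(content_normalize(zero, top_n = 2), "zero in sample")
})

test_that("replicate correlations hit the exact limit cases", {
  tbl <- tibble::tibble(
    probe_id = paste0("m", 1:4),
    probe_class = "endogenous",
    expected_conc = NA_real_,
    a = c(1, 5, 9, 2), b = c(1, 5, 9, 2), c = -c(1, 5, 9, 2) + 10
  )
  qc <- replicate_qc(tbl, groups = c(a = "g", b = "g", c = "g"))
  expect_equal(nrow(qc), 3)
  expect_equal(qc$pearson_r[qc$sample_a == "a" & qc$sample_b == "b"], 1)
  expect_equal(qc$pearson_r[qc$sample_a == "a" & qc$sample_b == "c"], -1)

  flat <- tbl
  flat$b <- 3
  expect_warning(
    qc2 <- replicate_qc(flat, groups = c(a = "g", b = "g")),
    "Zero-variance"
  )
  expect_true(is.na(qc2$pearson_r))

  # singleton groups emit nothing
  expect_equal(nrow(replicate_qc(tbl, groups = c(a = "g1", b = "g2", c = "g3"))), 0)
})

test_that("replicate merging averages per probe and renormalizes shares", {
  tbl <- tibble::tibble(
    probe_id = c("m1", "m2"),
    probe_class = "endogenous",
    expected_conc = NA_real_,
    a = c(2, 6), b = c(4, 2)
  )
  merged <- merge_replicates(tbl, c(a = "g", b = "g"))
  expect_equal(merged$g, c(3, 4))
  # identical replicates: merged equals either
  same <- merge_replicates(tbl[c(1:3, 4, 4)] |> setNames(c(names(tbl)[1:4], "b")),
                           c(a = "g", b = "g"))
  expect_equal(same$g, tbl$a)
  expect_error(merge_replicates(tbl, c(a = "g", b = "g", zz = "empty")),
               "no samples")
})

test_that("normalization invariances hold on random fixtures", {
  for (seed in 1:25) {
    cm <- random_counts(seed)
    np <- normalize_counts(cm, top_n = 10)
    samples <- sample_ids(cm)

    # shares sum to one per sample
    for (s in samples) expect_equal(sum(np$shares[[s]]), 1, tolerance = 1e-9)

    # uniform rescaling of one sample's raw counts leaves its shares unchanged
    scaled <- cm
    scaled[[samples[1]]] <- scaled[[samples[1]]] * 3
    np2 <- normalize_counts(as_count_matrix(as_tibble(scaled)), top_n = 10)
    expect_equal(np2$shares[[samples[1]]], np$shares[[samples[1]]], tolerance = 1e-9)

    # rank order of surviving endogenous probes is preserved within sample
    raw <- cm[[samples[2]]][cm$probe_class == "endogenous"]
    fin <- np$values[[samples[2]]][np$values$probe_class == "endogenous"]
    keep <- fin > 0
    expect_equal(order(-fin[keep]), order(-raw[keep]))
  }
})

test_that("the normalization pipeline is deterministic", {
  path <- write_counts_csv(as_tibble(random_counts(99)))
  np1 <- normalize_counts(read_counts(path), top_n = 10)
  np2 <- normalize_counts(read_counts(path), top_n = 10)
  expect_identical(np1$values, np2$values)
  expect_identical(np1$shares, np2$shares)
})
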