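# Fixtures are all built in code; nothing is read from disk except files the
# tests themselves write to tempdirs.

# minimal 4-probe, 2-sample counts table: 2 endogenous, 1 positive, 1 negative
tiny_counts_tbl <- function() {
  tibble::tibble(
    probe_id = c("hsa-miR-0001", "hsa-miR-0002", "POS_A", "NEG_01"),
    probe_class = c("endogenous", "endogenous", "positive", "negative"),
    expected_conc = c(NA, NA, 128, NA),
    s1 = c(500, 100, 4000, 5),
    s2 = c(450, 120, 3900, 8)
  )
}

write_counts_csv <- function(tbl, path = tempfile(fileext = ".csv")) {
  readr::write_csv(tbl, path, na = "")
  path
}

# random positive-count fixture: endogenous counts kept far above background so
# thresholding and pseudocounts never interfere with exact-invariance checks
random_counts <- function(seed, n_endo = 30, n_samples = 3) {
  set.seed(seed)
  samples <- paste0("s", seq_len(n_samples))
  tbl <- tibble::tibble(
    probe_id = c(sprintf("hsa-miR-%04d", seq_len(n_endo)), "POS_A", "POS_B", "NEG_01", "NEG_02"),
    probe_class = rep(c("endogenous", "positive", "negative"), c(n_endo, 2, 2)),
    expected_conc = c(rep(NA, n_endo), 128, 32, NA, NA)
  )
  for (s in samples) {
    tbl[[s]] <- c(
      rpois(n_endo, lambda = sample(200:2000, n_endo, replace = TRUE)) + 100,
      rpois(2, 5000) + 100, rpois(2, 5)
    )
  }
  as_count_matrix(tbl)
}

# ranked table straight from shares (values chosen so shares are exact)
ranked_from_shares <- function(shares, ids = NULL) {
  ids <- ids %||% sprintf("m%02d", seq_along(shares))
  rank_mirnas(tibble::tibble(mirna = ids, value = shares * 1000))
}

# independent hypergeometric upper-tail oracle: exact pmf summation from
# binomial coefficients, written without phyper/dhyper
hyper_tail_oracle <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# hand-made enrichment result with prescribed folds/ps (for filter arithmetic)
fake_enrichment <- function(fold, p = rep(0.5, length(fold)), k = rep(1L, length(fold))) {
  structure(
    list(
      table = tibble::tibble(
        term_id = sprintf("T%02d", seq_along(fold)),
        term_name = sprintf("term %d", seq_along(fold)),
        K = 10L, k = k, n = 20L, N = 100L,
        fold = fold, p = p, q = p.adjust(p, "BH")
      ),
      params = list(n_query = 20L, n_query_effective = 20L, background = "universe", N = 100L)
    ),
    class = "enrichment_result"
  )
}

# three-bucket miRNA/gene/term toy network inputs
toy_network <- function() {
  cts <- structure(
    list(
      edges = tibble::tibble(
        mirna = c("miR-a", "miR-a", "miR-b", "miR-b"),
        gene = c("G1", "G2", "G2", "G3"),
        support = 5L, integrated_score = 0.9
      ),
      genes = c("G1", "G2", "G3"),
      params = list(min_support = 5, score_mode = "mean", n_sources = 6, band_rule = NULL)
    ),
    class = "consensus_targets"
  )
  anno <- annotation_set(tibble::tibble(
    term_id = c("TERM1", "TERM2"),
    term_name = c("toy process", "unenriched process"),
    genes = list(c("G1", "G2", "G3"), c("G4", "G5"))
  ))
  res <- fake_enrichment(fold = c(3, 1), p = c(1e-9, 0.5), k = c(3L, 1L))
  res$table$term_id <- c("TERM1", "TERM2")
  res <- bespoke_filter(res, p_max = 1e-6, sd_mult = 0)
  list(cts = cts, anno = anno, res = res)
}
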