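#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generator. The
#' defaults emulate the data regime of a vesicle miRNA profiling run on a
#' digital hybridization platform: 171 endogenous probes whose abundances
#' follow a heavy-tailed log-normal (so the top ~13% of species carry
#' 70-85% of total reads), two biological replicates with multiplicative lane
#' effects and negative-binomial counting noise, six spiked positive-control
#' probes on a standard two-fold-ish titration, and low-count Poisson
#' negative controls. Downstream, a six-source target-prediction database is
#' simulated with planted true edges (higher per-source inclusion probability
#' and higher scores than false edges) and annotation terms with planted
#' enrichment: a designated "pro-angiogenic" miRNA receives a denser,
#' high-confidence true-target set from which strongly planted terms draw
#' most of their genes.
#'
#' @param seed Integer master seed; sub-generators (counts, target database,
#'   annotations) derive independent streams from it.
#' @param n_mirnas Number of endogenous miRNA probes.
#' @param replicates Named integer vector: replicate-group label -> number of
#'   replicate samples.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   population abundance profile: true per-miRNA abundances follow the
#'   quantile profile of this log-normal (a fixed heavy-tailed shape), so the
#'   dominance structure of the regime is reproduced stably across seeds.
#' @param abundance_jitter_sdlog Log-normal sd of the per-run multiplicative
#'   jitter applied to the abundance profile.
#' @param lane_effect_range Range of the uniform per-sample multiplicative
#'   lane effect.
#' @param replicate_sdlog Log-normal sd of per-probe, per-replicate
#'   multiplicative noise.
#' @param nb_size Negative-binomial size (inverse dispersion) of counting
#'   noise.
#' @param pos_control_conc Titration of the positive-control probes (fM).
#' @param pos_control_slope Expected counts per fM.
#' @param n_neg_controls,neg_control_lambda Number and Poisson mean of
#'   negative-control probes.
#' @param n_genes Size of the synthetic gene universe.
#' @param n_sources Number of prediction sources in the target database.
#' @param true_edge_density Probability that a (miRNA, gene) pair is a true
#'   target relation.
#' @param p_true,p_false Per-source inclusion probability of true and false
#'   edges.
#' @param score_true,score_false,score_planted Beta(a, b) parameters of the
#'   per-source scores for false, true, and planted-miRNA true edges.
#' @param planted_mirna Id of the planted pro-angiogenic miRNA; `NULL`
#'   (default) designates the most abundant true miRNA.
#' @param planted_mirna_density,planted_p_true True-edge density and
#'   per-source sensitivity for the planted miRNA.
#' @param n_terms Number of unplanted (null) annotation terms.
#' @param term_size Length-2 range of null-term sizes.
#' @param planted_terms Named character vector, term name -> effect (one of
#'   `"null"`, `"moderate"`, `"strong"`); strong terms draw 85% of their
#'   genes from the planted miRNA's true targets, moderate terms 50% from
#'   the union of selected-miRNA true targets.
#' @param planted_term_size Size of planted terms.
#' @param n_dominant Size of the ground-truth dominant cargo set (top by true
#'   abundance).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_mirnas = 171,
                       replicates = c(MSC = 2),
                       abundance_meanlog = log(500),
                       abundance_sdlog = 2.0,
                       abundance_jitter_sdlog = 0.3,
                       lane_effect_range = c(0.7, 1.3),
                       replicate_sdlog = 0.2,
                       nb_size = 10,
                       pos_control_conc = c(128, 32, 8, 2, 0.5, 0.125),
                       pos_control_slope = 250,
                       n_neg_controls = 8,
                       neg_control_lambda = 10,
                       n_genes = 600,
                       n_sources = 6,
                       true_edge_density = 0.02,
                       p_true = 0.9,
                       p_false = 0.03,
                       score_true = c(8, 2),
                       score_false = c(2, 5),
                       score_planted = c(12, 1.5),
                       planted_mirna = NULL,
                       planted_mirna_density = 0.12,
                       planted_p_true = 0.95,
                       n_terms = 50,
                       term_size = c(10, 40),
                       planted_terms = c("vasculature development" = "strong"),
                       planted_term_size = 35,
                       n_dominant = 23) {
  cfg <- as.list(environment())
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(seed) && length(seed) == 1 && seed == round(seed), "seed: single integer")
  chk(n_mirnas >= 2, "n_mirnas: >= 2")
  chk(is.numeric(replicates) && length(replicates) >= 1 && !is.null(names(replicates)) &&
        all(replicates >= 1), "replicates: named vector of counts >= 1")
  chk(abundance_sdlog >= 0, "abundance_sdlog: >= 0")
  chk(abundance_jitter_sdlog >= 0, "abundance_jitter_sdlog: >= 0")
  chk(length(lane_effect_range) == 2 && all(lane_effect_range > 0) &&
        diff(lane_effect_range) >= 0, "lane_effect_range: increasing positive pair")
  chk(replicate_sdlog >= 0, "replicate_sdlog: >= 0")
  chk(nb_size > 0, "nb_size: > 0")
  chk(all(pos_control_conc > 0), "pos_control_conc: positive")
  chk(pos_control_slope > 0, "pos_control_slope: > 0")
  chk(n_neg_controls >= 1 && neg_control_lambda >= 0, "negative controls: n >= 1, lambda >= 0")
  chk(n_genes >= 10, "n_genes: >= 10")
  chk(n_sources >= 1, "n_sources: >= 1")
  for (p in c("true_edge_density", "p_true", "p_false", "planted_mirna_density",
              "planted_p_true")) {
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste0(p, ": probability in [0, 1]"))
  }
  for (p in c("score_true", "score_false", "score_planted")) {
    chk(length(cfg[[p]]) == 2 && all(cfg[[p]] > 0), paste0(p, ": Beta(a, b) with a, b > 0"))
  }
  chk(n_terms >= 1, "n_terms: >= 1")
  chk(length(term_size) == 2 && term_size[1] >= 1 && term_size[2] <= n_genes &&
        term_size[1] <= term_size[2], "term_size: range within [1, n_genes]")
  chk(planted_term_size >= 1 && planted_term_size <= n_genes,
      "planted_term_size: within [1, n_genes]")
  chk(length(planted_terms) == 0 ||
        all(planted_terms %in% c("null", "moderate", "strong")),
      "planted_terms: effects in {null, moderate, strong}")
  chk(n_dominant >= 1 && n_dominant < n_mirnas, "n_dominant: in [1, n_mirnas)")
  if (length(problems) > 0) {
    abort(paste0("Invalid sim_config:\n", paste("-", problems, collapse = "\n")))
  }
  structure(cfg, class = "sim_config")
}

sim_mirna_ids <- function(n) sprintf("hsa-miR-%04d", seq_len(n))
sim_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate an nCounter-style count matrix
#'
#' Draws true per-miRNA abundances from the configured log-normal, applies a
#' uniform multiplicative lane effect per sample and log-normal per-replicate
#' noise per probe, and adds negative-binomial counting noise. Positive
#' controls follow `slope * concentration * lane_effect` with the same noise
#' model; negative controls are Poisson. Deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (a `count_matrix` with replicate groups set)
#'   and `truth` (list: `abundance` tibble, `dominant` miRNA ids, the
#'   `planted_mirna`, per-sample `lane_effects`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 1), {
    mirnas <- sim_mirna_ids(cfg$n_mirnas)
    abundance <- stats::qlnorm(stats::ppoints(cfg$n_mirnas),
                               cfg$abundance_meanlog, cfg$abundance_sdlog) *
      rlnorm(cfg$n_mirnas, 0, cfg$abundance_jitter_sdlog)
    samples <- unlist(lapply(names(cfg$replicates), function(g) {
      paste0(g, "_", seq_len(cfg$replicates[[g]]))
    }))
    groups <- setNames(rep(names(cfg$replicates), cfg$replicates), samples)
    lanes <- setNames(
      runif(length(samples), cfg$lane_effect_range[1], cfg$lane_effect_range[2]),
      samples
    )

    n_pos <- length(cfg$pos_control_conc)
    tab <- tibble(
      probe_id = c(
        mirnas,
        paste0("POS_", LETTERS[seq_len(n_pos)]),
        sprintf("NEG_%02d", seq_len(cfg$n_neg_controls))
      ),
      probe_class = rep(c("endogenous", "positive", "negative"),
                        c(cfg$n_mirnas, n_pos, cfg$n_neg_controls)),
      expected_conc = c(rep(NA_real_, cfg$n_mirnas), cfg$pos_control_conc,
                        rep(NA_real_, cfg$n_neg_controls))
    )
    for (s in samples) {
      mu_endo <- abundance * lanes[[s]] *
        rlnorm(cfg$n_mirnas, 0, cfg$replicate_sdlog)
      mu_pos <- cfg$pos_control_slope * cfg$pos_control_conc * lanes[[s]]
      tab[[s]] <- c(
        rnbinom(cfg$n_mirnas, mu = mu_endo, size = cfg$nb_size),
        rnbinom(n_pos, mu = mu_pos, size = cfg$nb_size),
        rpois(cfg$n_neg_controls, cfg$neg_control_lambda)
      )
    }

    ord <- order(-abundance, mirnas)
    dominant <- mirnas[ord][seq_len(cfg$n_dominant)]
    list(
      counts = as_count_matrix(tab, replicate_groups = groups),
      truth = list(
        abundance = tibble(mirna = mirnas, abundance = abundance),
        dominant = dominant,
        planted_mirna = cfg$planted_mirna %||% dominant[1],
        lane_effects = as.list(lanes)
      )
    )
  })
}

#' Simulate a multi-source target-prediction database
#'
#' Plants a set of true (miRNA, gene) relations — at elevated density and
#' per-source sensitivity for the designated pro-angiogenic miRNA — and emits
#' per-source prediction records: true edges appear in each source with
#' probability `p_true` (`planted_p_true` for the planted miRNA) and carry
#' high Beta scores; false edges appear with probability `p_false` and carry
#' low scores. Support counts of true edges therefore stochastically dominate
#' those of false edges.
#'
#' @param cfg A [sim_config()].
#' @param mirnas Character vector of miRNAs the database covers.
#' @param genes Gene universe; defaults to the configured synthetic universe.
#' @param planted_mirna Overrides `cfg$planted_mirna` (e.g. the ground-truth
#'   dominant miRNA from [simulate_counts()]).
#' @return List with `targets` (tibble `source`, `mirna`, `gene`, `score`)
#'   and `truth` (list: `true_edges` tibble, `planted_mirna`, `genes`).
#' @export
simulate_target_db <- function(cfg, mirnas, genes = NULL, planted_mirna = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- genes %||% sim_gene_ids(cfg$n_genes)
  planted <- planted_mirna %||% cfg$planted_mirna
  with_seed(derive_seed(cfg$seed, 2), {
    grid <- tidyr::expand_grid(mirna = mirnas, gene = genes)
    is_planted <- !is.null(planted) &
      canonical_mirna(grid$mirna) == canonical_mirna(planted %||% "")
    dens <- ifelse(is_planted, cfg$planted_mirna_density, cfg$true_edge_density)
    grid$true <- runif(nrow(grid)) < dens
    sens <- ifelse(is_planted, cfg$planted_p_true, cfg$p_true)

    sources <- sprintf("source_%02d", seq_len(cfg$n_sources))
    rows <- lapply(sources, function(src) {
      incl <- runif(nrow(grid)) < ifelse(grid$true, sens, cfg$p_false)
      d <- grid[incl, c("mirna", "gene", "true")]
      pl <- is_planted[incl]
      a <- ifelse(d$true, ifelse(pl, cfg$score_planted[1], cfg$score_true[1]),
                  cfg$score_false[1])
      b <- ifelse(d$true, ifelse(pl, cfg$score_planted[2], cfg$score_true[2]),
                  cfg$score_false[2])
      tibble(source = src, mirna = d$mirna, gene = d$gene,
             score = round(rbeta(nrow(d), a, b), 6))
    })
    targets <- dplyr::bind_rows(rows) |>
      dplyr::arrange(.data$source, .data$mirna, .data$gene)
    list(
      targets = targets,
      truth = list(
        true_edges = as_tibble(grid[grid$true, c("mirna", "gene")]),
        planted_mirna = planted,
        genes = genes
      )
    )
  })
}

#' Simulate annotation terms with planted enrichment
#'
#' Null terms draw genes uniformly from the universe. Planted terms draw a
#' fraction of their genes from true targets of the selected miRNAs — 50%
#' for `"moderate"` effects (union of selected-miRNA targets), 85% for
#' `"strong"` effects (targets of the planted pro-angiogenic miRNA when one
#' is designated) — and the remainder uniformly.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene universe.
#' @param true_edges Tibble `mirna`, `gene` of ground-truth relations (from
#'   [simulate_target_db()]).
#' @param selected Character vector of selected cargo miRNAs.
#' @param planted_mirna Overrides `cfg$planted_mirna`.
#' @return List with `annotations` (an `annotation_set`) and `truth` (tibble
#'   `term_id`, `term_name`, `effect` for planted terms).
#' @export
simulate_annotations <- function(cfg, genes, true_edges, selected,
                                 planted_mirna = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (max(cfg$term_size[2], cfg$planted_term_size) > length(genes)) {
    abort("Term size exceeds the gene universe.")
  }
  planted <- planted_mirna %||% cfg$planted_mirna
  sel_keys <- canonical_mirna(selected)
  union_pool <- sort(unique(
    true_edges$gene[canonical_mirna(true_edges$mirna) %in% sel_keys]
  ))
  planted_pool <- if (!is.null(planted)) {
    sort(unique(true_edges$gene[
      canonical_mirna(true_edges$mirna) == canonical_mirna(planted)
    ]))
  } else {
    union_pool
  }

  with_seed(derive_seed(cfg$seed, 3), {
    null_terms <- lapply(seq_len(cfg$n_terms), function(i) {
      size <- sample(cfg$term_size[1]:cfg$term_size[2], 1)
      tibble(
        term_id = sprintf("T%04d", i),
        term_name = sprintf("synthetic process %d", i),
        genes = list(sample(genes, size))
      )
    })
    effects <- cfg$planted_terms
    planted_rows <- lapply(seq_along(effects), function(i) {
      effect <- unname(effects[[i]])
      frac <- switch(effect, null = 0, moderate = 0.5, strong = 0.85)
      pool <- switch(effect, strong = planted_pool, union_pool)
      size <- cfg$planted_term_size
      n_eff <- min(round(frac * size), length(pool))
      eff_genes <- if (n_eff > 0) sample(pool, n_eff) else character()
      rest <- sample(setdiff(genes, eff_genes), size - length(eff_genes))
      tibble(
        term_id = sprintf("P%02d", i),
        term_name = names(effects)[i],
        genes = list(c(eff_genes, rest))
      )
    })
    terms <- dplyr::bind_rows(c(null_terms, planted_rows))
    list(
      annotations = annotation_set(terms),
      truth = tibble(
        term_id = sprintf("P%02d", seq_along(effects)),
        term_name = names(effects),
        effect = unname(unlist(effects)) %||% character()
      )
    )
  })
}

#' Emit a complete synthetic input bundle
#'
#' Runs the three sub-generators and writes the pipeline's input files to a
#' directory: `counts.csv` (the counts-CSV dialect), `targets.tsv` (the
#' multi-source prediction table, covering the ground-truth dominant set plus
#' a margin of tail miRNAs), `annotations.gmt`, and `truth.json` recording
#' the ground truth. Bit-identical for identical (cfg, seed).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the four `paths` and the combined `truth`.
#' @export
simulate_inputs <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim_c <- simulate_counts(cfg)
  mirnas <- sim_c$truth$abundance$mirna
  tail_m <- setdiff(mirnas, sim_c$truth$dominant)
  covered <- sort(c(
    sim_c$truth$dominant,
    tail_m[seq_len(min(30, length(tail_m)))]
  ))
  sim_t <- simulate_target_db(cfg, covered, planted_mirna = sim_c$truth$planted_mirna)
  sim_a <- simulate_annotations(
    cfg, sim_t$truth$genes, sim_t$truth$true_edges,
    selected = sim_c$truth$dominant, planted_mirna = sim_c$truth$planted_mirna
  )

  paths <- list(
    counts = file.path(dir, "counts.csv"),
    targets = file.path(dir, "targets.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_counts(sim_c$counts, paths$counts)
  readr::write_tsv(sim_t$targets, paths$targets)
  write_gmt(sim_a$annotations, paths$gmt)
  truth <- list(
    dominant = sim_c$truth$dominant,
    planted_mirna = sim_c$truth$planted_mirna,
    replicate_groups = as.list(replicate_groups(sim_c$counts)),
    true_edges = sim_t$truth$true_edges,
    planted_terms = sim_a$truth,
    lane_effects = sim_c$truth$lane_effects
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}
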