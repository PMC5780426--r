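#' Positive-control normalization
#'
#' Scales every sample by the spiked positive-control probes to remove
#' lane-to-lane hybridization efficiency differences. For each sample the
#' geometric mean of its positive-control counts is computed; the sample's
#' scale factor is the across-sample mean of these geometric means divided by
#' its own, so the factors average to one and a single-sample run is left
#' untouched.
#'
#' @param cm A `count_matrix` (see [read_counts()]).
#' @param mean_type How the across-sample reference is summarized:
#'   `"arithmetic"` (default) or `"geometric"`.
#' @param pseudocount Value substituted for zero positive-control counts
#'   before the geometric mean (default 0.5).
#' @return A list with `values` (the count table with every sample column
#'   scaled) and `factors`, a tibble with columns `sample`, `geomean`,
#'   `factor`.
#' @export
positive_control_normalize <- function(cm, mean_type = c("arithmetic", "geometric"),
                                       pseudocount = 0.5) {
  mean_type <- match.arg(mean_type)
  samples <- sample_ids(cm)
  pos <- cm$probe_class == "positive"
  geomeans <- vapply(samples, function(s) {
    v <- cm[[s]][pos]
    if (all(v == 0)) {
      abort(sprintf("All positive-control counts are zero in sample '%s'.", s))
    }
    geometric_mean(lift_zeros(v, pseudocount))
  }, numeric(1))
  ref <- switch(mean_type,
    arithmetic = mean(geomeans),
    geometric = geometric_mean(geomeans)
  )
  factors <- ref / geomeans
  values <- cm
  for (s in samples) values[[s]] <- values[[s]] * factors[[s]]
  list(
    values = as_tibble(unclass_cm(values)),
    factors = tibble(sample = samples, geomean = unname(geomeans), factor = unname(factors))
  )
}

#' Negative-control background thresholding
#'
#' Uses the spiked negative-control probes of each sample to estimate its
#' background level, `mean + k_sd * sd` of the negative counts (sample
#' standard deviation; zero when only one negative probe is present).
#' Endogenous and housekeeping values at or below the threshold are set to
#' zero (`mode = "floor"`, the default) or have the threshold subtracted with
#' clamping at zero (`mode = "subtract"`). Control probes are not modified.
#'
#' @param values Wide probe-by-sample table carrying a `probe_class` column,
#'   e.g. the `values` element of [positive_control_normalize()].
#' @param k_sd Multiplier on the negative-control standard deviation
#'   (default 2, the conventional background cut).
#' @param mode `"floor"` or `"subtract"`.
#' @return A list with `values` (thresholded table) and `thresholds`, a tibble
#'   with columns `sample`, `threshold`.
#' @export
background_threshold <- function(values, k_sd = 2, mode = c("floor", "subtract")) {
  mode <- match.arg(mode)
  check_number(k_sd, "k_sd", lower = 0)
  samples <- sample_ids(values)
  neg <- values$probe_class == "negative"
  if (!any(neg)) abort("No negative-control probes in table.")
  target <- values$probe_class %in% c("endogenous", "housekeeping")
  thresholds <- vapply(samples, function(s) {
    v <- values[[s]][neg]
    s_d <- if (length(v) > 1) sd(v) else 0
    mean(v) + k_sd * s_d
  }, numeric(1))
  out <- values
  for (s in samples) {
    v <- out[[s]]
    if (mode == "floor") {
      v[target & v <= thresholds[[s]]] <- 0
    } else {
      v[target] <- pmax(v[target] - thresholds[[s]], 0)
    }
    out[[s]] <- v
  }
  list(
    values = out,
    thresholds = tibble(sample = samples, threshold = unname(thresholds))
  )
}

#' Content (top-N) normalization
#'
#' Secondary scaling by the most abundant endogenous probes (by convention the
#' top 100) to remove input-amount differences between samples. The top-N
#' probe set is chosen once, by mean abundance across samples, so the same
#' probes anchor every sample's factor; per sample the factor is the
#' across-sample mean of the anchor-set geometric means divided by the
#' sample's own anchor geometric mean.
#'
#' @param values Wide probe-by-sample table with a `probe_class` column.
#' @param top_n Number of anchor probes (default 100). When fewer endogenous
#'   probes are available, all are used with a warning.
#' @param pseudocount Zero-lift for the geometric means (default 0.5).
#' @return A list with `values` (scaled table), `factors` (tibble `sample`,
#'   `factor`) and `anchor_probes` (character vector of the probes used).
#' @export
content_normalize <- function(values, top_n = 100, pseudocount = 0.5) {
  check_number(top_n, "top_n", lower = 1)
  samples <- sample_ids(values)
  endo <- values$probe_class == "endogenous"
  if (!any(endo)) abort("No endogenous probes in table.")
  mat <- as.matrix(values[endo, samples, drop = FALSE])
  rownames(mat) <- values$probe_id[endo]
  zero_samples <- samples[colSums(mat) == 0]
  if (length(zero_samples) > 0) {
    abort(sprintf(
      "All endogenous values are zero in sample(s): %s.",
      paste(zero_samples, collapse = ", ")
    ))
  }
  if (nrow(mat) < top_n) {
    warn(sprintf(
      "Only %d endogenous probes available; using all of them (top_n = %d).",
      nrow(mat), top_n
    ))
    top_n <- nrow(mat)
  }
  ord <- order(-rowMeans(mat), rownames(mat))
  anchors <- rownames(mat)[ord][seq_len(top_n)]
  t_s <- vapply(samples, function(s) {
    geometric_mean(lift_zeros(mat[anchors, s], pseudocount))
  }, numeric(1))
  factors <- mean(t_s) / t_s
  out <- values
  for (s in samples) out[[s]] <- out[[s]] * factors[[s]]
  list(
    values = out,
    factors = tibble(sample = samples, factor = unname(factors)),
    anchor_probes = anchors
  )
}

#' Pearson correlation of within-group replicates
#'
#' Computes the Pearson correlation of normalized endogenous values for every
#' pair of samples sharing a replicate-group label, the standard concordance
#' QC for biological replicates.
#'
#' @param values Wide probe-by-sample table with a `probe_class` column.
#' @param groups Named character vector, sample id -> group label.
#' @return Tibble with columns `group`, `sample_a`, `sample_b`, `pearson_r`.
#'   A zero-variance sample yields `NA` with a warning.
#' @export
replicate_qc <- function(values, groups) {
  samples <- intersect(sample_ids(values), names(groups))
  endo <- values$probe_class == "endogenous"
  res <- list()
  for (g in unique(groups[samples])) {
    members <- samples[groups[samples] == g]
    if (length(members) < 2) next
    pairs <- utils::combn(members, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- values[[pairs[1, j]]][endo]
      b <- values[[pairs[2, j]]][endo]
      r <- if (sd(a) == 0 || sd(b) == 0) {
        warn(sprintf(
          "Zero-variance sample in group '%s' (%s, %s); correlation undefined.",
          g, pairs[1, j], pairs[2, j]
        ))
        NA_real_
      } else {
        cor(a, b)
      }
      res[[length(res) + 1]] <- tibble(
        group = g, sample_a = pairs[1, j], sample_b = pairs[2, j], pearson_r = r
      )
    }
  }
  if (length(res) == 0) {
    return(tibble(
      group = character(), sample_a = character(),
      sample_b = character(), pearson_r = numeric()
    ))
  }
  dplyr::bind_rows(res)
}

#' Merge replicate samples into group profiles
#'
#' Averages normalized values per probe across the samples of each replicate
#' group; single-sample groups pass through unchanged.
#'
#' @inheritParams replicate_qc
#' @return Wide probe-by-group table (metadata columns preserved).
#' @export
merge_replicates <- function(values, groups) {
  samples <- sample_ids(values)
  unknown <- setdiff(samples, names(groups))
  if (length(unknown) > 0) {
    groups <- c(groups, setNames(unknown, unknown))
  }
  empty <- setdiff(unique(groups), groups[samples])
  if (length(empty) > 0) {
    abort(sprintf("Replicate group(s) with no samples: %s.", paste(empty, collapse = ", ")))
  }
  meta <- values[intersect(c("probe_id", "probe_class", "expected_conc"), names(values))]
  out <- meta
  for (g in unique(unname(groups[samples]))) {
    members <- samples[groups[samples] == g]
    out[[g]] <- rowMeans(as.matrix(values[members]))
  }
  as_tibble(out)
}

#' Full nCounter normalization pipeline
#'
#' Runs the three normalization stages in the conventional order —
#' positive-control scaling, negative-control background thresholding, then
#' top-N content normalization — followed by replicate QC and replicate
#' merging, and derives per-sample endogenous shares.
#'
#' @param cm A `count_matrix`.
#' @param k_sd Background threshold multiplier (see [background_threshold()]).
#' @param background_mode `"floor"` or `"subtract"`.
#' @param top_n Content-normalization anchor-set size.
#' @param pseudocount Zero-lift used in all geometric means.
#' @param mean_type Positive-control reference mean (see
#'   [positive_control_normalize()]).
#' @param groups Replicate-group mapping; defaults to the one stored on `cm`.
#' @return A `normalized_profile` object: a list with wide tibbles `values`
#'   (all probes, per sample), `shares` (endogenous, per sample; columns sum
#'   to 1), `merged` and `merged_shares` (per replicate group), plus
#'   `thresholds`, `factors` (positive-control and content factors per
#'   sample), `qc` (replicate Pearson correlations) and `params`.
#' @examples
#' cfg <- sim_config(seed = 1, n_mirnas = 60, n_terms = 10)
#' cm <- simulate_counts(cfg)$counts
#' np <- normalize_counts(cm)
#' glance(np)
#' @export
normalize_counts <- function(cm, k_sd = 2, background_mode = c("floor", "subtract"),
                             top_n = 100, pseudocount = 0.5,
                             mean_type = c("arithmetic", "geometric"),
                             groups = NULL) {
  background_mode <- match.arg(background_mode)
  mean_type <- match.arg(mean_type)
  groups <- groups %||% replicate_groups(cm)

  pos <- positive_control_normalize(cm, mean_type = mean_type, pseudocount = pseudocount)
  bg <- background_threshold(pos$values, k_sd = k_sd, mode = background_mode)
  cont <- content_normalize(bg$values, top_n = top_n, pseudocount = pseudocount)

  values <- cont$values
  samples <- sample_ids(values)
  shares <- to_shares(values, samples)
  merged <- merge_replicates(values, groups)
  merged_shares <- to_shares(merged, setdiff(names(merged), c("probe_id", "probe_class", "expected_conc")))

  structure(
    list(
      values = values,
      shares = shares,
      merged = merged,
      merged_shares = merged_shares,
      thresholds = bg$thresholds,
      factors = dplyr::full_join(
        dplyr::rename(pos$factors, pos_factor = "factor"),
        dplyr::rename(cont$factors, content_factor = "factor"),
        by = "sample"
      ),
      qc = replicate_qc(values, groups),
      params = list(
        k_sd = k_sd, background_mode = background_mode, top_n = top_n,
        pseudocount = pseudocount, mean_type = mean_type,
        groups = as.list(groups), anchor_probes = cont$anchor_probes
      )
    ),
    class = "normalized_profile"
  )
}

to_shares <- function(values, cols) {
  endo <- values$probe_class == "endogenous"
  out <- values[endo, c("probe_id", cols)]
  for (s in cols) {
    tot <- sum(out[[s]])
    out[[s]] <- if (tot > 0) out[[s]] / tot else out[[s]]
  }
  out
}

lift_zeros <- function(x, pseudocount) {
  x[x == 0] <- pseudocount
  x
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf(
    "<normalized_profile> %d probes x %d samples, %d replicate group(s)\n",
    nrow(x$values), nrow(x$factors), length(unique(unlist(x$params$groups)))
  ))
  if (nrow(x$qc) > 0) {
    cat(sprintf(
      "  replicate Pearson r: %s\n",
      paste(sprintf("%.3f", x$qc$pearson_r), collapse = ", ")
    ))
  }
  invisible(x)
}

#' @describeIn normalize_counts Long tibble of normalized endogenous values
#'   and shares, one row per probe and sample.
#' @param x A `normalized_profile`.
#' @param ... Unused.
#' @export
tidy.normalized_profile <- function(x, ...) {
  vals <- x$values[x$values$probe_class == "endogenous",
                   c("probe_id", sample_ids(x$values))]
  long_v <- tidyr::pivot_longer(vals, -"probe_id",
                                names_to = "sample", values_to = "value")
  long_s <- tidyr::pivot_longer(x$shares, -"probe_id",
                                names_to = "sample", values_to = "share")
  dplyr::left_join(long_v, long_s, by = c("probe_id", "sample"))
}

#' @describeIn normalize_counts One-row summary: probe/sample counts, factor
#'   ranges, mean replicate correlation.
#' @export
glance.normalized_profile <- function(x, ...) {
  tibble(
    n_probes = nrow(x$values),
    n_endogenous = sum(x$values$probe_class == "endogenous"),
    n_samples = nrow(x$factors),
    n_groups = length(unique(unlist(x$params$groups))),
    mean_background_threshold = mean(x$thresholds$threshold),
    mean_replicate_r = if (nrow(x$qc) > 0) mean(x$qc$pearson_r, na.rm = TRUE) else NA_real_
  )
}

#' Rank-abundance plot of a normalized profile
#'
#' Endogenous probes ranked by normalized value within each sample, on a log
#' scale — the standard first look at how top-heavy a cargo profile is.
#'
#' @param object A `normalized_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normalized_profile <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$value > 0) |>
    dplyr::group_by(.data$sample) |>
    dplyr::arrange(dplyr::desc(.data$value), .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot(df, aes(x = .data$rank, y = .data$value, colour = .data$sample)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "Abundance rank", y = "Normalized counts", colour = "Sample") +
    theme_minimal()
}
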