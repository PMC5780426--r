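#' Read an nCounter-style count table
#'
#' Parses the plain-CSV dialect used throughout the pipeline: a header row
#' `probe_id,probe_class,expected_conc,<sample1>,<sample2>,...` followed by one
#' row per probe. `probe_class` is one of `endogenous`, `positive`, `negative`,
#' `housekeeping`; `expected_conc` (fM) is filled for positive-control probes
#' only. The result is a wide tibble of class `count_matrix` with one column
#' per sample.
#'
#' Validation is strict: unknown probe classes, duplicated probe ids, missing
#' columns, negative or non-integral counts, and samples lacking positive or
#' negative control probes are all rejected.
#'
#' @param path Path to a CSV file.
#' @param replicate_groups Optional named character vector mapping sample id to
#'   replicate-group label; stored on the object and used by
#'   [normalize_counts()]. Defaults to each sample in its own group.
#' @return A `count_matrix` tibble.
#' @seealso [write_counts()], [normalize_counts()]
#' @export
read_counts <- function(path, replicate_groups = NULL) {
  if (!file.exists(path)) abort(sprintf("Counts file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    probe_class = readr::col_character(),
    expected_conc = readr::col_double(),
    .default = readr::col_double()
  ))
  as_count_matrix(raw, replicate_groups = replicate_groups)
}

#' Build a validated count matrix from a data frame
#'
#' @param x Data frame in the wide counts layout (see [read_counts()]).
#' @inheritParams read_counts
#' @return A `count_matrix` tibble.
#' @export
as_count_matrix <- function(x, replicate_groups = NULL) {
  x <- as_tibble(x)
  required <- c("probe_id", "probe_class", "expected_conc")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Counts table is missing required column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  samples <- setdiff(names(x), required)
  if (length(samples) == 0) abort("Counts table has no sample columns.")

  classes <- c("endogenous", "positive", "negative", "housekeeping")
  bad_class <- setdiff(unique(x$probe_class), classes)
  if (length(bad_class) > 0) {
    abort(sprintf(
      "Unknown probe class(es): %s. Allowed: %s.",
      paste(bad_class, collapse = ", "), paste(classes, collapse = ", ")
    ))
  }
  dup <- unique(x$probe_id[duplicated(x$probe_id)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicated probe id(s): %s.", paste(dup, collapse = ", ")))
  }

  counts <- as.matrix(x[samples])
  if (anyNA(counts)) abort("Counts contain missing values.")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (any(abs(counts - round(counts)) > 1e-8)) abort("Counts must be integral.")

  for (cls in c("positive", "negative")) {
    if (!any(x$probe_class == cls)) {
      abort(sprintf("Counts table has no %s-control probes.", cls))
    }
  }

  if (is.null(replicate_groups)) {
    replicate_groups <- setNames(samples, samples)
  } else {
    if (is.null(names(replicate_groups))) {
      abort("`replicate_groups` must be a named vector (names = sample ids).")
    }
    unknown <- setdiff(names(replicate_groups), samples)
    if (length(unknown) > 0) {
      abort(sprintf(
        "`replicate_groups` names not among samples: %s.",
        paste(unknown, collapse = ", ")
      ))
    }
    missing_s <- setdiff(samples, names(replicate_groups))
    replicate_groups <- c(replicate_groups, setNames(missing_s, missing_s))
    replicate_groups <- replicate_groups[samples]
  }

  structure(
    x,
    class = c("count_matrix", class(x)),
    replicate_groups = replicate_groups
  )
}

#' Write a count matrix to CSV
#'
#' Inverse of [read_counts()]: emits the same plain-CSV dialect.
#'
#' @param cm A `count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  readr::write_csv(as_tibble(unclass_cm(cm)), path, na = "")
  invisible(path)
}

#' Sample ids of a count matrix or profile table
#'
#' @param x A `count_matrix` or any wide probe-by-sample tibble with
#'   `probe_id` / `probe_class` metadata columns.
#' @return Character vector of sample column names.
#' @export
sample_ids <- function(x) {
  setdiff(names(x), c("probe_id", "probe_class", "expected_conc"))
}

#' Replicate-group mapping of a count matrix
#'
#' @param cm A `count_matrix`.
#' @return Named character vector, sample id -> group label.
#' @export
replicate_groups <- function(cm) {
  attr(cm, "replicate_groups") %||% setNames(sample_ids(cm), sample_ids(cm))
}

unclass_cm <- function(cm) {
  class(cm) <- setdiff(class(cm), "count_matrix")
  attr(cm, "replicate_groups") <- NULL
  cm
}

#' @export
print.count_matrix <- function(x, ...) {
  samples <- sample_ids(x)
  cat(sprintf(
    "<count_matrix> %d probes x %d samples (%d endogenous, %d positive, %d negative)\n",
    nrow(x), length(samples),
    sum(x$probe_class == "endogenous"),
    sum(x$probe_class == "positive"),
    sum(x$probe_class == "negative")
  ))
  print(as_tibble(unclass_cm(x)), ...)
  invisible(x)
}
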