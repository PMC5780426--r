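#' Geometric mean
#'
#' The geometric mean `exp(mean(log(x)))`, the standard summary for spiked
#' positive-control probe counts on digital hybridization platforms. Zeros are
#' lifted by an additive pseudocount before taking logs; values that remain
#' non-positive are an error, not silently dropped.
#'
#' @param x Numeric vector.
#' @param pseudocount Non-negative value substituted for zero elements before
#'   the log transform (default 0: caller is expected to have handled zeros).
#'   Pipeline callers use 0.5.
#' @return A single positive number.
#' @examples
#' geometric_mean(c(2, 8)) # 4
#' geometric_mean(c(1, 2, 4, 8)) # 2 * sqrt(2)
#' @export
geometric_mean <- function(x, pseudocount = 0) {
  if (length(x) == 0) abort("geometric_mean(): empty input.")
  if (!is.numeric(x) || anyNA(x)) abort("geometric_mean(): input must be numeric without NA.")
  x[x == 0] <- pseudocount
  if (any(x <= 0)) {
    abort("geometric_mean(): non-positive values remain after pseudocount; increase `pseudocount`.")
  }
  exp(mean(log(x)))
}

#' Canonicalize a miRNA identifier
#'
#' Matching between profiled probes and target-database rows ignores the
#' species prefix (`hsa-`) and letter case, so `hsa-miR-130a-3p`,
#' `Hsa-Mir-130A-3P` and `miR-130a-3p` all collapse to one key. No other alias
#' resolution is attempted.
#'
#' @param x Character vector of miRNA names.
#' @return Character vector of canonical keys.
#' @examples
#' canonical_mirna(c("hsa-miR-130a-3p", "MIR-130A-3P"))
#' @export
canonical_mirna <- function(x) {
  tolower(sub("^hsa-", "", x, ignore.case = TRUE))
}

#' Canonicalize a gene symbol
#'
#' Gene identity throughout the pipeline is the uppercased symbol; no alias or
#' orthology mapping is performed.
#'
#' @param x Character vector of gene symbols.
#' @return Uppercased character vector.
#' @export
canonical_gene <- function(x) toupper(trimws(x))

# stopifnot-style scalar checks used across modules
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in %s%s, %s%s.",
      name, if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]"
    ))
  }
  invisible(x)
}

# seed splitting for the simulator: each sub-generator gets its own stream,
# derived deterministically and kept inside 32-bit integer range
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 9973) %% 2147483629
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
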