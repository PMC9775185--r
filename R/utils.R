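# Shared small helpers: seed streams, table-style rounding, partition agreement.

#' Derive independent sub-seeds from one master seed
#'
#' All randomness in the package flows from a single user-supplied seed.
#' Stages and restarts receive sub-seeds drawn once from the master stream,
#' so adding restarts or toggling a pipeline stage never perturbs the
#' randomness of the others.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n, replace = FALSE)
}

#' Round half away from zero
#'
#' Clinical tables round 0.5 up, not to even as [round()] does.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  # small epsilon guards against 24.25 being represented as 24.2499...
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage as printed in characteristics tables
#'
#' Computes `100 * count / total` rounded half-up to one decimal, the
#' rendering used for every count/percent pair in the per-subtype
#' characteristics tables.
#'
#' @param count Non-negative integer count, `count <= total`.
#' @param total Positive integer denominator.
#' @return Percentage rounded to one decimal place.
#' @examples
#' percent(1142, 4632) # 24.7
#' @export
percent <- function(count, total) {
  if (any(total <= 0)) abort("`total` must be positive.")
  if (any(count < 0 | count > total)) abort("`count` must lie in [0, total].")
  round_half_up(100 * count / total, 1)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' to assess recovery of simulated subtype structure. Label values are
#' arbitrary; only the induced partitions matter.
#'
#' @param a,b Label vectors of equal length.
#' @return A number, 1 for identical partitions, about 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# mg/dL per mmol/L conversion factors for thresholds printed in mg/dL
MGDL_PER_MMOL <- c(TG = 88.57, glucose = 18.0, HDL_C = 38.67)

# internal: stop unless all named columns are present and non-missing
check_fields <- function(df, fields, where = "record") {
  missing_cols <- setdiff(fields, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing required field(s): %s",
                  where, paste(missing_cols, collapse = ", ")))
  }
  for (f in fields) {
    bad <- which(is.na(df[[f]]))
    if (length(bad) > 0) {
      ids <- if ("id" %in% names(df)) paste(df$id[head(bad, 3)], collapse = ", ")
             else paste(head(bad, 3), collapse = ", ")
      abort(sprintf("field `%s` has missing values (e.g. id %s)", f, ids))
    }
  }
  invisible(TRUE)
}
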