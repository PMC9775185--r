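# Case-control exome-wide association stage: genotype quality control
# (call rate, Hardy-Weinberg), sample quality control, and per-variant
# additive-model logistic regression with covariate adjustment.

#' One-degree-of-freedom Hardy-Weinberg chi-square test
#'
#' Compares observed genotype counts with the proportions expected from the
#' observed allele frequencies (`p^2`, `2pq`, `q^2`). Monomorphic variants
#' return statistic 0 and p = 1. Vectorised over variants.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return Tibble with columns `chi2`, `p`.
#' @examples
#' hwe_test(25, 50, 25)  # exact equilibrium: chi2 = 0, p = 1
#' hwe_test(50, 0, 50)   # total heterozygote deficit: chi2 = n
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (any(n == 0)) abort("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  eAA <- n * p^2; eAa <- n * 2 * p * q; eaa <- n * q^2
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  chi2 <- term(n_AA, eAA) + term(n_Aa, eAa) + term(n_aa, eaa)
  mono <- p == 0 | q == 0
  chi2[mono] <- 0
  tibble(chi2 = chi2, p = ifelse(mono, 1, pchisq(chi2, df = 1, lower.tail = FALSE)))
}

#' Variant-level quality control
#'
#' Fails variants with call rate below `call_rate_min` (default 99.9%),
#' Hardy-Weinberg deviation at `hwe_alpha` (default 1e-4, computed in
#' controls only when `control_ids` are supplied, the usual practice since
#' true associations distort case genotype proportions), or minor allele
#' frequency below `maf_min` (default 0, i.e. off).
#'
#' @param G n x m genotype matrix of minor-allele counts 0/1/2 with `NA` for
#'   missing; rows named by individual id.
#' @param variants Optional variant metadata tibble with an `id` column
#'   matching `colnames(G)`; carried through to the output.
#' @param call_rate_min,hwe_alpha,maf_min QC thresholds.
#' @param control_ids Individual ids on which to compute the Hardy-Weinberg
#'   test; `NULL` uses all individuals.
#' @return Tibble with one row per variant: id, call_rate, maf, hwe_p,
#'   fail_call_rate, fail_hwe, fail_maf, qc_pass (plus any `variants`
#'   columns).
#' @export
variant_qc <- function(G, variants = NULL, call_rate_min = 0.999,
                       hwe_alpha = 1e-4, maf_min = 0, control_ids = NULL) {
  call_rate <- colMeans(!is.na(G))
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  Gh <- if (!is.null(control_ids)) G[rownames(G) %in% control_ids, , drop = FALSE] else G
  counts <- vapply(seq_len(ncol(Gh)), function(j) {
    g <- Gh[, j]
    c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE), sum(g == 2, na.rm = TRUE))
  }, numeric(3))
  hwe <- hwe_test(counts[1, ], counts[2, ], counts[3, ])
  out <- tibble(id = colnames(G) %||% sprintf("v%d", seq_len(ncol(G))),
                call_rate = unname(call_rate), maf = unname(maf),
                hwe_p = hwe$p,
                fail_call_rate = unname(call_rate) < call_rate_min,
                fail_hwe = hwe$p < hwe_alpha,
                fail_maf = unname(maf) < maf_min) |>
    mutate(qc_pass = !(.data$fail_call_rate | .data$fail_hwe | .data$fail_maf))
  if (!is.null(variants)) out <- left_join(variants, out, by = "id")
  out
}

#' Sample-level quality control
#'
#' Flags individuals with genotype call rate below `call_rate_min` (default
#' 99%) or heterozygosity rate more than `het_sd` standard deviations
#' (default 3) from the sample mean.
#'
#' @inheritParams variant_qc
#' @param het_sd Heterozygosity outlier threshold in standard deviations.
#' @return Tibble: id, call_rate, het_rate, fail_call_rate, fail_het, keep.
#'   Retained ids are `filter(result, keep)$id`.
#' @export
sample_qc <- function(G, call_rate_min = 0.99, het_sd = 3) {
  call_rate <- rowMeans(!is.na(G))
  het_rate <- rowMeans(G == 1, na.rm = TRUE)
  mu <- mean(het_rate); s <- sd(het_rate)
  fail_het <- if (is.na(s) || s == 0) rep(FALSE, nrow(G)) else abs(het_rate - mu) > het_sd * s
  tibble(id = rownames(G) %||% sprintf("i%d", seq_len(nrow(G))),
         call_rate = unname(call_rate), het_rate = unname(het_rate),
         fail_call_rate = unname(call_rate) < call_rate_min,
         fail_het = unname(fail_het)) |>
    mutate(keep = !(.data$fail_call_rate | .data$fail_het))
}

#' Case-control exome-wide association scan
#'
#' For each variant, logistic regression of case status (membership of one
#' metabolic subtype) versus the reference group on the additive allele
#' count plus covariates (by default age, sex and the first three principal
#' components). The counted allele is the minor allele in the analysis
#' sample; when the stored coding counts the major allele the dosage is
#' flipped (and flagged), so reported effects always refer to the minor
#' allele. Missing genotypes are dropped casewise per variant. Variants
#' where the model is not estimable (monomorphic, separated) are returned
#' flagged rather than failing the scan.
#'
#' @param G n x m genotype matrix (minor-allele counts, `NA` missing), rows
#'   named by individual id.
#' @param case_ids,control_ids Individual ids of cases (one subtype) and
#'   controls (reference group).
#' @param covariates Data frame with an `id` column and numeric covariate
#'   columns, or `NULL` for the unadjusted scan.
#' @param variants Optional variant metadata (id, chrom, pos, ref, alt)
#'   joined onto results.
#' @param genome_wide_alpha,suggestive_alpha Significance thresholds for the
#'   flag columns (defaults 7.5e-8 and 5e-5).
#' @return `ewas_result` tibble: one row per variant with n, n_case, beta,
#'   se, or, ci_lo, ci_hi, p, flipped, status, genome_wide, suggestive.
#' @export
run_ewas <- function(G, case_ids, control_ids, covariates = NULL,
                     variants = NULL, genome_wide_alpha = 7.5e-8,
                     suggestive_alpha = 5e-5) {
  ids <- rownames(G)
  if (is.null(ids)) abort("genotype matrix must have individual ids as rownames")
  if (length(intersect(case_ids, control_ids)) > 0) abort("case and control ids overlap")
  keep <- ids %in% c(case_ids, control_ids)
  Gs <- G[keep, , drop = FALSE]
  y <- as.numeric(rownames(Gs) %in% case_ids)
  C <- NULL
  if (!is.null(covariates)) {
    idx <- match(rownames(Gs), covariates$id)
    if (any(is.na(idx))) abort("covariates missing for some case/control ids")
    C <- as.matrix(covariates[idx, setdiff(names(covariates), "id"), drop = FALSE])
  }
  rows <- purrr::map(seq_len(ncol(Gs)), function(j) {
    g <- Gs[, j]
    ok <- !is.na(g)
    gj <- g[ok]; yj <- y[ok]
    flipped <- FALSE
    if (length(gj) > 0 && mean(gj) / 2 > 0.5) {  # anchor to the minor allele
      gj <- 2 - gj
      flipped <- TRUE
    }
    base <- tibble(id = colnames(Gs)[j], n = length(gj), n_case = sum(yj),
                   beta = NA_real_, se = NA_real_, or = NA_real_,
                   ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                   flipped = flipped, status = "non_estimable")
    if (length(unique(gj)) < 2 || length(unique(yj)) < 2) return(base)
    design <- cbind(`(Intercept)` = 1, dosage = gj,
                    if (!is.null(C)) C[ok, , drop = FALSE])
    fit <- tryCatch(fit_logistic(yj, design), error = function(e) NULL)
    if (is.null(fit)) return(base)
    b <- fit$coefficients[["dosage"]]; s <- fit$se[["dosage"]]
    mutate(base, beta = b, se = s, or = exp(b),
           ci_lo = exp(b - 1.96 * s), ci_hi = exp(b + 1.96 * s),
           p = 2 * stats::pnorm(-abs(b / s)), status = "ok")
  })
  out <- list_rbind(rows) |>
    mutate(genome_wide = !is.na(.data$p) & .data$p < genome_wide_alpha,
           suggestive = !is.na(.data$p) & .data$p < suggestive_alpha)
  if (!is.null(variants)) out <- left_join(variants, out, by = "id")
  class(out) <- c("ewas_result", class(out))
  out
}

#' Manhattan-style plot of an association scan
#'
#' @param object An `ewas_result` with `pos` and `p` columns.
#' @param genome_wide_alpha,suggestive_alpha Threshold lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ewas_result <- function(object, genome_wide_alpha = 7.5e-8,
                                 suggestive_alpha = 5e-5, ...) {
  d <- filter(object, !is.na(.data$p))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(genome_wide_alpha),
                        colour = "red", linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(suggestive_alpha),
                        colour = "blue", linetype = 3) +
    ggplot2::labs(x = "position (bp)", y = "-log10 p") +
    ggplot2::theme_minimal()
}
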