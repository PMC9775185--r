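# SNP-to-gene mapping by a base-pair window and hypergeometric gene-set
# enrichment with within-category Bonferroni correction.

#' Map SNPs to genes within a window
#'
#' A SNP at position `x` maps to every gene on the same chromosome whose
#' coding-sequence interval `[start, end]` overlaps `[x - window, x + window]`
#' (closed intervals on both sides, so boundary touching counts; the window
#' is clipped at position 1). The default 50 kb window on each side follows
#' common annotation practice.
#'
#' @param snps Tibble with columns `id`, `chrom`, `pos` (1-based).
#' @param genes Tibble with columns `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive coding-sequence spans).
#' @param window Window size in bp on each side of the SNP.
#' @return Tibble of SNP-gene pairs: snp_id, gene, chrom, gene_start,
#'   gene_end, distance (0 when the SNP lies inside the gene), sorted and
#'   deduplicated. The mapped gene set is `sort(unique(result$gene))`.
#' @examples
#' snps <- tibble::tibble(id = "rs1", chrom = "1", pos = 150000)
#' genes <- tibble::tibble(gene = "G1", chrom = "1", start = 100000, end = 120000)
#' map_snps_to_genes(snps, genes)  # gap 30 kb <= 50 kb: mapped
#' @export
map_snps_to_genes <- function(snps, genes, window = 50000) {
  check_fields(snps, c("id", "chrom", "pos"), "snps")
  check_fields(genes, c("gene", "chrom", "start", "end"), "genes")
  unmatched <- setdiff(unique(as.character(snps$chrom)),
                       unique(as.character(genes$chrom)))
  if (length(unmatched) > 0) {
    abort(sprintf("SNP chromosome(s) absent from the gene annotation: %s",
                  paste(unmatched, collapse = ", ")))
  }
  snp_gr <- GenomicRanges::GRanges(
    seqnames = as.character(snps$chrom),
    ranges = IRanges::IRanges(start = pmax(1, snps$pos - window),
                              end = snps$pos + window))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  tibble(snp_id = snps$id[qi], gene = genes$gene[si],
         chrom = as.character(genes$chrom[si]),
         gene_start = genes$start[si], gene_end = genes$end[si],
         distance = pmax(0, pmax(genes$start[si] - snps$pos[qi],
                                 snps$pos[qi] - genes$end[si]))) |>
    distinct() |>
    arrange(.data$snp_id, .data$gene)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for the overlap `X` between a gene set of size `K` and a
#' mapped-gene list of size `n` drawn without replacement from a universe of
#' `N` genes.
#'
#' @param k Observed overlap.
#' @param K Gene-set size.
#' @param n Mapped-gene count in the universe.
#' @param N Universe size.
#' @return Upper-tail probability; 1 when `k = 0`.
#' @examples
#' hypergeometric_p(4, K = 5, n = 4, N = 10)  # 5 / choose(10, 4)
#' @export
hypergeometric_p <- function(k, K, n, N) {
  bad <- k < 0 | k > pmin(K, n) | K > N | n > N | K < 0 | n < 0
  if (any(bad)) abort("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set over-representation by hypergeometric tests
#'
#' Tests each gene set for over-representation of the mapped genes,
#' correcting with Bonferroni within each category (as ontology categories
#' or tissue panels are corrected separately). Mapped genes outside the
#' universe are dropped with a notice.
#'
#' @param mapped_genes Character vector of gene symbols (e.g.
#'   `unique(map$gene)`).
#' @param collection Tibble with columns `set`, `category` and list-column
#'   `genes` (see [read_gmt()], [generate_gene_sets()]).
#' @param universe Character vector defining the background universe;
#'   default the union of all collection genes. Typically the genes of the
#'   annotation used for mapping.
#' @param alpha Significance level applied to the Bonferroni-adjusted p.
#' @return `enrichment_result` tibble, one row per set, sorted by p within
#'   category: set, category, set_size (K), n_mapped (n), overlap (k),
#'   p_hyper, p_bonferroni, significant.
#' @export
enrich <- function(mapped_genes, collection, universe = NULL, alpha = 0.05) {
  check_fields(collection, c("set", "category"), "collection")
  if (!"genes" %in% names(collection)) abort("collection needs a `genes` list-column")
  universe <- universe %||% sort(unique(unlist(collection$genes)))
  N <- length(universe)
  dropped <- setdiff(mapped_genes, universe)
  if (length(dropped) > 0) {
    inform(sprintf("%d mapped gene(s) outside the universe dropped", length(dropped)))
  }
  mapped <- intersect(unique(mapped_genes), universe)
  if (length(mapped) == 0) {
    inform("no mapped genes in the universe; empty enrichment table")
    return(structure(tibble(set = character(), category = character(),
                            set_size = integer(), n_mapped = integer(),
                            overlap = integer(), p_hyper = numeric(),
                            p_bonferroni = numeric(), significant = logical()),
                     class = c("enrichment_result", class(tibble()))))
  }
  out <- collection |>
    mutate(genes = purrr::map(.data$genes, intersect, y = universe),
           set_size = purrr::map_int(.data$genes, length),
           n_mapped = length(mapped),
           overlap = purrr::map_int(.data$genes, ~ length(intersect(.x, mapped))),
           p_hyper = hypergeometric_p(.data$overlap, .data$set_size,
                                      .data$n_mapped, N)) |>
    group_by(.data$category) |>
    mutate(p_bonferroni = pmin(1, .data$p_hyper * n())) |>
    ungroup() |>
    mutate(significant = .data$p_bonferroni < alpha) |>
    arrange(.data$category, .data$p_hyper) |>
    select("set", "category", "set_size", "n_mapped", "overlap",
           "p_hyper", "p_bonferroni", "significant")
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Text report of the top sets per category
#'
#' @param result An `enrichment_result`.
#' @param top_n Sets to show per category (default 10).
#' @return Character vector of report lines (invisibly printed with `cat`
#'   when `file` is `NULL`).
#' @param file Optional path to write the report to.
#' @export
report_enrichment <- function(result, top_n = 10, file = NULL) {
  lines <- unlist(purrr::map(split(result, result$category), function(d) {
    d <- head(arrange(d, .data$p_hyper), top_n)
    c(sprintf("== %s (top %d) ==", d$category[1], nrow(d)),
      sprintf("%-28s k=%d/%d p=%.3g p_bonf=%.3g%s", d$set, d$overlap,
              d$set_size, d$p_hyper, d$p_bonferroni,
              ifelse(d$significant, " *", "")))
  }), use.names = FALSE)
  if (!is.null(file)) writeLines(lines, file) else cat(lines, sep = "\n")
  invisible(lines)
}

#' Bar chart of top enriched sets per category
#'
#' Shows `-log10` hypergeometric p for the strongest sets in each category,
#' significant sets (Bonferroni within category) filled.
#'
#' @param object An `enrichment_result`.
#' @param top_n Sets per category.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top_n = 10, ...) {
  d <- object |>
    group_by(.data$category) |>
    arrange(.data$p_hyper, .by_group = TRUE) |>
    filter(row_number() <= top_n) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_hyper),
                                  y = stats::reorder(.data$set, -.data$p_hyper),
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = "-log10 p (hypergeometric)", y = NULL, fill = "Bonferroni\nsignificant") +
    ggplot2::theme_minimal()
}
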