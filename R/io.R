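# Readers and writers for the plain-text formats the pipeline exchanges:
# cohort tables and dosage matrices as TSV, genotypes as VCF (via vcfR for
# reading), gene intervals as BED or 1-based TSV, gene sets as GMT.

#' Read and write cohort tables as TSV
#'
#' @param path File path.
#' @return [read_cohort()] returns a tibble.
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_cohort
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' Write genotypes as a VCF with GT fields
#'
#' Emits a minimal VCF 4.2 file with one sample column per individual and
#' unphased GT calls; missing genotypes are written `./.`. Genotype counts
#' refer to the alt allele.
#'
#' @param G n x m matrix of alt-allele counts (`NA` missing), rows named by
#'   individual id.
#' @param variants Tibble with id, chrom, pos, ref, alt.
#' @param path Output path (plain text).
#' @export
write_vcf <- function(G, variants, path) {
  stopifnot(ncol(G) == nrow(variants))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(j) {
    g <- G[, j]
    calls <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(variants$chrom[j], variants$pos[j], variants$id[j],
            variants$ref[j], variants$alt[j], ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF into a dosage matrix
#'
#' Parses the GT field with `vcfR` and returns alt-allele counts; any call
#' containing a missing allele becomes `NA`.
#'
#' @param path VCF path.
#' @return List: `variants` (tibble id, chrom, pos, ref, alt), `genotypes`
#'   (n x m integer matrix, individuals in rows).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || grepl("\\.", x)) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]))
  })
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  variants <- tibble(id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT)
  list(variants = variants, genotypes = t(dosage))
}

#' Write a dosage matrix as TSV
#'
#' First column `id`, one column per variant, `NA` for missing.
#'
#' @inheritParams write_vcf
#' @export
write_dosage_tsv <- function(G, path) {
  df <- bind_cols(tibble(id = rownames(G)), as_tibble(G))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  G <- as.matrix(df[, -1])
  storage.mode(G) <- "integer"
  rownames(G) <- df$id
  G
}

#' Read gene intervals from BED or 1-based TSV
#'
#' BED input (0-based half-open, columns chrom/start/end/name) is converted
#' to 1-based inclusive coordinates; TSV input must already carry columns
#' `gene`, `chrom`, `start`, `end` in 1-based inclusive coordinates.
#'
#' @param path File path.
#' @param format `"bed"` or `"tsv"`; default guessed from the extension.
#' @return Tibble: gene, chrom, start, end.
#' @export
read_gene_intervals <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene"),
                          show_col_types = FALSE, progress = FALSE,
                          comment = "#")
    tibble(gene = df$gene, chrom = as.character(df$chrom),
           start = df$start + 1L, end = df$end)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    check_fields(df, c("gene", "chrom", "start", "end"), "gene interval TSV")
    mutate(df, chrom = as.character(.data$chrom))
  }
}

#' Read gene sets from GMT
#'
#' Tab-delimited lines: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @param category Category label attached to every set in this file
#'   (default the file name without extension), used for within-category
#'   Bonferroni correction.
#' @return Tibble: set, category, description, genes (list column).
#' @export
read_gmt <- function(path, category = NULL) {
  category <- category %||% sub("\\.gmt$", "", basename(path), ignore.case = TRUE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(set = purrr::map_chr(parts, 1),
         category = category,
         description = purrr::map_chr(parts, 2),
         genes = purrr::map(parts, ~ unique(.x[-(1:2)])))
}

#' @rdname read_gmt
#' @param collection Tibble with set, genes (list column) and optionally
#'   description.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    list(collection$set,
         collection$description %||% rep("na", nrow(collection)),
         collection$genes),
    function(s, d, g) paste(c(s, d, g), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write an MFMR model as a structured text file
#'
#' Key-value YAML with K, pi, sigma2, trait and covariate names and the
#' alpha/gamma/beta matrices.
#'
#' @param model An `mfmr_model` (or the `model` element of an `mfmr_fit`).
#' @param path Output path.
#' @export
write_mfmr_model <- function(model, path) {
  if (inherits(model, "mfmr_fit")) model <- model$model
  obj <- list(K = model$K, P = model$P, Q = model$Q, F = model$F,
              trait_names = model$trait_names,
              covariate_names = model$covariate_names,
              pi = as.numeric(model$pi), sigma2 = as.numeric(model$sigma2),
              gamma = apply(model$gamma, 1, as.numeric, simplify = FALSE),
              alpha = if (model$Q > 0) apply(model$alpha, 1, as.numeric, simplify = FALSE),
              beta = if (model$F > 0) as.numeric(model$beta))
  yaml::write_yaml(obj, path)
  invisible(path)
}
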