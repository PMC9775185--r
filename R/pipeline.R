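# End-to-end orchestration: simulate -> phenotype -> cluster -> associate ->
# ewas -> enrich, with a YAML/list config, per-stage seed streams derived
# from one master seed, TSV outputs and a JSON manifest.

#' Default pipeline configuration
#'
#' Returns the configuration list for a fully synthetic run; every entry can
#' be overridden by the `config` argument of [run_pipeline()] (lists are
#' merged recursively). For runs on real data, disable the simulate stage
#' and point `inputs` at a cohort TSV, a VCF (or dosage TSV), a gene
#' interval file and GMT files.
#'
#' @param n_individuals,n_variants Synthetic cohort and genotype sizes.
#' @return Named list of stage toggles and options.
#' @export
default_pipeline_config <- function(n_individuals = 2000, n_variants = 500) {
  list(
    seed = 1,
    stages = list(simulate = TRUE, phenotype = TRUE, cluster = TRUE,
                  associate = TRUE, ewas = TRUE, enrich = TRUE),
    inputs = list(cohort = NULL, vcf = NULL, dosage = NULL, variants = NULL,
                  genes = NULL, gmt = NULL),
    simulate = list(n_individuals = n_individuals, n_variants = n_variants,
                    fraction_causal = 0.01, causal_log_or = 1.0,
                    missing_rate = 5e-4, n_genes = 120),
    cluster = list(k = NULL, k_range = 2:5, n_folds = 5, n_restarts = 5,
                   max_iter = 200, tol = 1e-6),
    associate = list(outcomes = c("chd", "stroke"),
                     adjust = c("age", "sex", "n_components")),
    ewas = list(call_rate_min = 0.999, hwe_alpha = 1e-4,
                sample_call_rate_min = 0.99, het_sd = 3,
                genome_wide_alpha = 7.5e-8, suggestive_alpha = 5e-5),
    enrich = list(window = 50000, alpha = 0.05))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full subtype-discovery pipeline
#'
#' Executes the enabled stages in order -- simulate, phenotype, cluster,
#' associate, ewas, enrich -- writing each stage's outputs as TSV (plus
#' text/YAML side files) into `out_dir` and recording a JSON manifest with
#' the config hash, seed, package and R versions and per-stage row counts.
#' Rerunning with an identical config and seed reproduces the TSV outputs
#' byte for byte.
#'
#' @param config Named list of options, or path to a YAML file; entries
#'   override [default_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  if (!is.null(cfg$cluster$k_range)) cfg$cluster$k_range <- unlist(cfg$cluster$k_range)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(cfg$seed, 6)
  res <- list()
  counts <- list()
  timings <- list()
  stage <- function(name, enabled, fn) {
    if (!isTRUE(enabled)) return(invisible(NULL))
    inform(sprintf("[%s] running", name))
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    out
  }

  # -- simulate ---------------------------------------------------------
  res$simulate <- stage("simulate", cfg$stages$simulate, function() {
    sp <- cfg$simulate
    sc <- generate_cohort(cohort_spec(n_individuals = sp$n_individuals),
                          seed = seeds[1])
    geno <- generate_genotypes(
      genotype_spec(n_variants = sp$n_variants,
                    fraction_causal = sp$fraction_causal,
                    causal_log_or = sp$causal_log_or,
                    missing_rate = sp$missing_rate),
      z_true = sc$z_true, seed = seeds[1], ids = sc$cohort$id)
    genes <- generate_gene_annotation(n_genes = sp$n_genes, seed = seeds[1])
    sets <- generate_gene_sets(genes$gene, seed = seeds[1])
    write_cohort(sc$cohort, file.path(out_dir, "cohort.tsv"))
    readr::write_tsv(tibble(id = sc$cohort$id, z_true = sc$z_true),
                     file.path(out_dir, "latent_labels.tsv"))
    write_vcf(geno$genotypes, geno$variants, file.path(out_dir, "genotypes.vcf"))
    write_dosage_tsv(geno$genotypes, file.path(out_dir, "dosages.tsv"))
    readr::write_tsv(geno$variants, file.path(out_dir, "variants.tsv"))
    readr::write_tsv(genes, file.path(out_dir, "genes.tsv"))
    write_gmt(mutate(sets, description = .data$category),
              file.path(out_dir, "gene_sets.gmt"))
    counts$simulate <<- nrow(sc$cohort)
    list(cohort = sc$cohort, genotypes = geno$genotypes,
         variants = geno$variants, genes = genes, sets = sets)
  })

  cohort <- res$simulate$cohort %||%
    (if (!is.null(cfg$inputs$cohort)) read_cohort(cfg$inputs$cohort))

  # -- phenotype --------------------------------------------------------
  res$phenotype <- stage("phenotype", cfg$stages$phenotype, function() {
    if (is.null(cohort)) abort("no cohort available: enable simulate or set inputs$cohort")
    comp <- classify_components(cohort) |> diagnose_conditions()
    refs <- select_reference(cohort)
    readr::write_tsv(comp, file.path(out_dir, "phenotypes.tsv"))
    readr::write_tsv(tibble(id = refs$reference_ids),
                     file.path(out_dir, "reference_ids.tsv"))
    counts$phenotype <<- nrow(comp)
    list(components = comp, reference = refs)
  })

  # -- cluster ----------------------------------------------------------
  res$cluster <- stage("cluster", cfg$stages$cluster, function() {
    if (is.null(res$phenotype)) abort("cluster stage needs the phenotype stage")
    cl <- cfg$cluster
    refs <- res$phenotype$reference
    sub <- cohort[cohort$id %in% refs$clustering_ids, , drop = FALSE]
    des <- mfmr_design(sub)
    std <- standardize_traits(des$traits)
    ksel <- NULL
    k <- cl$k
    if (is.null(k)) {
      ksel <- select_k(std$traits, des$X, k_range = cl$k_range,
                       n_folds = cl$n_folds, seed = seeds[3],
                       n_restarts = cl$n_restarts, max_iter = cl$max_iter,
                       tol = cl$tol)
      k <- ksel$chosen_k
      readr::write_tsv(ksel$summary, file.path(out_dir, "k_selection.tsv"))
    }
    fit <- fit_mfmr(std$traits, des$X, K = k, n_restarts = cl$n_restarts,
                    max_iter = cl$max_iter, tol = cl$tol, seed = seeds[3])
    asg <- assign_subtypes(fit)
    labels_all <- tibble(id = cohort$id) |>
      left_join(tibble(id = sub$id, label = asg$labels,
                       max_responsibility = apply(asg$responsibilities, 1, max)),
                by = "id") |>
      mutate(label = ifelse(is.na(.data$label), "reference",
                            as.character(.data$label)))
    readr::write_tsv(labels_all, file.path(out_dir, "subtype_labels.tsv"))
    write_mfmr_model(fit, file.path(out_dir, "mfmr_model.yaml"))
    char <- characterize(cohort, labels_all$label)
    readr::write_tsv(char, file.path(out_dir, "characterization.tsv"))
    counts$cluster <<- nrow(sub)
    list(fit = fit, k_selection = ksel, labels = labels_all,
         characterization = char)
  })

  # -- associate --------------------------------------------------------
  res$associate <- stage("associate", cfg$stages$associate, function() {
    if (is.null(res$cluster)) abort("associate stage needs the cluster stage")
    assoc <- purrr::map(cfg$associate$outcomes, function(oc) {
      subtype_outcome_associations(cohort, res$cluster$labels$label,
                                   outcome = oc, adjust = cfg$associate$adjust)
    }) |> list_rbind()
    readr::write_tsv(assoc, file.path(out_dir, "subtype_outcome_associations.tsv"))
    counts$associate <<- nrow(assoc)
    assoc
  })

  # -- ewas -------------------------------------------------------------
  res$ewas <- stage("ewas", cfg$stages$ewas, function() {
    if (is.null(res$cluster)) abort("ewas stage needs the cluster stage")
    G <- res$simulate$genotypes
    variants <- res$simulate$variants
    if (is.null(G)) {
      if (!is.null(cfg$inputs$vcf)) {
        geno <- read_vcf_genotypes(cfg$inputs$vcf)
        G <- geno$genotypes; variants <- geno$variants
      } else if (!is.null(cfg$inputs$dosage)) {
        G <- read_dosage_tsv(cfg$inputs$dosage)
        variants <- readr::read_tsv(cfg$inputs$variants, show_col_types = FALSE)
      } else abort("no genotypes available: enable simulate or set inputs$vcf/dosage")
    }
    ew <- cfg$ewas
    refs <- res$phenotype$reference
    sq <- sample_qc(G, call_rate_min = ew$sample_call_rate_min, het_sd = ew$het_sd)
    keep_ids <- sq$id[sq$keep]
    Gq <- G[rownames(G) %in% keep_ids, , drop = FALSE]
    vq <- variant_qc(Gq, variants, call_rate_min = ew$call_rate_min,
                     hwe_alpha = ew$hwe_alpha,
                     control_ids = refs$reference_ids)
    Gq <- Gq[, vq$qc_pass, drop = FALSE]
    readr::write_tsv(vq, file.path(out_dir, "variant_qc.tsv"))
    readr::write_tsv(sq, file.path(out_dir, "sample_qc.tsv"))
    covars <- tibble(id = cohort$id, age = cohort$age,
                     sex_male = as.numeric(cohort$sex == "male"),
                     pc1 = cohort$pc1, pc2 = cohort$pc2, pc3 = cohort$pc3)
    labels <- res$cluster$labels
    subtypes <- setdiff(sort(unique(labels$label)), "reference")
    scans <- purrr::map(subtypes, function(s) {
      cases <- intersect(labels$id[labels$label == s], keep_ids)
      controls <- intersect(refs$reference_ids, keep_ids)
      run_ewas(Gq, cases, controls, covariates = covars,
               variants = vq[vq$qc_pass, c("id", "chrom", "pos", "ref", "alt")],
               genome_wide_alpha = ew$genome_wide_alpha,
               suggestive_alpha = ew$suggestive_alpha) |>
        mutate(subtype = s, .before = 1)
    }) |> list_rbind()
    plink_like <- scans |>
      select(subtype = "subtype", CHR = "chrom", POS = "pos", ID = "id",
             REF = "ref", ALT = "alt", N = "n", BETA = "beta", SE = "se",
             OR = "or", L95 = "ci_lo", U95 = "ci_hi", P = "p",
             GW_SIG = "genome_wide", SUGGESTIVE = "suggestive")
    readr::write_tsv(plink_like, file.path(out_dir, "ewas.tsv"))
    counts$ewas <<- nrow(scans)
    scans
  })

  # -- enrich -----------------------------------------------------------
  res$enrich <- stage("enrich", cfg$stages$enrich, function() {
    if (is.null(res$ewas)) {
      abort("enrichment needs an EWAS SNP list; enable the ewas stage")
    }
    genes <- res$simulate$genes %||%
      (if (!is.null(cfg$inputs$genes)) read_gene_intervals(cfg$inputs$genes))
    sets <- res$simulate$sets %||%
      (if (!is.null(cfg$inputs$gmt))
        list_rbind(purrr::map(cfg$inputs$gmt, read_gmt)))
    if (is.null(genes) || is.null(sets)) {
      abort("enrichment needs gene intervals and gene sets (simulate stage or inputs)")
    }
    sugg <- filter(res$ewas, .data$suggestive)
    if (nrow(sugg) == 0) {
      inform("no suggestive SNPs; empty enrichment output")
      empty <- enrich(character(0), sets, universe = genes$gene)
      readr::write_tsv(empty, file.path(out_dir, "enrichment.tsv"))
      counts$enrich <<- 0L
      return(empty)
    }
    pairs <- map_snps_to_genes(distinct(sugg, .data$id, .data$chrom, .data$pos),
                               genes, window = cfg$enrich$window)
    er <- enrich(unique(pairs$gene), sets, universe = genes$gene,
                 alpha = cfg$enrich$alpha)
    readr::write_tsv(pairs, file.path(out_dir, "snp_gene_pairs.tsv"))
    readr::write_tsv(er, file.path(out_dir, "enrichment.tsv"))
    report_enrichment(er, file = file.path(out_dir, "enrichment_report.txt"))
    counts$enrich <<- nrow(er)
    er
  })

  cfg_file <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   seed = cfg$seed,
                   package_version = as.character(packageVersion("metsubtype")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   row_counts = counts, stage_seconds = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(res, list(manifest = manifest)))
}
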