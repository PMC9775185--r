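# Synthetic cohort and genotype generators. Defaults emulate a rural Chinese
# community cohort of ~4,600 adults aged 40+ with four metabolic subtypes
# (adiposity-, hypertension-, hyperglycemia- and dyslipidemia-dominant) plus a
# metabolically healthy reference stratum; marginal trait scales follow the
# published per-subtype characteristics of such cohorts.

# Clinical-scale anchors per trait: overall mean/sd define the affine map
# between the standardized generating scale and clinical units; stratum means
# define default subtype effects; subtype sds define default residual spread.
.trait_anchor <- function() {
  tibble::tribble(
    ~trait,   ~mean, ~sd,  ~ref,  ~s1,   ~s2,   ~s3,   ~s4,   ~sd1, ~sd2, ~sd3, ~sd4,
    "BMI",     26.0, 3.4,  23.8,  28.5,  25.9,  26.3,  26.6,  3.2,  3.2,  3.5,  2.9,
    "waist",   83.0, 8.5,  76.0,  90.2,  82.5,  84.4,  84.8,  6.7,  7.8,  8.9,  7.2,
    "SBP",    133.7, 16.5, 119.1, 130.9, 143.7, 133.5, 129.5, 13.3, 15.7, 14.6, 14.4,
    "DBP",     74.9, 9.9,  69.6,  73.6,  79.7,  73.3,  72.9,  8.5,  10.3, 9.3,  8.7,
    "FBG",      6.1, 1.7,   5.3,   5.8,   5.7,   7.4,   6.3,  0.9,  0.8,  2.5,  1.8,
    "PBG2h",    8.4, 3.8,   6.3,   7.5,   7.5,  11.6,   9.1,  2.8,  2.4,  4.9,  4.0,
    "TC",       5.3, 1.0,   4.9,   5.4,   5.4,   5.3,   5.5,  0.9,  1.0,  1.1,  1.1,
    "TG",       1.6, 1.1,   0.9,   1.4,   1.4,   1.4,   2.6,  0.5,  0.8,  0.6,  1.8,
    "HDL_C",    1.4, 0.4,   1.6,   1.4,   1.5,   1.4,   1.2,  0.3,  0.4,  0.4,  0.3,
    "LDL_C",    3.2, 0.8,   2.9,   3.3,   3.3,   3.3,   3.3,  0.8,  0.8,  0.9,  0.9
  )
}

.covariate_names <- c("age_std", "sex_male", "smoking", "drinking",
                      "pc1", "pc2", "pc3",
                      "med_antihypertensive", "med_antidiabetic",
                      "med_lipid_lowering")

# Default homogeneous covariate effects on the standardized trait scale.
# Signs follow ordinary demographic/pharmacological expectations: blood
# pressure and glycaemia rise with age, men carry more central adiposity and
# lower HDL-C, each medication lowers the traits it targets.
.default_alpha <- function(trait_names) {
  Q <- length(.covariate_names)
  alpha <- matrix(0, Q, length(trait_names),
                  dimnames = list(.covariate_names, trait_names))
  alpha["age_std", c("SBP", "DBP", "FBG", "PBG2h", "TC", "LDL_C", "waist")] <-
    c(0.25, 0.05, 0.10, 0.15, 0.10, 0.10, 0.05)
  alpha["sex_male", c("BMI", "waist", "TG", "HDL_C")] <- c(-0.10, 0.20, 0.10, -0.30)
  alpha["smoking", "HDL_C"] <- -0.10
  alpha["drinking", c("TG", "SBP")] <- c(0.10, 0.10)
  alpha["med_antihypertensive", c("SBP", "DBP")] <- c(-0.20, -0.15)
  alpha["med_antidiabetic", c("FBG", "PBG2h")] <- c(-0.20, -0.20)
  alpha["med_lipid_lowering", c("TC", "TG", "LDL_C")] <- c(-0.20, -0.15, -0.20)
  alpha
}

#' Specification of a synthetic metabolic cohort
#'
#' Bundles every parameter of the cohort generator. The defaults emulate a
#' community cohort of 4,632 adults aged 40 and over with a metabolically
#' healthy reference stratum (15.8%) and four metabolic subtypes whose
#' mixing proportions, trait means and spreads follow the per-subtype
#' characteristics table of such a cohort; covariate marginals (mean age
#' 57, 37% male) match the same source.
#'
#' @param n_individuals Cohort size.
#' @param K_true Number of latent metabolic subtypes.
#' @param mixing_weights Probabilities of each subtype among clustered
#'   (non-reference) individuals; must sum to 1.
#' @param reference_frac Probability of the reference-like stratum (latent
#'   label 0), a designated low-mean stratum from which the zero-component
#'   reference group is drawn.
#' @param trait_names Names of the ten metabolic cluster traits.
#' @param gamma_true `K_true x P` matrix of subtype trait means on the
#'   standardized scale. Default derived from clinical per-subtype means via
#'   the trait affine maps.
#' @param gamma_reference Length-`P` trait means of the reference stratum.
#' @param alpha_true `Q x P` matrix of homogeneous covariate effects on the
#'   standardized scale (covariates: age_std, sex_male, smoking, drinking,
#'   pc1-3, three medication flags).
#' @param residual_sd Length-`P` positive residual standard deviations.
#' @param covariate_spec List of covariate marginals: `age_mean`, `age_sd`,
#'   `age_min` (truncation), `p_male`, `p_smoking`, `p_drinking`, `p_med`
#'   (length 3: antihypertensive, antidiabetic, lipid-lowering).
#' @param outcome_model Per-outcome list with `intercept` (reference-stratum
#'   log-odds) and `log_or` (length `K_true` subtype log-odds effects).
#'   `NULL` (default) selects CHD/stroke effects typical of the four-subtype
#'   layout, or null effects for other `K_true`.
#' @param self_report List with `sensitivity` and `false_positive` governing
#'   self-reported disease flags given measured status.
#' @return A validated `cohort_spec` object (a list).
#' @seealso [generate_cohort()], [separated_gamma()]
#' @export
cohort_spec <- function(n_individuals = 4632,
                        K_true = 4,
                        mixing_weights = c(428, 1617, 919, 936) / 3900,
                        reference_frac = 0.158,
                        trait_names = c("BMI", "waist", "SBP", "DBP", "FBG",
                                        "PBG2h", "TC", "TG", "HDL_C", "LDL_C"),
                        gamma_true = NULL,
                        gamma_reference = NULL,
                        alpha_true = NULL,
                        residual_sd = NULL,
                        covariate_spec = list(age_mean = 57, age_sd = 9, age_min = 40,
                                              p_male = 0.37, p_smoking = 0.257,
                                              p_drinking = 0.249,
                                              p_med = c(0.321, 0.116, 0.107)),
                        outcome_model = NULL,
                        self_report = list(sensitivity = 0.6, false_positive = 0.02)) {
  anchor <- .trait_anchor()
  P <- length(trait_names)
  if (is.null(gamma_true) || is.null(gamma_reference) || is.null(residual_sd)) {
    if (!identical(trait_names, anchor$trait)) {
      abort("custom `trait_names` require explicit gamma_true, gamma_reference and residual_sd")
    }
    strata <- as.matrix(anchor[, c("ref", "s1", "s2", "s3", "s4")])
    std <- sweep(sweep(strata, 1, anchor$mean), 1, anchor$sd, "/")
    if (is.null(gamma_true)) {
      if (K_true != 4) abort("default gamma_true requires K_true = 4")
      gamma_true <- t(std[, -1, drop = FALSE])
      dimnames(gamma_true) <- list(NULL, trait_names)
    }
    if (is.null(gamma_reference)) gamma_reference <- setNames(std[, 1], trait_names)
    if (is.null(residual_sd)) {
      residual_sd <- setNames(
        rowMeans(as.matrix(anchor[, c("sd1", "sd2", "sd3", "sd4")])) / anchor$sd,
        trait_names)
    }
  }
  if (is.null(alpha_true)) alpha_true <- .default_alpha(trait_names)
  if (is.null(outcome_model)) {
    # default CHD/stroke subtype effects for the four-subtype layout;
    # other K get null outcome effects unless supplied explicitly
    outcome_model <- if (K_true == 4) {
      list(chd = list(intercept = qlogis(0.015),
                      log_or = log(c(3.461, 4.400, 6.440, 3.700))),
           stroke = list(intercept = qlogis(0.014),
                         log_or = log(c(1.5, 1.4, 2.119, 2.450))))
    } else {
      list(chd = list(intercept = qlogis(0.015), log_or = rep(0, K_true)),
           stroke = list(intercept = qlogis(0.014), log_or = rep(0, K_true)))
    }
  }
  spec <- structure(
    list(n_individuals = n_individuals, K_true = K_true,
         mixing_weights = mixing_weights, reference_frac = reference_frac,
         trait_names = trait_names, gamma_true = gamma_true,
         gamma_reference = gamma_reference, alpha_true = alpha_true,
         residual_sd = residual_sd,
         trait_scale = anchor[match(trait_names, anchor$trait),
                              c("trait", "mean", "sd")],
         covariate_spec = covariate_spec, outcome_model = outcome_model,
         self_report = self_report),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec` to validate.
#' @export
validate_cohort_spec <- function(spec) {
  with(spec, {
    if (!(is.numeric(n_individuals) && n_individuals >= 1))
      abort("invalid `n_individuals`: must be a positive count")
    if (!(is.numeric(K_true) && K_true >= 1))
      abort("invalid `K_true`: must be a positive count")
    if (length(mixing_weights) != K_true || any(mixing_weights <= 0) ||
        abs(sum(mixing_weights) - 1) > 1e-12)
      abort("invalid `mixing_weights`: must be K_true positive values summing to 1")
    if (reference_frac < 0 || reference_frac >= 1)
      abort("invalid `reference_frac`: must lie in [0, 1)")
    P <- length(trait_names)
    if (!all(dim(gamma_true) == c(K_true, P)))
      abort("invalid `gamma_true`: must be K_true x P")
    if (length(gamma_reference) != P)
      abort("invalid `gamma_reference`: must have one entry per trait")
    if (!all(dim(alpha_true) == c(length(.covariate_names), P)))
      abort("invalid `alpha_true`: must be Q x P with Q = 10 covariates")
    if (length(residual_sd) != P || any(residual_sd <= 0))
      abort("invalid `residual_sd`: must be P strictly positive values")
    for (nm in names(outcome_model)) {
      om <- outcome_model[[nm]]
      if (length(om$log_or) != K_true)
        abort(sprintf("invalid `outcome_model$%s`: log_or must have length K_true", nm))
    }
  })
  invisible(spec)
}

#' Well-separated subtype trait means for recovery studies
#'
#' Builds a `K x P` standardized trait-mean matrix in which each subtype
#' elevates its own block of traits by `gap` residual standard deviations,
#' mimicking dominance of a distinct trait group per subtype (adiposity,
#' blood pressure, glycaemia, lipids for the default K = 4, P = 10 layout).
#'
#' @param K Number of subtypes.
#' @param P Number of traits (default 10).
#' @param gap Separation between dominant and background means, in residual
#'   standard deviations.
#' @return `K x P` matrix with pairwise row distances of at least `gap`.
#' @export
separated_gamma <- function(K = 4, P = 10, gap = 3) {
  gamma <- matrix(0, K, P)
  for (k in seq_len(K)) {
    block <- seq.int(from = k, to = P, by = K)
    gamma[k, block] <- gap
  }
  gamma
}

#' Generate a synthetic metabolic cohort
#'
#' Draws latent stratum labels (0 = reference-like, 1..K subtypes), covariates,
#' standardized traits from the mixture-of-regressions generating model
#' `y_ip = X_i alpha[, p] + gamma[z_i, p] + e_ip`, with `e_ip ~ N(0,
#' residual_sd[p]^2)` independent across traits, then converts traits to
#' clinical units via each trait's fixed affine map and draws binary disease
#' outcomes from a per-outcome logistic model on the latent label. Clinical
#' values are floored at 0.01 so physiologic fields stay positive; the exact
#' pre-floor standardized traits are kept alongside.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   byte-for-byte.
#' @return A `synthetic_cohort`: list with `cohort` (clinical-unit tibble, one
#'   row per individual), `traits_std` (tibble of exact standardized traits),
#'   `z_true` (latent labels, 0 = reference stratum), `seed`, `spec`.
#' @examples
#' sc <- generate_cohort(cohort_spec(n_individuals = 200), seed = 1)
#' table(sc$z_true)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  validate_cohort_spec(spec)
  set.seed(as.integer(seed))
  n <- spec$n_individuals
  K <- spec$K_true
  P <- length(spec$trait_names)
  cs <- spec$covariate_spec

  z <- sample(0:K, n, replace = TRUE,
              prob = c(spec$reference_frac, (1 - spec$reference_frac) * spec$mixing_weights))

  # age: normal truncated below at age_min
  lo <- stats::pnorm(cs$age_min, cs$age_mean, cs$age_sd)
  age <- stats::qnorm(runif(n, lo, 1), cs$age_mean, cs$age_sd)
  sex <- ifelse(rbinom(n, 1, cs$p_male) == 1, "male", "female")
  smoking <- rbinom(n, 1, cs$p_smoking)
  drinking <- rbinom(n, 1, cs$p_drinking)
  pcs <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("pc1", "pc2", "pc3")))
  med <- sapply(cs$p_med, function(p) rbinom(n, 1, p))
  colnames(med) <- c("med_antihypertensive", "med_antidiabetic", "med_lipid_lowering")

  X <- cbind(age_std = (age - cs$age_mean) / cs$age_sd,
             sex_male = as.numeric(sex == "male"),
             smoking = smoking, drinking = drinking, pcs, med)
  X <- X[, .covariate_names, drop = FALSE]

  gamma_full <- rbind(spec$gamma_reference, spec$gamma_true)  # row z+1
  eps <- matrix(rnorm(n * P), n, P) %*% diag(spec$residual_sd, P)
  Ystd <- X %*% spec$alpha_true + gamma_full[z + 1L, , drop = FALSE] + eps
  colnames(Ystd) <- spec$trait_names

  sc_mean <- spec$trait_scale$mean
  sc_sd <- spec$trait_scale$sd
  Yclin <- sweep(sweep(Ystd, 2, sc_sd, "*"), 2, sc_mean, "+")
  Yclin <- pmax(Yclin, 0.01)

  # outcomes from the latent-label logistic model (effect 0 for stratum 0)
  draw_outcome <- function(om) {
    eta <- om$intercept + c(0, om$log_or)[z + 1L]
    rbinom(n, 1, plogis(eta))
  }
  chd <- draw_outcome(spec$outcome_model$chd)
  stroke <- draw_outcome(spec$outcome_model$stroke)

  # self-reported history: noisy reflection of measured status
  sr <- function(measured) {
    as.integer(ifelse(measured,
                      rbinom(n, 1, spec$self_report$sensitivity),
                      rbinom(n, 1, spec$self_report$false_positive)))
  }
  clin <- as_tibble(Yclin)
  self_hypertension <- sr(clin$SBP >= 140 | clin$DBP >= 90)
  self_t2d <- sr(clin$FBG >= 7.0 | clin$PBG2h >= 11.1)
  self_hyperlipidemia <- sr(clin$TC >= 5.18 | clin$TG >= 1.7 | clin$LDL_C >= 3.37)

  cohort <- bind_cols(
    tibble(id = sprintf("S%05d", seq_len(n)), age = age, sex = sex,
           smoking = smoking, drinking = drinking),
    as_tibble(med), as_tibble(pcs), clin,
    tibble(self_hypertension = self_hypertension, self_t2d = self_t2d,
           self_hyperlipidemia = self_hyperlipidemia,
           chd = chd, stroke = stroke))

  structure(list(cohort = cohort,
                 traits_std = bind_cols(tibble(id = cohort$id), as_tibble(Ystd)),
                 z_true = z, seed = as.integer(seed), spec = spec),
            class = "synthetic_cohort")
}

#' @method print synthetic_cohort
#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d subtypes + reference stratum (seed %d)\n",
              nrow(x$cohort), x$spec$K_true, x$seed))
  print(table(latent_label = x$z_true))
  invisible(x)
}

#' Specification of synthetic biallelic genotypes
#'
#' @param n_variants Number of variants to simulate.
#' @param maf_range Interval within (0, 0.5] from which each variant's minor
#'   allele frequency is drawn uniformly.
#' @param fraction_causal Probability that a variant is associated with the
#'   designated subtype.
#' @param causal_log_or Per-allele log odds of membership in the designated
#'   subtype versus everyone else; the subtype's allele frequency is shifted
#'   on the logit scale by this amount.
#' @param missing_rate Per-entry probability of a missing genotype call.
#' @param chrom_length Chromosome length for position sampling.
#' @param chrom Chromosome name.
#' @param causal_subtype Latent label enriched at causal variants; default the
#'   highest subtype label.
#' @return A validated `genotype_spec` object.
#' @export
genotype_spec <- function(n_variants = 500, maf_range = c(0.05, 0.5),
                          fraction_causal = 0.01, causal_log_or = 1.0,
                          missing_rate = 0.0005, chrom_length = 5e7,
                          chrom = "1", causal_subtype = NULL) {
  if (n_variants < 1) abort("invalid `n_variants`: must be a positive count")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    abort("invalid `maf_range`: must be an ordered interval within (0, 0.5]")
  for (p in c(fraction_causal, missing_rate)) {
    if (p < 0 || p > 1) abort("invalid probability: `fraction_causal` and `missing_rate` must lie in [0,1]")
  }
  if (chrom_length < n_variants) abort("invalid `chrom_length`: too short for n_variants distinct positions")
  structure(list(n_variants = as.integer(n_variants), maf_range = maf_range,
                 fraction_causal = fraction_causal, causal_log_or = causal_log_or,
                 missing_rate = missing_rate, chrom_length = chrom_length,
                 chrom = chrom, causal_subtype = causal_subtype),
            class = "genotype_spec")
}

#' Generate synthetic biallelic genotypes tied to latent subtypes
#'
#' Non-causal variants are drawn in Hardy-Weinberg proportions at a minor
#' allele frequency sampled from `maf_range`, independent of the labels.
#' Causal variants shift the allele frequency of the designated subtype on
#' the logit scale by `causal_log_or`, so a case-control logistic regression
#' of that subtype versus the rest has true per-allele log odds ratio equal
#' to `causal_log_or`. Missing calls are inserted at `missing_rate` and coded
#' `NA`.
#'
#' @param spec A [genotype_spec()].
#' @param z_true Latent label vector (0 allowed for the reference stratum).
#' @param seed Integer seed.
#' @param ids Optional individual ids for genotype row names.
#' @return List with `variants` (tibble: id, chrom, pos, ref, alt, maf_true,
#'   is_causal, causal_subtype) and `genotypes` (n x m integer matrix of
#'   minor-allele counts with `NA` for missing).
#' @export
generate_genotypes <- function(spec = genotype_spec(), z_true, seed = 1, ids = NULL) {
  if (length(z_true) == 0) abort("`z_true` must be nonempty")
  set.seed(as.integer(seed))
  n <- length(z_true)
  m <- spec$n_variants
  causal_subtype <- spec$causal_subtype %||% max(z_true)

  pos <- sort(sample.int(spec$chrom_length, m))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
  is_causal <- rbinom(m, 1, spec$fraction_causal) == 1

  in_sub <- z_true == causal_subtype
  G <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    if (is_causal[j]) {
      f1 <- plogis(qlogis(maf[j]) + spec$causal_log_or)
      g <- integer(n)
      g[in_sub] <- rbinom(sum(in_sub), 2, f1)
      g[!in_sub] <- rbinom(sum(!in_sub), 2, maf[j])
      G[, j] <- g
    } else {
      G[, j] <- rbinom(n, 2, maf[j])
    }
  }
  if (spec$missing_rate > 0) {
    G[matrix(rbinom(n * m, 1, spec$missing_rate) == 1, n, m)] <- NA_integer_
  }
  rownames(G) <- ids %||% sprintf("S%05d", seq_len(n))
  variant_ids <- sprintf("snp%05d", seq_len(m))
  colnames(G) <- variant_ids

  list(variants = tibble(id = variant_ids, chrom = spec$chrom, pos = pos,
                         ref = ref, alt = alt, maf_true = maf,
                         is_causal = is_causal,
                         causal_subtype = ifelse(is_causal, causal_subtype, NA_integer_)),
       genotypes = G)
}

#' Generate a toy gene annotation along one chromosome
#'
#' Non-overlapping coding-sequence intervals for exercising SNP-to-gene
#' mapping and enrichment end to end on synthetic data.
#'
#' @param n_genes Number of genes.
#' @param chrom_length,chrom Chromosome to populate.
#' @param length_range Range of gene lengths in bp.
#' @param seed Integer seed.
#' @return Tibble: gene, chrom, start, end (1-based inclusive).
#' @export
generate_gene_annotation <- function(n_genes = 120, chrom_length = 5e7,
                                     chrom = "1", length_range = c(5e3, 5e4),
                                     seed = 1) {
  set.seed(as.integer(seed))
  len <- round(runif(n_genes, length_range[1], length_range[2]))
  gap <- floor(chrom_length / n_genes)
  if (gap <= max(len)) abort("chromosome too short for non-overlapping genes")
  start <- (seq_len(n_genes) - 1L) * gap +
    round(runif(n_genes, 1, pmax(1, gap - len)))
  tibble(gene = sprintf("GENE%03d", seq_len(n_genes)), chrom = chrom,
         start = as.integer(start), end = as.integer(start + len - 1))
}

#' Generate toy gene-set collections
#'
#' Random gene sets over a gene universe, grouped into ontology-like
#' categories, for exercising hypergeometric enrichment on synthetic data.
#'
#' @param genes Character vector of gene symbols (the universe).
#' @param n_sets Sets per category.
#' @param categories Category names.
#' @param set_size_range Range of set sizes.
#' @param seed Integer seed.
#' @return Tibble: set, category, genes (list column).
#' @export
generate_gene_sets <- function(genes, n_sets = 15,
                               categories = c("biological_process",
                                              "cellular_component",
                                              "molecular_function"),
                               set_size_range = c(5, 40), seed = 1) {
  set.seed(as.integer(seed))
  hi <- min(set_size_range[2], length(genes))
  purrr::map(categories, function(cat) {
    tibble(set = sprintf("%s_set%02d", toupper(substr(cat, 1, 2)), seq_len(n_sets)),
           category = cat,
           genes = purrr::map(seq_len(n_sets), function(i) {
             sort(sample(genes, sample(seq(set_size_range[1], hi), 1)))
           }))
  }) |> list_rbind()
}
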