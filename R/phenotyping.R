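# NCEP-ATP III metabolic-syndrome phenotyping, disease definitions, reference
# group selection and per-subtype characterisation tables.
#
# Unit handling: the cohort table stores glucose and lipids in mmol/L;
# component thresholds printed in mg/dL (TG >= 150, HDL-C < 40, FBG >= 110)
# are applied after converting the stored value with fixed factors
# (TG 88.57, glucose 18.0, HDL-C 38.67 mg/dL per mmol/L).

#' Classify NCEP-ATP III metabolic-syndrome components
#'
#' Flags the five components for each individual: abdominal obesity (waist
#' >= 90 cm in men, >= 85 cm in women), high triglycerides (TG >= 150 mg/dL),
#' low HDL-C (< 40 mg/dL), elevated blood pressure (SBP >= 130 or DBP >= 85
#' mmHg, measured values only), and elevated fasting glucose (FBG >= 110
#' mg/dL). All thresholds are inclusive as stated. Metabolic syndrome is
#' diagnosed when 3 or more components are present.
#'
#' @param cohort Cohort tibble with columns sex, waist, TG, HDL_C, SBP, DBP,
#'   FBG (glucose/lipids in mmol/L) and id.
#' @param bp_include_medication If `TRUE`, antihypertensive medication also
#'   satisfies the blood-pressure component (a later revision of the
#'   criteria); default `FALSE`, the literal measured-BP criterion.
#' @param glucose_include_medication Same switch for antidiabetic medication
#'   and the glucose component; default `FALSE`.
#' @return The cohort with appended columns `abdominal_obesity`, `high_tg`,
#'   `low_hdl`, `high_bp`, `high_glucose`, `n_components` (0-5) and `mets`.
#' @examples
#' cohort <- tibble::tibble(id = "a", sex = "male", waist = 90, TG = 1.2,
#'                          HDL_C = 1.5, SBP = 120, DBP = 70, FBG = 5)
#' classify_components(cohort)$n_components  # 1 (waist threshold inclusive)
#' @export
classify_components <- function(cohort, bp_include_medication = FALSE,
                                glucose_include_medication = FALSE) {
  check_fields(cohort, c("sex", "waist", "TG", "HDL_C", "SBP", "DBP", "FBG"),
               where = "cohort")
  out <- cohort |>
    mutate(
      abdominal_obesity = ifelse(.data$sex == "male",
                                 .data$waist >= 90, .data$waist >= 85),
      high_tg = .data$TG * MGDL_PER_MMOL[["TG"]] >= 150,
      low_hdl = .data$HDL_C * MGDL_PER_MMOL[["HDL_C"]] < 40,
      high_bp = .data$SBP >= 130 | .data$DBP >= 85,
      high_glucose = .data$FBG * MGDL_PER_MMOL[["glucose"]] >= 110)
  if (bp_include_medication) {
    check_fields(cohort, "med_antihypertensive", "cohort")
    out <- mutate(out, high_bp = .data$high_bp | .data$med_antihypertensive == 1)
  }
  if (glucose_include_medication) {
    check_fields(cohort, "med_antidiabetic", "cohort")
    out <- mutate(out, high_glucose = .data$high_glucose | .data$med_antidiabetic == 1)
  }
  mutate(out,
         n_components = .data$abdominal_obesity + .data$high_tg + .data$low_hdl +
           .data$high_bp + .data$high_glucose,
         mets = .data$n_components >= 3)
}

#' Diagnose hypertension, type 2 diabetes and dyslipidemia
#'
#' Clinical definitions: hypertension is self-reported disease,
#' antihypertensive treatment, or measured SBP >= 140 / DBP >= 90 mmHg;
#' type 2 diabetes is self-report, FBG >= 7.0 mmol/L, 2h-PBG >= 11.1 mmol/L,
#' or antidiabetic medication; dyslipidemia is self-reported hyperlipidemia
#' or TC >= 5.18, TG >= 1.7, or LDL-C >= 3.37 mmol/L.
#'
#' @param cohort Cohort tibble (see [classify_components()]) with medication
#'   and self-report columns.
#' @return The cohort with appended logical columns `hypertension`, `t2d`,
#'   `dyslipidemia`.
#' @export
diagnose_conditions <- function(cohort) {
  check_fields(cohort,
               c("SBP", "DBP", "FBG", "PBG2h", "TC", "TG", "LDL_C",
                 "self_hypertension", "self_t2d", "self_hyperlipidemia",
                 "med_antihypertensive", "med_antidiabetic"),
               where = "cohort")
  cohort |>
    mutate(
      hypertension = .data$self_hypertension == 1 |
        .data$med_antihypertensive == 1 |
        .data$SBP >= 140 | .data$DBP >= 90,
      t2d = .data$self_t2d == 1 | .data$med_antidiabetic == 1 |
        .data$FBG >= 7.0 | .data$PBG2h >= 11.1,
      dyslipidemia = .data$self_hyperlipidemia == 1 |
        .data$TC >= 5.18 | .data$TG >= 1.7 | .data$LDL_C >= 3.37)
}

#' Select the metabolically healthy reference group
#'
#' The reference group comprises individuals with none of the five
#' metabolic-syndrome components; everyone else forms the clustering set.
#'
#' @param cohort Cohort tibble.
#' @param ... Passed to [classify_components()].
#' @return List with `reference_ids`, `clustering_ids` (disjoint, together
#'   covering all ids). Warns if the reference set is empty.
#' @export
select_reference <- function(cohort, ...) {
  comp <- classify_components(cohort, ...)
  ref <- comp$id[comp$n_components == 0]
  if (length(ref) == 0) warn("no individual is free of all metabolic-syndrome components; reference set is empty")
  list(reference_ids = ref, clustering_ids = setdiff(comp$id, ref))
}

# sample skewness (g1, biased moment version); used to pick the summary style
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Characterise subtypes in a Table-1 style summary
#'
#' Summarises each variable per subtype (and reference): continuous
#' variables as mean (sd) when roughly symmetric or median \[Q1, Q3\] when
#' skewed (|sample skewness| > `skew_cut`), categorical variables as n (%).
#' Across-subtype differences (reference excluded, matching the usual
#' presentation) are tested with one-way ANOVA (symmetric), Kruskal-Wallis
#' (skewed) or the chi-square test (categorical). Optionally re-runs the
#' whole summary within strata defined by each medication flag.
#'
#' @param cohort Cohort tibble.
#' @param labels Vector aligned with `cohort` rows: subtype labels for
#'   clustered individuals and `"reference"` (or 0 / NA) for the reference
#'   group.
#' @param variables Variables to summarise; default all metabolic traits,
#'   age, sex and binary history/outcome columns present.
#' @param stratify_by_medication If `TRUE`, additionally summarise within
#'   users and non-users of each medication.
#' @param skew_cut Absolute sample-skewness threshold above which a
#'   continuous variable is presented as median and quartiles.
#' @return Tibble with one row per variable per group: n, mean, sd, median,
#'   q1, q3, count, pct, `summary` (formatted), and per-variable `test`,
#'   `p_value` (NA for groups where a test was skipped). With stratification
#'   a `stratum` column is added.
#' @export
characterize <- function(cohort, labels, variables = NULL,
                         stratify_by_medication = FALSE, skew_cut = 1) {
  stopifnot(length(labels) == nrow(cohort))
  group <- as.character(labels)
  group[is.na(group) | group %in% c("0", "reference", "ref")] <- "reference"
  if (is.null(variables)) {
    candidates <- c("age", "BMI", "waist", "SBP", "DBP", "FBG", "PBG2h",
                    "TC", "TG", "HDL_C", "LDL_C", "sex", "smoking", "drinking",
                    "med_antihypertensive", "med_antidiabetic",
                    "med_lipid_lowering", "chd", "stroke")
    variables <- intersect(candidates, names(cohort))
  }
  main <- characterize_once(cohort, group, variables, skew_cut)
  if (!stratify_by_medication) return(main)
  med_flags <- intersect(c("med_antihypertensive", "med_antidiabetic",
                           "med_lipid_lowering"), names(cohort))
  strata <- purrr::map(med_flags, function(f) {
    purrr::map(c(0, 1), function(v) {
      keep <- cohort[[f]] == v
      characterize_once(cohort[keep, , drop = FALSE], group[keep],
                        setdiff(variables, f), skew_cut) |>
        mutate(stratum = sprintf("%s=%d", f, v), .before = 1)
    }) |> list_rbind()
  }) |> list_rbind()
  bind_rows(mutate(main, stratum = "all", .before = 1), strata)
}

characterize_once <- function(cohort, group, variables, skew_cut) {
  subtype_groups <- setdiff(unique(group), "reference")
  is_categorical <- function(x) {
    is.character(x) || is.factor(x) || is.logical(x) ||
      (is.numeric(x) && all(x %in% c(0, 1), na.rm = TRUE))
  }
  sizes <- table(group[group %in% subtype_groups])
  purrr::map(variables, function(v) {
    x <- cohort[[v]]
    if (is_categorical(x)) {
      pos <- if (is.character(x) || is.factor(x)) {
        lev <- sort(unique(as.character(x)))
        as.character(x) == lev[length(lev)]   # e.g. "male" for sex
      } else x %in% c(1, TRUE)
      rows <- purrr::map(sort(unique(group)), function(gr) {
        idx <- group == gr
        cnt <- sum(pos[idx], na.rm = TRUE)
        tibble(variable = v, group = gr, n = sum(idx), count = cnt,
               pct = percent(cnt, max(sum(idx), 1)),
               summary = sprintf("%d (%.1f%%)", cnt, percent(cnt, max(sum(idx), 1))))
      }) |> list_rbind()
      test <- safe_test(function() {
        tab <- table(group[group %in% subtype_groups], pos[group %in% subtype_groups])
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        list(name = "chi-square", p = ct$p.value)
      }, subtype_groups, sizes)
      bind_cols(rows, test[rep(1, nrow(rows)), ])
    } else {
      skewed <- abs(sample_skewness(x[group %in% subtype_groups])) > skew_cut
      rows <- purrr::map(sort(unique(group)), function(gr) {
        xi <- x[group == gr]
        tibble(variable = v, group = gr, n = length(xi),
               mean = mean(xi), sd = sd(xi), median = median(xi),
               q1 = unname(quantile(xi, 0.25)), q3 = unname(quantile(xi, 0.75)),
               summary = if (skewed)
                 sprintf("%.1f [%.1f, %.1f]", median(xi),
                         quantile(xi, 0.25), quantile(xi, 0.75))
               else sprintf("%.1f ± %.1f", mean(xi), sd(xi)))
      }) |> list_rbind()
      test <- safe_test(function() {
        xi <- x[group %in% subtype_groups]
        gi <- factor(group[group %in% subtype_groups])
        if (skewed) {
          list(name = "kruskal-wallis", p = kruskal.test(xi, gi)$p.value)
        } else {
          list(name = "anova", p = summary(aov(xi ~ gi))[[1]][["Pr(>F)"]][1])
        }
      }, subtype_groups, sizes)
      bind_cols(rows, test[rep(1, nrow(rows)), ])
    }
  }) |> list_rbind()
}

# run a between-subtype test unless some subtype is too small
safe_test <- function(fn, subtype_groups, sizes = NULL) {
  if (length(subtype_groups) < 2) {
    return(tibble(test = NA_character_, p_value = NA_real_))
  }
  if (!is.null(sizes) && any(sizes < 2)) {
    inform("between-subtype test skipped: a subtype has fewer than 2 individuals")
    return(tibble(test = NA_character_, p_value = NA_real_))
  }
  res <- tryCatch(fn(), error = function(e) {
    inform(sprintf("between-subtype test skipped: %s", conditionMessage(e)))
    NULL
  })
  if (is.null(res)) tibble(test = NA_character_, p_value = NA_real_)
  else tibble(test = res$name, p_value = res$p)
}
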