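test_that("metabolic-syndrome component thresholds are inclusive as printed", {
  row <- tibble::tibble(id = "a", sex = "male", waist = 90, TG = 1.2,
                        HDL_C = 1.5, SBP = 120, DBP = 70, FBG = 5)
  comp <- classify_components(row)
  expect_true(comp$abdominal_obesity)          # waist = 90 in men counts
  expect_equal(comp$n_components, 1)

  # female at 85 cm also inclusive; 84.9 is not
  expect_true(classify_components(dplyr::mutate(row, sex = "female", waist = 85))$abdominal_obesity)
  expect_false(classify_components(dplyr::mutate(row, sex = "female", waist = 84.9))$abdominal_obesity)

  # TG 1.70 mmol/L = 150.6 mg/dL crosses the 150 mg/dL line; 1.69 does not
  expect_true(classify_components(dplyr::mutate(row, waist = 70, TG = 1.70))$high_tg)
  expect_false(classify_components(dplyr::mutate(row, waist = 70, TG = 1.69))$high_tg)

  # all-normal female record has zero components
  normal <- tibble::tibble(id = "b", sex = "female", waist = 70, SBP = 110,
                           DBP = 70, FBG = 4.5, TG = 0.9, HDL_C = 1.6)
  expect_equal(classify_components(normal)$n_components, 0)
  expect_false(classify_components(normal)$mets)

  # missing field errors name the field and the id
  expect_error(classify_components(dplyr::select(row, -waist)), "waist")
  expect_error(classify_components(dplyr::mutate(row, FBG = NA_real_)), "FBG")
})

test_that("component flags agree between mmol/L storage and mg/dL thresholds", {
  # hand-converted boundary values: FBG 110 mg/dL = 6.1111 mmol/L,
  # HDL 40 mg/dL = 1.0344 mmol/L
  row <- tibble::tibble(id = "a", sex = "male", waist = 70, TG = 1.0,
                        SBP = 110, DBP = 70,
                        HDL_C = 40 / 38.67, FBG = 110 / 18)
  comp <- classify_components(row)
  expect_true(comp$high_glucose)   # exactly at threshold, inclusive
  expect_false(comp$low_hdl)       # HDL < 40 is strict
  eps <- 1e-6
  comp2 <- classify_components(dplyr::mutate(row, HDL_C = 40 / 38.67 - eps,
                                             FBG = 110 / 18 - eps))
  expect_true(comp2$low_hdl)
  expect_false(comp2$high_glucose)
})

test_that("clinical diagnoses follow the stated definitions", {
  base <- tibble::tibble(id = "x", sex = "male", waist = 70,
                         SBP = 120, DBP = 70, FBG = 5, PBG2h = 6, TC = 4.5,
                         TG = 1.0, HDL_C = 1.5, LDL_C = 2.5,
                         self_hypertension = 0, self_t2d = 0,
                         self_hyperlipidemia = 0,
                         med_antihypertensive = 0, med_antidiabetic = 0)
  d0 <- diagnose_conditions(base)
  expect_false(d0$hypertension); expect_false(d0$t2d); expect_false(d0$dyslipidemia)

  expect_true(diagnose_conditions(dplyr::mutate(base, SBP = 140))$hypertension)
  expect_true(diagnose_conditions(dplyr::mutate(base, med_antihypertensive = 1))$hypertension)
  expect_true(diagnose_conditions(dplyr::mutate(base, FBG = 7.0))$t2d)   # inclusive
  expect_true(diagnose_conditions(dplyr::mutate(base, PBG2h = 11.1))$t2d)
  expect_true(diagnose_conditions(dplyr::mutate(base, TC = 5.18))$dyslipidemia)
  expect_true(diagnose_conditions(dplyr::mutate(base, self_hyperlipidemia = 1))$dyslipidemia)
})

test_that("reference selection partitions the cohort on zero components", {
  cohort <- phenotype_fixture()
  refs <- select_reference(cohort)
  expect_setequal(refs$reference_ids, c("P01", "P02", "P03"))
  expect_setequal(c(refs$reference_ids, refs$clustering_ids), cohort$id)
  expect_length(intersect(refs$reference_ids, refs$clustering_ids), 0)

  # every row abnormal -> empty reference with a warning
  abnormal <- dplyr::mutate(cohort, SBP = 150)
  expect_warning(refs2 <- select_reference(abnormal), "empty")
  expect_length(refs2$reference_ids, 0)
})

test_that("characterisation reduces to degenerate test statistics on copied groups", {
  cohort <- phenotype_fixture()
  doubled <- dplyr::bind_rows(cohort, cohort)
  labels <- rep(c(1, 2), each = nrow(cohort))   # two identical subtypes
  tab <- characterize(doubled, labels, variables = c("SBP", "FBG", "smoking"))
  cont <- dplyr::filter(tab, variable == "SBP")
  expect_equal(unique(cont$test), "anova")
  expect_equal(unique(cont$p_value), 1, tolerance = 1e-10)
  # 2x2 layout with equal counts: chi-square statistic 0 -> p = 1
  half <- rep(c(0, 1), length.out = nrow(doubled))
  tab2 <- characterize(dplyr::mutate(doubled, smoking = half), labels,
                       variables = "smoking")
  expect_equal(unique(tab2$p_value), 1, tolerance = 1e-12)
})

test_that("characterisation summarises groups and skips tests on tiny subtypes", {
  cohort <- phenotype_fixture()
  labels <- c("reference", "reference", "reference", 1, 1, 1, 2, 2, 2, 2)
  tab <- characterize(cohort, labels, variables = c("SBP", "sex"))
  expect_setequal(unique(tab$group), c("reference", "1", "2"))
  ref_row <- dplyr::filter(tab, variable == "SBP", group == "reference")
  expect_equal(ref_row$n, 3)
  expect_equal(ref_row$mean, mean(cohort$SBP[1:3]))
  # a singleton subtype triggers the notice path, summaries still emitted
  labels2 <- c("reference", "reference", "reference", 1, 1, 1, 2, 2, 2, 3)
  expect_message(tab2 <- characterize(cohort, labels2, variables = "SBP"),
                 "skipped")
  expect_true(all(is.na(dplyr::filter(tab2, variable == "SBP")$p_value)))
  expect_equal(nrow(dplyr::filter(tab2, variable == "SBP")), 4)
})

test_that("medication stratification returns each stratum's summary", {
  sc <- generate_cohort(cohort_spec(n_individuals = 400), seed = 6)
  labels <- ifelse(sc$z_true == 0, "reference", sc$z_true)
  tab <- characterize(sc$cohort, labels, variables = c("SBP", "TG"),
                      stratify_by_medication = TRUE)
  expect_true("stratum" %in% names(tab))
  expect_setequal(unique(tab$stratum),
                  c("all", "med_antihypertensive=0", "med_antihypertensive=1",
                    "med_antidiabetic=0", "med_antidiabetic=1",
                    "med_lipid_lowering=0", "med_lipid_lowering=1"))
})

test_that("skewed variables take the kruskal-wallis path, calibrated under the null", {
  set.seed(31)
  n_rej <- 0
  n_rep <- 200
  tests_used <- character(0)
  for (i in seq_len(n_rep)) {
    d <- tibble::tibble(id = as.character(1:60), x = rexp(60)^2)  # skewed null
    tab <- characterize(d, rep(1:3, each = 20), variables = "x")
    tests_used <- c(tests_used, tab$test[1])
    if (tab$p_value[1] < 0.05) n_rej <- n_rej + 1
  }
  expect_gt(mean(tests_used == "kruskal-wallis"), 0.95)
  ci <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(n_rej / n_rep - 0.05), ci + 0.01)
})
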