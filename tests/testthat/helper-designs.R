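# Shared fixtures built in code.

# covariate design exactly as the cohort generator builds it (age scaled by
# the generating mean/sd, not the sample's), so fitted alpha/gamma live on
# the generating scale and can be compared to the spec's true values
generating_design <- function(sc) {
  co <- sc$cohort
  cs <- sc$spec$covariate_spec
  cbind(age_std = (co$age - cs$age_mean) / cs$age_sd,
        sex_male = as.numeric(co$sex == "male"),
        smoking = co$smoking, drinking = co$drinking,
        pc1 = co$pc1, pc2 = co$pc2, pc3 = co$pc3,
        med_antihypertensive = co$med_antihypertensive,
        med_antidiabetic = co$med_antidiabetic,
        med_lipid_lowering = co$med_lipid_lowering)
}

# well-separated four-subtype cohort used for recovery checks; everyone is
# clustered (no reference stratum) and subtypes are balanced
recovery_spec <- function(n = 2000, gap = 3) {
  cohort_spec(n_individuals = n, K_true = 4,
              mixing_weights = rep(0.25, 4), reference_frac = 0,
              gamma_true = separated_gamma(4, 10, gap),
              residual_sd = rep(1, 10))
}

# tiny all-normal / mixed phenotyping fixture with known component flags
phenotype_fixture <- function() {
  tibble::tibble(
    id = sprintf("P%02d", 1:10),
    sex = c("male", "female", "male", "female", "male",
            "female", "male", "female", "male", "female"),
    age = rep(55, 10),
    waist = c(80, 70, 75, 84.9, 91, 86, 89.9, 85, 70, 72),
    TG = c(0.9, 1.0, 1.2, 1.1, 2.0, 1.8, 1.0, 1.7, 0.8, 1.8),
    HDL_C = c(1.5, 1.6, 1.4, 1.2, 0.9, 1.0, 1.5, 1.3, 1.6, 1.7),
    SBP = c(118, 110, 125, 129, 135, 131, 128, 130, 130, 119),
    DBP = c(76, 70, 80, 85, 88, 86, 84, 85, 78, 75),
    FBG = c(5.0, 4.5, 5.5, 6.0, 7.2, 6.5, 6.2, 6.2, 5.1, 4.9),
    PBG2h = rep(6, 10), TC = rep(4.5, 10), LDL_C = rep(2.5, 10),
    self_hypertension = rep(0, 10), self_t2d = rep(0, 10),
    self_hyperlipidemia = rep(0, 10),
    med_antihypertensive = rep(0, 10), med_antidiabetic = rep(0, 10),
    med_lipid_lowering = rep(0, 10),
    smoking = rep(0, 10), drinking = rep(0, 10),
    pc1 = rep(0, 10), pc2 = rep(0, 10), pc3 = rep(0, 10),
    chd = rep(0, 10), stroke = rep(0, 10))
}
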