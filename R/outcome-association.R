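# Subtype-to-cardiovascular-outcome associations by multivariable logistic
# regression against the metabolically healthy reference group.

#' Logistic regression with Wald inference
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' (via [stats::glm.fit()], epsilon 1e-10, at most 100 iterations), with the
#' covariance taken as the inverse observed information. Complete or
#' quasi-complete separation is reported as an error naming the offending
#' column rather than returned as a divergent estimate.
#'
#' @param y Binary 0/1 response vector.
#' @param design n x d numeric design matrix (include the intercept column
#'   yourself).
#' @return List: `coefficients`, `vcov`, `se`, `deviance`, `n`, `fitted`.
#' @examples
#' # closed-form 2x2 check: log OR = log((20*90)/(80*10))
#' y <- rep(c(1, 0, 1, 0), c(20, 80, 10, 90))
#' x <- rep(c(1, 0), c(100, 100))
#' fit_logistic(y, cbind(1, exposed = x))$coefficients["exposed"]
#' @export
fit_logistic <- function(y, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (length(unique(y)) < 2) abort("response is constant; logistic model is not estimable")
  if (ncol(design) >= nrow(design)) abort("more columns than observations in design")
  empty <- !nzchar(colnames(design))
  colnames(design)[empty] <- paste0("x", which(empty))
  # glm.fit's 0/1-probability warning is superseded by the explicit
  # separation check below
  fit <- withCallingHandlers(
    glm.fit(design, y, family = binomial(),
            control = glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged) abort("logistic regression did not converge within 100 iterations")
  coefs <- fit$coefficients
  if (any(abs(coefs) > 15)) {
    abort(sprintf("separation suspected: coefficient for `%s` is diverging",
                  colnames(design)[which.max(abs(coefs))]))
  }
  w <- fit$weights
  info <- crossprod(design * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) {
    abort("information matrix is singular; check design for collinearity")
  })
  dimnames(vc) <- list(colnames(design), colnames(design))
  list(coefficients = coefs, vcov = vc, se = sqrt(diag(vc)),
       deviance = fit$deviance, n = nrow(design), fitted = fit$fitted.values)
}

#' Subtype-cardiovascular-disease association estimates
#'
#' Estimates the odds of a binary outcome (e.g. coronary heart disease or
#' stroke) in each metabolic subtype relative to the reference group by
#' multivariable logistic regression adjusted for age, sex and the number of
#' metabolic-syndrome components diagnosed (entering as an integer 0-5).
#' By default a single joint model with subtype indicator columns and the
#' reference group as baseline is fitted; `method = "per_subtype"` instead
#' fits one model per subtype restricted to that subtype plus the reference.
#'
#' @param cohort Cohort tibble.
#' @param labels Subtype labels aligned with `cohort` rows; the reference
#'   group as `"reference"`, 0 or `NA`.
#' @param outcome Name of the binary outcome column (default `"chd"`).
#' @param adjust Adjustment covariates among `"age"`, `"sex"`,
#'   `"n_components"`.
#' @param method `"joint"` (default) or `"per_subtype"`.
#' @param alpha Significance level for the flag column.
#' @return Tibble with one row per subtype: outcome, subtype, n_case,
#'   n_total, log_or, se, or, ci_lo, ci_hi, p, significant. Wald 95%
#'   intervals are `exp(log_or +/- 1.96 se)`.
#' @export
subtype_outcome_associations <- function(cohort, labels, outcome = "chd",
                                         adjust = c("age", "sex", "n_components"),
                                         method = c("joint", "per_subtype"),
                                         alpha = 0.05) {
  method <- match.arg(method)
  check_fields(cohort, outcome, "cohort")
  stopifnot(length(labels) == nrow(cohort))
  group <- as.character(labels)
  group[is.na(group) | group %in% c("0", "reference", "ref")] <- "reference"
  if (!any(group == "reference")) abort("reference group is empty")
  subtypes <- setdiff(sort(unique(group)), "reference")

  adj_cols <- NULL
  if ("n_components" %in% adjust) {
    cohort <- classify_components(cohort)
  }
  build_adjust <- function(df) {
    cols <- list()
    if ("age" %in% adjust) cols$age <- df$age
    if ("sex" %in% adjust) cols$sex_male <- as.numeric(df$sex == "male")
    if ("n_components" %in% adjust) cols$n_components <- df$n_components
    if (length(cols) == 0) NULL else do.call(cbind, cols)
  }

  y_all <- cohort[[outcome]]
  one_row <- function(subtype, coefs) {
    idx <- group == subtype
    est <- coefs$coefficients[[paste0("subtype", subtype)]]
    se <- coefs$se[[paste0("subtype", subtype)]]
    p <- 2 * stats::pnorm(-abs(est / se))
    tibble(outcome = outcome, subtype = subtype,
           n_case = sum(y_all[idx]), n_total = sum(idx),
           log_or = est, se = se, or = exp(est),
           ci_lo = exp(est - 1.96 * se), ci_hi = exp(est + 1.96 * se),
           p = p, significant = p < alpha)
  }

  if (method == "joint") {
    # groups without outcome variation make their coefficient diverge;
    # drop them from the model with a notice rather than fail the fit
    if (length(unique(y_all[group == "reference"])) < 2) {
      inform(sprintf("outcome `%s` has no variation in the reference group; associations skipped",
                     outcome))
      return(tibble(outcome = character(), subtype = character(),
                    n_case = integer(), n_total = integer(), log_or = numeric(),
                    se = numeric(), or = numeric(), ci_lo = numeric(),
                    ci_hi = numeric(), p = numeric(), significant = logical()))
    }
    estimable <- purrr::keep(subtypes, function(s) {
      ok <- length(unique(y_all[group == s])) == 2
      if (!ok) inform(sprintf("outcome `%s` has no variation in subtype %s; skipped", outcome, s))
      ok
    })
    keep <- group %in% c(estimable, "reference")
    ind <- vapply(estimable, function(s) as.numeric(group[keep] == s),
                  numeric(sum(keep)))
    colnames(ind) <- paste0("subtype", estimable)
    design <- cbind(`(Intercept)` = 1, ind, build_adjust(cohort[keep, , drop = FALSE]))
    fit <- fit_logistic(y_all[keep], design)
    rows <- purrr::map(estimable, one_row, coefs = fit)
  } else {
    rows <- purrr::map(subtypes, function(s) {
      keep <- group %in% c(s, "reference")
      sub <- cohort[keep, , drop = FALSE]
      y <- y_all[keep]
      if (sum(y) == 0) {
        inform(sprintf("outcome `%s` has no cases in subtype %s vs reference; skipped",
                       outcome, s))
        return(NULL)
      }
      ind <- matrix(as.numeric(group[keep] == s), ncol = 1,
                    dimnames = list(NULL, paste0("subtype", s)))
      design <- cbind(`(Intercept)` = 1, ind, build_adjust(sub))
      fit <- fit_logistic(y, design)
      idx <- group == s
      est <- fit$coefficients[[paste0("subtype", s)]]
      se <- fit$se[[paste0("subtype", s)]]
      p <- 2 * stats::pnorm(-abs(est / se))
      tibble(outcome = outcome, subtype = s,
             n_case = sum(y_all[idx]), n_total = sum(idx),
             log_or = est, se = se, or = exp(est),
             ci_lo = exp(est - 1.96 * se), ci_hi = exp(est + 1.96 * se),
             p = p, significant = p < alpha)
    })
  }
  list_rbind(purrr::compact(rows))
}
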