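# broom-style and plotting methods for fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method print mfmr_model
#' @export
print.mfmr_model <- function(x, ...) {
  cat(sprintf("MFMR model: K = %d subtypes, P = %d traits, Q = %d covariates, F = %d focal\n",
              x$K, x$P, x$Q, x$F))
  cat("mixing weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' @method print mfmr_fit
#' @export
print.mfmr_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("log-likelihood %.2f after %d EM iterations (%s), %d restarts kept\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged",
              x$n_restarts_used))
  invisible(x)
}

#' Tidy an MFMR fit into one row per parameter
#'
#' @param x An `mfmr_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term` (`gamma`, `alpha`, `beta`, `sigma2`,
#'   `pi`), `subtype`, `covariate`, `trait`, `estimate`.
#' @export
tidy.mfmr_fit <- function(x, ...) {
  m <- x$model
  traits <- m$trait_names %||% paste0("trait", seq_len(m$P))
  out <- list(
    tibble(term = "gamma",
           subtype = rep(seq_len(m$K), m$P),
           covariate = NA_character_,
           trait = rep(traits, each = m$K),
           estimate = as.vector(m$gamma)),
    tibble(term = "sigma2", subtype = NA_integer_, covariate = NA_character_,
           trait = traits, estimate = unname(m$sigma2)),
    tibble(term = "pi", subtype = seq_len(m$K), covariate = NA_character_,
           trait = NA_character_, estimate = unname(m$pi)))
  if (m$Q > 0) {
    covs <- m$covariate_names %||% paste0("x", seq_len(m$Q))
    out <- c(out, list(
      tibble(term = "alpha", subtype = NA_integer_,
             covariate = rep(covs, m$P),
             trait = rep(traits, each = m$Q),
             estimate = as.vector(m$alpha))))
  }
  if (m$F > 0) {
    out <- c(out, list(
      tibble(term = "beta",
             subtype = rep(seq_len(m$K), m$F * m$P),
             covariate = rep(rep(paste0("g", seq_len(m$F)), each = m$K), m$P),
             trait = rep(traits, each = m$K * m$F),
             estimate = as.vector(m$beta))))
  }
  list_rbind(out)
}

#' One-row summary of an MFMR fit
#'
#' @inheritParams tidy.mfmr_fit
#' @return Tibble: n, K, P, Q, F, loglik, n_iter, converged,
#'   n_restarts_used.
#' @export
glance.mfmr_fit <- function(x, ...) {
  tibble(n = x$n, K = x$model$K, P = x$model$P, Q = x$model$Q, F = x$model$F,
         loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         n_restarts_used = x$n_restarts_used)
}

#' Heatmap of subtype trait effects
#'
#' Displays the standardized subtype trait means (gamma) as a subtype-by-
#' trait tile plot, the profile by which subtypes are named.
#'
#' @param object An `mfmr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mfmr_fit <- function(object, ...) {
  d <- tidy.mfmr_fit(object) |> filter(.data$term == "gamma")
  d$trait <- factor(d$trait, levels = object$model$trait_names %||% unique(d$trait))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = factor(.data$subtype),
                                  fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = "subtype", fill = "standardized\ntrait mean") +
    ggplot2::theme_minimal()
}

#' @method print mfmr_kselect
#' @export
print.mfmr_kselect <- function(x, ...) {
  cat("Cross-validated likelihood selection of K\n")
  print(x$summary)
  cat("chosen K:", x$chosen_k, "\n")
  invisible(x)
}

#' @rdname select_k
#' @param x An `mfmr_kselect`.
#' @param ... Unused.
#' @export
tidy.mfmr_kselect <- function(x, ...) x$summary

#' Held-out log-likelihood against number of subtypes
#'
#' @param object An `mfmr_kselect`.
#' @param ... Unused.
#' @return A ggplot object: per-fold points and the mean curve, with the
#'   chosen K marked.
#' @export
autoplot.mfmr_kselect <- function(object, ...) {
  ggplot2::ggplot(object$cv, ggplot2::aes(x = .data$K, y = .data$holdout_loglik)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = object$summary,
                       ggplot2::aes(y = .data$mean_holdout_loglik)) +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::labs(x = "number of subtypes K", y = "held-out log-likelihood") +
    ggplot2::theme_minimal()
}

#' Build the default MFMR design from a cohort table
#'
#' Extracts the ten metabolic cluster traits and the homogeneous control
#' covariates (standardized age, male sex, smoking, drinking, the first
#' three principal components and the three medication flags) used by the
#' default clustering pipeline.
#'
#' @param cohort Cohort tibble.
#' @return List: `traits` (tibble), `X` (covariate matrix).
#' @export
mfmr_design <- function(cohort) {
  trait_names <- c("BMI", "waist", "SBP", "DBP", "FBG", "PBG2h", "TC", "TG",
                   "HDL_C", "LDL_C")
  check_fields(cohort, c(trait_names, "age", "sex", "smoking", "drinking",
                         "pc1", "pc2", "pc3", "med_antihypertensive",
                         "med_antidiabetic", "med_lipid_lowering"), "cohort")
  X <- cbind(age_std = as.numeric(scale(cohort$age)),
             sex_male = as.numeric(cohort$sex == "male"),
             smoking = cohort$smoking, drinking = cohort$drinking,
             pc1 = cohort$pc1, pc2 = cohort$pc2, pc3 = cohort$pc3,
             med_antihypertensive = cohort$med_antihypertensive,
             med_antidiabetic = cohort$med_antidiabetic,
             med_lipid_lowering = cohort$med_lipid_lowering)
  list(traits = cohort[, trait_names], X = X)
}
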