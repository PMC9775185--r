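# Multi-trait finite mixture of regressions (MFMR).
#
# Model: for individual i with traits y_i (length P), control covariates X_i
# (length Q) and optional focal covariates g_i (length F),
#
#   y_ip = X_i alpha[, p] + gamma[z_i, p] + g_i beta[z_i, , p] + mu_ip
#
# where z_i is a latent K-level subtype, alpha is homogeneous across
# subtypes, gamma are subtype main effects, beta are subtype-specific focal
# effects, and mu_ip ~ N(0, sigma2[p]) independently across traits
# (diagonal residual covariance, variance shared across subtypes). Mixing
# weights pi complete the finite mixture. Fitting is by EM; the number of
# subtypes is chosen to maximize cross-validated held-out likelihood.

as_num_matrix <- function(x, what) {
  if (is.null(x)) return(NULL)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort(sprintf("`%s` contains non-finite values", what))
  m
}

#' Standardize trait columns to mean 0, sd 1
#'
#' Records the centring/scaling so the transform is invertible; constant
#' traits are rejected by name.
#'
#' @param traits Data frame or matrix of continuous traits.
#' @return List of class `trait_standardization`: `traits` (standardized
#'   tibble), `center`, `scale`.
#' @seealso [destandardize_traits()]
#' @export
standardize_traits <- function(traits) {
  m <- as_num_matrix(traits, "traits")
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  if (any(scl == 0)) {
    abort(sprintf("constant trait(s) cannot be standardized: %s",
                  paste(colnames(m)[scl == 0], collapse = ", ")))
  }
  out <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  structure(list(traits = as_tibble(out), center = ctr, scale = scl),
            class = "trait_standardization")
}

#' @rdname standardize_traits
#' @param std A `trait_standardization`.
#' @param traits Standardized values to map back to the raw scale (default
#'   the ones recorded in `std`).
#' @export
destandardize_traits <- function(std, traits = std$traits) {
  m <- as_num_matrix(traits, "traits")
  as_tibble(sweep(sweep(m, 2, std$scale, "*"), 2, std$center, "+"))
}

new_mfmr_model <- function(alpha, gamma, beta, sigma2, pi,
                           trait_names = NULL, covariate_names = NULL) {
  K <- nrow(gamma); P <- ncol(gamma)
  stopifnot(length(sigma2) == P, length(pi) == K)
  if (any(sigma2 <= 0)) abort("residual variances must be strictly positive")
  if (abs(sum(pi) - 1) > 1e-8 || any(pi <= 0)) abort("mixing weights must be positive and sum to 1")
  structure(list(K = K, P = P, Q = if (is.null(alpha)) 0L else nrow(alpha),
                 F = if (is.null(beta)) 0L else dim(beta)[2],
                 alpha = alpha, gamma = gamma, beta = beta,
                 sigma2 = sigma2, pi = pi,
                 trait_names = trait_names %||% colnames(gamma),
                 covariate_names = covariate_names %||% rownames(alpha)),
            class = "mfmr_model")
}

# component means: list of K n x P matrices
component_means <- function(model, n, X, g) {
  base <- if (model$Q > 0) X %*% model$alpha else matrix(0, n, model$P)
  lapply(seq_len(model$K), function(k) {
    mk <- sweep(base, 2, model$gamma[k, ], "+")
    if (model$F > 0) mk <- mk + g %*% matrix(model$beta[k, , ], nrow = model$F)
    mk
  })
}

#' E-step: posterior subtype responsibilities and log-likelihood
#'
#' Computes `r_ik` proportional to `pi_k` times the product over traits of
#' Gaussian densities at the component means, normalized per row with a
#' log-sum-exp, and the total observed-data log-likelihood.
#'
#' @param model An `mfmr_model`.
#' @param Y n x P trait matrix (standardized scale).
#' @param X n x Q control covariate matrix, or `NULL` for none.
#' @param g n x F focal covariate matrix, or `NULL`.
#' @return List: `responsibilities` (n x K, rows sum to 1), `loglik` (total),
#'   `loglik_i` (per-observation contributions).
#' @export
mfmr_e_step <- function(model, Y, X = NULL, g = NULL) {
  Y <- as_num_matrix(Y, "Y"); X <- as_num_matrix(X, "X"); g <- as_num_matrix(g, "g")
  n <- nrow(Y)
  if (model$Q > 0 && (is.null(X) || ncol(X) != model$Q)) abort("X does not match model dimension Q")
  if (model$F > 0 && (is.null(g) || ncol(g) != model$F)) abort("g does not match model dimension F")
  means <- component_means(model, n, X, g)
  const <- sum(log(2 * pi * model$sigma2))
  L <- vapply(seq_len(model$K), function(k) {
    R <- Y - means[[k]]
    log(model$pi[k]) - 0.5 * (drop(R^2 %*% (1 / model$sigma2)) + const)
  }, numeric(n))
  L <- matrix(L, nrow = n)
  mx <- apply(L, 1, max)
  ll_i <- mx + log(rowSums(exp(L - mx)))
  resp <- exp(L - ll_i)
  list(responsibilities = resp, loglik = sum(ll_i), loglik_i = ll_i)
}

#' M-step: weighted least squares update of all parameters
#'
#' For each trait, `(alpha[, p], gamma[, p], beta[, , p])` jointly minimize
#' the responsibility-weighted squared error on a design expanded over
#' components (`alpha` columns shared, `gamma`/`beta` columns
#' component-specific); since the expanded design and weights are common to
#' all traits, one weighted Gram matrix serves every trait. Residual
#' variances are responsibility-weighted mean squared residuals; mixing
#' weights are mean responsibilities.
#'
#' @param resp n x K responsibility matrix (rows summing to 1).
#' @inheritParams mfmr_e_step
#' @return An `mfmr_model`.
#' @export
mfmr_m_step <- function(resp, Y, X = NULL, g = NULL) {
  Y <- as_num_matrix(Y, "Y"); X <- as_num_matrix(X, "X"); g <- as_num_matrix(g, "g")
  ed <- expand_design(nrow(Y), ncol(resp), X, g)
  m_step_core(resp, Y, ed, trait_names = colnames(Y),
              covariate_names = colnames(X))
}

# expanded design over components: rows are (component k, individual i)
# blocks; columns [X shared | K component indicators | K x F interactions]
expand_design <- function(n, K, X, g) {
  Q <- if (is.null(X)) 0L else ncol(X)
  F_ <- if (is.null(g)) 0L else ncol(g)
  d <- Q + K + K * F_
  A <- matrix(0, n * K, d)
  for (k in seq_len(K)) {
    rows <- (k - 1L) * n + seq_len(n)
    if (Q > 0) A[rows, seq_len(Q)] <- X
    A[rows, Q + k] <- 1
    if (F_ > 0) A[rows, Q + K + (k - 1L) * F_ + seq_len(F_)] <- g
  }
  list(A = A, n = n, K = K, Q = Q, F = F_)
}

m_step_core <- function(resp, Y, ed, trait_names = NULL, covariate_names = NULL) {
  n <- ed$n; K <- ed$K; Q <- ed$Q; F_ <- ed$F
  w <- sqrt(as.vector(resp))            # stacked by component blocks
  Aw <- ed$A * w
  Yw <- Y[rep(seq_len(n), K), , drop = FALSE] * w
  G <- crossprod(Aw)
  R <- tryCatch(chol(G), error = function(e) {
    abort("rank-deficient expanded design in M-step; check covariates for collinearity")
  })
  coefs <- backsolve(R, forwardsolve(t(R), crossprod(Aw, Yw)))
  alpha <- if (Q > 0) coefs[seq_len(Q), , drop = FALSE] else NULL
  gamma <- coefs[Q + seq_len(K), , drop = FALSE]
  beta <- NULL
  if (F_ > 0) {
    beta <- array(0, dim = c(K, F_, ncol(Y)))
    for (k in seq_len(K)) {
      beta[k, , ] <- coefs[Q + K + (k - 1L) * F_ + seq_len(F_), , drop = FALSE]
    }
  }
  resid <- Yw - Aw %*% coefs
  sigma2 <- pmax(colSums(resid^2) / n, 1e-12)
  pi_hat <- colMeans(resp)
  if (!is.null(alpha)) rownames(alpha) <- covariate_names
  colnames(gamma) <- trait_names
  new_mfmr_model(alpha, gamma, beta, sigma2, pi_hat,
                 trait_names = trait_names, covariate_names = covariate_names)
}

# one Dirichlet-perturbed random responsibility matrix
init_responsibilities <- function(n, K) {
  r <- matrix(rgamma(n * K, shape = 2), n, K)
  r / rowSums(r)
}

#' Fit the mixture of regressions by EM
#'
#' Alternates E- and M-steps from several random responsibility
#' initializations and keeps the highest-likelihood fit. A restart whose
#' smallest mixing weight falls below `min_weight` (default `1/(10K)`) is
#' treated as collapsed and discarded. Components of the returned model are
#' in canonical order (see [canonical_order()]).
#'
#' @inheritParams mfmr_e_step
#' @param K Number of subtypes.
#' @param n_restarts Number of random initializations.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param seed Integer seed; restart sub-seeds are derived with
#'   [split_seed()].
#' @param min_weight Collapse threshold for mixing weights; default
#'   `1/(10K)`.
#' @param canonical Put components in canonical order before returning.
#' @return An `mfmr_fit`: `model`, `responsibilities`, `loglik`,
#'   `loglik_trace`, `converged`, `n_iter`, `n_restarts_used`, `best_seed`,
#'   `n`.
#' @examples
#' Y <- matrix(rnorm(200), 100, 2)
#' fit <- fit_mfmr(Y, K = 1, n_restarts = 1, seed = 1)
#' glance(fit)
#' @export
fit_mfmr <- function(Y, X = NULL, g = NULL, K, n_restarts = 20, max_iter = 500,
                     tol = 1e-6, seed = 1, min_weight = NULL, canonical = TRUE) {
  Y <- as_num_matrix(Y, "Y"); X <- as_num_matrix(X, "X"); g <- as_num_matrix(g, "g")
  n <- nrow(Y)
  Q <- if (is.null(X)) 0L else ncol(X)
  F_ <- if (is.null(g)) 0L else ncol(g)
  if (n <= K * (1 + F_) + Q) abort("too few observations for this K, F and Q")
  min_weight <- min_weight %||% (1 / (10 * K))
  ed <- expand_design(n, K, X, g)
  # a collapsed run is restarted from a fresh initialization, up to 5 times
  max_tries <- 6L
  sub_seeds <- matrix(split_seed(seed, n_restarts * max_tries), n_restarts, max_tries)
  best <- NULL
  collapsed <- 0L
  for (r in seq_len(n_restarts)) {
   for (try in seq_len(max_tries)) {
    set.seed(sub_seeds[r, try])
    resp <- init_responsibilities(n, K)
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      model <- m_step_core(resp, Y, ed, trait_names = colnames(Y),
                           covariate_names = colnames(X))
      if (min(model$pi) < min_weight) { ok <- FALSE; break }
      es <- mfmr_e_step(model, Y, X, g)
      resp <- es$responsibilities
      trace <- c(trace, es$loglik)
      if (is.finite(ll_prev) &&
          abs(es$loglik - ll_prev) < tol * (abs(ll_prev) + 1e-3)) {
        converged <- TRUE
        break
      }
      ll_prev <- es$loglik
    }
    if (!ok) {
      inform(sprintf("restart %d try %d collapsed (mixing weight below %.3g)",
                     r, try, min_weight))
      if (try == max_tries) collapsed <- collapsed + 1L
      next
    }
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- list(model = model, responsibilities = resp,
                   loglik = trace[length(trace)], loglik_trace = trace,
                   converged = converged, n_iter = length(trace),
                   best_seed = sub_seeds[r, try])
    }
    break
   }
  }
  if (is.null(best)) abort("all restarts collapsed; reduce K or min_weight")
  fit <- structure(c(best, list(n_restarts_used = n_restarts - collapsed, n = n)),
                   class = "mfmr_fit")
  if (canonical) fit <- canonical_order(fit)
  fit
}

#' Put mixture components in canonical order
#'
#' Subtypes are identifiable only up to relabeling; the canonical order sorts
#' components by the index of the trait with the largest standardized
#' subtype effect (its dominant characteristic), ascending, with ties broken
#' by descending mixing weight. Idempotent and likelihood-preserving.
#'
#' @param x An `mfmr_model` or `mfmr_fit`.
#' @return The same object with components relabeled.
#' @export
canonical_order <- function(x) {
  model <- if (inherits(x, "mfmr_fit")) x$model else x
  dominant <- apply(model$gamma, 1, which.max)
  ord <- order(dominant, -model$pi)
  model$gamma <- model$gamma[ord, , drop = FALSE]
  model$pi <- model$pi[ord]
  if (!is.null(model$beta)) model$beta <- model$beta[ord, , , drop = FALSE]
  if (inherits(x, "mfmr_fit")) {
    x$model <- model
    x$responsibilities <- x$responsibilities[, ord, drop = FALSE]
    x
  } else model
}

#' Assign hard subtype labels
#'
#' Each individual gets the component with the highest posterior
#' responsibility; ties break to the smallest label.
#'
#' @param x An `mfmr_fit` (uses its stored responsibilities when `Y` is
#'   `NULL`) or `mfmr_model`.
#' @inheritParams mfmr_e_step
#' @return List: `labels` (integer in 1..K), `responsibilities`.
#' @export
assign_subtypes <- function(x, Y = NULL, X = NULL, g = NULL) {
  if (inherits(x, "mfmr_fit") && is.null(Y)) {
    resp <- x$responsibilities
  } else {
    model <- if (inherits(x, "mfmr_fit")) x$model else x
    resp <- mfmr_e_step(model, Y, X, g)$responsibilities
  }
  list(labels = max.col(resp, ties.method = "first"), responsibilities = resp)
}

#' Choose the number of subtypes by cross-validated likelihood
#'
#' For each candidate K the model is fitted on each training fold and the
#' fitted mixture log-likelihood is evaluated on the held-out fold; the K
#' with the highest mean held-out log-likelihood is chosen (ties to the
#' smaller K).
#'
#' @inheritParams fit_mfmr
#' @param k_range Candidate numbers of subtypes.
#' @param n_folds Number of cross-validation folds.
#' @param ... Passed on to [fit_mfmr()] (e.g. `n_restarts`, `max_iter`,
#'   `tol`).
#' @return An `mfmr_kselect`: tibble `cv` (K, fold, holdout_loglik), tibble
#'   `summary` (K, mean_holdout_loglik), `chosen_k`, `seed`.
#' @export
select_k <- function(Y, X = NULL, g = NULL, k_range = 1:6, n_folds = 5,
                     seed = 1, ...) {
  if (length(k_range) == 0) abort("`k_range` must be nonempty")
  if (n_folds < 2) abort("`n_folds` must be at least 2")
  Y <- as_num_matrix(Y, "Y"); X <- as_num_matrix(X, "X"); g <- as_num_matrix(g, "g")
  n <- nrow(Y)
  k_range <- sort(unique(as.integer(k_range)))
  Q <- if (is.null(X)) 0L else ncol(X)
  F_ <- if (is.null(g)) 0L else ncol(g)
  seeds <- split_seed(seed, 1 + length(k_range) * n_folds)
  set.seed(seeds[1])
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  min_train <- min(table(fold)) * (n_folds - 1)
  if (min_train <= max(k_range) * (1 + F_) + Q) {
    abort("folds too small for the largest K in `k_range`")
  }
  grid <- expand.grid(fold_i = seq_len(n_folds), K = k_range)
  cv <- purrr::pmap(grid, function(fold_i, K) {
    train <- fold != fold_i
    fit <- fit_mfmr(Y[train, , drop = FALSE],
                    if (Q > 0) X[train, , drop = FALSE] else NULL,
                    if (F_ > 0) g[train, , drop = FALSE] else NULL,
                    K = K,
                    seed = seeds[1 + (match(K, k_range) - 1) * n_folds + fold_i],
                    canonical = FALSE, ...)
    ll <- mfmr_e_step(fit$model, Y[!train, , drop = FALSE],
                      if (Q > 0) X[!train, , drop = FALSE] else NULL,
                      if (F_ > 0) g[!train, , drop = FALSE] else NULL)$loglik
    tibble(K = K, fold = fold_i, holdout_loglik = ll)
  }) |> list_rbind()
  summary <- cv |>
    group_by(.data$K) |>
    summarise(mean_holdout_loglik = mean(.data$holdout_loglik), .groups = "drop") |>
    arrange(.data$K)
  chosen <- summary$K[which.max(summary$mean_holdout_loglik)]
  structure(list(cv = cv, summary = summary, chosen_k = chosen,
                 seed = as.integer(seed)),
            class = "mfmr_kselect")
}
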