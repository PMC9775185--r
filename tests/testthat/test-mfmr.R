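test_that("trait standardization is exact, invertible and guards constants", {
  set.seed(1)
  raw <- tibble::tibble(a = rnorm(50, 10, 2), b = runif(50))
  std <- standardize_traits(raw)
  expect_equal(colMeans(as.matrix(std$traits)), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(as.matrix(std$traits), 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  # closed form: a value center + 2*scale maps to 2
  probe <- (std$center["a"] + 2 * std$scale["a"] - std$center["a"]) / std$scale["a"]
  expect_equal(unname(probe), 2)
  # idempotence on already-standardized input
  again <- standardize_traits(std$traits)
  expect_equal(as.matrix(again$traits), as.matrix(std$traits), tolerance = 1e-12)
  # round trip
  back <- destandardize_traits(std)
  expect_equal(as.matrix(back), as.matrix(raw), tolerance = 1e-10)
  expect_error(standardize_traits(tibble::tibble(a = rep(3, 5), b = 1:5)), "a")
})

test_that("E-step matches a brute-force density evaluation", {
  set.seed(2)
  n <- 5
  Y <- matrix(rnorm(n * 3), n, 3)
  X <- cbind(rnorm(n))
  model <- metsubtype:::new_mfmr_model(
    alpha = matrix(c(0.5, -0.2, 0.1), 1, 3),
    gamma = rbind(c(-1, 0, 1), c(1, 0.5, -1)),
    beta = NULL, sigma2 = c(0.8, 1.2, 1.0), pi = c(0.3, 0.7))
  es <- mfmr_e_step(model, Y, X)
  # direct evaluation of pi_k * prod_p N(y; mean, sigma2)
  for (i in 1:n) {
    dens <- sapply(1:2, function(k) {
      mu <- X[i, ] %*% model$alpha + model$gamma[k, ]
      model$pi[k] * prod(dnorm(Y[i, ], mu, sqrt(model$sigma2)))
    })
    expect_equal(es$responsibilities[i, ], dens / sum(dens), tolerance = 1e-12)
  }
  expect_equal(rowSums(es$responsibilities), rep(1, n), tolerance = 1e-9)
  expect_equal(es$loglik, sum(log(sapply(1:n, function(i) {
    sum(sapply(1:2, function(k) {
      mu <- X[i, ] %*% model$alpha + model$gamma[k, ]
      model$pi[k] * prod(dnorm(Y[i, ], mu, sqrt(model$sigma2)))
    }))
  }))), tolerance = 1e-8)
})

test_that("K = 1 E-step gives unit responsibilities and the Gaussian log-likelihood", {
  set.seed(3)
  Y <- matrix(rnorm(40), 20, 2)
  model <- metsubtype:::new_mfmr_model(NULL, matrix(c(0.1, -0.1), 1, 2), NULL,
                                       c(1, 1), 1)
  es <- mfmr_e_step(model, Y)
  expect_true(all(es$responsibilities == 1))
  expect_equal(es$loglik,
               sum(dnorm(Y[, 1], 0.1, 1, log = TRUE)) +
                 sum(dnorm(Y[, 2], -0.1, 1, log = TRUE)), tolerance = 1e-10)
})

test_that("symmetric two-component model splits responsibilities evenly", {
  model <- metsubtype:::new_mfmr_model(NULL, rbind(-1, 1), NULL, 1, c(0.5, 0.5))
  es <- mfmr_e_step(model, matrix(0, 1, 1))  # midway between the means
  expect_equal(es$responsibilities[1, ], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("M-step with hard responsibilities equals the ANCOVA oracle", {
  set.seed(4)
  n <- 120
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  z <- sample(1:3, n, replace = TRUE)
  Y <- matrix(rnorm(n * 2), n, 2) + cbind(z * 0.5, -z)
  resp <- outer(z, 1:3, "==") * 1
  model <- mfmr_m_step(resp, Y, X)
  for (p in 1:2) {
    ref <- lm(Y[, p] ~ 0 + factor(z) + X)
    expect_equal(unname(model$gamma[, p]), unname(coef(ref)[1:3]), tolerance = 1e-8)
    expect_equal(unname(model$alpha[, p]), unname(coef(ref)[4:5]), tolerance = 1e-8)
  }
  expect_equal(unname(model$pi), as.numeric(table(z)) / n)
})

test_that("K = 1 M-step reduces to ordinary least squares", {
  set.seed(5)
  n <- 80
  X <- cbind(rnorm(n), runif(n))
  Y <- matrix(rnorm(n * 3), n, 3)
  model <- mfmr_m_step(matrix(1, n, 1), Y, X)
  for (p in 1:3) {
    ref <- lm(Y[, p] ~ X)
    expect_equal(unname(model$gamma[1, p]), unname(coef(ref)[1]), tolerance = 1e-8)
    expect_equal(unname(model$alpha[, p]), unname(coef(ref)[-1]), tolerance = 1e-8)
  }
  expect_error(mfmr_m_step(matrix(1, n, 1), Y, cbind(X, X[, 1])), "collinearity")
})

test_that("uniform responsibilities give identical subtype effects", {
  set.seed(6)
  Y <- matrix(rnorm(60), 30, 2)
  model <- mfmr_m_step(matrix(1 / 3, 30, 3), Y)
  expect_equal(model$gamma[1, ], model$gamma[2, ], tolerance = 1e-10)
  expect_equal(model$gamma[2, ], model$gamma[3, ], tolerance = 1e-10)
})

test_that("fitting K = 1 agrees with per-trait ordinary least squares", {
  set.seed(7)
  n <- 300
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  Y <- cbind(1 + 0.5 * X[, 1] + rnorm(n), -0.3 * X[, 2] + rnorm(n, sd = 0.5))
  fit <- fit_mfmr(Y, X, K = 1, n_restarts = 2, seed = 1)
  for (p in 1:2) {
    ref <- lm(Y[, p] ~ X)
    expect_equal(unname(fit$model$gamma[1, p]), unname(coef(ref)[1]),
                 tolerance = 1e-6)
    expect_equal(unname(fit$model$alpha[, p]), unname(coef(ref)[-1]),
                 tolerance = 1e-6)
  }
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("well-separated subtypes are recovered with the right parameters", {
  sc <- generate_cohort(recovery_spec(n = 1200), seed = 17)
  Y <- as.matrix(sc$traits_std[, -1])
  X <- generating_design(sc)
  fit <- suppressMessages(fit_mfmr(Y, X, K = 4, n_restarts = 5, seed = 2))
  asg <- assign_subtypes(fit)
  expect_gt(adjusted_rand_index(asg$labels, sc$z_true), 0.9)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_equal(rowSums(fit$responsibilities), rep(1, nrow(Y)), tolerance = 1e-9)
  # component-wise alignment to the generating parameters
  perm <- apply(fit$model$gamma %*% t(sc$spec$gamma_true), 1, which.max)
  expect_setequal(perm, 1:4)
  expect_lt(max(abs(fit$model$gamma - sc$spec$gamma_true[perm, ])), 0.25)
})

test_that("labeling is invariant to the initialization seed after canonical ordering", {
  sc <- generate_cohort(recovery_spec(n = 800), seed = 23)
  Y <- as.matrix(sc$traits_std[, -1])
  X <- generating_design(sc)
  f1 <- suppressMessages(fit_mfmr(Y, X, K = 4, n_restarts = 3, seed = 101))
  f2 <- suppressMessages(fit_mfmr(Y, X, K = 4, n_restarts = 3, seed = 202))
  l1 <- assign_subtypes(f1)$labels
  l2 <- assign_subtypes(f2)$labels
  expect_gt(mean(l1 == l2), 0.98)
  # likelihood is invariant under component relabeling
  shuffled <- f1$model
  ord <- c(3, 1, 4, 2)
  shuffled$gamma <- shuffled$gamma[ord, ]; shuffled$pi <- shuffled$pi[ord]
  expect_equal(mfmr_e_step(shuffled, Y, X)$loglik,
               mfmr_e_step(f1$model, Y, X)$loglik, tolerance = 1e-8)
})

test_that("canonical ordering is deterministic, idempotent and involutive", {
  gamma <- rbind(c(0.2, 3, 0, 0), c(3, 0, 0.5, 0), c(0, 0, 0, 3), c(0, 0.1, 3, 0))
  model <- metsubtype:::new_mfmr_model(NULL, gamma, NULL, rep(1, 4),
                                       c(0.1, 0.2, 0.3, 0.4))
  ord <- canonical_order(model)
  # dominant traits 2,1,4,3 -> reordered to traits 1,2,3,4
  expect_equal(apply(ord$gamma, 1, which.max), 1:4)
  expect_equal(canonical_order(ord), ord)          # idempotent
  swapped <- ord
  swapped$gamma <- swapped$gamma[c(2, 1, 3, 4), ]
  swapped$pi <- swapped$pi[c(2, 1, 3, 4)]
  expect_equal(canonical_order(swapped)$gamma, ord$gamma)  # involution
  # ties in the dominant trait break by descending mixing weight
  tied <- metsubtype:::new_mfmr_model(NULL, rbind(c(3, 0), c(3, 0)), NULL,
                                      c(1, 1), c(0.3, 0.7))
  expect_equal(canonical_order(tied)$pi, c(0.7, 0.3))
})

test_that("hard assignment takes the arg-max with ties to the smallest label", {
  model <- metsubtype:::new_mfmr_model(NULL, rbind(0, 0), NULL, 1, c(0.5, 0.5))
  asg <- assign_subtypes(model, Y = matrix(c(0, 1), 2, 1))
  expect_equal(asg$labels, c(1, 1))   # exact ties -> smallest k
  fitlike <- structure(list(responsibilities = rbind(c(0.9, 0.1), c(0.2, 0.8))),
                       class = "mfmr_fit")
  expect_equal(assign_subtypes(fitlike)$labels, c(1, 2))
})

test_that("cross-validated likelihood selects a plausible K", {
  expect_error(select_k(matrix(rnorm(40), 20, 2), k_range = integer(0)), "nonempty")
  # k_range = {1} must return 1
  Y <- matrix(rnorm(200), 100, 2)
  ks1 <- select_k(Y, k_range = 1, n_folds = 3, seed = 1, n_restarts = 1)
  expect_equal(ks1$chosen_k, 1L)
  # two clearly separated components at small n
  set.seed(9)
  z <- rep(1:2, each = 150)
  Y2 <- matrix(rnorm(300 * 2), 300, 2) + cbind(ifelse(z == 1, -2, 2), 0)
  ks2 <- suppressMessages(select_k(Y2, k_range = 1:3, n_folds = 4, seed = 5,
                                   n_restarts = 3))
  # the true two-cluster structure must be detected; a single draw may
  # tolerate one spurious extra component, never fewer
  expect_true(ks2$chosen_k %in% 2:3)
  expect_gt(ks2$summary$mean_holdout_loglik[2],
            ks2$summary$mean_holdout_loglik[1])
  expect_equal(ks2$summary$K, 1:3)
  expect_error(select_k(Y2[1:8, ], k_range = 1:6, n_folds = 4, seed = 1),
               "folds too small")
})

test_that("held-out likelihood does not reward extra components on K = 1 data", {
  lls <- purrr::map(1:3, function(rep) {
    set.seed(rep * 11)
    Y <- matrix(rnorm(300 * 2), 300, 2)
    suppressMessages(select_k(Y, k_range = c(1, 3), n_folds = 3,
                              seed = rep, n_restarts = 2))$summary
  })
  diffs <- purrr::map_dbl(lls, function(s) {
    s$mean_holdout_loglik[s$K == 1] - s$mean_holdout_loglik[s$K == 3]
  })
  expect_gt(mean(diffs), 0)
})

test_that("focal covariates with subtype-specific slopes are estimated", {
  set.seed(12)
  n <- 600
  z <- sample(1:2, n, replace = TRUE)
  g <- cbind(dose = rnorm(n))
  beta_true <- c(1.5, -1.5)
  Y <- cbind(ifelse(z == 1, -2, 2) + beta_true[z] * g[, 1] + rnorm(n, sd = 0.5))
  fit <- suppressMessages(fit_mfmr(Y, X = NULL, g = g, K = 2, n_restarts = 4,
                                   seed = 3, canonical = FALSE))
  ord <- order(fit$model$gamma[, 1])
  expect_lt(abs(fit$model$gamma[ord[1], 1] - (-2)), 0.2)
  expect_lt(abs(fit$model$beta[ord[1], 1, 1] - 1.5), 0.25)
  expect_lt(abs(fit$model$beta[ord[2], 1, 1] - (-1.5)), 0.25)
})

test_that("broom and plotting methods expose the fit", {
  sc <- generate_cohort(recovery_spec(n = 600), seed = 31)
  Y <- as.matrix(sc$traits_std[, -1])
  fit <- suppressMessages(fit_mfmr(Y, generating_design(sc), K = 4,
                                   n_restarts = 3, seed = 4))
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("gamma", "sigma2", "pi", "alpha"))
  expect_equal(sum(td$term == "gamma"), 40)
  gl <- glance(fit)
  expect_equal(gl$K, 4)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
  ks <- suppressMessages(select_k(Y[1:300, ], k_range = 1:2, n_folds = 3,
                                  seed = 2, n_restarts = 2))
  expect_s3_class(autoplot(ks), "ggplot")
  expect_equal(tidy(ks), ks$summary)
})
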