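test_that("Hardy-Weinberg chi-square matches hand evaluation", {
  eq <- hwe_test(25, 50, 25)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  # complete heterozygote deficit at p = q = 0.5: chi2 = n
  def <- hwe_test(50, 0, 50)
  expect_equal(def$chi2, 100)
  expect_lt(def$p, 1e-4)
  # monomorphic variant is defined as perfectly in equilibrium
  mono <- hwe_test(100, 0, 0)
  expect_equal(mono$chi2, 0)
  expect_equal(mono$p, 1)
  expect_error(hwe_test(-1, 5, 5), "non-negative")
  expect_error(hwe_test(0, 0, 0), "positive")
  # vectorised call agrees with element-wise calls
  v <- hwe_test(c(25, 50), c(50, 0), c(25, 50))
  expect_equal(v$chi2, c(0, 100))
})

test_that("engineered variants fail exactly the intended QC rule", {
  set.seed(61)
  n <- 1000
  make_hw <- function(maf) rbinom(n, 2, maf)
  G <- cbind(v_ok = make_hw(0.3),
             v_callrate = make_hw(0.3),
             v_hwe = rep(c(0L, 2L), n / 2),   # no heterozygotes at all
             v_rare = make_hw(0.004),
             v_ok2 = make_hw(0.4))
  G[1:2, "v_callrate"] <- NA               # call rate 0.998 < 0.999
  rownames(G) <- sprintf("S%04d", 1:n)
  qc <- variant_qc(G, maf_min = 0.01)
  expect_equal(qc$id[qc$fail_call_rate], "v_callrate")
  expect_equal(qc$id[qc$fail_hwe], "v_hwe")
  expect_equal(qc$id[qc$fail_maf], "v_rare")
  expect_setequal(qc$id[qc$qc_pass], c("v_ok", "v_ok2"))
  # a complete, equilibrium variant passes
  expect_true(qc$qc_pass[qc$id == "v_ok"])
})

test_that("Hardy-Weinberg QC can be restricted to controls", {
  set.seed(67)
  n <- 1200
  controls <- sprintf("C%04d", 1:600)
  cases <- sprintf("A%04d", 1:600)
  # equilibrium in controls, strong deviation in cases
  g <- c(rbinom(600, 2, 0.3), rep(c(0L, 2L), 300))
  G <- matrix(g, ncol = 1, dimnames = list(c(controls, cases), "v1"))
  qc_all <- variant_qc(G)
  qc_ctrl <- variant_qc(G, control_ids = controls)
  expect_true(qc_all$fail_hwe)
  expect_false(qc_ctrl$fail_hwe)
})

test_that("sample QC drops low call rate and heterozygosity outliers", {
  set.seed(71)
  n <- 500; m <- 400
  # homogeneous heterozygosity: every individual carries the same genotype
  # counts in a different order, so the het-rate spread is exactly zero
  template <- rep(c(0L, 1L, 2L), times = c(200, 150, 50))
  G <- t(vapply(seq_len(n), function(i) sample(template), integer(m)))
  rownames(G) <- sprintf("S%04d", 1:n)
  sq0 <- sample_qc(G)
  expect_true(all(sq0$keep))              # complete data, no outliers
  G[1, seq_len(0.02 * m)] <- NA           # 2% missing -> call rate 0.98
  G[2, ] <- 1L                            # all-heterozygous individual
  sq <- sample_qc(G)
  expect_false(sq$keep[1])
  expect_true(sq$fail_call_rate[1])
  expect_false(sq$keep[2])
  expect_true(sq$fail_het[2])
  expect_gte(sum(sq$keep), n - 4)
})

test_that("association scan recovers a causal effect and flags it", {
  z <- rep(c(0, 1), 1000)
  gg <- generate_genotypes(genotype_spec(n_variants = 30, fraction_causal = 0,
                                         missing_rate = 0.001),
                           z_true = z, seed = 73, ids = sprintf("S%05d", 1:2000))
  causal <- generate_genotypes(genotype_spec(n_variants = 1, fraction_causal = 1,
                                             causal_log_or = 2, missing_rate = 0,
                                             maf_range = c(0.15, 0.25),
                                             causal_subtype = 1),
                               z_true = z, seed = 74, ids = sprintf("S%05d", 1:2000))
  G <- cbind(gg$genotypes, causal = causal$genotypes[, 1])
  res <- run_ewas(G, case_ids = rownames(G)[z == 1],
                  control_ids = rownames(G)[z == 0])
  hit <- res[res$id == "causal", ]
  expect_equal(hit$status, "ok")
  expect_lt(abs(abs(hit$beta) - 2), 0.3)
  expect_equal(res$id[which.min(res$p)], "causal")
  expect_true(hit$genome_wide)
  expect_true(hit$suggestive)
  # flag consistency: genome-wide significance implies suggestive
  expect_true(all(!res$genome_wide | res$suggestive))
})

test_that("monomorphic variants are reported as non-estimable", {
  z <- rep(c(0, 1), 50)
  G <- cbind(mono = rep(0L, 100), ok = rbinom(100, 2, 0.4))
  rownames(G) <- sprintf("S%03d", 1:100)
  res <- run_ewas(G, rownames(G)[z == 1], rownames(G)[z == 0])
  expect_equal(res$status[res$id == "mono"], "non_estimable")
  expect_true(is.na(res$p[res$id == "mono"]))
  expect_equal(res$status[res$id == "ok"], "ok")
})

test_that("scan results are invariant to individual order and allele relabeling", {
  set.seed(79)
  n <- 600
  z <- rbinom(n, 1, 0.5)
  G <- matrix(rbinom(n * 20, 2, runif(20, 0.1, 0.45)), n, 20, byrow = TRUE,
              dimnames = list(sprintf("S%04d", 1:n), sprintf("v%02d", 1:20)))
  cases <- rownames(G)[z == 1]; controls <- rownames(G)[z == 0]
  r1 <- run_ewas(G, cases, controls)
  perm <- sample(n)
  r2 <- run_ewas(G[perm, ], cases, controls)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  # relabel which allele is counted: p unchanged, effect magnitude preserved
  r3 <- run_ewas(2L - G, cases, controls)
  expect_equal(r1$p, r3$p, tolerance = 1e-8)
  expect_equal(abs(r1$beta), abs(r3$beta), tolerance = 1e-8)
})

test_that("an unadjusted binary-exposure scan matches the 2x2 oracle", {
  # collapsed genotype acts as a binary exposure
  y <- rep(c(1, 0, 1, 0), c(30, 70, 15, 85))
  g <- rep(c(1L, 0L), c(100, 100))
  G <- matrix(g, ncol = 1, dimnames = list(sprintf("S%03d", 1:200), "v1"))
  res <- run_ewas(G, case_ids = rownames(G)[y == 1], control_ids = rownames(G)[y == 0])
  expect_equal(res$beta, log((30 * 85) / (70 * 15)), tolerance = 1e-6)
  expect_equal(res$se, sqrt(1 / 30 + 1 / 70 + 1 / 15 + 1 / 85), tolerance = 1e-6)
})
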