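test_that("Stouffer combination matches its closed forms", {
  expect_equal(stouffer_combine(c(0.5, 0.5, 0.5)), 0.5, tolerance = 1e-12)
  # three p = 0.05: 1 - Phi(sqrt(3) * Phi^-1(0.95))
  oracle <- pnorm(sqrt(3) * qnorm(0.95), lower.tail = FALSE)
  expect_equal(stouffer_combine(rep(0.05, 3)), oracle, tolerance = 1e-12)
  expect_equal(oracle, 2.2e-3, tolerance = 0.05)
  # strict monotonicity in any component
  p0 <- stouffer_combine(c(0.2, 0.4, 0.6))
  expect_lt(stouffer_combine(c(0.1, 0.4, 0.6)), p0)
  expect_lt(stouffer_combine(c(0.2, 0.4, 0.3)), p0)
  # boundary clamping warns but returns a valid p
  expect_warning(pc <- stouffer_combine(c(0, 0.5)), "clamped")
  expect_gt(pc, 0); expect_lt(pc, 1)
  # equal weights reproduce the unweighted form
  expect_equal(stouffer_combine(c(0.01, 0.2, 0.7), weights = c(2, 2, 2)),
               stouffer_combine(c(0.01, 0.2, 0.7)), tolerance = 1e-12)
})

test_that("Li-Ji effective test count matches hand-computed cases", {
  expect_equal(effective_tests(diag(7)), 7)
  expect_equal(effective_tests(matrix(1, 5, 5)), 1)
  # 2x2 with off-diagonal 0.5: eigenvalues 1.5 and 0.5 -> 1 + 0.5 + 0 + 0.5
  C <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(effective_tests(C), 2.0)
  # duplicating a perfectly correlated column leaves M_eff unchanged
  set.seed(1)
  X <- matrix(rnorm(300), 100, 3)
  M1 <- effective_tests(cor(X))
  M2 <- effective_tests(cor(cbind(X, X[, 2])))
  expect_lt(abs(M1 - M2), 1e-6)
  # bounds on random correlation matrices
  for (s in 1:5) {
    set.seed(s)
    Cs <- cor(matrix(rnorm(40 * 6), 40, 6))
    m <- effective_tests(Cs)
    expect_gte(m, 1); expect_lte(m, 6 + 1e-9)
  }
  expect_error(effective_tests(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("the adjusted Bonferroni threshold follows the effective counts", {
  thr <- bonferroni_threshold(0.05, 37, 56, 3)
  expect_equal(thr$adjusted_threshold, 0.05 / (37 * 56 * 3), tolerance = 1e-12)
  expect_equal(bonferroni_threshold(0.05, 1, 1, 1)$adjusted_threshold, 0.05)
  # linear in alpha
  expect_equal(bonferroni_threshold(0.1, 5, 7, 3)$adjusted_threshold,
               2 * bonferroni_threshold(0.05, 5, 7, 3)$adjusted_threshold)
  expect_error(bonferroni_threshold(0.05, 0, 56, 3), "positive")
})

# One small pipeline fixture shared by the round-robin bookkeeping tests.
rr_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tpl <- tiny_template(40)
    cfg <- sim_config(n_per_cohort = c(80, 70, 90), L = 40,
                      mafs = c(snp_1 = 0.3, snp_2 = 0.45),
                      effect_segments = list(snp_1 = 5:12),
                      effect_size = c(snp_1 = 1.5), seed = 21)
    sim <- simulate_cohorts(tpl, cfg)
    res <- suppressWarnings(run_pipeline(sim, depth = 2, pa_reps = 20, seed = 22))
    cache <<- list(sim = sim, res = res, tpl = tpl)
    cache
  }
})

test_that("round-robin bookkeeping: nine p-values and three meta p-values", {
  fx <- rr_fixture()
  mt <- fx$res$meta_table
  cohorts <- paste0("cohort_", 1:3)
  expect_equal(nrow(mt), 2 * 7)                     # 2 SNPs x 7 segments
  expect_setequal(grep("^p_disc_", names(mt), value = TRUE),
                  paste0("p_disc_", cohorts))
  rep_cols <- grep("^p_rep_", names(mt), value = TRUE)
  expect_length(rep_cols, 6)
  expect_setequal(grep("^p_meta_", names(mt), value = TRUE),
                  paste0("p_meta_", cohorts))
  # each meta p combines exactly its discovery row
  row <- mt[3, ]
  for (d in cohorts) {
    reps <- setdiff(cohorts, d)
    expect_equal(row[[paste0("p_meta_", d)]],
                 stouffer_combine(c(row[[paste0("p_disc_", d)]],
                                    row[[paste0("p_rep_", d, "_", reps[1])]],
                                    row[[paste0("p_rep_", d, "_", reps[2])]])),
                 tolerance = 1e-12)
  }
  # all p-values in (0, 1]
  pcols <- grep("^p_", names(mt), value = TRUE)
  expect_true(all(as.matrix(mt[, pcols]) > 0 & as.matrix(mt[, pcols]) <= 1))
})

test_that("meta p-values ignore the ordering of the replication cohorts", {
  fx <- rr_fixture()
  seg <- fx$res$seg_pca
  geno <- lapply(fx$res$corrected, `[[`, "genotype_residuals")
  a <- run_round_robin(seg, geno, n_covariates = 10)
  b <- run_round_robin(seg, geno[c(3, 1, 2)], n_covariates = 10)
  for (d in paste0("p_meta_cohort_", 1:3))
    expect_equal(a[[d]], b[[d]], tolerance = 1e-12)
  # restricting to a segment subset keeps only those rows
  leaves <- seg$tree$nodes$node_id[seg$tree$nodes$level == 2]
  c2 <- run_round_robin(seg, geno, n_covariates = 10, segments = leaves)
  expect_setequal(unique(c2$segment_id), leaves)
  # fewer than two cohorts is refused; a missing SNP column is skipped
  expect_error(run_round_robin(seg, geno[1]), ">= 2")
  geno_miss <- geno
  geno_miss[[2]] <- geno_miss[[2]][, "snp_1", drop = FALSE]
  expect_warning(m <- run_round_robin(seg, geno_miss, n_covariates = 10),
                 "skipping")
  expect_setequal(unique(m$snp_id), "snp_1")
})

test_that("segment correlations are strongest along the hierarchy", {
  fx <- rr_fixture()
  C <- segment_correlation_matrix(fx$res$seg_pca)
  expect_true(isSymmetric(C))
  expect_equal(unname(diag(C)), rep(1, nrow(C)))
  # parent-child overlap beats disjoint segments on average
  tree <- fx$res$tree
  pc <- c(C["1", "2"], C["1", "3"], C["2", "4"], C["3", "6"])
  disjoint <- c(C["4", "6"], C["4", "7"], C["5", "6"], C["5", "7"])
  expect_gt(mean(pc), mean(disjoint))
  # effective segments between 1 and the segment count
  m <- effective_tests(C)
  expect_gte(m, 1); expect_lte(m, nrow(C))
})

test_that("significant SNPs are those crossing the adjusted threshold", {
  fx <- rr_fixture()
  mt <- fx$res$meta_table
  thr <- attr(mt, "threshold")
  expect_s3_class(thr, "threshold_spec")
  pm <- as.matrix(mt[, grep("p_meta", names(mt))])
  manual <- unique(mt$snp_id[rowSums(pm < thr$adjusted_threshold) > 0])
  expect_setequal(significant_snps(mt), manual)
  # the planted SNP is detected, the null SNP is not
  expect_true("snp_1" %in% significant_snps(mt))
  expect_false("snp_2" %in% significant_snps(mt))
})
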