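test_that("with one PC the CCA test reduces to simple regression", {
  set.seed(1)
  n <- 60
  s <- matrix(rnorm(n), n, 1)
  g <- rbinom(n, 2, 0.3) + 0.3 * s[, 1]
  rec <- cca_test(s, g)
  expect_equal(rec$cc, abs(cor(s[, 1], g)), tolerance = 1e-12)
  fit <- summary(lm(g ~ s))
  expect_equal(rec$p_value, unname(pf(fit$fstatistic[1], 1, n - 2,
                                      lower.tail = FALSE)), tolerance = 1e-12)
})

test_that("canonical correlation equals the OLS multiple correlation", {
  set.seed(2)
  n <- 50
  S <- matrix(rnorm(n * 3), n, 3)
  g <- rbinom(n, 2, 0.4) + S %*% c(0.2, -0.1, 0.3)
  rec <- cca_test(S, g)
  R <- sqrt(summary(lm(g ~ S))$r.squared)
  expect_equal(rec$cc, R, tolerance = 1e-10)
  # Rao F p-value equals the overall-regression F p-value
  fit <- summary(lm(g ~ S))
  expect_equal(rec$p_value,
               unname(pf(fit$fstatistic[1], fit$fstatistic[2],
                         fit$fstatistic[3], lower.tail = FALSE)),
               tolerance = 1e-10)
  # degenerate inputs are refused
  expect_error(cca_test(S, rep(1, n)), "monomorphic")
  expect_error(cca_test(matrix(rnorm(5 * 4), 5, 4), rbinom(5, 2, 0.5)),
               "truncate")
})

test_that("loadings orientation makes results allele-coding invariant", {
  set.seed(3)
  n <- 80
  S <- matrix(rnorm(n * 4), n, 4)
  g <- rbinom(n, 2, 0.35)
  g <- g + S %*% c(0.3, 0, -0.2, 0.1)
  rec <- cca_test(S, g)
  # oriented: projected score regresses positively on the genotype
  expect_gt(cov(S %*% rec$loadings, g)[1], 0)
  expect_equal(sqrt(sum(rec$loadings^2)), 1, tolerance = 1e-12)
  # recoding on the opposite allele flips loadings, keeps p-values
  rec2 <- cca_test(S, 2 - g)
  expect_equal(rec2$loadings, -rec$loadings, tolerance = 1e-8)
  expect_equal(rec2$p_value, rec$p_value, tolerance = 1e-12)
  expect_equal(rec2$cc, rec$cc, tolerance = 1e-12)
})

test_that("self-replication reproduces the canonical correlation", {
  set.seed(4)
  n <- 70
  S <- matrix(rnorm(n * 5), n, 5)
  g <- rbinom(n, 2, 0.25) + S %*% c(0.4, -0.2, 0, 0.1, 0)
  rec <- cca_test(S, g)
  pr <- project_and_test(rec$loadings, S, g)
  y <- S %*% rec$loadings
  expect_equal(abs(cor(y, g))[1], rec$cc, tolerance = 1e-10)
  # flipped loadings negate t and map one-sided p to its complement
  pr_flip <- project_and_test(-rec$loadings, S, g)
  expect_equal(pr_flip$t_statistic, -pr$t_statistic, tolerance = 1e-10)
  expect_equal(pr_flip$p_value, 1 - pr$p_value, tolerance = 1e-10)
  expect_error(project_and_test(rec$loadings[-1], S, g), "match")
})

test_that("replication p-values are uniform under permuted genotypes", {
  set.seed(5)
  n <- 100
  S <- matrix(rnorm(n * 3), n, 3)
  g <- rbinom(n, 2, 0.3)
  loadings <- c(1, 1, 1) / sqrt(3)
  ps <- replicate(1000, project_and_test(loadings, S, sample(g))$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("discovery p-values match a permutation oracle under the null", {
  set.seed(6)
  n <- 50
  S <- matrix(rnorm(n * 3), n, 3)
  g <- rbinom(n, 2, 0.4)
  rec <- cca_test(S, g)
  # permutation distribution of the squared multiple correlation
  Sc <- scale(S, scale = FALSE)
  H <- Sc %*% solve(crossprod(Sc), t(Sc))
  r2_of <- function(gg) {
    gc <- gg - mean(gg)
    sum((H %*% gc)^2) / sum(gc^2)
  }
  r2_obs <- r2_of(g)
  B <- 2000
  perm <- replicate(B, r2_of(sample(g)))
  p_perm <- (1 + sum(perm >= r2_obs)) / (B + 1)
  se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(rec$p_value - p_perm), 3 * se + 0.01)
})

test_that("variance explained matches the regression decomposition", {
  set.seed(7)
  n <- 90
  S <- matrix(rnorm(n * 4), n, 4)
  g <- as.numeric(rbinom(n, 2, 0.3))
  # oracle: per-column simple regression explained sum of squares
  Sc <- scale(S, scale = FALSE); gc <- g - mean(g)
  ess <- sum(vapply(1:4, function(j) {
    b <- sum(Sc[, j] * gc) / sum(gc^2)
    sum((b * gc)^2)
  }, numeric(1)))
  expect_equal(variance_explained(S, g), 100 * ess / sum(Sc^2),
               tolerance = 1e-8)
  # orthogonal genotype -> 0; exact linear scores -> 100
  gperp <- gc - Sc %*% solve(crossprod(Sc), crossprod(Sc, gc))
  expect_lt(variance_explained(S, gperp + mean(g)), 1e-10 + 100 * 1e-10)
  Slin <- gc %*% t(c(1, -2, 0.5, 3))
  expect_equal(variance_explained(Slin, g), 100, tolerance = 1e-10)
})

test_that("canonical correlation grows monotonically with planted effect", {
  med_cc <- vapply(c(0, 0.3, 0.8), function(beta) {
    ccs <- vapply(1:8, function(s) {
      set.seed(1000 + s)
      n <- 150
      S <- matrix(rnorm(n * 3), n, 3)
      g <- rbinom(n, 2, 0.3)
      S[, 1] <- S[, 1] + beta * g
      cca_test(S, g)$cc
    }, numeric(1))
    median(ccs)
  }, numeric(1))
  expect_true(all(diff(med_cc) >= 0))
})

test_that("effect visualization reconstructs mirror-displaced mean shapes", {
  tpl <- tiny_template(24, seed = 5)
  tree <- single_node_tree(24)
  set.seed(8)
  n <- 300
  g <- rbinom(n, 2, 0.4)
  U <- matrix(0, 24, 3); U[5:10, ] <- matrix(rnorm(18), 6, 3)
  U <- U / sqrt(mean(rowSums(U[5:10, ]^2)))
  A <- array(rep(tpl$coords, each = n), dim = c(n, 24, 3)) +
    outer(g * 0.8, U) + array(rnorm(n * 72, sd = 0.5), dim = c(n, 24, 3))
  sp <- suppressWarnings(segment_pca(A, tree, rep("c1", n), pa_reps = 40, seed = 9))
  seg <- sp$segments[["1"]]
  rec <- cca_test(seg$scores, g, segment_id = 1L)
  viz <- effect_visualization(sp, rec, exaggeration = 2)
  # zero exaggeration returns the mean twice; +/- displacements mirror
  viz0 <- effect_visualization(sp, rec, exaggeration = 0)
  expect_equal(viz0$minor, seg$mean_config)
  expect_equal(viz0$major, seg$mean_config)
  expect_equal(viz$minor + viz$major, 2 * seg$mean_config, tolerance = 1e-10)
  # the reconstructed per-allele field points along the planted field
  R <- opa_rotation(scale(tpl$coords, scale = FALSE), seg$mean_config)
  expect_gt(cosine_fields(viz$direction, U %*% R), 0.8)
})
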