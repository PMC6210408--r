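#' Canonical-correlation association test for one SNP in one segment
#'
#' Tests a single SNP (additive minor-allele code, residualized on
#' confounders) against the retained PC scores of one facial segment by
#' canonical correlation analysis. With a univariate genotype block the
#' canonical correlation equals the multiple correlation of the genotype on
#' the PCs, Wilks' Lambda is `1 - r^2`, and significance uses the Rao F
#' approximation (right tail):
#' `F = ((1 - Lambda) / Lambda) * ((n - p - 1) / p)` on `(p, n - p - 1)`
#' degrees of freedom — exactly the overall-regression F in this univariate
#' reduction.
#'
#' The phenotype loadings (the PC combination maximally correlated with the
#' genotype) are returned unit-normalized and sign-oriented so that the
#' projected score regresses on the genotype with a positive slope; this
#' orientation is what makes the one-sided replication tests well-defined.
#'
#' @param pc_scores `n x p` matrix of segment PC scores (centred within
#'   cohort by the caller or here).
#' @param genotype length-`n` residualized additive genotype.
#' @param n_covariates number of confounders both sides were residualized on
#'   before testing; each one costs a residual degree of freedom, so the F
#'   denominator df is `n - p - 1 - n_covariates` (the partial-correlation
#'   form; 0 when testing unresidualized data).
#' @param snp_id,segment_id,cohort_id identifiers carried into the record.
#' @return an object of class `assoc_record`: `snp_id`, `segment_id`,
#'   `cohort_id`, `cc` (canonical correlation), `p_value`, `pct_var_explained`,
#'   `loadings` (unit vector), `score_slope` (per-PC regression slopes on the
#'   genotype, used for effect reconstruction), `n`, `p`.
#' @export
cca_test <- function(pc_scores, genotype, n_covariates = 0L, snp_id = "snp",
                     segment_id = 1L, cohort_id = "cohort_1") {
  S <- as.matrix(pc_scores)
  g <- as.numeric(genotype)
  n <- nrow(S); p <- ncol(S)
  if (length(g) != n) stop("genotype length must match score rows")
  if (stats::var(g) == 0) stop("monomorphic SNP")
  if (n <= p + 1L + n_covariates)
    stop("n must exceed p + 1 (+ covariate df); truncate the PC space before testing")
  Sc <- scale(S, center = TRUE, scale = FALSE)
  gc <- g - mean(g)
  xty <- crossprod(Sc, gc)
  b <- drop(qr.coef(qr(Sc), gc))       # least-squares, stable when Sc is ill-conditioned
  b[is.na(b)] <- 0
  r2 <- drop(crossprod(xty, b)) / sum(gc^2)
  r2 <- min(max(r2, 0), 1)
  lambda <- 1 - r2
  if (lambda < 1e-15) lambda <- 1e-15
  df2 <- n - p - 1 - n_covariates
  Fstat <- ((1 - lambda) / lambda) * (df2 / p)
  p_value <- stats::pf(Fstat, p, df2, lower.tail = FALSE)
  loadings <- b / sqrt(sum(b^2))
  if (drop(crossprod(Sc %*% loadings, gc)) < 0) loadings <- -loadings
  structure(list(snp_id = snp_id, segment_id = segment_id,
                 cohort_id = cohort_id,
                 cc = sqrt(r2), p_value = p_value,
                 pct_var_explained = variance_explained(S, g),
                 loadings = loadings,
                 score_slope = drop(xty) / sum(gc^2),
                 n = n, p = p),
            class = "assoc_record")
}

#' Projection replication test
#'
#' Projects a replication cohort's segment PC scores onto the discovery
#' loadings, producing a univariate phenotype, and tests it against the
#' replication genotype by simple linear regression with a positive-sided
#' p-value: `p = P(T_{m-2} > t)` for the genotype slope. Because discovery
#' loadings are oriented toward a positive slope, a replicating effect in the
#' same direction yields a small p.
#'
#' @param loadings discovery loadings (length `p`).
#' @param replication_scores `m x p` matrix, same segment PC basis (pooled
#'   shape space) restricted to the replication cohort.
#' @param replication_genotype length-`m` residualized genotype.
#' @param n_covariates confounder count absorbed by residualization (as in
#'   [cca_test()]); the t reference has `m - 2 - n_covariates` df.
#' @param snp_id,segment_id,discovery_cohort,replication_cohort identifiers.
#' @return a `replication_record` list: identifiers, `t_statistic`,
#'   `p_value`.
#' @export
project_and_test <- function(loadings, replication_scores, replication_genotype,
                             n_covariates = 0L, snp_id = "snp", segment_id = 1L,
                             discovery_cohort = "discovery",
                             replication_cohort = "replication") {
  S <- as.matrix(replication_scores)
  if (ncol(S) != length(loadings))
    stop("loadings length must match the replication score dimension")
  g <- as.numeric(replication_genotype)
  m <- nrow(S)
  if (length(g) != m) stop("genotype length must match score rows")
  y <- drop(scale(S %*% loadings, center = TRUE, scale = FALSE))
  gc <- g - mean(g)
  sxx <- sum(gc^2)
  if (sxx == 0) stop("monomorphic SNP")
  slope <- sum(gc * y) / sxx
  res <- y - slope * gc
  df <- m - 2 - n_covariates
  se <- sqrt(sum(res^2) / df / sxx)
  t_stat <- slope / se
  structure(list(snp_id = snp_id, segment_id = segment_id,
                 discovery_cohort = discovery_cohort,
                 replication_cohort = replication_cohort,
                 t_statistic = t_stat,
                 p_value = stats::pt(t_stat, df, lower.tail = FALSE)),
            class = "replication_record")
}

#' Percentage of segment shape variance explained by a SNP
#'
#' One-component partial least-squares regression of the segment PC scores on
#' the genotype; with a univariate predictor this equals per-column simple
#' regression, and the statistic is 100 times the explained sum of squares
#' over the total (centred) sum of squares of the scores.
#'
#' @inheritParams cca_test
#' @return percentage in `[0, 100]`.
#' @export
variance_explained <- function(pc_scores, genotype) {
  S <- as.matrix(pc_scores)
  g <- as.numeric(genotype)
  if (stats::var(g) == 0) stop("monomorphic SNP")
  Sc <- scale(S, center = TRUE, scale = FALSE)
  gc <- g - mean(g)
  coefs <- drop(crossprod(Sc, gc)) / sum(gc^2)
  ss_exp <- sum(gc^2) * sum(coefs^2)
  100 * ss_exp / sum(Sc^2)
}

#' Reconstruct and exaggerate a SNP's shape effect
#'
#' Reconstructs the per-allele displacement field of a SNP in a segment by
#' passing the discovery regression slopes of the PC scores through the
#' segment's PC basis, then displaces the segment mean shape by plus/minus
#' `exaggeration` times that field: the `minor` configuration shows the shape
#' change per additional minor allele (exaggerated), the `major`
#' configuration the opposite displacement.
#'
#' @param seg_pca a [segment_pca()] object.
#' @param record an [cca_test()] `assoc_record` for a segment of `seg_pca`.
#' @param exaggeration displacement multiplier (0 returns the mean twice).
#' @return list with `minor` and `major` `k x 3` configurations and the
#'   `direction` field (`k x 3`, per minor allele).
#' @export
effect_visualization <- function(seg_pca, record, exaggeration = 1) {
  stopifnot(inherits(seg_pca, "segment_pca"), inherits(record, "assoc_record"))
  seg <- seg_pca$segments[[as.character(record$segment_id)]]
  if (is.null(seg)) stop("record's segment is not in the segment PCA")
  dir_flat <- drop(seg$basis %*% record$score_slope)
  if (sqrt(sum(dir_flat^2)) < 1e-300) stop("no effect to display")
  k <- length(seg$landmarks)
  direction <- unflatten_coords(matrix(dir_flat, nrow = 1))[1, , ]
  mean_cfg <- seg$mean_config
  list(minor = mean_cfg + exaggeration * direction,
       major = mean_cfg - exaggeration * direction,
       direction = direction)
}
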