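#' Stouffer combination of one-sided p-values
#'
#' Transforms each p to a standard normal quantile `z_i = qnorm(1 - p_i)`,
#' sums `Z = sum(w_i z_i) / sqrt(sum(w_i^2))` (unweighted by default), and
#' returns `1 - pnorm(Z)`. Inputs at 0 or 1 are clamped to the
#' machine-representable open interval with a warning.
#'
#' @param p_values numeric vector of one-sided p-values in `(0, 1)`;
#'   independence is the caller's responsibility.
#' @param weights optional positive weights (e.g. sample sizes); default
#'   unweighted.
#' @return combined one-sided p-value.
#' @export
stouffer_combine <- function(p_values, weights = NULL) {
  p <- as.numeric(p_values)
  if (length(p) < 1L) stop("need at least one p-value")
  if (any(p <= 0) || any(p >= 1)) {
    warning("p-values at 0 or 1 clamped to the open interval")
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  }
  z <- stats::qnorm(p, lower.tail = FALSE)
  if (is.null(weights)) weights <- rep(1, length(p))
  if (length(weights) != length(p) || any(weights <= 0))
    stop("weights must be positive and match the p-values")
  Z <- sum(weights * z) / sqrt(sum(weights^2))
  stats::pnorm(Z, lower.tail = FALSE)
}

#' Li-Ji effective number of independent tests
#'
#' Estimates the number of effectively independent tests among `M` correlated
#' ones from the eigenvalues `lambda_i` of the absolute-value correlation
#' matrix: `M_eff = sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`.
#' Equals `M` for the identity and 1 for total redundancy.
#'
#' @param correlation symmetric `M x M` correlation-type matrix with unit
#'   diagonal.
#' @return scalar `M_eff` in `[1, M]`.
#' @export
effective_tests <- function(correlation) {
  C <- as.matrix(correlation)
  if (nrow(C) != ncol(C) || !isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
    stop("correlation matrix must be square and symmetric")
  ev <- eigen(abs(C), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev[abs(ev - round(ev)) < 1e-8] <- round(ev[abs(ev - round(ev)) < 1e-8])
  sum((ev >= 1) + (ev - floor(ev)))
}

#' Multivariate correlation between facial segments
#'
#' Pairwise Escoufier RV coefficients between the retained PC score blocks of
#' every pair of segments (pooled individuals); the eigenvalues of this
#' matrix feed [effective_tests()] to count independent segments.
#'
#' @param seg_pca a [segment_pca()] object.
#' @return symmetric matrix with unit diagonal, one row/column per segment,
#'   dimnames = node ids.
#' @export
segment_correlation_matrix <- function(seg_pca) {
  stopifnot(inherits(seg_pca, "segment_pca"))
  keys <- names(seg_pca$segments)
  M <- length(keys)
  out <- diag(1, M)
  dimnames(out) <- list(keys, keys)
  for (i in seq_len(M - 1L)) {
    Si <- seg_pca$segments[[keys[i]]]$scores
    for (j in (i + 1L):M) {
      rv <- rv_coefficient(Si, seg_pca$segments[[keys[j]]]$scores)
      out[i, j] <- out[j, i] <- rv
    }
  }
  out
}

#' Effective-tests Bonferroni threshold
#'
#' The study-wide significance threshold
#' `alpha / (m_eff_segments * m_eff_snps * n_meta)`, correcting for the
#' effective number of independent segments, independent SNPs, and the three
#' round-robin meta-analyses.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m_eff_segments effective number of independent segments.
#' @param m_eff_snps effective number of independent SNPs.
#' @param n_meta number of meta-analyses corrected for (default 3).
#' @return an object of class `threshold_spec` with the inputs and
#'   `adjusted_threshold`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_eff_segments, m_eff_snps,
                                 n_meta = 3) {
  vals <- c(alpha, m_eff_segments, m_eff_snps, n_meta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all threshold inputs must be positive")
  structure(list(alpha = alpha, m_eff_segments = m_eff_segments,
                 m_eff_snps = m_eff_snps, n_meta = n_meta,
                 adjusted_threshold = alpha / (m_eff_segments * m_eff_snps * n_meta)),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> %g / (%g x %g x %g) = %.3g\n", x$alpha,
              x$m_eff_segments, x$m_eff_snps, x$n_meta, x$adjusted_threshold))
  invisible(x)
}

#' Round-robin discovery/replication meta-analysis
#'
#' For every SNP and segment, each cohort serves once as discovery: a
#' [cca_test()] on that cohort's (within-cohort centred) segment scores
#' against its residualized genotype defines loadings, onto which the other
#' two cohorts are projected and tested one-sidedly with
#' [project_and_test()]. Each discovery row's three p-values come from
#' non-overlapping cohorts and are combined with [stouffer_combine()],
#' yielding nine constituent p-values and three meta p-values per
#' (SNP, segment). A (SNP, segment, discovery) result is flagged significant
#' when its meta p falls below the adjusted threshold.
#'
#' @param seg_pca pooled [segment_pca()] (cohort labels inside).
#' @param genotype_residuals named list (one element per cohort, in cohort
#'   label order) of `n_c x n_snp` residualized genotype matrices with
#'   matching column names.
#' @param threshold a [bonferroni_threshold()] `threshold_spec`, or `NULL`
#'   for no flags.
#' @param n_covariates confounder count absorbed by residualization, passed
#'   through to [cca_test()] and [project_and_test()] df corrections.
#' @param segments optional integer vector of node ids to test (default all
#'   segments in the tree).
#' @return a `meta_table` data frame with one row per (SNP, segment):
#'   `snp_id`, `segment_id`, `level`, `p_disc_<cohort>` (3),
#'   `p_rep_<discovery>_<replication>` (6), `p_meta_<cohort>` (3),
#'   `sig_<cohort>` flags and `significant` (any). The threshold is attached
#'   as attribute `threshold`; per-record loadings are not retained here.
#' @export
run_round_robin <- function(seg_pca, genotype_residuals, threshold = NULL,
                            n_covariates = 0L, segments = NULL) {
  stopifnot(inherits(seg_pca, "segment_pca"))
  cohorts <- names(genotype_residuals)
  if (is.null(cohorts) || length(cohorts) < 2L)
    stop("round-robin needs >= 2 named cohorts (3 expected)")
  if (!all(cohorts %in% unique(seg_pca$cohort)))
    stop("genotype cohort names must match the pooled segment PCA labels")
  snps <- colnames(genotype_residuals[[1]])
  keep <- snps
  for (co in cohorts) {
    absent <- setdiff(keep, colnames(genotype_residuals[[co]]))
    if (length(absent)) {
      warning("skipping SNP(s) missing in ", co, ": ",
              paste(absent, collapse = ", "))
      keep <- setdiff(keep, absent)
    }
  }
  snps <- keep
  rows_by_cohort <- lapply(cohorts, function(co) which(seg_pca$cohort == co))
  names(rows_by_cohort) <- cohorts

  nodes <- seg_pca$tree$nodes
  if (!is.null(segments)) {
    if (!all(segments %in% nodes$node_id)) stop("unknown segment id(s)")
    nodes <- nodes[nodes$node_id %in% segments, , drop = FALSE]
  }
  out <- list()
  for (key in as.character(nodes$node_id)) {
    seg <- seg_pca$segments[[key]]
    scores_by_cohort <- lapply(rows_by_cohort, function(r)
      scale(seg$scores[r, , drop = FALSE], center = TRUE, scale = FALSE))
    lev <- nodes$level[nodes$node_id == as.integer(key)]
    for (s in snps) {
      row <- list(snp_id = s, segment_id = as.integer(key), level = lev)
      for (d in cohorts) {
        g_d <- genotype_residuals[[d]][, s]
        rec <- cca_test(scores_by_cohort[[d]], g_d, n_covariates = n_covariates,
                        snp_id = s, segment_id = as.integer(key), cohort_id = d)
        row[[paste0("p_disc_", d)]] <- rec$p_value
        reps <- setdiff(cohorts, d)
        p_reps <- numeric(0)
        for (r in reps) {
          pr <- project_and_test(rec$loadings, scores_by_cohort[[r]],
                                 genotype_residuals[[r]][, s],
                                 n_covariates = n_covariates,
                                 snp_id = s, segment_id = as.integer(key),
                                 discovery_cohort = d, replication_cohort = r)
          row[[paste0("p_rep_", d, "_", r)]] <- pr$p_value
          p_reps <- c(p_reps, pr$p_value)
        }
        row[[paste0("p_meta_", d)]] <-
          stouffer_combine(c(rec$p_value, p_reps))
      }
      out[[length(out) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, lapply(out, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  if (!is.null(threshold)) {
    stopifnot(inherits(threshold, "threshold_spec"))
    for (d in cohorts)
      tab[[paste0("sig_", d)]] <-
        tab[[paste0("p_meta_", d)]] < threshold$adjusted_threshold
    tab$significant <- Reduce(`|`, lapply(cohorts, function(d) tab[[paste0("sig_", d)]]))
  }
  attr(tab, "threshold") <- threshold
  class(tab) <- c("meta_table", class(tab))
  tab
}

#' Significant SNPs from a meta table
#'
#' A SNP is reported significant when any of its meta p-values falls below
#' the adjusted threshold in any segment for any discovery cohort.
#'
#' @param meta_table a [run_round_robin()] result with flags.
#' @return character vector of significant SNP ids.
#' @export
significant_snps <- function(meta_table) {
  if (is.null(meta_table$significant))
    stop("meta table carries no significance flags; supply a threshold")
  unique(meta_table$snp_id[meta_table$significant])
}
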