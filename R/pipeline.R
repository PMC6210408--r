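#' Run the full global-to-local association pipeline
#'
#' Orchestrates the analysis end to end on three cohorts of
#' correspondence-matched landmark configurations:
#' \enumerate{
#'   \item per cohort: centroid sizes measured on the raw configurations,
#'     generalized Procrustes superimposition, symmetrization against the
#'     template symmetry map, Mahalanobis quality report;
#'   \item per cohort: PLS residualization of shape and genotypes on
#'     age, age squared, sex, weight, height, centroid size and four ancestry
#'     axes;
#'   \item pooled across cohorts: landmark RV similarity, hierarchical
#'     spectral segmentation (template adjacency), per-segment Procrustes +
#'     PCA with parallel analysis;
#'   \item effective numbers of independent segments and SNPs (Li-Ji),
#'     adjusted Bonferroni threshold;
#'   \item round-robin discovery/replication meta-analysis with Stouffer
#'     combination and significance flags.
#' }
#' Fully deterministic given `seed`.
#'
#' @param cohorts a [simulate_cohorts()] object, or any list with the same
#'   shape (`$cohorts`: three elements each holding `shapes`, `genotypes`,
#'   `covariates`; `$template`).
#' @param depth segment-tree depth (default 5: 63 segments).
#' @param pa_reps,pa_percentile parallel-analysis settings.
#' @param alpha family-wise error rate for the adjusted threshold.
#' @param qc_z quality-flag Z threshold (report only; no one is dropped).
#' @param max_pc per-segment cap on retained PCs; the default
#'   `floor(min cohort size / 10)` keeps every per-cohort CCA comfortably
#'   overdetermined (see [segment_pca()]).
#' @param seed integer seed.
#' @param out_dir if non-NULL, outputs (segment tree JSON, meta table TSV, QC
#'   TSV, run manifest JSON) are written there.
#' @return (invisibly) a list: `meta_table`, `threshold`, `tree`, `seg_pca`,
#'   `similarity`, `qc`, `m_eff_segments`, `m_eff_snps`, `significant_snps`.
#' @export
run_pipeline <- function(cohorts, depth = 5L, pa_reps = 100L,
                         pa_percentile = 0.95, alpha = 0.05, qc_z = 2,
                         max_pc = NULL, seed = 1L, out_dir = NULL) {
  core <- pipeline_core(cohorts, depth = depth, pa_reps = pa_reps,
                        pa_percentile = pa_percentile, qc_z = qc_z,
                        max_pc = max_pc, seed = seed)
  corrected <- core$corrected
  pooled_counts <- lapply(cohorts$cohorts, function(co) co$genotypes$counts)

  m_eff_seg <- effective_tests(segment_correlation_matrix(core$seg_pca))
  common_snps <- Reduce(intersect, lapply(pooled_counts, colnames))
  geno_corr <- stats::cor(do.call(rbind, lapply(pooled_counts, function(m)
    m[, common_snps, drop = FALSE])))
  m_eff_snp <- if (length(common_snps) > 1L) effective_tests(geno_corr) else 1
  thr <- bonferroni_threshold(alpha, m_eff_seg, m_eff_snp,
                              n_meta = length(corrected))
  meta <- run_round_robin(core$seg_pca, core$genotype_residuals, threshold = thr,
                          n_covariates = length(corrected[[1]]$covariates_used))

  res <- list(meta_table = meta, threshold = thr, tree = core$tree,
              seg_pca = core$seg_pca, similarity = core$similarity,
              qc = core$qc, corrected = corrected,
              m_eff_segments = m_eff_seg, m_eff_snps = m_eff_snp,
              significant_snps = significant_snps(meta))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_segment_tree(core$tree, file.path(out_dir, "segment_tree.json"))
    write_meta_table(meta, file.path(out_dir, "meta_table.tsv"), seed = seed)
    qc_all <- do.call(rbind, Map(function(df, nm) cbind(cohort = nm, df),
                                 core$qc, names(core$qc)))
    utils::write.table(qc_all, file.path(out_dir, "qc_report.tsv"),
                       row.names = FALSE, quote = FALSE, sep = "\t")
    manifest <- list(package = "segcca",
                     version = as.character(utils::packageVersion("segcca")),
                     seed = seed, depth = depth, pa_reps = pa_reps,
                     pa_percentile = pa_percentile, alpha = alpha,
                     m_eff_segments = m_eff_seg, m_eff_snps = m_eff_snp,
                     adjusted_threshold = thr$adjusted_threshold,
                     cohort_sizes = vapply(corrected, function(x)
                       length(x$ids), integer(1)))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

# Shared preprocessing: per-cohort alignment, symmetrization, QC, correction,
# then pooled similarity, segmentation and per-segment PCA.
pipeline_core <- function(cohorts, depth = 5L, pa_reps = 100L,
                          pa_percentile = 0.95, qc_z = 2, max_pc = NULL,
                          seed = 1L) {
  if (is.null(cohorts$cohorts) || is.null(cohorts$template))
    stop("`cohorts` must carry $cohorts and $template")
  if (length(cohorts$cohorts) < 2L)
    stop("round-robin meta-analysis needs >= 2 cohorts (3 expected)")
  template <- cohorts$template

  corrected <- list(); qc_reports <- list(); geno_res <- list()
  for (nm in names(cohorts$cohorts)) {
    co <- cohorts$cohorts[[nm]]
    cov_tab <- co$covariates
    cov_tab$centroid_size <- apply(co$shapes$coords, 1, centroid_size)
    aligned <- gpa(co$shapes, with_scaling = FALSE)
    symm <- symmetrize(aligned, template$pairs, template$midline)
    qc_reports[[nm]] <- qc_flag(symm, z_threshold = qc_z)
    corr <- correct_dataset(symm, co$genotypes, cov_tab)
    corrected[[nm]] <- corr
    geno_res[[nm]] <- corr$genotype_residuals
  }

  pooled <- do.call(abind3, lapply(corrected, `[[`, "shape_corrected"))
  cohort_labels <- rep(names(corrected),
                       vapply(corrected, function(x) length(x$ids), integer(1)))
  sim <- build_similarity(do.call(rbind, lapply(corrected, `[[`, "shape_residuals")))
  tree <- hierarchical_spectral_cluster(sim, template$adjacency, depth = depth,
                                        seed = seed)
  if (is.null(max_pc)) {
    n_min <- min(vapply(corrected, function(x) length(x$ids), integer(1)))
    max_pc <- max(3L, n_min %/% 10L)
  }
  seg <- segment_pca(pooled, tree, cohort_labels, pa_reps = pa_reps,
                     pa_percentile = pa_percentile, seed = seed + 1L,
                     max_pc = max_pc)
  list(corrected = corrected, genotype_residuals = geno_res, qc = qc_reports,
       similarity = sim, tree = tree, seg_pca = seg)
}

# Bind N x L x 3 arrays along the first dimension.
abind3 <- function(...) {
  arrs <- list(...)
  L <- dim(arrs[[1]])[2]
  out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1], numeric(1))), L, 3))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1]
    out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}
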